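# ggplot2 views of the main result types.

#' MA-style plot of a DE analysis
#'
#' Mean normalized expression (log10) against the maximal absolute log2
#' fold change across contrasts, DE genes highlighted.
#'
#' @param x A `vno_de` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vno_de <- function(x, ...) {
  df <- tidy(x) |>
    group_by(.data$gene_id) |>
    summarise(base_mean = mean((.data$mean_a + .data$mean_b) / 2),
              max_lfc = .data$lfc[which.max(abs(.data$lfc))],
              de = dplyr::first(.data$de), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$base_mean, y = .data$max_lfc,
                                   colour = .data$de)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mean normalized count", y = "max log2 fold change",
                  colour = "DE") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.vno_de
#' @export
plot_ma <- function(x, ...) autoplot.vno_de(x, ...)

#' Genome-wide view of scored windows and called hotspots
#'
#' @param windows Scored windows from [scan_windows()].
#' @param hotspots Hotspot tibble from [call_hotspots()].
#' @return A ggplot object: -log10 window p-values along each chromosome
#'   with hotspot intervals shaded.
#' @export
plot_hotspots <- function(windows, hotspots) {
  p <- ggplot2::ggplot(windows,
                       ggplot2::aes(x = .data$start / 1e6,
                                    y = -log10(pmax(.data$pvalue, 1e-300)))) +
    ggplot2::geom_point(size = 0.4, colour = "grey40") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "-log10 p") +
    ggplot2::theme_minimal()
  if (nrow(hotspots)) {
    p <- p + ggplot2::geom_rect(
      data = hotspots,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, fill = "gold", alpha = 0.3,
      inherit.aes = FALSE)
  }
  p
}

#' Stacked dosage-compensation bar plot
#'
#' Female X expression next to the male X + Y stack per homolog pair.
#'
#' @param dosage Tibble from [dosage_compensation()].
#' @return A ggplot object.
#' @export
plot_dosage <- function(dosage) {
  df <- dosage |>
    tidyr::pivot_longer(c("x_female", "x_male", "y_male"),
                        names_to = "component", values_to = "mean_norm") |>
    mutate(sex = if_else(.data$component == "x_female", "female", "male"),
           chromosome = if_else(startsWith(.data$component, "x"), "X", "Y"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sex, y = .data$mean_norm,
                                   fill = .data$chromosome)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~x_gene, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(X = "firebrick", Y = "steelblue")) +
    ggplot2::labs(x = NULL, y = "mean normalized count") +
    ggplot2::theme_minimal()
}

#' Dendrogram with bootstrap (and AU) support
#'
#' @param x A `vno_boot` object.
#' @param ... Unused.
#' @return A ggplot object drawing the dendrogram with support labels at
#'   internal nodes.
#' @export
autoplot.vno_boot <- function(x, ...) {
  hc <- x$hclust
  n <- length(hc$labels)
  xpos <- setNames(match(seq_len(n), hc$order), hc$labels)
  seg <- list(); nodexy <- matrix(NA_real_, nrow(hc$merge), 2)
  for (i in seq_len(nrow(hc$merge))) {
    xy <- vapply(hc$merge[i, ], function(id) {
      if (id < 0) c(xpos[[hc$labels[-id]]], 0) else nodexy[id, ]
    }, numeric(2))
    seg[[i]] <- tibble(x = xy[1, ], xend = xy[1, ],
                       y = xy[2, ], yend = hc$height[i])
    seg[[length(seg) + 1]] <- tibble(x = xy[1, 1], xend = xy[1, 2],
                                     y = hc$height[i], yend = hc$height[i])
    nodexy[i, ] <- c(mean(xy[1, ]), hc$height[i])
  }
  segs <- list_rbind(seg)
  keys <- bipartition_keys(hc)
  sup <- x$support
  node_lab <- tibble(
    x = nodexy[, 1], y = nodexy[, 2],
    label = vapply(keys, function(k) {
      row <- sup[sup$leaves == k, ]
      if (!nrow(row)) return("")
      if ("au" %in% names(sup)) {
        sprintf("au %.0f / bp %.0f", 100 * row$au[[1]], 100 * row$bp[[1]])
      } else sprintf("bp %.0f", 100 * row$bp[[1]])
    }, character(1)))
  tips <- tibble(x = unname(xpos), y = 0, label = names(xpos))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = node_lab,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
                       vjust = -0.4, size = 3) +
    ggplot2::geom_text(data = tips,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
                       vjust = 1.5) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.15, 0.1))) +
    ggplot2::labs(x = NULL, y = "1 - Spearman distance (average linkage)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @rdname autoplot.vno_boot
#' @export
plot_dendrogram <- function(x, ...) autoplot.vno_boot(x, ...)
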