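# Sex-dimorphism calling across strains, within-strain sex DE, and X/Y
# homolog dosage-compensation accounting.
#
# A gene counts as sexually dimorphic only when the male/female difference
# is consistent across every strain: weighted fold change > fc, p < alpha,
# and the per-strain fold changes all point the same way.

#' Cross-strain sex-dimorphism screen
#'
#' Per gene and strain the male/female log2 fold change is computed on
#' normalized group means (pseudocount `c`); the weighted fold change is
#' the weight-averaged (by default sample-size-weighted) geometric mean of
#' per-strain fold changes, i.e. `2^(sum(w * lfc) / sum(w))`.  Its
#' standard error combines per-strain delta-method variances, and the
#' dimorphic flag requires `|weighted FC| > fc`, `p < alpha`, and --
#' optionally but by default -- the same direction in every strain.
#'
#' @param counts Counts tibble.
#' @param meta Sample metadata (every strain needs >= 2 samples per sex).
#' @param fc Fold-change threshold (default 2).
#' @param alpha P-value threshold (default 0.01; a plain p cutoff, not FDR).
#' @param weighting `"sample_size"` (w = strain sample count) or `"equal"`.
#' @param variance `"pooled"` (dispersion from strain x sex groups over
#'   all samples) or `"per_strain"` (dispersion re-estimated within each
#'   strain).
#' @param require_consistent_direction Demand the per-strain fold changes
#'   share a sign (default TRUE).
#' @param pseudocount Pseudocount on normalized means.
#' @return A `vno_dimorphism` object; `tidy()` gives the per-gene table,
#'   `$per_strain` the per-strain log fold changes.
#' @export
sex_dimorphism_cross_strain <- function(counts, meta, fc = 2, alpha = 0.01,
                                        weighting = c("sample_size", "equal"),
                                        variance = c("pooled", "per_strain"),
                                        require_consistent_direction = TRUE,
                                        pseudocount = 0.5) {
  weighting <- match.arg(weighting)
  variance <- match.arg(variance)
  validate_meta(meta, counts)
  strains <- unique(meta$strain)
  for (s in strains) {
    tab <- table(meta$sex[meta$strain == s])
    if (length(tab) < 2 || any(tab < 2)) {
      abort(sprintf("strain '%s' lacks >= 2 samples of each sex", s))
    }
  }
  norm <- estimate_size_factors(counts)
  nm <- norm_matrix(norm)
  meta <- meta[match(colnames(nm), meta$sample_id), ]
  disp_all <- estimate_dispersion(norm, meta)

  per_strain <- list_rbind(map(strains, function(s) {
    sel <- meta$strain == s
    male <- sel & meta$sex == "male"
    female <- sel & meta$sex == "female"
    mm <- rowMeans(nm[, male, drop = FALSE])
    mf <- rowMeans(nm[, female, drop = FALSE])
    a <- if (variance == "pooled") {
      disp_all$alpha
    } else {
      sub_norm <- structure(list(normalized = matrix_to_counts(
        nm[, sel, drop = FALSE])), class = "vno_norm")
      estimate_dispersion(sub_norm, meta[sel, ])$alpha
    }
    lfc <- log2((mm + pseudocount) / (mf + pseudocount))
    v <- ((mm + a * mm^2) / sum(male) / (mm + pseudocount)^2 +
            (mf + a * mf^2) / sum(female) / (mf + pseudocount)^2) / log(2)^2
    tibble(gene_id = rownames(nm), strain = s, n = sum(sel),
           lfc = unname(lfc), var_lfc = unname(v))
  }))

  res <- per_strain |>
    mutate(w = if (weighting == "sample_size") .data$n else 1) |>
    group_by(.data$gene_id) |>
    summarise(
      weighted_lfc = sum(.data$w * .data$lfc) / sum(.data$w),
      se = sqrt(sum(.data$w^2 * .data$var_lfc)) / sum(.data$w),
      consistent = all(.data$lfc > 0) || all(.data$lfc < 0),
      .groups = "drop") |>
    mutate(weighted_fc = 2^.data$weighted_lfc,
           stat = .data$weighted_lfc / .data$se,
           # t reference with the pooled-variance df, as in wald_test()
           pvalue = 2 * stats::pt(-abs(.data$stat),
                                  df = max(1L, nrow(meta) -
                                             nlevels(interaction(meta$strain,
                                                                 meta$sex,
                                                                 drop = TRUE)))),
           pvalue = if_else(is.na(.data$pvalue), 1, .data$pvalue),
           dimorphic = 2^abs(.data$weighted_lfc) > fc &
             .data$pvalue < alpha &
             (!require_consistent_direction | .data$consistent),
           direction = if_else(.data$weighted_lfc > 0, "male", "female"))

  structure(list(result = res, per_strain = per_strain, fc = fc,
                 alpha = alpha, weighting = weighting, variance = variance),
            class = "vno_dimorphism")
}

#' @export
print.vno_dimorphism <- function(x, ...) {
  cat("<vno_dimorphism> ", nrow(x$result), " genes, ",
      sum(x$result$dimorphic), " dimorphic (FC > ", x$fc,
      ", p < ", x$alpha, ", consistent across strains)\n", sep = "")
  invisible(x)
}

#' @rdname sex_dimorphism_cross_strain
#' @param x A `vno_dimorphism` object.
#' @param ... Unused.
#' @export
tidy.vno_dimorphism <- function(x, ...) x$result

#' @rdname sex_dimorphism_cross_strain
#' @export
glance.vno_dimorphism <- function(x, ...) {
  tibble(n_genes = nrow(x$result), n_dimorphic = sum(x$result$dimorphic),
         fc = x$fc, alpha = x$alpha, weighting = x$weighting)
}

#' Within-strain sex differential expression
#'
#' Runs the NB Wald test male vs female separately inside each strain
#' (catching strain-by-sex effects that vanish when strains are pooled --
#' the Simpson's-paradox cases), BH-corrects per strain, and reports genes
#' significant in at least one strain with their strain labels.
#'
#' @param counts Counts tibble.
#' @param meta Sample metadata.
#' @param fc Fold-change threshold.
#' @param fdr FDR threshold (per-strain BH).
#' @return List: `per_strain` (tibble of Wald rows with `strain`,
#'   `qvalue`, `significant`) and `combined` (one row per reported gene
#'   with comma-joined `strains`).
#' @export
within_strain_sex_de <- function(counts, meta, fc = 2, fdr = 0.05) {
  validate_meta(meta, counts)
  norm <- estimate_size_factors(counts)
  nm <- norm_matrix(norm)
  meta <- meta[match(colnames(nm), meta$sample_id), ]
  per_strain <- list_rbind(map(unique(meta$strain), function(s) {
    sel <- meta$strain == s
    sub_norm <- structure(list(normalized = matrix_to_counts(
      nm[, sel, drop = FALSE])), class = "vno_norm")
    sub_meta <- meta[sel, ]
    disp <- estimate_dispersion(sub_norm, sub_meta)
    wald_test(sub_norm, sub_meta, c("male", "female"), disp,
              group_by = "sex") |>
      mutate(strain = s, qvalue = bh_fdr(.data$pvalue),
             significant = abs(.data$lfc) > log2(fc) & .data$qvalue < fdr)
  }))
  combined <- per_strain |>
    filter(.data$significant) |>
    group_by(.data$gene_id) |>
    summarise(strains = paste(sort(unique(.data$strain)), collapse = ","),
              n_strains = dplyr::n_distinct(.data$strain),
              max_abs_lfc = max(abs(.data$lfc)), .groups = "drop")
  list(per_strain = per_strain, combined = combined)
}

#' Dosage-compensation accounting for X/Y homolog pairs
#'
#' Per pair, normalized group means by sex; the combined male value is the
#' exact sum of the male X and male Y means, and the compensation ratio is
#' `female X / (male X + male Y)`.  Nonzero Y counts in females are a
#' biological impossibility in the input and raise an error.
#'
#' @param norm A `vno_norm`.
#' @param meta Sample metadata.
#' @param xy_pairs Tibble with columns `x_gene`, `y_gene`.
#' @return Tibble: `x_gene, y_gene, x_female, x_male, y_male,
#'   combined_male, ratio`.
#' @export
dosage_compensation <- function(norm, meta, xy_pairs) {
  nm <- norm_matrix(norm)
  validate_meta(meta)
  meta <- meta[match(colnames(nm), meta$sample_id), ]
  genes <- c(xy_pairs$x_gene, xy_pairs$y_gene)
  miss <- setdiff(genes, rownames(nm))
  if (length(miss)) abort(paste("pair gene(s) absent:", paste(miss, collapse = ", ")))
  female <- meta$sex == "female"; male <- meta$sex == "male"
  ycounts <- nm[xy_pairs$y_gene, female, drop = FALSE]
  if (any(ycounts > 0)) {
    abort("nonzero Y-homolog counts in female samples: invalid input")
  }
  tibble(
    x_gene = xy_pairs$x_gene, y_gene = xy_pairs$y_gene,
    x_female = rowMeans(nm[xy_pairs$x_gene, female, drop = FALSE]),
    x_male = rowMeans(nm[xy_pairs$x_gene, male, drop = FALSE]),
    y_male = rowMeans(nm[xy_pairs$y_gene, male, drop = FALSE])
  ) |>
    mutate(combined_male = .data$x_male + .data$y_male,
           ratio = .data$x_female / .data$combined_male)
}
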