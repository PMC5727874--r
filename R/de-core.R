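# Negative-binomial differential-expression core: median-of-ratios size
# factors, method-of-moments dispersion, delta-method Wald tests on log2
# group means, BH correction, outlier-based independent filtering, and the
# DE classification (FC > 2, FDR < 0.05 in any pairwise strain contrast)
# every downstream stage consumes.

#' Median-of-ratios size factors
#'
#' For each sample j, `s_j` is the median over genes positive in all
#' samples of `count_gj / geometric_mean_g`, rescaled so the size factors
#' have geometric mean 1.  Normalized counts are `count / s_j`.
#'
#' @param counts Counts tibble (`gene_id` + sample columns).
#' @return A `vno_norm` list: `size_factors` tibble (`sample_id`,
#'   `size_factor`) and `normalized` tibble (same shape as `counts`).
#' @export
estimate_size_factors <- function(counts) {
  m <- counts_matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    abort(paste("no gene has positive counts in every sample;",
                "pseudo-reference fallback is disabled"))
  }
  ref <- exp(rowMeans(log(m[pos, , drop = FALSE])))
  sf <- apply(m[pos, , drop = FALSE] / ref, 2, median)
  sf <- sf / geometric_mean(sf)
  norm <- sweep(m, 2, sf, "/")
  structure(list(
    size_factors = tibble(sample_id = colnames(m), size_factor = unname(sf)),
    normalized = matrix_to_counts(norm)
  ), class = "vno_norm")
}

# normalized counts as a matrix
norm_matrix <- function(norm) counts_matrix(norm$normalized)

#' Method-of-moments NB dispersion per gene
#'
#' With groups defined by strain x sex, the pooled within-group variance v
#' and grand mean m of normalized counts give
#' `alpha_hat = max(0, (v - m) / m^2)` (Var = mu + alpha mu^2).  Genes with
#' all-zero counts are flagged, not estimated.
#'
#' @param norm A `vno_norm` from [estimate_size_factors()].
#' @param meta Sample metadata.
#' @return Tibble: `gene_id`, `alpha`, `all_zero`, `method`.
#' @export
estimate_dispersion <- function(norm, meta) {
  m <- norm_matrix(norm)
  validate_meta(meta)
  meta <- meta[match(colnames(m), meta$sample_id), ]
  grp <- interaction(meta$strain, meta$sex, drop = TRUE)
  if (max(table(grp)) < 2) abort("single-replicate design: dispersion unidentifiable")
  # pooled within-group variance: sum of squared residuals / (n - k)
  k <- nlevels(grp)
  n <- ncol(m)
  group_means <- matrix(vapply(levels(grp), function(g)
    rowMeans(m[, grp == g, drop = FALSE]), numeric(nrow(m))), nrow = nrow(m))
  fitted <- group_means[, as.integer(grp), drop = FALSE]
  ss <- rowSums((m - fitted)^2)
  v <- ss / (n - k)
  mu <- rowMeans(m)
  alpha <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), 0)
  tibble(gene_id = rownames(m), alpha = unname(alpha),
         all_zero = unname(mu == 0), method = "moments_pooled")
}

#' NB Wald test for one pairwise contrast
#'
#' The log2 fold change is `log2((mean_A + c) / (mean_B + c))` on
#' normalized group means with pseudocount `c`; its standard error comes
#' from the delta method with NB variance `mu + alpha mu^2` for each group
#' mean.  The two-sided p-value uses a t reference with the degrees of
#' freedom of the pooled variance behind the dispersion estimate
#' (samples minus strain-by-sex cells): at replicate-level sample sizes a
#' standard-normal tail is visibly anticonservative at the 1% level,
#' while the t tail keeps the null calibrated.
#'
#' @param norm A `vno_norm`.
#' @param meta Sample metadata.
#' @param contrast Length-2 character vector `(groupA, groupB)` of strain
#'   labels (or sex labels with `group_by = "sex"`).
#' @param dispersion Tibble from [estimate_dispersion()].
#' @param group_by Metadata column defining groups (default `"strain"`).
#' @param pseudocount Stabilizing constant `c` (normalized counts).
#' @return Tibble: `gene_id, contrast, mean_a, mean_b, lfc, se, stat,
#'   pvalue`.
#' @export
wald_test <- function(norm, meta, contrast, dispersion,
                      group_by = "strain", pseudocount = 0.5) {
  m <- norm_matrix(norm)
  validate_meta(meta)
  meta <- meta[match(colnames(m), meta$sample_id), ]
  g <- meta[[group_by]]
  if (!all(contrast %in% g)) {
    abort(sprintf("contrast group(s) absent from metadata: %s",
                  paste(setdiff(contrast, g), collapse = ", ")))
  }
  a <- g == contrast[1]; b <- g == contrast[2]
  if (sum(a) < 2 || sum(b) < 2) abort("both contrast groups need >= 2 samples")
  alpha <- dispersion$alpha[match(rownames(m), dispersion$gene_id)]
  if (anyNA(alpha)) abort("dispersion missing for some genes")
  ma <- rowMeans(m[, a, drop = FALSE])
  mb <- rowMeans(m[, b, drop = FALSE])
  lfc <- log2((ma + pseudocount) / (mb + pseudocount))
  va <- (ma + alpha * ma^2) / sum(a)
  vb <- (mb + alpha * mb^2) / sum(b)
  se <- sqrt(va / (ma + pseudocount)^2 + vb / (mb + pseudocount)^2) / log(2)
  se[se == 0] <- NA_real_
  stat <- lfc / se
  df <- ncol(m) - nlevels(interaction(meta$strain, meta$sex, drop = TRUE))
  p <- if (df >= 1) 2 * stats::pt(-abs(stat), df) else 2 * pnorm(-abs(stat))
  p[is.na(p)] <- 1  # zero-variance genes carry no evidence
  tibble(gene_id = rownames(m),
         contrast = paste(contrast, collapse = "_vs_"),
         mean_a = unname(ma), mean_b = unname(mb),
         lfc = unname(lfc), se = unname(se),
         stat = unname(stat), pvalue = unname(p))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment (delegates to [stats::p.adjust()]) with input
#' validation; `q_i >= p_i` always holds.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Outlier-based independent filtering
#'
#' A Cook's-distance analogue per gene and sample:
#' `D = (count - group_mean)^2 / (k * (mu + alpha mu^2))` with `k` the
#' number of fitted group means; a gene is filtered when any sample
#' exceeds the `F(k, n - k)` quantile at `cutoff_quantile`.
#'
#' Without dispersion shrinkage an extreme outlier inflates its own
#' gene's moment dispersion and masks itself, so each sample's distance
#' is computed leave-one-out: the group mean, the pooled within-group
#' variance and hence the NB variance exclude the sample being tested
#' (variance stays pooled over all groups, so it keeps `n - k - 1`
#' degrees of freedom and the F cutoff its calibration).
#'
#' @param norm A `vno_norm`.
#' @param meta Sample metadata.
#' @param dispersion Tibble from [estimate_dispersion()] (fallback for
#'   genes whose leave-one-out variance is degenerate).
#' @param group_by Grouping column (default `"strain"`).
#' @param cutoff_quantile F quantile above which a gene is filtered.
#' @param enabled Set `FALSE` to disable (no gene filtered).
#' @return Tibble: `gene_id`, `max_cooks`, `filtered`.
#' @export
independent_filter <- function(norm, meta, dispersion, group_by = "strain",
                               cutoff_quantile = 0.99, enabled = TRUE) {
  m <- norm_matrix(norm)
  validate_meta(meta)
  meta <- meta[match(colnames(m), meta$sample_id), ]
  grp <- factor(meta[[group_by]])
  k <- nlevels(grp)
  n <- ncol(m)
  ng <- as.numeric(table(grp)[as.character(grp)])      # group size per sample
  group_means <- matrix(vapply(levels(grp), function(g)
    rowMeans(m[, grp == g, drop = FALSE]), numeric(nrow(m))), nrow = nrow(m))
  fitted <- group_means[, as.integer(grp), drop = FALSE]
  resid <- m - fitted
  ss_total <- rowSums(resid^2)
  grand <- rowMeans(m)

  # leave-one-out group mean, pooled variance and dispersion per sample
  ngm <- matrix(ng, nrow(m), n, byrow = TRUE)
  mu_loo <- (ngm * fitted - m) / pmax(ngm - 1, 1)
  ss_loo <- pmax(ss_total - (ngm / pmax(ngm - 1, 1)) * resid^2, 0)
  v_loo <- ss_loo / max(n - k - 1, 1)
  # moment dispersion: pooled variance sits at the group means, so use
  # E[mu] and E[mu^2] over the fitted group means, not the grand mean
  mbar <- rowMeans(fitted)
  m2bar <- rowMeans(fitted^2)
  alpha_loo <- pmax(0, (v_loo - mbar) / m2bar)
  fallback <- dispersion$alpha[match(rownames(m), dispersion$gene_id)]
  bad <- !is.finite(alpha_loo)
  alpha_loo[bad] <- matrix(fallback, nrow(m), n)[bad]

  nbvar <- mu_loo + alpha_loo * mu_loo^2
  # (y - mu_loo) has variance sigma^2 * ng/(ng-1); rescale to the
  # within-group residual scale before comparing with the F quantile
  d <- ((m - mu_loo)^2 * (ngm - 1) / ngm) / (k * nbvar)
  d[!is.finite(d)] <- 0
  mx <- apply(d, 1, max)
  cut <- qf(cutoff_quantile, k, n - k)
  tibble(gene_id = rownames(m), max_cooks = unname(mx),
         filtered = if (enabled) unname(mx > cut) else FALSE)
}

#' Classify genes as DE across pairwise contrasts
#'
#' A gene is differentially expressed when, in at least one contrast, it
#' passes independent filtering, `|lfc| > log2(fc_threshold)` and
#' `q < fdr`.
#'
#' @param de_tables Tibble of Wald results for all required contrasts
#'   (rows from [wald_test()], with a `qvalue` column added per contrast).
#' @param filter Tibble from [independent_filter()].
#' @param contrasts Character vector of contrast labels that must all be
#'   present (error otherwise).
#' @param fc_threshold Fold-change threshold (default 2).
#' @param fdr FDR threshold (default 0.05).
#' @return Tibble: `gene_id`, `de`, `n_sig_contrasts`, `max_abs_lfc`.
#' @export
classify_de <- function(de_tables, filter, contrasts = NULL,
                        fc_threshold = 2, fdr = 0.05) {
  if (!is.null(contrasts)) {
    miss <- setdiff(contrasts, unique(de_tables$contrast))
    if (length(miss)) abort(paste("missing contrast(s):", paste(miss, collapse = ", ")))
  }
  if (!"filtered" %in% names(de_tables)) {
    de_tables <- left_join(de_tables, select(filter, "gene_id", "filtered"),
                           by = "gene_id")
  }
  de_tables |>
    group_by(.data$gene_id) |>
    summarise(
      n_sig_contrasts = sum(!.data$filtered & abs(.data$lfc) > log2(fc_threshold) &
                              .data$qvalue < fdr, na.rm = TRUE),
      max_abs_lfc = max(abs(.data$lfc)),
      .groups = "drop") |>
    mutate(de = .data$n_sig_contrasts > 0) |>
    select("gene_id", "de", "n_sig_contrasts", "max_abs_lfc")
}

#' Transcripts per million
#'
#' `tpm_gj = 1e6 * (count_gj / length_g) / sum_g(count_gj / length_g)`;
#' every sample column sums to 1e6.
#'
#' @param counts Counts tibble.
#' @param annotation Annotation tibble supplying `length_bp`.
#' @return Tibble of TPM values, same shape as `counts`.
#' @export
tpm <- function(counts, annotation) {
  m <- counts_matrix(counts)
  len <- annotation$length_bp[match(rownames(m), annotation$gene_id)]
  if (anyNA(len)) abort("annotation missing for some genes in counts")
  if (any(len <= 0)) abort("zero or negative gene length")
  rate <- m / len
  matrix_to_counts(sweep(rate, 2, colSums(rate), "/") * 1e6)
}

#' Expression flags per gene and per strain
#'
#' "Expressed (any sample)": raw count > `min_count` in at least one
#' sample.  "Expressed in a strain": mean normalized count >
#' `strain_threshold` over that strain's samples.
#'
#' @param counts Counts tibble.
#' @param norm A `vno_norm`.
#' @param meta Sample metadata.
#' @param min_count Raw-count threshold for "expressed anywhere" (default 0).
#' @param strain_threshold Normalized-mean threshold per strain (default 1).
#' @return List: `expressed` tibble (`gene_id`, `expressed`) and
#'   `by_strain` tibble (`gene_id`, `strain`, `expressed`).
#' @export
expression_flags <- function(counts, norm, meta, min_count = 0,
                             strain_threshold = 1) {
  m <- counts_matrix(counts)
  nm <- norm_matrix(norm)
  validate_meta(meta)
  meta <- meta[match(colnames(m), meta$sample_id), ]
  strains <- unique(meta$strain)
  by_strain <- list_rbind(map(strains, function(s) {
    tibble(gene_id = rownames(nm), strain = s,
           expressed = unname(rowMeans(nm[, meta$strain == s, drop = FALSE]) >
                                strain_threshold))
  }))
  list(expressed = tibble(gene_id = rownames(m),
                          expressed = unname(rowSums(m > min_count) > 0)),
       by_strain = by_strain)
}

#' Full DE analysis across all pairwise strain contrasts
#'
#' Convenience wrapper running normalization, dispersion estimation, the
#' Wald test for every pairwise strain contrast, per-contrast BH
#' correction, independent filtering and final DE classification.
#'
#' @param counts Counts tibble.
#' @param meta Sample metadata.
#' @param fc_threshold,fdr Classification thresholds.
#' @param filter_outliers Apply independent filtering (default TRUE).
#' @param pseudocount Pseudocount for the log2 fold change.
#' @return A `vno_de` object; see [tidy.vno_de()] and [glance.vno_de()].
#' @export
de_analysis <- function(counts, meta, fc_threshold = 2, fdr = 0.05,
                        filter_outliers = TRUE, pseudocount = 0.5) {
  validate_meta(meta, counts)
  norm <- estimate_size_factors(counts)
  disp <- estimate_dispersion(norm, meta)
  strains <- unique(meta$strain)
  pairs <- utils::combn(strains, 2, simplify = FALSE)
  tabs <- list_rbind(map(pairs, function(ct) {
    tab <- wald_test(norm, meta, ct, disp, pseudocount = pseudocount)
    mutate(tab, qvalue = bh_fdr(.data$pvalue))
  }))
  filt <- independent_filter(norm, meta, disp, enabled = filter_outliers)
  tabs <- tabs |>
    left_join(select(filt, "gene_id", "filtered"), by = "gene_id") |>
    mutate(qvalue = if_else(.data$filtered, NA_real_, .data$qvalue))
  cls <- classify_de(mutate(tabs, qvalue = if_else(is.na(.data$qvalue), 1, .data$qvalue)),
                     filt,
                     contrasts = map_chr(pairs, paste, collapse = "_vs_"),
                     fc_threshold = fc_threshold, fdr = fdr)
  structure(list(table = tabs, classification = cls, norm = norm,
                 dispersion = disp, filter = filt, meta = meta,
                 fc_threshold = fc_threshold, fdr = fdr),
            class = "vno_de")
}

#' @export
print.vno_de <- function(x, ...) {
  cat("<vno_de> ", length(unique(x$table$gene_id)), " genes, ",
      length(unique(x$table$contrast)), " contrasts; ",
      sum(x$classification$de), " DE (FC > ", x$fc_threshold,
      ", FDR < ", x$fdr, ")\n", sep = "")
  invisible(x)
}

#' Tidy a DE analysis into one row per gene and contrast
#'
#' @param x A `vno_de` object.
#' @param ... Unused.
#' @return Tibble with per-contrast Wald statistics, q-values and the
#'   gene-level DE flag.
#' @export
tidy.vno_de <- function(x, ...) {
  left_join(x$table, select(x$classification, "gene_id", "de"), by = "gene_id")
}

#' One-row summary of a DE analysis
#'
#' @param x A `vno_de` object.
#' @param ... Unused.
#' @return Tibble: gene totals, DE count and rate, filtered count.
#' @export
glance.vno_de <- function(x, ...) {
  tibble(n_genes = nrow(x$classification),
         n_contrasts = length(unique(x$table$contrast)),
         n_de = sum(x$classification$de),
         de_rate = mean(x$classification$de),
         n_filtered = sum(x$filter$filtered))
}
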