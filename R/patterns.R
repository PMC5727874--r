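# Strain-exclusive expression classification, Venn-style strain-sharing
# counts, and per-family "lacking expression" summaries.

#' Per-gene presence/absence patterns across strains
#'
#' Two absence rules are offered because "no expression" can reasonably
#' mean either literally zero raw counts in every sample of a strain
#' (`zero_raw`, the default) or a strain-mean normalized count at or
#' below one (`mean_norm_gt1`).  Borderline genes can flip between rules.
#'
#' @param counts Counts tibble.
#' @param meta Sample metadata.
#' @param rule `"zero_raw"` or `"mean_norm_gt1"`.
#' @param norm Optional `vno_norm` (required for `mean_norm_gt1`;
#'   computed if missing).
#' @return Tibble: `gene_id`, one logical presence column per strain,
#'   `n_strains` (strains expressing), `pattern` string (e.g. `"B6+SJL"`),
#'   and `class` in `{all_strains, missing_in_k, single_strain, none}`.
#' @export
presence_patterns <- function(counts, meta, rule = c("zero_raw", "mean_norm_gt1"),
                              norm = NULL) {
  rule <- match.arg(rule)
  validate_meta(meta, counts)
  strains <- unique(meta$strain)
  if (rule == "zero_raw") {
    m <- counts_matrix(counts)
    present <- vapply(strains, function(s)
      rowSums(m[, meta$sample_id[meta$strain == s], drop = FALSE]) > 0,
      logical(nrow(m)))
  } else {
    norm <- norm %||% estimate_size_factors(counts)
    nm <- norm_matrix(norm)
    present <- vapply(strains, function(s)
      rowMeans(nm[, meta$sample_id[meta$strain == s], drop = FALSE]) > 1,
      logical(nrow(nm)))
  }
  n_strains <- rowSums(present)
  pattern <- apply(present, 1, function(x) paste(strains[x], collapse = "+"))
  cls <- case_when(n_strains == length(strains) ~ "all_strains",
                   n_strains == 1 ~ "single_strain",
                   n_strains == 0 ~ "none",
                   TRUE ~ "missing_in_k")
  out <- as_tibble(present)
  names(out) <- strains
  bind_cols(tibble(gene_id = counts$gene_id), out,
            tibble(n_strains = as.integer(n_strains),
                   pattern = unname(pattern), class = unname(cls)))
}

#' Venn-style counts over nonempty strain subsets
#'
#' @param patterns Output of [presence_patterns()] (typically restricted
#'   to DE genes before calling).
#' @return Tibble: `subset` (strain combination), `n_strains`, `n_genes`;
#'   one row per nonempty subset (2^S - 1 rows), whose counts sum to the
#'   number of genes expressed in at least one strain.
#' @export
venn_counts <- function(patterns) {
  strains <- setdiff(names(patterns), c("gene_id", "n_strains", "pattern", "class"))
  subsets <- unlist(map(seq_along(strains), function(k)
    utils::combn(strains, k, function(x) paste(x, collapse = "+"),
                 simplify = FALSE)), recursive = FALSE)
  counts <- table(factor(patterns$pattern[patterns$n_strains > 0],
                         levels = unlist(subsets)))
  tibble(subset = names(counts),
         n_strains = stringr::str_count(names(counts), stringr::fixed("+")) + 1L,
         n_genes = as.integer(counts))
}

#' Per-family summary of genes lacking expression in >= 1 strain
#'
#' @param patterns Output of [presence_patterns()] restricted to the genes
#'   of interest (e.g. DE chemoreceptors).
#' @param annotation Annotation tibble supplying `family`.
#' @return Tibble: `family, n_lacking, n_total, pct` (1 dp, half-up),
#'   one row per family present among the input genes.
#' @export
family_lacking_summary <- function(patterns, annotation) {
  strains <- setdiff(names(patterns), c("gene_id", "n_strains", "pattern", "class"))
  patterns |>
    left_join(select(annotation, "gene_id", "family"), by = "gene_id") |>
    filter(!is.na(.data$family)) |>
    group_by(.data$family) |>
    summarise(n_lacking = sum(.data$n_strains < length(strains)),
              n_total = n(), .groups = "drop") |>
    mutate(pct = round_half_up(100 * .data$n_lacking / .data$n_total, 1))
}
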