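# Sliding-window Poisson scan for genomic regions enriched in DE genes.
#
# Windows hold a fixed number of *expressed* genes (default 25) and slide
# one gene at a time along each chromosome; the expected DE count per
# window is W * genome_de_rate and the p-value is the inclusive Poisson
# upper tail P(X >= k).  Significant windows (genome-wide BH) sharing a
# gene on the same chromosome merge into hotspots.

#' Build sliding windows of expressed genes
#'
#' @param annotation Annotation tibble (sorted or not; sorted internally).
#' @param expressed_ids Gene ids considered expressed.
#' @param window Number of expressed genes per window (>= 2).
#' @param step Step in genes between window starts (default 1).
#' @return Tibble: `chrom, window_index, first_idx, last_idx, start, end,
#'   gene_ids` (list column).  Chromosomes with fewer than `window`
#'   expressed genes contribute no windows.
#' @export
sliding_windows <- function(annotation, expressed_ids, window = 25L, step = 1L) {
  if (window < 2) abort("window must be >= 2")
  if (step < 1) abort("step must be >= 1")
  miss <- setdiff(expressed_ids, annotation$gene_id)
  if (length(miss)) abort(paste("expressed ids missing from annotation:",
                                paste(utils::head(miss, 3), collapse = ", ")))
  ann <- annotation |>
    filter(.data$gene_id %in% expressed_ids) |>
    arrange(.data$chrom, .data$start)
  out <- ann |>
    group_by(.data$chrom) |>
    dplyr::group_map(function(g, key) {
      n <- nrow(g)
      if (n < window) return(NULL)
      starts <- seq(1L, n - window + 1L, by = step)
      tibble(chrom = key$chrom[[1]],
             window_index = seq_along(starts),
             first_idx = starts,
             last_idx = starts + window - 1L,
             start = g$start[starts],
             end = g$end[starts + window - 1L],
             gene_ids = map(starts, function(s) g$gene_id[s:(s + window - 1L)]))
    }) |>
    keep(Negate(is.null))
  if (!length(out)) {
    return(tibble(chrom = character(), window_index = integer(),
                  first_idx = integer(), last_idx = integer(),
                  start = integer(), end = integer(), gene_ids = list()))
  }
  list_rbind(out)
}

#' Inclusive Poisson upper-tail test for a window's DE count
#'
#' `p = P(X >= k)` for `X ~ Poisson(lambda = window * genome_de_rate)`.
#'
#' @param k Observed DE genes in the window (vectorized).
#' @param window Window size in expressed genes.
#' @param genome_de_rate Genome-wide DE fraction, in (0, 1).
#' @return P-values (1 when `k = 0`).
#' @export
window_poisson_test <- function(k, window, genome_de_rate) {
  if (genome_de_rate <= 0 || genome_de_rate >= 1) {
    abort("genome_de_rate must be in (0, 1)")
  }
  if (any(k < 0 | k > window)) abort("k must be in [0, window]")
  ppois(k - 1, lambda = window * genome_de_rate, lower.tail = FALSE)
}

#' Score sliding windows against the genome-wide DE rate
#'
#' Convenience wrapper: builds the windows, counts DE members, fills
#' `lambda`, `pvalue` and the genome rate (computed as total DE / total
#' expressed over the same expressed set unless supplied).
#'
#' @inheritParams sliding_windows
#' @param de_ids Gene ids flagged DE.
#' @param genome_de_rate Override for the genome-wide rate.
#' @return The window tibble with `k`, `lambda`, `pvalue` columns; the
#'   rate used is attached as attribute `genome_de_rate`.
#' @export
scan_windows <- function(annotation, expressed_ids, de_ids, window = 25L,
                         step = 1L, genome_de_rate = NULL) {
  de_ids <- intersect(de_ids, expressed_ids)
  rate <- genome_de_rate %||% (length(de_ids) / length(expressed_ids))
  w <- sliding_windows(annotation, expressed_ids, window, step)
  w$k <- map_int(w$gene_ids, function(g) sum(g %in% de_ids))
  w$lambda <- window * rate
  w$pvalue <- if (nrow(w)) window_poisson_test(w$k, window, rate) else numeric()
  attr(w, "genome_de_rate") <- rate
  w
}

#' Call hotspots from scored windows
#'
#' BH correction is applied genome-wide across all windows; significant
#' windows on the same chromosome that share at least one gene are merged,
#' and each hotspot's interval, expressed/DE totals and prominent families
#' are computed from the union of member genes.
#'
#' @param windows Scored windows from [scan_windows()].
#' @param annotation Annotation tibble (for family labels).
#' @param de_ids DE gene ids (to recount within merged hotspots).
#' @param fdr BH threshold (default 0.05).
#' @return Tibble: `chrom, start, end, span_mb, n_expressed, n_de,
#'   pct_de, families, gene_ids` -- one row per hotspot, sorted by
#'   (chrom, start).
#' @export
call_hotspots <- function(windows, annotation, de_ids, fdr = 0.05) {
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  span_mb = numeric(), n_expressed = integer(),
                  n_de = integer(), pct_de = numeric(),
                  families = character(), gene_ids = list())
  if (!nrow(windows)) return(empty)
  windows$qvalue <- bh_fdr(windows$pvalue)
  sig <- filter(windows, .data$qvalue < fdr)
  if (!nrow(sig)) return(empty)
  fam <- setNames(annotation$family, annotation$gene_id)
  ann_start <- setNames(annotation$start, annotation$gene_id)
  ann_end <- setNames(annotation$end, annotation$gene_id)

  out <- sig |>
    arrange(.data$chrom, .data$first_idx) |>
    group_by(.data$chrom) |>
    dplyr::group_map(function(g, key) {
      # windows share a gene iff their index ranges overlap
      grp <- cumsum(c(1L, as.integer(g$first_idx[-1] > cummax(g$last_idx)[-nrow(g)])))
      list_rbind(map(split(seq_len(nrow(g)), grp), function(rows) {
        genes <- unique(unlist(g$gene_ids[rows]))
        de <- intersect(genes, de_ids)
        de_fams <- fam[de]
        de_fams <- de_fams[!is.na(de_fams)]
        modal <- if (length(de_fams)) {
          tb <- table(de_fams)
          paste(sort(names(tb)[tb == max(tb)]), collapse = ",")
        } else NA_character_
        tibble(chrom = key$chrom[[1]],
               start = min(ann_start[genes]), end = max(ann_end[genes]),
               n_expressed = length(genes), n_de = length(de),
               families = modal, gene_ids = list(genes))
      }))
    }) |>
    list_rbind() |>
    mutate(span_mb = (.data$end - .data$start) / 1e6,
           pct_de = 100 * .data$n_de / .data$n_expressed) |>
    select("chrom", "start", "end", "span_mb", "n_expressed", "n_de",
           "pct_de", "families", "gene_ids") |>
    arrange(.data$chrom, .data$start)
  out
}

#' Summarize hotspots in the style of a per-region report table
#'
#' Accepts any tibble with `chrom, start, end, n_expressed, n_de` (and
#' optionally `families`), e.g. the output of [call_hotspots()] or a table
#' of published hotspot coordinates.  Emits one row per hotspot with the
#' span in Mb (2 dp) and %DE (1 dp, half-up), a totals row (summed span
#' and counts, pooled %DE) and a genome row.
#'
#' @param hotspots Hotspot tibble.
#' @param genome_expressed Total expressed genes genome-wide.
#' @param genome_de Total DE genes genome-wide.
#' @return Tibble with a `row_type` column (`"hotspot"`, `"totals"`,
#'   `"genome"`).
#' @export
summarize_hotspots <- function(hotspots, genome_expressed, genome_de) {
  fam <- if ("families" %in% names(hotspots)) hotspots$families else NA_character_
  rows <- tibble(
    row_type = "hotspot",
    chrom = as.character(hotspots$chrom),
    start = hotspots$start, end = hotspots$end,
    span_mb = round_half_up((hotspots$end - hotspots$start) / 1e6, 2),
    n_expressed = hotspots$n_expressed, n_de = hotspots$n_de,
    pct_de = round_half_up(100 * hotspots$n_de / hotspots$n_expressed, 1),
    families = fam)
  totals <- tibble(
    row_type = "totals", chrom = NA_character_,
    start = NA_integer_, end = NA_integer_,
    span_mb = round_half_up(sum(hotspots$end - hotspots$start) / 1e6, 2),
    n_expressed = sum(hotspots$n_expressed), n_de = sum(hotspots$n_de),
    pct_de = if (nrow(hotspots)) {
      round_half_up(100 * sum(hotspots$n_de) / sum(hotspots$n_expressed), 1)
    } else 0,
    families = NA_character_)
  genome <- tibble(
    row_type = "genome", chrom = NA_character_,
    start = NA_integer_, end = NA_integer_, span_mb = NA_real_,
    n_expressed = genome_expressed, n_de = genome_de,
    pct_de = round_half_up(100 * genome_de / genome_expressed, 1),
    families = NA_character_)
  bind_rows(rows, totals, genome)
}
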