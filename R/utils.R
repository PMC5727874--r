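# Shared validation and small numeric helpers.

#' Convert a wide counts tibble to an integer matrix
#'
#' Counts travel through the package as a wide tibble whose first column is
#' `gene_id` and whose remaining columns are samples.  Internally most
#' statistics want a plain matrix; this helper converts and validates.
#'
#' @param counts A counts tibble (`gene_id` + one column per sample).
#' @param require_integer Require whole non-negative values (raw counts).
#' @return Numeric matrix with gene ids as rownames.
#' @keywords internal
counts_matrix <- function(counts, require_integer = FALSE) {
  stopifnot(is.data.frame(counts), ncol(counts) >= 2)
  if (names(counts)[1] != "gene_id") {
    abort("first column of a counts table must be 'gene_id'")
  }
  gid <- as.character(counts$gene_id)
  if (anyDuplicated(gid)) {
    abort(paste0("duplicate gene ids: ",
                 paste(unique(gid[duplicated(gid)]), collapse = ", ")))
  }
  m <- as.matrix(counts[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) abort("duplicate sample ids")
  storage.mode(m) <- "double"
  if (anyNA(m)) abort("counts contain missing values")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative count for gene '%s', sample '%s'",
                  gid[bad[1]], colnames(m)[bad[2]]))
  }
  if (require_integer && any(m != round(m))) {
    bad <- which(m != round(m), arr.ind = TRUE)[1, ]
    abort(sprintf("non-integer count for gene '%s', sample '%s'",
                  gid[bad[1]], colnames(m)[bad[2]]))
  }
  rownames(m) <- gid
  m
}

#' @keywords internal
matrix_to_counts <- function(m) {
  bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
}

#' Validate sample metadata against a counts table
#' @keywords internal
validate_meta <- function(meta, counts = NULL) {
  need <- c("sample_id", "strain", "sex")
  miss <- setdiff(need, names(meta))
  if (length(miss)) abort(paste("metadata missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(meta$sample_id)) abort("duplicate sample_id in metadata")
  if (!all(meta$sex %in% c("male", "female"))) {
    abort("sex must be 'male' or 'female'")
  }
  if (!is.null(counts)) {
    samples <- setdiff(names(counts), "gene_id")
    if (!setequal(samples, meta$sample_id)) {
      abort("metadata sample_ids do not match counts columns")
    }
  }
  invisible(meta)
}

# Round half away from zero (printed percentages use half-up, not banker's).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Write a sidecar provenance JSON next to an output file
#'
#' Every writer in the package drops `<path>.json` recording inputs,
#' parameters, seed and tool version so runs can be audited.
#' @keywords internal
write_provenance <- function(path, inputs = list(), params = list(), seed = NULL) {
  prov <- list(
    file = basename(path),
    tool = "vomeroseq",
    version = as.character(utils::packageVersion("vomeroseq")),
    inputs = inputs,
    params = params,
    seed = seed
  )
  jsonlite::write_json(prov, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}
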