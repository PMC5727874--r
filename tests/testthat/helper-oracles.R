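# Brute-force oracles, coded independently of the implementation paths
# they check.

oracle_size_factors <- function(m) {
  pos <- apply(m > 0, 1, all)
  logs <- log(m[pos, , drop = FALSE])
  geo <- exp(apply(logs, 1, mean))
  s <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) s[j] <- median(m[pos, j] / geo)
  s / exp(mean(log(s)))
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) q[o[i]] <- min(1, min(n * ps[i:n] / (i:n)))
  q
}

# enumerate every window directly and sum the Poisson tail by hand
oracle_scan <- function(ann, expressed, de, W, rate) {
  ann <- ann[ann$gene_id %in% expressed, ]
  ann <- ann[order(ann$chrom, ann$start), ]
  out <- list()
  for (ch in unique(ann$chrom)) {
    g <- ann[ann$chrom == ch, ]
    if (nrow(g) < W) next
    for (s in seq_len(nrow(g) - W + 1)) {
      ids <- g$gene_id[s:(s + W - 1)]
      k <- sum(ids %in% de)
      lam <- W * rate
      p <- if (k == 0) 1 else sum(exp(-lam) * lam^(k:(k + 400)) / factorial(k:(k + 400)))
      out[[length(out) + 1]] <- tibble::tibble(chrom = ch, first = s, k = k, p = p)
    }
  }
  dplyr::bind_rows(out)
}
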