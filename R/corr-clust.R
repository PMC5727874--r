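# Spearman correlation of expression profiles, average-linkage
# dendrograms, bootstrap support, and multiscale (approximately unbiased)
# support.  Clustering and the rank correlation are written out in full
# here -- they are the statistic under test -- and are checked against
# stats::cor / stats::hclust in the test suite.

#' Spearman correlation matrix between genes
#'
#' Ranks (average ties) each gene's per-sample expression, then applies
#' the Pearson formula to the ranks.  Constant genes have undefined rank
#' variance; their rows/columns are `NA` and listed in attribute
#' `constant_genes`.
#'
#' @param x Expression tibble (`gene_id` + samples), e.g.
#'   `norm$normalized`, or a numeric matrix with gene rownames.
#' @param gene_sets Optional character vector restricting the genes.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(x, gene_sets = NULL) {
  m <- if (is.matrix(x)) x else counts_matrix(x)
  if (!is.null(gene_sets)) m <- m[rownames(m) %in% gene_sets, , drop = FALSE]
  if (ncol(m) < 3) abort("need >= 3 samples for rank correlation")
  r <- t(apply(m, 1, rank))  # average ranks for ties
  rc <- r - rowMeans(r)
  denom <- sqrt(rowSums(rc^2))
  rho <- tcrossprod(rc) / outer(denom, denom)
  rho[denom == 0, ] <- NA_real_
  rho[, denom == 0] <- NA_real_
  diag(rho)[denom > 0] <- 1
  rho <- pmin(pmax(rho, -1), 1)
  attr(rho, "constant_genes") <- rownames(m)[denom == 0]
  rho
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Hand-rolled agglomeration with a deterministic tie-break: among pairs
#' at the minimal distance, the pair whose lexicographically smallest
#' leaf label is smallest merges first (then by the other member's
#' smallest label).  Returns a standard `hclust` object so `cutree()`,
#' `plot()` and [stats::as.dendrogram()] work.
#'
#' @param d Square symmetric distance matrix (labelled) or a
#'   [stats::dist].
#' @return An object of class `hclust` (method `"average"`).
#' @export
hclust_average <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("distance must be square")
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix must be symmetric")
  n <- nrow(d)
  labels <- rownames(d) %||% as.character(seq_len(n))
  if (n < 2) abort("need >= 2 leaves")

  # active clusters: id (negative leaf / positive merge row), size, min label
  active <- data.frame(id = -seq_len(n), size = 1, minlab = labels,
                       stringsAsFactors = FALSE)
  dm <- d
  diag(dm) <- Inf
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    k <- nrow(dm)
    best <- NULL
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      lo <- sort(c(active$minlab[i], active$minlab[j]))
      cand <- list(i = i, j = j, h = dm[i, j], lo = lo)
      if (is.null(best) || cand$h < best$h - 1e-12 ||
          (abs(cand$h - best$h) <= 1e-12 &&
           (lo[1] < best$lo[1] || (lo[1] == best$lo[1] && lo[2] < best$lo[2])))) {
        best <- cand
      }
    }
    i <- best$i; j <- best$j
    ids <- sort(c(active$id[i], active$id[j]))  # negatives (leaves) first
    merge[step, ] <- ids
    height[step] <- best$h
    si <- active$size[i]; sj <- active$size[j]
    newrow <- (si * dm[i, ] + sj * dm[j, ]) / (si + sj)
    keep_idx <- setdiff(seq_len(k), c(i, j))
    dm <- rbind(cbind(dm[keep_idx, keep_idx, drop = FALSE],
                      newrow[keep_idx]),
                c(newrow[keep_idx], Inf))
    active <- rbind(active[keep_idx, , drop = FALSE],
                    data.frame(id = step, size = si + sj,
                               minlab = min(active$minlab[c(i, j)]),
                               stringsAsFactors = FALSE))
  }

  order_of <- function(row) {
    unlist(lapply(merge[row, ], function(id)
      if (id < 0) -id else order_of(id)))
  }
  structure(list(merge = merge, height = height,
                 order = order_of(n - 1), labels = labels,
                 method = "average", call = match.call(),
                 dist.method = "user"),
            class = "hclust")
}

# leaf-label sets under each internal node of an hclust tree
node_leaf_sets <- function(hc) {
  n <- nrow(hc$merge) + 1
  sets <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    ids <- hc$merge[i, ]
    sets[[i]] <- sort(unlist(lapply(ids, function(id)
      if (id < 0) hc$labels[-id] else sets[[id]])))
  }
  sets
}

bipartition_keys <- function(hc) {
  vapply(node_leaf_sets(hc), paste, character(1), collapse = "|")
}

#' Per-strain mean expression profiles
#'
#' Aggregates normalized counts to strain means: the gene x strain matrix
#' used as "traits" for expression dendrograms (strains as leaves).
#'
#' @param norm A `vno_norm`.
#' @param meta Sample metadata.
#' @param gene_set Optional gene-id subset.
#' @return Numeric matrix, genes x strains.
#' @export
strain_profiles <- function(norm, meta, gene_set = NULL) {
  nm <- norm_matrix(norm)
  validate_meta(meta)
  meta <- meta[match(colnames(nm), meta$sample_id), ]
  if (!is.null(gene_set)) nm <- nm[rownames(nm) %in% gene_set, , drop = FALSE]
  strains <- unique(meta$strain)
  out <- matrix(vapply(strains, function(s)
    rowMeans(nm[, meta$strain == s, drop = FALSE]), numeric(nrow(nm))),
    nrow = nrow(nm), dimnames = list(rownames(nm), strains))
  out
}

# 1 - Spearman distance between the columns of a profile matrix
profile_distance <- function(profiles) {
  rho <- spearman_matrix(t(profiles))
  if (anyNA(rho)) abort("constant profile: distance undefined")
  1 - rho
}

#' Bootstrap support for an expression dendrogram
#'
#' Clusters the columns of `profiles` (typically strains) by
#' average linkage on 1 - Spearman distance, resamples genes (rows) with
#' replacement `n_boot` times, and reports per internal node the fraction
#' of bootstrap trees containing the same leaf set (bootstrap
#' probability, bp).
#'
#' @param profiles Gene x leaf numeric matrix (see [strain_profiles()]).
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @return A `vno_boot` list: `hclust`, `support` tibble (`leaves`, `bp`),
#'   `n_boot`, `seed`.
#' @export
bootstrap_support <- function(profiles, n_boot = 1000L, seed = 1L) {
  if (n_boot < 100) abort("n_boot must be >= 100")
  if (nrow(profiles) < 10) warn("fewer than 10 genes: bootstrap support will be unstable")
  set.seed(seed)
  hc <- hclust_average(profile_distance(profiles))
  keys <- bipartition_keys(hc)
  hits <- setNames(numeric(length(keys)), keys)
  ok <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(profiles), replace = TRUE)
    bd <- tryCatch(profile_distance(profiles[idx, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(bd)) next
    bk <- bipartition_keys(hclust_average(bd))
    hits[keys %in% bk] <- hits[keys %in% bk] + 1
    ok <- ok + 1L
  }
  structure(list(hclust = hc,
                 support = tibble(leaves = keys, bp = unname(hits) / ok),
                 n_boot = n_boot, n_effective = ok, seed = seed),
            class = "vno_boot")
}

#' Multiscale bootstrap: approximately unbiased (AU) support
#'
#' For each scale factor `r` the bootstrap draws `ceiling(r * n_genes)`
#' genes with replacement and records the per-node bootstrap probability
#' bp(r).  Writing `z(r) = qnorm(1 - bp(r))`, the signed-distance model
#' `z(r) = v * sqrt(r) + c / sqrt(r)` is fit by least squares over scales
#' with non-degenerate bp, and `au = 1 - pnorm(v - c)`.  Nodes whose bp is
#' 0 or 1 at every scale keep that bp as their au, flagged `degenerate`.
#'
#' @param profiles Gene x leaf matrix.
#' @param scales Scale factors; must include values below and above 1.
#' @param n_boot_per_scale Replicates per scale.
#' @param seed Integer seed.
#' @return A `vno_boot` with `support` columns `leaves, bp, au,
#'   degenerate` (`bp` is taken at the scale closest to 1).
#' @export
au_support <- function(profiles, scales = seq(0.5, 1.4, by = 0.1),
                       n_boot_per_scale = 1000L, seed = 1L) {
  if (length(scales) < 3 || !any(scales < 1) || !any(scales > 1)) {
    abort("need >= 3 scales spanning values below and above 1")
  }
  set.seed(seed)
  hc <- hclust_average(profile_distance(profiles))
  keys <- bipartition_keys(hc)
  n <- nrow(profiles)
  bp_mat <- matrix(NA_real_, length(keys), length(scales),
                   dimnames = list(keys, as.character(scales)))
  for (si in seq_along(scales)) {
    m_r <- max(3L, ceiling(scales[si] * n))
    hits <- setNames(numeric(length(keys)), keys)
    ok <- 0L
    for (b in seq_len(n_boot_per_scale)) {
      idx <- sample.int(n, size = m_r, replace = TRUE)
      bd <- tryCatch(profile_distance(profiles[idx, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(bd)) next
      bk <- bipartition_keys(hclust_average(bd))
      hits[keys %in% bk] <- hits[keys %in% bk] + 1
      ok <- ok + 1L
    }
    bp_mat[, si] <- hits / ok
  }
  near1 <- which.min(abs(scales - 1))
  sup <- list_rbind(imap(keys, function(key, i) {
    bp_r <- bp_mat[i, ]
    usable <- bp_r > 0 & bp_r < 1
    if (sum(usable) < 2) {
      return(tibble(leaves = key, bp = unname(bp_r[near1]),
                    au = unname(bp_r[near1]), degenerate = TRUE))
    }
    z <- qnorm(1 - bp_r[usable])
    sr <- sqrt(scales[usable])
    fit <- lm(z ~ 0 + sr + I(1 / sr))
    v <- coef(fit)[[1]]; cc <- coef(fit)[[2]]
    tibble(leaves = key, bp = unname(bp_r[near1]),
           au = 1 - pnorm(v - cc), degenerate = FALSE)
  }))
  structure(list(hclust = hc, support = sup, n_boot = n_boot_per_scale,
                 scales = scales, seed = seed),
            class = "vno_boot")
}

#' @export
print.vno_boot <- function(x, ...) {
  cat("<vno_boot> ", length(x$hclust$labels), " leaves, ",
      nrow(x$support), " internal nodes, n_boot = ", x$n_boot, "\n", sep = "")
  print(x$support)
  invisible(x)
}

#' Convert a supported dendrogram to an ape phylo with support labels
#'
#' Node labels carry `"au/bp"` (or bp alone) as percentages, matching the
#' composite labels written to Newick.
#'
#' @param boot A `vno_boot` object.
#' @return An [ape::phylo].
#' @export
boot_to_phylo <- function(boot) {
  ph <- ape::as.phylo(boot$hclust)
  sets <- lapply(seq_len(ph$Nnode) + length(ph$tip.label), function(nd) {
    sort(ph$tip.label[phangorn_descendants(ph, nd)])
  })
  key_of <- vapply(sets, paste, character(1), collapse = "|")
  sup <- boot$support
  lab_for <- function(k) {
    row <- sup[sup$leaves == k, ]
    if (!nrow(row)) return("")
    if ("au" %in% names(sup)) {
      sprintf("%.0f/%.0f", 100 * row$au[[1]], 100 * row$bp[[1]])
    } else {
      sprintf("%.0f", 100 * row$bp[[1]])
    }
  }
  ph$node.label <- unname(vapply(key_of, lab_for, character(1)))
  ph
}

# tips below a node (small trees; simple recursion, no phangorn needed)
phangorn_descendants <- function(ph, node) {
  ntip <- length(ph$tip.label)
  if (node <= ntip) return(node)
  kids <- ph$edge[ph$edge[, 1] == node, 2]
  unlist(lapply(kids, phangorn_descendants, ph = ph))
}

#' Label lncRNAs by the sign of their correlation to receptor clusters
#'
#' Average-linkage clustering of `1 - rho` over the receptor genes (two
#' clusters by default); each lncRNA is labelled by the sign of its mean
#' Spearman correlation to each receptor cluster.
#'
#' @param corr Spearman matrix over the union of both gene sets (from
#'   [spearman_matrix()]).
#' @param lnc_ids,receptor_ids Gene ids of the two sets.
#' @param k Number of receptor clusters (default `min(2, n_receptors)`).
#' @return Tibble: `gene_id` (lncRNA), `receptor_cluster`, `mean_rho`,
#'   `sign` (`"positive"`/`"negative"`).
#' @export
correlation_cluster_report <- function(corr, lnc_ids, receptor_ids, k = NULL) {
  lnc_ids <- intersect(lnc_ids, rownames(corr))
  receptor_ids <- intersect(receptor_ids, rownames(corr))
  k <- k %||% min(2L, length(receptor_ids))
  cl <- if (length(receptor_ids) == 1 || k == 1) {
    setNames(rep(1L, length(receptor_ids)), receptor_ids)
  } else {
    cutree(hclust_average(1 - corr[receptor_ids, receptor_ids]), k = k)
  }
  list_rbind(map(sort(unique(cl)), function(ci) {
    rec <- names(cl)[cl == ci]
    tibble(gene_id = lnc_ids,
           receptor_cluster = ci,
           mean_rho = vapply(lnc_ids, function(l)
             mean(corr[l, rec]), numeric(1)),
           ) |>
      mutate(sign = if_else(.data$mean_rho >= 0, "positive", "negative"))
  }))
}
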