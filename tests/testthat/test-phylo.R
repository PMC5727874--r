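# stats::cor and stats::hclust serve as independent oracles for the
# hand-written rank correlation and average-linkage agglomeration.

test_that("spearman matrix matches the rank-then-Pearson oracle exactly", {
  set.seed(81)
  m <- matrix(rnorm(10 * 12), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  rho <- spearman_matrix(m)
  oracle <- cor(t(m), method = "spearman")
  expect_equal(unclass(rho), oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(diag(rho), rep(1, 10), ignore_attr = TRUE)
  expect_true(all(abs(rho) <= 1 + 1e-12))
})

test_that("rank invariance: monotone transforms leave spearman at 1", {
  x <- c(3, 9, 1, 7, 5, 20)
  m <- rbind(a = x, b = exp(x / 3), c = rank(x))
  colnames(m) <- paste0("s", seq_along(x))
  rho <- spearman_matrix(m)
  expect_equal(unname(rho["a", "b"]), 1)
  expect_equal(unname(rho["a", "c"]), 1)
})

test_that("constant genes are flagged and set missing", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5), c = c(4, 3, 2, 1))
  colnames(m) <- paste0("s", 1:4)
  rho <- spearman_matrix(m)
  expect_true(all(is.na(rho["b", ])))
  expect_equal(attr(rho, "constant_genes"), "b")
  expect_equal(unname(rho["a", "c"]), -1)
})

test_that("average linkage reproduces stats::hclust on random matrices", {
  set.seed(83)
  for (rep in 1:5) {
    x <- matrix(rnorm(8 * 6), nrow = 8,
                dimnames = list(letters[1:8], NULL))
    d <- dist(x)
    mine <- hclust_average(as.matrix(d))
    ref <- stats::hclust(d, method = "average")
    expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-9)
    expect_equal(as.matrix(stats::cophenetic(mine))[letters[1:8], letters[1:8]],
                 as.matrix(stats::cophenetic(ref))[letters[1:8], letters[1:8]],
                 tolerance = 1e-9)
  }
})

test_that("zero-distance profiles merge first; planted blocks give ((A,B),(C,D))", {
  d <- matrix(c(0, 0, 5, 5,
                0, 0, 5, 5,
                5, 5, 0, 1,
                5, 5, 1, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  hc <- hclust_average(d)
  sets <- vomeroseq:::node_leaf_sets(hc)
  expect_equal(sets[[1]], c("A", "B"))   # zero distance merges first
  expect_true(list(c("C", "D")) %in% sets || any(sapply(sets, identical, c("C", "D"))))
  expect_error(hclust_average(matrix(1:6, 2, 3)), "square")
  dd <- d; dd[1, 2] <- 3
  expect_error(hclust_average(dd), "symmetric")
})

test_that("bootstrap support is deterministic, bounded and order-invariant", {
  prof <- outgroup_profiles(80, seed = 85)
  b1 <- bootstrap_support(prof, n_boot = 200, seed = 5)
  b2 <- bootstrap_support(prof, n_boot = 200, seed = 5)
  expect_identical(b1$support, b2$support)
  expect_true(all(b1$support$bp >= 0 & b1$support$bp <= 1))
  # permuting leaf (column) order changes nothing about the supports
  b3 <- bootstrap_support(prof[, c(3, 1, 4, 2)], n_boot = 200, seed = 5)
  expect_equal(dplyr::arrange(b1$support, leaves),
               dplyr::arrange(b3$support, leaves))
})

test_that("a planted outgroup split earns high support; noise does not", {
  prof <- outgroup_profiles(200, seed = 86)
  bt <- bootstrap_support(prof, n_boot = 500, seed = 6)
  split_bp <- bt$support$bp[bt$support$leaves == "129|SJL|SWR"]
  expect_gte(split_bp, 0.95)
  # pure noise: the best non-root split stays uncertain in the median
  maxbp <- sapply(1:10, function(s) {
    noise <- matrix(rlnorm(50 * 4, 3, 1), ncol = 4,
                    dimnames = list(NULL, c("B6", "129", "SJL", "SWR")))
    b <- bootstrap_support(noise, n_boot = 150, seed = s)
    max(b$support$bp[b$support$leaves != "129|B6|SJL|SWR"])
  })
  expect_lt(median(maxbp), 0.95)
})

test_that("AU support is deterministic, degenerate-safe and tracks bp", {
  prof <- outgroup_profiles(200, seed = 87)
  a1 <- au_support(prof, n_boot_per_scale = 300, seed = 7)
  a2 <- au_support(prof, n_boot_per_scale = 300, seed = 7)
  expect_identical(a1$support, a2$support)
  root <- a1$support[a1$support$leaves == "129|B6|SJL|SWR", ]
  expect_true(root$degenerate)   # bp = 1 at every scale
  expect_equal(root$au, 1)
  split <- a1$support[a1$support$leaves == "129|SJL|SWR", ]
  expect_gte(split$au, split$bp - 0.05)
  expect_error(au_support(prof, scales = c(1.1, 1.2, 1.3)), "below and above")
})

test_that("lncRNA/receptor correlation report recovers planted signs", {
  sim <- simulate_corr_blocks(toy_sim(seed = 88, n_genes = 120L),
                              n_lnc = 4, n_receptor = 5, n_anti = 2)
  norm <- estimate_size_factors(sim$counts)
  cb <- sim$truth$corr_blocks
  # correlate strain-mean profiles (the planted structure lives there)
  prof <- strain_profiles(norm, sim$meta, gene_set = cb$gene_id)
  rho <- spearman_matrix(prof)
  rep_tbl <- correlation_cluster_report(
    rho, cb$gene_id[cb$role == "lncRNA"],
    cb$gene_id[cb$role == "receptor"], k = 1)
  pos <- cb$gene_id[cb$sign == 1 & cb$role == "lncRNA"]
  anti <- cb$gene_id[cb$sign == -1]
  expect_true(all(rep_tbl$sign[rep_tbl$gene_id %in% pos] == "positive"))
  expect_true(all(rep_tbl$sign[rep_tbl$gene_id %in% anti] == "negative"))
  # single-gene sets still produce a report
  one <- correlation_cluster_report(rho, cb$gene_id[cb$role == "lncRNA"][1],
                                    cb$gene_id[cb$role == "receptor"][1])
  expect_equal(nrow(one), 1L)
})
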