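test_that("size factors match the brute-force median-of-ratios oracle", {
  set.seed(31)
  m <- matrix(rnbinom(500 * 8, mu = 80, size = 5), nrow = 500,
              dimnames = list(sprintf("g%03d", 1:500), sprintf("s%d", 1:8)))
  counts <- vomeroseq:::matrix_to_counts(m)
  norm <- estimate_size_factors(counts)
  expect_equal(norm$size_factors$size_factor, oracle_size_factors(m),
               tolerance = 1e-12)
})

test_that("size factors respect symmetry and forced scaling", {
  m <- matrix(rep(c(5L, 9L, 13L), 4), nrow = 3,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  norm <- estimate_size_factors(vomeroseq:::matrix_to_counts(m))
  expect_equal(norm$size_factors$size_factor, rep(1, 4))
  m2 <- m
  m2[, 2] <- m2[, 2] * 2L
  norm2 <- estimate_size_factors(vomeroseq:::matrix_to_counts(m2))
  sf <- norm2$size_factors$size_factor
  expect_equal(sf[2] / sf[1], 2)
  # normalization removes the doubling: samples are again interchangeable
  nm2 <- vomeroseq:::counts_matrix(norm2$normalized)
  expect_equal(nm2[, 2] / nm2[, 1], rep(1, 3), ignore_attr = TRUE)
})

test_that("a matrix with no all-positive gene is refused", {
  m <- matrix(c(0L, 3L, 5L, 0L), nrow = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(estimate_size_factors(vomeroseq:::matrix_to_counts(m)),
               "pseudo-reference")
})

test_that("moment dispersion recovers Poisson and NB truth", {
  meta <- tibble::tibble(sample_id = paste0("s", 1:200), strain = "B6",
                         sex = rep(c("male", "female"), each = 100),
                         replicate = rep(1:100, 2))
  # Poisson gene: alpha-hat stays near zero
  set.seed(41)
  pois_hits <- vapply(1:40, function(s) {
    m <- matrix(rpois(200, 100), nrow = 1, dimnames = list("g", meta$sample_id))
    norm <- structure(list(normalized = vomeroseq:::matrix_to_counts(m)),
                      class = "vno_norm")
    a <- estimate_dispersion(norm, meta)$alpha
    a >= 0 && a <= 0.05
  }, logical(1))
  expect_gte(mean(pois_hits), 0.95)
  # NB gene with alpha = 0.5
  nb_hits <- vapply(1:40, function(s) {
    m <- matrix(rnbinom(200, mu = 100, size = 2), nrow = 1,
                dimnames = list("g", meta$sample_id))
    norm <- structure(list(normalized = vomeroseq:::matrix_to_counts(m)),
                      class = "vno_norm")
    a <- estimate_dispersion(norm, meta)$alpha
    a >= 0.35 && a <= 0.65
  }, logical(1))
  expect_gte(mean(nb_hits), 0.95)
})

test_that("constant and all-zero genes get zero dispersion and a flag", {
  m <- matrix(c(rep(7, 8), rep(0, 8)), nrow = 2, byrow = TRUE,
              dimnames = list(c("const", "zero"), paste0("s", 1:8)))
  meta <- tibble::tibble(sample_id = paste0("s", 1:8),
                         strain = rep(c("B6", "SWR"), each = 4),
                         sex = rep(c("male", "female"), 4),
                         replicate = rep(1:2, each = 2, times = 2))
  norm <- structure(list(normalized = vomeroseq:::matrix_to_counts(m)),
                    class = "vno_norm")
  d <- estimate_dispersion(norm, meta)
  expect_equal(d$alpha, c(0, 0))
  expect_equal(d$all_zero, c(FALSE, TRUE))
})

test_that("Wald lfc is antisymmetric under contrast swap with identical p", {
  sim <- toy_sim(seed = 9, n_genes = 150L)
  norm <- estimate_size_factors(sim$counts)
  disp <- estimate_dispersion(norm, sim$meta)
  ab <- wald_test(norm, sim$meta, c("B6", "SWR"), disp)
  ba <- wald_test(norm, sim$meta, c("SWR", "B6"), disp)
  expect_equal(ab$lfc, -ba$lfc, tolerance = 1e-12)
  expect_equal(ab$pvalue, ba$pvalue, tolerance = 1e-12)
})

test_that("an all-zero group yields a finite negative lfc and small p", {
  gm <- tibble::tibble(gene_id = "g1", B6_M = 0, B6_F = 0,
                       SWR_M = 500, SWR_F = 500)
  fix <- counts_from_means(gm, n_rep = 4, seed = 5)
  norm <- estimate_size_factors(
    dplyr::bind_rows(fix$counts,
                     tibble::tibble(gene_id = "ref",
                                    !!!setNames(as.list(rep(100L, 16)),
                                                setdiff(names(fix$counts), "gene_id")))))
  disp <- estimate_dispersion(norm, fix$meta)
  wt <- wald_test(norm, fix$meta, c("B6", "SWR"), disp)
  row <- wt[wt$gene_id == "g1", ]
  expect_true(is.finite(row$lfc))
  expect_lt(row$lfc, 0)
  expect_lt(row$pvalue, 0.05)
})

test_that("BH q-values equal the brute-force step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(17)
  p <- runif(200)
  expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-14)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("independent filtering flags constructed outliers only", {
  sim <- toy_sim(seed = 13, n_genes = 100L)
  norm <- estimate_size_factors(sim$counts)
  disp <- estimate_dispersion(norm, sim$meta)
  base <- independent_filter(norm, sim$meta, disp)
  # spike one sample of one homogeneous gene to 100x its group mean
  counts2 <- sim$counts
  g <- counts2$gene_id[50]
  counts2[counts2$gene_id == g, 2] <- as.integer(
    100 * max(1, round(mean(as.numeric(counts2[counts2$gene_id == g, -1])))))
  norm2 <- estimate_size_factors(counts2)
  disp2 <- estimate_dispersion(norm2, sim$meta)
  filt2 <- independent_filter(norm2, sim$meta, disp2)
  expect_true(filt2$filtered[filt2$gene_id == g])
  # switch contract: disabling filters nothing
  off <- independent_filter(norm2, sim$meta, disp2, enabled = FALSE)
  expect_equal(sum(off$filtered), 0L)
  # a literally homogeneous gene is never filtered
  counts3 <- sim$counts
  counts3[counts3$gene_id == "gene00001", -1] <- 40L
  norm3 <- estimate_size_factors(counts3)
  disp3 <- estimate_dispersion(norm3, sim$meta)
  filt3 <- independent_filter(norm3, sim$meta, disp3)
  expect_false(filt3$filtered[filt3$gene_id == "gene00001"])
  # and filtering stays a minority affair on clean data
  expect_lt(mean(base$filtered), 0.25)
})

test_that("DE classification implements OR-over-contrasts with thresholds", {
  tab <- tibble::tibble(
    gene_id = rep(c("hit", "weak"), each = 2),
    contrast = rep(c("A_vs_B", "A_vs_C"), 2),
    lfc = c(2.5, 0.1, log2(1.9), log2(1.9)),
    qvalue = c(0.001, 0.9, 0.001, 0.001))
  filt <- tibble::tibble(gene_id = c("hit", "weak"), filtered = FALSE)
  cls <- classify_de(tab, filt, contrasts = c("A_vs_B", "A_vs_C"))
  expect_true(cls$de[cls$gene_id == "hit"])     # significant in one contrast
  expect_false(cls$de[cls$gene_id == "weak"])   # FC 1.9 < 2 everywhere
  expect_error(classify_de(tab, filt, contrasts = c("A_vs_B", "A_vs_D")),
               "missing contrast")
})

test_that("TPM normalizes by length and sums to one million per sample", {
  ann <- line_annotation(2)
  ann$length_bp <- c(1000L, 2000L)
  counts <- tibble::tibble(gene_id = ann$gene_id, s1 = c(100L, 100L),
                           s2 = c(30L, 60L))
  t <- tpm(counts, ann)
  expect_equal(t$s1, c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  expect_equal(colSums(as.matrix(t[, -1])), c(s1 = 1e6, s2 = 1e6),
               tolerance = 1e-6)
  one <- tpm(counts[1, ], ann[1, ])
  expect_equal(unlist(one[, -1], use.names = FALSE), c(1e6, 1e6))
  ann0 <- ann; ann0$length_bp[1] <- 0L
  expect_error(tpm(counts, ann0), "length")
})

test_that("null Wald p-values are calibrated at the 1% level", {
  sim <- simulate_counts(sim_params(n_genes = 5000L, lfc_magnitude = 0,
                                    seed = 23))
  norm <- estimate_size_factors(sim$counts)
  disp <- estimate_dispersion(norm, sim$meta)
  wt <- wald_test(norm, sim$meta, c("B6", "129"), disp)
  frac <- mean(wt$pvalue < 0.01)
  expect_gte(frac, 0.005)
  expect_lte(frac, 0.02)
})

test_that("planted log2 fold changes are recovered on average", {
  # 500 genes with planted LFC = 2 (A vs B), mean 200, alpha = 0.1,
  # n = 4 vs 4, embedded among 1000 null genes that anchor normalization
  set.seed(29)
  n_de <- 500; n_null <- 1000
  sign_up <- rep(c(1, -1), length.out = n_de)  # balanced directions
  mu_b <- c(rep(200, n_de), rep(200, n_null))
  mu_a <- c(200 * 4^sign_up, rep(200, n_null))
  cols <- cbind(sapply(1:4, function(r) rnbinom(length(mu_a), mu = mu_a, size = 10)),
                sapply(1:4, function(r) rnbinom(length(mu_b), mu = mu_b, size = 10)))
  colnames(cols) <- sprintf("s%02d", 1:8)
  rownames(cols) <- sprintf("g%04d", seq_along(mu_a))
  meta <- tibble::tibble(sample_id = colnames(cols),
                         strain = rep(c("A", "B"), each = 4),
                         sex = rep(c("male", "male", "female", "female"), 2),
                         replicate = rep(1:2, 4))
  counts <- vomeroseq:::matrix_to_counts(cols)
  norm <- estimate_size_factors(counts)
  disp <- estimate_dispersion(norm, meta)
  wt <- wald_test(norm, meta, c("A", "B"), disp)
  est <- mean(wt$lfc[seq_len(n_de)] * sign_up)
  expect_gt(est, 1.7)
  expect_lt(est, 2.3)
})

test_that("tidy and glance expose the DE fit in broom style", {
  sim <- toy_sim(seed = 15, n_genes = 120L)
  de <- de_analysis(sim$counts, sim$meta)
  td <- tidy(de)
  expect_true(all(c("gene_id", "contrast", "lfc", "pvalue", "qvalue", "de") %in%
                    names(td)))
  expect_equal(nrow(td), 120 * 6)
  # q >= p wherever not filtered
  ok <- !is.na(td$qvalue)
  expect_true(all(td$qvalue[ok] >= td$pvalue[ok] - 1e-12))
  gl <- glance(de)
  expect_equal(gl$n_genes, 120L)
  expect_equal(gl$n_contrasts, 6L)
  expect_equal(gl$n_de, sum(de$classification$de))
})

test_that("size-factor ratios agree with DESeq2's median-of-ratios", {
  skip_if_not_installed("DESeq2")
  set.seed(53)
  m <- matrix(rnbinom(400 * 8, mu = 120, size = 4), nrow = 400,
              dimnames = list(sprintf("g%03d", 1:400), sprintf("s%d", 1:8)))
  mine <- estimate_size_factors(vomeroseq:::matrix_to_counts(m))$size_factors$size_factor
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # same estimator up to the geometric-mean-1 rescaling applied here and
  # DESeq2's median-on-log-scale (geometric vs arithmetic midpoint when
  # the positive-gene count is even)
  expect_equal(mine / mine[1], unname(ref / ref[1]), tolerance = 1e-4)
})
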