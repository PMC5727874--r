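test_that("simulation is deterministic given params and seed", {
  s1 <- toy_sim(seed = 5)
  s2 <- toy_sim(seed = 5)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$truth$de_genes, s2$truth$de_genes)
  s3 <- toy_sim(seed = 6)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("null model (lfc_magnitude = 0) plants no DE and keeps group means equal", {
  sim <- toy_sim(seed = 2, lfc_magnitude = 0)
  expect_equal(nrow(sim$truth$de_genes), 0L)
  m <- vomeroseq:::counts_matrix(sim$counts)
  lib <- sim$lib_factors[colnames(m)]
  adj <- sweep(m, 2, lib, "/")
  strain_means <- sapply(unique(sim$meta$strain), function(s)
    mean(adj[, sim$meta$sample_id[sim$meta$strain == s]]))
  expect_lt(max(strain_means) / min(strain_means), 1.1)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_params(n_per_group = 1), "dispersion unidentifiable")
  expect_error(sim_params(genome_de_rate = 0), "in \\(0,1\\)")
  expect_error(sim_params(hotspot_local_de_rate = 0.1), "exceed")
})

test_that("realized genome-wide DE fraction matches the planted rate", {
  sim <- simulate_counts(sim_params(seed = 11))
  rate <- nrow(sim$truth$de_genes) / nrow(sim$counts)
  ci <- 0.128 + c(-1, 1) * qnorm(0.995) * sqrt(0.128 * 0.872 / nrow(sim$counts))
  expect_gt(rate, ci[1])
  expect_lt(rate, ci[2])
  # hotspot members are genuinely enriched
  hot_ids <- unlist(sim$truth$hotspot_intervals$gene_ids)
  local_rate <- mean(hot_ids %in% sim$truth$de_genes$gene_id)
  expect_gt(local_rate, 0.3)
})

test_that("X/Y pairs are dosage compensated and Y is silent in females", {
  sim <- simulate_xy_and_xist(toy_sim(seed = 3))
  m <- vomeroseq:::counts_matrix(sim$counts)
  lib <- sim$lib_factors[colnames(m)]
  adj <- sweep(m, 2, lib, "/")
  meta <- sim$meta
  male <- meta$sample_id[meta$sex == "male"]
  female <- meta$sample_id[meta$sex == "female"]
  xy <- sim$truth$xy_pairs
  expect_true(all(m[xy$y_gene, female] == 0))
  expect_true(all(m["xist_like", male] == 0))
  # planted X_f = X_m + Y_m: combined male mean recovers the female mean
  for (i in seq_len(nrow(xy))) {
    comb <- mean(adj[xy$x_gene[i], male] + adj[xy$y_gene[i], male])
    sem <- sd(adj[xy$x_gene[i], male] + adj[xy$y_gene[i], male]) / sqrt(length(male))
    expect_lt(abs(comb - xy$x_female_mean[i]), 3 * sem + 1e-9)
  }
})

test_that("degenerate pair with zero Y share leaves X means equal by sex", {
  sim <- simulate_xy_and_xist(toy_sim(seed = 4), n_pairs = 3, male_x_frac = 1)
  xy <- sim$truth$xy_pairs
  expect_equal(xy$x_male_mean, xy$x_female_mean)
  expect_equal(xy$y_male_mean, rep(0, 3))
  m <- vomeroseq:::counts_matrix(sim$counts)
  expect_true(all(m[xy$y_gene, ] == 0))
})

test_that("correlation blocks plant proportional and rank-reversed strain means", {
  sim <- simulate_corr_blocks(toy_sim(seed = 8))
  cb <- sim$truth$corr_blocks
  prof <- sim$truth$strain_profile
  # construction: positive-block genes share the profile (+1), antagonists
  # get the reversed ranks (-1)
  expect_equal(cor(prof, prof, method = "spearman"), 1)
  rev_prof <- sort(prof)[length(prof) + 1 - rank(prof)]
  expect_equal(unname(cor(prof, rev_prof, method = "spearman")), -1)
  # realized strain means recover the planted signs
  m <- vomeroseq:::counts_matrix(sim$counts)
  lib <- sim$lib_factors[colnames(m)]
  adj <- sweep(m, 2, lib, "/")
  strains <- unique(sim$meta$strain)
  sm <- sapply(strains, function(s)
    rowMeans(adj[cb$gene_id, sim$meta$sample_id[sim$meta$strain == s]]))
  pos <- cb$gene_id[cb$sign == 1]
  anti <- cb$gene_id[cb$sign == -1]
  rho_pos <- cor(t(sm[pos, ]), method = "spearman")
  expect_true(all(rho_pos[upper.tri(rho_pos)] > 0))
  for (a in anti) expect_lt(cor(sm[a, ], sm[pos[1], ], method = "spearman"), 0)
})

test_that("noisy positive blocks recover positive rank correlation across seeds", {
  hits <- vapply(1:40, function(s) {
    sim <- simulate_corr_blocks(toy_sim(seed = 100 + s, n_genes = 80L,
                                        n_hotspots = 0L))
    cb <- sim$truth$corr_blocks
    m <- vomeroseq:::counts_matrix(sim$counts)
    strains <- unique(sim$meta$strain)
    sm <- sapply(strains, function(st)
      rowMeans(m[cb$gene_id, sim$meta$sample_id[sim$meta$strain == st]]))
    pos <- cb$gene_id[cb$sign == 1]
    rho <- cor(t(sm[pos, ]), method = "spearman")
    all(rho[upper.tri(rho)] > 0)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pseudogene locus construction matches its declared truth", {
  lc <- simulate_pseudogene_locus(seed = 21, restore_mode = "snv_removes_stop")
  # reference translation is truncated, restored one reaches full length
  ref_orf <- find_orf(lc$reference)
  full <- 3 * lc$expected$protein_length + 3
  if (nrow(ref_orf)) expect_lt(ref_orf$width, 0.95 * full)
  restored <- apply_variants(lc$reference, lc$variants, lc$strain)
  expect_identical(restored, lc$functional)
  expect_equal(find_orf(restored)$width, full)
  # empty variant set leaves the reference untouched
  none <- lc$variants[0, ]
  expect_identical(apply_variants(lc$reference, none, lc$strain), lc$reference)
})

test_that("insertion mode plants the restoring base at the declared offset", {
  lc <- simulate_pseudogene_locus(seed = 22, restore_mode = "insertion_restores_frame")
  expect_equal(lc$variants$pos, 359L)
  expect_equal(lc$variants$kind, "insertion")
  expect_equal(substr(lc$variants$alt, 2, 2), "C")
  restored <- apply_variants(lc$reference, lc$variants, lc$strain)
  expect_identical(restored, lc$functional)
  expect_equal(nchar(restored), nchar(lc$reference) + 1L)
  expect_equal(find_orf(restored)$width, 3 * lc$expected$protein_length + 3)
})
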