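test_that("a planted female-only gene is flagged with female direction", {
  sim <- simulate_xy_and_xist(toy_sim(seed = 51, n_genes = 200L))
  dm <- sex_dimorphism_cross_strain(sim$counts, sim$meta)
  row <- tidy(dm)[tidy(dm)$gene_id == "xist_like", ]
  expect_true(row$dimorphic)
  expect_equal(row$direction, "female")
  expect_lt(row$weighted_fc, 1 / 2)
})

test_that("direction inconsistency across strains vetoes the flag", {
  # male-biased in three strains, female-biased in the fourth
  gm <- tibble::tibble(gene_id = "flip",
                       B6_M = 400, B6_F = 100, `129_M` = 400, `129_F` = 100,
                       SJL_M = 400, SJL_F = 100, SWR_M = 100, SWR_F = 400)
  ref <- tibble::tibble(gene_id = "ref", B6_M = 100, B6_F = 100,
                        `129_M` = 100, `129_F` = 100, SJL_M = 100,
                        SJL_F = 100, SWR_M = 100, SWR_F = 100)
  fix <- counts_from_means(dplyr::bind_rows(gm, ref), n_rep = 3)
  dm <- sex_dimorphism_cross_strain(fix$counts, fix$meta)
  row <- tidy(dm)[tidy(dm)$gene_id == "flip", ]
  expect_false(row$consistent)
  expect_false(row$dimorphic)
  # with the consistency rule off it would pass on magnitude alone
  dm2 <- sex_dimorphism_cross_strain(fix$counts, fix$meta,
                                     require_consistent_direction = FALSE)
  row2 <- tidy(dm2)[tidy(dm2)$gene_id == "flip", ]
  expect_true(row2$weighted_fc > 2 || row2$weighted_fc < 0.5 || !row2$dimorphic)
})

test_that("null data yields no more dimorphism flags than chance allows", {
  sim <- toy_sim(seed = 53, n_genes = 400L, lfc_magnitude = 0)
  dm <- sex_dimorphism_cross_strain(sim$counts, sim$meta)
  n_flag <- sum(tidy(dm)$dimorphic)
  # flags need p < 0.01 AND FC > 2 AND 4-strain direction agreement;
  # bound by the 99th percentile of Binomial(n, 0.01)
  expect_lte(n_flag, qbinom(0.99, 400, 0.01))
})

test_that("swapping sex labels inverts fold changes and keeps p-values", {
  sim <- simulate_xy_and_xist(toy_sim(seed = 54, n_genes = 150L))
  dm <- sex_dimorphism_cross_strain(sim$counts, sim$meta)
  meta_sw <- dplyr::mutate(sim$meta,
                           sex = ifelse(sex == "male", "female", "male"))
  dm_sw <- sex_dimorphism_cross_strain(sim$counts, meta_sw)
  a <- tidy(dm); b <- tidy(dm_sw)
  expect_equal(a$weighted_lfc, -b$weighted_lfc, tolerance = 1e-12)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-12)
})

test_that("strain-specific sex effects surface within strains, not across", {
  # Simpson-style: sex effect planted in SWR only
  gm <- tibble::tibble(gene_id = c("swr_only", "two_strains"),
                       B6_M = c(100, 400), B6_F = c(100, 100),
                       `129_M` = c(100, 100), `129_F` = c(100, 100),
                       SJL_M = c(100, 400), SJL_F = c(100, 100),
                       SWR_M = c(600, 100), SWR_F = c(100, 100))
  ref <- tibble::tibble(gene_id = sprintf("ref%02d", 1:20))
  for (cell in setdiff(names(gm), "gene_id")) ref[[cell]] <- 150
  fix <- counts_from_means(dplyr::bind_rows(gm, ref), n_rep = 4, seed = 77)
  ws <- within_strain_sex_de(fix$counts, fix$meta)
  hit <- ws$combined[ws$combined$gene_id == "swr_only", ]
  expect_equal(hit$strains, "SWR")
  # two planted strains are reported with both labels
  hit2 <- ws$combined[ws$combined$gene_id == "two_strains", ]
  expect_equal(hit2$strains, "B6,SJL")
  # the cross-strain screen (consistency required) does not flag it
  dm <- sex_dimorphism_cross_strain(fix$counts, fix$meta)
  expect_false(tidy(dm)$dimorphic[tidy(dm)$gene_id == "swr_only"])
  # unplanted genes stay quiet
  expect_false(any(grepl("^ref", ws$combined$gene_id)))
})

test_that("dosage accounting conserves male X+Y and validates female Y silence", {
  sim <- simulate_xy_and_xist(toy_sim(seed = 55, n_genes = 150L))
  norm <- estimate_size_factors(sim$counts)
  xy <- sim$truth$xy_pairs[, c("x_gene", "y_gene")]
  dose <- dosage_compensation(norm, sim$meta, xy)
  expect_equal(dose$combined_male, dose$x_male + dose$y_male)
  expect_true(all(dose$ratio > 0.6 & dose$ratio < 1.6))
  # degenerate pair: Y silent in males too
  sim2 <- simulate_xy_and_xist(toy_sim(seed = 56, n_genes = 150L),
                               n_pairs = 2, male_x_frac = 1)
  norm2 <- estimate_size_factors(sim2$counts)
  dose2 <- dosage_compensation(norm2, sim2$meta,
                               sim2$truth$xy_pairs[, c("x_gene", "y_gene")])
  expect_equal(dose2$ratio, dose2$x_female / dose2$x_male)
  # nonzero female Y counts are rejected
  broken <- sim$counts
  fem <- sim$meta$sample_id[sim$meta$sex == "female"][1]
  broken[broken$gene_id == xy$y_gene[1], fem] <- 5L
  norm3 <- estimate_size_factors(broken)
  expect_error(dosage_compensation(norm3, sim$meta, xy), "female")
  # absent pair gene is an error
  expect_error(dosage_compensation(norm, sim$meta,
                                   tibble::tibble(x_gene = "nope", y_gene = "yhom01")),
               "absent")
})

test_that("cross-strain flags are a subset of within-strain flags", {
  sim <- simulate_xy_and_xist(toy_sim(seed = 57, n_genes = 200L))
  dm <- sex_dimorphism_cross_strain(sim$counts, sim$meta, alpha = 0.01)
  ws <- within_strain_sex_de(sim$counts, sim$meta, fdr = 0.25)
  cross <- tidy(dm)$gene_id[tidy(dm)$dimorphic]
  per_strain_any <- unique(ws$per_strain$gene_id[
    ws$per_strain$pvalue < 0.05 & abs(ws$per_strain$lfc) > 0])
  # every cross-strain hit shows some within-strain signal
  expect_true(all(cross %in% per_strain_any))
})
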