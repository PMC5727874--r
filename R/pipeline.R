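# End-to-end pipeline: simulation -> DE -> dimorphism -> hotspots ->
# patterns -> pseudogenes -> dendrograms, with a manifest recording
# parameters, versions and output hashes, and recovery metrics against
# the planted truth.

#' Pipeline configuration
#'
#' @param out_dir Run directory (created if missing).
#' @param seed Integer seed driving every stage.
#' @param sim Simulation parameters ([sim_params()]).
#' @param fc,fdr,alpha,window Analysis thresholds: fold change, FDR,
#'   dimorphism p cutoff, window size.
#' @param absence_rule Rule for [presence_patterns()].
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "de", "dimorphism", "hotspots", "patterns",
#'   "pseudogene", "phylo")`.
#' @param n_boot Bootstrap replicates for the dendrogram stage.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, sim = sim_params(seed = seed),
                       fc = 2, fdr = 0.05, alpha = 0.01, window = 25L,
                       absence_rule = "zero_raw",
                       stages = c("simulate", "de", "dimorphism", "hotspots",
                                  "patterns", "pseudogene", "phylo"),
                       n_boot = 1000L) {
  all_stages <- c("simulate", "de", "dimorphism", "hotspots", "patterns",
                  "pseudogene", "phylo")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) abort(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  if (fc <= 0 || fdr <= 0 || alpha <= 0 || window < 2) {
    abort("thresholds must be positive (window >= 2)")
  }
  deps <- list(de = "simulate", dimorphism = "simulate", hotspots = c("simulate", "de"),
               patterns = c("simulate", "de"), pseudogene = character(),
               phylo = c("simulate", "de"))
  for (s in stages) {
    miss <- setdiff(deps[[s]] %||% character(), stages)
    if (length(miss)) {
      abort(sprintf("stage '%s' needs stage(s): %s", s, paste(miss, collapse = ", ")))
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 fc = fc, fdr = fdr, alpha = alpha, window = as.integer(window),
                 absence_rule = absence_rule, stages = stages,
                 n_boot = as.integer(n_boot)),
            class = "run_config")
}

#' Run the full pipeline on synthetic data
#'
#' Executes the enabled stages in dependency order, writes each stage's
#' outputs as TSV/VCF/FASTA/Newick under `config$out_dir`, computes
#' recovery metrics against the planted truth, and finishes with
#' `manifest.json` (parameters, versions, seed, per-file MD5 hashes).
#' Outputs are byte-reproducible given the seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  metrics <- list()
  stage_on <- function(s) s %in% config$stages

  if (stage_on("simulate")) {
    sim <- simulate_counts(config$sim)
    sim <- simulate_xy_and_xist(sim)
    sim <- simulate_corr_blocks(sim)
    res$sim <- sim
    write_counts(sim$counts, file.path(config$out_dir, "counts.tsv"),
                 seed = config$seed)
    write_sample_meta(sim$meta, file.path(config$out_dir, "meta.tsv"))
    write_annotation(sim$annotation, file.path(config$out_dir, "genes.tsv"))
    truth_json <- list(
      de_genes = sim$truth$de_genes,
      hotspot_intervals = select(sim$truth$hotspot_intervals, -"gene_ids"),
      xy_pairs = sim$truth$xy_pairs,
      female_only_gene = sim$truth$female_only_gene,
      corr_blocks = sim$truth$corr_blocks)
    jsonlite::write_json(truth_json, file.path(config$out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if (stage_on("de")) {
    de <- de_analysis(res$sim$counts, res$sim$meta,
                      fc_threshold = config$fc, fdr = config$fdr)
    res$de <- de
    readr::write_tsv(tidy(de), file.path(config$out_dir, "de_table.tsv"))
    truth_de <- res$sim$truth$de_genes$gene_id
    called <- de$classification$gene_id[de$classification$de]
    metrics$de <- list(
      sensitivity = if (length(truth_de)) mean(truth_de %in% called) else NA,
      fdp = if (length(called)) mean(!called %in% truth_de) else 0,
      n_called = length(called))
  }

  if (stage_on("dimorphism")) {
    dim_res <- sex_dimorphism_cross_strain(res$sim$counts, res$sim$meta,
                                           fc = config$fc, alpha = config$alpha)
    res$dimorphism <- dim_res
    readr::write_tsv(tidy(dim_res), file.path(config$out_dir, "dimorphism.tsv"))
    xy <- res$sim$truth$xy_pairs
    if (nrow(xy)) {
      dose <- dosage_compensation(res$de$norm %||%
                                    estimate_size_factors(res$sim$counts),
                                  res$sim$meta, xy)
      res$dosage <- dose
      readr::write_tsv(dose, file.path(config$out_dir, "dosage.tsv"))
      metrics$dosage <- list(mean_ratio = mean(dose$ratio))
    }
    fo <- res$sim$truth$female_only_gene
    if (!is.na(fo)) {
      metrics$dimorphism <- list(
        female_only_flagged =
          dim_res$result$dimorphic[dim_res$result$gene_id == fo])
    }
  }

  if (stage_on("hotspots")) {
    expressed <- res$de$norm$normalized$gene_id[
      rowSums(counts_matrix(res$sim$counts) > 0) > 0]
    de_ids <- res$de$classification$gene_id[res$de$classification$de]
    w <- scan_windows(res$sim$annotation, expressed, de_ids,
                      window = config$window)
    hs <- call_hotspots(w, res$sim$annotation, de_ids, fdr = config$fdr)
    res$hotspots <- hs
    summary_tbl <- summarize_hotspots(hs, length(expressed), length(de_ids))
    readr::write_tsv(select(summary_tbl, -dplyr::any_of("gene_ids")),
                     file.path(config$out_dir, "hotspots.tsv"))
    if (nrow(hs)) {
      write_bed(mutate(hs, gene_id = sprintf("hotspot%02d", row_number())),
                file.path(config$out_dir, "hotspots.bed"))
    }
    planted <- res$sim$truth$hotspot_intervals
    hit <- vapply(seq_len(nrow(planted)), function(i)
      any(hs$chrom == planted$chrom[i] & hs$start <= planted$end[i] &
            hs$end >= planted$start[i]), logical(1))
    false_hs <- vapply(seq_len(nrow(hs)), function(i)
      !any(planted$chrom == hs$chrom[i] & planted$start <= hs$end[i] &
             planted$end >= hs$start[i]), logical(1))
    metrics$hotspots <- list(planted_recovered = mean(hit),
                             n_false = sum(false_hs))
  }

  if (stage_on("patterns")) {
    pat <- presence_patterns(res$sim$counts, res$sim$meta,
                             rule = config$absence_rule)
    de_ids <- res$de$classification$gene_id[res$de$classification$de]
    pat_de <- filter(pat, .data$gene_id %in% de_ids)
    res$patterns <- pat
    readr::write_tsv(pat, file.path(config$out_dir, "patterns.tsv"))
    readr::write_tsv(venn_counts(pat_de), file.path(config$out_dir, "venn.tsv"))
    readr::write_tsv(family_lacking_summary(pat_de, res$sim$annotation),
                     file.path(config$out_dir, "families.tsv"))
  }

  if (stage_on("pseudogene")) {
    loci <- list(
      snv = simulate_pseudogene_locus(config$seed, "snv_removes_stop"),
      ins = simulate_pseudogene_locus(config$seed + 1L, "insertion_restores_frame"))
    reports <- list_rbind(imap(loci, function(lc, nm) {
      mutate(call_functionalization(lc$reference, lc$variants, lc$strain,
                                    lc$homolog),
             locus = nm, .before = 1)
    }))
    res$pseudogene <- reports
    readr::write_tsv(reports, file.path(config$out_dir, "orf_report.tsv"))
    write_sequences(
      setNames(Biostrings::DNAStringSet(
        c(loci$snv$reference, loci$snv$homolog,
          loci$ins$reference, loci$ins$homolog)),
        c("locus_snv_ref", "locus_snv_homolog",
          "locus_ins_ref", "locus_ins_homolog")),
      file.path(config$out_dir, "loci.fasta"))
    write_variants(bind_rows(snv = loci$snv$variants, ins = loci$ins$variants),
                   file.path(config$out_dir, "variants.vcf"))
    metrics$pseudogene <- list(all_functional = all(reports$functional))
  }

  if (stage_on("phylo")) {
    de_ids <- res$de$classification$gene_id[res$de$classification$de]
    prof <- strain_profiles(res$de$norm, res$sim$meta,
                            gene_set = if (length(de_ids) >= 10) de_ids else NULL)
    boot <- bootstrap_support(prof, n_boot = config$n_boot, seed = config$seed)
    res$phylo <- boot
    write_tree_newick(boot_to_phylo(boot),
                      file.path(config$out_dir, "strains.nwk"))
    cb <- res$sim$truth$corr_blocks
    if (nrow(cb)) {
      nm <- norm_matrix(res$de$norm)
      corr <- spearman_matrix(nm, gene_sets = cb$gene_id)
      rep_tbl <- correlation_cluster_report(
        corr, cb$gene_id[cb$role == "lncRNA"],
        cb$gene_id[cb$role == "receptor"], k = 1L)
      readr::write_tsv(rep_tbl, file.path(config$out_dir, "corr_clusters.tsv"))
    }
  }

  if (length(metrics)) {
    jsonlite::write_json(metrics, file.path(config$out_dir, "recovery_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  files <- setdiff(list.files(config$out_dir), "manifest.json")
  manifest <- list(
    tool = "vomeroseq",
    version = as.character(utils::packageVersion("vomeroseq")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stages = config$stages,
    params = list(fc = config$fc, fdr = config$fdr, alpha = config$alpha,
                  window = config$window, absence_rule = config$absence_rule,
                  n_genes = config$sim$n_genes,
                  genome_de_rate = config$sim$genome_de_rate,
                  hotspot_local_de_rate = config$sim$hotspot_local_de_rate),
    outputs = as.list(tools::md5sum(file.path(config$out_dir, files))))
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(results = res, metrics = metrics, manifest = manifest))
}
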