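# Fixtures built in code: a desk-scale simulation small enough for unit
# tests, plus hand-rolled count tables with known structure.

toy_params <- function(seed = 1L, n_genes = 600L,
                       n_hotspots = if (n_genes >= 400L) 2L else 0L, ...) {
  sim_params(n_genes = n_genes, n_chromosomes = 4L, n_hotspots = n_hotspots,
             hotspot_size = c(10L, 15L), window = 5L, seed = seed, ...)
}

toy_sim <- function(seed = 1L, ...) simulate_counts(toy_params(seed = seed, ...))

# counts tibble from per-group means: groups is a named list
# strain -> named list(male = mean, female = mean); n reps per cell
counts_from_means <- function(gene_means, n_rep = 3L, dispersion = 0.05,
                              seed = 42L) {
  # gene_means: tibble gene_id + one column per "strain_sex" cell
  set.seed(seed)
  cells <- setdiff(names(gene_means), "gene_id")
  cols <- list()
  meta <- list()
  for (cell in cells) {
    parts <- strsplit(cell, "_", fixed = TRUE)[[1]]
    for (r in seq_len(n_rep)) {
      id <- paste0(cell, "_", r)
      mu <- gene_means[[cell]]
      cols[[id]] <- as.integer(ifelse(mu <= 0, 0,
                                      rnbinom(length(mu), mu = mu, size = 1 / dispersion)))
      meta[[id]] <- tibble::tibble(sample_id = id, strain = parts[1],
                                   sex = ifelse(parts[2] == "M", "male", "female"),
                                   replicate = r)
    }
  }
  list(counts = dplyr::bind_cols(tibble::tibble(gene_id = gene_means$gene_id),
                                 tibble::as_tibble(cols)),
       meta = dplyr::bind_rows(meta))
}

# annotation for n genes laid regularly on one chromosome
line_annotation <- function(n, chrom = "chr1", start0 = 1e4, gap = 1e4,
                            width = 2e3, prefix = "g") {
  starts <- start0 + (seq_len(n) - 1) * (gap + width)
  tibble::tibble(gene_id = sprintf("%s%03d", prefix, seq_len(n)),
                 chrom = chrom, start = as.integer(starts),
                 end = as.integer(starts + width - 1),
                 strand = "+", biotype = "protein_coding",
                 family = NA_character_, length_bp = as.integer(width))
}

# gene x strain profile matrix in which B6 is an outgroup to three
# closely related strains
outgroup_profiles <- function(n_genes = 200L, seed = 1L, noise = 0.1) {
  set.seed(seed)
  shared <- rlnorm(n_genes, 4, 1)
  cbind(B6 = rlnorm(n_genes, 4, 1),
        `129` = shared * exp(rnorm(n_genes, 0, noise)),
        SJL = shared * exp(rnorm(n_genes, 0, noise)),
        SWR = shared * exp(rnorm(n_genes, 0, noise)))
}
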