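# Synthetic data with the statistical structure the downstream analyses
# assume: NB counts for 4 strains x 2 sexes, strain effects concentrated in
# planted genomic clusters, dosage-compensated X/Y pairs, a female-only
# Xist-like gene, correlated lncRNA/receptor blocks, and pseudogene loci
# whose strain variants restore an open reading frame.

#' Simulation parameters
#'
#' Defaults describe the study design the package targets: 4 inbred
#' strains, both sexes, 4 replicates per strain x sex, ~10,000 expressed
#' genes, a genome-wide differential-expression rate of 12.8% and a local
#' rate of 42% inside 12 planted genomic clusters.  Counts are negative
#' binomial with Var = mu + alpha * mu^2 and a log-normal per-gene alpha;
#' per-sample library factors are uniform on [0.7, 1.3] to exercise
#' normalization.
#'
#' @param strains Strain labels (>= 2).
#' @param n_per_group Replicates per strain x sex cell (>= 2).
#' @param n_genes Number of genes.
#' @param n_chromosomes Number of autosomes genes are spread over.
#' @param mean_meanlog,mean_sdlog Log-normal parameters for baseline means.
#' @param disp_meanlog,disp_sdlog Log-normal parameters for NB dispersion.
#' @param genome_de_rate Overall fraction of genes planted as DE.
#' @param hotspot_local_de_rate DE fraction inside planted clusters.
#' @param n_hotspots Number of planted clusters.
#' @param hotspot_size Integer range (min, max) of expressed genes per
#'   cluster; the default spans the sizes reported for real DE hotspots
#'   (25 to 122 expressed genes).
#' @param window Sliding-window size used downstream (buffer spacing only).
#' @param lfc_magnitude Absolute planted log2 fold change (0 = null model).
#' @param libsize_range Range of per-sample library scaling factors.
#' @param seed Integer seed; all outputs are reproducible given it.
#' @return A `sim_params` list, validated.
#' @export
sim_params <- function(strains = c("B6", "129", "SJL", "SWR"),
                       n_per_group = 4L,
                       n_genes = 10000L,
                       n_chromosomes = 19L,
                       mean_meanlog = log(60), mean_sdlog = 1.3,
                       disp_meanlog = log(0.08), disp_sdlog = 0.4,
                       genome_de_rate = 0.128,
                       hotspot_local_de_rate = 0.42,
                       n_hotspots = 12L,
                       hotspot_size = c(25L, 122L),
                       window = 25L,
                       lfc_magnitude = 2,
                       libsize_range = c(0.7, 1.3),
                       seed = 1L) {
  p <- list(strains = strains, n_per_group = as.integer(n_per_group),
            n_genes = as.integer(n_genes),
            n_chromosomes = as.integer(n_chromosomes),
            mean_meanlog = mean_meanlog, mean_sdlog = mean_sdlog,
            disp_meanlog = disp_meanlog, disp_sdlog = disp_sdlog,
            genome_de_rate = genome_de_rate,
            hotspot_local_de_rate = hotspot_local_de_rate,
            n_hotspots = as.integer(n_hotspots),
            hotspot_size = as.integer(hotspot_size),
            window = as.integer(window),
            lfc_magnitude = lfc_magnitude,
            libsize_range = libsize_range,
            seed = as.integer(seed))
  if (length(p$strains) < 2) abort("need >= 2 strains")
  if (p$n_per_group < 2) abort("n_per_group < 2: dispersion unidentifiable")
  if (p$genome_de_rate <= 0 || p$genome_de_rate >= 1) abort("genome_de_rate must be in (0,1)")
  if (p$hotspot_local_de_rate <= 0 || p$hotspot_local_de_rate >= 1) {
    abort("hotspot_local_de_rate must be in (0,1)")
  }
  if (p$hotspot_local_de_rate <= p$genome_de_rate) {
    abort("hotspot_local_de_rate must exceed genome_de_rate")
  }
  structure(p, class = "sim_params")
}

# NB draw with Var = mu + alpha mu^2 (alpha = 0 falls back to Poisson).
rnb <- function(n, mu, alpha) {
  out <- numeric(n)
  pois <- alpha <= 0
  if (any(pois)) out[pois] <- rpois(sum(pois), mu[pois])
  if (any(!pois)) {
    out[!pois] <- rnbinom(sum(!pois), mu = mu[!pois], size = 1 / alpha[!pois])
  }
  out
}

#' Simulate a multi-strain count matrix with planted DE hotspots
#'
#' Genes are laid along synthetic chromosomes in order; `n_hotspots`
#' contiguous clusters receive a local DE rate of
#' `hotspot_local_de_rate` while the background rate is lowered so the
#' genome-wide planted rate equals `genome_de_rate`.  Each DE gene gets a
#' mean shift of `2^lfc_magnitude` (random sign) in one random strain.
#'
#' @param params A [sim_params()] object.
#' @return A `vno_sim` list: `counts` (tibble), `meta`, `annotation`,
#'   `truth` (planted effects), `lib_factors`, `params`.
#' @export
simulate_counts <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  N <- params$n_genes
  gid <- sprintf("gene%05d", seq_len(N))

  # --- gene placement -------------------------------------------------
  chrom_of <- sort(sample.int(params$n_chromosomes, N, replace = TRUE))
  chroms <- paste0("chr", chrom_of)
  ann <- tibble(gene_id = gid, chrom = chroms) |>
    group_by(.data$chrom) |>
    mutate(gap = round(runif(n(), 5e3, 5e4)),
           len = round(runif(n(), 1e3, 5e3)),
           start = cumsum(.data$gap + .data$len) - .data$len,
           end = .data$start + .data$len - 1L) |>
    ungroup() |>
    select(-"gap", -"len")
  ann$strand <- sample(c("+", "-"), N, replace = TRUE)
  ann$biotype <- sample(c("protein_coding", "lncRNA", "pseudogene", "TEC"),
                        N, replace = TRUE, prob = c(0.75, 0.10, 0.10, 0.05))
  ann$family <- NA_character_
  ann$length_bp <- ann$end - ann$start + 1L
  ann <- arrange(ann, .data$chrom, .data$start)
  # index within chromosome, in genomic order
  ann <- ann |> group_by(.data$chrom) |> mutate(idx = row_number()) |> ungroup()

  # --- planted hotspot intervals (disjoint, buffered by >= window) ----
  fams <- c("Vmn1r", "Vmn2r", "Olfr", "GIMAP", "Clec", "Klr",
            "Trim", "Cd200", "Fpr", "Btnl", "MHC", "Skint")
  taken <- list()  # per chrom: occupied index ranges incl. buffer
  hs <- vector("list", params$n_hotspots)
  buffer <- 2L * params$window
  chrom_sizes <- table(ann$chrom)
  for (h in seq_len(params$n_hotspots)) {
    size <- sample(seq(params$hotspot_size[1], params$hotspot_size[2]), 1)
    placed <- FALSE
    for (try in 1:200) {
      ch <- sample(names(chrom_sizes), 1)
      nmax <- chrom_sizes[[ch]] - size - buffer
      if (nmax < buffer + 1) next
      s <- sample.int(nmax - buffer, 1) + buffer
      rng <- c(s - buffer, s + size - 1 + buffer)
      occ <- taken[[ch]]
      clash <- !is.null(occ) &&
        any(vapply(occ, function(o) rng[1] <= o[2] && o[1] <= rng[2], logical(1)))
      if (!clash) {
        taken[[ch]] <- c(occ, list(rng))
        hs[[h]] <- list(chrom = ch, from = s, to = s + size - 1L,
                        family = fams[(h - 1L) %% length(fams) + 1L])
        placed <- TRUE
        break
      }
    }
    if (!placed) abort("could not place hotspot intervals; reduce n_hotspots or sizes")
  }

  in_hotspot <- rep(NA_integer_, nrow(ann))
  for (h in seq_along(hs)) {
    sel <- ann$chrom == hs[[h]]$chrom & ann$idx >= hs[[h]]$from & ann$idx <= hs[[h]]$to
    in_hotspot[sel] <- h
    ann$family[sel] <- hs[[h]]$family
  }

  # --- DE assignment ---------------------------------------------------
  n_hot_genes <- sum(!is.na(in_hotspot))
  de <- rep(FALSE, nrow(ann))
  if (params$lfc_magnitude > 0) {
    p_bg <- (params$genome_de_rate * N -
               params$hotspot_local_de_rate * n_hot_genes) / (N - n_hot_genes)
    if (p_bg <= 0) abort("hotspots absorb more DE genes than genome_de_rate allows")
    pr <- ifelse(is.na(in_hotspot), p_bg, params$hotspot_local_de_rate)
    de <- runif(nrow(ann)) < pr
  }
  target_strain <- rep(NA_character_, nrow(ann))
  lfc <- rep(0, nrow(ann))
  if (any(de)) {
    target_strain[de] <- sample(params$strains, sum(de), replace = TRUE)
    lfc[de] <- sample(c(-1, 1), sum(de), replace = TRUE) * params$lfc_magnitude
  }

  # --- samples ---------------------------------------------------------
  meta <- tidyr::expand_grid(strain = params$strains,
                             sex = c("male", "female"),
                             replicate = seq_len(params$n_per_group)) |>
    mutate(sample_id = sprintf("%s_%s_%d", .data$strain,
                               ifelse(.data$sex == "male", "M", "F"),
                               .data$replicate)) |>
    select("sample_id", "strain", "sex", "replicate")
  n_samp <- nrow(meta)
  lib <- runif(n_samp, params$libsize_range[1], params$libsize_range[2])
  names(lib) <- meta$sample_id

  # --- counts ----------------------------------------------------------
  base <- rlnorm(nrow(ann), params$mean_meanlog, params$mean_sdlog)
  alpha <- rlnorm(nrow(ann), params$disp_meanlog, params$disp_sdlog)
  shift <- outer(lfc, rep(1, n_samp)) *
    outer(target_strain, meta$strain, function(a, b) !is.na(a) & a == b)
  mu <- (base * 2^shift) * rep(lib, each = nrow(ann))
  cnt <- matrix(rnb(length(mu), as.vector(mu), rep(alpha, times = n_samp)),
                nrow = nrow(ann), dimnames = list(ann$gene_id, meta$sample_id))
  storage.mode(cnt) <- "integer"

  hot_tbl <- if (!length(hs)) {
    tibble(hotspot_id = integer(), chrom = character(), start = integer(),
           end = integer(), family = character(), n_genes = integer(),
           gene_ids = list())
  } else list_rbind(imap(hs, function(h, i) {
    sel <- ann$chrom == h$chrom & ann$idx >= h$from & ann$idx <= h$to
    tibble(hotspot_id = i, chrom = h$chrom,
           start = min(ann$start[sel]), end = max(ann$end[sel]),
           family = h$family, n_genes = sum(sel),
           gene_ids = list(ann$gene_id[sel]))
  }))

  truth <- list(
    de_genes = tibble(gene_id = ann$gene_id[de],
                      strain = target_strain[de], lfc = lfc[de]),
    hotspot_intervals = hot_tbl,
    xy_pairs = tibble(x_gene = character(), y_gene = character()),
    female_only_gene = NA_character_,
    corr_blocks = tibble(block_id = integer(), gene_id = character(),
                         role = character(), sign = integer()),
    functional_pseudogenes = tibble(gene_id = character(), strain = character()),
    base_mean = setNames(base, ann$gene_id),
    dispersion = setNames(alpha, ann$gene_id)
  )

  structure(list(counts = matrix_to_counts(cnt),
                 meta = meta,
                 annotation = select(ann, -"idx"),
                 truth = truth,
                 lib_factors = lib,
                 params = params),
            class = "vno_sim")
}

# append genes to an existing simulation, drawing NB counts around
# planted per-sample means (already including library factors)
append_genes <- function(sim, ann_rows, mu, alpha) {
  cnt <- matrix(rnb(length(mu), as.vector(mu), rep(alpha, times = ncol(mu))),
                nrow = nrow(mu), dimnames = dimnames(mu))
  storage.mode(cnt) <- "integer"
  sim$counts <- bind_rows(sim$counts, matrix_to_counts(cnt))
  sim$annotation <- arrange(bind_rows(sim$annotation, ann_rows),
                            .data$chrom, .data$start)
  sim
}

#' Add dosage-compensated X/Y homolog pairs and a female-only gene
#'
#' For each pair the female X mean equals the male X mean plus the male Y
#' mean (dosage compensation); Y genes have exactly zero counts in
#' females, and the Xist-like `female_only_gene` has zero counts in males.
#'
#' @param sim A `vno_sim` from [simulate_counts()].
#' @param n_pairs Number of X/Y homolog pairs.
#' @param x_female_mean Baseline female X mean (per-pair scaled).
#' @param male_x_frac Fraction of the female X mean retained by the male X
#'   allele; the male Y homolog carries the remainder.
#' @param xist_mean Female mean of the female-only gene.
#' @param alpha NB dispersion for the added genes.
#' @param seed Seed for this augmentation (defaults to `params$seed + 1`).
#' @return The augmented `vno_sim`.
#' @export
simulate_xy_and_xist <- function(sim, n_pairs = 6L, x_female_mean = 100,
                                 male_x_frac = 0.7, xist_mean = 500,
                                 alpha = 0.02, seed = NULL) {
  stopifnot(inherits(sim, "vno_sim"))
  set.seed(seed %||% (sim$params$seed + 1L))
  meta <- sim$meta
  lib <- sim$lib_factors[meta$sample_id]
  scale <- rlnorm(n_pairs, 0, 0.5)
  x_ids <- sprintf("xhom%02d", seq_len(n_pairs))
  y_ids <- sprintf("yhom%02d", seq_len(n_pairs))
  male <- meta$sex == "male"

  mu_x <- t(vapply(seq_len(n_pairs), function(i) {
    xf <- x_female_mean * scale[i]
    ifelse(male, male_x_frac * xf, xf) * lib
  }, numeric(nrow(meta))))
  mu_y <- t(vapply(seq_len(n_pairs), function(i) {
    xf <- x_female_mean * scale[i]
    ifelse(male, (1 - male_x_frac) * xf, 0) * lib
  }, numeric(nrow(meta))))
  mu_xist <- matrix(ifelse(male, 0, xist_mean) * lib, nrow = 1)

  mu <- rbind(mu_x, mu_y, mu_xist)
  rownames(mu) <- c(x_ids, y_ids, "xist_like")
  colnames(mu) <- meta$sample_id

  pos <- seq_len(n_pairs)
  ann_rows <- tibble(
    gene_id = rownames(mu),
    chrom = c(rep("chrX", n_pairs), rep("chrY", n_pairs), "chrX"),
    start = c(pos * 1e5, pos * 1e5, (n_pairs + 1) * 1e5),
    end = c(pos * 1e5 + 4999, pos * 1e5 + 4999, (n_pairs + 1) * 1e5 + 4999),
    strand = "+", biotype = c(rep("protein_coding", 2 * n_pairs), "lncRNA"),
    family = NA_character_, length_bp = 5000L)

  sim <- append_genes(sim, ann_rows, mu, rep(alpha, nrow(mu)))
  # zero-mean cells must be exactly zero (rnb(mu = 0) already is, but be explicit)
  zero_cols <- meta$sample_id[!male]
  for (y in y_ids) sim$counts[sim$counts$gene_id == y, zero_cols] <- 0L
  sim$counts[sim$counts$gene_id == "xist_like", meta$sample_id[male]] <- 0L

  xf <- x_female_mean * scale
  sim$truth$xy_pairs <- tibble(x_gene = x_ids, y_gene = y_ids,
                               x_female_mean = xf,
                               x_male_mean = male_x_frac * xf,
                               y_male_mean = (1 - male_x_frac) * xf)
  sim$truth$female_only_gene <- "xist_like"
  sim
}

#' Add correlated / anti-correlated lncRNA-receptor blocks
#'
#' A positive block shares one strain-mean profile up to a per-gene scale
#' (Spearman +1 between group means before noise); an antagonistic lncRNA
#' gets the rank-reversed profile (Spearman -1 against the block).
#'
#' @param sim A `vno_sim`.
#' @param n_lnc,n_receptor Genes per role in the positive block.
#' @param n_anti Number of antagonistic lncRNAs.
#' @param base_mean Scale of the strain profile.
#' @param alpha NB dispersion for added genes.
#' @param seed Seed (defaults to `params$seed + 2`).
#' @return The augmented `vno_sim` with `truth$corr_blocks` filled.
#' @export
simulate_corr_blocks <- function(sim, n_lnc = 5L, n_receptor = 5L, n_anti = 2L,
                                 base_mean = 80, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(sim, "vno_sim"))
  set.seed(seed %||% (sim$params$seed + 2L))
  meta <- sim$meta
  strains <- unique(meta$strain)
  lib <- sim$lib_factors[meta$sample_id]
  # strictly increasing strain profile, then shuffled over strains
  prof <- sort(rlnorm(length(strains), log(base_mean), 0.9))
  prof <- setNames(sample(prof), strains)

  ids_lnc <- sprintf("lnc_pos%02d", seq_len(n_lnc))
  ids_rec <- sprintf("vmn_pos%02d", seq_len(n_receptor))
  ids_anti <- sprintf("lnc_anti%02d", seq_len(n_anti))
  scale <- rlnorm(n_lnc + n_receptor + n_anti, 0, 0.4)
  # reversed-rank profile: the strain with the highest value gets the lowest
  rev_prof <- setNames(sort(prof)[length(prof) + 1 - rank(prof)], names(prof))

  mu <- rbind(
    t(vapply(seq_len(n_lnc), function(i) scale[i] * prof[meta$strain] * lib,
             numeric(nrow(meta)))),
    t(vapply(seq_len(n_receptor), function(i)
      scale[n_lnc + i] * prof[meta$strain] * lib, numeric(nrow(meta)))),
    t(vapply(seq_len(n_anti), function(i)
      scale[n_lnc + n_receptor + i] * rev_prof[meta$strain] * lib,
      numeric(nrow(meta))))
  )
  rownames(mu) <- c(ids_lnc, ids_rec, ids_anti)
  colnames(mu) <- meta$sample_id

  n_new <- nrow(mu)
  ann_rows <- tibble(
    gene_id = rownames(mu), chrom = "chr1",
    start = max(sim$annotation$end) + seq_len(n_new) * 1e4,
    end = max(sim$annotation$end) + seq_len(n_new) * 1e4 + 1999,
    strand = "+",
    biotype = c(rep("lncRNA", n_lnc), rep("protein_coding", n_receptor),
                rep("lncRNA", n_anti)),
    family = c(rep(NA_character_, n_lnc), rep("Vmn1r", n_receptor),
               rep(NA_character_, n_anti)),
    length_bp = 2000L)

  sim <- append_genes(sim, ann_rows, mu, rep(alpha, n_new))
  sim$truth$corr_blocks <- tibble(
    block_id = 1L,
    gene_id = c(ids_lnc, ids_rec, ids_anti),
    role = c(rep("lncRNA", n_lnc), rep("receptor", n_receptor),
             rep("lncRNA", n_anti)),
    sign = c(rep(1L, n_lnc + n_receptor), rep(-1L, n_anti)))
  sim$truth$strain_profile <- prof
  sim
}

# ---------------------------------------------------------------------------
# Pseudogene locus simulation

STOP_CODONS <- c("TAA", "TAG", "TGA")

# random coding sequence: ATG + (n_aa - 1) non-stop codons + TAA
random_cds <- function(n_aa) {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  sense <- setdiff(codons, STOP_CODONS)
  paste0("ATG",
         paste(sample(sense, n_aa - 1, replace = TRUE), collapse = ""),
         "TAA")
}

codon_at <- function(seq, i) substr(seq, 3 * i - 2, 3 * i)
`codon_at<-` <- function(seq, i, value) {
  substr(seq, 3 * i - 2, 3 * i) <- value
  seq
}

#' Simulate a pseudogene locus whose strain variants restore an ORF
#'
#' Builds a functional coding sequence, derives a broken reference from it
#' (premature in-frame stops for `snv_removes_stop`; a single-base
#' deletion that shifts the frame for `insertion_restores_frame`), and the
#' variant set -- carried by one strain -- that restores the functional
#' sequence.  A homolog is generated by substituting a controlled number
#' of codons, so the expected percent identities are known exactly.
#'
#' @param seed Integer seed.
#' @param restore_mode `"snv_removes_stop"` or `"insertion_restores_frame"`.
#' @param n_aa Protein length (aa) of the restored ORF.
#' @param n_snv Number of SNVs (snv mode; >= `n_stops` of them create stops).
#' @param n_stops SNVs that introduce premature stops in the reference.
#' @param insertion_offset Insertion point, bp from the start codon
#'   (insertion mode).
#' @param homolog_identity_aa Target protein identity (%) to the homolog.
#' @param strain Carrier strain of the restoring variants.
#' @return List: `reference`, `functional`, `homolog` (character
#'   sequences), `variants` (tibble as from [read_variants()]),
#'   `expected` (list with planted identities, protein length and
#'   diagnosis flags), `strain`.
#' @export
simulate_pseudogene_locus <- function(seed = 1L,
                                      restore_mode = c("snv_removes_stop",
                                                       "insertion_restores_frame"),
                                      n_aa = NULL,
                                      n_snv = 10L, n_stops = 3L,
                                      insertion_offset = 359L,
                                      homolog_identity_aa = 84,
                                      strain = "SWR") {
  restore_mode <- match.arg(restore_mode)
  set.seed(seed)
  n_aa <- n_aa %||% if (restore_mode == "snv_removes_stop") 329L else 318L

  for (attempt in 1:100) {
    functional <- random_cds(n_aa)
    L <- nchar(functional)

    if (restore_mode == "snv_removes_stop") {
      # pick interior codons: n_stops become stops, the rest other codons
      slots <- sample(2:(n_aa - 1), n_snv)
      reference <- functional
      vr <- vector("list", n_snv)
      for (k in seq_len(n_snv)) {
        i <- slots[k]
        cod <- codon_at(functional, i)
        new <- if (k <= n_stops) {
          # a stop codon differing from the functional codon in one base
          hits <- STOP_CODONS[vapply(STOP_CODONS, function(s)
            sum(strsplit(s, "")[[1]] != strsplit(cod, "")[[1]]) == 1, logical(1))]
          if (!length(hits)) NA_character_ else sample(rep(hits, 2), 1)
        } else {
          # non-stop single-base change
          pos_in <- sample(1:3, 1)
          alt <- sample(setdiff(c("A", "C", "G", "T"), substr(cod, pos_in, pos_in)), 1)
          cand <- cod
          substr(cand, pos_in, pos_in) <- alt
          if (cand %in% STOP_CODONS) NA_character_ else cand
        }
        if (is.na(new)) { vr[[k]] <- NULL; next }
        diff_pos <- which(strsplit(new, "")[[1]] != strsplit(cod, "")[[1]])[1]
        pos <- 3 * (i - 1) + diff_pos
        reference <- `codon_at<-`(reference, i, new)
        vr[[k]] <- tibble(chrom = "locus", pos = pos,
                          ref = substr(new, diff_pos, diff_pos),
                          alt = substr(cod, diff_pos, diff_pos),
                          kind = "SNV", strains = list(strain))
      }
      variants <- list_rbind(keep(vr, Negate(is.null)))
      if (nrow(variants) < n_stops) next  # could not plant enough stops; retry
      frame_restored <- FALSE
      stop_removed <- TRUE
    } else {
      # force a C at insertion_offset + 1 of the functional sequence,
      # then delete it to make the frameshifted reference
      del_at <- insertion_offset + 1L
      i <- ceiling(del_at / 3)
      cod <- codon_at(functional, i)
      pos_in <- del_at - 3 * (i - 1)
      substr(cod, pos_in, pos_in) <- "C"
      if (cod %in% STOP_CODONS || (i == 1 && cod != "ATG")) next
      functional <- `codon_at<-`(functional, i, cod)
      reference <- paste0(substr(functional, 1, del_at - 1),
                          substr(functional, del_at + 1, L))
      variants <- tibble(chrom = "locus", pos = insertion_offset,
                         ref = substr(reference, insertion_offset, insertion_offset),
                         alt = paste0(substr(reference, insertion_offset,
                                             insertion_offset), "C"),
                         kind = "insertion", strains = list(strain))
      frame_restored <- TRUE
      stop_removed <- FALSE
    }

    # reference must actually be broken (truncated ORF)
    ref_orf <- find_orf(reference)
    full_orf_len <- 3 * n_aa + 3
    if (nrow(ref_orf) && ref_orf$width >= 0.95 * full_orf_len) next
    # restoring must give back the functional sequence
    if (apply_variants(reference, variants, strain) != functional) next

    # homolog: substitute codons so protein identity hits the target
    n_mut <- round((1 - homolog_identity_aa / 100) * n_aa)
    mut_at <- sample(2:(n_aa - 1), n_mut)
    homolog <- functional
    nt_changed <- 0L
    bases <- c("A", "C", "G", "T")
    codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
    # plain codon table (translate() would read initiator codons as M)
    aa_of <- Biostrings::GENETIC_CODE[codons]
    for (i in mut_at) {
      cod <- codon_at(functional, i)
      cand <- codons[aa_of != aa_of[[cod]] & !codons %in% STOP_CODONS & aa_of != "M"]
      new <- sample(cand, 1)
      nt_changed <- nt_changed +
        sum(strsplit(new, "")[[1]] != strsplit(cod, "")[[1]])
      homolog <- `codon_at<-`(homolog, i, new)
    }

    expected <- list(
      protein_length = n_aa,
      protein_identity = 100 * (n_aa - n_mut) / n_aa,
      nt_identity = 100 * (L - nt_changed) / L,
      functional = TRUE,
      stop_removed = stop_removed,
      frame_restored = frame_restored)
    return(list(reference = reference, functional = functional,
                homolog = homolog, variants = variants,
                expected = expected, strain = strain))
  }
  abort("failed to construct a pseudogene locus; try another seed")
}
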