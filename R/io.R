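# Readers/writers for the on-disk formats the pipeline touches.
#
# Conventions: counts are TSV with a `gene_id` header column; all internal
# coordinates are 1-based inclusive (Ensembl/GFF3 style); BED output is
# 0-based half-open.  Every writer drops a `<file>.json` provenance sidecar.

#' Read a gene-by-sample count matrix
#'
#' Expects a TSV whose header row names the samples and whose first column
#' holds gene ids.  Validation is strict: duplicate ids, ragged rows, and
#' negative or non-integer values are errors that name the offending line
#' or cell.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `gene_id` plus one integer column per sample, in
#'   file order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t3\t0", "g2\t10\t7"), tf)
#' read_counts(tf)
read_counts <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) abort("count file has no data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (header[1] != "gene_id") abort("count file header must start with 'gene_id'")
  ncol_expect <- length(header)
  widths <- lengths(fields[-1])
  if (any(widths != ncol_expect)) {
    bad <- which(widths != ncol_expect)[1] + 1
    abort(sprintf("ragged row at line %d: %d fields, expected %d",
                  bad, widths[bad - 1], ncol_expect))
  }
  body <- do.call(rbind, fields[-1])
  gid <- body[, 1]
  vals <- suppressWarnings(matrix(as.numeric(body[, -1, drop = FALSE]),
                                  nrow = nrow(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric count for gene '%s', sample '%s'",
                  gid[bad[1]], header[bad[2] + 1]))
  }
  colnames(vals) <- header[-1]
  rownames(vals) <- gid
  counts <- matrix_to_counts(vals)
  counts_matrix(counts, require_integer = TRUE)  # validates >= 0, integral, ids
  mutate(counts, across(-"gene_id", as.integer))
}

#' Write a count matrix to TSV (with provenance sidecar)
#'
#' @param counts Counts tibble as returned by [read_counts()].
#' @param path Output path.
#' @param seed Optional seed to record in the provenance sidecar.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, seed = NULL) {
  counts_matrix(counts, require_integer = TRUE)
  readr::write_tsv(counts, path)
  write_provenance(path, params = list(n_genes = nrow(counts),
                                       n_samples = ncol(counts) - 1L),
                   seed = seed)
  invisible(path)
}

#' Read sample metadata (sample_id, strain, sex, replicate)
#'
#' @param path TSV with columns `sample_id`, `strain`, `sex`, `replicate`.
#' @return Validated tibble.
#' @export
read_sample_meta <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            sample_id = readr::col_character(),
                            strain = readr::col_character(),
                            sex = readr::col_character(),
                            replicate = readr::col_integer()))
  if (any(meta$replicate < 1L)) abort("replicate must be a positive integer")
  validate_meta(meta)
  meta
}

#' @rdname read_sample_meta
#' @param meta Metadata tibble.
#' @export
write_sample_meta <- function(meta, path) {
  validate_meta(meta)
  readr::write_tsv(meta, path)
  write_provenance(path, params = list(n_samples = nrow(meta)))
  invisible(path)
}

#' Read gene annotation from GFF3 or TSV
#'
#' Both dialects are normalized to the same tibble with 1-based inclusive
#' coordinates, sorted by (chrom, start).  The TSV dialect expects columns
#' `gene_id, chrom, start, end, strand, biotype` and optionally `family`
#' and `length_bp`; the GFF3 dialect keeps `gene` features and reads the
#' `ID` (gene id), `biotype`/`gene_biotype` and `family` attributes.
#' Missing `length_bp` defaults to the genomic span.
#'
#' @param path Annotation file.
#' @param dialect `"tsv"` or `"gff3"`.
#' @return Tibble with columns `gene_id, chrom, start, end, strand,
#'   biotype, family, length_bp`.
#' @export
read_annotation <- function(path, dialect = c("tsv", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    ann <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
    miss <- setdiff(need, names(ann))
    if (length(miss)) abort(paste("annotation missing columns:",
                                  paste(miss, collapse = ", ")))
    if (!"family" %in% names(ann)) ann$family <- NA_character_
    if (!"length_bp" %in% names(ann)) ann$length_bp <- ann$end - ann$start + 1L
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    ann <- tibble(
      gene_id = as.character(gr$ID),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      biotype = as.character(gr$biotype %||% gr$gene_biotype %||%
                               rep(NA_character_, length(gr))),
      family = as.character(gr$family %||% rep(NA_character_, length(gr)))
    )
    ann$strand[ann$strand == "*"] <- "."
    ann$length_bp <- ann$end - ann$start + 1L
  }
  validate_annotation(ann)
  arrange(ann, .data$chrom, .data$start)
}

#' @keywords internal
validate_annotation <- function(ann) {
  if (anyDuplicated(ann$gene_id)) abort("duplicate gene_id in annotation")
  if (any(is.na(ann$chrom) | ann$chrom == "")) abort("empty chrom in annotation")
  bad <- ann$start > ann$end
  if (any(bad)) {
    abort(sprintf("start > end for gene '%s'", ann$gene_id[which(bad)[1]]))
  }
  if (!all(ann$strand %in% c("+", "-", "."))) abort("strand must be +, - or .")
  if (any(ann$length_bp <= 0)) abort("length_bp must be positive")
  invisible(ann)
}

#' @rdname read_annotation
#' @param ann Annotation tibble.
#' @export
write_annotation <- function(ann, path) {
  validate_annotation(ann)
  readr::write_tsv(ann, path)
  write_provenance(path, params = list(n_genes = nrow(ann)))
  invisible(path)
}

#' Convert 1-based inclusive gene intervals to BED (0-based half-open)
#'
#' The conversion subtracts 1 from `start` and leaves `end` alone, so it is
#' bijective on valid intervals ([bed_to_intervals()] inverts it).
#'
#' @param ann Annotation tibble (or any tibble with chrom/start/end and an
#'   id column named `gene_id` or `name`).
#' @return BED-schema tibble: `chrom, start, end, name, score, strand`.
#' @export
intervals_to_bed <- function(ann) {
  nm <- if ("gene_id" %in% names(ann)) ann$gene_id else ann$name
  strand <- if ("strand" %in% names(ann)) ann$strand else "."
  tibble(chrom = ann$chrom, start = ann$start - 1L, end = ann$end,
         name = nm, score = ".",
         strand = ifelse(strand == ".", ".", strand))
}

#' @rdname intervals_to_bed
#' @param bed BED-schema tibble.
#' @export
bed_to_intervals <- function(bed) {
  tibble(gene_id = bed$name, chrom = bed$chrom,
         start = bed$start + 1L, end = bed$end,
         strand = ifelse(bed$strand == ".", ".", bed$strand))
}

#' @rdname intervals_to_bed
#' @param path Output path.
#' @export
write_bed <- function(ann, path) {
  bed <- intervals_to_bed(ann)
  readr::write_tsv(bed, path, col_names = FALSE)
  write_provenance(path, params = list(n_intervals = nrow(bed)))
  invisible(path)
}

#' Read a VCF subset of SNVs and insertions with per-strain carriers
#'
#' Supports the narrow slice of VCF v4.2 this pipeline needs: biallelic
#' SNVs and insertions, one sample column per strain whose genotype is
#' read as presence/absence (any `1` allele means the strain carries the
#' variant).  Deletions and multi-allelic records are rejected with an
#' "unsupported variant class" error rather than silently skipped.
#'
#' @param path VCF file (uncompressed).
#' @return Tibble with columns `chrom, pos, ref, alt, kind, strains`
#'   (`strains` is a list column of carrier strain names), sorted by
#'   (chrom, pos).
#' @export
read_variants <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (!length(lines) || !startsWith(lines[1], "#CHROM")) {
    abort("not a VCF: missing #CHROM header")
  }
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  strains <- header[-(1:9)]
  if (!length(strains)) abort("VCF has no strain sample columns")
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  parse_row <- function(f) {
    ref <- f[4]; alt <- f[5]
    if (grepl(",", alt, fixed = TRUE)) {
      abort(sprintf("unsupported variant class at %s:%s: multi-allelic", f[1], f[2]))
    }
    if (nchar(ref) > 1) {
      abort(sprintf("unsupported variant class at %s:%s: deletion/indel REF", f[1], f[2]))
    }
    kind <- if (nchar(alt) == 1) "SNV" else "insertion"
    if (kind == "insertion" && substr(alt, 1, 1) != ref) {
      abort(sprintf("unsupported variant class at %s:%s: ALT does not extend REF", f[1], f[2]))
    }
    gts <- f[-(1:9)]
    carriers <- strains[grepl("1", sub(":.*", "", gts))]
    tibble(chrom = f[1], pos = as.integer(f[2]), ref = ref, alt = alt,
           kind = kind, strains = list(carriers))
  }
  out <- list_rbind(map(rows, parse_row))
  if (anyDuplicated(out[c("chrom", "pos", "ref", "alt")])) {
    abort("duplicate variant records")
  }
  arrange(out, .data$chrom, .data$pos)
}

#' @rdname read_variants
#' @param variants Variant tibble as returned by [read_variants()].
#' @param strains Character vector of all strain column names to emit.
#' @export
write_variants <- function(variants, path, strains = NULL) {
  all_strains <- strains %||% sort(unique(unlist(variants$strains)))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", all_strains), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    gt <- ifelse(all_strains %in% unlist(variants$strains[[i]]), "1/1", "0/0")
    paste(c(variants$chrom[i], variants$pos[i], ".", variants$ref[i],
            variants$alt[i], ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  write_provenance(path, params = list(n_variants = nrow(variants)))
  invisible(path)
}

#' Read/write FASTA sequences
#'
#' Thin wrappers around Biostrings keeping the package's provenance and
#' tibble conventions.
#' @param path FASTA file.
#' @return [read_sequences()]: a named [Biostrings::DNAStringSet].
#' @export
read_sequences <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname read_sequences
#' @param seqs Named `DNAStringSet` (or named character vector).
#' @export
write_sequences <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  write_provenance(path, params = list(n_seqs = length(seqs)))
  invisible(path)
}

#' Write a dendrogram as Newick with support values as node labels
#'
#' @param tree An [ape::phylo] object (node labels carry support).
#' @param path Output path.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  write_provenance(path, params = list(n_tips = length(tree$tip.label)))
  invisible(path)
}

#' @rdname write_tree_newick
#' @export
read_tree_newick <- function(path) {
  ape::read.tree(path)
}
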