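# Apply strain variants to reference gene sequences, reconstruct ORFs,
# translate, and call functionalized pseudogenes with percent identity to
# a designated homolog.

#' Apply SNVs and insertions to a reference sequence
#'
#' Edits are applied right-to-left so every variant position refers to the
#' original reference.  SNVs substitute one base; insertions add bases
#' *after* `pos` (VCF style: `alt` begins with `ref`).  Reference alleles
#' are verified, with an error naming the first mismatching position.
#'
#' @param refseq Reference nucleotide sequence (character or
#'   [Biostrings::DNAString]).
#' @param variants Variant tibble (`pos, ref, alt, kind, strains`), as
#'   from [read_variants()].
#' @param strain Strain whose carried variants are applied; variants not
#'   carried by `strain` are ignored.
#' @return Edited sequence (character).
#' @export
apply_variants <- function(refseq, variants, strain) {
  s <- as.character(refseq)
  v <- variants[map_lgl(variants$strains, function(x) strain %in% unlist(x)), ]
  if (!nrow(v)) return(s)
  if (anyDuplicated(v$pos)) abort("multiple variants at one position")
  bad <- substring(s, v$pos, v$pos) != v$ref
  if (any(bad)) {
    abort(sprintf("reference allele mismatch at position %d (found '%s', expected '%s')",
                  v$pos[which(bad)[1]],
                  substring(s, v$pos[which(bad)[1]], v$pos[which(bad)[1]]),
                  v$ref[which(bad)[1]]))
  }
  v <- arrange(v, dplyr::desc(.data$pos))
  for (i in seq_len(nrow(v))) {
    p <- v$pos[i]
    if (v$kind[i] == "SNV") {
      substr(s, p, p) <- v$alt[i]
    } else {
      s <- paste0(substr(s, 1, p - 1), v$alt[i], substr(s, p + 1, nchar(s)))
    }
  }
  s
}

#' Find the longest ATG-initiated open reading frame
#'
#' Scans the three forward frames for ORFs that start at an ATG and end at
#' the first in-frame stop; returns the longest (ties broken by earliest
#' start).  Sequences are supplied sense-strand, so reverse frames are not
#' searched.
#'
#' @param seq Nucleotide sequence (uppercase ACGT).
#' @return Tibble with 0 or 1 row: `start, end` (1-based inclusive,
#'   including the stop codon), `width`, `frame`.
#' @export
find_orf <- function(seq) {
  s <- as.character(seq)
  n <- nchar(s)
  best <- NULL
  for (frame in 0:2) {
    starts <- seq(1 + frame, n - 2, by = 3)
    if (!length(starts)) next
    codons <- substring(s, starts, starts + 2)
    is_start <- codons == "ATG"
    is_stop <- codons %in% STOP_CODONS
    stop_idx <- which(is_stop)
    for (a in which(is_start)) {
      stops_after <- stop_idx[stop_idx > a]
      if (!length(stops_after)) next
      b <- stops_after[1]
      width <- 3 * (b - a + 1)
      cand <- tibble(start = starts[a], end = starts[b] + 2L,
                     width = width, frame = frame)
      if (is.null(best) || width > best$width ||
          (width == best$width && cand$start < best$start)) {
        best <- cand
      }
      # later ATGs before the same stop are shorter; but keep scanning all
    }
  }
  if (is.null(best)) {
    return(tibble(start = integer(), end = integer(),
                  width = integer(), frame = integer()))
  }
  best
}

#' Translate an ORF (standard genetic code)
#'
#' @param orf_nt Nucleotide sequence of the ORF, length divisible by 3,
#'   ending in a stop codon (or stop-free).
#' @return Amino-acid string, terminal stop excluded.
#' @export
translate_orf <- function(orf_nt) {
  s <- as.character(orf_nt)
  if (nchar(s) %% 3 != 0) abort("ORF length not divisible by 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
  if (endsWith(aa, "*")) aa <- substr(aa, 1, nchar(aa) - 1)
  if (grepl("*", aa, fixed = TRUE)) abort("internal stop codon in ORF")
  aa
}

#' Percent identity from a global alignment
#'
#' Needleman-Wunsch global alignment: nucleotides score match +1 /
#' mismatch -1 with gap open 5 and extend 1; proteins use BLOSUM62 with
#' gap open 11 and extend 1.  Identity is `100 * matches / alignment
#' columns` (aligned length including gaps), so it is symmetric and fixed
#' scoring keeps it reproducible bit-exactly.
#'
#' @param a,b Sequences (character).
#' @param alphabet `"nt"` or `"aa"`.
#' @return Percentage in `[0, 100]`.
#' @export
percent_identity <- function(a, b, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  a <- as.character(a); b <- as.character(b)
  if (!nchar(a) || !nchar(b)) abort("empty sequence")
  if (alphabet == "nt") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      type = "global", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 1)
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
  }
  100 * Biostrings::nmatch(aln) /
    nchar(as.character(Biostrings::alignedPattern(aln)))
}

#' Call functionalization of a pseudogene for one strain
#'
#' Applies the strain's variants, finds the longest ORF in the edited and
#' the unedited reference sequence, and calls the locus functional when
#' the edited ORF covers at least `min_orf_frac` of the homolog's ORF
#' length while the reference ORF does not.  `stop_removed` /
#' `frame_restored` are diagnosed by comparing the reference and edited
#' sequences: any applied insertion implies a frame change, and an SNV
#' that overwrites a stop codon in the reference ORF frame implies a
#' removed stop.
#'
#' @param refseq Reference nucleotide sequence.
#' @param variants Variant tibble.
#' @param strain Strain to evaluate.
#' @param homolog Homolog nucleotide sequence (its longest ORF defines
#'   full length and the identity comparisons).
#' @param min_orf_frac Fraction of the homolog ORF the edited ORF must
#'   reach (default 0.95).
#' @return One-row tibble: `strain, orf_start, orf_end, protein_length,
#'   stop_removed, frame_restored, protein_identity, nt_identity,
#'   functional`.
#' @export
call_functionalization <- function(refseq, variants, strain, homolog,
                                   min_orf_frac = 0.95) {
  refseq <- as.character(refseq)
  edited <- apply_variants(refseq, variants, strain)
  ref_orf <- find_orf(refseq)
  ed_orf <- find_orf(edited)
  hom_orf <- find_orf(homolog)
  if (!nrow(hom_orf)) abort("homolog has no ATG-initiated ORF with a stop")
  hom_nt <- substr(as.character(homolog), hom_orf$start, hom_orf$end)
  hom_aa <- translate_orf(hom_nt)

  applied <- variants[map_lgl(variants$strains, function(x) strain %in% unlist(x)), ]
  frame_restored <- any(applied$kind == "insertion")
  stop_removed <- FALSE
  if (nrow(ed_orf) && any(applied$kind == "SNV")) {
    # a SNV removed a stop iff, read in the restored ORF's frame, the
    # reference had a stop codon overlapped by an applied SNV.  Map the
    # edited ORF start back to reference coordinates through insertions.
    snv_pos <- applied$pos[applied$kind == "SNV"]
    ref_start <- ed_orf$start
    ins <- applied[applied$kind == "insertion", ]
    if (nrow(ins)) {
      ins <- arrange(ins, .data$pos)
      off <- 0L
      for (i in seq_len(nrow(ins))) {
        extra <- nchar(ins$alt[i]) - 1L
        if (ed_orf$start > ins$pos[i] + off) off <- off + extra
      }
      ref_start <- ed_orf$start - off
    }
    if (ref_start >= 1 && ref_start <= nchar(refseq) - 2) {
      frame_starts <- seq(ref_start, nchar(refseq) - 2, by = 3)
      ref_codons <- substring(refseq, frame_starts, frame_starts + 2)
      stop_starts <- frame_starts[ref_codons %in% STOP_CODONS]
      stop_removed <- any(vapply(stop_starts, function(s)
        any(snv_pos >= s & snv_pos <= s + 2), logical(1)))
    }
  }

  functional <- nrow(ed_orf) > 0 &&
    ed_orf$width >= min_orf_frac * hom_orf$width &&
    !(nrow(ref_orf) > 0 && ref_orf$width >= min_orf_frac * hom_orf$width)

  if (nrow(ed_orf)) {
    ed_nt <- substr(edited, ed_orf$start, ed_orf$end)
    ed_aa <- translate_orf(ed_nt)
    pid_aa <- percent_identity(ed_aa, hom_aa, "aa")
    pid_nt <- percent_identity(ed_nt, hom_nt, "nt")
  } else {
    ed_aa <- ""
    pid_aa <- NA_real_
    pid_nt <- NA_real_
  }

  tibble(strain = strain,
         orf_start = if (nrow(ed_orf)) ed_orf$start else NA_integer_,
         orf_end = if (nrow(ed_orf)) ed_orf$end else NA_integer_,
         protein_length = nchar(ed_aa),
         stop_removed = stop_removed,
         frame_restored = frame_restored,
         protein_identity = pid_aa,
         nt_identity = pid_nt,
         functional = functional)
}
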