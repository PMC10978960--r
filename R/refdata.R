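#' Construct a reference annotation record
#'
#' A reference annotation ties landmark residues of a reference SAHH/SIHH
#' sequence to their 1-based positions: the five-residue nucleobase-binding
#' fingerprint motif (position of its His), the His/Phe molecular-gate
#' pair, the catalytic Asp the gate His faces in the His-IN state, the Glu
#' partner it hydrogen-bonds in the His-OUT state, the residue whose
#' main-chain carbonyl contacts the nucleobase C6 substituent (tautomer
#' evidence), named domain ranges and, where present, the 40-residue
#' catalytic-domain segment.
#'
#' @param ref_id identifier.
#' @param ref_sequence [protein_sequence()] (or string).
#' @param motif_start 1-based position of the motif His (motif spans
#'   `motif_start .. motif_start + 4`), or `NA`.
#' @param motif_residues expected residues at the motif anchor positions
#'   1/3/5 plus wildcards, e.g. `"HxExK"`; checked against the sequence.
#' @param gate_his,gate_phe,catalytic_asp,out_partner_glu,c6_partner
#'   1-based landmark indices (`NA` allowed).
#' @param domain_ranges named list of `c(start, end)` integer intervals
#'   (closed); conventional names are `substrate_binding`,
#'   `cofactor_binding`, `dimerisation`, `hinge`.
#' @param segment40 `c(start, end)` interval of the 40-residue segment in a
#'   segment-containing reference, or `NULL`.
#' @return an object of class `reference_annotation`.
#' @export
reference_annotation <- function(ref_id, ref_sequence, motif_start = NA,
                                 motif_residues = NA,
                                 gate_his = NA, gate_phe = NA,
                                 catalytic_asp = NA, out_partner_glu = NA,
                                 c6_partner = NA, domain_ranges = list(),
                                 segment40 = NULL) {
  seqstr <- as_residue_string(ref_sequence)
  n <- nchar(seqstr)
  idx <- c(motif_start = motif_start, gate_his = gate_his,
           gate_phe = gate_phe, catalytic_asp = catalytic_asp,
           out_partner_glu = out_partner_glu, c6_partner = c6_partner)
  for (nm in names(idx)) {
    v <- idx[[nm]]
    if (!is.na(v) && (v < 1 || v > n))
      stop("landmark ", nm, " = ", v, " outside [1, ", n, "] for ", ref_id)
  }
  if (!is.na(motif_start)) {
    if (motif_start + 4 > n) stop("motif extends past sequence end")
    if (!is.na(motif_residues)) {
      anchors <- strsplit(motif_residues, "")[[1]][c(1, 3, 5)]
      have <- substring(seqstr, motif_start + c(0, 2, 4),
                        motif_start + c(0, 2, 4))
      if (!all(have == anchors))
        stop("reference ", ref_id, ": motif anchors are ",
             paste(have, collapse = ""), ", annotation says ",
             paste(anchors, collapse = ""))
    }
  }
  if (!is.null(segment40)) {
    segment40 <- as.integer(segment40)
    stopifnot(length(segment40) == 2L, segment40[1] >= 1, segment40[2] <= n,
              segment40[1] <= segment40[2])
  }
  for (rng in domain_ranges) {
    stopifnot(length(rng) == 2L, rng[1] >= 1, rng[2] <= n, rng[1] <= rng[2])
  }
  if (inherits(ref_sequence, "protein_sequence")) {
    refseq <- ref_sequence
  } else {
    refseq <- protein_sequence(ref_id, seqstr)
  }
  structure(list(ref_id = ref_id, ref_sequence = refseq,
                 motif_start = motif_start, motif_residues = motif_residues,
                 gate_his = gate_his, gate_phe = gate_phe,
                 catalytic_asp = catalytic_asp,
                 out_partner_glu = out_partner_glu,
                 c6_partner = c6_partner,
                 domain_ranges = domain_ranges, segment40 = segment40),
            class = "reference_annotation")
}

#' @export
print.reference_annotation <- function(x, ...) {
  cat("<reference_annotation> ", x$ref_id, " (",
      nchar(x$ref_sequence$residues), " aa), motif at ",
      x$motif_start, if (!is.na(x$motif_residues))
        paste0(" [", x$motif_residues, "]"),
      ", gate ", x$gate_his, "/", x$gate_phe, "\n", sep = "")
  invisible(x)
}

parse_ranges <- function(s) {
  # "substrate_binding=1-180;cofactor_binding=181-350"
  if (is.na(s) || !nzchar(s)) return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    se <- as.integer(strsplit(kv[2], "-", fixed = TRUE)[[1]])
    out[[kv[1]]] <- se
  }
  out
}

#' Load the packaged reference set
#'
#' Reads the versioned plain-text reference tables shipped with the
#' package: reference sequences (synthetic scaffolds constructed to carry
#' the family's landmark residues at their literature positions, see the
#' package vignette) and their landmark annotations.
#'
#' @param dir directory holding `synthetic_reference_sequences.fasta` and
#'   `reference_annotations.tsv`; defaults to the installed package data.
#' @return named list of [reference_annotation()] objects.
#' @export
load_reference_set <- function(dir = system.file("extdata",
                                                 package = "sahhtools")) {
  seqs <- read_fasta(file.path(dir, "synthetic_reference_sequences.fasta"))
  tab <- utils::read.delim(file.path(dir, "reference_annotations.tsv"),
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  out <- list()
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (is.null(seqs[[r$ref_id]]))
      stop("no packaged sequence for reference ", r$ref_id)
    seg <- if (!is.na(r$segment40_start)) c(r$segment40_start,
                                            r$segment40_end) else NULL
    out[[r$ref_id]] <- reference_annotation(
      ref_id = r$ref_id, ref_sequence = seqs[[r$ref_id]],
      motif_start = r$motif_start, motif_residues = r$motif_residues,
      gate_his = r$gate_his, gate_phe = r$gate_phe,
      catalytic_asp = r$catalytic_asp, out_partner_glu = r$out_partner_glu,
      c6_partner = r$c6_partner,
      domain_ranges = parse_ranges(r$domain_ranges), segment40 = seg)
  }
  # sequence-only references (homolog-scan baits) carry no landmarks
  for (id in setdiff(names(seqs), tab$ref_id)) {
    out[[id]] <- reference_annotation(ref_id = id,
                                      ref_sequence = seqs[[id]])
  }
  out
}

#' Load the packaged synthetic study sequence set
#'
#' Eighteen synthetic stand-in sequences, one per biochemically tested
#' enzyme of the study set, built on the packaged reference scaffolds with
#' each enzyme's fingerprint-motif group, 40-residue-segment state and
#' C-terminal length planted. The accompanying metadata table carries the
#' organism, phylum and the published semi-quantitative conversion symbols
#' used as a fixed truth table.
#'
#' @param dir data directory, as in [load_reference_set()].
#' @return list with `sequences` (named list of [protein_sequence()]) and
#'   `metadata` (data.frame).
#' @export
load_study_set <- function(dir = system.file("extdata",
                                             package = "sahhtools")) {
  meta <- utils::read.delim(file.path(dir, "study_set_metadata.tsv"),
                            stringsAsFactors = FALSE)
  seqs <- read_fasta(file.path(dir, "study_set_synthetic.fasta"))
  for (i in seq_len(nrow(meta))) {
    id <- meta$enzyme[i]
    if (!is.null(seqs[[id]])) {
      seqs[[id]]$organism <- meta$organism[i]
      seqs[[id]]$phylum <- meta$phylum[i]
    }
  }
  list(sequences = seqs, metadata = meta)
}
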