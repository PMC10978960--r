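MOTIF_ANCHORS <- list(HxExK = c("H", "E", "K"),
                      HxTxE = c("H", "T", "E"),
                      HxTxQ = c("H", "T", "Q"))

#' Generate motif-planted protein sequences with ground truth
#'
#' Produces `n` sequences carrying a chosen fingerprint-motif class at
#' known anchor positions, on either a reference-derived scaffold (a
#' [reference_annotation()], keeping its landmark layout) or a seeded
#' random scaffold. Optional noise: random substitutions outside the
#' anchor columns, deletion of the scaffold's 40-residue segment, and
#' C-terminal truncation. Deterministic under `seed`; planting then
#' extracting with no noise always returns the planted class.
#'
#' @param n number of sequences (>= 1).
#' @param motif_class `"HxExK"`, `"HxTxE"` or `"HxTxQ"`.
#' @param scaffold a [reference_annotation()] to mutate, or `NULL` for a
#'   random scaffold of length `scaffold_length` with the motif at
#'   position `motif_start`.
#' @param motif_start motif His position for random scaffolds.
#' @param scaffold_length random-scaffold length.
#' @param n_outside_substitutions random substitutions per sequence at
#'   non-anchor columns.
#' @param delete_segment40 remove the scaffold's annotated 40-residue
#'   segment (requires a segment-annotated scaffold).
#' @param cterm_truncation residues removed from the C-terminus.
#' @param seed integer RNG seed.
#' @param fasta optional path; when given, sequences are written as FASTA
#'   with a ground-truth JSON sidecar.
#' @return list with `sequences` (named list of [protein_sequence()]) and
#'   `truth` (data.frame: `id`, `motif_class`, `motif_start`,
#'   `segment40_present`, `cterm_truncation`, `n_substitutions`).
#' @export
make_motif_sequences <- function(n, motif_class = "HxExK",
                                 scaffold = NULL, motif_start = 55,
                                 scaffold_length = 430,
                                 n_outside_substitutions = 0,
                                 delete_segment40 = FALSE,
                                 cterm_truncation = 0, seed = 1,
                                 fasta = NULL) {
  stopifnot(n >= 1, motif_class %in% names(MOTIF_ANCHORS))
  anchors <- MOTIF_ANCHORS[[motif_class]]
  set.seed(seed)
  aa20 <- setdiff(AA_ALPHABET, "X")
  if (!is.null(scaffold)) {
    stopifnot(inherits(scaffold, "reference_annotation"))
    base <- strsplit(scaffold$ref_sequence$residues, "")[[1]]
    mstart <- scaffold$motif_start
    if (is.na(mstart)) mstart <- motif_start
    seg <- scaffold$segment40
  } else {
    base <- sample(aa20, scaffold_length, replace = TRUE)
    mstart <- motif_start
    seg <- NULL
  }
  if (delete_segment40 && is.null(seg))
    stop("delete_segment40 requires a segment-annotated scaffold")
  if (cterm_truncation >= length(base) - mstart - 4)
    stop("truncation longer than the scaffold allows")
  anchor_pos <- mstart + c(0, 2, 4)
  seqs <- list()
  truth <- NULL
  for (i in seq_len(n)) {
    s <- base
    s[anchor_pos] <- anchors
    if (n_outside_substitutions > 0) {
      cand <- setdiff(seq_along(s), anchor_pos)
      pos <- sample(cand, n_outside_substitutions)
      for (p in pos) s[p] <- sample(setdiff(aa20, s[p]), 1)
    }
    if (delete_segment40) {
      drop <- seq.int(seg[1], seg[2])
      s <- s[-drop]
    }
    if (cterm_truncation > 0)
      s <- s[seq_len(length(s) - cterm_truncation)]
    id <- sprintf("planted_%s_%03d", motif_class, i)
    seqs[[id]] <- protein_sequence(id, paste(s, collapse = ""))
    truth <- rbind(truth, data.frame(
      id = id, motif_class = motif_class, motif_start = mstart,
      segment40_present = !is.null(seg) && !delete_segment40,
      cterm_truncation = cterm_truncation,
      n_substitutions = n_outside_substitutions,
      stringsAsFactors = FALSE))
  }
  if (!is.null(fasta)) {
    write_fasta(seqs, fasta)
    jsonlite::write_json(truth, paste0(fasta, ".json"), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  list(sequences = seqs, truth = truth)
}

#' Generate a random proteome (negative control for homolog scans)
#'
#' @param n_seqs number of sequences.
#' @param length sequence length.
#' @param seed RNG seed.
#' @return named list of [protein_sequence()] objects.
#' @export
make_random_proteome <- function(n_seqs = 50, length = 300, seed = 1) {
  set.seed(seed)
  aa20 <- setdiff(AA_ALPHABET, "X")
  out <- list()
  for (i in seq_len(n_seqs)) {
    id <- sprintf("random_%03d", i)
    out[[id]] <- protein_sequence(
      id, paste(sample(aa20, length, replace = TRUE), collapse = ""))
  }
  out
}
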