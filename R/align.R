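#' Global pairwise protein alignment with affine gap penalties
#'
#' Optimal global (Needleman-Wunsch) alignment under a substitution matrix
#' with affine gap costs: a gap of length L costs
#' `gap_open + L * gap_extend`. The default scoring (BLOSUM62, 11/1) is the
#' standard protein setting. The traceback is deterministic, so repeated
#' calls return the same alignment.
#'
#' @param query,ref [protein_sequence()] objects or amino-acid strings.
#' @param matrix name of a substitution matrix shipped with Biostrings
#'   (e.g. `"BLOSUM62"`) or a numeric matrix.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return an `alignment_result`: list with `query_id`, `ref_id`,
#'   `aligned_query`, `aligned_ref` (equal-length gapped strings), `score`,
#'   and `mapping`, a data.frame with columns `ref_pos`, `query_pos`
#'   (1-based, match/mismatch columns only, strictly increasing in both).
#' @export
global_align <- function(query, ref, matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  q <- as_residue_string(query)
  r <- as_residue_string(ref)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(r),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  aq <- as.character(Biostrings::alignedPattern(pa))
  ar <- as.character(Biostrings::alignedSubject(pa))
  res <- list(query_id = seq_id_of(query, "query"),
              ref_id = seq_id_of(ref, "ref"),
              aligned_query = unname(aq), aligned_ref = unname(ar),
              score = Biostrings::score(pa),
              mapping = alignment_mapping(aq, ar))
  class(res) <- "alignment_result"
  stopifnot(gsub("-", "", res$aligned_query) == q,
            gsub("-", "", res$aligned_ref) == r)
  res
}

# Match/mismatch column mapping between two gapped strings of equal length.
alignment_mapping <- function(aligned_query, aligned_ref) {
  qc <- strsplit(aligned_query, "")[[1]]
  rc <- strsplit(aligned_ref, "")[[1]]
  stopifnot(length(qc) == length(rc))
  qpos <- cumsum(qc != "-")
  rpos <- cumsum(rc != "-")
  keep <- qc != "-" & rc != "-"
  data.frame(ref_pos = rpos[keep], query_pos = qpos[keep])
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result> ", x$query_id, " vs ", x$ref_id,
      "  score ", x$score, ", ", nrow(x$mapping), " matched columns\n",
      sep = "")
  invisible(x)
}

# For each reference position, the aligned query position (NA if the query
# has a gap there or the position lies outside the alignment).
ref_to_query <- function(aln, ref_positions) {
  idx <- match(ref_positions, aln$mapping$ref_pos)
  aln$mapping$query_pos[idx]
}

#' Best local-alignment hit of a reference in a sequence collection
#'
#' Smith-Waterman scan of every sequence in `proteome` against `reference`;
#' the hit with the highest score is reported together with percent
#' identity over the aligned region and percent coverage of the reference.
#'
#' @param proteome list of [protein_sequence()] objects (or strings).
#' @param reference a [protein_sequence()] (or string).
#' @param matrix,gap_open,gap_extend scoring, as in [global_align()].
#' @return list with `best_query_id`, `score`, `identity_pct`,
#'   `coverage_pct`.
#' @keywords internal
best_local_hit <- function(proteome, reference, matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1) {
  if (length(proteome) == 0L) stop("empty proteome")
  r <- Biostrings::AAString(as_residue_string(reference))
  best <- NULL
  for (i in seq_along(proteome)) {
    q <- proteome[[i]]
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(as_residue_string(q)), r,
      type = "local", substitutionMatrix = matrix,
      gapOpening = gap_open, gapExtension = gap_extend)
    sc <- Biostrings::score(pa)
    if (is.null(best) || sc > best$score) {
      rng <- Biostrings::subject(pa)
      best <- list(
        best_query_id = seq_id_of(q, paste0("seq", i)),
        score = sc,
        identity_pct = Biostrings::pid(pa, type = "PID1"),
        coverage_pct = 100 * Biostrings::width(rng) / length(r))
    }
  }
  best
}
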