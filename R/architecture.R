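#' Detect architecture features relative to a segment-containing reference
#'
#' Two sequence features discriminate SAHH/SIHH subgroups: presence of a
#' 40-residue segment in the catalytic (substrate-binding) domain, which
#' archaeal homologues (bar two halophilic ones) and a few
#' bacterial/eukaryotic ones lack, and the length of the C-terminus, which
#' correlates with thermophilicity (thermophiles carry a shortened
#' C-terminus).
#'
#' The segment is called present when at least half of the reference
#' columns inside the annotated segment interval are aligned to (non-gap)
#' query residues. `cterm_delta` is the signed difference between the
#' number of query residues and reference residues past the last aligned
#' column; `thermophile_flag` is the heuristic `cterm_delta <= -15`,
#' reported but never used in preference prediction.
#'
#' @param query a [protein_sequence()] (or string).
#' @param ref a [reference_annotation()] annotated with `segment40` and a
#'   long C-terminus (mesophilic-type reference).
#' @param aln optional precomputed [global_align()] result.
#' @return an `architecture_features` list: `segment40_present`,
#'   `segment40_coverage`, `cterm_delta`, `thermophile_flag`.
#' @export
detect_architecture_features <- function(query, ref, aln = NULL) {
  stopifnot(inherits(ref, "reference_annotation"))
  if (is.null(ref$segment40))
    stop("reference ", ref$ref_id,
         " carries no segment40 annotation; use a segment-containing ",
         "reference")
  if (is.null(aln)) aln <- global_align(query, ref$ref_sequence)
  seg <- seq.int(ref$segment40[1], ref$segment40[2])
  qpos <- ref_to_query(aln, seg)
  coverage <- mean(!is.na(qpos))
  reflen <- nchar(ref$ref_sequence$residues)
  qlen <- nchar(as_residue_string(query))
  m <- aln$mapping
  if (nrow(m) == 0L) stop("query does not align to reference ", ref$ref_id)
  last <- m[nrow(m), ]
  cterm_delta <- (qlen - last$query_pos) - (reflen - last$ref_pos)
  structure(list(segment40_present = coverage >= 0.5,
                 segment40_coverage = coverage,
                 cterm_delta = as.integer(cterm_delta),
                 thermophile_flag = cterm_delta <= -15),
            class = "architecture_features")
}

#' @export
print.architecture_features <- function(x, ...) {
  cat("<architecture_features> segment40 ",
      if (x$segment40_present) "present" else "absent",
      sprintf(" (%.0f%% columns)", 100 * x$segment40_coverage),
      ", C-terminus delta ", x$cterm_delta,
      if (x$thermophile_flag) " [thermophile-like]", "\n", sep = "")
  invisible(x)
}
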