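MOTIF_CLASSES <- c("HxExK", "HxTxE", "HxTxQ", "HxExX", "other",
                   "undetermined")

#' Extract the nucleobase-binding fingerprint motif from an alignment
#'
#' Reads the query residues aligned to the reference motif span
#' (`motif_start .. motif_start + 4`). The motif class is derived from the
#' anchor positions 1/3/5 only; the "x" positions 2/4 never affect it.
#'
#' @param query a [protein_sequence()] (or string).
#' @param ref a [reference_annotation()] with a motif annotation.
#' @param aln an [global_align()] result relating `query` to the reference
#'   sequence; computed on the fly when `NULL`.
#' @return a `fingerprint_motif`: list with `residues` (5 characters, `-`
#'   for unaligned positions), `query_positions` (1-based indices, `NA`
#'   where gapped) and `motif_class`.
#' @export
extract_fingerprint <- function(query, ref, aln = NULL) {
  stopifnot(inherits(ref, "reference_annotation"))
  if (is.na(ref$motif_start))
    stop("reference ", ref$ref_id, " has no motif annotation")
  if (is.null(aln)) aln <- global_align(query, ref$ref_sequence)
  qstr <- as_residue_string(query)
  pos <- ref_to_query(aln, ref$motif_start + 0:4)
  resi <- ifelse(is.na(pos), "-", substring(qstr, pos, pos))
  motif <- structure(
    list(residues = paste(resi, collapse = ""),
         query_positions = pos,
         motif_class = motif_class_from_anchors(resi[1], resi[3], resi[5])),
    class = "fingerprint_motif")
  motif
}

# Pure classification of the three anchor characters ("-" = unaligned).
motif_class_from_anchors <- function(a1, a3, a5) {
  if (any(c(a1, a3, a5) == "-")) return("undetermined")
  if (a1 != "H") return("other")
  if (a3 == "E" && a5 == "K") return("HxExK")
  if (a3 == "T" && a5 == "E") return("HxTxE")
  if (a3 == "T" && a5 == "Q") return("HxTxQ")
  if (a3 == "E") return("HxExX")
  "other"
}

#' @export
print.fingerprint_motif <- function(x, ...) {
  cat("<fingerprint_motif> ", x$residues, " (class ", x$motif_class, ")\n",
      sep = "")
  invisible(x)
}

#' Predict substrate preference from a fingerprint motif
#'
#' The family rule: homologues with an HxExK motif prefer the hypoxanthine
#' substrate SIH, while an HxTxE or HxTxQ motif marks SAH-preferring
#' enzymes. Any other (or unalignable) motif yields `unknown`. A non-His
#' residue at motif position 1 invalidates the catalytic His and forces
#' `unknown` regardless of the remaining anchors.
#'
#' @param motif a `fingerprint_motif` from [extract_fingerprint()].
#' @return a `preference_prediction`: list with `label` (one of
#'   `SIH-preferring`, `SAH-preferring`, `unknown`), `basis` note and
#'   `valid_catalytic_his`.
#' @export
classify_motif <- function(motif) {
  stopifnot(inherits(motif, "fingerprint_motif"))
  resi <- strsplit(motif$residues, "")[[1]]
  valid_his <- length(resi) == 5L && resi[1] == "H"
  cls <- motif$motif_class
  if (!valid_his) {
    label <- "unknown"
    basis <- paste0("position-1 residue '", resi[1], "' is not His; ",
                    "the His residue is important for catalysis")
  } else if (cls == "HxExK") {
    label <- "SIH-preferring"
    basis <- "HxExK fingerprint motif"
  } else if (cls %in% c("HxTxE", "HxTxQ")) {
    label <- "SAH-preferring"
    basis <- paste0(cls, " fingerprint motif")
  } else {
    label <- "unknown"
    basis <- paste0("motif class ", cls, " carries no preference rule")
  }
  structure(list(label = label, basis = basis,
                 valid_catalytic_his = valid_his),
            class = "preference_prediction")
}

#' @export
print.preference_prediction <- function(x, ...) {
  cat("<preference_prediction> ", x$label, " (", x$basis, ")\n", sep = "")
  invisible(x)
}
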