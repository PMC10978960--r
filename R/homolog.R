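#' Scan a proteome for a homologue of a packaged reference enzyme
#'
#' Local-alignment (Smith-Waterman) scan of every sequence in a proteome
#' against a reference protein (DadD, the SAH deaminase, or MTAN, the SAH
#' nucleosidase). Presence is called when the best hit reaches both the
#' identity and the coverage threshold.
#'
#' @param proteome list of [protein_sequence()] objects (or strings).
#' @param reference a [protein_sequence()] reference (e.g. from
#'   [load_reference_set()]: `MjDadD_like`, `EcMTAN_like`).
#' @param reference_name display name, `"DadD"` or `"MTAN"`.
#' @param min_identity,min_coverage presence thresholds in percent
#'   (defaults 30 / 70, a conventional homology floor).
#' @return a `homolog_hit`: list with `reference_name`, `present`,
#'   `best_query_id`, `score`, `identity_pct`, `coverage_pct`.
#' @export
scan_homolog <- function(proteome, reference,
                         reference_name = c("DadD", "MTAN"),
                         min_identity = 30, min_coverage = 70) {
  reference_name <- match.arg(reference_name)
  hit <- best_local_hit(proteome, reference)
  structure(list(reference_name = reference_name,
                 present = hit$identity_pct >= min_identity &&
                   hit$coverage_pct >= min_coverage,
                 best_query_id = hit$best_query_id,
                 score = hit$score,
                 identity_pct = hit$identity_pct,
                 coverage_pct = hit$coverage_pct),
            class = "homolog_hit")
}

#' @export
print.homolog_hit <- function(x, ...) {
  cat(sprintf("<homolog_hit> %s: %s (best %s, %.1f%% id, %.1f%% cov)\n",
              x$reference_name,
              if (x$present) "present" else "absent",
              x$best_query_id, x$identity_pct, x$coverage_pct))
  invisible(x)
}

#' Infer SAH-degradation routes available to an organism
#'
#' Deterministic truth table over the organism's SAHH motif-based
#' preference and the presence of DadD and MTAN homologues. SAH can be
#' cleaved directly by an SAHH (both SAH-preferring enzymes and
#' SIH-preferring ones, which retain SAH activity); a DadD deaminase
#' together with an SIH-accepting hydrolase opens the two-step deamination
#' route via SIH; MTAN marks the MTAN/LuxS two-step route. An organism
#' encoding DadD but only an SAH-cleaving SAHH and no MTAN is flagged:
#' its SIH must be metabolised by another pathway.
#'
#' @param sahh_class preference label: `"SIH-preferring"`,
#'   `"SAH-preferring"` or `"unknown"` (a [classify_motif()] result is
#'   also accepted).
#' @param dadd_present,mtan_present logicals (or [scan_homolog()] results).
#' @return a `pathway_call`: list with `routes` (subset of
#'   `SAHH_direct`, `deamination_SIH`, `MTAN_LuxS`, or `none`) and
#'   `rationale`.
#' @export
infer_pathway <- function(sahh_class, dadd_present, mtan_present) {
  if (inherits(sahh_class, "preference_prediction"))
    sahh_class <- sahh_class$label
  if (inherits(dadd_present, "homolog_hit"))
    dadd_present <- dadd_present$present
  if (inherits(mtan_present, "homolog_hit"))
    mtan_present <- mtan_present$present
  stopifnot(sahh_class %in% c("SIH-preferring", "SAH-preferring",
                              "unknown"),
            is.logical(dadd_present), is.logical(mtan_present))
  routes <- character(0)
  notes <- character(0)
  if (sahh_class %in% c("SAH-preferring", "SIH-preferring")) {
    routes <- c(routes, "SAHH_direct")
    if (sahh_class == "SIH-preferring")
      notes <- c(notes, paste0("SIH-preferring hydrolase retains SAH ",
                               "activity (dual function)"))
  }
  if (dadd_present && sahh_class == "SIH-preferring")
    routes <- c(routes, "deamination_SIH")
  if (mtan_present) routes <- c(routes, "MTAN_LuxS")
  if (dadd_present && sahh_class == "SAH-preferring" && !mtan_present)
    notes <- c(notes, paste0("DadD present but hydrolase cleaves only ",
                             "SAH and no MTAN found: SIH metabolised by ",
                             "another pathway"))
  if (length(routes) == 0L) routes <- "none"
  structure(list(routes = routes,
                 rationale = if (length(notes)) paste(notes,
                                                      collapse = "; ")
                 else ""),
            class = "pathway_call")
}

#' @export
print.pathway_call <- function(x, ...) {
  cat("<pathway_call> {", paste(x$routes, collapse = ", "), "}",
      if (nzchar(x$rationale)) paste0("\n  note: ", x$rationale), "\n",
      sep = "")
  invisible(x)
}
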