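#' Default run configuration
#'
#' All tunable thresholds of the pipeline in one place. Values are
#' documented with their units in the package vignette.
#'
#' @return named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    gate_in_threshold = 6.0,      # A, His-IN call
    gate_out_threshold = 8.0,     # A, His-OUT call
    hbond_cutoff = 3.5,           # A, donor-acceptor heavy atoms
    homolog_min_identity = 30,    # %, presence floor
    homolog_min_coverage = 70,    # %, presence floor
    noise_floor = 1,              # %, conversion "no conversion" band
    flip_threshold = 120,         # deg, peptide-plane flip
    domain_angle_tolerance = 6,   # deg, open/closed call window
    open_angle = 18,              # deg, expected open-closed separation
    cation_cutoff = 6.0,          # A, hinge cation detection
    min_chain_identity = 0.3      # fraction, chain-to-reference mapping
  ), class = "run_config")
}

#' Read a plain-text key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Unknown keys
#' are rejected; all thresholds must be positive numbers. Values not in
#' the file keep their defaults.
#'
#' @param path config file, or `NULL` for pure defaults.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    if (is.na(val) || val <= 0) stop("config value for ", key,
                                     " must be a positive number")
    cfg[[key]] <- val
  }
  cfg
}

#' Annotate protein sequences with motif, preference and architecture
#'
#' The per-sequence report behind the `annotate-seq` command: fingerprint
#' motif and class, predicted substrate preference, 40-residue-segment
#' state and C-terminal length versus the segment-containing reference.
#'
#' @param seqs named list of [protein_sequence()] (or a FASTA path).
#' @param refs reference set from [load_reference_set()]; needs the
#'   motif reference (`PfuSAHH_like` by default) and a
#'   segment-containing reference (`LlSAHH_like`).
#' @param motif_ref,segment_ref reference ids to use.
#' @return data.frame, one row per sequence: `id`, `motif`,
#'   `motif_class`, `predicted`, `valid_catalytic_his`,
#'   `segment40_present`, `cterm_delta`, `thermophile_flag`.
#' @export
annotate_sequences <- function(seqs,
                               refs = load_reference_set(),
                               motif_ref = "PfuSAHH_like",
                               segment_ref = "LlSAHH_like") {
  if (is.character(seqs) && length(seqs) == 1L) seqs <- read_fasta(seqs)
  if (length(seqs) == 0L) stop("no sequences to annotate")
  mref <- refs[[motif_ref]]
  sref <- refs[[segment_ref]]
  if (is.null(mref) || is.null(sref))
    stop("reference set lacks ", motif_ref, " or ", segment_ref)
  rows <- lapply(seqs, function(s) {
    motif <- extract_fingerprint(s, mref)
    pred <- classify_motif(motif)
    arch <- detect_architecture_features(s, sref)
    data.frame(id = s$id, motif = motif$residues,
               motif_class = motif$motif_class, predicted = pred$label,
               valid_catalytic_his = pred$valid_catalytic_his,
               segment40_present = arch$segment40_present,
               cterm_delta = arch$cterm_delta,
               thermophile_flag = arch$thermophile_flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate structures with gate state, ligands, tautomer and cations
#'
#' The per-chain report behind the `annotate-structure` command.
#'
#' @param paths coordinate file paths.
#' @param ref a [reference_annotation()] to map landmarks from (default:
#'   the toy-site annotation when every model matches it, otherwise pass
#'   the appropriate family reference).
#' @param config a `run_config`.
#' @return data.frame, one row per chain: structure id, chain, ligand
#'   summary, gate state with supporting distances, rotamer, tautomer
#'   call, cation count.
#' @export
annotate_structures <- function(paths, ref,
                                config = default_run_config()) {
  rows <- list()
  for (p in paths) {
    model <- read_structure(p)
    rmap <- map_reference_residues(model, ref,
                                   min_identity = config$min_chain_identity)
    gates <- classify_gate_state(
      model, rmap, in_threshold = config$gate_in_threshold,
      out_threshold = config$gate_out_threshold,
      hbond_cutoff = config$hbond_cutoff)
    inv <- ligand_inventory(model)
    lig <- inv[inv$class %in% c("nucleoside", "thioether"), ,
               drop = FALSE]
    taut <- NA_character_
    if (nrow(lig)) {
      hb <- enumerate_hbonds(model, lig$resid[1],
                             cutoff = config$hbond_cutoff)
      taut <- infer_tautomer(hb, lig$resid[1],
                             cutoff = config$hbond_cutoff)$call
    }
    hinge <- ref$domain_ranges$hinge
    cat_rep <- detect_cation(
      model,
      hinge_resno = if (!is.null(hinge)) seq.int(hinge[1], hinge[2]),
      cutoff = config$cation_cutoff)
    for (i in seq_len(nrow(gates))) {
      g <- gates[i, ]
      rows[[length(rows) + 1L]] <- data.frame(
        structure_id = model$structure_id, chain = g$chain,
        ligands = paste(unique(inv$resid), collapse = ","),
        gate_state = g$state, d_gate = g$d_gate,
        d_gate_centroid = g$d_gate_centroid,
        d_out_partner = g$d_out_partner,
        d_his_o5prime = g$d_his_o5prime,
        chi1 = g$chi1, chi2 = g$chi2, rotamer = g$rotamer,
        tautomer = taut, n_cations = nrow(cat_rep),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Merge sequence, structure and assay reports into a study-style summary
#'
#' One row per enzyme: motif class and predicted preference from the
#' sequence report, observed gate states from the structure report,
#' assay preference call, pathway call and concordance flag. Reports may
#' be partial; missing columns stay NA.
#'
#' @param seq_report [annotate_sequences()] output (id column matched to
#'   enzyme ids).
#' @param struct_report [annotate_structures()] output or `NULL`;
#'   structure ids are matched to enzyme ids.
#' @param assay_calls data.frame with `enzyme_id`, `assay_label` (and
#'   optionally `sih_activity`) or `NULL`.
#' @param pathway data.frame with `enzyme_id`, `dadd_present`,
#'   `mtan_present` or `NULL`.
#' @return merged data.frame, one row per enzyme id.
#' @export
combined_report <- function(seq_report, struct_report = NULL,
                            assay_calls = NULL, pathway = NULL) {
  if (is.null(seq_report) || nrow(seq_report) == 0L)
    stop("at least a sequence report is required")
  if (anyDuplicated(seq_report$id))
    stop("duplicate enzyme ids in sequence report: ",
         paste(unique(seq_report$id[duplicated(seq_report$id)]),
               collapse = ", "))
  out <- seq_report
  names(out)[names(out) == "id"] <- "enzyme_id"
  if (!is.null(struct_report) && nrow(struct_report)) {
    agg <- stats::aggregate(gate_state ~ structure_id,
                            data = struct_report,
                            FUN = function(x) paste(unique(x),
                                                    collapse = "/"))
    names(agg) <- c("enzyme_id", "gate_states")
    out <- merge(out, agg, by = "enzyme_id", all.x = TRUE)
  } else out$gate_states <- NA_character_
  if (!is.null(assay_calls) && nrow(assay_calls)) {
    out <- merge(out, assay_calls, by = "enzyme_id", all.x = TRUE)
    conc <- concordance_report(
      data.frame(enzyme_id = out$enzyme_id, predicted = out$predicted),
      assay_calls)
    out <- merge(out, conc$table[, c("enzyme_id", "concordant", "note")],
                 by = "enzyme_id", all.x = TRUE)
  } else {
    out$assay_label <- NA_character_
    out$concordant <- NA
  }
  if (!is.null(pathway) && nrow(pathway)) {
    pw <- vapply(seq_len(nrow(pathway)), function(i) {
      lab <- out$predicted[match(pathway$enzyme_id[i], out$enzyme_id)]
      if (is.na(lab)) lab <- "unknown"
      paste(infer_pathway(lab, pathway$dadd_present[i],
                          pathway$mtan_present[i])$routes,
            collapse = "+")
    }, character(1))
    out <- merge(out,
                 data.frame(enzyme_id = pathway$enzyme_id, routes = pw),
                 by = "enzyme_id", all.x = TRUE)
  }
  out[order(out$enzyme_id), , drop = FALSE]
}

#' Write a report as TSV and/or JSON
#'
#' @param report data.frame.
#' @param tsv,json output paths (`NULL` to skip either).
#' @return invisibly, the report.
#' @export
write_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(report, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(report, json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}
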