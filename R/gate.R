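HIS_RING_ATOMS <- c("CG", "ND1", "CD2", "CE1", "NE2")
ASP_CARBOXYLATE <- c("OD1", "OD2")
GLU_CARBOXYLATE <- c("OE1", "OE2")
LANDMARK_EXPECTED_AA <- c(gate_his = "H", gate_phe = "F",
                          catalytic_asp = "D", out_partner_glu = "E")

#' Map reference landmark residues onto a structure
#'
#' Each protein chain's one-letter sequence is aligned to the reference
#' sequence; landmark positions (gate His/Phe, catalytic Asp, His-OUT Glu
#' partner, C6-contact residue, motif residues) are transferred through
#' the alignment to author residue numbers. Mapping goes via sequence, not
#' author numbering, so renumbered depositions are tolerated. A mapped
#' residue whose amino acid does not match the landmark's expectation
#' triggers a warning, not an error.
#'
#' @param model a `structure_model`.
#' @param ref a [reference_annotation()].
#' @param min_identity minimum alignment identity (fraction) for a chain
#'   to be mapped.
#' @return a `residue_map`: named list per chain; each entry is a named
#'   integer vector of author residue numbers (NA where unresolved) for
#'   `gate_his`, `gate_phe`, `catalytic_asp`, `out_partner_glu`,
#'   `c6_partner`, `motif_1` .. `motif_5`.
#' @export
map_reference_residues <- function(model, ref, min_identity = 0.3) {
  stopifnot(inherits(model, "structure_model"),
            inherits(ref, "reference_annotation"))
  chains <- protein_chains(model)
  out <- list()
  for (ch in chains) {
    cs <- chain_sequence(model, ch)
    aln <- global_align(cs$sequence, ref$ref_sequence)
    qc <- strsplit(cs$sequence, "")[[1]]
    rc <- strsplit(ref$ref_sequence$residues, "")[[1]]
    ident <- mean(qc[aln$mapping$query_pos] == rc[aln$mapping$ref_pos])
    if (!is.finite(ident) || ident < min_identity) next
    landmarks <- c(gate_his = ref$gate_his, gate_phe = ref$gate_phe,
                   catalytic_asp = ref$catalytic_asp,
                   out_partner_glu = ref$out_partner_glu,
                   c6_partner = ref$c6_partner)
    if (!is.na(ref$motif_start)) {
      mot <- ref$motif_start + 0:4
      names(mot) <- paste0("motif_", 1:5)
      landmarks <- c(landmarks, mot)
    }
    mapped <- rep(NA_integer_, length(landmarks))
    names(mapped) <- names(landmarks)
    for (nm in names(landmarks)) {
      rp <- landmarks[[nm]]
      if (is.na(rp)) next
      qp <- ref_to_query(aln, rp)
      if (is.na(qp)) next
      mapped[[nm]] <- cs$resno[qp]
      expect <- LANDMARK_EXPECTED_AA[nm]
      if (!is.na(expect) && qc[qp] != expect)
        warning("chain ", ch, ": landmark ", nm, " maps to residue ",
                qc[qp], cs$resno[qp], ", expected ", expect,
                call. = FALSE)
    }
    out[[ch]] <- mapped
  }
  if (length(out) == 0L)
    stop("no chain of ", model$structure_id, " aligns to reference ",
         ref$ref_id, " above the identity floor")
  class(out) <- "residue_map"
  out
}

coarse_chi_bin <- function(chi) {
  if (is.na(chi)) return(NA_character_)
  bins <- c(m = -60, p = 60, t = 180)
  # circular distance
  d <- pmin(abs(chi - bins), 360 - abs(chi - bins))
  names(bins)[which.min(d)]
}

#' Classify the molecular-gate state of each chain
#'
#' The gate His can sit inside the active site (His-IN, gate shut), its
#' imidazole ring facing the catalytic Asp carboxylate, or swing away
#' (His-OUT, gate open) and hydrogen-bond the carboxylate of a nearby Glu.
#' `d_gate` is the minimum heavy-atom distance between the His imidazole
#' ring (CG, ND1, CD2, CE1, NE2) and the Asp carboxylate oxygens; the
#' ring-centroid to carboxylate-centroid distance is reported alongside
#' for diagnostics. The call is IN when `d_gate <= in_threshold`, OUT when
#' `d_gate >= out_threshold` and the Glu contact is within the
#' hydrogen-bond cutoff, otherwise undetermined. Side-chain dihedrals
#' chi1 (N-CA-CB-CG) and chi2 (CA-CB-CG-ND1) and a coarse rotamer label
#' (chi bins m/p/t at -60/+60/180 degrees) support rotamer comparisons.
#'
#' @param model a `structure_model`.
#' @param residue_map a [map_reference_residues()] result.
#' @param in_threshold,out_threshold gate-distance thresholds (Angstrom);
#'   defaults 6.0 and 8.0 bracket the His-IN and His-OUT exemplars.
#' @param hbond_cutoff donor-acceptor heavy-atom cutoff for the Glu
#'   contact (Angstrom).
#' @return data.frame of class `gate_state_table`, one row per mapped
#'   chain: `chain`, `state`, `d_gate`, `d_gate_centroid`,
#'   `d_out_partner`, `d_his_o5prime`, `chi1`, `chi2`, `rotamer`,
#'   `reason`.
#' @export
classify_gate_state <- function(model, residue_map, in_threshold = 6.0,
                                out_threshold = 8.0, hbond_cutoff = 3.5) {
  stopifnot(inherits(residue_map, "residue_map"),
            in_threshold > 0, out_threshold >= in_threshold)
  rows <- list()
  for (ch in names(residue_map)) {
    rm <- residue_map[[ch]]
    row <- list(chain = ch, state = "undetermined", d_gate = NA_real_,
                d_gate_centroid = NA_real_, d_out_partner = NA_real_,
                d_his_o5prime = NA_real_, chi1 = NA_real_,
                chi2 = NA_real_, rotamer = NA_character_, reason = "")
    his <- if (!is.na(rm[["gate_his"]]))
      residue_coords(model, ch, rm[["gate_his"]], "ATOM") else NULL
    asp <- if (!is.na(rm[["catalytic_asp"]]))
      residue_coords(model, ch, rm[["catalytic_asp"]], "ATOM") else NULL
    ring <- if (!is.null(his))
      his[intersect(HIS_RING_ATOMS, rownames(his)), , drop = FALSE]
    carb <- if (!is.null(asp))
      asp[intersect(ASP_CARBOXYLATE, rownames(asp)), , drop = FALSE]
    if (is.null(ring) || nrow(ring) == 0L || is.null(carb) ||
        nrow(carb) == 0L) {
      row$reason <- "gate His or catalytic Asp side-chain atoms missing"
      rows[[ch]] <- row
      next
    }
    row$d_gate <- min(dist_matrix(ring, carb))
    row$d_gate_centroid <- point_dist(colMeans(ring), colMeans(carb))
    if (!is.na(rm[["out_partner_glu"]])) {
      glu <- residue_coords(model, ch, rm[["out_partner_glu"]], "ATOM")
      oe <- glu[intersect(GLU_CARBOXYLATE, rownames(glu)), ,
                drop = FALSE]
      if (nrow(oe)) row$d_out_partner <- min(dist_matrix(ring, oe))
    }
    if (all(c("N", "CA", "CB", "CG") %in% rownames(his))) {
      row$chi1 <- dihedral_angle(his["N", ], his["CA", ], his["CB", ],
                                 his["CG", ])
      if ("ND1" %in% rownames(his))
        row$chi2 <- dihedral_angle(his["CA", ], his["CB", ], his["CG", ],
                                   his["ND1", ])
    }
    row$rotamer <- paste0(coarse_chi_bin(row$chi1),
                          coarse_chi_bin(row$chi2))
    lig <- ligand_inventory(model)
    lig <- lig[lig$class %in% c("nucleoside", "thioether"), , drop = FALSE]
    if (nrow(lig) && "ND1" %in% rownames(his)) {
      d <- Inf
      for (k in seq_len(nrow(lig))) {
        lc <- residue_coords(model, lig$chain[k], lig$resno[k], "HETATM")
        if ("O5'" %in% rownames(lc))
          d <- min(d, point_dist(his["ND1", ], lc["O5'", ]))
      }
      if (is.finite(d)) row$d_his_o5prime <- d
    }
    if (row$d_gate <= in_threshold) {
      row$state <- "IN"
    } else if (row$d_gate >= out_threshold &&
               !is.na(row$d_out_partner) &&
               row$d_out_partner <= hbond_cutoff) {
      row$state <- "OUT"
    } else {
      row$reason <- sprintf(
        "d_gate %.2f A between thresholds or no His-OUT partner contact",
        row$d_gate)
    }
    rows[[ch]] <- row
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  class(out) <- c("gate_state_table", class(out))
  out
}
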