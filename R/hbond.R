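POLAR_ELEMENTS <- c("N", "O", "S")
MAINCHAIN_POLAR <- c("N", "O", "OXT")

#' Enumerate ligand-protein hydrogen bonds
#'
#' All N/O/S heavy-atom pairs between a ligand and protein atoms within a
#' distance cutoff, deduplicated and sorted by distance. Because
#' hydrogens are absent at typical crystallographic resolutions, the
#' criterion is a pure donor-acceptor heavy-atom distance with no angle
#' term. Waters are excluded from the partner set by default. Atom names
#' are normalised across prime dialects (O5' / O5*).
#'
#' @param model a `structure_model`.
#' @param ligand ligand selection: a het residue name (e.g. `"INO"`) or a
#'   list with `chain` and `resno`.
#' @param cutoff donor-acceptor heavy-atom distance cutoff (Angstrom).
#' @param pocket_radius protein atoms farther than this from every ligand
#'   atom are skipped before pairing (performance only; does not change
#'   the result for `pocket_radius >= cutoff`).
#' @param include_water include water oxygens as partners.
#' @return data.frame of class `hbond_table`: `ligand_atom`, `chain`,
#'   `resno`, `resid`, `atom`, `mainchain` (logical), `distance`.
#' @export
enumerate_hbonds <- function(model, ligand, cutoff = 3.5,
                             pocket_radius = max(8, cutoff),
                             include_water = FALSE) {
  stopifnot(cutoff >= 0)
  lig <- select_ligand_atoms(model, ligand)
  if (nrow(lig) == 0L) stop("ligand not found in model")
  lig <- lig[lig$element %in% POLAR_ELEMENTS, , drop = FALSE]
  prot <- model$atoms[model$atoms$record == "ATOM" &
                        model$atoms$element %in% POLAR_ELEMENTS, ,
                      drop = FALSE]
  if (include_water) {
    wat <- model$atoms[model$atoms$resid %in% WATER_CODES &
                         model$atoms$element %in% POLAR_ELEMENTS, ,
                       drop = FALSE]
    prot <- rbind(prot, wat)
  }
  empty <- data.frame(ligand_atom = character(0), chain = character(0),
                      resno = integer(0), resid = character(0),
                      atom = character(0), mainchain = logical(0),
                      distance = numeric(0))
  class(empty) <- c("hbond_table", class(empty))
  if (nrow(lig) == 0L || nrow(prot) == 0L || cutoff == 0) return(empty)
  L <- as.matrix(lig[, c("x", "y", "z")])
  P <- as.matrix(prot[, c("x", "y", "z")])
  D <- dist_matrix(L, P)
  near <- apply(D, 2, min) <= pocket_radius
  prot <- prot[near, , drop = FALSE]
  D <- D[, near, drop = FALSE]
  hits <- which(D <= cutoff, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(empty)
  out <- data.frame(
    ligand_atom = normalise_atom_name(lig$atom[hits[, 1]]),
    chain = prot$chain[hits[, 2]],
    resno = prot$resno[hits[, 2]],
    resid = prot$resid[hits[, 2]],
    atom = normalise_atom_name(prot$atom[hits[, 2]]),
    mainchain = prot$atom[hits[, 2]] %in% MAINCHAIN_POLAR &
      prot$record[hits[, 2]] == "ATOM",
    distance = D[hits],
    stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(out$ligand_atom, out$chain, out$resno,
                               out$atom)), , drop = FALSE]
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hbond_table", class(out))
  out
}

select_ligand_atoms <- function(model, ligand) {
  a <- model$atoms[model$atoms$record == "HETATM", , drop = FALSE]
  if (is.character(ligand) && length(ligand) == 1L) {
    a[a$resid == ligand, , drop = FALSE]
  } else if (is.list(ligand)) {
    a[a$chain == ligand$chain & a$resno == ligand$resno, , drop = FALSE]
  } else {
    stop("ligand must be a het residue name or list(chain=, resno=)")
  }
}

#' Infer the nucleobase tautomer from the hydrogen-bond pattern
#'
#' Hypoxanthine-containing ligands (inosine, SIH): when the C6 oxygen
#' (O6) donates to at least one main-chain carbonyl oxygen within the
#' cutoff, the ring is called imino-hydroxy (O6 protonated, O...O
#' contact); otherwise the default amino-oxo form, the dominant form in
#' water. Adenine-containing ligands (adenosine, SAH) are in the amino
#' form; an exo-amino N6 contact with main-chain carbonyls is recorded as
#' supporting evidence.
#'
#' @param hbonds an [enumerate_hbonds()] result for the ligand.
#' @param ligand_name het code: `INO`, `SIH`, `ADN` or `SAH`.
#' @param cutoff evidence distance cutoff (Angstrom).
#' @return a `tautomer_call`: list with `ligand`, `call` (`amino_oxo`,
#'   `imino_hydroxy`, `amino` or `undetermined`) and `evidence` (the
#'   contributing hydrogen-bond rows).
#' @export
infer_tautomer <- function(hbonds, ligand_name, cutoff = 3.5) {
  stopifnot(inherits(hbonds, "hbond_table"))
  hypo <- ligand_name %in% c("INO", "SIH")
  aden <- ligand_name %in% c("ADN", "SAH")
  if (!hypo && !aden) {
    return(structure(list(ligand = ligand_name, call = "undetermined",
                          evidence = hbonds[0, ]),
                     class = "tautomer_call"))
  }
  probe <- if (hypo) "O6" else "N6"
  ev <- hbonds[hbonds$ligand_atom == probe & hbonds$mainchain &
                 hbonds$atom == "O" & hbonds$distance <= cutoff, ,
               drop = FALSE]
  call <- if (hypo) {
    if (nrow(ev) >= 1L) "imino_hydroxy" else "amino_oxo"
  } else {
    "amino"
  }
  structure(list(ligand = ligand_name, call = call, evidence = ev),
            class = "tautomer_call")
}

#' @export
print.tautomer_call <- function(x, ...) {
  cat("<tautomer_call> ", x$ligand, ": ", x$call,
      " (", nrow(x$evidence), " supporting contacts)\n", sep = "")
  invisible(x)
}

#' Detect monovalent cations near the hinge element
#'
#' Reports Na+/K+ (and other monoatomic) het atoms within a cutoff of the
#' hinge-element residues, with their coordinating protein N/O atoms. An
#' empty report is the absence call. When no hinge residues are given the
#' scan falls back to the neighbourhood of any nucleoside/thioether
#' ligand (the nucleobase pocket).
#'
#' @param model a `structure_model`.
#' @param hinge_resno integer vector of hinge residue numbers (author
#'   numbering), or `NULL` for the pocket fallback.
#' @param chain protein chain to measure against (default: all chains).
#' @param cutoff detection radius (Angstrom).
#' @param elements ion element symbols of interest.
#' @return data.frame: `element`, `chain`, `resno`, `min_distance`,
#'   `n_coordinating`, `coordinating_atoms`.
#' @export
detect_cation <- function(model, hinge_resno = NULL, chain = NULL,
                          cutoff = 6.0,
                          elements = c("NA", "K")) {
  ions <- model$atoms[model$atoms$record == "HETATM" &
                        model$atoms$resid %in% elements, , drop = FALSE]
  empty <- data.frame(element = character(0), chain = character(0),
                      resno = integer(0), min_distance = numeric(0),
                      n_coordinating = integer(0),
                      coordinating_atoms = character(0))
  if (nrow(ions) == 0L) return(empty)
  prot <- model$atoms[model$atoms$record == "ATOM", , drop = FALSE]
  if (!is.null(chain)) prot <- prot[prot$chain %in% chain, , drop = FALSE]
  if (!is.null(hinge_resno)) {
    sel <- prot[prot$resno %in% hinge_resno, , drop = FALSE]
  } else {
    lig <- ligand_inventory(model)
    lig <- lig[lig$class %in% c("nucleoside", "thioether"), ,
               drop = FALSE]
    if (nrow(lig) == 0L) {
      sel <- prot
    } else {
      la <- do.call(rbind, lapply(seq_len(nrow(lig)), function(k)
        residue_atoms(model, lig$chain[k], lig$resno[k], "HETATM")))
      D <- dist_matrix(as.matrix(prot[, c("x", "y", "z")]),
                       as.matrix(la[, c("x", "y", "z")]))
      sel <- prot[apply(D, 1, min) <= 10, , drop = FALSE]
    }
  }
  if (nrow(sel) == 0L) return(empty)
  out <- empty
  S <- as.matrix(sel[, c("x", "y", "z")])
  for (k in seq_len(nrow(ions))) {
    p <- as.numeric(ions[k, c("x", "y", "z")])
    d <- sqrt(colSums((t(S) - p)^2))
    if (min(d) > cutoff) next
    coord <- sel$element %in% c("N", "O") & d <= 3.5
    out <- rbind(out, data.frame(
      element = ions$resid[k], chain = ions$chain[k],
      resno = ions$resno[k], min_distance = min(d),
      n_coordinating = sum(coord),
      coordinating_atoms = if (!any(coord)) "" else paste(
        paste0(sel$resid[coord], sel$resno[coord], ":", sel$atom[coord]),
        collapse = ","),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
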