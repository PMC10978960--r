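#' Interdomain rotation angle between two conformations
#'
#' Quantifies the open/closed rigid-body reorientation of the
#' substrate-binding domain relative to the cofactor-binding domain.
#' Model B is first superposed onto model A over the cofactor-binding
#' domain Calpha atoms; the residual Kabsch rotation mapping A's
#' substrate-binding domain onto the transformed B domain is then reduced
#' to an axis-angle magnitude. Ligand-free SAHH structures show an open
#' state roughly 18 degrees away from the substrate-bound closed state.
#'
#' @param modelA,modelB `structure_model`s of the same protein (A is the
#'   reference conformation).
#' @param domain_ranges named list with `substrate_binding` and
#'   `cofactor_binding` residue intervals `c(start, end)` (author
#'   numbering shared by both models), e.g. from a
#'   [reference_annotation()].
#' @param chainA,chainB chains to compare.
#' @param reference_state conformation of `modelA` (`"closed"` or
#'   `"open"`).
#' @param open_angle expected open/closed separation in degrees.
#' @param tolerance state-call tolerance in degrees.
#' @return a `conformation_call`: list with `angle` (degrees, [0, 180]),
#'   `axis`, `call` for model B (`open`, `closed` or `undetermined`) and
#'   `n_ca` per domain.
#' @export
domain_rotation_angle <- function(modelA, modelB, domain_ranges,
                                  chainA = NULL, chainB = NULL,
                                  reference_state = c("closed", "open"),
                                  open_angle = 18, tolerance = 6) {
  reference_state <- match.arg(reference_state)
  need <- c("substrate_binding", "cofactor_binding")
  if (!all(need %in% names(domain_ranges)))
    stop("domain_ranges must name substrate_binding and cofactor_binding")
  if (is.null(chainA)) chainA <- protein_chains(modelA)[1]
  if (is.null(chainB)) chainB <- protein_chains(modelB)[1]
  dom_ca <- function(model, chain, rng) {
    ca <- calpha_coords(model, chain)
    sel <- as.integer(rownames(ca)) >= rng[1] &
      as.integer(rownames(ca)) <= rng[2]
    ca[sel, , drop = FALSE]
  }
  match_common <- function(A, B) {
    common <- intersect(rownames(A), rownames(B))
    if (length(common) < 3)
      stop("fewer than 3 shared Calpha atoms in a domain; ",
           "domain ranges unresolvable")
    list(A = A[common, , drop = FALSE], B = B[common, , drop = FALSE])
  }
  cof <- match_common(dom_ca(modelA, chainA,
                             domain_ranges$cofactor_binding),
                      dom_ca(modelB, chainB,
                             domain_ranges$cofactor_binding))
  sub <- match_common(dom_ca(modelA, chainA,
                             domain_ranges$substrate_binding),
                      dom_ca(modelB, chainB,
                             domain_ranges$substrate_binding))
  sp_cof <- superpose_kabsch(cof$B, cof$A)   # B -> A frame
  subB <- apply_superposition(sp_cof, sub$B)
  sp_sub <- superpose_kabsch(sub$A, subB)
  angle <- rotation_angle_deg(sp_sub$rotation)
  ev <- eigen(sp_sub$rotation)
  axis <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  other_state <- if (reference_state == "closed") "open" else "closed"
  call <- if (angle <= tolerance) reference_state
  else if (abs(angle - open_angle) <= tolerance) other_state
  else "undetermined"
  structure(list(angle = angle, axis = axis / vnorm(axis), call = call,
                 n_ca = c(cofactor = nrow(cof$A),
                          substrate = nrow(sub$A))),
            class = "conformation_call")
}

#' @export
print.conformation_call <- function(x, ...) {
  cat(sprintf("<conformation_call> %.2f deg -> %s\n", x$angle, x$call))
  invisible(x)
}

#' Peptide-plane flip angle at the molecular gate
#'
#' The gate opens and shuts via an approximately 180-degree flip of the
#' peptide plane between the Calpha atoms of the gate His and Phe. The
#' local backbone (Calpha of His-2 .. Phe+2) of model B is superposed
#' onto model A; the angle between the His-Phe peptide-plane normals
#' (plane through Calpha(His), C(His), O(His), N(Phe)) is returned, with
#' a flip called at `flip_threshold` and above.
#'
#' @param modelA,modelB `structure_model`s.
#' @param residue_map a [map_reference_residues()] result valid for both
#'   models (shared numbering), or a named vector with `gate_his`,
#'   `gate_phe`.
#' @param chainA,chainB chains to compare.
#' @param flip_threshold degrees; a true flip is ~180, small librations
#'   stay far below.
#' @return list with `angle` (degrees), `flip` (logical).
#' @export
peptide_flip_angle <- function(modelA, modelB, residue_map,
                               chainA = NULL, chainB = NULL,
                               flip_threshold = 120) {
  if (is.null(chainA)) chainA <- protein_chains(modelA)[1]
  if (is.null(chainB)) chainB <- protein_chains(modelB)[1]
  rm <- if (inherits(residue_map, "residue_map"))
    residue_map[[chainA]] else residue_map
  his <- rm[["gate_his"]]; phe <- rm[["gate_phe"]]
  if (is.na(his) || is.na(phe)) stop("gate residues not mapped")
  local_ca <- function(model, chain) {
    ca <- calpha_coords(model, chain)
    sel <- as.integer(rownames(ca)) >= his - 2 &
      as.integer(rownames(ca)) <= phe + 2
    ca[sel, , drop = FALSE]
  }
  A <- local_ca(modelA, chainA); B <- local_ca(modelB, chainB)
  common <- intersect(rownames(A), rownames(B))
  if (length(common) < 3) stop("missing backbone atoms around the gate")
  sp <- superpose_kabsch(B[common, , drop = FALSE],
                         A[common, , drop = FALSE])
  normal_of <- function(model, chain, transform = NULL) {
    hc <- residue_coords(model, chain, his, "ATOM")
    pc <- residue_coords(model, chain, phe, "ATOM")
    need <- c("CA", "C", "O")
    if (!all(need %in% rownames(hc)) || !("N" %in% rownames(pc)))
      stop("missing backbone atoms for the His-Phe peptide plane")
    pts <- rbind(hc["CA", ], hc["C", ], hc["O", ], pc["N", ])
    if (!is.null(transform)) pts <- apply_superposition(transform, pts)
    ctr <- colMeans(pts)
    s <- svd(sweep(pts, 2, ctr))
    n <- s$v[, 3]
    # orient consistently from the atom order
    refn <- vcross(pts[2, ] - pts[1, ], pts[4, ] - pts[1, ])
    if (sum(n * refn) < 0) n <- -n
    n
  }
  nA <- normal_of(modelA, chainA)
  nB <- normal_of(modelB, chainB, transform = sp)
  angle <- vec_angle(nA, nB)
  list(angle = angle, flip = angle >= flip_threshold)
}
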