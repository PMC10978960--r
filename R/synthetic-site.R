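# Toy active-site generator. Residues are built from idealised internal
# coordinates (standard bond lengths/angles via NeRF placement); realism
# is limited to what the geometric classifiers consume. Controlled
# quantities (gate distance, H-bond distances, cation distance) are exact
# by construction and re-verified numerically before the file is written.

BACKBONE_GEOM <- list(n_c = 1.33, ca_n = 1.46, c_ca = 1.52, o_c = 1.23)

# Append one residue to a growing backbone. `prev` holds N, CA, C of the
# previous residue (NULL to seed a new fragment at `origin`).
build_residue <- function(resname, prev = NULL, origin = c(0, 0, 0),
                          phi = -120, psi = 130,
                          chi = c(-60, -60, 180)) {
  if (is.null(prev)) {
    N <- origin
    CA <- origin + c(1.46, 0, 0)
    C <- CA + 1.52 * c(cos(70 * pi / 180), sin(70 * pi / 180), 0)
  } else {
    N <- place_atom(prev["N", ], prev["CA", ], prev["C", ],
                    BACKBONE_GEOM$n_c, 114, psi)
    CA <- place_atom(prev["CA", ], prev["C", ], N,
                     BACKBONE_GEOM$ca_n, 123, 180)
    C <- place_atom(prev["C", ], N, CA, BACKBONE_GEOM$c_ca, 110, phi)
  }
  O <- place_atom(N, CA, C, BACKBONE_GEOM$o_c, 121, psi + 180)
  atoms <- rbind(N = N, CA = CA, C = C, O = O)
  side <- switch(resname,
    GLY = NULL,
    ALA = rbind(CB = place_atom(C, N, CA, 1.53, 110.5, 122.5)),
    HIS = {
      CB <- place_atom(C, N, CA, 1.53, 110.5, 122.5)
      CG <- place_atom(N, CA, CB, 1.50, 114, chi[1])
      ND1 <- place_atom(CA, CB, CG, 1.38, 122, chi[2])
      CD2 <- place_atom(CA, CB, CG, 1.36, 131, chi[2] + 180)
      CE1 <- place_atom(CB, CG, ND1, 1.32, 109, 180)
      NE2 <- place_atom(CG, ND1, CE1, 1.32, 108, 0)
      rbind(CB = CB, CG = CG, ND1 = ND1, CD2 = CD2, CE1 = CE1, NE2 = NE2)
    },
    PHE = {
      CB <- place_atom(C, N, CA, 1.53, 110.5, 122.5)
      CG <- place_atom(N, CA, CB, 1.51, 114, chi[1])
      CD1 <- place_atom(CA, CB, CG, 1.39, 120, chi[2])
      CD2 <- place_atom(CA, CB, CG, 1.39, 120, chi[2] + 180)
      CE1 <- place_atom(CB, CG, CD1, 1.39, 120, 180)
      CE2 <- place_atom(CB, CG, CD2, 1.39, 120, 180)
      CZ <- place_atom(CG, CD1, CE1, 1.39, 120, 0)
      rbind(CB = CB, CG = CG, CD1 = CD1, CD2 = CD2, CE1 = CE1,
            CE2 = CE2, CZ = CZ)
    },
    ASP = {
      CB <- place_atom(C, N, CA, 1.53, 110.5, 122.5)
      CG <- place_atom(N, CA, CB, 1.52, 113, chi[1])
      OD1 <- place_atom(CA, CB, CG, 1.25, 119, chi[2])
      OD2 <- place_atom(CA, CB, CG, 1.25, 119, chi[2] + 180)
      rbind(CB = CB, CG = CG, OD1 = OD1, OD2 = OD2)
    },
    GLU = {
      CB <- place_atom(C, N, CA, 1.53, 110.5, 122.5)
      CG <- place_atom(N, CA, CB, 1.52, 114, chi[1])
      CD <- place_atom(CA, CB, CG, 1.52, 114, chi[2])
      OE1 <- place_atom(CB, CG, CD, 1.25, 119, chi[3])
      OE2 <- place_atom(CB, CG, CD, 1.25, 119, chi[3] + 180)
      rbind(CB = CB, CG = CG, CD = CD, OE1 = OE1, OE2 = OE2)
    },
    stop("no template for residue ", resname))
  rbind(atoms, side)
}

# Rotation matrix that maps unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  a <- vunit(a); b <- vunit(b)
  ax <- vcross(a, b)
  if (vnorm(ax) < 1e-10) {
    if (sum(a * b) > 0) return(diag(3))
    # opposite: rotate 180 about any perpendicular axis
    perp <- vcross(a, c(1, 0, 0))
    if (vnorm(perp) < 1e-6) perp <- vcross(a, c(0, 1, 0))
    return(rotation_about_axis(perp, 180))
  }
  rotation_about_axis(ax, vec_angle(a, b))
}

# Rigidly place a residue template so that the atom `anchor` lands on
# `target` and the template centroid points along `direction` from it.
place_residue_towards <- function(template, anchor, target, direction) {
  ctr <- colMeans(template)
  ax <- template[anchor, ]
  R <- rotation_between(ctr - ax, direction)
  moved <- t(R %*% t(sweep(template, 2, ax)))
  sweep(moved, 2, target, FUN = "+")
}

toy_atom_row <- function(coords, resname, resno, chain,
                         record = "ATOM") {
  data.frame(record = record, atom = rownames(coords),
             resid = resname, chain = chain, resno = resno,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             stringsAsFactors = FALSE)
}

#' Reference annotation for the toy active site
#'
#' The toy site is a seven-residue chain `GHFGGDE`: a Gly cap, the gate
#' His/Phe pair, two Gly (residue 4 doubles as the hinge marker and the
#' main-chain carbonyl contact used in tautomer tests), the catalytic
#' Asp, and the His-OUT Glu partner.
#' @return a [reference_annotation()].
#' @export
toy_site_annotation <- function() {
  reference_annotation(
    ref_id = "toy_site", ref_sequence = "GHFGGDE",
    gate_his = 2, gate_phe = 3, catalytic_asp = 6, out_partner_glu = 7,
    c6_partner = 4, domain_ranges = list(hinge = c(4, 5)))
}

# Assemble the toy-site atom table in memory; used by make_toy_site and
# the flip-pair generator.
toy_site_atoms <- function(d_gate = 4.2, out_partner = FALSE,
                           d_out = 2.7,
                           ligand = c("none", "inosine", "adenosine"),
                           d_o5prime = 2.7, nucleobase_contact = FALSE,
                           cation = NULL, d_cation = 5.0,
                           n_padding = 0, slim = FALSE) {
  ligand <- match.arg(ligand)
  stopifnot(d_gate > 0)
  # slim sites swap the aromatic gate partner for Gly to stay within a
  # 50-atom budget (used by the brute-force hydrogen-bond checks)
  seq3 <- c("GLY", "HIS", if (slim) "GLY" else "PHE", "GLY", "GLY")
  chis <- list(NULL, c(-60, -60, 180), c(-60, 90, 180), NULL, NULL)
  res <- list()
  prev <- NULL
  for (i in seq_along(seq3)) {
    r <- build_residue(seq3[i], prev, chi = chis[[i]] %||% c(-60, -60, 180))
    res[[i]] <- r
    prev <- r
  }
  his <- res[[2]]
  ring <- his[HIS_RING_ATOMS, ]
  u <- vunit(colMeans(ring) - his["CA", ])        # outward, in-plane
  v <- vunit(vcross(his["ND1", ] - his["CG", ],
                    his["CD2", ] - his["CG", ])) # ring normal
  w <- -v
  tvec <- vunit(vcross(v, u))

  asp <- build_residue("ASP")
  asp <- place_residue_towards(asp, "OD1",
                               his["NE2", ] + d_gate * u, u)
  glu <- build_residue("GLU")
  glu_d <- if (out_partner) d_out else 20
  glu <- place_residue_towards(glu, "OE1",
                               his["NE2", ] + glu_d * v, v)

  atoms <- rbind(
    do.call(rbind, lapply(seq_along(seq3), function(i)
      toy_atom_row(res[[i]], seq3[i], i, "A"))),
    toy_atom_row(asp, "ASP", 6, "A"),
    toy_atom_row(glu, "GLU", 7, "A"))

  if (n_padding > 0) {
    # detached Gly grid well away from the active site (chain filler so
    # superposition statistics have enough Calpha atoms)
    for (k in seq_len(n_padding)) {
      g <- build_residue("GLY")
      off <- c(-25 - 6 * ((k - 1) %% 10), 8 * ((k - 1) %/% 10), -15)
      g <- sweep(g, 2, off, FUN = "+")
      atoms <- rbind(atoms, toy_atom_row(g, "GLY", 7 + k, "A"))
    }
  }

  truth <- list(d_gate = d_gate, out_partner = out_partner,
                d_out = if (out_partner) d_out else NA,
                ligand = ligand, cation = cation)

  if (ligand != "none") {
    resname <- if (ligand == "inosine") "INO" else "ADN"
    o5 <- his["ND1", ] + d_o5prime * w
    c1 <- o5 + 1.5 * w
    n1 <- c1 + 1.4 * w + 1.2 * tvec
    c6 <- n1 + 1.35 * tvec
    exo_name <- if (ligand == "inosine") "O6" else "N6"
    gly4 <- res[[4]]
    if (nucleobase_contact) {
      exo <- gly4["O", ] + 2.8 * vunit(gly4["O", ] - gly4["C", ])
    } else {
      exo <- c6 + 1.25 * tvec + 1.0 * w
    }
    lig <- rbind("O5'" = o5, "C1'" = c1, N1 = n1, C6 = c6)
    lig <- rbind(lig, exo)
    rownames(lig)[nrow(lig)] <- exo_name
    atoms <- rbind(atoms, toy_atom_row(lig, resname, 101, "A", "HETATM"))
    truth$d_o5prime <- d_o5prime
    truth$nucleobase_contact <- nucleobase_contact
  }
  if (!is.null(cation)) {
    stopifnot(cation %in% c("NA", "K"))
    hinge_ca <- res[[4]]["CA", ]
    pos <- hinge_ca + d_cation * vunit(c(0.3, -0.8, 0.6))
    ion <- matrix(pos, 1, 3, dimnames = list(cation, NULL))
    atoms <- rbind(atoms, toy_atom_row(ion, cation, 201, "A", "HETATM"))
    truth$d_cation <- d_cation
  }
  list(atoms = atoms, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Verify the controlled geometry of an assembled toy site and raise a
# generation error on clashes (< 1 A) or geometry drift (> 1e-6 A).
check_toy_geometry <- function(atoms, truth) {
  X <- as.matrix(atoms[, c("x", "y", "z")])
  D <- dist_matrix(X, X)
  diag(D) <- Inf
  same_res <- outer(atoms$resno, atoms$resno, "==")
  if (min(D[!same_res]) < 1.0)
    stop("generation error: atoms from different residues closer than 1 A")
  sel <- function(resno, nm) {
    i <- which(atoms$resno == resno & atoms$atom %in% nm)
    X[i, , drop = FALSE]
  }
  dg <- min(dist_matrix(sel(2, HIS_RING_ATOMS), sel(6, ASP_CARBOXYLATE)))
  if (abs(dg - truth$d_gate) > 1e-6)
    stop("generation error: gate distance drifted (", dg, " vs ",
         truth$d_gate, ")")
  if (isTRUE(truth$out_partner)) {
    do <- min(dist_matrix(sel(2, HIS_RING_ATOMS), sel(7, GLU_CARBOXYLATE)))
    if (abs(do - truth$d_out) > 1e-6)
      stop("generation error: His-OUT partner distance drifted")
  }
  invisible(TRUE)
}

write_toy_pdb <- function(atoms, path) {
  bio3d::write.pdb(file = path,
                   type = atoms$record,
                   xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   resno = atoms$resno, resid = atoms$resid,
                   eleno = seq_len(nrow(atoms)), elety = atoms$atom,
                   chain = atoms$chain, o = rep(1, nrow(atoms)),
                   b = rep(0, nrow(atoms)),
                   elesy = guess_element(atoms$atom))
  invisible(path)
}

#' Generate a toy active-site coordinate file with controlled geometry
#'
#' Writes a minimal PDB file containing the gate His/Phe pair, the
#' catalytic Asp, the His-OUT Glu partner and optional ligand/cation
#' atoms, placed so that the measured distances equal the requested
#' values exactly (verified to 1e-6 A before writing). A ground-truth
#' JSON sidecar is written next to the file. Deterministic under `seed`.
#'
#' @param path output PDB path.
#' @param d_gate target minimum distance His imidazole ring to Asp
#'   carboxylate (Angstrom).
#' @param out_partner place the Glu carboxylate within `d_out` of the His
#'   ring (His-OUT hydrogen bond); when `FALSE` the Glu sits 20 A away.
#' @param d_out His-Glu contact distance (Angstrom).
#' @param ligand `"none"`, `"inosine"` or `"adenosine"`: a minimal
#'   nucleoside-like het group whose O5' sits `d_o5prime` from the His
#'   ND1.
#' @param d_o5prime ND1 to O5' distance (Angstrom).
#' @param nucleobase_contact place the C6 substituent (O6 or N6) 2.8 A
#'   from the residue-4 main-chain carbonyl oxygen (tautomer evidence).
#' @param cation `NULL`, `"NA"` or `"K"`; placed `d_cation` from the
#'   hinge-marker Calpha.
#' @param d_cation ion to hinge distance (Angstrom).
#' @param n_chains 1 or 2; chain B is a rigidly moved copy of chain A
#'   with optional isotropic Calpha noise `ca_noise` (Angstrom sd per
#'   coordinate).
#' @param ca_noise Calpha noise sd for chain B (Angstrom).
#' @param n_padding extra detached Gly residues appended to each chain.
#' @param slim swap the gate Phe for Gly, keeping the site within a
#'   50-atom budget for exhaustive pairwise checks.
#' @param seed integer RNG seed (chain-B motion and noise).
#' @return invisibly, a list with `path`, `truth` and the atom table.
#' @export
make_toy_site <- function(path, d_gate = 4.2, out_partner = FALSE,
                          d_out = 2.7,
                          ligand = c("none", "inosine", "adenosine"),
                          d_o5prime = 2.7, nucleobase_contact = FALSE,
                          cation = NULL, d_cation = 5.0,
                          n_chains = 1, ca_noise = 0, n_padding = 0,
                          slim = FALSE, seed = 1) {
  site <- toy_site_atoms(d_gate = d_gate, out_partner = out_partner,
                         d_out = d_out, ligand = ligand,
                         d_o5prime = d_o5prime,
                         nucleobase_contact = nucleobase_contact,
                         cation = cation, d_cation = d_cation,
                         n_padding = n_padding, slim = slim)
  check_toy_geometry(site$atoms, site$truth)
  atoms <- site$atoms
  if (n_chains == 2) {
    set.seed(seed)
    R <- rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, 360))
    shift <- 60 * vunit(stats::rnorm(3))
    B <- site$atoms
    XB <- t(R %*% t(as.matrix(B[, c("x", "y", "z")]))) +
      matrix(shift, nrow(B), 3, byrow = TRUE)
    if (ca_noise > 0) {
      is_ca <- B$atom == "CA" & B$record == "ATOM"
      XB[is_ca, ] <- XB[is_ca, ] +
        matrix(stats::rnorm(3 * sum(is_ca), sd = ca_noise),
               sum(is_ca), 3)
    }
    B[, c("x", "y", "z")] <- XB
    B$chain <- "B"
    atoms <- rbind(atoms, B)
  } else if (n_chains != 1) {
    stop("n_chains must be 1 or 2")
  }
  write_toy_pdb(atoms, path)
  truth <- c(site$truth,
             list(n_chains = n_chains, ca_noise = ca_noise, seed = seed,
                  expected_state = expected_gate_state(d_gate,
                                                       out_partner)))
  jsonlite::write_json(truth, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(path = path, truth = truth, atoms = atoms))
}

# Expected gate call under the default thresholds (6 / 8 A, 3.5 A H-bond).
expected_gate_state <- function(d_gate, out_partner) {
  if (d_gate <= 6) "IN"
  else if (d_gate >= 8 && out_partner) "OUT"
  else "undetermined"
}

#' Generate a toy two-domain conformation pair
#'
#' Builds two Calpha-only models of a fictitious two-domain protein:
#' model B equals model A with its substrate-binding domain rotated by a
#' known angle about a fixed axis through the domain centroid, followed
#' by a global rigid motion of the whole molecule. Ground truth is exact,
#' for validating [domain_rotation_angle()].
#'
#' @param dir output directory (two PDB files are written).
#' @param angle rotation angle in degrees.
#' @param axis rotation axis (length-3).
#' @param n_per_domain Calpha count per domain.
#' @param seed RNG seed (domain point clouds and global motion).
#' @return list with `modelA`, `modelB` (re-read `structure_model`s),
#'   `domain_ranges` and `truth`.
#' @export
make_toy_domain_pair <- function(dir = tempdir(), angle = 18,
                                 axis = c(0, 0, 1), n_per_domain = 30,
                                 seed = 1) {
  set.seed(seed)
  dom1 <- matrix(stats::rnorm(3 * n_per_domain, sd = 8), ncol = 3)
  dom2 <- matrix(stats::rnorm(3 * n_per_domain, sd = 8), ncol = 3)
  dom2[, 1] <- dom2[, 1] + 40
  A <- rbind(dom1, dom2)
  ctr <- colMeans(dom2)
  Rd <- rotation_about_axis(axis, angle)
  dom2b <- t(Rd %*% t(sweep(dom2, 2, ctr))) +
    matrix(ctr, n_per_domain, 3, byrow = TRUE)
  B <- rbind(dom1, dom2b)
  Rg <- rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, 360))
  B <- t(Rg %*% t(B)) + matrix(stats::runif(3, -30, 30), nrow(B), 3,
                               byrow = TRUE)
  write_ca_model <- function(X, path) {
    n <- nrow(X)
    bio3d::write.pdb(file = path, type = rep("ATOM", n),
                     xyz = as.numeric(t(X)), resno = seq_len(n),
                     resid = rep("GLY", n), eleno = seq_len(n),
                     elety = rep("CA", n), chain = rep("A", n),
                     o = rep(1, n), b = rep(0, n),
                     elesy = rep("C", n))
    path
  }
  pa <- write_ca_model(A, file.path(dir, sprintf("domainA_%d.pdb", seed)))
  pb <- write_ca_model(B, file.path(dir, sprintf("domainB_%d.pdb", seed)))
  ranges <- list(cofactor_binding = c(1, n_per_domain),
                 substrate_binding = c(n_per_domain + 1, 2 * n_per_domain))
  list(modelA = read_structure(pa), modelB = read_structure(pb),
       domain_ranges = ranges,
       truth = list(angle = angle, axis = axis, seed = seed))
}

#' Generate a gate-peptide flip pair
#'
#' Model A is a toy active site; model B is the same site with the
#' His-Phe peptide unit (C and O of the gate His, N of the gate Phe)
#' rotated by `flip_deg` about the Calpha(His)-Calpha(Phe) axis: the
#' peptide-plane flip that opens and shuts the molecular gate.
#'
#' @param dir output directory.
#' @param flip_deg rotation of the peptide unit in degrees (a real flip
#'   is ~180).
#' @param seed passed to [make_toy_site()].
#' @return list with `modelA`, `modelB` and `truth`.
#' @export
make_toy_flip_pair <- function(dir = tempdir(), flip_deg = 180,
                               seed = 1) {
  pa <- file.path(dir, sprintf("flipA_%d.pdb", seed))
  siteA <- make_toy_site(pa, d_gate = 4.2, seed = seed)
  atoms <- siteA$atoms
  ca_his <- unlist(atoms[atoms$resno == 2 & atoms$atom == "CA",
                         c("x", "y", "z")])
  ca_phe <- unlist(atoms[atoms$resno == 3 & atoms$atom == "CA",
                         c("x", "y", "z")])
  R <- rotation_about_axis(ca_phe - ca_his, flip_deg)
  move <- (atoms$resno == 2 & atoms$atom %in% c("C", "O")) |
    (atoms$resno == 3 & atoms$atom == "N")
  X <- as.matrix(atoms[move, c("x", "y", "z")])
  X <- t(R %*% t(sweep(X, 2, ca_his))) +
    matrix(ca_his, nrow(X), 3, byrow = TRUE)
  atoms[move, c("x", "y", "z")] <- X
  pb <- file.path(dir, sprintf("flipB_%d.pdb", seed))
  write_toy_pdb(atoms, pb)
  list(modelA = read_structure(pa), modelB = read_structure(pb),
       truth = list(flip_deg = flip_deg, seed = seed))
}
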