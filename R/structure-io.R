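ION_CODES <- c("NA", "K", "MG", "ZN", "CA", "CL", "MN", "FE", "CS", "LI",
               "RB", "NI", "CU", "CO", "CD", "IOD", "BR")
WATER_CODES <- c("HOH", "WAT", "DOD")
COFACTOR_CODES <- c("NAD", "NAI", "NAJ", "NDP")
NUCLEOSIDE_CODES <- c("ADN", "INO")
THIOETHER_CODES <- c("SAH", "SIH")

#' Read a macromolecular coordinate file into a structure model
#'
#' Parses PDB (or mmCIF) files via bio3d and applies the alternate-location
#' policy: for each (chain, residue, atom name) the highest-occupancy
#' conformer is kept, ties resolved towards altloc "A". Hydrogens are
#' dropped; all downstream geometry uses heavy atoms only.
#'
#' @param path coordinate file (`.pdb` or `.cif`).
#' @param structure_id identifier; defaults to the file base name.
#' @return a `structure_model`: list with `structure_id` and `atoms`, a
#'   data.frame with columns `record`, `eleno`, `atom`, `altloc`, `resid`,
#'   `chain`, `resno`, `insert`, `x`, `y`, `z`, `occ`, `element`.
#' @export
read_structure <- function(path, structure_id = NULL) {
  if (!file.exists(path)) stop("coordinate file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext == "cif") bio3d::read.cif(path) else
      bio3d::read.pdb(path, rm.alt = FALSE),
    error = function(e) stop("cannot parse coordinate file ", path, ": ",
                             conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty model in ", path)
  atoms <- data.frame(
    record = a$type, eleno = a$eleno, atom = a$elety,
    altloc = ifelse(is.na(a$alt), "", a$alt),
    resid = a$resid, chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno, insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    element = if (!is.null(a$elesy)) a$elesy else guess_element(a$elety),
    stringsAsFactors = FALSE)
  # PDB het code "NA" (sodium) collides with R's missing value in some
  # readers; restore it.
  na_res <- is.na(atoms$resid) & atoms$record == "HETATM"
  atoms$resid[na_res] <- "NA"
  atoms$element[is.na(atoms$element) | atoms$element == ""] <-
    guess_element(atoms$atom[is.na(atoms$element) | atoms$element == ""])
  atoms$element[atoms$resid == "NA" & is.na(atoms$element)] <- "NA"
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in ", path)
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  atoms <- apply_altloc_policy(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid,
               atoms$atom)
  if (anyDuplicated(key))
    stop("duplicated atom records after altloc resolution in ", path)
  if (is.null(structure_id))
    structure_id <- tools::file_path_sans_ext(basename(path))
  structure(list(structure_id = structure_id, atoms = atoms,
                 source = path),
            class = "structure_model")
}

guess_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", toupper(atom_name))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("NA", "CL", "MG", "ZN", "MN", "FE", "BR"), two,
         substr(nm, 1, 1))
}

apply_altloc_policy <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid,
               atoms$atom)
  ord <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$insert,
                                   atoms$resid, atoms$atom)), ,
                 drop = FALSE]
  atoms[order(atoms$eleno), , drop = FALSE]
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- protein_chains(x)
  cat("<structure_model> ", x$structure_id, ": ", nrow(x$atoms),
      " atoms, chains {", paste(ch, collapse = ","), "}\n", sep = "")
  inv <- ligand_inventory(x)
  if (nrow(inv))
    cat("  het: ", paste(unique(inv$resid), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Protein chain identifiers of a model
#' @param model a `structure_model`.
#' @return character vector of chain ids with ATOM records.
#' @export
protein_chains <- function(model) {
  unique(model$atoms$chain[model$atoms$record == "ATOM"])
}

#' Inventory of het groups in a structure
#'
#' Lists non-water het residues and classifies them into the active-site
#' vocabulary: `cofactor` (NAD), `nucleoside` (adenosine/inosine),
#' `thioether` (SAH/SIH), `ion` (monoatomic), `other`.
#'
#' @param model a `structure_model`.
#' @return data.frame with columns `chain`, `resno`, `resid`, `class`,
#'   `n_atoms`.
#' @export
ligand_inventory <- function(model) {
  het <- model$atoms[model$atoms$record == "HETATM" &
                       !(model$atoms$resid %in% WATER_CODES), ,
                     drop = FALSE]
  if (nrow(het) == 0L)
    return(data.frame(chain = character(0), resno = integer(0),
                      resid = character(0), class = character(0),
                      n_atoms = integer(0)))
  key <- paste(het$chain, het$resno, het$resid)
  first <- !duplicated(key)
  n <- as.vector(table(key)[key[first]])
  inv <- data.frame(chain = het$chain[first], resno = het$resno[first],
                    resid = het$resid[first], n_atoms = n,
                    stringsAsFactors = FALSE)
  inv$class <- ifelse(inv$resid %in% COFACTOR_CODES, "cofactor",
               ifelse(inv$resid %in% NUCLEOSIDE_CODES, "nucleoside",
               ifelse(inv$resid %in% THIOETHER_CODES, "thioether",
               ifelse(inv$resid %in% ION_CODES & inv$n_atoms == 1L, "ion",
                      "other"))))
  rownames(inv) <- NULL
  inv[, c("chain", "resno", "resid", "class", "n_atoms")]
}

# Data frame of atoms of one residue.
residue_atoms <- function(model, chain, resno,
                          record = c("ATOM", "HETATM")) {
  a <- model$atoms
  a[a$chain == chain & a$resno == resno & a$record %in% record, ,
    drop = FALSE]
}

# Named matrix of coordinates for one residue; rows are atom names.
residue_coords <- function(model, chain, resno,
                           record = c("ATOM", "HETATM")) {
  a <- residue_atoms(model, chain, resno, record)
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- normalise_atom_name(a$atom)
  m
}

# O5' / O5* prime-dialect normalisation.
normalise_atom_name <- function(x) gsub("\\*", "'", x)

#' One-letter sequence of a protein chain
#'
#' @param model a `structure_model`.
#' @param chain chain id.
#' @return list with `sequence` (string) and `resno` (integer vector of
#'   author residue numbers, parallel to the sequence).
#' @export
chain_sequence <- function(model, chain) {
  a <- model$atoms[model$atoms$record == "ATOM" &
                     model$atoms$chain == chain, , drop = FALSE]
  if (nrow(a) == 0L) stop("no ATOM records for chain ", chain)
  key <- paste(a$resno, a$insert)
  first <- !duplicated(key)
  resno <- a$resno[first]
  resid <- a$resid[first]
  one <- suppressWarnings(bio3d::aa321(resid))
  one[is.na(one) | one == ""] <- "X"
  list(sequence = paste(one, collapse = ""), resno = resno)
}

#' Calpha coordinates of a chain
#' @param model a `structure_model`.
#' @param chain chain id.
#' @param resno optional residue numbers to restrict to (order preserved).
#' @return n x 3 matrix, rownames = residue numbers.
#' @export
calpha_coords <- function(model, chain, resno = NULL) {
  a <- model$atoms[model$atoms$record == "ATOM" &
                     model$atoms$chain == chain &
                     model$atoms$atom == "CA", , drop = FALSE]
  if (!is.null(resno)) a <- a[match(resno, a$resno), , drop = FALSE]
  a <- a[!is.na(a$resno), , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$resno
  m
}

#' Fetch a structure by accession into a local cache
#'
#' Downloads a PDB entry from the RCSB file server unless a cached copy
#' already exists. Requires network access; offline runs fail with a
#' download error.
#'
#' @param accession 4-character PDB id (e.g. `"7R37"`).
#' @param cache_dir directory for cached files.
#' @return path to the cached PDB file.
#' @export
fetch_structure <- function(accession, cache_dir = file.path(tempdir(),
                                                             "pdb_cache")) {
  stopifnot(grepl("^[0-9][A-Za-z0-9]{3}$", accession))
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(cache_dir, paste0(toupper(accession), ".pdb"))
  if (file.exists(dest)) return(dest)
  url <- paste0("https://files.rcsb.org/download/", toupper(accession),
                ".pdb")
  status <- tryCatch(utils::download.file(url, dest, quiet = TRUE,
                                          mode = "wb"),
                     error = function(e) -1L, warning = function(w) -1L)
  if (!identical(status, 0L) || !file.exists(dest) ||
      file.size(dest) == 0) {
    unlink(dest)
    stop("could not download ", accession, " (network unavailable?)")
  }
  dest
}
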