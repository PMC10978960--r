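AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Construct a validated protein sequence record
#'
#' Sequences are read case-insensitively; a single trailing stop character
#' (`*`) is stripped. Every remaining character must be one of the 20
#' standard amino acids or `X`.
#'
#' @param id character identifier.
#' @param residues amino-acid string (one-letter code).
#' @param organism,phylum optional annotation.
#' @return an object of class `protein_sequence` (a list with fields `id`,
#'   `residues`, `organism`, `phylum`).
#' @export
protein_sequence <- function(id, residues, organism = NULL, phylum = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(residues) != 1L || !is.character(residues))
    stop("residues must be a single character string")
  residues <- toupper(gsub("\\*+$", "", residues))
  if (!nzchar(residues)) stop("empty sequence for '", id, "'")
  chars <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad))
    stop("sequence '", id, "' contains invalid characters: ",
         paste(bad, collapse = ", "))
  structure(list(id = id, residues = residues,
                 organism = organism, phylum = phylum),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("<protein_sequence> ", x$id, " (", nchar(x$residues), " aa)",
      if (!is.null(x$organism)) paste0(" - ", x$organism), "\n", sep = "")
  invisible(x)
}

#' @export
length.protein_sequence <- function(x) nchar(x$residues)

# Accept either a protein_sequence or a bare string and return the string.
as_residue_string <- function(x) {
  if (inherits(x, "protein_sequence")) return(x$residues)
  if (is.character(x) && length(x) == 1L) {
    return(protein_sequence("query", x)$residues)
  }
  stop("expected a protein_sequence or a single amino-acid string")
}

seq_id_of <- function(x, default) {
  if (inherits(x, "protein_sequence")) x$id else default
}

#' Read a multi-record protein FASTA file
#'
#' @param path FASTA file (wrapped or single-line records).
#' @return a named list of [protein_sequence()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(set), function(i) {
    protein_sequence(ids[[i]], as.character(set[[i]]))
  })
  names(out) <- ids
  out
}

#' Write protein sequences to FASTA
#'
#' @param seqs a list of [protein_sequence()] objects (or a named character
#'   vector).
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.character(seqs)) {
    seqs <- mapply(protein_sequence, names(seqs), seqs, SIMPLIFY = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    n <- nchar(s$residues)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s$residues, starts, pmin(starts + width - 1L, n)),
               con)
  }
  invisible(path)
}
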