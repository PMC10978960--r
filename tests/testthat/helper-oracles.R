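# Independent oracles used by the unit and acceptance tests. These are
# deliberately written with different algorithms/formulations than the
# package implementations they check.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Exhaustive-recursion optimal global alignment score under affine gaps
# (gap of length L costs open + L * ext). States: 0 = start/diagonal,
# 1 = gap in query (ref consumed), 2 = gap in ref. Memoised recursion
# over alignment prefixes -- independent of the Biostrings C code path.
bf_align_score <- function(q, r, mat = blosum62, open = 11, ext = 1) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  n <- length(qc); m <- length(rc)
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, prev) {
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, mat[qc[i], rc[j]] + rec(i + 1, j + 1, 0))
    if (j <= m)
      best <- max(best,
                  -(ext + if (prev == 1) 0 else open) + rec(i, j + 1, 1))
    if (i <= n)
      best <- max(best,
                  -(ext + if (prev == 2) 0 else open) + rec(i + 1, j, 2))
    memo[[key]] <- best
    best
  }
  rec(1, 1, 0)
}

# Horn quaternion-based optimal superposition RMSD (closed form through
# the largest eigenvalue of the 4x4 key matrix).
quaternion_rmsd <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  S <- t(Ac) %*% Bc
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Ac^2) + sum(Bc^2) - 2 * lambda) / nrow(A)
  sqrt(max(0, msd))
}

# Brute-force all-pairs hydrogen-bond scan between a ligand residue and
# protein N/O/S atoms (no pocket prefilter, plain double loop).
bf_hbonds <- function(model, ligand_resid, cutoff) {
  a <- model$atoms
  lig <- a[a$record == "HETATM" & a$resid == ligand_resid &
             a$element %in% c("N", "O", "S"), , drop = FALSE]
  prot <- a[a$record == "ATOM" & a$element %in% c("N", "O", "S"), ,
            drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(lig))) {
    for (j in seq_len(nrow(prot))) {
      d <- sqrt(sum((as.numeric(lig[i, c("x", "y", "z")]) -
                       as.numeric(prot[j, c("x", "y", "z")]))^2))
      if (d <= cutoff && cutoff > 0)
        out <- rbind(out, data.frame(
          ligand_atom = gsub("\\*", "'", lig$atom[i]),
          chain = prot$chain[j], resno = prot$resno[j],
          atom = gsub("\\*", "'", prot$atom[j]), distance = d,
          stringsAsFactors = FALSE))
    }
  }
  out
}

hbond_key <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(character(0))
  sort(paste(df$ligand_atom, df$chain, df$resno, df$atom))
}

# Random coordinate cloud (rows ~ N(0, scale^2)).
random_cloud <- function(n, scale = 10) {
  matrix(stats::rnorm(3 * n, sd = scale), ncol = 3)
}

# Study-set assay preference calls from the packaged conversion symbols.
study_assay_calls <- function(meta) {
  calls <- lapply(seq_len(nrow(meta)), function(i) {
    call_assay_preference(data.frame(
      enzyme_id = meta$enzyme[i],
      substrate = c("SAH", "SAH", "SIH", "SIH"),
      direction = c("cleavage", "synthesis", "cleavage", "synthesis"),
      category = c(meta$sah_cleavage[i], meta$sah_synthesis[i],
                   meta$sih_cleavage[i], meta$sih_synthesis[i]),
      stringsAsFactors = FALSE))
  })
  data.frame(
    enzyme_id = vapply(calls, `[[`, "", "enzyme_id"),
    assay_label = vapply(calls, `[[`, "", "label"),
    sih_activity = meta$sih_cleavage != "-" | meta$sih_synthesis != "-",
    stringsAsFactors = FALSE)
}

# Reference annotation for a deposited PfuSAHH structure, built from the
# structure's own chain sequence with the published author numbering
# (motif 55-59, Asp128, gate His298/Phe299, Glu302, Asp348).
pfu_annotation_from_structure <- function(model, chain = NULL) {
  if (is.null(chain)) chain <- protein_chains(model)[1]
  cs <- chain_sequence(model, chain)
  landmark <- function(author_resno) match(author_resno, cs$resno)
  reference_annotation(
    ref_id = paste0(model$structure_id, "_", chain),
    ref_sequence = cs$sequence,
    motif_start = landmark(55),
    gate_his = landmark(298), gate_phe = landmark(299),
    catalytic_asp = landmark(128), out_partner_glu = landmark(302),
    c6_partner = landmark(348))
}
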