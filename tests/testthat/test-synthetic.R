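test_that("generators are byte-identical under a fixed seed", {
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  make_toy_site(p1, d_gate = 4.2, ligand = "inosine", n_chains = 2,
                ca_noise = 0.2, seed = 7)
  make_toy_site(p2, d_gate = 4.2, ligand = "inosine", n_chains = 2,
                ca_noise = 0.2, seed = 7)
  expect_identical(readLines(p1), readLines(p2))
  p3 <- withr::local_tempfile(fileext = ".pdb")
  make_toy_site(p3, d_gate = 4.2, ligand = "inosine", n_chains = 2,
                ca_noise = 0.2, seed = 8)
  expect_false(identical(readLines(p1), readLines(p3)))

  g1 <- make_motif_sequences(3, "HxExK", seed = 5,
                             n_outside_substitutions = 2)
  g2 <- make_motif_sequences(3, "HxExK", seed = 5,
                             n_outside_substitutions = 2)
  expect_identical(lapply(g1$sequences, `[[`, "residues"),
                   lapply(g2$sequences, `[[`, "residues"))

  t1 <- make_peak_table(40, noise_sd_pct = 2, seed = 3)
  t2 <- make_peak_table(40, noise_sd_pct = 2, seed = 3)
  expect_identical(t1$peaks$area, t2$peaks$area)
})

test_that("toy-site geometry survives the file round trip", {
  p <- withr::local_tempfile(fileext = ".pdb")
  res <- make_toy_site(p, d_gate = 4.2, out_partner = FALSE,
                       ligand = "inosine", d_o5prime = 2.7)
  truth <- jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE)
  expect_equal(truth$d_gate, 4.2)
  expect_equal(truth$expected_state, "IN")
  m <- read_structure(p)
  his <- sahhtools:::residue_coords(m, "A", 2, "ATOM")
  asp <- sahhtools:::residue_coords(m, "A", 6, "ATOM")
  d <- min(sahhtools:::dist_matrix(
    his[intersect(rownames(his), c("CG", "ND1", "CD2", "CE1", "NE2")), ],
    asp[intersect(rownames(asp), c("OD1", "OD2")), ]))
  expect_equal(d, 4.2, tolerance = 2e-3)  # PDB 0.001 A rounding
})

test_that("infeasible geometry is a generation error", {
  p <- withr::local_tempfile(fileext = ".pdb")
  expect_error(make_toy_site(p, d_gate = 0.5), "closer than 1 A")
  expect_error(make_toy_site(p, d_gate = -1))
})

test_that("sequence generation honours its truth table and errors", {
  refs <- load_reference_set()
  gen <- make_motif_sequences(4, "HxTxQ", scaffold = refs$LlSAHH_like,
                              delete_segment40 = TRUE,
                              cterm_truncation = 10, seed = 2)
  expect_equal(nrow(gen$truth), 4L)
  expect_true(all(!gen$truth$segment40_present))
  expect_true(all(gen$truth$cterm_truncation == 10))
  expect_equal(nchar(gen$sequences[[1]]$residues),
               nchar(refs$LlSAHH_like$ref_sequence$residues) - 40 - 10)
  expect_error(make_motif_sequences(1, "HxExK", cterm_truncation = 1e4),
               "truncation")
  expect_error(make_motif_sequences(1, "HxExK",
                                    delete_segment40 = TRUE),
               "segment")
})

test_that("generated FASTA and sidecar truth round-trip", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  gen <- make_motif_sequences(3, "HxExK", seed = 4, fasta = fa)
  back <- read_fasta(fa)
  expect_equal(names(back), gen$truth$id)
  expect_identical(back[[1]]$residues, gen$sequences[[1]]$residues)
  truth <- jsonlite::read_json(paste0(fa, ".json"),
                               simplifyVector = TRUE)
  expect_equal(truth$motif_class, rep("HxExK", 3))
})

test_that("peak-table generation is exact without noise", {
  for (conv in c(0, 12.5, 40, 70, 100)) {
    tab <- make_peak_table(conv, noise_sd_pct = 0)
    expect_equal(score_conversion(tab$peaks)$conversion_pct, conv)
  }
  # response factors do not bias the noise-free recovery
  tab <- make_peak_table(40, response_factors = c(SAH = 0.5,
                                                  adenosine = 2))
  expect_equal(score_conversion(tab$peaks)$conversion_pct, 40)
  expect_error(make_peak_table(40, noise_sd_pct = -1), "non-negative")
  expect_error(make_peak_table(140))
})
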