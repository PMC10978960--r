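refset <- load_reference_set()
pfu_ref <- refset$PfuSAHH_like

test_that("reference motifs extract at their annotated positions", {
  m <- extract_fingerprint(pfu_ref$ref_sequence, pfu_ref)
  expect_equal(m$query_positions, 55:59)
  expect_equal(m$motif_class, "HxExK")
  expect_equal(substr(m$residues, 1, 1), "H")
  expect_equal(substr(m$residues, 3, 3), "E")
  expect_equal(substr(m$residues, 5, 5), "K")

  # the crenarchaeal homologue: Thr at motif position 3 = residue 53
  sac <- extract_fingerprint(refset$SacSAHH_like$ref_sequence, pfu_ref)
  expect_equal(sac$motif_class, "HxTxE")
  expect_equal(sac$query_positions[3], 53)

  mma <- extract_fingerprint(refset$MmaSAHH_like$ref_sequence, pfu_ref)
  expect_equal(mma$motif_class, "HxExK")
  expect_equal(mma$query_positions[5], 74)
})

test_that("unalignable queries give an undetermined motif, not an error", {
  m <- extract_fingerprint(strrep("G", 10), pfu_ref)
  expect_equal(m$motif_class, "undetermined")
  expect_equal(classify_motif(m)$label, "unknown")
})

test_that("motif classification is total and exact on anchor patterns", {
  for (a1 in c("H", "A", "G")) {
    for (a3 in c("E", "T", "Q", "A")) {
      for (a5 in c("K", "E", "Q", "A")) {
        cls <- sahhtools:::motif_class_from_anchors(a1, a3, a5)
        if (a1 != "H") {
          expect_equal(cls, "other")
        } else if (a3 == "E" && a5 == "K") {
          expect_equal(cls, "HxExK")
        } else if (a3 == "T" && a5 == "E") {
          expect_equal(cls, "HxTxE")
        } else if (a3 == "T" && a5 == "Q") {
          expect_equal(cls, "HxTxQ")
        } else if (a3 == "E") {
          expect_equal(cls, "HxExX")
        } else {
          expect_equal(cls, "other")
        }
      }
    }
  }
  expect_equal(sahhtools:::motif_class_from_anchors("H", "-", "K"),
               "undetermined")
})

test_that("only HxExK maps to SIH preference and HxTxE/Q to SAH", {
  mk <- function(res, cls) structure(list(residues = res,
                                          query_positions = 1:5,
                                          motif_class = cls),
                                     class = "fingerprint_motif")
  expect_equal(classify_motif(mk("HSEVK", "HxExK"))$label,
               "SIH-preferring")
  expect_equal(classify_motif(mk("HSTVE", "HxTxE"))$label,
               "SAH-preferring")
  expect_equal(classify_motif(mk("HSTVQ", "HxTxQ"))$label,
               "SAH-preferring")
  expect_equal(classify_motif(mk("HSEVA", "HxExX"))$label, "unknown")
  # a non-His position 1 invalidates the catalytic residue
  bad <- classify_motif(mk("ASEVK", "other"))
  expect_equal(bad$label, "unknown")
  expect_false(bad$valid_catalytic_his)
  expect_match(bad$basis, "important for catalysis")
})

test_that("planted motifs are recovered across seeds", {
  classes <- c("HxExK", "HxTxE", "HxTxQ")
  # noise-free: 100 % recovery expected
  for (seed in 1:50) {
    cls <- classes[(seed %% 3) + 1]
    gen <- make_motif_sequences(1, cls, scaffold = pfu_ref, seed = seed)
    m <- extract_fingerprint(gen$sequences[[1]], pfu_ref)
    expect_equal(m$motif_class, cls, info = paste("seed", seed))
  }
  # three substitutions outside the anchors: >= 90 % recovery
  hits <- 0L
  for (seed in 1:50) {
    cls <- classes[(seed %% 3) + 1]
    gen <- make_motif_sequences(1, cls, scaffold = pfu_ref,
                                n_outside_substitutions = 3, seed = seed)
    m <- extract_fingerprint(gen$sequences[[1]], pfu_ref)
    hits <- hits + (m$motif_class == cls)
  }
  expect_gte(hits / 50, 0.9)
})
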