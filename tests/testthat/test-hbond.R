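test_that("hydrogen-bond enumeration equals the all-pairs brute force", {
  for (seed in 1:5) {
    p <- withr::local_tempfile(fileext = ".pdb")
    make_toy_site(p, d_gate = 3 + seed, ligand = "inosine",
                  d_o5prime = 2.5 + 0.2 * seed,
                  nucleobase_contact = seed %% 2 == 0, seed = seed)
    m <- read_structure(p)
    expect_lte(nrow(m$atoms), 60)
    for (cutoff in c(2.8, 3.5, 5.0)) {
      got <- enumerate_hbonds(m, "INO", cutoff = cutoff)
      want <- bf_hbonds(m, "INO", cutoff)
      expect_identical(hbond_key(got), hbond_key(want),
                       info = sprintf("seed %d cutoff %.1f", seed,
                                      cutoff))
    }
  }
})

test_that("hydrogen-bond sets are monotone in the cutoff", {
  p <- withr::local_tempfile(fileext = ".pdb")
  make_toy_site(p, d_gate = 4.2, ligand = "inosine",
                nucleobase_contact = TRUE)
  m <- read_structure(p)
  prev <- character(0)
  for (cutoff in c(2.0, 2.5, 3.0, 3.5, 4.0, 5.0)) {
    cur <- hbond_key(enumerate_hbonds(m, "INO", cutoff = cutoff))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("a zero cutoff returns an empty set; absent ligands error", {
  p <- withr::local_tempfile(fileext = ".pdb")
  make_toy_site(p, d_gate = 4.2, ligand = "inosine")
  m <- read_structure(p)
  expect_equal(nrow(enumerate_hbonds(m, "INO", cutoff = 0)), 0L)
  expect_error(enumerate_hbonds(m, "ADN"), "not found")
})

test_that("results are sorted by distance with main-chain annotation", {
  p <- withr::local_tempfile(fileext = ".pdb")
  make_toy_site(p, d_gate = 4.2, ligand = "inosine",
                nucleobase_contact = TRUE)
  hb <- enumerate_hbonds(read_structure(p), "INO")
  expect_true(!is.unsorted(hb$distance))
  o6 <- hb[hb$ligand_atom == "O6" & hb$atom == "O", ]
  expect_true(all(o6$mainchain))
  expect_equal(min(o6$distance), 2.8, tolerance = 0.01)
})

test_that("tautomer inference follows the C6-contact evidence", {
  p1 <- withr::local_tempfile(fileext = ".pdb")
  make_toy_site(p1, d_gate = 4.2, ligand = "inosine",
                nucleobase_contact = TRUE)
  hb1 <- enumerate_hbonds(read_structure(p1), "INO")
  t1 <- infer_tautomer(hb1, "INO")
  expect_equal(t1$call, "imino_hydroxy")
  expect_gte(nrow(t1$evidence), 1L)

  p2 <- withr::local_tempfile(fileext = ".pdb")
  make_toy_site(p2, d_gate = 4.2, ligand = "inosine",
                nucleobase_contact = FALSE)
  hb2 <- enumerate_hbonds(read_structure(p2), "INO")
  expect_equal(infer_tautomer(hb2, "INO")$call, "amino_oxo")

  p3 <- withr::local_tempfile(fileext = ".pdb")
  make_toy_site(p3, d_gate = 4.2, ligand = "adenosine",
                nucleobase_contact = TRUE)
  hb3 <- enumerate_hbonds(read_structure(p3), "ADN")
  expect_equal(infer_tautomer(hb3, "ADN")$call, "amino")

  expect_equal(infer_tautomer(hb1, "XYZ")$call, "undetermined")
})

test_that("hinge cations are detected within the cutoff and not beyond", {
  p <- withr::local_tempfile(fileext = ".pdb")
  make_toy_site(p, d_gate = 4.2, cation = "K", d_cation = 5)
  m <- read_structure(p)
  hit <- detect_cation(m, hinge_resno = 4:5, cutoff = 8)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$element, "K")
  expect_lte(hit$min_distance, 5)
  expect_equal(nrow(detect_cation(m, hinge_resno = 4:5, cutoff = 2)), 0L)

  p2 <- withr::local_tempfile(fileext = ".pdb")
  make_toy_site(p2, d_gate = 4.2)
  expect_equal(nrow(detect_cation(read_structure(p2),
                                  hinge_resno = 4:5, cutoff = 8)), 0L)
})

test_that("sodium het records survive the NA name collision", {
  p <- withr::local_tempfile(fileext = ".pdb")
  make_toy_site(p, d_gate = 4.2, cation = "NA", d_cation = 5)
  m <- read_structure(p)
  hit <- detect_cation(m, hinge_resno = 4:5, cutoff = 8)
  expect_equal(hit$element, "NA")
})
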