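toy_ref <- toy_site_annotation()

gate_state_of <- function(path) {
  m <- read_structure(path)
  rmap <- map_reference_residues(m, toy_ref)
  classify_gate_state(m, rmap)
}

test_that("landmarks map onto the toy site by sequence alignment", {
  p <- withr::local_tempfile(fileext = ".pdb")
  make_toy_site(p, d_gate = 4.2)
  m <- read_structure(p)
  rmap <- map_reference_residues(m, toy_ref)
  expect_named(rmap, "A")
  expect_equal(unname(rmap$A[c("gate_his", "gate_phe", "catalytic_asp",
                               "out_partner_glu")]),
               c(2L, 3L, 6L, 7L))
})

test_that("gate states recover across the constructed distance ladder", {
  d_ladder <- c(3.0, 4.2, 6.9, 8.5, 10.4)
  expected <- c("IN", "IN", "undetermined", "OUT", "OUT")
  for (seed in 1:20) {
    for (i in seq_along(d_ladder)) {
      p <- withr::local_tempfile(fileext = ".pdb")
      make_toy_site(p, d_gate = d_ladder[i],
                    out_partner = d_ladder[i] >= 8, d_out = 2.7,
                    n_chains = 2, seed = seed)
      g <- gate_state_of(p)
      expect_equal(nrow(g), 2L)
      expect_true(all(g$state == expected[i]),
                  info = sprintf("d=%.1f seed=%d", d_ladder[i], seed))
      expect_equal(g$d_gate, rep(d_ladder[i], 2), tolerance = 0.01)
    }
  }
})

test_that("measured gate distances match the construction targets", {
  p_in <- withr::local_tempfile(fileext = ".pdb")
  make_toy_site(p_in, d_gate = 4.2, ligand = "inosine", d_o5prime = 2.7)
  g_in <- gate_state_of(p_in)
  expect_equal(g_in$state, "IN")
  expect_equal(g_in$d_gate, 4.2, tolerance = 0.01)
  expect_equal(g_in$d_his_o5prime, 2.7, tolerance = 0.01)

  p_out <- withr::local_tempfile(fileext = ".pdb")
  make_toy_site(p_out, d_gate = 10.4, out_partner = TRUE, d_out = 2.7)
  g_out <- gate_state_of(p_out)
  expect_equal(g_out$state, "OUT")
  expect_equal(g_out$d_gate, 10.4, tolerance = 0.01)
  expect_equal(g_out$d_out_partner, 2.7, tolerance = 0.01)
})

test_that("a distant His without the Glu contact stays undetermined", {
  p <- withr::local_tempfile(fileext = ".pdb")
  make_toy_site(p, d_gate = 10.4, out_partner = FALSE)
  g <- gate_state_of(p)
  expect_equal(g$state, "undetermined")
  expect_match(g$reason, "partner")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  make_toy_site(p2, d_gate = 7.0, out_partner = FALSE)
  expect_equal(gate_state_of(p2)$state, "undetermined")
})

test_that("side-chain dihedrals and rotamer bins recover construction", {
  p <- withr::local_tempfile(fileext = ".pdb")
  make_toy_site(p, d_gate = 4.2)
  g <- gate_state_of(p)
  expect_equal(g$chi1, -60, tolerance = 0.1)
  expect_equal(g$chi2, -60, tolerance = 0.1)
  expect_equal(g$rotamer, "mm")
})

test_that("missing side-chain atoms yield undetermined with a reason", {
  p <- withr::local_tempfile(fileext = ".pdb")
  make_toy_site(p, d_gate = 4.2)
  m <- read_structure(p)
  m$atoms <- m$atoms[!(m$atoms$resno == 6 &
                         m$atoms$atom %in% c("OD1", "OD2")), ]
  rmap <- map_reference_residues(m, toy_ref)
  g <- classify_gate_state(m, rmap)
  expect_equal(g$state, "undetermined")
  expect_match(g$reason, "missing")
})

test_that("gate thresholds are configurable", {
  p <- withr::local_tempfile(fileext = ".pdb")
  make_toy_site(p, d_gate = 6.9, out_partner = FALSE)
  m <- read_structure(p)
  rmap <- map_reference_residues(m, toy_ref)
  g <- classify_gate_state(m, rmap, in_threshold = 7.0,
                           out_threshold = 8.0)
  expect_equal(g$state, "IN")
})
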