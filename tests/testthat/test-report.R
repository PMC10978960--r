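test_that("sequence annotation matches the generator truth table", {
  refs <- load_reference_set()
  fa <- withr::local_tempfile(fileext = ".fasta")
  make_motif_sequences(5, "HxExK", scaffold = refs$PfuSAHH_like,
                       seed = 21, fasta = fa)
  rep <- annotate_sequences(fa, refs = refs)
  expect_equal(nrow(rep), 5L)
  expect_true(all(rep$motif_class == "HxExK"))
  expect_true(all(rep$predicted == "SIH-preferring"))
})

test_that("the packaged study set reproduces the published grouping", {
  study <- load_study_set()
  rep <- annotate_sequences(study$sequences)
  meta <- study$metadata
  expect_equal(sum(rep$motif_class == "HxExK"), 6L)
  cren <- rep$motif_class[match(meta$enzyme[meta$phylum ==
                                              "Crenarchaeota"], rep$id)]
  expect_true(all(cren == "HxTxE"))
  # concordance of motif predictions with the published assay symbols
  calls <- study_assay_calls(meta)
  conc <- concordance_report(
    data.frame(enzyme_id = rep$id, predicted = rep$predicted), calls)
  expect_equal(conc$fraction, 1)
  # residual SIH turnover of SAH-motif enzymes stays flagged
  noted <- conc$table$enzyme_id[nzchar(conc$table$note)]
  expect_true(all(c("MmSAHH", "PaSAHH") %in% noted))
})

test_that("structure annotation reports gate states per file", {
  dir <- withr::local_tempdir()
  p_in <- file.path(dir, "site_in.pdb")
  p_out <- file.path(dir, "site_out.pdb")
  make_toy_site(p_in, d_gate = 4.2, ligand = "inosine",
                nucleobase_contact = TRUE)
  make_toy_site(p_out, d_gate = 10.4, out_partner = TRUE)
  rep <- annotate_structures(c(p_in, p_out), ref = toy_site_annotation())
  expect_equal(rep$gate_state[rep$structure_id == "site_in"], "IN")
  expect_equal(rep$gate_state[rep$structure_id == "site_out"], "OUT")
  expect_equal(rep$tautomer[rep$structure_id == "site_in"],
               "imino_hydroxy")
})

test_that("combined reports merge with hand-checked concordance flags", {
  seq_rep <- data.frame(
    id = c("E1", "E2", "E3"),
    motif = c("HSEVK", "HSTVE", "HSTVQ"),
    motif_class = c("HxExK", "HxTxE", "HxTxQ"),
    predicted = c("SIH-preferring", "SAH-preferring", "SAH-preferring"),
    valid_catalytic_his = TRUE, segment40_present = FALSE,
    cterm_delta = 0L, thermophile_flag = FALSE,
    stringsAsFactors = FALSE)
  calls <- data.frame(enzyme_id = c("E1", "E2", "E3"),
                      assay_label = c("SIH-preferring", "SAH-only",
                                      "SIH-preferring"))
  pw <- data.frame(enzyme_id = c("E1", "E2", "E3"),
                   dadd_present = c(TRUE, TRUE, FALSE),
                   mtan_present = FALSE)
  out <- combined_report(seq_rep, assay_calls = calls, pathway = pw)
  expect_equal(out$concordant, c(TRUE, TRUE, FALSE))
  expect_equal(out$routes[out$enzyme_id == "E1"],
               "SAHH_direct+deamination_SIH")
  expect_equal(out$routes[out$enzyme_id == "E2"], "SAHH_direct")

  solo <- combined_report(seq_rep)
  expect_true(all(is.na(solo$assay_label)))
  expect_error(combined_report(rbind(seq_rep, seq_rep)), "duplicate")
})

test_that("run configuration parses, validates and rejects unknowns", {
  cfg <- default_run_config()
  expect_true(all(unlist(cfg) > 0))
  f <- withr::local_tempfile(lines = c("# comment",
                                       "gate_in_threshold = 5.5",
                                       "noise_floor = 2"))
  got <- read_run_config(f)
  expect_equal(got$gate_in_threshold, 5.5)
  expect_equal(got$noise_floor, 2)
  expect_equal(got$hbond_cutoff, cfg$hbond_cutoff)
  bad <- withr::local_tempfile(lines = "no_such_key = 1")
  expect_error(read_run_config(bad), "unknown config key")
  neg <- withr::local_tempfile(lines = "noise_floor = -1")
  expect_error(read_run_config(neg), "positive")
})

test_that("the command-line wrapper returns documented exit codes", {
  script <- system.file("scripts", "sahh_tools.R",
                        package = "sahhtools")
  expect_true(nzchar(script))
  rlibs <- paste(.libPaths(), collapse = .Platform$path.sep)
  run_cli <- function(...) {
    suppressWarnings(system2(
      file.path(R.home("bin"), "Rscript"), c(script, ...),
      stdout = TRUE, stderr = TRUE,
      env = paste0("R_LIBS=", shQuote(rlibs))))
  }
  fa <- withr::local_tempfile(fileext = ".fasta")
  make_motif_sequences(2, "HxExK",
                       scaffold = load_reference_set()$PfuSAHH_like,
                       seed = 1, fasta = fa)
  out_tsv <- withr::local_tempfile(fileext = ".tsv")
  ok <- run_cli("annotate-seq", fa, "--out", out_tsv)
  expect_null(attr(ok, "status"))
  rep <- read.delim(out_tsv)
  expect_equal(nrow(rep), 2L)
  expect_true(all(rep$motif_class == "HxExK"))

  usage <- run_cli("annotate-seq", "does_not_exist.fasta")
  expect_equal(attr(usage, "status"), 1L)
  unknown <- run_cli("frobnicate")
  expect_equal(attr(unknown, "status"), 1L)
})
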