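mk_peaks <- function(substrate_area, product_area, side_area = 0,
                     substrate = "SAH", direction = "cleavage",
                     rf = NULL) {
  roles <- sahhtools:::default_analyte_roles(substrate, direction)
  analytes <- c(roles$substrate, roles$products, roles$side_products)
  tab <- data.frame(assay = "toy", direction = direction,
                    substrate = substrate, analyte = analytes,
                    rt_min = c(4, 6, 8),
                    area = c(substrate_area, product_area, side_area))
  if (!is.null(rf)) tab$response_factor <- rf
  as_peak_table(tab)
}

test_that("categories follow the published thresholds with closed 30-70", {
  expect_equal(conversion_category(c(85, 71, 70.0001)), rep("+++", 3))
  expect_equal(conversion_category(c(70, 50, 30)), rep("++", 3))
  expect_equal(conversion_category(c(29.999, 10, 1)), rep("+", 3))
  expect_equal(conversion_category(c(0.5, 0)), rep("-", 2))
  expect_error(conversion_category(101))
  # monotone non-decreasing over a fine grid
  grid <- seq(0, 100, by = 0.25)
  ranks <- match(conversion_category(grid), c("-", "+", "++", "+++"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("conversion scoring reproduces worked peak-area examples", {
  expect_equal(score_conversion(mk_peaks(15, 85))$conversion_pct, 85)
  expect_equal(score_conversion(mk_peaks(15, 85))$category, "+++")
  expect_equal(score_conversion(mk_peaks(50, 50))$category, "++")
  expect_equal(score_conversion(mk_peaks(90, 10))$category, "+")
  expect_equal(score_conversion(mk_peaks(100, 0))$category, "-")
  # side product counts as converted substrate
  expect_equal(score_conversion(mk_peaks(60, 30, 10))$conversion_pct, 40)
  expect_error(score_conversion(mk_peaks(0, 0, 0)), "zero")
})

test_that("conversion is invariant to uniform area rescaling", {
  for (f in c(0.01, 1, 250)) {
    expect_equal(score_conversion(mk_peaks(35 * f, 55 * f,
                                           10 * f))$conversion_pct, 65)
  }
})

test_that("response factors reweight the converted fraction", {
  # product response factor 2: its area counts double
  rec <- score_conversion(mk_peaks(50, 25, 0, rf = c(1, 2, 1)))
  expect_equal(rec$conversion_pct, 50)
})

test_that("synthetic tables recover the true conversion and category", {
  # single table: recovery within 3 sigma
  one <- make_peak_table(40, noise_sd_pct = 2, seed = 1)
  rec <- score_conversion(one$peaks)
  expect_lt(abs(rec$conversion_pct - 40), 3 * 2)
  # 200 seeded tables: mean within 0.5, >= 95 % category recovery
  convs <- numeric(200); cats <- character(200)
  for (seed in 1:200) {
    tab <- make_peak_table(40, noise_sd_pct = 2, seed = seed)
    r <- score_conversion(tab$peaks)
    convs[seed] <- r$conversion_pct
    cats[seed] <- r$category
  }
  expect_equal(mean(convs), 40, tolerance = 0.5)
  expect_gte(mean(cats == "++"), 0.95)
  # noise-free edge cases
  expect_equal(score_conversion(make_peak_table(0)$peaks)$category, "-")
  expect_equal(score_conversion(make_peak_table(100)$peaks)$category,
               "+++")
})

test_that("assay preference calls follow the ordinal category rule", {
  mk_records <- function(sah, sih, id = "E") data.frame(
    enzyme_id = id,
    substrate = c("SAH", "SAH", "SIH", "SIH"),
    direction = rep(c("cleavage", "synthesis"), 2),
    category = c(sah, sih), stringsAsFactors = FALSE)
  # the euryarchaeal exemplar: SAH +/++ vs SIH ++/+++
  expect_equal(call_assay_preference(
    mk_records(c("+", "++"), c("++", "+++")))$label, "SIH-preferring")
  # the crenarchaeal exemplar: SAH +++/+++ vs SIH -/-
  expect_equal(call_assay_preference(
    mk_records(c("+++", "+++"), c("-", "-")))$label, "SAH-only")
  expect_equal(call_assay_preference(
    mk_records(c("-", "-"), c("-", "-")))$label, "inactive")
  expect_equal(call_assay_preference(
    mk_records(c("++", "+"), c("+", "++")))$label, "both/no-preference")
  expect_equal(call_assay_preference(
    mk_records(c("+++", "++"), c("-", "+")))$label, "SAH-preferring")
  expect_error(call_assay_preference(mk_records(c("+", "+"),
                                                c("+", "+"))[1:3, ]),
               "both directions")
})

test_that("the packaged study truth table reproduces the study grouping", {
  meta <- load_study_set()$metadata
  calls <- study_assay_calls(meta)
  cren <- calls$assay_label[meta$phylum == "Crenarchaeota"]
  expect_true(all(cren == "SAH-only"))
  sih_pref <- calls$enzyme_id[calls$assay_label == "SIH-preferring"]
  expect_setequal(sih_pref, c("MiSAHH", "MjSIHH", "MmaSAHH", "PfuSAHH",
                              "TkSAHH", "TmSAHH"))
})

test_that("concordance fractions match constructed inputs", {
  preds <- data.frame(enzyme_id = c("a", "b", "c", "d"),
                      predicted = c("SIH-preferring", "SAH-preferring",
                                    "SAH-preferring", "SIH-preferring"))
  calls <- data.frame(enzyme_id = c("a", "b", "c", "d"),
                      assay_label = c("SIH-preferring", "SAH-only",
                                      "SAH-preferring", "SAH-preferring"))
  rep <- concordance_report(preds, calls)
  expect_equal(rep$fraction, 0.75)
  expect_false(rep$table$concordant[rep$table$enzyme_id == "d"])
  expect_match(rep$table$note[rep$table$enzyme_id == "d"], "disagree")
  # identical labels: full concordance
  calls2 <- data.frame(enzyme_id = preds$enzyme_id,
                       assay_label = preds$predicted)
  expect_equal(concordance_report(preds, calls2)$fraction, 1)
  expect_error(concordance_report(preds,
                                  data.frame(enzyme_id = "zz",
                                             assay_label = "inactive")),
               "shared")
})

test_that("the rendered preference table carries the category symbols", {
  call <- call_assay_preference(data.frame(
    enzyme_id = "PfuSAHH",
    substrate = c("SAH", "SAH", "SIH", "SIH"),
    direction = rep(c("cleavage", "synthesis"), 2),
    category = c("+", "++", "++", "+++")))
  lines <- render_preference_table(list(call))
  expect_match(lines[2], "\\+/\\+\\+")
  expect_match(lines[2], "SIH-preferring")
})
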