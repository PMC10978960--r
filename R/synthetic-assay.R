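#' Generate a synthetic HPLC peak table with known true conversion
#'
#' Builds a peak table whose noise-free [score_conversion()] equals the
#' requested true conversion exactly: the substrate pool is split into
#' unconverted substrate (100 - c), main product (0.75 c) and the
#' nucleobase side product (0.25 c), in response-corrected units; written
#' areas are divided by the analyte response factors. Multiplicative
#' Gaussian noise of relative sd `noise_sd_pct` percent is then applied
#' per peak. Deterministic under `seed`.
#'
#' @param true_conversion_pct true conversion in [0, 100].
#' @param substrate `"SAH"` or `"SIH"` (cleavage) / `"adenosine"`,
#'   `"inosine"` (synthesis).
#' @param direction `"cleavage"` or `"synthesis"`.
#' @param response_factors named numeric vector of per-analyte response
#'   factors (default all 1).
#' @param noise_sd_pct relative noise sd in percent (>= 0).
#' @param enzyme_id assay identifier.
#' @param seed RNG seed.
#' @param path optional CSV path; a ground-truth JSON sidecar is written
#'   next to it.
#' @return list with `peaks` (a `peak_table`) and `truth`.
#' @export
make_peak_table <- function(true_conversion_pct, substrate = "SAH",
                            direction = "cleavage",
                            response_factors = NULL, noise_sd_pct = 0,
                            enzyme_id = "toy_enzyme", seed = 1,
                            path = NULL) {
  stopifnot(true_conversion_pct >= 0, true_conversion_pct <= 100)
  if (noise_sd_pct < 0) stop("noise sd must be non-negative")
  roles <- default_analyte_roles(substrate, direction)
  analytes <- c(roles$substrate, roles$products, roles$side_products)
  rf <- stats::setNames(rep(1, length(analytes)), analytes)
  if (!is.null(response_factors))
    rf[names(response_factors)] <- response_factors
  c0 <- true_conversion_pct
  molar <- c(100 - c0, 0.75 * c0, 0.25 * c0)
  areas <- molar / rf[analytes]
  set.seed(seed)
  if (noise_sd_pct > 0)
    areas <- pmax(0, areas * (1 + stats::rnorm(length(areas),
                                               sd = noise_sd_pct / 100)))
  peaks <- as_peak_table(data.frame(
    assay = enzyme_id, direction = direction, substrate = substrate,
    analyte = analytes,
    rt_min = seq(4, by = 2, length.out = length(analytes)),
    area = unname(areas),
    response_factor = unname(rf[analytes]),
    stringsAsFactors = FALSE))
  truth <- list(true_conversion_pct = true_conversion_pct,
                true_category = conversion_category(true_conversion_pct),
                substrate = substrate, direction = direction,
                noise_sd_pct = noise_sd_pct, seed = seed)
  if (!is.null(path)) {
    utils::write.csv(as.data.frame(peaks), path, row.names = FALSE)
    jsonlite::write_json(truth, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  list(peaks = peaks, truth = truth)
}
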