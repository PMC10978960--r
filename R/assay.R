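ANALYTE_VOCAB <- c("SAH", "SIH", "adenosine", "inosine", "adenine",
                   "hypoxanthine", "Hcy", "Hcy-disulfide", "Met")
CATEGORY_LEVELS <- c("-", "+", "++", "+++")

# Default analyte roles per substrate x direction. The nucleobase side
# product counts toward converted substrate in cleavage assays;
# Hcy-derived species are excluded from the denominator (not
# UV-comparable at the detection wavelength).
default_analyte_roles <- function(substrate, direction) {
  stopifnot(direction %in% c("cleavage", "synthesis"))
  if (direction == "cleavage") {
    switch(substrate,
           SAH = list(substrate = "SAH", products = "adenosine",
                      side_products = "adenine"),
           SIH = list(substrate = "SIH", products = "inosine",
                      side_products = "hypoxanthine"),
           stop("no default roles for cleavage of ", substrate))
  } else {
    switch(substrate,
           adenosine = list(substrate = "adenosine", products = "SAH",
                            side_products = "adenine"),
           inosine = list(substrate = "inosine", products = "SIH",
                          side_products = "hypoxanthine"),
           stop("no default roles for synthesis from ", substrate))
  }
}

#' Read an HPLC peak-area table
#'
#' Delimited text with a header and columns `assay`, `direction`,
#' `substrate`, `analyte`, `rt_min`, `area` and optionally
#' `response_factor`. Analyte names must come from the known vocabulary
#' (substrates, nucleosides, nucleobases, Hcy-derived species).
#'
#' @param path CSV or TSV file (separator auto-detected from the
#'   extension).
#' @return a `peak_table` data.frame.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("peak table not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  as_peak_table(tab)
}

#' Validate a data.frame as a peak table
#' @param tab data.frame with the peak-table columns.
#' @return the validated `peak_table`.
#' @export
as_peak_table <- function(tab) {
  need <- c("assay", "direction", "substrate", "analyte", "area")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("peak table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!"rt_min" %in% names(tab)) tab$rt_min <- NA_real_
  if (!"response_factor" %in% names(tab)) tab$response_factor <- 1
  tab$response_factor[is.na(tab$response_factor)] <- 1
  if (any(tab$area < 0)) stop("negative peak areas")
  bad <- setdiff(unique(tab$analyte), ANALYTE_VOCAB)
  if (length(bad)) stop("unknown analytes: ", paste(bad, collapse = ", "))
  if (!all(tab$direction %in% c("cleavage", "synthesis")))
    stop("direction must be cleavage or synthesis")
  class(tab) <- c("peak_table", class(tab))
  tab
}

#' Semi-quantitative conversion category from a percentage
#'
#' The published category scheme: high conversion (>70%) is `+++`, medium
#' (30-70%, closed on both ends) `++`, low (<30%) `+`, and conversion
#' below the noise floor is `-` (no conversion). Chromatographic
#' baselines are never exactly zero, so "no conversion" means below a
#' small noise floor rather than identically zero.
#'
#' @param conversion_pct numeric vector in [0, 100].
#' @param noise_floor percent below which conversion counts as none.
#' @return character vector of `+++`, `++`, `+`, `-`.
#' @export
conversion_category <- function(conversion_pct, noise_floor = 1) {
  stopifnot(all(conversion_pct >= 0 & conversion_pct <= 100))
  ifelse(conversion_pct < noise_floor, "-",
  ifelse(conversion_pct < 30, "+",
  ifelse(conversion_pct <= 70, "++", "+++")))
}

#' Score conversion from an HPLC peak table
#'
#' Peak areas are response-corrected (`area * response_factor`, default
#' factors 1 assuming equal molar absorptivity) and conversion is the
#' converted fraction of the substrate pool:
#' `100 * (products + side products) / (substrate + products + side
#' products)`. Side products (the free nucleobase) count as converted
#' substrate. The result is invariant to uniform rescaling of all areas.
#'
#' @param peaks a `peak_table` covering one assay (one enzyme, substrate
#'   and direction).
#' @param roles list with `substrate`, `products`, `side_products`
#'   analyte names; defaults derived from the table's substrate and
#'   direction.
#' @param noise_floor percent, see [conversion_category()].
#' @param enzyme_id optional enzyme identifier for the record.
#' @return a `conversion_record`: list with `enzyme_id`, `substrate`,
#'   `direction`, `conversion_pct`, `category`.
#' @export
score_conversion <- function(peaks, roles = NULL, noise_floor = 1,
                             enzyme_id = NULL) {
  peaks <- as_peak_table(as.data.frame(peaks))
  substrate <- unique(peaks$substrate)
  direction <- unique(peaks$direction)
  if (length(substrate) != 1L || length(direction) != 1L)
    stop("score_conversion expects a single assay ",
         "(one substrate and direction)")
  if (is.null(roles)) roles <- default_analyte_roles(substrate, direction)
  if (!roles$substrate %in% peaks$analyte)
    stop("substrate analyte ", roles$substrate, " absent from table")
  corrected <- peaks$area * peaks$response_factor
  s <- sum(corrected[peaks$analyte == roles$substrate])
  p <- sum(corrected[peaks$analyte %in% roles$products])
  sp <- sum(corrected[peaks$analyte %in% roles$side_products])
  total <- s + p + sp
  if (total <= 0) stop("all peak areas are zero; measurement error")
  conv <- 100 * (p + sp) / total
  structure(list(enzyme_id = if (is.null(enzyme_id))
    unique(peaks$assay)[1] else enzyme_id,
    substrate = substrate, direction = direction,
    conversion_pct = conv,
    category = conversion_category(conv, noise_floor)),
    class = "conversion_record")
}

#' @export
print.conversion_record <- function(x, ...) {
  cat(sprintf("<conversion_record> %s %s %s: %.1f%% (%s)\n",
              x$enzyme_id, x$substrate, x$direction, x$conversion_pct,
              x$category))
  invisible(x)
}

category_rank <- function(x) match(x, CATEGORY_LEVELS) - 1L

#' Call per-enzyme substrate preference from four assay records
#'
#' Takes the four conversion records of one enzyme (SAH and SIH, cleavage
#' and synthesis) and compares the category symbols ordinally
#' (`- < + < ++ < +++`). A substrate strictly greater in at least one
#' direction and not smaller in the other is preferred; if the other
#' substrate shows no conversion in either direction the call is upgraded
#' to SAH-only / SIH-only. All four at `-` is inactive; anything else is
#' both/no-preference.
#'
#' @param records list of four `conversion_record`s (or a data.frame with
#'   columns `substrate`, `direction`, `category` and optionally
#'   `enzyme_id`).
#' @return a `preference_call_assay`: list with `enzyme_id`, `label`,
#'   `categories` (named 2x2 character matrix).
#' @export
call_assay_preference <- function(records) {
  if (is.data.frame(records)) {
    df <- records
  } else {
    df <- do.call(rbind, lapply(records, function(r)
      data.frame(enzyme_id = r$enzyme_id, substrate = r$substrate,
                 direction = r$direction, category = r$category,
                 stringsAsFactors = FALSE)))
  }
  # map synthesis substrates (nucleosides) onto their thioether products
  df$compound <- ifelse(df$substrate %in% c("SAH", "adenosine"), "SAH",
                 ifelse(df$substrate %in% c("SIH", "inosine"), "SIH",
                        NA_character_))
  if (any(is.na(df$compound))) stop("unrecognised substrate in records")
  cats <- matrix(NA_character_, 2, 2,
                 dimnames = list(c("SAH", "SIH"),
                                 c("cleavage", "synthesis")))
  for (i in seq_len(nrow(df)))
    cats[df$compound[i], df$direction[i]] <- df$category[i]
  if (any(is.na(cats)))
    stop("records must cover SAH and SIH in both directions")
  sah <- category_rank(cats["SAH", ])
  sih <- category_rank(cats["SIH", ])
  label <- if (all(sah == 0) && all(sih == 0)) {
    "inactive"
  } else if (all(sih >= sah) && any(sih > sah)) {
    if (all(sah == 0)) "SIH-only" else "SIH-preferring"
  } else if (all(sah >= sih) && any(sah > sih)) {
    if (all(sih == 0)) "SAH-only" else "SAH-preferring"
  } else {
    "both/no-preference"
  }
  structure(list(enzyme_id = unique(df$enzyme_id)[1], label = label,
                 categories = cats),
            class = "preference_call_assay")
}

#' @export
print.preference_call_assay <- function(x, ...) {
  cat("<preference_call_assay> ", x$enzyme_id, ": ", x$label,
      "  [SAH ", x$categories["SAH", "cleavage"], "/",
      x$categories["SAH", "synthesis"], ", SIH ",
      x$categories["SIH", "cleavage"], "/",
      x$categories["SIH", "synthesis"], "]\n", sep = "")
  invisible(x)
}

#' Concordance between motif-based predictions and assay calls
#'
#' A motif prediction is concordant when an SIH-preferring prediction
#' meets an SIH-preferring/SIH-only assay call, or an SAH-preferring
#' prediction meets an SAH-preferring/SAH-only call. Enzymes with an
#' SAH-type motif but measurable SIH turnover keep a note: the molecular
#' basis of such residual SIH activity is not explained by the
#' fingerprint motif.
#'
#' @param predictions data.frame with columns `enzyme_id` and
#'   `predicted` (labels from [classify_motif()]).
#' @param assay_calls data.frame with columns `enzyme_id` and
#'   `assay_label` (labels from [call_assay_preference()]), optionally
#'   `sih_activity` (logical).
#' @return list with `table` (per-enzyme data.frame with `concordant` and
#'   `note`) and `fraction` (overall concordant fraction).
#' @export
concordance_report <- function(predictions, assay_calls) {
  merged <- merge(predictions, assay_calls, by = "enzyme_id")
  if (nrow(merged) == 0L) stop("no shared enzyme ids")
  conc <- (merged$predicted == "SIH-preferring" &
             merged$assay_label %in% c("SIH-preferring", "SIH-only")) |
    (merged$predicted == "SAH-preferring" &
       merged$assay_label %in% c("SAH-preferring", "SAH-only"))
  note <- rep("", nrow(merged))
  if ("sih_activity" %in% names(merged)) {
    res <- merged$predicted == "SAH-preferring" & merged$sih_activity
    note[res] <- "residual SIH activity not explained by the motif"
  }
  note[!conc] <- trimws(paste(note[!conc],
                              "prediction and assay call disagree"))
  merged$concordant <- conc
  merged$note <- note
  list(table = merged, fraction = mean(conc))
}

#' Render conversion categories as a study-style text table
#'
#' @param calls list of `preference_call_assay` objects.
#' @return character vector of formatted lines (printed table body).
#' @export
render_preference_table <- function(calls) {
  header <- sprintf("%-12s %-18s %-18s %s", "Enzyme",
                    "SAH Cleav/Synth", "SIH Cleav/Synth", "Preference")
  body <- vapply(calls, function(x) {
    sprintf("%-12s %-18s %-18s %s", x$enzyme_id,
            paste0(x$categories["SAH", "cleavage"], "/",
                   x$categories["SAH", "synthesis"]),
            paste0(x$categories["SIH", "cleavage"], "/",
                   x$categories["SIH", "synthesis"]),
            x$label)
  }, character(1))
  c(header, body)
}
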