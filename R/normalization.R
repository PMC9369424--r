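#' Percent maximum possible effect for threshold-type assays
#'
#' Normalizes a pre/post drug pair from an assay with an instrument ceiling
#' (e.g. the von Frey paw withdrawal threshold, whose stiffest filament is
#' 6.84 g) onto the percent-of-maximum-possible-effect (%MPE) scale:
#' `100 * (post - pre) / (cutoff - pre)`. A score of 100 means the post-drug
#' measurement reached the cut-off (complete reversal); 0 means no change;
#' negative scores indicate worsening and are retained by default.
#'
#' @param pre Pre-drug measurement, same units as `cutoff`. Must satisfy
#'   `0 <= pre < cutoff`: a baseline at or above the cut-off leaves no room
#'   for a drug effect and makes the normalization degenerate.
#' @param post Post-drug measurement, `0 <= post <= cutoff`.
#' @param cutoff Instrument ceiling (default 6.84 g, the stiffest von Frey
#'   filament).
#' @return Numeric vector of %MPE scores (at most 100; unbounded below).
#' @examples
#' mpe_threshold(pre = 0.4, post = 3.62) # 50
#' mpe_threshold(pre = 0.4, post = 6.84) # 100: post at cut-off
#' @seealso [mpe_reduction()], [mpe_bar()], [add_mpe()]
#' @export
mpe_threshold <- function(pre, post, cutoff = 6.84) {
  check_nonneg(pre, post)
  if (any(post > cutoff + 1e-9, na.rm = TRUE)) {
    stop("`post` above the cut-off (", cutoff, "): malformed record", call. = FALSE)
  }
  if (any(pre >= cutoff, na.rm = TRUE)) {
    stop("`pre` at or above the cut-off: degenerate baseline, %MPE undefined",
         call. = FALSE)
  }
  100 * (post - pre) / (cutoff - pre)
}

#' Percent maximum possible effect for reduction-type assays
#'
#' Normalizes counts or latencies where the drug effect is a *decrease* from
#' the pre-drug baseline (acetone-evoked response counts, rotarod latency):
#' `100 * (pre - post) / pre`. Full suppression of the response scores 100.
#'
#' @param pre Pre-drug measurement; must be strictly positive (a zero
#'   baseline leaves the normalization undefined and the record should be
#'   flagged, not coerced).
#' @param post Post-drug measurement, `post >= 0`.
#' @return Numeric vector of %MPE scores (at most 100 when `post >= 0`).
#' @examples
#' mpe_reduction(pre = 8, post = 6) # 25
#' mpe_reduction(pre = 8, post = 0) # 100: full suppression
#' @export
mpe_reduction <- function(pre, post) {
  check_nonneg(pre, post)
  if (any(pre == 0, na.rm = TRUE)) {
    stop("`pre` is zero: %MPE undefined for this record", call. = FALSE)
  }
  100 * (pre - post) / pre
}

#' Percent maximum possible effect for the bar (catalepsy) test
#'
#' The bar test measures an *increase* in immobility latency, normalized
#' against the fixed cut-off rather than the (near-zero) baseline:
#' `100 * (post - pre) / cutoff` with a 120 s cut-off.
#'
#' @param pre,post Latencies in seconds, both within `[0, cutoff]`.
#' @param cutoff Test cut-off in seconds (default 120).
#' @return Numeric vector of %MPE scores.
#' @examples
#' mpe_bar(pre = 2, post = 62) # 50
#' @export
mpe_bar <- function(pre, post, cutoff = 120) {
  check_nonneg(pre, post)
  if (any(pre > cutoff | post > cutoff, na.rm = TRUE)) {
    stop("latency above the ", cutoff, " s cut-off: malformed record",
         call. = FALSE)
  }
  100 * (post - pre) / cutoff
}

check_nonneg <- function(pre, post) {
  if (any(pre < 0, na.rm = TRUE) || any(post < 0, na.rm = TRUE)) {
    stop("negative measurement: malformed record", call. = FALSE)
  }
  invisible(TRUE)
}

#' Invert a %MPE score back to a raw post-drug measurement
#'
#' The inverse of the per-assay normalizations, used by the synthetic-data
#' generator to turn latent drug effects into raw assay units. On valid
#' ranges `mpe_invert()` composed with the matching forward map is the
#' identity.
#'
#' @param assay One of `"mechanical_pwt"`, `"acetone"`, `"rotarod"`, `"bar"`.
#' @param pre Pre-drug baseline in raw units.
#' @param mpe %MPE score to invert.
#' @return Post-drug value in raw assay units (not clipped to assay bounds).
#' @export
mpe_invert <- function(assay, pre, mpe) {
  switch(assay,
    mechanical_pwt = pre + mpe / 100 * (6.84 - pre),
    acetone = ,
    rotarod = pre * (1 - mpe / 100),
    bar = pre + mpe / 100 * 120,
    stop("no %MPE normalization defined for assay '", assay, "'", call. = FALSE)
  )
}

# assays carried through raw, with no %MPE map
RAW_ASSAYS <- "open_field"

ASSAYS <- c("mechanical_pwt", "acetone", "rotarod", "bar", "open_field")

#' Append %MPE scores to a table of behavioral records
#'
#' Applies the assay-appropriate normalization row-wise: threshold form for
#' `mechanical_pwt` (cut-off 6.84 g), reduction form for `acetone` and
#' `rotarod`, cut-off form for `bar` (120 s). Open-field crossings have no
#' %MPE definition and get `NA` (the raw counts are analyzed directly).
#' When an animal has repeated measurements at the same timepoint they are
#' averaged on the raw scale *before* normalization (the maps are affine in
#' `post` at fixed `pre`, so for repeats sharing a baseline this equals
#' averaging the scores).
#'
#' @param records A data frame with at least `assay`, `pre_drug`, `post_drug`
#'   columns; typically the full record table read by
#'   [read_behavior_records()] or produced by [simulate_cci_study()].
#' @param clip_negative If `TRUE`, negative %MPE scores (worsening relative
#'   to baseline) are clipped to 0. Off by default: signed scores preserve
#'   information and let near-zero group means average out.
#' @return The input as a tibble with an `mpe` column appended.
#' @examples
#' recs <- tibble::tibble(
#'   assay = c("mechanical_pwt", "acetone"),
#'   pre_drug = c(0.4, 8), post_drug = c(3.62, 2)
#' )
#' add_mpe(recs)
#' @export
add_mpe <- function(records, clip_negative = FALSE) {
  stopifnot(all(c("assay", "pre_drug", "post_drug") %in% names(records)))
  bad <- setdiff(unique(records$assay), ASSAYS)
  if (length(bad)) {
    stop("unknown assay(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  records <- dplyr::as_tibble(records)
  # average raw repeats within animal x assay x timepoint, if identifiable
  key <- intersect(c("animal_id", "group", "drug_a_dose_nmol",
                     "drug_b_dose_nmol", "assay", "timepoint_h"),
                   names(records))
  if (all(c("animal_id", "assay") %in% key)) {
    records <- records |>
      dplyr::summarise(
        pre_drug = mean(.data$pre_drug),
        post_drug = mean(.data$post_drug),
        .by = dplyr::all_of(key)
      )
  }
  mpe <- rep(NA_real_, nrow(records))
  for (a in setdiff(unique(records$assay), RAW_ASSAYS)) {
    i <- records$assay == a
    f <- switch(a,
                mechanical_pwt = mpe_threshold,
                acetone = ,
                rotarod = mpe_reduction,
                bar = mpe_bar)
    mpe[i] <- f(records$pre_drug[i], records$post_drug[i])
  }
  out <- dplyr::mutate(records, mpe = mpe)
  if (clip_negative) out <- dplyr::mutate(out, mpe = pmax(.data$mpe, 0))
  out
}

#' Collapse normalized records to per-animal dose-response observations
#'
#' Filters one assay (and optionally one treatment group), averages the %MPE
#' score across the post-drug timepoints for each animal, and returns the
#' `(dose, effect)` table that [fit_hill()] consumes. The total dose is the
#' sum of the two drug-dose columns, so single-drug groups and fixed-ratio
#' combination rays are handled uniformly.
#'
#' @param records Output of [add_mpe()] (or raw records; normalization is
#'   applied if the `mpe` column is absent).
#' @param assay Assay to extract.
#' @param group Optional treatment-group label to filter on.
#' @param timepoints Post-drug timepoints (h) to average over. The default
#'   pools the 1 h and 2 h scores, the window where the drug effect peaks.
#' @return A tibble with `animal_id`, `group`, `dose` (nmol total) and
#'   `effect` (%MPE), one row per animal.
#' @export
mpe_dose_response <- function(records, assay, group = NULL,
                              timepoints = c(1, 2)) {
  if (!"mpe" %in% names(records)) records <- add_mpe(records)
  stopifnot(all(c("animal_id", "timepoint_h") %in% names(records)))
  out <- records |>
    dplyr::filter(.data$assay == !!assay,
                  .data$timepoint_h %in% timepoints)
  if (!is.null(group)) out <- dplyr::filter(out, .data$group == !!group)
  if (nrow(out) == 0L) {
    stop("no records for assay '", assay, "'",
         if (!is.null(group)) paste0(" in group '", group, "'"), call. = FALSE)
  }
  out |>
    dplyr::summarise(
      dose = sum(.data$drug_a_dose_nmol[1], .data$drug_b_dose_nmol[1]),
      effect = mean(.data$mpe),
      .by = dplyr::all_of(c("animal_id", "group"))
    ) |>
    dplyr::select("animal_id", "group", "dose", "effect")
}

RECORD_COLS <- c("animal_id", "group", "drug_a_dose_nmol", "drug_b_dose_nmol",
                 "assay", "timepoint_h", "pre_drug", "post_drug")

#' Read and write per-animal behavioral record tables
#'
#' The on-disk format is a plain CSV with header columns `animal_id`,
#' `group`, `drug_a_dose_nmol`, `drug_b_dose_nmol`, `assay`, `timepoint_h`,
#' `pre_drug`, `post_drug`; missing values are empty fields. The writer
#' accepts tables with extra columns (e.g. an appended `mpe` column) and
#' preserves them.
#'
#' @param path File path.
#' @return `read_behavior_records()` returns a tibble; the writer returns
#'   `records` invisibly.
#' @export
read_behavior_records <- function(path) {
  recs <- readr::read_csv(
    path,
    col_types = readr::cols(
      animal_id = readr::col_character(),
      group = readr::col_character(),
      assay = readr::col_character(),
      .default = readr::col_double()
    ),
    na = c("", "NA")
  )
  missing <- setdiff(RECORD_COLS, names(recs))
  if (length(missing)) {
    stop("record file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  recs
}

#' @rdname read_behavior_records
#' @param records Record table to write.
#' @export
write_behavior_records <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(records)
}
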