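#' Fit single-drug dose-response curves across assays
#'
#' Orchestrates the single-agent stage: normalizes the records, extracts the
#' per-animal dose-response observations for each drug x assay pair, screens
#' for dose dependence, and fits the Hill curve where there is a signal.
#' Assays without dose dependence (the side-effect battery, typically) are
#' reported as skipped rather than force-fitted; fit failures are reported
#' per item and the run continues.
#'
#' The dose-dependence screen requires either a significant positive
#' log-dose trend (`lm(effect ~ log10(dose))`, p < 0.05) or a mean effect at
#' some dose of at least `min_effect` %MPE.
#'
#' @param records Behavioral record table (raw or already normalized).
#' @param drugs Treatment-group labels to fit.
#' @param assays Assays to analyze; defaults to every %MPE assay present.
#' @param timepoints Timepoints pooled per animal (see
#'   [mpe_dose_response()]).
#' @param min_effect Dose-dependence screen threshold (%MPE).
#' @return A tibble with one row per drug x assay: `drug`, `assay`,
#'   `status` (`"fitted"`, `"skipped"` or `"error"`), `note`, and a `fit`
#'   list-column of `hill_fit` objects (NULL where not fitted).
#' @export
run_single_drug <- function(records, drugs = c("THC", "CBD"), assays = NULL,
                            timepoints = c(1, 2), min_effect = 20) {
  records <- add_mpe(records)
  assays <- assays %||%
    intersect(unique(records$assay), setdiff(ASSAYS, RAW_ASSAYS))
  combos <- tidyr::expand_grid(drug = drugs, assay = assays)
  res <- purrr::pmap(combos, function(drug, assay) {
    d <- tryCatch(
      mpe_dose_response(records, assay, group = drug, timepoints = timepoints),
      error = function(e) e
    )
    if (inherits(d, "error")) {
      return(list(status = "error", note = conditionMessage(d), fit = NULL))
    }
    if (!dose_dependent(d, min_effect)) {
      return(list(status = "skipped", note = "no dose dependence", fit = NULL))
    }
    fit <- tryCatch(fit_hill(d, drug = drug, assay = assay),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      list(status = "error", note = conditionMessage(fit), fit = NULL)
    } else {
      list(status = "fitted", note = NA_character_, fit = fit)
    }
  })
  combos |>
    dplyr::mutate(
      status = purrr::map_chr(res, "status"),
      note = purrr::map_chr(res, ~ .x$note %||% NA_character_),
      fit = purrr::map(res, "fit")
    )
}

dose_dependent <- function(d, min_effect) {
  means <- d |> dplyr::summarise(m = mean(.data$effect), .by = "dose")
  if (max(means$m) >= min_effect) return(TRUE)
  if (dplyr::n_distinct(d$dose) < 2) return(FALSE)
  sl <- stats::summary.lm(stats::lm(effect ~ log10(dose), data = d))$coefficients
  nrow(sl) > 1 && sl[2, 1] > 0 && sl[2, 4] < 0.05
}

#' Full combination analysis for one assay
#'
#' Runs the complete isobolographic workflow for a single assay: fits the
#' two single-drug curves, builds the dose-equivalence additive surface
#' (roles assigned by maximal effect), fits the experimental combination
#' curve along the fixed-ratio ray, computes the predicted-additive ED50
#' with its delta-method standard error, the non-linear additivity isoboles
#' at the requested effect levels plus the linear reference isobole, and the
#' synergy t-test of experimental against predicted ED50.
#'
#' @param records Behavioral record table containing both single-drug arms
#'   and the combination ray.
#' @param assay Assay to analyze.
#' @param drugs The two single-drug group labels (drug A is taken as the
#'   first for ray bookkeeping; surface roles are still assigned by Emax).
#' @param combination Combination group label.
#' @param frac Fixed-ratio fractions of total dose, aligned with `drugs`.
#' @param levels Effect levels (%MPE) for the non-linear isobole family.
#' @param alpha Significance level of the synergy verdict.
#' @param timepoints Timepoints pooled per animal.
#' @param dof_method `"welch"` or `"z"`, see [compare_ed50s()].
#' @return A `combination_analysis` list: `fits` (named single-drug
#'   `hill_fit`s), `experimental` (combination `hill_fit` on total dose),
#'   `surface`, `predicted` ([predicted_ed50()]), `isoboles` (tibble),
#'   `synergy` ([compare_ed50s()] report), `assay`.
#' @examples
#' recs <- simulate_cci_study(cci_config(seed = 7, assays = "mechanical_pwt",
#'                                       interaction_shift = 0.6))
#' res <- run_combination(recs, "mechanical_pwt")
#' tidy(res$synergy)
#' @export
run_combination <- function(records, assay, drugs = c("CBD", "THC"),
                            combination = "THC:CBD", frac = c(0.5, 0.5),
                            levels = c(20, 30, 40, 50), alpha = 0.05,
                            timepoints = c(1, 2),
                            dof_method = c("welch", "z")) {
  dof_method <- match.arg(dof_method)
  records <- add_mpe(records)
  fits <- purrr::map(
    stats::setNames(drugs, drugs),
    ~ fit_hill(mpe_dose_response(records, assay, group = .x,
                                 timepoints = timepoints),
               drug = .x, assay = assay)
  )
  comb_data <- tryCatch(
    mpe_dose_response(records, assay, group = combination,
                      timepoints = timepoints),
    error = function(e) {
      stop("no combination-ray records for assay '", assay,
           "' (group '", combination, "'): supply combination data or ",
           "generate it with simulate_cci_study()", call. = FALSE)
    }
  )
  experimental <- fit_hill(comb_data, drug = combination, assay = assay)
  surface <- additive_surface(fits[[1]], fits[[2]], frac = frac)
  predicted <- predicted_ed50(surface)
  reachable <- levels[levels < surface$params_b$emax]
  isoboles <- isobole_family(surface, levels = reachable)
  synergy <- compare_ed50s(experimental, predicted, alpha = alpha,
                           method = dof_method, assay = assay)
  structure(
    list(assay = assay, fits = fits, experimental = experimental,
         surface = surface, predicted = predicted, isoboles = isoboles,
         synergy = synergy),
    class = "combination_analysis"
  )
}

#' @export
print.combination_analysis <- function(x, ...) {
  cat("== Combination analysis:", x$assay, "==\n")
  cat(sprintf("  roles: A = %s, B = %s (assigned by maximal effect)\n",
              x$surface$params_a$drug, x$surface$params_b$drug))
  for (f in x$fits) {
    cat(sprintf("  %s: Emax %.3g, ED50 %.3g (se %.3g), Hill %.3g\n",
                f$drug, f$emax, f$ed50, f$se["ed50"], f$hill))
  }
  cat(sprintf("  experimental combination ED50: %.3g (se %.3g) nmol total\n",
              x$experimental$ed50, x$experimental$se["ed50"]))
  print(x$predicted)
  print(x$synergy)
  invisible(x)
}

#' Table-style summary of a combination analysis
#'
#' @param x A `combination_analysis` from [run_combination()].
#' @param ... Unused.
#' @return A one-row tibble mirroring a potency-table layout: single-drug
#'   ED50/Hill/Emax, experimental and predicted combination ED50s with
#'   standard errors, and the synergy test results.
#' @exportS3Method generics::tidy
#' @export
tidy.combination_analysis <- function(x, ...) {
  sd_cols <- purrr::imap(x$fits, function(f, nm) {
    out <- tibble::tibble(f$ed50, f$se[["ed50"]], f$hill, f$emax)
    names(out) <- paste0(tolower(nm), c("_ed50", "_ed50_se", "_hill", "_emax"))
    out
  })
  dplyr::bind_cols(
    tibble::tibble(assay = x$assay),
    !!!unname(sd_cols),
    tidy(x$synergy)[-1]
  )
}

#' Write the combination-analysis bundle to files
#'
#' Emits `fits.json` (single-drug and experimental fits), `combination.json`
#' (predicted vs experimental ED50s and the synergy test) and
#' `isoboles.csv` into a directory.
#'
#' @param x A `combination_analysis`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_combination_bundle <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fits <- c(x$fits, list(experimental = x$experimental))
  jsonlite::write_json(
    purrr::map(fits, ~ list(drug = .x$drug, assay = .x$assay, emax = .x$emax,
                            ed50 = .x$ed50, hill = .x$hill,
                            se_ed50 = unname(.x$se["ed50"]), dof = .x$dof)),
    file.path(dir, "fits.json"), auto_unbox = TRUE, digits = NA
  )
  report <- list(
    assay = x$assay,
    ratio = c(x$surface$frac_a, x$surface$frac_b),
    predicted_ed50 = x$predicted$ed50,
    predicted_se = x$predicted$se,
    experimental_ed50 = x$experimental$ed50,
    experimental_se = unname(x$experimental$se["ed50"]),
    effect_level = x$predicted$effect_level,
    t_stat = x$synergy$t_stat,
    p_value = x$synergy$p_value,
    verdict = x$synergy$verdict
  )
  jsonlite::write_json(report, file.path(dir, "combination.json"),
                       auto_unbox = TRUE, digits = NA)
  write_isobole_csv(x$isoboles, file.path(dir, "isoboles.csv"))
  invisible(dir)
}
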