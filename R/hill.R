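#' Evaluate the three-parameter Hill dose-response function
#'
#' `Effect(dose) = emax / (1 + 10^(hill * (log10(ed50) - log10(dose))))`,
#' the sigmoid used throughout the package: lower asymptote fixed at 0 %MPE,
#' half-maximal effect at `ed50`, steepness `hill`. The `dose = 0` limit is
#' 0 by continuity, not a log-domain error.
#'
#' @param dose Dose(s) in nmol, `>= 0`.
#' @param emax Maximal effect (%MPE), `> 0`.
#' @param ed50 Half-maximally effective dose (nmol), `> 0`.
#' @param hill Hill slope, `> 0`.
#' @return Effect(s) on the %MPE scale, in `[0, emax)`.
#' @examples
#' hill_effect(14, emax = 85, ed50 = 14, hill = 2.6) # 42.5, half-max at ED50
#' @export
hill_effect <- function(dose, emax, ed50, hill) {
  stopifnot(all(dose >= 0), emax > 0, ed50 > 0, hill > 0)
  out <- emax / (1 + 10^(hill * (log10(ed50) - log10(dose))))
  out[dose == 0] <- 0
  out
}

#' Invert the Hill function: dose producing a given effect
#'
#' @param effect Target effect (%MPE), strictly between 0 and `emax`; the
#'   maximal effect is only approached asymptotically, so `effect >= emax`
#'   is an unreachable level and signals an error.
#' @inheritParams hill_effect
#' @return Dose (nmol) with `hill_effect(dose, ...) == effect`.
#' @examples
#' inverse_hill(42.5, emax = 85, ed50 = 14, hill = 2.6) # 14
#' @export
inverse_hill <- function(effect, emax, ed50, hill) {
  stopifnot(emax > 0, ed50 > 0, hill > 0)
  if (any(effect <= 0) || any(effect >= emax)) {
    stop("effect level must lie strictly between 0 and emax = ", emax,
         " (unreachable level)", call. = FALSE)
  }
  ed50 * 10^(log10(effect / (emax - effect)) / hill)
}

#' Bundle Hill parameters (with optional uncertainties) into one object
#'
#' Constructs the parameter container shared by fitted curves and curves
#' specified directly from published estimates (e.g. a potency table giving
#' ED50, Hill slope and Emax with standard errors). [fit_hill()] returns a
#' subclass of this object, so anything accepting `hill_params` also accepts
#' a fit.
#'
#' @param emax,ed50,hill Parameter values (see [hill_effect()]).
#' @param se Optional named numeric of standard errors
#'   (`c(emax = , ed50 = , hill = )`). Used to build a diagonal covariance
#'   when `cov` is not supplied.
#' @param cov Optional 3x3 parameter covariance matrix, rows/cols ordered
#'   `(emax, ed50, hill)`, on the linear ED50 scale.
#' @param dof Residual degrees of freedom behind the estimates (`Inf` when
#'   unknown; a z approximation is then used downstream).
#' @param n_animals Number of animals behind the estimates, if known.
#' @param drug,assay Optional labels carried into reports.
#' @return An object of class `hill_params`.
#' @examples
#' thc <- hill_params(emax = 85, ed50 = 14, hill = 2.6,
#'                    se = c(emax = 2, ed50 = 0.8, hill = 0.3), drug = "THC")
#' @export
hill_params <- function(emax, ed50, hill, se = NULL, cov = NULL, dof = Inf,
                        n_animals = NA_integer_, drug = NULL, assay = NULL) {
  stopifnot(emax > 0, ed50 > 0, hill > 0)
  pnames <- c("emax", "ed50", "hill")
  if (is.null(cov)) {
    if (is.null(se)) se <- c(emax = 0, ed50 = 0, hill = 0)
    stopifnot(all(pnames %in% names(se)))
    cov <- diag(unname(se[pnames])^2, 3)
    dimnames(cov) <- list(pnames, pnames)
  } else {
    stopifnot(is.matrix(cov), all(dim(cov) == 3))
    dimnames(cov) <- list(pnames, pnames)
    if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov)))) {
      stop("parameter covariance must be symmetric", call. = FALSE)
    }
    if (min(eigen(cov, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("parameter covariance must be positive semi-definite", call. = FALSE)
    }
  }
  se <- sqrt(pmax(diag(cov), 0))
  structure(
    list(emax = emax, ed50 = ed50, hill = hill,
         se = stats::setNames(se, pnames), cov = cov, dof = dof,
         n_animals = n_animals, drug = drug, assay = assay),
    class = "hill_params"
  )
}

#' @export
print.hill_params <- function(x, ...) {
  lbl <- paste(c(x$drug, x$assay), collapse = " / ")
  cat("Hill dose-response parameters", if (nzchar(lbl)) paste0(" (", lbl, ")"),
      "\n", sep = "")
  cat(sprintf("  Emax  %7.3g %%MPE (se %.3g)\n", x$emax, x$se["emax"]))
  cat(sprintf("  ED50  %7.3g nmol (se %.3g)\n", x$ed50, x$se["ed50"]))
  cat(sprintf("  Hill  %7.3g      (se %.3g)\n", x$hill, x$se["hill"]))
  if (is.finite(x$dof)) cat("  residual dof:", x$dof, "\n")
  invisible(x)
}

#' @export
predict.hill_params <- function(object, dose, ...) {
  hill_effect(dose, object$emax, object$ed50, object$hill)
}

#' Fit the Hill dose-response curve by non-linear least squares
#'
#' Fits `(emax, ed50, hill)` to per-animal `(dose, effect)` observations by
#' Levenberg-Marquardt least squares ([minpack.lm::nlsLM()]). The ED50 is
#' parameterized as `log10(ed50)` internally — the curve is much closer to
#' linear in log-dose, which stabilizes the optimization — and reported on
#' the linear scale, with the covariance delta-transformed to match. The
#' lower asymptote is fixed at 0 %MPE.
#'
#' Individual animals' scores (not dose-group means) are the observations,
#' so the residual degrees of freedom and the standard errors reflect the
#' per-animal replication.
#'
#' @param data Data frame with `dose` (nmol, `> 0`) and `effect` (%MPE)
#'   columns, e.g. from [mpe_dose_response()]; at least 4 distinct doses are
#'   required for the 3-parameter fit.
#' @param init Optional starting values as a named list/vector with `emax`,
#'   `ed50`, `hill`. The default heuristic uses the maximum observed effect,
#'   the dose whose mean effect is nearest half of that, and a unit slope.
#' @param lower,upper Box bounds keeping the optimizer in the
#'   pharmacologically meaningful region: `emax` in (0, 120] %MPE, `ed50` in
#'   [0.1, 1000] nmol, `hill` in (0.1, 10].
#' @param drug,assay Optional labels carried into the result.
#' @return A `hill_fit` object (subclass of [hill_params()]) additionally
#'   holding the data, the `nls` fit, `n_obs`, residual `dof` and the
#'   residual standard deviation `sigma`.
#' @examples
#' d <- tibble::tibble(dose = rep(c(1, 3, 10, 30, 100), each = 2))
#' d$effect <- hill_effect(d$dose, 85, 14, 2.6)
#' fit_hill(d)
#' @export
fit_hill <- function(data, init = NULL,
                     lower = c(emax = 1e-3, ed50 = 0.1, hill = 0.1),
                     upper = c(emax = 120, ed50 = 1000, hill = 10),
                     drug = NULL, assay = NULL) {
  stopifnot(all(c("dose", "effect") %in% names(data)))
  data <- dplyr::as_tibble(data)[stats::complete.cases(data[c("dose", "effect")]), ]
  if (any(data$dose <= 0)) {
    stop("doses must be strictly positive for curve fitting", call. = FALSE)
  }
  if (dplyr::n_distinct(data$dose) < 4) {
    stop("at least 4 distinct doses are required for a 3-parameter fit",
         call. = FALSE)
  }
  if (diff(range(data$effect)) < 1e-8 || max(data$effect) <= 0) {
    stop("unidentifiable fit: no dose dependence in the effects", call. = FALSE)
  }
  if (is.null(init)) {
    emax0 <- min(max(data$effect), upper["emax"])
    means <- data |>
      dplyr::summarise(m = mean(.data$effect), .by = "dose")
    ed500 <- means$dose[which.min(abs(means$m - emax0 / 2))]
    init <- c(emax = emax0, ed50 = ed500, hill = 1)
  }
  init <- unlist(init)[c("emax", "ed50", "hill")]
  start <- list(emax = clamp(init["emax"], lower["emax"], upper["emax"]),
                led50 = log10(clamp(init["ed50"], lower["ed50"], upper["ed50"])),
                hill = clamp(init["hill"], lower["hill"], upper["hill"]))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      effect ~ emax / (1 + 10^(hill * (led50 - log10(dose)))),
      data = data, start = start,
      lower = c(lower["emax"], log10(lower["ed50"]), lower["hill"]),
      upper = c(upper["emax"], log10(upper["ed50"]), upper["hill"]),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) {
      stop("unidentifiable fit: ", conditionMessage(e), call. = FALSE)
    }
  )
  est <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(vc)) || any(diag(vc) < 0)) {
    stop("unidentifiable fit: rank-deficient Jacobian at the optimum",
         call. = FALSE)
  }
  ed50 <- 10^est[["led50"]]
  # delta-transform covariance from (emax, log10 ed50, hill) to linear ed50
  J <- diag(c(1, ed50 * log(10), 1))
  cov_lin <- J %*% vc %*% t(J)
  n_animals <- if ("animal_id" %in% names(data)) {
    dplyr::n_distinct(data$animal_id)
  } else {
    nrow(data)
  }
  out <- hill_params(
    emax = est[["emax"]], ed50 = ed50, hill = est[["hill"]],
    cov = cov_lin, dof = stats::df.residual(fit), n_animals = n_animals,
    drug = drug, assay = assay
  )
  out$data <- data
  out$fit <- fit
  out$n_obs <- nrow(data)
  out$sigma <- stats::sigma(fit)
  class(out) <- c("hill_fit", class(out))
  out
}

clamp <- function(x, lo, hi) pmin(pmax(unname(x), unname(lo)), unname(hi))

#' @export
print.hill_fit <- function(x, ...) {
  NextMethod()
  cat(sprintf("  n = %d observations (%s animals), residual SD %.3g %%MPE\n",
              x$n_obs, x$n_animals, x$sigma))
  invisible(x)
}

#' Tidy a Hill fit or parameter set into a term-level tibble
#'
#' @param x A `hill_params` or `hill_fit` object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`.
#' @exportS3Method generics::tidy
#' @export
tidy.hill_params <- function(x, ...) {
  tibble::tibble(
    term = c("emax", "ed50", "hill"),
    estimate = c(x$emax, x$ed50, x$hill),
    std.error = unname(x$se)
  )
}

#' One-row model summary of a Hill fit
#'
#' @param x A `hill_fit` object.
#' @param ... Unused.
#' @return A tibble with the fit labels, parameter estimates, residual SD,
#'   observation count and residual degrees of freedom.
#' @exportS3Method generics::glance
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(
    drug = x$drug %||% NA_character_,
    assay = x$assay %||% NA_character_,
    emax = x$emax, ed50 = x$ed50, hill = x$hill,
    sigma = x$sigma, nobs = x$n_obs, df.residual = x$dof
  )
}

#' Plot a fitted Hill curve over the observations
#'
#' @param object A `hill_fit`.
#' @param n Number of points on the curve.
#' @param ... Unused.
#' @return A ggplot: per-animal %MPE scores on a log-dose axis with the
#'   fitted sigmoid overlaid.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.hill_fit <- function(object, n = 200, ...) {
  rng <- range(object$data$dose)
  curve <- tibble::tibble(
    dose = 10^seq(log10(rng[1]), log10(rng[2]), length.out = n)
  )
  curve$effect <- predict(object, curve$dose)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dose, y = .data$effect)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve, colour = "#2166ac", linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Dose (nmol)", y = "Effect (%MPE)",
      title = paste(c(object$drug, object$assay), collapse = " / ")
    ) +
    ggplot2::theme_minimal()
}

#' Serialize a Hill fit to a JSON report
#'
#' @param x A `hill_params` or `hill_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(x, path) {
  report <- list(
    drug = x$drug, assay = x$assay,
    emax = x$emax, ed50 = x$ed50, hill = x$hill,
    se_emax = unname(x$se["emax"]), se_ed50 = unname(x$se["ed50"]),
    se_hill = unname(x$se["hill"]),
    cov = unclass(x$cov), n = x$n_animals, dof = x$dof
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}
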