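#' Build the Loewe dose-equivalence additive surface for two drugs
#'
#' Combines two single-drug Hill curves into the predicted-additive effect
#' surface for their combination, allowing different maximal effects and
#' Hill slopes. The construction follows the dose-equivalence principle:
#' a dose `a` of the weaker drug (A, the one with the lower maximum) is
#' converted into the dose of the stronger drug (B) producing the same
#' effect, added to the actual dose `b` of B, and pushed through B's Hill
#' curve.
#'
#' Roles are assigned automatically: drug B is the input with the larger
#' `emax` (ties broken by potency — the smaller ED50 becomes B). The
#' fixed-ratio fractions follow the drugs through any reordering.
#'
#' @param fit1,fit2 `hill_params`/`hill_fit` objects for the two drugs, in
#'   any order.
#' @param frac Length-2 numeric, the fixed-ratio fractions of total dose
#'   assigned to `fit1` and `fit2` respectively; must be positive and sum
#'   to 1. Default 1:1.
#' @param basis `"weight"` or `"mole"` — recorded for reporting. For drugs
#'   of equal molar mass (e.g. structural isomers) the two coincide.
#' @param k_form How the dose-equivalence factor `k` is oriented.
#'   `"dose-equivalence"` (default) uses
#'   `k = (E_B/E_A) * (1 + C_A^q / a^q) - 1`, the form implied by equating
#'   the two Hill effects, under which the B-equivalent dose `C_B / k^(1/p)`
#'   reproduces drug A's effect exactly. `"reciprocal"` uses the `E_A/E_B`
#'   orientation for comparison; it does not satisfy the dose-equivalence
#'   identity and can leave the half-maximal effect unreachable on the ray.
#' @return An `additive_surface` object with elements `params_a` (lower
#'   maximum), `params_b` (higher maximum), `frac_a`, `frac_b`, `basis`,
#'   `k_form`.
#' @examples
#' thc <- hill_params(85, 14, 2.6, drug = "THC")
#' cbd <- hill_params(79, 20, 1.5, drug = "CBD")
#' surf <- additive_surface(cbd, thc)
#' additive_effect(surf, a = 7, b = 7)
#' @export
additive_surface <- function(fit1, fit2, frac = c(0.5, 0.5),
                             basis = c("weight", "mole"),
                             k_form = c("dose-equivalence", "reciprocal")) {
  stopifnot(inherits(fit1, "hill_params"), inherits(fit2, "hill_params"),
            length(frac) == 2, all(frac > 0))
  if (abs(sum(frac) - 1) > 1e-9) {
    stop("fixed-ratio fractions must sum to 1", call. = FALSE)
  }
  basis <- match.arg(basis)
  k_form <- match.arg(k_form)
  b_first <- fit1$emax > fit2$emax ||
    (fit1$emax == fit2$emax && fit1$ed50 < fit2$ed50)
  if (b_first) {
    params_b <- fit1; params_a <- fit2
    frac_b <- frac[1]; frac_a <- frac[2]
  } else {
    params_b <- fit2; params_a <- fit1
    frac_b <- frac[2]; frac_a <- frac[1]
  }
  structure(
    list(params_a = params_a, params_b = params_b,
         frac_a = frac_a, frac_b = frac_b,
         basis = basis, k_form = k_form),
    class = "additive_surface"
  )
}

#' @export
print.additive_surface <- function(x, ...) {
  cat("Predicted-additive (dose-equivalence) surface\n")
  cat(sprintf("  drug A (lower max): %s  Emax %.3g, ED50 %.3g, Hill %.3g\n",
              x$params_a$drug %||% "?", x$params_a$emax, x$params_a$ed50,
              x$params_a$hill))
  cat(sprintf("  drug B (higher max): %s  Emax %.3g, ED50 %.3g, Hill %.3g\n",
              x$params_b$drug %||% "?", x$params_b$emax, x$params_b$ed50,
              x$params_b$hill))
  cat(sprintf("  fixed ratio A:B = %.3g:%.3g by %s\n",
              x$frac_a, x$frac_b, x$basis))
  invisible(x)
}

#' Dose-equivalence factor k
#'
#' The factor converting a dose of drug A into B-equivalents:
#' `k(a) = (E_B/E_A) * (1 + C_A^q / a^q) - 1` (default orientation), so that
#' drug A's effect at dose `a` equals `E_B / (1 + k)` and the B-equivalent
#' dose is `C_B / k^(1/p)`. As `a -> 0`, `k -> Inf` (no contribution); it is
#' bounded below by `E_B/E_A - 1 > 0` when `E_B > E_A`, so the equivalent
#' dose saturates: a finite amount of B exhausts what A can ever do.
#'
#' @param surface An [additive_surface()].
#' @param a Dose(s) of drug A (nmol), `>= 0`.
#' @return The dimensionless factor `k` (vectorized; `Inf` at `a = 0`).
#' @export
k_factor <- function(surface, a) {
  stopifnot(inherits(surface, "additive_surface"), all(a >= 0))
  pa <- surface$params_a
  pb <- surface$params_b
  ratio <- switch(surface$k_form,
    "dose-equivalence" = pb$emax / pa$emax,
    "reciprocal" = pa$emax / pb$emax
  )
  k <- ratio * (1 + (pa$ed50 / a)^pa$hill) - 1
  k[a == 0] <- Inf
  k
}

#' B-equivalent dose of a drug-A dose
#'
#' `C_B / k(a)^(1/p)`: the dose of drug B alone producing the same effect as
#' dose `a` of drug A. Satisfies
#' `hill_effect(b_equivalent(s, a), <params_b>) == hill_effect(a, <params_a>)`
#' for all `a > 0` under the default `k` orientation.
#'
#' @inheritParams k_factor
#' @return Equivalent dose(s) of drug B (nmol); 0 at `a = 0`.
#' @export
b_equivalent <- function(surface, a) {
  k <- k_factor(surface, a)
  beq <- surface$params_b$ed50 / k^(1 / surface$params_b$hill)
  beq[a == 0] <- 0
  beq
}

#' Predicted-additive effect of a dose pair
#'
#' Evaluates the dose-equivalence additive surface at doses `(a, b)`:
#' `E_B * (b + b_eq)^p / (C_B^p + (b + b_eq)^p)` with
#' `b_eq = b_equivalent(surface, a)`. Reduces exactly to drug B's Hill curve
#' at `a = 0` and to drug A's effect at `b = 0`; `(0, 0)` returns 0 by
#' convention.
#'
#' @inheritParams k_factor
#' @param b Dose(s) of drug B (nmol), `>= 0`.
#' @return Predicted-additive effect(s) (%MPE).
#' @export
additive_effect <- function(surface, a, b) {
  stopifnot(all(b >= 0))
  beq <- b_equivalent(surface, a)
  pb <- surface$params_b
  tot <- b + beq
  eff <- pb$emax * tot^pb$hill / (pb$ed50^pb$hill + tot^pb$hill)
  eff[tot == 0] <- 0
  eff
}

#' Predicted-additive ED50 on a fixed-ratio ray
#'
#' Restricts the additive surface to the ray `(a, b) = (frac_a * D,
#' frac_b * D)` and solves for the total dose `D` at which the predicted
#' effect reaches the target level — by default half the composite curve's
#' maximum, `E_B / 2`, the definition under which a sham combination (a drug
#' combined with itself) returns exactly the single-drug ED50. The root is
#' bracketed and refined to a relative tolerance of 1e-8.
#'
#' When both parameter sets carry covariance matrices (and `se = TRUE`), the
#' standard error of the predicted ED50 is propagated by the delta method:
#' the gradient of the root with respect to the six parameters
#' `(E_A, C_A, q, E_B, C_B, p)` is obtained by central differences
#' (re-solving the perturbed surface), and combined with the block-diagonal
#' covariance of the two independent fits.
#'
#' @inheritParams k_factor
#' @param level Target effect level (%MPE). Default `NULL` means
#'   `E_B / 2`, tracked symbolically so that the delta method also
#'   propagates uncertainty in `E_B` through the level itself.
#' @param se Compute the delta-method standard error?
#' @param se_step Relative step for the central-difference gradient.
#' @return A `predicted_ed50` object: `ed50` (nmol total dose), `se`,
#'   `effect_level` (%MPE), `dof` (sum of the two fits' residual dofs,
#'   `Inf` if either is unknown), `gradient`, and the generating surface.
#' @examples
#' thc <- hill_params(85, 14, 2.6, se = c(emax = 2, ed50 = 0.8, hill = 0.3))
#' cbd <- hill_params(79, 20, 1.5, se = c(emax = 2, ed50 = 0.6, hill = 0.1))
#' predicted_ed50(additive_surface(cbd, thc))
#' @export
predicted_ed50 <- function(surface, level = NULL, se = TRUE, se_step = 1e-5) {
  stopifnot(inherits(surface, "additive_surface"))
  half_max <- is.null(level)
  lev <- if (half_max) surface$params_b$emax / 2 else level
  ed50 <- solve_ray(surface, lev)
  grad <- se_val <- NULL
  if (se) {
    ds <- delta_se(surface, level = if (half_max) NULL else level,
                   step = se_step)
    se_val <- ds$se
    grad <- ds$gradient
  }
  structure(
    list(ed50 = ed50, se = se_val, effect_level = lev,
         dof = surface$params_a$dof + surface$params_b$dof,
         gradient = grad, surface = surface),
    class = "predicted_ed50"
  )
}

# root of additive_effect(frac_a * D, frac_b * D) = level on the ray
solve_ray <- function(surface, level) {
  if (level >= surface$params_b$emax) {
    stop("effect level ", level, " is at or above the composite maximum (",
         surface$params_b$emax, "): unreachable on the ray", call. = FALSE)
  }
  f <- function(D) {
    additive_effect(surface, surface$frac_a * D, surface$frac_b * D) - level
  }
  lo <- 1e-9
  hi <- 2 * max(surface$params_a$ed50, surface$params_b$ed50)
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e10) {
      stop("effect level unreachable on the ray: inconsistent surface",
           call. = FALSE)
    }
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12 * hi)$root
  stats::uniroot(f, c(root * (1 - 1e-6), root * (1 + 1e-6)),
                 tol = root * 1e-10, extendInt = "upX")$root
}

# delta-method SE of the ray ED50 w.r.t. the 6 Hill parameters
delta_se <- function(surface, level = NULL, step = 1e-5) {
  pa <- surface$params_a
  pb <- surface$params_b
  theta <- c(a_emax = pa$emax, a_ed50 = pa$ed50, a_hill = pa$hill,
             b_emax = pb$emax, b_ed50 = pb$ed50, b_hill = pb$hill)
  Sigma <- matrix(0, 6, 6)
  Sigma[1:3, 1:3] <- pa$cov
  Sigma[4:6, 4:6] <- pb$cov
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("non-positive-semi-definite parameter covariance: upstream fit failure",
         call. = FALSE)
  }
  solve_at <- function(th) {
    s <- surface
    s$params_a$emax <- th[1]; s$params_a$ed50 <- th[2]; s$params_a$hill <- th[3]
    s$params_b$emax <- th[4]; s$params_b$ed50 <- th[5]; s$params_b$hill <- th[6]
    lev <- if (is.null(level)) th[4] / 2 else level
    solve_ray(s, lev)
  }
  g <- vapply(seq_along(theta), function(i) {
    h <- step * max(abs(theta[i]), 1)
    up <- theta; up[i] <- up[i] + h
    dn <- theta; dn[i] <- dn[i] - h
    (solve_at(up) - solve_at(dn)) / (2 * h)
  }, numeric(1))
  names(g) <- names(theta)
  list(se = sqrt(max(drop(g %*% Sigma %*% g), 0)), gradient = g)
}

#' @export
print.predicted_ed50 <- function(x, ...) {
  cat(sprintf(
    "Predicted-additive ED50: %.4g nmol total dose%s at %.4g %%MPE\n",
    x$ed50,
    if (!is.null(x$se)) sprintf(" (se %.3g)", x$se) else "",
    x$effect_level
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @export
tidy.predicted_ed50 <- function(x, ...) {
  tibble::tibble(
    term = "predicted_ed50",
    estimate = x$ed50,
    std.error = x$se %||% NA_real_,
    effect_level = x$effect_level,
    df = x$dof
  )
}

#' Predicted-additive ray curve for plotting
#'
#' Evaluates the surface along its fixed-ratio ray over a grid of total
#' doses, giving the dotted "predicted additive" curve usually overlaid on
#' the experimental combination dose-response plot.
#'
#' @inheritParams k_factor
#' @param total_dose Grid of total doses (nmol).
#' @return A tibble with `total_dose` and `predicted_effect`.
#' @export
ray_curve <- function(surface, total_dose) {
  tibble::tibble(
    total_dose = total_dose,
    predicted_effect = additive_effect(surface,
                                       surface$frac_a * total_dose,
                                       surface$frac_b * total_dose)
  )
}

#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.additive_surface <- function(object, dose_range = NULL, n = 200, ...) {
  if (is.null(dose_range)) {
    dose_range <- c(0.5, 4) * range(object$params_a$ed50, object$params_b$ed50)
  }
  doses <- 10^seq(log10(dose_range[1]), log10(dose_range[2]), length.out = n)
  df <- dplyr::bind_rows(
    tibble::tibble(dose = doses,
                   effect = predict(object$params_a, doses),
                   curve = object$params_a$drug %||% "drug A"),
    tibble::tibble(dose = doses,
                   effect = predict(object$params_b, doses),
                   curve = object$params_b$drug %||% "drug B"),
    tibble::tibble(dose = doses,
                   effect = ray_curve(object, doses)$predicted_effect,
                   curve = "predicted additive")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$effect,
                                   colour = .data$curve,
                                   linetype = .data$curve)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Dose (nmol)", y = "Effect (%MPE)",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}
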