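#' Non-linear additivity isobole at a fixed effect level
#'
#' For each dose `a` of drug A, the additive dose `b` of drug B completing
#' the pair to the chosen effect level is `b = B_dose(level) -
#' b_equivalent(a)`, floored at 0, where `B_dose(level)` is the dose of drug
#' B alone producing that effect (the inverse Hill function of drug B). At
#' `a = 0` the isobole intercepts the B axis at `B_dose(level)`; at the 50%
#' level of B's maximum this is exactly B's ED50. The curve meets the A axis
#' exactly when drug A alone can produce the level (`level < ` A's maximum);
#' for levels above A's maximum the B-equivalent of drug A saturates below
#' `B_dose(level)` and the curve flattens to a strictly positive asymptote
#' instead — the signature geometry of additivity between drugs with
#' different maximal effects.
#'
#' Every returned point with `b > 0` closes the loop:
#' `additive_effect(surface, a, b)` returns the level to within 1e-6
#' relative tolerance.
#'
#' @inheritParams k_factor
#' @param level Effect level (%MPE, absolute units); must be below drug B's
#'   maximum.
#' @param a_grid Doses of drug A (nmol) at which to evaluate the isobole.
#' @return An `isobole` tibble with columns `a`, `b`, `level`, `kind`.
#' @examples
#' thc <- hill_params(85, 14, 2.6)
#' cbd <- hill_params(79, 20, 1.5)
#' nonlinear_isobole(additive_surface(cbd, thc), level = 50,
#'                   a_grid = seq(0, 60, by = 5))
#' @export
nonlinear_isobole <- function(surface, level, a_grid) {
  stopifnot(inherits(surface, "additive_surface"), all(a_grid >= 0),
            length(level) == 1, level > 0)
  pb <- surface$params_b
  if (level >= pb$emax) {
    stop("effect level ", level, " is unreachable (drug B maximum ",
         pb$emax, ")", call. = FALSE)
  }
  b_dose <- inverse_hill(level, pb$emax, pb$ed50, pb$hill)
  b <- pmax(b_dose - b_equivalent(surface, a_grid), 0)
  new_isobole(a = a_grid, b = b, level = level, kind = "nonlinear")
}

#' Linear 50%-effect isobole through the single-drug ED50s
#'
#' The classical straight-line isobole for the idealized case of two drugs
#' with equal 100% maxima and unit Hill slopes: `b = ed50_b * (1 -
#' a/ed50_a)`, floored at 0, intercepting the axes at the two individual
#' ED50s. Drawn as a reference against the non-linear isoboles.
#'
#' @param ed50_a,ed50_b Single-drug ED50s (nmol) of drugs A and B.
#' @param a_grid Doses of drug A (nmol).
#' @return An `isobole` tibble (`kind = "linear"`, `level = 50`).
#' @export
linear_isobole <- function(ed50_a, ed50_b, a_grid) {
  stopifnot(ed50_a > 0, ed50_b > 0, all(a_grid >= 0))
  b <- pmax(ed50_b * (1 - a_grid / ed50_a), 0)
  new_isobole(a = a_grid, b = b, level = 50, kind = "linear")
}

new_isobole <- function(a, b, level, kind) {
  out <- tibble::tibble(a = a, b = b, level = level, kind = kind)
  class(out) <- c("isobole", class(out))
  out
}

#' Classify a dose pair against an additivity isobole
#'
#' A combination whose `(a, b)` point lies below the additivity isobole
#' achieves the isobole's effect level with less drug than additivity
#' requires — supra-additivity (synergy). Above the curve is sub-additive;
#' on it (within tolerance) additive. The isobole's `b` value at the point's
#' `a`-coordinate is obtained by linear interpolation of the computed curve.
#'
#' @param isobole An [nonlinear_isobole()] / [linear_isobole()] result.
#' @param a,b The dose pair to classify (nmol).
#' @param tol Relative tolerance for calling the point "on" the curve.
#' @return `"supra-additive"`, `"additive"` or `"sub-additive"`.
#' @export
classify_point <- function(isobole, a, b, tol = 1e-6) {
  stopifnot(inherits(isobole, "isobole"), length(a) == 1, length(b) == 1,
            a >= 0, b >= 0)
  if (a < min(isobole$a) || a > max(isobole$a)) {
    stop("dose a = ", a, " lies outside the isobole's computed range [",
         min(isobole$a), ", ", max(isobole$a), "]: refusing to extrapolate",
         call. = FALSE)
  }
  b_curve <- stats::approx(isobole$a, isobole$b, xout = a)$y
  scale <- max(abs(b_curve), abs(b), 1)
  if (abs(b - b_curve) <= tol * scale) return("additive")
  if (b < b_curve) "supra-additive" else "sub-additive"
}

#' Isobole family for a surface, Figure-style panel data
#'
#' Computes the non-linear additivity isoboles at a family of effect levels
#' (default 20-50 %MPE in steps of 10) plus the linear reference isobole
#' through the single-drug ED50s, as one long tibble ready for plotting or
#' CSV export.
#'
#' @inheritParams k_factor
#' @param levels Effect levels (%MPE) for the non-linear family.
#' @param a_max Upper end of the drug-A dose grid; defaults to 3x drug A's
#'   ED50.
#' @param n Grid resolution.
#' @return A tibble of isobole points (`a`, `b`, `level`, `kind`).
#' @export
isobole_family <- function(surface, levels = c(20, 30, 40, 50),
                           a_max = NULL, n = 201) {
  a_max <- a_max %||% (3 * surface$params_a$ed50)
  a_grid <- seq(0, a_max, length.out = n)
  nonlin <- purrr::map(levels, ~ nonlinear_isobole(surface, .x, a_grid))
  lin <- linear_isobole(surface$params_a$ed50, surface$params_b$ed50, a_grid)
  dplyr::bind_rows(nonlin, lin)
}

#' Write an isobole (or family) to CSV
#'
#' Columns `a_nmol`, `b_nmol`, `level`, `kind`.
#'
#' @param isobole An isobole tibble or [isobole_family()] output.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_isobole_csv <- function(isobole, path) {
  isobole |>
    dplyr::rename(a_nmol = "a", b_nmol = "b") |>
    readr::write_csv(path)
  invisible(path)
}

#' Isobologram plot
#'
#' Plots an isobole family in the (dose A, dose B) plane, optionally with
#' experimental and predicted combination ED50 points split by the ray's
#' fixed ratio.
#'
#' @param isoboles Tibble of isobole points from [isobole_family()] (or a
#'   single isobole).
#' @param points Optional tibble of labelled dose pairs to overlay, with
#'   columns `a`, `b`, `label`.
#' @return A ggplot.
#' @export
plot_isobologram <- function(isoboles, points = NULL) {
  p <- ggplot2::ggplot(
    isoboles,
    ggplot2::aes(x = .data$a, y = .data$b,
                 group = interaction(.data$level, .data$kind),
                 colour = factor(.data$level),
                 linetype = .data$kind)
  ) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Dose of drug A (nmol)", y = "Dose of drug B (nmol)",
                  colour = "Effect level (%MPE)", linetype = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    p <- p +
      ggplot2::geom_point(
        data = points,
        ggplot2::aes(x = .data$a, y = .data$b, shape = .data$label),
        inherit.aes = FALSE, size = 2.5
      ) +
      ggplot2::labs(shape = NULL)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.isobole <- function(object, ...) plot_isobologram(object, ...)
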