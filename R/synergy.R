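#' Compare experimental and predicted-additive ED50s
#'
#' Unpaired t-test of the experimentally fitted combination ED50 against the
#' predicted-additive ED50 from the dose-equivalence surface:
#' `t = |pred - exp| / sqrt(se_exp^2 + se_pred^2)`, two-sided p-value. The
#' degrees of freedom are, by default, combined from the two estimates'
#' residual dofs by the Welch-Satterthwaite formula; `method = "z"` uses the
#' normal approximation instead (appropriate when the fit dofs are unknown).
#'
#' The verdict reads the direction: `synergistic` when the experimental ED50
#' is significantly *below* the predicted-additive one (the combination is
#' more potent than additivity predicts), `antagonistic` when significantly
#' above, `additive` otherwise. The potency ratio `pred/exp` quantifies the
#' shift (2 = twice as potent as predicted).
#'
#' @param exp Experimental combination estimate: a `hill_fit`/`hill_params`
#'   (its ED50, ED50 standard error and residual dof are used) or a list
#'   with `ed50`, `se`, `dof`.
#' @param pred Predicted-additive estimate: a [predicted_ed50()] object or a
#'   list with `ed50`, `se`, `dof`.
#' @param alpha Significance level for the verdict (default 0.05).
#' @param method `"welch"` (default) or `"z"`.
#' @param assay Optional label.
#' @return A `synergy_report` object (see [tidy.synergy_report()]).
#' @examples
#' compare_ed50s(exp = list(ed50 = 8.6, se = 0.7, dof = 45),
#'               pred = list(ed50 = 14, se = 1.6, dof = 90))
#' @export
compare_ed50s <- function(exp, pred, alpha = 0.05,
                          method = c("welch", "z"), assay = NULL) {
  method <- match.arg(method)
  e <- as_ed50_estimate(exp)
  p <- as_ed50_estimate(pred)
  stopifnot(e$ed50 > 0, p$ed50 > 0, e$se > 0, p$se > 0)
  if (method == "welch" && (e$dof < 1 || p$dof < 1)) {
    stop("residual dof below 1: malformed inputs for the Welch test",
         call. = FALSE)
  }
  se_diff <- sqrt(e$se^2 + p$se^2)
  t_stat <- abs(p$ed50 - e$ed50) / se_diff
  dof <- switch(method,
    welch = welch_satterthwaite(e$se, e$dof, p$se, p$dof),
    z = Inf
  )
  p_value <- 2 * stats::pt(-t_stat, df = dof)
  verdict <- if (p_value >= alpha) {
    "additive"
  } else if (e$ed50 < p$ed50) {
    "synergistic"
  } else {
    "antagonistic"
  }
  structure(
    list(assay = assay, exp_ed50 = e$ed50, exp_se = e$se,
         pred_ed50 = p$ed50, pred_se = p$se,
         t_stat = t_stat, dof = dof, p_value = p_value,
         alpha = alpha, method = method, verdict = verdict,
         potency_ratio = p$ed50 / e$ed50),
    class = "synergy_report"
  )
}

as_ed50_estimate <- function(x) {
  if (inherits(x, "predicted_ed50")) {
    list(ed50 = x$ed50, se = x$se, dof = x$dof)
  } else if (inherits(x, "hill_params")) {
    list(ed50 = x$ed50, se = unname(x$se["ed50"]), dof = x$dof)
  } else {
    stopifnot(all(c("ed50", "se") %in% names(x)))
    list(ed50 = x$ed50, se = x$se, dof = x$dof %||% Inf)
  }
}

welch_satterthwaite <- function(se1, dof1, se2, dof2) {
  if (is.infinite(dof1) && is.infinite(dof2)) return(Inf)
  v <- (se1^2 + se2^2)^2 / (se1^4 / dof1 + se2^4 / dof2)
  unname(v)
}

#' @export
print.synergy_report <- function(x, ...) {
  cat("Synergy analysis", if (!is.null(x$assay)) paste0(" (", x$assay, ")"),
      "\n", sep = "")
  cat(sprintf("  experimental ED50: %.4g (se %.3g) nmol\n", x$exp_ed50, x$exp_se))
  cat(sprintf("  predicted additive ED50: %.4g (se %.3g) nmol\n",
              x$pred_ed50, x$pred_se))
  cat(sprintf("  unpaired t = %.3g, dof = %.3g (%s), p = %.3g\n",
              x$t_stat, x$dof, x$method, x$p_value))
  cat(sprintf("  potency ratio (pred/exp): %.3g\n", x$potency_ratio))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Tidy a synergy report into a one-row tibble
#'
#' @param x A `synergy_report` from [compare_ed50s()].
#' @param ... Unused.
#' @return A one-row tibble with the estimates, test statistic, p-value,
#'   potency ratio and verdict.
#' @exportS3Method generics::tidy
#' @export
tidy.synergy_report <- function(x, ...) {
  tibble::tibble(
    assay = x$assay %||% NA_character_,
    exp_ed50 = x$exp_ed50, exp_se = x$exp_se,
    pred_ed50 = x$pred_ed50, pred_se = x$pred_se,
    t_stat = x$t_stat, dof = x$dof, p_value = x$p_value,
    potency_ratio = x$potency_ratio, verdict = x$verdict,
    method = x$method
  )
}

#' Serialize a synergy report to JSON
#'
#' @param x A `synergy_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_synergy_json <- function(x, path) {
  out <- unclass(x)
  out$dof <- if (is.infinite(out$dof)) "inf" else out$dof
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
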