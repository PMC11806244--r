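#' Non-inferiority decision
#'
#' Compares the lower limit of an estimator's two-sided interval with the
#' non-inferiority margin.  Non-inferiority is declared when the lower
#' limit lies strictly above the margin (a lower bound exactly equal to the
#' margin is not declared).  Under the sign convention used throughout the
#' package, higher outcomes are better, the estimate is new minus standard,
#' and the margin is negative.
#'
#' For normal-based estimators the lower limit is
#' `estimate - z_{1 - alpha} * se`; for the Bayesian IV estimator the
#' stored credible-interval bound is used (recomputed from the posterior
#' draws if the requested level differs from the stored one).
#'
#' @param result an [estimate_result].
#' @param margin non-inferiority margin on the outcome-difference scale
#'   (negative).
#' @param alpha_one_sided one-sided level in (0, 0.5); the default 0.025
#'   corresponds to a two-sided 95% interval.
#' @return An object of class `ni_decision` with fields `declared`,
#'   `interval_lower`, `margin`, `alpha_one_sided` and `indeterminate`.
#'   A failed fit (missing estimate or SE) yields an indeterminate
#'   decision, never a silent "not declared".
#' @examples
#' d <- generate_trial(scenario_preset("A1"), seed = 1)
#' declare_noninferiority(fit_itt(d), margin = -0.3)
#' @export
declare_noninferiority <- function(result, margin, alpha_one_sided = 0.025) {
  stopifnot(inherits(result, "estimate_result"))
  if (alpha_one_sided <= 0 || alpha_one_sided >= 0.5)
    stop("alpha_one_sided must lie in (0, 0.5)", call. = FALSE)
  level <- 1 - 2 * alpha_one_sided
  lower <- if (!is.null(result$diagnostics$draws)) {
    if (isTRUE(all.equal(level, result$level))) result$lower
    else unname(stats::quantile(result$diagnostics$draws, alpha_one_sided))
  } else if (is.finite(result$estimate) && is.finite(result$se)) {
    result$estimate - stats::qnorm(1 - alpha_one_sided) * result$se
  } else NA_real_
  out <- list(margin = margin, alpha_one_sided = alpha_one_sided,
              interval_lower = lower,
              indeterminate = !is.finite(lower),
              declared = if (is.finite(lower)) lower > margin else NA)
  class(out) <- "ni_decision"
  out
}

#' @export
print.ni_decision <- function(x, ...) {
  if (x$indeterminate) {
    cat("Non-inferiority decision: indeterminate (failed fit)\n")
  } else {
    cat(sprintf(
      "Non-inferiority %s: lower bound %.4f %s margin %.3f (one-sided alpha %.3f)\n",
      if (x$declared) "declared" else "NOT declared",
      x$interval_lower, if (x$declared) ">" else "<=", x$margin,
      x$alpha_one_sided))
  }
  invisible(x)
}
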