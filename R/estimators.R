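#' @title Estimator results
#' @description Every `fit_*` estimator returns an `estimate_result`: the
#' point estimate of the treatment-effect contrast (difference in mean
#' outcome, new minus standard), its standard error (posterior SD for the
#' Bayesian IV estimator), a two-sided interval (credible interval for the
#' Bayesian IV estimator), the number of analyzed participants, and
#' method-specific diagnostics.
#' @name estimate_result
NULL

new_estimate_result <- function(method, estimate, se, lower, upper, level,
                                n_used, diagnostics = list()) {
  stopifnot(is.numeric(estimate), length(estimate) == 1L)
  out <- list(method = method, estimate = unname(estimate),
              se = unname(se), lower = unname(lower), upper = unname(upper),
              level = level, n_used = n_used, diagnostics = diagnostics)
  class(out) <- "estimate_result"
  out
}

#' @export
print.estimate_result <- function(x, ...) {
  cat(sprintf("%s estimate: %.4f (SE %.4f), %g%% interval [%.4f, %.4f], n = %d\n",
              toupper(x$method), x$estimate, x$se, 100 * x$level,
              x$lower, x$upper, x$n_used))
  flg <- c(
    if (isTRUE(x$diagnostics$perfect_prediction)) "perfect prediction (observations dropped)",
    if (isFALSE(x$diagnostics$converged)) "sampler did not converge")
  if (length(flg)) cat("  flags:", paste(flg, collapse = "; "), "\n")
  invisible(x)
}

normal_interval <- function(estimate, se, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(estimate - z * se, estimate + z * se)
}

as_trial <- function(data) {
  d <- if (inherits(data, "trial_data")) data else trial_data(data)
  if (length(unique(d$Z)) < 2L)
    stop("both treatment arms must be non-empty", call. = FALSE)
  d
}

check_full_rank <- function(fit) {
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design: column(s) ",
         paste(names(cf)[is.na(cf)], collapse = ", "),
         " are collinear", call. = FALSE)
  invisible(fit)
}

ols_contrast <- function(d, method, level, diagnostics = list()) {
  fit <- stats::lm(Y ~ Z + X, data = d)
  check_full_rank(fit)
  est <- stats::coef(fit)[["Z"]]
  se <- sqrt(stats::vcov(fit)["Z", "Z"])
  ci <- normal_interval(est, se, level)
  new_estimate_result(method, est, se, ci[1], ci[2], level, nrow(d),
                      diagnostics)
}

#' Intention-to-treat estimator
#'
#' Ordinary least squares of the outcome on allocation `Z` and the observed
#' baseline covariate `X` over all randomized participants, regardless of
#' compliance.  Targets the treatment-policy estimand; it coincides with the
#' hypothetical estimand only under full compliance (or when outcomes under
#' compliance and non-compliance are identical).
#'
#' @param data a [trial_data()] object (or data.frame coercible to one).
#' @param level two-sided confidence level (normal-based interval).
#' @return An [estimate_result].
#' @export
fit_itt <- function(data, level = 0.95) {
  d <- as_trial(data)
  ols_contrast(d, "itt", level)
}

#' Per-protocol estimator
#'
#' The same covariate-adjusted regression as [fit_itt()], restricted to
#' participants who complied with their assigned treatment.  Unbiased for
#' the hypothetical estimand under conditional exchangeability given `X`
#' (no unmeasured confounding of compliance and outcome), a correctly
#' specified `X`-outcome association, and no treatment-effect heterogeneity
#' across levels of `X`.
#'
#' @inheritParams fit_itt
#' @return An [estimate_result]; diagnostics record per-arm exclusion
#'   counts.
#' @export
fit_pp <- function(data, level = 0.95) {
  d <- as_trial(data)
  excl <- c(arm0 = sum(d$Z == 0 & d$C == 0), arm1 = sum(d$Z == 1 & d$C == 0))
  dc <- d[d$C == 1, , drop = FALSE]
  for (z in 0:1)
    if (!any(dc$Z == z))
      stop("no compliers in arm ", z, call. = FALSE)
  ols_contrast(dc, "pp", level,
               diagnostics = list(n_excluded = excl))
}

#' Inverse-probability-weighting estimator
#'
#' Stage 1 fits a logistic regression of compliance on the observed
#' covariate `X` separately in each arm; compliers are weighted by the
#' inverse of their fitted compliance probability, so that the weighted
#' complier population recovers the full randomized population under
#' conditional exchangeability given `X` and positivity.  Stage 2 is a
#' weighted regression of the outcome on allocation among compliers, with a
#' heteroskedasticity-robust (sandwich, HC1) standard error.
#'
#' Perfect prediction in a weight model (a fitted compliance probability of
#' 0 or 1 within `tol`, while compliance still varies in that arm) leads to
#' the affected observations being dropped and the result flagged in
#' `diagnostics$perfect_prediction`.  An arm whose participants all comply
#' is treated as having compliance probability exactly 1 (unit weights, no
#' flag); an arm with no compliers is an error.
#'
#' @inheritParams fit_itt
#' @param tol fitted probabilities outside `[tol, 1 - tol]` count as perfect
#'   prediction.
#' @return An [estimate_result]; diagnostics record the weight range, the
#'   fitted per-(arm, X) compliance probabilities, the number of dropped
#'   observations and the perfect-prediction flag.
#' @export
fit_ipw <- function(data, level = 0.95, tol = 1e-6) {
  d <- as_trial(data)
  phat <- rep(NA_real_, nrow(d))
  dropped <- rep(FALSE, nrow(d))
  for (z in 0:1) {
    idx <- which(d$Z == z)
    cz <- d$C[idx]
    if (all(cz == 0)) stop("no compliers in arm ", z, call. = FALSE)
    if (all(cz == 1)) {            # degenerate: compliance certain
      phat[idx] <- 1
      next
    }
    fit <- suppressWarnings(
      stats::glm(C ~ X, family = stats::binomial(), data = d[idx, ]))
    p <- unname(stats::fitted(fit))
    phat[idx] <- p
    dropped[idx] <- p < tol | p > 1 - tol
  }
  keep <- d$C == 1 & !dropped
  if (!any(keep & d$Z == 0) || !any(keep & d$Z == 1))
    stop("no usable compliers left in one arm after dropping ",
         "perfectly predicted observations", call. = FALSE)
  w <- 1 / phat[keep]
  dk <- d[keep, , drop = FALSE]
  fit2 <- stats::lm(Y ~ Z, data = dk, weights = w)
  est <- stats::coef(fit2)[["Z"]]
  se <- sqrt(sandwich::vcovHC(fit2, type = "HC1")["Z", "Z"])
  ci <- normal_interval(est, se, level)
  cells <- stats::aggregate(phat, by = list(Z = d$Z, X = d$X),
                            FUN = function(p) p[1])
  names(cells)[3] <- "p_comply"
  new_estimate_result(
    "ipw", est, se, ci[1], ci[2], level, nrow(dk),
    diagnostics = list(weight_range = range(w),
                       cell_probs = cells,
                       n_dropped = sum(dropped & d$C == 1),
                       perfect_prediction = any(dropped)))
}

#' Interaction-instrument two-stage least squares estimator
#'
#' Uses randomization `Z` and the allocation-by-covariate interaction `ZX`
#' as instruments for the two endogenous receipt indicators `R0` (received
#' standard) and `R1` (received new).  Stage 1 regresses receipt on `X`
#' within each arm (receipt is identically zero in the opposite arm);
#' stage 2 regresses the outcome on the predicted receipts and `X`, and the
#' treatment effect is the contrast of the two receipt coefficients.  The
#' model is identified only if the predicted compliances are not
#' proportional across levels of `X` (there must be no constant k with
#' `C1hat = k * C0hat` at every X), which also rules out full compliance in
#' both arms.
#'
#' The covariance is the standard asymptotic two-stage least-squares
#' covariance (residual variance computed from the structural residuals,
#' divided by n).
#'
#' @inheritParams fit_itt
#' @param cond_tol reciprocal condition number of the projected design below
#'   which the model is declared unidentified.
#' @return An [estimate_result]; diagnostics record the per-arm stage-1
#'   coefficients, the stage-1 interaction strength (difference in
#'   covariate-compliance slopes between arms) and the smallest singular
#'   value of the projected design.
#' @export
fit_iv_interaction <- function(data, level = 0.95, cond_tol = 1e-8) {
  d <- as_trial(data)
  n <- nrow(d)
  c0hat <- numeric(n)
  c1hat <- numeric(n)
  s1 <- list()
  for (z in 0:1) {
    idx <- which(d$Z == z)
    receipt <- if (z == 0) "R0" else "R1"
    fit <- stats::lm(stats::reformulate("X", receipt), data = d[idx, ])
    if (z == 0) c0hat[idx] <- stats::fitted(fit)
    else c1hat[idx] <- stats::fitted(fit)
    cf <- stats::coef(fit)
    cf[is.na(cf)] <- 0                 # X constant within arm
    s1[[paste0("arm", z)]] <- cf
  }
  What <- cbind(1, d$X, c0hat, c1hat)
  colnames(What) <- c("(Intercept)", "X", "C0hat", "C1hat")
  sv <- svd(What, nu = 0, nv = 0)$d
  if (min(sv) / max(sv) < cond_tol)
    stop("IV(interaction) model not identified: predicted compliances ",
         "C1hat are proportional to C0hat across levels of X ",
         "(e.g. full compliance in both arms); the interaction instrument ",
         "carries no information", call. = FALSE)
  xtx <- crossprod(What)
  beta <- solve(xtx, crossprod(What, d$Y))[, 1]
  W <- cbind(1, d$X, d$R0, d$R1)
  resid <- d$Y - W %*% beta
  sigma2 <- sum(resid^2) / n
  vc <- sigma2 * solve(xtx)
  cvec <- c(0, 0, -1, 1)
  est <- beta[["C1hat"]] - beta[["C0hat"]]
  se <- sqrt(drop(t(cvec) %*% vc %*% cvec))
  ci <- normal_interval(est, se, level)
  new_estimate_result(
    "iv_interaction", est, se, ci[1], ci[2], level, n,
    diagnostics = list(
      stage1 = s1,
      interaction_strength = unname(s1$arm1["X"] - s1$arm0["X"]),
      min_singular_value = min(sv),
      coefficients = beta))
}
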