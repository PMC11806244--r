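#' Construct and validate a trial dataset
#'
#' A `trial_data` object is a data.frame with one row per participant and
#' columns `id`, `Z` (randomized arm: 0 = standard, 1 = new), `C`
#' (compliance with the assigned treatment), `X` (observed binary baseline
#' covariate), optionally `U` (unobserved binary baseline covariate, present
#' only for simulated data), `Y` (continuous outcome), and the derived
#' receipt indicators `R0 = (1 - Z) * C` (received standard) and
#' `R1 = Z * C` (received new).  `U` is flagged non-observable: estimators
#' never read it.
#'
#' @param df data.frame with columns `id`, `Z`, `C`, `X`, `Y` and optionally
#'   `U`.  `R0`/`R1` are (re)derived.
#' @return A validated `trial_data` object.
#' @export
trial_data <- function(df) {
  req <- c("id", "Z", "C", "X", "Y")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("trial data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("Z", "C", "X", if ("U" %in% names(df)) "U")) {
    bad <- which(!(df[[col]] %in% c(0, 1)))
    if (length(bad))
      stop("column '", col, "' must be binary (0/1); first offending row: ",
           bad[1], call. = FALSE)
  }
  if (!is.numeric(df$Y) || any(!is.finite(df$Y)))
    stop("column 'Y' must be finite numeric", call. = FALSE)
  df$R0 <- (1 - df$Z) * df$C
  df$R1 <- df$Z * df$C
  out <- df[, c("id", "Z", "C", "X", if ("U" %in% names(df)) "U",
                "Y", "R0", "R1")]
  class(out) <- c("trial_data", "data.frame")
  out
}

#' @export
print.trial_data <- function(x, ...) {
  cat("Trial dataset: n =", nrow(x), "\n")
  cat(sprintf("  arms: %d standard / %d new;  compliers: %d (%.1f%%)\n",
              sum(x$Z == 0), sum(x$Z == 1), sum(x$C),
              100 * mean(x$C)))
  if ("U" %in% names(x))
    cat("  latent covariate U present (simulated data; not used by estimators)\n")
  NextMethod()
  invisible(x)
}

check_binary_vectors <- function(...) {
  vs <- list(...)
  lens <- vapply(vs, length, 1L)
  if (length(unique(lens)) != 1L)
    stop("input vectors must have equal length", call. = FALSE)
  for (nm in names(vs))
    if (!all(vs[[nm]] %in% c(0, 1)))
      stop("input '", nm, "' must be binary (0/1)", call. = FALSE)
  invisible(lens[1])
}

#' Sample compliance indicators
#'
#' Draws compliance `C` from the logistic model
#' `expit(gamma0 + gammaZ Z + gammaX X + gammaU U + gammaZX ZX + gammaZU ZU)`.
#' Infinite intercepts are handled by clamping the probability to 0 or 1.
#'
#' @param config a [scenario_config()].
#' @param Z,X,U binary vectors of equal length.
#' @return Binary vector of compliance indicators (uses the current RNG
#'   state; seed with [set.seed()] for reproducibility).
#' @export
sample_compliance <- function(config, Z, X, U) {
  n <- check_binary_vectors(Z = Z, X = X, U = U)
  p <- compliance_probability(config, Z, X, U)
  as.integer(stats::runif(n) < p)
}

#' @rdname sample_compliance
#' @export
compliance_probability <- function(config, Z, X, U) {
  lp <- config$gamma0 + config$gammaZ * Z + config$gammaX * X +
    config$gammaU * U + config$gammaZX * Z * X + config$gammaZU * Z * U
  p <- stats::plogis(lp)
  # +/-Inf linear predictors degenerate to certain (non-)compliance
  p[lp == Inf] <- 1
  p[lp == -Inf] <- 0
  p
}

#' Sample continuous outcomes
#'
#' Draws the outcome from the linear-normal model
#' `Y = beta0 + betaC0 R0 + betaC1 R1 + betaX X + betaU U +
#'  deltaX R1 X + deltaU R1 U + N(0, sigma^2)`.
#'
#' @param config a [scenario_config()].
#' @param R0,R1 binary receipt indicators (standard / new); `R0 * R1` must
#'   be 0 for every participant.
#' @param X,U binary covariate vectors.
#' @return Numeric outcome vector.
#' @export
sample_outcome <- function(config, R0, R1, X, U) {
  n <- check_binary_vectors(R0 = R0, R1 = R1, X = X, U = U)
  if (any(R0 * R1 != 0))
    stop("R0 and R1 cannot both be 1 for the same participant",
         call. = FALSE)
  if (config$sigma <= 0)
    stop("sigma must be > 0", call. = FALSE)
  mu <- outcome_mean(config, R0, R1, X, U)
  mu + stats::rnorm(n, 0, config$sigma)
}

outcome_mean <- function(config, R0, R1, X, U) {
  config$beta0 + config$betaC0 * R0 + config$betaC1 * R1 +
    config$betaX * X + config$betaU * U +
    config$deltaX * R1 * X + config$deltaU * R1 * U
}

#' Generate one simulated trial
#'
#' Draws `X`, `U` and `Z` independently (`Z ~ Bernoulli(p_alloc)`), then
#' compliance via [sample_compliance()] and the outcome via
#' [sample_outcome()].  An identical `(config, seed)` pair yields a
#' bit-identical dataset.
#'
#' @param config a [scenario_config()].
#' @param seed optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return A [trial_data()] object of `config$n` participants (including
#'   the latent column `U`).
#' @examples
#' d <- generate_trial(scenario_preset("A1"), seed = 1)
#' mean(d$C)
#' @export
generate_trial <- function(config, seed = NULL) {
  validate_scenario_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  X <- as.integer(stats::runif(n) < config$pX)
  U <- as.integer(stats::runif(n) < config$pU)
  Z <- as.integer(stats::runif(n) < config$p_alloc)
  C <- sample_compliance(config, Z, X, U)
  R0 <- (1 - Z) * C
  R1 <- Z * C
  Y <- sample_outcome(config, R0, R1, X, U)
  trial_data(data.frame(id = seq_len(n), Z = Z, C = C, X = X, U = U, Y = Y))
}
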