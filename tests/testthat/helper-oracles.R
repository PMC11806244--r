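# Independent oracles and fixture builders shared across tests.

# normal-equations OLS solve (independent of stats::lm)
ols_oracle <- function(X, y) {
  unname(drop(solve(t(X) %*% X, t(X) %*% y)))
}

# moment-equation 2SLS solve: instruments V, regressors W
tsls_oracle <- function(W, V, y) {
  unname(drop(solve(t(V) %*% W, t(V) %*% y)))
}

make_trial <- function(Z, C, X, Y, U = NULL) {
  df <- data.frame(id = seq_along(Z), Z = Z, C = C, X = X, Y = Y)
  if (!is.null(U)) df$U <- U
  trial_data(df)
}

# hand fixture from the weighted-means worked example:
# arm 0, X=0: 4 participants, 2 compliers (Y = 1, 3);
# arm 0, X=1: 4 participants, all complying (Y = 2);
# arm 1: 8 compliers, all Y = 2.5.
ipw_hand_fixture <- function() {
  make_trial(
    Z = c(rep(0, 8), rep(1, 8)),
    C = c(1, 1, 0, 0, rep(1, 4), rep(1, 8)),
    X = c(0, 0, 0, 0, 1, 1, 1, 1, rep(c(0, 1), 4)),
    Y = c(1, 3, 9, 9, rep(2, 4), rep(2.5, 8)))
}

# deterministic full-compliance dataset with X balanced across arms
full_compliance_fixture <- function(n_per_arm = 10, delta = -0.3) {
  Z <- rep(0:1, each = n_per_arm)
  X <- rep(rep(0:1, length.out = n_per_arm), 2)
  resid <- rep(c(-0.3, 0.3, 0.2, -0.2), length.out = n_per_arm)
  Y <- 1 + delta * Z + 0.4 * X + rep(resid, 2)
  make_trial(Z, C = rep(1, 2 * n_per_arm), X, Y)
}

# deterministic dataset with arm compliance 0.9, arm-0 mean 0 and arm-1
# mean -0.27, X balanced and unrelated to outcome or compliance
bayes_closed_form_fixture <- function() {
  Z <- rep(0:1, each = 20)
  X <- rep(rep(0:1, each = 10), 2)
  C <- rep(c(rep(1, 9), 0), 4)            # 9/10 compliers per (Z, X) cell
  base <- rep(c(-0.3, 0.3), 10)           # zero-mean pattern per cell
  Y <- base + c(rep(0, 20), rep(-0.27, 20))
  make_trial(Z, C, X, Y)
}

expect_estimate <- function(res, value, tol = 1e-8) {
  expect_s3_class(res, "estimate_result")
  expect_equal(res$estimate, value, tolerance = tol)
}
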