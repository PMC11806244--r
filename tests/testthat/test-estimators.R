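test_that("ITT equals the normal-equations solution on a small fixture", {
  Z <- c(0, 0, 0, 1, 1, 1)
  X <- c(0, 1, 1, 0, 0, 1)
  Y <- c(1.2, 2.1, 1.7, 0.4, 0.9, 1.5)
  d <- make_trial(Z, C = rep(1, 6), X, Y)
  res <- fit_itt(d)
  beta <- ols_oracle(cbind(1, Z, X), Y)
  expect_equal(res$estimate, beta[2], tolerance = 1e-10)
})

test_that("ITT recovers an exact linear relationship with zero SE", {
  Z <- rep(0:1, each = 4)
  X <- rep(c(0, 1), 4)
  d <- make_trial(Z, C = rep(1, 8), X, Y = Z)
  res <- suppressWarnings(fit_itt(d))   # noiseless: perfect-fit warning
  expect_equal(res$estimate, 1, tolerance = 1e-10)
  expect_lt(res$se, 1e-8)
})

test_that("rank-deficient designs raise a named error", {
  # X identical to Z: collinear with the allocation column
  d <- make_trial(Z = rep(0:1, each = 3), C = rep(1, 6),
                  X = rep(0:1, each = 3), Y = rnorm(6))
  expect_error(fit_itt(d), "collinear")
})

test_that("per-protocol restricts to compliers and matches a subset oracle", {
  Z <- c(0, 0, 0, 0, 1, 1, 1, 1)
  C <- c(1, 1, 1, 0, 1, 1, 0, 1)
  X <- c(0, 1, 0, 1, 0, 1, 0, 1)
  Y <- c(1.0, 1.5, 0.8, 9.0, 0.6, 1.1, 9.0, 0.9)
  d <- make_trial(Z, C, X, Y)
  res <- fit_pp(d)
  keep <- C == 1
  beta <- ols_oracle(cbind(1, Z, X)[keep, ], Y[keep])
  expect_equal(res$estimate, beta[2], tolerance = 1e-10)
  expect_equal(res$n_used, 6L)
  expect_equal(unname(res$diagnostics$n_excluded), c(1L, 1L))
  # an arm without compliers cannot be analyzed
  d2 <- make_trial(Z, C = c(0, 0, 0, 0, 1, 1, 1, 1), X, Y)
  expect_error(fit_pp(d2), "no compliers in arm 0")
})

test_that("ITT and PP coincide on full-compliance data; IPW gives arm means", {
  d <- full_compliance_fixture()
  itt <- fit_itt(d); pp <- fit_pp(d); ipw <- fit_ipw(d)
  expect_equal(pp$estimate, itt$estimate, tolerance = 1e-12)
  expect_equal(pp$se, itt$se, tolerance = 1e-12)
  expect_equal(ipw$estimate, mean(d$Y[d$Z == 1]) - mean(d$Y[d$Z == 0]),
               tolerance = 1e-12)
  expect_equal(unname(ipw$diagnostics$weight_range), c(1, 1))
  expect_false(ipw$diagnostics$perfect_prediction)
})

test_that("IPW reproduces the hand-computed weighted means", {
  d <- ipw_hand_fixture()
  res <- fit_ipw(d)
  # weighted arm-0 mean (2*1 + 2*3 + 4*2) / 8 = 2.0; arm-1 mean 2.5
  expect_equal(res$estimate, 0.5, tolerance = 1e-10)
})

test_that("saturated IPW weights sum to cell counts exactly", {
  set.seed(21)
  cfg <- scenario_preset("A2b")
  for (s in 1:5) {
    d <- generate_trial(cfg, seed = s)
    res <- fit_ipw(d)
    if (res$diagnostics$perfect_prediction) next
    p <- res$diagnostics$cell_probs
    for (i in seq_len(nrow(p))) {
      cell <- d$Z == p$Z[i] & d$X == p$X[i]
      w_sum <- sum(1 / p$p_comply[i] * (d$C[cell] == 1))
      expect_equal(w_sum, sum(cell), tolerance = 1e-8)
    }
  }
})

test_that("perfect prediction drops observations and flags the fit", {
  # arm 0: X=1 cell fully compliant while X=0 cell is not -> separation
  Z <- c(rep(0, 8), rep(1, 8))
  C <- c(1, 0, 1, 0, 1, 1, 1, 1, 1, 1, 0, 1, 1, 0, 1, 1)
  X <- c(0, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0, 0, 1, 1, 1, 1)
  Y <- seq(0.1, 1.6, by = 0.1)
  d <- make_trial(Z, C, X, Y)
  res <- fit_ipw(d)
  expect_true(res$diagnostics$perfect_prediction)
  expect_equal(res$diagnostics$n_dropped, 4L)
  expect_error(fit_ipw(make_trial(Z, C = c(rep(0, 8), rep(1, 8)), X, Y)),
               "no compliers in arm 0")
})

test_that("IPW sandwich variance matches a direct computation", {
  set.seed(4)
  d <- generate_trial(scenario_preset("A2b"), seed = 4)
  res <- fit_ipw(d)
  # direct HC1 sandwich on the weighted complier regression
  dc <- d[d$C == 1, ]
  p <- res$diagnostics$cell_probs
  w <- apply(dc, 1, function(r)
    1 / p$p_comply[p$Z == r[["Z"]] & p$X == r[["X"]]])
  Xm <- cbind(1, dc$Z)
  beta <- solve(t(Xm * w) %*% Xm, t(Xm * w) %*% dc$Y)
  e <- dc$Y - Xm %*% beta
  bread <- solve(t(Xm * w) %*% Xm)
  meat <- t(Xm * as.vector(w * e)) %*% (Xm * as.vector(w * e))
  vc <- bread %*% meat %*% bread * nrow(dc) / (nrow(dc) - 2)
  expect_equal(res$estimate, beta[2, 1], tolerance = 1e-10)
  expect_equal(res$se, sqrt(vc[2, 2]), tolerance = 1e-8)
})
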