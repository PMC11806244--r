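test_that("a degenerate prior reproduces the two-equation closed form", {
  d <- bayes_closed_form_fixture()
  # with prior mass at b0, the posterior contrast centers on
  # (Ybar1 - Ybar0 + b0 * p0hat) / p1hat - b0;  here b0 = 0 -> -0.3
  pr <- prior_spec(mean = 0, sd = 1e-4)
  set.seed(31)
  plug <- fit_iv_bayes(d, pr, variant = "plugin", chains = 2,
                       iter = 2250, warmup = 250)
  expect_equal(plug$estimate, -0.3, tolerance = 0.01)
  set.seed(32)
  sampled <- fit_iv_bayes(d, pr, chains = 2, iter = 2250, warmup = 250)
  expect_equal(sampled$estimate, -0.3, tolerance = 0.03)
  # nonzero prior mean: same closed form with b0 = 0.5
  b0 <- 0.5
  closed <- (-0.27 - 0 + b0 * 0.9) / 0.9 - b0
  set.seed(33)
  plug2 <- fit_iv_bayes(d, prior_spec(b0, 1e-4), variant = "plugin",
                        chains = 2, iter = 2250, warmup = 250)
  expect_equal(plug2$estimate, closed, tolerance = 0.01)
})

test_that("under full compliance the contrast is identified despite the prior", {
  d <- full_compliance_fixture(n_per_arm = 20)
  set.seed(41)
  res <- fit_iv_bayes(d, prior_spec(mean = 5, sd = 0.3), chains = 2,
                      iter = 2250, warmup = 250)
  expect_equal(res$estimate, mean(d$Y[d$Z == 1]) - mean(d$Y[d$Z == 0]),
               tolerance = 0.05)
})

test_that("posterior summaries are seed-deterministic with diagnostics", {
  d <- generate_trial(scenario_preset("A1"), seed = 8)
  pr <- prior_spec(1, 1)
  set.seed(9); a <- fit_iv_bayes(d, pr, chains = 2, iter = 1000, warmup = 250)
  set.seed(9); b <- fit_iv_bayes(d, pr, chains = 2, iter = 1000, warmup = 250)
  expect_identical(a$estimate, b$estimate)
  expect_identical(a$lower, b$lower)
  expect_true(is.finite(a$diagnostics$rhat))
  expect_gt(a$diagnostics$ess, 100)
  expect_true(is.logical(a$diagnostics$converged))
  expect_lt(a$lower, a$estimate)
  expect_gt(a$upper, a$estimate)
})

test_that("plug-in and stage-1-sampled variants agree on scenario A1", {
  cfg <- scenario_preset("A1")
  pr <- prior_grid(cfg)$well_centered_precise
  set.seed(55)
  seeds <- sample.int(1e6, 100)
  diffs <- vapply(seeds, function(s) {
    d <- generate_trial(cfg, seed = s)
    j <- fit_iv_bayes(d, pr, chains = 2, iter = 1000, warmup = 250)
    p <- fit_iv_bayes(d, pr, variant = "plugin", chains = 2, iter = 1000,
                      warmup = 250)
    j$estimate - p$estimate
  }, 1)
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 0.01)
})

test_that("the stage-2 Gibbs updates agree with an independent JAGS fit", {
  # the plug-in variant conditions on the least-squares stage-1 fits, so
  # the identical model can be expressed in JAGS: a normal regression of Y
  # on the predicted receipts and X, prior on the standard-receipt effect
  d <- generate_trial(scenario_preset("A4a"), seed = 14)
  pr <- prior_spec(mean = 1, sd = 0.5)
  set.seed(15)
  mine <- fit_iv_bayes(d, pr, variant = "plugin", chains = 2, iter = 6000,
                       warmup = 1000)

  c0hat <- fitted(lm(R0 ~ Z + X, data = d))
  c1hat <- fitted(lm(R1 ~ Z + X, data = d))
  model <- "
  model {
    for (i in 1:N) {
      Y[i] ~ dnorm(b[1] + b[2] * C0hat[i] + b[3] * C1hat[i] + b[4] * X[i],
                   tauY)
    }
    b[1] ~ dnorm(0, 1e-8)
    b[2] ~ dnorm(pm, pprec)
    b[3] ~ dnorm(0, 1e-8)
    b[4] ~ dnorm(0, 1e-8)
    tauY ~ dgamma(0.001, 0.001)
    contrast <- b[3] - b[2]
  }"
  rjags::load.module("glm", quiet = TRUE)
  jm <- rjags::jags.model(
    textConnection(model),
    data = list(N = nrow(d), Y = d$Y, C0hat = c0hat, C1hat = c1hat,
                X = d$X, pm = pr$mean, pprec = 1 / pr$sd^2),
    inits = list(
      list(.RNG.name = "base::Wichmann-Hill", .RNG.seed = 1),
      list(.RNG.name = "base::Wichmann-Hill", .RNG.seed = 2)),
    n.chains = 2, n.adapt = 1000, quiet = TRUE)
  sm <- rjags::coda.samples(jm, "contrast", n.iter = 15000)
  draws <- unlist(lapply(sm, as.numeric))
  expect_equal(mine$estimate, mean(draws), tolerance = 0.05)
  expect_equal(mine$se, sd(draws), tolerance = 0.25 * sd(draws))
})
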