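test_that("run_study is fully reproducible from the master seed", {
  cfg <- scenario_preset("A1")
  r1 <- run_study(cfg, c("itt", "pp", "ipw"), n_reps = 3, master_seed = 7)
  r2 <- run_study(cfg, c("itt", "pp", "ipw"), n_reps = 3, master_seed = 7)
  expect_identical(r1, r2)
  r3 <- run_study(cfg, "itt", n_reps = 3, master_seed = 8)
  expect_false(identical(r1$estimate[r1$method == "itt"], r3$estimate))
  expect_error(run_study(cfg, "magic", 2, 1), "unknown estimator")
})

test_that("failed fits are recorded, never fatal", {
  cfg <- scenario_preset("A1")
  cfg$gamma0 <- 30        # essentially full compliance: IV(interaction)
  r <- run_study(cfg, c("itt", "iv_interaction"), n_reps = 2,
                 master_seed = 3)
  iv <- r[r$method == "iv_interaction", ]
  expect_true(all(is.na(iv$estimate)))
  expect_match(iv$error[1], "not identified")
})

test_that("summary metrics match spreadsheet arithmetic on listed records", {
  est_itt <- c(-0.25, -0.35, -0.30, -0.28, -0.40, -0.22, -0.31, -0.29,
               -0.36, -0.24)
  est_pp <- est_itt + 0.05
  rec <- data.frame(
    scenario = "hand", rep = rep(1:10, 2), seed = 1,
    method = rep(c("itt", "pp"), each = 10),
    estimate = c(est_itt, est_pp), se = 0.06,
    lower = c(est_itt, est_pp) - 1.96 * 0.06,
    upper = c(est_itt, est_pp) + 1.96 * 0.06,
    declared = rep(c(TRUE, FALSE), 10), ipw_dropped = FALSE,
    bayes_nonconverged = FALSE, error = NA_character_)
  sm <- summarize_study(rec, truth = -0.3)
  itt <- sm[sm$method == "itt", ]
  expect_equal(itt$mean_estimate, mean(est_itt))
  expect_equal(itt$bias, mean(est_itt) + 0.3)
  expect_equal(itt$empirical_se, sd(est_itt))
  expect_equal(itt$mcse_bias, sd(est_itt) / sqrt(10))
  expect_equal(itt$ni_rate, 50)
  expect_equal(itt$mcse_ni_rate, 100 * sqrt(0.5 * 0.5 / 10))
  pp <- sm[sm$method == "pp", ]
  expect_equal(pp$bias, mean(est_pp) + 0.3)
  expect_equal(pp$precision_increase_vs_itt, 0, tolerance = 1e-10)
})

test_that("the SE filter marks exactly the listed outliers", {
  se_iv <- c(0.2, 0.3, 8.0, 0.25, 0.22, 12.0, 0.28, 0.31, 0.26, 0.24)
  est_itt <- c(-0.2, -0.4, -0.3, -0.25, -0.35, -0.28, -0.33, -0.27,
               -0.38, -0.22)
  rec <- data.frame(
    scenario = "hand", rep = rep(1:10, 2), seed = 1,
    method = rep(c("itt", "iv_interaction"), each = 10),
    estimate = c(est_itt, est_itt), se = c(rep(0.06, 10), se_iv),
    lower = NA_real_, upper = NA_real_, declared = FALSE,
    ipw_dropped = FALSE, bayes_nonconverged = FALSE, error = NA_character_)
  out <- filter_replications(rec)
  marked <- out$iv_se_outlier[out$method == "iv_interaction"]
  expect_identical(which(marked), c(3L, 6L))   # SE > 10 * sd(est_itt)
  expect_equal(sum(out$used[out$method == "iv_interaction"]), 8)
  sm <- summarize_study(out, truth = -0.3)
  expect_equal(sm$n_reps_used[sm$method == "iv_interaction"], 8)
  # the filter needs ITT only when interaction-IV replications are present
  expect_error(filter_replications(rec[rec$method == "iv_interaction", ]),
               "ITT")
  expect_silent(filter_replications(rec[rec$method == "itt", ]))
})

test_that("IPW drop flags exclude replications from filtered summaries only", {
  rec <- data.frame(
    scenario = "hand", rep = rep(1:6, 2), seed = 1,
    method = rep(c("itt", "ipw"), each = 6),
    estimate = rep(c(-0.3, -0.2, -0.4, -0.25, -0.35, -0.3), 2), se = 0.1,
    lower = NA_real_, upper = NA_real_, declared = FALSE,
    ipw_dropped = rep(c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE), 2),
    bayes_nonconverged = FALSE, error = NA_character_)
  sm_f <- summarize_study(rec, truth = -0.3)
  expect_equal(sm_f$n_reps_used[sm_f$method == "ipw"], 5)
  expect_equal(sm_f$n_reps_used[sm_f$method == "itt"], 6)
  sm_u <- summarize_study(rec, truth = -0.3, filtered = FALSE)
  expect_equal(sm_u$n_reps_used[sm_u$method == "ipw"], 6)
})

test_that("precision-increase formula identities hold", {
  expect_equal(precision_increase(1, 1), 0)
  expect_equal(precision_increase(2, 1), 300)
  expect_equal(precision_increase(0.1, 0.1), 0)
})

test_that("ITT empirical SE agrees with the analytic least-squares SE", {
  cfg <- scenario_preset("A1")
  rec <- run_study(cfg, "itt", n_reps = 800, master_seed = 42)
  empse <- sd(rec$estimate)
  # analytic residual variance: error + latent covariate + compliance mixing
  p <- 0.7
  v_resid <- cfg$sigma^2 + cfg$betaU^2 * 0.25 +
    0.5 * p * (1 - p) * (cfg$betaC0^2 + cfg$betaC1^2)
  se_analytic <- sqrt(v_resid / (cfg$n * 0.25))
  expect_lt(abs(empse / se_analytic - 1), 0.2)
})
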