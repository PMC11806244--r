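#' Run a replicated simulation study
#'
#' Generates `n_reps` independent trials from a scenario and fits each
#' requested estimator to every replication.  Per-replication seeds are
#' derived deterministically from `master_seed`, so `(config, master_seed,
#' n_reps)` fully determine every downstream summary.  A failed fit is
#' recorded with its error message and never aborts the study.
#'
#' @param config a [scenario_config()].
#' @param estimators character vector from `itt`, `pp`, `ipw`,
#'   `iv_interaction`, `iv_bayes`.
#' @param n_reps number of replications (>= 1).
#' @param master_seed integer master seed.
#' @param margin non-inferiority margin.
#' @param alpha_one_sided one-sided test level.
#' @param prior [prior_spec()] for the Bayesian IV estimator; defaults to
#'   the well-centered precise prior implied by `config`.
#' @param bayes_args list of arguments passed on to [fit_iv_bayes()]
#'   (variant and sampler settings).  The default uses the plug-in variant
#'   with 2 chains of 1250 draws (250 warm-up), a setting chosen for
#'   simulation grids; single-dataset analyses should use
#'   [fit_iv_bayes()]'s own defaults.
#' @return A `replication_records` data.frame with one row per
#'   (replication, estimator): estimate, SE, interval, NI decision, flags
#'   (`ipw_dropped`, `bayes_nonconverged`) and any error message.  The
#'   scenario truth, margin and alpha are stored as attributes.
#' @examples
#' rec <- run_study(scenario_preset("A1"), c("itt", "pp"), n_reps = 5,
#'                  master_seed = 1)
#' summarize_study(rec)
#' @export
run_study <- function(config, estimators = c("itt", "pp", "ipw"),
                      n_reps, master_seed,
                      margin = -0.3, alpha_one_sided = 0.025,
                      prior = NULL,
                      bayes_args = list(variant = "plugin", chains = 2,
                                        iter = 1250, warmup = 250)) {
  validate_scenario_config(config)
  known <- c("itt", "pp", "ipw", "iv_interaction", "iv_bayes")
  bad <- setdiff(estimators, known)
  if (length(bad))
    stop("unknown estimator(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  stopifnot(n_reps >= 1)
  if ("iv_bayes" %in% estimators && is.null(prior))
    prior <- prior_grid(config)$well_centered_precise
  set.seed(master_seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  level <- 1 - 2 * alpha_one_sided

  rows <- vector("list", n_reps * length(estimators))
  k <- 0L
  for (r in seq_len(n_reps)) {
    d <- generate_trial(config, seed = rep_seeds[r])
    for (m in estimators) {
      res <- tryCatch(
        switch(m,
               itt = fit_itt(d, level),
               pp = fit_pp(d, level),
               ipw = fit_ipw(d, level),
               iv_interaction = fit_iv_interaction(d, level),
               iv_bayes = do.call(fit_iv_bayes,
                                  c(list(d, prior, level = level),
                                    bayes_args))),
        error = function(e) e)
      k <- k + 1L
      if (inherits(res, "error")) {
        rows[[k]] <- data.frame(
          scenario = config$label, rep = r, seed = rep_seeds[r], method = m,
          estimate = NA_real_, se = NA_real_, lower = NA_real_,
          upper = NA_real_, declared = NA, ipw_dropped = FALSE,
          bayes_nonconverged = FALSE, error = conditionMessage(res))
      } else {
        dec <- declare_noninferiority(res, margin, alpha_one_sided)
        rows[[k]] <- data.frame(
          scenario = config$label, rep = r, seed = rep_seeds[r], method = m,
          estimate = res$estimate, se = res$se, lower = res$lower,
          upper = res$upper, declared = dec$declared,
          ipw_dropped = isTRUE(res$diagnostics$perfect_prediction),
          bayes_nonconverged = m == "iv_bayes" &&
            !isTRUE(res$diagnostics$converged),
          error = NA_character_)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- true_hypothetical_estimand(config)
  attr(out, "margin") <- margin
  attr(out, "alpha_one_sided") <- alpha_one_sided
  class(out) <- c("replication_records", "data.frame")
  out
}

#' Mark replications excluded by the reporting filters
#'
#' Reproduces the reporting conventions of the simulation study:
#' interaction-IV replications whose model SE exceeds 10 times the
#' empirical SE of the intention-to-treat estimator (over all replications
#' of the scenario) are marked as SE outliers, and IPW replications in
#' which observations were dropped for perfect prediction are marked.
#' Marked replications are retained in the records (column `used` is set
#' to `FALSE`), so filtered and unfiltered summaries are both available.
#'
#' @param records a `replication_records` data.frame containing ITT rows
#'   (ITT defines the SE threshold).
#' @return The records with columns `iv_se_outlier` and `used` added.
#' @export
filter_replications <- function(records) {
  stopifnot(is.data.frame(records))
  if (any(records$method == "iv_interaction")) {
    if (!any(records$method == "itt"))
      stop("filter_replications needs ITT replications: the ",
           "IV(interaction) filter threshold is 10 times the ITT ",
           "empirical SE", call. = FALSE)
    est_itt <- records$estimate[records$method == "itt"]
    empse_itt <- stats::sd(est_itt, na.rm = TRUE)
    records$iv_se_outlier <- records$method == "iv_interaction" &
      !is.na(records$se) & records$se > 10 * empse_itt
  } else {
    records$iv_se_outlier <- FALSE
  }
  records$used <- !is.na(records$estimate) & !records$iv_se_outlier &
    !(records$method == "ipw" & records$ipw_dropped)
  records
}

#' Operating characteristics of a simulation study
#'
#' Computes, per estimator: the mean estimate, bias against the true
#' estimand, empirical SE (SD of the estimates), mean model SE and its
#' relative error, the non-inferiority declaration rate (the type-I error
#' when the truth equals the margin), the percentage increase in precision
#' of ITT versus the estimator, and Monte-Carlo standard errors.  The
#' precision increase is `100 * ((SE_alt / SE_ITT)^2 - 1)` using empirical
#' SEs; positive values mean ITT is more precise.
#'
#' @param records a `replication_records` data.frame; the reporting filters
#'   of [filter_replications()] are applied first unless `filtered =
#'   FALSE`.
#' @param truth true estimand (defaults to the value stored by
#'   [run_study()]).
#' @param filtered use only replications that pass the reporting filters?
#' @return A `simulation_summary` data.frame, one row per estimator.
#' @export
summarize_study <- function(records, truth = attr(records, "truth"),
                            filtered = TRUE) {
  stopifnot(is.data.frame(records), is.numeric(truth))
  if (is.null(records$used)) records <- filter_replications(records)
  if (!filtered) records$used <- !is.na(records$estimate)
  methods <- unique(records$method)
  out <- lapply(methods, function(m) {
    rm_all <- records[records$method == m, ]
    rm <- rm_all[rm_all$used, ]
    n_tot <- nrow(rm_all)
    n_used <- nrow(rm)
    if (n_used < 2L)
      return(data.frame(method = m, n_reps_total = n_tot,
                        n_reps_used = n_used, mean_estimate = NA_real_,
                        bias = NA_real_, mcse_bias = NA_real_,
                        empirical_se = NA_real_, mean_model_se = NA_real_,
                        rel_model_se_error = NA_real_, ni_rate = NA_real_,
                        mcse_ni_rate = NA_real_, empty = TRUE))
    empse <- stats::sd(rm$estimate)
    modse <- mean(rm$se, na.rm = TRUE)
    p <- mean(rm$declared, na.rm = TRUE)
    data.frame(
      method = m, n_reps_total = n_tot, n_reps_used = n_used,
      mean_estimate = mean(rm$estimate), bias = mean(rm$estimate) - truth,
      mcse_bias = empse / sqrt(n_used), empirical_se = empse,
      mean_model_se = modse,
      rel_model_se_error = 100 * (modse / empse - 1),
      ni_rate = 100 * p,
      mcse_ni_rate = 100 * sqrt(p * (1 - p) / n_used),
      empty = FALSE)
  })
  out <- do.call(rbind, out)
  if ("itt" %in% out$method) {
    se_itt <- out$empirical_se[out$method == "itt"]
    out$precision_increase_vs_itt <-
      100 * ((out$empirical_se / se_itt)^2 - 1)
  } else {
    out$precision_increase_vs_itt <- NA_real_
  }
  class(out) <- c("simulation_summary", "data.frame")
  out
}

#' Percentage increase in precision of ITT versus another estimator
#'
#' `100 * ((se_alt / se_itt)^2 - 1)`: 0 for equal empirical SEs, 300 when
#' the alternative's SE is twice the ITT SE.
#'
#' @param se_alt,se_itt empirical standard errors.
#' @return Percentage precision increase.
#' @export
precision_increase <- function(se_alt, se_itt) {
  100 * ((se_alt / se_itt)^2 - 1)
}
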