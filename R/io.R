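#' Read and write trial datasets
#'
#' Trial data are exchanged as comma-delimited text with header columns
#' `id, Z, C, X, Y` (and optionally the latent `U`, present for simulated
#' data and never read by estimators).  Reading validates the schema and
#' reports the offending column or row; writing serializes numeric columns
#' at full double precision so a write-then-read round trip reproduces the
#' dataset exactly.
#'
#' @param path file path.
#' @return `read_trial_table()` returns a validated [trial_data()] object.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  trial_data(df)
}

#' @rdname read_trial_table
#' @param data a [trial_data()] object.
#' @export
write_trial_table <- function(data, path) {
  d <- as.data.frame(data)
  d$Y <- sprintf("%.17g", d$Y)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a study configuration file
#'
#' A study configuration is a YAML file describing one simulation run:
#'
#' ```yaml
#' scenario: A1          # preset label, or an inline mapping of
#'                       # scenario_config() fields
#' estimators: [itt, pp, ipw]
#' n_reps: 2000
#' master_seed: 1
#' margin: -0.3
#' alpha_one_sided: 0.025
#' prior: {mean: 1, sd: 1}   # optional, for iv_bayes
#' output: results.csv       # optional
#' ```
#'
#' Unknown keys are rejected before any computation.
#'
#' @param path YAML file path.
#' @return A validated list of class `study_config`.
#' @export
read_study_config <- function(path) {
  # identity handlers keep YAML-1.1 boolean tokens (y/n/yes/no) as strings,
  # so the scenario field "n" survives as a key; the schema has no boolean
  # values
  cfg <- yaml::read_yaml(path, handlers = list("bool#yes" = identity,
                                               "bool#no" = identity))
  allowed <- c("scenario", "estimators", "n_reps", "master_seed", "margin",
               "alpha_one_sided", "prior", "output", "records_output")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown study-config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (req in c("scenario", "n_reps", "master_seed"))
    if (is.null(cfg[[req]]))
      stop("study config is missing required key '", req, "'",
           call. = FALSE)
  cfg$scenario <- if (is.character(cfg$scenario))
    scenario_preset(cfg$scenario)
  else do.call(scenario_config, cfg$scenario)
  if (is.null(cfg$estimators)) cfg$estimators <- c("itt", "pp", "ipw")
  if (is.null(cfg$margin)) cfg$margin <- -0.3
  if (is.null(cfg$alpha_one_sided)) cfg$alpha_one_sided <- 0.025
  if (!is.null(cfg$prior))
    cfg$prior <- prior_spec(cfg$prior$mean, cfg$prior$sd)
  class(cfg) <- "study_config"
  cfg
}

# tidy long-format summary: one metric per row
tidy_summary <- function(sm) {
  metrics <- c("mean_estimate", "bias", "empirical_se", "mean_model_se",
               "rel_model_se_error", "ni_rate", "precision_increase_vs_itt")
  rows <- lapply(seq_len(nrow(sm)), function(i) {
    mc <- c(bias = sm$mcse_bias[i], ni_rate = sm$mcse_ni_rate[i])
    data.frame(estimator = sm$method[i], metric = metrics,
               value = as.numeric(sm[i, metrics]),
               mc_se = as.numeric(mc[metrics]),
               n_reps_used = sm$n_reps_used[i])
  })
  do.call(rbind, rows)
}

cli_args_to_list <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument '", a, "'", call. = FALSE)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1], "--"))
      stop("flag '", a, "' needs a value", call. = FALSE)
    out[[key]] <- args[i + 1]
    i <- i + 2L
  }
  out
}

#' Command-line interface
#'
#' Thin command-line entry point over the package functions, used by the
#' `inst/cli/nicomply` wrapper script.  Subcommands:
#' \describe{
#'   \item{generate}{`--scenario <label> --seed <int> --out <file>
#'     [--reps <k>]`: write simulated trial CSV(s); with `--reps k > 1`,
#'     files are numbered `<out>_<i>.csv`.}
#'   \item{fit}{`--method <tag> --data <file> [--prior-mean --prior-sd]
#'     [--margin --alpha]`: fit one estimator and print the estimate plus
#'     non-inferiority decision as JSON.}
#'   \item{simulate}{`--scenario <label> --reps <n> --seed <int> --out
#'     <file> [--estimators a,b,c] [--config <yaml>] [--records <file>]`:
#'     run a full study and write the tidy long-format summary CSV
#'     (columns scenario, estimator, metric, value, mc_se, n_reps_used).}
#'   \item{summarize}{`--records <file> --truth <x> --out <file>`:
#'     recompute summaries from stored replication records.}
#' }
#'
#' @param args character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code, invisibly: 0 on success, 2 on configuration
#'   or fitting errors.  Diagnostics are logged to standard error.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (!length(args))
      stop("usage: nicomply <generate|fit|simulate|summarize> [--flags]",
           call. = FALSE)
    sub <- args[1]
    opt <- cli_args_to_list(args[-1])
    switch(sub,
           generate = cli_generate(opt),
           fit = cli_fit(opt),
           simulate = cli_simulate(opt),
           summarize = cli_summarize(opt),
           stop("unknown subcommand '", sub, "'", call. = FALSE))
    0L
  }, error = function(e) {
    message("nicomply error: ", conditionMessage(e))
    2L
  })
  invisible(code)
}

cli_generate <- function(opt) {
  for (k in c("scenario", "seed", "out"))
    if (is.null(opt[[k]])) stop("generate needs --", k, call. = FALSE)
  cfg <- scenario_preset(opt$scenario)
  reps <- as.integer(opt$reps %||% 1L)
  if (reps == 1L) {
    write_trial_table(generate_trial(cfg, seed = as.integer(opt$seed)),
                      opt$out)
    message("wrote ", opt$out)
  } else {
    set.seed(as.integer(opt$seed))
    seeds <- sample.int(.Machine$integer.max, reps)
    for (i in seq_len(reps)) {
      f <- paste0(sub("\\.csv$", "", opt$out), "_", i, ".csv")
      write_trial_table(generate_trial(cfg, seed = seeds[i]), f)
    }
    message("wrote ", reps, " trial files")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cli_fit <- function(opt) {
  for (k in c("method", "data"))
    if (is.null(opt[[k]])) stop("fit needs --", k, call. = FALSE)
  d <- read_trial_table(opt$data)
  margin <- as.numeric(opt$margin %||% -0.3)
  alpha <- as.numeric(opt$alpha %||% 0.025)
  res <- switch(opt$method,
                itt = fit_itt(d),
                pp = fit_pp(d),
                ipw = fit_ipw(d),
                iv_interaction = fit_iv_interaction(d),
                iv_bayes = fit_iv_bayes(
                  d, prior_spec(as.numeric(opt$prior_mean %||%
                                             stop("iv_bayes needs --prior-mean",
                                                  call. = FALSE)),
                                as.numeric(opt$prior_sd %||% 1))),
                stop("unknown method '", opt$method, "'", call. = FALSE))
  dec <- declare_noninferiority(res, margin, alpha)
  out <- list(method = res$method, estimate = res$estimate, se = res$se,
              interval = c(res$lower, res$upper), level = res$level,
              n_used = res$n_used, margin = margin,
              noninferiority_declared = dec$declared)
  cat(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA), "\n")
}

cli_simulate <- function(opt) {
  if (!is.null(opt$config)) {
    sc <- read_study_config(opt$config)
  } else {
    sc <- list(estimators = c("itt", "pp", "ipw"), margin = -0.3,
               alpha_one_sided = 0.025, prior = NULL)
  }
  if (!is.null(opt$scenario)) sc$scenario <- scenario_preset(opt$scenario)
  if (!is.null(opt$reps)) sc$n_reps <- as.integer(opt$reps)
  if (!is.null(opt$seed)) sc$master_seed <- as.integer(opt$seed)
  if (!is.null(opt$estimators))
    sc$estimators <- strsplit(opt$estimators, ",", fixed = TRUE)[[1]]
  if (!is.null(opt$margin)) sc$margin <- as.numeric(opt$margin)
  if (!is.null(opt$out)) sc$output <- opt$out
  if (!is.null(opt$records)) sc$records_output <- opt$records
  for (k in c("scenario", "n_reps", "master_seed", "output"))
    if (is.null(sc[[k]])) stop("simulate needs --",
                               c(scenario = "scenario", n_reps = "reps",
                                 master_seed = "seed", output = "out")[k],
                               call. = FALSE)
  rec <- run_study(sc$scenario, sc$estimators, sc$n_reps, sc$master_seed,
                   margin = sc$margin, alpha_one_sided = sc$alpha_one_sided,
                   prior = sc$prior)
  if (any(rec$method == "itt")) rec <- filter_replications(rec)
  if (!is.null(sc$records_output)) {
    utils::write.csv(rec, sc$records_output, row.names = FALSE)
    message("wrote records to ", sc$records_output)
  }
  sm <- summarize_study(rec)
  tidy <- cbind(scenario = sc$scenario$label, tidy_summary(sm))
  utils::write.csv(tidy, sc$output, row.names = FALSE)
  message("wrote summary to ", sc$output)
}

cli_summarize <- function(opt) {
  for (k in c("records", "truth", "out"))
    if (is.null(opt[[k]])) stop("summarize needs --", k, call. = FALSE)
  rec <- utils::read.csv(opt$records, stringsAsFactors = FALSE)
  sm <- summarize_study(rec, truth = as.numeric(opt$truth))
  tidy <- cbind(scenario = rec$scenario[1], tidy_summary(sm))
  utils::write.csv(tidy, opt$out, row.names = FALSE)
  message("wrote summary to ", opt$out)
}
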