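#' Run configuration for the simulate-fit-report pipeline
#'
#' A run is fully described by a config list (serializable to YAML): design
#' overrides, generating parameters per location, the simulation strategy,
#' the variants and strategies to fit, optimizer and quadrature options, and
#' the master seed. `default_run_config()` returns the package defaults
#' (the representative observer parameters per location, model averaging,
#' all four variants and three strategies); `load_run_config()` reads a YAML
#' file and merges it over the defaults.
#'
#' @param seed Master seed.
#' @param n_participants Number of simulated participants.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1, n_participants = 2) {
  structure(list(
    seed = as.integer(seed),
    n_participants = as.integer(n_participants),
    strategy = "model_averaging",
    heterogeneity = FALSE,
    params = list(
      across_blind_spot = unclass(reference_observer_params("across_blind_spot")),
      control = unclass(reference_observer_params("control"))),
    design = list(reps_per_condition = 5L),
    fit = list(variants = c("bci", "forced_fusion", "full_segregation", "mle"),
               strategies = strategy_levels(),
               n_starts = 10L, maxit = 300L,
               include_unimodal = TRUE,
               quadrature_nodes = 101L)),
    class = "run_config")
}

#' @rdname default_run_config
#' @param path Path to a YAML config file; entries override the defaults.
#' @export
load_run_config <- function(path = NULL, seed = 1) {
  cfg <- default_run_config(seed = seed)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
    class(cfg) <- "run_config"
  }
  cfg
}

config_design <- function(config) {
  design_spec(reps_per_condition = config$design$reps_per_condition)
}

config_params <- function(config) {
  lapply(config$params, function(p) do.call(bci_params, p))
}

config_settings <- function(config) {
  quadrature_settings(n_nodes = config$fit$quadrature_nodes)
}

#' Pipeline stage: simulate a cohort to disk
#'
#' Simulates a cohort under the config and writes `trials.csv`,
#' `generating_params.csv`, and a `manifest.json` recording the config, the
#' derived per-participant seeds, and a checksum of the trial table. Running
#' the same config twice produces byte-identical outputs.
#'
#' @param config A `run_config` list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
pipeline_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(
    n_participants = config$n_participants,
    params_by_location = config_params(config),
    strategy = config$strategy,
    design = config_design(config),
    seed = config$seed,
    heterogeneity = if (isTRUE(config$heterogeneity)) TRUE else NULL)

  trials_path <- file.path(out_dir, "trials.csv")
  params_path <- file.path(out_dir, "generating_params.csv")
  write_trials(cohort$trials, trials_path)
  utils::write.csv(cohort$participants, params_path, row.names = FALSE)

  manifest <- list(stage = "simulate", seed = config$seed,
                   config = unclass(config),
                   participant_seeds = as.list(cohort$seeds),
                   trials_md5 = unname(tools::md5sum(trials_path)),
                   n_trials = nrow(cohort$trials))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(trials = trials_path, params = params_path,
              manifest = file.path(out_dir, "manifest.json")))
}

#' Pipeline stage: fit models to a trial table
#'
#' Fits the configured variants and strategies per participant and location
#' via [compare_models()] and writes `fits.csv` plus `fits.json`. Schema
#' violations in the input table are rejected with row-level diagnostics.
#'
#' @param trials A trial data.frame or the path to a trials CSV.
#' @inheritParams pipeline_simulate
#' @return The fit table, invisibly; also written to `out_dir`.
#' @export
pipeline_fit <- function(trials, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(trials)) trials <- read_trials(trials)
  validate_trials(trials)
  settings <- config_settings(config)

  cells <- unique(trials[, c("participant", "location")])
  cells <- cells[order(cells$participant, cells$location), ]
  fits <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- trials[trials$participant == cells$participant[i] &
                  trials$location == cells$location[i], ]
    cmp <- compare_models(sub,
                          variants = config$fit$variants,
                          strategies = config$fit$strategies,
                          n_starts = config$fit$n_starts,
                          seed = derive_seed(config$seed, i),
                          settings = settings,
                          include_unimodal = config$fit$include_unimodal,
                          maxit = config$fit$maxit)
    cbind(participant = cells$participant[i], location = cells$location[i],
          cmp)
  }))
  rownames(fits) <- NULL

  utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(stage = "fit", seed = config$seed,
         bic_convention = "2*nll + k*log(n), n = trials in likelihood",
         fits = fits),
    file.path(out_dir, "fits.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(fits)
}

#' Pipeline stage: human-readable report
#'
#' Aggregates trial and fit tables into a markdown report mirroring the
#' standard reporting shapes of the paradigm: accuracy by condition,
#' illusion rates, signal-detection measures by beep context, BIC by
#' variant, and winning-fit parameter means with standard errors. Missing
#' inputs are named explicitly; regeneration is idempotent.
#'
#' @param out_dir Directory holding `trials.csv` and (optionally)
#'   `fits.csv`; the report is written there as `report.md`.
#' @return The report path, invisibly.
#' @export
pipeline_report <- function(out_dir) {
  trials_path <- file.path(out_dir, "trials.csv")
  fits_path <- file.path(out_dir, "fits.csv")
  if (!file.exists(trials_path)) {
    stop("missing input: ", trials_path, call. = FALSE)
  }
  trials <- read_trials(trials_path)
  lines <- c("# Pipeline report", "")

  acc <- accuracy_by_condition(trials)
  acc <- acc[!is.na(acc$accuracy), ]
  lines <- c(lines, "## Accuracy by condition", "",
             md_table(transform(acc, accuracy = round(accuracy, 3))), "")

  ill <- illusion_frequency(trials)
  lines <- c(lines, "## Illusion rates", "",
             md_table(transform(ill,
                                illusory_rate = round(illusory_rate, 3),
                                invisible_rate = round(invisible_rate, 3))),
             "")

  sdt <- sdt_summary(trials)
  sdt_mean <- stats::aggregate(cbind(d_prime, criterion) ~ context + location,
                               data = sdt, FUN = mean)
  lines <- c(lines, "## Signal detection (mean over participants)", "",
             md_table(transform(sdt_mean, d_prime = round(d_prime, 3),
                                criterion = round(criterion, 3))), "")

  if (file.exists(fits_path)) {
    fits <- utils::read.csv(fits_path, stringsAsFactors = FALSE)
    bic_mean <- stats::aggregate(bic ~ variant, data = fits[!fits$alias, ],
                                 FUN = function(x) round(mean(x), 2))
    lines <- c(lines, "## Mean BIC by variant", "", md_table(bic_mean), "")
    win <- fits[fits$winner, ]
    par_cols <- c("p_common", "mu_p", "sigma_p", "sigma_v", "sigma_a")
    par_tab <- do.call(rbind, lapply(sort(unique(win$location)), function(loc) {
      sub <- win[win$location == loc, par_cols, drop = FALSE]
      data.frame(location = loc, parameter = par_cols,
                 mean = round(colMeans(sub), 3),
                 se = round(apply(sub, 2, stats::sd) / sqrt(nrow(sub)), 3))
    }))
    rownames(par_tab) <- NULL
    lines <- c(lines, "## Winning-fit parameters (mean +/- SE)", "",
               md_table(par_tab), "")
  } else {
    lines <- c(lines, "## Model fits", "",
               "No fits available (fits.csv not found).", "")
  }
  report_path <- file.path(out_dir, "report.md")
  writeLines(lines, report_path)
  invisible(report_path)
}

#' Pipeline stage: parameter-recovery run
#'
#' Simulates a cohort, fits the full BCI model to every participant, and
#' scores the fits against the generating parameters. This is the one-stop
#' validation that the whole pipeline (generator, likelihood, optimizer)
#' round-trips.
#'
#' @inheritParams pipeline_simulate
#' @param per_location Fit each location separately (`TRUE`, default) or
#'   pool all of a participant's trials into one fit (`FALSE`; appropriate
#'   when both locations share generating parameters).
#' @return A list with `fits` (per participant), `recovery` (generating vs.
#'   recovered parameter table) and `summary` (means over participants);
#'   written to `out_dir` when given.
#' @export
pipeline_recover <- function(config, out_dir = NULL, per_location = TRUE) {
  design <- config_design(config)
  cohort <- simulate_cohort(
    n_participants = config$n_participants,
    params_by_location = config_params(config),
    strategy = config$strategy, design = design, seed = config$seed,
    heterogeneity = if (isTRUE(config$heterogeneity)) TRUE else NULL)
  settings <- config_settings(config)

  cells <- if (per_location) {
    unique(cohort$trials[, c("participant", "location")])
  } else {
    data.frame(participant = unique(cohort$trials$participant),
               location = "pooled")
  }
  rec <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- cohort$trials[cohort$trials$participant == cells$participant[i], ]
    if (per_location) sub <- sub[sub$location == cells$location[i], ]
    fit <- fit_model(sub, model_variant("bci"), config$strategy,
                     n_starts = config$fit$n_starts,
                     seed = derive_seed(config$seed, 1000L + i),
                     settings = settings,
                     include_unimodal = config$fit$include_unimodal,
                     maxit = config$fit$maxit)
    gen_loc <- if (per_location) cells$location[i] else
      cohort$participants$location[1]
    gen <- cohort$participants[
      cohort$participants$participant == cells$participant[i] &
      cohort$participants$location == gen_loc, ]
    data.frame(participant = cells$participant[i],
               location = cells$location[i],
               parameter = c("p_common", "mu_p", "sigma_p", "sigma_v", "sigma_a"),
               generating = unlist(gen[1, c("p_common", "mu_p", "sigma_p",
                                            "sigma_v", "sigma_a")]),
               recovered = unlist(unclass(fit$params)),
               r2 = fit$r2, nll = fit$nll, converged = fit$converged)
  }))
  rownames(rec) <- NULL
  summary <- stats::aggregate(cbind(generating, recovered) ~ parameter +
                                location, data = rec, FUN = mean)
  out <- list(recovery = rec, summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rec, file.path(out_dir, "recovery.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out, file.path(out_dir, "recovery.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

md_table <- function(df) {
  df[] <- lapply(df, as.character)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}
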