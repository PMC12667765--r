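#' Negative log-likelihood of trial-level reports
#'
#' Sums `-log P(reported category | condition, parameters, strategy)` over
#' trials, with the per-condition category probabilities computed by
#' [predict_response_distribution()]. Flash-block trials contribute through
#' the visual margin and beep-block trials through the auditory margin.
#' Beep-block trials of visual-only conditions carry no information (the
#' zero-beep report is deterministic) and are skipped. Predicted
#' probabilities are floored at `1e-12` before taking logs so stray
#' responses cannot produce infinite objectives.
#'
#' All trials supplied are evaluated under the single parameter set given;
#' group trials by participant and location before calling if parameters
#' differ across those factors.
#'
#' @param trials A trial data.frame (see [simulate_participant()] for the
#'   schema).
#' @param params A [bci_params] object.
#' @param strategy One of [strategy_levels()].
#' @param variant Optional [model_variant]; its fixings are imposed on
#'   `params` before evaluation.
#' @param settings A [quadrature_settings] object.
#' @param include_unimodal Include visual-only (`B0`) flash-block trials in
#'   the likelihood (default `TRUE`).
#' @return The negative log-likelihood (nonnegative).
#' @export
negative_log_likelihood <- function(trials, params, strategy = "model_averaging",
                                    variant = NULL,
                                    settings = quadrature_settings(),
                                    include_unimodal = TRUE) {
  if (is.null(trials) || nrow(trials) == 0) {
    stop("`trials` must contain at least one trial", call. = FALSE)
  }
  if (!is.null(variant)) params <- apply_variant(params, variant)
  counts <- aggregate_response_counts(trials, include_unimodal)
  nll_from_counts(counts, params, strategy, settings)
}

# Collapse trials to counts per (n_flashes, n_beeps, block, response).
# Trajectory and location do not enter the numerosity model.
aggregate_response_counts <- function(trials, include_unimodal = TRUE) {
  keep <- !(trials$block == "beep" & trials$n_beeps == 0)
  if (!include_unimodal) keep <- keep & !(trials$n_beeps == 0)
  t2 <- trials[keep, c("n_flashes", "n_beeps", "block", "response")]
  if (nrow(t2) == 0) {
    stop("no trials remain after excluding uninformative rows", call. = FALSE)
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(t2))), by = t2, FUN = sum)
  agg
}

nll_from_counts <- function(counts, params, strategy, settings,
                            floor = 1e-12) {
  stim <- unique(counts[, c("n_flashes", "n_beeps")])
  nll <- 0
  for (i in seq_len(nrow(stim))) {
    f <- stim$n_flashes[i]; b <- stim$n_beeps[i]
    dist <- predict_response_distribution(
      stimulus_condition(f, b), params, strategy, settings)
    rows <- counts[counts$n_flashes == f & counts$n_beeps == b, ]
    for (j in seq_len(nrow(rows))) {
      p_vec <- if (rows$block[j] == "flash") dist$p_visual else dist$p_auditory
      p <- p_vec[match(rows$response[j], dist$categories)]
      if (is.na(p)) p <- 0
      nll <- nll - rows$count[j] * log(max(p, floor))
    }
  }
  nll
}

#' Bayesian information criterion
#'
#' `BIC = 2 * nll + k * log(n)` with `nll` the negative log-likelihood at
#' the maximum, `k` the free-parameter count, and `n` the number of trials
#' entering the likelihood. Only differences between models fitted to the
#' same trials are meaningful; lower is better.
#'
#' @param nll Negative log-likelihood.
#' @param k Free-parameter count.
#' @param n Number of observations.
#' @return The BIC value.
#' @examples
#' bic(100, 5, 480)
#' @export
bic <- function(nll, k, n) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  if (k < 0) stop("`k` must be nonnegative", call. = FALSE)
  2 * nll + k * log(n)
}

# Map free parameters between the bounded natural scale and an unconstrained
# scale (scaled logit per parameter) for the optimizer.
to_unconstrained <- function(x, bounds) {
  u <- (x - bounds[1, ]) / (bounds[2, ] - bounds[1, ])
  u <- pmin(1 - 1e-9, pmax(1e-9, u))
  stats::qlogis(u)
}

to_natural <- function(z, bounds) {
  bounds[1, ] + (bounds[2, ] - bounds[1, ]) * stats::plogis(z)
}

#' Fit a BCI model variant by maximum likelihood
#'
#' Multi-start bounded maximization of the likelihood in
#' [negative_log_likelihood()]. Free parameters (those not fixed by the
#' variant) are optimized on an unconstrained scale via a scaled-logit
#' transform of their bounds (`p_common` in `[0,1]`, `mu_p` in `[0,5]`,
#' `sigma_p`, `sigma_v`, `sigma_a` in `[0.05,10]`) with Nelder-Mead, from
#' `n_starts` seeded Latin-hypercube initial points. Optimization is
#' coarse-to-fine: exploratory runs and basin polishing use a
#' half-resolution quadrature grid (the smooth marginalization makes the
#' objective nearly grid-independent), and the winning candidate is
#' refined on the full grid in `settings`.
#'
#' @inheritParams negative_log_likelihood
#' @param variant A [model_variant] (default the full 5-parameter model).
#' @param n_starts Number of Latin-hypercube starts (default 10).
#' @param seed Integer seed controlling the start points.
#' @param maxit Maximum Nelder-Mead iterations per exploratory start.
#' @param n_polish Number of best exploratory starts to polish with
#'   restarted Nelder-Mead runs (restarts stop once an additional run
#'   improves the objective by less than `1e-4`).
#' @param reltol Relative convergence tolerance on the objective.
#' @param r2_mode Goodness-of-fit mode passed to [goodness_of_fit_r2()].
#' @return An object of class `bci_fit`: the fitted [bci_params], `nll`,
#'   `k`, `n`, `bic`, `r2`, `strategy`, `variant`, `n_starts`, `converged`,
#'   and the per-start objective values (`start_nll`).
#' @examples
#' \donttest{
#' p <- reference_observer_params()
#' trials <- simulate_participant(list(across_blind_spot = p, control = p),
#'                                seed = 1)
#' fit <- fit_model(trials, model_variant("mle"), n_starts = 2, seed = 1,
#'                  settings = quadrature_settings(61))
#' fit$bic
#' }
#' @export
fit_model <- function(trials, variant = model_variant("bci"),
                      strategy = "model_averaging", n_starts = 10, seed = 1,
                      settings = quadrature_settings(),
                      include_unimodal = TRUE, maxit = 300, n_polish = 3,
                      reltol = 1e-8, r2_mode = "proportions") {
  strategy <- match.arg(strategy, strategy_levels())
  stopifnot(inherits(variant, "bci_variant"))
  counts <- aggregate_response_counts(trials, include_unimodal)
  n_obs <- sum(counts$count)

  all_b <- param_bounds()
  free <- variant$free
  bounds <- vapply(free, function(nm) all_b[[nm]], numeric(2))

  make_objective <- function(sett) {
    function(z) {
      x <- to_natural(z, bounds)
      p <- as.list(x)
      names(p) <- free
      for (nm in names(variant$fixed)) p[[nm]] <- unname(variant$fixed[[nm]])
      p <- structure(p[c("p_common", "mu_p", "sigma_p", "sigma_v", "sigma_a")],
                     class = "bci_params")
      nll_from_counts(counts, p, strategy, sett)
    }
  }
  coarse <- quadrature_settings(max(41L, (settings$n_nodes + 1L) %/% 2L),
                                settings$width_sd)
  obj_coarse <- make_objective(coarse)
  obj_fine <- make_objective(settings)

  # A fresh simplex at the incumbent point escapes premature simplex
  # collapse; restart until the objective stops improving.
  restart_nm <- function(obj, r, n_restarts) {
    done <- FALSE
    for (rep in seq_len(n_restarts)) {
      r2 <- stats::optim(r$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 2 * maxit, reltol = reltol))
      done <- (r$value - r2$value) < 1e-4
      r <- r2
      if (done) break
    }
    r$stable <- done
    r
  }

  starts <- withr::with_seed(as.integer(seed), {
    u <- lhs::randomLHS(n_starts, length(free))
    0.02 + 0.96 * u
  })

  # Phase 1: short exploratory runs from every start on the coarse grid.
  explore <- lapply(seq_len(n_starts), function(s) {
    stats::optim(stats::qlogis(starts[s, ]), obj_coarse,
                 method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-7))
  })
  start_nll <- vapply(explore, `[[`, numeric(1), "value")

  # Phase 2: restart-polish the most promising basins (coarse grid).
  polish_idx <- order(start_nll)[seq_len(min(n_polish, n_starts))]
  cands <- lapply(polish_idx, function(i) {
    restart_nm(obj_coarse, explore[[i]], 4L)
  })

  # Phase 3: refine the winning candidate on the full grid.
  best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "value"))]]
  best$value <- obj_fine(best$par)
  best <- restart_nm(obj_fine, best, 3L)
  conv <- best$stable || best$convergence == 0

  x_hat <- to_natural(best$par, bounds)
  p_hat <- as.list(x_hat)
  names(p_hat) <- free
  for (nm in names(variant$fixed)) p_hat[[nm]] <- unname(variant$fixed[[nm]])
  params_hat <- do.call(bci_params, p_hat[c("p_common", "mu_p", "sigma_p",
                                            "sigma_v", "sigma_a")])

  r2 <- goodness_of_fit_r2(trials, params_hat, strategy, settings = settings,
                           include_unimodal = include_unimodal,
                           mode = r2_mode)
  structure(list(params = params_hat, nll = best$value, k = variant$k,
                 n = n_obs, bic = bic(best$value, variant$k, n_obs), r2 = r2,
                 strategy = strategy, variant = variant$name,
                 n_starts = n_starts, converged = conv,
                 start_nll = start_nll, seed = as.integer(seed)),
            class = "bci_fit")
}

#' @export
print.bci_fit <- function(x, ...) {
  cat(sprintf("BCI fit: variant = %s, strategy = %s\n", x$variant, x$strategy))
  print(x$params)
  cat(sprintf("  nll = %.3f  k = %d  n = %d  BIC = %.3f  R2 = %.4f  converged = %s\n",
              x$nll, x$k, x$n, x$bic, x$r2, x$converged))
  invisible(x)
}

#' Goodness of fit (coefficient of determination)
#'
#' Compares observed responses with model predictions as `R^2 = 1 -
#' SS_res / SS_tot`. In `"proportions"` mode (default) the units are the
#' observed response-category proportions versus predicted probabilities,
#' pooled over stimulus x category x modality cells; in `"means"` mode they
#' are per-condition mean reported counts versus model-expected counts.
#'
#' @inheritParams negative_log_likelihood
#' @param mode `"proportions"` or `"means"`.
#' @param predictor `"model"` (default) scores the BCI predictions;
#'   `"grand_mean"` scores the degenerate predictor that forecasts the
#'   grand mean of the observations everywhere, which yields 0 by
#'   definition and anchors the scale.
#' @return `R^2` (at most 1), or `NA` if the observations have zero
#'   variance.
#' @export
goodness_of_fit_r2 <- function(trials, params, strategy = "model_averaging",
                               settings = quadrature_settings(),
                               include_unimodal = TRUE,
                               mode = c("proportions", "means"),
                               predictor = c("model", "grand_mean")) {
  mode <- match.arg(mode)
  predictor <- match.arg(predictor)
  counts <- aggregate_response_counts(trials, include_unimodal)
  stim <- unique(counts[, c("n_flashes", "n_beeps")])
  obs <- numeric(0); pred <- numeric(0)
  for (i in seq_len(nrow(stim))) {
    f <- stim$n_flashes[i]; b <- stim$n_beeps[i]
    dist <- predict_response_distribution(stimulus_condition(f, b), params,
                                          strategy, settings)
    for (blk in unique(counts$block[counts$n_flashes == f &
                                    counts$n_beeps == b])) {
      rows <- counts[counts$n_flashes == f & counts$n_beeps == b &
                     counts$block == blk, ]
      n_cell <- sum(rows$count)
      p_vec <- if (blk == "flash") dist$p_visual else dist$p_auditory
      o_vec <- vapply(dist$categories, function(cat) {
        sum(rows$count[rows$response == cat]) / n_cell
      }, numeric(1))
      if (mode == "proportions") {
        obs <- c(obs, o_vec); pred <- c(pred, p_vec)
      } else {
        obs <- c(obs, sum(dist$categories * o_vec))
        pred <- c(pred, sum(dist$categories * p_vec))
      }
    }
  }
  if (predictor == "grand_mean") pred <- rep(mean(obs), length(obs))
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / ss_tot
}

#' Fit and compare all model variants and strategies
#'
#' Fits the four model variants crossed with the three decision strategies
#' to one participant-by-location trial set and flags the minimum-BIC fit
#' as the winner. Strategies only alter predictions when causal inference
#' is active (i.e., `p_common` free); for variants with `p_common` fixed at
#' 0 or 1 the three strategies coincide, so a single fit is performed and
#' the duplicates are recorded as aliases.
#'
#' @inheritParams fit_model
#' @param variants Character vector of variant names to fit.
#' @param strategies Character vector of strategy names to fit.
#' @return A data.frame with one row per variant x strategy: parameter
#'   estimates, `nll`, `k`, `n`, `bic`, `r2`, `converged`, `alias` (TRUE for
#'   rows duplicating a fixed-`p_common` fit) and `winner` (TRUE on exactly
#'   one row). The `bci_fit` objects are attached as the `"fits"` attribute.
#' @export
compare_models <- function(trials,
                           variants = c("bci", "forced_fusion",
                                        "full_segregation", "mle"),
                           strategies = strategy_levels(),
                           n_starts = 10, seed = 1,
                           settings = quadrature_settings(),
                           include_unimodal = TRUE, maxit = 300,
                           n_polish = 3, reltol = 1e-8) {
  rows <- list(); fits <- list()
  for (v in variants) {
    variant <- model_variant(v)
    degenerate <- "p_common" %in% names(variant$fixed) &&
      variant$fixed[["p_common"]] %in% c(0, 1)
    strat_to_fit <- if (degenerate) strategies[1] else strategies
    fitted <- list()
    for (st in strat_to_fit) {
      fitted[[st]] <- fit_model(trials, variant, st, n_starts = n_starts,
                                seed = seed, settings = settings,
                                include_unimodal = include_unimodal,
                                maxit = maxit, n_polish = n_polish,
                                reltol = reltol)
    }
    for (st in strategies) {
      f <- if (st %in% names(fitted)) fitted[[st]] else fitted[[strat_to_fit[1]]]
      alias <- !(st %in% names(fitted))
      key <- paste(v, st, sep = ".")
      fits[[key]] <- f
      rows[[key]] <- data.frame(variant = v, strategy = st,
                                as.data.frame(unclass(f$params)),
                                nll = f$nll, k = f$k, n = f$n, bic = f$bic,
                                r2 = f$r2, converged = f$converged,
                                alias = alias)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$winner <- FALSE
  cand <- which(!out$alias)
  out$winner[cand[which.min(out$bic[cand])]] <- TRUE
  attr(out, "fits") <- fits
  out
}
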