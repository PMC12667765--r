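#' Factorial design of the audiovisual rabbit task
#'
#' The default design crosses 2 flash counts, 3 beep counts, 4 sweep
#' trajectories, and 2 stimulus locations (48 conditions), each repeated 5
#' times per block, in two report blocks (flash report, beep report): 240
#' trials per block, 480 per participant.
#'
#' @param flash_levels Integer flash counts.
#' @param beep_levels Integer beep counts (0 = visual-only).
#' @param trajectories Trajectory level names.
#' @param locations Location level names.
#' @param reps_per_condition Repetitions of each condition within a block.
#' @param blocks Report blocks.
#' @return An object of class `av_design`.
#' @examples
#' d <- design_spec()
#' nrow(condition_grid(d))  # 48
#' @export
design_spec <- function(flash_levels = c(2L, 3L),
                        beep_levels = c(0L, 2L, 3L),
                        trajectories = trajectory_levels(),
                        locations = location_levels(),
                        reps_per_condition = 5L,
                        blocks = c("flash", "beep")) {
  if (length(flash_levels) == 0 || length(beep_levels) == 0 ||
      length(trajectories) == 0 || length(locations) == 0 ||
      length(blocks) == 0) {
    stop("every design factor needs at least one level", call. = FALSE)
  }
  if (reps_per_condition < 0) {
    stop("`reps_per_condition` must be nonnegative", call. = FALSE)
  }
  structure(list(flash_levels = as.integer(flash_levels),
                 beep_levels = as.integer(beep_levels),
                 trajectories = trajectories, locations = locations,
                 reps_per_condition = as.integer(reps_per_condition),
                 blocks = blocks),
            class = "av_design")
}

#' @rdname design_spec
#' @param design An `av_design` object.
#' @export
condition_grid <- function(design = design_spec()) {
  g <- expand.grid(n_flashes = design$flash_levels,
                   n_beeps = design$beep_levels,
                   trajectory = design$trajectories,
                   location = design$locations,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$condition <- condition_label(g$n_flashes, g$n_beeps)
  g
}

#' Build a randomized trial schedule
#'
#' Within each block, every condition of the design appears exactly
#' `reps_per_condition` times; the order within a block is a seeded random
#' permutation.
#'
#' @param design An [design_spec()] object.
#' @param seed Integer seed for the permutations.
#' @return A data.frame with one row per trial: `block`, `trial` (index
#'   within block), `condition`, `n_flashes`, `n_beeps`, `trajectory`,
#'   `location`.
#' @export
build_trial_schedule <- function(design = design_spec(), seed = 1) {
  grid <- condition_grid(design)
  withr::with_seed(as.integer(seed), {
    blocks <- lapply(design$blocks, function(b) {
      idx <- rep(seq_len(nrow(grid)), times = design$reps_per_condition)
      idx <- idx[sample.int(length(idx))]
      out <- grid[idx, , drop = FALSE]
      out$block <- rep(b, nrow(out))
      out$trial <- seq_len(nrow(out))
      out
    })
    out <- do.call(rbind, blocks)
  })
  rownames(out) <- NULL
  out[, c("block", "trial", "condition", "n_flashes", "n_beeps",
          "trajectory", "location")]
}

# Positions marked for a report of k flashes: k of the five response-screen
# positions, symmetric about the trajectory midpoint (position 3), with the
# midpoint included for odd k. Plumbing for position analyses; the
# generative model itself is numerosity-only.
positions_for_count <- function(k) {
  map <- list(`0` = integer(0), `1` = 3L, `2` = c(1L, 5L), `3` = c(1L, 3L, 5L),
              `4` = c(1L, 2L, 4L, 5L), `5` = 1:5)
  map[[as.character(k)]]
}

format_positions <- function(k) {
  vapply(k, function(ki) paste(positions_for_count(ki), collapse = ";"), "")
}

#' Parse a positions field back into integer positions
#'
#' @param x Character vector of `";"`-separated position reports.
#' @return A list of integer vectors.
#' @export
parse_positions <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE),
         function(p) as.integer(p[nzchar(p)]))
}

#' Simulate one participant from the BCI generative model
#'
#' Runs the full generative chain trial by trial: sensations are sampled
#' around the true counts, the causal posterior and conditional estimates
#' are computed, the decision strategy is applied (probability matching
#' draws its uniform threshold per trial), and the final continuous estimate
#' is binned into the reported count. Flash-block trials record the visual
#' report plus a position report derived from the count; beep-block trials
#' record the auditory report (0 on visual-only trials, where no beep is
#' presented). Visual-only flash trials involve no causal inference: the
#' report combines the visual sensation with the numerosity prior.
#'
#' @param params_by_location Named list mapping each design location to a
#'   [bci_params] object.
#' @param strategy One of [strategy_levels()].
#' @param design An [design_spec()] object.
#' @param seed Integer seed; the full trial list is reproducible from it.
#' @param participant Participant identifier stored in the output.
#' @return A data.frame of trials with columns `participant`, `block`,
#'   `trial`, `condition`, `n_flashes`, `n_beeps`, `trajectory`, `location`,
#'   `response`, `positions`.
#' @examples
#' p <- reference_observer_params()
#' trials <- simulate_participant(
#'   list(across_blind_spot = p, control = p),
#'   strategy = "model_averaging", seed = 7)
#' table(trials$block)
#' @export
simulate_participant <- function(params_by_location,
                                 strategy = "model_averaging",
                                 design = design_spec(), seed = 1,
                                 participant = "P01") {
  strategy <- match.arg(strategy, strategy_levels())
  missing_loc <- setdiff(design$locations, names(params_by_location))
  if (length(missing_loc) > 0) {
    stop("missing parameters for location(s): ",
         paste(missing_loc, collapse = ", "), call. = FALSE)
  }
  for (p in params_by_location) validate_bci_params(p)

  sched <- build_trial_schedule(design, seed = seed)
  sched$response <- NA_integer_
  sched$positions <- NA_character_

  withr::with_seed(derive_seed(seed, 1L), {
    for (loc in design$locations) {
      pars <- params_by_location[[loc]]
      for (blk in design$blocks) {
        rows <- which(sched$location == loc & sched$block == blk)
        if (length(rows) == 0) next
        sub <- sched[rows, ]
        n <- nrow(sub)
        x_v <- stats::rnorm(n, sub$n_flashes, pars$sigma_v)
        bim <- sub$n_beeps > 0
        x_a <- rep(NA_real_, n)
        x_a[bim] <- stats::rnorm(sum(bim), sub$n_beeps[bim], pars$sigma_a)
        xi <- if (strategy == "probability_matching") stats::runif(n) else NULL

        s_v <- s_a <- rep(NA_real_, n)
        if (any(bim)) {
          post <- posterior_common(x_v[bim], x_a[bim], pars)
          e2 <- estimate_independent(x_v[bim], x_a[bim], pars)
          est <- apply_strategy(strategy, post,
                                list(s_c1 = estimate_common(x_v[bim], x_a[bim], pars),
                                     s_v_c2 = e2$s_v, s_a_c2 = e2$s_a),
                                xi = xi[bim])
          s_v[bim] <- est$s_v
          s_a[bim] <- est$s_a
        }
        if (any(!bim)) {
          s_v[!bim] <- estimate_independent(x_v[!bim], NULL, pars)$s_v
          s_a[!bim] <- 0  # no beeps presented, none perceived
        }

        if (blk == "flash") {
          resp <- bin_estimate(s_v)
          sched$positions[rows] <- format_positions(resp)
        } else {
          resp <- bin_estimate(s_a)
        }
        sched$response[rows] <- as.integer(resp)
      }
    }
  })
  cbind(participant = participant, sched)
}

# Deterministic sub-seed derivation, kept within 32-bit signed range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 9973) %% 2147483587)
}

#' Simulate a cohort of participants
#'
#' Participants are simulated independently with seeds derived from the
#' cohort seed, so any participant is reproducible from (seed, index).
#' Parameters are either fixed (shared by all participants) or drawn per
#' participant from Gaussians centered on the supplied means with
#' `heterogeneity` s.d.s, truncated to the fitting bounds.
#'
#' @inheritParams simulate_participant
#' @param n_participants Number of participants.
#' @param heterogeneity `NULL` for a fixed-parameter cohort, or a named list
#'   mapping locations to named s.d. vectors (defaults per location to
#'   [reference_observer_se()] when `TRUE`).
#' @return A list of class `av_cohort` with elements `trials` (all trials,
#'   row-bound), `participants` (generating parameters per participant and
#'   location) and `seeds`.
#' @export
simulate_cohort <- function(n_participants, params_by_location,
                            strategy = "model_averaging",
                            design = design_spec(), seed = 1,
                            heterogeneity = NULL) {
  if (n_participants < 1) stop("`n_participants` must be >= 1", call. = FALSE)
  if (isTRUE(heterogeneity)) {
    heterogeneity <- lapply(stats::setNames(nm = design$locations), function(loc) {
      reference_observer_se(loc)
    })
  }
  seeds <- vapply(seq_len(n_participants), function(i) derive_seed(seed, i), 1L)
  ids <- sprintf("P%02d", seq_len(n_participants))

  trials <- vector("list", n_participants)
  gen <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    pars_i <- params_by_location
    if (!is.null(heterogeneity)) {
      pars_i <- withr::with_seed(derive_seed(seeds[i], 7L), {
        lapply(stats::setNames(nm = design$locations), function(loc) {
          sample_observer_params(params_by_location[[loc]],
                                 heterogeneity[[loc]])
        })
      })
    }
    trials[[i]] <- simulate_participant(pars_i, strategy = strategy,
                                        design = design, seed = seeds[i],
                                        participant = ids[i])
    gen[[i]] <- do.call(rbind, lapply(design$locations, function(loc) {
      data.frame(participant = ids[i], location = loc,
                 as.data.frame(unclass(pars_i[[loc]])))
    }))
  }
  structure(list(trials = do.call(rbind, trials),
                 participants = do.call(rbind, gen),
                 seeds = stats::setNames(seeds, ids)),
            class = "av_cohort")
}

# Draw one observer's parameters around the given means, truncated to the
# fitting bounds by rejection (with clamping as a last resort).
sample_observer_params <- function(means, sds) {
  b <- param_bounds()
  out <- unlist(unclass(means))
  for (nm in names(sds)) {
    if (sds[[nm]] <= 0) next
    lo <- b[[nm]][1]; hi <- b[[nm]][2]
    if (stats::pnorm(hi, out[[nm]], sds[[nm]]) -
        stats::pnorm(lo, out[[nm]], sds[[nm]]) <= 0) {
      stop("degenerate parameter sampler for `", nm, "`: no mass in bounds",
           call. = FALSE)
    }
    val <- stats::rnorm(1, out[[nm]], sds[[nm]])
    for (dummy in 1:20) {
      if (val >= lo && val <= hi) break
      val <- stats::rnorm(1, out[[nm]], sds[[nm]])
    }
    out[[nm]] <- min(hi, max(lo, val))
  }
  do.call(bci_params, as.list(out))
}

#' Read and write trial tables
#'
#' Trial tables are plain CSV with the documented column schema (see
#' [simulate_participant()]). `read_trials()` validates the schema and
#' condition labels, reporting offending row indices.
#'
#' @param trials A trial data.frame.
#' @param path File path.
#' @return `read_trials()` returns the validated data.frame.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("positions" %in% names(df)) df$positions <- as.character(df$positions)
  validate_trials(df)
}

#' @rdname write_trials
#' @param df A candidate trial data.frame.
#' @export
validate_trials <- function(df) {
  required <- c("participant", "block", "trial", "condition", "n_flashes",
                "n_beeps", "trajectory", "location", "response")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ok <- grepl("^F[0-9]+B[0-9]+$", df$condition)
  if (any(!ok)) {
    stop("malformed condition label at row(s): ",
         paste(utils::head(which(!ok), 10), collapse = ", "), call. = FALSE)
  }
  parsed <- parse_condition_label(df$condition)
  mism <- which(parsed$n_flashes != df$n_flashes | parsed$n_beeps != df$n_beeps)
  if (length(mism) > 0) {
    stop("condition label disagrees with counts at row(s): ",
         paste(utils::head(mism, 10), collapse = ", "), call. = FALSE)
  }
  bad_loc <- which(!df$location %in% location_levels())
  if (length(bad_loc) > 0) {
    stop("unknown location at row(s): ",
         paste(utils::head(bad_loc, 10), collapse = ", "), call. = FALSE)
  }
  df
}
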