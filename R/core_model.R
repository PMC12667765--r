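#' Draw noisy sensations for a stimulus condition
#'
#' Each presented sequence of `n_flashes` flashes and `n_beeps` beeps gives
#' rise to noisy internal counts `x_v ~ N(n_flashes, sigma_v)` and
#' `x_a ~ N(n_beeps, sigma_a)`, drawn independently. On visual-only trials
#' (`n_beeps == 0`) no auditory sensation exists and `x_a` is `NA`.
#'
#' @param cond An [stimulus_condition] object (or any list with `n_flashes`
#'   and `n_beeps`).
#' @param params A [bci_params] object.
#' @param n Number of independent draws.
#' @param seed Integer seed; identical seeds give identical draws.
#' @return A data.frame with columns `x_v` and `x_a` (`x_a` all `NA` for
#'   visual-only conditions).
#' @examples
#' sample_sensations(stimulus_condition(2, 3),
#'                   reference_observer_params(), n = 5, seed = 1)
#' @export
sample_sensations <- function(cond, params, n, seed) {
  validate_bci_params(params)
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    x_v <- stats::rnorm(n, cond$n_flashes, params$sigma_v)
    x_a <- if (cond$n_beeps > 0) {
      stats::rnorm(n, cond$n_beeps, params$sigma_a)
    } else {
      rep(NA_real_, n)
    }
    data.frame(x_v = x_v, x_a = x_a)
  })
}

#' Sensation likelihoods under common and independent causes
#'
#' `likelihood_common()` evaluates the joint density of a bimodal sensation
#' pair assuming one shared source count `s` drawn from the numerosity prior:
#' the integral of `N(x_v; s, sigma_v) * N(x_a; s, sigma_a) * N(s; mu_p,
#' sigma_p)` over `s`, in closed form. `likelihood_independent()` assumes
#' separate source counts per modality, giving the product
#' `N(x_v; mu_p, sqrt(sigma_v^2 + sigma_p^2)) * N(x_a; mu_p,
#' sqrt(sigma_a^2 + sigma_p^2))`. Both are vectorized over `x_v`, `x_a`.
#'
#' @param x_v,x_a Numeric sensation values; both must be present (bimodal
#'   trials only).
#' @param params A [bci_params] object.
#' @return Nonnegative density values.
#' @examples
#' p <- bci_params(0.5, 0, 1, 1, 1)
#' likelihood_common(0, 0, p)       # 1 / (2 * pi * sqrt(3))
#' likelihood_independent(0, 0, p)  # 1 / (4 * pi)
#' @export
likelihood_common <- function(x_v, x_a, params) {
  validate_bci_params(params)
  check_bimodal(x_v, x_a)
  v2 <- params$sigma_v^2; a2 <- params$sigma_a^2; p2 <- params$sigma_p^2
  mu <- params$mu_p
  det <- v2 * a2 + v2 * p2 + a2 * p2
  q <- (x_v - x_a)^2 * p2 + (x_v - mu)^2 * a2 + (x_a - mu)^2 * v2
  exp(-q / (2 * det)) / (2 * pi * sqrt(det))
}

#' @rdname likelihood_common
#' @export
likelihood_independent <- function(x_v, x_a, params) {
  validate_bci_params(params)
  check_bimodal(x_v, x_a)
  stats::dnorm(x_v, params$mu_p, sqrt(params$sigma_v^2 + params$sigma_p^2)) *
    stats::dnorm(x_a, params$mu_p, sqrt(params$sigma_a^2 + params$sigma_p^2))
}

check_bimodal <- function(x_v, x_a) {
  if (any(is.na(x_v)) || any(is.na(x_a))) {
    stop("both `x_v` and `x_a` must be present: causal inference is ",
         "defined for bimodal trials only", call. = FALSE)
  }
  invisible(NULL)
}

#' Posterior probability of a common cause
#'
#' Combines the two sensation likelihoods with the causal prior `p_common`
#' by Bayes' rule: `P(C = 1 | x_v, x_a)`.
#'
#' @inheritParams likelihood_common
#' @return Probabilities in `[0, 1]`, vectorized over sensations.
#' @export
posterior_common <- function(x_v, x_a, params) {
  lc <- likelihood_common(x_v, x_a, params)
  li <- likelihood_independent(x_v, x_a, params)
  pc <- params$p_common
  num <- lc * pc
  den <- num + li * (1 - pc)
  # Both likelihoods can underflow far in the tails; fall back on the prior.
  out <- ifelse(den > 0, num / den, pc)
  pmin(1, pmax(0, out))
}

#' Conditional numerosity estimates
#'
#' Under a common cause the estimate is the reliability-weighted average of
#' both sensations and the prior mean (the prior acts as a pseudo-observation
#' at `mu_p` with reliability `1/sigma_p^2`); it is shared by both
#' modalities. Under independent causes each modality combines only its own
#' sensation with the prior. `estimate_independent()` accepts a missing
#' `x_a` (visual-only trials), returning `NA` for the auditory estimate.
#'
#' @inheritParams likelihood_common
#' @return `estimate_common()`: numeric estimates. `estimate_independent()`:
#'   a list with elements `s_v` and `s_a`.
#' @examples
#' p <- bci_params(0.5, 0, 1, 1, 1)
#' estimate_common(2, 3, p)  # 5/3
#' @export
estimate_common <- function(x_v, x_a, params) {
  validate_bci_params(params)
  check_bimodal(x_v, x_a)
  wv <- 1 / params$sigma_v^2; wa <- 1 / params$sigma_a^2
  wp <- 1 / params$sigma_p^2
  (x_v * wv + x_a * wa + params$mu_p * wp) / (wv + wa + wp)
}

#' @rdname estimate_common
#' @export
estimate_independent <- function(x_v, x_a = NULL, params) {
  validate_bci_params(params)
  wv <- 1 / params$sigma_v^2; wa <- 1 / params$sigma_a^2
  wp <- 1 / params$sigma_p^2
  s_v <- (x_v * wv + params$mu_p * wp) / (wv + wp)
  s_a <- if (is.null(x_a)) {
    rep(NA_real_, length(x_v))
  } else {
    ifelse(is.na(x_a), NA_real_,
           (x_a * wa + params$mu_p * wp) / (wa + wp))
  }
  list(s_v = s_v, s_a = s_a)
}

#' Combine conditional estimates with a decision strategy
#'
#' Given the causal posterior and the conditional estimates under the two
#' causal structures, returns the final visual and auditory estimates.
#' Model averaging forms the posterior-weighted sum; model selection takes
#' the common-cause estimates when the posterior exceeds 0.5; probability
#' matching compares the posterior against a per-trial uniform threshold
#' `xi`.
#'
#' @param strategy One of [strategy_levels()].
#' @param post_c1 Posterior probability of a common cause (vectorized).
#' @param est A list with elements `s_c1` (the shared common-cause estimate),
#'   `s_v_c2` and `s_a_c2` (independent-cause estimates).
#' @param xi Uniform threshold(s) in `[0, 1]`; required for (and only
#'   consumed by) probability matching.
#' @return A list with final estimates `s_v` and `s_a`.
#' @export
apply_strategy <- function(strategy, post_c1, est, xi = NULL) {
  strategy <- match.arg(strategy, strategy_levels())
  take_c1 <- switch(strategy,
    model_averaging = NULL,
    model_selection = post_c1 > 0.5,
    probability_matching = {
      if (is.null(xi)) {
        stop("probability matching requires the threshold `xi`", call. = FALSE)
      }
      post_c1 > xi
    })
  if (strategy == "model_averaging") {
    list(s_v = post_c1 * est$s_c1 + (1 - post_c1) * est$s_v_c2,
         s_a = post_c1 * est$s_c1 + (1 - post_c1) * est$s_a_c2)
  } else {
    list(s_v = ifelse(take_c1, est$s_c1, est$s_v_c2),
         s_a = ifelse(take_c1, est$s_c1, est$s_a_c2))
  }
}

#' Quadrature settings for response-distribution prediction
#'
#' Sensory noise is marginalized on a deterministic uniform tensor grid
#' spanning `width_sd` noise s.d.s around the true stimulus counts. Each
#' grid cell carries the exact Gaussian mass of its interval (differences
#' of the normal CDF, renormalized), and the estimate surface is treated as
#' piecewise linear between nodes when it is cut at the half-integer
#' category thresholds, so predicted category probabilities vary smoothly
#' with the model parameters. The grid must cover at least +/- 5 s.d. so
#' that no appreciable noise mass is truncated.
#'
#' @param n_nodes Nodes per dimension (default 101).
#' @param width_sd Half-width of the grid in noise s.d.s (default 5; must be
#'   at least 5).
#' @return An object of class `quadrature_settings`.
#' @export
quadrature_settings <- function(n_nodes = 101, width_sd = 5) {
  if (n_nodes < 3) stop("`n_nodes` must be at least 3", call. = FALSE)
  if (width_sd < 5) {
    stop("`width_sd` must be at least 5: a narrower grid truncates ",
         "sensory-noise mass", call. = FALSE)
  }
  structure(list(n_nodes = as.integer(n_nodes), width_sd = width_sd),
            class = "quadrature_settings")
}

# Uniform node grid over mean +/- width_sd * sd with exact Gaussian segment
# masses (n - 1 segments) and trapezoid-style per-node weights (normalized),
# both used by the marginalization below.
noise_grid <- function(mean, sd, settings) {
  x <- seq(mean - settings$width_sd * sd, mean + settings$width_sd * sd,
           length.out = settings$n_nodes)
  m <- diff(stats::pnorm(x, mean, sd))
  m <- m / sum(m)
  w <- c(m / 2, 0) + c(0, m / 2)
  list(x = x, seg_mass = m, w = w / sum(w))
}

# Half-integer thresholds separating adjacent response categories.
category_thresholds <- function(cats) utils::head(cats, -1) + 0.5

# Marginal category probabilities of an estimate surface S whose rows index
# the integrated-out (inner) sensation and whose columns index the other
# (outer) sensation. Within each inner segment the estimate is linearly
# interpolated, so the Gaussian mass falling below each category threshold
# is allocated in proportion to where the threshold cuts the segment; this
# keeps the probabilities smooth in the parameters (hard binning at nodes
# makes the likelihood piecewise constant). `post_seg` optionally mixes two
# surfaces (probability matching).
margin_probs <- function(S, seg_mass, w_outer, cats, S2 = NULL,
                         post = NULL) {
  n <- nrow(S)
  cdf_at <- function(S) {
    lo <- S[-n, , drop = FALSE]
    hi <- S[-1, , drop = FALSE]
    den <- hi - lo
    function(t) {
      frac <- (t - lo) / den
      flat <- den == 0
      if (any(flat)) frac[flat] <- as.numeric((t >= lo)[flat])
      pmin(pmax(frac, 0), 1)
    }
  }
  thresholds <- category_thresholds(cats)
  if (is.null(S2)) {
    f <- cdf_at(S)
    cum <- vapply(thresholds, function(t) {
      sum(crossprod(seg_mass, f(t)) * w_outer)
    }, numeric(1))
  } else {
    f1 <- cdf_at(S); f2 <- cdf_at(S2)
    p_seg <- (post[-n, , drop = FALSE] + post[-1, , drop = FALSE]) / 2
    cum <- vapply(thresholds, function(t) {
      sum(crossprod(seg_mass, p_seg * f1(t) + (1 - p_seg) * f2(t)) * w_outer)
    }, numeric(1))
  }
  p <- diff(c(0, cum, 1))
  stats::setNames(p, as.character(cats))
}

# Exact category probabilities for a unimodal (prior-shrunk) estimate:
# s_hat = lambda * x + (1 - lambda) * mu_p is Gaussian, so threshold
# crossings are normal CDF evaluations.
unimodal_visual_probs <- function(s_v, params, cats) {
  lambda <- params$sigma_p^2 / (params$sigma_p^2 + params$sigma_v^2)
  m <- lambda * s_v + (1 - lambda) * params$mu_p
  s <- lambda * params$sigma_v
  cum <- stats::pnorm(category_thresholds(cats), m, s)
  stats::setNames(diff(c(0, cum, 1)), as.character(cats))
}

#' Predicted response distribution for one condition
#'
#' Composes the full generative chain for a stimulus condition: sensory
#' noise, causal posterior, conditional estimates, decision strategy, and
#' binning of the continuous estimate into response categories 0-5 at
#' half-integer thresholds with clamped tails. The marginalization over
#' sensory noise is deterministic quadrature on a tensor grid (see
#' [quadrature_settings()]): the exact Gaussian mass of each grid cell is
#' allocated across categories by piecewise-linear interpolation of the
#' estimate surface at the thresholds. For probability matching the
#' expectation over the uniform threshold is taken analytically: mass is
#' split between the two conditional estimate surfaces with weight
#' `post_c1`. Visual-only conditions (`n_beeps == 0`) involve no causal
#' inference; the visual estimate combines the visual sensation with the
#' numerosity prior, its distribution is computed exactly (the estimate is
#' Gaussian), and only a visual distribution is returned.
#'
#' @inheritParams sample_sensations
#' @param strategy One of [strategy_levels()].
#' @param settings A [quadrature_settings] object.
#' @return An object of class `response_distribution`: a list with
#'   `categories` (0-5), `p_visual`, and `p_auditory` (`NULL` for
#'   visual-only conditions); each probability vector sums to one.
#' @examples
#' predict_response_distribution(stimulus_condition(2, 3),
#'                               reference_observer_params(),
#'                               "model_averaging")
#' @export
predict_response_distribution <- function(cond, params,
                                          strategy = "model_averaging",
                                          settings = quadrature_settings()) {
  validate_bci_params(params)
  strategy <- match.arg(strategy, strategy_levels())
  stopifnot(inherits(settings, "quadrature_settings"))
  cats <- response_categories()

  if (cond$n_beeps == 0) {
    p_v <- unimodal_visual_probs(cond$n_flashes, params, cats)
    return(structure(list(categories = cats, p_visual = p_v,
                          p_auditory = NULL, condition = cond,
                          strategy = strategy),
                     class = "response_distribution"))
  }

  gv <- noise_grid(cond$n_flashes, params$sigma_v, settings)
  ga <- noise_grid(cond$n_beeps, params$sigma_a, settings)
  n <- settings$n_nodes
  xv <- rep(gv$x, times = n)   # rows: visual sensation
  xa <- rep(ga$x, each = n)    # cols: auditory sensation

  post <- matrix(posterior_common(xv, xa, params), n, n)
  s_c1 <- matrix(estimate_common(xv, xa, params), n, n)
  e2 <- estimate_independent(xv, xa, params)
  s_v_c2 <- matrix(e2$s_v, n, n)
  s_a_c2 <- matrix(e2$s_a, n, n)

  if (strategy == "probability_matching") {
    p_v <- margin_probs(s_c1, gv$seg_mass, ga$w, cats, S2 = s_v_c2,
                        post = post)
    p_a <- margin_probs(t(s_c1), ga$seg_mass, gv$w, cats, S2 = t(s_a_c2),
                        post = t(post))
  } else {
    est <- apply_strategy(strategy, post,
                          list(s_c1 = s_c1, s_v_c2 = s_v_c2,
                               s_a_c2 = s_a_c2))
    S_v <- matrix(est$s_v, n, n)
    S_a <- matrix(est$s_a, n, n)
    p_v <- margin_probs(S_v, gv$seg_mass, ga$w, cats)
    p_a <- margin_probs(t(S_a), ga$seg_mass, gv$w, cats)
  }

  structure(list(categories = cats, p_visual = p_v, p_auditory = p_a,
                 condition = cond, strategy = strategy),
            class = "response_distribution")
}

#' @export
print.response_distribution <- function(x, digits = 3, ...) {
  cat(sprintf("Predicted response distribution (%s, %s):\n",
              x$condition$label, x$strategy))
  m <- rbind(visual = x$p_visual)
  if (!is.null(x$p_auditory)) m <- rbind(m, auditory = x$p_auditory)
  print(round(m, digits))
  invisible(x)
}
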