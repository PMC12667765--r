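# Shared fixtures: observers and small simulated data sets built in code.

unit_params <- function(p_common = 0.5) {
  bci_params(p_common, mu_p = 0, sigma_p = 1, sigma_v = 1, sigma_a = 1)
}

blindspot_params <- function() reference_observer_params("across_blind_spot")

# A quiet, segregating observer: reports are essentially veridical.
quiet_params <- function(p_common = 0) {
  bci_params(p_common, mu_p = 2.5, sigma_p = 100, sigma_v = 0.01,
             sigma_a = 0.01)
}

coarse_quadrature <- function() quadrature_settings(n_nodes = 61)

# Brute-force numerical oracle for the common-cause likelihood:
# trapezoid integration of the triple-Gaussian integrand over s.
integrate_common_oracle <- function(x_v, x_a, params, n_grid = 200001) {
  s <- seq(-20, 20, length.out = n_grid)
  f <- stats::dnorm(x_v, s, params$sigma_v) *
    stats::dnorm(x_a, s, params$sigma_a) *
    stats::dnorm(s, params$mu_p, params$sigma_p)
  pracma::trapz(s, f)
}

# Monte-Carlo forward simulation of the response distribution for one
# bimodal condition: the independent oracle for the quadrature predictor.
mc_response_distribution <- function(cond, params, strategy, n, seed) {
  x <- sample_sensations(cond, params, n, seed)
  post <- posterior_common(x$x_v, x$x_a, params)
  e2 <- estimate_independent(x$x_v, x$x_a, params)
  est_list <- list(s_c1 = estimate_common(x$x_v, x$x_a, params),
                   s_v_c2 = e2$s_v, s_a_c2 = e2$s_a)
  xi <- if (strategy == "probability_matching") {
    withr::with_seed(seed + 1L, stats::runif(n))
  } else NULL
  est <- apply_strategy(strategy, post, est_list, xi = xi)
  bin <- function(s) pmin(5, pmax(0, floor(s + 0.5)))
  list(p_visual = tabulate(bin(est$s_v) + 1, 6) / n,
       p_auditory = tabulate(bin(est$s_a) + 1, 6) / n)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# Small factorial design for fast end-to-end tests: one trajectory,
# fewer repetitions, both locations and blocks.
small_design <- function(reps = 5L) {
  design_spec(trajectories = "horizontal_fwd", reps_per_condition = reps)
}

make_trial_row <- function(condition, block, response, location = "control",
                           participant = "P01", positions = NA_character_) {
  cnt <- parse_condition_label(condition)
  data.frame(participant = participant, block = block, trial = 1L,
             condition = condition, n_flashes = cnt$n_flashes,
             n_beeps = cnt$n_beeps, trajectory = "horizontal_fwd",
             location = location, response = as.integer(response),
             positions = positions)
}
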