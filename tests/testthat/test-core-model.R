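test_that("sensation sampling honors the generative contract", {
  p <- blindspot_params()

  # zero-noise limit: sensations collapse onto the true counts
  tight <- bci_params(0.5, 1.5, 1, 1e-9, 1e-9)
  x <- sample_sensations(stimulus_condition(2, 3), tight, n = 3, seed = 1)
  expect_equal(x$x_v, rep(2, 3), tolerance = 1e-6)
  expect_equal(x$x_a, rep(3, 3), tolerance = 1e-6)

  # unimodal conditions have no auditory sensation
  x0 <- sample_sensations(stimulus_condition(3, 0), p, n = 5, seed = 1)
  expect_true(all(is.na(x0$x_a)))
  expect_equal(nrow(x0), 5)

  # determinism
  expect_identical(sample_sensations(stimulus_condition(2, 3), p, 10, seed = 7),
                   sample_sensations(stimulus_condition(2, 3), p, 10, seed = 7))

  # law of large numbers at the representative visual noise level
  big <- sample_sensations(stimulus_condition(2, 3), p, n = 1e5, seed = 11)
  expect_lt(abs(mean(big$x_v) - 2), 3 * p$sigma_v / sqrt(1e5))
  expect_lt(abs(sd(big$x_v) - p$sigma_v) / p$sigma_v, 0.02)
  expect_error(sample_sensations(stimulus_condition(2, 3),
                                 list(sigma_v = -1), 3, 1))
})

test_that("closed-form likelihoods match hand-derived values and the integration oracle", {
  p <- unit_params()
  expect_equal(likelihood_common(0, 0, p), 1 / (2 * pi * sqrt(3)),
               tolerance = 1e-12)
  expect_equal(likelihood_independent(0, 0, p), 1 / (4 * pi),
               tolerance = 1e-12)

  # mode of the common-cause density sits at equal sensations
  delta <- 0.7
  expect_gt(likelihood_common(0, 0, p),
            likelihood_common(delta, -delta, p))

  # bimodal-only contract
  expect_error(likelihood_common(1, NA, p), "bimodal")
  expect_error(likelihood_independent(NA, 1, p), "bimodal")

  # randomized oracle equivalence for the common-cause integral
  set.seed(42)
  for (i in 1:20) {
    pr <- bci_params(runif(1), runif(1, 0, 3), runif(1, 0.3, 3),
                     runif(1, 0.3, 3), runif(1, 0.3, 3))
    xv <- runif(1, -1, 4); xa <- runif(1, -1, 4)
    expect_equal(likelihood_common(xv, xa, pr),
                 integrate_common_oracle(xv, xa, pr),
                 tolerance = 1e-6)
  }

  # the independent-cause density integrates to one over a wide grid
  g <- seq(-12, 12, length.out = 601)
  vals <- outer(g, g, function(a, b) likelihood_independent(a, b, p))
  h <- g[2] - g[1]
  expect_equal(sum(vals) * h^2, 1, tolerance = 1e-3)
})

test_that("the causal posterior is a proper Bayes combination", {
  p0 <- unit_params(0); p1 <- unit_params(1); p5 <- unit_params(0.5)
  expect_equal(posterior_common(0.3, -1.2, p0), 0)
  expect_equal(posterior_common(0.3, -1.2, p1), 1)

  a <- 1 / (2 * pi * sqrt(3)); b <- 1 / (4 * pi)
  expect_equal(posterior_common(0, 0, p5), a / (a + b), tolerance = 1e-12)

  # strictly increasing in p_common when both likelihoods are positive
  posts <- vapply(seq(0.1, 0.9, by = 0.1), function(pc) {
    posterior_common(1, 2, unit_params(pc))
  }, numeric(1))
  expect_true(all(diff(posts) > 0))

  # decreasing in sensory conflict |x_v - x_a|
  conflict <- vapply(seq(0, 3, by = 0.5), function(d) {
    posterior_common(1 + d / 2, 1 - d / 2, p5)
  }, numeric(1))
  expect_true(all(diff(conflict) < 0))

  expect_error(posterior_common(0, 0, list(p_common = 1.5, mu_p = 0,
                                           sigma_p = 1, sigma_v = 1,
                                           sigma_a = 1)),
               "p_common")
})

test_that("conditional estimates are the documented reliability-weighted averages", {
  p <- unit_params()
  expect_equal(estimate_common(2, 3, p), 5 / 3, tolerance = 1e-12)

  # representative blind-spot observer, hand arithmetic on the weights
  ref <- blindspot_params()
  wv <- 1 / ref$sigma_v^2; wa <- 1 / ref$sigma_a^2; wp <- 1 / ref$sigma_p^2
  hand <- (2 * wv + 3 * wa + ref$mu_p * wp) / (wv + wa + wp)
  expect_equal(estimate_common(2, 3, ref), hand, tolerance = 1e-12)
  expect_equal(hand, 2.9593, tolerance = 1e-4)

  hand_v <- (2 * wv + ref$mu_p * wp) / (wv + wp)
  expect_equal(estimate_independent(2, 3, ref)$s_v, hand_v, tolerance = 1e-12)
  expect_equal(hand_v, 1.9204, tolerance = 1e-4)

  # infinitely reliable audition pulls the fused estimate onto x_a
  sharp_a <- bci_params(0.5, 0, 1, 1, 1e-7)
  expect_equal(estimate_common(2, 3, sharp_a), 3, tolerance = 1e-6)

  # flat prior leaves the unisensory estimate at the sensation
  flat <- bci_params(0.5, 1.5, 4000, 1, 1)
  expect_equal(estimate_independent(2.7, NULL, flat)$s_v, 2.7,
               tolerance = 1e-4)

  # prior mean is a fixed point
  expect_equal(estimate_independent(ref$mu_p, NULL, ref)$s_v, ref$mu_p)

  # sigma_v -> Inf: fused estimate converges to audio-plus-prior average
  wide_v <- bci_params(0.5, 1.9, 1.19, 1e6, 0.21)
  aud_branch <- estimate_independent(2, 3, wide_v)$s_a
  expect_equal(estimate_common(2, 3, wide_v), aud_branch, tolerance = 1e-6)

  # symmetry: equal noise and swapping sensations swaps the estimates
  sym <- bci_params(0.5, 1.5, 1.3, 0.8, 0.8)
  e12 <- estimate_independent(1.2, 2.6, sym)
  e21 <- estimate_independent(2.6, 1.2, sym)
  expect_equal(e12$s_v, e21$s_a)
  expect_equal(e12$s_a, e21$s_v)
  expect_equal(estimate_common(1.2, 2.6, sym), estimate_common(2.6, 1.2, sym))
})

test_that("decision strategies combine conditional estimates correctly", {
  est <- list(s_c1 = 3, s_v_c2 = 2, s_a_c2 = 4)

  # degenerate posterior: all strategies agree on the common-cause estimate
  for (st in strategy_levels()) {
    out <- apply_strategy(st, 1, est, xi = 0.5)
    expect_equal(out$s_v, 3)
    expect_equal(out$s_a, 3)
  }

  expect_equal(apply_strategy("model_averaging", 0.5, est)$s_v, 2.5)
  expect_equal(apply_strategy("model_selection", 0.6, est)$s_v, 3)
  expect_equal(apply_strategy("model_selection", 0.4, est)$s_v, 2)
  expect_equal(apply_strategy("probability_matching", 0.6, est, xi = 0.59)$s_v, 3)
  expect_equal(apply_strategy("probability_matching", 0.6, est, xi = 0.61)$s_v, 2)
  expect_error(apply_strategy("probability_matching", 0.6, est), "xi")
})

test_that("predicted response distributions are normalized and hit known limits", {
  segregate <- bci_params(0, 2.5, 5, 0.01, 0.01)
  d <- predict_response_distribution(stimulus_condition(2, 3), segregate,
                                     "model_averaging", coarse_quadrature())
  expect_equal(sum(d$p_visual), 1, tolerance = 1e-9)
  expect_equal(sum(d$p_auditory), 1, tolerance = 1e-9)
  expect_gte(d$p_visual[["2"]], 0.999)
  expect_gte(d$p_auditory[["3"]], 0.999)

  # certain common cause: the three strategies coincide exactly
  fuse <- bci_params(1, 1.9, 1.19, 2.35, 0.21)
  dists <- lapply(strategy_levels(), function(st) {
    predict_response_distribution(stimulus_condition(2, 3), fuse, st,
                                  coarse_quadrature())
  })
  for (i in 2:3) {
    expect_equal(dists[[i]]$p_visual, dists[[1]]$p_visual, tolerance = 1e-9)
    expect_equal(dists[[i]]$p_auditory, dists[[1]]$p_auditory,
                 tolerance = 1e-9)
  }

  # unimodal conditions produce only a visual distribution
  du <- predict_response_distribution(stimulus_condition(3, 0),
                                      blindspot_params(), "model_averaging",
                                      coarse_quadrature())
  expect_null(du$p_auditory)
  expect_equal(sum(du$p_visual), 1, tolerance = 1e-9)

  expect_error(quadrature_settings(width_sd = 3), "grid")
})

test_that("quadrature predictions match Monte-Carlo forward simulation", {
  cond <- stimulus_condition(2, 3)
  p <- blindspot_params()
  for (st in strategy_levels()) {
    d <- predict_response_distribution(cond, p, st)
    mc <- mc_response_distribution(cond, p, st, n = 2e5, seed = 99)
    expect_lt(total_variation(d$p_visual, mc$p_visual), 0.01)
    expect_lt(total_variation(d$p_auditory, mc$p_auditory), 0.01)
  }
})

test_that("nested variants reproduce the degenerate models' predictions", {
  base <- blindspot_params()
  cond <- stimulus_condition(3, 2)
  s <- coarse_quadrature()

  fusion_by_pc <- predict_response_distribution(
    cond, bci_params(1, base$mu_p, base$sigma_p, base$sigma_v, base$sigma_a),
    "model_averaging", s)
  fusion_variant <- predict_response_distribution(
    cond, apply_variant(base, model_variant("forced_fusion")),
    "model_averaging", s)
  expect_equal(fusion_by_pc$p_visual, fusion_variant$p_visual,
               tolerance = 1e-9)

  seg_by_pc <- predict_response_distribution(
    cond, bci_params(0, base$mu_p, base$sigma_p, base$sigma_v, base$sigma_a),
    "model_averaging", s)
  seg_variant <- predict_response_distribution(
    cond, apply_variant(base, model_variant("full_segregation")),
    "model_averaging", s)
  expect_equal(seg_by_pc$p_visual, seg_variant$p_visual, tolerance = 1e-9)

  mle_manual <- predict_response_distribution(
    cond, bci_params(1, 1.5, 4000, base$sigma_v, base$sigma_a),
    "model_averaging", s)
  mle_variant <- predict_response_distribution(
    cond, apply_variant(base, model_variant("mle")), "model_averaging", s)
  expect_equal(mle_manual$p_visual, mle_variant$p_visual, tolerance = 1e-9)
  expect_equal(mle_manual$p_auditory, mle_variant$p_auditory,
               tolerance = 1e-9)
})
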