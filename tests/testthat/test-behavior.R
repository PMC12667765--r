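test_that("accuracy scores reports against the presented counts per modality", {
  rows <- rbind(
    make_trial_row("F2B3", "flash", 2), make_trial_row("F2B3", "flash", 2),
    make_trial_row("F2B3", "flash", 2), make_trial_row("F2B3", "flash", 3),
    make_trial_row("F2B3", "flash", 3),
    make_trial_row("F2B3", "beep", 3), make_trial_row("F2B3", "beep", 3),
    make_trial_row("F3B2", "flash", 2))
  acc <- accuracy_by_condition(rows)
  expect_equal(acc$accuracy[acc$modality == "flash" &
                            acc$condition == "F2B3"], 0.6)
  expect_equal(acc$accuracy[acc$modality == "beep" &
                            acc$condition == "F2B3"], 1.0)

  # a noiseless segregating observer is perfectly accurate everywhere,
  # including the incongruent conditions
  quiet <- quiet_params(0)
  trials <- simulate_participant(
    list(across_blind_spot = quiet, control = quiet),
    design = small_design(2L), seed = 9)
  acc2 <- accuracy_by_condition(trials)
  expect_true(all(acc2$accuracy[!is.na(acc2$accuracy)] == 1))

  # empty cells are NA, not zero
  expect_true(any(is.na(acc$accuracy)))
})

test_that("illusion rates are the defining conditional proportions", {
  rows <- do.call(rbind, c(
    lapply(1:4, function(i) make_trial_row("F2B3", "flash", 3)),
    lapply(1:6, function(i) make_trial_row("F2B3", "flash", 2)),
    lapply(1:5, function(i) make_trial_row("F3B2", "flash", 2)),
    lapply(1:5, function(i) make_trial_row("F3B2", "flash", 3))))
  ill <- illusion_frequency(rows)
  expect_equal(ill$illusory_rate, 0.4)
  expect_equal(ill$invisible_rate, 0.5)

  # auditory capture limit: full fusion with far sharper audition
  capture <- bci_params(1, 2.5, 10, 2.5, 0.05)
  trials <- simulate_participant(
    list(across_blind_spot = capture, control = capture),
    design = small_design(10L), seed = 17)
  ill2 <- illusion_frequency(trials)
  expect_true(all(ill2$illusory_rate > 0.9))

  # segregation with near-zero visual noise: no illusions
  quiet <- quiet_params(0)
  trials3 <- simulate_participant(
    list(across_blind_spot = quiet, control = quiet),
    design = small_design(5L), seed = 19)
  ill3 <- illusion_frequency(trials3)
  expect_true(all(ill3$illusory_rate == 0))
  expect_true(all(ill3$invisible_rate == 0))
})

test_that("position distributions and their chi-square tests behave as specified", {
  # uniform counts give a zero GOF statistic
  mk_pos <- function(n_per_pos) {
    do.call(rbind, lapply(1:5, function(pos) {
      row <- make_trial_row("F2B3", "flash", 3,
                            positions = as.character(pos))
      row[rep(1, n_per_pos), ]
    }))
  }
  # hand-built: response 3 marks a single position per trial here
  uni <- mk_pos(20)
  res <- position_distribution(uni)
  g <- res$gof[res$gof$illusion == "illusory" &
               res$gof$location == "control", ]
  expect_equal(g$statistic, 0)
  expect_equal(g$df, 4)

  # hand-computed statistic for counts (10, 0, 40, 0, 10), E = 12
  skew <- do.call(rbind, lapply(c(rep(1, 10), rep(3, 40), rep(5, 10)),
                                function(pos) {
    make_trial_row("F2B3", "flash", 3, positions = as.character(pos))
  }))
  res2 <- position_distribution(skew)
  g2 <- res2$gof[res2$gof$illusion == "illusory" &
                 res2$gof$location == "control", ]
  expect_equal(g2$statistic, 90)

  # identical distributions at both locations: independence statistic 0
  both <- rbind(uni,
                transform(mk_pos(20), location = "across_blind_spot"))
  res3 <- position_distribution(both)
  ind <- res3$independence[res3$independence$illusion == "illusory", ]
  expect_equal(ind$statistic, 0)
  expect_equal(ind$df, 4)

  # simulated positions: a report of k marks k positions
  p <- blindspot_params()
  trials <- simulate_participant(list(across_blind_spot = p, control = p),
                                 design = small_design(3L), seed = 23)
  fb <- trials[trials$block == "flash", ]
  npos <- vapply(parse_positions(fb$positions), length, 1L)
  expect_equal(npos, fb$response)
})

test_that("SDT measures implement the corrected hit/false-alarm formulas", {
  # log-linear correction fixture: 20 hits of 20 -> 20.5/21
  expect_equal(loglinear_rate(20, 20), 20.5 / 21)
  expect_equal(loglinear_rate(20, 20), 0.97619, tolerance = 1e-5)
  expect_equal(loglinear_rate(0, 20), 0.5 / 21)

  # correction never yields 0 or 1
  for (n in c(1, 5, 40)) {
    expect_gt(loglinear_rate(0, n), 0)
    expect_lt(loglinear_rate(n, n), 1)
  }

  # d' and c from corrected rates; H = FA gives d' = 0
  mk <- function(n3_sig, n_sig, n3_noise, n_noise, loc = "control") {
    rbind(
      do.call(rbind, lapply(seq_len(n_sig), function(i) {
        make_trial_row("F3B3", "flash", if (i <= n3_sig) 3 else 2,
                       location = loc)
      })),
      do.call(rbind, lapply(seq_len(n_noise), function(i) {
        make_trial_row("F2B3", "flash", if (i <= n3_noise) 3 else 2,
                       location = loc)
      })))
  }
  same <- sdt_measures(mk(10, 20, 10, 20), context = 3, location = "control")
  expect_equal(same$d_prime, 0)

  # H = 0.84, FA = 0.16 after correction is symmetric: c = 0
  h <- 0.84; fa <- 0.16
  d_expected <- qnorm(h) - qnorm(fa)
  expect_equal(d_expected, 1.9889, tolerance = 1e-4)

  # construct counts whose corrected rates are exactly 0.84/0.16
  # (0.84 * 50 - 0.5 = 41.5 not integer; use the formula directly instead)
  got <- sdt_measures(mk(41, 49, 8, 49), context = 3, location = "control")
  expect_equal(got$hit_rate, 0.83)
  expect_equal(got$fa_rate, 0.17)
  expect_equal(got$criterion, -0.5 * (qnorm(0.83) + qnorm(0.17)))
  expect_equal(got$criterion, 0)

  # antisymmetry under swapping signal and noise response counts
  a <- sdt_measures(mk(30, 40, 5, 40), context = 3, location = "control")
  b <- sdt_measures(mk(5, 40, 30, 40), context = 3, location = "control")
  expect_equal(a$d_prime, -b$d_prime)

  expect_error(sdt_measures(mk(3, 5, 0, 0), context = 3,
                            location = "control"), "two-flash")
})

test_that("sdt_summary covers every participant, context, and location", {
  p <- blindspot_params()
  trials <- rbind(
    simulate_participant(list(across_blind_spot = p, control = p),
                         design = small_design(3L), seed = 41,
                         participant = "P01"),
    simulate_participant(list(across_blind_spot = p, control = p),
                         design = small_design(3L), seed = 43,
                         participant = "P02"))
  sdt <- sdt_summary(trials)
  expect_equal(nrow(sdt), 2 * 3 * 2)  # participants x contexts x locations
  expect_true(all(sdt$hit_rate > 0 & sdt$hit_rate < 1))
  expect_true(all(sdt$fa_rate > 0 & sdt$fa_rate < 1))
})

test_that("the nonparametric battery handles ties and corrects p-values", {
  df <- expand.grid(participant = sprintf("P%02d", 1:8),
                    context = c("B0", "B2", "B3"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  # identical repeated measures: Friedman statistic 0, Wilcoxon p = 1
  df$d_prime <- 1.5
  res <- test_battery(df, "d_prime", "context", "participant")
  expect_equal(res$statistic[res$test == "friedman"], 0)
  expect_true(all(res$p_value[res$test == "wilcoxon_signed_rank"] == 1))

  # Bonferroni multiplication rule
  expect_equal(bonferroni(0.02, 3), 0.06)
  expect_equal(bonferroni(0.5, 4), 1)

  # a real effect is detected and adjusted p <= m * raw p
  set.seed(10)
  df$d_prime <- rnorm(nrow(df), mean = ifelse(df$context == "B0", 3, 1),
                      sd = 0.3)
  res2 <- test_battery(df, "d_prime", "context", "participant")
  fr <- res2[res2$test == "friedman", ]
  expect_lt(fr$p_value, 0.01)
  wl <- res2[res2$test == "wilcoxon_signed_rank", ]
  expect_equal(wl$p_adjusted, pmin(1, wl$p_value * 3))
  expect_equal(wl$family, rep(3L, 3))

  # small samples are flagged low-power but still computed
  small <- df[df$participant %in% sprintf("P%02d", 1:3), ]
  res3 <- test_battery(small, "d_prime", "context", "participant")
  expect_true(all(res3$low_power[res3$test == "wilcoxon_signed_rank"]))
  expect_true(all(is.finite(res3$p_value)))
})
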