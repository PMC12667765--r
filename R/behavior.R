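#' Report accuracy by condition
#'
#' Proportion of trials whose reported count equals the presented count,
#' separately per condition, location, and report modality (flash-block
#' reports are scored against the flash count, beep-block reports against
#' the beep count). Empty cells yield `NA`, not zero.
#'
#' @param trials A trial data.frame (see [simulate_participant()]).
#' @return A data.frame with columns `condition`, `location`, `modality`,
#'   `n_trials`, `accuracy`.
#' @export
accuracy_by_condition <- function(trials) {
  validate_trials(trials)
  truth <- ifelse(trials$block == "flash", trials$n_flashes, trials$n_beeps)
  correct <- as.integer(trials$response == truth)
  cells <- expand.grid(condition = sort(unique(trials$condition)),
                       location = sort(unique(trials$location)),
                       modality = c("flash", "beep"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$n_trials <- NA_integer_
  cells$accuracy <- NA_real_
  for (i in seq_len(nrow(cells))) {
    idx <- trials$condition == cells$condition[i] &
      trials$location == cells$location[i] &
      trials$block == cells$modality[i]
    cells$n_trials[i] <- sum(idx)
    if (any(idx)) cells$accuracy[i] <- mean(correct[idx])
  }
  cells
}

#' Illusion frequency
#'
#' The defining rates of the two audiovisual rabbit illusions, computed per
#' participant and location from flash-block reports: the illusory-rabbit
#' rate `P(report 3 | F2B3)` (an extra beep conjures an illusory flash) and
#' the invisible-rabbit rate `P(report 2 | F3B2)` (a missing beep suppresses
#' a real flash). Missing condition cells yield `NA`.
#'
#' @inheritParams accuracy_by_condition
#' @return A data.frame with columns `participant`, `location`,
#'   `illusory_rate`, `invisible_rate`.
#' @export
illusion_frequency <- function(trials) {
  validate_trials(trials)
  fb <- trials[trials$block == "flash", ]
  cells <- unique(fb[, c("participant", "location")])
  rate <- function(sub, cond, resp) {
    idx <- sub$condition == cond
    if (!any(idx)) return(NA_real_)
    mean(sub$response[idx] == resp)
  }
  cells$illusory_rate <- NA_real_
  cells$invisible_rate <- NA_real_
  for (i in seq_len(nrow(cells))) {
    sub <- fb[fb$participant == cells$participant[i] &
              fb$location == cells$location[i], ]
    cells$illusory_rate[i] <- rate(sub, "F2B3", 3L)
    cells$invisible_rate[i] <- rate(sub, "F3B2", 2L)
  }
  rownames(cells) <- NULL
  cells
}

#' Reported flash positions in illusion trials
#'
#' Counts reported positions (1-5) in illusion trials only (F2B3 trials
#' reported as 3 flashes; F3B2 trials reported as 2), per illusion type and
#' location, with a chi-square goodness-of-fit test of each distribution
#' against uniform and a chi-square test of independence of position and
#' location. Tests with an expected cell count of zero are not computed.
#'
#' @inheritParams accuracy_by_condition
#' @return A list with elements `counts` (illusion x location x position),
#'   `gof` (chi-square GOF vs. uniform per illusion x location) and
#'   `independence` (position x location chi-square per illusion).
#' @export
position_distribution <- function(trials) {
  validate_trials(trials)
  if (!"positions" %in% names(trials)) {
    stop("`trials` must carry a `positions` column for position analyses",
         call. = FALSE)
  }
  fb <- trials[trials$block == "flash", ]
  sel <- list(
    illusory = fb[fb$condition == "F2B3" & fb$response == 3L, ],
    invisible = fb[fb$condition == "F3B2" & fb$response == 2L, ])

  counts <- do.call(rbind, lapply(names(sel), function(ill) {
    do.call(rbind, lapply(sort(unique(fb$location)), function(loc) {
      sub <- sel[[ill]][sel[[ill]]$location == loc, ]
      pos <- unlist(parse_positions(sub$positions))
      data.frame(illusion = ill, location = loc, position = 1:5,
                 count = vapply(1:5, function(p) sum(pos == p), 1L))
    }))
  }))

  gof <- unique(counts[, c("illusion", "location")])
  gof$statistic <- NA_real_; gof$df <- NA_integer_; gof$p_value <- NA_real_
  for (i in seq_len(nrow(gof))) {
    cnt <- counts$count[counts$illusion == gof$illusion[i] &
                        counts$location == gof$location[i]]
    if (sum(cnt) == 0) next
    ct <- suppressWarnings(stats::chisq.test(cnt, p = rep(1 / 5, 5)))
    gof$statistic[i] <- unname(ct$statistic)
    gof$df[i] <- unname(ct$parameter)
    gof$p_value[i] <- ct$p.value
  }

  indep <- data.frame(illusion = unique(counts$illusion),
                      statistic = NA_real_, df = NA_integer_,
                      p_value = NA_real_)
  for (i in seq_len(nrow(indep))) {
    sub <- counts[counts$illusion == indep$illusion[i], ]
    tab <- stats::xtabs(count ~ location + position, data = sub)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    indep$statistic[i] <- unname(ct$statistic)
    indep$df[i] <- unname(ct$parameter)
    indep$p_value[i] <- ct$p.value
  }
  list(counts = counts, gof = gof, independence = indep)
}

#' Signal-detection measures for flash discrimination
#'
#' Treats three-flash trials as signal and two-flash trials as noise within
#' one beep context (B0, B2, or B3) and location, using flash-block reports:
#' the hit rate is `P(report 3 | F3)`, the false-alarm rate
#' `P(report 3 | F2)`. A log-linear correction (add 0.5 to each "3"-response
#' count and 1 to each trial total) keeps both rates strictly inside (0, 1).
#' Sensitivity is `d' = z(H) - z(FA)` and criterion `c = -0.5 * (z(H) +
#' z(FA))`, `z` the standard normal quantile.
#'
#' @inheritParams accuracy_by_condition
#' @param context Beep count defining the context: 0, 2 or 3.
#' @param location Stimulus location.
#' @return A one-row data.frame: `context`, `location`, `n_signal`,
#'   `n_noise`, `hit_rate`, `fa_rate` (corrected), `d_prime`, `criterion`.
#' @examples
#' p <- reference_observer_params()
#' trials <- simulate_participant(list(across_blind_spot = p, control = p),
#'                                seed = 2)
#' sdt_measures(trials, context = 3, location = "control")
#' @export
sdt_measures <- function(trials, context, location) {
  validate_trials(trials)
  fb <- trials[trials$block == "flash" & trials$n_beeps == context &
               trials$location == location, ]
  sig <- fb[fb$n_flashes == 3L, ]
  noi <- fb[fb$n_flashes == 2L, ]
  if (nrow(sig) == 0 || nrow(noi) == 0) {
    stop("need both three-flash and two-flash trials in context B", context,
         " at ", location, call. = FALSE)
  }
  h <- loglinear_rate(sum(sig$response == 3L), nrow(sig))
  fa <- loglinear_rate(sum(noi$response == 3L), nrow(noi))
  data.frame(context = paste0("B", context), location = location,
             n_signal = nrow(sig), n_noise = nrow(noi),
             hit_rate = h, fa_rate = fa,
             d_prime = stats::qnorm(h) - stats::qnorm(fa),
             criterion = -0.5 * (stats::qnorm(h) + stats::qnorm(fa)))
}

#' @rdname sdt_measures
#' @param count Number of "3" responses.
#' @param total Number of trials.
#' @export
loglinear_rate <- function(count, total) {
  (count + 0.5) / (total + 1)
}

#' @rdname sdt_measures
#' @description `sdt_summary()` computes the measures for every participant,
#'   beep context, and location present in the trials.
#' @export
sdt_summary <- function(trials) {
  validate_trials(trials)
  cells <- unique(trials[trials$block == "flash",
                         c("participant", "n_beeps", "location")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- trials[trials$participant == cells$participant[i], ]
    cbind(participant = cells$participant[i],
          sdt_measures(sub, cells$n_beeps[i], cells$location[i]))
  }))
  rownames(out) <- NULL
  out
}

#' Nonparametric test battery for paired behavioral summaries
#'
#' The omnibus-plus-posthoc battery used for per-participant summaries:
#' a Friedman test across the levels of a within-participant factor,
#' followed by paired Wilcoxon signed-rank contrasts with Bonferroni
#' correction. The correction family defaults to the number of contrasts
#' computed but can be declared explicitly; adjusted p-values are capped at
#' 1. Contrasts with fewer than 5 non-tied pairs are flagged `low_power`
#' (and still computed); fully tied samples give p = 1 by convention.
#'
#' @param data A long data.frame of per-participant summaries.
#' @param value Name of the numeric summary column.
#' @param within Name of the within-participant factor column.
#' @param subject Name of the participant column.
#' @param contrasts List of length-2 character vectors of factor levels to
#'   compare; default all pairwise combinations.
#' @param family Bonferroni family size; default `length(contrasts)`.
#' @return A data.frame with one row per test: `test`, `contrast`,
#'   `statistic`, `df`, `p_value`, `p_adjusted`, `family`, `n_pairs`,
#'   `low_power`.
#' @export
test_battery <- function(data, value, within, subject, contrasts = NULL,
                         family = NULL) {
  lev <- sort(unique(data[[within]]))
  if (is.null(contrasts)) {
    contrasts <- utils::combn(as.character(lev), 2, simplify = FALSE)
  }
  if (is.null(family)) family <- length(contrasts)

  wide <- stats::reshape(
    data[, c(subject, within, value)],
    idvar = subject, timevar = within, direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub(paste0("^", value, "\\."), "", colnames(mat))

  fried <- friedman_row(mat)
  rows <- list(data.frame(test = "friedman", contrast = "omnibus",
                          statistic = fried$statistic, df = fried$df,
                          p_value = fried$p, p_adjusted = fried$p,
                          family = 1L, n_pairs = nrow(mat),
                          low_power = FALSE))
  for (ct in contrasts) {
    x <- mat[, as.character(ct[1])]
    y <- mat[, as.character(ct[2])]
    w <- wilcoxon_paired(x, y)
    rows[[length(rows) + 1]] <- data.frame(
      test = "wilcoxon_signed_rank",
      contrast = paste(ct, collapse = " vs "),
      statistic = w$statistic, df = NA_integer_, p_value = w$p,
      p_adjusted = min(1, w$p * family), family = family,
      n_pairs = w$n_pairs, low_power = w$n_pairs < 5)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Friedman statistic; identical repeated measures give a statistic of 0.
friedman_row <- function(mat) {
  k <- ncol(mat)
  if (all(apply(mat, 1, function(r) length(unique(r)) == 1))) {
    return(list(statistic = 0, df = k - 1L, p = 1))
  }
  ft <- stats::friedman.test(mat)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p = ft$p.value)
}

# Paired Wilcoxon signed-rank with the convention that fully tied samples
# (no nonzero differences) give V = 0, p = 1.
wilcoxon_paired <- function(x, y) {
  d <- x - y
  nz <- sum(d != 0)
  if (nz == 0) return(list(statistic = 0, p = 1, n_pairs = 0L))
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value, n_pairs = nz)
}

#' Bonferroni adjustment
#'
#' Multiplies raw p-values by the declared family size, capping at 1.
#'
#' @param p Raw p-values.
#' @param family Number of comparisons in the family.
#' @return Adjusted p-values.
#' @examples
#' bonferroni(0.02, 3)  # 0.06
#' @export
bonferroni <- function(p, family) {
  pmin(1, p * family)
}
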