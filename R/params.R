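#' Observer parameters for the Bayesian causal inference model
#'
#' Bundles the five parameters of the BCI observer: the causal prior
#' `p_common` (prior probability that flashes and beeps share a common
#' cause), the numerosity prior mean `mu_p` and s.d. `sigma_p` (a Gaussian
#' expectation over event counts, in stimulus-count units), and the sensory
#' noise s.d.s `sigma_v` (visual) and `sigma_a` (auditory).
#'
#' @param p_common Prior probability of a common cause, in `[0, 1]`.
#' @param mu_p Mean of the Gaussian numerosity prior (stimulus-count units).
#' @param sigma_p S.d. of the numerosity prior; strictly positive.
#' @param sigma_v Visual noise s.d.; strictly positive.
#' @param sigma_a Auditory noise s.d.; strictly positive.
#'
#' @return An object of class `bci_params`: a named list of the five values.
#' @examples
#' bci_params(p_common = 0.5, mu_p = 1.9, sigma_p = 1.19,
#'            sigma_v = 2.35, sigma_a = 0.21)
#' @export
bci_params <- function(p_common, mu_p, sigma_p, sigma_v, sigma_a) {
  p <- list(p_common = as.numeric(p_common), mu_p = as.numeric(mu_p),
            sigma_p = as.numeric(sigma_p), sigma_v = as.numeric(sigma_v),
            sigma_a = as.numeric(sigma_a))
  validate_bci_params(p)
  structure(p, class = "bci_params")
}

validate_bci_params <- function(p) {
  vals <- unlist(p[c("p_common", "mu_p", "sigma_p", "sigma_v", "sigma_a")])
  if (any(!is.finite(vals))) {
    stop("all BCI parameters must be finite", call. = FALSE)
  }
  if (p$p_common < 0 || p$p_common > 1) {
    stop("`p_common` must lie in [0, 1]", call. = FALSE)
  }
  for (nm in c("sigma_p", "sigma_v", "sigma_a")) {
    if (p[[nm]] <= 0) stop("`", nm, "` must be strictly positive", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.bci_params <- function(x, ...) {
  cat("BCI observer parameters:\n")
  cat(sprintf("  p_common = %.4g  mu_p = %.4g  sigma_p = %.4g  sigma_v = %.4g  sigma_a = %.4g\n",
              x$p_common, x$mu_p, x$sigma_p, x$sigma_v, x$sigma_a))
  invisible(x)
}

#' Representative observer parameter sets
#'
#' Group-level parameter estimates (means, with standard errors available via
#' `reference_observer_se()`) for observers performing the audiovisual rabbit
#' task, one set per stimulus location: across the blind spot, where one flash
#' falls inside the retinal blind spot, and at a matched fully visible control
#' location. Across the blind spot visual noise is larger and the numerosity
#' prior flatter; the causal prior and auditory noise are similar at both
#' locations. These sets are the package defaults for generating synthetic
#' observers and for recovery studies.
#'
#' @param location `"across_blind_spot"` or `"control"`.
#' @return For `reference_observer_params()`, a [bci_params] object; for
#'   `reference_observer_se()`, a named numeric vector of standard errors.
#' @examples
#' reference_observer_params("across_blind_spot")
#' @export
reference_observer_params <- function(location = c("across_blind_spot", "control")) {
  location <- match.arg(location)
  switch(location,
    across_blind_spot = bci_params(0.50, 1.90, 1.19, 2.35, 0.21),
    control           = bci_params(0.58, 2.32, 0.85, 1.34, 0.20))
}

#' @rdname reference_observer_params
#' @export
reference_observer_se <- function(location = c("across_blind_spot", "control")) {
  location <- match.arg(location)
  switch(location,
    across_blind_spot = c(p_common = 0.06, mu_p = 0.13, sigma_p = 0.13,
                          sigma_v = 0.12, sigma_a = 0.02),
    control           = c(p_common = 0.08, mu_p = 0.16, sigma_p = 0.07,
                          sigma_v = 0.15, sigma_a = 0.01))
}

#' Stimulus conditions of the audiovisual rabbit task
#'
#' A condition is a flash count (2 or 3), a beep count (0, 2, or 3; 0 means
#' a visual-only trial), a stimulus location, and a trajectory (horizontal or
#' vertical sweep, two directions each). Conditions are labeled with the
#' `FXBY` convention: `F2B3` is two flashes with three beeps.
#'
#' @param n_flashes Integer flash count, 2 or 3.
#' @param n_beeps Integer beep count, 0, 2, or 3.
#' @param location Stimulus location, `"across_blind_spot"` or `"control"`.
#' @param trajectory One of `trajectory_levels()`.
#' @return An object of class `av_condition`.
#' @examples
#' stimulus_condition(2, 3)
#' parse_condition_label("F3B2")
#' @export
stimulus_condition <- function(n_flashes, n_beeps,
                               location = c("control", "across_blind_spot"),
                               trajectory = trajectory_levels()[1]) {
  location <- match.arg(location)
  trajectory <- match.arg(trajectory, trajectory_levels())
  if (!n_flashes %in% c(2L, 3L)) stop("`n_flashes` must be 2 or 3", call. = FALSE)
  if (!n_beeps %in% c(0L, 2L, 3L)) stop("`n_beeps` must be 0, 2 or 3", call. = FALSE)
  structure(list(n_flashes = as.integer(n_flashes), n_beeps = as.integer(n_beeps),
                 location = location, trajectory = trajectory,
                 label = condition_label(n_flashes, n_beeps)),
            class = "av_condition")
}

#' @rdname stimulus_condition
#' @export
condition_label <- function(n_flashes, n_beeps) {
  sprintf("F%dB%d", as.integer(n_flashes), as.integer(n_beeps))
}

#' @rdname stimulus_condition
#' @param label A condition label such as `"F2B3"`.
#' @export
parse_condition_label <- function(label) {
  m <- regmatches(label, regexec("^F([0-9]+)B([0-9]+)$", label))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed condition label(s): ", paste(label[bad], collapse = ", "),
         call. = FALSE)
  }
  data.frame(n_flashes = as.integer(vapply(m, `[`, "", 2L)),
             n_beeps = as.integer(vapply(m, `[`, "", 3L)))
}

#' @rdname stimulus_condition
#' @export
trajectory_levels <- function() {
  c("horizontal_fwd", "horizontal_rev", "vertical_fwd", "vertical_rev")
}

#' @rdname stimulus_condition
#' @export
location_levels <- function() {
  c("across_blind_spot", "control")
}

#' Decision strategies
#'
#' The three strategies an observer may use to combine the conditional
#' numerosity estimates under common (C = 1) and independent (C = 2) causes:
#' `model_averaging` weights them by the causal posterior; `model_selection`
#' takes the common-cause estimate when the posterior exceeds 0.5;
#' `probability_matching` takes it when the posterior exceeds a per-trial
#' uniform threshold `xi`.
#'
#' @return Character vector of strategy names.
#' @export
strategy_levels <- function() {
  c("model_averaging", "model_selection", "probability_matching")
}

#' Model variants of the BCI observer
#'
#' The full BCI model and its three nested special cases, distinguished by
#' which parameters are fixed:
#' \describe{
#'   \item{`bci`}{all five parameters free (k = 5).}
#'   \item{`forced_fusion`}{`p_common = 1`; cues are always integrated (k = 4).}
#'   \item{`full_segregation`}{`p_common = 0`; cues are never integrated (k = 4).}
#'   \item{`mle`}{`p_common = 1` with a flat numerosity prior
#'     (`sigma_p = 4000`, `mu_p = 1.5`): pure reliability-weighted averaging
#'     (k = 2).}
#' }
#'
#' @param name Variant name.
#' @return An object of class `bci_variant` with elements `name`, `fixed`
#'   (named numeric vector of parameter fixings), `free` (names of free
#'   parameters) and `k` (free-parameter count).
#' @examples
#' model_variant("mle")
#' @export
model_variant <- function(name = c("bci", "forced_fusion", "full_segregation", "mle")) {
  name <- match.arg(name)
  fixed <- switch(name,
    bci = numeric(0),
    forced_fusion = c(p_common = 1),
    full_segregation = c(p_common = 0),
    mle = c(p_common = 1, sigma_p = 4000, mu_p = 1.5))
  all_par <- c("p_common", "mu_p", "sigma_p", "sigma_v", "sigma_a")
  free <- setdiff(all_par, names(fixed))
  structure(list(name = name, fixed = fixed, free = free, k = length(free)),
            class = "bci_variant")
}

#' Apply a variant's parameter fixings to a parameter set
#'
#' @param params A [bci_params] object.
#' @param variant A [model_variant].
#' @return A [bci_params] object with the variant's fixed values imposed.
#' @export
apply_variant <- function(params, variant) {
  stopifnot(inherits(variant, "bci_variant"))
  p <- unclass(params)
  for (nm in names(variant$fixed)) p[[nm]] <- unname(variant$fixed[[nm]])
  structure(p, class = "bci_params")
}

# Bounds used for fitting and for truncating sampled cohort parameters.
param_bounds <- function() {
  list(p_common = c(0, 1), mu_p = c(0, 5), sigma_p = c(0.05, 10),
       sigma_v = c(0.05, 10), sigma_a = c(0.05, 10))
}

#' Response categories
#'
#' Reportable counts run from 0 to 5 in both modalities; continuous internal
#' estimates are binned at half-integer edges with the open tails clamped
#' into the extreme categories.
#'
#' @return Integer vector `0:5`.
#' @export
response_categories <- function() 0:5

# Bin a continuous numerosity estimate into a response category (0-5).
# Half-integer edges, half rounded up, tails clamped.
bin_estimate <- function(s_hat) {
  pmin(max(response_categories()), pmax(min(response_categories()),
                                        floor(s_hat + 0.5)))
}
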