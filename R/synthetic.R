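# Default sampling schedule: the known dry state at t = 0 (rehydration
# ratio 0 by definition), the gravimetric measurement times (minutes), and
# the 180 min endpoint weighing.
DEFAULT_REHYDRATION_TIMES <- c(0, 5, 10, 15, 20, 25, 30, 40, 50, 60, 80, 120,
                               180)

#' Specification of a synthetic rehydration curve
#'
#' Bundles the kinetic model, its parameters, the sampling schedule and the
#' noise level used by [gen_rehydration_curve()].
#'
#' @param model `"first_order"` (params: `k` in 1/min), `"peleg"`
#'   (`K1` in min.(g/g)^-1, `K2` in (g/g)^-1) or `"weibull"`
#'   (`a` in min, `beta` dimensionless).
#' @param params named list of model parameters as above.
#' @param M0 initial moisture ratio (g/g), >= 0.
#' @param Me equilibrium moisture ratio (g/g), >= `M0`.  Ignored by the
#'   Peleg model, whose asymptote is `M0 + 1/K2`.
#' @param times sampling grid in minutes, strictly increasing, first >= 0.
#' @param noise_sd standard deviation of additive Gaussian measurement noise
#'   on the moisture ratio (g/g), >= 0.
#' @param seed integer RNG seed.
#' @return An object of class `curve_spec`.
#' @export
curve_spec <- function(model = c("weibull", "first_order", "peleg"),
                       params, M0 = 0, Me = 6.5,
                       times = DEFAULT_REHYDRATION_TIMES,
                       noise_sd = 0.05, seed = 1L) {
  if (length(model) == 1 && !model %in% KINETIC_MODELS) {
    stop(sprintf("unknown kinetic model '%s' (expected %s)", model,
                 paste(KINETIC_MODELS, collapse = ", ")), call. = FALSE)
  }
  model <- match.arg(model, KINETIC_MODELS)
  needed <- switch(model, first_order = "k", peleg = c("K1", "K2"),
                   weibull = c("a", "beta"))
  if (!is.list(params) || !all(needed %in% names(params))) {
    stop(sprintf("model '%s' needs parameters: %s", model,
                 paste(needed, collapse = ", ")), call. = FALSE)
  }
  for (nm in needed) stopifnot_scalar(params[[nm]], nm, positive = TRUE)
  stopifnot_scalar(M0, "M0", nonneg = TRUE)
  stopifnot_scalar(Me, "Me")
  if (Me < M0) stop("invariant Me >= M0 violated", call. = FALSE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (length(times) < 1 || times[1] < 0 ||
      (length(times) > 1 && any(diff(times) <= 0))) {
    stop("`times` must be strictly increasing with first time >= 0",
         call. = FALSE)
  }
  structure(list(model = model, params = params[needed], M0 = M0, Me = Me,
                 times = as.numeric(times), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "curve_spec")
}

#' Generate a synthetic rehydration curve
#'
#' Evaluates the specified kinetic model on the sampling grid and adds
#' i.i.d. Gaussian noise `N(0, noise_sd^2)`.  Negative draws are clipped to
#' zero (moisture is physically non-negative); the number of clipped values
#' is recorded in the `"clipped"` attribute and reported via [message()]
#' when non-zero.  Output is bit-reproducible for a fixed seed.
#'
#' @param spec a [curve_spec()].
#' @return A [rehydration_curve()] with attribute `"clipped"`.
#' @export
gen_rehydration_curve <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  mean_M <- model_moisture(spec$model, spec$params, spec$M0, spec$Me,
                           spec$times)
  M <- if (spec$noise_sd > 0) {
    with_seed(spec$seed,
              mean_M + stats::rnorm(length(mean_M), sd = spec$noise_sd))
  } else {
    mean_M
  }
  n_clip <- sum(M < 0)
  if (n_clip > 0) {
    message(sprintf("gen_rehydration_curve: clipped %d negative draw(s) to 0",
                    n_clip))
  }
  out <- rehydration_curve(spec$times, pmax(M, 0))
  attr(out, "clipped") <- n_clip
  out
}

#' Specification of a synthetic CPMG decay
#'
#' Defines a multi-exponential transverse-relaxation decay
#' `S(t_j) = sum_i area_i * exp(-t_j / T2_i) + noise` sampled at echo times
#' `t_j = j * echo_spacing`.  Defaults mirror a low-field CPMG acquisition
#' (0.35 ms echo spacing) with a tri-exponential mixture whose peak times
#' and areas are typical of a rehydrated SPI/KGM gel: bound water near
#' 2.25 ms, immobilised water near 44.5 ms, free water near 333 ms.
#'
#' @param populations two-column matrix or data frame `(T2_ms, area)`; all
#'   T2 > 0, all areas >= 0.
#' @param echo_spacing echo time spacing in ms, > 0.
#' @param n_echoes number of echoes, >= 1.
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   amplitude (signal units), >= 0.
#' @param seed integer RNG seed.
#' @return An object of class `decay_spec`.
#' @export
decay_spec <- function(populations = cbind(T2_ms = c(2.25, 44.5, 333),
                                           area = c(2, 772, 66)),
                       echo_spacing = 0.35, n_echoes = 4000L,
                       noise_sd = 0, seed = 1L) {
  populations <- as.matrix(populations)
  if (ncol(populations) != 2 || nrow(populations) < 1) {
    stop("`populations` must be a (T2, area) two-column table", call. = FALSE)
  }
  if (any(populations[, 1] <= 0)) {
    stop("all T2 values must be > 0", call. = FALSE)
  }
  if (any(populations[, 2] < 0)) {
    stop("all areas must be >= 0", call. = FALSE)
  }
  stopifnot_scalar(echo_spacing, "echo_spacing", positive = TRUE)
  n_echoes <- as.integer(n_echoes)
  if (n_echoes < 1) stop("`n_echoes` must be >= 1", call. = FALSE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  structure(list(populations = populations, echo_spacing = echo_spacing,
                 n_echoes = n_echoes, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "decay_spec")
}

#' Generate a synthetic CPMG decay
#'
#' @param spec a [decay_spec()].
#' @return A [cpmg_decay()] with echo times `j * echo_spacing`,
#'   `j = 1..n_echoes`.  With `noise_sd = 0` the signal extrapolates to
#'   `sum(areas)` at `t = 0` and is strictly decreasing.
#' @export
gen_cpmg_decay <- function(spec) {
  stopifnot(inherits(spec, "decay_spec"))
  t <- seq_len(spec$n_echoes) * spec$echo_spacing
  S <- drop(exp(-outer(t, spec$populations[, 1], `/`)) %*%
              spec$populations[, 2])
  if (spec$noise_sd > 0) {
    S <- with_seed(spec$seed, S + stats::rnorm(length(S), sd = spec$noise_sd))
  }
  cpmg_decay(t, S)
}

#' Sample pore radii from SEM-style pore-size statistics
#'
#' Scanning electron microscopy of dried gels yields a main pore *diameter*
#' as mean +/- SD (micrometres).  Radii are drawn from
#' `Normal(mean_diameter/2, sd/2)` truncated at > 0 (by resampling), so the
#' samples emulate the measured distribution on the radius scale.
#'
#' @param mean_diameter mean pore diameter in um, > 0.
#' @param sd standard deviation of the diameter in um, >= 0.
#' @param n number of radii, >= 1.
#' @param seed integer RNG seed.
#' @return Vector of `n` positive radii in um.
#' @examples
#' r <- gen_pore_radii(138.21, 9.14, n = 5, seed = 42)
#' @export
gen_pore_radii <- function(mean_diameter, sd, n, seed = 1L) {
  stopifnot_scalar(mean_diameter, "mean_diameter", positive = TRUE)
  stopifnot_scalar(sd, "sd", nonneg = TRUE)
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  with_seed(seed, {
    out <- stats::rnorm(n, mean_diameter / 2, sd / 2)
    while (any(bad <- out <= 0)) {
      out[bad] <- stats::rnorm(sum(bad), mean_diameter / 2, sd / 2)
    }
    out
  })
}
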