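#' @useDynLib gelrehyd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef lm median predict
NULL

KINETIC_MODELS <- c("first_order", "peleg", "weibull")

# Evaluate a kinetic model at times t given parameter list, M0 and Me.
# first_order: M = Me + (M0 - Me) exp(-k t)
# peleg:       M = M0 + t / (K1 + K2 t)        (implied Me = M0 + 1/K2)
# weibull:     M = Me + (M0 - Me) exp(-(t/a)^beta)
model_moisture <- function(model, params, M0, Me, t) {
  switch(model,
    first_order = Me + (M0 - Me) * exp(-params$k * t),
    peleg = M0 + t / (params$K1 + params$K2 * t),
    weibull = Me + (M0 - Me) * exp(-(t / params$a)^params$beta),
    stop(sprintf("unknown kinetic model '%s'", model), call. = FALSE)
  )
}

#' Predict moisture ratio from a fitted kinetic model
#'
#' Evaluates the fitted first-order, Peleg or Weibull model at new times.
#' At `t = 0` every model returns `M0`; the Peleg asymptote is
#' `M0 + 1/K2`; the Weibull model at `t = a` has completed a fraction
#' `1 - exp(-1)` (63.2\%) of the total moisture change for any shape `beta`.
#'
#' @param fit a converged [kinetic_fit] from [fit_kinetics()].
#' @param t times in minutes, >= 0; may be a vector.
#' @return Predicted moisture ratio(s) in g/g.
#' @export
predict_moisture <- function(fit, t) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (!isTRUE(fit$converged)) {
    stop("fit did not converge; parameters are flagged unusable", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and >= 0", call. = FALSE)
  }
  model_moisture(fit$model, fit$params, fit$M0, fit$Me, t)
}

#' @export
predict.kinetic_fit <- function(object, t, ...) predict_moisture(object, t)

#' Goodness of fit of a predicted rehydration curve
#'
#' `SSE = sum((obs - pred)^2)` and `R^2 = 1 - SSE / sum((obs - mean(obs))^2)`.
#' A constant observed series has zero total variance, leaving `R^2`
#' undefined; this is signalled as an error rather than returning NaN.
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return A list with elements `r_squared` and `sse`.
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    stop("`observed` and `predicted` must have equal length >= 2",
         call. = FALSE)
  }
  if (anyNA(observed) || anyNA(predicted)) {
    stop("NA values in observed/predicted series", call. = FALSE)
  }
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    stop("observed series is constant: R^2 is undefined", call. = FALSE)
  }
  list(r_squared = 1 - sse / sst, sse = sse)
}

# Deterministic, seed-free starting values (see the methods vignette).
kinetic_start <- function(model, times, M, M0) {
  Mmax <- max(M)
  span <- Mmax - M0
  tpos <- times > 0
  switch(model,
    first_order = {
      half <- M0 + span / 2
      t_half <- if (span > 0 && any(M >= half)) {
        approx(M, times, xout = half, ties = "ordered")$y
      } else NA_real_
      if (!is.finite(t_half) || t_half <= 0) t_half <- median(times[tpos])
      list(k = 1 / t_half, Me = Mmax)
    },
    peleg = {
      ok <- tpos & (M > M0 + 1e-12)
      if (sum(ok) >= 2) {
        y <- times[ok] / (M[ok] - M0)
        cf <- coef(lm(y ~ times[ok]))
        K1 <- max(cf[[1]], 1e-6)
        K2 <- max(cf[[2]], 1e-6)
      } else {
        K1 <- max(median(times[tpos]), 1e-6)
        K2 <- if (span > 0) 1 / span else 1
      }
      list(K1 = K1, K2 = K2)
    },
    weibull = {
      # double-log linearisation with Me slightly above the largest observation
      Me0 <- Mmax + max(0.05 * span, 1e-6)
      frac <- (M - Me0) / (M0 - Me0)
      ok <- tpos & frac > 0 & frac < 1
      if (sum(ok) >= 2) {
        y <- log(-log(frac[ok]))
        x <- log(times[ok])
        cf <- coef(lm(y ~ x))
        beta0 <- min(max(cf[[2]], 0.1), 8)
        a0 <- exp(-cf[[1]] / cf[[2]])
        if (!is.finite(a0) || a0 <= 0) a0 <- median(times[tpos])
      } else {
        beta0 <- 1
        a0 <- median(times[tpos])
      }
      list(a = a0, beta = beta0, Me = Mmax)
    }
  )
}

kinetic_bounds <- function(model, M) {
  Mmax <- max(M)
  switch(model,
    first_order = list(lower = c(k = 1e-8, Me = Mmax),
                       upper = c(k = 1e4, Me = Inf)),
    peleg = list(lower = c(K1 = 1e-8, K2 = 1e-8),
                 upper = c(K1 = 1e8, K2 = 1e8)),
    weibull = list(lower = c(a = 1e-6, beta = 0.05, Me = Mmax),
                   upper = c(a = 1e8, beta = 10, Me = Inf))
  )
}

#' Fit a rehydration kinetics model
#'
#' Least-squares fit of the first-order, Peleg or Weibull model to a
#' rehydration curve, by Levenberg-Marquardt with box bounds
#' (via \pkg{minpack.lm}).  The initial moisture ratio `M0` is fixed to the
#' first observation; the equilibrium ratio `Me` is a free parameter bounded
#' below by the largest observation (Peleg's implied `Me` is `M0 + 1/K2`).
#' Starting values come from deterministic linearisations of each model,
#' so repeated fits are bit-identical.
#'
#' A fit that fails, exhausts its iteration budget, or lands on a parameter
#' bound is returned with `converged = FALSE` rather than raising: the Peleg
#' model in particular cannot represent sigmoidal uptake and is expected to
#' fail on such data.
#'
#' @param curve a [rehydration_curve()] with at least 4 points and more
#'   points than free parameters.
#' @param model one of `"first_order"`, `"peleg"`, `"weibull"`.
#' @param control a [minpack.lm::nls.lm.control()] list; the default runs up
#'   to 500 iterations with tight (1e-12 .. 1e-15) tolerances.
#' @return An object of class `kinetic_fit`: list with `model`, `params`
#'   (named list of fitted parameters), `M0`, `Me`, `r_squared`, `sse`,
#'   `converged`, `n_iter`, and the fitted values.
#' @examples
#' cv <- gen_rehydration_curve(curve_spec("weibull",
#'   params = list(a = 20, beta = 0.8), M0 = 0, Me = 6.5, noise_sd = 0))
#' fit <- fit_kinetics(cv, "weibull")
#' fit$params$a  # ~20
#' @export
fit_kinetics <- function(curve, model = c("weibull", "first_order", "peleg"),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-13)) {
  model <- match.arg(model, KINETIC_MODELS)
  stopifnot(inherits(curve, "rehydration_curve"))
  times <- curve$time_min
  M <- curve$moisture_g_per_g
  if (anyNA(M) || anyNA(times)) stop("NaN/NA in curve data", call. = FALSE)
  start <- kinetic_start(model, times, M, M0 = M[1])
  n_free <- length(start)
  if (length(times) < 4 || length(times) <= n_free) {
    stop(sprintf("need >= 4 points and more points than the %d free parameters",
                 n_free), call. = FALSE)
  }
  M0 <- M[1]
  bounds <- kinetic_bounds(model, M)

  df <- data.frame(.t = times, .M = M)
  formula <- switch(model,
    first_order = .M ~ Me + (M0 - Me) * exp(-k * .t),
    peleg = .M ~ M0 + .t / (K1 + K2 * .t),
    weibull = .M ~ Me + (M0 - Me) * exp(-(.t / a)^beta)
  )
  env <- list2env(list(M0 = M0), parent = environment())
  environment(formula) <- env

  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = df, start = start,
                      lower = bounds$lower, upper = bounds$upper,
                      control = control),
    error = function(e) e
  )

  if (inherits(fit, "error")) {
    params <- start
    converged <- FALSE
    n_iter <- 0L
  } else {
    params <- as.list(coef(fit))
    n_iter <- fit$convInfo$finIter %||% NA_integer_
    converged <- isTRUE(fit$convInfo$isConv) &&
      (n_iter < control$maxiter)
    # landing on a box bound at the final iterate flags the fit unusable
    p <- unlist(params)
    scale <- pmax(abs(p), 1)
    at_lower <- abs(p - bounds$lower[names(p)]) < 1e-8 * scale
    at_upper <- is.finite(bounds$upper[names(p)]) &
      abs(p - bounds$upper[names(p)]) < 1e-8 * scale
    if (any(at_lower) || any(at_upper)) converged <- FALSE
  }

  Me <- switch(model,
    first_order = params$Me,
    weibull = params$Me,
    peleg = M0 + 1 / params$K2
  )
  pred <- model_moisture(model, params, M0, Me, times)
  gof <- tryCatch(goodness_of_fit(M, pred),
                  error = function(e) list(r_squared = NA_real_, sse = NA_real_))
  structure(
    list(model = model, params = params, M0 = M0, Me = Me,
         r_squared = gof$r_squared, sse = gof$sse,
         converged = converged, n_iter = n_iter,
         times = times, observed = M, fitted = pred),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit: %s model (%s)\n", x$model,
              if (x$converged) "converged" else "NOT converged"))
  cat("  params:", paste(sprintf("%s = %.6g", names(x$params),
                                 unlist(x$params)), collapse = ", "), "\n")
  cat(sprintf("  M0 = %.4g g/g, Me = %.4g g/g\n", x$M0, x$Me))
  cat(sprintf("  R^2 = %.6f, SSE = %.4g (%d iterations)\n",
              x$r_squared, x$sse, x$n_iter))
  invisible(x)
}
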