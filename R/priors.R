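#' Time-continuous data representations
#'
#' The variational objective replaces discrete measurements by differentiable
#' data representations: a course `S(t)` standing in for the values and an
#' uncertainty course `Ssigma2(t)` (a variance; its reciprocal is the weight
#' `w(t)`) standing in for the measurement uncertainties, both defined on a
#' finite interval `[0, T]`. `continuous_representation()` constructs one
#' directly from functions; [fit_spline_prior()] and [constant_prior()] are
#' the usual builders.
#'
#' @param S function `S(t)`, vectorized over `t`.
#' @param dS derivative of `S`; finite differences of `S` if `NULL`.
#' @param sigma2 variance course, a function of `t` or a single positive
#'   number, or `NULL` if the representation carries values only.
#' @param domain numeric length-2, the time interval `[0, T]`.
#' @return An object of class `continuous_representation` with function
#'   fields `S`, `dS`, `sigma2` and the `domain`.
#' @export
continuous_representation <- function(S, dS = NULL, sigma2 = NULL,
                                      domain = c(0, 1)) {
  stopifnot(is.function(S), length(domain) == 2, domain[1] < domain[2])
  if (is.null(dS)) {
    h <- 1e-6 * diff(domain)
    dS <- function(t) (S(pmin(t + h, domain[2])) - S(pmax(t - h, domain[1]))) /
      (pmin(t + h, domain[2]) - pmax(t - h, domain[1]))
  }
  if (!is.null(sigma2) && !is.function(sigma2)) {
    v <- as.numeric(sigma2)
    stopifnot(length(v) == 1, v > 0)
    sigma2 <- function(t) rep(v, length(t))
  }
  structure(list(S = S, dS = dS, sigma2 = sigma2, domain = as.numeric(domain)),
            class = "continuous_representation")
}

#' @export
print.continuous_representation <- function(x, ...) {
  cat("continuous representation on [", x$domain[1], ", ", x$domain[2], "]",
      if (is.null(x$sigma2)) " (no uncertainty course)" else "", "\n", sep = "")
  invisible(x)
}

#' Smoothing-spline data prior
#'
#' Builds the differentiable data representation `S(t)` for one measured
#' component as a cubic smoothing spline through the data, the standard
#' choice of prior knowledge about shape and time scale of changes. Outside
#' the data range the representation is continued by the constant boundary
#' value (with zero derivative). The uncertainty course is attached in one of
#' two modes: `"interpolate"` carries the reported per-point variances
#' through linear interpolation (the dense-sampling default), while
#' `"gaussian_sum"` uses the Gaussian-sum weight of [gaussian_sum_weight()],
#' which concentrates confidence near the measurement times and is preferable
#' when sampling is sparse.
#'
#' @param times,values measurement times and values (>= 2 distinct times).
#' @param smoothing smoothing penalty: `NULL` (default) selects it by
#'   generalized cross-validation, `0` gives the natural interpolating
#'   spline, a positive number is used as the `lambda` of
#'   [stats::smooth.spline()]. Fewer than 4 distinct points always
#'   interpolate.
#' @param sigmas optional per-point uncertainties (sd, same units as
#'   `values`); required for an uncertainty course.
#' @param weight_mode `"auto"` (interpolate for >= 10 points, Gaussian sum
#'   otherwise), `"interpolate"` or `"gaussian_sum"`.
#' @param tau correlation length of the Gaussian-sum weight; default half
#'   the median inter-measurement spacing.
#' @param var_cap cap on the variance course (avoids `w -> 0` overflow far
#'   from measurements); default `1e4 * max(sigmas^2)`.
#' @param domain time interval `[0, T]`; default `[0, max(times)]` (extended
#'   to cover the data).
#' @return A [continuous_representation()].
#' @export
fit_spline_prior <- function(times, values, smoothing = NULL, sigmas = NULL,
                             weight_mode = c("auto", "interpolate", "gaussian_sum"),
                             tau = NULL, var_cap = NULL, domain = NULL) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(length(times) == length(values))
  keep <- is.finite(times) & is.finite(values)
  times <- times[keep]; values <- values[keep]
  if (!is.null(sigmas)) sigmas <- sigmas[keep]
  ut <- sort(unique(times))
  if (length(ut) < 2)
    stop("need at least 2 distinct measurement times; ",
         "use constant_prior() for a single value")
  if (!is.null(smoothing) && smoothing < 0) stop("smoothing must be >= 0")
  if (is.null(domain)) domain <- c(min(0, min(times)), max(times))
  tmin <- min(times); tmax <- max(times)

  interpolating <- (length(ut) < 4) || (!is.null(smoothing) && smoothing == 0)
  if (interpolating) {
    ymean <- as.numeric(tapply(values, factor(times, levels = ut), mean))
    sf <- splinefun(ut, ymean, method = "natural")
    Sfun <- function(t) sf(pmin(pmax(t, tmin), tmax))
    dSfun <- function(t) ifelse(t < tmin | t > tmax, 0,
                                sf(pmin(pmax(t, tmin), tmax), deriv = 1))
  } else {
    ss <- if (is.null(smoothing))
      smooth.spline(times, values, cv = FALSE)
    else
      smooth.spline(times, values, lambda = smoothing, all.knots = TRUE)
    Sfun <- function(t) predict(ss, pmin(pmax(t, tmin), tmax))$y
    dSfun <- function(t) ifelse(t < tmin | t > tmax, 0,
                                predict(ss, pmin(pmax(t, tmin), tmax), deriv = 1)$y)
  }

  sigma2 <- NULL
  if (!is.null(sigmas)) {
    stopifnot(length(sigmas) == length(times), all(sigmas > 0))
    if (weight_mode == "auto")
      weight_mode <- if (length(ut) >= 10) "interpolate" else "gaussian_sum"
    if (weight_mode == "interpolate") {
      af <- approxfun(times, sigmas^2, rule = 2, ties = mean)
      sigma2 <- function(t) af(t)
    } else {
      if (is.null(tau)) tau <- median(diff(ut)) / 2
      wf <- gaussian_sum_weight(times, sigmas, tau)
      cap <- if (is.null(var_cap)) 1e4 * max(sigmas^2) else var_cap
      sigma2 <- function(t) pmin(1 / wf$w(t), cap)
    }
  }
  continuous_representation(Sfun, dSfun, sigma2, domain)
}

#' Gaussian-sum uncertainty weight
#'
#' The weight course
#' \deqn{w_\tau(t) = \sum_i \frac{1}{\sqrt{2\pi\tau^2}}
#'   e^{-(t-t_i)^2/(2\tau^2)} \frac{1}{\sigma_i^2},}
#' a sum of Gaussians located around the measurement points. It expresses
#' that the data prior is trusted near measurement times and carries little
#' information in between; the correlation length `tau` sets how quickly
#' confidence decays. The corresponding variance course is
#' `Ssigma2(t) = 1/w(t)`. For a single anchor the weight integrates to
#' `1/sigma_i^2` over the whole line.
#'
#' Choose `tau` small for comprehensive input reconstruction and larger for
#' propagation of uncertainties; the package default (set where priors are
#' built) is half the median inter-measurement spacing.
#'
#' @param times measurement times (the anchors).
#' @param sigmas per-point uncertainties, all positive, same length.
#' @param tau correlation length, > 0.
#' @return An object of class `weight_function`: list with the vectorized
#'   weight `w(t)`, `tau` and the anchors.
#' @export
gaussian_sum_weight <- function(times, sigmas, tau) {
  if (length(tau) != 1 || !is.finite(tau) || tau <= 0)
    stop("tau must be a single positive number")
  stopifnot(length(times) == length(sigmas))
  if (any(sigmas <= 0)) stop("all sigmas must be > 0")
  times <- as.numeric(times); sigmas <- as.numeric(sigmas)
  w <- function(t) {
    out <- numeric(length(t))
    for (i in seq_along(times))
      out <- out + dnorm(t, times[i], tau) / sigmas[i]^2
    out
  }
  structure(list(w = w, tau = tau, times = times, sigmas = sigmas),
            class = "weight_function")
}

#' Constant data prior
#'
#' A representation with constant value and constant uncertainty on
#' `[0, T]`. With value 0 it is the natural prior for the derivative inputs
#' `d` of the positivity extension, where it acts as a penalty on the first
#' derivative of the reconstructed input.
#'
#' @param value constant course value.
#' @param sigma constant uncertainty (sd), > 0.
#' @param T end of the time interval, > 0.
#' @return A [continuous_representation()].
#' @export
constant_prior <- function(value, sigma, T) {
  if (length(sigma) != 1 || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be a single positive number")
  stopifnot(length(value) == 1, is.finite(value), T > 0)
  continuous_representation(
    S = function(t) rep(value, length(t)),
    dS = function(t) rep(0, length(t)),
    sigma2 = sigma^2,
    domain = c(0, T))
}

#' Build per-component priors from a measurement table
#'
#' Convenience builder turning a measurement table (columns
#' `component,time,value,sigma`) into the lists of species and input
#' representations consumed by [augmented_system()] and [fit_variational()].
#'
#' @param data measurement data frame, see [as_measurements()].
#' @param model the `ode_model` whose component names select rows.
#' @param settings optional per-component or global overrides: a list with
#'   any of `smoothing`, `weight_mode`, `tau`, `var_cap`, applied to every
#'   component, or a named list of such lists keyed by component name.
#' @param T end of the time interval; default the latest measurement time.
#' @return list with elements `y` and `x`: named lists of
#'   [continuous_representation()] objects.
#' @export
build_priors <- function(data, model, settings = list(), T = NULL) {
  data <- as_measurements(data)
  if (is.null(T)) T <- max(data$time)
  comp_settings <- function(comp) {
    if (!is.null(settings[[comp]]) && is.list(settings[[comp]])) settings[[comp]]
    else settings[setdiff(names(settings), c(model$species_names, model$input_names))]
  }
  one <- function(comp) {
    rows <- data[data$component == comp, , drop = FALSE]
    if (nrow(rows) == 0)
      stop("no measurements for component ", sQuote(comp),
           "; supply a prior explicitly (e.g. constant_prior())")
    s <- comp_settings(comp)
    fit_spline_prior(rows$time, rows$value, smoothing = s$smoothing,
                     sigmas = rows$sigma,
                     weight_mode = if (is.null(s$weight_mode)) "auto" else s$weight_mode,
                     tau = s$tau, var_cap = s$var_cap, domain = c(0, T))
  }
  list(y = setNames(lapply(model$species_names, one), model$species_names),
       x = setNames(lapply(model$input_names, one), model$input_names))
}
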