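#' Input course families for data generation
#'
#' The three input shapes used in the toy studies, each scaled by
#' `amplitude` and returned as a vectorized function of time:
#' \itemize{
#' \item `exp_decay`: \eqn{x(t) = a\,e^{-\alpha t}};
#' \item `activation`: \eqn{x(t) = a\,|e^{-\beta t} - e^{-\alpha t}|} with
#'   \eqn{\alpha > \beta} — a fast rise followed by a slow decay, positive on
#'   `(0, T]` with a single interior maximum at
#'   \eqn{\ln(\alpha/\beta)/(\alpha-\beta)};
#' \item `gaussian`: \eqn{x(t) = a\,(2\pi\tau_{in}^2)^{-1/2}
#'   e^{-(t-t_{dip})^2/(2\tau_{in}^2)}}, a pulse centred at `t_dip`.
#' }
#'
#' @param family one of `"exp_decay"`, `"activation"`, `"gaussian"`.
#' @param params named list of family parameters (`alpha`, `beta`, `t_dip`,
#'   `tau_in`, `amplitude`); unset entries take the package defaults.
#' @return function `x(t)`, vectorized.
#' @export
make_input <- function(family, params = list()) {
  families <- c("exp_decay", "activation", "gaussian")
  if (!is.character(family) || length(family) != 1 || !(family %in% families))
    stop("unknown input family ", sQuote(as.character(family)[1]),
         "; options: ", paste(families, collapse = ", "))
  defaults <- switch(family,
    exp_decay = list(alpha = 1, amplitude = 1),
    activation = list(alpha = 5, beta = 1, amplitude = 2),
    gaussian = list(t_dip = 2, tau_in = 0.8, amplitude = 2))
  pp <- modifyList(defaults, params)
  switch(family,
    exp_decay = {
      if (pp$alpha <= 0) stop("alpha must be > 0")
      function(t) pp$amplitude * exp(-pp$alpha * t)
    },
    activation = {
      if (pp$alpha <= 0 || pp$beta <= 0) stop("alpha and beta must be > 0")
      if (pp$alpha <= pp$beta) stop("activation requires alpha > beta")
      function(t) pp$amplitude * abs(exp(-pp$beta * t) - exp(-pp$alpha * t))
    },
    gaussian = {
      if (pp$tau_in <= 0) stop("tau_in must be > 0")
      function(t) pp$amplitude * exp(-(t - pp$t_dip)^2 / (2 * pp$tau_in^2)) /
        sqrt(2 * pi * pp$tau_in^2)
    })
}

#' Toy-study scenario configuration
#'
#' Bundles everything that defines one simulated experiment on the
#' reversible toy model: the true input course, true rates and initial
#' values, the measurement designs, the noise level and the prior settings.
#' The defaults are the package's stated world: `k1 = 2`, `k2 = 0.5`,
#' `A0 = 1`, `B0 = 0` on `[0, 5]`, 20 equidistant species measurement times,
#' 20 (dense) or 4 (sparse) input measurement times, and i.i.d. Gaussian
#' noise with `sigma = 0.1`.
#'
#' @param input_family,input_params input shape, see [make_input()].
#' @param p,y0 true rates and initial values (named).
#' @param T time horizon.
#' @param n_species_times,n_input_times numbers of equidistant measurement
#'   times on `[0, T]` (endpoints included); overridden by explicit
#'   `species_times` / `input_times`.
#' @param species_times,input_times explicit measurement times.
#' @param sigma measurement noise sd (also the reported uncertainty).
#' @param prior_settings settings forwarded to [build_priors()].
#' @param seed default seed for [simulate_dataset()].
#' @return list of class `scenario_config` (with the input course attached
#'   as `$input`).
#' @export
scenario_config <- function(input_family = "gaussian", input_params = list(),
                            p = c(k1 = 2, k2 = 0.5), y0 = c(A = 1, B = 0),
                            T = 5, n_species_times = 20, n_input_times = 20,
                            species_times = NULL, input_times = NULL,
                            sigma = 0.1, prior_settings = list(),
                            seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (is.null(species_times))
    species_times <- seq(0, T, length.out = n_species_times)
  if (is.null(input_times))
    input_times <- seq(0, T, length.out = n_input_times)
  stopifnot(all(species_times >= 0), all(species_times <= T),
            all(input_times >= 0), all(input_times <= T))
  structure(list(input_family = input_family, input_params = input_params,
                 input = make_input(input_family, input_params),
                 p = p, y0 = y0, T = T,
                 species_times = sort(species_times),
                 input_times = sort(input_times),
                 sigma = sigma, prior_settings = prior_settings, seed = seed),
            class = "scenario_config")
}

#' Simulate one noisy dataset
#'
#' Forward-solves the model from the true initial values under the scenario
#' input, samples the species at their measurement times and the input at
#' its times, and adds i.i.d. Gaussian noise with sd `sigma`; `sigma` is also
#' recorded as the reported per-point uncertainty. Fully reproducible from
#' the seed.
#'
#' @param model an `ode_model` (the toy model in the shipped scenarios).
#' @param scenario a [scenario_config()].
#' @param seed RNG seed (defaults to the scenario's).
#' @return measurement data frame (`component,time,value,sigma`).
#' @export
simulate_dataset <- function(model, scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  times <- make_time_grid(scenario$T, 200L,
                          extra = c(scenario$species_times, scenario$input_times))
  Y <- rk4_solve(model, scenario$y0, scenario$p, times,
                 x_course = function(t) matrix(scenario$input(t), nrow = model$m))
  rows <- list()
  for (i in seq_len(model$n)) {
    ti <- scenario$species_times
    rows[[length(rows) + 1]] <- data.frame(
      component = model$species_names[i], time = ti,
      value = Y[i, match(ti, times)], sigma = scenario$sigma)
  }
  for (j in seq_len(model$m)) {
    ti <- scenario$input_times
    rows[[length(rows) + 1]] <- data.frame(
      component = model$input_names[j], time = ti,
      value = scenario$input(ti), sigma = scenario$sigma)
  }
  out <- do.call(rbind, rows)
  out$value <- out$value + rnorm(nrow(out), 0, scenario$sigma)
  rownames(out) <- NULL
  out
}

## Deterministic per-replicate seeds below 2^31, individually re-runnable.
replicate_seeds <- function(master_seed, n) {
  state <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(state)) assign(".Random.seed", state, envir = globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

fit_both <- function(model, data, scenario, methods, options) {
  priors <- build_priors(data, model, scenario$prior_settings, T = scenario$T)
  fits <- list()
  if ("variational" %in% methods)
    fits$variational <- fit_variational(model, priors, data, options = options)
  if ("fixed_input" %in% methods)
    fits$fixed_input <- fit_fixed_input(model, priors$x, data, options = options)
  fits
}

#' Repeated-estimation comparison of the two approaches
#'
#' For each of `n_reps` noise realizations: simulate a dataset, build the
#' data priors, estimate `(p, y0)` with the variational approach and with
#' the fixed-input baseline (input frozen to its data-prior spline), and
#' collect the estimates. This is the experiment behind the parameter
#' distribution comparisons: with dense input sampling both methods are
#' comparably accurate, with sparse input sampling the fixed-input estimates
#' are biased while the variational ones are not.
#'
#' @param model an `ode_model`.
#' @param scenario a [scenario_config()].
#' @param n_reps number of replicates (>= 2).
#' @param master_seed master seed; per-replicate seeds are derived from it.
#' @param methods methods to run.
#' @param options fit options.
#' @return data frame of class `estimates_table`: `replicate`, `seed`,
#'   `method`, `parameter`, `estimate`, `converged`. Failed replicates are
#'   recorded in `attr(, "failures")`; more than 20% failures is an error.
#' @export
run_estimator_comparison <- function(model, scenario, n_reps, master_seed = 1L,
                                     methods = c("variational", "fixed_input"),
                                     options = list()) {
  stopifnot(n_reps >= 2)
  seeds <- replicate_seeds(master_seed, n_reps)
  truth_names <- c(names(scenario$p), names(scenario$y0))
  out <- list(); failures <- list()
  for (i in seq_len(n_reps)) {
    res <- tryCatch({
      data <- simulate_dataset(model, scenario, seed = seeds[i])
      fits <- fit_both(model, data, scenario, methods, options)
      do.call(rbind, lapply(names(fits), function(mm) {
        est <- coef(fits[[mm]])
        data.frame(replicate = i, seed = seeds[i], method = mm,
                   parameter = truth_names, estimate = as.numeric(est),
                   converged = fits[[mm]]$converged)
      }))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- list(replicate = i, seed = seeds[i],
                                               message = conditionMessage(res))
    } else out[[length(out) + 1]] <- res
  }
  if (length(failures) > 0.2 * n_reps)
    stop("more than 20% of replicates failed (", length(failures), "/",
         n_reps, "); first message: ", failures[[1]]$message)
  res <- do.call(rbind, out)
  attr(res, "failures") <- failures
  attr(res, "truth") <- c(scenario$p, scenario$y0)
  class(res) <- c("estimates_table", "data.frame")
  res
}

#' Coverage study of profile-likelihood confidence intervals
#'
#' Repeats simulation and estimation and records, per replicate, whether the
#' true parameter value lies inside the profile-likelihood confidence
#' interval at each nominal level. Containment is evaluated by the interval's
#' defining sub-level-set test ([profile_delta_chi2()] against the 1-dof
#' chi-square quantile), which avoids constructing the full interval.
#' Results aggregate to empirical coverage fractions with binomial
#' Monte-Carlo standard errors.
#'
#' @inheritParams run_estimator_comparison
#' @param levels nominal confidence levels.
#' @param parameters parameter names whose coverage is tracked.
#' @return data frame of class `coverage_table`: `parameter`, `level`,
#'   `method`, `n_reps`, `n_covered`, `coverage`, `mc_se`.
#' @export
coverage_study <- function(model, scenario, n_reps,
                           levels = c(0.68, 0.90),
                           methods = c("variational", "fixed_input"),
                           parameters = c("k1", "k2"),
                           master_seed = 1L, options = list()) {
  stopifnot(n_reps >= 2)
  seeds <- replicate_seeds(master_seed, n_reps)
  truth <- c(scenario$p, scenario$y0)
  qs <- qchisq(levels, df = 1)
  cover <- array(0L, c(length(parameters), length(levels), length(methods)),
                 dimnames = list(parameters, paste(levels), methods))
  n_ok <- 0L; failures <- list()
  for (i in seq_len(n_reps)) {
    res <- tryCatch({
      data <- simulate_dataset(model, scenario, seed = seeds[i])
      fits <- fit_both(model, data, scenario, methods, options)
      hit <- array(FALSE, dim(cover))
      for (mi in seq_along(methods)) {
        fit <- fits[[methods[mi]]]
        for (pi in seq_along(parameters)) {
          dchi <- profile_delta_chi2(fit, parameters[pi],
                                     truth[[parameters[pi]]])
          hit[pi, , mi] <- dchi <= qs
        }
      }
      hit
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- list(replicate = i, seed = seeds[i],
                                               message = conditionMessage(res))
    } else {
      cover <- cover + res
      n_ok <- n_ok + 1L
    }
  }
  if (length(failures) > 0.2 * n_reps)
    stop("more than 20% of replicates failed (", length(failures), "/",
         n_reps, "); first message: ", failures[[1]]$message)
  rows <- expand.grid(parameter = parameters, level = levels,
                      method = methods, stringsAsFactors = FALSE)
  rows$n_reps <- n_ok
  rows$n_covered <- mapply(function(pa, le, me)
    cover[pa, paste(le), me], rows$parameter, rows$level, rows$method)
  rows$coverage <- rows$n_covered / rows$n_reps
  rows$mc_se <- sqrt(rows$coverage * (1 - rows$coverage) / rows$n_reps)
  attr(rows, "failures") <- failures
  class(rows) <- c("coverage_table", "data.frame")
  rows
}
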