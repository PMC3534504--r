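#' Measurement tables
#'
#' Measurements are tabular: one row per observed value with columns
#' `component` (a species or input name of the model), `time`, `value` and
#' `sigma` (the reported measurement uncertainty, sd, in value units).
#' `as_measurements()` validates and coerces; `read_measurements()` reads the
#' CSV interchange format with header `component,time,value,sigma`.
#'
#' @param data a data frame with the four columns above.
#' @return the validated data frame (invisibly classed `measurements`).
#' @export
as_measurements <- function(data) {
  need <- c("component", "time", "value", "sigma")
  if (!all(need %in% names(data)))
    stop("measurements need columns ", paste(need, collapse = ", "))
  data <- as.data.frame(data)[need]
  data$component <- as.character(data$component)
  for (cl in c("time", "value", "sigma")) data[[cl]] <- as.numeric(data[[cl]])
  if (any(!is.finite(data$time)) || any(!is.finite(data$value)))
    stop("non-finite time or value in measurements")
  if (any(!is.finite(data$sigma)) || any(data$sigma <= 0))
    stop("all measurement sigmas must be > 0")
  class(data) <- c("measurements", "data.frame")
  data
}

#' @rdname as_measurements
#' @param path CSV file path.
#' @export
read_measurements <- function(path) {
  as_measurements(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname as_measurements
#' @param x measurements to write.
#' @export
write_measurements <- function(x, path) {
  utils::write.csv(as.data.frame(as_measurements(x)), path, row.names = FALSE)
  invisible(path)
}

## Predicted value for every measurement row. `trajectory` is either an
## augmented_trajectory (species and inputs predicted) or a forward
## (fixed-input) trajectory (species only).
predict_rows <- function(trajectory, data, species_only = FALSE) {
  model <- if (inherits(trajectory, "augmented_trajectory"))
    trajectory$system$model else trajectory$model
  tq <- sort(unique(data$time))
  span <- range(trajectory$times)
  if (any(tq < span[1] - 1e-9) || any(tq > span[2] + 1e-9))
    stop("measurement time outside the trajectory span [",
         span[1], ", ", span[2], "]")
  pred <- numeric(nrow(data))
  if (inherits(trajectory, "augmented_trajectory")) {
    pq <- predict(trajectory, tq)
    courses <- rbind(pq$y, pq$x)
    rn <- c(model$species_names, model$input_names)
  } else {
    courses <- hermite_interp(trajectory$times, trajectory$y, trajectory$f, tq)
    rn <- model$species_names
  }
  for (i in seq_len(nrow(data))) {
    comp <- data$component[i]
    row <- match(comp, rn)
    if (is.na(row)) {
      if (species_only && comp %in% model$input_names) { pred[i] <- NA; next }
      stop("component ", sQuote(comp), " is not predicted by this trajectory")
    }
    pred[i] <- courses[row, match(data$time[i], tq)]
  }
  pred
}

#' Time-discrete chi-square
#'
#' The conventional objective
#' \eqn{\chi^2 = \sum_{i,\mu} ((d_{\mu,i} - Y_\mu(t_i))/\sigma_{\mu,i})^2}
#' summed over measured components and time points. For an augmented
#' (variational) trajectory the prediction for input components is the
#' reconstructed input course, so input measurements contribute; for a
#' fixed-input forward trajectory only species terms contribute (the input is
#' not a model output there).
#'
#' @param trajectory an `augmented_trajectory` or a forward trajectory from
#'   the fixed-input route.
#' @param data measurements, see [as_measurements()].
#' @return scalar chi-square value.
#' @export
discrete_chi2 <- function(trajectory, data) {
  data <- as_measurements(data)
  species_only <- !inherits(trajectory, "augmented_trajectory")
  pred <- predict_rows(trajectory, data, species_only = species_only)
  keep <- !is.na(pred)
  sum(((data$value[keep] - pred[keep]) / data$sigma[keep])^2)
}

## ---- Gauss-Newton with Levenberg damping ------------------------------------

## fn(theta) returns the sigma-scaled residual vector; chi2 = sum(fn^2).
## `fixed` holds indices of theta that are held at their theta0 value.
gauss_newton <- function(fn, theta0, fixed = integer(0), control = list()) {
  ctl <- modifyList(list(max_iter = 40L, fd_step = 1e-6, lambda0 = 1e-3,
                         tol_chi2 = 1e-8, tol_step = 1e-8, max_reject = 15L),
                    control)
  theta <- theta0
  free <- setdiff(seq_along(theta), fixed)
  r <- fn(theta)
  chi2 <- sum(r^2)
  lambda <- ctl$lambda0
  iter <- 0L
  converged <- FALSE
  J <- NULL
  while (iter < ctl$max_iter) {
    iter <- iter + 1L
    J <- matrix(0.0, length(r), length(free))
    for (jj in seq_along(free)) {
      th <- theta
      th[free[jj]] <- th[free[jj]] + ctl$fd_step
      rj <- tryCatch(fn(th), error = function(e) NULL)
      if (is.null(rj)) rj <- r     # frozen column; damping will cope
      J[, jj] <- (rj - r) / ctl$fd_step
    }
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    D <- diag(pmax(diag(JtJ), 1e-12), nrow = nrow(JtJ))
    accepted <- FALSE
    for (rej in seq_len(ctl$max_reject)) {
      delta <- tryCatch(solve(JtJ + lambda * D, -g), error = function(e) NULL)
      if (!is.null(delta) && all(is.finite(delta))) {
        th_new <- theta
        th_new[free] <- th_new[free] + as.numeric(delta)
        r_new <- tryCatch(fn(th_new), error = function(e) NULL)
        if (!is.null(r_new) && all(is.finite(r_new)) && sum(r_new^2) < chi2) {
          rel_dec <- (chi2 - sum(r_new^2)) / max(chi2, 1e-300)
          step_norm <- sqrt(sum(delta^2))
          theta <- th_new; r <- r_new; chi2 <- sum(r_new^2)
          lambda <- max(lambda / 10, 1e-12)
          accepted <- TRUE
          if (rel_dec < ctl$tol_chi2 || step_norm < ctl$tol_step)
            converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!accepted) { converged <- TRUE; break }  # no further descent possible
    if (converged) break
  }
  list(theta = theta, chi2 = chi2, n_iter = iter, converged = converged,
       J = J, residuals = r, free = free)
}

## ---- fitting routes ---------------------------------------------------------

default_inits <- function(model, data) {
  y0 <- vapply(model$species_names, function(comp) {
    rows <- data[data$component == comp, , drop = FALSE]
    if (nrow(rows) == 0) return(1)
    rows$value[which.min(rows$time)]
  }, numeric(1))
  list(p = setNames(rep(1, model$r), model$parameter_names), y0 = y0)
}

fit_options_default <- function(options) {
  modifyList(list(n_mesh = 96L, bvp_tol = 1e-9, boundary_tol = 1e-8,
                  max_nodes = 1537L, ivp_steps = 200L,
                  max_iter = 40L, fd_step = 1e-6, lambda0 = 1e-3,
                  tol_chi2 = 1e-8, tol_step = 1e-8, max_retry = 2L),
             options)
}

new_vode_fit <- function(method, model, data, gn, resid_fn, make_traj,
                         options, extra = list()) {
  n <- model$n; r <- model$r
  theta <- gn$theta
  p_hat <- setNames(exp(theta[seq_len(r)]), model$parameter_names)
  y0_hat <- setNames(theta[r + seq_len(n)], model$species_names)
  vcov_theta <- tryCatch({
    V <- solve(crossprod(gn$J))
    rn <- c(paste0("log_", model$parameter_names), model$species_names)[gn$free]
    dimnames(V) <- list(rn, rn)
    V
  }, error = function(e) NULL)
  structure(c(list(method = method, model = model, data = data,
                   p_hat = p_hat, y0_hat = y0_hat, theta_hat = theta,
                   chi2 = gn$chi2, n_iter = gn$n_iter,
                   converged = gn$converged,
                   vcov_theta = vcov_theta, resid_fn = resid_fn,
                   make_trajectory = make_traj, gn = gn, options = options),
              extra),
            class = "vode_fit")
}

#' Variational fit: joint estimation of parameters and input course
#'
#' Minimizes the time-discrete chi-square over the rate parameters `p`
#' (internally on log scale, reported on natural scale) and the initial
#' species values `y0`, where the model prediction at each iterate is the
#' solution of the augmented two-point BVP — i.e. the input course that is
#' optimal for the current `(p, y0)` given the data priors. Species *and*
#' input measurements enter the objective; the input prediction is the
#' reconstructed course. Optimization is Gauss-Newton with Levenberg damping
#' and forward-difference Jacobians; BVP solves are warm-started from the
#' previous iterate.
#'
#' @param model an `ode_model`.
#' @param priors list with elements `y` and `x` as from [build_priors()], or
#'   `NULL` to build them from `data` with default settings.
#' @param data measurements ([as_measurements()]).
#' @param p_init,y0_init initializers; defaults: all rates 1, species started
#'   at their earliest measured value.
#' @param options list of optimizer/solver options, see Details of
#'   [solve_augmented_bvp()] plus `max_iter`, `fd_step`, `lambda0`,
#'   `tol_chi2`, `tol_step`.
#' @param prior_settings settings forwarded to [build_priors()] when
#'   `priors` is `NULL`.
#' @return An object of class `vode_fit` with components `p_hat`, `y0_hat`,
#'   `chi2`, `converged`, `trajectory` (the solved augmented BVP at the
#'   optimum) and standard S3 methods (`print`, `summary`, `coef`,
#'   `predict`, `residuals`, `plot`, `profile`, `confint`, `simulate`).
#' @export
fit_variational <- function(model, priors = NULL, data, p_init = NULL,
                            y0_init = NULL, options = list(),
                            prior_settings = list()) {
  data <- as_measurements(data)
  if (!any(data$component %in% model$species_names))
    stop("measurements contain no species component")
  if (is.null(priors)) priors <- build_priors(data, model, prior_settings)
  system <- augmented_system(model, priors$y, priors$x)
  o <- fit_options_default(options)
  ini <- default_inits(model, data)
  if (is.null(p_init)) p_init <- ini$p
  if (is.null(y0_init)) y0_init <- ini$y0
  stopifnot(all(p_init > 0), all(is.finite(y0_init)))
  theta0 <- c(log(p_init), y0_init)

  warm <- new.env(parent = emptyenv())
  solve_at <- function(theta) {
    p <- exp(theta[seq_len(model$r)])
    y0 <- theta[model$r + seq_len(model$n)]
    bo <- list(n_mesh = o$n_mesh, bvp_tol = o$bvp_tol,
               boundary_tol = o$boundary_tol, max_nodes = o$max_nodes,
               init = warm$Z)
    traj <- NULL
    for (attempt in 0:o$max_retry) {
      traj <- tryCatch(solve_augmented_bvp(system, p, y0, bo),
                       error = function(e) e)
      if (!inherits(traj, "error")) break
      bo$init <- NULL                      # damped retry: cold start
      bo$n_mesh <- bo$n_mesh * 2L
    }
    if (inherits(traj, "error")) stop(traj)
    warm$Z <- rbind(traj$y, traj$u)
    traj
  }
  resid_fn <- function(theta) {
    traj <- solve_at(theta)
    pred <- predict_rows(traj, data)
    (data$value - pred) / data$sigma
  }
  gn <- gauss_newton(resid_fn, theta0,
                     control = o[c("max_iter", "fd_step", "lambda0",
                                   "tol_chi2", "tol_step")])
  fit <- new_vode_fit("variational", model, data, gn, resid_fn,
                      make_traj = solve_at, options = o,
                      extra = list(priors = priors, system = system))
  fit$trajectory <- solve_at(gn$theta)
  fit
}

#' Fixed-input fit: the conventional baseline
#'
#' Freezes the input at a given course (typically the smoothing-spline data
#' prior of the input measurements), solves the plain initial value problem
#' forward, and minimizes the species-only discrete chi-square over
#' `(p, y0)` with the same Gauss-Newton machinery and stopping rules as
#' [fit_variational()]. Input measurements do not contribute to the
#' objective because the input is not a model output in this approach —
#' which is precisely why it ignores input uncertainty.
#'
#' @param model an `ode_model`.
#' @param input_course the frozen input: function of `t`, a
#'   [continuous_representation()], or a list of per-input representations.
#' @param data measurements; input rows are ignored.
#' @inheritParams fit_variational
#' @return A `vode_fit` of method `"fixed_input"`.
#' @export
fit_fixed_input <- function(model, input_course, data, p_init = NULL,
                            y0_init = NULL, options = list()) {
  data <- as_measurements(data)
  sdata <- data[data$component %in% model$species_names, , drop = FALSE]
  if (nrow(sdata) == 0) stop("measurements contain no species component")
  o <- fit_options_default(options)
  ini <- default_inits(model, data)
  if (is.null(p_init)) p_init <- ini$p
  if (is.null(y0_init)) y0_init <- ini$y0
  stopifnot(all(p_init > 0), all(is.finite(y0_init)))
  theta0 <- c(log(p_init), y0_init)

  Tend <- max(data$time)
  times <- make_time_grid(Tend, o$ivp_steps, extra = sdata$time)
  xs <- rk4_input_values(input_course, times, model$m)

  solve_at <- function(theta) {
    p <- exp(theta[seq_len(model$r)])
    y0 <- theta[model$r + seq_len(model$n)]
    Y <- rk4_solve(model, y0, p, times, xs = xs)
    structure(list(times = times, y = Y, x = xs$node,
                   f = model_f_mat(model, Y, xs$node, p),
                   model = model, p = p, y0 = y0),
              class = "forward_trajectory")
  }
  resid_fn <- function(theta) {
    traj <- solve_at(theta)
    pred <- predict_rows(traj, sdata)
    (sdata$value - pred) / sdata$sigma
  }
  gn <- gauss_newton(resid_fn, theta0,
                     control = o[c("max_iter", "fd_step", "lambda0",
                                   "tol_chi2", "tol_step")])
  fit <- new_vode_fit("fixed_input", model, data, gn, resid_fn,
                      make_traj = solve_at, options = o,
                      extra = list(input_course = input_course))
  fit$trajectory <- solve_at(gn$theta)
  fit
}

#' One-call fitting front end
#'
#' Dispatches to [fit_variational()] or [fit_fixed_input()]. For the fixed
#' route the frozen input defaults to the smoothing-spline prior of the
#' input measurements in `data` — the conventional procedure.
#'
#' @inheritParams fit_variational
#' @param method `"variational"` or `"fixed_input"`.
#' @param input_course frozen input course for the fixed route (default: the
#'   input data prior built from `data`).
#' @return A `vode_fit`.
#' @export
vode_fit <- function(model, data, method = c("variational", "fixed_input"),
                     priors = NULL, input_course = NULL, p_init = NULL,
                     y0_init = NULL, options = list(), prior_settings = list()) {
  method <- match.arg(method)
  data <- as_measurements(data)
  if (method == "variational")
    return(fit_variational(model, priors, data, p_init, y0_init, options,
                           prior_settings))
  if (is.null(input_course)) {
    if (is.null(priors)) priors <- build_priors(data, model, prior_settings)
    input_course <- priors$x
  }
  fit_fixed_input(model, input_course, data, p_init, y0_init, options)
}
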