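#' Time-continuous chi-square functional
#'
#' Evaluates
#' \deqn{J[x] = \int_0^T \sum_\mu \frac{(y_\mu(t;[x]) - S_{y\mu}(t))^2}
#'   {S_{\sigma y\mu}^2(t)}\,dt
#'   + \int_0^T \sum_\nu \frac{(x_\nu(t) - S_{x\nu}(t))^2}
#'   {S_{\sigma x\nu}^2(t)}\,dt,}
#' where the species courses `y` are obtained by a forward solve of the model
#' from `y0` under the input course `x`. The solution of the augmented BVP is
#' the stationary point of this functional for given `(p, y0)`. Quadrature is
#' composite Simpson on a uniform grid.
#'
#' @param x_course the input course: a function of `t` (returning an
#'   `m`-vector or `m x K` matrix), a [continuous_representation()], a list
#'   of representations, or an `augmented_trajectory` (whose reconstructed
#'   input, starting values and parameters are then used).
#' @param system an [augmented_system()].
#' @param p parameter vector (taken from the trajectory if omitted).
#' @param y0 initial species values (taken from the trajectory if omitted).
#' @param n_quad number of Simpson intervals (made even); default
#'   `quadrature_factor` times the BVP default mesh.
#' @param quadrature_factor grid density multiplier, default 4.
#' @return scalar value of the functional.
#' @export
continuous_chi2 <- function(x_course, system, p = NULL, y0 = NULL,
                            n_quad = NULL, quadrature_factor = 4) {
  stopifnot(inherits(system, "augmented_system"))
  model <- system$model
  if (inherits(x_course, "augmented_trajectory")) {
    traj <- x_course
    if (is.null(p)) p <- traj$p
    if (is.null(y0)) y0 <- traj$y[, 1]
    if (is.null(n_quad)) n_quad <- quadrature_factor * traj$n_mesh
    x_course <- function(t) predict(traj, t)$x
  }
  if (is.null(p) || is.null(y0))
    stop("p and y0 are required unless x_course is an augmented_trajectory")
  if (is.null(n_quad)) n_quad <- quadrature_factor * 96
  n_quad <- 2L * ceiling(n_quad / 2)
  times <- seq(0, system$T, length.out = n_quad + 1)

  xs <- rk4_input_values(x_course, times, model$m)
  Y <- rk4_solve(model, y0, p, times, xs = xs)
  pg <- prior_grid(system, times)

  h <- times[2] - times[1]
  wsimp <- c(1, rep(c(4, 2), length.out = n_quad - 1), 1) * h / 3
  Jy <- sum(((Y - pg$Sy)^2 * pg$Wy) %*% wsimp)
  Jx <- if (model$m > 0)
    sum(((xs$node - pg$Sx)^2 / pg$Vx) %*% wsimp) else 0
  Jy + Jx
}

#' Numerical stationarity diagnostic
#'
#' Checks that the first variation of the time-continuous functional vanishes
#' at a trajectory: for `n_directions` random smooth perturbation courses `h`
#' (unit-normalized spline bumps, one course per input component), the
#' central-difference directional derivative
#' \eqn{(J[x + \epsilon h] - J[x - \epsilon h])/(2\epsilon)} is computed and
#' the maximum absolute value returned. At a solution of the augmented BVP
#' this diagnostic is orders of magnitude below its value at a non-stationary
#' input course; it is convention-free and therefore pins the sign
#' conventions of the augmented system.
#'
#' @param system an [augmented_system()].
#' @param trajectory an `augmented_trajectory` from [solve_augmented_bvp()],
#'   or any input course accepted by [continuous_chi2()] (then `p`, `y0`
#'   must be supplied).
#' @param n_directions number of random perturbation directions.
#' @param seed RNG seed for the directions.
#' @param p,y0 parameters and starting values when `trajectory` is a bare
#'   course.
#' @param eps finite-difference step on the input scale.
#' @param n_knots spline knots per perturbation course.
#' @return maximum absolute directional derivative over the sampled
#'   directions.
#' @export
stationarity_check <- function(system, trajectory, n_directions = 10,
                               seed = 1L, p = NULL, y0 = NULL,
                               eps = 1e-4, n_knots = 9) {
  stopifnot(inherits(system, "augmented_system"))
  model <- system$model
  if (model$m == 0) stop("system has no inputs to perturb")
  if (inherits(trajectory, "augmented_trajectory")) {
    if (is.null(p)) p <- trajectory$p
    if (is.null(y0)) y0 <- trajectory$y[, 1]
    base <- function(t) predict(trajectory, t)$x
  } else {
    if (is.null(p) || is.null(y0)) stop("p and y0 required for a bare course")
    base <- function(t) eval_input_course(trajectory, t, model$m)
  }
  Tend <- system$T
  knots <- seq(0, Tend, length.out = n_knots)
  tnorm <- seq(0, Tend, length.out = 201)

  state <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(state)) assign(".Random.seed", state, envir = globalenv()))
  set.seed(seed)
  worst <- 0
  for (dd in seq_len(n_directions)) {
    sf <- lapply(seq_len(model$m), function(nu)
      splinefun(knots, rnorm(n_knots), method = "natural"))
    hfun <- function(t) do.call(rbind, lapply(sf, function(f) f(t)))
    nrm <- sqrt(sum(apply(hfun(tnorm)^2, 1, function(v)
      sum((v[-1] + v[-length(v)]) / 2) * diff(tnorm)[1])))
    hf <- function(t) hfun(t) / nrm
    Jp <- continuous_chi2(function(t) base(t) + eps * hf(t), system, p, y0)
    Jm <- continuous_chi2(function(t) base(t) - eps * hf(t), system, p, y0)
    worst <- max(worst, abs(Jp - Jm) / (2 * eps))
  }
  worst
}
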