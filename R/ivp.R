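## Fixed-step classic Runge-Kutta (RK4) integration of y' = f(y, x(t), p) on a
## given (not necessarily uniform) time grid. Fixed step keeps the objective
## smooth in (p, y0), which the Gauss-Newton outer loop relies on.

## Evaluate an input course at a vector of times; accepts a function
## (returning an m-vector per time or an m x K matrix for vector input),
## a continuous_representation, or a list of per-input representations.
eval_input_course <- function(x_course, t, m) {
  if (inherits(x_course, "continuous_representation"))
    return(matrix(x_course$S(t), nrow = m))
  if (is.list(x_course) && !is.function(x_course)) {
    stopifnot(length(x_course) == m)
    return(do.call(rbind, lapply(x_course, function(r) r$S(t))))
  }
  out <- x_course(t)
  if (is.matrix(out)) {
    stopifnot(nrow(out) == m)
    out
  } else if (length(t) == 1L) {
    matrix(out, nrow = m)
  } else {
    stopifnot(m == 1L, length(out) == length(t))
    matrix(out, nrow = 1)
  }
}

## Precompute input values at grid nodes and midpoints for rk4_solve.
rk4_input_values <- function(x_course, times, m) {
  K <- length(times)
  tm <- (times[-K] + times[-1]) / 2
  list(node = eval_input_course(x_course, times, m),
       mid = eval_input_course(x_course, tm, m))
}

## Integrate and return the n x K matrix of states at `times`.
## `xs` may carry precomputed input values (see rk4_input_values).
rk4_solve <- function(model, y0, p, times, x_course = NULL, xs = NULL) {
  n <- model$n; K <- length(times)
  stopifnot(length(y0) == n, K >= 2, all(diff(times) > 0))
  if (is.null(xs)) xs <- rk4_input_values(x_course, times, model$m)
  Y <- matrix(0.0, n, K)
  Y[, 1] <- y0
  f <- model$f
  y <- as.numeric(y0)
  for (k in seq_len(K - 1)) {
    h <- times[k + 1] - times[k]
    x1 <- xs$node[, k]; xm <- xs$mid[, k]; x2 <- xs$node[, k + 1]
    k1 <- f(y, x1, p)
    k2 <- f(y + h / 2 * k1, xm, p)
    k3 <- f(y + h / 2 * k2, xm, p)
    k4 <- f(y + h * k3, x2, p)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(y)))
      stop("forward solve diverged at t = ", format(times[k + 1]))
    Y[, k + 1] <- y
  }
  Y
}

## Uniform grid on [0, T] with n_steps intervals, augmented by extra times
## (e.g. measurement times) so states are available there without interpolation.
make_time_grid <- function(T, n_steps, extra = numeric(0), t0 = 0) {
  g <- seq(t0, T, length.out = n_steps + 1)
  sort(unique(c(g, extra[extra >= t0 & extra <= T])))
}
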