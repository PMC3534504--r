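#' ODE reaction-network models with time-varying inputs
#'
#' An `ode_model` bundles the right-hand side \eqn{f(y, x, p)} of a reaction
#' network with `n` species `y`, `m` time-dependent inputs `x` and `r` rate
#' parameters `p`, together with the analytic Jacobians \eqn{\nabla_y f}
#' (`n x n`) and \eqn{\nabla_x f} (`n x m`). The Jacobians are consumed at
#' every step of the augmented adjoint system, which is why they are required
#' analytically; a central finite-difference self-check against `f` is run at
#' construction time.
#'
#' All three functions must accept `y` (length `n`), `x` (length `m`) and `p`
#' (length `r`). If `vectorized = TRUE` they must additionally accept `y` and
#' `x` as matrices with one column per evaluation point (`n x K`, `m x K`) and
#' return an `n x K` matrix (`f`) or an array with the point index last
#' (`n x n x K`, `n x m x K`). Non-vectorized models are wrapped in a column
#' loop, which is correct but slower inside the collocation solver.
#'
#' @param n,m,r species, input and parameter counts.
#' @param f right-hand side, `f(y, x, p)` in concentration per time unit.
#' @param jac_y,jac_x analytic Jacobians of `f` with respect to `y` and `x`.
#' @param species_names,input_names,parameter_names character identifiers.
#' @param vectorized logical; do `f`, `jac_y`, `jac_x` handle matrix input?
#' @param check logical; run the finite-difference Jacobian self-check.
#' @param name optional model name (used by [register_model()]).
#'
#' @return An object of class `ode_model`.
#' @seealso [make_toy_model()], [eval_model()], [extend_positive_input()],
#'   [apply_input_transform()]
#' @export
new_ode_model <- function(n, m, r, f, jac_y, jac_x,
                          species_names = paste0("y", seq_len(n)),
                          input_names = if (m > 0) paste0("x", seq_len(m)) else character(0),
                          parameter_names = if (r > 0) paste0("p", seq_len(r)) else character(0),
                          vectorized = FALSE, check = TRUE, name = NULL) {
  stopifnot(n >= 1, m >= 0, r >= 0,
            is.function(f), is.function(jac_y), is.function(jac_x),
            length(species_names) == n, length(input_names) == m,
            length(parameter_names) == r)
  model <- structure(
    list(n = as.integer(n), m = as.integer(m), r = as.integer(r),
         f = f, jac_y = jac_y, jac_x = jac_x,
         species_names = as.character(species_names),
         input_names = as.character(input_names),
         parameter_names = as.character(parameter_names),
         vectorized = isTRUE(vectorized), name = name),
    class = "ode_model")
  if (check) check_model_jacobians(model)
  model
}

#' @export
print.ode_model <- function(x, ...) {
  cat("ODE model", if (!is.null(x$name)) sQuote(x$name) else "", "\n")
  cat("  species   (n=", x$n, "): ", paste(x$species_names, collapse = ", "), "\n", sep = "")
  cat("  inputs    (m=", x$m, "): ", paste(x$input_names, collapse = ", "), "\n", sep = "")
  cat("  parameters(r=", x$r, "): ", paste(x$parameter_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

## central finite differences of f; the oracle that analytic Jacobians must match
fd_jac <- function(fun, v, eps = NULL) {
  if (is.null(eps)) eps <- pmax(1e-6, 1e-6 * abs(v))
  f0 <- fun(v)
  J <- matrix(0.0, length(f0), length(v))
  for (j in seq_along(v)) {
    vp <- v; vm <- v
    vp[j] <- v[j] + eps[j]; vm[j] <- v[j] - eps[j]
    J[, j] <- (fun(vp) - fun(vm)) / (2 * eps[j])
  }
  J
}

#' Self-check analytic Jacobians against central finite differences
#'
#' Samples random states with positive parameters and compares `jac_y` and
#' `jac_x` with central finite differences of `f`.
#'
#' @param model an [new_ode_model()] object.
#' @param n_states number of random states to test.
#' @param rel_tol relative tolerance of the comparison.
#' @param seed RNG seed for the sampled states.
#' @return `TRUE` invisibly; errors if a Jacobian disagrees.
#' @export
check_model_jacobians <- function(model, n_states = 10, rel_tol = 1e-5, seed = 1L) {
  state <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(state)) assign(".Random.seed", state, envir = globalenv()))
  set.seed(seed)
  for (i in seq_len(n_states)) {
    y <- runif(model$n, 0.1, 2)
    x <- if (model$m > 0) runif(model$m, 0.1, 2) else numeric(0)
    p <- if (model$r > 0) runif(model$r, 0.1, 3) else numeric(0)
    f0 <- model$f(y, x, p)
    if (!all(is.finite(f0)) || length(f0) != model$n)
      stop("model f() returned a non-finite or wrong-length value")
    Jy <- model$jac_y(y, x, p)
    Jy_fd <- fd_jac(function(v) model$f(v, x, p), y)
    scl <- max(abs(Jy_fd), 1)
    if (max(abs(Jy - Jy_fd)) > rel_tol * scl)
      stop("analytic jac_y disagrees with finite differences (max abs diff ",
           format(max(abs(Jy - Jy_fd))), ")")
    if (model$m > 0) {
      Jx <- model$jac_x(y, x, p)
      Jx_fd <- fd_jac(function(v) model$f(y, v, p), x)
      scl <- max(abs(Jx_fd), 1)
      if (max(abs(Jx - Jx_fd)) > rel_tol * scl)
        stop("analytic jac_x disagrees with finite differences (max abs diff ",
             format(max(abs(Jx - Jx_fd))), ")")
    }
  }
  invisible(TRUE)
}

#' Evaluate a model once
#'
#' Single entry point returning the consistent triple
#' `(f, jac_y, jac_x)` at a state, with dimension checking.
#'
#' @param model an `ode_model`.
#' @param y,x,p state, input and parameter vectors.
#' @return list with elements `f` (length `n`), `jac_y` (`n x n`),
#'   `jac_x` (`n x m`).
#' @export
eval_model <- function(model, y, x, p) {
  if (length(y) != model$n)
    stop("argument 'y' has length ", length(y), ", expected n = ", model$n)
  if (length(x) != model$m)
    stop("argument 'x' has length ", length(x), ", expected m = ", model$m)
  if (length(p) != model$r)
    stop("argument 'p' has length ", length(p), ", expected r = ", model$r)
  list(f = as.numeric(model$f(y, x, p)),
       jac_y = matrix(model$jac_y(y, x, p), model$n, model$n),
       jac_x = matrix(model$jac_x(y, x, p), model$n, model$m))
}

## vectorized evaluation over K columns; wraps non-vectorized models
model_f_mat <- function(model, Y, X, p) {
  if (model$vectorized) return(model$f(Y, X, p))
  K <- ncol(Y)
  out <- matrix(0.0, model$n, K)
  for (k in seq_len(K)) out[, k] <- model$f(Y[, k], X[, k, drop = TRUE], p)
  out
}

model_jacy_arr <- function(model, Y, X, p) {
  if (model$vectorized) return(model$jac_y(Y, X, p))
  K <- ncol(Y)
  out <- array(0.0, c(model$n, model$n, K))
  for (k in seq_len(K)) out[, , k] <- model$jac_y(Y[, k], X[, k, drop = TRUE], p)
  out
}

model_jacx_arr <- function(model, Y, X, p) {
  if (model$vectorized) return(model$jac_x(Y, X, p))
  K <- ncol(Y)
  out <- array(0.0, c(model$n, model$m, K))
  for (k in seq_len(K)) out[, , k] <- model$jac_x(Y[, k], X[, k, drop = TRUE], p)
  out
}

#' The reversible two-species toy model
#'
#' The built-in reaction network \eqn{A \rightleftharpoons B} in which the
#' forward reaction \eqn{A \to B} is mediated by a time-varying input `x`
#' (mass-action rate `k1*A*x`) while the back reaction proceeds at rate
#' `k2*B`:
#' \deqn{\dot A = -k_1 A x + k_2 B, \qquad \dot B = +k_1 A x - k_2 B.}
#' Total mass `A + B` is conserved along any trajectory, and the input enters
#' the dynamics linearly, so the closed-form input elimination of the
#' variational approach applies.
#'
#' @return An `ode_model` with `n = 2` species (`A`, `B`), `m = 1` input
#'   (`x`) and `r = 2` rate parameters (`k1`, `k2`).
#' @examples
#' toy <- make_toy_model()
#' eval_model(toy, y = c(A = 1, B = 0.5), x = 1, p = c(k1 = 2, k2 = 0.5))$f
#' @export
make_toy_model <- function() {
  f <- function(y, x, p) {
    if (is.matrix(y)) {
      v <- p[1] * y[1, ] * x[1, ] - p[2] * y[2, ]
      rbind(-v, v, deparse.level = 0)
    } else {
      v <- p[1] * y[1] * x[1] - p[2] * y[2]
      c(-v, v)
    }
  }
  jac_y <- function(y, x, p) {
    if (is.matrix(y)) {
      K <- ncol(y)
      J <- array(0.0, c(2, 2, K))
      J[1, 1, ] <- -p[1] * x[1, ]; J[1, 2, ] <- p[2]
      J[2, 1, ] <- p[1] * x[1, ];  J[2, 2, ] <- -p[2]
      J
    } else {
      matrix(c(-p[1] * x[1], p[1] * x[1], p[2], -p[2]), 2, 2)
    }
  }
  jac_x <- function(y, x, p) {
    if (is.matrix(y)) {
      K <- ncol(y)
      J <- array(0.0, c(2, 1, K))
      J[1, 1, ] <- -p[1] * y[1, ]
      J[2, 1, ] <- p[1] * y[1, ]
      J
    } else {
      matrix(c(-p[1] * y[1], p[1] * y[1]), 2, 1)
    }
  }
  new_ode_model(2, 1, 2, f, jac_y, jac_x,
                species_names = c("A", "B"), input_names = "x",
                parameter_names = c("k1", "k2"),
                vectorized = TRUE, check = FALSE, name = "reversible_toy")
}

## ---- model registry (plug-in contract) --------------------------------------

the_registry <- new.env(parent = emptyenv())

#' Model registry
#'
#' Models are registered by name so that configuration files and the command
#' line can refer to them. The toy model is registered as `"reversible_toy"`
#' when the package is loaded.
#'
#' @param name model name.
#' @param model an `ode_model`; its Jacobian self-check is re-run on
#'   registration.
#' @return `register_model` returns the model invisibly; `get_model` returns
#'   the registered model or errors; `list_models` returns the registered
#'   names.
#' @export
register_model <- function(name, model) {
  stopifnot(is.character(name), length(name) == 1, inherits(model, "ode_model"))
  check_model_jacobians(model)
  model$name <- name
  assign(name, model, envir = the_registry)
  invisible(model)
}

#' @rdname register_model
#' @export
get_model <- function(name) {
  if (!exists(name, envir = the_registry, inherits = FALSE))
    stop("unknown model ", sQuote(name), "; registered models: ",
         paste(list_models(), collapse = ", "))
  get(name, envir = the_registry, inherits = FALSE)
}

#' @rdname register_model
#' @export
list_models <- function() sort(ls(the_registry))
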