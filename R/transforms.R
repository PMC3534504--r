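#' Input transforms
#'
#' Declares a coordinate change of the input variables,
#' \eqn{\tilde x = \varphi(x, p)}, under which the right-hand side of a model
#' factorizes linearly, \eqn{f_\mu = \sum_\nu g_{\mu\nu}(y,p)\,\tilde x_\nu +
#' g_{\mu 0}(y,p)}. Typical examples are \eqn{\varphi(x) = x^2} for a
#' bimolecular reaction or \eqn{\varphi(x, K_D) = x/(K_D + x)} for an
#' enzymatic (saturating) rate. `phi` must be monotone and differentiable on
#' the declared domain so that the original input can be reported back.
#'
#' @param phi function `phi(x, p)` mapping the original input (vector of
#'   length `m`) to the transformed input, componentwise.
#' @param phi_inv optional inverse `phi_inv(xt, p)`; if omitted, a monotone
#'   root search on `domain` is used.
#' @param dphi optional derivative `dphi(x, p)` of `phi` in `x`
#'   (componentwise); finite differences otherwise.
#' @param domain numeric length-2, the input domain on which `phi` is
#'   monotone (applies to every component).
#' @param description identifier used in printing.
#' @return An object of class `input_transform`.
#' @seealso [apply_input_transform()]
#' @export
input_transform <- function(phi, phi_inv = NULL, dphi = NULL,
                            domain = c(1e-8, 1e6), description = "transform") {
  stopifnot(is.function(phi), length(domain) == 2, domain[1] < domain[2])
  structure(list(phi = phi, phi_inv = phi_inv, dphi = dphi,
                 domain = as.numeric(domain), description = description),
            class = "input_transform")
}

transform_dphi <- function(tr, x, p) {
  if (!is.null(tr$dphi)) return(as.numeric(tr$dphi(x, p)))
  h <- pmax(1e-7, 1e-7 * abs(x))
  as.numeric((tr$phi(x + h, p) - tr$phi(x - h, p)) / (2 * h))
}

transform_inverse <- function(tr, xt, p) {
  if (!is.null(tr$phi_inv)) return(as.numeric(tr$phi_inv(xt, p)))
  vapply(seq_along(xt), function(nu) {
    g <- function(z) {
      x <- xt; x[nu] <- z
      tr$phi(x, p)[nu] - xt[nu]
    }
    uniroot(g, lower = tr$domain[1], upper = tr$domain[2],
            extendInt = "yes", tol = 1e-12)$root
  }, numeric(1))
}

check_transform_monotone <- function(tr, p, n_points = 25) {
  z <- seq(tr$domain[1], min(tr$domain[2], tr$domain[1] + 10), length.out = n_points)
  d <- vapply(z, function(zz) transform_dphi(tr, rep(zz, 1), p)[1], numeric(1))
  if (any(d > 0) && any(d < 0))
    stop("input transform ", sQuote(tr$description),
         " is not monotone on its declared domain")
  invisible(TRUE)
}

#' Positivity extension of the input
#'
#' Reformulates a model with inputs `x` so that the original inputs become
#' ordinary state variables with dynamics \eqn{\dot x = -D(t)\,x},
#' \eqn{D = \mathrm{diag}(d_1,\dots,d_m)}, driven by new inputs `d` that enter
#' linearly. Because \eqn{\dot x_\nu = -d_\nu x_\nu}, each \eqn{x_\nu(t)}
#' keeps the sign of \eqn{x_\nu(0)} for any bounded course of `d`; choosing
#' \eqn{x_\nu(0) > 0} therefore enforces positivity of the reconstructed
#' input. It also provides a workaround for nonlinearly entering inputs: the
#' augmented model is always linear in its (new) inputs.
#'
#' A constant data prior `S_d = 0` with constant uncertainty acts as a
#' penalty on the first derivative of `x` (see [constant_prior()]).
#'
#' @param model an `ode_model` with `m >= 1` inputs.
#' @return An `ode_model` with `n + m` states (the old species followed by
#'   the old inputs) and `m` new inputs named `d_<input>`.
#' @export
extend_positive_input <- function(model) {
  stopifnot(inherits(model, "ode_model"))
  if (model$m < 1) stop("model has no inputs to extend")
  n <- model$n; m <- model$m
  ne <- n + m
  iy <- seq_len(n); ix <- n + seq_len(m)
  f0 <- model$f; jy0 <- model$jac_y; jx0 <- model$jac_x
  vec <- model$vectorized

  f <- function(y, x, p) {
    if (is.matrix(y)) {
      yo <- y[iy, , drop = FALSE]; xo <- y[ix, , drop = FALSE]
      rbind(if (vec) f0(yo, xo, p) else
              vapply(seq_len(ncol(y)), function(k) f0(yo[, k], xo[, k], p), numeric(n)),
            -x * xo, deparse.level = 0)
    } else {
      c(f0(y[iy], y[ix], p), -x * y[ix])
    }
  }
  jac_y <- function(y, x, p) {
    if (is.matrix(y)) {
      K <- ncol(y)
      yo <- y[iy, , drop = FALSE]; xo <- y[ix, , drop = FALSE]
      J <- array(0.0, c(ne, ne, K))
      Jy <- if (vec) jy0(yo, xo, p) else {
        a <- array(0.0, c(n, n, K))
        for (k in seq_len(K)) a[, , k] <- jy0(yo[, k], xo[, k], p)
        a
      }
      Jx <- if (vec) jx0(yo, xo, p) else {
        a <- array(0.0, c(n, m, K))
        for (k in seq_len(K)) a[, , k] <- jx0(yo[, k], xo[, k], p)
        a
      }
      J[iy, iy, ] <- Jy
      J[iy, ix, ] <- Jx
      for (nu in seq_len(m)) J[n + nu, n + nu, ] <- -x[nu, ]
      J
    } else {
      J <- matrix(0.0, ne, ne)
      J[iy, iy] <- jy0(y[iy], y[ix], p)
      J[iy, ix] <- jx0(y[iy], y[ix], p)
      J[cbind(ix, ix)] <- -x
      J
    }
  }
  jac_x <- function(y, x, p) {
    if (is.matrix(y)) {
      K <- ncol(y)
      J <- array(0.0, c(ne, m, K))
      for (nu in seq_len(m)) J[n + nu, nu, ] <- -y[n + nu, ]
      J
    } else {
      J <- matrix(0.0, ne, m)
      J[cbind(n + seq_len(m), seq_len(m))] <- -y[ix]
      J
    }
  }
  new_ode_model(ne, m, model$r, f, jac_y, jac_x,
                species_names = c(model$species_names, model$input_names),
                input_names = paste0("d_", model$input_names),
                parameter_names = model$parameter_names,
                vectorized = TRUE, check = FALSE,
                name = if (!is.null(model$name)) paste0(model$name, "_positive"))
}

#' Change of input variables
#'
#' Re-expresses a model in transformed input coordinates
#' \eqn{\tilde x = \varphi(x, p)}. The caller asserts that the right-hand
#' side factorizes linearly in \eqn{\tilde x}; this is verified by a
#' finite-difference linearity test, and violation is an error (such models
#' should be routed through [extend_positive_input()] instead). The returned
#' model's input Jacobian is independent of the input, so the closed-form
#' input elimination of the augmented system applies.
#'
#' @param model an `ode_model`.
#' @param transform an [input_transform()].
#' @param p_check parameter vector at which the linearity and monotonicity
#'   checks are run (defaults to all ones).
#' @return An `ode_model` in the transformed input coordinates, with input
#'   names prefixed `phi_`.
#' @export
apply_input_transform <- function(model, transform, p_check = rep(1, model$r)) {
  stopifnot(inherits(model, "ode_model"), inherits(transform, "input_transform"))
  if (model$m < 1) stop("model has no inputs to transform")
  check_transform_monotone(transform, p_check)
  n <- model$n; m <- model$m

  f_t <- function(y, xt, p) model$f(y, transform_inverse(transform, xt, p), p)
  jac_y_t <- function(y, xt, p) model$jac_y(y, transform_inverse(transform, xt, p), p)
  jac_x_t <- function(y, xt, p) {
    x <- transform_inverse(transform, xt, p)
    d <- transform_dphi(transform, x, p)
    Jx <- matrix(model$jac_x(y, x, p), n, m)
    sweep(Jx, 2, d, "/")
  }

  ## linearity test in the transformed coordinates
  state <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(state)) assign(".Random.seed", state, envir = globalenv()))
  set.seed(7L)
  lo <- transform$domain[1]; hi <- min(transform$domain[2], lo + 2)
  for (i in 1:5) {
    y <- runif(n, 0.1, 2)
    xa <- runif(m, lo, hi); xc <- runif(m, lo, hi)
    a <- transform$phi(xa, p_check); cc <- transform$phi(xc, p_check)
    b <- (a + cc) / 2
    fa <- f_t(y, a, p_check); fc <- f_t(y, cc, p_check); fb <- f_t(y, b, p_check)
    scl <- max(abs(c(fa, fb, fc)), 1)
    if (max(abs(fa + fc - 2 * fb)) > 1e-6 * scl)
      stop("right-hand side is not linear in the transformed input; ",
           "use extend_positive_input() for nonlinearly entering inputs")
  }

  new_ode_model(n, m, model$r, f_t, jac_y_t, jac_x_t,
                species_names = model$species_names,
                input_names = paste0("phi_", model$input_names),
                parameter_names = model$parameter_names,
                vectorized = FALSE, check = FALSE,
                name = if (!is.null(model$name)) paste0(model$name, "_", transform$description))
}
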