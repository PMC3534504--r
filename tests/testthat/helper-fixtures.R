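## Shared fixtures: zero-residual priors, small scenarios, FD oracles.

toy <- make_toy_model()

## Priors whose species courses are the (numerically exact) forward solution
## under the given input course: the augmented BVP then has the exact solution
## y = S_y, u = 0, x = S_x.
forward_solution_priors <- function(model, p, y0, x_course, T = 5,
                                    sigma = 0.1, n_grid = 1001) {
  tg <- seq(0, T, length.out = n_grid)
  xmat <- function(t) matrix(x_course(t), nrow = model$m)
  Y <- varode:::rk4_solve(model, y0, p, tg, x_course = xmat)
  priors_y <- lapply(seq_len(model$n), function(i) {
    sf <- splinefun(tg, Y[i, ], method = "fmm")
    continuous_representation(sf, sigma2 = sigma^2, domain = c(0, T))
  })
  priors_x <- lapply(seq_len(model$m), function(j) {
    continuous_representation(function(t) x_course(t), sigma2 = sigma^2,
                              domain = c(0, T))
  })
  list(y = priors_y, x = priors_x)
}

## Central finite differences, independent of the package's fd_jac.
num_jac <- function(fun, v, eps = 1e-6) {
  f0 <- fun(v)
  J <- matrix(0.0, length(f0), length(v))
  for (j in seq_along(v)) {
    vp <- v; vm <- v
    vp[j] <- v[j] + eps; vm[j] <- v[j] - eps
    J[, j] <- (fun(vp) - fun(vm)) / (2 * eps)
  }
  J
}

## The printed augmented toy system (states A, B, adjoints uA, uB) and the
## printed input relation, written out verbatim as an independent oracle.
toy_printed_rhs <- function(state, p, SA, SB, Sx, VA, VB, Vx) {
  A <- state[1]; B <- state[2]; uA <- state[3]; uB <- state[4]
  k1 <- p[1]; k2 <- p[2]
  x <- Sx + Vx * k1 * A * (uA - uB)
  c(-k1 * A * x + k2 * B,
    k1 * A * x - k2 * B,
    k1 * x * (uA - uB) - (A - SA) / VA,
    -k2 * (uA - uB) - (B - SB) / VB)
}

## Constant-prior augmented system for the toy model, handy for pointwise checks.
toy_const_system <- function(SA = 1, SB = 0.5, Sx = 1,
                             VA = 0.01, VB = 0.01, Vx = 0.25, T = 5) {
  augmented_system(
    toy,
    priors_y = list(continuous_representation(function(t) rep(SA, length(t)),
                                              sigma2 = VA, domain = c(0, T)),
                    continuous_representation(function(t) rep(SB, length(t)),
                                              sigma2 = VB, domain = c(0, T))),
    priors_x = list(continuous_representation(function(t) rep(Sx, length(t)),
                                              sigma2 = Vx, domain = c(0, T))))
}
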