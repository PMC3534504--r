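test_that("input elimination solves the stationarity condition in closed form", {
  sys <- toy_const_system(Sx = 1, Vx = 0.25)
  p <- c(2, 0.5)

  ## zero adjoint: the input equals its prior
  expect_equal(eliminate_input(sys, y = c(1, 0), u = c(0, 0), t = 2, p), 1)

  ## printed toy relation: x = Sx + Vx * k1 * A * (uA - uB)
  x <- eliminate_input(sys, y = c(1, 0), u = c(0.3, -0.1), t = 2, p)
  expect_equal(x, 1 + 0.25 * 2 * 1 * 0.4, tolerance = 1e-12)

  ## stationarity residual of the continuous functional is zero at the
  ## eliminated input: (x - Sx)/Vx + (jac_x^T u) = 0
  Jx <- eval_model(toy, c(1, 0), x, p)$jac_x
  expect_lt(abs((x - 1) / 0.25 + sum(Jx[, 1] * c(0.3, -0.1))), 1e-10)

  ## nonlinearly entering input is refused at system construction
  nl <- new_ode_model(1, 1, 1,
                      f = function(y, x, p) -p[1] * y[1] * x[1]^2,
                      jac_y = function(y, x, p) matrix(-p[1] * x[1]^2),
                      jac_x = function(y, x, p) matrix(-2 * p[1] * y[1] * x[1]))
  expect_error(
    augmented_system(nl,
                     list(constant_prior(1, 0.1, 5)),
                     list(constant_prior(1, 0.1, 5))),
    "extend_positive_input")
})

test_that("augmented rhs reduces to the printed toy system", {
  p <- c(2, 0.5)

  ## residual-free point: u = 0, y on the prior => udot = 0, ydot = f(y, Sx, p)
  sys <- toy_const_system(SA = 1, SB = 0.5, Sx = 1)
  rhs <- augmented_rhs(sys, t = 1, state = c(1, 0.5, 0, 0), p = p)
  expect_equal(rhs[3:4], c(0, 0))
  expect_equal(rhs[1:2], toy$f(c(1, 0.5), 1, p))

  ## adjoint source terms at (A,B) = (S_A,S_B) = (1,0), u = (0.3, -0.1)
  sys <- toy_const_system(SA = 1, SB = 0, Sx = 1, Vx = 0.25)
  x <- eliminate_input(sys, c(1, 0), c(0.3, -0.1), 1, p)
  rhs <- augmented_rhs(sys, 1, c(1, 0, 0.3, -0.1), p)
  expect_equal(rhs[3], 2 * x * 0.4, tolerance = 1e-12)
  expect_equal(rhs[4], -0.5 * 0.4, tolerance = 1e-12)

  ## mass conservation for arbitrary adjoints and priors
  set.seed(8)
  for (i in 1:20) {
    sys_i <- toy_const_system(SA = runif(1), SB = runif(1), Sx = runif(1, 0.2, 2),
                              VA = runif(1, 0.005, 0.1), VB = runif(1, 0.005, 0.1),
                              Vx = runif(1, 0.05, 1))
    st <- c(runif(2, 0.1, 2), runif(2, -1, 1))
    rhs <- augmented_rhs(sys_i, runif(1, 0, 5), st, runif(2, 0.2, 3))
    expect_equal(rhs[1] + rhs[2], 0, tolerance = 1e-12)
  }

  expect_error(augmented_rhs(sys, 1, c(1, NA, 0, 0), p), "non-finite")
})

test_that("general augmented system matches the printed equations to 1e-12", {
  set.seed(13)
  for (i in 1:50) {
    SA <- runif(1, 0.2, 2); SB <- runif(1, 0, 1); Sx <- runif(1, 0.1, 2)
    VA <- runif(1, 0.005, 0.2); VB <- runif(1, 0.005, 0.2); Vx <- runif(1, 0.05, 1)
    p <- runif(2, 0.2, 4)
    st <- c(runif(2, 0.05, 2.5), runif(2, -1.5, 1.5))
    sys <- toy_const_system(SA, SB, Sx, VA, VB, Vx)
    got_x <- eliminate_input(sys, st[1:2], st[3:4], 1, p)
    want_x <- Sx + Vx * p[1] * st[1] * (st[3] - st[4])
    expect_equal(got_x, want_x, tolerance = 1e-12)
    got <- augmented_rhs(sys, 1, st, p)
    want <- toy_printed_rhs(st, p, SA, SB, Sx, VA, VB, Vx)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("zero-residual fixture is recovered for all three input families", {
  p <- c(2, 0.5); y0 <- c(1, 0)
  for (family in c("exp_decay", "activation", "gaussian")) {
    xfun <- make_input(family)
    pr <- forward_solution_priors(toy, p, y0, xfun)
    sys <- augmented_system(toy, pr$y, pr$x)
    traj <- solve_augmented_bvp(sys, p, y0, options = list(n_mesh = 384))
    expect_lt(max(abs(traj$u)), 1e-6)
    Sy <- rbind(pr$y[[1]]$S(traj$times), pr$y[[2]]$S(traj$times))
    expect_lt(max(abs(traj$y - Sy)), 1e-6)
    expect_lt(max(abs(traj$x - rbind(xfun(traj$times)))), 1e-6)
    ## boundary condition on every converged solve
    expect_lt(max(abs(traj$u[, ncol(traj$u)])), 1e-8)
    ## the functional is at its global minimum zero
    expect_lt(continuous_chi2(traj, sys), 1e-8)
  }
})

test_that("continuous chi2 matches closed forms and converges under refinement", {
  ## inert single-species model: constant offset c with constant weight w
  ## gives J = w * c^2 * T exactly
  inert <- new_ode_model(1, 1, 0,
                         f = function(y, x, p) 0 * y,
                         jac_y = function(y, x, p) matrix(0),
                         jac_x = function(y, x, p) matrix(0))
  Tend <- 2; w <- 4; cc <- 0.3
  sys0 <- augmented_system(
    inert,
    list(continuous_representation(function(t) rep(0, length(t)),
                                   sigma2 = 1 / w, domain = c(0, Tend))),
    list(constant_prior(1, 1, Tend)))
  J <- continuous_chi2(function(t) rbind(rep(1, length(t))), sys0,
                       p = numeric(0), y0 = cc)
  expect_equal(J, w * cc^2 * Tend, tolerance = 1e-10)

  ## quadrature refinement changes a smooth J by <= 1e-6 relative
  xfun <- make_input("gaussian")
  pr <- forward_solution_priors(toy, c(2, 0.5), c(1, 0), xfun)
  sys <- augmented_system(toy, pr$y, pr$x)
  course <- function(t) rbind(xfun(t) + 0.1 * sin(t))
  J1 <- continuous_chi2(course, sys, p = c(2, 0.5), y0 = c(1, 0), n_quad = 400)
  J2 <- continuous_chi2(course, sys, p = c(2, 0.5), y0 = c(1, 0), n_quad = 800)
  expect_lt(abs(J2 - J1) / abs(J1), 1e-6)
})

test_that("the BVP solution is stationary and locally minimal", {
  sc <- scenario_config(seed = 21)
  data <- simulate_dataset(toy, sc)
  priors <- build_priors(data, toy, T = sc$T)
  sys <- augmented_system(toy, priors$y, priors$x)
  p <- c(2, 0.5); y0 <- c(1, 0)
  traj <- solve_augmented_bvp(sys, p, y0)

  ## stationary: directional derivatives orders below a non-stationary course
  d_sol <- stationarity_check(sys, traj, n_directions = 10, seed = 3)
  d_prior <- stationarity_check(sys, function(t) rbind(priors$x$x$S(t)),
                                n_directions = 10, seed = 3, p = p, y0 = y0)
  expect_lt(d_sol, 1e-3 * d_prior)

  ## deliberately perturbed course is clearly non-stationary
  d_pert <- stationarity_check(
    sys, function(t) predict(traj, t)$x + 0.2, n_directions = 10, seed = 3,
    p = p, y0 = y0)
  expect_gt(d_pert, 10 * d_sol)

  ## the stationary input can only improve the functional over the prior course
  J_sol <- continuous_chi2(traj, sys)
  J_prior <- continuous_chi2(function(t) rbind(priors$x$x$S(t)), sys,
                             p = p, y0 = y0)
  expect_lt(J_sol, J_prior)

  ## local minimality under 50 random smooth perturbations
  set.seed(99)
  knots <- seq(0, 5, length.out = 9)
  base <- function(t) predict(traj, t)$x
  for (i in 1:50) {
    hf <- splinefun(knots, rnorm(9), method = "natural")
    eps <- 0.02
    Jp <- continuous_chi2(function(t) base(t) + eps * rbind(hf(t)), sys,
                          p = p, y0 = y0)
    expect_gte(Jp, J_sol - 1e-9)
  }
})
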