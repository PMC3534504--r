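test_that("toy model reproduces its closed-form rates and Jacobians", {
  ev <- eval_model(toy, y = c(1, 0.5), x = 1, p = c(2, 0.5))
  expect_equal(ev$f, c(-1.75, 1.75))
  expect_equal(ev$jac_y, matrix(c(-2, 2, 0.5, -0.5), 2, 2))

  ## all reaction terms vanish with x = 0 and k2 = 0
  expect_equal(eval_model(toy, c(0.3, 1.2), x = 0, p = c(2, 0))$f, c(0, 0))

  ## input Jacobian column at (A, B) = (1, 0)
  expect_equal(eval_model(toy, c(1, 0), x = 1, p = c(2, 0.5))$jac_x,
               matrix(c(-2, 2), 2, 1))
})

test_that("eval_model validates dimensions and conserves toy mass", {
  expect_equal(sum(eval_model(toy, c(1, 0.5), 1, c(2, 0.5))$f), 0)
  expect_error(eval_model(toy, c(1, 0.5), 1, c(2, 0.5, 3)), "'p'")
  expect_error(eval_model(toy, c(1, 0.5, 2), 1, c(2, 0.5)), "'y'")
  expect_error(eval_model(toy, c(1, 0.5), c(1, 2), c(2, 0.5)), "'x'")
})

test_that("analytic Jacobians match central finite differences at random states", {
  set.seed(41)
  for (i in 1:100) {
    y <- runif(2, 0.05, 3); x <- runif(1, 0.05, 3); p <- runif(2, 0.05, 4)
    ev <- eval_model(toy, y, x, p)
    Jy <- num_jac(function(v) toy$f(v, x, p), y)
    Jx <- num_jac(function(v) toy$f(y, v, p), x)
    expect_lt(max(abs(ev$jac_y - Jy)), 1e-5 * max(abs(Jy), 1))
    expect_lt(max(abs(ev$jac_x - Jx)), 1e-5 * max(abs(Jx), 1))
  }
})

test_that("model registration self-checks Jacobians and rejects bad ones", {
  bad <- new_ode_model(1, 1, 1,
                       f = function(y, x, p) -p[1] * y * x,
                       jac_y = function(y, x, p) matrix(-p[1] * x + 0.1),  # wrong
                       jac_x = function(y, x, p) matrix(-p[1] * y),
                       check = FALSE)
  expect_error(register_model("bad_model", bad), "jac_y")
  expect_true("reversible_toy" %in% list_models())
  expect_error(get_model("no_such_model"), "unknown model")
})

test_that("positivity extension preserves the input sign and its closed form", {
  ext <- extend_positive_input(toy)
  expect_equal(ext$n, 3L)
  expect_equal(ext$m, 1L)
  expect_identical(check_model_jacobians(ext), TRUE)

  tg <- seq(0, 5, length.out = 201)
  solve_ext <- function(z0, d_course)
    varode:::rk4_solve(ext, z0, c(2, 0.5), tg,
                       x_course = function(t) matrix(d_course(t), 1))

  ## d = 0: the input state is frozen
  Z <- solve_ext(c(1, 0, 0.7), function(t) rep(0, length(t)))
  expect_equal(Z[3, ], rep(0.7, 201), tolerance = 1e-12)

  ## d = 0.5: exponential decay, strictly positive
  Z <- solve_ext(c(1, 0, 1), function(t) rep(0.5, length(t)))
  expect_equal(Z[3, ], exp(-0.5 * tg), tolerance = 1e-9)
  expect_true(all(Z[3, ] > 0))

  ## negative start stays negative for any bounded d
  set.seed(5)
  for (i in 1:5) {
    d_fun <- splinefun(seq(0, 5, 1), runif(6, -2, 2))
    Z <- solve_ext(c(1, 0, -1), d_fun)
    expect_true(all(Z[3, ] < 0))
  }
})

test_that("input change-of-variables linearizes factorizing models", {
  ## bimolecular-like model: rate k * A * x^2
  bimol <- new_ode_model(1, 1, 1,
                         f = function(y, x, p) -p[1] * y[1] * x[1]^2,
                         jac_y = function(y, x, p) matrix(-p[1] * x[1]^2),
                         jac_x = function(y, x, p) matrix(-2 * p[1] * y[1] * x[1]),
                         check = TRUE)
  sq <- input_transform(phi = function(x, p) x^2,
                        phi_inv = function(xt, p) sqrt(xt),
                        domain = c(1e-6, 10), description = "square")
  tmod <- apply_input_transform(bimol, sq)
  ## transformed rhs equals the original at matched points
  expect_equal(tmod$f(2, 1.44, 3), bimol$f(2, 1.2, 3), tolerance = 1e-10)
  ## linear in the transformed input: jac_x independent of x-tilde
  J1 <- tmod$jac_x(2, 0.5, 3); J2 <- tmod$jac_x(2, 2.5, 3)
  expect_equal(as.numeric(J1), as.numeric(J2), tolerance = 1e-7)
  expect_equal(as.numeric(J1), -3 * 2, tolerance = 1e-7)

  ## identity transform leaves the toy model unchanged
  idt <- input_transform(phi = function(x, p) x,
                         phi_inv = function(xt, p) xt,
                         domain = c(1e-6, 10), description = "identity")
  tmod2 <- apply_input_transform(toy, idt, p_check = c(2, 0.5))
  expect_equal(tmod2$f(c(1, 0.5), 0.8, c(2, 0.5)),
               toy$f(c(1, 0.5), 0.8, c(2, 0.5)), tolerance = 1e-10)

  ## saturation transform maps (0, Inf) into (0, 1)
  sat <- input_transform(phi = function(x, p) x / (0.5 + x),
                         domain = c(1e-6, 1e6), description = "saturation")
  xs <- 10^seq(-5, 5, length.out = 50)
  xt <- sat$phi(xs, numeric(0))
  expect_true(all(xt > 0 & xt < 1))

  ## a non-factorizing model is refused with a pointer to the extension
  nl <- new_ode_model(1, 1, 1,
                      f = function(y, x, p) -p[1] * y[1] * sin(x[1]),
                      jac_y = function(y, x, p) matrix(-p[1] * sin(x[1])),
                      jac_x = function(y, x, p) matrix(-p[1] * y[1] * cos(x[1])),
                      check = TRUE)
  expect_error(apply_input_transform(nl, idt), "extend_positive_input")
})
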