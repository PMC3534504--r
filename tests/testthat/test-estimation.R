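test_that("discrete chi2 sums weighted squared residuals over components", {
  pr <- forward_solution_priors(toy, c(2, 0.5), c(1, 0), make_input("gaussian"))
  sys <- augmented_system(toy, pr$y, pr$x)
  traj <- solve_augmented_bvp(sys, c(2, 0.5), c(1, 0))

  ## residual-free data give chi2 = 0 (up to solver error on a 1e-6-exact fixture)
  t_obs <- c(1, 2, 3)
  pred <- predict(traj, t_obs)
  d0 <- data.frame(component = "A", time = t_obs, value = pred$y[1, ], sigma = 0.1)
  expect_lt(discrete_chi2(traj, d0), 1e-6)

  ## one point with residual 0.1 at sigma 0.1 contributes exactly 1
  d1 <- data.frame(component = "A", time = 2, value = pred$y[1, 2] + 0.1,
                   sigma = 0.1)
  expect_equal(discrete_chi2(traj, d1), 1, tolerance = 1e-9)

  ## additivity across components (species and input)
  d2 <- data.frame(component = "x", time = 2, value = pred$x[1, 2] - 0.05,
                   sigma = 0.1)
  expect_equal(discrete_chi2(traj, rbind(d1, d2)),
               discrete_chi2(traj, d1) + discrete_chi2(traj, d2),
               tolerance = 1e-9)

  ## measurement time outside the trajectory span is an error
  d3 <- data.frame(component = "A", time = 6, value = 1, sigma = 0.1)
  expect_error(discrete_chi2(traj, d3), "span")

  ## validation of the measurement table
  expect_error(as_measurements(data.frame(component = "A", time = 1,
                                          value = 1, sigma = 0)), "sigma")
  expect_error(as_measurements(data.frame(component = "A", time = 1)), "columns")
})

test_that("both fitting routes descend, converge and are deterministic", {
  sc <- scenario_config(seed = 31)
  data <- simulate_dataset(toy, sc)
  priors <- build_priors(data, toy, T = sc$T)

  fv <- fit_variational(toy, priors, data)
  ff <- fit_fixed_input(toy, priors$x, data)
  for (fit in list(fv, ff)) {
    expect_true(fit$converged)
    expect_gte(fit$chi2, 0)
    ## descent: chi2 at the optimum does not exceed chi2 at the initializer
    ini <- varode:::default_inits(toy, data)
    chi2_init <- sum(fit$resid_fn(c(log(ini$p), ini$y0))^2)
    expect_lte(fit$chi2, chi2_init)
  }

  ## no internal randomness: identical refit
  fv2 <- fit_variational(toy, priors, data)
  expect_identical(coef(fv), coef(fv2))
  expect_identical(fv$chi2, fv2$chi2)

  ## S3 surface
  expect_named(coef(fv), c("k1", "k2", "A", "B"))
  expect_equal(nrow(summary(fv)$coefficients), 4)
  pred <- predict(fv, times = c(0, 2.5, 5))
  expect_setequal(unique(pred$component), c("A", "B", "x"))
  expect_length(residuals(fv), nrow(data))
  expect_length(residuals(ff), sum(data$component %in% c("A", "B")))
  sim <- simulate(fv, nsim = 2, seed = 1)
  expect_length(sim, 2)
  expect_equal(dim(sim[[1]]), dim(data))
})

test_that("fixed-input route recovers truth from noiseless data", {
  sc <- scenario_config(sigma = 0)
  data <- simulate_dataset(toy, sc, seed = 1)
  data$sigma <- 0.01
  fit <- fit_fixed_input(toy, function(t) rbind(sc$input(t)), data)
  expect_lt(max(abs(fit$p_hat - c(2, 0.5)) / c(2, 0.5)), 1e-3)
  expect_lt(abs(fit$y0_hat[["A"]] - 1), 1e-3)
  expect_lt(abs(fit$y0_hat[["B"]]), 1e-3)
})

test_that("profile intervals equal Wald intervals on a quadratic surface", {
  ## hand-built fit whose chi2 is exactly quadratic:
  ## theta = (log k, A0), resid = ((theta1 - log 2)/0.1, (theta2 - 1)/0.2)
  fake <- structure(list(
    model = list(r = 1L, n = 1L, parameter_names = "k", species_names = "A"),
    method = "variational",
    theta_hat = c(log(2), 1), chi2 = 0, converged = TRUE,
    resid_fn = function(theta) c((theta[1] - log(2)) / 0.1,
                                 (theta[2] - 1) / 0.2),
    options = varode:::fit_options_default(list()),
    gn = list(free = 1:2),
    vcov_theta = diag(c(0.01, 0.04))), class = "vode_fit")

  pr <- profile_likelihood_ci(fake, levels = c(0.68, 0.90), bisect_tol = 1e-4)
  for (lv in c(0.68, 0.90)) {
    q <- qchisq(lv, 1)
    row <- paste0(lv * 100, "%")
    expect_equal(pr$parameters$k$bounds[row, "lower"],
                 exp(log(2) - sqrt(q) * 0.1), tolerance = 1e-3)
    expect_equal(pr$parameters$k$bounds[row, "upper"],
                 exp(log(2) + sqrt(q) * 0.1), tolerance = 1e-3)
    expect_equal(pr$parameters$A$bounds[row, "lower"], 1 - sqrt(q) * 0.2,
                 tolerance = 1e-3)
    expect_equal(pr$parameters$A$bounds[row, "upper"], 1 + sqrt(q) * 0.2,
                 tolerance = 1e-3)
  }

  ## estimate inside its own interval; 90% contains 68%; profile >= chi2_min
  for (pp in pr$parameters) {
    expect_true(all(pp$bounds[, "lower"] <= pp$estimate))
    expect_true(all(pp$bounds[, "upper"] >= pp$estimate))
    expect_lte(pp$bounds["90%", "lower"], pp$bounds["68%", "lower"])
    expect_gte(pp$bounds["90%", "upper"], pp$bounds["68%", "upper"])
    expect_true(all(pp$curve$chi2 >= -1e-12))
  }

  ## the sub-level-set containment test agrees with the interval
  expect_equal(profile_delta_chi2(fake, "k", 2), 0, tolerance = 1e-10)
  expect_lt(profile_delta_chi2(fake, "k", exp(log(2) + 0.05)), qchisq(0.68, 1))
  expect_gt(profile_delta_chi2(fake, "k", 3), qchisq(0.90, 1))
})

test_that("variational route uses its extra freedom on sparse input data", {
  ## aggregate form: over several sparse datasets the variational total chi2
  ## is below the fixed-input species chi2 on average and in the majority
  sc <- scenario_config(n_input_times = 4)
  seeds <- varode:::replicate_seeds(3, 5)
  dv <- df <- numeric(5)
  for (i in 1:5) {
    data <- simulate_dataset(toy, sc, seed = seeds[i])
    priors <- build_priors(data, toy, T = sc$T)
    dv[i] <- fit_variational(toy, priors, data)$chi2
    df[i] <- fit_fixed_input(toy, priors$x, data)$chi2
  }
  expect_lt(mean(dv), mean(df))
  expect_gte(sum(dv <= df), 3)
})
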