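test_that("input families have the stated shapes", {
  ## exponential decay starts at its amplitude
  x <- make_input("exp_decay", list(alpha = 1, amplitude = 1))
  expect_equal(x(0), 1)
  expect_equal(x(2), exp(-2))

  ## gaussian pulse peaks at t_dip
  x <- make_input("gaussian", list(t_dip = 2, tau_in = 0.8, amplitude = 2))
  tg <- seq(0, 5, length.out = 2001)
  expect_equal(tg[which.max(x(tg))], 2, tolerance = 3e-3)
  expect_true(all(x(tg) > 0))

  ## activation: zero at 0, single interior maximum at ln(a/b)/(a-b)
  x <- make_input("activation", list(alpha = 5, beta = 1, amplitude = 1))
  expect_equal(x(0), 0)
  expect_equal(tg[which.max(x(tg))], log(5) / 4, tolerance = 3e-3)
  expect_error(make_input("activation", list(alpha = 1, beta = 5)), "alpha > beta")

  expect_error(make_input("frobnicate"), "exp_decay")
})

test_that("dataset simulation is reproducible and exact at sigma = 0", {
  sc <- scenario_config(seed = 5)
  d1 <- simulate_dataset(toy, sc)
  d2 <- simulate_dataset(toy, sc)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 60)  # 20 per species + 20 input

  ## noiseless data lie exactly on the true courses where they are known
  sc0 <- scenario_config(sigma = 0, seed = 5)
  d0 <- simulate_dataset(toy, sc0)
  x_rows <- d0[d0$component == "x", ]
  expect_equal(x_rows$value, sc0$input(x_rows$time), tolerance = 1e-12)
  a0 <- d0[d0$component == "A" & d0$time == 0, "value"]
  b0 <- d0[d0$component == "B" & d0$time == 0, "value"]
  expect_equal(c(a0, b0), c(1, 0), tolerance = 1e-12)
  ## species values conserve total mass at every time
  ad <- d0[d0$component == "A", ]; bd <- d0[d0$component == "B", ]
  expect_equal(ad$value + bd$value, rep(1, 20), tolerance = 1e-9)
})

test_that("simulated noise has the configured standard deviation", {
  ## 4000 fixed-seed draws of one measurement; sd within 2% of 0.1
  sc <- scenario_config(species_times = c(0, 2.5), input_times = c(0, 2.5))
  set.seed(1234)
  vals <- replicate(4000, simulate_dataset(toy, sc, seed = NULL)$value[2])
  expect_lt(abs(sd(vals) - 0.1) / 0.1, 0.02)
})

test_that("estimator comparison returns one row per replicate, method and parameter", {
  sc <- scenario_config(seed = 1)
  est <- run_estimator_comparison(toy, sc, n_reps = 2, master_seed = 17)
  expect_equal(nrow(est), 2 * 2 * 4)
  expect_setequal(unique(est$parameter), c("k1", "k2", "A", "B"))
  expect_setequal(unique(est$method), c("variational", "fixed_input"))
  expect_length(attr(est, "failures"), 0)

  ## full pipeline reproducibility under the master seed
  est2 <- run_estimator_comparison(toy, sc, n_reps = 2, master_seed = 17)
  expect_identical(est$estimate, est2$estimate)
})

test_that("coverage bookkeeping is sound and reproducible", {
  sc <- scenario_config()
  ## degenerate check: at level 1 the threshold is infinite, coverage exactly 1
  cov1 <- coverage_study(toy, sc, n_reps = 2, levels = 1,
                         methods = "variational", parameters = "k1",
                         master_seed = 23)
  expect_equal(cov1$coverage, 1)
  expect_equal(cov1$n_covered, cov1$n_reps)
  expect_equal(cov1$mc_se, 0)

  cov2 <- coverage_study(toy, sc, n_reps = 2, levels = c(0.68, 0.90),
                         methods = "variational", parameters = "k1",
                         master_seed = 23)
  expect_true(all(cov2$coverage >= 0 & cov2$coverage <= 1))
  expect_true(all(cov2$n_covered <= cov2$n_reps))
  ## nested levels: 90% cannot cover less than 68%
  expect_gte(cov2$n_covered[cov2$level == 0.90],
             cov2$n_covered[cov2$level == 0.68])
  cov3 <- coverage_study(toy, sc, n_reps = 2, levels = c(0.68, 0.90),
                         methods = "variational", parameters = "k1",
                         master_seed = 23)
  expect_identical(cov2$coverage, cov3$coverage)
})
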