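test_that("steady state is linear in the expenditure change", {
  m <- energy_balance_model("men")
  w <- energy_balance_model("women")
  expect_equal(steady_state_weight(m, 0), 76.9)
  expect_equal(round(steady_state_weight(m, -142), 1), 89.7)
  d50 <- steady_state_weight(w, -50) - w$baseline_weight_kg
  d100 <- steady_state_weight(w, -100) - w$baseline_weight_kg
  expect_equal(d100, 2 * d50, tolerance = 1e-12)
  # predict method is the same closed form
  expect_equal(predict(m, delta_ee = c(-50, -142)),
               steady_state_weight(m, c(-50, -142)))
})

test_that("larger expenditure reductions give strictly larger steady states", {
  m <- energy_balance_model("men")
  reductions <- seq(10, 300, by = 10)
  ws <- steady_state_weight(m, -reductions)
  expect_true(all(diff(ws) > 0))
})

test_that("simulation reaches the closed-form steady state", {
  m <- energy_balance_model("men")
  still <- simulate_weight(m, delta_ee = 0)
  expect_true(still$converged)
  expect_equal(still$days_to_tolerance, 0)
  expect_equal(still$weight_kg, 76.9)

  sim <- simulate_weight(m, delta_ee = -142)
  expect_true(sim$converged)
  expect_equal(sim$weight_kg, steady_state_weight(m, -142), tolerance = 0.05)
  expect_equal(round(sim$weight_kg, 1), 89.7)
  # conservation at equilibrium: gamma * dW offsets the imposed reduction
  expect_lt(abs(m$gamma * sim$delta_weight_kg - 142), 0.01)
})

test_that("the integrator matches the closed-form exponential solution", {
  set.seed(101)
  for (i in 1:20) {
    m <- energy_balance_model(
      sample(c("men", "women"), 1),
      baseline_weight_kg = runif(1, 55, 95),
      gamma = runif(1, 5, 30),
      rho = runif(1, 5000, 9000))
    delta <- runif(1, -250, -20)
    sim <- simulate_weight(m, delta, horizon_days = 8000)
    t <- sample(sim$trajectory$day, 1)
    expected <- ode_closed_form(m$baseline_weight_kg, m$gamma, m$rho, delta, t)
    expect_equal(sim$trajectory$weight_kg[sim$trajectory$day == t],
                 expected, tolerance = 1e-4)
  }
})

test_that("non-convergence within the horizon is flagged, not thrown", {
  m <- energy_balance_model("men")
  sim <- simulate_weight(m, delta_ee = -142, horizon_days = 30)
  expect_false(sim$converged)
  expect_true(is.na(sim$days_to_tolerance))
})

test_that("the 50/100/150 calibration recovers the published sensitivities", {
  expect_equal(round(as.numeric(kg_per_kcal_ratio(energy_balance_model("men"))),
                     3), 0.090)
  expect_equal(round(as.numeric(kg_per_kcal_ratio(energy_balance_model("women"))),
                     3), 0.092)
})

test_that("linearity makes the three calibration ratios identical", {
  m <- energy_balance_model("men", gamma = 12.5)
  # closed-form ratios are exactly equal ...
  analytic <- (steady_state_weight(m, -c(50, 100, 150)) -
                 m$baseline_weight_kg) / c(50, 100, 150)
  expect_lt(max(analytic) - min(analytic), 1e-9)
  # ... and the simulated ratios agree with them within the termination band
  r <- kg_per_kcal_ratio(m)
  band <- 1e-6 * m$rho / m$gamma / 50
  expect_true(all(abs(attr(r, "ratios") - analytic[1]) < band))
  expect_error(kg_per_kcal_ratio(m, horizon_days = 10), "did not converge")
})

test_that("gamma calibration is the reciprocal and round-trips", {
  expect_equal(calibrate_gamma(0.090), 1 / 0.090, tolerance = 1e-12)
  expect_equal(calibrate_gamma(0.092), 1 / 0.092, tolerance = 1e-12)
  expect_error(calibrate_gamma(0), "positive")
  expect_error(calibrate_gamma(-1), "positive")

  set.seed(77)
  ratios <- runif(50, 0.01, 0.2)
  for (r in ratios) {
    m <- energy_balance_model("men", gamma = calibrate_gamma(r))
    sim_ratio <- as.numeric(kg_per_kcal_ratio(
      m, horizon_days = 60000, tolerance = 1e-11, step_days = 25,
      rtol = 1e-12, atol = 1e-12))
    expect_equal(sim_ratio, r, tolerance = 1e-9)
    # gamma recovered from the simulated sensitivity matches the generator
    expect_equal(calibrate_gamma(sim_ratio), m$gamma, tolerance = 1e-6)
  }
})

test_that("trajectory prediction anchors at baseline and scales with the workweek", {
  m <- energy_balance_model("men")
  ee <- c(`1960-62` = 1582, `1988-94` = 1480, `2003-06` = 1440)
  traj_full <- predict_trajectory(m, ee, apply_workweek = FALSE)
  traj_5of7 <- predict_trajectory(m, ee, apply_workweek = TRUE)
  expect_equal(traj_full$predicted_kg[1], 76.9)
  expect_equal(traj_5of7$predicted_kg[1], 76.9)
  d_full <- traj_full$predicted_kg - 76.9
  d_5of7 <- traj_5of7$predicted_kg - 76.9
  expect_equal(d_5of7, d_full * 5 / 7, tolerance = 1e-12)

  obs <- c(`2003-06` = 91.8)
  traj <- predict_trajectory(m, ee, apply_workweek = FALSE, observed = obs)
  expect_equal(traj$observed_kg, c(NA, NA, 91.8))
  expect_error(predict_trajectory(m, numeric(0)), "baseline")
  expect_error(predict_trajectory(m, c(`1960-62` = -5)), "positive")
})

test_that("a 142 kcal workday reduction from baseline predicts 89.7 kg", {
  m <- energy_balance_model("men")
  ee <- c(`1960-62` = 1582, `2003-06` = 1582 - 142)
  traj <- predict_trajectory(m, ee, apply_workweek = FALSE)
  expect_equal(round(traj$predicted_kg[2], 1), 89.7)
})
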