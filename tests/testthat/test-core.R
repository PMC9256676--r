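attrs1 <- attribute_vector(v_p = 0.5, v_m = 0.3, v_a = 1)

test_that("M1 drift schedule switches attributes at the starting time", {
  p <- stddm_params(w_p = 1, w_m = 2, s = 0.3, model_id = "M1")
  expect_equal(drift_rate(p, attrs1, 0.1), 0.5)          # probability only
  expect_equal(drift_rate(p, attrs1, 0.5), 1.1)          # both attributes
  p_neg <- stddm_params(w_p = 1, w_m = 2, s = -0.2, model_id = "M1")
  expect_equal(drift_rate(p_neg, attrs1, 0.1), 0.6)      # magnitude first
  p0 <- stddm_params(w_p = 1, w_m = 2, s = 0, model_id = "M1")
  expect_equal(drift_rate(p0, attrs1, c(0.01, 2)), c(1.1, 1.1))
})

test_that("M3 drift keeps the accumulated-reward term in every branch", {
  p <- stddm_params(w_p = 1, w_m = 2, w_a = -0.2, s = 0.3, model_id = "M3")
  expect_equal(drift_rate(p, attrs1, 0.1), -0.2 + 0.5)
  expect_equal(drift_rate(p, attrs1, 1.0), -0.2 + 0.5 + 0.6)
  p_neg <- stddm_params(w_p = 1, w_m = 2, w_a = -0.2, s = -0.2, model_id = "M3")
  expect_equal(drift_rate(p_neg, attrs1, 0.1), -0.2 + 0.6)
})

test_that("M4 drift separates current-trial terms from the accumulated term", {
  p <- stddm_params(w_p = 1, w_m = 2, w_a = -0.2, s = 0.3, model_id = "M4")
  expect_equal(drift_rate(p, attrs1, 0.1), 0.5 + 0.6)
  expect_equal(drift_rate(p, attrs1, 0.5), 0.5 + 0.6 - 0.2)
  p_neg <- stddm_params(w_p = 1, w_m = 2, w_a = -0.2, s = -0.2, model_id = "M4")
  expect_equal(drift_rate(p_neg, attrs1, 0.1), -0.2)
})

test_that("model family nests as expected", {
  tgrid <- seq(0, 2, by = 0.05)
  p1 <- stddm_params(w_p = 1.3, w_m = 0.7, s = 0.4, model_id = "M1")
  p3 <- stddm_params(w_p = 1.3, w_m = 0.7, w_a = 0, s = 0.4, model_id = "M3")
  expect_equal(drift_rate(p1, attrs1, tgrid), drift_rate(p3, attrs1, tgrid))
  p0 <- stddm_params(w_p = 1.3, w_m = 0.7, model_id = "M0")
  p1s0 <- stddm_params(w_p = 1.3, w_m = 0.7, s = 0, model_id = "M1")
  expect_equal(drift_rate(p0, attrs1, tgrid), drift_rate(p1s0, attrs1, tgrid))
})

test_that("drift schedules integrate exactly as piecewise-constant functions", {
  p <- stddm_params(w_p = 1, w_m = 2, w_a = -0.4, s = 0.35, model_id = "M3")
  T_end <- 1.7
  early <- drift_rate(p, attrs1, 0.1); late <- drift_rate(p, attrs1, 1)
  exact <- early * 0.35 + late * (T_end - 0.35)
  tg <- seq(0, T_end, length.out = 200001)
  numint <- mean(drift_rate(p, attrs1, head(tg, -1))) * T_end
  expect_equal(numint, exact, tolerance = 1e-4)
})

test_that("starting point honors bias, the M2 shift, and clipping", {
  expect_equal(start_point(stddm_params(B = 2), attribute_vector()), 0)
  expect_equal(
    start_point(stddm_params(bias = 0.75, B = 2, model_id = "M1"),
                attribute_vector()), 1)
  p2 <- stddm_params(w_a = 0.4, B = 2, model_id = "M2")
  expect_equal(start_point(p2, attribute_vector(v_a = 1)), 0.4)
  p_big <- stddm_params(w_a = 10, B = 2, model_id = "M2")
  sp <- start_point(p_big, attribute_vector(v_a = 1))
  expect_lt(sp, 2)
  expect_equal(sp, 2 * (1 - 1e-6))
})

test_that("trial simulation respects dt contracts and the non-decision floor", {
  p <- stddm_params(w_p = 1, ndt = 0.4)
  expect_error(simulate_trial(p, attrs1, dt = 0), "positive")
  expect_error(simulate_trial(p, attrs1, dt = 0.01), "0.005")
  set.seed(1)
  for (i in 1:20) {
    out <- simulate_trial(p, attrs1)
    if (out$choice != "none") expect_gte(out$rt, 0.4)
  }
})

test_that("symmetric diffusion splits choices evenly", {
  set.seed(11)
  sim <- .sim_fpt_cpp(20000L, 0, 0, 0, 2, 0.5, 0.001, 30)
  p_hat <- mean(sim$hit == 1, na.rm = TRUE)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 20000))
})

test_that("simulated acceptance matches the closed-form absorption probability", {
  set.seed(12)
  grid <- expand.grid(v = c(-1, 0.5, 1.5), w = c(0.35, 0.5, 0.65))
  for (i in seq_len(nrow(grid))) {
    v <- grid$v[i]; w <- grid$w[i]
    sim <- .sim_fpt_cpp(20000L, v, v, 0, 2, w, 0.001, 30)
    p_hat <- mean(sim$hit == 1, na.rm = TRUE)
    p_true <- prob_upper(v, 2, w)
    expect_lt(abs(p_hat - p_true),
              3 * sqrt(p_true * (1 - p_true) / 20000) + 0.004)
  }
})
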