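test_that("upper-boundary absorption probability matches the closed form", {
  expect_equal(prob_upper(1, 2, 0.5), (1 - exp(-2)) / (1 - exp(-4)),
               tolerance = 1e-12)
  expect_equal(prob_upper(0, 2, 0.5), 0.5)
  expect_equal(prob_upper(1, 2, 0.5), 0.8808, tolerance = 1e-4)
})

test_that("constant-drift density integrates to the absorption masses", {
  tt <- seq(1e-4, 40, length.out = 80000); h <- tt[2] - tt[1]
  for (v in c(-0.8, 0, 1.2)) {
    fu <- constant_drift_density(v, 2, 0.4, tt, "upper")
    fl <- constant_drift_density(v, 2, 0.4, tt, "lower")
    expect_equal(sum(fu + fl) * h, 1, tolerance = 1e-4)
    expect_equal(sum(fu) * h, prob_upper(v, 2, 0.4), tolerance = 1e-4)
  }
})

test_that("zero drift from the midpoint gives half the mass to each bound", {
  tt <- seq(1e-4, 60, length.out = 80000); h <- tt[2] - tt[1]
  fu <- constant_drift_density(0, 2, 0.5, tt, "upper")
  expect_equal(sum(fu) * h, 0.5, tolerance = 1e-4)
})

test_that("piecewise density degenerates to the constant-drift form at s = 0", {
  tt <- seq(0.02, 4, length.out = 150)
  for (v in c(-1, 0.7)) {
    d_pw <- piecewise_density(v, v, 0, 2.6, 0.45, tt, "upper")
    d_c <- constant_drift_density(v, 2.6, 0.45, tt, "upper")
    expect_lt(max(abs(d_pw - d_c)), 1e-8)
  }
})

test_that("the two quadrature rules agree on two-segment densities", {
  tt <- seq(0.35, 4, length.out = 80)
  d_tr <- piecewise_density(-0.6, 1.4, 0.3, 2.4, 0.5, tt, "upper")
  d_gl <- piecewise_density(-0.6, 1.4, 0.3, 2.4, 0.5, tt, "upper",
                            quadrature = "gauss")
  expect_lt(max(abs(d_tr - d_gl)) / max(d_tr), 1e-6)
})

test_that("two-segment densities are continuous across the change point", {
  eps <- 1e-6
  for (cfg in list(c(-0.5, 1.2, 0.3), c(1.0, -0.4, 0.45))) {
    below <- piecewise_density(cfg[1], cfg[2], cfg[3], 2, 0.5,
                               cfg[3] - eps, "upper")
    above <- piecewise_density(cfg[1], cfg[2], cfg[3], 2, 0.5,
                               cfg[3] + eps, "upper")
    expect_equal(below, above, tolerance = 1e-3)
  }
})

test_that("two-segment densities normalize over both boundaries", {
  tt <- seq(1e-4, 40, length.out = 60000); h <- tt[2] - tt[1]
  fu <- piecewise_density(-0.5, 1.2, 0.3, 2, 0.5, tt, "upper",
                          quadrature = "gauss")
  fl <- piecewise_density(-0.5, 1.2, 0.3, 2, 0.5, tt, "lower",
                          quadrature = "gauss")
  expect_equal(sum(fu + fl) * h, 1, tolerance = 1e-4)
})

test_that("analytic and KDE backends agree on the two-segment density", {
  set.seed(31)
  tt <- seq(0.4, 3.5, length.out = 60)
  an <- piecewise_density(-0.5, 1.3, 0.35, 2, 0.5, tt, "upper")
  kd <- piecewise_density(-0.5, 1.3, 0.35, 2, 0.5, tt, "upper",
                          method = "simulated_kde", n_sims = 4e4)
  expect_lt(max(abs(an - kd)) / max(an), 0.08)
})

test_that("trial log-likelihood handles impossible RTs and prefers the truth", {
  p <- stddm_params(w_p = 1.2, w_m = 0.6, w_a = -0.2, s = 0.3, ndt = 0.4,
                    B = 1.3, model_id = "M3")
  a <- attribute_vector(v_p = 0.4, v_m = -0.2, v_a = 0.5)
  d <- trial_density(p, a, "accept", 1.1)
  expect_equal(trial_loglik(p, a, "accept", 1.1), log(d))
  expect_identical(trial_loglik(p, a, "accept", 0.3), -Inf)   # rt < ndt
  # likelihood is maximized near the generating parameters
  set.seed(32)
  n <- 400
  vp <- rnorm(n); vm <- rnorm(n); va <- rnorm(n)
  sim <- .sim_trials_cpp(vp, vm, va, p$w_p, p$w_m, p$w_a, p$s, p$ndt, p$B,
                         p$bias, 3L, 0.001, 10, 4)
  ok <- !is.na(sim$accept) & sim$rt >= 0.2
  attrs <- tibble::tibble(v_p = vp[ok], v_m = vm[ok], v_a = va[ok])
  ch <- ifelse(sim$accept[ok] == 1, "accept", "reject")
  ll_true <- trial_loglik(p, attrs, ch, sim$rt[ok])
  for (delta in list(c(w_p = 0.8), c(s = 0.4), c(ndt = -0.25))) {
    q <- p
    q[[names(delta)]] <- q[[names(delta)]] + delta
    ll_alt <- trial_loglik(q, attrs, ch, sim$rt[ok])
    expect_gt(ll_true, ll_alt)
  }
})

test_that("deadline renormalization raises the log-likelihood", {
  p <- stddm_params(w_p = 0.5, ndt = 0.4, B = 2)
  a <- attribute_vector(v_p = 0.2)
  base <- trial_loglik(p, a, "accept", 1.0)
  renorm <- trial_loglik(p, a, "accept", 1.0, normalize_deadline = TRUE)
  expect_gt(renorm, base)  # dividing by P(response < deadline) < 1
})
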