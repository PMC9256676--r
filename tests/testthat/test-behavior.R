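test_that("EV-independent choices give a near-zero logistic slope", {
  set.seed(41)
  evs <- runif(2000, -94, 97)
  res <- ev_logistic_slope(rbinom(2000, 1, 0.5), evs)
  expect_lt(abs(res$slope), 0.01)
  expect_false(res$separation)
})

test_that("a known generative logistic slope is recovered", {
  set.seed(42)
  evs <- runif(10000, -90, 90)
  p <- plogis(0.05 * evs)
  res <- ev_logistic_slope(rbinom(10000, 1, p), evs)
  # 3 SEs of the MLE at this design
  se <- sqrt(1 / sum(p * (1 - p) * evs^2))
  expect_lt(abs(res$slope - 0.05), 3 * se + 1e-4)
})

test_that("complete separation is capped and flagged", {
  evs <- seq(-50, 50, length.out = 60)
  res <- ev_logistic_slope(as.numeric(evs > 0), evs)
  expect_true(res$separation)
  expect_lte(abs(res$slope), 10)
  expect_error(ev_logistic_slope(rep(1, 30), seq(1, 30)), "span")
  expect_error(ev_logistic_slope(c(1, 0), c(-1, 1)), "at least 20")
})

test_that("per-participant slopes are computed for every condition", {
  tr <- small_trials() |> dplyr::filter(.data$choice != "none")
  sl <- ev_slopes(tr)
  expect_equal(nrow(sl), 12)  # 6 participants x 2 conditions
  expect_true(all(is.finite(sl$slope)))
})

.sim_slopes <- function(n_per_group, age_shift = 0, cond_shift = 0,
                        inter_shift = 0, sigma = 1) {
  ids <- sprintf("s%03d", seq_len(2 * n_per_group))
  age <- rep(c("younger", "older"), each = n_per_group)
  subj_re <- rnorm(2 * n_per_group, 0, 0.5)
  tidyr::crossing(tibble::tibble(participant_id = ids, age_group = age,
                                 re = subj_re),
                  condition = c("aid", "control")) |>
    dplyr::mutate(
      slope = re +
        age_shift * (age_group == "younger") +
        cond_shift * (condition == "aid") +
        inter_shift * (age_group == "younger") * (condition == "aid") +
        rnorm(dplyr::n(), 0, sigma)
    ) |>
    dplyr::select(-"re")
}

test_that("the aligned-rank interaction test holds its type-I error rate", {
  set.seed(43)
  hits <- 0; n_rep <- 200
  for (r in seq_len(n_rep)) {
    d <- .sim_slopes(20, age_shift = 1, cond_shift = 1, inter_shift = 0)
    p <- aligned_rank_anova(d)$p_value[3]
    hits <- hits + (p < 0.05)
  }
  rate <- hits / n_rep
  # 200 replicates of a nominal 5% test: binomial 3-sigma band
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / n_rep) - 0.01)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
})

test_that("a one-SD age shift is detected with high power", {
  set.seed(44)
  hits <- 0; n_rep <- 100
  for (r in seq_len(n_rep)) {
    d <- .sim_slopes(40, age_shift = 1, sigma = 0.8)
    p <- aligned_rank_anova(d)$p_value[1]
    hits <- hits + (p < 0.05)
  }
  expect_gt(hits / n_rep, 0.9)
})

test_that("degenerate constant responses give p = 1 by convention", {
  d <- .sim_slopes(5) |> dplyr::mutate(slope = 1)
  out <- aligned_rank_anova(d)
  expect_true(all(out$p_value == 1))
})

test_that("cells with fewer than two subjects are rejected", {
  d <- .sim_slopes(1)
  expect_error(aligned_rank_anova(d), "at least 2")
})

test_that("the HDI matches closed-form intervals on known distributions", {
  set.seed(45)
  x <- rnorm(1e6)
  h <- hdi(x)
  expect_equal(h[1], -1.96, tolerance = 0.02)
  expect_equal(h[2], 1.96, tolerance = 0.02)
  u <- runif(1e5)
  expect_equal(diff(hdi(u)), 0.95, tolerance = 0.01)
  expect_equal(diff(hdi(rep(3, 500))), 0)
  # the interval is the shortest window containing the mass
  skew <- rgamma(1e5, shape = 2)
  hs <- hdi(skew)
  qs <- quantile(skew, c(0.025, 0.975))
  expect_lt(diff(hs), diff(qs))
})

test_that("posterior contrasts respond correctly to constructed shifts", {
  set.seed(46)
  n <- 4000
  pars <- c("w_p", "w_m")
  # four cells with identical posterior distributions (independent draws)
  mu0 <- array(rnorm(n * 4 * 2, 0, 0.3), c(n, 4, 2))
  same <- posterior_contrasts(fake_fit_from_mu(mu0, pars))
  for (i in seq_len(nrow(same))) {
    expect_lt(abs(same$mean[i]), 0.05)
    expect_lt(abs(same$pp[i] - 0.5), 0.06)
  }
  # shift the younger cells by +1 on w_p only
  mu1 <- mu0; mu1[, 1:2, 1] <- mu1[, 1:2, 1] + 1
  shifted <- posterior_contrasts(fake_fit_from_mu(mu1, pars))
  age_wp <- shifted[shifted$parameter == "w_p" & shifted$contrast == "age", ]
  expect_equal(age_wp$mean, 1, tolerance = 0.05)
  expect_gt(age_wp$pp, 0.99)
  expect_lt(age_wp$hdi_lower, age_wp$mean)
  expect_gt(age_wp$hdi_upper, age_wp$mean)
  # derived probability-minus-magnitude contrast shifts identically
  dd <- shifted[shifted$parameter == "w_p_minus_w_m" &
                  shifted$contrast == "age", ]
  expect_equal(dd$mean, 1, tolerance = 0.05)
})

test_that("contrast operators are linear and PP is two-sided consistent", {
  n <- 2000
  m1 <- array(rnorm(n * 4 * 1), c(n, 4, 1))
  m2 <- array(rnorm(n * 4 * 1), c(n, 4, 1))
  c1 <- posterior_contrasts(fake_fit_from_mu(m1, "w_p"))
  c2 <- posterior_contrasts(fake_fit_from_mu(m2, "w_p"))
  cs <- posterior_contrasts(fake_fit_from_mu(m1 + m2, "w_p"))
  expect_equal(cs$mean, c1$mean + c2$mean, tolerance = 1e-12)
  draws <- (m1[, 1, 1] + m1[, 2, 1]) / 2 - (m1[, 3, 1] + m1[, 4, 1]) / 2
  expect_equal(mean(draws > 0) + mean(draws < 0), 1)
})
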