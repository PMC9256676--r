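test_that("the recorded deviance trace equals -2 x the trial log-likelihood", {
  fit <- small_fit()
  ks <- c(1, 37, 150)
  for (k in ks) {
    ll <- stddm:::.blocks_ll_at(fit, fit$draws$theta[k, , ])
    expect_equal(fit$draws$dev[k], -2 * sum(ll), tolerance = 1e-12)
    cell_ll <- tapply(ll, factor(fit$blocks$cell, 1:4), sum)
    expect_equal(as.numeric(fit$draws$cell_dev[k, ]), as.numeric(-2 * cell_ll),
                 tolerance = 1e-12)
  }
})

test_that("identical seeds and configurations give identical chains", {
  std <- small_standardized()
  cfg <- mcmc_config("test", n_burn = 60L, n_keep = 40L)
  f1 <- suppressWarnings(fit_stddm(std, "M3", mcmc = cfg, seed = 7))
  f2 <- suppressWarnings(fit_stddm(std, "M3", mcmc = cfg, seed = 7))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_stddm(std, "M3", mcmc = cfg, seed = 8))
  expect_false(identical(f1$draws$dev, f3$draws$dev))
})

test_that("with the likelihood off the sampler recovers the priors", {
  std <- small_standardized()
  fit <- suppressWarnings(
    fit_stddm(std, "M3",
              mcmc = mcmc_config("test", n_burn = 800L, n_keep = 2500L),
              seed = 9, prior_only = TRUE)
  )
  # group-level weight means have standard-normal priors
  for (j in match(c("w_p", "s"), fit$par_names)) {
    draws <- fit$draws$mu[, 2, j]
    thin <- draws[seq(1, length(draws), by = 5)]
    ks <- suppressWarnings(stats::ks.test(thin, "pnorm", 0, 1)$statistic)
    expect_lt(unname(ks), 0.08)
    expect_lt(abs(mean(draws)), 0.15)
    expect_lt(abs(sd(draws) - 1), 0.15)
  }
  # bias mean has a Beta(2, 2) prior
  bias_draws <- fit$draws$mu[, 1, match("bias", fit$par_names)]
  expect_lt(abs(mean(bias_draws) - 0.5), 0.1)
})

test_that("condition-symmetric data yield condition-symmetric posteriors", {
  # both condition labels carry literally identical trials, so the two cells
  # of each age group must agree up to Monte-Carlo error
  tr <- small_standardized() |> dplyr::filter(.data$condition == "aid")
  tr2 <- dplyr::bind_rows(tr, dplyr::mutate(tr, condition = "control"))
  fit <- suppressWarnings(
    fit_stddm(tr2, "M3", mcmc = mcmc_config("test", n_burn = 250L,
                                            n_keep = 250L), seed = 10)
  )
  for (j in seq_along(fit$par_names)) {
    d_y <- fit$draws$mu[, 1, j] - fit$draws$mu[, 2, j]
    pooled_sd <- sd(c(fit$draws$mu[, 1, j], fit$draws$mu[, 2, j]))
    expect_lt(abs(mean(d_y)), 3 * pooled_sd)
  }
})

test_that("posterior prediction returns probabilities on the 1/n grid", {
  fit <- small_fit()
  pred <- posterior_predict(fit, n_sims = 20, seed = 5)
  expect_true(all(pred$p_accept >= 0 & pred$p_accept <= 1))
  expect_true(all(abs(pred$p_accept * 20 - round(pred$p_accept * 20)) < 1e-9))
})

test_that("degenerate parameters drive predicted choice probabilities to 1", {
  fit <- small_fit()
  boosted <- fit
  boosted$theta_mean[, match("w_p", fit$par_names)] <- 60
  pred <- posterior_predict(boosted, n_sims = 10, seed = 6)
  hi <- pred[pred$v_p > 0.5, ]
  expect_gt(mean(hi$p_accept), 0.97)
})

test_that("fits expose tidy and glance summaries", {
  fit <- small_fit()
  td <- tidy(fit)
  expect_setequal(unique(td$parameter), fit$par_names)
  expect_equal(nrow(td), 4 * length(fit$par_names))
  expect_true(all(td$hdi_lower < td$hdi_upper))
  ti <- tidy(fit, level = "individual")
  expect_equal(nrow(ti), nrow(fit$blocks) * length(fit$par_names))
  gl <- glance(fit)
  expect_equal(gl$model_id, "M3")
  expect_equal(gl$n_draws, length(fit$draws$dev))
})

test_that("unfiltered or malformed inputs are rejected", {
  std <- small_standardized()
  bad <- std
  bad$choice[1] <- "none"
  expect_error(suppressWarnings(fit_stddm(bad, "M3")), "unfiltered")
  expect_error(fit_stddm(std[, setdiff(names(std), "v_p")], "M3"),
               "standardized")
})
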