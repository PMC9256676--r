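test_that("trial filtering removes fast RTs and non-responses", {
  tr <- tibble::tibble(
    participant_id = c("a", "a", "a", "b"),
    choice = c("accept", "none", "accept", "reject"),
    rt = c(0.150, NA, 1.2, 0.210)
  )
  out <- filter_trials(tr)
  expect_equal(nrow(out$trials), 2)
  expect_true(all(out$trials$rt >= 0.200))
  expect_false(any(out$trials$choice == "none"))
  rep_a <- out$exclusions[out$exclusions$participant_id == "a", ]
  expect_equal(rep_a$n_short_rt, 1)
  expect_equal(rep_a$n_no_response, 1)
  expect_equal(rep_a$n_removed, 2)
})

test_that("attribute standardization yields pooled z-scores", {
  tr <- small_trials()
  std <- standardize_attributes(filter_trials(tr)$trials)
  for (v in c("v_p", "v_m", "v_a")) {
    expect_equal(mean(std[[v]]), 0, tolerance = 1e-10)
    expect_equal(sqrt(mean(std[[v]]^2)), 1, tolerance = 1e-10)
  }
  # win_prob 0.75 has raw probability difference 0.5 before scaling
  raw <- .apply_scaling(0.75, 56, 0,
                        attribute_scaling(pd_mean = 0, pd_sd = 1))
  expect_equal(raw$v_p, 0.5)
})

test_that("log-accumulated-reward z-scores match a hand computation", {
  tr <- tibble::tibble(
    participant_id = "a", win_prob = c(0.3, 0.5, 0.7),
    magnitude = c(10, 50, 90),
    accumulated_before = exp(1:3)
  )
  std <- standardize_attributes(tr)
  expect_equal(std$v_a, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
})

test_that("non-positive accumulated totals are floored before the log", {
  sc <- attribute_scaling(a_mean = 0, a_sd = 1)
  out <- .apply_scaling(0.5, 56, c(-120, 0, 1, exp(2)), sc)
  expect_equal(out$v_a, c(0, 0, 0, 2))
})

test_that("standardization fails on zero-variance attributes", {
  tr <- tibble::tibble(participant_id = "a", win_prob = rep(0.5, 10),
                       magnitude = rep(50, 10),
                       accumulated_before = rep(10, 10))
  expect_error(standardize_attributes(tr), "zero variance")
})

test_that("simulated experiments keep exact accumulated-reward books", {
  tr <- small_trials()
  by_p <- split(tr, tr$participant_id)
  for (d in by_p) {
    d <- d[order(d$trial_index), ]
    expect_equal(d$accumulated_before,
                 cumsum(dplyr::lag(d$outcome, default = 0)))
    expect_true(all(d$outcome[d$choice != "accept"] == 0))
    expect_true(all(abs(d$outcome[d$choice == "accept"]) ==
                      d$magnitude[d$choice == "accept"]))
  }
})

test_that("experiment simulation is seed-reproducible", {
  pars <- sample_cohort_params(n_per_group = 2, seed = 1)
  a <- simulate_experiment(pars, stimulus_design(n_trials = 24), seed = 3)
  b <- simulate_experiment(pars, stimulus_design(n_trials = 24), seed = 3)
  expect_identical(a, b)
})

test_that("dominant probability drift drives acceptance to the matching bound", {
  pars <- tibble::tibble(
    participant_id = "p1", age_group = "younger",
    condition = c("aid", "control"),
    w_p = 50, w_m = 0, w_a = 0, s = 0, ndt = 0.3, B = 1.2, bias = 0.5
  )
  tr <- simulate_experiment(pars, stimulus_design(n_trials = 40), seed = 4)
  hi <- tr[tr$win_prob > 0.6 & tr$choice != "none", ]
  lo <- tr[tr$win_prob < 0.4 & tr$choice != "none", ]
  expect_gt(mean(hi$choice == "accept"), 0.95)
  expect_lt(mean(lo$choice == "accept"), 0.05)
})

test_that("zero weights and neutral bias give chance-level acceptance", {
  pars <- tibble::tibble(
    participant_id = sprintf("p%d", 1:4), age_group = "younger"
  ) |> tidyr::crossing(condition = c("aid", "control")) |>
    dplyr::mutate(w_p = 0, w_m = 0, w_a = 0, s = 0, ndt = 0.3, B = 1,
                  bias = 0.5)
  tr <- simulate_experiment(pars, stimulus_design(n_trials = 60), seed = 5)
  resp <- tr[tr$choice != "none", ]
  p_hat <- mean(resp$choice == "accept")
  se <- sqrt(0.25 / nrow(resp))
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("trial tables survive a CSV round trip", {
  tr <- small_trials() |> dplyr::select(-dplyr::any_of("ev"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)
})
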