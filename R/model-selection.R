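# log-likelihood of every block at given per-block parameters (used for the
# deviance at the posterior means)
.blocks_ll_at <- function(fit, theta) {
  pars <- fit$par_names
  mcode <- .model_code(fit$model_id)
  vapply(seq_len(nrow(fit$blocks)), function(b) {
    tr <- fit$trials[fit$trials$participant_id == fit$blocks$participant_id[b] &
                       fit$trials$condition == fit$blocks$condition[b], ]
    th <- setNames(theta[b, ], pars)
    .block_loglik_cpp(tr$rt, as.integer(tr$choice == "accept"),
                      tr$v_p, tr$v_m, tr$v_a,
                      th[["w_p"]], th[["w_m"]], .th_get(th, "w_a"),
                      .th_get(th, "s"), th[["ndt"]], th[["B"]], th[["bias"]],
                      mcode, 1L, fit$mcmc$n_nodes)
  }, 0.0)
}

#' Deviance information criterion
#'
#' `DIC = D-bar + pD`, where `D-bar` is the posterior mean of the deviance and
#' `pD = D-bar - D(theta-bar)` is the effective number of parameters, the
#' difference between the posterior mean of the deviance and the deviance at
#' the posterior means of the parameters. Computed overall and per
#' (age group x condition) cell by restricting the deviance to that cell's
#' trials (parameters come from the joint fit).
#'
#' @param fit An `stddm_fit`.
#' @return A tibble with columns `age_group`, `condition`, `d_bar`, `d_hat`,
#'   `p_d`, `dic`; the first row (`all`, `all`) is the whole-data criterion.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "stddm_fit"))
  if (fit$prior_only) abort("DIC is undefined for a prior-only fit.")
  ll_hat <- .blocks_ll_at(fit, fit$theta_mean)
  cell_dhat <- -2 * tapply(ll_hat, factor(fit$blocks$cell, 1:4), sum)
  cell_dbar <- colMeans(fit$draws$cell_dev)
  out <- tibble::tibble(
    age_group = c("all", fit$cells$age_group),
    condition = c("all", fit$cells$condition),
    d_bar = unname(c(mean(fit$draws$dev), cell_dbar)),
    d_hat = unname(c(-2 * sum(ll_hat), cell_dhat))
  ) |>
    dplyr::mutate(p_d = .data$d_bar - .data$d_hat,
                  dic = .data$d_bar + .data$p_d)
  if (any(out$p_d < 0, na.rm = TRUE)) {
    warn("Negative pD encountered; DIC reported as-is.")
  }
  out
}

#' Root-mean-squared error between binary choices and choice probabilities
#'
#' @param choices 0/1 (or logical) observed acceptances.
#' @param probs Predicted acceptance probabilities in `[0, 1]`, recycled.
#' @return The RMSE, a value in `[0, 1]`.
#' @export
choice_rmse <- function(choices, probs) {
  choices <- as.numeric(choices)
  probs <- rep_len(probs, length(choices))
  if (any(probs < 0 | probs > 1)) abort("`probs` must be probabilities in [0, 1].")
  sqrt(mean((choices - probs)^2))
}

#' Split-half cross-validated choice RMSE
#'
#' Fits the model on half of each participant-condition's trials (odd or even
#' trial indices), simulates the held-out half `n_sims` times per trial at the
#' per-participant posterior-mean parameters, averages the simulated choices
#' into a per-trial choice probability, and reports the RMSE between the
#' held-out binary choices (accept = 1) and those probabilities, per
#' participant-condition. By default both splits are computed and averaged.
#'
#' @param trials Filtered, standardized trial tibble.
#' @param model_id Model variant.
#' @param n_sims Simulations per held-out trial.
#' @param priors,mcmc,seed Passed to [fit_stddm()].
#' @param splits `"both"`, `"odd"` or `"even"` (which half is the training set).
#' @return A list with `per_participant` (RMSE per participant-condition) and
#'   `summary` (mean and SD per age group x condition).
#' @export
split_half_rmse <- function(trials, model_id = "M3", n_sims = 100,
                            priors = prior_spec(), mcmc = mcmc_config("test"),
                            seed = 1, splits = c("both", "odd", "even")) {
  splits <- match.arg(splits)
  use <- if (splits == "both") c("odd", "even") else splits
  n_half <- trials |>
    dplyr::count(.data$participant_id, .data$condition,
                 half = .data$trial_index %% 2L)
  if (any(n_half$n < 20)) {
    warn("Fewer than 20 trials in a half for some participant-condition.")
  }
  res <- purrr::map(use, function(which_half) {
    odd <- trials$trial_index %% 2L == 1L
    train <- if (which_half == "odd") trials[odd, ] else trials[!odd, ]
    test <- if (which_half == "odd") trials[!odd, ] else trials[odd, ]
    f <- fit_stddm(train, model_id = model_id, priors = priors, mcmc = mcmc,
                   seed = seed)
    pred <- posterior_predict(f, test, n_sims = n_sims, seed = seed + 7L)
    pred |>
      dplyr::group_by(.data$participant_id, .data$age_group, .data$condition) |>
      dplyr::summarise(
        rmse = choice_rmse(.data$choice == "accept", .data$p_accept),
        .groups = "drop") |>
      dplyr::mutate(split = which_half)
  }) |> dplyr::bind_rows()
  per <- res |>
    dplyr::group_by(.data$participant_id, .data$age_group, .data$condition) |>
    dplyr::summarise(rmse = mean(.data$rmse), .groups = "drop")
  list(
    per_participant = per,
    summary = per |>
      dplyr::group_by(.data$age_group, .data$condition) |>
      dplyr::summarise(rmse_mean = mean(.data$rmse), rmse_sd = sd(.data$rmse),
                       .groups = "drop")
  )
}

#' Rank fitted models by DIC
#'
#' Combines per-model DIC tables (and optionally RMSE summaries and an
#' EV-pattern check) into a ranked comparison: within each age group x
#' condition cell, models are ordered by DIC (smaller is better) and models
#' within 2 DIC units of the cell's best are flagged as indistinguishable.
#'
#' @param dic_results Named list of [compute_dic()] tibbles, one per model.
#' @param rmse_results Optional named list of [split_half_rmse()] summaries.
#' @param ev_pattern Optional tibble from [ev_pattern_check()] attached to the
#'   report.
#' @param path Optional path; when given, the report is also written as JSON.
#' @return An `stddm_comparison` list with `table` (ranked tibble), `best`
#'   (modal best model across cells), and the optional attachments.
#' @export
comparison_report <- function(dic_results, rmse_results = NULL,
                              ev_pattern = NULL, path = NULL) {
  tab <- purrr::imap_dfr(dic_results, function(d, m) {
    dplyr::mutate(d, model_id = m, .before = 1)
  })
  if (!is.null(rmse_results)) {
    rms <- purrr::imap_dfr(rmse_results, function(r, m) {
      dplyr::mutate(r$summary, model_id = m, .before = 1)
    })
    tab <- dplyr::left_join(tab, rms,
                            by = c("model_id", "age_group", "condition"))
  }
  tab <- tab |>
    dplyr::group_by(.data$age_group, .data$condition) |>
    dplyr::mutate(rank = rank(.data$dic, ties.method = "min"),
                  indistinguishable = .data$dic - min(.data$dic) < 2 &
                    .data$rank > 1) |>
    dplyr::arrange(.data$age_group, .data$condition, .data$rank) |>
    dplyr::ungroup()
  best_by_cell <- tab |>
    dplyr::filter(.data$rank == 1) |>
    dplyr::count(.data$model_id, sort = TRUE)
  out <- structure(list(
    table = tab,
    best = best_by_cell$model_id[1],
    ev_pattern = ev_pattern
  ), class = "stddm_comparison")
  if (!is.null(path)) {
    jsonlite::write_json(
      list(best = out$best, table = tab, ev_pattern = ev_pattern),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  out
}

#' @export
print.stddm_comparison <- function(x, ...) {
  cat(sprintf("<stddm_comparison> best model by DIC: %s\n", x$best))
  print(x$table, n = 20)
  invisible(x)
}

#' @export
tidy.stddm_comparison <- function(x, ...) x$table

#' @export
glance.stddm_comparison <- function(x, ...) {
  tibble::tibble(best = x$best,
                 n_models = length(unique(x$table$model_id)),
                 n_cells = nrow(dplyr::distinct(
                   x$table, .data$age_group, .data$condition)))
}
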