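#' Reference group-level stDDM parameter means
#'
#' Group-level means for the four (age group x condition) cells used as the
#' default generative truth of the synthetic cohort. The pattern encodes the
#' age and decision-aid effects of interest:
#' younger adults weight the probability attribute more than older adults and
#' the decision-aid raises the probability weight in both groups (more so in
#' the younger group); older adults have an earlier relative starting time for
#' probability (larger `s`), longer non-decision times and higher boundaries;
#' the accumulated-reward weight is negative everywhere; bias is neutral.
#'
#' @return A tibble with one row per (age_group, condition) and columns
#'   `w_p`, `w_m`, `w_a`, `s`, `ndt`, `B`, `bias`.
#' @export
default_group_means <- function() {
  tibble::tibble(
    age_group = rep(.age_levels, each = 2),
    condition = rep(.cond_levels, 2),
    w_p  = c(1.70, 1.25, 0.80, 0.55),
    w_m  = c(0.80, 0.60, 0.60, 0.30),
    w_a  = c(-0.24, -0.24, -0.16, -0.16),
    s    = c(0.35, 0.33, 0.70, 0.70),
    ndt  = c(0.475, 0.525, 0.635, 0.685),
    B    = c(1.30, 1.30, 1.50, 1.50),
    bias = c(0.50, 0.50, 0.50, 0.50)
  )
}

#' Draw individual parameter sets around group means
#'
#' Individual participant-condition parameters are normal around their group
#' cell mean, with spreads on the scale of the hierarchical prior (mean 0.1);
#' bounded parameters are clipped to their supports.
#'
#' @param group_means Tibble as returned by [default_group_means()].
#' @param n_per_group Participants per age group.
#' @param sds Named numeric vector of individual SDs per parameter.
#' @param seed Optional integer seed.
#' @return Tibble with one row per (participant_id, condition) and the
#'   parameter columns, plus `age_group`.
#' @export
sample_cohort_params <- function(group_means = default_group_means(),
                                 n_per_group = 20,
                                 sds = c(w_p = 0.15, w_m = 0.12, w_a = 0.08,
                                         s = 0.10, ndt = 0.05, B = 0.10,
                                         bias = 0.02),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pars <- c("w_p", "w_m", "w_a", "s", "ndt", "B", "bias")
  ids <- tibble::tibble(
    participant_id = sprintf("p%03d", seq_len(2 * n_per_group)),
    age_group = rep(.age_levels, each = n_per_group)
  )
  out <- tidyr::crossing(ids, condition = .cond_levels) |>
    dplyr::left_join(group_means, by = c("age_group", "condition"))
  for (p in pars) {
    out[[p]] <- out[[p]] + rnorm(nrow(out), 0, sds[[p]])
  }
  out$ndt  <- pmax(out$ndt, 0.05)
  out$B    <- pmax(out$B, 0.2)
  out$bias <- pmin(pmax(out$bias, 0.05), 0.95)
  out
}

#' Simulate a full synthetic lottery experiment
#'
#' Generates choices, RTs, feedback and the running points total for a cohort
#' of synthetic participants from a known generative stDDM. Each participant
#' completes one session containing `design$n_trials` decision-aid and the
#' same number of control trials, randomly interleaved, with a shared
#' accumulated-reward total: accepting a gamble yields `+magnitude` points
#' with probability `win_prob` and `-magnitude` otherwise; rejected or missed
#' gambles leave the total unchanged. The accumulated total before each trial
#' feeds back into the next decision through the standardized `v_a` attribute
#' (using `scaling`, so the generative process is fully specified up front).
#' Simulated responses slower than the 4 s deadline become `none`.
#'
#' @param params Tibble of true individual parameters as from
#'   [sample_cohort_params()] (one row per participant-condition).
#' @param design A [stimulus_design()] for the per-condition stimulus sets.
#' @param model_id Generative model variant (`"M0"`..`"M4"`).
#' @param scaling [attribute_scaling()] defining the generative attribute
#'   standardization.
#' @param seed Optional integer seed.
#' @param dt Euler-Maruyama step in seconds.
#' @return A trial tibble in the [read_trials()] column layout (plus `ev`).
#' @export
simulate_experiment <- function(params,
                                design = stimulus_design(),
                                model_id = "M3",
                                scaling = attribute_scaling(),
                                seed = NULL, dt = 0.001) {
  model_id <- match.arg(model_id, .model_ids)
  needed <- c("participant_id", "age_group", "condition",
              "w_p", "w_m", "w_a", "s", "ndt", "B", "bias")
  if (!all(needed %in% names(params))) {
    abort(paste("`params` must contain columns:", paste(needed, collapse = ", ")))
  }
  if (!is.null(seed)) set.seed(seed)
  mcode <- .model_code(model_id)

  sessions <- params |>
    dplyr::group_by(.data$participant_id, .data$age_group) |>
    dplyr::group_split()
  out <- purrr::map(sessions, function(pp) {
    if (!setequal(pp$condition, .cond_levels)) {
      abort("Every participant needs a parameter set for both conditions.")
    }
    stim <- purrr::map(.cond_levels, function(cc) {
      design_stimuli(design) |>
        dplyr::mutate(condition = cc)
    }) |> dplyr::bind_rows()
    stim <- stim[sample.int(nrow(stim)), ]
    n <- nrow(stim)
    acc_before <- numeric(n); choice <- character(n)
    rt <- numeric(n); outcome <- numeric(n)
    acc <- 0
    prow <- split(pp, pp$condition)
    for (i in seq_len(n)) {
      acc_before[i] <- acc
      th <- prow[[stim$condition[i]]]
      vv <- .apply_scaling(stim$win_prob[i], stim$magnitude[i], acc, scaling)
      sim <- .sim_trials_cpp(vv$v_p, vv$v_m, vv$v_a,
                             th$w_p, th$w_m, th$w_a, th$s, th$ndt, th$B,
                             th$bias, mcode, dt, 10, 4)
      if (is.na(sim$accept[1])) {
        choice[i] <- "none"; rt[i] <- NA_real_; outcome[i] <- 0
      } else if (sim$accept[1] == 1L) {
        choice[i] <- "accept"; rt[i] <- sim$rt[1]
        outcome[i] <- if (runif(1) < stim$win_prob[i]) stim$magnitude[i] else
          -stim$magnitude[i]
      } else {
        choice[i] <- "reject"; rt[i] <- sim$rt[1]; outcome[i] <- 0
      }
      acc <- acc + outcome[i]
    }
    tibble::tibble(
      participant_id = pp$participant_id[1],
      age_group = pp$age_group[1],
      condition = stim$condition,
      trial_index = seq_len(n),
      win_prob = stim$win_prob,
      magnitude = stim$magnitude,
      ev = stim$ev,
      accumulated_before = acc_before,
      choice = choice, rt = rt, outcome = outcome
    )
  }) |> dplyr::bind_rows()
  out
}
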