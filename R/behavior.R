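#' Expected-value sensitivity (logistic slope)
#'
#' Maximum-likelihood logistic regression of gamble acceptance (accept = 1)
#' on the trial expected value in raw points. The slope is the EV sensitivity:
#' steeper means choices track value more closely. Under complete separation
#' the slope is capped at +/- 10 and flagged.
#'
#' `ev_logistic_slope()` fits a single choice vector; `ev_slopes()` maps it
#' over every participant x condition of a trial tibble.
#'
#' @param choices Logical or 0/1 vector of acceptances (or `"accept"` strings).
#' @param evs Expected values in points; must span negative and positive values.
#' @param trials A trial tibble with `choice` and `ev` columns (computed from
#'   `win_prob`/`magnitude` if absent).
#' @param cap Absolute slope cap under separation.
#' @return A one-row tibble (`slope`, `intercept`, `separation`), or for
#'   `ev_slopes()` one row per participant-condition.
#' @export
ev_logistic_slope <- function(choices, evs, cap = 10) {
  if (is.character(choices)) choices <- choices == "accept"
  choices <- as.numeric(choices)
  if (length(choices) < 20) abort("Need at least 20 trials for an EV slope.")
  if (min(evs) >= 0 || max(evs) <= 0) {
    abort("EVs must span negative and positive values.")
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(choices ~ evs, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || abs(slope) > cap) {
    sep <- TRUE
    slope <- sign(slope) * cap
  }
  tibble::tibble(slope = slope, intercept = intercept, separation = sep)
}

#' @rdname ev_logistic_slope
#' @export
ev_slopes <- function(trials, cap = 10) {
  if (!"ev" %in% names(trials)) {
    trials$ev <- expected_value(trials$win_prob, trials$magnitude)
  }
  trials |>
    dplyr::group_by(.data$participant_id, .data$age_group, .data$condition) |>
    dplyr::group_modify(function(d, key) {
      ev_logistic_slope(d$choice, d$ev, cap = cap)
    }) |>
    dplyr::ungroup()
}

#' Aligned-rank-transform 2 x 2 mixed factorial ANOVA
#'
#' Nonparametric test of the age (between-subject) and condition
#' (within-subject) effects on a participant-level response (typically the EV
#' slope). For each effect, responses are aligned by removing the estimated
#' contributions of all other effects (cell-mean alignment), the aligned
#' values are ranked with average ties, and a factorial ANOVA with subject as
#' a random blocking factor is run on the ranks; only the aligned-for effect's
#' p-value is read from each ANOVA. Completely tied ranks give p = 1 by
#' convention.
#'
#' @param data Tibble with one response per participant x condition.
#' @param response Column name of the response (default `"slope"`).
#' @return A tibble with `effect` (`age`, `condition`, `age:condition`),
#'   `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
aligned_rank_anova <- function(data, response = "slope") {
  need <- c("participant_id", "age_group", "condition", response)
  if (!all(need %in% names(data))) {
    abort(paste("`data` must contain:", paste(need, collapse = ", ")))
  }
  n_cell <- data |> dplyr::count(.data$age_group, .data$condition)
  if (nrow(n_cell) < 4 || any(n_cell$n < 2)) {
    abort("Need at least 2 subjects in each of the four cells.")
  }
  y <- data[[response]]
  a <- factor(data$age_group); c_ <- factor(data$condition)
  pid <- factor(data$participant_id)
  grand <- mean(y)
  mean_a <- tapply(y, a, mean)[a]
  mean_c <- tapply(y, c_, mean)[c_]
  cell <- interaction(a, c_)
  mean_cell <- tapply(y, cell, mean)[cell]
  resid <- y - mean_cell
  effects <- list(
    age = as.numeric(mean_a - grand),
    condition = as.numeric(mean_c - grand),
    `age:condition` = as.numeric(mean_cell - mean_a - mean_c + grand)
  )
  strata <- c(age = "between", condition = "within", `age:condition` = "within")
  purrr::imap_dfr(effects, function(eff, nm) {
    aligned <- resid + eff
    r <- rank(aligned)
    if (var(r) == 0) {
      return(tibble::tibble(effect = nm, statistic = NA_real_,
                            df1 = NA_real_, df2 = NA_real_, p_value = 1))
    }
    d <- data.frame(r = r, a = a, c_ = c_, pid = pid)
    fit <- aov(r ~ a * c_ + Error(pid / c_), data = d)
    sm <- summary(fit)
    row_name <- switch(nm, age = "a", condition = "c_", `age:condition` = "a:c_")
    found <- NULL; df_resid <- NA_real_
    for (stratum in sm) {
      tt <- stratum[[1]]
      hit <- trimws(rownames(tt)) == row_name
      if (any(hit)) {
        found <- tt[hit, , drop = FALSE]
        res <- trimws(rownames(tt)) == "Residuals"
        if (any(res)) df_resid <- tt[res, "Df"]
      }
    }
    if (is.null(found) || !is.finite(found[1, "F value"])) {
      return(tibble::tibble(effect = nm, statistic = NA_real_,
                            df1 = NA_real_, df2 = NA_real_, p_value = 1))
    }
    tibble::tibble(effect = nm, statistic = found[1, "F value"],
                   df1 = found[1, "Df"], df2 = df_resid,
                   p_value = found[1, "Pr(>F)"])
  })
}

#' Highest density interval
#'
#' Shortest contiguous interval containing the requested posterior mass:
#' over the sorted sample, the window of `ceiling(mass * n)` points with the
#' smallest width.
#'
#' @param samples Numeric sample (at least 100 values recommended).
#' @param mass Probability mass (default 0.95).
#' @return Length-2 numeric `c(lower, upper)`.
#' @examples
#' hdi(rnorm(10000))
#' @export
hdi <- function(samples, mass = 0.95) {
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n == 0) abort("`samples` has no finite values.")
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[k:n] - x[1:(n - k + 1)]
  i <- which.min(widths)
  c(x[i], x[i + k - 1])
}

#' Posterior contrasts between age groups and conditions
#'
#' Per-draw contrasts of the four group-level posterior distributions:
#' the age main effect (mean over conditions, younger minus older), the
#' condition main effect (mean over age groups, decision-aid minus control),
#' and the interaction (aid-minus-control in the younger group minus
#' aid-minus-control in the older group). Besides the model parameters, the
#' derived "probability minus magnitude weight" (`w_p - w_m`, per draw) is
#' contrasted. Each contrast is summarized by its posterior mean, 95% HDI and
#' the posterior probability PP that the difference exceeds zero.
#'
#' @param fit An `stddm_fit`.
#' @param mass HDI mass.
#' @return A tibble with `parameter`, `contrast`, `mean`, `hdi_lower`,
#'   `hdi_upper`, `pp`.
#' @export
posterior_contrasts <- function(fit, mass = 0.95) {
  stopifnot(inherits(fit, "stddm_fit"))
  cells <- fit$cells
  ya <- which(cells$age_group == "younger")
  oa <- which(cells$age_group == "older")
  aid <- which(cells$condition == "aid")
  ctl <- which(cells$condition == "control")
  ya_aid <- intersect(ya, aid); ya_ctl <- intersect(ya, ctl)
  oa_aid <- intersect(oa, aid); oa_ctl <- intersect(oa, ctl)

  par_draws <- lapply(seq_along(fit$par_names), function(j) fit$draws$mu[, , j])
  names(par_draws) <- fit$par_names
  if (all(c("w_p", "w_m") %in% fit$par_names)) {
    par_draws$w_p_minus_w_m <- par_draws$w_p - par_draws$w_m
  }

  purrr::imap_dfr(par_draws, function(m, pname) {
    cons <- list(
      age = (m[, ya_aid] + m[, ya_ctl]) / 2 - (m[, oa_aid] + m[, oa_ctl]) / 2,
      condition = (m[, ya_aid] + m[, oa_aid]) / 2 -
        (m[, ya_ctl] + m[, oa_ctl]) / 2,
      interaction = (m[, ya_aid] - m[, ya_ctl]) - (m[, oa_aid] - m[, oa_ctl])
    )
    purrr::imap_dfr(cons, function(d, cname) {
      h <- hdi(d, mass)
      tibble::tibble(parameter = pname, contrast = cname, mean = mean(d),
                     hdi_lower = h[1], hdi_upper = h[2], pp = mean(d > 0))
    })
  })
}

#' End-to-end EV-sensitivity pattern check
#'
#' Computes per-participant EV slopes from observed (or simulated) choices,
#' runs the aligned-rank ANOVA, and reports whether the qualitative pattern
#' holds: younger adults' slopes exceed older adults', the decision-aid
#' raises slopes in both groups, and the corresponding main effects are
#' significant at `alpha`.
#'
#' @param trials Trial tibble with choices (e.g. empirical data or a
#'   [posterior_predict()]-simulated set with simulated `choice`).
#' @param alpha Significance threshold.
#' @return A list with `slopes`, `anova`, and logical `pattern` flags.
#' @export
ev_pattern_check <- function(trials, alpha = 0.05) {
  slopes <- ev_slopes(trials)
  anova <- aligned_rank_anova(slopes)
  cellm <- slopes |>
    dplyr::group_by(.data$age_group, .data$condition) |>
    dplyr::summarise(slope = mean(.data$slope), .groups = "drop")
  m <- function(ag, cc) cellm$slope[cellm$age_group == ag & cellm$condition == cc]
  p_of <- function(e) anova$p_value[anova$effect == e]
  list(
    slopes = slopes, anova = anova, cell_means = cellm,
    pattern = c(
      younger_higher = mean(c(m("younger", "aid"), m("younger", "control"))) >
        mean(c(m("older", "aid"), m("older", "control"))),
      aid_higher_younger = m("younger", "aid") > m("younger", "control"),
      aid_higher_older = m("older", "aid") > m("older", "control"),
      age_significant = p_of("age") < alpha,
      condition_significant = p_of("condition") < alpha
    )
  )
}
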