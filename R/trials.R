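#' Attribute standardization parameters
#'
#' Centers and scales used to map raw trial attributes to the standardized
#' decision inputs `v_p` (win minus loss probability), `v_m` (reward
#' magnitude) and `v_a` (natural log of the accumulated reward, floored at 1
#' point before the log). Fitting estimates these from data
#' ([standardize_attributes()]); simulation reuses a stored set so synthetic
#' and fitted data live on the same scale.
#'
#' @param pd_mean,pd_sd Center/scale of the probability difference `2p - 1`.
#' @param m_mean,m_sd Center/scale of the magnitude (points).
#' @param a_mean,a_sd Center/scale of `log(max(accumulated_before, 1))`.
#' @param center If `FALSE`, attributes are only divided by their SDs
#'   (scale-only standardization).
#' @return An `attribute_scaling` list.
#' @export
attribute_scaling <- function(pd_mean = 0, pd_sd = 0.64,
                              m_mean = 56, m_sd = 40,
                              a_mean = 4.5, a_sd = 2.6,
                              center = TRUE) {
  if (any(c(pd_sd, m_sd, a_sd) <= 0)) abort("Scales must be positive.")
  structure(list(pd_mean = pd_mean, pd_sd = pd_sd, m_mean = m_mean,
                 m_sd = m_sd, a_mean = a_mean, a_sd = a_sd, center = center),
            class = "attribute_scaling")
}

.apply_scaling <- function(win_prob, magnitude, accumulated_before, scaling) {
  ctr <- if (isTRUE(scaling$center)) 1 else 0
  tibble::tibble(
    v_p = ((2 * win_prob - 1) - ctr * scaling$pd_mean) / scaling$pd_sd,
    v_m = (magnitude - ctr * scaling$m_mean) / scaling$m_sd,
    v_a = (log(pmax(accumulated_before, 1)) - ctr * scaling$a_mean) / scaling$a_sd
  )
}

#' Filter lottery trials as in the behavioral analyses
#'
#' Removes trials with response times below 200 ms and trials without a choice
#' response before the 4 s deadline. All model fitting and behavioral
#' analyses operate on the retained trials.
#'
#' @param trials A trial tibble with at least `participant_id`, `choice`, `rt`.
#' @param min_rt Minimum admissible RT in seconds.
#' @return A list with `trials` (retained rows) and `exclusions` (per
#'   participant: `n_short_rt`, `n_no_response`, `n_removed`, `n_kept`).
#' @export
filter_trials <- function(trials, min_rt = 0.200) {
  short <- !is.na(trials$rt) & trials$choice != "none" & trials$rt < min_rt
  none  <- trials$choice == "none" | is.na(trials$rt)
  drop  <- short | none
  report <- trials |>
    dplyr::mutate(.short = short, .none = none) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_short_rt = sum(.data$.short),
      n_no_response = sum(.data$.none),
      n_removed = sum(.data$.short | .data$.none),
      n_kept = sum(!(.data$.short | .data$.none)),
      .groups = "drop"
    )
  list(trials = trials[!drop, setdiff(names(trials), c(".short", ".none"))],
       exclusions = report)
}

#' Standardize trial attributes across all participants and trials
#'
#' Adds the standardized decision inputs used by every model variant:
#' `v_p` = z-scored win-minus-loss probability difference, `v_m` = z-scored
#' reward magnitude, and `v_a` = z-scored natural log of the previously
#' accumulated reward (non-positive totals are floored at 1 point before the
#' log, so a zero starting total maps to `log(1) = 0`). Standardization pools
#' all retained participants and trials. The estimated centers/scales are
#' attached as the `"scaling"` attribute so simulated data can be placed on
#' the identical scale.
#'
#' @param trials A filtered trial tibble with `win_prob`, `magnitude`,
#'   `accumulated_before`.
#' @param scaling Optionally an existing [attribute_scaling()] to apply
#'   instead of estimating one from `trials`.
#' @param center If `FALSE`, estimate a scale-only standardization (divide by
#'   SD without centering).
#' @return The input tibble with `v_p`, `v_m`, `v_a` columns added and a
#'   `"scaling"` attribute.
#' @export
standardize_attributes <- function(trials, scaling = NULL, center = TRUE) {
  if (is.null(scaling)) {
    pd <- 2 * trials$win_prob - 1
    la <- log(pmax(trials$accumulated_before, 1))
    # z-scoring treats the pooled trials as the population of interest
    sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
    sds <- c(sd_pop(pd), sd_pop(trials$magnitude), sd_pop(la))
    if (any(!is.finite(sds)) || any(sds <= 0)) {
      abort("An attribute has zero variance; cannot standardize.")
    }
    scaling <- attribute_scaling(
      pd_mean = mean(pd), pd_sd = sds[1],
      m_mean = mean(trials$magnitude), m_sd = sds[2],
      a_mean = mean(la), a_sd = sds[3], center = center
    )
  }
  out <- dplyr::bind_cols(
    trials,
    .apply_scaling(trials$win_prob, trials$magnitude,
                   trials$accumulated_before, scaling)
  )
  attr(out, "scaling") <- scaling
  out
}

#' Read and write trial tables
#'
#' CSV round trip for the trial-table format: one row per lottery trial with
#' columns `participant_id`, `age_group`, `condition`, `trial_index`,
#' `win_prob` (fraction), `magnitude` (points), `accumulated_before` (points),
#' `choice` (`accept`/`reject`/`none`), `rt` (seconds), `outcome` (points).
#'
#' @param path File path.
#' @param trials Trial tibble to write.
#' @return `read_trials`: a tibble; `write_trials`: `path`, invisibly.
#' @export
read_trials <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      age_group = readr::col_character(),
      condition = readr::col_character(),
      trial_index = readr::col_integer(),
      win_prob = readr::col_double(),
      magnitude = readr::col_double(),
      accumulated_before = readr::col_double(),
      choice = readr::col_character(),
      rt = readr::col_double(),
      outcome = readr::col_double()
    )
  )
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}
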