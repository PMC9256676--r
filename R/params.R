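#' stDDM parameter set
#'
#' One participant-condition parameter set for a starting-time drift diffusion
#' model. Evidence accumulates with diffusion coefficient fixed at 1 between
#' absorbing boundaries at `-B` (reject) and `+B` (accept); the starting point
#' is `E0 = (2 * bias - 1) * B` so `bias = 0.5` is neutral.
#'
#' Model variants:
#' * `M0` — standard DDM: constant drift `w_p * V_P + w_m * V_M`, no starting
#'   time, no accumulated-reward term.
#' * `M1` — stDDM: probability and magnitude enter the drift at different
#'   times; `s > 0` means probability first, `s < 0` magnitude first.
#' * `M2` — as M1, but the (log, standardized) accumulated reward shifts the
#'   starting point by `w_a * V_A` evidence units.
#' * `M3` — accumulated reward contributes `w_a * V_A` to the drift from
#'   accumulation onset; probability and magnitude switch on at 0 and `|s|`.
#' * `M4` — probability and magnitude enter together; the accumulated-reward
#'   drift term leads (`s < 0`) or lags (`s > 0`) them by `|s|`.
#'
#' @param w_p,w_m,w_a Weighting strengths: drift (evidence/s) per standardized
#'   unit of the probability difference, reward magnitude and accumulated
#'   reward. For `M2`, `w_a` acts on the starting point instead of the drift.
#' @param s Relative starting time in seconds (signed); forced to 0 for `M0`.
#' @param ndt Non-decision time in seconds (>= 0).
#' @param B Boundary height in evidence units (> 0); boundaries sit at `-B`, `+B`.
#' @param bias Starting-point bias as a fraction in (0, 1); 0.5 = unbiased.
#' @param model_id One of `"M0"`, `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @return An `stddm_params` list.
#' @examples
#' stddm_params(w_p = 1.2, w_m = 0.6, w_a = -0.3, s = 0.25, model_id = "M3")
#' @export
stddm_params <- function(w_p = 0, w_m = 0, w_a = 0, s = 0,
                         ndt = 0.3, B = 1.5, bias = 0.5,
                         model_id = c("M3", "M0", "M1", "M2", "M4")) {
  model_id <- match.arg(model_id)
  if (model_id == "M0" && s != 0) s <- 0
  if (B <= 0) abort("`B` must be positive.")
  if (bias <= 0 || bias >= 1) abort("`bias` must lie strictly in (0, 1).")
  if (ndt < 0) abort("`ndt` must be non-negative.")
  structure(
    list(w_p = w_p, w_m = w_m, w_a = w_a, s = s, ndt = ndt, B = B,
         bias = bias, model_id = model_id),
    class = "stddm_params"
  )
}

#' @export
print.stddm_params <- function(x, ...) {
  cat(sprintf(
    "<stddm_params %s> w_p=%.3g w_m=%.3g w_a=%.3g s=%.3g ndt=%.3g B=%.3g bias=%.3g\n",
    x$model_id, x$w_p, x$w_m, x$w_a, x$s, x$ndt, x$B, x$bias))
  invisible(x)
}

#' Standardized attribute vector for one trial
#'
#' @param v_p,v_m,v_a Standardized (z-unit) win-loss probability difference,
#'   reward magnitude, and log accumulated reward.
#' @return A named numeric vector.
#' @export
attribute_vector <- function(v_p = 0, v_m = 0, v_a = 0) {
  c(v_p = v_p, v_m = v_m, v_a = v_a)
}

#' Time-varying drift rate of an stDDM
#'
#' Evaluates the piecewise-constant drift schedule of the given model variant
#' at accumulation time `t` (seconds after non-decision time). Each schedule
#' has at most one change point, at `|s|`.
#'
#' @param params An [stddm_params()].
#' @param attrs An [attribute_vector()] (or named vector with `v_p`, `v_m`, `v_a`).
#' @param t Accumulation time(s) in seconds (>= 0).
#' @return Drift rate(s) in evidence units per second.
#' @examples
#' p <- stddm_params(w_p = 1, w_m = 2, s = 0.3, model_id = "M1")
#' drift_rate(p, attribute_vector(v_p = 0.5, v_m = 0.3), t = c(0.1, 0.5))
#' @export
drift_rate <- function(params, attrs, t) {
  stopifnot(inherits(params, "stddm_params"), all(t >= 0))
  P <- params$w_p * attrs[["v_p"]]
  M <- params$w_m * attrs[["v_m"]]
  A <- params$w_a * attrs[["v_a"]]
  s <- params$s
  early <- switch(params$model_id,
    M0 = P + M,
    M1 = ,
    M2 = if (s > 0) P else M,
    M3 = A + if (s > 0) P else M,
    M4 = if (s > 0) P + M else A
  )
  late <- switch(params$model_id,
    M0 = P + M, M1 = P + M, M2 = P + M,
    M3 = A + P + M, M4 = A + P + M
  )
  ifelse(t < abs(s), early, late)
}

#' Starting point of the accumulation process
#'
#' Base starting point `E0 = (2 * bias - 1) * B`; for `M2` the accumulated
#' reward shifts it by `w_a * v_a`, clipped just inside the boundaries
#' (within `1e-6 * B`).
#'
#' @inheritParams drift_rate
#' @return Starting evidence in `(-B, B)`.
#' @export
start_point <- function(params, attrs) {
  stopifnot(inherits(params, "stddm_params"))
  e0 <- (2 * params$bias - 1) * params$B
  if (params$model_id == "M2") {
    e0 <- e0 + params$w_a * attrs[["v_a"]]
    lim <- params$B * (1 - 1e-6)
    e0 <- min(max(e0, -lim), lim)
  }
  e0
}

#' Simulate a single stDDM trial
#'
#' Euler-Maruyama integration of the evidence process with diffusion
#' coefficient 1: `E <- E + mu(t) * dt + sqrt(dt) * N(0, 1)`. The first
#' crossing of `+B` is an accept, of `-B` a reject; the reported RT adds the
#' non-decision time. Responses slower than the task deadline (4 s) or without
#' a crossing by `max_t` are returned as no-response.
#'
#' @inheritParams drift_rate
#' @param dt Integration step in seconds (must be positive and at most 0.005).
#' @param max_t Maximum accumulation time in seconds.
#' @param deadline Response deadline in seconds (RT above it becomes `none`).
#' @return A one-row tibble with `choice` (`"accept"`, `"reject"` or `"none"`)
#'   and `rt` (seconds, `NA` for `none`).
#' @export
simulate_trial <- function(params, attrs, dt = 0.001, max_t = 10,
                           deadline = 4) {
  stopifnot(inherits(params, "stddm_params"))
  if (dt <= 0) abort("`dt` must be positive.")
  if (dt > 0.005) abort("`dt` must be at most 0.005 s.")
  out <- .sim_trials_cpp(attrs[["v_p"]], attrs[["v_m"]], attrs[["v_a"]],
                         params$w_p, params$w_m, params$w_a, params$s,
                         params$ndt, params$B, params$bias,
                         .model_code(params$model_id), dt, max_t, deadline)
  choice <- if (is.na(out$accept[1])) "none" else
    c("reject", "accept")[out$accept[1] + 1L]
  tibble::tibble(choice = choice, rt = out$rt[1])
}
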