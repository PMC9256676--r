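#' Prior specification for the hierarchical stDDM
#'
#' Group-level means of the weighting strengths (`w_p`, `w_m`, `w_a`) and the
#' relative starting time `s` have standard-normal priors; the boundary `B`
#' and non-decision time `ndt` means have uniform priors on (0.0001, 5) and
#' (0, 10); the bias mean has a Beta(2, 2) prior. The spread of the
#' individual-level distribution around each group mean has a Gamma(shape 1,
#' scale 0.1) prior, interpreted on the SD scale by default (set
#' `spread_on = "precision"` for a gamma prior on the precision instead).
#'
#' @param weight_mean,weight_sd Normal hyperprior for weight/starting-time means.
#' @param B_range,ndt_range Uniform supports for boundary and non-decision time.
#' @param bias_shape1,bias_shape2 Beta hyperprior for the bias mean.
#' @param spread_shape,spread_scale Gamma hyperprior for individual spreads.
#' @param spread_on `"sd"` or `"precision"`.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(weight_mean = 0, weight_sd = 1,
                       B_range = c(1e-4, 5), ndt_range = c(0, 10),
                       bias_shape1 = 2, bias_shape2 = 2,
                       spread_shape = 1, spread_scale = 0.1,
                       spread_on = c("sd", "precision")) {
  structure(list(
    weight_mean = weight_mean, weight_sd = weight_sd,
    B_range = B_range, ndt_range = ndt_range,
    bias_shape1 = bias_shape1, bias_shape2 = bias_shape2,
    spread_shape = spread_shape, spread_scale = spread_scale,
    spread_on = match.arg(spread_on)
  ), class = "prior_spec")
}

#' MCMC configuration
#'
#' The `"desk"` preset (default) keeps 3 chains of 1,000 samples each after
#' 2,000 burn-in iterations per chain; `"full"` keeps 3 chains of 10,000
#' after 50,000 burn-in; `"test"` is a minimal smoke-test setting. Proposal
#' scales adapt toward 20--50% acceptance during burn-in and are frozen
#' afterwards.
#'
#' @param preset `"desk"`, `"full"` or `"test"`.
#' @param n_chains,n_burn,n_keep Override the preset.
#' @param n_nodes Gauss-Legendre nodes for the likelihood quadrature.
#' @param target_accept Target proposal acceptance rate during adaptation.
#' @param recenter_every Interleave a group-recentering move (shift a cell's
#'   group mean and all its members together) every this many iterations;
#'   it decorrelates group means from their members at a modest extra
#'   likelihood cost. Prior-only runs recenter every iteration.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(preset = c("desk", "full", "test"),
                        n_chains = NULL, n_burn = NULL, n_keep = NULL,
                        n_nodes = 48L, target_accept = 0.3,
                        recenter_every = 25L) {
  preset <- match.arg(preset)
  def <- switch(preset,
    desk  = list(n_chains = 3L, n_burn = 2000L, n_keep = 1000L),
    full  = list(n_chains = 3L, n_burn = 50000L, n_keep = 10000L),
    test  = list(n_chains = 1L, n_burn = 150L, n_keep = 150L)
  )
  structure(list(
    preset = preset,
    n_chains = as.integer(n_chains %||% def$n_chains),
    n_burn = as.integer(n_burn %||% def$n_burn),
    n_keep = as.integer(n_keep %||% def$n_keep),
    n_nodes = as.integer(n_nodes), target_accept = target_accept,
    recenter_every = as.integer(recenter_every)
  ), class = "mcmc_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.pars_for_model <- function(model_id) {
  switch(model_id,
    M0 = c("w_p", "w_m", "ndt", "B", "bias"),
    M1 = c("w_p", "w_m", "s", "ndt", "B", "bias"),
    c("w_p", "w_m", "w_a", "s", "ndt", "B", "bias")
  )
}

# parameter supports (NA = unbounded); bias kept off exact 0/1
.par_support <- function(par, priors) {
  switch(par,
    ndt = priors$ndt_range,
    B = priors$B_range,
    bias = c(1e-6, 1 - 1e-6),
    c(-Inf, Inf)
  )
}

.reflect <- function(x, lo, hi) {
  if (!is.finite(lo) && !is.finite(hi)) return(x)
  for (k in 1:100) {
    if (x < lo) x <- 2 * lo - x else if (x > hi) x <- 2 * hi - x else break
  }
  min(max(x, lo), hi)
}

# truncated-normal log density of individuals given hypers (vectorized over x)
.ind_logprior <- function(x, mu, sg, lo, hi) {
  if (sg <= 0) return(-Inf)
  ll <- sum(dnorm(x, mu, sg, log = TRUE))
  if (is.finite(lo) || is.finite(hi)) {
    z <- pnorm((hi - mu) / sg) - pnorm((lo - mu) / sg)
    if (z <= 0) return(-Inf)
    ll <- ll - length(x) * log(z)
  }
  ll
}

.hyper_mu_logprior <- function(par, mu, priors) {
  switch(par,
    ndt = stats::dunif(mu, priors$ndt_range[1], priors$ndt_range[2], log = TRUE),
    B = stats::dunif(mu, priors$B_range[1], priors$B_range[2], log = TRUE),
    bias = stats::dbeta(mu, priors$bias_shape1, priors$bias_shape2, log = TRUE),
    dnorm(mu, priors$weight_mean, priors$weight_sd, log = TRUE)
  )
}

.hyper_sg_logprior <- function(sg, priors) {
  if (priors$spread_on == "sd") {
    stats::dgamma(sg, shape = priors$spread_shape,
                  scale = priors$spread_scale, log = TRUE)
  } else {
    # gamma prior on the precision 1/sg^2; include Jacobian to the sd scale
    prec <- 1 / sg^2
    stats::dgamma(prec, shape = priors$spread_shape,
                  scale = priors$spread_scale, log = TRUE) + log(2 / sg^3)
  }
}

#' Fit a hierarchical stDDM by adaptive Metropolis-within-Gibbs
#'
#' Individual participant-condition parameters are drawn from one of four
#' group-level distributions (2 age groups x 2 conditions) and estimated
#' jointly with the group-level means and spreads. Individual blocks are
#' updated by joint random-walk Metropolis steps against the trial-level
#' first-passage likelihood; Normal-prior group means are updated by
#' conjugate Gibbs draws, bounded and Beta/Gamma hyperparameters by
#' Metropolis steps. The per-draw deviance (`-2 x` total log-likelihood) is
#' recorded for DIC computation, and split-R-hat / effective-sample-size
#' diagnostics are computed on the group-level draws (a warning names any
#' hyperparameter with R-hat above 1.1).
#'
#' @param trials A filtered, standardized trial tibble (columns `v_p`, `v_m`,
#'   `v_a`, `choice`, `rt`, `participant_id`, `age_group`, `condition`).
#' @param model_id Model variant `"M0"`..`"M4"`.
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @param seed Integer seed; chains use `seed`, `seed + 1`, ...
#' @param prior_only If `TRUE`, the likelihood is switched off and the
#'   sampler explores the prior (used for prior-recovery checks).
#' @return An `stddm_fit` object.
#' @export
fit_stddm <- function(trials, model_id = "M3", priors = prior_spec(),
                      mcmc = mcmc_config(), seed = 1, prior_only = FALSE) {
  model_id <- match.arg(model_id, .model_ids)
  pars <- .pars_for_model(model_id)
  npar <- length(pars)
  mcode <- .model_code(model_id)

  need <- c("participant_id", "age_group", "condition", "choice", "rt",
            "v_p", "v_m", "v_a")
  if (!all(need %in% names(trials))) {
    abort("`trials` must be filtered and standardized first (see standardize_attributes()).")
  }
  if (any(!trials$choice %in% c("accept", "reject"))) {
    abort("`trials` still contains unfiltered no-response rows.")
  }
  agm <- trials |> dplyr::distinct(.data$participant_id, .data$age_group)
  if (anyDuplicated(agm$participant_id) > 0) {
    abort("Each participant must belong to exactly one age group.")
  }

  blocks <- trials |>
    dplyr::distinct(.data$participant_id, .data$age_group, .data$condition) |>
    dplyr::arrange(.data$participant_id, .data$condition) |>
    dplyr::mutate(cell = .cell_index(.data$age_group, .data$condition))
  nb <- nrow(blocks)
  bdat <- purrr::pmap(blocks, function(participant_id, age_group, condition, cell) {
    tr <- trials[trials$participant_id == participant_id &
                   trials$condition == condition, ]
    list(rt = tr$rt, accept = as.integer(tr$choice == "accept"),
         v_p = tr$v_p, v_m = tr$v_m, v_a = tr$v_a, n = nrow(tr))
  })

  supports <- vapply(pars, .par_support, numeric(2), priors = priors)
  norm_pars <- pars[!pars %in% c("ndt", "B", "bias")]

  block_ll <- function(th, b) {
    if (prior_only) return(0)
    .block_loglik_cpp(bdat[[b]]$rt, bdat[[b]]$accept, bdat[[b]]$v_p,
                      bdat[[b]]$v_m, bdat[[b]]$v_a,
                      th[["w_p"]], th[["w_m"]], .th_get(th, "w_a"),
                      .th_get(th, "s"), th[["ndt"]], th[["B"]], th[["bias"]],
                      mcode, 1L, mcmc$n_nodes)
  }

  run_chain <- function(chain) {
    set.seed(seed + chain - 1L)
    # initial values: data-informed, jittered per chain. For a constant-drift
    # diffusion started midway, P(accept) = logistic(v * a), so a logistic
    # regression of choices on the attributes gives drift-weight starting
    # values once divided by the boundary separation.
    theta <- matrix(0, nb, npar, dimnames = list(NULL, pars))
    B0 <- 1.2
    for (b in seq_len(nb)) {
      co <- tryCatch(suppressWarnings(
        coef(glm(bdat[[b]]$accept ~ bdat[[b]]$v_p + bdat[[b]]$v_m +
                   bdat[[b]]$v_a, family = binomial()))[2:4]),
        error = function(e) c(1, 0.5, 0))
      co[!is.finite(co)] <- 0
      co <- pmin(pmax(co / (2 * B0), -3), 3)
      init <- c(w_p = unname(co[1]), w_m = unname(co[2]), w_a = unname(co[3]),
                s = 0.2, ndt = 0.5 * min(bdat[[b]]$rt), B = B0, bias = 0.5)
      theta[b, ] <- init[pars] + rnorm(npar, 0, 0.02)
      theta[b, "bias"] <- min(max(theta[b, "bias"], 0.2), 0.8)
      theta[b, "ndt"] <- min(theta[b, "ndt"], 0.9 * min(bdat[[b]]$rt))
    }
    mu <- sapply(pars, function(p) tapply(theta[, p], blocks$cell, mean))
    mu <- matrix(mu, 4, npar, dimnames = list(NULL, pars))
    sg <- matrix(0.2, 4, npar, dimnames = list(NULL, pars))

    cur_ll <- vapply(seq_len(nb), function(b) block_ll(theta[b, ], b), 0.0)
    if (any(!is.finite(cur_ll))) {
      abort("Initial state has zero likelihood; check RT filtering.")
    }

    base_step <- c(w_p = 0.12, w_m = 0.12, w_a = 0.08, s = 0.06,
                   ndt = 0.02, B = 0.05, bias = 0.02)[pars]
    lsc_block <- rep(0, nb)          # log scale multiplier per block
    lsc_mu <- matrix(log(0.1), 4, npar)
    lsc_sg <- matrix(log(0.3), 4, npar)
    lsc_shift <- matrix(log(0.2), 4, npar)

    n_iter <- mcmc$n_burn + mcmc$n_keep
    keep_mu <- array(NA_real_, c(mcmc$n_keep, 4, npar))
    keep_sg <- array(NA_real_, c(mcmc$n_keep, 4, npar))
    keep_th <- array(NA_real_, c(mcmc$n_keep, nb, npar))
    keep_dev <- numeric(mcmc$n_keep)
    keep_cell_dev <- matrix(NA_real_, mcmc$n_keep, 4)

    for (it in seq_len(n_iter)) {
      adapting <- it <= mcmc$n_burn
      gam <- if (adapting) min(0.1, 5 / sqrt(it)) else 0

      # --- individual blocks: joint random-walk MH -------------------------
      lo <- supports[1, ]; hi <- supports[2, ]
      for (b in seq_len(nb)) {
        g <- blocks$cell[b]
        prop <- theta[b, ] + exp(lsc_block[b]) * base_step * rnorm(npar)
        # reflect into supports (two passes cover any realistic proposal)
        for (pass in 1:2) {
          below <- prop < lo; above <- prop > hi
          prop[below] <- 2 * lo[below] - prop[below]
          prop[above] <- 2 * hi[above] - prop[above]
        }
        prop <- pmin(pmax(prop, lo), hi)
        # truncation normalizers depend only on (mu, sg) and cancel in the
        # MH ratio, so the individual prior reduces to plain normal terms
        lp_cur <- sum(dnorm(theta[b, ], mu[g, ], sg[g, ], log = TRUE))
        lp_prop <- sum(dnorm(prop, mu[g, ], sg[g, ], log = TRUE))
        ll_prop <- block_ll(prop, b)
        lacc <- (ll_prop + lp_prop) - (cur_ll[b] + lp_cur)
        acc <- is.finite(lacc) && log(runif(1)) < lacc
        if (acc) { theta[b, ] <- prop; cur_ll[b] <- ll_prop }
        if (adapting) {
          lsc_block[b] <- lsc_block[b] +
            gam * ((if (acc) 1 else 0) - mcmc$target_accept)
        }
      }

      # --- group-level updates --------------------------------------------
      for (g in 1:4) {
        members <- which(blocks$cell == g)
        if (!length(members)) next
        for (j in seq_len(npar)) {
          p <- pars[j]
          x <- theta[members, j]
          lo <- supports[1, j]; hi <- supports[2, j]
          if (p %in% norm_pars) {
            # conjugate Gibbs for Normal-prior means
            prec <- 1 / priors$weight_sd^2 + length(x) / sg[g, j]^2
            m <- (priors$weight_mean / priors$weight_sd^2 +
                    sum(x) / sg[g, j]^2) / prec
            mu[g, j] <- rnorm(1, m, sqrt(1 / prec))
          } else {
            prop <- .reflect(mu[g, j] + exp(lsc_mu[g, j]) * rnorm(1),
                             if (p == "bias") 1e-6 else lo,
                             if (p == "bias") 1 - 1e-6 else hi)
            lp_c <- .hyper_mu_logprior(p, mu[g, j], priors) +
              .ind_logprior(x, mu[g, j], sg[g, j], lo, hi)
            lp_p <- .hyper_mu_logprior(p, prop, priors) +
              .ind_logprior(x, prop, sg[g, j], lo, hi)
            acc <- is.finite(lp_p) && log(runif(1)) < lp_p - lp_c
            if (acc) mu[g, j] <- prop
            if (adapting) {
              lsc_mu[g, j] <- lsc_mu[g, j] +
                gam * ((if (acc) 1 else 0) - mcmc$target_accept)
            }
          }
          # spread update on the log scale
          lprop <- log(sg[g, j]) + exp(lsc_sg[g, j]) * rnorm(1)
          sprop <- exp(lprop)
          lp_c <- .hyper_sg_logprior(sg[g, j], priors) + log(sg[g, j]) +
            .ind_logprior(x, mu[g, j], sg[g, j], lo, hi)
          lp_p <- .hyper_sg_logprior(sprop, priors) + log(sprop) +
            .ind_logprior(x, mu[g, j], sprop, lo, hi)
          acc <- is.finite(lp_p) && log(runif(1)) < lp_p - lp_c
          if (acc) sg[g, j] <- sprop
          if (adapting) {
            lsc_sg[g, j] <- lsc_sg[g, j] +
              gam * ((if (acc) 1 else 0) - mcmc$target_accept)
          }
        }
      }

      # --- group-recentering move ------------------------------------------
      # shift a cell's mean and all its members together; this traverses the
      # (mu, theta) ridge of the centered hierarchy directly
      recenter_now <- if (prior_only) TRUE else
        (mcmc$recenter_every > 0L && it %% mcmc$recenter_every == 0L)
      if (recenter_now) {
        for (g in 1:4) {
          members <- which(blocks$cell == g)
          if (!length(members)) next
          for (j in seq_len(npar)) {
            p <- pars[j]
            delta <- exp(lsc_shift[g, j]) * rnorm(1)
            mu_p <- mu[g, j] + delta
            th_p <- theta[members, j] + delta
            lo <- supports[1, j]; hi <- supports[2, j]
            ok <- th_p > lo & th_p < hi
            if (p %in% c("ndt", "B", "bias")) {
              plo <- if (p == "bias") 1e-6 else lo
              phi <- if (p == "bias") 1 - 1e-6 else hi
              ok_mu <- mu_p > plo && mu_p < phi
            } else ok_mu <- TRUE
            acc <- FALSE
            if (all(ok) && ok_mu) {
              # member normal terms are shift-invariant; only the hyperprior,
              # the truncation normalizer and the likelihood change
              lp_c <- .hyper_mu_logprior(p, mu[g, j], priors) +
                .ind_logprior(theta[members, j], mu[g, j], sg[g, j], lo, hi)
              lp_p <- .hyper_mu_logprior(p, mu_p, priors) +
                .ind_logprior(th_p, mu_p, sg[g, j], lo, hi)
              ll_new <- numeric(length(members))
              dll <- 0
              if (!prior_only) {
                for (mi in seq_along(members)) {
                  b <- members[mi]
                  th_b <- theta[b, ]; th_b[j] <- th_p[mi]
                  ll_new[mi] <- block_ll(th_b, b)
                }
                dll <- sum(ll_new) - sum(cur_ll[members])
              }
              lacc <- (lp_p - lp_c) + dll
              acc <- is.finite(lacc) && log(runif(1)) < lacc
              if (acc) {
                mu[g, j] <- mu_p
                theta[members, j] <- th_p
                if (!prior_only) cur_ll[members] <- ll_new
              }
            }
            if (adapting) {
              lsc_shift[g, j] <- lsc_shift[g, j] +
                gam * ((if (acc) 1 else 0) - mcmc$target_accept)
            }
          }
        }
      }

      if (!adapting) {
        k <- it - mcmc$n_burn
        keep_mu[k, , ] <- mu
        keep_sg[k, , ] <- sg
        keep_th[k, , ] <- theta
        keep_dev[k] <- -2 * sum(cur_ll)
        keep_cell_dev[k, ] <- -2 * tapply(cur_ll, factor(blocks$cell, 1:4), sum)
      }
    }
    list(mu = keep_mu, sg = keep_sg, theta = keep_th, dev = keep_dev,
         cell_dev = keep_cell_dev)
  }

  chains <- purrr::map(seq_len(mcmc$n_chains), run_chain)
  bindc <- function(getter) do.call(abind1, purrr::map(chains, getter))
  draws <- list(
    mu = bindc(function(x) x$mu),
    sg = bindc(function(x) x$sg),
    theta = bindc(function(x) x$theta),
    dev = unlist(purrr::map(chains, "dev")),
    cell_dev = do.call(rbind, purrr::map(chains, "cell_dev"))
  )
  chain_id <- rep(seq_len(mcmc$n_chains), each = mcmc$n_keep)

  fit <- structure(list(
    model_id = model_id, par_names = pars, blocks = blocks, draws = draws,
    chain_id = chain_id, priors = priors, mcmc = mcmc, seed = seed,
    prior_only = prior_only, trials = trials,
    theta_mean = apply(draws$theta, c(2, 3), mean),
    cells = .cell_labels()
  ), class = "stddm_fit")
  fit$diagnostics <- .fit_diagnostics(fit)
  bad <- fit$diagnostics$hyperparameter[fit$diagnostics$rhat > 1.1]
  if (length(bad)) {
    warn(paste("R-hat above 1.1 for:", paste(bad, collapse = ", ")))
  }
  fit
}

`%||na%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# parameter value from a named vector, 0 when the model lacks it
.th_get <- function(th, nm) if (nm %in% names(th)) th[[nm]] else 0

# bind kept-draw arrays along the first (iteration) dimension
abind1 <- function(...) {
  args <- list(...)
  if (length(args) == 1) return(args[[1]])
  d <- dim(args[[1]])
  out <- array(NA_real_, c(sum(vapply(args, function(a) dim(a)[1], 0L)), d[2], d[3]))
  at <- 0L
  for (a in args) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

.cell_labels <- function() {
  tibble::tibble(
    cell = 1:4,
    age_group = rep(.age_levels, each = 2),
    condition = rep(.cond_levels, 2)
  )
}

.cell_index <- function(age_group, condition) {
  2L * (match(age_group, .age_levels) - 1L) + match(condition, .cond_levels)
}

.split_rhat <- function(x, chain_id) {
  halves <- unlist(lapply(split(seq_along(x), chain_id), function(ix) {
    h <- length(ix) %/% 2
    rep(1:2, c(h, length(ix) - h))
  }))
  grp <- interaction(chain_id, halves)
  m <- tapply(x, grp, mean); v <- tapply(x, grp, var)
  n <- min(tapply(x, grp, length))
  W <- mean(v); B <- n * var(m)
  if (!is.finite(W) || W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.ess_basic <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
  ssum <- 0
  for (k in seq_along(ac)) {
    if (ac[k] < 0.05) break
    ssum <- ssum + ac[k]
  }
  n / (1 + 2 * ssum)
}

.fit_diagnostics <- function(fit) {
  pars <- fit$par_names
  out <- list()
  for (g in 1:4) {
    for (j in seq_along(pars)) {
      for (lvl in c("mu", "sg")) {
        x <- fit$draws[[lvl]][, g, j]
        out[[length(out) + 1]] <- tibble::tibble(
          hyperparameter = sprintf("%s[%s,%s]", lvl,
                                   paste(fit$cells$age_group[g],
                                         fit$cells$condition[g], sep = "."),
                                   pars[j]),
          rhat = .split_rhat(x, fit$chain_id),
          ess = .ess_basic(x)
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.stddm_fit <- function(x, ...) {
  cat(sprintf("<stddm_fit %s> %d blocks, %d draws (%d chains), preset '%s'\n",
              x$model_id, nrow(x$blocks), length(x$draws$dev),
              x$mcmc$n_chains, x$mcmc$preset))
  if (!x$prior_only) {
    cat(sprintf("  mean deviance %.1f, max split-Rhat %.3f\n",
                mean(x$draws$dev), max(x$diagnostics$rhat)))
  }
  invisible(x)
}

#' @export
tidy.stddm_fit <- function(x, level = c("group", "individual"), ...) {
  level <- match.arg(level)
  pars <- x$par_names
  if (level == "group") {
    out <- purrr::map_dfr(1:4, function(g) {
      purrr::map_dfr(seq_along(pars), function(j) {
        draws_mu <- x$draws$mu[, g, j]
        hh <- hdi(draws_mu)
        tibble::tibble(
          age_group = x$cells$age_group[g], condition = x$cells$condition[g],
          parameter = pars[j],
          mean = mean(draws_mu), sd = sd(draws_mu),
          hdi_lower = hh[1], hdi_upper = hh[2],
          spread_mean = mean(x$draws$sg[, g, j])
        )
      })
    })
    return(out)
  }
  purrr::map_dfr(seq_len(nrow(x$blocks)), function(b) {
    tibble::tibble(
      participant_id = x$blocks$participant_id[b],
      age_group = x$blocks$age_group[b], condition = x$blocks$condition[b],
      parameter = pars, mean = x$theta_mean[b, ],
      sd = apply(x$draws$theta[, b, , drop = FALSE], 3, sd)
    )
  })
}

#' @export
glance.stddm_fit <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id,
    n_blocks = nrow(x$blocks),
    n_draws = length(x$draws$dev),
    n_chains = x$mcmc$n_chains,
    mean_deviance = mean(x$draws$dev),
    max_rhat = max(x$diagnostics$rhat),
    min_ess = min(x$diagnostics$ess)
  )
}

#' Posterior-mean individual parameters
#'
#' @param fit An `stddm_fit`.
#' @return Tibble with one row per participant-condition and posterior-mean
#'   parameter columns.
#' @export
posterior_mean_params <- function(fit) {
  stopifnot(inherits(fit, "stddm_fit"))
  out <- fit$blocks |> dplyr::select(-"cell")
  for (j in seq_along(fit$par_names)) {
    out[[fit$par_names[j]]] <- fit$theta_mean[, j]
  }
  if (!"w_a" %in% names(out)) out$w_a <- 0
  if (!"s" %in% names(out)) out$s <- 0
  out
}

#' Posterior-predictive choice simulation
#'
#' Simulates each trial `n_sims` times at the per-participant posterior-mean
#' parameters; the per-trial acceptance frequency across simulations is the
#' model's choice probability for that trial.
#'
#' @param fit An `stddm_fit`.
#' @param trials Trials to predict (default: the fitted trials).
#' @param n_sims Simulations per trial.
#' @param seed Optional integer seed.
#' @param dt Simulation step (seconds).
#' @return `trials` with a `p_accept` column added.
#' @export
posterior_predict <- function(fit, trials = NULL, n_sims = 100, seed = NULL,
                              dt = 0.001) {
  stopifnot(inherits(fit, "stddm_fit"))
  if (!is.null(seed)) set.seed(seed)
  trials <- trials %||% fit$trials
  pm <- posterior_mean_params(fit)
  mcode <- .model_code(fit$model_id)
  trials$p_accept <- NA_real_
  for (r in seq_len(nrow(pm))) {
    ix <- which(trials$participant_id == pm$participant_id[r] &
                  trials$condition == pm$condition[r])
    if (!length(ix)) next
    nacc <- numeric(length(ix))
    for (ss in seq_len(n_sims)) {
      sim <- .sim_trials_cpp(trials$v_p[ix], trials$v_m[ix], trials$v_a[ix],
                             pm$w_p[r], pm$w_m[r], pm$w_a[r], pm$s[r],
                             pm$ndt[r], pm$B[r], pm$bias[r], mcode,
                             dt, 10, 4)
      nacc <- nacc + dplyr::coalesce(as.numeric(sim$accept), 0)
    }
    trials$p_accept[ix] <- nacc / n_sims
  }
  trials
}
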