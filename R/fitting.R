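# Simulation-based likelihood against reversal/repetition curves, bounded
# multi-start fitting, model validation, parameter recovery.

#' Fitting specification
#'
#' Controls of the simulation-based fit: number of random starts, number of
#' seeded simulations per likelihood evaluation (common random numbers
#' across parameter evaluations, so the objective surface is deterministic
#' given the fit seed), the probability floor applied to predicted bin
#' probabilities, the curve targets, and optimizer iteration caps.
#'
#' The four default targets are the choice reversal curve, the confidence
#' reversal curve, the choice repetition curve, and the confidence
#' repetition curves split by repeat/switch (the split is what identifies
#' the switch-specific confidence gain); all targets enter the binomial
#' likelihood with equal weight.
#'
#' @param n_starts Random starting points (default 5).
#' @param n_sims_per_eval Simulations per likelihood evaluation (default 200).
#' @param prob_floor Floor `eps` on predicted probabilities, clamped to
#'   `[eps, 1 - eps]` (default 1e-3).
#' @param targets Subset of
#'   `c("choice_rev", "conf_rev", "choice_rep", "conf_rep")`.
#' @param window Reversal alignment window (default `c(-4, 8)`).
#' @param n_evidence_bins Equal-count evidence bins for repetition targets.
#' @param maxit,reltol Nelder-Mead controls per start.
#' @return A list of class `vol_fit_spec`.
#' @export
fit_spec <- function(n_starts = 5, n_sims_per_eval = 200, prob_floor = 1e-3,
                     targets = c("choice_rev", "conf_rev", "choice_rep",
                                 "conf_rep"),
                     window = c(-4, 8), n_evidence_bins = 8,
                     maxit = 400, reltol = 1e-7) {
  stopifnot(n_starts >= 1, prob_floor > 0, prob_floor < 0.1)
  targets <- match.arg(targets, several.ok = TRUE)
  structure(list(n_starts = n_starts, n_sims_per_eval = n_sims_per_eval,
                 prob_floor = prob_floor, targets = targets, window = window,
                 n_evidence_bins = n_evidence_bins, maxit = maxit,
                 reltol = reltol),
            class = "vol_fit_spec")
}

# Precompute everything the likelihood needs about the observed data:
# reversal-position trial indices, evidence bin breaks, and observed
# per-bin counts for each target curve.
build_fit_targets <- function(session, responses, spec) {
  n <- nrow(session)
  positions <- spec$window[1]:spec$window[2]
  positions <- positions[positions != 0]
  rev_idx <- which(session$is_reversal)
  pos_trials <- lapply(positions, function(k) {
    t <- if (k >= 1) rev_idx + k - 1 else rev_idx + k
    ok <- t >= 1 & t <= n & session$block[pmin(pmax(t, 1), n)] == session$block[rev_idx]
    t2 <- t[ok]; r2 <- rev_idx[ok]
    if (k >= 1) t2[session$episode[t2] == session$episode[r2]]
    else t2[session$episode[t2] == session$episode[r2] - 1]
  })
  names(pos_trials) <- positions

  high_obs <- responses$confidence == "high"
  rep_obs <- ifelse(is.na(responses$is_switch), NA, !responses$is_switch)
  ev_obs <- responses$signed_evidence
  breaks <- {
    e <- ev_obs[!is.na(ev_obs)]
    qs <- stats::quantile(e, probs = seq(0, 1, length.out =
                                           spec$n_evidence_bins + 1),
                          names = FALSE)
    b <- unique(qs); b[1] <- -Inf; b[length(b)] <- Inf
    b
  }
  nb <- length(breaks) - 1
  bin_obs <- findInterval(ev_obs, breaks, all.inside = TRUE)
  bin_obs[is.na(ev_obs)] <- NA

  counts <- list()
  if ("choice_rev" %in% spec$targets) {
    counts$choice_rev <- lapply(pos_trials, function(tt) {
      ok <- tt[!is.na(responses$correct[tt])]
      c(n = length(ok), k = sum(responses$correct[ok]))
    })
  }
  if ("conf_rev" %in% spec$targets) {
    counts$conf_rev <- lapply(pos_trials, function(tt) {
      c(n = length(tt), k = sum(high_obs[tt]))
    })
  }
  if ("choice_rep" %in% spec$targets) {
    counts$choice_rep <- lapply(seq_len(nb), function(b) {
      ii <- !is.na(bin_obs) & bin_obs == b & !is.na(rep_obs)
      c(n = sum(ii), k = sum(rep_obs[ii]))
    })
  }
  if ("conf_rep" %in% spec$targets) {
    counts$conf_rep <- lapply(seq_len(nb), function(b) {
      ii <- !is.na(bin_obs) & bin_obs == b & !is.na(rep_obs)
      c(n_rep = sum(ii & rep_obs), k_rep = sum(high_obs[ii & rep_obs]),
        n_sw = sum(ii & !rep_obs), k_sw = sum(high_obs[ii & !rep_obs]))
    })
  }
  list(pos_trials = pos_trials, breaks = breaks, n_bins = nb,
       counts = counts)
}

# Model-predicted bin probabilities from a batch of simulations.
predict_bin_probs <- function(sim, targets, spec) {
  out <- list()
  if ("choice_rev" %in% spec$targets || "conf_rev" %in% spec$targets) {
    out$choice_rev <- vapply(targets$pos_trials, function(tt) {
      if (length(tt) == 0) NA_real_ else mean(sim$correct[tt, ])
    }, numeric(1))
    out$conf_rev <- vapply(targets$pos_trials, function(tt) {
      if (length(tt) == 0) NA_real_ else mean(sim$p_high[tt, ])
    }, numeric(1))
  }
  if ("choice_rep" %in% spec$targets || "conf_rep" %in% spec$targets) {
    ev <- as.vector(sim$signed_evidence)
    rep_sim <- as.vector(sim$repeat_flag)
    ph <- as.vector(sim$p_high)
    ok <- !is.na(ev) & !is.na(rep_sim)
    ev <- ev[ok]; rep_sim <- rep_sim[ok]; ph <- ph[ok]
    bin <- findInterval(ev, targets$breaks, all.inside = TRUE)
    nb <- targets$n_bins
    wsum <- function(x, b) {
      out <- numeric(nb)
      if (length(x)) {
        r <- rowsum(x, b)
        out[as.integer(rownames(r))] <- r
      }
      out
    }
    n_tot <- tabulate(bin, nb)
    n_rep <- tabulate(bin[rep_sim], nb)
    k_rep <- wsum(ph[rep_sim], bin[rep_sim])
    k_sw <- wsum(ph[!rep_sim], bin[!rep_sim])
    n_sw <- n_tot - n_rep
    div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
    out$choice_rep <- div(n_rep, n_tot)
    out$conf_rep <- list(rep = div(k_rep, n_rep), sw = div(k_sw, n_sw))
  }
  out
}

binom_nll <- function(n, k, p, eps) {
  if (is.na(n) || n == 0 || is.na(p)) return(0)
  p <- clamp(p, eps, 1 - eps)
  -(k * log(p) + (n - k) * log(1 - p))
}

#' Simulation-based negative log-likelihood of curve targets
#'
#' Estimates the model's per-bin event probabilities from
#' `spec$n_sims_per_eval` seeded simulations of the observer on the session
#' (common random numbers across parameter evaluations), floors them at
#' `[eps, 1 - eps]`, and returns the summed binomial negative log-likelihood
#' of the observed curve counts. Empty observed bins contribute exactly 0.
#'
#' @param params A [model_params()].
#' @param session A `vol_session` (typically one condition).
#' @param targets Precomputed observed targets (internal structure built
#'   from `session` and `responses` inside [fit_model()]); users normally
#'   call [fit_model()] directly.
#' @param spec A [fit_spec()].
#' @param seed Fit seed for the common random numbers.
#' @param crn Optional pre-drawn common random numbers (internal reuse
#'   across evaluations; must come from `seed`).
#' @return Scalar negative log-likelihood.
#' @export
curve_neg_log_likelihood <- function(params, session, targets, spec, seed,
                                     crn = NULL) {
  sim <- simulate_agents_matrix(session, params, spec$n_sims_per_eval, seed,
                                crn = crn)
  pred <- predict_bin_probs(sim, targets, spec)
  eps <- spec$prob_floor
  nll <- 0
  if ("choice_rev" %in% spec$targets) {
    for (j in seq_along(targets$counts$choice_rev)) {
      cc <- targets$counts$choice_rev[[j]]
      nll <- nll + binom_nll(cc["n"], cc["k"], pred$choice_rev[j], eps)
    }
  }
  if ("conf_rev" %in% spec$targets) {
    for (j in seq_along(targets$counts$conf_rev)) {
      cc <- targets$counts$conf_rev[[j]]
      nll <- nll + binom_nll(cc["n"], cc["k"], pred$conf_rev[j], eps)
    }
  }
  if ("choice_rep" %in% spec$targets) {
    for (b in seq_along(targets$counts$choice_rep)) {
      cc <- targets$counts$choice_rep[[b]]
      nll <- nll + binom_nll(cc["n"], cc["k"], pred$choice_rep[b], eps)
    }
  }
  if ("conf_rep" %in% spec$targets) {
    for (b in seq_along(targets$counts$conf_rep)) {
      cc <- targets$counts$conf_rep[[b]]
      nll <- nll + binom_nll(cc["n_rep"], cc["k_rep"], pred$conf_rep$rep[b], eps)
      nll <- nll + binom_nll(cc["n_sw"], cc["k_sw"], pred$conf_rep$sw[b], eps)
    }
  }
  nll
}

#' Fit the observer model to responses
#'
#' Bounded derivative-free minimization of [curve_neg_log_likelihood()]:
#' parameters are mapped to the real line by scaled-logit transforms of
#' their bounds and searched by Nelder-Mead from `n_starts` starting points
#' (one central, the rest seeded-random). Parameters are fitted per
#' condition (every parameter is allowed to differ between conditions);
#' pass a single-condition session to fit one condition.
#'
#' @param session A `vol_session`.
#' @param responses Matching responses.
#' @param spec A [fit_spec()].
#' @param seed Fit seed (drives starts and the common random numbers).
#' @return For a single-condition session, a list of class `vol_fit` with
#'   `params`, `nll`, `starts` (per-start diagnostics), `converged`;
#'   for a mixed session, a named list of such fits per condition.
#' @export
fit_model <- function(session, responses, spec = fit_spec(), seed = 1) {
  conds <- unique(session$condition)
  if (length(conds) > 1) {
    fits <- lapply(seq_along(conds), function(i) {
      keep <- session$condition == conds[i]
      fit_model(subset_session(session, keep), responses[keep, ], spec,
                seed = child_seed(seed, i))
    })
    names(fits) <- conds
    return(fits)
  }
  targets <- build_fit_targets(session, responses, spec)
  crn <- draw_crn(session, spec$n_sims_per_eval, seed)
  obj <- function(x) {
    p <- from_unbounded(x)
    curve_neg_log_likelihood(p, session, targets, spec, seed = seed,
                             crn = crn)
  }
  # random-point pre-screen: cheap evaluations across the plausible box pick
  # the Nelder-Mead starting points (the surface has well-separated basins,
  # e.g. in the threshold x metacognitive-noise plane)
  rand_point <- function() {
    to_unbounded(model_params(
      hazard = stats::runif(1, 0.02, 0.5),
      sigma_inf = stats::runif(1, 0.1, 3),
      conf_threshold = stats::runif(1, -0.5, 4.5),
      sigma_meta = stats::runif(1, 0.05, 4),
      conf_gain = stats::runif(1, 0.3, 2.5)))
  }
  central <- to_unbounded(model_params(hazard = 0.15, sigma_inf = 1,
                                       conf_threshold = 1, sigma_meta = 1,
                                       conf_gain = 1))
  starts <- with_seed(child_seed(seed, 999), {
    screen <- c(list(central), lapply(seq_len(8 * spec$n_starts),
                                      function(i) rand_point()))
    sv <- vapply(screen, obj, numeric(1))
    screen[order(sv)][seq_len(spec$n_starts)]
  })
  runs <- lapply(starts, function(s) {
    tryCatch(stats::optim(s, obj, method = "Nelder-Mead",
                          control = list(maxit = spec$maxit,
                                         reltol = spec$reltol)),
             error = function(e) NULL)
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0) stop_config("all optimization starts failed")
  vals <- vapply(runs, `[[`, numeric(1), "value")
  # near-ties between basins can be Monte-Carlo artifacts at the search
  # precision: re-rank candidate optima under 10x simulations before
  # declaring a winner, then polish it briefly
  ord <- order(vals)
  cand <- runs[ord[vals[ord] <= vals[ord[1]] + 5]]
  if (length(cand) > 1) {
    spec_hi <- spec
    spec_hi$n_sims_per_eval <- spec$n_sims_per_eval * 10L
    crn_hi <- draw_crn(session, spec_hi$n_sims_per_eval,
                       child_seed(seed, 777))
    vhi <- vapply(cand, function(r) {
      curve_neg_log_likelihood(from_unbounded(r$par), session, targets,
                               spec_hi, seed = child_seed(seed, 777),
                               crn = crn_hi)
    }, numeric(1))
    best <- cand[[which.min(vhi)]]
  } else {
    best <- cand[[1]]
  }
  polish <- tryCatch(
    stats::optim(best$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = spec$reltol)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) best <- polish
  structure(list(
    params = from_unbounded(best$par),
    nll = best$value,
    starts = data.frame(nll = vals,
                        convergence = vapply(runs, `[[`, numeric(1),
                                             "convergence")),
    converged = best$convergence == 0
  ), class = "vol_fit")
}

subset_session <- function(session, keep) {
  out <- session[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- attr(session, "config")
  attr(out, "seed") <- attr(session, "seed")
  class(out) <- class(session)
  out
}

#' @export
print.vol_fit <- function(x, ...) {
  cat(sprintf("<vol_fit> NLL = %.2f (%d starts, best %s)\n", x$nll,
              nrow(x$starts), if (x$converged) "converged" else "hit maxit"))
  print(x$params)
  invisible(x)
}

#' Default generative sampling ranges for parameter recovery
#'
#' Plausible sub-intervals of the fitting bounds used to sample generative
#' parameters (the participant-derived min/max of fitted values are not
#' available without the behavioral dataset, so fixed plausible ranges are
#' used instead): hazard 0.05-0.4, inference and metacognitive noise 0-3,
#' confidence threshold 0-4, confidence gain 0.5-2.
#'
#' @return A named list of `c(lo, hi)` ranges.
#' @export
recovery_ranges <- function() {
  list(hazard = c(0.05, 0.4), sigma_inf = c(0, 3), conf_threshold = c(0, 4),
       sigma_meta = c(0, 3), conf_gain = c(0.5, 2))
}

#' Parameter-recovery harness
#'
#' For each synthetic dataset: sample generative parameters independently
#' and uniformly within `ranges`, simulate a session and an agent, refit
#' with [fit_model()], and report the Spearman correlation matrix between
#' generative and recovered parameters (diagonal = same-parameter
#' recovery).
#'
#' @param ranges Named list of `c(lo, hi)` per parameter
#'   (default [recovery_ranges()]); a parameter can be pinned by a
#'   zero-width range.
#' @param n_datasets Number of synthetic datasets (>= 10).
#' @param cfg Task configuration for the synthetic sessions.
#' @param spec A [fit_spec()].
#' @param seed Master seed.
#' @param free Optional character vector of parameters to fit; others are
#'   fixed at their generative values (reduced-dimension recovery).
#' @return A list of class `vol_recovery`: `generative` and `recovered`
#'   matrices (rows = datasets), `rho` (5 x 5 Spearman matrix), `n_failed`.
#' @export
parameter_recovery <- function(ranges = recovery_ranges(), n_datasets = 20,
                               cfg = task_config(n_blocks = 4,
                                                 condition_order =
                                                   rep("C-", 4)),
                               spec = fit_spec(n_starts = 3),
                               seed = 1, free = NULL) {
  if (n_datasets < 10) stop_config("n_datasets must be >= 10")
  nm <- names(param_bounds()$lower)
  gen <- rec <- matrix(NA_real_, n_datasets, length(nm),
                       dimnames = list(NULL, nm))
  n_failed <- 0L
  for (i in seq_len(n_datasets)) {
    gi <- with_seed(child_seed(seed, i * 3L), {
      vapply(nm, function(p) stats::runif(1, ranges[[p]][1], ranges[[p]][2]),
             numeric(1))
    })
    gp <- do.call(model_params, as.list(gi))
    sess <- generate_session(cfg, seed = child_seed(seed, i * 3L + 1L))
    agent <- simulate_agent(sess, gp, seed = child_seed(seed, i * 3L + 2L))
    fit <- tryCatch({
      if (is.null(free)) {
        fit_model(sess, agent$responses, spec, seed = child_seed(seed, i * 3L + 2L))
      } else {
        fit_model_fixed(sess, agent$responses, spec,
                        seed = child_seed(seed, i * 3L + 2L),
                        free = free, fixed = gi)
      }
    }, error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    gen[i, ] <- gi
    rec[i, ] <- param_vector(fit$params)
  }
  ok <- stats::complete.cases(gen)
  rho <- suppressWarnings(
    stats::cor(gen[ok, , drop = FALSE], rec[ok, , drop = FALSE],
               method = "spearman"))
  structure(list(generative = gen, recovered = rec, rho = rho,
                 n_failed = n_failed),
            class = "vol_recovery")
}

# reduced-dimension fit: only `free` parameters are searched, the rest stay
# at the supplied fixed values
fit_model_fixed <- function(session, responses, spec, seed, free, fixed) {
  targets <- build_fit_targets(session, responses, spec)
  crn <- draw_crn(session, spec$n_sims_per_eval, seed)
  nm <- names(param_bounds()$lower)
  idx <- match(free, nm)
  base <- fixed
  obj <- function(x) {
    v <- base
    full <- to_unbounded(do.call(model_params, as.list(v)))
    full[idx] <- x
    curve_neg_log_likelihood(from_unbounded(full), session, targets, spec,
                             seed = seed, crn = crn)
  }
  starts <- with_seed(child_seed(seed, 999), {
    lapply(seq_len(spec$n_starts), function(i) {
      stats::rnorm(length(idx), 0, 1)
    })
  })
  runs <- Filter(Negate(is.null), lapply(starts, function(s) {
    tryCatch(stats::optim(s, obj, method = if (length(idx) == 1) "Brent"
                          else "Nelder-Mead",
                          lower = if (length(idx) == 1) -15 else -Inf,
                          upper = if (length(idx) == 1) 15 else Inf,
                          control = list(maxit = spec$maxit)),
             error = function(e) NULL)
  }))
  if (length(runs) == 0) stop_config("all optimization starts failed")
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  full <- to_unbounded(do.call(model_params, as.list(base)))
  full[idx] <- best$par
  structure(list(params = from_unbounded(full), nll = best$value,
                 starts = data.frame(nll = vapply(runs, `[[`, numeric(1),
                                                  "value")),
                 converged = best$convergence == 0),
            class = "vol_fit")
}

#' @export
print.vol_recovery <- function(x, ...) {
  cat(sprintf("<vol_recovery> %d datasets (%d failed)\n",
              nrow(x$generative), x$n_failed))
  cat("diagonal Spearman rho (generative vs recovered):\n")
  print(round(diag(x$rho), 3))
  invisible(x)
}

#' Validate fitted parameters by forward simulation
#'
#' Simulates the observer `n_sims` times on a session at the given
#' parameters and returns the mean predicted reversal and repetition
#' curves, analyzed exactly as observed data would be.
#'
#' @param params A [model_params()] (or per-condition list).
#' @param session A `vol_session`.
#' @param n_sims Number of simulations to average (default 50).
#' @param seed Simulation seed.
#' @param spec A [fit_spec()] (binning controls).
#' @param breaks Optional evidence-bin breaks (e.g. from the observed data)
#'   so validation curves are binned like the fitting targets.
#' @return A named list of `vol_curve`s: `choice_rev`, `conf_rev`,
#'   `choice_rep`, `conf_rep_repeat`, `conf_rep_switch`.
#' @export
validate_model <- function(params, session, n_sims = 50, seed = 1,
                           spec = fit_spec(), breaks = NULL) {
  sim <- simulate_agents_matrix(session, params, n_sims, seed)
  positions <- spec$window[1]:spec$window[2]
  positions <- positions[positions != 0]
  targets <- list(pos_trials = NULL, breaks = breaks)
  rev_idx <- which(session$is_reversal)
  n <- nrow(session)
  pos_trials <- lapply(positions, function(k) {
    t <- if (k >= 1) rev_idx + k - 1 else rev_idx + k
    ok <- t >= 1 & t <= n & session$block[pmin(pmax(t, 1), n)] == session$block[rev_idx]
    t2 <- t[ok]; r2 <- rev_idx[ok]
    if (k >= 1) t2[session$episode[t2] == session$episode[r2]]
    else t2[session$episode[t2] == session$episode[r2] - 1]
  })
  curve_from <- function(mat) {
    n_total <- vapply(pos_trials, function(tt) length(tt) * n_sims, numeric(1))
    n_event <- vapply(pos_trials, function(tt) sum(mat[tt, ]), numeric(1))
    new_curve(data.frame(position = positions, n_total = n_total,
                         n_event = n_event,
                         p = ifelse(n_total > 0, n_event / n_total, NA)),
              axis = "trials-from-reversal", outcome = "simulated")
  }
  ev <- as.vector(sim$signed_evidence)
  rep_f <- as.vector(sim$repeat_flag)
  high <- as.vector(sim$high) == 1
  list(
    choice_rev = curve_from(sim$correct),
    conf_rev = curve_from(sim$high),
    choice_rep = build_repetition_curve(ev, rep_f,
                                        n_bins = spec$n_evidence_bins,
                                        breaks = breaks, outcome = "repeat"),
    conf_rep_repeat = build_repetition_curve(
      ev[!is.na(rep_f) & rep_f], high[!is.na(rep_f) & rep_f],
      n_bins = spec$n_evidence_bins, breaks = breaks, outcome = "high_conf"),
    conf_rep_switch = build_repetition_curve(
      ev[!is.na(rep_f) & !rep_f], high[!is.na(rep_f) & !rep_f],
      n_bins = spec$n_evidence_bins, breaks = breaks, outcome = "high_conf")
  )
}
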