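# Normative hazard-rate observer: evidence, belief propagation, choice,
# confidence readout, and full agent simulation.

#' Stimulus log-likelihood ratio
#'
#' Log ratio of the two category von Mises densities evaluated on the doubled
#' circle. With orthogonal category means (`mu_gap = pi/2`) this reduces to
#' `2 * kappa * cos(2 * (theta - mu))`, antisymmetric under category swap.
#' Positive values favor category +1.
#'
#' @param theta Orientation(s) in `[0, pi)`.
#' @param cfg A [task_config()].
#' @return Numeric vector of log-odds.
#' @examples
#' cfg <- task_config()
#' stimulus_llr(cfg$mu, cfg)            # maximal evidence for category +1
#' stimulus_llr(cfg$mu + pi / 4, cfg)   # equidistant orientation: 0
#' @export
stimulus_llr <- function(theta, cfg) {
  mus <- category_means(cfg)
  cfg$kappa * (cos(2 * (theta - mus[["1"]])) - cos(2 * (theta - mus[["-1"]])))
}

#' Propagate a belief through one reversal opportunity
#'
#' The Bayes-consistent log-odds update for a symmetric two-state environment
#' with per-trial reversal probability `h`:
#' `L' = L + log((1-h)/h + exp(-L)) - log((1-h)/h + exp(L))`.
#' Odd in `L`, bounded by `log((1-h)/h)` for `h < 1/2`, and computed in the
#' log domain so large `|L|` cannot overflow.
#'
#' @param L Log-odds belief (vectorized).
#' @param h Hazard rate, strictly inside (0, 1).
#' @return Propagated log-odds.
#' @examples
#' propagate_prior(3, 0.1)
#' propagate_prior(3, 0.5)  # memoryless: 0
#' @export
propagate_prior <- function(L, h) {
  if (any(h <= 0 | h >= 1)) stop_config("hazard must be strictly inside (0, 1)")
  a <- log((1 - h) / h)
  L + logaddexp(a, -L) - logaddexp(a, L)
}

#' Accumulate a sequence of noisy evidence samples
#'
#' Adds i.i.d. Gaussian inference noise `N(0, sigma_inf^2)` to each sample
#' log-likelihood ratio before summation, so the accumulated noise variance
#' is `length(llrs) * sigma_inf^2` — noise scales with sequence length. If
#' `hazard` is supplied, the prior is propagated through the reversal
#' opportunity first.
#'
#' @param L_prior Log-odds belief before the sequence.
#' @param llrs Numeric vector of per-stimulus log-likelihood ratios.
#' @param sigma_inf Per-sample inference-noise SD (>= 0).
#' @param hazard Optional hazard rate applied to `L_prior` via
#'   [propagate_prior()] before accumulation.
#' @return Posterior log-odds. Uses the current RNG stream.
#' @export
accumulate_sequence <- function(L_prior, llrs, sigma_inf, hazard = NULL) {
  if (sigma_inf < 0) stop_config("sigma_inf must be >= 0")
  if (!is.null(hazard)) L_prior <- propagate_prior(L_prior, hazard)
  eps <- if (sigma_inf > 0) stats::rnorm(length(llrs), 0, sigma_inf) else 0
  L_prior + sum(llrs + eps)
}

#' Deterministic choice from the posterior belief
#'
#' The observer has no selection noise: the choice is the sign of the
#' posterior log-odds, with exact ties broken toward repeating the previous
#' choice (or +1 when no previous choice exists).
#'
#' @param L_post Posterior log-odds.
#' @param prev_choice Previous choice (+1/-1) or `NULL`/`NA`.
#' @return +1 or -1.
#' @export
decide <- function(L_post, prev_choice = NULL) {
  if (L_post > 0) return(1)
  if (L_post < 0) return(-1)
  if (is.null(prev_choice) || is.na(prev_choice)) return(1)
  prev_choice
}

#' Binary confidence readout
#'
#' The confidence readout is the absolute posterior belief, multiplied by
#' `conf_gain` on switch trials, then corrupted by metacognitive noise
#' `N(0, sigma_meta^2)`; the response is high-confidence when the readout
#' exceeds `conf_threshold`. With `order = "noise-before-gain"` the noise is
#' applied to `|L|` before the gain (alternative reading; default applies
#' noise last).
#'
#' @param L_post Posterior log-odds (vectorized).
#' @param is_switch Logical (vectorized); `NA` is treated as not-a-switch.
#' @param params A [model_params()].
#' @param order Where metacognitive noise enters the readout.
#' @return Character vector, `"high"` or `"low"`. Uses the current RNG
#'   stream.
#' @export
rate_confidence <- function(L_post, is_switch, params,
                            order = c("gain-before-noise", "noise-before-gain")) {
  order <- match.arg(order)
  sw <- !is.na(is_switch) & is_switch
  gain <- ifelse(sw, params$conf_gain, 1)
  eta <- if (params$sigma_meta > 0) {
    stats::rnorm(length(L_post), 0, params$sigma_meta)
  } else 0
  readout <- if (order == "gain-before-noise") {
    abs(L_post) * gain + eta
  } else {
    (abs(L_post) + eta) * gain
  }
  ifelse(readout > params$conf_threshold, "high", "low")
}

resolve_params <- function(params, conditions) {
  if (inherits(params, "vol_model_params")) {
    return(stats::setNames(list(params, params), c("C-", "C+"))[conditions])
  }
  if (is.list(params) && all(c("C-", "C+") %in% names(params))) {
    return(params[conditions])
  }
  stop_config("params must be a vol_model_params or a list with 'C-' and 'C+'")
}

#' Simulate the observer on a session
#'
#' Runs the full observer on every trial of a session: the belief is reset to
#' zero at each block start, propagated through the reversal opportunity,
#' updated with the (noise-corrupted) sequence evidence, then read out as a
#' choice and a binary confidence. In the controllable condition the agent's
#' own actions drive the realized categories (closed loop); because the
#' session stores canonical draws, the state evidence is
#' `hidden_state * canonical LLR sum` in both conditions and the loop closes
#' exactly. The first response of each block under a zero belief is resolved
#' by a seeded coin flip; its switch flag is `NA`.
#'
#' @param session A `vol_session`.
#' @param params A [model_params()], or a named list with elements `"C-"`
#'   and `"C+"` to let parameters differ between conditions.
#' @param seed Integer seed; the simulation is deterministic given
#'   session and seed.
#' @param conf_order Passed to [rate_confidence()].
#' @return A list of class `vol_agent` with elements `trace` (per-trial
#'   `L_prior`, `evidence_noisy`, `L_post`) and `responses` (per-trial
#'   `choice`, `confidence`, `is_switch`, `is_confirmed`, `correct`,
#'   `prev_choice`, `signed_evidence`).
#' @examples
#' s <- generate_session(task_config(n_blocks = 2, trials_per_block = 36), seed = 1)
#' a <- simulate_agent(s, model_params(hazard = 0.15, sigma_inf = 0.5,
#'                                     conf_threshold = 1, sigma_meta = 0.3,
#'                                     conf_gain = 1), seed = 2)
#' head(a$responses)
#' @export
simulate_agent <- function(session, params, seed,
                           conf_order = "gain-before-noise") {
  n <- nrow(session)
  if (n == 0) {
    return(structure(list(trace = data.frame(), responses = data.frame()),
                     class = "vol_agent"))
  }
  par_by_cond <- resolve_params(params, session$condition)
  with_seed(seed, {
    L <- 0
    prev <- NA_real_
    L_prior <- L_post <- ev_noisy <- numeric(n)
    choice <- numeric(n)
    is_switch <- rep(NA, n)
    conf <- character(n)
    for (t in seq_len(n)) {
      p <- par_by_cond[[t]]
      new_block <- t == 1 || session$block[t] != session$block[t - 1]
      if (new_block) {
        L <- 0
        prev <- sample(c(-1, 1), 1)  # block-initial probe action
      }
      L_prior[t] <- propagate_prior(L, p$hazard)
      noise_sd <- sqrt(session$seq_len[t]) * p$sigma_inf
      ev_noisy[t] <- session$evidence_state[t] +
        if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
      L_post[t] <- L_prior[t] + ev_noisy[t]
      ch <- decide(L_post[t], prev)
      is_switch[t] <- if (new_block) NA else ch != prev
      conf[t] <- rate_confidence(L_post[t], is_switch[t], p, order = conf_order)
      choice[t] <- ch
      L <- L_post[t]
      prev <- ch
    }
    prev_choice <- c(NA, choice[-n])
    first_of_block <- c(TRUE, session$block[-1] != session$block[-n])
    prev_choice[first_of_block] <- NA
    nxt <- c(choice[-1], NA)
    nxt[c(first_of_block[-1], TRUE)] <- NA  # next block's first trial doesn't confirm
    is_confirmed <- ifelse(!is.na(is_switch) & is_switch & !is.na(nxt),
                           nxt == choice, NA)
    responses <- data.frame(
      trial = session$trial,
      block = session$block,
      condition = session$condition,
      choice = choice,
      confidence = conf,
      is_switch = is_switch,
      is_confirmed = is_confirmed,
      correct = choice == session$hidden_state,
      prev_choice = prev_choice,
      signed_evidence = prev_choice * session$evidence_state,
      stringsAsFactors = FALSE
    )
    trace <- data.frame(trial = session$trial, L_prior = L_prior,
                        evidence_noisy = ev_noisy, L_post = L_post)
    structure(list(trace = trace, responses = responses), class = "vol_agent")
  })
}

#' @export
print.vol_agent <- function(x, ...) {
  r <- x$responses
  cat(sprintf("<vol_agent> %d trials | accuracy %.3f | switch rate %.3f | P(high) %.3f\n",
              nrow(r), mean(r$correct), mean(r$is_switch, na.rm = TRUE),
              mean(r$confidence == "high")))
  invisible(x)
}

# propagate_prior fast path: scalar h, vector L, no overflow (the exact
# logaddexp form is the exported oracle-checked version; this one agrees to
# machine precision and is used in the inner simulation loops)
propagate_fast <- function(L, w, a) {
  out <- sign(L) * a
  m <- abs(L) < 33
  Lm <- L[m]
  out[m] <- Lm + log((w + exp(-Lm)) / (w + exp(Lm)))
  out
}

# Pre-drawn common random numbers for the vectorized simulator: fixed given
# (session, n_sims, seed) and independent of the observer parameters.
draw_crn <- function(session, n_sims, seed) {
  n <- nrow(session)
  first_of_block <- c(TRUE, session$block[-1] != session$block[-n])
  with_seed(seed, list(
    z_inf = matrix(stats::rnorm(n * n_sims), n, n_sims),
    z_meta = matrix(stats::rnorm(n * n_sims), n, n_sims),
    u_init = matrix(stats::runif(sum(first_of_block) * n_sims),
                    ncol = n_sims),
    first_of_block = first_of_block
  ))
}

# Vectorized multi-simulation core used by the simulation-based likelihood,
# model validation and the pipeline. All randomness is pre-drawn from `seed`
# independently of the parameters (common random numbers), so the implied
# objective surface is deterministic given the seed and smooth in params.
# Returns n_trials x n_sims matrices.
simulate_agents_matrix <- function(session, params, n_sims, seed,
                                   conf_order = "gain-before-noise",
                                   crn = NULL) {
  n <- nrow(session)
  par_by_cond <- resolve_params(params, session$condition)
  if (is.null(crn)) crn <- draw_crn(session, n_sims, seed)
  z_inf <- crn$z_inf
  z_meta <- crn$z_meta
  u_init <- crn$u_init
  first_of_block <- crn$first_of_block
  choice <- high <- p_high <- matrix(0, n, n_sims)
  repeat_flag <- matrix(NA, n, n_sims)
  L <- numeric(n_sims)
  prev <- numeric(n_sims)
  bi <- 0L
  noise_sd <- sqrt(session$seq_len)
  for (t in seq_len(n)) {
    p <- par_by_cond[[t]]
    if (first_of_block[t]) {
      bi <- bi + 1L
      L <- numeric(n_sims)
      prev <- 1 - 2 * (u_init[bi, ] < 0.5)
    }
    w <- (1 - p$hazard) / p$hazard
    Lp <- propagate_fast(L, w, log(w))
    Lt <- Lp + session$evidence_state[t] +
      z_inf[t, ] * (noise_sd[t] * p$sigma_inf)
    ch <- sign(Lt)
    tie <- ch == 0
    if (any(tie)) ch[tie] <- prev[tie]
    sw <- ch != prev
    if (!first_of_block[t]) repeat_flag[t, ] <- !sw
    gain <- 1 + (p$conf_gain - 1) * (sw & !first_of_block[t])
    readout <- if (conf_order == "gain-before-noise") {
      abs(Lt) * gain + z_meta[t, ] * p$sigma_meta
    } else {
      (abs(Lt) + z_meta[t, ] * p$sigma_meta) * gain
    }
    high[t, ] <- readout > p$conf_threshold
    # metacognitive noise marginalized analytically: P(high | L, switch);
    # confidence feeds nothing downstream, so this is an exact
    # Rao-Blackwellization used by the curve likelihood
    margin <- if (conf_order == "gain-before-noise") {
      abs(Lt) * gain - p$conf_threshold
    } else {
      abs(Lt) - p$conf_threshold / gain
    }
    p_high[t, ] <- if (p$sigma_meta > 0) {
      stats::pnorm(margin / p$sigma_meta)
    } else {
      as.numeric(margin > 0)
    }
    choice[t, ] <- ch
    L <- Lt
    prev <- ch
  }
  correct <- choice == session$hidden_state
  # per-simulation signed evidence (previous simulated choice x state evidence)
  prev_choice <- rbind(NA, choice[-n, , drop = FALSE])
  prev_choice[first_of_block, ] <- NA
  signed_ev <- prev_choice * session$evidence_state
  list(choice = choice, high = high, p_high = p_high,
       repeat_flag = repeat_flag, correct = correct,
       signed_evidence = signed_ev)
}
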