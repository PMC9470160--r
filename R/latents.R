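# Particle filtering of latent prior belief and evidence direction,
# conditioned on an observed response sequence.

#' Particle filter conditioned on observed responses
#'
#' Sequential importance resampling over the observer's noisy latent belief
#' path, keeping only trajectories consistent with the observed choices
#' (and, by default, confidences). Per trial, each particle propagates its
#' belief through the hazard, draws its own inference noise on the summed
#' sequence evidence, and is reweighted by the probability of the observed
#' response under the model: an indicator for the (noiseless-selection)
#' choice, times the Gaussian-CDF probability of the observed confidence
#' when `condition_on = "choice+confidence"`. Systematic resampling is
#' triggered when the effective sample size drops below `n_particles / 2`;
#' a total weight collapse is rejuvenated by resetting to uniform weights
#' with a warning.
#'
#' The per-trial outputs are the conditioned posterior means of the two
#' model latents: `prior_belief` (absolute pre-sequence belief `|L_prior|`)
#' and `evidence_direction` (the trial's summed — noisy — evidence signed by
#' the sign of the prior belief).
#'
#' @param session A `vol_session`.
#' @param responses Observed responses covering the session.
#' @param params A [model_params()] or per-condition list (from a fit).
#' @param n_particles Number of particles (default 1000).
#' @param seed Integer seed.
#' @param condition_on `"choice+confidence"` (default) or `"choice"`.
#' @param resampling `"systematic"` (default) or `"stratified"`.
#' @return A list of class `vol_latents`: `latents` (per-trial
#'   `prior_belief`, `evidence_direction`, `ess`, `resampled`) and
#'   `diagnostics` (resampling/rejuvenation counts).
#' @export
particle_filter <- function(session, responses, params, n_particles = 1000,
                            seed = 1,
                            condition_on = c("choice+confidence", "choice"),
                            resampling = c("systematic", "stratified")) {
  condition_on <- match.arg(condition_on)
  resampling <- match.arg(resampling)
  n <- nrow(session)
  stopifnot(nrow(responses) == n)
  par_by_cond <- resolve_params(params, session$condition)
  first_of_block <- c(TRUE, session$block[-1] != session$block[-n])
  with_seed(seed, {
    L <- numeric(n_particles)
    w <- rep(1 / n_particles, n_particles)
    prior_belief <- evidence_direction <- ess <- numeric(n)
    resampled <- logical(n)
    n_rejuv <- 0L
    for (t in seq_len(n)) {
      p <- par_by_cond[[t]]
      if (first_of_block[t]) {
        L <- numeric(n_particles)
        w <- rep(1 / n_particles, n_particles)
      }
      Lp <- propagate_prior(L, p$hazard)
      sd_t <- sqrt(session$seq_len[t]) * p$sigma_inf
      ev <- session$evidence_state[t] +
        if (sd_t > 0) stats::rnorm(n_particles, 0, sd_t) else 0
      Lt <- Lp + ev
      ch <- responses$choice[t]
      lik <- as.numeric(sign_pos(Lt) == ch | Lt == 0)
      if (condition_on == "choice+confidence" &&
          !is.na(responses$confidence[t])) {
        sw <- responses$is_switch[t]
        gain <- if (!is.na(sw) && sw) p$conf_gain else 1
        margin <- abs(Lt) * gain - p$conf_threshold
        p_high <- if (p$sigma_meta > 0) {
          stats::pnorm(margin / p$sigma_meta)
        } else {
          as.numeric(margin > 0)
        }
        lik <- lik * if (responses$confidence[t] == "high") p_high else 1 - p_high
      }
      wn <- w * lik
      if (sum(wn) <= 0) {
        warning("particle weight collapse at trial ", t,
                "; rejuvenating with uniform weights", call. = FALSE)
        n_rejuv <- n_rejuv + 1L
        wn <- rep(1 / n_particles, n_particles)
      }
      w <- wn / sum(wn)
      prior_belief[t] <- sum(w * abs(Lp))
      evidence_direction[t] <- sum(w * ev * sign_pos(Lp))
      ess[t] <- 1 / sum(w^2)
      if (ess[t] < n_particles / 2) {
        idx <- resample_indices(w, n_particles, resampling)
        Lt <- Lt[idx]
        w <- rep(1 / n_particles, n_particles)
        resampled[t] <- TRUE
      }
      L <- Lt
    }
    structure(list(
      latents = data.frame(trial = session$trial,
                           condition = session$condition,
                           prior_belief = prior_belief,
                           evidence_direction = evidence_direction,
                           ess = ess, resampled = resampled),
      diagnostics = list(n_resampled = sum(resampled), n_rejuvenated = n_rejuv)
    ), class = "vol_latents")
  })
}

resample_indices <- function(w, m, scheme) {
  cw <- cumsum(w)
  u <- if (scheme == "systematic") {
    (stats::runif(1) + 0:(m - 1)) / m
  } else {
    (stats::runif(m) + 0:(m - 1)) / m
  }
  findInterval(u, cw) + 1L
}

#' @export
print.vol_latents <- function(x, ...) {
  cat(sprintf("<vol_latents> %d trials | mean |prior| %.3f | resampled %d | rejuvenated %d\n",
              nrow(x$latents), mean(x$latents$prior_belief),
              x$diagnostics$n_resampled, x$diagnostics$n_rejuvenated))
  invisible(x)
}

#' Cell means of particle-filtered latents
#'
#' Mean `prior_belief` and `evidence_direction` by response type
#' (repeat/switch) and condition, ready to feed [rm_anova_2x2()] across
#' participants.
#'
#' @param latents A `vol_latents` (or its `$latents` data frame).
#' @param responses The responses the filter was conditioned on.
#' @return A data frame with columns `condition`, `response_type`,
#'   `prior_belief`, `evidence_direction`, `n`; cells with no trials are
#'   `NA`.
#' @export
summarize_latents <- function(latents, responses) {
  lt <- if (inherits(latents, "vol_latents")) latents$latents else latents
  stopifnot(nrow(lt) == nrow(responses))
  out <- expand.grid(condition = unique(lt$condition),
                     response_type = c("repeat", "switch"),
                     stringsAsFactors = FALSE)
  out$prior_belief <- out$evidence_direction <- NA_real_
  out$n <- 0L
  for (i in seq_len(nrow(out))) {
    ii <- lt$condition == out$condition[i] &
      !is.na(responses$is_switch) &
      responses$is_switch == (out$response_type[i] == "switch")
    out$n[i] <- sum(ii)
    if (any(ii)) {
      out$prior_belief[i] <- mean(lt$prior_belief[ii])
      out$evidence_direction[i] <- mean(lt$evidence_direction[ii])
    }
  }
  out
}
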