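#' Configuration of the generative reversal task
#'
#' Describes the generative statistics of the two-condition reversal task:
#' oriented-bar stimuli drawn from one of two von Mises categories whose
#' means are `mu_gap` apart in orientation space (period pi), a hidden state
#' that reverses between episodes of truncated-exponential length, and blocks
#' alternating between the uncontrollable (`"C-"`) and controllable (`"C+"`)
#' conditions.
#'
#' Orientations are handled internally on the doubled circle (`2*theta`,
#' period `2*pi`) because bars are axial stimuli; exposed values live in
#' `[0, pi)`.
#'
#' @param n_blocks Number of blocks (default 8).
#' @param trials_per_block Trials (stimulus sequences) per block (default 72).
#' @param episode_min,episode_max Hard truncation bounds on episode length in
#'   trials (defaults 4 and 24).
#' @param episode_scale Scale (mean of the untruncated exponential) of the
#'   truncated-exponential episode-length distribution, in trials. The default
#'   of 5 gives a mean episode length of about 9 trials and a near-constant
#'   reversal hazard beyond `episode_min`.
#' @param seq_lengths Allowed stimulus-sequence lengths; drawn uniformly per
#'   trial (default `c(2, 4, 6, 8)`).
#' @param kappa von Mises concentration of each category (default 0.5).
#' @param mu Orientation mean of category +1, radians in `[0, pi)`
#'   (default `pi/4`).
#' @param mu_gap Angular gap between the two category means, radians
#'   (default `pi/2`, i.e. orthogonal categories).
#' @param condition_order Optional character vector of length `n_blocks` with
#'   entries `"C-"`/`"C+"`. `NULL` (default) alternates conditions with the
#'   starting condition set by the session seed's parity, mirroring
#'   pseudo-random counterbalancing across participants.
#' @param rule_regime `"block"` (rules fixed within a block; the standard
#'   design) or `"trial"` (rule instructions change every trial; supported as
#'   a metadata variant, the generative statistics are identical).
#' @param isi_ms,isi_jitter_ms Inter-stimulus interval metadata in ms
#'   (nominal 500 +/- 50, i.e. 2 Hz presentation); carried for completeness,
#'   no effect on computation.
#'
#' @return An object of class `vol_task_config`.
#' @examples
#' cfg <- task_config()
#' cfg$n_blocks * cfg$trials_per_block  # 576 trials
#' @export
task_config <- function(n_blocks = 8, trials_per_block = 72,
                        episode_min = 4, episode_max = 24,
                        episode_scale = 5,
                        seq_lengths = c(2, 4, 6, 8),
                        kappa = 0.5, mu = pi / 4, mu_gap = pi / 2,
                        condition_order = NULL,
                        rule_regime = c("block", "trial"),
                        isi_ms = 500, isi_jitter_ms = 50) {
  rule_regime <- match.arg(rule_regime)
  if (episode_min < 1) stop_config("episode_min must be >= 1")
  if (episode_min > episode_max) stop_config("episode_min must be <= episode_max")
  if (episode_scale <= 0) stop_config("episode_scale must be > 0")
  if (kappa <= 0) stop_config("kappa must be > 0")
  if (any(seq_lengths < 1)) stop_config("all seq_lengths must be >= 1")
  if (n_blocks < 1 || trials_per_block < 1) {
    stop_config("n_blocks and trials_per_block must be >= 1")
  }
  if (!is.null(condition_order)) {
    if (length(condition_order) != n_blocks ||
        !all(condition_order %in% c("C-", "C+"))) {
      stop_config("condition_order must be length n_blocks with entries 'C-'/'C+'")
    }
  }
  structure(
    list(
      n_blocks = as.integer(n_blocks),
      trials_per_block = as.integer(trials_per_block),
      episode_min = as.integer(episode_min),
      episode_max = as.integer(episode_max),
      episode_scale = episode_scale,
      seq_lengths = as.integer(seq_lengths),
      kappa = kappa, mu = mu, mu_gap = mu_gap,
      condition_order = condition_order,
      rule_regime = rule_regime,
      isi_ms = isi_ms, isi_jitter_ms = isi_jitter_ms
    ),
    class = "vol_task_config"
  )
}

#' @export
print.vol_task_config <- function(x, ...) {
  cat("<vol_task_config>\n")
  cat(sprintf("  %d blocks x %d trials = %d trials\n",
              x$n_blocks, x$trials_per_block, x$n_blocks * x$trials_per_block))
  cat(sprintf("  episodes: truncated exponential on [%d, %d], scale %.2f\n",
              x$episode_min, x$episode_max, x$episode_scale))
  cat(sprintf("  sequences: {%s} stimuli, von Mises kappa = %.2f, mu gap = %.3f rad\n",
              paste(x$seq_lengths, collapse = ","), x$kappa, x$mu_gap))
  cat(sprintf("  rule regime: %s-wise\n", x$rule_regime))
  invisible(x)
}

# Orientation means of the two categories in [0, pi)
category_means <- function(cfg) {
  c(`1` = cfg$mu %% pi, `-1` = (cfg$mu + cfg$mu_gap) %% pi)
}
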