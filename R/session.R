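# Generative task simulator: episodes, stimulus sequences, sessions.

#' Draw episode lengths from a truncated exponential
#'
#' Samples hidden-state episode durations (in trials) from a truncated
#' exponential distribution on `[episode_min, episode_max]`, by inverse-CDF
#' sampling of the continuous truncated exponential on
#' `[episode_min, episode_max + 1)` followed by flooring. Lengths are drawn
#' until they cover `n_trials`; the caller clips the last episode to fill.
#'
#' @param n_trials Number of trials the episodes must cover.
#' @param cfg A [task_config()].
#' @return Integer vector of episode lengths with `sum >= n_trials`, each in
#'   `[episode_min, episode_max]`. Uses the current RNG stream.
#' @export
draw_episode_lengths <- function(n_trials, cfg) {
  a <- cfg$episode_min
  b <- cfg$episode_max + 1
  if (a > cfg$episode_max) stop_config("episode_min must be <= episode_max")
  if (n_trials < cfg$episode_min) stop_config("n_trials must be >= episode_min")
  if (a == cfg$episode_max) {
    # degenerate truncation: every episode has the same length
    return(rep.int(a, ceiling(n_trials / a)))
  }
  s <- cfg$episode_scale
  z <- 1 - exp(-(b - a) / s)
  lens <- integer(0)
  while (sum(lens) < n_trials) {
    u <- stats::runif(16)
    x <- a - s * log(1 - u * z)
    lens <- c(lens, pmin(as.integer(floor(x)), cfg$episode_max))
  }
  lens[seq_len(which(cumsum(lens) >= n_trials)[1])]
}

# Best-Fisher (1979) von Mises sampler on [0, 2*pi); exact for all kappa.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- (sign(u3 - 0.5) * acos(clamp(f, -1, 1)) + mu) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

#' Draw a stimulus sequence from a category
#'
#' Draws `seq_len` orientations i.i.d. from the category's von Mises
#' distribution on the doubled circle (`2*theta`, concentration `kappa`,
#' mean `2*mu_category`), mapped back to orientation space `[0, pi)`.
#'
#' @param category +1 or -1, the generative category.
#' @param seq_len Sequence length; must be in `cfg$seq_lengths`.
#' @param cfg A [task_config()].
#' @return Numeric vector of orientations in `[0, pi)`. Uses the current
#'   RNG stream.
#' @export
draw_sequence <- function(category, seq_len, cfg) {
  if (!seq_len %in% cfg$seq_lengths) {
    stop_config("seq_len ", seq_len, " not in allowed set {",
                paste(cfg$seq_lengths, collapse = ","), "}")
  }
  if (!category %in% c(-1, 1)) stop_config("category must be +1 or -1")
  mu <- unname(category_means(cfg)[as.character(category)])
  phi <- rvonmises(seq_len, 2 * mu, cfg$kappa)
  (phi / 2) %% pi
}

#' Category realized on a trial
#'
#' In the uncontrollable condition (`"C-"`) the drawn category is the hidden
#' state itself. In the controllable condition (`"C+"`) the sequence is the
#' outcome of the agent's previous action passed through the hidden
#' action-to-category mapping: `category = hidden_state * prev_action`
#' (hidden state +1 is the identity mapping).
#'
#' @param hidden_state +1 or -1.
#' @param condition `"C-"` or `"C+"`.
#' @param prev_action +1/-1; required in `"C+"` (the block-initial probe
#'   supplies the first action).
#' @return +1 or -1.
#' @export
realize_trial_category <- function(hidden_state, condition, prev_action = NULL) {
  if (!hidden_state %in% c(-1, 1)) stop_config("hidden_state must be +1 or -1")
  if (condition == "C-") return(hidden_state)
  if (condition == "C+") {
    if (is.null(prev_action) || is.na(prev_action)) {
      stop_config("prev_action is required in the C+ condition")
    }
    return(hidden_state * prev_action)
  }
  stop_config("condition must be 'C-' or 'C+'")
}

#' Mirror canonical orientations into a realized category
#'
#' Sessions store each trial's stimuli as "canonical" draws from category +1.
#' Because the two category distributions are mirror images on the doubled
#' circle, a draw from category -1 is obtained by rotating the doubled angle
#' by pi, i.e. shifting the orientation by `mu_gap` modulo pi. The stimulus
#' log-likelihood ratio flips sign under this map.
#'
#' @param theta Canonical orientations (category +1 draws), radians.
#' @param category Realized category, +1 or -1.
#' @param cfg A [task_config()].
#' @return Realized orientations in `[0, pi)`.
#' @export
realize_orientations <- function(theta, category, cfg) {
  if (category == 1) return(theta %% pi)
  (theta + cfg$mu_gap) %% pi
}

#' Generate a synthetic task session
#'
#' Builds the full generative world of one session: blocks alternating
#' conditions, hidden-state episodes with truncated-exponential durations,
#' uniform sequence lengths, and canonical von Mises stimulus draws.
#' Deterministic given `seed`.
#'
#' The returned data frame stores, per trial, the canonical orientations
#' (as if drawn from category +1) plus the summed canonical stimulus
#' log-likelihood ratio. The evidence each trial carries about the hidden
#' state is `evidence_state = hidden_state * sum(canonical LLRs)` in both
#' conditions: in C- the realized category is the state; in C+ the category
#' is `state * prev_action` but the evidence is re-signed by the agent's own
#' previous action, and the two signs cancel. This makes the session
#' "closed-loop ready": any action stream can realize C+ stimuli from the
#' same canonical draws via [realize_orientations()].
#'
#' @param cfg A [task_config()].
#' @param seed Integer seed.
#' @return A `vol_session`: a data frame with one row per trial (columns
#'   `trial`, `block`, `condition`, `episode`, `pos_in_episode`,
#'   `is_reversal`, `hidden_state`, `seq_len`, `evidence_state`, and the
#'   list-column `orientations` of canonical draws), with the config and seed
#'   stored as attributes.
#' @examples
#' s <- generate_session(task_config(), seed = 1)
#' nrow(s)  # 576
#' @export
generate_session <- function(cfg, seed) {
  stopifnot(inherits(cfg, "vol_task_config"))
  with_seed(seed, {
    conds <- cfg$condition_order
    if (is.null(conds)) {
      start <- if (seed %% 2 == 1) c("C-", "C+") else c("C+", "C-")
      conds <- rep_len(start, cfg$n_blocks)
    }
    rows <- vector("list", cfg$n_blocks)
    for (b in seq_len(cfg$n_blocks)) {
      npb <- cfg$trials_per_block
      # clip the last episode so the block has exactly npb trials; redraw if
      # the clipped remainder would violate the hard minimum (pseudo-random
      # design constraint: every realized episode stays in [min, max])
      repeat {
        lens <- draw_episode_lengths(npb, cfg)
        lens[length(lens)] <- lens[length(lens)] - (sum(lens) - npb)
        if (lens[length(lens)] >= cfg$episode_min) break
      }
      episode <- rep(seq_along(lens), lens)
      pos <- unlist(lapply(lens, seq_len), use.names = FALSE)
      s0 <- sample(c(-1L, 1L), 1)
      state <- s0 * (-1L)^(episode - 1L)
      seq_len_t <- sample(cfg$seq_lengths, npb, replace = TRUE)
      orientations <- lapply(seq_len_t, function(k) {
        draw_sequence(1, k, cfg)
      })
      llr_sum <- vapply(orientations, function(th) sum(stimulus_llr(th, cfg)),
                        numeric(1))
      rows[[b]] <- data.frame(
        block = b,
        condition = conds[b],
        episode = episode,
        pos_in_episode = pos,
        is_reversal = pos == 1L & episode > 1L,
        hidden_state = state,
        seq_len = seq_len_t,
        evidence_state = state * llr_sum,
        stringsAsFactors = FALSE
      )
      rows[[b]]$orientations <- I(orientations)
    }
    out <- do.call(rbind, rows)
    out$trial <- seq_len(nrow(out))
    out <- out[, c("trial", setdiff(names(out), "trial"))]
    rownames(out) <- NULL
    attr(out, "config") <- cfg
    attr(out, "seed") <- as.integer(seed)
    class(out) <- c("vol_session", "data.frame")
    out
  })
}

session_config <- function(session) attr(session, "config")

#' @export
print.vol_session <- function(x, ...) {
  cfg <- session_config(x)
  cat(sprintf("<vol_session> %d trials, %d blocks, seed %d\n",
              nrow(x), cfg$n_blocks, attr(x, "seed")))
  cat(sprintf("  conditions: %s\n",
              paste(rle(x$condition)$values, collapse = " ")))
  print(utils::head(as.data.frame(x)[, setdiff(names(x), "orientations")]), ...)
  invisible(x)
}

#' Subset a session to one condition
#'
#' Keeps whole blocks of the given condition; block structure (and the belief
#' reset it implies) is preserved.
#'
#' @param session A `vol_session`.
#' @param condition `"C-"` or `"C+"`.
#' @return A `vol_session` containing only the matching blocks.
#' @export
filter_condition <- function(session, condition) {
  keep <- session$condition == condition
  out <- session[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- session_config(session)
  attr(out, "seed") <- attr(session, "seed")
  class(out) <- class(session)
  out
}
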