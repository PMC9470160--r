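# Reversal- and repetition-aligned curves and psychometric fits.

new_curve <- function(df, axis, outcome) {
  structure(df, axis = axis, outcome = outcome,
            class = c("vol_curve", "data.frame"))
}

#' @export
print.vol_curve <- function(x, ...) {
  cat(sprintf("<vol_curve> axis = %s, outcome = %s\n",
              attr(x, "axis"), attr(x, "outcome")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Reversal-aligned response curve
#'
#' Pools trials around every hidden-state reversal and computes, per relative
#' position, the fraction of trials on which the event occurred: a correct
#' report of the trial's own hidden state (`outcome = "correct"`) or a
#' high-confidence response (`outcome = "high_conf"`). Positions are clipped
#' to the surrounding episodes: position `k >= 1` is the k-th trial of the
#' new episode, `k <= -1` counts back into the immediately preceding episode.
#'
#' @param responses Response data frame from [simulate_agent()] (or the
#'   ingested equivalent).
#' @param session The matching `vol_session`.
#' @param window Integer vector `c(pre, post)` of most negative and most
#'   positive relative positions (default `c(-4, 8)`).
#' @param outcome `"correct"` or `"high_conf"`.
#' @return A `vol_curve` data frame with columns `position`, `n_total`,
#'   `n_event`, `p`.
#' @export
build_reversal_curve <- function(responses, session, window = c(-4, 8),
                                 outcome = c("correct", "high_conf")) {
  outcome <- match.arg(outcome)
  if (window[1] > -1 || window[2] < 4) {
    stop_config("window must span at least 1 pre- and 4 post-reversal trials")
  }
  rev_idx <- which(session$is_reversal)
  if (length(rev_idx) == 0) stop_config("no reversals in the session")
  event <- if (outcome == "correct") responses$correct else
    responses$confidence == "high"
  positions <- window[1]:window[2]
  positions <- positions[positions != 0]
  n_total <- n_event <- stats::setNames(numeric(length(positions)),
                                        positions)
  for (r in rev_idx) {
    for (j in seq_along(positions)) {
      k <- positions[j]
      t <- if (k >= 1) r + k - 1 else r + k
      if (t < 1 || t > nrow(session)) next
      if (session$block[t] != session$block[r]) next
      # stay inside the episode the position refers to
      if (k >= 1 && session$episode[t] != session$episode[r]) next
      if (k <= -1 && session$episode[t] != session$episode[r] - 1) next
      if (is.na(event[t])) next
      n_total[j] <- n_total[j] + 1
      n_event[j] <- n_event[j] + event[t]
    }
  }
  new_curve(
    data.frame(position = positions, n_total = n_total, n_event = n_event,
               p = ifelse(n_total > 0, n_event / n_total, NA_real_),
               row.names = NULL),
    axis = "trials-from-reversal", outcome = outcome
  )
}

#' Repetition curve over signed evidence bins
#'
#' Bins trials by the objective evidence signed in favor of repeating the
#' previous choice (equal-count bins) and computes the per-bin fraction of
#' the event: repeats (`outcome = "repeat"`) or high-confidence responses
#' (`outcome = "high_conf"`). Binning is for display and for the
#' simulation-based likelihood; trial-level fits use the unbinned values.
#'
#' @param evidence Signed evidence per trial (`NA` dropped).
#' @param flags Logical event per trial.
#' @param n_bins Number of equal-count bins (default 8).
#' @param breaks Optional explicit bin breaks (overrides `n_bins`).
#' @param outcome Label stored on the curve.
#' @return A `vol_curve` with columns `bin`, `center`, `n_total`, `n_event`,
#'   `p`, plus the breaks as an attribute.
#' @export
build_repetition_curve <- function(evidence, flags, n_bins = 8, breaks = NULL,
                                   outcome = "repeat") {
  keep <- !is.na(evidence) & !is.na(flags)
  evidence <- evidence[keep]; flags <- flags[keep]
  if (length(evidence) == 0) stop_config("no usable trials")
  if (is.null(breaks)) {
    qs <- stats::quantile(evidence, probs = seq(0, 1, length.out = n_bins + 1),
                          names = FALSE)
    breaks <- unique(qs)
    breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
  }
  bin <- cut(evidence, breaks = breaks, labels = FALSE, include.lowest = TRUE)
  nb <- length(breaks) - 1
  n_total <- tabulate(bin, nbins = nb)
  n_event <- tabulate(bin[flags], nbins = nb)
  center <- vapply(seq_len(nb), function(b) {
    if (n_total[b] > 0) stats::median(evidence[bin == b]) else NA_real_
  }, numeric(1))
  out <- new_curve(
    data.frame(bin = seq_len(nb), center = center, n_total = n_total,
               n_event = n_event,
               p = ifelse(n_total > 0, n_event / n_total, NA_real_)),
    axis = "signed-evidence-bin", outcome = outcome
  )
  attr(out, "breaks") <- breaks
  out
}

new_psychfit <- function(model, params, loss, converged, degenerate = FALSE,
                         note = NULL) {
  structure(list(model = model, params = params, loss = loss,
                 converged = converged, degenerate = degenerate, note = note),
            class = "vol_psychfit")
}

#' @export
print.vol_psychfit <- function(x, ...) {
  cat(sprintf("<vol_psychfit> %s%s\n", x$model,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  print(unlist(x$params))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

# multi-start Nelder-Mead on an unconstrained parameterization
multistart_optim <- function(obj, starts) {
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-9)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best
}

#' Fit the reversal recovery curve
#'
#' Binomial-weighted least-squares fit of the two-parameter recovery function
#' `p(k) = asym - (2*asym - 1) * exp(-k / tau)` to the post-reversal
#' positions of a choice reversal curve: just after a reversal the fraction
#' of correct-state reports starts near `1 - asym` (the mirrored pre-reversal
#' level) and recovers toward the asymptote `asym` with time constant `tau`.
#'
#' @param curve A `vol_curve` from [build_reversal_curve()].
#' @return A `vol_psychfit` with parameters `asymptote` and `tau`. Fits with
#'   `tau` at its search bounds or an asymptote indistinguishable from chance
#'   are flagged degenerate rather than raising errors.
#' @export
fit_reversal_exponential <- function(curve) {
  d <- curve[curve$position >= 1 & curve$n_total > 0, ]
  if (nrow(d) < 4) stop_config("need >= 4 post-reversal bins")
  obj <- function(par) {
    asym <- 0.5 + 0.5 * stats::plogis(par[1])
    tau <- exp(par[2])
    pk <- asym - (2 * asym - 1) * exp(-d$position / tau)
    sum(d$n_total * (d$p - pk)^2)
  }
  starts <- list(c(1, log(2)), c(2, log(0.5)), c(0.5, log(5)),
                 c(1.5, log(1)), c(0.2, log(10)))
  best <- multistart_optim(obj, starts)
  asym <- 0.5 + 0.5 * stats::plogis(best$par[1])
  tau <- exp(best$par[2])
  degen <- tau < 1e-3 || tau > 1e3 || asym - 0.5 < 1e-3
  new_psychfit("trunc-exponential",
               list(asymptote = asym, tau = tau),
               loss = best$value, converged = best$convergence == 0,
               degenerate = degen,
               note = if (degen) "tau at bound or asymptote at chance" else NULL)
}

#' Fit the confidence reversal curve and its drop
#'
#' Exponential-learning fit `p(k) = pmin + (pmax - pmin) * (1 - exp(-k/tau))`
#' to the post-reversal positions of a high-confidence reversal curve,
#' followed by the confidence-drop statistic (see [confidence_drop()]).
#'
#' @param curve A `vol_curve` built with `outcome = "high_conf"`.
#' @param drop_formula Passed to [confidence_drop()].
#' @return A `vol_psychfit` with parameters `pmin`, `pmax`, `tau`, `drop`.
#' @export
fit_confidence_reversal <- function(curve, drop_formula = "gap-at-1") {
  d <- curve[curve$position >= 1 & curve$n_total > 0, ]
  if (nrow(d) < 4) stop_config("need >= 4 post-reversal bins")
  obj <- function(par) {
    pmin_ <- stats::plogis(par[1])
    pmax_ <- pmin_ + (1 - pmin_) * stats::plogis(par[2])
    tau <- exp(par[3])
    pk <- pmin_ + (pmax_ - pmin_) * (1 - exp(-d$position / tau))
    sum(d$n_total * (d$p - pk)^2)
  }
  starts <- list(c(-1, 1, log(2)), c(0, 0, log(1)), c(-2, 2, log(5)),
                 c(-0.5, 0.5, log(0.5)), c(0.5, -1, log(3)))
  best <- multistart_optim(obj, starts)
  pmin_ <- stats::plogis(best$par[1])
  pmax_ <- pmin_ + (1 - pmin_) * stats::plogis(best$par[2])
  tau <- exp(best$par[3])
  degen <- tau < 1e-3 || tau > 1e3
  params <- list(pmin = pmin_, pmax = pmax_, tau = tau)
  params$drop <- if (degen && pmax_ - pmin_ > 1e-3) {
    NA_real_
  } else {
    confidence_drop(pmin_, pmax_, tau, formula = drop_formula)
  }
  new_psychfit("exp-learning", params, loss = best$value,
               converged = best$convergence == 0, degenerate = degen,
               note = if (degen) "tau at bound; drop undefined" else NULL)
}

#' Confidence-drop statistic
#'
#' Decrement of confidence immediately after a reversal implied by the fitted
#' exponential-learning curve. The default reading, `"gap-at-1"`, is the gap
#' between the upper asymptote and the curve's value at the first
#' post-reversal trial:
#' `drop = pmax - [pmin + (pmax - pmin) * (1 - exp(-1/tau))]`,
#' which simplifies to `(pmax - pmin) * exp(-1/tau)`. The alternative
#' parenthesization of the same time-constant correction,
#' `"sum"`, is `(pmax - pmin) + (pmax - pmin) * (1 - exp(-1/tau))`.
#'
#' @param pmin,pmax Lower and upper asymptotes.
#' @param tau Time constant (> 0).
#' @param formula `"gap-at-1"` (default) or `"sum"`.
#' @return Numeric drop.
#' @export
confidence_drop <- function(pmin, pmax, tau, formula = c("gap-at-1", "sum")) {
  formula <- match.arg(formula)
  if (formula == "gap-at-1") {
    (pmax - pmin) * exp(-1 / tau)
  } else {
    (pmax - pmin) + (pmax - pmin) * (1 - exp(-1 / tau))
  }
}

#' Evidence signed in favor of repeating
#'
#' Sums the noiseless per-stimulus log-likelihood ratios (in the hidden-state
#' frame) and signs them by the previous choice, so positive values are
#' consistent with repeating.
#'
#' @param llrs Per-stimulus state log-likelihood ratios of the trial.
#' @param prev_choice Previous choice, +1/-1; `NA` (first trial of a block)
#'   yields `NA`.
#' @return Signed evidence (log-odds) or `NA`.
#' @export
signed_evidence <- function(llrs, prev_choice) {
  if (is.null(prev_choice) || is.na(prev_choice)) return(NA_real_)
  prev_choice * sum(llrs)
}

#' Logistic repetition fit: choice-PSE and slope
#'
#' Maximum-likelihood logistic regression of P(repeat) on signed evidence at
#' the trial level. The point of subjective equivalence (choice-PSE) is the
#' evidence level at which repeating and switching are equally likely
#' (`-intercept/slope`); the slope is the sensitivity to evidence. Complete
#' separation is caught and refit with the Gaussian-prior MAP solver
#' ([map_logistic_regression()], prior SD 2) with a warning; single-class
#' data return a degenerate flagged fit instead of an error so group-level
#' pipelines can proceed.
#'
#' @param evidence Signed evidence per trial.
#' @param repeat_flags Logical, `TRUE` for repeats.
#' @return A `vol_psychfit` with parameters `pse`, `slope`, `intercept`.
#' @export
fit_repetition_logistic <- function(evidence, repeat_flags) {
  keep <- !is.na(evidence) & !is.na(repeat_flags)
  e <- evidence[keep]; y <- as.numeric(repeat_flags[keep])
  if (length(unique(y)) < 2) {
    return(new_psychfit("logistic", list(pse = NA_real_, slope = NA_real_,
                                         intercept = NA_real_),
                        loss = NA_real_, converged = FALSE, degenerate = TRUE,
                        note = "single-class data"))
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ e, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged || any(abs(stats::coef(fit)) > 1e3)) {
    warning("separation detected; using ridge-stabilized MAP fit",
            call. = FALSE)
    m <- map_logistic_regression(cbind(1, e), y, prior_sd = 2)
    beta <- m$coef
    loss <- m$neg_log_post
  } else {
    beta <- unname(stats::coef(fit))
    loss <- fit$deviance / 2
  }
  pse <- -beta[1] / beta[2]
  rng <- range(e)
  pad <- diff(rng) * 0.5
  degen <- !is.finite(pse) || pse < rng[1] - pad || pse > rng[2] + pad
  new_psychfit("logistic",
               list(pse = pse, slope = beta[2], intercept = beta[1]),
               loss = loss, converged = TRUE, degenerate = degen,
               note = if (degen) "PSE outside padded evidence range" else NULL)
}

#' Dual-sigmoid confidence fit and confidence-PSE
#'
#' Fits two independent logistic curves of P(high confidence) on signed
#' evidence, one on repeat trials and one on switch trials, and returns the
#' evidence level at which the two fitted curves intersect (confidence-PSE).
#' Because both curves share the logistic link, the crossing is the root of
#' the difference of their linear predictors; curves with (near-)equal slopes
#' never cross and yield a `NULL` PSE with a diagnostic, as do crossings far
#' outside the padded evidence range.
#'
#' @param evidence Signed evidence per trial.
#' @param confidence Character `"high"`/`"low"` or logical high-confidence.
#' @param repeat_flags Logical, `TRUE` for repeats.
#' @return A `vol_psychfit` with parameters `offset_repeat`, `slope_repeat`,
#'   `offset_switch`, `slope_switch` and `confidence_pse` (possibly `NULL`).
#' @export
fit_confidence_dual_sigmoid <- function(evidence, confidence, repeat_flags) {
  high <- if (is.character(confidence)) confidence == "high" else
    as.logical(confidence)
  keep <- !is.na(evidence) & !is.na(high) & !is.na(repeat_flags)
  e <- evidence[keep]; h <- as.numeric(high[keep]); rep_ <- repeat_flags[keep]
  if (sum(rep_) < 2 || sum(!rep_) < 2) {
    stop_config("need both repeat and switch trials with >= 2 cases each")
  }
  fit_one <- function(ii) {
    if (length(unique(h[ii])) < 2) {
      m <- map_logistic_regression(cbind(1, e[ii]), h[ii], prior_sd = 2)
      return(m$coef)
    }
    f <- suppressWarnings(stats::glm(h[ii] ~ e[ii],
                                     family = stats::binomial()))
    b <- unname(stats::coef(f))
    if (any(!is.finite(b)) || any(abs(b) > 1e3)) {
      b <- map_logistic_regression(cbind(1, e[ii]), h[ii], prior_sd = 2)$coef
    }
    b
  }
  br <- fit_one(rep_)
  bs <- fit_one(!rep_)
  params <- list(offset_repeat = br[1], slope_repeat = br[2],
                 offset_switch = bs[1], slope_switch = bs[2],
                 confidence_pse = NULL)
  note <- NULL
  dslope <- br[2] - bs[2]
  if (abs(dslope) < 1e-8) {
    note <- "curves parallel: no intersection"
  } else {
    pse <- (bs[1] - br[1]) / dslope
    rng <- range(e); pad <- diff(rng) * 0.5
    if (pse >= rng[1] - pad && pse <= rng[2] + pad) {
      params$confidence_pse <- pse
    } else {
      note <- "intersection outside padded evidence range"
    }
  }
  new_psychfit("dual-logistic", params, loss = NA_real_, converged = TRUE,
               degenerate = is.null(params$confidence_pse), note = note)
}

#' Choice-PSE conditioned on the previous trial
#'
#' Refits the repetition logistic on the subsample of trials whose previous
#' trial matches a label: previous repeat/switch, or previous high/low
#' confidence.
#'
#' @param responses Response data frame from [simulate_agent()].
#' @param condition_on One of `"prev-repeat"`, `"prev-switch"`,
#'   `"prev-high-conf"`, `"prev-low-conf"`.
#' @return A `vol_psychfit` (degenerate-flagged when the subsample lacks a
#'   class).
#' @export
conditioned_pse <- function(responses,
                            condition_on = c("prev-repeat", "prev-switch",
                                             "prev-high-conf", "prev-low-conf")) {
  condition_on <- match.arg(condition_on)
  n <- nrow(responses)
  first_of_block <- c(TRUE, responses$block[-1] != responses$block[-n])
  prev_switch <- c(NA, responses$is_switch[-n])
  prev_high <- c(NA, responses$confidence[-n] == "high")
  prev_switch[first_of_block] <- NA
  prev_high[first_of_block] <- NA
  sel <- switch(condition_on,
    "prev-repeat" = !is.na(prev_switch) & !prev_switch,
    "prev-switch" = !is.na(prev_switch) & prev_switch,
    "prev-high-conf" = !is.na(prev_high) & prev_high,
    "prev-low-conf" = !is.na(prev_high) & !prev_high)
  fit_repetition_logistic(responses$signed_evidence[sel],
                          !responses$is_switch[sel])
}
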