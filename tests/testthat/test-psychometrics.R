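# Curve construction and psychometric fits.

test_that("reversal curve equals a hand-rolled group-by oracle on a toy session", {
  # 20-trial single-block toy: episodes of 5, known reversals at 6, 11, 16
  s <- toy_session(block = rep(1, 20), condition = "C-",
                   hidden_state = rep(c(1, -1, 1, -1), each = 5),
                   seq_len = rep(2, 20), evidence_state = rep(0.5, 20))
  choice <- c(1, 1, 1, 1, 1, 1, -1, -1, -1, -1,
              -1, 1, 1, 1, 1, 1, -1, -1, -1, -1)
  r <- toy_responses(s, choice)
  crv <- build_reversal_curve(r, s, window = c(-2, 4))
  # oracle: for each reversal (trials 6, 11, 16) gather positions by hand
  oracle <- function(k) {
    tt <- c(6, 11, 16) + ifelse(k >= 1, k - 1, k)
    mean(r$correct[tt])
  }
  for (k in c(-2, -1, 1, 2, 3, 4)) {
    expect_equal(crv$p[crv$position == k], oracle(k), ignore_attr = TRUE)
  }
  # instantly adapting agent: all post-reversal fractions 1
  r_perfect <- toy_responses(s, s$hidden_state)
  crv_p <- build_reversal_curve(r_perfect, s, window = c(-2, 4))
  expect_true(all(crv_p$p[crv_p$position >= 1] == 1))
})

test_that("a random agent sits at chance across reversal positions", {
  s <- generate_session(task_config(n_blocks = 8,
                                    condition_order = rep("C-", 8)),
                        seed = 60)
  ch <- with_seed(61, sample(c(-1, 1), nrow(s), replace = TRUE))
  crv <- build_reversal_curve(toy_responses(s, ch), s)
  expect_true(all(abs(crv$p - 0.5) < 3 * sqrt(0.25 / crv$n_total)))
})

test_that("reversal curve errors without reversals", {
  s <- toy_session(block = rep(1, 10), condition = "C-",
                   hidden_state = rep(1, 10), seq_len = rep(2, 10),
                   evidence_state = rep(0.5, 10))
  expect_error(build_reversal_curve(toy_responses(s, rep(1, 10)), s),
               "no reversals")
})

test_that("reversal exponential fit recovers constructed parameters", {
  asym <- 0.85; tau <- 2
  pos <- c(-4:-1, 1:8)
  p_true <- ifelse(pos >= 1, asym - (2 * asym - 1) * exp(-pos / tau), asym)
  n <- 500
  k <- with_seed(62, stats::rbinom(length(pos), n, p_true))
  crv <- volinfer:::new_curve(
    data.frame(position = pos, n_total = n, n_event = k, p = k / n),
    axis = "trials-from-reversal", outcome = "correct")
  fit <- fit_reversal_exponential(crv)
  expect_false(fit$degenerate)
  expect_equal(fit$params$asymptote, asym, tolerance = 0.03)
  expect_equal(fit$params$tau, tau, tolerance = 0.3)

  # flat chance-level curve: asymptote ~ 0.5, flagged degenerate
  crv_flat <- volinfer:::new_curve(
    data.frame(position = pos, n_total = n, n_event = round(n / 2),
               p = 0.5),
    axis = "trials-from-reversal", outcome = "correct")
  fit_flat <- fit_reversal_exponential(crv_flat)
  expect_true(fit_flat$degenerate)
  expect_equal(fit_flat$params$asymptote, 0.5, tolerance = 0.02)

  # instant step: time constant collapses to its lower bound
  crv_step <- volinfer:::new_curve(
    data.frame(position = pos, n_total = n,
               n_event = ifelse(pos >= 1, n, 0),
               p = ifelse(pos >= 1, 1, 0)),
    axis = "trials-from-reversal", outcome = "correct")
  fit_step <- fit_reversal_exponential(crv_step)
  expect_lt(fit_step$params$tau, 0.3)
})

test_that("confidence-drop follows the adopted formula and its limits", {
  expect_equal(confidence_drop(0.4, 0.8, 3), 0.4 * exp(-1 / 3))
  expect_equal(confidence_drop(0.5, 0.5, 2), 0)
  expect_equal(confidence_drop(0.4, 0.8, 1e-9), 0)
  # alternative parenthesization is available and differs
  expect_equal(confidence_drop(0.4, 0.8, 3, formula = "sum"),
               0.4 + 0.4 * (1 - exp(-1 / 3)))
})

test_that("confidence reversal fit recovers an exponential learning curve", {
  pmin_ <- 0.45; pmax_ <- 0.8; tau <- 3
  pos <- c(-4:-1, 1:8)
  p_true <- ifelse(pos >= 1,
                   pmin_ + (pmax_ - pmin_) * (1 - exp(-pos / tau)), pmax_)
  n <- 600
  k <- with_seed(63, stats::rbinom(length(pos), n, p_true))
  crv <- volinfer:::new_curve(
    data.frame(position = pos, n_total = n, n_event = k, p = k / n),
    axis = "trials-from-reversal", outcome = "high_conf")
  fit <- fit_confidence_reversal(crv)
  expect_false(fit$degenerate)
  expect_equal(fit$params$pmin, pmin_, tolerance = 0.1)
  expect_equal(fit$params$pmax, pmax_, tolerance = 0.05)
  expect_equal(fit$params$drop,
               confidence_drop(fit$params$pmin, fit$params$pmax,
                               fit$params$tau))
})

test_that("signed evidence sums state LLRs with the repeat sign convention", {
  llrs <- c(0.4, -0.1, 0.3)
  expect_equal(signed_evidence(llrs, 1), 0.6)
  expect_equal(signed_evidence(llrs, -1), -0.6)
  expect_true(is.na(signed_evidence(llrs, NA)))
})

test_that("repetition logistic recovers a generating PSE and slope", {
  pse <- -1.5; slope <- 1
  e <- with_seed(64, stats::runif(5000, -4, 4))
  y <- with_seed(65, stats::rbinom(5000, 1, stats::plogis(slope * (e - pse))))
  fit <- fit_repetition_logistic(e, y == 1)
  expect_false(fit$degenerate)
  expect_equal(fit$params$pse, pse, tolerance = 0.15)
  expect_equal(fit$params$slope, slope, tolerance = 0.15)
  # symmetric data: PSE at zero
  y_sym <- with_seed(66, stats::rbinom(5000, 1, stats::plogis(2 * e)))
  expect_lt(abs(fit_repetition_logistic(e, y_sym == 1)$params$pse), 0.15)
  # mirrored evidence flips the PSE, sensitivity magnitude unchanged
  fit_m <- fit_repetition_logistic(-e, y == 1)
  expect_equal(fit_m$params$pse, -fit$params$pse, tolerance = 1e-6)
  expect_equal(abs(fit_m$params$slope), abs(fit$params$slope),
               tolerance = 1e-6)
})

test_that("repetition logistic flags degenerate data and survives separation", {
  expect_true(fit_repetition_logistic(c(1, 2, 3), c(TRUE, TRUE, TRUE))$degenerate)
  # complete separation: ridge-stabilized refit with a warning, finite slope
  e <- c(-(20:1) / 10, (1:20) / 10)
  y <- e > 0
  expect_warning(fit <- fit_repetition_logistic(e, y), "separation")
  expect_true(is.finite(fit$params$slope))
  expect_lt(abs(fit$params$pse), 0.5)
})

test_that("dual-sigmoid confidence fit finds a constructed crossing", {
  # repeat curve: plogis(1.0 * (e - (-2))); switch curve crosses it at -2
  e <- with_seed(67, stats::runif(6000, -5, 3))
  rep_ <- with_seed(68, stats::rbinom(6000, 1, 0.5)) == 1
  p_rep <- stats::plogis(1.0 * (e + 2))
  p_sw <- stats::plogis(-0.8 * (e + 2))
  p <- ifelse(rep_, p_rep, p_sw)
  high <- with_seed(69, stats::rbinom(6000, 1, p)) == 1
  fit <- fit_confidence_dual_sigmoid(e, high, rep_)
  expect_false(fit$degenerate)
  expect_equal(fit$params$confidence_pse, -2, tolerance = 0.25)
  # flat parallel curves at different levels never cross inside the padded
  # evidence range: degenerate flag with diagnostic, PSE undefined
  high_par <- with_seed(70, stats::rbinom(6000, 1,
                                          ifelse(rep_, 0.8, 0.3))) == 1
  fit_par <- fit_confidence_dual_sigmoid(e, high_par, rep_)
  expect_true(fit_par$degenerate)
  expect_null(fit_par$params$confidence_pse)
  expect_match(fit_par$note, "parallel|outside")
  # flat switch-confidence curve has near-zero slope
  high_flat <- ifelse(rep_, high, with_seed(71, stats::rbinom(6000, 1, 0.5)) == 1)
  fit_flat <- fit_confidence_dual_sigmoid(e, high_flat, rep_)
  expect_lt(abs(fit_flat$params$slope_switch), 0.1)
})

test_that("conditioning on a behavior-independent label leaves the PSE unchanged", {
  s <- generate_session(task_config(n_blocks = 8,
                                    condition_order = rep("C-", 8)),
                        seed = 72)
  a <- simulate_agent(s, quick_params(sigma_meta = 0), seed = 73)
  r <- a$responses
  # overwrite confidence with an independent coin: conditioning on the
  # previous confidence is then null conditioning
  r$confidence <- with_seed(74, sample(c("high", "low"), nrow(r),
                                       replace = TRUE))
  full <- fit_repetition_logistic(r$signed_evidence, !r$is_switch)
  f_hi <- conditioned_pse(r, "prev-high-conf")
  f_lo <- conditioned_pse(r, "prev-low-conf")
  expect_lt(abs(f_hi$params$pse - full$params$pse), 0.35)
  expect_lt(abs(f_lo$params$pse - full$params$pse), 0.35)
})

test_that("repetition curve builder matches a direct group-by computation", {
  e <- with_seed(75, stats::rnorm(500))
  y <- with_seed(76, stats::rbinom(500, 1, stats::plogis(e))) == 1
  crv <- build_repetition_curve(e, y, n_bins = 4)
  br <- attr(crv, "breaks")
  bin <- findInterval(e, br, all.inside = TRUE)
  for (b in 1:4) {
    expect_equal(crv$n_total[b], sum(bin == b))
    expect_equal(crv$p[b], mean(y[bin == b]))
  }
})
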