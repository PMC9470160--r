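# Change-of-mind metrics, repeated-measures ANOVA, MAP logistic regression,
# group-level tests.

test_that("change-of-mind metrics match hand enumeration on a worked toy", {
  s <- toy_session(block = rep(1, 10), condition = "C-",
                   hidden_state = rep(c(1, -1), each = 5),
                   seq_len = rep(2, 10), evidence_state = rep(0, 10))
  # choices: 1 1 -1 -1 1 1 1 -1 1 1
  # switches (trials 2-10): F T F T F F T T F -> rate 4/9
  # confirmed (switch trials 3, 5, 8, 9): trial3 next=-1 ==  -1 TRUE;
  # trial5 next=1 == 1 TRUE; trial8 next=1 != -1 FALSE; trial9 next=1 TRUE
  ch <- c(1, 1, -1, -1, 1, 1, 1, -1, 1, 1)
  conf <- c("high", "high", "low", "low", "high", "high", "high", "low",
            "low", "high")
  m <- change_of_mind_metrics(toy_responses(s, ch, conf))
  g <- function(metric, level) m$value[m$metric == metric & m$level == level]
  expect_equal(g("switch_rate", "all"), 4 / 9)
  expect_equal(g("confirmed_fraction", "all"), 3 / 4)
  # p(high | repeat): repeats are trials 2,4?,... repeat trials: 2,4? no:
  # switch flags above; repeats = trials {2,5,6,9?} -> 2,5,6,10 wait trial4
  # is a repeat of -1. repeats: 2 (high), 4 (low), 6 (high), 7 (high),
  # 10 (high) -> 4/5; switches: 3 (low), 5 (high), 8 (low), 9 (low) -> 1/4
  expect_equal(g("p_high", "repeat"), 4 / 5)
  expect_equal(g("p_high", "switch"), 1 / 4)
  # confirmed switches: 3, 5, 9 -> conf low, high, low -> p_high 1/3
  expect_equal(g("p_high_switch", "confirmed"), 1 / 3)
  expect_equal(g("p_high_switch", "aborted"), 0)
  # p(confirmed | high-conf switch): only trial 5 -> 1
  expect_equal(g("p_confirmed", "high"), 1)
  expect_equal(g("p_confirmed", "low"), 2 / 3)
})

test_that("degenerate choice streams give unit or zero switch rates", {
  s <- toy_session(block = rep(1, 8), condition = "C-",
                   hidden_state = rep(1, 8), seq_len = rep(2, 8),
                   evidence_state = rep(0, 8))
  alt <- change_of_mind_metrics(toy_responses(s, rep(c(1, -1), 4)))
  expect_equal(alt$value[alt$metric == "switch_rate"], 1)
  expect_equal(alt$value[alt$metric == "confirmed_fraction"], 0)
  expect_message(
    const <- change_of_mind_metrics(toy_responses(s, rep(1, 8))),
    "no switches")
  expect_equal(const$value[const$metric == "switch_rate"], 0)
})

test_that("rm ANOVA matches the sums-of-squares decomposition oracle", {
  # constructed 2x2 within-participant data, 8 participants
  d <- with_seed(80, {
    ids <- rep(1:8, each = 4)
    A <- rep(c("a1", "a2"), times = 16)
    B <- rep(rep(c("b1", "b2"), each = 2), 8)
    y <- 10 + 0.8 * (A == "a2") - 0.5 * (B == "b2") +
      0.6 * (A == "a2") * (B == "b2") +
      rep(stats::rnorm(8, 0, 1), each = 4) + stats::rnorm(32, 0, 0.5)
    data.frame(participant = ids, A = A, B = B, y = y)
  })
  res <- rm_anova_2x2(d, dv = "y", within = c("A", "B"))
  # oracle: classical within-subject SS decomposition via difference scores
  # (for a 2x2 design each F equals the squared one-sample t on the
  # corresponding per-participant contrast)
  m <- matrix(d$y, nrow = 8, byrow = TRUE)  # a1b1, a2b1, a1b2, a2b2
  effA <- (m[, 2] + m[, 4] - m[, 1] - m[, 3]) / 2
  effB <- (m[, 3] + m[, 4] - m[, 1] - m[, 2]) / 2
  effAB <- (m[, 1] + m[, 4] - m[, 2] - m[, 3]) / 2
  f_oracle <- function(eff) {
    n <- length(eff)
    (n * mean(eff)^2) / (sum((eff - mean(eff))^2) / (n - 1))
  }
  expect_equal(res$F[res$effect == "A"], f_oracle(effA), tolerance = 1e-8)
  expect_equal(res$F[res$effect == "B"], f_oracle(effB), tolerance = 1e-8)
  expect_equal(res$F[res$effect == "A:B"], f_oracle(effAB), tolerance = 1e-8)
  expect_true(all(res$df1 == 1) && all(res$df2 == 7))
})

test_that("additive effects leave the interaction contrast at zero", {
  d <- expand.grid(participant = 1:8, A = c("a1", "a2"), B = c("b1", "b2"))
  d$y <- 5 + (d$A == "a2") * 2 + (d$B == "b2") * 1 +
    with_seed(90, stats::rnorm(32, 0, 0.1))
  res <- rm_anova_2x2(d, dv = "y", within = c("A", "B"))
  # the per-participant interaction contrast is pure noise: its mean is
  # near zero while the main effects dominate by orders of magnitude
  m <- matrix(d$y[order(d$participant, d$B, d$A)], nrow = 8, byrow = TRUE)
  effAB <- (m[, 1] + m[, 4] - m[, 2] - m[, 3]) / 2
  expect_lt(abs(mean(effAB)), 0.2)
  expect_gt(res$F[res$effect == "A"], 100 * res$F[res$effect == "A:B"])
  # F statistics are invariant to adding per-participant constants
  d2 <- d; d2$y <- d$y + rep(c(10, -3, 0, 7, 1, 5, -2, 4), 4)
  res2 <- rm_anova_2x2(d2, dv = "y", within = c("A", "B"))
  expect_equal(res$F, res2$F, tolerance = 1e-8)
})

test_that("participants with incomplete cells are dropped (with jackknife option)", {
  d <- expand.grid(participant = 1:6, A = c("a1", "a2"), B = c("b1", "b2"))
  d$y <- with_seed(81, stats::rnorm(24) + (d$A == "a2"))
  d_miss <- d[!(d$participant == 6 & d$A == "a2" & d$B == "b2"), ]
  res <- rm_anova_2x2(d_miss, dv = "y", within = c("A", "B"))
  expect_equal(attr(res, "n_used"), 5)
  expect_equal(attr(res, "n_dropped"), 1)
  resj <- rm_anova_2x2(d, dv = "y", within = c("A", "B"), jackknife = TRUE)
  expect_true(all(is.finite(resj$F)))
  expect_error(rm_anova_2x2(d[d$participant == 1, ], dv = "y",
                            within = c("A", "B")), ">= 2 participants")
})

test_that("permuting condition labels within participant destroys a main effect", {
  base <- expand.grid(participant = 1:10, A = c("a1", "a2"),
                      B = c("b1", "b2"))
  base$y <- with_seed(82, stats::rnorm(40, 0, 1) + 2 * (base$A == "a2"))
  res <- rm_anova_2x2(base, dv = "y", within = c("A", "B"))
  expect_lt(res$p[res$effect == "A"], 0.01)
  pvals <- with_seed(83, vapply(1:200, function(i) {
    d <- base
    for (pid in 1:10) {
      ii <- d$participant == pid
      d$A[ii] <- sample(d$A[ii])
    }
    rm_anova_2x2(d, dv = "y", within = c("A", "B"))$p[1]
  }, numeric(1)))
  # under the within-participant permutation null p-values are ~uniform
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
  expect_lt(mean(pvals < 0.05), 0.12)
})

test_that("MAP logistic regression shrinks, converges and matches IRLS", {
  # independence: non-intercept coefficients near zero
  X <- cbind(1, with_seed(84, matrix(stats::rnorm(3000 * 2), ncol = 2)))
  y <- with_seed(85, stats::rbinom(3000, 1, 0.6))
  f <- map_logistic_regression(X, y)
  expect_true(f$converged)
  expect_true(all(abs(f$coef[2:3]) < 0.1))
  # perfect separation stays finite (the prior's purpose)
  Xs <- cbind(1, c(-(10:1), 1:10))
  ys <- as.numeric(Xs[, 2] > 0)
  fs <- map_logistic_regression(Xs, ys, prior_sd = 2)
  expect_true(fs$converged)
  expect_true(all(is.finite(fs$coef)) && all(abs(fs$coef) < 20))
  # objective decreases monotonically across iterations
  expect_true(all(diff(fs$trace) <= 1e-12))
  # well-conditioned data: MAP within 5% of the unpenalized IRLS estimate
  Xb <- cbind(1, with_seed(86, stats::rnorm(10000)))
  yb <- with_seed(87, stats::rbinom(10000, 1,
                                    stats::plogis(0.5 + 1.2 * Xb[, 2])))
  fb <- map_logistic_regression(Xb, yb, prior_sd = 2)
  g <- stats::glm(yb ~ Xb[, 2], family = stats::binomial())
  expect_true(all(abs(fb$coef - unname(stats::coef(g))) /
                    abs(unname(stats::coef(g))) < 0.05))
})

test_that("group-level tests match closed forms and handle degenerate samples", {
  x <- c(2.1, 1.4, 0.3, -0.5, 1.9, 2.4, 0.8, 1.1, -0.2, 1.6)
  res <- group_level_tests(x)
  t_manual <- mean(x) / (stats::sd(x) / sqrt(10))
  expect_equal(res$t, t_manual, tolerance = 1e-10)
  expect_equal(res$p_t, 2 * stats::pt(-abs(t_manual), 9), tolerance = 1e-10)
  w <- suppressWarnings(stats::wilcox.test(x, exact = FALSE))
  expect_equal(res$p_wilcoxon, w$p.value, tolerance = 1e-10)
  # identical paired samples: no evidence
  same <- group_level_tests(rep(1, 5), rep(1, 5))
  expect_true(is.na(same$t))
  expect_equal(same$p_t, 1)
  # constant nonzero shift with zero variance: p -> 0
  shift <- group_level_tests(2:11, 1:10)
  expect_equal(shift$p_t, 0)
  expect_true(is.infinite(shift$t) && shift$t > 0)
})

test_that("confidence regression design uses effects coding and standardized evidence", {
  s <- generate_session(tiny_cfg(), seed = 88)
  a <- simulate_agent(s, quick_params(), seed = 89)
  dz <- confidence_regression_design(a$responses)
  expect_equal(colnames(dz$X),
               c("intercept", "type", "condition", "interaction", "evidence"))
  expect_true(all(dz$X[, "type"] %in% c(-1, 1)))
  expect_true(all(dz$X[, "condition"] %in% c(-1, 1)))
  expect_equal(dz$X[, "interaction"], dz$X[, "type"] * dz$X[, "condition"])
  expect_equal(mean(dz$X[, "evidence"]), 0, tolerance = 1e-10)
  expect_equal(stats::sd(dz$X[, "evidence"]), 1, tolerance = 1e-10)
  expect_true(all(dz$y %in% 0:1))
})
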