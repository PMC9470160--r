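# Normative observer: evidence, belief propagation, choice, confidence.

test_that("stimulus LLR has the analytic von Mises-ratio form", {
  cfg <- task_config()
  # equidistant orientation between the two means
  expect_equal(stimulus_llr(cfg$mu + pi / 4, cfg), 0, tolerance = 1e-12)
  # orthogonal-means antisymmetry
  th <- seq(0, pi, length.out = 17)
  expect_equal(stimulus_llr((th + pi / 2) %% pi, cfg), -stimulus_llr(th, cfg))
  # density-ratio oracle: direct evaluation of the two von Mises log-densities
  mus <- c(cfg$mu, cfg$mu + cfg$mu_gap)
  oracle <- function(t) {
    (cfg$kappa * cos(2 * t - 2 * mus[1])) - (cfg$kappa * cos(2 * t - 2 * mus[2]))
  }
  expect_equal(stimulus_llr(th, cfg), oracle(th))
  # reduces to 2*kappa*cos(2(theta - mu)) for orthogonal means
  expect_equal(stimulus_llr(th, cfg), 2 * cfg$kappa * cos(2 * (th - cfg$mu)))
})

test_that("belief propagation is odd, bounded, monotone and memoryless at h = 1/2", {
  L <- seq(-30, 30, length.out = 121)
  for (h in c(0.01, 0.1, 0.3, 0.49)) {
    y <- propagate_prior(L, h)
    expect_equal(propagate_prior(0, h), 0)
    expect_equal(y, -propagate_prior(-L, h))
    expect_true(all(abs(y) <= log((1 - h) / h) + 1e-12))
    expect_true(all(diff(y) > 0))
  }
  expect_equal(propagate_prior(L, 0.5), rep(0, length(L)), tolerance = 1e-12)
  # h -> 0 limit: the belief passes through unchanged
  expect_equal(propagate_prior(3, 1e-9), 3, tolerance = 1e-6)
  expect_error(propagate_prior(1, 0), "hazard")
  expect_error(propagate_prior(1, 1), "hazard")
})

test_that("belief propagation matches direct high-precision evaluation", {
  grid <- expand.grid(L = seq(-25, 25, by = 0.5),
                      h = c(1e-5, 0.01, 0.1, 0.25, 0.4, 0.49, 0.6, 0.9))
  direct <- with(grid, L + log((1 - h) / h + exp(-L)) - log((1 - h) / h + exp(L)))
  expect_lt(max(abs(propagate_prior(grid$L, grid$h) - direct)), 1e-10)
})

test_that("accumulated noise variance scales with sequence length", {
  llrs4 <- rep(0, 4); llrs8 <- rep(0, 8)
  reps <- 4000
  v <- function(llrs, s) {
    with_seed(20, stats::var(replicate(reps, accumulate_sequence(0, llrs, s))))
  }
  expect_equal(v(llrs4, 1.5), 4 * 1.5^2, tolerance = 0.12)
  expect_equal(v(llrs8, 1.5), 8 * 1.5^2, tolerance = 0.12)
  # noiseless limit is the plain sum, optionally after hazard propagation
  expect_identical(accumulate_sequence(2, c(0.5, -0.2), 0), 2.3)
  expect_equal(accumulate_sequence(2, c(0.5, -0.2), 0, hazard = 0.2),
               propagate_prior(2, 0.2) + 0.3)
  # zero-evidence distribution is centred on zero
  m <- with_seed(21, mean(replicate(2000, accumulate_sequence(0, rep(0, 4), 1))))
  expect_lt(abs(m), 0.1)
})

test_that("choice is the belief sign with ties broken toward repetition", {
  expect_identical(decide(0.3), 1)
  expect_identical(decide(-1e-9), -1)
  expect_identical(decide(0, prev_choice = -1), -1)
  expect_identical(decide(0, prev_choice = 1), 1)
  expect_identical(decide(0), 1)
})

test_that("confidence readout matches the closed-form Gaussian CDF", {
  p <- quick_params(sigma_meta = 0.8, conf_gain = 1.6, conf_threshold = 1.2)
  for (L in c(0.2, 1, 2.5)) {
    for (sw in c(TRUE, FALSE)) {
      emp <- with_seed(22, mean(
        rate_confidence(rep(L, 6000), rep(sw, 6000), p) == "high"))
      gain <- if (sw) p$conf_gain else 1
      theo <- stats::pnorm((gain * L - p$conf_threshold) / p$sigma_meta)
      expect_lt(abs(emp - theo), 3 * sqrt(theo * (1 - theo) / 6000) + 0.005)
    }
  }
  # noiseless threshold rule
  p0 <- quick_params(sigma_meta = 0, conf_gain = 1, conf_threshold = 1)
  expect_identical(rate_confidence(1.5, FALSE, p0), "high")
  expect_identical(rate_confidence(0.5, FALSE, p0), "low")
  # saturating threshold at the lower bound
  psat <- quick_params(sigma_meta = 0.5, conf_threshold = -10)
  expect_true(all(rate_confidence(rep(0.1, 200), rep(FALSE, 200), psat) ==
                    "high"))
})

test_that("high-confidence fraction is non-increasing in the threshold", {
  s <- generate_session(tiny_cfg(), seed = 23)
  fracs <- vapply(c(-2, 0, 1, 2, 4), function(thr) {
    a <- simulate_agent(s, quick_params(sigma_meta = 0, conf_gain = 1,
                                        conf_threshold = thr), seed = 24)
    mean(a$responses$confidence == "high")
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("agent simulation is deterministic, resets at blocks, flags switches", {
  s <- generate_session(tiny_cfg(), seed = 25)
  a1 <- simulate_agent(s, quick_params(), seed = 26)
  a2 <- simulate_agent(s, quick_params(), seed = 26)
  expect_identical(a1, a2)
  r <- a1$responses
  first_of_block <- c(TRUE, s$block[-1] != s$block[-nrow(s)])
  expect_true(all(is.na(r$is_switch[first_of_block])))
  expect_true(all(!is.na(r$is_switch[!first_of_block])))
  expect_true(all(is.na(r$is_confirmed[!r$is_switch %in% TRUE])))
  expect_true(all(r$choice %in% c(-1, 1)))
  # belief trace is internally consistent: L_post = propagate(L_prior stream)
  expect_equal(a1$trace$L_post, a1$trace$L_prior + a1$trace$evidence_noisy)
  # empty session
  empty <- simulate_agent(s[0, ], quick_params(), seed = 1)
  expect_equal(nrow(empty$responses), 0)
})

test_that("category relabeling flips beliefs and choices exactly", {
  s <- generate_session(tiny_cfg(), seed = 27)
  sm <- s
  sm$hidden_state <- -sm$hidden_state
  sm$evidence_state <- -sm$evidence_state
  p <- quick_params(sigma_inf = 0, sigma_meta = 0)
  a <- simulate_agent(s, p, seed = 28)
  am <- simulate_agent(sm, p, seed = 28)
  expect_equal(am$trace$L_post, -a$trace$L_post)
  expect_equal(am$responses$choice, -a$responses$choice)
  expect_equal(am$responses$correct, a$responses$correct)
})

test_that("noiseless hazard-matched observer beats a noisy one on accuracy", {
  cfg <- tiny_cfg()
  s <- generate_session(cfg, seed = 29)
  h_gen <- 1 - exp(-1 / cfg$episode_scale)
  acc0 <- mean(simulate_agent(s, quick_params(hazard = h_gen, sigma_inf = 0),
                              seed = 30)$responses$correct)
  acc5 <- mean(simulate_agent(s, quick_params(hazard = h_gen, sigma_inf = 5),
                              seed = 30)$responses$correct)
  expect_gt(acc0, acc5)
})

test_that("a patient observer on a reversal-free session approaches certainty", {
  cfg <- task_config(n_blocks = 1, trials_per_block = 20, episode_min = 20,
                     episode_max = 20)
  accs <- vapply(1:5, function(i) {
    s <- generate_session(cfg, seed = 40 + i)
    a <- simulate_agent(s, quick_params(hazard = 1e-6, sigma_inf = 0),
                        seed = 50 + i)
    mean(a$responses$correct[11:20])
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
})

test_that("the vectorized simulator agrees with the per-trial agent", {
  s <- generate_session(tiny_cfg(), seed = 31)
  p <- quick_params(sigma_inf = 0, sigma_meta = 0)
  a <- simulate_agent(s, p, seed = 32)
  sim <- volinfer:::simulate_agents_matrix(s, p, n_sims = 3, seed = 33)
  # noiseless: every simulation deterministic given the tie-break draws;
  # choices can only differ through block-initial tie-breaks (measure zero)
  expect_equal(sim$choice[, 1], a$responses$choice)
  expect_equal(as.logical(sim$correct[, 1]), a$responses$correct)
  expect_equal(sim$high[, 1] == 1, a$responses$confidence == "high")
})
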