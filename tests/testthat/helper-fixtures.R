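# Shared fixtures: small configurations, quick parameter sets, and a
# hand-buildable toy session constructor.

tiny_cfg <- function(...) {
  task_config(n_blocks = 2, trials_per_block = 36, ...)
}

quick_params <- function(hazard = 0.15, sigma_inf = 1, conf_threshold = 1.5,
                         sigma_meta = 0.5, conf_gain = 1) {
  model_params(hazard = hazard, sigma_inf = sigma_inf,
               conf_threshold = conf_threshold, sigma_meta = sigma_meta,
               conf_gain = conf_gain)
}

# build a vol_session by hand from explicit per-trial fields (orientations
# default to empty; evidence given directly)
toy_session <- function(block, condition, hidden_state, seq_len,
                        evidence_state, cfg = task_config()) {
  n <- length(hidden_state)
  episode <- integer(n); pos <- integer(n)
  e <- 1L; p0 <- 0L
  for (t in seq_len(n)) {
    first <- t == 1 || block[t] != block[t - 1]
    if (first) { e <- 1L; p0 <- 0L }
    else if (hidden_state[t] != hidden_state[t - 1]) { e <- e + 1L; p0 <- 0L }
    p0 <- p0 + 1L
    episode[t] <- e; pos[t] <- p0
  }
  s <- data.frame(trial = seq_len(n), block = block, condition = condition,
                  episode = episode, pos_in_episode = pos,
                  is_reversal = pos == 1L & episode > 1L,
                  hidden_state = hidden_state, seq_len = seq_len,
                  evidence_state = evidence_state,
                  stringsAsFactors = FALSE)
  s$orientations <- I(replicate(n, numeric(0), simplify = FALSE))
  attr(s, "config") <- cfg
  attr(s, "seed") <- 0L
  class(s) <- c("vol_session", "data.frame")
  s
}

# responses data frame from explicit choices (confidence optional)
toy_responses <- function(session, choice, confidence = NULL) {
  n <- nrow(session)
  first_of_block <- c(TRUE, session$block[-1] != session$block[-n])
  prev_choice <- c(NA, choice[-n]); prev_choice[first_of_block] <- NA
  is_switch <- ifelse(first_of_block, NA, choice != prev_choice)
  nxt <- c(choice[-1], NA); nxt[c(first_of_block[-1], TRUE)] <- NA
  data.frame(
    trial = session$trial, block = session$block,
    condition = session$condition, choice = choice,
    confidence = confidence %||% rep("high", n),
    is_switch = is_switch,
    is_confirmed = ifelse(!is.na(is_switch) & is_switch & !is.na(nxt),
                          nxt == choice, NA),
    correct = choice == session$hidden_state,
    prev_choice = prev_choice,
    signed_evidence = prev_choice * session$evidence_state,
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# realized episode lengths of a session, per block
session_episode_lengths <- function(session) {
  unlist(lapply(split(session, session$block), function(b) {
    as.vector(table(b$episode))
  }), use.names = FALSE)
}
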