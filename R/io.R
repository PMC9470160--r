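# Tidy CSV/JSON serialization and the reader for deposited behavioral files.

#' Write / read a session as tidy CSV plus a JSON sidecar
#'
#' One row per trial; the canonical orientation list is serialized as a
#' semicolon-delimited field. The task configuration and seed go to a JSON
#' sidecar next to the CSV (same path with extension `.json`).
#'
#' @param session A `vol_session`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  df <- as.data.frame(session)
  df$orientations <- vapply(session$orientations, function(th) {
    paste(format(th, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = ";")
  }, character(1))
  utils::write.csv(df, path, row.names = FALSE)
  cfg <- session_config(session)
  sidecar <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(config = unclass(cfg), seed = attr(session, "seed"),
         schema_version = 1L),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  cfgl <- meta$config
  cfg <- task_config(
    n_blocks = cfgl$n_blocks, trials_per_block = cfgl$trials_per_block,
    episode_min = cfgl$episode_min, episode_max = cfgl$episode_max,
    episode_scale = cfgl$episode_scale, seq_lengths = cfgl$seq_lengths,
    kappa = cfgl$kappa, mu = cfgl$mu, mu_gap = cfgl$mu_gap,
    condition_order = cfgl$condition_order, rule_regime = cfgl$rule_regime,
    isi_ms = cfgl$isi_ms, isi_jitter_ms = cfgl$isi_jitter_ms)
  df$orientations <- I(lapply(strsplit(df$orientations, ";", fixed = TRUE),
                              as.numeric))
  attr(df, "config") <- cfg
  attr(df, "seed") <- meta$seed
  class(df) <- c("vol_session", "data.frame")
  df
}

#' Write / read responses as tidy CSV
#'
#' @param responses Response data frame.
#' @param path CSV path.
#' @return `path` (writer) or the data frame (reader).
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("is_switch", "is_confirmed", "correct")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' Write / read model parameters as JSON
#'
#' @param params A [model_params()] or per-condition list of them.
#' @param path JSON path.
#' @return `path` (writer) or the parameters (reader).
#' @export
write_params <- function(params, path) {
  payload <- if (inherits(params, "vol_model_params")) {
    list(shared = unclass(params))
  } else {
    lapply(params, unclass)
  }
  jsonlite::write_json(list(schema_version = 1L, params = payload), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pl <- obj$params
  if (identical(names(pl), "shared")) {
    return(do.call(model_params, as.list(pl$shared)))
  }
  out <- lapply(pl, function(x) do.call(model_params, as.list(x)))
  out
}

#' Read a deposited-format per-trial behavioral CSV
#'
#' Ingests per-trial behavioral files (trial index, condition, stimulus
#' orientations, response, confidence) into the same session/response
#' schema the simulator produces. The column mapping is declared in a YAML
#' file (or list) so different deposited layouts can be adapted without
#' code changes.
#'
#' The mapping must provide entries `trial`, `block`, `condition`,
#' `hidden_state`, `orientations`, `response`, `confidence`, each naming a
#' column of the CSV; optional entries: `condition_levels` (named list
#' mapping the file's condition codes to `"C-"`/`"C+"`),
#' `confidence_levels` (codes for `high`/`low`), `orientation_sep`
#' (default `";"`), and `task` (a list of [task_config()] arguments).
#'
#' Orientations in the file are the *realized* stimuli; they are converted
#' to canonical (category +1) frame using the recorded hidden state and, in
#' the controllable condition, the previous response, so downstream
#' analyses see the same `evidence_state` convention as synthetic sessions.
#'
#' @param path CSV path.
#' @param mapping YAML path or list as described above.
#' @return A list with elements `session` (a `vol_session`) and `responses`.
#' @export
read_behavior_csv <- function(path, mapping) {
  if (is.character(mapping)) mapping <- yaml::read_yaml(mapping)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "block", "condition", "hidden_state", "orientations",
            "response", "confidence")
  for (k in need) {
    if (is.null(mapping[[k]]) || !mapping[[k]] %in% names(df)) {
      stop_config("mapping entry '", k, "' missing or not a column of the CSV")
    }
  }
  cfg <- do.call(task_config, mapping$task %||% list())
  sep <- mapping$orientation_sep %||% ";"
  cond_raw <- as.character(df[[mapping$condition]])
  if (!is.null(mapping$condition_levels)) {
    cond <- unlist(mapping$condition_levels)[cond_raw]
  } else {
    cond <- cond_raw
  }
  if (!all(cond %in% c("C-", "C+"))) {
    stop_config("conditions must map to 'C-'/'C+'")
  }
  conf_raw <- as.character(df[[mapping$confidence]])
  if (!is.null(mapping$confidence_levels)) {
    lv <- mapping$confidence_levels
    conf <- ifelse(conf_raw == as.character(lv$high), "high", "low")
  } else {
    conf <- conf_raw
  }
  ori <- lapply(strsplit(as.character(df[[mapping$orientations]]), sep,
                         fixed = TRUE), as.numeric)
  state <- as.numeric(df[[mapping$hidden_state]])
  block <- as.integer(df[[mapping$block]])
  choice <- as.numeric(df[[mapping$response]])
  n <- nrow(df)
  ord <- order(block, as.integer(df[[mapping$trial]]))
  if (!identical(ord, seq_len(n))) {
    df <- df[ord, ]; ori <- ori[ord]; state <- state[ord]
    block <- block[ord]; choice <- choice[ord]; cond <- cond[ord]
    conf <- conf[ord]
  }
  first_of_block <- c(TRUE, block[-1] != block[-n])
  prev_choice <- c(NA, choice[-n]); prev_choice[first_of_block] <- NA
  # realized category: state itself in C-, state * previous response in C+
  category <- ifelse(cond == "C-", state, state * prev_choice)
  canonical <- mapply(function(th, cat) {
    if (is.na(cat) || cat == 1) th %% pi else (th - cfg$mu_gap) %% pi
  }, ori, category, SIMPLIFY = FALSE)
  llr_sum <- vapply(canonical, function(th) sum(stimulus_llr(th, cfg)),
                    numeric(1))
  # episodes from state reversals within block
  episode <- integer(n); pos <- integer(n)
  e <- 1L; p0 <- 0L
  for (t in seq_len(n)) {
    if (first_of_block[t]) { e <- 1L; p0 <- 0L }
    else if (state[t] != state[t - 1]) { e <- e + 1L; p0 <- 0L }
    p0 <- p0 + 1L
    episode[t] <- e; pos[t] <- p0
  }
  session <- data.frame(
    trial = seq_len(n), block = block, condition = cond, episode = episode,
    pos_in_episode = pos, is_reversal = pos == 1L & episode > 1L,
    hidden_state = state, seq_len = lengths(ori),
    evidence_state = state * llr_sum, stringsAsFactors = FALSE)
  session$orientations <- I(canonical)
  attr(session, "config") <- cfg
  attr(session, "seed") <- NA_integer_
  class(session) <- c("vol_session", "data.frame")
  is_switch <- ifelse(first_of_block, NA, choice != prev_choice)
  nxt <- c(choice[-1], NA); nxt[c(first_of_block[-1], TRUE)] <- NA
  responses <- data.frame(
    trial = seq_len(n), block = block, condition = cond, choice = choice,
    confidence = conf, is_switch = is_switch,
    is_confirmed = ifelse(!is.na(is_switch) & is_switch & !is.na(nxt),
                          nxt == choice, NA),
    correct = choice == state, prev_choice = prev_choice,
    signed_evidence = prev_choice * session$evidence_state,
    stringsAsFactors = FALSE)
  list(session = session, responses = responses)
}
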