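# End-to-end orchestration over a synthetic cohort (or ingested data).

#' Default end-to-end configuration
#'
#' A cohort of simulated participants whose observer parameters are drawn
#' around condition-level means chosen to emulate the qualitative group
#' effects of interest: a lower perceived hazard rate and a higher
#' confidence threshold in the controllable condition, equal inference
#' noise, metacognitive noise and switch confidence gain across conditions.
#'
#' @param n_participants Cohort size (default 12).
#' @param cfg Task configuration.
#' @param param_means Named list of per-condition [model_params()].
#' @param param_jitter_sd Between-participant SD applied to each parameter
#'   (truncated at the fitting bounds).
#' @param stages Character vector of stages to run, a subset of
#'   `c("psychometrics", "stats", "fit", "validate", "latents", "recover")`;
#'   simulation always runs. Fitting and recovery are compute-heavy and off
#'   by default.
#' @return A configuration list for [run_end_to_end()].
#' @export
pipeline_config <- function(n_participants = 12,
                            cfg = task_config(),
                            param_means = list(
                              "C-" = model_params(hazard = 0.20,
                                                  sigma_inf = 1,
                                                  conf_threshold = 1.2,
                                                  sigma_meta = 0.5,
                                                  conf_gain = 1),
                              "C+" = model_params(hazard = 0.10,
                                                  sigma_inf = 1,
                                                  conf_threshold = 1.8,
                                                  sigma_meta = 0.5,
                                                  conf_gain = 1)),
                            param_jitter_sd = c(hazard = 0.03,
                                                sigma_inf = 0.2,
                                                conf_threshold = 0.3,
                                                sigma_meta = 0.1,
                                                conf_gain = 0.1),
                            stages = c("psychometrics", "stats", "latents")) {
  if (n_participants < 1) stop_config("empty cohort")
  list(n_participants = n_participants, cfg = cfg,
       param_means = param_means, param_jitter_sd = param_jitter_sd,
       stages = stages)
}

jitter_params <- function(base, sd_vec) {
  b <- param_bounds()
  v <- param_vector(base)
  v <- v + stats::rnorm(length(v), 0, sd_vec[names(v)])
  v <- clamp(v, b$lower + 1e-9, b$upper - 1e-9)
  do.call(model_params, as.list(v))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates a cohort of sessions and agents, then runs the requested
#' stages: per-participant psychometrics (reversal fits, repetition
#' logistic, dual-sigmoid confidence, conditioned PSEs), change-of-mind
#' statistics with group-level ANOVAs, model fitting and validation,
#' particle-filtered latents with their ANOVA, and parameter recovery.
#' Every stage derives its own child seed from the global seed, so each is
#' independently reproducible; outputs (CSV/JSON) and a run manifest are
#' written under `out_dir` when given.
#'
#' @param config A [pipeline_config()].
#' @param seed Global seed.
#' @param out_dir Optional output directory.
#' @return A list of class `vol_run`: `manifest`, `participants` (per
#'   participant: params, psychometric fits, metrics), `group` (group-level
#'   tables), plus stage outputs.
#' @export
run_end_to_end <- function(config = pipeline_config(), seed = 1,
                           out_dir = NULL) {
  stages <- config$stages
  if (config$n_participants < 1) stop_config("empty cohort")
  manifest <- list(seed = seed, n_participants = config$n_participants,
                   stages = stages, started = format(Sys.time()),
                   completed_stages = character(0))
  participants <- vector("list", config$n_participants)
  for (i in seq_len(config$n_participants)) {
    s_par <- child_seed(seed, i * 10L)
    params <- with_seed(s_par, list(
      "C-" = jitter_params(config$param_means[["C-"]],
                           config$param_jitter_sd),
      "C+" = jitter_params(config$param_means[["C+"]],
                           config$param_jitter_sd)))
    sess <- generate_session(config$cfg, seed = child_seed(seed, i * 10L + 1L))
    agent <- simulate_agent(sess, params,
                            seed = child_seed(seed, i * 10L + 2L))
    participants[[i]] <- list(id = i, params = params, session = sess,
                              responses = agent$responses)
  }
  manifest$completed_stages <- c(manifest$completed_stages, "simulate")

  run <- list(manifest = manifest, participants = participants,
              group = list())

  if ("psychometrics" %in% stages) {
    psych <- lapply(participants, function(pp) {
      out <- list()
      for (cond in c("C-", "C+")) {
        keep <- pp$session$condition == cond
        sess_c <- subset_session(pp$session, keep)
        resp_c <- pp$responses[keep, ]
        crv <- build_reversal_curve(resp_c, sess_c, outcome = "correct")
        ccv <- build_reversal_curve(resp_c, sess_c, outcome = "high_conf")
        out[[cond]] <- list(
          reversal = fit_reversal_exponential(crv),
          confidence_reversal = fit_confidence_reversal(ccv),
          repetition = fit_repetition_logistic(resp_c$signed_evidence,
                                               !resp_c$is_switch),
          confidence_dual = tryCatch(
            fit_confidence_dual_sigmoid(resp_c$signed_evidence,
                                        resp_c$confidence,
                                        !resp_c$is_switch),
            error = function(e) NULL),
          pse_after_repeat = conditioned_pse(resp_c, "prev-repeat"),
          pse_after_switch = conditioned_pse(resp_c, "prev-switch"),
          pse_after_high = conditioned_pse(resp_c, "prev-high-conf"),
          pse_after_low = conditioned_pse(resp_c, "prev-low-conf"))
      }
      out
    })
    run$psychometrics <- psych
    pse <- sapply(psych, function(x)
      c(`C-` = x[["C-"]]$repetition$params$pse,
        `C+` = x[["C+"]]$repetition$params$pse))
    run$group$choice_pse <- data.frame(
      participant = seq_len(ncol(pse)), pse_cminus = pse[1, ],
      pse_cplus = pse[2, ])
    run$group$choice_pse_test <- group_level_tests(pse[2, ], pse[1, ])
    run$manifest$completed_stages <-
      c(run$manifest$completed_stages, "psychometrics")
  }

  if ("stats" %in% stages) {
    cells <- do.call(rbind, lapply(participants, function(pp) {
      m <- change_of_mind_metrics(pp$responses)
      m$participant <- pp$id
      m
    }))
    run$group$cells <- cells
    conf_cells <- cells[cells$metric == "p_high", ]
    run$group$anova_confidence <- tryCatch(
      rm_anova_2x2(data.frame(participant = conf_cells$participant,
                              response_type = conf_cells$level,
                              condition = conf_cells$condition,
                              y = conf_cells$value),
                   dv = "y", within = c("response_type", "condition")),
      error = function(e) NULL)
    sw <- cells[cells$metric == "switch_rate", ]
    run$group$switch_rate <- stats::aggregate(value ~ condition, sw, mean)
    cf <- cells[cells$metric == "confirmed_fraction", ]
    run$group$confirmed_fraction <- stats::aggregate(value ~ condition, cf,
                                                     mean)
    run$manifest$completed_stages <-
      c(run$manifest$completed_stages, "stats")
  }

  if ("fit" %in% stages) {
    run$fits <- lapply(seq_along(participants), function(i) {
      pp <- participants[[i]]
      fit_model(pp$session, pp$responses, fit_spec(),
                seed = child_seed(seed, 5000L + i))
    })
    run$manifest$completed_stages <- c(run$manifest$completed_stages, "fit")
  }

  if ("validate" %in% stages && !is.null(run$fits)) {
    run$validation <- lapply(seq_along(participants), function(i) {
      pp <- participants[[i]]
      prm <- lapply(run$fits[[i]], `[[`, "params")
      validate_model(prm, pp$session, n_sims = 50,
                     seed = child_seed(seed, 6000L + i))
    })
    run$manifest$completed_stages <-
      c(run$manifest$completed_stages, "validate")
  }

  if ("latents" %in% stages) {
    lat <- lapply(seq_along(participants), function(i) {
      pp <- participants[[i]]
      pf <- particle_filter(pp$session, pp$responses, pp$params,
                            n_particles = 500,
                            seed = child_seed(seed, 7000L + i))
      cbind(participant = i, summarize_latents(pf, pp$responses))
    })
    run$latent_cells <- do.call(rbind, lat)
    run$group$anova_prior_belief <- tryCatch(
      rm_anova_2x2(data.frame(participant = run$latent_cells$participant,
                              response_type = run$latent_cells$response_type,
                              condition = run$latent_cells$condition,
                              y = run$latent_cells$prior_belief),
                   dv = "y", within = c("response_type", "condition")),
      error = function(e) NULL)
    run$manifest$completed_stages <-
      c(run$manifest$completed_stages, "latents")
  }

  if ("recover" %in% stages) {
    run$recovery <- parameter_recovery(seed = child_seed(seed, 9000L))
    run$manifest$completed_stages <-
      c(run$manifest$completed_stages, "recover")
  }

  run$manifest$finished <- format(Sys.time())
  class(run) <- "vol_run"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (pp in participants) {
      write_session(pp$session,
                    file.path(out_dir, sprintf("session_%02d.csv", pp$id)))
      write_responses(pp$responses,
                      file.path(out_dir, sprintf("responses_%02d.csv", pp$id)))
      write_params(pp$params,
                   file.path(out_dir, sprintf("params_%02d.json", pp$id)))
    }
    if (!is.null(run$group$cells)) {
      utils::write.csv(run$group$cells,
                       file.path(out_dir, "cell_table.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  run
}

#' @export
print.vol_run <- function(x, ...) {
  cat(sprintf("<vol_run> %d participants | stages: %s\n",
              x$manifest$n_participants,
              paste(x$manifest$completed_stages, collapse = ", ")))
  if (!is.null(x$group$switch_rate)) {
    cat("mean switch rate by condition:\n"); print(x$group$switch_rate)
  }
  if (!is.null(x$group$choice_pse_test)) {
    cat("choice-PSE C+ minus C- group test:\n")
    print(x$group$choice_pse_test)
  }
  invisible(x)
}

#' Plot a curve set
#'
#' Simple ggplot2 rendering of a `vol_curve` (reversal- or evidence-axis).
#'
#' @param curve A `vol_curve`.
#' @return A ggplot object.
#' @export
plot_curve <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_config("ggplot2 is required for plotting")
  }
  xcol <- if (attr(curve, "axis") == "trials-from-reversal") "position"
  else "center"
  ggplot2::ggplot(as.data.frame(curve),
                  ggplot2::aes(x = .data[[xcol]], y = .data[["p"]])) +
    ggplot2::geom_point(ggplot2::aes(size = .data[["n_total"]]),
                        show.legend = FALSE) +
    ggplot2::geom_line() +
    ggplot2::labs(x = attr(curve, "axis"),
                  y = paste("P(", attr(curve, "outcome"), ")"),
                  title = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
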