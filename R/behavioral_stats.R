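# Change-of-mind statistics: switch/confirmation metrics, repeated-measures
# ANOVAs, MAP-regularized logistic regression, group-level tests.

#' Change-of-mind metrics for one response set
#'
#' Per condition: the switch rate, the fraction of switches confirmed on the
#' next trial, the fraction of high-confidence responses split by response
#' type (repeat/switch) and by switch outcome (confirmed/aborted).
#'
#' @param responses Response data frame from [simulate_agent()] or the
#'   ingested equivalent.
#' @return A data frame (class `vol_cell_table`) with columns `condition`,
#'   `metric`, `level`, `value`, `n`. Conditions without switches get `NA`
#'   values with a message.
#' @export
change_of_mind_metrics <- function(responses) {
  out <- list()
  for (cond in unique(responses$condition)) {
    r <- responses[responses$condition == cond, ]
    sw <- r$is_switch
    high <- r$confidence == "high"
    n_def <- sum(!is.na(sw))
    n_sw <- sum(sw, na.rm = TRUE)
    add <- function(metric, level, value, n) {
      out[[length(out) + 1]] <<- data.frame(
        condition = cond, metric = metric, level = level,
        value = value, n = n, stringsAsFactors = FALSE)
    }
    add("switch_rate", "all", if (n_def > 0) n_sw / n_def else NA_real_, n_def)
    if (n_sw == 0) {
      message("no switches in condition ", cond,
              "; confirmation metrics are NA")
      add("confirmed_fraction", "all", NA_real_, 0)
    } else {
      conf_def <- !is.na(r$is_confirmed)
      add("confirmed_fraction", "all",
          mean(r$is_confirmed[conf_def]), sum(conf_def))
    }
    for (lev in c("repeat", "switch")) {
      ii <- !is.na(sw) & (sw == (lev == "switch"))
      add("p_high", lev, if (any(ii)) mean(high[ii]) else NA_real_, sum(ii))
    }
    for (lev in c("confirmed", "aborted")) {
      ii <- !is.na(r$is_confirmed) & (r$is_confirmed == (lev == "confirmed"))
      add("p_high_switch", lev, if (any(ii)) mean(high[ii]) else NA_real_,
          sum(ii))
    }
    for (lev in c("high", "low")) {
      ii <- !is.na(sw) & sw & !is.na(r$is_confirmed) & (high == (lev == "high"))
      add("p_confirmed", lev,
          if (any(ii)) mean(r$is_confirmed[ii]) else NA_real_, sum(ii))
    }
  }
  structure(do.call(rbind, out), class = c("vol_cell_table", "data.frame"))
}

#' 2 x 2 repeated-measures ANOVA
#'
#' Within-participant ANOVA for two crossed two-level factors, as used for
#' cell fractions (e.g. high-confidence rate by response type x condition).
#' Participants with incomplete cells are dropped listwise (with a count in
#' the result); a jackknife alternative over complete participants is
#' available via `jackknife = TRUE`, which reports jackknifed F statistics
#' computed by leave-one-out averaging.
#'
#' @param data Long data frame.
#' @param dv Name of the numeric response column.
#' @param within Character vector of the two factor column names.
#' @param id Name of the participant column.
#' @param jackknife If `TRUE`, F statistics are jackknifed over participants.
#' @return A data frame with one row per effect (`A`, `B`, `A:B`):
#'   `effect`, `F`, `df1`, `df2`, `p`, plus attributes `n_used`, `n_dropped`.
#' @export
rm_anova_2x2 <- function(data, dv, within, id = "participant",
                         jackknife = FALSE) {
  stopifnot(length(within) == 2)
  d <- data[, c(id, within, dv)]
  names(d) <- c("id", "A", "B", "y")
  d <- d[stats::complete.cases(d), ]
  d$A <- factor(d$A); d$B <- factor(d$B); d$id <- factor(d$id)
  if (nlevels(d$A) != 2 || nlevels(d$B) != 2) {
    stop_config("both factors must have exactly 2 levels")
  }
  # keep participants with all four cells
  tab <- table(d$id, interaction(d$A, d$B))
  complete <- rownames(tab)[apply(tab >= 1, 1, all)]
  n_dropped <- nlevels(d$id) - length(complete)
  d <- droplevels(d[d$id %in% complete, ])
  if (nlevels(d$id) < 2) stop_config("need >= 2 participants with complete cells")
  # average replicate observations within cell
  agg <- stats::aggregate(y ~ id + A + B, data = d, FUN = mean)
  run_aov <- function(dd) {
    fit <- stats::aov(y ~ A * B + Error(id / (A * B)), data = dd)
    sm <- summary(fit)
    grab <- function(stratum, term) {
      tb <- sm[[stratum]][[1]]
      i <- trimws(rownames(tb)) == term
      c(F = tb[i, "F value"], df1 = tb[i, "Df"],
        df2 = tb[trimws(rownames(tb)) == "Residuals", "Df"],
        p = tb[i, "Pr(>F)"])
    }
    rbind(A = grab("Error: id:A", "A"),
          B = grab("Error: id:B", "B"),
          `A:B` = grab("Error: id:A:B", "A:B"))
  }
  res <- run_aov(agg)
  if (jackknife) {
    ids <- levels(agg$id)
    fj <- sapply(ids, function(i) {
      run_aov(droplevels(agg[agg$id != i, ]))[, "F"]
    })
    res[, "F"] <- rowMeans(fj)
    res[, "p"] <- stats::pf(res[, "F"], res[, "df1"], res[, "df2"] - 1,
                            lower.tail = FALSE)
  }
  out <- data.frame(effect = c(within[1], within[2],
                               paste(within, collapse = ":")),
                    F = res[, "F"], df1 = res[, "df1"], df2 = res[, "df2"],
                    p = res[, "p"], row.names = NULL)
  attr(out, "n_used") <- length(complete)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' MAP logistic regression with Gaussian priors
#'
#' Maximum a posteriori estimate of a Bernoulli logistic model with
#' independent Gaussian priors `N(0, prior_sd^2)` on every coefficient
#' (intercept included). The prior keeps coefficients finite under complete
#' separation or sparse cells. Fitted by damped Newton iterations on the
#' negative log posterior (monotone by step-halving), converged when the
#' gradient norm drops below `tol`.
#'
#' @param X Design matrix including an intercept column.
#' @param y Binary outcomes (0/1 or logical).
#' @param prior_sd Prior SD (default 2).
#' @param max_iter,tol Newton iteration controls.
#' @return A list: `coef`, `converged`, `n_iter`, `neg_log_post`, `trace`
#'   (negative log posterior per iteration).
#' @export
map_logistic_regression <- function(X, y, prior_sd = 2, max_iter = 200,
                                    tol = 1e-6) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  lam <- 1 / prior_sd^2
  beta <- numeric(ncol(X))
  nlp <- function(b) {
    eta <- drop(X %*% b)
    # -sum[y*eta - log(1+e^eta)] + lam/2 * ||b||^2
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      lam / 2 * sum(b^2)
  }
  f <- nlp(beta)
  trace <- f
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    p <- stats::plogis(drop(X %*% beta))
    g <- drop(crossprod(X, p - y)) + lam * beta
    if (sqrt(sum(g^2)) < tol) { converged <- TRUE; break }
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X * w, X) + diag(lam, ncol(X))
    step <- solve(H, g)
    # step-halving guarantees a monotone decrease of the objective
    alpha <- 1
    repeat {
      bnew <- beta - alpha * step
      fnew <- nlp(bnew)
      if (fnew <= f || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    beta <- bnew; f <- fnew
    trace <- c(trace, f)
  }
  list(coef = beta, converged = converged, n_iter = it, neg_log_post = f,
       trace = trace)
}

#' Group-level tests on per-participant statistics
#'
#' One-sample (or paired, via `y`) t-test against `mu`, plus the Wilcoxon
#' signed-rank alternative. Zero-variance samples are handled: the t-test
#' reports `NA`/p = 1 rather than erroring, and exact ties follow the rank
#' test convention of dropping zeros.
#'
#' @param x Numeric vector of per-participant statistics.
#' @param y Optional paired second sample.
#' @param mu Null value (default 0).
#' @return A one-row data frame: `n`, `mean`, `t`, `df`, `p_t`, `wilcoxon_z`,
#'   `p_wilcoxon`.
#' @export
group_level_tests <- function(x, y = NULL, mu = 0) {
  if (!is.null(y)) x <- x - y
  x <- x[!is.na(x)]
  if (length(x) < 2) stop_config("need >= 2 participants")
  if (stats::sd(x) == 0) {
    # degenerate sample: identical values give no evidence (p = 1) unless
    # every value differs from the null, in which case the t statistic
    # diverges and p -> 0
    if (x[1] == mu) {
      tt <- list(statistic = NA_real_, parameter = length(x) - 1, p.value = 1)
    } else {
      tt <- list(statistic = sign(x[1] - mu) * Inf,
                 parameter = length(x) - 1, p.value = 0)
    }
  } else {
    t0 <- stats::t.test(x, mu = mu)
    tt <- list(statistic = unname(t0$statistic),
               parameter = unname(t0$parameter), p.value = t0$p.value)
  }
  nz <- x[x != mu]
  if (length(nz) == 0) {
    wz <- NA_real_; wp <- 1
  } else {
    w0 <- suppressWarnings(stats::wilcox.test(x, mu = mu, exact = FALSE,
                                              correct = TRUE))
    wp <- w0$p.value
    wz <- sign(stats::median(x) - mu) * stats::qnorm(1 - wp / 2)
  }
  data.frame(n = length(x), mean = mean(x), t = tt$statistic,
             df = tt$parameter, p_t = tt$p.value,
             wilcoxon_z = wz, p_wilcoxon = wp)
}

#' Confidence regression design for change-of-mind analyses
#'
#' Builds the per-trial design matrix and outcome for the regularized
#' logistic regression of high confidence on response type, condition, their
#' interaction, and evidence strength in favor of the previous response.
#' Factors use effects (+1/-1) coding; the evidence covariate is
#' standardized within participant so coefficients are comparable across
#' participants in group-level t-tests.
#'
#' @param responses Response data frame (one participant).
#' @param contrast `"switch"` (repeat vs switch) or `"confirmed"`
#'   (confirmed vs aborted switches only).
#' @return A list with `X` (intercept, type, condition, interaction,
#'   evidence) and `y` (high confidence 0/1).
#' @export
confidence_regression_design <- function(responses,
                                         contrast = c("switch", "confirmed")) {
  contrast <- match.arg(contrast)
  r <- responses
  if (contrast == "switch") {
    keep <- !is.na(r$is_switch) & !is.na(r$signed_evidence)
    r <- r[keep, ]
    type <- ifelse(r$is_switch, -1, 1)
  } else {
    keep <- !is.na(r$is_confirmed) & !is.na(r$signed_evidence)
    r <- r[keep, ]
    type <- ifelse(r$is_confirmed, 1, -1)
  }
  cond <- ifelse(r$condition == "C-", 1, -1)
  ev <- r$signed_evidence
  ev <- (ev - mean(ev)) / max(stats::sd(ev), 1e-12)
  X <- cbind(intercept = 1, type = type, condition = cond,
             interaction = type * cond, evidence = ev)
  list(X = X, y = as.numeric(r$confidence == "high"))
}
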