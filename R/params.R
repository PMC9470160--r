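#' Observer model parameters
#'
#' The five fitted quantities of the normative observer:
#'
#' * `hazard` — assumed per-trial probability of a hidden-state reversal;
#'   lower values make beliefs stickier.
#' * `sigma_inf` — inference noise: SD of the additive Gaussian corruption of
#'   each stimulus log-likelihood ratio, so accumulated noise variance scales
#'   with sequence length.
#' * `conf_threshold` — log-odds level of the belief readout above which a
#'   response is reported with high confidence.
#' * `sigma_meta` — metacognitive noise: SD of the Gaussian corruption of the
#'   confidence readout (the readout only, choices are unaffected).
#' * `conf_gain` — multiplicative gain applied to the absolute belief in the
#'   confidence readout on switch trials only.
#'
#' @param hazard Probability in `[1e-6, 1 - 1e-6]`.
#' @param sigma_inf Non-negative SD in `[0, 10]`.
#' @param conf_threshold Log-odds in `[-10, 10]`.
#' @param sigma_meta Non-negative SD in `[0, 10]`.
#' @param conf_gain Gain in `[0, 10]`.
#' @return An object of class `vol_model_params`.
#' @examples
#' model_params(hazard = 0.15, sigma_inf = 1, conf_threshold = 1.5)
#' @export
model_params <- function(hazard = 0.5, sigma_inf = 5, conf_threshold = 0,
                         sigma_meta = 5, conf_gain = 5) {
  b <- param_bounds()
  p <- c(hazard = hazard, sigma_inf = sigma_inf,
         conf_threshold = conf_threshold, sigma_meta = sigma_meta,
         conf_gain = conf_gain)
  for (nm in names(p)) {
    if (is.na(p[[nm]]) || p[[nm]] < b$lower[[nm]] || p[[nm]] > b$upper[[nm]]) {
      stop_config(nm, " = ", p[[nm]], " outside [", b$lower[[nm]], ", ",
                  b$upper[[nm]], "]")
    }
  }
  structure(as.list(p), class = "vol_model_params")
}

#' Fitting bounds of the observer parameters
#'
#' @return A list with named numeric vectors `lower` and `upper`.
#' @export
param_bounds <- function() {
  list(
    lower = c(hazard = 1e-6, sigma_inf = 0, conf_threshold = -10,
              sigma_meta = 0, conf_gain = 0),
    upper = c(hazard = 1 - 1e-6, sigma_inf = 10, conf_threshold = 10,
              sigma_meta = 10, conf_gain = 10)
  )
}

#' @export
print.vol_model_params <- function(x, ...) {
  cat("<vol_model_params>\n")
  cat(sprintf("  hazard = %.4g, sigma_inf = %.4g, conf_threshold = %.4g,\n",
              x$hazard, x$sigma_inf, x$conf_threshold))
  cat(sprintf("  sigma_meta = %.4g, conf_gain = %.4g\n",
              x$sigma_meta, x$conf_gain))
  invisible(x)
}

#' @export
as.data.frame.vol_model_params <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

param_vector <- function(params) {
  unlist(unclass(params))[c("hazard", "sigma_inf", "conf_threshold",
                            "sigma_meta", "conf_gain")]
}

# --- bounded <-> unbounded transforms for derivative-free search ---------

# scaled logit: maps (lo, hi) to the real line
to_unbounded <- function(theta) {
  b <- param_bounds()
  v <- param_vector(theta)
  z <- (v - b$lower) / (b$upper - b$lower)
  stats::qlogis(clamp(z, 1e-9, 1 - 1e-9))
}

from_unbounded <- function(x) {
  b <- param_bounds()
  v <- b$lower + (b$upper - b$lower) * stats::plogis(x)
  names(v) <- names(b$lower)
  do.call(model_params, as.list(v))
}
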