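# Two-mode subpopulation survival model f = s * Pn: a population's
# non-growing-persister frequency f is the fraction of non-growing cells Pn
# times the probability s that a non-growing cell survives exposure and
# regrows. s is anchored on one condition (by default the one with the
# largest Pn, i.e. the most stationary population) and used to predict f
# elsewhere.

#' Estimate the per-non-growing-cell survival probability s
#'
#' `s = f / Pn` at the anchoring condition. Two error conventions are
#' computed: `"linear"` (default) propagates a symmetric first-order error,
#' `delta_s = s * sqrt((delta_f / f)^2 + (delta_Pn / Pn)^2)` with `delta_f`
#' taken as half the width of the linear-scale range of `f`; `"log"`
#' propagates on the log10 scale and yields an asymmetric range.
#'
#' @param f_late A `surviving_fraction` (from [surviving_fraction()]) or a
#'   list with `f`, `lower`, `upper`.
#' @param Pn_late A `fraction_se` (from [fraction_se()]) or a list with `p`,
#'   `se`.
#' @param method `"linear"` or `"log"` error propagation.
#' @return List of class `survival_prob`: `s`, `se`, `lower`, `upper`,
#'   `method`. `s` is clamped to [0, 1] with a warning if the ratio
#'   exceeds 1.
#' @examples
#' f <- structure(list(f = 5.1e-2, lower = 3.9e-2, upper = 6.6e-2,
#'                     se_log10 = NA), class = "surviving_fraction")
#' estimate_s(f, fraction_se(318, 521))  # ~ (8.4 +/- 2.2) x 10^-2
#' @export
estimate_s <- function(f_late, Pn_late, method = c("linear", "log")) {
  method <- match.arg(method)
  f <- f_late$f
  if (is.null(f) || !is.finite(f) || f < 0) stop("invalid surviving fraction")
  if (Pn_late$p <= 0) stop("Pn must be positive")
  if (f == 0)
    return(structure(list(s = 0, se = 0, lower = 0, upper = 0, method = method),
                     class = "survival_prob"))
  s <- f / Pn_late$p
  if (s > 1) {
    warning("f / Pn exceeds 1; s clamped to 1")
    s <- 1
  }
  if (method == "linear") {
    df <- (f_late$upper - f_late$lower) / 2
    rel <- sqrt((df / f)^2 + (Pn_late$se / Pn_late$p)^2)
    se <- s * rel
    lower <- max(0, s - se); upper <- min(1, s + se)
  } else {
    se_logf <- (log10(f_late$upper) - log10(f_late$lower)) / 2
    se_logPn <- Pn_late$se / (Pn_late$p * log(10))
    se_log <- sqrt(se_logf^2 + se_logPn^2)
    lower <- s * 10^(-se_log); upper <- min(1, s * 10^(se_log))
    se <- (upper - lower) / 2
  }
  structure(list(s = s, se = se, lower = lower, upper = upper,
                 method = method),
            class = "survival_prob")
}

#' @export
print.survival_prob <- function(x, ...) {
  cat(sprintf("s = %.3g (%.3g-%.3g), %s propagation\n",
              x$s, x$lower, x$upper, x$method))
  invisible(x)
}

#' Predict the non-growing-persister frequency from s and Pn
#'
#' `f = s * Pn`, with a prediction band spanning
#' `[s_lower * Pn, s_upper * Pn]`.
#'
#' @param s A `survival_prob` (from [estimate_s()]) or a scalar.
#' @param Pn Non-growing fraction(s) in [0, 1]; vectorized.
#' @return Data frame with columns `Pn`, `f`, `lower`, `upper`.
#' @export
predict_f <- function(s, Pn) {
  if (any(Pn < 0 | Pn > 1)) stop("Pn must be in [0, 1]")
  if (inherits(s, "survival_prob")) {
    lo <- s$lower; hi <- s$upper; sc <- s$s
  } else {
    sc <- lo <- hi <- as.numeric(s)
  }
  data.frame(Pn = Pn, f = sc * Pn, lower = lo * Pn, upper = hi * Pn)
}

#' Compare an observed persister frequency with the constant-s prediction
#'
#' Classifies a condition as `below_prediction` when the observed range lies
#' entirely below the prediction band, `above_prediction` when entirely
#' above, and `consistent_with_constant_s` otherwise. When growing
#' persisters are present the observed frequency is only an upper bound for
#' the non-growing-persister frequency, which is noted in the result.
#'
#' @param observed A `surviving_fraction`-style list with `f`, `lower`,
#'   `upper`.
#' @param band One row of [predict_f()] output (`f`, `lower`, `upper`).
#' @param growing_persisters_present Logical note carried into the result.
#' @return List with `classification`, `observed`, `band`, `note`.
#' @export
classify_scenario <- function(observed, band,
                              growing_persisters_present = FALSE) {
  stopifnot(is.finite(observed$lower), is.finite(observed$upper),
            is.finite(band$lower), is.finite(band$upper))
  cls <- if (observed$upper < band$lower) "below_prediction"
         else if (observed$lower > band$upper) "above_prediction"
         else "consistent_with_constant_s"
  note <- if (growing_persisters_present)
    "observed f includes growing persisters and is an upper bound for the non-growing-persister frequency"
  else NA_character_
  list(classification = cls,
       observed = c(f = observed$f, lower = observed$lower,
                    upper = observed$upper),
       band = c(f = band$f, lower = band$lower, upper = band$upper),
       note = note)
}

#' Fit the constant-s survival model across conditions
#'
#' Anchors s on one condition (by default the one with the largest Pn,
#' i.e. the most stationary population), predicts f for every condition,
#' and classifies each observation against the prediction band.
#'
#' @param conditions Data frame with columns `condition`, `Pn`, `Pn_se`,
#'   `f`, `f_lower`, `f_upper`, and optionally `growing_persisters`
#'   (logical).
#' @param anchor Condition name to anchor on, or `NULL` for largest Pn.
#' @param method Error propagation for [estimate_s()].
#' @return List of class `survival_mode_model`: `s` (`survival_prob`),
#'   `anchor`, `conditions` (input plus `f_pred`, `band_lower`,
#'   `band_upper`, `classification`).
#' @export
fit_survival_model <- function(conditions, anchor = NULL,
                               method = c("linear", "log")) {
  method <- match.arg(method)
  req <- c("condition", "Pn", "Pn_se", "f", "f_lower", "f_upper")
  miss <- setdiff(req, names(conditions))
  if (length(miss)) stop("missing condition columns: ", paste(miss, collapse = ", "))
  if (is.null(anchor)) anchor <- conditions$condition[which.max(conditions$Pn)]
  ai <- match(anchor, conditions$condition)
  if (is.na(ai)) stop("anchor condition not found: ", anchor)
  f_anchor <- list(f = conditions$f[ai], lower = conditions$f_lower[ai],
                   upper = conditions$f_upper[ai])
  # reconstruct the binomial SE structure from Pn and its SE
  Pn_anchor <- list(p = conditions$Pn[ai], se = conditions$Pn_se[ai])
  s <- estimate_s(f_anchor, Pn_anchor, method = method)
  pred <- predict_f(s, conditions$Pn)
  # the prediction for a condition is uncertain both through s and through
  # that condition's measured Pn: widen the band by +/- 1 SE of Pn
  if (inherits(s, "survival_prob")) {
    pred$lower <- s$lower * pmax(conditions$Pn - conditions$Pn_se, 0)
    pred$upper <- s$upper * pmin(conditions$Pn + conditions$Pn_se, 1)
  }
  gp <- if ("growing_persisters" %in% names(conditions))
    conditions$growing_persisters else rep(FALSE, nrow(conditions))
  cls <- vapply(seq_len(nrow(conditions)), function(i) {
    classify_scenario(list(f = conditions$f[i], lower = conditions$f_lower[i],
                           upper = conditions$f_upper[i]),
                      pred[i, ], growing_persisters_present = gp[i])$classification
  }, character(1))
  out <- conditions
  out$f_pred <- pred$f; out$band_lower <- pred$lower; out$band_upper <- pred$upper
  out$classification <- cls
  structure(list(s = s, anchor = anchor, conditions = out),
            class = "survival_mode_model")
}

#' @export
print.survival_mode_model <- function(x, ...) {
  cat("Constant-s survival model, anchored on", x$anchor, "\n")
  print(x$s)
  print(x$conditions[, c("condition", "Pn", "f", "f_pred", "classification")],
        row.names = FALSE)
  invisible(x)
}
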