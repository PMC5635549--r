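#' Convert odds to a probability
#'
#' Applies `probability = odds / (1 + odds)`, the conversion used throughout
#' the model after odds have been adjusted by odds ratios.
#'
#' @param odds Nonnegative, finite numeric vector of odds.
#' @return Probabilities in `[0, 1)`, strictly increasing in `odds`.
#' @examples
#' odds_to_prob(2.125) # 0.68, high-school graduation
#' @seealso [prob_to_odds()], [adjust_odds()]
#' @export
odds_to_prob <- function(odds) {
  if (!is.numeric(odds) || any(!is.finite(odds)) || any(odds < 0)) {
    stop("`odds` must be finite and nonnegative")
  }
  odds / (1 + odds)
}

#' Convert a probability to odds
#'
#' Inverse of [odds_to_prob()]: `odds = p / (1 - p)`.
#'
#' @param p Numeric vector of probabilities in `[0, 1)`.
#' @return Nonnegative odds.
#' @examples
#' prob_to_odds(0.927) # ~12.7, employment
#' @export
prob_to_odds <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p >= 1)) {
    stop("`p` must lie in [0, 1)")
  }
  p / (1 - p)
}

#' Adjust baseline odds by one or more odds ratios
#'
#' Odds ratios compose multiplicatively on the odds scale (the standard
#' logistic-model convention, and the only order-independent choice), so the
#' adjusted odds are `base_odds * prod(odds_ratios)`.
#'
#' @param base_odds Nonnegative baseline odds (vectorised).
#' @param odds_ratios Numeric vector of strictly positive odds ratios applied
#'   to every element of `base_odds`; may be empty.
#' @return Adjusted odds, same length as `base_odds`.
#' @examples
#' adjust_odds(0.146, c(3.846, 0.26)) # intervention offsets the risk factor
#' @export
adjust_odds <- function(base_odds, odds_ratios = numeric()) {
  if (!is.numeric(base_odds) || any(!is.finite(base_odds)) || any(base_odds < 0)) {
    stop("`base_odds` must be finite and nonnegative")
  }
  if (length(odds_ratios) &&
      (!is.numeric(odds_ratios) || any(!is.finite(odds_ratios)) || any(odds_ratios <= 0))) {
    stop("every odds ratio must be finite and strictly positive")
  }
  base_odds * prod(odds_ratios)
}

#' Back-calculate an annual probability from a cumulative one
#'
#' Assumes a uniform (constant) incidence rate over the horizon, so that
#' `1 - (1 - annual)^horizon = cumulative`.
#'
#' @param cumulative Cumulative probability over the horizon, in `[0, 1)`.
#' @param horizon_years Positive integer number of years.
#' @return The constant annual probability.
#' @examples
#' annual_prob_from_cumulative(0.266, 40)
#' @export
annual_prob_from_cumulative <- function(cumulative, horizon_years) {
  if (!is.numeric(cumulative) || any(!is.finite(cumulative)) ||
      any(cumulative < 0) || any(cumulative >= 1)) {
    stop("`cumulative` must lie in [0, 1); a cumulative probability of 1 has no constant annual rate")
  }
  if (!is.numeric(horizon_years) || any(horizon_years < 1) ||
      any(horizon_years != as.integer(horizon_years))) {
    stop("`horizon_years` must be a positive integer")
  }
  1 - (1 - cumulative)^(1 / horizon_years)
}

#' Present-value discount factor
#'
#' @param rate Discount rate per year (fraction, `>= 0`).
#' @param years_elapsed Nonnegative integer years since model entry
#'   (vectorised).
#' @return `(1 + rate)^(-years_elapsed)`, equal to 1 at year 0.
#' @examples
#' discount_factor(0.05, 1) # 0.95238...
#' @export
discount_factor <- function(rate, years_elapsed) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate < 0) {
    stop("`rate` must be a single nonnegative number")
  }
  if (!is.numeric(years_elapsed) || any(years_elapsed < 0)) {
    stop("`years_elapsed` must be nonnegative")
  }
  (1 + rate)^(-years_elapsed)
}

#' Random-effects pooling of effect estimates (DerSimonian-Laird)
#'
#' Pools estimates on the log-odds-ratio scale with the moment-based
#' between-study variance of DerSimonian and Laird. Fixed-effect weights
#' `w_i = 1/v_i` give the Q statistic `Q = sum w_i (theta_i - theta_FE)^2`;
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`; the pooled value
#' reweights by `1/(v_i + tau2)`.
#'
#' Homogeneity is flagged when the Q-test p-value exceeds `q_p_threshold`
#' and `I2` is below `i2_threshold` (both configurable; see the methods
#' vignette for the interpretation of the decision rule).
#'
#' @param values Numeric vector of study estimates (log-OR scale).
#' @param variances Positive within-study variances, same length.
#' @param q_p_threshold Q-test p-value above which heterogeneity is not
#'   flagged (default 0.10).
#' @param i2_threshold I-squared (%) below which heterogeneity is not flagged
#'   (default 25).
#' @return A list of class `pooled_result`: `pooled`, `se`, `tau2`, `Q`,
#'   `I2` (%), `p_value` (Q test), `k`, `homogeneous`.
#' @examples
#' pool_estimates(c(0, 2), c(1, 1))$pooled # 1 by symmetry
#' @export
pool_estimates <- function(values, variances,
                           q_p_threshold = 0.10, i2_threshold = 25) {
  if (length(values) < 2L) stop("pooling needs at least 2 estimates")
  if (length(variances) != length(values)) stop("`values` and `variances` lengths differ")
  if (any(!is.finite(variances)) || any(variances <= 0)) stop("variances must be strictly positive")
  k <- length(values)
  w <- 1 / variances
  theta_fe <- sum(w * values) / sum(w)
  Q <- sum(w * (values - theta_fe)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w_re <- 1 / (variances + tau2)
  pooled <- sum(w_re * values) / sum(w_re)
  I2 <- if (Q > 0) max(0, 100 * (Q - (k - 1)) / Q) else 0
  p_value <- stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
  structure(
    list(pooled = pooled, se = sqrt(1 / sum(w_re)), tau2 = tau2, Q = Q,
         I2 = I2, p_value = p_value, k = k,
         homogeneous = (p_value > q_p_threshold) && (I2 < i2_threshold)),
    class = "pooled_result"
  )
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("Pooled estimate (DL random effects, k = %d)\n", x$k))
  cat(sprintf("  pooled = %.4f (SE %.4f), tau2 = %.4f\n", x$pooled, x$se, x$tau2))
  cat(sprintf("  Q = %.3f (p = %.3f), I2 = %.1f%%, homogeneous: %s\n",
              x$Q, x$p_value, x$I2, x$homogeneous))
  invisible(x)
}

#' Median fallback for heterogeneous evidence
#'
#' When estimates are not homogeneous under [pool_estimates()], the decision
#' rule falls back to the median estimate with a plausible range spanning the
#' lowest and highest reported confidence limits.
#'
#' @param values Numeric vector of study estimates (at least one).
#' @param lows,highs Reported lower/upper confidence limits, same length as
#'   `values`.
#' @return List with `value` (median), `low` (min of lows), `high` (max of
#'   highs).
#' @export
median_fallback <- function(values, lows, highs) {
  if (!length(values)) stop("at least one estimate is required")
  if (length(lows) != length(values) || length(highs) != length(values)) {
    stop("`lows` and `highs` must match `values` in length")
  }
  list(value = stats::median(values), low = min(lows), high = max(highs))
}
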