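# Mean and SD estimators from quantile summaries, for the three reporting
# scenarios encountered in systematic reviews:
#   C1: {min, median, max; n}
#   C2: {min, q1, median, q3, max; n}
#   C3: {q1, median, q3; n}

# Ordering check across whichever summaries are present.  Inputs may be
# vectors (the simulation module applies estimators to whole replication
# columns at once); ties are legal, only strict inversions are errors.
.check_order <- function(...) {
  vals <- list(...)
  vals <- vals[!vapply(vals, function(v) all(is.na(v)), logical(1))]
  if (length(vals) < 2) return(invisible(TRUE))
  nm <- names(vals)
  for (i in seq_len(length(vals) - 1L)) {
    lo <- vals[[i]]
    hi <- vals[[i + 1L]]
    bad <- which(lo > hi)
    if (length(bad))
      stop(sprintf("summary ordering violated: %s (%g) exceeds %s (%g)",
                   nm[i], lo[bad[1]], nm[i + 1L], hi[bad[1]]), call. = FALSE)
  }
  invisible(TRUE)
}

.warn_nonneg <- function(a, what) {
  if (any(a < 0, na.rm = TRUE))
    warning(sprintf("%s was derived under a non-negative data assumption; ",
                    what),
            "the minimum supplied is negative, interpret with care",
            call. = FALSE)
}

#' Mean from \{min, median, max\} (Hozo's estimator)
#'
#' The classical scenario-C1 mean estimate.  The full form carries a
#' 1/n correction term,
#' `(a + 2m + b)/4 + (a - 2m + b)/(4n)`;
#' the simplified form drops it, leaving `(a + 2m + b)/4`.  The two agree
#' as `n` grows.
#'
#' @param a,m,b Minimum, median, maximum (same units).  Vectorised.
#' @param n Sample size; required unless `simplified = TRUE`.
#' @param simplified Drop the 1/n correction term.
#' @return Numeric mean estimate(s).
#' @export
mean_c1_hozo <- function(a, m, b, n = NULL, simplified = FALSE) {
  .check_order(min = a, median = m, max = b)
  base <- (a + 2 * m + b) / 4
  if (simplified) return(base)
  if (is.null(n))
    stop("the full estimator needs 'n'; use simplified = TRUE to drop ",
         "the 1/n correction", call. = FALSE)
  if (any(n < 1)) stop("'n' must be >= 1", call. = FALSE)
  base + (a - 2 * m + b) / (4 * n)
}

#' SD from \{min, median, max\}: Hozo's adaptive range rule
#'
#' The sample-size-adaptive legacy rule:
#' `sqrt(((a - 2m + b)^2 / 4 + (b - a)^2) / 12)` for `n <= 15`
#' (equidistantly-spaced-data derivation), `(b - a)/4` for `15 < n <= 70`,
#' and `(b - a)/6` for `n > 70` (Chebyshev bound).  Derived for
#' non-negative data; a warning is issued when `a < 0` but the value is
#' still computed so the rule can be compared on any input.
#'
#' @inheritParams mean_c1_hozo
#' @param n Sample size(s), `>= 1`.
#' @return Nonnegative SD estimate(s).
#' @seealso [sd_range_rule()] for the fixed-divisor rules, [sd_c1()] for
#'   the sample-size-adaptive replacement.
#' @export
sd_c1_hozo <- function(a, m, b, n) {
  .check_order(min = a, median = m, max = b)
  if (any(n < 1)) stop("'n' must be >= 1", call. = FALSE)
  .warn_nonneg(a, "Hozo's adaptive range rule")
  small <- sqrt(((a - 2 * m + b)^2 / 4 + (b - a)^2) / 12)
  ifelse(n <= 15, small, ifelse(n <= 70, (b - a) / 4, (b - a) / 6))
}

#' Fixed-divisor range rules of thumb
#'
#' The sample-size-independent legacy rules `(b - a)/4` and `(b - a)/6`.
#'
#' @param a,b Minimum and maximum.  Vectorised.
#' @param divisor Range divisor, typically 4 or 6.
#' @return Nonnegative SD estimate(s).
#' @export
sd_range_rule <- function(a, b, divisor = 4) {
  .check_order(min = a, max = b)
  if (any(divisor <= 0)) stop("'divisor' must be positive", call. = FALSE)
  (b - a) / divisor
}

#' SD from the range, scaled by the normal-order-statistic constant
#'
#' The scenario-C1 estimator `(b - a) / xi(n)`, with
#' `xi(n) = 2 * E(Z_(n:n))` exactly or its closed form
#' `2 * qnorm((n - 0.375)/(n + 0.25))`.  Unlike the fixed range rules this
#' adapts continuously to the sample size and needs no non-negativity
#' assumption.
#'
#' @param a,b Minimum and maximum.  Vectorised.
#' @param n Single sample size, `n >= 2` (`xi(1) = 0` leaves the estimator
#'   undefined for a single observation).
#' @param mode Passed to [xi_n()].
#' @return Nonnegative SD estimate(s); zero when the range is zero.
#' @export
sd_c1 <- function(a, b, n, mode = c("auto", "exact", "approx")) {
  .check_order(min = a, max = b)
  n <- .check_count(n, "n", min = 2)
  (b - a) / as.numeric(xi_n(n, match.arg(mode)))
}

#' Mean from the full five-number summary (Bland's estimator)
#'
#' The scenario-C2 mean `(a + 2*q1 + 2*m + 2*q3 + b) / 8`.  The full form
#' retains the 1/n terms of the underlying bound midpoint,
#' `(Q*(a + 2*q1 + 2*m + 2*q3 + b) + a + b) / (2n)` with `Q = (n - 1)/4`,
#' which the simplified form discards as negligible.
#'
#' @param a,q1,m,q3,b The five-number summary.  Vectorised.
#' @param n Sample size; required for `full = TRUE`.
#' @param full Keep the 1/n terms.
#' @return Numeric mean estimate(s).
#' @export
mean_c2_bland <- function(a, q1, m, q3, b, n = NULL, full = FALSE) {
  .check_order(min = a, q1 = q1, median = m, q3 = q3, max = b)
  if (!full) return((a + 2 * q1 + 2 * m + 2 * q3 + b) / 8)
  if (is.null(n))
    stop("the full estimator needs 'n'", call. = FALSE)
  if (any(n < 5)) stop("'n' must be >= 5", call. = FALSE)
  Q <- (n - 1) / 4
  (Q * (a + 2 * q1 + 2 * m + 2 * q3 + b) + a + b) / (2 * n)
}

#' SD from the full five-number summary (Bland's estimator)
#'
#' The legacy scenario-C2 estimator: the square root of
#' \deqn{(a^2 + 2 q_1^2 + 2 m^2 + 2 q_3^2 + b^2)/16 +
#'       (a q_1 + q_1 m + m q_3 + q_3 b)/8 -
#'       (a + 2 q_1 + 2 m + 2 q_3 + b)^2/64.}
#' The radicand equals \eqn{[4 \sum u_i^2 - (\sum u_i)^2]/64} with
#' \eqn{u_i} the adjacent pair sums `a+q1, q1+m, m+q3, q3+b`, hence is
#' nonnegative for any real summaries; the estimator is independent of the
#' sample size, which is its main limitation.
#'
#' @param a,q1,m,q3,b The five-number summary.  Vectorised.
#' @return Nonnegative SD estimate(s).
#' @export
sd_c2_bland <- function(a, q1, m, q3, b) {
  .check_order(min = a, q1 = q1, median = m, q3 = q3, max = b)
  rad <- (a^2 + 2 * q1^2 + 2 * m^2 + 2 * q3^2 + b^2) / 16 +
    (a * q1 + q1 * m + m * q3 + q3 * b) / 8 -
    (a + 2 * q1 + 2 * m + 2 * q3 + b)^2 / 64
  if (any(!is.finite(rad)) || any(rad < -1e-12))
    stop("inconsistent summaries: negative variance under Bland's formula",
         call. = FALSE)
  sqrt(pmax(rad, 0))
}

#' SD from range and IQR combined
#'
#' The recommended scenario-C2 estimator: the average of the range-based
#' and IQR-based estimates,
#' `((b - a)/xi(n) + (q3 - q1)/eta(n)) / 2`.
#' With the closed-form constants this is
#' `(b - a) / (4*qnorm((n - 0.375)/(n + 0.25))) +
#'  (q3 - q1) / (4*qnorm((0.75n - 0.125)/(n + 0.25)))`.
#'
#' @param a,q1,q3,b Minimum, quartiles, maximum.  Vectorised.
#' @param n Single sample size, `n >= 5`; `mode = "exact"` additionally
#'   requires `n = 4Q + 1`.
#' @param mode Passed to [xi_n()] and [eta_n()].
#' @return Nonnegative SD estimate(s); by construction exactly the average
#'   of [sd_c1()] and [sd_c3()] on the same inputs.
#' @export
sd_c2 <- function(a, q1, q3, b, n, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  .check_order(min = a, q1 = q1, q3 = q3, max = b)
  n <- .check_count(n, "n", min = 5)
  0.5 * ((b - a) / as.numeric(xi_n(n, mode)) +
           (q3 - q1) / as.numeric(eta_n(n, mode)))
}

#' Mean from \{q1, median, q3\}
#'
#' The scenario-C3 mean `(q1 + m + q3) / 3`: with symmetric quartile
#' expectations around the median, the three-term average is unbiased for
#' normal data and needs no extreme values.
#'
#' @param q1,m,q3 First quartile, median, third quartile.  Vectorised.
#' @return Numeric mean estimate(s).
#' @export
mean_c3 <- function(q1, m, q3) {
  .check_order(q1 = q1, median = m, q3 = q3)
  (q1 + m + q3) / 3
}

#' SD from the IQR, scaled by the normal-order-statistic constant
#'
#' The scenario-C3 estimator `(q3 - q1) / eta(n)`, with
#' `eta(n) = 2 * E(Z_(3Q+1:n))` exactly or its closed form
#' `2 * qnorm((0.75n - 0.125)/(n + 0.25))`.  Converges to the
#' Cochrane-Handbook rule as `n` grows but adapts at small `n`.
#'
#' @param q1,q3 Quartiles.  Vectorised.
#' @param n Single sample size, `n >= 5`; `mode = "exact"` requires
#'   `n = 4Q + 1`.
#' @param mode Passed to [eta_n()].
#' @return Nonnegative SD estimate(s).
#' @export
sd_c3 <- function(q1, q3, n, mode = c("auto", "exact", "approx")) {
  .check_order(q1 = q1, q3 = q3)
  n <- .check_count(n, "n", min = 5)
  (q3 - q1) / as.numeric(eta_n(n, match.arg(mode)))
}

#' SD from the IQR: the Cochrane-Handbook rule
#'
#' The sample-size-independent rule `(q3 - q1) / 1.35`.
#'
#' @param q1,q3 Quartiles.  Vectorised.
#' @return Nonnegative SD estimate(s).
#' @export
sd_c3_cochrane <- function(q1, q3) {
  .check_order(q1 = q1, q3 = q3)
  (q3 - q1) / 1.35
}

# ---- scenario container & dispatch -----------------------------------------

#' A study's reported quantile summary
#'
#' Bundles one study's sample size with whichever of the five-number
#' summary values it reported, validates their ordering, and detects the
#' reporting scenario: `C1` = \{min, median, max\}, `C2` = all five,
#' `C3` = \{q1, median, q3\}.  Any other pattern is tagged `unsupported`
#' (and rejected by [estimate_moments()]).
#'
#' @param n Sample size (positive integer).
#' @param min,q1,median,q3,max Reported summaries; `NA` = not reported.
#' @param study_id Optional label carried through to results.
#' @return An object of class `summary_input`.
#' @examples
#' summary_input(41, min = 10, median = 20, max = 70)
#' @export
summary_input <- function(n, min = NA_real_, q1 = NA_real_,
                          median = NA_real_, q3 = NA_real_, max = NA_real_,
                          study_id = NA_character_) {
  n <- .check_count(n, "n")
  vals <- c(min = as.numeric(min), q1 = as.numeric(q1),
            median = as.numeric(median), q3 = as.numeric(q3),
            max = as.numeric(max))
  do.call(.check_order, as.list(vals))
  p <- !is.na(vals)
  scenario <- if (p["min"] && p["median"] && p["max"] &&
                  !p["q1"] && !p["q3"]) {
    "C1"
  } else if (all(p)) {
    "C2"
  } else if (p["q1"] && p["median"] && p["q3"] && !p["min"] && !p["max"]) {
    "C3"
  } else {
    "unsupported"
  }
  structure(list(study_id = study_id, n = n, min = vals[["min"]],
                 q1 = vals[["q1"]], median = vals[["median"]],
                 q3 = vals[["q3"]], max = vals[["max"]],
                 scenario = scenario),
            class = "summary_input")
}

#' @export
print.summary_input <- function(x, ...) {
  cat(sprintf("<summary_input %s> scenario %s, n = %d\n",
              if (is.na(x$study_id)) "" else x$study_id, x$scenario, x$n))
  v <- unlist(x[c("min", "q1", "median", "q3", "max")])
  cat(paste(sprintf("%s = %s", names(v),
                    ifelse(is.na(v), ".", format(v))), collapse = ", "), "\n")
  invisible(x)
}

# method registry: required inputs, native scenario, target, estimator.
# `fn` receives the summary_input and the constants mode.
.methods <- list(
  hozo_mean     = list(scenario = "C1", target = "mean",
                       needs = c("min", "median", "max"),
                       fn = function(s, mode)
                         mean_c1_hozo(s$min, s$median, s$max,
                                      simplified = TRUE)),
  hozo_adaptive = list(scenario = "C1", target = "sd",
                       needs = c("min", "median", "max"),
                       fn = function(s, mode)
                         sd_c1_hozo(s$min, s$median, s$max, s$n)),
  range_rule_4  = list(scenario = "C1", target = "sd",
                       needs = c("min", "max"),
                       fn = function(s, mode)
                         sd_range_rule(s$min, s$max, 4)),
  range_rule_6  = list(scenario = "C1", target = "sd",
                       needs = c("min", "max"),
                       fn = function(s, mode)
                         sd_range_rule(s$min, s$max, 6)),
  range_sd      = list(scenario = "C1", target = "sd",
                       needs = c("min", "max"),
                       fn = function(s, mode)
                         sd_c1(s$min, s$max, s$n, mode)),
  bland_mean    = list(scenario = "C2", target = "mean",
                       needs = c("min", "q1", "median", "q3", "max"),
                       fn = function(s, mode)
                         mean_c2_bland(s$min, s$q1, s$median, s$q3, s$max)),
  bland_sd      = list(scenario = "C2", target = "sd",
                       needs = c("min", "q1", "median", "q3", "max"),
                       fn = function(s, mode)
                         sd_c2_bland(s$min, s$q1, s$median, s$q3, s$max)),
  combined_sd   = list(scenario = "C2", target = "sd",
                       needs = c("min", "q1", "q3", "max"),
                       fn = function(s, mode)
                         sd_c2(s$min, s$q1, s$q3, s$max, s$n, mode)),
  quantile_mean = list(scenario = "C3", target = "mean",
                       needs = c("q1", "median", "q3"),
                       fn = function(s, mode)
                         mean_c3(s$q1, s$median, s$q3)),
  iqr_sd        = list(scenario = "C3", target = "sd",
                       needs = c("q1", "q3"),
                       fn = function(s, mode)
                         sd_c3(s$q1, s$q3, s$n, mode)),
  cochrane_sd   = list(scenario = "C3", target = "sd",
                       needs = c("q1", "q3"),
                       fn = function(s, mode)
                         sd_c3_cochrane(s$q1, s$q3))
)

# methods returned per (scenario, policy)
.policy_methods <- function(scenario, policy) {
  switch(policy,
         recommended = switch(scenario,
                              C1 = c("hozo_mean", "range_sd"),
                              C2 = c("bland_mean", "combined_sd"),
                              C3 = c("quantile_mean", "iqr_sd")),
         legacy = switch(scenario,
                         C1 = c("hozo_mean", "hozo_adaptive"),
                         C2 = c("bland_mean", "bland_sd"),
                         C3 = "cochrane_sd"),
         all = {
           # every method whose required inputs are present
           NULL
         })
}

#' Estimate mean and SD from a reported quantile summary
#'
#' Detects the reporting scenario of a [summary_input()] and applies the
#' matching estimators.  `policy = "recommended"` returns the
#' sample-size-adaptive methods (simplified Hozo mean plus [sd_c1()] for
#' C1; Bland mean plus [sd_c2()] for C2; [mean_c3()] plus [sd_c3()] for
#' C3).  `policy = "legacy"` returns the Hozo / Bland / Cochrane
#' comparators.  `policy = "all"` returns every method whose required
#' summaries are present, including cross-scenario ones when the full
#' five-number summary is available.
#'
#' When `mode = "exact"` is requested but the sample size is not of the
#' form `4Q + 1`, IQR-based methods fall back to the closed-form
#' approximation (the exact quartile rank does not exist).
#'
#' @param x A `summary_input`.
#' @param policy `"recommended"`, `"legacy"` or `"all"`.
#' @param mode Constants mode, see [xi_n()] / [eta_n()].
#' @return A `data.frame` with one row per estimate: columns `study_id`,
#'   `scenario`, `n`, `method`, `mean_est`, `sd_est` (the column not
#'   targeted by a method is `NA`).
#' @examples
#' s <- summary_input(41, min = 10, median = 20, max = 70)
#' estimate_moments(s)
#' @export
estimate_moments <- function(x, policy = c("recommended", "legacy", "all"),
                             mode = c("auto", "exact", "approx")) {
  policy <- match.arg(policy)
  mode <- match.arg(mode)
  if (!inherits(x, "summary_input"))
    stop("'x' must be a summary_input object", call. = FALSE)
  if (x$scenario == "unsupported")
    stop("scenario not covered: supported reporting patterns are ",
         "{min, median, max}, {min, q1, median, q3, max} and ",
         "{q1, median, q3}", call. = FALSE)
  ids <- .policy_methods(x$scenario, policy)
  if (is.null(ids)) {
    present <- names(which(!vapply(x[c("min", "q1", "median", "q3", "max")],
                                   is.na, logical(1))))
    ids <- names(Filter(function(m) all(m$needs %in% present), .methods))
  }
  # exact mode is unavailable for IQR constants unless n = 4Q + 1
  eff_mode <- mode
  if (mode == "exact" && (x$n - 1) %% 4 != 0) eff_mode <- "approx"
  rows <- lapply(ids, function(id) {
    m <- .methods[[id]]
    use_mode <- if (id %in% c("combined_sd", "iqr_sd")) eff_mode else mode
    val <- m$fn(x, use_mode)
    data.frame(study_id = x$study_id, scenario = x$scenario, n = x$n,
               method = id,
               mean_est = if (m$target == "mean") val else NA_real_,
               sd_est = if (m$target == "sd") val else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
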