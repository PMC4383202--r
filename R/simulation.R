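# Monte-Carlo framework quantifying estimator bias: draw samples from a
# parametric distribution, reduce each to its scenario summaries via order
# statistics, apply the estimators, and average signed relative errors
# against the per-sample true mean and SD.

.distributions <- list(
  normal = list(
    params = c("mean", "sd"),
    check = function(p) p[["sd"]] > 0,
    sampler = function(n, p) stats::rnorm(n, p[["mean"]], p[["sd"]])),
  lognormal = list(
    # location/scale are the mean and SD of the underlying normal
    params = c("location", "scale"),
    check = function(p) p[["scale"]] > 0,
    sampler = function(n, p) stats::rlnorm(n, p[["location"]], p[["scale"]])),
  beta = list(
    params = c("alpha", "beta"),
    check = function(p) p[["alpha"]] > 0 && p[["beta"]] > 0,
    sampler = function(n, p) stats::rbeta(n, p[["alpha"]], p[["beta"]])),
  exponential = list(
    params = "rate",
    check = function(p) p[["rate"]] > 0,
    sampler = function(n, p) stats::rexp(n, p[["rate"]])),
  weibull = list(
    params = c("shape", "scale"),
    check = function(p) p[["shape"]] > 0 && p[["scale"]] > 0,
    sampler = function(n, p) stats::rweibull(n, p[["shape"]], p[["scale"]]))
)

.check_dist <- function(distribution, params) {
  if (!is.character(distribution) || length(distribution) != 1L ||
      !distribution %in% names(.distributions))
    stop("'distribution' must be one of: ",
         paste(names(.distributions), collapse = ", "), call. = FALSE)
  d <- .distributions[[distribution]]
  params <- as.list(params)
  missing <- setdiff(d$params, names(params))
  if (length(missing))
    stop(sprintf("distribution '%s' needs parameter(s): %s", distribution,
                 paste(missing, collapse = ", ")), call. = FALSE)
  p <- lapply(params[d$params], as.numeric)
  if (!all(vapply(p, is.finite, logical(1))) || !d$check(p))
    stop(sprintf("invalid parameters for distribution '%s'", distribution),
         call. = FALSE)
  p
}

# deterministic per-cell seed so any (distribution, n) cell is
# reproducible in isolation; stays below 2^31 (exact in doubles)
.cell_seed <- function(seed, distribution, n) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(distribution)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h * 31 + n) %% 2147483647)
}

#' Draw an i.i.d. sample from a study distribution
#'
#' Supported families (parameter names in brackets): `normal` (`mean`,
#' `sd`), `lognormal` (`location`, `scale` of the underlying normal),
#' `beta` (`alpha`, `beta`), `exponential` (`rate`), `weibull` (`shape`,
#' `scale`).
#'
#' @param distribution Family name.
#' @param params Named list/vector of parameters.
#' @param n Number of draws.
#' @return Numeric vector of `n` draws.  Uses the current RNG state; seed
#'   with `set.seed()` (or let [run_study()] manage substreams).
#' @examples
#' set.seed(1)
#' draw_sample("normal", list(mean = 50, sd = 17), 5)
#' @export
draw_sample <- function(distribution, params, n) {
  p <- .check_dist(distribution, params)
  n <- .check_count(n, "n")
  .distributions[[distribution]]$sampler(n, p)
}

#' Reduce a sample to its scenario quantile summary
#'
#' Summaries are exact order statistics, never interpolated quantiles: the
#' minimum and maximum; the median as the central order statistic (odd `n`
#' required); and for samples of size `n = 4Q + 1`, the quartiles as the
#' `(Q+1)`-th and `(3Q+1)`-th order statistics.
#'
#' @param x Numeric sample.
#' @param scenario `"C1"`, `"C2"` or `"C3"` (which summaries to keep).
#' @return A [summary_input()] with the fields the scenario reports.
#' @examples
#' summarize_sample(c(5, 4, 3, 2, 1), "C2")
#' @export
summarize_sample <- function(x, scenario = c("C1", "C2", "C3")) {
  scenario <- match.arg(scenario)
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)))
    stop("'x' must be a finite numeric sample", call. = FALSE)
  n <- length(x)
  xs <- sort(x)
  if (n %% 2 == 0)
    stop("the median is taken as the central order statistic; ",
         "sample size must be odd", call. = FALSE)
  m <- xs[(n + 1) / 2]
  if (scenario == "C1")
    return(summary_input(n, min = xs[1], median = m, max = xs[n]))
  if ((n - 1) %% 4 != 0)
    stop("quartile order statistics need n = 4Q + 1; got n = ", n,
         call. = FALSE)
  Q <- (n - 1) / 4
  if (Q < 1) stop("quartiles need n >= 5", call. = FALSE)
  q1 <- xs[Q + 1]
  q3 <- xs[3 * Q + 1]
  if (scenario == "C3")
    return(summary_input(n, q1 = q1, median = m, q3 = q3))
  summary_input(n, min = xs[1], q1 = q1, median = m, q3 = q3, max = xs[n])
}

#' Signed relative error in percent
#'
#' `(estimate - truth) / truth * 100`: positive when the estimator
#' overestimates.  Averaged over replications by [run_study()].
#'
#' @param estimate,truth Numeric vectors; `truth` must be nonzero.
#' @return Signed percent deviation(s).
#' @export
relative_error <- function(estimate, truth) {
  if (any(truth == 0)) stop("'truth' must be nonzero", call. = FALSE)
  (estimate - truth) / truth * 100
}

# methods applicable per scenario for simulation runs
.scenario_methods <- list(
  C1 = c("hozo_mean", "hozo_adaptive", "range_rule_4", "range_rule_6",
         "range_sd"),
  C2 = c("bland_mean", "bland_sd", "combined_sd"),
  C3 = c("quantile_mean", "iqr_sd", "cochrane_sd")
)

# vectorised estimator application over replication columns
.apply_method <- function(id, a, q1, m, q3, b, n, mode) {
  switch(id,
    hozo_mean     = mean_c1_hozo(a, m, b, simplified = TRUE),
    hozo_adaptive = suppressWarnings(sd_c1_hozo(a, m, b, n)),
    range_rule_4  = sd_range_rule(a, b, 4),
    range_rule_6  = sd_range_rule(a, b, 6),
    range_sd      = sd_c1(a, b, n, mode),
    bland_mean    = mean_c2_bland(a, q1, m, q3, b),
    bland_sd      = sd_c2_bland(a, q1, m, q3, b),
    combined_sd   = sd_c2(a, q1, q3, b, n, mode),
    quantile_mean = mean_c3(q1, m, q3),
    iqr_sd        = sd_c3(q1, q3, n, mode),
    cochrane_sd   = sd_c3_cochrane(q1, q3),
    stop("unknown method: ", id, call. = FALSE))
}

#' Run a Monte-Carlo bias study
#'
#' For each sample size in `n_grid`, draws `reps` samples from the given
#' distribution, computes the true sample mean and SD of each sample,
#' reduces each sample to its scenario summary via order statistics,
#' applies each estimator, and averages the signed relative errors.  Each
#' (distribution, n) cell runs on its own RNG substream derived from
#' `seed`, so results are reproducible cell by cell.
#'
#' @param distribution,params Passed to [draw_sample()].
#' @param scenario `"C1"`, `"C2"` or `"C3"`.
#' @param n_grid Sample sizes; default `4Q + 1` for `Q = 1, ..., 50`
#'   (5 to 201).  C2/C3 grids must be of the form `4Q + 1`.
#' @param methods Estimator identifiers (see [estimate_moments()]);
#'   default: all methods applicable to the scenario.
#' @param reps Replications per cell (default 1000).
#' @param seed Root seed.
#' @param mode Constants mode, see [xi_n()].
#' @return A `data.frame` with one row per (n, method): columns
#'   `scenario`, `distribution`, `n`, `method`, `target` (`mean` or `sd`),
#'   `avg_rel_err_pct`, `reps`, `seed`.
#' @examples
#' run_study("normal", list(mean = 5, sd = 1), "C2",
#'           n_grid = c(5, 41), reps = 50, seed = 1)
#' @export
run_study <- function(distribution, params,
                      scenario = c("C1", "C2", "C3"),
                      n_grid = 4 * (1:50) + 1, methods = NULL,
                      reps = 1000, seed = 1,
                      mode = c("auto", "exact", "approx")) {
  scenario <- match.arg(scenario)
  mode <- match.arg(mode)
  .check_dist(distribution, params)
  reps <- .check_count(reps, "reps")
  seed <- .check_count(seed, "seed", min = 0)
  if (is.null(methods)) methods <- .scenario_methods[[scenario]]
  bad <- setdiff(methods, names(.methods))
  if (length(bad))
    stop("unknown method(s): ", paste(bad, collapse = ", "), call. = FALSE)
  targets <- vapply(methods, function(id) .methods[[id]]$target, "")

  out <- vector("list", length(n_grid))
  for (i in seq_along(n_grid)) {
    n <- .check_count(n_grid[i], "n")
    set.seed(.cell_seed(seed, distribution, n))
    X <- matrix(draw_sample(distribution, params, n * reps), nrow = n)
    Xs <- apply(X, 2, sort)
    if (reps == 1L) Xs <- matrix(Xs, nrow = n)
    true_mean <- colMeans(Xs)
    true_sd <- sqrt(pmax(colSums(Xs^2) - n * true_mean^2, 0) / (n - 1))
    a <- Xs[1, ]
    b <- Xs[n, ]
    if (n %% 2 != 1)
      stop(sprintf("n = %d: simulation grids use odd sample sizes ", n),
           call. = FALSE)
    m <- Xs[(n + 1) / 2, ]
    q1 <- q3 <- NULL
    if (scenario != "C1") {
      if ((n - 1) %% 4 != 0)
        stop(sprintf(
          "n = %d: quartile scenarios need sample sizes of the form 4Q + 1",
          n), call. = FALSE)
      Q <- (n - 1) / 4
      q1 <- Xs[Q + 1, ]
      q3 <- Xs[3 * Q + 1, ]
    }
    cell <- lapply(seq_along(methods), function(j) {
      est <- tryCatch(
        .apply_method(methods[j], a, q1, m, q3, b, n, mode),
        error = function(e)
          stop(sprintf("method '%s' failed at n = %d: %s", methods[j], n,
                       conditionMessage(e)), call. = FALSE))
      truth <- if (targets[j] == "mean") true_mean else true_sd
      data.frame(scenario = scenario, distribution = distribution, n = n,
                 method = methods[j], target = targets[j],
                 avg_rel_err_pct = mean(relative_error(est, truth)),
                 reps = reps, seed = seed, stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, cell)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a per-replication summary fixture to CSV
#'
#' Draws `reps` samples, reduces each to its scenario summary, and writes
#' one CSV row per replication together with the true sample mean and SD,
#' enabling end-to-end tests of the file-based estimation pipeline without
#' external data.  Fields the scenario does not report are left blank.
#'
#' @param distribution,params Passed to [draw_sample()].
#' @param scenario `"C1"`, `"C2"` or `"C3"`.
#' @param n Sample size per replication.
#' @param reps Number of replications (rows).
#' @param seed Root seed; the same seed reproduces the file byte for byte.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
generate_fixture <- function(distribution, params, scenario, n, reps = 10,
                             seed = 1, path) {
  .check_dist(distribution, params)
  n <- .check_count(n, "n")
  reps <- .check_count(reps, "reps")
  set.seed(.cell_seed(seed, distribution, n))
  rows <- lapply(seq_len(reps), function(i) {
    x <- draw_sample(distribution, params, n)
    s <- summarize_sample(x, scenario)
    data.frame(study_id = sprintf("rep%03d", i), n = n,
               min = s$min, q1 = s$q1, median = s$median, q3 = s$q3,
               max = s$max, true_mean = mean(x), true_sd = stats::sd(x),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("cannot write fixture to '%s': %s", path,
                 conditionMessage(ok)), call. = FALSE)
  invisible(path)
}
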