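# Expected values of standard-normal order statistics and the scaling
# constants xi(n), eta(n) that convert a range or IQR into an SD estimate.

# cache of exact integrals, keyed "r:n"
.enos_cache <- new.env(parent = emptyenv())

# E(Z_(r:n)) by adaptive quadrature of the classical order-statistic
# expectation: r*choose(n,r) * Integral z phi(z) Phi(z)^(r-1) (1-Phi(z))^(n-r) dz.
# Powers of Phi are taken in log space so the integrand cannot underflow at
# large n; the [-12, 12] window leaves < 1e-12 of the mass outside for any
# n up to 1e6 (the maximum concentrates near sqrt(2 log n) < 12).
.enos_exact <- function(r, n) {
  key <- paste0(r, ":", n)
  hit <- .enos_cache[[key]]
  if (!is.null(hit)) return(hit)
  logc <- lgamma(n + 1) - lgamma(r) - lgamma(n - r + 1)
  f <- function(z) {
    z * exp(logc + stats::dnorm(z, log = TRUE) +
              (r - 1) * stats::pnorm(z, log.p = TRUE) +
              (n - r) * stats::pnorm(z, lower.tail = FALSE, log.p = TRUE))
  }
  val <- stats::integrate(f, -12, 12, rel.tol = 1e-10, abs.tol = 1e-12,
                          subdivisions = 500L)$value
  assign(key, val, envir = .enos_cache)
  val
}

.check_count <- function(x, name, min = 1) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) ||
      x < min || x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  invisible(as.integer(x))
}

# round half away from zero (printed-table convention)
.round_half_away <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Expected value of a standard-normal order statistic
#'
#' Computes `E(Z_(r:n))`, the expected value of the `r`-th smallest of `n`
#' independent standard-normal draws, either exactly (adaptive quadrature of
#' the order-statistic expectation integral, accurate to better than 1e-6)
#' or through Blom's plotting-position approximation
#' `qnorm((r - alpha) / (n - 2*alpha + 1))`.
#'
#' These expectations drive every quantile-based standard deviation
#' estimator in the package: the sample range concentrates around
#' `2*sigma*E(Z_(n:n))` and the interquartile range around
#' `2*sigma*E(Z_(3Q+1:n))` for samples of size `n = 4Q + 1`.
#'
#' @param r Integer order index (or vector of indices), `1 <= r <= n`.
#' @param n Single positive integer sample size.
#' @param method `"exact"` for numerical integration, `"blom"` for the
#'   closed-form approximation.
#' @param alpha Blom offset in `[0, 0.5)`; 0.375 is Blom's compromise value.
#' @return Numeric vector of expectations (dimensionless), with attribute
#'   `method` recording how it was computed.
#' @examples
#' expected_normal_os(2, 2)              # 1/sqrt(pi)
#' expected_normal_os(50, 50, "blom")
#' @export
expected_normal_os <- function(r, n, method = c("exact", "blom"),
                               alpha = 0.375) {
  method <- match.arg(method)
  n <- .check_count(n, "n")
  if (!is.numeric(r) || !all(is.finite(r)) || any(r != floor(r)))
    stop("'r' must be integer order indices", call. = FALSE)
  if (any(r < 1 | r > n))
    stop(sprintf("'r' must lie in [1, %d]", n), call. = FALSE)
  if (method == "blom") {
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 0.5)
      stop("'alpha' must lie in [0, 0.5): larger offsets push the qnorm ",
           "argument outside (0, 1) at the extreme ranks", call. = FALSE)
    val <- stats::qnorm((r - alpha) / (n - 2 * alpha + 1))
  } else {
    val <- vapply(r, .enos_exact, numeric(1), n = n)
  }
  structure(val, method = method)
}

#' Range-to-SD scaling constant xi(n)
#'
#' `xi(n) = 2 * E(Z_(n:n))` is the factor by which the expected range of a
#' normal sample of size `n` exceeds its standard deviation, so
#' `(max - min) / xi(n)` estimates the SD.  The classical range rule of
#' thumb corresponds to freezing `xi` at 4 (or 6 for large samples);
#' `xi(27)` is approximately 4 and `xi(n)` reaches 6 near `n = 463`.
#'
#' @param n Positive integer sample size(s).
#' @param mode `"exact"` integrates the order-statistic expectation;
#'   `"approx"` uses the Blom form `2*qnorm((n - 0.375)/(n + 0.25))`;
#'   `"auto"` uses exact integration for `n <= 50` and the approximation
#'   beyond, mirroring the tabulated range of the constants.
#' @return Numeric vector of constants with attribute `method` (per-element
#'   `"exact"` or `"approx"`).
#' @seealso [eta_n()] for the IQR analogue, [constants_table()].
#' @examples
#' xi_n(10)            # 3.078
#' xi_n(463, "approx") # ~6
#' @export
xi_n <- function(n, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || !all(is.finite(n)) || any(n < 1 | n != floor(n)))
    stop("'n' must be positive integer sample size(s)", call. = FALSE)
  use_exact <- switch(mode,
                      exact  = rep(TRUE, length(n)),
                      approx = rep(FALSE, length(n)),
                      auto   = n <= 50)
  val <- numeric(length(n))
  val[use_exact] <- vapply(n[use_exact],
                           function(k) 2 * .enos_exact(k, k), numeric(1))
  val[!use_exact] <- 2 * stats::qnorm((n[!use_exact] - 0.375) /
                                        (n[!use_exact] + 0.25))
  structure(val, method = ifelse(use_exact, "exact", "approx"))
}

#' IQR-to-SD scaling constant eta(n)
#'
#' For samples of size `n = 4Q + 1` whose quartiles are the `(Q+1)`-th and
#' `(3Q+1)`-th order statistics, `eta(n) = 2 * E(Z_(3Q+1:n))` scales the
#' interquartile range into an SD estimate: `(q3 - q1) / eta(n)`.  As `n`
#' grows `eta(n)` tends to `2 * qnorm(0.75) = 1.34898`, the constant behind
#' the Cochrane-Handbook rule `(q3 - q1) / 1.35`.
#'
#' @param n Integer sample size(s), `n >= 5`.  Exact mode additionally
#'   requires `n = 4Q + 1` (otherwise the quartile order statistic `3Q + 1`
#'   is not an integer rank).
#' @param mode `"exact"`, `"approx"`
#'   (`2*qnorm((0.75n - 0.125)/(n + 0.25))`), or `"auto"` (exact whenever
#'   `n = 4Q + 1` with `Q <= 50`, the tabulated range; approximation
#'   otherwise).
#' @return Numeric vector with attribute `method` as in [xi_n()].
#' @examples
#' eta_n(5)    # 0.990
#' eta_n(41)   # 1.303
#' @export
eta_n <- function(n, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || !all(is.finite(n)) || any(n < 5 | n != floor(n)))
    stop("'n' must be integer sample size(s) >= 5", call. = FALSE)
  q4 <- (n - 1) %% 4 == 0
  Q <- (n - 1) %/% 4
  if (mode == "exact" && !all(q4))
    stop("exact eta(n) requires n = 4Q + 1; use mode = \"approx\" (or ",
         "\"auto\") for other sample sizes", call. = FALSE)
  use_exact <- switch(mode,
                      exact  = rep(TRUE, length(n)),
                      approx = rep(FALSE, length(n)),
                      auto   = q4 & Q <= 50)
  val <- numeric(length(n))
  if (any(use_exact))
    val[use_exact] <- mapply(function(k, q) 2 * .enos_exact(3 * q + 1, k),
                             n[use_exact], Q[use_exact])
  val[!use_exact] <- 2 * stats::qnorm((0.75 * n[!use_exact] - 0.125) /
                                        (n[!use_exact] + 0.25))
  structure(val, method = ifelse(use_exact, "exact", "approx"))
}

#' Tabulate the scaling constants xi(n) or eta(n)
#'
#' Reproduces the reference tables of scaling constants: `xi(n)` for
#' `n = 1, ..., max_index`, or `eta(4Q + 1)` for `Q = 1, ..., max_index`.
#' Values are rounded half away from zero to 3 decimals, the convention of
#' the printed tables; full-precision values are available from [xi_n()]
#' and [eta_n()] directly.
#'
#' @param max_index Largest `n` (for `xi`) or `Q` (for `eta`) to tabulate.
#' @param which `"xi"` or `"eta"`.
#' @param mode Passed to [xi_n()] / [eta_n()].
#' @return A `data.frame` with columns `index` (`n` or `Q`), `n`, `value`
#'   (3 decimals) and `method`.
#' @examples
#' constants_table(10, "xi")
#' @export
constants_table <- function(max_index, which = c("xi", "eta"),
                            mode = c("exact", "approx", "auto")) {
  which <- match.arg(which)
  mode <- match.arg(mode)
  max_index <- .check_count(max_index, "max_index")
  if (which == "xi") {
    idx <- seq_len(max_index)
    n <- idx
    v <- xi_n(n, mode)
  } else {
    idx <- seq_len(max_index)
    n <- 4L * idx + 1L
    v <- eta_n(n, mode)
  }
  data.frame(index = idx, n = n,
             value = .round_half_away(as.numeric(v), 3),
             method = attr(v, "method"),
             stringsAsFactors = FALSE)
}
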