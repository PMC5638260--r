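#' Maximum-likelihood power-law fit with a KS-optimal lower cutoff
#'
#' Fits P(x) ~ x^-gamma to the tail x >= x_min of a continuous sample,
#' following the standard maximum-likelihood recipe: for a candidate
#' cutoff the MLE is
#'
#'   gamma_hat = 1 + n_tail / sum(log(x_i / x_min)),
#'
#' and x_min itself is chosen to minimize the Kolmogorov-Smirnov
#' distance between the fitted tail CDF and the empirical one. Candidate
#' cutoffs are the unique sample values, thinned to at most `max_xmin`
#' log-spaced candidates for large samples; KS ties are broken towards
#' the smallest x_min (the longest tail).
#'
#' @param x positive numeric sample (>= 50 values).
#' @param xmin optional fixed lower cutoff; skips the scan.
#' @param max_xmin cap on the number of scanned cutoff candidates.
#' @return an object of class `power_law_fit`: list with `exponent`,
#'   `xmin`, `ks_distance`, `n_tail`, `type = "xmin"`.
#' @examples
#' x <- exp(stats::rexp(200, rate = 1.5))  # Pareto with exponent 2.5
#' fit_power_law(x, xmin = 1)
#' @export
fit_power_law <- function(x, xmin = NULL, max_xmin = 500L) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 50L) stop("need at least 50 positive samples", call. = FALSE)
  x <- sort(x)
  if (!is.null(xmin)) {
    fit <- .pl_fit_at(x, xmin)
    if (fit$n_tail < 2L) stop("fewer than 2 samples above `xmin`", call. = FALSE)
    return(structure(c(fit, list(type = "xmin")), class = "power_law_fit"))
  }
  cand <- unique(x[x < x[length(x)]])  # a cutoff must leave a nonempty tail
  if (length(cand) > max_xmin) {
    probe <- exp(seq(log(cand[1L]), log(cand[length(cand)]), length.out = max_xmin))
    cand <- unique(cand[findInterval(probe, cand)])
    cand <- cand[cand > 0]
  }
  best <- NULL
  for (xm in cand) {
    f <- .pl_fit_at(x, xm)
    if (f$n_tail < 10L) next
    if (is.null(best) || f$ks_distance < best$ks_distance) best <- f
  }
  if (is.null(best)) stop("power-law fit failed: no viable cutoff", call. = FALSE)
  structure(c(best, list(type = "xmin")), class = "power_law_fit")
}

# MLE + KS at a fixed cutoff; x must be sorted ascending.
.pl_fit_at <- function(x, xmin) {
  tail_x <- x[x >= xmin]
  n <- length(tail_x)
  slog <- sum(log(tail_x / xmin))
  expo <- 1 + n / slog
  # fitted CDF on the tail vs empirical CDF
  fitted <- 1 - (tail_x / xmin)^(1 - expo)
  emp_hi <- seq_len(n) / n
  emp_lo <- (seq_len(n) - 1L) / n
  ks <- max(pmax(abs(fitted - emp_hi), abs(fitted - emp_lo)))
  list(exponent = expo, xmin = xmin, ks_distance = ks, n_tail = n)
}

#' Maximum-likelihood power law on a bounded interval
#'
#' Fits P(x) ~ x^-delta restricted (and normalized) to [lo, hi], the
#' form used for displacement distributions whose shallow exponents
#' (delta near 1) are only normalizable on a finite range. The
#' one-dimensional likelihood in delta is maximized numerically.
#'
#' @param x positive sample; values outside [lo, hi] are discarded.
#' @param lo,hi interval bounds, lo < hi.
#' @param interval search interval for the exponent.
#' @return a `power_law_fit` with `type = "range"` and elements
#'   `exponent`, `xmin = lo`, `xmax = hi`, `ks_distance`, `n_tail`.
#' @export
fit_power_law_range <- function(x, lo, hi, interval = c(0.01, 20)) {
  if (lo <= 0 || hi <= lo) stop("need 0 < lo < hi", call. = FALSE)
  x <- x[is.finite(x) & x >= lo & x <= hi]
  if (length(x) < 50L) stop("fewer than 50 samples in [lo, hi]", call. = FALSE)
  if (max(x) == min(x)) stop("degenerate sample: all values equal", call. = FALSE)
  slog <- sum(log(x))
  n <- length(x)
  negll <- function(delta) {
    logC <- if (abs(delta - 1) < 1e-9)
      -log(log(hi / lo))
    else
      log((1 - delta) / (hi^(1 - delta) - lo^(1 - delta)))
    -(n * logC - delta * slog)
  }
  opt <- stats::optimize(negll, interval = interval)
  delta <- opt$minimum
  xs <- sort(x)
  cdf <- if (abs(delta - 1) < 1e-9)
    log(xs / lo) / log(hi / lo)
  else
    (xs^(1 - delta) - lo^(1 - delta)) / (hi^(1 - delta) - lo^(1 - delta))
  emp_hi <- seq_len(n) / n
  emp_lo <- (seq_len(n) - 1L) / n
  ks <- max(pmax(abs(cdf - emp_hi), abs(cdf - emp_lo)))
  structure(list(exponent = delta, xmin = lo, xmax = hi,
                 ks_distance = ks, n_tail = n, type = "range"),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  if (x$type == "range")
    cat(sprintf("<power_law_fit> exponent %.3f on [%g, %g], KS %.4f, n = %d\n",
                x$exponent, x$xmin, x$xmax, x$ks_distance, x$n_tail))
  else
    cat(sprintf("<power_law_fit> exponent %.3f, x_min %.4g, KS %.4f, n_tail = %d\n",
                x$exponent, x$xmin, x$ks_distance, x$n_tail))
  invisible(x)
}

#' Draw from a Pareto or interval-truncated power law
#'
#' Inverse-CDF samplers used by the synthetic generator and by
#' known-truth recovery tests. `rpareto()` draws from
#' P(x) ~ x^-gamma, x >= xmin (requires gamma > 1);
#' `rpowerlaw_trunc()` draws from the power law normalized to
#' [lo, hi] (any exponent).
#'
#' @param n number of draws.
#' @param gamma,delta exponent of the density.
#' @param xmin,lo,hi support bounds.
#' @return numeric vector of draws.
#' @export
rpareto <- function(n, gamma, xmin = 1) {
  if (gamma <= 1) stop("Pareto tail requires exponent > 1", call. = FALSE)
  xmin * stats::runif(n)^(-1 / (gamma - 1))
}

#' @rdname rpareto
#' @export
rpowerlaw_trunc <- function(n, delta, lo, hi) {
  if (lo <= 0 || hi <= lo) stop("need 0 < lo < hi", call. = FALSE)
  u <- stats::runif(n)
  if (abs(delta - 1) < 1e-9)
    lo * (hi / lo)^u
  else
    (lo^(1 - delta) + u * (hi^(1 - delta) - lo^(1 - delta)))^(1 / (1 - delta))
}
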