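## Convergence diagnostics for alchemical series: per-window hysteresis,
## half-split comparison, and statistical-inefficiency subsampling.

#' Statistical inefficiency of a correlated sample series
#'
#' \eqn{g = 1 + 2\sum_t (1 - t/N)\,\rho_t}, with the autocorrelation sum
#' truncated at the first non-positive term (initial-positive-sequence
#' convention) and \eqn{g} clamped to at least 1. A constant series has
#' \eqn{g = 1} by convention. Autocorrelations are computed by FFT so long
#' series stay cheap.
#'
#' @param samples ordered numeric series (>= 4 samples).
#' @return list with `g` (>= 1) and `indices`, the subsampled index vector
#'   strided by `ceiling(g)`.
#' @export
statistical_inefficiency <- function(samples) {
  .check_num(samples, "samples", len = NULL)
  n <- length(samples)
  if (n < 4L) stop("need at least 4 samples", call. = FALSE)
  v <- var(samples)
  if (v == 0) {
    return(list(g = 1, indices = seq_len(n)))
  }
  x <- samples - mean(samples)
  npad <- 2^ceiling(log2(2L * n))
  f <- fft(c(x, rep(0, npad - n)))
  ac <- Re(fft(Mod(f)^2, inverse = TRUE))[seq_len(n)] / npad
  rho <- ac / ac[1]
  g <- 1
  for (t in seq_len(n - 1L)) {
    if (rho[t + 1L] <= 0) break
    g <- g + 2 * (1 - t / n) * rho[t + 1L]
  }
  g <- max(g, 1)
  list(g = g, indices = seq(1L, n, by = as.integer(ceiling(g))))
}

#' Per-window hysteresis between forward and backward EXP estimates
#'
#' \eqn{\delta_\lambda} = forward EXP minus backward EXP per window.
#' Well-converged series show small \eqn{\delta_\lambda} randomly
#' distributed with respect to lambda; a Wald-Wolfowitz sign-runs statistic
#' quantifies the randomness.
#'
#' @param series a [fep_series()] with both directions in every window.
#' @param decorrelate subsample before estimating (default `TRUE`).
#' @return list with `per_window_delta`, `lambda_mid`, `mean_delta`,
#'   `max_abs_delta`, and `runs` (list `n_runs`, `z`, `p`; `z` near 0 means
#'   no sign clustering across lambda).
#' @export
hysteresis <- function(series, decorrelate = TRUE) {
  if (!inherits(series, "fep_series")) {
    stop("`series` must be a fep_series", call. = FALSE)
  }
  missing_dir <- which(vapply(series$windows, function(w) {
    !length(w$forward_work) || !length(w$backward_work)
  }, NA))
  if (length(missing_dir)) {
    stop(sprintf("windows missing a work direction: %s",
                 paste(missing_dir, collapse = ", ")), call. = FALSE)
  }
  delta <- vapply(series$windows, function(w) {
    if (decorrelate) w <- .decorrelate_window(w)
    exp_estimate(w, "forward")$value - exp_estimate(w, "backward")$value
  }, 0)
  lam_mid <- vapply(series$windows,
                    function(w) (w$lambda_a + w$lambda_b) / 2, 0)
  runs <- .runs_test(sign(delta))
  list(per_window_delta = delta, lambda_mid = lam_mid,
       mean_delta = mean(delta), max_abs_delta = max(abs(delta)),
       runs = runs)
}

## Wald-Wolfowitz runs test on a +/- sign sequence (zeros dropped)
.runs_test <- function(s) {
  s <- s[s != 0]
  n <- length(s)
  npos <- sum(s > 0); nneg <- sum(s < 0)
  if (npos == 0 || nneg == 0 || n < 2L) {
    return(list(n_runs = if (n) 1L else 0L, z = NA_real_, p = NA_real_))
  }
  r <- 1L + sum(s[-1] != s[-n])
  mu <- 1 + 2 * npos * nneg / n
  sig2 <- 2 * npos * nneg * (2 * npos * nneg - n) / (n^2 * (n - 1))
  z <- (r - mu) / sqrt(sig2)
  list(n_runs = r, z = z, p = 2 * pnorm(-abs(z)))
}

#' Half-split convergence check
#'
#' Splits every window's work samples into their first and second temporal
#' halves (raw order, before any subsampling), accumulates each half
#' independently, and compares the totals; the conventional acceptance
#' threshold is agreement within ~1 kcal/mol.
#'
#' @param series a [fep_series()] with at least 2 samples per direction per
#'   window.
#' @param decorrelate passed to [accumulate()] for each half.
#' @param threshold acceptance threshold in kcal/mol (default 1).
#' @return object of class `half_split_report`: `dg_first`, `dg_second`,
#'   `abs_diff`, `passes_1kcal`.
#' @export
half_split <- function(series, decorrelate = TRUE, threshold = 1) {
  if (!inherits(series, "fep_series")) {
    stop("`series` must be a fep_series", call. = FALSE)
  }
  short <- which(vapply(series$windows, function(w) {
    length(w$forward_work) < 2L || length(w$backward_work) < 2L
  }, NA))
  if (length(short)) {
    stop(sprintf("windows with < 2 samples per direction: %s",
                 paste(short, collapse = ", ")), call. = FALSE)
  }
  take <- function(w, part) {
    for (f in c("forward_work", "backward_work")) {
      n <- length(w[[f]])
      h <- n %/% 2L
      w[[f]] <- if (part == 1L) w[[f]][seq_len(h)] else w[[f]][(h + 1L):n]
    }
    w
  }
  s1 <- fep_series(lapply(series$windows, take, part = 1L),
                   replica_id = paste0(series$replica_id, "-h1"))
  s2 <- fep_series(lapply(series$windows, take, part = 2L),
                   replica_id = paste0(series$replica_id, "-h2"))
  d1 <- accumulate(s1, decorrelate = decorrelate)$total$value
  d2 <- accumulate(s2, decorrelate = decorrelate)$total$value
  structure(list(dg_first = d1, dg_second = d2, abs_diff = abs(d1 - d2),
                 passes_1kcal = abs(d1 - d2) <= threshold,
                 threshold = threshold),
            class = "half_split_report")
}

#' @export
print.half_split_report <- function(x, ...) {
  cat(sprintf(
    "<half_split> first %.4g, second %.4g, |diff| %.4g kcal/mol -> %s\n",
    x$dg_first, x$dg_second, x$abs_diff,
    if (x$passes_1kcal) "PASS" else "FAIL"))
  invisible(x)
}

#' Full convergence report for a series
#'
#' Bundles [half_split()], [hysteresis()] and per-window statistical
#' inefficiencies into one object.
#'
#' @param series a [fep_series()].
#' @param decorrelate passed through to the component diagnostics.
#' @return object of class `convergence_report`.
#' @export
convergence_report <- function(series, decorrelate = TRUE) {
  hs <- half_split(series, decorrelate = decorrelate)
  hy <- hysteresis(series, decorrelate = decorrelate)
  g_fwd <- vapply(series$windows, function(w) {
    if (length(w$forward_work) >= 4L)
      statistical_inefficiency(w$forward_work)$g else NA_real_
  }, 0)
  g_bwd <- vapply(series$windows, function(w) {
    if (length(w$backward_work) >= 4L)
      statistical_inefficiency(w$backward_work)$g else NA_real_
  }, 0)
  structure(list(per_window_delta = hy$per_window_delta,
                 lambda_mid = hy$lambda_mid,
                 half_split = hs,
                 passes_1kcal = hs$passes_1kcal,
                 runs = hy$runs,
                 inefficiency_g = data.frame(forward = g_fwd,
                                             backward = g_bwd)),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("<convergence_report>\n")
  print(x$half_split)
  cat(sprintf("  hysteresis: mean %.4g, max |delta| %.4g kcal/mol; runs z = %.2f\n",
              mean(x$per_window_delta), max(abs(x$per_window_delta)),
              x$runs$z))
  invisible(x)
}
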