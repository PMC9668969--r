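## Free-energy estimation from bidirectional per-window work samples:
## exponential averaging (EXP) and Bennett acceptance ratio (BAR), with
## accumulation across a lambda series.

#' Construct an alchemical window of bidirectional work samples
#'
#' @param lambda_a,lambda_b window endpoints in `[0, 1]`, `lambda_a <
#'   lambda_b`.
#' @param forward_work forward-direction work samples (kcal/mol).
#' @param backward_work reverse-direction work samples (kcal/mol), e.g. from
#'   interleaved double-wide sampling; may be empty (BAR then unavailable).
#' @param temperature temperature (K).
#' @return object of class `fep_window`.
#' @export
fep_window <- function(lambda_a, lambda_b, forward_work,
                       backward_work = numeric(0), temperature = 303.15) {
  .check_num(lambda_a, "lambda_a", lower = 0, upper = 1)
  .check_num(lambda_b, "lambda_b", lower = 0, upper = 1)
  if (lambda_a >= lambda_b) .bad_param("lambda_b", "must exceed lambda_a")
  .check_num(temperature, "temperature", lower = 0, strict_lower = TRUE)
  if (length(forward_work)) .check_num(forward_work, "forward_work", len = NULL)
  if (length(backward_work)) .check_num(backward_work, "backward_work", len = NULL)
  structure(list(lambda_a = lambda_a, lambda_b = lambda_b,
                 forward_work = as.numeric(forward_work),
                 backward_work = as.numeric(backward_work),
                 temperature = temperature),
            class = "fep_window")
}

#' Construct an ordered series of alchemical windows
#'
#' Windows must be contiguous (`lambda_b` of one equals `lambda_a` of the
#' next) and jointly cover `[0, 1]`.
#'
#' @param windows list of [fep_window()] objects.
#' @param replica_id free-text replica label.
#' @return object of class `fep_series`.
#' @export
fep_series <- function(windows, replica_id = "replica-1") {
  if (!length(windows)) stop("no windows supplied", call. = FALSE)
  la <- vapply(windows, `[[`, 0, "lambda_a")
  windows <- windows[order(la)]
  la <- vapply(windows, `[[`, 0, "lambda_a")
  lb <- vapply(windows, `[[`, 0, "lambda_b")
  if (abs(la[1]) > 1e-12 || abs(lb[length(lb)] - 1) > 1e-12) {
    stop(sprintf("windows must cover [0, 1]; found [%g, %g]",
                 la[1], lb[length(lb)]), call. = FALSE)
  }
  if (length(windows) > 1L) {
    gap <- which(abs(lb[-length(lb)] - la[-1]) > 1e-9)
    if (length(gap)) {
      stop(sprintf("lambda coverage gap between windows %d and %d (%g vs %g)",
                   gap[1], gap[1] + 1L, lb[gap[1]], la[gap[1] + 1L]),
           call. = FALSE)
    }
  }
  structure(list(windows = windows, replica_id = as.character(replica_id)),
            class = "fep_series")
}

#' @export
print.fep_series <- function(x, ...) {
  cat(sprintf("<fep_series> %s: %d windows on [0, 1]\n", x$replica_id,
              length(x$windows)))
  invisible(x)
}

#' Exponential (Zwanzig) free-energy estimate for one window
#'
#' Forward: \eqn{\Delta G = -RT \log \langle e^{-W/RT} \rangle} over the
#' forward work samples, computed with log-sum-exp. The backward estimate is
#' sign-corrected to the forward convention
#' (\eqn{\Delta G = +RT \log \langle e^{-W_R/RT}\rangle} negated).
#'
#' @param window a [fep_window()].
#' @param direction `"forward"` or `"backward"`.
#' @return object of class `dg_estimate`: `value`, `stat_error`, `method`,
#'   `n_effective`.
#' @export
exp_estimate <- function(window, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  w <- if (direction == "forward") window$forward_work else
    window$backward_work
  if (!length(w)) {
    stop(sprintf("no %s work samples in window [%g, %g]", direction,
                 window$lambda_a, window$lambda_b), call. = FALSE)
  }
  rt <- rt_kcal(window$temperature)
  n <- length(w)
  x <- -w / rt
  lme <- .logsumexp(x) - log(n)          # log mean exp(-w/RT)
  dg_dir <- -rt * lme                    # in the sampled direction
  value <- if (direction == "forward") dg_dir else -dg_dir
  ## effective sample size of the exponential average
  ess <- exp(2 * .logsumexp(x) - .logsumexp(2 * x))
  ## delta-method error of -RT log mean(exp), computed on shifted exponents
  e <- exp(x - max(x))
  se <- if (n > 1L) rt * sd(e) / (mean(e) * sqrt(n)) else 0
  structure(list(value = value, stat_error = se,
                 method = paste0("EXP_", direction),
                 n_effective = ess),
            class = "dg_estimate")
}

#' @export
print.dg_estimate <- function(x, ...) {
  cat(sprintf("<dg_estimate> %s: %.6g +/- %.3g kcal/mol (n_eff ~ %.1f)\n",
              x$method, x$value, x$stat_error, x$n_effective))
  invisible(x)
}

## BAR self-consistency function in kcal/mol; monotone increasing in dg.
.bar_fn <- function(dg, wf, wr, rt, m) {
  sum(plogis(-(m + wf - dg) / rt)) - sum(plogis(-(-m + wr + dg) / rt))
}

#' Bennett acceptance ratio estimate for one window
#'
#' Solves the BAR self-consistency condition over both work directions
#' (with the \eqn{RT\log(n_F/n_R)} offset) by bracketed root finding to
#' 1e-8 kcal/mol; the statistical error comes from the asymptotic variance
#' of the Fermi-weighted sums. When the Fermi-weight effective sample size
#' drops below 10 in either direction a poor-overlap warning is raised and
#' the error is inflated to at least half the forward/backward EXP spread.
#'
#' @param window a [fep_window()] with at least one sample per direction.
#' @return a `dg_estimate` (method `"BAR"`); attribute `"overlap_warning"`
#'   records whether overlap was poor.
#' @export
bar_estimate <- function(window) {
  wf <- window$forward_work; wr <- window$backward_work
  if (!length(wf) || !length(wr)) {
    stop(sprintf("BAR needs samples in both directions in window [%g, %g]",
                 window$lambda_a, window$lambda_b), call. = FALSE)
  }
  rt <- rt_kcal(window$temperature)
  m <- rt * log(length(wf) / length(wr))
  lo <- min(c(wf, -wr)) - 50
  hi <- max(c(wf, -wr)) + 50
  root <- uniroot(.bar_fn, c(lo, hi), wf = wf, wr = wr, rt = rt, m = m,
                  tol = 1e-10)
  dg <- root$root
  ff <- plogis(-(m + wf - dg) / rt)
  fr <- plogis(-(-m + wr + dg) / rt)
  nf <- length(wf); nr <- length(wr)
  varf <- (mean(ff^2) / mean(ff)^2 - 1) / nf
  varr <- (mean(fr^2) / mean(fr)^2 - 1) / nr
  se <- rt * sqrt(max(varf + varr, 0))
  ## effective sample size as the summed Fermi weights: near n/2 for well
  ## overlapped windows, near zero when the work distributions are disjoint
  ## (the weight-concentration form (sum f)^2 / sum f^2 would report ~n
  ## there, since all weights are equally tiny)
  essf <- sum(ff)
  essr <- sum(fr)
  poor <- essf < 10 || essr < 10
  if (poor) {
    spread <- abs(exp_estimate(window, "forward")$value -
                  exp_estimate(window, "backward")$value)
    se <- max(se, spread / 2)
    warning(sprintf(
      "poor forward/backward overlap in window [%g, %g] (ESS %.1f/%.1f); error inflated",
      window$lambda_a, window$lambda_b, essf, essr), call. = FALSE)
  }
  out <- structure(list(value = dg, stat_error = se, method = "BAR",
                        n_effective = min(essf, essr)),
                   class = "dg_estimate")
  attr(out, "overlap_warning") <- poor
  out
}

## subsample a window's work vectors by their statistical inefficiency
.decorrelate_window <- function(w) {
  for (f in c("forward_work", "backward_work")) {
    if (length(w[[f]]) >= 4L) {
      idx <- statistical_inefficiency(w[[f]])$indices
      w[[f]] <- w[[f]][idx]
    }
  }
  w
}

#' Accumulate per-window BAR estimates across a lambda series
#'
#' @param series a [fep_series()].
#' @param decorrelate subsample each window's work series by its statistical
#'   inefficiency before estimation (default `TRUE`).
#' @return list with `total` (a `dg_estimate`; error combined in
#'   quadrature), `profile` (data.frame `lambda`, `cum_dg`, `cum_err` at
#'   window boundaries), and `per_window` (list of `dg_estimate`).
#' @export
accumulate <- function(series, decorrelate = TRUE) {
  if (!inherits(series, "fep_series")) {
    stop("`series` must be a fep_series", call. = FALSE)
  }
  ests <- lapply(series$windows, function(w) {
    if (decorrelate) w <- .decorrelate_window(w)
    bar_estimate(w)
  })
  vals <- vapply(ests, `[[`, 0, "value")
  errs <- vapply(ests, `[[`, 0, "stat_error")
  lam <- c(series$windows[[1]]$lambda_a,
           vapply(series$windows, `[[`, 0, "lambda_b"))
  profile <- data.frame(lambda = lam,
                        cum_dg = c(0, cumsum(vals)),
                        cum_err = c(0, sqrt(cumsum(errs^2))))
  total <- structure(list(value = sum(vals),
                          stat_error = sqrt(sum(errs^2)),
                          method = "BAR",
                          n_effective = sum(vapply(ests, `[[`, 0,
                                                   "n_effective"))),
                     class = "dg_estimate")
  list(total = total, profile = profile, per_window = ests)
}

#' Aggregate replica free-energy estimates
#'
#' With two or more replicas the value is their mean and the error the
#' standard error of the mean; a single replica passes through with its own
#' estimator error. The mode used is recorded.
#'
#' @param estimates list of `dg_estimate` objects (or numeric values).
#' @return a `dg_estimate` with extra field `mode` (`"sem_replicas"` or
#'   `"single_replica"`).
#' @export
aggregate_replicas <- function(estimates) {
  if (!length(estimates)) stop("no replica estimates supplied", call. = FALSE)
  vals <- vapply(estimates, function(e) if (is.numeric(e)) e else e$value, 0)
  n <- length(vals)
  if (n >= 2L) {
    out <- list(value = mean(vals), stat_error = sd(vals) / sqrt(n),
                method = "replica_mean", n_effective = n,
                mode = "sem_replicas")
  } else {
    e <- estimates[[1]]
    out <- list(value = vals[1],
                stat_error = if (is.numeric(e)) NA_real_ else e$stat_error,
                method = "replica_mean", n_effective = 1,
                mode = "single_replica")
  }
  structure(out, class = "dg_estimate")
}

#' Build a linear lambda schedule
#'
#' @param n_windows number of windows (>= 1); the schedule has
#'   `n_windows + 1` linearly spaced values on `[0, 1]`.
#' @param elec_start lambda at which electrostatic scaling begins (metadata;
#'   0.25 for membrane-only transformations to prevent complete lipid
#'   discharging, 0.5 otherwise).
#' @return object of class `lambda_schedule`: `values`, `elec_start`.
#' @export
make_lambda_schedule <- function(n_windows, elec_start = 0.5) {
  .check_num(n_windows, "n_windows", lower = 1)
  .check_num(elec_start, "elec_start", lower = 0, upper = 1)
  structure(list(values = seq(0, 1, length.out = as.integer(n_windows) + 1L),
                 elec_start = elec_start),
            class = "lambda_schedule")
}
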