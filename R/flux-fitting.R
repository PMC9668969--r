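## Stretched-exponential trace fitting, instantaneous flux rates,
## and exponential-decay fits for desensitization/deactivation.

## Profile the two linear parameters (Finf and the quench amplitude) at
## fixed (log tau, beta).  Both are constrained non-negative: fluorescence
## cannot go below zero and a quenching trace cannot have negative
## amplitude.  Without these physical constraints the amplitude blows up
## along the (tau, beta) ridge of truncation-limited slow traces.
.stretched_profile <- function(par, t, y) {
  tau <- exp(par[1]); beta <- par[2]
  b <- exp(-(t / tau)^beta)
  fit <- lm.fit(cbind(1, b), y)
  finf <- unname(fit$coefficients[1]); a <- unname(fit$coefficients[2])
  if (is.na(a)) a <- 0
  if (finf < 0 || a < 0) {
    ## project onto the feasible corner with the smaller RSS
    a0 <- max(sum(y * b) / sum(b * b), 0)          # Finf pinned at 0
    rss0 <- sum((y - a0 * b)^2)
    f1 <- mean(y)                                   # amplitude pinned at 0
    rss1 <- sum((y - f1)^2)
    if (rss0 <= rss1) {
      finf <- 0; a <- a0
    } else {
      finf <- max(f1, 0); a <- 0
    }
  }
  list(Finf = finf, F0 = finf + a, tau = tau, beta = beta,
       rss = sum((y - finf - a * b)^2))
}

.stretched_rss <- function(par, t, y) .stretched_profile(par, t, y)$rss

#' Fit a stretched exponential to a quenching trace
#'
#' Nonlinear least squares of
#' \eqn{F(t) = F_\infty + (F_0 - F_\infty) e^{-(t/\tau)^\beta}} over the fit
#' window. \eqn{F_0} and \eqn{F_\infty} are profiled linearly; \eqn{(\tau,
#' \beta)} are optimized by bounded quasi-Newton from a data-driven start
#' (\eqn{F_0} = first sample, \eqn{F_\infty} = mean of the last 5\%,
#' \eqn{\tau} = time to 1/e of amplitude, \eqn{\beta = 0.9}).
#'
#' @param trace a [quench_trace()] (or list with `time`/`fluorescence`).
#' @param window fit window in seconds, default `c(0, 0.1)` (the first
#'   0.1 s of the quenching record).
#' @param beta_bounds,tau_bounds box constraints on the shape parameters.
#' @return object of class `stretched_exp_fit` with fields `F0`, `Finf`,
#'   `tau`, `beta`, `rss`, `window`, `converged`.
#' @export
fit_stretched_exp <- function(trace, window = c(0, 0.1),
                              beta_bounds = c(0.05, 1.5),
                              tau_bounds = c(1e-5, 1e3)) {
  t_all <- trace$time; y_all <- trace$fluorescence
  .check_num(window, "window", len = 2L)
  if (window[2] > max(t_all) + 1e-12) {
    window[2] <- max(t_all)  # clamp to trace duration
  }
  sel <- t_all >= window[1] & t_all <= window[2]
  if (sum(sel) < 10L) {
    stop(sprintf("fit window contains %d points; need at least 10", sum(sel)),
         call. = FALSE)
  }
  t <- t_all[sel]; y <- y_all[sel]

  ## initialization per package convention
  f0 <- y[1]
  finf <- mean(y[t >= window[1] + 0.95 * diff(window)])
  amp <- f0 - finf
  tau0 <- if (abs(amp) > 0) {
    target <- finf + amp / exp(1)
    idx <- which(y <= target)[1]
    if (is.na(idx) || t[idx] <= 0) diff(window) / 3 else t[idx]
  } else diff(window) / 3
  tau0 <- min(max(tau0, tau_bounds[1] * 2), tau_bounds[2] / 2)

  ## second start in the slow-decay basin: assume the quench runs to zero
  ## and extrapolate tau from the amplitude lost across the window.  For
  ## truncation-limited traces the in-window heuristic above lands in a
  ## spurious fast/small-amplitude basin; multi-start disambiguates.
  starts <- list(c(log(tau0), 0.9))
  drop_win <- f0 - mean(y[t >= window[1] + 0.9 * diff(window)])
  if (f0 > 0 && drop_win > 0 && drop_win < 0.5 * f0) {
    tau_slow <- diff(window) / (drop_win / f0)^(1 / 0.85)
    tau_slow <- min(max(tau_slow, tau_bounds[1] * 2), tau_bounds[2] / 2)
    starts <- c(starts, list(c(log(tau_slow), 0.85)))
  }
  opt <- NULL
  for (s0 in starts) {
    o <- optim(s0, .stretched_rss, t = t, y = y,
               method = "L-BFGS-B",
               lower = c(log(tau_bounds[1]), beta_bounds[1]),
               upper = c(log(tau_bounds[2]), beta_bounds[2]),
               control = list(factr = 1, pgtol = 1e-14, maxit = 500))
    if (is.null(opt) || o$value < opt$value) opt <- o
  }
  ## polish with a Nelder-Mead pass (cheap; helps on flat valleys), then
  ## clamp back into the box and keep the polish only if it still improves
  opt2 <- optim(opt$par, .stretched_rss, t = t, y = y,
                control = list(reltol = 1e-15, maxit = 2000))
  opt2$par[1] <- min(max(opt2$par[1], log(tau_bounds[1])), log(tau_bounds[2]))
  opt2$par[2] <- min(max(opt2$par[2], beta_bounds[1]), beta_bounds[2])
  opt2$value <- .stretched_rss(opt2$par, t, y)
  if (opt2$value < opt$value) opt <- opt2
  cf <- .stretched_profile(opt$par, t, y)
  structure(list(F0 = cf[["F0"]], Finf = cf[["Finf"]], tau = cf[["tau"]],
                 beta = cf[["beta"]], rss = cf[["rss"]],
                 window = window,
                 converged = isTRUE(opt$convergence == 0)),
            class = "stretched_exp_fit")
}

#' @export
print.stretched_exp_fit <- function(x, ...) {
  cat(sprintf(
    "<stretched_exp_fit> tau = %.4g s, beta = %.3f, F0 = %.4g, Finf = %.4g, rss = %.3g%s\n",
    x$tau, x$beta, x$F0, x$Finf, x$rss,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Instantaneous flux rate from a stretched-exponential fit
#'
#' Evaluates \eqn{k = (\beta/\tau)\,(t/\tau)^{\beta-1}} at `t_eval`
#' (default 2 ms), the time derivative of the stretched exponent. Depends
#' only on \eqn{\tau} and \eqn{\beta}, so it is invariant to fluorescence
#' rescaling.
#'
#' @param fit a `stretched_exp_fit`, or any list with `tau` and `beta`.
#' @param t_eval evaluation time (s, > 0).
#' @return object of class `flux_rate`: list with `k` (1/s) and `t_eval`.
#' @examples
#' flux_rate(list(tau = 0.1, beta = 1))$k  # 10, independent of t_eval
#' @export
flux_rate <- function(fit, t_eval = 0.002) {
  tau <- fit$tau; beta <- fit$beta
  .check_num(tau, "tau", lower = 0, strict_lower = TRUE)
  .check_num(beta, "beta", lower = 0, strict_lower = TRUE)
  .check_num(t_eval, "t_eval", lower = 0, strict_lower = TRUE)
  structure(list(k = (beta / tau) * (t_eval / tau)^(beta - 1),
                 t_eval = t_eval),
            class = "flux_rate")
}

#' Amplitude-weighted time constant
#'
#' \eqn{\tau_w = (A_1\tau_1 + A_2\tau_2)/(A_1 + A_2)}.
#'
#' @param A1,A2 component amplitudes (>= 0, not both zero).
#' @param tau1,tau2 component time constants (s, > 0).
#' @return weighted time constant (s).
#' @export
weighted_tau <- function(A1, tau1, A2, tau2) {
  .check_num(A1, "A1", lower = 0)
  .check_num(A2, "A2", lower = 0)
  if (A1 + A2 <= 0) stop("both amplitudes are zero", call. = FALSE)
  .check_num(tau1, "tau1", lower = 0, strict_lower = TRUE)
  .check_num(tau2, "tau2", lower = 0, strict_lower = TRUE)
  (A1 * tau1 + A2 * tau2) / (A1 + A2)
}

## RSS for a sum of decaying exponentials; par = (A1, log tau1[, A2, log tau2])
.decay_rss <- function(par, d, r) {
  ncomp <- length(par) / 2L
  pred <- 0
  for (j in seq_len(ncomp)) {
    pred <- pred + par[2L * j - 1L] * exp(-d / exp(par[2L * j]))
  }
  sum((r - pred)^2)
}

#' Fit an exponential decay to a rate-vs-delay time course
#'
#' Single- or double-exponential least squares with non-negative amplitudes.
#' For the double model the components are ordered by ascending time
#' constant (ties broken by descending amplitude) and the weighted time
#' constant is computed with [weighted_tau()].
#'
#' @param delays delay times (s).
#' @param rates flux rates (1/s), same length.
#' @param model `"double"` (default) or `"single"`.
#' @return object of class `decay_fit`: `components` (data.frame A, tau),
#'   `weighted_tau`, `model`, `rss`, `converged`.
#' @export
fit_decay <- function(delays, rates, model = c("double", "single")) {
  model <- match.arg(model)
  .check_num(delays, "delays", len = NULL, lower = 0)
  .check_num(rates, "rates", len = NULL)
  if (length(delays) != length(rates)) {
    stop("`delays` and `rates` must have equal length", call. = FALSE)
  }
  npar <- if (model == "double") 4L else 2L
  if (length(delays) < 2L * npar) {
    stop(sprintf(
      "need at least %d points for a %s-exponential fit; got %d",
      2L * npar, model, length(delays)), call. = FALSE)
  }
  if (sd(rates) < 1e-12 * max(abs(rates), 1e-300) || max(abs(rates)) == 0) {
    stop("no decay detected: rates are constant (zero-amplitude decay)",
         call. = FALSE)
  }
  ord <- order(delays)
  d <- delays[ord]; r <- rates[ord]
  span <- max(d) - min(d)
  r0 <- max(r)
  starts <- if (model == "double") {
    list(c(0.6 * r0, log(span / 10), 0.4 * r0, log(span)),
         c(0.5 * r0, log(span / 30), 0.5 * r0, log(span / 3)),
         c(0.8 * r0, log(span / 5), 0.2 * r0, log(3 * span)))
  } else {
    list(c(r0, log(span / 5)), c(r0, log(span / 2)))
  }
  ## time constants beyond ~3x the observed span are unidentifiable from
  ## the data; cap them rather than let a biased tail run tau to infinity
  lower <- rep(c(0, log(span) - 10), npar / 2L)
  upper <- rep(c(10 * abs(r0) + 1, log(3 * span)), npar / 2L)
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, .decay_rss, d = d, r = r, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(factr = 1, pgtol = 1e-14, maxit = 1000)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("decay fit failed from all starts", call. = FALSE)
  ncomp <- npar / 2L
  A <- best$par[seq(1, npar, by = 2)]
  tau <- exp(best$par[seq(2, npar, by = 2)])
  ord2 <- order(tau, -A)
  A <- A[ord2]; tau <- tau[ord2]
  wt <- if (sum(A) > 0) sum(A * tau) / sum(A) else NA_real_
  structure(list(components = data.frame(A = A, tau = tau),
                 weighted_tau = wt, model = model, rss = best$value,
                 converged = isTRUE(best$convergence == 0) && sum(A) > 0),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %s: weighted tau = %.4g s%s\n", x$model,
              x$weighted_tau, if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$components)
  invisible(x)
}

#' Fit a Hill dose-response curve
#'
#' Logistic fit in log concentration with bottom pinned at 0 and the top
#' profiled linearly; \eqn{EC_{50}} and the Hill coefficient are optimized
#' with box constraints. Flat (no-transition) data yield a flagged,
#' non-converged result rather than an error.
#'
#' @param concentrations agonist concentrations (mM, >= 0), at least 4.
#' @param responses responses (e.g. peak flux rates, 1/s).
#' @param hill_bounds bounds on the Hill coefficient.
#' @return object of class `hill_fit`: `ec50`, `hill_n`, `top`, `bottom`,
#'   `rss`, `converged`.
#' @export
fit_hill <- function(concentrations, responses, hill_bounds = c(0.2, 10)) {
  .check_num(concentrations, "concentrations", len = NULL, lower = 0)
  .check_num(responses, "responses", len = NULL)
  if (length(concentrations) != length(responses)) {
    stop("`concentrations` and `responses` must have equal length",
         call. = FALSE)
  }
  if (length(concentrations) < 4L) {
    stop("need at least 4 concentrations spanning the transition",
         call. = FALSE)
  }
  cpos <- concentrations[concentrations > 0]
  obj <- function(par) {
    ec50 <- exp(par[1]); n <- par[2]
    h <- ifelse(concentrations == 0, 0,
                concentrations^n / (concentrations^n + ec50^n))
    fit <- lm.fit(cbind(h), responses)
    sum(fit$residuals^2)
  }
  start <- c(log(stats::median(cpos)), 1)
  o <- optim(start, obj, method = "L-BFGS-B",
             lower = c(log(min(cpos) / 100), hill_bounds[1]),
             upper = c(log(max(cpos) * 100), hill_bounds[2]),
             control = list(factr = 1, pgtol = 1e-14, maxit = 1000))
  ec50 <- exp(o$par[1]); n <- o$par[2]
  h <- ifelse(concentrations == 0, 0,
              concentrations^n / (concentrations^n + ec50^n))
  top <- unname(lm.fit(cbind(h), responses)$coefficients[1])
  ## no transition: the profiled curve explains nothing beyond a flat line
  rng <- diff(range(responses))
  spread <- diff(range(h))
  converged <- isTRUE(o$convergence == 0) && spread > 0.1 &&
    rng > 1e-8 * max(abs(responses), 1) &&
    ec50 > min(cpos) / 99 && ec50 < max(cpos) * 99
  structure(list(ec50 = ec50, hill_n = n, top = top, bottom = 0,
                 rss = o$value, converged = converged),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> EC50 = %.4g mM, n = %.3f, top = %.4g%s\n",
              x$ec50, x$hill_n, x$top,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}
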