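## Assembly of per-delay flux rates into activation/desensitization time
## courses.

#' Build a flux-rate time course from a delay series of traces
#'
#' Fits each trace with [fit_stretched_exp()], converts to an instantaneous
#' rate with [flux_rate()], and aggregates mean and SEM per delay. When a
#' no-agonist control is supplied its rate is subtracted from every point
#' and the subtraction is recorded.
#'
#' @param traces list of [quench_trace()] objects, each carrying a
#'   `delay_time`; all must share one agonist concentration.
#' @param control optional no-agonist control: a single `quench_trace` or a
#'   numeric background rate (1/s).
#' @param window fit window passed to [fit_stretched_exp()].
#' @param t_eval rate evaluation time (s).
#' @param desensitization `"auto"` (fit a double exponential past the peak
#'   when enough points are available, else omit quietly), `"double"`,
#'   `"single"` (fit or error), or `"none"`.
#' @param extend_slow for truncation-limited slow traces the fit window is
#'   too short to identify \eqn{(\tau, \beta)}: a small fast quench and the
#'   onset of a large slow quench fit the window equally well. When `TRUE`
#'   (default) each window fit is checked against the trace beyond the
#'   window, and refit over the full record if it extrapolates poorly.
#'   Appropriate when the stretched-exponential model holds over the whole
#'   record (true for the synthetic generator); disable for real traces
#'   that go multi-phasic at long times.
#' @return object of class `time_course`: `points` (data.frame delay,
#'   mean_rate, sem, n), `peak_rate`, `desensitization` (a
#'   [fit_decay()] result or `NULL`), `control_rate`, `t_eval`.
#' @export
build_time_course <- function(traces, control = NULL, window = c(0, 0.1),
                              t_eval = 0.002,
                              desensitization = c("auto", "double",
                                                  "single", "none"),
                              extend_slow = TRUE) {
  desensitization <- match.arg(desensitization)
  if (length(traces) < 1L) stop("no traces supplied", call. = FALSE)
  delays <- vapply(traces, function(x) as.numeric(x$delay_time), 0)
  if (anyNA(delays)) {
    stop("every trace must carry a delay_time", call. = FALSE)
  }
  conc <- vapply(traces, function(x) as.numeric(x$agonist_conc), 0)
  uc <- unique(conc[!is.na(conc)])
  if (length(uc) > 1L) {
    stop(sprintf(
      "traces mix agonist concentrations (%s); group them before building a time course",
      paste(format(uc), collapse = ", ")), call. = FALSE)
  }
  fit_one <- function(tr) {
    f <- fit_stretched_exp(tr, window = window)
    if (extend_slow && max(tr$time) > window[2] * 1.5) {
      tail_sel <- tr$time > window[2]
      pred <- .stretched_model(tr$time[tail_sel], f$F0, f$Finf, f$tau,
                               f$beta)
      rmse_tail <- sqrt(mean((pred - tr$fluorescence[tail_sel])^2))
      rmse_win <- sqrt(f$rss / sum(tr$time >= window[1] &
                                     tr$time <= window[2]))
      if (rmse_tail > 3 * rmse_win + 1e-3 * abs(f$F0)) {
        f <- fit_stretched_exp(tr, window = c(window[1], max(tr$time)))
      }
    }
    f
  }
  control_rate <- 0
  if (!is.null(control)) {
    control_rate <- if (is.numeric(control)) {
      control
    } else {
      flux_rate(fit_one(control), t_eval = t_eval)$k
    }
  }
  rates <- vapply(traces, function(tr) {
    flux_rate(fit_one(tr), t_eval = t_eval)$k - control_rate
  }, 0)
  ud <- sort(unique(delays))
  pts <- do.call(rbind, lapply(ud, function(d) {
    r <- rates[delays == d]
    data.frame(delay = d, mean_rate = mean(r),
               sem = if (length(r) > 1L) sd(r) / sqrt(length(r)) else 0,
               n = length(r))
  }))
  peak <- max(pts$mean_rate)
  des <- NULL
  if (desensitization != "none") {
    ipk <- which.max(pts$mean_rate)
    post <- pts[ipk:nrow(pts), ]
    model <- if (desensitization == "single") "single" else "double"
    need <- if (model == "double") 8L else 4L
    if (desensitization == "auto") {
      if (nrow(post) >= 8L) {
        des <- fit_decay(post$delay, post$mean_rate, model = "double")
      } else if (nrow(post) >= 4L) {
        des <- fit_decay(post$delay, post$mean_rate, model = "single")
      }  # else: too few points, omit quietly in auto mode
    } else {
      if (nrow(post) < need) {
        stop(sprintf(
          "desensitization fit refused: %d post-peak point(s), need %d for a %s-exponential",
          nrow(post), need, model), call. = FALSE)
      }
      des <- fit_decay(post$delay, post$mean_rate, model = model)
    }
  }
  structure(list(points = pts, peak_rate = peak, desensitization = des,
                 control_rate = if (is.null(control)) NA_real_ else
                   control_rate,
                 t_eval = t_eval, normalized = FALSE),
            class = "time_course")
}

#' Normalize a time course to its peak rate
#'
#' Rates and SEMs are scaled so the peak equals exactly 1; decay-fit
#' amplitudes are scaled identically (time constants unchanged). Idempotent.
#'
#' @param tc a `time_course`.
#' @return the normalized `time_course`.
#' @export
normalize_time_course <- function(tc) {
  if (!inherits(tc, "time_course")) stop("not a time_course", call. = FALSE)
  if (!is.finite(tc$peak_rate) || tc$peak_rate <= 0) {
    stop("cannot normalize: peak rate is not positive", call. = FALSE)
  }
  s <- 1 / tc$peak_rate
  tc$points$mean_rate <- tc$points$mean_rate * s
  tc$points$sem <- tc$points$sem * s
  if (!is.null(tc$desensitization)) {
    tc$desensitization$components$A <- tc$desensitization$components$A * s
  }
  tc$peak_rate <- 1
  tc$normalized <- TRUE
  tc
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("<time_course> %d delays, peak rate = %.4g 1/s%s\n",
              nrow(x$points), x$peak_rate,
              if (isTRUE(x$normalized)) " (normalized)" else ""))
  if (!is.null(x$desensitization)) {
    cat(sprintf("  desensitization weighted tau = %.4g s (%s)\n",
                x$desensitization$weighted_tau, x$desensitization$model))
  }
  invisible(x)
}
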