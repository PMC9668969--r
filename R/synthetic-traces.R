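## Synthetic stopped-flow data: stretched-exponential quenching traces,
## delay series with activation/desensitization, and Hill dose-response
## records, all with recorded ground truth.

#' Parameters for one synthetic quenching trace
#'
#' Describes a stretched-exponential fluorescence decay
#' \eqn{F(t) = F_\infty + (F_0 - F_\infty) e^{-(t/\tau)^\beta}} sampled on a
#' uniform time grid with optional additive Gaussian noise.
#'
#' @param F0 initial fluorescence (a.u.).
#' @param Finf final fluorescence (a.u.); must be below `F0` for a quenching
#'   trace unless the amplitude is exactly zero (`F0 == Finf`).
#' @param tau stretched-exponential time constant (s, > 0).
#' @param beta stretching exponent, in (0, 1.5].
#' @param noise_sd additive Gaussian noise s.d. (a.u., >= 0).
#' @param n_points number of samples (>= 2).
#' @param duration trace duration (s, > 0); samples are uniform on
#'   `[0, duration]`.
#' @param seed integer seed; fully determines the noise realisation.
#' @return an object of class `trace_params`.
#' @export
trace_params <- function(F0 = 1, Finf = 0, tau = 0.1, beta = 0.85,
                         noise_sd = 0, n_points = 1000L, duration = 1,
                         seed = 1L) {
  .check_num(F0, "F0")
  .check_num(Finf, "Finf")
  if (Finf > F0) .bad_param("Finf", "must be <= F0 for a quenching trace")
  .check_num(tau, "tau", lower = 0, strict_lower = TRUE)
  .check_num(beta, "beta", lower = 0, upper = 1.5, strict_lower = TRUE)
  .check_num(noise_sd, "noise_sd", lower = 0)
  .check_num(n_points, "n_points", lower = 2)
  .check_num(duration, "duration", lower = 0, strict_lower = TRUE)
  .check_num(seed, "seed")
  structure(list(F0 = F0, Finf = Finf, tau = tau, beta = beta,
                 noise_sd = noise_sd, n_points = as.integer(n_points),
                 duration = duration, seed = as.integer(seed)),
            class = "trace_params")
}

#' Construct a quenching trace object
#'
#' @param time strictly increasing sample times (s), starting at >= 0.
#' @param fluorescence fluorescence values (a.u.), same length as `time`.
#' @param delay_time delay between agonist and thallium mixing (s), or `NA`.
#' @param agonist_conc agonist concentration (mM), or `NA`.
#' @param label free-text label.
#' @return an object of class `quench_trace`.
#' @export
quench_trace <- function(time, fluorescence, delay_time = NA_real_,
                         agonist_conc = NA_real_, label = "") {
  if (length(time) != length(fluorescence)) {
    .bad_param("fluorescence", "must match length of `time`")
  }
  .check_num(time, "time", len = NULL, lower = 0)
  if (any(diff(time) <= 0)) .bad_param("time", "must be strictly increasing")
  .check_num(fluorescence, "fluorescence", len = NULL)
  structure(list(time = time, fluorescence = fluorescence,
                 delay_time = delay_time, agonist_conc = agonist_conc,
                 label = as.character(label)),
            class = "quench_trace")
}

#' @export
print.quench_trace <- function(x, ...) {
  cat(sprintf("<quench_trace> %d points, %.4g-%.4g s, delay = %s s%s\n",
              length(x$time), min(x$time), max(x$time),
              format(x$delay_time),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

## noiseless stretched-exponential model
.stretched_model <- function(t, F0, Finf, tau, beta) {
  Finf + (F0 - Finf) * exp(-(t / tau)^beta)
}

#' Generate one synthetic quenching trace
#'
#' At `noise_sd = 0` every sample equals the stretched-exponential model
#' exactly; with noise, i.i.d. Gaussian deviates are added. The generating
#' parameters are attached as attribute `"truth"`.
#'
#' @param params a [trace_params()] object.
#' @param delay_time,agonist_conc,label metadata copied onto the trace.
#' @return a [quench_trace()].
#' @examples
#' tr <- gen_quench_trace(trace_params(tau = 0.05, beta = 0.8, seed = 7))
#' @export
gen_quench_trace <- function(params, delay_time = NA_real_,
                             agonist_conc = NA_real_, label = "") {
  if (!inherits(params, "trace_params")) {
    params <- do.call(trace_params, as.list(params))
  }
  t <- seq(0, params$duration, length.out = params$n_points)
  f <- .stretched_model(t, params$F0, params$Finf, params$tau, params$beta)
  if (params$noise_sd > 0) {
    f <- f + .with_seed(.substream(params$seed, 101L),
                        rnorm(length(t), 0, params$noise_sd))
  }
  out <- quench_trace(t, f, delay_time = delay_time,
                      agonist_conc = agonist_conc, label = label)
  attr(out, "truth") <- params
  out
}

#' Scenario for a delay-series gating experiment
#'
#' Emulates the sequential-mixing protocol: proteoliposomes are mixed with
#' agonist, then with thallium after a variable delay, so the flux rate
#' traced out over delays reports channel activation followed by
#' biexponential desensitization.
#'
#' The true rate at delay \eqn{d} is
#' \deqn{r(d) \propto (1 - e^{-d/\tau_{act}})\,(A_1 e^{-d/\tau_1} + A_2 e^{-d/\tau_2})}
#' rescaled so its maximum over the delay grid equals `peak_rate`.
#'
#' @param peak_rate peak flux rate over the delay grid (1/s).
#' @param activation_tau activation time constant (s); activation is faster
#'   than the first delay in the default protocol.
#' @param A1,A2 amplitude fractions of the desensitization components,
#'   `A1 + A2 == 1`.
#' @param tau1,tau2 desensitization time constants (s, > 0).
#' @param delay_times delay grid (s); default log-spaced 10 ms to 25 s.
#' @param replicates traces per delay (default 5).
#' @param beta stretching exponent given to every generated trace.
#' @param noise_sd additive noise s.d. on unit-amplitude traces.
#' @param n_points,duration trace sampling (see [trace_params()]).
#' @param seed integer seed.
#' @return an object of class `gating_scenario`.
#' @export
gating_scenario <- function(peak_rate = 17.5, activation_tau = 0.005,
                            A1 = 0.7, tau1 = 2, A2 = 0.3, tau2 = 20,
                            delay_times = 10^seq(log10(0.01), log10(25),
                                                 length.out = 18),
                            replicates = 5L, beta = 0.85, noise_sd = 0.005,
                            n_points = 1000L, duration = 1, seed = 1L) {
  .check_num(peak_rate, "peak_rate", lower = 0, strict_lower = TRUE)
  .check_num(activation_tau, "activation_tau", lower = 0)
  .check_num(A1, "A1", lower = 0)
  .check_num(A2, "A2", lower = 0)
  if (abs(A1 + A2 - 1) > 1e-9) .bad_param("A1", "A1 + A2 must equal 1")
  .check_num(tau1, "tau1", lower = 0, strict_lower = TRUE)
  .check_num(tau2, "tau2", lower = 0, strict_lower = TRUE)
  .check_num(delay_times, "delay_times", len = NULL, lower = 0,
             strict_lower = TRUE)
  if (length(delay_times) < 1L) .bad_param("delay_times", "must be non-empty")
  .check_num(replicates, "replicates", lower = 1)
  .check_num(beta, "beta", lower = 0, upper = 1.5, strict_lower = TRUE)
  .check_num(noise_sd, "noise_sd", lower = 0)
  structure(list(peak_rate = peak_rate, activation_tau = activation_tau,
                 A1 = A1, tau1 = tau1, A2 = A2, tau2 = tau2,
                 delay_times = sort(delay_times),
                 replicates = as.integer(replicates), beta = beta,
                 noise_sd = noise_sd, n_points = as.integer(n_points),
                 duration = duration, seed = as.integer(seed)),
            class = "gating_scenario")
}

## true flux rate (1/s) at each delay, normalized to scenario peak over grid
.scenario_rates <- function(sc, delays = sc$delay_times) {
  act <- if (sc$activation_tau <= 0) 1 else 1 - exp(-delays / sc$activation_tau)
  des <- sc$A1 * exp(-delays / sc$tau1) + sc$A2 * exp(-delays / sc$tau2)
  raw <- act * des
  grid_act <- if (sc$activation_tau <= 0) 1 else
    1 - exp(-sc$delay_times / sc$activation_tau)
  grid_raw <- grid_act * (sc$A1 * exp(-sc$delay_times / sc$tau1) +
                          sc$A2 * exp(-sc$delay_times / sc$tau2))
  raw * sc$peak_rate / max(grid_raw)
}

## invert rate equation k = (beta/tau) (t_eval/tau)^(beta-1) for tau
.tau_for_rate <- function(k, beta, t_eval = 0.002) {
  (beta * t_eval^(beta - 1) / k)^(1 / beta)
}

#' Generate a delay series of quenching traces
#'
#' Each delay gets `replicates` traces whose stretched-exponential \eqn{\tau}
#' is solved so the instantaneous flux rate at 2 ms reproduces the
#' scenario's true rate at that delay (with the configured \eqn{\beta}).
#' Ground truth (per-delay true rates and taus) is attached as attribute
#' `"truth"`.
#'
#' @param scenario a [gating_scenario()].
#' @param t_eval evaluation time for the rate definition (s, default 2 ms).
#' @return list of [quench_trace()] objects, each tagged with its delay.
#' @export
gen_delay_series <- function(scenario, t_eval = 0.002) {
  if (!inherits(scenario, "gating_scenario")) {
    stop("`scenario` must be a gating_scenario", call. = FALSE)
  }
  rates <- .scenario_rates(scenario)
  taus <- .tau_for_rate(rates, scenario$beta, t_eval)
  traces <- vector("list", length(rates) * scenario$replicates)
  k <- 0L
  for (i in seq_along(rates)) {
    for (r in seq_len(scenario$replicates)) {
      k <- k + 1L
      p <- trace_params(F0 = 1, Finf = 0, tau = taus[i], beta = scenario$beta,
                        noise_sd = scenario$noise_sd,
                        n_points = scenario$n_points,
                        duration = scenario$duration,
                        seed = .substream(scenario$seed, 1000L * i + r))
      traces[[k]] <- gen_quench_trace(
        p, delay_time = scenario$delay_times[i], agonist_conc = 10,
        label = sprintf("delay_%g_rep_%d", scenario$delay_times[i], r))
    }
  }
  attr(traces, "truth") <- list(scenario = scenario, true_rates = rates,
                                true_taus = taus, t_eval = t_eval)
  traces
}

#' Generate synthetic dose-response records
#'
#' Noiseless response is the Hill curve
#' \eqn{top \cdot c^n / (c^n + EC_{50}^n)} with bottom fixed at 0.
#'
#' @param ec50 half-maximal concentration (mM, > 0).
#' @param hill_n Hill coefficient.
#' @param concentrations agonist concentrations (mM, >= 0), non-empty.
#' @param top maximal response (1/s).
#' @param noise_sd additive Gaussian noise s.d.
#' @param seed integer seed.
#' @return data.frame with columns `conc_mM`, `response`.
#' @export
gen_dose_series <- function(ec50, hill_n, concentrations, top = 1,
                            noise_sd = 0, seed = 1L) {
  .check_num(ec50, "ec50", lower = 0, strict_lower = TRUE)
  .check_num(hill_n, "hill_n", lower = 0, strict_lower = TRUE)
  if (length(concentrations) < 1L) {
    .bad_param("concentrations", "must be non-empty")
  }
  .check_num(concentrations, "concentrations", len = NULL, lower = 0)
  .check_num(noise_sd, "noise_sd", lower = 0)
  resp <- ifelse(concentrations == 0, 0,
                 top * concentrations^hill_n /
                   (concentrations^hill_n + ec50^hill_n))
  if (noise_sd > 0) {
    resp <- resp + .with_seed(.substream(seed, 202L),
                              rnorm(length(resp), 0, noise_sd))
  }
  out <- data.frame(conc_mM = concentrations, response = resp)
  attr(out, "truth") <- list(ec50 = ec50, hill_n = hill_n, top = top,
                             noise_sd = noise_sd, seed = seed)
  out
}
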