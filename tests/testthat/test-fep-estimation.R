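test_that("EXP estimates satisfy the closed-form identities", {
  w <- fep_window(0, 1, forward_work = rep(2.5, 5),
                  backward_work = rep(-2.5, 5))
  # constant forward work c -> dG = c
  expect_equal(exp_estimate(w, "forward")$value, 2.5, tolerance = 1e-12)
  # backward estimate sign-corrected to the forward convention
  expect_equal(exp_estimate(w, "backward")$value, 2.5, tolerance = 1e-12)

  # mirrored sample set negates the forward estimate
  set.seed(7)
  wf <- rnorm(200, 1, 0.5)
  wm <- fep_window(0, 1, forward_work = wf, backward_work = wf)
  f <- exp_estimate(wm, "forward")$value
  b <- exp_estimate(wm, "backward")$value
  expect_equal(b, -f, tolerance = 1e-12)

  # Gaussian closed form: dG = mu - sigma^2 / (2 RT), large n
  rt <- rt_kcal(303.15)
  set.seed(11)
  wg <- fep_window(0, 1, forward_work = rnorm(2e5, 2 + 1 / (2 * rt), 1),
                   backward_work = 0)
  expect_equal(exp_estimate(wg, "forward")$value, 2, tolerance = 0.05)

  expect_error(exp_estimate(fep_window(0, 1, forward_work = 1), "backward"),
               "backward")
})

test_that("BAR reduces to the midpoint for single equal-n samples", {
  w <- fep_window(0, 1, forward_work = 3, backward_work = 1)
  expect_equal(bar_estimate(w)$value, 1, tolerance = 1e-7)
  # symmetric samples -> exactly zero
  set.seed(3)
  s <- rnorm(100, 0.5, 1)
  ws <- fep_window(0, 1, forward_work = s, backward_work = s)
  expect_equal(bar_estimate(ws)$value, 0, tolerance = 1e-7)
})

test_that("BAR recovers the Crooks-Gaussian truth within its error", {
  ser <- gen_fep_dataset(fep_scenario(2.0, work_sd = 1,
                                      samples_per_window = 5000, seed = 42))
  e <- bar_estimate(ser$windows[[1]])
  expect_lt(abs(e$value - 2.0), 3 * e$stat_error)
  expect_gt(e$stat_error, 0)
  # EXP and BAR agree within 3 SE in the high-overlap limit (sigma ~ RT)
  f <- exp_estimate(ser$windows[[1]], "forward")
  b <- exp_estimate(ser$windows[[1]], "backward")
  tol3 <- 3 * (e$stat_error + f$stat_error + b$stat_error)
  expect_lt(abs(e$value - f$value), tol3)
  expect_lt(abs(e$value - b$value), tol3)
})

test_that("BAR lies between the EXP estimates once their bias separates", {
  # at sigma >> RT the forward EXP is biased high and the backward EXP low
  # (finite-sample Jensen bias), bracketing BAR; at high overlap all three
  # coincide and the ordering is random noise, so test where it is defined
  for (s in 1:10) {
    ser <- gen_fep_dataset(fep_scenario(2.0, work_sd = 4,
                                        samples_per_window = 2000,
                                        seed = 500 + s))
    w <- ser$windows[[1]]
    e <- suppressWarnings(bar_estimate(w)$value)
    f <- exp_estimate(w, "forward")$value
    b <- exp_estimate(w, "backward")$value
    expect_gte(e, min(f, b) - 1e-9)
    expect_lte(e, max(f, b) + 1e-9)
  }
})

test_that("reversing a window negates its BAR estimate exactly", {
  set.seed(9)
  w <- fep_window(0, 1, forward_work = rnorm(300, 1.2, 0.8),
                  backward_work = rnorm(200, -0.9, 0.8))
  wrev <- fep_window(0, 1, forward_work = w$backward_work,
                     backward_work = w$forward_work)
  expect_equal(bar_estimate(wrev)$value, -bar_estimate(w)$value,
               tolerance = 1e-7)
})

test_that("poor overlap triggers a warning with inflated error", {
  w <- fep_window(0, 1, forward_work = rnorm(50, 30, 0.5),
                  backward_work = rnorm(50, 20, 0.5))
  expect_warning(e <- bar_estimate(w), "overlap")
  expect_gt(e$stat_error, 1)
})

test_that("accumulate telescopes window estimates and validates coverage", {
  ser <- gen_fep_dataset(fep_scenario(c(1, -1), work_sd = 0.5,
                                      samples_per_window = 2000, seed = 1))
  acc <- accumulate(ser)
  expect_lt(abs(acc$total$value), 3 * acc$total$stat_error + 0.05)
  expect_equal(nrow(acc$profile), 3L)
  expect_equal(acc$profile$cum_dg[3], acc$total$value)

  # 10-window synthetic: profile tracks cumulative truth
  dg <- seq(-1, 1, length.out = 10)
  ser10 <- gen_fep_dataset(fep_scenario(dg, work_sd = 1,
                                        samples_per_window = 1000,
                                        seed = 2))
  acc10 <- accumulate(ser10)
  expect_lt(max(abs(acc10$profile$cum_dg[-1] - cumsum(dg))),
            3 * max(acc10$profile$cum_err))

  # single window spanning [0,1]: total equals that window's BAR
  w1 <- ser$windows[[1]]; w1$lambda_b <- 1
  s1 <- fep_series(list(w1))
  expect_equal(accumulate(s1, decorrelate = FALSE)$total$value,
               bar_estimate(ser$windows[[1]])$value, tolerance = 1e-9)

  # gap in coverage named
  g1 <- fep_window(0, 0.4, 1, 1); g2 <- fep_window(0.6, 1, 1, 1)
  expect_error(fep_series(list(g1, g2)), "gap")
})

test_that("hysteresis is zero for noiseless windows and flags bias", {
  wins <- lapply(1:5, function(i) {
    fep_window((i - 1) / 5, i / 5, forward_work = rep(0.5, 10),
               backward_work = rep(-0.5, 10))
  })
  hy <- hysteresis(fep_series(wins), decorrelate = FALSE)
  expect_equal(hy$per_window_delta, rep(0, 5), tolerance = 1e-12)

  # max |delta| shrinks with n
  d_small <- hysteresis(gen_fep_dataset(
    fep_scenario(rep(0.5, 5), work_sd = 1, samples_per_window = 100,
                 seed = 3)))$max_abs_delta
  d_big <- hysteresis(gen_fep_dataset(
    fep_scenario(rep(0.5, 5), work_sd = 1, samples_per_window = 10000,
                 seed = 3)))$max_abs_delta
  expect_lt(d_big, d_small)

  # constructed +1 kcal/mol backward bias: all deltas at unit magnitude
  # with one sign (+1 under this package's forward-convention backward
  # estimate), and the runs statistic flags the non-randomness
  ser <- gen_fep_dataset(fep_scenario(rep(0, 10), work_sd = 0.3,
                                      samples_per_window = 4000, seed = 6))
  ser$windows <- lapply(ser$windows, function(w) {
    w$backward_work <- w$backward_work + 1
    w
  })
  hyb <- hysteresis(ser)
  expect_true(all(abs(hyb$per_window_delta - 1) < 0.15))
  # all deltas share one sign: a single run, strongly non-random
  expect_equal(hyb$runs$n_runs, 1L)

  # missing direction errors with window indices
  bad <- fep_series(list(fep_window(0, 0.5, 1, 1),
                         fep_window(0.5, 1, 1, numeric(0))))
  expect_error(hysteresis(bad), "missing a work direction")
})

test_that("half_split detects drift and passes stationary series", {
  # exactly duplicated halves -> zero difference
  w <- fep_window(0, 1, forward_work = rep(c(1, 2), each = 4),
                  backward_work = rep(c(-1.5, -0.5), each = 4))
  w$forward_work <- c(1, 2, 3, 1, 2, 3)
  w$backward_work <- c(-1, -2, -3, -1, -2, -3)
  hs <- half_split(fep_series(list(w)), decorrelate = FALSE)
  expect_equal(hs$abs_diff, 0, tolerance = 1e-9)
  expect_true(hs$passes_1kcal)

  # stationary synthetic series passes in >= 18 of 20 seeds
  passes <- sum(vapply(1:20, function(s) {
    ser <- gen_fep_dataset(fep_scenario(rep(0.2, 5), work_sd = 1,
                                        samples_per_window = 400,
                                        seed = 100 + s))
    half_split(ser)$passes_1kcal
  }, NA))
  expect_gte(passes, 18)

  # +2 kcal/mol second-half shift in one window -> flagged
  ser <- gen_fep_dataset(fep_scenario(rep(0, 5), work_sd = 0.5,
                                      samples_per_window = 1000, seed = 17))
  n <- length(ser$windows[[3]]$forward_work)
  ser$windows[[3]]$forward_work[(n %/% 2 + 1):n] <-
    ser$windows[[3]]$forward_work[(n %/% 2 + 1):n] + 2
  ser$windows[[3]]$backward_work[(n %/% 2 + 1):n] <-
    ser$windows[[3]]$backward_work[(n %/% 2 + 1):n] - 2
  hs2 <- half_split(ser)
  expect_gte(hs2$abs_diff, 1)
  expect_false(hs2$passes_1kcal)

  wshort <- fep_window(0, 1, forward_work = 1, backward_work = c(1, 2))
  expect_error(half_split(fep_series(list(wshort))), "< 2 samples")
})

test_that("statistical inefficiency matches i.i.d. and AR(1) closed forms", {
  set.seed(31)
  g_iid <- statistical_inefficiency(rnorm(1e4))$g
  expect_lt(abs(g_iid - 1), 0.1)

  # AR(1), phi = 0.9: g -> (1 + phi)/(1 - phi) = 19
  phi <- 0.9
  x <- as.numeric(stats::arima.sim(list(ar = phi), n = 1e5))
  g_ar <- statistical_inefficiency(x)$g
  expect_lt(abs(g_ar - 19) / 19, 0.25)

  # alternating series clamps to 1
  alt <- rep(c(1, -1), 50)
  res <- statistical_inefficiency(alt)
  expect_equal(res$g, 1)
  expect_equal(res$indices, seq_along(alt))

  # constant series: g = 1 by convention
  expect_equal(statistical_inefficiency(rep(2, 10))$g, 1)
  expect_error(statistical_inefficiency(c(1, 2, 3)), "at least 4")
})

test_that("aggregate_replicas uses SEM across replicas or passthrough", {
  mk <- function(v, e = 0.3) structure(list(value = v, stat_error = e,
                                            method = "BAR",
                                            n_effective = 10),
                                       class = "dg_estimate")
  five <- aggregate_replicas(lapply(rep(-17, 5), mk))
  expect_equal(five$value, -17)
  expect_equal(five$stat_error, 0)
  expect_equal(five$mode, "sem_replicas")

  three <- aggregate_replicas(lapply(c(-16, -17, -18), mk))
  expect_equal(three$value, -17)
  expect_equal(three$stat_error, 1 / sqrt(3), tolerance = 1e-9)

  one <- aggregate_replicas(list(mk(-21, 0.7)))
  expect_equal(one$value, -21)
  expect_equal(one$stat_error, 0.7)
  expect_equal(one$mode, "single_replica")
  expect_error(aggregate_replicas(list()), "no replica")
})

test_that("lambda schedules are linear with stored electrostatics onset", {
  s40 <- make_lambda_schedule(40, elec_start = 0.25)
  expect_length(s40$values, 41L)
  expect_equal(unique(round(diff(s40$values), 12)), 0.025)
  expect_equal(s40$elec_start, 0.25)
  s120 <- make_lambda_schedule(120)
  expect_equal(diff(s120$values)[1], 1 / 120, tolerance = 1e-12)
  expect_equal(range(s120$values), c(0, 1))
  expect_error(make_lambda_schedule(0), "n_windows")
})

test_that("DBC is frame-invariant and matches a direct RMSD oracle", {
  g <- oracle_site_geometry()
  ref <- dbc_reference(g$frame, g$glycerol)
  # snapshot = reference -> 0
  expect_equal(dbc(list(frame = g$frame, glycerol = g$glycerol), ref), 0,
               tolerance = 1e-10)
  # invariance under 20 random rigid motions
  set.seed(5)
  for (i in 1:20) {
    R <- oracle_random_rotation(); tvec <- rnorm(3, 0, 50)
    snap <- list(frame = g$frame %*% R + rep(tvec, each = nrow(g$frame)),
                 glycerol = g$glycerol %*% R +
                   rep(tvec, each = nrow(g$glycerol)))
    expect_lt(dbc(snap, ref), 1e-8)
  }
  # uniform +1 A glycerol displacement after the frame transform -> 1.0
  R <- oracle_random_rotation(); tvec <- c(5, -3, 8)
  snap <- list(frame = g$frame %*% R + rep(tvec, each = nrow(g$frame)),
               glycerol = (g$glycerol +
                             matrix(c(1, 0, 0), nrow(g$glycerol), 3,
                                    byrow = TRUE)) %*% R +
                 rep(tvec, each = nrow(g$glycerol)))
  expect_equal(dbc(snap, ref), 1.0, tolerance = 1e-8)
  expect_error(dbc(list(frame = g$frame[1:3, ] * 0, glycerol = g$glycerol),
                   ref), "frame")
})

test_that("dbc_wall implements the linear-interpolation percentile", {
  expect_equal(dbc_wall(rep(3, 25)), 3)
  set.seed(8)
  u <- runif(20000, 0, 10)
  expect_equal(dbc_wall(u, 95), 9.5, tolerance = 0.05)
  expect_equal(dbc_wall(u, 100), max(u))
  expect_error(dbc_wall(u[1:5]), "at least 20")
})
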