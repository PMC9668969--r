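## Independent oracles used across the suite.  These stay deliberately
## naive/brute-force and must not call into the code paths they check.

## three-state Boltzmann partition: weights K_s * x_s relative to POPE
oracle_occupancy <- function(ddg_from_ref, comp, temperature = 303.15) {
  rt <- 0.0019872041 * temperature
  w <- exp(-ddg_from_ref / rt) * comp
  w / sum(w)
}

## dense grid search of the stretched-exponential RSS with linear profiling
oracle_stretched_grid <- function(t, y, tau_grid, beta_grid) {
  best <- list(rss = Inf)
  for (tau in tau_grid) {
    for (beta in beta_grid) {
      b <- exp(-(t / tau)^beta)
      cf <- stats::lm.fit(cbind(1, b), y)$coefficients
      rss <- sum((y - cf[1] - cf[2] * b)^2)
      if (rss < best$rss) best <- list(rss = rss, tau = tau, beta = beta)
    }
  }
  best
}

## central finite difference of (t/tau)^beta at t
oracle_rate_fd <- function(tau, beta, t, h = 1e-7) {
  (((t + h) / tau)^beta - ((t - h) / tau)^beta) / (2 * h)
}

## random rotation matrix for invariance tests
oracle_random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## small well-conditioned frame/glycerol geometry
oracle_site_geometry <- function() {
  list(frame = rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0), c(1, 1, 5),
                     c(-2, 3, 1)),
       glycerol = rbind(c(1, 1, 1), c(2, 1.5, 0.5), c(1.2, 2.5, 1.8)))
}
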