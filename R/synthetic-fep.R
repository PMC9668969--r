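## Synthetic alchemical work samples obeying the Crooks fluctuation relation,
## and rigid-body coordinate snapshots for the DBC coordinate.

#' Scenario for a synthetic bidirectional FEP dataset
#'
#' For a window with true free-energy change \eqn{\Delta G} and work s.d.
#' \eqn{\sigma}, forward work is drawn from
#' \eqn{N(\Delta G + \sigma^2/2RT,\ \sigma^2)} and reverse-direction work
#' from \eqn{N(-\Delta G + \sigma^2/2RT,\ \sigma^2)}; this Gaussian pair
#' satisfies the Crooks relation exactly.
#'
#' @param true_dg_per_window per-window true free-energy changes (kcal/mol).
#' @param work_sd work distribution s.d. (kcal/mol, > 0).
#' @param samples_per_window samples per direction per window (>= 1).
#' @param temperature temperature (K).
#' @param seed integer seed.
#' @return an object of class `fep_scenario`.
#' @export
fep_scenario <- function(true_dg_per_window, work_sd = 1,
                         samples_per_window = 100L, temperature = 303.15,
                         seed = 1L) {
  .check_num(true_dg_per_window, "true_dg_per_window", len = NULL)
  if (length(true_dg_per_window) < 1L) {
    .bad_param("true_dg_per_window", "must be non-empty")
  }
  .check_num(work_sd, "work_sd", lower = 0, strict_lower = TRUE)
  .check_num(samples_per_window, "samples_per_window", lower = 1)
  .check_num(temperature, "temperature", lower = 0, strict_lower = TRUE)
  structure(list(true_dg_per_window = true_dg_per_window, work_sd = work_sd,
                 samples_per_window = as.integer(samples_per_window),
                 temperature = temperature, seed = as.integer(seed)),
            class = "fep_scenario")
}

#' Generate a Crooks-Gaussian FEP series
#'
#' @param scenario a [fep_scenario()].
#' @return a [fep_series()] whose windows tile `[0, 1]` uniformly; the
#'   generating scenario is attached as attribute `"truth"`.
#' @examples
#' ser <- gen_fep_dataset(fep_scenario(c(1, -1), samples_per_window = 50))
#' @export
gen_fep_dataset <- function(scenario) {
  if (!inherits(scenario, "fep_scenario")) {
    stop("`scenario` must be a fep_scenario", call. = FALSE)
  }
  nw <- length(scenario$true_dg_per_window)
  lam <- seq(0, 1, length.out = nw + 1L)
  rt <- rt_kcal(scenario$temperature)
  shift <- scenario$work_sd^2 / (2 * rt)
  windows <- .with_seed(.substream(scenario$seed, 303L), {
    lapply(seq_len(nw), function(i) {
      dg <- scenario$true_dg_per_window[i]
      fw <- rnorm(scenario$samples_per_window, dg + shift, scenario$work_sd)
      bw <- rnorm(scenario$samples_per_window, -dg + shift, scenario$work_sd)
      fep_window(lam[i], lam[i + 1L], fw, bw,
                 temperature = scenario$temperature)
    })
  })
  out <- fep_series(windows)
  attr(out, "truth") <- scenario
  out
}

#' Scenario for synthetic binding-site coordinate snapshots
#'
#' Each snapshot is a rigid transform of the protein-frame atoms plus the
#' lipid glycerol atoms, with optional Gaussian jitter applied to the
#' glycerol atoms only (after the transform). The jitter is exactly what the
#' distance-to-bound-configuration (DBC) coordinate should report after
#' frame superposition.
#'
#' @param frame_coords n x 3 matrix of protein-frame atom coordinates (A);
#'   at least 3 non-collinear atoms.
#' @param glycerol_coords m x 3 matrix of lipid glycerol atom coordinates (A).
#' @param rigid_rotation fixed 3 x 3 rotation (det +1), or `NULL` to draw a
#'   fresh random rotation per snapshot.
#' @param translation fixed 3-vector (A), or `NULL` for random per snapshot.
#' @param jitter_sd glycerol jitter s.d. (A, >= 0).
#' @param n_snapshots number of snapshots.
#' @param seed integer seed.
#' @return an object of class `site_geometry_scenario`.
#' @export
site_geometry_scenario <- function(frame_coords, glycerol_coords,
                                   rigid_rotation = NULL, translation = NULL,
                                   jitter_sd = 0, n_snapshots = 10L,
                                   seed = 1L) {
  frame_coords <- as.matrix(frame_coords)
  glycerol_coords <- as.matrix(glycerol_coords)
  if (ncol(frame_coords) != 3L || nrow(frame_coords) < 3L) {
    .bad_param("frame_coords", "must be an n x 3 matrix with n >= 3")
  }
  if (.is_collinear(frame_coords)) {
    .bad_param("frame_coords",
               "atoms are collinear; superposition is underdetermined")
  }
  if (ncol(glycerol_coords) != 3L || nrow(glycerol_coords) < 1L) {
    .bad_param("glycerol_coords", "must be an m x 3 matrix with m >= 1")
  }
  if (!is.null(rigid_rotation)) {
    rigid_rotation <- as.matrix(rigid_rotation)
    if (!all(dim(rigid_rotation) == c(3L, 3L)) ||
        max(abs(crossprod(rigid_rotation) - diag(3))) > 1e-8 ||
        abs(det(rigid_rotation) - 1) > 1e-8) {
      .bad_param("rigid_rotation", "must be orthonormal with determinant +1")
    }
  }
  if (!is.null(translation)) .check_num(translation, "translation", len = 3L)
  .check_num(jitter_sd, "jitter_sd", lower = 0)
  .check_num(n_snapshots, "n_snapshots", lower = 1)
  structure(list(frame_coords = frame_coords,
                 glycerol_coords = glycerol_coords,
                 rigid_rotation = rigid_rotation, translation = translation,
                 jitter_sd = jitter_sd, n_snapshots = as.integer(n_snapshots),
                 seed = as.integer(seed)),
            class = "site_geometry_scenario")
}

.is_collinear <- function(x, tol = 1e-8) {
  xc <- sweep(x, 2, colMeans(x))
  s <- svd(xc, nu = 0, nv = 0)$d
  s[2] <= tol * max(s[1], 1)
}

## uniform random rotation (QR of a Gaussian matrix, det fixed to +1)
.random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- diag(sign(diag(qr.R(qr_))))
  q <- q %*% d
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate rigid-motion coordinate snapshots with known DBC
#'
#' @param scenario a [site_geometry_scenario()].
#' @return list of snapshots, each `list(frame =, glycerol =)`; attribute
#'   `"truth"` holds the per-snapshot true DBC values (RMS glycerol jitter).
#' @export
gen_site_coords <- function(scenario) {
  if (!inherits(scenario, "site_geometry_scenario")) {
    stop("`scenario` must be a site_geometry_scenario", call. = FALSE)
  }
  m <- nrow(scenario$glycerol_coords)
  .with_seed(.substream(scenario$seed, 404L), {
    snaps <- vector("list", scenario$n_snapshots)
    true_dbc <- numeric(scenario$n_snapshots)
    for (i in seq_len(scenario$n_snapshots)) {
      rot <- scenario$rigid_rotation
      if (is.null(rot)) rot <- .random_rotation()
      trans <- scenario$translation
      if (is.null(trans)) trans <- rnorm(3, 0, 20)
      fr <- scenario$frame_coords %*% rot +
        matrix(trans, nrow(scenario$frame_coords), 3, byrow = TRUE)
      gl <- scenario$glycerol_coords %*% rot +
        matrix(trans, m, 3, byrow = TRUE)
      if (scenario$jitter_sd > 0) {
        jit <- matrix(rnorm(3 * m, 0, scenario$jitter_sd), m, 3)
        gl <- gl + jit
        true_dbc[i] <- sqrt(mean(rowSums(jit^2)))
      }
      snaps[[i]] <- list(frame = fr, glycerol = gl)
    }
    attr(snaps, "truth") <- list(scenario = scenario, dbc = true_dbc)
    snaps
  })
}
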