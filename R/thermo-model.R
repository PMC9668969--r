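## Allosteric lipid-site model: relative binding constants, occupancy
## curves, x50, and conformational-stability landscapes over the ternary
## POPC/POPE/POPG simplex.

#' Relative binding constant from a replacement free energy
#'
#' \eqn{K^{ab} = \exp(-\Delta\Delta G^{a \to b} / RT)}: the binding constant
#' of species `b` relative to species `a` for one site/conformation.
#'
#' @param ddg replacement free energy (kcal/mol).
#' @param temperature temperature (K, default 303.15).
#' @return dimensionless relative binding constant.
#' @export
relative_K <- function(ddg, temperature = 303.15) {
  .check_num(ddg, "ddg", len = NULL)
  exp(-ddg / rt_kcal(temperature))
}

#' Build the relative-affinity matrix for one conformation
#'
#' Constructs replacement free energies for every ordered species pair from
#' a common reference species (POPE, the shared origin of the packaged
#' transformations), so the matrix is cycle-consistent by construction:
#' \eqn{K^{ab} K^{ba} = 1} and \eqn{K^{ab} K^{bc} = K^{ac}} exactly.
#'
#' @param table a [transform_free_energies()].
#' @param conformation `"WT_CA"` or `"ELIC5_CA"`.
#' @param bulk_label bulk row used as the cycle reference (default
#'   `"2:1:1"`, the mixture underlying the published occupancy curves;
#'   other bulk rows are selectable).
#' @param temperature temperature (K) for the Boltzmann conversion.
#' @param reference reference species for matrix construction.
#' @return object of class `affinity_matrix`: 3 x 3 matrix `K` (rows = from
#'   species a, cols = to species b), plus `conformation`, `temperature`,
#'   `bulk_label`, and the per-species `ddg_from_ref` used.
#' @export
affinity_matrix <- function(table, conformation, bulk_label = "2:1:1",
                            temperature = 303.15, reference = "POPE") {
  .check_species(reference, "reference")
  ddg_ref <- vapply(.LIPID_SPECIES, function(sp) {
    if (sp == reference) 0 else
      ddg_replacement(table, conformation, bulk_label,
                      from = reference, to = sp)$ddg
  }, 0)
  err_ref <- vapply(.LIPID_SPECIES, function(sp) {
    if (sp == reference) 0 else
      ddg_replacement(table, conformation, bulk_label,
                      from = reference, to = sp)$err
  }, 0)
  K <- outer(ddg_ref, ddg_ref,
             function(a, b) exp(-(b - a) / rt_kcal(temperature)))
  dimnames(K) <- list(.LIPID_SPECIES, .LIPID_SPECIES)
  structure(list(K = K, conformation = conformation,
                 temperature = temperature, bulk_label = bulk_label,
                 reference = reference,
                 ddg_from_ref = setNames(ddg_ref, .LIPID_SPECIES),
                 err_from_ref = setNames(err_ref, .LIPID_SPECIES)),
            class = "affinity_matrix")
}

#' @export
print.affinity_matrix <- function(x, ...) {
  cat(sprintf("<affinity_matrix> %s (bulk ref %s, T = %g K)\n",
              x$conformation, x$bulk_label, x$temperature))
  print(signif(x$K, 4))
  invisible(x)
}

#' Ternary lipid composition
#'
#' @param x_POPC,x_POPE,x_POPG mole fractions, >= 0, summing to 1.
#' @return named numeric vector of class `composition`.
#' @export
composition <- function(x_POPC, x_POPE, x_POPG) {
  x <- c(POPC = x_POPC, POPE = x_POPE, POPG = x_POPG)
  .check_num(unname(x), "composition", len = 3L, lower = 0)
  if (abs(sum(x) - 1) > 1e-9) {
    .bad_param("composition", sprintf("mole fractions sum to %.12g, not 1",
                                      sum(x)))
  }
  structure(x, class = "composition")
}

## composition on the 2 POPC : 1 POPE : x POPG path
.path_composition <- function(x) {
  composition(2 / (3 + x), 1 / (3 + x), x / (3 + x))
}

#' Site occupancy probabilities at a composition
#'
#' For conformation M, the probability that the site is occupied by species
#' a is \eqn{p^a = (1 + K^{ab} x_b/x_a + K^{ac} x_c/x_a)^{-1}}, equivalent
#' to Boltzmann weights \eqn{K_a x_a / \sum_s K_s x_s}. Species with zero
#' mole fraction have zero occupancy; probabilities sum to 1 (the site is
#' never empty under the saturation assumption).
#'
#' @param K an [affinity_matrix()].
#' @param comp a [composition()] (or 3-vector of mole fractions in
#'   POPC, POPE, POPG order).
#' @return named occupancy vector of class `occupancy_result`.
#' @export
occupancy <- function(K, comp) {
  if (!inherits(K, "affinity_matrix")) {
    stop("`K` must be an affinity_matrix", call. = FALSE)
  }
  if (!inherits(comp, "composition")) {
    comp <- composition(comp[[1]], comp[[2]], comp[[3]])
  }
  ref <- K$reference
  w <- K$K[ref, ] * as.numeric(comp)   # K_s (relative to ref) * x_s
  p <- w / sum(w)
  structure(setNames(p, .LIPID_SPECIES), class = "occupancy_result")
}

#' Occupancy curve along the 2:1:x POPG titration path
#'
#' Each grid value x is normalized to the composition
#' \eqn{(2, 1, x)/(3 + x)} before evaluating [occupancy()].
#'
#' @param K an [affinity_matrix()].
#' @param x_grid non-negative POPG path coordinates.
#' @return data.frame with columns `x` (path coordinate), `x_POPG`
#'   (normalized mole fraction) and `p_POPC`, `p_POPE`, `p_POPG`.
#' @export
occupancy_curve <- function(K, x_grid) {
  .check_num(x_grid, "x_grid", len = NULL, lower = 0)
  rows <- lapply(x_grid, function(x) {
    p <- occupancy(K, .path_composition(x))
    data.frame(x = x, x_POPG = x / (3 + x),
               p_POPC = p[["POPC"]], p_POPE = p[["POPE"]],
               p_POPG = p[["POPG"]])
  })
  do.call(rbind, rows)
}

#' POPG mole fraction at half-maximal site occupancy (x50)
#'
#' Solves \eqn{p^{POPG}(x) = 1/2} on the 2:1:x path by bisection in
#' \eqn{\log x} to a relative tolerance of 1e-6. Reported both as the raw
#' path coordinate x and as the normalized mole fraction \eqn{x/(3+x)}.
#'
#' @param K an [affinity_matrix()].
#' @return list with `x50` (normalized POPG mole fraction), `x_raw` (path
#'   coordinate), and `p_at_x50` (diagnostic, ~0.5).
#' @export
x50 <- function(K) {
  pg <- function(x) occupancy(K, .path_composition(x))[["POPG"]] - 0.5
  lo <- 1e-12; hi <- 1e12
  if (pg(lo) > 0 || pg(hi) < 0) {
    stop("POPG occupancy does not cross 50% on the 2:1:x path",
         call. = FALSE)
  }
  ## bisection on log x; p_POPG is monotone increasing along the path
  llo <- log(lo); lhi <- log(hi)
  while ((lhi - llo) > 1e-6 * 1e-3) {   # relative tol 1e-6 on x (log scale)
    mid <- (llo + lhi) / 2
    if (pg(exp(mid)) > 0) lhi <- mid else llo <- mid
    if ((lhi - llo) < 1e-9) break
  }
  x <- exp((llo + lhi) / 2)
  list(x50 = x / (3 + x), x_raw = x,
       p_at_x50 = occupancy(K, .path_composition(x))[["POPG"]])
}

#' Log-ratio of conformational stabilities at a composition
#'
#' \deqn{\Delta\log\frac{p_{open}}{p_{closed}} =
#'   \log\frac{x_C + K^{CE}_{open} x_E + K^{CG}_{open} x_G}
#'            {x_C + K^{CE}_{closed} x_E + K^{CG}_{closed} x_G}}
#' relative to the pure-POPC reference, where the value is 0 by definition.
#' Positive values mean the open (gain-of-function) conformation is
#' stabilized by the lipid composition.
#'
#' @param K_open,K_closed [affinity_matrix()] objects for the two
#'   conformations (conventionally ELIC5 CA and WT CA).
#' @param comp a [composition()].
#' @param base `"natural"` (default) or `"log10"` for display.
#' @return the log stability ratio (dimensionless).
#' @export
stability_ratio <- function(K_open, K_closed, comp, base = c("natural",
                                                             "log10")) {
  base <- match.arg(base)
  if (!inherits(comp, "composition")) {
    comp <- composition(comp[[1]], comp[[2]], comp[[3]])
  }
  term <- function(K) {
    comp[["POPC"]] + K$K["POPC", "POPE"] * comp[["POPE"]] +
      K$K["POPC", "POPG"] * comp[["POPG"]]
  }
  num <- term(K_open); den <- term(K_closed)
  if (den <= 0 || num <= 0) {
    stop("degenerate stability ratio: non-positive partition term",
         call. = FALSE)
  }
  out <- log(num) - log(den)
  if (base == "log10") out <- out / log(10)
  out
}

#' Conformational-stability landscape over the ternary simplex
#'
#' Evaluates [stability_ratio()] on a barycentric grid of compositions with
#' `resolution * (resolution + 1) / 2` points (all non-negative integer
#' triples summing to `resolution - 1`, scaled to mole fractions).
#'
#' @param K_open,K_closed [affinity_matrix()] objects.
#' @param resolution grid resolution (>= 2).
#' @param base log base, as in [stability_ratio()].
#' @return data.frame of class `stability_map` with columns `x_POPC`,
#'   `x_POPE`, `x_POPG`, `delta_log`.
#' @export
stability_map <- function(K_open, K_closed, resolution = 25L,
                          base = c("natural", "log10")) {
  base <- match.arg(base)
  .check_num(resolution, "resolution", lower = 2)
  n <- as.integer(resolution) - 1L
  rows <- list(); k <- 0L
  for (i in 0:n) {        # POPC count
    for (j in 0:(n - i)) {  # POPE count
      k <- k + 1L
      comp <- composition(i / n, j / n, (n - i - j) / n)
      rows[[k]] <- data.frame(x_POPC = comp[["POPC"]],
                              x_POPE = comp[["POPE"]],
                              x_POPG = comp[["POPG"]],
                              delta_log = stability_ratio(K_open, K_closed,
                                                          comp, base = base))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "base") <- base
  class(out) <- c("stability_map", "data.frame")
  out
}

#' Monte-Carlo propagation of table uncertainties
#'
#' Draws each directed table entry from \eqn{N(\Delta G, err)}, rebuilds the
#' affinity matrices and recomputes x50 for both conformations and the
#' stability log-ratio at a chosen composition, reporting percentile
#' intervals. Draws are seed-deterministic.
#'
#' @param table a [transform_free_energies()].
#' @param n_draws number of Monte-Carlo draws (>= 2).
#' @param seed integer seed.
#' @param bulk_label,temperature forwarded to [affinity_matrix()].
#' @param comp composition at which the stability ratio is propagated
#'   (default pure POPG).
#' @param probs percentile probabilities for the reported intervals.
#' @return list with per-quantity matrices of quantiles (`x50_WT_CA`,
#'   `x50_ELIC5_CA`, `K_CG_WT_CA`, `K_CG_ELIC5_CA`, `delta_log`) and the
#'   raw draws.
#' @export
propagate_table_errors <- function(table, n_draws = 1000L, seed = 1L,
                                   bulk_label = "2:1:1",
                                   temperature = 303.15,
                                   comp = composition(0, 0, 1),
                                   probs = c(0.025, 0.5, 0.975)) {
  .check_num(n_draws, "n_draws", lower = 2)
  ent <- table$entries
  draws <- .with_seed(.substream(seed, 707L), {
    lapply(seq_len(n_draws), function(i) {
      e <- ent
      e$dg_kcal_mol <- rnorm(nrow(e), ent$dg_kcal_mol, ent$err_kcal_mol)
      e$err_kcal_mol <- 0
      tb <- transform_free_energies(e)
      kw <- affinity_matrix(tb, "WT_CA", bulk_label, temperature)
      k5 <- affinity_matrix(tb, "ELIC5_CA", bulk_label, temperature)
      c(x50_WT_CA = x50(kw)$x50,
        x50_ELIC5_CA = x50(k5)$x50,
        K_CG_WT_CA = kw$K["POPC", "POPG"],
        K_CG_ELIC5_CA = k5$K["POPC", "POPG"],
        delta_log = stability_ratio(k5, kw, comp))
    })
  })
  m <- do.call(rbind, draws)
  qs <- apply(m, 2, quantile, probs = probs)
  list(quantiles = qs, draws = m, n_draws = as.integer(n_draws),
       seed = as.integer(seed))
}
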