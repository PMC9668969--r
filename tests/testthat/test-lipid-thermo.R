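tb <- load_packaged_table()

test_that("the packaged table loads with 10 directed entries", {
  expect_s3_class(tb, "transform_free_energies")
  expect_equal(nrow(tb$entries), 10L)
  expect_setequal(unique(tb$entries$environment),
                  c("2:1:1", "3:1_PC:PG", "POPC", "WT_CA", "ELIC5_CA"))
})

test_that("lookups resolve directly, by antisymmetry, and by composition", {
  expect_equal(fte_lookup(tb, "ELIC5_CA", "POPE", "POPG")$dg, -24)
  expect_equal(fte_lookup(tb, "ELIC5_CA", "POPG", "POPE")$dg, 24)
  expect_equal(fte_lookup(tb, "WT_CA", "POPG", "POPG")$dg, 0)
  # POPC -> POPG composed through POPE: (E->G) - (E->C)
  cg <- fte_lookup(tb, "WT_CA", "POPC", "POPG")
  expect_equal(cg$dg, -19 - 5)
  expect_equal(cg$err, sqrt(2^2 + 1^2))
  expect_error(fte_lookup(tb, "nope", "POPE", "POPG"), "environment")
})

test_that("antisymmetry conflicts are rejected, consistent reverses kept", {
  e <- tb$entries
  ok <- rbind(e, data.frame(environment = "2:1:1", species_from = "POPG",
                            species_to = "POPE", dg_kcal_mol = 17,
                            err_kcal_mol = 2))
  expect_s3_class(transform_free_energies(ok), "transform_free_energies")
  bad <- rbind(e, data.frame(environment = "2:1:1", species_from = "POPG",
                             species_to = "POPE", dg_kcal_mol = 10,
                             err_kcal_mol = 2))
  expect_error(transform_free_energies(bad), "antisymmetry")
})

test_that("ddg_replacement matches the thermodynamic-cycle subtractions", {
  e5 <- ddg_replacement(tb, "ELIC5_CA", "2:1:1", "POPE", "POPG")
  expect_equal(e5$ddg, -24 - (-17))   # -7 kcal/mol
  expect_equal(e5$err, sqrt(2^2 + 2^2))
  wt <- ddg_replacement(tb, "WT_CA", "2:1:1", "POPE", "POPG")
  expect_equal(wt$ddg, -19 - (-17))   # -2 kcal/mol
  expect_equal(ddg_replacement(tb, "WT_CA", "2:1:1", "POPG", "POPG")$ddg, 0)
  expect_error(ddg_replacement(tb, "WT_CA", "no_such_bulk"), "environment")
})

test_that("relative_K implements the Boltzmann conversion", {
  rt <- rt_kcal(303.15)
  expect_equal(relative_K(0), 1)
  expect_equal(relative_K(-rt * log(10)), 10, tolerance = 1e-12)
  # high-precision check of exp(2/RT) at 303.15 K
  expect_equal(relative_K(-2), exp(2 / rt), tolerance = 1e-14)
})

test_that("affinity matrices are cycle-consistent by construction", {
  for (conf in c("WT_CA", "ELIC5_CA")) {
    K <- affinity_matrix(tb, conf)$K
    expect_equal(diag(K), c(POPC = 1, POPE = 1, POPG = 1))
    for (a in rownames(K)) for (b in colnames(K)) {
      expect_equal(K[a, b] * K[b, a], 1, tolerance = 1e-12)
      for (c3 in rownames(K)) {
        expect_equal(K[a, b] * K[b, c3], K[a, c3], tolerance = 1e-12)
      }
    }
  }
})

test_that("occupancy matches the Boltzmann partition oracle", {
  kw <- affinity_matrix(tb, "WT_CA")
  # neutral affinities: p_a = x_a
  e0 <- tb$entries; e0$dg_kcal_mol <- 0; e0$err_kcal_mol <- 0
  k_neutral <- affinity_matrix(transform_free_energies(e0), "WT_CA")
  p <- occupancy(k_neutral, composition(0.5, 0.3, 0.2))
  expect_equal(as.numeric(p), c(0.5, 0.3, 0.2), tolerance = 1e-12)

  # single-species membrane
  expect_equal(occupancy(kw, composition(1, 0, 0))[["POPC"]], 1)

  # oracle agreement at 100 random compositions to 1e-12
  set.seed(19)
  for (i in 1:100) {
    x <- runif(3); x <- x / sum(x)
    p_pkg <- as.numeric(occupancy(kw, composition(x[1], x[2], x[3])))
    p_orc <- oracle_occupancy(kw$ddg_from_ref, x)
    expect_equal(p_pkg, unname(p_orc), tolerance = 1e-12)
    expect_equal(sum(p_pkg), 1, tolerance = 1e-12)
  }
  expect_error(occupancy(kw, composition(0.5, 0.2, 0.2)), "sum")
})

test_that("occupancy_curve follows the 2:1:x path and is monotone", {
  kw <- affinity_matrix(tb, "WT_CA")
  grid <- c(0, 10^seq(-4, 2, length.out = 40))
  cur <- occupancy_curve(kw, grid)
  expect_equal(cur$p_POPG[1], 0)                 # x = 0 -> no POPG
  expect_true(all(diff(cur$p_POPG) >= -1e-12))   # monotone nondecreasing
  # composition normalization: 2/(3+x), 1/(3+x), x/(3+x)
  expect_equal(cur$x_POPG, grid / (3 + grid))
  # large x -> p_POPG -> 1
  expect_gt(occupancy_curve(kw, 1e8)$p_POPG, 0.999)
  expect_error(occupancy_curve(kw, c(-1, 2)), "x_grid")
})

test_that("x50 solves half occupancy; neutral affinities give 0.5", {
  e0 <- tb$entries; e0$dg_kcal_mol <- 0; e0$err_kcal_mol <- 0
  k_neutral <- affinity_matrix(transform_free_energies(e0), "WT_CA")
  res <- x50(k_neutral)
  expect_equal(res$x_raw, 3, tolerance = 1e-6)
  expect_equal(res$x50, 0.5, tolerance = 1e-6)

  kw <- affinity_matrix(tb, "WT_CA")
  rw <- x50(kw)
  expect_equal(rw$p_at_x50, 0.5, tolerance = 1e-6)
  # x50 strictly decreases as bound dG(PE->PG) becomes more negative
  vals <- vapply(c(-19, -21, -23), function(dg) {
    e <- tb$entries
    e$dg_kcal_mol[e$environment == "WT_CA" &
                    e$species_to == "POPG"] <- dg
    x50(affinity_matrix(transform_free_energies(e), "WT_CA"))$x50
  }, 0)
  expect_true(all(diff(vals) < 0))
})

test_that("stability ratio has the exact single-species limits", {
  kw <- affinity_matrix(tb, "WT_CA")
  k5 <- affinity_matrix(tb, "ELIC5_CA")
  # pure POPC: 0 by definition, exactly
  expect_identical(stability_ratio(k5, kw, composition(1, 0, 0)), 0)
  # pure POPG: log(K_CG_open / K_CG_closed)
  expect_equal(stability_ratio(k5, kw, composition(0, 0, 1)),
               log(k5$K["POPC", "POPG"] / kw$K["POPC", "POPG"]),
               tolerance = 1e-12)
  # identical matrices -> 0 everywhere
  set.seed(23)
  for (i in 1:20) {
    x <- runif(3); x <- x / sum(x)
    expect_equal(stability_ratio(kw, kw, composition(x[1], x[2], x[3])), 0)
  }
  # log10 display option scales by ln 10
  v <- stability_ratio(k5, kw, composition(0.2, 0.3, 0.5))
  expect_equal(stability_ratio(k5, kw, composition(0.2, 0.3, 0.5),
                               base = "log10"), v / log(10))
})

test_that("stability_map covers the simplex with the stated grid size", {
  kw <- affinity_matrix(tb, "WT_CA")
  k5 <- affinity_matrix(tb, "ELIC5_CA")
  res <- 12L
  map <- stability_map(k5, kw, resolution = res)
  expect_equal(nrow(map), res * (res + 1) / 2)
  expect_equal(rowSums(map[, 1:3]), rep(1, nrow(map)), tolerance = 1e-12)
  # pure-POPC vertex exactly zero
  expect_identical(map$delta_log[map$x_POPC == 1], 0)
  # POPG edge monotone when K_CG_open > K_CG_closed (true for this table)
  edge <- map[map$x_POPE == 0, ]
  edge <- edge[order(edge$x_POPG), ]
  expect_true(all(diff(edge$delta_log) > 0))
})

test_that("Monte-Carlo error propagation behaves sanely", {
  # zero errors -> degenerate intervals at the point estimates
  e0 <- tb$entries; e0$err_kcal_mol <- 0
  t0 <- transform_free_energies(e0)
  pr0 <- propagate_table_errors(t0, n_draws = 20, seed = 2)
  pt <- x50(affinity_matrix(t0, "WT_CA"))$x50
  expect_equal(unname(pr0$quantiles[, "x50_WT_CA"]), rep(pt, 3),
               tolerance = 1e-9)

  # interval width grows with the errors; median tracks point estimate
  mk_err <- function(err) {
    e <- tb$entries; e$err_kcal_mol <- err
    propagate_table_errors(transform_free_energies(e), n_draws = 400,
                           seed = 3)
  }
  w_small <- mk_err(0.5); w_big <- mk_err(2.0)
  spread <- function(pr) diff(log10(range(pr$quantiles[, "x50_WT_CA"])))
  expect_gt(spread(w_big), spread(w_small))
  expect_equal(log10(unname(w_small$quantiles[2, "x50_WT_CA"])),
               log10(x50(affinity_matrix(tb, "WT_CA"))$x50),
               tolerance = 0.15)
  # determinism
  expect_equal(mk_err(0.5)$quantiles, w_small$quantiles)
  expect_error(propagate_table_errors(tb, n_draws = 1), "n_draws")
})
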