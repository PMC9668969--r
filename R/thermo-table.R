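## Transformation free-energy tables: lipid a -> b alchemical free energies
## per environment (bulk membrane composition or bound protein conformation),
## with antisymmetry and cycle bookkeeping.

.LIPID_SPECIES <- c("POPC", "POPE", "POPG")
.CONFORMATIONS <- c("WT_CA", "ELIC5_CA")

.check_species <- function(x, field = "species") {
  if (!all(x %in% .LIPID_SPECIES)) {
    .bad_param(field, paste("must be one of", paste(.LIPID_SPECIES,
                                                    collapse = ", ")))
  }
  x
}

#' Construct a transformation free-energy table
#'
#' Each entry is the alchemical free energy of transforming lipid species
#' `from` into `to` within an `environment` — either a bulk membrane
#' composition label (e.g. `"2:1:1"`) or a bound protein conformation
#' (`"WT_CA"`, `"ELIC5_CA"`). Antisymmetry
#' \eqn{\Delta G(a \to b) = -\Delta G(b \to a)} is enforced on construction:
#' reverse entries are derivable, and conflicting duplicates are an error.
#'
#' @param entries data.frame with columns `environment`, `species_from`,
#'   `species_to`, `dg_kcal_mol`, `err_kcal_mol`.
#' @return object of class `transform_free_energies`.
#' @export
transform_free_energies <- function(entries) {
  need <- c("environment", "species_from", "species_to", "dg_kcal_mol",
            "err_kcal_mol")
  if (!all(need %in% names(entries))) {
    stop(sprintf("table must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  entries <- entries[, need]
  .check_species(entries$species_from, "species_from")
  .check_species(entries$species_to, "species_to")
  .check_num(entries$dg_kcal_mol, "dg_kcal_mol", len = NULL)
  .check_num(entries$err_kcal_mol, "err_kcal_mol", len = NULL, lower = 0)
  ## antisymmetry conflict check (a->b given twice, or alongside b->a)
  key_f <- paste(entries$environment, entries$species_from,
                 entries$species_to)
  key_r <- paste(entries$environment, entries$species_to,
                 entries$species_from)
  for (i in seq_len(nrow(entries))) {
    dup <- which(key_f == key_f[i])
    if (any(abs(entries$dg_kcal_mol[dup] - entries$dg_kcal_mol[i]) > 1e-6)) {
      stop(sprintf("conflicting duplicate entries for (%s, %s->%s)",
                   entries$environment[i], entries$species_from[i],
                   entries$species_to[i]), call. = FALSE)
    }
    rev <- which(key_f == key_r[i])
    if (any(abs(entries$dg_kcal_mol[rev] + entries$dg_kcal_mol[i]) > 1e-6)) {
      stop(sprintf(
        "antisymmetry conflict for (%s, %s<->%s): %g vs %g",
        entries$environment[i], entries$species_from[i],
        entries$species_to[i], entries$dg_kcal_mol[i],
        entries$dg_kcal_mol[rev[1]]), call. = FALSE)
    }
  }
  structure(list(entries = unique(entries)), class = "transform_free_energies")
}

#' @export
print.transform_free_energies <- function(x, ...) {
  cat(sprintf("<transform_free_energies> %d directed entries, environments: %s\n",
              nrow(x$entries),
              paste(unique(x$entries$environment), collapse = ", ")))
  invisible(x)
}

#' Look up a transformation free energy
#'
#' Resolves directly, by antisymmetry, or by composing through a common
#' third species (cycle closure); `from == to` returns 0.
#'
#' @param table a [transform_free_energies()].
#' @param environment environment label.
#' @param from,to lipid species.
#' @return list with `dg` and `err` (kcal/mol).
#' @export
fte_lookup <- function(table, environment, from, to) {
  .check_species(from, "from"); .check_species(to, "to")
  if (from == to) return(list(dg = 0, err = 0))
  e <- table$entries[table$entries$environment == environment, ]
  if (!nrow(e)) {
    stop(sprintf("no entries for environment '%s'", environment),
         call. = FALSE)
  }
  direct <- e[e$species_from == from & e$species_to == to, ]
  if (nrow(direct)) {
    return(list(dg = direct$dg_kcal_mol[1], err = direct$err_kcal_mol[1]))
  }
  rev <- e[e$species_from == to & e$species_to == from, ]
  if (nrow(rev)) {
    return(list(dg = -rev$dg_kcal_mol[1], err = rev$err_kcal_mol[1]))
  }
  ## compose through a third species: from -> c -> to
  for (c3 in setdiff(.LIPID_SPECIES, c(from, to))) {
    leg1 <- tryCatch(fte_lookup(table, environment, from, c3),
                     error = function(e) NULL)
    leg2 <- tryCatch(fte_lookup(table, environment, c3, to),
                     error = function(e) NULL)
    if (!is.null(leg1) && !is.null(leg2)) {
      return(list(dg = leg1$dg + leg2$dg,
                  err = sqrt(leg1$err^2 + leg2$err^2)))
    }
  }
  stop(sprintf("missing free-energy entry for (%s, %s->%s)", environment,
               from, to), call. = FALSE)
}

#' Relative free energy of lipid replacement at a bound site
#'
#' Thermodynamic-cycle difference
#' \eqn{\Delta\Delta G_{Bulk \to M}^{a \to b} = \Delta G_M^{a \to b} -
#' \Delta G_{Bulk}^{a \to b}}: the free energy of exchanging a bound lipid
#' of species `a` for a bulk lipid of species `b`. Errors combine in
#' quadrature.
#'
#' @param table a [transform_free_energies()].
#' @param conformation bound-state environment label (`"WT_CA"` or
#'   `"ELIC5_CA"`).
#' @param bulk_label bulk-environment label (default `"2:1:1"`).
#' @param from,to lipid species of the transformation.
#' @return list with `ddg` and `err` (kcal/mol).
#' @export
ddg_replacement <- function(table, conformation, bulk_label = "2:1:1",
                            from = "POPE", to = "POPG") {
  bound <- fte_lookup(table, conformation, from, to)
  bulk <- fte_lookup(table, bulk_label, from, to)
  list(ddg = bound$dg - bulk$dg, err = sqrt(bound$err^2 + bulk$err^2))
}

#' Load the packaged bound/bulk transformation free-energy table
#'
#' Convenience wrapper around [read_free_energy_table()] for the fixture
#' shipped in `inst/extdata` (POPE to POPC and POPE to POPG transformations
#' in three bulk compositions and two bound conformations, with their
#' reported uncertainties).
#'
#' @return a [transform_free_energies()].
#' @export
load_packaged_table <- function() {
  read_free_energy_table(system.file("extdata",
                                     "lipid_transform_free_energies.tsv",
                                     package = "fluxfep", mustWork = TRUE))
}
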