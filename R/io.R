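## File I/O: trace CSV, work-table TSV, NAMD fepout subset, free-energy
## tables, minimal PDB coordinates, and provenance-stamped writers.

.provenance_header <- function(seed = NA, extra = character(0)) {
  cfg <- paste(c(sprintf("fluxfep %s", as.character(packageVersion("fluxfep"))),
                 sprintf("seed=%s", format(seed)), extra), collapse = "; ")
  c(sprintf("# %s", cfg), sprintf("# config_hash=%s", .fnv1a(cfg)))
}

## FNV-1a 32-bit hash of a string, hex-encoded
.fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Read a quenching trace from CSV/TSV
#'
#' Expects two numeric columns (`time_s`, `fluorescence_au`); the header is
#' optional and the delimiter (comma or tab) is sniffed. Comment lines
#' starting with `#` may carry `delay_time_s=` / `agonist_conc_mM=`
#' metadata, which is picked up. Ragged rows raise an error naming the line.
#'
#' @param path file path.
#' @return a [quench_trace()].
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines)))) {
    stop(sprintf("empty trace file: %s", path), call. = FALSE)
  }
  meta <- grep("^#", lines, value = TRUE)
  pick <- function(key) {
    m <- regmatches(meta, regexpr(paste0(key, "=[^;[:space:]]+"), meta))
    m <- unlist(m)
    if (!length(m)) return(NA_real_)
    v <- sub(paste0(key, "="), "", m[1])
    if (identical(v, "NA")) NA_real_ else as.numeric(v)
  }
  delay <- pick("delay_time_s"); conc <- pick("agonist_conc_mM")
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  sep <- if (grepl("\t", body[1])) "\t" else ","
  nf <- vapply(strsplit(body, sep, fixed = TRUE), length, 0L)
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged row in %s at data line %d (%d fields, expected %d)",
                 path, bad, nf[bad], nf[1]), call. = FALSE)
  }
  first <- strsplit(body[1], sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  df <- read.table(text = paste(body, collapse = "\n"), sep = sep,
                   header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("trace file needs two columns", call. = FALSE)
  quench_trace(as.numeric(df[[1]]), as.numeric(df[[2]]),
               delay_time = delay, agonist_conc = conc,
               label = basename(path))
}

#' Write a quenching trace as CSV with a provenance header
#'
#' @param path output path.
#' @param trace a [quench_trace()].
#' @param seed seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(path, trace, seed = NA) {
  extra <- c(sprintf("delay_time_s=%s", format(trace$delay_time)),
             sprintf("agonist_conc_mM=%s", format(trace$agonist_conc)))
  hdr <- .provenance_header(seed, extra)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(hdr, "time_s,fluorescence_au"), con)
  writeLines(sprintf("%.15g,%.15g", trace$time, trace$fluorescence), con)
  invisible(path)
}

#' Write a fit result (or any list of scalars) as JSON
#'
#' Provenance (package version, seed, config hash) is embedded as a
#' `provenance` field since JSON has no comments.
#'
#' @param path output path.
#' @param fit a fit object (e.g. `stretched_exp_fit`, `hill_fit`).
#' @param seed seed recorded in provenance.
#' @return `path`, invisibly.
#' @export
write_fit <- function(path, fit, seed = NA) {
  x <- unclass(fit)
  x$provenance <- list(package = "fluxfep",
                       version = as.character(packageVersion("fluxfep")),
                       seed = seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read a bidirectional work table (TSV dialect)
#'
#' Columns: `window_index`, `lambda_a`, `lambda_b`, `direction`
#' (`fwd`/`bwd`), `work_kcal_mol`, `step`; one row per work sample. Rows
#' are ordered by `step` within each window/direction, so shuffled files
#' parse identically. A `# temperature_K=...` header is honoured.
#'
#' @param path file path.
#' @param temperature fallback temperature (K) if the file has no header.
#' @return a [fep_series()].
#' @export
read_work_table <- function(path, temperature = 303.15) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  m <- regmatches(meta, regexpr("temperature_K=[0-9.]+", meta))
  m <- unlist(m)
  if (length(m)) temperature <- as.numeric(sub("temperature_K=", "", m[1]))
  df <- read.table(text = paste(lines[!grepl("^#", lines)], collapse = "\n"),
                   header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("window_index", "lambda_a", "lambda_b", "direction",
            "work_kcal_mol", "step")
  if (!all(need %in% names(df))) {
    stop(sprintf("work table must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  bad <- setdiff(unique(df$direction), c("fwd", "bwd"))
  if (length(bad)) {
    stop(sprintf("unknown direction token(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  windows <- lapply(sort(unique(df$window_index)), function(wi) {
    d <- df[df$window_index == wi, ]
    la <- unique(d$lambda_a); lb <- unique(d$lambda_b)
    if (length(la) != 1L || length(lb) != 1L) {
      stop(sprintf("window %d has inconsistent lambda bounds", wi),
           call. = FALSE)
    }
    fw <- d[d$direction == "fwd", ]; bw <- d[d$direction == "bwd", ]
    fep_window(la, lb, fw$work_kcal_mol[order(fw$step)],
               bw$work_kcal_mol[order(bw$step)], temperature = temperature)
  })
  ## overlapping windows are a dialect violation distinct from gaps
  la <- vapply(windows, `[[`, 0, "lambda_a")
  lb <- vapply(windows, `[[`, 0, "lambda_b")
  o <- order(la)
  if (any(lb[o][-length(o)] - la[o][-1] > 1e-9)) {
    stop("overlapping lambda windows in work table", call. = FALSE)
  }
  fep_series(windows, replica_id = basename(path))
}

#' Write a FEP series in the work-table TSV dialect
#'
#' @param path output path.
#' @param series a [fep_series()].
#' @param seed seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_work_table <- function(path, series, seed = NA) {
  con <- file(path, "w"); on.exit(close(con))
  temp <- series$windows[[1]]$temperature
  writeLines(c(.provenance_header(seed, sprintf("temperature_K=%g", temp)),
               paste(c("window_index", "lambda_a", "lambda_b", "direction",
                       "work_kcal_mol", "step"), collapse = "\t")), con)
  for (i in seq_along(series$windows)) {
    w <- series$windows[[i]]
    for (dir in c("fwd", "bwd")) {
      ws <- if (dir == "fwd") w$forward_work else w$backward_work
      if (length(ws)) {
        writeLines(sprintf("%d\t%.10g\t%.10g\t%s\t%.15g\t%d", i,
                           w$lambda_a, w$lambda_b, dir, ws,
                           seq_along(ws)), con)
      }
    }
  }
  invisible(path)
}

#' Read a NAMD fepout subset into a FEP series
#'
#' Supported dialect subset: window headers
#' `#NEW FEP WINDOW: LAMBDA SET TO <a> LAMBDA2 <b> [LAMBDA_IDWS <c>]` and
#' `FepEnergy:` records whose 2nd field is the step and 7th field the
#' energy difference (work sample); the 10th field (accumulated dG) is
#' ignored for estimation. Without `LAMBDA_IDWS`, all records in a window
#' are forward (`b > a`) or backward (`b < a`) work; with it, records
#' alternate forward/backward starting forward (interleaved double-wide
#' sampling). Windows are merged on their forward lambda interval.
#'
#' @param path file path.
#' @param temperature temperature (K).
#' @return a [fep_series()].
#' @export
read_fepout <- function(path, temperature = 303.15) {
  lines <- readLines(path, warn = FALSE)
  acc <- list()  # key "a_b" -> list(la, lb, fwd, bwd)
  cur <- NULL
  push <- function(key, la, lb, fwd, bwd) {
    e <- acc[[key]]
    if (is.null(e)) e <- list(la = la, lb = lb, fwd = numeric(0),
                              bwd = numeric(0))
    e$fwd <- c(e$fwd, fwd); e$bwd <- c(e$bwd, bwd)
    acc[[key]] <<- e
  }
  flush <- function() {
    if (is.null(cur)) return(invisible())
    if (is.na(cur$idws)) {
      if (cur$lb > cur$la) {
        push(sprintf("%.8f_%.8f", cur$la, cur$lb), cur$la, cur$lb,
             cur$de, numeric(0))
      } else {
        push(sprintf("%.8f_%.8f", cur$lb, cur$la), cur$lb, cur$la,
             numeric(0), cur$de)
      }
    } else {
      ## IDWS: alternate fwd (toward lambda2) / bwd (toward lambda_idws)
      idx <- seq_along(cur$de)
      fwd <- cur$de[idx %% 2L == 1L]
      bwd <- cur$de[idx %% 2L == 0L]
      push(sprintf("%.8f_%.8f", cur$la, cur$lb), cur$la, cur$lb, fwd,
           numeric(0))
      push(sprintf("%.8f_%.8f", cur$idws, cur$la), cur$idws, cur$la,
           numeric(0), bwd)
    }
    cur <<- NULL
  }
  for (ln in lines) {
    if (grepl("^#NEW FEP WINDOW", ln)) {
      flush()
      toks <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      la <- as.numeric(toks[which(toks == "TO") + 1L])
      lb <- as.numeric(toks[which(toks == "LAMBDA2") + 1L])
      iw <- if ("LAMBDA_IDWS" %in% toks) {
        as.numeric(toks[which(toks == "LAMBDA_IDWS") + 1L])
      } else NA_real_
      cur <- list(la = la, lb = lb, idws = iw, de = numeric(0))
    } else if (grepl("^FepEnergy:", ln)) {
      if (is.null(cur)) {
        stop("FepEnergy record before any window header", call. = FALSE)
      }
      toks <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      if (length(toks) < 7L) {
        stop("malformed FepEnergy record", call. = FALSE)
      }
      cur$de <- c(cur$de, as.numeric(toks[7]))
    }
  }
  flush()
  if (!length(acc)) stop("no FEP windows found", call. = FALSE)
  windows <- lapply(acc, function(e) {
    fep_window(e$la, e$lb, e$fwd, e$bwd, temperature = temperature)
  })
  fep_series(unname(windows), replica_id = basename(path))
}

#' Read a transformation free-energy table (TSV or JSON)
#'
#' TSV schema: columns `environment`, `species_from`, `species_to`,
#' `dg_kcal_mol`, `err_kcal_mol`. JSON: an array of objects with the same
#' fields. Antisymmetric closure and conflict checking happen in
#' [transform_free_energies()].
#'
#' @param path file path (`.json` triggers JSON parsing).
#' @return a [transform_free_energies()].
#' @export
read_free_energy_table <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    read.table(path, header = TRUE, sep = "\t", comment.char = "#",
               stringsAsFactors = FALSE)
  }
  transform_free_energies(df)
}

#' Read coordinates from a minimal PDB file
#'
#' Fixed-column parser for `ATOM`/`HETATM` records; `MODEL`/`ENDMDL` split
#' multi-model files into snapshots. Only names, residue names and
#' coordinates are used.
#'
#' @param path file path.
#' @param atom_names optional atom-name filter (e.g. glycerol atoms
#'   `c("C1", "C2", "C3", "O21", "O31")`).
#' @param resnames optional residue-name filter.
#' @return list of models; each a list with `coords` (n x 3), `atom_name`,
#'   `resname`.
#' @export
read_pdb_coords <- function(path, atom_names = NULL, resnames = NULL) {
  lines <- readLines(path, warn = FALSE)
  models <- list(); current <- list(); in_model <- FALSE
  close_model <- function() {
    if (length(current)) {
      df <- do.call(rbind, current)
      models[[length(models) + 1L]] <<- list(
        coords = unname(as.matrix(df[, c("x", "y", "z")])),
        atom_name = df$name, resname = df$resname)
    }
    current <<- list()
  }
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (grepl("^MODEL", tag)) {
      close_model(); in_model <- TRUE
    } else if (grepl("^ENDMDL", tag)) {
      close_model()
    } else if (tag %in% c("ATOM  ", "HETATM")) {
      nm <- trimws(substr(ln, 13, 16))
      rn <- trimws(substr(ln, 18, 20))
      if ((!is.null(atom_names) && !(nm %in% atom_names)) ||
          (!is.null(resnames) && !(rn %in% resnames))) next
      current[[length(current) + 1L]] <- data.frame(
        name = nm, resname = rn,
        x = as.numeric(substr(ln, 31, 38)),
        y = as.numeric(substr(ln, 39, 46)),
        z = as.numeric(substr(ln, 47, 54)),
        stringsAsFactors = FALSE)
    }
  }
  close_model()
  if (!length(models)) stop(sprintf("no coordinates in %s", path),
                            call. = FALSE)
  models
}

#' Write a data frame as TSV with a provenance header
#'
#' @param path output path.
#' @param df data.frame.
#' @param seed seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(path, df, seed = NA) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.provenance_header(seed), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
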