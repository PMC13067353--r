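data_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("pp_data_error", "error")))
}

#' Read hydration frames from PDB or XYZ-like files
#'
#' PDB files (single model, fixed-width columns, parsed with bio3d) and
#' XYZ-like whitespace tables (possibly multi-frame: repeated blocks of
#' `n_atoms` / comment / `name x y z` lines) are supported. Water oxygens
#' are recognised by atom name (and, for PDB, residue name); the
#' excess-charge probe by its atom name.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @param probe_name Atom name of the excess-charge probe (default "CEC").
#' @param water_names Accepted water-oxygen atom names.
#' @param water_resnames Accepted water residue names (PDB only).
#' @return List of [hydration_frame()] objects.
#' @export
read_frames <- function(path, format = c("auto", "pdb", "xyz"),
                        probe_name = "CEC",
                        water_names = c("OW", "O", "OH2"),
                        water_resnames = c("HOH", "WAT", "SOL", "TIP3")) {
  format <- match.arg(format)
  if (!file.exists(path)) data_error("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path)
    at <- pdb$atom
    wat <- at$resid %in% water_resnames & at$elety %in% water_names
    prb <- at$elety == probe_name
    if (sum(prb) != 1L)
      data_error("expected exactly one probe atom named ", probe_name)
    if (sum(wat) == 0L) data_error("no water oxygens found")
    return(list(hydration_frame(
      as.matrix(at[wat, c("x", "y", "z")]),
      probe = as.numeric(at[prb, c("x", "y", "z")]))))
  }
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      data_error("malformed atom count at line ", i)
    if (i + 1L + nat > length(lines))
      data_error("truncated frame starting at line ", i)
    blk <- lines[(i + 2L):(i + 1L + nat)]
    tok <- strsplit(trimws(blk), "\\s+")
    bad <- which(vapply(tok, length, integer(1)) < 4L)
    if (length(bad))
      data_error("malformed atom record at line ", i + 1L + bad[1])
    nm <- vapply(tok, `[[`, character(1), 1L)
    xyz <- t(vapply(tok, function(t)
      suppressWarnings(as.numeric(t[2:4])), numeric(3)))
    if (anyNA(xyz)) {
      bad <- which(apply(is.na(xyz), 1, any))[1]
      data_error("non-numeric coordinate at line ", i + 1L + bad)
    }
    wat <- nm %in% water_names
    prb <- nm == probe_name
    if (sum(prb) != 1L)
      data_error("frame at line ", i, ": expected exactly one probe atom named ",
                 probe_name)
    frames[[length(frames) + 1L]] <-
      hydration_frame(xyz[wat, , drop = FALSE], probe = as.numeric(xyz[prb, ]))
    i <- i + 2L + nat
  }
  if (length(frames) == 0L) data_error("no frames in ", path)
  frames
}

#' Write hydration frames as a multi-frame XYZ-like file
#'
#' @param frames List of [hydration_frame()] objects.
#' @param path Output path.
#' @param probe_name Probe atom name (default "CEC").
#' @return `path`, invisibly.
#' @export
write_frames_xyz <- function(frames, path, probe_name = "CEC") {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    nw <- nrow(fr$water_oxygens)
    writeLines(c(sprintf("%d", nw + 1L), sprintf("frame %d", k)), con)
    writeLines(sprintf("OW %14.8f %14.8f %14.8f",
                       fr$water_oxygens[, 1], fr$water_oxygens[, 2],
                       fr$water_oxygens[, 3]), con)
    writeLines(sprintf("%s %14.8f %14.8f %14.8f", probe_name,
                       fr$probe[1], fr$probe[2], fr$probe[3]), con)
  }
  invisible(path)
}

#' Write path nodes
#'
#' `"table"` writes a whitespace table (index, x, y, z) with the frame
#' metadata in the header; `"pdb"` writes pseudo-atoms for visualisation.
#'
#' @param nodes A `path_nodes` object.
#' @param path Output path.
#' @param format `"table"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_path_nodes <- function(nodes, path, format = c("table", "pdb")) {
  format <- match.arg(format)
  stopifnot(inherits(nodes, "path_nodes"))
  if (format == "pdb") {
    n <- nodes$n_nodes
    bio3d::write.pdb(file = path, xyz = as.numeric(t(nodes$nodes)),
                     type = rep("HETATM", n), resno = seq_len(n),
                     resid = rep("NOD", n), elety = rep("ND", n))
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# path_nodes origin_index=%d orientation=%d",
                     nodes$origin_index, nodes$orientation), con)
  writeLines("# index x y z", con)
  writeLines(sprintf("%4d %16.10f %16.10f %16.10f", seq_len(nodes$n_nodes),
                     nodes$nodes[, 1], nodes$nodes[, 2], nodes$nodes[, 3]),
             con)
  invisible(path)
}

#' Read path nodes from a whitespace table
#'
#' @param path File written by [write_path_nodes()] (table format).
#' @return A `path_nodes` object.
#' @export
read_path_nodes <- function(path) {
  if (!file.exists(path)) data_error("file not found: ", path)
  lines <- readLines(path)
  meta <- grep("^# path_nodes", lines, value = TRUE)
  oi <- 1L; orient <- 1L
  if (length(meta)) {
    oi <- as.integer(sub(".*origin_index=(-?\\d+).*", "\\1", meta[1]))
    orient <- as.integer(sub(".*orientation=(-?\\d+).*", "\\1", meta[1]))
  }
  dat <- utils::read.table(text = lines[!grepl("^#", lines)])
  if (ncol(dat) < 4L) data_error("expected columns: index x y z")
  path_nodes(as.matrix(dat[, 2:4]), origin_index = oi, orientation = orient)
}

#' Write a COLVAR-style time series
#'
#' Whitespace columns with a `# FIELDS` header line naming them; any
#' restraints are recorded as `# RESTRAINT cv center k` header lines so the
#' file round-trips through [read_colvar()].
#'
#' @param series A `colvar_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_colvar <- function(series, path) {
  stopifnot(inherits(series, "colvar_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# FIELDS", paste(names(series), collapse = " ")), con)
  for (r in attr(series, "restraints") %||% list())
    writeLines(sprintf("# RESTRAINT %s %.10g %.10g", r$cv, r$center, r$k), con)
  utils::write.table(format(as.data.frame(series), digits = 12,
                            scientific = FALSE, trim = TRUE),
                     con, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a COLVAR-style time series
#'
#' @param path File written by [write_colvar()] (or any whitespace table
#'   with a `# FIELDS` header whose first field is `time`).
#' @return A `colvar_series`.
#' @export
read_colvar <- function(path) {
  if (!file.exists(path)) data_error("file not found: ", path)
  lines <- readLines(path)
  fh <- grep("^#\\s*FIELDS", lines, value = TRUE)
  if (!length(fh)) data_error("missing # FIELDS header in ", path)
  fields <- strsplit(trimws(sub("^#\\s*FIELDS", "", fh[1])), "\\s+")[[1]]
  rl <- grep("^#\\s*RESTRAINT", lines, value = TRUE)
  restraints <- lapply(rl, function(l) {
    tok <- strsplit(trimws(sub("^#\\s*RESTRAINT", "", l)), "\\s+")[[1]]
    restraint(tok[1], as.numeric(tok[2]), as.numeric(tok[3]))
  })
  if (length(restraints) == 0L) restraints <- NULL
  dat <- utils::read.table(text = lines[!grepl("^#", lines)])
  if (ncol(dat) != length(fields))
    data_error("column count does not match FIELDS header in ", path)
  names(dat) <- fields
  colvar_series(dat, restraints = restraints)
}

#' Write a HILLS-style metadynamics log
#'
#' @param hills A `hills_log`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hills <- function(hills, path) {
  stopifnot(inherits(hills, "hills_log"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# FIELDS", paste(names(hills), collapse = " ")),
               paste("# CV", attr(hills, "cv"))), con)
  utils::write.table(format(as.data.frame(hills), digits = 12,
                            scientific = FALSE, trim = TRUE),
                     con, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a HILLS-style metadynamics log
#'
#' @param path File written by [write_hills()].
#' @return A `hills_log`.
#' @export
read_hills <- function(path) {
  if (!file.exists(path)) data_error("file not found: ", path)
  lines <- readLines(path)
  fh <- grep("^#\\s*FIELDS", lines, value = TRUE)
  if (!length(fh)) data_error("missing # FIELDS header in ", path)
  fields <- strsplit(trimws(sub("^#\\s*FIELDS", "", fh[1])), "\\s+")[[1]]
  cvl <- grep("^#\\s*CV", lines, value = TRUE)
  cv <- if (length(cvl)) trimws(sub("^#\\s*CV", "", cvl[1])) else "phi_star"
  dat <- utils::read.table(text = lines[!grepl("^#", lines)])
  names(dat) <- fields
  dat$biasf[dat$biasf == "Inf"] <- Inf
  dat$biasf <- as.numeric(dat$biasf)
  hills_log(dat, cv = cv)
}

#' Write a free-energy grid file
#'
#' Whitespace grid file: one `# AXIS name min max n` header per axis, then
#' one row per bin (axis coordinates, F, SE, mask), round-trippable by
#' [read_fes()]. Masked bins carry `NA` free energies.
#'
#' @param grid An `fe_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fes <- function(grid, path) {
  stopifnot(inherits(grid, "fe_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ax in grid$axes)
    writeLines(sprintf("# AXIS %s %.10g %.10g %d", ax$name, ax$min, ax$max,
                       ax$n), con)
  writeLines(sprintf("# TEMPERATURE %g", grid$temperature), con)
  mids <- lapply(grid$axes, axis_mids)
  co <- if (grid$dim == 1L) {
    cbind(mids[[1]])
  } else {
    cbind(rep(mids[[1]], times = length(mids[[2]])),
          rep(mids[[2]], each = length(mids[[1]])))
  }
  df <- data.frame(co, F = as.numeric(grid$F), se = as.numeric(grid$se),
                   mask = as.integer(grid$mask))
  utils::write.table(format(df, digits = 12, scientific = FALSE, trim = TRUE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a free-energy grid file
#'
#' @param path File written by [write_fes()].
#' @return An `fe_grid`.
#' @export
read_fes <- function(path) {
  if (!file.exists(path)) data_error("file not found: ", path)
  lines <- readLines(path)
  axl <- grep("^#\\s*AXIS", lines, value = TRUE)
  if (!length(axl)) data_error("missing # AXIS header in ", path)
  axes <- lapply(axl, function(l) {
    tok <- strsplit(trimws(sub("^#\\s*AXIS", "", l)), "\\s+")[[1]]
    fe_axis(tok[1], as.numeric(tok[2]), as.numeric(tok[3]),
            as.integer(tok[4]))
  })
  tl <- grep("^#\\s*TEMPERATURE", lines, value = TRUE)
  temp <- if (length(tl))
    as.numeric(trimws(sub("^#\\s*TEMPERATURE", "", tl[1]))) else NA_real_
  dat <- utils::read.table(text = lines[!grepl("^#", lines)],
                           na.strings = "NA")
  nc <- ncol(dat)
  Fv <- suppressWarnings(as.numeric(dat[[nc - 2L]]))
  se <- suppressWarnings(as.numeric(dat[[nc - 1L]]))
  mask <- as.logical(as.integer(dat[[nc]]))
  dims <- vapply(axes, function(a) a$n, integer(1))
  shape <- function(v) if (length(dims) == 1L) v else matrix(v, dims[1], dims[2])
  fe_grid(axes, shape(Fv), se = shape(se), mask = shape(mask),
          temperature = temp)
}

#' Default analysis configuration
#'
#' Nested list of the default protocol: temperature 310 K, 25 path nodes,
#' occupancy switch (r0 = 2.5 A, exponents 6/12), metadynamics (hill height
#' 0.6 kcal/mol, sigma 0.02, bias factor 35, pace 1000, 8 walkers sharing
#' every 100 steps), umbrella protocols (130 windows for 2D, 24 for 1D;
#' force constants 2500 on phi*, 10-30 on xi*) and block averaging (8/4 for
#' 2D, 6/3 for 1D). Every field can be overridden.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    temperature = 310,
    path = list(n_nodes = 25L, smoothing = 0.10),
    cv = list(switch_r0 = 2.5, switch_n = 6L, switch_m = 12L,
              switch_dmax = 2.5 * 2.5, locality_sigma = 3, cap_k = 20),
    umbrella = list(
      `2d` = list(n_windows = 130L, n_xi = 13L, n_phi = 10L,
                  k_xi = 10, k_phi = 2500, blocks = 8L, keep_last = 4L),
      `1d` = list(n_windows = 24L, k_xi = 20, blocks = 6L, keep_last = 3L)),
    metad = list(height = 0.6, sigma = 0.02, bias_factor = 35,
                 pace = 1000L, n_walkers = 8L, share = 100L),
    wham = list(tol = 1e-7, max_iter = 1e5),
    sampler = list(timestep = 2e-4, friction = 1, stride = 10L),
    seed = 1L
  )
}

#' Read / write configuration files (YAML)
#'
#' @param path Config file path.
#' @return For `read_config()`, [default_config()] with the file's fields
#'   merged over it.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) data_error("file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_lists(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge_lists(default_config(), user)
}

#' @rdname read_config
#' @param config Configuration list to serialise.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
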