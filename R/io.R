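# Readers/writers for the package's on-disk formats: XYZ and multi-model PDB
# trajectories, unit-suffixed CSV series, multi-frame TIFF stacks with JSON
# sidecars, and point-charge tables.
#
# Conventions: time columns carry a unit suffix (time_s / time_ns); image
# arrays are row-major with origin top-left; frame indices are 0-based in
# file comments and 1-based inside R.

#' Write / read a trajectory in XYZ format
#'
#' Package XYZ dialect: one block per frame — atom count, then a comment
#' line `time_ns=<t>`, then one line per atom `group/name x y z` with
#' coordinates in Angstrom.
#'
#' @param traj A [trajectory].
#' @param path Output file.
#' @return `write_xyz`: `path`, invisibly. `read_xyz`: a [trajectory].
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  n_atoms <- nrow(traj$atoms)
  tag <- paste0(traj$atoms$group, "/", traj$atoms$name)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(traj$times)) {
    writeLines(c(
      as.character(n_atoms),
      sprintf("time_ns=%.9g", traj$times[k]),
      sprintf("%s %.6f %.6f %.6f", tag,
              traj$coords[, 1, k], traj$coords[, 2, k], traj$coords[, 3, k])
    ), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  pos <- 1L
  times <- numeric(0)
  frames <- list()
  atoms <- NULL
  frame_no <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) {
      pos <- pos + 1L
      next
    }
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n)) {
      stop("XYZ parse error at line ", pos, ": expected an atom count",
           call. = FALSE)
    }
    frame_no <- frame_no + 1L
    if (pos + 1L + n > length(lines)) {
      stop("XYZ parse error: truncated frame ", frame_no, " at line ", pos,
           call. = FALSE)
    }
    comment <- lines[pos + 1L]
    t_ns <- suppressWarnings(as.numeric(sub(".*time_ns=([-0-9.eE+]+).*", "\\1",
                                            comment)))
    if (is.na(t_ns)) {
      stop("XYZ parse error at line ", pos + 1L, ": no time_ns tag",
           call. = FALSE)
    }
    body <- lines[pos + 1L + seq_len(n)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(vapply(parts, length, integer(1)) != 4)
    if (length(bad) > 0) {
      stop("XYZ parse error at line ", pos + 1L + bad[1], call. = FALSE)
    }
    tags <- vapply(parts, `[[`, character(1), 1L)
    xyz <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                  ncol = 3, byrow = TRUE)
    gn <- strsplit(tags, "/", fixed = TRUE)
    frame_atoms <- data.frame(
      name = vapply(gn, function(v) v[length(v)], character(1)),
      group = vapply(gn, `[[`, character(1), 1L)
    )
    if (is.null(atoms)) {
      atoms <- frame_atoms
    } else if (nrow(atoms) != n) {
      stop("inconsistent atom count in frame ", frame_no, call. = FALSE)
    }
    times <- c(times, t_ns)
    frames[[frame_no]] <- xyz
    pos <- pos + 2L + n
  }
  if (frame_no < 2) stop("XYZ file has fewer than 2 frames", call. = FALSE)
  coords <- array(0, dim = c(nrow(atoms), 3, frame_no))
  for (k in seq_len(frame_no)) coords[, , k] <- frames[[k]]
  trajectory(times, coords, atoms)
}

# group label -> PDB chain id: F1..F5 -> A..E, G -> G, others cycle over
# remaining letters
.group_chain_map <- function(groups) {
  u <- unique(groups)
  chain <- character(length(u))
  names(chain) <- u
  for (g in u) {
    chain[g] <- if (grepl("^F[0-9]+$", g)) {
      LETTERS[as.integer(sub("F", "", g))]
    } else if (nchar(g) == 1) {
      g
    } else {
      NA_character_
    }
  }
  left <- setdiff(LETTERS, chain[!is.na(chain)])
  chain[is.na(chain)] <- left[seq_len(sum(is.na(chain)))]
  chain
}

#' Write / read a trajectory as a multi-model PDB
#'
#' Each frame becomes a `MODEL`/`ENDMDL` block of fixed-width `ATOM` records.
#' Filament subunit groups `F1`..`F5` map to chains `A`-`E` and the monomer
#' group `G` to chain `G`; frame times in ns are carried on `REMARK 250`
#' lines inside each model. Reading groups atoms by chain id (chains `A`-`E`
#' become `F1`..`F5` again).
#'
#' @param traj A [trajectory].
#' @param path Output file.
#' @param ca_only When reading: keep only atoms named `CA`.
#' @return `write_pdb_trajectory`: `path`, invisibly.
#'   `read_pdb_trajectory`: a [trajectory].
#' @export
write_pdb_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  chain <- .group_chain_map(traj$atoms$group)[traj$atoms$group]
  con <- file(path, "w")
  on.exit(close(con))
  n_atoms <- nrow(traj$atoms)
  for (k in seq_along(traj$times)) {
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf("REMARK 250 TIME_NS %.9g", traj$times[k]), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(n_atoms),
      substr(traj$atoms$name, 1, 4), "ALA", chain, seq_len(n_atoms),
      traj$coords[, 1, k], traj$coords[, 2, k], traj$coords[, 3, k],
      1.0, 0.0
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname write_pdb_trajectory
#' @export
read_pdb_trajectory <- function(path, ca_only = FALSE) {
  lines <- readLines(path)
  times <- numeric(0)
  frames <- list()
  atoms <- NULL
  cur <- NULL
  cur_atoms <- NULL
  cur_time <- NA_real_
  frame_no <- 0L
  chain_to_group <- function(ch) {
    ifelse(ch %in% LETTERS[1:5], paste0("F", match(ch, LETTERS[1:5])), ch)
  }
  flush_model <- function() {
    if (is.null(cur)) return()
    frame_no <<- frame_no + 1L
    if (is.null(atoms)) {
      atoms <<- cur_atoms
    } else if (nrow(cur_atoms) != nrow(atoms)) {
      stop("inconsistent atom count in model ", frame_no, call. = FALSE)
    }
    times <<- c(times, if (is.na(cur_time)) frame_no - 1 else cur_time)
    frames[[frame_no]] <<- cur
    cur <<- NULL
    cur_atoms <<- NULL
    cur_time <<- NA_real_
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    rec <- substr(ln, 1, 6)
    if (rec == "MODEL ") {
      cur <- matrix(numeric(0), ncol = 3)
      cur_atoms <- data.frame(name = character(0), group = character(0))
    } else if (startsWith(ln, "REMARK 250 TIME_NS")) {
      cur_time <- as.numeric(trimws(sub("REMARK 250 TIME_NS", "", ln)))
    } else if (rec == "ATOM  " || rec == "HETATM") {
      if (is.null(cur)) {  # single-model file without MODEL records
        cur <- matrix(numeric(0), ncol = 3)
        cur_atoms <- data.frame(name = character(0), group = character(0))
      }
      x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
      y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
      z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
      if (any(is.na(c(x, y, z)))) {
        stop("PDB parse error at line ", i, call. = FALSE)
      }
      cur <- rbind(cur, c(x, y, z))
      cur_atoms <- rbind(cur_atoms, data.frame(
        name = trimws(substr(ln, 13, 16)),
        group = chain_to_group(trimws(substr(ln, 22, 22)))
      ))
    } else if (rec == "ENDMDL") {
      flush_model()
    }
  }
  flush_model()
  if (frame_no < 2) stop("PDB trajectory has fewer than 2 models", call. = FALSE)
  coords <- array(0, dim = c(nrow(atoms), 3, frame_no))
  for (k in seq_len(frame_no)) coords[, , k] <- frames[[k]]
  traj <- trajectory(times, coords, atoms)
  if (ca_only) {
    keep <- traj$atoms$name == "CA"
    if (!any(keep)) stop("no CA atoms in trajectory", call. = FALSE)
    traj <- trajectory(traj$times, traj$coords[keep, , , drop = FALSE],
                       traj$atoms[keep, ])
  }
  traj
}

#' Read a trajectory, dispatching on format
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"xyz"` or `"pdb"`.
#' @param ca_only Keep only `CA` atoms (PDB only).
#' @return A [trajectory].
#' @export
read_trajectory <- function(path, format = c("auto", "xyz", "pdb"),
                            ca_only = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xyz = "xyz", pdb = "pdb",
      stop("cannot infer trajectory format from extension '", ext, "'",
           call. = FALSE))
  }
  switch(format,
    xyz = read_xyz(path),
    pdb = read_pdb_trajectory(path, ca_only = ca_only)
  )
}

# ---- CSV series ------------------------------------------------------------

.series_spec <- function(x) {
  if (inherits(x, "msd_series")) {
    list(cols = c("time_ns", "msd_A2"), data = data.frame(
      time_ns = x$times, msd_A2 = x$msd))
  } else if (inherits(x, "inter_distance_series")) {
    list(cols = c("time_ns", "delta_L_A"), data = data.frame(
      time_ns = x$times, delta_L_A = x$delta_L),
      header = c(l0_A = x$l0))
  } else if (inherits(x, "filament_track")) {
    list(cols = c("time_s", "length_um"), data = data.frame(
      time_s = x$times, length_um = x$lengths_um),
      header = c(source = x$source))
  } else if (inherits(x, "fluorescence_series")) {
    list(cols = c("time_s", "intensity_au"), data = data.frame(
      time_s = x$times, intensity_au = x$intensities),
      header = c(polymerization_start_s = x$polymerization_start,
                 label = x$label))
  } else {
    stop("unsupported series type", call. = FALSE)
  }
}

#' Write / read typed series as CSV
#'
#' Series CSVs have unit-suffixed column names (`time_ns,msd_A2`;
#' `time_s,length_um`; `time_s,intensity_au`; `time_ns,delta_L_A`) and carry
#' series metadata (e.g. `polymerization_start_s`) in leading `# key: value`
#' comment lines. Decimal points are always `.` regardless of locale, and
#' extra columns present in a file are preserved in the `extra` attribute.
#'
#' @param x An `msd_series`, `inter_distance_series`, `filament_track` or
#'   [fluorescence_series].
#' @param path File path.
#' @return `write_series`: `path` invisibly; `read_series`: the typed object.
#' @export
write_series <- function(x, path) {
  spec <- .series_spec(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(spec$header)) {
    writeLines(sprintf("# %s: %s", names(spec$header), spec$header), con)
  }
  utils::write.csv(spec$data, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @param type Which series type to construct: one of `"msd"`,
#'   `"interdist"`, `"track"`, `"fluorescence"`.
#' @export
read_series <- function(path, type = c("msd", "interdist", "track",
                                       "fluorescence")) {
  type <- match.arg(type)
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines)
  meta <- list()
  for (h in hdr_lines) {
    m <- regmatches(lines[h], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[h]))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  df <- utils::read.csv(text = lines[setdiff(seq_along(lines), hdr_lines)],
                        check.names = FALSE)
  need <- switch(type,
    msd = c("time_ns", "msd_A2"),
    interdist = c("time_ns", "delta_L_A"),
    track = c("time_s", "length_um"),
    fluorescence = c("time_s", "intensity_au")
  )
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- df[setdiff(names(df), need)]
  out <- switch(type,
    msd = msd_series(df$time_ns, df$msd_A2),
    interdist = structure(
      list(times = df$time_ns, delta_L = df$delta_L_A,
           l0 = as.numeric(meta$l0_A %||% NA),
           filament_selection = NA, monomer_selection = NA),
      class = "inter_distance_series"
    ),
    track = filament_track(df$time_s, df$length_um,
      source = meta$source %||% "extracted"),
    fluorescence = fluorescence_series(df$time_s, df$intensity_au,
      polymerization_start = as.numeric(meta$polymerization_start_s %||% 0),
      label = meta$label %||% "")
  )
  if (ncol(extra) > 0) attr(out, "extra") <- extra
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- TIFF stacks -----------------------------------------------------------

#' Write / read a timelapse stack as multi-frame TIFF + JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF pages scaled into `[0, 1]`; the
#' scale and offset, pixel size, frame interval, and anchor metadata go to a
#' `<path>.json` sidecar so that reading reproduces the original intensities.
#'
#' @param stack A `"timelapse_stack"`.
#' @param path TIFF file path; the sidecar is written next to it.
#' @return `write_stack`: `path` invisibly; `read_stack`: the stack.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "timelapse_stack"))
  d <- dim(stack$frames)
  lo <- min(stack$frames)
  hi <- max(stack$frames)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[3]), function(k) {
    (stack$frames[, , k] - lo) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(
    pixel_size_um = stack$pixel_size_um,
    frame_interval_s = stack$frame_interval_s,
    t0_s = stack$times_s[1],
    intensity_offset = lo, intensity_scale = scale,
    anchor_col = stack$anchor_col %||% NA,
    filament_row = stack$filament_row %||% NA
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("missing sidecar ", sidecar_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  frames <- array(0, dim = c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) {
    frames[, , k] <- pages[[k]] * meta$intensity_scale + meta$intensity_offset
  }
  t0 <- meta$t0_s %||% 0
  structure(
    list(frames = frames, pixel_size_um = meta$pixel_size_um,
         frame_interval_s = meta$frame_interval_s,
         times_s = t0 + (seq_along(pages) - 1) * meta$frame_interval_s,
         anchor_col = if (is.na(meta$anchor_col)) NULL else meta$anchor_col,
         filament_row = if (is.na(meta$filament_row)) NULL else meta$filament_row),
    class = "timelapse_stack"
  )
}

#' Write a kymograph as a CSV matrix and/or PNG image
#'
#' @param kymo A `"kymograph"`.
#' @param csv_path,png_path Output paths; `NULL` skips that output.
#' @return Invisibly, a character vector of the files written.
#' @export
write_kymograph <- function(kymo, csv_path = NULL, png_path = NULL) {
  stopifnot(inherits(kymo, "kymograph"))
  written <- character(0)
  if (!is.null(csv_path)) {
    utils::write.table(kymo$intensity, csv_path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    written <- c(written, csv_path)
  }
  if (!is.null(png_path)) {
    z <- kymo$intensity
    rng <- range(z)
    if (diff(rng) > 0) z <- (z - rng[1]) / diff(rng) else z <- z * 0
    grDevices::png(png_path, width = ncol(z) * 2, height = nrow(z) * 2)
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::image(t(z)[, rev(seq_len(nrow(z))), drop = FALSE],
                    axes = FALSE, useRaster = TRUE,
                    col = grDevices::gray.colors(256, 0, 1))
    grDevices::dev.off()
    written <- c(written, png_path)
  }
  invisible(written)
}

# ---- point-charge systems --------------------------------------------------

#' Write / read point-charge systems
#'
#' CSV dialect: columns `x,y,z,q` (Angstrom and elementary charges). PDB
#' dialect: `HETATM` records with the charge stored in the occupancy column
#' (columns 55-60), a minimal interchange convention for point-charge
#' models.
#'
#' @param system A [point_charges] system.
#' @param path File path.
#' @param label Label for the system read back.
#' @return Writers return `path` invisibly; readers a [point_charges].
#' @export
write_charges_csv <- function(system, path) {
  stopifnot(inherits(system, "point_charges"))
  utils::write.csv(data.frame(
    x = system$positions[, 1], y = system$positions[, 2],
    z = system$positions[, 3], q = system$charges
  ), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_charges_csv
#' @export
read_charges_csv <- function(path, label = "") {
  df <- utils::read.csv(path)
  missing_cols <- setdiff(c("x", "y", "z", "q"), names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  point_charges(as.matrix(df[c("x", "y", "z")]), df$q, label = label)
}

#' @rdname write_charges_csv
#' @export
write_charges_pdb <- function(system, path) {
  stopifnot(inherits(system, "point_charges"))
  n <- nrow(system$positions)
  writeLines(c(
    sprintf(
      "HETATM%5d  Q   CHG X%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(n), seq_len(n),
      system$positions[, 1], system$positions[, 2], system$positions[, 3],
      system$charges, 0
    ),
    "END"
  ), path)
  invisible(path)
}

#' @rdname write_charges_csv
#' @export
read_charges_pdb <- function(path, label = "") {
  lines <- grep("^(HETATM|ATOM  )", readLines(path), value = TRUE)
  if (length(lines) == 0) stop("no atom records in ", path, call. = FALSE)
  num <- function(a, b) as.numeric(substr(lines, a, b))
  point_charges(cbind(num(31, 38), num(39, 46), num(47, 54)), num(55, 60),
                label = label)
}
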