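## Readers/writers for the LAMMPS-dump-style trajectory dialect and two
## bond-table dialects (simple 3-column and ReaxFF-neighbour-list style).
## Internally everything is nm / ps; readers apply a unit map on ingest.

.unit_map <- function(units) {
  if (is.list(units)) {
    stopifnot(all(c("length", "velocity") %in% names(units)))
    return(units)
  }
  switch(units,
    nm = list(length = 1, velocity = 1),
    angstrom = list(length = 0.1, velocity = 0.1),  # A -> nm, A/ps -> nm/ps
    stop("unknown unit system '", units, "' (use 'nm', 'angstrom' or a list)")
  )
}

#' Read a trajectory from a LAMMPS-dump-style text file
#'
#' Expects repeated blocks of `ITEM: TIMESTEP` (the value is read as the time
#' in the file's time unit), `ITEM: NUMBER OF ATOMS`, an optional
#' `ITEM: BOX BOUNDS` block, and `ITEM: ATOMS <columns>` followed by one row
#' per atom. Column order is taken from the ATOMS header; `id`, `element`,
#' `x y z` and `vx vy vz` are all required (velocities feed the sputter
#' criterion). Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @param units `"nm"` (native), `"angstrom"`, or a
#'   `list(length = , velocity = )` of multiplicative factors to nm and nm/ps.
#' @param alphabet Allowed element symbols.
#' @param frame_interval Optional nominal frame spacing (ps).
#' @return An [md_trajectory()].
#' @export
read_trajectory <- function(path, units = "nm", alphabet = c("H", "C", "O"),
                            frame_interval = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  um <- .unit_map(units)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  frames <- list()
  i <- 1L
  n_lines <- length(lines)
  fail <- function(i, msg) {
    stop("parse error at line ", if (i <= length(lineno)) lineno[i] else "EOF",
         ": ", msg)
  }
  while (i <= n_lines) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (!grepl("^ITEM: TIMESTEP", lines[i])) fail(i, "expected 'ITEM: TIMESTEP'")
    time <- suppressWarnings(as.numeric(trimws(lines[i + 1L])))
    if (is.na(time)) fail(i + 1L, "timestep value is not numeric")
    i <- i + 2L
    if (i > n_lines || !grepl("^ITEM: NUMBER OF ATOMS", lines[i])) {
      fail(i, "expected 'ITEM: NUMBER OF ATOMS'")
    }
    n_atoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n_atoms) || n_atoms < 0) fail(i + 1L, "atom count is not a non-negative integer")
    i <- i + 2L
    if (i <= n_lines && grepl("^ITEM: BOX BOUNDS", lines[i])) i <- i + 4L
    if (i > n_lines || !grepl("^ITEM: ATOMS", lines[i])) fail(i, "expected 'ITEM: ATOMS'")
    cols <- strsplit(trimws(sub("^ITEM: ATOMS", "", lines[i])), "\\s+")[[1]]
    required <- c("id", "element", "x", "y", "z", "vx", "vy", "vz")
    missing <- setdiff(required, cols)
    if (length(missing)) {
      fail(i, paste0("ATOMS header lacks required column(s): ",
                     paste(missing, collapse = ", ")))
    }
    i <- i + 1L
    if (i + n_atoms - 1L > n_lines) fail(n_lines, "truncated atom block")
    block <- lines[seq.int(i, length.out = n_atoms)]
    fields <- strsplit(trimws(block), "\\s+")
    bad <- which(lengths(fields) != length(cols))
    if (length(bad)) fail(i + bad[1L] - 1L, "wrong number of columns in atom row")
    mat <- do.call(rbind, fields)
    colnames(mat) <- cols
    atoms <- data.frame(
      id = as.integer(mat[, "id"]),
      element = mat[, "element"],
      x = as.numeric(mat[, "x"]) * um$length,
      y = as.numeric(mat[, "y"]) * um$length,
      z = as.numeric(mat[, "z"]) * um$length,
      vx = as.numeric(mat[, "vx"]) * um$velocity,
      vy = as.numeric(mat[, "vy"]) * um$velocity,
      vz = as.numeric(mat[, "vz"]) * um$velocity,
      stringsAsFactors = FALSE
    )
    unknown <- setdiff(unique(atoms$element), alphabet)
    if (length(unknown)) {
      fail(i, paste0("element(s) outside declared alphabet: ",
                     paste(unknown, collapse = ", ")))
    }
    frames[[length(frames) + 1L]] <- md_frame(time, atoms)
    i <- i + n_atoms
  }
  if (!length(frames)) stop("no frames found in ", path)
  md_trajectory(frames, frame_interval = frame_interval)
}

#' Write a trajectory in the LAMMPS-dump-style dialect
#'
#' Positions/velocities are written in nm and nm/ps at full double precision,
#' so a write/read round trip is the identity.
#'
#' @param trajectory An [md_trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in trajectory$frames) {
    a <- f$atoms
    writeLines(c(
      "ITEM: TIMESTEP",
      sprintf("%.17g", f$time),
      "ITEM: NUMBER OF ATOMS",
      sprintf("%d", nrow(a)),
      "ITEM: BOX BOUNDS ff ff ff",
      sprintf("%.6g %.6g", min(a$x), max(a$x)),
      sprintf("%.6g %.6g", min(a$y), max(a$y)),
      sprintf("%.6g %.6g", min(a$z), max(a$z)),
      "ITEM: ATOMS id element x y z vx vy vz",
      sprintf("%d %s %.17g %.17g %.17g %.17g %.17g %.17g",
              a$id, a$element, a$x, a$y, a$z, a$vx, a$vy, a$vz)
    ), con)
  }
  invisible(path)
}

#' Read per-frame bond tables
#'
#' Two dialects are supported. `"simple"`: blocks headed by
#' `# Timestep <t>` followed by `i j bond_order` rows (the canonical fixture
#' format). `"reaxff"`: blocks headed by `# Timestep <t>` with rows
#' `id n_neighbours id_1 ... id_n bo_1 ... bo_n`; each bond appears from both
#' endpoints and is deduplicated to the `i < j` record.
#'
#' @param path File path.
#' @param dialect `"simple"` or `"reaxff"`.
#' @return List of [bond_table()] objects sorted by time.
#' @export
read_bond_tables <- function(path, dialect = c("simple", "reaxff")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grepl("^#\\s*Timestep", lines)
  if (!any(hdr)) stop("no '# Timestep' block headers found in ", path)
  starts <- which(hdr)
  ends <- c(starts[-1] - 1L, length(lines))
  tables <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    time <- suppressWarnings(as.numeric(sub("^#\\s*Timestep\\s+", "", lines[starts[k]])))
    if (is.na(time)) stop("unreadable timestep in header at line ", starts[k])
    body <- if (starts[k] + 1L > ends[k]) character(0) else
      lines[seq.int(starts[k] + 1L, ends[k])]
    body <- body[!grepl("^\\s*#", body) & nzchar(trimws(body))]
    if (!length(body)) {
      tables[[k]] <- bond_table(time, NULL)
      next
    }
    fields <- strsplit(trimws(body), "\\s+")
    if (dialect == "simple") {
      if (any(lengths(fields) != 3L)) {
        stop("simple bond dialect expects 3 columns (i j bo) near line ", starts[k])
      }
      m <- do.call(rbind, lapply(fields, as.numeric))
      tables[[k]] <- bond_table(time, data.frame(i = m[, 1], j = m[, 2], bo = m[, 3]))
    } else {
      recs <- lapply(fields, function(fld) {
        v <- as.numeric(fld)
        id <- as.integer(v[1]); nb <- as.integer(v[2])
        if (length(v) != 2 + 2 * nb) {
          stop("malformed reaxff bond row for atom ", id, " (expected ",
               2 + 2 * nb, " fields, got ", length(v), ")")
        }
        if (nb == 0L) return(NULL)
        nbr <- as.integer(v[seq.int(3, length.out = nb)])
        bo <- v[seq.int(3 + nb, length.out = nb)]
        data.frame(i = pmin(id, nbr), j = pmax(id, nbr), bo = bo)
      })
      recs <- do.call(rbind, recs)
      if (is.null(recs)) {
        tables[[k]] <- bond_table(time, NULL)
      } else {
        key <- paste(recs$i, recs$j)
        tables[[k]] <- bond_table(time, recs[!duplicated(key), , drop = FALSE])
      }
    }
  }
  tables[order(vapply(tables, function(b) b$time, numeric(1)))]
}

#' Write bond tables in the simple 3-column dialect
#'
#' @param bond_tables List of [bond_table()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bond_tables <- function(bond_tables, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (b in bond_tables) {
    writeLines(sprintf("# Timestep %.17g", b$time), con)
    if (nrow(b$bonds)) {
      writeLines(sprintf("%d %d %.17g", b$bonds$i, b$bonds$j, b$bonds$bo), con)
    }
  }
  invisible(path)
}

#' Pair a frame with the nearest-in-time bond table
#'
#' Bond tables may be saved less often than frames; the table whose timestamp
#' is nearest to the frame's is used and the time gap is reported. A gap
#' larger than one frame interval triggers a warning.
#'
#' @param trajectory An [md_trajectory()].
#' @param bond_tables List of [bond_table()] objects.
#' @param time Query time (ps), within the trajectory span.
#' @return List with elements `frame`, `bonds`, `gap` (ps).
#' @export
match_bonds_to_frame <- function(trajectory, bond_tables, time) {
  if (!length(bond_tables)) stop("no bond tables available")
  frame <- nearest_frame(trajectory, time)
  bt <- vapply(bond_tables, function(b) b$time, numeric(1))
  k <- which.min(abs(bt - frame$time))
  gap <- abs(bt[k] - frame$time)
  fi <- trajectory$frame_interval
  if (is.finite(fi) && !is.na(fi) && gap > fi) {
    warning(sprintf("bond table gap %.3g ps exceeds frame interval %.3g ps at t = %g",
                    gap, fi, frame$time))
  }
  list(frame = frame, bonds = bond_tables[[k]], gap = gap)
}
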