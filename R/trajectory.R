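#' Construct a single trajectory frame
#'
#' A frame holds the state of every atom at one instant: integer atom id,
#' element symbol, position (nm) and velocity (nm/ps). Atom ids must be
#' unique; rows are stored sorted by id so that frames compare reproducibly.
#'
#' @param time Time of the frame in ps.
#' @param atoms data.frame with columns `id`, `element`, `x`, `y`, `z`,
#'   `vx`, `vy`, `vz`.
#' @return An object of class `md_frame`.
#' @export
md_frame <- function(time, atoms) {
  required <- c("id", "element", "x", "y", "z", "vx", "vy", "vz")
  missing <- setdiff(required, names(atoms))
  if (length(missing)) {
    stop("frame atoms table lacks column(s): ", paste(missing, collapse = ", "))
  }
  atoms <- atoms[required]
  atoms$id <- as.integer(atoms$id)
  atoms$element <- as.character(atoms$element)
  for (col in required[-(1:2)]) atoms[[col]] <- as.numeric(atoms[[col]])
  if (anyDuplicated(atoms$id)) {
    stop("duplicate atom id(s) in frame at t = ", time, " ps: ",
         paste(unique(atoms$id[duplicated(atoms$id)]), collapse = ", "))
  }
  if (anyNA(atoms)) stop("NA values in frame atoms at t = ", time, " ps")
  atoms <- atoms[order(atoms$id), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(time = as.numeric(time), atoms = atoms), class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("<md_frame> t = %g ps, %d atoms (%s)\n", x$time, nrow(x$atoms),
              paste(sort(unique(x$atoms$element)), collapse = ",")))
  invisible(x)
}

#' Construct a trajectory
#'
#' An ordered sequence of frames sharing one atom-id universe. Frame times
#' must be strictly increasing.
#'
#' @param frames List of [md_frame()] objects.
#' @param frame_interval Nominal spacing between saved frames (ps). Defaults
#'   to the median of the observed time differences.
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(frames, frame_interval = NULL) {
  if (!length(frames)) stop("trajectory needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "md_frame"))) {
    stop("all frames must be md_frame objects")
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  ord <- order(times)
  frames <- frames[ord]
  times <- times[ord]
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  ids0 <- frames[[1]]$atoms$id
  for (f in frames[-1]) {
    if (!identical(f$atoms$id, ids0)) {
      stop("all frames must share the same atom-id universe (differs at t = ",
           f$time, " ps)")
    }
  }
  if (is.null(frame_interval)) {
    frame_interval <- if (length(times) > 1) stats::median(diff(times)) else NA_real_
  }
  structure(list(frames = frames, frame_interval = as.numeric(frame_interval)),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  t <- frame_times(x)
  cat(sprintf("<md_trajectory> %d frames, t = %g..%g ps, %d atoms\n",
              length(x$frames), min(t), max(t), nrow(x$frames[[1]]$atoms)))
  invisible(x)
}

#' Frame times of a trajectory
#' @param trajectory An `md_trajectory`.
#' @return Numeric vector of frame times (ps).
#' @export
frame_times <- function(trajectory) {
  vapply(trajectory$frames, function(f) f$time, numeric(1))
}

#' Extract the frame nearest to a time
#' @param trajectory An `md_trajectory`.
#' @param time Query time (ps); must lie within the trajectory span.
#' @return An `md_frame`.
#' @export
nearest_frame <- function(trajectory, time) {
  t <- frame_times(trajectory)
  if (time < min(t) - 1e-9 || time > max(t) + 1e-9) {
    stop("time ", time, " ps outside trajectory span [", min(t), ", ", max(t), "]")
  }
  trajectory$frames[[which.min(abs(t - time))]]
}

#' Construct a per-frame bond table
#'
#' Stores ReaxFF-style bond orders for unordered atom pairs at one time.
#' Pairs are canonicalised to `i < j`; duplicate pairs and self-bonds are
#' rejected, bond orders must be non-negative.
#'
#' @param time Time in ps.
#' @param bonds data.frame with columns `i`, `j`, `bo`.
#' @return An object of class `bond_table`.
#' @export
bond_table <- function(time, bonds) {
  if (is.null(bonds) || !nrow(bonds)) {
    bonds <- data.frame(i = integer(), j = integer(), bo = numeric())
  }
  missing <- setdiff(c("i", "j", "bo"), names(bonds))
  if (length(missing)) {
    stop("bond table lacks column(s): ", paste(missing, collapse = ", "))
  }
  bonds <- bonds[c("i", "j", "bo")]
  bonds$i <- as.integer(bonds$i)
  bonds$j <- as.integer(bonds$j)
  bonds$bo <- as.numeric(bonds$bo)
  if (any(bonds$i == bonds$j)) stop("self-bond (i == j) in bond table at t = ", time)
  if (any(bonds$bo < 0)) stop("negative bond order in bond table at t = ", time)
  swap <- bonds$i > bonds$j
  tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
  key <- paste(bonds$i, bonds$j)
  if (anyDuplicated(key)) {
    stop("duplicate bond record(s) for pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
  rownames(bonds) <- NULL
  structure(list(time = as.numeric(time), bonds = bonds), class = "bond_table")
}

#' @export
print.bond_table <- function(x, ...) {
  cat(sprintf("<bond_table> t = %g ps, %d bonds\n", x$time, nrow(x$bonds)))
  invisible(x)
}
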