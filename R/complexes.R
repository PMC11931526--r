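## Lifetime analysis of (single trehalose)-water complexes through the
## extended flight phase. A complex is a sputtered cluster holding exactly
## one intact trehalose plus adjoining waters; its stability clock starts at
## ejection (the first frame the enclosing cluster satisfies the sputter
## criterion) and runs until the first water-free frame.

#' Build per-complex contact traces over the extended phase
#'
#' One trace per trehalose whose enclosing cluster is, at some frame,
#' sputtered with exactly one intact trehalose, at least one water and no
#' fragments. Water contact is evaluated per frame as a direct
#' smallest-atom-distance test against the trehalose with the same cutoff
#' used for clustering.
#'
#' @param analysis A [analyze_trajectory()] result spanning impact and
#'   extended frames.
#' @param sample_atom_ids Atom ids of the sample (surface reference).
#' @param config A [census_config()].
#' @return List of `complex_trace` objects; each holds `trehalose_stable_id`,
#'   `ejection_time`, `intervals` (per water stable id, matrix of t_start /
#'   t_end), `contacts_per_frame`, `stable_duration`, `final_water_count`,
#'   `single_throughout`, `end_water_free`.
#' @export
build_complex_traces <- function(analysis, sample_atom_ids,
                                 config = analysis$config) {
  traj <- analysis$trajectory
  times <- frame_times(traj)
  if (length(times) < 2) stop("extended frames are required beyond the first")
  z0 <- surface_reference(traj$frames[[1]], sample_atom_ids,
                          method = config$surface_method)
  nfr <- length(times)
  msets <- analysis$molecule_sets
  csets <- analysis$cluster_sets
  sput <- lapply(csets, is_sputtered, z0 = z0, height_min = config$height_min)

  ## stable id -> molecule id lookup per frame
  stable_lookup <- lapply(msets, function(ms) {
    stats::setNames(ms$molecules$molecule_id, ms$molecules$stable_id)
  })
  treh_ids <- sort(unique(unlist(lapply(msets, function(ms) {
    ms$molecules$stable_id[ms$molecules$species == "intact_trehalose"]
  }))))

  traces <- list()
  for (tid in treh_ids) {
    eject_idx <- NA_integer_
    cluster_of <- rep(NA_integer_, nfr)
    for (k in seq_len(nfr)) {
      mid <- stable_lookup[[k]][as.character(tid)]
      if (is.na(mid)) next
      ms <- msets[[k]]
      if (ms$molecules$species[ms$molecules$molecule_id == mid] !=
          "intact_trehalose") next
      cs <- csets[[k]]
      cid <- cs$assignment$cluster_id[cs$assignment$molecule_id == mid]
      cluster_of[k] <- cid
      cl <- cs$clusters[cs$clusters$cluster_id == cid, ]
      sp <- sput[[k]]$sputtered[sput[[k]]$cluster_id == cid]
      if (is.na(eject_idx) && sp && cl$n_intact == 1 && cl$n_water >= 1 &&
          cl$n_fragment == 0) {
        eject_idx <- k
      }
    }
    if (is.na(eject_idx)) next

    ## per-frame water contacts from ejection to the last frame
    contacts <- vector("list", nfr)
    single_ok <- TRUE
    for (k in seq.int(eject_idx, nfr)) {
      ms <- msets[[k]]
      cs <- csets[[k]]
      mid <- stable_lookup[[k]][as.character(tid)]
      if (is.na(mid) ||
          ms$molecules$species[ms$molecules$molecule_id == mid] !=
            "intact_trehalose") {
        single_ok <- FALSE
        contacts[[k]] <- integer(0)
        next
      }
      cid <- cs$assignment$cluster_id[cs$assignment$molecule_id == mid]
      cl <- cs$clusters[cs$clusters$cluster_id == cid, ]
      if (cl$n_intact != 1) single_ok <- FALSE
      members <- cs$assignment$molecule_id[cs$assignment$cluster_id == cid]
      waters <- members[ms$molecules$species[
        match(members, ms$molecules$molecule_id)] == "water"]
      asn <- ms$assignment
      treh_atoms <- asn$atom_id[asn$molecule_id == mid]
      in_contact <- integer(0)
      for (w in waters) {
        wa <- asn$atom_id[asn$molecule_id == w]
        d <- min_intermolecular_distance(traj$frames[[k]], treh_atoms, wa)
        if (d < config$contact_cutoff) {
          ws <- ms$molecules$stable_id[ms$molecules$molecule_id == w]
          in_contact <- c(in_contact, ws)
        }
      }
      contacts[[k]] <- in_contact
    }

    idx <- seq.int(eject_idx, nfr)
    counts <- lengths(contacts[idx])
    ## stability: first water-free run longer than allow_gap_frames
    zero_runs <- rle(counts == 0)
    stable_duration <- times[nfr] - times[eject_idx]
    pos <- 1L
    for (r in seq_along(zero_runs$lengths)) {
      if (zero_runs$values[r] && zero_runs$lengths[r] > config$allow_gap_frames) {
        stable_duration <- times[idx[pos]] - times[eject_idx]
        break
      }
      pos <- pos + zero_runs$lengths[r]
    }
    final_water_count <- counts[length(counts)]

    ## per-water contact intervals from consecutive in-contact frames
    all_waters <- sort(unique(unlist(contacts[idx])))
    intervals <- lapply(all_waters, function(ws) {
      present <- vapply(contacts[idx], function(v) ws %in% v, logical(1))
      runs <- rle(present)
      starts <- cumsum(c(1L, runs$lengths))[seq_along(runs$lengths)]
      iv <- lapply(which(runs$values), function(r) {
        a <- idx[starts[r]]
        b <- idx[starts[r] + runs$lengths[r] - 1L]
        c(t_start = times[a], t_end = times[b])
      })
      do.call(rbind, iv)
    })
    names(intervals) <- as.character(all_waters)

    traces[[length(traces) + 1L]] <- structure(list(
      trehalose_stable_id = tid,
      ejection_time = times[eject_idx],
      intervals = intervals,
      stable_duration = stable_duration,
      final_water_count = final_water_count,
      single_throughout = single_ok,
      end_water_free = final_water_count == 0
    ), class = "complex_trace")
  }
  traces
}

#' @export
print.complex_trace <- function(x, ...) {
  cat(sprintf(
    "<complex_trace> trehalose %d: ejected %g ps, stable %g ps, %d water(s) at end\n",
    x$trehalose_stable_id, x$ejection_time, x$stable_duration,
    x$final_water_count))
  invisible(x)
}

#' Apply the complex stability and residual-water filters
#'
#' A trace is included when its stable duration reaches `min_stable`, it has
#' at most `max_final_waters` waters at the last frame, and it held exactly
#' one trehalose throughout. A complex that sheds all waters but was stable
#' long enough remains included (only "more than one water at the end" is an
#' exclusion); such traces carry `end_water_free = TRUE`.
#'
#' @param traces List from [build_complex_traces()].
#' @param min_stable Minimum stable duration (ps, default 320).
#' @param max_final_waters Maximum waters at the last frame (default 1).
#' @return The traces with an `included` flag added; attribute
#'   `included_count` gives the total.
#' @export
apply_stability_filter <- function(traces, min_stable = 320,
                                   max_final_waters = 1) {
  traces <- lapply(traces, function(tr) {
    tr$included <- tr$stable_duration >= min_stable &&
      tr$final_water_count <= max_final_waters && tr$single_throughout
    tr
  })
  attr(traces, "included_count") <-
    sum(vapply(traces, function(tr) tr$included, logical(1)))
  traces
}

#' Included-complex counts over a grid of filter settings
#'
#' @param traces List from [build_complex_traces()].
#' @param min_stable_grid Numeric grid of stability cutoffs (ps).
#' @param max_final_grid Integer grid of residual-water cutoffs.
#' @return data.frame with min_stable, max_final_waters, included.
#' @export
sweep_cutoffs <- function(traces, min_stable_grid, max_final_grid) {
  if (!length(min_stable_grid) || !length(max_final_grid)) {
    stop("cutoff grids must be non-empty")
  }
  grid <- expand.grid(min_stable = min_stable_grid,
                      max_final_waters = max_final_grid)
  grid$included <- vapply(seq_len(nrow(grid)), function(r) {
    attr(apply_stability_filter(traces, grid$min_stable[r],
                                grid$max_final_waters[r]), "included_count")
  }, numeric(1))
  grid
}

#' Map complex-forming waters back to their initial positions
#'
#' For every water appearing in any trace with total contact time of at
#' least `min_display`, emits the water's centre of mass at the first frame
#' (its position inside the projectile) together with its summed contact
#' duration. Waters whose stable id does not exist at the first frame are
#' tagged `"sample-origin"` and emitted with NA positions.
#'
#' @param traces List from [build_complex_traces()].
#' @param frame0 The initial [md_frame()].
#' @param molecule_set0 The first frame's `molecule_set` (with stable ids).
#' @param min_display Minimum total contact (ps, default 40).
#' @return data.frame with water_stable_id, x0, y0, z0, duration, origin.
#' @export
contact_time_map <- function(traces, frame0, molecule_set0, min_display = 40) {
  durs <- list()
  for (tr in traces) {
    for (ws in names(tr$intervals)) {
      iv <- tr$intervals[[ws]]
      d <- sum(iv[, "t_end"] - iv[, "t_start"])
      durs[[ws]] <- (if (is.null(durs[[ws]])) 0 else durs[[ws]]) + d
    }
  }
  keep <- names(durs)[vapply(durs, function(d) d >= min_display, logical(1))]
  if (!length(keep)) {
    return(data.frame(water_stable_id = integer(), x0 = numeric(),
                      y0 = numeric(), z0 = numeric(), duration = numeric(),
                      origin = character()))
  }
  mols0 <- molecule_set0$molecules
  rows <- lapply(keep, function(ws) {
    sid <- as.integer(ws)
    m <- mols0$molecule_id[mols0$stable_id == sid]
    if (!length(m)) {
      return(data.frame(water_stable_id = sid, x0 = NA_real_, y0 = NA_real_,
                        z0 = NA_real_, duration = durs[[ws]],
                        origin = "sample-origin", stringsAsFactors = FALSE))
    }
    atoms <- molecule_set0$assignment$atom_id[
      molecule_set0$assignment$molecule_id == m]
    kin <- cluster_kinematics(frame0, atoms)
    data.frame(water_stable_id = sid, x0 = kin$com[1], y0 = kin$com[2],
               z0 = kin$com[3], duration = durs[[ws]], origin = "projectile",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$water_stable_id), , drop = FALSE]
}
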