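## Synthetic-scene generator: trajectories, bond tables and cross-section
## fixtures with planted ground truth. Kinematics are scripted, not
## simulated -- the package tests the census, not the force field. The
## default configuration mirrors the physical setup emulated throughout:
## a trehalose sample shaped as a hemisphere of diameter 60 nm, a water
## cluster arriving at 45 degrees in the xz plane with 20 keV total kinetic
## energy, a 75 ps impact phase and an extended flight phase to 900 ps.

TREHALOSE_FORMULA <- "C12H22O11"

## 45-atom trehalose stand-in: two ring halves (C6H11O6 / C6H11O5) on snake
## grids 0.16 nm apart, joined by one C-O bridge bond whose scission yields
## the two half-sugar fragments. Internal geometry is arbitrary; only the
## formula, connectivity and ~1 nm extent matter to the census.
trehalose_template <- function() {
  snake <- function(n, spacing = 0.16) {
    g <- expand.grid(i = 0:2, j = 0:2, k = 0:2)
    g <- g[order(g$k, g$j, ifelse(g$j %% 2 == 0, 1, -1) * g$i), ]
    as.matrix(g[seq_len(n), ]) * spacing
  }
  half <- function(n_c, n_h, n_o, first, last) {
    els <- c(rep("C", n_c), rep("H", n_h), rep("O", n_o))
    els <- els[-match(first, els)]
    els <- els[-match(last, els)]
    c(first, els, last)
  }
  els_a <- half(6, 11, 6, "C", "O")   # ends with O (bridge donor)
  els_b <- half(6, 11, 5, "C", "H")   # starts with C (bridge acceptor)
  xyz_a <- snake(23); xyz_a[, 1] <- xyz_a[, 1] - 0.16 - 0.30
  xyz_b <- snake(22); xyz_b[, 1] <- xyz_b[, 1] + 0.30 - 0.16
  xyz <- rbind(xyz_a, xyz_b)
  xyz[, 2] <- xyz[, 2] - 0.16
  xyz[, 3] <- xyz[, 3] - 0.16
  colnames(xyz) <- c("x", "y", "z")
  bonds <- rbind(
    cbind(1:22, 2:23),          # chain through half A
    cbind(23, 24),              # O-C bridge between the halves
    cbind(24:44, 25:45)         # chain through half B
  )
  list(elements = c(els_a, els_b), xyz = xyz,
       bonds = data.frame(i = bonds[, 1], j = bonds[, 2]),
       bridge_row = 23L, half_a = 1:23, half_b = 24:45)
}

water_template <- function() {
  list(elements = c("O", "H", "H"),
       xyz = matrix(c(0, 0, 0,
                      0.096, 0, 0,
                      -0.032, 0.0906, 0), ncol = 3, byrow = TRUE,
                    dimnames = list(NULL, c("x", "y", "z"))),
       bonds = data.frame(i = c(1, 1), j = c(2, 3)))
}

#' Scripted ejection event for a synthetic scene
#'
#' @param type One of `"single_bare"`, `"multiple_bare"`,
#'   `"single_solvated"`, `"multiple_solvated"`, `"fragmenting"`,
#'   `"retained"`, `"debris"`.
#' @param n_trehalose Number of trehalose molecules in the ejected cluster.
#' @param n_water Number of adjoining projectile waters (max 3).
#' @param vz Vertical ejection velocity (nm/ps); motion is purely vertical
#'   so scripted columns never cross.
#' @param t_eject Ejection time (ps).
#' @param detach_times Per-water detachment times (ps, `Inf` = never);
#'   must be at or after `t_eject`.
#' @param frag_time Bridge-bond scission time for `"fragmenting"` (ps).
#' @param start_height Initial height above the surface (nm); used for
#'   falling-debris events.
#' @return List of class `eject_event`.
#' @export
eject_event <- function(type = c("single_bare", "multiple_bare",
                                 "single_solvated", "multiple_solvated",
                                 "fragmenting", "retained", "debris"),
                        n_trehalose = NULL, n_water = NULL, vz = NULL,
                        t_eject = 10, detach_times = NULL, frag_time = NA,
                        start_height = 0) {
  type <- match.arg(type)
  defaults <- switch(type,
    single_bare       = list(nt = 1, nw = 0, vz = 0.40),
    multiple_bare     = list(nt = 2, nw = 0, vz = 0.45),
    single_solvated   = list(nt = 1, nw = 2, vz = 0.35),
    multiple_solvated = list(nt = 2, nw = 2, vz = 0.38),
    fragmenting       = list(nt = 1, nw = 0, vz = 0.40),
    retained          = list(nt = 1, nw = 0, vz = 0.05),
    debris            = list(nt = 1, nw = 0, vz = -0.20))
  if (is.null(n_trehalose)) n_trehalose <- defaults$nt
  if (is.null(n_water)) n_water <- defaults$nw
  if (is.null(vz)) vz <- defaults$vz
  if (is.null(detach_times)) detach_times <- rep(Inf, n_water)
  if (length(detach_times) != n_water) {
    stop("detach_times must have one entry per adjoining water")
  }
  if (any(detach_times < t_eject)) {
    stop("water detachment cannot precede ejection")
  }
  if (n_water > 3) stop("at most 3 adjoining waters per event")
  if (type == "fragmenting" && is.na(frag_time)) frag_time <- 30
  if (type == "debris" && start_height <= 0) start_height <- 20
  structure(list(type = type, n_trehalose = n_trehalose, n_water = n_water,
                 vz = vz, t_eject = t_eject, detach_times = detach_times,
                 frag_time = frag_time, start_height = start_height),
            class = "eject_event")
}

default_events <- function() {
  list(
    eject_event("single_bare", vz = 0.40, t_eject = 10),
    eject_event("multiple_bare", vz = 0.45, t_eject = 12),
    eject_event("single_solvated", n_water = 2, vz = 0.35, t_eject = 15,
                detach_times = c(400, Inf)),
    eject_event("single_solvated", n_water = 2, vz = 0.35, t_eject = 15,
                detach_times = c(150, 180)),
    eject_event("single_solvated", n_water = 3, vz = 0.35, t_eject = 15,
                detach_times = c(Inf, Inf, Inf)),
    eject_event("multiple_solvated", n_water = 2, vz = 0.38, t_eject = 18),
    eject_event("fragmenting", vz = 0.40, t_eject = 8, frag_time = 30),
    eject_event("retained"),
    eject_event("debris")
  )
}

#' Specification of a synthetic impact scene
#'
#' Defaults encode the emulated study conditions: 60 nm hemisphere apex as
#' the surface, 45 degree incidence in the xz plane, 20 keV total projectile
#' energy, frames every 1 ps during the 75 ps impact phase and every 10 ps
#' out to 900 ps.
#'
#' @param events List of [eject_event()]s (default: one of each behaviour).
#' @param n_background Stationary sample trehalose molecules.
#' @param projectile_nominal_n Nominal projectile size (sets the impact
#'   speed through the energy per molecule).
#' @param projectile_waters Free waters generated in the rebounding
#'   projectile ball.
#' @param projectile_energy Total projectile kinetic energy (eV).
#' @param sample_diameter Hemisphere diameter (nm); the apex is the surface
#'   reference.
#' @param incidence_deg Incidence angle from the surface normal, xz plane.
#' @param cadence_impact,cadence_extended Frame spacing (ps) for the impact
#'   and extended phases.
#' @param t_impact_end,t_end End of the impact phase / of the extended
#'   phase (ps).
#' @param extended Generate extended-phase frames.
#' @param attach_time Time at which adjoining waters reach their sites (ps).
#' @param seed RNG seed; the same spec and seed give a byte-identical scene.
#' @return List of class `scene_spec`.
#' @export
scene_spec <- function(events = default_events(), n_background = 6,
                       projectile_nominal_n = 10000, projectile_waters = 30,
                       projectile_energy = 20000, sample_diameter = 60,
                       incidence_deg = 45, cadence_impact = 1,
                       cadence_extended = 10, t_impact_end = 75,
                       t_end = 900, extended = TRUE, attach_time = 5,
                       seed = 1) {
  stopifnot(all(vapply(events, inherits, logical(1), "eject_event")))
  for (ev in events) {
    if (any(is.finite(ev$detach_times) & ev$detach_times < attach_time)) {
      stop("detachment before attachment in scripted event")
    }
  }
  structure(list(events = events, n_background = n_background,
                 projectile_nominal_n = projectile_nominal_n,
                 projectile_waters = projectile_waters,
                 projectile_energy = projectile_energy,
                 sample_diameter = sample_diameter,
                 incidence_deg = incidence_deg,
                 cadence_impact = cadence_impact,
                 cadence_extended = cadence_extended,
                 t_impact_end = t_impact_end, t_end = t_end,
                 extended = extended, attach_time = attach_time,
                 seed = seed),
            class = "scene_spec")
}

## piecewise-linear motion: segments (t0, x, y, z, vx, vy, vz); position at
## t uses the last segment with t0 <= t
.motion_eval <- function(seg, t) {
  k <- findInterval(t, seg$t0)
  k[k < 1] <- 1L
  cbind(x = seg$x[k] + seg$vx[k] * (t - seg$t0[k]),
        y = seg$y[k] + seg$vy[k] * (t - seg$t0[k]),
        z = seg$z[k] + seg$vz[k] * (t - seg$t0[k]),
        vx = seg$vx[k], vy = seg$vy[k], vz = seg$vz[k])
}

.seg <- function(t0, pos, vel) {
  data.frame(t0 = t0, x = pos[1], y = pos[2], z = pos[3],
             vx = vel[1], vy = vel[2], vz = vel[3])
}

#' Generate a synthetic scene with planted ground truth
#'
#' Realises the scripted kinematics exactly (ballistic motion, no forces):
#' intra-molecular bond orders are 0.9 and inter-molecular 0; adjoining
#' waters sit ~0.25 nm from their trehalose and leave at > 0.5 nm within
#' one ps of their scripted detachment; a fragmenting molecule's bridge
#' bond drops to 0 at its scripted time. The manifest records, per scripted
#' event, the expected sputter label, category masses, complex stability
#' and per-water contact durations, all quantised to the frame grid.
#'
#' @param spec A [scene_spec()].
#' @return Object of class `scene`: list with `spec`, `trajectory`,
#'   `bond_tables`, `manifest`, `sample_atom_ids`,
#'   `projectile_molecule_ids`.
#' @export
build_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  treh <- trehalose_template()
  wat <- water_template()
  m_water <- sum(element_mass(wat$elements))
  R <- spec$sample_diameter / 2
  zc <- R - 0.16                       # template tops reach exactly z = R
  tt <- seq(0, spec$t_impact_end, by = spec$cadence_impact)
  if (spec$extended) {
    ext <- seq(0, spec$t_end, by = spec$cadence_extended)
    tt <- c(tt, ext[ext > spec$t_impact_end])
  }

  ## slot grid for background + events, 3 nm pitch, centred near the origin
  n_slots <- spec$n_background + length(spec$events)
  side <- ceiling(sqrt(n_slots))
  g <- expand.grid(ix = seq_len(side), iy = seq_len(side))[seq_len(n_slots), ]
  ## seeded sub-slot jitter: placements vary with the seed, planted truths
  ## (labels, categories, durations) do not
  slot_xy <- cbind((g$ix - (side + 1) / 2) * 3.0 +
                     stats::runif(n_slots, -0.2, 0.2),
                   (g$iy - (side + 1) / 2) * 3.0 +
                     stats::runif(n_slots, -0.2, 0.2))

  ## projectile ball: grid-packed waters, 45-degree approach, rebound at +z
  v_mag <- sqrt(2 * (spec$projectile_energy / spec$projectile_nominal_n) /
                  KE_EV_PER_AMU_NM2_PS2 / m_water)
  th <- spec$incidence_deg * pi / 180
  v_in <- v_mag * c(sin(th), 0, -cos(th))
  grid_extent <- (side / 2) * 3.0
  impact_t <- 6
  P_imp <- c(grid_extent + 8, 0, R + 3) + stats::runif(3, -0.3, 0.3)
  C0 <- P_imp - v_in * impact_t
  v_reb <- c(0, 0, 0.45)
  bs <- max(1, ceiling(spec$projectile_waters^(1 / 3)))
  bg <- expand.grid(i = seq_len(bs), j = seq_len(bs), k = seq_len(bs))
  bg <- bg[seq_len(spec$projectile_waters), , drop = FALSE]
  ball_local <- (as.matrix(bg) - (bs + 1) / 2) * 0.28
  ball_half <- bs / 2 * 0.28

  mols <- list()
  add_mol <- function(kind, template, motion, meta = list()) {
    mols[[length(mols) + 1L]] <<- c(list(kind = kind, template = template,
                                         motion = motion), meta)
  }

  ## background sample molecules (stationary)
  for (b in seq_len(spec$n_background)) {
    add_mol("background", treh,
            .seg(0, c(slot_xy[b, 1], slot_xy[b, 2], zc), c(0, 0, 0)))
  }

  ## scripted events; adjoining waters start in a vertically spaced stack on
  ## the projectile's leading (lower) face so approach paths never cross
  adjoin_q <- 0L
  for (ei in seq_along(spec$events)) {
    ev <- spec$events[[ei]]
    sl <- slot_xy[spec$n_background + ei, ]
    base <- c(sl[1], sl[2], zc + ev$start_height)
    for (m in seq_len(ev$n_trehalose)) {
      ctr <- base + c(0, (m - 1) * 0.57, 0)
      seg <- rbind(.seg(0, ctr, c(0, 0, 0)),
                   .seg(ev$t_eject, ctr, c(0, 0, ev$vz)))
      add_mol("event_treh", treh, seg,
              list(event = ei, member = m,
                   frag_time = if (ev$type == "fragmenting") ev$frag_time else NA))
    }
    if (ev$n_water > 0) {
      ## anchor sites: highest atoms of member 1, kept >= 0.32 nm apart so
      ## the adjoining waters never overlap each other
      ord <- order(-treh$xyz[, "z"], treh$xyz[, "x"], treh$xyz[, "y"])
      anchors <- integer(0)
      for (a in ord) {
        if (!length(anchors) ||
            min(sqrt(rowSums((treh$xyz[anchors, , drop = FALSE] -
                              rep(treh$xyz[a, ], each = length(anchors)))^2))) >= 0.32) {
          anchors <- c(anchors, a)
        }
        if (length(anchors) >= ev$n_water) break
      }
      stopifnot(length(anchors) >= ev$n_water)
      for (w in seq_len(ev$n_water)) {
        anchor <- treh$xyz[anchors[w], ] + base
        site <- anchor + c(0, 0, 0.25)
        adjoin_q <- adjoin_q + 1L
        start <- C0 - c(0, 0, ball_half + 1.0 + 1.2 * (adjoin_q - 1L)) +
          c(0.3 * (adjoin_q %% 3), 0.3 * (adjoin_q %% 2), 0)
        waypoint <- c(site[1], site[2], R + 6)
        t_wp <- spec$attach_time - 2
        td <- ev$detach_times[w]
        seg <- rbind(
          .seg(0, start, (waypoint - start) / t_wp),
          .seg(t_wp, waypoint, (site - waypoint) / 2),
          .seg(spec$attach_time, site, c(0, 0, 0)),
          .seg(ev$t_eject, site, c(0, 0, ev$vz))
        )
        if (is.finite(td)) {
          pos_td <- site + c(0, 0, ev$vz * (td - ev$t_eject))
          seg <- rbind(seg, .seg(td, pos_td, c(0, 0, ev$vz + 0.6)))
        }
        add_mol("adjoin_water", wat, seg,
                list(event = ei, water = w, detach = td))
      }
    }
  }

  ## free projectile waters (rebounding ball)
  for (w in seq_len(spec$projectile_waters)) {
    start <- C0 + ball_local[w, ]
    at_imp <- start + v_in * impact_t
    seg <- rbind(.seg(0, start, v_in), .seg(impact_t, at_imp, v_reb))
    add_mol("free_water", wat, seg)
  }

  ## assign atom ids and build frames + bond tables
  n_atoms_per <- vapply(mols, function(m) length(m$template$elements), integer(1))
  first_id <- cumsum(c(1L, n_atoms_per))[seq_along(mols)]
  all_elements <- unlist(lapply(mols, function(m) m$template$elements))
  all_ids <- seq_len(sum(n_atoms_per))

  bond_rows <- do.call(rbind, lapply(seq_along(mols), function(k) {
    b <- mols[[k]]$template$bonds
    data.frame(i = b$i + first_id[k] - 1L, j = b$j + first_id[k] - 1L,
               bo = 0.9, mol = k, row = seq_len(nrow(b)))
  }))
  frag_info <- do.call(rbind, lapply(seq_along(mols), function(k) {
    ft <- mols[[k]]$frag_time
    if (is.null(ft) || is.na(ft)) return(NULL)
    data.frame(mol = k, frag_time = ft, bridge_row = treh$bridge_row)
  }))

  frames <- vector("list", length(tt))
  bonds_out <- vector("list", length(tt))
  centers <- array(0, dim = c(length(mols), 6, length(tt)))
  for (k in seq_along(mols)) {
    centers[k, , ] <- t(.motion_eval(mols[[k]]$motion, tt))
  }
  for (fi in seq_along(tt)) {
    pos <- vector("list", length(mols))
    for (k in seq_along(mols)) {
      ctr <- centers[k, , fi]
      xyz <- mols[[k]]$template$xyz
      pos[[k]] <- cbind(xyz[, 1] + ctr[1], xyz[, 2] + ctr[2],
                        xyz[, 3] + ctr[3],
                        matrix(rep(ctr[4:6], each = nrow(xyz)), ncol = 3))
    }
    P <- do.call(rbind, pos)
    frames[[fi]] <- md_frame(tt[fi], data.frame(
      id = all_ids, element = all_elements,
      x = P[, 1], y = P[, 2], z = P[, 3],
      vx = P[, 4], vy = P[, 5], vz = P[, 6]))
    bo <- bond_rows$bo
    if (!is.null(frag_info)) {
      for (r in seq_len(nrow(frag_info))) {
        if (tt[fi] >= frag_info$frag_time[r]) {
          hit <- bond_rows$mol == frag_info$mol[r] &
            bond_rows$row == frag_info$bridge_row[r]
          bo[hit] <- 0
        }
      }
    }
    bonds_out[[fi]] <- bond_table(tt[fi], data.frame(
      i = bond_rows$i, j = bond_rows$j, bo = bo))
  }

  .check_overlaps(mols, centers, tt)

  traj <- md_trajectory(frames, frame_interval = spec$cadence_impact)
  sample_atoms <- unlist(lapply(seq_along(mols), function(k) {
    m <- mols[[k]]
    sample_mol <- m$kind == "background" ||
      (m$kind == "event_treh" &&
         spec$events[[m$event]]$start_height == 0)
    if (sample_mol) seq.int(first_id[k], length.out = n_atoms_per[k]) else NULL
  }))
  proj_mols <- which(vapply(mols, function(m)
    m$kind %in% c("adjoin_water", "free_water"), logical(1)))

  manifest <- .build_manifest(spec, mols, centers, tt, first_id, n_atoms_per,
                              treh, wat)
  structure(list(spec = spec, trajectory = traj, bond_tables = bonds_out,
                 manifest = manifest, sample_atom_ids = sample_atoms,
                 projectile_molecule_ids = proj_mols),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d molecules, %d atoms, %d frames (seed %d)\n",
              length(x$projectile_molecule_ids) + x$manifest$n_molecules_sample,
              nrow(x$trajectory$frames[[1]]$atoms),
              length(x$trajectory$frames), x$spec$seed))
  invisible(x)
}

## generation error when any two molecules come closer than 0.1 nm
.check_overlaps <- function(mols, centers, tt) {
  rad <- vapply(mols, function(m) {
    sqrt(max(rowSums(m$template$xyz^2)))
  }, numeric(1))
  n <- length(mols)
  for (fi in seq_along(tt)) {
    C <- matrix(centers[, 1:3, fi], ncol = 3)
    cd <- as.matrix(stats::dist(C))
    lim <- outer(rad, rad, "+") + 0.1
    cand <- which(upper.tri(cd) & cd < lim, arr.ind = TRUE)
    for (r in seq_len(nrow(cand))) {
      a <- cand[r, 1]; b <- cand[r, 2]
      A <- sweep(mols[[a]]$template$xyz, 2, -C[a, ])
      B <- sweep(mols[[b]]$template$xyz, 2, -C[b, ])
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
      if (min(d2) < 0.1^2) {
        stop(sprintf(
          "scene generation error: molecules %d and %d overlap (%.3f nm) at t = %g ps",
          a, b, sqrt(max(min(d2), 0)), tt[fi]))
      }
    }
  }
  invisible(TRUE)
}

## ground truth per scripted event, quantised to the frame grid
.build_manifest <- function(spec, mols, centers, tt, first_id, n_atoms_per,
                            treh, wat) {
  m_treh_total <- sum(element_mass(treh$elements))
  m_frag_a <- sum(element_mass(treh$elements[treh$half_a]))
  m_frag_b <- sum(element_mass(treh$elements[treh$half_b]))
  m_water <- sum(element_mass(wat$elements))
  t_eval <- tt[which.min(abs(tt - spec$t_impact_end))]
  t_last <- tt[length(tt)]
  z0 <- spec$sample_diameter / 2
  height_min <- 15

  kinds <- vapply(mols, function(m) m$kind, character(1))
  ev_of <- vapply(mols, function(m) if (is.null(m$event)) NA_integer_ else m$event,
                  integer(1))

  ## COM height and vz of a set of molecules at a frame index
  com_z_vz <- function(mol_idx, fi) {
    masses <- vapply(mol_idx, function(k) {
      sum(element_mass(mols[[k]]$template$elements))
    }, numeric(1))
    mz <- vapply(mol_idx, function(k) {
      ctr <- centers[k, , fi]
      mean_local <- sum(element_mass(mols[[k]]$template$elements) *
                          (mols[[k]]$template$xyz[, "z"])) /
        sum(element_mass(mols[[k]]$template$elements))
      ctr[3] + mean_local
    }, numeric(1))
    vz <- vapply(mol_idx, function(k) centers[k, 6, fi], numeric(1))
    list(z = sum(masses * mz) / sum(masses),
         vz = sum(masses * vz) / sum(masses))
  }

  cats <- stats::setNames(numeric(6),
                          c(YIELD_CATEGORIES, "pure_water"))
  complexes <- list()
  contact_map <- list()
  n_scissions <- 0L
  fi_eval <- which(tt == t_eval)

  for (ei in seq_along(spec$events)) {
    ev <- spec$events[[ei]]
    treh_idx <- which(kinds == "event_treh" & ev_of == ei)
    wat_idx <- which(kinds == "adjoin_water" & ev_of == ei)
    td <- if (length(wat_idx)) vapply(mols[wat_idx], function(m) m$detach,
                                      numeric(1)) else numeric(0)
    attached_eval <- wat_idx[td >= t_eval]
    members_eval <- c(treh_idx, attached_eval)
    kin <- com_z_vz(members_eval, fi_eval)
    sputtered <- (kin$z - z0 >= height_min) && kin$vz > 0
    fragmented <- ev$type == "fragmenting" && !is.na(ev$frag_time) &&
      ev$frag_time <= t_eval

    if (sputtered) {
      nw <- length(attached_eval)
      nt <- ev$n_trehalose
      if (fragmented) {
        cats["fragments"] <- cats["fragments"] + nt * m_treh_total
        if (nw > 0) cats["pure_water"] <- cats["pure_water"] + nw * m_water
      } else {
        lab <- if (nt == 1 && nw == 0) "single_bare"
          else if (nt >= 2 && nw == 0) "multiple_bare"
          else if (nt == 1) "single_solvated" else "multiple_solvated"
        cats[lab] <- cats[lab] + nt * m_treh_total + nw * m_water
      }
      ## waters detached before evaluation fly with the cluster column
      detached_eval <- wat_idx[td < t_eval]
      if (length(detached_eval)) {
        cats["pure_water"] <- cats["pure_water"] +
          length(detached_eval) * m_water
      }
    }
    if (fragmented) n_scissions <- n_scissions + 1L

    ## complex trace ground truth (single intact trehalose with waters)
    if (ev$n_trehalose == 1 && ev$n_water >= 1 && ev$type != "fragmenting") {
      eject_fi <- NA_integer_
      for (fi in seq_along(tt)) {
        attached <- wat_idx[td >= tt[fi] & spec$attach_time <= tt[fi]]
        if (!length(attached)) next
        kin <- com_z_vz(c(treh_idx, attached), fi)
        if (kin$z - z0 >= height_min && kin$vz > 0) { eject_fi <- fi; break }
      }
      if (!is.na(eject_fi)) {
        t_ej <- tt[eject_fi]
        max_td <- max(td)
        first_zero <- if (any(tt > max_td)) min(tt[tt > max_td]) else NA
        stable_duration <- if (is.na(first_zero)) t_last - t_ej
          else first_zero - t_ej
        final_waters <- sum(td >= t_last)
        complexes[[length(complexes) + 1L]] <- data.frame(
          event = ei, ejection_time = t_ej,
          stable_duration = stable_duration,
          final_water_count = final_waters,
          included = stable_duration >= spec_min_stable_default() &&
            final_waters <= 1)
        for (wq in seq_along(wat_idx)) {
          tdw <- td[wq]
          if (tdw < t_ej) next
          last_c <- max(tt[tt <= tdw])
          dur <- last_c - t_ej
          ctr0 <- centers[wat_idx[wq], , 1]
          mean_local <- colSums(element_mass(wat$elements) * wat$xyz) /
            sum(element_mass(wat$elements))
          contact_map[[length(contact_map) + 1L]] <- data.frame(
            event = ei, water = wq,
            x0 = ctr0[1] + mean_local[1], y0 = ctr0[2] + mean_local[2],
            z0 = ctr0[3] + mean_local[3], duration = dur)
        }
      }
    }
  }

  ## rebounding ball (pure water)
  ball_idx <- which(kinds == "free_water")
  if (length(ball_idx)) {
    kin <- com_z_vz(ball_idx, fi_eval)
    if (kin$z - z0 >= height_min && kin$vz > 0) {
      cats["pure_water"] <- cats["pure_water"] + length(ball_idx) * m_water
    }
  }

  complexes <- if (length(complexes)) do.call(rbind, complexes) else
    data.frame(event = integer(), ejection_time = numeric(),
               stable_duration = numeric(), final_water_count = integer(),
               included = logical())
  contact_map <- if (length(contact_map)) do.call(rbind, contact_map) else
    data.frame(event = integer(), water = integer(), x0 = numeric(),
               y0 = numeric(), z0 = numeric(), duration = numeric())

  list(z0 = z0, frame_times = tt, eval_time = t_eval,
       category_masses = cats,
       total_sputtered_mass = sum(cats),
       yields = cats / 342.3,
       complexes = complexes,
       included_count = sum(complexes$included),
       contact_map = contact_map,
       n_scissions = n_scissions,
       masses = list(trehalose = m_treh_total, water = m_water,
                     fragment_a = m_frag_a, fragment_b = m_frag_b),
       n_molecules_sample = sum(kinds %in% c("background", "event_treh")),
       n_atoms = sum(n_atoms_per))
}

spec_min_stable_default <- function() 320

#' Random scene specification with planted ground truth margins
#'
#' Draws a randomized mix of scripted events (bare/solvated/fragmenting/
#' retained/debris) with velocities and detachment times kept away from the
#' decision boundaries of the census (sputter height, 320 ps stability), so
#' the planted labels are unambiguous at the frame cadence. Uses coarser
#' cadences (5/15 ps) than the default scene to keep suites fast.
#'
#' @param seed RNG seed.
#' @return A [scene_spec()].
#' @export
random_scene_spec <- function(seed) {
  set.seed(seed)
  evs <- list()
  for (k in seq_len(sample(1:2, 1))) {
    evs <- c(evs, list(eject_event("single_bare",
                                   vz = stats::runif(1, 0.32, 0.5),
                                   t_eject = sample(5:25, 1))))
  }
  if (stats::runif(1) < 0.5) {
    evs <- c(evs, list(eject_event("multiple_bare",
                                   vz = stats::runif(1, 0.35, 0.5),
                                   t_eject = sample(5:20, 1))))
  }
  for (k in seq_len(sample(1:3, 1))) {
    nw <- sample(1:3, 1)
    regime <- sample(c("early", "late", "never"), nw, replace = TRUE)
    td <- ifelse(regime == "early", round(stats::runif(nw, 100, 240)),
          ifelse(regime == "late", round(stats::runif(nw, 480, 820)), Inf))
    evs <- c(evs, list(eject_event("single_solvated", n_water = nw,
                                   vz = stats::runif(1, 0.32, 0.45),
                                   t_eject = sample(5:25, 1),
                                   detach_times = td)))
  }
  if (stats::runif(1) < 0.4) {
    evs <- c(evs, list(eject_event("multiple_solvated",
                                   n_water = sample(1:3, 1),
                                   vz = stats::runif(1, 0.34, 0.45),
                                   t_eject = sample(5:20, 1))))
  }
  if (stats::runif(1) < 0.5) {
    evs <- c(evs, list(eject_event("fragmenting",
                                   vz = stats::runif(1, 0.32, 0.5),
                                   t_eject = sample(5:15, 1),
                                   frag_time = sample(20:60, 1))))
  }
  if (stats::runif(1) < 0.5) evs <- c(evs, list(eject_event("retained")))
  if (stats::runif(1) < 0.5) evs <- c(evs, list(eject_event("debris")))
  scene_spec(events = evs, n_background = 3, projectile_waters = 18,
             projectile_nominal_n = sample(c(4000, 7000, 10000, 15000), 1),
             cadence_impact = 5, cadence_extended = 15, seed = seed)
}

#' Write a scene to disk (dump + bonds + manifest)
#'
#' @param scene A [build_scene()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trajectory(scene$trajectory, file.path(dir, "trajectory.dump"))
  write_bond_tables(scene$bond_tables, file.path(dir, "bonds.txt"))
  jsonlite::write_json(scene$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
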