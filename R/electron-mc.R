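## Table-driven track-structure Monte Carlo of a low-energy electron in a
## nanoscale water (ice) sphere. Physics enters only through the
## cross-section tables (inverse mean free paths per process); the engine
## samples competing processes, cascades secondaries, and terminates each
## electron by escape through the sphere surface or by solvation (kinetic
## energy below the solvation threshold, default 11 eV, while inside).

#' Construct a cross-section table
#'
#' Inverse mean free paths (nm^-1) per process on a common, strictly
#' increasing energy grid (eV), with the energy-loss bookkeeping rules:
#' a fixed excitation loss, a single effective ionization threshold, a
#' secondary-energy sampling rule and angular rules. Energies outside the
#' grid are clamped to the nearest grid point.
#'
#' @param energy Strictly increasing energy grid (eV).
#' @param elastic,excitation,ionization Inverse MFPs (nm^-1) on the grid.
#' @param excitation_loss Energy lost per excitation (eV).
#' @param ionization_threshold Effective binding energy I (eV); ionization
#'   is switched off below it and each ionization removes I plus the
#'   sampled secondary energy from the projectile electron.
#' @param secondary_rule `"fixed"` (constant `secondary_energy`),
#'   `"uniform"` (uniform on `[0, (E - I)/2]`), or `"lorentzian"` (density
#'   proportional to `1/(w^2 + a^2)` on the same interval, the steeply
#'   falling shape of knock-on spectra; `a` = `secondary_energy`).
#' @param secondary_energy Secondary energy for the `"fixed"` rule, or the
#'   scale parameter `a` of the `"lorentzian"` rule (eV).
#' @param elastic_angle,ionization_angle `"isotropic"` or `"forward"`;
#'   direction rule after an elastic collision / for both electrons after an
#'   ionization.
#' @return Object of class `xs_table`.
#' @export
cross_section_table <- function(energy, elastic, excitation, ionization,
                                excitation_loss, ionization_threshold,
                                secondary_rule = c("fixed", "uniform", "lorentzian"),
                                secondary_energy = 0,
                                elastic_angle = c("isotropic", "forward"),
                                ionization_angle = c("forward", "isotropic")) {
  secondary_rule <- match.arg(secondary_rule)
  elastic_angle <- match.arg(elastic_angle)
  ionization_angle <- match.arg(ionization_angle)
  stopifnot(length(energy) >= 2, all(diff(energy) > 0),
            length(elastic) == length(energy),
            length(excitation) == length(energy),
            length(ionization) == length(energy))
  if (any(c(elastic, excitation, ionization) < 0)) {
    stop("inverse mean free paths must be non-negative")
  }
  structure(list(
    energy = energy,
    f_elastic = stats::approxfun(energy, elastic, rule = 2),
    f_excitation = stats::approxfun(energy, excitation, rule = 2),
    f_ionization = stats::approxfun(energy, ionization, rule = 2),
    excitation_loss = excitation_loss,
    ionization_threshold = ionization_threshold,
    secondary_rule = secondary_rule,
    secondary_energy = secondary_energy,
    elastic_angle = elastic_angle,
    ionization_angle = ionization_angle
  ), class = "xs_table")
}

#' @export
print.xs_table <- function(x, ...) {
  cat(sprintf(
    "<xs_table> %g-%g eV, I = %g eV, excitation loss %g eV, secondary '%s'\n",
    min(x$energy), max(x$energy), x$ionization_threshold, x$excitation_loss,
    x$secondary_rule))
  invisible(x)
}

## physically gated inverse MFPs at energy E; under the fixed secondary rule
## an ionization needs E >= I + E_secondary so energies never go negative
.rates <- function(tables, E) {
  ion_min <- tables$ionization_threshold +
    if (tables$secondary_rule == "fixed") tables$secondary_energy else 0
  c(elastic = tables$f_elastic(E),
    excitation = if (E >= tables$excitation_loss) tables$f_excitation(E) else 0,
    ionization = if (E >= ion_min) tables$f_ionization(E) else 0)
}

#' Sample a free path and the next process
#'
#' Path lengths are exponential with the total inverse MFP at E; the process
#' is chosen proportionally to its inverse MFP. Zero total rate yields an
#' infinite path (the electron leaves the medium untouched).
#'
#' @param E Electron kinetic energy (eV).
#' @param tables An [cross_section_table()].
#' @return List with `path` (nm, possibly `Inf`) and `process`
#'   (`"elastic"`, `"excitation"`, `"ionization"`, or `"none"`).
#' @export
sample_step <- function(E, tables) {
  r <- .rates(tables, E)
  total <- sum(r)
  if (total <= 0) return(list(path = Inf, process = "none"))
  path <- stats::rexp(1, rate = total)
  u <- stats::runif(1) * total
  process <- names(r)[min(which(cumsum(r) >= u))]
  list(path = path, process = process)
}

.isotropic_dir <- function() {
  z <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  c(s * cos(phi), s * sin(phi), z)
}

#' Transport one primary electron through a water sphere
#'
#' The primary enters moving in -z; secondaries are cascaded with the same
#' rules. Each electron terminates by escaping through the sphere surface or
#' by dropping below the solvation threshold inside (a solvated electron).
#' Exact energy bookkeeping is returned with every event: the initial energy
#' equals the energy deposited in ionization thresholds and excitations plus
#' the terminal kinetic energies of all electrons.
#'
#' @param sphere_diameter Sphere diameter (nm); the sphere is centred at the
#'   origin.
#' @param tables A [cross_section_table()].
#' @param E0 Primary kinetic energy (eV, default 100).
#' @param solvation_threshold Solvation energy (eV, default 11).
#' @param entry `"disk"` (entry point uniform over the projected disk,
#'   direction -z) or `"axis"` (entry on the vertical axis through the
#'   centre, direction -z).
#' @param max_steps Cap on total collision steps (default 1e6).
#' @return List with `ion_pos` (matrix of ionization positions, nm),
#'   `n_ionizations`, `n_solvated_inside`, `net_charge`, `n_escaped`,
#'   `energy` (list: deposited, terminal, residual = E0 - deposited -
#'   terminal) and `steps`.
#' @export
transport_electron <- function(sphere_diameter, tables, E0 = 100,
                               solvation_threshold = 11,
                               entry = c("disk", "axis"), max_steps = 1e6) {
  entry <- match.arg(entry)
  R <- sphere_diameter / 2
  if (E0 <= solvation_threshold) stop("E0 must exceed the solvation threshold")
  ## entry point on the upper surface, direction -z
  if (entry == "disk") {
    repeat {
      x0 <- stats::runif(1, -R, R); y0 <- stats::runif(1, -R, R)
      if (x0^2 + y0^2 < R^2) break
    }
  } else {
    x0 <- 0; y0 <- 0
  }
  z0 <- sqrt(max(R^2 - x0^2 - y0^2, 0))
  stack <- list(list(pos = c(x0, y0, z0), dir = c(0, 0, -1), E = E0))
  ion_pos <- matrix(numeric(0), ncol = 3)
  n_ion <- 0L; n_solv <- 0L; n_esc <- 0L
  deposited <- 0; terminal <- 0
  steps <- 0L
  while (length(stack)) {
    el <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    repeat {
      steps <- steps + 1L
      if (steps > max_steps) stop("transport exceeded the step cap")
      st <- sample_step(el$E, tables)
      if (!is.finite(st$path)) { n_esc <- n_esc + 1L; terminal <- terminal + el$E; break }
      p2 <- el$pos + st$path * el$dir
      if (sum(p2^2) > R^2) { n_esc <- n_esc + 1L; terminal <- terminal + el$E; break }
      el$pos <- p2
      if (st$process == "elastic") {
        if (tables$elastic_angle == "isotropic") el$dir <- .isotropic_dir()
      } else if (st$process == "excitation") {
        el$E <- el$E - tables$excitation_loss
        deposited <- deposited + tables$excitation_loss
        if (el$E < solvation_threshold) {
          n_solv <- n_solv + 1L; terminal <- terminal + el$E; break
        }
      } else {  # ionization
        I <- tables$ionization_threshold
        wmax <- max((el$E - I) / 2, 0)
        Es <- switch(tables$secondary_rule,
          fixed = tables$secondary_energy,
          uniform = stats::runif(1, 0, wmax),
          lorentzian = {
            a <- tables$secondary_energy
            a * tan(stats::runif(1) * atan(wmax / a))
          })
        n_ion <- n_ion + 1L
        ion_pos <- rbind(ion_pos, el$pos)
        deposited <- deposited + I
        sec_dir <- if (tables$ionization_angle == "isotropic") .isotropic_dir() else el$dir
        if (Es < solvation_threshold) {
          n_solv <- n_solv + 1L; terminal <- terminal + Es
        } else {
          stack[[length(stack) + 1L]] <- list(pos = el$pos, dir = sec_dir, E = Es)
        }
        el$E <- el$E - I - Es
        if (tables$ionization_angle == "isotropic") el$dir <- .isotropic_dir()
        if (el$E < solvation_threshold) {
          n_solv <- n_solv + 1L; terminal <- terminal + el$E; break
        }
      }
    }
  }
  list(ion_pos = ion_pos, n_ionizations = n_ion, n_solvated_inside = n_solv,
       net_charge = n_ion - n_solv, n_escaped = n_esc,
       energy = list(deposited = deposited, terminal = terminal,
                     residual = E0 - deposited - terminal),
       steps = steps)
}

#' Run a campaign of electron impacts, selecting on final net charge
#'
#' Repeats [transport_electron()] until `n_events` events whose net cluster
#' charge (ionizations minus electrons solvated inside) equals
#' `selection_net_charge` have been collected; `selection_net_charge = NULL`
#' keeps every event. With a fixed RNG seed the campaign is bit-identical.
#'
#' @param sphere_diameter Sphere diameter (nm).
#' @param tables A [cross_section_table()].
#' @param n_events Number of events to keep.
#' @param selection_net_charge Net charge selected for (default +1);
#'   `NULL` disables selection.
#' @param E0,solvation_threshold,entry,max_steps See [transport_electron()].
#' @param max_attempts Attempt cap before giving up (default 1000 *
#'   `n_events`).
#' @return Object of class `ionization_events`: list with `diameter`,
#'   `n_ionizations` / `n_solvated` (per kept event), `positions` (matrix
#'   event, x, y, z), `attempts`, `acceptance`, `energy_max_error`,
#'   `selection_net_charge`.
#' @export
run_campaign <- function(sphere_diameter, tables, n_events,
                         selection_net_charge = 1, E0 = 100,
                         solvation_threshold = 11, entry = "disk",
                         max_steps = 1e6, max_attempts = 1000 * n_events) {
  stopifnot(n_events >= 1)
  n_ion <- integer(n_events)
  n_solv <- integer(n_events)
  pos <- vector("list", n_events)
  kept <- 0L; attempts <- 0L
  emax <- 0
  while (kept < n_events) {
    if (attempts >= max_attempts) {
      stop("attempt cap reached with ", kept, " of ", n_events,
           " events kept (acceptance ", signif(kept / attempts, 3), ")")
    }
    attempts <- attempts + 1L
    ev <- transport_electron(sphere_diameter, tables, E0 = E0,
                             solvation_threshold = solvation_threshold,
                             entry = entry, max_steps = max_steps)
    emax <- max(emax, abs(ev$energy$residual))
    if (!is.null(selection_net_charge) &&
        ev$net_charge != selection_net_charge) next
    kept <- kept + 1L
    n_ion[kept] <- ev$n_ionizations
    n_solv[kept] <- ev$n_solvated_inside
    if (ev$n_ionizations > 0) {
      pos[[kept]] <- cbind(event = kept, ev$ion_pos)
    }
  }
  positions <- do.call(rbind, pos[!vapply(pos, is.null, logical(1))])
  if (is.null(positions)) positions <- matrix(numeric(0), ncol = 4)
  colnames(positions) <- c("event", "x", "y", "z")
  structure(list(diameter = sphere_diameter, n_events = n_events,
                 n_ionizations = n_ion, n_solvated = n_solv,
                 positions = positions, attempts = attempts,
                 acceptance = kept / attempts, energy_max_error = emax,
                 selection_net_charge = selection_net_charge,
                 settings = list(E0 = E0,
                                 solvation_threshold = solvation_threshold,
                                 entry = entry)),
            class = "ionization_events")
}

#' @export
print.ionization_events <- function(x, ...) {
  cat(sprintf(
    "<ionization_events> d = %g nm, %d events (acceptance %.3g), mean %0.2f ionizations\n",
    x$diameter, x$n_events, x$acceptance, mean(x$n_ionizations)))
  invisible(x)
}

#' Ionization-position map in a central slab
#'
#' Normalised x-z histogram of ionization positions inside a slab
#' `|y| < slab_thickness / 2` through the sphere centre.
#'
#' @param events An [run_campaign()] result.
#' @param slab_thickness Slab thickness (nm, default 1).
#' @param bin_size Bin size (nm, default 0.1).
#' @return Matrix of probabilities (rows: x bins, cols: z bins) with
#'   attributes `x_mid` and `z_mid`; sums to 1 when non-empty.
#' @export
ionization_depth_map <- function(events, slab_thickness = 1, bin_size = 0.1) {
  R <- events$diameter / 2
  breaks <- seq(-R - bin_size, R + bin_size, by = bin_size)
  p <- events$positions
  p <- p[abs(p[, "y"]) < slab_thickness / 2, , drop = FALSE]
  h <- matrix(0, length(breaks) - 1, length(breaks) - 1)
  if (!nrow(p)) {
    warning("no ionizations within the slab; returning an empty map")
  } else {
    ix <- findInterval(p[, "x"], breaks, rightmost.closed = TRUE)
    iz <- findInterval(p[, "z"], breaks, rightmost.closed = TRUE)
    for (r in seq_along(ix)) h[ix[r], iz[r]] <- h[ix[r], iz[r]] + 1
    h <- h / sum(h)
  }
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  attr(h, "x_mid") <- mid
  attr(h, "z_mid") <- mid
  h
}

#' Distribution of the number of hydronium ions per electron impact
#'
#' Under the cryogenic assumption each ionization yields one hydronium ion
#' that stays at the ionization point, so the hydronium count equals the
#' ionization count of the (charge-selected) event.
#'
#' @param events An [run_campaign()] result.
#' @return data.frame with `k` and probability `p`; probabilities sum to 1.
#' @export
hydronium_count_distribution <- function(events) {
  tab <- table(events$n_ionizations)
  data.frame(k = as.integer(names(tab)),
             p = as.numeric(tab) / sum(tab))
}
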