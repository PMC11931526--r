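## Comparison of simulated complex counts against an experimental intensity
## series on the kinetic-energy-per-projectile-molecule axis, both scaled to
## their maxima.

#' Kinetic energy per projectile molecule
#'
#' All projectiles carry the same total kinetic energy (default 20 keV), so
#' the energy per molecule is simply `E_total / n`.
#'
#' @param n Projectile size (number of water molecules), >= 1.
#' @param e_total Total projectile kinetic energy (eV, default 20000).
#' @return Energy per molecule in eV.
#' @export
energy_per_molecule <- function(n, e_total = 20000) {
  if (any(n < 1)) stop("projectile size n must be >= 1")
  e_total / n
}

#' Build a signal series on the projectile-size axis
#'
#' @param n Projectile sizes (molecules).
#' @param value Signal values (arbitrary units, >= 0).
#' @param e_total Total projectile kinetic energy (eV, default 20000).
#' @return data.frame with n, energy_per_molecule, value.
#' @export
signal_series <- function(n, value, e_total = 20000) {
  stopifnot(length(n) == length(value))
  if (any(value < 0)) stop("signal values must be non-negative")
  data.frame(n = n, energy_per_molecule = energy_per_molecule(n, e_total),
             value = value)
}

#' Scale a series to its maximum
#'
#' Divides every value by the series maximum so the maximum maps to 1;
#' idempotent and invariant under positive rescaling of the input.
#'
#' @param series A [signal_series()] data.frame or a numeric vector.
#' @return Same shape as the input, values scaled.
#' @export
scale_to_max <- function(series) {
  v <- if (is.data.frame(series)) series$value else series
  m <- max(v)
  if (m <= 0) stop("cannot scale: series maximum is not positive")
  if (is.data.frame(series)) {
    series$value <- v / m
    series
  } else {
    v / m
  }
}

#' Compare a simulated and an experimental series
#'
#' Both series are scaled to their maxima, joined on projectile size n, and
#' compared point-wise. The contiguous energy region where the absolute
#' deviation exceeds `divergence_threshold` is flagged.
#'
#' @param simulated,experimental [signal_series()] data.frames.
#' @param divergence_threshold Deviation flag level (default 0.2).
#' @return Object of class `series_comparison`: list with `table`
#'   (n, energy_per_molecule, simulated, experimental, deviation, ratio),
#'   `max_abs_deviation`, `divergent` (flagged sub-table) and
#'   `divergent_energy_range` (NULL when nothing is flagged).
#' @export
compare_series <- function(simulated, experimental, divergence_threshold = 0.2) {
  s <- scale_to_max(simulated)
  e <- scale_to_max(experimental)
  j <- merge(s[c("n", "energy_per_molecule", "value")],
             e[c("n", "value")], by = "n", suffixes = c("_sim", "_exp"))
  if (!nrow(j)) stop("series share no common projectile sizes")
  j <- j[order(j$n), ]
  tab <- data.frame(n = j$n, energy_per_molecule = j$energy_per_molecule,
                    simulated = j$value_sim, experimental = j$value_exp,
                    deviation = abs(j$value_sim - j$value_exp),
                    ratio = ifelse(j$value_exp > 0,
                                   j$value_sim / j$value_exp, NA_real_))
  rownames(tab) <- NULL
  div <- tab[tab$deviation > divergence_threshold, , drop = FALSE]
  structure(list(
    table = tab,
    max_abs_deviation = max(tab$deviation),
    divergent = div,
    divergent_energy_range = if (nrow(div)) range(div$energy_per_molecule) else NULL,
    divergence_threshold = divergence_threshold
  ), class = "series_comparison")
}

#' @export
print.series_comparison <- function(x, ...) {
  cat(sprintf("<series_comparison> %d points, max |deviation| = %.3g\n",
              nrow(x$table), x$max_abs_deviation))
  if (!is.null(x$divergent_energy_range)) {
    cat(sprintf("  divergence (> %.2g) between %.3g and %.3g eV/molecule\n",
                x$divergence_threshold, x$divergent_energy_range[1],
                x$divergent_energy_range[2]))
  }
  invisible(x)
}
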