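## Cross-section fixtures and models for the electron Monte Carlo.

#' Toy cross-section tables with closed-form behaviour
#'
#' Constant-rate tables designed so the ionization-count distribution has a
#' closed form. In the `"ionization_only"` variant an electron entering on
#' the sphere axis travels a straight chord of length d (the diameter) and
#' ionizes at constant rate 1/`mean_free_path`, losing `ionization_loss` eV
#' each time (secondary energy 0), so the count follows a Poisson(d / mfp)
#' distribution truncated at the energy-allowed cap; the cap and rate are
#' recorded in the `oracle` attribute. `"elastic_ionization"` adds an
#' isotropic elastic channel (no closed form; used for ordering checks) and
#' `"inert"` has zero rates everywhere.
#'
#' @param mean_free_path Ionization mean free path (nm).
#' @param ionization_loss Energy lost per ionization (eV); also the
#'   effective threshold.
#' @param variant `"ionization_only"`, `"elastic_ionization"`, or `"inert"`.
#' @param E0 Primary energy the oracle cap is computed for (eV).
#' @param solvation_threshold Solvation energy used for the cap (eV).
#' @param elastic_mean_free_path Elastic MFP for `"elastic_ionization"`.
#' @return An [cross_section_table()] with an `oracle` attribute
#'   (`rate_per_nm`, `cap`, `E0`).
#' @export
make_toy_cross_sections <- function(mean_free_path, ionization_loss,
                                    variant = c("ionization_only",
                                                "elastic_ionization", "inert"),
                                    E0 = 100, solvation_threshold = 11,
                                    elastic_mean_free_path = mean_free_path) {
  variant <- match.arg(variant)
  if (mean_free_path <= 0) stop("mean_free_path must be > 0")
  grid <- c(0.001, E0 * 2)
  rate <- switch(variant,
    ionization_only = 1 / mean_free_path,
    elastic_ionization = 1 / mean_free_path,
    inert = 0)
  el_rate <- if (variant == "elastic_ionization") 1 / elastic_mean_free_path else 0
  tab <- cross_section_table(
    energy = grid,
    elastic = rep(el_rate, 2),
    excitation = c(0, 0),
    ionization = rep(rate, 2),
    excitation_loss = 1,
    ionization_threshold = ionization_loss,
    secondary_rule = "fixed", secondary_energy = 0,
    elastic_angle = "isotropic", ionization_angle = "forward"
  )
  ## energy-allowed cap: each ionization needs E >= ionization_loss, and the
  ## electron only keeps transporting while E stays at or above the
  ## solvation threshold
  cap <- 0L
  E <- E0
  repeat {
    if (E < ionization_loss) break
    cap <- cap + 1L
    E <- E - ionization_loss
    if (E < solvation_threshold) break
  }
  attr(tab, "oracle") <- list(rate_per_nm = rate, cap = cap, E0 = E0,
                              loss = ionization_loss,
                              solvation_threshold = solvation_threshold)
  tab
}

#' Approximate liquid-water cross sections for low-energy electrons
#'
#' A self-contained, approximate model of electron interactions in liquid
#' water (density 1.0 g/cm^3, 33.37 molecules/nm^3), intended for
#' order-of-magnitude track-structure studies where tabulated
#' condensed-phase cross sections are not at hand:
#'
#' * ionization: Binary-Encounter-Bethe (BEB) total cross sections summed
#'   over the five molecular orbitals of H2O (vapour binding and orbital
#'   kinetic energies), with a single effective threshold taken as the
#'   BEB-weighted mean binding energy at 100 eV;
#' * excitation: a single effective electronic level at 8.4 eV with a
#'   Born-like `ln(E/W)/E` shape normalised to 0.8 A^2 at 100 eV;
#' * elastic: a power-law fit `5 A^2 (100 eV / E)^0.7`, capped at 15 A^2,
#'   scattered isotropically.
#'
#' Secondary electrons are sampled from a steeply falling Lorentzian
#' spectrum (`1/(w^2 + a^2)` with `a` = 13 eV on `[0, (E - I)/2]`, the
#' characteristic shape of knock-on spectra) and cascaded with the same
#' rules.
#' These are deliberate simplifications; see the package vignette for what
#' they do and do not capture.
#'
#' @param energy Energy grid in eV (default 1 to 200 eV in 1 eV steps).
#' @return An [cross_section_table()].
#' @export
make_water_cross_sections <- function(energy = seq(1, 200, by = 1)) {
  n_water <- 33.37            # molecules per nm^3 at 1.0 g/cm^3
  A2_to_nm2 <- 0.01
  ## H2O orbital parameters for BEB: binding B (eV), orbital kinetic U (eV),
  ## occupancy N
  orb <- data.frame(
    B = c(12.62, 14.75, 18.51, 32.40, 539.7),
    U = c(61.91, 59.52, 48.36, 70.71, 794.0),
    N = c(2, 2, 2, 2, 2)
  )
  beb_orbital <- function(T, B, U, N) {
    t <- T / B; u <- U / B
    ifelse(t <= 1, 0, {
      S <- 4 * pi * 0.529177e-1^2 * N * (13.6057 / B)^2  # nm^2 (a0 in nm)
      S / (t + u + 1) * (log(t) / 2 * (1 - 1 / t^2) + 1 - 1 / t -
                           log(t) / (t + 1))
    })
  }
  sigma_ion <- rowSums(vapply(seq_len(nrow(orb)), function(k) {
    beb_orbital(energy, orb$B[k], orb$U[k], orb$N[k])
  }, numeric(length(energy))))                    # nm^2
  ## effective threshold: BEB-weighted mean binding at 100 eV
  w100 <- vapply(seq_len(nrow(orb)), function(k) {
    beb_orbital(100, orb$B[k], orb$U[k], orb$N[k])
  }, numeric(1))
  I_eff <- sum(w100 * orb$B) / sum(w100)
  ## excitation: single effective level
  W_exc <- 8.4
  c_exc <- 0.8 * 100 / log(100 / W_exc)           # A^2 eV
  sigma_exc <- ifelse(energy > W_exc,
                      c_exc * log(energy / W_exc) / energy, 0) * A2_to_nm2
  ## elastic: power-law fit, capped at low energy
  sigma_el <- pmin(15, 5 * (100 / energy)^0.7) * A2_to_nm2
  cross_section_table(
    energy = energy,
    elastic = n_water * sigma_el,
    excitation = n_water * sigma_exc,
    ionization = n_water * sigma_ion,
    excitation_loss = W_exc,
    ionization_threshold = I_eff,
    secondary_rule = "lorentzian",
    secondary_energy = 13,
    elastic_angle = "isotropic",
    ionization_angle = "isotropic"
  )
}
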