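# 1 amu nm^2 / ps^2 expressed in eV (CODATA amu and elementary charge).
KE_EV_PER_AMU_NM2_PS2 <- 0.0103642688

.ejecta_env <- new.env(parent = emptyenv())

#' Standard atomic masses
#'
#' Returns the table of conventional atomic masses (amu, 3 decimals) used for
#' all formula masses in the package. The values are stored in a plain-text
#' data file so that mass-dependent results are bit-stable.
#'
#' @return Named numeric vector, element symbol -> mass in amu.
#' @export
#' @examples
#' atomic_masses()[["O"]]
atomic_masses <- function() {
  if (is.null(.ejecta_env$masses)) {
    path <- system.file("extdata", "atomic-masses.csv", package = "ejecta")
    tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    .ejecta_env$masses <- stats::setNames(tab$mass_amu, tab$element)
  }
  .ejecta_env$masses
}

#' Mass of one or more elements
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of masses in amu.
#' @export
element_mass <- function(element) {
  m <- atomic_masses()[element]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Convert kinetic energy from internal units to eV
#'
#' Internal kinetic energies are amu nm^2/ps^2; this applies the exact
#' conversion factor (1 amu nm^2/ps^2 = 0.0103642688 eV).
#'
#' @param ke_internal Numeric vector in amu nm^2/ps^2.
#' @return Numeric vector in eV.
#' @export
ke_to_ev <- function(ke_internal) ke_internal * KE_EV_PER_AMU_NM2_PS2
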