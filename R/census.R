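## Sputter census: a cluster is sputtered when, at the end of the impact
## phase, its centre of mass is at least 15 nm above the surface reference
## and its COM velocity has a positive z component. Yields are reported in
## multiples of the trehalose mass (342.3 amu).

YIELD_CATEGORIES <- c("single_bare", "multiple_bare", "single_solvated",
                      "multiple_solvated", "fragments")

#' Surface reference height
#'
#' The "above the sample" origin: by default the maximum z coordinate among
#' the sample atoms in the initial frame (conservative for a hemisphere);
#' alternatively the mean of the top decile of sample-atom heights.
#'
#' @param frame Initial [md_frame()].
#' @param sample_atom_ids Atom ids belonging to the sample.
#' @param method `"max"` or `"top_decile_mean"`.
#' @return z0 in nm.
#' @export
surface_reference <- function(frame, sample_atom_ids,
                              method = c("max", "top_decile_mean")) {
  method <- match.arg(method)
  if (!length(sample_atom_ids)) stop("sample atom set is empty")
  z <- frame$atoms$z[match(sample_atom_ids, frame$atoms$id)]
  if (anyNA(z)) stop("sample atom id(s) absent from frame")
  if (method == "max") max(z) else mean(sort(z, decreasing = TRUE)[
    seq_len(max(1L, ceiling(length(z) / 10)))])
}

#' Decide which clusters are sputtered
#'
#' @param cluster_set Output of [identify_clusters()] at the evaluation frame.
#' @param z0 Surface reference height (nm), see [surface_reference()].
#' @param height_min Minimum height above `z0` (nm, default 15).
#' @param require_positive_vz Require COM vz > 0 (default TRUE).
#' @return data.frame with cluster_id, height, vz, sputtered (logical) and
#'   the evaluation time.
#' @export
is_sputtered <- function(cluster_set, z0, height_min = 15,
                         require_positive_vz = TRUE) {
  cl <- cluster_set$clusters
  height <- cl$com_z - z0
  ok <- height >= height_min
  if (require_positive_vz) ok <- ok & cl$vcom_z > 0
  data.frame(cluster_id = cl$cluster_id, time = cluster_set$time,
             height = height, vz = cl$vcom_z, sputtered = ok)
}

#' Categorise an ejected cluster's composition
#'
#' Fragment molecules' mass is pooled into `fragments`; the residual intact
#' composition is then categorised: one trehalose without water ->
#' `single_bare`, several without water -> `multiple_bare`, one/several with
#' water -> `single_solvated` / `multiple_solvated`. Pure-water clusters are
#' tallied under `pure_water` and excluded from the five yield categories.
#' With `solvated_mass_includes_water = FALSE` the adjoining waters' mass in
#' solvated clusters is tallied under `pure_water` instead.
#'
#' @param species Character vector of member-molecule species labels.
#' @param mass Numeric vector of member-molecule masses (amu).
#' @param solvated_mass_includes_water Count adjoining waters' mass in the
#'   solvated categories (default TRUE).
#' @return List with `category` (label of the residual intact composition,
#'   or `"pure_water"`, or `"fragments_only"`) and `masses` (named vector
#'   over the five categories plus `pure_water`, amu).
#' @export
categorize_cluster <- function(species, mass,
                               solvated_mass_includes_water = TRUE) {
  if (!length(species)) stop("empty cluster composition")
  stopifnot(length(species) == length(mass))
  out <- stats::setNames(numeric(length(YIELD_CATEGORIES) + 1),
                         c(YIELD_CATEGORIES, "pure_water"))
  frag <- species == "fragment"
  out["fragments"] <- sum(mass[frag])
  n_treh <- sum(species == "intact_trehalose")
  n_water <- sum(species == "water")
  treh_mass <- sum(mass[species == "intact_trehalose"])
  water_mass <- sum(mass[species == "water"])
  category <- if (n_treh == 0 && n_water == 0) {
    "fragments_only"
  } else if (n_treh == 0) {
    out["pure_water"] <- out["pure_water"] + water_mass
    "pure_water"
  } else {
    cat_label <- if (n_treh == 1 && n_water == 0) "single_bare"
      else if (n_treh >= 2 && n_water == 0) "multiple_bare"
      else if (n_treh == 1) "single_solvated"
      else "multiple_solvated"
    if (n_water > 0 && !solvated_mass_includes_water) {
      out[cat_label] <- treh_mass
      out["pure_water"] <- out["pure_water"] + water_mass
    } else {
      out[cat_label] <- treh_mass + water_mass
    }
    cat_label
  }
  list(category = category, masses = out)
}

#' Combine per-impact category masses into a yield breakdown
#'
#' Yields are (sputtered mass in category) / reference mass, averaged over
#' impacts; `total` is the sum of the five categories (pure-water ejecta are
#' reported separately and excluded from the total).
#'
#' @param impacts List with one named mass vector (amu) per impact, with
#'   names `single_bare`, `multiple_bare`, `single_solvated`,
#'   `multiple_solvated`, `fragments` and optionally `pure_water`.
#' @param reference_mass Reference mass in amu (default 342.3, trehalose).
#' @return Object of class `yield_breakdown`: data.frame with category,
#'   mean, sd (in reference-mass units) plus attributes `n_impacts` and
#'   `reference_mass`.
#' @export
compute_yields <- function(impacts, reference_mass = 342.3) {
  if (!length(impacts)) stop("need at least one impact")
  cats <- c(YIELD_CATEGORIES, "pure_water")
  m <- t(vapply(impacts, function(v) {
    out <- stats::setNames(numeric(length(cats)), cats)
    out[names(v)] <- v
    out
  }, numeric(length(cats))))
  y <- m / reference_mass
  total <- rowSums(y[, YIELD_CATEGORIES, drop = FALSE])
  y <- cbind(y, total = total)
  res <- data.frame(
    category = colnames(y),
    mean = colMeans(y),
    sd = apply(y, 2, stats::sd),
    row.names = NULL
  )
  structure(res, class = c("yield_breakdown", "data.frame"),
            n_impacts = length(impacts), reference_mass = reference_mass)
}

#' Mass spectrum of sputtered molecules
#'
#' Histogram of molecule (or cluster) masses per impact.
#'
#' @param masses Masses (amu) of the sputtered entities, pooled over impacts.
#' @param bin_width Bin width in amu (default 1).
#' @param n_impacts Number of impacts pooled (default 1).
#' @return data.frame with `mass` (bin centre, amu) and `count_per_impact`;
#'   empty bins are dropped.
#' @export
mass_spectrum <- function(masses, bin_width = 1, n_impacts = 1) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (!length(masses)) {
    return(data.frame(mass = numeric(), count_per_impact = numeric()))
  }
  bin <- floor(masses / bin_width)
  tab <- table(bin)
  data.frame(mass = (as.numeric(names(tab)) + 0.5) * bin_width,
             count_per_impact = as.numeric(tab) / n_impacts)
}

#' Kinetic energy of each molecule in a frame
#'
#' KE = 1/2 sum_atoms m v^2, converted from amu nm^2/ps^2 to eV.
#'
#' @param frame An [md_frame()].
#' @param molecule_set Output of [identify_molecules()].
#' @return data.frame with molecule_id and ke_ev.
#' @export
per_molecule_kinetic_energy <- function(frame, molecule_set) {
  a <- frame$atoms
  asn <- molecule_set$assignment
  idx <- match(asn$atom_id, a$id)
  m <- element_mass(a$element[idx])
  ke_atom <- 0.5 * m * (a$vx[idx]^2 + a$vy[idx]^2 + a$vz[idx]^2)
  ke <- tapply(ke_atom, asn$molecule_id, sum)
  data.frame(molecule_id = as.integer(names(ke)),
             ke_ev = ke_to_ev(as.numeric(ke)))
}
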