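#' Census configuration
#'
#' Collects the tunable parameters of the trajectory census in one place.
#' Defaults follow the analysis conventions: bond-order connectivity 0.3,
#' contact cutoff 0.3 nm, sputter height 15 nm evaluated at the 75 ps end of
#' the impact phase, complex stability cutoff 320 ps with at most one water
#' at the end, 40 ps minimum displayed contact, trehalose reference mass
#' 342.3 amu.
#'
#' @param bo_threshold Bond-order threshold for molecular connectivity.
#' @param contact_cutoff Molecule contact distance (nm).
#' @param height_min Sputter height criterion (nm).
#' @param eval_time End-of-impact evaluation time (ps).
#' @param reference_mass Yield reference mass (amu).
#' @param min_stable Minimum complex stability (ps).
#' @param max_final_waters Maximum waters at the last frame for inclusion.
#' @param min_display Minimum total contact for the contact map (ps).
#' @param solvated_mass_includes_water Count adjoining-water mass in the
#'   solvated yield categories.
#' @param surface_method `"max"` or `"top_decile_mean"`, see
#'   [surface_reference()].
#' @param allow_gap_frames Number of consecutive water-free frames tolerated
#'   before a complex counts as dissolved (0 = strict continuity).
#' @param templates Species templates, see [species_templates()].
#' @return Named list of class `census_config`.
#' @export
census_config <- function(bo_threshold = 0.3, contact_cutoff = 0.3,
                          height_min = 15, eval_time = 75,
                          reference_mass = 342.3, min_stable = 320,
                          max_final_waters = 1, min_display = 40,
                          solvated_mass_includes_water = TRUE,
                          surface_method = "max", allow_gap_frames = 0,
                          templates = species_templates()) {
  structure(list(bo_threshold = bo_threshold, contact_cutoff = contact_cutoff,
                 height_min = height_min, eval_time = eval_time,
                 reference_mass = reference_mass, min_stable = min_stable,
                 max_final_waters = max_final_waters, min_display = min_display,
                 solvated_mass_includes_water = solvated_mass_includes_water,
                 surface_method = surface_method,
                 allow_gap_frames = allow_gap_frames, templates = templates),
            class = "census_config")
}

#' Run molecule identification, identity tracking and clustering per frame
#'
#' The workhorse pass shared by the sputter census and the complex-lifetime
#' analysis: every frame is paired with its nearest bond table, molecules are
#' identified from bond orders, stable ids are threaded through time, and
#' contact clusters are assembled.
#'
#' @param trajectory An [md_trajectory()].
#' @param bond_tables List of [bond_table()] objects.
#' @param config A [census_config()].
#' @return Object of class `trajectory_analysis`: list with `trajectory`,
#'   `molecule_sets`, `cluster_sets`, `reaction_events`, `config`.
#' @export
analyze_trajectory <- function(trajectory, bond_tables,
                               config = census_config()) {
  times <- frame_times(trajectory)
  msets <- vector("list", length(times))
  for (k in seq_along(times)) {
    mb <- match_bonds_to_frame(trajectory, bond_tables, times[k])
    msets[[k]] <- identify_molecules(mb$frame, mb$bonds,
                                     bo_threshold = config$bo_threshold,
                                     templates = config$templates)
  }
  tracked <- track_molecule_identity(msets)
  csets <- vector("list", length(times))
  for (k in seq_along(times)) {
    csets[[k]] <- identify_clusters(trajectory$frames[[k]], tracked$sets[[k]],
                                    contact_cutoff = config$contact_cutoff)
  }
  structure(list(trajectory = trajectory, molecule_sets = tracked$sets,
                 cluster_sets = csets, reaction_events = tracked$events,
                 config = config),
            class = "trajectory_analysis")
}

#' @export
print.trajectory_analysis <- function(x, ...) {
  cat(sprintf("<trajectory_analysis> %d frames, %d reaction events\n",
              length(x$molecule_sets), nrow(x$reaction_events)))
  invisible(x)
}

#' Sputter census of a single impact
#'
#' Evaluates the sputter criterion at the end-of-impact frame and decomposes
#' the sputtered mass into yield categories.
#'
#' @param analysis A [analyze_trajectory()] result covering the impact phase.
#' @param sample_atom_ids Atom ids of the sample (for the surface reference).
#' @param config A [census_config()].
#' @return List with `z0`, `records` (per-cluster sputter decisions),
#'   `category_masses` (named vector, amu), `categories` (per sputtered
#'   cluster), `eval_time`.
#' @export
census_impact <- function(analysis, sample_atom_ids,
                          config = analysis$config) {
  traj <- analysis$trajectory
  times <- frame_times(traj)
  z0 <- surface_reference(traj$frames[[1]], sample_atom_ids,
                          method = config$surface_method)
  k <- which.min(abs(times - config$eval_time))
  cs <- analysis$cluster_sets[[k]]
  ms <- analysis$molecule_sets[[k]]
  rec <- is_sputtered(cs, z0, height_min = config$height_min)
  masses <- stats::setNames(numeric(length(YIELD_CATEGORIES) + 1),
                            c(YIELD_CATEGORIES, "pure_water"))
  cats <- character(0)
  mol_tab <- ms$molecules
  for (cid in rec$cluster_id[rec$sputtered]) {
    members <- cs$assignment$molecule_id[cs$assignment$cluster_id == cid]
    mrows <- mol_tab[match(members, mol_tab$molecule_id), ]
    cc <- categorize_cluster(mrows$species, mrows$mass,
                             config$solvated_mass_includes_water)
    masses <- masses + cc$masses
    cats[as.character(cid)] <- cc$category
  }
  list(z0 = z0, records = rec, category_masses = masses,
       categories = cats, eval_time = times[k])
}
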