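## Molecule identification: connected components of the bond-order graph.
## Two atoms are connected when their ReaxFF bond order exceeds the
## threshold (default 0.3, low enough to tolerate bond stretching).

#' Parse or canonicalise a chemical formula
#'
#' Accepts a formula string ("C12H22O11"), a named count vector
#' (`c(C = 12, H = 22, O = 11)`), or a character vector of per-atom element
#' symbols. Returns counts in Hill order (C, H, then alphabetical).
#'
#' @param formula See description.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    counts <- formula
  } else if (is.character(formula) && length(formula) == 1) {
    parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
    if (!length(parts) || sum(nchar(parts)) != nchar(formula)) {
      stop("cannot parse formula string: ", formula)
    }
    el <- sub("[0-9]*$", "", parts)
    n <- sub("^[A-Z][a-z]?", "", parts)
    counts <- stats::setNames(ifelse(nzchar(n), as.integer(n), 1L), el)
    counts <- tapply(counts, names(counts), sum)
    counts <- stats::setNames(as.integer(counts), names(counts))
  } else if (is.character(formula)) {
    tab <- table(formula)
    counts <- stats::setNames(as.integer(tab), names(tab))
  } else {
    stop("unsupported formula representation")
  }
  counts <- counts[counts > 0]
  els <- names(counts)
  ord <- if ("C" %in% els) {
    c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  } else {
    sort(els)
  }
  storage.mode(counts) <- "integer"
  counts[ord]
}

#' Formula string in Hill order
#' @param counts Named element counts (any representation [parse_formula()] takes).
#' @return Single formula string, e.g. "C12H22O11".
#' @export
formula_string <- function(counts) {
  counts <- parse_formula(counts)
  paste0(names(counts), ifelse(counts > 1, counts, ""), collapse = "")
}

#' Formula and mass of a molecule
#'
#' Mass is the sum of conventional atomic masses over the element counts;
#' for trehalose C12H22O11 this gives the reference mass 342.3 amu
#' (to one decimal).
#'
#' @param formula Any representation accepted by [parse_formula()].
#' @return List with `formula` (canonical string), `counts`, `mass` (amu).
#' @export
#' @examples
#' formula_and_mass("C12H22O11")$mass  # 342.297
formula_and_mass <- function(formula) {
  counts <- parse_formula(formula)
  mass <- sum(counts * element_mass(names(counts)))
  list(formula = formula_string(counts), counts = counts, mass = mass)
}

#' Species templates for classification
#'
#' @param intact Formula of the intact sample molecule.
#' @param solvent Formula of the solvent molecule.
#' @return Named list of canonical formula strings.
#' @export
species_templates <- function(intact = "C12H22O11", solvent = "H2O") {
  list(intact = formula_string(intact), solvent = formula_string(solvent))
}

#' Classify a molecular formula as water, intact molecule, or fragment
#'
#' Classification is per-frame and purely by formula: anything that is not
#' the solvent or the intact-sample template is a fragment.
#'
#' @param formula Any representation accepted by [parse_formula()].
#' @param templates Output of [species_templates()].
#' @return One of `"water"`, `"intact_trehalose"`, `"fragment"`.
#' @export
classify_species <- function(formula, templates = species_templates()) {
  f <- formula_string(formula)
  if (f == templates$solvent) return("water")
  if (f == templates$intact) return("intact_trehalose")
  "fragment"
}

#' Identify molecules in a frame from its bond table
#'
#' Molecules are the connected components of the graph on the frame's atoms
#' whose edges are the bonds with `bond_order > bo_threshold` (strict).
#' Isolated atoms become single-atom molecules. Molecule ids are assigned in
#' order of each component's smallest atom id, so output is deterministic.
#'
#' @param frame An [md_frame()].
#' @param bonds A [bond_table()]; its atoms must be a subset of the frame's.
#' @param bo_threshold Bond-order connectivity threshold (default 0.3).
#' @param templates Species templates, see [species_templates()].
#' @return An object of class `molecule_set`: list with `time`,
#'   `assignment` (data.frame atom_id -> molecule_id) and `molecules`
#'   (data.frame molecule_id, formula, n_atoms, mass, species).
#' @export
identify_molecules <- function(frame, bonds, bo_threshold = 0.3,
                               templates = species_templates()) {
  stopifnot(inherits(frame, "md_frame"), inherits(bonds, "bond_table"))
  if (bo_threshold <= 0) stop("bo_threshold must be > 0")
  ids <- frame$atoms$id
  b <- bonds$bonds
  unknown <- setdiff(unique(c(b$i, b$j)), ids)
  if (length(unknown)) {
    stop("bond table references atom id(s) absent from frame: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  b <- b[b$bo > bo_threshold, , drop = FALSE]
  membership <- .components(ids, b$i, b$j)
  ## deterministic molecule ids: order components by smallest member atom id
  comp_min <- tapply(ids, membership, min)
  relabel <- stats::setNames(rank(comp_min, ties.method = "first"),
                             names(comp_min))
  mol_id <- as.integer(relabel[as.character(membership)])
  assignment <- data.frame(atom_id = ids, molecule_id = mol_id)
  elements <- split(frame$atoms$element, mol_id)
  mols <- lapply(names(elements), function(k) {
    fm <- formula_and_mass(elements[[k]])
    data.frame(molecule_id = as.integer(k), formula = fm$formula,
               n_atoms = length(elements[[k]]), mass = fm$mass,
               species = classify_species(fm$counts, templates),
               stringsAsFactors = FALSE)
  })
  molecules <- do.call(rbind, mols)
  molecules <- molecules[order(molecules$molecule_id), , drop = FALSE]
  rownames(molecules) <- NULL
  ## mass conservation invariant
  atom_mass_sum <- sum(element_mass(frame$atoms$element))
  stopifnot(abs(sum(molecules$mass) - atom_mass_sum) < 1e-9)
  structure(list(time = frame$time, assignment = assignment,
                 molecules = molecules),
            class = "molecule_set")
}

## connected components over integer vertex ids (edges ei -> ej), via igraph
.components <- function(ids, ei, ej) {
  if (!length(ei)) return(seq_along(ids))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(ei), to = as.character(ej)),
    directed = FALSE,
    vertices = data.frame(name = as.character(ids))
  )
  comp <- igraph::components(g)$membership
  as.integer(comp[as.character(ids)])
}

#' @export
print.molecule_set <- function(x, ...) {
  tab <- table(x$molecules$species)
  cat(sprintf("<molecule_set> t = %g ps, %d molecules (%s)\n", x$time,
              nrow(x$molecules),
              paste(names(tab), tab, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Track molecule identity across frames
#'
#' A molecule keeps its stable id from one frame to the next exactly when
#' the correspondence is one-to-one: all of its atoms stay together and no
#' other molecule's atoms join (in a conserved atom universe the two atom
#' sets are then identical). A molecule whose atoms land in two or more
#' successors loses its id in a logged scission event; a molecule drawing
#' atoms from two or more predecessors is a logged merge. Fresh stable ids
#' are assigned to every product.
#'
#' @param molecule_sets List of `molecule_set` objects ordered by time.
#' @return List with `sets` (the inputs, each `molecules` table gaining a
#'   `stable_id` column) and `events` (data.frame time, type
#'   ("scission"/"merge"), old_ids, new_ids).
#' @export
track_molecule_identity <- function(molecule_sets) {
  if (length(molecule_sets) < 1) stop("need at least one molecule set")
  counter <- 0L
  events <- list()
  prev_stable <- NULL  # named: molecule_id -> stable_id
  out <- molecule_sets
  for (fi in seq_along(molecule_sets)) {
    ms <- molecule_sets[[fi]]
    mids <- ms$molecules$molecule_id
    if (fi == 1L) {
      stable <- stats::setNames(seq_along(mids) + counter, mids)
      counter <- counter + length(mids)
    } else {
      prev <- molecule_sets[[fi - 1L]]
      ov <- merge(
        stats::setNames(prev$assignment, c("atom_id", "prev_mol")),
        stats::setNames(ms$assignment, c("atom_id", "cur_mol")),
        by = "atom_id"
      )
      pairs <- unique(ov[c("prev_mol", "cur_mol")])
      kids_of <- split(pairs$cur_mol, pairs$prev_mol)
      parents_of <- split(pairs$prev_mol, pairs$cur_mol)
      stable <- stats::setNames(integer(length(mids)), mids)
      for (m in mids) {
        parents <- parents_of[[as.character(m)]]
        one_to_one <- length(parents) == 1L &&
          length(kids_of[[as.character(parents)]]) == 1L
        if (one_to_one) {
          stable[as.character(m)] <- prev_stable[as.character(parents)]
        } else {
          counter <- counter + 1L
          stable[as.character(m)] <- counter
        }
      }
      for (p in names(kids_of)) {
        kids <- kids_of[[p]]
        if (length(kids) >= 2) {
          events[[length(events) + 1L]] <- data.frame(
            time = ms$time, type = "scission",
            old_ids = as.character(prev_stable[p]),
            new_ids = paste(sort(stable[as.character(kids)]), collapse = "+"),
            stringsAsFactors = FALSE)
        }
      }
      for (m in names(parents_of)) {
        parents <- parents_of[[m]]
        if (length(parents) >= 2) {
          events[[length(events) + 1L]] <- data.frame(
            time = ms$time, type = "merge",
            old_ids = paste(sort(prev_stable[as.character(parents)]),
                            collapse = "+"),
            new_ids = as.character(stable[as.character(m)]),
            stringsAsFactors = FALSE)
        }
      }
    }
    out[[fi]]$molecules$stable_id <- as.integer(stable[as.character(mids)])
    prev_stable <- stable
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(time = numeric(), type = character(),
               old_ids = character(), new_ids = character())
  list(sets = out, events = events)
}
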