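## Cluster assembly: molecules are in contact when the smallest distance
## between their atoms is below the contact cutoff (default 0.3 nm, strict
## inequality); clusters are connected components of the contact graph.
## All distances are Euclidean -- the sample is an open hemisphere in
## vacuum, so there is no periodic boundary handling anywhere.

.coords <- function(frame, atom_ids) {
  a <- frame$atoms
  idx <- match(atom_ids, a$id)
  if (anyNA(idx)) stop("atom id(s) absent from frame")
  as.matrix(a[idx, c("x", "y", "z")])
}

#' Smallest inter-atomic distance between two molecules
#'
#' Minimum Euclidean distance over all cross pairs of atoms.
#'
#' @param frame An [md_frame()].
#' @param atoms_a,atoms_b Disjoint atom-id vectors of the two molecules.
#' @return Distance in nm.
#' @export
min_intermolecular_distance <- function(frame, atoms_a, atoms_b) {
  if (!length(atoms_a) || !length(atoms_b)) stop("empty molecule")
  if (length(intersect(atoms_a, atoms_b))) stop("molecules share atoms")
  A <- .coords(frame, atoms_a)
  B <- .coords(frame, atoms_b)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(max(min(d2), 0))
}

#' Group molecules into contact clusters
#'
#' Builds the molecule contact graph (edges where the smallest inter-atomic
#' distance is `< contact_cutoff`) and returns its connected components with
#' per-cluster composition and mass-weighted kinematics. A bounding-sphere
#' prefilter skips molecule pairs that cannot be in contact; the result is
#' identical to the all-pairs computation.
#'
#' @param frame An [md_frame()].
#' @param molecule_set Output of [identify_molecules()].
#' @param contact_cutoff Contact distance in nm (default 0.3, strict `<`).
#' @return Object of class `cluster_set`: list with `time`, `assignment`
#'   (molecule_id -> cluster_id) and `clusters` (composition counts, mass,
#'   COM position and velocity). Cluster ids are ordered by smallest member
#'   molecule id.
#' @export
identify_clusters <- function(frame, molecule_set, contact_cutoff = 0.3) {
  stopifnot(inherits(frame, "md_frame"), inherits(molecule_set, "molecule_set"))
  if (contact_cutoff <= 0) stop("contact_cutoff must be > 0")
  asn <- molecule_set$assignment
  mol_atoms <- split(asn$atom_id, asn$molecule_id)
  mids <- as.integer(names(mol_atoms))
  n <- length(mids)
  ## bounding spheres
  centers <- matrix(0, n, 3)
  radius <- numeric(n)
  coords <- lapply(mol_atoms, function(idx) .coords(frame, idx))
  for (k in seq_len(n)) {
    C <- coords[[k]]
    ctr <- colMeans(C)
    centers[k, ] <- ctr
    radius[k] <- sqrt(max(rowSums((C - rep(ctr, each = nrow(C)))^2)))
  }
  ei <- integer(0); ej <- integer(0)
  if (n > 1) {
    cd <- as.matrix(stats::dist(centers))
    lim <- outer(radius, radius, "+") + contact_cutoff
    cand <- which(upper.tri(cd) & cd < lim, arr.ind = TRUE)
    if (nrow(cand)) {
      hit <- logical(nrow(cand))
      for (r in seq_len(nrow(cand))) {
        A <- coords[[cand[r, 1]]]
        B <- coords[[cand[r, 2]]]
        d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
        hit[r] <- min(d2) < contact_cutoff^2
      }
      ei <- mids[cand[hit, 1]]
      ej <- mids[cand[hit, 2]]
    }
  }
  membership <- .components(mids, ei, ej)
  comp_min <- tapply(mids, membership, min)
  relabel <- stats::setNames(rank(comp_min, ties.method = "first"), names(comp_min))
  cl_id <- as.integer(relabel[as.character(membership)])
  assignment <- data.frame(molecule_id = mids, cluster_id = cl_id)
  mol_tab <- molecule_set$molecules
  mol_species <- stats::setNames(mol_tab$species, mol_tab$molecule_id)
  rows <- lapply(sort(unique(cl_id)), function(cid) {
    members <- mids[cl_id == cid]
    atoms <- unlist(mol_atoms[as.character(members)], use.names = FALSE)
    kin <- cluster_kinematics(frame, atoms)
    sp <- mol_species[as.character(members)]
    data.frame(cluster_id = cid,
               n_molecules = length(members),
               n_intact = sum(sp == "intact_trehalose"),
               n_water = sum(sp == "water"),
               n_fragment = sum(sp == "fragment"),
               mass = kin$mass,
               com_x = kin$com[1], com_y = kin$com[2], com_z = kin$com[3],
               vcom_x = kin$vcom[1], vcom_y = kin$vcom[2], vcom_z = kin$vcom[3])
  })
  clusters <- do.call(rbind, rows)
  rownames(clusters) <- NULL
  structure(list(time = frame$time, assignment = assignment, clusters = clusters),
            class = "cluster_set")
}

#' Mass-weighted kinematics of a group of atoms
#'
#' @param frame An [md_frame()].
#' @param atom_ids Atom ids of the group (non-empty).
#' @return List with `com` (nm), `vcom` (nm/ps) and `mass` (amu).
#' @export
cluster_kinematics <- function(frame, atom_ids) {
  if (!length(atom_ids)) stop("empty cluster")
  a <- frame$atoms
  idx <- match(atom_ids, a$id)
  if (anyNA(idx)) stop("atom id(s) absent from frame")
  m <- element_mass(a$element[idx])
  M <- sum(m)
  com <- c(sum(m * a$x[idx]), sum(m * a$y[idx]), sum(m * a$z[idx])) / M
  vcom <- c(sum(m * a$vx[idx]), sum(m * a$vy[idx]), sum(m * a$vz[idx])) / M
  list(com = com, vcom = vcom, mass = M)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> t = %g ps, %d clusters over %d molecules\n",
              x$time, nrow(x$clusters), nrow(x$assignment)))
  invisible(x)
}
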