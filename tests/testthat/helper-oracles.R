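# Independent oracles, written without igraph or any package internals.

# connected components by depth-first search over an edge list
oracle_components <- function(ids, ei, ej) {
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  adj <- vector("list", n)
  for (k in seq_along(ei)) {
    a <- idx[as.character(ei[k])]; b <- idx[as.character(ej[k])]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      stack <- c(stack, adj[[v]])
    }
  }
  comp
}

# canonical labelling of a partition (first-occurrence order)
canon_partition <- function(labels) {
  match(labels, unique(labels))
}

# brute-force cluster oracle: all-pairs smallest atom distance, DFS merge
oracle_clusters <- function(frame, molecule_set, cutoff) {
  asn <- molecule_set$assignment
  mol_atoms <- split(asn$atom_id, asn$molecule_id)
  mids <- as.integer(names(mol_atoms))
  n <- length(mids)
  a <- frame$atoms
  coord <- function(idv) as.matrix(a[match(idv, a$id), c("x", "y", "z")])
  ei <- integer(0); ej <- integer(0)
  if (n > 1) {
    for (p in 1:(n - 1)) for (q in (p + 1):n) {
      A <- coord(mol_atoms[[p]]); B <- coord(mol_atoms[[q]])
      dmin <- Inf
      for (r in seq_len(nrow(A))) {
        d <- sqrt(colSums((t(B) - A[r, ])^2))
        dmin <- min(dmin, min(d))
      }
      if (dmin < cutoff) { ei <- c(ei, mids[p]); ej <- c(ej, mids[q]) }
    }
  }
  oracle_components(mids, ei, ej)
}

# random bond-graph instance over a toy frame
random_bond_instance <- function(seed, n_atoms = 60) {
  set.seed(seed)
  atoms <- data.frame(
    id = sample(seq_len(5 * n_atoms), n_atoms),  # scrambled, sparse ids
    element = sample(c("H", "C", "O"), n_atoms, replace = TRUE),
    x = runif(n_atoms, 0, 5), y = runif(n_atoms, 0, 5),
    z = runif(n_atoms, 0, 5),
    vx = rnorm(n_atoms), vy = rnorm(n_atoms), vz = rnorm(n_atoms))
  frame <- md_frame(0, atoms)
  n_bonds <- sample(0:(2 * n_atoms), 1)
  if (n_bonds > 0) {
    pairs <- t(replicate(n_bonds, sample(atoms$id, 2)))
    b <- data.frame(i = pmin(pairs[, 1], pairs[, 2]),
                    j = pmax(pairs[, 1], pairs[, 2]),
                    bo = runif(n_bonds, 0, 1))
    b <- b[!duplicated(paste(b$i, b$j)), ]
  } else {
    b <- NULL
  }
  list(frame = frame, bonds = bond_table(0, b))
}

# random scene of small molecules for the cluster oracle
random_cluster_instance <- function(seed, n_mol = 18) {
  set.seed(seed)
  rows <- list(); bonds <- list(); next_id <- 1L
  for (m in seq_len(n_mol)) {
    k <- sample(1:4, 1)
    ctr <- runif(3, 0, 4)
    ids <- seq.int(next_id, length.out = k)
    next_id <- next_id + k
    xyz <- matrix(ctr, k, 3, byrow = TRUE) + matrix(runif(3 * k, -0.1, 0.1), k)
    rows[[m]] <- data.frame(id = ids,
                            element = sample(c("H", "C", "O"), k, TRUE),
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            vx = 0, vy = 0, vz = 0)
    if (k > 1) bonds[[m]] <- data.frame(i = ids[-k], j = ids[-1], bo = 0.9)
  }
  frame <- md_frame(0, do.call(rbind, rows))
  bt <- bond_table(0, if (length(bonds)) do.call(rbind, bonds) else NULL)
  list(frame = frame, molecule_set = identify_molecules(frame, bt))
}

# truncated Poisson pmf on 0..cap (mass above cap collapsed onto cap)
trunc_pois_pmf <- function(lambda, cap) {
  p <- dpois(0:cap, lambda)
  p[cap + 1] <- 1 - ppois(cap - 1, lambda)
  p
}

# tiny water frame: O,H,H at given center
water_frame_atoms <- function(id0, ctr, vz = 0) {
  data.frame(id = id0 + 0:2, element = c("O", "H", "H"),
             x = ctr[1] + c(0, 0.096, -0.032),
             y = ctr[2] + c(0, 0, 0.0906),
             z = ctr[3] + c(0, 0, 0),
             vx = 0, vy = 0, vz = vz)
}

# small fast scene spec for io/e2e tests
small_scene_spec <- function(events, seed = 1, extended = TRUE, ...) {
  scene_spec(events = events, n_background = 2, projectile_waters = 8,
             cadence_impact = 15, cadence_extended = 25, seed = seed,
             extended = extended, ...)
}
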