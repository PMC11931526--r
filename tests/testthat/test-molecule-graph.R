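make_water_pieces <- function(bo) {
  frame <- md_frame(0, water_frame_atoms(1L, c(0, 0, 0)))
  bonds <- bond_table(0, data.frame(i = c(1, 1), j = c(2, 3), bo = bo))
  list(frame = frame, bonds = bonds)
}

test_that("bond-order threshold splits or joins a water molecule", {
  w <- make_water_pieces(c(0.8, 0.8))
  ms <- identify_molecules(w$frame, w$bonds)
  expect_equal(nrow(ms$molecules), 1)
  expect_equal(ms$molecules$formula, "H2O")
  expect_equal(ms$molecules$species, "water")

  w2 <- make_water_pieces(c(0.2, 0.2))
  ms2 <- identify_molecules(w2$frame, w2$bonds)
  expect_equal(nrow(ms2$molecules), 3)
  expect_true(all(ms2$molecules$n_atoms == 1))

  # exactly at the threshold counts as not bonded (strict >)
  w3 <- make_water_pieces(c(0.3, 0.3))
  expect_equal(nrow(identify_molecules(w3$frame, w3$bonds)$molecules), 3)
})

test_that("molecule partition equals the DFS oracle on random bond graphs", {
  for (seed in 1:12) {
    inst <- random_bond_instance(seed, n_atoms = 80)
    ms <- identify_molecules(inst$frame, inst$bonds, bo_threshold = 0.3)
    b <- inst$bonds$bonds
    b <- b[b$bo > 0.3, ]
    oracle <- oracle_components(inst$frame$atoms$id, b$i, b$j)
    expect_equal(canon_partition(ms$assignment$molecule_id),
                 canon_partition(oracle))
  }
})

test_that("raising the bond-order threshold never decreases molecule count", {
  inst <- random_bond_instance(99, n_atoms = 120)
  counts <- vapply(c(0.1, 0.2, 0.3, 0.5, 0.7, 0.9), function(th) {
    nrow(identify_molecules(inst$frame, inst$bonds, bo_threshold = th)$molecules)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("mass is conserved by the atom-to-molecule partition", {
  inst <- random_bond_instance(7, n_atoms = 100)
  ms <- identify_molecules(inst$frame, inst$bonds)
  expect_equal(sum(ms$molecules$mass),
               sum(element_mass(inst$frame$atoms$element)),
               tolerance = 1e-12)
})

test_that("formulas and masses match standard atomic masses", {
  treh <- formula_and_mass("C12H22O11")
  expect_equal(round(treh$mass, 1), 342.3)
  expect_equal(formula_and_mass("H2O")$mass, 18.015, tolerance = 1e-9)
  expect_equal(formula_and_mass("C")$mass, 12.011, tolerance = 1e-9)
  expect_equal(formula_and_mass(c(O = 1, H = 2))$formula, "H2O")
  expect_equal(formula_and_mass(c("H", "H", "O"))$formula, "H2O")
  expect_error(formula_and_mass("Xx3"), "unknown element")
})

test_that("species classification is template-driven and exhaustive", {
  expect_equal(classify_species("C12H22O11"), "intact_trehalose")
  expect_equal(classify_species("H2O"), "water")
  expect_equal(classify_species("C6H11O5"), "fragment")
  tpl <- species_templates(intact = "C6H12O6")
  expect_equal(classify_species("C6H12O6", tpl), "intact_trehalose")
  expect_equal(classify_species("C12H22O11", tpl), "fragment")
})

test_that("stable ids persist through unchanged partitions", {
  inst <- random_bond_instance(3, n_atoms = 50)
  ms <- identify_molecules(inst$frame, inst$bonds)
  ms2 <- ms; ms2$time <- 1
  tr <- track_molecule_identity(list(ms, ms2))
  expect_equal(tr$sets[[1]]$molecules$stable_id,
               tr$sets[[2]]$molecules$stable_id)
  expect_equal(nrow(tr$events), 0)
})

test_that("a split molecule gets two new ids and a logged scission", {
  frame <- md_frame(0, water_frame_atoms(1L, c(0, 0, 0)))
  full <- bond_table(0, data.frame(i = c(1, 1), j = c(2, 3), bo = 0.9))
  cut <- bond_table(1, data.frame(i = c(1, 1), j = c(2, 3), bo = c(0.9, 0.0)))
  ms1 <- identify_molecules(frame, full)
  frame2 <- frame; frame2$time <- 1
  ms2 <- identify_molecules(frame2, cut)
  tr <- track_molecule_identity(list(ms1, ms2))
  expect_equal(tr$events$type, "scission")
  expect_equal(tr$events$time, 1)
  old_id <- tr$sets[[1]]$molecules$stable_id
  expect_false(any(tr$sets[[2]]$molecules$stable_id %in% old_id))
})

test_that("a scripted fragmentation is reported at the first frame after it", {
  sc <- build_scene(small_scene_spec(
    list(eject_event("fragmenting", frag_time = 30)), extended = FALSE))
  an <- analyze_trajectory(sc$trajectory, sc$bond_tables)
  expect_equal(nrow(an$reaction_events), 1)
  expect_equal(an$reaction_events$type, "scission")
  tt <- frame_times(sc$trajectory)
  expect_equal(an$reaction_events$time, min(tt[tt >= 30]))
})

test_that("a quiescent scene yields zero reaction events", {
  sc <- build_scene(small_scene_spec(list(eject_event("single_bare")),
                                     extended = FALSE))
  an <- analyze_trajectory(sc$trajectory, sc$bond_tables)
  expect_equal(nrow(an$reaction_events), 0)
})
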