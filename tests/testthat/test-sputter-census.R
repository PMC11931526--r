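flat_frame <- function(zs) {
  md_frame(0, data.frame(id = seq_along(zs), element = "C",
                         x = 0, y = 0, z = zs, vx = 0, vy = 0, vz = 0))
}

test_that("surface reference takes the top of the sample", {
  f <- flat_frame(c(10, 20, 30))
  expect_equal(surface_reference(f, 1:3), 30)
  # hemisphere-like profile: apex wins
  f2 <- flat_frame(c(30, 29, 25, 15, 5))
  expect_equal(surface_reference(f2, 1:5), 30)
  expect_equal(surface_reference(f2, 1:5, method = "top_decile_mean"), 30)
  expect_error(surface_reference(f, integer(0)), "empty")
})

fake_cluster_set <- function(com_z, vz) {
  structure(list(
    time = 75,
    assignment = data.frame(molecule_id = seq_along(com_z),
                            cluster_id = seq_along(com_z)),
    clusters = data.frame(cluster_id = seq_along(com_z), n_molecules = 1,
                          n_intact = 1, n_water = 0, n_fragment = 0,
                          mass = 342.297, com_x = 0, com_y = 0,
                          com_z = com_z, vcom_x = 0, vcom_y = 0,
                          vcom_z = vz)), class = "cluster_set")
}

test_that("the sputter rule needs both height and upward motion", {
  cs <- fake_cluster_set(com_z = c(16, 16, 14), vz = c(0.5, -0.5, 0.5))
  rec <- is_sputtered(cs, z0 = 0, height_min = 15)
  expect_equal(rec$sputtered, c(TRUE, FALSE, FALSE))
  expect_equal(rec$height, c(16, 16, 14))
})

test_that("lowering the height threshold can only add sputtered clusters", {
  set.seed(5)
  cs <- fake_cluster_set(com_z = runif(40, 0, 30), vz = rnorm(40, 0, 0.4))
  s15 <- is_sputtered(cs, 0, height_min = 15)$sputtered
  s10 <- is_sputtered(cs, 0, height_min = 10)$sputtered
  s5 <- is_sputtered(cs, 0, height_min = 5)$sputtered
  expect_true(all(s15 <= s10))
  expect_true(all(s10 <= s5))
})

test_that("cluster categorisation follows the five-way taxonomy", {
  m_t <- 342.297; m_w <- 18.015
  one <- categorize_cluster("intact_trehalose", m_t)
  expect_equal(one$category, "single_bare")
  expect_equal(unname(one$masses["single_bare"]), m_t)

  solv <- categorize_cluster(c("intact_trehalose", rep("water", 3)),
                             c(m_t, rep(m_w, 3)))
  expect_equal(solv$category, "single_solvated")
  expect_equal(unname(solv$masses["single_solvated"]), m_t + 3 * m_w)

  multi <- categorize_cluster(rep("intact_trehalose", 2), rep(m_t, 2))
  expect_equal(multi$category, "multiple_bare")

  # mixed fragment cluster: fragment mass pooled, residual re-categorised
  mix <- categorize_cluster(c("fragment", "water"), c(163.149, m_w))
  expect_equal(unname(mix$masses["fragments"]), 163.149)
  expect_equal(unname(mix$masses["pure_water"]), m_w)
  expect_equal(sum(mix$masses[c("single_bare", "multiple_bare",
                                "single_solvated", "multiple_solvated")]), 0)

  # solvated mass convention switch: waters tallied separately
  alt <- categorize_cluster(c("intact_trehalose", "water"), c(m_t, m_w),
                            solvated_mass_includes_water = FALSE)
  expect_equal(unname(alt$masses["single_solvated"]), m_t)
  expect_equal(unname(alt$masses["pure_water"]), m_w)

  expect_error(categorize_cluster(character(0), numeric(0)), "empty")
})

test_that("yields are reported in reference-mass units with a conserved total", {
  y <- compute_yields(list(c(single_bare = 684.6)), reference_mass = 342.3)
  expect_equal(y$mean[y$category == "single_bare"], 2.0)
  expect_equal(y$mean[y$category == "total"], 2.0)

  yw <- compute_yields(list(c(pure_water = 18.015)))
  expect_equal(yw$mean[yw$category == "pure_water"], 18.015 / 342.3)
  expect_equal(yw$mean[yw$category == "total"], 0)  # water excluded

  set.seed(2)
  impacts <- lapply(1:5, function(k) {
    v <- runif(5, 0, 800)
    names(v) <- c("single_bare", "multiple_bare", "single_solvated",
                  "multiple_solvated", "fragments")
    v
  })
  y2 <- compute_yields(impacts)
  cats <- y2$mean[match(c("single_bare", "multiple_bare", "single_solvated",
                          "multiple_solvated", "fragments"), y2$category)]
  expect_equal(sum(cats), y2$mean[y2$category == "total"], tolerance = 1e-9)
  expect_true(all(y2$mean >= 0))
  expect_error(compute_yields(list()), "at least one impact")
})

test_that("mass spectra bin sputtered molecule masses per impact", {
  sp <- mass_spectrum(rep(18.015, 3))
  expect_equal(nrow(sp), 1)
  expect_equal(sp$count_per_impact, 3)
  expect_equal(sp$mass, 18.5)

  sp2 <- mass_spectrum(c(342.297, 18.015), n_impacts = 2)
  expect_equal(sp2$mass, c(18.5, 342.5))
  expect_equal(sp2$count_per_impact, c(0.5, 0.5))
  expect_equal(sum(mass_spectrum(runif(25, 1, 400))$count_per_impact), 25)
})

test_that("per-molecule kinetic energy converts exactly to eV", {
  atoms <- water_frame_atoms(1L, c(0, 0, 0), vz = 1)
  f <- md_frame(0, atoms)
  b <- bond_table(0, data.frame(i = c(1, 1), j = c(2, 3), bo = 0.9))
  ms <- identify_molecules(f, b)
  ke <- per_molecule_kinetic_energy(f, ms)
  expect_equal(ke$ke_ev, 0.5 * 18.015 * 0.0103642688, tolerance = 1e-12)
  expect_equal(round(ke$ke_ev, 4), 0.0934, tolerance = 2e-4)

  atoms0 <- water_frame_atoms(1L, c(0, 0, 0), vz = 0)
  ke0 <- per_molecule_kinetic_energy(md_frame(0, atoms0), ms)
  expect_equal(ke0$ke_ev, 0)
})

test_that("a projectile at 20 keV total shares energy equally per molecule", {
  n <- 10
  v <- sqrt(2 * (20000 / n) / 0.0103642688 / 18.015)
  atoms <- do.call(rbind, lapply(seq_len(n), function(k) {
    a <- water_frame_atoms(3L * (k - 1L) + 1L, c(k, 0, 0))
    a$vz <- -v
    a
  }))
  f <- md_frame(0, atoms)
  b <- bond_table(0, do.call(rbind, lapply(seq_len(n), function(k) {
    data.frame(i = 3 * (k - 1) + 1, j = 3 * (k - 1) + 2:3, bo = 0.9)
  })))
  ke <- per_molecule_kinetic_energy(f, identify_molecules(f, b))
  expect_equal(mean(ke$ke_ev), 20000 / n, tolerance = 1e-9)
  expect_equal(sum(ke$ke_ev), 20000, tolerance = 1e-6)
})
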