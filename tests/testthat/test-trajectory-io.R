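test_that("trajectory write/read round trip is the identity", {
  set.seed(42)
  frames <- lapply(c(0, 1.5, 3), function(t) {
    md_frame(t, data.frame(
      id = c(7L, 2L, 11L), element = c("O", "H", "C"),
      x = runif(3, -5, 5), y = runif(3, -5, 5), z = runif(3, -5, 5),
      vx = rnorm(3), vy = rnorm(3), vz = rnorm(3)))
  })
  traj <- md_trajectory(frames)
  path <- withr::local_tempfile()
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(back, traj, tolerance = 0)
})

test_that("unit conversion nm -> angstrom -> nm is self-inverse", {
  f <- md_frame(0, data.frame(id = 1:2, element = c("O", "C"),
                              x = c(1.234567, -2), y = c(0, 3), z = c(5, -7),
                              vx = c(0.1, 0.2), vy = 0, vz = c(-1, 1)))
  traj <- md_trajectory(list(f))
  ang <- traj
  for (col in c("x", "y", "z", "vx", "vy", "vz")) {
    ang$frames[[1]]$atoms[[col]] <- ang$frames[[1]]$atoms[[col]] * 10
  }
  path <- withr::local_tempfile()
  write_trajectory(ang, path)
  back <- read_trajectory(path, units = "angstrom")
  expect_equal(back$frames[[1]]$atoms, traj$frames[[1]]$atoms,
               tolerance = 1e-12)
})

test_that("malformed dumps are rejected with line information", {
  path <- withr::local_tempfile()
  writeLines(c("ITEM: TIMESTEP", "0", "ITEM: NUMBER OF ATOMS", "2",
               "ITEM: ATOMS id element x y z vx vy vz",
               "1 O 0 0 0 0 0 0",
               "1 O 1 0 0 0 0 0"), path)
  expect_error(read_trajectory(path), "duplicate atom id")

  writeLines(c("ITEM: TIMESTEP", "0", "ITEM: NUMBER OF ATOMS", "1",
               "ITEM: ATOMS id element x y z",
               "1 O 0 0 0"), path)
  expect_error(read_trajectory(path), "vx")

  writeLines(c("garbage header", "0"), path)
  expect_error(read_trajectory(path), "line 1")
})

test_that("frames reject duplicate ids and incongruent arrays", {
  expect_error(md_frame(0, data.frame(id = c(1, 1), element = c("O", "O"),
                                      x = 0, y = 0, z = 0,
                                      vx = 0, vy = 0, vz = 0)),
               "duplicate atom id")
  expect_error(md_frame(0, data.frame(id = 1, element = "O", x = 0, y = 0)),
               "lacks column")
})

test_that("bond tables round trip, reject bad records, allow empty frames", {
  tabs <- list(bond_table(0, data.frame(i = c(3, 1), j = c(1, 2),
                                        bo = c(0.9, 0.25))),
               bond_table(10, NULL))
  path <- withr::local_tempfile()
  write_bond_tables(tabs, path)
  back <- read_bond_tables(path)
  expect_equal(back, tabs, tolerance = 0)
  expect_equal(nrow(back[[2]]$bonds), 0)

  expect_error(bond_table(0, data.frame(i = 1, j = 2, bo = -0.1)),
               "negative bond order")
  expect_error(bond_table(0, data.frame(i = 1, j = 1, bo = 0.5)),
               "self-bond")
  expect_error(bond_table(0, data.frame(i = c(1, 2), j = c(2, 1),
                                        bo = c(0.5, 0.6))),
               "duplicate bond")
})

test_that("the reaxff neighbour-list dialect matches the simple dialect", {
  path <- withr::local_tempfile()
  writeLines(c("# Timestep 5",
               "1 2 2 3 0.9 0.4",
               "2 1 1 0.9",
               "3 1 1 0.4",
               "# Timestep 15",
               "1 0"), path)
  rx <- read_bond_tables(path, dialect = "reaxff")
  expect_equal(rx[[1]]$bonds,
               data.frame(i = c(1L, 1L), j = c(2L, 3L), bo = c(0.9, 0.4)))
  expect_equal(rx[[2]]$time, 15)
  expect_equal(nrow(rx[[2]]$bonds), 0)
})

test_that("bond tables attach to frames by nearest time with reported gap", {
  frames <- lapply(0:10, function(t) {
    md_frame(t, data.frame(id = 1, element = "O", x = 0, y = 0, z = 0,
                           vx = 0, vy = 0, vz = 0))
  })
  traj <- md_trajectory(frames)
  tabs <- list(bond_table(0, NULL), bond_table(10, NULL))
  expect_warning(m4 <- match_bonds_to_frame(traj, tabs, 4),
                 "exceeds frame interval")
  expect_equal(m4$bonds$time, 0)
  expect_equal(m4$gap, 4)
  m0 <- match_bonds_to_frame(traj, tabs, 10)
  expect_equal(m0$gap, 0)
  expect_error(match_bonds_to_frame(traj, list(), 4), "no bond tables")
})

test_that("a written scene reads back matching its manifest", {
  sc <- build_scene(small_scene_spec(list(eject_event("single_bare")),
                                     extended = FALSE))
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  traj <- read_trajectory(file.path(dir, "trajectory.dump"))
  expect_equal(frame_times(traj), sc$manifest$frame_times)
  expect_equal(nrow(traj$frames[[1]]$atoms), sc$manifest$n_atoms)
  bt <- read_bond_tables(file.path(dir, "bonds.txt"))
  expect_equal(length(bt), length(sc$manifest$frame_times))
})
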