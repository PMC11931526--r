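# traces built directly for filter-rule tests
fake_trace <- function(duration, final_waters, single = TRUE) {
  structure(list(trehalose_stable_id = 1L, ejection_time = 60,
                 intervals = list(), stable_duration = duration,
                 final_water_count = final_waters,
                 single_throughout = single,
                 end_water_free = final_waters == 0),
            class = "complex_trace")
}

test_that("stability and residual-water filters follow the inclusion rule", {
  traces <- list(fake_trace(200, 0),    # dissolved too early
                 fake_trace(841, 1),    # one water kept to the end
                 fake_trace(841, 3),    # too many waters at the end
                 fake_trace(500, 0))    # stable then fully shed: included
  out <- apply_stability_filter(traces, min_stable = 320, max_final_waters = 1)
  expect_equal(vapply(out, function(t) t$included, logical(1)),
               c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(attr(out, "included_count"), 2)
  expect_true(out[[4]]$end_water_free)
})

test_that("cutoff sweeps are monotone and unfiltered at the origin", {
  set.seed(11)
  traces <- lapply(1:20, function(k) {
    fake_trace(runif(1, 0, 850), sample(0:3, 1))
  })
  sw <- sweep_cutoffs(traces, min_stable_grid = c(0, 160, 320, 480, 640),
                      max_final_grid = c(0, 1, 2, Inf))
  expect_equal(sw$included[sw$min_stable == 0 & sw$max_final_waters == Inf],
               20)
  for (mf in unique(sw$max_final_waters)) {
    col <- sw$included[sw$max_final_waters == mf][order(
      sw$min_stable[sw$max_final_waters == mf])]
    expect_true(all(diff(col) <= 0))
  }
  for (ms in unique(sw$min_stable)) {
    row <- sw$included[sw$min_stable == ms][order(
      sw$max_final_waters[sw$min_stable == ms])]
    expect_true(all(diff(row) >= 0))
  }
  expect_error(sweep_cutoffs(traces, numeric(0), 1), "non-empty")
})

test_that("scripted water detachment is recovered within one frame", {
  sp <- scene_spec(events = list(
    eject_event("single_solvated", n_water = 2, vz = 0.35, t_eject = 15,
                detach_times = c(400, Inf))),
    n_background = 2, projectile_waters = 8,
    cadence_impact = 5, cadence_extended = 15, seed = 4)
  sc <- build_scene(sp)
  an <- analyze_trajectory(sc$trajectory, sc$bond_tables)
  traces <- build_complex_traces(an, sc$sample_atom_ids)
  expect_length(traces, 1)
  tr <- traces[[1]]
  man <- sc$manifest$complexes
  expect_equal(tr$ejection_time, man$ejection_time)
  expect_equal(tr$stable_duration, man$stable_duration,
               tolerance = 15 / man$stable_duration)
  expect_equal(tr$final_water_count, man$final_water_count)
  # the detaching water's interval ends within one extended frame of 400 ps
  ends <- vapply(tr$intervals, function(iv) max(iv[, "t_end"]), numeric(1))
  expect_true(any(abs(ends - 400) <= 15))
  expect_true(tr$single_throughout)
})

test_that("multi-trehalose clusters never form a complex trace", {
  sc <- build_scene(small_scene_spec(
    list(eject_event("multiple_solvated", n_water = 2))))
  an <- analyze_trajectory(sc$trajectory, sc$bond_tables)
  expect_length(build_complex_traces(an, sc$sample_atom_ids), 0)
})

test_that("the contact map keeps long contacts and drops short ones", {
  sp <- scene_spec(events = list(
    eject_event("single_solvated", n_water = 2, vz = 0.35, t_eject = 10,
                detach_times = c(120, 700))),
    n_background = 2, projectile_waters = 8,
    cadence_impact = 5, cadence_extended = 15, seed = 9)
  sc <- build_scene(sp)
  an <- analyze_trajectory(sc$trajectory, sc$bond_tables)
  traces <- build_complex_traces(an, sc$sample_atom_ids)
  cm <- contact_time_map(traces, sc$trajectory$frames[[1]],
                         an$molecule_sets[[1]], min_display = 40)
  man <- sc$manifest$contact_map
  keep <- man[man$duration >= 40, ]
  expect_equal(nrow(cm), nrow(keep))
  expect_equal(sort(cm$duration), sort(keep$duration))
  expect_equal(sort(cm$z0), sort(keep$z0), tolerance = 1e-9)
  expect_true(all(cm$origin == "projectile"))
  # a 30 ps contact would be omitted
  cm120 <- contact_time_map(traces, sc$trajectory$frames[[1]],
                            an$molecule_sets[[1]], min_display = 200)
  expect_true(all(cm120$duration >= 200))
})
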