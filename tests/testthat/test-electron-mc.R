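const_tables <- function(rate_ion, rate_el = 0, I = 20) {
  cross_section_table(energy = c(0.001, 200),
                      elastic = rep(rate_el, 2), excitation = c(0, 0),
                      ionization = rep(rate_ion, 2),
                      excitation_loss = 1, ionization_threshold = I,
                      secondary_rule = "fixed", secondary_energy = 0,
                      elastic_angle = "isotropic", ionization_angle = "forward")
}

test_that("free paths are exponential and processes compete by rate", {
  tab <- const_tables(rate_ion = 0.5)
  set.seed(1)
  paths <- replicate(4000, sample_step(50, tab)$path)
  ks <- suppressWarnings(stats::ks.test(paths, "pexp", 0.5))
  expect_gt(ks$p.value, 1e-3)
  expect_equal(mean(paths), 2, tolerance = 0.1)

  tab2 <- const_tables(rate_ion = 0.2, rate_el = 0.4)
  set.seed(2)
  proc <- replicate(3000, sample_step(50, tab2)$process)
  p_el <- mean(proc == "elastic")
  expect_equal(p_el, 2 / 3, tolerance = 3 * sqrt(2 / 9 / 3000) / (2 / 3))

  none <- sample_step(50, const_tables(rate_ion = 0))
  expect_equal(none$path, Inf)
  expect_equal(none$process, "none")
})

test_that("transport produces no ionizations when energetically forbidden", {
  inert <- make_toy_cross_sections(2, 20, variant = "inert")
  set.seed(3)
  ev <- transport_electron(7, inert, E0 = 100)
  expect_equal(ev$n_ionizations, 0)
  expect_equal(ev$n_solvated_inside, 0)
  expect_equal(ev$energy$residual, 0)

  below <- const_tables(rate_ion = 1, I = 150)  # threshold above E0
  set.seed(4)
  ev2 <- transport_electron(7, below, E0 = 100)
  expect_equal(ev2$n_ionizations, 0)
})

test_that("ionization counts follow the truncated Poisson closed form", {
  d <- 7
  tab <- make_toy_cross_sections(mean_free_path = d / 2, ionization_loss = 20)
  oc <- attr(tab, "oracle")
  expect_equal(oc$cap, 5L)
  set.seed(10)
  ev <- run_campaign(d, tab, n_events = 10000, selection_net_charge = NULL,
                     entry = "axis")
  lam <- d * oc$rate_per_nm
  pk <- trunc_pois_pmf(lam, oc$cap)
  emp <- vapply(0:oc$cap, function(k) mean(ev$n_ionizations == k), numeric(1))
  expect_lt(0.5 * sum(abs(emp - pk)), 0.03)
  expect_lt(ev$energy_max_error, 1e-9)
})

test_that("the solvation-threshold cap is honoured by the oracle metadata", {
  # losing 20 eV per ionization from 100 eV: the fifth ionization leaves the
  # electron below the 11 eV solvation threshold, so the cap is 5
  expect_equal(attr(make_toy_cross_sections(1, 20), "oracle")$cap, 5L)
  # losing 5 eV: solvation (not the threshold) terminates the ladder
  expect_equal(attr(make_toy_cross_sections(1, 5), "oracle")$cap, 18L)
})

test_that("energy bookkeeping closes for cascading realistic tables", {
  tab <- make_water_cross_sections()
  set.seed(6)
  worst <- 0
  for (k in 1:200) {
    ev <- transport_electron(7, tab, E0 = 100)
    worst <- max(worst, abs(ev$energy$residual))
  }
  expect_lt(worst, 1e-9)
})

test_that("campaigns are bit-identical under a fixed seed", {
  tab <- make_toy_cross_sections(2, 20)
  set.seed(123)
  a <- run_campaign(7, tab, n_events = 200, selection_net_charge = NULL)
  set.seed(123)
  b <- run_campaign(7, tab, n_events = 200, selection_net_charge = NULL)
  expect_identical(a, b)
})

test_that("net-charge selection keeps single-ionization escape events", {
  ## ionization possible only above 90 eV; both the 50 eV secondary and the
  ## 20 eV primary then leave the sphere untouched, so every +1 event has
  ## exactly one ionization and no solvated electron
  tab <- cross_section_table(energy = c(0.001, 89, 90, 200),
                             elastic = rep(0, 4), excitation = rep(0, 4),
                             ionization = c(0, 0, 0.5, 0.5),
                             excitation_loss = 1, ionization_threshold = 30,
                             secondary_rule = "fixed", secondary_energy = 50,
                             ionization_angle = "forward")
  set.seed(7)
  ev <- run_campaign(6, tab, n_events = 300, selection_net_charge = 1)
  expect_true(all(ev$n_ionizations == 1))
  expect_true(all(ev$n_solvated == 0))
  hd <- hydronium_count_distribution(ev)
  expect_equal(hd$k, 1L)
  expect_equal(hd$p, 1)
  # acceptance fraction consistent with direct estimate of P(net = +1)
  set.seed(7)
  direct <- mean(replicate(2000, transport_electron(6, tab)$net_charge == 1))
  expect_equal(ev$acceptance, direct,
               tolerance = 5 * sqrt(direct * (1 - direct) / 2000) / direct)
})

test_that("hydronium count probabilities sum to one", {
  tab <- make_water_cross_sections()
  set.seed(8)
  ev <- run_campaign(5, tab, n_events = 300, selection_net_charge = 1)
  hd <- hydronium_count_distribution(ev)
  expect_equal(sum(hd$p), 1)
  expect_true(all(hd$k >= 1))
})

test_that("depth maps are normalised and deepen with longer mean free paths", {
  fake_events <- structure(list(
    diameter = 4, n_events = 1,
    positions = cbind(event = 1, x = 0, y = 0, z = 0)),
    class = "ionization_events")
  h <- ionization_depth_map(fake_events)
  expect_equal(sum(h), 1)
  expect_equal(sum(h > 0), 1)

  short <- make_toy_cross_sections(0.8, 20, variant = "elastic_ionization")
  long <- make_toy_cross_sections(2.5, 20, variant = "elastic_ionization")
  set.seed(9)
  ev_s <- run_campaign(7, short, n_events = 800, selection_net_charge = NULL,
                       entry = "axis")
  ev_l <- run_campaign(7, long, n_events = 800, selection_net_charge = NULL,
                       entry = "axis")
  depth_s <- mean(3.5 - ev_s$positions[, "z"])
  depth_l <- mean(3.5 - ev_l$positions[, "z"])
  expect_lt(depth_s, 3.5)
  expect_lt(depth_s, depth_l)
  expect_equal(sum(ionization_depth_map(ev_s)), 1)
})
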