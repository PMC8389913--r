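test_that("peak detection finds a single synthetic mode near its true centre", {
  spec <- traj_spec(n_lipids = 20, duration = 50, tau_unbound = 0,
                    modes = list(mode_spec("eth", 0.29, 0.008, 5, 1)), seed = 1)
  s <- generate_distance_series(spec)
  prof <- closest_atom_profile(s, normalization = "per_frame")
  modes <- detect_peak_bounds(prof)
  expect_equal(nrow(modes), 1)
  expect_gte(modes$center, 0.27)
  expect_lte(modes$center, 0.31)
  expect_lt(modes$r1, 0.29)
  expect_gt(modes$r2, 0.29)
})

test_that("a flat profile yields no modes, not an error", {
  s <- manual_series(matrix(rep(seq(0.005, 1.995, by = 0.01), 4), ncol = 4))
  prof <- closest_atom_profile(s, normalization = "per_frame")
  expect_equal(nrow(detect_peak_bounds(prof, smoothing = 21,
                                       min_prominence = 0.5)), 0)
  zero <- manual_series(matrix(0.5, 10, 1))
  pz <- closest_atom_profile(zero, normalization = "per_frame")
  expect_equal(nrow(detect_peak_bounds(pz)), 1)  # single spike is a peak
})

test_that("the default three-mode palette is resolved with ordered centres", {
  s <- generate_distance_series(traj_spec(n_lipids = 60, duration = 400, seed = 17))
  prof <- closest_atom_profile(s, normalization = "per_frame")
  modes <- detect_peak_bounds(prof)
  expect_equal(nrow(modes), 3)
  expect_true(all(diff(modes$center) > 0))
  expect_lt(abs(modes$center[1] - 0.235), 0.015)
  expect_lt(abs(modes$center[2] - 0.29), 0.015)
  expect_lt(abs(modes$center[3] - 0.435), 0.015)
})

test_that("binding probability is a normalized peak integral", {
  set.seed(3)
  s <- manual_series(matrix(runif(20000, 0, 1), 1000, 20))
  prof <- closest_atom_profile(s, normalization = "per_frame", r_max = 1)
  # full range integrates to 1
  expect_equal(binding_probability(prof, list(r1 = 0, r2 = 1)), 1)
  # half range of a uniform profile gives ~1/2
  expect_lt(abs(binding_probability(prof, list(r1 = 0, r2 = 0.5)) - 0.5), 0.02)
  # additivity over adjacent disjoint ranges
  pa <- binding_probability(prof, list(r1 = 0.1, r2 = 0.3))
  pb <- binding_probability(prof, list(r1 = 0.3, r2 = 0.6))
  pab <- binding_probability(prof, list(r1 = 0.1, r2 = 0.6))
  expect_equal(pa + pb, pab, tolerance = 1e-12)
  expect_error(binding_probability(prof, list(r1 = 0.5, r2 = 0.2)), "r1")
  expect_error(binding_probability(prof, list(r1 = 0, r2 = 2)), "r_max")
})

test_that("residence events are maximal in-range runs with censoring flags", {
  d <- matrix(2, 100, 1)
  d[10:19, 1] <- 0.3                      # one 10-frame event
  s <- manual_series(d, frame_interval_ps = 5)
  st <- residence_times(s, list(r1 = 0.25, r2 = 0.35))
  expect_equal(st$n_events, 1L)
  expect_equal(st$mean_residence, 10 * 5 / 1000)   # 0.05 ns
  expect_equal(st$censored_events, 0L)
  # an always-bound lipid yields one censored event of full duration
  s2 <- manual_series(matrix(0.3, 200, 1), frame_interval_ps = 5)
  st2 <- residence_times(s2, list(r1 = 0.25, r2 = 0.35))
  expect_equal(st2$n_events, 1L)
  expect_equal(st2$censored_events, 1L)
  expect_equal(st2$mean_residence, 1)     # 200 frames x 5 ps
  expect_true(st2$lower_bound)
  # out-of-range mode: zero events
  st3 <- residence_times(s2, list(r1 = 1, r2 = 2))
  expect_equal(st3$n_events, 0L)
})

test_that("gap tolerance forgives short excursions", {
  d <- matrix(2, 60, 1)
  d[c(10:19, 21:30), 1] <- 0.3            # 1-frame excursion at frame 20
  s <- manual_series(d)
  expect_equal(residence_times(s, list(r1 = 0.25, r2 = 0.35))$n_events, 2L)
  merged <- residence_times(s, list(r1 = 0.25, r2 = 0.35),
                            gap_tolerance_frames = 1)
  expect_equal(merged$n_events, 1L)
  expect_equal(merged$mean_residence, 21 * 5 / 1000)  # gap frames included
})

test_that("occurrence-weighted and binned-histogram means are both reported", {
  d <- matrix(2, 1000, 2)
  d[1:400, 1] <- 0.3     # censored 2 ns event
  d[500:579, 1] <- 0.3   # 0.4 ns event
  d[300:379, 2] <- 0.3   # 0.4 ns event
  s <- manual_series(d)
  st <- residence_times(s, list(r1 = 0.25, r2 = 0.35), hist_bin_ns = 0.5)
  expect_equal(st$n_events, 3L)
  expect_equal(st$censored_events, 1L)
  expect_equal(st$mean_residence, mean(c(2, 0.4, 0.4)))
  expect_equal(sum(st$residence_histogram$occurrence), 3)
  expect_lt(abs(st$mean_residence_binned - st$mean_residence), 0.25)
})

test_that("adsorbed fraction is monotone in layer width with exact end points", {
  s <- generate_distance_series(traj_spec(n_lipids = 20, duration = 50, seed = 9))
  prof <- closest_atom_profile(s, normalization = "per_frame")
  expect_equal(adsorbed_fraction(prof, 0)$adsorbed_fraction, 0)
  expect_equal(adsorbed_fraction(prof, max(s$dist) + 0.1)$adsorbed_fraction, 100)
  widths <- seq(0.2, 4, by = 0.2)
  fr <- vapply(widths, function(w) adsorbed_fraction(prof, w)$adsorbed_fraction,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
  # 1 nm layer captures exactly the bound population (unbound mass >= 1 nm)
  truth <- 100 * label_truth(s)$bound_fraction
  expect_lt(abs(adsorbed_fraction(prof, 1)$adsorbed_fraction - truth), 2)
})

test_that("the fitted estimator recovers generator parameters on one long run", {
  s <- generate_distance_series(traj_spec(n_lipids = 80, duration = 500, seed = 31))
  fit <- binding_analysis(s)
  tr <- label_truth(s)
  expect_equal(nrow(fit$modes), 3)
  for (k in 1:3) {
    expect_lt(abs(fit$p_b[[k]] - tr$occupancy[[k + 1]]), 0.02)
  }
  # taus recoverable below the censoring scale (8 and 6 ns here)
  expect_lt(abs(fit$residence[[2]]$mean_residence - 8) / 8, 0.10)
  expect_lt(abs(fit$residence[[3]]$mean_residence - 6) / 6, 0.10)
  # structural identity: mode probabilities never exceed the all-mode layer
  expect_lte(sum(fit$p_b),
             adsorbed_fraction(fit$profile, max(fit$modes$r2))$adsorbed_fraction / 100 + 1e-9)
  # coef/summary/table surfaces
  expect_named(coef(fit))
  tab <- binding_mode_table(fit, "anatase(101)")
  expect_identical(names(tab), c("binding mode", "TiO2 nanosurface",
                                 "P_b (%)", "residence time (ns)"))
  ads <- adsorption_table(fit, "anatase(101)")
  expect_identical(names(ads), c("TiO2 surface", "N_lipids",
                                 "fraction of adsorbed lipids (%)",
                                 "adsorption layer width (nm)"))
})

test_that("simulate() round-trips a fit back through the generator", {
  s <- generate_distance_series(traj_spec(n_lipids = 30, duration = 200, seed = 12))
  fit <- binding_analysis(s)
  sims <- simulate(fit, nsim = 2, seed = 5, n_lipids = 10, duration = 50)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "distance_series")
  refit <- binding_analysis(sims[[1]])
  expect_gte(nrow(refit$modes), 2)
})
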