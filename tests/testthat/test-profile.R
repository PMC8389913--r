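test_that("nearest-surface distances handle direct and minimum-image cases", {
  box <- c(20, 20, 60)
  st <- toy_structure(surface_xyz = matrix(c(0, 0, 0), 1),
                      probe_xyz = matrix(c(0, 0, 3), 1), box = box)
  fr <- list(as.matrix(st$atoms[, c("x", "y", "z")]))
  ds <- nearest_surface_distances(fr, st)
  expect_equal(ds$dist[1, 1], 0.3)   # 3 A = 0.3 nm
  # probe at L - 1 A with surface atom at 0: minimum image gives 1 A
  st2 <- toy_structure(matrix(c(0, 0, 0), 1), matrix(c(19, 0, 0), 1), box)
  fr2 <- list(as.matrix(st2$atoms[, c("x", "y", "z")]))
  expect_equal(nearest_surface_distances(fr2, st2)$dist[1, 1], 0.1)
})

test_that("distances match the explicit-image oracle on a 50-atom toy system, every frame", {
  set.seed(99)
  box <- c(15, 12, 30)
  surf <- cbind(runif(40, 0, box[1]), runif(40, 0, box[2]), runif(40, 0, 6))
  probes <- cbind(runif(10, 0, box[1]), runif(10, 0, box[2]), runif(10, 6, 28))
  st <- toy_structure(surf, probes, box)
  frames <- lapply(1:5, function(i) {
    m <- as.matrix(st$atoms[, c("x", "y", "z")])
    m + matrix(runif(length(m), -0.5, 0.5), nrow(m))
  })
  ds <- nearest_surface_distances(frames, st)
  for (i in 1:5) {
    expected <- brute_nearest(frames[[i]][41:50, , drop = FALSE],
                              frames[[i]][1:40, , drop = FALSE],
                              box, c(TRUE, TRUE, TRUE)) / 10
    expect_equal(unname(ds$dist[i, ]), expected, tolerance = 1e-12)
  }
})

test_that("hydroxyl atoms are excluded from the surface group", {
  box <- c(20, 20, 60)
  st <- toy_structure(matrix(c(0, 0, 0), 1), matrix(c(0, 0, 5), 1), box)
  # insert a hydroxyl oxygen right under the probe; it must not shorten the
  # measured distance
  oh <- data.frame(element = "O", name = "O", resname = "OHX", resid = 1L,
                   x = 0, y = 0, z = 3, hydroxyl = TRUE,
                   stringsAsFactors = FALSE)
  st$atoms <- rbind(st$atoms[1, ], oh, st$atoms[2, ])
  fr <- list(as.matrix(st$atoms[, c("x", "y", "z")]))
  expect_equal(nearest_surface_distances(fr, st)$dist[1, 1], 0.5)
})

test_that("frame/structure atom-count mismatches are rejected", {
  st <- toy_structure(matrix(c(0, 0, 0), 1), matrix(c(0, 0, 3), 1), c(10, 10, 10))
  expect_error(nearest_surface_distances(list(matrix(0, 5, 3)), st), "atoms")
})

test_that("profiles are exact histograms with the stated normalizations", {
  # all mass at one distance lands in a single bin
  s <- manual_series(matrix(0.30, 50, 4))
  p <- density_profile(s, normalization = "per_frame")
  expect_equal(sum(p$value > 0), 1)
  expect_equal(p$r[p$value > 0], 0.305)
  expect_equal(sum(p$value), 4)   # n_lipids observations per frame
  # volumetric mode rescales by face area x bin width
  pv <- density_profile(s, normalization = "volumetric",
                        geometry = list(type = "slab", face_area_nm2 = 25))
  expect_equal(pv$value, p$value / (25 * 0.01))
  expect_error(density_profile(manual_series(matrix(numeric(0), 0, 1))),
               "empty")
})

test_that("profile mass is conserved: counts equal lipid-frame observations", {
  s <- generate_distance_series(traj_spec(n_lipids = 7, duration = 10, seed = 2))
  p <- closest_atom_profile(s, normalization = "per_frame")
  expect_equal(sum(attr(p, "counts")),
               nrow(s$dist) * ncol(s$dist))
  # per-frame closest-mode values sum to one observation per lipid
  expect_equal(sum(p$value), ncol(s$dist))
})

test_that("uniform distances give a flat volumetric profile within 3 standard errors", {
  set.seed(7)
  nf <- 400; nl <- 20
  s <- manual_series(matrix(runif(nf * nl, 0, 2), nf, nl))
  p <- density_profile(s, bin_width = 0.1, normalization = "per_frame",
                       r_max = 2)
  counts <- attr(p, "counts")
  counts <- counts[seq_len(20)]        # bins covering [0, 2)
  expected <- nf * nl / 20
  se <- sqrt(nf * nl * (1 / 20) * (1 - 1 / 20))
  expect_true(all(abs(counts - expected) < 3.5 * se))
})

test_that("closest-atom reduction takes the per-lipid minimum", {
  # two tracked atoms of one lipid at fixed 0.3 and 0.5 nm
  d <- cbind(rep(0.3, 20), rep(0.5, 20))
  s <- titania:::distance_series(d, c(1L, 1L), c("P", "N"), 5)
  p <- closest_atom_profile(s, normalization = "per_frame")
  expect_equal(p$r[p$value > 0], 0.305)
  # single-atom lipids: closest profile equals the plain atom profile
  s1 <- manual_series(matrix(runif(100, 0, 1), 50, 2))
  expect_equal(closest_atom_profile(s1, normalization = "per_frame")$value,
               density_profile(s1, normalization = "per_frame")$value)
})

test_that("stride-100 and stride-1 profiles agree in expectation on stationary data", {
  s <- generate_distance_series(traj_spec(n_lipids = 30, duration = 250, seed = 4))
  p1 <- closest_atom_profile(s, normalization = "per_frame")
  p100 <- closest_atom_profile(s, normalization = "per_frame", stride = 100,
                               r_max = max(s$dist))
  # compare integrated adsorbed fractions rather than noisy single bins
  a1 <- adsorbed_fraction(p1)$adsorbed_fraction
  a100 <- adsorbed_fraction(p100)$adsorbed_fraction
  expect_lt(abs(a1 - a100), 3)
  expect_equal(attr(p100, "n_frames"), ceiling(nrow(s$dist) / 100))
})
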