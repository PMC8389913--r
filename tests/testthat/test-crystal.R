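test_that("conventional cells have the right stoichiometry and valid fractions", {
  ana <- build_unit_cell("anatase")
  rut <- build_unit_cell("rutile")
  expect_equal(sum(ana$basis$element == "Ti"), 4)
  expect_equal(sum(ana$basis$element == "O"), 8)
  expect_equal(sum(rut$basis$element == "Ti"), 2)
  expect_equal(sum(rut$basis$element == "O"), 4)
  for (cell in list(ana, rut)) {
    f <- as.matrix(cell$basis[, c("fx", "fy", "fz")])
    expect_true(all(f >= 0 & f < 1))
    expect_equal(sum(cell$basis$element == "O"),
                 2 * sum(cell$basis$element == "Ti"))
  }
  expect_error(build_unit_cell("brookite"), "phase")
})

test_that("every Ti in a periodic bulk supercell is 6-coordinated, matching the image-enumeration oracle", {
  for (phase in c("anatase", "rutile")) {
    bulk <- replicate_cell(build_unit_cell(phase), 2, 2, 2)
    for (cutoff in c(2.2, 2.6, 2.8)) {
      rep6 <- compute_coordination(bulk, cutoff)
      expect_true(all(rep6$neighbor_count == 6L))
      expect_length(rep6$ti5_indices, 0)
      expect_length(rep6$ti4_indices, 0)
    }
    expect_equal(unname(compute_coordination(bulk)$neighbor_count),
                 brute_ti_coordination(bulk))
  }
})

test_that("slab census equals the explicit-image brute-force oracle on a mini-slab", {
  slab <- build_slab("anatase", "101", 2, 2, 2)   # 96 Ti + O atoms < 500
  rep5 <- compute_coordination(slab)
  expect_equal(unname(rep5$neighbor_count), brute_ti_coordination(slab))
  # report invariants
  expect_true(all(rep5$neighbor_count[as.character(rep5$ti5_indices)] == 5L))
  expect_length(intersect(rep5$ti5_indices, rep5$ti4_indices), 0)
  expect_false(is.unsorted(rep5$ti5_indices))
})

test_that("slabs are stoichiometric with only 5-fold undercoordination on ideal faces", {
  for (cfg in list(c("anatase", "101"), c("anatase", "100"),
                   c("rutile", "110"), c("rutile", "101"))) {
    slab <- build_slab(cfg[1], cfg[2], 2, 2, 2)
    el <- slab$atoms$element
    expect_equal(sum(el == "O"), 2 * sum(el == "Ti"))
    rep5 <- compute_coordination(slab)
    expect_length(rep5$ti4_indices, 0)
    expect_gt(length(rep5$ti5_indices), 0)
    expect_gt(titania:::min_pair_dist(as.matrix(slab$atoms[, c("x", "y", "z")]),
                                      slab$box, slab$periodic), 1.0)
  }
})

test_that("Ti(5) count scales as per-cell count x n_u x n_v x 2 faces, independent of thickness", {
  per_cell <- list()
  for (cfg in list(c("anatase", "101"), c("rutile", "110"))) {
    n22 <- length(compute_coordination(build_slab(cfg[1], cfg[2], 2, 2, 2))$ti5_indices)
    n32 <- length(compute_coordination(build_slab(cfg[1], cfg[2], 3, 2, 2))$ti5_indices)
    n23 <- length(compute_coordination(build_slab(cfg[1], cfg[2], 2, 2, 3))$ti5_indices)
    expect_equal(n22 %% (2 * 2 * 2), 0)
    per_face_cell <- n22 / (2 * 2 * 2)
    expect_equal(n32, per_face_cell * 3 * 2 * 2)
    expect_equal(n23, n22)   # thickness-independent
  }
})

test_that("coordination census is invariant under rigid translation and atom relabeling", {
  slab <- build_slab("rutile", "101", 2, 2, 2)
  base <- compute_coordination(slab)
  shifted <- slab
  shifted$atoms$x <- shifted$atoms$x + 1.23
  shifted$atoms$y <- shifted$atoms$y - 4.56
  expect_equal(sort(unname(compute_coordination(shifted)$neighbor_count)),
               sort(unname(base$neighbor_count)))
  perm <- sample(nrow(slab$atoms))
  shuffled <- slab
  shuffled$atoms <- slab$atoms[perm, ]
  expect_equal(sort(unname(compute_coordination(shuffled)$neighbor_count)),
               sort(unname(base$neighbor_count)))
})

test_that("unsupported faces and too-thin slabs are rejected", {
  expect_error(build_slab("anatase", "110", 2, 2, 2), "unsupported")
  expect_error(build_slab("rutile", "100", 2, 2, 2), "unsupported")
  expect_error(build_slab("anatase", "101", 2, 2, 1), "n_layers")
})

test_that("carved nanoparticles satisfy their geometric and census invariants", {
  np <- carve_nanoparticle("anatase", 8)
  at <- np$atoms
  r <- sqrt((at$x - np$center[1])^2 + (at$y - np$center[2])^2 +
              (at$z - np$center[3])^2)
  expect_true(all(r <= np$radius + 0.5))
  expect_gt(sum(at$element == "Ti"), 0)
  cc <- np$census
  # census partitions all Ti
  n6 <- sum(cc$neighbor_count == 6)
  n5 <- length(cc$ti5_indices)
  n4 <- length(cc$ti4_indices)
  n_low <- sum(cc$neighbor_count <= 3)
  expect_equal(n6 + n5 + n4 + n_low, cc$n_ti)
  # approximate stoichiometry: |O - 2 Ti| bounded by the surface Ti count
  n_surface_ti <- sum(cc$neighbor_count < 6)
  expect_lte(abs(sum(at$element == "O") - 2 * sum(at$element == "Ti")),
             n_surface_ti)
  # no dangling oxygen survives the carve
  ox <- as.matrix(at[at$element == "O", c("x", "y", "z")])
  ti <- as.matrix(at[at$element == "Ti", c("x", "y", "z")])
  expect_true(all(brute_count_within(ox, ti, np$box, np$periodic, 2.6) >= 1))
  expect_error(carve_nanoparticle("anatase", 5), "radius")
})

test_that("nanoparticle census matches the brute-force oracle without periodicity", {
  np <- carve_nanoparticle("rutile", 8.5)
  expect_equal(unname(np$census$neighbor_count), brute_ti_coordination(np))
})
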