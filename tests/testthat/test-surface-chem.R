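test_that("the floor(30% Ti5) + all Ti4 rule reproduces all published hydroxyl counts", {
  census_rows <- list(list(504, 0, 151),   # anatase(101)
                      list(504, 0, 151),   # anatase(100)
                      list(528, 0, 158),   # rutile(110)
                      list(780, 0, 234),   # rutile(101)
                      list(162, 96, 144))  # anatase NP R = 20 A
  for (row in census_rows) {
    plan <- plan_hydroxylation(coordination_counts(row[[1]], row[[2]]),
                               fraction = 0.30, seed = 1)
    expect_equal(plan$n_oh, row[[3]])
  }
  expect_equal(plan_hydroxylation(coordination_counts(504, 0), fraction = 0)$n_oh, 0)
  expect_error(plan_hydroxylation(coordination_counts(10, 0), fraction = 1.2),
               "fraction")
})

test_that("site selection is seed-deterministic and seed changes never alter counts", {
  rep5 <- coordination_counts(100, 7)
  p1 <- plan_hydroxylation(rep5, seed = 42)
  p2 <- plan_hydroxylation(rep5, seed = 42)
  p3 <- plan_hydroxylation(rep5, seed = 43)
  expect_identical(p1$ti5_selected, p2$ti5_selected)
  expect_false(identical(p1$ti5_selected, p3$ti5_selected))
  expect_equal(p1$n_oh, p3$n_oh)
  expect_identical(p1$ti4_selected, p3$ti4_selected)   # all Ti4, always
  expect_true(all(p1$ti5_selected %in% rep5$ti5_indices))
  expect_length(p1$ti5_selected, floor(0.30 * 100))
})

test_that("surface charge density follows sigma = n_oh q_oh / area", {
  plan <- plan_hydroxylation(coordination_counts(504, 0), seed = 1, q_oh = -0.40)
  area <- 2 * (68.2 * 71.8) / 100   # both faces, nm^2
  sigma <- surface_charge_density(plan, area)
  expect_lt(abs(sigma - (-0.62)), 0.02)
  expect_equal(surface_charge_density(plan, 2 * area), sigma / 2)
  p0 <- plan_hydroxylation(coordination_counts(504, 0), fraction = 0, seed = 1)
  expect_equal(surface_charge_density(p0, area), 0)
  expect_error(surface_charge_density(plan, 0), "area")
})

test_that("with q_oh = -0.40 e all four slab charge densities match the reported values", {
  rows <- list(list(504, 0, 68.2 * 71.8, -0.62),
               list(504, 0, 68.2 * 66.7, -0.67),
               list(528, 0, 71.0 * 71.5, -0.63),
               list(780, 0, 68.9 * 71.0, -0.97))
  for (row in rows) {
    plan <- plan_hydroxylation(coordination_counts(row[[1]], row[[2]]),
                               seed = 1, q_oh = -0.40)
    sigma <- surface_charge_density(plan, 2 * row[[3]] / 100)
    expect_lt(abs(sigma - row[[4]]), 0.02)
  }
})

test_that("attaching hydroxyls adds flagged O-H pairs at the expected geometry", {
  slab <- build_slab("anatase", "100", 3, 1, 2)
  census <- compute_coordination(slab)
  plan <- plan_hydroxylation(census, seed = 11)
  m <- attach_hydroxyls(slab, plan)
  expect_equal(nrow(m$atoms), nrow(slab$atoms) + 2 * plan$n_oh)
  added <- m$atoms[m$atoms$hydroxyl, ]
  expect_equal(sum(added$element == "O"), plan$n_oh)
  expect_equal(sum(added$element == "H"), plan$n_oh)
  # each selected Ti gains a hydroxyl O within the bond cutoff
  for (i in plan$ti5_selected) {
    ti <- as.numeric(slab$atoms[i, c("x", "y", "z")])
    oh_o <- as.matrix(added[added$element == "O", c("x", "y", "z")])
    expect_lte(min(brute_nearest(matrix(ti, 1), oh_o, m$box, m$periodic)), 2.6)
  }
  # no overlap introduced
  expect_gt(titania:::min_pair_dist(as.matrix(m$atoms[, c("x", "y", "z")]),
                                    m$box, m$periodic), 0.95)
})

test_that("every 4-fold Ti of a nanoparticle carries a hydroxyl after attachment", {
  np <- carve_nanoparticle("anatase", 8)
  plan <- plan_hydroxylation(np$census, seed = 2)
  m <- attach_hydroxyls(np, plan)
  added_o <- as.matrix(m$atoms[m$atoms$hydroxyl & m$atoms$element == "O",
                               c("x", "y", "z")])
  for (i in plan$ti4_selected) {
    ti <- as.numeric(np$atoms[i, c("x", "y", "z")])
    expect_lte(min(brute_nearest(matrix(ti, 1), added_o, m$box, m$periodic)), 2.6)
  }
})

test_that("an empty plan leaves the model unchanged", {
  slab <- build_slab("rutile", "110", 2, 1, 2)
  plan <- plan_hydroxylation(coordination_counts(0, 0), seed = 1)
  expect_identical(attach_hydroxyls(slab, plan), slab)
})

test_that("hydroxylation plans survive a JSON round trip", {
  plan <- plan_hydroxylation(coordination_counts(50, 3), seed = 7,
                             exposed_area_nm2 = 10)
  f <- tempfile(fileext = ".json")
  write_plan(plan, f)
  back <- read_plan(f)
  expect_equal(back$n_oh, plan$n_oh)
  expect_equal(back$ti5_selected, plan$ti5_selected)
  expect_equal(back$sigma, plan$sigma)
})
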