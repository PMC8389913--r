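test_that("generation is bit-identical for identical spec and seed", {
  s1 <- generate_distance_series(traj_spec(n_lipids = 5, duration = 20, seed = 8))
  s2 <- generate_distance_series(traj_spec(n_lipids = 5, duration = 20, seed = 8))
  s3 <- generate_distance_series(traj_spec(n_lipids = 5, duration = 20, seed = 9))
  expect_identical(s1$dist, s2$dist)
  expect_identical(s1$labels, s2$labels)
  expect_false(identical(s1$dist, s3$dist))
})

test_that("a single always-bound mode keeps essentially all mass within 3 sd of its centre", {
  spec <- traj_spec(n_lipids = 10, duration = 100, tau_unbound = 0,
                    modes = list(mode_spec("only", 0.30, 0.01, 5, 1)),
                    seed = 3)
  s <- generate_distance_series(spec)
  expect_true(all(s$labels == 1L))
  inside <- mean(s$dist >= 0.30 - 0.03 & s$dist <= 0.30 + 0.03)
  expect_gte(inside, 0.99)
})

test_that("occupancy weights are realized as stationary time shares", {
  modes <- list(mode_spec("a", 0.235, 0.006, 25, 0.05),
                mode_spec("b", 0.29, 0.006, 8, 0.45),
                mode_spec("c", 0.435, 0.006, 6, 0.50))
  spec <- traj_spec(n_lipids = 80, duration = 1000, tau_unbound = 0,
                    modes = modes, seed = 21)
  s <- generate_distance_series(spec)
  tr <- label_truth(s)
  pi_k <- c(0.05, 0.45, 0.50)
  expect_equal(tr$bound_fraction, 1)
  for (k in 1:3) {
    expect_lt(abs(tr$occupancy[[k + 1]] - pi_k[k] * tr$bound_fraction), 0.02)
  }
})

test_that("label-run dwell means recover the generator taus in the censoring-light regime", {
  modes <- list(mode_spec("fast", 0.29, 0.006, 8, 0.25),
                mode_spec("slow", 0.435, 0.006, 12, 0.25))
  spec <- traj_spec(n_lipids = 60, duration = 600, tau_unbound = 8,
                    modes = modes, seed = 5)
  s <- generate_distance_series(spec)
  dw <- label_truth(s)$mean_dwell_ns
  expect_lt(abs(dw[["fast"]] - 8) / 8, 0.10)
  expect_lt(abs(dw[["slow"]] - 12) / 12, 0.10)
})

test_that("occupancies are stationary across the two halves of a long run", {
  s <- generate_distance_series(traj_spec(n_lipids = 40, duration = 500, seed = 6))
  nf <- nrow(s$labels)
  h1 <- colMeans(matrix(s$labels[1:(nf / 2), ] > 0, nf / 2))
  h2 <- colMeans(matrix(s$labels[(nf / 2 + 1):nf, ] > 0, nf / 2))
  # Monte-Carlo error of a mean over 40 lipids x 250 ns of ~8/8 ns dwells
  expect_lt(abs(mean(h1) - mean(h2)), 0.04)
})

test_that("spec validation rejects degenerate inputs", {
  expect_error(traj_spec(duration = 0.01), "duration")
  expect_error(traj_spec(modes = list(mode_spec("a", 0.3, 0.01, 5, 0.8),
                                      mode_spec("b", 0.4, 0.01, 5, 0.8))),
               "sum")
  expect_error(mode_spec("bad", -0.1, 0.01, 5, 0.5))
})

test_that("embedding round-trips distances through the geometric pipeline", {
  slab <- build_slab("anatase", "101", 2, 1, 2)
  plan <- plan_hydroxylation(compute_coordination(slab), seed = 2)
  m <- attach_hydroxyls(slab, plan)
  s <- generate_distance_series(traj_spec(n_lipids = 3, duration = 1, seed = 4))
  emb <- embed_in_geometry(s, m, seed = 7)
  st <- read_structure(emb$structure_file)
  ds <- nearest_surface_distances(read_trajectory(emb$traj_file, st), st)
  expect_equal(dim(ds$dist), dim(s$dist))
  expect_lt(max(abs(ds$dist - s$dist)), 1e-3)
})

test_that("a zero-length series embeds to a valid empty trajectory", {
  slab <- build_slab("anatase", "101", 2, 1, 2)
  s <- manual_series(matrix(numeric(0), 0, 2))
  emb <- embed_in_geometry(s, slab, seed = 1)
  st <- read_structure(emb$structure_file)
  frames <- collect_frames(emb$traj_file, st)
  expect_length(frames, 0)
})

test_that("embedded lateral positions are uniform when separations allow free placement", {
  slab <- build_slab("rutile", "110", 2, 2, 2)
  # all separations >= 1 nm: every lateral point is feasible, so positions
  # are drawn uniformly
  spec <- traj_spec(n_lipids = 5, duration = 10, tau_unbound = 0,
                    modes = list(mode_spec("far", 2.0, 0.1, 5, 1)), seed = 13)
  s <- generate_distance_series(spec)
  emb <- embed_in_geometry(s, slab, seed = 3)
  xs <- as.vector(emb$coords[, , 1]) / slab$box[1]
  ys <- as.vector(emb$coords[, , 2]) / slab$box[2]
  expect_gt(suppressWarnings(ks.test(xs, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(ys, "punif"))$p.value, 0.01)
})
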