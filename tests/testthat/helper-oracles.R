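# Brute-force oracles and small fixtures shared across test files.
# The oracles enumerate periodic images explicitly and never share code with
# the package's minimum-image implementations.

# neighbour counts of points `a` against `b` by explicit image enumeration
brute_count_within <- function(a, b, box, periodic, cutoff) {
  shifts <- expand.grid(sx = if (periodic[1]) -1:1 else 0,
                        sy = if (periodic[2]) -1:1 else 0,
                        sz = if (periodic[3]) -1:1 else 0)
  sapply(seq_len(nrow(a)), function(i) {
    hits <- rep(FALSE, nrow(b))
    for (s in seq_len(nrow(shifts))) {
      bb <- sweep(b, 2, c(shifts$sx[s] * box[1], shifts$sy[s] * box[2],
                          shifts$sz[s] * box[3]), "+")
      d2 <- (bb[, 1] - a[i, 1])^2 + (bb[, 2] - a[i, 2])^2 + (bb[, 3] - a[i, 3])^2
      hits <- hits | d2 < cutoff^2
    }
    sum(hits)
  })
}

# nearest distance of each point of `a` to the set `b`, explicit images
brute_nearest <- function(a, b, box, periodic) {
  shifts <- expand.grid(sx = if (periodic[1]) -1:1 else 0,
                        sy = if (periodic[2]) -1:1 else 0,
                        sz = if (periodic[3]) -1:1 else 0)
  sapply(seq_len(nrow(a)), function(i) {
    best <- Inf
    for (s in seq_len(nrow(shifts))) {
      bb <- sweep(b, 2, c(shifts$sx[s] * box[1], shifts$sy[s] * box[2],
                          shifts$sz[s] * box[3]), "+")
      d2 <- (bb[, 1] - a[i, 1])^2 + (bb[, 2] - a[i, 2])^2 + (bb[, 3] - a[i, 3])^2
      best <- min(best, min(d2))
    }
    sqrt(best)
  })
}

brute_ti_coordination <- function(model, cutoff = 2.6) {
  at <- model$atoms
  ti <- at[at$element == "Ti" & !at$hydroxyl, c("x", "y", "z")]
  ox <- at[at$element == "O" & !at$hydroxyl, c("x", "y", "z")]
  brute_count_within(as.matrix(ti), as.matrix(ox), model$box, model$periodic,
                     cutoff)
}

# hand-made structure: a few surface atoms plus one tracked lipid atom
toy_structure <- function(surface_xyz, probe_xyz, box) {
  ns <- nrow(surface_xyz)
  np <- nrow(probe_xyz)
  atoms <- data.frame(
    element = c(rep("Ti", ns), rep("P", np)),
    name = c(rep("Ti", ns), rep("P", np)),
    resname = c(rep("TIO", ns), rep("LIP", np)),
    resid = c(rep(1L, ns), 1L + seq_len(np)),
    x = c(surface_xyz[, 1], probe_xyz[, 1]),
    y = c(surface_xyz[, 2], probe_xyz[, 2]),
    z = c(surface_xyz[, 3], probe_xyz[, 3]),
    hydroxyl = FALSE, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, box = box, periodic = c(TRUE, TRUE, TRUE),
                 dialect = "memory"),
            class = "tio2_structure")
}

# distance series built directly from a matrix (frames x lipids, nm)
manual_series <- function(dist, frame_interval_ps = 5) {
  titania:::distance_series(dist, seq_len(ncol(dist)),
                            rep("closest", ncol(dist)), frame_interval_ps)
}
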