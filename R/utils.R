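# internal helpers shared across modules

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# minimum-image displacement along one box dimension
min_image <- function(d, L) d - L * round(d / L)

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# squared distances between two point sets under selective periodicity;
# chunked so memory stays modest for large structures.
# Returns, for each row of `a`, the number of rows of `b` within `cutoff`.
count_within <- function(a, b, box, periodic, cutoff, chunk = 400L) {
  stopifnot(ncol(a) == 3, ncol(b) == 3)
  n <- nrow(a)
  out <- integer(n)
  if (n == 0L || nrow(b) == 0L) return(out)
  c2 <- cutoff^2
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    d2 <- matrix(0, length(idx), nrow(b))
    for (k in 1:3) {
      dd <- outer(a[idx, k], b[, k], "-")
      if (periodic[k]) dd <- min_image(dd, box[k])
      d2 <- d2 + dd * dd
    }
    out[idx] <- rowSums(d2 < c2)
  }
  out
}

# for each row of `a`, distance to the nearest row of `b` (same conventions)
nearest_dist <- function(a, b, box, periodic, chunk = 400L) {
  stopifnot(ncol(a) == 3, ncol(b) == 3, nrow(b) > 0)
  n <- nrow(a)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    d2 <- matrix(0, length(idx), nrow(b))
    for (k in 1:3) {
      dd <- outer(a[idx, k], b[, k], "-")
      if (periodic[k]) dd <- min_image(dd, box[k])
      d2 <- d2 + dd * dd
    }
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}

# smallest inter-point distance within one set (used by overlap contracts)
min_pair_dist <- function(xyz, box, periodic) {
  n <- nrow(xyz)
  if (n < 2) return(Inf)
  best <- Inf
  chunk <- 400L
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    d2 <- matrix(0, length(idx), n)
    for (k in 1:3) {
      dd <- outer(xyz[idx, k], xyz[, k], "-")
      if (periodic[k]) dd <- min_image(dd, box[k])
      d2 <- d2 + dd * dd
    }
    d2[cbind(seq_along(idx), idx)] <- Inf
    best <- min(best, min(d2))
  }
  sqrt(best)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
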