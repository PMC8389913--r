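# Synthetic lipid-surface distance trajectories.
#
# Each lipid is an independent alternating renewal process between an
# unbound state and a set of binding modes: unbound dwells are
# Exponential(tau_unbound); on binding, a mode is entered with probability
# proportional to pi/tau_bound (so the time share among bound modes is
# proportional to pi, the stationary occupancy weight) and held for an
# Exponential(tau_bound) dwell.  While bound the frame-wise distance is
# Normal(mu_r, sd_r) truncated at 0.05 nm; while unbound it is uniform on
# unbound_range.  The per-frame ground-truth mode labels are returned
# alongside and are never read by the analysis code.

#' Define a binding mode for the synthetic generator
#'
#' @param name Mode name.
#' @param mu_r Peak centre of the lipid-surface separation, nm.
#' @param sd_r Peak width (standard deviation), nm.
#' @param tau_bound Mean bound dwell time, ns.
#' @param pi Stationary occupancy weight (fraction of total time spent in
#'   this mode); weights over all modes plus the unbound state sum to 1.
#' @return A `mode_spec` list.
#' @export
mode_spec <- function(name, mu_r, sd_r, tau_bound, pi) {
  stopifnot(mu_r > 0, sd_r > 0, tau_bound > 0, pi >= 0, pi <= 1)
  structure(list(name = name, mu_r = mu_r, sd_r = sd_r,
                 tau_bound = tau_bound, pi = pi), class = "mode_spec")
}

#' Default binding-mode palette
#'
#' Mirrors the three POPE binding modes seen on flat anatase/rutile faces: a
#' rare direct phosphate contact at 0.22-0.25 nm with a very long dwell, an
#' ethanolamine hydrogen-bonding mode at 0.28-0.30 nm, and a water-mediated
#' phosphate mode at 0.42-0.45 nm.  The occupancy weights sum to 0.47,
#' leaving 53% of lipid time unbound, in line with roughly half the lipids
#' residing within the 1 nm adsorption layer.
#'
#' @return List of three [mode_spec()] objects.
#' @export
default_binding_modes <- function() {
  list(mode_spec("phosphate-direct", 0.235, 0.006, 250, 0.025),
       mode_spec("ethanolamine",     0.290, 0.006,   8, 0.210),
       mode_spec("phosphate-water",  0.435, 0.006,   6, 0.235))
}

#' Specify a synthetic trajectory
#'
#' @param n_lipids Number of independent lipids (default 80).
#' @param frame_interval Frame spacing, ps (default 5).
#' @param duration Trajectory length, ns (default 1000, i.e. 1 us).
#' @param tau_unbound Mean unbound dwell, ns; `NULL` derives the value that
#'   makes the long-run bound fraction equal `sum(pi)` over the modes.
#' @param unbound_range Distance interval sampled while unbound, nm.
#' @param modes List of [mode_spec()] objects.
#' @param seed Integer seed.
#' @return A `traj_spec` list with the derived entry probabilities
#'   (`entry_prob`), mean bound dwell (`mean_bound_dwell`) and resolved
#'   `tau_unbound`.
#' @export
traj_spec <- function(n_lipids = 80L, frame_interval = 5, duration = 1000,
                      tau_unbound = NULL, unbound_range = c(1, 4),
                      modes = default_binding_modes(), seed = 1L) {
  stopifnot(n_lipids >= 1, frame_interval > 0, length(unbound_range) == 2,
            unbound_range[1] < unbound_range[2])
  if (duration < 10 * frame_interval / 1000) {
    stop("duration must be at least 10 frame intervals", call. = FALSE)
  }
  pi_k <- vapply(modes, `[[`, numeric(1), "pi")
  tau_k <- vapply(modes, `[[`, numeric(1), "tau_bound")
  if (sum(pi_k) > 1 + 1e-9) stop("mode occupancy weights must sum to <= 1", call. = FALSE)
  pin <- pi_k / sum(pi_k)
  entry <- (pin / tau_k) / sum(pin / tau_k)
  mean_bound <- sum(entry * tau_k)
  always_bound <- isTRUE(tau_unbound == 0) || sum(pi_k) >= 1 - 1e-9
  if (always_bound) {
    tau_unbound <- 0
  } else if (is.null(tau_unbound)) {
    f <- sum(pi_k)
    tau_unbound <- mean_bound * (1 - f) / f
  }
  structure(list(n_lipids = as.integer(n_lipids),
                 frame_interval = frame_interval, duration = duration,
                 tau_unbound = tau_unbound, unbound_range = unbound_range,
                 modes = modes, seed = as.integer(seed),
                 pi_norm = pin, entry_prob = entry,
                 mean_bound_dwell = mean_bound,
                 always_bound = always_bound),
            class = "traj_spec")
}

#' @export
print.traj_spec <- function(x, ...) {
  cat(sprintf("synthetic trajectory spec: %d lipids, %g ns at %g ps/frame, seed %d\n",
              x$n_lipids, x$duration, x$frame_interval, x$seed))
  for (m in x$modes) {
    cat(sprintf("  mode %-18s mu = %.3f nm, sd = %.3f nm, tau = %g ns, pi = %.3f\n",
                m$name, m$mu_r, m$sd_r, m$tau_bound, m$pi))
  }
  cat(if (x$always_bound) "  always bound\n" else
      sprintf("  tau_unbound = %.2f ns, unbound range [%g, %g] nm\n",
              x$tau_unbound, x$unbound_range[1], x$unbound_range[2]))
  invisible(x)
}

# distance-series container shared by the generator and the trajectory
# analysis. dist is an n_frames x n_atoms matrix in nm; lipid_id maps atom
# columns to lipids; labels (generator only) holds per-frame ground truth
# (0 = unbound, k = k-th mode).
distance_series <- function(dist, lipid_id, atom_name, frame_interval_ps,
                            labels = NULL, modes = NULL) {
  stopifnot(is.matrix(dist), length(lipid_id) == ncol(dist),
            length(atom_name) == ncol(dist))
  structure(list(dist = dist, lipid_id = as.integer(lipid_id),
                 atom_name = atom_name,
                 frame_interval_ps = frame_interval_ps,
                 labels = labels, modes = modes),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("distance series: %d frames x %d tracked atoms (%d lipids), %g ps/frame%s\n",
              nrow(x$dist), ncol(x$dist), length(unique(x$lipid_id)),
              x$frame_interval_ps,
              if (!is.null(x$labels)) ", with ground-truth labels" else ""))
  invisible(x)
}

#' Number of frames / lipids of a distance series
#' @param series A `distance_series`.
#' @return Integer count.
#' @export
n_frames <- function(series) nrow(series$dist)

#' Generate a synthetic lipid-surface distance trajectory
#'
#' Simulates the alternating renewal process described in [traj_spec()] for
#' every lipid independently, starting each lipid in its stationary state
#' (so occupancy fractions are stationary from the first frame).  The
#' returned series carries per-frame ground-truth mode labels for
#' validation; analysis functions never read them.
#'
#' @param spec A [traj_spec()].
#' @return A `distance_series` with one tracked ("closest") atom per lipid,
#'   `labels` (0 = unbound, k = k-th mode) and the generating `modes`.
#' @examples
#' s <- generate_distance_series(traj_spec(n_lipids = 4, duration = 10))
#' @export
generate_distance_series <- function(spec) {
  stopifnot(inherits(spec, "traj_spec"))
  dt_ns <- spec$frame_interval / 1000
  nf <- round(spec$duration / dt_ns)
  tau_k <- vapply(spec$modes, `[[`, numeric(1), "tau_bound")
  mu_k <- vapply(spec$modes, `[[`, numeric(1), "mu_r")
  sd_k <- vapply(spec$modes, `[[`, numeric(1), "sd_r")
  n_modes <- length(spec$modes)
  f_bound <- if (spec$always_bound) 1 else
    spec$mean_bound_dwell / (spec$mean_bound_dwell + spec$tau_unbound)

  with_seed(spec$seed, {
    dist <- matrix(NA_real_, nf, spec$n_lipids)
    labels <- matrix(NA_integer_, nf, spec$n_lipids)
    t_frames <- seq_len(nf) * dt_ns
    for (l in seq_len(spec$n_lipids)) {
      states <- integer(0); dwells <- numeric(0)
      # stationary initial state (exponential dwells are memoryless, so the
      # residual dwell has the full exponential law)
      if (runif(1) < f_bound) {
        s0 <- sample.int(n_modes, 1, prob = spec$pi_norm)
        states <- s0; dwells <- rexp(1, 1 / tau_k[s0])
      } else {
        states <- 0L; dwells <- rexp(1, 1 / spec$tau_unbound)
      }
      while (sum(dwells) < spec$duration) {
        need <- max(16L, ceiling((spec$duration - sum(dwells)) /
                                   (spec$mean_bound_dwell + max(spec$tau_unbound, 1e-9))) * 4L)
        for (i in seq_len(need)) {
          last <- states[length(states)]
          if (last == 0L || spec$always_bound) {
            s <- sample.int(n_modes, 1, prob = spec$entry_prob)
            states <- c(states, s); dwells <- c(dwells, rexp(1, 1 / tau_k[s]))
          } else {
            states <- c(states, 0L)
            dwells <- c(dwells, rexp(1, 1 / spec$tau_unbound))
          }
        }
      }
      lab <- states[findInterval(t_frames, cumsum(dwells), left.open = TRUE) + 1L]
      d <- numeric(nf)
      unb <- lab == 0L
      if (any(unb)) d[unb] <- runif(sum(unb), spec$unbound_range[1], spec$unbound_range[2])
      for (k in seq_len(n_modes)) {
        sel <- lab == k
        if (!any(sel)) next
        x <- rnorm(sum(sel), mu_k[k], sd_k[k])
        while (any(x < 0.05)) {        # truncate at 0.05 nm by redraw
          bad <- x < 0.05
          x[bad] <- rnorm(sum(bad), mu_k[k], sd_k[k])
        }
        d[sel] <- x
      }
      dist[, l] <- d
      labels[, l] <- lab
    }
    distance_series(dist, seq_len(spec$n_lipids),
                    rep("closest", spec$n_lipids),
                    spec$frame_interval, labels = labels, modes = spec$modes)
  })
}

#' Ground-truth summaries of a generated series
#'
#' Occupancy fraction per state and label-run dwell statistics, computed
#' from the generator's per-frame labels.
#'
#' @param series A labelled `distance_series`.
#' @return List with `occupancy` (named vector incl. `unbound`),
#'   `bound_fraction`, and `mean_dwell_ns` per mode (from maximal label
#'   runs, trajectory-end runs included).
#' @export
label_truth <- function(series) {
  if (is.null(series$labels)) stop("series carries no ground-truth labels", call. = FALSE)
  lab <- series$labels
  n_modes <- length(series$modes)
  occ <- vapply(0:n_modes, function(k) mean(lab == k), numeric(1))
  names(occ) <- c("unbound", vapply(series$modes, `[[`, character(1), "name"))
  dt_ns <- series$frame_interval_ps / 1000
  dwell <- vapply(seq_len(n_modes), function(k) {
    runs <- unlist(apply(lab, 2, function(col) {
      r <- rle(col == k); r$lengths[r$values]
    }), use.names = FALSE)
    if (length(runs)) mean(runs) * dt_ns else NA_real_
  }, numeric(1))
  names(dwell) <- names(occ)[-1]
  list(occupancy = occ, bound_fraction = 1 - occ[["unbound"]],
       mean_dwell_ns = dwell)
}

#' Embed a distance series into an explicit slab geometry
#'
#' Writes a trajectory and matching structure file in which each tracked
#' atom sits at its sampled nearest-surface distance above the upper face of
#' a built (and typically hydroxylated) slab, at a random lateral position
#' with periodic wrapping.  The height is solved so that the minimum-image
#' distance to the nearest non-hydroxyl surface atom equals the sampled
#' value exactly, which lets the geometric pipeline (structure parsing,
#' nearest-atom search, hydroxyl exclusion) be exercised end to end.  If a
#' sampled distance is too short to be realized above the drawn lateral
#' point, the point is redrawn; as a last resort it snaps onto the nearest
#' surface-atom column.
#'
#' @param series A `distance_series` (one tracked atom per column).
#' @param model A `tio2_slab`.
#' @param seed Integer seed for the lateral positions.
#' @param traj_file,structure_file Output paths (`.gro` dialect).
#' @return Invisibly, a list with the two paths and the placed coordinate
#'   array (angstrom).
#' @export
embed_in_geometry <- function(series, model, seed = 1L,
                              traj_file = tempfile(fileext = ".gro"),
                              structure_file = tempfile(fileext = ".gro")) {
  stopifnot(inherits(series, "distance_series"), inherits(model, "tio2_slab"))
  surf <- model$atoms[!model$atoms$hydroxyl, ]
  sx <- surf$x; sy <- surf$y; sz <- surf$z
  nf <- nrow(series$dist); na <- ncol(series$dist)
  box <- model$box
  coords <- array(NA_real_, c(nf, na, 3))
  with_seed(seed, {
    for (j in seq_len(na)) {
      d_A <- series$dist[, j] * 10
      for (i in seq_len(nf)) {
        d <- d_A[i]
        done <- FALSE
        for (try in seq_len(100L)) {
          px <- runif(1, 0, box[1]); py <- runif(1, 0, box[2])
          s2 <- min_image(px - sx, box[1])^2 + min_image(py - sy, box[2])^2
          feas <- s2 <= d^2
          if (any(feas)) {
            z <- max(sz[feas] + sqrt(d^2 - s2[feas]))
            coords[i, j, ] <- c(px, py, z)
            done <- TRUE
            break
          }
        }
        if (!done) {  # snap onto the closest surface column
          k <- which.max(sz)
          coords[i, j, ] <- c(sx[k], sy[k], sz[k] + d)
        }
      }
    }
  })
  # grow the box upward so that no sampled separation can be shortcut by a
  # periodic image through the top face
  if (nf > 0 && na > 0) {
    box[3] <- max(box[3], max(coords[, , 3]) + max(series$dist) * 10 + 5)
  }
  atoms <- data.frame(
    element = rep("P", na), name = series$atom_name,
    resname = "LIP", resid = series$lipid_id,
    x = 0, y = 0, z = 0, hydroxyl = FALSE, stringsAsFactors = FALSE)
  atoms$name[atoms$name == "closest"] <- "P"
  sys_at <- rbind(
    data.frame(element = model$atoms$element, name = model$atoms$element,
               resname = ifelse(model$atoms$hydroxyl, "OHX", "TIO"),
               resid = 1L, x = model$atoms$x, y = model$atoms$y,
               z = model$atoms$z, hydroxyl = model$atoms$hydroxyl,
               stringsAsFactors = FALSE),
    atoms)
  if (nf > 0) {
    first <- which(!sys_at$resname %in% c("TIO", "OHX"))
    sys_at$x[first] <- coords[1, , 1]
    sys_at$y[first] <- coords[1, , 2]
    sys_at$z[first] <- coords[1, , 3]
  }
  write_gro(sys_at, box, structure_file, title = "embedded synthetic system")
  ns <- nrow(sys_at) - na
  frames <- lapply(seq_len(nf), function(i) {
    m <- as.matrix(sys_at[, c("x", "y", "z")])
    if (na > 0) m[(ns + 1):(ns + na), ] <- coords[i, , , drop = TRUE]
    m
  })
  write_trajectory(frames, sys_at, box, traj_file,
                   frame_interval_ps = series$frame_interval_ps)
  invisible(list(traj_file = traj_file, structure_file = structure_file,
                 coords = coords))
}
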