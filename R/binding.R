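#' Detect binding-mode boundaries from a closest-atom profile
#'
#' Peaks of the smoothed closest-atom profile that exceed a prominence
#' threshold are taken as binding modes; each mode's boundaries `[r1, r2)`
#' are placed at the flanking minima of the smoothed profile (the centre of
#' the minimal plateau between adjacent peaks, which is deterministic even
#' when the valley floor is flat), or at the profile ends.  Manual mode
#' definitions are always honoured by the downstream operations, which
#' accept any data frame with `r1`/`r2` columns.
#'
#' @param profile A [closest_atom_profile()] result.
#' @param smoothing Moving-average window, bins (odd; default 3; kept
#'   narrower than the typical inter-peak spacing so adjacent contact modes
#'   are not merged).
#' @param min_prominence Minimum topographic prominence of a peak, as a
#'   fraction of the global maximum of the smoothed profile (default 0.02;
#'   low, so that rare but real contact modes survive, while flat-plateau
#'   noise, whose prominence is near zero, does not).
#' @param r_search Largest peak centre considered a binding mode, nm
#'   (default 1, the adsorption-layer width): lipid-surface contact modes
#'   live within the headgroup region, while density beyond it belongs to
#'   the unbound background, whose flat plateau would otherwise register as
#'   a spurious wide mode.
#' @return A data frame (class `binding_mode_set`) with columns `name`,
#'   `center`, `r1`, `r2`, ordered by `center`; zero rows when the profile
#'   is flat.
#' @export
detect_peak_bounds <- function(profile, smoothing = 3L, min_prominence = 0.02,
                               r_search = 1.0) {
  stopifnot(inherits(profile, "density_profile"))
  if (!identical(attr(profile, "mode"), "closest")) {
    stop("peak detection expects a closest-atom profile", call. = FALSE)
  }
  v <- profile$value
  n <- length(v)
  w <- max(1L, as.integer(smoothing))
  if (w %% 2 == 0) w <- w + 1L
  if (w > 1L && n >= w) {
    pad <- (w - 1L) / 2L
    vs <- stats::filter(c(rep(v[1], pad), v, rep(v[n], pad)), rep(1 / w, w))
    vs <- as.numeric(vs[(pad + 1):(pad + n)])
  } else vs <- v
  if (max(vs) <= 0) return(empty_mode_set())
  thr <- min_prominence * max(vs)
  # local maxima with plateau handling: compare to nearest differing values
  cand <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && vs[j + 1] == vs[i]) j <- j + 1L
    left_ok <- i == 1L || vs[i - 1] < vs[i]
    right_ok <- j == n || vs[j + 1] < vs[i]
    # a plateau spanning the whole profile is featureless, not a peak
    if (left_ok && right_ok && !(i == 1L && j == n)) {
      cand[[length(cand) + 1L]] <- c(i, j)
    }
    i <- j + 1L
  }
  if (length(cand) == 0) return(empty_mode_set())
  # topographic prominence: walk out from the peak plateau to the nearest
  # higher point on each side; the peak's base is the higher of the two
  # valley floors passed on the way.  The density is zero outside the
  # observed range, so a plateau touching a profile end keeps a zero base
  # on that side.
  prominence <- vapply(cand, function(pl) {
    top <- vs[pl[1]]
    lo_l <- if (pl[1] == 1L) 0 else top
    for (k in rev(seq_len(pl[1] - 1L))) {
      if (vs[k] > top) break
      lo_l <- min(lo_l, vs[k])
      if (k == 1L) lo_l <- 0
    }
    lo_r <- if (pl[2] == n) 0 else top
    for (k in seq_len(n - pl[2]) + pl[2]) {
      if (vs[k] > top) break
      lo_r <- min(lo_r, vs[k])
      if (k == n) lo_r <- 0
    }
    top - max(lo_l, lo_r)
  }, numeric(1))
  peaks <- vapply(cand, function(pl) as.integer((pl[1] + pl[2]) / 2), integer(1))
  peaks <- peaks[prominence >= thr & profile$r[peaks] <= r_search]
  if (length(peaks) == 0) return(empty_mode_set())
  # Boundary between two peaks: the midpoint of the minimal plateau of the
  # raw profile between them.  Bins within a small tolerance of the valley
  # floor count as part of the plateau, so the boundary sits midway across
  # a near-empty valley instead of at whichever of its bins happens to be
  # lowest (the raw values are used here because smoothing tilts narrow
  # valleys toward their steeper side).
  edges <- attr(profile, "edges")
  tol <- 0.005 * max(v)
  valley_mid <- function(a, b) {
    if (b - a <= 1L) return(edges[b])
    seg <- v[(a + 1):(b - 1)]
    m <- min(seg)
    idx <- which(seg <= m + tol) + a
    (edges[min(idx)] + edges[max(idx) + 1L]) / 2
  }
  bounds <- c(if (peaks[1] > 1L) valley_mid(0L, peaks[1]) else edges[1],
              if (length(peaks) > 1)
                mapply(valley_mid, peaks[-length(peaks)], peaks[-1]),
              if (peaks[length(peaks)] < n)
                valley_mid(peaks[length(peaks)], n + 1L) else edges[n + 1L])
  out <- data.frame(
    name = paste0("mode", seq_along(peaks)),
    center = profile$r[peaks],
    r1 = bounds[-length(bounds)],
    r2 = bounds[-1],
    stringsAsFactors = FALSE)
  class(out) <- c("binding_mode_set", "data.frame")
  out
}

empty_mode_set <- function() {
  out <- data.frame(name = character(0), center = numeric(0),
                    r1 = numeric(0), r2 = numeric(0), stringsAsFactors = FALSE)
  class(out) <- c("binding_mode_set", "data.frame")
  out
}

#' Binding probability of a mode from a closest-atom profile
#'
#' The probability of a lipid being adsorbed through a mode is the ratio of
#' the profile integral over the mode's boundaries to the integral over the
#' whole observed range:
#' `P_b = int_{r1}^{r2} n(r) dr / int_0^{r_max} n(r) dr`,
#' with both integrals taken as bin sums.  With `r_max` at the largest
#' observed distance the denominator counts every lipid-frame observation,
#' so `P_b` is a fraction of all lipids.
#'
#' @param profile A [closest_atom_profile()] result.
#' @param mode A single-row data frame or list with `r1` and `r2` (nm).
#' @param r_max Upper integration limit of the denominator, nm (default:
#'   the profile's full extent).
#' @return `P_b`, a fraction in `[0, 1]`.
#' @export
binding_probability <- function(profile, mode, r_max = NULL) {
  stopifnot(inherits(profile, "density_profile"))
  if (!identical(attr(profile, "mode"), "closest")) {
    stop("binding probabilities are defined on the closest-atom profile",
         call. = FALSE)
  }
  r1 <- as.numeric(mode$r1)[1]
  r2 <- as.numeric(mode$r2)[1]
  if (is.na(r1) || is.na(r2) || r1 < 0 || r2 <= r1) {
    stop("mode must satisfy 0 <= r1 < r2", call. = FALSE)
  }
  edges <- attr(profile, "edges")
  r_max <- r_max %||% edges[length(edges)]
  if (r2 > r_max + 1e-9) stop("mode range exceeds r_max", call. = FALSE)
  denom <- sum(profile$value[profile$r <= r_max])
  if (denom <= 0) stop("zero profile mass up to r_max", call. = FALSE)
  num <- sum(profile$value[profile$r >= r1 & profile$r < r2])
  num / denom
}

#' Residence-time statistics of a binding mode
#'
#' A residence event is a maximal run of consecutive frames in which a
#' lipid's closest-atom distance lies in the mode's range `[r1, r2)`;
#' out-of-range gaps no longer than `gap_tolerance_frames` are forgiven and
#' merged into the surrounding event.  The mean residence time is the
#' occurrence-weighted average of event durations; events touching either
#' trajectory end are counted but flagged as censored, so the mean is a
#' lower bound of the true mean dwell (finite trajectories cannot observe
#' dwells longer than themselves).  A binned-histogram variant of the mean
#' (weights from a coarse duration histogram, durations at bin midpoints) is
#' reported alongside.
#'
#' @param series A `distance_series`; reduced to the closest atom per lipid
#'   if multi-atom.
#' @param mode A single-row data frame or list with `r1`/`r2` (nm).
#' @param gap_tolerance_frames Forgiven excursion length, frames (default 0).
#' @param hist_bin_ns Bin width of the reported residence histogram, ns
#'   (default 1).
#' @return A `binding_mode_stats` list: `n_events`, `censored_events`,
#'   `mean_residence` (ns, lower bound), `mean_residence_binned`,
#'   `residence_histogram` (data frame of duration-bin midpoints and
#'   occurrences), `durations_ns`, `r1`, `r2`.
#' @export
residence_times <- function(series, mode, gap_tolerance_frames = 0L,
                            hist_bin_ns = 1) {
  stopifnot(inherits(series, "distance_series"))
  cs <- closest_series(series)
  r1 <- as.numeric(mode$r1); r2 <- as.numeric(mode$r2)
  if (is.na(r1) || is.na(r2) || r1 < 0 || r2 <= r1) {
    stop("mode must satisfy 0 <= r1 < r2", call. = FALSE)
  }
  dt_ns <- cs$frame_interval_ps / 1000
  nf <- nrow(cs$dist)
  durations <- numeric(0)
  censored <- logical(0)
  for (l in seq_len(ncol(cs$dist))) {
    inb <- cs$dist[, l] >= r1 & cs$dist[, l] < r2
    if (!any(inb)) next
    r <- rle(inb)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ev <- data.frame(start = starts[r$values], end = ends[r$values])
    if (gap_tolerance_frames > 0 && nrow(ev) > 1) {
      keep <- list(ev[1, ])
      for (k in 2:nrow(ev)) {
        gap <- ev$start[k] - keep[[length(keep)]]$end - 1L
        if (gap <= gap_tolerance_frames) {
          keep[[length(keep)]]$end <- ev$end[k]
        } else keep[[length(keep) + 1L]] <- ev[k, ]
      }
      ev <- do.call(rbind, keep)
    }
    durations <- c(durations, (ev$end - ev$start + 1L) * dt_ns)
    censored <- c(censored, ev$start == 1L | ev$end == nf)
  }
  n_events <- length(durations)
  if (n_events == 0) {
    return(structure(list(n_events = 0L, censored_events = 0L,
                          mean_residence = NA_real_,
                          mean_residence_binned = NA_real_,
                          residence_histogram = data.frame(duration_ns = numeric(0),
                                                           occurrence = integer(0)),
                          durations_ns = numeric(0), r1 = r1, r2 = r2,
                          lower_bound = TRUE),
                     class = "binding_mode_stats"))
  }
  mean_res <- mean(durations)  # == occurrence-weighted mean at full resolution
  br <- seq(0, max(durations) + hist_bin_ns, by = hist_bin_ns)
  h <- hist(durations, breaks = br, plot = FALSE)
  hd <- data.frame(duration_ns = h$mids, occurrence = h$counts)
  hd <- hd[hd$occurrence > 0, ]
  mean_binned <- sum(hd$duration_ns * hd$occurrence) / sum(hd$occurrence)
  structure(list(n_events = n_events, censored_events = sum(censored),
                 mean_residence = mean_res,
                 mean_residence_binned = mean_binned,
                 residence_histogram = hd,
                 durations_ns = durations, r1 = r1, r2 = r2,
                 lower_bound = TRUE),
            class = "binding_mode_stats")
}

#' @export
print.binding_mode_stats <- function(x, ...) {
  cat(sprintf("residence in [%.3f, %.3f) nm: %d events (%d censored), mean %.2f ns (lower bound; binned %.2f ns)\n",
              x$r1, x$r2, x$n_events, x$censored_events,
              x$mean_residence, x$mean_residence_binned))
  invisible(x)
}

#' Fraction of adsorbed lipids within a surface layer
#'
#' The adsorption layer runs from the surface (0 nm separation) out to
#' `layer_width` (default 1 nm, roughly the thickness of the headgroup
#' region of a bilayer); the fraction of lipid-frames whose closest-atom
#' distance falls inside it measures the overall adsorption strength.
#'
#' @param profile A [closest_atom_profile()] result.
#' @param layer_width Adsorption layer width, nm (default 1).
#' @return An `adsorption_summary`: list with `layer_width` and
#'   `adsorbed_fraction` (percent).
#' @export
adsorbed_fraction <- function(profile, layer_width = 1.0) {
  stopifnot(inherits(profile, "density_profile"))
  if (!identical(attr(profile, "mode"), "closest")) {
    stop("adsorbed fraction is defined on the closest-atom profile", call. = FALSE)
  }
  if (layer_width < 0) stop("layer_width must be >= 0", call. = FALSE)
  denom <- sum(profile$value)
  if (denom <= 0) stop("zero profile mass", call. = FALSE)
  frac <- if (layer_width == 0) 0 else
    sum(profile$value[profile$r < layer_width]) / denom
  structure(list(layer_width = layer_width,
                 adsorbed_fraction = 100 * frac),
            class = "adsorption_summary")
}

#' @export
print.adsorption_summary <- function(x, ...) {
  cat(sprintf("adsorbed lipids within %.2f nm: %.1f%%\n",
              x$layer_width, x$adsorbed_fraction))
  invisible(x)
}
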