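#' Nearest-surface distances from a trajectory
#'
#' For every frame and every tracked lipid headgroup atom, computes the
#' minimum-image distance to the nearest atom of the TiO2 surface, with
#' hydroxyl atoms excluded from the surface group.
#'
#' @param trajectory A trajectory reader from [read_trajectory()], or a list
#'   of coordinate matrices (angstrom, one row per structure atom).
#' @param structure The matching structure, from [read_structure()] or
#'   [embed_in_geometry()]'s structure file.  Surface atoms are the `TIO`
#'   residue; `OHX` (hydroxyl) atoms are excluded; solvent residues
#'   (`SOL`, `NA`, `CL`) are ignored.
#' @param atom_names Lipid headgroup atom names to track (default: the
#'   phospholipid headgroup set `P`, `O13`, `O14`, `N`, `C13`, `C14`, `C15`,
#'   `O32`; atoms not present are silently dropped).
#' @return A `distance_series` in nm, one column per tracked atom, with
#'   `lipid_id` mapping columns to lipid residues.
#' @export
nearest_surface_distances <- function(trajectory, structure,
                                      atom_names = c("P", "O13", "O14", "N",
                                                     "C13", "C14", "C15",
                                                     "O32")) {
  at <- structure$atoms
  surf <- which(at$resname == "TIO" & !at$hydroxyl)
  lip <- which(!at$resname %in% c("TIO", "OHX", "SOL", "NA", "CL") &
                 at$name %in% atom_names)
  if (length(surf) == 0 || length(lip) == 0) {
    stop("surface and lipid atom groups must both be non-empty", call. = FALSE)
  }
  box <- structure$box
  periodic <- structure$periodic %||% c(TRUE, TRUE, TRUE)
  is_reader <- inherits(trajectory, "trajectory_reader")
  frames <- if (is_reader) NULL else trajectory
  get_frame <- if (is_reader) trajectory$next_frame else {
    i <- 0L
    function() {
      i <<- i + 1L
      if (i > length(frames)) NULL else frames[[i]]
    }
  }
  rows <- list()
  smat <- NULL
  repeat {
    fr <- get_frame()
    if (is.null(fr)) break
    if (nrow(fr) != nrow(at)) {
      stop(sprintf("frame has %d atoms but structure has %d", nrow(fr), nrow(at)),
           call. = FALSE)
    }
    smat <- fr[surf, , drop = FALSE]
    rows[[length(rows) + 1L]] <-
      nearest_dist(fr[lip, , drop = FALSE], smat, box, periodic) / 10
  }
  dist <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, length(lip))
  fi <- (if (is_reader) trajectory$frame_interval_ps else NULL) %||% 5
  distance_series(dist, lipid_id = at$resid[lip], atom_name = at$name[lip],
                  frame_interval_ps = fi)
}

#' Reduce a multi-atom series to the closest tracked atom per lipid
#'
#' @param series A `distance_series`.
#' @return A `distance_series` with one column per lipid holding, per frame,
#'   the minimum over that lipid's tracked atoms.
#' @export
closest_series <- function(series) {
  ids <- sort(unique(series$lipid_id))
  if (length(ids) == ncol(series$dist)) {
    out <- series
    out$atom_name <- rep("closest", ncol(series$dist))
    return(out)
  }
  d <- vapply(ids, function(id) {
    cols <- series$dist[, series$lipid_id == id, drop = FALSE]
    apply(cols, 1, min)
  }, numeric(nrow(series$dist)))
  if (is.null(dim(d))) d <- matrix(d, nrow = nrow(series$dist))
  distance_series(d, ids, rep("closest", length(ids)),
                  series$frame_interval_ps, labels = series$labels,
                  modes = series$modes)
}

#' Number-density profile of lipid-surface distances
#'
#' Histograms all tracked-atom distances of a series into bins of width
#' `bin_width`, averaged over lipids and frames.  In `"volumetric"`
#' normalization bin counts are divided by the number of frames and the bin
#' volume (`face_area x bin_width` for a slab), giving nm^-3; in
#' `"per_frame"` mode only the number of frames divides the counts (the
#' convention used for nanoparticle profiles, where a radial bin volume is
#' not constant).
#'
#' @param series A `distance_series` (nm).
#' @param bin_width Bin width, nm (default 0.01).
#' @param normalization `"volumetric"` or `"per_frame"`.
#' @param geometry For volumetric mode, `list(type = "slab",
#'   face_area_nm2 = ...)`; `list(type = "nanoparticle")` forces per-frame
#'   normalization.
#' @param stride Use every `stride`-th frame (default 1; trajectory analyses
#'   often subsample, e.g. every 100 recorded frames).
#' @param r_max Histogram upper limit, nm (default: largest observed
#'   distance).
#' @return A `density_profile` data frame with columns `r` (bin centre, nm)
#'   and `value`, and attributes `edges`, `counts`, `normalization`,
#'   `n_frames`, `n_lipids`, `bin_width`, `mode`.
#' @export
density_profile <- function(series, bin_width = 0.01,
                            normalization = c("volumetric", "per_frame"),
                            geometry = list(type = "slab", face_area_nm2 = NULL),
                            stride = 1L, r_max = NULL) {
  stopifnot(inherits(series, "distance_series"))
  normalization <- match.arg(normalization)
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  if (nrow(series$dist) == 0) stop("empty distance series", call. = FALSE)
  if (identical(geometry$type, "nanoparticle")) normalization <- "per_frame"
  rows <- seq(1L, nrow(series$dist), by = stride)
  d <- as.vector(series$dist[rows, , drop = FALSE])
  r_max <- r_max %||% max(d)
  # extend one bin past r_max so a value exactly on the upper limit keeps
  # its own half-open bin
  edges <- seq(0, (floor(r_max / bin_width + 1e-9) + 1) * bin_width,
               by = bin_width)
  cnt <- tabulate(pmin(findInterval(d, edges, left.open = FALSE),
                       length(edges) - 1L),
                  nbins = length(edges) - 1L)
  nf <- length(rows)
  value <- switch(normalization,
    per_frame = cnt / nf,
    volumetric = {
      if (is.null(geometry$face_area_nm2)) {
        stop("volumetric normalization needs geometry$face_area_nm2", call. = FALSE)
      }
      cnt / (nf * geometry$face_area_nm2 * bin_width)
    })
  out <- data.frame(r = (edges[-1] + edges[-length(edges)]) / 2, value = value)
  structure(out,
            class = c("density_profile", "data.frame"),
            edges = edges, counts = cnt, normalization = normalization,
            n_frames = nf, n_lipids = length(unique(series$lipid_id)),
            bin_width = bin_width, mode = "atom",
            geometry = geometry)
}

#' Number-density profile of the closest headgroup atom
#'
#' Per lipid and frame, only the minimum distance over the lipid's tracked
#' atoms is binned.  This is the profile from which binding modes are read:
#' each of its peaks is a distinct lipid-surface contact geometry.
#'
#' @inheritParams density_profile
#' @return A `density_profile` with attribute `mode = "closest"`; its
#'   unnormalized counts sum to one observation per lipid per frame.
#' @export
closest_atom_profile <- function(series, bin_width = 0.01,
                                 normalization = c("volumetric", "per_frame"),
                                 geometry = list(type = "slab", face_area_nm2 = NULL),
                                 stride = 1L, r_max = NULL) {
  cs <- closest_series(series)
  p <- density_profile(cs, bin_width, normalization, geometry, stride, r_max)
  attr(p, "mode") <- "closest"
  p
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("number-density profile (%s, %s normalization): %d bins of %.3g nm, %d frames x %d lipids\n",
              attr(x, "mode"), attr(x, "normalization"), nrow(x),
              attr(x, "bin_width"), attr(x, "n_frames"), attr(x, "n_lipids")))
  invisible(x)
}

#' @export
plot.density_profile <- function(x, ..., xlab = "r (nm)",
                                 ylab = if (attr(x, "normalization") == "volumetric")
                                   expression(n(r) ~ (nm^-3)) else "n(r) (counts/frame)",
                                 type = "l") {
  graphics::plot(x$r, x$value, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
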