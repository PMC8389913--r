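# Miller-indexed slab construction.
#
# For each supported (phase, face) pair an orthogonal surface frame is defined
# by two in-plane lattice vectors A1 (slab x), A2 (slab y) and a stacking
# lattice vector A3 with a positive component d along the outward normal.  A1
# and A2 are mutually perpendicular for every supported face, so the slab box
# is orthorhombic; A3 may shear in-plane, which is immaterial once lateral
# coordinates are wrapped.

face_basis <- function(phase, miller) {
  key <- paste0(phase, paste(miller, collapse = ""))
  def <- switch(key,
    "anatase101" = list(A1 = c(0, 1, 0), A2 = c(1, 0, -1), A3 = c(0, 0, 1)),
    "anatase100" = list(A1 = c(0, 1, 0), A2 = c(0, 0, 1),  A3 = c(1, 0, 0)),
    "rutile110"  = list(A1 = c(0, 0, 1), A2 = c(1, -1, 0), A3 = c(1, 1, 0)),
    "rutile101"  = list(A1 = c(0, 1, 0), A2 = c(1, 0, -1), A3 = c(0, 0, 1)),
    NULL)
  if (is.null(def)) {
    stop(sprintf("unsupported (phase, miller) pair: %s(%s); supported faces are anatase(101), anatase(100), rutile(110), rutile(101)",
                 phase, paste(miller, collapse = "")), call. = FALSE)
  }
  def
}

# One surface-oriented repeat cell: atoms in the rotated cartesian frame
# (x along A1, y along A2, z along the outward normal), plus lateral repeat
# lengths Lu, Lv, stacking height d and the in-plane shear of A3.
oriented_cell <- function(phase, miller) {
  cell <- build_unit_cell(phase)
  fb <- face_basis(phase, miller)
  L <- diag(c(cell$a, cell$a, cell$c))
  M <- cbind(fb$A1, fb$A2, fb$A3)
  A <- L %*% M
  mult <- abs(det(M))
  # enumerate conventional cells and keep atoms with oriented-cell fractional
  # coordinates in [0,1)^3
  rng <- -4:4
  g <- as.matrix(expand.grid(rng, rng, rng))
  b <- as.matrix(cell$basis[, c("fx", "fy", "fz")])
  frac <- do.call(rbind, lapply(seq_len(nrow(b)), function(i) sweep(g, 2, b[i, ], "+")))
  el <- rep(cell$basis$element, each = nrow(g))
  f <- round(t(solve(M) %*% t(frac)), 9)
  eps <- 1e-8
  keep <- f[, 1] >= -eps & f[, 1] < 1 - eps &
          f[, 2] >= -eps & f[, 2] < 1 - eps &
          f[, 3] >= -eps & f[, 3] < 1 - eps
  f <- f[keep, , drop = FALSE]; el <- el[keep]
  dup <- duplicated(apply(round(f, 6), 1, paste, collapse = ","))
  f <- f[!dup, , drop = FALSE]; el <- el[!dup]
  stopifnot(nrow(f) == nrow(cell$basis) * mult)
  ex <- A[, 1] / sqrt(sum(A[, 1]^2))
  ey <- A[, 2] / sqrt(sum(A[, 2]^2))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  if (sum(A[, 3] * ez) < 0) { ey <- -ey; ez <- -ez }  # outward normal, d > 0
  cart <- t(A %*% t(f))
  xyz <- cbind(cart %*% ex, cart %*% ey, cart %*% ez)
  list(xyz = xyz, element = el,
       Lu = sqrt(sum(A[, 1]^2)), Lv = sqrt(sum(A[, 2]^2)),
       d = sum(A[, 3] * ez),
       shear = c(sum(A[, 3] * ex), sum(A[, 3] * ey)))
}

# raw slab: replicate the oriented cell laterally and in stacking, keep atoms
# with z in the cut window [z0, z0 + n_layers*d), wrap laterally
slab_atoms <- function(oc, n_u, n_v, n_layers, z0) {
  reps <- as.matrix(expand.grid(0:(n_u - 1), 0:(n_v - 1), -1:n_layers))
  n <- nrow(oc$xyz)
  xyz <- matrix(NA_real_, nrow(reps) * n, 3)
  for (k in seq_len(nrow(reps))) {
    off <- c(reps[k, 1] * oc$Lu + reps[k, 3] * oc$shear[1],
             reps[k, 2] * oc$Lv + reps[k, 3] * oc$shear[2],
             reps[k, 3] * oc$d)
    xyz[((k - 1) * n + 1):(k * n), ] <- sweep(oc$xyz, 2, off, "+")
  }
  el <- rep(oc$element, nrow(reps))
  keep <- xyz[, 3] >= z0 - 1e-9 & xyz[, 3] < z0 + n_layers * oc$d - 1e-9
  xyz <- xyz[keep, , drop = FALSE]; el <- el[keep]
  Lx <- n_u * oc$Lu; Ly <- n_v * oc$Lv
  xyz[, 1] <- xyz[, 1] %% Lx
  xyz[, 2] <- xyz[, 2] %% Ly
  xyz[, 3] <- xyz[, 3] - min(xyz[, 3])
  list(xyz = xyz, element = el, Lx = Lx, Ly = Ly)
}

# Candidate cut heights are midpoints between consecutive atomic z-levels of
# one repeat; a cut is valid when the resulting faces leave no Ti below
# 5-fold and no O below 2-fold coordination.  The window height is an exact
# multiple of the repeat, so every cut is stoichiometric.  The search runs on
# a small 3x3x2 slab; termination is scale-invariant.
find_termination <- function(oc, cutoff = 2.6) {
  zl <- sort(unique(round(oc$xyz[, 3] %% oc$d, 5)))
  cuts <- (zl + c(zl[-1], zl[1] + oc$d)) / 2
  for (z0 in cuts) {
    s <- slab_atoms(oc, 3, 3, 2, z0)
    box <- c(s$Lx, s$Ly, 2 * oc$d + 20)
    per <- c(TRUE, TRUE, FALSE)
    ti <- s$element == "Ti"
    cti <- count_within(s$xyz[ti, , drop = FALSE], s$xyz[!ti, , drop = FALSE],
                        box, per, cutoff)
    cox <- count_within(s$xyz[!ti, , drop = FALSE], s$xyz[ti, , drop = FALSE],
                        box, per, cutoff)
    if (min(cti) >= 5 && min(cox) >= 2) return(z0)
  }
  stop("no valid autocompensated flat-cut termination found for this face",
       call. = FALSE)
}

#' Build a Miller-indexed TiO2 slab
#'
#' Cleaves a laterally periodic, vacuum-terminated slab of the requested
#' phase and face from the bulk crystal.  The cut plane is chosen
#' automatically as the stoichiometric, autocompensated termination on which
#' a defect-free face exposes only 5-fold-coordinated (never 4-fold or less)
#' titanium, so that the undercoordinated-Ti census of an ideal slab contains
#' no Ti(4).
#'
#' Supported faces: anatase(101), anatase(100), rutile(110), rutile(101).
#' Slab thickness is expressed in stacking repeat layers; the achieved
#' thickness in angstrom is reported on the returned object.
#'
#' @param phase `"anatase"` or `"rutile"`.
#' @param miller Miller index of the exposed face, as a length-3 integer
#'   vector (e.g. `c(1, 0, 1)`) or compact string (`"101"`).
#' @param n_u,n_v Lateral supercell repeats along the two in-plane lattice
#'   directions.
#' @param n_layers Number of stacking repeat layers (>= 2).
#' @param vacuum Vacuum padding added above and below the slab, angstrom.
#' @return A `tio2_slab`/`tio2_model` object with fields `atoms` (element,
#'   cartesian x/y/z in angstrom, hydroxyl flag), `box`, `periodic`
#'   (lateral dimensions only), `miller`, `face_area` (one face, angstrom^2),
#'   `thickness`, `layer_spacing`.
#' @examples
#' slab <- build_slab("rutile", "110", 3, 2, 2)
#' @export
build_slab <- function(phase, miller, n_u, n_v, n_layers, vacuum = 20) {
  miller <- parse_miller(miller)
  if (n_u < 1 || n_v < 1) stop("n_u and n_v must be >= 1", call. = FALSE)
  if (n_layers < 2) {
    stop("n_layers must be >= 2 so the two faces are separated", call. = FALSE)
  }
  face_basis(phase, miller)  # early rejection of unsupported pairs
  oc <- oriented_cell(phase, miller)
  z0 <- find_termination(oc)
  s <- slab_atoms(oc, n_u, n_v, n_layers, z0)
  thickness <- n_layers * oc$d
  atoms <- data.frame(element = s$element,
                      x = s$xyz[, 1], y = s$xyz[, 2],
                      z = s$xyz[, 3] + vacuum / 2,
                      hydroxyl = FALSE, stringsAsFactors = FALSE)
  new_tio2_model(
    atoms = atoms,
    box = c(s$Lx, s$Ly, thickness + vacuum),
    periodic = c(TRUE, TRUE, FALSE),
    phase = phase, subclass = "tio2_slab",
    miller = miller, face_area = s$Lx * s$Ly,
    thickness = thickness, layer_spacing = oc$d,
    n_u = n_u, n_v = n_v, n_layers = n_layers)
}

parse_miller <- function(miller) {
  if (is.character(miller) && length(miller) == 1) {
    miller <- as.integer(strsplit(miller, "")[[1]])
  }
  if (length(miller) != 3 || anyNA(miller)) {
    stop("miller must be three integers, e.g. c(1,0,1) or \"101\"",
         call. = FALSE)
  }
  as.integer(miller)
}

#' Carve a spherical TiO2 nanoparticle from the bulk crystal
#'
#' Retains the atoms of a bulk supercell that lie within `radius` of the
#' carving centre, then removes dangling oxygen atoms left with no titanium
#' neighbour.  The carve is deterministic given the centre; a coordination
#' census of the carved particle is attached as `$census`.
#'
#' @param phase `"anatase"` or `"rutile"`.
#' @param radius Particle radius, angstrom (>= 8).
#' @param center_mode `"ti_site"` (default; a titanium lattice site),
#'   `"origin"` (the cell origin, also a Ti site in both phases, kept for
#'   explicitness), or a numeric length-3 cartesian point in angstrom
#'   expressed in the conventional-cell frame.
#' @param box_edge Edge of the cubic box the particle is centred in,
#'   angstrom; default `2 * radius + 40`.
#' @param cutoff Ti-O bond cutoff used for the dangling-oxygen sweep and the
#'   census, angstrom.
#' @return A `tio2_np`/`tio2_model` object with fields `radius`, `center`
#'   (box frame) and `census` (a [compute_coordination()] report).
#' @examples
#' np <- carve_nanoparticle("anatase", 9)
#' @export
carve_nanoparticle <- function(phase, radius, center_mode = "ti_site",
                               box_edge = NULL, cutoff = 2.6) {
  if (radius < 8) stop("radius must be >= 8 angstrom", call. = FALSE)
  cell <- build_unit_cell(phase)
  center <- if (is.numeric(center_mode) && length(center_mode) == 3) {
    center_mode
  } else if (identical(center_mode, "ti_site") || identical(center_mode, "origin")) {
    c(0, 0, 0)  # (0,0,0) is a Ti site in both conventional cells
  } else {
    stop("center_mode must be \"ti_site\", \"origin\" or a length-3 numeric",
         call. = FALSE)
  }
  nra <- ceiling((radius + max(abs(center)) + 2) / cell$a)
  nrc <- ceiling((radius + max(abs(center)) + 2) / cell$c)
  g <- as.matrix(expand.grid(-nra:nra, -nra:nra, -nrc:nrc))
  b <- as.matrix(cell$basis[, c("fx", "fy", "fz")])
  frac <- do.call(rbind, lapply(seq_len(nrow(b)), function(i) sweep(g, 2, b[i, ], "+")))
  el <- rep(cell$basis$element, each = nrow(g))
  xyz <- sweep(frac, 2, c(cell$a, cell$a, cell$c), "*")
  r <- sqrt(rowSums(sweep(xyz, 2, center, "-")^2))
  keep <- r <= radius
  xyz <- xyz[keep, , drop = FALSE]; el <- el[keep]
  if (!any(el == "Ti")) {
    stop("radius too small: no titanium atom survives the carve", call. = FALSE)
  }
  # drop O with no Ti neighbour
  per <- c(FALSE, FALSE, FALSE)
  box <- rep(2 * radius + 10, 3)
  is_o <- el == "O"
  oc <- count_within(xyz[is_o, , drop = FALSE], xyz[!is_o, , drop = FALSE],
                     box, per, cutoff)
  drop <- which(is_o)[oc == 0]
  if (length(drop)) { xyz <- xyz[-drop, , drop = FALSE]; el <- el[-drop] }
  edge <- box_edge %||% (2 * radius + 40)
  shift <- edge / 2 - center
  atoms <- data.frame(element = el,
                      x = xyz[, 1] + shift[1], y = xyz[, 2] + shift[2],
                      z = xyz[, 3] + shift[3],
                      hydroxyl = FALSE, stringsAsFactors = FALSE)
  np <- new_tio2_model(
    atoms = atoms, box = rep(edge, 3), periodic = c(FALSE, FALSE, FALSE),
    phase = phase, subclass = "tio2_np",
    radius = radius, center = rep(edge / 2, 3))
  np$census <- compute_coordination(np, cutoff)
  np
}
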