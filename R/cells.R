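#' Conventional TiO2 unit cells
#'
#' Returns the conventional tetragonal cell of an anatase (I4\eqn{_1}/amd,
#' 4 Ti + 8 O) or rutile (P4\eqn{_2}/mnm, 2 Ti + 4 O) TiO2 polymorph with
#' standard experimental lattice constants: anatase a = 3.784, c = 9.515;
#' rutile a = 4.593, c = 2.959 angstrom.
#'
#' @param phase `"anatase"` or `"rutile"`.
#' @return An object of class `tio2_cell`: a list with elements `phase`,
#'   `a`, `c` (lattice lengths, angstrom), and `basis`, a data frame of
#'   `element` ("Ti"/"O") and fractional coordinates `fx`, `fy`, `fz` in
#'   `[0, 1)`.
#' @examples
#' build_unit_cell("anatase")
#' @export
build_unit_cell <- function(phase = c("anatase", "rutile")) {
  if (!is.character(phase) || length(phase) != 1 ||
      !phase %in% c("anatase", "rutile")) {
    stop("unknown TiO2 phase: must be \"anatase\" or \"rutile\"",
         call. = FALSE)
  }
  if (phase == "anatase") {
    a <- 3.784; cc <- 9.515
    u <- 0.2081  # apical oxygen parameter
    ti <- rbind(c(0, 0, 0), c(0, 0.5, 0.25), c(0.5, 0.5, 0.5), c(0.5, 0, 0.75))
    ox <- rbind(sweep(ti, 2, c(0, 0, u), "+"),
                sweep(ti, 2, c(0, 0, u), "-")) %% 1
  } else {
    a <- 4.593; cc <- 2.959
    u <- 0.305
    ti <- rbind(c(0, 0, 0), c(0.5, 0.5, 0.5))
    ox <- rbind(c(u, u, 0), c(-u, -u, 0),
                c(0.5 + u, 0.5 - u, 0.5), c(0.5 - u, 0.5 + u, 0.5)) %% 1
  }
  basis <- data.frame(
    element = c(rep("Ti", nrow(ti)), rep("O", nrow(ox))),
    fx = c(ti[, 1], ox[, 1]), fy = c(ti[, 2], ox[, 2]),
    fz = c(ti[, 3], ox[, 3]),
    stringsAsFactors = FALSE
  )
  structure(list(phase = phase, a = a, c = cc, basis = basis),
            class = "tio2_cell")
}

#' @export
print.tio2_cell <- function(x, ...) {
  cat(sprintf("TiO2 %s conventional cell: a = %.3f A, c = %.3f A, %d Ti + %d O\n",
              x$phase, x$a, x$c,
              sum(x$basis$element == "Ti"), sum(x$basis$element == "O")))
  invisible(x)
}

#' Replicate a unit cell into a fully periodic bulk supercell
#'
#' @param cell A [build_unit_cell()] result.
#' @param nx,ny,nz Replication counts along the three cell vectors.
#' @return A `tio2_bulk`/`tio2_model` object: atoms in cartesian angstrom with
#'   an orthorhombic box periodic in all three dimensions.
#' @examples
#' bulk <- replicate_cell(build_unit_cell("rutile"), 2, 2, 2)
#' @export
replicate_cell <- function(cell, nx = 1L, ny = 1L, nz = 1L) {
  stopifnot(inherits(cell, "tio2_cell"), nx >= 1, ny >= 1, nz >= 1)
  g <- as.matrix(expand.grid(0:(nx - 1), 0:(ny - 1), 0:(nz - 1)))
  b <- as.matrix(cell$basis[, c("fx", "fy", "fz")])
  frac <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) sweep(b, 2, g[i, ], "+")))
  el <- rep(cell$basis$element, nrow(g))
  L <- c(cell$a * nx, cell$a * ny, cell$c * nz)
  xyz <- sweep(frac, 2, c(cell$a, cell$a, cell$c), "*")
  new_tio2_model(
    atoms = data.frame(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       hydroxyl = FALSE, stringsAsFactors = FALSE),
    box = L, periodic = c(TRUE, TRUE, TRUE),
    phase = cell$phase, subclass = "tio2_bulk")
}

# shared constructor for structural models
new_tio2_model <- function(atoms, box, periodic, phase, subclass, ...) {
  obj <- c(list(atoms = atoms, box = box, periodic = periodic, phase = phase),
           list(...))
  class(obj) <- c(subclass, "tio2_model")
  obj
}

#' @export
print.tio2_model <- function(x, ...) {
  nti <- sum(x$atoms$element == "Ti")
  nox <- sum(x$atoms$element == "O" & !x$atoms$hydroxyl)
  noh <- sum(x$atoms$hydroxyl)
  cat(sprintf("TiO2 %s model (%s): %d atoms (%d Ti, %d lattice O%s)\n",
              x$phase, class(x)[1], nrow(x$atoms), nti, nox,
              if (noh) sprintf(", %d hydroxyl atoms", noh) else ""))
  cat(sprintf("  box: %.2f x %.2f x %.2f A, periodic: %s\n",
              x$box[1], x$box[2], x$box[3],
              paste(c("x", "y", "z")[x$periodic], collapse = ",")))
  invisible(x)
}
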