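# Structure and trajectory I/O.
#
# Internal coordinates are angstrom; the .gro dialect stores nm and PDB
# stores angstrom, conversion is handled per dialect.  Hydroxyl atoms are
# written with the reserved residue name "OHX" so the hydroxyl-exclusion
# rule survives serialization; TiO2 lattice atoms use "TIO".

# coordinate (or coordinate+velocity) field width of a .gro atom line:
# the tail after the fixed 20-character prefix splits into 3 or 6 equal
# fields of width >= 8
gro_field_width <- function(line, n_fields = 3L) {
  w <- (nchar(line) - 20L) %/% n_fields
  if (w < 8L) {
    stop("malformed .gro record: coordinate fields too narrow", call. = FALSE)
  }
  w
}

# normalize any structural object to a flat atom table + box
as_atom_table <- function(x) {
  if (inherits(x, "tio2_system")) {
    list(atoms = x$atoms, box = x$box)
  } else if (inherits(x, "tio2_model")) {
    at <- x$atoms
    list(atoms = data.frame(element = at$element, name = at$element,
                            resname = ifelse(at$hydroxyl, "OHX", "TIO"),
                            resid = 1L, x = at$x, y = at$y, z = at$z,
                            hydroxyl = at$hydroxyl, stringsAsFactors = FALSE),
         box = x$box)
  } else if (inherits(x, "tio2_structure")) {
    list(atoms = x$atoms, box = x$box)
  } else stop("cannot interpret object as a structure", call. = FALSE)
}

element_from_name <- function(name) {
  base <- sub("[0-9']+.*$", "", name)
  ifelse(base %in% c("Ti", "TI"), "Ti",
  ifelse(base %in% c("Na", "NA"), "Na",
  ifelse(base %in% c("Cl", "CL"), "Cl",
  ifelse(base == "OW", "O", substr(base, 1, 1)))))
}

#' Write a structure in the GROMACS .gro dialect
#'
#' @param x Atom table (data frame with `name`, `resname`, `resid`, `x`,
#'   `y`, `z` in angstrom) or any `tio2_model`/`tio2_system`.
#' @param box Box vectors in angstrom (ignored when `x` carries its own).
#' @param path Output file.
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(x, box = NULL, path, title = "titania structure") {
  if (is.data.frame(x)) {
    at <- x
    stopifnot(!is.null(box))
  } else {
    tab <- as_atom_table(x)
    at <- tab$atoms; box <- tab$box
  }
  n <- nrow(at)
  lines <- character(n + 3)
  lines[1] <- title
  lines[2] <- sprintf("%d", n)
  if (n > 0) {
    # 4-decimal coordinate fields (the .gro dialect admits any precision
    # with field width = decimals + 5)
    lines[3:(n + 2)] <- sprintf("%5d%-5s%5s%5d%9.4f%9.4f%9.4f",
                                at$resid %% 100000L,
                                substr(at$resname, 1, 5),
                                substr(at$name, 1, 5),
                                seq_len(n) %% 100000L,
                                at$x / 10, at$y / 10, at$z / 10)
  }
  lines[n + 3] <- sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10, box[3] / 10)
  writeLines(lines, path)
  invisible(path)
}

#' Read a .gro structure
#'
#' @param path File path.
#' @return A `tio2_structure`: list with `atoms` (element, name, resname,
#'   resid, x/y/z angstrom, hydroxyl flag recovered from the `OHX` residue),
#'   `box` (angstrom), `periodic`, `dialect`.
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) {
    stop(sprintf("malformed .gro file %s: fewer than 3 lines", path), call. = FALSE)
  }
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 0) {
    stop(sprintf("malformed .gro file %s at line 2: bad atom count", path),
         call. = FALSE)
  }
  if (length(lines) < n + 3) {
    stop(sprintf("truncated .gro file %s: expected %d atom lines, file ends at line %d",
                 path, n, length(lines)), call. = FALSE)
  }
  al <- lines[seq_len(n) + 2L]
  parse_num <- function(s, what, lineno) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("malformed .gro record at line %d: bad %s", lineno[bad[1]], what),
           call. = FALSE)
    }
    v
  }
  linenos <- seq_len(n) + 2L
  resid <- parse_num(substr(al, 1, 5), "residue number", linenos)
  resname <- trimws(substr(al, 6, 10))
  name <- trimws(substr(al, 11, 15))
  w <- gro_field_width(al[1], 3L)
  x <- parse_num(substr(al, 21, 20 + w), "x coordinate", linenos) * 10
  y <- parse_num(substr(al, 21 + w, 20 + 2 * w), "y coordinate", linenos) * 10
  z <- parse_num(substr(al, 21 + 2 * w, 20 + 3 * w), "z coordinate", linenos) * 10
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]]))
  if (length(boxv) < 3 || anyNA(boxv[1:3])) {
    stop(sprintf("malformed .gro box record at line %d", n + 3), call. = FALSE)
  }
  atoms <- data.frame(element = element_from_name(name), name = name,
                      resname = resname, resid = as.integer(resid),
                      x = x, y = y, z = z,
                      hydroxyl = resname == "OHX", stringsAsFactors = FALSE)
  structure(list(atoms = atoms, box = boxv[1:3] * 10,
                 periodic = c(TRUE, TRUE, TRUE), dialect = "gro"),
            class = c("tio2_structure"))
}

#' Write a structure in PDB format
#'
#' ATOM records plus a CRYST1 box record; coordinates in angstrom.  (PDB
#' reading goes through bio3d; writing is done directly because the box
#' record must round-trip.)
#'
#' @inheritParams write_gro
#' @export
write_pdb <- function(x, box = NULL, path, title = "titania structure") {
  if (is.data.frame(x)) {
    at <- x; stopifnot(!is.null(box))
  } else {
    tab <- as_atom_table(x); at <- tab$atoms; box <- tab$box
  }
  n <- nrow(at)
  out <- c(sprintf("TITLE     %s", title),
           sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   box[1], box[2], box[3], 90, 90, 90))
  if (n > 0) {
    el <- if (!is.null(at$element)) at$element else element_from_name(at$name)
    out <- c(out, sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(n) %% 100000L, substr(at$name, 1, 4), substr(at$resname, 1, 3),
      at$resid %% 10000L, at$x, at$y, at$z, toupper(el)))
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Read a PDB structure (via bio3d)
#'
#' @param path File path.
#' @return A `tio2_structure` (see [read_gro()]); box from the CRYST1
#'   record, `NA` if absent.
#' @export
read_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  name <- trimws(a$elety)
  resname <- trimws(a$resid)
  el <- trimws(a$elesy)
  el <- ifelse(is.na(el) | el == "", element_from_name(name),
               paste0(substr(el, 1, 1), tolower(substr(el, 2, 2))))
  box <- rep(NA_real_, 3)
  cl <- grep("^CRYST1", readLines(path), value = TRUE)
  if (length(cl)) {
    box <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                        substr(cl[1], 25, 33)))
  }
  atoms <- data.frame(element = el, name = name, resname = resname,
                      resid = as.integer(a$resno),
                      x = a$x, y = a$y, z = a$z,
                      hydroxyl = resname == "OHX", stringsAsFactors = FALSE)
  structure(list(atoms = atoms, box = box,
                 periodic = c(TRUE, TRUE, TRUE), dialect = "pdb"),
            class = c("tio2_structure"))
}

#' Write a structure, dialect chosen by extension
#'
#' @param x A `tio2_model`, `tio2_system` or atom table.
#' @param path Output path; `.gro` or `.pdb`.
#' @param dialect `"auto"` (default, from extension), `"gro"` or `"pdb"`.
#' @param box Box override in angstrom (for plain atom tables).
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, dialect = c("auto", "gro", "pdb"),
                            box = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- switch(tolower(tools::file_ext(path)),
                      gro = "gro", pdb = "pdb",
                      stop("cannot infer dialect from extension; pass dialect=",
                           call. = FALSE))
  }
  if (dialect == "gro") write_gro(x, box, path) else write_pdb(x, box, path)
}

#' Read a structure, dialect chosen by extension
#'
#' @param path File path (`.gro` or `.pdb`).
#' @param dialect `"auto"`, `"gro"` or `"pdb"`.
#' @return A `tio2_structure`.
#' @export
read_structure <- function(path, dialect = c("auto", "gro", "pdb")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- switch(tolower(tools::file_ext(path)),
                      gro = "gro", pdb = "pdb",
                      stop("cannot infer dialect from extension; pass dialect=",
                           call. = FALSE))
  }
  if (dialect == "gro") read_gro(path) else read_pdb(path)
}

#' @export
print.tio2_structure <- function(x, ...) {
  cat(sprintf("structure (%s): %d atoms, %d residues, box %.2f x %.2f x %.2f A\n",
              x$dialect, nrow(x$atoms), length(unique(x$atoms$resid)),
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Write a multi-frame .gro trajectory
#'
#' @param frames List of coordinate matrices (angstrom), one row per atom.
#' @param atoms Atom table matching the frames.
#' @param box Box, angstrom.
#' @param path Output file.
#' @param frame_interval_ps Frame spacing recorded in the title lines.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, atoms, box, path, frame_interval_ps = 5) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(atoms)
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    stopifnot(nrow(fr) == n)
    writeLines(c(sprintf("frame %d t= %.3f ps", i, (i - 1) * frame_interval_ps),
                 sprintf("%d", n),
                 sprintf("%5d%-5s%5s%5d%9.4f%9.4f%9.4f",
                         atoms$resid %% 100000L, substr(atoms$resname, 1, 5),
                         substr(atoms$name, 1, 5), seq_len(n) %% 100000L,
                         fr[, 1] / 10, fr[, 2] / 10, fr[, 3] / 10),
                 sprintf("%10.5f%10.5f%10.5f",
                         box[1] / 10, box[2] / 10, box[3] / 10)),
               con)
  }
  invisible(path)
}

#' Open a trajectory for streaming frame-by-frame reading
#'
#' Frames are parsed one at a time from an open connection, so peak memory
#' is independent of trajectory length.
#'
#' @param path A multi-frame `.gro` trajectory.
#' @param structure The matching structure; every frame must have the same
#'   atom count.
#' @return A `trajectory_reader`: list with `next_frame()` (returns an
#'   n x 3 coordinate matrix in angstrom, or `NULL` at end of file),
#'   `close()`, `n_atoms`, `frame_interval_ps` (from the title lines when
#'   present).
#' @export
read_trajectory <- function(path, structure) {
  n_ref <- nrow(structure$atoms)
  con <- file(path, "r")
  env <- new.env(parent = emptyenv())
  env$open <- TRUE
  env$dt <- NA_real_
  env$times <- numeric(0)
  next_frame <- function() {
    if (!env$open) return(NULL)
    title <- readLines(con, n = 1)
    if (length(title) == 0) { close(con); env$open <- FALSE; return(NULL) }
    cnt_line <- readLines(con, n = 1)
    n <- suppressWarnings(as.integer(trimws(cnt_line)))
    if (is.na(n)) stop("malformed trajectory frame: bad atom count", call. = FALSE)
    if (n != n_ref) {
      stop(sprintf("trajectory frame has %d atoms but structure has %d", n, n_ref),
           call. = FALSE)
    }
    body <- readLines(con, n = n + 1)
    if (length(body) < n + 1) stop("truncated trajectory frame", call. = FALSE)
    al <- body[seq_len(n)]
    w <- gro_field_width(al[1], 3L)
    m <- cbind(as.numeric(substr(al, 21, 20 + w)),
               as.numeric(substr(al, 21 + w, 20 + 2 * w)),
               as.numeric(substr(al, 21 + 2 * w, 20 + 3 * w))) * 10
    if (anyNA(m)) stop("malformed coordinate record in trajectory", call. = FALSE)
    tm <- regmatches(title, regexpr("t= *[-0-9.eE+]+", title))
    if (length(tm)) {
      t_ps <- as.numeric(sub("t= *", "", tm))
      env$times <- c(utils::tail(env$times, 1), t_ps)
      if (length(env$times) == 2) env$dt <- diff(env$times)
    }
    m
  }
  structure(list(next_frame = next_frame,
                 close = function() if (env$open) { close(con); env$open <- FALSE },
                 n_atoms = n_ref,
                 frame_interval_ps = 5),
            class = "trajectory_reader")
}

#' Read all frames of a trajectory into a list
#'
#' @param reader A [read_trajectory()] reader (or a path plus `structure`).
#' @param structure Needed when `reader` is a path.
#' @return List of coordinate matrices, angstrom.
#' @export
collect_frames <- function(reader, structure = NULL) {
  if (is.character(reader)) reader <- read_trajectory(reader, structure)
  frames <- list()
  repeat {
    fr <- reader$next_frame()
    if (is.null(fr)) break
    frames[[length(frames) + 1L]] <- fr
  }
  frames
}

#' Serialize a hydroxylation plan to JSON
#' @param plan A [plan_hydroxylation()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "hydroxylation_plan"))
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a hydroxylation plan from JSON
#' @param path File path.
#' @return A `hydroxylation_plan`.
#' @export
read_plan <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$ti5_selected <- as.integer(p$ti5_selected)
  p$ti4_selected <- as.integer(p$ti4_selected)
  structure(p, class = "hydroxylation_plan")
}

#' Write a distance series as headered TSV
#'
#' @param series A `distance_series`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_distance_series <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# frame_interval_ps\t%g", series$frame_interval_ps),
               sprintf("# lipid_id\t%s", paste(series$lipid_id, collapse = ",")),
               sprintf("# atom_name\t%s", paste(series$atom_name, collapse = ","))),
             con)
  utils::write.table(series$dist, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a distance series written by [write_distance_series()]
#' @param path File path.
#' @return A `distance_series`.
#' @export
read_distance_series <- function(path) {
  hdr <- readLines(path, n = 3)
  meta <- strsplit(sub("^# ", "", hdr), "\t")
  stopifnot(length(meta) == 3)
  fi <- as.numeric(meta[[1]][2])
  lid <- as.integer(strsplit(meta[[2]][2], ",")[[1]])
  an <- strsplit(meta[[3]][2], ",")[[1]]
  d <- as.matrix(utils::read.table(path, sep = "\t", skip = 3))
  dimnames(d) <- NULL
  if (nrow(d) == 0) d <- matrix(numeric(0), 0, length(lid))
  distance_series(d, lid, an, fi)
}
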