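#' Composition rule for simulated lipid/TiO2 systems
#'
#' Bundles the conventions used to size a simulated system: the area per
#' lipid in a bilayer leaflet, the target salt concentration, and the molar
#' reference concentration of water.
#'
#' @param area_per_lipid Area per lipid, nm^2 (default 0.6).
#' @param salt_conc NaCl concentration, mol/L (default 0.15).
#' @param water_molarity_ref Molar concentration of pure water, mol/L
#'   (default 55.5).
#' @return A `composition_rule` list.
#' @export
composition_rule <- function(area_per_lipid = 0.6, salt_conc = 0.15,
                             water_molarity_ref = 55.5) {
  if (area_per_lipid <= 0) stop("area_per_lipid must be > 0", call. = FALSE)
  if (salt_conc < 0) stop("salt_conc must be >= 0", call. = FALSE)
  structure(list(area_per_lipid = area_per_lipid, salt_conc = salt_conc,
                 water_molarity_ref = water_molarity_ref,
                 coverage_mode = "half-surface-bilayer"),
            class = "composition_rule")
}

#' Number of lipids for half-coverage bilayer arrangement
#'
#' The lipid count is chosen so that about half of the surface would be
#' occupied by a bilayer adsorbed via its headgroups:
#' `round(0.5 * face_area * 2 / area_per_lipid)`; the half-coverage factor
#' and the two leaflets cancel, leaving `round(face_area / area_per_lipid)`
#' with half-away-from-zero rounding.
#'
#' @param face_area_nm2 Lateral area of one face, nm^2.
#' @param rule A [composition_rule()].
#' @return Integer lipid count.
#' @examples
#' lipid_count(7.10 * 7.15)  # rutile(110) face
#' @export
lipid_count <- function(face_area_nm2, rule = composition_rule()) {
  if (face_area_nm2 <= 0) stop("face_area_nm2 must be > 0", call. = FALSE)
  as.integer(round_half_up(face_area_nm2 / rule$area_per_lipid))
}

#' Sodium and chloride counts for a charged, salted system
#'
#' Chloride provides the bulk salt concentration,
#' `n_cl = round(salt_conc * n_water / water_molarity_ref)`; sodium adds the
#' excess cations that neutralize the negative surface,
#' `n_na = n_cl + round(|total_surface_charge|)`.
#'
#' @param n_water Number of water molecules (> 0).
#' @param rule A [composition_rule()].
#' @param total_surface_charge_e Net surface charge, elementary charges
#'   (typically negative).
#' @return Named integer vector `c(n_na, n_cl)`.
#' @examples
#' ion_counts(11785, total_surface_charge_e = -60.7)
#' @export
ion_counts <- function(n_water, rule = composition_rule(),
                       total_surface_charge_e = 0) {
  if (n_water <= 0) stop("n_water must be > 0", call. = FALSE)
  n_cl <- as.integer(round_half_up(rule$salt_conc * n_water / rule$water_molarity_ref))
  n_na <- n_cl + as.integer(round_half_up(abs(total_surface_charge_e)))
  c(n_na = n_na, n_cl = n_cl)
}

#' System composition record
#'
#' @param lipid_species `"POPE"` or `"DMPC"`.
#' @param n_lipids Number of phospholipids.
#' @param n_cholesterol Number of cholesterol molecules.
#' @param n_water Number of waters, or `NA` to fill at bulk density during
#'   assembly and count the result.
#' @param n_na,n_cl Ion counts, or `NA` to derive from [ion_counts()] at
#'   assembly time.
#' @param box_nm Box vectors in nm (length 3), or `NULL` to size from the
#'   surface model during assembly.
#' @return A `system_composition` list.
#' @export
system_composition <- function(lipid_species = c("POPE", "DMPC"),
                               n_lipids, n_cholesterol = 0L,
                               n_water = NA_integer_,
                               n_na = NA_integer_, n_cl = NA_integer_,
                               box_nm = NULL) {
  lipid_species <- match.arg(lipid_species)
  stopifnot(n_lipids >= 0, n_cholesterol >= 0)
  structure(list(lipid_species = lipid_species,
                 n_lipids = as.integer(n_lipids),
                 n_cholesterol = as.integer(n_cholesterol),
                 n_water = n_water, n_na = n_na, n_cl = n_cl,
                 box_nm = box_nm),
            class = "system_composition")
}

# ---- idealized rigid lipid templates (extended conformers, angstrom) -------
# Headgroup atom names follow the usual phospholipid convention: P, O13, O14
# (anionic phosphate oxygens), N (amine/choline nitrogen), C13/C14/C15
# (choline methyls), O32 (sn-2 carbonyl oxygen of the glycerol moiety).
lipid_template <- function(species = c("POPE", "DMPC", "CHOL")) {
  species <- match.arg(species)
  chain <- function(x0, n) {
    data.frame(name = paste0("C2", seq_len(n) + 1),
               element = "C",
               x = x0 + 0.4 * (seq_len(n) %% 2), y = 0,
               z = -seq_len(n) * 1.27, stringsAsFactors = FALSE)
  }
  if (species == "CHOL") {
    ang <- seq(0, 2 * pi, length.out = 9)[-9]
    df <- rbind(
      data.frame(name = "O3", element = "O", x = 0, y = 0, z = 0,
                 stringsAsFactors = FALSE),
      data.frame(name = paste0("C", 1:8), element = "C",
                 x = 1.6 * cos(ang), y = 1.6 * sin(ang), z = -2 - 1.1 * (1:8) / 3,
                 stringsAsFactors = FALSE),
      data.frame(name = paste0("C1", 1:6), element = "C",
                 x = 0.3, y = 0, z = -6 - 1.27 * (1:6), stringsAsFactors = FALSE))
    df$resname <- "CHOL"
    return(df)
  }
  head <- if (species == "POPE") {
    data.frame(
      name = c("N", "C12", "C11", "P", "O13", "O14", "O11", "O12"),
      element = c("N", "C", "C", "P", "O", "O", "O", "O"),
      x = c(0, 0.8, 0.4, 0, -1.2, 1.2, -0.6, 0.6),
      y = c(0, 0.9, -0.9, 0, 0.6, 0.6, -1.1, -1.1),
      z = c(3.2, 2.4, 1.4, 0.0, 0.6, 0.6, -0.9, -0.9),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      name = c("N", "C13", "C14", "C15", "C12", "C11", "P", "O13", "O14",
               "O11", "O12"),
      element = c("N", "C", "C", "C", "C", "C", "P", "O", "O", "O", "O"),
      x = c(0, 1.3, -1.3, 0, 0.8, 0.4, 0, -1.2, 1.2, -0.6, 0.6),
      y = c(0, 0.5, 0.5, -1.4, 0.9, -0.9, 0, 0.6, 0.6, -1.1, -1.1),
      z = c(3.6, 4.4, 4.4, 4.1, 2.6, 1.4, 0.0, 0.6, 0.6, -0.9, -0.9),
      stringsAsFactors = FALSE)
  }
  glyc <- data.frame(
    name = c("C1", "C2", "C3", "O31", "C31", "O32"),
    element = c("C", "C", "C", "O", "C", "O"),
    x = c(0, 0.9, 0.2, 1.9, 2.4, 3.5),
    y = c(0.2, -0.4, -1.6, -0.4, -1.2, -1.3),
    z = c(-2.2, -3.3, -4.0, -3.9, -4.8, -4.5),
    stringsAsFactors = FALSE)
  n_tail <- if (species == "POPE") 16 else 13
  t1 <- chain(-0.7, n_tail); t1$z <- t1$z - 4.5
  t2 <- chain(2.6, n_tail - 1); t2$z <- t2$z - 5.2
  t2$name <- sub("C2", "C3", t2$name)
  df <- rbind(head, glyc, t1, t2)
  df$resname <- species
  df
}

# TRUE when a rigid molecule touches its own periodic image: some atom pair
# comes within min_sep through lateral wrapping while being farther apart
# directly (direct intramolecular distances are bonded geometry, not
# clashes)
self_image_clash <- function(cand, box, periodic, min_sep) {
  n <- nrow(cand)
  if (n < 2) return(FALSE)
  reachable <- any(vapply(which(periodic), function(k)
    diff(range(cand[, k])) >= box[k] - min_sep, logical(1)))
  if (!reachable) return(FALSE)
  d_dir <- as.matrix(stats::dist(cand))
  d2 <- matrix(0, n, n)
  for (j in 1:3) {
    dd <- outer(cand[, j], cand[, j], "-")
    if (periodic[j]) dd <- min_image(dd, box[j])
    d2 <- d2 + dd * dd
  }
  d_mi <- sqrt(d2)
  any(d_mi < min_sep & d_mi < d_dir - 1e-6)
}

#' Assemble an initial configuration of lipids, water and ions near a surface
#'
#' Places rigid lipid templates at random unoccupied positions in random
#' orientations (above the upper face only in `"single-side"` mode), fills
#' the remaining box volume with water sites on a bulk-density grid, counts
#' the waters, and substitutes random waters by Na+/Cl- ions per
#' [ion_counts()] so the final system balances the surface charge at the
#' requested salt concentration.
#'
#' @param model A (typically hydroxylated) `tio2_slab` or `tio2_np`.
#' @param composition A [system_composition()].
#' @param seed Integer seed; recorded on the result.
#' @param rule A [composition_rule()].
#' @param mode `"single-side"` (lipids above the top face only) or
#'   `"both-sides"`.
#' @param min_sep Minimum allowed heavy-atom separation when inserting a
#'   molecule, angstrom (default 2.0).
#' @param lipid_region Height of the lipid insertion region above the face,
#'   angstrom (default 40, matching a bilayer leaflet plus headgroup).
#' @param hydration Hydration-layer padding used when auto-sizing the box,
#'   angstrom (default 10).
#' @param max_attempts Insertion attempts per molecule before giving up.
#' @return A `tio2_system`: list with `atoms` (element, name, resname, resid,
#'   x/y/z angstrom, hydroxyl), `box`, `periodic`, `composition` (with
#'   realized `n_water`, `n_na`, `n_cl`), `seed`, `net_charge_e`.
#' @export
assemble_initial_state <- function(model, composition, seed = 1L,
                                   rule = composition_rule(),
                                   mode = c("single-side", "both-sides"),
                                   min_sep = 2.0, lipid_region = 40,
                                   hydration = 10, max_attempts = 10000L) {
  stopifnot(inherits(model, "tio2_model"),
            inherits(composition, "system_composition"))
  mode <- match.arg(mode)
  is_np <- inherits(model, "tio2_np")
  at <- model$atoms
  box <- model$box
  if (!is.null(composition$box_nm)) {
    box <- composition$box_nm * 10
  } else if (!is_np) {
    # sizing recipe: slab extent (incl. hydroxyls) + 2 x lipid region +
    # 2 x hydration
    box[3] <- diff(range(at$z)) + 2 * lipid_region + 2 * hydration
  }
  if (!is_np) {
    z_top_req <- max(at$z) - min(at$z) + 2 * lipid_region + 2 * hydration
    if (box[3] < z_top_req - 1e-6) {
      stop(sprintf("box height %.1f A too small: need >= slab + 2 x %g A lipids + 2 x %g A hydration = %.1f A",
                   box[3], lipid_region, hydration, z_top_req), call. = FALSE)
    }
    # centre the slab vertically in the (possibly re-sized) box
    at$z <- at$z - (min(at$z) + max(at$z)) / 2 + box[3] / 2
  }
  z_top <- if (is_np) NA_real_ else max(at$z)

  sys_at <- data.frame(element = at$element, name = at$element,
                       resname = ifelse(at$hydroxyl, "OHX", "TIO"),
                       resid = 1L, x = at$x, y = at$y, z = at$z,
                       hydroxyl = at$hydroxyl, stringsAsFactors = FALSE)
  xyz <- as.matrix(sys_at[, c("x", "y", "z")])
  periodic <- if (is_np) c(TRUE, TRUE, TRUE) else c(TRUE, TRUE, FALSE)

  mols <- c(rep(composition$lipid_species, composition$n_lipids),
            rep("CHOL", composition$n_cholesterol))
  resid <- 1L
  placed <- list()
  with_seed(seed, {
    for (m in mols) {
      tpl <- lipid_template(m)
      txyz0 <- as.matrix(tpl[, c("x", "y", "z")])
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        q <- qr.Q(qr(matrix(rnorm(9), 3)))  # random orthogonal rotation
        if (det(q) < 0) q[, 1] <- -q[, 1]
        txyz <- txyz0 %*% t(q)
        if (is_np) {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          off <- model$center + (model$radius + 2 + runif(1, 0, 15)) * u
        } else {
          zlo <- z_top + 2
          zhi <- min(z_top + lipid_region, box[3] - 2)
          off <- c(runif(1, 0, box[1]), runif(1, 0, box[2]), runif(1, zlo, zhi))
          if (mode == "both-sides" && runif(1) < 0.5) {
            z_bot <- min(at$z)
            off[3] <- runif(1, max(2, z_bot - lipid_region), z_bot - 2)
          }
        }
        cand <- sweep(txyz, 2, off, "+")
        if (!is_np && (any(cand[, 3] < 1) || any(cand[, 3] > box[3] - 1))) next
        if (min(nearest_dist(cand, xyz, box, periodic)) >= min_sep &&
            !self_image_clash(cand, box, periodic, min_sep)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf("failed to insert %s molecule %d after %d attempts (%d molecules placed)",
                     m, resid, max_attempts, resid - 1L), call. = FALSE)
      }
      resid <- resid + 1L
      rows <- data.frame(element = tpl$element, name = tpl$name,
                         resname = tpl$resname, resid = resid,
                         x = cand[, 1], y = cand[, 2], z = cand[, 3],
                         hydroxyl = FALSE, stringsAsFactors = FALSE)
      placed[[length(placed) + 1L]] <- rows
      xyz <- rbind(xyz, cand)
    }

    # water grid at approximately bulk density (one site per ~30 A^3)
    sp <- 3.11
    gx <- seq(sp / 2, box[1] - sp / 2, by = sp)
    gy <- seq(sp / 2, box[2] - sp / 2, by = sp)
    gz <- seq(sp / 2, box[3] - sp / 2, by = sp)
    grid <- as.matrix(expand.grid(gx, gy, gz))
    free <- nearest_dist(grid, xyz, box, periodic, chunk = 100L) >= 2.8
    wpos <- grid[free, , drop = FALSE]
    n_water <- nrow(wpos)
    if (n_water == 0) stop("no room left for water in the box", call. = FALSE)

    q_surface <- if (!is.null(model$hydroxylation)) {
      model$hydroxylation$n_oh * model$hydroxylation$q_oh
    } else 0
    ions <- c(n_na = composition$n_na, n_cl = composition$n_cl)
    if (anyNA(ions)) ions <- ion_counts(n_water, rule, q_surface)
    n_ion <- sum(ions)
    if (n_ion > n_water) stop("more ions requested than waters available", call. = FALSE)
    ion_idx <- sample(n_water, n_ion)
    na_idx <- ion_idx[seq_len(ions["n_na"])]
    cl_idx <- setdiff(ion_idx, na_idx)
    keep_w <- setdiff(seq_len(n_water), ion_idx)

    mk <- function(idx, element, name, resname, r0) {
      if (length(idx) == 0) return(NULL)
      data.frame(element = element, name = name, resname = resname,
                 resid = r0 + seq_along(idx),
                 x = wpos[idx, 1], y = wpos[idx, 2], z = wpos[idx, 3],
                 hydroxyl = FALSE, stringsAsFactors = FALSE)
    }
    placed[[length(placed) + 1L]] <- mk(keep_w, "O", "OW", "SOL", resid)
    resid <- resid + length(keep_w)
    placed[[length(placed) + 1L]] <- mk(na_idx, "Na", "NA", "NA", resid)
    resid <- resid + length(na_idx)
    placed[[length(placed) + 1L]] <- mk(cl_idx, "Cl", "CL", "CL", resid)

    composition$n_water <- length(keep_w) + n_ion  # waters before substitution
    composition$n_na <- unname(ions["n_na"])
    composition$n_cl <- unname(ions["n_cl"])
    composition$box_nm <- box / 10

    structure(list(
      atoms = rbind(sys_at, do.call(rbind, placed)),
      box = box, periodic = periodic,
      composition = composition, seed = as.integer(seed),
      net_charge_e = q_surface + ions["n_na"] - ions["n_cl"]
    ), class = c("tio2_system"))
  })
}

#' @export
print.tio2_system <- function(x, ...) {
  cmp <- x$composition
  cat(sprintf("assembled system: %d %s + %d CHOL, %d waters, %d Na+ %d Cl- (net %+.2f e)\n",
              cmp$n_lipids, cmp$lipid_species, cmp$n_cholesterol,
              cmp$n_water, cmp$n_na, cmp$n_cl, x$net_charge_e))
  cat(sprintf("  box %.2f x %.2f x %.2f nm, %d atoms, seed %d\n",
              x$box[1] / 10, x$box[2] / 10, x$box[3] / 10, nrow(x$atoms), x$seed))
  invisible(x)
}
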