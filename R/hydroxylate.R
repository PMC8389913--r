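#' Plan surface hydroxylation from a coordination census
#'
#' Hydrated TiO2 surfaces at neutral pH carry hydroxyl groups and a negative
#' charge.  The model rule applied here hydroxylates a fixed fraction
#' (default 30%) of randomly picked 5-fold-coordinated Ti atoms, plus every
#' 4-fold-coordinated Ti atom (those are highly reactive).  The 5-fold count
#' is rounded down: `n_oh = floor(fraction * N_Ti(5)) + N_Ti(4)`.
#'
#' @param report A [compute_coordination()] or [coordination_counts()] report.
#' @param fraction Fraction of Ti(5) sites to hydroxylate, in `[0, 1]`.
#' @param seed Integer seed for the site selection (sampling is uniform,
#'   without replacement, via R's Mersenne-Twister generator; the seed is
#'   recorded on the plan).
#' @param q_oh Net charge attributed to one surface hydroxyl, in elementary
#'   charge units.  Default -0.40 e, the value consistent with reported
#'   surface charge densities of all four flat faces at 30% coverage.
#' @param exposed_area_nm2 Optional exposed area (slab: both faces; particle:
#'   4 pi R^2) in nm^2; when given, the resulting surface charge density
#'   `sigma` is stored on the plan.
#' @return A `hydroxylation_plan`: list with `target_fraction`, `seed`,
#'   `ti5_selected`, `ti4_selected`, `n_oh`, `q_oh`, `sigma` (e/nm^2 or `NA`).
#' @examples
#' plan_hydroxylation(coordination_counts(504, 0), seed = 1)
#' @export
plan_hydroxylation <- function(report, fraction = 0.30, seed = 1L,
                               q_oh = -0.40, exposed_area_nm2 = NULL) {
  stopifnot(inherits(report, "coordination_report"))
  if (fraction < 0 || fraction > 1) {
    stop("fraction must be in [0, 1]", call. = FALSE)
  }
  n5 <- length(report$ti5_indices)
  k <- floor(fraction * n5)
  ti5_sel <- if (k > 0) {
    with_seed(seed, sort(sample(report$ti5_indices, k, replace = FALSE)))
  } else integer(0)
  n_oh <- k + length(report$ti4_indices)
  sigma <- if (!is.null(exposed_area_nm2)) {
    n_oh * q_oh / exposed_area_nm2
  } else NA_real_
  structure(list(
    target_fraction = fraction, seed = as.integer(seed),
    ti5_selected = ti5_sel, ti4_selected = report$ti4_indices,
    n_oh = n_oh, q_oh = q_oh, sigma = sigma
  ), class = "hydroxylation_plan")
}

#' @export
print.hydroxylation_plan <- function(x, ...) {
  cat(sprintf("hydroxylation plan: %d OH (%d of Ti(5) at %.0f%%, %d Ti(4)); q_OH = %.2f e; seed %d\n",
              x$n_oh, length(x$ti5_selected), 100 * x$target_fraction,
              length(x$ti4_selected), x$q_oh, x$seed))
  if (!is.na(x$sigma)) cat(sprintf("  surface charge density: %.3f e/nm^2\n", x$sigma))
  invisible(x)
}

#' Surface charge density of a hydroxylation plan
#'
#' `sigma = n_oh * q_oh / exposed_area`, in e/nm^2.  For a slab the exposed
#' area is twice the lateral face area; for a spherical particle `4 pi R^2`.
#'
#' @param plan A [plan_hydroxylation()] result.
#' @param exposed_area_nm2 Exposed area in nm^2 (> 0).
#' @return Charge density, e/nm^2.
#' @export
surface_charge_density <- function(plan, exposed_area_nm2) {
  stopifnot(inherits(plan, "hydroxylation_plan"))
  if (!is.numeric(exposed_area_nm2) || exposed_area_nm2 <= 0) {
    stop("exposed_area_nm2 must be > 0", call. = FALSE)
  }
  plan$n_oh * plan$q_oh / exposed_area_nm2
}

#' Attach hydroxyl groups to a surface model
#'
#' Adds one O-H pair per Ti site selected in the plan.  The oxygen is placed
#' 1.9 A from the Ti along its vacant coordination direction (the outward
#' surface normal for a slab face, the outward radial direction for a
#' nanoparticle); the hydrogen 0.96 A beyond the oxygen along the same
#' direction.  If a placed atom would come within 1 A of an existing atom,
#' the direction is perturbed and the placement retried (up to 50 times).
#' Added atoms carry `hydroxyl = TRUE` so downstream surface-distance
#' calculations can exclude them.
#'
#' @param model A `tio2_slab` or `tio2_np`.
#' @param plan A [plan_hydroxylation()] result whose indices refer to rows of
#'   `model$atoms`.
#' @return The model with `2 * n_oh` additional atoms and the plan stored as
#'   `$hydroxylation`.
#' @examples
#' slab <- build_slab("anatase", "100", 2, 1, 2)
#' plan <- plan_hydroxylation(compute_coordination(slab), seed = 7)
#' attach_hydroxyls(slab, plan)
#' @export
attach_hydroxyls <- function(model, plan) {
  stopifnot(inherits(model, "tio2_model"), inherits(plan, "hydroxylation_plan"))
  sites <- c(plan$ti5_selected, plan$ti4_selected)
  if (length(sites) == 0) return(model)
  if (any(sites < 1 | sites > nrow(model$atoms)) ||
      any(model$atoms$element[sites] != "Ti")) {
    stop("plan indices do not name Ti atoms of this model", call. = FALSE)
  }
  at <- model$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  mid <- if (inherits(model, "tio2_np")) model$center else
    c(NA, NA, (max(at$z) + min(at$z)) / 2)
  new_rows <- vector("list", length(sites))
  for (i in seq_along(sites)) {
    p <- xyz[sites[i], ]
    dir0 <- if (inherits(model, "tio2_np")) {
      v <- p - mid
      v / sqrt(sum(v^2))
    } else {
      c(0, 0, if (p[3] >= mid[3]) 1 else -1)
    }
    placed <- FALSE
    dir <- dir0
    for (try in 0:50) {
      o_pos <- p + 1.9 * dir
      h_pos <- p + (1.9 + 0.96) * dir
      d_o <- nearest_dist(rbind(o_pos), xyz, model$box, model$periodic)
      d_h <- nearest_dist(rbind(h_pos), xyz, model$box, model$periodic)
      if (d_o >= 1.0 && d_h >= 1.0) { placed <- TRUE; break }
      # deterministic perturbation sequence derived from the plan seed
      dir <- with_seed(plan$seed + 1000L * sites[i] + try, {
        v <- dir0 + rnorm(3, sd = 0.25)
        v / sqrt(sum(v^2))
      })
    }
    if (!placed) {
      stop(sprintf("could not place hydroxyl at Ti index %d without overlap after 50 tries",
                   sites[i]), call. = FALSE)
    }
    new_rows[[i]] <- data.frame(
      element = c("O", "H"),
      x = c(o_pos[1], h_pos[1]), y = c(o_pos[2], h_pos[2]),
      z = c(o_pos[3], h_pos[3]),
      hydroxyl = TRUE, stringsAsFactors = FALSE)
    xyz <- rbind(xyz, o_pos, h_pos)
  }
  model$atoms <- rbind(at, do.call(rbind, new_rows))
  rownames(model$atoms) <- NULL
  model$hydroxylation <- plan
  model
}
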