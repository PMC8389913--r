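#' Census of Ti-O coordination
#'
#' Counts, for every titanium atom of a structural model, its oxygen
#' neighbours within a bond cutoff, using minimum-image distances along the
#' model's periodic dimensions only.  Hydroxyl atoms are excluded by default
#' so the census describes the surface before hydroxylation, which is how
#' undercoordinated-Ti populations are conventionally reported.
#'
#' @param model A `tio2_model` (slab, nanoparticle, or bulk).
#' @param cutoff Ti-O bond cutoff in angstrom, in (1.5, 3); the first
#'   coordination shell sits at 1.93-1.98 A and the second beyond 3.4 A, so
#'   any cutoff in the gap gives identical counts. Default 2.6.
#' @param include_hydroxyl Count hydroxyl oxygens as neighbours? Default
#'   `FALSE`.
#' @return A `coordination_report`: list with `neighbor_count` (named integer
#'   vector, names are Ti row indices into `model$atoms`), `ti5_indices` and
#'   `ti4_indices` (sorted ascending), `n_ti`, `cutoff`.
#' @examples
#' slab <- build_slab("anatase", "101", 2, 2, 2)
#' rep5 <- compute_coordination(slab)
#' length(rep5$ti5_indices)
#' @export
compute_coordination <- function(model, cutoff = 2.6, include_hydroxyl = FALSE) {
  stopifnot(inherits(model, "tio2_model"))
  if (cutoff <= 1.5 || cutoff >= 3.0) {
    stop("cutoff must lie in (1.5, 3.0) angstrom", call. = FALSE)
  }
  at <- model$atoms
  ti_idx <- which(at$element == "Ti" & !at$hydroxyl)
  if (length(ti_idx) == 0) stop("model contains no titanium", call. = FALSE)
  o_sel <- at$element == "O"
  if (!include_hydroxyl) o_sel <- o_sel & !at$hydroxyl
  o_idx <- which(o_sel)
  cnt <- count_within(as.matrix(at[ti_idx, c("x", "y", "z")]),
                      as.matrix(at[o_idx, c("x", "y", "z")]),
                      model$box, model$periodic, cutoff)
  names(cnt) <- ti_idx
  structure(list(
    neighbor_count = cnt,
    ti5_indices = sort(ti_idx[cnt == 5L]),
    ti4_indices = sort(ti_idx[cnt == 4L]),
    n_ti = length(ti_idx),
    cutoff = cutoff
  ), class = "coordination_report")
}

#' Construct a coordination report from known undercoordination counts
#'
#' Builds a minimal `coordination_report` from tabulated Ti(5)/Ti(4)
#' populations (e.g. a published census) so that downstream rules such as
#' [plan_hydroxylation()] can be applied without rebuilding the structure.
#'
#' @param n_ti5,n_ti4 Numbers of 5-fold and 4-fold coordinated Ti atoms.
#' @param n_ti Total Ti count (defaults to `n_ti5 + n_ti4`).
#' @param cutoff Nominal bond cutoff recorded on the report.
#' @return A `coordination_report` whose ti5/ti4 index lists are synthetic
#'   placeholders `1..n_ti5` and `n_ti5+1..n_ti5+n_ti4`.
#' @examples
#' coordination_counts(504, 0)
#' @export
coordination_counts <- function(n_ti5, n_ti4, n_ti = n_ti5 + n_ti4,
                                cutoff = 2.6) {
  stopifnot(n_ti5 >= 0, n_ti4 >= 0, n_ti >= n_ti5 + n_ti4)
  ti5 <- seq_len(n_ti5)
  ti4 <- if (n_ti4 > 0) n_ti5 + seq_len(n_ti4) else integer(0)
  cnt <- c(rep(5L, n_ti5), rep(4L, n_ti4), rep(6L, n_ti - n_ti5 - n_ti4))
  names(cnt) <- seq_len(n_ti)
  structure(list(neighbor_count = cnt, ti5_indices = ti5, ti4_indices = ti4,
                 n_ti = n_ti, cutoff = cutoff),
            class = "coordination_report")
}

#' @export
print.coordination_report <- function(x, ...) {
  tab <- table(x$neighbor_count)
  cat(sprintf("Ti-O coordination census (cutoff %.2f A): %d Ti\n",
              x$cutoff, x$n_ti))
  cat(sprintf("  N_Ti(5) = %d, N_Ti(4) = %d; full distribution: %s\n",
              length(x$ti5_indices), length(x$ti4_indices),
              paste(sprintf("%s:%d", names(tab), tab), collapse = " ")))
  invisible(x)
}
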