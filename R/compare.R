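#' Projection factors from the SPM plane to the isocenter plane
#'
#' The spot position monitor (SPM) sits upstream of the isocenter, so
#' coordinates it records are demagnified relative to the isocenter plane.
#' Projection multiplies each SPM coordinate by a fixed per-axis factor:
#' `x_iso = x_spm * f_x`, `y_iso = y_spm * f_y`. The defaults are the
#' clinical factors for the beamline geometry this package models.
#'
#' @param f_x,f_y Dimensionless positive projection factors.
#' @return An object of class `projection_factors`.
#' @export
#' @examples
#' project_to_iso(1, 1, projection_factors()) # c(1.696, 1.391)
projection_factors <- function(f_x = 1.696, f_y = 1.391) {
  .assert(is.numeric(f_x) && length(f_x) == 1L && is.finite(f_x) && f_x > 0, "f_x must be > 0")
  .assert(is.numeric(f_y) && length(f_y) == 1L && is.finite(f_y) && f_y > 0, "f_y must be > 0")
  structure(list(f_x = f_x, f_y = f_y), class = "projection_factors")
}

#' Project SPM-plane coordinates to the isocenter plane
#'
#' @param x_spm,y_spm Numeric vectors of SPM-plane coordinates (mm).
#' @param f A [projection_factors()] object.
#' @return A two-column `data.frame` with `x_iso`, `y_iso` (mm).
#' @export
project_to_iso <- function(x_spm, y_spm, f = projection_factors()) {
  .assert(inherits(f, "projection_factors"), "f must be projection_factors")
  .assert(all(is.finite(x_spm)) && all(is.finite(y_spm)), "coordinates must be finite")
  data.frame(x_iso = x_spm * f$f_x, y_iso = y_spm * f$f_y)
}

#' Synchronize a delivery session with its plan
#'
#' Pairs every logged spot with its planned counterpart strictly by position:
#' the i-th record of layer k pairs with the i-th planned spot of layer k
#' (both are stored in delivery order). Demand data records every planned
#' spot, so any count mismatch is a data-integrity failure and raises an
#' error rather than being repaired by nearest-neighbour matching. The
#' nominal energy label is taken from the plan, not the log.
#'
#' @param plan An [ion_plan()].
#' @param session A [delivery_session()] referencing `plan`.
#' @return A `data.frame` with one row per paired spot: `layer_index`,
#'   `spot_index`, `energy`, `room`, `date`, planned `x`, `y`, `meterset`,
#'   and delivered `x_spm`, `y_spm`, `mu`.
#' @export
match_spots <- function(plan, session) {
  .assert(inherits(plan, "ion_plan"), "plan must be an ion_plan")
  .assert(inherits(session, "delivery_session"), "session must be a delivery_session")
  .assert(identical(session$plan_id, plan$plan_id),
          "session references plan '%s', not '%s'", session$plan_id, plan$plan_id)
  nl <- length(plan$energies)
  .assert(length(session$energies) == nl,
          "layer-count mismatch: plan has %d layers, session has %d", nl, length(session$energies))
  planned <- plan$spots
  logged <- session$records
  out <- vector("list", nl)
  for (k in seq_len(nl)) {
    p <- planned[planned$layer_index == k, , drop = FALSE]
    l <- logged[logged$layer_index == k, , drop = FALSE]
    if (nrow(p) != nrow(l)) {
      .stop_fmt("synchronization error in layer %d: plan has %d spots, log has %d",
                k, nrow(p), nrow(l))
    }
    out[[k]] <- data.frame(
      layer_index = k, spot_index = seq_len(nrow(p)),
      energy = plan$energies[k], room = session$room, date = session$date,
      x = p$x, y = p$y, meterset = p$meterset,
      x_spm = l$x_spm, y_spm = l$y_spm, mu = l$mu
    )
  }
  do.call(rbind, out)
}

#' Spot-wise deviations between delivered and planned parameters
#'
#' Projects delivered SPM coordinates to the isocenter plane and computes,
#' per spot, `dx`, `dy`, `dmu` with the sign convention delivered minus
#' planned (a positive mean reads as delivered positions shifted in the
#' positive axis direction), the Euclidean distance `d = sqrt(dx^2 + dy^2)`,
#' and its square `d2`. Factor labels (energy, room, date) are carried along
#' for downstream group analyses.
#'
#' @param pairs Output of [match_spots()] (rows may span several sessions).
#' @param f A [projection_factors()] object.
#' @return A `data.frame` of class `deviation_table` with columns
#'   `layer_index`, `spot_index`, `energy`, `room`, `date`, `dx`, `dy`, `d`,
#'   `d2`, `dmu` (mm, mm² and MU).
#' @export
compute_deviations <- function(pairs, f = projection_factors()) {
  .assert(is.data.frame(pairs) && all(c("x", "y", "meterset", "x_spm", "y_spm", "mu") %in% names(pairs)),
          "pairs must come from match_spots()")
  iso <- project_to_iso(pairs$x_spm, pairs$y_spm, f)
  dx <- iso$x_iso - pairs$x
  dy <- iso$y_iso - pairs$y
  out <- data.frame(
    layer_index = pairs$layer_index, spot_index = pairs$spot_index,
    energy = pairs$energy, room = pairs$room, date = pairs$date,
    dx = dx, dy = dy, d = sqrt(dx^2 + dy^2), d2 = dx^2 + dy^2,
    dmu = pairs$mu - pairs$meterset
  )
  class(out) <- c("deviation_table", "data.frame")
  out
}

#' Pool deviation tables from several sessions
#'
#' @param tables A list of `deviation_table` objects.
#' @return A single `deviation_table`.
#' @export
bind_deviations <- function(tables) {
  out <- do.call(rbind, lapply(tables, as.data.frame))
  class(out) <- c("deviation_table", "data.frame")
  out
}
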