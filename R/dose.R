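# Simplified analytical pencil-beam dose model. This is deliberately a
# lightweight stand-in engine for studying *relative* dosimetric effects of
# spot-position deviations: tabulated synthetic Bragg curves from a
# range-energy power law, a single energy-dependent Gaussian lateral kernel
# (no nuclear halo), homogeneous water, beam axis along grid z. It is not a
# commissioned clinical dose engine and its absolute dose magnitudes carry no
# clinical meaning.

#' Synthetic beam model for the analytical dose engine
#'
#' For each tabulated energy: range in water from the Bragg-Kleeman power law
#' `R[mm] = 0.022 * E[MeV]^1.77`, a normalized synthetic Bragg curve (entrance
#' plateau plus Gaussian peak near the range, smooth distal falloff) sampled
#' on a fine depth grid, and a lateral Gaussian sigma at isocenter that
#' shrinks with energy.
#'
#' @param energies Energies (MeV) the model must cover.
#' @param mu_to_dose Scaling in Gy·mm² per MU applied to every spot.
#' @param depth_step Depth sampling step of the Bragg tables (mm).
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(energies, mu_to_dose = 1.0, depth_step = 0.5) {
  energies <- sort(unique(as.numeric(energies)))
  .assert(all(is.finite(energies)) && all(energies > 0), "energies must be positive")
  .assert(mu_to_dose > 0, "mu_to_dose must be > 0")
  range_mm <- 0.022 * energies^1.77
  sigma_mm <- 2.5 + 400 / energies
  curves <- lapply(seq_along(energies), function(i) {
    R <- range_mm[i]
    z <- seq(0, 1.15 * R, by = depth_step)
    wp <- 0.012 * R + 0.8 # peak width grows with range (straggling)
    dd <- 0.30 * stats::pnorm((R - z) / wp) + exp(-(z - 0.985 * R)^2 / (2 * wp^2))
    dd <- dd / max(dd)
    list(depth = z, dd = dd)
  })
  structure(list(energies = energies, range_mm = range_mm, sigma_mm = sigma_mm,
                 curves = curves, mu_to_dose = mu_to_dose),
            class = "beam_model")
}

.model_index <- function(model, energy) {
  i <- match(energy, model$energies)
  if (is.na(i)) {
    .stop_fmt("energy %g MeV is not covered by the beam model (tabulated: %s)",
              energy, paste(signif(model$energies, 4), collapse = ", "))
  }
  i
}

#' Uniform 3-D dose grid specification
#'
#' @param origin Numeric `c(x, y, z)` of the first voxel center (mm).
#' @param spacing Isotropic voxel spacing (mm); 2 mm is the conventional
#'   evaluation grid.
#' @param shape Integer `c(nx, ny, nz)` voxel counts.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin, spacing = 2.0, shape) {
  .assert(length(origin) == 3L && all(is.finite(origin)), "origin must be length-3 numeric")
  .assert(spacing > 0, "spacing must be > 0")
  .assert(length(shape) == 3L && all(shape >= 1) && all(shape == round(shape)),
          "shape must be three positive integers")
  structure(list(origin = as.numeric(origin), spacing = spacing, shape = as.integer(shape)),
            class = "grid_spec")
}

#' Default evaluation grid for a plan
#'
#' Lateral extent covering the plan's spot bounding box plus a margin of 5
#' maximum lateral sigmas; depth covering all Bragg curves.
#'
#' @param plan An [ion_plan()].
#' @param model A [beam_model()].
#' @param spacing Voxel spacing (mm).
#' @return A [grid_spec()].
#' @export
default_grid <- function(plan, model, spacing = 2.0) {
  margin <- 5 * max(model$sigma_mm)
  xr <- range(plan$spots$x) + c(-margin, margin)
  yr <- range(plan$spots$y) + c(-margin, margin)
  zmax <- 1.15 * max(model$range_mm[vapply(plan$energies, function(e) .model_index(model, e), 0L)])
  shape <- c(ceiling(diff(xr) / spacing) + 1L, ceiling(diff(yr) / spacing) + 1L,
             ceiling(zmax / spacing) + 1L)
  grid_spec(origin = c(xr[1], yr[1], 0), spacing = spacing, shape = shape)
}

#' Compute a voxel-wise dose grid from a spot plan
#'
#' Superposes, over all spots, `MU * scale * DD_E(z) * G(x - x_s, y - y_s)`
#' where `DD_E` is the energy's normalized depth-dose at the voxel depth
#' (beam axis along grid z) and `G` is the 2-D isotropic Gaussian lateral
#' kernel integrated over the voxel cross-section (density at the voxel
#' center times voxel area), so that summing a lateral slice recovers
#' `MU * scale * DD(z)` when the field extends well beyond 5 sigma.
#'
#' @param plan An [ion_plan()].
#' @param model A [beam_model()] covering all plan energies.
#' @param grid A [grid_spec()], or `NULL` for [default_grid()].
#' @return A list of class `dose_grid` with `origin`, `spacing`, `shape` and
#'   `values` (a 3-D array, Gy).
#' @export
compute_dose <- function(plan, model, grid = NULL) {
  .assert(inherits(plan, "ion_plan"), "plan must be an ion_plan")
  .assert(inherits(model, "beam_model"), "model must be a beam_model")
  if (is.null(grid)) grid <- default_grid(plan, model)
  .assert(inherits(grid, "grid_spec"), "grid must be a grid_spec")
  sp <- grid$spacing
  xs <- grid$origin[1] + (seq_len(grid$shape[1]) - 1L) * sp
  ys <- grid$origin[2] + (seq_len(grid$shape[2]) - 1L) * sp
  zs <- grid$origin[3] + (seq_len(grid$shape[3]) - 1L) * sp
  values <- array(0, dim = grid$shape)
  area <- sp * sp
  for (k in seq_along(plan$energies)) {
    i <- .model_index(model, plan$energies[k])
    curve <- model$curves[[i]]
    dd_z <- stats::approx(curve$depth, curve$dd, xout = zs, yleft = 0, yright = 0,
                          rule = 1)$y
    dd_z[is.na(dd_z)] <- 0
    if (all(dd_z == 0)) next
    sigma <- model$sigma_mm[i]
    spots <- plan$spots[plan$spots$layer_index == k, , drop = FALSE]
    lateral <- matrix(0, grid$shape[1], grid$shape[2])
    for (s in seq_len(nrow(spots))) {
      gx <- stats::dnorm(xs, spots$x[s], sigma)
      gy <- stats::dnorm(ys, spots$y[s], sigma)
      lateral <- lateral + spots$meterset[s] * outer(gx, gy)
    }
    lateral <- lateral * model$mu_to_dose * area
    nz <- which(dd_z > 0)
    for (z in nz) values[, , z] <- values[, , z] + lateral * dd_z[z]
  }
  structure(list(origin = grid$origin, spacing = grid$spacing, shape = grid$shape,
                 values = values),
            class = "dose_grid")
}

#' Substitute delivered or predicted spots into a plan template
#'
#' Returns a new plan with the template's identity, energies and layer
#' structure but the given spot positions and metersets — the conversion used
#' to turn a delivery log (or model predictions) back into a DICOM-writable
#' ion plan for dose recomputation.
#'
#' @param spots Either a [delivery_session()] (positions are projected to the
#'   isocenter plane with `f`) or a `data.frame` with columns `x`, `y` and
#'   `meterset` (or `mu`) in the template's spot order.
#' @param template The planned [ion_plan()].
#' @param f [projection_factors()] (used for a `delivery_session` input).
#' @return An [ion_plan()].
#' @export
spots_to_plan <- function(spots, template, f = projection_factors()) {
  .assert(inherits(template, "ion_plan"), "template must be an ion_plan")
  if (inherits(spots, "delivery_session")) {
    pairs <- match_spots(template, spots)
    iso <- project_to_iso(pairs$x_spm, pairs$y_spm, f)
    spots <- data.frame(x = iso$x_iso, y = iso$y_iso, meterset = pairs$mu)
  }
  .assert(is.data.frame(spots) && all(c("x", "y") %in% names(spots)),
          "spots must be a delivery_session or a data.frame with x, y")
  mu <- spots$meterset %||% spots$mu
  .assert(!is.null(mu), "spots must carry meterset (or mu)")
  .assert(nrow(spots) == n_spots(template),
          "synchronization error: %d spots supplied for a %d-spot template",
          nrow(spots), n_spots(template))
  new_spots <- template$spots
  new_spots$x <- spots$x
  new_spots$y <- spots$y
  new_spots$meterset <- mu
  ion_plan(template$plan_id, template$gantry_angle, template$energies, new_spots)
}

#' Compare two congruent dose grids
#'
#' @param a,b `dose_grid` objects on identical origin/spacing/shape.
#' @return A list of class `dose_comparison`: `stats_a` and `stats_b` (mean,
#'   sd, min, max in Gy), `mean_abs_diff_of_means`, `max_abs_voxel_diff`,
#'   `sd_voxel_diff`.
#' @export
compare_dose <- function(a, b) {
  .assert(inherits(a, "dose_grid") && inherits(b, "dose_grid"),
          "a and b must be dose_grid objects")
  congruent <- identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$origin, b$origin)) && isTRUE(all.equal(a$spacing, b$spacing))
  .assert(congruent, "dose grids are not congruent (origin/spacing/shape differ)")
  gstats <- function(g) c(mean = mean(g$values), sd = stats::sd(as.vector(g$values)),
                          min = min(g$values), max = max(g$values))
  diff <- b$values - a$values
  structure(list(
    stats_a = gstats(a), stats_b = gstats(b),
    mean_abs_diff_of_means = abs(mean(b$values) - mean(a$values)),
    max_abs_voxel_diff = max(abs(diff)),
    sd_voxel_diff = stats::sd(as.vector(diff))
  ), class = "dose_comparison")
}

#' @export
print.dose_comparison <- function(x, ...) {
  cat(sprintf("<dose_comparison> mean %.4g vs %.4g Gy | max abs voxel diff %.4g Gy | sd of diffs %.4g Gy\n",
              x$stats_a["mean"], x$stats_b["mean"], x$max_abs_voxel_diff, x$sd_voxel_diff))
  invisible(x)
}
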