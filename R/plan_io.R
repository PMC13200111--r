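# DICOM RT Ion Plan tags used by this module
# (300A,03A2) IonBeamSequence          (300A,03A8) IonControlPointSequence
# (300A,0392) NumberOfScanSpotPositions (300A,0394) ScanSpotPositionMap [FL]
# (300A,0396) ScanSpotMetersetWeights  [FL]
# (300A,010E) FinalCumulativeMetersetWeight  (300A,0086) BeamMeterset

#' Construct a spot-scanning ion treatment plan
#'
#' An `ion_plan` holds one beam's spot map: per-layer nominal energies and,
#' per spot, the planned lateral position at the isocenter plane (IEC
#' beam-limiting-device x/y, millimetres) and the planned meterset in
#' absolute MU. Layer order is delivery order and is never re-sorted by
#' energy; spot order within a layer is delivery order.
#'
#' @param plan_id Character plan identifier (becomes the RT Plan Label).
#' @param gantry_angle Gantry angle in degrees.
#' @param energies Numeric vector of nominal beam energies (MeV), one per
#'   layer, in delivery order.
#' @param spots `data.frame` with columns `layer_index` (1-based),
#'   `spot_index` (1-based order within layer), `x`, `y` (mm at isocenter)
#'   and `meterset` (MU, > 0).
#' @param total_mu Total beam meterset in MU; defaults to the sum of spot
#'   metersets and must agree with it to 1e-6 relative.
#' @param energy_range Permitted clinical energy range in MeV.
#' @return An object of class `ion_plan`.
#' @export
#' @examples
#' p <- ion_plan("demo", 0, energies = 100,
#'               spots = data.frame(layer_index = 1, spot_index = 1,
#'                                  x = 0, y = 0, meterset = 1))
#' p$total_mu
ion_plan <- function(plan_id, gantry_angle, energies, spots,
                     total_mu = sum(spots$meterset), energy_range = c(60, 250)) {
  .assert(is.character(plan_id) && length(plan_id) == 1L && nzchar(plan_id),
          "plan_id must be a non-empty string")
  .assert(is.numeric(gantry_angle) && length(gantry_angle) == 1L && is.finite(gantry_angle),
          "gantry_angle must be a finite number")
  .assert(length(energies) >= 1L && all(is.finite(energies)), "at least one layer energy required")
  .assert(all(energies >= energy_range[1] & energies <= energy_range[2]),
          "layer energies outside the configured clinical range [%g, %g] MeV",
          energy_range[1], energy_range[2])
  need <- c("layer_index", "spot_index", "x", "y", "meterset")
  .assert(is.data.frame(spots) && all(need %in% names(spots)),
          "spots must be a data.frame with columns %s", paste(need, collapse = ", "))
  .assert(nrow(spots) > 0L, "plan has no spots")
  .assert(all(spots$meterset > 0), "all spot metersets must be > 0")
  .assert(!anyDuplicated(spots[, c("layer_index", "spot_index")]),
          "(layer_index, spot_index) pairs must be unique")
  .assert(all(spots$layer_index %in% seq_along(energies)),
          "spot layer_index outside 1..%d", length(energies))
  s <- sum(spots$meterset)
  .assert(abs(total_mu - s) <= 1e-6 * max(s, 1e-12),
          "total_mu (%.8g) disagrees with the sum of spot metersets (%.8g)", total_mu, s)
  structure(list(plan_id = plan_id, gantry_angle = gantry_angle,
                 energies = as.numeric(energies),
                 spots = spots[order(spots$layer_index, spots$spot_index), need],
                 total_mu = total_mu),
            class = "ion_plan")
}

#' @export
print.ion_plan <- function(x, ...) {
  cat(sprintf("<ion_plan> %s: %d layers (%.1f-%.1f MeV), %d spots, %.4f MU, gantry %.1f deg\n",
              x$plan_id, length(x$energies), min(x$energies), max(x$energies),
              nrow(x$spots), x$total_mu, x$gantry_angle))
  invisible(x)
}

#' Number of layers / spots in a plan
#' @param plan An [ion_plan()].
#' @return Integer count.
#' @export
n_layers <- function(plan) length(plan$energies)

#' @rdname n_layers
#' @export
n_spots <- function(plan) nrow(plan$spots)

# Deterministic SOP instance UID so repeated writes of the same plan are
# byte-identical.
.plan_uid <- function(plan_id) {
  paste0(.UID_IMPL_ROOT, ".", derive_seed(1L, plan_id), ".1")
}

#' Write an ion plan as a DICOM RT Ion Plan file
#'
#' Emits one ion beam whose layers are stored as paired control points, the
#' standard DICOM convention: the even control point of each pair carries the
#' nominal beam energy, the scan spot position map (alternating x,y pairs,
#' float32) and the per-spot meterset weights; the odd control point repeats
#' the map with zero weights and the cumulative meterset weight after the
#' layer. Meterset weights are written in absolute MU so that the beam
#' meterset equals the final cumulative meterset weight.
#'
#' @param plan An [ion_plan()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_ion_plan()]
#' @export
write_ion_plan <- function(plan, path) {
  .assert(inherits(plan, "ion_plan"), "plan must be an ion_plan")
  .assert(length(plan$energies) >= 1L, "plan has an empty layer list")
  spots_by_layer <- split(plan$spots, plan$spots$layer_index)
  .assert(length(spots_by_layer) == length(plan$energies), "every layer must contain spots")
  .assert(max(vapply(spots_by_layer, nrow, 0L)) <= 8191L,
          "explicit-VR scan spot maps support at most 8191 spots per layer")

  cps <- list()
  cum <- 0
  for (k in seq_along(plan$energies)) {
    sp <- spots_by_layer[[k]]
    pos_map <- as.vector(rbind(sp$x, sp$y)) # x1,y1,x2,y2,...
    cp_even <- c(
      .el_is(0x300A, 0x0112, 2L * (k - 1L)),
      .el_ds(0x300A, 0x0114, plan$energies[k]),
      if (k == 1L) .el_ds(0x300A, 0x011E, plan$gantry_angle),
      .el_ds(0x300A, 0x0134, cum),
      .el_is(0x300A, 0x0392, nrow(sp)),
      .el_fl(0x300A, 0x0394, pos_map),
      .el_fl(0x300A, 0x0396, sp$meterset)
    )
    cum <- cum + sum(sp$meterset)
    cp_odd <- c(
      .el_is(0x300A, 0x0112, 2L * k - 1L),
      .el_ds(0x300A, 0x0114, plan$energies[k]),
      .el_ds(0x300A, 0x0134, cum),
      .el_is(0x300A, 0x0392, nrow(sp)),
      .el_fl(0x300A, 0x0394, pos_map),
      .el_fl(0x300A, 0x0396, numeric(nrow(sp)))
    )
    cps[[2L * k - 1L]] <- cp_even
    cps[[2L * k]] <- cp_odd
  }

  beam_item <- c(
    .el_is(0x300A, 0x00C0, 1L),
    .el_str(0x300A, 0x00C2, "LO", plan$plan_id),
    .el_str(0x300A, 0x00C6, "CS", "PROTON"),
    .el_str(0x300A, 0x0308, "CS", "MODULATED"),
    .el_ds(0x300A, 0x010E, plan$total_mu),
    .el_is(0x300A, 0x0110, 2L * length(plan$energies)),
    .el_sq(0x300A, 0x03A8, cps)
  )
  ref_beam_item <- c(.el_ds(0x300A, 0x0086, plan$total_mu), .el_is(0x300C, 0x0006, 1L))
  fraction_item <- c(
    .el_is(0x300A, 0x0071, 1L),
    .el_is(0x300A, 0x0078, 1L),
    .el_is(0x300A, 0x0080, 1L),
    .el_sq(0x300C, 0x0004, list(ref_beam_item))
  )
  uid <- .plan_uid(plan$plan_id)
  dataset <- c(
    .el_str(0x0008, 0x0016, "UI", .UID_RT_ION_PLAN),
    .el_str(0x0008, 0x0018, "UI", uid),
    .el_str(0x0008, 0x0060, "CS", "RTPLAN"),
    .el_str(0x300A, 0x0002, "SH", plan$plan_id),
    .el_sq(0x300A, 0x0070, list(fraction_item)),
    .el_sq(0x300A, 0x03A2, list(beam_item))
  )
  .write_dicom(dataset, uid, path)
  invisible(path)
}

.require_el <- function(item, key, what, path) {
  v <- item[[key]]
  if (is.null(v)) .stop_fmt("DICOM RT Ion Plan format error: missing %s (%s) in %s", what, key, path)
  v
}

#' Read a DICOM RT Ion Plan into an ion_plan
#'
#' Parses the ion beam sequence and collects, in control-point order, every
#' control point that carries a scan spot position map with non-zero meterset
#' weights; each such control point is one energy layer. Per-spot absolute MU
#' is recovered as `weight * beam_meterset / final_cumulative_meterset_weight`,
#' the standard DICOM ion-plan convention. Layer order is file order (delivery
#' order), never re-sorted by energy.
#'
#' @param path Path to a DICOM RT Ion Plan file.
#' @param beam Which beam to return (1-based index into the ion beam
#'   sequence); the file may contain several.
#' @param energy_range Permitted clinical energy range passed to [ion_plan()].
#' @return An [ion_plan()]; the attribute `n_beams` gives the number of beams
#'   present in the file.
#' @export
read_ion_plan <- function(path, beam = 1L, energy_range = c(60, 250)) {
  dcm <- .read_dicom(path)
  ds <- dcm$data
  sop <- ds[["0008,0016"]]
  .assert(identical(sop, .UID_RT_ION_PLAN),
          "not an RT Ion Plan (SOP class %s): %s", sop %||% "<missing>", path)
  beams <- .require_el(ds, "300A,03A2", "IonBeamSequence", path)
  .assert(beam >= 1L && beam <= length(beams), "beam %d not present (%d beams): %s",
          beam, length(beams), path)
  b <- beams[[beam]]
  beam_number <- .require_el(b, "300A,00C0", "BeamNumber", path)
  final_cum <- .require_el(b, "300A,010E", "FinalCumulativeMetersetWeight", path)
  if (final_cum == 0) .stop_fmt("zero FinalCumulativeMetersetWeight in %s", path)

  # beam meterset from the fraction group's referenced beam sequence
  beam_meterset <- NA_real_
  for (fg in (ds[["300A,0070"]] %||% list())) {
    for (rb in (fg[["300C,0004"]] %||% list())) {
      if (identical(rb[["300C,0006"]], beam_number)) beam_meterset <- rb[["300A,0086"]]
    }
  }
  .assert(is.finite(beam_meterset), "missing BeamMeterset (300A,0086) for beam %d in %s",
          beam_number, path)
  scale <- beam_meterset / final_cum

  cps <- .require_el(b, "300A,03A8", "IonControlPointSequence", path)
  gantry <- cps[[1L]][["300A,011E"]] %||% 0
  energies <- numeric(0)
  layers <- list()
  for (cp in cps) {
    w <- cp[["300A,0396"]]
    if (is.null(w) || sum(w) <= 0) next
    nsp <- .require_el(cp, "300A,0392", "NumberOfScanSpotPositions", path)
    pm <- .require_el(cp, "300A,0394", "ScanSpotPositionMap", path)
    .assert(length(pm) == 2L * nsp && length(w) == nsp,
            "scan spot map / weights length mismatch in %s", path)
    en <- .require_el(cp, "300A,0114", "NominalBeamEnergy", path)
    k <- length(energies) + 1L
    energies[k] <- en
    layers[[k]] <- data.frame(
      layer_index = k, spot_index = seq_len(nsp),
      x = pm[seq(1L, 2L * nsp, by = 2L)], y = pm[seq(2L, 2L * nsp, by = 2L)],
      meterset = w * scale
    )
  }
  .assert(length(layers) > 0L, "no scan spot data found in %s", path)
  plan <- ion_plan(plan_id = ds[["300A,0002"]] %||% "unnamed",
                   gantry_angle = gantry, energies = energies,
                   spots = do.call(rbind, layers),
                   total_mu = beam_meterset, energy_range = energy_range)
  attr(plan, "n_beams") <- length(beams)
  plan
}

`%||%` <- function(a, b) if (is.null(a)) b else a
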