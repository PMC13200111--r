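#' Systematic + random delivery-error model
#'
#' Specifies how delivered spot positions and MU deviate from plan in a
#' simulated session. The position error on each axis is additive:
#' a global mean shift, a per-room offset, a linear energy-dependent term
#' about the plan's mid-energy, a per-date drift, and independent Gaussian
#' jitter (x and y jitters are sampled independently; the cross-axis
#' correlation of real deliveries is negligible). Delivered MU is planned MU
#' plus Gaussian noise truncated at zero.
#'
#' Defaults are all-zero (the null model: delivered equals planned).
#' [paper_error_model()] returns the configuration matching the campaign this
#' package emulates.
#'
#' @param mu_x,mu_y Global mean position error per axis (mm).
#' @param sigma_x,sigma_y Random jitter SD per axis (mm, >= 0).
#' @param room_offsets Named list mapping room -> numeric `c(dx, dy)` offset
#'   in mm, or `NULL` for none.
#' @param energy_slope Numeric `c(x, y)` slope in mm per MeV applied to
#'   `energy - E_ref` with `E_ref` the midpoint of the plan's energy range.
#' @param date_drift Named list mapping ISO date -> numeric `c(dx, dy)` mm,
#'   or `NULL` for none.
#' @param room_sigma_scale Named list mapping room -> multiplier applied to
#'   both jitter SDs (rooms can differ in spot-to-spot variability), or
#'   `NULL` for 1 everywhere.
#' @param mu_noise_mean,mu_noise_sd Mean and SD (MU) of the additive MU
#'   noise; `mu_noise_sd >= 0`.
#' @return An object of class `error_model`.
#' @export
error_model <- function(mu_x = 0, mu_y = 0, sigma_x = 0, sigma_y = 0,
                        room_offsets = NULL, energy_slope = c(0, 0),
                        date_drift = NULL, room_sigma_scale = NULL,
                        mu_noise_mean = 0, mu_noise_sd = 0) {
  .assert(sigma_x >= 0 && sigma_y >= 0 && mu_noise_sd >= 0,
          "sigma_x, sigma_y and mu_noise_sd must be >= 0")
  .assert(length(energy_slope) == 2L && all(is.finite(energy_slope)),
          "energy_slope must be a length-2 numeric")
  for (nm in names(room_offsets)) {
    .assert(length(room_offsets[[nm]]) == 2L, "room_offsets[['%s']] must be length-2", nm)
  }
  for (nm in names(date_drift)) {
    .assert(length(date_drift[[nm]]) == 2L, "date_drift[['%s']] must be length-2", nm)
  }
  structure(list(mu_x = mu_x, mu_y = mu_y, sigma_x = sigma_x, sigma_y = sigma_y,
                 room_offsets = room_offsets, energy_slope = as.numeric(energy_slope),
                 date_drift = date_drift, room_sigma_scale = room_sigma_scale,
                 mu_noise_mean = mu_noise_mean, mu_noise_sd = mu_noise_sd),
            class = "error_model")
}

#' Error model reproducing the reference QA campaign's marginal distributions
#'
#' Position errors: x mean 0.163 mm, SD 0.199 mm; y mean 0.096 mm, SD
#' 0.151 mm. MU noise: mean 0.70e-5 MU, SD 1e-4 MU. With
#' `structured = TRUE`, small room offsets, a linear energy slope, per-date
#' drifts and room-dependent jitter scales are added so that room, date and
#' energy become detectable factors of the error; their magnitudes are this
#' package's choice (see the methods vignette).
#'
#' @param structured Add room/date/energy systematic structure?
#' @param dates Session dates (required when `structured = TRUE`; drifts are
#'   drawn once per date from `drift_seed`).
#' @param drift_seed Seed for the per-date drifts.
#' @param drift_sd SD (mm) of per-date drifts on each axis.
#' @return An [error_model()].
#' @export
paper_error_model <- function(structured = FALSE, dates = NULL,
                              drift_seed = 20260520L, drift_sd = 0.04) {
  if (!structured) {
    return(error_model(mu_x = 0.163, mu_y = 0.096, sigma_x = 0.199, sigma_y = 0.151,
                       mu_noise_mean = 0.70e-5, mu_noise_sd = 1e-4))
  }
  .assert(!is.null(dates), "dates are required for a structured error model")
  dates <- format(.as_iso_date(dates))
  set.seed(drift_seed)
  drift <- lapply(dates, function(d) stats::rnorm(2L, 0, drift_sd))
  names(drift) <- dates
  error_model(
    mu_x = 0.163, mu_y = 0.096, sigma_x = 0.199, sigma_y = 0.151,
    room_offsets = list(G1 = c(0.02, 0.01), G2 = c(-0.03, 0.02)),
    energy_slope = c(0.002, 0.001),
    date_drift = drift,
    room_sigma_scale = list(G1 = 1.25, G2 = 0.8),
    mu_noise_mean = 0.70e-5, mu_noise_sd = 1e-4
  )
}

#' Build the rectangular-grid QA fixture plan
#'
#' Lays `spots_per_layer` spots on a near-square rectangular grid spanning
#' `field_mm` on both axes of the isocenter plane, repeats the grid on every
#' layer, spaces layer energies evenly from `energy_min` to `energy_max`, and
#' gives every spot the same meterset so metersets sum to `total_mu`.
#'
#' @param n_layers Number of energy layers (>= 1).
#' @param spots_per_layer Spots per layer (>= 1).
#' @param energy_min,energy_max Energy range in MeV (`energy_min <= energy_max`).
#' @param total_mu Total beam meterset in MU (> 0).
#' @param gantry_angle Gantry angle in degrees.
#' @param field_mm Half-width of the spot grid (mm); spots span
#'   `[-field_mm, field_mm]`.
#' @param plan_id Plan identifier.
#' @return An [ion_plan()].
#' @export
#' @examples
#' plan <- make_fixture_plan(20, 725, 99.2, 124.8, 233.3, 0)
#' n_spots(plan) # 14500
make_fixture_plan <- function(n_layers, spots_per_layer, energy_min, energy_max,
                              total_mu, gantry_angle = 0, field_mm = 100,
                              plan_id = "QA-FIXTURE") {
  .assert(.is_count(n_layers) && n_layers >= 1, "n_layers must be a positive integer")
  .assert(.is_count(spots_per_layer) && spots_per_layer >= 1,
          "spots_per_layer must be a positive integer")
  .assert(energy_min <= energy_max, "energy_min must be <= energy_max")
  .assert(total_mu > 0, "total_mu must be > 0")
  .assert(field_mm > 0, "field_mm must be > 0")
  energies <- if (n_layers == 1L) energy_min else
    seq(energy_min, energy_max, length.out = n_layers)
  # near-square grid with at least spots_per_layer nodes, truncated in
  # row-major (scan-line) order to the exact count
  ncol_grid <- ceiling(sqrt(spots_per_layer))
  nrow_grid <- ceiling(spots_per_layer / ncol_grid)
  xs <- if (ncol_grid == 1L) 0 else seq(-field_mm, field_mm, length.out = ncol_grid)
  ys <- if (nrow_grid == 1L) 0 else seq(-field_mm, field_mm, length.out = nrow_grid)
  gx <- rep(xs, times = nrow_grid)[seq_len(spots_per_layer)]
  gy <- rep(ys, each = ncol_grid)[seq_len(spots_per_layer)]
  per_spot <- total_mu / (n_layers * spots_per_layer)
  spots <- data.frame(
    layer_index = rep(seq_len(n_layers), each = spots_per_layer),
    spot_index = rep(seq_len(spots_per_layer), times = n_layers),
    x = rep(gx, times = n_layers), y = rep(gy, times = n_layers),
    meterset = per_spot
  )
  ion_plan(plan_id, gantry_angle, energies, spots, total_mu = total_mu)
}

#' Simulate one delivery session of a plan
#'
#' For each spot the delivered isocenter position is the planned position
#' plus the error model's systematic terms and Gaussian jitter; SPM-plane
#' coordinates are then obtained by dividing by the projection factors (the
#' inverse of the isocenter projection), so that a downstream
#' project/compare pipeline recovers exactly the simulated errors. Delivered
#' MU is planned MU plus truncated Gaussian noise. Spot widths are filled
#' with a deterministic energy-dependent nominal width.
#'
#' @param plan An [ion_plan()].
#' @param room Room identifier; must be a key of the model's `room_offsets`
#'   when those are set.
#' @param date Session date.
#' @param model An [error_model()].
#' @param seed Integer seed; the session is reproducible given
#'   `(seed, room, date)`.
#' @param f [projection_factors()] used for the inverse projection.
#' @return A [delivery_session()].
#' @export
simulate_session <- function(plan, room, date, model, seed,
                             f = projection_factors()) {
  .assert(inherits(plan, "ion_plan"), "plan must be an ion_plan")
  .assert(inherits(model, "error_model"), "model must be an error_model")
  date <- .as_iso_date(date)
  if (!is.null(model$room_offsets) && !(room %in% names(model$room_offsets))) {
    .stop_fmt("room '%s' has no entry in the error model's room_offsets", room)
  }
  set.seed(derive_seed(seed, room, format(date)))
  sp <- plan$spots
  n <- nrow(sp)
  energy <- plan$energies[sp$layer_index]
  e_ref <- mean(range(plan$energies))

  roff <- model$room_offsets[[room]] %||% c(0, 0)
  doff <- model$date_drift[[format(date)]] %||% c(0, 0)
  sscale <- model$room_sigma_scale[[room]] %||% 1
  sys_x <- model$mu_x + roff[1] + model$energy_slope[1] * (energy - e_ref) + doff[1]
  sys_y <- model$mu_y + roff[2] + model$energy_slope[2] * (energy - e_ref) + doff[2]

  x_iso <- sp$x + sys_x + stats::rnorm(n, 0, model$sigma_x * sscale)
  y_iso <- sp$y + sys_y + stats::rnorm(n, 0, model$sigma_y * sscale)
  mu <- pmax(0, sp$meterset + stats::rnorm(n, model$mu_noise_mean, model$mu_noise_sd))
  width <- 2.5 + 400 / energy # nominal spot sigma, mm; not used by QA statistics

  delivery_session(
    room = room, date = date, plan_id = plan$plan_id, energies = plan$energies,
    records = data.frame(layer_index = sp$layer_index, spot_index = sp$spot_index,
                         x_spm = x_iso / f$f_x, y_spm = y_iso / f$f_y,
                         width_x = width, width_y = width, mu = mu)
  )
}

#' Specify a simulated QA campaign
#'
#' A campaign delivers one plan repeatedly: one session per (room, date)
#' combination, all sharing one error model, with optional fault injection
#' (a constant extra position offset applied to every spot of one session,
#' emulating a session-specific systematic delivery error).
#'
#' @param rooms Character vector of room identifiers.
#' @param dates Vector of session dates (each date is delivered in every
#'   room: paired room-day sampling).
#' @param plan An [ion_plan()].
#' @param model An [error_model()].
#' @param faults `NULL`, or a `data.frame` with columns `room`, `date`,
#'   `offset_x`, `offset_y` (mm); each entry must reference a scheduled
#'   session.
#' @param seed Campaign seed; per-session seeds are derived from it and the
#'   session's (room, date) labels.
#' @return An object of class `campaign_spec`.
#' @export
campaign_spec <- function(rooms, dates, plan, model, faults = NULL, seed = 1L) {
  .assert(length(rooms) >= 1L && !anyDuplicated(rooms), "rooms must be unique")
  dates <- .as_iso_date(dates)
  .assert(!anyDuplicated(dates), "dates must be unique (one paired session per date)")
  .assert(inherits(plan, "ion_plan"), "plan must be an ion_plan")
  .assert(inherits(model, "error_model"), "model must be an error_model")
  if (!is.null(faults)) {
    .assert(is.data.frame(faults) &&
              all(c("room", "date", "offset_x", "offset_y") %in% names(faults)),
            "faults needs columns room, date, offset_x, offset_y")
    faults$date <- .as_iso_date(faults$date)
    ok <- faults$room %in% rooms & faults$date %in% dates
    .assert(all(ok), "fault entries must reference scheduled (room, date) sessions")
  }
  structure(list(rooms = rooms, dates = dates, plan = plan, model = model,
                 faults = faults, seed = as.integer(seed)),
            class = "campaign_spec")
}

#' Simulate a campaign and write one PQA1 log per session
#'
#' Sessions are generated in date-major order (each date's rooms together,
#' matching paired room-day sampling) and written as PQA1 logs named
#' `<room>_<date>.pqa`. Fault entries add their constant offset to every
#' delivered isocenter position of the affected session.
#'
#' @param spec A [campaign_spec()].
#' @param out_dir Output directory (created if needed).
#' @param f [projection_factors()] for the inverse projection.
#' @return The campaign manifest: a `data.frame` with columns `room`, `date`,
#'   `file`, `faulted`.
#' @export
simulate_campaign <- function(spec, out_dir, f = projection_factors()) {
  .assert(inherits(spec, "campaign_spec"), "spec must be a campaign_spec")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (d in format(spec$dates)) {
    for (room in spec$rooms) {
      session <- simulate_session(spec$plan, room, d, spec$model, spec$seed, f = f)
      faulted <- FALSE
      if (!is.null(spec$faults)) {
        hit <- spec$faults$room == room & format(spec$faults$date) == d
        if (any(hit)) {
          faulted <- TRUE
          off <- spec$faults[which(hit)[1L], ]
          session$records$x_spm <- session$records$x_spm + off$offset_x / f$f_x
          session$records$y_spm <- session$records$y_spm + off$offset_y / f$f_y
        }
      }
      file <- file.path(out_dir, sprintf("%s_%s.pqa", room, d))
      write_log(session, file)
      rows[[length(rows) + 1L]] <- data.frame(room = room, date = d,
                                              file = file, faulted = faulted)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(room = character(0), date = character(0),
                      file = character(0), faulted = logical(0)))
  }
  do.call(rbind, rows)
}

#' The reference campaign's QA calendar
#'
#' 32 paired session dates over three consecutive months (12 + 12 + 8); the
#' final month contributes 8 dates, so a final-month temporal split reserves
#' 16 of the 64 room-sessions. The final-month day pattern includes the 20th,
#' the day on which the campaign's fault session is scheduled by default.
#'
#' @param start Month the campaign starts in, as `"YYYY-MM"`.
#' @return A `Date` vector of length 32.
#' @export
campaign_dates <- function(start = "2026-03") {
  first <- as.Date(paste0(start, "-01"))
  months <- seq(first, by = "month", length.out = 3L)
  early <- c(4L, 6L, 9L, 11L, 13L, 16L, 18L, 20L, 23L, 25L, 27L, 30L)
  final <- c(6L, 11L, 14L, 18L, 20L, 24L, 25L, 28L)
  c(months[1] + early - 1L, months[2] + early - 1L, months[3] + final - 1L)
}

#' Paper-shaped campaign specification
#'
#' Two rooms (G1, G2) x 32 paired dates over three months delivering one
#' fixture plan (20 layers, 99.2-124.8 MeV, 233.3 MU total), with the
#' structured error model and, by default, one faulted session (G2 on the
#' final month's 20th, +1.1 mm in x) emulating a session-specific systematic
#' deviation beyond the 1-mm annual tolerance.
#'
#' @param spots_per_layer Spots per layer of the fixture plan (725 reproduces
#'   the full-scale campaign's 928,000 spot records; smaller values give a
#'   scaled-down campaign of identical structure).
#' @param seed Campaign seed.
#' @param include_fault Schedule the fault session?
#' @param start Campaign start month, `"YYYY-MM"`.
#' @return A [campaign_spec()].
#' @export
paper_campaign <- function(spots_per_layer = 725L, seed = 1L,
                           include_fault = TRUE, start = "2026-03") {
  dates <- campaign_dates(start)
  plan <- make_fixture_plan(20L, spots_per_layer, 99.2, 124.8, 233.3, 0)
  model <- paper_error_model(structured = TRUE, dates = dates,
                             drift_seed = derive_seed(seed, "date-drift"))
  fault_date <- dates[length(dates) - 3L] # the final month's 20th
  faults <- if (include_fault) {
    data.frame(room = "G2", date = fault_date, offset_x = 1.1, offset_y = 0)
  }
  campaign_spec(rooms = c("G1", "G2"), dates = dates, plan = plan,
                model = model, faults = faults, seed = seed)
}
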