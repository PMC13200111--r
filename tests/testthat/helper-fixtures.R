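# Shared fixtures, all generated in code.

tiny_plan <- function(n_layers = 2L, spots_per_layer = 6L, total_mu = 12,
                      plan_id = "TINY") {
  make_fixture_plan(n_layers, spots_per_layer, 100, 110, total_mu, 0,
                    field_mm = 50, plan_id = plan_id)
}

# A random but valid delivery session for round-trip property tests.
random_session <- function(seed, n_layers = NULL) {
  set.seed(seed)
  if (is.null(n_layers)) n_layers <- sample(0:4, 1L)
  per_layer <- if (n_layers > 0L) sample(0:30, n_layers, replace = TRUE) else integer(0)
  records <- if (sum(per_layer) > 0L) {
    data.frame(
      layer_index = rep(seq_len(n_layers), times = per_layer),
      spot_index = unlist(lapply(per_layer, seq_len)),
      x_spm = rnorm(sum(per_layer), 0, 50),
      y_spm = rnorm(sum(per_layer), 0, 50),
      width_x = runif(sum(per_layer), 0, 10),
      width_y = runif(sum(per_layer), 0, 10),
      mu = runif(sum(per_layer), 0, 0.1)
    )
  } else {
    data.frame(layer_index = numeric(0), spot_index = numeric(0),
               x_spm = numeric(0), y_spm = numeric(0),
               width_x = numeric(0), width_y = numeric(0), mu = numeric(0))
  }
  delivery_session(
    room = sample(c("G1", "G2"), 1L),
    date = as.Date("2026-03-01") + sample(0:90, 1L),
    plan_id = paste0("P", seed),
    energies = if (n_layers > 0L) runif(n_layers, 99, 125) else numeric(0),
    records = records
  )
}

# Brute-force O(n * window) re-scan: oracle for the rolling flag implementation.
brute_force_flags <- function(dx, tol_mm, w) {
  n <- length(dx)
  flagged <- logical(n)
  for (j in seq_len(n - w + 1L)) {
    if (abs(mean(dx[j:(j + w - 1L)])) > tol_mm) flagged[j:(j + w - 1L)] <- TRUE
  }
  flagged
}

single_spot_plan <- function(x = 0, y = 0, mu = 2, energy = 100) {
  ion_plan("SPOT", 0, energies = energy,
           spots = data.frame(layer_index = 1L, spot_index = 1L, x = x, y = y,
                              meterset = mu))
}

# Deviation table built directly (without simulation) for statistics tests.
synthetic_deviations <- function(dx, dy, room = "G1", date = "2026-03-04",
                                 energy = 100, layer_index = 1L) {
  n <- length(dx)
  out <- data.frame(
    layer_index = rep_len(layer_index, n), spot_index = seq_len(n),
    energy = rep_len(energy, n), room = rep_len(room, n),
    date = rep_len(as.Date(date), n),
    dx = dx, dy = dy, d = sqrt(dx^2 + dy^2), d2 = dx^2 + dy^2,
    dmu = numeric(n)
  )
  class(out) <- c("deviation_table", "data.frame")
  out
}
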