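.FEATURES <- c("planned_x", "planned_y", "energy", "date_ordinal", "room_code")

#' Build the training table for position prediction
#'
#' One row per delivered spot across all sessions. Features are the planned
#' isocenter coordinates, nominal beam energy, session date as ordinal days
#' since the campaign's earliest session, and an integer room code; targets
#' are the delivered coordinates projected to the isocenter plane.
#'
#' @param plan An [ion_plan()].
#' @param sessions List of [delivery_session()] objects synchronized with
#'   `plan`.
#' @param f [projection_factors()].
#' @return A `data.frame` of class `feature_table` with columns
#'   `planned_x`, `planned_y`, `energy`, `date_ordinal`, `room_code`,
#'   `target_x`, `target_y`, plus bookkeeping columns `room`, `date`,
#'   `layer_index`, `spot_index`.
#' @export
build_features <- function(plan, sessions, f = projection_factors()) {
  .assert(is.list(sessions) && length(sessions) >= 1L, "need at least one session")
  rows <- lapply(sessions, function(s) {
    pairs <- match_spots(plan, s)
    iso <- project_to_iso(pairs$x_spm, pairs$y_spm, f)
    data.frame(planned_x = pairs$x, planned_y = pairs$y, energy = pairs$energy,
               date = pairs$date, room = pairs$room,
               layer_index = pairs$layer_index, spot_index = pairs$spot_index,
               target_x = iso$x_iso, target_y = iso$y_iso)
  })
  out <- do.call(rbind, rows)
  rooms <- sort(unique(out$room))
  out$room_code <- match(out$room, rooms) - 1L
  out$date_ordinal <- as.numeric(out$date - min(out$date))
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Temporal train/test split by final calendar month
#'
#' Every session whose date falls in the last calendar month present in the
#' data becomes test; all earlier sessions become train. Because campaign
#' dates are paired across rooms, the split is identical for both rooms; if a
#' room happens to have no final-month session it is simply absent from the
#' test set (a warning is issued).
#'
#' @param rows A `feature_table` from [build_features()].
#' @return A list with `train` and `test` subsets (both `feature_table`s)
#'   and `test_month` (`"YYYY-MM"`).
#' @export
temporal_split <- function(rows) {
  .assert(is.data.frame(rows) && "date" %in% names(rows), "rows must carry session dates")
  month <- format(rows$date, "%Y-%m")
  months <- sort(unique(month))
  .assert(length(months) >= 2L, "temporal split needs sessions spanning at least 2 calendar months")
  test_month <- months[length(months)]
  is_test <- month == test_month
  absent <- setdiff(unique(rows$room), unique(rows$room[is_test]))
  if (length(absent) > 0L) {
    warning(sprintf("room(s) %s have no session in the final month and are absent from the test set",
                    paste(absent, collapse = ", ")), call. = FALSE)
  }
  list(train = rows[!is_test, , drop = FALSE], test = rows[is_test, , drop = FALSE],
       test_month = test_month)
}

#' Gradient-boosting configuration for the position models
#'
#' @param n_trees Number of boosting rounds (500 matches the reference
#'   configuration).
#' @param learning_rate Shrinkage per tree, in (0, 1].
#' @param seed Integer seed (training is single-threaded and deterministic
#'   given the seed).
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_trees = 500L, learning_rate = 0.1, seed = 1L) {
  .assert(.is_count(n_trees) && n_trees >= 1, "n_trees must be a positive integer")
  .assert(learning_rate > 0 && learning_rate <= 1, "learning_rate must be in (0, 1]")
  structure(list(n_trees = as.integer(n_trees), learning_rate = learning_rate,
                 objective = "reg:squarederror", seed = as.integer(seed)),
            class = "model_config")
}

#' Train a per-axis delivered-position model
#'
#' Fits gradient-boosted regression trees (squared-error objective) mapping
#' `{planned_x, planned_y, energy, date_ordinal, room_code}` to the delivered
#' coordinate of one axis.
#'
#' @param rows Training `feature_table` (>= 100 rows).
#' @param axis `"x"` or `"y"`.
#' @param config A [model_config()].
#' @return An object of class `axis_model` wrapping the fitted booster.
#' @export
train_axis_model <- function(rows, axis = c("x", "y"), config = model_config()) {
  axis <- match.arg(axis)
  .assert(inherits(config, "model_config"), "config must be a model_config")
  .assert(nrow(rows) >= 100L, "need at least 100 training rows (got %d)", nrow(rows))
  target <- rows[[paste0("target_", axis)]]
  if (length(unique(target)) == 1L) {
    warning(sprintf("target_%s is constant in the training data", axis), call. = FALSE)
  }
  X <- as.matrix(rows[, .FEATURES])
  set.seed(config$seed)
  booster <- xgboost::xgb.train(
    params = xgboost::xgb.params(objective = config$objective,
                                 learning_rate = config$learning_rate,
                                 nthread = 1L, seed = config$seed),
    data = xgboost::xgb.DMatrix(X, label = target, nthread = 1L),
    nrounds = config$n_trees, verbose = 0L
  )
  structure(list(booster = booster, axis = axis, features = .FEATURES, config = config),
            class = "axis_model")
}

#' @export
print.axis_model <- function(x, ...) {
  cat(sprintf("<axis_model> delivered %s-coordinate: %d trees, lr %.3g\n",
              x$axis, x$config$n_trees, x$config$learning_rate))
  invisible(x)
}

#' Predict delivered coordinates for new feature rows
#'
#' @param object An `axis_model`.
#' @param newdata A `feature_table` (or data.frame with the feature columns).
#' @param ... Unused.
#' @return Numeric vector of predicted delivered coordinates (mm).
#' @export
predict.axis_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features])
  stats::predict(object$booster, xgboost::xgb.DMatrix(X, nthread = 1L))
}

.r2 <- function(actual, predicted) {
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((actual - predicted)^2) / sst
}

.axis_metrics <- function(actual, predicted) {
  c(mse = mean((actual - predicted)^2), r2 = .r2(actual, predicted))
}

#' Evaluate the per-axis models on held-out rows
#'
#' Computes, overall and per (room, date) session and per beam-energy band,
#' the mean squared error `(1/n) * sum((A - P)^2)` and the coefficient of
#' determination `R^2 = 1 - SSR/SST` for each axis, plus the per-spot
#' Euclidean distance between predicted and delivered positions. Also
#' reports the Pearson correlation between the x and y position deviations
#' (delivered minus planned), a check on the independence of the two
#' steering axes.
#'
#' @param model_x,model_y Trained `axis_model`s for the two axes.
#' @param rows Non-empty test `feature_table`.
#' @param energy_breaks Break points (MeV) for the energy-band breakdown.
#' @return A list of class `eval_report`: `overall` (named vector `mse_x`,
#'   `r2_x`, `mse_y`, `r2_y`, `euclid_mean`, `euclid_max`), `by_session` and
#'   `by_energy` data.frames, `cross_axis_r`, `n`.
#' @export
evaluate_models <- function(model_x, model_y, rows,
                            energy_breaks = c(90, 110, 120, 130)) {
  .assert(nrow(rows) > 0L, "test rows must be non-empty")
  px <- predict(model_x, rows)
  py <- predict(model_y, rows)
  ex <- .axis_metrics(rows$target_x, px)
  ey <- .axis_metrics(rows$target_y, py)
  euclid <- sqrt((rows$target_x - px)^2 + (rows$target_y - py)^2)

  breakdown <- function(groups) {
    parts <- split(seq_len(nrow(rows)), groups)
    do.call(rbind, lapply(names(parts), function(g) {
      i <- parts[[g]]
      data.frame(group = g, n = length(i),
                 mse_x = mean((rows$target_x[i] - px[i])^2),
                 r2_x = .r2(rows$target_x[i], px[i]),
                 mse_y = mean((rows$target_y[i] - py[i])^2),
                 r2_y = .r2(rows$target_y[i], py[i]),
                 euclid_mean = mean(euclid[i]), euclid_max = max(euclid[i]))
    }))
  }
  band_labels <- paste(energy_breaks[-length(energy_breaks)],
                       energy_breaks[-1] - 1, sep = "-")
  bands <- cut(rows$energy, breaks = energy_breaks, labels = band_labels,
               right = FALSE)
  bands <- as.character(bands)
  bands[is.na(bands)] <- "other"

  structure(list(
    overall = c(mse_x = unname(ex["mse"]), r2_x = unname(ex["r2"]),
                mse_y = unname(ey["mse"]), r2_y = unname(ey["r2"]),
                euclid_mean = mean(euclid), euclid_max = max(euclid)),
    by_session = breakdown(paste(rows$room, format(rows$date))),
    by_energy = breakdown(paste(rows$room, bands)),
    cross_axis_r = stats::cor(rows$target_x - rows$planned_x,
                              rows$target_y - rows$planned_y),
    n = nrow(rows)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf("<eval_report> n = %d test spots\n", x$n))
  cat(sprintf("  x: MSE %.4g mm^2, R^2 %.6f | y: MSE %.4g mm^2, R^2 %.6f\n",
              o["mse_x"], o["r2_x"], o["mse_y"], o["r2_y"]))
  cat(sprintf("  Euclidean distance: mean %.4g mm, max %.4g mm; cross-axis r = %.3f\n",
              o["euclid_mean"], o["euclid_max"], x$cross_axis_r))
  invisible(x)
}

#' Per-feature importance of a trained axis model
#'
#' Total split gain per feature, normalized to fractions summing to 1
#' ("average gain" importance). Features never used for a split get fraction
#' zero.
#'
#' @param model A trained `axis_model`.
#' @return A `data.frame` with `feature` and `gain` (fractions, sum 1),
#'   sorted by decreasing gain.
#' @export
feature_importance <- function(model) {
  .assert(inherits(model, "axis_model"), "model must be a trained axis_model")
  imp <- as.data.frame(xgboost::xgb.importance(model = model$booster))
  gain <- stats::setNames(rep(0, length(model$features)), model$features)
  gain[imp$Feature] <- imp$Gain
  gain <- gain / sum(gain)
  out <- data.frame(feature = names(gain), gain = unname(gain))
  out[order(-out$gain), , drop = FALSE]
}
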