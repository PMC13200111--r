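make_campaign_features <- function(spots_per_layer = 10L, model = paper_error_model(),
                                   dates = c("2026-03-04", "2026-03-11",
                                             "2026-04-06", "2026-04-11"),
                                   rooms = c("G1", "G2"), seed = 1L) {
  plan <- tiny_plan(2L, spots_per_layer, plan_id = "FEAT")
  sessions <- list()
  for (d in dates) for (r in rooms) {
    sessions[[length(sessions) + 1L]] <- simulate_session(plan, r, d, model, seed)
  }
  list(plan = plan, sessions = sessions,
       features = build_features(plan, sessions))
}

test_that("feature rows cover every delivered spot with consistent encodings", {
  fx <- make_campaign_features()
  rows <- fx$features
  expect_equal(nrow(rows), 8L * n_spots(fx$plan))
  expect_setequal(unique(rows$room_code), c(0L, 1L))
  expect_equal(min(rows$date_ordinal), 0)
  expect_equal(max(rows$date_ordinal), as.numeric(as.Date("2026-04-11") - as.Date("2026-03-04")))

  # null error model: targets equal planned coordinates after SPM round trip
  fx0 <- make_campaign_features(model = error_model())
  expect_equal(fx0$features$target_x, fx0$features$planned_x, tolerance = 1e-12)
  expect_equal(fx0$features$target_y, fx0$features$planned_y, tolerance = 1e-12)
})

test_that("temporal split reserves exactly the final calendar month", {
  fx <- make_campaign_features()
  split <- temporal_split(fx$features)
  expect_equal(split$test_month, "2026-04")
  expect_equal(nrow(split$train) + nrow(split$test), nrow(fx$features))
  expect_equal(nrow(split$test), 4L * n_spots(fx$plan)) # 2 dates x 2 rooms
  expect_true(all(format(split$test$date, "%Y-%m") == "2026-04"))
  expect_true(all(format(split$train$date, "%Y-%m") == "2026-03"))

  two <- make_campaign_features(dates = c("2026-03-04", "2026-04-06"), rooms = "G1")
  s2 <- temporal_split(two$features)
  expect_equal(nrow(s2$train), n_spots(two$plan))
  expect_equal(nrow(s2$test), n_spots(two$plan))

  one_month <- make_campaign_features(dates = c("2026-03-04", "2026-03-11"))
  expect_error(temporal_split(one_month$features), "2 calendar months")

  # a room with no final-month session is absent from test, with a warning
  rows <- data.frame(date = as.Date(c("2026-03-04", "2026-03-04", "2026-04-06")),
                     room = c("G1", "G2", "G1"))
  expect_warning(s3 <- temporal_split(rows), "G2")
  expect_false("G2" %in% s3$test$room)
})

test_that("the identity mapping is learnable and training is deterministic", {
  fx <- make_campaign_features(spots_per_layer = 60L, model = error_model())
  split <- temporal_split(fx$features)
  cfg <- model_config(n_trees = 400L, seed = 7L)
  mx <- train_axis_model(split$train, "x", cfg)
  pred <- predict(mx, split$test)
  expect_lt(mean((pred - split$test$target_x)^2), 1e-6)

  mx2 <- train_axis_model(split$train, "x", cfg)
  expect_identical(predict(mx2, split$test), pred)

  expect_error(train_axis_model(split$train[1:50, ], "x", cfg), "at least 100")
  const <- split$train
  const$target_x <- 1
  expect_warning(train_axis_model(const, "x", model_config(n_trees = 2L)), "constant")
})

test_that("evaluation metrics follow their definitions", {
  # hand-checked arithmetic: A = (0,1,2), P = (0,1,1)
  expect_equal(unname(protonqa:::.axis_metrics(c(0, 1, 2), c(0, 1, 1))),
               c(1 / 3, 0.5))
  # constant predictor at the target mean has R^2 = 0; perfect prediction R^2 = 1
  y <- c(4, 5, 7, 9)
  expect_equal(protonqa:::.r2(y, rep(mean(y), 4L)), 0)
  expect_equal(protonqa:::.r2(y, y), 1)
  expect_true(is.na(protonqa:::.r2(rep(1, 4L), rep(1, 4L)))) # zero SST

  fx <- make_campaign_features(spots_per_layer = 60L)
  split <- temporal_split(fx$features)
  cfg <- model_config(n_trees = 60L, seed = 7L)
  mx <- train_axis_model(split$train, "x", cfg)
  my <- train_axis_model(split$train, "y", cfg)
  ev <- evaluate_models(mx, my, split$test)

  # oracle: straightforward recomputation from stored predictions
  px <- predict(mx, split$test); py <- predict(my, split$test)
  expect_equal(unname(ev$overall["mse_x"]), mean((split$test$target_x - px)^2))
  expect_equal(unname(ev$overall["r2_y"]),
               1 - sum((split$test$target_y - py)^2) /
                 sum((split$test$target_y - mean(split$test$target_y))^2))
  euclid <- sqrt((split$test$target_x - px)^2 + (split$test$target_y - py)^2)
  expect_equal(unname(ev$overall["euclid_mean"]), mean(euclid))
  expect_equal(unname(ev$overall["euclid_max"]), max(euclid))
  expect_gte(ev$overall["euclid_max"], ev$overall["euclid_mean"])
  expect_equal(ev$cross_axis_r,
               cor(split$test$target_x - split$test$planned_x,
                   split$test$target_y - split$test$planned_y))
  expect_equal(sum(ev$by_session$n), ev$n)
  expect_error(evaluate_models(mx, my, split$test[0, ]), "non-empty")
})

test_that("the trained model never loses to the identity baseline on test MSE", {
  fx <- make_campaign_features(spots_per_layer = 60L)
  split <- temporal_split(fx$features)
  cfg <- model_config(n_trees = 150L, seed = 3L)
  mx <- train_axis_model(split$train, "x", cfg)
  model_mse <- mean((predict(mx, split$test) - split$test$target_x)^2)
  identity_mse <- mean((split$test$planned_x - split$test$target_x)^2)
  expect_lte(model_mse, identity_mse)
})

test_that("gain importances are normalized and track the informative feature", {
  fx <- make_campaign_features(spots_per_layer = 60L)
  split <- temporal_split(fx$features)
  mx <- train_axis_model(split$train, "x", model_config(n_trees = 60L, seed = 7L))
  imp <- feature_importance(mx)
  expect_equal(sum(imp$gain), 1, tolerance = 1e-9)
  expect_true(all(imp$gain >= 0))
  expect_setequal(imp$feature, c("planned_x", "planned_y", "energy",
                                 "date_ordinal", "room_code"))
  # the target is planned_x plus small errors: planned_x must dominate
  expect_equal(imp$feature[1L], "planned_x")
  expect_gt(imp$gain[1L], 0.5)
})
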