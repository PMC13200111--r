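test_that("distribution summaries use the sample SD and expose the Gaussian fit", {
  s <- summarize_deviations(c(1, 1, 1))
  expect_equal(s$mean, 1)
  expect_equal(s$sd, 0)
  s <- summarize_deviations(c(0, 2))
  expect_equal(s$mean, 1)
  expect_equal(s$sd, sqrt(2))
  expect_equal(unname(s$gaussian_fit), c(1, sqrt(2)))
  expect_error(summarize_deviations(numeric(0)), "non-empty")

  set.seed(163)
  draws <- rnorm(1e6, 0.163, 0.199)
  s <- summarize_deviations(draws)
  expect_lt(abs(s$mean - 0.163), 3 * 0.199 / 1000)
})

test_that("expected squared distance equals the sum of squared means and variances", {
  expect_equal(round(expected_squared_distance(0.163, 0.199, 0.096, 0.151), 3), 0.098)
  expect_equal(expected_squared_distance(0, 0, 0, 0), 0)
  # Monte-Carlo oracle at a different parameter set
  set.seed(99)
  dx <- rnorm(1e6, 0.5, 0.2); dy <- rnorm(1e6, 0, 0.3)
  mc <- mean(dx^2 + dy^2)
  se <- sd(dx^2 + dy^2) / 1000
  expect_lt(abs(expected_squared_distance(0.5, 0.2, 0, 0.3) - mc), 3 * se)
})

test_that("Levene's test detects variance heterogeneity and matches car's mean-centered form", {
  g <- rnorm(50)
  res <- levene_test(list(g, g))
  expect_equal(res$statistic, 0)

  set.seed(5)
  het <- list(rnorm(200, 0, 1), rnorm(200, 0, 10))
  expect_lt(levene_test(het)$p_value, 0.05)

  vals <- unlist(het)
  grp <- factor(rep(1:2, each = 200))
  ref <- car::leveneTest(vals, grp, center = mean)
  expect_equal(levene_test(het)$statistic, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(levene_test(het)$p_value, ref[1, "Pr(>F)"], tolerance = 1e-10)

  # null behaviour: p rarely extreme when groups share a distribution
  set.seed(7)
  ps <- replicate(200, levene_test(list(rnorm(100), rnorm(100)))$p_value)
  expect_gte(mean(ps > 0.001), 0.99)
  expect_error(levene_test(list(rnorm(5), 1)), "at least 2")
})

test_that("Welch's ANOVA matches the reference implementation and the t-test identity", {
  set.seed(11)
  g <- list(rnorm(50, 0, 1), rnorm(50, 1, 3))
  res <- welch_anova(g)
  ref <- oneway.test(v ~ f, data.frame(v = unlist(g), f = factor(rep(1:2, each = 50))),
                     var.equal = FALSE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-6)
  expect_equal(res$df2, unname(ref$parameter["denom df"]), tolerance = 1e-6)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-6)

  tt <- t.test(g[[2]], g[[1]])
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-9)

  # three groups, heteroscedastic: still matches oneway.test
  set.seed(12)
  g3 <- list(rnorm(40, 0, 1), rnorm(60, 0.5, 2), rnorm(80, 1, 4))
  res3 <- welch_anova(g3)
  ref3 <- oneway.test(v ~ f, data.frame(v = unlist(g3), f = factor(rep(1:3, c(40, 60, 80)))),
                      var.equal = FALSE)
  expect_equal(res3$statistic, unname(ref3$statistic), tolerance = 1e-6)
  expect_equal(res3$p_value, ref3$p.value, tolerance = 1e-6)

  expect_error(welch_anova(list(rep(1, 10), rnorm(10))), "zero-variance")
})

test_that("Welch's F agrees with the classic one-way F under homoscedastic balance", {
  # exact identity for two groups (the small-sample correction carries k - 2)
  set.seed(21)
  a <- rnorm(30); b <- rnorm(30)
  b <- (b - mean(b)) / sd(b) * sd(a) + mean(b) # equal sample variances
  classic <- anova(lm(v ~ f, data.frame(v = c(a, b), f = factor(rep(1:2, each = 30)))))
  expect_equal(welch_anova(list(a, b))$statistic, classic[1, "F value"], tolerance = 1e-10)

  # k = 3: converges at rate O(1/n)
  for (n in c(50, 5000)) {
    set.seed(n)
    g <- lapply(1:3, function(i) rnorm(n, i * 0.01, 1))
    g <- lapply(g, function(x) (x - mean(x)) / sd(x) + mean(x))
    classic <- anova(lm(v ~ f, data.frame(v = unlist(g), f = factor(rep(1:3, each = n)))))
    rel_gap <- abs(welch_anova(g)$statistic / classic[1, "F value"] - 1)
    expect_lt(rel_gap, 2 / (n - 1))
  }
})

test_that("Games-Howell isolates the shifted group and matches Welch's t for two groups", {
  set.seed(31)
  g <- rnorm(100)
  res <- games_howell(list(a = g, b = g, c = g))
  expect_equal(res$diff, rep(0, 3))
  expect_equal(res$p_value, rep(1, 3))

  set.seed(32)
  shifted <- list(a = rnorm(100), b = rnorm(100), c = rnorm(100, 5))
  res <- games_howell(shifted)
  involving_c <- res$group1 == "c" | res$group2 == "c"
  expect_true(all(res$p_value[involving_c] < 0.01))
  expect_true(all(res$p_value[!involving_c] > 0.05))

  set.seed(33)
  two <- list(rnorm(60, 0, 1), rnorm(40, 0.6, 2))
  gh <- games_howell(two)
  tt <- t.test(two[[2]], two[[1]])
  expect_equal(gh$p_value, tt$p.value, tolerance = 1e-3)
  expect_equal(gh$df, unname(tt$parameter), tolerance = 1e-9)
})

test_that("moving-window flags match a brute-force window re-scan", {
  tol <- tolerance_config(annual_mm = 1.0, daily_mm = 2.0, window = 50L)

  dev <- synthetic_deviations(numeric(600), numeric(600))
  fr <- moving_window_flags(dev, tol)
  expect_equal(fr$summary$n_annual, 0L)

  dev <- synthetic_deviations(rep(1.1, 600), numeric(600),
                              layer_index = rep(1:3, each = 200))
  fr <- moving_window_flags(dev, tol)
  expect_equal(fr$summary$n_annual, 600L)
  expect_equal(fr$affected_layers[[1]], 1:3)
  expect_true(all(fr$per_spot$tier == "annual"))

  # offset confined to layers 5-8 of a 20-layer session with jitter
  set.seed(41)
  layer <- rep(1:20, each = 60)
  dx <- rnorm(1200, 0, 0.2) + ifelse(layer %in% 5:8, 1.1, 0)
  dy <- rnorm(1200, 0, 0.2)
  dev <- synthetic_deviations(dx, dy, layer_index = layer)
  fr <- moving_window_flags(dev, tol)
  oracle <- brute_force_flags(dx, 1.0, 50L) | brute_force_flags(dy, 1.0, 50L)
  expect_equal(fr$summary$n_annual, sum(oracle))
  expect_equal(fr$per_spot$tier != "none", oracle)
  flagged_layers <- unique(layer[oracle])
  expect_true(all(fr$affected_layers[[1]] %in% flagged_layers))
  expect_gte(mean(layer[oracle] %in% 5:8), 0.9)

  expect_error(moving_window_flags(synthetic_deviations(rnorm(10), rnorm(10)), tol),
               "window")
})

test_that("running means are trailing within-session windows", {
  dev <- synthetic_deviations(c(rep(0, 4), rep(2, 4)), numeric(8))
  fr <- moving_window_flags(dev, tolerance_config(window = 4L))
  expect_true(all(is.na(fr$per_spot$run_mean_x[1:3])))
  expect_equal(fr$per_spot$run_mean_x[4:8], c(0, 0.5, 1, 1.5, 2))
})

test_that("factor analysis runs the heteroscedastic battery per factor", {
  set.seed(51)
  n <- 400
  dev <- rbind(
    synthetic_deviations(rnorm(n, 0.3, 0.2), rnorm(n, 0, 0.15), room = "G1"),
    synthetic_deviations(rnorm(n, -0.2, 0.2), rnorm(n, 0, 0.15), room = "G2")
  )
  class(dev) <- c("deviation_table", "data.frame")
  fa <- factor_analysis(dev, "room", "dx")
  expect_s3_class(fa, "factor_analysis")
  expect_lt(fa$welch$p_value, 0.05)
  expect_equal(nrow(fa$groups), 2L)
  expect_equal(nrow(fa$games_howell), 1L)

  # null: i.i.d. jitter only, no factor effects
  set.seed(52)
  ps <- replicate(20, {
    d <- rbind(
      synthetic_deviations(rnorm(150, 0, 0.2), rnorm(150, 0, 0.2), room = "G1"),
      synthetic_deviations(rnorm(150, 0, 0.2), rnorm(150, 0, 0.2), room = "G2")
    )
    class(d) <- c("deviation_table", "data.frame")
    factor_analysis(d, "room", "dx")$welch$p_value
  })
  expect_gte(mean(ps > 0.05), 0.9)

  single <- synthetic_deviations(rnorm(50), rnorm(50), room = "G1")
  expect_warning(res <- factor_analysis(single, "room", "dx"), "skipped")
  expect_null(res)

  uneven <- rbind(
    synthetic_deviations(rnorm(50), rnorm(50), energy = 100),
    synthetic_deviations(rnorm(1), rnorm(1), energy = 110),
    synthetic_deviations(rnorm(50), rnorm(50), energy = 120)
  )
  class(uneven) <- c("deviation_table", "data.frame")
  expect_warning(res <- factor_analysis(uneven, "energy", "dx"), "singleton")
  expect_equal(nrow(res$groups), 2L)
})
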