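#' Distribution summary with Gaussian density fit
#'
#' Moments of a deviation sample, plus the `(mu, sigma)` of the Gaussian
#' density overlaid on its histogram (the maximum-likelihood normal fit,
#' i.e. the sample mean and sample SD).
#'
#' @param values Numeric vector, length >= 1.
#' @return A list with `n`, `mean`, `sd` (sample, n-1 denominator; `NA` for
#'   n = 1), `min`, `max`, and `gaussian_fit = c(mu, sigma)`.
#' @export
summarize_deviations <- function(values) {
  .assert(is.numeric(values) && length(values) >= 1L, "values must be a non-empty numeric vector")
  .assert(all(is.finite(values)), "values must be finite")
  m <- mean(values)
  s <- stats::sd(values)
  list(n = length(values), mean = m, sd = s, min = min(values), max = max(values),
       gaussian_fit = c(mu = m, sigma = s))
}

#' Expected squared Euclidean spot-position deviation
#'
#' Under independent normal per-axis errors, the squared Euclidean distance
#' is a (scaled, noncentral) chi-square-type variable with two degrees of
#' freedom whose mean is `mu_x^2 + sd_x^2 + mu_y^2 + sd_y^2`.
#'
#' @param mu_x,sd_x,mu_y,sd_y Per-axis mean and SD in mm (`sd >= 0`).
#' @return Expected squared distance in mm².
#' @export
#' @examples
#' expected_squared_distance(0.163, 0.199, 0.096, 0.151) # ~0.098 mm^2
expected_squared_distance <- function(mu_x, sd_x, mu_y, sd_y) {
  .assert(sd_x >= 0 && sd_y >= 0, "SDs must be >= 0")
  mu_x^2 + sd_x^2 + mu_y^2 + sd_y^2
}

.as_group_list <- function(groups, min_n = 2L) {
  .assert(is.list(groups) && length(groups) >= 2L, "need at least 2 groups")
  groups <- lapply(groups, function(g) as.numeric(g[is.finite(g)]))
  ns <- lengths(groups)
  .assert(all(ns >= min_n), "every group needs at least %d observations", min_n)
  groups
}

#' Levene's test for homogeneity of variance
#'
#' Classic mean-centered Levene statistic: a one-way ANOVA F on the absolute
#' deviations from each group's center, referred to F(k-1, N-k). The center
#' is the group mean by default (Levene's original proposal); `center =
#' "median"` gives the Brown-Forsythe variant.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @param center `"mean"` or `"median"`.
#' @return List with `statistic` (W), `df1`, `df2`, `p_value`.
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- .as_group_list(groups)
  cfun <- if (center == "mean") mean else stats::median
  z <- lapply(groups, function(g) abs(g - cfun(g)))
  k <- length(z)
  ns <- lengths(z)
  N <- sum(ns)
  zbar_i <- vapply(z, mean, 0)
  zbar <- sum(ns * zbar_i) / N
  num <- sum(ns * (zbar_i - zbar)^2) / (k - 1)
  den <- sum(vapply(z, function(zi) sum((zi - mean(zi))^2), 0)) / (N - k)
  W <- if (den == 0) {
    if (num == 0) 0 else Inf
  } else num / den
  list(statistic = W, df1 = k - 1, df2 = N - k,
       p_value = stats::pf(W, k - 1, N - k, lower.tail = FALSE))
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch's F statistic with the Satterthwaite-type denominator degrees of
#' freedom, the standard choice when group variances differ. Reduces to
#' Welch's t-test (F = t²) for two groups.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2, each with
#'   nonzero variance).
#' @return List with `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
welch_anova <- function(groups) {
  groups <- .as_group_list(groups)
  v <- vapply(groups, stats::var, 0)
  .assert(all(v > 0), "Welch's ANOVA is undefined for zero-variance groups")
  k <- length(groups)
  ns <- lengths(groups)
  m <- vapply(groups, mean, 0)
  w <- ns / v
  W <- sum(w)
  mw <- sum(w * m) / W
  a <- sum((1 - w / W)^2 / (ns - 1)) / (k^2 - 1)
  F_stat <- sum(w * (m - mw)^2) / (k - 1) / (1 + 2 * (k - 2) * a)
  df2 <- 1 / (3 * a)
  list(statistic = F_stat, df1 = k - 1, df2 = df2,
       p_value = stats::pf(F_stat, k - 1, df2, lower.tail = FALSE))
}

#' Games-Howell post hoc pairwise comparisons
#'
#' All pairwise mean comparisons without assuming equal variances: for each
#' pair, `q = |m_i - m_j| / sqrt((s_i^2/n_i + s_j^2/n_j) / 2)` with
#' Welch-Satterthwaite degrees of freedom, referred to the studentized range
#' distribution with `k` groups (so the familywise studentized-range
#' correction is built in).
#'
#' @param groups Named or unnamed list of numeric vectors (>= 2 groups, each
#'   n >= 2, nonzero variance).
#' @return A `data.frame` with one row per pair: `group1`, `group2`, `diff`
#'   (mean difference, group2 - group1), `se`, `df`, `q`, `p_value`.
#' @export
games_howell <- function(groups) {
  groups <- .as_group_list(groups)
  v <- vapply(groups, stats::var, 0)
  .assert(all(v > 0), "Games-Howell is undefined for zero-variance groups")
  k <- length(groups)
  nm <- names(groups) %||% as.character(seq_len(k))
  ns <- lengths(groups)
  m <- vapply(groups, mean, 0)
  pairs <- utils::combn(k, 2L)
  out <- data.frame(group1 = nm[pairs[1L, ]], group2 = nm[pairs[2L, ]],
                    diff = NA_real_, se = NA_real_, df = NA_real_,
                    q = NA_real_, p_value = NA_real_)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    se2 <- v[i] / ns[i] + v[j] / ns[j]
    df <- se2^2 / ((v[i] / ns[i])^2 / (ns[i] - 1) + (v[j] / ns[j])^2 / (ns[j] - 1))
    diff <- m[j] - m[i]
    q <- abs(diff) / sqrt(se2 / 2)
    out$diff[p] <- diff
    out$se[p] <- sqrt(se2)
    out$df[p] <- df
    out$q[p] <- q
    out$p_value[p] <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
  }
  out
}

#' Tolerance configuration for moving-window flagging
#'
#' @param annual_mm Annual QA spot-position tolerance in mm (TG-224: 1 mm).
#' @param daily_mm Daily QA spot-position tolerance in mm (2 mm, the
#'   conventional daily tolerance; configurable).
#' @param window Moving-window length in consecutive spots.
#' @return An object of class `tolerance_config`.
#' @export
tolerance_config <- function(annual_mm = 1.0, daily_mm = 2.0, window = 50L) {
  .assert(annual_mm > 0 && daily_mm > 0, "tolerances must be > 0")
  .assert(.is_count(window) && window >= 1, "window must be a positive integer")
  structure(list(annual_mm = annual_mm, daily_mm = daily_mm, window = as.integer(window)),
            class = "tolerance_config")
}

# Trailing-window means of v for windows 1..n-w+1 (window j covers j..j+w-1).
.window_means <- function(v, w) {
  cs <- cumsum(v)
  (cs[w:length(v)] - c(0, cs[seq_len(length(v) - w)])) / w
}

# Spots covered by any window whose |mean| exceeds tol; O(n) via a
# difference-array of window coverage.
.flag_covered <- function(wm, tol, n, w) {
  exceed <- which(abs(wm) > tol)
  if (length(exceed) == 0L) return(logical(n))
  delta <- integer(n + 1L)
  for (j in exceed) {
    delta[j] <- delta[j] + 1L
    delta[j + w] <- delta[j + w] - 1L
  }
  cumsum(delta[seq_len(n)]) > 0L
}

#' Moving-window systematic-error flags
#'
#' Within each session (never across sessions), running means of the per-axis
#' deviations are computed over every contiguous window of `window` spots in
#' delivery order. A spot is flagged at a tier if any window containing it
#' has an absolute running mean above that tier's tolerance on either axis;
#' tiers are `"annual"` and `"daily"` (daily implies annual for the default
#' tolerances). Per-axis counts are reported alongside the union counts.
#'
#' @param table A `deviation_table` (from [compute_deviations()] /
#'   [bind_deviations()]), covering whole sessions.
#' @param tol A [tolerance_config()].
#' @return A list of class `flag_report`:
#'   `per_spot` — data.frame with `room`, `date`, `layer_index`,
#'   `spot_index`, trailing running means `run_mean_x`, `run_mean_y` (NA for
#'   the first `window - 1` spots), and `tier` (`"none"`, `"annual"`,
#'   `"daily"`);
#'   `summary` — per-session flag counts (union and per-axis);
#'   `affected_layers` — per-session list of layers containing flagged spots;
#'   `tol` — the configuration used.
#' @export
moving_window_flags <- function(table, tol = tolerance_config()) {
  .assert(inherits(table, "deviation_table") || is.data.frame(table),
          "table must be a deviation_table")
  .assert(inherits(tol, "tolerance_config"), "tol must be a tolerance_config")
  w <- tol$window
  key <- paste(table$room, format(table$date))
  per_spot <- vector("list", 0L)
  summaries <- vector("list", 0L)
  affected <- list()
  for (s in unique(key)) {
    rows <- table[key == s, , drop = FALSE]
    n <- nrow(rows)
    .assert(w <= n, "window (%d) larger than session '%s' (%d spots)", w, s, n)
    wmx <- .window_means(rows$dx, w)
    wmy <- .window_means(rows$dy, w)
    fl <- list()
    for (tier in c("annual", "daily")) {
      lim <- if (tier == "annual") tol$annual_mm else tol$daily_mm
      fl[[paste0(tier, "_x")]] <- .flag_covered(wmx, lim, n, w)
      fl[[paste0(tier, "_y")]] <- .flag_covered(wmy, lim, n, w)
    }
    annual <- fl$annual_x | fl$annual_y
    daily <- fl$daily_x | fl$daily_y
    tier <- ifelse(daily, "daily", ifelse(annual, "annual", "none"))
    per_spot[[s]] <- data.frame(
      room = rows$room, date = rows$date,
      layer_index = rows$layer_index, spot_index = rows$spot_index,
      run_mean_x = c(rep(NA_real_, w - 1L), wmx),
      run_mean_y = c(rep(NA_real_, w - 1L), wmy),
      tier = tier
    )
    summaries[[s]] <- data.frame(
      room = rows$room[1L], date = rows$date[1L], n_spots = n,
      n_annual = sum(annual), n_daily = sum(daily),
      n_annual_x = sum(fl$annual_x), n_annual_y = sum(fl$annual_y),
      n_daily_x = sum(fl$daily_x), n_daily_y = sum(fl$daily_y)
    )
    affected[[s]] <- sort(unique(rows$layer_index[annual]))
  }
  structure(list(per_spot = do.call(rbind, c(per_spot, list(make.row.names = FALSE))),
                 summary = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
                 affected_layers = affected, tol = tol),
            class = "flag_report")
}

#' @export
print.flag_report <- function(x, ...) {
  cat(sprintf("<flag_report> %d sessions, window %d, tolerances %.2g/%.2g mm\n",
              nrow(x$summary), x$tol$window, x$tol$annual_mm, x$tol$daily_mm))
  flagged <- x$summary[x$summary$n_annual > 0, , drop = FALSE]
  if (nrow(flagged) == 0L) cat("  no spots exceed tolerance\n") else print(flagged)
  invisible(x)
}

#' Factor analysis of deviations (Levene + Welch ANOVA + Games-Howell)
#'
#' Groups a deviation response by one factor (energy, date, or room) and runs
#' the heteroscedastic test battery: Levene's test for homogeneity of
#' variance, Welch's ANOVA for mean differences, and Games-Howell post hoc
#' pairwise comparisons. Levels with fewer than two observations are dropped
#' with a warning; if fewer than two levels remain the analysis is skipped
#' (returns `NULL` with a warning).
#'
#' @param table A `deviation_table`.
#' @param factor One of `"energy"`, `"date"`, `"room"`.
#' @param response One of `"dx"`, `"dy"`, `"d"`, `"dmu"`.
#' @return `NULL`, or a list of class `factor_analysis` with `factor`,
#'   `response`, `groups` (per-level summary data.frame), `levene`, `welch`,
#'   `games_howell`.
#' @export
factor_analysis <- function(table, factor = c("energy", "date", "room"),
                            response = c("dx", "dy", "d", "dmu")) {
  factor <- match.arg(factor)
  response <- match.arg(response)
  labels <- switch(factor, energy = table$energy, date = format(table$date),
                   room = table$room)
  groups <- split(table[[response]], labels)
  small <- lengths(groups) < 2L
  if (any(small)) {
    warning(sprintf("excluding singleton %s level(s): %s", factor,
                    paste(names(groups)[small], collapse = ", ")), call. = FALSE)
    groups <- groups[!small]
  }
  if (length(groups) < 2L) {
    warning(sprintf("factor '%s' has fewer than 2 usable levels; analysis skipped", factor),
            call. = FALSE)
    return(NULL)
  }
  summaries <- data.frame(
    level = names(groups), n = lengths(groups),
    mean = vapply(groups, mean, 0), sd = vapply(groups, stats::sd, 0),
    row.names = NULL
  )
  structure(list(factor = factor, response = response, groups = summaries,
                 levene = levene_test(groups), welch = welch_anova(groups),
                 games_howell = games_howell(groups)),
            class = "factor_analysis")
}

#' @export
print.factor_analysis <- function(x, ...) {
  cat(sprintf("<factor_analysis> %s by %s (%d levels)\n", x$response, x$factor, nrow(x$groups)))
  cat(sprintf("  Levene W = %.4g (p = %.3g); Welch F = %.4g on (%g, %.1f) df (p = %.3g)\n",
              x$levene$statistic, x$levene$p_value,
              x$welch$statistic, x$welch$df1, x$welch$df2, x$welch$p_value))
  invisible(x)
}

#' Plot per-session running means against tolerances
#'
#' Base-graphics view of one session's trailing running means for both axes
#' with the annual and daily tolerance bands.
#'
#' @param report A `flag_report` from [moving_window_flags()].
#' @param room,date Session selector.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted per-spot subset.
#' @export
plot_running_mean <- function(report, room, date, ...) {
  ps <- report$per_spot
  rows <- ps[ps$room == room & format(ps$date) == format(.as_iso_date(date)), , drop = FALSE]
  .assert(nrow(rows) > 0L, "no session %s @ %s in the report", room, date)
  idx <- seq_len(nrow(rows))
  ylim <- range(c(rows$run_mean_x, rows$run_mean_y, report$tol$daily_mm,
                  -report$tol$daily_mm), na.rm = TRUE)
  graphics::plot(idx, rows$run_mean_x, type = "l", col = "steelblue", ylim = ylim,
                 xlab = "spot index (delivery order)", ylab = "running mean deviation (mm)",
                 main = sprintf("%s @ %s", room, format(rows$date[1L])), ...)
  graphics::lines(idx, rows$run_mean_y, col = "seagreen")
  graphics::abline(h = c(-1, 1) * report$tol$annual_mm, lty = 2, col = "blue")
  graphics::abline(h = c(-1, 1) * report$tol$daily_mm, lty = 2, col = "red")
  graphics::legend("topleft", legend = c("x", "y"), col = c("steelblue", "seagreen"),
                   lty = 1, bty = "n")
  invisible(rows)
}
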