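test_that("beam model tables are physically ordered", {
  bm <- beam_model(c(99.2, 110, 124.8))
  expect_true(all(diff(bm$range_mm) > 0)) # range grows with energy
  expect_true(all(bm$sigma_mm > 0))
  for (c in bm$curves) {
    expect_true(all(c$dd >= 0))
    expect_equal(max(c$dd), 1)
  }
  expect_error(compute_dose(single_spot_plan(energy = 70), bm), "not covered")
})

test_that("dose is linear in MU: superposition is exact", {
  bm <- beam_model(100)
  grid <- grid_spec(origin = c(-20, -20, 0), spacing = 2, shape = c(21, 21, 45))
  one <- compute_dose(single_spot_plan(mu = 2), bm, grid)
  two_halves <- ion_plan("SPOT", 0, energies = 100,
                         spots = data.frame(layer_index = 1L, spot_index = 1:2,
                                            x = 0, y = 0, meterset = 1))
  halves <- compute_dose(two_halves, bm, grid)
  expect_equal(halves$values, one$values, tolerance = 1e-12)
})

test_that("lateral Gaussian integrates to the depth dose over a wide slice", {
  bm <- beam_model(100)
  sigma <- bm$sigma_mm[1]
  half <- ceiling(6 * sigma / 2) * 2
  grid <- grid_spec(origin = c(-half, -half, 0), spacing = 2,
                    shape = c(half + 1, half + 1, 45))
  dg <- compute_dose(single_spot_plan(mu = 2), bm, grid)
  zs <- (seq_len(45) - 1) * 2
  dd <- approx(bm$curves[[1]]$depth, bm$curves[[1]]$dd, xout = zs, yleft = 0,
               yright = 0)$y
  peak <- which.max(dd)
  slice_sum <- sum(dg$values[, , peak])
  expect_equal(slice_sum, 2 * bm$mu_to_dose * dd[peak], tolerance = 0.01)
})

test_that("total dose is invariant under lateral shifts well inside the grid", {
  bm <- beam_model(100)
  grid <- grid_spec(origin = c(-50, -50, 0), spacing = 2, shape = c(51, 51, 45))
  a <- compute_dose(single_spot_plan(0, 0), bm, grid)
  b <- compute_dose(single_spot_plan(8, -6), bm, grid)
  expect_equal(sum(b$values), sum(a$values), tolerance = 0.01)
})

test_that("dose matches a naive voxel-by-voxel recomputation", {
  bm <- beam_model(c(100, 110))
  plan <- ion_plan("P2", 0, energies = c(100, 110),
                   spots = data.frame(layer_index = c(1L, 1L, 2L), spot_index = c(1:2, 1L),
                                      x = c(-4, 6, 0), y = c(0, 2, -4),
                                      meterset = c(1, 2, 1.5)))
  grid <- grid_spec(origin = c(-10, -10, 0), spacing = 4, shape = c(6, 6, 20))
  dg <- compute_dose(plan, bm, grid)

  naive <- array(0, dim = grid$shape)
  for (ix in 1:6) for (iy in 1:6) for (iz in 1:20) {
    vx <- grid$origin[1] + (ix - 1) * 4
    vy <- grid$origin[2] + (iy - 1) * 4
    vz <- grid$origin[3] + (iz - 1) * 4
    acc <- 0
    for (s in seq_len(3)) {
      ei <- match(plan$energies[plan$spots$layer_index[s]], bm$energies)
      curve <- bm$curves[[ei]]
      dd <- approx(curve$depth, curve$dd, xout = vz, yleft = 0, yright = 0)$y
      sg <- bm$sigma_mm[ei]
      g <- exp(-((vx - plan$spots$x[s])^2 + (vy - plan$spots$y[s])^2) / (2 * sg^2)) /
        (2 * pi * sg^2)
      acc <- acc + plan$spots$meterset[s] * bm$mu_to_dose * dd * g * 16
    }
    naive[ix, iy, iz] <- acc
  }
  expect_equal(dg$values, naive, tolerance = 1e-12)
})

test_that("a 2-mm spot shift moves dose by one voxel up to discretization", {
  bm <- beam_model(100)
  grid <- grid_spec(origin = c(-30, -30, 0), spacing = 2, shape = c(31, 31, 45))
  a <- compute_dose(single_spot_plan(0, 0), bm, grid)
  b <- compute_dose(single_spot_plan(2, 0), bm, grid)
  # interior voxels of the shifted grid equal the unshifted grid one index over
  expect_equal(b$values[2:31, , ], a$values[1:30, , ], tolerance = 1e-9)
})

test_that("dose comparisons report congruence-checked voxel statistics", {
  bm <- beam_model(100)
  grid <- grid_spec(origin = c(-20, -20, 0), spacing = 2, shape = c(21, 21, 45))
  a <- compute_dose(single_spot_plan(0, 0), bm, grid)

  same <- compare_dose(a, a)
  expect_equal(same$max_abs_voxel_diff, 0)
  expect_equal(same$sd_voxel_diff, 0)
  expect_equal(same$mean_abs_diff_of_means, 0)

  b <- a
  b$values <- a$values + 0.5
  shifted <- compare_dose(a, b)
  expect_equal(shifted$max_abs_voxel_diff, 0.5)
  expect_equal(shifted$sd_voxel_diff, 0)
  expect_equal(shifted$mean_abs_diff_of_means, 0.5)

  other <- compute_dose(single_spot_plan(0, 0), bm,
                        grid_spec(origin = c(-20, -20, 0), spacing = 2,
                                  shape = c(20, 21, 45)))
  expect_error(compare_dose(a, other), "congruent")

  # a 5-mm single-spot perturbation is localized relative to the field volume
  wide <- grid_spec(origin = c(-100, -100, 0), spacing = 4, shape = c(51, 51, 23))
  wa <- compute_dose(single_spot_plan(0, 0), bm, wide)
  pert <- compute_dose(single_spot_plan(5, 0), bm, wide)
  cmp <- compare_dose(wa, pert)
  diffs <- abs(pert$values - wa$values)
  expect_gt(cmp$max_abs_voxel_diff, 0)
  expect_gt(mean(diffs < 0.01 * cmp$max_abs_voxel_diff), 0.95)
})

test_that("spots_to_plan substitutes positions and MU into the template", {
  plan <- tiny_plan(2L, 8L)
  sess <- simulate_session(plan, "G1", "2026-03-04", error_model(), seed = 2L)
  same <- spots_to_plan(sess, plan)
  expect_equal(same$spots$x, plan$spots$x, tolerance = 1e-12)
  expect_equal(same$spots$meterset, plan$spots$meterset, tolerance = 1e-12)
  expect_equal(same$energies, plan$energies)

  preds <- data.frame(x = plan$spots$x + 0.25, y = plan$spots$y - 0.1,
                      meterset = plan$spots$meterset)
  sub <- spots_to_plan(preds, plan)
  expect_equal(sub$spots$x, plan$spots$x + 0.25)
  expect_equal(sub$spots$y, plan$spots$y - 0.1)

  path <- withr::local_tempfile(fileext = ".dcm")
  write_ion_plan(sub, path)
  back <- read_ion_plan(path)
  expect_equal(back$spots$x, sub$spots$x, tolerance = 1e-6)

  expect_error(spots_to_plan(preds[-1, ], plan), "synchronization")
})
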