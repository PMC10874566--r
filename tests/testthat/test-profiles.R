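test_that("a constant image profiles to a constant value in every covered bin", {
  img <- projection_image(matrix(3.5, 64, 64), "retro", 1)
  ax <- axis_spec(c(32, 32), 0, strip_width_um = 20, bin_um = 8,
                  extent_um = 24)
  p <- profile_axis(img, ax)
  expect_true(all(p$values == 3.5))
  expect_equal(diff(p$positions_mm), rep(0.008, length(p$positions_mm) - 1))
})

test_that("strip profiles match the per-pixel loop oracle", {
  set.seed(12)
  mat <- matrix(stats::runif(128 * 128, 0, 100), 128, 128)
  img <- projection_image(mat, "retro", 1)
  for (ang in c(0, 30, 90, -45)) {
    ax <- axis_spec(c(63.7, 64.2), ang, strip_width_um = 30, bin_um = 10,
                    extent_um = 50)
    p <- profile_axis(img, ax)
    expect_equal(p$values, oracle_profile(mat, 1, ax), tolerance = 1e-6)
  }
  # non-unit pixel size
  ax <- axis_spec(c(100, 90), 15, strip_width_um = 40, bin_um = 12,
                  extent_um = 60)
  img2 <- projection_image(mat, "retro", 1.6)
  expect_equal(profile_axis(img2, ax)$values, oracle_profile(mat, 1.6, ax),
               tolerance = 1e-6)
})

test_that("a bright vertical stripe peaks at its x position", {
  mat <- matrix(1, 100, 100)
  mat[, 41:43] <- 200
  img <- projection_image(mat, "retro", 1)
  ax <- axis_spec(c(50, 50), 0, strip_width_um = 40, bin_um = 5,
                  extent_um = 45)
  p <- profile_axis(img, ax)
  peak_um <- p$positions_mm[p$peak_index] * 1000 + 50
  expect_lt(abs(peak_um - 41.5), 5)
})

test_that("rotating the axis by 90 degrees on the transposed image is a symmetry", {
  set.seed(13)
  mat <- matrix(stats::runif(80 * 80), 80, 80)
  ax_h <- axis_spec(c(40.3, 37.3), 0, strip_width_um = 24, bin_um = 8,
                    extent_um = 32)
  ax_v <- axis_spec(c(37.3, 40.3), 90, strip_width_um = 24, bin_um = 8,
                    extent_um = 32)
  p_h <- profile_axis(projection_image(mat, "retro", 1), ax_h)
  p_v <- profile_axis(projection_image(t(mat), "retro", 1), ax_v)
  expect_equal(p_h$values, p_v$values)
})

test_that("the strip must intersect the image", {
  img <- projection_image(matrix(1, 32, 32), "retro", 1)
  ax <- axis_spec(c(500, 500), 0, strip_width_um = 10, extent_um = 20)
  expect_error(profile_axis(img, ax), "outside")
})

test_that("z-scoring standardizes with the population SD", {
  img <- projection_image(matrix(1, 8, 8), "retro", 1)
  ax <- axis_spec(c(4, 4), 0, strip_width_um = 8, bin_um = 2, extent_um = 3)
  p <- profile_axis(img, ax)
  p$values <- c(1, 2, 3)
  p$positions_mm <- c(-0.002, 0, 0.002)
  z <- zscore_profile(p)
  expect_equal(z$values, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-4)
  expect_equal(round(z$values[3], 4), 1.2247)
  # any profile: mean 0, SD 1 within 1e-9
  set.seed(14)
  p$values <- stats::runif(3, 1, 9)
  z2 <- zscore_profile(p)
  expect_lt(abs(mean(z2$values)), 1e-9)
  expect_lt(abs(sqrt(mean(z2$values^2)) - 1), 1e-9)
  # degenerate constant profile: all zeros, flagged
  p$values <- c(2, 2, 2)
  z3 <- zscore_profile(p)
  expect_true(all(z3$values == 0))
  expect_true(z3$degenerate)
})

test_that("peak ties break toward the bin closest to the axis origin", {
  img <- projection_image(matrix(1, 8, 8), "retro", 1)
  ax <- axis_spec(c(4, 4), 0, strip_width_um = 8, bin_um = 2, extent_um = 5)
  p <- profile_axis(img, ax)
  p$values <- c(1, 5, 2, 2, 5)
  p$positions_mm <- c(-4, -2, 0, 2, 4) / 1000
  p2 <- clamap:::new_profile(p$channel, p$axis, p$positions_mm, p$values)
  expect_equal(p2$positions_mm[p2$peak_index], -0.002)
})

test_that("realignment puts every reference peak at zero and averages shifted slices", {
  mk_prof <- function(values, positions_mm, channel = "retro") {
    img <- projection_image(matrix(1, 4, 4), channel, 1)
    ax <- axis_spec(c(2, 2), 0, strip_width_um = 4, bin_um = 2, extent_um = 4)
    p <- profile_axis(img, ax)
    clamap:::new_profile(channel, p$axis, positions_mm, values)
  }
  base <- c(0.1, 0.4, 1.0, 0.5, 0.2, 0.1)
  pos <- seq(-0.05, 0.05, by = 0.02)
  s1 <- list(retro = mk_prof(base, pos))
  # the same profile translated by 0.3 bins' worth of position labels:
  # values shifted one bin along the grid
  s2 <- list(retro = mk_prof(c(base[-1], 0.05), pos))
  out <- realign_and_average(list(a = s1, b = s2), "retro")
  for (sl in out$aligned) {
    ref <- sl$retro
    expect_equal(ref$positions_mm[ref$peak_index], 0)
  }
  env <- out$envelope
  # bins covered by both slices have SD 0 because the profiles are identical
  # up to the shift
  common <- env[env$n == 2, ]
  expect_true(all(abs(common$sd) < 1e-12))
  # single slice: mean equals the shifted profile
  one <- realign_and_average(list(a = s1), "retro")
  expect_equal(one$envelope$mean, base)
  flat <- zscore_profile(mk_prof(rep(1, 6), pos))
  expect_error(realign_and_average(list(a = list(retro = flat)), "retro"),
               "degenerate")
})
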