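test_that("z-stack convention gives 11 planes for 2 um steps over 20 um", {
  cfg <- generator_config()
  expect_identical(cfg$n_z, 11L)
  expect_identical(cfg$frame_px, 1024L)
  # inclusive endpoints also at other depths
  expect_identical(generator_config(z_step_um = 5, z_depth_um = 20)$n_z, 5L)
})

test_that("config validation rejects bad inputs", {
  expect_error(generator_config(pixel_um = 0), "pixel_um")
  expect_error(generator_config(coloc_fractions = c("retro:Nurr1" = 1.2)),
               "\\[0, 1\\]")
  expect_error(generator_config(coloc_fractions = c("retro:Missing" = 0.5)),
               "absent")
  dens <- default_densities(); dens$enriched["retro"] <- -1
  expect_error(generator_config(densities = dens), ">= 0")
})

test_that("zero densities give an empty ground truth", {
  cfg <- small_config()
  cfg$densities <- list(enriched = c(retro = 0), ring = c(Tle4 = 0))
  tr <- sample_cells(cfg)
  expect_identical(nrow(tr$cells), 0L)
})

test_that("a colocalization fraction of 1 forces full membership", {
  cfg <- small_config(seed = 3)
  cfg$coloc_fractions["retro:Nurr1"] <- 1.0
  tr <- sample_cells(cfg)
  retro <- tr$cells[tr$cells$primary == "retro", ]
  expect_gt(nrow(retro), 0)
  expect_true(all(retro$Nurr1))
})

test_that("realized colocalization fraction converges to the configured one", {
  # binomial oracle: pooled fraction within 3 SE of f at n >= 5000
  f <- 0.87
  n_tot <- 0; n_pos <- 0; s <- 0
  while (n_tot < 10000) {
    s <- s + 1
    tr <- sample_cells(small_config(seed = s, density_scale = 20))
    retro <- tr$cells[tr$cells$primary == "retro", ]
    n_tot <- n_tot + nrow(retro)
    n_pos <- n_pos + sum(retro$Nurr1)
  }
  se <- sqrt(f * (1 - f) / n_tot)
  expect_lt(abs(n_pos / n_tot - f), 3 * se)
})

test_that("zone labels agree with a direct point-in-region oracle", {
  tr <- sample_cells(small_config(seed = 11))
  g <- tr$geometry
  th <- g$orientation_deg * pi / 180
  r2 <- function(x, y, grow) {
    u <- cos(th) * (x - g$center_um[1]) + sin(th) * (y - g$center_um[2])
    v <- -sin(th) * (x - g$center_um[1]) + cos(th) * (y - g$center_um[2])
    (u / (g$axes_um[1] + grow))^2 + (v / (g$axes_um[2] + grow))^2
  }
  cells <- tr$cells
  inner <- g$devoid_margin_um; outer <- inner + g$ring_width_um
  expect_true(all(r2(cells$x_um, cells$y_um, 0)[cells$zone == "enriched"] <= 1))
  ring <- cells[cells$zone == "ring", ]
  expect_true(all(r2(ring$x_um, ring$y_um, outer) <= 1 &
                    r2(ring$x_um, ring$y_um, inner) > 1))
  bg <- cells[cells$zone == "background", ]
  # background = outside the outer band, or in the devoid margin gap between
  # the core ellipse and the band
  expect_true(all(r2(bg$x_um, bg$y_um, outer) > 1 |
                    (r2(bg$x_um, bg$y_um, 0) > 1 &
                       r2(bg$x_um, bg$y_um, inner) <= 1)))
  # every cell inside the frame
  expect_true(all(cells$x_um >= 0 & cells$x_um <= 256 &
                    cells$y_um >= 0 & cells$y_um <= 256))
})

test_that("oversized geometry errors and names the offending dimension", {
  geom <- claustrum_geometry(center_um = c(100, 128), axes_um = c(120, 40))
  cfg <- small_config()
  cfg$geometry <- geom
  expect_error(sample_cells(cfg), "along x")
})

test_that("sampling and rendering are deterministic given the seed", {
  cfg <- small_config(seed = 9)
  t1 <- sample_cells(cfg); t2 <- sample_cells(cfg)
  expect_identical(t1$cells, t2$cells)
  v1 <- render_slice(t1, cfg, channels = "retro")
  v2 <- render_slice(t2, cfg, channels = "retro")
  expect_identical(v1$data, v2$data)
})

test_that("rendering an empty truth without noise gives an all-zero stack", {
  cfg <- small_config(noise = FALSE)
  cfg$densities <- list(enriched = c(retro = 0))
  tr <- sample_cells(cfg)
  vol <- render_slice(tr, cfg, channels = "retro")
  expect_true(all(vol$data == 0))
})

test_that("a single noiseless cell projects to a peak at its true centroid", {
  cfg <- small_config(noise = FALSE)
  tr <- grid_truth(256, 128, jitter_um = 5, seed = 4)
  tr$cells <- tr$cells[1, , drop = FALSE]
  vol <- render_slice(tr, cfg, channels = "retro")
  mp <- max_project(vol, "retro")
  peak <- which(mp$data == max(mp$data), arr.ind = TRUE)[1, ]
  expect_lte(abs((peak["col"] - 1) * cfg$pixel_um - tr$cells$x_um), 1)
  expect_lte(abs((peak["row"] - 1) * cfg$pixel_um - tr$cells$y_um), 1)
})

test_that("noiseless non-overlapping spots deposit equal integrated intensity", {
  cfg <- small_config(noise = FALSE)
  tr <- grid_truth(256, 32, jitter_um = 3, seed = 5) # 49 cells, >= 24 um apart
  vol <- render_slice(tr, cfg, channels = "retro")
  stack <- vol$data[, , , 1]
  # integrate each spot over a window that captures its full mass
  masses <- vapply(seq_len(nrow(tr$cells)), function(k) {
    cx <- round(tr$cells$x_um[k]) + 1; cy <- round(tr$cells$y_um[k]) + 1
    rows <- max(1, cy - 15):min(256, cy + 15)
    cols <- max(1, cx - 15):min(256, cx + 15)
    sum(stack[rows, cols, ])
  }, numeric(1))
  expect_lt(diff(range(masses)) / mean(masses), 0.01)
})

test_that("cohort generation writes the expected artifacts deterministically", {
  cfg <- small_config(density_scale = 2)
  dir1 <- withr::local_tempdir()
  man <- generate_cohort(cfg, n_mice = 1, slices_per_subdivision = 1,
                         out_dir = dir1, master_seed = 5,
                         write_images = FALSE)
  expect_identical(nrow(man), 3L)
  expect_setequal(man$subdivision, c("anterior", "middle", "posterior"))
  expect_length(list.files(dir1, pattern = "_truth\\.csv$"), 3L)
  expect_true(file.exists(file.path(dir1, "manifest.csv")))
  # AP coordinates inside their subdivision ranges and consistent labels
  expect_identical(unname(assign_subdivision(man$ap_mm)), man$subdivision)
  # byte-identical truth tables on rerun with the same master seed
  dir2 <- withr::local_tempdir()
  generate_cohort(cfg, n_mice = 1, slices_per_subdivision = 1,
                  out_dir = dir2, master_seed = 5, write_images = FALSE)
  for (f in list.files(dir1, pattern = "_truth\\.csv$")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  # defaults: 6 mice x 3 subdivisions x 2 slices = 36 slices
  man6 <- generate_cohort(cfg, n_mice = 6, master_seed = 5,
                          write_images = FALSE)
  expect_identical(nrow(man6), 36L)
  # adding a mouse does not perturb existing mice's seeds
  man7 <- generate_cohort(cfg, n_mice = 7, master_seed = 5,
                          write_images = FALSE)
  expect_identical(man6$seed, man7$seed[seq_len(36)])
})
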