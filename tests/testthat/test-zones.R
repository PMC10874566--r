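meta_z <- slice_meta(mouse_id = "m1", ap_mm = 1.0, subdivision = "anterior")

cells_from_xy <- function(x, y, channel = "retro", meta = meta_z) {
  cell_set(channel, data.frame(id = seq_along(x), x_um = x, y_um = y,
                               area_um2 = 50, intensity = 1), meta)
}

test_that("vertex centroid is the plain vertex mean, not the area centroid", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(unname(vertex_centroid(square)), c(0.5, 0.5))
  # subdividing the bottom edge pulls the vertex centroid toward it while
  # the area centroid would stay put
  sub_x <- seq(0, 1, length.out = 11)
  subdivided <- rbind(cbind(sub_x, 0), c(1, 1), c(0, 1))
  ctr <- vertex_centroid(subdivided)
  expect_lt(ctr[2], 0.5)
  expect_equal(unname(ctr[2]), 2 / 13)
  # translation moves the centroid by exactly the same shift
  shifted <- sweep(square, 2, c(-7, 3), "+")
  expect_equal(unname(vertex_centroid(shifted)), c(0.5 - 7, 0.5 + 3))
  expect_error(vertex_centroid(rbind(c(0, 0), c(1, 1))), "degenerate")
})

test_that("point-in-polygon agrees with an independent oracle", {
  skip_if_not_installed("mgcv")
  set.seed(4)
  for (rep in 1:5) {
    pts <- matrix(stats::runif(20, 0, 100), ncol = 2)
    hull <- pts[grDevices::chull(pts), ]
    qx <- stats::runif(200, -10, 110); qy <- stats::runif(200, -10, 110)
    mine <- point_in_polygon(qx, qy, hull[, 1], hull[, 2])
    bnd <- rbind(hull, hull[1, ])
    oracle <- mgcv::in.out(bnd, cbind(qx, qy))
    expect_identical(mine, oracle)
  }
})

test_that("the enriched polygon contains at least the target cell fraction", {
  set.seed(5)
  n <- 200
  cs <- cells_from_xy(stats::rnorm(n, 300, 40), stats::rnorm(n, 280, 25))
  zp <- delineate_enriched_zone(cs, zone_config())
  expect_s3_class(zp, "clamap_zone_polygon")
  inside <- point_in_polygon(cs$cells$x_um, cs$cells$y_um,
                             zp$vertices[, 1], zp$vertices[, 2])
  expect_gte(mean(inside), 0.90)
  expect_equal(zp$contained_fraction, mean(inside))
  expect_lte(nrow(zp$vertices), 200)
  expect_error(delineate_enriched_zone(cells_from_xy(1:5, 1:5)),
               "fewer than 10")
})

test_that("enriched delineation is translation-equivariant", {
  set.seed(6)
  x <- stats::rnorm(150, 200, 30); y <- stats::rnorm(150, 220, 35)
  p1 <- delineate_enriched_zone(cells_from_xy(x, y))
  p2 <- delineate_enriched_zone(cells_from_xy(x + 57.3, y - 21.9))
  expect_equal(p2$vertices[, 1], p1$vertices[, 1] + 57.3, tolerance = 1e-8)
  expect_equal(p2$vertices[, 2], p1$vertices[, 2] - 21.9, tolerance = 1e-8)
})

test_that("a dense ellipse with uniform background is delineated near its true area", {
  set.seed(7)
  cfg <- generator_config(seed = 7L)
  g <- cfg$geometry
  n_in <- 450
  inside <- clamap:::.sample_in_zone(n_in, "enriched", g, 1024)
  n_bg <- 50 # 10% background contamination
  cs <- cells_from_xy(c(inside[, 1], stats::runif(n_bg, 0, 1024)),
                      c(inside[, 2], stats::runif(n_bg, 0, 1024)))
  zp <- delineate_enriched_zone(cs, zone_config())
  true_area <- pi * prod(g$axes_um)
  expect_lt(abs(polygon_area(zp$vertices) - true_area) / true_area, 0.25)
  expect_gte(zp$contained_fraction, 0.90)
})

test_that("devoid delineation recovers the interior of a marker ring", {
  set.seed(8)
  # dense Tle4 ring around an empty ellipse
  geom <- claustrum_geometry(center_um = c(512, 512), axes_um = c(220, 100),
                             orientation_deg = 20, ring_width_um = 150,
                             devoid_margin_um = 50)
  ring_pts <- clamap:::.sample_in_zone(1200, "ring", geom, 1024)
  cs <- cells_from_xy(ring_pts[, 1], ring_pts[, 2], "Tle4")
  dz <- delineate_devoid_zone(cs, anchor = c(512, 512),
                              frame_um = c(1024, 1024))
  expect_identical(dz$kind, "devoid")
  interior <- clamap:::.sample_in_zone(1000, "enriched", geom, 1024)
  covered <- mean(point_in_polygon(interior[, 1], interior[, 2],
                                   dz$vertices[, 1], dz$vertices[, 2]))
  expect_gte(covered, 0.95)
  expect_lt(dz$contained_fraction, 0.05)
})

test_that("devoid delineation errors on uniform labelling and tolerates empty frames", {
  set.seed(9)
  dense <- cells_from_xy(stats::runif(2000, 0, 512),
                         stats::runif(2000, 0, 512), "Tle4")
  expect_error(delineate_devoid_zone(dense, anchor = c(256, 256),
                                     frame_um = c(512, 512)),
               "exceeds the devoid threshold|leaks")
  # marker only in one corner: the central anchor sits in a devoid region
  corner <- cells_from_xy(stats::runif(50, 0, 60), stats::runif(50, 0, 60),
                          "Tle4")
  dz <- delineate_devoid_zone(corner, anchor = c(256, 256),
                              frame_um = c(512, 512))
  expect_true(point_in_polygon(256, 256, dz$vertices[, 1], dz$vertices[, 2]))
})

test_that("overlays center the reference polygon and accumulate occupancy", {
  sq <- function(ctr, half, ...) {
    zone_polygon(rbind(ctr + c(-half, -half), ctr + c(half, -half),
                       ctr + c(half, half), ctr + c(-half, half)), ...)
  }
  pair_for <- function(ctr) list(
    reference = sq(ctr, 50, kind = "enriched", channel = "retro",
                   meta = meta_z),
    partner = sq(ctr + c(20, 0), 60, kind = "enriched", channel = "Nurr1",
                 meta = meta_z))
  one <- overlay_cohort(list(m1 = pair_for(c(300, 300))), "anterior")
  expect_true(all(one$occupancy$reference %in% 0:1))
  expect_equal(unname(vertex_centroid(one$polygons$m1$reference)), c(0, 0))
  # six mice with identical shapes at different positions: occupancy 6 in the
  # common region, and the overlay ignores each mouse's global translation
  six <- overlay_cohort(lapply(1:6, function(i)
    pair_for(c(100 * i, 50 * i + 30))), "anterior")
  expect_identical(max(six$occupancy$reference), 6L)
  expect_identical(max(six$occupancy$partner), 6L)
  inner <- expand.grid(x = seq(-45, 45, by = 10), y = seq(-45, 45, by = 10))
  v <- six$polygons[[1]]$reference$vertices
  expect_true(all(point_in_polygon(inner$x, inner$y, v[, 1], v[, 2])))
  # pairwise Jaccard of identically shaped aligned references is 1
  j <- polygon_jaccard(six$polygons[[1]]$reference,
                       six$polygons[[2]]$reference, grid_um = 5)
  expect_gte(j, 0.99)
  expect_error(overlay_cohort(list(m1 = pair_for(c(10, 10))), "middle"),
               "subdivision")
})

test_that("zone polygons round-trip through GeoJSON text", {
  set.seed(11)
  cs <- cells_from_xy(stats::rnorm(80, 200, 30), stats::rnorm(80, 180, 25))
  zp <- delineate_enriched_zone(cs)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_zone_polygon(zp, path)
  back <- read_zone_polygon(path)
  expect_equal(back$vertices, zp$vertices)
  expect_identical(back$kind, "enriched")
  expect_identical(back$channel, "retro")
  expect_equal(back$contained_fraction, zp$contained_fraction)
  expect_identical(back$meta$mouse_id, "m1")
})
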