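#' Claustrum-like zone geometry
#'
#' Parametrizes the qualitative spatial layout the pipeline assumes: a dense
#' elliptical zone of claustrum-enriched cells (the "claustrum"), separated by
#' a thin devoid margin from a surrounding elliptical band of Tle4+ cells (the
#' cortical sheet bordering the claustrum on all sides). The major axis is a
#' proxy for the external-capsule direction and anchors profile axis 1.
#'
#' All lengths in micrometres; angles in degrees relative to the image x-axis
#' (x rightward, y downward, origin at the top-left pixel center).
#'
#' @param center_um length-2 numeric, ellipse center (x, y).
#' @param axes_um length-2 numeric, (major, minor) semi-axes of the enriched
#'   ellipse.
#' @param orientation_deg major-axis angle in [-90, 90).
#' @param ring_width_um width of the surrounding Tle4 band.
#' @param devoid_margin_um buffer between the ellipse edge and the inner edge
#'   of the ring.
#' @return an object of class `clamap_geometry`.
#' @export
claustrum_geometry <- function(center_um = c(512, 512),
                               axes_um = c(250, 80),
                               orientation_deg = 30,
                               ring_width_um = 150,
                               devoid_margin_um = 20) {
  stopifnot(length(center_um) == 2, length(axes_um) == 2)
  if (any(axes_um <= 0)) stop("axes_um must be positive")
  if (ring_width_um <= 0) stop("ring_width_um must be > 0")
  if (orientation_deg < -90 || orientation_deg >= 90)
    stop("orientation_deg must lie in [-90, 90)")
  if (devoid_margin_um < 0) stop("devoid_margin_um must be >= 0")
  structure(list(center_um = as.numeric(center_um),
                 axes_um = as.numeric(axes_um),
                 orientation_deg = orientation_deg,
                 ring_width_um = ring_width_um,
                 devoid_margin_um = devoid_margin_um),
            class = "clamap_geometry")
}

# squared normalized elliptical radius for points (x, y) against semi-axes
# grown by `grow` um; <= 1 means inside
.ellipse_r2 <- function(x, y, geom, grow = 0) {
  th <- geom$orientation_deg * pi / 180
  dx <- x - geom$center_um[1]
  dy <- y - geom$center_um[2]
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  (u / (geom$axes_um[1] + grow))^2 + (v / (geom$axes_um[2] + grow))^2
}

#' Classify points into geometry zones
#'
#' @param x,y point coordinates in um.
#' @param geom a [claustrum_geometry()].
#' @return character vector, one of `"enriched"`, `"ring"`, `"background"`.
#' @export
zone_of_points <- function(x, y, geom) {
  inner <- geom$devoid_margin_um
  outer <- geom$devoid_margin_um + geom$ring_width_um
  r2_core <- .ellipse_r2(x, y, geom)
  r2_in <- .ellipse_r2(x, y, geom, grow = inner)
  r2_out <- .ellipse_r2(x, y, geom, grow = outer)
  out <- rep("background", length(x))
  out[r2_out <= 1 & r2_in > 1] <- "ring"
  out[r2_core <= 1] <- "enriched"
  out
}

# areas in mm^2 of each zone (ellipses assumed fully inside the frame;
# validated by the generator)
.zone_areas_mm2 <- function(geom, frame_um) {
  a <- geom$axes_um[1]; b <- geom$axes_um[2]
  inner <- geom$devoid_margin_um
  outer <- inner + geom$ring_width_um
  area_core <- pi * a * b
  area_outer <- pi * (a + outer) * (b + outer)
  area_inner <- pi * (a + inner) * (b + inner)
  c(enriched = area_core,
    ring = area_outer - area_inner,
    background = frame_um^2 - area_outer) / 1e6
}

# check the outer ring ellipse fits inside the frame; names the offending
# dimension as required by the generator contract
.check_geometry_fits <- function(geom, frame_um) {
  outer <- geom$devoid_margin_um + geom$ring_width_um
  half <- geom$axes_um[1] + outer # conservative bound: max extent <= major+outer
  for (dim in c("x", "y")) {
    ctr <- geom$center_um[if (dim == "x") 1 else 2]
    if (ctr - half < 0 || ctr + half > frame_um)
      stop(sprintf(
        "zone geometry exceeds the frame along %s: center %.1f um, extent %.1f um, frame %.1f um",
        dim, ctr, half, frame_um), call. = FALSE)
  }
  invisible(TRUE)
}

# rejection-sample n uniform points inside a zone of the geometry
.sample_in_zone <- function(n, zone, geom, frame_um) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  pts <- matrix(numeric(0), 0, 2)
  outer <- geom$devoid_margin_um + geom$ring_width_um
  # bounding box (whole frame for background)
  if (zone == "background") {
    lo <- c(0, 0); hi <- c(frame_um, frame_um)
  } else {
    half <- geom$axes_um[1] + outer
    lo <- pmax(geom$center_um - half, 0)
    hi <- pmin(geom$center_um + half, frame_um)
  }
  while (nrow(pts) < n) {
    m <- max(2L * (n - nrow(pts)), 32L)
    cx <- stats::runif(m, lo[1], hi[1])
    cy <- stats::runif(m, lo[2], hi[2])
    keep <- zone_of_points(cx, cy, geom) == zone
    pts <- rbind(pts, cbind(cx[keep], cy[keep]))
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  colnames(pts) <- c("x", "y")
  pts
}
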