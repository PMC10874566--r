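#' Zone delineation parameters
#'
#' The enriched zone is the outer contour of the largest connected
#' superlevel region of a Gaussian kernel density estimate of the cell
#' centroids, with the density level chosen (by bisection) as the highest
#' level whose region still contains at least `enrichment_fraction` of the
#' cells — the automated counterpart of outlining the zone enriched with
#' more than 90% of the labelled cells.
#'
#' @param enrichment_fraction target contained fraction of cells, in (0, 1).
#' @param kde_bandwidth_um Gaussian KDE sigma in um.
#' @param grid_um KDE evaluation grid spacing in um.
#' @param devoid_rel_threshold fraction of the surround density below which a
#'   region counts as devoid.
#' @param devoid_bandwidth_um starting KDE sigma for the devoid-zone
#'   estimate; defaults to 1.4 x `kde_bandwidth_um`. The devoid marker
#'   surrounds the zone as a band whose cell spacing is coarser than the
#'   enriched cluster's; a kernel that is too narrow lets the sublevel set
#'   leak through chance gaps in the band, so [delineate_devoid_zone()]
#'   widens the kernel adaptively when it detects a leak.
#' @param max_vertices vertex cap for simplified polygons.
#' @return object of class `clamap_zone_config`.
#' @export
zone_config <- function(enrichment_fraction = 0.90, kde_bandwidth_um = 25,
                        grid_um = 8, devoid_rel_threshold = 0.25,
                        devoid_bandwidth_um = 1.4 * kde_bandwidth_um,
                        max_vertices = 200) {
  if (enrichment_fraction <= 0 || enrichment_fraction >= 1)
    stop("enrichment_fraction must lie in (0, 1)")
  if (kde_bandwidth_um <= 0 || grid_um <= 0 || devoid_bandwidth_um <= 0)
    stop("bandwidth and grid spacing must be > 0")
  structure(list(enrichment_fraction = enrichment_fraction,
                 kde_bandwidth_um = kde_bandwidth_um, grid_um = grid_um,
                 devoid_rel_threshold = devoid_rel_threshold,
                 devoid_bandwidth_um = devoid_bandwidth_um,
                 max_vertices = max_vertices), class = "clamap_zone_config")
}

#' Point-in-polygon test (ray casting)
#'
#' Even-odd rule with a horizontal ray; vectorized over points.
#'
#' @param x,y point coordinates.
#' @param vx,vy polygon vertex coordinates (closed implicitly; do not repeat
#'   the first vertex).
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > y) != (vy[j] > y)) &
      (x < (vx[j] - vx[i]) * (y - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Closed zone polygon with vertex centroid
#'
#' The centroid is the unweighted arithmetic mean of the vertex coordinates
#' (not the area centroid) — the registration convention for cross-animal
#' overlays.
#'
#' @param vertices 2-column matrix of (x, y) um coordinates, first vertex not
#'   repeated.
#' @param kind "enriched" or "devoid".
#' @param channel source channel.
#' @param contained_fraction fraction of the channel's cells inside.
#' @param meta a [slice_meta()].
#' @return object of class `clamap_zone_polygon`.
#' @export
zone_polygon <- function(vertices, kind = c("enriched", "devoid"),
                         channel = NA_character_,
                         contained_fraction = NA_real_, meta = slice_meta()) {
  kind <- match.arg(kind)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3)
    stop("vertices must be an n x 2 matrix with n >= 3")
  if (all(vertices[1, ] == vertices[nrow(vertices), ]) && nrow(vertices) > 3)
    vertices <- vertices[-nrow(vertices), , drop = FALSE]
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices, centroid = colMeans(vertices),
                 kind = kind, channel = channel,
                 contained_fraction = contained_fraction, meta = meta),
            class = "clamap_zone_polygon")
}

#' Vertex centroid of a zone polygon
#'
#' Unweighted mean of the vertex coordinates. Note this differs from the area
#' centroid: subdividing one edge into extra collinear vertices pulls the
#' vertex centroid toward that edge while leaving the area centroid unchanged.
#'
#' @param p a [zone_polygon()] or an n x 2 vertex matrix (n >= 3).
#' @return length-2 numeric (x, y) in um.
#' @export
vertex_centroid <- function(p) {
  v <- if (inherits(p, "clamap_zone_polygon")) p$vertices else as.matrix(p)
  if (nrow(v) < 3) stop("degenerate polygon: fewer than 3 vertices")
  colMeans(v)
}

#' @export
print.clamap_zone_polygon <- function(x, ...) {
  cat(sprintf("<clamap_zone_polygon> %s/%s: %d vertices, centroid (%.1f, %.1f) um, contains %.1f%%\n",
              x$kind, x$channel, nrow(x$vertices), x$centroid[1],
              x$centroid[2], 100 * x$contained_fraction))
  invisible(x)
}

# Ramer-Douglas-Peucker simplification of an open polyline (matrix of points)
.rdp <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2) return(pts)
  a <- pts[1, ]; b <- pts[n, ]
  ab <- b - a
  len <- sqrt(sum(ab^2))
  d <- if (len < 1e-12) sqrt(rowSums(sweep(pts, 2, a)^2)) else
    abs((pts[, 1] - a[1]) * ab[2] - (pts[, 2] - a[2]) * ab[1]) / len
  k <- which.max(d)
  if (d[k] <= tol) return(pts[c(1, n), , drop = FALSE])
  left <- .rdp(pts[1:k, , drop = FALSE], tol)
  right <- .rdp(pts[k:n, , drop = FALSE], tol)
  rbind(left[-nrow(left), , drop = FALSE], right)
}

# simplify a closed ring: anchor at the two mutually distant vertices
.simplify_ring <- function(ring, tol, max_vertices) {
  repeat {
    n <- nrow(ring)
    if (n <= 4) return(ring)
    k <- which.max(rowSums(sweep(ring, 2, ring[1, ])^2))
    part1 <- .rdp(ring[1:k, , drop = FALSE], tol)
    part2 <- .rdp(ring[c(k:n, 1), , drop = FALSE], tol)
    out <- rbind(part1[-nrow(part1), , drop = FALSE],
                 part2[-nrow(part2), , drop = FALSE])
    if (nrow(out) <= max_vertices) return(out)
    tol <- tol * 2
  }
}

# KDE of a point pattern on a regular grid with spacing ~grid_um, padded by
# pad_um beyond the point bounding box. MASS::kde2d's h is 4x the Gaussian
# sigma, hence the factor.
.kde_grid <- function(x, y, bw_um, grid_um, pad_um = 4 * bw_um,
                      lims = NULL) {
  if (is.null(lims))
    lims <- c(min(x) - pad_um, max(x) + pad_um,
              min(y) - pad_um, max(y) + pad_um)
  nx <- max(32L, ceiling((lims[2] - lims[1]) / grid_um) + 1L)
  ny <- max(32L, ceiling((lims[4] - lims[3]) / grid_um) + 1L)
  MASS::kde2d(x, y, h = 4 * bw_um, n = c(nx, ny), lims = lims)
}

# outer contour ring of the largest (or anchor-containing) component of a
# logical grid mask; kde-like list(x, y) gives the grid coordinates
.mask_ring <- function(mask, gx, gy, anchor = NULL) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- round(as.numeric(lab))
  dim(lab) <- dim(mask)
  if (max(lab) == 0) return(NULL)
  if (is.null(anchor)) {
    sizes <- tabulate(lab[lab > 0])
    comp <- which.max(sizes)
  } else {
    ai <- which.min(abs(gx - anchor[1]))
    aj <- which.min(abs(gy - anchor[2]))
    comp <- lab[ai, aj]
    if (comp == 0) return(NULL)
  }
  sel <- (lab == comp) * 1
  # zero-pad so contours always close
  dx <- gx[2] - gx[1]; dy <- gy[2] - gy[1]
  pz <- matrix(0, nrow(sel) + 2, ncol(sel) + 2)
  pz[2:(nrow(sel) + 1), 2:(ncol(sel) + 1)] <- sel
  px <- c(gx[1] - dx, gx, gx[length(gx)] + dx)
  py <- c(gy[1] - dy, gy, gy[length(gy)] + dy)
  rings <- grDevices::contourLines(px, py, pz, levels = 0.5)
  if (!length(rings)) return(NULL)
  # outer ring = largest enclosed (shoelace) area
  area <- vapply(rings, function(r) {
    xx <- r$x; yy <- r$y
    abs(sum(xx * c(yy[-1], yy[1]) - c(xx[-1], xx[1]) * yy)) / 2
  }, numeric(1))
  r <- rings[[which.max(area)]]
  cbind(x = r$x, y = r$y)
}

#' Delineate the enriched zone of a cell point pattern
#'
#' Gaussian KDE of the centroids on a regular grid; bisection over the density
#' level for the highest level whose largest connected superlevel region
#' contains at least the configured fraction of the cells; the polygon is the
#' outer contour of that region, simplified (Ramer-Douglas-Peucker, tolerance
#' grid_um/2) to at most `max_vertices` vertices. Containment is always
#' verified on the final simplified polygon.
#'
#' @param cells a [cell_set()] with at least 10 cells.
#' @param cfg a [zone_config()].
#' @return a [zone_polygon()] of kind "enriched".
#' @export
delineate_enriched_zone <- function(cells, cfg = zone_config()) {
  stopifnot(inherits(cells, "clamap_cellset"))
  x <- cells$cells$x_um; y <- cells$cells$y_um
  if (length(x) < 10)
    stop("enriched zone undefined: fewer than 10 cells")
  kde <- .kde_grid(x, y, cfg$kde_bandwidth_um, cfg$grid_um)
  target <- cfg$enrichment_fraction
  poly_at <- function(t) {
    ring <- .mask_ring(kde$z >= t, kde$x, kde$y)
    if (is.null(ring)) return(NULL)
    .simplify_ring(ring, cfg$grid_um / 2, cfg$max_vertices)
  }
  frac_of <- function(ring)
    mean(point_in_polygon(x, y, ring[, 1], ring[, 2]))
  lo <- 0; hi <- max(kde$z)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    ring <- poly_at(mid)
    if (!is.null(ring) && frac_of(ring) >= target) lo <- mid else hi <- mid
  }
  ring <- poly_at(lo)
  # guard: walk the level down until the simplified polygon itself satisfies
  # the containment rule (lo = 0 contains everything by construction)
  while (is.null(ring) || frac_of(ring) < target) {
    lo <- lo * 0.9
    if (lo < max(kde$z) * 1e-9) lo <- 0
    ring <- poly_at(lo)
    if (lo == 0) break
  }
  zone_polygon(ring, kind = "enriched", channel = cells$channel,
               contained_fraction = frac_of(ring), meta = cells$meta)
}

#' Delineate the marker-devoid zone around an anchor point
#'
#' KDE of the devoid-marker (Tle4) centroids; the devoid region is the
#' connected component of the sublevel set
#' {density <= devoid_rel_threshold x median density at the marker cells}
#' that contains the anchor (in the pipeline, the centroid of the retrograde
#' enriched zone); the polygon is its outer contour. Errors when the anchor
#' does not lie in any sub-threshold region (e.g. uniformly dense labelling).
#'
#' @param tle4_cells a [cell_set()] of the devoid marker with >= 10 cells.
#' @param anchor length-2 (x, y) um point inside the image.
#' @param cfg a [zone_config()].
#' @param frame_um optional c(width, height) of the frame in um; defaults to
#'   the cell bounding box.
#' @return a [zone_polygon()] of kind "devoid".
#' @export
delineate_devoid_zone <- function(tle4_cells, anchor, cfg = zone_config(),
                                  frame_um = NULL) {
  stopifnot(inherits(tle4_cells, "clamap_cellset"))
  x <- tle4_cells$cells$x_um; y <- tle4_cells$cells$y_um
  if (length(x) < 10) stop("devoid zone undefined: fewer than 10 marker cells")
  lims <- if (is.null(frame_um))
    c(min(x), max(x), min(y), max(y)) else c(0, frame_um[1], 0, frame_um[2])
  # adaptive kernel width: if the sublevel set leaks through a chance gap in
  # the surrounding band (detected as the "devoid" polygon swallowing the
  # marker cells), widen the kernel and retry
  bw <- cfg$devoid_bandwidth_um
  for (attempt in 1:4) {
    kde <- .kde_grid(x, y, bw, cfg$grid_um, lims = lims)
    dens_at <- function(px, py) {
      ii <- vapply(px, function(v) which.min(abs(kde$x - v)), integer(1))
      jj <- vapply(py, function(v) which.min(abs(kde$y - v)), integer(1))
      kde$z[cbind(ii, jj)]
    }
    thr <- cfg$devoid_rel_threshold * stats::median(dens_at(x, y))
    if (dens_at(anchor[1], anchor[2]) > thr)
      stop("no devoid region at the anchor: local density exceeds the devoid threshold")
    ring <- .mask_ring(kde$z <= thr, kde$x, kde$y, anchor = anchor)
    if (is.null(ring)) stop("no devoid region at the anchor")
    ring <- .simplify_ring(ring, cfg$grid_um / 2, cfg$max_vertices)
    contained <- mean(point_in_polygon(x, y, ring[, 1], ring[, 2]))
    if (contained <= 0.2) break
    bw <- bw * 1.5
  }
  if (contained > 0.2)
    stop("devoid region could not be separated from the background (sublevel set leaks around the marker band)")
  zone_polygon(ring, kind = "devoid", channel = tle4_cells$channel,
               contained_fraction = contained, meta = tle4_cells$meta)
}

#' Translate a zone polygon
#' @param p a [zone_polygon()].
#' @param shift length-2 (dx, dy) um.
#' @return translated [zone_polygon()].
#' @export
translate_polygon <- function(p, shift) {
  zone_polygon(sweep(p$vertices, 2, -as.numeric(shift)), kind = p$kind,
               channel = p$channel, contained_fraction = p$contained_fraction,
               meta = p$meta)
}

#' Overlay zone polygon pairs across mice
#'
#' Each mouse contributes a reference (retrograde) polygon and a partner
#' polygon from the same slice; both are translated so the reference polygon's
#' vertex centroid sits at the origin, and occupancy maps count how many
#' mice's polygons cover each grid point — the cumulative spatial distribution
#' of a subdivision across animals.
#'
#' @param mouse_pairs list (one element per mouse) of
#'   `list(reference = , partner = )` [zone_polygon()] pairs.
#' @param subdivision subdivision label; every polygon's metadata must match.
#' @param grid_um occupancy raster spacing.
#' @return object of class `clamap_overlay`: translated polygon pairs,
#'   occupancy rasters (`reference`, `partner`), grid coordinates and counts.
#' @export
overlay_cohort <- function(mouse_pairs, subdivision, grid_um = 10) {
  shifted <- lapply(mouse_pairs, function(pr) {
    for (role in c("reference", "partner")) {
      sub <- pr[[role]]$meta$subdivision
      if (!is.na(sub) && sub != subdivision)
        stop(sprintf("%s polygon from subdivision '%s', expected '%s'",
                     role, sub, subdivision))
    }
    ctr <- vertex_centroid(pr$reference)
    list(reference = translate_polygon(pr$reference, -ctr),
         partner = translate_polygon(pr$partner, -ctr))
  })
  allv <- do.call(rbind, lapply(shifted, function(pr)
    rbind(pr$reference$vertices, pr$partner$vertices)))
  gx <- seq(min(allv[, 1]) - grid_um, max(allv[, 1]) + grid_um, by = grid_um)
  gy <- seq(min(allv[, 2]) - grid_um, max(allv[, 2]) + grid_um, by = grid_um)
  pts <- expand.grid(x = gx, y = gy)
  occ <- function(role) {
    counts <- rep(0L, nrow(pts))
    for (pr in shifted) {
      v <- pr[[role]]$vertices
      counts <- counts + point_in_polygon(pts$x, pts$y, v[, 1], v[, 2])
    }
    matrix(counts, nrow = length(gx))
  }
  structure(list(subdivision = subdivision,
                 reference_channel = mouse_pairs[[1]]$reference$channel,
                 polygons = shifted, grid_x = gx, grid_y = gy,
                 occupancy = list(reference = occ("reference"),
                                  partner = occ("partner")),
                 n_mice = length(mouse_pairs)),
            class = "clamap_overlay")
}

#' Rasterized Jaccard overlap of two polygons
#'
#' @param p1,p2 [zone_polygon()] objects.
#' @param grid_um raster spacing.
#' @return intersection-over-union in [0, 1].
#' @export
polygon_jaccard <- function(p1, p2, grid_um = 5) {
  v <- rbind(p1$vertices, p2$vertices)
  gx <- seq(min(v[, 1]), max(v[, 1]), by = grid_um)
  gy <- seq(min(v[, 2]), max(v[, 2]), by = grid_um)
  pts <- expand.grid(x = gx, y = gy)
  in1 <- point_in_polygon(pts$x, pts$y, p1$vertices[, 1], p1$vertices[, 2])
  in2 <- point_in_polygon(pts$x, pts$y, p2$vertices[, 1], p2$vertices[, 2])
  if (!any(in1 | in2)) return(0)
  sum(in1 & in2) / sum(in1 | in2)
}

#' Write / read a zone polygon as GeoJSON-style text
#'
#' A single Feature with a closed Polygon ring in um coordinates and the
#' kind/channel/metadata in `properties`.
#'
#' @param p a [zone_polygon()].
#' @param path output path.
#' @return `path` (write) or a [zone_polygon()] (read).
#' @export
write_zone_polygon <- function(p, path) {
  ring <- rbind(p$vertices, p$vertices[1, ])
  feat <- list(type = "Feature",
               geometry = list(type = "Polygon",
                               coordinates = list(unname(split(ring, row(ring))))),
               properties = list(kind = p$kind, channel = p$channel,
                                 contained_fraction = p$contained_fraction,
                                 units = "um", meta = unclass(p$meta)))
  jsonlite::write_json(feat, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_zone_polygon
#' @export
read_zone_polygon <- function(path) {
  feat <- jsonlite::read_json(path, simplifyVector = FALSE)
  ring <- do.call(rbind, lapply(feat$geometry$coordinates[[1]], unlist))
  pr <- feat$properties
  mi <- pr$meta
  meta <- slice_meta(mouse_id = mi$mouse_id %||% NA_character_,
                     sex = mi$sex %||% NA_character_,
                     age_group = mi$age_group %||% NA_character_,
                     hemisphere = mi$hemisphere %||% NA_character_,
                     ap_mm = mi$ap_mm %||% NA_real_,
                     subdivision = mi$subdivision %||% NA_character_,
                     condition = mi$condition %||% NA_character_)
  zone_polygon(ring, kind = pr$kind, channel = pr$channel %||% NA_character_,
               contained_fraction = pr$contained_fraction %||% NA_real_,
               meta = meta)
}
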