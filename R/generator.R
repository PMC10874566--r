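#' Default per-zone, per-channel cell densities (cells/mm^2)
#'
#' Calibrated so that a default frame carries roughly 63 retrograde-labelled
#' cells (the adult per-slice count the analysis is sized for), ~210 Nurr1+
#' and ~185 Tle4+ cells in total: enriched markers concentrate inside the
#' claustrum ellipse, Tle4 in the surrounding band, with sparse cortical
#' background expression of all markers.
#'
#' @return named list: zone -> named numeric vector of densities.
#' @export
default_densities <- function() {
  list(
    enriched = c(retro = 1000, Nurr1 = 1200, Nr2f2 = 1000, Tle4 = 15),
    ring = c(Nurr1 = 150, Nr2f2 = 150, Tle4 = 600),
    background = c(Nurr1 = 60, Nr2f2 = 60, Tle4 = 50)
  )
}

#' Default pairwise colocalization fractions
#'
#' Names are "A:B"; the value is the probability that a cell whose primary
#' channel is A is also positive for B. Defaults reflect typical adult
#' claustrum co-expression levels: retrograde cells co-express Nurr1 at 0.87 and Nr2f2 at
#' 0.81 but Tle4 at only 0.01; Nurr1+ claustrum cells co-express Tle4 at 0.015
#' and Nr2f2+ cells at 0.004. c-Fos memberships are condition-dependent and
#' set by [condition_presets()].
#'
#' @return named numeric vector.
#' @export
default_coloc_fractions <- function() {
  c("retro:Nurr1" = 0.87, "retro:Nr2f2" = 0.81, "retro:Tle4" = 0.01,
    "Nurr1:Tle4" = 0.015, "Nr2f2:Tle4" = 0.004,
    "Nurr1:cFos" = 0.10, "Tle4:cFos" = 0.030)
}

#' Synthetic slice generator configuration
#'
#' Bundles everything needed to simulate one multi-channel confocal slice:
#' frame geometry and calibration, the z-sampling convention (2 um steps over
#' a 20 um volume, inclusive endpoints, hence 11 planes), the cell/PSF
#' rendering model, the noise model (Poisson on signal, then additive
#' Gaussian), the spatial zone geometry, per-zone cell densities and pairwise
#' colocalization fractions.
#'
#' @param frame_px pixels per side of the (square) frame.
#' @param pixel_um micrometres per pixel.
#' @param z_step_um,z_depth_um axial step and total depth in um; the plane
#'   count is `floor(z_depth_um / z_step_um) + 1`.
#' @param cell_radius_um mean soma radius; sets lateral/axial spot size.
#' @param psf_sigma_um lateral Gaussian PSF sigma.
#' @param spot_intensity total (3D-integrated, per-plane normalized) spot
#'   brightness in intensity units.
#' @param noise_gauss_sd additive Gaussian read-noise SD (0 disables).
#' @param noise_poisson_gain photons per intensity unit for shot noise
#'   (0 disables).
#' @param channels ordered channel names.
#' @param geometry a [claustrum_geometry()].
#' @param densities per-zone per-channel densities, see [default_densities()].
#' @param coloc_fractions named "A:B" fractions, see
#'   [default_coloc_fractions()].
#' @param seed RNG seed for this slice.
#' @return object of class `clamap_generator_config`.
#' @export
generator_config <- function(frame_px = 1024L,
                             pixel_um = 1.0,
                             z_step_um = 2.0,
                             z_depth_um = 20.0,
                             cell_radius_um = 4.0,
                             psf_sigma_um = 1.5,
                             spot_intensity = 2000,
                             noise_gauss_sd = 2.0,
                             noise_poisson_gain = 1.0,
                             channels = c("retro", "Nurr1", "Nr2f2", "Tle4", "cFos"),
                             geometry = claustrum_geometry(center_um = rep(frame_px * pixel_um / 2, 2)),
                             densities = default_densities(),
                             coloc_fractions = default_coloc_fractions(),
                             seed = 1L) {
  stopifnot_scalar_num(frame_px, "frame_px", positive = TRUE)
  stopifnot_scalar_num(pixel_um, "pixel_um", positive = TRUE)
  stopifnot_scalar_num(z_step_um, "z_step_um", positive = TRUE)
  stopifnot_scalar_num(z_depth_um, "z_depth_um", positive = TRUE)
  if (any(unlist(densities) < 0)) stop("densities must be >= 0")
  if (length(coloc_fractions) && (any(coloc_fractions < 0) || any(coloc_fractions > 1)))
    stop("coloc_fractions must lie in [0, 1]")
  bad <- setdiff(names(densities), c("enriched", "ring", "background"))
  if (length(bad)) stop("unknown density zones: ", paste(bad, collapse = ", "))
  pair_ch <- unlist(strsplit(names(coloc_fractions), ":", fixed = TRUE))
  if (!all(pair_ch %in% channels))
    stop("coloc_fractions reference channels absent from 'channels'")
  cfg <- structure(list(
    frame_px = as.integer(frame_px), pixel_um = pixel_um,
    z_step_um = z_step_um, z_depth_um = z_depth_um,
    n_z = as.integer(floor(z_depth_um / z_step_um) + 1),
    cell_radius_um = cell_radius_um, psf_sigma_um = psf_sigma_um,
    spot_intensity = spot_intensity,
    noise_gauss_sd = noise_gauss_sd, noise_poisson_gain = noise_poisson_gain,
    channels = channels, geometry = geometry, densities = densities,
    coloc_fractions = coloc_fractions, seed = as.integer(seed)),
    class = "clamap_generator_config")
  cfg
}

#' Sample a ground-truth cell population
#'
#' Draws Poisson cell counts per zone at the configured densities, places
#' cells uniformly within their zone, assigns each cell a primary channel and
#' then secondary channel memberships by independent Bernoulli draws with the
#' configured pairwise fractions (membership of B conditional on primary A
#' equals f(A:B)). Depth coordinates are uniform over the imaged volume.
#'
#' @param config a [generator_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return object of class `clamap_truth`: list with `cells` (data frame: id,
#'   zone, primary, x_um, y_um, z_um, one logical column per channel),
#'   `geometry`, and `config_digest`.
#' @export
sample_cells <- function(config, seed = config$seed) {
  frame_um <- config$frame_px * config$pixel_um
  .check_geometry_fits(config$geometry, frame_um)
  areas <- .zone_areas_mm2(config$geometry, frame_um)
  set.seed(seed)
  rows <- list()
  for (zone in names(config$densities)) {
    dens <- config$densities[[zone]]
    for (ch in names(dens)) {
      if (!ch %in% config$channels)
        stop(sprintf("density channel '%s' not in config$channels", ch))
      n <- stats::rpois(1, dens[[ch]] * areas[[zone]])
      if (n == 0) next
      pts <- .sample_in_zone(n, zone, config$geometry, frame_um)
      rows[[length(rows) + 1L]] <- data.frame(
        zone = zone, primary = ch, x_um = pts[, "x"], y_um = pts[, "y"],
        z_um = stats::runif(n, 0, config$z_depth_um))
    }
  }
  cells <- if (length(rows)) do.call(rbind, rows) else
    data.frame(zone = character(0), primary = character(0),
               x_um = numeric(0), y_um = numeric(0), z_um = numeric(0))
  n <- nrow(cells)
  cells <- cbind(id = seq_len(n), cells)
  for (ch in config$channels) cells[[ch]] <- cells$primary == ch
  # secondary memberships: Bernoulli per configured ordered pair
  for (key in names(config$coloc_fractions)) {
    ab <- strsplit(key, ":", fixed = TRUE)[[1]]
    idx <- which(cells$primary == ab[1])
    if (length(idx))
      cells[[ab[2]]][idx] <- stats::runif(length(idx)) < config$coloc_fractions[[key]]
  }
  structure(list(cells = cells, geometry = config$geometry,
                 config_digest = config_digest(unclass(config))),
            class = "clamap_truth")
}

# per-cell z-plane weights: Gaussian in z centered on the cell, renormalized
# over the acquired planes so every cell deposits the same integrated
# intensity regardless of depth
.z_weights <- function(z_um, z_planes, sigma_z) {
  w <- stats::dnorm(outer(z_planes, z_um, "-"), sd = sigma_z)
  sweep(w, 2, colSums(w), "/")
}

#' Render one channel's z-stack from ground truth
#'
#' Each member cell contributes a lateral Gaussian spot whose sigma combines
#' the soma radius and the PSF, distributed over z-planes with a Gaussian
#' axial footprint centered on the cell's true depth; Poisson shot noise then
#' additive Gaussian noise are applied and intensities are clamped to be
#' nonnegative. Values stay continuous in memory; [write_stack()] quantizes
#' to 16-bit counts on disk. Deterministic given the config seed.
#'
#' @param truth a [sample_cells()] result.
#' @param config the matching [generator_config()].
#' @param channels channels to render (default all configured).
#' @return an [image_volume()] with dimensions (y, x, z, channel).
#' @export
render_slice <- function(truth, config, channels = config$channels) {
  stopifnot(inherits(truth, "clamap_truth"))
  if (!all(channels %in% config$channels)) stop("unknown channel requested")
  np <- config$frame_px
  nz <- config$n_z
  px <- config$pixel_um
  sigma_xy_px <- sqrt((config$cell_radius_um / 2)^2 + config$psf_sigma_um^2) / px
  sigma_z <- config$cell_radius_um
  z_planes <- seq(0, config$z_depth_um, by = config$z_step_um)
  half <- ceiling(4 * sigma_xy_px)
  data <- array(0, dim = c(np, np, nz, length(channels)))
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    stack <- array(0, dim = c(np, np, nz))
    cells <- truth$cells[truth$cells[[ch]], , drop = FALSE]
    if (nrow(cells)) {
      wz <- .z_weights(cells$z_um, z_planes, sigma_z)
      # column index from x (rightward), row index from y (downward); 0-based
      # physical origin at the center of pixel (1,1)
      ccol <- cells$x_um / px + 1
      crow <- cells$y_um / px + 1
      for (k in seq_len(nrow(cells))) {
        r0 <- max(1L, floor(crow[k]) - half); r1 <- min(np, floor(crow[k]) + half)
        c0 <- max(1L, floor(ccol[k]) - half); c1 <- min(np, floor(ccol[k]) + half)
        if (r0 > r1 || c0 > c1) next
        gr <- exp(-((r0:r1 - crow[k])^2) / (2 * sigma_xy_px^2))
        gc <- exp(-((c0:c1 - ccol[k])^2) / (2 * sigma_xy_px^2))
        spot <- config$spot_intensity / (2 * pi * sigma_xy_px^2) * outer(gr, gc)
        for (zi in seq_len(nz)) {
          if (wz[zi, k] < 1e-12) next
          stack[r0:r1, c0:c1, zi] <- stack[r0:r1, c0:c1, zi] + spot * wz[zi, k]
        }
      }
    }
    set.seed(derive_seed(config$seed, "render", ch))
    if (config$noise_poisson_gain > 0) {
      gain <- config$noise_poisson_gain
      stack[] <- stats::rpois(length(stack), lambda = stack * gain) / gain
    }
    if (config$noise_gauss_sd > 0)
      stack[] <- stack + stats::rnorm(length(stack), 0, config$noise_gauss_sd)
    data[, , , ci] <- pmax(stack, 0)
  }
  image_volume(data, channel_names = channels, pixel_um = px,
               z_step_um = config$z_step_um, meta = slice_meta())
}

#' Convert ground truth to a CellSet
#'
#' Bypasses rendering and detection: the true centroids of all cells positive
#' for `channel` become detections. Used for detector-independent tests of the
#' colocalization and zone stages, and wherever image rendering would only add
#' noise to a question about the point pattern.
#'
#' @param truth a [sample_cells()] result.
#' @param channel channel name.
#' @param meta a [slice_meta()].
#' @param config generator config (for the nominal soma area).
#' @return a [cell_set()].
#' @export
cellset_from_truth <- function(truth, channel, meta = slice_meta(),
                               config = NULL) {
  cells <- truth$cells[truth$cells[[channel]], , drop = FALSE]
  r <- if (is.null(config)) 4 else config$cell_radius_um
  cell_set(channel = channel,
           cells = data.frame(id = cells$id, x_um = cells$x_um,
                              y_um = cells$y_um,
                              area_um2 = rep(pi * r^2, nrow(cells)),
                              intensity = rep(NA_real_, nrow(cells))),
           meta = meta)
}

#' Anteroposterior bregma ranges of the claustrum subdivisions (mm)
#' @return named list of c(lo, hi) bregma ranges.
#' @export
subdivision_ranges <- function() {
  list(anterior = c(0.70, 1.80), middle = c(-0.20, 0.70),
       posterior = c(-1.00, -0.20))
}

#' Generate a synthetic cohort of slices
#'
#' Simulates `n_mice` animals with `slices_per_subdivision` slices in each of
#' the anterior/middle/posterior claustrum subdivisions (default 2, i.e. the
#' six imaged slices per mouse). Per-slice seeds are derived deterministically
#' from the master seed and the (mouse, subdivision, slice) identity, and AP
#' coordinates are drawn uniformly within each subdivision's bregma range.
#' Ground truth is always written as a delimited table per slice; image stacks
#' are rendered and written as TIFF when `write_images` is TRUE.
#'
#' @param config base [generator_config()] (its seed is ignored).
#' @param n_mice number of mice.
#' @param slices_per_subdivision slices per AP subdivision per mouse.
#' @param out_dir output directory (created if missing); NULL keeps everything
#'   in memory.
#' @param master_seed master RNG seed.
#' @param condition condition label stored in slice metadata.
#' @param write_images render and write TIFF stacks (slower).
#' @param channels channels to render when writing images.
#' @return a cohort manifest data frame (one row per slice) with attribute
#'   `"slices"`: a list of per-slice records (truth, meta, seed, paths).
#' @export
generate_cohort <- function(config = generator_config(), n_mice = 6,
                            slices_per_subdivision = 2, out_dir = NULL,
                            master_seed = 1L, condition = "naive",
                            write_images = !is.null(out_dir),
                            channels = config$channels) {
  if (n_mice < 1) stop("n_mice must be >= 1")
  if (!is.null(out_dir) && !dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE))
    stop("cannot create out_dir: ", out_dir)
  ranges <- subdivision_ranges()
  sexes <- rep(c("M", "F"), length.out = n_mice)
  slices <- list()
  rows <- list()
  for (m in seq_len(n_mice)) {
    mouse_id <- sprintf("mouse%02d", m)
    for (sub in names(ranges)) {
      for (s in seq_len(slices_per_subdivision)) {
        seed <- derive_seed(master_seed, mouse_id, sub, s, condition)
        set.seed(seed)
        ap <- stats::runif(1, ranges[[sub]][1], ranges[[sub]][2])
        meta <- slice_meta(mouse_id = mouse_id, sex = sexes[m],
                           age_group = "adult", hemisphere = "left",
                           ap_mm = ap, subdivision = sub,
                           condition = condition)
        cfg <- config
        cfg$seed <- derive_seed(seed, "cells")
        truth <- sample_cells(cfg)
        slice_id <- sprintf("%s_%s_%d", mouse_id, sub, s)
        truth_path <- image_path <- NA_character_
        if (!is.null(out_dir)) {
          truth_path <- file.path(out_dir, paste0(slice_id, "_truth.csv"))
          tt <- truth$cells
          tt$config_digest <- truth$config_digest
          utils::write.csv(tt, truth_path, row.names = FALSE)
        }
        if (write_images) {
          vol <- render_slice(truth, cfg, channels = channels)
          vol$meta <- meta
          image_path <- file.path(out_dir, paste0(slice_id, ".tif"))
          write_stack(vol, image_path)
        }
        slices[[slice_id]] <- list(slice_id = slice_id, truth = truth,
                                   meta = meta, seed = cfg$seed,
                                   truth_path = truth_path,
                                   image_path = image_path)
        rows[[length(rows) + 1L]] <- data.frame(
          slice_id = slice_id, mouse_id = mouse_id, sex = sexes[m],
          age_group = "adult", hemisphere = "left", subdivision = sub,
          slice = s, ap_mm = ap, condition = condition, seed = cfg$seed,
          n_cells = nrow(truth$cells), truth_path = truth_path,
          image_path = image_path, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  attr(manifest, "slices") <- slices
  manifest
}
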