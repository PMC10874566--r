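#' Per-slice metadata
#'
#' @param mouse_id animal identifier.
#' @param sex "M"/"F" or NA.
#' @param age_group e.g. "P7", "P14", "P21", "P56", "adult".
#' @param hemisphere imaged hemisphere.
#' @param ap_mm anteroposterior bregma coordinate in mm.
#' @param subdivision optional "anterior"/"middle"/"posterior"; when given it
#'   must agree with [assign_subdivision()] applied to `ap_mm`.
#' @param condition optional condition label (e.g. "naive", "OF").
#' @return object of class `clamap_slice_meta`.
#' @export
slice_meta <- function(mouse_id = NA_character_, sex = NA_character_,
                       age_group = NA_character_, hemisphere = NA_character_,
                       ap_mm = NA_real_, subdivision = NA_character_,
                       condition = NA_character_) {
  if (!is.na(subdivision)) {
    if (is.na(ap_mm)) stop("subdivision given without ap_mm")
    expected <- assign_subdivision(ap_mm)
    if (subdivision != expected)
      stop(sprintf("subdivision '%s' inconsistent with ap_mm %.2f (expected '%s')",
                   subdivision, ap_mm, expected))
  }
  structure(list(mouse_id = mouse_id, sex = sex, age_group = age_group,
                 hemisphere = hemisphere, ap_mm = ap_mm,
                 subdivision = subdivision, condition = condition),
            class = "clamap_slice_meta")
}

.same_slice <- function(m1, m2) {
  identical(m1$mouse_id, m2$mouse_id) &&
    (identical(m1$ap_mm, m2$ap_mm) ||
       (is.na(m1$ap_mm) && is.na(m2$ap_mm))) &&
    identical(m1$condition, m2$condition)
}

#' Multi-channel calibrated image volume
#'
#' The canonical in-memory container for one slice: a nonnegative 4D array
#' stored (y, x, z, channel) — R column-major order; the logical/on-disk page
#' order is channel-major (channel, then z) — with physical calibration.
#' Physical coordinates are micrometres, origin at the center of the top-left
#' pixel, x rightward (columns), y downward (rows).
#'
#' @param data 4D numeric array (y, x, z, channel); a 2D/3D array is promoted.
#' @param channel_names ordered channel labels, length = channel axis.
#' @param pixel_um micrometres per pixel (> 0).
#' @param z_step_um axial step in micrometres.
#' @param meta a [slice_meta()].
#' @return object of class `clamap_volume`.
#' @export
image_volume <- function(data, channel_names, pixel_um, z_step_um = NA_real_,
                         meta = slice_meta()) {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L, 1L)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) stop("data must be a (y, x, z, channel) array")
  if (length(channel_names) != dim(data)[4])
    stop(sprintf("%d channel names for %d channels",
                 length(channel_names), dim(data)[4]))
  stopifnot_scalar_num(pixel_um, "pixel_um", positive = TRUE)
  if (any(data < 0)) stop("image data must be nonnegative")
  structure(list(data = data, channel_names = channel_names,
                 pixel_um = pixel_um, z_step_um = z_step_um, meta = meta),
            class = "clamap_volume")
}

#' @export
print.clamap_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<clamap_volume> %d x %d px, %d z-planes, channels: %s (%.2g um/px)\n",
              d[1], d[2], d[3], paste(x$channel_names, collapse = ", "),
              x$pixel_um))
  invisible(x)
}

# intensities are stored as 16-bit grayscale pages scaled by 1/65535;
# calibration and metadata live in a JSON sidecar next to the TIFF
.sidecar_path <- function(path) paste0(path, ".json")

#' Write an image volume as a multi-page TIFF
#'
#' Pages are written channel-major (all z-planes of channel 1, then channel 2,
#' ...). Intensities are rounded to integers and stored as 16-bit samples, so
#' the round trip is lossless for integer data in [0, 65535]; values above
#' that are clipped with a warning. Channel names, calibration and slice
#' metadata go to a JSON sidecar (`<path>.json`).
#'
#' @param vol an [image_volume()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(vol, path) {
  stopifnot(inherits(vol, "clamap_volume"))
  d <- dim(vol$data)
  x <- round(vol$data)
  if (any(x > 65535)) {
    warning("intensities above 65535 clipped at write")
    x[x > 65535] <- 65535
  }
  pages <- vector("list", d[3] * d[4])
  i <- 0L
  for (ci in seq_len(d[4])) for (zi in seq_len(d[3])) {
    i <- i + 1L
    pages[[i]] <- x[, , zi, ci] / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "deflate",
                  reduce = FALSE)
  side <- list(channel_names = vol$channel_names, n_z = d[3],
               frame = d[1:2], pixel_um = vol$pixel_um,
               z_step_um = vol$z_step_um, scale = 65535,
               page_order = "channel_major",
               meta = unclass(vol$meta))
  jsonlite::write_json(side, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read an image volume written by [write_stack()]
#'
#' @param path TIFF path (its `.json` sidecar must exist).
#' @return an [image_volume()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sp <- .sidecar_path(path)
  if (!file.exists(sp))
    stop("missing metadata sidecar (channel names unknown): ", sp)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nch <- length(side$channel_names)
  nz <- side$n_z
  if (length(pages) != nch * nz)
    stop(sprintf("TIFF has %d pages but metadata declares %d channels x %d planes",
                 length(pages), nch, nz))
  d <- dim(pages[[1]])
  data <- array(0, dim = c(d[1], d[2], nz, nch))
  i <- 0L
  for (ci in seq_len(nch)) for (zi in seq_len(nz)) {
    i <- i + 1L
    data[, , zi, ci] <- round(pages[[i]] * side$scale)
  }
  mi <- side$meta
  meta <- slice_meta(mouse_id = mi$mouse_id %||% NA_character_,
                     sex = mi$sex %||% NA_character_,
                     age_group = mi$age_group %||% NA_character_,
                     hemisphere = mi$hemisphere %||% NA_character_,
                     ap_mm = mi$ap_mm %||% NA_real_,
                     subdivision = mi$subdivision %||% NA_character_,
                     condition = mi$condition %||% NA_character_)
  image_volume(data, channel_names = side$channel_names,
               pixel_um = side$pixel_um, z_step_um = side$z_step_um,
               meta = meta)
}

#' Single-channel 2D projection image
#'
#' @param data 2D nonnegative array (y, x).
#' @param channel channel label.
#' @param pixel_um micrometres per pixel.
#' @param meta a [slice_meta()].
#' @return object of class `clamap_projection`.
#' @export
projection_image <- function(data, channel, pixel_um, meta = slice_meta()) {
  if (length(dim(data)) != 2L) stop("projection data must be 2D")
  if (any(data < 0)) stop("projection data must be nonnegative")
  structure(list(data = data, channel = channel, pixel_um = pixel_um,
                 meta = meta), class = "clamap_projection")
}

#' Maximum-intensity projection of one channel
#'
#' Pointwise maximum over z, the projection the whole quantification pipeline
#' operates on.
#'
#' @param vol an [image_volume()].
#' @param channel channel name.
#' @return a [projection_image()].
#' @export
max_project <- function(vol, channel) {
  stopifnot(inherits(vol, "clamap_volume"))
  ci <- match(channel, vol$channel_names)
  if (is.na(ci)) stop("unknown channel: ", channel)
  stack <- vol$data[, , , ci, drop = FALSE]
  dim(stack) <- dim(vol$data)[1:3]
  proj <- apply(stack, c(1, 2), max)
  projection_image(proj, channel = channel, pixel_um = vol$pixel_um,
                   meta = vol$meta)
}
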