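#' Profile axis specification
#'
#' A straight sampling axis through the claustrum region: axis 1 runs
#' parallel to the external capsule (the configured zone orientation), axis 2
#' perpendicular to it. Intensity values are strip means: for each bin along
#' the axis, the mean of all pixels whose projection onto the axis falls in
#' that bin and whose perpendicular offset is at most half the strip width
#' (default 100 um, i.e. the 0.1 mm strip convention).
#'
#' @param origin_um length-2 (x, y) axis origin in um.
#' @param direction_deg axis angle in degrees from the image x-axis.
#' @param strip_width_um full averaging width perpendicular to the axis.
#' @param bin_um sample spacing along the axis.
#' @param extent_um half-length of the axis.
#' @return object of class `clamap_axis`.
#' @export
axis_spec <- function(origin_um, direction_deg, strip_width_um = 100,
                      bin_um = 20, extent_um = 400) {
  stopifnot(length(origin_um) == 2)
  stopifnot_scalar_num(strip_width_um, "strip_width_um", positive = TRUE)
  stopifnot_scalar_num(bin_um, "bin_um", positive = TRUE)
  stopifnot_scalar_num(extent_um, "extent_um", positive = TRUE)
  structure(list(origin_um = as.numeric(origin_um),
                 direction_deg = direction_deg,
                 strip_width_um = strip_width_um, bin_um = bin_um,
                 extent_um = extent_um), class = "clamap_axis")
}

#' The two claustrum profile axes
#'
#' @param origin_um common origin (the retrograde enriched-zone centroid in
#'   the pipeline).
#' @param orientation_deg external-capsule direction.
#' @param ... passed to [axis_spec()].
#' @return list with `parallel` and `perpendicular` [axis_spec()]s, 90 degrees
#'   apart.
#' @export
claustrum_axes <- function(origin_um, orientation_deg, ...) {
  list(parallel = axis_spec(origin_um, orientation_deg, ...),
       perpendicular = axis_spec(origin_um, orientation_deg + 90, ...))
}

#' Binned intensity profile container
#' @keywords internal
new_profile <- function(channel, axis, positions_mm, values, zscored = FALSE,
                        degenerate = FALSE, meta = slice_meta()) {
  pres <- which(!is.na(values))
  peak_index <- if (length(pres)) {
    best <- pres[values[pres] == max(values[pres])]
    # ties broken toward the bin closest to the axis origin
    best[which.min(abs(positions_mm[best]))]
  } else NA_integer_
  structure(list(channel = channel, axis = axis, positions_mm = positions_mm,
                 values = values, zscored = zscored, degenerate = degenerate,
                 peak_index = peak_index, meta = meta),
            class = "clamap_profile")
}

#' Strip-mean intensity profile along an axis
#'
#' Projects every pixel center onto the axis; pixels within half a strip
#' width of the axis contribute to the bin their axial coordinate falls in;
#' each bin value is the plain mean of its pixels' intensities. Bins that
#' receive no pixel are NA. Positions are bin centers in mm relative to the
#' axis origin (negative = before the origin along the axis direction).
#'
#' @param img a [projection_image()].
#' @param axis an [axis_spec()].
#' @return a profile object (class `clamap_profile`).
#' @export
profile_axis <- function(img, axis) {
  stopifnot(inherits(img, "clamap_projection"), inherits(axis, "clamap_axis"))
  px <- img$pixel_um
  nr <- nrow(img$data); nc <- ncol(img$data)
  th <- axis$direction_deg * pi / 180
  u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
  # pixel centers in um: x from columns, y from rows
  xs <- ((seq_len(nc)) - 1) * px - axis$origin_um[1]
  ys <- ((seq_len(nr)) - 1) * px - axis$origin_um[2]
  s <- outer(ys * u[2], xs * u[1], "+") # axial coordinate, (row, col)
  d <- outer(ys * v[2], xs * v[1], "+") # perpendicular offset
  nbins <- max(1L, round(2 * axis$extent_um / axis$bin_um))
  sel <- abs(d) <= axis$strip_width_um / 2 & s >= -axis$extent_um &
    s < -axis$extent_um + nbins * axis$bin_um
  if (!any(sel)) stop("axis strip lies fully outside the image")
  bin <- floor((s[sel] + axis$extent_um) / axis$bin_um) + 1L
  sums <- tapply(img$data[sel], bin, sum)
  counts <- tapply(img$data[sel], bin, length)
  values <- rep(NA_real_, nbins)
  idx <- as.integer(names(sums))
  values[idx] <- as.numeric(sums) / as.numeric(counts)
  centers_mm <- (-axis$extent_um + (seq_len(nbins) - 0.5) * axis$bin_um) / 1000
  new_profile(img$channel, axis, centers_mm, values, meta = img$meta)
}

#' Z-score an intensity profile
#'
#' Standardizes over the present (non-NA) bins using the population SD
#' (divisor n). A constant profile (SD = 0) becomes all zeros with
#' `degenerate = TRUE`.
#'
#' @param p a profile from [profile_axis()].
#' @return a z-scored profile.
#' @export
zscore_profile <- function(p) {
  stopifnot(inherits(p, "clamap_profile"))
  pres <- !is.na(p$values)
  if (sum(pres) < 2) stop("cannot z-score a profile with fewer than 2 bins")
  v <- p$values[pres]
  mu <- mean(v)
  sdp <- sqrt(mean((v - mu)^2))
  out <- p$values
  degenerate <- sdp == 0
  out[pres] <- if (degenerate) 0 else (v - mu) / sdp
  new_profile(p$channel, p$axis, p$positions_mm, out, zscored = TRUE,
              degenerate = degenerate, meta = p$meta)
}

#' Realign profiles to the reference-channel peak and average across slices
#'
#' Shifts all channels of each slice by that slice's reference-channel peak
#' position, so the reference peak sits at 0 mm everywhere; then averages per
#' channel across slices on the shifted common bin grid, keeping bins covered
#' by at least half of the slices. This is what makes profiles from different
#' sections and mice comparable.
#'
#' @param slice_profiles list (one per slice) of named lists of profiles by
#'   channel; all profiles of a slice share the same bin grid.
#' @param reference_channel channel whose peak defines the alignment (the
#'   retrograde channel in the pipeline).
#' @return list with `aligned` (shifted per-slice profiles) and `envelope`
#'   (data frame: channel, position_mm, mean, sd, n).
#' @export
realign_and_average <- function(slice_profiles, reference_channel = "retro") {
  n_slices <- length(slice_profiles)
  if (!n_slices) stop("no slices given")
  aligned <- lapply(slice_profiles, function(sl) {
    ref <- sl[[reference_channel]]
    if (is.null(ref)) stop("slice lacks the reference channel profile")
    if (isTRUE(ref$degenerate) || is.na(ref$peak_index))
      stop("reference profile is degenerate; no peak to align on")
    shift <- ref$positions_mm[ref$peak_index]
    lapply(sl, function(p)
      new_profile(p$channel, p$axis, p$positions_mm - shift, p$values,
                  zscored = p$zscored, degenerate = p$degenerate,
                  meta = p$meta))
  })
  channels <- names(slice_profiles[[1]])
  bin_mm <- diff(aligned[[1]][[1]]$positions_mm[1:2])
  env <- list()
  for (ch in channels) {
    pos <- unlist(lapply(aligned, function(sl) sl[[ch]]$positions_mm))
    val <- unlist(lapply(aligned, function(sl) sl[[ch]]$values))
    key <- round(pos / bin_mm)
    keep <- !is.na(val)
    cnt <- table(key[keep])
    use <- as.integer(names(cnt))[cnt >= ceiling(n_slices / 2)]
    for (k in sort(use)) {
      vv <- val[keep & key == k]
      env[[length(env) + 1L]] <- data.frame(
        channel = ch, position_mm = k * bin_mm, mean = mean(vv),
        sd = if (length(vv) > 1) stats::sd(vv) else 0, n = length(vv))
    }
  }
  list(aligned = aligned, envelope = do.call(rbind, env))
}
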