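#' Detected cells of one channel in one slice
#'
#' @param channel channel label.
#' @param cells data frame with columns id, x_um, y_um, area_um2, intensity.
#' @param meta a [slice_meta()].
#' @return object of class `clamap_cellset`.
#' @export
cell_set <- function(channel, cells, meta = slice_meta()) {
  need <- c("id", "x_um", "y_um", "area_um2", "intensity")
  if (!all(need %in% names(cells)))
    stop("cells must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(cells$id)) stop("cell ids must be unique")
  structure(list(channel = channel, cells = cells, meta = meta),
            class = "clamap_cellset")
}

#' @export
print.clamap_cellset <- function(x, ...) {
  cat(sprintf("<clamap_cellset> channel %s: %d cells\n", x$channel,
              nrow(x$cells)))
  invisible(x)
}

#' Cell detection parameters
#'
#' The counting pipeline is deliberately simple and fully specified: Gaussian
#' smooth, threshold (Otsu by default, so detection is invariant to uniform
#' intensity rescaling), connected components, splitting of touching
#' components by local intensity maxima separated by at least
#' `min_separation_um`, then an area filter. Centroids are intensity-weighted
#' for sub-pixel accuracy.
#'
#' @param smooth_sigma_um Gaussian smoothing sigma in um.
#' @param threshold_mode "otsu" or "fixed".
#' @param fixed_threshold intensity threshold when `threshold_mode = "fixed"`.
#' @param min_area_um2,max_area_um2 accepted detection area range.
#' @param min_separation_um minimum distance between distinct cell peaks.
#' @return object of class `clamap_detection_config`.
#' @export
detection_config <- function(smooth_sigma_um = 2, threshold_mode = c("otsu", "fixed"),
                             fixed_threshold = NULL, min_area_um2 = 8,
                             max_area_um2 = 500, min_separation_um = 6) {
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "fixed" && is.null(fixed_threshold))
    stop("fixed_threshold required when threshold_mode = 'fixed'")
  if (min_area_um2 >= max_area_um2) stop("min_area_um2 must be < max_area_um2")
  if (min_separation_um < 0) stop("min_separation_um must be >= 0")
  structure(list(smooth_sigma_um = smooth_sigma_um,
                 threshold_mode = threshold_mode,
                 fixed_threshold = fixed_threshold,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 min_separation_um = min_separation_um),
            class = "clamap_detection_config")
}

# strict-ish 8-neighborhood local maxima of a matrix above a floor value;
# returns a 2-column matrix of (row, col)
.local_maxima <- function(m, floor_value) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  ok <- m > floor_value
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ok <- ok & (m >= pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
  }
  which(ok, arr.ind = TRUE)
}

#' Detect labelled cells in a projection image
#'
#' Smooth, threshold, label connected components, split touching cells by
#' local maxima with non-maximum suppression at `min_separation_um`, filter by
#' area, and report intensity-weighted centroids in micrometres. Deterministic;
#' a blank image yields an empty set, a contrast-free (e.g. saturated) image
#' yields a warning and an empty set.
#'
#' @param img a [projection_image()].
#' @param cfg a [detection_config()].
#' @return a [cell_set()].
#' @export
detect_cells <- function(img, cfg = detection_config()) {
  stopifnot(inherits(img, "clamap_projection"))
  px <- img$pixel_um
  m <- img$data
  empty <- cell_set(img$channel,
                    data.frame(id = integer(0), x_um = numeric(0),
                               y_um = numeric(0), area_um2 = numeric(0),
                               intensity = numeric(0)), img$meta)
  if (max(m) == 0) return(empty)
  sm <- if (cfg$smooth_sigma_um > 0)
    EBImage::gblur(m, sigma = cfg$smooth_sigma_um / px) else m
  if (diff(range(sm)) < .Machine$double.eps * max(sm)) {
    warning("image has no contrast; no cells detected")
    return(empty)
  }
  thr <- if (cfg$threshold_mode == "otsu")
    EBImage::otsu(EBImage::Image(sm / max(sm)), range = c(0, 1)) * max(sm)
  else cfg$fixed_threshold
  mask <- sm > thr
  if (!any(mask)) return(empty)
  peaks <- .local_maxima(sm, thr)
  if (nrow(peaks) == 0) return(empty)
  # non-maximum suppression: strongest peak wins within min_separation_um
  ord <- order(sm[peaks], decreasing = TRUE)
  peaks <- peaks[ord, , drop = FALSE]
  sep_px2 <- (cfg$min_separation_um / px)^2
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    acc <- peaks[keep, , drop = FALSE]
    d2 <- (acc[, 1] - peaks[i, 1])^2 + (acc[, 2] - peaks[i, 2])^2
    keep[i] <- all(d2 >= sep_px2)
  }
  peaks <- peaks[keep, , drop = FALSE]
  # assign every foreground pixel to its nearest surviving peak
  fg <- which(mask, arr.ind = TRUE)
  d2 <- outer(fg[, 1], peaks[, 1], "-")^2 + outer(fg[, 2], peaks[, 2], "-")^2
  assign_id <- max.col(-d2, ties.method = "first")
  rows <- lapply(seq_len(nrow(peaks)), function(k) {
    sel <- fg[assign_id == k, , drop = FALSE]
    area <- nrow(sel) * px^2
    if (area < cfg$min_area_um2 || area > cfg$max_area_um2) return(NULL)
    w <- m[sel]
    if (sum(w) == 0) w <- rep(1, nrow(sel))
    data.frame(x_um = sum((sel[, 2] - 1) * w) / sum(w) * px,
               y_um = sum((sel[, 1] - 1) * w) / sum(w) * px,
               area_um2 = area, intensity = mean(m[sel]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    if (mean(mask) > 0.5) warning("most of the image is above threshold and no component passed the area filter")
    return(empty)
  }
  cells <- do.call(rbind, rows)
  cells <- cells[order(cells$y_um, cells$x_um), , drop = FALSE]
  cells <- cbind(id = seq_len(nrow(cells)), cells)
  rownames(cells) <- NULL
  cell_set(img$channel, cells, img$meta)
}

#' Summarize cell counts per mouse, channel and subdivision
#'
#' Mean and SD of per-slice counts for each (mouse, channel, subdivision),
#' plus a pooled row per (mouse, channel) averaging over all of that mouse's
#' slices — the "average cell counts across anterior, middle and posterior
#' planes" convention. SD is reported as 0 with `n_flag = "n=1"` when only one
#' slice contributes.
#'
#' @param cellsets list of [cell_set()] objects; every `meta` must carry
#'   `mouse_id` and `subdivision`.
#' @return data frame with columns mouse_id, channel, subdivision, n_slices,
#'   mean_cells, sd_cells, n_flag.
#' @export
count_summary <- function(cellsets) {
  if (!length(cellsets))
    return(data.frame(mouse_id = character(0), channel = character(0),
                      subdivision = character(0), n_slices = integer(0),
                      mean_cells = numeric(0), sd_cells = numeric(0),
                      n_flag = character(0)))
  rows <- lapply(cellsets, function(cs) {
    if (is.na(cs$meta$subdivision))
      stop("cell set without subdivision in metadata (mouse ",
           cs$meta$mouse_id, ")")
    data.frame(mouse_id = cs$meta$mouse_id, channel = cs$channel,
               subdivision = cs$meta$subdivision, n = nrow(cs$cells))
  })
  tab <- do.call(rbind, rows)
  agg <- function(df, subdiv_label) {
    sp <- split(df, list(df$mouse_id, df$channel), drop = TRUE)
    do.call(rbind, lapply(sp, function(g) {
      n <- nrow(g)
      data.frame(mouse_id = g$mouse_id[1], channel = g$channel[1],
                 subdivision = subdiv_label %||% g$subdivision[1],
                 n_slices = n, mean_cells = mean(g$n),
                 sd_cells = if (n > 1) stats::sd(g$n) else 0,
                 n_flag = if (n > 1) "" else "n=1")
    }))
  }
  per_sub <- do.call(rbind, lapply(split(tab, tab$subdivision),
                                   function(s) agg(s, NULL)))
  pooled <- agg(tab, "pooled")
  out <- rbind(per_sub, pooled)
  rownames(out) <- NULL
  out[order(out$mouse_id, out$channel, out$subdivision), , drop = FALSE]
}
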