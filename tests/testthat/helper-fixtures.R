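# Small-scale fixtures and independent oracles used across the suite.

# compact geometry/config for fast tests: 256 um frame, densities scaled so
# zones hold enough cells for delineation
small_geometry <- function() {
  claustrum_geometry(center_um = c(128, 128), axes_um = c(70, 30),
                     orientation_deg = 30, ring_width_um = 45,
                     devoid_margin_um = 10)
}

small_config <- function(seed = 1L, density_scale = 8, noise = TRUE, ...) {
  generator_config(frame_px = 256L, geometry = small_geometry(),
                   densities = lapply(default_densities(),
                                      function(v) v * density_scale),
                   noise_gauss_sd = if (noise) 2 else 0,
                   noise_poisson_gain = if (noise) 1 else 0,
                   seed = seed, ...)
}

# hand-built ground truth with cells on a jittered grid: non-overlapping by
# construction, for detection-fidelity tests
grid_truth <- function(frame_um, spacing_um, jitter_um = 3, z_um = 10,
                       channel = "retro",
                       channels = c("retro", "Nurr1", "Nr2f2", "Tle4", "cFos"),
                       seed = 1) {
  set.seed(seed)
  centers <- seq(spacing_um, frame_um - spacing_um, by = spacing_um)
  pts <- expand.grid(x = centers, y = centers)
  pts$x <- pts$x + stats::runif(nrow(pts), -jitter_um, jitter_um)
  pts$y <- pts$y + stats::runif(nrow(pts), -jitter_um, jitter_um)
  cells <- data.frame(id = seq_len(nrow(pts)), zone = "enriched",
                      primary = channel, x_um = pts$x, y_um = pts$y,
                      z_um = rep(z_um, nrow(pts)))
  for (ch in channels) cells[[ch]] <- ch == channel
  structure(list(cells = cells, geometry = small_geometry(),
                 config_digest = "fixture"),
            class = "clamap_truth")
}

# --- independent oracles -----------------------------------------------------

# per-pixel double-loop strip profile (the definition, computed the slow way)
oracle_profile <- function(mat, pixel_um, axis) {
  nbins <- max(1L, round(2 * axis$extent_um / axis$bin_um))
  th <- axis$direction_deg * pi / 180
  u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
  sums <- counts <- numeric(nbins)
  for (r in seq_len(nrow(mat))) for (cc in seq_len(ncol(mat))) {
    x <- (cc - 1) * pixel_um - axis$origin_um[1]
    y <- (r - 1) * pixel_um - axis$origin_um[2]
    s <- x * u[1] + y * u[2]
    d <- x * v[1] + y * v[2]
    if (abs(d) <= axis$strip_width_um / 2 && s >= -axis$extent_um &&
        s < -axis$extent_um + nbins * axis$bin_um) {
      b <- floor((s + axis$extent_um) / axis$bin_um) + 1
      sums[b] <- sums[b] + mat[r, cc]
      counts[b] <- counts[b] + 1
    }
  }
  ifelse(counts > 0, sums / counts, NA_real_)
}

# exhaustive bipartite matching: maximum number of pairs within the radius,
# minimum total distance among those; exponential, for tiny instances only
oracle_matching <- function(ax, ay, bx, by, radius) {
  na <- length(ax); nb <- length(bx)
  d <- sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
  best_count <- -1L; best_dist <- Inf
  rec <- function(i, used_b, count, dist) {
    if (count + (na - i + 1L) < best_count) return(invisible())
    if (i > na) {
      if (count > best_count ||
          (count == best_count && dist < best_dist)) {
        best_count <<- count; best_dist <<- dist
      }
      return(invisible())
    }
    rec(i + 1L, used_b, count, dist)
    for (j in seq_len(nb)) {
      if (used_b[j] || d[i, j] > radius) next
      used_b[j] <- TRUE
      rec(i + 1L, used_b, count + 1L, dist + d[i, j])
      used_b[j] <- FALSE
    }
  }
  rec(1L, logical(nb), 0L, 0)
  list(count = best_count, dist = best_dist)
}

# closed-form one-way ANOVA from sums of squares
oracle_anova <- function(groups) {
  values <- unlist(groups)
  grand <- mean(values)
  k <- length(groups); N <- length(values)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fstat, df1 = k - 1, df2 = N - k,
       p = stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE))
}

# two-sided t p-value by numerical integration of the t density
oracle_t_pvalue <- function(t, df) {
  2 * stats::integrate(function(x) stats::dt(x, df), abs(t), Inf,
                       rel.tol = 1e-12)$value
}

# shoelace polygon area
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
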