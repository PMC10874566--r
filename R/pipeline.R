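#' Condition presets for the novelty (open field) contrast
#'
#' Generator colocalization overrides per condition: in naive controls 10% of
#' Nurr1+ and 3.0% of Tle4+ cells are c-Fos+; after open-field exposure these
#' rise to 25.6% and 5.7%, i.e. the +15.6 and +2.7 percentage-point
#' activation differences the c-Fos contrast is designed around. Group sizes
#' default to 5 naive and 10 OF mice.
#'
#' @return named list of per-condition settings.
#' @export
condition_presets <- function() {
  list(naive = list(n_mice = 5,
                    coloc = c("Nurr1:cFos" = 0.100, "Tle4:cFos" = 0.030)),
       OF = list(n_mice = 10,
                 coloc = c("Nurr1:cFos" = 0.256, "Tle4:cFos" = 0.057)))
}

#' Full pipeline run configuration
#'
#' One object controlling every stage: generation, detection, colocalization
#' pairing, zone delineation, profiling and statistics. All stage randomness
#' derives from `master_seed`.
#'
#' @param generator a [generator_config()].
#' @param detection a [detection_config()].
#' @param zone a [zone_config()].
#' @param channel_pairs "A:B" pairs for the colocalization tables.
#' @param detect_channels channels put through the full render / project /
#'   detect path; other channels enter downstream stages as ground-truth
#'   centroids ([cellset_from_truth()]).
#' @param profile_channels channels profiled along the two axes.
#' @param profile_args list of [axis_spec()] arguments (strip_width_um,
#'   bin_um, extent_um).
#' @param conditions named list as in [condition_presets()]; each may carry
#'   `n_mice` and generator `coloc` overrides.
#' @param n_mice default mice per condition when a condition does not say.
#' @param slices_per_subdivision slices per AP subdivision per mouse.
#' @param master_seed master RNG seed.
#' @return object of class `clamap_run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       detection = detection_config(),
                       zone = zone_config(),
                       channel_pairs = c("retro:Nurr1", "retro:Nr2f2", "retro:Tle4"),
                       detect_channels = "retro",
                       profile_channels = c("retro", "Nurr1", "Tle4"),
                       profile_args = list(strip_width_um = 100, bin_um = 20,
                                           extent_um = 400),
                       conditions = condition_presets(),
                       n_mice = 6,
                       slices_per_subdivision = 2,
                       master_seed = 1L) {
  pair_ch <- unique(unlist(strsplit(channel_pairs, ":", fixed = TRUE)))
  missing_ch <- setdiff(c(pair_ch, detect_channels, profile_channels),
                        generator$channels)
  if (length(missing_ch))
    stop("channels not present in the generator: ",
         paste(missing_ch, collapse = ", "))
  structure(list(generator = generator, detection = detection, zone = zone,
                 channel_pairs = channel_pairs,
                 detect_channels = detect_channels,
                 profile_channels = profile_channels,
                 profile_args = profile_args, conditions = conditions,
                 n_mice = n_mice,
                 slices_per_subdivision = slices_per_subdivision,
                 master_seed = as.integer(master_seed)),
            class = "clamap_run_config")
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys `generator`, `detection`, `zone`, `profile_args` are passed
#' as argument lists to the corresponding constructors (generator
#' `geometry` as [claustrum_geometry()] arguments, `coloc_fractions` /
#' `densities` as named maps); remaining keys go to [run_config()] directly.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$generator)) {
    g <- y$generator
    if (!is.null(g$geometry)) g$geometry <- do.call(claustrum_geometry, g$geometry)
    if (!is.null(g$coloc_fractions)) g$coloc_fractions <- unlist(g$coloc_fractions)
    if (!is.null(g$densities)) g$densities <- lapply(g$densities, unlist)
    args$generator <- do.call(generator_config, g)
  }
  if (!is.null(y$detection)) args$detection <- do.call(detection_config, y$detection)
  if (!is.null(y$zone)) args$zone <- do.call(zone_config, y$zone)
  for (k in c("channel_pairs", "detect_channels", "profile_channels",
              "profile_args", "conditions", "n_mice",
              "slices_per_subdivision", "master_seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(run_config, args)
}

# build per-slice cell sets for the requested channels: detected for
# detect_channels, ground-truth centroids otherwise
.slice_cellsets <- function(slice, channels, config) {
  gen <- config$generator
  gen$seed <- slice$seed
  out <- list()
  det_ch <- intersect(channels, config$detect_channels)
  if (length(det_ch)) {
    vol <- render_slice(slice$truth, gen, channels = det_ch)
    vol$meta <- slice$meta
    for (ch in det_ch)
      out[[ch]] <- detect_cells(max_project(vol, ch), config$detection)
  }
  for (ch in setdiff(channels, det_ch))
    out[[ch]] <- cellset_from_truth(slice$truth, ch, meta = slice$meta,
                                    config = gen)
  out
}

#' Run the full demarcation pipeline on a synthetic cohort
#'
#' Executes generate -> detect -> colocalization -> zones -> profiles ->
#' statistics for every configured condition and writes all stage tables,
#' polygons and a provenance record under `out_dir`. Deterministic given the
#' configuration: rerunning with the same config reproduces every table.
#'
#' @param config a [run_config()].
#' @param out_dir output directory; NULL returns results in memory only.
#' @return a run manifest list: per-condition cohort manifests, cell sets,
#'   coloc tables, zone polygons, overlays, profile envelopes and stats.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "clamap_run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE))
    stop("cannot create out_dir: ", out_dir)
  gen <- config$generator
  pair_ch <- unique(unlist(strsplit(config$channel_pairs, ":", fixed = TRUE)))
  need_ch <- unique(c(pair_ch, config$profile_channels))
  run <- list(config = config, conditions = list())
  for (cond in names(config$conditions)) {
    cspec <- config$conditions[[cond]]
    cgen <- gen
    if (!is.null(cspec$coloc))
      cgen$coloc_fractions[names(cspec$coloc)] <- unlist(cspec$coloc)
    nm <- cspec$n_mice %||% config$n_mice
    manifest <- generate_cohort(cgen, n_mice = nm,
                                slices_per_subdivision = config$slices_per_subdivision,
                                out_dir = NULL,
                                master_seed = derive_seed(config$master_seed, cond),
                                condition = cond, write_images = FALSE)
    slices <- attr(manifest, "slices")
    ccfg <- config; ccfg$generator <- cgen
    cellsets <- lapply(slices, .slice_cellsets, channels = need_ch,
                       config = ccfg)
    coloc <- coloc_table(cellsets, config$channel_pairs)
    # zones: reference retro polygon + partner polygons per slice
    zones <- lapply(names(slices), function(id) {
      cs <- cellsets[[id]]
      res <- list()
      ref <- try(delineate_enriched_zone(cs[["retro"]], config$zone),
                 silent = TRUE)
      if (inherits(ref, "try-error")) return(res)
      res$retro <- ref
      for (ch in intersect(c("Nurr1", "Nr2f2"), names(cs))) {
        p <- try(delineate_enriched_zone(cs[[ch]], config$zone), silent = TRUE)
        if (!inherits(p, "try-error")) res[[ch]] <- p
      }
      if ("Tle4" %in% names(cs)) {
        p <- try(delineate_devoid_zone(cs[["Tle4"]], vertex_centroid(ref),
                                       config$zone,
                                       frame_um = rep(cgen$frame_px * cgen$pixel_um, 2)),
                 silent = TRUE)
        if (!inherits(p, "try-error")) res$Tle4_devoid <- p
      }
      res
    })
    names(zones) <- names(slices)
    # overlays per subdivision: first slice per subdivision per mouse
    overlays <- list()
    for (sub in c("anterior", "middle", "posterior")) {
      for (partner in intersect(c("Nurr1", "Nr2f2"), need_ch)) {
        pairs <- list()
        for (id in names(slices)) {
          sl <- slices[[id]]
          if (sl$meta$subdivision != sub) next
          if (manifest$slice[manifest$slice_id == id] != 1) next
          z <- zones[[id]]
          if (is.null(z$retro) || is.null(z[[partner]])) next
          pairs[[sl$meta$mouse_id]] <- list(reference = z$retro,
                                            partner = z[[partner]])
        }
        if (length(pairs) >= 1)
          overlays[[paste(sub, partner, sep = ":")]] <-
            overlay_cohort(pairs, sub)
      }
    }
    # profiles: both axes anchored at the retro zone centroid
    profiles <- list()
    for (ax_name in c("parallel", "perpendicular")) {
      slice_profiles <- list()
      for (id in names(slices)) {
        z <- zones[[id]]
        if (is.null(z$retro)) next
        axes <- do.call(claustrum_axes,
                        c(list(origin_um = vertex_centroid(z$retro),
                               orientation_deg = cgen$geometry$orientation_deg),
                          config$profile_args))
        scfg <- cgen; scfg$seed <- slices[[id]]$seed
        vol <- render_slice(slices[[id]]$truth, scfg,
                            channels = config$profile_channels)
        vol$meta <- slices[[id]]$meta
        slice_profiles[[id]] <- lapply(
          stats::setNames(config$profile_channels, config$profile_channels),
          function(ch) zscore_profile(profile_axis(max_project(vol, ch),
                                                   axes[[ax_name]])))
      }
      if (length(slice_profiles))
        profiles[[ax_name]] <- realign_and_average(slice_profiles, "retro")
    }
    run$conditions[[cond]] <- list(manifest = manifest, cellsets = cellsets,
                                   coloc = coloc, zones = zones,
                                   overlays = overlays, profiles = profiles)
  }
  # statistics
  run$stats <- list()
  if (all(c("naive", "OF") %in% names(run$conditions)) &&
      "cFos" %in% gen$channels && "cFos" %in% need_ch) {
    run$stats$cfos <- cfos_activation(
      run$conditions$naive$cellsets, run$conditions$OF$cellsets)
  }
  first <- run$conditions[[1]]
  fr <- first$coloc$mice
  fr <- fr[fr$pair == config$channel_pairs[1] & fr$subdivision != "pooled", ]
  if (nrow(fr) && length(unique(fr$subdivision)) >= 3 &&
      all(table(fr$subdivision) >= 2)) {
    run$stats$subdivision_anova <- anova_bonferroni(
      split(fr$frac_mean, fr$subdivision))
  }
  if (!is.null(out_dir)) .write_run(run, out_dir)
  run
}

# serialize run outputs as delimited text + GeoJSON + provenance JSON
.write_run <- function(run, out_dir) {
  for (cond in names(run$conditions)) {
    cc <- run$conditions[[cond]]
    pre <- file.path(out_dir, cond)
    dir.create(pre, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cc$manifest, file.path(pre, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(cc$coloc$slices, file.path(pre, "coloc_slices.csv"),
                     row.names = FALSE)
    utils::write.csv(cc$coloc$mice, file.path(pre, "coloc_mice.csv"),
                     row.names = FALSE)
    utils::write.csv(cc$coloc$cohort, file.path(pre, "coloc_cohort.csv"),
                     row.names = FALSE)
    for (id in names(cc$zones))
      for (zn in names(cc$zones[[id]]))
        write_zone_polygon(cc$zones[[id]][[zn]],
                           file.path(pre, sprintf("zone_%s_%s.geojson", id, zn)))
    for (ax in names(cc$profiles))
      utils::write.csv(cc$profiles[[ax]]$envelope,
                       file.path(pre, sprintf("profile_envelope_%s.csv", ax)),
                       row.names = FALSE)
  }
  if (!is.null(run$stats$cfos)) {
    utils::write.csv(run$stats$cfos$per_mouse,
                     file.path(out_dir, "cfos_per_mouse.csv"), row.names = FALSE)
    utils::write.csv(run$stats$cfos$summary,
                     file.path(out_dir, "cfos_summary.csv"), row.names = FALSE)
  }
  prov <- list(package_version = as.character(utils::packageVersion("clamap")),
               master_seed = run$config$master_seed,
               config_digest = config_digest(unclass(run$config)),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' Render a plain-text summary report of a pipeline run
#'
#' Venn-style colocalization summaries per pair and subdivision, overlay
#' occupancy statistics, profile envelope peaks, and the statistics tables
#' with significance stars, written as a markdown document.
#'
#' @param run a [run_pipeline()] result.
#' @param path output file (markdown).
#' @return `path`, invisibly.
#' @export
pipeline_report <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Claustrum demarcation pipeline report")
  w("")
  for (cond in names(run$conditions)) {
    cc <- run$conditions[[cond]]
    w("## Condition: %s (%d slices)", cond, nrow(cc$manifest))
    w("")
    w("### Colocalization (mean cell counts, cohort level)")
    ct <- cc$coloc$cohort
    w("")
    w("| pair | subdivision | n mice | n_A | n_AB | frac (mean +/- SD) |")
    w("|---|---|---|---|---|---|")
    for (i in seq_len(nrow(ct)))
      w("| %s | %s | %d | %.1f | %.1f | %.3f +/- %.3f |", ct$pair[i],
        ct$subdivision[i], ct$n_mice[i], ct$mean_n_a[i], ct$mean_n_ab[i],
        ct$mean_frac[i], ifelse(is.na(ct$sd_frac[i]), 0, ct$sd_frac[i]))
    w("")
    if (length(cc$overlays)) {
      w("### Zone overlays")
      for (ov_name in names(cc$overlays)) {
        ov <- cc$overlays[[ov_name]]
        w("- %s: %d mice, max reference occupancy %d", ov_name, ov$n_mice,
          max(ov$occupancy$reference))
      }
      w("")
    }
    for (ax in names(cc$profiles)) {
      env <- cc$profiles[[ax]]$envelope
      w("### Profile envelope, %s axis", ax)
      for (ch in unique(env$channel)) {
        e <- env[env$channel == ch, ]
        w("- %s: peak %.2f at %.2f mm (n up to %d)", ch, max(e$mean),
          e$position_mm[which.max(e$mean)], max(e$n))
      }
      w("")
    }
  }
  if (!is.null(run$stats$cfos)) {
    w("## c-Fos activation (OF vs naive)")
    s <- run$stats$cfos$summary
    w("")
    w("| marker | naive %% | OF %% | upregulation (pts) | t(df) | p | |")
    w("|---|---|---|---|---|---|---|")
    for (i in seq_len(nrow(s)))
      w("| %s | %.1f | %.1f | %+.1f | t(%d)=%.2f | %.2g | %s |", s$marker[i],
        s$mean_naive_pct[i], s$mean_of_pct[i], s$upregulation_pct[i],
        s$df[i], s$t[i], s$p[i], s$stars[i])
    w("")
  }
  if (!is.null(run$stats$subdivision_anova)) {
    a <- run$stats$subdivision_anova
    w("## Colocalization fraction across subdivisions")
    w("one-way ANOVA: F(%d, %d) = %.3f, p = %.3g %s", a$df_between,
      a$df_within, a$F, a$p, significance_stars(a$p))
  }
  invisible(path)
}
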