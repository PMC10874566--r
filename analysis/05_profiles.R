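# Dual-axis z-scored intensity profiles realigned to the retrograde peak.
#
# For one mouse's six slices, the retro / Nurr1 / Tle4 channels are rendered,
# projected, and profiled along the axis parallel to the external capsule
# and its perpendicular (0.1 mm strips, 20 um bins), z-scored, shifted so the
# retrograde peak sits at 0 mm, and averaged into cohort envelopes. The
# expected pattern: retro and Nurr1 peak together at 0; Tle4 dips at the
# peak and rises on both flanks.

source(file.path("analysis", "00_config.R"))

cfg <- base_generator()
man <- generate_cohort(cfg, n_mice = 1, slices_per_subdivision = 2,
                       master_seed = MASTER_SEED, write_images = FALSE)
slices <- attr(man, "slices")
channels <- c("retro", "Nurr1", "Tle4")

for (axis_name in c("parallel", "perpendicular")) {
  slice_profiles <- lapply(slices, function(sl) {
    scfg <- cfg; scfg$seed <- sl$seed
    vol <- render_slice(sl$truth, scfg, channels = channels)
    vol$meta <- sl$meta
    ctr <- vertex_centroid(delineate_enriched_zone(
      cellset_from_truth(sl$truth, "retro", sl$meta, scfg)))
    ax <- claustrum_axes(ctr, cfg$geometry$orientation_deg,
                         strip_width_um = 100, bin_um = 20,
                         extent_um = 400)[[axis_name]]
    lapply(setNames(channels, channels), function(ch)
      zscore_profile(profile_axis(max_project(vol, ch), ax)))
  })
  env <- realign_and_average(slice_profiles, "retro")$envelope
  write.csv(env, file.path(RESULTS, sprintf("profile_envelope_%s.csv",
                                            axis_name)), row.names = FALSE)
  for (ch in channels) {
    e <- env[env$channel == ch, ]
    msg("%s axis, %-6s peak %.2f at %+.2f mm; value at 0 mm %.2f", axis_name,
        ch, max(e$mean), e$position_mm[which.max(e$mean)],
        e$mean[which.min(abs(e$position_mm))])
  }
}
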