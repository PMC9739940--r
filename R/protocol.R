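## Reproducible synthetic cohorts: the fixed recipes from which the test
## suite and the acceptance analysis draw their training and evaluation
## populations. Everything is a pure function of the seed vector.

#' Build a cohort of normalized seedling clouds
#'
#' One seedling per seed, cycling through the 1/2/3-leaf growth stages,
#' normalized and farthest-point-sampled to the network resolution. Labels
#' (semantic, instance) and the analytic leaf areas ride along.
#'
#' @param seeds integer vector; one cloud per seed.
#' @param n_points resolution of each cloud.
#' @return list of [labeled_cloud()]s in the normalized frame.
#' @export
seedling_cohort <- function(seeds, n_points = 256L) {
  lapply(seeds, function(s) {
    sp <- seedling_spec(n_leaves = 1L + (s %% 3L), seed = s)
    fps_downsample(normalize_unit(generate_seedling(sp))$cloud, n_points)
  })
}

#' Build a cohort of normalized single-leaf clouds
#'
#' One leaf per seed with the leaf radius cycling over 3-5 cm (so reference
#' areas have real variance), extracted from a 1-leaf seedling, normalized
#' per leaf and resampled. The analytic area (m^2) and the per-leaf
#' normalization transform are attached as attributes `true_area` and
#' `transform`.
#'
#' @param seeds integer vector.
#' @param n_points resolution of each leaf cloud.
#' @return list of [labeled_cloud()]s in the normalized frame.
#' @export
leaf_cohort <- function(seeds, n_points = 256L) {
  lapply(seeds, function(s) {
    radius <- 0.03 + 0.02 * ((s * 7L) %% 5L) / 4
    sp <- seedling_spec(n_leaves = 1L, leaf_radius = radius, seed = s)
    cl <- generate_seedling(sp)
    leaf <- cloud_subset(cl, cl$instance == 1L)
    nz <- normalize_unit(leaf)
    out <- fps_downsample(nz$cloud, n_points)
    attr(out, "true_area") <- unname(attr(cl, "leaf_areas")[1L])
    attr(out, "transform") <- nz$transform
    out
  })
}

#' Build a noisy synthetic scene
#'
#' Seedling + ground/tray background + sensor noise, all driven by one seed:
#' the input the preprocessing stack is designed to clean.
#'
#' @param seed integer seed (also selects the growth stage).
#' @param noise a [noise_spec()]; its seed is overridden by `seed`.
#' @return a sensor-frame [labeled_cloud()] with `noise_mask` set.
#' @export
noisy_scene <- function(seed, noise = noise_spec()) {
  sp <- seedling_spec(n_leaves = 1L + (seed %% 3L), seed = seed)
  sc <- add_scene_background(generate_seedling(sp), seed = seed)
  noise$seed <- as.integer(seed)
  add_sensor_noise(sc, noise)
}

#' Measure hover/outlier filter efficacy on synthetic scenes
#'
#' For each seed: build a noisy scene, run the pass-through crop, ground and
#' tray removal, then the neighborhood filter, and score removal against the
#' generator's noise mask and labels.
#'
#' @param seeds integer vector of scene seeds.
#' @param fparams a [filter_params()].
#' @return data.frame with per-scene `noise_removed` and `plant_removed`
#'   fractions (relative to the noise/plant points still present after
#'   background removal).
#' @export
filter_efficacy <- function(seeds, fparams = filter_params()) {
  rows <- lapply(seeds, function(s) {
    sc <- noisy_scene(s)
    pre <- passthrough_filter(sc, box_limits())
    plant <- remove_ground_and_tray(pre, estimate_ground_plane(pre))
    nf <- neighborhood_filter(plant, fparams)
    noise <- plant$noise_mask
    organ <- plant$semantic >= 0L
    data.frame(seed = s,
               noise_removed = sum(nf$removed_mask & noise) /
                 max(1L, sum(noise)),
               plant_removed = sum(nf$removed_mask & organ) / sum(organ))
  })
  do.call(rbind, rows)
}
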