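# Shared fixtures. Heavier artifacts (trained models) are built lazily and
# cached for the session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

random_cloud <- function(n, seed = 1, labels = FALSE) {
  set.seed(seed)
  pts <- matrix(runif(n * 3, -1, 1), n, 3)
  if (labels) {
    labeled_cloud(pts, semantic = sample(0:1, n, TRUE),
                  instance = sample(0:2, n, TRUE), frame = "sensor")
  } else labeled_cloud(pts, frame = "sensor")
}

# a small seedling cloud normalized and resampled for the desk-scale network
desk_cloud <- function(seed, n = 256L, n_leaves = NULL) {
  sp <- seedling_spec(n_leaves = if (is.null(n_leaves))
    1L + (seed %% 3) else n_leaves, seed = seed)
  fps_downsample(normalize_unit(generate_seedling(sp))$cloud, n)
}

# a tiny network configuration for fast structural tests
tiny_config <- function(...) {
  stage_config(encoder_resolutions = c(64L, 32L, 16L, 8L),
               encoder_k = c(8L, 4L, 4L, 2L),
               encoder_dims = c(8L, 12L, 16L, 20L),
               decoder_resolutions = c(8L, 16L, 32L, 64L),
               decoder_dims = c(20L, 16L, 12L, 8L),
               mixer_layers_per_stage = 1L,
               group_hidden_max = 16L, head_hidden = c(16L, 8L), ...)
}
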