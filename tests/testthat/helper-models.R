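# Desk-scale trained models, built once per test session and shared across
# test files. The protocols mirror the package's documented desk-scale
# study conditions: 20 seedlings (4x augmented) / 50 leaf pairs, 30 epochs.

get_seg_fit <- function() {
  cache_fixture("seg_fit", function() {
    sources <- seedling_cohort(1:20)
    data <- build_segmentation_dataset(sources, augment_params(),
                                       rep("train", 20L), seed = 42L,
                                       n_points = 256L)$train
    mixnet_train(mixnet_init(desk_stage_config(), seed = 1L), data,
                 train_config("instance", batch_size = 4L, epochs = 30L,
                              lr0 = 0.1, seed = 0L))
  })
}

get_com_fit <- function() {
  cache_fixture("com_fit", function() {
    pairs <- build_completion_dataset(leaf_cohort(1:50), seed = 1L)
    tset <- completion_training_set(pairs, desk_stage_config(), seed = 1L)
    mixnet_train(mixnet_init(desk_stage_config(), seed = 1L), tset,
                 train_config("completion", batch_size = 8L, epochs = 30L,
                              lr0 = 0.01, seed = 0L))
  })
}
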