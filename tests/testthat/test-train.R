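# Training-loop and pipeline plumbing at miniature sizes; the desk-scale
# learning behaviour itself is covered by the acceptance tests.

tiny_seedlings <- function(seeds) {
  lapply(seeds, function(s) {
    sp <- seedling_spec(n_leaves = 1L + (s %% 2L), seed = s,
                        points_per_organ = 200L)
    fps_downsample(normalize_unit(generate_seedling(sp))$cloud, 64L)
  })
}

test_that("training is reproducible and a zero-epoch-like run is the init", {
  data <- tiny_seedlings(1:4)
  model <- mixnet_init(tiny_config(), seed = 3)
  tc <- train_config("semantic", batch_size = 2L, epochs = 2L, seed = 5L)
  f1 <- mixnet_train(model, data, tc)
  f2 <- mixnet_train(model, data, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params$seg_head$lin$W, f2$model$params$seg_head$lin$W)
  # parameters actually move, in every module
  expect_gt(max(abs(f1$model$params$agg[[1]]$lin$W - model$params$agg[[1]]$lin$W)), 0)
  expect_gt(max(abs(f1$model$params$enc_mix[[2]][[1]]$m1$l1$W -
                    model$params$enc_mix[[2]][[1]]$m1$l1$W)), 0)
  expect_gt(max(abs(f1$model$params$seg$fuse[[1]]$lin$W -
                    model$params$seg$fuse[[1]]$lin$W)), 0)
})

test_that("instance-task training also updates the embedding head", {
  data <- tiny_seedlings(1:3)
  model <- mixnet_init(tiny_config(), seed = 3)
  tc <- train_config("instance", batch_size = 3L, epochs = 1L, seed = 5L)
  fit <- mixnet_train(model, data, tc)
  expect_gt(max(abs(fit$model$params$inst_head$lin$W -
                    model$params$inst_head$lin$W)), 0)
  expect_true(all(is.finite(fit$history)))
})

test_that("classification training lowers the category loss", {
  data <- lapply(1:8, function(s) {
    sp <- seedling_spec(n_leaves = 1L + (s %% 2L), seed = s,
                        points_per_organ = 150L)
    cl <- fps_downsample(normalize_unit(generate_seedling(sp))$cloud, 64L)
    list(cloud = cl, category = 1L + (s %% 2L))
  })
  model <- mixnet_init(tiny_config(n_classes = 2L), seed = 1)
  fit <- mixnet_train(model, data,
                      train_config("classification", batch_size = 4L,
                                   epochs = 8L, lr0 = 0.05, seed = 2L))
  expect_lt(fit$history[8], fit$history[1])
})

test_that("completion training decreases the four-stage chamfer loss", {
  leaves <- leaf_cohort(1:6, n_points = 64L)
  cfg <- tiny_config()
  pairs <- build_completion_dataset(leaves, seed = 1)
  tset <- completion_training_set(pairs, cfg, seed = 1)
  expect_equal(nrow(tset[[1]]$input), 64L)
  expect_equal(sapply(tset[[1]]$targets, nrow), c(8, 16, 32, 64))
  model <- mixnet_init(cfg, seed = 2)
  fit <- mixnet_train(model, tset,
                      train_config("completion", batch_size = 3L,
                                   epochs = 6L, lr0 = 0.01, seed = 0L))
  expect_lt(fit$history[6], fit$history[1])
})

test_that("inference contracts: determinism, union completion, resampling", {
  cl <- tiny_seedlings(9)[[1]]
  model <- mixnet_init(tiny_config(), seed = 4)
  a <- mixnet_infer(model, cl, "semantic")
  b <- mixnet_infer(model, cl, "semantic")
  expect_identical(a$semantic, b$semantic)
  inst <- mixnet_infer(model, cl, "instance")
  expect_true(all(inst$instance >= 0L))
  expect_true(all(inst$instance[inst$semantic == 0L] == 0L))
  comp <- mixnet_infer(model, cl, "completion")
  # every partial point is kept verbatim in the completed cloud
  expect_gte(nrow(comp$completed$points), nrow(cl$points))
  expect_identical(comp$completed$points[seq_len(nrow(cl$points)), ],
                   cl$points)
  expect_length(comp$Y, 4)
  # wrong-size input resamples with a warning
  small <- cloud_subset(cl, 1:40)
  expect_warning(mixnet_infer(model, small, "semantic"), "resampling")
})

test_that("checkpoints round-trip through save/load", {
  model <- mixnet_init(tiny_config(), seed = 6)
  f <- withr::local_tempfile(fileext = ".rds")
  mixnet_save(model, f)
  back <- mixnet_load(f)
  expect_identical(back$params, model$params)
  expect_identical(back$config, model$config)
  expect_identical(back$seed, model$seed)
})

test_that("scene preprocessing and the pipeline report plumbing hold together", {
  scene <- noisy_scene(3)
  plant <- preprocess_scene(scene)
  expect_gt(nrow(plant$points), 500)
  # background gone, nearly all kept points are labelled organs
  expect_gt(mean(plant$semantic >= 0L), 0.95)
  # untrained models: the pipeline must still produce a well-formed report
  seg_model <- mixnet_init(tiny_config(), seed = 1)
  com_model <- mixnet_init(tiny_config(), seed = 2)
  out <- suppressWarnings(run_pipeline(list(scene), seg_model, com_model))
  expect_true(is.null(out$report) || all(c("scene", "instance", "area_cm2")
                                         %in% names(out$report)))
  # reproducible end to end
  out2 <- suppressWarnings(run_pipeline(list(scene), seg_model, com_model))
  expect_identical(out$report, out2$report)
})

test_that("cohort builders are deterministic and carry ground truth", {
  a <- seedling_cohort(4:5, n_points = 64L)
  b <- seedling_cohort(4:5, n_points = 64L)
  expect_identical(a[[1]]$points, b[[1]]$points)
  leaves <- leaf_cohort(c(3, 4), n_points = 64L)
  expect_true(all(sapply(leaves, function(l) attr(l, "true_area")) > 0))
  expect_false(attr(leaves[[1]], "true_area") == attr(leaves[[2]], "true_area"))
})
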