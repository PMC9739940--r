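## Orchestration: the SGD training loop with cosine learning-rate decay,
## task-specific forward/backward passes, eval-mode inference, and the
## end-to-end scene -> phenotype pipeline.

sgd_step <- function(params, grads, vel, lr, momentum = 0.9, scale = 1) {
  rec <- function(p, g, v) {
    if (is.numeric(p)) {
      if (is.null(g)) return(list(p = p, v = v))
      v2 <- momentum * v - lr * scale * g
      list(p = p + v2, v = v2)
    } else if (is.list(p)) {
      for (key in seedlingmix_child_keys(p)) {
        if (identical(key, "id")) next
        gv <- if (is.list(g) && (is.character(key) || key <= length(g)))
          g[[key]] else NULL
        r <- rec(p[[key]], gv, v[[key]])
        p[[key]] <- r$p
        v[[key]] <- r$v
      }
      list(p = p, v = v)
    } else list(p = p, v = v)
  }
  rec(params, grads, vel)
}

seedlingmix_child_keys <- function(x) {
  nms <- names(x)
  if (is.null(nms)) seq_along(x) else nms
}

#' Training configuration
#'
#' Batch sizes default to 32 (classification/segmentation) and 16
#' (completion); the initial learning rate to 0.01 (0.001 for completion)
#' with cosine decay to zero over the epochs. The reference protocol trains
#' for 250 epochs; the desk-scale default is 30.
#'
#' @param task one of `"semantic"`, `"instance"`, `"completion"`,
#'   `"classification"`.
#' @param batch_size gradient-accumulation batch (>= 1).
#' @param epochs training epochs (>= 1).
#' @param lr0 initial learning rate (> 0).
#' @param momentum SGD momentum.
#' @param seed integer seed governing shuffling, dropout and initial state.
#' @param delta_s instance-loss margin (instance task only).
#' @param clip_norm global gradient-norm clip applied to each (averaged)
#'   batch gradient; stabilises short high-rate schedules.
#' @return an object of class `train_config`.
#' @export
train_config <- function(task = c("semantic", "instance", "completion",
                                  "classification"),
                         batch_size = NULL, epochs = 30L, lr0 = NULL,
                         momentum = 0.9, seed = 1L, delta_s = 0.1,
                         clip_norm = 5) {
  task <- match.arg(task)
  if (is.null(batch_size)) batch_size <- if (task == "completion") 16L else 32L
  if (is.null(lr0)) lr0 <- if (task == "completion") 0.01 else 0.01
  stopifnot(batch_size >= 1L, epochs >= 1L, lr0 > 0, delta_s > 0,
            clip_norm > 0)
  structure(list(task = task, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr0 = lr0,
                 momentum = momentum, seed = as.integer(seed),
                 delta_s = delta_s, clip_norm = clip_norm),
            class = "train_config")
}

#' Resample a cloud to an exact size
#'
#' Farthest-point sampling when shrinking; seeded duplication of random
#' points when growing (used to feed partial clouds of varying size into the
#' fixed-resolution network).
#'
#' @param cloud a [labeled_cloud()].
#' @param n target size.
#' @param seed seed for the duplication draw.
#' @return a [labeled_cloud()] with exactly `n` points.
#' @export
resample_cloud <- function(cloud, n, seed = 1L) {
  N <- n_points(cloud)
  if (N >= n) return(fps_downsample(cloud, n))
  extra <- with_seed(seed, sample.int(N, n - N, replace = TRUE))
  out <- cloud_subset(cloud, c(seq_len(N), extra))
  attr(out, "leaf_areas") <- attr(cloud, "leaf_areas")
  attr(out, "spec") <- attr(cloud, "spec")
  out
}

#' Build completion training samples from pairs
#'
#' Resamples every partial cloud to the network input resolution and
#' farthest-point-samples the complete cloud to the four decoder output
#' resolutions (the ground-truth pyramid).
#'
#' @param pairs list of `completion_pair` objects in the normalized frame.
#' @param config a [stage_config()].
#' @param seed resampling seed.
#' @return list of samples: `input` (matrix), `targets` (list of 4),
#'   `pair` (the source pair).
#' @export
completion_training_set <- function(pairs, config, seed = 1L) {
  res <- config$encoder_resolutions[1L]
  lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    input <- resample_cloud(pr$partial, res, seed = seed + i)$points
    targets <- completion_targets(pr$complete, config$decoder_resolutions)
    list(input = input, targets = targets, pair = pr)
  })
}

# ---- per-sample forward/backward passes ---------------------------------

.fb_segmentation <- function(model, cloud, category, task, delta_s, state,
                             plan = NULL) {
  enc <- mixnet_encode(model, cloud$points, train = TRUE, state = state,
                       plan = plan)
  dec <- decoder_forward(model, enc, "seg", train = TRUE, state = state)
  sh <- segment_head(model, dec$features, category, train = TRUE,
                     state = state)
  loss <- semantic_loss(sh$scores, cloud$semantic)
  hb <- head_backward(model$params$seg_head, sh$cache,
                      semantic_loss_grad(sh$scores, cloud$semantic))
  d_dec <- ncol(dec$features)
  gfeat <- hb$gin[, seq_len(d_dec), drop = FALSE]
  grads <- list(seg_head = hb$grads)
  if (task == "instance") {
    ih <- instance_head(model, dec$features)
    il <- instance_loss(ih$embedding, cloud$instance, delta_s)
    ib <- instance_head_backward(model, ih$cache,
                                 instance_loss_grad(ih$embedding,
                                                    cloud$instance, delta_s))
    gfeat <- gfeat + ib$gin
    grads$inst_head <- ib$grads
    loss <- loss + il$total
  }
  db <- decoder_backward(model, enc, dec, "seg", g_final = gfeat)
  grads$seg <- db$grads
  eb <- encoder_backward(model, enc, db$genc)
  grads$agg <- eb$agg
  grads$enc_mix <- eb$enc_mix
  list(loss = loss, grads = grads)
}

.fb_completion <- function(model, sample, state, plan = NULL) {
  enc <- mixnet_encode(model, sample$input, train = TRUE, state = state,
                       plan = plan)
  dec <- decoder_forward(model, enc, "com", train = TRUE, state = state)
  loss <- completion_loss(dec$Y, sample$targets)
  gY <- lapply(1:4, function(t) chamfer_grad(dec$Y[[t]], sample$targets[[t]]))
  db <- decoder_backward(model, enc, dec, "com", gY = gY)
  eb <- encoder_backward(model, enc, db$genc)
  list(loss = loss,
       grads = list(com = db$grads, agg = eb$agg, enc_mix = eb$enc_mix))
}

.fb_classification_batch <- function(model, batch, state) {
  B <- length(batch)
  encs <- vector("list", B)
  pooled <- matrix(0, B, model$config$encoder_dims[4L])
  argrow <- matrix(0L, B, model$config$encoder_dims[4L])
  labels <- integer(B)
  for (b in seq_len(B)) {
    encs[[b]] <- mixnet_encode(model, batch[[b]]$cloud$points, train = TRUE,
                               state = state)
    f4 <- encs[[b]]$pyramid[[4L]]$features
    argrow[b, ] <- max.col(t(f4), ties.method = "first")
    pooled[b, ] <- f4[cbind(argrow[b, ], seq_len(ncol(f4)))]
    labels[b] <- batch[[b]]$category - 1L
  }
  ch <- classify_head(model, pooled, train = TRUE, state = state)
  loss <- semantic_loss(ch$scores, labels)
  hb <- head_backward(model$params$cls, ch$cache,
                      semantic_loss_grad(ch$scores, labels))
  grads <- list(cls = hb$grads)
  agg_grads <- NULL
  for (b in seq_len(B)) {
    genc <- lapply(encs[[b]]$pyramid, function(st) 0 * st$features)
    g4 <- genc[[4L]]
    g4[cbind(argrow[b, ], seq_len(ncol(g4)))] <- hb$gin[b, ]
    genc[[4L]] <- g4
    eb <- encoder_backward(model, encs[[b]], genc)
    g_b <- list(agg = eb$agg, enc_mix = eb$enc_mix)
    agg_grads <- if (is.null(agg_grads)) g_b else
      params_axpy(1, g_b, agg_grads)
  }
  grads$agg <- agg_grads$agg
  grads$enc_mix <- agg_grads$enc_mix
  list(loss = loss, grads = grads)
}

#' Train the network
#'
#' SGD with momentum and cosine learning-rate decay, gradient accumulation
#' over `batch_size` samples, per-cloud batch-norm statistics, and full
#' reproducibility from `config$seed` on CPU.
#'
#' Expected `data`:
#' * `semantic`/`instance`: list of normalized [labeled_cloud()]s, each
#'   exactly the input resolution, with semantic (and instance) labels; an
#'   optional `category` attribute selects the object-category one-hot
#'   (default 1).
#' * `completion`: output of [completion_training_set()].
#' * `classification`: list of `list(cloud, category)`.
#'
#' @param model a [mixnet_init()] model.
#' @param data training samples (see details).
#' @param config a [train_config()].
#' @param verbose print per-epoch losses.
#' @return list with the trained `model`, per-epoch mean `history`, and
#'   `config`.
#' @export
mixnet_train <- function(model, data, config, verbose = FALSE) {
  stopifnot(inherits(model, "mixnet_model"), inherits(config, "train_config"))
  set.seed(config$seed)
  state <- new.env(parent = emptyenv())
  vel <- params_zero_like(model$params)
  history <- numeric(config$epochs)
  nd <- length(data)
  task <- config$task
  # geometry-only sampling plans are reused across epochs
  plans <- vector("list", nd)
  get_plan <- function(i, pts) {
    if (is.null(plans[[i]]))
      plans[[i]] <<- mixnet_plan(model$config, pts)
    plans[[i]]
  }
  clipped <- function(g, denom) {
    g <- params_scale(g, 1 / denom)
    nrm <- params_grad_norm(g)
    if (is.finite(nrm) && nrm > config$clip_norm)
      g <- params_scale(g, config$clip_norm / nrm)
    g
  }
  for (e in seq_len(config$epochs)) {
    lr <- config$lr0 * 0.5 * (1 + cos(pi * (e - 1) / config$epochs))
    ord <- sample.int(nd)
    eloss <- 0
    if (task == "classification") {
      starts <- seq(1L, nd, by = config$batch_size)
      for (s0 in starts) {
        batch <- data[ord[s0:min(nd, s0 + config$batch_size - 1L)]]
        fb <- .fb_classification_batch(model, batch, state)
        model$params <- apply_bn_updates(model$params, state)
        st <- sgd_step(model$params, clipped(fb$grads, 1), vel, lr,
                       config$momentum)
        model$params <- st$p
        vel <- st$v
        eloss <- eloss + fb$loss * length(batch)
      }
    } else {
      acc <- NULL
      bcount <- 0L
      for (ii in seq_len(nd)) {
        di <- ord[ii]
        smp <- data[[di]]
        fb <- switch(task,
          semantic = ,
          instance = .fb_segmentation(
            model, smp,
            category = if (is.null(attr(smp, "category"))) 1L else
              attr(smp, "category"),
            task, config$delta_s, state,
            plan = get_plan(di, smp$points)),
          completion = .fb_completion(model, smp, state,
                                      plan = get_plan(di, smp$input)))
        model$params <- apply_bn_updates(model$params, state)
        acc <- if (is.null(acc)) fb$grads else params_axpy(1, fb$grads, acc)
        bcount <- bcount + 1L
        eloss <- eloss + fb$loss
        if (bcount == config$batch_size || ii == nd) {
          st <- sgd_step(model$params, clipped(acc, bcount), vel, lr,
                         config$momentum)
          model$params <- st$p
          vel <- st$v
          acc <- NULL
          bcount <- 0L
        }
      }
    }
    history[e] <- eloss / nd
    if (verbose)
      message(sprintf("epoch %3d/%d  lr %.5f  loss %.5f",
                      e, config$epochs, lr, history[e]))
  }
  list(model = model, history = history, config = config)
}

#' Run inference with a trained model
#'
#' Eval-mode (deterministic) forward passes. Sensor-frame inputs are
#' normalized internally and results mapped back; clouds whose size differs
#' from the input resolution are resampled with a warning.
#'
#' * `semantic`: returns the (resampled) cloud with predicted semantic
#'   labels.
#' * `instance`: additionally clusters the 5-D embeddings of predicted leaf
#'   points by mean-shift (`bandwidth = 2 * delta_s` by default); stem
#'   points get instance 0, leaf clusters 1.. by size.
#' * `completion`: returns the union of the partial input with the final
#'   predicted stage (the original points are kept unchanged), keeping only
#'   predicted points farther than `merge_eps` from every input point — by
#'   default 1.5x the input's median point spacing, so the prediction
#'   contributes only genuinely new surface (the missing region) rather
#'   than near-duplicates jittered onto the observed part. The raw pyramid
#'   `Y` is returned alongside.
#'
#' @param model a trained model.
#' @param cloud input [labeled_cloud()].
#' @param task `"semantic"`, `"instance"` or `"completion"`.
#' @param category object-category index for the segmentation head.
#' @param delta_s instance margin used for the default bandwidth.
#' @param bandwidth mean-shift bandwidth override.
#' @param merge_eps de-duplication radius in normalized units; `NULL`
#'   (default) uses 1.5x the input's median nearest-neighbour spacing.
#' @return task output (see details).
#' @export
mixnet_infer <- function(model, cloud, task = c("semantic", "instance",
                                                "completion"),
                         category = 1L, delta_s = 0.1, bandwidth = NULL,
                         merge_eps = NULL) {
  task <- match.arg(task)
  stopifnot(inherits(cloud, "labeled_cloud"))
  transform <- NULL
  if (cloud$frame == "sensor") {
    nz <- normalize_unit(cloud)
    cloud <- nz$cloud
    transform <- nz$transform
  }
  res <- model$config$encoder_resolutions[1L]
  if (n_points(cloud) != res) {
    warning(sprintf("resampling cloud from %d to %d points",
                    n_points(cloud), res))
    cloud <- resample_cloud(cloud, res)
  }
  enc <- mixnet_encode(model, cloud$points, train = FALSE)
  if (task == "completion") {
    Y <- decode_completion(model, enc)
    Y4 <- Y[[4L]]
    if (is.null(merge_eps))
      merge_eps <- 1.5 * median_nn_spacing(cloud$points)
    keep <- cpp_nn_dist(Y4, cloud$points)$dist > merge_eps
    merged_pts <- rbind(cloud$points, Y4[keep, , drop = FALSE])
    completed <- labeled_cloud(merged_pts, frame = "normalized")
    if (!is.null(transform)) completed <- denormalize_cloud(completed, transform)
    return(list(completed = completed, Y = Y,
                n_new = sum(keep), transform = transform))
  }
  dec <- decoder_forward(model, enc, "seg", train = FALSE)
  sh <- segment_head(model, dec$features, category, train = FALSE)
  out <- cloud
  out$semantic <- sh$labels
  if (task == "instance") {
    ih <- instance_head(model, dec$features)
    inst <- rep(0L, n_points(out))
    leaf_rows <- which(sh$labels == 1L)
    if (length(leaf_rows)) {
      bw <- if (is.null(bandwidth)) 2 * delta_s else bandwidth
      cl <- mean_shift_cluster(ih$embedding[leaf_rows, , drop = FALSE], bw)
      inst[leaf_rows] <- cl + 1L
    }
    out$instance <- inst
    attr(out, "embedding") <- ih$embedding
  }
  attr(out, "scores") <- sh$scores
  attr(out, "gt_semantic") <- cloud$semantic
  attr(out, "gt_instance") <- cloud$instance
  if (!is.null(transform)) {
    out <- denormalize_cloud(out, transform)
    attr(out, "transform") <- transform
  }
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the configuration and initialisation seed.
#'
#' @param model a `mixnet_model` (or [mixnet_train()] result).
#' @param path file path.
#' @return `mixnet_load` returns the model; `mixnet_save` the path.
#' @export
mixnet_save <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname mixnet_save
#' @export
mixnet_load <- function(path) readRDS(path)

#' Estimate the ground plane of a scene
#'
#' The ground is the dominant flat structure: the modal 5-mm z-bin selects
#' its points, and a total-least-squares fit over a 1-cm window around the
#' mode gives the plane.
#'
#' @param cloud scene in the sensor frame.
#' @param bin z histogram bin width, metres.
#' @param window half-window around the modal bin, metres.
#' @return a [plane3()].
#' @export
estimate_ground_plane <- function(cloud, bin = 0.005, window = 0.01) {
  z <- cloud$points[, 3L]
  br <- seq(min(z) - bin, max(z) + bin, by = bin)
  h <- hist(z, breaks = br, plot = FALSE)
  zc <- h$mids[which.max(h$counts)]
  rows <- which(abs(z - zc) <= window)
  fit_plane_lsq(cloud$points[rows, , drop = FALSE])
}

#' Preprocess a raw scene to a plant-only cloud
#'
#' Pass-through crop, ground-plane estimation, ground/tray removal and the
#' neighborhood-space-constraint filter, in that order.
#'
#' @param scene raw scene [labeled_cloud()].
#' @param box a [box_limits()].
#' @param fparams a [filter_params()].
#' @param cut_offset tray cutting band, metres.
#' @return the filtered plant cloud.
#' @export
preprocess_scene <- function(scene, box = box_limits(),
                             fparams = filter_params(), cut_offset = 0.12) {
  cropped <- passthrough_filter(scene, box)
  plane <- estimate_ground_plane(cropped)
  plant <- remove_ground_and_tray(cropped, plane, cut_offset)
  neighborhood_filter(plant, fparams)$kept
}

#' Run the full scene-to-phenotype pipeline
#'
#' For every scene: preprocess, segment semantically, cluster leaf
#' instances, complete each detected leaf, and measure its area by
#' triangulation — in physical units via the recorded normalization
#' transforms. When scenes carry ground-truth labels and analytic leaf
#' areas (synthetic data), predicted leaves are matched to ground-truth
#' instances by point overlap and a correlation report is appended.
#'
#' @param scenes list of scene [labeled_cloud()]s.
#' @param seg_model trained instance/semantic model.
#' @param com_model trained completion model.
#' @param box,fparams,cut_offset preprocessing settings.
#' @param delta_s instance margin for clustering bandwidth.
#' @param min_leaf_points smallest usable leaf cluster.
#' @return list with `report` (data.frame: scene, instance, matched ground
#'   truth id, areas in cm^2) and `correlation` (when truth is available).
#' @export
run_pipeline <- function(scenes, seg_model, com_model,
                         box = box_limits(), fparams = filter_params(),
                         cut_offset = 0.12, delta_s = 0.1,
                         min_leaf_points = 30L) {
  rows <- list()
  for (si in seq_along(scenes)) {
    plant <- preprocess_scene(scenes[[si]], box, fparams, cut_offset)
    nz <- normalize_unit(plant)
    rs <- resample_cloud(nz$cloud, seg_model$config$encoder_resolutions[1L])
    inf <- mixnet_infer(seg_model, rs, "instance", delta_s = delta_s)
    truth_areas <- attr(scenes[[si]], "leaf_areas")
    gt_inst <- attr(inf, "gt_instance")
    for (id in setdiff(sort(unique(inf$instance)), 0L)) {
      rows_id <- which(inf$instance == id)
      if (length(rows_id) < min_leaf_points) next
      leaf <- cloud_subset(rs, rows_id)
      lnz <- normalize_unit(leaf)
      comp <- mixnet_infer(com_model, lnz$cloud, "completion")
      smooth <- mls_smooth(comp$completed)
      comp_scene <- denormalize_cloud(smooth, lnz$transform)
      ar <- leaf_area(comp_scene, transform = nz$transform)
      gt_id <- NA_integer_
      true_area <- NA_real_
      if (!is.null(gt_inst)) {
        votes <- gt_inst[rows_id]
        votes <- votes[votes > 0L]
        if (length(votes))
          gt_id <- as.integer(names(which.max(table(votes))))
        if (!is.null(truth_areas) && !is.na(gt_id))
          true_area <- unname(truth_areas[as.character(gt_id)]) * 1e4
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scene = si, instance = id, gt_instance = gt_id,
        area_cm2 = ar$area * 1e4, true_area_cm2 = true_area)
    }
  }
  report <- do.call(rbind, rows)
  correlation <- NULL
  if (!is.null(report) && any(!is.na(report$true_area_cm2))) {
    ok <- !is.na(report$true_area_cm2)
    if (sum(ok) >= 2L && stats::var(report$true_area_cm2[ok]) > 0)
      correlation <- area_correlation(report$area_cm2[ok],
                                      report$true_area_cm2[ok])
  }
  list(report = report, correlation = correlation)
}
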