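## The mixer-based encoder/decoder for seedling point clouds: a
## curvature-sampled neighborhood-aggregation encoder over four resolutions,
## residual point-mixer blocks that mix features within each point group and
## then across groups via transposition, a progressive coarse-to-fine
## completion decoder with encoder skip fusion, and four heads
## (classification, semantic segmentation, 5-D instance embedding,
## completion). Everything runs on CPU with hand-derived gradients.

#' Network stage configuration
#'
#' Encoder stages pair resolutions `[2048, 1024, 512, 256]` with neighbour
#' counts `[32, 16, 8, 4]` and channel widths `[128, 256, 512, 1024]`
#' (widths grow as resolution shrinks); the completion decoder emits
#' `[256, 512, 1024, 2048]` points with widths `[1024, 512, 256, 128]`.
#' `decoder_resolutions` must mirror `encoder_resolutions` so skip fusion
#' finds a feature map of matching resolution.
#'
#' @param encoder_resolutions strictly decreasing length-4 integer vector;
#'   the first entry is the input size.
#' @param encoder_k neighbours per stage.
#' @param encoder_dims feature widths per encoder stage.
#' @param decoder_resolutions strictly increasing; `rev(encoder_resolutions)`.
#' @param decoder_dims feature widths per decoder stage.
#' @param mixer_layers_per_stage mixer blocks per stage.
#' @param n_classes number of object categories (growth stages).
#' @param n_parts number of semantic part labels (2: stem, leaf).
#' @param instance_dim instance embedding width (fixed at 5).
#' @param dropout head dropout probability.
#' @param group_hidden_max cap on the inter-group mixing MLP hidden width.
#' @param head_hidden the two head LBR widths.
#' @param leaky_slope LeakyReLU negative slope.
#' @return an object of class `stage_config`.
#' @export
stage_config <- function(encoder_resolutions = c(2048L, 1024L, 512L, 256L),
                         encoder_k = c(32L, 16L, 8L, 4L),
                         encoder_dims = c(128L, 256L, 512L, 1024L),
                         decoder_resolutions = rev(encoder_resolutions),
                         decoder_dims = rev(encoder_dims),
                         mixer_layers_per_stage = 2L,
                         n_classes = 3L, n_parts = 2L, instance_dim = 5L,
                         dropout = 0.5, group_hidden_max = 256L,
                         head_hidden = c(128L, 64L), leaky_slope = 0.01) {
  stopifnot(length(encoder_resolutions) == 4L, length(encoder_k) == 4L,
            length(encoder_dims) == 4L, length(decoder_resolutions) == 4L,
            length(decoder_dims) == 4L,
            all(diff(encoder_resolutions) < 0),
            all(diff(decoder_resolutions) > 0),
            identical(as.integer(decoder_resolutions),
                      rev(as.integer(encoder_resolutions))),
            instance_dim == 5L, mixer_layers_per_stage >= 1L,
            n_classes >= 1L, n_parts >= 2L, length(head_hidden) == 2L)
  structure(list(encoder_resolutions = as.integer(encoder_resolutions),
                 encoder_k = as.integer(encoder_k),
                 encoder_dims = as.integer(encoder_dims),
                 decoder_resolutions = as.integer(decoder_resolutions),
                 decoder_dims = as.integer(decoder_dims),
                 mixer_layers_per_stage = as.integer(mixer_layers_per_stage),
                 n_classes = as.integer(n_classes),
                 n_parts = as.integer(n_parts),
                 instance_dim = as.integer(instance_dim),
                 dropout = dropout,
                 group_hidden_max = as.integer(group_hidden_max),
                 head_hidden = as.integer(head_hidden),
                 leaky_slope = leaky_slope),
            class = "stage_config")
}

#' Desk-scale configuration
#'
#' A reduced operating point (input 256 points, widths 32..128, one mixer
#' layer per stage) sized for CPU training in minutes rather than GPU-days;
#' the architecture is otherwise identical to the full configuration.
#'
#' @param ... overrides forwarded to [stage_config()].
#' @return a `stage_config`.
#' @export
desk_stage_config <- function(...) {
  stage_config(encoder_resolutions = c(256L, 128L, 64L, 32L),
               encoder_k = c(16L, 8L, 8L, 4L),
               encoder_dims = c(32L, 64L, 96L, 128L),
               decoder_resolutions = c(32L, 64L, 128L, 256L),
               decoder_dims = c(128L, 96L, 64L, 32L),
               mixer_layers_per_stage = 1L,
               group_hidden_max = 64L,
               head_hidden = c(64L, 32L), ...)
}

mixer_init <- function(S, D, hidden_gr) {
  list(ln1 = ln_init(D), m1 = mlp2_init(D, D, D),
       ln2 = ln_init(D), m2 = mlp2_init(S, hidden_gr, S))
}

#' Initialise network weights
#'
#' Builds every learnable weight (aggregation LBRs, mixer MLPs, decoder
#' fusion layers, coordinate MLPs and the four heads), deterministically
#' from `seed` (He-style initialisation).
#'
#' @param config a [stage_config()].
#' @param seed integer RNG seed (recorded in the model).
#' @return an object of class `mixnet_model` with elements `params`,
#'   `config`, `seed`.
#' @export
mixnet_init <- function(config = stage_config(), seed = 1L) {
  stopifnot(inherits(config, "stage_config"))
  cfg <- config
  with_seed(seed, {
    p <- list(agg = list(), enc_mix = list(),
              seg = list(fuse = list(), mix = list()),
              com = list(fuse = list(), mix = list(), coord = list()))
    d_prev <- 3L
    for (s in 1:4) {
      d_s <- cfg$encoder_dims[s]
      p$agg[[s]] <- lbr_init(2L * d_prev, d_s)
      p$enc_mix[[s]] <- lapply(seq_len(cfg$mixer_layers_per_stage), function(l)
        mixer_init(cfg$encoder_resolutions[s], d_s,
                   min(cfg$encoder_resolutions[s], cfg$group_hidden_max)))
      d_prev <- d_s
    }
    for (branch in c("seg", "com")) {
      d_prev <- cfg$encoder_dims[4L]
      for (t in 1:4) {
        es <- 5L - t
        d_in <- d_prev + cfg$encoder_dims[es]
        d_t <- cfg$decoder_dims[t]
        p[[branch]]$fuse[[t]] <- lbr_init(d_in, d_t)
        p[[branch]]$mix[[t]] <- lapply(
          seq_len(cfg$mixer_layers_per_stage), function(l)
            mixer_init(cfg$decoder_resolutions[t], d_t,
                       min(cfg$decoder_resolutions[t], cfg$group_hidden_max)))
        if (branch == "com") {
          cc <- mlp2_init(d_t, max(32L, d_t %/% 2L), 3L)
          # small-output initialisation: stage predictions start as a tight
          # cluster near the origin of the normalized frame and spread
          # outward under the loss, instead of starting as a random blob
          cc$l2$W <- cc$l2$W * 0.1
          p$com$coord[[t]] <- cc
        }
        d_prev <- d_t
      }
    }
    h <- cfg$head_hidden
    d_dec <- cfg$decoder_dims[4L]
    p$cls <- list(lbr1 = lbr_init(cfg$encoder_dims[4L], h[1L]),
                  lbr2 = lbr_init(h[1L], h[2L]),
                  lin = linear_init(h[2L], cfg$n_classes))
    p$seg_head <- list(lbr1 = lbr_init(d_dec + cfg$n_classes, h[1L]),
                       lbr2 = lbr_init(h[1L], h[2L]),
                       lin = linear_init(h[2L], cfg$n_parts))
    p$inst_head <- list(lin = linear_init(d_dec, cfg$instance_dim))
    structure(list(params = p, config = cfg, seed = as.integer(seed)),
              class = "mixnet_model")
  })
}

#' @export
print.mixnet_model <- function(x, ...) {
  count <- function(p) {
    if (is.numeric(p)) return(length(p))
    if (!is.list(p)) return(0L)
    keys <- if (is.null(names(p))) seq_along(p) else setdiff(names(p), "id")
    if (!length(keys)) return(0L)
    sum(vapply(keys, function(k) count(p[[k]]), 0))
  }
  cat(sprintf("<mixnet_model> input %d pts, %d parameters\n",
              x$config$encoder_resolutions[1L], count(x$params)))
  invisible(x)
}

## ---- neighborhood aggregation ------------------------------------------

#' Neighborhood feature aggregation
#'
#' Samples `n_out` centers by curvature sampling, groups each with its `k`
#' nearest input points (the center itself is its own first neighbour), and
#' aggregates `max-pool_k LBR(concat(F_i - F_ik, repeat(F_i, k)))`: the
#' neighbour-difference channel captures local shape, the repeated center
#' feature keeps absolute context, and the max pool makes the output
#' independent of neighbour order.
#'
#' @param points `N x 3` input coordinates.
#' @param features `N x d_in` input features.
#' @param n_out number of sampled centers (`<= N`).
#' @param k neighbourhood size (`<= N`).
#' @param params an `lbr` parameter list mapping `2 d_in -> d_out`.
#' @param train training mode (batch-norm statistics).
#' @param state optional batch-norm side-channel environment.
#' @param slope LeakyReLU slope.
#' @return list with `points` (`n_out x 3`), `out` (`n_out x d_out`) and a
#'   backward `cache`.
#' @export
neighborhood_aggregate <- function(points, features, n_out, k, params,
                                   train = FALSE, state = NULL,
                                   slope = 0.01, plan = NULL) {
  N <- nrow(points)
  if (k > N) stop("k exceeds the number of input points")
  if (n_out > N) stop("n_out exceeds the number of input points")
  if (is.null(plan)) {
    centers <- .curvature_sample_pts(points, n_out)
    nn_idx <- cpp_knn(points, points[centers, , drop = FALSE], k)$idx
  } else {
    centers <- plan$centers
    nn_idx <- plan$nn_idx
  }
  idx_vec <- as.vector(t(nn_idx))               # center-major blocks of k
  rep_ctr <- rep(seq_len(n_out), each = k)
  Fc_rep <- features[centers, , drop = FALSE][rep_ctr, , drop = FALSE]
  Fnb <- features[idx_vec, , drop = FALSE]
  X <- cbind(Fnb - Fc_rep, Fc_rep)
  lb <- lbr_forward(params, X, train, state, slope)
  d_out <- ncol(lb$out)
  nk <- n_out * k
  out <- lb$out[seq(1L, nk, by = k), , drop = FALSE]
  win <- matrix(1L, n_out, d_out)
  if (k > 1L) {
    for (j in 2:k) {
      sj <- lb$out[seq(j, nk, by = k), , drop = FALSE]
      upd <- sj > out
      out[upd] <- sj[upd]
      win[upd] <- j
    }
  }
  list(points = points[centers, , drop = FALSE], out = out,
       cache = list(centers = centers, idx_vec = idx_vec, lb = lb$cache,
                    win = win, n_out = n_out, k = k, N = N,
                    d_in = ncol(features)))
}

nagg_backward <- function(params, cache, G) {
  n_out <- cache$n_out; k <- cache$k; nk <- n_out * k
  d_out <- ncol(G)
  GY <- matrix(0, nk, d_out)
  for (j in seq_len(k)) {
    mask <- cache$win == j
    tmp <- matrix(0, n_out, d_out)
    tmp[mask] <- G[mask]
    GY[seq(j, nk, by = k), ] <- tmp
  }
  bl <- lbr_backward(params, cache$lb, GY)
  d <- cache$d_in
  gdiff <- bl$gin[, seq_len(d), drop = FALSE]
  grep_ <- bl$gin[, d + seq_len(d), drop = FALSE]
  gfeats <- matrix(0, cache$N, d)
  rs <- rowsum(gdiff, cache$idx_vec)
  gfeats[as.integer(rownames(rs)), ] <- gfeats[as.integer(rownames(rs)), ] + rs
  gctr <- rowsum(grep_ - gdiff, rep(seq_len(n_out), each = k))
  gfeats[cache$centers, ] <- gfeats[cache$centers, ] + gctr
  list(grads = bl$grads, gin_feats = gfeats)
}

## ---- point-mixer block --------------------------------------------------

#' Residual point-mixer block
#'
#' Two residual sublayers over an `S x D` group-feature matrix:
#' `Fc = Fs + MLP1(LayerNorm(Fs))` mixes channels within each group row, and
#' `Fo = Fc + t(MLP2(t(LayerNorm(Fc))))` mixes information across groups by
#' operating on the transposed matrix. Each MLP is two fully connected
#' layers with a LeakyReLU between; the output shape equals the input shape.
#'
#' @param Fs `S x D` feature matrix.
#' @param params mixer parameter list from the model initialiser.
#' @param slope LeakyReLU slope.
#' @return list with `out` (`S x D`) and `cache`.
#' @export
point_mixer_block <- function(Fs, params, slope = 0.01) {
  l1 <- ln_forward(params$ln1, Fs)
  m1 <- mlp2_forward(params$m1, l1$out, slope)
  Fc <- Fs + m1$out
  l2 <- ln_forward(params$ln2, Fc)
  m2 <- mlp2_forward(params$m2, t(l2$out), slope)
  Fo <- Fc + t(m2$out)
  list(out = Fo, cache = list(l1 = l1$cache, m1 = m1$cache,
                              l2 = l2$cache, m2 = m2$cache))
}

mixer_backward <- function(params, cache, G) {
  b2 <- mlp2_backward(params$m2, cache$m2, t(G))
  bl2 <- ln_backward(params$ln2, cache$l2, t(b2$gin))
  gFc <- G + bl2$gin
  b1 <- mlp2_backward(params$m1, cache$m1, gFc)
  bl1 <- ln_backward(params$ln1, cache$l1, b1$gin)
  gFs <- gFc + bl1$gin
  list(grads = list(ln1 = bl1$grads, m1 = b1$grads,
                    ln2 = bl2$grads, m2 = b2$grads),
       gin = gFs)
}

## ---- encoder ------------------------------------------------------------

#' Encode a point cloud into a feature pyramid
#'
#' Runs the four encoder stages (neighborhood aggregation followed by the
#' configured number of point-mixer blocks) and returns every stage, since
#' the decoders fuse skip features at matching resolutions.
#'
#' @param model a [mixnet_init()] model.
#' @param points input `N x 3` matrix (or [labeled_cloud()]) in the
#'   normalized frame; `N` must equal `encoder_resolutions[1]`.
#' @param train training mode.
#' @param state optional batch-norm side channel.
#' @return list with `pyramid` (per stage: `points`, `features`) and
#'   `caches` for the backward pass.
#' @export
mixnet_encode <- function(model, points, train = FALSE, state = NULL,
                          plan = NULL) {
  cfg <- model$config
  if (inherits(points, "labeled_cloud")) points <- points$points
  if (nrow(points) != cfg$encoder_resolutions[1L])
    stop(sprintf("input must have %d points", cfg$encoder_resolutions[1L]))
  slope <- cfg$leaky_slope
  feats <- points
  pts <- points
  pyramid <- vector("list", 4L)
  caches <- vector("list", 4L)
  for (s in 1:4) {
    ag <- neighborhood_aggregate(pts, feats, cfg$encoder_resolutions[s],
                                 cfg$encoder_k[s], model$params$agg[[s]],
                                 train, state, slope,
                                 plan = if (is.null(plan)) NULL else
                                   plan[[s]])
    f <- ag$out
    mix_caches <- vector("list", cfg$mixer_layers_per_stage)
    for (l in seq_len(cfg$mixer_layers_per_stage)) {
      mx <- point_mixer_block(f, model$params$enc_mix[[s]][[l]], slope)
      f <- mx$out
      mix_caches[[l]] <- mx$cache
    }
    pyramid[[s]] <- list(points = ag$points, features = f)
    caches[[s]] <- list(agg = ag$cache, mix = mix_caches)
    pts <- ag$points
    feats <- f
  }
  list(pyramid = pyramid, caches = caches)
}

# Precompute the sampling plan (curvature centers + kNN groups per stage)
# of one cloud: geometry-only work that the training loop caches across
# epochs since the input points never change.
mixnet_plan <- function(config, points) {
  pts <- points
  plan <- vector("list", 4L)
  for (s in 1:4) {
    centers <- .curvature_sample_pts(pts, config$encoder_resolutions[s])
    nn_idx <- cpp_knn(pts, pts[centers, , drop = FALSE],
                      config$encoder_k[s])$idx
    plan[[s]] <- list(centers = centers, nn_idx = nn_idx)
    pts <- pts[centers, , drop = FALSE]
  }
  plan
}

# backward through the encoder; genc[[s]] holds accumulated gradients on
# stage s features (from decoder skips). Returns parameter gradients.
encoder_backward <- function(model, enc, genc) {
  cfg <- model$config
  grads <- list(agg = vector("list", 4L), enc_mix = vector("list", 4L))
  for (s in 4:1) {
    g <- genc[[s]]
    mg <- vector("list", cfg$mixer_layers_per_stage)
    for (l in rev(seq_len(cfg$mixer_layers_per_stage))) {
      mb <- mixer_backward(model$params$enc_mix[[s]][[l]],
                           enc$caches[[s]]$mix[[l]], g)
      mg[[l]] <- mb$grads
      g <- mb$gin
    }
    grads$enc_mix[[s]] <- mg
    ab <- nagg_backward(model$params$agg[[s]], enc$caches[[s]]$agg, g)
    grads$agg[[s]] <- ab$grads
    if (s > 1L) genc[[s - 1L]] <- genc[[s - 1L]] + ab$gin_feats
  }
  grads
}

## ---- interpolation up-sampling -------------------------------------------

.upsample_fwd <- function(points_lo, feats_lo, points_hi, eps = 1e-8) {
  k <- min(3L, nrow(points_lo))
  nn <- cpp_knn(points_lo, points_hi, k)
  w <- 1 / (nn$dist + eps)
  w <- w / rowSums(w)
  out <- matrix(0, nrow(points_hi), ncol(feats_lo))
  for (j in seq_len(k))
    out <- out + w[, j] * feats_lo[nn$idx[, j], , drop = FALSE]
  list(out = out, cache = list(idx = nn$idx, w = w, n_lo = nrow(points_lo)))
}

.upsample_bwd <- function(cache, G) {
  g_lo <- matrix(0, cache$n_lo, ncol(G))
  for (j in seq_len(ncol(cache$idx))) {
    rs <- rowsum(cache$w[, j] * G, cache$idx[, j])
    ridx <- as.integer(rownames(rs))
    g_lo[ridx, ] <- g_lo[ridx, ] + rs
  }
  g_lo
}

#' Inverse-distance interpolation up-sampling
#'
#' Propagates features from a coarse point set to a denser one as the
#' weighted average of the 3 nearest coarse points, weights proportional to
#' `1 / (distance + 1e-8)` and normalized. Coincident points therefore copy
#' their features exactly.
#'
#' @param points_lo `M x 3` coarse coordinates.
#' @param feats_lo `M x d` coarse features.
#' @param points_hi `N x 3` target coordinates (`N > M` in normal use).
#' @return `N x d` interpolated features.
#' @export
upsample_interpolate <- function(points_lo, feats_lo, points_hi) {
  .upsample_fwd(points_lo, feats_lo, points_hi)$out
}

## ---- decoders -----------------------------------------------------------

# shared progressive decoder walk. branch: "seg" (features only) or "com"
# (features + per-stage coordinate offsets). Returns per-stage features and,
# for "com", the predicted clouds Y1..Y4.
decoder_forward <- function(model, enc, branch, train = FALSE, state = NULL) {
  cfg <- model$config
  slope <- cfg$leaky_slope
  p <- model$params[[branch]]
  f <- enc$pyramid[[4L]]$features
  pts_src <- enc$pyramid[[4L]]$points
  stages <- vector("list", 4L)
  Y <- vector("list", 4L)
  for (t in 1:4) {
    es <- 5L - t
    tgt_pts <- enc$pyramid[[es]]$points
    if (t == 1L) {
      up <- list(out = f, cache = NULL)
    } else {
      up <- .upsample_fwd(pts_src, f, tgt_pts)
    }
    fused <- cbind(up$out, enc$pyramid[[es]]$features)
    lb <- lbr_forward(p$fuse[[t]], fused, train, state, slope)
    f_t <- lb$out
    mix_caches <- vector("list", cfg$mixer_layers_per_stage)
    for (l in seq_len(cfg$mixer_layers_per_stage)) {
      mx <- point_mixer_block(f_t, p$mix[[t]][[l]], slope)
      f_t <- mx$out
      mix_caches[[l]] <- mx$cache
    }
    coord_cache <- NULL
    if (branch == "com") {
      cc <- mlp2_forward(p$coord[[t]], f_t, slope)
      Y[[t]] <- cc$out           # absolute coordinates, not offsets
      coord_cache <- cc$cache
      pts_src <- Y[[t]]          # geometry for the next interpolation
    } else {
      pts_src <- tgt_pts
    }
    stages[[t]] <- list(up_cache = up$cache, lb_cache = lb$cache,
                        mix_caches = mix_caches, coord_cache = coord_cache,
                        d_up = ncol(up$out), features = f_t)
    f <- f_t
  }
  list(stages = stages, Y = Y, features = f)
}

# backward through the decoder. g_final: gradient on the last stage features
# (seg branch); gY: list of gradients on Y1..Y4 (com branch). Returns
# parameter grads and the accumulated encoder feature grads genc.
decoder_backward <- function(model, enc, dec, branch, g_final = NULL,
                             gY = NULL) {
  cfg <- model$config
  p <- model$params[[branch]]
  grads <- list(fuse = vector("list", 4L), mix = vector("list", 4L))
  if (branch == "com") grads$coord <- vector("list", 4L)
  genc <- lapply(enc$pyramid, function(st) 0 * st$features)
  g_chain <- if (branch == "seg") g_final else
    matrix(0, nrow(dec$stages[[4L]]$features),
           ncol(dec$stages[[4L]]$features))
  for (t in 4:1) {
    es <- 5L - t
    st <- dec$stages[[t]]
    g <- g_chain
    if (branch == "com" && !is.null(gY[[t]])) {
      cb <- mlp2_backward(p$coord[[t]], st$coord_cache, gY[[t]])
      grads$coord[[t]] <- cb$grads
      g <- g + cb$gin
    }
    mg <- vector("list", cfg$mixer_layers_per_stage)
    for (l in rev(seq_len(cfg$mixer_layers_per_stage))) {
      mb <- mixer_backward(p$mix[[t]][[l]], st$mix_caches[[l]], g)
      mg[[l]] <- mb$grads
      g <- mb$gin
    }
    grads$mix[[t]] <- mg
    lb <- lbr_backward(p$fuse[[t]], st$lb_cache, g)
    grads$fuse[[t]] <- lb$grads
    g_up <- lb$gin[, seq_len(st$d_up), drop = FALSE]
    g_skip <- lb$gin[, st$d_up + seq_len(ncol(lb$gin) - st$d_up),
                     drop = FALSE]
    genc[[es]] <- genc[[es]] + g_skip
    if (t == 1L) {
      genc[[4L]] <- genc[[4L]] + g_up
      g_chain <- NULL
    } else {
      g_chain <- .upsample_bwd(st$up_cache, g_up)
    }
  }
  list(grads = grads, genc = genc)
}

#' Progressive completion decoding
#'
#' Decodes a feature pyramid of a partial leaf into four predicted clouds of
#' increasing resolution. Each stage interpolates the previous stage's
#' features onto the encoder points of the next resolution, fuses the
#' encoder skip features of that resolution, applies the point-mixer blocks
#' and predicts per-point coordinate offsets; the predicted points carry the
#' features to the next stage. The final stage emits exactly the input
#' resolution (2048 in the full configuration).
#'
#' @param model a [mixnet_init()] model.
#' @param pyramid result of [mixnet_encode()] on the partial cloud.
#' @return list of predicted clouds `Y1..Y4` (matrices of increasing size).
#' @export
decode_completion <- function(model, pyramid) {
  dec <- decoder_forward(model, pyramid, "com", train = FALSE)
  dec$Y
}

# median nearest-neighbour spacing of a point set
median_nn_spacing <- function(points) {
  stats::median(cpp_knn(points, points, 2L)$dist[, 2L])
}

## ---- heads ---------------------------------------------------------------

head_forward <- function(p, X, dropout, train, state = NULL, slope = 0.01) {
  f1 <- lbr_forward(p$lbr1, X, train, state, slope)
  d1 <- dropout_forward(f1$out, dropout, train)
  f2 <- lbr_forward(p$lbr2, d1$out, train, state, slope)
  d2 <- dropout_forward(f2$out, dropout, train)
  f3 <- linear_forward(p$lin, d2$out)
  list(out = f3$out, cache = list(f1 = f1$cache, d1 = d1$cache,
                                  f2 = f2$cache, d2 = d2$cache,
                                  f3 = f3$cache))
}

head_backward <- function(p, cache, G) {
  b3 <- linear_backward(p$lin, cache$f3, G)
  g <- dropout_backward(cache$d2, b3$gin)
  b2 <- lbr_backward(p$lbr2, cache$f2, g)
  g <- dropout_backward(cache$d1, b2$gin)
  b1 <- lbr_backward(p$lbr1, cache$f1, g)
  list(grads = list(lbr1 = b1$grads, lbr2 = b2$grads, lin = b3$grads),
       gin = b1$gin)
}

#' Classification head
#'
#' Two cascaded LBR units, each followed by dropout, and a final linear
#' layer; the predicted category is the argmax score. The global feature is
#' the channelwise max pool over the coarsest encoder stage.
#'
#' @param model a [mixnet_init()] model.
#' @param global_features `B x d` pooled features (one row per cloud).
#' @param train training mode (dropout active).
#' @param state optional batch-norm side channel.
#' @return list with `scores` (`B x n_classes`), `labels` (argmax, 1-based)
#'   and `cache`.
#' @export
classify_head <- function(model, global_features, train = FALSE,
                          state = NULL) {
  hf <- head_forward(model$params$cls, global_features, model$config$dropout,
                     train, state, model$config$leaky_slope)
  list(scores = hf$out, labels = max.col(hf$out, ties.method = "first"),
       cache = hf$cache)
}

#' Semantic segmentation head
#'
#' Broadcast-concatenates the object category one-hot vector to every
#' point's feature row, then applies the classification stack without
#' pooling; the per-point label is the argmax over part scores.
#'
#' @param model a [mixnet_init()] model.
#' @param per_point_features `N x d` decoder features at full resolution.
#' @param category 1-based category index (`<= n_classes`).
#' @param train training mode.
#' @param state optional batch-norm side channel.
#' @return list with `scores` (`N x n_parts`), `labels` (0-based part ids:
#'   0 = stem, 1 = leaf) and `cache`.
#' @export
segment_head <- function(model, per_point_features, category,
                         train = FALSE, state = NULL) {
  cfg <- model$config
  if (category < 1L || category > cfg$n_classes)
    stop("category index out of range")
  onehot <- matrix(0, nrow(per_point_features), cfg$n_classes)
  onehot[, category] <- 1
  X <- cbind(per_point_features, onehot)
  hf <- head_forward(model$params$seg_head, X, cfg$dropout, train, state,
                     cfg$leaky_slope)
  list(scores = hf$out,
       labels = max.col(hf$out, ties.method = "first") - 1L,
       cache = hf$cache)
}

#' Instance embedding head
#'
#' A pointwise (kernel-size-1) linear map with LeakyReLU reducing the
#' feature dimension to 5; permutation-equivariant by construction.
#'
#' @param model a [mixnet_init()] model.
#' @param per_point_features `N x d` decoder features.
#' @return list with `embedding` (`N x 5`) and `cache`.
#' @export
instance_head <- function(model, per_point_features) {
  f1 <- linear_forward(model$params$inst_head$lin, per_point_features)
  f2 <- lrelu_forward(f1$out, model$config$leaky_slope)
  list(embedding = f2$out, cache = list(f1 = f1$cache, f2 = f2$cache))
}

instance_head_backward <- function(model, cache, G) {
  g <- lrelu_backward(cache$f2, G)
  b <- linear_backward(model$params$inst_head$lin, cache$f1, g)
  list(grads = list(lin = b$grads), gin = b$gin)
}

## ---- mean-shift clustering ------------------------------------------------

#' Flat-kernel mean-shift clustering
#'
#' Shifts every point to the mean of the original points within `bandwidth`
#' until convergence, merges modes closer than `bandwidth / 2`, and labels
#' every point by its mode. Labels are contiguous from 0, ordered by cluster
#' size descending (ties by first occurrence).
#'
#' @param embedding `N x d` matrix (the 5-D instance embedding in normal use).
#' @param bandwidth kernel radius (> 0).
#' @param max_iter iteration cap.
#' @param tol convergence threshold on the maximum shift.
#' @return integer vector of per-point cluster labels starting at 0.
#' @export
mean_shift_cluster <- function(embedding, bandwidth, max_iter = 100L,
                               tol = NULL) {
  stopifnot(bandwidth > 0)
  X <- as.matrix(embedding)
  n <- nrow(X)
  if (is.null(tol)) tol <- 1e-4 * bandwidth
  if (n == 1L) return(0L)
  modes <- X
  bw2 <- bandwidth^2
  sq <- rowSums(X^2)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(modes^2), sq, "+") - 2 * modes %*% t(X)
    inb <- d2 <= bw2
    cnt <- pmax(rowSums(inb), 1L)
    new_modes <- (inb %*% X) / cnt
    shift <- max(abs(new_modes - modes))
    modes <- new_modes
    if (shift < tol) break
  }
  # merge modes within bandwidth/2, greedily in point order
  centers <- matrix(numeric(0), 0L, ncol(X))
  assign_ <- integer(n)
  thr2 <- (bandwidth / 2)^2
  for (i in seq_len(n)) {
    if (nrow(centers)) {
      d2 <- rowSums(sweep(centers, 2L, modes[i, ], "-")^2)
      j <- which.min(d2)
      if (d2[j] <= thr2) {
        assign_[i] <- j
        next
      }
    }
    centers <- rbind(centers, modes[i, ])
    assign_[i] <- nrow(centers)
  }
  sizes <- tabulate(assign_, nbins = nrow(centers))
  rank_ <- rank(-sizes, ties.method = "first")
  as.integer(rank_[assign_] - 1L)
}
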