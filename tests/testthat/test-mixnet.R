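test_that("stage_config validates shape relationships", {
  expect_s3_class(stage_config(), "stage_config")
  expect_error(stage_config(encoder_resolutions = c(2048L, 1024L, 512L, 512L)))
  expect_error(stage_config(decoder_resolutions = c(256L, 512L, 1024L, 4096L)))
  expect_error(stage_config(instance_dim = 4L))
})

test_that("neighborhood aggregation matches a per-center loop oracle", {
  set.seed(41)
  N <- 32; d_in <- 3; n_out <- 8; k <- 4; d_out <- 16
  pts <- matrix(runif(N * 3), N, 3)
  feats <- matrix(rnorm(N * d_in), N, d_in)
  p <- seedlingmix:::lbr_init(2 * d_in, d_out)
  ag <- neighborhood_aggregate(pts, feats, n_out, k, p, train = FALSE)
  expect_equal(dim(ag$points), c(n_out, 3))
  expect_equal(dim(ag$out), c(n_out, d_out))
  # explicit loop over centers: knn, concat(diff, repeat), LBR, max-pool
  centers <- seedlingmix:::.curvature_sample_pts(pts, n_out)
  lbr_eval <- function(X) {
    z <- X %*% p$lin$W
    z <- sweep(z, 2, p$lin$b, "+")
    z <- sweep(sweep(z, 2, p$bn$running_mean, "-"), 2,
               sqrt(p$bn$running_var + 1e-5), "/")
    z <- sweep(sweep(z, 2, p$bn$gamma, "*"), 2, p$bn$beta, "+")
    ifelse(z > 0, z, 0.01 * z)
  }
  for (i in seq_len(n_out)) {
    ci <- centers[i]
    dd <- sqrt(colSums((t(pts) - pts[ci, ])^2))
    nb <- order(dd, seq_len(N))[1:k]
    X <- cbind(feats[nb, , drop = FALSE] -
                 matrix(feats[ci, ], k, d_in, byrow = TRUE),
               matrix(feats[ci, ], k, d_in, byrow = TRUE))
    expect_equal(ag$out[i, ], apply(lbr_eval(X), 2, max), tolerance = 1e-5)
  }
})

test_that("self-neighbor aggregation reduces to LBR(concat(0, F))", {
  set.seed(42)
  N <- 16
  pts <- matrix(runif(N * 3), N, 3)
  feats <- matrix(rnorm(N * 3), N, 3)
  p <- seedlingmix:::lbr_init(6L, 8L)
  ag <- neighborhood_aggregate(pts, feats, N, 1L, p, train = FALSE)
  direct <- seedlingmix:::lbr_forward(p, cbind(feats * 0, feats),
                                      train = FALSE)$out
  expect_equal(ag$out, direct, tolerance = 1e-12)
})

test_that("mixer block is a residual identity at zero weights", {
  set.seed(43)
  S <- 6; D <- 8
  p <- seedlingmix:::mixer_init(S, D, 4L)
  p$m1$l1$W[] <- 0; p$m1$l1$b[] <- 0; p$m1$l2$W[] <- 0; p$m1$l2$b[] <- 0
  p$m2$l1$W[] <- 0; p$m2$l1$b[] <- 0; p$m2$l2$W[] <- 0; p$m2$l2$b[] <- 0
  Fs <- matrix(rnorm(S * D), S, D)
  expect_equal(point_mixer_block(Fs, p)$out, Fs)
})

test_that("mixer block matches a hand computation of its two sublayers", {
  p <- seedlingmix:::mixer_init(2L, 2L, 2L)
  # unit weights, no bias, identity-ish layer norms
  for (m in c("m1", "m2")) for (l in c("l1", "l2")) {
    p[[m]][[l]]$W <- matrix(1, 2, 2); p[[m]][[l]]$b <- c(0, 0)
  }
  Fs <- rbind(c(1, -1), c(2, 0))
  lnorm <- function(x) (x - mean(x)) / sqrt(mean(x^2) - mean(x)^2 + 1e-5)
  lrelu <- function(x) ifelse(x > 0, x, 0.01 * x)
  mlp <- function(X) lrelu(X %*% matrix(1, 2, 2)) %*% matrix(1, 2, 2)
  L1 <- t(apply(Fs, 1, lnorm))
  Fc <- Fs + mlp(L1)
  L2 <- t(apply(Fc, 1, lnorm))
  Fo <- Fc + t(mlp(t(L2)))
  expect_equal(point_mixer_block(Fs, p)$out, Fo, tolerance = 1e-10)
})

test_that("mixer block preserves arbitrary shapes", {
  for (sd in list(c(1L, 8L), c(64L, 128L))) {
    p <- seedlingmix:::mixer_init(sd[1], sd[2], 16L)
    Fs <- matrix(rnorm(prod(sd)), sd[1], sd[2])
    expect_equal(dim(point_mixer_block(Fs, p)$out), sd)
  }
})

test_that("encoder emits the configured pyramid shapes deterministically", {
  cfg <- tiny_config()
  model <- mixnet_init(cfg, seed = 2)
  pts <- matrix(runif(64 * 3, -1, 1), 64, 3)
  enc <- mixnet_encode(model, pts)
  for (s in 1:4) {
    expect_equal(dim(enc$pyramid[[s]]$points),
                 c(cfg$encoder_resolutions[s], 3L))
    expect_equal(dim(enc$pyramid[[s]]$features),
                 c(cfg$encoder_resolutions[s], cfg$encoder_dims[s]))
    expect_true(all(is.finite(enc$pyramid[[s]]$features)))
  }
  enc2 <- mixnet_encode(model, pts)
  expect_identical(enc$pyramid[[4]]$features, enc2$pyramid[[4]]$features)
  expect_error(mixnet_encode(model, pts[1:10, ]), "must have 64 points")
})

test_that("neighborhood aggregation is permutation-equivariant up to sampling", {
  set.seed(45)
  pts <- matrix(runif(64 * 3, -1, 1), 64, 3)
  feats <- matrix(rnorm(64 * 3), 64, 3)
  perm <- sample(64)
  p <- seedlingmix:::lbr_init(6L, 8L)
  a <- neighborhood_aggregate(pts, feats, 16L, 4L, p, train = FALSE)
  b <- neighborhood_aggregate(pts[perm, ], feats[perm, ], 16L, 4L, p,
                              train = FALSE)
  key <- function(P) apply(round(P, 10), 1, paste, collapse = ",")
  ka <- key(a$points); kb <- key(b$points)
  # the greedy curvature selector can swap near-tied centers when float
  # summation order changes; the shared centers must agree exactly
  shared <- intersect(ka, kb)
  expect_gte(length(shared) / 16, 0.75)
  ia <- match(shared, ka); ib <- match(shared, kb)
  expect_equal(a$out[ia, , drop = FALSE], b$out[ib, , drop = FALSE],
               tolerance = 1e-8)
})

test_that("interpolation up-sampling matches a 3-NN loop oracle", {
  set.seed(44)
  lo <- matrix(runif(30), 10, 3)
  f_lo <- matrix(rnorm(40), 10, 4)
  hi <- matrix(runif(90), 30, 3)
  out <- upsample_interpolate(lo, f_lo, hi)
  for (i in 1:30) {
    d <- sqrt(colSums((t(lo) - hi[i, ])^2))
    nb <- order(d)[1:3]
    w <- 1 / (d[nb] + 1e-8)
    w <- w / sum(w)
    expect_equal(out[i, ], colSums(f_lo[nb, ] * w), tolerance = 1e-6)
  }
  # coincident points copy features exactly
  copies <- upsample_interpolate(lo, f_lo, lo[c(2, 5), ])
  expect_equal(copies, f_lo[c(2, 5), ], tolerance = 1e-6)
  # midpoint of two close points with the third neighbour far: the average
  seg <- rbind(c(0, 0, 0), c(0.2, 0, 0), c(1e6, 0, 0))
  fs <- rbind(c(1, 0), c(0, 1), c(100, 100))
  mid <- upsample_interpolate(seg, fs, matrix(c(0.1, 0, 0), 1, 3))
  expect_equal(mid, matrix(c(0.5, 0.5), 1, 2), tolerance = 1e-3)
})

test_that("completion decoder emits the configured resolutions", {
  cfg <- tiny_config()
  model <- mixnet_init(cfg, seed = 5)
  pts <- matrix(runif(64 * 3, -1, 1), 64, 3)
  Y <- decode_completion(model, mixnet_encode(model, pts))
  expect_equal(sapply(Y, nrow), c(8, 16, 32, 64))
  expect_true(all(sapply(Y, function(y) all(is.finite(y)))))
  Y2 <- decode_completion(model, mixnet_encode(model, pts))
  expect_identical(Y[[4]], Y2[[4]])
})

test_that("full-scale decoder's final stage emits exactly 2048 points", {
  model <- cache_fixture("full_model", function()
    mixnet_init(stage_config(), seed = 1))
  set.seed(46)
  pts <- matrix(runif(2048 * 3, -1, 1), 2048, 3)
  Y <- decode_completion(model, mixnet_encode(model, pts))
  expect_equal(sapply(Y, nrow), c(256, 512, 1024, 2048))
  expect_true(all(is.finite(Y[[4]])))
})

test_that("heads honour their contracts", {
  cfg <- tiny_config()
  model <- mixnet_init(cfg, seed = 7)
  feats <- matrix(rnorm(64 * cfg$decoder_dims[4]), 64, cfg$decoder_dims[4])
  seg <- segment_head(model, feats, 1L)
  expect_equal(dim(seg$scores), c(64L, cfg$n_parts))
  expect_true(all(seg$labels %in% 0:(cfg$n_parts - 1)))
  seg2 <- segment_head(model, feats, 2L)
  expect_gt(max(abs(seg$scores - seg2$scores)), 0)  # category sensitivity
  expect_error(segment_head(model, feats, 99L), "out of range")
  ih <- instance_head(model, feats)
  expect_equal(ncol(ih$embedding), 5L)
  # pointwise equivariance: permuting rows permutes the embedding
  perm <- sample(64)
  expect_equal(instance_head(model, feats[perm, ])$embedding,
               ih$embedding[perm, ])
  # explicit affine+lrelu oracle
  W <- model$params$inst_head$lin$W
  b <- model$params$inst_head$lin$b
  z <- sweep(feats %*% W, 2, b, "+")
  expect_equal(ih$embedding, ifelse(z > 0, z, 0.01 * z), tolerance = 1e-12)
  glob <- matrix(rnorm(2 * cfg$encoder_dims[4]), 2, cfg$encoder_dims[4])
  cls <- classify_head(model, glob)
  expect_equal(dim(cls$scores), c(2L, cfg$n_classes))
  expect_identical(classify_head(model, glob)$scores, cls$scores)
})

test_that("segment head argmax matches a hand calculation on 2 points", {
  cfg <- tiny_config(n_classes = 1L)
  model <- mixnet_init(cfg, seed = 8)
  d <- cfg$decoder_dims[4]
  # collapse the head to a transparent map: identity-ish LBRs are hard to
  # hand-set, so drive only the final linear layer on fixed inputs
  feats <- matrix(0, 2, d)
  sh <- segment_head(model, feats, 1L)
  # both rows identical input -> identical scores; forcing the final layer
  # weights decides the argmax
  model$params$seg_head$lin$W[] <- 0
  model$params$seg_head$lin$b <- c(1, -1)
  sh2 <- segment_head(model, feats, 1L)
  expect_equal(sh2$labels, c(0L, 0L))
  model$params$seg_head$lin$b <- c(-1, 1)
  expect_equal(segment_head(model, feats, 1L)$labels, c(1L, 1L))
  expect_equal(sh$scores[1, ], sh$scores[2, ])
})

test_that("dropout masks are reproducible under a fixed seed", {
  cfg <- tiny_config()
  model <- mixnet_init(cfg, seed = 9)
  glob <- matrix(rnorm(4 * cfg$encoder_dims[4]), 4, cfg$encoder_dims[4])
  set.seed(123)
  a <- classify_head(model, glob, train = TRUE)$scores
  set.seed(123)
  b <- classify_head(model, glob, train = TRUE)$scores
  expect_identical(a, b)
  set.seed(124)
  c2 <- classify_head(model, glob, train = TRUE)$scores
  expect_gt(max(abs(a - c2)), 0)
})

test_that("analytic gradients of the full network match finite differences", {
  cfg <- stage_config(encoder_resolutions = c(24L, 12L, 8L, 4L),
                      encoder_k = c(4L, 4L, 3L, 2L),
                      encoder_dims = c(6L, 8L, 10L, 12L),
                      decoder_resolutions = c(4L, 8L, 12L, 24L),
                      decoder_dims = c(12L, 10L, 8L, 6L),
                      mixer_layers_per_stage = 1L, group_hidden_max = 8L,
                      head_hidden = c(8L, 6L), dropout = 0)
  model <- mixnet_init(cfg, seed = 11)
  set.seed(47)
  cl <- labeled_cloud(matrix(runif(24 * 3, -1, 1), 24, 3),
                      semantic = sample(0:1, 24, TRUE),
                      instance = sample(0:1, 24, TRUE),
                      frame = "normalized")
  sm <- asNamespace("seedlingmix")
  fb <- sm$.fb_segmentation(model, cl, 1L, "instance", 0.1, NULL)
  loss_at <- function(m) {
    enc <- mixnet_encode(m, cl$points, train = TRUE)
    dec <- sm$decoder_forward(m, enc, "seg", train = TRUE)
    sh <- segment_head(m, dec$features, 1L, train = TRUE)
    semantic_loss(sh$scores, cl$semantic) +
      instance_loss(instance_head(m, dec$features)$embedding,
                    cl$instance, 0.1)$total
  }
  probes <- list(list(c("agg"), 2L, c("lin", "W"), 3L),
                 list(c("enc_mix"), 3L, NULL, NULL),
                 list(c("seg", "fuse"), 2L, c("bn", "beta"), 2L),
                 list(c("seg_head"), NULL, c("lbr1", "lin", "W"), 5L))
  eps <- 1e-5
  for (pr in probes) {
    path <- as.list(pr[[1]])
    if (!is.null(pr[[2]])) path <- c(path, pr[[2]])
    if (identical(pr[[1]], c("enc_mix"))) path <- c(path, 1L, "m1", "l1", "W")
    if (!is.null(pr[[3]])) path <- c(path, as.list(pr[[3]]))
    idx <- if (is.null(pr[[4]])) 2L else pr[[4]]
    leaf_get <- function(x) { for (p in path) x <- x[[p]]; x }
    g <- leaf_get(fb$grads)[idx]
    bump <- function(m, dd) {
      set_rec <- function(x, pp) {
        if (length(pp) == 1L) {
          x[[pp[[1]]]][idx] <- x[[pp[[1]]]][idx] + dd
          return(x)
        }
        x[[pp[[1]]]] <- set_rec(x[[pp[[1]]]], pp[-1])
        x
      }
      m$params <- set_rec(m$params, path)
      m
    }
    num <- (loss_at(bump(model, eps)) - loss_at(bump(model, -eps))) / (2 * eps)
    expect_equal(g, num, tolerance = 1e-4,
                 info = paste(unlist(path), collapse = "/"))
  }
})
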