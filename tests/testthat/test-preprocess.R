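test_that("passthrough filter matches a brute-force box test", {
  cl <- random_cloud(1000, seed = 2)
  cl$points <- cl$points * 0.6            # spread beyond the box
  box <- box_limits(0.5, 0.5, 0.7)
  kept <- passthrough_filter(cl, box)
  zmax <- max(cl$points[, 3])
  manual <- abs(cl$points[, 1]) <= 0.25 & abs(cl$points[, 2]) <= 0.25 &
    cl$points[, 3] >= zmax - 0.7
  expect_equal(kept$points, cl$points[manual, , drop = FALSE])
  far <- labeled_cloud(rbind(c(0, 0, 0), c(1.25, 0, 0)))
  expect_equal(nrow(passthrough_filter(far, box)$points), 1)
  expect_error(passthrough_filter(labeled_cloud(matrix(c(5, 5, -5), 1, 3)),
                                  box), "no plant")
})

test_that("total-least-squares plane fit recovers exact and noisy planes", {
  # exact horizontal plane
  set.seed(1)
  pts <- cbind(runif(50), runif(50), 0.2)
  p <- fit_plane_lsq(pts)
  expect_equal(p$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(p$offset, -0.2, tolerance = 1e-12)
  # three non-collinear points: zero residual
  tri <- rbind(c(0, 0, 0), c(1, 0, 0.3), c(0, 1, 0.1))
  p3 <- fit_plane_lsq(tri)
  expect_equal(max(abs(plane_distance(p3, tri))), 0, tolerance = 1e-12)
  # collinear input errors
  expect_error(fit_plane_lsq(cbind(1:5, 2 * (1:5), 3 * (1:5))), "collinear")
  # noisy plane: within 0.5 degrees of truth and equal to the
  # covariance-eigenvector oracle
  n_true <- c(1, 2, 3) / sqrt(14)
  basis <- qr.Q(qr(cbind(n_true, c(1, 0, 0), c(0, 1, 0))))[, 2:3]
  uv <- matrix(runif(400, -1, 1), 200, 2)
  pts <- uv %*% t(basis) + matrix(rnorm(600, 0, 1e-3), 200, 3)
  pf <- fit_plane_lsq(pts)
  ev <- eigen(cov(pts), symmetric = TRUE)$vectors[, 3]
  if (ev[3] < 0) ev <- -ev
  expect_lt(acos(abs(sum(pf$normal * n_true))) * 180 / pi, 0.5)
  expect_equal(abs(sum(pf$normal * ev)), 1, tolerance = 1e-9)
})

test_that("ground and tray removal keeps exactly the plant", {
  pl <- generate_seedling(seedling_spec(seed = 3, points_per_organ = 300L))
  sc <- add_scene_background(pl, seed = 3, density = 8000)
  plane <- estimate_ground_plane(sc)
  out <- remove_ground_and_tray(sc, plane, 0.12)
  expect_equal(sum(out$semantic == -1L), 0)
  expect_equal(nrow(out$points), nrow(pl$points))
  # plant strictly above the plane is untouched
  expect_identical(remove_ground_and_tray(pl, plane, 0.12)$points, pl$points)
  expect_warning(remove_ground_and_tray(pl, plane, 0.2), "0.11-0.13")
})

test_that("normal estimation matches constructed geometry", {
  # dense flat horizontal patch: all normals along z
  set.seed(4)
  flat <- labeled_cloud(cbind(runif(300), runif(300), 0))
  nf <- estimate_normals(flat, 12L)
  expect_true(all(abs(nf[, 3] - 1) < 1e-6))
  # points on a vertical line with tiny jitter: normals perpendicular to z
  line <- labeled_cloud(cbind(rnorm(200, 0, 1e-6), rnorm(200, 0, 1e-6),
                              seq(0, 1, length.out = 200)))
  nl <- estimate_normals(line, 12L)
  expect_true(all(abs(90 - acos(pmin(1, abs(nl[, 3]))) * 180 / pi) < 1))
  # sphere sample: normals within 5 degrees of the radial direction
  set.seed(5)
  dir <- matrix(rnorm(3000), 1000, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  ns <- estimate_normals(labeled_cloud(dir), 12L)
  ang <- acos(pmin(1, abs(rowSums(ns * dir)))) * 180 / pi
  expect_lt(stats::median(ang), 5)
  expect_lt(mean(ang > 5), 0.05)
})

test_that("neighborhood filter implements the D/W rule in a single pass", {
  set.seed(6)
  # dense horizontal patch, spacing well under d: all kept
  patch <- cbind(runif(400, 0, 0.02), runif(400, 0, 0.02), 0)
  d <- 0.0034
  cl <- labeled_cloud(rbind(patch, c(0.5, 0.5, 0.5)))   # plus a far outlier
  nf <- neighborhood_filter(cl, filter_params(12L, d, 60))
  expect_false(any(nf$removed_mask[1:400]))
  expect_true(nf$removed_mask[401])                      # isolated: D >= d
  # per-point D equals a brute-force recomputation
  D_oracle <- sapply(1:401, function(i) {
    di <- sort(sqrt(rowSums(sweep(cl$points, 2, cl$points[i, ], "-")^2)))
    mean(di[2:13])
  })
  expect_equal(nf$D, D_oracle, tolerance = 1e-12)
  # a synthetic hover chain along z over the patch: >= 95% removed
  chain <- cbind(0.01 + rnorm(40, 0, 1e-4), 0.01 + rnorm(40, 0, 1e-4),
                 seq(0.004, 0.2, length.out = 40))
  cl2 <- labeled_cloud(rbind(patch, chain))
  nf2 <- neighborhood_filter(cl2, filter_params())
  expect_gte(mean(nf2$removed_mask[401:440]), 0.95)
  expect_error(neighborhood_filter(labeled_cloud(diag(3)), filter_params()),
               "smaller than N")
})

test_that("filter is idempotent on clean flat patches", {
  set.seed(7)
  patch <- labeled_cloud(cbind(runif(500, 0, 0.03), runif(500, 0, 0.03),
                               rnorm(500, 0, 5e-5)))
  first <- neighborhood_filter(patch, filter_params())
  second <- neighborhood_filter(first$kept, filter_params())
  expect_false(any(second$removed_mask))
})

test_that("unit normalization centres, scales and inverts exactly", {
  cl <- labeled_cloud(rbind(c(0, 0, 0), c(2, 0, 0)))
  nz <- normalize_unit(cl)
  expect_equal(nz$cloud$points, rbind(c(-1, 0, 0), c(1, 0, 0)))
  expect_equal(nz$transform$scale, 1)
  r <- random_cloud(100, seed = 8)
  nr <- normalize_unit(r)
  expect_equal(max(abs(nr$cloud$points)), 1)
  back <- denormalize_cloud(nr$cloud, nr$transform)
  expect_equal(back$points, r$points, tolerance = 1e-9)
  expect_identical(back$frame, "sensor")
})

test_that("farthest-point sampling picks extremes and spreads points", {
  line <- labeled_cloud(cbind(c(0, 0.5, 1), 0, 0))
  out <- fps_downsample(line, 2L)
  expect_setequal(out$points[, 1], c(0, 1))
  cl <- random_cloud(512, seed = 9)
  full <- fps_downsample(cl, 512L)
  expect_setequal(attr(full, "indices"), 1:512)
  expect_error(fps_downsample(cl, 600L), "more points")
  # min pairwise distance beats random sampling in nearly all trials
  fps16 <- fps_downsample(cl, 16L)$points
  min_d <- function(P) min(dist(P))
  wins <- mean(sapply(1:40, function(i) {
    set.seed(100 + i)
    min_d(cl$points[sample(512, 16), ]) < min_d(fps16)
  }))
  expect_gte(wins, 0.95)
})

test_that("curvature sampling prefers creases and degrades to FPS on ties", {
  # flat plane: tie case equals the FPS fallback
  set.seed(10)
  flat <- labeled_cloud(cbind(runif(200), runif(200), 0))
  cs <- curvature_sample(flat, 20L)
  ctr <- colMeans(flat$points)
  start <- which.max(rowSums(sweep(flat$points, 2, ctr, "-")^2))
  fps_ref <- seedlingmix:::cpp_fps(flat$points, 20L, start - 1L)
  expect_equal(cs, as.integer(fps_ref))
  # plane with a sharp crease: crease points rank first (the suppression
  # radius then forces spatial coverage, so only the earliest picks must be
  # on the fold)
  g <- as.matrix(expand.grid(x = seq(0, 1, length.out = 30),
                             y = seq(0, 1, length.out = 30)))
  z <- abs(g[, 1] - 0.5)                      # roof fold at x = 0.5
  crease <- labeled_cloud(cbind(g, z))
  sel <- curvature_sample(crease, 12L)
  expect_lt(abs(crease$points[sel[1], 1] - 0.5), 0.06)
  expect_gte(sum(abs(crease$points[sel[1:3], 1] - 0.5) < 0.06), 2)
  # n = N returns every index
  expect_equal(curvature_sample(flat, 200L), 1:200)
})
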