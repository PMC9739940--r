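## Background removal and the neighborhood-space-constraint filter, plus the
## normalization / down-sampling utilities shared by the network and the
## dataset builders. Distances are metres in the sensor frame.

#' Neighborhood-space-constraint filter parameters
#'
#' The defaults are the operating point of the filter: `N = 12` neighbours,
#' mean-distance threshold `d = 0.0034` m and normal-offset threshold
#' `c = 60` degrees.
#'
#' @param N neighbourhood size (>= 3).
#' @param d distance threshold in metres (> 0).
#' @param c angle threshold in degrees, in (0, 90].
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(N = 12L, d = 0.0034, c = 60) {
  stopifnot(N >= 3L, d > 0, c > 0, c <= 90)
  structure(list(N = as.integer(N), d = d, c = c), class = "filter_params")
}

#' Axis-aligned crop box
#'
#' Length/width/height of the pass-through crop box, centred on the camera
#' axis (x, y) with height measured down from the maximum z. Defaults are
#' 0.5 m x 0.5 m x 0.7 m.
#'
#' @param length,width,height box extents in metres (> 0).
#' @return an object of class `box_limits`.
#' @export
box_limits <- function(length = 0.5, width = 0.5, height = 0.7) {
  stopifnot(length > 0, width > 0, height > 0)
  structure(list(length = length, width = width, height = height),
            class = "box_limits")
}

#' Pass-through (straight-pass) crop filter
#'
#' Keeps exactly the points inside the closed axis-aligned box: `|x| <=
#' length/2`, `|y| <= width/2`, and z within `height` of the highest point.
#' Order and labels are preserved.
#'
#' @param cloud a [labeled_cloud()] in the sensor frame.
#' @param box a [box_limits()].
#' @return the cropped [labeled_cloud()].
#' @export
passthrough_filter <- function(cloud, box) {
  stopifnot(inherits(cloud, "labeled_cloud"), inherits(box, "box_limits"))
  p <- cloud$points
  zmax <- max(p[, 3L])
  keep <- abs(p[, 1L]) <= box$length / 2 &
    abs(p[, 2L]) <= box$width / 2 &
    p[, 3L] >= zmax - box$height
  if (!any(keep)) stop("no plant in crop box")
  out <- cloud_subset(cloud, keep)
  attr(out, "leaf_areas") <- attr(cloud, "leaf_areas")
  attr(out, "spec") <- attr(cloud, "spec")
  out
}

#' Total-least-squares plane fit
#'
#' Fits the plane minimising orthogonal residuals (smallest eigenvector of
#' the point covariance), with the normal oriented so its z component is
#' non-negative.
#'
#' @param points `M x 3` matrix, `M >= 3`, not all collinear.
#' @return a [plane3()].
#' @export
fit_plane_lsq <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("need at least 3 points to fit a plane")
  ctr <- colMeans(points)
  X <- sweep(points, 2L, ctr, "-")
  C <- crossprod(X) / nrow(X)
  e <- eigen(C, symmetric = TRUE)
  # eigenvalues descending; collinear input has two near-zero eigenvalues
  scale2 <- max(e$values[1L], .Machine$double.eps)
  if (e$values[2L] / scale2 < 1e-12)
    stop("degenerate input: points are collinear")
  n <- e$vectors[, 3L]
  if (n[3L] < 0) n <- -n
  plane3(n, -sum(n * ctr))
}

#' Remove ground plane and seedling tray
#'
#' Drops every point on or below the fitted ground plane (within a small
#' jitter tolerance above it) together with the band extending `cut_offset`
#' below the plane, which contains the tray. The cutting band 0.11-0.13 m
#' reflects tray depth; values outside it raise a warning, not an error.
#'
#' @param cloud a [labeled_cloud()].
#' @param plane the ground [plane3()] from [fit_plane_lsq()].
#' @param cut_offset depth of the tray cutting band, metres.
#' @param ground_eps tolerance above the plane treated as ground jitter.
#' @return the plant-only [labeled_cloud()].
#' @export
remove_ground_and_tray <- function(cloud, plane, cut_offset = 0.12,
                                   ground_eps = 0.005) {
  stopifnot(inherits(cloud, "labeled_cloud"), inherits(plane, "plane3"))
  if (cut_offset < 0.11 || cut_offset > 0.13)
    warning("cut_offset outside the 0.11-0.13 m tray band")
  d <- plane_distance(plane, cloud$points)
  keep <- d > ground_eps
  if (!any(keep)) stop("no points above the ground plane")
  if (all(keep)) return(cloud)
  out <- cloud_subset(cloud, keep)
  attr(out, "leaf_areas") <- attr(cloud, "leaf_areas")
  attr(out, "spec") <- attr(cloud, "spec")
  out
}

# smallest-eigenvector normals for each point's {self + N nearest} patch;
# returns list(normals, degenerate, eigvals) with normals folded to z >= 0
.normals_knn <- function(points, N) {
  n <- nrow(points)
  if (n < N + 1L) stop("cloud smaller than N + 1 points")
  nn <- cpp_knn(points, points, N + 1L)$idx    # self is first neighbour
  normals <- matrix(0, n, 3L)
  degen <- logical(n)
  for (i in seq_len(n)) {
    P <- points[nn[i, ], , drop = FALSE]
    C <- crossprod(sweep(P, 2L, colMeans(P), "-")) / nrow(P)
    e <- eigen(C, symmetric = TRUE)
    if (e$values[2L] / max(e$values[1L], .Machine$double.eps) < 1e-9) {
      normals[i, ] <- c(0, 0, 1)
      degen[i] <- TRUE
    } else {
      v <- e$vectors[, 3L]
      if (v[3L] < 0) v <- -v
      normals[i, ] <- v
    }
  }
  list(normals = normals, degenerate = degen)
}

#' Per-point normal estimation by local plane fits
#'
#' The normal of each point is the total-least-squares plane normal of the
#' patch formed by the point and its `N` nearest neighbours, folded so the z
#' component is non-negative (normals from a single view are sign-ambiguous).
#' Degenerate (collinear) patches get the viewing axis and are flagged in the
#' `degenerate` attribute.
#'
#' @param cloud a [labeled_cloud()] with at least `N + 1` points.
#' @param N neighbourhood size.
#' @return `N x 3` matrix of unit normals with attribute `degenerate`.
#' @export
estimate_normals <- function(cloud, N = 12L) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  r <- .normals_knn(cloud$points, N)
  structure(r$normals, degenerate = r$degenerate)
}

#' Neighborhood-space-constraint hover/outlier filter
#'
#' For every point of the input cloud, computes `D`, the mean Euclidean
#' distance to its `N` nearest neighbours, and `W`, the angle in degrees
#' between the locally fitted normal and the viewing axis folded to
#' `[0, 90]`. A point is removed iff `D >= d` or `W >= c`. All `D`, `W` are
#' computed on the input cloud before any deletion (single full pass), so the
#' result is order-independent.
#'
#' Hover points string out along the viewing ray, so their local plane
#' contains the z axis (`W ~ 90`); sparse outliers fail the density test
#' (`D >= d`). The visible ribbon of a thin stem fits a near-horizontal
#' plane, so stems survive the angle test.
#'
#' @param cloud a [labeled_cloud()] in the sensor frame, metres.
#' @param params a [filter_params()].
#' @return list with `kept` (the filtered cloud), `removed_mask` (logical per
#'   input point), and the per-point `D` and `W` diagnostics.
#' @export
neighborhood_filter <- function(cloud, params = filter_params()) {
  stopifnot(inherits(cloud, "labeled_cloud"), inherits(params, "filter_params"))
  pts <- cloud$points
  n <- nrow(pts)
  if (n < params$N + 1L) stop("cloud smaller than N + 1 points")
  nn <- cpp_knn(pts, pts, params$N + 1L)
  D <- rowMeans(nn$dist[, -1L, drop = FALSE])
  nr <- .normals_knn(pts, params$N)
  cosw <- pmin(1, abs(nr$normals[, 3L]))
  W <- acos(cosw) * 180 / pi
  removed <- D >= params$d | W >= params$c
  if (all(removed)) stop("filter removed every point")
  kept <- cloud_subset(cloud, !removed)
  attr(kept, "leaf_areas") <- attr(cloud, "leaf_areas")
  attr(kept, "spec") <- attr(cloud, "spec")
  list(kept = kept, removed_mask = removed, D = D, W = W)
}

#' Normalize a cloud to the unit cube
#'
#' Translates the centroid to the origin and applies one isotropic scale so
#' the maximum absolute coordinate is exactly 1. The returned transform
#' (centroid, scale) supports inverse mapping of coordinates and areas.
#'
#' @param cloud a [labeled_cloud()] with at least 2 points.
#' @return list with `cloud` (normalized frame) and `transform`
#'   (`centroid`, `scale`; original = normalized * scale + centroid).
#' @export
normalize_unit <- function(cloud) {
  stopifnot(inherits(cloud, "labeled_cloud"), n_points(cloud) >= 2L)
  ctr <- colMeans(cloud$points)
  X <- sweep(cloud$points, 2L, ctr, "-")
  s <- max(abs(X))
  if (s == 0) stop("zero-extent cloud cannot be normalized")
  out <- cloud
  out$points <- X / s
  out$frame <- "normalized"
  list(cloud = out, transform = list(centroid = ctr, scale = s))
}

#' Undo [normalize_unit()]
#'
#' @param cloud a normalized [labeled_cloud()].
#' @param transform the transform record from [normalize_unit()].
#' @return the cloud mapped back to the sensor frame.
#' @export
denormalize_cloud <- function(cloud, transform) {
  out <- cloud
  out$points <- sweep(cloud$points * transform$scale, 2L,
                      transform$centroid, "+")
  out$frame <- "sensor"
  out
}

#' Iterative farthest-point down-sampling
#'
#' Greedy subsampling maximising the minimum pairwise distance. The start
#' point defaults to the point farthest from the centroid (deterministic
#' without an RNG); an integer `seed` instead selects a seeded random start.
#'
#' @param cloud a [labeled_cloud()].
#' @param n target size (`n <= N`).
#' @param seed optional integer seed for a random start point.
#' @return the sampled [labeled_cloud()] (with attribute `indices`).
#' @export
fps_downsample <- function(cloud, n, seed = NULL) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  N <- n_points(cloud)
  if (n > N) stop("cannot sample more points than the cloud contains")
  start <- if (is.null(seed)) {
    ctr <- colMeans(cloud$points)
    which.max(rowSums(sweep(cloud$points, 2L, ctr, "-")^2)) - 1L
  } else {
    with_seed(seed, sample.int(N, 1L)) - 1L
  }
  idx <- cpp_fps(cloud$points, as.integer(n), as.integer(start))
  out <- cloud_subset(cloud, idx)
  attr(out, "indices") <- idx
  attr(out, "leaf_areas") <- attr(cloud, "leaf_areas")
  attr(out, "spec") <- attr(cloud, "spec")
  out
}

#' Moving-least-squares surface smoothing
#'
#' Projects every point onto the total-least-squares plane of its
#' k-neighbourhood, iterated; the classical point-set denoiser. Collapses
#' the off-surface scatter of network-completed clouds before surface-area
#' estimation while leaving clean surfaces essentially unchanged (flat
#' regions are fixed points of the projection).
#'
#' @param cloud a [labeled_cloud()] with more than `k` points.
#' @param k neighbourhood size.
#' @param iterations projection passes.
#' @return the smoothed [labeled_cloud()] (labels preserved).
#' @export
mls_smooth <- function(cloud, k = 12L, iterations = 2L) {
  stopifnot(inherits(cloud, "labeled_cloud"), n_points(cloud) > k)
  pts <- cloud$points
  for (it in seq_len(iterations)) {
    nn <- cpp_knn(pts, pts, k + 1L)$idx
    out <- pts
    for (i in seq_len(nrow(pts))) {
      P <- pts[nn[i, ], , drop = FALSE]
      ctr <- colMeans(P)
      e <- eigen(crossprod(sweep(P, 2L, ctr, "-")) / nrow(P),
                 symmetric = TRUE)
      n <- e$vectors[, 3L]
      out[i, ] <- pts[i, ] - sum((pts[i, ] - ctr) * n) * n
    }
    pts <- out
  }
  res <- cloud
  res$points <- pts
  res
}

# matrix-level curvature key-point selection (used by the encoder)
.curvature_sample_pts <- function(points, n) {
  N <- nrow(points)
  if (n > N) stop("cannot sample more points than available")
  if (n == N) return(seq_len(N))
  k <- min(16L, N - 1L)
  nn <- cpp_knn(points, points, k + 1L)$idx
  s <- numeric(N)
  for (i in seq_len(N)) {
    P <- points[nn[i, ], , drop = FALSE]
    ev <- eigen(crossprod(sweep(P, 2L, colMeans(P), "-")) / nrow(P),
                symmetric = TRUE, only.values = TRUE)$values
    tot <- sum(ev)
    s[i] <- if (tot > 0) ev[3L] / tot else 0
  }
  bbox <- apply(points, 2L, range)
  radius <- sqrt(sum((bbox[2L, ] - bbox[1L, ])^2)) / sqrt(n)
  fps_start <- {
    ctr <- colMeans(points)
    which.max(rowSums(sweep(points, 2L, ctr, "-")^2))
  }
  if (diff(range(s)) < 1e-9) {
    # tie case (e.g. a flat plane): pure farthest-point sampling
    return(as.integer(cpp_fps(points, as.integer(n),
                              as.integer(fps_start - 1L))))
  }
  ord <- order(-s, seq_len(N))
  sel <- integer(0)
  mind <- rep(Inf, N)
  for (i in ord) {
    if (length(sel) >= n) break
    if (mind[i] >= radius) {
      sel <- c(sel, i)
      d2 <- sqrt(rowSums(sweep(points, 2L, points[i, ], "-")^2))
      mind <- pmin(mind, d2)
    }
  }
  # exhaustion: fill remaining slots farthest-point style
  while (length(sel) < n) {
    cand <- which.max(replace(mind, sel, -Inf))
    sel <- c(sel, cand)
    d2 <- sqrt(rowSums(sweep(points, 2L, points[cand, ], "-")^2))
    mind <- pmin(mind, d2)
  }
  as.integer(sel)
}

#' Curvature-based key-point sampling
#'
#' Ranks points by surface variation `s = lambda_0 / (lambda_0 + lambda_1 +
#' lambda_2)` (smallest covariance eigenvalue fraction of the 16-nearest-
#' neighbour patch) and selects greedily from the highest `s` downward, with
#' a suppression radius of `bbox diagonal / sqrt(n)` to keep spatial
#' coverage. Ties across the whole cloud, and exhaustion of candidates, fall
#' back to farthest-point sampling. Deterministic.
#'
#' @param cloud a [labeled_cloud()] with at least 10 points.
#' @param n number of key points (`n <= N`).
#' @return integer vector of `n` point indices.
#' @export
curvature_sample <- function(cloud, n) {
  stopifnot(inherits(cloud, "labeled_cloud"), n_points(cloud) >= 10L)
  .curvature_sample_pts(cloud$points, n)
}
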