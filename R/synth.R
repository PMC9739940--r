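## Synthetic single-view seedling scenes with ground-truth labels, analytic
## leaf areas, and a depth-camera noise model. The camera is orthographic
## along -z (top view): organs are sampled as the surfaces such a camera
## actually measures, which is what makes the hover/normal filtering logic
## meaningful on these clouds.

# evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic seedling specification
#'
#' Describes a single seedling at the 1-, 2- or 3-leaf stage: a thin, slightly
#' tilted stem plus curved elliptic leaf patches arranged around the stem top.
#' The leaf surface is `z = curvature * (u^2 + v^2)` over an ellipse with
#' semi-axes `leaf_radius` and `0.7 * leaf_radius`, so its area has a
#' closed-form first-fundamental-form integral that the generator attaches as
#' metadata (the phenotype ground truth).
#'
#' @param n_leaves 1, 2 or 3.
#' @param leaf_radius semi-major axis of the leaf ellipse, metres.
#' @param leaf_curvature quadratic bend coefficient, 1/m (0 = flat leaf).
#' @param stem_height stem length, metres.
#' @param stem_radius stem radius, metres.
#' @param overlap_fraction in `[0, 1)`: 0 places leaves just touching at the
#'   stem; values toward 1 slide their top-view projections into each other.
#' @param points_per_organ points sampled per organ (>= 50).
#' @param seed integer RNG seed.
#' @return an object of class `seedling_spec`.
#' @export
seedling_spec <- function(n_leaves = 2L, leaf_radius = 0.04,
                          leaf_curvature = 6, stem_height = 0.05,
                          stem_radius = 0.0025, overlap_fraction = 0.25,
                          points_per_organ = 1600L, seed = 1L) {
  stopifnot(n_leaves %in% 1:3, leaf_radius > 0, stem_height > 0,
            stem_radius > 0, points_per_organ >= 50L,
            leaf_curvature >= 0)
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie in [0, 1): impossible overlap geometry")
  structure(list(n_leaves = as.integer(n_leaves), leaf_radius = leaf_radius,
                 leaf_curvature = leaf_curvature, stem_height = stem_height,
                 stem_radius = stem_radius,
                 overlap_fraction = overlap_fraction,
                 points_per_organ = as.integer(points_per_organ),
                 seed = as.integer(seed)),
            class = "seedling_spec")
}

#' Depth-camera noise specification
#'
#' Models the two noise families of time-of-flight depth imaging: hover
#' points strung along the viewing ray at silhouette edges (mixed returns
#' where light grazes an object boundary) and sparse uniform outliers. The
#' defaults are free parameters of the simulator, not calibrated claims about
#' any particular camera.
#'
#' @param hover_fraction fraction of detected silhouette-edge points that
#'   spawn a hover chain, in `[0, 1]`.
#' @param hover_chain_len points per chain (>= 1).
#' @param outlier_fraction fraction of cloud size added as uniform outliers.
#' @param outlier_box_scale bounding-box inflation factor for outliers.
#' @param seed integer RNG seed.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(hover_fraction = 0.3, hover_chain_len = 8L,
                       outlier_fraction = 0.02, outlier_box_scale = 1.5,
                       seed = 1L) {
  stopifnot(hover_fraction >= 0, hover_fraction <= 1,
            outlier_fraction >= 0, outlier_fraction <= 1,
            hover_chain_len >= 1L, outlier_box_scale > 0)
  structure(list(hover_fraction = hover_fraction,
                 hover_chain_len = as.integer(hover_chain_len),
                 outlier_fraction = outlier_fraction,
                 outlier_box_scale = outlier_box_scale,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# area of the bent elliptic patch z = kappa (u^2 + v^2) over the (a, b)
# ellipse, by midpoint quadrature of the first fundamental form in polar
# parameter coordinates (integrand is smooth; 256^2 cells are ample)
leaf_patch_area <- function(a, b, kappa, n_grid = 256L) {
  r <- (seq_len(n_grid) - 0.5) / n_grid
  th <- (seq_len(n_grid) - 0.5) / n_grid * 2 * pi
  rr <- matrix(r, n_grid, n_grid)
  tt <- matrix(th, n_grid, n_grid, byrow = TRUE)
  u <- a * rr * cos(tt)
  v <- b * rr * sin(tt)
  g <- sqrt(1 + 4 * kappa^2 * (u^2 + v^2))
  sum(g * a * b * rr) * (1 / n_grid) * (2 * pi / n_grid)
}

# sample n points uniformly by surface area on the bent elliptic patch
sample_leaf_patch <- function(n, a, b, kappa) {
  gmax <- sqrt(1 + 4 * kappa^2 * max(a, b)^2)
  out <- matrix(0, 0L, 3L)
  while (nrow(out) < n) {
    m <- max(64L, ceiling((n - nrow(out)) * 1.5))
    rr <- sqrt(stats::runif(m))
    tt <- stats::runif(m, 0, 2 * pi)
    u <- a * rr * cos(tt)
    v <- b * rr * sin(tt)
    g <- sqrt(1 + 4 * kappa^2 * (u^2 + v^2))
    keep <- stats::runif(m) < g / gmax
    out <- rbind(out, cbind(u[keep], v[keep], kappa * (u[keep]^2 + v[keep]^2)))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic seedling point cloud
#'
#' The stem is sampled as the ribbon a top-down depth camera measures on a
#' slightly tilted cylinder (the upper half of its surface), labelled
#' semantic 0 / instance 0. Each leaf is a curved elliptic patch (semantic 1,
#' instances 1..n) posed around the stem top so that the requested top-view
#' overlap is realised. The exact analytic surface area of every leaf is
#' attached as the `leaf_areas` attribute (named by instance id), and the
#' generating spec as the `spec` attribute. Deterministic given
#' `spec$seed`. The plant is placed with its stem base at `z = 0.1` m in the
#' sensor frame.
#'
#' @param spec a [seedling_spec()].
#' @return a [labeled_cloud()] in the sensor frame with attributes
#'   `leaf_areas` and `spec`.
#' @export
generate_seedling <- function(spec) {
  stopifnot(inherits(spec, "seedling_spec"))
  with_seed(spec$seed, {
    base <- c(0, 0, 0.1)
    ## A top-down view only sees the leaned, arched part of the hypocotyl
    ## (near-vertical sections are edge-on and return no depth); the visible
    ## stem is modelled leaning 34-46 degrees from vertical.
    tilt <- stats::runif(1, 0.70, 0.90)           # stem lean, rad
    phi <- stats::runif(1, 0, 2 * pi)
    axis <- c(sin(tilt) * cos(phi), sin(tilt) * sin(phi), cos(tilt))
    side <- c(-sin(phi), cos(phi), 0)             # horizontal, perp to axis
    up <- c(axis[2] * side[3] - axis[3] * side[2],
            axis[3] * side[1] - axis[1] * side[3],
            axis[1] * side[2] - axis[2] * side[1])
    if (up[3] < 0) up <- -up

    ## A top-down depth camera resolves a millimetre stem over only a few
    ## pixels, and its depth noise swamps the sub-millimetre crest relief:
    ## the measured stem is a dense quasi-1-D smear along the axis with
    ## lateral spread of one stem radius. Its k-neighbourhoods are thin
    ## across the axis, which is exactly why the normal-offset test spares
    ## thin stems while deleting hover chains.
    np <- spec$points_per_organ
    z_sd <- 1e-4                                  # depth noise, metres
    s <- stats::runif(np, 0, spec$stem_height)
    chord <- stats::runif(np, -spec$stem_radius, spec$stem_radius)
    stem <- matrix(base, np, 3L, byrow = TRUE) +
      outer(s, axis) + outer(chord, side) +
      cbind(0, 0, stats::rnorm(np, 0, z_sd))

    pts <- list(stem)
    sem <- list(rep(0L, np))
    ins <- list(rep(0L, np))
    a <- spec$leaf_radius
    b <- 0.7 * a
    area <- leaf_patch_area(a, b, spec$leaf_curvature)
    top <- base + spec$stem_height * axis
    rho <- a * (1 - spec$overlap_fraction)
    psi0 <- stats::runif(1, 0, 2 * pi)
    areas <- stats::setNames(numeric(0), character(0))
    for (i in seq_len(spec$n_leaves)) {
      psi <- psi0 + 2 * pi * (i - 1) / spec$n_leaves +
        stats::runif(1, -0.1, 0.1)
      tau <- stats::runif(1, 0.05, 0.25)          # leaf pitch, rad
      uhat <- c(cos(psi) * cos(tau), sin(psi) * cos(tau), sin(tau))
      vhat <- c(-sin(psi), cos(psi), 0)
      what <- c(uhat[2] * vhat[3] - uhat[3] * vhat[2],
                uhat[3] * vhat[1] - uhat[1] * vhat[3],
                uhat[1] * vhat[2] - uhat[2] * vhat[1])
      centre <- top + rho * c(cos(psi), sin(psi), 0)
      loc <- sample_leaf_patch(np, a, b, spec$leaf_curvature)
      world <- matrix(centre, np, 3L, byrow = TRUE) +
        loc[, 1L] %o% uhat + loc[, 2L] %o% vhat + loc[, 3L] %o% what +
        cbind(0, 0, stats::rnorm(np, 0, z_sd))
      pts <- c(pts, list(world))
      sem <- c(sem, list(rep(1L, np)))
      ins <- c(ins, list(rep(i, np)))
      areas[as.character(i)] <- area
    }
    cloud <- labeled_cloud(do.call(rbind, pts),
                           semantic = unlist(sem),
                           instance = unlist(ins),
                           noise_mask = rep(FALSE, np * (1L + spec$n_leaves)),
                           frame = "sensor")
    attr(cloud, "leaf_areas") <- areas
    attr(cloud, "spec") <- spec
    cloud
  })
}

#' Append a ground plane and seedling tray to a scene
#'
#' Ground points are scattered over a square patch at `ground_z`; the tray is
#' a box (four walls plus bottom) whose top edge sits at ground level and
#' which extends `tray_height` below it. All appended points carry the
#' semantic sentinel -1 (preprocessing, not labels, must remove them) and
#' `noise_mask = FALSE`. The appended count equals
#' `round(density * area)` for each part.
#'
#' @param cloud plant cloud in the sensor frame (min z above `ground_z`).
#' @param ground_z ground plane height, metres.
#' @param tray_height tray depth below ground, metres.
#' @param seed integer RNG seed.
#' @param ground_extent side length of the square ground patch, metres.
#' @param tray_side side length of the square tray, metres.
#' @param density points per square metre for ground and tray.
#' @param jitter_sd vertical ground jitter standard deviation, metres.
#' @return the cloud with background appended (original points first).
#' @export
add_scene_background <- function(cloud, ground_z = 0, tray_height = 0.12,
                                 seed = 1L, ground_extent = 0.45,
                                 tray_side = 0.2, density = 20000,
                                 jitter_sd = 3e-4) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  if (min(cloud$points[, 3L]) <= ground_z)
    stop("ground_z must lie below the plant")
  with_seed(seed, {
    n_g <- round(density * ground_extent^2)
    gx <- stats::runif(n_g, -ground_extent / 2, ground_extent / 2)
    gy <- stats::runif(n_g, -ground_extent / 2, ground_extent / 2)
    gz <- ground_z + stats::rnorm(n_g, 0, jitter_sd)
    ground <- cbind(gx, gy, gz)

    wall_area <- 4 * tray_side * tray_height
    n_w <- round(density * wall_area)
    n_b <- round(density * tray_side^2)
    wside <- sample.int(4L, n_w, replace = TRUE)
    wt <- stats::runif(n_w, -tray_side / 2, tray_side / 2)
    wz <- ground_z - stats::runif(n_w, 0, tray_height)
    h <- tray_side / 2
    wx <- ifelse(wside == 1L, -h, ifelse(wside == 2L, h, wt))
    wy <- ifelse(wside <= 2L, wt, ifelse(wside == 3L, -h, h))
    bx <- stats::runif(n_b, -h, h)
    by <- stats::runif(n_b, -h, h)
    bz <- rep(ground_z - tray_height, n_b)
    bg <- rbind(ground, cbind(wx, wy, wz), cbind(bx, by, bz))
    bg_cloud <- labeled_cloud(bg,
                              semantic = rep(-1L, nrow(bg)),
                              instance = rep(-1L, nrow(bg)),
                              noise_mask = rep(FALSE, nrow(bg)),
                              frame = "sensor")
    out <- cloud_rbind(cloud, bg_cloud)
    attr(out, "leaf_areas") <- attr(cloud, "leaf_areas")
    attr(out, "spec") <- attr(cloud, "spec")
    out
  })
}

# silhouette-edge detection in the top view: a point is an edge candidate if
# its 2-D k-nearest neighbourhood is one-sided, i.e. the norm of the mean
# neighbour offset is a large fraction of the mean neighbour distance
detect_silhouette_edges <- function(points, k = 8L, ratio = 0.6) {
  xy <- points[, 1:2, drop = FALSE]
  if (nrow(xy) <= k) return(integer(0))
  nn <- cpp_knn(xy, xy, k + 1L)
  idx <- nn$idx[, -1L, drop = FALSE]
  dist <- nn$dist[, -1L, drop = FALSE]
  mx <- matrix(xy[idx, 1L], nrow(xy), k) - xy[, 1L]
  my <- matrix(xy[idx, 2L], nrow(xy), k) - xy[, 2L]
  offset <- sqrt(rowMeans(mx)^2 + rowMeans(my)^2)
  md <- rowMeans(dist)
  which(md > 0 & offset / md > ratio)
}

#' Inject depth-camera noise into a scene
#'
#' Implements the two noise families the neighborhood-space-constraint filter
#' targets. Hover points: a subset of silhouette-edge points (one-sided
#' top-view neighbourhoods) each spawns a chain of `hover_chain_len` points
#' interpolated straight down the viewing axis between the organ and the
#' first surface behind it (or a default 6 cm gap when nothing lies behind),
#' so each chain is exactly collinear with z. Outliers: uniform points in the
#' bounding box inflated by `outlier_box_scale`. All injected points get
#' `noise_mask = TRUE` and label sentinel -1. The injected count is exactly
#' `floor(hover_fraction * n_edges) * hover_chain_len +
#' floor(outlier_fraction * N)`.
#'
#' @param cloud scene in the sensor frame, +z the viewing axis.
#' @param noise a [noise_spec()].
#' @return the cloud with noise appended (original points first, order kept).
#' @export
add_sensor_noise <- function(cloud, noise) {
  stopifnot(inherits(cloud, "labeled_cloud"), inherits(noise, "noise_spec"))
  if (noise$hover_fraction == 0 && noise$outlier_fraction == 0) return(cloud)
  pts <- cloud$points
  n <- nrow(pts)
  with_seed(noise$seed, {
    inj <- list()
    if (noise$hover_fraction > 0) {
      edges <- detect_silhouette_edges(pts)
      n_pick <- floor(noise$hover_fraction * length(edges))
      if (n_pick > 0) {
        pick <- sample(edges, n_pick)
        L <- noise$hover_chain_len
        for (p in pick) {
          below <- which(pts[, 3L] < pts[p, 3L] - 0.012 &
                         (pts[, 1L] - pts[p, 1L])^2 +
                         (pts[, 2L] - pts[p, 2L])^2 < 0.005^2)
          z_back <- if (length(below)) max(pts[below, 3L]) else
            pts[p, 3L] - 0.06
          # mixed returns scatter at random depths along the ray
          frac <- sort(stats::runif(L, 0.05, 0.95))
          zs <- pts[p, 3L] + frac * (z_back - pts[p, 3L])
          inj <- c(inj, list(cbind(rep(pts[p, 1L], L),
                                   rep(pts[p, 2L], L), zs)))
        }
      }
    }
    if (noise$outlier_fraction > 0) {
      n_out <- floor(noise$outlier_fraction * n)
      if (n_out > 0) {
        lo <- apply(pts, 2L, min)
        hi <- apply(pts, 2L, max)
        mid <- (lo + hi) / 2
        half <- (hi - lo) / 2 * noise$outlier_box_scale
        out <- sapply(1:3, function(j)
          stats::runif(n_out, mid[j] - half[j], mid[j] + half[j]))
        if (n_out == 1L) out <- matrix(out, 1L)
        inj <- c(inj, list(out))
      }
    }
    if (!length(inj)) return(cloud)
    inj <- do.call(rbind, inj)
    noise_cloud <- labeled_cloud(inj,
                                 semantic = rep(-1L, nrow(inj)),
                                 instance = rep(-1L, nrow(inj)),
                                 noise_mask = rep(TRUE, nrow(inj)),
                                 frame = "sensor")
    out <- cloud_rbind(cloud, noise_cloud)
    attr(out, "leaf_areas") <- attr(cloud, "leaf_areas")
    attr(out, "spec") <- attr(cloud, "spec")
    out
  })
}

#' Write a scene fixture as PLY plus a JSON sidecar
#'
#' The sidecar records the generating spec and the per-leaf analytic areas,
#' which downstream phenotype tests use as ground truth.
#'
#' @param cloud a cloud from [generate_seedling()] (possibly with background
#'   and noise added).
#' @param path output PLY path; the sidecar is written as `<path>.json`.
#' @param binary write binary PLY.
#' @return `invisible(path)`.
#' @export
write_scene <- function(cloud, path, binary = TRUE) {
  write_cloud(cloud, path, format = "ply", binary = binary)
  spec <- attr(cloud, "spec")
  sidecar <- list(leaf_areas = as.list(attr(cloud, "leaf_areas")),
                  spec = if (is.null(spec)) NULL else unclass(spec))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
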