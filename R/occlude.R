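## Self-supervised occlusion machinery: the 14-viewpoint missing-point-cloud
## generator, augmentation, and the segmentation/completion dataset builders.

#' Augmentation parameters
#'
#' Random panning in `[-0.2, 0.2]` per axis and random anisotropic scaling in
#' `[0.67, 1.5]` per axis, applied in the normalized frame;
#' `copies_per_cloud` counts the original, so the default 4 turns 130 source
#' clouds into 520 entries.
#'
#' @param translation_range length-2 numeric, ordered.
#' @param scale_range length-2 numeric, ordered.
#' @param copies_per_cloud integer >= 1 (includes the original).
#' @return an object of class `augment_params`.
#' @export
augment_params <- function(translation_range = c(-0.2, 0.2),
                           scale_range = c(0.67, 1.5),
                           copies_per_cloud = 4L) {
  stopifnot(length(translation_range) == 2L, diff(translation_range) >= 0,
            length(scale_range) == 2L, diff(scale_range) >= 0,
            copies_per_cloud >= 1L)
  structure(list(translation_range = translation_range,
                 scale_range = scale_range,
                 copies_per_cloud = as.integer(copies_per_cloud)),
            class = "augment_params")
}

#' The 14 occlusion viewpoints of a cube
#'
#' Returns the 8 cube corners `center + half_extent * (+-1, +-1, +-1)`
#' followed by the 6 face centers `center +- half_extent * e_i`. Corner order:
#' x varies fastest, then y, then z, from negative to positive; face order:
#' -x, +x, -y, +y, -z, +z.
#'
#' @param center length-3 numeric cube center.
#' @param half_extent half the cube edge (> 0).
#' @return a `14 x 3` matrix of viewpoints.
#' @export
cube_viewpoints <- function(center = c(0, 0, 0), half_extent = 1) {
  stopifnot(half_extent > 0, length(center) == 3L)
  signs <- unname(as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))))
  faces <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                 c(0, 0, -1), c(0, 0, 1))
  vp <- rbind(signs, faces) * half_extent
  unname(sweep(vp, 2L, as.numeric(center), "+"))
}

#' Remove the fraction of points nearest a viewpoint
#'
#' Removes the `round(fraction * N)` points with smallest Euclidean distance
#' to the viewpoint (ties broken by input index), emulating occlusion of the
#' leaf surface facing that direction.
#'
#' @param complete a [labeled_cloud()] (the intact leaf).
#' @param viewpoint length-3 numeric.
#' @param fraction in (0, 1); the canonical missingness set is
#'   \{0.15, 0.25, 0.50\}.
#' @return an object of class `completion_pair`: list with `partial`,
#'   `removed`, `complete`, `viewpoint`, `fraction` and the removed indices.
#' @export
remove_nearest_fraction <- function(complete, viewpoint, fraction) {
  stopifnot(inherits(complete, "labeled_cloud"),
            fraction > 0, fraction < 1, length(viewpoint) == 3L)
  N <- n_points(complete)
  m <- round(fraction * N)
  if (m == 0L || m == N)
    stop("fraction removes none or all of the cloud")
  d <- sqrt(rowSums(sweep(complete$points, 2L, as.numeric(viewpoint), "-")^2))
  ord <- order(d, seq_len(N))
  removed_idx <- sort(ord[seq_len(m)])
  kept_idx <- setdiff(seq_len(N), removed_idx)
  structure(list(partial = cloud_subset(complete, kept_idx),
                 removed = cloud_subset(complete, removed_idx),
                 complete = complete,
                 viewpoint = as.numeric(viewpoint),
                 fraction = fraction,
                 removed_idx = removed_idx),
            class = "completion_pair")
}

#' Augment a cloud by random panning and anisotropic scaling
#'
#' Returns the original plus `copies_per_cloud - 1` clones, each translated
#' by a per-axis uniform draw from `translation_range` and scaled per axis by
#' a uniform draw from `scale_range`. Labels are copied verbatim.
#' Deterministic given `seed`.
#'
#' @param cloud a [labeled_cloud()] (augmentation is intended for the
#'   normalized frame).
#' @param params an [augment_params()].
#' @param seed integer seed.
#' @return list of [labeled_cloud()]s, the original first.
#' @export
augment_cloud <- function(cloud, params = augment_params(), seed = 1L) {
  stopifnot(inherits(cloud, "labeled_cloud"), inherits(params, "augment_params"))
  if (params$copies_per_cloud == 1L) return(list(cloud))
  with_seed(seed, {
    out <- vector("list", params$copies_per_cloud)
    out[[1L]] <- cloud
    for (i in seq_len(params$copies_per_cloud - 1L)) {
      tr <- stats::runif(3L, params$translation_range[1L],
                         params$translation_range[2L])
      sc <- stats::runif(3L, params$scale_range[1L], params$scale_range[2L])
      clone <- cloud
      clone$points <- sweep(sweep(cloud$points, 2L, sc, "*"), 2L, tr, "+")
      out[[i + 1L]] <- clone
    }
    out
  })
}

#' Assemble a segmentation dataset
#'
#' Resamples every labelled source cloud to `n_points` by farthest-point
#' sampling, augments each by `params$copies_per_cloud`, and returns a
#' manifest with the train/test entries. 130 train + 20 test sources at the
#' default 4 copies yield 520 + 80 entries.
#'
#' @param clouds list of [labeled_cloud()]s carrying semantic and instance
#'   labels.
#' @param params an [augment_params()].
#' @param split character vector (`"train"`/`"test"`) per source cloud.
#' @param seed integer seed.
#' @param n_points resampling size (2048 by convention).
#' @return list with `train`, `test` (lists of clouds), `n_train`, `n_test`,
#'   and the generating settings.
#' @export
build_segmentation_dataset <- function(clouds, params = augment_params(),
                                       split, seed = 1L, n_points = 2048L) {
  stopifnot(length(split) == length(clouds),
            all(split %in% c("train", "test")))
  for (cl in clouds) {
    if (is.null(cl$semantic) || is.null(cl$instance))
      stop("segmentation dataset requires semantic and instance labels")
  }
  entries <- list(train = list(), test = list())
  for (i in seq_along(clouds)) {
    cl <- clouds[[i]]
    if (n_points(cl) > n_points) cl <- fps_downsample(cl, n_points)
    copies <- augment_cloud(cl, params, seed = seed + i)
    entries[[split[i]]] <- c(entries[[split[i]]], copies)
  }
  list(train = entries$train, test = entries$test,
       n_train = length(entries$train), n_test = length(entries$test),
       params = params, n_points = n_points, seed = seed)
}

#' Assemble a self-supervised completion dataset
#'
#' For every (leaf, augmentation copy), draws one viewpoint uniformly from
#' the 14 cube viewpoints placed at 1.5 x the bounding-box half-diagonal
#' around the leaf (so every viewpoint lies outside it) and one missingness
#' fraction uniformly from `fractions`, and emits the resulting
#' [remove_nearest_fraction()] pair. Deterministic given `seed`.
#'
#' @param leaves list of single-leaf [labeled_cloud()]s.
#' @param fractions candidate missingness fractions.
#' @param seed integer seed.
#' @param params an [augment_params()] (`copies_per_cloud = 1` disables
#'   augmentation).
#' @return list of `completion_pair` objects.
#' @export
build_completion_dataset <- function(leaves, fractions = c(0.15, 0.25, 0.50),
                                     seed = 1L,
                                     params = augment_params(copies_per_cloud = 1L)) {
  pairs <- list()
  for (i in seq_along(leaves)) {
    copies <- augment_cloud(leaves[[i]], params, seed = seed + 7L * i)
    for (j in seq_along(copies)) {
      leaf <- copies[[j]]
      bbox <- apply(leaf$points, 2L, range)
      ctr <- colMeans(bbox)
      half_diag <- sqrt(sum((bbox[2L, ] - bbox[1L, ])^2)) / 2
      vps <- cube_viewpoints(ctr, 1.5 * half_diag)
      draw <- with_seed(seed + 1000003L * i + j, {
        c(sample.int(14L, 1L), sample.int(length(fractions), 1L))
      })
      pairs <- c(pairs, list(remove_nearest_fraction(
        leaf, vps[draw[1L], ], fractions[draw[2L]])))
    }
  }
  pairs
}
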