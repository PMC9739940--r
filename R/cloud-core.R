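#' Labeled point cloud
#'
#' The universal container of the pipeline: an `N x 3` coordinate matrix with
#' optional per-point semantic labels (0 = stem, 1 = leaf, -1 = unlabeled
#' sentinel), instance ids (>= 0, -1 = unlabeled), a noise mask flagging
#' synthetically injected points, and unit normals. Coordinates are metres in
#' the sensor frame or dimensionless in the normalized frame.
#'
#' Unlabeled points carry sentinel -1 and are excluded from losses and
#' metrics; instance id 0 is a valid id (conventionally the stem).
#'
#' @param points numeric matrix, `N x 3`, all finite, `N >= 1`.
#' @param semantic optional integer vector of length `N`.
#' @param instance optional integer vector of length `N`, values >= -1.
#' @param noise_mask optional logical vector of length `N`.
#' @param normals optional `N x 3` matrix of unit vectors (within 1e-6).
#' @param frame `"sensor"` or `"normalized"`.
#' @return an object of class `labeled_cloud`.
#' @export
labeled_cloud <- function(points, semantic = NULL, instance = NULL,
                          noise_mask = NULL, normals = NULL,
                          frame = c("sensor", "normalized")) {
  frame <- match.arg(frame)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (ncol(points) != 3L) stop("points must have 3 columns")
  n <- nrow(points)
  if (n < 1L) stop("cloud must contain at least one point")
  bad <- which(!is.finite(points))
  if (length(bad)) {
    stop(sprintf("non-finite coordinate at row %d",
                 ((bad[1L] - 1L) %% n) + 1L))
  }
  chk_len <- function(x, what) {
    if (!is.null(x) && length(x) != n)
      stop(sprintf("%s must have length %d", what, n))
    x
  }
  semantic <- chk_len(if (is.null(semantic)) NULL else as.integer(semantic),
                      "semantic")
  instance <- chk_len(if (is.null(instance)) NULL else as.integer(instance),
                      "instance")
  noise_mask <- chk_len(if (is.null(noise_mask)) NULL else
                        as.logical(noise_mask), "noise_mask")
  if (!is.null(instance) && any(instance < -1L, na.rm = TRUE))
    stop("instance ids must be >= -1")
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    dimnames(normals) <- NULL
    if (!all(dim(normals) == c(n, 3L))) stop("normals must be N x 3")
    len <- sqrt(rowSums(normals^2))
    if (any(abs(len - 1) > 1e-6))
      stop("normals must have unit length within 1e-6")
  }
  structure(list(points = points, semantic = semantic, instance = instance,
                 noise_mask = noise_mask, normals = normals, frame = frame),
            class = "labeled_cloud")
}

#' @export
print.labeled_cloud <- function(x, ...) {
  cat(sprintf("<labeled_cloud> %d points, frame=%s%s%s%s\n",
              nrow(x$points), x$frame,
              if (!is.null(x$semantic)) ", semantic" else "",
              if (!is.null(x$instance)) ", instance" else "",
              if (!is.null(x$noise_mask)) ", noise_mask" else ""))
  invisible(x)
}

n_points <- function(cloud) nrow(cloud$points)

#' Subset a labeled cloud by point index, keeping all attributes aligned.
#'
#' @param cloud a `labeled_cloud`.
#' @param idx integer or logical index over points.
#' @return a `labeled_cloud` with the selected points, order preserved.
#' @export
cloud_subset <- function(cloud, idx) {
  labeled_cloud(cloud$points[idx, , drop = FALSE],
                semantic = cloud$semantic[idx],
                instance = cloud$instance[idx],
                noise_mask = cloud$noise_mask[idx],
                normals = if (is.null(cloud$normals)) NULL else
                  cloud$normals[idx, , drop = FALSE],
                frame = cloud$frame)
}

#' Concatenate labeled clouds
#'
#' Missing label arrays are padded with the -1 sentinel (semantic/instance)
#' or `FALSE` (noise mask) so the result stays total.
#'
#' @param ... `labeled_cloud` objects in the same frame.
#' @return a `labeled_cloud`.
#' @export
cloud_rbind <- function(...) {
  cls <- list(...)
  stopifnot(length(cls) >= 1L)
  frame <- cls[[1L]]$frame
  if (!all(vapply(cls, function(c) c$frame, "") == frame))
    stop("clouds must share a frame")
  ns <- vapply(cls, n_points, 0L)
  any_sem <- any(vapply(cls, function(c) !is.null(c$semantic), TRUE))
  any_ins <- any(vapply(cls, function(c) !is.null(c$instance), TRUE))
  any_nm <- any(vapply(cls, function(c) !is.null(c$noise_mask), TRUE))
  grab <- function(c, field, fill) {
    if (!is.null(c[[field]])) c[[field]] else rep(fill, n_points(c))
  }
  labeled_cloud(
    do.call(rbind, lapply(cls, function(c) c$points)),
    semantic = if (any_sem) unlist(lapply(cls, grab, "semantic", -1L)) else NULL,
    instance = if (any_ins) unlist(lapply(cls, grab, "instance", -1L)) else NULL,
    noise_mask = if (any_nm) unlist(lapply(cls, grab, "noise_mask", FALSE)) else NULL,
    frame = frame)
}

#' Infinite plane in Hessian normal form
#'
#' Represents `normal . x + offset = 0` with a unit normal.
#'
#' @param normal length-3 vector; normalized internally, must be non-zero.
#' @param offset signed scalar offset.
#' @return an object of class `plane3`.
#' @export
plane3 <- function(normal, offset) {
  normal <- as.numeric(normal)
  stopifnot(length(normal) == 3L, is.finite(offset))
  len <- sqrt(sum(normal^2))
  if (len < 1e-12) stop("plane normal must be non-zero")
  structure(list(normal = normal / len, offset = offset / len),
            class = "plane3")
}

#' Signed distance of points to a plane
#'
#' @param plane a `plane3`.
#' @param points `N x 3` matrix.
#' @return numeric vector of signed distances (positive on the normal side).
#' @export
plane_distance <- function(plane, points) {
  as.numeric(points %*% plane$normal + plane$offset)
}
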