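## Leaf-area estimation from (completed) leaf point clouds and the
## correlation analysis against ground truth.

#' Leaf area by projected Delaunay triangulation
#'
#' Projects the leaf onto its best-fit (PCA) plane, triangulates the 2-D
#' projection, lifts the triangles back to 3-D and sums their areas.
#' Triangles with any 3-D edge longer than `edge_factor` times the median
#' triangulation edge length are discarded (hole guard against bridging
#' concavities and gaps; the median Delaunay edge is a stable measure of
#' point spacing even for irregular sampling). If a normalization transform is supplied the area
#' is rescaled to physical units (`scale^2`). Deterministic: exactly
#' cocircular projections (regular grids) are broken by a fixed microscopic
#' jitter (1e-9 of the extent) before triangulation.
#'
#' @param leaf a single-leaf [labeled_cloud()] with at least 50 points.
#' @param transform optional transform record from [normalize_unit()].
#' @param edge_factor hole-guard multiplier on the median spacing.
#' @return an object of class `leaf_area_result`: list with `area`
#'   (squared input units, rescaled if `transform` given), `n_triangles`,
#'   `holes_discarded`.
#' @export
leaf_area <- function(leaf, transform = NULL, edge_factor = 4) {
  stopifnot(inherits(leaf, "labeled_cloud"))
  P <- leaf$points
  if (nrow(P) < 50L) stop("leaf area needs at least 50 points")
  ctr <- colMeans(P)
  X <- sweep(P, 2L, ctr, "-")
  C <- crossprod(X) / nrow(X)
  e <- eigen(C, symmetric = TRUE)
  if (e$values[2L] / max(e$values[1L], .Machine$double.eps) < 1e-10)
    stop("degenerate (collinear) leaf")
  uv <- X %*% e$vectors[, 1:2]
  span <- max(apply(uv, 2L, function(c) diff(range(c))))
  jit <- with_seed(20481L, matrix(stats::runif(2L * nrow(uv), -1, 1),
                                  ncol = 2L)) * 1e-9 * span
  tri <- cpp_delaunay(uv[, 1L] + jit[, 1L], uv[, 2L] + jit[, 2L])
  if (!nrow(tri)) stop("triangulation failed")
  a <- P[tri[, 1L], , drop = FALSE]
  b <- P[tri[, 2L], , drop = FALSE]
  cc <- P[tri[, 3L], , drop = FALSE]
  elen <- cbind(sqrt(rowSums((a - b)^2)), sqrt(rowSums((b - cc)^2)),
                sqrt(rowSums((cc - a)^2)))
  max_edge <- edge_factor * stats::median(elen)
  keep <- apply(elen, 1L, max) <= max_edge
  ab <- b[keep, , drop = FALSE] - a[keep, , drop = FALSE]
  ac <- cc[keep, , drop = FALSE] - a[keep, , drop = FALSE]
  cross <- cbind(ab[, 2L] * ac[, 3L] - ab[, 3L] * ac[, 2L],
                 ab[, 3L] * ac[, 1L] - ab[, 1L] * ac[, 3L],
                 ab[, 1L] * ac[, 2L] - ab[, 2L] * ac[, 1L])
  area <- sum(0.5 * sqrt(rowSums(cross^2)))
  if (!is.null(transform)) area <- area * transform$scale^2
  structure(list(area = area, n_triangles = sum(keep),
                 holes_discarded = sum(!keep)),
            class = "leaf_area_result")
}

#' @export
print.leaf_area_result <- function(x, ...) {
  cat(sprintf("<leaf_area_result> area = %.6g (%d triangles, %d discarded)\n",
              x$area, x$n_triangles, x$holes_discarded))
  invisible(x)
}

#' Correlate predicted leaf areas with ground truth
#'
#' Delegates to [r2_mse()] and returns the paired data for plotting; if
#' `plot_file` is given a scatter plot with the identity line is written.
#'
#' @param pred_areas numeric vector of estimated areas.
#' @param true_areas numeric vector of reference areas (same length, m >= 2).
#' @param plot_file optional path for a PNG scatter plot.
#' @return list with `r2`, `mse`, `rmse`, `m` and `data` (a data.frame with
#'   columns `true`, `pred`).
#' @export
area_correlation <- function(pred_areas, true_areas, plot_file = NULL) {
  stats <- r2_mse(true_areas, pred_areas)
  out <- c(stats, list(data = data.frame(true = true_areas,
                                         pred = pred_areas)))
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 640, height = 640)
    on.exit(grDevices::dev.off())
    lim <- range(c(true_areas, pred_areas))
    plot(true_areas, pred_areas, xlim = lim, ylim = lim,
         xlab = "reference leaf area", ylab = "estimated leaf area",
         main = sprintf("R2 = %.3f, RMSE = %.3g", stats$r2, stats$rmse),
         pch = 19, col = "forestgreen")
    abline(0, 1, lty = 2)
  }
  out
}
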