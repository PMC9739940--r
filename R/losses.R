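## Training objectives: softmax cross-entropy for semantic segmentation, the
## discriminative pull-to-center loss for instance embeddings, and the
## four-stage Chamfer loss for progressive completion. Each has a matching
## internal gradient used by the training loop.

.as_points <- function(x) {
  if (inherits(x, "labeled_cloud")) x$points else as.matrix(x)
}

#' Softmax cross-entropy over per-point part scores
#'
#' Mean over labelled points of `-log softmax(scores)[label]`. Points with
#' the sentinel label -1 are excluded.
#'
#' @param scores `N x Ns` logit matrix.
#' @param labels integer vector of 0-based part labels (-1 = unlabeled).
#' @return scalar loss.
#' @export
semantic_loss <- function(scores, labels) {
  scores <- as.matrix(scores)
  valid <- which(labels >= 0L)
  if (!length(valid)) stop("no labelled points")
  if (any(labels[valid] >= ncol(scores))) stop("label out of range")
  S <- scores[valid, , drop = FALSE]
  m <- apply(S, 1L, max)
  lse <- m + log(rowSums(exp(S - m)))
  picked <- S[cbind(seq_along(valid), labels[valid] + 1L)]
  mean(lse - picked)
}

# gradient of semantic_loss w.r.t. scores (zero rows for sentinel points)
semantic_loss_grad <- function(scores, labels) {
  scores <- as.matrix(scores)
  G <- matrix(0, nrow(scores), ncol(scores))
  valid <- which(labels >= 0L)
  S <- scores[valid, , drop = FALSE]
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  P <- E / rowSums(E)
  P[cbind(seq_along(valid), labels[valid] + 1L)] <-
    P[cbind(seq_along(valid), labels[valid] + 1L)] - 1
  G[valid, ] <- P / length(valid)
  G
}

#' Discriminative instance embedding loss
#'
#' `Ls` pulls every embedded point within the margin `delta_s` of its
#' instance center via a squared hinge on the center distance,
#' `(1/I) sum_i (1/N_i) sum_j max(0, ||c_i - f_j|| - delta_s)^2`; `Lreg =
#' (1/I) sum_i ||c_i||` keeps the centers bounded. No inter-instance push
#' term is used; mean-shift clustering separates instances at inference.
#' Points labelled -1 are excluded; an instance id with no points is skipped
#' with a warning.
#'
#' @param embedding `N x d` embedding matrix (d = 5 in the pipeline).
#' @param instance_labels integer vector (>= 0; -1 = unlabeled).
#' @param delta_s pull margin (> 0), in embedding units; default 0.1.
#' @param instance_ids optional explicit id set (ids without points warn).
#' @return list with `total`, `Ls`, `Lreg`.
#' @export
instance_loss <- function(embedding, instance_labels, delta_s = 0.1,
                          instance_ids = NULL) {
  stopifnot(delta_s > 0)
  E <- as.matrix(embedding)
  if (is.null(instance_ids))
    instance_ids <- sort(unique(instance_labels[instance_labels >= 0L]))
  present <- instance_ids[instance_ids %in% instance_labels]
  if (length(present) < length(instance_ids))
    warning("instance id(s) with no points skipped")
  if (!length(present)) stop("at least one instance required")
  I <- length(present)
  Ls <- 0; Lreg <- 0
  for (id in present) {
    rows <- which(instance_labels == id)
    ci <- colMeans(E[rows, , drop = FALSE])
    d <- sqrt(rowSums(sweep(E[rows, , drop = FALSE], 2L, ci, "-")^2))
    Ls <- Ls + mean(pmax(0, d - delta_s)^2)
    Lreg <- Lreg + sqrt(sum(ci^2))
  }
  Ls <- Ls / I
  Lreg <- Lreg / I
  list(total = Ls + Lreg, Ls = Ls, Lreg = Lreg)
}

# exact gradient of instance_loss w.r.t. the embedding (propagating through
# the instance centers)
instance_loss_grad <- function(embedding, instance_labels, delta_s = 0.1) {
  E <- as.matrix(embedding)
  G <- matrix(0, nrow(E), ncol(E))
  ids <- sort(unique(instance_labels[instance_labels >= 0L]))
  I <- length(ids)
  for (id in ids) {
    rows <- which(instance_labels == id)
    Ni <- length(rows)
    Ei <- E[rows, , drop = FALSE]
    ci <- colMeans(Ei)
    R <- sweep(Ei, 2L, ci, "-")
    d <- sqrt(rowSums(R^2))
    h <- pmax(0, d - delta_s)
    # dLs/df_l = (2/(I*Ni)) (h_l r_l/d_l - mean_j h_j r_j/d_j)
    U <- R * ifelse(d > 0, h / d, 0)
    G[rows, ] <- G[rows, ] +
      (2 / (I * Ni)) * sweep(U, 2L, colMeans(U), "-")
    nc <- sqrt(sum(ci^2))
    if (nc > 0)
      G[rows, ] <- G[rows, ] +
        matrix(ci / nc / (I * Ni), Ni, ncol(E), byrow = TRUE)
  }
  G
}

#' Chamfer distance between two point sets
#'
#' `0.5 * [mean_x min_y ||x-y|| + mean_y min_x ||x-y||]` with plain
#' (non-squared) Euclidean norms. Zero iff the two sets coincide.
#'
#' @param S1,S2 point matrices or [labeled_cloud()]s, both non-empty.
#' @return scalar distance (same units as the coordinates).
#' @export
chamfer_distance <- function(S1, S2) {
  A <- .as_points(S1); B <- .as_points(S2)
  if (!nrow(A) || !nrow(B)) stop("chamfer distance needs non-empty sets")
  0.5 * (mean(cpp_nn_dist(A, B)$dist) + mean(cpp_nn_dist(B, A)$dist))
}

# gradient of chamfer_distance w.r.t. S1 (S2 treated as constant target)
chamfer_grad <- function(S1, S2) {
  A <- .as_points(S1); B <- .as_points(S2)
  n1 <- nrow(A); n2 <- nrow(B)
  fwd <- cpp_nn_dist(A, B)
  diffs <- A - B[fwd$idx, , drop = FALSE]
  unit <- diffs / ifelse(fwd$dist > 0, fwd$dist, 1)
  unit[fwd$dist == 0, ] <- 0
  G <- 0.5 * unit / n1
  bwd <- cpp_nn_dist(B, A)
  diffs2 <- A[bwd$idx, , drop = FALSE] - B
  d2 <- bwd$dist
  unit2 <- diffs2 / ifelse(d2 > 0, d2, 1)
  unit2[d2 == 0, ] <- 0
  rs <- rowsum(0.5 * unit2 / n2, bwd$idx)
  ridx <- as.integer(rownames(rs))
  G[ridx, ] <- G[ridx, ] + rs
  G
}

#' Ground-truth pyramid for the completion loss
#'
#' Farthest-point-samples the complete cloud to the decoder's four output
#' resolutions (N/8, N/4, N/2, N in the standard configuration), coarsest
#' first, matching the prediction order Y1..Y4.
#'
#' @param complete the complete cloud (matrix or [labeled_cloud()]).
#' @param sizes increasing output sizes.
#' @return list of 4 matrices.
#' @export
completion_targets <- function(complete, sizes) {
  P <- .as_points(complete)
  stopifnot(length(sizes) == 4L, all(diff(sizes) > 0),
            max(sizes) <= nrow(P))
  lapply(sizes, function(s) {
    ctr <- colMeans(P)
    start <- which.max(rowSums(sweep(P, 2L, ctr, "-")^2)) - 1L
    P[cpp_fps(P, as.integer(s), as.integer(start)), , drop = FALSE]
  })
}

#' Progressive completion loss
#'
#' Sum of the four per-stage Chamfer distances between predicted clouds
#' `Y1..Y4` and the matching ground-truth samples.
#'
#' @param Y list of 4 predicted clouds (coarse to fine).
#' @param targets list of 4 ground-truth clouds from [completion_targets()].
#' @return scalar loss.
#' @export
completion_loss <- function(Y, targets) {
  stopifnot(length(Y) == 4L, length(targets) == 4L)
  for (t in 1:4) {
    if (nrow(.as_points(Y[[t]])) != nrow(.as_points(targets[[t]])))
      stop("stage size mismatch between prediction and target")
  }
  sum(vapply(1:4, function(t)
    chamfer_distance(Y[[t]], targets[[t]]), 0))
}

#' Earth mover's distance between equal-size point sets
#'
#' `min_phi mean_x ||x - phi(x)||` over bijections `phi`. Solved exactly by
#' the Hungarian algorithm for sets up to 512 points; larger sets use an
#' entropically regularised transport plan rounded to a bijection, an upper
#' bound typically within a few percent of the optimum.
#'
#' @param S1,S2 point matrices or [labeled_cloud()]s with `|S1| = |S2|`.
#' @param exact_max largest size solved exactly.
#' @return scalar distance.
#' @export
emd_distance <- function(S1, S2, exact_max = 512L) {
  A <- .as_points(S1); B <- .as_points(S2)
  if (nrow(A) != nrow(B))
    stop("EMD is only defined for equal-size sets")
  n <- nrow(A)
  if (n == 1L) return(sqrt(sum((A - B)^2)))
  C <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  C[C < 0] <- 0
  C <- sqrt(C)
  if (n <= exact_max) {
    return(cpp_hungarian(C)$cost / n)
  }
  # Sinkhorn plan, then greedy rounding to a bijection
  eps <- 0.02 * mean(C)
  K <- exp(-C / eps)
  u <- rep(1, n)
  for (it in 1:200) {
    v <- 1 / (crossprod(K, u))
    u <- 1 / (K %*% v)
  }
  P <- (u %*% t(v)) * K
  ord <- order(-P)
  rows_used <- logical(n); cols_used <- logical(n)
  total <- 0; matched <- 0L
  for (o in ord) {
    i <- (o - 1L) %% n + 1L
    j <- (o - 1L) %/% n + 1L
    if (rows_used[i] || cols_used[j]) next
    rows_used[i] <- TRUE; cols_used[j] <- TRUE
    total <- total + C[i, j]
    matched <- matched + 1L
    if (matched == n) break
  }
  total / n
}
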