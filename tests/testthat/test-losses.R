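test_that("cross-entropy hits its analytic values", {
  # saturated logits: loss near zero
  sc <- rbind(c(10, 0), c(0, 10))
  expect_lt(semantic_loss(sc, c(0L, 1L)), 1e-3)
  # uniform logits over 2 classes: ln 2 per point
  expect_equal(semantic_loss(matrix(0, 5, 2), rep(0L, 5)), log(2),
               tolerance = 1e-12)
  # hand computation for 3 points
  S <- rbind(c(1, 2), c(-0.5, 0.3), c(0, 0))
  y <- c(1L, 0L, 1L)
  hand <- mean(-log(exp(S[cbind(1:3, y + 1)]) / rowSums(exp(S))))
  expect_equal(semantic_loss(S, y), hand, tolerance = 1e-7)
  # sentinel rows are excluded
  expect_equal(semantic_loss(rbind(S, c(99, -99)), c(y, -1L)), hand)
  expect_error(semantic_loss(S, rep(-1L, 3)), "no labelled")
})

test_that("cross-entropy decreases when a wrong row becomes the true one-hot", {
  set.seed(21)
  S <- matrix(rnorm(20), 10, 2)
  y <- sample(0:1, 10, TRUE)
  wrong <- which(max.col(S) - 1L != y)[1]
  S2 <- S
  S2[wrong, ] <- ifelse(seq_len(2) == y[wrong] + 1, 10, -10)
  expect_lt(semantic_loss(S2, y), semantic_loss(S, y))
})

test_that("semantic loss gradient matches finite differences", {
  set.seed(22)
  S <- matrix(rnorm(12), 4, 3)
  y <- c(0L, 2L, -1L, 1L)
  G <- seedlingmix:::semantic_loss_grad(S, y)
  eps <- 1e-6
  for (idx in c(1, 5, 9, 12)) {
    S1 <- S; S1[idx] <- S1[idx] + eps
    S2 <- S; S2[idx] <- S2[idx] - eps
    expect_equal(G[idx], (semantic_loss(S1, y) - semantic_loss(S2, y)) /
                   (2 * eps), tolerance = 1e-5)
  }
  expect_equal(G[3, ], c(0, 0, 0))   # sentinel row
})

test_that("instance loss follows its closed form", {
  # all points at their centers: Ls = 0, total = mean center norm
  E <- rbind(c(1, 0), c(1, 0), c(0, 2), c(0, 2))
  il <- instance_loss(E, c(0L, 0L, 1L, 1L), delta_s = 0.1)
  expect_equal(il$Ls, 0)
  expect_equal(il$Lreg, (1 + 2) / 2)
  # inside the margin the hinge is inactive
  E2 <- rbind(c(0.05, 0), c(-0.05, 0))
  expect_equal(instance_loss(E2, c(0L, 0L), delta_s = 0.1)$Ls, 0)
  # 2 instances, 2 points each, 1-D embedding, hand evaluation
  e <- c(0, 1, 4, 7)
  lab <- c(0L, 0L, 1L, 1L)
  ds <- 0.2
  c1 <- 0.5; c2 <- 5.5
  Ls_hand <- mean(pmax(0, abs(e[1:2] - c1) - ds)^2) / 2 +
    mean(pmax(0, abs(e[3:4] - c2) - ds)^2) / 2
  il2 <- instance_loss(matrix(e, 4, 1), lab, ds)
  expect_equal(il2$Ls, Ls_hand, tolerance = 1e-7)
  expect_equal(il2$Lreg, (0.5 + 5.5) / 2, tolerance = 1e-7)
  expect_warning(instance_loss(E, c(0L, 0L, 1L, 1L), 0.1,
                               instance_ids = 0:2), "skipped")
})

test_that("instance loss: Ls is translation invariant, Lreg is not", {
  set.seed(23)
  E <- matrix(rnorm(40), 20, 2)
  lab <- rep(0:1, each = 10L)
  a <- instance_loss(E, lab, 0.1)
  b <- instance_loss(E + 5, lab, 0.1)
  expect_equal(a$Ls, b$Ls, tolerance = 1e-9)
  expect_gt(abs(a$Lreg - b$Lreg), 1)
})

test_that("instance loss gradient matches finite differences", {
  set.seed(24)
  E <- matrix(rnorm(18), 6, 3)
  lab <- c(0L, 0L, 1L, 1L, 1L, -1L)
  G <- seedlingmix:::instance_loss_grad(E, lab, 0.15)
  f <- function(E) instance_loss(E, lab, 0.15)$total
  eps <- 1e-6
  for (idx in c(1, 4, 8, 15)) {
    E1 <- E; E1[idx] <- E1[idx] + eps
    E2 <- E; E2[idx] <- E2[idx] - eps
    expect_equal(G[idx], (f(E1) - f(E2)) / (2 * eps), tolerance = 1e-4)
  }
  expect_equal(G[6, ], c(0, 0, 0))   # unlabeled point
})

test_that("chamfer distance matches analytic values and a brute-force oracle", {
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(chamfer_distance(A, A), 0)
  expect_equal(chamfer_distance(matrix(0, 1, 3), matrix(c(1, 0, 0), 1, 3)), 1)
  set.seed(25)
  S1 <- matrix(runif(150), 50, 3)
  S2 <- matrix(runif(150), 50, 3)
  Dm <- as.matrix(stats::dist(rbind(S1, S2)))[1:50, 51:100]
  oracle <- 0.5 * (mean(apply(Dm, 1, min)) + mean(apply(Dm, 2, min)))
  expect_equal(chamfer_distance(S1, S2), oracle, tolerance = 1e-6)
  expect_equal(chamfer_distance(S1, S2), chamfer_distance(S2, S1))
  expect_error(chamfer_distance(S1, matrix(numeric(0), 0, 3)), "non-empty")
})

test_that("chamfer gradient matches finite differences", {
  set.seed(26)
  S1 <- matrix(runif(24), 8, 3)
  S2 <- matrix(runif(36), 12, 3)
  G <- seedlingmix:::chamfer_grad(S1, S2)
  eps <- 1e-6
  for (idx in c(2, 11, 20)) {
    P1 <- S1; P1[idx] <- P1[idx] + eps
    P2 <- S1; P2[idx] <- P2[idx] - eps
    expect_equal(G[idx],
                 (chamfer_distance(P1, S2) - chamfer_distance(P2, S2)) /
                   (2 * eps), tolerance = 1e-4)
  }
})

test_that("completion loss is the sum of its stage chamfers", {
  set.seed(27)
  sizes <- c(8, 16, 32, 64)
  Y <- lapply(sizes, function(s) matrix(runif(3 * s), s, 3))
  gt <- lapply(sizes, function(s) matrix(runif(3 * s), s, 3))
  expect_equal(completion_loss(Y, gt),
               sum(mapply(chamfer_distance, Y, gt)))
  expect_equal(completion_loss(gt, gt), 0)
  # shifting only Y4 changes the loss by exactly that stage's change
  Y2 <- Y
  Y2[[4]] <- Y[[4]] + matrix(c(0.01, 0, 0), 64, 3, byrow = TRUE)
  expect_equal(completion_loss(Y2, gt) - completion_loss(Y, gt),
               chamfer_distance(Y2[[4]], gt[[4]]) -
                 chamfer_distance(Y[[4]], gt[[4]]), tolerance = 1e-12)
  Ybad <- Y; Ybad[[2]] <- Y[[3]]
  expect_error(completion_loss(Ybad, gt), "size mismatch")
})

test_that("EMD equals the exhaustive-permutation optimum on tiny sets", {
  set.seed(28)
  for (n in c(2, 4, 6)) {
    S1 <- matrix(runif(3 * n), n, 3)
    S2 <- matrix(runif(3 * n), n, 3)
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
      out
    }
    best <- min(sapply(perms(seq_len(n)), function(p)
      mean(sqrt(rowSums((S1 - S2[p, , drop = FALSE])^2)))))
    expect_equal(emd_distance(S1, S2), best, tolerance = 1e-9)
  }
  # identical sets under permutation: zero
  S <- matrix(runif(15), 5, 3)
  expect_equal(emd_distance(S, S[c(3, 1, 5, 2, 4), ]), 0)
  expect_equal(emd_distance(cbind(c(0, 1), 0, 0), cbind(c(1, 0), 0, 0)), 0)
  expect_error(emd_distance(S, S[1:3, ]), "equal-size")
})

test_that("chamfer lower-bounds EMD on equal-size sets", {
  set.seed(29)
  for (i in 1:100) {
    n <- sample(3:20, 1)
    S1 <- matrix(runif(3 * n), n, 3)
    S2 <- matrix(runif(3 * n), n, 3)
    expect_lte(chamfer_distance(S1, S2), emd_distance(S1, S2) + 1e-12)
  }
})

test_that("approximate EMD for large sets stays near the exact solve", {
  set.seed(30)
  n <- 600
  S1 <- matrix(runif(3 * n), n, 3)
  S2 <- S1 + matrix(rnorm(3 * n, 0, 0.02), n, 3)
  approx <- emd_distance(S1, S2)                      # sinkhorn path
  exact <- emd_distance(S1, S2, exact_max = 1024L)    # hungarian path
  expect_gte(approx, exact - 1e-12)                   # upper bound
  expect_lt((approx - exact) / exact, 0.1)
})
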