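## Minimal dense-layer toolkit with hand-derived reverse-mode gradients.
## Parameters are nested lists of numeric matrices/vectors; every forward
## returns (out, cache) and every backward returns (grad_params, grad_in).
## Batch-norm running statistics are updated through a side-channel
## environment keyed by a per-layer id, so forward passes stay functional.

.layer_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    sprintf("bn%06d", i)
  }
})


# fast column-wise arithmetic (avoids sweep's array/aperm overhead)
.cadd <- function(X, v) X + rep(v, each = nrow(X))
.csub <- function(X, v) X - rep(v, each = nrow(X))
.cmul <- function(X, v) X * rep(v, each = nrow(X))

he_mat <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
         fan_in, fan_out)
}

linear_init <- function(d_in, d_out) {
  list(W = he_mat(d_in, d_out), b = numeric(d_out))
}

linear_forward <- function(p, X) {
  out <- .cadd(X %*% p$W, p$b)
  list(out = out, cache = list(X = X))
}

linear_backward <- function(p, cache, G) {
  list(grads = list(W = crossprod(cache$X, G), b = colSums(G)),
       gin = G %*% t(p$W))
}

lrelu_forward <- function(X, slope = 0.01) {
  fac <- slope + (1 - slope) * (X > 0)
  list(out = X * fac, cache = list(fac = fac))
}

lrelu_backward <- function(cache, G) {
  G * cache$fac
}

bn_init <- function(d) {
  list(gamma = rep(1, d), beta = numeric(d),
       running_mean = numeric(d), running_var = rep(1, d),
       id = .layer_counter())
}

bn_forward <- function(p, X, train, state = NULL, momentum = 0.9,
                       eps = 1e-5) {
  if (train) {
    mu <- colMeans(X)
    va <- colMeans(X^2) - mu^2
    va[va < 0] <- 0
    if (!is.null(state)) {
      state[[p$id]] <- list(
        running_mean = momentum * p$running_mean + (1 - momentum) * mu,
        running_var = momentum * p$running_var + (1 - momentum) * va)
    }
  } else {
    mu <- p$running_mean
    va <- p$running_var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- .cmul(.csub(X, mu), inv)
  out <- .cadd(.cmul(xhat, p$gamma), p$beta)
  list(out = out, cache = list(xhat = xhat, inv = inv, train = train))
}

bn_backward <- function(p, cache, G) {
  xhat <- cache$xhat
  ggamma <- colSums(G * xhat)
  gbeta <- colSums(G)
  gxhat <- .cmul(G, p$gamma)
  if (cache$train) {
    gX <- .csub(gxhat, colMeans(gxhat)) -
      .cmul(xhat, colMeans(gxhat * xhat))
    gX <- .cmul(gX, cache$inv)
  } else {
    gX <- .cmul(gxhat, cache$inv)
  }
  list(grads = list(gamma = ggamma, beta = gbeta), gin = gX)
}

ln_init <- function(d) list(gamma = rep(1, d), beta = numeric(d))

ln_forward <- function(p, X, eps = 1e-5) {
  mu <- rowMeans(X)
  va <- rowMeans(X^2) - mu^2
  va[va < 0] <- 0
  inv <- 1 / sqrt(va + eps)
  xhat <- (X - mu) * inv
  out <- .cadd(.cmul(xhat, p$gamma), p$beta)
  list(out = out, cache = list(xhat = xhat, inv = inv))
}

ln_backward <- function(p, cache, G) {
  xhat <- cache$xhat
  ggamma <- colSums(G * xhat)
  gbeta <- colSums(G)
  gxhat <- .cmul(G, p$gamma)
  gX <- (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat)) * cache$inv
  list(grads = list(gamma = ggamma, beta = gbeta), gin = gX)
}

dropout_forward <- function(X, p_drop, train) {
  if (!train || p_drop <= 0) {
    return(list(out = X, cache = list(mask = NULL)))
  }
  mask <- matrix(stats::rbinom(length(X), 1L, 1 - p_drop), nrow(X)) /
    (1 - p_drop)
  list(out = X * mask, cache = list(mask = mask))
}

dropout_backward <- function(cache, G) {
  if (is.null(cache$mask)) G else G * cache$mask
}

## linear -> batch norm -> LeakyReLU, the recurring feed-forward unit
lbr_init <- function(d_in, d_out) {
  list(lin = linear_init(d_in, d_out), bn = bn_init(d_out))
}

lbr_forward <- function(p, X, train, state = NULL, slope = 0.01) {
  f1 <- linear_forward(p$lin, X)
  f2 <- bn_forward(p$bn, f1$out, train, state)
  f3 <- lrelu_forward(f2$out, slope)
  list(out = f3$out, cache = list(f1 = f1$cache, f2 = f2$cache,
                                  f3 = f3$cache))
}

lbr_backward <- function(p, cache, G) {
  g3 <- lrelu_backward(cache$f3, G)
  b2 <- bn_backward(p$bn, cache$f2, g3)
  b1 <- linear_backward(p$lin, cache$f1, b2$gin)
  list(grads = list(lin = b1$grads, bn = b2$grads), gin = b1$gin)
}

## two fully connected layers with a LeakyReLU between (the mixer MLP and
## the per-point coordinate MLP)
mlp2_init <- function(d_in, d_hidden, d_out) {
  list(l1 = linear_init(d_in, d_hidden), l2 = linear_init(d_hidden, d_out))
}

mlp2_forward <- function(p, X, slope = 0.01) {
  f1 <- linear_forward(p$l1, X)
  f2 <- lrelu_forward(f1$out, slope)
  f3 <- linear_forward(p$l2, f2$out)
  list(out = f3$out, cache = list(f1 = f1$cache, f2 = f2$cache,
                                  f3 = f3$cache))
}

mlp2_backward <- function(p, cache, G) {
  b3 <- linear_backward(p$l2, cache$f3, G)
  g2 <- lrelu_backward(cache$f2, b3$gin)
  b1 <- linear_backward(p$l1, cache$f1, g2)
  list(grads = list(l1 = b1$grads, l2 = b3$grads), gin = b1$gin)
}

## ---- nested-list parameter algebra -------------------------------------

.is_param_leaf <- function(x) is.numeric(x)

# Child accessor that works for both named nodes (lbr/bn/...; gradient
# structures may omit entries such as bn running statistics) and unnamed
# stage lists (agg, enc_mix, decoder stages), matching by name when names
# exist and by position otherwise.
.child_keys <- function(x) {
  nms <- names(x)
  if (is.null(nms)) seq_along(x) else nms
}

params_zero_like <- function(x) {
  if (.is_param_leaf(x)) return(x * 0)
  if (!is.list(x)) return(x)
  out <- x
  for (key in .child_keys(x)) {
    if (identical(key, "id")) next
    out[[key]] <- params_zero_like(x[[key]])
  }
  out
}

# y + a * x over congruent nested lists (missing grads treated as zero)
params_axpy <- function(a, x, y) {
  if (is.null(x)) return(y)
  if (.is_param_leaf(y)) return(y + a * x)
  if (!is.list(y)) return(y)
  out <- y
  for (key in .child_keys(y)) {
    if (identical(key, "id")) next
    xv <- if (is.list(x) && (is.character(key) || key <= length(x)))
      x[[key]] else NULL
    out[[key]] <- params_axpy(a, xv, y[[key]])
  }
  out
}

# global L2 norm over every leaf of a gradient structure
params_grad_norm <- function(x) {
  acc <- 0
  rec <- function(g) {
    if (is.null(g)) return(invisible(NULL))
    if (.is_param_leaf(g)) {
      acc <<- acc + sum(g * g)
    } else if (is.list(g)) {
      for (key in .child_keys(g)) {
        if (identical(key, "id")) next
        rec(g[[key]])
      }
    }
    invisible(NULL)
  }
  rec(x)
  sqrt(acc)
}

params_scale <- function(x, a) {
  if (is.null(x)) return(NULL)
  if (.is_param_leaf(x)) return(a * x)
  if (!is.list(x)) return(x)
  for (key in .child_keys(x)) {
    if (identical(key, "id")) next
    x[[key]] <- params_scale(x[[key]], a)
  }
  x
}

# apply batch-norm running-statistic updates recorded in `state`
apply_bn_updates <- function(params, state) {
  if (!is.list(params)) return(params)
  if (!is.null(params$id) && !is.null(state[[params$id]])) {
    params$running_mean <- state[[params$id]]$running_mean
    params$running_var <- state[[params$id]]$running_var
    return(params)
  }
  for (key in .child_keys(params)) {
    if (identical(key, "id")) next
    if (is.list(params[[key]])) {
      params[[key]] <- apply_bn_updates(params[[key]], state)
    }
  }
  params
}
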