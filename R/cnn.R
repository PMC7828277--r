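# Dual-branch convolutional network internals.
#
# Each branch: conv(k x k, F1) -> ReLU -> 2x2 average pool -> conv(k x k,
# F2) -> ReLU -> 2x2 average pool -> flatten. The two branch feature
# vectors (spatial- and temporal-emphasis orderings of the same signature)
# are concatenated into a dense 3-way softmax head. Implemented with
# im2col convolutions and explicit backpropagation; sizes are kept small
# because single-CPU training is the target.

# memoized im2col index maps, keyed by input shape and kernel size
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(h, w, C, k) {
  key <- paste(h, w, C, k, sep = "x")
  cached <- .im2col_cache[[key]]
  if (!is.null(cached)) return(cached)
  oh <- h - k + 1L
  ow <- w - k + 1L
  base <- rep(seq_len(oh), times = ow) + (rep(seq_len(ow), each = oh) - 1L) * h
  offs <- as.vector(outer(
    as.vector(outer(seq_len(k) - 1L, (seq_len(k) - 1L) * h, "+")),
    (seq_len(C) - 1L) * h * w, "+"))
  idx <- outer(base, offs, "+")
  .im2col_cache[[key]] <- list(idx = idx, oh = oh, ow = ow)
  .im2col_cache[[key]]
}

im2col <- function(x, k) {
  d <- dim(x)
  map <- im2col_index(d[1], d[2], d[3], k)
  matrix(x[map$idx], nrow = map$oh * map$ow)
}

col2im <- function(dcol, dims, k) {
  map <- im2col_index(dims[1], dims[2], dims[3], k)
  dx <- numeric(prod(dims))
  for (j in seq_len(ncol(dcol))) {
    t1 <- map$idx[, j]
    dx[t1] <- dx[t1] + dcol[, j]
  }
  array(dx, dim = dims)
}

avg_pool2 <- function(x) {
  d <- dim(x)
  oh <- d[1] %/% 2L
  ow <- d[2] %/% 2L
  a <- x[seq_len(2L * oh), seq_len(2L * ow), , drop = FALSE]
  dim(a) <- c(2L, oh, 2L, ow, d[3])
  s <- a[1, , 1, , , drop = FALSE] + a[2, , 1, , , drop = FALSE] +
    a[1, , 2, , , drop = FALSE] + a[2, , 2, , , drop = FALSE]
  array(s, dim = c(oh, ow, d[3])) / 4
}

avg_unpool2 <- function(d_out, dims) {
  od <- dim(d_out)
  big <- array(0, dim = c(2L * od[1], 2L * od[2], od[3]))
  q <- d_out / 4
  r1 <- seq(1L, 2L * od[1], by = 2L)
  c1 <- seq(1L, 2L * od[2], by = 2L)
  big[r1, c1, ] <- q
  big[r1 + 1L, c1, ] <- q
  big[r1, c1 + 1L, ] <- q
  big[r1 + 1L, c1 + 1L, ] <- q
  dx <- array(0, dim = dims)
  dx[seq_len(dim(big)[1]), seq_len(dim(big)[2]), ] <- big
  dx
}

branch_dims <- function(input_dim, filters, k) {
  h1 <- input_dim[1] - k + 1L; w1 <- input_dim[2] - k + 1L
  p1 <- c(h1 %/% 2L, w1 %/% 2L, filters[1])
  h2 <- p1[1] - k + 1L; w2 <- p1[2] - k + 1L
  p2 <- c(h2 %/% 2L, w2 %/% 2L, filters[2])
  list(conv1 = c(h1, w1, filters[1]), pool1 = p1,
       conv2 = c(h2, w2, filters[2]), pool2 = p2,
       flat = prod(p2))
}

init_dual_cnn_params <- function(input_dim, filters, k) {
  bd <- branch_dims(input_dim, filters, k)
  he <- function(fan_in, n) stats::rnorm(n, sd = sqrt(2 / fan_in))
  branch <- function() {
    list(
      K1 = matrix(he(k * k, k * k * filters[1]), k * k, filters[1]),
      b1 = numeric(filters[1]),
      K2 = matrix(he(k * k * filters[1], k * k * filters[1] * filters[2]),
                  k * k * filters[1], filters[2]),
      b2 = numeric(filters[2])
    )
  }
  ps <- branch()
  pt <- branch()
  params <- list(
    sp.K1 = ps$K1, sp.b1 = ps$b1, sp.K2 = ps$K2, sp.b2 = ps$b2,
    tm.K1 = pt$K1, tm.b1 = pt$b1, tm.K2 = pt$K2, tm.b2 = pt$b2,
    W = matrix(he(2 * bd$flat, 2 * bd$flat * 3), 2 * bd$flat, 3),
    b = numeric(3)
  )
  attr(params, "branch_dims") <- bd
  params
}

branch_forward <- function(x_mat, prefix, params, k, bd) {
  a0 <- array(x_mat, dim = c(dim(x_mat), 1L))
  col1 <- im2col(a0, k)
  z1 <- sweep(col1 %*% params[[paste0(prefix, ".K1")]], 2L,
              params[[paste0(prefix, ".b1")]], "+")
  r1 <- pmax(z1, 0)
  p1 <- avg_pool2(array(r1, dim = bd$conv1))
  col2 <- im2col(p1, k)
  z2 <- sweep(col2 %*% params[[paste0(prefix, ".K2")]], 2L,
              params[[paste0(prefix, ".b2")]], "+")
  r2 <- pmax(z2, 0)
  p2 <- avg_pool2(array(r2, dim = bd$conv2))
  list(flat = as.vector(p2), col1 = col1, z1 = z1, col2 = col2, z2 = z2,
       a0_dim = dim(a0))
}

branch_backward <- function(dflat, cache, prefix, params, k, bd, grads) {
  dp2 <- array(dflat, dim = bd$pool2)
  dr2 <- avg_unpool2(dp2, bd$conv2)
  dz2 <- matrix(dr2, nrow = prod(bd$conv2[1:2])) * (cache$z2 > 0)
  grads[[paste0(prefix, ".K2")]] <- grads[[paste0(prefix, ".K2")]] +
    crossprod(cache$col2, dz2)
  grads[[paste0(prefix, ".b2")]] <- grads[[paste0(prefix, ".b2")]] +
    colSums(dz2)
  dcol2 <- dz2 %*% t(params[[paste0(prefix, ".K2")]])
  dp1 <- col2im(dcol2, bd$pool1, k)
  dr1 <- avg_unpool2(dp1, bd$conv1)
  dz1 <- matrix(dr1, nrow = prod(bd$conv1[1:2])) * (cache$z1 > 0)
  grads[[paste0(prefix, ".K1")]] <- grads[[paste0(prefix, ".K1")]] +
    crossprod(cache$col1, dz1)
  grads[[paste0(prefix, ".b1")]] <- grads[[paste0(prefix, ".b1")]] +
    colSums(dz1)
  grads
}

dual_cnn_forward_one <- function(state, sig) {
  k <- state$hyper$kernel
  bd <- attr(state$params, "branch_dims")
  sp <- branch_forward(sig, "sp", state$params, k, bd)
  tm <- branch_forward(reorder_signature(sig, "temporal"), "tm",
                       state$params, k, bd)
  f <- c(sp$flat, tm$flat)
  score <- drop(f %*% state$params$W) + state$params$b
  list(score = score, f = f, sp = sp, tm = tm, bd = bd, k = k)
}

dual_cnn_scores <- function(state, arr) {
  n <- dim(arr)[3]
  t(vapply(seq_len(n), function(s) {
    dual_cnn_forward_one(state, arr[, , s])$score
  }, numeric(3)))
}

train_dual_cnn <- function(state, arr, y, epochs, seed) {
  n <- dim(arr)[3]
  bs <- min(state$hyper$batch_size, n)
  lr <- state$hyper$lr
  yk <- diag(3)
  losses <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        grads <- lapply(state$params, function(p) p * 0)
        for (s in idx) {
          fw <- dual_cnn_forward_one(state, arr[, , s])
          p <- exp(fw$score - max(fw$score))
          p <- p / sum(p)
          ep_loss <- ep_loss - log(max(p[y[s]], 1e-12))
          dscore <- (p - yk[y[s], ]) / length(idx)
          grads$W <- grads$W + outer(fw$f, dscore)
          grads$b <- grads$b + dscore
          df <- drop(state$params$W %*% dscore)
          nf <- fw$bd$flat
          grads <- branch_backward(df[seq_len(nf)], fw$sp, "sp",
                                   state$params, fw$k, fw$bd, grads)
          grads <- branch_backward(df[nf + seq_len(nf)], fw$tm, "tm",
                                   state$params, fw$k, fw$bd, grads)
        }
        bdims <- attr(state$params, "branch_dims")
        upd <- adam_step(state$params, grads, state$opt, lr)
        state$params <- upd$params
        attr(state$params, "branch_dims") <- bdims
        state$opt <- upd$opt
      }
      losses[ep] <- ep_loss / n
    }
  })
  state$history <- rbind(state$history,
                         data.frame(call = state$n_train_calls,
                                    epoch = seq_len(epochs),
                                    loss = losses))
  state
}
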