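# Internal neural-network primitives.
#
# A batch of M encoded records of length L with C channels is carried as an
# (M*L) x C matrix, positions of record r occupying rows (r-1)*L + 1..L.
# Convolutions use 'same' zero padding via an im2col patch matrix so every
# stage preserves the sequence length and parallel branches can be
# concatenated along the channel axis.

# --- im2col ------------------------------------------------------------

# (M*L) x k matrix of source-row indices into rbind(X, 0); out-of-range
# positions point at the appended zero row (N + 1)
patch_index <- function(M, L, k) {
  N <- M * L
  lo <- -((k - 1L) %/% 2L)
  offs <- lo + seq_len(k) - 1L
  t_pos <- rep(seq_len(L), times = M)
  base <- rep((seq_len(M) - 1L) * L, each = L)
  idx <- matrix(0L, N, k)
  for (j in seq_len(k)) {
    src <- t_pos + offs[j]
    ok <- src >= 1L & src <= L
    idx[, j] <- ifelse(ok, base + src, N + 1L)
  }
  idx
}

im2col <- function(X, idx, k) {
  N <- nrow(X)
  C <- ncol(X)
  Xaug <- rbind(X, 0)
  P <- matrix(0, N, k * C)
  for (j in seq_len(k)) {
    P[, ((j - 1L) * C + 1L):(j * C)] <- Xaug[idx[, j], , drop = FALSE]
  }
  P
}

col2im <- function(dP, idx, k, N, C) {
  dX <- matrix(0, N, C)
  for (j in seq_len(k)) {
    block <- dP[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
    src <- idx[, j]
    keep <- src <= N          # drop gradient flowing into the pad row
    dX[src[keep], ] <- dX[src[keep], , drop = FALSE] +
      block[keep, , drop = FALSE]
  }
  dX
}

# --- layers ------------------------------------------------------------

conv_fwd <- function(X, W, b, idx, k) {
  P <- im2col(X, idx, k)
  Z <- P %*% W
  Z <- Z + matrix(b, nrow(Z), length(b), byrow = TRUE)
  A <- pmax(Z, 0)
  list(out = A, P = P, mask = Z > 0)
}

conv_bwd <- function(dA, cache, W, idx, k, N, C) {
  dZ <- dA * cache$mask
  list(dW = crossprod(cache$P, dZ),
       db = colSums(dZ),
       dX = col2im(dZ %*% t(W), idx, k, N, C))
}

bn_fwd <- function(X, gamma, beta, run_mean, run_var, training,
                   momentum = 0.9, eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2
    v[v < 0] <- 0
    new_mean <- momentum * run_mean + (1 - momentum) * mu
    new_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean
    v <- run_var
    new_mean <- run_mean
    new_var <- run_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(X, 2, mu), 2, inv_sd, `*`)
  out <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = out, xhat = xhat, inv_sd = inv_sd,
       run_mean = new_mean, run_var = new_var)
}

bn_bwd <- function(dout, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, gamma, `*`)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, `*`)
  dx <- sweep(dx, 2, cache$inv_sd, `*`)
  list(dX = dx, dgamma = dgamma, dbeta = dbeta)
}

dropout_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = X, mask = NULL))
  }
  mask <- matrix((stats::runif(length(X)) >= rate) / (1 - rate),
                 nrow(X), ncol(X))
  list(out = X * mask, mask = mask)
}

dropout_bwd <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}

max_pool_fwd <- function(X, M, L) {
  C <- ncol(X)
  best <- matrix(-Inf, M, C)
  argb <- matrix(1L, M, C)
  for (t in seq_len(L)) {
    rows <- (seq_len(M) - 1L) * L + t
    cur <- X[rows, , drop = FALSE]
    better <- cur > best
    best[better] <- cur[better]
    argb[better] <- t
  }
  list(out = best, arg = argb)
}

max_pool_bwd <- function(dpool, arg, M, L, C) {
  N <- M * L
  dX <- matrix(0, N, C)
  rows <- (seq_len(M) - 1L) * L + arg          # M x C of row indices
  lin <- as.vector(rows + matrix((seq_len(C) - 1L) * N, M, C, byrow = TRUE))
  dX[lin] <- as.vector(dpool)
  dX
}

avg_pool_fwd <- function(X, M, L) {
  rowsum(X, rep(seq_len(M), each = L)) / L
}

avg_pool_bwd <- function(dpool, M, L) {
  dpool[rep(seq_len(M), each = L), , drop = FALSE] / L
}

# softmax cross-entropy; y is 1-based class index
softmax_xent <- function(logits, y) {
  p <- softmax(logits)
  n <- nrow(logits)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(n), y)] + eps))
  dlogits <- p
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = dlogits / n)
}

#' Row-wise softmax
#'
#' Numerically stable softmax applied to each row of a logit matrix; rows
#' sum to 1.
#'
#' @param logits Numeric matrix (or vector, treated as one row).
#' @return Matrix of probabilities with the same shape.
#' @examples
#' softmax(rbind(c(1, 2, 3, 0, 0, 0)))
#' @export
softmax <- function(logits) {
  if (is.vector(logits)) logits <- matrix(logits, nrow = 1)
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# --- Adam --------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, frozen = character(0)) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    if (nm %in% frozen) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Glorot-uniform initializer
glorot <- function(fan_in, fan_out, nrow, ncol) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}
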