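# Neural-network primitives: GRU forward/backward, dense heads, softmax
# cross-entropy, and Adam. Written in base R matrix operations with manual
# backpropagation; gradient correctness is checked against finite
# differences in the test suite.

cg_sigmoid <- function(x) 1 / (1 + exp(-x))

#' Numerically stable softplus
#'
#' `softplus(x) = log(1 + exp(x))`, evaluated stably for large `x`.
#'
#' @param x numeric.
#' @return numeric of the same shape.
#' @export
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

cg_softmax <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# uniform Glorot-style initialization, deterministic under the caller's seed
cg_init_mat <- function(nr, nc) {
  a <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

cg_zero_like <- function(params) lapply(params, function(p) p * 0)

cg_axpy <- function(acc, inc) {
  for (nm in names(inc)) acc[[nm]] <- acc[[nm]] + inc[[nm]]
  acc
}

# ---- GRU cell ---------------------------------------------------------------
# convention: r = sigm(xW_r + hW_r + b_r); z = sigm(xW_z + hW_z + b_z);
#             n = tanh(xW_n + r * (hW_n) + b_n); h' = (1 - z) * n + z * h

cg_gru_fwd <- function(x, hprev, Wx, Wh, b) {
  nh <- ncol(Wh) / 3L
  ri <- 1:nh; zi <- nh + ri; ni <- 2L * nh + ri
  xW <- x %*% Wx
  hW <- hprev %*% Wh
  r <- cg_sigmoid(xW[, ri, drop = FALSE] + hW[, ri, drop = FALSE] +
                    rep(b[ri], each = nrow(x)))
  z <- cg_sigmoid(xW[, zi, drop = FALSE] + hW[, zi, drop = FALSE] +
                    rep(b[zi], each = nrow(x)))
  n <- tanh(xW[, ni, drop = FALSE] + r * hW[, ni, drop = FALSE] +
              rep(b[ni], each = nrow(x)))
  h <- (1 - z) * n + z * hprev
  list(h = h, cache = list(x = x, hprev = hprev, r = r, z = z, n = n,
                           hWn = hW[, ni, drop = FALSE]))
}

cg_gru_bwd <- function(dh, cache, Wx, Wh) {
  r <- cache$r; z <- cache$z; n <- cache$n
  daz <- dh * (cache$hprev - n) * z * (1 - z)
  dan <- dh * (1 - z) * (1 - n^2)
  dar <- dan * cache$hWn * r * (1 - r)
  dxW <- cbind(dar, daz, dan)
  dhW <- cbind(dar, daz, dan * r)
  list(
    dx = dxW %*% t(Wx),
    dhprev = dh * z + dhW %*% t(Wh),
    dWx = t(cache$x) %*% dxW,
    dWh = t(cache$hprev) %*% dhW,
    db = colSums(dxW)
  )
}

# accumulate embedding-row gradients: demb[idx, ] += dx, with repeats
cg_emb_accum <- function(demb, idx, dx) {
  g <- rowsum(dx, group = idx)
  rows <- as.integer(rownames(g))
  demb[rows, ] <- demb[rows, , drop = FALSE] + g
  demb
}

# ---- Adam -------------------------------------------------------------------

cg_adam_init <- function(params) {
  list(m = cg_zero_like(params), v = cg_zero_like(params), t = 0L)
}

cg_adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, which = names(grads)) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in which) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
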