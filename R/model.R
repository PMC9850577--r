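# The sequence VAE: GRU encoder producing a diagonal latent Gaussian, GRU
# decoder conditioned on the latent vector (initializes the hidden state and
# is concatenated to every input embedding), and sampling-based generation.

DECODER_PARAM_NAMES <- c("dec_emb", "dec_Wz", "dec_bz", "dec_Wx", "dec_Wh",
                         "dec_b", "W_out", "b_out")
ENCODER_PARAM_NAMES <- c("enc_emb", "enc_Wx", "enc_Wh", "enc_b",
                         "W_mu", "b_mu", "W_lv", "b_lv")

#' Model configuration
#'
#' Hyperparameters of the sequence VAE. Defaults are desk-scale: small
#' enough to train in minutes on one CPU while leaving the latent geometry
#' observable; all are exposed here.
#'
#' @param latent_dim latent dimensionality d (default 32).
#' @param hidden_size GRU hidden width (default 64).
#' @param embed_size token embedding width (default 16).
#' @param max_len maximum encoded sequence length incl. sentinels
#'   (default 120).
#' @param seed parameter-initialization seed.
#' @return list of configuration values.
#' @export
contragen_config <- function(latent_dim = 32L, hidden_size = 64L,
                             embed_size = 16L, max_len = 120L, seed = 1L) {
  list(latent_dim = as.integer(latent_dim),
       hidden_size = as.integer(hidden_size),
       embed_size = as.integer(embed_size),
       max_len = as.integer(max_len),
       seed = as.integer(seed))
}

cg_init_params <- function(vocab_size, cfg) {
  m <- cfg$embed_size; h <- cfg$hidden_size; d <- cfg$latent_dim
  V <- vocab_size
  cg_with_seed(cfg$seed, list(
    enc_emb = cg_init_mat(V, m),
    enc_Wx = cg_init_mat(m, 3L * h),
    enc_Wh = cg_init_mat(h, 3L * h),
    enc_b = numeric(3L * h),
    W_mu = cg_init_mat(h, d), b_mu = numeric(d),
    W_lv = cg_init_mat(h, d), b_lv = numeric(d),
    dec_emb = cg_init_mat(V, m),
    dec_Wz = cg_init_mat(d, h), dec_bz = numeric(h),
    dec_Wx = cg_init_mat(m + d, 3L * h),
    dec_Wh = cg_init_mat(h, 3L * h),
    dec_b = numeric(3L * h),
    W_out = cg_init_mat(h, V), b_out = numeric(V)
  ))
}

# pad a list of index vectors into a B x T matrix
cg_pad_batch <- function(seqs) {
  Tmax <- max(lengths(seqs))
  out <- matrix(IDX_PAD, nrow = length(seqs), ncol = Tmax)
  for (i in seq_along(seqs)) out[i, seq_along(seqs[[i]])] <- seqs[[i]]
  out
}

# ---- encoder ----------------------------------------------------------------
# input: B x T index matrix of (tokens..., EOS, PAD...) -- BOS stripped

cg_encode_fwd <- function(params, X, want_cache = FALSE) {
  B <- nrow(X); Tm <- ncol(X)
  h <- matrix(0, B, ncol(params$enc_Wh) / 3L)
  caches <- if (want_cache) vector("list", Tm) else NULL
  for (t in seq_len(Tm)) {
    idx <- X[, t]
    mask <- as.numeric(idx != IDX_PAD)
    xe <- params$enc_emb[idx, , drop = FALSE]
    st <- cg_gru_fwd(xe, h, params$enc_Wx, params$enc_Wh, params$enc_b)
    hnew <- mask * st$h + (1 - mask) * h
    if (want_cache) caches[[t]] <- list(cache = st$cache, mask = mask, idx = idx)
    h <- hnew
  }
  lv_raw <- h %*% params$W_lv + rep(params$b_lv, each = B)
  lv <- pmin(pmax(lv_raw, -8), 8)
  list(mu = h %*% params$W_mu + rep(params$b_mu, each = B),
       lv = lv, lv_raw = lv_raw, hT = h, caches = caches, X = X)
}

cg_encode_bwd <- function(params, fwd, dmu, dlv) {
  B <- nrow(fwd$X)
  dlv <- dlv * (fwd$lv_raw > -8 & fwd$lv_raw < 8)
  g <- cg_zero_like(params[ENCODER_PARAM_NAMES])
  g$W_mu <- t(fwd$hT) %*% dmu
  g$b_mu <- colSums(dmu)
  g$W_lv <- t(fwd$hT) %*% dlv
  g$b_lv <- colSums(dlv)
  dh <- dmu %*% t(params$W_mu) + dlv %*% t(params$W_lv)
  for (t in rev(seq_along(fwd$caches))) {
    st <- fwd$caches[[t]]
    res <- cg_gru_bwd(dh * st$mask, st$cache, params$enc_Wx, params$enc_Wh)
    g$enc_Wx <- g$enc_Wx + res$dWx
    g$enc_Wh <- g$enc_Wh + res$dWh
    g$enc_b <- g$enc_b + res$db
    g$enc_emb <- cg_emb_accum(g$enc_emb, st$idx, res$dx * st$mask)
    dh <- dh * (1 - st$mask) + res$dhprev
  }
  g
}

# ---- decoder ----------------------------------------------------------------
# Y: B x T matrix of full sequences (BOS, tokens..., EOS, PAD...)

cg_decode_fwd <- function(params, z, Y, want_cache = FALSE) {
  B <- nrow(Y)
  if (is.null(dim(z))) z <- matrix(z, nrow = B, ncol = length(z), byrow = TRUE)
  if (ncol(z) != nrow(params$dec_Wz)) {
    stop("latent dimension mismatch", call. = FALSE)
  }
  Tm <- ncol(Y)
  a0 <- z %*% params$dec_Wz + rep(params$dec_bz, each = B)
  h <- tanh(a0)
  h0 <- h
  nll <- numeric(B)
  caches <- if (want_cache) vector("list", Tm - 1L) else NULL
  for (t in seq_len(Tm - 1L)) {
    inp <- Y[, t]; tgt <- Y[, t + 1L]
    mask <- as.numeric(tgt != IDX_PAD)
    xe <- cbind(params$dec_emb[inp, , drop = FALSE], z)
    st <- cg_gru_fwd(xe, h, params$dec_Wx, params$dec_Wh, params$dec_b)
    hnew <- mask * st$h + (1 - mask) * h
    logits <- hnew %*% params$W_out + rep(params$b_out, each = B)
    p <- cg_softmax(logits)
    pick <- p[cbind(seq_len(B), tgt)]
    nll <- nll - log(pmax(pick, 1e-12)) * mask
    if (want_cache) {
      caches[[t]] <- list(cache = st$cache, mask = mask, p = p, h = hnew,
                          inp = inp, tgt = tgt)
    }
    h <- hnew
  }
  list(nll = nll, caches = caches, h0 = h0, z = z)
}

# weights: per-sequence scalars multiplying each sequence's summed token NLL
cg_decode_bwd <- function(params, fwd, weights) {
  z <- fwd$z
  B <- nrow(z); d <- ncol(z); m <- ncol(params$dec_emb)
  g <- cg_zero_like(params[DECODER_PARAM_NAMES])
  dz <- matrix(0, B, d)
  dh <- matrix(0, B, ncol(params$dec_Wh) / 3L)
  for (t in rev(seq_along(fwd$caches))) {
    st <- fwd$caches[[t]]
    dlogits <- st$p
    dlogits[cbind(seq_len(B), st$tgt)] <-
      dlogits[cbind(seq_len(B), st$tgt)] - 1
    dlogits <- dlogits * (st$mask * weights)
    g$W_out <- g$W_out + t(st$h) %*% dlogits
    g$b_out <- g$b_out + colSums(dlogits)
    dh <- dh + dlogits %*% t(params$W_out)
    res <- cg_gru_bwd(dh * st$mask, st$cache, params$dec_Wx, params$dec_Wh)
    g$dec_Wx <- g$dec_Wx + res$dWx
    g$dec_Wh <- g$dec_Wh + res$dWh
    g$dec_b <- g$dec_b + res$db
    dx <- res$dx * st$mask
    g$dec_emb <- cg_emb_accum(g$dec_emb, st$inp, dx[, seq_len(m), drop = FALSE])
    dz <- dz + dx[, m + seq_len(d), drop = FALSE]
    dh <- dh * (1 - st$mask) + res$dhprev
  }
  da0 <- dh * (1 - fwd$h0^2)
  g$dec_Wz <- g$dec_Wz + t(z) %*% da0
  g$dec_bz <- g$dec_bz + colSums(da0)
  dz <- dz + da0 %*% t(params$dec_Wz)
  list(grads = g, dz = dz)
}

# autoregressive sampling; returns list(tokens = B x L matrix, text, valid)
cg_sample_decode <- function(params, z, vocab, max_len) {
  B <- nrow(z)
  a0 <- z %*% params$dec_Wz + rep(params$dec_bz, each = B)
  h <- tanh(a0)
  prev <- rep(IDX_BOS, B)
  finished <- rep(FALSE, B)
  toks <- matrix(IDX_PAD, B, max_len)
  for (t in seq_len(max_len)) {
    xe <- cbind(params$dec_emb[prev, , drop = FALSE], z)
    st <- cg_gru_fwd(xe, h, params$dec_Wx, params$dec_Wh, params$dec_b)
    h <- st$h
    logits <- h %*% params$W_out + rep(params$b_out, each = B)
    p <- cg_softmax(logits)
    u <- stats::runif(B)
    for (b in seq_len(B)) {
      if (finished[b]) next
      k <- 1L + sum(cumsum(p[b, ]) < u[b])
      toks[b, t] <- k
      if (k == IDX_EOS) finished[b] <- TRUE
    }
    prev <- ifelse(finished, IDX_PAD, toks[, t])
    prev[prev == IDX_PAD] <- IDX_PAD
    if (all(finished)) break
  }
  text <- vapply(seq_len(B), function(b) decode_indices(toks[b, ], vocab),
                 character(1))
  list(tokens = toks, text = text)
}

# ---- exported model operations ---------------------------------------------

#' Initialize an untrained model
#'
#' @param vocab a `cg_vocab`.
#' @param config a [contragen_config()] list.
#' @return an object of class `contragen` (untrained).
#' @export
contragen_init <- function(vocab, config = contragen_config()) {
  stopifnot(inherits(vocab, "cg_vocab"))
  structure(list(
    params = cg_init_params(length(vocab), config),
    vocab = vocab,
    config = config,
    metric_history = NULL,
    rl_history = NULL
  ), class = "contragen")
}

cg_encode_batch_idx <- function(model, smiles) {
  lapply(smiles, function(s) {
    idx <- encode_smiles(s, model$vocab, model$config$max_len)
    idx[-1L]  # encoder consumes tokens + EOS (no BOS)
  })
}

#' Encode SMILES into latent Gaussians
#'
#' Deterministically maps each sequence to the mean and (strictly positive,
#' via an exponential transform) diagonal variance of its latent Gaussian.
#'
#' @param model a `contragen` model.
#' @param smiles character vector of SMILES.
#' @return object of class `cg_latent`: list with matrices `mean` and
#'   `variance` (rows = molecules).
#' @export
encode_latent <- function(model, smiles) {
  stopifnot(inherits(model, "contragen"), length(smiles) >= 1L)
  if (any(!nzchar(smiles))) stop("empty sequence", call. = FALSE)
  X <- cg_pad_batch(cg_encode_batch_idx(model, smiles))
  fwd <- cg_encode_fwd(model$params, X)
  structure(list(mean = fwd$mu, variance = exp(fwd$lv)), class = "cg_latent")
}

#' @export
print.cg_latent <- function(x, ...) {
  cat(sprintf("<latent Gaussian: %d molecule(s), dimension %d>\n",
              nrow(x$mean), ncol(x$mean)))
  invisible(x)
}

#' Reparameterized latent sample
#'
#' Draws `mean + sqrt(variance) * eps` with standard-normal `eps`, one draw
#' per row of the Gaussian.
#'
#' @param g a `cg_latent`.
#' @param seed optional seed for a reproducible draw.
#' @return matrix of samples (rows = molecules).
#' @export
sample_latent <- function(g, seed = NULL) {
  stopifnot(inherits(g, "cg_latent"))
  draw <- function() {
    eps <- matrix(stats::rnorm(length(g$mean)), nrow(g$mean), ncol(g$mean))
    g$mean + sqrt(g$variance) * eps
  }
  if (is.null(seed)) draw() else cg_with_seed(seed, draw())
}

#' Teacher-forced decoder negative log-likelihood
#'
#' Summed token NLL of each sequence given its latent vector.
#'
#' @param model a `contragen` model.
#' @param z latent matrix (rows = sequences) or a single latent vector.
#' @param smiles character vector of sequences to score.
#' @return numeric vector of per-sequence NLLs (>= 0).
#' @export
decode_nll <- function(model, z, smiles) {
  stopifnot(inherits(model, "contragen"))
  if (is.null(dim(z))) z <- matrix(z, nrow = length(smiles),
                                   ncol = length(z), byrow = TRUE)
  if (ncol(z) != model$config$latent_dim) {
    stop("latent dimension mismatch", call. = FALSE)
  }
  Y <- cg_pad_batch(lapply(smiles, encode_smiles, vocab = model$vocab,
                           max_len = model$config$max_len))
  cg_decode_fwd(model$params, z, Y)$nll
}

#' Generate SMILES text from latent vectors
#'
#' Autoregressive multinomial sampling from the decoder until `<eos>` or
#' `max_len`. Output validity is NOT guaranteed; the `"valid"` attribute
#' flags outputs that canonicalize.
#'
#' @param model a `contragen` model.
#' @param z latent matrix (rows = draws) or single latent vector.
#' @param seed optional seed.
#' @param max_len maximum generated length.
#' @return character vector with attribute `valid` (logical).
#' @export
generate_smiles <- function(model, z, seed = NULL,
                            max_len = model$config$max_len) {
  stopifnot(inherits(model, "contragen"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != model$config$latent_dim) {
    stop("latent dimension mismatch", call. = FALSE)
  }
  res <- if (is.null(seed)) {
    cg_sample_decode(model$params, z, model$vocab, max_len)
  } else {
    cg_with_seed(seed, cg_sample_decode(model$params, z, model$vocab, max_len))
  }
  structure(res$text, valid = smiles_is_valid(res$text))
}

#' Structure-constrained translation of a source molecule
#'
#' Encodes the source, draws `k` latent samples, and decodes each: the
#' 20-samples-per-source generation protocol.
#'
#' @param model a trained `contragen` model.
#' @param source a single valid SMILES string.
#' @param k number of generated molecules (default 20).
#' @param seed optional seed.
#' @return character vector of length `k` with attribute `valid`.
#' @export
translate_smiles <- function(model, source, k = 20L, seed = NULL) {
  stopifnot(inherits(model, "contragen"), length(source) == 1L)
  if (!smiles_is_valid(source)) stop("invalid source SMILES: ", source,
                                     call. = FALSE)
  g <- encode_latent(model, source)
  gk <- structure(list(
    mean = g$mean[rep(1L, k), , drop = FALSE],
    variance = g$variance[rep(1L, k), , drop = FALSE]
  ), class = "cg_latent")
  run <- function() {
    z <- sample_latent(gk)
    generate_smiles(model, z)
  }
  if (is.null(seed)) run() else cg_with_seed(seed, run())
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single archive holding the parameters, vocabulary,
#' configuration snapshot and training histories; encode/decode behaviour is
#' bit-identical after a round trip.
#'
#' @param model a `contragen` model.
#' @param path checkpoint file path.
#' @export
save_contragen <- function(model, path) {
  stopifnot(inherits(model, "contragen"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_contragen
#' @export
load_contragen <- function(path) {
  obj <- readRDS(path)
  stopifnot(is.list(obj), !is.null(obj$params), !is.null(obj$vocab))
  structure(obj, class = "contragen")
}
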