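# Metric-learning objective: reconstruction + contractive + margin losses
# over (source, target, negative) triplets.

#' Contractive loss: Fréchet distance between diagonal latent Gaussians
#'
#' For Gaussians with means \eqn{\mu_a, \mu_b} and diagonal covariances, the
#' Fréchet (2-Wasserstein) distance
#' \deqn{\|\mu_a-\mu_b\|^2 + tr[\Sigma_a + \Sigma_b - 2(\Sigma_a\Sigma_b)^{1/2}]}
#' reduces to
#' \eqn{\|\mu_a-\mu_b\|^2 + \sum_i(\sqrt{\sigma_{a,i}}-\sqrt{\sigma_{b,i}})^2}
#' because diagonal matrices commute. Symmetric, non-negative, zero iff the
#' Gaussians coincide. Used to pull a similar source/target pair onto the
#' same latent position.
#'
#' @param a,b `cg_latent` objects with matching dimensions (and matching row
#'   counts, or one row recycled).
#' @return numeric vector of per-row losses.
#' @export
contractive_loss <- function(a, b) {
  stopifnot(inherits(a, "cg_latent"), inherits(b, "cg_latent"))
  if (ncol(a$mean) != ncol(b$mean)) {
    stop("latent dimension mismatch", call. = FALSE)
  }
  if (nrow(a$mean) != nrow(b$mean)) {
    if (nrow(a$mean) == 1L) {
      a <- structure(list(mean = a$mean[rep(1, nrow(b$mean)), , drop = FALSE],
                          variance = a$variance[rep(1, nrow(b$mean)), ,
                                                drop = FALSE]),
                     class = "cg_latent")
    } else if (nrow(b$mean) == 1L) {
      return(contractive_loss(b, a))
    } else stop("row counts differ", call. = FALSE)
  }
  rowSums((a$mean - b$mean)^2) +
    rowSums((sqrt(a$variance) - sqrt(b$variance))^2)
}

#' Margin loss: softplus repulsion of dissimilar latent means
#'
#' \deqn{softplus(1 - \|\mu_a - \mu_b\|^2)}
#' Strictly decreasing in the squared distance; bounded below by 0 (limit at
#' infinite distance) and above by `softplus(1)` at distance 0, which keeps
#' dissimilar molecules apart without spreading the latent space without
#' bound.
#'
#' @param mu_a,mu_b numeric vectors or matrices (rows = observations).
#' @return numeric vector of per-row losses, each in `(0, softplus(1)]`.
#' @export
margin_loss <- function(mu_a, mu_b) {
  if (is.null(dim(mu_a))) mu_a <- matrix(mu_a, nrow = 1L)
  if (is.null(dim(mu_b))) mu_b <- matrix(mu_b, nrow = 1L)
  if (ncol(mu_a) != ncol(mu_b)) stop("dimension mismatch", call. = FALSE)
  softplus(1 - rowSums((mu_a - mu_b)^2))
}

# forward (+ optional backward) pass of the triplet objective on one batch.
# seqs: list(source=, target=, negative=) of character vectors.
cg_metric_batch <- function(params, model, seqs, use_contractive = TRUE,
                            use_margin = TRUE, want_grad = TRUE) {
  roles <- c("source", "target", "negative")
  B <- length(seqs$source)
  d <- model$config$latent_dim
  enc <- list(); dec <- list(); mu <- list(); sd <- list(); eps <- list()
  Y <- list()
  for (r in roles) {
    Xenc <- cg_pad_batch(cg_encode_batch_idx(model, seqs[[r]]))
    Y[[r]] <- cg_pad_batch(lapply(seqs[[r]], encode_smiles,
                                  vocab = model$vocab,
                                  max_len = model$config$max_len))
    enc[[r]] <- cg_encode_fwd(params, Xenc, want_cache = want_grad)
    mu[[r]] <- enc[[r]]$mu
    sd[[r]] <- exp(enc[[r]]$lv / 2)
    eps[[r]] <- matrix(stats::rnorm(B * d), B, d)
    z <- mu[[r]] + sd[[r]] * eps[[r]]
    dec[[r]] <- cg_decode_fwd(params, z, Y[[r]], want_cache = want_grad)
  }
  recon_vec <- dec$source$nll + dec$target$nll + dec$negative$nll
  contr_vec <- rowSums((mu$target - mu$source)^2) +
    rowSums((sd$target - sd$source)^2)
  marg_vec <- softplus(1 - rowSums((mu$target - mu$negative)^2)) +
    softplus(1 - rowSums((mu$source - mu$negative)^2))
  loss <- list(reconstruction = mean(recon_vec),
               contractive = mean(contr_vec),
               margin = mean(marg_vec))
  loss$total <- loss$reconstruction +
    (if (use_contractive) loss$contractive else 0) +
    (if (use_margin) loss$margin else 0)
  if (!want_grad) return(list(loss = loss))

  grads <- cg_zero_like(params)
  dmu <- stats::setNames(lapply(roles, function(r) matrix(0, B, d)), roles)
  dlv <- stats::setNames(lapply(roles, function(r) matrix(0, B, d)), roles)
  w <- rep(1 / B, B)
  for (r in roles) {
    bwd <- cg_decode_bwd(params, dec[[r]], w)
    grads <- cg_axpy(grads, bwd$grads)
    dmu[[r]] <- dmu[[r]] + bwd$dz
    dlv[[r]] <- dlv[[r]] + bwd$dz * eps[[r]] * 0.5 * sd[[r]]
  }
  if (use_contractive) {
    dmu$target <- dmu$target + 2 * (mu$target - mu$source) / B
    dmu$source <- dmu$source - 2 * (mu$target - mu$source) / B
    dlv$target <- dlv$target + (sd$target - sd$source) * sd$target / B
    dlv$source <- dlv$source - (sd$target - sd$source) * sd$source / B
  }
  if (use_margin) {
    for (pair in list(c("target", "negative"), c("source", "negative"))) {
      a <- pair[1]; b <- pair[2]
      diff <- mu[[a]] - mu[[b]]
      sgrad <- cg_sigmoid(1 - rowSums(diff^2))
      dmu[[a]] <- dmu[[a]] - 2 * sgrad * diff / B
      dmu[[b]] <- dmu[[b]] + 2 * sgrad * diff / B
    }
  }
  for (r in roles) {
    grads <- cg_axpy(grads, cg_encode_bwd(params, enc[[r]], dmu[[r]],
                                          dlv[[r]]))
  }
  list(loss = loss, grads = grads)
}

#' Triplet metric-learning objective
#'
#' Evaluates the full objective on one (source, target, negative) triplet:
#' the summed reconstruction NLL of all three strings from their own sampled
#' latents, the contractive loss between target and source Gaussians, and
#' the margin losses pushing the negative away from both pair members.
#'
#' @param model a `contragen` model.
#' @param triplet list or one-row data.frame with `source`, `target`,
#'   `negative`.
#' @param seed optional seed for the latent draws.
#' @return list of class `cg_loss_breakdown` with elements `reconstruction`,
#'   `contractive`, `margin`, `total` (= their sum).
#' @export
metric_objective <- function(model, triplet, seed = NULL) {
  stopifnot(inherits(model, "contragen"))
  seqs <- list(source = as.character(triplet$source),
               target = as.character(triplet$target),
               negative = as.character(triplet$negative))
  run <- function() cg_metric_batch(model$params, model, seqs,
                                    want_grad = FALSE)$loss
  loss <- if (is.null(seed)) run() else cg_with_seed(seed, run())
  structure(loss, class = "cg_loss_breakdown")
}

#' @export
print.cg_loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "loss: total %.4f (reconstruction %.4f + contractive %.4f + margin %.4f)\n",
    x$total, x$reconstruction, x$contractive, x$margin))
  invisible(x)
}

#' Metric-learning training phase
#'
#' Minibatch Adam on the triplet objective. Per-epoch means of the loss
#' components are appended to the model's `metric_history`; the run is
#' deterministic for a fixed seed on a single CPU thread. Either
#' regularization term can be ablated.
#'
#' @param model a `contragen` model.
#' @param triplets data.frame with columns source, target, negative.
#' @param epochs training epochs (0 leaves the parameters untouched).
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed RNG seed for shuffling and latent draws.
#' @param use_contractive,use_margin include each regularization term.
#' @param verbose print per-epoch losses.
#' @return the updated model.
#' @export
train_metric_phase <- function(model, triplets, epochs = 30L,
                               batch_size = 32L, learning_rate = 5e-3,
                               seed = 1L, use_contractive = TRUE,
                               use_margin = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "contragen"), is.data.frame(triplets),
            nrow(triplets) >= 1L)
  if (epochs == 0L) return(model)
  params <- model$params
  adam <- cg_adam_init(params)
  n <- nrow(triplets)
  hist <- vector("list", epochs)
  cg_with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      sums <- c(reconstruction = 0, contractive = 0, margin = 0, total = 0)
      nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        seqs <- list(source = triplets$source[idx],
                     target = triplets$target[idx],
                     negative = triplets$negative[idx])
        step <- cg_metric_batch(params, model, seqs, use_contractive,
                                use_margin, want_grad = TRUE)
        if (!is.finite(step$loss$total)) {
          stop(sprintf("metric training diverged at epoch %d (total=%g)",
                       ep, step$loss$total), call. = FALSE)
        }
        upd <- cg_adam_step(params, step$grads, adam, learning_rate)
        params <- upd$params; adam <- upd$state
        sums <- sums + unlist(step$loss)
        nb <- nb + 1L
      }
      hist[[ep]] <- as.list(sums / nb)
      if (verbose) {
        message(sprintf(
          "epoch %d: total %.3f (recon %.3f, contractive %.3f, margin %.3f)",
          ep, hist[[ep]]$total, hist[[ep]]$reconstruction,
          hist[[ep]]$contractive, hist[[ep]]$margin))
      }
    }
  })
  hdf <- do.call(rbind, lapply(seq_len(epochs), function(ep) {
    data.frame(epoch = ep, reconstruction = hist[[ep]]$reconstruction,
               contractive = hist[[ep]]$contractive,
               margin = hist[[ep]]$margin, total = hist[[ep]]$total)
  }))
  model$params <- params
  model$metric_history <- rbind(model$metric_history, hdf)
  model
}

#' Fit a structure-constrained generator
#'
#' The model-fitting front end: builds the vocabulary from the corpus,
#' constructs metric-learning triplets from the (source, target) pairs, and
#' runs the metric-learning phase. Reinforcement-learning fine-tuning is a
#' separate second phase ([train_rl_phase()]).
#'
#' @param pairs data.frame with columns `source`, `target` (or a path to a
#'   two-column TSV).
#' @param negatives_pool candidate negatives (default: the pair molecules).
#' @param config model hyperparameters ([contragen_config()]).
#' @param epochs,batch_size,learning_rate metric-phase settings.
#' @param negative_threshold triplet dissimilarity cut (default 0.4).
#' @param seed seed governing triplet sampling, initialization and training.
#' @param use_contractive,use_margin ablation switches for the two
#'   regularization terms.
#' @param verbose print training progress.
#' @return a fitted `contragen` object. Component `train_smiles` holds the
#'   canonical training molecules (the novelty reference set).
#' @export
contragen <- function(pairs, negatives_pool = NULL,
                      config = contragen_config(), epochs = 30L,
                      batch_size = 32L, learning_rate = 5e-3,
                      negative_threshold = 0.4, seed = 1L,
                      use_contractive = TRUE, use_margin = TRUE,
                      verbose = FALSE) {
  if (is.character(pairs)) pairs <- load_pairs(pairs)
  stopifnot(is.data.frame(pairs), all(c("source", "target") %in% names(pairs)))
  config$seed <- as.integer(seed)
  triplets <- build_triplets(pairs, pool = negatives_pool,
                             negative_threshold = negative_threshold,
                             seed = seed)
  corpus <- unique(c(triplets$source, triplets$target, triplets$negative,
                     negatives_pool))
  vocab <- build_vocab(corpus)
  model <- contragen_init(vocab, config)
  model$train_smiles <- unique(canonicalize_smiles(
    c(pairs$source, pairs$target)))
  model$triplets <- triplets
  train_metric_phase(model, triplets, epochs = epochs,
                     batch_size = batch_size,
                     learning_rate = learning_rate, seed = seed,
                     use_contractive = use_contractive,
                     use_margin = use_margin, verbose = verbose)
}

#' Classic metric-learning comparison losses
#'
#' Reference implementations of the two traditional metric-learning terms
#' (not used by the model's objective): the triplet hinge loss
#' `max(0, ||a-p||^2 - ||a-n||^2 + margin)` and the contrastive pair loss
#' (`||a-b||^2` for similar pairs, `max(0, margin - ||a-b||)^2` for
#' dissimilar ones).
#'
#' @param mu_a,mu_p,mu_n,mu_b latent mean vectors or matrices.
#' @param margin margin constant (default 1).
#' @return numeric vector of per-row losses.
#' @export
triplet_hinge_loss <- function(mu_a, mu_p, mu_n, margin = 1) {
  if (is.null(dim(mu_a))) { mu_a <- rbind(mu_a); mu_p <- rbind(mu_p)
    mu_n <- rbind(mu_n) }
  pmax(0, rowSums((mu_a - mu_p)^2) - rowSums((mu_a - mu_n)^2) + margin)
}

#' @rdname triplet_hinge_loss
#' @param similar logical: is the pair similar?
#' @export
contrastive_pair_loss <- function(mu_a, mu_b, similar, margin = 1) {
  if (is.null(dim(mu_a))) { mu_a <- rbind(mu_a); mu_b <- rbind(mu_b) }
  dist <- sqrt(rowSums((mu_a - mu_b)^2))
  ifelse(similar, dist^2, pmax(0, margin - dist)^2)
}
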