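# Similarity-gated property rewards and REINFORCE fine-tuning of the
# decoder. The encoder is frozen by contract: gradients are computed for
# decoder parameters only.

#' Construct a reward configuration
#'
#' Rewards are gated by Tanimoto similarity (`T(x_hat, x) > epsilon`,
#' strictly) and scale the property score into `[0, 1]`:
#' \describe{
#'   \item{increase}{`max(0, (phi(x_hat) - delta) / (1 - delta))` — push a
#'     bounded property above threshold `delta`.}
#'   \item{improvement}{`max(0, (phi(x_hat) - phi(x) - delta) / (1 - delta))`
#'     — reward the gain over the source (can exceed 1 for unbounded
#'     properties).}
#'   \item{decrease}{`max(0, (delta - phi(x_hat)) / delta)` — push the
#'     property below `delta`.}
#' }
#' An optional auxiliary oracle adds the hard constraint
#' `aux_oracle(x_hat) > aux_min` (e.g. retained affinity for the primary
#' kinase target while the anti-target affinity is reduced).
#'
#' @param direction one of `"increase"`, `"improvement"`, `"decrease"`.
#' @param delta property threshold (must be `< 1` for increase, `> 0` for
#'   decrease).
#' @param epsilon similarity threshold in `[0, 1]`.
#' @param oracle the property oracle (`cg_oracle`).
#' @param aux_oracle,aux_min optional auxiliary constraint.
#' @return object of class `cg_reward_config`.
#' @export
make_reward_config <- function(direction, delta, epsilon, oracle = NULL,
                               aux_oracle = NULL, aux_min = NULL) {
  direction <- match.arg(direction, c("increase", "improvement", "decrease"))
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0,1]",
                                       call. = FALSE)
  if (direction == "decrease" && delta <= 0) {
    stop("direction=decrease needs delta > 0", call. = FALSE)
  }
  if (direction == "increase" && delta >= 1) {
    stop("direction=increase needs delta < 1", call. = FALSE)
  }
  if (!is.null(aux_oracle) && is.null(aux_min)) {
    stop("aux_oracle needs aux_min", call. = FALSE)
  }
  structure(list(direction = direction, delta = delta, epsilon = epsilon,
                 oracle = oracle, aux_oracle = aux_oracle,
                 aux_min = aux_min),
            class = "cg_reward_config")
}

#' @export
print.cg_reward_config <- function(x, ...) {
  cat(sprintf("<reward: %s, delta=%g, epsilon=%g%s%s>\n", x$direction,
              x$delta, x$epsilon,
              if (is.null(x$oracle)) ", oracle unset" else
                sprintf(", oracle '%s'", x$oracle$name),
              if (is.null(x$aux_oracle)) "" else
                sprintf(", aux > %g", x$aux_min)))
  invisible(x)
}

#' Benchmark task reward configurations
#'
#' The published per-task thresholds: DRD2 (increase, delta 0, epsilon 0.3),
#' QED (increase, delta 0.75, epsilon 0.3), pLogP04 (improvement, delta 0,
#' epsilon 0.3), pLogP06 (improvement, delta 0, epsilon 0.5), and the
#' sorafenib/ABCG2 task (decrease, delta 4.989, epsilon 0.4, with the
#' auxiliary constraint that predicted BRAF affinity stays above 6.235 —
#' both thresholds being sorafenib's own predicted affinities).
#'
#' QED and pLogP tasks get their oracles automatically; DRD2 and ABCG2
#' depend on external activity/affinity predictors, so their oracles (and
#' the ABCG2 task's auxiliary BRAF oracle) must be supplied — typically as
#' tabulated or external-command oracles.
#'
#' @param task one of `"drd2"`, `"qed"`, `"plogp04"`, `"plogp06"`,
#'   `"abcg2"`.
#' @param oracle property oracle override (required for drd2/abcg2).
#' @param aux_oracle auxiliary oracle (abcg2: BRAF affinity).
#' @return a `cg_reward_config`.
#' @export
task_reward_config <- function(task, oracle = NULL, aux_oracle = NULL) {
  task <- match.arg(task, c("drd2", "qed", "plogp04", "plogp06", "abcg2"))
  switch(task,
    drd2 = make_reward_config("increase", delta = 0, epsilon = 0.3,
                              oracle = oracle),
    qed = make_reward_config("increase", delta = 0.75, epsilon = 0.3,
                             oracle = if (is.null(oracle))
                               make_oracle("qed") else oracle),
    plogp04 = make_reward_config("improvement", delta = 0, epsilon = 0.3,
                                 oracle = if (is.null(oracle))
                                   make_oracle("plogp") else oracle),
    plogp06 = make_reward_config("improvement", delta = 0, epsilon = 0.5,
                                 oracle = if (is.null(oracle))
                                   make_oracle("plogp") else oracle),
    abcg2 = make_reward_config("decrease", delta = 4.989, epsilon = 0.4,
                               oracle = oracle, aux_oracle = aux_oracle,
                               aux_min = 6.235)
  )
}

#' Piecewise reward kernel
#'
#' The pure arithmetic of the reward, exposed so boundary behaviour can be
#' examined directly: given property scores and a similarity value, applies
#' the direction-specific scaling and the strict similarity gate
#' (`sim > epsilon`), plus the auxiliary constraint when `aux` is supplied.
#'
#' @param phi property score(s) of the generated molecule(s).
#' @param sim Tanimoto similarity to the source.
#' @param cfg a `cg_reward_config`.
#' @param phi_source source property score (required for
#'   `direction = "improvement"`).
#' @param aux auxiliary oracle score(s), when the config has an auxiliary
#'   constraint.
#' @return numeric reward(s).
#' @export
reward_kernel <- function(phi, sim, cfg, phi_source = NULL, aux = NULL) {
  stopifnot(inherits(cfg, "cg_reward_config"))
  r <- switch(cfg$direction,
    increase = pmax(0, (phi - cfg$delta) / (1 - cfg$delta)),
    improvement = {
      if (is.null(phi_source)) {
        stop("improvement direction needs phi_source", call. = FALSE)
      }
      pmax(0, ((phi - phi_source) - cfg$delta) / (1 - cfg$delta))
    },
    decrease = pmax(0, (cfg$delta - phi) / cfg$delta)
  )
  r <- r * as.numeric(sim > cfg$epsilon)
  if (!is.null(cfg$aux_oracle) || !is.null(aux)) {
    if (is.null(aux)) stop("config has an auxiliary constraint: supply aux",
                           call. = FALSE)
    r <- r * as.numeric(aux > cfg$aux_min)
  }
  r
}

#' Similarity-gated property reward
#'
#' Scores generated molecules against their source under a reward
#' configuration. Invalid generated SMILES receive reward 0 (they can be
#' neither scored nor compared); the similarity gate is strict
#' (`T <= epsilon` gives 0); the auxiliary constraint, when configured,
#' zeroes the reward unless `aux_oracle(x_hat) > aux_min`.
#'
#' @param x_hat character vector of generated SMILES (any text).
#' @param x the source molecule (single valid SMILES).
#' @param cfg a `cg_reward_config` with its oracle set.
#' @return numeric vector of rewards.
#' @export
reward <- function(x_hat, x, cfg) {
  stopifnot(inherits(cfg, "cg_reward_config"), length(x) == 1L)
  if (is.null(cfg$oracle)) stop("reward config has no oracle", call. = FALSE)
  if (!smiles_is_valid(x)) stop("invalid source SMILES: ", x, call. = FALSE)
  out <- numeric(length(x_hat))
  valid <- smiles_is_valid(x_hat)
  if (!any(valid)) return(out)
  idx <- which(valid)
  sims <- tanimoto_smiles(x, x_hat[idx])
  gate <- sims > cfg$epsilon
  live <- idx[gate]
  if (!length(live)) return(out)
  phi <- oracle_score(cfg$oracle, x_hat[live])
  phi_x <- if (cfg$direction == "improvement") {
    oracle_score(cfg$oracle, x)
  } else NULL
  aux <- if (!is.null(cfg$aux_oracle)) {
    oracle_score(cfg$aux_oracle, x_hat[live])
  } else NULL
  out[live] <- reward_kernel(phi, sims[gate], cfg, phi_source = phi_x,
                             aux = aux)
  out
}

# The policy-gradient estimator: for each source, sample z from the frozen
# encoder, sample x_hat from the decoder, and accumulate
# -R(x_hat, x) * grad log p(x_hat | z) over DECODER parameters only.
# Returns the decoder gradient of the batch-mean objective.
cg_reinforce_grad <- function(model, sources, cfg,
                              samples_per_source = 1L,
                              max_len = model$config$max_len) {
  params <- model$params
  B0 <- length(sources)
  g <- encode_latent(model, sources)
  rep_idx <- rep(seq_len(B0), each = samples_per_source)
  gk <- structure(list(mean = g$mean[rep_idx, , drop = FALSE],
                       variance = g$variance[rep_idx, , drop = FALSE]),
                  class = "cg_latent")
  z <- sample_latent(gk)
  res <- cg_sample_decode(params, z, model$vocab, max_len)
  B <- nrow(z)
  rewards <- numeric(B)
  for (i in seq_len(B0)) {
    rows <- which(rep_idx == i)
    rewards[rows] <- reward(res$text[rows], sources[i], cfg)
  }
  grads <- cg_zero_like(params[DECODER_PARAM_NAMES])
  if (any(rewards != 0)) {
    # teacher-force the decoder on its own sampled sequences
    seqs <- lapply(seq_len(B), function(b) {
      toks <- res$tokens[b, ]
      eos <- which(toks == IDX_EOS)
      keep <- if (length(eos)) toks[seq_len(eos[1])] else toks[toks != IDX_PAD]
      c(IDX_BOS, keep)
    })
    Y <- cg_pad_batch(seqs)
    fwd <- cg_decode_fwd(params, z, Y, want_cache = TRUE)
    grads <- cg_decode_bwd(params, fwd, rewards / B)$grads
  }
  list(grads = grads, rewards = rewards, outputs = res$text)
}

#' One REINFORCE update of the decoder
#'
#' Samples one episode per source (a translation of the source through the
#' frozen encoder and the stochastic decoder), scores it with the reward,
#' and applies a plain gradient step `psi <- psi - lr * grad` to the decoder
#' parameters. Encoder parameters are bit-identical before and after.
#'
#' @param model a metric-phase-trained `contragen` model.
#' @param sources character vector of source SMILES.
#' @param cfg a `cg_reward_config`.
#' @param lr gradient step size.
#' @param seed optional seed for the episode sampling.
#' @param samples_per_source episodes per source (default 1).
#' @param max_len episode length cap (defaults to the model's `max_len`).
#' @return list with the updated `model`, `mean_reward`, and the sampled
#'   `outputs`.
#' @export
reinforce_step <- function(model, sources, cfg, lr = 0.05, seed = NULL,
                           samples_per_source = 1L,
                           max_len = model$config$max_len) {
  stopifnot(inherits(model, "contragen"))
  run <- function() cg_reinforce_grad(model, sources, cfg,
                                      samples_per_source, max_len)
  est <- if (is.null(seed)) run() else cg_with_seed(seed, run())
  for (nm in DECODER_PARAM_NAMES) {
    model$params[[nm]] <- model$params[[nm]] - lr * est$grads[[nm]]
  }
  list(model = model, mean_reward = mean(est$rewards), outputs = est$outputs)
}

#' Reinforcement-learning fine-tuning phase
#'
#' Iterates the REINFORCE estimator over minibatches of source molecules
#' with Adam on the decoder parameters, logging the mean reward per epoch
#' to the model's `rl_history`. Deterministic for a fixed seed.
#'
#' @param model a metric-phase-trained `contragen` model.
#' @param sources character vector of source SMILES.
#' @param cfg a `cg_reward_config`.
#' @param epochs RL epochs (0 leaves the model untouched).
#' @param batch_size sources per update.
#' @param learning_rate Adam step size.
#' @param seed RNG seed.
#' @param samples_per_source episodes per source per update.
#' @param verbose print per-epoch mean rewards.
#' @return the updated model.
#' @export
train_rl_phase <- function(model, sources, cfg, epochs = 20L,
                           batch_size = 32L, learning_rate = 2e-3,
                           seed = 1L, samples_per_source = 1L,
                           verbose = FALSE) {
  stopifnot(inherits(model, "contragen"), length(sources) >= 1L)
  if (epochs == 0L) return(model)
  params <- model$params
  adam <- cg_adam_init(params[DECODER_PARAM_NAMES])
  n <- length(sources)
  hist <- numeric(epochs)
  cg_with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      rsum <- 0; nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        est <- cg_reinforce_grad(model, sources[idx], cfg,
                                 samples_per_source)
        if (any(!vapply(est$grads, function(x) all(is.finite(x)),
                        logical(1)))) {
          stop(sprintf("RL training diverged at epoch %d", ep),
               call. = FALSE)
        }
        upd <- cg_adam_step(params[DECODER_PARAM_NAMES], est$grads, adam,
                            learning_rate)
        params[DECODER_PARAM_NAMES] <- upd$params
        model$params <- params
        adam <- upd$state
        rsum <- rsum + mean(est$rewards); nb <- nb + 1L
      }
      hist[ep] <- rsum / nb
      if (verbose) message(sprintf("RL epoch %d: mean reward %.4f", ep,
                                   hist[ep]))
    }
  })
  model$rl_history <- rbind(model$rl_history,
                            data.frame(epoch = seq_len(epochs),
                                       mean_reward = hist))
  model
}
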