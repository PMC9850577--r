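# S3 methods for the fitted model object.

#' @export
print.contragen <- function(x, ...) {
  cfg <- x$config
  cat("Structure-constrained molecular generator (sequence VAE)\n")
  cat(sprintf("  vocabulary: %d tokens; latent %d, hidden %d, embedding %d\n",
              length(x$vocab), cfg$latent_dim, cfg$hidden_size,
              cfg$embed_size))
  cat(sprintf("  metric phase: %s; RL phase: %s\n",
              if (is.null(x$metric_history)) "untrained" else
                sprintf("%d epochs (final total loss %.3f)",
                        max(x$metric_history$epoch),
                        utils::tail(x$metric_history$total, 1)),
              if (is.null(x$rl_history)) "untrained" else
                sprintf("%d epochs (final mean reward %.3f)",
                        max(x$rl_history$epoch),
                        utils::tail(x$rl_history$mean_reward, 1))))
  invisible(x)
}

#' @export
summary.contragen <- function(object, ...) {
  n_par <- sum(vapply(object$params, length, integer(1)))
  out <- list(
    config = object$config,
    n_parameters = n_par,
    vocab_size = length(object$vocab),
    metric_history = object$metric_history,
    rl_history = object$rl_history,
    n_train_smiles = length(object$train_smiles)
  )
  class(out) <- "summary.contragen"
  out
}

#' @export
print.summary.contragen <- function(x, ...) {
  cat(sprintf(
    "sequence VAE: %d parameters, vocabulary %d, latent dim %d\n",
    x$n_parameters, x$vocab_size, x$config$latent_dim))
  cat(sprintf("training molecules: %d\n", x$n_train_smiles))
  if (!is.null(x$metric_history)) {
    h <- x$metric_history
    cat(sprintf(
      "metric phase: %d epochs, total loss %.3f -> %.3f\n",
      max(h$epoch), h$total[1], utils::tail(h$total, 1)))
  }
  if (!is.null(x$rl_history)) {
    h <- x$rl_history
    cat(sprintf("RL phase: %d epochs, mean reward %.4f -> %.4f\n",
                max(h$epoch), h$mean_reward[1],
                utils::tail(h$mean_reward, 1)))
  }
  invisible(x)
}

#' @export
coef.contragen <- function(object, ...) {
  object$params
}

#' Predict from a fitted generator
#'
#' `type = "latent"` returns the latent mean vectors of `newdata` (one row
#' per molecule); `type = "translate"` returns `k` sampled translations per
#' source as a list of character vectors.
#'
#' @param object a `contragen` model.
#' @param newdata character vector of SMILES.
#' @param type `"latent"` or `"translate"`.
#' @param k translations per source (default 20).
#' @param seed optional seed.
#' @param ... unused.
#' @export
predict.contragen <- function(object, newdata, type = c("latent", "translate"),
                              k = 20L, seed = NULL, ...) {
  type <- match.arg(type)
  if (type == "latent") {
    g <- encode_latent(object, newdata)
    rownames(g$mean) <- newdata
    return(g$mean)
  }
  run <- function() {
    stats::setNames(lapply(newdata, function(s) {
      translate_smiles(object, s, k = k)
    }), newdata)
  }
  if (is.null(seed)) run() else cg_with_seed(seed, run())
}

#' Simulate generations from the fitted model
#'
#' Draws `nsim` molecules for each source in `newdata` (the generation
#' protocol), returning a list of generation sets.
#'
#' @param object a `contragen` model.
#' @param nsim generated molecules per source.
#' @param seed optional seed.
#' @param newdata character vector of source SMILES.
#' @param ... unused.
#' @export
simulate.contragen <- function(object, nsim = 20L, seed = NULL,
                               newdata, ...) {
  generate_sets(object, newdata, k = nsim, seed = seed)
}

#' Plot training histories
#'
#' Loss components of the metric phase and, when present, the mean reward
#' of the RL phase.
#'
#' @param x a `contragen` model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.contragen <- function(x, ...) {
  h <- x$metric_history
  if (is.null(h)) stop("model has no training history", call. = FALSE)
  has_rl <- !is.null(x$rl_history)
  if (has_rl) {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old), add = TRUE)
  }
  graphics::matplot(h$epoch, h[, c("reconstruction", "contractive",
                                   "margin", "total")],
                    type = "l", lty = 1, lwd = 2,
                    col = c("#1b9e77", "#d95f02", "#7570b3", "black"),
                    xlab = "epoch", ylab = "loss",
                    main = "metric-learning phase", ...)
  graphics::legend("topright", c("reconstruction", "contractive", "margin",
                                 "total"),
                   col = c("#1b9e77", "#d95f02", "#7570b3", "black"),
                   lty = 1, lwd = 2, bty = "n")
  if (has_rl) {
    graphics::plot(x$rl_history$epoch, x$rl_history$mean_reward, type = "b",
                   pch = 16, xlab = "epoch", ylab = "mean reward",
                   main = "reinforcement phase")
  }
  invisible(x)
}
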