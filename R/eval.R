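# The seven structure-constrained generation metrics, the
# similarity-threshold sweep, and the latent-embedding ablation analytics.

#' Bundle a source molecule with its generated outputs
#'
#' @param source a single valid SMILES string.
#' @param outputs character vector of generated texts (typically 20).
#' @return object of class `cg_genset`: list with `source`, `outputs`,
#'   `valid` (logical flags consistent with [canonicalize_smiles()]) and
#'   `canonical` (canonical forms, `NA` for invalid outputs).
#' @export
make_generation_set <- function(source, outputs) {
  stopifnot(length(source) == 1L)
  if (!smiles_is_valid(source)) stop("invalid source SMILES: ", source,
                                     call. = FALSE)
  canonical <- canonicalize_smiles(outputs)
  structure(list(source = source, outputs = outputs,
                 valid = !is.na(canonical), canonical = canonical),
            class = "cg_genset")
}

#' @export
print.cg_genset <- function(x, ...) {
  cat(sprintf("<generation set: source %s, %d outputs (%d valid)>\n",
              x$source, length(x$outputs), sum(x$valid)))
  invisible(x)
}

#' Run the k-samples-per-source generation protocol
#'
#' @param model a trained `contragen` model.
#' @param sources character vector of valid source SMILES.
#' @param k generated molecules per source (default 20).
#' @param seed optional seed.
#' @return list of `cg_genset` objects.
#' @export
generate_sets <- function(model, sources, k = 20L, seed = NULL) {
  run <- function() {
    lapply(sources, function(s) {
      make_generation_set(s, as.character(translate_smiles(model, s, k = k)))
    })
  }
  if (is.null(seed)) run() else cg_with_seed(seed, run())
}

#' Structure-constrained generation metrics
#'
#' Computes the seven benchmark metrics over a list of generation sets:
#' \describe{
#'   \item{validity}{fraction of sources with at least one valid output.}
#'   \item{novelty}{fraction of sources with at least one valid output
#'     absent (by canonical SMILES) from the training set.}
#'   \item{property}{mean over sources of the mean oracle score of valid
#'     outputs.}
#'   \item{improvement}{mean over sources of the mean score gain of valid
#'     outputs over the source.}
#'   \item{similarity}{mean over sources of the mean Tanimoto similarity of
#'     valid outputs to the source.}
#'   \item{diversity}{mean over sources of one minus the mean pairwise
#'     Tanimoto similarity among valid outputs.}
#'   \item{success_rate}{fraction of sources with at least one output that
#'     is simultaneously valid, novel, property-improved by at least
#'     `delta`, and at least `epsilon`-similar to the source.}
#' }
#' Sources with no valid output are excluded from the property, improvement
#' and similarity means (their per-source terms are 0/0), and sources with
#' fewer than two valid outputs from the diversity mean; all sources count
#' in the validity, novelty and success-rate denominators. `total` is the
#' sum of the six metrics other than the success rate.
#'
#' @param sets list of `cg_genset` objects.
#' @param train_set character vector of training SMILES (novelty
#'   reference; compared on canonical forms).
#' @param oracle property oracle.
#' @param delta success threshold on the property improvement (default 0:
#'   any non-degradation counts).
#' @param epsilon success threshold on the Tanimoto similarity.
#' @return object of class `cg_metrics`.
#' @export
compute_metrics <- function(sets, train_set, oracle, delta = 0,
                            epsilon = 0.4) {
  stopifnot(length(sets) >= 1L, inherits(oracle, "cg_oracle"))
  train_canon <- unique(canonicalize_smiles(train_set))
  if (anyNA(train_canon)) stop("invalid SMILES in train_set", call. = FALSE)
  n <- length(sets)
  valid_ind <- novel_ind <- success_ind <- logical(n)
  prop_terms <- impr_terms <- sim_terms <- div_terms <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    gs <- sets[[i]]
    stopifnot(inherits(gs, "cg_genset"))
    vidx <- which(gs$valid)
    valid_ind[i] <- length(vidx) > 0L
    if (!length(vidx)) next
    vcanon <- gs$canonical[vidx]
    novel <- !(vcanon %in% train_canon)
    novel_ind[i] <- any(novel)
    phi <- oracle_score(oracle, vcanon)
    phi_x <- oracle_score(oracle, gs$source)
    sims <- tanimoto_smiles(gs$source, vcanon)
    prop_terms[i] <- mean(phi)
    impr_terms[i] <- mean(phi - phi_x)
    sim_terms[i] <- mean(sims)
    success_ind[i] <- any(novel & (phi - phi_x >= delta) & (sims >= epsilon))
    if (length(vidx) >= 2L) {
      M <- cg_tanimoto_matrix(vcanon)
      div_terms[i] <- 1 - mean(M[upper.tri(M)])
    }
  }
  res <- list(
    validity = mean(valid_ind),
    novelty = mean(novel_ind),
    property = mean(prop_terms, na.rm = TRUE),
    improvement = mean(impr_terms, na.rm = TRUE),
    similarity = mean(sim_terms, na.rm = TRUE),
    diversity = mean(div_terms, na.rm = TRUE),
    success_rate = mean(success_ind),
    n_sources = n, delta = delta, epsilon = epsilon
  )
  for (nm in c("property", "improvement", "similarity", "diversity")) {
    if (is.nan(res[[nm]])) res[[nm]] <- NA_real_
  }
  res$total <- res$validity + res$property + res$improvement +
    res$similarity + res$novelty + res$diversity
  structure(res, class = "cg_metrics")
}

#' @export
print.cg_metrics <- function(x, ...) {
  cat(sprintf("generation metrics over %d sources (delta=%g, epsilon=%g):\n",
              x$n_sources, x$delta, x$epsilon))
  for (nm in c("validity", "novelty", "property", "improvement",
               "similarity", "diversity", "success_rate", "total")) {
    cat(sprintf("  %-12s %8.4f\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' @export
as.data.frame.cg_metrics <- function(x, ...) {
  data.frame(validity = x$validity, novelty = x$novelty,
             property = x$property, improvement = x$improvement,
             similarity = x$similarity, diversity = x$diversity,
             success_rate = x$success_rate, total = x$total)
}

#' Success rate over a grid of similarity thresholds
#'
#' Evaluates the success rate at each threshold (ascending) and the mean
#' over thresholds — the headline summary of a structure-constrained
#' generation benchmark. The default grid is 0.40 to 0.70 in steps of 0.05.
#'
#' @inheritParams compute_metrics
#' @param thresholds ascending similarity thresholds.
#' @return data.frame (threshold, success_rate) with the grid mean attached
#'   as attribute `"mean"`.
#' @export
success_rate_sweep <- function(sets, train_set, oracle, delta = 0,
                               thresholds = seq(0.40, 0.70, by = 0.05)) {
  if (!length(thresholds)) stop("empty threshold list", call. = FALSE)
  if (is.unsorted(thresholds, strictly = FALSE)) {
    stop("thresholds must be ascending", call. = FALSE)
  }
  rates <- vapply(thresholds, function(eps) {
    compute_metrics(sets, train_set, oracle, delta = delta,
                    epsilon = eps)$success_rate
  }, numeric(1))
  out <- data.frame(threshold = thresholds, success_rate = rates)
  attr(out, "mean") <- mean(rates)
  out
}

#' Partition molecule pairs by Tanimoto similarity
#'
#' All unordered pairs of distinct molecules, split into similar
#' (`T >= threshold`) and dissimilar (`T < threshold`) sets — the two pair
#' populations compared in the latent-embedding ablation analysis.
#'
#' @param molecules character vector of valid SMILES.
#' @param threshold similarity split point (default 0.4).
#' @return list of two data.frames `similar` and `dissimilar` with columns
#'   `a`, `b` (SMILES) and `tanimoto`.
#' @export
partition_pairs_by_similarity <- function(molecules, threshold = 0.4) {
  stopifnot(length(molecules) >= 2L)
  M <- cg_tanimoto_matrix(molecules)
  idx <- which(upper.tri(M), arr.ind = TRUE)
  df <- data.frame(a = molecules[idx[, 1]], b = molecules[idx[, 2]],
                   tanimoto = M[idx], stringsAsFactors = FALSE)
  list(similar = df[df$tanimoto >= threshold, , drop = FALSE],
       dissimilar = df[df$tanimoto < threshold, , drop = FALSE])
}

#' Latent-embedding ablation analytics
#'
#' Projects the latent mean vectors of a molecule set to two dimensions by
#' PCA, computes the Euclidean distances of the similar and dissimilar
#' molecule pairs in that plane, and compares the two distance samples with
#' the Kruskal-Wallis H test. A large H means similar molecules sit close
#' together while dissimilar ones sit far apart — the geometry the
#' contractive and margin losses are designed to produce.
#'
#' @param model a `contragen` model.
#' @param molecules character vector of valid SMILES.
#' @param similar_pairs,dissimilar_pairs data.frames with SMILES columns
#'   `a`, `b` (e.g. from [partition_pairs_by_similarity()]); neither may be
#'   empty.
#' @return object of class `cg_embedding`: list with `embedding` (n x 2
#'   coordinates, rownames = molecules), `H`, `p_value`, and the two
#'   distance samples.
#' @export
embedding_analysis <- function(model, molecules, similar_pairs,
                               dissimilar_pairs) {
  stopifnot(inherits(model, "contragen"))
  if (!nrow(similar_pairs) || !nrow(dissimilar_pairs)) {
    stop("both pair sets must be non-empty", call. = FALSE)
  }
  molecules <- unique(molecules)
  g <- encode_latent(model, molecules)
  pc <- stats::prcomp(g$mean, center = TRUE, scale. = FALSE)
  emb <- pc$x[, 1:2, drop = FALSE]
  rownames(emb) <- molecules
  pair_dist <- function(pairs) {
    ia <- match(pairs$a, molecules); ib <- match(pairs$b, molecules)
    if (anyNA(ia) || anyNA(ib)) {
      stop("pair members must appear in `molecules`", call. = FALSE)
    }
    sqrt(rowSums((emb[ia, , drop = FALSE] - emb[ib, , drop = FALSE])^2))
  }
  d_sim <- pair_dist(similar_pairs)
  d_dis <- pair_dist(dissimilar_pairs)
  kt <- stats::kruskal.test(list(d_sim, d_dis))
  structure(list(embedding = emb, H = unname(kt$statistic),
                 p_value = kt$p.value, similar_distances = d_sim,
                 dissimilar_distances = d_dis),
            class = "cg_embedding")
}

#' @export
print.cg_embedding <- function(x, ...) {
  cat(sprintf(
    "latent embedding: %d molecules; Kruskal-Wallis H = %.3f (p = %.3g)\n",
    nrow(x$embedding), x$H, x$p_value))
  cat(sprintf("  median distance: similar %.3f, dissimilar %.3f\n",
              stats::median(x$similar_distances),
              stats::median(x$dissimilar_distances)))
  invisible(x)
}

#' Read/write generation tables (source + k outputs per row, TSV)
#'
#' @param sets list of `cg_genset`.
#' @param path file path.
#' @export
write_generation_table <- function(sets, path) {
  k <- max(vapply(sets, function(s) length(s$outputs), integer(1)))
  rows <- vapply(sets, function(s) {
    paste(c(s$source, s$outputs, rep("", k - length(s$outputs))),
          collapse = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' @rdname write_generation_table
#' @export
read_generation_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    make_generation_set(f[1], f[-1])
  })
}
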