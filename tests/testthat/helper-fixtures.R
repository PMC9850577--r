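# Shared fixtures and independent oracles for the test suite. Expensive
# objects (synthetic data, trained models) are built once per run and
# memoised here.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

syn_small <- function() {
  fixture("syn_small", function() generate_synthetic_dataset(36, seed = 101))
}

# a small metric-phase-trained model shared across tests
fit_small <- function() {
  fixture("fit_small", function() {
    syn <- syn_small()
    contragen(syn$pairs, negatives_pool = syn$negatives_pool,
              epochs = 12L, batch_size = 18L, seed = 5L)
  })
}

heavy_oracle <- function() {
  make_oracle("function", fn = heavy_atom_score, name = "heavy-atoms",
              range = c(0, 1))
}

# pool of small molecules (plus some deliberately broken strings) for toy
# generation sets
toy_pool_valid <- c("CCO", "CCN", "CCC", "CCS", "CCOC", "CC(C)C", "CCCC",
                    "CCCCC",
                    "C=CC", "CC=O", "COC", "CSC", "CCCO", "CCCN",
                    "c1ccccc1", "Cc1ccccc1")
toy_pool_invalid <- c("C(C", "xyz", "C1CC", "")

# deterministic tabulated oracle over the toy pool (canonical keys)
toy_oracle <- function() {
  fixture("toy_oracle", function() {
    canon <- canonicalize_smiles(toy_pool_valid)
    tab <- stats::setNames(round(seq(0.05, 0.95,
                                     length.out = length(canon)), 3), canon)
    make_oracle("tabulated", table = tab, name = "toy-activity",
                range = c(0, 1))
  })
}

toy_oracle_table <- function() {
  or <- toy_oracle()
  environment(or$score)$tab
}

random_toy_sets <- function(n_sets, k = 8L) {
  canon <- canonicalize_smiles(toy_pool_valid)
  lapply(seq_len(n_sets), function(i) {
    source <- sample(toy_pool_valid, 1L)
    outputs <- sample(c(toy_pool_valid, toy_pool_invalid, source), k,
                      replace = TRUE)
    make_generation_set(source, outputs)
  })
}

# ---- independent brute-force implementation of the seven metrics ----------
# Deliberately naive: plain loops over the printed definitions, no shared
# aggregation code with the package implementation.
naive_metrics <- function(sets, train_set, score_tab, delta, epsilon) {
  train_canon <- unique(canonicalize_smiles(train_set))
  n <- length(sets)
  valid <- novel <- success <- 0
  prop <- impr <- sim <- div <- c()
  for (gs in sets) {
    canon <- canonicalize_smiles(gs$outputs)
    zeta <- !is.na(canon)
    if (sum(zeta) > 0) valid <- valid + 1
    vout <- canon[zeta]
    if (any(!(vout %in% train_canon))) novel <- novel + 1
    if (length(vout) > 0) {
      phis <- unname(score_tab[vout])
      phix <- unname(score_tab[canonicalize_smiles(gs$source)])
      sims <- tanimoto_smiles(gs$source, vout)
      prop <- c(prop, mean(phis))
      impr <- c(impr, mean(phis - phix))
      sim <- c(sim, mean(sims))
      hit <- FALSE
      for (j in seq_along(vout)) {
        if (!(vout[j] %in% train_canon) && (phis[j] - phix >= delta) &&
            (sims[j] >= epsilon)) hit <- TRUE
      }
      if (hit) success <- success + 1
      if (length(vout) >= 2) {
        tot <- 0; cnt <- 0
        for (a in seq_along(vout)) for (b in seq_along(vout)) {
          if (a != b) {
            tot <- tot + tanimoto_smiles(vout[a], vout[b])
            cnt <- cnt + 1
          }
        }
        div <- c(div, 1 - tot / cnt)
      }
    }
  }
  avg <- function(x) if (length(x)) mean(x) else NA_real_
  list(validity = valid / n, novelty = novel / n, property = avg(prop),
       improvement = avg(impr), similarity = avg(sim), diversity = avg(div),
       success_rate = success / n)
}

# ---- independent Fréchet-distance oracle -----------------------------------
# the general matrix formula ||mu1 - mu2||^2 + tr[S1 + S2 - 2 (S1 S2)^{1/2}],
# with the matrix square root taken by eigendecomposition
frechet_general <- function(mu1, S1, mu2, S2) {
  prod <- S1 %*% S2
  eig <- eigen(prod)
  sq <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)),
                             nrow = length(eig$values)) %*%
    solve(eig$vectors)
  sum((mu1 - mu2)^2) + sum(diag(S1 + S2 - 2 * sq))
}

# ---- independent Kruskal-Wallis H (rank closed form with tie correction) ---
naive_kruskal_h <- function(x, y) {
  all <- c(x, y)
  r <- rank(all)
  N <- length(all)
  ns <- c(length(x), length(y))
  rs <- c(sum(r[seq_along(x)]), sum(r[-seq_along(x)]))
  H <- 12 / (N * (N + 1)) * sum(rs^2 / ns) - 3 * (N + 1)
  ties <- table(all)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}
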