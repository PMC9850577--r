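# contragen

Structure-constrained molecular generation in R: a sequence-to-sequence
variational autoencoder over SMILES strings whose encoder is trained by
**metric learning with contractive and margin losses**, and whose decoder is
fine-tuned by **REINFORCE with similarity-gated property rewards**.

## The problem

Lead optimization wants molecules that *resemble* a given source compound
(a hit, an approved drug) but have *better* properties — higher
drug-likeness, stronger predicted activity, or lower affinity for a
resistance-mediating protein. The two constraints fight each other:
generators that improve properties freely tend to wander away from the
source scaffold. `contragen` is for computational chemists who want a small,
fully inspectable, CPU-scale implementation of a generator built
specifically for that trade-off, together with the complete evaluation suite
used for structure-constrained generation benchmarks.

## The model

Molecular similarity is the Tanimoto coefficient over radius-2, 2048-bit
circular fingerprints,

```
T(x, y) = sum_i p_i q_i / sum_j (p_j + q_j - p_j q_j).
```

**Phase 1 — metric learning.** A GRU encoder maps a SMILES string to a
diagonal latent Gaussian (mu, Sigma). Over triplets (x_s, x_t, x_n) — a
Tanimoto-similar source/target pair and a dissimilar negative — the
objective adds to the three reconstruction NLLs a *contractive loss*, the
Fréchet distance between the pair's latent Gaussians,

```
||mu_t - mu_s||^2 + tr[Sigma_t + Sigma_s - 2 (Sigma_t Sigma_s)^(1/2)]
```

and a *margin loss* `softplus(1 - ||mu - mu_n||^2)` repelling the negative
from both pair members. Similar molecules end up sharing latent positions;
dissimilar ones are pushed apart, but boundedly.

**Phase 2 — reinforcement learning.** With the encoder frozen, the decoder
is updated by the score-function gradient
`-R(x_hat, x) * grad log p(x_hat | z_x)`, where the reward is a
similarity-gated, rescaled property score — e.g. for a property to increase:
`max(0, (phi(x_hat) - delta) / (1 - delta))` if `T(x_hat, x) > epsilon`,
else 0. The published task thresholds (DRD2, QED, pLogP at similarity 0.4
and 0.6, and the sorafenib/ABCG2 task with its BRAF side-constraint) ship in
`task_reward_config()`.

**Evaluation.** The seven-metric suite — validity, novelty, property,
improvement, similarity, diversity, success rate — over the
20-samples-per-source generation protocol, plus success-rate sweeps over
similarity thresholds 0.40–0.70 and a latent-embedding ablation analysis
(PCA + Kruskal–Wallis H on similar vs dissimilar pair distances).

## A worked example

```r
library(contragen)

# a synthetic structure-constrained benchmark: 300 similar (source, target)
# pairs from six scaffold families, with a strictly improving property
syn <- generate_synthetic_dataset(300, seed = 42)
fit <- contragen(syn$pairs, negatives_pool = syn$negatives_pool,
                 epochs = 30, seed = 7)
fit
#> Structure-constrained molecular generator (sequence VAE)
#>   vocabulary: 13 tokens; latent 32, hidden 64, embedding 16
#>   metric phase: 30 epochs (final total loss 10.519); RL phase: untrained

oracle <- make_oracle("function", fn = heavy_atom_score,
                      name = "heavy-atoms", range = c(0, 1))
cfg <- make_reward_config("increase", delta = 0, epsilon = 0.3,
                          oracle = oracle)
fit_rl <- train_rl_phase(fit, unique(syn$pairs$source), cfg,
                         epochs = 20, seed = 7)

sets <- generate_sets(fit_rl, unique(syn$pairs$source)[1:20], k = 20,
                      seed = 1)
compute_metrics(sets, fit_rl$train_smiles, oracle, delta = 0, epsilon = 0.3)
#> generation metrics over 20 sources (delta=0, epsilon=0.3):
#>   validity       1.0000
#>   novelty        1.0000
#>   property       0.9342
#>   improvement    0.5917
#>   similarity     0.4694
#>   diversity      0.2568
#>   success_rate   0.9500
#>   total          4.2521
```

The printed metrics mean: every source produced at least one valid and one
novel molecule; generated molecules average a heavy-atom property score of
0.93 (a +0.59 mean gain over their sources); they retain a mean Tanimoto
similarity of 0.47 to their source while staying mutually diverse (mean
pairwise dissimilarity 0.26); and for 95% of sources at least one output is
simultaneously valid, novel, property-improved and at least 0.3-similar.
After 20 RL epochs on this saturating size reward the decoder also begins
to exploit it — some translations grow into very long chains that still
clear the 0.3 similarity gate — the classic reward-design trade-off that
the similarity threshold `epsilon` exists to control.

A command-line interface covering the same workflow
(`make-fixtures`, `train`, `generate`, `evaluate`, YAML-configured) is
installed at `inst/cli/contragen`.

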