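---
title: "Structure-constrained molecular generation with contractive and margin losses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-constrained molecular generation with contractive and margin losses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Lead optimization asks for new molecules that keep the structural identity
of a hit compound — its scaffold, its pharmacophore — while improving some
property: drug-likeness, activity against a receptor, reduced affinity for a
resistance-mediating transporter. `contragen` implements a
sequence-to-sequence variational autoencoder (VAE) over SMILES strings that
is trained specifically for this *structure-constrained* setting, in two
phases:

1. **Metric learning.** The encoder $q_\phi$ maps a SMILES string to a
   diagonal Gaussian $(\mu, \Sigma)$ in latent space. Training minimizes,
   over triplets $(x_s, x_t, x_n)$ of a similar source/target pair plus a
   dissimilar negative,
   $$
   L = \underbrace{\textstyle\sum_{r \in \{s,t,n\}}
        \mathbb{E}_{z \sim q_\phi(z|x_r)}[-\log p_\psi(x_r|z)]}_{\text{reconstruction}}
     + \underbrace{\|\mu_t-\mu_s\|^2 +
        \mathrm{tr}[\Sigma_t+\Sigma_s-2(\Sigma_t\Sigma_s)^{1/2}]}_{\text{contractive}}
     + \underbrace{\mathrm{sp}(1-\|\mu_t-\mu_n\|^2) +
        \mathrm{sp}(1-\|\mu_s-\mu_n\|^2)}_{\text{margin}},
   $$
   with $\mathrm{sp}(x)=\log(1+e^x)$. The contractive term is the Fréchet
   (2-Wasserstein) distance between the two latent Gaussians of a similar
   pair; it replaces the KL terms that appear when the VAE prior is swapped
   for the paired posterior, because it is symmetric and cheap to
   differentiate. For diagonal covariances it reduces to
   $\|\mu_t-\mu_s\|^2 + \sum_i (\sqrt{\sigma_{t,i}}-\sqrt{\sigma_{s,i}})^2$,
   which is what `contractive_loss()` computes (the test suite checks this
   against the general matrix-square-root formula). The margin term pushes
   the dissimilar negative away from both pair members; the softplus keeps
   the repulsion bounded above by $\mathrm{sp}(1)$ so the latent space does
   not spread without limit. This objective *replaces* the standard
   $N(0, I)$ KL prior entirely — no extra KL term is added, because the
   final objective contains none.

2. **Reinforcement learning.** The decoder $p_\psi$ is then fine-tuned with
   REINFORCE: an episode is one translation of a source $x$ into $\hat{x}$,
   and the gradient $-R(\hat{x},x)\,\nabla_\psi \log p_\psi(\hat{x}|z_x)$
   is applied to *decoder parameters only* — the encoder is frozen as a
   hard contract (`reinforce_step()` cannot touch it). Rewards are
   similarity-gated, piecewise-linear property scores (`reward_kernel()`),
   with the published task thresholds exposed by `task_reward_config()`.

Structural similarity throughout is the Tanimoto coefficient over
radius-2, 2048-bit circular fingerprints.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `latent_dim` | 32 | latent Gaussian dimension $d$ |
| `hidden_size` | 64 | GRU hidden width (encoder and decoder) |
| `embed_size` | 16 | token embedding width |
| `max_len` | 120 tokens | longest encodable SMILES (error, never truncation) |
| `epochs` (metric) | 30 | Adam epochs on the triplet objective |
| `learning_rate` (metric) | 5e-3 | Adam step size |
| `epochs` (RL) | 20 | REINFORCE epochs |
| `learning_rate` (RL) | 2e-3 | Adam step size on decoder parameters |
| `negative_threshold` | 0.4 | a negative must have $T < 0.4$ to both pair members |
| `delta`, `epsilon` | task-specific | reward thresholds (property, similarity) |
| `k` | 20 | generated molecules per source in the evaluation protocol |

The architecture defaults are deliberately desk-scale: a single-layer GRU
with these widths trains in minutes on one CPU while leaving the latent
geometry and the RL dynamics clearly observable. They are not the scale one
would use against a 30k-pair activity benchmark; all of them are exposed in
`contragen_config()` and the run configuration.

The margin constant inside $\mathrm{sp}(1 - \cdot)$ is fixed at 1: it is
part of the objective's definition, not a tuning knob.

## Design choices

**Canonical form.** All molecule identity decisions (spelling invariance,
novelty membership, fingerprint caching) run over OpenBabel canonical
aromatic SMILES. We deliberately do *not* canonicalize to Kekulé form: the
toolchain's canonical writer does not produce a unique Kekulé spelling
(two Kekulé spellings of benzene survive as distinct strings), which would
break the invariant `canonicalize(canonicalize(s)) == canonicalize(s)`.
The tokenizer therefore handles aromatic (lowercase) tokens, and generated
molecules are emitted in aromatic form. The parser is also deliberately
stricter than OpenBabel alone: a syntactic screen rejects unbalanced
parentheses/brackets and unmatched ring-bond labels, which OpenBabel would
silently repair.

**Fingerprints.** The radius-2/2048-bit circular fingerprint is implemented
in-package as an ECFP-style iterative neighborhood hash over atom
invariants (element, formal charge, heavy degree, implicit hydrogens, ring
membership). It is deterministic and spelling-invariant but its bit
positions are its own — Tanimoto values are internally consistent across
the whole package (dataset thresholds, rewards, metrics), which is what
every similarity constraint relies on. The 0/0 case (two empty
fingerprints) is defined as similarity 0: no shared evidence of structure,
and no NaN propagating into metric averages.

**Property oracles.** QED and penalized logP are standard quantities, so
they delegate to the reference cheminformatics toolkit (RDKit, called in
batches through a bundled helper script) rather than being re-derived.
Penalized logP follows the widely used unnormalized convention
$\log P - SA - \max(0, \text{largest ring} - 6)$, with the z-scored variant
available behind `normalized = TRUE`; both circulate in the literature, so
the choice is explicit and configurable. Activity and affinity predictors
(dopamine-receptor activity, transporter affinities) are external artifacts
and are *not* re-trained: they plug in as tabulated, external-command, or
R-function oracles. The function-oracle kind exists because a finite table
cannot score novel generated molecules — the synthetic benchmark's property
(a scaled heavy-atom count) must be computable for anything the decoder
emits.

**Reconstruction reduction.** Token NLLs are summed within a sequence and
averaged over the minibatch; a single reparameterized latent sample per
string per step estimates the expectation. Rewards use one sampled episode
per source per update by default (`samples_per_source` raises it). The RL
estimator is implemented exactly as the score-function form above — no
baseline subtraction — keeping it faithful to its printed definition;
variance is instead controlled by Adam and minibatching.

**Degenerate metric denominators.** A source with zero valid outputs
contributes nothing to the property/improvement/similarity means (its
per-source term is 0/0) but still counts in the validity, novelty and
success-rate denominators; a source with fewer than two valid outputs is
likewise excluded from the diversity mean. Novelty and success-rate
membership tests run on canonical SMILES, so respelling a training molecule
does not count as novel. Generated duplicates are kept as duplicates
(multiset semantics): twenty copies of one valid molecule have diversity
exactly 0.

**Triplet negatives** are drawn uniformly (seeded) from the training pool
among candidates with $T < 0.4$ to both pair members — "similar" means
$T \ge 0.4$ throughout, so "relatively different" is its complement. The
sampling distribution is an assumption (uniform, not similarity-weighted),
flagged here deliberately.

## The synthetic benchmark

`generate_synthetic_dataset()` emulates the structure of a
structure-constrained pair benchmark at desk scale. Molecules come from six
scaffold families (alkane, ether, amine, thioether, aromatic, alkene
chains) built from family-specific chain units; a pair is a chain plus the
same chain with one extra unit inserted, so the target always gains heavy
atoms (a strictly positive property gap under the heavy-atom-count oracle,
`min(1, n_heavy/40)`) while staying structurally close. Families use
disjoint chemistries, and generation rejection-samples with safety margins
(intra-pair $T \ge 0.45$, cross-family $T < 0.35$) so the advertised
invariants — every pair $T \ge 0.4$, every cross-family pair $T < 0.4$ —
hold for every seed, not just on average.

What this emulates: paired similarity structure, a property gradient from
source to target, and dissimilar negatives for triplets. What it does not
emulate: the property landscapes of real oracles (activity cliffs,
multi-modal QED), realistic scaffold diversity, stereochemistry, charged
species, or SMILES lengths near `max_len`. Passing the end-to-end tests
therefore demonstrates that the machinery — losses, latent geometry,
policy gradient, metrics — behaves as designed, not that the desk-scale
model reaches benchmark-grade success rates on real chemistry.

## Numerical choices

- Latent log-variances are clamped to $[-8, 8]$ before exponentiation.
- Softplus is evaluated as `log1p(exp(x))` with a linear branch above 30.
- Decoder probabilities are floored at $10^{-12}$ inside the NLL.
- Gate order in the GRU is (reset, update, candidate); the candidate uses
  the reset-scaled hidden contribution. Gradient correctness of every
  parameter tensor is verified against central finite differences in the
  test suite.
- Generation samples from the full softmax (multinomial, never greedy) —
  the diversity metric and the 20-samples-per-source protocol presuppose
  stochastic decoding. Sampling, shuffling and initialization all run
  through seeded, restorable RNG scopes, which is what makes every phase
  bit-for-bit reproducible on a single CPU thread.

## Problem sizes used in verification

The end-to-end checks train on ~300 synthetic pairs (vocabulary ≈ 15
tokens, latent dimension 32) for 30 metric-learning epochs and 20 RL
epochs, evaluate 20 generations per held-out source, and compare latent
pair-distance distributions (Kruskal–Wallis H) for a 60-molecule sample —
sizes chosen so the full workflow, including its ablation arm, completes in
a few minutes of one CPU while leaving all the qualitative effects (loss
decrease, latent separation, reward lift, success-rate lift) visible.

## Known limitations

- The fingerprint is not bit-compatible with any external toolkit's Morgan
  implementation; Tanimoto values are comparable within the package only.
- Validity is OpenBabel-based (plus the syntactic screen) and mildly more
  permissive than stricter parsers, e.g. for unusual valences; the QED and
  penalized-logP oracles will refuse molecules their backend cannot parse.
- Single-layer GRUs at desk-scale widths; no attention, no graph decoder.
- The RL phase, as a pure score-function method without a baseline, has
  high gradient variance; at these problem sizes Adam absorbs it, but
  larger runs would want the (config-gated) variance reduction extensions.

## A worked run

```{r}
library(contragen)

syn <- generate_synthetic_dataset(300, seed = 42)
fit <- contragen(syn$pairs, negatives_pool = syn$negatives_pool,
                 epochs = 30, seed = 7)

oracle <- make_oracle("function", fn = heavy_atom_score,
                      name = "heavy-atoms", range = c(0, 1))
cfg <- make_reward_config("increase", delta = 0, epsilon = 0.3,
                          oracle = oracle)
fit_rl <- train_rl_phase(fit, unique(syn$pairs$source), cfg,
                         epochs = 20, seed = 7)
plot(fit_rl)

sets <- generate_sets(fit_rl, unique(syn$pairs$source)[1:20], k = 20,
                      seed = 1)
compute_metrics(sets, fit_rl$train_smiles, oracle, delta = 0,
                epsilon = 0.3)
```
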