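---
title: "Methods: heterogeneous graph neural network drug repurposing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterogeneous graph neural network drug repurposing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`drhgnn` treats computational drug repurposing as a link-labeling problem on
a heterogeneous drug–protein–disease (DPD) graph. The observed entities are
four node types — drugs, proteins, diseases, drug side effects — connected by
six binary association networks and two real-valued similarity networks
(drug–drug and protein–protein similarity in `[0,1]`). Diseases are not
predicted as free-floating nodes: they act as *labels on drug–protein edges*,
so a prediction is a triple `(d, p, δ)` — disease `δ` bridges drug `d` and
its protein target `p`.

The pipeline has four stages, each usable on its own:

1. **DPD construction** (`build_dpd`). Every drug–protein interaction gets a
   disease label set. Two rules are provided because the natural definitions
   disagree: `protein` attaches all diseases of the protein (a pure adjacency
   join on protein names), `intersection` (default) only diseases associated
   with both endpoints. The intersection rule is stricter and semantically
   closer to "the disease connects these two"; it is the default, and the
   switch makes the choice auditable rather than hidden. Pairs with no
   eligible disease are dropped and counted, so a user can detect when the
   rule is mismatched to their data.
2. **Compact feature learning** (`rwr`, `network_diffusion_profile`,
   `dca_embed`). Node side information is summarized by network diffusion:
   for each sub-network incident to a node type, a random walk with restart
   produces per-node diffusion states (the fixed point of
   `s_i = p e_i + (1 - p) P' s_i` with `P` row-stochastic), and the
   horizontally concatenated states are compressed by a
   diffusion-component-analysis style factorization. The deterministic
   default takes the truncated SVD of the column-centered element-wise log of
   the smoothed states and returns `U Σ^{1/2}`; an optional solver refines a
   multinomial-logistic (softmax) reconstruction by gradient descent on the
   mean row-wise KL divergence, initialized from the SVD solution. The
   deterministic default makes feature learning reproducible without seeds
   and is the standard closed-form approximation of the softmax objective.
3. **Multi-label transformation** (`transform_labels`). Label sets are
   reduced to one representative per edge: the disease with the smallest
   global edge frequency in the multi-label graph, ties broken by
   lexicographically smallest identifier. Rare labels are the most
   distinctive, and the global-argmin rule is deterministic and auditable. A
   secondary ranking hook (`score` argument of `select_representative`)
   exists for richer criteria — e.g. an information-theoretic score — but no
   such score is enabled by default, because any particular choice of the
   two variables to relate would be arbitrary.
4. **HinSAGE + edge head** (`hinsage_model`, `train_drhgnn`). A heterogeneous
   GraphSAGE: per layer, each node mixes its own (dropout-masked) features
   with relation-wise means of sampled neighbor features, with separate
   self-weight matrices per node type and neighbor-weight matrices per
   ordered relation tuple. Drug and protein embeddings are concatenated into
   an edge embedding and a single dense softmax layer predicts the disease
   class. Training minimizes cross-entropy over positive triples with Adam
   plus an L2 penalty on weight matrices; model selection keeps the epoch
   with the best validation AUC.

### Layer arithmetic and its ambiguity

The layer update is implemented in *sum form*:

    h_v^k = σ( W_self[t_v] · D_p[h_v^{k-1}] + Σ_r W_neigh[r] · mean_{u∈N_r(v)} D_p[h_u^{k-1}] + b_k )

with full `d_k × d_{k-1}` matrices, which makes the per-layer parameter count
exactly `(T_v + R_e) d_k d_{k-1} + d_k` (one self matrix per node type, one
neighbor matrix per relation, one shared bias) — `parameter_count()` and the
enumerated weights of a constructed layer agree identically. A
concatenation-style variant in which self and neighbor terms each produce
`d_k/2` columns is available as `combine = "concat"`; the two variants
reflect two published readings of the update rule that are mutually
inconsistent as printed, and the sum form is canonical here because it is the
one whose parameter accounting closes.

### Neighbor sampling semantics

`sample_neighbors` draws uniformly **with replacement** only when the
requested sample size is *below* the node's degree. At or above the degree it
returns the full neighborhood with equal multiplicity, so the sampled mean
equals the exact neighborhood mean. This makes "sampling saturated" runs
exactly equal to dense message passing (verified against an independent
dense oracle to 1e-8), keeps inference deterministic, and changes nothing in
the sub-degree regime where sampling actually matters. Empty neighborhoods
aggregate to the zero vector, so isolated nodes reduce to
`σ(W_self x + b)`.

Training resamples neighborhoods per minibatch (seeded); scoring
(`score_triples`, and all AUC evaluation) uses exact full neighborhoods so
reported metrics carry no sampling noise.

## Tunable parameters

| parameter | default | notes |
|---|---|---|
| restart probability `p` | 0.5 | common diffusion default; balances local vs global structure |
| RWR tolerance / max iterations | 1e-10 / 1000 | L1 change per state; at `p = 0.5` convergence is ~35 iterations |
| log smoothing `eps` | `1/ncol(profile)` | standard smoothing scale for log-diffusion states |
| feature dims (drug / protein) | 100 / 400 | mirrors the published feature sizes of the reference dataset; use smaller values for small networks |
| layers / hidden dims | 2 / 256 | two layers propagate drug↔protein information both ways; deeper stacks over-smooth |
| neighbor samples | (8, 4) | GraphSAGE convention, outer to inner layer |
| activation | ReLU hidden, identity final | identity final layer keeps embeddings unbounded for the head |
| learning rate / dropout | 0.001 / 0.1 | tuned optimum of the method's published grid |
| epochs / batch size | 50 / 200 | epochs from the published tuning; batch size unstated there, 200 is a moderate minibatch |
| L2 coefficient | 5e-4 | unstated in the source; standard weight-decay scale |
| negatives per positive | 1 | class-balanced evaluation sets |
| split ratios / repeats | 60/20/20, 5 | repeated seeded shuffles; `protocol = "cv5"` gives standard 5-fold with an inner 75/25 validation split |

The evaluation protocol intentionally implements the *described* procedure
(five seeded 60/20/20 shuffles) as canonical and keeps the *named* one
(5-fold CV) as an option, since the two are described interchangeably in the
method this package implements.

Negative triples pair a uniformly drawn non-interacting (drug, protein) pair
with a uniformly drawn vocabulary disease. Scoring a triple means reading off
the softmax probability of *its* disease class, for positives the true label,
for negatives the sampled one; the binary AUC then measures how much
probability mass the model concentrates on real bridges.

## The synthetic generator

`generate_hetnet` emulates the statistical shape of DTINet-style data: every
node carries a latent unit vector (spherical Gaussian, rank 8 by default);
each association network connects the pairs whose logistic edge probability
`sigmoid(β·⟨u_a, u_b⟩ + c)` falls in the top density-quantile, with `c`
calibrated so the expected density matches the target; similarity matrices
are clipped cosines of the latents. Thresholding (rather than Bernoulli
sampling) makes the network an exact function of the latent factors, so
`noise_rate` — which rewires a fraction of edges to random non-edges — is the
*only* noise dial: `noise_rate = 0` is genuinely clean data. Because the
drug–disease and protein–disease networks are driven by the same latent space
as the drug–protein network, intersection label sets are shared across latent
neighborhoods, which is what makes the representative labels learnable.

Default densities are scaled up from the real data's order of magnitude
(drug–protein density ≈ 0.002 there) so that a 200 + 200 node network keeps
mean degree ≈ 5; disease-association densities (0.25) are chosen so
intersection label sets are mostly non-empty at 20 diseases.

What the generator does *not* emulate: real pharmacology (no chemistry, ATC
classes or sequence structure), heavy-tailed degree distributions, and the
extreme label imbalance of real disease vocabularies (5,603 diseases
collapsing to 39 representatives). Passing the synthetic recovery experiment
therefore shows the pipeline can extract planted relational structure at
realistic sparsity — not that it reproduces any particular real-data figure.

## Numerical choices and degenerate inputs

- RWR: isolated nodes get a self-loop so probability mass is conserved; rows
  are renormalized on exit (a no-op up to round-off); the iteration is
  invariant to uniform scaling of the adjacency.
- `dca_embed` refuses `dim ≥ min(dim(profile))` and non-positive `eps`; the
  SVD solver is deterministic, and with a degenerate spectrum (e.g. an
  identity diffusion profile) a truncated embedding is only defined up to
  rotation inside the degenerate eigenspace — full-rank embeddings restore
  the exact symmetry.
- Weight init is Gaussian with variance `2/(fan_in + fan_out)`, seeded; all
  training randomness (shuffles, sampling, dropout, negatives) derives from
  one master seed with fixed offsets, so runs reproduce byte-identically.
- Dropout is inverted (survivors scaled by `1/(1-p)`) and applied
  independently to self and neighbor terms, only in training mode; `p = 0`
  in training mode is exactly inference mode.
- Backpropagation through the sampled-mean operators is exact (the operators
  are fixed per minibatch); gradients are verified against finite
  differences in the test suite.
- `lr = 0` performs no updates (useful as a baseline); divergence (non-finite
  loss or weights) aborts with the epoch number.
- AUPR uses step-interpolation (average-precision style) over descending
  distinct score thresholds, documented to avoid trapezoid/step
  discrepancies; its chance baseline is the positive prevalence.

## Problem sizes used in the tests

Unit and property tests run on hand-built graphs of 2–20 nodes and synthetic
networks of 30–100 nodes. The recovery experiment uses the generator defaults
(200 drugs, 200 proteins, 20 diseases, rank 8; ~1,000 DP edges), 64-dim
features and a 64-dim two-layer model over 3 shuffle repeats — dimensions
chosen to be proportionate to a 400-node graph (a 256-dim model would be
over-parameterized at this scale and learns no better here), with the
published training settings (Adam, lr 0.001, dropout 0.1, 50 epochs). On
clean data this reaches mean test AUC-ROC ≈ 0.94; on rewired null data it
stays at chance, and added noise does not help — together these bracket the
pipeline's behaviour from above and below.

## Known limitations

- The real-data headline numbers require the external DTINet download;
  desk-scale tests assert self-consistency of the published counts and the
  synthetic experiments, not the external figures. Whether the published
  1,923-triple DPD graph arises from the protein rule or the intersection
  rule is not decidable from the description; both are provided.
- Message passing uses the full positive graph during training (the standard
  setup for edge-label prediction with known structure); held-out triples
  are unseen as *labels* but their endpoints participate in diffusion and
  aggregation. Pos/neg AUC therefore measures label concentration on known
  structure, not de-novo edge discovery.
- The "more mutual information" refinement of representative selection is
  not implemented — only the frequency rule is operationalizable; the hook
  for a secondary score is exposed.
- Single-threaded dense linear algebra: comfortable to a few thousand nodes
  per network; the full 12,015-node reference network is loadable, and
  feature learning at that scale is minutes-level, but the package makes no
  attempt at GPU or sparse-diffusion shortcuts.
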