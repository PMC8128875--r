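---
title: "misinfonet: models, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{misinfonet: models, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(misinfonet)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, the numerical choices, and
the design decisions taken where the design was genuinely open. It states
no empirical number that the test suite does not itself compute.

## The object of study

A misinformation stream is a sequence of records, each with a day index, a
unit-norm embedding of its text, optional tokens, and an optional
popularity count. Two records are considered "the same story" when the
cosine similarity of their embeddings exceeds a threshold. Everything in
the package derives from that one modelling act: similarity networks over
records, their temporal evolution, and classifiers over the embeddings.

Real streams are produced by encoding claims with a sentence transformer.
The package deliberately does not run a language model: the embedding
interface is a matrix of unit rows, so any encoder can be plugged in.
A widely used encoder width is 768, which is the default
`embedding_dim`; it is configurable because published descriptions of such
pipelines occasionally print other widths.

## Popularity: power law versus log-normal

Both families are fitted above a cutoff `x_min` by exact maximum
likelihood on the tail:

* power law: `alpha_hat = 1 + n_tail / sum(log(x_i/x_min))` (continuous
  Hill estimator);
* log-normal: truncated-lognormal ML. Writing `y = log x`, the tail is a
  left-truncated normal, an exponential family in `(y, y^2)`, so the MLE
  equals moment matching: with `z = (log x_min − mu)/sigma` and hazard
  `h(z)`, solve `E[Y] = mu + sigma h(z)` and
  `Var[Y] = sigma^2 (1 + z h − h^2)` against the sample moments, a 1-D
  root-find in `z`. This is exact and O(1) per cutoff candidate, which is
  what makes the 50-replicate bootstrap affordable; candidates are every
  distinct observed value and the selected cutoff minimises the KS
  distance of the fitted tail.

Two numerical safeguards matter:

* **Identifiability cap `z <= 3`.** An unconstrained truncated lognormal
  with `mu -> −inf`, `sigma -> inf` converges to a pure power law on any
  tail, so the likelihood comparison between the families degenerates —
  we verified this mimicry empirically (fits with log-mean dozens of
  log-sds below the data). The package therefore requires the truncation
  point to lie at most 3 log-sd above the fitted log-mean. A genuine
  lognormal tail containing more than ~0.1% of its distribution's mass
  has `z` far below 3, so the cap only removes the regime in which the
  hypothesised lognormal's entire body is unobservable.
* **Shared cutoff for the comparison.** `compare_families` fits both
  families above the single cutoff selected by the power-law KS scan
  (`xmin_rule = "powerlaw"`), the convention of the canonical heavy-tail
  toolchain. The alternative "larger of the two scan cutoffs" rule is
  available (`xmin_rule = "max"`) but lets the lognormal scan park its
  cutoff in a far-tail regime it can mimic, which empirically destroys
  the ability to recognise power-law data.

The bootstrap `p_KS` follows the semi-parametric recipe: each replicate
draws from the fitted tail model with probability `n_tail/n` and otherwise
resamples the empirical body, is refitted from scratch (including cutoff
re-selection), and `p_KS` is the exact fraction of replicates whose KS
distance exceeds the empirical one. The default of 50 replicates gives
`p_KS` a resolution of 0.02; raise `n_boot` for finer resolution. The
decision conventions are `p_KS > 0.1` (not rejected) and, for the ratio
test, `R > 0` favouring the first family with Vuong significance `p`.

## The three network formulations

* **I — daily networks.** The day-t graph holds exactly the records of
  day t; edges where similarity strictly exceeds 0.7. Isolated records
  are kept: a day's graph is a census, not a giant component.
* **II — cumulative growth.** Day-0 records form the base network; later
  records join with edges to every existing node (and earlier same-day
  arrivals) above 0.8.
* **III — growth with deletion.** As II, but after each day's insertions
  any node that gained no edge on each of the last `delta = 3` days is
  removed with its edges, in one simultaneous sweep.

Choices the underlying description leaves open, and what this package
does:

* *Strict thresholds* ("more than 70%/80%") — edges require strictly
  greater similarity.
* *Intra-day edges in II/III* — allowed, processed in `(day, id)` order,
  for consistency with formulation I. A base network of mutually similar
  day-0 records would otherwise be edgeless.
* *Deletion timing* — insertions first, then one simultaneous deletion
  sweep computed from pre-sweep state. Sequential removal could cascade
  in an order-dependent way the day-granular description never defines.
* *Birth-day convention* — a node arriving with zero edges starts its
  no-gain window on its birth day: an isolated day-0 node with
  `delta = 3` dies at the end of day 2. This makes "unpopular on
  arrival" and "abandoned later" behave identically.
* *Two degree histories* — `hist_gain` is the cumulative count of edges
  ever attached (non-decreasing; the growth-curve input for fitness
  estimation), `hist_deg` the live degree (drops when neighbours die and
  satisfies the per-day conservation identity
  `sum_i dk_i = 2 created − 2 removed`). Under no deletion the two
  coincide, which is also the internal consistency check used by the
  tests: formulation III with `delta > n_days` must reproduce
  formulation II bit for bit.

## Centrality

Degree, closeness and betweenness are delegated to igraph behind thin
wrappers fixing the conventions (normalisation by `N−1` and
`(N−1)(N−2)/2`; closeness within connected components, optional
Wasserman–Faust scaling for cross-day comparability; both raw and
normalised degree are available because mean-degree time series are
usually plotted normalised). The independent check is a brute-force BFS
implementation in the test suite, exhaustive over small random graphs.

Second-order centrality — the standard deviation of the return times of a
perpetual uniform random walk to a node — is computed exactly.  For node
i, first-step analysis gives the hitting-time moments from every other
node as two linear systems in the walk's substochastic matrix with row and
column i removed; conditioning on the first step yields the mean and
second moment of the return time, hence its standard deviation. Lower
values mark more central nodes. Periodic (bipartite) chains pose no
problem — return-time moments stay finite — and disconnected graphs are
handled per component with a warning. The Monte-Carlo twin
(`second_order_mc`) simulates one long walk and reports per-node sample
standard deviations of the visit gaps; exact and simulated versions must
agree within 5% on small graphs, which is an acceptance criterion.

`top_k` breaks ties lexicographically by node id so that labelling is
deterministic; rank-100 ties are otherwise a real source of
irreproducibility.

## Attachment, fitness, and their joint estimation

The per-day attachment probability of node i is `k_i / sum_j k_j` over
the alive nodes (exactly linear in degree, which is why its fitted slope
equals `1/sum k`). The empirical attachment kernel divides, for each
degree k, the number of new-edge endpoints landing on pre-existing
degree-k nodes by the node-day exposures at k (one exposure per alive
pre-existing node per day with arrivals), normalised to `A_1 = 1`; the
exponent of `A_k = k^alpha` comes from least squares of `log A_k` on
`log k` over degrees with at least 5 exposures, weighted by attachment
counts.

Node fitness is proxied by the growth exponent `beta`: OLS of
`log k(i,t)` on `log t` over the node's alive span, using the cumulative
gained degree. Two time conventions are provided. The default is age
since birth (`t = 1` on the first full day), which is the natural reading
when tracking a cohort born on day 0. For growth benchmarks with
late-born nodes the absolute-day flag is the correct one: under
`k ∝ (t/t_i)^beta` the log-degree is linear in log *absolute* time for
every node, while in log-age it is curved for `t_i` large — using age
there destroys rank recovery of planted fitness, which is why
`fitness_table(..., time = "absolute")` is used in the
Bianconi–Barabási acceptance test.

The joint estimator for `P ∝ A_k × eta` is a deliberately simple
alternating scheme, not a reimplementation of any penalised-likelihood
package. Three devices make it behave:

* **Kernel log-binning** — degrees 0–9 exact, geometric bins (factor
  1.25) above, so sparse high degrees pool their events instead of
  producing one-observation kernel values the fitness update would then
  absorb.
* **Empirical-Bayes shrinkage of eta** — with `obs_i` the node's
  attachment count and `exp_i` its expectation under the current kernel
  (day totals calibrated to observed totals), the update is the
  Gamma-Poisson posterior mean `(obs_i + c)/(exp_i + c)` whose prior
  strength `c` is set each pass from the moment identity
  `Var(obs) = exp + exp^2 Var(eta)`. A homogeneous world shows no
  overdispersion, so `c` grows large and every fitness collapses to 1;
  genuinely heterogeneous fitness keeps its spread. This is what makes
  the null-model recovery test pass without hand-tuned pseudo-counts.
* **Damped updates** — a half-step in log space suppresses the slow
  drift along the `A_k`-versus-`eta` trade-off direction (the model is
  only weakly identified there). Convergence is declared at maximum
  relative change below `1e-4`; hitting the 50-iteration default emits a
  flagged warning rather than an error, per the module contract.

`simulate_pa_growth` provides the generators these estimators are tested
against: linear PA (`alpha = 1`), uniform attachment (`alpha = 0`), and
planted multiplicative fitness, with a `per_day` batch size so a
2000-node growth can emulate a ~month of daily batches. Batching matters:
with one arrival per day, a "20-day-old" node has gained a handful of
edges and every slope estimate is noise.

## Cycles, survivors, topic shift

`detect_cycles` watches the alive-node count. A shrink event fires when
the count falls by at least `drop_frac` (default 0.5) against the maximum
of the trailing `window` days (default 2). Expansion is only armed after
a shrink: recovery by the symmetric relative amount above the post-shrink
trough emits the expand event. A stateless symmetric rule would fire
"expand" during ordinary early growth (a network doubling from day 0 to
day 1 is not a reconstruction), so the two-state machine is deliberate.

Survivor sets `S_[a,b]` are nodes born on day a alive at the end of day
b, directly from the birth/death ledger. TF-IDF top terms over the token
documents of a survivor cohort use raw term frequency, smoothed idf
`log((1+N)/(1+df)) + 1`, unigrams and bigrams, corpus score = sum of
per-document tf·idf, ties lexicographic. The smoothing and aggregation
conventions are stated here precisely because common tool defaults differ
silently.

## The predictor

Each node of each daily network becomes one example: features are the
record's embedding, the label is membership in the day's top-k by the
chosen centrality. Classes are balanced by upsampling the minority with
replacement (originals retained), and the classifier is the fixed
three-hidden-layer MLP (32 units, ReLU, dropout 0.5 after each hidden
layer, 2-way softmax), trained with Adam on minibatches, a 10% held-out
validation split, early stopping with patience 10 and restoration of the
best-validation weights. No neural-network package is assumed by the
target environment, so forward/backward passes are implemented directly
with matrix algebra; inverted dropout keeps prediction-time passes
deterministic, and all randomness (init, split, dropout, batching) is
seeded.

Rolling evaluation trains, for each consecutive `horizon`-day block, on
all days strictly before the block and scores the block's nodes from
embeddings alone — no test-day leakage by construction. Accuracy is
reported at threshold 0.5 on the natural class distribution, together
with balanced accuracy (the reference description is ambiguous about
which its accuracies use, so both are emitted) and rank-based AUROC;
blocks with a single test class are excluded from AUROC. The
`min_train_days` warm-up mirrors the reference protocol of starting
1-day prediction at day 10.

## The synthetic world

`generate_stream` draws, per day and active topic, a Poisson number of
records (the simplest count model with a rate parameter; the reference
setting gives no arrival model), embeds each as
`normalize(center + dispersion * z / sqrt(d))` with isotropic Gaussian
`z`, samples tokens from the topic vocabulary and popularity from a
log-normal (default `meanlog = 1, sdlog = 1`) or Pareto model. The
`1/sqrt(d)` scaling makes `dispersion` the expected angular deviation
regardless of the embedding width — without it, a dispersion that forms
clusters at d = 16 produces pure noise at d = 768. Topic shift is a hard
activity window (on/off), which is what makes the day-`shift` collapse in
the deletion network reproducible enough to test. Planted hubs need no
extra machinery: a second topic at the same center with near-zero
dispersion plants records that accumulate degree.

Benchmark worlds used by the tests:

* `example_stream_config` — ~60 days, a persistent background topic and
  an era shift at day 30; era topics at 15 records/day, the background at
  40% of that so the era collapse removes the majority of the deletion
  network (the reference collapse left a single day-0 node); dispersion
  0.35 (within-topic expected similarity ≈ 0.89, above the 0.8 growth
  threshold); paired zero-dispersion hub topics at one record/day.
* `planted_hub_config` — two topics, each a diffuse background
  (dispersion 2, essentially edgeless at threshold 0.8) plus a
  concentrated hub population (dispersion 0.4, ~20/topic-day). With
  k = 30 the daily top-k is an embedding-identifiable set. This
  geometry was chosen by first computing the Bayes-like ceiling of a
  logistic model on the true radial feature: worlds whose *oracle*
  cannot reach the required accuracy/AUROC (because top-k membership
  depends on the day's joint composition, not on the record alone) were
  rejected before any MLP tuning. The residual gap between oracle and
  MLP is what the acceptance test actually measures.

What a green test does **not** establish: the generator draws topics as
isotropic clouds with hard windows, has no bursty arrivals, no
category/annotation structure, no hashtag-style token correlation, and no
real encoder geometry (anisotropy, hubness). Quantitative results printed
by published analyses of real streams (likelihood ratios per category,
survivor counts, prediction accuracies) depend on proprietary data and a
trained encoder and are out of reach by design; the tests establish
estimator correctness and dynamical mechanisms, not real-world effect
sizes.

## Known limitations

* The deletion engine is day-granular and in-memory; it is sized for
  desk-scale streams (months × thousands of records), not firehoses.
* The exact second-order centrality solves two linear systems per node
  (O(n^4) per component); use the Monte-Carlo twin beyond a few hundred
  nodes per component.
* The joint PA/fitness estimator assumes time-invariant fitness within
  the estimation window — exactly the assumption the deletion-network
  analysis shows to be violated on real streams; treat its output there
  as descriptive.
* `p_KS` at `n_boot = 50` has resolution 0.02 and its own Monte-Carlo
  error; borderline decisions near 0.1 deserve a larger `n_boot`.
* The MLP is a minimal, dependency-free implementation; it reproduces
  the fixed reference architecture and is not a general deep-learning
  framework.
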