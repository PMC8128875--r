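# misinfonet

Network-dynamics analysis of timestamped misinformation streams.

During an infodemic — for instance the wave of COVID-19 misinformation on
social media in spring 2020 — individual false claims arrive daily, cluster
into topics, compete for attention, and fade. `misinfonet` treats each claim
as a node carrying a unit-norm sentence embedding, links claims whose cosine
similarity exceeds a threshold, and studies how the resulting networks are
born, grow, and die. The package is aimed at computational social scientists
and network researchers who want the full pipeline — popularity statistics,
temporal network construction, centrality evolution, attachment/fitness
estimation, topic-shift detection, and central-node prediction — as tested,
reusable R functions, exercisable end-to-end on a bundled synthetic stream
generator with ground truth.

## What it computes

**Heavy-tailed popularity.** Claim popularity counts are compared between a
continuous power law, density `f(x) = ((α−1)/x_min) (x/x_min)^(−α)` for
`x ≥ x_min`, and a log-normal, by maximum likelihood above a cutoff `x_min`
chosen to minimise the Kolmogorov–Smirnov distance over every distinct
observed value. Plausibility is the semi-parametric bootstrap `p_KS`: the
fraction of 50 synthetic replicates whose refitted KS distance exceeds the
empirical one (a model with `p_KS > 0.1` is not rejected). The families are
compared by the signed log-likelihood ratio `R` with a Vuong-type
significance `p`; `R > 0` favours the first family.

**Three network formulations.**
I. one similarity network per day (cosine similarity > 0.7);
II. cumulative growth from the day-0 base network (similarity > 0.8);
III. as II, plus node deletion: a node that gains no new edge on δ = 3
consecutive days is removed with all its edges.

**Centrality.** Degree `deg(n)` (raw and `/(N−1)`), closeness
`1/Σ_u d(u,n)` within components, Brandes betweenness, and second-order
centrality — the standard deviation of return times of a perpetual uniform
random walk, computed exactly from first-return-time moments (lower =
more central) with a Monte-Carlo estimator as an independent check.

**Evolution.** Per-day attachment probabilities `k_i/Σ_j k_j`; the empirical
preferential-attachment kernel `A_k` with its log-linear exponent in
`A_k = k^α`; per-node growth exponents `β` from OLS of `log k(i,t)` on
`log t` (a linear transform of node fitness `η` under `P ∝ A_k × η`); a
joint alternating estimator of `A_k` and `η`; survivor sets `S_[a,b]`;
shrink–expand cycle detection; and TF-IDF (unigram+bigram) top terms for
survivor cohorts.

**Prediction.** Nodes in each daily network are labelled 1 if they are in
the top-k by centrality; an MLP
(`IN(d)–FC(32)–Dropout(0.5)–FC(32)–Dropout(0.5)–FC(32)–Dropout(0.5)–OUT(2)`,
ReLU, softmax, Adam, upsampled classes, early stopping) predicts the labels
of future days from embeddings alone, evaluated by rolling 1/5/10-day
windows with accuracy and AUROC over repeated seeds.

## Worked example

```r
library(misinfonet)

# 60 days of synthetic stream: a background topic plus two topic eras
# with a hard shift at day 30, 768-dim embeddings, planted daily hubs
st <- generate_stream(example_stream_config(seed = 1))
st
#> misinfo_stream: 1355 records over 60 days, embedding dim 768

# heavy-tail selection on the popularity counts
compare_families(st$records$popularity)
#> lrt_result: R=3.012 (favours lognormal), p=0.132, shared xmin=7.89

# deletion-mechanism network and its collapse at the topic shift
tg <- grow_with_deletion(st, threshold = 0.8, delta = 3)
tg
#> temporal_graph: 1355 nodes ever (878 alive), 193578 live edges, day 59, delta=3
detect_cycles(tg)
#>     kind day relative_change
#> 1 shrink  32      -0.6178082
#> 2 expand  44       1.0000000
length(survivors(tg, 0, 30))   # day-0 sentences still alive at day 30
#> [1] 13

# centrality series over the daily networks
daily <- build_daily_networks(st, threshold = 0.7)
head(centrality_series(daily, "degree"), 3)
#>   day      mean  n
#> 1   0 0.4871795 13
#> 2   1 0.5034483 30
#> 3   2 0.4985755 27

# what were the long-lived sentences about?
tfidf_top_terms(st$tokens[survivors(tg, 0, 20)], top_n = 3)
#>      term     score df
#> 1 early35 10.148097  4
#> 2 early23  9.011052  3
#> 3 background10  8.118478  4
```

The `R = 3.01 > 0` says the popularity counts look log-normal rather than
power-law on this stream (they are generated log-normal). The shrink event
at day 32 is the deletion mechanism purging the pre-shift era three days
after its last arrivals — 62% of the network disappears at once — and the
expand event at day 44 marks the recovery past the post-collapse trough.
The survivor cohort's top TF-IDF terms come from the early-era vocabulary,
which is exactly the topic-shift signature the survivor analysis is meant
to surface. Numbers above are what the code actually prints for this seed;
regenerate them with the same calls (the whole example runs in ~4 s).

## Command line

```sh
Rscript inst/scripts/misinfonet run-all --out my-run --seed 1
Rscript inst/scripts/misinfonet validate --stream my-run/stream.jsonl
```

`run-all` writes the stream (JSONL), tail-fit report (JSON), edge lists /
GraphML, centrality and evolution tables (CSV), the prediction report, and
`run_manifest.json` with an MD5 per artifact; reruns with the same config
and seed reproduce identical hashes for deterministic stages.

## Vignette

`vignettes/misinfonet-methods.Rmd` documents the models, estimators,
numerical safeguards, synthetic-world design, and known limitations.
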