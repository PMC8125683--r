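---
title: "Signature-similarity benchmarking for shotgun drug repurposing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-similarity benchmarking for shotgun drug repurposing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugrank)
```

## The model

A virtual-screening pipeline reduces each compound to its drug-proteome
interaction signature: the vector of predicted interaction scores between
that compound and every protein in a screening library. `drugrank` takes
such signatures as given — any docking or scoring method may produce them —
and implements the downstream machinery: similarity ranking, recovery
benchmarking, a chance control, pipeline hybridisation and cross-pipeline
comparison.

The core assumption is that similarity of interaction behaviour across a
proteome implies similarity of therapeutic behaviour. Operationally,
compound similarity is the root-mean-square deviation between signatures,

$$\mathrm{RMSD}(i,j) \;=\; \sqrt{\tfrac{1}{P}\sum_{p=1}^{P}(s_{ip}-s_{jp})^2},$$

and each compound's prediction list is the other $N-1$ compounds sorted by
ascending RMSD. Because RMSD is computed on raw scores, signatures are only
comparable within one matrix; scores from different methods live on
different scales, so cross-pipeline analytics only ever compare rankings
and accuracies, never raw distances.

### Leave-one-out recovery

For an indication with $d \ge 2$ approved drugs, each drug $g$ is held out
in turn and *recovered at cutoff $k$* if at least one co-approved drug
appears within the top $k$ of $g$'s list. With $c$ the number of recovered
held-out drugs, the indication accuracy is $c/d \times 100$. This
per-held-out-drug reading is the only one consistent with $c \le d$:
$c$ counts drugs that find a neighbour, not neighbours found. Indications
with fewer than two drugs are excluded — with nothing to recover, the
protocol is undefined for them.

Three pipeline-level metrics summarise the per-indication accuracies at
each cutoff: their mean (average indication accuracy), their $d$-weighted
mean (pairwise accuracy, which up-weights drug-rich indications), and
coverage (how many indications score above zero, reported both as a count
and as a percentage of the benchmark set).

### Cutoffs

The conventional grid mixes absolute ranks (top10, top25, top50, top100)
with library fractions (1%, 5%, 10%, 50%). Fractions resolve as
$\lfloor f \cdot N \rfloor$ — for the reference 3733-compound library the
1% cutoff is rank 37 — and all cutoffs are clamped to $N-1$, the length of
a similarity list. Resolution de-duplicates and sorts, so a grid is always
strictly ascending.

### The random control

Under the null of uniformly random rankings, each query's list is an
independent uniform permutation of the other $N-1$ compounds. The number
of an indication's $d-1$ co-drugs landing in a held-out drug's top $k$ is
then hypergeometric, so the per-drug recovery probability is

$$P(N,d,k) \;=\; 1-\binom{N-d}{k}\Big/\binom{N-1}{k},$$

computed on the log scale for numerical safety. Because the $d$ held-out
draws are independent permutations, the expected indication accuracy is
exactly $100\,P(N,d,k)$ — no independence approximation is involved at the
level of expectations. Closed forms $100k/(N-1)$ at $d=2$ and $100$ at
$k=N-1$ serve as exact anchors.

`monte_carlo_control()` is the simulation twin: for each replicate and
held-out drug it samples the hypergeometric count of co-drugs inside the
top $k$ — the distribution induced by materialising a full random ranking
table — and returns the replicate mean and standard error. A separate test
at small $N$ materialises literal random permutation tables and pushes them
through the real benchmark, tying the fast simulation to the literal null.
The control's expected coverage is reported as the mean per-indication
probability of nonzero accuracy, which under this null is the same recovery
probability; its `c` column holds real-valued expectations $d \cdot P$.

### Hybrid decision trees

Pipelines with different scoring methods recover different indications.
The hybrid assigns each indication the constituent pipeline with the
highest accuracy at a single *selection cutoff* (default: the most
stringent rank in the grid, conventionally top10), breaking ties — including
the common all-zero case — by an explicit pipeline priority order so runs
are reproducible. The selection is made once and carried to every other
cutoff; at the selection cutoff the hybrid per-indication accuracy equals
the max over constituents by construction, so its average dominates each
constituent there. At other cutoffs no dominance is guaranteed (a pipeline
chosen for its top10 behaviour may trail elsewhere), and the test suite
asserts only well-formedness there. A `reselect_per_cutoff` mode re-runs
the selection at every cutoff for users who want the per-cutoff envelope;
it is off by default because carrying one selection is the decision-tree
reading of the method.

### Cross-pipeline comparison

At any cutoff, two benchmark results over the same indications yield: a
win/tie partition by strict accuracy comparison (with the ties-at-zero
subcount reported separately, since at stringent cutoffs most ties are
double misses); signed per-indication accuracy differences sorted by
descending $d$; and a two-sample Kolmogorov–Smirnov comparison of the two
accuracy distributions. The KS $D$ statistic is the exact sup-distance of
the two ECDFs; the p-value uses the asymptotic Kolmogorov distribution,
adequate at the ~1000-indication scale this is designed for but
approximate in the presence of the heavy ties accuracy vectors exhibit —
it should be read as descriptive, not as an exact test.

Two further analytics work at the drug level. The pair rank consensus
assigns every (drug, indication) association the best rank at which any
co-approved drug appears in that drug's list, per pipeline; plotting the
two ranks shows consensus and divergence association by association. The
indication association network is a declared reconstruction: indication
$i$'s candidate set $C_i$ is the union of its drugs' top-$k$ lists, and
indications are linked with weight $|C_i \cap C_j|$. Other definitions of
"shared highly ranked compounds" are possible; this one is simple,
symmetric and bounded by $\min(|C_i|,|C_j|)$.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `min_drugs` | 2 | smallest benchmarkable indication; 2 is the logical floor for leave-one-out |
| cutoff grid | 10, 25, 50, 100, 1%, 5%, 10%, 50% | ranks / library fractions; the conventional stringency ladder |
| `selection_cutoff` | smallest rank in grid | rank at which the hybrid selects, top10 by convention |
| `signal` | 2 | prototype scale in units of `noise_sd`; ~2 gives strong but imperfect recovery |
| `noise_sd` | 1 | within-cluster signature noise SD (score units are arbitrary) |
| `n_proteins` | 16 | signature length; a small screening-sublibrary scale |
| `mc_replicates` | 1e5 | Monte Carlo precision; SE of the control mean scales as $1/\sqrt{R}$ |

## What the generator emulates — and what it does not

`generate_platform()` plants one Gaussian prototype signature per
indication (i.i.d. $\mathcal N(0, (\text{signal}\cdot\text{noise\_sd})^2)$
per protein) and draws each approved drug's signature as prototype plus
i.i.d. $\mathcal N(0,\text{noise\_sd}^2)$ noise. Expected between-prototype
distance grows with `signal`, so `signal` is cluster separation in noise
units. Background compounds draw a private prototype, i.e. they follow the
same marginal distribution as cluster members; consequently `signal = 0`
degenerates *exactly* to i.i.d. signatures — the hypergeometric null — and
the null mode is a special case, not a separate code path
(`generate_null_platform()` uses unit-variance signatures directly).
Prototypes are scaled Gaussian draws rather than an orthogonal design:
simpler, and the property the tests rely on — average recovery monotone in
`signal` — holds either way. Indication drug sets are disjoint by default;
an `overlap` option adds cross-indication associations to exercise the
shared-drug analytics.

What this does *not* emulate: docking-score marginal shapes (e.g. kcal/mol
binding-energy distributions), correlated proteins, heteroscedastic
compounds, or the heavy-tailed indication-size distribution of real drug
libraries. Passing tests therefore demonstrate the correctness of the
benchmarking machinery under controlled signal, not the performance of any
real scoring method.

## Numerical and design choices

- **Tie-break.** Equal-RMSD compounds are ordered by compound id in
  C-locale byte order (`order(..., method = "radix")`): deterministic
  across platforms and locales. Real-valued scores make ties rare;
  discretised scores make them common, and the oracle tests exercise both.
- **Ranks.** No fractional credit at tie boundaries: the rank is the
  position in the fully tie-broken list.
- **Floor rule and clamping.** Fractional cutoffs floor (1% of 3733 → 37);
  every cutoff is clamped to $N-1$; a cutoff resolving below rank 1 is an
  error rather than silently clamped up.
- **Score I/O.** TSVs are written with `%.17g`, so doubles round-trip
  bit-exactly; readers reject ragged rows, duplicate ids and non-numeric
  cells with located errors. Mapping drugs absent from a matrix are dropped
  with a warning (library-version skew in public data is normal), which may
  legitimately push an indication below the benchmarkable threshold.
- **Degenerate inputs.** All-singleton mappings filter to an empty
  benchmark set (warning, then a hard error if benchmarked); $k = N-1$
  forces 100% accuracy for every indication and is used as an exact anchor
  throughout the tests.

## Problem sizes used by the test suite

Oracle equivalence runs 200 random instances at $N \le 12$ compounds and
$\le 5$ proteins against a naive brute-force reimplementation, exactly.
The control grid covers $N \in \{10,25,50\}$, $d \in \{2,3,5,8\}$,
$k \in \{1,2,5,N-1\}$ at $10^5$ Monte Carlo replicates within 3 SE. The
end-to-end null check benchmarks 200 i.i.d. platforms of 500 compounds,
16 proteins and 30 indications (sizes cycling 2–8) and compares the mean
top10 accuracy to the analytic control within 3 SE. These sizes keep the
whole suite under a few minutes on one core while leaving the Monte Carlo
bands tight enough to detect real defects.

## Known limitations

- The hypergeometric control models fully exchangeable rankings; it is not
  a permutation test preserving the empirical similarity structure (a
  signature-label shuffle would be; noted as an extension).
- KS p-values are asymptotic; with heavy ties they are conservative
  descriptions rather than exact probabilities.
- Alternative similarity measures (cosine, correlation) are deliberate
  non-features: the ranking contract is RMSD.
- Accuracy reflects recovery of *known* co-indicated drugs; it is a
  benchmarking metric, not a clinical effectiveness estimate, and high
  accuracy on synthetic clusters says nothing about any particular docking
  method's real-world signal.
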