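---
title: "Distribution-based OTU calling: model, criteria and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distribution-based OTU calling: model, criteria and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distotu)
```

# The problem

Dereplicated 16S rRNA amplicon data arrive as a FASTA of unique sequences
and a table counting each sequence in each sample. Grouping these into
operational taxonomic units (OTUs) by sequence similarity alone ignores a
second source of information: how each sequence is distributed across
samples. A one-mismatch variant that never co-occurs with its neighbour is
likely a distinct population; a three-mismatch variant that tracks an
abundant sequence in a constant ratio everywhere is likely sequencing error
or the same population. `distotu` merges a candidate into an OTU only when
abundance, genetics and distribution all say it may belong there.

# The greedy caller

Candidates are processed in decreasing order of total count (ties broken by
sequence ID, so the run is fully deterministic). The most abundant sequence
founds the first OTU. For each later candidate:

1. OTUs whose **current** total count is at least `abundance_fold` times
   the candidate's total pass the abundance criterion.
2. Among those, OTUs whose representative is within `genetic_threshold` of
   the candidate under the normalised Levenshtein dissimilarity pass the
   genetic criterion.
3. The genetically eligible OTUs are tested in order of increasing
   dissimilarity (ties by OTU creation order, i.e. favouring the more
   abundant, earlier-founded OTU); the candidate merges into the first one
   whose likelihood-ratio p-value is at least `p_threshold`, adding its
   counts to the OTU's. If none qualifies, the candidate founds a new OTU.

The criteria are ordered cheapest-first: the abundance comparison is a
vectorised inequality, the edit distance costs a dynamic-programming table,
and the distribution test is only run on pairs that survive both. An OTU's
counts change with every merge — the abundance and distribution criteria
always see the accumulated counts — but its representative sequence is
fixed at founding, so the genetic criterion is stable. Merging a candidate
can only increase an OTU's total, so a decision already taken is never
invalidated by later merges.

# The genetic criterion

The metric is `2E / (l1 + l2)` with `E` the Levenshtein edit distance. For
near-identical sequences of similar length it approximates the proportion
of mismatched sites in a pairwise alignment, at a small fraction of the
cost. Comparison details chosen here:

* **Case** is ignored (inputs are uppercased on read).
* **N matches nothing, not even another N.** An ambiguous base carries no
  evidence of identity, so treating N/N as a match would spuriously lower
  distances between low-quality reads. This is implemented by remapping N
  to different sentinel characters on the two sides before the distance
  computation (`utils::adist`, a C implementation of the full
  dynamic-programming recurrence).
* **Characters outside A/C/G/T/N are rejected at input.** Edit-distance
  semantics for degenerate IUPAC codes are not well defined (should R match
  A half the time?), and silently accepting them would make distances
  depend on upstream denoisers' conventions.
* **The threshold is inclusive**: a pair exactly at `genetic_threshold`
  passes. The criterion is phrased as "block the merge when the
  dissimilarity exceeds the threshold", so equality is not an exceedance.

`alignment_dissimilarity()` provides the reference metric used by the
evaluation utilities: a global Needleman–Wunsch alignment
(match-favouring scores: match +1, mismatch −1, gap opening 2, gap
extension 1, via `Biostrings::pairwiseAlignment`) whose dissimilarity is
the number of mismatched aligned columns divided by the number of columns
where neither sequence has a gap. Gap columns are excluded from both
numerator and denominator; consequently the Levenshtein metric — which
charges every indel — can only overestimate relative to this reference on
closely related pairs, which makes it conservative in the direction of
sending borderline pairs on to the distribution test rather than splitting
them outright. For substitution-only divergence the two metrics coincide
exactly; the test suite asserts both properties.

# The distribution criterion

Counts are modelled as Poisson. Under the alternative every count
`x1(i)`, `x2(i)` has its own rate; under the null the candidate's rates are
a common multiple `rho` of the OTU's: `x1(i) ~ Poisson(lambda(i))`,
`x2(i) ~ Poisson(rho * lambda(i))`. Maximising both likelihoods gives the
closed forms `rho = X2/X1`, `lambda(i) = X1 (x1(i)+x2(i)) / (X1+X2)`, and
the deviance collapses to

```
Lambda = -2 [ f(x1+x2) - f(x1) - f(x2) ],   f(y) = sum y_i ln y_i - Y ln Y,
```

with `0 ln 0 := 0` (the continuity limit; a sample in which both vectors
are zero contributes nothing). Numerical notes:

* `Lambda >= 0` holds mathematically (nested models); floating-point
  cancellation can produce values like `-1e-13` on exactly proportional
  vectors, which are clamped to zero.
* **Degrees of freedom** are `n_samples - 1`: 2n free parameters under the
  alternative against n + 1 under the null. With one sample the models
  coincide, `Lambda = 0` identically, and `lrt_pvalue()` returns p = 1 with
  a warning rather than an error — a single-sample dataset degenerates to
  abundance-plus-genetics calling.
* The p-value is the asymptotic upper chi-squared tail, with no continuity
  correction. That asymptotic convenience is the entire speed advantage
  over the simulated test; its adequacy at moderate rates is checked
  empirically (below).
* These p-values are merge thresholds, not inference; no multiple-testing
  correction is applied, matching how the threshold is calibrated.
* `rho > 1` (candidate more abundant than OTU) is mathematically fine and
  is allowed by the functions; in the caller the abundance criterion
  ensures tested candidates are at least `abundance_fold`-fold rarer.

The legacy criterion is kept as `simulate_pvalue()`: the Pearson statistic
of the 2×n table with its null distribution estimated from `B` random
tables drawn uniformly with fixed margins (sequential conditional
hypergeometric sampling, vectorised over simulations with `rhyper`; the
same null as `r2dtable`, which the tests use as an independent oracle).
Zero-total columns are dropped — they cannot receive counts under fixed
margins and contribute nothing to the statistic. The estimator is
`(1 + #{sim >= obs}) / (B + 1)`, never zero, so thresholding is always
well defined; ties with the observed statistic are counted as exceedances
within a small floating-point tolerance. `exact_pvalue()` enumerates all
tables with the given margins (feasible up to ~1e5 tables) and anchors the
Monte-Carlo estimate in the tests.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `genetic_threshold` | 0.1 | dimensionless dissimilarity; 0.1 roughly matches the conventional 97%-identity intuition once indel normalisation is accounted for |
| `abundance_fold` | 10 | OTU total : candidate total ratio required before a merge is considered; 10 means "an order of magnitude rarer, plausibly error" |
| `p_threshold` | 5e-4 | LRT p-value below which a merge is blocked. The asymptotic LRT is more sensitive than the simulated test at equal thresholds; it reproduces a simulated-test criterion of 0.001 best when set roughly twenty-fold smaller (~5e-5). The default splits the difference between the legacy 0.001 and that migration value; evaluation runs against the simulated gold standard use 0.001 on both sides. |
| `max_distribution_tests` | Inf | cap on distribution tests per candidate; all eligible OTUs are tested by default, in similarity order |

# The synthetic community generator

`make_community()` produces datasets with known ground truth at the scale
of a dereplicated mock-community benchmark: by default 187-nt sequences in
6 samples, base populations with per-sample Poisson rates drawn uniformly
from 50–500, and for each base (a) an *error derivative* — within 1–2
edits, counts Poisson with rates `rho = 0.1` times the base's (exactly the
distribution criterion's null, so type-I/power statements are meaningful) —
and (b) an *ecological twin* — within 1–2 edits but with counts confined to
a random half of the samples and a total around 5% of the base's. Ground
truth: derivatives belong in the base's OTU, twins do not. Base sequences
are kept mutually dissimilar (pairwise metric > 0.2) so the only genetic
neighbours are intentional. Edit operations are sampled uniformly among
substitution, insertion and deletion at uniform positions.

What the generator does **not** emulate: realistic error profiles
(homopolymer indels, quality gradients, position-dependent error),
chimeras, compositional correlation between samples, and overdispersed
(non-Poisson) biological replication. Passing recovery tests therefore
demonstrates that the caller implements its model correctly, not that the
model captures every property of real sequencing runs.

**Recovery study design.** The recovery tests run the caller at
`abundance_fold = 5`. With the generator's derivative ratio `rho = 0.1`,
a fold of 10 puts every intended merge exactly on the abundance boundary
(`E[X2] = X1 / 10`), so whether a derivative is even *eligible* for
merging is a coin toss dominated by Poisson noise in the totals — the
study would measure abundance censoring, not the genetic and distribution
criteria it is meant to exercise. At fold 5 the intended merges are
essentially always eligible and failures can only come from the criteria
under test. On 50 seeds of the default configuration the suite requires at
least 95% of error derivatives to merge and 95% of twins to separate.

# Evaluation utilities

`evaluate_genetic()` scores the fast metric against the alignment
reference at several thresholds (confusion counts with "similar" as the
positive class, sensitivity/specificity) and reports the Pearson
correlation between the metrics on pairs whose reference dissimilarity is
at most 10%, with a Fisher-z 95% confidence interval (`stats::cor.test`;
the interval method is the standard parametric choice).
`evaluate_distribution()` replays the distribution tests recorded in a
merge log — the log stores the exact count vectors at test time, so the
sweep is replayable without re-running the caller — against the simulated
gold standard, and sweeps the LRT threshold. Sweep thresholds default to
geometric midpoints between consecutive observed p-values (plus endpoints
below the minimum and above the maximum): p-values span orders of
magnitude, and midpoints realise every achievable confusion table without
the ambiguity of placing a threshold exactly on an observed value. F1 uses
"dissimilar" as the positive class: `2 TD / (2 TD + FD + FS)`.

# Problem sizes and checks

The test suite works at deliberately small scales: edit-distance oracles on
1,000 random string pairs (lengths 3–12), LRT calibration with 1e4 null
replicates at 6 samples (type-I error within three Monte-Carlo standard
errors of 0.05), simulated-vs-exact tail agreement on tables small enough
to enumerate, 1e6-simulation runs of the simulated test on the worked
example, and 50-seed recovery studies on 10-base communities. The
command-line pipeline and merge-log replay are exercised end to end on
generated fixtures.

# Known limitations

* The Levenshtein metric saturates for distant pairs (it cannot exceed
  ~2 max(l1,l2)/(l1+l2) and underestimates large alignment distances), so
  the genetic threshold should be treated as an inclusion filter; the
  distribution criterion is the final arbiter for borderline pairs.
* The asymptotic chi-squared tail is approximate for very sparse counts;
  the simulated test remains available where exactness matters more than
  speed.
* The caller is single-threaded by design: results must be identical,
  bit for bit, across runs, and candidate order is part of the algorithm.
* Counts must be integers; the Poisson model is undefined for normalised
  or relative abundances, which are rejected at input.
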