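---
title: "Causal networks of G-quadruplex thermostability: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal networks of G-quadruplex thermostability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4causal)
```

## The scientific question

G-quadruplexes (G4s) are four-stranded structures formed at guanine-rich DNA.
Their in vitro thermostability can be read out genome-wide as the G4-Seq
mismatch percentage (MM%): polymerase stalling under K+ (stabilising) versus
Na+ conditions produces base-calling discrepancies proportional to how stably
a locus folds. The question this package operationalises is whether that
sequence-intrinsic stability *causally* shapes what happens at endogenous G4
(eG4) regions in vivo — chromatin state, accessibility, transcription-factor
(TF) recruitment, antibody-based eG4 signal — or merely correlates with it.

The analysis has two halves:

1. **Signal mapping** — project per-locus tracks onto eG4 regions under
   explicit window/midpoint rules (`build_region_table()`).
2. **Causal structure learning** — discretize the merged multi-cell-line
   table and learn a causal Bayesian network with the PC-stable algorithm
   driven by a Monte-Carlo permutation test of Pearson's chi-squared,
   wrapped in a stratified-sampling bootstrap with consensus layers
   (`run_trials()`, `common_network()`, `resolve_directions()`).

Because the real inputs are multi-gigabyte sequencing accessions, the package
ships a fully specified synthetic world — a ground-truth DAG with conditional
probability tables (CPTs) and a toy genome generator — so that every stage is
testable against a recoverable truth.

## Mapping rules and their conventions

All coordinates are 0-based half-open internally; BED and bedGraph are read
natively, GFF3 is converted on read. Conventions the upstream description
leaves open are fixed as follows and are deliberately boring:

* The midpoint of `[s, e)` is `floor((s + e) / 2)`.
* The *w* bp window centred on position *m* is `[m - w/2, m + w/2)` —
  symmetric and exactly *w* long. Stability uses *w* = 150, phyloP *w* = 50.
* Stability of a pG4 is the **maximum** same-strand MM% in its window;
  phyloP is the **per-base mean** over covered positions, strand-agnostic.
* A region inherits the value of the overlapping pG4 whose midpoint is
  nearest the region midpoint; ties break to the lower start coordinate,
  then to the + strand (determinism, nothing more). Only pG4s that actually
  carry a value are candidates — otherwise a region with one uncovered and
  one covered pG4 would be reported missing despite available data.
* The chromatin state of a region is the segmentation label at its midpoint;
  with half-open segments a midpoint at a boundary belongs to the
  right-hand segment.
* ATAC intensity is `(fragment coverage summed over region positions /
  region length) / mean_depth`. The "average sequencing depth" has no stated
  denominator upstream; by default it is total fragment bases divided by
  genome size, and callers may supply their own.
* TF occupancy is the number of a TF's peaks overlapping the region. The
  recruitment metric ("the amount of the hits") is ambiguous between total
  peak hits and distinct TFs; **both are implemented**
  (`tf_metrics(recruitment = "hits" | "distinct")`), total hits being the
  default. The choice is a visible flag because the two readings genuinely
  differ.

Missing stability/phyloP values propagate as `NA` through the region table
and are dropped (with a reported count) only at discretization time, because
the conditional-independence tests need complete cases.

## Discretization and stratified sampling

`discretize()` splits each numeric metric at its *cell-line-specific* median:
High iff strictly greater (ties at the median go Low; `median_ties = "high"`
flips this — the upstream rule is unstated, so it is a flag, and under the
default the per-stratum High fraction can never exceed 1/2). Stability alone
uses a fixed empirical cutoff, MM% >= 25 by default, on the logic that MM% is
an absolute in vitro quantity rather than a per-cell-line one.

`stratified_sample()` draws without replacement within each stratum — the
upstream protocol caps the equal-allocation size at the smallest stratum,
which only makes sense without replacement; bootstrap-with-replacement is
available as an option. Proportional allocation rounds with round-half-even
for cross-platform determinism.

## The conditional-independence test

For discrete X, Y and conditioning set S the statistic is the conditional
Pearson chi-squared: the two-way chi-squared between X and Y summed over
every configuration of S, expected counts from within-stratum margins;
zero-margin cells contribute nothing. The null distribution is Monte-Carlo:
permute X within each S-stratum, re-tabulate, recompute; the p-value is

p = (1 + #\{T_b >= T_obs\}) / (B + 1),

which lies in (0, 1] and counts ties as exceedances, making the test valid
(conservative) at any B.

*Implementation note.* Permuting X within a stratum and re-tabulating
induces exactly the fixed-margin (multiple hypergeometric) distribution on
the stratum's contingency table. The test therefore samples tables directly
— `rhyper()` for two-level variables, `r2dtable()` (Patefield) in general —
at O(levels^2) per draw instead of O(n). A literal shuffle implementation is
kept in the test suite as an independent oracle; the two agree within
Monte-Carlo error.

Two consequences worth knowing:

* The p-values are **discrete and super-uniform**: with a 2x2 statistic at
  n = 500 the permutation distribution has large atoms, so the p-value CDF
  sits at or below the uniform CDF (atoms at p = 1 etc.). Calibration checks
  should test the one-sided, anti-conservative direction; a two-sided
  goodness-of-fit test against a continuous uniform will reject any valid
  discrete permutation test.
* Defaults are alpha = 0.05 and B = 1000 (p-value floor 1/1001). The
  upstream analysis states neither; these are conventional knobs, not claims
  about the original runs, and both are exposed in `ci_test_config()`.

Degenerate inputs: a constant X or Y yields p = 1 with a warning (no
evidence of dependence), never an error, so a bootstrap replicate with an
unlucky sample cannot abort a run.

## Structure learning

`pc_stable()` implements the order-independent PC variant: the skeleton
search proceeds level-wise with neighbour sets frozen per level, so the
result is invariant to column order (a tested property). Separating sets are
recorded; v-structures x -> z <- y are oriented where z is outside the
recorded separating set of a non-adjacent pair; Meek rules R1-R4 run to a
fixed point. Two deliberate conservatisms:

* conflicting v-structure orientations leave the edge **undirected** with a
  message (the consensus layer later treats undirectedness as direction
  uncertainty anyway);
* an orientation that would create a directed cycle is skipped rather than
  forced.

The maximum conditioning-set size defaults to |V| - 2, i.e. unrestricted for
the 6-10 node problems this package targets; `max_cond` caps it for safety
on wider tables.

`dag_to_cpdag()` — the test oracle for `pc_stable()` — uses Chickering's
order-edges/label-edges characterization of compelled edges, a different
algorithm from the Meek closure, so oracle and implementation cannot share a
bug. With the exact d-separation test, `pc_stable()` returns the true CPDAG
for every labelled DAG on four nodes (543 of them) and random five-node
DAGs; this is asserted in the acceptance tests.

## Consensus, robustness, and the common network

One *trial* draws `n_sample_sets` (default 10) stratified samples, learns
one candidate network from each, and forms the *average model* at threshold
N: adjacencies present in at least N candidates, oriented by plurality vote
(ties undirected). Accuracy and coverage of the candidates are measured
against the same trial's average model at the same N — the self-consistency
reading of the robustness protocol; a cross-trial reference can be had by
scoring against `common_network()` output instead. Edge membership is
compared at the skeleton level by default because the upstream
edge-counting granularity is unstated and skeleton matching is the weaker,
more stable choice; `directed = TRUE` switches to strict matching.

Across `n_trials` (default 50) trials the record aggregates means and
standard deviations, and the coverage-vs-accuracy curve over N is summarized
by a trapezoidal AUC **normalized by the spanned accuracy range**. The
normalization makes the index scale-free and comparable across sampling
strategies, but its absolute value need not match any other convention —
treat it as a ranking device, which is how it is used (`select_N()` picks
the N nearest the (1, 1) corner).

`common_network()` intersects the per-trial average models' skeletons and
attaches to each surviving edge a direction frequency (forward = 1,
backward = 0, undirected = 1/2, averaged over models).
`resolve_directions()` keeps the majority direction, leaves exact ties
undirected, and — in TF-specific network mode — refuses to direct any edge
into a protected node (by default the stability node when requested):
thermostability is sequence-intrinsic and measured in vitro, so an in-vivo
signal "causing" it would be incoherent, and such edges are conservatively
reported undirected.

## The synthetic world

`g4_ground_truth()` ships the six-node network that the analysis of real
K562/HepG2/HEK293T data reports: Stability -> \{ChromState, TFs, eG4s\},
phyloP -> \{ChromState, TFs\}, ATACSig -> \{ChromState, TFs\},
ChromState -> TFs (8 edges). The generative model had to be invented — the
upstream work characterizes no joint distribution — and is deliberately
simple:

* roots (Stability, phyloP, ATACSig) are Bernoulli(0.5) over Low/High;
* each binary child is logistic in the centred, scaled count of High
  parents with a single shared slope (`effect`, default 1.5);
* ChromState is categorical over 8 collapsed state groups (a full 18-level
  CPT would leave parent configurations unobserved at realistic n); its
  log-probabilities are linear in an ordered state score times the same
  parent summary, and it feeds the TFs CPT through that score.

The default `effect = 1.5` was chosen once, by the design criterion the
simulator exists for: every edge must be comfortably detectable at the
study's own sample size (about 7000 regions per cell line, three cell
lines). Default stratum sizes for end-to-end simulations mirror the real
eG4 region counts (K562 7639, HepG2 21996, HEK293T 8986) so that
equal-allocation sampling at k = 7000 subsamples meaningfully rather than
degenerating to the identity permutation. Optional per-stratum CPT
overrides on root nodes emulate cell-line-specific marginals.

The true CPDAG of this DAG has six compelled edges (the three roots into
ChromState and into TFs) and two reversible ones (Stability - eG4s,
ChromState - TFs). A correct learner therefore *should* leave those two
undirected; recovering them as directed would be an error of the method,
not a success.

What the toy genome (`make_genome_fixture()`) does and does not emulate: it
exercises every mapping rule (strand-matched windows, midpoint lookups,
decoy regions that the pG4 filter must remove, partial track coverage) on a
~50 kb genome, but its signals are independent random tracks — it makes no
attempt to reproduce the correlation structure of real chromatin. A green
mapping test establishes that the geometry of the mapping is right, not
that the biology is.

## Numerical and degenerate-input choices

* Permutation tie-counting uses a relative tolerance of 1e-8 on
  T_b >= T_obs to absorb float noise; ties count as exceedances
  (conservative).
* `robustness_auc()` errors on a curve with zero accuracy span rather than
  returning 0/0.
* `average_model()` orientation votes: a three-way plurality over forward /
  backward / undirected; any tie falls back to undirected.
* Strata with fewer than two complete rows abort discretization with an
  error naming the stratum — silent degeneracy would poison every
  downstream median.
* All bootstrap randomness derives from one master seed (one sampling seed
  and one permutation seed per trial x sample set, drawn up front), so a
  rerun of `run_trials()` or `run_pipeline()` with the same configuration
  is bit-identical; this is asserted on file checksums in the tests.

## Known limitations

* The CI test's p-value floor of 1/(B+1) means alpha below ~0.001 requires
  raising B; the cost is linear in B.
* PC-stable fixes skeleton order-dependence but v-structure orientation can
  still conflict on noisy data; conflicts are surfaced as messages and
  resolved to undirected edges rather than hidden.
* The AUC is a comparative index; its absolute value depends on the
  normalization documented above.
* The synthetic CPTs are stand-ins chosen for detectability, not estimates
  of the real joint distribution; conclusions about power on real data do
  not transfer.
* Acyclicity is a modelling constraint: genuinely bidirectional regulatory
  relationships (e.g. accessibility and histone state) can only appear in
  one direction per learned network.
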