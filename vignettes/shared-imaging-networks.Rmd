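---
title: "Detecting shared CT/MRI use and analyzing referral networks from claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting shared CT/MRI use and analyzing referral networks from claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shareduse)
```

## The problem

Japan operates one of the densest CT/MRI fleets in the world, and prefectural
governments are required to plan for the *shared use* of this equipment:
smaller clinics sending patients to better-equipped facilities for a scan and
receiving them back for continuing care. Administrative insurance claims
(receipt data) record every patient–facility–date service contact and flag
imaging examinations, so collaboration between facilities leaves a
recognizable temporal footprint even though no "referral" field exists in the
data.

`shareduse` implements an analytic framework for quantifying that
collaboration: a rule-based detector of shared-use episodes, per-stratum
(fiscal year × modality) directed referral networks with density and
reciprocity metrics, Louvain community detection, and annual summary tables
with nonparametric comparisons. Because real receipt data cannot be shared, a
seeded synthetic-claims generator with planted ground truth is a first-class
part of the package: every claim the detector sees in the tests was
constructed so that the correct answer is known exactly.

## The detection rule

A **shared-use event** is an imaging examination at a *target* facility
embedded in an ongoing course of visits at a *source* facility. For an exam
by patient $p$ at facility $T$ on date $d$, three conditions must hold:

1. **Isolation.** The exam is the only diagnostic-imaging visit by $p$ at
   $T$ within a continuous 3-month period. We read this in its strongest
   form: *every* 91-day window containing the exam holds only that one
   imaging visit, which is equivalent to "no other imaging exam (CT *or*
   MRI) by $p$ at $T$ within ±91 days". The weaker existential reading
   ("there exists some 3-month window…") is almost vacuously true and
   detects nothing useful.
2. **Continuity.** Some other facility $S \neq T$ has *multiple* visits by
   $p$ within a continuous 6-month period: two or more distinct service
   dates $u < v$ with $v - u \le 182$ days. A same-day consult and
   procedure count as one visit.
3. **Containment.** The exam date falls inside that visit course:
   $u \le d \le v$. In addition $S$ must have performed *no* imaging exam
   for $p$ inside $[u, v]$ — the source requests the exam, it does not
   perform it.

Months are fixed at 91/182 days because calendar-month arithmetic is
ambiguous across month lengths. Both windows are configurable
(`detection_params()`), and the window monotonicity is testable: shrinking
the isolation window only relaxes Condition 1 (supersets of events),
shrinking the continuity window only restricts Conditions 2–3 (subsets).

When several facilities qualify for one exam, the default `"nearest"` policy
keeps the facility whose qualifying visit is closest in time to the exam
(ties: larger visit count, then smallest facility id), giving at most one
event per exam; the `"all"` policy emits one event per qualifying source.
The reported source window is the *tightest* qualifying bracket (minimum
span, ties to the later start). Strata are assigned by the exam date using
the Japanese fiscal year (April 1 – March 31, labelled by the starting
year); the surrounding visit course may cross the boundary and still count.

Two independent implementations exist: `detect_shared_use()` derives the
tightest bracket analytically (for each candidate start $u$, only the
earliest visit on or after the exam date can end a tightest window), while
`brute_force_oracle()` enumerates every exam × facility × visit-date pair
with no pruning. The test suite asserts exact set equality between the two
on 100 seeded noisy configurations, including injected violations of each
condition.

## Network measures

For each stratum, facilities with at least one event become nodes and each
ordered pair (source, target) an edge weighted by its event count.
Facilities with no events are excluded from $n$; including every facility in
the prefecture would change density arbitrarily and is unknowable from
events alone.

* **Density** $= m / (n(n-1))$ — realized directed connections over all
  possible ordered pairs, unweighted.
* **Reciprocity** — with $a$ mutual dyads and $b + c$ one-way dyads, the
  default *dyadic* convention reports $a/(a+b+c)$, the proportion of
  connected facility pairs linked in both directions. The description
  "$a$ bidirectional, $b$ and $c$ unidirectional" is ambiguous between
  pair-wise and edge-wise counting, so the *edge-wise* convention
  $2a/(2a+b+c)$ is available behind a flag. Reciprocity depends only on the
  unweighted dyad census.
* **Modularity** $Q = \frac{1}{2W}\sum_{ij}\left[w_{ij} -
  \frac{k_i k_j}{2W}\right]\delta(c_i, c_j)$, evaluated on the symmetrized
  undirected projection ($w_{ij}$ = sum of both directed weights), the
  convention under which classical Louvain is defined and which the common
  network libraries use for directed input.

`louvain_communities()` is the classical two-phase algorithm: greedy local
moving (accept the best move with modularity gain $> 10^{-10}$; node order
shuffled deterministically from `seed`) until no move improves, then
aggregation of communities into super-nodes, iterated until a pass no
longer raises $Q$. Per-pass $Q$ values are recorded (attribute `pass_Q`)
and are non-decreasing — that is the algorithm's only guarantee; the final
$Q$ need not beat the trivial one-community partition.

Greedy local moving has strict local optima even on very small graphs — we
observed random 7-node graphs where *no* starting order reaches the global
optimum, and igraph's `cluster_louvain` lands on the same suboptimal value.
`louvain_communities()` therefore multistarts: the first run uses the
classical all-singleton start, later restarts (default 20) begin local
moving from a random initial partition, and nodes may also detach into a
fresh singleton community; the best final $Q$ wins. On random suites of
graphs with ≤ 8 nodes this lands within 5% of the exhaustive-search optimum
(`best_partition_exhaustive()`, which enumerates all set partitions via
restricted growth strings and is the oracle in the tests — never the
implementation).

## The synthetic-claims generator

`generate_claims()` emulates the structure of the study data rather than
its scale: patients continuously enrolled over FY2016–FY2019, repeated
visits at a source facility, isolated imaging exams at a target facility,
and facility bed counts (≈55% zero-bed clinics, log-normal hospital sizes
capped at 600 beds). It does **not** attempt realistic disease
trajectories, costs, geography, or the study's real volumes — in the real
data shared exams are ≈0.5% of all exams, while in a scaled-down synthetic
cohort most exams are planted events. Passing tests therefore demonstrate
the *correctness of the machinery* on data with known truth, not the
reproduction of the study's empirical magnitudes, which require the
undeposited claims.

Design points that matter:

* **Exact ground truth.** Episodes are forward-simulated (two source visits
  at gaps of 7–80 days bracketing the exam), then every patient with
  imaging rows is verified against `brute_force_oracle()`; when background
  noise accidentally corrupts an episode (e.g. two noise visits at a third
  facility forming a closer qualifying source), that patient's noise is
  redrawn, with a bounded retry count. Truth is exact by construction, not
  with high probability.
* **Violations.** `violation_mix` plants episodes failing exactly one
  condition — a second target exam within 91 days (Condition 1), a
  bracketing pair spanning 184–240 days (Condition 2), or a tight visit
  course entirely before the exam (Condition 3). It is specified as integer
  counts per condition: a proportion of an unspecified total would be
  underdetermined.
* **Substreams.** All randomness derives from one master seed through
  per-patient substreams, so claims are byte-identical across runs and
  adding patients does not reshuffle existing ones.
* **One episode per patient.** Detection is per-patient separable, so
  hosting each planted episode on its own patient keeps episodes
  independent; generation errors out as infeasible if episodes outnumber
  patients.
* **Stratum per dyad.** `plant_network()` assigns the (modality, fiscal
  year) stratum per *dyad*, so both directions of a mutual pair land in the
  same per-stratum network and planted reciprocity is recoverable. The
  number of mutual dyads is `round(reciprocity_fraction * n_dyads)` with a
  random selection of which dyads — deterministic rounding keeps the
  realized dyadic reciprocity within $1/(2 \cdot n_{dyads})$ of the request
  instead of Bernoulli noise.

One caveat the per-stratum analysis exposes: planted community structure
lives on the *pooled* network, and a single stratum sees only the dyads
assigned to it, so per-stratum community recovery on a small multi-stratum
simulation is fragmentary (ARI ≈ 0.2–0.4 in the `analysis/` workflow). The
community-recovery experiment therefore uses a single-stratum
configuration: 4 communities × 25 facilities, within-community dyad
probability 0.3, between 0.01, 3 events per edge — under which Louvain
recovers the planted partition with ARI ≈ 1.

## Statistics and report tables

`volume_summary()` reports, per stratum, total imaging exams among the
filtered population, detected shared events, and the proportion of
collaborative use **per 100 examinations** (100 × shared/total; the
published table prints 0.524 for 1507/287,782, which matches the percentage
reading, not the raw fraction). Full precision is kept alongside the
3-decimal display column. `facility_summary()` reports per-role facility
counts, per-facility request means and sample SDs ($n-1$; `NA` below two
facilities), and bed-count summaries. `kruskal_wallis()` and
`mann_whitney()` wrap `stats::kruskal.test` and `stats::wilcox.test`
(normal approximation, tie and continuity corrections, $U = \min(U_x,
U_y)$), adding explicit degenerate-input handling; both hold their nominal
5% type-I error within [0.035, 0.065] under 1000 null simulations in the
acceptance suite.

## Numerical and scale choices

Problem sizes in the tests are chosen to keep the whole suite around a
minute while still exercising every path: the oracle-equivalence sweep uses
100 configurations of 8–16 facilities and ~25–60 patients each; the
community-recovery experiment uses 20 seeds of the 4×25 design; the
Louvain-vs-exhaustive comparison uses 200 random graphs with 4–8 nodes
(Bell(8) = 4140 partitions each, evaluated via a single matrix product per
graph). Degenerate inputs are signalled, not silently computed: density
needs $n \ge 2$, reciprocity needs a connected dyad (both return `NA` with
a warning so multi-stratum pipelines can record the gap), all-identical
samples yield $H = 0, p = 1$ flagged as degenerate, and an exam with no
qualifying source simply emits no event.

## Known limitations

* The detection criteria are the study's operationalization; claims carry
  no referral intent, so a detected event is a temporal-pattern inference.
  Varying the windows (the package makes this one argument) can move the
  counts.
* The "failed to follow medical advice" exclusion of the original study
  population is not computable from claims and is not represented.
* The generator's realism is structural, not volumetric; empirical
  magnitudes from the study (density ~3×10⁻³ on hundreds of nodes,
  shared-use proportions ~0.5%) are not reproduced at desk scale.
* Reciprocity's published convention is ambiguous; both conventions are
  implemented and the choice is surfaced, but comparisons against published
  values inherit that ambiguity.
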