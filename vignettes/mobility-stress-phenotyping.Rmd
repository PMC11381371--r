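---
title: "Mobility multigraphs and stress phenotyping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mobility multigraphs and stress phenotyping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobstress)
```

`mobstress` implements a two-stage pipeline from raw smartphone sensor
streams to stress classification. This vignette documents the model, the
parameters that matter, the numerical choices, and what the synthetic
cohort generator does and does not establish about real data.

## Stage 1: fixed-area location nodes

Smartphone GPS is noisy: the same physical place yields slightly different
coordinates at every estimation. The pipeline therefore represents a
location as a disc of fixed area (`area_m2`, default 5000 m², radius
`sqrt(area_m2/pi)` ≈ 39.9 m) and treats all coordinates falling into the
disc as one location.

The area is a modelling constant, not an algorithm, so a clustering rule
had to be chosen. We use greedy sequential assignment: scanning fixes in
time order, a fix joins the *first* existing node whose anchor lies within
the radius, otherwise it founds a new node anchored at that fix. Anchors
are frozen at founding. The alternatives — centroid-drifting leaders or
density-based clustering (DBSCAN and relatives) — were rejected
deliberately: drifting centroids make the result depend on subtle update
order and can chain far beyond the stated area, and density-based methods
have no notion of a fixed area at all. Greedy frozen-anchor assignment is
deterministic, order-stable, and guarantees the radius bound that the
tests assert (`every fix within r of its node's anchor`). Its one known
bias is that a place whose first observed fix sits off-centre may shed
fringe fixes to a neighbouring node; at the default area this needs
>40 m of within-place spread, which the area constant is there to absorb.

Visits: consecutive fixes at one node merge into a visit; a new visit at
the same node requires either an intervening visit elsewhere or a gap
longer than `visit_gap_minutes` (default 30 min — long enough to bridge
sampling dropouts at one place, short enough that morning and evening at
home count separately). Home is the node with the most visits (ties:
higher fix count, then lower node id). Nodes with fewer than
`relevance_min_visits` visits (default 2: removes one-off GPS noise) are
flagged irrelevant; home is never flagged.

Pairwise place distances use the haversine great-circle formula at Earth
radius 6371.0088 km, computed between node *anchors* ("the distance
between these places"), and are reported as missing when a user has fewer
than two places.

## Stage 2: the mobility matrix and multigraph

Each visit becomes a row of the mobility matrix: local calendar date,
time of day in minutes since local midnight, node id, and order within
the day. "Local" is defined by a per-cohort IANA timezone
(`timezone`, default `Australia/Sydney`); timestamps are stored UTC and
rendered local only for day bucketing, because day-level features need a
midnight and sensor streams do not carry one.

The multigraph: every consecutive visit pair (u → v) across the whole
trace adds one to the weight of directed edge (u, v). Transitions span
midnight deliberately — routes are not day-bounded and night movement is
informative. Irrelevant nodes are excluded before edge building by
default; transitions touching an excluded node are dropped, not bridged
(bridging would invent routes never travelled), and the exact drop count
is reported so the conservation identity
`sum(weights) + drops = visits − 1` is checkable. Self-loops can only
arise from the visit gap rule (a long pause at one place) and are off by
default.

Percentiles of the edge-weight multiset and of daily step totals use
linear interpolation between closest ranks (R quantile type 7). This is a
substantive choice, not a convenience: fractional 75th-percentile path
weights (such as 8.25 on integer weights) only arise under an
interpolating definition.

Steps are never merged with GPS: the two streams need not overlap in
time, so step counts are summed per local day and summarized
independently (quartiles, extremes, mean); days without records are
missing, not zero.

One interpretive decision: "number of paths" is defined as the number of
distinct directed edges (ordered place pairs), not multi-hop routes. The
engineered feature combines the per-place daily visit rate with the
75th-percentile path weight, standardized across the cohort and
multiplied (a `sum` mode exists); with a single user the standardized
product degenerates to zero, which is harmless since the feature is
cohort-level by construction.

## Stress scoring

The stress subscale raw score is twice the sum of seven items rated 0–3,
an even integer in [0, 42]; the population z-score is
(raw − 11.19)/8.25 using young-adult norms, so z lives on a lattice of
step 2/8.25 ≈ 0.242. Discretization schemes: three-class
(none < 0.5 ≤ mild–moderate ≤ 2 < severe), binary (mild–moderate
excluded), and polarized binary (severe requires z > 2.2; the 2.0–2.2
cusp is excluded). Boundary closure follows the printed strict outer
inequalities: the middle interval is closed. When several questionnaire
waves exist, the first wave defines the outcome by default
(`dass_wave`), since no pairing of wave to sensing window is canonical.

## Screening statistics

Pearson correlations (complete-case, t-transform p values), Kruskal–
Wallis (tie-corrected, chi-square approximation), and Dunn's post-hoc z
tests with tie correction, two-sided, Benjamini–Hochberg-adjusted within
each feature's pairwise family. BH across features is a separate,
optional family — the correction family is a genuine modelling choice and
keeping the two separate makes each reproducible. A note on power: with
fully separated groups the Dunn z for *adjacent* groups depends only on
group sizes, and at 5 per group its two-sided p is ≈ 0.077 — significance
on all three pairs requires roughly 10 per group. The test suite checks
the normal-approximation p against a 10⁵-draw label-permutation oracle at
5 per group and tolerates 0.04 absolute disagreement, the scale of the
exact distribution's discreteness at that size.

## The classifier bench

Six families: elastic-net logistic regression (α ∈ {0, 1},
λ ∈ [0.001, 1]; glmnet), shrinkage discriminant analysis — pooled
covariance shrunk toward its diagonal with intensity λ, or purely
diagonal — KNN (k ∈ 1..15), CART (complexity ∈ [0.001, 0.1]; rpart),
random forest (mtry ∈ 1..p), and a feed-forward network with 0 or 1
hidden layer (nnet: logistic activation, L2 weight decay as the
regularizer; the desk-scale grid uses 3/10/25 neurons, and `full_grid`
widens to 50). Optimizer and activation axes of a deep-learning grid
collapse under nnet's BFGS training; this is a documented substitution of
implementation, not of model class — the hypothesis space (small
single-hidden-layer feed-forward networks) is the same.

Harness semantics, all asserted by tests: stratified 70/30 split;
random minority oversampling (duplication only) applied to training data
*inside each CV fold*, never to validation folds or the held-out set,
with a row-identity audit; grid tuning by 3-fold CV repeated 5 times
maximizing mean AUC; ties broken toward the simpler grid point (stronger
shrinkage, fewer neighbours considered first in preference order, larger
complexity penalty, fewer neurons). AUC is the Mann–Whitney rank
statistic (ties counted half); precision/recall/F1 use a 0.5 threshold
(`threshold`), positive class = severe stress. All randomness flows from
one master seed through named substreams (`derive_seed`), so changing,
say, the oversampling draw cannot silently perturb the split.

Cross-validated AUC can sit well below held-out AUC on small polarized
cohorts: with ~11 severe users in training, each CV fold estimates the
severe class from ~7, and the nonconforming users drag the fold AUCs
down while the final model, fit on all training rows, still generalizes.
Fold-to-fold deviation (100·(max−min)/mean of fold AUCs) is reported so
this instability is visible rather than hidden.

## The synthetic cohort generator

The generator emulates the study conditions: 150 users, 30 days, a
latent stress z drawn from a normal (mean 0.9, sd 1.0) truncated to
[−1.5, 3.5] — a screened, distressed cohort in which all severity classes
are populated. Coupling (signs fixed +, +, −): expected places
12 + 3z (noise sd 7.5, clamped 3..40), per-place daily visit rate
1.3 + 0.35z (noise sd 0.85, floor 0.4), daily steps 7500 − 900z (user
noise sd 3500, day noise sd 1200). The noise scales were calibrated once
by Monte-Carlo so the severity-polarized subset shows place-count
correlations near 0.4 and step correlations near −0.3 at n = 150, and
are frozen; they are study conditions, not tuning knobs.

Mechanics: places on a 500 m grid (far beyond the 79.8 m cluster
diameter); home-anchored Markov day schedules (each day starts at home,
successive places drawn by a popularity law with home as the heavy hub,
no immediate repeats) so multigraphs have realistic hub structure rather
than degenerate uniform weights; 1–3 fixes per visit with half-normal
radial GPS jitter (sd 10 m) hard-capped at 18 m — under half the cluster
radius, which makes exact place-count recovery a theorem rather than a
probability; DASS items constructed so the scored z equals the latent z
up to the raw-score lattice.

What passing tests on this cohort do *not* show about real data: real
GPS has heavy-tailed, occasionally unbounded error and accuracy-dependent
dropout; real visit schedules have dwell times, weekly rhythm and
travel-mode structure; real stress couples to mobility much more weakly
(observed correlations ≈ 0.1–0.2 before severity polarization) and
through confounders the generator does not model. The synthetic cohort
validates the *machinery* — recovery, accounting, leakage-freedom,
calibration of signs and rough magnitudes — not clinical effect sizes.

## Representative-user fixtures

Two deterministic users are constructed in reverse: an edge-weight
multiset with the documented 75th percentile is chosen analytically
(A: {4,4,4, 5,5,5, 7,7,7,7,7,7, 12,12, 58,58}, q75 = 7 + 0.25·5 = 8.25,
sum 209; B: 51×1, 24×2, 24×3, 48×4, 46×39, 2×46, q75 = 4, sum 2249),
realized as a balanced directed multigraph, and unrolled into a visit
sequence by a deterministic Eulerian circuit (Hierholzer, ascending
adjacency). A has 7 places and 210 visits over 30 days (per-place rate
exactly 1.0); B has 25 places and 2250 visits (rate 3.0). B's
hub-and-spoke weights are stylized — the home node is visited very often —
which is acceptable for a worked example whose purpose is exact,
documented feature values. GPS jitter is seeded but bounded, so every
seed yields identical clustered output.

## Problem sizes and runtime

The test suite simulates one 150-user, 30-day cohort (~200k fixes,
shared across tests via a cache), runs the full benchmark with tuning on
its polarized subset, a 20-seed label-permutation null for all six
families, and a 10⁵-draw permutation oracle for Dunn's test; the whole
suite runs in about a minute on one CPU. These sizes were chosen as the
smallest at which the statistical properties under test are stable.

## Known limitations

- The clustering is order-dependent by design; a different fix ordering
  of the same multiset of coordinates can yield different (equally valid)
  partitions. Determinism is guaranteed, permutation invariance is not.
- "Tracked days" counts distinct local days with at least one fix;
  sparse tracking inflates per-day rates rather than imputing zeros.
- The SDA implementation is the classical regularized LDA score; it does
  not estimate the shrinkage intensity analytically but tunes it on the
  grid like every other hyperparameter.
- The bench's primary contract is the binary severe-vs-none contrast; a
  multiclass outcome is evaluated through the macro one-vs-rest AUC
  helper (`macro_auc_ovr`), a convention flagged here because it is one
  of several defensible multiclass AUC definitions.
- No travel-mode inference and no accelerometer/gyroscope ingestion:
  step and GPS streams are treated as non-overlapping by contract.
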