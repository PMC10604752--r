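---
title: "Mining branching disease trajectories from longitudinal claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining branching disease trajectories from longitudinal claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajtree)
```

## The model

trajtree treats disease progression not as a chain of isolated events but
as movement through a space of *cumulative disease states*.  Every
diagnosis record is a triple (patient, visit date, ICD-9 code); codes are
truncated to their 3-digit category, and each code is counted at most once
per patient per day.  A patient's state on a given day is the vector of
cumulative counts — for each code, the number of distinct days so far on
which it was recorded.  States are non-decreasing in every coordinate, so
each patient traces a monotone path from the all-zero *pre-diagnosis
state*, which the encoder materializes explicitly for every patient
(`cumulate(..., preState = TRUE)`): the root of the trajectory tree must
exist in the data for the rooting rule below to apply.

States are standardized per code (centering and scaling to unit variance,
population 1/n convention; zero-variance codes map to exact zeros with a
recorded scale of 1) and embedded by PCA.  The component count is either
fixed (the pipeline default is 60, capped at the data's rank bound) or
chosen by the elbow rule, implemented as the maximizer of the discrete
second difference of the explained-variance profile with ties broken
toward the smaller index.  Identical state vectors are collapsed before
any fitting and their multiplicities carried as point weights; this is
why the number of fitted rows is smaller than the number of raw states.

## The elastic principal tree

The embedded state cloud is approximated by an elastic principal tree: a
set of nodes with positions $p_1, \dots, p_m$ joined by an acyclic edge
set $E$, minimizing

$$U = \frac{1}{W}\sum_i w_i \lVert x_i - p_{a(i)}\rVert^2
    + \lambda \sum_{(u,v) \in E} \lVert p_u - p_v\rVert^2
    + \mu \sum_{j : \deg(j) \ge 2}
      \Bigl\lVert p_j - \tfrac{1}{\deg(j)}\sum_{v \in N(j)} p_v\Bigr\rVert^2,$$

where $a(i)$ assigns each point to its nearest node.  The first term is
the weighted approximation error, the $\lambda$ term keeps edges short,
and the $\mu$ term is a star-bending penalty that keeps branches smooth.
Node positions are optimized by alternating the nearest-node assignment
with an *exact* solve of the (quadratic) energy — a small symmetric
positive-definite linear system in the node positions.  We chose the
exact solve over iterated local averaging because it reaches the same
fixed point in fewer iterations, is deterministic, and makes the
per-iteration energy provably non-increasing, which the tests assert.

Topology is grown greedily from a two-node segment placed at $\pm 1$
standard deviation along the first principal component.  At each step two
grammar operations are tried everywhere they apply — *bisect an edge*
(new node at the midpoint) and *attach a node to a node* (new node at the
centroid of the host node's assigned points) — each candidate is
optimized briefly, and the lowest-energy candidate is kept and then
optimized to convergence.  The fit is deterministic; the `seed` argument
exists only for interface stability.

Defaults: `nNodes = 25` (matching the size of the published reference
tree), `lambda = 0.01`, `mu = 0.1`, convergence at a relative energy
change of `1e-6`, at most 100 optimizer iterations per grammar step and
10 during candidate scoring.  The source study does not report its
elasticity settings, so these are this package's own reconstructions,
exposed as arguments.

## Rooting, orientation, trajectories

The root is the node onto which the all-zero pre-diagnosis states
project.  Because those states are identical vectors they share one
embedding and agree on a single node; if pre-states were not
materialized, `findRoot()` says so rather than guessing.  A configurable
fallback (`method = "min-count"`) roots at the node whose assigned states
have the smallest mean total count.  Edges are oriented away from the
root breadth-first with children ordered by node index, so orientation is
independent of input edge order.  A *trajectory* is a root-to-leaf path;
there are exactly as many trajectories as leaves.

## Odds-ratio screen

Candidate comorbidities come from a patient-level case/control screen:
for each code, the 2-by-2 table counts patients ever diagnosed with it.
The odds ratio is $ad/(bc)$, reported as $+\infty$ when no control is
exposed but at least one case is.  The default confidence interval is
Woolf's log-normal interval; when any cell is zero the interval is
computed on the Haldane–Anscombe table (0.5 added to every cell), keeping
the structurally infinite bound.  An exact conditional interval
(`method = "exact"`, via `fisher.test`) is available because the interval
method behind published tables of this kind is often unstated.  A code is
*significant* when its OR is at least 2 and the CI excludes 1 — the
log-odds reading of "the interval does not include zero", consistent with
every row of the packaged reference screen table.  No multiplicity
correction is applied by default, matching the screening convention the
method reproduces; `adjust = "BH"` tightens the selection when wanted.

## Edge attribution

Each node's *profile* is the arithmetic mean of the raw cumulative
vectors of its assigned states.  A candidate code is *associated* with a
directed edge when its mean count increases by more than `epsilon` from
parent to child; candidates are the significant screen codes plus the
index disease.  The increase rule is evaluated on mean node profiles —
one of several defensible readings of "the number of diagnoses increased
during a state transition" — and `epsilon` defaults to 0.05 mean counts,
exposed in the interface because the source description names no
threshold.

The *branch-only* set of an edge removes from its associated set
everything shared with sibling edges at the same parent and everything
inherited from ancestor edges on the root path.  The exclusivity summary
counts distinct non-index codes that are associated anywhere, branch-only
anywhere, and branch-only on exactly one edge; on the packaged reference
table these counts are (28, 26, 23), recomputed exactly from the printed
associated sets.

A consequence worth knowing: any disease whose onset begins *at* a
bifurcation leaks a small mean-count increase onto the last shared edge
(the bifurcation node averages over early-branch states), and the
ancestor-exclusion rule then removes it from the branches themselves.
Branch-only attribution therefore highlights diseases that onset deep
inside a branch — which is also where the reference table's branch-only
codes sit.

## Patient classification

Each patient's final observed state maps to its nearest node (Euclidean
distance, ties to the smaller index).  If that node lies on exactly one
root-to-leaf trajectory the patient is assigned to it; otherwise — the
node precedes a bifurcation, so several futures are compatible — the
patient joins the uncategorized group.  Reporting merges trajectories
with fewer than `minSupport = 3` patients into the uncategorized group;
the unfiltered counts remain available (`filterSupport = FALSE`) because
"n trajectories" and "n trajectories plus an uncategorized group" are
both common reporting conventions.

## The synthetic cohort generator

Protected claims data cannot ship with a package, so `generateCohort()`
plants a known truth: a rooted tree of *stages*, each with onset codes, a
dwell time in days, and branch probabilities at bifurcations.  Cases walk
a root-to-leaf stage path; visit days follow a homogeneous Poisson
process (`visitRate` per 30 days); each active stage's onset codes are
recorded at a visit with probability `onsetProb` (default 0.3 — claims
record a diagnosis at some visits, not all, keeping per-code counts
single-digit as in real data); background codes occur in cases and
controls at the same per-visit probability.  Controls are matched 4:1 on
gender and birthdate within 1000 days, drawn without replacement,
preferring the closest birthdate with ties to the smallest pool index.
Every patient has a private RNG substream derived from (seed, index), so
enlarging a cohort never perturbs existing patients.  Control visit
intensity is a free parameter (`controlVisitRate`) defaulting to the case
rate, since matched-cohort visit intensity is not something the method
itself pins down.

The canonical test scenario is a Y: a three-code stem, then two branches
of two stages each — transitional codes just after the bifurcation and
deep marker codes later.  The deep markers are what branch-only
attribution can and should recover (see the leak note above).  What the
generator does *not* emulate: realistic ICD-9 frequency distributions,
censoring and death, coding drift, or visit-intensity differences between
stages.  Passing tests on this generator show the pipeline recovers
planted structure under its stated noise; they do not certify behaviour
on real claims.

## Numerical choices and problem sizes

Population-variance standardization; exact duplicate-row collapse before
PCA; deterministic loading signs (largest-magnitude loading positive);
first-index tie-breaks in nearest-node assignment; half-open stage
windows; ISO-8601 dates.  The test suite runs the full pipeline at 200
synthetic cases with 10 tree nodes and 8 components (about 10,000 state
rows), five seeds, and the generator property checks at up to 2,000
cases — sizes chosen so the planted-structure checks are statistically
meaningful while a full run stays comfortable on a laptop.

## Worked example

```{r example, eval = FALSE}
spec <- trajectorySpec(
    stageEdges = rbind(c("stem", "brA1"), c("brA1", "brA2"),
                       c("stem", "brB1"), c("brB1", "brB2")),
    onsets = list(stem = c("100", "101", "102"),
                  brA1 = c("210", "211", "212"),
                  brA2 = c("200", "201", "202"),
                  brB1 = c("310", "311", "312"),
                  brB2 = c("300", "301", "302")),
    durations = c(stem = 300, brA1 = 300, brA2 = 300,
                  brB1 = 300, brB2 = 300),
    visitRate = 2, backgroundCodes = sprintf("7%02d", 0:9),
    backgroundProb = 0.1)
bundle <- runPipeline(spec = spec, nCases = 200, nNodes = 10,
                      nComponents = 8, seed = 1)
bundle$exclusivity
bundle$summary
```

## Known limitations

The elastic tree is a local optimizer: pathological seeds of a greedy
grammar can mis-grow a branch, which is why topology recovery is asserted
across seeds rather than per seed.  Mean-profile edge attribution blurs
onsets near bifurcations (see above).  The screen reports
patient-level, ever-diagnosed associations only — no time-at-risk
adjustment, no multiplicity correction by default.  And reproducing any
particular published cohort's odds ratios or tree geometry requires that
cohort's raw records, which are not publicly available; what this package
reproduces exactly are the counts derivable from the published edge
table itself.
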