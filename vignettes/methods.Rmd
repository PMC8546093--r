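---
title: "Causal structure discovery from two-window EHR event panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal structure discovery from two-window EHR event panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrCSD)
```

## The problem

Electronic health records hold time-stamped diagnoses, prescriptions,
laboratory results and vital signs, but those records follow no study
design: a billing code does not say whether a condition is new or
long-standing, and the time stamp of a diagnosis usually reflects
documentation, not onset — occasionally even reversing the true order of two
diseases. General-purpose causal structure discovery (CSD) algorithms run on
such data report edges that contradict known disease progression, and often
cannot orient edges at all because observationally equivalent structures
score identically.

ehrCSD implements a CSD workflow built around two ideas. First, a **data
transformation** that replaces unreliable time stamps with a coarse but
robust two-window design: an event is *pre-existing* if it is recorded on or
before the end of an early observation window, and *incident* if it first
appears by the end of a later window. At this resolution only the window
membership of the first record matters, so documentation lag and
within-window order reversals are irrelevant unless they cross a window
boundary. Second, a **precedence-constrained search**: the only edges a
graph may contain are ordered pairs for which the data show a statistically
clear temporal precedence, so every edge's orientation is fixed before the
search begins.

## The model

Write $x_s^{(1)}, x_s^{(2)} \in \{0,1\}^V$ for the event statuses of subject
$s$ at the two cross sections. Pre-existing events are assumed to persist,
so $x^{(1)} \le x^{(2)}$ cell-wise. A candidate structure is a DAG
$\mathcal{G}$ over the events, read as a *transition graph*: the probability
that subject $s$ has event $v$ at the second cross section depends on the
window-1 statuses of $v$'s parents,

$$\mathcal{L}(\mathcal{G}) \;=\; \prod_s \prod_{v \in V}
  P\!\left(v_s^{(2)} \mid pa(v, \mathcal{G})_s^{(1)}\right),$$

where the window-1 marginal term is constant in $\mathcal{G}$ and is
dropped. Each factor is a logistic regression of $v$'s window-2 status on
the window-1 parent statuses, fitted on the node's **risk set** — subjects
without $v$ at the first cross section that are under observation at both
cross sections. Subjects already positive contribute probability 1 and drop
out of the node's likelihood. The search criterion is

$$\mathrm{BIC}(\mathcal{G}) = -2 \ln \mathcal{L}(\mathcal{G})
  + \ln(n)\,|\mathcal{G}|,$$

with $n$ the number of patients observed at both cross sections and
$|\mathcal{G}|$ the **edge count** — the penalty is deliberately per edge,
not per parameter, and intercepts are unpenalised. This score decomposes
over nodes, so adding or removing one edge changes exactly one node term;
the implementation exploits this with a per-(node, parent-set) cache, and
the test suite asserts bit-for-bit equality of warm- and cold-cache scores.

## Precedence constraints

For an unordered pair $\{A, B\}$, patients carrying both events by window 2
split into concordant ones (both pre-existing or both incident — no ordering
information at window resolution) and discordant ones: $n_{AB}$ with $A$
pre-existing and $B$ incident, $n_{BA}$ with the converse. Under no
systematic ordering the discordant split is Binomial$(n_{AB}+n_{BA},
\tfrac12)$. The pair is admitted to the constraint set $C$ — oriented along
the majority direction — when the exact two-sided binomial test rejects at
level $\alpha$ (default 0.05, configurable; no multiplicity correction,
since $C$ is deliberately permissive and the BIC search filters it).

A note on the test construction: declaring "$A$ precedes $B$" by running a
*one-sided* test at $\alpha$ in each direction admits null pairs at nearly
$2\alpha$, because the two rejection regions are disjoint and each has size
close to $\alpha$. We therefore use the two-sided exact test at $\alpha$ and
orient by the majority — equivalent to one-sided tests at $\alpha/2$ — which
keeps the per-pair type-I rate at the nominal level. The package's
calibration test verifies this on exchangeable null simulations. Pairs with
zero discordant patients (events that always co-occur within a window) have
no defined test and are never admitted: such pairs have no clear precedence.

Two optional knobs exist: a minimum discordant count (default 0, i.e. off)
to suppress unstable small-sample pairs, and the $\alpha$ level itself.

## The search

The graph is built greedily from the empty graph: at each step the candidate
set is every ordered pair of $C$ not yet in the graph whose addition keeps
the graph acyclic and whose child has a non-empty risk set; the candidate
with the largest BIC decrease is added, and the search stops when no
candidate strictly decreases the BIC. Ties are broken lexicographically by
(child, parent) so results are deterministic. Because orientations come from
$C$, the same adjacency can never appear in opposite directions across runs
— this is what drives the ambiguous-orientation percentage to zero in
bootstrap stability reports, and the suite asserts exactly that over 200
replicas.

The canonical procedure is forward-only. An optional backward sweep
(`prune = TRUE`) greedily deletes single edges while deletion lowers the
BIC; it is off by default because forward addition is the procedure the
method defines, and on the strong-signal synthetic conditions pruning almost
never fires.

Greedy forward search is not globally optimal in general; the suite checks
*step-optimality* (each accepted edge is the brute-force best admissible
candidate) on random instances, and full agreement with exhaustive
enumeration on instances with at most three candidate edges.

## Numerical choices

* Logistic fits use IRLS (`stats::glm.fit`) with relative log-likelihood
  tolerance $10^{-8}$ and at most 100 iterations.
* A constant outcome on the risk set falls back to an intercept-only model
  at the empirical proportion clipped to $[0.5/m,\, 1-0.5/m]$; the model is
  flagged `degenerate` and its `converged` slot is `FALSE`.
* (Quasi-)separation — detected by a fitted-probability warning,
  non-convergence, or a coefficient beyond 15 on the log-odds scale —
  triggers a ridge-stabilised Newton refit with a small fixed L2 penalty
  ($\lambda = 10^{-4}$ on parent coefficients, not the intercept), flagged
  `ridge`. The BIC penalty is unchanged for such nodes.
* Regressors constant on a risk set are dropped from the design and reported
  with coefficient 0.
* BIC comparisons in the search use an absolute guard of $10^{-12}$ so that
  exact ties fall to the lexicographic rule.

## Evaluation metrics

Against a curated evidence base (associative pairs from observational
literature; positive and negative causal relationships from trials, the
latter optionally context-tagged: "in patients with X, A does not cause B"):

* **Precision** — one minus the share of discovered edges with no
  associative evidence or with an unconditional causal negative in that
  orientation.
* **Causal recall** — a positive relationship A→B is discovered if a direct
  edge exists or a directed path exists whose every *intermediate* node is
  not cited by a context-tagged negative for that relationship. Evidence
  names map to event codes through a required alias table (e.g. "blood
  pressure" to both `sbp` and `dbp`). We generalise the path clause from the
  length-2 worked case to any path length (a `maxPathLen` option restores
  the literal reading) because recall should not depend on how finely the
  vocabulary happens to split an aetiological chain.
* **Associative recall** — a pair is explained when its endpoints are
  connected in the orientation-blind skeleton; this is the literal
  "a path between A and B exists" reading and is documented as permissive.
* **Stability** — over bootstrap replicas (patients resampled with
  replacement, precedence and search recomputed per replica so the report
  reflects the whole method's variability), an adjacency present in at least
  half the graphs is reported, and is *ambiguous* when both orientations
  each occur in at least 30% of the graphs containing it.
* **Cross-cohort concordance** — per-site pooled edge sets (directed edges
  with bootstrap support at or above a threshold) are compared edge by edge.
  The pooling cutoff is not canonically fixed; we default to 0.5,
  consistent with the stability inclusion rule, and expose it.

## The synthetic generator

Because real two-window EHR cohorts cannot be redistributed, the package
ships a generator that makes the entire pipeline testable. A
`GroundTruthModel` holds a DAG, per-node logistic models for the window-1
cross section (sampled ancestrally, so baseline statuses are realistically
correlated rather than independent), per-node logistic transition models for
window-2 incidence given window-1 parent statuses (pre-existing events
persist deterministically — the single-incidence assumption; remitting
conditions are out of scope), an observation-anchor probability, and
timestamp noise: an exponential documentation lag and a probability of
shuffling a patient-window's record dates.

The default model (`defaultGroundTruth()`) is a ten-node, twelve-edge
chronic-disease progression network (obesity → hypertension /
hyperlipidemia / pre-diabetes; pre-diabetes → diabetes; hypertension,
hyperlipidemia and diabetes → coronary disease; hypertension and diabetes →
renal failure; coronary disease → infarction → heart failure; hypertension
→ cerebrovascular disease) with window-1 prevalences of roughly 0.05–0.3,
baseline two-year incidences of 0.03–0.06 and odds ratios of 3 (window-1
model) and 4 (transitions) — effect sizes typical of established
comorbidity risk factors, and strong enough that structure recovery should
be near-perfect at a few thousand patients. These values were fixed once as
the package's study conditions.

What the generator does *not* emulate: coding vocabulary drift, visit-driven
informative observation (anchors are independent of disease status),
remitting/relapsing conditions, measurement error in labs, and
site-specific treatment policies. Passing tests therefore demonstrate
correctness of the machinery and calibration of the statistics under the
model's assumptions — not performance on real EHR extracts.

## Problem sizes used by the tests

The suite and the acceptance script run, as the package's chosen validation
sizes: 200 bootstrap replicas on a 2,000-patient, 10-node panel for the
stability property; 20 cohorts of 5,000 patients for end-to-end structure
recovery (mean directed-edge precision and recall ≥ 0.9); one 20,000-patient
panel for coefficient recovery within three standard errors; 40 exchangeable
null simulations of 1,500 patients for precedence calibration; and ~50 small
random instances for step-optimality against brute-force enumeration.

## Design decisions that were genuinely open

* **Gap events.** An event first recorded strictly between the windows is
  incident for window 2 (`x1 = 0`, `x2 = 1`): each status is a total
  function of a single boundary, which keeps the transition conditioning
  well defined. Window-end comparisons are inclusive.
* **Inclusion anchors.** The "two blood-pressure measurements bracketing the
  study" criterion generalises to a configurable anchor-code set: the
  criterion is a proxy for being under observation at both ends. The default
  configuration ships the blood-pressure version.
* **Unknown codes** drop with a warning by default (EHR extracts routinely
  carry stray codes); `strict = TRUE` aborts instead.
* **`n` in the BIC** is the count of cohort patients observed at both cross
  sections, not a per-node risk-set size — the literal reading of the
  criterion, and it keeps the penalty comparable across nodes.
* **Bootstrap scope.** The constraint set is recomputed inside each replica
  rather than fixed from the full data, so stability quantifies the whole
  method.
* **Two-sided precedence test** at $\alpha$ with majority orientation, for
  the calibration reason given above.

## Known limitations

Precedence at window resolution cannot order events that typically arise
within the same window, so genuinely causal but fast-following pairs are
excluded from $C$ and can never be discovered (they surface as reduced
causal recall, not as wrong edges). The method assumes persistence;
transient conditions violate the panel invariant and are out of scope.
Confounding by unmeasured common causes is not addressed — the constrained
search orients edges, it does not license interventional claims. Finally,
the edge-count BIC penalty is lighter than a parameter-count penalty for
nodes with many parents; with very dense truths the search may over-connect
high-degree children.
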