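---
title: "Comorbidity networks from diagnosis records: methods and design"
author: "ComorbidNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comorbidity networks from diagnosis records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ComorbidNet)
```

## The problem

Patients with a severe index disease — the package ships hepatocellular
carcinoma (HCC, ICD-10 C22.0) as its default — typically carry several
coexisting diagnoses. Given inpatient records with one primary and up to 15
secondary ICD-10 codes per patient, we want to know which diseases
accompany the index disease more often than chance, and whether the
excess co-occurrence organizes into *comorbidity modules*: groups of
diseases that travel together (e.g. the cirrhosis complex, the chronic
cardiovascular cluster). ComorbidNet implements that workflow end to end:
cohort construction, stratified prevalence statistics, pairwise relative
risk, thresholded network assembly, and community detection — plus a
synthetic-cohort generator with closed-form expected statistics so the
whole pipeline can be validated without access to patient data.

## The relative-risk statistic

For diseases $A$ and $B$ with carrier counts $C_A$, $C_B$ and pair count
$C_{AB}$ in a cohort of size $N$, the co-occurrence relative risk is the
observed pair prevalence over its expectation under independence:

$$
RR_{AB} \;=\; \frac{C_{AB}/N}{(C_A/N)(C_B/N)} \;=\; \frac{C_{AB}\,N}{C_A\,C_B}.
$$

A pair is flagged significant when $RR > 1$, strictly — the bare
threshold used by comorbidity-network studies in this tradition. Note the
identity $RR_{AB} = \frac{C_{AB}/C_A}{C_B/N}$: it is also the classical
cohort relative risk of carrying $B$ given $A$ versus $B$ in the whole
cohort. That identity justifies the Katz log-normal 95% interval we store
alongside each estimate, with
$\mathrm{SE}(\log RR) = \sqrt{1/C_{AB} - 1/C_A + 1/C_B - 1/N}$.
The interval is informational only: filtering uses the bare $RR > 1$ rule
so that results are comparable with the published convention, and because
with cohort sizes in the $10^4$ range the interval excludes 1 for all but
the rarest pairs anyway. Pairs with a zero marginal count have an
undefined $RR$ and are excluded rather than assigned 0 or $\infty$.

The index disease is excluded from all pairwise statistics: every cohort
member carries it, so its observed and expected pair prevalences coincide
and its $RR$ to anything is identically 1.

Prevalence denominators are always the stratum size $N$, never a
diagnosed-subset size; percentages in report tables are rounded half-up to
two decimals (base `round()` is round-half-even, which disagrees with how
clinical tables are conventionally printed).

## Group comparisons

Between-stratum prevalence differences use the standard menu for 2×2
tables, selected by the Cochran rule on expected counts: Pearson
$\chi^2$ when all expected counts are at least 5, the Yates
continuity-corrected $\chi^2$ when the minimum expected count is in
$[1, 5)$, and Fisher's exact test (two-sided, by summation of
hypergeometric tables at most as probable as the observed one) when any
expected count falls below 1. Age comparisons are 2×5 tables and always
use the plain $\chi^2$; Yates and Fisher are 2×2 constructions. All tests
are two-sided; no multiple-testing correction is applied, matching the
reporting convention the pipeline reproduces — callers who want one can
apply `p.adjust` to the report column.

## Network construction

Nodes are diseases with prevalence strictly above `minPrevalence`
(default 1%); edges join retained pairs with $RR$ strictly above
`rrThreshold` (default 1.0). The edge weight is the raw co-occurrence
count $C_{AB}$ — the one edge-strength quantity such studies print — and
$RR$ rides along as an annotation. Node and edge criteria are independent,
so nodes passing the prevalence filter but gaining no edge remain as
isolates. Both thresholds are strict inequalities; raising either can
only shrink the network (tested as a monotonicity property).

Exports: GEXF 1.2 (Gephi-readable, with `viz` hints — node size
proportional to prevalence, color bucket by degree tercile), GraphML (via
igraph), and a delimited edge list with a companion node-attribute file.
All three round-trip losslessly through `importNetwork()`.
`validateGexf()` checks the GEXF structure directly (root namespace and
version, attribute declarations, node-id uniqueness, edge referential
integrity, numeric weights) — a structural conformance check implemented
in the package rather than an XSD run.

## Modularity and community detection

For a weighted undirected network with total edge weight $m$, community
internal weights $W_c$ and community degree sums $d_c$, the modularity at
resolution $\gamma$ is

$$
Q \;=\; \sum_c \left[ \frac{W_c}{m} - \gamma \left(\frac{d_c}{2m}\right)^2 \right],
$$

the fraction of edge weight inside communities minus its expectation
under the configuration null model. `louvain()` implements the Blondel
two-phase greedy optimizer: local sweeps in seeded-random order (re-drawn
each sweep) moving each node to the neighboring community with the
largest positive gain, ties broken by lowest community id; then
aggregation of communities into super-nodes, with intra-community weight
becoming a self-loop that contributes $w$ to $W_c$ and $2w$ to the degree
— the convention under which $Q$ is preserved exactly across levels
(asserted internally each pass, which is how a mapping-composition bug
was caught during development). Isolated nodes keep singleton communities
and contribute nothing to $Q$. The default $\gamma = 1$ reproduces plain
modularity; the parameter is exposed because it costs nothing and is the
standard extension.

`bruteForceBestPartition()` enumerates all set partitions (restricted
growth strings) for networks of at most 12 nodes and is the exact oracle
the heuristic is tested against: on random small graphs Louvain never
exceeds the oracle and matches it in the large majority of cases.

**Known limitation.** A single seeded Louvain run is a greedy heuristic
and can land in a local optimum. On roughly 1–2% of tiny (≤10-node)
Erdős–Rényi test graphs the gap to the exact optimum slightly exceeds
0.05; on every such graph igraph's independent Louvain implementation
lands in the identical local optimum, so this is a property of the
algorithm, not of this implementation. On well-separated planted-module
networks the optimum is recovered exactly across seeds. The seed is
recorded in the `CommunityPartition` and in every pipeline output, so
runs are reproducible rather than averaged.

## The synthetic-cohort generator

`generateCohort()` samples from a planted-partition model: every patient
carries the index code; each module $m$ activates per patient with
probability $\pi_m$; an active module's disease $j$ is carried with
probability $q_{1j}$, an inactive one's with $q_{0j} < q_{1j}$;
background diseases are independent Bernoulli draws. Activations are
independent across modules, so cross-module pairs have $RR = 1$ exactly —
a sharp null for the pipeline. The closed forms

$$
p_j = \pi q_{1j} + (1-\pi) q_{0j}, \qquad
RR_{jk} = \frac{\pi q_{1j} q_{1k} + (1-\pi) q_{0j} q_{0k}}{p_j\,p_k}
$$

(`expectedPrevalence()`, `expectedPairRR()`) are the analytic oracles the
Monte-Carlo tests converge to. The recovery benchmark uses three planted
modules of five diseases with $\pi = 0.3$, $q_1 = 0.8$, $q_0 = 0.05$
(within-module $RR \approx 2.562$) at $N = 5{,}000$: Louvain on the built
network recovers the planted partition with ARI 1.0 in essentially all
seeded replicates.

`defaultSyntheticConfig()` emulates the structure of a large HCC
inpatient cohort: $N = 14{,}891$; five modules of 12/10/10/9/6 diseases
(cirrhosis complex, cysts/stones/lung, metabolic + gastrointestinal
hemorrhage, chronic cardiovascular, secondary cancers) plus eight
background diseases, 55 comorbid codes in total with marginal prevalences
spanning ~0.2% to ~56%; age-bin probabilities
2.89/14.59/29.47/35.26/17.79% and a 76.01% male fraction. Module rates
were chosen once so the leading diseases sit near the reference
prevalences (cirrhosis ~56%, chronic hepatitis B ~28%, hypertension
~15%) and the mean comorbidity count is ~3.6; they are the package's
fixed study conditions, not tuning knobs. At this scale the pipeline
yields a network of ~50 nodes and ~700 edges partitioned into 4–5
modules — the same regime as the reference analysis.

What the generator does *not* emulate: the zero-inflation of real EHR
count distributions (real cohorts record more "index-only" patients than
an independent-module model produces), demographic confounding (age/sex
are sampled independently of disease by default; a correlated extension
was deliberately left out to keep the cross-module null exact), coding
noise, and visit structure. Passing tests therefore demonstrate that the
statistics and algorithms are correct on data with known ground truth,
not that real hospital data meet the model's assumptions.

Patients exceeding the 15 secondary-diagnosis slots are truncated to the
15 highest-marginal-rate codes (mimicking the EHR slot limit rather than
resampling); at default rates this is rare and it is logged and counted.

## Numerical and interface choices

* Codes are compared as exact strings after uppercasing, whitespace
  stripping and dot removal; the only hierarchy operation is the
  3-character truncation (`normalizeCodes(level = "category3")`). The
  coding granularity is a configuration knob because disease-level
  analyses can reasonably pool subcodes or not; both levels flow through
  the whole pipeline.
* A patient split across rows in the long layout is merged; conflicting
  age or sex across a patient's rows is an error, not an overwrite, and
  sex is strictly two-level since all group tests are 2×k.
* Modularity comparisons use a $10^{-12}$ tolerance; Louvain move gains
  must exceed $10^{-12}$ to count, which makes sweeps terminate
  deterministically; oracle ties are broken by fewest communities, then
  enumeration order.
* All randomness (generation, sweep order) is seeded through a helper
  that restores the caller's RNG state, so library calls never perturb a
  user's stream, and identical inputs give byte-identical pipeline
  outputs.
* Test problem sizes: Monte-Carlo convergence checks run at
  $N = 50{,}000$; recovery at $N = 5{,}000 \times 20$ seeds; the
  Louvain-vs-oracle suite uses 100 random graphs of 5–10 nodes (the
  exhaustive oracle is Bell-number bounded). These sizes make the
  stochastic tolerances (±0.01 on prevalences, ±0.1 on RR, ±0.05 on the
  null mean RR) comfortable while keeping the default suite fast.

## Limitations

Beyond the generator caveats above: the pipeline establishes
co-occurrence, not causation or temporal precedence (records are
single-visit); the bare $RR > 1$ edge rule admits sampling-noise edges
between truly independent common diseases (the Katz interval is stored
precisely so stricter users can filter on it); and no correction is made
for the number of pairs tested.
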