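---
title: "Methods: rule mining, the Trader optimizer, and the benchmark protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule mining, the Trader optimizer, and the benchmark protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntrader)
```

## The problem

Synthetic drug repurposing replaces one drug with a *combination* of other
approved drugs. The given drug hits a set of targets; only some of them are
relevant to the disease (its *main targets*), the rest are side effects. A
good substitute combination covers all main targets with the required
pharmacological effect (inhibit, induce, agonize or antagonize) while
carrying as few side-effect interactions as possible, and contains no pair
of drugs with a known adverse reaction.

The pipeline has two stages:

1. **Candidate mining.** Deterministic If-Then rules over the drug-target
   interaction matrix and one-hop target-target relations admit drugs that
   act on a disease target — or on an enzyme/protein related to one — with
   exactly the required effect.
2. **Combination selection.** A discrete metaheuristic (*Trader*) searches
   binary selections of the mined candidates for the best-scoring
   combination.

## Rule semantics

The disease target set is a list of (target, required effect) pairs. Rule 1
admits a drug hitting such a target with exactly the required effect.
Rules 2-5 fire on relations `source -> sink` (enzyme->protein,
protein->enzyme, protein->protein, enzyme->enzyme) whose effect equals the
required effect on the sink; any drug interacting with the source is then
admitted. Two deliberate choices:

* **Strict effect equality.** An agonist of a receptor is *not* admitted
  when the disease requires an antagonist on that same receptor, even
  though both drugs bind the same target. No inhibit/antagonize aliasing.
* **One-hop chaining only.** The rule templates relate exactly two
  entities; no transitive closure is taken, so removing a relation can only
  shrink the admitted set.

When two indicated drugs touch the same target with conflicting effects,
both (target, effect) pairs are retained and flagged: the matrix records
evidence, and discarding either reading silently would bias the candidate
pool. The target set may also be supplied directly from a curated file,
bypassing derivation from the indication matrix.

## The score

For a binary selection $v \in \{0,1\}^m$ over candidates with side-effect
counts $SE_i$:

$$\mathrm{score}(v) = AT(v) - \frac{\sum_{i: v_i=1} SE_i}{\sum_i v_i},$$

where $AT(v)$ is the number of *distinct* main targets covered by the
union of the selected drugs' coverage sets. Coverage is read as a union,
not a sum with multiplicity: covering the same target twice buys nothing.
The score is maximized internally; every reported objective is its
negation so that lower is better, matching the convention in which the
best benchmark values are the most negative.

Degenerate and constrained cases:

* **Empty selections** are undefined (the mean divides by the selection
  size); operators repair an all-zero trial by setting one uniformly
  random bit before scoring.
* **Adverse pairs.** Under the default hard mode any selection containing
  an adverse pair scores a *finite* infeasibility sentinel,
  $-(\sum_i SE_i + |\text{main targets}| + 1)$, strictly worse than every
  feasible score (any feasible score exceeds $-\sum_i SE_i$). A finite
  sentinel keeps group properties (sums of member scores) well defined
  when infeasible solutions appear in the population; $-\infty$ would
  break the proportional group allocation. A penalty mode
  (subtract $\lambda$ per violating pair) is available for soft-constraint
  experiments.

## The Trader optimizer

A population of `population_size` (default C = 50) binary solutions is
partitioned into `n_groups` (default T = 5) trader groups. Each iteration:

1. **Distributing.** Each group's master (its best member; ties go to the
   lowest population index) copies R positions (R uniform on 1..m,
   positions sampled without replacement) onto every slave.
2. **Retailing.** Every slave flips R distinct positions, R uniform on
   1..max(1, ceiling(m/10)).
3. **Importing-exporting.** One event per iteration: the importer master is
   drawn uniformly; the exporter is drawn from the remaining masters with
   probability proportional to their positively shifted group properties
   ("richer traders export"); R positions are copied exporter to importer.
4. **Regrouping.** Each group keeps `min_members` (M = 2) guaranteed
   members — no group is ever eliminated — and receives a share of the
   remaining C − M·T members proportional to its property (the sum of its
   members' scores, shifted by −min + 1 when any is nonpositive), with
   largest-remainder rounding so sizes sum exactly to C. Surplus groups
   shed their worst non-master members to the group with the largest
   deficit; masters never migrate.

Every trial solution is accepted only if its score strictly improves, so
the best-so-far trace never worsens. The stop rule is a score-evaluation
budget (default 10,000), not an iteration count, which makes equal-budget
comparisons across algorithms meaningful; each iteration consumes
2(C − T) + 1 evaluations, so a run can overshoot the budget by at most one
iteration. Seeded runs are bit-reproducible.

Choices the algorithm description leaves open, fixed here:

* distributing is applied to **every** slave each iteration;
* the importer is uniform among masters and the exporter
  property-weighted among the rest;
* master ties break to the lowest index;
* the retailing radius uses ceiling with a floor of one flip.

## Baselines and the exact oracle

Random search (Bernoulli(0.5) samples, all-zero repaired) and
first-improvement hill climbing with random restarts share the identical
scoring and evaluation accounting. The exhaustive oracle enumerates every
nonempty selection up to m = 20 and is the ground truth for the
oracle-equivalence and planted-recovery tests. Published competitor
algorithms are represented by these generic baselines: the benchmark
harness only needs score distributions under an equal budget, and faithful
replicas of the four comparison methods are out of scope.

## Synthetic instances

Real candidate pools come from curated interaction databases that are not
redistributable, so instances are generated: each candidate covers a
nonempty random subset of the main targets, side-effect counts are
Poisson, adverse pairs are Bernoulli. Defaults, chosen once:

* `se_rate = 2` — published pool shapes carry 0-11 non-main interactions
  per drug and highlighted substitutes include zero-side-effect drugs, so
  a small Poisson mean with mass at zero is realistic;
* `coverage_p = 0.6` (truncated geometric subset sizes) — most drugs hit a
  single main target;
* `ddar_density = 0.05` — adverse pairs are sparse among candidate pairs.

Nine presets reproduce the published (targets, main targets, candidates)
pool shapes — e.g. the Nicardipine-shaped pool has 4 main targets and 40
candidates — but per-candidate side-effect values are synthetic: no
per-drug counts were ever published. Generated instances therefore
exercise the *mechanics* (coverage unions, mean side-effect load, hard
constraints) and say nothing about the pharmacology of real pools:
coverage sets are independent across drugs, side effects are homogeneous
Poisson, and adverse pairs are independent — real interaction data are
correlated in all three.

`plant_optimum()` builds instances whose optimum is known by construction:
a designated k-subset partitions the main targets with zero side effects
while every other candidate carries at least one, so the planted subset is
the unique score maximizer; the constructor re-verifies this with the
exhaustive oracle (and rejects planted selections containing an adverse
pair) before returning.

## Benchmark protocol and statistics

Every algorithm is run `n_runs = 50` times per instance under an equal
evaluation budget with per-run seeds. Reports carry worst/best/mean,
sample standard deviation, a symmetric 95% t-interval on the mean, a
p-value against random search on the same instance and budget (the
"produced by chance" column — undefined in the source protocol; rank-sum
against equal-budget random search is the interpretation used here), and
one-sided Wilcoxon rank-sum comparisons against the base algorithm with
the decision rule: p < 0.05 rejects H0 (equal performance) in favor of H1
(base more efficient). The exact rank-sum distribution is used when both
samples are at most 25 with no ties, otherwise the tie-corrected normal
approximation; two identical constant samples return p = 1 with a warning
rather than a spurious decision.

## Numerical choices and edge cases

* Infeasibility sentinel: finite, instance-dependent (see above).
* Group quotas: largest-remainder rounding; property shift −min + 1
  applied only when some property is nonpositive.
* Similarity weights: $w_r = \min(d_r, 1) \cdot \min(C_{a,r}, C_{b,r}) /
  (\max(C_{a,r}, C_{b,r}) + \varepsilon)$ with $\varepsilon = 10^{-12}$;
  the component frequency $d_r$ defaults to the fraction of corpus drugs
  containing the component, or 1 without a corpus. Two modes ship because
  the literal ratio form is unbounded on realistic formulas; the weighted
  cosine (default) is bounded in [0, 1]. The cosine is *not* monotone
  under adding a shared equal-count component: proportional vectors sit at
  exactly 1 and any addition pulls them below it.
* Formula parsing is case-sensitive Hill notation tolerating underscores;
  a lone hydrogen in a carbon-rich formula parses verbatim but warns,
  since such strings are usually truncated exports.

## Problem sizes used by the test suite

The oracle-equivalence study runs 30 preset-shaped instances capped at 15
candidates (so the exhaustive optimum is exact) with 50 seeded Trader and
random-search runs each at a 5,000-evaluation budget; planted-recovery
uses k in 1..3 and n in {10, 15, 20}; the type-I study performs 200
self-comparisons of 20-run random-search streams. These sizes keep the
full suite within a few minutes on one core while leaving every statistic
well above its detection floor.

## Known limitations

* Improvement-only acceptance can absorb the whole population at a strict
  local optimum: once all groups hold the same solution, retailing's small
  flip radius (ceiling(m/10)) is the only exploration left, and a hard
  adverse-reaction constraint can wall off the basin of the global
  optimum. The suite computes such a case (one preset-shaped instance
  where a selection one tie-move deep traps a minority of runs); larger
  budgets do not rescue absorbed runs. Penalty mode or restarts would
  mitigate this but are deliberately outside the algorithm's definition.
* The exhaustive oracle is limited to 20 candidates; beyond that only
  relative comparisons between optimizers are available.
* Engines encode coverage as 30-bit masks, so instances are limited to 30
  distinct main targets (far above any published pool shape).
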