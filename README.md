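# syntrader

Synthetic drug repurposing: replacing a single drug with a **combination**
of other approved drugs that jointly cover its disease-relevant targets —
ideally with fewer total side effects and no adverse drug-drug pairs. The
package is aimed at computational drug-repurposing researchers who want a
reproducible, fully testable implementation of the two-step pipeline:
deterministic If-Then association rules mine candidate drugs from
drug-target interaction matrices, and the **Trader** discrete metaheuristic
selects the best-scoring combination.

## The model

A candidate pool for substituting a given drug consists of `m` candidate
drugs, each covering a nonempty subset of the given drug's *main targets*
(with the pharmacologically required effect: INH/IND/AGO/ANT) and carrying
a side-effect count `SE_i` (its remaining drug-target interactions). A
binary selection `v` is scored

```
score(v) = AT(v) - sum(SE_i over selected) / (number selected)
```

where `AT(v)` is the number of distinct main targets covered by the union
of selected drugs. The score is maximized; reports negate it (lower is
better). Selections containing a drug-drug adverse-reaction pair are
infeasible under the default hard constraint mode.

Trader evolves a population of binary solutions organized into trader
groups: group masters *distribute* values to slaves, slaves *retail* (small
random flips), masters *import/export* values between groups, and group
sizes are reallocated each iteration in proportion to group properties
(sum of member scores, with a guaranteed minimum of 2 members per group).
Changes are kept only when they strictly improve the score; the stop rule
is a score-evaluation budget.

Also included: exact exhaustive oracles and generic baselines (random
search, hill climbing), a weighted chemical-formula similarity score,
synthetic instance generators with planted optima and published pool-shape
presets, and a benchmark harness (worst/best/mean/STD/95% CI, convergence
and stability traces, one-sided Wilcoxon rank-sum comparisons).

## Worked example

```r
library(syntrader)

# a Nicardipine-shaped pool: 4 main targets, 40 candidates
ds <- generate_instance(preset_spec("NIC", seed = 2))
ds
#> candidate_dataset: given drug 'GIVEN', 4 main target(s), 40 candidate(s), 48 adverse pair(s)

res <- run_trader(ds, trader_config(max_evaluations = 10000), seed = 1)
res
#> trader: objective -4.0000 (feasible), 10060 evaluations, selected {D023, D025}
```

The reported objective −4.0 means the selected pair covers all 4 main
targets with zero mean side-effect load — a perfect substitute under the
model; `feasible` confirms the pair has no adverse reaction. On small
pools the result can be certified exactly:

```r
small <- generate_instance(generator_spec(12, 3, seed = 5))
exhaustive_oracle(small)
#> oracle: objective -2.6667 over 1919 feasible selections
```

Chemical-formula similarity between a drug and a proposed substitute
(weighted cosine over element counts, in [0, 1]):

```r
similarity_table(c(Trandolapril = "C24H34N2O5", Cilazapril = "C22H31N3O5"),
                 data.frame(a = "Trandolapril", b = "Cilazapril"))
#>                    drug_a     drug_b similarity
#> Trandolapril Trandolapril Cilazapril   0.999591
```

A thin command-line dispatcher over the same functions ships at
`inst/cli/repurpose.R` with `mine`, `optimize`, `similarity` and
`benchmark` subcommands.

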