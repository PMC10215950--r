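# causalstab

Robustness analysis for learned causal structures: PC-stable structure
learning over categorical genotype data, customized graph-comparison
metrics, and a three-pillar leave-k-out resampling pipeline that
quantifies how much of a learned network — globally, and locally around an
outcome's Markov blanket — survives when patients are randomly excluded
from the dataset.

## Who this is for

Constraint-based learners such as the PC algorithm return a completed
partially directed acyclic graph (CPDAG): directed edges are orientations
shared by every DAG in the Markov equivalence class, undirected edges are
orientations the data cannot decide. Applied to a patients × SNPs table
(plus a clinical outcome such as a disease-complexity score), the graph
invites biological interpretation — but a single graph says nothing about
its own stability. causalstab answers the follow-up question: *if k of the
n patients had not been enrolled, how much of this structure would have
been learned anyway?*

## What it computes

For a dataset with n subjects, a k grid (default 1, 2, 3, 5, 10, 20, 30,
50) and R replicates (default 100) per k:

1. **Pillar I — global stability.** Learn the reference CPDAG on all n
   subjects; per replicate, remove k random subjects, re-learn, and
   tally: common undirected edges, common directed edges, directed edges
   that turned undirected / changed direction / vanished (a partition of
   the reference's directed edges), the structural Hamming distance
   (SHD), and the relative SHD `100 · SHD / C(p, 2)`.
2. **Pillar II — stability of a similarity.** The same comparison between
   two structures re-learned from two subpopulations (e.g. outcome = 0 vs
   outcome > 0), with per-k means expressed as ratios to the unperturbed
   baseline comparison.
3. **Pillar III — local stability.** The Markov blanket (parents,
   children, spouses) of the outcome variable is re-determined per
   replicate; the pipeline reports per-variable inclusion percentages,
   the distribution of how many reference-blanket members are recovered,
   and the mean number of extra variables.

The learner is PC-stable with a stratified G² conditional-independence
test for categorical data (a symmetric two-response multinomial
likelihood-ratio test is available), conservative collider checking, and
Meek-rule completion; `alpha = 0.005` throughout by default. A discrete
Bayesian-network simulator with a plantable outcome blanket
(`gess_like_scenario()`, `plant_outcome()`) provides ground truth for
validation, and a d-separation oracle (`dsep_oracle()`) lets every graph
operation be tested exactly. See the vignette in `vignettes/` for the
model, the design decisions and their rationale.

## Worked example

Simulate a 600-patient, 12-SNP cohort whose outcome has a planted
four-variable Markov blanket, learn the structure, and check the blanket:

```r
library(causalstab)
sc <- gess_like_scenario(n_snps = 12, n = 600, seed = 42)
ds <- simulate_dataset(sc)
g  <- learn_cpdag(ds, alpha = 0.005)
g
#> mixed_graph: 13 nodes, 6 undirected, 4 directed edge(s)
#>   rs003 -> syntax_score
#>   rs005 -> rs007
#>   rs009 -> syntax_score
#>   syntax_score -> rs007
#>   rs001 -- rs006
#>   ...
markov_blanket(g, "syntax_score")
#> [1] "rs003" "rs005" "rs007" "rs009"
sort(sc$planted_mb)   # the planted truth
#> [1] "rs003" "rs005" "rs007" "rs009"
```

The learned blanket equals the planted one: rs003 and rs009 are recovered
as parents of the outcome, rs007 as its child, and rs005 enters as the
child's other parent (spouse). Now quantify global stability under
leave-k-out for a 25-SNP cohort with heterogeneous effect sizes:

```r
options(scipen = 6)
sc  <- gess_like_scenario(n_snps = 25, n = 597, seed = 11, strength = c(0.3, 5))
ds  <- simulate_dataset(sc)
keep <- setdiff(ds$variables, "syntax_score")
snp <- genotype_dataset(ds$values[, keep], cardinalities = ds$cardinalities[keep])
p1  <- run_pillar_one(snp, resampling_plan(k_grid = c(1, 5, 20, 50),
                                           replicates = 30, master_seed = 11))
format_pillar_one(p1)
#>                                                          metric k=1    k=5   k=20  k=50
#> 1                        mean number of common undirected edges  10  10.00  10.00  9.87
#> 2                mean percentage of common undirected edges (%) 100 100.00 100.00 98.67
#> 3                          mean number of common directed edges   9   9.00   8.93  8.53
#> 4                  mean percentage of common directed edges (%) 100 100.00  99.26 94.81
#> 5               mean number of directed edges turned undirected   0   0.00   0.00  0.10
#> 6       mean percentage of directed edges turned undirected (%)   0   0.00   0.00  1.11
#> 7          mean number of directed edges that changed direction   0   0.00   0.07  0.37
#> 8  mean percentage of directed edges that changed direction (%)   0   0.00   0.74  4.07
#> 9                              mean structural Hamming distance   0   0.07   0.20  0.90
#> 10                mean relative structural Hamming distance (%)   0   0.02   0.07  0.30
```

Read the columns left to right: removing a single patient changes
nothing; by k = 50 (8% of the cohort) about 5% of the directed edges are
no longer recovered with their orientation — most of those changed
direction rather than disappearing — and the mean SHD to the reference has
grown from 0 to 0.9 operators. Mild interventions leave the structure
essentially intact; stronger ones bite, and the metrics say exactly
where.

`run_command("all", config)` wires the whole flow — simulate or read a
CSV, complete-case filter, outcome split, all three pillars — and writes
wide/long CSV tables plus a manifest that reproduces the run byte for
byte; `inst/scripts/causalstab-cli.R` exposes the same commands from a
shell.

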