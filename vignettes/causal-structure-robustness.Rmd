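---
title: "Assessing the robustness of learned causal structures by leave-k-out resampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the robustness of learned causal structures by leave-k-out resampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalstab)
```

## The question the package answers

A constraint-based structure learner applied to a patients-by-genotypes
table returns a single graph: a completed partially directed acyclic graph
(CPDAG) whose directed edges are orientations shared by every member of a
Markov equivalence class and whose undirected edges are orientations that
the data cannot decide. Before reading biology off such a graph one should
ask how much of it survives a perturbation of the sample. causalstab
operationalizes that question as *leave-k-out resampling*: remove k
randomly chosen patients, re-learn the structure on the n − k that remain,
compare the re-learned graph to the reference, and repeat — by default 100
times per k over the grid k ∈ {1, 2, 3, 5, 10, 20, 30, 50}. Stability is
then summarized along three pillars:

1. **Global stability of one structure.** For each k, the mean number (and
   percentage) of the reference's undirected and directed edges that are
   preserved, the directed edges that turned undirected, changed direction,
   or vanished, and the mean structural Hamming distance (SHD) to the
   reference.
2. **Stability of the similarity between two structures** (e.g. the
   subpopulations with zero and positive values of a clinical outcome):
   the same quantities computed between the two independently re-learned
   graphs, expressed relative to the unperturbed baseline comparison.
3. **Local stability around an outcome.** The Markov blanket of the
   outcome variable — its parents, children and spouses — is re-determined
   per replicate; the package tallies per-variable inclusion percentages,
   the distribution of how many reference-blanket members are recovered,
   and the mean number of extra variables.

## The learner

The structure learner is PC in its *stable* variant: at level
$\ell$ the adjacency sets are frozen at the start of the level, and every
surviving pair $(X, Y)$ is tested against conditioning sets $S$ of size
$\ell$ drawn from the frozen neighbourhoods of $X$ and of $Y$. An edge is
removed at the first test with $p > \alpha$ and the separating set is
recorded. The frozen snapshots make the skeleton invariant to the column
order of the input, which matters here: resampling metrics would otherwise
confound sampling noise with order effects.

Conditional independence between categorical genotype variables is tested
with the likelihood-ratio statistic
$$G^2 = 2 \sum_{ijk} O_{ijk} \log \frac{O_{ijk}}{E_{ijk}},$$
summed over the strata of the conditioning configuration. Degrees of
freedom accumulate per stratum as
$(\text{rows}_+ - 1)(\text{cols}_+ - 1)$ over the observed positive
margins, so empty categories and empty strata contribute nothing; when no
stratum retains positive degrees of freedom the test is undecidable and is
treated as independence. A conditioning set whose configuration count
exceeds what any sample could populate is treated the same way. The
two-response symmetric test is available as an alternative: each variable
in turn is modelled as a multinomial logistic response on $S$ and on
$S \cup \{$other$\}$, the two likelihood-ratio p-values are combined —
by default by taking their maximum, a conservative and symmetric rule;
Fisher's combination is the alternative — and a non-convergent fit falls
back to $G^2$.

### Collider orientation

After skeleton search, unshielded triples $x - y - z$ are examined for
colliders. The textbook rule orients $x \to y \leftarrow z$ whenever $y$
is absent from the recorded separating set of $(x, z)$. That rule is
exact under a d-separation oracle but brittle on finite data: one
false-positive adjacency incident to a true collider's parent creates a
spurious unshielded triple whose (correctly) empty separating set demands
the opposite orientation, and the two demands cancel. In desk-scale
experiments during development this single mechanism destroyed about one
in five planted local structures. `learn_cpdag()` therefore defaults to
*conservative* collider checking: for each unshielded triple all
separating subsets of the two endpoints' neighbourhoods (up to
`max_cond`) are re-examined, and the triple is declared a collider only
when $y$ lies in none of them, a non-collider when it lies in all, and is
left unoriented otherwise. Under the oracle the two rules coincide; the
sepset rule remains available (`v_rule = "sepset"`, and it is the default
of the lower-level `orient_v_structures()`).

Orientation demands are collected first and applied together: an edge
demanded in both directions reverts to undirected, and an orientation that
would close a directed cycle is skipped; both events are logged in the
`orientation_conflicts` attribute. This guarantees that the directed part
of every returned graph is acyclic even under adversarial test noise.
Orientation is completed with Meek's rules 1–4 to a fixpoint (rules 1–3
already suffice for PC output without background knowledge; rule 4 is
included for completeness with the usual adjacency side-condition).

### Markov blanket on a CPDAG

`markov_blanket()` returns parents, children, *undirected neighbours*
(each is a parent or child in some member of the equivalence class), and
spouses computed only through strictly directed child edges. The target is
never a member of its own blanket.

## Comparison metrics

`edge_overlap()` classifies every node pair of the reference against the
re-learned graph. The four fates of a directed reference edge — preserved,
turned undirected, reversed, vanished — partition the reference's directed
edges; the identity is asserted on every call. SHD follows the operator
list *add/delete an undirected edge; add, remove, or reverse an
orientation*: per pair, equal states cost 0; directed vs reversed,
directed vs undirected, and undirected vs absent cost 1; directed vs
absent costs 2 (remove the orientation, then delete the edge). Some
published variants charge 1 for that last case; `directed_absent_cost = 1`
selects it, the literal operator count of 2 is the default. The suite
verifies the implementation against a brute-force breadth-first search
over the full operator graph of all three-node structures.

The *relative* SHD divides by the largest value the distance could take
if every pair relation were altered, with one alteration counted per
pair: $100 \cdot \mathrm{SHD} / \binom{p}{2}$. With the cost-2 convention
a graph pair can in principle exceed this reference point; the quantity
is a normalization to panel size, not a probability. Published tables
based on this family of metrics are not always reconstructible to the
last printed hundredth from any single denominator convention; the
package states its convention rather than reverse-engineering any
particular rounding path.

All percentages are computed on unrounded means and rounded only for
presentation, half away from zero at two decimals — the convention that
reproduces printed values such as $100 \cdot 34.21/40 = 85.53$, where
round-half-to-even would print 85.52. A percentage with a zero reference
total is reported as `NA`, never as 0.

## The resampling pipeline

`resampling_plan()` holds the k grid, the replicate count and a master
seed. The seed of replicate $r$ at level $k$ is derived as
$\mathrm{master} + 1009\,k + 9973\,r \pmod{2^{31}-2}$, a counter scheme
that makes each replicate's subject draw independent of the order in
which the k grid is traversed; the two primes cannot collide on any
realistic grid. In pillar II the two datasets draw their exclusion
subsets independently (a second counter stream), since nothing ties a
removed patient in one subpopulation to one in the other. Replicates that
fail (e.g. a degenerate subsample) are excluded from the means and
counted; more than 10% failures at one k aborts that level. `k = 0` is
accepted as a self-agreement control and must return 100% agreement
everywhere — the suite asserts it.

The outcome column is excluded when learning the genotype-only
structures (pillars I and II) and retained, as a categorical variable,
for pillar III. A continuous outcome is discretized first;
`discretize_outcome()` defaults to three quantile bins over the analysed
subjects, with binary (zero vs positive) and raw-integer codings as
alternatives. No published convention exists for this choice, so it is a
documented knob rather than a fixed rule.

Determinism is a contract: two runs of `run_command("all", cfg)` with the
same configuration write byte-identical tables and manifests (the
manifest echoes seeds, settings and package version, and deliberately
omits the output path).

## The synthetic generator

Real genotype panels with matched clinical outcomes are rarely
redistributable, so the package ships a simulator rich enough to make
every stage testable against known ground truth. `random_dag()` samples a
topological order and includes forward pairs independently; the default
density in `gess_like_scenario()` targets expected degree ≈ 1, matching
the sparsity that constraint-based learners typically report on SNP
panels at stringent significance levels. Each variable carries three
categories (genotype dose codes 0/1/2) whose base distribution is drawn
from a symmetric Dirichlet, imitating allele-frequency variation.

Dependence is injected by tilting each parent-configuration row of a
child's conditional table towards a modal category with weight
`strength`: row $= (\mathrm{base} + s\,e_{\mathrm{mode}})/(1+s)$, so
$s = 0$ recovers exact independence and large $s$ pushes the modal
probability towards 1. The mode follows an additive dose-response in the
summed parent codes — the standard picture of allelic dose effects — so
that every parent has a monotone, individually detectable marginal
effect. (An earlier design drew modes independently per configuration;
it routinely produced parents whose marginal effect vanished by
cancellation, which defeats the generator's purpose of providing
recoverable ground truth.) `strength` may also be a range: per-node
strengths are then drawn log-uniformly, giving the heterogeneous
spectrum — some relations strong, some hovering at the detection
boundary — that makes resampling degradation visible at small k, as in
real association data. The homogeneous default (`strength = 5`) is used
where exact recovery of a planted structure is the point; the
heterogeneous regime (`strength = c(0.1, 5)`) where degradation trends
are the point.

`plant_outcome()` adds an outcome node wired so that its graph-theoretic
Markov blanket equals a designated parents ∪ children ∪ spouses set (the
default scenario plants two parents, one child and one spouse — a
four-variable blanket). The construction validates itself: children may
not have parents outside the spouse set, spouse wiring may not close a
cycle, and the resulting blanket is checked against the request.
`gess_like_scenario()` draws the child from previously unconnected loci
and the other blanket members from parentless loci, so the planted
blanket is identifiable rather than entangled with upstream structure.

What the generator does **not** emulate: linkage-disequilibrium block
structure, Hardy–Weinberg allele-frequency constraints, covariates, and
continuous liability mechanisms for the outcome. Passing tests therefore
certify the pipeline's statistical machinery on faithful discrete
Bayesian networks — they do not certify that any particular biological
dataset satisfies faithfulness or causal sufficiency, which the PC
framework assumes throughout.

## Defaults, sizes and numerical choices

* `alpha = 0.005` — the working significance level of the study design
  this pipeline follows; every CI decision uses it.
* `max_cond = 3` — the largest conditioning set searched. Unbounded
  search is permitted but rarely changes sparse skeletons and costs
  combinatorially.
* k grid `{1, 2, 3, 5, 10, 20, 30, 50}`, 100 replicates — the study
  defaults in `resampling_plan()` and `validate_config()`.
* The test suite exercises the pipeline at reduced sizes chosen to keep a
  full run in minutes on one core: 25-variable scenarios with n = 597,
  30 replicates over k ∈ {1, 5, 20}, ten master seeds for the
  planted-blanket separation property and thirty for the degradation
  trend; the oracle equivalence-class property uses 500 random DAGs on up
  to six nodes; CI-test calibration uses 2000 null simulations at
  n = 500.
* G² contingency counting is implemented in C++; everything else is plain
  R on integer matrices.

## Known limitations

* Finite-sample orientation noise is irreducible at fixed alpha: a
  false-positive adjacency rate of about `alpha` per tested pair does not
  vanish with n, so exact CPDAG recovery on data is a property of
  favourable instances, not a guarantee. The conservative collider rule
  reduces, but does not eliminate, its effect on local structure.
* The symmetric two-response test refits two multinomial models per
  query and is markedly slower than G²; it is provided for fidelity to
  regression-based testing practice, not as the workhorse.
* Pillar II's baseline ratios are undefined when the two reference
  structures share no edges of the relevant kind; the tables report `NA`
  there.
* The pipeline treats subjects as exchangeable; stratified or related
  samples would need a resampling scheme the package does not provide.
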