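---
title: "Methods: resistance, resilience and co-occurrence analysis of disturbed microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resistance, resilience and co-occurrence analysis of disturbed microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripresil)
```

## The scientific setting

Riparian soils along regulated rivers are flooded and re-exposed in cycles.
A space-for-time design samples each study area in three groups: *reference*
soils at an elevation never reached by the water, *flooding* soils currently
under the influence of inundation, and *recovery* soils that were flooded
and have since been re-exposed. Comparing the three groups asks two
questions about a community variable (total gene-copy abundance, an alpha
diversity index, or the relative abundance of a taxon): how much did the
disturbance change it, and how completely has it returned?

## The resistance and resilience indices

Let $C_0$ be the reference-group mean of a variable, $P_0$ the
flooding-group mean and $P_x$ the recovery-group mean. Because the
reference sites are assumed stable over the study, the end-of-study
reference value $C_x$ is taken equal to $C_0$. The two indices are

$$
RS \;=\; 1 - \frac{2\,|C_0 - P_0|}{C_0 + |C_0 - P_0|},
\qquad
RL \;=\; \frac{2\,|C_0 - P_0|}{|C_0 - P_0| + |C_0 - P_x|} - 1 .
$$

Both lie in $[-1, 1]$. $RS = +1$ exactly when the disturbance changed
nothing (maximal resistance), and $RS \to -1$ as the disturbed value grows
without bound relative to the reference. $RL = +1$ exactly when the
recovery group sits back on the reference value (complete recovery),
$RL = 0$ when it is as far from the reference as the flooded group was, and
$RL < 0$ when it drifted further away. Both indices are invariant to
rescaling $(C_0, P_0, P_x)$ by any positive constant, which is what
justifies applying the same formulas to absolute copy numbers, to
dimensionless diversity indices and to relative abundances.

Two degenerate cases need a convention, and ours is:

* $C_0 = P_0 = 0$ (the variable is absent everywhere): `resistance_index()`
  returns 1 — nothing changed. The raw formula is 0/0 here. Synthetic taxa
  can hit this case even though field data rarely do.
* $C_0 = P_0$ (no displacement): `resilience_index()` returns `NA` rather
  than the raw formula's limit of $-1$, because "recovery" is meaningless
  when nothing was displaced. Pipelines report these as `NA` and warn.

Group means are unweighted arithmetic means over the samples of one
(area, group) cell. Full precision is kept internally; report tables round
to two decimals.

```{r indices}
# reference 3.2e8, flooding 1.2e9, recovery 2.1e8 copies per g d.w.s.
c(rs = resistance_index(3.2e8, 1.2e9),
  rl = resilience_index(3.2e8, 1.2e9, 2.1e8))
```

Note that agreement with published two-decimal index tables is to rounded
precision only: indices recomputed from *printed, rounded* group means can
differ in the second decimal from values computed on unrounded source data
(e.g. $RS(8.6\times10^8, 1.9\times10^9) = -0.095$, which a source working
from unrounded means may print as $-0.10$).

## Rarefaction and alpha diversity

Sequencing effort differs between samples, so counts are rarefied —
subsampled without replacement — to a common depth before diversity is
compared; `rarefy_table()` errors when the requested depth exceeds a
sample's total unless `drop_shallow = TRUE`. Rarefaction is a single draw
under a fixed seed (each sample gets a deterministic substream), with a
`rarefaction_curve()` helper for depth-sensitivity checks. Diversity is
computed after metadata filtering, on the rarefied table.

The indices are the standard ones, implemented from their definitions and
cross-checked against vegan in the test suite:

* Shannon $H = -\sum_i p_i \ln p_i$ over taxa with positive counts
  (natural log by default; the base is an argument).
* Chao1 in the bias-corrected form
  $S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))$, defined even without
  doubletons; the classic $S_{obs} + F_1^2/(2F_2)$ is available by flag.
* Pielou evenness $J = H / \ln S_{obs}$, reported as `NA` when only one
  taxon is observed.

Pairwise community dissimilarity is Bray–Curtis,
$d(A,B) = 1 - 2\sum_i \min(A_i, B_i) / (\sum_i A_i + \sum_i B_i)$.

## Group comparisons

ANOSIM is implemented from scratch: all $n(n-1)/2$ pairwise dissimilarities
are ranked (average ranks on ties), and
$R = (\bar r_{between} - \bar r_{within}) / (n(n-1)/4)$. The one-sided p
value permutes group labels over samples, with the add-one convention
$p = (1 + \#\{R_{perm} \ge R_{obs}\})/(1 + N)$ so p is never 0 and never
below $1/(N+1)$. The default is 999 permutations. Pairwise comparisons
between the three groups subset the precomputed distance matrix and re-rank
within the subset; recomputing distances per pair would give identical
values since Bray–Curtis is pairwise, so only the rank pool differs from a
joint analysis.

Kruskal–Wallis uses the tie-corrected $H$ with the $\chi^2_{k-1}$
approximation (identical values give $H = 0$, $p = 1$). Mann–Whitney
reports the smaller of the mirrored $U$ statistics; the two-sided p is
exact (from the exact Wilcoxon null distribution) when
$n_a n_b \le 400$ and there are no ties, otherwise a normal approximation
with tie and continuity corrections. ANOSIM p values are one-sided (large
$R$ = separation); $U$ and $H$ tests are two-sided. No multiple-testing
correction is applied by default; `p.adjust`-style correction is left to
the caller, matching common practice for these report tables.

## Co-occurrence networks

Networks are built at genus level: OTU tables are aggregated with
`aggregate_to_rank()`, which sums rows sharing a genus name and pools taxa
unresolved at that rank into one `unclassified_<parent>` row per parent
lineage — pooling rather than dropping keeps per-sample totals exactly
conserved. Correlations are Spearman: ranks per taxon (average ranks on
ties), Pearson on the ranks, and a two-sided p from the $t$ approximation
on $n-2$ degrees of freedom. Taxa constant across samples have undefined
correlations and are reported `NA` with a warning.

An edge joins two genera iff $|\rho| > 0.6$ **and** $p < 0.01$, both strict
inequalities. No multiple-testing correction is applied to the pair p
values by default. Because taxa detected in only a few samples produce
rank vectors dominated by tied zeros, `filter_network_taxa()` keeps genera
present in at least a third of samples by default (plus an optional mean
relative-abundance floor); both thresholds are fully exposed, and
`drop_isolated` controls whether unconnected genera count as nodes, since
either convention is defensible when comparing node counts between areas.

`topology_summary()` reports: node and edge counts split by correlation
sign; average degree $avgK = 2E/N$; average path length and diameter on the
largest connected component of the unweighted graph (thresholded networks
are often disconnected, and path lengths over an entire disconnected graph
are undefined — the summary also records the component size so this choice
is visible); mean local clustering coefficient with nodes of degree $< 2$
contributing 0; and modularity $Q$ from Louvain community detection on the
unweighted, sign-ignored graph under a fixed seed — the workflow of common
graph viewers. Signed or weighted modularity variants are deliberately out
of scope. Louvain is seeded and therefore reproducible run-to-run; across
seeds $Q$ varies little on the fixtures we test (< 0.05), but it is a
heuristic optimum, not an exact one.

Networks export to GraphML, GEXF 1.2 and a plain edge-list TSV, preserving
phylum and degree on nodes and $\rho$, p and sign on edges.

## The synthetic-data generator

Real surveys of this kind deposit raw reads, and reproducing their tables
requires the full upstream read-processing chain. To make every downstream
stage testable on its own, `generate_dataset()` emulates the study design
directly at the level the analyses consume — a rarefied genus table, a
sample sheet and a qPCR abundance series — with fully known ground truth:

* **Design.** Two areas ("NA", low anthropogenic pollution; "AA", high),
  per area 4 reference, 13 flooding and 7 recovery samples; 24 archaeal
  genera with built-in lineages (ammonia-oxidising Thaumarchaeota,
  methanogenic Euryarchaeota, and others typical of riparian soil).
* **Counts.** Per sample, latent genus abundances are log-normal around
  baseline × group fold-change (a geometric rank-abundance baseline by
  default, log-sd 0.5), renormalised to proportions, and counts drawn
  multinomially at a fixed depth of 20,826 reads — the rarefied-table
  convention of the emulated study, and the reason every generated column
  sums to the depth exactly.
* **Group effects.** Defaults encode the disturbance response the study
  reports qualitatively: flooding enriches methanogens (×3) and depletes
  ammonia oxidisers (×0.4) in both areas; the recovery group returns nearly
  to baseline in NA (×1.15 / ×0.95) and only part-way in AA (×1.8 / ×0.65).
* **Abundance.** Total 16S copies per g dry-weight soil are log-normal
  around the published per-(area, group) qPCR means (NA:
  $8.6\times10^8 / 1.9\times10^9 / 4.6\times10^8$; AA:
  $3.2\times10^8 / 1.2\times10^9 / 2.1\times10^8$ for
  reference/flooding/recovery). The survey reports group means but not
  dispersions, so the coefficient of variation is our choice: 0.5 by
  default, a typical spread for qPCR copy numbers across field replicates.
* **Planted correlations.** A genus pair listed in `planted_edges` shares a
  per-sample standard-normal factor added to both log abundances with
  loading $\lambda$ (sign flipped for negative plants), giving a log-scale
  correlation of $\lambda^2 / (\lambda^2 + \sigma^2)$ before
  renormalisation.
* **Determinism.** One master seed; every sample draws from a
  deterministically derived substream, so datasets are bit-identical across
  runs and machines.

`ground_truth_rs_rl()` computes the RS/RL implied by a configuration by
pure arithmetic — on the configured abundance means, and on expected genus
proportions defined as renormalised baseline × fold.

### What the generator does and does not emulate

Passing tests on synthetic data shows the *estimators* recover known
truth under the generating model; it does not validate the upstream
bioinformatics (read QC, OTU picking, taxonomy assignment are out of
scope), nor does the logistic-normal/multinomial model capture PCR bias,
chimeras or spatial autocorrelation between neighbouring sampling sites.
Two model-level caveats matter when interpreting tests:

* **Renormalisation bias.** The expected value of a renormalised log-normal
  ratio is not exactly the renormalised expectation; the gap is second
  order in the log-sd. Convergence tests therefore compare empirical group
  means to the analytic expectations within three standard errors plus a
  small allowance of this order.
* **Compositional coupling.** Proportions share a common denominator, so a
  strongly fluctuating abundant genus induces correlations among all
  others. If correlation plants are placed on the *dominant* genera, their
  shared factor leaks into every proportion through the denominator and can
  blur the planted/null distinction. Edge-recovery tests therefore plant on
  an even (flat-baseline) community; this is a real limitation of
  correlation-based co-occurrence analysis on compositions, not just of the
  generator, and is one reason compositionality-aware methods exist (they
  are out of scope here, as the emulated analysis uses plain Spearman).

## Pipeline, determinism and problem sizes

`run_pipeline()` drives all stages per area from one config (JSON file or R
list) with a single seed: rarefy (to the shallowest sample by default) →
aggregate to genus → alpha diversity → RS/RL for abundance, Shannon, Chao1,
evenness and the top-4 most abundant taxa per area (top-k by total relative
abundance) → pairwise ANOSIM → network and topology. Outputs are plain TSV,
GraphML and a JSON manifest recording thresholds, seeds and file checksums;
no timestamps are written, so a rerun of the same config is byte-identical.
Any stage failure aborts with the stage name and offending entity.

The test suite runs the statistical machinery at deliberately small sizes —
6-sample toys for exhaustive permutation enumeration, 24-sample single-area
datasets for network recovery, the full two-area design at depth ~1,000–2,000
reads for pipeline tests, and a twenty-fold-enlarged design (80/260/140 per
area, CV 0.3) for RS/RL parameter recovery to within ±0.05. These sizes are
chosen so each property is measurable with comfortable Monte-Carlo margins
while the whole suite stays fast; the generator itself defaults to the
emulated study's real dimensions.

## Known limitations

* The indices compare group means only; within-group dispersion enters
  neither RS nor RL, and no uncertainty is attached to them (the emulated
  analysis reports them as point values). Bootstrapping over samples would
  be a natural extension.
* The three-group design collapses time: multi-timepoint resilience
  trajectories are out of scope.
* Spearman co-occurrence on relative abundances inherits the compositional
  caveats above; edges are associations, not interactions.
* The exact Mann-Whitney p is unavailable with ties (the normal
  approximation is used and flagged); the ANOSIM p resolution is bounded by
  the permutation count.
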