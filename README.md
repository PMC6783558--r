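# ripresil

Resistance and resilience analysis of disturbed microbial communities.

## What this package is for

Riparian soils along regulated rivers are periodically flooded and
re-exposed. A common way to ask whether the soil microbial (here: archaeal)
community withstands and recovers from such disturbance is a three-group,
space-for-time design per study area: **reference** soils at an elevation
the water never reaches, **flooding** soils currently inundated, and
**recovery** soils previously flooded and now exposed. `ripresil`
implements the complete downstream analysis for that design:

* **Resistance and resilience indices.** With C₀ the reference-group mean
  of a variable, P₀ the flooding-group mean and Pₓ the recovery-group mean
  (the reference is assumed stable, so Cₓ = C₀):

  ```
  RS = 1 − 2|C₀ − P₀| / (C₀ + |C₀ − P₀|)
  RL = 2|C₀ − P₀| / (|C₀ − P₀| + |C₀ − Pₓ|) − 1
  ```

  Both lie in [−1, 1]: RS = +1 means the disturbance changed nothing;
  RL = +1 means complete recovery, 0 no recovery beyond the disturbed
  state, negative values further drift. Applied to total 16S gene-copy
  abundance, alpha-diversity indices, and per-taxon relative abundances.

* **Rarefaction and alpha diversity**: subsampling without replacement to a
  common depth; Shannon H (natural log), bias-corrected Chao1, Pielou
  evenness; Bray–Curtis dissimilarities.

* **Group comparisons**: ANOSIM (rank-based R with label-permutation p,
  999 permutations by default, implemented from scratch), Kruskal–Wallis
  and Mann–Whitney U with tie handling.

* **Co-occurrence networks**: genus-level Spearman correlation matrices;
  an edge joins two genera iff |ρ| > 0.6 and p < 0.01 (strict); topology
  summaries — node/edge counts by sign, average degree avgK = 2E/N, path
  length and diameter on the largest component, clustering coefficient,
  Louvain modularity — and export to GraphML/GEXF/TSV.

* **A synthetic-data generator** that emulates the two-area, three-group
  survey (group sizes 4/13/7 per area, 24 archaeal genera, multinomial
  counts at a rarefied depth of 20,826 reads, log-normal qPCR abundances
  around published group means) with analytically known ground-truth RS/RL
  and planted genus–genus correlations, so the whole pipeline is testable
  without any sequence data.

## Worked example

Indices straight from published group means (archaeal 16S copies per gram
dry-weight soil in a high-pollution area: reference 3.2 × 10⁸, flooding
1.2 × 10⁹, recovery 2.1 × 10⁸):

```r
library(ripresil)
round(c(RS = resistance_index(3.2e8, 1.2e9),
        RL = resilience_index(3.2e8, 1.2e9, 2.1e8)), 2)
#>    RS    RL
#> -0.47  0.78
```

RS = −0.47 says flooding nearly quadrupled the abundance (low resistance);
RL = 0.78 says the recovery soils returned most of the way back to the
reference value (high resilience).

The same estimate from data — here a synthetic survey with those means as
ground truth:

```r
cfg <- synthetic_config(seed = 42)      # the emulated two-area design
d <- generate_dataset(cfg)
md_aa <- d$metadata[d$metadata$area == "AA", ]
rs_rl_profile(d$abundance, md_aa, "AA", "abundance",
              units = "copies per g d.w.s.")
#>   area  variable               units       c0       p0       px     rs    rl
#> 1   AA abundance copies per g d.w.s. 3.18e+08 1.16e+09 2.54e+08 -0.454 0.859
```

Community-composition comparison among the three groups of that area:

```r
dmat <- bray_curtis_matrix(subset_samples(d$table, md_aa$sample_id))
pairwise_anosim(dmat, setNames(md_aa$group, md_aa$sample_id),
                n_permutations = 999, seed = 42)
#>              comparison r_statistic p_value n_permutations
#> 1  flooding vs recovery       0.540   0.002            999
#> 2 flooding vs reference       0.885   0.001            999
#> 3 recovery vs reference       0.487   0.006            999
```

The flooded community differs sharply from the reference (R = 0.885); in
this high-pollution area the recovery group is still distinguishable from
the reference (R = 0.487, p = 0.006), i.e. incomplete compositional
recovery.

## The analysis workflow

The `analysis/` directory holds numbered drivers that run the whole study
on the default synthetic survey and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R              # dataset + analytic ground truth
Rscript analysis/02_diversity.R             # rarefaction, alpha diversity, Kruskal-Wallis
Rscript analysis/03_resilience.R            # RS/RL per area and variable
Rscript analysis/04_community_comparison.R  # Bray-Curtis + pairwise ANOSIM
Rscript analysis/05_network.R               # co-occurrence networks + topology
```

Every step is a thin script over exported package functions;
`run_pipeline()` performs the same chain from a single JSON/R config and
writes a checksummed manifest (reruns are byte-identical for a fixed
config and seed).

Methodological details — index conventions and degenerate cases, tie and
threshold handling, what the generator does and does not emulate — are in
the methods vignette: `vignettes/ripresil-methods.Rmd`.

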