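# connstate

Paired two-condition functional-connectome analysis in R: network-based
statistics (NBS) with permutation family-wise error control,
graph-theoretic characterisation against degree-preserving rewired
nulls, and covariate analyses of component connectivity — validated end
to end on a seeded synthetic-data generator that emulates a 24-subject,
two-condition (natural vs built environment viewing) resting-state fMRI
design.

## The problem

Given one ROI timeseries per subject and condition, does whole-network
functional connectivity differ between conditions, and does the
difference relate to subject covariates?  Edge-wise testing across all
N(N−1)/2 Pearson correlations needs family-wise error control; NBS
gains power by testing *connected components* of suprathreshold edges
instead of single edges:

1. per edge, a paired t statistic on the condition differences
   (optionally adjusted for a nuisance covariate such as the
   between-condition difference in mean framewise displacement);
2. edges with t above a primary threshold (default 2.5) form a graph
   whose connected components are found by breadth-first search;
3. each subject's difference vector is sign-flipped over `n_perm`
   permutations; the maximal component extent per permutation forms the
   null, and a component's FWE p-value is
   `(1 + #{null ≥ extent}) / (1 + n_perm)`.

Topology is characterised by five measures on binary graphs obtained by
proportional thresholding at cost K (the retained edge fraction):
betweenness fraction B, transitivity T, degree assortativity A, global
efficiency Geff, and small-worldness `S = (C/Crand)/(L/Lrand)` against a
Maslov–Sneppen rewired null.  Curves over the cost grid are reduced to
areas under the curve (AUC), compared between conditions by paired
sign-flip permutation, and corrected across the five measures by
Benjamini–Hochberg FDR (q < 0.05).

Because the kind of cohort data this design describes is typically not
public, the package ships a first-class generator
(`synthetic_config()` / `simulate_dataset()`) with planted
between-network condition effects, a planted covariate dependence, and
fully seeded reproducibility — so calibration (null rejection rates,
p-value uniformity), power, and parameter recovery are all testable.

## Worked example

The analysis is organised as numbered drivers over the package API; run
them from the repository root:

```sh
Rscript analysis/01_simulate.R     # synthetic cohort -> results/study/simulate
Rscript analysis/02_preprocess.R   # FD, inclusion, band-pass -> prep
Rscript analysis/03_connectome.R   # Pearson matrices -> connectome
Rscript analysis/04_nbs.R          # NBS, both contrasts -> nbs
Rscript analysis/05_graph.R        # measure curves, AUC tests -> graph
Rscript analysis/06_stats.R        # ratings, covariate analyses -> stats
```

With the default seed the drivers print (abridged):

```
mean FD, natural condition: 0.125 +/- 0.055 mm
mean FD, built condition:   0.126 +/- 0.080 mm
natural > built: component over {Somatomotor, DorsalAttention,
  VentralAttention, Default}, extent 3, p_fwe = 0.0036
built > natural: no suprathreshold component
Geff  AUC diff (natural - built) = +0.004259, p = 0.332, FDR-adjusted = 0.553
mean component connectivity (natural) vs years urban:
  r = -0.399 (df = 22), p = 0.05322
```

Read: the three planted between-network edges (Default–DorsalAttention,
Default–Somatomotor, DorsalAttention–VentralAttention) are recovered as
one significant NBS component in the natural > built contrast and in no
other (a stray single-edge component at p = 0.18 is correctly not
significant); no graph-measure AUC difference survives FDR (none was
planted); the planted negative dependence of natural-condition
component connectivity on years of urban upbringing is recovered with
the expected sign (one seed's estimate of a ρ ≈ −0.47 population
correlation).  Exact numbers vary with the seed in
`analysis/00_config.R`.

The same machinery is callable directly:

```r
library(connstate)
se  <- simulate_condition_edges(synthetic_config(seed = 1))
res <- nbs_permutation(se$stacked$conditions$natural,
                       se$stacked$conditions$built,
                       nbs_config(n_permutations = 10000,
                                  covariate = se$fd_diff, seed = 2))
print(res)
```

## Layout

```
R/                 package implementation (generator, prep, connectome,
                   NBS, graph measures/nulls/curves, group statistics,
                   pipeline orchestration, text I/O)
analysis/          numbered narrative drivers (the workflow)
scripts/           acceptance script
tests/testthat/    unit, property, and acceptance test suites
vignettes/         methods vignette (model, calibration, conventions)
inst/extdata/      editable 90-region -> 7-network mapping table
```
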