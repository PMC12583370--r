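# mitonet

Quantitative analysis of mitochondrial network morphology, compartmental
calcium, and cell viability from multi-channel fluorescence microscopy
fields, under two-factor treatment designs (KATP-channel modulation x
rotenone-induced mitochondrial stress).

The package is written for cell biologists who image a calcium indicator
(e.g. Fluo-4), a mitochondrial marker (e.g. MitoTracker) and an ER marker
(e.g. ER-Tracker) per field, and need the whole chain from raw channels to
publication statistics to be reproducible and testable. Because raw
microscopy data of this kind is rarely shareable, the package ships a
synthetic-field generator with exactly known ground truth (skeleton
topology, compartment intensities, factorial effect sizes), and its whole
verification suite runs against that truth.

## What it computes

**Morphology** — the mitochondrial channel is thresholded, cleaned,
thinned to a 1-pixel skeleton and parsed into a typed graph of branches
(`B`), junctions (`J`) and solitary rods (`R`, connected components
without a junction). Per field:

- fragmentation = `R / B` (each rod is one branch, so this is in [0, 1]),
- branching = `J / B`,
- mean branch length = mean branch pixel count x pixel size (um).

**Compartmental calcium** — background-corrected mean calcium-channel
intensity over the whole-cell, mitochondrial and ER masks
(`mean(channel[mask]) - background`, clipped at 0), with the background
taken as the median of the stain's negative control.

**Viability** — MTT absorbances as percent of the control-group mean
(control maps to exactly 100%), and per-replicate mean cell counts.

**Inference** — balanced two-way fixed-effects ANOVA with interaction
(first-principles sums of squares), Tukey HSD with adjusted p-values from
a direct numerical integration of the studentized-range distribution,
gatekept on the ANOVA (interaction significant -> cell means; otherwise
marginal means of each significant main effect), pooled-variance t-tests
against control, and a Pearson correlation matrix across variables. The
analysis unit is the biological replicate (fields are averaged first).

## Worked example

```r
library(mitonet)

# a ground-truth network: 12 branches, 4 junctions, 3 solitary rods
net <- generate_network(n_branches = 12, n_junctions = 4, n_rods = 3, seed = 7)
net
#> ground-truth network: 12 branches, 4 junctions, 3 rods on 512x512 grid

# render it as a noisy three-channel field and measure it back
field <- render_field(net, spec = render_spec(seed = 42))
measure_field(field, mn_config())[, 5:10]
#>  branch_count junction_count rod_count fragmentation branching mean_branch_length_um
#>            12              4         3          0.25 0.3333333              2.591667
```

The measured topology equals the generating truth exactly: fragmentation
0.25 = 3 rods / 12 branches, branching 0.333 = 4 junctions / 12 branches;
mean branch length is in micrometres (0.1 um/px default).

```r
measure_calcium(field, mn_config())[, 5:8]
#>  ca_whole_cell ca_mito ca_er background
#>          38.19      88  49.8      10.03
```

The generator placed calcium at 100 AU on mitochondria, 60 on ER, 40 in
the cytosol over a 10 AU background; the corrected means recover these
(mito 88 vs 90 generated — marker-defined masks carry a thin boundary
layer at cytosolic intensity, which biases organelle means down by a few
AU).

```r
# a simulated factorial experiment with the reported effect directions
spec <- reported_effects(effect_spec(seed = 11), magnitude = 2)
rep_df <- aggregate_replicates(generate_experiment(spec)$fields)
tab <- two_way_anova(rep_df$fragmentation, rep_df$katp_level, rep_df$rotenone,
                     term_names = c("katp", "rotenone"))
tab
#>            term df    sumsq   meansq statistic p_value
#> 1          katp  2 1.31e-05 6.54e-06   0.00194 0.99806
#> 2      rotenone  1 3.19e-02 3.19e-02   9.47242 0.00516
#> 3 katp:rotenone  2 7.90e-03 3.95e-03   1.17098 0.32716
#> 4     Residuals 24 8.09e-02 3.37e-03        NA      NA

gatekept_posthoc(tab, alpha = 0.05)$comparisons$rotenone
#>     group1  group2    diff    se    q   p_adj significant
#> 1 rotenone vehicle -0.0653 0.015 4.35 0.00516        TRUE
```

The simulated rotenone effect on fragmentation (+2 between-replicate sds)
is detected as a rotenone main effect (p = 0.005) with no KATP or
interaction signal, and the gatekeeper emits only the rotenone marginal
comparison.

## Batch pipeline

`mn_simulate()` writes a full factorial dataset (multi-page TIFF per
field + truth/design tables), `mn_measure()` produces tidy per-field
`morphology.csv` / `calcium.csv` (unreadable images become flagged rows),
`mn_stats()` writes `anova.csv`, `tukey.csv`, `ttests.csv`,
`correlations.csv` and a JSON run report. The same stages are available
from a shell:

```sh
Rscript inst/cli/mitonet.R all --out runs/demo --seed 1
```

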