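# xsmm

Positional and type effects of single-base probe–target mismatches on
oligonucleotide microarrays.

## The problem

Short-oligo expression arrays interrogate each transcript with 25-mer
probes. A single base difference between a probe and its target — a SNP, or
a species difference when samples are hybridized to an array designed for a
related genome — weakens the duplex and depresses the fluorescence signal.
How much signal is lost depends on *where* on the probe the mismatch sits
(position 1 = the free 5' end, position 25 = the surface-attached 3' end)
and on *which* base pair is disrupted.

`xsmm` implements the full analysis pipeline for quantifying these effects
when two array designs share consensus transcript sequences (the
cross-species human/rhesus setting is the motivating case):

1. **Discovery** — align each probe of one design to its probeset's
   consensus (semi-global, affine gaps), discard probesets whose probes do
   not align sequentially and completely, and call **PM/MM probe pairs**:
   a query probe with exactly one mismatch to the consensus (the MM probe)
   paired with the other design's probe that matches the consensus window
   exactly (the PM probe). Probes identical across designs become
   negative controls.
2. **Preprocessing** — quantile normalization applied *within replicate
   groups* (the two arrays sharing a platform and tissue).
3. **Effect estimation** — for each pair, the discrimination statistic
   log2(PM/MM_i) is the chip-effect coefficient of the additive
   tissue + chip linear model on per-(tissue, chip) mean log2 intensities;
   under the balanced design this equals the across-tissue mean of
   per-tissue PM−MM differences (both routes are computed and asserted
   equal).
4. **Summaries** — the per-position profile (n, mean, median, MAD, IQR),
   the regression of MAD on median across the 25 positions, the 12
   mismatch types (PM→MM notation: `C-A` means C on the PM probe, A on the
   MM probe) crossed with the 5'/center/3' position groups (1–8, 9–17,
   18–25) with pooled Student's t-tests, and t-tests of mismatch pairs
   against identical-probe controls.
5. **Cross-study comparison** — 12-type effect vectors from different
   studies are harmonized to a common stability direction, rank-ordered,
   and compared by Spearman and Pearson correlation (N = 12); types whose
   stability-list position contradicts Watson–Crick base-pairing
   (an A·T-pair mismatch outside positions 1–6, a C·G-pair mismatch inside
   them) are flagged as outliers.

A first-class synthetic data generator (`simulation_truth()`,
`generate_designs()`, `simulate_intensities()`) produces consensus
sequences, paired designs with controlled substitutions, and intensities
under a known penalty surface delta(position, type), so every stage is
testable against ground truth without any external download.

## Worked example

```r
library(xsmm)
library(dplyr)

truth   <- simulation_truth(seed = 42)          # default penalty surface
designs <- generate_designs(truth, n_probesets = 400, probes_per_set = 11)
ints    <- simulate_intensities(truth, designs)

pm <- list(values = quantile_normalize(ints$pm$values, ints$pm$metadata),
           metadata = ints$pm$metadata)
qu <- list(values = quantile_normalize(ints$query$values, ints$query$metadata),
           metadata = ints$query$metadata)

calls <- call_mismatch_pairs(
  filter_probesets(align_probes(designs$query_probes, designs$consensus))$kept,
  designs$pm_probes, designs$consensus
)
#> pairs: 1299   controls: 2622

estimates <- estimate_log_ratios(calls$pairs, pm, qu)
profile   <- position_profile(estimates)
profile[10:14, ]
#>   position     n  mean median   mad   iqr
#> 1       10    50 0.900  0.890 0.210 0.420
#> 2       11    39 0.971  0.928 0.234 0.413
#> 3       12    49 0.956  0.940 0.155 0.325
#> 4       13    49 0.972  0.942 0.217 0.459
#> 5       14    55 0.901  0.868 0.179 0.319

glance(spread_regression(profile))
#>   r.squared slope intercept n_positions
#> 1     0.283 0.143    0.0539          25

g <- tapply(estimates$estimate, position_group(estimates$position), mean)
contrast_percent(g[["five_prime"]],  g[["center"]], "log2")  # +13.8 %
contrast_percent(g[["three_prime"]], g[["center"]], "log2")  # +18.1 %
```

The per-pair estimates sit near one log2 unit (the generator's peak
penalty), central mismatches cost more than terminal ones — the center
group is ~14% and ~18% above the 5' and 3' flanks here — and the positional
spread grows with the positional median. `plot_position_profile()`,
`plot_type_group_summary()` and `autoplot()` on the spread fit draw the
standard figures; `tidy()`/`glance()` expose fits broom-style.

The same run can be driven from a single YAML config:

```r
run_pipeline(pipeline_config(
  system.file("extdata", "demo_config.yaml", package = "xsmm"),
  out_dir = "demo_results"
))
```

which writes `pairs.tsv`, `position_profile.tsv`, `spread_regression.tsv`,
`type_group_summary.tsv`, `control_tests.tsv` and a `manifest.json` with
per-file digests; identical config + seed reproduce byte-identical
outputs. A thin command-line wrapper lives at `inst/scripts/xsmm`.

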