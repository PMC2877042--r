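---
title: "Estimating positional and type effects of single-base probe mismatches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating positional and type effects of single-base probe mismatches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xsmm)
```

## The measurement model

A 25-mer probe hybridized to a target carrying one complementary-base
difference yields less signal than its perfectly matching counterpart. When
two array designs interrogate the same transcripts — one matching the
consensus sequences exactly, one carrying naturally occurring single-base
differences — every such probe duo is a PM/MM pair whose signal ratio
measures the mismatch penalty *in situ*.

`xsmm` models the probe-level log2 intensity of probe $p$ on array
$(t, r)$ (tissue $t$, replicate $r$) as

$$
y_{ptr} = a_p + \tau_t - \delta(i_p, m_p)\,[p \text{ is a mismatch copy}] + \varepsilon_{ptr},
$$

where $a_p$ is a probe affinity shared by the two members of a pair,
$\tau_t$ a tissue abundance offset, $\delta(i, m)$ the penalty (log2
units) of a mismatch at probe position $i \in 1..25$ of type $m$ (12
ordered PM$\to$MM base pairs), and $\varepsilon$ measurement noise. The
target of inference is $\delta$, summarized by position and by type.

The discrimination statistic for a pair whose mismatch sits at position
$i$ is $\log_2(\mathrm{PM}/\mathrm{MM}_i)$. Per tissue, replicate log2
intensities are averaged; the pair's estimate is the chip-effect
coefficient of the additive two-factor model
$\bar y_{tc} = \mu + \tau_t + \beta\,[c = \mathrm{PM}]$ fitted to the ten
(tissue, chip) cell means. The stated design is balanced, so this
coefficient reduces in closed form to the across-tissue mean of per-tissue
PM$-$MM differences. `estimate_log_ratios()` computes **both** routes —
the closed form and the least-squares projection — and aborts if they
disagree beyond $10^{-8}$; the equivalence is also pinned against an
independent `lm()` oracle in the test suite. The two-factor reading is a
deliberate resolution of an ambiguity in the source description of the
procedure (a "one-way" analysis with two named variables): under balance
the distinction carries no numerical consequence, which is exactly what
the dual-route assertion verifies on every run.

## Pair discovery

Probes of the query design are aligned to their probeset's consensus with
a semi-global aligner: the probe end-to-end, consensus overhangs free,
affine gap costs. The score scale is match $+1$, mismatch $-1$, gap open
$5$, gap extend $0.5$ — chosen so that for a 25-mer one substitution
(cost 2) always beats any gapped alternative (cost $\ge 5.5$). The
original discovery procedure used a proprietary aligner with analogous
gap-weight and length-weight roles; bit-compatibility with that tool is
neither possible nor useful, so correctness is anchored instead to a
brute-force sliding-window Hamming oracle, to which the aligner must be
identical on indel-free inputs.

Two implementation details matter:

* **Fast path.** The best ungapped window is found by a vectorized
  Hamming scan. If its score meets the upper bound attainable by *any*
  gapped alignment ($25 - 5.5 = 19.5$, i.e. at most two mismatches), it
  is provably optimal and returned directly — with the leftmost window
  taken on ties. Only noisier probes (three or more mismatches) fall
  through to the full dynamic program, whose gapped results are
  discarded by the downstream filter anyway; there, ties resolve to the
  leftmost alignment end.
* **Filtering.** A probeset survives iff alignment starts are strictly
  increasing in probe order ("sequential") and every probe aligns fully
  without gaps ("complete"); the discard log names the first violated
  criterion. "Sequential" is interpreted as strict increase because probe
  windows are tiled along the transcript; the source description does not
  define it further.

A pair is then called iff the query probe has exactly one mismatch to the
consensus *and* the PM design contains a probe exactly equal to the
aligned consensus window. The mismatch type is read as (consensus base,
probe base) — valid because the PM probe matches the window exactly. A
window matching PM probes of the probe's own probeset wins; a unique
match elsewhere is accepted; matches confined to several foreign
probesets raise an ambiguity error (the source procedure does not state
its resolution, so the package refuses to guess silently). Query probes
with zero mismatches whose windows have identical PM partners become
negative controls; probes with two or more mismatches are dropped.

## Normalization

Quantile normalization is applied within replicate groups — by default the
two arrays sharing a (platform, tissue) cell, following the stated
preprocessing contract; a per-platform grouping is available for
sensitivity analysis. Within a group, each column's sorted values are
replaced by the across-column mean of order statistics. Ties share the
average of the reference quantiles over their rank span; this is the
common convention and is stated here because the source does not specify
one. With ties present, exact distribution equality across columns cannot
hold (the tied column collapses several reference values into their
mean); intensities are continuous, so ties have measure zero in practice.
Normalizing an already-normalized group is the identity to within
$10^{-12}$. Whether normalization should see all probes or only the
studied subset is unstated in the source; the default is all probes in
the supplied matrix.

## Summaries and conventions

* **Positional profile** — per position: pair count, mean, median, MAD,
  IQR of the estimates. MAD is the *raw* median absolute deviation
  (no 1.4826 consistency constant): the constant is a scalar factor that
  cancels in the spread regression's $R^2$ and the source names only
  "MAD". Quartiles use linear interpolation of order statistics (R's
  type 7), declared here because the convention is otherwise invisible.
* **Spread regression** — OLS of per-position MAD on per-position median;
  $R^2$ is the squared Pearson correlation, defined as 0 when either
  vector is constant.
* **Position groups** — 5' end = positions 1–8, center = 9–17, 3' end =
  18–25. Position 1 is the 5'-most base of the written probe sequence;
  the 3' end is the surface-attached end, a labeling fact with no
  computational role.
* **Type × group table** — per-type group means and pair frequencies, and
  per-type two-sided two-sample Student's t-tests (pooled variance;
  Welch behind a flag) for the three group contrasts. No multiple-testing
  correction is applied anywhere, matching the raw-p reporting
  convention of the analysis this package operationalizes. Undersized
  cells (< 2 estimates) yield `NA` p-values and are logged rather than
  silently dropped.
* **Percent contrasts** — two conventions coexist and are both exposed:
  the ratio-scale change $100(1 - 2^{\Delta})$ of the geometric-mean
  PM/MM ratio, and the "percent higher on the log2 scale"
  $100(\mu_1/\mu_0 - 1)$. They answer different questions and are easily
  conflated; `contrast_percent()` forces the caller to pick.
* **Control comparison** — per position, a pooled t-test of mismatch-pair
  estimates against the cross-design signal differences of identical
  probes. Its type-I error under the null is verified by Monte-Carlo
  calibration (1,000 replications) in the acceptance suite.

## Cross-study machinery

Different studies summarize mismatch-type effects in different notations
and directions. The package fixes the following conventions:

* **PM→MM notation**: `C-A` = C on the PM probe, A on the MM probe.
  **Duplex notation**: (probe base, target base) = (MM base,
  complement of the PM base), with U replacing T for RNA targets. The two
  conversions are mutually inverse and round-trip over all 12 types.
* **Directions**: a *discrimination* measure (log2(PM/MM)) grows when the
  duplex destabilizes; a *stability* measure grows when it stabilizes.
  `rank_types()` ranks ascending in the requested direction (rank 1 =
  smallest value; flipped when input and output directions differ).
  Printed stability lists, however, conventionally put the **most stable
  type at position 1**; `stability_positions()` produces exactly that
  orientation, and `flag_wc_outliers()` consumes it. Keeping the two
  functions distinct resolves a genuine ambiguity — "rank in the
  stability direction" and "position on the stability list" are opposite
  orders — without overloading one function with both meanings.
* **Correlation** — vectors are harmonized to the stability direction,
  then all pairwise Spearman (on ranks) and Pearson coefficients are
  computed with two-sided p-values at $N = 12$. Spearman p uses the
  t-approximation by default — consistent with `Prob > |r|`-style
  reporting — with an exact permutation option for untied ranks. Whether
  Pearson should see raw values or ranks-as-values is unstated in
  cross-study tables of this kind, so both are reported, labeled
  `pearson_*` and `pearson_rank_*`.
* **Watson–Crick outliers** — on a complete stability list, the six
  A·T-pair-disrupting types are expected at positions 1–6 and the six
  C·G-pair types at 7–12; any type outside its block is flagged. By
  pigeonhole the two flag counts are always equal.

Other studies' 12-type vectors are user-supplied TSV inputs. The two
vectors bundled under `inst/extdata/` are **synthetic examples**
(`study_vector_synthetic_*.tsv`), not data from any published study.

## The synthetic generator

The generator is the package's test bed: it emulates the structure of the
motivating experiment — two designs over shared consensus sequences, five
tissue sources × two replicates per platform, substitutions spread over
all 25 positions and 12 types, an identical-control fraction, and
two-substitution fodder for the exclusion filter — with full knowledge of
the truth.

Defaults, with units and rationale:

| parameter | default | meaning |
|---|---|---|
| `delta` surface | see below | penalty, log2 units |
| `tissue_effects` | 0, 0.6, −0.4, 1.1, −0.8 | per-tissue log2 abundance offsets, a realistic cross-tissue spread |
| `probe_affinity_sd` | 1.0 | SD of per-probe baseline log2 affinity; probe-to-probe brightness on real arrays varies by orders of magnitude |
| `noise_sd` | 0.3 | per-measurement log2 noise; the source reports no noise magnitude, so this is a free choice at the scale of well-replicated arrays, and recovery checks are phrased within standard errors rather than as fixed tolerances |
| `control_fraction` | 0.6 | identical-probe copies; mirrors the roughly 70/30 split of identical to single-mismatch probes in the motivating data, leaving room for fodder |
| `multi_mismatch_fraction` | 0.1 | probes given exactly two substitutions — enough to exercise the exclusion filter |
| `baseline_log2` | 8 | mean baseline log2 intensity |

The default penalty surface factorizes as
$\delta(i, m) = e_m \, w(i)$: twelve type effects $e_m$ (0.70–1.25 log2
units) separating the pair classes — C·G-pair disruptions (strongest:
`C-A`, `G-A`, `C-G`) above A·T-pair ones (weakest: `A-C`, `A-G`, `A-T`) —
and a unimodal positional weight $w$ peaking at position 12, steady
through the center, falling off toward both ends with the 3' side
slightly steeper. $w$ is a two-sided power curve plus a small Gaussian
bump (amplitude 0.08, sd 1.5 positions) at the peak; its four constants
were solved once so that, in expectation, the surface reproduces the
reported shape of the effect: a 24%/29% decrease of the PM/MM ratio from
position 12 to positions 1/25 and a 13%/17% excess of the center group
over the 5'/3' groups. The bump exists because a pure power curve
matching those group contrasts is numerically flat across positions
9–16, which would make "the peak position" meaningless; a distinct
single-position peak is the behavior being emulated.

Substitution mechanics guarantee exact ground truth: the drawn (position,
type) is planted by first setting the consensus base at that offset to
the type's PM base, then copying the window into both designs and
substituting the MM base in the query copy. Probes are tiled
left-to-right with random non-negative gaps, so windows never overlap
and probe order follows consensus coordinates. Generation is fully
seeded; identical truth objects give byte-identical designs and
intensities. Linear intensities are floored at $2^{-10}$ so logs stay
finite.

What the generator does **not** emulate — and what passing tests
therefore do not show about real arrays: sequence-composition-dependent
affinity (GC content, nearest-neighbor stacking), optical background,
cross-hybridization, probe saturation, and any dependence of noise on
intensity. The generator validates the *pipeline*, not the biophysics.

## Problem sizes and numerical guards

The test and acceptance suites run at sizes chosen to make the
statistical checks sharp while staying desk-scale: the parameter-recovery
run uses ~500 pairs per position (≈12,500 pairs among ≈42,000 probes,
5 tissues × 2 replicates, `noise_sd` 0.3), the aligner oracle 1,000
planted instances, the estimator identity 1,000 random balanced
instances, and the type-I calibration 1,000 null replications. At these
sizes the positional mean has standard error ≈0.009 log2 units per
position, comfortably below the designed peak margin.

Degenerate inputs are handled explicitly rather than by convention:
empty probe tables parse to empty tibbles; positions with no pairs carry
`n = 0` and `NA` summaries; a constant response gives a defined
zero-$R^2$ spread fit; undersized t-test cells are skipped and logged;
and validation errors name the offending probe, array or probeset.

## Known limitations

* The estimator assumes the complete balanced design; unbalanced layouts
  are rejected rather than approximated.
* Probes are compared in the orientation given in the probe table; no
  reverse-complement search is attempted by default (the generator is
  sense-consistent by construction).
* Ambiguity codes (N, IUPAC) in probe sequences are rejected at parse
  time, not tolerated.
* The cross-study correlations are only as meaningful as the supplied
  vectors; with $N = 12$ the t-approximate Spearman p-values are coarse,
  which is why an exact option exists.
* With only two replicates per group, quantile normalization within
  replicate pairs removes distributional differences between replicates
  but cannot correct platform-level effects; the control-probe comparison
  exists precisely to bound what remains.
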