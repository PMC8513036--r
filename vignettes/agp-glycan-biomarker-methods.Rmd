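---
title: "Methods: AGP N-glycan isomer biomarker analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AGP N-glycan isomer biomarker analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agpglyco)
```

This vignette documents the models, conventions, and design choices behind
`agpglyco`. The package analyzes N-glycan isomer profiles of serum
alpha-1-acid glycoprotein (AGP) measured by negative-mode HILIC-MS/MS of
anthranilic-acid (AA) labeled glycans, and classifies samples
(melanoma vs control) from the resulting feature matrix.

## Mass model

Compositions are written in the `N`/`H`/`S`/`F` shorthand (HexNAc, hexose,
NeuAc, deoxyhexose/fucose; `G` for galactose is accepted on input and counted
as a hexose). Neutral masses are residue sums:

$$ M = \sum_r n_r m_r + m_{H_2O} + m_{AA}, $$

with monoisotopic residue masses HexNAc 203.079373, Hex 162.052824, NeuAc
291.095417, dHex 146.057909 Da, water 18.010565 Da, and the AA label
increment $m_{AA} = 121.052764$ Da — the net change of reductive amination
with anthranilic acid (+C7H7NO2 − H2O + H2), verified against the labeled
Y-ion series (Y1 at m/z 487.19 with core fucose, 341.14 without). Negative-mode
ions are deprotonated species,

$$ m/z = \frac{M - z\,m_{p} - n_{CO_2} m_{CO_2}}{z}, $$

using the proton mass 1.007276 Da. We note a subtlety for anyone comparing
with 2-decimal instrument-software output: the proton and hydrogen-atom
conventions differ by the electron mass (0.00055 Da), and a handful of ions
(e.g. the unfucosylated Y1 at 341.1354) sit close enough to a rounding
boundary that the two conventions round to different second decimals. We
freeze the proton convention and compare printed values at their stated
precision (±0.01) rather than after re-rounding. Printed-value comparison
uses round-half-away-from-zero (`round_half_up()`), matching how instrument
software formats m/z.

## Fragment enumeration and diagnostic ions

Glycan topologies are rooted residue trees (`build_topology()`): chitobiose
core, trimannosyl branch point, 2–4 antennae of GlcNAc–Gal optionally capped
with sialic acid carrying an α-2,3/α-2,6 linkage tag, fucose on the
reducing-end GlcNAc (core) or an antenna GlcNAc, and optional
N-acetyllactosamine extensions. Tri-/tetraantennary templates place extra
antennae on the two branch mannoses; the true attachment in branched AGP
glycans is not chromatographically resolved, so these are documented
canonical assumptions.

`enumerate_fragments()` produces Domon–Costello B/C (non-reducing side) and
Y/Z (reducing side, retaining label and water) ions for all glycosidic
cleavage combinations up to `max_cleavages` (capped at 3, the deepest label
observed in practice being triple cuts such as Y4/Y5/Y5). Multi-cleavage cut
sets are antichains — a cut inside an already removed branch changes nothing
and is not emitted twice. Subscripts count non-fucose residues from the
reducing end along the cleaved branch. Cross-ring enumeration is deliberately
restricted to the two linkage diagnostics actually used:

* ⁰·⁴A₂−CO₂ (NeuAc + C2H4O2 remnant, deprotonated, −CO₂) at m/z 306.12 →
  α-2,6 evidence;
* B₂−CO₂ (NeuAc + Hex, deprotonated, −CO₂) at m/z 408.15 → α-2,3 evidence.

Exhaustive A/X-ion enumeration is out of scope.

**Fucose position rules.** `assign_isomer_features()` returns evidence flags
with supporting ions, never hard verdicts, because real spectra often carry
partial evidence (a low-intensity isomer may show only Y1/Y2). Core fucose
requires the fucose-retaining Y1 (m/z 487.19); the fucosylated Y2 raises
confidence from "medium" to "high". Antenna fucose requires the fucose-free
Y1 *and* Y2 together with at least one larger fucose-free Y ion — antenna
fucose is bound weakly and is preferentially lost during fragmentation —
*and* the absence of core-fucose evidence. The last clause matters: during
implementation we found that a core-fucosylated precursor also produces
fucose-free Y ions by double cleavage (e.g. Y1/Y3 at 1233.45), identical in
mass to the antenna diagnostic series, so without the precedence rule every
core-fucosylated spectrum would also be called antenna-fucosylated.

Peak matching (`match_spectrum()`) uses a ±10 ppm default tolerance, an
order-of-magnitude figure consistent with a 17,500-FWHM orbital-trap
instrument; it is a config knob, and the match set is monotone in it. An
optional absolute intensity threshold (`min_intensity`, default 0) is
provided but has no anchored default — whether the original analysis
thresholded diagnostic ions is not recorded.

## Quantification

Relative peak areas close each sample to 100 %
(`isomer % = 100·area/Σarea`), removing injected-amount and response
differences; glycan sums add the isomers of one composition (partitioning
the 100 %), and isomer ratios divide two isomer percentages of the same
glycan — identical to raw-area ratios since the per-sample total cancels.
Zero-area isomers stay as 0 % features; a zero denominator in a ratio is
floored at half the smallest nonzero percentage in the matrix and flagged
(`ratio_floored` attribute), a policy choice the source data leaves open.
RSDs are per class, with the sample (n−1) standard deviation.

Closure makes features compositional: one isomer rising forces all others
down slightly, inducing negative correlation among features. The synthetic
generator reproduces this (raw areas are generated without closure and
normalized by the pipeline), so the downstream statistics are exercised
under realistic dependence.

## Discriminant analysis

Fisher's index for one feature is the between- over within-group variance
ratio in its two-class ANOVA form, with (G−1) and (n−G) denominators. The
convention matters for absolute F values and is documented here because the
published per-feature indices cannot be recomputed without the raw cohort;
zero within-group variance with distinct means yields an `Inf` sentinel.
Feature selection takes the top k by F (ties broken lexicographically, so
selection is deterministic) and enforces the small-sample rule that the
number of variables stays below one third of the cohort size — for 37
samples, at most 12. The rule governs panel selection against the full
cohort; the discriminant fit itself (which in cross-validation sees only 25
training samples for the same 10 features) only requires a well-posed
pooled covariance (p ≤ n − 3).

The discriminant solves $S_w w = \mu_{mel} - \mu_{ctrl}$ with $S_w$ the
pooled within-class covariance, shrinkage-regularized as
$(1-\lambda)S_w + \lambda\,\mathrm{diag}(S_w)$ with default
$\lambda = 10^{-3}$: 25 training samples by 10 features is routinely
ill-conditioned, and the diagonal target preserves scale equivariance
(rescaling a feature never changes predicted labels). The threshold is the
midpoint of the projected class means — equal priors, reasonable for an
18/19 design; samples projecting exactly onto the threshold are called
melanoma (documented tie rule; melanoma is the positive class everywhere).
The weight direction is verified in the tests against a brute-force
maximizer of the Fisher ratio $J(w)$ on two-feature instances and against an
independent LDA implementation.

Cross-validation follows the leave-one-third-out scheme: 25 randomly drawn
training samples, the remaining 12 predicted, repeated 10 times, pooling
120 predictions. Draws are uniform without replacement and unstratified by
default (a stratified option exists); a draw missing a class is redrawn, with
a bounded retry count and a message. Feature selection is by default done
once on the full cohort — replicating the original workflow, whose panel was
fixed before cross-validation — while `nested = TRUE` re-selects inside each
training fold. The nested estimate is the honest generalization estimate
(selection on the full data leaks the held-out labels into the panel); the
default exists for fidelity, the flag for correctness. Repetitions draw
independently; overlap between test sets across repetitions is allowed, so
the pooled counts are not 120 independent Bernoulli trials.

Confusion metrics (sensitivity, specificity, PPV, NPV, accuracy) are
recomputed exactly from counts, in percent, rounded half-away-from-zero to
one decimal; undefined ratios (zero denominator) are reported `NA`, never 0.
When checked against the published comparator table, two printed cells are
internally inconsistent with their own printed counts (a cross-validation
sensitivity of 94.6 vs 52/55 = 94.5, and a classification PPV of 94.7 vs
15/16 = 93.8); the package reports the count-derived values and takes no
position on which figure was intended.

For a two-dimensional display of an intrinsically one-dimensional two-class
discriminant, `autoplot()` adds a jitter axis labeled non-inferential; it
has zero effect on classification.

## Synthetic cohorts: what they emulate and what they do not

`default_catalog()` ships 102 sialylated complex-type isomers (mono- to
tetrasialylated, 0–3 fucoses, N-acetyllactosamine variants) with the
structurally anchored multiplicities (five isomers of N4H5SF, three of
N4H5S2, two of N4H5S2F) and retention times in sialylation-ordered clusters
(43.49–47.15, 61.36–75.31, 83.46–112.60 min). Baseline abundances are
*synthetic placeholders* — plausible, bi/triantennary-dominated, summing to
100 % — because true per-isomer abundances are not published; the catalog is
also shipped as `inst/extdata/synthetic_isomer_catalog.csv` for review.

`generate_cohort()` draws per-sample isomer abundances around class-adjusted
means: melanoma means are baselines times the effect map, after ratio shifts
move a stated fraction of a donor isomer's mean to a later-eluting acceptor
of the same glycan (emulating increased α-2,6 linkage). Noise is lognormal
by default (positive, right-skewed; gamma available for robustness checks)
at 30 % within-class RSD — the tens-of-percent inter-individual scale — and
each sample gets a global lognormal scale factor (sd 0.3) for
injection/response variability, so closure is genuinely recovered by
normalization rather than built in.

The within-class log-variance is split: a fraction `glycan_cor = 0.7` is a
per-sample factor shared by all isomers of one glycan, the rest is
per-isomer residual (total per-isomer RSD stays at the catalog value). This
dependence structure is essential, not cosmetic: isomers of one glycan
respond to shared glycan-level regulation, the shared factor cancels in
isomer ratios, and that cancellation is precisely what makes isomer-ratio
features competitive biomarkers. With fully independent isomers, a ratio of
two 30 %-RSD quantities is so noisy that no ratio feature could ever enter a
top-10 panel — contradicting the observation that ratios carry much of the
discriminative signal.

Default planted effects follow the observed directions: N5H6S2 down
(isomer 4 strongest at 0.50, isomer 5 at 0.67), N6H7S2F up (isomer 3 at
1.9, isomers 1–2 mildly at 1.15), and donor→acceptor shifts for the five
tracked ratio pairs (fraction 0.25; 0.15 for the weakest, N5H6S3F 1→2).
Magnitudes sit in the 1.5–2× band and are configuration, not claims about
the clinical cohort. `planted_features()` lists the ten feature descriptors
these defaults make informative, mirroring the shape of the published panel.

**What passing tests show — and don't.** On these synthetic cohorts the
pipeline recovers ≥ 8 of the 10 planted features at k = 10 and nested
cross-validation exceeds 90 % accuracy. That validates the generator +
pipeline pair: selection finds planted signal at realistic noise, and the
classifier generalizes when real structure exists. It does not validate the
clinical effect sizes, the true abundance baselines, instrument artifacts
(in-source decay, spray instability), retention-time drift, or batch
effects — none of which the generator attempts to model.

## Numerical and interface conventions

* Problem sizes in the tests are kept modest by design: property suites use
  tens of random instances, moment checks a few hundred samples — the
  regimes where the asserted tolerances are comfortably non-marginal.
* Determinism: every stochastic function takes a seed; equal seeds give
  byte-identical cohorts, spectra, and cross-validation reports.
* CSV exchange is UTF-8, comma-separated, `.` decimal, mandatory header;
  feature columns are named `<composition>|iso<k>`, `<composition>|sum`,
  `<composition>|r<i>:<j>`. MGF blocks use `TITLE`, `PEPMASS`, and negative
  `CHARGE` (e.g. `1-`); reading validates with line numbers.
* `run_pipeline()` chains quantify → select → fit/classify → ablate →
  crossval, writes a report bundle plus a JSON manifest (seed, package
  version, config hash), and fails fast with the stage name on error. The
  command-line-equivalent surface is these exported functions; the package
  is meant to be driven from R scripts.

## Known limitations

* No raw-file processing: peak detection, XIC extraction, and RT alignment
  happen upstream; the package starts at the peak-area table.
* De novo topology inference is out of scope — topologies are built from
  templates, and branched-glycan templates are canonical assumptions.
* Two-class linear discriminants only; no multi-class, quadratic, ROC
  optimization, or probability calibration.
* The evidence rules read presence/absence of diagnostic ions; relative
  intensity modeling (e.g. distinguishing mixed core+antenna fucosylation
  on multiply fucosylated glycans) is not attempted, and on such glycans
  the core-fucose precedence rule makes simultaneous antenna detection
  conservative by design.
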