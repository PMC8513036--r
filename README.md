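# agpglyco

Serum alpha-1-acid glycoprotein (AGP, orosomucoid) carries five N-glycosylation
sites whose complex-type glycans are remodeled in malignancy: fucosylated
species rise, their nonfucosylated counterparts fall, and the balance of
sialic-acid linkage isomers (α-2,3 vs α-2,6) shifts toward α-2,6. `agpglyco`
implements the analysis that turns AGP glycan-isomer profiles, measured by
negative-mode HILIC-MS/MS of anthranilic-acid (AA) labeled N-glycans, into a
melanoma/control classifier — for analytical chemists and biostatisticians
working on glycan biomarkers.

The package covers the whole chain:

* **Mass engine** — a composition grammar (`N4H5S2F` = 4 HexNAc, 5 Hex,
  2 NeuAc, 1 Fuc) with monoisotopic residue-sum masses and negative-mode m/z
  arithmetic, `m/z = (M − z·m_p − n·m_CO2)/z`.
* **Fragment annotation** — Domon–Costello B/C/Y/Z enumeration over a glycan
  topology tree, the two sialic-linkage diagnostics (⁰·⁴A₂−CO₂ at m/z 306.12
  for α-2,6; B₂−CO₂ at m/z 408.15 for α-2,3), and evidence rules for core vs
  antenna fucose from the fucose-retaining or fucose-free Y series.
* **Quantification** — relative peak areas (closure to 100 % per sample),
  per-glycan sums, and isomer ratios of the same glycan.
* **Discriminant pipeline** — Fisher's index
  `F = [Σ n_g(μ_g − μ)²/(G−1)] / [Σ(x − μ_g)²/(n−G)]` for univariate feature
  ranking under the one-third rule (fewer than n/3 variables), a two-class
  linear discriminant solving `S_w w = μ_mel − μ_ctrl` with shrinkage
  `(1−λ)S_w + λ·diag(S_w)`, per-feature ablation, and repeated
  leave-one-third-out cross-validation (25 training / 12 held-out samples,
  10 repetitions → 120 pooled predictions on a 37-sample cohort) reported as
  sensitivity / specificity / PPV / NPV / accuracy with melanoma as the
  positive class.
* **Synthetic cohorts** — a generator that emulates the study layout
  (18 melanoma / 19 control over a 102-isomer catalog) with planted effects,
  isomer-ratio shifts, lognormal or gamma noise, and per-sample scale factors,
  so every stage is testable without clinical data.

## Worked example

```r
library(agpglyco)

coh <- generate_cohort(seed = 1)                      # 37-sample synthetic cohort
run <- run_pipeline(coh$peak_table, default_config(seed = 1L))

head(run$scores, 5)
#>   feature      fisher_f  rank
#> 1 N6H7S2|r3:5     127.      1
#> 2 N6H7S2|r4:5     114.      2
#> 3 N6H7S2F|r2:3     99.4     3
#> 4 N6H7S2|iso5      45.7     4
#> 5 N6H7S2F|iso3     36.4     5

run$cv$report
#>      tp    fn    tn    fp sensitivity specificity   ppv   npv accuracy
#> 1    60     0    59     1         100        98.3  98.4   100     99.2
```

The Fisher table ranks the features (isomer percentages such as
`N6H7S2F|iso3`, glycan sums such as `N5H6S2|sum`, and isomer ratios such as
`N6H7S2|r3:5` = isomer 3 % / isomer 5 %) by between- over within-group
variance; the top 10 form the discriminant panel. The cross-validation row
pools the 120 held-out predictions: here 60 of 60 melanoma and 59 of 60
control calls were correct (99.2 % accuracy on this synthetic cohort, where
the planted group differences are by construction recoverable).
`autoplot(run$model, run$features)` draws the projected discriminant scores,
`plot_group_summary(run$group_summary)` the melanoma/control fold changes.

Single spectra can be interrogated directly:

```r
topo <- build_topology(2, sialylation = "a23", core_fucose = TRUE)  # N4H5SF
enumerate_fragments(topo, types = "Y")  # Y1 487.19, Y2 690.27, Y4/Y4 1176.43 ...
assign_isomer_features(read_mgf("spectra.mgf")[[1]], "N4H5SF")
```

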