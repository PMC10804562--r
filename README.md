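# lmdhet

Multi-region laser-microdissection (LMD) proteomic intratumor
heterogeneity analysis.

Tumors are mixtures. Bulk proteomics averages tumor epithelium, stroma,
and immune infiltrate, so both differential signals and apparent
"heterogeneity" can be artifacts of shifting cell-type composition. LMD
studies address this by harvesting, from the same specimen, enriched
tumor epithelium (**ET**), enriched tumor-involved stroma (**ES**), and
bulk tissue (**BT**) — and by sectioning the frozen block at several
spatially distinct sampling levels, so that variability *across space
within one compartment* becomes measurable. `lmdhet` implements the
quantitative workflow for such TMT multi-plex designs, for proteomics
analysts and method developers who want every stage testable against
planted ground truth:

* **Simulation** — a PSM-level cohort generator (`simulate_cohort()`)
  emulating 9 patient-specific TMTpro 16-plexes × 5 levels × {ET, ES,
  BT}, with planted log2 fold changes, linear-scale BT tumor/stroma
  mixing `I_BT = f·2^ET + (1−f)·2^ES`, random-walk spatial drift
  (inflated for secreted proteins), reporter noise, nuisance q-values /
  isolation interference, and per-plex dropout — plus the ground truth
  for all of it.
* **Quantitation** (`quantify_cohort()`) — strict PSM filtering
  (q < 0.01, interference < 50%, reference signal required), log2
  ratio-to-reference, median roll-up with a ≥ 2 PSM per-plex rule,
  column-median normalization, plex merging, and deterministic k-NN
  imputation of proteins observed in ≥ 50% of samples.
* **Heterogeneity** — raw-MAD feature selection, `1 − r` average-linkage
  clustering of samples and proteins (newick export), all-protein
  pairwise Spearman correlations between sampling levels, per-patient
  ET-vs-ES dendrograms with Mann–Whitney heterogeneity tests, and a
  secreted-protein spatial variance test.
* **Differential analysis** — empirical-Bayes moderated t-statistics

  t_g = logFC_g / (s̃_g · c),  s̃²_g = (d₀s₀² + d_g s²_g) / (d₀ + d_g),

  with patient as a blocking covariate, (d₀, s₀²) by moment matching on
  log s², BH adjustment, per-patient median logFCs, and an all-patient
  sign-concordance filter for reporting robust alterations.
* **Admixture** — ssGSEA scoring (rank-weight exponent α = 0.25) of
  tumor/stroma signatures and recovery of the planted BT mixing
  fractions.
* **Comparison** — concordant-alteration overlap between datasets
  (shared / discordant / unique partitions), logFC correlations, RPPA
  preprocessing (`exp(−10)` detection floor, target-wise median
  centering), cross-platform per-sample/per-feature Spearman tables, and
  purity association.

Everything is tibble-in / tibble-out and pipe-friendly; fitted objects
have `tidy()` / `glance()` methods and results have `autoplot()` /
`plot_*()` views. See `vignette("lmdhet-methods")` for the generative
model, the statistics, and the design decisions.

## Worked example

```r
library(lmdhet)

co  <- simulate_cohort(sim_config(seed = 1))
co
#> <lmd_cohort> 9 plexes, 111 samples, 2000 proteins, 64527 PSMs

q <- quantify_cohort(co$psms, co$design, co$annotation)
q$exclusions
#>                q_value isolation_interference    no_reference_signal
#>                   3284                   3066                   1149
#>        no_other_signal               retained
#>                      0                  57028

fit <- moderated_ttest(q$matrix, co$annotation)
fit
#> <lmd_diff> 1929 proteins, 66 samples; prior df = 12, prior var = 0.0652; 374 at BH < 0.05

alt <- concordance_filter(fit, per_patient_logfc(q$matrix, co$annotation))
head(alt, 3)
#> # A tibble: 3 x 4
#>   protein   direction logfc    adj_p
#>   <chr>         <dbl> <dbl>    <dbl>
#> 1 PROT00008         1  1.90 2.46e-40
#> 2 PROT00011         1  1.39 1.16e-31
#> 3 PROT00015         1  1.71 1.65e-40

de <- co$truth$proteins$protein[co$truth$proteins$de]
c(sensitivity = mean(de %in% alt$protein),
  fdp = mean(!alt$protein %in% de))
#> sensitivity         fdp
#>       0.930       0.041

sc  <- ssgsea_score(q$matrix, truth_signatures(co$truth, 50))
rec <- purity_recovery(sc, co$truth, "Stroma")
rec$rho
#> [1] 0.961
```

Reading the numbers: 111 LMD samples across 9 plexes are quantified into
a complete 1929-protein matrix (proteins observed in < 50% of samples
are dropped; 88% of PSMs survive filtering). The moderated t +
concordance filter recovers 93% of the planted alterations with a
realized false-discovery proportion of 4%, and the ssGSEA stroma score
tracks the true BT stroma fraction at Spearman ρ = 0.96 over 45 bulk
samples.

The same flow runs end to end from the shell, writing TSV/newick/GMT
outputs and an MD5-hashed `manifest.json`:

```sh
exec/lmdhet run --outdir out --seed 1
```

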