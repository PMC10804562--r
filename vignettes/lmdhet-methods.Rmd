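---
title: "Models and methods behind lmdhet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lmdhet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmdhet)
```

# The problem

Bulk tumor proteomics averages over a mixed cell population: tumor
epithelium, stroma, immune infiltrate. Laser microdissection (LMD) lets a
study harvest enriched tumor epithelium (ET), enriched tumor-involved
stroma (ES), and ordinary bulk tissue (BT) from the *same* specimen, and
— by sectioning the frozen block at several spatially distinct sampling
levels — ask how much the proteome varies across space within each
compartment. `lmdhet` implements the full quantitative workflow for such
a design on isobaric-label (TMT) data: PSM-level quantitation, spatial
heterogeneity statistics, compartment-differential analysis with a strict
cross-patient concordance requirement, single-sample enrichment (ssGSEA)
admixture scoring, and cross-dataset comparison — together with a
synthetic-cohort generator that plants known ground truth so every stage
can be tested end to end without any external download.

# The generative model

`sim_config()` defaults describe the emulated study: 9 patients, each one
TMTpro 16-plex; 5 sampling levels per specimen; BT collected at all 5
levels, ET at 4–5, ES at 2–5 (collection is not always complete in
practice — low-yield stroma levels drop out); 2,000 proteins.

Per protein $g$ the model draws a global baseline
$\mu_g \sim N(0, 1)$ (log2 scale) plus a per-patient shift
$N(0, 0.3)$ — tumors differ. A fraction (10% by default) of proteins is
differential between compartments: the ES baseline is shifted by a signed
log2 fold change whose magnitude is $N(1.5, 0.3^2)$ truncated below at
0.2, so every planted effect has a stable sign. The mean of 1.5 log2
units reflects the strong epithelial/stromal contrasts that
marker proteins (keratins, collagens) show in enriched compartments.

**Spatial drift.** Within a (patient, compartment) pair the level
profiles follow a Gaussian random walk with step SD 0.15 log2 units:
contiguous levels of one tissue block are more alike than distant ones.
An i.i.d. option (`drift_model = "iid"`) is available. Proteins flagged
as secreted / extracellular (20% of the panel) take drift steps twice as
large (`secreted_var_inflation = 2`), planting the excess spatial
variability of signal-peptide proteins that the secreted-variance test is
designed to detect.

**Bulk tissue is a physical mixture.** BT at level $\ell$ mixes the two
compartments on the *linear* intensity scale,

$$I_{BT}(\ell) = f_\ell \, 2^{x_{ET}(\ell)} + (1 - f_\ell) \, 2^{x_{ES}(\ell)},$$

with $f_\ell$ the level's tumor-cell fraction, drawn uniformly from
0.15–0.99 per level. Reporter intensities are ion counts, and cell
populations add in counts, not in log space; the mixture identity is an
exact invariant of the generator and the anchor for all purity-recovery
tests.

**Measurement layer.** Each protein receives Poisson(4) PSMs per plex
(or a constant count, used when a test needs complete coverage); each PSM
has a log-normal ionization factor shared across channels (it cancels in
ratios) and per-channel multiplicative noise $2^{N(0, 0.3)}$. The pooled
reference in channel 126 is the *mean* linear intensity over the
patient's samples — pooling equal peptide masses approximates averaging.
Nuisance q-values and isolation-interference values are drawn
independently of abundance (a simplification: in real data co-isolation
correlates with local spectral density), with 5% of PSMs failing each
filter so the filters are exercised. Whole proteins drop out of a plex
with probability 0.1, creating the between-plex missingness that drives
imputation.

What the simulator does **not** model: peptide sequence realism,
spectrum-level physics, isotope-impurity (reagent-lot) effects — the
emitted intensities are treated as already impurity-corrected — and
immune admixture (BT mixes exactly two compartments). Passing tests
therefore validate the statistical pipeline, not MS physics.

# Quantitation

The quantitation contract follows standard TMT practice:

1. **PSM filter** (`filter_psms()`): keep PSMs with q-value < 0.01 and
   isolation interference < 50% — both strict, so a PSM at exactly 50% is
   excluded — plus a present, positive reference-channel intensity and
   signal in at least one other channel. Multi-accession PSMs are
   rejected (or first-accession with `keep_first`); razor-peptide logic
   is out of scope.
2. **Ratios** (`psm_ratios()`): per PSM, log2(channel / reference).
3. **Roll-up** (`rollup_proteins()`): per plex, protein abundance in a
   sample is the median PSM ratio; proteins with fewer than 2 PSMs in a
   plex are dropped from that plex. The count is per plex, after
   filtering, because quantitation is per multiplex.
4. **Normalization** (`normalize_medians()`): subtract each sample
   column's observed-value median (idempotent).
5. **Merge** (`merge_plexes()`): union of proteins over plexes; a cell is
   missing when the protein was not quantified in the sample's plex.
6. **Imputation** (`impute_knn()`): proteins observed in fewer than 50%
   of samples are dropped (inclusive threshold; a "patients" denominator
   is available by flag — the per-sample reading is the stricter
   contract and the default). Each remaining missing cell takes the
   unweighted mean, in that sample, of the k = 10 nearest proteins by
   Euclidean distance over mutually observed samples, candidates
   restricted to proteins observed in the target sample, distance ties
   broken by protein id order so the result is deterministic. The
   implementation is verified against an exhaustive brute-force oracle.

With noise, dropout, and nuisance failures all disabled the pipeline is
an exact round trip: the final matrix equals the latent log2
ratio-to-pool profiles up to the column-median shift, to 1e-9.

# Heterogeneity statistics

All spread statistics use the **raw MAD**, `median(|x - median(x)|)`,
without the 1.4826 normal-consistency factor: the selection thresholds
(1 for proteome-wide clustering, 0.5 for smaller effect scales) are used
as raw cutoffs, and the secreted-variance comparison is scale-free.

*Clustering* (`hier_cluster()`): distance `1 - Pearson r`, average
linkage, the defaults of the correlation-clustering tools commonly used
for proteome heatmaps; both are configurable. Columns are processed in
label order, so the tree and its newick serialization are deterministic.
On the default simulation the 2-cluster cut separates every ET from
every ES sample, and BT samples join the ET-majority cluster when their
true tumor fraction is at least 0.8 and the ES-majority cluster below
0.3 — the qualitative behavior expected when bulk purity drives cluster
membership. For the cohort-level tree the package default cutoff is
MAD > 0.5 rather than 1: with a mean planted |log2FC| of 1.5 and a
pooled-reference design, a fully differential protein reaches an
across-sample raw MAD of only ~0.7, so MAD > 1 would select almost
nothing at the simulated effect scale. This is a property of the
generative model's scale, chosen from that model, not fitted to any test
outcome.

*Pairwise level correlations* (`pairwise_spearman()`): Spearman with
average-rank ties over **all** proteins (no MAD cutoff), within each
(patient, collection type); self-correlations are excluded from the
median/min/max summaries.

*Patient dendrograms* (`patient_dendrogram()`): for patients with at
least 3 levels in both ET and ES, proteins are selected at MAD > 1
**within that patient's ET+ES samples** (the within-patient reading
matches per-case selections of very different sizes; the alternative —
selecting on the global matrix — is a one-line change), a `1 - Spearman`
average-linkage tree is built, and the intra-ET pairwise correlations
are compared to the intra-ES ones by a two-sided Mann–Whitney U test:
all C(n,2) within-type level pairs enter each side. The compartment with
the higher median internal correlation is reported as the more
homogeneous.

*Secreted-variance test* (`secreted_variance_test()`): within each
(patient, compartment) scope of patients having 4–5 levels in both ET
and ES, each protein's between-level variability is its raw MAD across
levels (MAD rather than variance for robustness to one aberrant level;
configurable in principle), and flagged vs unflagged proteins are
compared by a two-sided Mann–Whitney U. Mann–Whitney is `wilcox.test`:
exact for small untied samples, normal approximation with tie correction
otherwise; the suite checks it against exhaustive enumeration for group
sizes up to 8. Under a null inflation of 1.0 the test holds its size
(rejection at alpha = 0.01 stays below 0.02 over 200 simulated
cohorts); under the default two-fold inflation it detects the effect in
over 95% of cohorts.

# Differential analysis

`moderated_ttest()` fits, per protein, a linear model of log2 abundance
on compartment with **patient as an additive blocking covariate** — the
design is paired within patients, and pooling across patients would let
inter-tumor variability swamp the compartment effect (pooling is
available with `block_patient = FALSE`). Residual variances are shrunk
by empirical Bayes: with $z_g = \log s_g^2$,

$$E[z] = \log s_0^2 + \psi(d_g/2) - \log(d_g/2) - \psi(d_0/2) + \log(d_0/2),
\qquad \mathrm{Var}[z] = \psi'(d_g/2) + \psi'(d_0/2),$$

the hyperparameters $(d_0, s_0^2)$ are obtained by moment matching with
a Newton inversion of the trigamma function, the posterior variance is
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, and the moderated
$t$ is referred to $d_0 + d_g$ degrees of freedom. P-values are BH
adjusted. The implementation is written from these formulas; the test
suite cross-checks it against the limma package to 1e-8 and verifies the
classical limit ($d_0 = 0$), the full-shrinkage limit
($d_0 = \infty$), the betweenness of the posterior variance, sign
symmetry, and the null type-I rate on 10,000 simulated null proteins.

Per-patient log fold changes (`per_patient_logfc()`) are differences of
medians over levels — robust to one aberrant level. The
**concordance filter** keeps proteins with BH-adjusted p < 0.05 *and* a
strict, nonzero, identical per-patient logFC sign in every patient; an
exact zero (possible only on synthetic data) counts as discordant. On
the default cohort this recovers the planted alteration set with
sensitivity above 0.9 at a realized false-discovery proportion below
0.05 (averaged over 10 simulation seeds).

# Admixture scoring

`ssgsea_score()` implements the single-sample enrichment statistic: per
sample, features are ranked by abundance (average ranks for ties; the
most abundant feature carries the largest rank), and the ranked list is
walked from the top accumulating a weighted in-set ECDF (weights
$r^\alpha$, $\alpha = 0.25$, normalized over the set) minus the
unweighted out-of-set ECDF; the score is the sum of running differences.
Scores are raw running sums by default — min–max normalization across
samples is behind a flag, since cross-sample normalization changes the
meaning of a *single-sample* statistic. Scores depend only on
within-sample ranks, hence are invariant under strictly monotone
transforms; the implementation is verified against an independent
brute-force oracle and a maximality property (the top-m features are the
highest-scoring m-subset).

For synthetic runs the Tumor and Stroma signatures are the top planted
ET-up / ES-up proteins (`truth_signatures()`); real signature sets are
supplied as GMT. No Immune signature is generated because the simulator
does not plant an immune compartment. On default simulations the Stroma
score recovers the planted BT stroma fraction with Spearman rho above
0.9 over the 45 BT samples, and Tumor/Stroma scores are anti-correlated
across the purity range.

# Cross-dataset and cross-platform comparison

`overlap_concordant()` partitions two alteration sets into shared
same-direction, shared discordant-direction, and unique proteins — the
discordant category is reported explicitly rather than silently dropped,
so the bookkeeping always sums to the union. `logfc_correlation()`
correlates logFCs over shared proteins (logFC rather than mean
abundance, since alteration tables are logFC tables; a flag restricts to
same-direction proteins). `rppa_preprocess()` floors values below
detection at `exp(-10)`, log2-transforms, and median-centers each
antibody target. `cross_platform_correlation()` computes per-sample or
per-feature Spearman correlations over co-measured features, expanding
many-to-one antibody maps to one row per (target, accession) pair.
`purity_association()` correlates altered-protein abundance — and the
mean ET-up signature — with per-sample tumor purity.

# Numerical and design choices

* Strict inequalities at both PSM thresholds, matching "< 1%" and
  ">= 50% excluded" phrasing of standard filter descriptions.
* Missing values are empty TSV cells, never sentinel numbers; TSV rather
  than CSV because protein and antibody ids contain commas in the wild.
* All randomness flows from one integer seed; emission uses `seed + 1`
  and the latent-matrix noise helper `seed + 2`, so stages are
  individually reproducible. Identical configurations give
  byte-identical outputs, asserted by MD5 manifests.
* Distance ties in k-NN imputation and leaf order in clustering are
  broken by id order for determinism.
* `trigamma` inversion uses Newton iteration with the asymptotic
  endpoints `1/x` (small x) and `1/sqrt(x)` (large x).
* Degenerate inputs error early and name the offending sample, protein,
  or signature (all-missing column, zero-variance sample, empty
  signature intersection, constant purity).

# Problem sizes used by the test suite

The suite exercises the defaults (9 x 2000) for the round-trip,
clustering, recovery, and admixture properties; calibration loops use
200 null and 100 alternative cohorts generated through the fast
latent-matrix path (`latent_protein_matrix()`, which skips PSM emission
but preserves the abundance model); the k-NN and ssGSEA oracles run on
matrices up to 30 x 16 and 10-feature toys where exhaustive enumeration
is feasible. These sizes were chosen so each property is measured at the
scale where its guarantee is exact or its simulation error is far below
the asserted margin.

# Known limitations

* Isotope-impurity (Quan) correction is not modeled; inputs are treated
  as already corrected.
* Shared peptides are rejected rather than apportioned; razor logic
  would change roll-up for paralog families.
* Nuisance q-values/interference are independent of abundance.
* The ssGSEA immune axis and any three-way admixture are untested
  against ground truth (only tumor/stroma mixing is planted).
* Real-data signature derivation (differential expression + SVM-RFE) is
  out of scope; signatures are inputs.
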