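---
title: "Pathway-partitioned polygenic scores for psychosis endophenotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-partitioned polygenic scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the pipeline does

Psychotic disorders (schizophrenia, schizoaffective disorder, bipolar
disorder with psychosis) share polygenic risk, yet diagnosis is a coarse
label: patients with the same diagnosis differ widely in symptoms,
functioning and cognition, and patients with different diagnoses can look
alike. `ppgs` implements an analysis strategy that partitions genome-wide
polygenic risk into biologically defined slices — pathway polygenic scores
(pPGS) for glutamatergic, GABAergic, dopaminergic and serotonergic
neurotransmission — and asks two questions:

1. Do pathway slices of risk explain specific *endophenotypes* (symptom
   composites, global/social/role functioning, mania, cognitive-control task
   performance and its fMRI correlates) over and above overall risk and
   diagnosis?
2. Do diagnosis-agnostic patient subgroups ("biotypes") obtained by
   clustering those endophenotypes carry genetic signal that diagnosis does
   not?

Because individual-level psychiatric genotype data cannot be redistributed,
every stage is exercised against a synthetic cohort generator with known
ground truth, which turns the whole pipeline into a parameter-recovery
instrument: planted heritability, pathway effect shares, population labels,
related pairs, QC defects and endophenotype clusters must all be recovered
by the downstream stages.

# Pipeline stages and their models

## Quality control (`run_qc`)

The filter chain mirrors standard array/imputation QC: variant missingness
(> 5% removed; boundaries are kept because removal criteria are phrased as
strict inequalities), case/control differential missingness (two-sided
Fisher exact test on the missing-by-status 2x2 table, removal at p < 0.001),
an exact Hardy–Weinberg test (removal at p < 1e-6), relatedness exclusion,
and imputation-quality filters (INFO < 0.7 or empirical INFO < 0.8 removed).
Sample missingness (> 1%) is flagged but not removed — the decision is the
analyst's. A sex-check appears in the report as an explicit no-op because
the simulated genome is autosomal.

The HWE test enumerates all heterozygote counts compatible with the observed
allele counts and sums the probabilities of tables no more likely than the
observed one (the classical exact formulation). The test suite sweeps every
genotype table with n <= 50 against an independently coded enumeration
oracle.

Two QC design points deserve justification:

* **Relatedness statistic.** Genome-wide *dosage correlation* between
  unrelated individuals is inflated by shared ancestry (and, uncentered, by
  the allele-frequency profile itself), so in a multi-ancestry cohort a
  fixed threshold of 0.2 would exclude many unrelated same-ancestry pairs.
  We therefore use twice the KING-robust kinship estimator,
  `2 (N_het,het - 2 N_opposite-hom) / (N_het_i + N_het_j)`, which is 1 for
  duplicate genomes, about 0.5 for first-degree relatives, and centered at 0
  for unrelated pairs *regardless of population structure*. The 0.2 default
  therefore means "closer than second degree". Dosage-only data fall back to
  mean-centered correlation.
* **HWE on the pooled cohort.** Testing Hardy–Weinberg on a pooled
  multi-ancestry sample legitimately rejects variants whose allele
  frequencies differ strongly across ancestries (the Wahlund effect). This
  is intended behavior — such variants are QC liabilities — but it means
  "zero planted defects" does not imply "zero removals" when drift is
  extreme; the property tests therefore check the zero-removal contract at
  low drift.

## Ancestry (`fit_reference_pca`, `project_samples`, `assign_superpopulation`, `residualize_scores`)

Reference-panel PCA uses GRM-standardized dosages (center `2p`, scale
`sqrt(2p(1-p))` with reference frequencies); study samples are projected
with the reference means/scales (missing dosages impute to the reference
mean, i.e. standardized zero) and assigned the nearest superpopulation
centroid in 20-dimensional PC space, ties broken lexicographically for
determinism. No projection-shrinkage correction is applied; at small
reference sizes projected study samples shrink toward the origin, a known
bias we accept because assignment only needs relative distances.

Two PC sources coexist deliberately: ancestry *assignment* uses the
reference-panel projection, while score *residualization* regresses each
polygenic score on the first 10 PCs computed within the study cohort itself
— stratification control should reflect the structure of the analyzed
sample. Residuals are exactly orthogonal to the PCs used (tested to 1e-10)
and residualization is idempotent.

## Scoring (`ld_clump`, `snps_in_genes`, `compute_score`, `pathway_score`)

Clumping is the standard greedy procedure: take the most significant
unclaimed variant as an index, claim everything within 250 kb at dosage
r^2 >= 0.7 (0.7 by default; 0.1/0.3/0.5/0.9 remain available, and a tested property is
that the sign of the case-status association is stable across them), repeat. P-value ties break by position then id, making the result
deterministic; a brute-force reference implementation backs it on random
instances. r^2 comes from the designated LD reference panel, with missing
reference dosages mean-imputed.

Scores are `sum(beta * effect-allele dosage)` with **no p-value filter** —
pathway restriction must not be confounded with significance filtering.
Missing study dosages impute to `2 * effect-allele frequency` from the
summary statistics. Effect alleles are reconciled against the genotype alt
allele (dosage complemented when the effect allele is the other allele);
strand-ambiguous A/T and C/G variants that cannot be reconciled are dropped
and counted. One property worth stating: the *location* of a raw PGS is
representation-dependent (re-expressing a variant on the other allele
shifts every score by `2*beta`), so invariance holds for centered scores,
and all downstream use is standardized or residualized.

Gene membership is left-closed/right-open (`start <= pos < end`, plus an
optional symmetric window, default 0: gene body only), matching the
annotation's half-open intervals.

## The competitive permuted null (`sample_null_gene_sets`, `competitive_p`)

A pathway score that associates with case status may do so only because any
set of that many genes would. The competitive test draws 10,000 null gene
sets of the same size, with each gene's inclusion probability proportional
to its length (longer genes host more SNPs), scores each over the same
clumped variants, residualizes identically, and computes the same
case-status statistic. The empirical p is `(1 + #{null >= observed}) /
(1 + N)`, never exactly zero. Sampling uses base R's sequential weighted
draw without replacement, which realizes "inclusion probability
proportional to length" draw by draw and is seed-deterministic.

The default association statistic is the point-biserial z of score versus
case status — asymptotically the score-only logistic Wald z, but computable
for all 10,001 sets in one matrix product (a sparse gene-to-SNP incidence
handles overlapping genes exactly). A per-set logistic fit is available
(`method = "logistic_z"`). Calibration is verified by the property that the
competitive p is uniform when the "tested" set is itself a length-weighted
draw.

## Association and multiple testing (`fit_association`, `galwey_meff`, `bh_fdr`)

Binary outcomes use maximum-likelihood logistic regression, continuous
outcomes least squares. The predictor is standardized to unit SD within the
analysis subset before fitting, so `exp(beta)` is the per-SD odds ratio;
CIs are Wald (deterministic, matching bracketed-interval reporting).
Nagelkerke's R^2 rescales Cox–Snell:
`R2 = (1 - exp((2/n)(ll0 - ll1))) / (1 - exp((2/n) ll0))`. Observations with
Cook's distance >= 1 are excluded and the model refit once (0.5 flags
only); both thresholds are arguments.

The covariate sets follow the analysis plan: sex, age, self-reported race
and ethnicity everywhere; diagnosis added within-case; scanner/protocol for
cognitive-control outcomes; the genome-wide score as a covariate in pPGS
endophenotype models so pathway slices are tested over and above overall
burden.

Correlated scores and correlated endophenotypes make a Bonferroni-style
count too harsh, so the number of effective tests follows Galwey:
`meff = (sum sqrt(lambda))^2 / sum(lambda)` over the eigenvalues (clipped at
zero) of the respective correlation matrices, computed pairwise-complete
within cases. The two meff values are rounded half-up *before* multiplying, so budgets
are integers (e.g. effective counts of 5 and 12 plus one standalone
treatment-response test give 5 x 12 + 1 = 61), and the raw values are also
reported. BH step-up runs at q = 0.10 against this
budget (`m_override`), not the list length.

## Clustering (`select_k`, `kmeans_missing`, `classify_response`, `compare_models`)

The battery is z-normalized within cases (sample SD), with
cognitive-control measures normalized within scanner stratum. Functioning
scales measured repeatedly are summarized as `(max + min) / 2` over the past
year, and the mania total omits item 8 ("Content"), which probes psychotic
rather than manic symptoms.

Cluster number is chosen on complete cases by a five-index ensemble —
average silhouette width, Calinski–Harabasz, Davies–Bouldin, the gap
statistic (first-SE-max rule), and Hartigan's rule (smallest k with
H(k) <= 10) — by majority vote, ties to the smaller k. Five canonical indices stand in for heavyweight 30-index selection tools;
the ensemble is pluggable and the vote trace is always returned. One degeneracy rule: the gap statistic is the only member
with a null reference distribution, so when it selects k = 1 ("no
structure") the ensemble reports the boundary of the candidate range
(k = 2 by default) rather than letting structure-free drift of
silhouette/Davies–Bouldin/Hartigan toward large k win the vote. When no k
satisfies Hartigan's criterion, that index votes the boundary for the same
reason.

K-means with missing data defines the case-to-centroid distance as the
squared Euclidean over observed variables rescaled by
`(total variables / observed variables)`, updates centroids from observed
entries only, and keeps the best of 50 seeded k-means++ starts by total
cost. On complete data this reduces *exactly* to standard k-means (tested
against `stats::kmeans`). Cases with at most 50% of variables observed are
excluded (the rule is strictly greater than 50%); the threshold is the `min_observed` argument because the
one-observed-variable nearest-centroid contract is also part of the
interface.

Treatment response subtracts the BPRS instrument minimum (24) from both
scores and calls a responder iff the decrease strictly exceeds 20% of the
rescaled baseline; rescaled baselines below 5 lack the resolution to
detect a 20% change and are excluded with a reason.

The cluster-versus-diagnosis comparison fits, per score, `score ~ cluster +
covariates`, `score ~ diagnosis + covariates`, and the combined model, with
BP and the low-pathology cluster as reference levels, and reports BIC,
adjusted R^2 and per-level Wald CIs. Cluster labels are permutation
-equivalent everywhere: recovery is always measured by adjusted Rand index.

# The synthetic cohort generator

`sim_config()` fixes the study conditions; `simulate_study()` realizes them.
Default conditions: a reference panel of 5 superpopulations x 60 genomes;
8,000 biallelic variants on one chromosome in 10-variant LD blocks;
Balding–Nichols drift Fst = 0.05 from shared ancestral frequencies; 400
non-overlapping genes (2–50 kb) carrying four 40-gene pathways with 10%
shared membership; liability heritability 0.5 with variance shares
glutamate 0.25, GABA 0.20, dopamine 0.10, serotonin 0.05 (pathway effects
planted as the strongest for glutamatergic/GABAergic risk); a cohort of 320
with case fraction 0.64 (liability-threshold ascertainment mirroring a
205-case / 115-control design, SZ:SA:BP sampled 118:39:48); a 12-measure
endophenotype battery with three planted archetypes; 7% MCAR endophenotype
missingness (reproducing a ~44% complete-case fraction); follow-up BPRS for
~31% of cases at a 35/63 responder base rate with response probability tied
to dopamine pathway load; QC defects at rates 2% (variant missingness), 1%
(heterozygote-free HWE violations), 1% of samples in near-duplicate related
pairs (2% of genotypes resampled), and 2% low-INFO variants, all on
disjoint variant sets.

Choices that were genuinely open, and why they were made:

* **LD copula calibration.** Genotypes come from thresholding two latent
  Gaussian haplotype fields with block equicorrelation. Thresholding
  attenuates correlation, so the latent correlation is inflated by the
  tetrachoric map `rho = sin(pi r / 2)`; the requested `within_block_r`
  then approximates the realized *genotype* correlation at mid frequencies.
  The default r = 0.9 makes clumping at r^2 = 0.7 genuinely active: blocks
  prune where neighbor frequencies are similar and survive where
  attenuation pulls realized r^2 below threshold.
* **Variant count.** 8,000 variants is the smallest scale at which the
  kinship statistic's null noise sits several standard deviations below the
  0.2 relatedness threshold under block LD, so a defect-free cohort passes
  QC untouched while the three planted duplicate pairs are found exactly.
* **Archetype separation.** "Separated by two within-cluster SDs" is
  encoded as an exact property of the default archetype matrix: its minimum
  pairwise centroid distance equals `2 * sqrt(12)`, the within-cluster SD
  of the full 12-measure battery under unit per-measure noise. Cluster 1 is
  the mania/disorganization/reality-distortion profile, cluster 2 the
  poverty-symptom/poor-functioning/worst-cognitive-control profile,
  cluster 3 low pathology; signs follow instrument semantics (higher is
  worse for symptoms, better for functioning and cognition).
* **Liability thresholding** uses the empirical mean/SD of the realized
  liability, so the case fraction tracks `1 - prevalence_threshold` with
  binomial noise even when population structure perturbs the genetic
  variance.
* **Heritability pinning.** True effects are drawn per pathway, scaled to
  the configured variance shares measured on the reference panel, then
  rescaled so the panel's realized genetic variance equals `h2_liability`
  exactly; reported betas add `N(0, se^2)` noise at an effective GWAS n of
  100,000 with p-values consistent with beta/SE.

What the generator does **not** emulate — and therefore what green tests do
not certify about real data: realistic human LD (haplotype blocks with
recombination-rate structure), imputation error correlated with INFO,
X-chromosome, genotyping batch effects, diagnosis-dependent ascertainment of
endophenotype missingness (missingness is MCAR), item-level construction of
the symptom composites (reality distortion, poverty symptoms and
disorganization enter as first-class measures because their composite
weights live in unpublished instrument derivations), rater noise, and
medication confounding of treatment response.

# Numerical conventions

* Boundary semantics everywhere follow "remove on strict inequality":
  missingness 5/100 at a 5% threshold is kept, INFO exactly 0.7 is kept,
  a BPRS decrease of exactly 20% is a non-responder.
* Competitive p-values use the add-one estimator and cannot be 0.
* meff eigenvalues are clipped at zero before the square roots.
* All k-means paths are seeded; `select_k` and `kmeans_missing` are
  deterministic given their seed, and the pipeline fans a single global
  seed out to stages by a stable hash of the stage name.
* Problem sizes used by the test suite and the acceptance script: default
  cohorts (320 subjects, 8,000 variants) for end-to-end recovery; 20 seeds
  for cluster-number convergence and pathway recovery; 500 replicates
  against 1,000 null sets for competitive-p calibration; 500 logistic
  replicates at n = 320 for odds-ratio recovery; an exhaustive n <= 50
  sweep for the exact HWE test; 200 random instances for the clumping
  oracle. A heritability-recovery check runs once at 20,000 variants x
  2,000 subjects with minimal drift.

# Known limitations

* The permuted-null machinery residualizes null-set scores on the same PCs
  as the observed score but does not re-run clumping per null set (null
  sets reuse the genome-wide clumped variants): the null answers "is this a
  special set of genes", not "is this a special clumping".
* `project_samples` applies no shrinkage correction; centroid assignment is
  robust to the shared shrinkage but absolute PC coordinates of projected
  samples are biased toward zero.
* The Galwey budget depends on the observed correlation structure, so the
  synthetic cohort's budget differs from any particular empirical cohort's;
  the arithmetic (round-half-up, multiply, add standalone tests) is what is
  fixed.
* Fisher's exact test for cluster enrichment falls back to chi-square (and
  says so) when the network algorithm is infeasible for large tables.
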