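---
title: "Methods: comorbidity topic modelling and polygenic risk association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comorbidity topic modelling and polygenic risk association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, parameter choices, numerical decisions and
known limitations behind `topicprs`. It is the design record: everything here
is either a definition or a choice with its rationale; empirical behaviour is
established by the test suite and `scripts/acceptance.R`, not asserted here.

## Problem and model

The pipeline asks whether subgroups of co-occurring clinical conditions in a
phenotyped, genotyped cohort are associated with polygenic risk — risk scored
either for the index condition itself or for the comorbid phenotypes (e.g.
allergic disease, chronic pain) in general-population GWAS.

Comorbidity subgroups are modelled with latent Dirichlet allocation. Each
subject's "pseudo-EMR" document is the set of their present clinical features
rendered as single hyphenated terms. LDA treats each document as a mixture
θ_d over K topics and each topic as a distribution φ_k over terms. A topic is
therefore a cluster of conditions that co-occur across subjects, and θ_dk is
how strongly subject d expresses cluster k. Topic loadings are tested against
polygenic risk scores by ordinary least squares with covariate adjustment.

Assumptions worth stating explicitly:

* **Documents are sets.** Presence/absence phenotypes carry no term
  frequency; each present feature contributes exactly one token. LDA remains
  the standard multinomial model over these tokens. A consequence, verified
  during design, is that topic structure is identifiable only when presence is
  sparse — if most terms are present in most subjects, the presence table
  saturates and no document-level mixture can be recovered. The synthetic
  generator therefore defaults to ~10% presence density (300 candidate terms,
  ~30 present), which matches the character of structured phenotype batteries.
* **Exchangeable subjects, no family structure.** The OLS stage treats
  subjects as independent; related subjects (siblings, trios) would need a
  mixed model, which is out of scope.
* **Additive genetics.** PRS are linear in allele dosage with externally
  estimated weights.

## Pseudo-EMR construction

* Continuous features are dichotomized by **exact 1-D 2-means**: the optimal
  two-cluster partition in one dimension is an interval split of the sorted
  values, so the within-cluster sum of squares is minimised exactly by
  scanning all n−1 split points (prefix-sum algebra, O(n log n)). This
  removes the initialization nondeterminism of Lloyd-style k-means; there is
  nothing stochastic to seed. The higher-mean cluster is coded "present",
  because clinically salient continuous features (delays, low tolerance
  scores) code the extreme tail; features whose direction is reversed, or
  whose cut-point comes from clinical literature, use explicit per-feature
  threshold overrides (`cut`, `direction`).
* Categorical features with more than two levels expand to one indicator per
  level before filtering; "collapse to presence/absence" under-specifies
  multi-level handling and indicator expansion preserves every level's
  information.
* Features with presence count ≤ 1 are removed as prohibitively sparse (a
  feature seen once cannot co-occur informatively).
* Missing values are excluded from clustering and contribute no token.
  Absence and missingness both yield no token; the exclusion log records
  feature-level decisions so the distinction is auditable.
* Term labels are lowercased, whitespace-hyphenated feature names; an
  explicit `name_map` handles curated renamings (e.g. reordering
  "floppy infant" to `infant-floppy`), since no automatic rule can guess
  editorial word order. Duplicate resulting labels are an error, not a silent
  merge. Subjects with zero present features are dropped with a warning —
  an empty document has no likelihood contribution.

## Topic model

The collapsed Gibbs sampler integrates out φ and θ and resamples each token's
topic from P(z_i = k | z_-i, w) ∝ (n_dk + α)(n_kw + β)/(n_k + Vβ). The
implementation is ~100 lines of C++ (Rcpp) using R's RNG, so `set.seed` gives
bit-identical chains across platforms.

* **Priors and schedule:** symmetric α = 0.1, β = 0.01 (small concentrations
  keep topics well separated); 2000 iterations, burn-in 1000, thinning 500.
  "Thinning 500" is interpreted as retention spacing, so the retained states
  are iterations 1500 and 2000. The reported φ and θ are posterior means over
  the retained samples — more stable than a single final draw — and the
  final-state estimates are also exposed (`phi_last`, `theta_last`) for users
  who prefer the single-sample convention. If a user schedule retains no
  sample, the final state is used with a warning.
* **Diagnostics:** the collapsed joint log-probability is traced per
  iteration (Dirichlet-multinomial closed form); it is a mixing diagnostic,
  not a monotone objective.
* **Topic-number selection** runs candidate K over a grid and computes, per
  K: held-out per-token perplexity by cross-validated document completion
  (fit on training folds; for each held-out document, estimate θ from
  alternate tokens by fold-in Gibbs with φ fixed, score the remaining
  tokens), UMass semantic coherence of the top 10 terms, and term exclusivity
  (mean share of a top term's probability mass owned by its topic). The
  selected K maximises the mean of min-max-normalised −perplexity and
  exclusivity: predictive fit is the sensitivity axis, exclusivity the
  term-specificity axis. Coherence is reported but deliberately excluded
  from the composite: on presence/absence corpora both coherence and
  exclusivity are monotone in K (merging topics always raises coherence and
  trivially raises term "ownership" at small K), so a three-way mean hands
  the grid endpoints two of three normalised points and can never select an
  interior K. This was observed directly on planted-truth simulations during
  development; with the two-metric composite the planted K is recovered
  reliably (see the acceptance tests).
* **Label switching:** topics are identified only up to permutation; all
  truth comparisons use permutation matching by total-variation distance
  (exhaustive for K ≤ 8). No test or report asserts raw topic indices.
* **Top terms:** ranked by φ within topic, ties broken lexicographically so
  output is deterministic; default 16 terms per topic, annotated at the
  φ ≥ 0.05 mark.

## Genetics

* **QC order:** sample call rate ≥ 0.9 → SNP call rate ≥ 0.9 → HWE → strand-
  ambiguous removal → reference-panel presence and |Δfreq| ≤ 0.2. Every
  dropped item is logged with a reason, and the QC report plus survivors
  partition the input exactly.
* **Hardy-Weinberg:** 1-df chi-square on hard-called genotypes against
  expectations under the sample allele frequency — the conventional array-QC
  test at the coarse 1e-6 threshold. The conditional exact test (enumerating
  heterozygote counts of matching parity) is available via
  `method = "exact"`; monomorphic SNPs return p = 1 by convention.
* **Harmonization:** effects are re-expressed on the dosage-counted ALT
  allele: matching order keeps β, swapped order negates β and reflects the
  frequency, and a failed match is retried after complementing (a strand
  flip) for non-ambiguous SNPs only; anything else is dropped with a reason.
  Harmonization is an involution: flipping A1/A2 and negating β in the input
  leaves scores unchanged (property-tested).
* **Clumping:** greedy by ascending p (ties: chromosome, position, id — so
  the result is independent of row order); the index SNP claims all unclaimed
  SNPs on its chromosome within 250 kb with dosage r² ≥ 0.5. "Minimum R² 0.5"
  is read as *removal when r² ≥ 0.5*. r² is the squared Pearson correlation
  of dosages (composite LD, no phasing), pairwise-complete; an undefined
  correlation (zero variance) counts as unlinked.
* **Tranches:** S2–S8 ceilings 1e-2 … 1e-7, 5e-8; each tranche contains every
  retained SNP with p at or below its ceiling, so the SNP sets are nested.
  Missing dosages are mean-imputed (2 × sample effect-allele frequency).
  Scores are standardized within cohort so association coefficients are
  per-SD and comparable across tranches; an empty or constant tranche scores
  zero, is flagged, and is reported as untestable (NA) in the scan rather
  than fitted.
* **PCA:** dosages mean-imputed, centred at 2p̂ and scaled by √(2p̂(1−p̂));
  scores are the leading left singular vectors (orthonormal), with the
  deterministic sign convention that each component's largest-magnitude SNP
  loading is positive.

## Association statistics

* **INT:** y = Φ⁻¹((r − c)/(n − 2c + 1)) with average ranks for ties and the
  Blom offset c = 3/8 — the standard choice in statistical genetics; the
  offset is configurable. Degenerate (constant) outcomes are an error.
* **Per-cell model:** OLS of the transformed loading on [PRS, age, sex,
  PC1–5], complete cases per model. sr² = R²_full − R²_without-PRS is the
  PRS's unique variance share (100·sr² is the percent-variance convention);
  partial r² = sr²/(1 − R²_without-PRS). Both are reported because
  percent-variance summaries in this literature do not always say which is
  meant.
* **Model comparison:** F = [(RSS_red − RSS_full)/(df_red − df_full)] /
  [RSS_full/df_full]; with one added predictor this equals the squared t of
  its coefficient (identity-tested against `anova()`).
* **Multiplicity:** the scan reports nominal p as primary (the procedure it
  reproduces tested a topic × tranche grid at nominal levels) and annotates
  Bonferroni and Benjamini–Hochberg columns so users can correct; no
  correction is silently applied.
* **Exclusions:** user-flagged topics (e.g. an artefact topic dominated by
  maternal substance use) are dropped from the scan by index.

## Gene-list overlap

Exact upper-tail hypergeometric probability P(X ≥ k), computed by log-space
summation; the observed k is included (enrichment convention); symmetry in
the two sets and monotonicity in k are property-tested. The universe size N
is a **required** argument: published overlap p-values are not reproducible
without knowing N, and ~20,000 protein-coding genes is a common default
choice, documented rather than hard-coded.

## Synthetic-data generator

The generator is first-class, tested code. It emulates:

* an LDA corpus (θ_d ~ Dir(0.5): subjects load on a few clusters; φ_k ~
  Dir(0.05): concentrated, largely distinct condition clusters; ~30 of 300
  terms present per subject) plus the binary feature table so the pseudo-EMR
  stage is exercised end to end;
* biallelic genotypes from a latent Gaussian with block-exchangeable
  correlation (default blocks of 10, ρ = 0.8, MAF ~ U(0.05, 0.5)), thresholded
  per haplotype — enough local r² structure to exercise clumping without a
  recombination map;
* an external GWAS: causal effects ~ N(0, 0.2²) on 50 of 2000 SNPs, a
  unit-noise liability, and per-SNP marginal OLS in an **independent**
  discovery cohort of the same size, so PRS transfer to the target cohort is
  honest (weights are noisy, as in practice); alleles are drawn uniformly so
  a realistic fraction is strand-ambiguous and exercised by QC;
* a planted effect: the target topic's loading is shifted on the log scale in
  proportion to the standardized true burden Σ_j β_j d_ij.
  `prs_topic_effect` is specified in interpretable units — loading SDs per
  burden SD — and the log-scale coefficient is calibrated via the softmax
  derivative (effect × sd(θ_t) / mean(θ_t(1 − θ_t)) over the base mixtures),
  because a raw log-scale shift of the same number is attenuated roughly
  three-fold at the default concentrations and would not mean what "SD per
  SD" says. With effect 0 the output is distributed exactly as the base
  corpus.

What it does **not** emulate: realistic human LD (no recombination map or
MAF-LD coupling), case/control ascertainment, genotyping batch effects or
missingness patterns, imputation quality, family structure, or population
stratification by default (PCA covariates are exercised but the default
cohort is homogeneous). Passing tests therefore demonstrate correctness of
the machinery and calibration under the stated generative conditions — not
robustness to every pathology of real cohort data.

## Reproducibility and numerical conventions

* One global seed; every stochastic stage derives its own seed by hashing a
  stage label (`derive_seed`), so stages can be re-run standalone and the
  full pipeline is bit-identical under a fixed seed (tested file-by-file).
  All randomness goes through R's RNG, including inside the C++ sampler.
* p-values from marginal GWAS are floored at the smallest positive double to
  respect the (0, 1] contract.
* All on-disk formats are plain text: VCF v4.2 (GT for integer dosages, DS
  otherwise), TSV summary statistics (`SNP CHR BP A1 A2 BETA FREQ P`; odds
  ratios log-transformed on read), one-document-per-line corpora, JSON
  manifests and truth sidecars. Writers round-trip losslessly at 17
  significant digits.

## Problem sizes used by the validation suite

Chosen to make each check informative at desk scale: exact-enumeration
sampler checks on corpora of ≤ 6 tokens (20 seeds); topic recovery at
D = 500, V = 100, K = 5, ~50 tokens/document; topic-number selection at
D = 200, planted K = 4, 25 seeds; null calibration over 1000 simulated
datasets of n = 500; power at n = 1000 over 200 seeds; end-to-end planted
(topic, trait) recovery over 20 full pipeline runs at n = 1000 with an
unlinked second trait; clumping and 2-means oracle equivalence on 100 and
200 random instances respectively.

## Known limitations

* Set-documents discard severity/frequency information; ordinal severity
  scores are flattened by dichotomization.
* The selection composite weights its two metrics equally; all per-K metrics
  are reported so users can re-weight or plot the grid.
* OLS ignores relatedness and assumes the INT'd loading is homoscedastic in
  covariates.
* Clumping uses in-sample LD from the scored cohort rather than an external
  LD reference.
* The overlap test treats gene lists as simple random draws from the
  universe — no accounting for gene length, LD between neighbouring genes, or
  list-construction bias.
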