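---
title: "Methods: spatial-temporal analysis of skin ASV communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial-temporal analysis of skin ASV communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

Longitudinal tape-strip studies of the skin microbiome ask how much of the
variation in 16S amplicon sequence variant (ASV) communities is explained by
who the sample came from (interindividual variation), where in the epidermis
it was taken (tape 1 = surface vs tape 5 = within the epidermis), disease
state (atopic dermatitis, lesional/nonlesional, vs healthy control), and
when it was taken (repeated visits at 4-week intervals). `dermadiv`
implements the full post-ASV-table analysis chain for such designs:
decontamination and normalization, α/β-diversity, PERMANOVA-based variance
partitioning with restricted permutations, within-participant persistence
statistics, and core-community identification, together with a synthetic
study generator so that every stage is testable without sequencing data.

# Preprocessing

Starting from a raw count table (samples × ASVs) the chain applies:

1. **Negative-control contaminant filter.** An ASV detected (count > 0) in
   at least `min_negatives = 10` extraction negatives is removed from every
   sample; the whole column is deleted, not subtracted per sample. The
   negatives themselves leave the table here.
2. **Prevalence filter.** ASVs detected in fewer than `min_samples = 5`
   samples are removed (an ASV in exactly 5 samples stays).
3. **Taxonomy filter.** Only ASVs whose domain is Bacteria or Archaea and
   whose lineage contains neither "Mitochondria" nor "Chloroplast"
   (case-insensitive, any rank) are kept.
4. **Fourth-root normalization.** Counts x are replaced by x^(1/4) and each
   sample is rescaled to relative abundances summing to 1. The fourth root
   damps PCR amplification bias; it also pushes abundance-weighted
   statistics toward presence/absence behaviour, which matters when
   interpreting the PERMANOVA partition below.

The filter order (negatives → prevalence → taxonomy) is a convention; the
final ASV set is order-invariant (tested), only the per-stage attribution in
the `FilterReport` changes. The report also carries the per-sample fraction
of reads removed, averaged over non-control samples. Samples with all-zero
rows (failed sequencing) are dropped at alignment with a warning — the
upstream protocol this reproduces does not say how such samples were
handled, so the package takes the conservative choice and logs it.

# Diversity

* **Richness** is the number of detected ASVs (count > 0, on the
  pre-normalization counts). Detection has no abundance threshold: the
  source protocol gives none, so any nonzero count is a detection.
* **Shannon diversity** H = −Σ pᵢ ln pᵢ, natural log. By default it is
  computed on the fourth-root relative abundances, since that is the
  normalization applied "for downstream statistical analyses"; a flag
  (`shannon_on = "raw"`) gives the untransformed version, because the
  upstream description does not pin this down.
* **β-diversity** is deliberately three numbers per sample pair, computed
  on all within-participant temporal pairs at fixed depth and skin status:
  the absolute richness difference, the Jaccard membership similarity
  (proportion of shared ASVs — reported as similarity, not distance), and
  the Yue-Clayton similarity θ = Σpq / (Σ(p−q)² + Σpq), which weights by
  relative abundance. Pairing uses *all* temporal pairs, not only
  consecutive visits ("paired samples" carries no restriction);
  `pairing = "consecutive"` restricts if wanted.

Degenerate inputs are defined, not crashed on: two empty samples have
Jaccard 1 (with a warning), Yue-Clayton of two empty compositions is
missing, Shannon of an empty sample is missing.

# Variance partitioning (PERMANOVA)

Distances default to Bray-Curtis on the fourth-root relative abundances.
The upstream analysis never names its dissimilarity; Bray-Curtis is the
default of the standard `adonis2`-style implementation it cites, and the
metric is a config option (`jaccard_binary`, `euclidean`).

The engine is written from first principles: Gower-centered inner-product
matrix G = −½ J D² J, sequential (Type I) sums of squares as trace
differences between nested design projections, pseudo-F against the
residual. Permutation p-values use the add-one estimator; `n_perm =
"exact"` enumerates all arrangements (refusing above 10⁶) and reports the
exact exceedance fraction. The implementation is checked against `vegan`
(SS/R²/F), against classical one-way ANOVA for Euclidean distances of a
univariate response, and against a brute-force enumeration oracle for exact
p-values.

**Term order matters.** With sequential SS and disease status constant
within participant, status after the participant term adds no estimable
contrasts. The pooled model therefore enters terms as status, depth, time,
participant — the order in which the factors are tabulated upstream — and
the participant term, entered last, absorbs the remaining between-person
variance. A consequence worth knowing: a first-entered, participant-constant
factor picks up "leakage" of roughly R²(participant)/(number of
participants − 1) purely by chance, which is why small status effects in
such designs should be read cautiously.

**Strata.** With `strata = "participant_id"`, permutations shuffle labels
only within participants. A factor constant within blocks (status again)
cannot be tested that way, so the engine automatically switches to
exchanging the factor's block-level values across participants and says so
in the result's notes. How the original analysis resolved this
contradiction is unknown; the fallback is this package's own decision.

# Persistence and the core community

Persistence of an ASV over a sample set is the exact fraction of samples in
which it is detected. Profiles are per participant, within any combination
of non-pooled design axes.

* **Depth test:** paired t across participants of surface-minus-within
  persistence, for ASVs detected in more than 5 samples overall;
  Benjamini-Hochberg q-values. Zero-variance differences or fewer than 3
  pairs give a flagged missing statistic.
* **Status test:** fixed effect of cohort on per-participant persistence at
  one depth with a participant random intercept. With one value per
  participant (the standard design) the random intercept is unidentifiable;
  the operation detects this and reports the equivalent two-sample
  linear-model test, flagged `degenerate_random_effect`, rather than a
  silently singular mixed fit. ASVs enter only with non-zero persistence in
  more than 5 participants.
* **Core community:** per participant, ASVs with persistence ≥ 0.7 pooled
  over time and depth, lesional samples excluded. Membership is inclusive
  at the threshold — the two upstream phrasings (">0.7" for the core,
  "0.7 or more" for ubiquitous ASVs) are reconciled in favour of ≥, and the
  threshold is configurable. **Ubiquitous ASVs** are detected in ≥ 70% of
  all retained samples; by default lesional samples are excluded here too,
  for consistency with the core definition (a flag includes them — whether
  "all samples" included lesional ones upstream is ambiguous).
* Cohort comparisons of core share/richness use Kruskal-Wallis; core-subset
  composition uses the PERMANOVA engine with participant strata. Both a
  rank test and a mixed-model route exist upstream; neither is privileged
  here.

Benjamini-Hochberg is used wherever "FDR" is called for; the specific FDR
variant was not named upstream, and BH is the step-up default everywhere in
this field. Wald tests are the default for mixed-model inference.

# The synthetic study generator

`generate_study()` emits a full study — counts, metadata, taxonomy, and
ground truth — from a mechanism chosen to reproduce the *structure* the
analysis assumes, not any particular noise family:

1. a global log-normal abundance base over the ASV pool;
2. per-participant surface profiles: base + Normal(0, σ_P) per ASV, a
   Bernoulli occupancy mask (`participant_occupancy`), and
   `n_core_asvs_per_participant` planted core ASVs boosted by
   `core_log_boost` on the log scale;
3. within-epidermis profiles as a participant-consistent subset of the
   surface support (fraction `depth_retention_fraction` of the non-core
   ASVs; core and pathobiont ASVs are treated as depth-stable), renormalized
   — the inner community is a strict subset of the outer;
4. pathobiont ("Staphylococcus") ASVs up-weighted by exp(δ_S) in AD
   participants;
5. per sample: per-ASV log-normal overdispersion (`sample_noise_sd`) and a
   multinomial read draw at a log-normal sequencing depth — with δ_T = 0
   there is no systematic temporal shift, matching the finding of
   negligible temporal variation;
6. extraction negatives drawing only from a contaminant pool that is also
   sporadically spiked into surface samples;
7. optional lesional samples with per-body-location log shifts.

## Why these defaults

The defaults are the package's statement of the world the analysis was
designed for, fixed before the acceptance checks were run:

* `n_participants_ad = n_participants_hc = 20`, 4 visits, 2 depths, mean
  42,569 reads/sample — the design and depth of the motivating study.
* `participant_occupancy = 0.8`, `participant_effect_sd = 1.5`,
  `sample_noise_sd = 2`: interindividual variation is carried both by
  membership (who hosts which ASVs) and abundance; the overdispersion term
  is essential — with multinomial resampling alone the design factors would
  explain nearly all community variance, whereas real amplicon studies
  leave most variance unexplained. With these values the realized pooled
  partition is participant ≈ 0.45–0.5, depth ≈ 0.04, status ≈ 0.02–0.03,
  time ≈ 0 — the qualitative 25:2:1:0 hierarchy.
* `depth_retention_fraction = 0.35` with depth-stable cores gives overall
  within-epidermis retention near one half and a realized surface/within
  richness ratio of ≈ 1.8–1.9, matching the reported ≈ 198 vs ≈ 107 mean
  ASVs (the full-scale default study realizes ≈ 173 vs ≈ 92, ratio 1.88,
  Shannon 4.97 vs 4.31).
* `status_effect = 0.5` on 20 pathobiont ASVs keeps the status term small
  and below depth, as observed (0.9% vs 2.0%).
* `n_contaminant_asvs = 27` and 30 negatives with per-negative detection
  probability 0.97: 27 contaminants were removed upstream at a threshold of
  10 ≈ one-third of the negatives; under these defaults every contaminant
  is detected in ≥ 10 negatives essentially surely, so the filter removes
  exactly the planted set.
* `location_effect_sd = 1` for lesional body-location shifts is a free
  parameter; no quantitative location effect is stated anywhere, only that
  it is large relative to other factors.

Two generator parameters go beyond the minimal mechanism: the occupancy
mask (without it every participant hosts the whole pool and richness is
unrealistic) and the core boost (the core must be reliably detectable for
recovery tests to mean anything). Both are documented knobs, not hidden
constants.

## What the generator does *not* emulate

No read-level error, chimeras or primer bias; no taxonomy uncertainty
(every simulated ASV has a clean lineage); no abundance-correlated
contamination (presence in negatives is the only contaminant signal, as in
the filter it feeds); no participant dropout or antibiotic-use covariates;
body-location effects are plain log-normal shifts. A green test therefore
establishes that the pipeline recovers planted structure under the stated
mechanism — not that the mechanism is a complete model of skin microbiome
data.

# Numerical choices

* Detection is count > 0; persistence values are exact rationals
  detections/n.
* Yue-Clayton/Jaccard conventions for empty compositions are warnings +
  defined values (see above); Bray-Curtis between two empty samples is 0.
* Exact permutation p is the plain exceedance fraction over the full
  enumeration (identity included); Monte-Carlo p uses (1 + exceedances)/(1
  + n_perm), so p ≥ 1/(n_perm + 1).
* Ties in F comparisons use a 1e-12 slack so that equal-statistic
  permutations count as exceedances.
* Core membership at exactly the threshold is *in* (≥).
* All randomness is drawn from seeded streams that restore the caller's
  RNG state; identical seeds give bit-identical studies and p-values.

# Known limitations

* Sequential SS means reported R² depend on term order; the chosen orders
  are documented above and in the output objects.
* The block-exchange fallback for participant-constant factors assumes
  participants are exchangeable units; with strongly unbalanced designs
  its p-values are approximate.
* The mixed-model route for persistence responses treats proportions as
  Gaussian; for small per-participant sample counts a binomial model would
  be preferable but is out of scope here.
* `diversity_model`'s "GLM" is Gaussian least squares (no link was ever
  specified upstream); a count-family option for richness exists but is
  not the default.
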