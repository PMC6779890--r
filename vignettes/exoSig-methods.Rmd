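---
title: "exoSig: methods and design notes"
author: "exoSig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{exoSig: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery in `exoSig`, the
reasoning behind the design choices that were genuinely open, and what the
simulation-based validation does and does not establish. The package
addresses a recurring study design in fluid-biomarker transcriptomics:
small RNA sequencing of CSF exosomes in a signature-identification cohort
(AD dementia vs controls), validation on an untouched replication cohort,
a longitudinal MCI cohort for conversion prediction, and combination with
the CSF protein biomarkers pTau and the Aβ42/40 ratio.

# The data container and the leakage guard

`SncExperiment` extends `SummarizedExperiment`: raw counts plus feature
kinds (miRNA/piRNA) in `rowData`, the clinical table (diagnosis, center,
age, sex, protein markers) in `colData`. Two slots carry pipeline
semantics: an immutable cohort `role` and a `provenance` log. Every
fitting operation (`runSelection`, `tuneAndTrain` via `combinedModel`,
`runPipeline`'s selection stage) refuses cohorts whose role ends in
`_test`. This makes the held-out discipline structural rather than
conventional: the replication cohort physically cannot leak into feature
selection or model tuning.

# Preprocessing

**Sample filter.** Samples with fewer than 50,000 total counts are
removed (strictly below; a 49,999-read library is dropped, a 50,000-read
library kept). Library size is the column sum of the quantified matrix —
the number of uniquely mapped reads is no longer available after
quantification, a documented divergence that only matters for borderline
libraries.

**Variance-stabilizing normalization.** Each sample receives an affine
calibration followed by a generalized log:
$h_s(x) = \mathrm{glog}_2\!\big((x - a_s)/b_s\big)$ with
$\mathrm{glog}_2(z) = \log_2\!\big((z + \sqrt{z^2 + c^2})/2\big)$.
For large counts $h_s \to \log_2((x - a_s)/b_s)$, so fold changes read as
log2 differences; near zero the glog damps the variance inflation of the
plain log. Calibration is iterative: the scale $b_s$ is the median of
count/reference ratios over the central expression band (trim fraction
0.1 per tail, plus the lowest quartile excluded from the band), the
offset $a_s$ is the median residual of the lowest-quartile features (a
background estimate, near zero for clean count data), and the reference
profile is the trimmed mean of the calibrated matrix, recomputed each
round until no parameter moves by more than 1e-6 or 50 rounds have run
(the cap is a deliberate stop, not an error; the fit is flagged
non-converged in the metadata). The glog offset $c$ is the median
calibrated feature mean among low-abundance features (mean < 10). An
earlier draft fit the calibration by band-limited least squares; that
allowed offsets of hundreds of counts, which pushed low counts negative
and exploded the variance of mid-abundance features — the median-based
estimators are the robust replacement. The monotonicity of $h_s$ within
each sample, the log2 asymptote, and the flatness of the SD-vs-mean-rank
trend on negative-binomial counts spanning means 1–10⁴ are all asserted
in the test suite.

**Removal of unwanted variation.** $k$ nuisance factors (default 1) are
estimated as the top right-singular vectors of the row-centered matrix of
empirical control features — the least-variable quartile, on the premise
that features untouched by biology mainly carry technical variation — and
regressed out of every feature. Spike-ins are not assumed. Batch labels
are accepted for diagnostics only; with the factors estimated
unsupervised, the correction is identical under any batch relabelling,
which is exactly the behaviour required of a nuisance component
orthogonal to the group signal. `k = 0` is the identity.

**Expression filter.** A feature is removed iff, in *both* groups, at
least 95 % of samples sit below 0.5 on the normalized scale. The AND
rule (rather than OR across groups) is deliberate: an OR rule would
discard group-specific markers, the very features a discriminative
signature needs. The boundary is sharp and tested: expressed in 2 of 20
samples of one group (10 % > 5 %) keeps a feature; 1 of 20 (fraction
below = 0.95) removes it.

The driver enforces the order sample filter → VSN → RUV → expression
filter; stages called out of order fail on missing prerequisites.

# Three-iteration feature selection

**Iteration 1 — MoR + reliability analysis.** The relevance score is the
Welch-standardized absolute mean difference with a floor of 1e-8 on the
standard error; it is affine-invariant and treats every feature
independently. The critical value is the $(1-\alpha)$ empirical quantile
(order statistic at $\lceil (1-\alpha) N \rceil$) of the pooled
per-feature score null under case/control label permutations; when
$\binom{n}{n_\text{case}} \le 10{,}000$ every arrangement is enumerated,
and the suite checks exact equality with a brute-force enumeration
oracle. Passing is strict (`score > cutoff`). Reliability analysis then
redraws stratified bootstrap resamples (default 100), re-estimates the
cutoff within each resample, and keeps features that passed on the full
data and were re-selected in at least 80 % of resamples. Bootstrap
stability is an *estimation-stability* check, not a second null test: a
chance-extreme feature is often stably re-selected because the resamples
reuse the observed data. Familywise control is therefore the job of
Iteration 3.

**Iteration 2 — information ranking.** Plug-in mutual information (bits)
between equal-frequency-binned expression (3 bins by default;
deduplicated quantile edges, so heavily tied features use fewer bins) and
the class label, compared per feature against the 95th percentile of its
own label-permutation null. Rank ties break by MoR score, then
lexicographic ID. The plug-in estimator's positive bias is immaterial
here because each feature is compared against its own permutation null,
which carries the same bias.

**Iteration 3 — covariate confound filter.** Per feature, the partial
F-test of the group term in `value ~ group + age + sex` against the
covariate-only model; constant covariates are dropped, reducing the test
to one-way ANOVA. The Bonferroni family in the pipeline is the *full
screened feature set*, not the handful surviving Iterations 1–2:
correcting only across data-selected extremes would be circular and
leaves the familywise error uncontrolled (in null simulations a
survivor-family correction admitted spurious signatures in over half of
runs; the full-family correction keeps the pipeline empty under the
null, which the acceptance suite verifies over 20 seeds). The standalone
`mancovaFilter` defaults to the features it is given, with an explicit
`mTests` argument. Pillai's trace from the joint multivariate fit of the
retained features is reported as an omnibus diagnostic, not used for
filtering — a joint multivariate test cannot by itself remove individual
features. The retained features, ordered by MoR score and signed by the
group mean difference, form the `Signature`.

An empty set after any iteration raises an error naming the iteration —
under the global null this is the expected (and tested) outcome.

# Classification and evaluation

The forest size is chosen from a grid (100–1000 trees, step 100) by
stratified tenfold cross-validation of the class-weighted
misclassification error, ties resolved toward fewer trees; the final
model is refit on all training data with stratified per-tree sampling and
class weights 0.5 (control) / 1.0 (case), prioritizing sensitivity.
Permutation variable importance is stored. Evaluation uses the empirical
Mann–Whitney AUC with ties counted 0.5 — no curve smoothing enters any
computation — and a 95 % percentile interval over 500 class-stratified
bootstrap resamples. The suite checks the AUC against brute-force pair
enumeration (including ties) and the interval's coverage at a true AUC of
0.8. Combined models concatenate the signature expression with pTau and
the Aβ42/40 ratio; `pirna_only` supports the MCI design, where the piRNA
members identified in the signature cohort are applied unchanged to the
conversion cohort rather than re-selected.

# Descriptive sncRNAome analytics

Composition fractions are per-biotype read sums over the grand total.
Locus annotation uses the precedence first exon > other exon > intron >
intergenic over all same-strand transcripts (antisense overlap is
available via `ignoreStrand`), with "first exon" defined in transcription
order — the rightmost interval of a minus-strand transcript — an overlap
being any ≥ 1 bp intersection, and host-gene ties resolved to the
lexicographically smallest gene ID. The precedence ordering resolves
multi-transcript ambiguity in favour of the first-exon call, matching the
biological emphasis on exon-1-derived piRNAs. GTF input (1-based
inclusive) and BED (0-based half-open on disk) go through `rtracklayer`;
round trips are tested. Arm dominance pairs `-5p`/`-3p` suffixed IDs by
stem, calls the higher mean-expression arm dominant (exact equality is a
tie), and concordance between two tissues is the agreement fraction over
shared tie-free precursors.

# The synthetic-data generator

`simulateStudy` draws counts
$x_{fs} \sim \mathrm{NB}(\mu_{fs}, k)$ with variance $\mu + \mu^2/k$ and
$$\mu_{fs} = L_s \, \pi_f \, 2^{\text{case}_s \cdot \beta_f}
  \, 2^{(\text{age}_s - \bar a)\gamma_f} \, 2^{b_{f,\text{batch}(s)}},$$
where $L_s$ is a lognormal library size (meanlog $\log 3\times10^5$,
sdlog 0.4 — comfortably above the 50,000-read floor, as in a competently
run study), $\pi_f$ a lognormal baseline abundance profile (sd 2 natural
logs), $\beta_f$ the planted log2 fold changes, $\gamma_f$ the
age-confound slopes (0.08 log2/year on the decoys), and
$b_{f,\text{batch}}$ i.i.d. N(0, 0.2 log2) center effects. Defaults
encode the targeted study design: 38 controls vs 23 cases; 150 miRNAs +
50 piRNAs (the scale of an expressed CSF sncRNAome after filtering);
dispersion $k = 10$; two centers; six planted markers at |log2FC| = 1.5 —
three miRNAs up, two piRNAs up, one down, the direction pattern of the
motivating study, with the magnitude a free parameter since only
directions are established; and two age-confounded decoys. Age ranges
default to identical 60–84 y uniforms for both groups (age-matched
cohorts); offsetting the ranges creates group–age confounding of any
desired point-biserial strength, which the confound-filter tests set to
0.8.

Two deliberate structural choices: the **baseline profile has its own
seed** (`baselineSeed`, fixed by default) so that cohorts simulated with
different subject seeds share one population-level abundance profile —
without this, "train on cohort 1, validate on cohort 2" would be
ill-posed because each cohort would inhabit a different expression space.
And **planted/confounded features draw their baselines from the upper
half of the abundance distribution**, emulating the fact that reported
signature sncRNAs are by construction detectable features that survived
expression filtering.

`simulateBiomarkers` enforces the clinical rule exactly — cases (and MCI
converters) receive Aβ42 < 450 pg/ml and total Tau > 200 pg/ml, controls
(and stable MCI) the inverse — with pTau a noisy linear function of Tau
and Aβ40 positive so the ratio is always defined. The planted separation
makes the protein panel strongly informative, mirroring its clinical
status. `simulatePairedCellExosome` produces bivariate-normal
log-expression with exact population correlation ρ (Cholesky
construction, so ρ = 1 is an exact linear dependence), plus optional
independent decoy features. `simulateGeneModel` lays out non-overlapping
multi-exon genes on both strands and places piRNA-sized (26–31 nt) loci
wholly inside known contexts, giving the annotation module an exact
truth set.

**What the generator does not emulate** — and hence what green tests do
not establish about real data: compositional coupling between features
(baselines are independent), realistic dispersion heterogeneity and
zero-inflation, hemolysis/contamination artifacts, overlapping genes and
multi-transcript loci, diagnosis uncertainty, and cohort-level
distribution shift beyond multiplicative center effects. Recovery of
planted effects at |log2FC| = 1.5 demonstrates the machinery is correct
and well-calibrated, not that real CSF signatures of that size are
detectable at these n.

# Numerical choices and degenerate inputs

Empirical permutation quantiles use the order statistic at
$\lceil (1-\alpha)N \rceil$ consistently across the package and its test
oracles. The Welch denominator is floored at 1e-8, so constant features
score 0 and never pass a strict cutoff. Quantile bin edges are
deduplicated before binning. Random-forest tuning breaks error ties
toward fewer trees; an all-constant feature matrix is rejected up front
(the underlying forest implementation does not terminate on such input).
The bootstrap CI is clamped to contain the point estimate (relevant only
in degenerate resampling situations). All randomness flows from a single
seed through fixed integer substreams (kept below 2³¹); reports are
stamped with the configuration's MD5 (of its canonical YAML form) and
seed, never with timestamps, so reruns are byte-identical — verified by
hashing every report file across repeated runs.

# Problem sizes used in validation

The test and acceptance suites run at the study's native scale: 20
simulated signature cohorts (38/23, 200 features) for recovery and 20
null cohorts (400 features) for calibration; 1,000 random score/label
sets for the AUC oracle and 200 replications × 500 resamples for CI
coverage; 1,000 random loci against 15-gene models for annotation; a
44/19 replication cohort and an 11/6 MCI-style cohort for held-out
evaluation. These sizes keep the full validation in the minutes range
while matching the cohort sizes the design targets.

# Known limitations

The MoR/reliability/information-ranking stages implement one defensible
reading of methods that are published only as names with scalar cutoffs;
all thresholds (α = 0.05, stability 0.8, 3 bins, MI null at the 95th
percentile) are exposed as arguments. The RUV variant is unsupervised
(control-feature SVD); replicate-anchored or residual-based variants are
not implemented. MANCOVA is realized as per-feature ANCOVA with an
omnibus diagnostic, not a joint multivariate filter. The pipeline
normalizes each cohort independently; systematic cross-cohort shifts
beyond what calibration absorbs would degrade transfer, and no explicit
cross-cohort alignment step is provided.
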