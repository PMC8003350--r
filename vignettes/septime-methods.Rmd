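---
title: "Standardized expression profiles for two-group developmental time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized expression profiles for two-group developmental time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(septime)
```

# The problem

Crop domestication reshapes development. A direct way to see this at the
molecular level is a factorial time-course RNA-seq experiment: several
domesticated (D) and wild (W) accessions of the same species, each sampled
at the same developmental times (here, days after anthesis, DAA, through
fruit development), with replicate libraries per accession and time. The
reference design in this package is 6 D + 4 W accessions x 7 times
(0--60 DAA in steps of 10) x 2 replicates = 140 libraries; accessions whose
fruits mature later can carry extra libraries past the shared grid, which
are analyzed separately by pairwise time contrasts.

The unit of comparison is the **standardized expression profile (SEP)**:
for one gene in one accession, the vector of time-point mean expressions
(counts per million, averaged over replicates) rescaled to mean 0 and
standard deviation 1 across the time grid. Standardization removes
expression *level* so that accessions and genes are compared purely on the
*shape* of their developmental trajectory.

# Profile estimation

1. **Filtering.** A gene is kept only if, in *every* accession, at least
   `min_positive = 2` of that accession's libraries have a nonzero raw
   count. This targets consistent expression across the whole panel rather
   than expression in any single accession.
2. **Normalization.** Plain counts per million (CPM). Level information is
   about to be discarded by standardization, so elaborate scale factors buy
   nothing here and plain CPM keeps the profile pipeline transparent. (The
   count-based *tests* below are a different matter; see "Offsets".)
3. **Cell means.** For every (accession, time) cell, the mean CPM over that
   cell's replicate libraries, over the time grid shared by all accessions.
4. **Standardization.** Per gene and accession, the 7-point mean vector is
   centered and divided by its standard deviation. Genes with a constant
   mean vector in some accession have no profile shape there; they are
   flagged invalid rather than silently zeroed, and cross-accession
   analyses use only genes valid everywhere.

**Why the population (divide-by-n) standard deviation?** With the
population convention every SEP has squared norm exactly $n$ (the number of
time points), which gives the exact identity

$$\lVert x - y \rVert^2 = 2n\,(1 - r(x, y))$$

between Euclidean SEP distance and Pearson correlation. The network
module's two thresholds — "distance below 1 standardized unit" and
"correlation above 0.96" — are thereby two views of one geometry: at
$n = 7$, a distance threshold $d$ equals a correlation threshold
$1 - d^2/14$. The sample convention is available via
`sd_convention = "sample"` for comparison with tools that use it.

# Count-based tests

## Tendency classification

For each gene, accession and adjacent time interval (0--10, 10--20, ...,
50--60 DAA) the package classifies the expression tendency as
*increasing*, *steady* or *decreasing* at a Type-I level of 0.01. The test
is a negative-binomial (NB) quasi-likelihood-ratio test of equal relative
abundance in the two cells, with the NB variance $\mu + \phi\mu^2$.

Three design choices matter, all driven by the tiny per-cell sample size
(2 replicates):

* **Dispersion pooling.** A method-of-moments estimate from a single
  2-replicate cell has one degree of freedom and is useless alone. The
  per-gene estimate therefore pools all replicated cells of the tested
  unit (the 7 cells of an accession; all cells of a contrast) and is then
  shrunk halfway toward the across-gene mean. The mean (not the median) is
  the shrinkage target because the median of such noisy, floored-at-zero
  estimates is biased low by about a third, which would inflate every
  test statistic.
* **F reference.** Because $\phi$ is estimated, the likelihood-ratio
  statistic is referred to $F(1,\ d/(1-w))$ instead of $\chi^2_1$, where
  $d$ is the pooled residual df of the moment estimator and $w = 0.5$ the
  shrinkage weight. This is the usual empirical-Bayes accounting (a shrink
  weight $w$ acts like a prior carrying $d\,w/(1-w)$ df, so the posterior
  has $d/(1-w)$ df). The test suite verifies the resulting calibration
  directly: under an all-flat null at the full 140-library design the
  realized non-steady rate at $\alpha = 0.01$ is below
  $\alpha + 3\,\mathrm{SE}$.
* **Offsets.** Library sizes enter as offsets, but as *median-of-ratios
  effective* sizes (the size-factor construction familiar from
  count-based differential expression) computed within the tested unit. A
  handful of strongly changing genes can inflate a library's raw total
  enough to make every other gene look shifted; the median ratio to the
  per-gene geometric mean is insensitive to them. With fewer than 20
  all-positive genes the raw totals are used as a fallback.

## Time contrasts

`contrast_times()` applies the same test to two arbitrary times over a
chosen accession subset (e.g. 60 vs 70 DAA in the late-maturing
accessions) and corrects across genes with Benjamini-Hochberg, calling
differential expression at FDR 0.01 by default.

# Group comparison

* **Pointwise tests.** At each time point the gene's standardized values
  across the 6 D accessions are compared with those across the 4 W
  accessions by Welch's t-test. Welch rather than pooled-variance because
  the groups are small and there is no reason to assume equal
  between-accession variance in domesticated and wild germplasm.
* **Divergence calls.** All gene x time p-values enter one
  Benjamini-Hochberg correction; a gene is *distinct* when any of its time
  points reaches $q \le$ FDR (0.01 by default). Pooling gene x time tests
  (rather than correcting per gene) mirrors the framing in which an FDR
  threshold corresponds to a single realized per-test p cutoff, which the
  function reports. A multivariate profile-level test would be a
  reasonable alternative; the any-time-point rule is simpler, calibrated
  (verified under the null), and sensitive to localized shape changes.
* **Accession clustering.** The dissimilarity between two accessions is
  the mean over genes of the Euclidean distance between their SEPs;
  accessions are clustered agglomeratively (UPGMA/average linkage by
  default, configurable) and the dendrogram can be exported as Newick.
  Heights are reported as raw mean distances.
* **Peak times.** Per gene and accession, the peak is the grid time of the
  SEP's maximum; ties break toward the earlier time (logged in the per-gene
  table), which at worst biases both groups equally. Group means and the
  D - W difference summarize the developmental lag.
* **Diversity.** Expression diversity of a gene within a group is the
  coefficient of variation of its accession-level mean expression (each
  accession's libraries pooled over all times). The paired comparison
  across genes uses log(CV) differences, since CVs are positive and
  right-skewed. Genes with zero means or zero CVs are excluded and
  counted.

# Peak patterns and enrichment

A **peak pattern** such as D10W30 — peak at 10 DAA in D, at 30 DAA in W —
is detected on the group-mean SEPs by default (`group-mean` mode); the
`per-accession-strict` mode demands the argmax condition in every single
accession and is the right input filter for network seeding, where
signals must replicate in all accessions. In practice the pattern search
is run on the divergence-classified `distinct` genes: under the null a
flat gene matches any given pattern with probability about $(1/7)^2$ by
argmax chance alone, so prefiltering by divergence is what keeps the
matched set clean.

GO biological-process enrichment uses the one-sided Fisher exact test per
term with the conditional-MLE odds ratio and BH correction across terms.
Genes without annotation stay in the universe (they count in the "neither"
margin). Term-ancestor propagation is deliberately not performed:
annotations are used as given, so results depend on the annotation's
granularity exactly as provided.

# Network estimation

Starting from a candidate set (e.g. pattern-matched genes annotated with a
process of interest), all unordered pairs are formed and a pair becomes a
candidate edge when the Euclidean distance between the genes' mean SEPs
(averaged over all accessions; a per-group mode is available) is below 1
standardized unit. Candidate edges are then validated on group-mean SEPs:

* within-group coordination: $r > 0.96$ in both D and W with one-sided
  $p < 10^{-4}$ (t transform, df = 5 for 7 time points);
* between-group divergence: cross-group $r < 0.4$ with one-sided
  $p > 0.5$, i.e. no evidence of positive cross-group coordination. The
  between-group correlation is the mean of the two cross-pairings
  $r(D_i, W_j)$ and $r(W_i, D_j)$; the direct pairing $r(D_i, W_i)$ is
  available as an option.

All four correlation p-values test the *positive-association* direction.
This keeps the two criteria complementary: a genuinely peak-shifted pair
has a moderately negative cross-group correlation (about $-0.3$ for the
default curve shapes), which one-sided testing treats — correctly — as a
clear absence of shared coordination rather than as borderline
"significance" of an anticorrelation.

**TF imputation.** A transcription factor is imputed as a candidate
regulator of a target when their SEPs are concordant
($r \ge$ `tf_concordance_min`, default 0.95) in *every accession
independently*. Because the accessions are independent datasets, the
probability that an unrelated gene passes by chance in all $A$ accessions
is approximately $p_\mathrm{pass}^A$, where $p_\mathrm{pass}$ — the
single-accession pass probability for a random expressed gene — is
estimated empirically by random draws; each imputed edge carries this
chance estimate. The same logic underlies
`repeated_error_probability(epsilon, n)` $= \varepsilon^n$: even a lax
per-accession error of $\varepsilon = 0.1$ yields $10^{-10}$ over ten
accessions.

# The synthetic generator

Every statistical guarantee above is verified against simulations with
planted ground truth, so the generator is a first-class module:

* **Design.** The full factorial of `sim_spec()` (defaults: 6 D + 4 W, 7
  times, 2 replicates), with optional late-maturation extensions.
* **Noise model.** NB counts with mean
  $\mathrm{libsize} \times \mathrm{CPM}/10^6$ and dispersion $\phi$
  (default 0.1, i.e. a biological CV of about 0.32 — typical for field-grown
  accession material; 0.01 represents the low-noise regime of tightly
  controlled replicates). Library sizes are drawn log-uniformly between 10
  and 24 million to echo realistic per-library depths. `dispersion = 0`
  gives the Poisson limit used by the mean-recovery tests.
* **Archetypes.** Latent per-group CPM curves are piecewise-linear through
  anchors at the grid times: `flat` (identical constant curve in both
  groups — the true null), `d10w30`-style peak shifts (peak_fold x baseline
  at the peak, shoulders at 25% of the excess on flanking grid points, so
  the argmax is unique), single-time group `shift`s, co-regulated
  `module`s sharing one latent curve per group up to log-normal jitter
  (sd 0.1 on log2), and `tf` genes inheriting their target's curve shape.
* **Seeding.** One master seed; each stage (curves, jitter, library sizes,
  counts, permutations) draws from a derived stream, so the same spec
  reproduces the identical matrix byte for byte.

Two generator choices deserve a note. First, "unrelated" candidate genes
for network simulations are *independently peaked* genes (distinct peak
pairs), not flat nulls: averaging a flat gene's SEPs over 10 accessions
shrinks its mean SEP toward the origin, so any two flat genes sit within
about one standardized unit of each other and would defeat any distance
threshold by construction — a geometric artifact, not a biological signal.
Second, per-accession TF concordance at $r \ge 0.95$ is only attainable
when count noise is small relative to curve shape (with 2 replicates,
dispersion around 0.01); at dispersion 0.1 counting noise alone caps
per-accession correlations near 0.9, so TF-recovery simulations use the
low-noise regime while peak-pattern recovery runs at dispersion 0.1.

**What the simulations do not emulate:** batch effects, isoform structure,
length biases, correlated noise between neighboring time points, GO
annotation realism, or accession-level random effects beyond the planted
ones. Passing recovery tests therefore demonstrates correctness of the
machinery under the stated noise model, not performance on any particular
real dataset.

# Problem sizes and numerical choices

The test suite runs the full 140-library design throughout: 5,000 genes
for the standardization sweep, 2,000 genes for null calibration (120,000
gene x accession x interval tests), 3,000 genes with 300 planted
peak-shift genes for recovery, and a 600-gene module/TF simulation; the
Fisher p-value is checked against a direct hypergeometric enumeration on
500 random tables at $10^{-10}$. Degenerate inputs fail loudly: zero-total
libraries, constant profiles, empty gene sets, off-grid pattern times and
out-of-range thresholds are all errors or logged exclusions, never silent
coercions.

# Limitations

* The divergence call is pointwise, not a profile-level multivariate test;
  genes whose profiles differ only in ways invisible to any single time
  point (e.g. pure autocorrelation changes) are not detected.
* Correlation p-values on 7-point profiles have 5 df; with thresholds as
  strict as $p < 10^{-4}$ the implied correlation bound ($\approx 0.985$)
  is stricter than the headline $r > 0.96$.
* The TF imputation rule (per-accession unanimity at a fixed correlation
  threshold) is a reconstruction of the class of concordance algorithms;
  its chance-probability estimate is reported per edge precisely so that
  users can judge imputed regulators quantitatively.
* CPM-based SEPs inherit CPM's compositional nature; the count tests are
  composition-robust, the profiles themselves are not.

# A worked sketch

```{r example, eval = FALSE}
spec <- sim_spec(n_genes = 2000,
                 archetypes = plant_archetypes(2000, n_d10w30 = 200),
                 seed = 42)
design <- build_design(spec)              # 140 libraries
counts <- simulate_counts(design, make_archetype_curves(spec), spec)
profiles <- compute_profiles(counts, design)

div <- classify_divergence(profiles, fdr = 0.01)
distinct <- div$calls$gene[div$calls$call == "distinct"]
hits <- detect_peak_pattern(profiles, peak_pattern(10, 30),
                            genes = distinct)
peak_time_summary(profiles, hits)$difference  # close to -20 DAA
```
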