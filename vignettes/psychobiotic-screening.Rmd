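---
title: "Screening longitudinal multi-omics data for mood-associated gut microbes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening longitudinal multi-omics data for mood-associated gut microbes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(psychoscreen)
library(dplyr)
```

## The problem

Small closed cohorts — isolation facilities, space-analog habitats, long
expeditions — pair repeated mood questionnaires with repeated stool
sampling. The question is which gut taxa (or microbial gene families,
protein groups, metabolites) *track* mood over time within such a cohort:
candidate psychobiotics. The statistical obstacles are that the cohort is
tiny (around eight subjects), the series per subject are short (around
a dozen timepoints), the feature table is high-dimensional and
compositional, and the mood panel is itself a correlated battery of 19
scores — eight POMS factors (including the Total Mood Disturbance summary)
and eleven SCL-90 scores (ten symptom factors plus the SUM-SCL total). Two
factors, Vigour-activity and Self-esteem, score in the positive direction;
the other seventeen measure symptom burden.

`psychoscreen` implements that screening pipeline end to end, together with
a synthetic cohort generator whose ground truth lets every stage be
calibrated: sensitivity on planted signal taxa and false-positive rate on
null cohorts.

## Pipeline and model assumptions

### Normalization

Feature tables are normalized per feature: $x' = \log_2(x + c) \,/\,
|\overline{\log_2(x + c)}|$, i.e. a log transform followed by a quotient
against the feature's across-sample mean log value. The pseudocount $c$
defaults to half the smallest nonzero value of the matrix (standard
compositional practice); a fixed pseudocount, including 0 for strictly
positive data, is available.

Two deliberate numerical choices:

* **Log first, then quotient** (default). The quotient of raw compositional
  values is already scale-free, so dividing the *log* values by their mean
  is what puts species, KO, protein-group and metabolite features on one
  comparable scale. The opposite order, $\log_2(x/\bar{x})$, is available
  via `log_first = FALSE` for users who prefer a plain centered log.
* **The quotient divides by the absolute mean.** Relative abundances are
  below 1, so their log values — and their mean — are negative. Dividing by
  a negative mean is a *decreasing* transform: it would silently flip the
  sign of every downstream correlation and invert the positive/negative
  mood classification. Dividing by $|\bar{\ell}|$ preserves each feature's
  orientation and is identical to the plain quotient whenever the mean log
  is positive (e.g. LFQ intensities). A feature whose mean log is exactly 0
  is divided by 1.

Sparse matrices (protein groups especially) should first pass
`filter_prevalence()`: a feature is kept only when detected in at least
half (configurable) of the samples of *every* subject group — a
conjunction, not an average, so a feature riding on one subject cannot
survive.

### Stationarity gate

Correlating two time series is only meaningful if both are roughly
stationary; a shared trend manufactures correlation. Before screening, each
(subject, variable) series can be assessed with `assess_stationarity()`:
the sample autocorrelation function at lags $1..L$ (default $L = \min(10,
\lfloor n/2 \rfloor - 1)$) must stay inside the white-noise band $\pm
z_{1-\alpha/2}/\sqrt{n}$, and the Ljung–Box statistic

$$Q = n(n+2) \sum_{k=1}^{h} \frac{r_k^2}{n-k} \sim \chi^2_h$$

must be non-significant at $\alpha = 0.05$. Both the band (the "blue
lines" of a standard ACF plot) and $\alpha$ are conventions; series are
never pooled across subjects, and series shorter than four points are
reported as `insufficient` rather than judged. Sampling days are treated as
an ordered, equally spaced index even when real collection days are
irregular — the day index is kept in the metadata for the user, but the ACF
is computed on the plain series.

### Ordination and group structure

`pca_ordination()` (centered, unscaled SVD) plus `manova_groups()` describe
the dominant cohort structure — individual and gender differences. MANOVA
uses Wilks' $\Lambda = \det(W)/\det(W+B)$ on the score columns; the
default p-value is Bartlett's chi-square approximation
$-(n-1-(k+g)/2)\log\Lambda \sim \chi^2_{k(g-1)}$, with Rao's F transform
(`p_approx = "rao"`, exact for $k \le 2$ or $g \le 2$; it reduces to the
univariate F test at $k = 1$) as the alternative. Group separation is
summarized by Mahalanobis distances between group means under the pooled
within-group covariance and a reproducible average-linkage dendrogram
(labels sorted lexicographically before clustering so ties always merge in
the same order). The number of score dimensions fed to MANOVA is the
user's choice (default `k = 2`, matching the 2-D ordination plots usually
inspected alongside); sensitivity to `k` is worth reporting when group
sizes are small, because pooled covariance estimation degrades quickly.

### PLS with leave-one-out evaluation

The engine is single-response NIPALS PLS (PLS1) — one model per mood
factor, never a joint PLS2, so each factor's predictability is evaluated on
its own terms. Predictors are centered and, by default, autoscaled to unit
variance — the standard choice for VIP-based screening, where features of
very different dynamic range must compete fairly. Each leave-one-out fold
recomputes centering and scaling on its training part; scaling on the full
data before cross-validation is a leakage that flatters Q².

Model size $A$ is chosen per response by maximizing leave-one-out
$Q^2 = 1 - \mathrm{PRESS}/\sum(y-\bar y)^2$ over $1..A_{\max}$ (default
$A_{\max} = \min(10, n-2, p)$), with one refinement: the selected $A$ is
the *smallest* within 0.01 of the best Q². Beyond the true latent
dimension the Q² path is flat to within sampling noise, so a literal argmax
lands essentially at random along the plateau; the near-tie rule restores
parsimony and leaves genuine ties resolving toward fewer components.

Feature importance uses Wold's VIP,

$$\mathrm{VIP}_j = \sqrt{ p \sum_a SS_a \, (w_{ja}/\lVert w_a \rVert)^2
\Big/ \sum_a SS_a }, \qquad SS_a = q_a^2 \, t_a^\top t_a ,$$

whose squares average to 1 across the $p$ predictors, making VIP $\ge 1$ a
natural "more than its share" cutoff.

Spearman correlation is the Pearson correlation of midranks; its two-sided
P-value comes from the usual t approximation, or from full enumeration of
all $n!$ orderings for $n \le 8$ (`p_method = "exact_perm"`). Which method
produced a reported P is recorded in the run configuration because at
small $n$ they can differ by a few percent.

### The two-stage screen

`screen_features()` applies the selection rule:

1. **VIP vote.** A feature is *key* if VIP $\ge 1$ in strictly more than
   50% of the factors. "More than 50%" is read strictly: with 19 factors a
   feature needs at least 10 votes; 9 is not enough.
2. **Correlation vote.** Key features are tested factor-by-factor:
   $|R| \ge 0.5$ with $P < 0.001$ (the protein-group variant lowers the
   magnitude cutoff to $|R| \ge 0.35$), again in strictly more than 50% of
   the factors, makes a *candidate*.
3. **Sign consistency.** A candidate is `positive_mood_associated` when it
   correlates positively ($P < 0.05$) with *every* positive-polarity factor
   and negatively ($P < 0.05$) with a strict majority of the seventeen
   negative-polarity ones; mirror-image for `negative_mood_associated`;
   anything else is `inconsistent`. Unanimity over all seventeen negative
   factors would be stricter than the evidence usually supports — observed
   significance is rarely uniform across a questionnaire battery — so
   majority is required there, while the two positive factors must both
   agree.

No multiple-testing correction is applied across features or factors: the
vote thresholds themselves are the error control, and the null calibration
below measures what they deliver. Stage 2 is computed only for Stage-1
survivors; since a candidate must pass both votes anyway, restricting the
correlation stage cannot change the candidate set (a property asserted in
the test suite).

The metabolite variant, `screen_metabolites()`, inverts the regression —
metabolites predict each candidate taxon's abundance — and requires VIP
$\ge 1$ in **every** taxon model (a conjunction over typically 4–6 taxa,
not a majority over 19 factors). A user-supplied allowlist (for example a
literature-curated set of nervous-system metabolites) restricts only the
reported table, never the fitting.

## The synthetic cohort

`generate_cohort()` emulates the study conditions the screen assumes:

| parameter | default | meaning |
|---|---|---|
| `n_subjects` | 8 (4 F / 4 M) | closed-cohort size |
| `timepoints_per_subject` | 13 | ~104 samples in total |
| `n_taxa` | 200 | species-level features |
| `n_planted` | 5 | taxa tracking the latent mood state |
| `effect_size` | 1.0 | loading of the state on planted log-abundance |
| `ar_phi` | 0.3 | AR(1) coefficient of the latent state |
| `lambda` | 1.0 | loading of the state on the mood factors |
| `factor_noise_sd` | 0.5 | factor noise, latent scale |
| `taxon_noise_sd` | 0.5 | taxon log-abundance noise |
| `subject_offset_sd` | 0.5 | per-subject, per-taxon offsets |
| `gender_offset_sd` | 0.5 | per-taxon gender effects |

Each subject carries an independent latent mood state $m_t$, a stationary
AR(1) with standard-normal innovations, initialized from its marginal
$N(0, 1/(1-\phi^2))$ — stationary by construction, which is exactly the
property the ACF gate checks. Positive-polarity factors read $+\lambda
m_t$ plus noise, negative ones $-\lambda m_t$; scores are then rescaled to
plausible questionnaire ranges (POMS-like to mean 10, sd 4; SCL-like to
mean 1.5, sd 0.4), which is purely cosmetic since the screen is rank-based
and the PLS autoscales. Taxon log-abundances combine a per-taxon baseline,
per-subject and per-gender offsets (these generate the individual/gender
separation the MANOVA stage detects), the planted effect
$\beta \cdot \mathrm{sign} \cdot m_t$, and noise; per-sample closure to the
simplex gives a logistic-normal composition. The noise scales are the
package's choice of a realistic regime — planted taxa end up with pooled
$|R| \approx 0.7$–0.85 against the factors, comfortably but not trivially
above the 0.5 screening cutoff.

What the generator deliberately does **not** model: taxon–taxon
interactions and blooms, diet shifts, sequencing depth and zero-inflation,
irregular sampling days, and any real questionnaire discreteness. Passing
tests on these cohorts therefore demonstrate that the screening *logic*
recovers planted monotone associations at realistic noise under the
stationarity structure it assumes — not that the pipeline is robust to
compositional artifacts or confounding in real data.

`make_null_cohort()` zeroes all planted loadings, keeping everything else
(including the RNG stream) identical: the false-positive calibration runs
on data whose only difference is the absence of signal.

## A worked run

```{r, message = FALSE}
cohort <- generate_cohort(cohort_config(seed = 1))
normalized <- normalize_abundance(cohort$abundance)
screen <- screen_features(normalized, cohort$panel, run_config())
glance(screen)
candidates(screen)
cohort$truth$planted
```

All five planted taxa come back as `positive_mood_associated` candidates
and nothing else does. The per-factor evaluation table (the analogue of a
per-questionnaire prediction summary: chosen components, Q², Spearman R/P
of held-out predictions) is in `screen$factors`.

```{r}
head(screen$factors)
```

## Numerical and degenerate-input policies

* All-zero features abort normalization with a pointer to
  `filter_prevalence()`; zero-variance features abort a scaled PLS fit by
  name. Inside a LOO fold, a feature that loses its variance is dropped for
  that fold (its scaled column is zero) and a message is emitted.
* Zero-variance mood factors are excluded from the vote denominator and
  logged, so votes are always out of the number of informative factors.
* NIPALS stops early when no covariance is left ($\lVert X^\top y \rVert <
  10^{-12}$); the model then has fewer components than requested.
* Constant series make the ACF (and Spearman) undefined and raise errors at
  the single-series level; the panel-level assessment converts them to
  `insufficient` status instead of failing a whole run.
* Mahalanobis distances require a non-singular pooled covariance
  (reciprocal condition number above $10^{-12}$); the error suggests
  reducing `k`.

## Problem sizes used in the tests

The test-suite calibrations use: 50 default cohorts (8 × 13 samples, 200
taxa, 5 planted) for recovery and 50 for the null; 2,000 white-noise series
of length 50 for the Ljung–Box size; 1,000 two-group replicates for the
MANOVA size; exhaustive 720-permutation enumeration for the exact Spearman
oracle at $n = 6$. These sizes give Monte-Carlo standard errors a factor of
~3 below the tolerances they are checked against.

## Known limitations

* The screen is correlational; sign-consistent candidates are candidates,
  not causal psychobiotics.
* Thresholds (VIP ≥ 1, |R| ≥ 0.5 or 0.35, P < 0.001, >50% votes) are
  conventions inherited from the screening tradition this package
  implements, not optimized quantities; `run_config()` exposes all of them,
  and `rescreen()` re-applies stricter ones without refitting.
* With eight subjects, the per-subject stationarity tests at 12–13
  timepoints have modest power; "stationary" means "no detectable
  autocorrelation at this length", not stationarity in any strong sense.
* Mood scores enter the PLS unnormalized by default
  (`normalize_panel = FALSE`); whether to transform the response like the
  features is left to the user since ranks (and hence the screen) are
  unaffected, only Q²/RMSECV units change.
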