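---
title: "Rank-based lncRNA-pair risk models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based lncRNA-pair risk models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reopair)
```

## The model

`reopair` builds prognostic classifiers for hepatocellular carcinoma
from **relative expression orderings** (REOs). A pair of lncRNAs
(*a*, *b*) contributes one binary covariate per sample,
$X_{ij} = \mathbf{1}\{\mathrm{expr}_j(a) < \mathrm{expr}_j(b)\}$, with
ties assigned to the $\ge$ state (0), deterministically — no random
tie-breaking. Because $X$ depends only on the within-sample ranking of
two transcripts, it is invariant to any strictly monotone per-sample
transform: TPM versus counts-per-million, log transforms, quantile
shifts. The price is a loss of magnitude information; the gain is that a
fitted signature, including its numeric risk threshold, transfers to a
single new sample without renormalisation.

Risk is modelled by a Cox proportional-hazards linear predictor over the
signature pairs, $\mathrm{score}_j = \sum_i \beta_i X_{ij}$, and samples
are classified high-risk when the score reaches a threshold chosen by
the Youden index on the 5-year time-dependent ROC of the training set.

## Pipeline stages and the choices behind them

**Sample and transcript filters.** Samples with follow-up under 30 days
or missing survival are removed; the boundary (exactly 30 days) is
retained, since the rule removes "less than 30 days". mRNAs below 1
count and lncRNAs below 0.5 counts *in every sample* are excluded — a
single sample above threshold rescues a transcript. These thresholds are
applied to raw counts (the natural reading; normalised values have no
absolute count scale). miRNAs with zeros in strictly more than half the
samples are dropped before RPM normalisation; zeros in exactly half is
tolerated.

**Train/validation split.** A simple seeded random split. Stratification
is deliberately not applied; instead a post-hoc balance report
(rank-sum for numeric, chi-square for categorical covariates) documents
between-arm comparability, flagging degenerate covariates rather than
testing them.

**Clustering scale.** Samples are clustered on the pyroptosis panel by
Ward linkage (`ward.D2`, so Euclidean distances are treated in the
classical minimum-variance sense) over per-gene z-scored
$\log_2(\mathrm{TPM}+1)$ values — the conventional heatmap setup. The
feature scale for clustering is a genuinely open choice; z-scoring makes
the clusters reflect profile shape rather than absolute abundance.
Cluster labels are identifiable: label 1 is the larger cluster.

**Differential expression.** The two-group moderated t is computed by
limma (`lmFit`/`eBayes`), the field-standard implementation of
empirical-Bayes variance shrinkage, with BH correction. The contrast is
cluster 1 minus cluster 2 under the size-ranked labelling. Selection
uses strict inequalities: $|\log_2 FC| > 1$ and $FDR < 0.05$; a gene at
exactly $\log_2 FC = 1$ is excluded.

**Pair screening.** All $\binom{k}{2}$ pairs are formed in canonical
lexicographic orientation. The prevalence filter keeps pairs whose
REO-1 fraction lies in $[0.20, 0.80]$ — boundaries retained, strict
removal outside — because near-constant pairs carry no within-cohort
reversal information. Each surviving pair is screened by univariate Cox
regression on its binary state (Breslow tie handling; Efron available),
kept at Wald $p < 0.005$. No multiplicity correction is applied at this
stage by design: the raw 0.005 cut is the screening rule. With five
pairs driving the hazard simultaneously, each pair's *marginal*
univariate effect is attenuated by the omitted others (Cox
non-collapsibility), so per-pair retention, not joint all-pair
retention, is the calibrated quantity in our tests.

**Signature selection.** LASSO-Cox over a log-spaced penalty grid with
tenfold cross-validated partial-likelihood deviance; the
deviance-minimal $\lambda$ defines the candidate set. Binary covariates
are standardized internally during fitting and coefficients reported on
the 0/1 scale. Fold assignment is seeded and recorded. If the optimal
$\lambda$ keeps nothing, the closest $\lambda$ with a nonzero
coefficient is used with a warning. The candidates are then refined by
bidirectional stepwise search (via `MASS::stepAIC`) starting from the
full candidate model, minimising $AIC = -2\log PL + 2|{\rm terms}|$ on
the Cox partial likelihood; the search direction is an open choice and
bidirectional-from-full mirrors the common default. Note AIC retains a
pure-noise term whenever its Wald chi-square exceeds 2 (probability
$\approx 0.16$), so occasional noise terms in the final model are
expected behaviour, not a defect.

**Pair orientation.** Enumeration canonicalises pairs alphabetically,
but a fitted or published model stores its own orientation ("a|b" means
$X=1 \iff a<b$), and `compute_risk_scores()` honours the stored
orientation — flipping a pair flips $X \to 1-X$ and $\beta \to -\beta$
without changing predictions. The published 11-pair signature is stored
exactly as printed, first-listed lncRNA as the *a* member, threshold
0.025, 5-year horizon.

**Time-dependent ROC.** Cumulative cases / dynamic controls at horizon
$t$ (1, 3 or 5 years at 365.25 days/year): cases have an event by $t$,
controls survive past $t$. Censoring before the horizon is handled by
the Kaplan–Meier estimator within marker strata (default), following
the classic cumulative/dynamic construction: with
$S_c(t)$ the KM survival among $\{M \ge c\}$ and $p_c = P(M \ge c)$,
$TP(c) = (1-S_c(t))\,p_c / (1-S(t))$ and $FP(c) = S_c(t)\,p_c / S(t)$.
A nearest-neighbour variant (span $0.25\,n^{-0.20}$ on the marker
percentile scale, Akritas-type weighted KM) is available via
`estimator = "NNE"`. The raw KM curve need not be monotone; an isotonic
cleanup is applied *only* for curve reporting, while the AUC and the
Youden search use the raw estimates. The AUC is the signed trapezoid
along the cutoff-ordered path anchored at (0,0) and (1,1); with no
censoring before the horizon this reduces exactly to the Mann–Whitney
statistic, which our tests verify against a pairwise oracle. Youden
ties are broken toward the smaller (more sensitive) cutoff, and the
threshold boundary itself classifies high-risk.

**Multivariate Cox coding.** Age enters continuously (years), gender
with reference `female`, and stage/grade are collapsed to early/late
binaries (I–II vs III–IV, G1–G2 vs G3–G4) by default — the exact
sub-level coding is unstated in common practice and collapsing keeps
event-per-covariate ratios healthy; `collapse_stage = FALSE` keeps full
factors. Collinear covariates are dropped with a warning naming them.

**Downstream.** The overlap test is the exact upper-tail hypergeometric
$P(X \ge k)$ — one-sided enrichment. ceRNA axes are assembled purely
from user-supplied edge tables (database exports), keeping the module
hermetic; candidate miRNA and mRNA nodes are tested by univariate Cox on
continuous $\log_2(\mathrm{expr}+1)$ at $\alpha = 0.05$ (the node-level
rule and covariate coding are open choices documented here).

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the pipeline
assumes, not any particular real dataset:

- two latent subtypes (minority fraction defaults to 35/240) with panel
  genes shifted by $\ge 2.5\sigma$ between subtypes, so Ward clustering
  is recoverable;
- a block of subtype-differential lncRNAs with $|\log_2 FC| \in
  [1.3, 2.5]$ (default 104 of them, mirroring the cohort scale the
  pipeline targets);
- planted prognostic pairs: each pair's latent state $Z \sim
  \mathrm{Bern}(p)$ with $p$ drawn from the configured prevalence range
  (default (0.3, 0.7)); the two members share a common centre (including
  a *shared* subtype shift, so pair members remain differential without
  their effects cancelling) and are separated by a guaranteed margin
  $\ge 3\sigma$, which makes the REO recomputed from expression equal
  $Z$ exactly, with no ties;
- survival from an exponential proportional-hazards model with linear
  predictor $\sum_i \beta_i Z_i$ (defaults $\beta = (1.2, -1.2, 1.0,
  -1.0, 1.5)$), baseline hazard $10^{-4}$/day; uniform censoring on
  $(0, T_{\max})$ with $T_{\max}$ solved numerically for the requested
  censor rate (default 60%). The baseline scale is chosen so that the
  calibrated censoring horizon ($T_{\max} \approx 1.3/\bar\lambda$)
  extends well past the 5-year ROC horizon the pipeline thresholds on —
  with a much higher baseline hazard no subject remains at risk at 5
  years and the ROC is degenerate;
- a configurable fraction (default 7.5%) of samples with follow-up under
  30 days or missing survival, exercising the preprocessing filter;
- clinical covariates (age, gender, stage, grade) drawn independently of
  the hazard, so the risk score should, and in tests does, remain the
  only independent prognostic factor.

What the generator does **not** emulate: TCGA marginal abundance
distributions, library-size or batch effects, correlated co-expression
modules, or clinical covariates that truly affect hazard. Passing
recovery tests therefore demonstrates the pipeline's statistical
correctness under its own assumptions, not performance on real tumours.

## Numerical and degenerate-input conventions

- Ties in REO construction always map to state 0; no randomness.
- `censor_rate = 0` disables censoring ($T_{\max} = \infty$).
- Log-abundance matrices are kept non-negative by a global
  order-preserving shift, leaving REOs and log-fold-changes untouched.
- Zero-variance panel genes are excluded from z-scoring with a warning;
  a constant pair covariate is flagged `constant covariate` and skipped
  by the screen rather than aborting it; an all-censored cohort is a
  hard error.
- Problem sizes in the test-suite simulations (typically 8–20 seeds,
  cohorts of 120–400 samples, 50–200 lncRNAs) were chosen as the
  smallest sizes at which the tested effects are statistically
  unambiguous.

## Known limitations

- The REO matrix is materialised densely; beyond a few thousand lncRNAs
  (~millions of pairs) screening should be chunked by the caller.
- AIC-based stepwise search finds a local optimum; our tests compare it
  against exhaustive subset search on small instances (it attains the
  global optimum in most random instances, and never worsens the
  starting AIC).
- The NNE ROC estimator is provided for completeness; the KM estimator
  is the default and the one used for thresholding.
- `published_model()` reproduces the printed signature for scoring and
  classification; its coefficients cannot be re-derived here because the
  originating cohort is not shipped.
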