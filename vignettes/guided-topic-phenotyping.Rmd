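---
title: "Seed-and-guided topic modelling of multi-modal EHR data"
author: "sagehr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-and-guided topic modelling of multi-modal EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagehr)
```

## The phenotyping problem

Electronic health records describe each patient through co-occurring coded
observations — ICD diagnoses, medication (ATC) codes, surgical procedure
(OPCS) codes. Treating each patient's record as a *document* and each code
as a *word*, a topic model summarizes these co-occurrences as a small set of
latent *phenotype topics*, and each patient's topic mixture
$\theta_d \in \Delta^{K-1}$ becomes a continuous disease score usable for
risk ranking or as a quantitative trait in genetic association studies.

Plain topic models produce topics that need post hoc interpretation.
`sagehr` instead anchors every topic to a PheCode — a curated grouping of
ICD codes used in phenome-wide association studies — in two complementary
ways:

1. **Guided priors.** Patients with many codes mapping to a PheCode get a
   larger Dirichlet prior weight $\alpha_{dk}$ on that topic, via a
   per-phenotype two-component Gaussian mixture fit to PheCode counts.
2. **Seed topics.** In the guided (diagnosis) modality each topic $k$ owns
   two word distributions: a *seed* distribution $\phi^s_k$ supported only
   on the PheCode's mapped codes $V_k$, and a *regular* distribution
   $\phi^r_k$ over the whole vocabulary. A guided token is drawn from the
   seed distribution with probability $\pi_k$ (the *seed rate*, learned)
   and from the regular one otherwise. Unguided modalities (medications,
   procedures) carry regular distributions only, but still share the
   patient mixture $\theta_d$ and therefore inherit phenotype anchoring.

## Model and inference

For patient $d$ with prior row $\alpha_d$:
$\theta_d \sim \mathrm{Dir}(\alpha_d)$; for each token $i$ in modality $m$,
$z_{di} \sim \mathrm{Cat}(\theta_d)$ and, for the guided modality,
$x_{di} \sim \mathrm{Bern}(\pi_{z_{di}})$ selects the seed vs regular
channel. Inference is zeroth-order collapsed variational Bayes (CVB0):
topic mixtures and topic-word distributions are integrated out, and the
token-level responsibilities are updated from expected counts. For a
guided token of code $w$ the joint responsibility over $(k, x)$ is

$$
r(k,1) \propto (m_{dk}^{-i} + \alpha_{dk})\,\pi_k\,
  \frac{s_{wk}+\mu}{s_{\cdot k}+\mu V_k} \,[w \in V_k],\qquad
r(k,0) \propto (m_{dk}^{-i} + \alpha_{dk})(1-\pi_k)
  \frac{n_{wk}+\beta}{n_{\cdot k}+\beta V},
$$

where $m_{dk}$, $n_{wk}$, $s_{wk}$ are expected document-topic, regular and
seed counts and the superscript $-i$ removes the current token's own mass
(the CVB0 zeroth-order approximation). Unguided tokens use the regular
factor only. After convergence the expected distributions are

$$
\hat\theta_{dk} = \frac{m_{dk}+\alpha_{dk}}{m_{d\cdot}+\sum_k\alpha_{dk}},
\quad
\hat\phi^{r(m)}_{wk} = \frac{n^{(m)}_{wk}+\beta}{n^{(m)}_{\cdot k}+\beta V^{(m)}},
\quad
\hat\phi^{s}_{wk} = \frac{s_{wk}+\mu}{s_{\cdot k}+\mu V_k}.
$$

Within a document, identical codes share one responsibility vector weighted
by their count: tokens are exchangeable under the model, so this changes
nothing in expectation and removes the dependence on record length. The
engine sweeps all token groups jointly (a Jacobi-style update) `n_inner`
times per document per epoch; for single-token documents the responsibility
equals the exact collapsed posterior regardless of sweep order, which the
test suite exploits as an oracle.

**Stochastic updates.** Global expected counts are updated from mini-batches
(default 1000 documents) by
$n \leftarrow (1-\rho_t)\,n + \rho_t \frac{D}{|B|}\hat n_B$ with step size
$\rho_t = (\tau_0+t)^{-\kappa}$, $\tau_0 = 1$, $\kappa = 0.7$. When the
batch covers the corpus the step size is 1 and training is exactly
full-batch variational EM — the regime used throughout the tests, where
token mass is conserved exactly: $\sum_{w,k} n^{(m)}_{wk}$ (plus seed
counts for the guided modality) equals the modality's token total.

**Seed rates.** $\pi_k$ is a Beta($a$=1, $b$=1) posterior mean over the
expected seed vs regular guided assignments,
$\pi_k = (s_{\cdot k}+a)/(s_{\cdot k}+n^{(g)}_{\cdot k}+a+b)$, recomputed
after every global update; it is initialized at 0.7. The published
formulation gives the Bernoulli likelihood but not the estimator; the
conjugate smoothed mean is the natural choice and keeps $\pi_k$ in (0,1).

**Initialization.** Regular counts start at uniform jitter
$\mathrm{U}(0, 0.01)$ (tie-breaking); seed counts start at 1.0 on every
(seed code, topic) pair — an indicator-presence pre-assignment rather than
raw counts, chosen because it makes initialization independent of cohort
composition. This informative start is what keeps topic $k$ identified with
its PheCode: topics are anchored, not exchangeable, and permuting seed-set
labels permutes the recovered topics identically.

## The mixture-model prior

For each topic, patients' seed-code counts are transformed as
$x = \log(1+\text{count})$ (counts are heavy-tailed; the raw-count option
remains available via `transform = "raw"`) and a two-component 1-D Gaussian
mixture is fit by EM: deterministic initialization from the 10th/90th
percentiles, variance floor $10^{-6}$, at most 500 iterations, tolerance
$10^{-8}$ on the log-likelihood. The larger-mean component is the
"phenotype-active" regime and

$$\alpha_{dk} = 0.01 + 1.0 \cdot P(\text{active} \mid x_{dk}).$$

The affine map (floor 0.01, scale 1.0) keeps the Dirichlet proper while
concentrating prior mass on phenotypes the patient's record flags; the
responsibilities are not normalized across topics, so one patient can carry
strong priors for several phenotypes. Degenerate columns (constant counts
or EM collapse) fall back to the floor and are flagged. The prior is fit
per phenotype across patients, is fully deterministic, and is **held fixed
during training** — re-estimating it would let topics drift away from their
PheCodes.

Note that the two-component posterior is monotone in the count only when
the active component's variance does not reverse the tail ordering; the
corresponding property test checks the derivative of the quadratic
log-odds at the observed range boundaries before asserting monotonicity.

## Calibrated phenotype scores

The model's expected patient-by-code matrix is
$\tilde y = \theta\,\phi$ with
$\phi_{kj} = \pi_k \phi^s_{kj}[j \in V_k] + (1-\pi_k)\phi^r_{kj}$ — the
model's actual marginal word distribution per topic (a regular-only variant
is available via `mixture = "regular"`). Because $\tilde y$ rows are
probabilities over 100+ codes, individual entries are numerically tiny; to
make them comparable with binary phenotypes each code $j$ is rescaled by a
one-feature logistic regression of the observed indicator $y_{dj}$ on
$\tilde y_{dj}$, fit by IRLS on the cross-entropy loss:
$\hat y_{dj} = \sigma(\beta^*_j \tilde y_{dj} + b^*_j)$. In one dimension
separability is exactly the non-overlap of case and control feature
ranges; such fits get the slope clamped at $|\beta| \le 30$ (intercept
refit at the clamped slope) and an unconverged flag, preserving the plain
maximum-likelihood form everywhere else. A positive slope makes the
calibration strictly monotone, so within-code patient ranking is never
changed.

Codes aggregate onto PheCodes by noisy-OR,
$1-\prod_{j \mapsto k}(1-\hat y_{dj})$ — PheCode semantics are "any
constituent diagnosis", and the independence-OR uses every mapped code
while staying in [0,1]; `rule = "max"` is available. The *expected sample
size* of a PheCode is its score column sum, a continuous analogue of a case
count used to threshold the PLINK quantitative-trait export. Both
probability and logit scales can be exported, since downstream linear-model
users may prefer either.

## Evaluation utilities

* **Topic purity**: share of a topic's top-5 guided codes in the modal
  ICD-10 organ-system chapter (ties broken by vocabulary order; unmapped
  codes leave the denominator and are counted). The chapter table (letter
  plus two-digit block) ships with the package.
* **Phenotype similarity / comorbidity**: Pearson correlations between
  topic-word rows and between patient-mixture columns; zero-variance rows
  are flagged and set to 0.
* **Precision at K** for incident-diagnosis ranking: prevalent cases of the
  target leave the pool (they cannot become incident), non-cases carrying a
  control-exclusion PheCode leave the pool, ties break by patient index,
  and the incident prevalence of the eligible pool is reported as the
  random baseline. Dates follow a half-open convention: events strictly
  before baseline are prevalent; an event on or after baseline with no
  prior record is incident.

## The simulator, and what passing tests do and do not show

`simulate_corpus()` draws from the generative process above with planted
ground truth. Defaults define the package's reference study conditions:
2000 patients, 5 topics, 3 modalities with vocabularies (100, 60, 60) and
token shares (0.5, 0.25, 0.25), 4 disjoint seed codes per topic, seed rates
uniform in [0.6, 0.9], Dirichlet concentration 0.1 for regular topics
(sparse, well-separated), negative-binomial document lengths (mean 60,
dispersion 5), per-topic active probability 0.15 with Dirichlet boost 5
over a base of 0.1. Guided codes are synthetic ICD-10-like strings whose
seed codes share a chapter letter per topic, so purity has a planted
signal. Event simulation gives each patient one baseline date; prevalent
and incident probabilities increase linearly in the true topic weight
(saturating at `theta_ref = 0.5`), with incident hazard 0.5.

These conditions are deliberately favourable: topics are sparse and well
separated, seed sets are disjoint and exactly known, counts follow the
model family, and there is no coding drift, censoring, or site effect.
Passing recovery tests therefore demonstrates the *correctness of the
inference machinery* — not that real EHR corpora are this easy. Conversely,
the simulator makes no attempt to mimic real ICD-10 frequencies or
semantics.

At these sizes a full 50-epoch full-batch fit takes a few seconds on one
core, which is why the test suite and the acceptance script can rerun the
whole pipeline from scratch.

## Numerical choices and degenerate inputs

* Responsibilities are floored at $10^{-300}$ before normalization;
  log-space arithmetic is unnecessary at these scales. An all-zero
  responsibility row is impossible unless $\alpha$, $\beta$ or $\mu$ is
  misconfigured to 0, and raises an error.
* Topics with empty seed sets get an all-zero $\phi^s$ row and are flagged;
  the seed-likelihood denominator guard keeps them out of the responsibility
  computation.
* Patients with zero tokens (possible after vocabulary filtering) are
  retained with prior-only $\theta_d = \alpha_d / \sum_k \alpha_{dk}$, so
  score matrices keep a fixed patient axis.
* Held-out likelihood uses document completion: a binomial token split
  (seeded, reproducible) folds in half the tokens and scores the rest under
  the per-topic marginal word distribution; per-token normalization makes
  the measure invariant to duplicating a held-out record.
* Hyperparameter search returns the grid argmin of validation NLL with
  exact ties broken toward larger smoothing (more regularization at equal
  fit).
* All randomness flows from explicit integer seeds; refitting with the same
  seed is bit-identical, and the pipeline derives per-stage seeds from the
  run seed by hashing the stage name.

## Design decisions that were genuinely open

* **CVB0** was chosen as the concrete collapsed variational scheme: it
  matches the expected-count form of the posterior expectations above and
  is the standard choice for seeded topic models. First-order CVB
  corrections are isolated behind the update functions should they ever be
  wanted.
* **The prior-responsibility-to-$\alpha$ map** is affine rather than
  normalized across topics (the normalized variant would force every
  patient's prior mass to sum to the same constant, erasing differences in
  record richness).
* **Repeated hospitalizations** contribute repeated tokens: counts are
  taken as given, not deduplicated per patient.
* **Seed pre-assignment** uses indicator presence, not raw counts (see
  Initialization above).
* The interface is the classic R modelling idiom — `sage()` returns a
  classed object with `print`, `summary`, `coef` and `predict` methods —
  with a YAML-driven `run_pipeline()` and a thin Rscript wrapper
  (`inst/scripts/sagehr.R`) for shell use.

## Known limitations

* $K$ is the number of retained PheCodes; there are no additional unguided
  "discovery" topics, so novel phenotype clusters outside the PheCode
  vocabulary will fold into regular distributions of existing topics.
* The calibration treats codes independently; correlated codes within a
  PheCode make the noisy-OR an upper-bound-flavoured aggregate.
* CVB0 lacks a strict ELBO guarantee; the practical convergence of
  validation NLL is asserted as a trend (tolerance $10^{-3}$ per token
  after epoch 3 across seeds), not as a theorem.
* The GWAS stages themselves (association testing, clumping, locus
  annotation) are out of scope; the package stops at the quantitative-trait
  export.
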