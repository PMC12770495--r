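---
title: "Cost-benefit models of naturalistic helping decisions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-benefit models of naturalistic helping decisions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(helpcb)
```

This vignette is the package's own account of the models and procedures it
implements, the assumptions behind them, the tunable parameters that matter,
what the synthetic-data generator does and does not emulate, and the design
choices made where the design was genuinely open. No empirical claim is made
here beyond what the test suite and `scripts/acceptance.R` compute.

## 1. The decision model

A participant facing scenario $s$ is assumed to compute a utility of helping
$U_s$ and to choose probabilistically through a softmax,

$$P(\text{help}\mid s) = \frac{1}{1 + e^{-\beta U_s}},\qquad \beta\in(0,10],$$

where the inverse temperature $\beta$ controls decision noise: $\beta\to 0$
gives coin-flipping, large $\beta$ nearly deterministic choice. Seven
candidate forms of $U_s$ are implemented (`model_spec()`, `utility()`),
ranging from a scenario-independent disposition ($U=b$, model 1.0) through
the single-weight cost–benefit tradeoff

$$U_s = -w_{cost}\,C_s + (1-w_{cost})\,B_s + b,\qquad w_{cost}\in[0,1],$$

(model 2.0) to variants with independent weights (3.0), a power transform on
cost or benefit (2.1, 2.2, exponent $\alpha$), a cost-by-benefit interaction
(2.3, weight $w_{cb}$), and a binary urgency bonus (2.4, weight $w_u$).
Models 2.1 ($\alpha=1$), 2.3 ($w_{cb}=0$) and 2.4 ($w_u=0$) all reduce
exactly to 2.0; these nesting identities are asserted in the test suite.

$C_s$ and $B_s$ are the min–max-normalized cost and benefit factor scores
(section 3), so both live on $[0,1]$ and the utility scale is comparable
across studies. The key assumptions are: a common $C_s,B_s$ for all
participants (consensus ratings stand in for individual perception), and
trial independence given the parameters.

### Parameter bounds and numerics

* $\beta\in(10^{-6},10]$: the lower bound keeps the likelihood defined; the
  upper bound is where choice curves are already effectively step functions.
* $b\in[-10,10]$: with $\beta\le 10$ and $|U|$ of order 1, biases beyond
  $\pm10$ are behaviourally indistinguishable; the box keeps the optimizer
  stable. $\alpha\in(0,10]$, $w_{cb}\in[-5,5]$, $w_u\in[0,5]$ are wide
  relative to the $[0,1]$ input scale.
* Choice probabilities are clipped at $10^{-12}$ inside the likelihood so
  complete separation (an all-help participant) yields a finite objective.
* Fitting (`fit_participant()`) runs L-BFGS-B from 10 Latin-hypercube starts
  (`lhs`); ties within $10^{-9}$ in negative log-likelihood are broken by the
  smaller parameter norm. For model 2.0 the likelihood is a reparameterized
  logistic regression, and the test suite checks the fit against `glm()`.
* Pseudo-$R^2$ uses the chance null $n\log 0.5$ rather than a fitted
  bias-only null, so model 1.0 itself has a defined value. AIC $=2k-2LL$,
  BIC $=k\ln n - 2LL$.
* Leave-one-out accuracy refits per held-out trial (the strict reading of
  leave-one-out); a predicted probability of exactly 0.5 counts as "help"
  (the majority class in data of this kind), configurable via `tie=`.

### Identifiability: what parameter recovery can and cannot show

Only the products $\beta w_{cost}$, $\beta(1-w_{cost})$ and $\beta b$ enter
the likelihood (they are the logistic-regression coefficients), so the
natural parameters are identified through the curvature along the
$\beta$-scale ridge. Two consequences, quantified in the package's
acceptance checks with a Cramér–Rao computation and an exact-MLE GLM oracle:

* at 50 binary trials with agents drawn broadly ($\beta\in[1,5]$,
  $b\in[-1,1]$, $w_{cost}\in[0.1,0.9]$) the recovery correlations of a
  perfect estimator are capped near 0.5 for $b$ and 0.35 for $w_{cost}$ —
  $w_{cost}$ is nearly confounded with $b$ because
  $\partial U/\partial w_{cost} = -(C_s+B_s)$ varies little across
  scenarios;
* recovery improves steadily with trials (all correlations exceed 0.8 by
  1000 trials in the self-consistency tests).

`parameter_recovery()` therefore reports per-repetition and pooled
correlations and leaves the interpretation explicit rather than implying
that 50-trial recovery is precise. The default sampling ranges are the broad
ones above.

### The continuous rating model

As a robustness check, `fit_rating_model()` refits a model to the ordinal
WTH codes ($-5..5$): the prediction is $scale\cdot U$ with a positive scaling
factor replacing the softmax, and parameters minimize the mean squared
error. The test suite verifies planted-solution recovery and that its
$w_{cost}$ tracks the decision model's across simulated participants.

## 2. Quality control and consensus

`apply_decision_qc()` implements four participant-level exclusion rules, in
this precedence order (each participant is counted once, under the first
rule that fires — the order follows the order in which the rules are
usually reported, since no canonical precedence exists): (1) $\ge 2$ of 3
failed attention checks; (2) $\ge 2$ of 3 repeated scenarios answered
inconsistently after binarization; (3) straight-lining, SD of all
non-attention ratings $<0.5$ (computed over all rating trials including
repeats); (4) $\ge 10$ scenarios flagged as not understood/imagined.
Surviving participants' flagged trials are dropped and repeats/attention
rows removed.

`apply_rating_qc()` excludes raters with $\ge2$ attention failures, then
drops rater–question pairs whose ratings have SD $<0.1$ across the rater's
scenarios (checked first) or whose mean is more than 3 group-level SDs from
the group mean of rater means (checked second; a pair can satisfy both, and
gets the first label). Pairs with fewer than two ratings are skipped with a
warning because their SD is undefined.

Consensus ratings (`compute_consensus()`) are plain means with rater counts.
Inter-rater reliability (`icc_a_k()`) is the two-way random-effects
absolute-agreement average-measures intraclass correlation,

$$ICC(A,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n},$$

computed from the raters × scenarios ANOVA mean squares. On incomplete
matrices the default uses the complete sub-matrix; `use = "pairwise"`
estimates the mean squares from all available cells via the additive
two-way fit, which is the practical choice for designs where each rater sees
a scenario subset. Full ANOVA-expectation estimation on arbitrary missing
patterns is an extension point, not implemented here.

## 3. Factor structure of the motivation ratings

Twelve of the fifteen motivation questions enter the factor analysis; the
urgency question is treated as a separate environmental variable and the two
summary questions are excluded as redundant (an explicit include-list
enforces this). `parallel_analysis()` retains factors whose correlation-
matrix eigenvalues exceed the rank-wise mean of eigenvalues from simulated
standard-normal data of the same shape; the mean is the common default, a
quantile reference (e.g. 0.95) is available — note that against the mean
reference, pure noise retains a factor with roughly 50% probability per
rank, which is why the package's no-structure tests use the quantile
reference.

`fit_efa()` uses minimum-residual extraction (uniquenesses optimized by
L-BFGS-B, loadings from the reduced correlation matrix's leading
eigenpairs), varimax rotation by default, promax as the oblique robustness
option. Factor signs are fixed so each factor's dominant item loads
positively. Factor scores use the Thurstone regression estimator
$Z R^{-1} L$. An item belongs to the factor on which its absolute loading is
maximal, provided it exceeds 0.3. The reported total variance explained is
the rotated sum of squared loadings over the number of items.

`normalize_scores()` min–max normalizes the benefit and cost scores,
median-splits urgency (strictly above the median = high), and assigns
quadrants (LL/LH/HL/HH by benefit then cost, "high" strictly above the
median).

`motivation_wth_lmm()` fits, per motivation, `WTH ~ 1 + m + (1 + m | sub)`
by REML with lme4 — one model per motivation because the dimensions are
highly collinear — and reports the Nakagawa marginal
($\sigma^2_f/(\sigma^2_f+\sigma^2_r+\sigma^2_e)$) and conditional
($(\sigma^2_f+\sigma^2_r)/(\cdot)$) $R^2$, with the random-slope
contribution averaged over the design rows.

## 4. Representational spaces

The decision space dissimilarity between scenarios $x,y$ is

$$F(S_x,S_y)=\frac{1}{n}\Big[0.5\sum_{i=1}^n |W_{i,x}-W_{i,y}| +
0.5\,\big|\sum_{i=1}^n (W_{i,x}-W_{i,y})\big|\Big]$$

over the $n$ participants who rated both ($W$ = WTH codes); the joint-rater
set is used for both terms. The motivation space uses 2-D Euclidean
distances on (benefit, cost) with per-axis absolute-difference component
RDMs. The semantic space starts from high-dimensional scenario text
embeddings (an input; synthetic embeddings are cluster centroids plus
isotropic noise), takes cosine distances, embeds them in 2-D, and clusters
the plane with Ward agglomerative clustering (12 clusters by default).

Embedding choices: `mds_embed()` is classical (Torgerson) metric scaling —
deterministic, reproduces 2-D-embeddable distance patterns exactly, stress-1
reported. The 2-D semantic embedding likewise uses metric scaling of the
cosine distances; a stochastic neighbour-embedding step is deliberately not
used, keeping the semantic space fully deterministic, at the cost of
preserving global rather than local structure. Cluster recovery on
well-separated synthetic embeddings (adjusted Rand index $\ge0.9$) is part
of the acceptance checks.

`rsa()` correlates upper-triangle vectors and builds the permutation null by
applying one random scenario permutation jointly to the rows and columns of
one RDM — this preserves the RDM's internal structure and randomizes only
the alignment. The p-value is the strict proportion of null correlations
exceeding the observed one; a smoothed $(s+1)/(N+1)$ variant avoids exact
zeros. `decompose_decision_rdm()` splits the decision RDM into a mean-WTH
component and an OLS residual; `rdm_regression()` regresses z-scored upper
triangles (standardized betas) with a collinearity warning at condition
number $>10^8$. Quadrant differences in mean WTH use Welch's ANOVA (unequal
variances are the rule for these quadrants) with an approximate partial
$\eta^2 = F\,df_1/(F\,df_1+df_2)$ and Games-Howell post-hoc comparisons
(studentized range on Welch-Satterthwaite degrees of freedom).

## 5. Individual differences

`correlate()` gives Pearson's r with a two-sided permutation p (comparison
on $|r|$), a percentile bootstrap CI, and Bonferroni adjustment by the
caller's family size (traits and demographics form separate families, 5 and
7 tests). `group_compare()` uses Welch's t (two groups; Levene diagnostic)
or Welch's ANOVA (more groups; Bartlett diagnostic), with a
D'Agostino-Pearson omnibus normality check per group reported alongside —
diagnostics are informative, not gatekeepers, since the permutation and
Welch procedures do not require normality. `trait_effect_grid()`
median-splits each trait (ties to the low group), and computes Cohen's d
(pooled SD) of per-participant mean WTH per scenario category, with optional
bootstrap CIs.

## 6. The synthetic-data generator

`synthetic_config()` defaults encode the emulated study design: 100
scenarios; ~28 raters per scenario, each rating 20 scenarios (raters are
organized in waves that partition the scenario set, so every scenario gets
exactly the configured rater count); 215 agents rating 50 scenarios each;
agents generated from the single-weight model with $\beta\in[1,5]$,
$w_{cost}\in[0.1,0.9]$, $b\in[-1,1]$ uniform.

Scenario latents are independent standard-normal benefit and cost and a
uniform urgency. Ratings are loading-weighted combinations of the latents
plus rater bias (SD 0.3) and noise (SD 0.5), discretized to 1..5. The
default loading matrix puts all eleven benefit-type questions at 0.85 on the
benefit factor and the self-cost question alone at 0.85 on the cost factor;
four affect-laden questions carry secondary 0.45 cost loadings. The
secondary loadings matter: with a strictly single-indicator cost factor the
population eigenvalue of that factor is exactly 1 and no retention rule can
distinguish it from noise, so a generator without cross-loadings would make
the two-factor structure unrecoverable in principle.

Traits are coupled to agent parameters through a Gaussian copula whose
correlation matrix carries the requested parameter–trait correlations
(positive-semi-definiteness checked); parameter marginals are the uniform
ranges, trait marginals questionnaire-like normals. Default couplings: $b$
with agreeableness, empathic concern and social value orientation at 0.3;
$w_{cost}$ with punishment sensitivity at 0.3 and reward responsiveness at
−0.3 — the direction structure the trait hypotheses of this literature
predict. The copula's marginal transforms attenuate a nominal 0.3 to ~0.29
in Pearson terms; the tests account for that.

Binary decisions are Bernoulli draws from the forward model, on the same
normalized scores the analysis later uses. Each agent has its own seed
sub-stream (global seed + fixed offset + agent index) so single agents can
be re-simulated; the test suite replays the stream with an independent
brute-force loop and requires exact agreement. The ordinal WTH level is
derived from the choice probability by fixed equal-probability bins with the
help/not-help boundary at $P=0.5$ (levels 4–6 iff help) — the generative
link between the ordinal scale and the binary decision is not specified by
the modelling framework itself; this binning is a construction that
guarantees consistency with the binary draw and gives the rating model
ordinal data to work with.

`inject_qc_violations()` plants rule violations (straight-liners, attention
failures, inconsistent repeats, imagination flags, low-variability and
outlier rater-questions) and returns the ground truth. Two design points:
outlier victims are spread over different questions, because several
planted outliers on the same question shift the group mean/SD enough to
mask each other; and exact planted-vs-detected agreement is only a
well-posed requirement on data that cannot violate rules naturally. The
exactness fixtures therefore use raters who each rate every scenario with
zero rater bias (honest rater-question means then coincide, and the 3-sigma
outlier rule — a tail rule that any stochastic population trips at ~0.3%
per pair — cannot fire) and deterministic deciders ($\beta\in[4,6]$,
$|b|\le0.2$, $w_{cost}\in[0.3,0.7]$) whose choice probabilities traverse
several WTH bins, since the straight-line rule fires naturally both for
near-random agents (levels hugging 3/4) and saturated ones (constant 1 or
6). The default generator keeps the broad, realistic population — natural
straight-liners at a few percent are a feature there, mirroring the
exclusion rates such surveys see; robustness of the rules themselves is
additionally tested against an independent naive-loop oracle on
contaminated broad-population data.

What the generator does not emulate: real motivation ratings are not
conditionally independent given two factors (raters share situational
construals); scenario texts do not exist, so the semantic space rests on
synthetic cluster-structured embeddings; demographics are generated without
any effect on behaviour. Passing tests therefore validate the machinery and
its statistical calibration, not the psychological claims on real data.

## 7. Problem sizes and reproducibility

Simulation sizes in the tests and acceptance script are desk-scale choices:
parameter recovery uses 100 parameter sets at 25/50/200 trials; model
selection 50 simulated participants; calibration checks 200 null
replicates; trait-power checks 20 generator seeds at $n=215$; the
end-to-end determinism run uses 100 scenarios × 60 participants × 50 trials
with two fitted models and 500 RSA permutations. Fifty trials per
participant (not fewer) are used in the end-to-end run because the
decision-RDM definition requires every scenario pair to share at least one
rater, and sparser designs leave empty pairs. All randomness descends from
one global seed through fixed offsets; reruns with an identical
configuration are byte-identical, which the pipeline manifest's file hashes
make checkable.

## 8. Known limitations

* Consensus-based $C_s, B_s$ cannot separate "weights cost more" from
  "perceives more cost"; the fitted $w_{cost}$ mixes both.
* ICC on arbitrary missing-data patterns uses the additive-ANOVA
  approximation rather than full expectation-based estimation.
* The Welch-ANOVA partial $\eta^2$ is a large-sample approximation; its
  uncertainty is best assessed by bootstrap rather than a closed-form CI.
* Leave-one-out refits make group-level LOO comparisons expensive; the
  pipeline leaves LOO off by default and exposes it as a switch.
* Discretization to the 1..5 Likert scale biases loadings recovered from
  consensus ratings (and, counterintuitively, more so at very low noise,
  where dithering is absent). The EFA-recovery check therefore uses a
  planted continuous 300 × 12 loading-structure matrix, which isolates
  extraction/rotation quality from that bias and keeps the cost factor's
  sample eigenvalue well separated from the parallel-analysis reference;
  the discretized survey round trip is tested separately at the
  item-assignment level.
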