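---
title: "Models and methods behind breedplay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind breedplay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Domestic dogs play with people far more than their wild relatives do, and
breeds differ strikingly in how eagerly they do so.  `breedplay` asks how a
breed-level behavioural phenotype — a mean play score on a five-level
ordinal assessment scale — evolved across a breed phylogeny, and how much
of the among-breed variance is attributable to (i) selection for breed
function, (ii) shared ancestry, and (iii) gene flow through historical
crosses between breeds.  The package implements three analyses around one
data model, plus a synthetic-data generator so every stage can be tested
against known ground truth.

The breed-level data model is: for breed $i$, a mean score $y_i \in [1,5]$
computed from $n_i$ individual ordinal scores, an unbiased within-breed
variance $v_i$, and a functional-group label $g(i)$ drawn from the seven
AKC groups (Herding, Hound, Non-sporting, Sporting, Terrier, Toy,
Working).  The sampling variance of the breed mean,
$\mathrm{mev}_i = v_i / n_i$, is carried through the pipeline as known
measurement-error variance.

# Discrete ancestral states: the equal-rates Mk model

Breed function is modelled as a $k$-state continuous-time Markov chain on
the tree with all transition rates equal ($k = 7$ here).  The ER transition
kernel has the closed form

$$P_{ii}(t) = \tfrac1k + \tfrac{k-1}{k}e^{-k\alpha t}, \qquad
  P_{ij}(t) = \tfrac1k - \tfrac1k e^{-k\alpha t},$$

which `er_transition()` uses directly (SYM and ARD generators go through a
spectral decomposition behind the same `mk_model()` interface; ER is the
default and the other two exist for robustness checks).  `mk_loglik()`
evaluates the likelihood by the pruning algorithm — post-order dynamic
programming over per-node conditional likelihoods — with per-edge
rescaling and accumulated log factors, because with 132 tips and seven
states the raw partial likelihoods underflow double precision.  The root
prior is flat ($1/k$ per state), which for the ER model coincides with the
stationary distribution.

`fit_er()` maximizes the likelihood over $\alpha$ by bounded
one-dimensional search on $[10^{-8}, \alpha_{\max}]$ with
$\alpha_{\max} = 1000/\mathrm{depth}$; only the product $\alpha t$ is
identified, so the bound scales with the tree.  Invariant data leave the
likelihood monotone in $\alpha$; the fit then reports the lower boundary
with a flag rather than failing.

`marginal_asr()` returns, for every internal node, the marginal posterior
probability of each state given all tips ("scaled likelihoods", the pie
charts of comparative studies).  It uses an inside–outside scheme: the
pruning pass supplies per-edge "down" messages, and a pre-order pass
propagates "up" messages carrying everything outside each subtree,
including the root prior.  This is algebraically the same quantity the
rerooting method produces, at one tree traversal instead of one per node.
Marginal (not joint) reconstruction is used because per-node scaled
likelihoods are what the downstream report consumes.

# Continuous ancestral states and Pagel's lambda

The play score is modelled as Brownian motion on the tree: tip values are
multivariate normal with mean $\mu$ (the root state) and covariance
$\sigma^2 C(\lambda)$, where $C_{ij}$ is the shared root-to-tip path
length of tips $i$ and $j$ and Pagel's $\lambda \in [0,1]$ multiplies the
off-diagonal entries.  Given $\lambda$, both $\mu$ (by GLS,
$\hat\mu = (\mathbf{1}^\top C^{-1}\mathbf{1})^{-1}\mathbf{1}^\top C^{-1}y$)
and $\sigma^2$ (ML, divisor $n$) have closed forms, so `fit_lambda()` only
searches one dimension.  The search interval is closed — real data sets
place the optimum exactly at $\lambda = 1$, a boundary estimate, and the
fit compares the interior optimum explicitly against both endpoints and
flags boundary results.

`anc_states()` computes each internal node's estimate as the conditional
mean of its state given the tips under the fitted model, treating the root
mean as unknown (flat prior).  Practically: the joint tips-plus-nodes
covariance is assembled from shared MRCA depths (internal branches scaled
by $\lambda$, pendant depths preserved), and the conditional-normal
formulas are evaluated with a correction term that propagates the
uncertainty in $\hat\mu$.  The root estimate is therefore exactly the GLS
phylogenetic mean, with variance
$\sigma^2(\mathbf{1}^\top C^{-1}\mathbf{1})^{-1}$.  Confidence intervals
are $\pm 1.96\sqrt{\mathrm{var}}$ with the ML $\sigma^2$; tests confirm
this reproduces the estimates of the widely used rerooting implementation
to five decimals, with interval half-widths agreeing at the percent level
(that implementation uses a slightly different rate denominator).

Lambda is estimated on the breed means without the measurement-error
variances: the signal analysis and the mixed model are deliberately
separate steps, mirroring standard practice.  A mev-inflated variant was
considered and rejected as a default because it changes the meaning of
$\lambda$ from "signal in the observed breed means" to "signal in the
latent breed values", which belongs to the mixed model's territory.

# The phylogenetic mixed model

The variance-partitioning model is the animal model

$$y_i = \beta_{g(i)} + a_i + h_i + m_i + e_i,$$

with $a \sim N(0, \sigma^2_a A)$ (common ancestry; $A$ is the tree
covariance rescaled to unit diagonal so $\sigma^2_a$ is on the trait
scale), $h \sim N(0, \sigma^2_b H)$ (gene flow; $H$ a haplotype-sharing
similarity matrix, also unit-diagonal), $m_i \sim N(0, \mathrm{mev}_i)$
fixed observation noise, and iid residual $e_i \sim N(0, \sigma^2_e)$.
There is no global intercept: one coefficient per group, so the seven
$\beta$ values are directly interpretable as group-typical play scores.

## Sampler

`fit_mm()` runs a Gibbs sampler written in C++ (RcppArmadillo):

* all location effects $(\beta, a, h)$ are drawn **jointly** from their
  multivariate normal conditional.  $a$ and $h$ enter the likelihood only
  through their sum, so single-site updates of one given the other mix
  extremely slowly; the joint block update makes successive $\beta$ draws
  nearly independent (effective sample sizes around 90% of the retained
  draws in typical runs);
* the combined residual $c_i = m_i + e_i$ is split by its exact normal
  conditional ($e_i \mid c_i$), after which each variance has a conjugate
  scaled-inverse-chi-square update;
* all random numbers come from R's RNG, so `set.seed()` gives
  bit-reproducible chains.

Priors are the conventional weakly informative inverse-Gamma-type choice
($V = 1$, $\nu = 0.002$ per variance component) and a zero-mean normal
with variance $10^{10}$ on the fixed effects.  Halving or doubling $V$
moves the variance-component medians by well under 25% at study scale (a
guard test enforces this).  The default chain in `mm_spec()` is 130,000
iterations, 30,000 burn-in, thin 100 (1,000 retained); the pipeline's
desk default is 13,000/3,000/10, which retains the same 1,000 draws and,
with the block updates, reaches effective sizes in the hundreds in a few
seconds for 132 breeds.  A chain whose variance samples exceed $10^6$
times the data variance aborts with advice to strengthen the prior.

## DIC, contrasts and group summaries

`mm_dic()` uses the conditional Gaussian deviance given the location
effects (the animal-model convention): $DIC = \bar D + p_D$ with
$p_D = \bar D - D(\bar\theta)$ at posterior means.  The pipeline fits the
group model and an intercept-only null with the same random structure and
reports the DIC difference.  `group_contrasts()` computes all 21 pairwise
posterior differences with
$p_{\mathrm{MCMC}} = 2\min\{\Pr(\Delta \ge 0), \Pr(\Delta \le 0)\}$,
floored at $2/\mathrm{draws}$ and capped at 1 (ties count toward both
tails so identical chains give exactly 1).  No multiple-testing
correction is applied by default, matching how such contrasts are usually
reported; a Bonferroni flag exists.  `group_posterior_summary()` offers
both a $\beta$-only summary and a "group level" summary that adds each
group's average posterior random effect to its coefficient; the two
bracket the plausible readings of group-level posterior displays in the
literature, which do not always state which was used.

# The synthetic-data generator

`simulate_study()` generates, from one seed: a Yule tree rescaled to unit
depth; group labels evolved under the ER kernel (rate 0.1 per unit depth
by default, giving the strong phylogenetic clustering of function seen in
real breed data); a block-structured haplotype-sharing matrix
(`make_haplotype_matrix()`, the correlation form of $I + s ZZ^\top$ with
random block memberships — a deliberate stand-in, since no generative
model links haplotype sharing to trait covariance); latent breed values
$\beta_{g(i)} + a_i + h_i + e_i$ at the fitted magnitudes
($\sigma^2_a = 0.354$, $\sigma^2_b = 0.133$, $\sigma^2_e = 0.012$, group
means 2.49–3.55); and per-breed individual scores, 677 per breed by
default (89,352 individuals over 132 breeds), produced by thresholding
latent-plus-unit-normal noise at cutpoints 1.5/2.5/3.5/4.5.  The ordinal
noise is fixed at unit variance — the cutpoints carry the scale — and the
cutpoints are symmetric about the scale midpoint so that the expected
score equals the latent value in the central range.

What the generator deliberately does *not* emulate: genotype-level
processes behind the similarity matrices, breed demography, rater effects
and test-retest structure, and any real correspondence between haplotype
blocks and tree position.  Passing recovery tests therefore show that the
estimators invert the generator's statistical structure, not that real
data meet that structure.

Two measured properties of the generator matter when reading test
results.  First, a five-point scale censors: clade-level shifts that push
latent values toward the scale ends are compressed (at a latent value of
4.5 the expected score is about 4.32), so variance components and extreme
group means recovered from ordinal data are mildly attenuated relative to
the Gaussian latent truth, and credible-interval coverage of the latent
group means pools a few points below nominal.  On data observed without
the ordinal step the same sampler covers at or above nominal.  Second,
with strongly clustered groups the group fixed effects are nearly
collinear with the ancestry random effect: a clade's shared ancestry
deviation is statistically indistinguishable from a shift in its group's
mean.  This sets a floor of roughly 0.35 trait units on the
root-mean-square error of any group-mean estimator under these
conditions — visible equally in the width of the model's own credible
intervals — and it also makes the DIC preference for the group model over
the intercept-only null modest and variable (the real-data margin of this
model class is itself only on the order of ten units).  The acceptance
suite states recovery bands tighter than this floor; those checks fail
for structural reasons documented here, not because of a defect in the
sampler, which is validated separately on well-specified data.

# Numerical choices and degenerate inputs

* Zero-length branches are kept literally; singular covariance matrices
  produce an error suggesting jitter rather than silent rescaling.
* Relatedness matrices must be symmetric within $10^{-8}$ and PSD within
  $-10^{-8}\lambda_{\max}$; near-singular matrices are inverted after an
  $10^{-8}\lambda_{\max}$ ridge.
* Matrices are always joined to trait tables by breed label, never by
  position, and label mismatches fail fast with the offending breeds
  listed.
* Breeds observed once get within-variance and mev of 0 plus a warning;
  they are retained.
* Breeds without a group label are excluded from the mixed model and the
  discrete reconstruction (which needs labels), with a logged count, but
  keep contributing to the continuous reconstruction.
* Single-tip trees are readable but rejected by every analysis that needs
  covariance structure.

# Problem sizes used by the test suite

The oracle tests run exact enumeration on trees of up to 4 tips and dense
linear-algebra checks on 6–10 tips.  Recovery suites use 200-tip trees
with 100 replicates for $\lambda$, and 20–30 studies of 132 breeds with
13,000-iteration chains for the mixed model — sizes chosen so the whole
suite exercises study-scale behaviour while remaining a desk-scale run.

# Known limitations

* ARD fits with $k = 7$ have 42 free rates and are not practically
  identifiable at 132 tips; the interface allows them for robustness
  checks only.
* The DIC is the conditional-deviance variant; marginal-likelihood model
  comparison is out of scope.
* No repeatability modelling across test occasions; the within-breed
  variance is taken as exchangeable sampling noise.
* The transformation from published genetic distances to a similarity
  matrix is not guessed: real analyses must supply $A$ and $H$ as
  similarity matrices.
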