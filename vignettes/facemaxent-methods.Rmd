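---
title: "Models and methods in facemaxent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in facemaxent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facemaxent)
```

## The data and the inference problem

The package models *sculpted facial vectors*: configurations of $n = 8$
facial landmarks, each with $(x, y)$ coordinates in units of facial height,
chosen by experimental subjects as preferred modifications of a reference
portrait. Each subject contributes a set of repetitions, so a study is a
table of $S$ records with subject ids, repetition indices and a gender
label. The object of inference is the distribution of the fluctuations
$\Delta^{(s)} = \mathbf{r}^{(s)} - \langle \mathbf{r} \rangle$
around the mean configuration.

Two structural features drive all of the numerics:

* **Exact linear constraints.** The face-space is defined so that the
  $2n = 16$ coordinates carry only $10$ degrees of freedom; six directions
  of the coordinate space have exactly zero variance. `find_constraints()`
  detects them spectrally (eigenvalues below `rel_tol = 1e-10` times the
  leading one; the constraints are exact, so the spectral gap is many
  orders of magnitude and the threshold is uncritical) and
  `reduce_and_standardize()` removes them before any nonlinear fit.
* **Subject structure.** Repetitions by one subject are far more similar
  to each other than to other subjects' vectors. This matters for error
  estimation (resampling must operate on subjects) and for train/test
  splitting (a vector-level split leaks subject identity).

## Maximum-Entropy models

The MaxEnt model of order $p$ is the least-committal density reproducing
the empirical moments up to order $p$. With means and pairwise
correlations $C_{\mu\nu} = \langle \Delta_\mu \Delta_\nu \rangle$ as
sufficient statistics, the density is the Gaussian
$\mathcal{L}(\Delta) \propto e^{-H_2(\Delta)}$ with
$H_2 = \tfrac12 \Delta^\top J \Delta + \mathbf{h}^\top \Delta$, and the
inverse problem has the closed-form solution $J = C^{-1}$ (pseudo-inverse:
the constraint null modes are excluded) and $\mathbf{h} = J\,\langle\Delta\rangle$.
The density is defined with respect to Lebesgue measure on the support
subspace, so the normalisation uses $(2\pi)^{r/2}$ with $r$ the rank and
the pseudo-determinant of $C$. Evaluating the density at a vector with an
off-support component projects that component out (with a warning) rather
than returning $-\infty$: measured data sit slightly off-support through
rounding, and classifiers still need to rank such points.

Sampling is exact: draws are built from the non-null eigenpairs of $C$,
so null directions carry exactly zero fluctuation.

The order-1 model keeps only the means (couplings fixed to
$J_{ij} = \sigma_i^{-2}\delta_{ij}$); the order-3 model adds the symmetric
tensor of triplet correlations and the Hamiltonian gains
$H_3 = \tfrac16 \sum_{\mu\nu\kappa} \Delta_\mu \Delta_\nu \Delta_\kappa
Q_{\mu\nu\kappa}$. A cubic Hamiltonian is unbounded below, so the density
is truncated to the hypercube $[-B, B]^D$ with $B = 6$ in standardised
units: six standard deviations, where the truncation of a near-Gaussian
fit is negligible.

### Learning the third-order model

There is no closed form at order 3. `fit_cubic_maxent()` performs
exponential-family maximum likelihood by moment matching: each
independent parameter ($h_\mu$, $J_{\mu\le\nu}$, $Q_{\mu\le\nu\le\kappa}$)
moves proportionally to the difference between the model moment
(estimated from persistent Metropolis chains) and the data moment.
Numerical choices that proved necessary:

* **Gradient clipping** (elementwise at $0.5$). Strongly skewed targets
  can have third moments of order tens; an unclipped first step then
  overshoots into a boundary-dominated density and the ascent oscillates.
* **Box bound on $Q$** (`q_max = 1`). A diagonal coupling beyond
  $3/B = 0.5$ makes the one-dimensional density boundary-dominated on the
  hypercube; on small noisy training sets the unbounded ascent drifts
  there and destabilises. The bound is a projection, not a penalty, and
  sits well above the couplings the recovery tests exercise.
* **Relative residuals.** Convergence is declared on the largest moment
  residual relative to the moment's magnitude, which coincides with the
  absolute residual on standardised data (the intended input) but stays
  meaningful when a user feeds unstandardised moments.
* **Divergence detection on the raw residual.** The smoothed
  (exponentially averaged) residual rises monotonically during benign
  transients; fifty consecutive increases of the *unsmoothed* residual,
  by contrast, only occur in a genuine blow-up, and that is the condition
  that raises a learning-failure error.

Defaults (128 chains, 5 Metropolis sweeps per iteration, learning rate
$0.05/\sqrt{t}$, tolerance $0.02$, at most $2{,}000$ iterations) were
validated by planted-parameter recovery: a single planted
$Q_{111} = 0.5$ at $D = 3$, $n = 50{,}000$ is recovered within about
$15\%$ relative error in a few seconds.

### Normalising the cubic density

`estimate_log_z3()` first tries plain importance sampling with the
model's own Gaussian part as proposal:
$\log Z_3 = \log Z_2 + \log \mathbb{E}\,[e^{-H_3}\,\mathbf{1}(\text{cube})]$.
When the cubic term is strong the target concentrates near a hypercube
face and the importance weights degenerate; if the effective sample size
falls below 100 the estimator switches to annealed importance sampling
along $e^{-H_2 - \beta H_3}$ with a uniform $\beta$ ladder and one
Metropolis sweep per rung, from the same Gaussian base. Both routes were
checked against adaptive quadrature in one and two dimensions.

## The Gaussian–Bernoulli RBM

The GRBM couples the $D$ visible coordinates to $N_h$ binary hidden
units through the energy
$E(\mathbf{v}, \mathbf{h}) = \sum_i (v_i - b_i)^2 / 2\sigma_i^2
- \sum_j c_j h_j - \sum_{ij} (v_i/\sigma_i^2) W_{ij} h_j$.
Marginalising the hidden layer induces effective interactions of *all*
orders among the visibles, which is why it sits at the top of the model
hierarchy here. Training is standard CD-$k$ stochastic gradient with
minibatches and momentum.

One modelling point deserves emphasis: **the visible scales must be
learnable even on standardised data.** With $\sigma_i$ fixed at 1 the
conditional noise already accounts for the entire unit variance of each
standardised coordinate, leaving the hidden units no room to model shared
variance; the stationary solution then systematically understates
correlations (we measured a ceiling of $\approx 0.45$ model covariance
against a target of $0.8$, invariant to learning rate, epochs and CD
order). The package therefore trains $\log \sigma_i^2$ by gradient
(at one fifth of the main learning rate) with a floor at
$\sigma = 0.05$. A teacher–student experiment ($D = 6$, $N_h = 4$)
reproduces the teacher's held-out mean log-density to within $0.01$ nat.

Normalised likelihoods come from annealed importance sampling along
$W \to \beta W$ starting at the factorised $W = 0$ model, whose
normalisation is closed-form; the estimate is validated against exact
hidden-state enumeration for small hidden layers.

## The synthetic study generator

`make_two_class_study()` emulates the study conditions so that every
stage is testable without the original data. Its defaults *are* the
study's dimensions: 95 subjects (48 + 47 per class), 28 repetitions each,
8 landmarks, 6 exact constraints. Choices the data do not pin down:

* **Mean geometry.** Landmarks sit at a face-like arrangement of distinct
  positions (eyes, cheeks, nose, mouth corners, chin) in units of facial
  height. Distinct mean positions are essential: inter-landmark segment
  angles — the axes of the longitudinal/torsion decomposition — are
  undefined when landmarks coincide on average.
* **Scale.** Subject-level fluctuations have standard deviation
  `base_scale = 0.02` facial heights per coordinate, the scale of subtle
  preference differences rather than gross face shape.
* **Subject structure.** `intra_to_inter_ratio = 0.25`: within-subject
  variance is a quarter of between-subject variance, so subjects are
  individually resolvable, consistent with the observation that repeated
  sculpting by one subject is recognisably self-similar.
* **Planted class differences.** Order 1 shifts class B's mean along a
  random support direction; order 2 mixes in a second covariance shape;
  order 3 draws class B's subject effects from a cubic MaxEnt model with
  diagonal couplings `effect_size = 0.4` (kept below the
  interior-dominance bound $3/B = 0.5$) and then *affinely corrects*
  class B's first and second moments to match class A's (whitening and
  re-colouring on the support), so the classes differ at third order
  only. The correction leaves third cumulants approximately intact;
  residual first/second-moment mismatch is below $10^{-3}$.

What the generator does **not** emulate: the genetic-algorithm sculpting
dynamics, realistic anatomical covariance structure, texture degrees of
freedom, or any asymmetry between x and y fluctuations. Tests passing on
this generator therefore certify the inference machinery, not claims
about real faces.

## Classification protocol

Each class's training set is fitted separately by every generative model;
a test vector is scored by
$s(\Delta) = \ln \mathcal{L}(\Delta \mid \theta_A) -
\ln \mathcal{L}(\Delta \mid \theta_B)$, and the ROC curve is traced by
sweeping a threshold over midpoints of consecutive distinct scores (tied
scores move diagonally in one step), with trapezoidal area and maximal
accuracy at empirical class proportions. Preprocessing — the constraint
basis and standardisation — is fitted once on the pooled training
coordinates and applied frozen everywhere, so scores reflect
distributional differences only.

Two split modes are provided. The default splits *vectors* (20% train),
matching the description of splitting the elements of each class; the
*subject* mode keeps each subject's vectors on one side. The distinction
is not cosmetic: with 28 vectors per subject, a vector-level split puts
every test subject in the training set, and the per-class fits encode
subject identity. On synthetic data with *identical* class distributions
a vector-level split yields auROC well above 0.5 through this leakage
alone, while a subject-level split sits at chance. Chance-level tests in
the package therefore always use subject-level splits, and real-data
analyses should report both.

The supervised baselines are a Random Forest (500 trees, via the
`randomForest` package) and a principal-component $t$-test score: axes
from pooled-training PCA, per-axis Welch $t$ between the class
projections, test score $\sum_k t_k z_k$ with $z_k$ the standardised
projection. The latter formula is one concretisation of "a $t$-test on
principal components" — the one-line description leaves the weighting
open, and $t$-weighted standardised projections make the score a linear
discriminant whose axis ordering is inherited from the training data
alone.

## Interaction tables

For a landmark pair $(i, j)$ with mean segment direction
$\hat u = (\cos\alpha_{ij}, \sin\alpha_{ij})$ and normal $\hat v$, and
$M_{ij}$ the $2 \times 2$ cross-block of a $2n \times 2n$ matrix, the
longitudinal and torsion components are the quadratic forms
$\hat u^\top M_{ij} \hat u$ and $\hat v^\top M_{ij} \hat v$: the elastic
constants resisting changes of the segment's length and angle. The
definition is rotation-equivariant and reduces to the plain $xx$ / $yy$
entries for an axis-aligned segment. Diagonal-block contributions are
deliberately excluded; a spring-network reading could include them, and
the table exposes the raw blocks needed to compute such variants.

Errors come from a subject-level bootstrap (subjects resampled with
replacement, the whole pipeline re-run per replica), and entries are
flagged significant when $t = |\text{value}|/\sigma > 1$. Simulation
shows the bootstrap $\sigma$ is well calibrated
($\sigma / \mathrm{sd}_{\text{true}} \approx 1.0$), while the
pseudo-inverse *point estimator* carries finite-sample bias of order
$0.7\,\sigma$ at 200 subjects, decaying like $n^{-1/2}$ relative to
$\sigma$; nominal one-sigma coverage ($\approx 0.69$ measured) is reached
at study scales of a few hundred subjects. The contrast between the
correlation table (dense in significant entries) and the coupling table
(sparse) is a finite-information statement: with unlimited data the
systematic constraint-propagation corrections in $J$ also become
significant. The property suite tests it with structured constraints
(translations, scale, rotation, smooth modes) at study-scale samples.

## Problem sizes in the test suite

The suite is sized to certify each mechanism at desk scale: planted-Q
recovery at $D = 3$, $n = 50{,}000$; Gaussian fit–sample–refit at
$n = 50{,}000$; teacher–student GRBM at $D = 6$, $N_h = 4$ with 4,000
training vectors; classification on studies of 24–60 subjects per class;
coverage pooled over eight independent 300-subject studies. These sizes
are the package's validation choices; all thresholds (25% recovery error,
5% Frobenius error, 0.1 nat, 0.1 auROC gap) are stated in the
corresponding tests.

## Known limitations

* The third-order fit is stochastic-approximation based; on small noisy
  training sets it typically stops at the iteration cap with residuals
  above tolerance, and the returned model is the final iterate. The fit
  diagnostics expose the residual trace so users can judge convergence.
* The GRBM's CD-1 training underestimates long-range dependence when
  undertrained; the moment-reproduction test documents a configuration
  (1,000 epochs on 2,000 vectors) that suffices at $D = 2$.
* The bootstrap treats subjects as exchangeable and ignores any
  repetition-order effects within subjects.
* `parameter_count(order = 3, ...)` reports the printed closed-form
  count, which is fractional for some dimensions; the exact count of
  stored symmetric triples is available via `exact_triples = TRUE`.
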