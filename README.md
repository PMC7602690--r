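# facemaxent

Unsupervised generative modelling of sculpted facial-landmark preference
data, for researchers studying facial perception with probabilistic models:
Maximum-Entropy (MaxEnt) models of interaction order 1–3 and a
Gaussian–Bernoulli Restricted Boltzmann Machine (GRBM) fitted to
landmark-coordinate fluctuations, generative likelihood-ratio
classification of the sculpting subject's gender, and interpretation of the
inferred pairwise coupling network.

## The problem and the models

A study records, for each of $n_s$ subjects, $\mathcal{N}$ sculpted facial
vectors: the $(x, y)$ positions of $n = 8$ facial landmarks in units of
facial height. The analysis models the fluctuations
$\Delta^{(s)} = \mathbf{r}^{(s)} - \langle \mathbf{r} \rangle$ around the
mean configuration. The 16 coordinates satisfy 6 exact linear constraints,
so all inference runs on the 10-dimensional support subspace.

The MaxEnt model of order $p$ is the maximum-entropy density constrained to
reproduce the empirical moments up to order $p$:

* order 2 (Gaussian): $\mathcal{L}(\Delta) \propto
  \exp\!\big({-\tfrac12 \Delta^\top J \Delta - \mathbf{h}^\top \Delta}\big)$
  with the closed-form solution $J = C^{-1}$ (pseudo-inverse on the
  support) and $\mathbf{h} = J \langle \Delta \rangle$;
* order 3: adds $H_3 = \tfrac16 \sum_{\mu\nu\kappa}
  \Delta_\mu \Delta_\nu \Delta_\kappa\, Q_{\mu\nu\kappa}$, truncated to the
  hypercube $[-B, B]^D$ with $B = 6$ in standardised units, fitted by
  moment-matching gradient ascent with persistent Metropolis chains;
* GRBM: binary hidden units coupled linearly to Gaussian visibles; hidden
  marginalisation induces effective interactions of all orders. Normalised
  likelihoods come from annealed importance sampling.

Classification fits each model to the two gender classes separately and
scores test vectors by
$s(\Delta) = \ln \mathcal{L}(\Delta|\theta_A) - \ln \mathcal{L}(\Delta|\theta_B)$,
summarised by ROC curves, auROC and maximal accuracy, alongside Random
Forest and principal-component $t$-test baselines. The coupling matrix $J$
is decomposed per landmark pair into longitudinal and torsion components
$J^{\parallel}_{ij}, J^{\perp}_{ij}$ — elastic constants resisting changes
of the inter-landmark distance and angle — with subject-bootstrap errors
and $t$-value significance ($t_{ij} = |J_{ij}|/\sigma_{ij} > 1$).

A synthetic-study generator reproduces the statistical structure of the
data (exact constraints, subject-level variance structure, class
differences planted at interaction order 1, 2 or 3 with lower moments
matched), so the entire pipeline is testable without the original dataset.

## Worked example

Generate a study in which the two classes share their first and second
moments exactly and differ only at third order, then run the
classification pipeline:

```r
library(facemaxent)

spec <- synthetic_study_spec(n_subjects_per_class = 60,
                             difference_order = 3, seed = 11)
ds <- make_two_class_study(spec)
ds
#> landmark_dataset: 3360 records, 120 subjects, 8 landmarks (16 coords)
#> gender:  F=1680  M=1680

report <- run_gender_pipeline(ds, spec = split_spec(seed = 21), seed = 31)
report
#> gender_report: 672 train / 2688 test vectors (vector split)
#>   maxent1   auROC = 0.456  max accuracy = 0.519
#>   maxent2   auROC = 0.454  max accuracy = 0.521
#>   maxent3   auROC = 0.630  max accuracy = 0.592
#>   grbm      auROC = 0.507  max accuracy = 0.529
#>   rf        auROC = 0.808  max accuracy = 0.733
#>   pc_ttest  auROC = 0.485  max accuracy = 0.512
```

The order-1 and order-2 models and the PCA baseline sit at chance — the
planted difference is invisible to means and pairwise correlations — while
the third-order MaxEnt model and the (supervised, discriminatively
trained) Random Forest detect it. The interaction network of the same
study:

```r
tab <- interaction_analysis(ds, n_boot = 100, seed = 41)
head(significant_segments(tab)[, c("i", "j", "alpha", "J_par",
                                   "J_par_sigma", "J_par_t")], 4)
#>     i j alpha J_par J_par_sigma J_par_t
#> x62 3 6 0.876  -777         106    7.35
#> x3  1 3 1.843   874         128    6.83
#> x64 5 6 2.096   862         168    5.12
#> x31 2 3 2.576   364         101    3.62
```

Each row is a landmark pair: the mean-segment angle `alpha`, the
longitudinal coupling `J_par` (units of inverse squared facial height),
its bootstrap error and $t$-value. Real landmark tables are read with
`read_landmark_table()` (CSV dialect
`subject_id,rep_index,gender,x1..x8,y1..y8`; an adapter config maps other
layouts).

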