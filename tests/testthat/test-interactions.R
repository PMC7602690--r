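# Longitudinal/torsion decomposition, bootstrap errors, significance.

test_that("axis-aligned segments pick out the plain matrix components", {
  n <- 2L
  # mean geometry: landmark 1 at (0, 0), landmark 2 at (1, 0): alpha = 0
  geom <- c(0, 1, 0, 0)
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.7      # x1-x2
  m[3, 4] <- m[4, 3] <- -0.2     # y1-y2
  m[1, 4] <- m[4, 1] <- 0.1      # x1-y2
  tab <- longitudinal_torsion_table(m, geom)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$alpha, 0)
  expect_equal(tab$par, 0.7)     # u' M u = M[x1, x2]
  expect_equal(tab$perp, -0.2)   # v' M v = M[y1, y2]

  geom45 <- c(0, 1, 0, 1)        # segment along (1, 1): alpha = pi / 4
  tab45 <- longitudinal_torsion_table(m, geom45)
  expect_equal(tab45$alpha, pi / 4)

  expect_error(longitudinal_torsion_table(m, c(0, 0, 0, 0)), "coincide")
})

test_that("the decomposition is rotation equivariant", {
  set.seed(111)
  n <- 5L
  geom <- c(runif(n), runif(n))
  a <- matrix(rnorm((2 * n)^2), 2 * n)
  m <- crossprod(a) / (2 * n)
  psi <- pi / 6
  R2 <- cbind(c(cos(psi), sin(psi)), c(-sin(psi), cos(psi)))
  # block rotation acting on (x_1..x_n, y_1..y_n) stacking
  big <- rbind(cbind(diag(n) * R2[1, 1], diag(n) * R2[1, 2]),
               cbind(diag(n) * R2[2, 1], diag(n) * R2[2, 2]))
  t0 <- longitudinal_torsion_table(m, geom)
  t1 <- longitudinal_torsion_table(big %*% m %*% t(big),
                                   drop(big %*% geom))
  expect_equal(t1$par, t0$par, tolerance = 1e-9)
  expect_equal(t1$perp, t0$perp, tolerance = 1e-9)
  expect_equal((t1$alpha - t0$alpha - psi + pi) %% (2 * pi) - pi,
               rep(0, nrow(t0)), tolerance = 1e-9)
})

test_that("bootstrap errors vanish on degenerate data and are reproducible", {
  # all subjects identical: resampling subjects never changes the pooled data
  set.seed(112)
  block <- matrix(rnorm(4 * 16, sd = 0.1), 4, 16)
  coords <- do.call(rbind, replicate(6, block, simplify = FALSE))
  ds <- landmark_dataset(coords + 0.5,
                         subject_id = rep(paste0("s", 1:6), each = 4),
                         rep_index = rep(1:4, times = 6),
                         gender = rep("F", 24))
  est <- function(d) colMeans(d$coords)
  bt <- bootstrap_errors(ds, est, n_boot = 50, seed = 113)
  expect_lt(max(bt$sigma), 1e-12)

  # reproducibility on non-degenerate data
  ds2 <- make_two_class_study(synthetic_study_spec(
    n_subjects_per_class = 10L, reps_per_subject = 6L, seed = 114))
  b1 <- bootstrap_errors(ds2, est, n_boot = 50, seed = 115)
  b2 <- bootstrap_errors(ds2, est, n_boot = 50, seed = 115)
  expect_identical(b1$sigma, b2$sigma)
  expect_error(bootstrap_errors(ds2, est, n_boot = 10), "n_boot")
})

test_that("one-sigma bootstrap intervals cover true couplings at the nominal rate", {
  # Gaussian studies with a known J on the constrained support; coverage is
  # pooled over several independent datasets because the 28 pair estimates
  # within one dataset are strongly correlated.
  spec <- synthetic_study_spec(n_subjects_per_class = 150L,
                               reps_per_subject = 4L,
                               effect_size = 0, seed = 116)
  ds0 <- make_two_class_study(spec)
  gt <- ds0$ground_truth
  # true record covariance: between-subject + within-subject parts
  pc <- gt$basis$projector %*% gt$base_cov %*% gt$basis$projector
  true_cov <- pc * (1 + spec$intra_to_inter_ratio)
  true_J <- sym_pseudo_inverse_oracle(true_cov)
  true_par <- longitudinal_torsion_table(true_J, gt$geometry)$par

  mk <- function(seed, ns = 300L, reps = 4L) {
    x <- sample_gaussian_population(rep(0, 16), gt$base_cov, ns, gt$basis,
                                    seed = seed)$deltas
    noise <- sample_gaussian_population(
      rep(0, 16), spec$intra_to_inter_ratio * gt$base_cov, ns * reps,
      gt$basis, seed = seed + 1L)$deltas
    coords <- sweep(x[rep(seq_len(ns), each = reps), ] + noise, 2L,
                    gt$geometry, "+")
    landmark_dataset(coords, rep(paste0("s", seq_len(ns)), each = reps),
                     rep(seq_len(reps), ns), rep("F", ns * reps))
  }
  covered <- unlist(lapply(1:8, function(k) {
    tab <- interaction_analysis(mk(5000L + 23L * k), n_boot = 60,
                                seed = 9000L + k)
    abs(tab$J_par - true_par) <= tab$J_par_sigma
  }))
  expect_gt(mean(covered), 0.58)
  expect_lt(mean(covered), 0.78)
})

test_that("significance filtering follows the t rule", {
  tab <- data.frame(i = c(1, 1), j = c(2, 3),
                    J_par = c(1, 3), J_par_sigma = c(2, 2))
  tab$J_par_t <- abs(tab$J_par) / tab$J_par_sigma   # 0.5 and 1.5
  out <- significant_segments(tab, t_threshold = 1)
  expect_equal(nrow(out), 1L)
  expect_equal(out$J_par, 3)
  # zero sigma with non-zero value: infinite t, kept and flagged
  tab2 <- data.frame(i = 1, j = 2, J_par = 1, J_par_sigma = 0,
                     J_par_t = Inf)
  expect_equal(nrow(significant_segments(tab2)), 1L)
  # enormous sigma: nothing survives
  tab$J_par_t <- abs(tab$J_par) / 1e9
  expect_equal(nrow(significant_segments(tab)), 0L)
})

test_that("raw correlations are denser than effective couplings at equal threshold", {
  # A sparse coupling network propagated through structured face-space
  # constraints (translations, scale, rotation, smooth modes): the global
  # constraints spread correlations across all pairs, so the correlation
  # table stays dense while the effective-coupling table, which has to
  # resolve the noisier inverse problem, flags fewer pairs at the same
  # threshold. The contrast is a finite-information statement, so the
  # sample is study-scale.
  n <- 8L
  d2 <- 2L * n
  g <- default_geometry(n)
  gx <- g[1:n] - mean(g[1:n])
  gy <- g[n + 1:n] - mean(g[n + 1:n])
  V <- cbind(c(rep(1, n), rep(0, n)),              # x translation
             c(rep(0, n), rep(1, n)),              # y translation
             c(gx, gy),                            # scale
             c(-gy, gx),                           # rotation
             c(cos(2 * pi * (1:n) / n), rep(0, n)),
             c(rep(0, n), cos(2 * pi * (1:n) / n)))
  P <- diag(d2) - tcrossprod(qr.Q(qr(V)))
  J0 <- diag(d2) * 4
  for (i in 1:(n - 1)) {                           # nearest-neighbour chain
    J0[i, i + 1] <- J0[i + 1, i] <- -1.2
    J0[n + i, n + i + 1] <- J0[n + i + 1, n + i] <- -1.2
  }
  C0 <- solve(J0)
  ns <- 25L
  reps <- 6L
  subj <- sample_gaussian_population(rep(0, d2), C0, ns, P,
                                     seed = 120)$deltas * 0.02
  noise <- sample_gaussian_population(rep(0, d2), C0, ns * reps, P,
                                      seed = 121)$deltas * 0.01
  coords <- sweep(subj[rep(seq_len(ns), each = reps), ] + noise, 2L, g, "+")
  ds <- landmark_dataset(coords,
                         subject_id = rep(paste0("s", 1:ns), each = reps),
                         rep_index = rep(seq_len(reps), times = ns),
                         gender = rep(c("F", "M"), length.out = ns * reps))
  tab <- interaction_analysis(ds, n_boot = 60, seed = 122)
  frac_c <- mean(tab$C_par_t > 1)
  frac_j <- mean(tab$J_par_t > 1)
  expect_gte(frac_c, frac_j)
})

test_that("interaction tables round-trip through TSV", {
  ds <- make_two_class_study(synthetic_study_spec(
    n_subjects_per_class = 12L, reps_per_subject = 6L, seed = 123))
  tab <- interaction_analysis(ds, n_boot = 50, seed = 124)
  expect_equal(nrow(tab), choose(8, 2))
  expect_true(all(tab$alpha > -pi & tab$alpha <= pi))
  expect_true(all(tab$J_par_sigma >= 0))
  expect_equal(tab$J_par_t, abs(tab$J_par) / tab$J_par_sigma)
  p <- tempfile(fileext = ".tsv")
  write_interaction_table(tab, p)
  back <- utils::read.delim(p)
  expect_equal(back$J_par, tab$J_par, tolerance = 1e-12)
  expect_identical(back$significant, tab$significant)
})
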