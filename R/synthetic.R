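# Synthetic landmark studies with the statistical structure the analysis
# assumes: exact linear constraints (a seeded random null space), subject
# structure (between-subject variance dominating within-subject variance),
# and two classes whose distributions differ at interaction order 1, 2 or 3
# with lower moments matched.
#
# Default dimensions mirror the study: 95 subjects x 28 repetitions,
# 8 landmarks (16 coordinates), 6 exact constraints.

#' Random orthogonal projector with an exact null space
#'
#' @param dim ambient dimension (2n).
#' @param n_constraints number of exact null directions (k < dim).
#' @param seed integer seed.
#' @return `constraint_basis` with a seeded random orthonormal null basis.
#' @export
make_constraint_projector <- function(dim, n_constraints, seed = NULL) {
  if (n_constraints < 0L || n_constraints >= dim) {
    stop("n_constraints must satisfy 0 <= n_constraints < dim")
  }
  null_vectors <- with_seed(seed, {
    if (n_constraints == 0L) matrix(0, dim, 0L) else {
      q <- qr.Q(qr(matrix(stats::rnorm(dim * dim), dim, dim)))
      q[, seq_len(n_constraints), drop = FALSE]
    }
  })
  projector <- diag(dim) - tcrossprod(null_vectors)
  retained <- greedy_retained(null_vectors, dim)
  structure(list(null_vectors = null_vectors, retained_indices = retained,
                 projector = (projector + t(projector)) / 2,
                 rank = dim - n_constraints, rel_tol = 1e-10),
            class = "constraint_basis")
}

#' Sample a Gaussian population constrained to a subspace
#'
#' Draws from `N(mean, cov)` and maps every sample through the projector, so
#' the sample covariance converges to `P cov P`.
#'
#' @param mean length-dim mean vector.
#' @param cov dim x dim PSD covariance.
#' @param n number of draws.
#' @param projector `constraint_basis` or a projector matrix.
#' @param seed integer seed.
#' @return `fluctuation_data` with the n x dim sample matrix.
#' @export
sample_gaussian_population <- function(mean, cov, n, projector = NULL,
                                       seed = NULL) {
  stopifnot(n >= 1)
  d <- length(mean)
  es <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  if (min(es$values) < -1e-8 * max(abs(es$values))) {
    stop("cov is not positive semidefinite")
  }
  lam <- pmax(es$values, 0)
  x <- with_seed(seed, {
    z <- matrix(stats::rnorm(n * d), n, d)
    sweep(z, 2L, sqrt(lam), "*") %*% t(es$vectors)
  })
  x <- sweep(x, 2L, mean, "+")
  if (!is.null(projector)) {
    p <- if (inherits(projector, "constraint_basis")) projector$projector else
      projector
    x <- x %*% p
  }
  structure(list(deltas = x, mean = rep(0, d), scales = rep(1, d),
                 n_landmarks = d / 2L),
            class = "fluctuation_data")
}

#' Sample from a cubic MaxEnt population
#'
#' Thin wrapper over [metropolis_sample()] for use as a study-population
#' generator.
#'
#' @param model `cubic_maxent`.
#' @param n draws.
#' @param mcmc_params list overriding `step_scale`, `burn_in`, `thin`,
#'   `n_chains`.
#' @param seed integer seed.
#' @return `fluctuation_data`.
#' @export
sample_cubic_population <- function(model, n, mcmc_params = list(),
                                    seed = NULL) {
  mp <- modifyList(list(step_scale = 0.5, burn_in = 500L, thin = 5L,
                        n_chains = 64L), mcmc_params)
  metropolis_sample(model, n, step_scale = mp$step_scale,
                    burn_in = mp$burn_in, thin = mp$thin,
                    n_chains = mp$n_chains, seed = seed)
}

#' Specification of a synthetic two-class landmark study
#'
#' @param n_subjects_per_class subjects per class: one number for balanced
#'   classes or a length-2 vector `c(n_A, n_B)` (the study's 95 subjects
#'   split as `c(48, 47)`).
#' @param reps_per_subject sculpted vectors per subject (default 28).
#' @param n_landmarks landmarks (default 8 -> 16 coordinates).
#' @param n_constraints exact linear constraints (default 6).
#' @param intra_to_inter_ratio within- to between-subject variance ratio
#'   (default 0.25: inter-subject variance dominates).
#' @param difference_order 1, 2 or 3: the lowest interaction order at which
#'   the two classes differ. 1 shifts class B's mean; 2 changes class B's
#'   covariance shape; 3 draws class B's subject effects from a cubic MaxEnt
#'   model and affinely corrects its first and second moments to match
#'   class A's.
#' @param effect_size magnitude of the planted difference (mean shift in
#'   inter-subject sd units, log variance factor, or third-order coupling
#'   strength, by order). Default NULL picks 1, 1 or 0.4 by order; the
#'   third-order default stays below 0.5 so the planted cubic density
#'   remains interior-dominated on the `B = 6` hypercube
#'   (`H(-B) = B^2/2 - q B^3/6 > 0` requires `q < 3/B`).
#' @param base_scale inter-subject standard deviation of each coordinate
#'   before projection (facial-height units; default 0.02, the scale of
#'   landmark preference fluctuations).
#' @param seed integer seed.
#' @return object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(n_subjects_per_class = c(48L, 47L),
                                 reps_per_subject = 28L,
                                 n_landmarks = 8L, n_constraints = 6L,
                                 intra_to_inter_ratio = 0.25,
                                 difference_order = 1L,
                                 effect_size = NULL,
                                 base_scale = 0.02,
                                 seed = 1L) {
  stopifnot(all(n_subjects_per_class >= 1L),
            length(n_subjects_per_class) %in% 1:2, reps_per_subject >= 1L,
            n_landmarks >= 2L, n_constraints < 2L * n_landmarks,
            intra_to_inter_ratio > 0, difference_order %in% 1:3)
  if (length(n_subjects_per_class) == 1L) {
    n_subjects_per_class <- rep(n_subjects_per_class, 2L)
  }
  if (is.null(effect_size)) {
    effect_size <- c(1, 1, 0.4)[difference_order]
  }
  structure(as.list(environment()), class = "synthetic_study_spec")
}

#' Canonical mean landmark geometry
#'
#' Mean landmark positions in units of facial height (image convention,
#' y increasing downwards). For 8 landmarks, a face-like arrangement
#' (eyes, cheeks, nose, mouth corners, chin); otherwise landmarks are
#' placed on an ellipse. Distinct mean positions matter: inter-landmark
#' segment angles are only well defined when landmarks do not coincide.
#'
#' @param n_landmarks number of landmarks.
#' @return length-2n vector `(x1..xn, y1..yn)`.
#' @export
default_geometry <- function(n_landmarks) {
  if (n_landmarks == 8L) {
    x <- c(0.35, 0.65, 0.28, 0.72, 0.50, 0.40, 0.60, 0.50)
    y <- c(0.35, 0.35, 0.58, 0.58, 0.55, 0.72, 0.72, 0.92)
  } else {
    th <- seq(0, 2 * pi, length.out = n_landmarks + 1L)[-1L]
    x <- 0.5 + 0.3 * cos(th)
    y <- 0.5 + 0.4 * sin(th)
  }
  c(x, y)
}

# random positive-definite correlation-like matrix on the full space
random_spd <- function(d, seed_offset, seed) {
  with_seed(seed + seed_offset, {
    a <- matrix(stats::rnorm(d * d, sd = 0.3), d, d)
    s <- diag(d) + crossprod(a) / d
    s / mean(diag(s))
  })
}

#' Generate a two-class landmark study
#'
#' Subject-level effects are drawn from each class's population
#' distribution, projected onto the constraint subspace; each subject's
#' repetitions add within-subject Gaussian noise whose variance is
#' `intra_to_inter_ratio` times the between-subject variance (also
#' projected). Gender labels: class A = `"F"`, class B = `"M"`. For a pure
#' third-order difference, class B's subject effects are whitened and
#' re-coloured to match class A's population mean and covariance (affine
#' map, third cumulants approximately preserved), leaving moment mismatch
#' below 1e-3.
#'
#' @param spec `synthetic_study_spec`.
#' @return `landmark_dataset` with attributes `ground_truth` (list with the
#'   projector, class parameters and seed).
#' @export
make_two_class_study <- function(spec) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  d2 <- 2L * spec$n_landmarks
  basis <- make_constraint_projector(d2, spec$n_constraints, spec$seed)
  p <- basis$projector
  nsa <- spec$n_subjects_per_class[1L]
  nsb <- spec$n_subjects_per_class[2L]
  base_cov <- spec$base_scale^2 * random_spd(d2, 101L, spec$seed)

  subj_a <- sample_gaussian_population(rep(0, d2), base_cov, nsa, basis,
                                       seed = spec$seed + 1L)$deltas
  subj_b <- switch(as.character(spec$difference_order),
    "1" = {
      shift <- with_seed(spec$seed + 5L, stats::rnorm(d2))
      shift <- drop(p %*% shift)
      shift <- shift / sqrt(sum(shift^2)) * spec$effect_size *
        spec$base_scale * sqrt(basis$rank)
      sweep(sample_gaussian_population(rep(0, d2), base_cov, nsb, basis,
                                       seed = spec$seed + 2L)$deltas,
            2L, shift, "+")
    },
    "2" = {
      cov_b <- spec$base_scale^2 *
        (random_spd(d2, 202L, spec$seed) * exp(spec$effect_size) +
           random_spd(d2, 101L, spec$seed)) / (1 + exp(spec$effect_size))
      sample_gaussian_population(rep(0, d2), cov_b, nsb, basis,
                                 seed = spec$seed + 2L)$deltas
    },
    "3" = third_order_class(spec, basis, base_cov, subj_a)
  )

  noise_cov <- spec$intra_to_inter_ratio * base_cov
  build_class <- function(subj_means, label, prefix, seed_off) {
    reps <- spec$reps_per_subject
    ns <- nrow(subj_means)
    noise <- sample_gaussian_population(rep(0, d2), noise_cov, ns * reps,
                                        basis,
                                        seed = spec$seed + seed_off)$deltas
    coords <- sweep(subj_means[rep(seq_len(ns), each = reps), ,
                               drop = FALSE] + noise,
                    2L, default_geometry(spec$n_landmarks), "+")
    list(coords = coords,
         subject_id = paste0(prefix, rep(seq_len(ns), each = reps)),
         rep_index = rep(seq_len(reps), times = ns),
         gender = rep(label, ns * reps))
  }
  a <- build_class(subj_a, "F", "A", 3L)
  b <- build_class(subj_b, "M", "B", 4L)
  ds <- landmark_dataset(rbind(a$coords, b$coords),
                         c(a$subject_id, b$subject_id),
                         c(a$rep_index, b$rep_index),
                         c(a$gender, b$gender))
  ds$ground_truth <- list(basis = basis, base_cov = base_cov,
                          spec = spec,
                          geometry = default_geometry(spec$n_landmarks),
                          subject_means = list(A = subj_a, B = subj_b))
  ds
}

# Class-B subject effects for a pure third-order difference: draw from a
# cubic MaxEnt model on the reduced subspace, map to the full frame, then
# affinely correct mean and covariance to match class A's sample moments.
third_order_class <- function(spec, basis, base_cov, subj_a) {
  d2 <- 2L * spec$n_landmarks
  rank <- basis$rank
  # skewed population on the support subspace, in standardised units
  qarr <- array(0, dim = c(rank, rank, rank))
  for (m in seq_len(rank)) qarr[m, m, m] <- spec$effect_size
  model <- cubic_maxent_model(rep(0, rank), diag(rank), qarr, B = 6)
  z <- sample_cubic_population(model, spec$n_subjects_per_class[2L],
                               mcmc_params = list(burn_in = 800L, thin = 10L),
                               seed = spec$seed + 2L)$deltas
  # map the rank-dim standardised draws into the support of the full frame,
  # with class-A scale
  es <- eigen(basis$projector, symmetric = TRUE)
  u <- es$vectors[, es$values > 0.5, drop = FALSE]
  x <- spec$base_scale * (z %*% t(u))
  match_moments(x, subj_a, basis)
}

# Affine map (whiten then re-colour, both on the support subspace) taking
# the sample mean and covariance of x to those of ref.
match_moments <- function(x, ref, basis) {
  es <- eigen(basis$projector, symmetric = TRUE)
  u <- es$vectors[, es$values > 0.5, drop = FALSE]
  ax <- x %*% u
  ar <- ref %*% u
  cx <- stats::cov(ax) * (nrow(ax) - 1) / nrow(ax)
  cr <- stats::cov(ar) * (nrow(ar) - 1) / nrow(ar)
  sqrt_m <- function(m) {
    e <- eigen((m + t(m)) / 2, symmetric = TRUE)
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  }
  isqrt_m <- function(m) {
    e <- eigen((m + t(m)) / 2, symmetric = TRUE)
    if (min(e$values) < 1e-12 * max(e$values)) {
      stop("infeasible moment correction: degenerate class covariance")
    }
    e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
  }
  amap <- sqrt_m(cr) %*% isqrt_m(cx)
  ax2 <- sweep(sweep(ax, 2L, colMeans(ax)) %*% t(amap), 2L, colMeans(ar), "+")
  ax2 %*% t(u)
}
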