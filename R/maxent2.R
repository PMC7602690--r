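# Order-1 and order-2 Maximum-Entropy models of landmark fluctuations.
#
# With means and pairwise correlations as sufficient statistics the MaxEnt
# density is Gaussian, L(Delta) = exp(-H2(Delta)) / Z with
# H2 = (1/2) Delta' J Delta + h' Delta, and the inverse problem is solved in
# closed form: J is the pseudo-inverse of the correlation matrix C (null
# modes induced by the face-space constraints are excluded) and h = J <Delta>.
# The density is taken with respect to Lebesgue measure on the support
# subspace, so log Z uses rank/2 as the power of 2*pi and the
# pseudo-determinant of C.

#' Fit the order-2 (Gaussian) Maximum-Entropy model
#'
#' @param moments `moment_statistics` with `cov` (order >= 2).
#' @param basis optional `constraint_basis`; its `rel_tol` sets the
#'   pseudo-inverse tolerance so the model's null modes match the detected
#'   constraints. Without it, `rel_tol` is used directly.
#' @param rel_tol eigenvalue tolerance when no basis is given.
#' @return object of class `gaussian_maxent`: fields `h`, `J`, `mean`,
#'   `log_z`, `order` (2), `support` (eigenvectors/eigenvalues/null mask of
#'   C), `rel_tol`.
#' @export
fit_gaussian_maxent <- function(moments, basis = NULL, rel_tol = 1e-10) {
  cv <- moments$cov
  if (is.null(cv)) stop("moments must include the covariance")
  if (!is.null(basis)) rel_tol <- basis$rel_tol
  mu <- moments$mean
  cv <- cv - tcrossprod(mu)     # centre: stored moments are <Delta Delta'>
  pi_ <- sym_pseudo_inverse(cv, rel_tol)
  J <- pi_$pinv
  h <- drop(J %*% mu)
  log_z <- (pi_$rank / 2) * log(2 * pi) + pi_$log_pdet / 2
  structure(list(h = h, J = J, mean = mu, log_z = log_z, order = 2L,
                 support = list(vectors = pi_$vectors,
                                eigenvalues = pi_$eigenvalues,
                                null_mask = pi_$null_mask,
                                rank = pi_$rank),
                 rel_tol = rel_tol, basis = basis),
            class = c("gaussian_maxent", "facemaxent_model"))
}

#' Fit the order-1 (independent) Maximum-Entropy model
#'
#' Only the means are sufficient statistics; equivalently the couplings are
#' fixed to `J = diag(1 / var)` so coordinates are independent.
#'
#' @inheritParams fit_gaussian_maxent
#' @return `gaussian_maxent` with diagonal `J` and `order = 1`.
#' @export
fit_independent_maxent <- function(moments) {
  cv <- moments$cov
  if (is.null(cv)) stop("moments must include per-coordinate variances")
  v <- diag(cv) - moments$mean^2
  if (any(v <= 0)) stop("zero-variance coordinate: reduce the data first")
  J <- diag(1 / v, nrow = length(v))
  mu <- moments$mean
  log_z <- (length(v) / 2) * log(2 * pi) + sum(log(v)) / 2
  structure(list(h = drop(J %*% mu), J = J, mean = mu, log_z = log_z,
                 order = 1L,
                 support = list(vectors = diag(length(v)),
                                eigenvalues = v,
                                null_mask = rep(FALSE, length(v)),
                                rank = length(v)),
                 rel_tol = 0, basis = NULL),
            class = c("gaussian_maxent", "facemaxent_model"))
}

#' Log-density of a Gaussian MaxEnt model
#'
#' Components of `delta` outside the support subspace carry zero model
#' variance; they are projected out before evaluation (the density is defined
#' on the support), and a warning is raised when the off-support part is
#' non-negligible.
#'
#' @param model `gaussian_maxent`.
#' @param delta numeric vector of length D, or an S x D matrix.
#' @param off_support_warn relative norm above which a warning is raised.
#' @return numeric vector of log-densities.
#' @export
gaussian_log_density <- function(model, delta, off_support_warn = 1e-6) {
  x <- if (is.matrix(delta)) delta else matrix(delta, nrow = 1L)
  xc <- sweep(x, 2L, model$mean)
  sup <- model$support
  if (any(sup$null_mask)) {
    nv <- sup$vectors[, sup$null_mask, drop = FALSE]
    off <- xc %*% nv
    off_norm <- sqrt(rowSums(off^2))
    tot_norm <- pmax(sqrt(rowSums(xc^2)), .Machine$double.eps)
    if (any(off_norm / tot_norm > off_support_warn)) {
      warning("off-support component projected out before evaluation")
    }
    xc <- xc - off %*% t(nv)
  }
  q <- rowSums((xc %*% model$J) * xc)
  drop(-q / 2 - model$log_z)
}

#' Sample from a Gaussian MaxEnt model
#'
#' Draws `mean + sum_k sqrt(lambda_k) u_k z_k` over the non-null eigenpairs
#' of `C = pinv(J)`, so samples respect the support exactly (zero fluctuation
#' along constraint directions).
#'
#' @param model `gaussian_maxent`.
#' @param n number of draws.
#' @param seed integer seed (NULL to use the current RNG state).
#' @return `fluctuation_data` whose `deltas` is the n x D sample matrix.
#' @export
sample_gaussian <- function(model, n, seed = NULL) {
  stopifnot(n >= 1)
  sup <- model$support
  keep <- !sup$null_mask
  u <- sup$vectors[, keep, drop = FALSE]
  sdv <- sqrt(pmax(sup$eigenvalues[keep], 0))
  x <- with_seed(seed, {
    z <- matrix(stats::rnorm(n * sum(keep)), nrow = n)
    sweep(z, 2L, sdv, "*") %*% t(u)
  })
  x <- sweep(x, 2L, model$mean, "+")
  structure(list(deltas = x, mean = rep(0, ncol(x)),
                 scales = rep(1, ncol(x)), n_landmarks = ncol(x) / 2L),
            class = "fluctuation_data")
}

#' Number of free parameters of a MaxEnt model of given order
#'
#' Order 1 counts fields plus per-coordinate variances (2D); order 2 counts
#' fields plus the symmetric coupling matrix, D + D(D+1)/2; order 3
#' additionally counts third-order couplings via the printed closed form
#' D^3/6 + D^2/3 + 5D/2, rounded to the nearest integer. The order-3 formula
#' is not an integer for every D; when the rounding error exceeds 1e-9 a
#' warning reports the discrepancy and the rounded value is returned (the
#' full symmetric-triple count is `D + D(D+1)/2 + choose(D + 2, 3)` and can
#' be obtained with `exact_triples = TRUE`).
#'
#' @param order 1, 2 or 3.
#' @param D dimension.
#' @param exact_triples if TRUE and `order = 3`, count one parameter per
#'   stored non-decreasing triple instead of using the closed form.
#' @return integer.
#' @export
parameter_count <- function(order, D, exact_triples = FALSE) {
  stopifnot(D >= 1, order %in% 1:3)
  if (order == 1L) return(as.integer(2 * D))
  if (order == 2L) return(as.integer(D + D * (D + 1) / 2))
  if (exact_triples) {
    return(as.integer(D + D * (D + 1) / 2 + choose(D + 2, 3)))
  }
  v <- D^3 / 6 + D^2 / 3 + 5 * D / 2
  if (abs(v - round(v)) > 1e-9) {
    warning(sprintf("order-3 parameter-count formula gives %.6f for D = %d%s",
                    v, D, "; returning the rounded value"))
  }
  as.integer(round(v))
}

#' Map a model fitted in reduced coordinates back to the full frame
#'
#' Given a coupling matrix fitted on reduced standardised coordinates and the
#' reduction recorded by [reduce_and_standardize()], returns the equivalent
#' full-frame coupling: the pseudo-inverse of the full-frame model
#' covariance, whose quadratic form agrees with the reduced one on the
#' support subspace.
#'
#' @param J_reduced D x D coupling matrix.
#' @param reduced the reduced `fluctuation_data` (carries the reduction).
#' @return 2n x 2n symmetric matrix.
#' @export
map_coupling_to_full <- function(J_reduced, reduced) {
  tmap <- reduction_map(reduced)            # Delta_full = T delta_red
  # C_full = T C_red T' with C_red = pinv(J_red); then J_full = pinv(C_full)
  c_red <- sym_pseudo_inverse(J_reduced)$pinv
  c_full <- tmap %*% c_red %*% t(tmap)
  sym_pseudo_inverse(c_full)$pinv
}
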