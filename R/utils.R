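# Shared numerical helpers: symmetric rank-3 tensor storage, pseudo-inverse
# on a rank-deficient support, and overflow-safe log-space reductions.

#' Index table for a symmetric rank-3 tensor
#'
#' A symmetric tensor `Q[mu, nu, kappa]` is stored as one value per
#' non-decreasing index triple `mu <= nu <= kappa`. The multiplicity column
#' counts the distinct permutations of each triple (1, 3 or 6), so that sums
#' over all ordered triples can be taken over stored entries only.
#'
#' @param d dimension.
#' @return data frame with integer columns `i`, `j`, `k` (`i <= j <= k`) and
#'   `mult`, ordered lexicographically.
#' @keywords internal
triplet_index <- function(d) {
  out <- do.call(rbind, lapply(seq_len(d), function(i) {
    do.call(rbind, lapply(i:d, function(j) {
      cbind(i = i, j = j, k = j:d)
    }))
  }))
  out <- as.data.frame(out)
  out$mult <- ifelse(out$i == out$j & out$j == out$k, 1L,
                     ifelse(out$i == out$j | out$j == out$k, 3L, 6L))
  out
}

#' Evaluate all third-order monomials of sample rows
#'
#' For a sample matrix `x` (rows are observations) returns the matrix of
#' products `x[, i] * x[, j] * x[, k]` for each stored triple.
#'
#' @param x numeric matrix, n x d.
#' @param trip triple table from [triplet_index()].
#' @return n x nrow(trip) matrix.
#' @keywords internal
triple_products <- function(x, trip) {
  x[, trip$i, drop = FALSE] * x[, trip$j, drop = FALSE] *
    x[, trip$k, drop = FALSE]
}

#' Eigen pseudo-inverse of a symmetric PSD matrix
#'
#' Inverts on the span of eigenvalues larger than `rel_tol` times the largest
#' eigenvalue; smaller eigenvalues are treated as exact null modes.
#'
#' @param m symmetric matrix.
#' @param rel_tol relative eigenvalue tolerance.
#' @return list with `pinv`, `eigenvalues`, `vectors`, `rank`, `null_mask`
#'   (TRUE for null modes), `log_pdet` (sum of log non-null eigenvalues).
#' @keywords internal
sym_pseudo_inverse <- function(m, rel_tol = 1e-10) {
  es <- eigen((m + t(m)) / 2, symmetric = TRUE)
  lam <- es$values
  lam_max <- max(lam, 0)
  if (lam_max <= 0) stop("matrix has no positive eigenvalue; degenerate data")
  if (min(lam) < -rel_tol * lam_max * 100) {
    stop("matrix has a significantly negative eigenvalue: not PSD")
  }
  null_mask <- lam < rel_tol * lam_max
  inv_lam <- ifelse(null_mask, 0, 1 / lam)
  pinv <- es$vectors %*% (inv_lam * t(es$vectors))
  list(pinv = (pinv + t(pinv)) / 2, eigenvalues = lam, vectors = es$vectors,
       rank = sum(!null_mask), null_mask = null_mask,
       log_pdet = sum(log(lam[!null_mask])))
}

#' Overflow-safe log of the mean of exponentials
#' @param lw numeric vector of log-weights.
#' @keywords internal
log_mean_exp <- function(lw) {
  m <- max(lw)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(lw - m)))
}

#' Run an expression under a local, seeded RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so package samplers are reproducible without clobbering
#' the user's stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Finite stand-in for log(0) outside a model's support; large in magnitude but
# safe to add or negate without overflowing double precision.
LOG_ZERO <- -1e300

#' Quadrant-aware fluctuation angle
#' @keywords internal
angle_of <- function(dx, dy) atan2(dy, dx)
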