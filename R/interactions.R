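# Interpretation of pairwise couplings: longitudinal / torsion decomposition
# per landmark pair, subject-level bootstrap errors, and t-value filtering.
#
# For a landmark pair (i, j), let alpha_ij be the angle of the mean
# inter-landmark segment <r_ij> = <r_j> - <r_i>, u = (cos a, sin a) the unit
# vector along it and v its normal. With M_ij the 2x2 cross-block of a
# 2n x 2n matrix between landmarks i and j, the longitudinal component is
# u' M_ij u and the torsion component v' M_ij v: the elastic constants
# resisting changes of the segment's length and of its angle. The same
# decomposition applied to the raw correlation matrix C gives the contrast
# table (constraint-propagated correlations make C's table dense while J's
# stays sparse).

pair_block <- function(m, i, j, n) {
  rbind(c(m[i, j], m[i, n + j]), c(m[n + i, j], m[n + i, n + j]))
}

#' Longitudinal / torsion decomposition of a coupling or correlation matrix
#'
#' @param matrix 2n x 2n symmetric matrix in the full coordinate frame
#'   (coupling matrix `J` mapped back from reduced coordinates, or the raw
#'   correlation matrix `C`).
#' @param mean_geometry length-2n vector of mean landmark positions
#'   (`x1..xn, y1..yn`).
#' @return data frame with one row per unordered pair `i < j`: `i`, `j`,
#'   `r_mean_x`, `r_mean_y`, `length`, `alpha`, `par`, `perp`.
#' @export
longitudinal_torsion_table <- function(matrix, mean_geometry) {
  d2 <- nrow(matrix)
  stopifnot(ncol(matrix) == d2, length(mean_geometry) == d2, d2 %% 2L == 0L)
  n <- d2 / 2L
  pairs <- utils::combn(n, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    rij <- c(mean_geometry[j] - mean_geometry[i],
             mean_geometry[n + j] - mean_geometry[n + i])
    len <- sqrt(sum(rij^2))
    if (len == 0) {
      stop(sprintf("undefined segment angle: landmarks %d and %d coincide",
                   i, j))
    }
    a <- angle_of(rij[1L], rij[2L])
    u <- c(cos(a), sin(a))
    v <- c(-sin(a), cos(a))
    m <- pair_block(matrix, i, j, n)
    data.frame(i = i, j = j, r_mean_x = rij[1L], r_mean_y = rij[2L],
               length = len, alpha = a,
               par = drop(u %*% m %*% u), perp = drop(v %*% m %*% v))
  })
  do.call(rbind, rows)
}

#' Subject-level bootstrap standard errors of a pipeline estimator
#'
#' Resamples units (subjects by default; vectors within a subject are
#' dependent, so subject resampling is the honest unit) with replacement and
#' re-runs the full estimator pipeline on each replica; the standard error
#' is the standard deviation over replicas.
#'
#' @param dataset `landmark_dataset`.
#' @param estimator function taking a `landmark_dataset` and returning a
#'   numeric vector (constant length across replicas).
#' @param n_boot number of replicas (>= 50).
#' @param resample_unit `"subject"` or `"vector"`.
#' @param seed integer seed.
#' @return list with `sigma` (sd per estimator component), `estimate` (on
#'   the original data), `replicas` (n_boot x p matrix), `n_failed`.
#' @export
bootstrap_errors <- function(dataset, estimator, n_boot = 100L,
                             resample_unit = c("subject", "vector"),
                             seed = NULL) {
  resample_unit <- match.arg(resample_unit)
  stopifnot(n_boot >= 50L)
  est0 <- estimator(dataset)
  subjects <- unique(dataset$subject_id)
  idx_by_subject <- split(seq_along(dataset$subject_id), dataset$subject_id)
  with_seed(seed, {
    reps <- matrix(NA_real_, n_boot, length(est0))
    n_failed <- 0L
    for (b in seq_len(n_boot)) {
      if (resample_unit == "subject") {
        pick <- sample(subjects, length(subjects), replace = TRUE)
        picked <- idx_by_subject[pick]
        idx <- unlist(picked, use.names = FALSE)
        sizes <- lengths(picked)
        # re-key subjects so replicated subjects stay distinct records
        sid <- rep(seq_along(pick), times = sizes)
        rep_ix <- sequence(sizes)
      } else {
        idx <- sample(length(dataset$subject_id),
                      length(dataset$subject_id), replace = TRUE)
        sid <- seq_along(idx)
        rep_ix <- rep(1L, length(idx))
      }
      ds_b <- landmark_dataset(dataset$coords[idx, , drop = FALSE],
                               as.character(sid), rep_ix,
                               dataset$gender[idx])
      val <- tryCatch(estimator(ds_b), error = function(e) NULL)
      if (is.null(val)) n_failed <- n_failed + 1L else reps[b, ] <- val
    }
    if (n_failed > 0.1 * n_boot) {
      stop(sprintf("robustness error: estimator failed on %d of %d replicas",
                   n_failed, n_boot))
    }
    sigma <- apply(reps, 2L, stats::sd, na.rm = TRUE)
    list(sigma = sigma, estimate = est0, replicas = reps,
         n_failed = n_failed)
  })
}

# Point estimator used by interaction_analysis: decomposed J and C entries
# for every pair, as one flat numeric vector (J_par, J_perp, C_par).
decompose_estimator <- function(dataset, rel_tol = 1e-10) {
  fl <- compute_fluctuations(dataset)
  mom <- moment_statistics(fl, max_order = 2L)
  J <- sym_pseudo_inverse(mom$cov, rel_tol)$pinv
  geom <- colMeans(dataset$coords)
  tj <- longitudinal_torsion_table(J, geom)
  tc <- longitudinal_torsion_table(mom$cov, geom)
  c(tj$par, tj$perp, tc$par)
}

#' Full interaction analysis with bootstrap significance
#'
#' Fits the Gaussian MaxEnt coupling matrix on the full coordinate frame
#' (pseudo-inverse of the correlation matrix), decomposes both `J` and the
#' raw correlation matrix `C` into longitudinal and torsion components per
#' landmark pair, and attaches subject-bootstrap standard errors and
#' t-values `t = |value| / sigma`.
#'
#' @param dataset `landmark_dataset`.
#' @param n_boot bootstrap replicas (default 100).
#' @param resample_unit `"subject"` (default) or `"vector"`.
#' @param t_threshold significance threshold on the t-value (default 1).
#' @param seed integer seed.
#' @return object of class `segment_interaction_table`: a data frame with
#'   per-pair geometry, `J_par`, `J_perp`, `C_par`, their `_sigma` and `_t`
#'   columns and a `significant` flag (on `J_par`'s t-value), plus the
#'   threshold as an attribute.
#' @export
interaction_analysis <- function(dataset, n_boot = 100L,
                                 resample_unit = "subject",
                                 t_threshold = 1, seed = NULL) {
  fl <- compute_fluctuations(dataset)
  mom <- moment_statistics(fl, max_order = 2L)
  J <- sym_pseudo_inverse(mom$cov)$pinv
  geom <- colMeans(dataset$coords)
  tj <- longitudinal_torsion_table(J, geom)
  tc <- longitudinal_torsion_table(mom$cov, geom)
  bt <- bootstrap_errors(dataset, decompose_estimator, n_boot = n_boot,
                         resample_unit = resample_unit, seed = seed)
  np <- nrow(tj)
  sig <- matrix(bt$sigma, ncol = 3L)
  tab <- data.frame(tj[, c("i", "j", "r_mean_x", "r_mean_y", "length",
                           "alpha")],
                    J_par = tj$par, J_par_sigma = sig[, 1L],
                    J_perp = tj$perp, J_perp_sigma = sig[, 2L],
                    C_par = tc$par, C_par_sigma = sig[, 3L])
  tval <- function(v, s) ifelse(s == 0, ifelse(v == 0, 0, Inf), abs(v) / s)
  tab$J_par_t <- tval(tab$J_par, tab$J_par_sigma)
  tab$J_perp_t <- tval(tab$J_perp, tab$J_perp_sigma)
  tab$C_par_t <- tval(tab$C_par, tab$C_par_sigma)
  tab$significant <- tab$J_par_t > t_threshold
  attr(tab, "t_threshold") <- t_threshold
  attr(tab, "n_boot") <- n_boot
  class(tab) <- c("segment_interaction_table", "data.frame")
  tab
}

#' Filter an interaction table to significant rows
#'
#' Keeps rows whose t-value for the chosen column exceeds the threshold,
#' sorted by t descending. A zero bootstrap error with a non-zero value
#' gives t = Inf and is kept (and flagged via the `t` column).
#'
#' @param table `segment_interaction_table` (or compatible data frame).
#' @param t_threshold threshold (default 1).
#' @param column which component's t-value to filter on
#'   (`"J_par"`, `"J_perp"` or `"C_par"`).
#' @return filtered, sorted data frame.
#' @export
significant_segments <- function(table, t_threshold = 1,
                                 column = c("J_par", "J_perp", "C_par")) {
  column <- match.arg(column)
  tcol <- paste0(column, "_t")
  stopifnot(tcol %in% names(table))
  out <- table[table[[tcol]] > t_threshold, , drop = FALSE]
  out[order(-out[[tcol]]), , drop = FALSE]
}

#' Write an interaction table as TSV
#' @param table `segment_interaction_table`.
#' @param path output path.
#' @export
write_interaction_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
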