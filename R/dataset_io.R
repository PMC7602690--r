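# Landmark tables, fluctuation vectors, sufficient statistics, constraint
# detection and angle histograms.
#
# A facial configuration is a vector of 2n coordinates (x_1..x_n, y_1..y_n)
# in units of the facial height. Each record carries a subject id, a
# repetition index and a gender label. Fluctuations are deviations from the
# grand mean configuration; because the face-space is defined through exact
# linear constraints, the 2n coordinates live on a lower-dimensional
# subspace, which is detected spectrally and removed before model fitting.

#' Construct a landmark dataset
#'
#' @param coords numeric matrix, S x 2n, columns ordered `x1..xn, y1..yn`.
#' @param subject_id character vector of length S.
#' @param rep_index integer vector of length S (>= 1).
#' @param gender factor/character vector with levels in `F`, `M`, `NA`
#'   (the literal string "NA" denotes an unlabelled record).
#' @return object of class `landmark_dataset` with elements `coords`,
#'   `subject_id`, `rep_index`, `gender`, `n_landmarks`.
#' @export
landmark_dataset <- function(coords, subject_id, rep_index, gender) {
  coords <- as.matrix(coords)
  if (ncol(coords) %% 2L != 0L) stop("coords must have an even column count")
  n <- ncol(coords) / 2L
  if (n < 2L) stop("at least 2 landmarks are required")
  if (!all(is.finite(coords))) {
    bad <- which(!apply(is.finite(coords), 1L, all))[1L]
    stop(sprintf("non-finite coordinate in record %d", bad))
  }
  S <- nrow(coords)
  subject_id <- as.character(subject_id)
  rep_index <- as.integer(rep_index)
  gender <- as.character(gender)
  stopifnot(length(subject_id) == S, length(rep_index) == S,
            length(gender) == S)
  if (any(rep_index < 1L)) stop("rep_index must be >= 1")
  bad_g <- setdiff(unique(gender), c("F", "M", "NA"))
  if (length(bad_g) > 0L) {
    stop(sprintf("unknown gender code(s): %s", paste(bad_g, collapse = ", ")))
  }
  key <- paste(subject_id, rep_index)
  if (anyDuplicated(key)) stop("duplicate (subject_id, rep_index) pair")
  colnames(coords) <- c(paste0("x", seq_len(n)), paste0("y", seq_len(n)))
  structure(list(coords = coords, subject_id = subject_id,
                 rep_index = rep_index, gender = gender, n_landmarks = n),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat(sprintf(
    "landmark_dataset: %d records, %d subjects, %d landmarks (%d coords)\n",
    nrow(x$coords), length(unique(x$subject_id)), x$n_landmarks,
    2L * x$n_landmarks))
  tb <- table(x$gender)
  cat("gender: ", paste(names(tb), tb, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Read a landmark table from CSV
#'
#' The native dialect has header
#' `subject_id,rep_index,gender,x1..xn,y1..yn` with gender codes `F`/`M`/`NA`.
#' A `format_config` list can adapt other layouts by renaming columns.
#'
#' @param path CSV file path.
#' @param format_config optional list with elements `column_map` (named
#'   character vector, `native = file_column`) and `gender_map` (named
#'   character vector recoding gender values).
#' @return [landmark_dataset()].
#' @export
read_landmark_table <- function(path, format_config = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, na.strings = NULL)
  if (!is.null(format_config$column_map)) {
    cm <- format_config$column_map
    for (native in names(cm)) {
      if (!cm[[native]] %in% names(df)) {
        stop(sprintf("format error: mapped column '%s' absent", cm[[native]]))
      }
      names(df)[names(df) == cm[[native]]] <- native
    }
  }
  need <- c("subject_id", "rep_index", "gender")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    if ("gender" %in% miss && length(miss) == 1L) {
      stop("labelling error: required column 'gender' is missing")
    }
    stop(sprintf("format error: missing column(s) %s",
                 paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(names(df))) {
    stop(sprintf("format error: duplicate column(s) %s",
                 paste(unique(names(df)[duplicated(names(df))]),
                       collapse = ", ")))
  }
  coord_cols <- grep("^[xy][0-9]+$", names(df), value = TRUE)
  n <- length(coord_cols) / 2L
  want <- c(paste0("x", seq_len(n)), paste0("y", seq_len(n)))
  if (n < 2L || !setequal(coord_cols, want)) {
    stop("format error: coordinate columns must be x1..xn, y1..yn")
  }
  coords <- as.matrix(df[, want])
  suppressWarnings(storage.mode(coords) <- "double")
  if (anyNA(coords)) {
    bad <- which(apply(is.na(coords), 1L, any))[1L]
    stop(sprintf("parse error: non-numeric coordinate in data row %d", bad))
  }
  gender <- as.character(df$gender)
  if (!is.null(format_config$gender_map)) {
    gm <- format_config$gender_map
    hit <- gender %in% names(gm)
    gender[hit] <- gm[gender[hit]]
  }
  landmark_dataset(coords, df$subject_id, df$rep_index, gender)
}

#' Write a landmark table as CSV
#'
#' Numbers are written with 12 significant digits so a written table reread
#' with [read_landmark_table()] reproduces the written precision exactly.
#'
#' @param dataset a [landmark_dataset()].
#' @param path output path.
#' @export
write_landmark_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  co <- format(dataset$coords, digits = 12, trim = TRUE, scientific = FALSE)
  df <- data.frame(subject_id = dataset$subject_id,
                   rep_index = dataset$rep_index,
                   gender = dataset$gender,
                   co, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fluctuations of landmark positions about the grand mean
#'
#' Delta^(s) = r^(s) - <r>, where <.> is the average over all records. With
#' `standardize = TRUE` each column is additionally divided by its
#' (population) standard deviation; zero-variance columns are left unscaled
#' and flagged.
#'
#' @param dataset a [landmark_dataset()], or an object with a `deltas`
#'   matrix (re-centering already-reduced data is allowed).
#' @param standardize logical.
#' @return object of class `fluctuation_data`: `deltas` (S x D), `mean`
#'   (the subtracted mean), `scales` (per-column divisor, all 1 if not
#'   standardised), `zero_variance` (logical flags), plus carried-over
#'   `subject_id`, `rep_index`, `gender`, `n_landmarks`.
#' @export
compute_fluctuations <- function(dataset, standardize = FALSE) {
  if (inherits(dataset, "landmark_dataset")) {
    x <- dataset$coords
    labs <- dataset[c("subject_id", "rep_index", "gender")]
    n_landmarks <- dataset$n_landmarks
  } else if (!is.null(dataset$deltas)) {
    x <- dataset$deltas
    labs <- dataset[intersect(c("subject_id", "rep_index", "gender"),
                              names(dataset))]
    n_landmarks <- dataset$n_landmarks
  } else stop("unsupported input")
  if (nrow(x) < 2L) stop("at least 2 records are required")
  mu <- colMeans(x)
  deltas <- sweep(x, 2L, mu)
  scales <- rep(1, ncol(x))
  zero_var <- rep(FALSE, ncol(x))
  if (standardize) {
    sdv <- sqrt(colMeans(deltas^2))
    zero_var <- sdv < .Machine$double.eps^0.5
    scales <- ifelse(zero_var, 1, sdv)
    deltas <- sweep(deltas, 2L, scales, "/")
  }
  structure(c(list(deltas = deltas, mean = mu, scales = scales,
                   zero_variance = zero_var, n_landmarks = n_landmarks),
              labs),
            class = "fluctuation_data")
}

#' Empirical moments of a fluctuation set
#'
#' Moments use the 1/S convention: `mean = <Delta>`,
#' `cov[u, v] = <Delta_u Delta_v>` (uncentred second moment about the stored
#' mean; for centred fluctuations this is the population covariance), and
#' for `max_order = 3` the symmetric tensor `<Delta_u Delta_v Delta_k>`
#' stored once per non-decreasing triple.
#'
#' @param fluct a `fluctuation_data` (or any list with a `deltas` matrix).
#' @param max_order 1, 2 or 3.
#' @return object of class `moment_statistics`: `mean`, `cov`, `third`
#'   (data frame `i, j, k, mult, value`, or NULL), `n_samples`, `max_order`.
#' @export
moment_statistics <- function(fluct, max_order = 2L) {
  x <- if (is.matrix(fluct)) fluct else fluct$deltas
  if (is.null(x) || nrow(x) < 1L) stop("empty fluctuation set")
  max_order <- as.integer(max_order)
  stopifnot(max_order %in% 1:3)
  S <- nrow(x)
  mu <- colMeans(x)
  cv <- if (max_order >= 2L) crossprod(x) / S else NULL
  third <- NULL
  if (max_order == 3L) {
    trip <- triplet_index(ncol(x))
    trip$value <- colMeans(triple_products(x, trip))
    third <- trip
  }
  structure(list(mean = mu, cov = cv, third = third, n_samples = S,
                 max_order = max_order, d = ncol(x)),
            class = "moment_statistics")
}

#' Expand stored third moments into a dense array
#' @param moments a `moment_statistics` with `third`.
#' @return d x d x d symmetric array.
#' @export
third_moment_array <- function(moments) {
  stopifnot(!is.null(moments$third))
  d <- moments$d
  arr <- array(0, dim = c(d, d, d))
  tr <- moments$third
  for (r in seq_len(nrow(tr))) {
    p <- unique(rbind(
      c(tr$i[r], tr$j[r], tr$k[r]), c(tr$i[r], tr$k[r], tr$j[r]),
      c(tr$j[r], tr$i[r], tr$k[r]), c(tr$j[r], tr$k[r], tr$i[r]),
      c(tr$k[r], tr$i[r], tr$j[r]), c(tr$k[r], tr$j[r], tr$i[r])))
    arr[p] <- tr$value[r]
  }
  arr
}

#' Detect exact linear constraints from a covariance spectrum
#'
#' Eigenvectors whose eigenvalue falls below `rel_tol` times the largest
#' eigenvalue are taken as exact null modes (constraint directions). A
#' deterministic greedy rule selects which coordinates to drop for the
#' reduced representation: repeatedly drop the coordinate with the largest
#' absolute loading in the current null basis (ties to the lowest index),
#' then rotate that basis so the remaining null vectors have no support on
#' the dropped coordinate.
#'
#' @param moments `moment_statistics` (needs `cov`), or a covariance matrix.
#' @param rel_tol relative eigenvalue tolerance; constraints are exact by
#'   construction, so the spectral gap is many orders of magnitude and the
#'   default 1e-10 is uncritical.
#' @return object of class `constraint_basis`: `null_vectors` (2n x k,
#'   orthonormal), `retained_indices` (length D = 2n - k), `projector`
#'   (2n x 2n orthogonal projector onto the data subspace), `rank`,
#'   `rel_tol`.
#' @export
find_constraints <- function(moments, rel_tol = 1e-10) {
  cv <- if (inherits(moments, "moment_statistics")) moments$cov else
    as.matrix(moments)
  if (is.null(cv)) stop("covariance required (fit moments with max_order >= 2)")
  if (max(abs(cv)) == 0) stop("degenerate data: all-zero covariance")
  es <- eigen((cv + t(cv)) / 2, symmetric = TRUE)
  null_mask <- es$values < rel_tol * max(es$values)
  k <- sum(null_mask)
  d2 <- ncol(cv)
  null_vectors <- es$vectors[, null_mask, drop = FALSE]
  projector <- diag(d2) - tcrossprod(null_vectors)
  retained <- greedy_retained(null_vectors, d2)
  structure(list(null_vectors = null_vectors, retained_indices = retained,
                 projector = (projector + t(projector)) / 2,
                 rank = d2 - k, rel_tol = rel_tol),
            class = "constraint_basis")
}

# Greedy coordinate elimination: one coordinate per null mode, chosen by the
# largest row norm of the running null basis, which is then rotated so its
# remaining columns vanish on the dropped coordinate.
greedy_retained <- function(null_vectors, d2) {
  dropped <- integer(0)
  nb <- null_vectors
  while (ncol(nb) > 0L) {
    load <- sqrt(rowSums(nb^2))
    load[dropped] <- -Inf
    m <- which.max(load)              # which.max takes the lowest tied index
    dropped <- c(dropped, m)
    # rotate columns so only column 1 has support on coordinate m, drop it
    row_m <- nb[m, ]
    if (sqrt(sum(row_m^2)) < .Machine$double.eps^0.5) {
      nb <- nb[, -1L, drop = FALSE]   # degenerate; should not happen
      next
    }
    g <- qr.Q(qr(cbind(row_m, diag(length(row_m)))))[, seq_along(row_m)]
    # ensure first rotated column carries row m's full norm
    nb <- nb %*% g
    if (abs(nb[m, 1L]) < max(abs(nb[m, ]))) {
      o <- order(abs(nb[m, ]), decreasing = TRUE)
      nb <- nb[, o, drop = FALSE]
    }
    nb <- nb[, -1L, drop = FALSE]
    if (ncol(nb) > 0L) {
      nb[m, ] <- 0                    # exact zero (numerically tiny already)
      nb <- qr.Q(qr(nb))              # re-orthonormalise
    }
  }
  sort(setdiff(seq_len(d2), dropped))
}

#' Reduce fluctuations to retained coordinates and standardise
#'
#' Keeps the `retained_indices` columns of the fluctuation matrix,
#' re-centres, and scales each column to unit (population) variance. The
#' basis, retained indices and scales are stored so model parameters can be
#' mapped back to the full coordinate frame.
#'
#' @param fluct `fluctuation_data` in the full frame.
#' @param basis `constraint_basis` from [find_constraints()].
#' @return `fluctuation_data` with D columns and attributes `basis`,
#'   `retained_indices`, `reduce_scales` recorded in fields of the object.
#' @export
reduce_and_standardize <- function(fluct, basis) {
  stopifnot(inherits(basis, "constraint_basis"))
  x <- fluct$deltas
  if (ncol(x) != nrow(basis$projector)) {
    stop("basis inconsistent with fluctuation dimensionality")
  }
  keep <- basis$retained_indices
  xr <- x[, keep, drop = FALSE]
  mu <- colMeans(xr)
  xr <- sweep(xr, 2L, mu)
  sdv <- sqrt(colMeans(xr^2))
  if (any(sdv < .Machine$double.eps^0.5)) {
    stop("basis error: retained coordinate with (near) zero variance")
  }
  xr <- sweep(xr, 2L, sdv, "/")
  cr <- crossprod(xr) / nrow(xr)
  if (rcond(cr) < 1e-10) stop("basis error: reduced covariance still singular")
  out <- fluct
  out$deltas <- xr
  out$reduced_from <- list(basis = basis, retained_indices = keep,
                           center = mu, scales = sdv,
                           full_mean = fluct$mean)
  out$scales <- sdv
  out
}

#' Linear map from reduced standardised coordinates to the full frame
#'
#' Returns the 2n x D matrix `T` with `Delta_full = T %*% delta_reduced`
#' for vectors on the constraint subspace.
#' @param reduced output of [reduce_and_standardize()].
#' @return 2n x D matrix.
#' @export
reduction_map <- function(reduced) {
  info <- reduced$reduced_from
  stopifnot(!is.null(info))
  basis <- info$basis
  p <- basis$projector
  es <- eigen(p, symmetric = TRUE)
  u <- es$vectors[, es$values > 0.5, drop = FALSE]  # support basis
  ru <- u[info$retained_indices, , drop = FALSE]
  # Delta_full = U a;  delta_red = S^-1 R U a  =>  a = (S^-1 R U)^-1 delta_red
  m <- sweep(ru, 1L, info$scales, "/")
  u %*% solve(m)
}

#' Histogram of single-landmark fluctuation angles
#'
#' The angle of landmark i's fluctuation, `phi_i = atan2(Delta_iy,
#' Delta_ix)`, ranges over the full circle (-pi, pi]. Records with zero
#' fluctuation of that landmark are excluded and counted.
#'
#' @param fluct `fluctuation_data` in the full (2n-coordinate) frame.
#' @param landmark_index landmark number in `1..n`.
#' @param n_bins number of uniform bins on (-pi, pi].
#' @param y_axis `"down"` (image convention, default) or `"up"`; flips the
#'   sign of the y fluctuation for angle computation only.
#' @return object of class `angle_histogram`: `landmark`, `breaks`,
#'   `density`, `mids`, `n_used`, `n_excluded`.
#' @export
angle_histogram <- function(fluct, landmark_index, n_bins = 24L,
                            y_axis = c("down", "up")) {
  y_axis <- match.arg(y_axis)
  n <- fluct$n_landmarks
  if (is.null(n)) n <- ncol(fluct$deltas) / 2L
  stopifnot(landmark_index >= 1L, landmark_index <= n)
  dx <- fluct$deltas[, landmark_index]
  dy <- fluct$deltas[, n + landmark_index]
  if (y_axis == "up") dy <- -dy
  r <- sqrt(dx^2 + dy^2)
  keep <- r > 0
  if (!any(keep)) stop("empty histogram: all fluctuations zero for landmark")
  phi <- angle_of(dx[keep], dy[keep])
  breaks <- seq(-pi, pi, length.out = n_bins + 1L)
  # atan2 returns [-pi, pi]; fold -pi onto +pi so bins cover (-pi, pi]
  phi[phi <= -pi] <- pi
  cnt <- tabulate(findInterval(phi, breaks, left.open = TRUE,
                               all.inside = TRUE), nbins = n_bins)
  width <- 2 * pi / n_bins
  structure(list(landmark = landmark_index, breaks = breaks,
                 density = cnt / (sum(cnt) * width),
                 mids = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2,
                 n_used = sum(keep), n_excluded = sum(!keep)),
            class = "angle_histogram")
}
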