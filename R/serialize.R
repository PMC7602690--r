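# JSON serialisation of fitted models and bases so analyses can be archived
# and reloaded without R-specific binary formats.

#' Serialise a fitted model or basis to JSON
#'
#' Supports `gaussian_maxent`, `cubic_maxent` (sparse `mu <= nu <= kappa`
#' triple list for Q), `grbm`, `constraint_basis` and `fluctuation_data`.
#'
#' @param object object to serialise.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(object, path) {
  payload <- if (inherits(object, "gaussian_maxent")) {
    list(type = "gaussian_maxent", order = object$order, h = object$h,
         J = object$J, mean = object$mean, log_z = object$log_z,
         rel_tol = object$rel_tol)
  } else if (inherits(object, "cubic_maxent")) {
    list(type = "cubic_maxent", h = object$h, J = object$J,
         Q = object$Q[object$Q$value != 0, c("i", "j", "k", "value")],
         B = object$B, d = object$d, log_z3 = object$log_z3,
         log_z3_stderr = object$log_z3_stderr)
  } else if (inherits(object, "grbm")) {
    list(type = "grbm", W = object$W, b = object$b, c = object$c,
         sigma = object$sigma, n_hidden = object$n_hidden,
         log_z = object$log_z, log_z_stderr = object$log_z_stderr)
  } else if (inherits(object, "constraint_basis")) {
    list(type = "constraint_basis", null_vectors = object$null_vectors,
         retained_indices = object$retained_indices,
         projector = object$projector, rank = object$rank,
         rel_tol = object$rel_tol)
  } else if (inherits(object, "fluctuation_data")) {
    list(type = "fluctuation_data", deltas = object$deltas,
         mean = object$mean, scales = object$scales)
  } else stop("unsupported object class")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a model or basis serialised with [write_model_json()]
#' @param path JSON file.
#' @return the reconstructed object.
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(x$type,
    gaussian_maxent = {
      J <- as.matrix(x$J)
      rel_tol <- if (x$rel_tol > 0) x$rel_tol else 1e-10
      pi_ <- sym_pseudo_inverse(J, rel_tol)
      # eigenvalues of C = pinv(J): reciprocal on the support, 0 on nulls
      ev_c <- ifelse(pi_$null_mask, 0, 1 / pi_$eigenvalues)
      structure(list(h = x$h, J = J, mean = x$mean, log_z = x$log_z,
                     order = x$order,
                     support = list(vectors = pi_$vectors,
                                    eigenvalues = ev_c,
                                    null_mask = pi_$null_mask,
                                    rank = pi_$rank),
                     rel_tol = x$rel_tol, basis = NULL),
                class = c("gaussian_maxent", "facemaxent_model"))
    },
    cubic_maxent = {
      m <- cubic_maxent_model(x$h, as.matrix(x$J), NULL, B = x$B)
      if (!is.null(x$Q) && NROW(x$Q) > 0) {
        q <- as.data.frame(x$Q)
        key_m <- paste(m$Q$i, m$Q$j, m$Q$k)
        m$Q$value[match(paste(q$i, q$j, q$k), key_m)] <- q$value
      }
      m$log_z3 <- x$log_z3
      m$log_z3_stderr <- x$log_z3_stderr
      m
    },
    grbm = {
      m <- grbm_model(as.matrix(x$W), x$b, x$c, x$sigma)
      m$log_z <- x$log_z
      m$log_z_stderr <- x$log_z_stderr
      m
    },
    constraint_basis = structure(
      list(null_vectors = as.matrix(x$null_vectors),
           retained_indices = x$retained_indices,
           projector = as.matrix(x$projector), rank = x$rank,
           rel_tol = x$rel_tol),
      class = "constraint_basis"),
    fluctuation_data = structure(
      list(deltas = as.matrix(x$deltas), mean = x$mean, scales = x$scales,
           n_landmarks = ncol(as.matrix(x$deltas)) / 2L),
      class = "fluctuation_data"),
    stop("unknown serialised type"))
}
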