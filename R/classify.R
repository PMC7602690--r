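# Gender classification by generative likelihood ratio, with ROC analysis
# and Random-Forest / principal-component t-test baselines.
#
# Protocol: split each class into train (20%) and test (80%); fit each
# generative model to the two training sets separately; score every test
# vector by s(Delta) = log L(Delta | theta_A) - log L(Delta | theta_B);
# sweep the decision threshold to obtain the ROC curve, its area and the
# maximal accuracy. Preprocessing (constraint basis and standardisation) is
# fitted on the pooled training data and applied frozen everywhere, so
# scores reflect distributional differences only.

#' Generic log-density of a fitted generative model
#' @param model fitted model object.
#' @param x vector or matrix of configurations.
#' @param ... passed to methods.
#' @return numeric vector of log-densities.
#' @export
log_density <- function(model, x, ...) UseMethod("log_density")

#' @rdname log_density
#' @export
log_density.gaussian_maxent <- function(model, x, ...)
  gaussian_log_density(model, x, ...)

#' @rdname log_density
#' @export
log_density.cubic_maxent <- function(model, x, ...)
  cubic_log_density(model, x)

#' @rdname log_density
#' @export
log_density.grbm <- function(model, x, ...) grbm_log_density(model, x)

#' Train/test split specification
#'
#' @param train_fraction fraction used for training (default 0.2).
#' @param unit `"vector"` (default, matching the protocol of splitting the
#'   elements) or `"subject"` (keeps each subject's vectors together; avoids
#'   leaking subject identity across the split).
#' @param seed integer seed.
#' @param stratify_by_class logical; split is always per class here.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.2, unit = c("vector", "subject"),
                       seed = 1L, stratify_by_class = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  unit <- match.arg(unit)
  structure(list(train_fraction = train_fraction, unit = unit, seed = seed,
                 stratify_by_class = stratify_by_class),
            class = "split_spec")
}

subset_dataset <- function(dataset, idx) {
  landmark_dataset(dataset$coords[idx, , drop = FALSE],
                   dataset$subject_id[idx], dataset$rep_index[idx],
                   dataset$gender[idx])
}

#' Split a two-class dataset into per-class train and test sets
#'
#' @param dataset `landmark_dataset` with gender labels `F` and `M`.
#' @param spec `split_spec`.
#' @return list with `train_A`, `test_A`, `train_B`, `test_B`
#'   (`landmark_dataset`s; class A = `F`, class B = `M`).
#' @export
split_train_test <- function(dataset, spec = split_spec()) {
  g <- dataset$gender
  if (!all(c("F", "M") %in% g)) stop("both classes must be non-empty")
  pick_train <- function(idx) {
    if (spec$unit == "subject") {
      subj <- unique(dataset$subject_id[idx])
      n_tr <- round(spec$train_fraction * length(subj))
      if (n_tr < 1L || n_tr >= length(subj)) {
        stop("class too small to split at this fraction")
      }
      tr_subj <- sample(subj, n_tr)
      idx[dataset$subject_id[idx] %in% tr_subj]
    } else {
      n_tr <- round(spec$train_fraction * length(idx))
      if (n_tr < 1L || n_tr >= length(idx)) {
        stop("class too small to split at this fraction")
      }
      sample(idx, n_tr)
    }
  }
  with_seed(spec$seed, {
    ia <- which(g == "F"); ib <- which(g == "M")
    tr_a <- pick_train(ia); tr_b <- pick_train(ib)
    list(train_A = subset_dataset(dataset, tr_a),
         test_A = subset_dataset(dataset, setdiff(ia, tr_a)),
         train_B = subset_dataset(dataset, tr_b),
         test_B = subset_dataset(dataset, setdiff(ib, tr_b)))
  })
}

#' Likelihood-ratio scores of test vectors
#'
#' `s(Delta) = log L(Delta | theta_A) - log L(Delta | theta_B)`; higher
#' means more A-like. Both models must be fitted on the same reduced frame.
#'
#' @param model_A,model_B fitted models exposing [log_density()].
#' @param test_vectors matrix of test configurations in the models' frame.
#' @return numeric score vector.
#' @export
likelihood_ratio_scores <- function(model_A, model_B, test_vectors) {
  da <- if (!is.null(model_A$d)) model_A$d else length(model_A$h)
  db <- if (!is.null(model_B$d)) model_B$d else length(model_B$h)
  if (!is.null(da) && !is.null(db) && da != db) {
    stop("frame mismatch: models have different dimensions")
  }
  log_density(model_A, test_vectors) - log_density(model_B, test_vectors)
}

#' ROC curve, auROC and maximal accuracy from scores
#'
#' Sweeps thresholds over midpoints of consecutive sorted unique scores
#' plus +/-Inf (tied scores move diagonally in one step); the area is
#' trapezoidal and the maximal accuracy uses the empirical class
#' proportions.
#'
#' @param scores numeric vector (higher = predicted A / positive).
#' @param labels logical or character vector; TRUE / `"A"` / `"F"` marks the
#'   positive class.
#' @return object of class `roc_result`: `thresholds`, `fpr`, `tpr`,
#'   `auroc`, `max_accuracy`, `max_accuracy_threshold`, `scores`, `labels`.
#' @export
roc_analysis <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels) %in% c("A", "F", "TRUE", "1")
  }
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  p <- sum(labels); n <- sum(!labels)
  if (p == 0L || n == 0L) stop("both classes must be present in labels")
  su <- sort(unique(scores))
  # decreasing thresholds so FPR and TPR sweep non-decreasingly from (0,0)
  thr <- rev(c(-Inf, if (length(su) > 1L) (su[-1L] + su[-length(su)]) / 2,
               Inf))
  tpr <- vapply(thr, function(d) sum(scores > d & labels) / p, 1)
  fpr <- vapply(thr, function(d) sum(scores > d & !labels) / n, 1)
  auroc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  acc <- (tpr * p + (1 - fpr) * n) / (p + n)
  best <- which.max(acc)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr,
                 auroc = auroc, max_accuracy = acc[best],
                 max_accuracy_threshold = thr[best],
                 scores = scores, labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: auROC = %.3f, max accuracy = %.3f (%d+, %d-)\n",
              x$auroc, x$max_accuracy, sum(x$labels), sum(!x$labels)))
  invisible(x)
}

#' Principal-component t-test baseline scores
#'
#' Principal axes are estimated from the pooled training data; a Welch
#' t-statistic between the two classes' projections is computed per axis,
#' and a test vector scores `sum_k t_k z_k` with `z_k` its projection on
#' axis k standardised by the pooled training spread. Test vectors play no
#' role in axis estimation.
#'
#' @param train_A,train_B training matrices (rows = vectors, reduced frame).
#' @param test_vectors matrix of test vectors in the same frame.
#' @return numeric score vector (higher = more A-like).
#' @export
pc_ttest_scores <- function(train_A, train_B, test_vectors) {
  pooled <- rbind(train_A, train_B)
  if (nrow(pooled) <= ncol(pooled)) stop("degenerate PCA: too few vectors")
  pc <- stats::prcomp(pooled, center = TRUE, scale. = FALSE)
  keep <- pc$sdev > 1e-10 * pc$sdev[1L]
  if (!any(keep)) stop("degenerate PCA: no variance")
  rot <- pc$rotation[, keep, drop = FALSE]
  sdv <- pc$sdev[keep]
  proj <- function(x) sweep(x, 2L, pc$center) %*% rot
  pa <- proj(train_A); pb <- proj(train_B)
  welch_t <- vapply(seq_len(ncol(pa)), function(k) {
    va <- stats::var(pa[, k]) / nrow(pa)
    vb <- stats::var(pb[, k]) / nrow(pb)
    (mean(pa[, k]) - mean(pb[, k])) / sqrt(va + vb)
  }, 1)
  z <- sweep(proj(test_vectors), 2L, sdv, "/")
  drop(z %*% welch_t)
}

#' Random-Forest baseline scores
#'
#' Ensemble-of-randomised-trees classifier on the reduced standardised
#' coordinates; the score is the predicted probability of class A.
#'
#' @param train matrix of training vectors.
#' @param train_labels logical vector (TRUE = class A).
#' @param test matrix of test vectors.
#' @param rf_params list overriding `ntree` (500).
#' @param seed integer seed.
#' @return numeric vector of class-A probabilities in `[0, 1]`.
#' @export
rf_scores <- function(train, train_labels, test, rf_params = list(),
                      seed = NULL) {
  rp <- modifyList(list(ntree = 500L), rf_params)
  y <- factor(ifelse(train_labels, "A", "B"), levels = c("A", "B"))
  with_seed(seed, {
    fit <- randomForest::randomForest(x = train, y = y, ntree = rp$ntree)
    unname(stats::predict(fit, test, type = "prob")[, "A"])
  })
}

# Shared preprocessing: constraint basis + standardisation fitted on pooled
# training coordinates, applied frozen to any coordinate matrix.
fit_preprocessing <- function(train_coords, rel_tol = 1e-10) {
  mu <- colMeans(train_coords)
  deltas <- sweep(train_coords, 2L, mu)
  mom <- moment_statistics(deltas, max_order = 2L)
  basis <- find_constraints(mom, rel_tol)
  keep <- basis$retained_indices
  xr <- deltas[, keep, drop = FALSE]
  sdv <- sqrt(colMeans(sweep(xr, 2L, colMeans(xr))^2))
  list(mean = mu, basis = basis, keep = keep,
       center = colMeans(xr), scales = sdv)
}

apply_preprocessing <- function(prep, coords) {
  x <- sweep(coords, 2L, prep$mean)[, prep$keep, drop = FALSE]
  sweep(sweep(x, 2L, prep$center), 2L, prep$scales, "/")
}

#' Run the full gender-classification pipeline
#'
#' Splits the data, fits the shared preprocessing on the pooled training
#' coordinates, fits the 1-, 2- and 3-MaxEnt and GRBM models to each class's
#' training set, scores the pooled test set by likelihood ratio, and adds
#' the Random-Forest and principal-component t-test baselines. Methods are
#' isolated: one method failing is reported, not fatal.
#'
#' @param dataset `landmark_dataset` with `F`/`M` labels.
#' @param spec `split_spec`.
#' @param methods character subset of
#'   `c("maxent1", "maxent2", "maxent3", "grbm", "rf", "pc_ttest")`.
#' @param maxent3_params,grbm_params,rf_params per-method parameter lists.
#' @param seed master seed for model fitting (split seed lives in `spec`).
#' @return object of class `gender_report`: per-method list with `auroc`,
#'   `max_accuracy`, `roc` (the `roc_result`) or `error`; plus `n_train`,
#'   `n_test`, `seeds`.
#' @export
run_gender_pipeline <- function(dataset, spec = split_spec(),
                                methods = c("maxent1", "maxent2", "maxent3",
                                            "grbm", "rf", "pc_ttest"),
                                maxent3_params = list(),
                                grbm_params = list(),
                                rf_params = list(),
                                seed = 1L) {
  sp <- split_train_test(dataset, spec)
  prep <- fit_preprocessing(rbind(sp$train_A$coords, sp$train_B$coords))
  xa <- apply_preprocessing(prep, sp$train_A$coords)
  xb <- apply_preprocessing(prep, sp$train_B$coords)
  xt <- apply_preprocessing(prep, rbind(sp$test_A$coords, sp$test_B$coords))
  lab <- rep(c(TRUE, FALSE), c(nrow(sp$test_A$coords),
                               nrow(sp$test_B$coords)))
  mom <- function(x, order) moment_statistics(x, max_order = order)

  fit_pair <- function(method) {
    switch(method,
      maxent1 = list(A = fit_independent_maxent(mom(xa, 2L)),
                     B = fit_independent_maxent(mom(xb, 2L))),
      maxent2 = list(A = fit_gaussian_maxent(mom(xa, 2L)),
                     B = fit_gaussian_maxent(mom(xb, 2L))),
      maxent3 = {
        fa <- fit_cubic_maxent(mom(xa, 3L), learn_params = maxent3_params,
                               seed = seed + 31L)
        fb <- fit_cubic_maxent(mom(xb, 3L), learn_params = maxent3_params,
                               seed = seed + 32L)
        list(A = estimate_log_z3(fa, seed = seed + 33L),
             B = estimate_log_z3(fb, seed = seed + 34L))
      },
      grbm = {
        ga <- do.call(train_grbm, c(list(xa), grbm_params,
                                    list(seed = seed + 41L)))
        gb <- do.call(train_grbm, c(list(xb), grbm_params,
                                    list(seed = seed + 42L)))
        list(A = estimate_log_z_ais(ga, seed = seed + 43L),
             B = estimate_log_z_ais(gb, seed = seed + 44L))
      })
  }

  results <- list()
  for (method in methods) {
    res <- tryCatch({
      scores <- if (method == "rf") {
        rf_scores(rbind(xa, xb),
                  rep(c(TRUE, FALSE), c(nrow(xa), nrow(xb))),
                  xt, rf_params, seed = seed + 51L)
      } else if (method == "pc_ttest") {
        pc_ttest_scores(xa, xb, xt)
      } else {
        fits <- fit_pair(method)
        likelihood_ratio_scores(fits$A, fits$B, xt)
      }
      roc <- roc_analysis(scores, lab)
      list(auroc = roc$auroc, max_accuracy = roc$max_accuracy, roc = roc)
    }, error = function(e) list(error = conditionMessage(e)))
    results[[method]] <- res
  }
  structure(list(methods = results,
                 n_train = nrow(xa) + nrow(xb), n_test = nrow(xt),
                 seeds = list(split = spec$seed, fit = seed),
                 split_unit = spec$unit,
                 train_fraction = spec$train_fraction),
            class = "gender_report")
}

#' @export
print.gender_report <- function(x, ...) {
  cat(sprintf("gender_report: %d train / %d test vectors (%s split)\n",
              x$n_train, x$n_test, x$split_unit))
  for (m in names(x$methods)) {
    r <- x$methods[[m]]
    if (!is.null(r$error)) {
      cat(sprintf("  %-9s FAILED: %s\n", m, r$error))
    } else {
      cat(sprintf("  %-9s auROC = %.3f  max accuracy = %.3f\n",
                  m, r$auroc, r$max_accuracy))
    }
  }
  invisible(x)
}

#' Write a gender report (JSON summary plus per-method ROC TSVs)
#'
#' @param report `gender_report`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_gender_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- lapply(report$methods, function(r) {
    if (!is.null(r$error)) list(error = r$error) else
      list(auroc = r$auroc, max_accuracy = r$max_accuracy)
  })
  jsonlite::write_json(
    list(methods = summ, n_train = report$n_train, n_test = report$n_test,
         seeds = report$seeds, split_unit = report$split_unit),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  for (m in names(report$methods)) {
    r <- report$methods[[m]]
    if (is.null(r$error)) {
      utils::write.table(
        data.frame(threshold = r$roc$thresholds, fpr = r$roc$fpr,
                   tpr = r$roc$tpr),
        file.path(dir, paste0(m, "_roc.tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}
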