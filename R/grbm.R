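# Gaussian-Bernoulli Restricted Boltzmann Machine.
#
# Energy convention (Gaussian visible units v, binary hidden units h):
#   E(v, h) = sum_i (v_i - b_i)^2 / (2 sigma_i^2) - sum_j c_j h_j
#             - sum_ij (v_i / sigma_i^2) W_ij h_j
# Marginalising the hidden layer gives the free energy
#   F(v) = sum_i (v_i - b_i)^2 / (2 sigma_i^2)
#          - sum_j softplus(c_j + sum_i v_i W_ij / sigma_i^2)
# so the visible marginal is exp(-F(v)) / Z. Hidden marginalisation induces
# effective interactions of all orders among the visibles, which is what
# makes the GRBM the most expressive model in the comparison.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Construct a GRBM model
#'
#' @param W D x N_h coupling matrix.
#' @param b visible biases (length D).
#' @param c_h hidden biases (length N_h).
#' @param sigma visible scales (length D, default 1: standardised data).
#' @return object of class `grbm`.
#' @export
grbm_model <- function(W, b, c_h, sigma = rep(1, length(b))) {
  W <- as.matrix(W)
  stopifnot(nrow(W) == length(b), ncol(W) == length(c_h),
            length(sigma) == length(b), all(sigma > 0), ncol(W) >= 1L)
  structure(list(W = W, b = b, c = c_h, sigma = sigma,
                 d = length(b), n_hidden = length(c_h),
                 log_z = NULL, log_z_stderr = NULL, training = NULL),
            class = c("grbm", "facemaxent_model"))
}

# hidden pre-activation for a batch of visibles (rows)
hidden_input <- function(model, v) {
  sweep(sweep(v, 2L, model$sigma^2, "/") %*% model$W, 2L, model$c, "+")
}

#' GRBM free energy
#'
#' Negative log of the hidden-marginalised unnormalised density; computed
#' with an overflow-safe softplus.
#'
#' @param model `grbm`.
#' @param v numeric vector of length D or an S x D matrix.
#' @return numeric vector.
#' @export
free_energy <- function(model, v) {
  x <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
  quad <- rowSums(sweep(x, 2L, model$b)^2 /
                    matrix(2 * model$sigma^2, nrow(x), model$d, byrow = TRUE))
  drop(quad - rowSums(softplus(hidden_input(model, x))))
}

#' Train a GRBM with contrastive divergence
#'
#' CD-k stochastic gradient training with minibatches and momentum; visible
#' scales are held fixed (unit on standardised data). The per-epoch mean
#' squared reconstruction error is recorded.
#'
#' @param fluct `fluctuation_data` (standardised) or an S x D matrix.
#' @param n_hidden number of hidden units.
#' @param train_params list overriding any of: `cd_k` (1), `batch_size`
#'   (64), `learning_rate` (5e-3), `epochs` (500), `momentum_start` (0.5),
#'   `momentum_final` (0.9), `momentum_switch` (5), `weight_init_sd` (0.01),
#'   `learn_sigma` (TRUE), `sigma_learning_rate` (`learning_rate / 5`,
#'   applied to log sigma^2). Learnable visible scales matter even on
#'   standardised data: with sigma fixed at 1 the conditional noise already
#'   exhausts the unit data variance and hidden units cannot model shared
#'   variance, so the marginal covariance is structurally biased.
#' @param seed integer seed.
#' @return trained `grbm` with `training` metadata (reconstruction-error
#'   trace, parameters, seed).
#' @export
train_grbm <- function(fluct, n_hidden = 20L, train_params = list(),
                       seed = NULL) {
  x <- if (is.matrix(fluct)) fluct else fluct$deltas
  tp <- modifyList(list(cd_k = 1L, batch_size = 64L, learning_rate = 5e-3,
                        epochs = 500L, momentum_start = 0.5,
                        momentum_final = 0.9, momentum_switch = 5L,
                        weight_init_sd = 0.01, learn_sigma = TRUE,
                        sigma_learning_rate = NULL), train_params)
  if (is.null(tp$sigma_learning_rate)) {
    tp$sigma_learning_rate <- tp$learning_rate / 5
  }
  d <- ncol(x)
  S <- nrow(x)
  with_seed(seed, {
    W <- matrix(stats::rnorm(d * n_hidden, sd = tp$weight_init_sd),
                d, n_hidden)
    b <- colMeans(x)
    c_h <- rep(0, n_hidden)
    sigma <- rep(1, d)
    vW <- matrix(0, d, n_hidden); vb <- rep(0, d); vc <- rep(0, n_hidden)
    recon <- numeric(tp$epochs)
    model <- grbm_model(W, b, c_h, sigma)
    for (epoch in seq_len(tp$epochs)) {
      mom <- if (epoch < tp$momentum_switch) tp$momentum_start else
        tp$momentum_final
      perm <- sample.int(S)
      err <- 0
      nb <- 0L
      for (start in seq(1L, S, by = tp$batch_size)) {
        idx <- perm[start:min(start + tp$batch_size - 1L, S)]
        v0 <- x[idx, , drop = FALSE]
        m <- length(idx)
        ph0 <- sigmoid(hidden_input(model, v0))
        vk <- v0
        phk <- ph0
        for (k in seq_len(tp$cd_k)) {
          hk <- (matrix(stats::runif(m * n_hidden), m) < phk) * 1
          mu_v <- sweep(hk %*% t(model$W), 2L, model$b, "+")
          vk <- mu_v + matrix(stats::rnorm(m * d), m, d) *
            matrix(model$sigma, m, d, byrow = TRUE)
          phk <- sigmoid(hidden_input(model, vk))
        }
        inv_s2 <- 1 / model$sigma^2
        gW <- (crossprod(v0 * matrix(inv_s2, m, d, byrow = TRUE), ph0) -
                 crossprod(vk * matrix(inv_s2, m, d, byrow = TRUE), phk)) / m
        gb <- colMeans(v0 - vk) * inv_s2
        gc <- colMeans(ph0) - colMeans(phk)
        vW <- mom * vW + tp$learning_rate * gW
        vb <- mom * vb + tp$learning_rate * gb
        vc <- mom * vc + tp$learning_rate * gc
        model$W <- model$W + vW
        model$b <- model$b + vb
        model$c <- model$c + vc
        if (tp$learn_sigma) {
          # gradient on log sigma^2:
          # < (v-b)^2 / (2 sigma^2) - v (W p_h) / sigma^2 >_data - <.>_model
          term <- function(v, ph) {
            wh <- ph %*% t(model$W)
            colMeans(sweep(v, 2L, model$b)^2) / (2 * model$sigma^2) -
              colMeans(v * wh) / model$sigma^2
          }
          gs <- term(v0, ph0) - term(vk, phk)
          model$sigma <- pmax(sqrt(exp(log(model$sigma^2) +
                                         tp$sigma_learning_rate * gs)), 0.05)
        }
        if (any(!is.finite(model$W)) || any(!is.finite(model$b)) ||
            any(!is.finite(model$c)) || any(!is.finite(model$sigma))) {
          stop(sprintf("training failure: non-finite parameter at epoch %d",
                       epoch))
        }
        # deterministic one-step reconstruction for the error trace
        vrec <- sweep(ph0 %*% t(model$W), 2L, model$b, "+")
        err <- err + mean((v0 - vrec)^2)
        nb <- nb + 1L
      }
      recon[epoch] <- err / nb
    }
    model$training <- list(reconstruction_error = recon, params = tp,
                           seed = seed, n_samples = S)
    model
  })
}

#' Block-Gibbs sampling from a GRBM
#'
#' Alternates the Bernoulli hidden and Gaussian visible conditionals of the
#' bipartite graph; returns the final visible state of `n` independent
#' chains started from the visible prior `N(b, sigma^2)`.
#'
#' @param model `grbm`.
#' @param n number of samples (chains).
#' @param gibbs_steps alternations per chain.
#' @param seed integer seed.
#' @return `fluctuation_data` with the n x D sample matrix.
#' @export
sample_grbm <- function(model, n, gibbs_steps = 200L, seed = NULL) {
  stopifnot(n >= 1)
  d <- model$d
  with_seed(seed, {
    v <- sweep(matrix(stats::rnorm(n * d), n, d) *
                 matrix(model$sigma, n, d, byrow = TRUE), 2L, model$b, "+")
    for (t in seq_len(gibbs_steps)) {
      ph <- sigmoid(hidden_input(model, v))
      h <- (matrix(stats::runif(n * model$n_hidden), n) < ph) * 1
      mu_v <- sweep(h %*% t(model$W), 2L, model$b, "+")
      v <- mu_v + matrix(stats::rnorm(n * d), n, d) *
        matrix(model$sigma, n, d, byrow = TRUE)
    }
    structure(list(deltas = v, mean = rep(0, d), scales = rep(1, d),
                   n_landmarks = d / 2L),
              class = "fluctuation_data")
  })
}

# closed-form log Z of the W = 0 model with the same biases and scales
grbm_base_log_z <- function(model) {
  sum(log(sqrt(2 * pi) * model$sigma)) + sum(softplus(model$c))
}

#' Annealed importance sampling estimate of the GRBM log-partition function
#'
#' Anneals from the factorised `W = 0` base model (same biases and scales,
#' closed-form normalisation) to the target along the path `W -> beta W`
#' with a uniform beta ladder, taking one block-Gibbs transition per rung.
#' The estimate and its delta-method standard error over runs are stored on
#' the model.
#'
#' @param model `grbm`.
#' @param n_runs independent AIS chains (default 100).
#' @param n_temperatures ladder length (default 1000).
#' @param seed integer seed.
#' @return model with `log_z`, `log_z_stderr` and `log_z_n_runs` set.
#' @export
estimate_log_z_ais <- function(model, n_runs = 100L, n_temperatures = 1000L,
                               seed = NULL) {
  d <- model$d
  betas <- seq(0, 1, length.out = n_temperatures + 1L)
  model_at <- function(beta) {
    m <- model; m$W <- beta * model$W; m
  }
  with_seed(seed, {
    v <- sweep(matrix(stats::rnorm(n_runs * d), n_runs, d) *
                 matrix(model$sigma, n_runs, d, byrow = TRUE),
               2L, model$b, "+")
    lw <- rep(0, n_runs)
    f_prev <- free_energy(model_at(0), v)
    for (k in seq(2L, length(betas))) {
      mk <- model_at(betas[k])
      lw <- lw + f_prev - free_energy(mk, v)
      ph <- sigmoid(hidden_input(mk, v))
      h <- (matrix(stats::runif(n_runs * model$n_hidden), n_runs) < ph) * 1
      mu_v <- sweep(h %*% t(mk$W), 2L, mk$b, "+")
      v <- mu_v + matrix(stats::rnorm(n_runs * d), n_runs, d) *
        matrix(mk$sigma, n_runs, d, byrow = TRUE)
      f_prev <- free_energy(mk, v)
    }
    m <- max(lw)
    w <- exp(lw - m)
    log_ratio <- m + log(mean(w))
    se <- stats::sd(w) / (mean(w) * sqrt(n_runs))
    if (se > 1) warning(sprintf("AIS stderr %.2f nat > 1: unreliable", se))
    model$log_z <- grbm_base_log_z(model) + log_ratio
    model$log_z_stderr <- se
    model$log_z_n_runs <- n_runs
    model
  })
}

#' GRBM log-density of visible configurations
#'
#' `-F(v) - log Z`; requires the partition function estimate.
#'
#' @param model `grbm` with `log_z` set.
#' @param v vector or matrix of visibles.
#' @return numeric vector.
#' @export
grbm_log_density <- function(model, v) {
  if (is.null(model$log_z)) {
    stop("log_z missing: run estimate_log_z_ais() first")
  }
  -free_energy(model, v) - model$log_z
}

#' Exact GRBM partition function by hidden-state enumeration
#'
#' For small hidden layers (N_h <= 12) sums the analytic Gaussian integral
#' over all 2^N_h hidden configurations. Used as an exactness oracle for
#' the AIS estimator.
#'
#' @param model `grbm`.
#' @return exact log Z.
#' @export
grbm_log_z_exact <- function(model) {
  nh <- model$n_hidden
  stopifnot(nh <= 12L)
  states <- as.matrix(expand.grid(rep(list(c(0, 1)), nh)))
  # For fixed h: integral over v of exp(-E) =
  #   prod_i sqrt(2 pi) sigma_i * exp(c'h + ||W h / sigma||^2 / 2 + b'(Wh)/sigma^2)
  lw <- apply(states, 1L, function(h) {
    wh <- drop(model$W %*% h)
    sum(model$c * h) + sum((wh / model$sigma)^2) / 2 +
      sum(model$b * wh / model$sigma^2)
  })
  sum(log(sqrt(2 * pi) * model$sigma)) + log_mean_exp(lw) + nh * log(2)
}
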