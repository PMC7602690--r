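# Third-order Maximum-Entropy model: cubic Hamiltonian, hypercube-truncated
# density, Metropolis sampling, moment-matching gradient ascent, and
# importance-sampling normalisation.
#
# The density is L(Delta) = exp(-(H2 + H3)) * 1(|Delta_u| <= B) / Z3 with
# H3 = (1/6) sum_{u,v,k} Delta_u Delta_v Delta_k Q_{uvk}. The hypercube
# factor makes the cubic Hamiltonian normalisable; B = 6 on standardised
# data, so truncation is negligible for a near-Gaussian fit.

#' Construct a cubic MaxEnt model
#'
#' @param h field vector (length D).
#' @param J symmetric D x D coupling matrix.
#' @param Q third-order couplings: either a dense symmetric D x D x D array
#'   or a triple table as returned by [triplet_index()] with a `value`
#'   column. Stored internally as the triple table.
#' @param B hypercube half-width in standardised units (default 6).
#' @param mean model mean (default zero vector; data are centred).
#' @return object of class `cubic_maxent`.
#' @export
cubic_maxent_model <- function(h, J, Q = NULL, B = 6, mean = NULL) {
  d <- length(h)
  stopifnot(nrow(J) == d, ncol(J) == d, B > 0)
  trip <- triplet_index(d)
  if (is.null(Q)) {
    trip$value <- 0
  } else if (is.array(Q) && length(dim(Q)) == 3L) {
    trip$value <- Q[cbind(trip$i, trip$j, trip$k)]
  } else {
    stopifnot(is.data.frame(Q), nrow(Q) == nrow(trip))
    trip$value <- Q$value
  }
  if (is.null(mean)) mean <- rep(0, d)
  structure(list(h = h, J = (J + t(J)) / 2, Q = trip, B = B, mean = mean,
                 d = d, log_z3 = NULL, log_z3_stderr = NULL,
                 fit_diagnostics = NULL),
            class = c("cubic_maxent", "facemaxent_model"))
}

#' Cubic Hamiltonian H2 + H3
#'
#' `H2 = (1/2) Delta' J Delta + h' Delta` and `H3 = (1/6) * sum over all
#' ordered triples of Delta_u Delta_v Delta_k Q_{uvk}`, evaluated from the
#' stored non-decreasing triples with their permutation multiplicities.
#'
#' @param delta vector of length D or an S x D matrix.
#' @param h,J,Q model parameters; `Q` a triple table with `value` (or a
#'   dense array, or NULL for zero).
#' @return numeric vector of Hamiltonian values.
#' @export
cubic_hamiltonian <- function(delta, h, J, Q = NULL) {
  x <- if (is.matrix(delta)) delta else matrix(delta, nrow = 1L)
  h2 <- rowSums((x %*% J) * x) / 2 + drop(x %*% h)
  if (is.null(Q)) return(drop(h2))
  if (is.array(Q) && length(dim(Q)) == 3L) {
    trip <- triplet_index(ncol(x))
    trip$value <- Q[cbind(trip$i, trip$j, trip$k)]
    Q <- trip
  }
  nz <- Q$value != 0
  if (!any(nz)) return(drop(h2))
  qq <- Q[nz, , drop = FALSE]
  h3 <- drop(triple_products(x, qq) %*% (qq$mult * qq$value)) / 6
  drop(h2 + h3)
}

hamiltonian_of_model <- function(model, x) {
  cubic_hamiltonian(x, model$h, model$J, model$Q)
}

#' Metropolis sampler for the cubic MaxEnt density
#'
#' Independent chains with isotropic Gaussian proposals; any proposal
#' leaving the hypercube `[-B, B]^D` is rejected. The proposal scale is
#' adapted towards a target acceptance rate during burn-in, then frozen.
#'
#' @param model `cubic_maxent`.
#' @param n number of pooled post-burn-in draws to return.
#' @param step_scale initial proposal standard deviation.
#' @param burn_in burn-in sweeps per chain.
#' @param thin keep one state every `thin` sweeps.
#' @param n_chains number of parallel chains.
#' @param seed integer seed.
#' @param init optional n_chains x D matrix of starting states.
#' @return `fluctuation_data` with an attribute-like field `acceptance_rate`
#'   and `final_states` (for persistent-chain reuse).
#' @export
metropolis_sample <- function(model, n, step_scale = 0.5, burn_in = 500L,
                              thin = 5L, n_chains = 32L, seed = NULL,
                              init = NULL) {
  d <- model$d
  B <- model$B
  with_seed(seed, {
    x <- if (is.null(init)) {
      matrix(stats::rnorm(n_chains * d, sd = min(1, B / 3)), n_chains, d)
    } else init
    x[abs(x) > B] <- 0
    hx <- hamiltonian_of_model(model, x)
    scale <- step_scale
    # burn-in with Robbins-Monro scale adaptation towards ~40% acceptance
    for (t in seq_len(burn_in)) {
      prop <- x + matrix(stats::rnorm(n_chains * d, sd = scale), n_chains, d)
      inside <- rowSums(abs(prop) > B) == 0L
      hp <- rep(Inf, n_chains)
      if (any(inside)) {
        hp[inside] <- hamiltonian_of_model(model, prop[inside, , drop = FALSE])
      }
      acc <- log(stats::runif(n_chains)) < (hx - hp)
      x[acc, ] <- prop[acc, , drop = FALSE]
      hx[acc] <- hp[acc]
      rate <- mean(acc)
      scale <- scale * exp((rate - 0.4) / sqrt(t + 10))
    }
    n_keep_per_chain <- ceiling(n / n_chains)
    draws <- vector("list", n_keep_per_chain)
    n_acc <- 0L
    n_tot <- 0L
    for (s in seq_len(n_keep_per_chain)) {
      for (tt in seq_len(thin)) {
        prop <- x + matrix(stats::rnorm(n_chains * d, sd = scale), n_chains, d)
        inside <- rowSums(abs(prop) > B) == 0L
        hp <- rep(Inf, n_chains)
        if (any(inside)) {
          hp[inside] <- hamiltonian_of_model(model,
                                             prop[inside, , drop = FALSE])
        }
        acc <- log(stats::runif(n_chains)) < (hx - hp)
        x[acc, ] <- prop[acc, , drop = FALSE]
        hx[acc] <- hp[acc]
        n_acc <- n_acc + sum(acc)
        n_tot <- n_tot + n_chains
      }
      draws[[s]] <- x
    }
    rate <- n_acc / n_tot
    if (rate < 0.05 || rate > 0.95) {
      warning(sprintf("Metropolis acceptance rate %.3f outside [0.05, 0.95]",
                      rate))
    }
    out <- do.call(rbind, draws)[seq_len(n), , drop = FALSE]
    structure(list(deltas = out, mean = rep(0, d), scales = rep(1, d),
                   n_landmarks = d / 2L, acceptance_rate = rate,
                   final_states = x, proposal_scale = scale),
              class = "fluctuation_data")
  })
}

# One Metropolis sweep over persistent chains; returns updated state list.
mh_sweep <- function(model, x, hx, scale, n_steps = 1L) {
  n_chains <- nrow(x)
  d <- ncol(x)
  B <- model$B
  n_acc <- 0L
  for (tt in seq_len(n_steps)) {
    prop <- x + matrix(stats::rnorm(n_chains * d, sd = scale), n_chains, d)
    inside <- rowSums(abs(prop) > B) == 0L
    hp <- rep(Inf, n_chains)
    if (any(inside)) {
      hp[inside] <- hamiltonian_of_model(model, prop[inside, , drop = FALSE])
    }
    acc <- log(stats::runif(n_chains)) < (hx - hp)
    x[acc, ] <- prop[acc, , drop = FALSE]
    hx[acc] <- hp[acc]
    n_acc <- n_acc + sum(acc)
  }
  list(x = x, hx = hx, rate = n_acc / (n_steps * n_chains))
}

#' Fit the third-order MaxEnt model by moment-matching gradient ascent
#'
#' Exponential-family maximum likelihood: each parameter moves its conjugate
#' moment towards the data value; the ascent direction for a coupling is
#' (model moment - data moment), estimated from persistent Metropolis
#' chains. Gradients are taken with respect to the independent entries
#' (`mu <= nu <= kappa`) so moment matching is entrywise. Convergence is
#' declared when the largest absolute residual between (smoothed) model
#' moments and data moments falls below `tol`.
#'
#' @param data_moments `moment_statistics` with `third` (order 3), computed
#'   on reduced standardised data.
#' @param init optional `gaussian_maxent` used to initialise `(h, J)`;
#'   `Q` always starts at zero so the ascent starts from the Gaussian fit.
#' @param learn_params list overriding any of: `n_chains` (128),
#'   `mh_steps` (5) sweeps per iteration, `learning_rate` (0.05 with 1/sqrt(t)
#'   decay), `tol` (0.02), `max_iters` (2000), `B` (6), `ema` (0.05)
#'   smoothing weight for model-moment tracking, `burn_in` (300),
#'   `grad_clip` (0.5) elementwise gradient clip, `q_max` (1) box bound on
#'   third-order couplings (keeps the density interior-dominated during
#'   the ascent).
#' @param seed integer seed.
#' @return `cubic_maxent` with `fit_diagnostics` (residual trace, iterations,
#'   convergence flag, acceptance rate).
#' @export
fit_cubic_maxent <- function(data_moments, init = NULL, learn_params = list(),
                             seed = NULL) {
  if (is.null(data_moments$third)) {
    stop("data_moments must include third-order moments (max_order = 3)")
  }
  lp <- modifyList(list(n_chains = 128L, mh_steps = 5L, learning_rate = 0.05,
                        tol = 0.02, max_iters = 2000L, B = 6,
                        ema = 0.05, burn_in = 300L, grad_clip = 0.5,
                        q_max = 1), learn_params)
  d <- data_moments$d
  if (is.null(init)) init <- fit_gaussian_maxent(data_moments)
  J <- init$J
  # In the H = (1/2) d'Jd + h'd parameterisation a Gaussian with mean m has
  # h = -J m (zero for centred data).
  h <- -drop(init$J %*% init$mean)
  model <- cubic_maxent_model(h, J, NULL, B = lp$B)
  trip <- model$Q
  m1_data <- data_moments$mean
  m2_data <- data_moments$cov
  m3_data <- data_moments$third$value

  with_seed(seed, {
    x <- matrix(stats::rnorm(lp$n_chains * d, sd = 1), lp$n_chains, d)
    x[abs(x) > lp$B] <- 0
    hx <- hamiltonian_of_model(model, x)
    scale <- 2.4 / sqrt(d)
    for (t in seq_len(lp$burn_in)) {
      sw <- mh_sweep(model, x, hx, scale)
      x <- sw$x; hx <- sw$hx
      scale <- scale * exp((sw$rate - 0.4) / sqrt(t + 10))
    }
    # smoothed model moments
    m1 <- colMeans(x)
    m2 <- crossprod(x) / nrow(x)
    m3 <- colMeans(triple_products(x, trip))
    resid_trace <- numeric(0)
    converged <- FALSE
    grow <- 0L
    prev_resid <- Inf
    rate <- NA_real_
    for (t in seq_len(lp$max_iters)) {
      sw <- mh_sweep(model, x, hx, scale, n_steps = lp$mh_steps)
      x <- sw$x; hx <- sw$hx; rate <- sw$rate
      w <- lp$ema
      cur1 <- colMeans(x)
      cur2 <- crossprod(x) / nrow(x)
      cur3 <- colMeans(triple_products(x, trip))
      m1 <- (1 - w) * m1 + w * cur1
      m2 <- (1 - w) * m2 + w * cur2
      m3 <- (1 - w) * m3 + w * cur3
      g1 <- m1 - m1_data
      g2 <- m2 - m2_data
      g3 <- m3 - m3_data
      # residuals are relative to the moment scale (equal to the absolute
      # residual on standardised data, where moments are O(1))
      rel_resid <- function(a1, a2, a3) {
        max(max(abs(a1 - m1_data) / pmax(1, abs(m1_data))),
            max(abs(a2 - m2_data) / pmax(1, abs(m2_data))),
            max(abs(a3 - m3_data) / pmax(1, abs(m3_data))))
      }
      resid <- rel_resid(m1, m2, m3)
      resid_trace <- c(resid_trace, resid)
      if (resid < lp$tol) { converged <- TRUE; break }
      # divergence check on the raw (unsmoothed) residual: 50 consecutive
      # increases of this noisy series only happen in a genuine blow-up
      resid_raw <- rel_resid(cur1, cur2, cur3)
      grow <- if (resid_raw > prev_resid) grow + 1L else 0L
      prev_resid <- resid_raw
      if (grow >= 50L) {
        stop(sprintf(
          "learning failure: moment residual grew for 50 iterations (%.4f)",
          resid_raw))
      }
      eta <- lp$learning_rate / sqrt(t)
      clip <- function(g) pmin(pmax(g, -lp$grad_clip), lp$grad_clip)
      model$h <- model$h + eta * clip(g1)
      g2s <- clip((g2 + t(g2)) / 2)
      model$J <- model$J + eta * g2s
      # projected ascent: couplings beyond q_max put the density's mass on
      # the hypercube boundary, where small noisy samples push the fit
      model$Q$value <- pmin(pmax(model$Q$value + eta * clip(g3),
                                 -lp$q_max), lp$q_max)
      hx <- hamiltonian_of_model(model, x)  # parameters moved
    }
    model$fit_diagnostics <- list(residual_trace = resid_trace,
                                  iterations = length(resid_trace),
                                  converged = converged,
                                  final_residual = prev_resid,
                                  acceptance_rate = rate,
                                  proposal_scale = scale)
    model$mh_state <- list(x = x, scale = scale)
    model
  })
}

# H3 alone, vectorised over rows
h3_of_model <- function(model, x) {
  nz <- model$Q$value != 0
  if (!any(nz)) return(rep(0, nrow(x)))
  qq <- model$Q[nz, , drop = FALSE]
  drop(triple_products(x, qq) %*% (qq$mult * qq$value)) / 6
}

# Draw from the (full-rank) Gaussian part exp(-H2); returns draws and log Z2.
gaussian_part_sampler <- function(model) {
  d <- model$d
  g <- sym_pseudo_inverse(model$J)
  if (g$rank < d) stop("Gaussian part is rank deficient: no proper proposal")
  mu <- drop(-g$pinv %*% model$h)
  log_z2 <- (d / 2) * log(2 * pi) - g$log_pdet / 2 +
    drop(model$h %*% g$pinv %*% model$h) / 2
  sdv <- sqrt(1 / g$eigenvalues)
  u <- g$vectors
  list(draw = function(n) {
    z <- matrix(stats::rnorm(n * d), n, d)
    sweep(sweep(z, 2L, sdv, "*") %*% t(u), 2L, mu, "+")
  }, log_z2 = log_z2)
}

#' Importance-sampling estimate of the cubic model's log-normalisation
#'
#' Uses the model's own Gaussian part as the proposal:
#' `log Z3 = log Z2 + log mean(exp(-H3) * 1(hypercube))` over proposal
#' draws, with a delta-method standard error. When the cubic term makes the
#' single-stage weights degenerate (effective sample size below
#' `min_ess`), the estimator anneals instead: the same Gaussian base is
#' tempered along `exp(-H2 - beta * H3)` restricted to the hypercube with a
#' uniform beta ladder and one Metropolis sweep per rung (standard annealed
#' importance sampling), which keeps the weights controlled even when the
#' target is boundary-dominated.
#'
#' @param model `cubic_maxent`.
#' @param n_samples proposal draws for the single-stage estimate
#'   (default 1e5).
#' @param seed integer seed.
#' @param n_temperatures beta rungs used if annealing is needed
#'   (default 200).
#' @param n_runs annealing chains (default 200).
#' @param min_ess effective-sample-size threshold below which the
#'   single-stage estimate is abandoned for annealing (default 100).
#' @return the model with `log_z3`, `log_z3_stderr`, `log_z3_ess` and
#'   `log_z3_method` set.
#' @export
estimate_log_z3 <- function(model, n_samples = 1e5, seed = NULL,
                            n_temperatures = 200L, n_runs = 200L,
                            min_ess = 100) {
  gp <- gaussian_part_sampler(model)
  with_seed(seed, {
    x <- gp$draw(n_samples)
    inside <- rowSums(abs(x) > model$B) == 0L
    lw <- rep(-Inf, n_samples)
    if (any(inside)) lw[inside] <- -h3_of_model(model,
                                                x[inside, , drop = FALSE])
    m <- max(lw)
    w <- exp(lw - m)
    wbar <- mean(w)
    ess <- sum(w)^2 / sum(w^2)
    if (ess >= min_ess) {
      model$log_z3 <- gp$log_z2 + m + log(wbar)
      model$log_z3_stderr <- stats::sd(w) / (wbar * sqrt(n_samples))
      model$log_z3_ess <- ess
      model$log_z3_method <- "importance_sampling"
      return(model)
    }
    # annealed path: beta ladder over the cubic term
    betas <- seq(0, 1, length.out = n_temperatures + 1L)
    v <- gp$draw(n_runs)
    # fold the cube indicator into the first rung: restart any chain
    # outside the cube (negligible mass for a standardised Gaussian, B = 6)
    out <- rowSums(abs(v) > model$B) > 0L
    tries <- 0L
    while (any(out) && tries < 100L) {
      v[out, ] <- gp$draw(sum(out))
      out <- rowSums(abs(v) > model$B) > 0L
      tries <- tries + 1L
    }
    lw <- rep(0, n_runs)
    h3v <- h3_of_model(model, v)
    scale <- 2.4 / sqrt(model$d)
    mb <- model
    for (k in seq(2L, length(betas))) {
      lw <- lw - (betas[k] - betas[k - 1L]) * h3v
      mb$Q$value <- betas[k] * model$Q$value
      hv <- cubic_hamiltonian(v, mb$h, mb$J, mb$Q)
      sw <- mh_sweep(mb, v, hv, scale, n_steps = 1L)
      v <- sw$x
      scale <- scale * exp((sw$rate - 0.4) / sqrt(k + 10))
      h3v <- h3_of_model(model, v)
    }
    m <- max(lw)
    w <- exp(lw - m)
    wbar <- mean(w)
    ess2 <- sum(w)^2 / sum(w^2)
    if (ess2 < min_ess / 10) {
      stop(sprintf(
        "unreliable normalisation: annealed effective sample size %.1f%s",
        ess2, "; increase n_temperatures or n_runs"))
    }
    model$log_z3 <- gp$log_z2 + m + log(wbar)
    model$log_z3_stderr <- stats::sd(w) / (wbar * sqrt(n_runs))
    model$log_z3_ess <- ess2
    model$log_z3_method <- "annealed_importance_sampling"
    model
  })
}

#' Log-density of the cubic MaxEnt model
#'
#' Inside the hypercube returns `-(H2 + H3) - log Z3`; outside it returns a
#' finite log-zero sentinel (so classifiers can still rank off-support
#' points) rather than -Inf or an error.
#'
#' @param model `cubic_maxent` with `log_z3` set (see [estimate_log_z3()]).
#' @param delta vector or S x D matrix.
#' @return numeric vector.
#' @export
cubic_log_density <- function(model, delta) {
  if (is.null(model$log_z3)) {
    stop("log_z3 missing: run estimate_log_z3() first")
  }
  x <- if (is.matrix(delta)) delta else matrix(delta, nrow = 1L)
  out <- rep(LOG_ZERO, nrow(x))
  inside <- rowSums(abs(x) > model$B) == 0L
  if (any(inside)) {
    hh <- hamiltonian_of_model(model, x[inside, , drop = FALSE])
    out[inside] <- -hh - model$log_z3
  }
  out
}
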