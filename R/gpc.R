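#' Labeled sample set on a mesh, with fidelity tags
#'
#' Container for binary-labeled pacing/observation sites on a surface
#' mesh. Each sample is a (vertex, label, fidelity) triple; a site may
#' carry both a low- and a high-fidelity label (they are distinct
#' observations) but duplicate labels for the same (vertex, fidelity)
#' pair are rejected.
#'
#' @param vertices integer vector of 1-based vertex indices.
#' @param labels binary labels (0/1).
#' @param fidelity `"high"` (default) or `"low"`, scalar or per-sample.
#' @param n_vertices optional vertex count for index validation.
#' @return object of class `fidelity_dataset` (a data frame with columns
#'   `vertex`, `label`, `fidelity`).
#' @export
fidelity_dataset <- function(vertices, labels, fidelity = "high",
                             n_vertices = NULL) {
  vertices <- as.integer(vertices)
  if (length(labels) != length(vertices))
    stop("labels and vertices lengths differ")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  fidelity <- rep_len(as.character(fidelity), length(vertices))
  if (!all(fidelity %in% c("low", "high")))
    stop("fidelity must be 'low' or 'high'")
  if (any(vertices < 1L)) stop("vertex indices must be >= 1")
  if (!is.null(n_vertices) && any(vertices > n_vertices))
    stop("vertex index exceeds mesh size ", n_vertices)
  key <- paste(vertices, fidelity)
  if (anyDuplicated(key))
    stop("duplicate label for vertex/fidelity pair: ",
         key[duplicated(key)][1])
  structure(data.frame(vertex = vertices, label = as.integer(labels),
                       fidelity = fidelity, stringsAsFactors = FALSE),
            class = c("fidelity_dataset", "data.frame"))
}

#' Inference configuration
#'
#' Settings for the NUTS-based Bayesian inference. Defaults follow the
#' reference analysis: 500 warmup iterations used to adapt the sampler
#' and then discarded, 500 retained samples, one chain, target acceptance
#' probability 0.9, 1,000 eigenpairs (clamped to the available basis) and
#' Matern smoothness `nu = 3/2`.
#'
#' @param n_warmup,n_samples,n_chains positive integers.
#' @param target_accept in (0,1).
#' @param seed integer seed; chain `c` uses `seed + 1000*(c-1)`.
#' @param n_eig number of eigenpairs used by the kernel.
#' @param nu Matern smoothness (fixed, not inferred).
#' @param jitter relative diagonal jitter added to training covariance
#'   matrices for numerical stability.
#' @param n_prob_draws latent draws used to summarize class probabilities.
#' @param eta_scale scale of the half-normal prior on `eta`. The
#'   reference value is 1e4; because the logistic likelihood saturates
#'   for |f| beyond ~10 an override is allowed.
#' @return object of class `inference_config`.
#' @export
inference_config <- function(n_warmup = 500, n_samples = 500, n_chains = 1,
                             target_accept = 0.9, seed = 1, n_eig = 1000,
                             nu = 1.5, jitter = 1e-6, n_prob_draws = 500,
                             eta_scale = 10000) {
  stopifnot(n_warmup >= 1, n_samples >= 1, n_chains >= 1,
            target_accept > 0, target_accept < 1, n_eig >= 1, nu > 0,
            jitter >= 0, n_prob_draws >= 1, eta_scale > 0)
  structure(list(n_warmup = as.integer(n_warmup),
                 n_samples = as.integer(n_samples),
                 n_chains = as.integer(n_chains),
                 target_accept = target_accept, seed = as.integer(seed),
                 n_eig = as.integer(n_eig), nu = nu, jitter = jitter,
                 n_prob_draws = as.integer(n_prob_draws),
                 eta_scale = eta_scale),
            class = "inference_config")
}

# view of the first m eigenpairs of a basis
trunc_basis <- function(basis, m) {
  m <- min(m, basis$n_eig)
  if (m == basis$n_eig) return(basis)
  basis$values <- basis$values[seq_len(m)]
  basis$vectors <- basis$vectors[, seq_len(m), drop = FALSE]
  basis$lumped_norms <- basis$lumped_norms[seq_len(m)]
  basis$n_eig <- m
  basis
}

# log posterior + gradient of the single-fidelity classifier in the
# unconstrained parametrization theta = (a = log eta, b = log ell, w).
# Latent field at data vertices: f = (eta/sqrt(C)) Psi_X (s * w) with
# s_i = (2 nu/ell^2 + lambda_i)^-(nu+1)/2 and C = sum(g_i q_i)/area.
make_lp_single <- function(Psi_X, y, lambda, qn, area, nu, eta_scale,
                           ell_alpha = 1, ell_beta = 1) {
  m <- length(lambda)
  function(theta) {
    a <- theta[1]; b <- theta[2]; w <- theta[-(1:2)]
    eta <- exp(a); ell <- exp(b)
    if (!is.finite(eta) || !is.finite(ell))
      return(list(lp = -Inf, grad = numeric(length(theta))))
    u <- 2 * nu / ell^2 + lambda
    s <- u^(-(nu + 1) / 2)
    g <- s^2
    C <- sum(g * qn) / area
    amp <- eta / sqrt(C)
    sw <- s * w
    f <- as.numeric(Psi_X %*% sw) * amp
    p_log <- -log1p(exp(-abs(f)))              # log sigma(|f|)
    ll <- sum(ifelse(y == 1, ifelse(f >= 0, p_log, f + p_log),
                     ifelse(f >= 0, -f + p_log, p_log)))
    lp <- ll - eta^2 / (2 * eta_scale^2) + a +
      (ell_alpha - 1) * b + (-ell_beta * ell) + b - 0.5 * sum(w^2)
    # note: Gamma(alpha,beta) log-density (alpha-1)log(ell) - beta*ell,
    # plus the log-Jacobian b of ell = exp(b)
    r <- y - 1 / (1 + exp(-f))
    ga <- sum(r * f) + 1 - eta^2 / eta_scale^2
    dsdb <- 2 * nu * (nu + 1) * u^(-(nu + 3) / 2) / ell^2
    dCdb <- 2 * sum(s * dsdb * qn) / area
    dcoef <- dsdb / sqrt(C) - s * dCdb / (2 * C^1.5)
    dfdb <- eta * as.numeric(Psi_X %*% (dcoef * w))
    gb <- sum(r * dfdb) + ell_alpha - ell_beta * ell
    gw <- amp * s * as.numeric(crossprod(Psi_X, r)) - w
    list(lp = lp, grad = c(ga, gb, gw))
  }
}

#' Fit the single-fidelity Gaussian-process classifier
#'
#' Samples the fully Bayesian model
#' `eta ~ HalfNormal(1e4)`, `ell ~ Gamma(1, 1)`, `w_i ~ N(0, 1)`,
#' latent `f` given by the truncated spectral expansion, and
#' `y_i ~ Bernoulli(sigma(f(x_i)))` with the No-U-Turn sampler. The
#' non-centered weight parametrization makes the spectral expansion the
#' sampling representation of the prior, so no covariance factorization
#' is needed inside the sampler.
#'
#' @param dataset a [fidelity_dataset()] with a single fidelity level.
#' @param basis a `spectral_basis` built on the (normalized) mesh the
#'   labels live on.
#' @param config an [inference_config()].
#' @return object of class `gpc_posterior`: posterior draws of
#'   `eta`, `ell` and the weight matrix `W` (`n_draws x n_eig`),
#'   the training data, and sampler diagnostics.
#' @export
gpc_fit <- function(dataset, basis, config = inference_config()) {
  stopifnot(inherits(dataset, "fidelity_dataset"),
            inherits(basis, "spectral_basis"),
            inherits(config, "inference_config"))
  if (nrow(dataset) == 0) stop("empty dataset")
  if (length(unique(dataset$fidelity)) > 1)
    stop("dataset has both fidelities; use gpc_fit_mf()")
  nv <- nrow(basis$vectors)
  if (max(dataset$vertex) > nv) stop("vertex index exceeds basis size")
  if (length(unique(dataset$label)) == 1)
    warning("all labels belong to one class; posterior will be one-sided")
  tb <- trunc_basis(basis, config$n_eig)
  m <- tb$n_eig
  idx <- dataset$vertex
  y <- dataset$label
  Psi_X <- tb$vectors[idx, , drop = FALSE]
  lp <- make_lp_single(Psi_X, y, tb$values, tb$lumped_norms, tb$total_area,
                       config$nu, config$eta_scale,
                       ell_alpha = 1, ell_beta = 1)
  init <- c(0, log(0.5), numeric(m))
  chains <- lapply(seq_len(config$n_chains), function(ch) {
    nuts_sample(lp, init, n_warmup = config$n_warmup,
                n_samples = config$n_samples,
                target_accept = config$target_accept,
                seed = config$seed + 1000L * (ch - 1L))
  })
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  n_div <- sum(vapply(chains, `[[`, integer(1), "n_divergent"))
  div_frac <- n_div / nrow(draws)
  if (div_frac > 0.1)
    warning(sprintf(paste0("NUTS divergence fraction %.1f%% exceeds 10%% ",
                           "(step size %.3g, mean accept %.2f); ",
                           "inference may be unreliable"),
                    100 * div_frac, chains[[1]]$step_size,
                    chains[[1]]$mean_accept))
  structure(list(eta = exp(draws[, 1]), ell = exp(draws[, 2]),
                 W = draws[, -(1:2), drop = FALSE],
                 data = list(vertex = idx, label = y),
                 n_eig = m, nu = config$nu, jitter = config$jitter,
                 basis_checksum = basis$mesh_checksum,
                 diagnostics = list(
                   n_divergent = n_div, divergence_fraction = div_frac,
                   mean_accept = mean(vapply(chains, `[[`, numeric(1),
                                             "mean_accept")),
                   mean_treedepth = mean(vapply(chains, `[[`, numeric(1),
                                                "mean_treedepth")),
                   step_size = vapply(chains, `[[`, numeric(1),
                                      "step_size"))),
            class = "gpc_posterior")
}

#' @export
print.gpc_posterior <- function(x, ...) {
  cat(sprintf("gpc_posterior: %d draws, %d training labels, %d eigenpairs\n",
              length(x$eta), length(x$data$vertex), x$n_eig))
  cat(sprintf("  eta: median %.3g [%.3g, %.3g]; ell: median %.3g [%.3g, %.3g]\n",
              stats::median(x$eta), stats::quantile(x$eta, 0.05),
              stats::quantile(x$eta, 0.95), stats::median(x$ell),
              stats::quantile(x$ell, 0.05), stats::quantile(x$ell, 0.95)))
  cat(sprintf("  divergent: %d (%.1f%%), mean accept %.2f\n",
              x$diagnostics$n_divergent,
              100 * x$diagnostics$divergence_fraction,
              x$diagnostics$mean_accept))
  invisible(x)
}

# latent field of draw s at given vertices via the spectral expansion
latent_field_draw <- function(fit, basis, s, idx) {
  tb <- trunc_basis(basis, fit$n_eig)
  sw <- spectral_weights(tb, fit$ell[s], fit$nu)
  amp <- fit$eta[s] / sqrt(sw$C)
  as.numeric(tb$vectors[idx, , drop = FALSE] %*%
               (sqrt(sw$g) * fit$W[s, ])) * amp
}

#' Posterior class-probability prediction
#'
#' For each posterior draw, conditions the latent Gaussian process on the
#' training latent values through the standard GP predictive equations
#' (mean `k(x*,X) K^-1 f`, variance `k(x*,x*) - k(x*,X) K^-1 k(X,x*)`),
#' then averages the predictive means and variances across draws, samples
#' latent values from the averaged Gaussian, and maps them through the
#' logistic sigmoid to class probabilities.
#'
#' @param fit a `gpc_posterior` from [gpc_fit()].
#' @param basis the `spectral_basis` the model was fitted on.
#' @param query_vertices integer vertex indices to predict at (default:
#'   all mesh vertices).
#' @param n_prob_draws latent draws for the probability summary.
#' @param seed seed for the probability-summary draws.
#' @return object of class `class_prob_field`: list with `query_vertices`,
#'   `mu` (averaged latent mean), `sigma2` (averaged latent variance,
#'   diagonal), `prob` (mean class probability), `prob_lo`/`prob_hi`
#'   (central 90% interval), `label` (hard label at threshold 0.5).
#' @export
gpc_predict <- function(fit, basis, query_vertices = NULL,
                        n_prob_draws = 500, seed = 1) {
  stopifnot(inherits(fit, "gpc_posterior"),
            inherits(basis, "spectral_basis"))
  if (!identical(fit$basis_checksum, basis$mesh_checksum))
    stop("basis does not match the one the model was fitted on")
  nv <- nrow(basis$vectors)
  if (is.null(query_vertices)) query_vertices <- seq_len(nv)
  if (min(query_vertices) < 1L || max(query_vertices) > nv)
    stop("query vertex index out of range")
  tb <- trunc_basis(basis, fit$n_eig)
  idx <- fit$data$vertex
  Psi_X <- tb$vectors[idx, , drop = FALSE]
  Psi_q <- tb$vectors[query_vertices, , drop = FALSE]
  ns <- length(fit$eta)
  nq <- length(query_vertices)
  mu_acc <- numeric(nq)
  var_acc <- numeric(nq)
  for (s in seq_len(ns)) {
    sw <- spectral_weights(tb, fit$ell[s], fit$nu)
    scale <- fit$eta[s]^2 / sw$C
    gPsiX <- sw$g * t(Psi_X)                       # m x N
    K <- scale * (Psi_X %*% gPsiX)
    K <- (K + t(K)) / 2
    diag(K) <- diag(K) + fit$jitter * fit$eta[s]^2
    f <- sqrt(scale) * as.numeric(Psi_X %*% (sqrt(sw$g) * fit$W[s, ]))
    L <- chol(K)
    kqX <- scale * (Psi_q %*% gPsiX)               # nq x N
    z <- backsolve(L, backsolve(L, f, transpose = TRUE))
    mu_acc <- mu_acc + as.numeric(kqX %*% z)
    S <- backsolve(L, t(kqX), transpose = TRUE)    # N x nq
    kd <- scale * as.numeric((Psi_q^2) %*% sw$g)
    var_acc <- var_acc + pmax(kd - colSums(S^2), 0)
  }
  mu_hat <- mu_acc / ns
  sig2_hat <- var_acc / ns
  summarize_prob_field(query_vertices, mu_hat, sig2_hat, n_prob_draws, seed)
}

summarize_prob_field <- function(query_vertices, mu_hat, sig2_hat,
                                 n_prob_draws, seed) {
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  nq <- length(query_vertices)
  Z <- matrix(stats::rnorm(nq * n_prob_draws), nq, n_prob_draws)
  Fs <- mu_hat + sqrt(sig2_hat) * Z
  P <- 1 / (1 + exp(-Fs))
  qs <- t(apply(P, 1, stats::quantile, probs = c(0.05, 0.95), names = FALSE))
  structure(list(query_vertices = as.integer(query_vertices),
                 mu = mu_hat, sigma2 = sig2_hat,
                 prob = rowMeans(P), prob_lo = qs[, 1], prob_hi = qs[, 2],
                 label = as.integer(rowMeans(P) >= 0.5)),
            class = "class_prob_field")
}

#' @export
print.class_prob_field <- function(x, ...) {
  cat(sprintf("class_prob_field: %d vertices, %d predicted positive\n",
              length(x$query_vertices), sum(x$label)))
  cat(sprintf("  prob range [%.3f, %.3f], mean latent sd %.3g\n",
              min(x$prob), max(x$prob), mean(sqrt(x$sigma2))))
  invisible(x)
}
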