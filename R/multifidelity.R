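#' Joint covariance of the two-fidelity autoregressive GP
#'
#' The multi-fidelity model couples a low-fidelity latent function `f_L`
#' and a high-fidelity one `f_H` through the autoregressive
#' (Kennedy-O'Hagan) structure `f_H(x) = rho * f_L(x) + delta(x)`, with
#' independent manifold Matern priors on `f_L` (parameters `eta_L`,
#' `ell_L`) and on the discrepancy `delta` (parameters `eta_H`, `ell_H`).
#' The implied joint covariance over stacked low/high observation sites
#' has blocks
#' `K_LL = k_L(X_L, X_L)`, `K_LH = rho * k_L(X_L, X_H)`,
#' `K_HH = rho^2 * k_L(X_H, X_H) + k_H(X_H, X_H)`.
#'
#' @param basis a `spectral_basis`.
#' @param X_L,X_H integer vertex indices of the low/high-fidelity sites.
#' @param eta_L,ell_L low-fidelity kernel parameters.
#' @param eta_H,ell_H discrepancy kernel parameters.
#' @param rho autoregressive scaling (any sign).
#' @param nu shared Matern smoothness.
#' @return symmetric matrix of size `length(X_L) + length(X_H)`.
#' @export
joint_covariance <- function(basis, X_L, X_H, eta_L, ell_L, eta_H, ell_H,
                             rho, nu = 1.5) {
  kL <- matern_kernel(basis, eta = eta_L, ell = ell_L, nu = nu)
  kH <- matern_kernel(basis, eta = eta_H, ell = ell_H, nu = nu)
  K_LL <- kernel_matrix(kL, X_L, X_L)
  K_LH <- rho * kernel_matrix(kL, X_L, X_H)
  K_HH <- rho^2 * kernel_matrix(kL, X_H, X_H) + kernel_matrix(kH, X_H, X_H)
  K <- rbind(cbind(K_LL, K_LH), cbind(t(K_LH), K_HH))
  (K + t(K)) / 2
}

# log posterior + gradient of the two-fidelity model, unconstrained
# parameters theta = (aL, bL, aH, bH, rho, w_L, w_d).
# f_L = ampL Psi (sL * wL); delta = ampH Psi (sH * wd); f_H = rho f_L + delta.
# Priors: eta ~ HalfNormal(eta_scale), ell ~ Gamma(2,2), rho ~ N(0,10).
make_lp_mf <- function(Psi_L, y_L, Psi_H, y_H, lambda, qn, area, nu,
                       eta_scale, ell_alpha = 2, ell_beta = 2,
                       rho_sd = 10) {
  m <- length(lambda)
  half <- (nu + 1) / 2
  function(theta) {
    aL <- theta[1]; bL <- theta[2]; aH <- theta[3]; bH <- theta[4]
    rho <- theta[5]
    wL <- theta[5 + seq_len(m)]
    wd <- theta[5 + m + seq_len(m)]
    etaL <- exp(aL); ellL <- exp(bL); etaH <- exp(aH); ellH <- exp(bH)
    if (!all(is.finite(c(etaL, ellL, etaH, ellH))))
      return(list(lp = -Inf, grad = numeric(length(theta))))
    uL <- 2 * nu / ellL^2 + lambda; sL <- uL^(-half)
    CL <- sum(sL^2 * qn) / area
    uH <- 2 * nu / ellH^2 + lambda; sH <- uH^(-half)
    CH <- sum(sH^2 * qn) / area
    ampL <- etaL / sqrt(CL); ampH <- etaH / sqrt(CH)
    fL_L <- ampL * as.numeric(Psi_L %*% (sL * wL))
    fL_H <- ampL * as.numeric(Psi_H %*% (sL * wL))
    dH <- ampH * as.numeric(Psi_H %*% (sH * wd))
    fH <- rho * fL_H + dH
    bern <- function(y, f) {
      p_log <- -log1p(exp(-abs(f)))
      sum(ifelse(y == 1, ifelse(f >= 0, p_log, f + p_log),
                 ifelse(f >= 0, -f + p_log, p_log)))
    }
    lp <- bern(y_L, fL_L) + bern(y_H, fH) -
      etaL^2 / (2 * eta_scale^2) + aL - etaH^2 / (2 * eta_scale^2) + aH +
      ell_alpha * bL - ell_beta * ellL + ell_alpha * bH - ell_beta * ellH -
      rho^2 / (2 * rho_sd^2) - 0.5 * sum(wL^2) - 0.5 * sum(wd^2)
    # (alpha-1)*log(ell) - beta*ell + Jacobian log(ell) = alpha*b - beta*ell

    rL <- y_L - 1 / (1 + exp(-fL_L))
    rH <- y_H - 1 / (1 + exp(-fH))
    PsiL_rL <- as.numeric(crossprod(Psi_L, rL))
    PsiH_rH <- as.numeric(crossprod(Psi_H, rH))
    # d/d aL: fL scales with etaL
    gaL <- sum(rL * fL_L) + rho * sum(rH * fL_H) + 1 - etaL^2 / eta_scale^2
    gaH <- sum(rH * dH) + 1 - etaH^2 / eta_scale^2
    # d/d bL through sL and CL
    dsLdb <- 2 * nu * (nu + 1) * uL^(-(nu + 3) / 2) / ellL^2
    dCLdb <- 2 * sum(sL * dsLdb * qn) / area
    dcoefL <- dsLdb / sqrt(CL) - sL * dCLdb / (2 * CL^1.5)
    dfL_Ldb <- etaL * as.numeric(Psi_L %*% (dcoefL * wL))
    dfL_Hdb <- etaL * as.numeric(Psi_H %*% (dcoefL * wL))
    gbL <- sum(rL * dfL_Ldb) + rho * sum(rH * dfL_Hdb) +
      ell_alpha - ell_beta * ellL
    dsHdb <- 2 * nu * (nu + 1) * uH^(-(nu + 3) / 2) / ellH^2
    dCHdb <- 2 * sum(sH * dsHdb * qn) / area
    dcoefH <- dsHdb / sqrt(CH) - sH * dCHdb / (2 * CH^1.5)
    ddHdb <- etaH * as.numeric(Psi_H %*% (dcoefH * wd))
    gbH <- sum(rH * ddHdb) + ell_alpha - ell_beta * ellH
    grho <- sum(rH * fL_H) - rho / rho_sd^2
    gwL <- ampL * sL * (PsiL_rL + rho * PsiH_rH) - wL
    gwd <- ampH * sH * PsiH_rH - wd
    list(lp = lp, grad = c(gaL, gbL, gaH, gbH, grho, gwL, gwd))
  }
}

#' Fit the two-fidelity autoregressive GP classifier
#'
#' Samples the joint model: `eta_L, eta_H ~ HalfNormal(1e4)`,
#' `ell_L, ell_H ~ Gamma(2, 2)`, `rho ~ Normal(0, 10)`, independent
#' standard-normal spectral weights for `f_L` and `delta`;
#' `f_H = rho * f_L + delta`; low-fidelity labels are Bernoulli in
#' `sigma(f_L)` and high-fidelity labels Bernoulli in `sigma(f_H)`.
#'
#' @param dataset a [fidelity_dataset()] containing both fidelities.
#' @param basis a `spectral_basis`.
#' @param config an [inference_config()].
#' @return object of class `gpc_mf_posterior`.
#' @export
gpc_fit_mf <- function(dataset, basis, config = inference_config()) {
  stopifnot(inherits(dataset, "fidelity_dataset"),
            inherits(basis, "spectral_basis"),
            inherits(config, "inference_config"))
  dl <- dataset[dataset$fidelity == "low", ]
  dh <- dataset[dataset$fidelity == "high", ]
  if (nrow(dl) == 0 || nrow(dh) == 0)
    stop("multi-fidelity fit needs both fidelity levels; ",
         "use gpc_fit() for a single level")
  tb <- trunc_basis(basis, config$n_eig)
  m <- tb$n_eig
  Psi_L <- tb$vectors[dl$vertex, , drop = FALSE]
  Psi_H <- tb$vectors[dh$vertex, , drop = FALSE]
  lp <- make_lp_mf(Psi_L, dl$label, Psi_H, dh$label, tb$values,
                   tb$lumped_norms, tb$total_area, config$nu,
                   config$eta_scale)
  init <- c(0, log(0.5), 0, log(0.5), 1, numeric(2 * m))
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
    warning(sprintf("NUTS divergence fraction %.1f%% exceeds 10%%",
                    100 * div_frac))
  structure(list(eta_L = exp(draws[, 1]), ell_L = exp(draws[, 2]),
                 eta_H = exp(draws[, 3]), ell_H = exp(draws[, 4]),
                 rho = draws[, 5],
                 W_L = draws[, 5 + seq_len(m), drop = FALSE],
                 W_d = draws[, 5 + m + seq_len(m), drop = FALSE],
                 data = list(vertex_L = dl$vertex, label_L = dl$label,
                             vertex_H = dh$vertex, label_H = dh$label),
                 n_eig = m, nu = config$nu, jitter = config$jitter,
                 basis_checksum = basis$mesh_checksum,
                 diagnostics = list(
                   n_divergent = n_div, divergence_fraction = div_frac,
                   mean_accept = mean(vapply(chains, `[[`, numeric(1),
                                             "mean_accept")),
                   mean_treedepth = mean(vapply(chains, `[[`, numeric(1),
                                                "mean_treedepth")))),
            class = "gpc_mf_posterior")
}

#' @export
print.gpc_mf_posterior <- function(x, ...) {
  cat(sprintf(paste0("gpc_mf_posterior: %d draws, %d low + %d high labels, ",
                     "%d eigenpairs\n"),
              length(x$rho), length(x$data$vertex_L),
              length(x$data$vertex_H), x$n_eig))
  cat(sprintf("  rho: median %.3g [%.3g, %.3g]; P(rho>0) = %.2f\n",
              stats::median(x$rho), stats::quantile(x$rho, 0.05),
              stats::quantile(x$rho, 0.95), mean(x$rho > 0)))
  invisible(x)
}

#' Predict high-fidelity class probabilities from the multi-fidelity fit
#'
#' Conditions the high-fidelity process on the entire joint dataset
#' through the block covariance of the autoregressive model: for each
#' posterior draw the cross-covariance of `f_H(x*)` with the stacked
#' observations `(f_L(X_L), f_H(X_H))` is
#' `[rho * k_L(x*, X_L), rho^2 * k_L(x*, X_H) + k_H(x*, X_H)]`, and the
#' standard GP conditioning equations are applied with the joint `K`.
#' Means and variances are averaged over draws as in the single-fidelity
#' predictor.
#'
#' @inheritParams gpc_predict
#' @param fit a `gpc_mf_posterior` from [gpc_fit_mf()].
#' @param fix_rho optional numeric: condition with `rho` forced to this
#'   value in every draw (diagnostic use).
#' @return a `class_prob_field` for the high-fidelity process.
#' @export
gpc_predict_high <- function(fit, basis, query_vertices = NULL,
                             n_prob_draws = 500, seed = 1, fix_rho = NULL) {
  stopifnot(inherits(fit, "gpc_mf_posterior"),
            inherits(basis, "spectral_basis"))
  if (!identical(fit$basis_checksum, basis$mesh_checksum))
    stop("basis does not match the one the model was fitted on")
  nv <- nrow(basis$vectors)
  if (is.null(query_vertices)) query_vertices <- seq_len(nv)
  if (min(query_vertices) < 1L || max(query_vertices) > nv)
    stop("query vertex index out of range")
  tb <- trunc_basis(basis, fit$n_eig)
  iL <- fit$data$vertex_L; iH <- fit$data$vertex_H
  Psi_L <- tb$vectors[iL, , drop = FALSE]
  Psi_H <- tb$vectors[iH, , drop = FALSE]
  Psi_q <- tb$vectors[query_vertices, , drop = FALSE]
  nL <- length(iL); nH <- length(iH); nq <- length(query_vertices)
  ns <- length(fit$rho)
  mu_acc <- numeric(nq); var_acc <- numeric(nq)
  for (s in seq_len(ns)) {
    rho <- if (is.null(fix_rho)) fit$rho[s] else fix_rho
    swL <- spectral_weights(tb, fit$ell_L[s], fit$nu)
    swH <- spectral_weights(tb, fit$ell_H[s], fit$nu)
    scL <- fit$eta_L[s]^2 / swL$C
    scH <- fit$eta_H[s]^2 / swH$C
    gL_PsiL <- swL$g * t(Psi_L)                  # m x nL
    gL_PsiH <- swL$g * t(Psi_H)
    gH_PsiH <- swH$g * t(Psi_H)
    K_LL <- scL * (Psi_L %*% gL_PsiL)
    K_LH <- rho * scL * (Psi_L %*% gL_PsiH)
    K_HH <- rho^2 * scL * (Psi_H %*% gL_PsiH) + scH * (Psi_H %*% gH_PsiH)
    K <- rbind(cbind(K_LL, K_LH), cbind(t(K_LH), K_HH))
    K <- (K + t(K)) / 2
    diag(K) <- diag(K) + fit$jitter * mean(diag(K))
    fL <- sqrt(scL) * as.numeric(Psi_L %*% (sqrt(swL$g) * fit$W_L[s, ]))
    fLH <- sqrt(scL) * as.numeric(Psi_H %*% (sqrt(swL$g) * fit$W_L[s, ]))
    dH <- sqrt(scH) * as.numeric(Psi_H %*% (sqrt(swH$g) * fit$W_d[s, ]))
    fobs <- c(fL, rho * fLH + dH)
    kq <- cbind(rho * scL * (Psi_q %*% gL_PsiL),
                rho^2 * scL * (Psi_q %*% gL_PsiH) +
                  scH * (Psi_q %*% gH_PsiH))     # nq x (nL+nH)
    L <- chol(K)
    z <- backsolve(L, backsolve(L, fobs, transpose = TRUE))
    mu_acc <- mu_acc + as.numeric(kq %*% z)
    S <- backsolve(L, t(kq), transpose = TRUE)
    kd <- rho^2 * scL * as.numeric((Psi_q^2) %*% swL$g) +
      scH * as.numeric((Psi_q^2) %*% swH$g)
    var_acc <- var_acc + pmax(kd - colSums(S^2), 0)
  }
  summarize_prob_field(query_vertices, mu_acc / ns, var_acc / ns,
                       n_prob_draws, seed)
}
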