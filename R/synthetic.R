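#' Generate binary labels from a Matern random field
#'
#' Draws a zero-mean Gaussian random field with the manifold Matern
#' covariance, passes it through the logistic sigmoid and rounds to the
#' nearest integer: since the sigmoid is monotone with
#' `sigma(0) = 0.5`, the label is 1 exactly where the field is
#' nonnegative (a field value of exactly 0, a measure-zero event, maps
#' to label 1).
#'
#' @param basis a `spectral_basis` on a normalized mesh.
#' @param ell_true,eta_true,nu field covariance parameters (defaults
#'   `eta = 1`, `nu = 3/2` as in the synthetic assessment).
#' @param n_eig eigenpairs used for the field (clamped to the basis).
#' @param seed integer seed.
#' @return list with `labels` (integer 0/1 per vertex), `field` (the
#'   latent field), and the generating parameters.
#' @export
generate_labels <- function(basis, ell_true, eta_true = 1, nu = 1.5,
                            n_eig = 1000, seed = 1) {
  stopifnot(inherits(basis, "spectral_basis"), ell_true > 0, eta_true > 0)
  tb <- trunc_basis(basis, n_eig)
  k <- matern_kernel(tb, eta = eta_true, ell = ell_true, nu = nu)
  f <- sample_prior(k, n = 1, seed = seed)
  list(labels = as.integer(f >= 0), field = f, ell_true = ell_true,
       eta_true = eta_true, nu = nu, seed = as.integer(seed))
}

# probability that two jointly Gaussian zero-mean variables with
# correlation r have the same sign (orthant probability)
same_sign_prob <- function(r) 0.5 + asin(pmin(1, pmax(-1, r))) / pi

# expected label agreement of the two-fidelity generator, area-weighted
expected_agreement <- function(basis, ell, eta, ell_delta, eta_delta, rho,
                               nu, n_eig) {
  tb <- trunc_basis(basis, n_eig)
  vL <- kernel_diag(matern_kernel(tb, eta, ell, nu))
  vD <- kernel_diag(matern_kernel(tb, max(eta_delta, 1e-12), ell_delta, nu))
  if (eta_delta <= 0) vD <- vD * 0
  r <- rho * vL / sqrt(vL * (rho^2 * vL + vD))
  if (any(!is.finite(r))) r[!is.finite(r)] <- 0
  w <- tb$vertex_areas / tb$total_area
  sum(w * same_sign_prob(r))
}

#' Generate correlated low/high-fidelity label pairs
#'
#' Emulates a pair of simulators at two resolutions that agree on most
#' but not all pacing sites: the low-fidelity latent field `f_L` is a
#' Matern random field, the high-fidelity one is
#' `f_H = rho_true * f_L + delta` with an independent Matern discrepancy
#' `delta`, and both are thresholded at zero into labels. The expected
#' label agreement can be calibrated to a target (e.g. ~0.82, the level
#' observed between coarse and fine electrophysiology models) by
#' bisecting on the discrepancy amplitude `eta_delta`, using the exact
#' Gaussian orthant probability of sign agreement at each vertex.
#'
#' @param basis a `spectral_basis` on a normalized mesh.
#' @param ell_true low-fidelity field length scale.
#' @param eta_true low-fidelity field amplitude.
#' @param rho_true autoregressive scaling of the generator.
#' @param ell_delta discrepancy length scale (default `ell_true`).
#' @param eta_delta discrepancy amplitude; ignored when
#'   `target_agreement` is given.
#' @param target_agreement optional value in (0,1): calibrate
#'   `eta_delta` so the expected label agreement matches it (tolerance
#'   0.001 in expectation; a warning reports the realized agreement if
#'   calibration cannot converge).
#' @param nu,n_eig,seed as in [generate_labels()].
#' @return list with `labels_low`, `labels_high`, the two latent fields,
#'   the realized vertex `agreement` fraction, and the generator
#'   parameters including the calibrated `eta_delta`.
#' @export
generate_two_fidelity <- function(basis, ell_true, eta_true = 1,
                                  rho_true = 1, ell_delta = ell_true,
                                  eta_delta = 0.5, target_agreement = NULL,
                                  nu = 1.5, n_eig = 1000, seed = 1) {
  stopifnot(inherits(basis, "spectral_basis"))
  tb <- trunc_basis(basis, n_eig)
  if (!is.null(target_agreement)) {
    stopifnot(target_agreement > 0, target_agreement < 1)
    agr <- function(log_ed) expected_agreement(
      tb, ell_true, eta_true, ell_delta, exp(log_ed), rho_true, nu,
      tb$n_eig)
    # agreement decreases monotonically in eta_delta
    lo <- -8; hi <- 8
    a_lo <- agr(lo); a_hi <- agr(hi)
    if (target_agreement > a_lo || target_agreement < a_hi) {
      warning(sprintf(paste0("target agreement %.3f outside achievable ",
                             "range [%.3f, %.3f]; using nearest endpoint"),
                      target_agreement, a_hi, a_lo))
      eta_delta <- exp(if (target_agreement > a_lo) lo else hi)
    } else {
      for (i in 1:60) {
        mid <- (lo + hi) / 2
        if (agr(mid) > target_agreement) lo <- mid else hi <- mid
        if (abs(agr(mid) - target_agreement) < 1e-3) break
      }
      eta_delta <- exp((lo + hi) / 2)
    }
  }
  fL <- sample_prior(matern_kernel(tb, eta_true, ell_true, nu), seed = seed)
  dseed <- as.integer(seed) + 499979L
  dlt <- if (eta_delta > 0)
    sample_prior(matern_kernel(tb, eta_delta, ell_delta, nu), seed = dseed)
  else numeric(length(fL))
  fH <- rho_true * fL + dlt
  yL <- as.integer(fL >= 0); yH <- as.integer(fH >= 0)
  list(labels_low = yL, labels_high = yH, field_low = fL, field_high = fH,
       agreement = mean(yL == yH), ell_true = ell_true,
       eta_true = eta_true, rho_true = rho_true, ell_delta = ell_delta,
       eta_delta = eta_delta, nu = nu, seed = as.integer(seed))
}

#' Balanced accuracy
#'
#' Arithmetic mean of sensitivity (recall on the positive class) and
#' specificity (recall on the negative class), robust to class
#' imbalance. When the truth contains a single class, the recall of that
#' class is returned with a warning.
#'
#' @param truth,predicted binary 0/1 vectors of equal length.
#' @return a value in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1)))
    stop("labels must be binary 0/1")
  pos <- truth == 1
  if (all(pos) || !any(pos)) {
    warning("truth contains a single class; returning its recall")
    return(mean(predicted == truth))
  }
  (mean(predicted[pos] == 1) + mean(predicted[!pos] == 0)) / 2
}

#' Inducibility: the fraction of the surface where the indicator is 1
#'
#' For an indicator field `F` on the mesh (e.g. "pacing here induces
#' fibrillation"), computes the area fraction
#' `I = (1/|S|) * integral of F`, using lumped vertex areas (mass-matrix
#' row sums) as the quadrature. With a focus density `rho` the weighted
#' variant `I_rho = integral of F * rho` is returned, where `rho` is a
#' per-vertex density integrating to 1 against the vertex areas
#' (renormalized with a warning otherwise). With `mode = "sample"` the
#' plain fraction of positive labels among the supplied sites is
#' returned, the convention used when reporting inducibility of a
#' train/test sample set.
#'
#' @param indicator binary 0/1 vector: per-vertex for the area modes, or
#'   per-site for `mode = "sample"`.
#' @param basis a `spectral_basis` (carries vertex areas); unused in
#'   sample mode.
#' @param rho optional per-vertex focus density.
#' @param mode `"uniform"`, `"weighted"` (implied by `rho`), or
#'   `"sample"`.
#' @return inducibility in `[0, 1]`.
#' @export
inducibility <- function(indicator, basis = NULL, rho = NULL,
                         mode = c("uniform", "weighted", "sample")) {
  mode <- match.arg(mode)
  if (!all(indicator %in% c(0, 1))) stop("indicator must be binary 0/1")
  if (!is.null(rho) && mode == "uniform") mode <- "weighted"
  if (mode == "sample") return(mean(indicator))
  stopifnot(inherits(basis, "spectral_basis"))
  w <- basis$vertex_areas
  if (length(indicator) != length(w))
    stop("indicator length does not match mesh size")
  if (mode == "uniform") return(sum(indicator * w) / sum(w))
  if (any(rho < 0)) stop("focus density must be nonnegative")
  tot <- sum(rho * w)
  if (abs(tot - 1) > 1e-8) {
    warning("focus density does not integrate to 1; renormalizing")
    rho <- rho / tot
  }
  sum(indicator * rho * w)
}
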