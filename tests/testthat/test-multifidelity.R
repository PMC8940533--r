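test_that("joint covariance has the autoregressive block structure", {
  b <- ico2_basis()
  XL <- 1:20; XH <- 31:45
  # rho = 0 decouples the fidelities
  K0 <- joint_covariance(b, XL, XH, eta_L = 1, ell_L = 0.5, eta_H = 0.7,
                         ell_H = 0.4, rho = 0)
  expect_equal(K0[1:20, 21:35], matrix(0, 20, 15), ignore_attr = TRUE)
  kH <- kernel_matrix(matern_kernel(b, 0.7, 0.4), XH, XH)
  expect_equal(K0[21:35, 21:35], kH, tolerance = 1e-12)
  # rho = 1 with a vanishing discrepancy degenerates to the LF kernel
  K1 <- joint_covariance(b, XL, XH, eta_L = 1, ell_L = 0.5, eta_H = 1e-8,
                         ell_H = 0.4, rho = 1)
  kL <- kernel_matrix(matern_kernel(b, 1, 0.5), XH, XH)
  expect_equal(K1[21:35, 21:35], kL, tolerance = 1e-6)
  # PSD for random parameter draws
  set.seed(8)
  for (i in 1:3) {
    K <- joint_covariance(b, sample(162, 30), sample(162, 30),
                          eta_L = runif(1, 0.5, 3), ell_L = runif(1, 0.2, 1),
                          eta_H = runif(1, 0.1, 2), ell_H = runif(1, 0.2, 1),
                          rho = rnorm(1, 0, 2))
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * max(ev))
  }
})

test_that("multi-fidelity fit requires both fidelities", {
  b <- ico2_basis()
  ds <- fidelity_dataset(1:10, rep(c(0, 1), 5), "high")
  expect_error(gpc_fit_mf(ds, b, test_config()), "both fidelity")
})

test_that("rho is identified as positive when the fidelities agree", {
  b <- ico2_basis()
  g <- generate_labels(b, ell_true = 0.6, n_eig = 80, seed = 71)
  set.seed(72)
  iL <- sample(162, 100)
  iH <- sample(162, 60)
  ds <- fidelity_dataset(c(iL, iH), c(g$labels[iL], g$labels[iH]),
                         c(rep("low", 100), rep("high", 60)))
  fit <- gpc_fit_mf(ds, b, test_config(seed = 73, n_warmup = 400))
  expect_gt(mean(fit$rho > 0), 0.8)
})

test_that("high-fidelity conditioning reproduces fixed draws at observed sites", {
  b <- ico2_basis()
  set.seed(81)
  iL <- sample(162, 25); iH <- sample(162, 15)
  W_L <- matrix(rnorm(2 * 80), 2, 80)
  W_d <- matrix(rnorm(2 * 80), 2, 80)
  fit <- manual_mf_posterior(b, eta_L = c(1, 1.5), ell_L = c(0.5, 0.8),
                             eta_H = c(0.6, 0.3), ell_H = c(0.4, 0.9),
                             rho = c(1.2, 0.7), W_L = W_L, W_d = W_d,
                             vertex_L = iL, label_L = rep(0L, 25),
                             vertex_H = iH, label_H = rep(0L, 15))
  # direct spectral evaluation of f_H = rho f_L + delta at the HF sites
  direct <- vapply(1:2, function(s) {
    sf <- manual_posterior(b, fit$eta_L[s], fit$ell_L[s],
                           W_L[s, , drop = FALSE], iL, rep(0L, 25))
    sd_ <- manual_posterior(b, fit$eta_H[s], fit$ell_H[s],
                            W_d[s, , drop = FALSE], iH, rep(0L, 15))
    fit$rho[s] * surfgpc:::latent_field_draw(sf, b, 1, iH) +
      surfgpc:::latent_field_draw(sd_, b, 1, iH)
  }, numeric(15))
  pred <- gpc_predict_high(fit, b, iH)
  expect_equal(pred$mu, rowMeans(direct), tolerance = 1e-6)
  expect_lt(max(pred$sigma2), 1e-6)
})

test_that("with rho = 0 the high-fidelity prediction uses only HF data", {
  b <- ico2_basis()
  set.seed(91)
  iL <- sample(162, 30); iH <- sample(1:162, 20)
  W_L <- matrix(rnorm(2 * 80), 2, 80)
  W_d <- matrix(rnorm(2 * 80), 2, 80)
  mf <- manual_mf_posterior(b, eta_L = c(1, 1), ell_L = c(0.5, 0.5),
                            eta_H = c(0.8, 1.2), ell_H = c(0.6, 0.4),
                            rho = c(5, -3), W_L = W_L, W_d = W_d,
                            vertex_L = iL, label_L = rep(0L, 30),
                            vertex_H = iH, label_H = rep(0L, 20))
  # forcing rho = 0 must match a single-fidelity posterior made of the
  # discrepancy draws conditioned on the HF subset alone
  sf <- manual_posterior(b, eta = c(0.8, 1.2), ell = c(0.6, 0.4),
                         W = W_d, vertex = iH, label = rep(0L, 20))
  q <- seq(1, 162, by = 7)
  p_mf <- gpc_predict_high(mf, b, q, seed = 3, fix_rho = 0)
  p_sf <- gpc_predict(sf, b, q, seed = 3)
  expect_equal(p_mf$mu, p_sf$mu, tolerance = 1e-8)
  expect_equal(p_mf$sigma2, p_sf$sigma2, tolerance = 1e-8)
})

test_that("posterior variance is smaller at training sites than far away", {
  b <- ico2_basis()
  g <- generate_two_fidelity(b, ell_true = 0.6, target_agreement = 0.82,
                             n_eig = 80, seed = 95)
  set.seed(96)
  iL <- sample(162, 60); iH <- sample(162, 25)
  ds <- fidelity_dataset(c(iL, iH),
                         c(g$labels_low[iL], g$labels_high[iH]),
                         c(rep("low", 60), rep("high", 25)))
  fit <- gpc_fit_mf(ds, b, test_config(seed = 97))
  pred <- gpc_predict_high(fit, b)
  far <- setdiff(seq_len(162), c(iL, iH))
  expect_lt(median(pred$sigma2[iH]), median(pred$sigma2[far]))
})
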