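test_that("dataset and config containers validate their inputs", {
  expect_error(fidelity_dataset(c(1, 1), c(0, 1)), "duplicate")
  # same vertex with two fidelities is allowed
  expect_silent(fidelity_dataset(c(1, 1), c(0, 1), c("low", "high")))
  expect_error(fidelity_dataset(1, 2), "binary")
  expect_error(fidelity_dataset(1, 1, "medium"), "fidelity")
  expect_error(fidelity_dataset(200, 1, n_vertices = 162), "exceeds")
  expect_error(inference_config(target_accept = 1.2), "target_accept")
  expect_error(inference_config(n_warmup = 0), "n_warmup")
})

test_that("an all-positive dataset drives probabilities above one half", {
  b <- ico2_basis()
  ds <- fidelity_dataset(c(5, 40, 80, 120, 160), rep(1, 5))
  expect_warning(fit <- gpc_fit(ds, b, test_config()), "one class")
  pred <- gpc_predict(fit, b, ds$vertex)
  expect_true(all(pred$prob > 0.5))
  expect_true(all(pred$sigma2 >= 0))
})

test_that("posterior recovers the generating length scale within a factor 2", {
  b <- ico2_basis()
  g <- generate_labels(b, ell_true = 0.5, n_eig = 80, seed = 21)
  set.seed(22)
  idx <- sample(162, 100)
  fit <- gpc_fit(fidelity_dataset(idx, g$labels[idx]), b,
                 test_config(seed = 23, n_warmup = 400))
  ci <- quantile(fit$ell, c(0.05, 0.95))
  expect_lt(ci[1], 1.0)   # interval reaches below 2 * ell_true
  expect_gt(ci[2], 0.25)  # and above ell_true / 2
})

test_that("prediction is consistent at training vertices and reproducible across seeds", {
  b <- ico2_basis()
  g <- generate_labels(b, ell_true = 0.8, n_eig = 80, seed = 31)
  set.seed(32)
  idx <- sample(162, 40)
  ds <- fidelity_dataset(idx, g$labels[idx])
  fit1 <- gpc_fit(ds, b, test_config(seed = 1, n_warmup = 400))
  p1 <- gpc_predict(fit1, b)
  # at a training vertex whose neighbors agree, the posterior follows the label
  agree <- vapply(seq_along(idx), function(i) {
    v <- idx[i]
    nb <- unique(as.vector(b$mesh$triangles[rowSums(
      b$mesh$triangles == v) > 0, ]))
    nb_lab <- g$labels[intersect(nb, idx)]
    length(nb_lab) > 1 && all(nb_lab == g$labels[v])
  }, logical(1))
  consistent <- (p1$prob[idx] > 0.5) == (g$labels[idx] == 1)
  expect_true(all(consistent[agree]))
  expect_true(all(p1$sigma2 >= 0))
  # an independent chain gives the same probability field within MC noise
  fit2 <- gpc_fit(ds, b, test_config(seed = 77, n_warmup = 400))
  p2 <- gpc_predict(fit2, b)
  expect_gt(mean(abs(p1$prob - p2$prob) < 0.05), 0.95)
})

test_that("predictions are invariant to sample order up to MC noise", {
  b <- ico2_basis()
  g <- generate_labels(b, ell_true = 0.8, n_eig = 80, seed = 41)
  set.seed(42)
  idx <- sample(162, 30)
  perm <- sample(30)
  f1 <- gpc_fit(fidelity_dataset(idx, g$labels[idx]), b,
                test_config(seed = 5, n_warmup = 400))
  f2 <- gpc_fit(fidelity_dataset(idx[perm], g$labels[idx][perm]), b,
                test_config(seed = 5, n_warmup = 400))
  p1 <- gpc_predict(f1, b)
  p2 <- gpc_predict(f2, b)
  expect_gt(mean(abs(p1$prob - p2$prob) < 0.05), 0.95)
})

test_that("conditioning reproduces the latent draw exactly at observed vertices", {
  # with fixed draws, the GP conditional mean at the training vertices
  # equals the spectral-expansion field there (up to jitter)
  b <- ico2_basis()
  set.seed(51)
  idx <- sample(162, 10)
  W <- matrix(rnorm(3 * 80), 3, 80)
  fit <- manual_posterior(b, eta = c(1, 2, 0.5), ell = c(0.4, 0.7, 1.1),
                          W = W, vertex = idx,
                          label = rep(0L, 10))
  direct <- vapply(1:3, function(s)
    surfgpc:::latent_field_draw(fit, b, s, idx), numeric(10))
  pred <- gpc_predict(fit, b, idx)
  expect_equal(pred$mu, rowMeans(direct), tolerance = 1e-6)
  # and the conditional variance there collapses
  expect_lt(max(pred$sigma2), 1e-6)
})

test_that("a collapsed amplitude prior yields a half-probability field", {
  b <- ico2_basis()
  g <- generate_labels(b, ell_true = 0.6, n_eig = 80, seed = 61)
  set.seed(62)
  idx <- sample(162, 30)
  fit <- gpc_fit(fidelity_dataset(idx, g$labels[idx]), b,
                 test_config(seed = 6, eta_scale = 1e-4))
  pred <- gpc_predict(fit, b)
  expect_lt(max(abs(pred$prob - 0.5)), 0.05)
})

test_that("fit rejects mixed fidelities and invalid queries", {
  b <- ico2_basis()
  ds <- fidelity_dataset(c(1, 2), c(0, 1), c("low", "high"))
  expect_error(gpc_fit(ds, b, test_config()), "both fidelities")
  g <- generate_labels(b, 0.6, n_eig = 80, seed = 1)
  fit <- suppressWarnings(gpc_fit(fidelity_dataset(1:10, g$labels[1:10]),
                                  b, test_config(n_warmup = 60,
                                                 n_samples = 50)))
  expect_error(gpc_predict(fit, b, 10000), "out of range")
})
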