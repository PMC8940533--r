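#' Synthetic classifier benchmark on random fields
#'
#' Runs the full synthetic assessment: for each length scale and
#' replicate, draws a ground-truth Matern random-field labeling of the
#' mesh, builds a fixed farthest-point design, and evaluates the
#' requested classifiers at each training-set size by balanced accuracy
#' over the evaluation vertex set. The nearest-neighbor and fixed-design
#' GP classifiers are trained on identical data; the active-learning GP
#' shares only the first `active_init` design points and selects the
#' rest itself; the multi-fidelity classifier additionally receives
#' `n_low` low-fidelity labels from a correlated field.
#'
#' @param basis a `spectral_basis` on a normalized mesh.
#' @param scales numeric vector of true field length scales.
#' @param ns integer vector of training-set sizes.
#' @param replicates replicate fields per scale.
#' @param classifiers subset of `c("nn", "gp_fixed", "gp_active", "mf")`.
#' @param seed master seed; replicate `r` of scale index `s` derives its
#'   field seed as `seed + 1000*s + r` and its design seed as
#'   `seed + 500*s + r` (logged in the output).
#' @param config an [inference_config()] used for every GP fit.
#' @param solver optional precomputed [geodesic_solver()].
#' @param exclude_training if `TRUE`, evaluate on vertices outside the
#'   training design; default evaluates on all mesh vertices.
#' @param active_init shared design prefix for active learning
#'   (default 20).
#' @param active_budget total labels for the active-learning classifier
#'   (default `max(ns)`).
#' @param n_low low-fidelity sample count for the `mf` classifier
#'   (default 100).
#' @param mf_agreement expected low/high label agreement of the
#'   generator (default 0.82).
#' @param n_eig_field eigenpairs for field generation (default 1000,
#'   clamped).
#' @return a tidy data frame, one row per (scale, replicate, classifier,
#'   n): columns `ell`, `replicate`, `classifier`, `n`,
#'   `balanced_accuracy`, `field_seed`, `design_seed`, plus `error`
#'   (NA unless that fit failed, in which case the benchmark continues).
#' @export
run_benchmark <- function(basis, scales = c(0.4, 0.8), ns = c(20, 60, 100),
                          replicates = 3,
                          classifiers = c("nn", "gp_fixed"),
                          seed = 1, config = inference_config(),
                          solver = NULL, exclude_training = FALSE,
                          active_init = 20, active_budget = NULL,
                          n_low = 100,
                          mf_agreement = 0.82, n_eig_field = 1000) {
  stopifnot(inherits(basis, "spectral_basis"))
  classifiers <- match.arg(classifiers,
                           c("nn", "gp_fixed", "gp_active", "mf"),
                           several.ok = TRUE)
  if (is.null(solver)) solver <- geodesic_solver(basis$mesh)
  nv <- nrow(basis$vectors)
  rows <- list()
  add_row <- function(ell, rep_, cls, n, ba, fs, ds, err = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      ell = ell, replicate = rep_, classifier = cls, n = n,
      balanced_accuracy = ba, field_seed = fs, design_seed = ds,
      error = err, stringsAsFactors = FALSE)
  }
  for (si in seq_along(scales)) {
    ell <- scales[si]
    for (r in seq_len(replicates)) {
      fseed <- seed + 1000L * si + r
      dseed <- seed + 500L * si + r
      truth <- if ("mf" %in% classifiers) {
        g2 <- generate_two_fidelity(basis, ell_true = ell,
                                    target_agreement = mf_agreement,
                                    n_eig = n_eig_field, seed = fseed)
        list(high = g2$labels_high, low = g2$labels_low)
      } else {
        g1 <- generate_labels(basis, ell_true = ell, n_eig = n_eig_field,
                              seed = fseed)
        list(high = g1$labels, low = NULL)
      }
      design <- farthest_point_design(solver, max(ns), seed = dseed)$vertices
      lf_design <- if (!is.null(truth$low))
        farthest_point_design(solver, n_low, seed = dseed + 250L)$vertices
      eval_set <- function(train) {
        if (exclude_training) setdiff(seq_len(nv), train) else seq_len(nv)
      }
      for (n in sort(ns)) {
        tr <- design[seq_len(n)]
        ev <- eval_set(tr)
        if ("nn" %in% classifiers) {
          pred <- nn_classify(solver, tr, truth$high[tr], ev)
          add_row(ell, r, "nn", n,
                  balanced_accuracy(truth$high[ev], pred), fseed, dseed)
        }
        if ("gp_fixed" %in% classifiers) {
          ba <- tryCatch({
            fit <- gpc_fit(fidelity_dataset(tr, truth$high[tr]), basis,
                           config)
            pr <- gpc_predict(fit, basis, ev,
                              n_prob_draws = config$n_prob_draws,
                              seed = config$seed)
            balanced_accuracy(truth$high[ev], pr$label)
          }, error = function(e) conditionMessage(e))
          if (is.character(ba))
            add_row(ell, r, "gp_fixed", n, NA_real_, fseed, dseed, ba)
          else add_row(ell, r, "gp_fixed", n, ba, fseed, dseed)
        }
        if ("mf" %in% classifiers) {
          ba <- tryCatch({
            ds_mf <- fidelity_dataset(
              c(lf_design, tr),
              c(truth$low[lf_design], truth$high[tr]),
              c(rep("low", length(lf_design)), rep("high", n)))
            fit <- gpc_fit_mf(ds_mf, basis, config)
            pr <- gpc_predict_high(fit, basis, ev,
                                   n_prob_draws = config$n_prob_draws,
                                   seed = config$seed)
            balanced_accuracy(truth$high[ev], pr$label)
          }, error = function(e) conditionMessage(e))
          if (is.character(ba))
            add_row(ell, r, "mf", n, NA_real_, fseed, dseed, ba)
          else add_row(ell, r, "mf", n, ba, fseed, dseed)
        }
      }
      if ("gp_active" %in% classifiers) {
        budget <- if (is.null(active_budget)) max(ns) else active_budget
        ba_steps <- tryCatch({
          al <- active_learn(basis, oracle = function(v) truth$high[v],
                             initial_design = design[seq_len(active_init)],
                             budget = budget, config = config,
                             solver = solver, truth = truth$high)
          al$metrics
        }, error = function(e) conditionMessage(e))
        if (is.character(ba_steps)) {
          add_row(ell, r, "gp_active", budget, NA_real_, fseed, dseed,
                  ba_steps)
        } else {
          for (n in intersect(sort(ns), ba_steps$n_labels)) {
            add_row(ell, r, "gp_active", n,
                    ba_steps$balanced_accuracy[ba_steps$n_labels == n],
                    fseed, dseed)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
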