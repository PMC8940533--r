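#' Acquisition criterion: next vertex to label
#'
#' Selects, among candidate vertices, the minimizer of
#' `|mu(x)| / Sigma(x)` — the posterior-mean magnitude of the latent
#' function divided by its posterior variance. Small values flag points
#' that are near the decision boundary (`sigma(0) = 0.5`) or carry high
#' uncertainty, balancing exploitation and exploration. The division is
#' by the variance itself, not its square root.
#'
#' @param field a `class_prob_field` from [gpc_predict()] or
#'   [gpc_predict_high()] covering all candidates.
#' @param candidates integer vertex indices to choose among. Boundary
#'   vertices (which have artificially inflated variance under the
#'   Neumann basis) and already-labeled vertices should be excluded by
#'   the caller; [active_learn()] does this automatically.
#' @return the selected vertex index (ties broken by lowest index).
#' @export
acquire_next <- function(field, candidates) {
  stopifnot(inherits(field, "class_prob_field"))
  candidates <- as.integer(candidates)
  if (length(candidates) == 0) stop("empty candidate set")
  pos <- match(candidates, field$query_vertices)
  if (anyNA(pos)) stop("field does not cover all candidates")
  s2 <- field$sigma2[pos]
  crit <- abs(field$mu[pos]) / s2
  if (any(s2 == 0)) {
    warning("zero posterior variance among candidates; ",
            "treating as +Inf criterion")
    crit[s2 == 0] <- Inf
  }
  if (all(!is.finite(crit)))
    stop("all candidates have zero posterior variance; nothing to acquire")
  ord <- order(candidates)
  candidates[ord][which.min(crit[ord])]
}

#' Sequential active-learning loop
#'
#' Seeds the training set with a farthest-point design, then alternates
#' fit / acquire / label until the budget is reached, one acquisition per
#' retraining round. Candidates are all mesh vertices except boundary
#' vertices and vertices already labeled.
#'
#' @param basis a `spectral_basis` on the classification mesh.
#' @param oracle a function mapping a vertex index to a binary label
#'   (e.g. a lookup into a ground-truth field).
#' @param initial_design integer vector of seed vertices, or `NULL` to
#'   generate a farthest-point design of size `initial_size`.
#' @param initial_size size of the generated seed design (default 20).
#' @param budget total number of labeled samples at the end
#'   (`>= initial_size`).
#' @param config an [inference_config()].
#' @param solver optional [geodesic_solver()] (built on demand when a
#'   design must be generated).
#' @param truth optional full ground-truth label vector; when given,
#'   balanced accuracy over all mesh vertices is recorded at each step.
#' @param design_seed seed for the generated initial design.
#' @return list with `dataset` (the final [fidelity_dataset()]),
#'   `acquired` (vertices added by the criterion, in order),
#'   `criterion_values` (their criterion values), and `metrics` (data
#'   frame of per-step training-set size and balanced accuracy when
#'   `truth` is supplied).
#' @export
active_learn <- function(basis, oracle, initial_design = NULL,
                         initial_size = 20, budget = 60,
                         config = inference_config(), solver = NULL,
                         truth = NULL, design_seed = 1) {
  stopifnot(inherits(basis, "spectral_basis"), is.function(oracle))
  nv <- nrow(basis$vectors)
  if (is.null(initial_design)) {
    if (is.null(solver)) solver <- geodesic_solver(basis$mesh)
    initial_design <- farthest_point_design(solver, initial_size,
                                            seed = design_seed)$vertices
  }
  if (budget < length(initial_design))
    stop("budget smaller than the initial design")
  label_one <- function(v) {
    y <- tryCatch(oracle(v), error = function(e)
      stop("oracle failed at vertex ", v, ": ", conditionMessage(e)))
    if (!y %in% c(0, 1)) stop("oracle returned non-binary label at vertex ", v)
    as.integer(y)
  }
  verts <- as.integer(initial_design)
  labs <- vapply(verts, label_one, integer(1))
  acquired <- integer(0)
  crit_vals <- numeric(0)
  metrics <- list()
  step <- 0L
  repeat {
    ds <- fidelity_dataset(verts, labs, n_vertices = nv)
    fit <- gpc_fit(ds, basis, config)
    pred <- gpc_predict(fit, basis, n_prob_draws = config$n_prob_draws,
                        seed = config$seed)
    if (!is.null(truth)) {
      step <- step + 1L
      metrics[[step]] <- data.frame(
        n_labels = length(verts),
        balanced_accuracy = balanced_accuracy(truth, pred$label))
    }
    if (length(verts) >= budget) break
    candidates <- setdiff(seq_len(nv),
                          c(basis$mesh$boundary_vertices, verts))
    if (length(candidates) == 0) {
      warning("no candidates left before budget was reached")
      break
    }
    v_new <- acquire_next(pred, candidates)
    pos <- match(v_new, pred$query_vertices)
    acquired <- c(acquired, v_new)
    crit_vals <- c(crit_vals, abs(pred$mu[pos]) / pred$sigma2[pos])
    verts <- c(verts, v_new)
    labs <- c(labs, label_one(v_new))
  }
  list(dataset = fidelity_dataset(verts, labs, n_vertices = nv),
       acquired = acquired, criterion_values = crit_vals,
       metrics = if (length(metrics)) do.call(rbind, metrics) else NULL,
       fit = fit, prediction = pred)
}
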