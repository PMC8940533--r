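#' Read and write label / field tables
#'
#' Delimited-text interchange for labeled samples and per-vertex fields.
#' File convention: comma-separated, header row, UTF-8, and — prominently
#' — **vertex indices are 0-based on disk** (matching the mesh file
#' formats), while all in-memory R structures are 1-based. The readers
#' and writers perform the shift.
#'
#' @param path CSV file path.
#' @param n_vertices optional mesh size for validation.
#' @return `read_labels`: a [fidelity_dataset()]. `read_field`: a
#'   numeric vector ordered by vertex. Writers return `path` invisibly.
#' @export
read_labels <- function(path, n_vertices = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vertex_index", "label")
  if (!all(need %in% names(df)))
    stop("labels CSV must have columns vertex_index,label[,fidelity]")
  fid <- if ("fidelity" %in% names(df)) df$fidelity else "high"
  fidelity_dataset(df$vertex_index + 1L, df$label, fid,
                   n_vertices = n_vertices)
}

#' @rdname read_labels
#' @param dataset a [fidelity_dataset()].
#' @export
write_labels <- function(dataset, path) {
  stopifnot(inherits(dataset, "fidelity_dataset"))
  utils::write.csv(data.frame(vertex_index = dataset$vertex - 1L,
                              label = dataset$label,
                              fidelity = dataset$fidelity),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_labels
#' @param values numeric per-vertex values.
#' @export
write_field <- function(values, path) {
  utils::write.csv(data.frame(vertex_index = seq_along(values) - 1L,
                              value = sprintf("%.17g", values)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_labels
#' @export
read_field <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("vertex_index", "value") %in% names(df)))
    stop("field CSV must have columns vertex_index,value")
  out <- numeric(max(df$vertex_index) + 1L)
  out[df$vertex_index + 1L] <- as.numeric(df$value)
  out
}

#' Write a run manifest
#'
#' Every command-line run records a JSON manifest next to its outputs:
#' the configuration snapshot, input checksums, seeds, package version
#' and a timestamp, so any result file can be traced to the exact run
#' that produced it.
#'
#' @param path output JSON path.
#' @param config list of configuration values (serialized as-is).
#' @param seeds named list/vector of seeds in effect.
#' @param mesh_checksum,basis_checksum optional md5 strings.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), seeds = list(),
                           mesh_checksum = NULL, basis_checksum = NULL) {
  manifest <- list(
    package = "surfgpc",
    version = as.character(utils::packageVersion("surfgpc")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = seeds, config = config,
    mesh_checksum = mesh_checksum, basis_checksum = basis_checksum)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Load an inference configuration from YAML
#'
#' The YAML keys mirror the [inference_config()] argument names exactly
#' (`n_warmup`, `n_samples`, `n_chains`, `target_accept`, `seed`,
#' `n_eig`, `nu`, `jitter`, `n_prob_draws`, `eta_scale`); missing keys
#' take the defaults, unknown keys are an error.
#'
#' @param path YAML file path.
#' @param overrides named list overriding file values (e.g. a
#'   command-line `--seed`).
#' @return an [inference_config()].
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  if (is.null(vals)) vals <- list()
  allowed <- names(formals(inference_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  vals[names(overrides)] <- overrides
  do.call(inference_config, vals)
}
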