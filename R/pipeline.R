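# End-to-end pipeline: completion -> metric learning -> distances.

#' Fit the full model
#'
#' Runs the two stages on labeled input matrices: (1) build the
#' heterogeneous network (normalize similarities, apply the penalty
#' factor, assemble the block adjacency), train the GCN completion
#' model and threshold its scores into a completed association matrix;
#' (2) train the symmetric metric model on the completed matrix.  With
#' `completion = FALSE` stage (1) is skipped and the raw binary matrix
#' feeds the metric stage directly (the metric-learning-only
#' ablation).
#'
#' @param drug_sim,disease_sim similarity matrices
#'   ([as_similarity_matrix()]).
#' @param Y binary association matrix whose dimnames match the
#'   similarity matrices.
#' @param config configuration list ([default_config()]).
#' @param completion run the completion stage.
#' @param verbose log per-epoch losses.
#' @return an object of class `rsml_fit`: list with `completion` (the
#'   `completion_model` or `NULL`), `Y_completed`, `metric` (the
#'   `metric_model`), and the `M x N` `distances` matrix.
#' @export
rsml_fit <- function(drug_sim, disease_sim, Y, config = default_config(),
                     completion = TRUE, verbose = FALSE) {
  if (!identical(rownames(Y), rownames(drug_sim))) {
    abort("drug ids of Y and drug_sim differ")
  }
  if (!identical(colnames(Y), rownames(disease_sim))) {
    abort("disease ids of Y and disease_sim differ")
  }
  completion_model <- NULL
  if (completion) {
    Sr_hat <- apply_penalty(normalize_similarity(drug_sim), config$completion$mu)
    Sd_hat <- apply_penalty(normalize_similarity(disease_sim), config$completion$mu)
    het <- build_hetero_adjacency(Sr_hat, Sd_hat, Y)
    completion_model <- train_completion(het, Y, config, verbose = verbose)
    Y_completed <- threshold_complete(completion_model$scores, Y, config$completion$theta)
  } else {
    Y_completed <- Y
  }
  metric <- train_metric(Y_completed, config, verbose = verbose)
  structure(list(completion = completion_model, Y_completed = Y_completed,
                 metric = metric, distances = score_all(metric)),
            class = "rsml_fit")
}

#' @export
print.rsml_fit <- function(x, ...) {
  cat(sprintf("rsml fit: %d drugs x %d diseases (%s completion)\n",
              nrow(x$distances), ncol(x$distances),
              if (is.null(x$completion)) "without" else "with"))
  invisible(x)
}

#' Save a metric model as plain-text files
#'
#' Writes `drug_vectors.tsv`, `disease_vectors.tsv`,
#' `drug_margins.tsv`, `disease_margins.tsv` and `meta.json` into a
#' directory.
#'
#' @param model a `metric_model`.
#' @param dir destination directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_metric_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dimn <- function(v) ncol(v)
  vec_mat <- function(v) {
    colnames(v) <- sprintf("dim%03d", seq_len(ncol(v)))
    v
  }
  write_labeled_matrix(vec_mat(model$drug_vectors), file.path(dir, "drug_vectors.tsv"))
  write_labeled_matrix(vec_mat(model$disease_vectors), file.path(dir, "disease_vectors.tsv"))
  write_labeled_matrix(vec_mat(cbind(margin = model$drug_margins)),
                       file.path(dir, "drug_margins.tsv"))
  write_labeled_matrix(vec_mat(cbind(margin = model$disease_margins)),
                       file.path(dir, "disease_margins.tsv"))
  jsonlite::write_json(list(clip_bound = model$clip_bound,
                            n = dimn(model$drug_vectors),
                            epochs_run = model$epochs_run),
                       file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a metric model saved by [save_metric_model()]
#'
#' @param dir model directory.
#' @return a `metric_model`.
#' @export
load_metric_model <- function(dir) {
  rd <- function(f) read_labeled_matrix(file.path(dir, f), kind = "numeric")
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  model <- list(
    drug_vectors = rd("drug_vectors.tsv"),
    disease_vectors = rd("disease_vectors.tsv"),
    drug_margins = rd("drug_margins.tsv")[, 1],
    disease_margins = rd("disease_margins.tsv")[, 1],
    clip_bound = meta$clip_bound,
    epochs_run = meta$epochs_run %||% NA_integer_,
    history = NULL
  )
  class(model) <- "metric_model"
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
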