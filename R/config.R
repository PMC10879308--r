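# Run configuration: defaults, YAML loading, validation.

#' Default run configuration
#'
#' Returns the full configuration tree with the method's published
#' hyperparameter settings: GCN embedding dimension `k = 64`, `L = 3`
#' convolution layers, learning rate `lr1 = 0.008`, node dropout 0.6,
#' regularization dropout 0.4, similarity penalty `mu = 6`; metric
#' space dimension `n = 250`, learning rate `lr2 = 0.05`, batch size
#' 512; cold-start neighbor count `h = 5`; 10x10-fold cross-validation.
#' Values the method leaves open (completion threshold `theta`, margin
#' regularization weight `gamma`, clip bound `l`, epoch budgets) carry
#' package defaults documented in the methods vignette.
#'
#' @return a nested list with blocks `completion`, `metric`,
#'   `coldstart`, `evaluation`.
#' @export
default_config <- function() {
  list(
    completion = list(
      k = 64L,            # GCN embedding dimension
      L = 3L,             # number of convolution layers
      lr1 = 0.008,        # Adam learning rate for the completion stage
      node_dropout = 0.6, # row dropout on node features
      reg_dropout = 0.4,  # dropout on layer activations
      mu = 6,             # similarity penalty factor
      theta = 0.9,        # completion confidence threshold
      epochs = 250L,      # Adam step budget
      val_fraction = 0.05,# positives held out for snapshot selection
      patience = 40L,     # epochs without validation-AUC improvement
      trainable_attention = TRUE,
      include_layer0 = TRUE,
      seed = 1L
    ),
    metric = list(
      n = 250L,           # latent dimension of the shared metric space
      lr2 = 0.05,         # AdaGrad learning rate
      batch_size = 512L,
      gamma = 1,          # weight of the adaptive-margin term
      clip_bound_l = 1,   # Euclidean ball radius / margin cap
      P = NULL,           # negatives per positive; NULL = min(M, N)
      epochs = 300L,
      patience = 10L,     # early-stopping patience on validation loss
      val_fraction = 0.05,
      init_spread_is_variance = TRUE, # 0.03 read as variance (sd ~ 0.173)
      seed = 2L
    ),
    coldstart = list(
      h = 5L              # nearest neighbors used to embed a new entity
    ),
    evaluation = list(
      folds = 10L,
      repeats = 10L,
      K = c(5L, 10L, 50L),
      min_positive_degree = 1L
    )
  )
}

#' Load a run configuration from YAML
#'
#' Missing keys are filled with [default_config()]; an empty or absent
#' file therefore yields the full default configuration.  Loading a
#' fully specified configuration returns it unchanged (defaulting is
#' idempotent).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort("no such config file: '%s'", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      if (!is.list(user)) abort("config file must contain a YAML mapping")
      cfg <- utils::modifyList(cfg, user)
    }
  }
  validate_config(cfg)
}

#' Validate a configuration tree
#'
#' @param cfg nested configuration list (see [default_config()]).
#' @return `cfg`, with integer-valued fields coerced to integer.
#' @export
validate_config <- function(cfg) {
  chk <- function(block, key, ok, what) {
    v <- cfg[[block]][[key]]
    if (is.null(v) || !ok(v)) {
      abort("config %s.%s %s (got %s)", block, key, what,
            if (is.null(v)) "nothing" else paste(format(v), collapse = ","))
    }
  }
  pos <- function(v) is_scalar_number(v) && v > 0
  posint <- function(v) is_scalar_number(v) && v >= 1 && v == floor(v)
  frac01 <- function(v) is_scalar_number(v) && v >= 0 && v < 1

  chk("completion", "k", posint, "must be a positive integer dimension")
  chk("completion", "L", posint, "must be a positive integer layer count")
  chk("completion", "lr1", pos, "must be a positive rate")
  chk("completion", "node_dropout", frac01, "must be in [0, 1)")
  chk("completion", "reg_dropout", frac01, "must be in [0, 1)")
  chk("completion", "mu", pos, "must be a positive penalty factor")
  chk("completion", "theta", function(v) is_scalar_number(v) && v >= 0 && v <= 1,
      "must lie in [0, 1]")
  chk("completion", "epochs", function(v) is_scalar_number(v) && v >= 0 && v == floor(v),
      "must be a non-negative integer")
  chk("completion", "val_fraction", frac01, "must be in [0, 1)")
  chk("completion", "patience", posint, "must be a positive integer")
  chk("metric", "n", posint, "must be a positive integer dimension")
  chk("metric", "lr2", pos, "must be a positive rate")
  chk("metric", "batch_size", posint, "must be a positive integer")
  chk("metric", "gamma", function(v) is_scalar_number(v) && v >= 0, "must be non-negative")
  chk("metric", "clip_bound_l", pos, "must be a positive radius")
  if (!is.null(cfg$metric$P)) chk("metric", "P", posint, "must be a positive integer")
  chk("metric", "epochs", function(v) is_scalar_number(v) && v >= 0 && v == floor(v),
      "must be a non-negative integer")
  chk("metric", "patience", posint, "must be a positive integer")
  chk("metric", "val_fraction", frac01, "must be in [0, 1)")
  chk("coldstart", "h", posint, "must be a positive integer")
  chk("evaluation", "folds", function(v) posint(v) && v >= 2, "must be an integer >= 2")
  chk("evaluation", "repeats", posint, "must be a positive integer")
  if (!all(vapply(cfg$evaluation$K, function(v) posint(v), logical(1)))) {
    abort("config evaluation.K must be positive integers")
  }

  for (b in c("completion", "metric")) {
    for (key in c("k", "L", "epochs", "n", "batch_size", "patience")) {
      if (!is.null(cfg[[b]][[key]])) cfg[[b]][[key]] <- as.integer(cfg[[b]][[key]])
    }
  }
  cfg$evaluation$K <- as.integer(cfg$evaluation$K)
  cfg
}
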