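# Ranking metrics and evaluation protocols.

#' Repeated cross-validation splits over known positives
#'
#' Positives are shuffled and partitioned into `folds` near-equal
#' groups, independently per repeat.  For each fold the training
#' matrix is `Y` with the fold's positives zeroed.
#'
#' @param Y binary association matrix.
#' @param folds number of folds (>= 2).
#' @param repeats number of repetitions.
#' @param seed RNG seed.
#' @return list of splits, each a list with `repeat_index`, `fold`,
#'   `train_Y`, and `test_pairs` (2-column index matrix of held-out
#'   positives).
#' @export
make_cv_splits <- function(Y, folds, repeats = 1L, seed = 1L) {
  pos <- which(Y == 1, arr.ind = TRUE)
  n_pos <- nrow(pos)
  if (folds < 2) abort("folds must be >= 2")
  if (n_pos < folds) abort("only %d positives for %d folds", n_pos, folds)
  with_seed(seed, {
    splits <- list()
    for (r in seq_len(repeats)) {
      assign_fold <- sample(rep_len(seq_len(folds), n_pos))
      for (f in seq_len(folds)) {
        test <- pos[assign_fold == f, , drop = FALSE]
        train_Y <- Y
        train_Y[test] <- 0
        splits[[length(splits) + 1]] <- list(repeat_index = r, fold = f,
                                             train_Y = train_Y, test_pairs = test)
      }
    }
    splits
  })
}

#' Area under the ROC curve
#'
#' The probability that a uniformly chosen positive outscores a
#' uniformly chosen negative, with ties counted one half; computed
#' from midranks (equivalent to exhaustive pair counting).
#'
#' @param scores numeric scores, higher = more associated.
#' @param labels binary labels (needs both classes).
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) abort("AUC needs at least one positive and one negative")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation over distinct score thresholds in decreasing
#' order: `sum (R_t - R_{t-1}) * P_t`.  Equals 1 for perfect
#' separation and the positive prevalence in expectation for random
#' scores.
#'
#' @param scores numeric scores, higher = more associated.
#' @param labels binary labels (needs at least one positive).
#' @return AUPR in \[0, 1\].
#' @export
aupr_score <- function(scores, labels) {
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) abort("AUPR needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cum_tp <- cumsum(y)
  cum_n <- seq_along(y)
  # evaluate precision/recall only at threshold boundaries (last index
  # of every run of tied scores)
  boundary <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cum_tp[boundary]; nn <- cum_n[boundary]
  prec <- tp / nn
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Precision and recall at K
#'
#' @param ranked_ids partner identifiers in ranked order (best first).
#' @param positive_ids identifiers of the test positives (>= 1).
#' @param K cutoff (>= 1).
#' @return list with `precision` (= hits in top K / K) and `recall`
#'   (= hits in top K / number of positives).
#' @export
precision_recall_at_k <- function(ranked_ids, positive_ids, K) {
  if (!is_scalar_number(K) || K < 1) abort("K must be >= 1")
  if (length(positive_ids) == 0) abort("recall undefined with zero test positives")
  hits <- sum(utils::head(ranked_ids, K) %in% positive_ids)
  list(precision = hits / K, recall = hits / length(positive_ids))
}

# Score test candidates for one split: returns scores (= -distance)
# and labels over all pairs that are not training positives.
split_scores <- function(distmat, train_Y, test_pairs) {
  candidate <- train_Y == 0
  labels <- matrix(0, nrow(train_Y), ncol(train_Y))
  labels[test_pairs] <- 1
  list(scores = -distmat[candidate], labels = labels[candidate],
       candidate = candidate)
}

topk_by_drug <- function(distmat, train_Y, test_pairs, K_values) {
  test_by_drug <- split(test_pairs[, 2], test_pairs[, 1])
  p_at_k <- r_at_k <- stats::setNames(numeric(length(K_values)), paste0("K", K_values))
  n_drugs <- 0L
  for (drug_chr in names(test_by_drug)) {
    i <- as.integer(drug_chr)
    pos_j <- test_by_drug[[drug_chr]]
    cand <- which(train_Y[i, ] == 0)
    ord <- cand[order(distmat[i, cand])]
    n_drugs <- n_drugs + 1L
    for (ki in seq_along(K_values)) {
      pr <- precision_recall_at_k(ord, pos_j, K_values[ki])
      p_at_k[ki] <- p_at_k[ki] + pr$precision
      r_at_k[ki] <- r_at_k[ki] + pr$recall
    }
  }
  list(p_at_k = p_at_k / n_drugs, r_at_k = r_at_k / n_drugs)
}

#' Run an evaluation protocol
#'
#' Executes the full pipeline (optional completion, then metric
#' learning, then distance scoring) per split and aggregates ranking
#' metrics:
#'
#' * `"cv"` — repeated k-fold cross-validation over known positives;
#'   held-out positives are ranked against all pairs unknown to
#'   training.
#' * `"new_drug"` / `"new_disease"` — leave-one-entity-out: all of an
#'   entity's associations are removed, the model is retrained, the
#'   entity is re-embedded from its `h` nearest similarity neighbors,
#'   and its true partners are ranked against all its candidates.
#'   Entities are filtered by `evaluation$min_positive_degree`.
#' * `"independent"` — train on `associations`, evaluate the positives
#'   of `data$independent` (same entity universe), excluding training
#'   positives from the candidate set.
#'
#' AUC/AUPR are computed globally over all test candidates; p@K / r@K
#' per drug and averaged.
#'
#' @param data list with `drug_sim`, `disease_sim`, `associations`,
#'   and (for `"independent"`) `independent`.
#' @param protocol one of `"cv"`, `"new_drug"`, `"new_disease"`,
#'   `"independent"`.
#' @param config configuration list ([default_config()]).
#' @param completion run the GCN completion stage (`FALSE` gives the
#'   metric-learning-only ablation).
#' @param max_entities cap on the number of left-out entities for the
#'   leave-one-out protocols (`Inf` = all eligible).
#' @param verbose log progress to stderr.
#' @return a `metrics_report`: list with `auc`, `aupr`, `p_at_k`,
#'   `r_at_k`, and a `per_split` data.frame.
#' @export
run_protocol <- function(data, protocol = c("cv", "new_drug", "new_disease", "independent"),
                         config = default_config(), completion = TRUE,
                         max_entities = Inf, verbose = FALSE) {
  protocol <- match.arg(protocol)
  Y <- data$associations
  K_values <- config$evaluation$K
  per_split <- list()
  collect <- function(tag, distmat, train_Y, test_pairs) {
    sc <- split_scores(distmat, train_Y, test_pairs)
    tk <- topk_by_drug(distmat, train_Y, test_pairs, K_values)
    row <- data.frame(split = tag,
                      auc = auc_score(sc$scores, sc$labels),
                      aupr = aupr_score(sc$scores, sc$labels))
    for (ki in seq_along(K_values)) {
      row[[paste0("p_at_", K_values[ki])]] <- tk$p_at_k[ki]
      row[[paste0("r_at_", K_values[ki])]] <- tk$r_at_k[ki]
    }
    row
  }

  if (protocol == "cv") {
    splits <- make_cv_splits(Y, config$evaluation$folds, config$evaluation$repeats,
                             seed = config$metric$seed)
    for (sp in splits) {
      fit <- rsml_fit(data$drug_sim, data$disease_sim, sp$train_Y,
                      config = config, completion = completion, verbose = FALSE)
      tag <- sprintf("rep%d_fold%d", sp$repeat_index, sp$fold)
      per_split[[tag]] <- collect(tag, fit$distances, sp$train_Y, sp$test_pairs)
      if (verbose) message(sprintf("[cv] %s  auc %.3f", tag, per_split[[tag]]$auc))
    }
  } else if (protocol %in% c("new_drug", "new_disease")) {
    drugs_side <- protocol == "new_drug"
    degree <- if (drugs_side) rowSums(Y) else colSums(Y)
    eligible <- which(degree >= config$evaluation$min_positive_degree & degree <
                        (if (drugs_side) ncol(Y) else nrow(Y)))
    if (length(eligible) == 0) abort("no eligible entities for the %s protocol", protocol)
    eligible <- utils::head(eligible, max_entities)
    for (e in eligible) {
      train_Y <- Y
      if (drugs_side) train_Y[e, ] <- 0 else train_Y[, e] <- 0
      fit <- rsml_fit(data$drug_sim, data$disease_sim, train_Y,
                      config = config, completion = completion, verbose = FALSE)
      sim <- if (drugs_side) data$drug_sim[e, -e] else data$disease_sim[e, -e]
      trained <- if (drugs_side) {
        fit$metric$drug_vectors[-e, , drop = FALSE]
      } else {
        fit$metric$disease_vectors[-e, , drop = FALSE]
      }
      v <- cold_start_embed(sim, trained, config$coldstart$h,
                            l = config$metric$clip_bound_l)
      partner_vecs <- if (drugs_side) fit$metric$disease_vectors else fit$metric$drug_vectors
      dist_e <- as.numeric(pairwise_sqdist(matrix(v, 1), partner_vecs))
      pos_j <- if (drugs_side) which(Y[e, ] == 1) else which(Y[, e] == 1)
      labels <- as.numeric(seq_along(dist_e) %in% pos_j)
      tag <- sprintf("%s_%d", protocol, e)
      row <- data.frame(split = tag,
                        auc = auc_score(-dist_e, labels),
                        aupr = aupr_score(-dist_e, labels))
      ord <- order(dist_e)
      for (ki in seq_along(K_values)) {
        pr <- precision_recall_at_k(ord, pos_j, K_values[ki])
        row[[paste0("p_at_", K_values[ki])]] <- pr$precision
        row[[paste0("r_at_", K_values[ki])]] <- pr$recall
      }
      per_split[[tag]] <- row
      if (verbose) message(sprintf("[%s] entity %d  auc %.3f", protocol, e, row$auc))
    }
  } else {  # independent
    ind <- data$independent
    if (is.null(ind)) abort("independent protocol requires data$independent")
    if (!identical(rownames(ind), rownames(Y)) || !identical(colnames(ind), colnames(Y))) {
      miss_r <- setdiff(rownames(ind), rownames(Y))
      miss_c <- setdiff(colnames(ind), colnames(Y))
      abort("independent set does not share the entity universe (offending ids: %s)",
            paste(utils::head(c(miss_r, miss_c), 10), collapse = ", "))
    }
    fit <- rsml_fit(data$drug_sim, data$disease_sim, Y,
                    config = config, completion = completion, verbose = FALSE)
    test_pairs <- which(ind == 1 & Y == 0, arr.ind = TRUE)
    if (nrow(test_pairs) == 0) abort("independent set adds no new positives")
    per_split[["independent"]] <- collect("independent", fit$distances, Y, test_pairs)
  }

  per_split <- do.call(rbind, per_split)
  report <- list(auc = mean(per_split$auc), aupr = mean(per_split$aupr),
                 p_at_k = colMeans(per_split[, grep("^p_at_", names(per_split)), drop = FALSE]),
                 r_at_k = colMeans(per_split[, grep("^r_at_", names(per_split)), drop = FALSE]),
                 per_split = per_split, protocol = protocol)
  class(report) <- "metrics_report"
  report
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Evaluation (%s, %d split(s)): AUC %.4f, AUPR %.4f\n",
              x$protocol, nrow(x$per_split), x$auc, x$aupr))
  k <- sub("^p_at_", "", names(x$p_at_k))
  for (i in seq_along(k)) {
    cat(sprintf("  K = %-4s p@K %.4f  r@K %.4f\n", k[i], x$p_at_k[i], x$r_at_k[i]))
  }
  invisible(x)
}
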