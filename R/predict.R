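# Scoring, top-k ranking, and cold-start embedding.

#' Score all drug-disease pairs
#'
#' Entry (i, j) is the squared Euclidean distance between drug i's and
#' disease j's latent vectors; smaller means a more likely
#' association.  Under ball clipping every entry is at most `(2l)^2`.
#'
#' @param model a trained `metric_model`.
#' @return `M x N` non-negative distance matrix with entity dimnames.
#' @export
score_all <- function(model) {
  d <- pairwise_sqdist(model$drug_vectors, model$disease_vectors)
  dimnames(d) <- list(rownames(model$drug_vectors), rownames(model$disease_vectors))
  d
}

#' Top-k candidates for one anchor
#'
#' Returns the `k` unexcluded partners with the smallest distance,
#' ties broken lexicographically by partner id for reproducibility;
#' fewer than `k` rows when candidates run out.
#'
#' @param distances distance matrix from [score_all()] (anchors in
#'   rows) or a named distance vector for a single anchor.
#' @param anchor row identifier (or index) of the anchor.
#' @param exclude partner identifiers to drop (e.g. known positives).
#' @param k number of candidates (>= 1).
#' @return data.frame with columns `drug_id`, `disease_id`,
#'   `distance`, `rank`.
#' @export
rank_candidates <- function(distances, anchor, exclude = character(0), k = 10L) {
  if (!is_scalar_number(k) || k < 1) abort("k must be >= 1")
  if (is.matrix(distances)) {
    d <- distances[anchor, ]
    anchor_id <- if (is.character(anchor)) anchor else rownames(distances)[anchor]
  } else {
    d <- distances
    anchor_id <- as.character(anchor)
  }
  if (is.null(names(d))) names(d) <- as.character(seq_along(d))
  d <- d[!(names(d) %in% exclude)]
  ord <- order(d, names(d))
  take <- ord[seq_len(min(k, length(d)))]
  data.frame(drug_id = rep(anchor_id, length(take)),
             disease_id = names(d)[take],
             distance = unname(d[take]),
             rank = seq_along(take),
             stringsAsFactors = FALSE)
}

#' Embed a new (cold-start) entity from its similarity profile
#'
#' A drug or disease with no known associations is placed at the
#' similarity-weighted mean of the latent vectors of its `h` most
#' similar training entities (unweighted mean with
#' `weighted = FALSE`), then clipped to the l-ball.
#'
#' @param sim_row similarity of the new entity to each training entity
#'   (named vector aligned with `trained_vectors` rows).
#' @param trained_vectors latent vectors of the training entities.
#' @param h number of neighbors (>= 1).
#' @param l clip bound of the metric space.
#' @param weighted weight neighbors by similarity (default) or not.
#' @return a latent vector of length `ncol(trained_vectors)`.
#' @export
cold_start_embed <- function(sim_row, trained_vectors, h, l = 1, weighted = TRUE) {
  if (!is_scalar_number(h) || h < 1) abort("h must be >= 1")
  if (length(sim_row) != nrow(trained_vectors)) {
    abort("similarity profile length (%d) does not match training entities (%d)",
          length(sim_row), nrow(trained_vectors))
  }
  if (all(sim_row <= 0)) abort("cold start impossible: all similarities are zero")
  ord <- order(sim_row, decreasing = TRUE)
  top <- ord[seq_len(min(h, length(sim_row)))]
  top <- top[sim_row[top] > 0]
  w <- if (weighted) sim_row[top] else rep(1, length(top))
  v <- colSums(trained_vectors[top, , drop = FALSE] * w) / sum(w)
  as.numeric(clip_to_ball(matrix(v, 1), l))
}
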