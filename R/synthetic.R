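# Seeded synthetic drug-disease worlds.
#
# The generator emulates the statistical structure the method assumes:
# drugs and diseases drawn around shared latent cluster centers, so
# that similar drugs treat similar diseases; associations are the
# highest-affinity pairs, similarity matrices are within-type
# proximity kernels.

#' Generate a synthetic drug-disease world
#'
#' Drugs and diseases are placed in a `latent_dim`-dimensional space
#' around `n_clusters` shared Gaussian cluster centers.  Cross-type
#' affinity is `exp(-||u_i - v_j||^2)`; the `round(density * M * N)`
#' highest-affinity pairs become positive associations, after which a
#' `noise` fraction of positives is swapped with uniformly chosen
#' non-planted pairs (the positive count is preserved).  Within-type
#' similarities are `exp(-||.||^2 / 2)` with unit diagonal.
#'
#' @param M,N number of drugs / diseases.
#' @param latent_dim dimension of the generating space.
#' @param density fraction of the `M*N` pairs that are positive.
#' @param noise fraction of positives replaced by random pairs.
#' @param n_clusters number of shared cluster centers.
#' @param seed RNG seed.
#' @return an object of class `synthetic_world`: list with `drug_sim`,
#'   `disease_sim`, `associations`, the ground-truth `affinity`
#'   matrix, the generating `latent` positions, and `seed`.
#' @export
generate_world <- function(M = 60, N = 80, latent_dim = 8, density = 0.05,
                           noise = 0.05, n_clusters = 4, seed = 7L) {
  if (density <= 0 || density >= 1) abort("density must lie in (0, 1)")
  if (latent_dim < 1) abort("latent_dim must be >= 1")
  n_pos <- round(density * M * N)
  if (n_pos < 1) abort("density too low: no positive associations")
  if (n_pos >= M * N) abort("density too high: no negatives would remain")
  with_seed(seed, {
    centers <- matrix(stats::rnorm(n_clusters * latent_dim, 0, 1.5), n_clusters, latent_dim)
    place <- function(n_entities) {
      cl <- sample(rep_len(seq_len(n_clusters), n_entities))
      centers[cl, , drop = FALSE] +
        matrix(stats::rnorm(n_entities * latent_dim, 0, 0.4), n_entities, latent_dim)
    }
    U <- place(M)  # drugs
    V <- place(N)  # diseases
    drug_ids <- sprintf("DR%03d", seq_len(M))
    disease_ids <- sprintf("DI%03d", seq_len(N))
    rownames(U) <- drug_ids; rownames(V) <- disease_ids

    affinity <- exp(-pairwise_sqdist(U, V))
    dimnames(affinity) <- list(drug_ids, disease_ids)
    Y <- matrix(0, M, N, dimnames = dimnames(affinity))
    planted <- order(affinity, decreasing = TRUE)[seq_len(n_pos)]
    Y[planted] <- 1
    if (noise > 0) {
      n_flip <- round(noise * n_pos)
      if (n_flip > 0) {
        drop_idx <- sample(planted, n_flip)
        zeros <- which(Y == 0)
        add_idx <- sample(zeros, n_flip)
        Y[drop_idx] <- 0
        Y[add_idx] <- 1
      }
    }

    kernel_sim <- function(X) {
      s <- exp(-pairwise_sqdist(X, X) / 2)
      diag(s) <- 1
      s <- (s + t(s)) / 2
      dimnames(s) <- list(rownames(X), rownames(X))
      as_similarity_matrix(s)
    }
    structure(list(
      drug_sim = kernel_sim(U),
      disease_sim = kernel_sim(V),
      associations = as_association_matrix(Y),
      affinity = affinity,
      latent = list(drugs = U, diseases = V),
      seed = seed
    ), class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("Synthetic world: %d drugs x %d diseases, %d positives (seed %d)\n",
              nrow(x$associations), ncol(x$associations),
              sum(x$associations), x$seed))
  invisible(x)
}

#' Hold out a fraction of the positive associations
#'
#' Uniformly samples positives and zeroes them in a training copy; the
#' original matrix is untouched.
#'
#' @param world a `synthetic_world` (or any list with an
#'   `associations` matrix).
#' @param fraction fraction of positives to hold out, in (0, 1).
#' @param seed RNG seed.
#' @return list with `train` (association matrix with held-out
#'   positives zeroed) and `held_out` (2-column index matrix).
#' @export
holdout_positives <- function(world, fraction, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) abort("holdout fraction must lie in (0, 1)")
  Y <- world$associations
  pos <- which(Y == 1, arr.ind = TRUE)
  n_hold <- round(fraction * nrow(pos))
  if (n_hold >= nrow(pos)) abort("holdout would remove every positive")
  if (n_hold < 1) abort("holdout fraction removes no positives")
  with_seed(seed, {
    idx <- sample(nrow(pos), n_hold)
    held <- pos[idx, , drop = FALSE]
    train <- Y
    train[held] <- 0
    list(train = train, held_out = held)
  })
}
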