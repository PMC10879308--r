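# Heterogeneous drug-disease network construction.
#
# The network has two node types: M drugs and N diseases.  Within-type
# edges carry (penalized, normalized) similarity weights; cross-type
# edges are the known binary associations.  The block adjacency is
#
#   G = | mu * Sr'   Y  |
#       |   Y^T   mu * Sd' |
#
# with Sr' = E^-1/2 Sr E^-1/2 the symmetrically degree-normalized
# similarity matrix.

#' Jaccard similarity from binary feature profiles
#'
#' `S[i, j] = |P_i intersect P_j| / |P_i union P_j|` over binary
#' feature sets (e.g. substructure or target profiles).  Entities with
#' an all-zero profile yield off-diagonal 0 (with a warning) and keep
#' a unit diagonal.
#'
#' @param profiles binary matrix, one row per entity (row names =
#'   identifiers), one column per feature.
#' @return a [as_similarity_matrix()]-valid matrix.
#' @examples
#' p <- rbind(a = c(1, 1, 0), b = c(0, 1, 1))
#' jaccard_similarity(p)["a", "b"] # 1 shared of 3 total -> 1/3
#' @export
jaccard_similarity <- function(profiles) {
  if (!is.matrix(profiles) || !all(profiles %in% c(0, 1))) {
    abort("profiles must be a binary matrix")
  }
  if (is.null(rownames(profiles))) abort("profiles must carry entity row names")
  sizes <- rowSums(profiles)
  if (any(sizes == 0)) {
    warning(sprintf("all-zero feature profile(s): %s; their similarities are set to 0",
                    paste(rownames(profiles)[sizes == 0], collapse = ", ")))
  }
  inter <- tcrossprod(profiles)
  union <- outer(sizes, sizes, "+") - inter
  s <- ifelse(union > 0, inter / union, 0)
  diag(s) <- 1
  dimnames(s) <- list(rownames(profiles), rownames(profiles))
  as_similarity_matrix(s)
}

#' Symmetric degree normalization of a similarity matrix
#'
#' `S' = E^-1/2 S E^-1/2` with `E = diag(rowSums(S))`, i.e.
#' `S'[i, j] = S[i, j] / sqrt(d_i d_j)`.  The result is symmetric with
#' spectral radius at most 1.
#'
#' @param S non-negative symmetric matrix with positive row sums.
#' @return the normalized matrix (diagonal no longer 1 in general).
#' @export
normalize_similarity <- function(S) {
  if (max(abs(S - t(S))) > 1e-8) abort("similarity matrix must be symmetric")
  if (min(S) < 0) abort("similarity matrix must be non-negative")
  d <- rowSums(S)
  if (any(d <= 0)) {
    bad <- rownames(S)[which(d <= 0)[1]]
    abort("entity '%s' has zero total similarity; add a self-similarity of 1 first",
          if (is.null(bad)) as.character(which(d <= 0)[1]) else bad)
  }
  inv_sqrt <- 1 / sqrt(d)
  S * outer(inv_sqrt, inv_sqrt)
}

#' Apply the similarity penalty factor
#'
#' Scales a normalized similarity matrix by `mu`, controlling how much
#' the within-type similarity edges contribute to the heterogeneous
#' graph relative to the binary association edges.
#'
#' @param S matrix (normally the output of [normalize_similarity()]).
#' @param mu positive scalar.
#' @return `mu * S`.
#' @export
apply_penalty <- function(S, mu) {
  if (!is_scalar_number(mu) || mu <= 0) abort("penalty factor mu must be > 0")
  mu * S
}

#' Assemble the heterogeneous block adjacency
#'
#' @param Sr_hat M x M penalized, normalized drug similarity block.
#' @param Sd_hat N x N penalized, normalized disease similarity block.
#' @param Y M x N binary association matrix.
#' @return an object of class `rsml_hetero`: list with the
#'   `(M+N) x (M+N)` matrix `G`, its `degree` vector, and the
#'   partition sizes `M`, `N`.
#' @export
build_hetero_adjacency <- function(Sr_hat, Sd_hat, Y) {
  M <- nrow(Y); N <- ncol(Y)
  if (nrow(Sr_hat) != M || ncol(Sr_hat) != M) {
    abort("drug similarity block is %dx%d but Y has %d drugs", nrow(Sr_hat), ncol(Sr_hat), M)
  }
  if (nrow(Sd_hat) != N || ncol(Sd_hat) != N) {
    abort("disease similarity block is %dx%d but Y has %d diseases", nrow(Sd_hat), ncol(Sd_hat), N)
  }
  G <- rbind(cbind(Sr_hat, Y), cbind(t(Y), Sd_hat))
  ids <- c(rownames(Y), colnames(Y))
  if (!is.null(rownames(Y)) && !is.null(colnames(Y))) dimnames(G) <- list(ids, ids)
  structure(list(G = G, degree = rowSums(G), M = M, N = N), class = "rsml_hetero")
}

#' @export
print.rsml_hetero <- function(x, ...) {
  cat(sprintf("Heterogeneous drug-disease graph: %d drugs + %d diseases, %d weighted edges\n",
              x$M, x$N, sum(x$G != 0) %/% 2))
  invisible(x)
}
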