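# Independent brute-force oracles used to cross-check the vectorized
# implementations.  Deliberately written as plain loops over the
# definitions, sharing no code with the package internals.

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

oracle_aupr <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  prev_recall <- 0
  for (t in thresholds) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    precision <- tp / sum(sel)
    recall <- tp / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

oracle_bce <- function(scores, Y, eps = 1e-7) {
  n_pos <- sum(Y == 1)
  eta <- sum(Y == 0) / n_pos
  acc <- 0
  for (i in seq_len(nrow(Y))) for (j in seq_len(ncol(Y))) {
    s <- min(max(scores[i, j], eps), 1 - eps)
    acc <- acc + if (Y[i, j] == 1) eta * log(s) else log(1 - s)
  }
  -acc / (nrow(Y) * ncol(Y))
}

oracle_matmul3 <- function(A, H, W) {
  # element-by-element triple product A %*% H %*% W
  out <- matrix(0, nrow(A), ncol(W))
  AH <- matrix(0, nrow(A), ncol(H))
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(H))) {
    AH[i, j] <- sum(sapply(seq_len(ncol(A)), function(k) A[i, k] * H[k, j]))
  }
  for (i in seq_len(nrow(AH))) for (j in seq_len(ncol(W))) {
    out[i, j] <- sum(sapply(seq_len(ncol(AH)), function(k) AH[i, k] * W[k, j]))
  }
  out
}

oracle_bilinear <- function(H_R, H_D, W) {
  out <- matrix(0, nrow(H_R), nrow(H_D))
  for (i in seq_len(nrow(H_R))) for (j in seq_len(nrow(H_D))) {
    z <- 0
    for (a in seq_len(ncol(H_R))) for (b in seq_len(ncol(H_D))) {
      z <- z + H_R[i, a] * W[a, b] * H_D[j, b]
    }
    out[i, j] <- 1 / (1 + exp(-z))
  }
  out
}

oracle_sqdist <- function(a, b) {
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  acc
}
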