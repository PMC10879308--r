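# Association-matrix completion: GCN encoder + bilinear decoder.
#
# Forward model on the heterogeneous graph G ((M+N) nodes):
#   A      = E^-1/2 G E^-1/2           (degree-normalized adjacency)
#   H^0    = G W0                      (linear embedding of each node's
#                                       adjacency profile; W0 is
#                                       (M+N) x k)
#   H^l    = ReLU(A H^{l-1} W^l)       l = 1..L      (k x k weights)
#   Hc     = sum_l beta_l H^l          layer attention, beta_l trainable,
#                                      initialized to 1/(l+1), l = 0..L
#   Ytilde = sigmoid(H_R W' H_D^T)     bilinear decoder over the drug
#                                      rows H_R and disease rows H_D of Hc
# trained with a class-balanced binary cross-entropy (eta = #neg/#pos
# up-weights the sparse positives), by full-batch Adam with manual
# gradients.  Dropout: node dropout zeroes whole feature rows at each
# layer input; regularization dropout acts element-wise on activations
# (both inverted-scaled, training only).

#' Degree-normalized adjacency of a heterogeneous graph
#'
#' Isolated nodes (zero degree) receive a unit self-loop before
#' normalization so that `E^-1/2` is defined.
#'
#' @param het an `rsml_hetero` object from [build_hetero_adjacency()].
#' @return the `(M+N) x (M+N)` matrix `E^-1/2 G E^-1/2`.
#' @export
normalized_adjacency <- function(het) {
  G <- het$G
  deg <- rowSums(G)
  if (any(deg == 0)) {
    idx <- which(deg == 0)
    G[cbind(idx, idx)] <- 1
    deg <- rowSums(G)
  }
  inv_sqrt <- 1 / sqrt(deg)
  G * outer(inv_sqrt, inv_sqrt)
}

#' One graph-convolution layer
#'
#' `activation(A %*% H %*% W)` with a pre-normalized adjacency `A`.
#'
#' @param A_norm normalized adjacency.
#' @param H node feature matrix.
#' @param W weight matrix.
#' @param activation activation function (default [relu]).
#' @return transformed node features.
#' @export
gcn_layer <- function(A_norm, H, W, activation = relu) {
  out <- activation(A_norm %*% H %*% W)
  if (!all(is.finite(out))) abort("non-finite values in GCN layer output")
  out
}

#' Attention-weighted combination of per-layer embeddings
#'
#' `Hc = sum_l beta[l] H_list[[l]]`, split into the drug rows (first
#' `M`) and disease rows (last `N`).
#'
#' @param H_list list of `(M+N) x k` matrices (layers 0..L).
#' @param beta attention weights, one per layer.
#' @param M,N partition sizes.
#' @return list with elements `H_R` (`M x k`) and `H_D` (`N x k`).
#' @export
layer_attention_combine <- function(H_list, beta, M, N) {
  if (length(H_list) != length(beta)) abort("need one attention weight per layer")
  dims <- vapply(H_list, dim, integer(2))
  if (any(dims[1, ] != M + N) || length(unique(dims[2, ])) != 1) {
    abort("all layer embeddings must share the shape (M+N) x k")
  }
  Hc <- Reduce(`+`, Map(`*`, beta, H_list))
  list(H_R = Hc[seq_len(M), , drop = FALSE],
       H_D = Hc[M + seq_len(N), , drop = FALSE])
}

#' Bilinear decoder
#'
#' `sigmoid(H_R %*% W_dec %*% t(H_D))`; entry (i, j) is the predicted
#' association score of drug i and disease j, strictly inside (0, 1).
#'
#' @param H_R drug embeddings (`M x k`).
#' @param H_D disease embeddings (`N x k`).
#' @param W_dec `k x k` decoder weight.
#' @return `M x N` score matrix.
#' @export
bilinear_decode <- function(H_R, H_D, W_dec) {
  sigmoid(H_R %*% W_dec %*% t(H_D))
}

#' Class-balanced binary cross-entropy
#'
#' `-(1/(N*M)) * (eta * sum_{Y=1} log s + sum_{Y=0} log(1 - s))` with
#' `eta = #negatives / #positives` balancing the sparse positive class.
#' Scores are clamped to `[eps, 1 - eps]` (with a warning when the
#' clamp is active) to avoid `log(0)`.
#'
#' @param scores predicted score matrix in (0, 1).
#' @param Y binary association matrix of the same shape.
#' @param eps clamp width (default `1e-7`).
#' @return non-negative scalar loss.
#' @export
weighted_bce_loss <- function(scores, Y, eps = 1e-7) {
  if (!all(dim(scores) == dim(Y))) abort("scores and Y must have the same shape")
  n_pos <- sum(Y == 1)
  if (n_pos == 0) abort("loss undefined: no positive associations (eta = #neg/#pos)")
  if (any(scores <= 0 | scores >= 1)) {
    warning("scores at 0 or 1 clamped inside the cross-entropy")
  }
  s <- pmin(pmax(scores, eps), 1 - eps)
  eta <- sum(Y == 0) / n_pos
  -(eta * sum(log(s[Y == 1])) + sum(log1p(-s[Y == 0]))) / length(Y)
}

# -- internal forward/backward ------------------------------------------------

init_completion_params <- function(n_nodes, k, L, include_layer0 = TRUE) {
  # weight variables uniform in [-0.01, 0.01]; attention beta_l = 1/(l+1)
  ru <- function(nr, nc) matrix(stats::runif(nr * nc, -0.01, 0.01), nr, nc)
  list(
    W0 = ru(n_nodes, k),
    W = lapply(seq_len(L), function(i) ru(k, k)),
    beta = attention_init(L, include_layer0),
    W_dec = ru(k, k)
  )
}

#' Initial layer-attention weights
#'
#' `beta_l = 1/(l+1)` for layers `l = 0..L` (or `l = 1..L` when the
#' input embedding is excluded from the combination).
#'
#' @param L number of convolution layers.
#' @param include_layer0 include the input embedding in the sum.
#' @return numeric vector of attention weights.
#' @export
attention_init <- function(L, include_layer0 = TRUE) {
  l <- if (include_layer0) 0:L else 1:L
  1 / (l + 1)
}

completion_forward <- function(A, G, par, dropout = NULL) {
  L <- length(par$W)
  H <- vector("list", L + 1)
  cache <- list(node_mask = vector("list", L), reg_mask = vector("list", L),
                Z = vector("list", L), Hin_drop = vector("list", L))
  H[[1]] <- G %*% par$W0
  for (l in seq_len(L)) {
    Hin <- H[[l]]
    if (!is.null(dropout) && dropout$node > 0) {
      keep <- stats::rbinom(nrow(Hin), 1, 1 - dropout$node) / (1 - dropout$node)
      cache$node_mask[[l]] <- keep
      Hin <- Hin * keep
    }
    cache$Hin_drop[[l]] <- Hin
    Z <- A %*% Hin %*% par$W[[l]]
    cache$Z[[l]] <- Z
    Hl <- relu(Z)
    if (!is.null(dropout) && dropout$reg > 0) {
      mask <- matrix(stats::rbinom(length(Hl), 1, 1 - dropout$reg) / (1 - dropout$reg),
                     nrow(Hl), ncol(Hl))
      cache$reg_mask[[l]] <- mask
      Hl <- Hl * mask
    }
    H[[l + 1]] <- Hl
  }
  H_used <- if (isTRUE(par$include_layer0) || is.null(par$include_layer0)) H else H[-1]
  cache$H <- H
  cache$H_used <- H_used
  cache
}

completion_backward <- function(A, G, par, cache, emb, scores, Y, eta) {
  # d(loss)/d(decoder logits): positives -(eta/(NM))(1-s), negatives s/(NM)
  NM <- length(Y)
  dZdec <- ifelse(Y == 1, -eta * (1 - scores), scores) / NM
  M <- nrow(Y)
  H_R <- emb$H_R; H_D <- emb$H_D
  grads <- list()
  grads$W_dec <- crossprod(H_R, dZdec %*% H_D)
  dH_R <- dZdec %*% H_D %*% t(par$W_dec)
  dH_D <- crossprod(dZdec, H_R %*% par$W_dec)
  dHc <- rbind(dH_R, dH_D)

  H_used <- cache$H_used
  n_layers_used <- length(H_used)
  grads$beta <- vapply(H_used, function(h) sum(dHc * h), numeric(1))
  offset <- length(cache$H) - n_layers_used  # 1 when layer 0 excluded
  dH <- vector("list", length(cache$H))
  for (i in seq_along(cache$H)) dH[[i]] <- matrix(0, nrow(cache$H[[i]]), ncol(cache$H[[i]]))
  for (i in seq_len(n_layers_used)) {
    dH[[i + offset]] <- dH[[i + offset]] + par$beta[i] * dHc
  }

  L <- length(par$W)
  grads$W <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dHl <- dH[[l + 1]]
    if (!is.null(cache$reg_mask[[l]])) dHl <- dHl * cache$reg_mask[[l]]
    dZ <- dHl * (cache$Z[[l]] > 0)
    AH <- A %*% cache$Hin_drop[[l]]
    grads$W[[l]] <- crossprod(AH, dZ)
    dHin <- A %*% dZ %*% t(par$W[[l]])  # A symmetric
    if (!is.null(cache$node_mask[[l]])) dHin <- dHin * cache$node_mask[[l]]
    dH[[l]] <- dH[[l]] + dHin
  }
  grads$W0 <- crossprod(G, dH[[1]])
  grads
}

adam_step <- function(state, par_names, par, grads, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in par_names) {
    g <- grads[[nm]]
    if (is.list(g)) {
      for (i in seq_along(g)) {
        key <- paste0(nm, i)
        state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g[[i]]
        state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g[[i]]^2
        mhat <- state$m[[key]] / (1 - beta1^t)
        vhat <- state$v[[key]] / (1 - beta2^t)
        par[[nm]][[i]] <- par[[nm]][[i]] - lr * mhat / (sqrt(vhat) + eps)
      }
    } else {
      state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
      state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]] / (1 - beta1^t)
      vhat <- state$v[[nm]] / (1 - beta2^t)
      par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(state = state, par = par)
}

adam_init <- function(par, par_names) {
  zeros_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  state <- list(m = list(), v = list())
  for (nm in par_names) {
    if (is.list(par[[nm]])) {
      for (i in seq_along(par[[nm]])) {
        state$m[[paste0(nm, i)]] <- zeros_like(par[[nm]][[i]])
        state$v[[paste0(nm, i)]] <- zeros_like(par[[nm]][[i]])
      }
    } else {
      state$m[[nm]] <- zeros_like(par[[nm]])
      state$v[[nm]] <- zeros_like(par[[nm]])
    }
  }
  state
}

# -- training -----------------------------------------------------------------

#' Train the completion model
#'
#' Full-batch Adam on the class-balanced cross-entropy.  When
#' `completion$val_fraction > 0` and the matrix holds at least 20
#' positives, that fraction of positives is withheld from the loss and
#' the returned model is the epoch snapshot with the best validation
#' ranking (AUC of the withheld positives against the zero cells);
#' training stops early after `completion$patience` epochs without
#' improvement.  Snapshot selection guards the filling step against
#' the encoder eventually memorizing the zero entries of small
#' matrices (the withheld positives still enter the completed matrix,
#' because [threshold_complete()] pins every known positive).  With
#' `val_fraction = 0` the model from the final epoch is returned.
#'
#' The reported per-epoch losses are evaluation losses (dropout off)
#' on the full matrix; epoch 0 is the loss of the freshly initialized
#' model.
#'
#' @param het heterogeneous graph ([build_hetero_adjacency()]).
#' @param Y binary association matrix (`M x N`, matching `het`).
#' @param config configuration list; only the `completion` block is
#'   used (see [default_config()]).
#' @param verbose log per-epoch losses to stderr.
#' @return an object of class `completion_model`: the trained
#'   parameters, embeddings `H_R`/`H_D` and score matrix `scores` of
#'   the selected snapshot, the `losses` trace, and `val_auc` (NA
#'   without validation).
#' @export
train_completion <- function(het, Y, config = default_config(), verbose = FALSE) {
  cc <- config$completion
  A <- normalized_adjacency(het)
  G <- het$G
  M <- het$M; N <- het$N
  if (nrow(Y) != M || ncol(Y) != N) abort("Y does not match the graph partition sizes")
  n_pos <- sum(Y == 1)
  if (n_pos == 0) abort("cannot train completion without positive associations")

  with_seed(cc$seed, {
    # validation positives withheld from the loss for snapshot selection
    val_frac <- cc$val_fraction %||% 0
    val_idx <- integer(0)
    if (val_frac > 0 && n_pos >= 20) {
      val_idx <- sample(which(Y == 1), max(1L, round(val_frac * n_pos)))
    }
    Y_fit <- Y
    Y_fit[val_idx] <- 0
    eta <- sum(Y_fit == 0) / sum(Y_fit == 1)
    zero_cells <- which(Y_fit == 0)
    val_labels <- as.numeric(zero_cells %in% val_idx)

    par <- init_completion_params(M + N, cc$k, cc$L, cc$include_layer0)
    par$include_layer0 <- isTRUE(cc$include_layer0)
    par_names <- c("W0", "W", "W_dec", if (isTRUE(cc$trainable_attention)) "beta")
    state <- adam_init(par, par_names)
    dropout <- if (cc$node_dropout > 0 || cc$reg_dropout > 0) {
      list(node = cc$node_dropout, reg = cc$reg_dropout)
    } else {
      NULL
    }

    eval_pass <- function(par) {
      cache <- completion_forward(A, G, par, dropout = NULL)
      emb <- layer_attention_combine(cache$H_used, par$beta, M, N)
      scores <- bilinear_decode(emb$H_R, emb$H_D, par$W_dec)
      list(emb = emb, scores = scores, loss = weighted_bce_loss(scores, Y))
    }

    losses <- numeric(0)
    ev <- eval_pass(par)
    losses[1] <- ev$loss
    best <- list(par = par, ev = ev, val_auc = NA_real_)
    best_val <- -Inf
    stall <- 0L
    if (verbose) message(sprintf("[complete] epoch %4d  loss %.6f", 0L, losses[1]))
    if (cc$epochs > 0) {
      for (epoch in seq_len(cc$epochs)) {
        cache <- completion_forward(A, G, par, dropout = dropout)
        emb <- layer_attention_combine(cache$H_used, par$beta, M, N)
        scores <- bilinear_decode(emb$H_R, emb$H_D, par$W_dec)
        grads <- completion_backward(A, G, par, cache, emb, scores, Y_fit, eta)
        upd <- adam_step(state, par_names, par, grads, cc$lr1, epoch)
        state <- upd$state
        inc0 <- par$include_layer0
        par <- upd$par
        par$include_layer0 <- inc0
        ev <- eval_pass(par)
        if (!is.finite(ev$loss)) {
          abort("completion training diverged at epoch %d; try a lower lr1", epoch)
        }
        losses[epoch + 1] <- ev$loss
        if (length(val_idx) > 0) {
          val_auc <- auc_score(ev$scores[zero_cells], val_labels)
          if (verbose) {
            message(sprintf("[complete] epoch %4d  loss %.6f  val-auc %.4f",
                            epoch, ev$loss, val_auc))
          }
          if (val_auc > best_val + 1e-6) {
            best_val <- val_auc
            best <- list(par = par, ev = ev, val_auc = val_auc)
            stall <- 0L
          } else {
            stall <- stall + 1L
            if (stall >= cc$patience) break
          }
        } else {
          if (verbose) message(sprintf("[complete] epoch %4d  loss %.6f", epoch, ev$loss))
          best <- list(par = par, ev = ev, val_auc = NA_real_)
        }
      }
    }
    scores <- best$ev$scores
    dimnames(scores) <- dimnames(Y)
    structure(list(params = best$par, H_R = best$ev$emb$H_R, H_D = best$ev$emb$H_D,
                   scores = scores, losses = losses, eta = eta,
                   val_auc = best$val_auc),
              class = "completion_model")
  })
}

#' @export
print.completion_model <- function(x, ...) {
  cat(sprintf(paste0("GCN completion model: %d drugs x %d diseases, k = %d, ",
                     "%d layers; loss %.4f -> %.4f over %d epochs\n"),
              nrow(x$scores), ncol(x$scores), ncol(x$H_R),
              length(x$params$W), x$losses[1], x$losses[length(x$losses)],
              length(x$losses) - 1L))
  invisible(x)
}

#' Threshold the completion scores into a completed association matrix
#'
#' Known positives are always kept (pinned at 1); a zero entry whose
#' predicted score reaches the confidence threshold `theta` is filled
#' with that score, otherwise it stays 0.  The support of the result
#' shrinks monotonically as `theta` grows.
#'
#' @param scores predicted score matrix in (0, 1).
#' @param Y raw binary association matrix.
#' @param theta confidence threshold in \[0, 1\].
#' @return the completed, real-valued association matrix.
#' @export
threshold_complete <- function(scores, Y, theta) {
  if (!is_scalar_number(theta) || theta < 0 || theta > 1) abort("theta must lie in [0, 1]")
  if (!all(dim(scores) == dim(Y))) abort("scores and Y must have the same shape")
  out <- ifelse(Y == 1, 1, ifelse(scores >= theta, scores, 0))
  dimnames(out) <- dimnames(Y)
  out
}
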