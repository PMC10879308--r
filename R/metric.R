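# Symmetric collaborative metric learning with adaptive margins.
#
# Drugs and diseases are embedded in one n-dimensional space; a known
# association (r, d) must sit closer than any sampled non-association,
# by a learned per-entity margin:
#
#   drug-centric    d(r,d) + m_r <= d(r, dbar)
#   disease-centric d(r,d) + n_d <= d(d, rbar)
#
# with d the squared Euclidean distance.  The loss is the sum of the
# two hinge losses plus -gamma * (mean m + mean n), which pushes
# margins to grow as far as the hinges allow; embeddings are clipped
# to the l-ball and margins clamped to (0, l] after every update.
# Optimized with AdaGrad over negative-sampled triplets.

#' Squared Euclidean distance
#'
#' @param a,b numeric vectors of equal length.
#' @return `sum((a - b)^2)`.
#' @examples
#' squared_distance(c(0, 0), c(3, 4)) # 25
#' @export
squared_distance <- function(a, b) {
  if (length(a) != length(b)) abort("vectors differ in length (%d vs %d)", length(a), length(b))
  sum((a - b)^2)
}

#' Sample a batch of triplets from a completed association matrix
#'
#' For every positive entry (anchor, positive partner) the batch holds
#' `P` negatives drawn uniformly without replacement from the anchor's
#' zero-entry partners (fewer when not enough are available).  Any
#' entry of `Y_completed` strictly greater than 0 counts as a
#' positive.  Anchors with no zero-entry partner contribute no
#' triplets (with a warning).
#'
#' @param Y_completed completed (or raw) association matrix.
#' @param centric `"drug"` (anchors are drugs, partners diseases) or
#'   `"disease"`.
#' @param P negatives per positive; default `min(M, N)`.
#' @param positives optional 2-column matrix of (row, col) indices into
#'   `Y_completed` restricting which positive entries are used.
#' @return an object of class `triplet_batch`: data.frame with integer
#'   columns `anchor`, `pos`, `neg` (indices into the anchor-side and
#'   partner-side entity lists) and attribute `centric`.
#' @export
sample_triplets <- function(Y_completed, centric = c("drug", "disease"), P = NULL,
                            positives = NULL) {
  centric <- match.arg(centric)
  A <- if (centric == "drug") Y_completed else t(Y_completed)
  if (is.null(P)) P <- min(dim(Y_completed))
  if (is.null(positives)) {
    positives <- which(A > 0, arr.ind = TRUE)
  } else if (centric == "disease") {
    positives <- positives[, c(2, 1), drop = FALSE]
  }
  if (nrow(positives) == 0) abort("no positive associations to sample from")
  pos_by_anchor <- split(positives[, 2], positives[, 1])
  parts <- vector("list", length(pos_by_anchor))
  skipped <- 0L
  for (i in seq_along(pos_by_anchor)) {
    a <- as.integer(names(pos_by_anchor)[i])
    pool <- which(A[a, ] == 0)
    if (length(pool) == 0) {
      skipped <- skipped + 1L
      next
    }
    a_pos <- pos_by_anchor[[i]]
    k <- min(P, length(pool))
    neg <- if (length(pool) == 1) {
      rep.int(pool, length(a_pos))
    } else {
      as.vector(vapply(a_pos, function(p) sample(pool, k), integer(k)))
    }
    parts[[i]] <- data.frame(anchor = rep.int(a, k * length(a_pos)),
                             pos = rep(a_pos, each = k), neg = neg)
  }
  if (skipped > 0) {
    warning(sprintf("%d anchor(s) with no zero-entry partners skipped", skipped))
  }
  out <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(anchor = integer(0), pos = integer(0), neg = integer(0))
  structure(out, centric = centric, class = c("triplet_batch", "data.frame"))
}

#' Drug-centric triplet hinge loss
#'
#' `sum over triplets of max(d(r,d) - d(r,dbar) + m_r, 0)` with the
#' anchor drug's adaptive margin `m_r`; zero exactly when every
#' sampled constraint is satisfied.
#'
#' @param model a `metric_model` (or any list with `drug_vectors`,
#'   `disease_vectors`, `drug_margins`).
#' @param triplets drug-centric batch from [sample_triplets()].
#' @return non-negative scalar.
#' @export
drug_centric_loss <- function(model, triplets) {
  if (nrow(triplets) == 0) return(0)
  Ar <- model$drug_vectors[triplets$anchor, , drop = FALSE]
  d_pos <- rowSums((Ar - model$disease_vectors[triplets$pos, , drop = FALSE])^2)
  d_neg <- rowSums((Ar - model$disease_vectors[triplets$neg, , drop = FALSE])^2)
  sum(pmax(d_pos - d_neg + model$drug_margins[triplets$anchor], 0))
}

#' Disease-centric triplet hinge loss
#'
#' `sum over triplets of max(d(r,d) - d(d,rbar) + n_d, 0)` with the
#' anchor disease's adaptive margin `n_d`.  Anchors index diseases,
#' partners index drugs.
#'
#' @param model a `metric_model`.
#' @param triplets disease-centric batch from [sample_triplets()].
#' @return non-negative scalar.
#' @export
disease_centric_loss <- function(model, triplets) {
  if (nrow(triplets) == 0) return(0)
  Bd <- model$disease_vectors[triplets$anchor, , drop = FALSE]
  d_pos <- rowSums((model$drug_vectors[triplets$pos, , drop = FALSE] - Bd)^2)
  d_neg <- rowSums((Bd - model$drug_vectors[triplets$neg, , drop = FALSE])^2)
  sum(pmax(d_pos - d_neg + model$disease_margins[triplets$anchor], 0))
}

#' Adaptive-margin regularizer
#'
#' `-(mean(drug margins) + mean(disease margins))`; always in
#' `[-2l, 0)`, rewarding large margins.
#'
#' @param model a `metric_model`.
#' @return negative scalar.
#' @export
adaptive_margin_loss <- function(model) {
  -(mean(model$drug_margins) + mean(model$disease_margins))
}

#' Total metric-learning objective
#'
#' `L = L_R + L_D + gamma * L_AM`.
#'
#' @param model a `metric_model`.
#' @param drug_triplets,disease_triplets batches from [sample_triplets()].
#' @param gamma weight of the adaptive-margin term (>= 0).
#' @return scalar loss.
#' @export
total_loss <- function(model, drug_triplets, disease_triplets, gamma) {
  if (!is_scalar_number(gamma) || gamma < 0) abort("gamma must be >= 0")
  drug_centric_loss(model, drug_triplets) +
    disease_centric_loss(model, disease_triplets) +
    gamma * adaptive_margin_loss(model)
}

#' Project row vectors onto the l-ball
#'
#' Rows with Euclidean norm above `l` are rescaled to norm exactly
#' `l`; others are untouched.  Idempotent.
#'
#' @param vectors numeric matrix, one vector per row.
#' @param l ball radius (> 0).
#' @return the projected matrix.
#' @export
clip_to_ball <- function(vectors, l) {
  if (!is_scalar_number(l) || l <= 0) abort("clip bound l must be > 0")
  nrm <- row_norms(vectors)
  over <- nrm > l
  if (any(over)) vectors[over, ] <- vectors[over, , drop = FALSE] * (l / nrm[over])
  vectors
}

#' Clamp margins into (0, l]
#'
#' The open lower end is approximated by `eps`.
#'
#' @param margins numeric vector.
#' @param l upper bound (> 0).
#' @param eps positive floor (default `1e-6`).
#' @return the clamped vector.
#' @export
clamp_margins <- function(margins, l, eps = 1e-6) {
  if (!is_scalar_number(l) || l <= 0) abort("clip bound l must be > 0")
  pmin(pmax(margins, eps), l)
}

# -- training -----------------------------------------------------------------

# Gradient of one batch (both centrics), accumulated into dense
# matrices via rowsum().  Margin gradients include the hinge count
# plus the adaptive-margin pull scaled by the batch's share of the
# epoch, so a full epoch applies exactly one L_AM gradient.
metric_batch_grads <- function(model, dt, st, gamma, batch_frac) {
  M <- nrow(model$drug_vectors); N <- nrow(model$disease_vectors)
  n <- ncol(model$drug_vectors)
  gA <- matrix(0, M, n); gB <- matrix(0, N, n)
  gm <- numeric(M); gn <- numeric(N)

  add_rows <- function(acc, rows, idx) {
    s <- rowsum(rows, idx)
    ii <- as.integer(rownames(s))
    acc[ii, ] <- acc[ii, , drop = FALSE] + s
    acc
  }

  if (nrow(dt) > 0) {
    Ar <- model$drug_vectors[dt$anchor, , drop = FALSE]
    Bp <- model$disease_vectors[dt$pos, , drop = FALSE]
    Bq <- model$disease_vectors[dt$neg, , drop = FALSE]
    act <- rowSums((Ar - Bp)^2) - rowSums((Ar - Bq)^2) +
      model$drug_margins[dt$anchor] > 0
    if (any(act)) {
      Ar <- Ar[act, , drop = FALSE]; Bp <- Bp[act, , drop = FALSE]; Bq <- Bq[act, , drop = FALSE]
      gA <- add_rows(gA, 2 * (Bq - Bp), dt$anchor[act])
      gB <- add_rows(gB, -2 * (Ar - Bp), dt$pos[act])
      gB <- add_rows(gB, 2 * (Ar - Bq), dt$neg[act])
      cnt <- table(dt$anchor[act])
      gm[as.integer(names(cnt))] <- gm[as.integer(names(cnt))] + as.numeric(cnt)
    }
  }
  if (nrow(st) > 0) {
    Bd <- model$disease_vectors[st$anchor, , drop = FALSE]
    Ap <- model$drug_vectors[st$pos, , drop = FALSE]
    Aq <- model$drug_vectors[st$neg, , drop = FALSE]
    act <- rowSums((Ap - Bd)^2) - rowSums((Bd - Aq)^2) +
      model$disease_margins[st$anchor] > 0
    if (any(act)) {
      Bd <- Bd[act, , drop = FALSE]; Ap <- Ap[act, , drop = FALSE]; Aq <- Aq[act, , drop = FALSE]
      gB <- add_rows(gB, -2 * (Ap - Bd) - 2 * (Bd - Aq), st$anchor[act])
      gA <- add_rows(gA, 2 * (Ap - Bd), st$pos[act])
      gA <- add_rows(gA, 2 * (Bd - Aq), st$neg[act])
      cnt <- table(st$anchor[act])
      gn[as.integer(names(cnt))] <- gn[as.integer(names(cnt))] + as.numeric(cnt)
    }
  }
  gm <- gm - batch_frac * gamma / M
  gn <- gn - batch_frac * gamma / N
  list(A = gA, B = gB, m = gm, n = gn)
}

#' Train the symmetric metric-learning model
#'
#' Latent vectors are initialized from N(0.1, 0.03) (the spread read
#' as a variance; see `init_spread_is_variance`), margins uniformly in
#' (0, l].  Each epoch samples, for every positive entry of
#' `Y_completed`, `P` negatives for both centric views; the resulting
#' triplets are consumed in shuffled batches of about `batch_size`
#' triplets, grouped so that a positive's negatives stay in one batch;
#' each batch applies one AdaGrad step on the total objective followed
#' by re-projection (ball clipping, margin clamping).  Training stops at the epoch budget or when the
#' validation loss (on a held-out 5% of positives with fixed
#' triplets) fails to improve for `patience` epochs.
#'
#' @param Y_completed completed (or raw binary) association matrix;
#'   entries > 0 are treated as positives.
#' @param config configuration list; only the `metric` block is used.
#' @param verbose log per-epoch losses to stderr.
#' @return an object of class `metric_model` with `drug_vectors`
#'   (`M x n`), `disease_vectors` (`N x n`), `drug_margins`,
#'   `disease_margins`, `clip_bound`, and a per-epoch `history`
#'   (training loss, validation loss, max row norm, margin range).
#' @export
train_metric <- function(Y_completed, config = default_config(), verbose = FALSE) {
  mc <- config$metric
  M <- nrow(Y_completed); N <- ncol(Y_completed)
  n <- mc$n
  l <- mc$clip_bound_l
  P <- if (is.null(mc$P)) min(M, N) else mc$P
  pos_all <- which(Y_completed > 0, arr.ind = TRUE)
  if (nrow(pos_all) == 0) abort("cannot train: no positive associations")

  with_seed(mc$seed, {
    sd0 <- if (isTRUE(mc$init_spread_is_variance)) sqrt(0.03) else 0.03
    model <- list(
      drug_vectors = matrix(stats::rnorm(M * n, 0.1, sd0), M, n),
      disease_vectors = matrix(stats::rnorm(N * n, 0.1, sd0), N, n),
      drug_margins = stats::runif(M) * l,
      disease_margins = stats::runif(N) * l,
      clip_bound = l
    )
    model$drug_vectors <- clip_to_ball(model$drug_vectors, l)
    model$disease_vectors <- clip_to_ball(model$disease_vectors, l)
    model$drug_margins <- clamp_margins(model$drug_margins, l)
    model$disease_margins <- clamp_margins(model$disease_margins, l)

    # validation split over positives, with frozen validation triplets
    n_val <- if (mc$val_fraction > 0 && nrow(pos_all) >= 20) {
      max(1L, round(mc$val_fraction * nrow(pos_all)))
    } else {
      0L
    }
    val_idx <- if (n_val > 0) sample(nrow(pos_all), n_val) else integer(0)
    train_pos <- if (n_val > 0) pos_all[-val_idx, , drop = FALSE] else pos_all
    val_trip <- NULL
    if (n_val > 0) {
      vp <- pos_all[val_idx, , drop = FALSE]
      val_trip <- list(
        drug = sample_triplets(Y_completed, "drug", P, positives = vp),
        disease = sample_triplets(Y_completed, "disease", P, positives = vp)
      )
    }
    n_train <- nrow(train_pos)

    acc <- list(A = matrix(0, M, n), B = matrix(0, N, n), m = numeric(M), n = numeric(N))
    eps_ada <- 1e-8
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0), max_norm = numeric(0),
                          min_margin = numeric(0), max_margin = numeric(0))
    best_val <- Inf; stall <- 0L
    epochs_run <- 0L

    # each positive contributes P triplets per centric view, so a batch
    # of batch_size triplets holds about batch_size / (2P) whole positives
    pos_per_batch <- max(1L, as.integer(round(mc$batch_size / (2 * P))))

    for (epoch in seq_len(mc$epochs)) {
      # fresh negative samples each epoch, both centric views
      trip_d <- sample_triplets(Y_completed, "drug", P, positives = train_pos)
      trip_s <- sample_triplets(Y_completed, "disease", P, positives = train_pos)
      # triplet rows grouped by the positive pair they expand
      key <- paste(train_pos[, 1], train_pos[, 2])
      grp_d <- split(seq_len(nrow(trip_d)), match(paste(trip_d$anchor, trip_d$pos), key))
      grp_s <- split(seq_len(nrow(trip_s)), match(paste(trip_s$pos, trip_s$anchor), key))
      ord <- sample(n_train)
      epoch_loss <- 0
      for (start in seq(1, n_train, by = pos_per_batch)) {
        take <- ord[start:min(start + pos_per_batch - 1, n_train)]
        dt <- trip_d[unlist(grp_d[as.character(take)], use.names = FALSE), , drop = FALSE]
        st <- trip_s[unlist(grp_s[as.character(take)], use.names = FALSE), , drop = FALSE]
        frac <- length(take) / n_train
        epoch_loss <- epoch_loss + drug_centric_loss(model, dt) +
          disease_centric_loss(model, st) +
          frac * mc$gamma * adaptive_margin_loss(model)
        g <- metric_batch_grads(model, dt, st, mc$gamma, frac)
        acc$A <- acc$A + g$A^2; acc$B <- acc$B + g$B^2
        acc$m <- acc$m + g$m^2; acc$n <- acc$n + g$n^2
        model$drug_vectors <- model$drug_vectors - mc$lr2 * g$A / (sqrt(acc$A) + eps_ada)
        model$disease_vectors <- model$disease_vectors - mc$lr2 * g$B / (sqrt(acc$B) + eps_ada)
        model$drug_margins <- model$drug_margins - mc$lr2 * g$m / (sqrt(acc$m) + eps_ada)
        model$disease_margins <- model$disease_margins - mc$lr2 * g$n / (sqrt(acc$n) + eps_ada)
        model$drug_vectors <- clip_to_ball(model$drug_vectors, l)
        model$disease_vectors <- clip_to_ball(model$disease_vectors, l)
        model$drug_margins <- clamp_margins(model$drug_margins, l)
        model$disease_margins <- clamp_margins(model$disease_margins, l)
      }
      if (!is.finite(epoch_loss)) abort("metric training diverged (non-finite loss) at epoch %d", epoch)
      val_loss <- if (!is.null(val_trip)) {
        total_loss(model, val_trip$drug, val_trip$disease, mc$gamma)
      } else {
        NA_real_
      }
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = epoch_loss, val_loss = val_loss,
        max_norm = max(row_norms(model$drug_vectors), row_norms(model$disease_vectors)),
        min_margin = min(model$drug_margins, model$disease_margins),
        max_margin = max(model$drug_margins, model$disease_margins)))
      if (verbose) {
        message(sprintf("[metric] epoch %4d  train %.4f  val %s", epoch, epoch_loss,
                        if (is.na(val_loss)) "-" else sprintf("%.4f", val_loss)))
      }
      epochs_run <- epoch
      if (!is.na(val_loss)) {
        if (val_loss < best_val - 1e-9) {
          best_val <- val_loss
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= mc$patience) break
        }
      }
    }

    rownames(model$drug_vectors) <- rownames(Y_completed)
    rownames(model$disease_vectors) <- colnames(Y_completed)
    names(model$drug_margins) <- rownames(Y_completed)
    names(model$disease_margins) <- colnames(Y_completed)
    model$history <- history
    model$epochs_run <- epochs_run
    class(model) <- "metric_model"
    model
  })
}

#' @export
print.metric_model <- function(x, ...) {
  cat(sprintf(paste0("Symmetric metric model: %d drugs + %d diseases in %d dims ",
                     "(ball radius %g), %d epochs\n"),
              nrow(x$drug_vectors), nrow(x$disease_vectors),
              ncol(x$drug_vectors), x$clip_bound, x$epochs_run))
  invisible(x)
}
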