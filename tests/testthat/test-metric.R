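test_that("squared distance is the squared Euclidean norm", {
  expect_equal(squared_distance(c(0, 0), c(3, 4)), 25)
  a <- rnorm(6)
  expect_equal(squared_distance(a, a), 0)
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(5)
    expect_equal(squared_distance(x, y), squared_distance(y, x))
    expect_equal(squared_distance(x, y), oracle_sqdist(x, y), tolerance = 1e-12)
  }
  expect_error(squared_distance(1:3, 1:4), "length")
})

# a small hand-built model: distances are controlled exactly
toy_model <- function() {
  list(drug_vectors = rbind(c(0, 0), c(1, 0)),
       disease_vectors = rbind(c(0.5, 0), c(0, 1), c(2, 0)),
       drug_margins = c(0.5, 0.2),
       disease_margins = c(0.4, 0.3, 0.6),
       clip_bound = 1)
}

test_that("hinge losses are zero iff every sampled constraint holds", {
  m <- toy_model()
  # drug 1: d(r1,d1) = 0.25, d(r1,d3) = 4; margin 0.5 -> satisfied
  sat <- data.frame(anchor = 1L, pos = 1L, neg = 3L)
  expect_identical(drug_centric_loss(m, sat), 0)
  # violated: d(r1,d1) = 0.25 vs d(r1,d2) = 1, margin 0.5 -> 0.25-1+0.5 < 0 ok;
  # make it active by enlarging the margin
  m2 <- m; m2$drug_margins[1] <- 0.9
  act <- data.frame(anchor = 1L, pos = 1L, neg = 2L)
  expect_equal(drug_centric_loss(m2, act), 0.25 - 1 + 0.9)
  expect_gt(drug_centric_loss(m2, act), 0)

  # explicit arithmetic: d_pos 0.9, d_neg 0.4, margin 0.2 -> 0.7
  m3 <- list(drug_vectors = matrix(c(0, 0), 1),
             disease_vectors = rbind(c(sqrt(0.9), 0), c(sqrt(0.4), 0)),
             drug_margins = 0.2, disease_margins = 1, clip_bound = 1)
  t3 <- data.frame(anchor = 1L, pos = 1L, neg = 2L)
  expect_equal(drug_centric_loss(m3, t3), 0.7)

  # batches with every constraint satisfied sum exactly to zero
  batch <- data.frame(anchor = c(1L, 1L), pos = c(1L, 1L), neg = c(3L, 3L))
  expect_identical(drug_centric_loss(m, batch), 0)
})

test_that("disease-centric loss mirrors the drug-centric loss by role swap", {
  set.seed(8)
  M <- 6; N <- 7; n <- 3
  model <- list(drug_vectors = matrix(rnorm(M * n), M, n),
                disease_vectors = matrix(rnorm(N * n), N, n),
                drug_margins = runif(M), disease_margins = runif(N),
                clip_bound = 1)
  swapped <- list(drug_vectors = model$disease_vectors,
                  disease_vectors = model$drug_vectors,
                  drug_margins = model$disease_margins,
                  disease_margins = model$drug_margins,
                  clip_bound = 1)
  trip <- data.frame(anchor = sample(N, 20, TRUE), pos = sample(M, 20, TRUE),
                     neg = sample(M, 20, TRUE))
  # same index pattern read in the swapped roles
  expect_equal(disease_centric_loss(model, trip),
               drug_centric_loss(swapped, trip), tolerance = 1e-12)
})

test_that("adaptive margin and total losses follow their formulas", {
  m <- list(drug_margins = c(0.5, 1), disease_margins = c(1, 1))
  expect_equal(adaptive_margin_loss(m), -1.75)
  m2 <- list(drug_margins = rep(0.8, 4), disease_margins = rep(0.8, 5))
  expect_equal(adaptive_margin_loss(m2), -1.6)  # all margins at l -> -2l

  tm <- toy_model()
  dt <- data.frame(anchor = 1L, pos = 1L, neg = 3L)
  st <- data.frame(anchor = 1L, pos = 1L, neg = 2L)
  lr <- drug_centric_loss(tm, dt)
  ld <- disease_centric_loss(tm, st)
  lam <- adaptive_margin_loss(tm)
  expect_equal(total_loss(tm, dt, st, 0.1), lr + ld + 0.1 * lam)
  expect_equal(total_loss(tm, dt, st, 0), lr + ld)
  expect_error(total_loss(tm, dt, st, -1), "gamma")
})

test_that("triplet sampling draws valid negatives with the published P default", {
  set.seed(12)
  Y <- matrix(rbinom(35, 1, 0.4), 7, 5)
  Y[3, ] <- 1  # anchor with no zero-entry partners
  Y[1, 1] <- 1
  expect_warning(tb <- sample_triplets(Y, "drug"), "skipped")
  expect_true(all(Y[cbind(tb$anchor, tb$pos)] > 0))
  expect_true(all(Y[cbind(tb$anchor, tb$neg)] == 0))
  expect_false(3 %in% tb$anchor)

  # default P = min(M, N) = 5, capped at the available pool
  counts <- table(paste(tb$anchor, tb$pos))
  pool_size <- rowSums(Y == 0)
  for (a in unique(tb$anchor)) {
    expect_true(all(counts[grep(paste0("^", a, " "), names(counts))] ==
                      min(5, pool_size[a])))
  }

  s1 <- with_seed_for_tests(99, suppressWarnings(sample_triplets(Y, "drug")))
  s2 <- with_seed_for_tests(99, suppressWarnings(sample_triplets(Y, "drug")))
  expect_identical(s1, s2)

  Yfull <- matrix(1, 2, 3)
  expect_warning(empty <- sample_triplets(Yfull, "drug"), "skipped")
  expect_equal(nrow(empty), 0)
})

test_that("projections clip norms and clamp margins idempotently", {
  v <- rbind(c(3, 4), c(0.1, 0))
  out <- clip_to_ball(v, 1)
  expect_equal(out[1, ], c(0.6, 0.8))
  expect_equal(out[2, ], c(0.1, 0))
  expect_identical(clip_to_ball(out, 1), out)

  set.seed(31)
  r <- matrix(rnorm(60, sd = 3), 20, 3)
  clipped <- clip_to_ball(r, 1.5)
  expect_true(all(sqrt(rowSums(clipped^2)) <= 1.5 + 1e-12))

  expect_equal(clamp_margins(c(1.7, -0.2, 0.5), 1), c(1, 1e-6, 0.5))
  m <- clamp_margins(runif(10, -1, 2), 1)
  expect_identical(clamp_margins(m, 1), m)
  expect_true(all(m > 0 & m <= 1))
})

test_that("metric gradients match finite differences", {
  set.seed(42)
  M <- 5; N <- 6; n <- 3
  model <- list(drug_vectors = matrix(rnorm(M * n), M, n),
                disease_vectors = matrix(rnorm(N * n), N, n),
                drug_margins = runif(M), disease_margins = runif(N),
                clip_bound = 1)
  Y <- matrix(rbinom(M * N, 1, 0.3), M, N)
  if (sum(Y) == 0) Y[2, 2] <- 1
  dt <- sample_triplets(Y, "drug", P = 3)
  st <- sample_triplets(Y, "disease", P = 3)
  gamma <- 0.7
  g <- rsmlgcn:::metric_batch_grads(model, dt, st, gamma, 1)
  f <- function(m) total_loss(m, dt, st, gamma)
  eps <- 1e-6
  for (probe in list(c("drug_vectors", 3), c("disease_vectors", 7),
                     c("drug_vectors", 11), c("disease_vectors", 2))) {
    fld <- probe[1]; i <- as.integer(probe[2])
    m1 <- model; m1[[fld]][i] <- m1[[fld]][i] + eps
    m2 <- model; m2[[fld]][i] <- m2[[fld]][i] - eps
    num <- (f(m1) - f(m2)) / (2 * eps)
    ana <- if (fld == "drug_vectors") g$A[i] else g$B[i]
    expect_equal(num, ana, tolerance = 1e-5)
  }
  for (i in 1:M) {
    m1 <- model; m1$drug_margins[i] <- m1$drug_margins[i] + eps
    m2 <- model; m2$drug_margins[i] <- m2$drug_margins[i] - eps
    expect_equal((f(m1) - f(m2)) / (2 * eps), g$m[i], tolerance = 1e-5)
  }
})

test_that("drug-centric loss is non-decreasing in each drug margin", {
  m <- toy_model()
  trip <- data.frame(anchor = c(1L, 2L, 1L), pos = c(1L, 2L, 2L),
                     neg = c(3L, 1L, 3L))
  for (i in 1:2) {
    vals <- sapply(seq(0, 1, by = 0.1), function(mm) {
      m2 <- m; m2$drug_margins[i] <- mm
      drug_centric_loss(m2, trip)
    })
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("metric training respects its invariants and seeds", {
  w <- tiny_world(20, 30, seed = 13)
  cfg <- tiny_config()
  model <- train_metric(w$associations, cfg)
  l <- cfg$metric$clip_bound_l
  expect_true(all(model$history$max_norm <= l + 1e-12))
  expect_true(all(model$history$min_margin > 0))
  expect_true(all(model$history$max_margin <= l + 1e-12))
  # optimization sanity: hinge loss falls from the first epoch
  expect_lt(model$history$train_loss[nrow(model$history)],
            model$history$train_loss[1])

  model2 <- train_metric(w$associations, cfg)
  expect_identical(model$drug_vectors, model2$drug_vectors)
  expect_identical(model$disease_margins, model2$disease_margins)
})

test_that("training recovers planted metric structure", {
  # plant clustered ground-truth vectors in dimension 4 (the structure
  # the method assumes: similar drugs treat similar diseases);
  # positives are the closest cross-type pairs
  set.seed(77)
  M <- 30; N <- 40
  centers <- matrix(rnorm(16, 0, 1.5), 4, 4)
  U <- centers[sample(rep(1:4, length.out = M)), ] + matrix(rnorm(M * 4, 0, 0.4), M, 4)
  V <- centers[sample(rep(1:4, length.out = N)), ] + matrix(rnorm(N * 4, 0, 0.4), N, 4)
  d <- rsmlgcn:::pairwise_sqdist(U, V)
  Y <- labeled((d < quantile(d, 0.12)) * 1)
  pos <- which(Y == 1)
  set.seed(78)
  test_idx <- sample(pos, round(0.3 * length(pos)))
  train_Y <- Y; train_Y[test_idx] <- 0

  cfg <- default_config()  # n = 250, the published latent dimension
  cfg$metric$epochs <- 40L; cfg$metric$patience <- 40L
  model <- suppressWarnings(train_metric(train_Y, cfg))
  dd <- score_all(model)
  zeros <- which(train_Y == 0)
  labels <- as.numeric(zeros %in% test_idx)
  auc <- auc_score(-dd[zeros], labels)
  expect_gte(auc, 0.8)
})
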