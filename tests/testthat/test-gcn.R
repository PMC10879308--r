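test_that("gcn_layer agrees with the dense triple-product oracle", {
  A <- matrix(0, 3, 3)
  H0 <- matrix(0, 3, 2)
  W <- diag(2)
  expect_equal(gcn_layer(A, H0, W), matrix(0, 3, 2))  # zero propagation

  set.seed(11)
  A4 <- matrix(runif(16), 4, 4); A4 <- (A4 + t(A4)) / 2
  H <- matrix(rnorm(12), 4, 3)
  W4 <- diag(3)
  expect_equal(unname(gcn_layer(A4, H, W4, activation = identity)),
               oracle_matmul3(A4, H, W4), tolerance = 1e-12)

  # single node with a unit self-loop
  expect_equal(gcn_layer(matrix(1), matrix(2.5), matrix(-3)), matrix(0))
  expect_equal(gcn_layer(matrix(1), matrix(2.5), matrix(3)), matrix(7.5))
})

test_that("layer attention combines and initializes as 1/(l+1)", {
  H <- matrix(rnorm(10), 5, 2)
  out <- layer_attention_combine(list(H), 1, M = 2, N = 3)
  expect_equal(rbind(out$H_R, out$H_D), H)  # single layer is identity

  out2 <- layer_attention_combine(list(H, H), c(0.5, 0.5), 2, 3)
  expect_equal(rbind(out2$H_R, out2$H_D), H)  # convexity on equal layers

  expect_equal(attention_init(3), c(1, 1 / 2, 1 / 3, 1 / 4))
  expect_equal(attention_init(3, include_layer0 = FALSE), c(1 / 2, 1 / 3, 1 / 4))
  expect_error(layer_attention_combine(list(H, H[1:4, ]), c(1, 1), 2, 3), "shape")
})

test_that("bilinear decoder matches the explicit double-loop oracle", {
  H_R <- matrix(rnorm(6), 3, 2)
  H_D <- matrix(rnorm(8), 4, 2)
  expect_equal(bilinear_decode(H_R, H_D, matrix(0, 2, 2)),
               matrix(0.5, 3, 4))  # sigmoid(0)
  expect_equal(bilinear_decode(matrix(2), matrix(3), matrix(1)),
               matrix(1 / (1 + exp(-6))))

  set.seed(5)
  W <- matrix(rnorm(4), 2, 2)
  expect_equal(unname(bilinear_decode(H_R, H_D, W)),
               oracle_bilinear(H_R, H_D, W), tolerance = 1e-12)
})

test_that("class-balanced cross-entropy matches closed form and oracle", {
  Y <- matrix(c(1, 0, 0, 0), 2, 2)
  s <- matrix(0.5, 2, 2)
  # one positive, three negatives: eta = 3, loss = 6 ln 2 / 4 = 1.5 ln 2
  expect_equal(weighted_bce_loss(s, Y), 1.5 * log(2), tolerance = 1e-12)
  expect_equal(oracle_bce(s, Y), 1.5 * log(2), tolerance = 1e-12)

  set.seed(21)
  for (rep in 1:5) {
    Y2 <- matrix(rbinom(40, 1, 0.3), 5, 8)
    if (sum(Y2) == 0) Y2[1, 1] <- 1
    s2 <- matrix(runif(40, 0.01, 0.99), 5, 8)
    expect_equal(weighted_bce_loss(s2, Y2), oracle_bce(s2, Y2), tolerance = 1e-10)
  }

  # the loss vanishes in the perfect-fit limit
  eps <- 1e-9
  fit <- ifelse(Y == 1, 1 - eps, eps)
  expect_lt(weighted_bce_loss(fit, Y, eps = 1e-12), 1e-7)

  expect_error(weighted_bce_loss(s, matrix(0, 2, 2)), "positive")
  expect_warning(weighted_bce_loss(matrix(c(1, 0.5, 0.5, 0.5), 2, 2), Y), "clamp")
})

test_that("completion backprop matches finite differences", {
  set.seed(7)
  M <- 4; N <- 5; k <- 3; L <- 2
  Y <- labeled(matrix(rbinom(M * N, 1, 0.4), M, N))
  if (sum(Y) == 0) Y[1, 1] <- 1
  Sr <- random_similarity(M, 1, rownames(Y))
  Sd <- random_similarity(N, 2, colnames(Y))
  het <- build_hetero_adjacency(2 * normalize_similarity(Sr),
                                2 * normalize_similarity(Sd), Y)
  A <- normalized_adjacency(het)
  par <- rsmlgcn:::init_completion_params(M + N, k, L, TRUE)
  par$include_layer0 <- TRUE
  eta <- sum(Y == 0) / sum(Y == 1)
  fwd <- function(par) {
    cache <- rsmlgcn:::completion_forward(A, het$G, par, NULL)
    emb <- layer_attention_combine(cache$H_used, par$beta, M, N)
    scores <- bilinear_decode(emb$H_R, emb$H_D, par$W_dec)
    list(cache = cache, emb = emb, scores = scores,
         loss = weighted_bce_loss(scores, Y))
  }
  r <- fwd(par)
  g <- rsmlgcn:::completion_backward(A, het$G, par, r$cache, r$emb, r$scores, Y, eta)
  eps <- 1e-6
  numgrad <- function(set) {
    (fwd(set(par, eps))$loss - fwd(set(par, -eps))$loss) / (2 * eps)
  }
  idx <- c(1, 5, 11)
  for (i in idx) {
    expect_equal(numgrad(function(p, e) { p$W0[i] <- p$W0[i] + e; p }),
                 g$W0[i], tolerance = 1e-5)
    expect_equal(numgrad(function(p, e) { p$W[[1]][i %% 9 + 1] <- p$W[[1]][i %% 9 + 1] + e; p }),
                 g$W[[1]][i %% 9 + 1], tolerance = 1e-5)
    expect_equal(numgrad(function(p, e) { p$W_dec[i %% 9 + 1] <- p$W_dec[i %% 9 + 1] + e; p }),
                 g$W_dec[i %% 9 + 1], tolerance = 1e-5)
  }
  for (i in seq_along(par$beta)) {
    expect_equal(numgrad(function(p, e) { p$beta[i] <- p$beta[i] + e; p }),
                 g$beta[i], tolerance = 1e-5)
  }
})

test_that("completion training reduces the loss and is seed-deterministic", {
  w <- tiny_world(10, 12, seed = 9)
  cfg <- tiny_config()
  cfg$completion$val_fraction <- 0  # plain fixed-epoch training
  Sr <- apply_penalty(normalize_similarity(w$drug_sim), cfg$completion$mu)
  Sd <- apply_penalty(normalize_similarity(w$disease_sim), cfg$completion$mu)
  het <- build_hetero_adjacency(Sr, Sd, w$associations)

  cm <- train_completion(het, w$associations, cfg)
  expect_lt(cm$losses[length(cm$losses)], cm$losses[1])
  expect_true(all(cm$scores > 0 & cm$scores < 1))

  cm2 <- train_completion(het, w$associations, cfg)
  expect_identical(cm$scores, cm2$scores)  # same seed, same result
  expect_identical(cm$losses, cm2$losses)

  cfg0 <- cfg
  cfg0$completion$epochs <- 0L
  init1 <- train_completion(het, w$associations, cfg0)
  init2 <- train_completion(het, w$associations, cfg0)
  expect_length(init1$losses, 1)
  expect_identical(init1$scores, init2$scores)

  # bitwise reproducibility also with dropout disabled
  cfg_nd <- cfg
  cfg_nd$completion$node_dropout <- 0
  cfg_nd$completion$reg_dropout <- 0
  a <- train_completion(het, w$associations, cfg_nd)
  b <- train_completion(het, w$associations, cfg_nd)
  expect_identical(a$params, b$params)
})

test_that("thresholding keeps known positives and shrinks with theta", {
  s <- rbind(c(0.9, 0.2), c(0.4, 0.7))
  Y <- rbind(c(1, 0), c(0, 0))
  expect_equal(threshold_complete(s, Y, 0.5), rbind(c(1, 0), c(0, 0.7)))
  expect_equal(threshold_complete(s, Y, 1), Y)    # nothing passes
  got0 <- threshold_complete(s, Y, 0)
  expect_equal(got0, rbind(c(1, 0.2), c(0.4, 0.7)))  # everything passes

  set.seed(2)
  s2 <- matrix(runif(48), 6, 8)
  Y2 <- matrix(rbinom(48, 1, 0.2), 6, 8)
  thetas <- seq(0, 1, by = 0.1)
  supports <- lapply(thetas, function(t) which(threshold_complete(s2, Y2, t) > 0))
  for (i in seq_along(thetas)[-1]) {
    expect_true(all(supports[[i]] %in% supports[[i - 1]]))  # monotone shrink
    expect_true(all(which(Y2 == 1) %in% supports[[i]]))     # positives kept
  }
})
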