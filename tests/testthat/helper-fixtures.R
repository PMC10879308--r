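# Shared fixtures: small labeled matrices and a fast configuration for
# tests that exercise training loops.

labeled <- function(m, rows = sprintf("r%02d", seq_len(nrow(m))),
                    cols = sprintf("c%02d", seq_len(ncol(m)))) {
  dimnames(m) <- list(rows, cols)
  m
}

random_similarity <- function(n, seed = 1, ids = sprintf("e%02d", seq_len(n))) {
  set.seed(seed)
  s <- matrix(runif(n * n), n, n)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- list(ids, ids)
  s
}

# scaled-down configuration for training-loop tests
tiny_config <- function() {
  cfg <- default_config()
  cfg$completion$k <- 16L
  cfg$completion$L <- 2L
  cfg$completion$epochs <- 40L
  cfg$completion$patience <- 40L
  cfg$metric$n <- 32L
  cfg$metric$epochs <- 15L
  cfg$metric$patience <- 15L
  cfg
}

with_seed_for_tests <- function(seed, code) {
  set.seed(seed)
  code
}

tiny_world <- function(M = 16, N = 20, seed = 5) {
  generate_world(M = M, N = N, latent_dim = 4, density = 0.15, noise = 0,
                 n_clusters = 3, seed = seed)
}
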