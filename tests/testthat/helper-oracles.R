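# Independent dense/brute-force oracles used to cross-check the package's
# linear-algebra kernels, plus small fixture builders. Oracles are written
# with explicit loops so they share no code path with the implementation.

oracle_flatten <- function(M) {
  n <- nrow(M)
  out <- numeric(0)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) out <- c(out, M[i, j])
  out
}

oracle_squeeze <- function(X) {
  z <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    acc <- 0
    for (i in seq_len(nrow(X))) acc <- acc + X[i, j]
    z[j] <- acc / nrow(X)
  }
  z
}

oracle_excitation <- function(z, W1, W2) {
  h <- numeric(nrow(W1))
  for (a in seq_len(nrow(W1))) {
    acc <- 0
    for (j in seq_len(ncol(W1))) acc <- acc + W1[a, j] * z[j]
    h[a] <- max(acc, 0)
  }
  s <- numeric(nrow(W2))
  for (j in seq_len(nrow(W2))) {
    acc <- 0
    for (a in seq_len(ncol(W2))) acc <- acc + W2[j, a] * h[a]
    s[j] <- 1 / (1 + exp(-acc))
  }
  s
}

oracle_rescale <- function(X, s) {
  out <- X
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X))) out[i, j] <- X[i, j] * s[j]
  out
}

oracle_normalize_adjacency <- function(A) {
  n <- nrow(A)
  At <- A + diag(n)
  Dt <- diag(rowSums(At))
  Dh <- diag(1 / sqrt(diag(Dt)))
  Dh %*% At %*% Dh
}

oracle_gcn_forward <- function(X, A_hat, W0, W1) {
  H <- A_hat %*% X %*% W0
  H[H < 0] <- 0
  A_hat %*% H %*% W1
}

oracle_masked_ce <- function(logits, labels, mask) {
  total <- 0
  idx <- which(mask)
  for (i in idx) {
    p <- exp(logits[i, ]) / sum(exp(logits[i, ]))
    total <- total - log(p[labels[i]])
  }
  total / length(idx)
}

# Central finite differences of a scalar function over a gcn_params theta.
numeric_gcn_grad <- function(fn, theta, eps = 1e-6) {
  lapply(seq_along(theta), function(l) {
    g <- theta[[l]] * 0
    for (i in seq_along(g)) {
      tp <- theta; tm <- theta
      tp[[l]][i] <- tp[[l]][i] + eps
      tm[[l]][i] <- tm[[l]][i] - eps
      g[i] <- (fn(tp) - fn(tm)) / (2 * eps)
    }
    g
  })
}

random_symmetric <- function(n, density = 0.5) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, density)
  A + t(A)
}

# A small task graph built directly (bypassing the samplers) so GCN tests
# control every ingredient.
make_toy_task <- function(n_s = 4, n_q = 2, d = 3, C = 3, seed = 1) {
  withr::with_seed(seed, {
    n <- n_s + n_q
    structure(
      list(node_ids = sprintf("n%02d", seq_len(n)),
           support_mask = c(rep(TRUE, n_s), rep(FALSE, n_q)),
           query_mask = c(rep(FALSE, n_s), rep(TRUE, n_q)),
           labels = sample(seq_len(C), n, replace = TRUE),
           A = random_symmetric(n),
           X = matrix(rnorm(n * d), n, d)),
      class = "meta_task")
  })
}

small_cohort <- function(seed = 1, ...) {
  args <- list(n_regions = 12L, class_counts = c(8L, 10L, 14L),
               n_signal_edges = 20L, seed = seed)
  args[names(list(...))] <- list(...)
  generate_cohort(do.call(cohort_config, args))
}
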