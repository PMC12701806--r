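test_that("adjacency normalization matches the explicit degree-matrix oracle", {
  expect_equal(normalize_adjacency(matrix(0, 4, 4)), diag(4))
  expect_equal(normalize_adjacency(matrix(c(0, 1, 1, 0), 2)),
               matrix(0.5, 2, 2))
  withr::with_seed(14, {
    for (k in 1:20) {
      A <- random_symmetric(8)
      expect_lt(max(abs(normalize_adjacency(A) - oracle_normalize_adjacency(A))),
                1e-10)
    }
  })
  expect_error(normalize_adjacency(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("the GCN forward pass matches the dense oracle and respects locality", {
  withr::with_seed(15, {
    for (k in 1:10) {
      n <- sample(4:10, 1); d <- sample(2:6, 1); C <- 3
      A_hat <- normalize_adjacency(random_symmetric(n))
      X <- matrix(rnorm(n * d), n, d)
      p <- init_gcn_params(d, 5, C, seed = k)
      expect_lt(max(abs(gcn_forward(X, A_hat, p) -
                          oracle_gcn_forward(X, A_hat, p$theta[[1]], p$theta[[2]]))),
                1e-10)
    }
  })
  # identity network on an edgeless graph passes features through
  X <- matrix(abs(rnorm(12)), 4, 3)
  idp <- structure(list(theta = list(diag(3), diag(3))), class = "gcn_params")
  expect_equal(gcn_forward(X, normalize_adjacency(matrix(0, 4, 4)), idp), X)
  # an isolated node's logits depend only on its own features
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
  Ah <- normalize_adjacency(A)
  p <- init_gcn_params(3, 4, 2, seed = 2)
  X2 <- matrix(rnorm(9), 3, 3)
  X3 <- X2; X3[1:2, ] <- rnorm(6)
  expect_equal(gcn_forward(X2, Ah, p)[3, ], gcn_forward(X3, Ah, p)[3, ])
})

test_that("masked cross-entropy matches the softmax oracle and its limits", {
  logits <- matrix(0, 4, 3)
  labels <- c(1L, 2L, 3L, 1L)
  expect_equal(masked_ce_loss(logits, labels, rep(TRUE, 4)), log(3))
  strong <- matrix(-50, 2, 3); strong[cbind(1:2, c(2L, 3L))] <- 50
  expect_lt(masked_ce_loss(strong, c(2L, 3L), c(TRUE, TRUE)), 1e-8)
  withr::with_seed(16, {
    for (k in 1:10) {
      n <- sample(3:8, 1); C <- sample(2:4, 1)
      lg <- matrix(rnorm(n * C, sd = 2), n, C)
      lb <- sample(seq_len(C), n, replace = TRUE)
      mask <- rep(FALSE, n); mask[sample(n, sample(seq_len(n), 1))] <- TRUE
      expect_lt(abs(masked_ce_loss(lg, lb, mask) - oracle_masked_ce(lg, lb, mask)),
                1e-6)
    }
  })
  expect_error(masked_ce_loss(logits, labels, rep(FALSE, 4)), "at least one")
})

test_that("inner adaptation is a pure gradient step verified by finite differences", {
  task <- make_toy_task(n_s = 4, n_q = 2, d = 3, C = 3, seed = 3)
  cfg <- meta_config(alpha1 = 0.05, inner_steps = 1, dropout = 0, seed = 1)
  p <- init_gcn_params(3, 4, 3, seed = 4)
  snapshot <- unserialize(serialize(p, NULL))
  adapted <- inner_update(p, task, cfg)
  expect_identical(p, snapshot)  # purity
  A_hat <- normalize_adjacency(task$A)
  loss_fn <- function(theta) {
    pp <- structure(list(theta = theta), class = "gcn_params")
    masked_ce_loss(gcn_forward(task$X, A_hat, pp), task$labels, task$support_mask)
  }
  num <- numeric_gcn_grad(loss_fn, p$theta)
  for (l in 1:2) {
    implied <- (p$theta[[l]] - adapted$theta[[l]]) / cfg$alpha1
    rel <- abs(implied - num[[l]]) / pmax(abs(num[[l]]), 1e-8)
    expect_lt(max(rel), 1e-4)
  }
  # multiple inner steps compose sequentially
  cfg2 <- cfg; cfg2$inner_steps <- 2L
  two <- inner_update(p, task, cfg2)
  mid <- inner_update(p, task, cfg)
  expect_equal(inner_update(mid, task, cfg)$theta, two$theta, tolerance = 1e-12)
})

test_that("the Hessian-vector product matches differentiated gradients", {
  task <- make_toy_task(n_s = 5, n_q = 2, d = 3, C = 3, seed = 9)
  A_hat <- normalize_adjacency(task$A)
  p <- init_gcn_params(3, 4, 3, seed = 5)
  withr::with_seed(6, V <- list(matrix(rnorm(12), 3, 4), matrix(rnorm(12), 4, 3)))
  cache <- metagcn:::gcn_forward_cache(p, task$X, A_hat)
  gi <- metagcn:::gcn_grad_cache(p, cache, A_hat, task$labels, task$support_mask)
  hv <- metagcn:::gcn_hvp(p, V, cache, A_hat, task$labels, task$support_mask, gi)
  eps <- 1e-6
  shift <- function(sign) {
    th <- list(p$theta[[1]] + sign * eps * V[[1]], p$theta[[2]] + sign * eps * V[[2]])
    metagcn:::gcn_grad(structure(list(theta = th), class = "gcn_params"),
                       task$X, A_hat, task$labels, task$support_mask)$grads
  }
  gp <- shift(1); gm <- shift(-1)
  for (l in 1:2) {
    num <- (gp[[l]] - gm[[l]]) / (2 * eps)
    expect_lt(max(abs(num - hv[[l]])), 1e-5)
  }
})

test_that("second-order and first-order meta-gradients differ when the inner gradient is parameter-dependent", {
  task <- make_toy_task(n_s = 5, n_q = 3, d = 3, C = 3, seed = 10)
  p <- init_gcn_params(3, 4, 3, seed = 6)
  cfg2 <- meta_config(dropout = 0, second_order = TRUE, seed = 1)
  cfg1 <- meta_config(dropout = 0, second_order = FALSE, seed = 1)
  g2 <- metagcn:::meta_task_grad(p, task, cfg2)$grad
  g1 <- metagcn:::meta_task_grad(p, task, cfg1)$grad
  expect_false(isTRUE(all.equal(g2[[1]], g1[[1]])))
})

test_that("repeated meta-updates on a fixed batch of easy tasks cut the query loss", {
  withr::with_seed(30, {
    tasks <- lapply(1:4, function(k) {
      tk <- make_toy_task(n_s = 6, n_q = 6, d = 4, C = 3, seed = 30 + k)
      tk$labels <- rep(1:3, 4)[sample(12)]
      # well-separated class means, sparse graph: an easy episodic problem
      tk$X <- matrix(rnorm(48, sd = 0.3), 12, 4) +
        outer(tk$labels, 1:4, function(a, b) (a - 2) * 2)
      tk$A <- matrix(0, 12, 12)
      tk
    })
  })
  cfg <- meta_config(alpha2 = 0.05, dropout = 0, hidden = 8, seed = 2)
  p <- init_gcn_params(4, 8, 3, seed = 7)
  first <- metagcn:::meta_update(p, tasks, cfg)
  loss0 <- first$query_loss
  p <- first$params
  for (i in 1:49) {
    upd <- metagcn:::meta_update(p, tasks, cfg)
    p <- upd$params
  }
  expect_lt(upd$query_loss, 0.7 * loss0)
})

test_that("meta-training is deterministic and learns a strong planted signal", {
  coh <- small_cohort(seed = 31, effect_size = 1, noise_sd = 0.1,
                      class_counts = c(12L, 16L, 20L), demo_assoc = 1)
  lab <- coh$phenotypes$label
  feats <- scale(coh$features)
  tcfg <- task_config(C = 3, k_train_s = 2, k_train_q = 3, M = 30, seed = 3)
  mcfg <- meta_config(iterations = 500, hidden = 8, seed = 5)
  f1 <- meta_train(feats, coh$phenotypes, lab, tcfg, mcfg)
  f2 <- meta_train(feats, coh$phenotypes, lab, tcfg, mcfg)
  expect_identical(f1$params$theta, f2$params$theta)
  # evaluation-mode accuracy on fresh episodic tasks (dropout off)
  tcfg2 <- tcfg; tcfg2$seed <- 77L; tcfg2$M <- 30L
  rg <- phenotype_ranges(coh$phenotypes)
  pairs <- sample_train_tasks(lab, tcfg2)
  accs <- vapply(pairs, function(p) {
    tk <- build_meta_task(p$support, p$query, feats, coh$phenotypes, lab, tcfg2, rg)
    ad <- inner_update(f1$params, tk, mcfg)
    Z <- gcn_forward(tk$X, normalize_adjacency(tk$A), ad)
    mean(max.col(Z[tk$query_mask, , drop = FALSE]) == tk$labels[tk$query_mask])
  }, numeric(1))
  expect_gt(mean(accs), 0.85)
})

test_that("meta-testing predicts every test subject exactly once and leaves parameters untouched", {
  coh <- small_cohort(seed = 33, effect_size = 0.8, noise_sd = 0.1)
  lab <- coh$phenotypes$label
  feats <- scale(coh$features)
  tr <- which(seq_along(lab) %% 4 != 0)
  te <- which(seq_along(lab) %% 4 == 0)
  tcfg <- task_config(C = 3, k_train_s = 2, k_train_q = 2, k_test_s = 2,
                      t = 3, M = 20, seed = 8)
  mcfg <- meta_config(iterations = 60, hidden = 8, seed = 9)
  fit <- meta_train(feats[tr, ], coh$phenotypes[tr, ], lab[tr], tcfg, mcfg)
  labm <- lab; labm[te] <- NA
  tt <- sample_test_tasks(lab[tr], te, tcfg)
  tasks <- lapply(tt, function(p)
    build_meta_task(tr[p$support], p$query, feats, coh$phenotypes, labm, tcfg,
                    phenotype_ranges(coh$phenotypes[tr, ])))
  before <- unserialize(serialize(fit$params, NULL))
  pred <- meta_test(fit, tasks, mcfg)
  expect_identical(fit$params, before)
  expect_setequal(pred$subject_id, coh$phenotypes$subject_id[te])
  expect_equal(nrow(pred), length(te))
  expect_true(all(abs(rowSums(as.matrix(pred[, grep("score_", names(pred))])) - 1) < 1e-9))
  # fine-tuning changes predictions relative to the unadapted initialization
  mcfg0 <- mcfg; mcfg0$finetune_steps <- 0L
  pred0 <- meta_test(fit, tasks, mcfg0)
  expect_false(isTRUE(all.equal(
    as.matrix(pred[order(pred$subject_id), grep("score_", names(pred))]),
    as.matrix(pred0[order(pred0$subject_id), grep("score_", names(pred0))]))))
})

test_that("with no planted signal, training-task query accuracy stays near chance", {
  coh <- generate_cohort(cohort_config(n_regions = 12, class_counts = c(15, 15, 15),
                                       effect_size = 0, demo_assoc = 0, seed = 40))
  feats <- scale(coh$features)
  tcfg <- task_config(C = 3, k_train_s = 2, k_train_q = 3, M = 30, seed = 3)
  mcfg <- meta_config(iterations = 120, hidden = 8, seed = 4)
  f <- meta_train(feats, coh$phenotypes, coh$phenotypes$label, tcfg, mcfg)
  late <- utils::tail(f$log$query_acc, 40)
  # 40 iterations x 9 query nodes, correlated draws; allow a generous band
  expect_lt(abs(mean(late) - 1 / 3), 0.15)
})
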