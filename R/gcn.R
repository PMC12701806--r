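#' Symmetric normalization of a binary adjacency matrix
#'
#' Adds self-loops and applies the symmetric degree normalization used by
#' graph convolutional networks:
#' `A_hat = D^{-1/2} (A + I) D^{-1/2}` with `D` the degree matrix of
#' `A + I`. Self-loops guarantee every degree is at least 1.
#'
#' @param A Symmetric binary matrix with zero diagonal.
#' @return Symmetric numeric matrix of the same size.
#' @export
normalize_adjacency <- function(A) {
  assert_that(is.matrix(A) && nrow(A) == ncol(A), "A must be square")
  assert_that(max(abs(A - t(A))) == 0, "A must be symmetric")
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  At * outer(dinv, dinv)
}

#' Configuration of the meta-trained graph convolutional network
#'
#' @param alpha1 Inner-loop (task-level) learning rate; default 0.01.
#' @param alpha2 Meta learning rate; default 0.003. The task rate exceeding
#'   the meta rate is the usual MAML convention.
#' @param inner_steps Gradient steps on a task's support set during
#'   meta-training.
#' @param finetune_steps Gradient steps on a meta-testing task's support set
#'   before predicting its query; 0 predicts from the meta-initialization
#'   unadapted. The default 10 gives meaningful per-task adaptation at the
#'   small task learning rate while staying cheap.
#' @param task_batch Tasks per meta-update.
#' @param iterations Meta-updates to run.
#' @param dropout Dropout rate on GCN layer inputs during training (0.5 by
#'   default); always disabled at evaluation.
#' @param second_order If `TRUE` (default) the meta-gradient flows through
#'   the inner update (full second-order MAML); `FALSE` treats the adapted
#'   parameters' dependence on the initialization as constant (first-order
#'   approximation, faster).
#' @param hidden Width of the first GCN layer.
#' @param optimizer Outer-loop optimizer used by [meta_train()] on the
#'   summed query-loss meta-gradient: `"adam"` (default; the optimizer of
#'   the standard MAML reference implementations, needed for convergence at
#'   small learning rates) or `"sgd"` (the plain update rule of
#'   [meta_update()]).
#' @param seed Integer seed for initialization, dropout and batch sampling.
#' @return A `meta_config` list.
#' @export
meta_config <- function(alpha1 = 0.01, alpha2 = 0.003, inner_steps = 1L,
                        finetune_steps = 10L, task_batch = 4L,
                        iterations = 1000L, dropout = 0.5,
                        second_order = TRUE, hidden = 16L,
                        optimizer = c("adam", "sgd"), seed = 1L) {
  optimizer <- match.arg(optimizer)
  assert_that(alpha1 > 0 && alpha2 > 0, "learning rates must be > 0")
  assert_that(dropout >= 0 && dropout < 1, "dropout must lie in [0, 1)")
  assert_that(inner_steps >= 1, "inner_steps must be >= 1")
  assert_that(finetune_steps >= 0, "finetune_steps must be >= 0")
  structure(list(alpha1 = alpha1, alpha2 = alpha2,
                 inner_steps = as.integer(inner_steps),
                 finetune_steps = as.integer(finetune_steps),
                 task_batch = as.integer(task_batch),
                 iterations = as.integer(iterations), dropout = dropout,
                 second_order = isTRUE(second_order), hidden = as.integer(hidden),
                 optimizer = optimizer, seed = as.integer(seed)),
            class = "meta_config")
}

#' Initialize two-layer GCN parameters
#'
#' Glorot-uniform initialization of the two layer weight matrices
#' (input width -> hidden -> C).
#'
#' @param d_in Node feature width.
#' @param hidden Hidden layer width.
#' @param C Number of classes.
#' @param seed Integer seed.
#' @return A `gcn_params` object: list with `theta`, a list of two weight
#'   matrices.
#' @export
init_gcn_params <- function(d_in, hidden, C, seed = 1L) {
  glorot <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
  }
  withr::with_seed(seed, {
    structure(list(theta = list(glorot(d_in, hidden), glorot(hidden, C))),
              class = "gcn_params")
  })
}

# Sample inverted-dropout masks for the two layer inputs.
sample_dropmasks <- function(n, d_in, hidden, p) {
  keep <- 1 - p
  list(M0 = matrix(stats::rbinom(n * d_in, 1L, keep), n, d_in) / keep,
       M1 = matrix(stats::rbinom(n * hidden, 1L, keep), n, hidden) / keep)
}

# Full forward pass with cached intermediates (shared by gradient and HVP).
gcn_forward_cache <- function(params, X, A_hat, dropmasks = NULL) {
  W0 <- params$theta[[1]]; W1 <- params$theta[[2]]
  Xd <- if (!is.null(dropmasks)) X * dropmasks$M0 else X
  AXd <- A_hat %*% Xd
  U <- AXd %*% W0
  H <- relu(U)
  Hd <- if (!is.null(dropmasks)) H * dropmasks$M1 else H
  AHd <- A_hat %*% Hd
  Z <- AHd %*% W1
  list(Xd = Xd, AXd = AXd, U = U, H = H, Hd = Hd, AHd = AHd, Z = Z,
       dropmasks = dropmasks)
}

#' Two-layer GCN forward pass
#'
#' Computes node logits via the layer rule
#' `X^(l+1) = act(A_hat X^(l) theta^(l))` with ReLU after the first layer and
#' raw logits after the second (softmax is folded into the loss). Dropout is
#' applied to layer inputs only when `training = TRUE`.
#'
#' @param X Node feature matrix (n x d_in).
#' @param A_hat Normalized adjacency from [normalize_adjacency()].
#' @param params A `gcn_params`.
#' @param dropout Dropout rate (used only when training).
#' @param training Enable dropout.
#' @return n x C matrix of logits.
#' @export
gcn_forward <- function(X, A_hat, params, dropout = 0, training = FALSE) {
  assert_that(nrow(X) == nrow(A_hat), "X and A_hat disagree on node count")
  assert_that(ncol(X) == nrow(params$theta[[1]]),
              "feature width %d does not match theta[[1]] (%d rows)",
              ncol(X), nrow(params$theta[[1]]))
  dm <- if (training && dropout > 0)
    sample_dropmasks(nrow(X), ncol(X), ncol(params$theta[[1]]), dropout) else NULL
  gcn_forward_cache(params, X, A_hat, dm)$Z
}

#' Masked cross-entropy loss
#'
#' Mean over the masked nodes of the cross-entropy between the one-hot label
#' and the softmax of the node's logits; nodes outside the mask contribute
#' nothing, which is how support and query losses share one transductive
#' graph without leaking query labels.
#'
#' @param logits n x C matrix.
#' @param labels Integer labels 1..C (may be NA outside the mask).
#' @param mask Logical vector selecting the scored nodes (>= 1 of them).
#' @return Scalar loss.
#' @export
masked_ce_loss <- function(logits, labels, mask) {
  assert_that(sum(mask) >= 1, "mask must select at least one node")
  assert_that(!anyNA(labels[mask]), "masked nodes must have labels")
  ls <- log_softmax(logits[mask, , drop = FALSE])
  -mean(ls[cbind(seq_len(sum(mask)), labels[mask])])
}

# Gradient of the masked CE loss w.r.t. both layer weights, reusing a
# forward cache. Returns loss, gradient list and the softmax residual G.
gcn_grad_cache <- function(params, cache, A_hat, labels, mask) {
  n <- nrow(cache$Z)
  C <- ncol(cache$Z)
  P <- softmax_rows(cache$Z)
  Y <- matrix(0, n, C)
  idx <- which(mask)
  Y[cbind(idx, labels[idx])] <- 1
  G <- (P - Y)
  G[!mask, ] <- 0
  G <- G / length(idx)
  ls <- log_softmax(cache$Z[idx, , drop = FALSE])
  loss <- -mean(ls[cbind(seq_along(idx), labels[idx])])
  gW1 <- crossprod(cache$AHd, G)
  dHd <- (A_hat %*% G) %*% t(params$theta[[2]])
  if (!is.null(cache$dropmasks)) dHd <- dHd * cache$dropmasks$M1
  dU <- dHd * (cache$U > 0)
  gW0 <- crossprod(cache$AXd, dU)
  list(loss = loss, grads = list(gW0, gW1), P = P, G = G)
}

gcn_grad <- function(params, X, A_hat, labels, mask, dropmasks = NULL) {
  cache <- gcn_forward_cache(params, X, A_hat, dropmasks)
  gcn_grad_cache(params, cache, A_hat, labels, mask)
}

# Hessian-vector product of the masked CE loss at `params` with direction
# `V` (list of two matrices), via forward-over-reverse differentiation of
# the backprop above. ReLU and dropout masks are held fixed (the loss is
# piecewise smooth; this is the a.e. Hessian).
gcn_hvp <- function(params, V, cache, A_hat, labels, mask, grad_info) {
  W1 <- params$theta[[2]]
  dU_fwd <- cache$AXd %*% V[[1]]
  dH <- dU_fwd * (cache$U > 0)
  dHd <- if (!is.null(cache$dropmasks)) dH * cache$dropmasks$M1 else dH
  AdHd <- A_hat %*% dHd
  dZ <- AdHd %*% W1 + cache$AHd %*% V[[2]]
  P <- grad_info$P
  dP <- P * dZ - P * rowSums(P * dZ)
  dG <- dP
  dG[!mask, ] <- 0
  dG <- dG / sum(mask)
  hW1 <- crossprod(AdHd, grad_info$G) + crossprod(cache$AHd, dG)
  dHd_b <- (A_hat %*% dG) %*% t(W1) + (A_hat %*% grad_info$G) %*% t(V[[2]])
  if (!is.null(cache$dropmasks)) dHd_b <- dHd_b * cache$dropmasks$M1
  dU_b <- dHd_b * (cache$U > 0)
  hW0 <- crossprod(cache$AXd, dU_b)
  list(hW0, hW1)
}

# Train a single plain (non-episodic) GCN on one transductive graph by Adam
# on the masked CE of the training nodes. Backs the -Meta ablation.
train_plain_gcn <- function(X, A_hat, labels, train_mask, cfg) {
  withr::with_seed(cfg$seed, {
    params <- structure(
      list(theta = init_gcn_params(ncol(X), cfg$hidden,
                                   max(labels, na.rm = TRUE),
                                   seed = cfg$seed)$theta),
      class = "gcn_params")
    flat <- list(W0 = params$theta[[1]], W1 = params$theta[[2]])
    state <- adam_init(flat)
    for (i in seq_len(cfg$iterations)) {
      dm <- if (cfg$dropout > 0)
        sample_dropmasks(nrow(X), ncol(X), cfg$hidden, cfg$dropout) else NULL
      g <- gcn_grad(params, X, A_hat, labels, train_mask, dm)
      upd <- adam_step(flat, list(W0 = g$grads[[1]], W1 = g$grads[[2]]),
                       state, cfg$alpha1)
      flat <- upd$params; state <- upd$state
      params$theta <- list(flat$W0, flat$W1)
    }
    params
  })
}
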