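# Cache the normalized adjacency on a task the first time it is needed.
task_ahat <- function(task) {
  if (is.null(task$A_hat)) task$A_hat <- normalize_adjacency(task$A)
  task
}

# Inner adaptation returning the full parameter trajectory
# theta_0 = theta, ..., theta_k (needed by the second-order meta-gradient)
# together with the forward caches and gradient info at each step.
inner_trajectory <- function(params, task, cfg, dropmasks = NULL) {
  task <- task_ahat(task)
  traj <- vector("list", cfg$inner_steps)
  theta <- params$theta
  for (s in seq_len(cfg$inner_steps)) {
    p <- structure(list(theta = theta), class = "gcn_params")
    cache <- gcn_forward_cache(p, task$X, task$A_hat, dropmasks)
    g <- gcn_grad_cache(p, cache, task$A_hat, task$labels, task$support_mask)
    traj[[s]] <- list(theta = theta, cache = cache, grad = g)
    theta <- list(theta[[1]] - cfg$alpha1 * g$grads[[1]],
                  theta[[2]] - cfg$alpha1 * g$grads[[2]])
  }
  list(steps = traj, theta_adapted = theta, task = task)
}

#' Adapt GCN parameters to one task's support set
#'
#' Performs `cfg$inner_steps` gradient-descent steps of size `cfg$alpha1` on
#' the masked cross-entropy of the task's support nodes:
#' `theta' = theta - alpha1 * grad L_support(theta)`. The input parameters
#' are never modified (pure function). Dropout is disabled unless `training`
#' is set, so the adapted parameters are deterministic given the task.
#'
#' @param params A `gcn_params`.
#' @param task A `meta_task` with labelled support nodes.
#' @param cfg A [meta_config()].
#' @param training Apply dropout during adaptation.
#' @return Adapted `gcn_params`.
#' @export
inner_update <- function(params, task, cfg, training = FALSE) {
  assert_that(sum(task$support_mask) >= 1 && !anyNA(task$labels[task$support_mask]),
              "task support set must be nonempty and labelled")
  dm <- if (training && cfg$dropout > 0)
    sample_dropmasks(nrow(task$X), ncol(task$X), cfg$hidden, cfg$dropout) else NULL
  tr <- inner_trajectory(params, task, cfg, dm)
  structure(list(theta = tr$theta_adapted), class = "gcn_params")
}

# Meta-gradient for one task: gradient of the query loss at the adapted
# parameters, back-propagated through the inner steps when second_order.
# Returns the gradient pair plus the query loss/accuracy for logging.
meta_task_grad <- function(params, task, cfg, dropmasks = NULL) {
  tr <- inner_trajectory(params, task, cfg, dropmasks)
  task <- tr$task
  adapted <- structure(list(theta = tr$theta_adapted), class = "gcn_params")
  cache_q <- gcn_forward_cache(adapted, task$X, task$A_hat, dropmasks)
  gq <- gcn_grad_cache(adapted, cache_q, task$A_hat, task$labels, task$query_mask)
  v <- gq$grads
  if (cfg$second_order) {
    for (s in rev(seq_len(cfg$inner_steps))) {
      st <- tr$steps[[s]]
      p <- structure(list(theta = st$theta), class = "gcn_params")
      hv <- gcn_hvp(p, v, st$cache, task$A_hat, task$labels,
                    task$support_mask, st$grad)
      v <- list(v[[1]] - cfg$alpha1 * hv[[1]], v[[2]] - cfg$alpha1 * hv[[2]])
    }
  }
  pred <- max.col(gq$P[task$query_mask, , drop = FALSE], ties.method = "first")
  acc <- mean(pred == task$labels[task$query_mask])
  list(grad = v, query_loss = gq$loss, query_acc = acc)
}

#' One meta-update over a batch of tasks
#'
#' Adapts the shared initialization to every task in the batch via
#' [inner_update()], evaluates each task's query loss under its adapted
#' parameters, and moves the initialization against the summed query-loss
#' gradient: `theta <- theta - alpha2 * grad sum_i L_query_i(theta'_i)`.
#' With `cfg$second_order` the gradient flows through the inner steps
#' (exact MAML); otherwise the first-order approximation is used.
#'
#' @param params A `gcn_params` (not modified; the update is returned).
#' @param task_batch Nonempty list of `meta_task`s with labelled query
#'   nodes.
#' @param cfg A [meta_config()].
#' @param training Apply dropout in the per-task forward passes.
#' @return List with updated `params`, mean `query_loss` and `query_acc`
#'   over the batch.
#' @export
meta_batch_grad <- function(params, task_batch, cfg, training = FALSE) {
  assert_that(length(task_batch) >= 1, "task batch must be nonempty")
  acc_g <- NULL; losses <- numeric(0); accs <- numeric(0)
  for (task in task_batch) {
    dm <- if (training && cfg$dropout > 0)
      sample_dropmasks(nrow(task$X), ncol(task$X), cfg$hidden, cfg$dropout) else NULL
    mg <- meta_task_grad(params, task, cfg, dm)
    acc_g <- if (is.null(acc_g)) mg$grad else
      list(acc_g[[1]] + mg$grad[[1]], acc_g[[2]] + mg$grad[[2]])
    losses <- c(losses, mg$query_loss); accs <- c(accs, mg$query_acc)
  }
  list(grad = acc_g, query_loss = mean(losses), query_acc = mean(accs))
}

meta_update <- function(params, task_batch, cfg, training = FALSE) {
  bg <- meta_batch_grad(params, task_batch, cfg, training)
  theta <- list(params$theta[[1]] - cfg$alpha2 * bg$grad[[1]],
                params$theta[[2]] - cfg$alpha2 * bg$grad[[2]])
  list(params = structure(list(theta = theta), class = "gcn_params"),
       query_loss = bg$query_loss, query_acc = bg$query_acc)
}

#' Meta-train the GCN on episodic tasks
#'
#' Samples `task_cfg$M` label-balanced meta-training tasks from the labelled
#' subjects, then runs `meta_cfg$iterations` meta-updates, each on a random
#' batch of `meta_cfg$task_batch` tasks. Fully seeded: the same inputs and
#' seeds reproduce the trained parameters bit-for-bit.
#'
#' @param features Encoded feature matrix over the training-fold subjects.
#' @param phenotypes Phenotype data.frame aligned with `features`.
#' @param labels Integer class labels (1..C) aligned with `features`.
#' @param task_cfg A [task_config()].
#' @param meta_cfg A [meta_config()].
#' @param ranges Frozen phenotype ranges; default computed from
#'   `phenotypes` (the training fold).
#' @return A `meta_gcn_fit`: list with trained `params`, per-iteration `log`
#'   (mean query loss and accuracy), and the config echoes.
#' @export
meta_train <- function(features, phenotypes, labels, task_cfg, meta_cfg,
                       ranges = phenotype_ranges(phenotypes)) {
  assert_that(nrow(features) == length(labels),
              "features and labels disagree on subject count")
  pairs <- sample_train_tasks(labels, task_cfg)
  tasks <- lapply(pairs, function(p)
    task_ahat(build_meta_task(p$support, p$query, features, phenotypes,
                              labels, task_cfg, ranges)))
  C <- task_cfg$C
  params <- init_gcn_params(ncol(features), meta_cfg$hidden, C,
                            seed = meta_cfg$seed)
  log <- data.frame(iteration = seq_len(meta_cfg$iterations),
                    query_loss = NA_real_, query_acc = NA_real_)
  use_adam <- identical(meta_cfg$optimizer %||% "adam", "adam")
  flat <- list(W0 = params$theta[[1]], W1 = params$theta[[2]])
  state <- adam_init(flat)
  withr::with_seed(child_seed(meta_cfg$seed, 1L), {
    for (it in seq_len(meta_cfg$iterations)) {
      batch <- tasks[sample.int(length(tasks), meta_cfg$task_batch, replace = TRUE)]
      if (use_adam) {
        bg <- meta_batch_grad(params, batch, meta_cfg, training = TRUE)
        upd <- adam_step(flat, list(W0 = bg$grad[[1]], W1 = bg$grad[[2]]),
                         state, meta_cfg$alpha2)
        flat <- upd$params; state <- upd$state
        params$theta <- list(flat$W0, flat$W1)
        log$query_loss[it] <- bg$query_loss
        log$query_acc[it] <- bg$query_acc
      } else {
        upd <- meta_update(params, batch, meta_cfg, training = TRUE)
        params <- upd$params
        log$query_loss[it] <- upd$query_loss
        log$query_acc[it] <- upd$query_acc
      }
    }
  })
  structure(list(params = params, log = log, task_cfg = task_cfg,
                 meta_cfg = meta_cfg, ranges = ranges),
            class = "meta_gcn_fit")
}

#' @export
print.meta_gcn_fit <- function(x, ...) {
  n <- nrow(x$log)
  tail_acc <- mean(utils::tail(x$log$query_acc, max(1, n %/% 10)))
  cat(sprintf("meta_gcn_fit: %d iterations, final training-task query accuracy %.3f\n",
              n, tail_acc))
  invisible(x)
}

#' Predict test subjects via per-task fine-tuning
#'
#' For every meta-testing task, fine-tunes a copy of the meta-learned
#' initialization on the task's labelled support nodes for
#' `cfg$finetune_steps` steps (dropout off), then predicts the query nodes
#' by the argmax of the softmax scores. The input parameters are never
#' mutated, and each test subject appears in exactly one query, so it
#' receives exactly one prediction.
#'
#' @param params Trained `gcn_params` (or a `meta_gcn_fit`).
#' @param test_tasks List of `meta_task`s whose query nodes are the test
#'   subjects (support labelled, query labels ignored).
#' @param cfg A [meta_config()].
#' @return data.frame with one row per test subject: `subject_id`,
#'   predicted class `pred`, and one `score_<c>` column per class.
#' @export
meta_test <- function(params, test_tasks, cfg) {
  if (inherits(params, "meta_gcn_fit")) params <- params$params
  out <- list()
  for (task in test_tasks) {
    if (sum(task$query_mask) == 0) {
      message("skipping meta-test task with empty query set")
      next
    }
    task <- task_ahat(task)
    adapted <- if (cfg$finetune_steps >= 1) {
      ft_cfg <- cfg; ft_cfg$inner_steps <- cfg$finetune_steps
      inner_update(params, task, ft_cfg, training = FALSE)
    } else params
    Z <- gcn_forward(task$X, task$A_hat, adapted)
    P <- softmax_rows(Z)
    qi <- which(task$query_mask)
    df <- data.frame(subject_id = task$node_ids[qi],
                     pred = max.col(P[qi, , drop = FALSE], ties.method = "first"),
                     stringsAsFactors = FALSE)
    scores <- P[qi, , drop = FALSE]
    colnames(scores) <- paste0("score_", seq_len(ncol(scores)))
    out[[length(out) + 1L]] <- cbind(df, as.data.frame(scores))
  }
  assert_that(length(out) > 0, "no meta-test task had query nodes")
  do.call(rbind, out)
}
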