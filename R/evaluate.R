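#' Composite configuration for a full pipeline run
#'
#' Bundles the feature-processing, task-sampling and meta-learning
#' configurations with the cross-validation layout and the ablation
#' switches.
#'
#' @param folds Number of stratified cross-validation folds (>= 2).
#' @param repeats Number of repeated cross-validation rounds; round r uses
#'   `seed + r - 1`.
#' @param se_ae An [se_ae_config()].
#' @param task A [task_config()].
#' @param meta A [meta_config()].
#' @param val_frac Fraction of the training fold held out as the SE-AE
#'   validation split.
#' @param positive Positive class for binary metrics (default: the higher
#'   class index, i.e. the severer class).
#' @param no_se,no_ae,no_meta,no_ni Ablation switches: skip the excitation
#'   weighting, skip the autoencoder compression (raw-width features enter
#'   the GCN), replace episodic meta-learning by a single transductive GCN,
#'   or drop the phenotype edges. `no_se + no_ae` removes the whole
#'   feature-processing block.
#' @param seed Master seed; all stage seeds are derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(folds = 5L, repeats = 1L, se_ae = se_ae_config(),
                       task = task_config(), meta = meta_config(),
                       val_frac = 0.2, positive = NULL,
                       no_se = FALSE, no_ae = FALSE, no_meta = FALSE,
                       no_ni = FALSE, seed = 1L) {
  assert_that(folds >= 2, "folds must be >= 2")
  assert_that(repeats >= 1, "repeats must be >= 1")
  assert_that(val_frac > 0 && val_frac < 1, "val_frac must lie in (0, 1)")
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 se_ae = se_ae, task = task, meta = meta,
                 val_frac = val_frac, positive = positive,
                 ablation = list(no_se = isTRUE(no_se), no_ae = isTRUE(no_ae),
                                 no_meta = isTRUE(no_meta), no_ni = isTRUE(no_ni)),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Stratified fold assignment
#'
#' Assigns every subject to one of `k` folds so that class proportions are
#' preserved within one subject per class.
#'
#' @param labels Integer class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k) aligned with `labels`.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  counts <- table(labels)
  if (min(counts) < k)
    stopf("smallest class has %d members < %d folds; use fewer folds",
          min(counts), k)
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (c in unique(labels)) {
      idx <- sample(which(labels == c))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Prepare per-fold features according to the ablation flags: returns the
# feature matrix over ALL subjects (test features transformed with
# parameters learned on the training fold only). Features entering the GCN
# are standardized per dimension with training-fold statistics.
prepare_fold_features <- function(X, train_idx, cfg, fold_seed) {
  ab <- cfg$ablation
  fit <- NULL
  if (ab$no_se && ab$no_ae) {
    feats <- X
  } else {
    n_val <- max(1L, round(cfg$val_frac * length(train_idx)))
    val_local <- withr::with_seed(child_seed(fold_seed, 7L),
                                  sample(length(train_idx), n_val))
    hyper <- cfg$se_ae
    hyper$seed <- child_seed(fold_seed, 11L)
    hyper$use_se <- !ab$no_se
    fit <- fit_se_ae(X[train_idx[-val_local], , drop = FALSE],
                     X[train_idx[val_local], , drop = FALSE], hyper)
    feats <- if (ab$no_ae) rescale_features(X, fit$se$s) else encode_features(X, fit)
  }
  mu <- colMeans(feats[train_idx, , drop = FALSE])
  sg <- pmax(apply(feats[train_idx, , drop = FALSE], 2, stats::sd), 1e-8)
  feats <- sweep(sweep(feats, 2L, mu, "-"), 2L, sg, "/")
  list(features = feats, fit = fit)
}

# Run one train/test split end to end; returns metrics plus raw predictions.
run_fold <- function(cohort, train_idx, test_idx, cfg, fold_seed) {
  X <- cohort$features
  phen <- cohort$phenotypes
  labels <- phen$label
  C <- length(cohort$class_labels)
  ab <- cfg$ablation

  prep <- prepare_fold_features(X, train_idx, cfg, fold_seed)
  feats <- prep$features
  ranges <- phenotype_ranges(phen[train_idx, , drop = FALSE])
  task_cfg <- cfg$task
  task_cfg$C <- C
  task_cfg$phenotype_edges <- !ab$no_ni
  task_cfg$seed <- child_seed(fold_seed, 13L)
  meta_cfg <- cfg$meta
  meta_cfg$seed <- child_seed(fold_seed, 17L)

  labels_masked <- labels
  labels_masked[test_idx] <- NA_integer_

  if (ab$no_meta) {
    A <- if (ab$no_ni) matrix(0, nrow(feats), nrow(feats)) else
      build_adjacency(phen, task_cfg$beta1, task_cfg$beta2, ranges, task_cfg$rule)
    A_hat <- normalize_adjacency(A)
    train_mask <- rep(FALSE, nrow(feats)); train_mask[train_idx] <- TRUE
    params <- train_plain_gcn(feats, A_hat, labels_masked, train_mask, meta_cfg)
    P <- softmax_rows(gcn_forward(feats, A_hat, params))
    pred_df <- data.frame(subject_id = phen$subject_id[test_idx],
                          pred = max.col(P[test_idx, , drop = FALSE],
                                         ties.method = "first"),
                          stringsAsFactors = FALSE)
    scores <- P[test_idx, , drop = FALSE]
    colnames(scores) <- paste0("score_", seq_len(C))
    pred_df <- cbind(pred_df, as.data.frame(scores))
  } else {
    fit <- meta_train(feats[train_idx, , drop = FALSE],
                      phen[train_idx, , drop = FALSE],
                      labels[train_idx], task_cfg, meta_cfg, ranges)
    tt <- sample_test_tasks(labels[train_idx], test_idx, task_cfg)
    tasks <- lapply(tt, function(p)
      build_meta_task(train_idx[p$support], p$query, feats, phen,
                      labels_masked, task_cfg, ranges))
    pred_df <- meta_test(fit, tasks, meta_cfg)
  }
  ord <- match(phen$subject_id[test_idx], pred_df$subject_id)
  pred_df <- pred_df[ord, , drop = FALSE]
  scores <- as.matrix(pred_df[, paste0("score_", seq_len(C)), drop = FALSE])
  metrics <- compute_metrics(labels[test_idx], pred_df$pred, scores, C,
                             positive = cfg$positive)
  list(metrics = metrics, predictions = pred_df)
}

#' Stratified repeated cross-validation of the full pipeline
#'
#' For every fold: fits the SE-AE block on the training split (with an
#' internal validation subsplit), encodes all subjects with the frozen
#' parameters, meta-trains the GCN on episodic tasks from the training
#' split, partitions the held-out split into meta-testing tasks and
#' fine-tunes/predicts each. Phenotype ranges and all learned parameters
#' come from the training split only. Metrics are aggregated as mean and
#' standard deviation over `folds x repeats` runs.
#'
#' @param cohort An `fc_cohort`.
#' @param cfg A [run_config()].
#' @return An `eval_report`: `per_fold` data.frame, `mean` and `sd` per
#'   metric, pooled `confusion` matrix, mean per-class `recall`, config
#'   echo and seed.
#' @export
cross_validate <- function(cohort, cfg = run_config()) {
  labels <- cohort$phenotypes$label
  assert_that(!anyNA(labels), "cross-validation needs fully labelled subjects")
  C <- length(cohort$class_labels)
  per_fold <- list()
  confusion <- matrix(0, C, C)
  recalls <- list()
  for (r in seq_len(cfg$repeats)) {
    rep_seed <- child_seed(cfg$seed, r - 1L)
    fold_id <- stratified_folds(labels, cfg$folds, seed = rep_seed)
    for (f in seq_len(cfg$folds)) {
      fold_seed <- child_seed(rep_seed, 1000L + f)
      res <- run_fold(cohort, which(fold_id != f), which(fold_id == f),
                      cfg, fold_seed)
      m <- res$metrics
      per_fold[[length(per_fold) + 1L]] <-
        data.frame(rep = r, fold = f, acc = m$acc, sen = m$sen, spe = m$spe,
                   auc = m$auc, f1 = m$f1)
      confusion <- confusion + m$confusion
      recalls[[length(recalls) + 1L]] <- m$recall
    }
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- c("acc", "sen", "spe", "auc", "f1")
  structure(
    list(per_fold = per_fold,
         mean = vapply(per_fold[metric_cols], mean, numeric(1), na.rm = TRUE),
         sd = vapply(per_fold[metric_cols], stats::sd, numeric(1), na.rm = TRUE),
         recall = colMeans(do.call(rbind, recalls), na.rm = TRUE),
         confusion = confusion,
         class_labels = cohort$class_labels,
         config = cfg, seed = cfg$seed),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d fold-runs\n", nrow(x$per_fold)))
  for (m in names(x$mean))
    cat(sprintf("  %s: %.3f +/- %.3f\n", m, x$mean[[m]], x$sd[[m]]))
  cat("per-class recall:",
      paste(sprintf("%s=%.3f", x$class_labels, x$recall), collapse = ", "), "\n")
  invisible(x)
}

#' Ablation study over the pipeline components
#'
#' Re-runs cross-validation with individual components removed: the
#' excitation weighting (`no_se`), the autoencoder compression (`no_ae`),
#' the episodic meta-learning (`no_meta`: one transductive GCN trained on a
#' single population graph), the phenotype edges (`no_ni`: edgeless task
#' graphs), and the whole feature-processing block (`no_se_ae`). The full
#' model is always included.
#'
#' @param cohort An `fc_cohort`.
#' @param cfg Base [run_config()].
#' @param variants Character subset of
#'   `c("full", "no_se", "no_ae", "no_meta", "no_ni", "no_se_ae")`.
#' @return List with `table` (one row of metric means/sds per variant) and
#'   `reports` (the named `eval_report`s).
#' @export
run_ablation <- function(cohort, cfg = run_config(),
                         variants = c("full", "no_se", "no_ae", "no_meta",
                                      "no_ni", "no_se_ae")) {
  variants <- match.arg(variants, several.ok = TRUE)
  if (!"full" %in% variants) variants <- c("full", variants)
  flag_sets <- list(
    full = list(), no_se = list(no_se = TRUE), no_ae = list(no_ae = TRUE),
    no_meta = list(no_meta = TRUE), no_ni = list(no_ni = TRUE),
    no_se_ae = list(no_se = TRUE, no_ae = TRUE))
  reports <- lapply(variants, function(v) {
    vcfg <- cfg
    for (nm in names(flag_sets[[v]])) vcfg$ablation[[nm]] <- flag_sets[[v]][[nm]]
    cross_validate(cohort, vcfg)
  })
  names(reports) <- variants
  table <- do.call(rbind, lapply(variants, function(v) {
    r <- reports[[v]]
    data.frame(variant = v, acc = r$mean[["acc"]], acc_sd = r$sd[["acc"]],
               sen = r$mean[["sen"]], spe = r$mean[["spe"]],
               auc = r$mean[["auc"]], f1 = r$mean[["f1"]])
  }))
  list(table = table, reports = reports)
}

#' Sweep the episodic task size
#'
#' Re-runs cross-validation over a grid of per-class support and query
#' sizes for the meta-training tasks, under a shared seed, to probe the
#' sensitivity of accuracy to the task-graph size.
#'
#' @param cohort An `fc_cohort`.
#' @param cfg Base [run_config()].
#' @param grid data.frame with integer columns `k_s` and `k_q`.
#' @return data.frame: `k_s`, `k_q`, `acc`, `acc_sd`.
#' @export
sweep_graph_size <- function(cohort, cfg = run_config(), grid) {
  assert_that(is.data.frame(grid) && nrow(grid) >= 1 &&
                all(c("k_s", "k_q") %in% names(grid)),
              "grid must be a nonempty data.frame with columns k_s, k_q")
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    gcfg <- cfg
    gcfg$task$k_train_s <- as.integer(grid$k_s[i])
    gcfg$task$k_train_q <- as.integer(grid$k_q[i])
    r <- cross_validate(cohort, gcfg)
    data.frame(k_s = grid$k_s[i], k_q = grid$k_q[i],
               acc = r$mean[["acc"]], acc_sd = r$sd[["acc"]])
  }))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Serialize an evaluation report to JSON
#'
#' Deterministic, timestamp-free JSON: the same report always produces
#' byte-identical output.
#'
#' @param report An `eval_report`.
#' @param path Optional output file; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_to_json <- function(report, path = NULL) {
  payload <- list(
    per_fold = report$per_fold,
    mean = as.list(report$mean), sd = as.list(report$sd),
    recall = as.list(stats::setNames(report$recall, report$class_labels)),
    confusion = unname(apply(report$confusion, 1, as.list)),
    seed = report$seed,
    config = unclass_deep(report$config))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
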