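#' Configuration for episodic task sampling and the phenotype adjacency
#'
#' @param C Number of classes.
#' @param k_train_s,k_train_q Per-class support / query sizes for
#'   meta-training tasks (the best-performing published setting is
#'   `k_train_s = 3`, `k_train_q = 5`, giving tasks of `C * 8` nodes for
#'   three classes).
#' @param k_test_s Per-class support size of meta-testing tasks (support
#'   drawn from the training set). Default 3, mirroring the training support
#'   size; raise it (e.g. 6) when classification rides on phenotype edges,
#'   where test queries profit from more labelled graph neighbours.
#' @param t Query size of meta-testing tasks; test subjects are split into
#'   `ceiling(n_test / t)` disjoint queries. `t = 1` predicts each new
#'   subject independently.
#' @param M Number of meta-training tasks to sample.
#' @param beta1 Per-feature similarity threshold in \[0, 1\]: subjects i, j
#'   count as similar on phenotype u iff `1 - |s_iu - s_ju| / range_u >= beta1`.
#'   The default 0.9 keeps ages within 10 percent of the cohort range and
#'   requires exact sex and APOE4 matches.
#' @param beta2 Edge threshold in \[0, 1\] on the mean of the three
#'   per-feature indicators. The default 1 requires all three phenotypes
#'   (age, sex, APOE4) to be similar, which keeps task graphs sparse and
#'   class-assortative; 2/3 relaxes this to any two of the three.
#' @param rule `"mean_ge"` thresholds the mean indicator at `beta2`;
#'   `"sum_ge"` thresholds the indicator sum at `3 * beta2` (equivalent).
#' @param phenotype_edges If `FALSE`, task graphs carry no edges at all
#'   (only the self-loops added by normalization survive), removing the
#'   non-image information. Used by the `-NI` ablation.
#' @param seed Integer seed for task sampling.
#' @return A `task_config` list.
#' @export
task_config <- function(C = 3L, k_train_s = 3L, k_train_q = 5L, k_test_s = 3L,
                        t = 10L, M = 100L, beta1 = 0.9, beta2 = 1,
                        rule = c("mean_ge", "sum_ge"), phenotype_edges = TRUE,
                        seed = 1L) {
  rule <- match.arg(rule)
  assert_that(C >= 2, "need at least 2 classes")
  assert_that(k_train_s >= 1 && k_train_q >= 1 && k_test_s >= 1 && t >= 1 && M >= 1,
              "all task sizes must be >= 1")
  assert_that(beta1 >= 0 && beta2 >= 0, "beta1 and beta2 must be >= 0")
  structure(list(C = as.integer(C), k_train_s = as.integer(k_train_s),
                 k_train_q = as.integer(k_train_q), k_test_s = as.integer(k_test_s),
                 t = as.integer(t), M = as.integer(M), beta1 = beta1,
                 beta2 = beta2, rule = rule,
                 phenotype_edges = isTRUE(phenotype_edges),
                 seed = as.integer(seed)),
            class = "task_config")
}

# Sample k subjects from one class, falling back to within-task replacement
# (with a warning) when the class has fewer members than requested.
sample_class <- function(ids, k, class_name) {
  if (length(ids) >= k) {
    ids[sample.int(length(ids), k)]
  } else {
    warning(sprintf("class %s has %d members < %d requested; sampling with replacement",
                    class_name, length(ids), k))
    ids[sample.int(length(ids), k, replace = TRUE)]
  }
}

#' Sample label-balanced meta-training tasks
#'
#' Draws `cfg$M` episodic tasks from a labelled training fold. Every task has
#' exactly `k_train_s` support and `k_train_q` query subjects per class
#' (support and query disjoint within a task whenever the class is large
#' enough); subjects may recur across tasks, which is what lets a small
#' cohort yield many label-balanced episodes.
#'
#' @param labels Integer class labels (1..C) of the training-fold subjects.
#' @param cfg A [task_config()].
#' @return List of `M` lists with integer vectors `support` and `query`,
#'   indices into `labels`.
#' @export
sample_train_tasks <- function(labels, cfg) {
  by_class <- lapply(seq_len(cfg$C), function(c) which(labels == c))
  empty <- which(vapply(by_class, length, integer(1)) == 0L)
  assert_that(length(empty) == 0, "class %s absent from training labels",
              paste(empty, collapse = ", "))
  k_tot <- cfg$k_train_s + cfg$k_train_q
  withr::with_seed(cfg$seed, {
    lapply(seq_len(cfg$M), function(m) {
      sup <- integer(0); qry <- integer(0)
      for (c in seq_len(cfg$C)) {
        picked <- sample_class(by_class[[c]], k_tot, c)
        sup <- c(sup, picked[seq_len(cfg$k_train_s)])
        qry <- c(qry, picked[cfg$k_train_s + seq_len(cfg$k_train_q)])
      }
      list(support = sup, query = qry)
    })
  })
}

#' Partition the test set into meta-testing tasks
#'
#' Each meta-testing task couples a label-balanced support set drawn from the
#' training fold (`C * k_test_s` subjects) with a query chunk of unlabelled
#' test subjects. Query chunks are disjoint and their union is exactly the
#' test set, so every test subject is predicted exactly once;
#' `P = ceiling(length(test_ids) / t)` tasks are produced and the last query
#' may be smaller than `t`.
#'
#' @param train_labels Integer class labels of the training-fold subjects.
#' @param test_ids Identifiers of the test subjects (any vector).
#' @param cfg A [task_config()].
#' @return List of `P` lists with `support` (indices into `train_labels`)
#'   and `query` (elements of `test_ids`).
#' @export
sample_test_tasks <- function(train_labels, test_ids, cfg) {
  assert_that(length(test_ids) >= 1, "test_ids must be nonempty")
  by_class <- lapply(seq_len(cfg$C), function(c) which(train_labels == c))
  empty <- which(vapply(by_class, length, integer(1)) == 0L)
  assert_that(length(empty) == 0, "class %s absent from training labels",
              paste(empty, collapse = ", "))
  withr::with_seed(cfg$seed, {
    order_q <- sample.int(length(test_ids))
    P <- ceiling(length(test_ids) / cfg$t)
    lapply(seq_len(P), function(p) {
      lo <- (p - 1L) * cfg$t + 1L
      hi <- min(p * cfg$t, length(test_ids))
      sup <- unlist(lapply(seq_len(cfg$C), function(c)
        sample_class(by_class[[c]], cfg$k_test_s, c)))
      list(support = sup, query = test_ids[order_q[lo:hi]])
    })
  })
}

#' Per-phenotype similarity indicator between two subjects
#'
#' Returns 1 iff `1 - |si_u - sj_u| / range_u >= beta1`, i.e. the two
#' subjects' values of one non-image feature are within `(1 - beta1)` of the
#' cohort range of that feature. A degenerate feature with zero range makes
#' all subjects identical on it, so the indicator is defined as 1.
#'
#' @param si_u,sj_u Feature values of the two subjects (vectorized).
#' @param range_u Cohort range (max - min) of the feature.
#' @param beta1 Similarity threshold in \[0, 1\].
#' @return 0/1 (vectorized over the inputs).
#' @export
pairwise_feature_indicator <- function(si_u, sj_u, range_u, beta1) {
  if (range_u == 0) return(rep(1L, length(si_u)))
  as.integer(1 - abs(si_u - sj_u) / range_u >= beta1)
}

#' Ranges of the non-image features over a reference set
#'
#' Computes `max - min` for age, sex and APOE4 over the given phenotype
#' rows. Ranges should be computed on the training fold and frozen, so test
#' subjects never influence the graph construction.
#'
#' @param phenotypes data.frame with columns `age`, `sex`, `apoe4`.
#' @return Named numeric vector of ranges.
#' @export
phenotype_ranges <- function(phenotypes) {
  vapply(c("age", "sex", "apoe4"), function(u) {
    v <- phenotypes[[u]]
    assert_that(!is.null(v), "phenotype table lacks feature %s", u)
    diff(range(v))
  }, numeric(1))
}

#' Phenotype-similarity adjacency matrix
#'
#' Builds the binary population-graph adjacency over a set of subjects from
#' their three non-image features (age, sex, APOE4 allele count). An edge is
#' present iff the mean of the three per-feature similarity indicators
#' reaches `beta2`; the diagonal is always zero and the matrix is symmetric.
#'
#' @param phenotypes data.frame with columns `subject_id` (optional), `age`,
#'   `sex`, `apoe4`; one row per node.
#' @param beta1 Per-feature similarity threshold.
#' @param beta2 Edge threshold on the mean indicator.
#' @param ranges Named feature ranges from [phenotype_ranges()] (computed on
#'   the training fold).
#' @param rule `"mean_ge"` or the equivalent `"sum_ge"` (see [task_config()]).
#' @return n x n binary matrix.
#' @export
build_adjacency <- function(phenotypes, beta1, beta2, ranges,
                            rule = c("mean_ge", "sum_ge")) {
  rule <- match.arg(rule)
  feats <- c("age", "sex", "apoe4")
  for (u in feats) {
    v <- phenotypes[[u]]
    assert_that(!is.null(v), "phenotype table lacks feature %s", u)
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      id <- phenotypes$subject_id[i] %||% i
      stopf("subject %s is missing non-image feature %s", id, u)
    }
  }
  n <- nrow(phenotypes)
  S <- matrix(0, n, n)
  for (u in feats) {
    v <- phenotypes[[u]]
    D <- abs(outer(v, v, "-"))
    Iu <- if (ranges[[u]] == 0) matrix(1, n, n) else (1 - D / ranges[[u]] >= beta1) * 1
    S <- S + Iu
  }
  # small tolerance so the mean and sum readings agree at exact thresholds
  A <- if (rule == "mean_ge") (S / 3 >= beta2 - 1e-9) * 1 else
    (S >= 3 * beta2 - 1e-9) * 1
  diag(A) <- 0
  A
}

#' Assemble one meta-task graph
#'
#' Combines sampled support and query subjects into a small transductive
#' graph: node features come from the encoded feature matrix, edges from the
#' phenotype adjacency. Nodes are ordered support block first then query
#' block, each block stably sorted by subject id, so masks and adjacency are
#' reproducible.
#'
#' @param support_idx,query_idx Row indices into `features` / `phenotypes`.
#' @param features Encoded feature matrix (rows = subjects).
#' @param phenotypes Phenotype data.frame aligned with `features`.
#' @param labels Integer labels aligned with `features`; query labels may be
#'   `NA` at meta-test time.
#' @param cfg A [task_config()] (for `beta1`, `beta2`, `rule`).
#' @param ranges Frozen feature ranges from [phenotype_ranges()].
#' @return A `meta_task`: `node_ids`, `support_mask`, `query_mask`,
#'   `labels`, binary adjacency `A`, node features `X`.
#' @export
build_meta_task <- function(support_idx, query_idx, features, phenotypes,
                            labels, cfg, ranges) {
  ids <- phenotypes$subject_id %||% as.character(seq_len(nrow(phenotypes)))
  support_idx <- support_idx[order(ids[support_idx])]
  query_idx <- query_idx[order(ids[query_idx])]
  node_idx <- c(support_idx, query_idx)
  n_s <- length(support_idx)
  n <- length(node_idx)
  A <- if (isTRUE(cfg$phenotype_edges %||% TRUE)) {
    build_adjacency(phenotypes[node_idx, , drop = FALSE],
                    cfg$beta1, cfg$beta2, ranges, cfg$rule)
  } else {
    matrix(0, n, n)
  }
  structure(
    list(node_ids = ids[node_idx],
         node_idx = node_idx,
         support_mask = c(rep(TRUE, n_s), rep(FALSE, n - n_s)),
         query_mask = c(rep(FALSE, n_s), rep(TRUE, n - n_s)),
         labels = labels[node_idx],
         A = A,
         X = features[node_idx, , drop = FALSE]),
    class = "meta_task")
}
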