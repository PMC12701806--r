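#' Configuration for a synthetic connectome cohort
#'
#' Describes a label-imbalanced cohort of subjects, each carrying a
#' functional-connectivity feature vector (the flattened upper triangle of an
#' `n_regions` x `n_regions` correlation matrix) plus three non-image
#' phenotype features (age, sex, APOE4 allele count) that may be partially
#' associated with the class label.
#'
#' Class `c` (1..C) shifts the mean of the `n_signal_edges` signal entries by
#' `(c - (C + 1) / 2) * effect_size`, so the gap between adjacent classes is
#' `effect_size` correlation units and the shifts stay centred inside the
#' admissible correlation range before clipping to \[-1, 1\].
#'
#' @param n_regions Number of atlas regions; feature dimension is
#'   `n_regions * (n_regions - 1) / 2` (4005 for a 90-region atlas).
#' @param class_counts Integer vector of per-class subject counts; length
#'   defines the number of classes C (>= 2). Default mirrors a typical
#'   imbalanced dementia cohort (30 / 92 / 243).
#' @param n_signal_edges Number of connectivity entries carrying a
#'   class-dependent mean shift; default 150, capped at the feature width.
#' @param effect_size Mean-shift gap between adjacent classes on signal
#'   edges, in correlation units (>= 0; 0 means no imaging signal).
#' @param noise_sd Standard deviation of the connectivity noise (> 0).
#' @param demo_assoc Strength in \[0, 1\] of the association between class and
#'   demographics; 0 makes age/sex/APOE4 independent of the label.
#' @param seed Integer seed; the same configuration always regenerates an
#'   identical cohort.
#' @param class_labels Optional character names for the classes.
#' @return A `cohort_config` object (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_regions = 90L,
                          class_counts = c(30L, 92L, 243L),
                          n_signal_edges = 150L,
                          effect_size = 0.4,
                          noise_sd = 0.15,
                          demo_assoc = 0.8,
                          seed = 1L,
                          class_labels = NULL) {
  assert_that(length(n_regions) == 1L && n_regions >= 2, "n_regions must be >= 2")
  assert_that(length(class_counts) >= 2L, "need at least 2 classes")
  assert_that(all(class_counts >= 1), "all class counts must be positive")
  assert_that(effect_size >= 0, "effect_size must be >= 0")
  assert_that(noise_sd > 0, "noise_sd must be > 0")
  assert_that(demo_assoc >= 0 && demo_assoc <= 1, "demo_assoc must lie in [0, 1]")
  d <- n_regions * (n_regions - 1) / 2
  if (missing(n_signal_edges)) n_signal_edges <- min(150L, d)
  assert_that(n_signal_edges >= 0 && n_signal_edges <= d,
              "n_signal_edges must lie in [0, %d]", d)
  C <- length(class_counts)
  if (is.null(class_labels)) class_labels <- paste0("class", seq_len(C))
  assert_that(length(class_labels) == C, "class_labels must match class_counts")
  structure(
    list(n_regions = as.integer(n_regions),
         class_counts = as.integer(class_counts),
         n_signal_edges = as.integer(n_signal_edges),
         effect_size = effect_size,
         noise_sd = noise_sd,
         demo_assoc = demo_assoc,
         seed = as.integer(seed),
         class_labels = as.character(class_labels)),
    class = "cohort_config")
}

#' Generate a synthetic connectome cohort
#'
#' Draws `sum(class_counts)` subjects. Connectivity features are independent
#' Gaussian noise around zero, with class-dependent mean shifts planted on a
#' random subset of entries, clipped to the correlation range \[-1, 1\].
#' Demographics are drawn with class association proportional to
#' `demo_assoc`: age ~ Normal(70 + class shift, 6), sex ~ Bernoulli(0.5),
#' APOE4 ~ Binomial(2, p_c) with p_c increasing in class index.
#'
#' Positive definiteness of the implied correlation matrices is deliberately
#' not enforced: the downstream pipeline consumes entries independently.
#'
#' @param config A [cohort_config()].
#' @return An `fc_cohort`: list with `features` (N x d matrix, rows named by
#'   subject id), `phenotypes` (data.frame: subject_id, age, sex, apoe4,
#'   label), `n_regions`, `class_labels`, and the planted `signal_edges`
#'   (kept for diagnostics; not used by the classifier).
#' @examples
#' coh <- generate_cohort(cohort_config(n_regions = 10, class_counts = c(5, 8)))
#' table(coh$phenotypes$label)
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "cohort_config"), "config must be a cohort_config")
  C <- length(config$class_counts)
  d <- config$n_regions * (config$n_regions - 1L) / 2L
  N <- sum(config$class_counts)
  max_shift <- (C - 1) / 2 * config$effect_size
  if (max_shift > 1)
    warning("class mean shifts exceed the correlation range; clipping will distort classes")

  withr::with_seed(config$seed, {
    signal_edges <- sort(sample.int(d, config$n_signal_edges))
    X <- matrix(stats::rnorm(N * d, sd = config$noise_sd), N, d)
    labels <- rep(seq_len(C), config$class_counts)
    age <- numeric(N); sex <- integer(N); apoe4 <- integer(N)
    for (c in seq_len(C)) {
      rows <- which(labels == c)
      centred <- c - (C + 1) / 2
      shift <- centred * config$effect_size
      if (config$n_signal_edges > 0)
        X[rows, signal_edges] <- X[rows, signal_edges] + shift
      age[rows] <- stats::rnorm(length(rows),
                                mean = 70 + centred * 10 * config$demo_assoc, sd = 6)
      sex[rows] <- stats::rbinom(length(rows), 1L, 0.5)
      p_apoe <- clamp(0.5 + 0.45 * centred * config$demo_assoc, 0.02, 0.98)
      apoe4[rows] <- stats::rbinom(length(rows), 2L, p_apoe)
    }
  })
  X <- clamp(X, -1, 1)
  ids <- sprintf("S%04d", seq_len(N))
  rownames(X) <- ids
  phen <- data.frame(subject_id = ids, age = age, sex = sex, apoe4 = apoe4,
                     label = labels, stringsAsFactors = FALSE)
  new_cohort(X, phen, config$n_regions, config$class_labels,
             signal_edges = signal_edges)
}

new_cohort <- function(features, phenotypes, n_regions, class_labels,
                       signal_edges = NULL) {
  structure(
    list(features = features, phenotypes = phenotypes,
         n_regions = as.integer(n_regions), class_labels = class_labels,
         signal_edges = signal_edges),
    class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat(sprintf("fc_cohort: %d subjects, %d regions, %d connectivity features\n",
              nrow(x$features), x$n_regions, ncol(x$features)))
  lab <- x$phenotypes$label
  if (any(!is.na(lab))) {
    counts <- table(factor(lab[!is.na(lab)], levels = seq_along(x$class_labels),
                           labels = x$class_labels))
    cat("class counts:", paste(sprintf("%s=%d", names(counts), counts),
                               collapse = ", "), "\n")
  }
  if (anyNA(lab)) cat(sum(is.na(lab)), "unlabelled subjects\n")
  invisible(x)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a cohort to disk
#'
#' Serializes a cohort as a phenotype TSV (`phenotypes.tsv`, columns
#' `subject_id age sex apoe4 label`) plus either one wide TSV of flattened
#' connectivity vectors (`features.tsv`, default) or one whitespace-delimited
#' square matrix file `<subject_id>.txt` per subject. Numbers are written
#' with 17 significant digits so the round trip through [read_cohort()] is
#' exact.
#'
#' @param cohort An `fc_cohort`.
#' @param path Output directory (created if missing).
#' @param format `"wide"` or `"matrix"`.
#' @export
write_cohort <- function(cohort, path, format = c("wide", "matrix")) {
  format <- match.arg(format)
  assert_that(inherits(cohort, "fc_cohort"), "cohort must be an fc_cohort")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  phen <- cohort$phenotypes
  phen$age <- fmt_num(phen$age)
  utils::write.table(phen, file.path(path, "phenotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(n_regions = cohort$n_regions, class_labels = cohort$class_labels)
  jsonlite::write_json(meta, file.path(path, "cohort.json"), auto_unbox = TRUE)
  if (format == "wide") {
    d <- ncol(cohort$features)
    con <- file(file.path(path, "features.tsv"), "w")
    on.exit(close(con))
    writeLines(paste(c("subject_id", paste0("f", seq_len(d))), collapse = "\t"), con)
    for (i in seq_len(nrow(cohort$features))) {
      writeLines(paste(c(cohort$phenotypes$subject_id[i],
                         fmt_num(cohort$features[i, ])), collapse = "\t"), con)
    }
  } else {
    for (i in seq_len(nrow(cohort$features))) {
      M <- unflatten_upper_triangle(cohort$features[i, ], cohort$n_regions)
      utils::write.table(matrix(fmt_num(M), nrow(M)),
                         file.path(path, paste0(cohort$phenotypes$subject_id[i], ".txt")),
                         sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' Read a cohort from disk
#'
#' Reads either on-disk dialect produced by [write_cohort()] (wide TSV of
#' flattened vectors, or per-subject square matrix files). Connectivity
#' values are validated to lie in \[-1, 1\]; a `label` column is optional and
#' missing labels are kept as `NA` (prediction-time subjects).
#'
#' @param path Directory containing `phenotypes.tsv` plus either
#'   `features.tsv` or `<subject_id>.txt` matrix files.
#' @return An `fc_cohort`.
#' @export
read_cohort <- function(path) {
  phen_path <- file.path(path, "phenotypes.tsv")
  assert_that(file.exists(phen_path), "missing phenotype table: %s", phen_path)
  phen <- utils::read.table(phen_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  needed <- c("subject_id", "age", "sex", "apoe4")
  missing_cols <- setdiff(needed, names(phen))
  assert_that(length(missing_cols) == 0,
              "phenotypes.tsv lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (is.null(phen$label)) phen$label <- NA_integer_
  assert_that(!anyDuplicated(phen$subject_id), "duplicated subject ids")

  meta_path <- file.path(path, "cohort.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()

  wide_path <- file.path(path, "features.tsv")
  if (file.exists(wide_path)) {
    wide <- utils::read.table(wide_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, check.names = FALSE)
    assert_that(identical(sort(wide$subject_id), sort(phen$subject_id)),
                "features.tsv and phenotypes.tsv disagree on subject ids")
    wide <- wide[match(phen$subject_id, wide$subject_id), , drop = FALSE]
    X <- as.matrix(wide[, -1, drop = FALSE])
    storage.mode(X) <- "double"
    n_regions <- meta$n_regions %||% infer_regions(ncol(X))
  } else {
    mats <- lapply(phen$subject_id, function(id) {
      f <- file.path(path, paste0(id, ".txt"))
      assert_that(file.exists(f), "missing connectivity matrix file for subject %s", id)
      M <- as.matrix(utils::read.table(f, header = FALSE))
      storage.mode(M) <- "double"
      M
    })
    dims <- vapply(mats, nrow, integer(1))
    assert_that(length(unique(dims)) == 1L, "connectivity matrices have mixed sizes")
    n_regions <- meta$n_regions %||% dims[1]
    X <- t(vapply(mats, flatten_upper_triangle, numeric(dims[1] * (dims[1] - 1) / 2)))
  }
  bad <- which(abs(X) > 1 + 1e-12, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("connectivity value %g outside [-1, 1] for subject %s (feature %d)",
          X[bad[1, 1], bad[1, 2]], phen$subject_id[bad[1, 1]], bad[1, 2])
  }
  rownames(X) <- phen$subject_id
  colnames(X) <- NULL
  labs <- phen$label
  class_labels <- unlist(meta$class_labels %||%
                           paste0("class", seq_len(max(labs, 1, na.rm = TRUE))))
  new_cohort(X, phen, n_regions, class_labels)
}

infer_regions <- function(d) {
  n <- (1 + sqrt(1 + 8 * d)) / 2
  assert_that(abs(n - round(n)) < 1e-9,
              "feature width %d is not n*(n-1)/2 for any integer n", d)
  as.integer(round(n))
}
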