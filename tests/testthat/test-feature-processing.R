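test_that("upper-triangle flattening is row-major and matches the loop oracle", {
  M <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(flatten_upper_triangle(M), 0.5)
  expect_length(flatten_upper_triangle(diag(90)), 4005)
  # row-major order: (1,2), (1,3), (2,3)
  M3 <- matrix(0, 3, 3); M3[1, 2] <- M3[2, 1] <- 12
  M3[1, 3] <- M3[3, 1] <- 13; M3[2, 3] <- M3[3, 2] <- 23
  expect_equal(flatten_upper_triangle(M3), c(12, 13, 23))
  withr::with_seed(8, {
    for (k in 1:20) {
      n <- sample(3:9, 1)
      M <- matrix(rnorm(n * n), n, n); M <- (M + t(M)) / 2
      expect_identical(flatten_upper_triangle(M), oracle_flatten(M))
    }
  })
  expect_error(flatten_upper_triangle(matrix(1, 2, 3)), "square")
  Masym <- matrix(c(0, 1, 0, 0), 2)
  expect_error(flatten_upper_triangle(Masym), "symmetric")
})

test_that("unflattening inverts flattening", {
  withr::with_seed(3, {
    x <- runif(10 * 9 / 2, -1, 1)
    M <- metagcn:::unflatten_upper_triangle(x, 10)
    expect_equal(flatten_upper_triangle(M), x)
    expect_equal(diag(M), rep(1, 10))
  })
})

test_that("squeeze is the column mean and matches the summation oracle", {
  expect_equal(squeeze_features(matrix(c(1, 3, 2, 4), 2)), c(2, 3))
  one <- matrix(rnorm(5), 1)
  expect_equal(squeeze_features(one), as.vector(one))
  withr::with_seed(4, {
    X <- matrix(rnorm(35), 7, 5)
    expect_lt(max(abs(squeeze_features(X) - oracle_squeeze(X))), 1e-12)
  })
})

test_that("excitation implements sigmoid(W2 relu(W1 z)) with outputs in (0,1)", {
  d <- 3
  z <- c(0.2, -0.4, 0.9)
  zero <- list(W1 = matrix(0, 1, d), W2 = matrix(0, d, 1))
  expect_equal(excitation(z, zero), rep(0.5, d))
  hand <- list(W1 = matrix(c(0.5, -1, 2), 1, d), W2 = matrix(c(1, -2, 0.5), d, 1))
  expect_equal(excitation(z, hand), oracle_excitation(z, hand$W1, hand$W2),
               tolerance = 1e-10)
  withr::with_seed(5, {
    for (k in 1:10) {
      dd <- sample(2:12, 1); h <- sample(1:4, 1)
      p <- list(W1 = matrix(rnorm(h * dd), h, dd), W2 = matrix(rnorm(dd * h), dd, h))
      s <- excitation(rnorm(dd), p)
      expect_true(all(s > 0 & s < 1))
    }
  })
  expect_error(excitation(rnorm(4), zero), "columns")
})

test_that("rescaling shrinks features elementwise by the weight vector", {
  X <- matrix(rnorm(12), 3, 4)
  expect_equal(rescale_features(X, rep(0.5, 4)), X / 2)
  expect_equal(rescale_features(rescale_features(X, rep(0.5, 4)), rep(0.5, 4)), X / 4)
  withr::with_seed(6, {
    s <- runif(4)
    expect_identical(rescale_features(X, s), oracle_rescale(X, s))
    expect_true(all(abs(rescale_features(X, s)) <= abs(X)))
  })
  expect_error(rescale_features(X, rep(0.5, 3)), "length")
})

test_that("joint SE-AE training reduces validation reconstruction error and is reproducible", {
  withr::with_seed(21, {
    X <- matrix(rnorm(80 * 60, sd = 0.3), 80, 60)
    X[, 1:10] <- X[, 1:10] + rep(rnorm(80), 10)  # shared low-rank structure
  })
  hyper <- se_ae_config(latent = 5, hidden = 24, epochs = 60, seed = 3)
  fit <- fit_se_ae(X[1:60, ], X[61:80, ], hyper)
  expect_lt(fit$best_val_mse, fit$init_val_mse)
  expect_equal(fit$log$val_mse[fit$best_epoch], fit$best_val_mse)
  expect_true(all(fit$se$s > 0 & fit$se$s < 1))
  # excitation weights stored in the fit agree with the excitation operator
  expect_equal(fit$se$s, excitation(fit$se$z, fit$se), tolerance = 1e-12)
  fit2 <- fit_se_ae(X[1:60, ], X[61:80, ], hyper)
  expect_identical(fit$ae$We1, fit2$ae$We1)
  expect_identical(fit$se$s, fit2$se$s)
})

test_that("constant training data is reconstructed to the variance floor", {
  X <- matrix(rep(seq(-0.5, 0.5, length.out = 30), each = 40), 40, 30)
  fit <- fit_se_ae(X, X[1:5, , drop = FALSE],
                   se_ae_config(latent = 2, hidden = 16, epochs = 300, lr = 5e-3, seed = 2))
  expect_lt(fit$best_val_mse, 1e-3)
})

test_that("the SE-AE analytic gradient matches finite differences", {
  withr::with_seed(12, {
    X <- matrix(rnorm(6 * 8, sd = 0.5), 6, 8)
    hyper <- se_ae_config(r = 4, latent = 2, hidden = 3, epochs = 1, seed = 1)
    P <- metagcn:::init_se_ae_params(8, hyper)
    z <- squeeze_features(X)
    g <- metagcn:::se_ae_grad(P, X, z, hyper)
    eps <- 1e-6
    for (nm in names(P)) {
      idx <- sample(length(P[[nm]]), min(4, length(P[[nm]])))
      for (i in idx) {
        Pp <- P; Pm <- P
        Pp[[nm]][i] <- Pp[[nm]][i] + eps
        Pm[[nm]][i] <- Pm[[nm]][i] - eps
        num <- (metagcn:::se_ae_mse(Pp, X, z, hyper) -
                  metagcn:::se_ae_mse(Pm, X, z, hyper)) / (2 * eps)
        expect_lt(abs(num - g$grads[[nm]][i]) / max(abs(num), 1e-6), 1e-4)
      }
    }
  })
})

test_that("encoding compresses to the latent width, is pure and deterministic", {
  withr::with_seed(7, X <- matrix(rnorm(50 * 40, sd = 0.4), 50, 40))
  fit <- fit_se_ae(X[1:40, ], X[41:50, ], se_ae_config(latent = 6, hidden = 16, epochs = 20))
  enc <- encode_features(X, fit)
  expect_equal(dim(enc), c(50, 6))
  expect_identical(enc, encode_features(X, fit))
  expect_error(fit_se_ae(X[1:40, ], X[41:50, ], se_ae_config(latent = 40)), "latent")
  expect_error(encode_features(matrix(0, 3, 39), fit), "width")
})

test_that("encoded features keep a strongly planted class signal linearly separable", {
  coh <- small_cohort(seed = 13, effect_size = 0.8, noise_sd = 0.1,
                      class_counts = c(20L, 20L, 20L))
  fit <- fit_se_ae(coh$features[1:48, ], coh$features[49:60, ],
                   se_ae_config(latent = 8, hidden = 32, epochs = 80))
  enc <- encode_features(coh$features, fit)
  lab <- coh$phenotypes$label
  centroids <- sapply(1:3, function(c) colMeans(enc[lab == c, , drop = FALSE]))
  pred <- apply(enc, 1, function(r) which.min(colSums((centroids - r)^2)))
  expect_gt(mean(pred == lab), 0.9)
})
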