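#' Hyperparameters for the SE-AE feature-processing block
#'
#' @param r Reduction rate of the squeeze-and-excitation bottleneck
#'   (bottleneck width = `floor(d / r)`, at least 1).
#' @param hidden Width of the autoencoder hidden layers.
#' @param latent Encoded feature width (must be well below the raw width d).
#' @param epochs Full-batch training epochs.
#' @param lr Adam learning rate.
#' @param seed Integer seed for weight initialization.
#' @param use_se If `FALSE` the excitation weighting is skipped (all weights
#'   fixed at 1): the autoencoder alone is trained. Used by the `-SE`
#'   ablation.
#' @param reconstruct_target `"raw"` reconstructs the unweighted features
#'   (default); `"rescaled"` reconstructs the SE-weighted features.
#' @return An `se_ae_config` list.
#' @export
se_ae_config <- function(r = 16L, hidden = 256L, latent = 64L, epochs = 200L,
                         lr = 1e-3, seed = 1L, use_se = TRUE,
                         reconstruct_target = c("raw", "rescaled")) {
  reconstruct_target <- match.arg(reconstruct_target)
  assert_that(r >= 1 && hidden >= 1 && latent >= 1 && epochs >= 1,
              "r, hidden, latent and epochs must be positive")
  assert_that(lr > 0, "lr must be > 0")
  structure(list(r = as.integer(r), hidden = as.integer(hidden),
                 latent = as.integer(latent), epochs = as.integer(epochs),
                 lr = lr, seed = as.integer(seed), use_se = isTRUE(use_se),
                 reconstruct_target = reconstruct_target),
            class = "se_ae_config")
}

init_se_ae_params <- function(d, hyper) {
  dr <- max(1L, d %/% hyper$r)
  h <- hyper$hidden; k <- hyper$latent
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  P <- list()
  if (hyper$use_se) {
    P$W1se <- he(d, dr)  # stored transposed relative to the algebra: z %*% W1se
    P$W2se <- he(dr, d) * 0.1
  }
  P$We1 <- he(d, h);  P$be1 <- numeric(h)
  P$We2 <- he(h, k);  P$be2 <- numeric(k)
  P$Wd1 <- he(k, h);  P$bd1 <- numeric(h)
  P$Wd2 <- he(h, d);  P$bd2 <- numeric(d)
  P
}

# Excitation weights from frozen global vector z under current parameters.
se_weights <- function(P, z, use_se) {
  if (!use_se) return(rep(1, length(z)))
  h1 <- relu(as.vector(z %*% P$W1se))
  as.vector(sigmoid(h1 %*% P$W2se))
}

se_ae_forward <- function(P, X, z, hyper) {
  s <- se_weights(P, z, hyper$use_se)
  Xt <- if (hyper$use_se) sweep(X, 2L, s, "*") else X
  E1 <- relu(sweep(Xt %*% P$We1, 2L, P$be1, "+"))
  Code <- sweep(E1 %*% P$We2, 2L, P$be2, "+")
  D1 <- relu(sweep(Code %*% P$Wd1, 2L, P$bd1, "+"))
  Xr <- sweep(D1 %*% P$Wd2, 2L, P$bd2, "+")
  list(s = s, Xt = Xt, E1 = E1, Code = Code, D1 = D1, Xr = Xr)
}

se_ae_mse <- function(P, X, z, hyper) {
  fw <- se_ae_forward(P, X, z, hyper)
  target <- if (hyper$reconstruct_target == "raw") X else fw$Xt
  mean((fw$Xr - target)^2)
}

# Analytic gradient of the reconstruction MSE with respect to all SE and AE
# parameters (full batch).
se_ae_grad <- function(P, X, z, hyper) {
  fw <- se_ae_forward(P, X, z, hyper)
  target <- if (hyper$reconstruct_target == "raw") X else fw$Xt
  n_el <- length(X)
  R <- fw$Xr - target
  loss <- mean(R^2)
  dXr <- 2 * R / n_el
  G <- list()
  G$Wd2 <- crossprod(fw$D1, dXr); G$bd2 <- colSums(dXr)
  dD1 <- (dXr %*% t(P$Wd2)) * (fw$D1 > 0)
  G$Wd1 <- crossprod(fw$Code, dD1); G$bd1 <- colSums(dD1)
  dCode <- dD1 %*% t(P$Wd1)
  G$We2 <- crossprod(fw$E1, dCode); G$be2 <- colSums(dCode)
  dE1 <- (dCode %*% t(P$We2)) * (fw$E1 > 0)
  G$We1 <- crossprod(fw$Xt, dE1); G$be1 <- colSums(dE1)
  if (hyper$use_se) {
    dXt <- dE1 %*% t(P$We1)
    if (hyper$reconstruct_target == "rescaled") dXt <- dXt - dXr
    ds <- colSums(X * dXt)
    s <- fw$s
    da2 <- ds * s * (1 - s)
    h1 <- relu(as.vector(z %*% P$W1se))
    G$W2se <- outer(h1, da2)
    dh1 <- as.vector(P$W2se %*% da2) * (h1 > 0)
    G$W1se <- outer(z, dh1)
  }
  list(loss = loss, grads = G)
}

adam_init <- function(P) {
  list(m = lapply(P, function(p) p * 0), v = lapply(P, function(p) p * 0), t = 0L)
}

adam_step <- function(P, G, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(G)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * G[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * G[[nm]]^2
    P[[nm]] <- P[[nm]] - lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = P, state = state)
}

#' Train the SE-AE feature-processing block
#'
#' Jointly trains the squeeze-and-excitation weighting and a two-layer
#' encoder / two-layer decoder autoencoder under an unsupervised mean-squared
#' reconstruction loss: raw features are weighted by the excitation vector s,
#' compressed to `latent` dimensions and reconstructed; the loss compares the
#' reconstruction with the raw input. The squeeze vector z is computed once
#' from the training matrix and frozen, so validation/test subjects never
#' influence the weights (no leakage). The parameter snapshot with the lowest
#' validation reconstruction error is returned.
#'
#' @param X_train N x d matrix of raw training features.
#' @param X_val Validation matrix (same width), used only for model
#'   selection.
#' @param hyper An [se_ae_config()].
#' @return An `se_ae_fit`: list with `se` (an `se_params` with `W1`, `W2`,
#'   `r`, frozen `z` and final weights `s`), `ae` (encoder/decoder weights),
#'   `log` (per-epoch train/validation MSE), `init_val_mse`, `best_epoch`,
#'   `best_val_mse`, and the hyperparameter echo.
#' @export
fit_se_ae <- function(X_train, X_val, hyper = se_ae_config()) {
  assert_that(is.matrix(X_train) && nrow(X_train) >= 1, "X_train must be a nonempty matrix")
  assert_that(is.matrix(X_val) && nrow(X_val) >= 1, "validation set must be nonempty")
  d <- ncol(X_train)
  assert_that(ncol(X_val) == d, "X_train and X_val widths differ")
  assert_that(hyper$latent < d,
              "latent width (%d) must be smaller than the raw width (%d)",
              hyper$latent, d)

  z <- squeeze_features(X_train)
  P <- withr::with_seed(hyper$seed, init_se_ae_params(d, hyper))
  state <- adam_init(P)
  init_val_mse <- se_ae_mse(P, X_val, z, hyper)
  best <- list(val = init_val_mse, P = P, epoch = 0L)
  log <- data.frame(epoch = seq_len(hyper$epochs), train_mse = NA_real_,
                    val_mse = NA_real_)
  for (e in seq_len(hyper$epochs)) {
    g <- se_ae_grad(P, X_train, z, hyper)
    upd <- adam_step(P, g$grads, state, hyper$lr)
    P <- upd$params; state <- upd$state
    val <- se_ae_mse(P, X_val, z, hyper)
    log$train_mse[e] <- g$loss
    log$val_mse[e] <- val
    if (val < best$val) best <- list(val = val, P = P, epoch = e)
  }
  Pb <- best$P
  s <- se_weights(Pb, z, hyper$use_se)
  se <- structure(list(W1 = if (hyper$use_se) t(Pb$W1se) else NULL,
                       W2 = if (hyper$use_se) t(Pb$W2se) else NULL,
                       r = hyper$r, z = z, s = s, use_se = hyper$use_se),
                  class = "se_params")
  ae <- structure(list(We1 = Pb$We1, be1 = Pb$be1, We2 = Pb$We2, be2 = Pb$be2,
                       Wd1 = Pb$Wd1, bd1 = Pb$bd1, Wd2 = Pb$Wd2, bd2 = Pb$bd2,
                       latent = hyper$latent, activation = "relu"),
                  class = "ae_params")
  structure(list(se = se, ae = ae, log = log, init_val_mse = init_val_mse,
                 best_val_mse = best$val, best_epoch = best$epoch,
                 hyper = hyper),
            class = "se_ae_fit")
}

#' @export
print.se_ae_fit <- function(x, ...) {
  cat(sprintf(
    "se_ae_fit: d=%d -> latent=%d, best val MSE %.5g (epoch %d) from initial %.5g\n",
    nrow(x$ae$We1), x$ae$latent, x$best_val_mse, x$best_epoch, x$init_val_mse))
  invisible(x)
}

#' Encode features with a trained SE-AE block
#'
#' Applies the frozen excitation weights s (learned on the training fold) and
#' the trained encoder to a raw feature matrix, producing the reduced
#' representation consumed by the graph network. Deterministic and pure.
#'
#' @param X N x d matrix of raw features.
#' @param fit An `se_ae_fit` from [fit_se_ae()].
#' @return N x latent matrix of encoded features.
#' @export
encode_features <- function(X, fit) {
  assert_that(inherits(fit, "se_ae_fit"), "fit must come from fit_se_ae()")
  assert_that(ncol(X) == nrow(fit$ae$We1),
              "X width %d does not match trained width %d", ncol(X), nrow(fit$ae$We1))
  Xt <- if (fit$se$use_se) rescale_features(X, fit$se$s) else X
  E1 <- relu(sweep(Xt %*% fit$ae$We1, 2L, fit$ae$be1, "+"))
  out <- sweep(E1 %*% fit$ae$We2, 2L, fit$ae$be2, "+")
  rownames(out) <- rownames(X)
  out
}
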