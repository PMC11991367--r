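#' VAE configuration
#'
#' Architecture and training hyperparameters for the fully-connected
#' variational autoencoder. The encoder maps the input through hidden layers
#' of 128 and 64 rectified-linear units to `2 * latent_dim` outputs (posterior
#' mean and log-variance); the decoder mirrors the hidden widths back to the
#' input dimension with a linear output layer.
#'
#' @param input_dim signal length consumed by the model.
#' @param latent_dim latent space dimension.
#' @param hidden_dims widths of the two hidden layers (encoder order).
#' @param learning_rate optimizer step size.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param beta weight of the KL term in the loss.
#' @param seed integer seed governing weight initialization and training
#'   stochasticity (shuffling and reparameterization draws).
#' @param optimizer `"adam"` (default) or plain `"sgd"`.
#' @param early_stopping if `TRUE` and validation data are supplied to
#'   [vae_train()], stop when validation loss has not improved for
#'   `patience` epochs.
#' @param patience early-stopping patience in epochs.
#' @return object of class `vae_config`.
#' @export
vae_config <- function(input_dim = 90L, latent_dim = 20L,
                       hidden_dims = c(128L, 64L), learning_rate = 0.001,
                       batch_size = 32L, epochs = 400L, beta = 1,
                       seed = 1L, optimizer = c("adam", "sgd"),
                       early_stopping = FALSE, patience = 50L) {
  optimizer <- match.arg(optimizer)
  input_dim <- .check_count(input_dim, "input_dim", lower = 1L)
  latent_dim <- .check_count(latent_dim, "latent_dim", lower = 1L)
  if (length(hidden_dims) != 2L)
    stop("`hidden_dims` must be a pair of hidden-layer widths", call. = FALSE)
  hidden_dims <- c(.check_count(hidden_dims[1], "hidden_dims[1]"),
                   .check_count(hidden_dims[2], "hidden_dims[2]"))
  .check_number(learning_rate, "learning_rate", lower = 1e-12)
  batch_size <- .check_count(batch_size, "batch_size", lower = 1L)
  epochs <- .check_count(epochs, "epochs", lower = 1L)
  .check_number(beta, "beta", lower = 0)
  seed <- .check_count(seed, "seed", lower = 0L)
  patience <- .check_count(patience, "patience", lower = 1L)
  structure(list(input_dim = input_dim, latent_dim = latent_dim,
                 hidden_dims = hidden_dims, learning_rate = learning_rate,
                 batch_size = batch_size, epochs = epochs, beta = beta,
                 seed = seed, optimizer = optimizer,
                 early_stopping = isTRUE(early_stopping), patience = patience),
            class = "vae_config")
}

# one dense layer: weight is (in x out), bias length out
.init_layer <- function(n_in, n_out) {
  bound <- 1 / sqrt(n_in)  # uniform fan-in initialization
  list(W = matrix(stats::runif(n_in * n_out, -bound, bound), n_in, n_out),
       b = stats::runif(n_out, -bound, bound))
}

#' Create an (untrained) VAE model
#'
#' Weights are initialized with a uniform fan-in scheme under the
#' configuration seed, so model creation is fully reproducible.
#'
#' @param config a [vae_config()].
#' @return object of class `ecg_vae` holding parameters, config and an empty
#'   training history.
#' @export
vae <- function(config = vae_config()) {
  if (!inherits(config, "vae_config"))
    stop("`config` must be a vae_config", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)
  h1 <- config$hidden_dims[1]; h2 <- config$hidden_dims[2]
  d <- config$input_dim; L <- config$latent_dim
  params <- list(
    enc1 = .init_layer(d, h1),
    enc2 = .init_layer(h1, h2),
    enc3 = .init_layer(h2, 2L * L),
    dec1 = .init_layer(L, h2),
    dec2 = .init_layer(h2, h1),
    dec3 = .init_layer(h1, d)
  )
  structure(list(params = params, config = config,
                 history = data.frame(epoch = integer(), total = numeric(),
                                      recon = numeric(), kl = numeric()),
                 trained = FALSE),
            class = "ecg_vae")
}

#' @export
print.ecg_vae <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Fully-connected VAE: %d -> %d -> %d -> (mu, log_var) x %d, %strained\n",
    cfg$input_dim, cfg$hidden_dims[1], cfg$hidden_dims[2], cfg$latent_dim,
    if (x$trained) "" else "un"))
  if (nrow(x$history) > 0)
    cat(sprintf("last epoch %d: total %.6g (recon %.6g, kl %.6g)\n",
                max(x$history$epoch), utils::tail(x$history$total, 1),
                utils::tail(x$history$recon, 1), utils::tail(x$history$kl, 1)))
  invisible(x)
}

.affine <- function(X, layer) {
  sweep(X %*% layer$W, 2L, layer$b, `+`)
}

#' Encode signals to latent posterior statistics
#'
#' Deterministic forward pass through the encoder. The final layer's output
#' is split into the posterior mean `mu` and log-variance `log_var`.
#'
#' @param model an `ecg_vae`.
#' @param x numeric vector (one signal) or matrix (one signal per row) of
#'   width `input_dim`.
#' @return object of class `latent_stats`: list of matrices `mu` and
#'   `log_var`, one row per input signal.
#' @export
vae_encode <- function(model, x) {
  stopifnot(inherits(model, "ecg_vae"))
  X <- .as_signal_matrix(x)
  if (ncol(X) != model$config$input_dim)
    stop(sprintf("input width %d does not match input_dim %d",
                 ncol(X), model$config$input_dim), call. = FALSE)
  p <- model$params
  H1 <- pmax(.affine(X, p$enc1), 0)
  H2 <- pmax(.affine(H1, p$enc2), 0)
  S <- .affine(H2, p$enc3)
  L <- model$config$latent_dim
  structure(list(mu = S[, seq_len(L), drop = FALSE],
                 log_var = S[, L + seq_len(L), drop = FALSE]),
            class = "latent_stats")
}

.as_stats <- function(stats) {
  if (!inherits(stats, "latent_stats")) {
    if (is.list(stats) && !is.null(stats$mu) && !is.null(stats$log_var))
      stats <- structure(list(mu = .as_signal_matrix(stats$mu),
                              log_var = .as_signal_matrix(stats$log_var)),
                         class = "latent_stats")
    else stop("`stats` must be a latent_stats object", call. = FALSE)
  }
  stats$mu <- .as_signal_matrix(stats$mu)
  stats$log_var <- .as_signal_matrix(stats$log_var)
  if (!all(dim(stats$mu) == dim(stats$log_var)))
    stop("`mu` and `log_var` must have equal dimensions", call. = FALSE)
  if (!all(is.finite(stats$mu)) || !all(is.finite(stats$log_var)))
    stop("latent statistics must be finite", call. = FALSE)
  stats
}

#' Reparameterization: draw a latent variable
#'
#' Computes `z = mu + epsilon * exp(0.5 * log_var)` element-wise. With
#' `epsilon = 0` this returns `mu` exactly.
#'
#' @param stats `latent_stats` (or list with `mu` and `log_var`).
#' @param epsilon standard-normal draw: a scalar (recycled), a vector/matrix
#'   matching `mu`, or `NULL` to draw from N(0, I).
#' @param seed optional seed used when `epsilon` is drawn internally.
#' @return matrix of latent vectors, one row per signal.
#' @export
vae_reparameterize <- function(stats, epsilon = NULL, seed = NULL) {
  stats <- .as_stats(stats)
  dm <- dim(stats$mu)
  if (is.null(epsilon)) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(as.integer(seed))
    }
    epsilon <- matrix(stats::rnorm(prod(dm)), dm[1], dm[2])
  } else if (length(epsilon) == 1L) {
    epsilon <- matrix(epsilon, dm[1], dm[2])
  } else {
    epsilon <- .as_signal_matrix(epsilon, "epsilon")
    if (!all(dim(epsilon) == dm))
      stop("`epsilon` must match the dimensions of `mu`", call. = FALSE)
  }
  stats$mu + epsilon * exp(0.5 * stats$log_var)
}

#' Decode latent vectors to reconstructed signals
#'
#' @param model an `ecg_vae`.
#' @param z numeric vector (one latent point) or matrix (one per row) of
#'   width `latent_dim`.
#' @return matrix of reconstructions, one row per latent point.
#' @export
vae_decode <- function(model, z) {
  stopifnot(inherits(model, "ecg_vae"))
  Z <- .as_signal_matrix(z, "z")
  if (ncol(Z) != model$config$latent_dim)
    stop(sprintf("latent width %d does not match latent_dim %d",
                 ncol(Z), model$config$latent_dim), call. = FALSE)
  p <- model$params
  D1 <- pmax(.affine(Z, p$dec1), 0)
  D2 <- pmax(.affine(D1, p$dec2), 0)
  .affine(D2, p$dec3)
}

#' Deterministic reconstruction of a signal
#'
#' Encodes `x` and decodes at the posterior mean (`epsilon = 0` draw).
#'
#' @inheritParams vae_encode
#' @param epsilon reparameterization draw, default 0 (decode at the mean).
#' @return numeric vector (single signal input) or matrix of reconstructions.
#' @export
vae_reconstruct <- function(model, x, epsilon = 0) {
  st <- vae_encode(model, x)
  out <- vae_decode(model, vae_reparameterize(st, epsilon = epsilon))
  if (is.null(dim(x)) && nrow(out) == 1L) out <- drop(out)
  out
}

#' Gaussian KL divergence to the standard-normal prior
#'
#' Closed form `-0.5 * sum(1 + log_var - mu^2 - exp(log_var))` per signal,
#' averaged over the batch when `stats` holds several rows. Nonnegative up to
#' floating-point round-off.
#'
#' @param stats `latent_stats` (vectors or one row per signal).
#' @return single nonnegative number.
#' @export
kl_divergence <- function(stats) {
  stats <- .as_stats(stats)
  per_row <- -0.5 * rowSums(1 + stats$log_var - stats$mu^2 - exp(stats$log_var))
  mean(per_row)
}

#' VAE training loss
#'
#' `total = recon + beta * kl` where `recon` is the mean squared error over
#' all samples and `kl` is the Gaussian KL divergence (summed over latent
#' dimensions, averaged over the batch).
#'
#' @param x input signals (vector or matrix).
#' @param x_hat reconstructions, same shape.
#' @param stats `latent_stats` for the batch.
#' @param beta KL weight.
#' @return list with `total`, `recon`, `kl`.
#' @export
vae_loss <- function(x, x_hat, stats, beta = 1) {
  X <- .as_signal_matrix(x); Xh <- .as_signal_matrix(x_hat, "x_hat")
  if (!all(dim(X) == dim(Xh)))
    stop("`x` and `x_hat` must have equal dimensions", call. = FALSE)
  .check_number(beta, "beta", lower = 0)
  recon <- mean((X - Xh)^2)
  kl <- kl_divergence(stats)
  list(total = recon + beta * kl, recon = recon, kl = kl)
}

#' Train a VAE
#'
#' Minibatch training with manually derived gradients of the reconstruction
#' + KL objective, using Adam (default) or plain SGD. Fully deterministic
#' under the configuration seed: shuffling and reparameterization draws come
#' from a private RNG stream.
#'
#' @param model an `ecg_vae` (untrained or to be trained further).
#' @param x_train matrix of training signals, one per row.
#' @param x_val optional matrix of validation signals (required for early
#'   stopping).
#' @param epochs number of epochs; defaults to the model configuration.
#' @param verbose print a line every 50 epochs.
#' @return the trained model; `model$history` holds per-epoch total,
#'   reconstruction and KL losses (plus `val_total` when validation data are
#'   given).
#' @export
vae_train <- function(model, x_train, x_val = NULL, epochs = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(model, "ecg_vae"))
  X <- .as_signal_matrix(x_train, "x_train")
  if (nrow(X) == 0L) stop("training set is empty", call. = FALSE)
  cfg <- model$config
  if (ncol(X) != cfg$input_dim)
    stop("training signal width does not match input_dim", call. = FALSE)
  if (!is.null(x_val)) x_val <- .as_signal_matrix(x_val, "x_val")
  epochs <- if (is.null(epochs)) cfg$epochs else .check_count(epochs, "epochs")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(.child_seed(cfg$seed, 104729))

  p <- model$params
  L <- cfg$latent_dim
  beta <- cfg$beta
  lr <- cfg$learning_rate
  n <- nrow(X)
  use_adam <- cfg$optimizer == "adam"
  if (use_adam) {
    zeros_like <- function(pp) lapply(pp, function(l) list(W = l$W * 0, b = l$b * 0))
    m1 <- zeros_like(p); m2 <- zeros_like(p); tstep <- 0
    b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  }

  hist_total <- hist_recon <- hist_kl <- hist_val <- numeric(epochs)
  best_val <- Inf; wait <- 0L; done <- epochs

  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    ep_tot <- ep_rec <- ep_kl <- 0
    for (s in starts) {
      idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      B <- nrow(Xb); d <- ncol(Xb)

      # forward
      A1 <- .affine(Xb, p$enc1); H1 <- pmax(A1, 0)
      A2 <- .affine(H1, p$enc2); H2 <- pmax(A2, 0)
      S <- .affine(H2, p$enc3)
      mu <- S[, seq_len(L), drop = FALSE]
      lv <- S[, L + seq_len(L), drop = FALSE]
      sig <- exp(0.5 * lv)
      eps <- matrix(stats::rnorm(B * L), B, L)
      Z <- mu + eps * sig
      C1 <- .affine(Z, p$dec1); D1 <- pmax(C1, 0)
      C2 <- .affine(D1, p$dec2); D2 <- pmax(C2, 0)
      Xh <- .affine(D2, p$dec3)

      recon <- mean((Xh - Xb)^2)
      kl <- mean(-0.5 * rowSums(1 + lv - mu^2 - exp(lv)))
      tot <- recon + beta * kl
      if (!is.finite(tot))
        stop(sprintf("non-finite loss at epoch %d (recon %g, kl %g); reduce the learning rate",
                     ep, recon, kl), call. = FALSE)
      w <- B / n
      ep_tot <- ep_tot + tot * w; ep_rec <- ep_rec + recon * w
      ep_kl <- ep_kl + kl * w

      # backward
      dXh <- 2 * (Xh - Xb) / (B * d)
      g <- list()
      g$dec3 <- list(W = crossprod(D2, dXh), b = colSums(dXh))
      dD2 <- tcrossprod(dXh, p$dec3$W) * (C2 > 0)
      g$dec2 <- list(W = crossprod(D1, dD2), b = colSums(dD2))
      dD1 <- tcrossprod(dD2, p$dec2$W) * (C1 > 0)
      g$dec1 <- list(W = crossprod(Z, dD1), b = colSums(dD1))
      dZ <- tcrossprod(dD1, p$dec1$W)
      dmu <- dZ + beta * mu / B
      dlv <- dZ * eps * 0.5 * sig + beta * 0.5 * (exp(lv) - 1) / B
      dS <- cbind(dmu, dlv)
      g$enc3 <- list(W = crossprod(H2, dS), b = colSums(dS))
      dH2 <- tcrossprod(dS, p$enc3$W) * (A2 > 0)
      g$enc2 <- list(W = crossprod(H1, dH2), b = colSums(dH2))
      dH1 <- tcrossprod(dH2, p$enc2$W) * (A1 > 0)
      g$enc1 <- list(W = crossprod(Xb, dH1), b = colSums(dH1))

      if (use_adam) {
        tstep <- tstep + 1
        corr1 <- 1 - b1^tstep; corr2 <- 1 - b2^tstep
        for (nm in names(p)) {
          for (q in c("W", "b")) {
            m1[[nm]][[q]] <- b1 * m1[[nm]][[q]] + (1 - b1) * g[[nm]][[q]]
            m2[[nm]][[q]] <- b2 * m2[[nm]][[q]] + (1 - b2) * g[[nm]][[q]]^2
            p[[nm]][[q]] <- p[[nm]][[q]] -
              lr * (m1[[nm]][[q]] / corr1) / (sqrt(m2[[nm]][[q]] / corr2) + aeps)
          }
        }
      } else {
        for (nm in names(p))
          for (q in c("W", "b"))
            p[[nm]][[q]] <- p[[nm]][[q]] - lr * g[[nm]][[q]]
      }
    }
    hist_total[ep] <- ep_tot; hist_recon[ep] <- ep_rec; hist_kl[ep] <- ep_kl

    if (!is.null(x_val)) {
      model$params <- p
      st <- vae_encode(model, x_val)
      xh <- vae_decode(model, vae_reparameterize(st, epsilon = 0))
      vl <- vae_loss(x_val, xh, st, beta = beta)$total
      hist_val[ep] <- vl
      if (cfg$early_stopping) {
        if (vl < best_val - 1e-12) { best_val <- vl; wait <- 0L }
        else {
          wait <- wait + 1L
          if (wait >= cfg$patience) { done <- ep; break }
        }
      }
    }
    if (verbose && ep %% 50L == 0L)
      message(sprintf("epoch %4d  total %.6g  recon %.6g  kl %.6g",
                      ep, ep_tot, ep_rec, ep_kl))
  }

  model$params <- p
  keep <- seq_len(done)
  h <- data.frame(epoch = keep, total = hist_total[keep],
                  recon = hist_recon[keep], kl = hist_kl[keep])
  if (!is.null(x_val)) h$val_total <- hist_val[keep]
  model$history <- h
  model$trained <- TRUE
  model
}

#' Save or load a VAE checkpoint
#'
#' The checkpoint is a serialized container holding parameters, configuration
#' (seed included) and training history.
#'
#' @param model an `ecg_vae`.
#' @param path file path.
#' @return `vae_save` returns `path` invisibly; `vae_load` returns the model.
#' @export
vae_save <- function(model, path) {
  stopifnot(inherits(model, "ecg_vae"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname vae_save
#' @export
vae_load <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ecg_vae"))
    stop("file does not contain a VAE checkpoint", call. = FALSE)
  model
}
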