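# shared fixtures and independent oracles, built in code at test time

.fixtures <- new.env(parent = emptyenv())

# one converged model on noiseless data, trained once per test run
trained_fixture <- function() {
  if (is.null(.fixtures$run)) {
    ds <- generate_dataset(n_signals = 200, noise_factor = 0, seed = 7)
    model <- vae_train(vae(vae_config(seed = 7, epochs = 200)), ds$train)
    .fixtures$run <- list(ds = ds, model = model,
                          x = ds$train[1, ],
                          recon = vae_reconstruct(model, ds$train[1, ]))
  }
  .fixtures$run
}

# a tiny model whose parameters tests may overwrite
tiny_model <- function(input_dim = 8L, latent_dim = 3L) {
  vae(vae_config(input_dim = input_dim, latent_dim = latent_dim,
                 hidden_dims = c(6L, 5L), seed = 42))
}

zero_params <- function(model) {
  model$params <- lapply(model$params, function(l)
    list(W = l$W * 0, b = l$b * 0))
  model
}

# DTW oracle: enumerate every monotone warping path and take the cheapest.
# Independent of the dynamic-programming implementation under test.
dtw_enumerate <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible(NULL))
    }
    if (i < n) walk(i + 1L, j, acc)
    if (j < m) walk(i, j + 1L, acc)
    if (i < n && j < m) walk(i + 1L, j + 1L, acc)
  }
  walk(1L, 1L, 0)
  best
}

# all signals of length 1..max_len over the alphabet
enumerate_signals <- function(alphabet = 0:2, max_len = 3L) {
  out <- list()
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    for (r in seq_len(nrow(grid)))
      out[[length(out) + 1L]] <- as.numeric(grid[r, ])
  }
  out
}
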