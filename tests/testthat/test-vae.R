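test_that("encoder and decoder are deterministic shape-checked maps", {
  m <- tiny_model()

  z <- zero_params(m)
  st <- vae_encode(z, rep(0.5, 8))
  expect_equal(as.numeric(st$mu), rep(0, 3))
  expect_equal(as.numeric(st$log_var), rep(0, 3))
  expect_equal(as.numeric(vae_decode(z, c(1, -1, 2))), rep(0, 8))

  x <- matrix(rnorm(32 * 8, 0, 0.3), 32, 8)
  st1 <- vae_encode(m, x)
  st2 <- vae_encode(m, x)
  expect_identical(st1, st2)
  expect_equal(dim(st1$mu), c(32L, 3L))
  expect_equal(dim(st1$log_var), c(32L, 3L))

  zz <- matrix(rnorm(4 * 3), 4, 3)
  expect_identical(vae_decode(m, zz), vae_decode(m, zz))
  expect_error(vae_encode(m, rep(0, 7)), "input width")
  expect_error(vae_decode(m, rep(0, 4)), "latent width")
})

test_that("reparameterization follows z = mu + eps * exp(log_var / 2)", {
  st <- list(mu = c(1, -1), log_var = c(log(4), log(4)))
  expect_equal(as.numeric(vae_reparameterize(st, epsilon = c(0.5, 0.5))),
               c(2, 0))
  expect_equal(as.numeric(vae_reparameterize(st, epsilon = 0)), c(1, -1))
  st0 <- list(mu = c(0.3, 0.7), log_var = c(0, 0))
  e <- c(-1.2, 0.4)
  expect_equal(as.numeric(vae_reparameterize(st0, epsilon = e)),
               c(0.3, 0.7) + e)
  expect_identical(vae_reparameterize(st, seed = 21),
                   vae_reparameterize(st, seed = 21))
})

test_that("KL closed form matches values, nonnegativity and Monte Carlo", {
  expect_equal(kl_divergence(list(mu = c(0, 0), log_var = c(0, 0))), 0)
  expect_equal(kl_divergence(list(mu = 1, log_var = 0)), 0.5)

  set.seed(8)
  for (i in 1:50) {
    st <- list(mu = rnorm(4), log_var = rnorm(4, 0, 0.7))
    expect_gte(kl_divergence(st), -1e-12)
  }

  # oracle: E_q[log q(z) - log p(z)] by simulation on 2-dim stats
  mu <- c(0.8, -0.4); lv <- c(log(0.5), log(2))
  sd_ <- exp(0.5 * lv)
  set.seed(123)
  n_draw <- 1e5
  z1 <- rnorm(n_draw, mu[1], sd_[1]); z2 <- rnorm(n_draw, mu[2], sd_[2])
  lq <- dnorm(z1, mu[1], sd_[1], log = TRUE) + dnorm(z2, mu[2], sd_[2], log = TRUE)
  lp <- dnorm(z1, log = TRUE) + dnorm(z2, log = TRUE)
  diff <- lq - lp
  mc <- mean(diff); se <- sd(diff) / sqrt(n_draw)
  expect_lt(abs(kl_divergence(list(mu = mu, log_var = lv)) - mc), 3 * se)
})

test_that("loss composes reconstruction and weighted KL", {
  x <- matrix(rnorm(20), 4, 5)
  st0 <- list(mu = matrix(0, 4, 2), log_var = matrix(0, 4, 2))
  l <- vae_loss(x, x, st0, beta = 1)
  expect_equal(unlist(l), c(total = 0, recon = 0, kl = 0))

  xh <- x + 0.1
  st <- list(mu = matrix(0.5, 4, 2), log_var = matrix(0.2, 4, 2))
  l0 <- vae_loss(x, xh, st, beta = 0)
  expect_equal(l0$total, l0$recon)
  l2 <- vae_loss(x, xh, st, beta = 2)
  expect_equal(l2$total, l2$recon + 2 * l2$kl)
  expect_equal(l2$recon, mean((x - xh)^2))
})

test_that("training descends, is reproducible and records history", {
  ds <- generate_dataset(n_signals = 100, noise_factor = 0, seed = 31)
  cfg <- vae_config(seed = 31, epochs = 50)

  m1 <- vae_train(vae(cfg), ds$train)
  expect_equal(nrow(m1$history), 50)
  expect_lt(tail(m1$history$recon, 1), m1$history$recon[1])
  expect_lt(mean(tail(m1$history$total, 10)), mean(head(m1$history$total, 10)))

  # identical seed, identical parameters and loss curve
  m2 <- vae_train(vae(cfg), ds$train)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)

  # smoothed loss curve declines smoothly on noiseless data: any residual
  # uptick of the 10-epoch moving average stays within 2% of its level
  run <- trained_fixture()
  sm <- stats::filter(run$model$history$total, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 0.02 * pmax(sm[-length(sm)], 1e-12)))
  expect_lt(sm[length(sm)], 0.05 * sm[1])

  expect_error(vae_train(vae(cfg), ds$train[0, , drop = FALSE]), "empty")
})

test_that("a converged model reconstructs noiseless beats closely", {
  run <- trained_fixture()
  expect_lt(mse(run$x, run$recon), 1e-2)
  # reconstruction at the mean equals decode(reparameterize(encode, 0))
  st <- vae_encode(run$model, run$x)
  manual <- vae_decode(run$model, vae_reparameterize(st, epsilon = 0))
  expect_equal(as.numeric(manual), as.numeric(run$recon))
})

test_that("early stopping halts on a stalled validation loss", {
  ds <- generate_dataset(n_signals = 100, noise_factor = 0, seed = 13)
  cfg <- vae_config(seed = 13, epochs = 120, early_stopping = TRUE,
                    patience = 10)
  m <- vae_train(vae(cfg), ds$train, x_val = ds$val)
  expect_true("val_total" %in% names(m$history))
  expect_lte(nrow(m$history), 120)
})

test_that("checkpoints round-trip through disk", {
  m <- tiny_model()
  path <- withr::local_tempfile(fileext = ".rds")
  vae_save(m, path)
  m2 <- vae_load(path)
  expect_identical(m$params, m2$params)
  expect_identical(m$config, m2$config)
})
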