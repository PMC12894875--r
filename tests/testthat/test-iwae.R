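ns <- asNamespace("crossmet")

test_that("config validation enforces the contract", {
  expect_error(iwae_config(K = 0), "K")
  expect_error(iwae_config(value_mask_rate = 0, target_mask_rate = 0),
               "vacuous")
  expect_error(iwae_config(value_mask_rate = 1), "value_mask_rate")
  expect_silent(iwae_config(target_mask_rate = 1))  # closed at 1 by design
  expect_error(iwae_config(hidden = c(8, 8, 8, 8)), "hidden")
  expect_error(iwae_config(patience = 25), "patience")
  expect_error(iwae_config(dropout_rate = 1), "dropout")
})

test_that("analytic gradients match finite differences", {
  set.seed(40)
  B <- 5; D <- 4
  x <- matrix(rnorm(B * D), B, D)
  vis <- matrix(rbinom(B * D, 1, 0.8), B, D)
  lm_ <- matrix(rbinom(B * D, 1, 0.9), B, D)
  for (loss in c("gaussian", "mse")) for (bn in c(FALSE, TRUE)) {
    cfg <- iwae_config(latent_dim = 2, hidden = c(6, 5), K = 3,
                       loss = loss, batch_norm = bn,
                       value_mask_rate = 0.2, seed = 40)
    par <- ns$.init_params(D, cfg)
    bns <- ns$.init_bn_state(par)
    eps <- lapply(1:3, function(k) matrix(rnorm(B * 2), B, 2))
    st <- ns$.iwae_step(par, x, vis, lm_, cfg, bns, training = TRUE,
                        eps_list = eps)
    th <- unlist(par); g <- unlist(st$grads)
    idx <- sample(length(th), 25)
    fd <- vapply(idx, function(i) {
      h <- 1e-5
      up <- th; up[i] <- up[i] + h
      dn <- th; dn[i] <- dn[i] - h
      (ns$.iwae_step(utils::relist(up, par), x, vis, lm_, cfg, bns,
                     training = TRUE, eps_list = eps,
                     want_grads = FALSE)$loss -
         ns$.iwae_step(utils::relist(dn, par), x, vis, lm_, cfg, bns,
                       training = TRUE, eps_list = eps,
                       want_grads = FALSE)$loss) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(fd - g[idx])), 1e-6)
  }
})

test_that("K = 1 bound equals an independently computed ELBO", {
  m <- tiny_model(D = 4, latent_dim = 2, hidden = 5L, seed = 51)
  set.seed(52)
  x <- matrix(rnorm(6 * 4), 6, 4)
  x[cbind(c(1, 3), c(2, 4))] <- NA
  bound <- iw_lower_bound(m, x, K = 1, seed = 99)
  # independent path: explicit forward pass in plain R
  obs <- !is.na(x); x0 <- x; x0[!obs] <- 0
  enc_in <- cbind(x0 * obs, obs * 1)
  p <- m$par
  h1 <- tanh(sweep(enc_in %*% p$enc$body[[1]]$W, 2, p$enc$body[[1]]$b, "+"))
  mu <- sweep(h1 %*% p$enc$mu$W, 2, p$enc$mu$b, "+")
  ls <- pmin(pmax(sweep(h1 %*% p$enc$ls$W, 2, p$enc$ls$b, "+"), -5), 3)
  set.seed(99)                       # same draw stream as iw_lower_bound
  eps <- matrix(rnorm(6 * 2), 6, 2)
  z <- mu + exp(ls) * eps
  d1 <- tanh(sweep(z %*% p$dec$body[[1]]$W, 2, p$dec$body[[1]]$b, "+"))
  mux <- sweep(d1 %*% p$dec$out$W, 2, p$dec$out$b, "+")
  lv <- pmin(pmax(p$logvar, -6), 3)
  ll <- rowSums(-0.5 * (sweep((x0 - mux)^2 * obs, 2, exp(-lv), "*") +
                          sweep(obs, 2, lv + log(2 * pi), "*")))
  elbo <- ll + rowSums(-0.5 * z^2 - 0.5 * log(2 * pi)) -
    rowSums(-0.5 * eps^2 - ls - 0.5 * log(2 * pi))
  expect_equal(bound, elbo, tolerance = 1e-6)
})

test_that("the bound is monotone non-decreasing in K (Monte Carlo)", {
  m <- tiny_model(D = 5, latent_dim = 2, hidden = 6L, seed = 53)
  set.seed(54)
  b1 <- b20 <- numeric(200)
  for (i in 1:200) {
    x <- matrix(rnorm(10 * 5), 10, 5)
    b1[i] <- mean(iw_lower_bound(m, x, K = 1, seed = 1000 + i))
    b20[i] <- mean(iw_lower_bound(m, x, K = 20, seed = 3000 + i))
  }
  expect_gte(mean(b20), mean(b1))
})

test_that("with everything hidden the bound is the log-mean prior/posterior ratio", {
  m <- tiny_model(D = 4, latent_dim = 2, hidden = 5L, seed = 55)
  x <- matrix(NA_real_, 5, 4)        # nothing observed
  K <- 7
  bound <- iw_lower_bound(m, x, K = K, seed = 7)
  p <- m$par
  enc_in <- matrix(0, 5, 8)
  h1 <- tanh(sweep(enc_in %*% p$enc$body[[1]]$W, 2, p$enc$body[[1]]$b, "+"))
  mu <- sweep(h1 %*% p$enc$mu$W, 2, p$enc$mu$b, "+")
  ls <- pmin(pmax(sweep(h1 %*% p$enc$ls$W, 2, p$enc$ls$b, "+"), -5), 3)
  set.seed(7)
  logr <- sapply(1:K, function(k) {
    eps <- matrix(rnorm(5 * 2), 5, 2)
    z <- mu + exp(ls) * eps
    rowSums(-0.5 * z^2) - rowSums(-0.5 * eps^2 - ls)
  })
  expect_equal(bound,
               apply(logr, 1, function(r) {
                 mx <- max(r); mx + log(mean(exp(r - mx)))
               }),
               tolerance = 1e-8)
})

test_that("iw_lower_bound validates masks and K", {
  m <- tiny_model()
  x <- matrix(rnorm(12), 3, 4)
  x[1, 1] <- NA
  bad <- matrix(FALSE, 3, 4); bad[1, 1] <- TRUE   # masks a missing entry
  expect_error(iw_lower_bound(m, x, train_mask = bad), "subset")
  expect_error(iw_lower_bound(m, x, K = 0), "K")
})

test_that("training is deterministic given the seed", {
  fit <- shared_linear_fit()
  ss <- fit$ss
  cfg <- iwae_config(latent_dim = 3, hidden = 16L, K = 2, L = 10,
                     value_mask_rate = 0.2, target_mask_rate = 0.5,
                     max_epochs = 8, patience = 5, seed = 77)
  m1 <- train_iwae(ss$train, ss$val, ss$target_features, cfg)
  m2 <- train_iwae(ss$train, ss$val, ss$target_features, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$par, m2$par)
})

test_that("early stopping halts before max_epochs on a tiny overfitting run", {
  set.seed(60)
  n <- 26; D <- 10
  x <- matrix(rnorm(n * D), n, D, dimnames = list(NULL, paste0("f", 1:D)))
  xv <- matrix(rnorm(12 * D), 12, D, dimnames = list(NULL, paste0("f", 1:D)))
  cfg <- iwae_config(latent_dim = 4, hidden = 32L, K = 2, L = 5,
                     value_mask_rate = 0.3, target_mask_rate = 0.5,
                     max_epochs = 500, patience = 10, val_L = 5, seed = 60)
  m <- train_iwae(x, xv, paste0("f", 1:4), cfg)
  expect_lt(m$stopped_epoch, 500)
  expect_lte(m$best_val_error,
             m$history$val_error[nrow(m$history)] + 1e-12)
  expect_identical(m$best_val_error, min(m$history$val_error))
})

test_that("noise-free loading-1 cohort is imputed with R2 > 0.95 per target", {
  co <- generate_cohort(cohort_config(
    n_samples = 400, n_classes = 2, n_input_per_class = 15,
    n_target_per_class = 8, latent_dim = 2, cross_platform_loading = 1,
    noise_sd = 0, seed = 12))
  ss <- scaled_split(co, seed = 12)
  m <- train_iwae(ss$train, ss$val, ss$target_features,
                  iwae_config(latent_dim = 4, hidden = c(48, 24), K = 5,
                              L = 50, value_mask_rate = 0.2,
                              target_mask_rate = 0.5, loss = "gaussian",
                              max_epochs = 400, patience = 20, seed = 12))
  xh <- ss$test; xh[, ss$target_features] <- NA
  imp <- iwae_impute(m, xh, seed = 1)
  r2 <- vapply(ss$target_features,
               function(f) stats::cor(imp[, f], ss$test[, f])^2, numeric(1))
  expect_gt(min(r2), 0.95)
})

test_that("imputation passes observed entries through and inverts the scaler", {
  fit <- shared_linear_fit()
  ss <- fit$ss
  x <- ss$test
  x[, ss$target_features] <- NA
  x[3, ss$target_features[1]] <- 0.25   # one observed target entry
  imp <- iwae_impute(fit$model, x, seed = 2)
  keep <- !is.na(x)
  expect_identical(imp[keep], x[keep])
  inv <- scaler_inverse_transform(imp, ss$scaler)
  # observed input values return to original units
  orig <- cbind(fit$cohort$input_matrix$values,
                fit$cohort$target_matrix$values)[ss$split$test_ids, ]
  inr <- abs(ss$test[, ss$input_features]) < 1  # un-clipped entries
  expect_lt(max(abs((inv[, ss$input_features] -
                       orig[, ss$input_features])[inr])), 1e-8)
})

test_that("L = 50 imputation beats L = 1 on average (variance reduction)", {
  fit <- shared_linear_fit()
  ss <- fit$ss
  xh <- ss$test; xh[, ss$target_features] <- NA
  truth <- ss$test[, ss$target_features]
  mse <- function(L, s) {
    imp <- iwae_impute(fit$model, xh, L = L, seed = s)
    mean((imp[, ss$target_features] - truth)^2)
  }
  m1 <- vapply(1:20, function(s) mse(1, s), numeric(1))
  m50 <- vapply(1:20, function(s) mse(50, 400 + s), numeric(1))
  expect_lt(mean(m50), mean(m1))
})

test_that("grid search returns the single config trivially and prefers capacity", {
  fit <- shared_linear_fit()
  ss <- fit$ss
  solo <- iwae_config(latent_dim = 3, hidden = 16L, K = 2, L = 10,
                      value_mask_rate = 0.3, target_mask_rate = 0.5,
                      max_epochs = 10, patience = 5, val_L = 5, seed = 81)
  g1 <- iwae_grid_search(ss$train, ss$val, ss$target_features,
                         list(solo), refine = FALSE)
  expect_identical(g1$best_config, solo)
  expect_identical(nrow(g1$leaderboard), 1L)
  crippled <- iwae_config(latent_dim = 1, hidden = 2L, K = 2, L = 10,
                          value_mask_rate = 0.3, target_mask_rate = 0.5,
                          max_epochs = 30, patience = 5, val_L = 5,
                          seed = 81)
  able <- iwae_config(latent_dim = 6, hidden = c(32, 16), K = 3, L = 10,
                      value_mask_rate = 0.2, target_mask_rate = 0.5,
                      max_epochs = 60, patience = 10, val_L = 5, seed = 81)
  g2 <- iwae_grid_search(ss$train, ss$val, ss$target_features,
                         list(crippled, able), refine = FALSE)
  expect_identical(g2$best_config$latent_dim, 6L)
  expect_error(iwae_grid_search(ss$train, ss$val, ss$target_features,
                                list()), "empty")
})

test_that("mix-up, dropout and batch norm train without diverging", {
  fit <- shared_linear_fit()
  ss <- fit$ss
  cfg <- iwae_config(latent_dim = 3, hidden = 16L, K = 2, L = 5,
                     value_mask_rate = 0.2, target_mask_rate = 0.5,
                     mixup_alpha = 0.2, dropout_rate = 0.2,
                     batch_norm = TRUE, max_epochs = 10, patience = 5,
                     val_L = 5, seed = 90)
  m <- train_iwae(ss$train, ss$val, ss$target_features, cfg)
  expect_true(all(is.finite(m$history$train_loss)))
  expect_true(all(is.finite(m$history$val_error)))
})

test_that("the default grid exposes the documented axes", {
  g <- default_iwae_grid()
  expect_identical(nrow(g), 432L)
  expect_setequal(unique(g$target_mask_rate), c(0.25, 0.5, 1.0))
  expect_setequal(unique(g$loss), c("gaussian", "mse", "mae"))
})
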