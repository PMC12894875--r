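# shared fixtures and small oracles, all built in code

# scaled train/val/test matrices (plus ids and scaler) from a cohort
scaled_split <- function(cohort, seed = 1L) {
  sp <- split_samples(cohort$input_matrix$sample_ids, seed = seed)
  allpm <- platform_matrix(cbind(cohort$input_matrix$values,
                                 cohort$target_matrix$values),
                           platform = "both")
  sc <- fit_scaler(allpm, train_ids = sp$train_ids)
  xs <- scaler_transform(allpm, sc)$values
  list(train = xs[sp$train_ids, , drop = FALSE],
       val = xs[sp$val_ids, , drop = FALSE],
       test = xs[sp$test_ids, , drop = FALSE],
       all = xs, split = sp, scaler = sc,
       input_features = cohort$input_matrix$feature_ids,
       target_features = cohort$target_matrix$feature_ids)
}

# least-squares oracle: fit target ~ inputs on train, predict on test.
# Aliased (collinear) coefficients are zeroed: the pivoted QR solution is
# still a valid least-squares predictor.
ols_oracle_predict <- function(train, test, input_features,
                               target_features) {
  B <- stats::lm.fit(cbind(1, train[, input_features, drop = FALSE]),
                     train[, target_features, drop = FALSE])$coefficients
  B[is.na(B)] <- 0
  pred <- cbind(1, test[, input_features, drop = FALSE]) %*% B
  colnames(pred) <- target_features
  pred
}

# adjusted Rand index (closed form over the contingency table)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  si <- sum_comb(rowSums(tab)); sj <- sum_comb(colSums(tab))
  exp_idx <- si * sj / choose(n, 2)
  (sum_comb(c(tab)) - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# one small trained model on a linear cohort, built once per test run
.shared_env <- new.env(parent = emptyenv())
shared_linear_fit <- function() {
  if (!is.null(.shared_env$fit)) return(.shared_env$fit)
  co <- generate_cohort(cohort_config(
    n_samples = 300, n_classes = 2, n_input_per_class = 12,
    n_target_per_class = 6, latent_dim = 2,
    cross_platform_loading = 0.8, noise_sd = 0.2, seed = 101))
  ss <- scaled_split(co, seed = 101)
  cfg <- iwae_config(latent_dim = 4, hidden = c(32, 16), K = 3, L = 50,
                     value_mask_rate = 0.2, target_mask_rate = 0.5,
                     loss = "gaussian", max_epochs = 120, patience = 12,
                     seed = 101)
  model <- train_iwae(ss$train, ss$val, ss$target_features, cfg)
  .shared_env$fit <- list(cohort = co, ss = ss, cfg = cfg, model = model)
  .shared_env$fit
}

# tiny random model (untrained) for bound/property checks
tiny_model <- function(D = 4, latent_dim = 2, hidden = 5L, K = 3,
                       loss = "gaussian", batch_norm = FALSE, seed = 5L) {
  cfg <- iwae_config(latent_dim = latent_dim, hidden = hidden, K = K,
                     loss = loss, batch_norm = batch_norm,
                     value_mask_rate = 0.2, target_mask_rate = 0.5,
                     seed = seed)
  ns <- asNamespace("crossmet")
  set.seed(seed)
  par <- ns$.init_params(D, cfg)
  structure(list(config = cfg, par = par,
                 bn_state = ns$.init_bn_state(par),
                 feature_ids = paste0("f", seq_len(D)),
                 target_features = paste0("f", seq_len(D %/% 2))),
            class = "trained_iwae")
}
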