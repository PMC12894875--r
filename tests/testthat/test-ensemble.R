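# cluster assignment taken from the generator's true classes
assignment_from_classes <- function(cohort) {
  md <- cohort$feature_metadata
  cls <- sort(unique(md$class))
  labels <- stats::setNames(match(md$class, cls), md$feature_id)
  structure(list(feature_ids = md$feature_id,
                 coords = matrix(0, nrow(md), 2,
                                 dimnames = list(md$feature_id, NULL)),
                 labels = labels, k = length(cls),
                 cluster_names = stats::setNames(cls,
                                                 seq_along(cls)),
                 silhouette_by_k = NULL),
            class = "cluster_assignment")
}

# small trained ensemble reused across tests (3 classes, 4 models)
ens_fixture <- local({
  fx <- NULL
  function() {
    if (!is.null(fx)) return(fx)
    co <- generate_cohort(cohort_config(
      n_samples = 260, n_classes = 3, n_input_per_class = 10,
      n_target_per_class = 5, latent_dim = 2,
      cross_platform_loading = 0.8, noise_sd = 0.2, seed = 201))
    ss <- scaled_split(co, seed = 201)
    asg <- assignment_from_classes(co)
    cfg <- iwae_config(latent_dim = 4, hidden = 24L, K = 3, L = 20,
                       value_mask_rate = 0.2, target_mask_rate = 0.5,
                       max_epochs = 80, patience = 10, val_L = 10,
                       seed = 201)
    ens <- train_ensemble(ss$train, ss$val, ss$target_features, asg, cfg)
    vm <- validation_metrics(ens, ss$val, metric = "r2", seed = 3)
    sel <- greedy_select(vm)
    fx <<- list(cohort = co, ss = ss, asg = asg, ens = ens, vm = vm,
                sel = sel)
    fx
  }
})

test_that("five clusters yield six trained models", {
  co <- generate_cohort(cohort_config(
    n_samples = 120, n_classes = 5, n_input_per_class = 6,
    n_target_per_class = 3, cross_platform_loading = 0.8,
    noise_sd = 0.2, seed = 205))
  ss <- scaled_split(co, seed = 205)
  cfg <- iwae_config(latent_dim = 2, hidden = 8L, K = 2, L = 5,
                     value_mask_rate = 0.2, target_mask_rate = 0.5,
                     max_epochs = 5, patience = 3, val_L = 3, seed = 205)
  ens <- train_ensemble(ss$train, ss$val, ss$target_features,
                        assignment_from_classes(co), cfg)
  expect_length(ens$models, 6)
  expect_true("all" %in% names(ens$models))
})

test_that("a single cluster makes the cluster and all models see identical data", {
  fx <- ens_fixture()
  co <- fx$cohort
  md <- co$feature_metadata
  asg1 <- assignment_from_classes(co)
  asg1$labels[] <- 1L
  asg1$k <- 1L
  asg1$cluster_names <- c(`1` = "Everything")
  cfg <- iwae_config(latent_dim = 2, hidden = 8L, K = 2, L = 5,
                     value_mask_rate = 0.2, target_mask_rate = 0.5,
                     max_epochs = 3, patience = 3, val_L = 3, seed = 1)
  ens <- train_ensemble(fx$ss$train, fx$ss$val, fx$ss$target_features,
                        asg1, cfg)
  expect_length(ens$models, 2)
  expect_identical(ens$models$Everything$feature_ids,
                   ens$models$all$feature_ids)
})

test_that("cluster-restricted models are no worse than the all model on their class", {
  # classes are mutually independent, so a model restricted to a class's
  # own features loses no information relevant to that class's targets.
  # With only ~26 validation samples the per-class R2 comparison is noisy,
  # so per class a small tolerance is allowed and the class-average
  # dominance is asserted exactly.
  fx <- ens_fixture()
  vm <- fx$vm
  md <- fx$cohort$feature_metadata
  deltas <- vapply(sort(unique(md$class)), function(cc) {
    tg <- md$feature_id[md$class == cc & md$platform == "target"]
    cl_name <- fx$ens$assignment$cluster_names[
      as.character(fx$ens$assignment$labels[tg[1]])]
    mean(vm[tg, cl_name]) - mean(vm[tg, "all"])
  }, numeric(1))
  expect_true(all(deltas > -0.05))
  expect_gt(mean(deltas), 0)
})

test_that("greedy selection is an argmax with cluster-favouring tie-break", {
  metrics <- matrix(c(0.6, 0.4,
                      0.5, 0.5,
                      NA, NA),
                    nrow = 3, byrow = TRUE,
                    dimnames = list(c("m1", "m2", "m3"),
                                    c("ClusterA", "all")))
  attr(metrics, "metric") <- "r2"
  sel <- greedy_select(metrics)
  expect_identical(sel$model[sel$metabolite == "m1"], "ClusterA")
  expect_identical(sel$model[sel$metabolite == "m2"], "ClusterA")
  expect_true(sel$tie[sel$metabolite == "m2"])
  expect_identical(attr(sel, "excluded"), "m3")
  # lower-is-better metric flips the argmax
  attr(metrics, "metric") <- "mae"
  sel2 <- greedy_select(metrics)
  expect_identical(sel2$model[sel2$metabolite == "m1"], "all")
})

test_that("greedy dominance holds on the fitted ensemble", {
  fx <- ens_fixture()
  vm <- fx$vm
  sel <- fx$sel
  for (i in seq_len(nrow(sel))) {
    met <- sel$metabolite[i]
    expect_gte(sel$metric_value[i], max(vm[met, ], na.rm = TRUE) - 1e-12)
  }
  # and per class the selected mean is >= the all-model mean
  md <- fx$cohort$feature_metadata
  for (cc in unique(md$class)) {
    mets <- intersect(sel$metabolite,
                      md$feature_id[md$class == cc])
    if (length(mets) == 0) next
    sel_val <- sel$metric_value[match(mets, sel$metabolite)]
    expect_gte(mean(sel_val), mean(vm[mets, "all"]) - 1e-12)
  }
})

test_that("impute_dataset is seeded, leakage-free and cycle-structured", {
  fx <- ens_fixture()
  x <- fx$ss$test
  a <- impute_dataset(fx$ens, fx$sel, x, n_cycles = 1, seed = 9)
  b <- impute_dataset(fx$ens, fx$sel, x, n_cycles = 1, seed = 9)
  expect_identical(a, b)
  expect_length(impute_dataset(fx$ens, fx$sel, x, n_cycles = 3, seed = 1), 3)
  # permuting observed target truth changes nothing (no leakage)
  x_perm <- x
  x_perm[, fx$ss$target_features] <-
    x_perm[sample(nrow(x_perm)), fx$ss$target_features]
  expect_identical(a, impute_dataset(fx$ens, fx$sel, x_perm, n_cycles = 1,
                                     seed = 9))
  # unknown model / absent features error
  sel_bad <- fx$sel
  sel_bad$model[1] <- "nope"
  expect_error(impute_dataset(fx$ens, sel_bad, x, 1, 1), "nope")
})

test_that("perfect imputation scores perfectly", {
  set.seed(220)
  truth <- matrix(rnorm(40 * 6), 40, 6,
                  dimnames = list(paste0("s", 1:40), paste0("m", 1:6)))
  cycles <- replicate(5, truth, simplify = FALSE)
  ev <- evaluate_imputation(cycles, truth)
  expect_true(all(abs(ev$per_metabolite$baseline_r2 - 1) < 1e-12))
  expect_true(all(ev$per_metabolite$r2_variance == 0))
  expect_true(all(abs(ev$per_sample$spearman_rho - 1) < 1e-12))
})

test_that("independent-noise imputation has null mean R2 about 1/(n-1)", {
  set.seed(221)
  n <- 200; p <- 300
  truth <- matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, paste0("m", 1:p)))
  cycles <- list(matrix(rnorm(n * p), n, p,
                        dimnames = dimnames(truth)))
  ev <- evaluate_imputation(cycles, truth)
  expect_lt(abs(mean(ev$per_metabolite$baseline_r2) - 1 / (n - 1)), 0.002)
})

test_that("cycle statistics are exchangeable and constants are flagged", {
  set.seed(222)
  truth <- matrix(rnorm(30 * 4), 30, 4,
                  dimnames = list(NULL, paste0("m", 1:4)))
  truth[, 4] <- 2                          # constant truth column
  cycles <- replicate(6, truth + matrix(rnorm(120, sd = 0.5), 30, 4),
                      simplify = FALSE)
  ev1 <- evaluate_imputation(cycles, truth)
  perm <- cycles[c(1, 5, 3, 2, 6, 4)]      # cycle 1 fixed, rest permuted
  ev2 <- evaluate_imputation(perm, truth)
  expect_equal(ev1$per_metabolite$mean_r2, ev2$per_metabolite$mean_r2)
  expect_equal(ev1$per_metabolite$r2_variance,
               ev2$per_metabolite$r2_variance)
  expect_true(ev1$per_metabolite$constant_truth[4])
  expect_true(is.na(ev1$per_metabolite$baseline_r2[4]))
})

test_that("well-imputed selection applies the joint rule monotonically", {
  pm <- data.frame(metabolite = paste0("m", 1:4),
                   baseline_r2 = c(0.60, 0.60, 0.50, 0.90),
                   mean_r2 = c(0.6, 0.6, 0.5, 0.9),
                   r2_variance = c(0.01, 0.03, 0.01, 0.02),
                   r2_ss = NA_real_, constant_truth = FALSE,
                   stringsAsFactors = FALSE)
  ev <- structure(list(per_metabolite = pm, per_sample = NULL,
                       n_cycles = 51), class = "imputation_evaluation")
  md <- data.frame(feature_id = c(paste0("m", 1:4), "in1"),
                   platform = c(rep("target", 4), "input"),
                   class = c("Lipid", "Lipid", "Amino acid", "Xeno",
                             "Lipid"),
                   annotation = c("a", "b", "c", "d", "a"),
                   stringsAsFactors = FALSE)
  sw <- select_well_imputed(ev, md)
  expect_setequal(sw$selected, c("m1", "m4"))      # 0.60/0.03 rejected
  expect_identical(sw$n_unique_to_target, 1L)      # m4: annotation d unique
  expect_setequal(sw$unique_to_target, "m4")
  # monotonicity: stricter thresholds never grow the set
  stricter1 <- select_well_imputed(ev, md, r2_min = 0.8)$selected
  stricter2 <- select_well_imputed(ev, md, var_max = 0.015)$selected
  expect_true(all(stricter1 %in% sw$selected))
  expect_true(all(stricter2 %in% sw$selected))
})

test_that("mean R2 and R2 variance are inversely related on the fitted ensemble", {
  fx <- ens_fixture()
  cycles <- impute_dataset(fx$ens, fx$sel, fx$ss$test, n_cycles = 11,
                           seed = 31)
  ev <- evaluate_imputation(cycles,
                            fx$ss$test[, colnames(cycles[[1]]),
                                       drop = FALSE])
  pm <- ev$per_metabolite
  expect_lt(stats::cor(pm$mean_r2, pm$r2_variance, method = "spearman"), 0)
})
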