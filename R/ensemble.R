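#' Train the cluster-wise + all-feature model ensemble
#'
#' Trains one IWAE per cluster, restricted to that cluster's features
#' (both platforms' members), plus one model on all features — k + 1
#' models in total. A cluster with no target-platform member is skipped
#' with a warning (it has nothing to impute). Each model may be tuned
#' independently by passing a grid; with a single config no search is run.
#'
#' @param x_train,x_val scaled (to [-1, 1]) numeric matrices over all
#'   features (colnames required), `NA` for missing.
#' @param target_features character vector naming the target-platform
#'   columns.
#' @param assignment a `cluster_assignment` from [cluster_features()]
#'   covering every column of `x_train`.
#' @param config an [iwae_config()] used for every model, or a list of
#'   configs passed to [iwae_grid_search()] per model.
#' @param verbose print progress.
#' @return object of class `ensemble_model`: list with `models` (named
#'   list of `trained_iwae`, names = cluster names plus `"all"`),
#'   `assignment`, `target_features`.
#' @export
train_ensemble <- function(x_train, x_val, target_features, assignment,
                           config, verbose = FALSE) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  fids <- colnames(x_train)
  if (!all(fids %in% names(assignment$labels)))
    stop("cluster assignment does not cover all features")
  cl_of <- assignment$cluster_names[
    as.character(assignment$labels[fids])]
  fit_one <- function(cols, seed_shift) {
    tf <- intersect(target_features, cols)
    if (is.list(config) && !inherits(config, "iwae_config")) {
      grid <- lapply(config, function(cf) {
        cf$seed <- cf$seed + seed_shift; cf
      })
      iwae_grid_search(x_train[, cols, drop = FALSE],
                       x_val[, cols, drop = FALSE], tf, grid,
                       verbose = verbose)$best_model
    } else {
      cf <- config; cf$seed <- cf$seed + seed_shift
      train_iwae(x_train[, cols, drop = FALSE],
                 x_val[, cols, drop = FALSE], tf, cf, verbose = verbose)
    }
  }
  models <- list()
  cl_names <- unique(cl_of)
  for (i in seq_along(cl_names)) {
    nm <- cl_names[i]
    cols <- fids[cl_of == nm]
    if (!any(cols %in% target_features)) {
      warning("cluster '", nm, "' has no target-platform members; skipped")
      next
    }
    if (verbose) message("training cluster model: ", nm)
    models[[nm]] <- fit_one(cols, seed_shift = i)
  }
  if (verbose) message("training all-feature model")
  models[["all"]] <- fit_one(fids, seed_shift = 0L)
  structure(list(models = models, assignment = assignment,
                 target_features = target_features),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("ensemble_model: %d models (%s)\n", length(x$models),
              paste(names(x$models), collapse = ", ")))
  invisible(x)
}

#' Per-metabolite validation metrics for every candidate model
#'
#' Imputes the validation set once per model with all target columns
#' masked (seeded) and scores each target metabolite under the chosen
#' metric.
#'
#' @param ensemble an [train_ensemble()] result.
#' @param x_val scaled validation matrix over all features, `NA` for
#'   missing.
#' @param metric `"r2"` (squared Pearson correlation, higher better),
#'   `"mae"` or `"mse"` (lower better).
#' @param L importance draws per model (default: each model's config `L`).
#' @param seed seed for the validation imputation.
#' @return numeric matrix: target metabolites x models (NA where a model
#'   does not cover a metabolite).
#' @export
validation_metrics <- function(ensemble, x_val, metric = c("r2", "mae",
                                                           "mse"),
                               L = NULL, seed = 1L) {
  metric <- match.arg(metric)
  tf <- ensemble$target_features
  out <- matrix(NA_real_, length(tf), length(ensemble$models),
                dimnames = list(tf, names(ensemble$models)))
  for (mi in seq_along(ensemble$models)) {
    m <- ensemble$models[[mi]]
    cols <- m$feature_ids
    xv <- x_val[, cols, drop = FALSE]
    xh <- xv
    xh[, m$target_features] <- NA
    imp <- iwae_impute(m, xh, L = L, seed = seed + mi)
    for (f in m$target_features) {
      truth <- xv[, f]
      ok <- !is.na(truth)
      if (sum(ok) < 3) next
      e <- imp[ok, f] - truth[ok]
      out[f, mi] <- switch(metric,
        r2 = if (stats::sd(truth[ok]) == 0 || stats::sd(imp[ok, f]) == 0)
               NA_real_
             else stats::cor(imp[ok, f], truth[ok])^2,
        mae = mean(abs(e)),
        mse = mean(e^2))
    }
  }
  attr(out, "metric") <- metric
  out
}

#' Greedy per-metabolite model selection
#'
#' Picks, for every target metabolite, the candidate model with the best
#' validation metric (highest R-squared or lowest error). Exact ties are
#' broken toward the cluster-specific model (smaller input space); the
#' winning margin is recorded. Metabolites with no finite metric are
#' excluded with a reason.
#'
#' @param metrics matrix from [validation_metrics()] (metabolites x
#'   models, attribute `"metric"`).
#' @return object of class `selection_table`: data.frame with
#'   `metabolite`, `model`, `metric_value`, `margin`, `tie` plus attribute
#'   `"excluded"` (character vector) and `"metric"`.
#' @export
greedy_select <- function(metrics) {
  metric <- attr(metrics, "metric")
  if (is.null(metric)) stop("metrics must carry a 'metric' attribute")
  higher_better <- metric == "r2"
  models <- colnames(metrics)
  rows <- list()
  excluded <- character(0)
  for (f in rownames(metrics)) {
    v <- metrics[f, ]
    fin <- is.finite(v)
    if (!any(fin)) { excluded <- c(excluded, f); next }
    score <- if (higher_better) v else -v
    best_val <- max(score[fin])
    cand <- models[fin & score == best_val]
    tie <- length(cand) > 1
    # tie-break: prefer a cluster model over "all"
    pick <- if (tie && any(cand != "all")) cand[cand != "all"][1]
            else cand[1]
    others <- score[fin & models != pick]
    margin <- if (length(others)) best_val - max(others) else NA_real_
    rows[[f]] <- data.frame(metabolite = f, model = pick,
                            metric_value = v[pick], margin = margin,
                            tie = tie, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("selection_table", "data.frame"),
            excluded = excluded, metric = metric)
}

#' Run repeated imputation cycles over a dataset
#'
#' Each cycle imputes every target metabolite with its selected model
#' using fresh stochastic importance draws, assembles the per-model
#' outputs into one full target matrix, and (optionally) returns values
#' in original units via the inverse scaler. Observed target entries in
#' `x` are never shown to the models: all target columns are masked
#' before encoding, so evaluation-mode truth cannot leak.
#'
#' @param ensemble an [train_ensemble()] result.
#' @param selection a [greedy_select()] table.
#' @param x scaled matrix over all features (target columns may be `NA`
#'   or hold truth for later evaluation; they are ignored as inputs).
#' @param n_cycles number of imputation cycles (51 in the reference
#'   protocol: 1 baseline + 50 uncertainty cycles).
#' @param seed integer seed; cycle c of metabolite-model m uses a
#'   deterministic stream derived from it.
#' @param scaler optional [fit_scaler()] params; when given, returned
#'   matrices are inverse-transformed to original units.
#' @return list of `n_cycles` numeric matrices (samples x selected
#'   metabolites).
#' @export
impute_dataset <- function(ensemble, selection, x, n_cycles = 51L,
                           seed = 1L, scaler = NULL) {
  stopifnot(inherits(selection, "selection_table"))
  mets <- selection$metabolite
  used_models <- unique(selection$model)
  for (mn in used_models) {
    m <- ensemble$models[[mn]]
    if (is.null(m)) stop("selected model not in ensemble: ", mn)
    missing_in <- setdiff(m$feature_ids, colnames(x))
    if (length(missing_in))
      stop("model '", mn, "' needs absent features: ",
           paste(utils::head(missing_in, 5), collapse = ", "))
  }
  cycles <- vector("list", n_cycles)
  for (cy in seq_len(n_cycles)) {
    out <- matrix(NA_real_, nrow(x), length(mets),
                  dimnames = list(rownames(x), mets))
    for (mi in seq_along(used_models)) {
      mn <- used_models[mi]
      m <- ensemble$models[[mn]]
      xm <- x[, m$feature_ids, drop = FALSE]
      xm[, m$target_features] <- NA      # never expose target truth
      imp <- iwae_impute(m, xm, seed = seed + 7919L * cy + mi)
      sel <- mets[selection$model == mn]
      out[, sel] <- imp[, sel, drop = FALSE]
    }
    if (!is.null(scaler))
      out <- scaler_inverse_transform(out, scaler)
    cycles[[cy]] <- out
  }
  cycles
}

#' Score repeated imputation cycles against truth
#'
#' Cycle 1 gives the baseline per-metabolite R-squared (squared Pearson
#' correlation of imputed vs true values over samples, the bounded-[0,1]
#' definition); cycles 2..n give its mean and variance (the uncertainty
#' measure). Per-sample Spearman rank correlation compares the cycle-mean
#' imputed profile (cycles 2..n) with the true profile. Metabolites with
#' constant truth are flagged and excluded from summaries. The 1 -
#' SS_res/SS_tot definition is also reported (`r2_ss`) for reference.
#'
#' @param cycles list of imputed matrices from [impute_dataset()].
#' @param truth numeric matrix with the same samples and (at least) the
#'   imputed metabolites, in the same units as `cycles`.
#' @return object of class `imputation_evaluation`: list with
#'   `per_metabolite` (data.frame: metabolite, baseline_r2, mean_r2,
#'   r2_variance, r2_ss, constant_truth), `per_sample` (data.frame:
#'   sample, spearman_rho), `n_cycles`.
#' @export
evaluate_imputation <- function(cycles, truth) {
  stopifnot(length(cycles) >= 1)
  mets <- colnames(cycles[[1]])
  truth <- as.matrix(truth)[, mets, drop = FALSE]
  if (!identical(dim(truth), dim(cycles[[1]])))
    stop("truth shape must match cycle matrices")
  n_cycles <- length(cycles)
  r2_of <- function(imp, tr) {
    ok <- !is.na(tr) & !is.na(imp)
    if (sum(ok) < 3 || stats::sd(tr[ok]) == 0) return(NA_real_)
    if (stats::sd(imp[ok]) == 0) return(0)
    stats::cor(imp[ok], tr[ok])^2
  }
  per_met <- data.frame(metabolite = mets, baseline_r2 = NA_real_,
                        mean_r2 = NA_real_, r2_variance = NA_real_,
                        r2_ss = NA_real_, constant_truth = FALSE,
                        stringsAsFactors = FALSE)
  later <- if (n_cycles > 1) 2:n_cycles else 1
  for (j in seq_along(mets)) {
    tr <- truth[, j]
    if (stats::sd(tr[!is.na(tr)]) == 0) {
      per_met$constant_truth[j] <- TRUE
      next
    }
    per_met$baseline_r2[j] <- r2_of(cycles[[1]][, j], tr)
    r2s <- vapply(later, function(cy) r2_of(cycles[[cy]][, j], tr),
                  numeric(1))
    per_met$mean_r2[j] <- mean(r2s, na.rm = TRUE)
    per_met$r2_variance[j] <- if (length(r2s) > 1)
      stats::var(r2s, na.rm = TRUE) else 0
    cm <- rowMeans(sapply(later, function(cy) cycles[[cy]][, j]))
    ok <- !is.na(tr) & !is.na(cm)
    ss_res <- sum((tr[ok] - cm[ok])^2)
    ss_tot <- sum((tr[ok] - mean(tr[ok]))^2)
    per_met$r2_ss[j] <- 1 - ss_res / ss_tot
  }
  cycle_mean <- Reduce(`+`, cycles[later]) / length(later)
  rho <- vapply(seq_len(nrow(truth)), function(i) {
    ok <- !is.na(truth[i, ]) & !is.na(cycle_mean[i, ])
    if (sum(ok) < 3) return(NA_real_)
    stats::cor(cycle_mean[i, ok], truth[i, ok], method = "spearman")
  }, numeric(1))
  structure(list(per_metabolite = per_met,
                 per_sample = data.frame(
                   sample = rownames(truth) %||%
                     as.character(seq_len(nrow(truth))),
                   spearman_rho = rho, stringsAsFactors = FALSE),
                 n_cycles = n_cycles),
            class = "imputation_evaluation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.imputation_evaluation <- function(x, ...) {
  pm <- x$per_metabolite[!x$per_metabolite$constant_truth, ]
  cat(sprintf(
    "imputation_evaluation: %d metabolites, %d cycles\n  baseline R2 mean %.3f; R2 variance mean %.4f; sample rho mean %.3f\n",
    nrow(x$per_metabolite), x$n_cycles, mean(pm$baseline_r2, na.rm = TRUE),
    mean(pm$r2_variance, na.rm = TRUE),
    mean(x$per_sample$spearman_rho, na.rm = TRUE)))
  invisible(x)
}

#' Select the well-imputed metabolite subset
#'
#' Applies the joint quality rule (baseline R-squared at least `r2_min`
#' and R-squared variance at most `var_max`; defaults 0.55 / 0.025) and
#' summarises performance by compound superclass. A selected metabolite
#' counts as "unique to the target platform" when no input-platform
#' feature shares its annotation tag.
#'
#' @param eval an [evaluate_imputation()] result.
#' @param feature_metadata data.frame with `feature_id`, `platform`,
#'   `class`, `annotation` columns.
#' @param r2_min,var_max selection thresholds.
#' @return list with `selected` (character vector), `summary`
#'   (data.frame: class, n, n_selected, mean_r2, sd_r2),
#'   `n_unique_to_target` and `unique_to_target` (selected metabolites
#'   with no same-annotation input feature).
#' @export
select_well_imputed <- function(eval, feature_metadata, r2_min = 0.55,
                                var_max = 0.025) {
  pm <- eval$per_metabolite
  ok <- !pm$constant_truth & is.finite(pm$baseline_r2) &
    pm$baseline_r2 >= r2_min & pm$r2_variance <= var_max
  selected <- pm$metabolite[ok]
  md <- feature_metadata[match(pm$metabolite, feature_metadata$feature_id), ]
  cls <- md$class
  summary <- do.call(rbind, lapply(unique(cls[!is.na(cls)]), function(cc) {
    idx <- which(cls == cc & !pm$constant_truth)
    data.frame(class = cc, n = length(idx),
               n_selected = sum(pm$metabolite[idx] %in% selected),
               mean_r2 = mean(pm$baseline_r2[idx], na.rm = TRUE),
               sd_r2 = stats::sd(pm$baseline_r2[idx]),
               stringsAsFactors = FALSE)
  }))
  input_annot <- feature_metadata$annotation[
    feature_metadata$platform == "input"]
  sel_annot <- feature_metadata$annotation[
    match(selected, feature_metadata$feature_id)]
  uniq <- selected[!(sel_annot %in% input_annot)]
  list(selected = selected, summary = summary,
       n_unique_to_target = length(uniq), unique_to_target = uniq,
       r2_min = r2_min, var_max = var_max)
}
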