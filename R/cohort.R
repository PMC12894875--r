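#' Configuration for the synthetic two-platform cohort generator
#'
#' Describes a paired-platform metabolomics cohort with block-correlated
#' compound classes. Each class c has `latent_dim` shared latent factors
#' loaded by both platforms, plus platform-private factors. A feature in
#' class c is built as
#' \deqn{x = \sqrt{\lambda}\, U_c w + \sqrt{1-\lambda}\, P_c w' + \sigma \epsilon}
#' where \eqn{\lambda} = `cross_platform_loading`, \eqn{U_c} are the shared
#' class factors, \eqn{P_c} the platform-private class factors, and
#' \eqn{\sigma} = `noise_sd`. Loading directions w are random unit vectors in
#' the positive orthant, so same-class features correlate positively. With
#' `latent_dim = 1` the expected correlation between a same-class input and
#' target feature is exactly \eqn{\lambda / (1 + \sigma^2)}.
#'
#' Outcomes are linear in the first shared factor of each class (effect sizes
#' on the standardised-beta scale) plus age and sex effects plus noise, and
#' are standardised after generation.
#'
#' @param n_samples number of samples.
#' @param n_classes number of compound classes (default 5, echoing the
#'   Fatty acids / Sphingolipids / Phospholipids / Acyl-glycerides / Others
#'   partition of a real lipid-dominated panel).
#' @param n_input_per_class input-platform features per class (scalar or
#'   length-`n_classes` vector).
#' @param n_target_per_class target-platform features per class.
#' @param latent_dim within-class shared latent dimension.
#' @param cross_platform_loading fraction in [0, 1]: share of a feature's
#'   signal variance carried by factors shared across platforms. May be a
#'   scalar or a per-class vector.
#' @param noise_sd per-feature measurement noise SD on top of unit-variance
#'   signal.
#' @param missing_frac MCAR missingness fraction per feature in [0, 1).
#' @param outlier_frac fraction of samples turned into gross outliers.
#' @param outlier_multiplier multiplicative inflation applied to outlier
#'   samples' values.
#' @param n_high_missing_features number of target features forced to
#'   `high_missing_frac` missingness (to exercise the 25% filter).
#' @param high_missing_frac elevated missingness fraction for those features.
#' @param outcome_effects `n_classes` x n_outcomes matrix of standardised
#'   effect sizes of each class factor on each outcome. Default: BMI effects
#'   decaying from 0.30 to 0.05 across classes, CRP at half those values —
#'   the scale of reported metabolite-adiposity associations.
#' @param outcome_names names of the synthetic outcomes.
#' @param age_range range of the uniform age distribution, in years.
#' @param class_names labels used for compound classes; recycled/truncated
#'   to `n_classes`.
#' @param seed integer seed; the whole cohort is deterministic given the
#'   config.
#' @return An object of class `cohort_config` (validated list).
#' @export
cohort_config <- function(n_samples = 500,
                          n_classes = 5,
                          n_input_per_class = 40,
                          n_target_per_class = 25,
                          latent_dim = 2,
                          cross_platform_loading = 0.7,
                          noise_sd = 0.3,
                          missing_frac = 0,
                          outlier_frac = 0,
                          outlier_multiplier = 10,
                          n_high_missing_features = 0,
                          high_missing_frac = 0.3,
                          outcome_effects = NULL,
                          outcome_names = c("BMI", "CRP"),
                          age_range = c(20, 65),
                          class_names = c("Fatty acids", "Sphingolipids",
                                          "Phospholipids", "Acyl-glycerides",
                                          "Others", paste0("Class", 6:20)),
                          seed = 1L) {
  chk_count <- function(x, nm, min = 1L) {
    if (length(x) < 1 || any(!is.finite(x)) || any(x < min))
      stop(sprintf("invalid %s", nm), call. = FALSE)
    as.integer(x)
  }
  chk_frac <- function(x, nm, hi_open = TRUE) {
    hi_ok <- if (hi_open) all(x < 1) else all(x <= 1)
    if (any(!is.finite(x)) || any(x < 0) || !hi_ok)
      stop(sprintf("invalid fraction %s", nm), call. = FALSE)
    as.numeric(x)
  }
  n_samples <- chk_count(n_samples, "n_samples")
  n_classes <- chk_count(n_classes, "n_classes")
  n_input_per_class <- rep_len(chk_count(n_input_per_class,
                                         "n_input_per_class"), n_classes)
  n_target_per_class <- rep_len(chk_count(n_target_per_class,
                                          "n_target_per_class"), n_classes)
  latent_dim <- chk_count(latent_dim, "latent_dim")
  cross_platform_loading <- rep_len(
    chk_frac(cross_platform_loading, "cross_platform_loading",
             hi_open = FALSE), n_classes)
  if (!is.finite(noise_sd) || noise_sd < 0) stop("invalid noise_sd")
  missing_frac <- chk_frac(missing_frac, "missing_frac")
  outlier_frac <- chk_frac(outlier_frac, "outlier_frac")
  high_missing_frac <- chk_frac(high_missing_frac, "high_missing_frac")
  n_high_missing_features <- chk_count(n_high_missing_features,
                                       "n_high_missing_features", min = 0L)
  if (is.null(outcome_effects)) {
    bmi <- seq(0.30, 0.05, length.out = n_classes)
    outcome_effects <- cbind(BMI = bmi, CRP = bmi / 2)
    colnames(outcome_effects) <- outcome_names[seq_len(ncol(outcome_effects))]
  }
  outcome_effects <- as.matrix(outcome_effects)
  if (nrow(outcome_effects) != n_classes)
    stop("outcome_effects must have n_classes rows")
  if (is.null(colnames(outcome_effects)))
    colnames(outcome_effects) <- outcome_names[seq_len(ncol(outcome_effects))]
  structure(list(
    n_samples = n_samples, n_classes = n_classes,
    n_input_per_class = n_input_per_class,
    n_target_per_class = n_target_per_class,
    latent_dim = latent_dim,
    cross_platform_loading = cross_platform_loading,
    noise_sd = as.numeric(noise_sd),
    missing_frac = missing_frac, outlier_frac = outlier_frac,
    outlier_multiplier = as.numeric(outlier_multiplier),
    n_high_missing_features = n_high_missing_features,
    high_missing_frac = high_missing_frac,
    outcome_effects = outcome_effects,
    outcome_names = colnames(outcome_effects),
    age_range = as.numeric(age_range),
    class_names = rep_len(class_names, n_classes),
    seed = as.integer(seed)), class = "cohort_config")
}

# random unit loading direction in the positive orthant
.unit_dir <- function(q) {
  w <- abs(stats::rnorm(q)) + 1e-6
  w / sqrt(sum(w^2))
}

#' Generate a synthetic paired-platform cohort
#'
#' Draws shared and platform-private class factors, builds both platform
#' matrices, feature metadata (class + annotation tags), and a phenotype
#' table with age, sex and standardised outcomes that are linear in the
#' class factors. Ground-truth factors are kept in `true_factors` for tests
#' only and are never consumed by pipeline stages.
#'
#' @param config a [cohort_config()].
#' @return An object of class `synthetic_cohort`: list with
#'   `input_matrix`, `target_matrix` (both [platform_matrix()]),
#'   `feature_metadata` (data.frame: feature_id, platform, class,
#'   annotation, annotated), `phenotypes` (data.frame: sample_id, age, sex,
#'   one column per outcome), `true_factors` (samples x (n_classes *
#'   latent_dim) shared-factor matrix), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  q <- config$latent_dim
  k <- config$n_classes
  sample_ids <- sprintf("S%04d", seq_len(n))

  U <- vector("list", k)  # shared factors
  P <- vector("list", k)  # input-private
  V <- vector("list", k)  # target-private
  for (c in seq_len(k)) {
    U[[c]] <- matrix(stats::rnorm(n * q), n, q)
    P[[c]] <- matrix(stats::rnorm(n * q), n, q)
    V[[c]] <- matrix(stats::rnorm(n * q), n, q)
  }

  gen_platform <- function(counts, private, prefix, platform) {
    total <- sum(counts)
    vals <- matrix(0, n, total)
    fid <- character(total)
    fclass <- character(total)
    annot <- character(total)
    j <- 0L
    for (c in seq_len(k)) {
      lam <- config$cross_platform_loading[c]
      for (i in seq_len(counts[c])) {
        j <- j + 1L
        w <- .unit_dir(q); wp <- .unit_dir(q)
        sig <- sqrt(lam) * drop(U[[c]] %*% w) +
          sqrt(1 - lam) * drop(private[[c]] %*% wp)
        vals[, j] <- sig + config$noise_sd * stats::rnorm(n)
        fid[j] <- sprintf("%s_c%d_%03d", prefix, c, i)
        fclass[j] <- config$class_names[c]
        # annotation tag: shared across platforms for most features; a
        # tail of target features gets platform-unique annotations so the
        # "unique to target platform" summary has substance
        annot[j] <- sprintf("cmpd_c%d_%03d", c, i)
      }
    }
    list(pm = platform_matrix(vals, sample_ids = sample_ids,
                              feature_ids = fid, platform = platform),
         class = fclass, annot = annot)
  }

  inp <- gen_platform(config$n_input_per_class, P, "in", "input")
  tgt <- gen_platform(config$n_target_per_class, V, "tg", "target")

  # roughly 1 in 5 target features per class is annotation-unique to the
  # target platform (no input feature shares its tag)
  for (c in seq_len(k)) {
    idx <- grep(sprintf("^tg_c%d_", c), tgt$pm$feature_ids)
    uniq <- idx[seq_along(idx) %% 5 == 0]
    tgt$annot[uniq] <- sprintf("tgonly_c%d_%03d", c, seq_along(uniq))
  }

  feature_metadata <- data.frame(
    feature_id = c(inp$pm$feature_ids, tgt$pm$feature_ids),
    platform = rep(c("input", "target"),
                   c(length(inp$pm$feature_ids), length(tgt$pm$feature_ids))),
    class = c(inp$class, tgt$class),
    annotation = c(inp$annot, tgt$annot),
    stringsAsFactors = FALSE)
  feature_metadata$annotated <- !grepl("^tgonly_", feature_metadata$annotation)

  # phenotypes: age, sex, outcomes linear in first shared factor per class
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- stats::rbinom(n, 1, 0.5)
  age_std <- as.numeric(scale(age))
  eff <- config$outcome_effects
  g_age <- 0.2; g_sex <- 0.2
  class_proxy <- sapply(seq_len(k), function(c) U[[c]][, 1])
  outcomes <- matrix(0, n, ncol(eff),
                     dimnames = list(NULL, colnames(eff)))
  for (o in seq_len(ncol(eff))) {
    lin <- drop(class_proxy %*% eff[, o]) + g_age * age_std + g_sex * sex
    resid_var <- max(0.05, 1 - sum(eff[, o]^2) - g_age^2 - g_sex^2 * 0.25)
    y <- lin + sqrt(resid_var) * stats::rnorm(n)
    outcomes[, o] <- as.numeric(scale(y))
  }
  phenotypes <- data.frame(sample_id = sample_ids, age = age, sex = sex,
                           outcomes, stringsAsFactors = FALSE)

  true_factors <- do.call(cbind, U)
  colnames(true_factors) <- as.vector(outer(seq_len(q), seq_len(k),
                                            function(i, c)
                                              sprintf("class%d_f%d", c, i)))
  structure(list(input_matrix = inp$pm, target_matrix = tgt$pm,
                 feature_metadata = feature_metadata,
                 phenotypes = phenotypes, true_factors = true_factors,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d samples; %d input + %d target features; %d classes\n",
    length(x$input_matrix$sample_ids), length(x$input_matrix$feature_ids),
    length(x$target_matrix$feature_ids), x$config$n_classes))
  invisible(x)
}

#' Inject missing values and outlier samples into a cohort
#'
#' Missingness is MCAR at `missing_frac` per feature on both platforms; a
#' configurable number of target features receives elevated missingness
#' (`high_missing_frac`) to exercise the 25% feature filter. Outlier samples
#' are produced by multiplying all their values (both platforms) by
#' `outlier_multiplier`. The planted outlier sample ids are recorded in
#' attribute `"planted_outliers"` and the forced high-missing feature ids in
#' attribute `"high_missing_features"`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param config the [cohort_config()] controlling the fractions (defaults
#'   to `cohort$config`).
#' @return the modified `synthetic_cohort`.
#' @export
inject_missing_and_outliers <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            inherits(config, "cohort_config"))
  set.seed(config$seed + 1000003L)
  n <- length(cohort$input_matrix$sample_ids)

  planted <- character(0)
  if (config$outlier_frac > 0) {
    n_out <- ceiling(config$outlier_frac * n)
    idx <- sample.int(n, n_out)
    planted <- cohort$input_matrix$sample_ids[idx]
    for (slot in c("input_matrix", "target_matrix")) {
      cohort[[slot]]$values[idx, ] <-
        cohort[[slot]]$values[idx, , drop = FALSE] * config$outlier_multiplier
    }
  }

  drop_mcar <- function(pm, frac, cols = seq_along(pm$feature_ids)) {
    if (frac <= 0) return(pm)
    for (j in cols) {
      hide <- stats::runif(n) < frac
      pm$values[hide, j] <- NA_real_
      pm$observed_mask[hide, j] <- FALSE
    }
    pm
  }
  cohort$input_matrix <- drop_mcar(cohort$input_matrix, config$missing_frac)
  cohort$target_matrix <- drop_mcar(cohort$target_matrix, config$missing_frac)

  high_ids <- character(0)
  if (config$n_high_missing_features > 0) {
    nf <- length(cohort$target_matrix$feature_ids)
    hm <- sample.int(nf, min(config$n_high_missing_features, nf))
    high_ids <- cohort$target_matrix$feature_ids[hm]
    for (j in hm) {
      # force exact count of missing entries to hit the stated fraction
      n_miss <- ceiling(config$high_missing_frac * n)
      hide <- sample.int(n, n_miss)
      cohort$target_matrix$values[hide, j] <- NA_real_
      cohort$target_matrix$observed_mask[hide, j] <- FALSE
    }
  }
  attr(cohort, "planted_outliers") <- planted
  attr(cohort, "high_missing_features") <- high_ids
  cohort
}

#' Write a cohort to a directory of CSV files plus a JSON config sidecar
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(pm, file) {
    df <- data.frame(sample_id = pm$sample_ids, pm$values,
                     check.names = FALSE)
    utils::write.csv(df, file.path(dir, file), row.names = FALSE, na = "")
  }
  wr(cohort$input_matrix, "input_matrix.csv")
  wr(cohort$target_matrix, "target_matrix.csv")
  utils::write.csv(cohort$feature_metadata,
                   file.path(dir, "feature_metadata.csv"), row.names = FALSE)
  utils::write.csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  cfg$outcome_effects <- as.data.frame(cfg$outcome_effects)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a platform matrix from CSV (first column = sample id, empty cell =
#' missing)
#'
#' @param file path to a CSV written by [write_cohort()] or of the same
#'   layout.
#' @param platform platform tag to attach.
#' @return a [platform_matrix()].
#' @export
read_platform_matrix <- function(file, platform = "unknown") {
  df <- utils::read.csv(file, check.names = FALSE,
                        colClasses = c("character"))
  sample_ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  vals[vals == ""] <- NA
  storage.mode(vals) <- "double"
  platform_matrix(vals, sample_ids = sample_ids,
                  feature_ids = colnames(df)[-1], platform = platform)
}
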