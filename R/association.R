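#' Covariate-adjusted metabolite-outcome association
#'
#' Ordinary least squares of the standardised outcome on the standardised
#' metabolite, adjusted for age (standardised) and sex (0/1, not
#' standardised). The reported beta is the metabolite coefficient on the
#' standardised-beta scale, with its closed-form OLS standard error.
#' Complete cases only; refuses fewer than 10.
#'
#' @param metabolite numeric vector of metabolite values.
#' @param outcome numeric outcome vector.
#' @param age numeric age vector (years).
#' @param sex 0/1 vector.
#' @param metabolite_id,outcome_name,dataset identifier strings carried
#'   into the record.
#' @return one-row data.frame (class `association_record`): metabolite,
#'   outcome, beta, se, p, n, dataset.
#' @export
fit_association <- function(metabolite, outcome, age, sex,
                            metabolite_id = "metabolite",
                            outcome_name = "outcome",
                            dataset = "real") {
  ok <- stats::complete.cases(metabolite, outcome, age, sex)
  if (sum(ok) < 10) stop("fewer than 10 complete cases")
  m <- metabolite[ok]; y <- outcome[ok]; a <- age[ok]; s <- sex[ok]
  if (stats::sd(m) == 0) stop("constant metabolite")
  if (stats::sd(y) == 0) stop("constant outcome")
  d <- data.frame(y = as.numeric(scale(y)), m = as.numeric(scale(m)),
                  age = as.numeric(scale(a)), sex = s)
  fit <- stats::lm(y ~ m + age + sex, data = d)
  co <- summary(fit)$coefficients["m", ]
  structure(data.frame(metabolite = metabolite_id,
                       outcome = outcome_name,
                       beta = unname(co[1]), se = unname(co[2]),
                       p = unname(co[4]), n = sum(ok),
                       dataset = dataset, stringsAsFactors = FALSE),
            class = c("association_record", "data.frame"))
}

#' Association panel over a metabolite set
#'
#' One record per metabolite per outcome. When run on imputed data the
#' caller restricts `metabolites` to the well-imputed set; the identical
#' list must be used on the real data so records pair one-to-one.
#'
#' @param values numeric matrix (samples x metabolites) or a
#'   [platform_matrix()].
#' @param phenotypes data.frame with `sample_id`, `age`, `sex` and one
#'   column per outcome, aligned to the rows of `values` by sample id.
#' @param metabolites metabolite column names to test (non-empty).
#' @param outcomes outcome column names (default all phenotype columns
#'   beyond sample_id/age/sex).
#' @param dataset dataset tag attached to every record.
#' @return data.frame of stacked association records.
#' @export
run_association_panel <- function(values, phenotypes, metabolites,
                                  outcomes = NULL, dataset = "real") {
  if (inherits(values, "platform_matrix")) values <- values$values
  values <- as.matrix(values)
  if (length(metabolites) == 0) stop("empty metabolite set")
  if (!all(metabolites %in% colnames(values)))
    stop("metabolite(s) absent from matrix")
  idx <- match(rownames(values), phenotypes$sample_id)
  if (anyNA(idx)) stop("sample ids missing from phenotypes")
  ph <- phenotypes[idx, ]
  if (is.null(outcomes))
    outcomes <- setdiff(colnames(phenotypes),
                        c("sample_id", "age", "sex"))
  recs <- list()
  for (oc in outcomes)
    for (met in metabolites)
      recs[[paste(met, oc)]] <- fit_association(
        values[, met], ph[[oc]], ph$age, ph$sex,
        metabolite_id = met, outcome_name = oc, dataset = dataset)
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Concordance of paired association panels (Bland-Altman)
#'
#' Pairs records by metabolite id for one outcome, computes the Spearman
#' correlation of the paired betas, the per-metabolite differences
#' \eqn{d_i = \beta_{real,i} - \beta_{imputed,i}}, their mean and SD,
#' Bland-Altman limits of agreement (mean +/- 1.96 SD), and flags
#' metabolites with \eqn{|d_i - \bar d| > 1.96\,SD}. Unpairable
#' metabolites are listed, excluded and warned about.
#'
#' @param real,imputed data.frames of association records (from
#'   [run_association_panel()]).
#' @param outcome outcome name to compare.
#' @param z flagging multiple of the SD (default 1.96).
#' @return object of class `concordance_report`: list with `outcome`,
#'   `pairs` (data.frame: metabolite, beta_real, beta_imputed, diff,
#'   flagged), `spearman_rho`, `mean_difference`, `sd_difference`,
#'   `limits` (length 2), `n_flagged`, `pct_flagged`, `unpaired`.
#' @export
concordance <- function(real, imputed, outcome, z = 1.96) {
  r <- real[real$outcome == outcome, ]
  i <- imputed[imputed$outcome == outcome, ]
  if (nrow(r) == 0 || nrow(i) == 0) stop("no records for outcome ", outcome)
  if (anyDuplicated(r$metabolite) || anyDuplicated(i$metabolite))
    stop("duplicate metabolite records for outcome ", outcome)
  common <- intersect(r$metabolite, i$metabolite)
  unpaired <- setdiff(union(r$metabolite, i$metabolite), common)
  if (length(unpaired))
    warning(length(unpaired), " unpairable metabolite(s) excluded")
  if (length(common) < 3) stop("fewer than 3 paired metabolites")
  br <- r$beta[match(common, r$metabolite)]
  bi <- i$beta[match(common, i$metabolite)]
  d <- br - bi
  mu <- mean(d); sdd <- stats::sd(d)
  flagged <- abs(d - mu) > z * sdd
  pairs <- data.frame(metabolite = common, beta_real = br,
                      beta_imputed = bi, diff = d, flagged = flagged,
                      stringsAsFactors = FALSE)
  structure(list(outcome = outcome, pairs = pairs,
                 spearman_rho = stats::cor(br, bi, method = "spearman"),
                 mean_difference = mu, sd_difference = sdd,
                 limits = c(lower = mu - z * sdd, upper = mu + z * sdd),
                 n_flagged = sum(flagged),
                 pct_flagged = 100 * mean(flagged),
                 unpaired = unpaired, z = z),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "concordance [%s]: n = %d, rho = %.3f, mean diff = %.4f (SD %.4f)\n  limits [%.4f, %.4f]; %d flagged (%.1f%%)\n",
    x$outcome, nrow(x$pairs), x$spearman_rho, x$mean_difference,
    x$sd_difference, x$limits[1], x$limits[2], x$n_flagged,
    x$pct_flagged))
  invisible(x)
}

#' Concordance against an external panel via an annotation name map
#'
#' Restricts the comparison to metabolites mapped (by annotation string)
#' to the external panel's ids, renames and delegates to [concordance()].
#' Matching is exact by default; `ignore_case = TRUE` lowers both sides.
#'
#' @param imputed imputed-panel association records.
#' @param external external-panel association records.
#' @param name_map named character vector: names are imputed-panel
#'   metabolite ids, values are the matching external ids.
#' @param outcome outcome name.
#' @param ignore_case case-insensitive matching flag (default FALSE).
#' @param z flagging multiple of the SD.
#' @return a `concordance_report` over the mapped pairs with an extra
#'   `unmapped` element.
#' @export
match_external_panel <- function(imputed, external, name_map, outcome,
                                 ignore_case = FALSE, z = 1.96) {
  imp_ids <- names(name_map)
  ext_have <- unique(external$metabolite)
  map_vals <- unname(name_map)
  hit <- if (ignore_case) tolower(map_vals) %in% tolower(ext_have)
         else map_vals %in% ext_have
  hit <- hit & (imp_ids %in% imputed$metabolite)
  if (!any(hit)) stop("empty intersection with external panel")
  unmapped <- imp_ids[!hit]
  imp <- imputed[imputed$metabolite %in% imp_ids[hit] &
                   imputed$outcome == outcome, ]
  ext <- external[external$outcome == outcome, ]
  if (ignore_case) {
    ext$metabolite <- tolower(ext$metabolite)
    imp$metabolite <- tolower(name_map[imp$metabolite])
  } else {
    imp$metabolite <- unname(name_map[imp$metabolite])
  }
  ext <- ext[ext$metabolite %in% imp$metabolite, ]
  rep <- concordance(ext, imp, outcome, z = z)
  rep$unmapped <- unmapped
  rep
}
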