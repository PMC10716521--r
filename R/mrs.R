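# Per-gene weighted methylation risk scores (MRS). A gene's score for a
# sample is the sum of methylation percentages at its included CpG sites,
# each weighted by that site's regression effect size. Associations with
# disease status use covariate-adjusted linear and logistic models.

#' Select genes eligible for a methylation risk score
#'
#' A gene qualifies when its expression is differential
#' (`q_expression < q_threshold`) and more than five — i.e. at least
#' `min_sites = 6` — CpG sites with methylation `q_value < q_threshold` map
#' into its flanked window.
#'
#' @param ewas An `ewas_table` (needs `probe_id`, `q_value`).
#' @param degs Gene/DEG tibble (needs `gene_id`, `q_expression`).
#' @param site_gene_map Mapping tibble (`probe_id`, `gene_id`) from
#'   [sites_in_gene_windows()].
#' @param q_threshold Shared significance threshold; default 0.05.
#' @param min_sites Minimum count of significant sites; default 6.
#' @return A tibble with `gene_id` and `n_sig_sites`, one row per selected
#'   gene.
#' @export
select_mrs_genes <- function(ewas, degs, site_gene_map, q_threshold = 0.05,
                             min_sites = 6) {
  if (nrow(site_gene_map) == 0 || nrow(ewas) == 0 || nrow(degs) == 0) {
    return(tibble(gene_id = character(), n_sig_sites = integer()))
  }
  sig_sites <- ewas$probe_id[!is.na(ewas$q_value) & ewas$q_value < q_threshold]
  deg_ids <- degs$gene_id[!is.na(degs$q_expression) & degs$q_expression < q_threshold]
  counts <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(site_gene_map, .data$probe_id %in% sig_sites),
                    .data$gene_id),
    n_sig_sites = dplyr::n_distinct(.data$probe_id), .groups = "drop")
  dplyr::arrange(
    dplyr::filter(counts, .data$gene_id %in% deg_ids, .data$n_sig_sites >= min_sites),
    .data$gene_id)
}

#' Per-site effect-size weights for a risk score
#'
#' Refits the covariate-adjusted per-site linear model with methylation as
#' the outcome on the chosen scale and returns the case/control coefficient
#' as the weight. The default `"beta_pct"` scale makes score units
#' interpretable per percent of methylation; `"m"` uses M-value
#' coefficients instead.
#'
#' @param mat Methylation tibble (`probe_id` + sample columns).
#' @param samples Sample table with `group` and the covariates.
#' @param sites Character vector of probe ids to weight.
#' @param covariates Covariate column names.
#' @param scale `"beta_pct"` (default) or `"m"`.
#' @return A tibble with `probe_id` and `weight`.
#' @export
mrs_weights <- function(mat, samples, sites,
                        covariates = c("age", "bmi", "sex", "purity", "days_culture"),
                        scale = c("beta_pct", "m")) {
  scale <- match.arg(scale)
  missing_sites <- setdiff(sites, mat$probe_id)
  if (length(missing_sites) > 0) {
    abort(sprintf("unknown site id(s): %s", paste(head(missing_sites, 3), collapse = ", ")))
  }
  M <- meth_as_matrix(mat[match(sites, mat$probe_id), , drop = FALSE])
  common <- intersect(colnames(M), samples$sample_id)
  samples <- samples[match(common, samples$sample_id), , drop = FALSE]
  M <- M[, common, drop = FALSE]
  des <- build_design(samples, "binary", covariates)
  ok <- complete.cases(des$X)
  X <- des$X[ok, , drop = FALSE]
  Y <- t(M[, ok, drop = FALSE])
  Y <- if (scale == "beta_pct") 100 * Y else beta_to_m_matrix(Y)
  w <- vapply(seq_len(ncol(Y)), function(j) {
    keep <- !is.na(Y[, j])
    fit <- ols_phenotype_stats(X[keep, , drop = FALSE], Y[keep, j, drop = FALSE])
    fit$coef[1]
  }, numeric(1))
  tibble(probe_id = sites, weight = unname(w))
}

#' Compute per-sample weighted methylation risk scores
#'
#' `score_s = sum_j weight_j * (100 * beta_{s,j})`. Missing methylation at a
#' site is imputed with that site's cohort mean before summation; the number
#' of imputed cells is recorded in the `n_imputed` attribute.
#'
#' @param mat Methylation tibble (`probe_id` + sample columns).
#' @param sites Character vector of probe ids (must exist in `mat`).
#' @param weights Numeric vector aligned with `sites`.
#' @return A tibble with `sample_id` and `score`.
#' @export
compute_mrs <- function(mat, sites, weights) {
  if (length(sites) != length(weights)) {
    abort("`sites` and `weights` must have the same length")
  }
  if (any(!is.finite(weights))) abort("weights must be finite")
  missing_sites <- setdiff(sites, mat$probe_id)
  if (length(missing_sites) > 0) {
    abort(sprintf("unknown site id(s): %s", paste(head(missing_sites, 3), collapse = ", ")))
  }
  M <- meth_as_matrix(mat[match(sites, mat$probe_id), , drop = FALSE])
  n_imputed <- sum(is.na(M))
  if (n_imputed > 0) {
    site_means <- rowMeans(M, na.rm = TRUE)
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- site_means[idx[, 1]]
  }
  scores <- drop(crossprod(100 * M, weights))
  out <- tibble(sample_id = colnames(M), score = unname(scores))
  attr(out, "n_imputed") <- n_imputed
  out
}

#' Associate a methylation risk score with disease status
#'
#' Fits (i) a linear model of the score on case/control status plus
#' covariates (the group coefficient is the covariate-adjusted score
#' difference) and (ii) a logistic model of status on the score plus
#' covariates, reporting the odds ratio per unit score with a Wald 95%
#' confidence interval. Non-convergence and (quasi-)complete separation are
#' flagged; a separated fit carries no silent estimate.
#'
#' @param scores Tibble from [compute_mrs()] (`sample_id`, `score`).
#' @param samples Sample table with `group` and the covariates.
#' @param covariates Covariate column names; default the donor covariates.
#' @return An object of class `mrs_fit` with [tidy()] and [glance()]
#'   methods.
#' @export
mrs_association <- function(scores, samples,
                            covariates = c("age", "bmi", "sex", "purity", "days_culture")) {
  assert_columns(scores, c("sample_id", "score"), "score table")
  assert_columns(samples, c("sample_id", "group"), "sample table")
  df <- dplyr::inner_join(scores, samples, by = "sample_id")
  des <- build_design(df, "binary", covariates)
  rhs_cov <- setdiff(colnames(des$X), c("(Intercept)", "phenotype"))
  dat <- as.data.frame(des$X[, rhs_cov, drop = FALSE])
  dat$score <- df$score
  dat$case <- des$X[, "phenotype"]
  lin_formula <- stats::reformulate(c("case", rhs_cov), response = "score")
  logi_formula <- stats::reformulate(c("score", rhs_cov), response = "case")

  linear <- lm(lin_formula, data = dat)
  logistic <- withCallingHandlers(
    glm(logi_formula, data = dat, family = binomial()),
    warning = function(w) invokeRestart("muffleWarning"))
  fitted_p <- stats::fitted(logistic)
  separation <- any(fitted_p < 1e-8 | fitted_p > 1 - 1e-8) ||
    abs(coef(logistic)[["score"]]) * sd(dat$score) > 30
  structure(list(linear = linear, logistic = logistic,
                 separation = separation,
                 converged = isTRUE(logistic$converged),
                 covariates = covariates),
            class = "mrs_fit")
}

#' @method tidy mrs_fit
#' @export
tidy.mrs_fit <- function(x, ...) {
  sl <- summary(x$linear)$coefficients
  rows <- list(tibble(model = "linear", term = rownames(sl),
                      estimate = sl[, 1], std.error = sl[, 2],
                      statistic = sl[, 3], p.value = sl[, 4]))
  if (!x$separation) {
    sg <- summary(x$logistic)$coefficients
    rows <- c(rows, list(tibble(model = "logistic", term = rownames(sg),
                                estimate = sg[, 1], std.error = sg[, 2],
                                statistic = sg[, 3], p.value = sg[, 4])))
  }
  dplyr::bind_rows(rows)
}

#' @method glance mrs_fit
#' @export
glance.mrs_fit <- function(x, ...) {
  sl <- summary(x$linear)$coefficients
  out <- tibble(
    linear_beta = sl["case", 1], linear_se = sl["case", 2],
    linear_p = sl["case", 4],
    odds_ratio = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
    logistic_p = NA_real_,
    converged = x$converged, separation = x$separation
  )
  if (!x$separation) {
    sg <- summary(x$logistic)$coefficients
    b <- sg["score", 1]; se <- sg["score", 2]
    out$odds_ratio <- exp(b)
    out$or_ci_low <- exp(b - qnorm(0.975) * se)
    out$or_ci_high <- exp(b + qnorm(0.975) * se)
    out$logistic_p <- sg["score", 4]
  }
  out
}
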