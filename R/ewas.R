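#' Convert methylation beta-values to M-values
#'
#' The M-value is `log2(beta / (1 - beta))`, the variance-stabilised scale on
#' which all site-level regression models in this package are fit. Beta-values
#' are clipped to `[eps, 1 - eps]` before the logit so that degenerate sites
#' (fully methylated or unmethylated) map to large but finite M-values.
#'
#' @param beta Numeric vector of methylation fractions in `[0, 1]`. `NA`s are
#'   propagated.
#' @param eps Clipping constant; default `1e-6`.
#' @return Numeric vector of M-values.
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (!is.numeric(beta)) abort("`beta` must be numeric")
  bad <- !is.na(beta) & (beta < 0 | beta > 1)
  if (any(bad)) {
    abort(sprintf("beta-values must lie in [0, 1]; offending value %g at position %d",
                  beta[which(bad)[1]], which(bad)[1]))
  }
  b <- clip(beta, eps, 1 - eps)
  log2(b / (1 - b))
}

#' Convert M-values back to beta-values
#'
#' Inverse of [beta_to_m()] away from the clipping boundary:
#' `2^m / (1 + 2^m)`.
#'
#' @param m Numeric vector of M-values; must be finite (`NA` allowed).
#' @return Numeric vector of methylation fractions.
#' @export
m_to_beta <- function(m) {
  if (!is.numeric(m)) abort("`m` must be numeric")
  if (any(!is.na(m) & !is.finite(m))) abort("M-values must be finite")
  plogis(m * log(2))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: with sorted p-values `p_(1) <=
#' ... <= p_(m)`, `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and
#' returned in input order. Delegates to [stats::p.adjust()] after range
#' validation; `NA` p-values yield `NA` q-values and do not count towards `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    abort(sprintf("p-values must lie in [0, 1]; offending value %g at position %d",
                  p[which(bad)[1]], which(bad)[1]))
  }
  p.adjust(p, method = "BH")
}

#' Absolute and relative methylation difference
#'
#' Summarises a case/control contrast of group-mean methylation percentages as
#' the absolute difference in percentage points and the relative (fold) change
#' in percent of the control mean. A control mean of zero with a non-zero case
#' mean leaves the relative change undefined (`NA` with a warning).
#'
#' @param mean_control_pct,mean_case_pct Group means in percent, in
#'   `[0, 100]`. Vectorised.
#' @return A tibble with columns `delta_pp` (case minus control, percentage
#'   points) and `relative_change_pct` (`100 * delta / control`).
#' @examples
#' effect_summary(12.9, 23.3)
#' @export
effect_summary <- function(mean_control_pct, mean_case_pct) {
  for (nm in c("mean_control_pct", "mean_case_pct")) {
    x <- get(nm)
    if (!is.numeric(x)) abort(sprintf("`%s` must be numeric", nm))
    if (any(!is.na(x) & (x < 0 | x > 100))) {
      abort(sprintf("`%s` must lie in [0, 100]", nm))
    }
  }
  delta <- mean_case_pct - mean_control_pct
  rel <- 100 * delta / mean_control_pct
  undef <- !is.na(mean_control_pct) & mean_control_pct == 0 &
    !is.na(mean_case_pct) & mean_case_pct != 0
  if (any(undef)) {
    warn("relative change undefined where the control mean is 0; set to NA")
    rel[undef] <- NA_real_
  }
  rel[!is.na(mean_control_pct) & mean_control_pct == 0 & !undef] <- 0
  tibble(delta_pp = delta, relative_change_pct = rel)
}

# Build the design matrix for the site-level models. Returns list(X, pheno_col,
# sex_coding). Character/factor covariates with two levels become a 0/1
# indicator (second sorted level = 1); anything else must already be numeric.
build_design <- function(samples, phenotype, covariates) {
  pheno_col <- switch(phenotype, binary = "group", continuous = "hba1c")
  if (!pheno_col %in% names(samples)) {
    abort(sprintf("phenotype column '%s' is absent from the sample table", pheno_col))
  }
  assert_columns(samples, covariates, "sample table")
  if (phenotype == "binary") {
    g <- samples$group
    if (!all(g %in% c("case", "control"))) {
      abort("`group` must contain only 'case' and 'control'")
    }
    y <- as.numeric(g == "case")
  } else {
    y <- as.numeric(samples$hba1c)
  }
  codings <- list()
  covs <- lapply(covariates, function(cv) {
    x <- samples[[cv]]
    if (is.character(x) || is.factor(x)) {
      lev <- sort(unique(as.character(x)))
      if (length(lev) > 2) abort(sprintf("covariate '%s' has more than two levels", cv))
      codings[[cv]] <<- setNames(as.numeric(lev == lev[length(lev)]), lev)
      as.numeric(as.character(x) == lev[length(lev)])
    } else {
      as.numeric(x)
    }
  })
  X <- cbind(`(Intercept)` = 1, phenotype = y)
  if (length(covs) > 0) {
    covmat <- do.call(cbind, covs)
    colnames(covmat) <- covariates
    X <- cbind(X, covmat)
  }
  list(X = X, codings = codings)
}

# Multi-site OLS of M-values on a shared design via one QR factorisation.
# Y: n x p matrix (samples x sites), X: n x k. Returns per-site coefficient,
# se, t and p for the `phenotype` column.
ols_phenotype_stats <- function(X, Y) {
  n <- nrow(X); k <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < k || n < k + 2) {
    return(list(coef = rep(NA_real_, ncol(Y)), se = NA_real_, t = NA_real_,
                p = NA_real_, ok = FALSE))
  }
  cf <- qr.coef(qrX, Y)                       # k x p
  res <- Y - X %*% cf
  df <- n - k
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  j <- which(colnames(X) == "phenotype")
  se <- unname(sqrt(sigma2 * XtXinv[j, j]))
  tt <- unname(cf[j, ] / se)
  pp <- 2 * pt(-abs(tt), df)
  list(coef = unname(cf[j, ]), se = se, t = tt, p = pp, ok = TRUE, df = df)
}

#' Epigenome-wide association study on the M-value scale
#'
#' Fits, per CpG site, an ordinary least-squares regression of M-values on the
#' phenotype plus covariates, with a two-sided t-test on the phenotype
#' coefficient. p-values across all retained sites are adjusted once with
#' [bh_fdr()]. For the binary phenotype, unadjusted group means of beta (in
#' percent) and the derived absolute/relative differences are reported
#' alongside the adjusted inference — inference on the M scale, effect sizes
#' on the beta scale.
#'
#' Samples with a missing phenotype or covariate are dropped up front; sites
#' with missing beta-values use the complete cases available at that site
#' (recorded in `n_used`). Sites whose per-site design is rank deficient or
#' has fewer than `k + 2` complete samples are flagged in `status` rather
#' than raising an error.
#'
#' @param mat Methylation table: `probe_id` column plus one numeric column of
#'   beta-values per sample.
#' @param samples Sample table with `sample_id`, the phenotype column
#'   (`group` with values case/control, or `hba1c`), and the covariates.
#' @param phenotype `"binary"` (case/control) or `"continuous"` (HbA1c,
#'   modelled linearly in mmol/mol).
#' @param covariates Character vector of covariate column names; default the
#'   donor covariates age, BMI, sex, islet purity and days in culture.
#'   Additional numeric columns (e.g. surrogate or cell-composition
#'   covariates) may be appended.
#' @return A tibble of class `ewas_table`, one row per site, with columns
#'   `probe_id`, `coefficient_m`, `se_m`, `t_statistic`, `p_value`, `q_value`,
#'   `n_used`, `status`, and for the binary phenotype also
#'   `mean_beta_control`, `mean_beta_case` (percent), `delta_beta_pp`,
#'   `relative_change_pct`. Attributes record phenotype, covariates, the sex
#'   coding and cohort size.
#' @export
run_ewas <- function(mat, samples,
                     phenotype = c("binary", "continuous"),
                     covariates = c("age", "bmi", "sex", "purity", "days_culture")) {
  phenotype <- match.arg(phenotype)
  assert_columns(mat, "probe_id", "methylation table")
  assert_columns(samples, "sample_id", "sample table")
  M <- meth_as_matrix(mat)
  common <- intersect(colnames(M), samples$sample_id)
  if (length(common) == 0) abort("no sample ids shared between methylation table and sample table")
  samples <- samples[match(common, samples$sample_id), , drop = FALSE]
  M <- M[, common, drop = FALSE]

  des <- build_design(samples, phenotype, covariates)
  X <- des$X
  row_ok <- complete.cases(X)
  X <- X[row_ok, , drop = FALSE]
  B <- t(M[, row_ok, drop = FALSE])           # samples x sites, beta
  Ym <- beta_to_m_matrix(B)
  k <- ncol(X)

  p_sites <- ncol(Ym)
  coef_m <- se_m <- tstat <- pval <- rep(NA_real_, p_sites)
  n_used <- integer(p_sites)
  status <- rep("ok", p_sites)

  complete_site <- colSums(is.na(Ym)) == 0
  if (any(complete_site)) {
    fit <- ols_phenotype_stats(X, Ym[, complete_site, drop = FALSE])
    if (fit$ok) {
      coef_m[complete_site] <- fit$coef
      se_m[complete_site] <- fit$se
      tstat[complete_site] <- fit$t
      pval[complete_site] <- fit$p
    } else {
      status[complete_site] <- "rank_deficient"
    }
    n_used[complete_site] <- nrow(X)
  }
  for (jj in which(!complete_site)) {
    keep <- !is.na(Ym[, jj])
    n_used[jj] <- sum(keep)
    if (sum(keep) < k + 2) {
      status[jj] <- "insufficient_n"
      next
    }
    fit <- ols_phenotype_stats(X[keep, , drop = FALSE], Ym[keep, jj, drop = FALSE])
    if (!fit$ok) {
      status[jj] <- "rank_deficient"
      next
    }
    coef_m[jj] <- fit$coef; se_m[jj] <- fit$se
    tstat[jj] <- fit$t; pval[jj] <- fit$p
  }

  out <- tibble(
    probe_id = colnames(Ym),
    coefficient_m = coef_m,
    se_m = se_m,
    t_statistic = tstat,
    p_value = pval,
    q_value = bh_fdr(pval),
    n_used = n_used,
    status = status
  )

  if (phenotype == "binary") {
    case <- X[, "phenotype"] == 1
    Bk <- B  # already restricted to model-complete samples
    mean_ctrl <- unname(100 * colMeans(Bk[!case, , drop = FALSE], na.rm = TRUE))
    mean_case <- unname(100 * colMeans(Bk[case, , drop = FALSE], na.rm = TRUE))
    eff <- effect_summary(clip(mean_ctrl, 0, 100), clip(mean_case, 0, 100))
    out$mean_beta_control <- mean_ctrl
    out$mean_beta_case <- mean_case
    out$delta_beta_pp <- eff$delta_pp
    out$relative_change_pct <- eff$relative_change_pct
  }

  structure(out,
            class = c("ewas_table", class(out)),
            phenotype = phenotype,
            covariates = covariates,
            sex_coding = des$codings,
            n_samples = nrow(X))
}

# beta -> M for a matrix without losing dimnames; NA propagated.
beta_to_m_matrix <- function(B) {
  out <- B
  ok <- !is.na(B)
  out[ok] <- beta_to_m(B[ok])
  out
}

#' Write an EWAS table as TSV with a provenance header
#'
#' Emits `#`-prefixed header comments recording phenotype, covariates, cohort
#' size and package version, followed by the tab-delimited table, plus a
#' sidecar log.
#'
#' @param ewas An `ewas_table` from [run_ewas()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ewas_table <- function(ewas, path) {
  hdr <- c(
    sprintf("# phenotype: %s", attr(ewas, "phenotype") %||% "unknown"),
    sprintf("# covariates: %s", paste(attr(ewas, "covariates") %||% character(), collapse = ",")),
    sprintf("# n_samples: %s", attr(ewas, "n_samples") %||% NA),
    sprintf("# significance: q < 0.05"),
    sprintf("# software: isletewas %s", as.character(packageVersion("isletewas")))
  )
  writeLines(hdr, path)
  readr::write_tsv(as_tibble(ewas), path, append = TRUE, col_names = TRUE)
  write_sidecar(path, nrow(ewas), sprintf("ewas (%s)", attr(ewas, "phenotype") %||% "?"))
  invisible(path)
}
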