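# Candidate-site screening and conditional logistic regression for
# 1:1-matched incident-disease case-control pairs. For 1:1 matching the
# conditional likelihood equals that of an intercept-free logistic model on
# within-pair (case - control) differences with all responses equal to 1;
# it is maximised here by Newton iterations with step-halving.

#' Screen candidate CpG sites for prospective follow-up
#'
#' Candidates are sites in the concordant "both" set of the two islet
#' analyses that also map into at least one differentially expressed gene
#' window, ordered deterministically by chromosome and position.
#'
#' @param concordance A `concordance` object from [concordant_sites()].
#' @param site_gene_map Mapping tibble (`probe_id`, `gene_id`) from
#'   [sites_in_gene_windows()].
#' @param degs Gene/DEG tibble (`gene_id`, `q_expression`).
#' @param manifest Probe manifest with `probe_id`, `chromosome`, `pos0`
#'   (for ordering).
#' @param q_threshold Expression significance threshold; default 0.05.
#' @return A tibble with `probe_id`, `chromosome`, `pos0` and
#'   `genes` (comma-separated DEG ids), possibly empty.
#' @export
screen_candidate_sites <- function(concordance, site_gene_map, degs, manifest,
                                   q_threshold = 0.05) {
  deg_ids <- degs$gene_id[!is.na(degs$q_expression) & degs$q_expression < q_threshold]
  hits <- dplyr::filter(site_gene_map,
                        .data$probe_id %in% concordance$both$probe_id,
                        .data$gene_id %in% deg_ids)
  if (nrow(hits) == 0) {
    return(tibble(probe_id = character(), chromosome = character(),
                  pos0 = numeric(), genes = character()))
  }
  agg <- dplyr::summarise(dplyr::group_by(hits, .data$probe_id),
                          genes = paste(sort(unique(.data$gene_id)), collapse = ","),
                          .groups = "drop")
  out <- dplyr::inner_join(agg,
                           manifest[, c("probe_id", "chromosome", "pos0")],
                           by = "probe_id")
  dplyr::arrange(out,
                 factor(.data$chromosome, levels = chrom_levels(.data$chromosome)),
                 .data$pos0)[, c("probe_id", "chromosome", "pos0", "genes")]
}

# Validate pair structure and return within-pair (case - control) differences
# for the given numeric columns: a matrix with one row per pair.
pair_differences <- function(pairs, vars) {
  assert_columns(pairs, c("pair_id", "is_case", vars), "matched-pair table")
  isc <- as.logical(pairs$is_case)
  split_idx <- split(seq_len(nrow(pairs)), pairs$pair_id)
  bad <- vapply(split_idx, function(ix) {
    length(ix) != 2 || sum(isc[ix]) != 1
  }, logical(1))
  if (any(bad)) {
    abort(sprintf("pair '%s' does not have exactly one case and one control",
                  names(split_idx)[which(bad)[1]]))
  }
  D <- t(vapply(split_idx, function(ix) {
    ca <- ix[isc[ix]]
    co <- ix[!isc[ix]]
    vapply(vars, function(v) as.numeric(pairs[[v]][ca]) - as.numeric(pairs[[v]][co]),
           numeric(1))
  }, numeric(length(vars))))
  if (length(vars) == 1) D <- matrix(D, ncol = 1)
  colnames(D) <- vars
  rownames(D) <- names(split_idx)
  D
}

#' Conditional logistic regression for 1:1-matched pairs
#'
#' Maximises the 1:1 conditional likelihood for one candidate site plus
#' optional adjustment covariates: with within-pair differences `d_i`
#' (case minus control), `loglik(b) = sum_i log plogis(d_i' b)`. Newton
#' iterations with step-halving stop when successive log-likelihoods differ
#' by less than `tol` (default 1e-10) or after `max_iter` (default 50)
#' iterations, flagging the cap. Pairs with zero difference in every
#' predictor are non-informative and dropped (counted). Separation is
#' declared when any standardised coefficient `|b_j| * sd(d_j)` exceeds
#' `sep_bound` (default 15); a separated fit is flagged and carries no
#' estimate. The predictor is on the percent scale, so the coefficient reads
#' "per 1 percentage point of methylation".
#'
#' @param pairs Long tibble, two rows per pair: `pair_id`, logical
#'   `is_case`, the site column, optional adjustment covariate columns.
#' @param site Name of the methylation column (percent scale).
#' @param adjust Optional character vector of adjustment covariate columns
#'   (numeric; matched covariates difference out and must not be listed).
#' @param tol,max_iter,sep_bound Convergence / separation controls.
#' @return An object of class `cond_logit_fit` with [tidy()] and [glance()]
#'   methods. Key fields: `coef` (log OR per unit), `se`, `odds_ratio`,
#'   `ci` (Wald 95%), `p`, `n_pairs`, `n_informative`, `converged`, `flag`
#'   (`"ok"`, `"non_informative"`, `"separation"`, or `"max_iter"`).
#' @export
conditional_logistic <- function(pairs, site, adjust = NULL,
                                 tol = 1e-10, max_iter = 50, sep_bound = 15) {
  vars <- c(site, adjust)
  D_all <- pair_differences(pairs, vars)
  n_pairs <- nrow(D_all)
  if (n_pairs < 2) abort("at least 2 pairs are required")
  informative <- rowSums(abs(D_all) > 0) > 0
  n_inf <- sum(informative)
  base <- list(site = site, adjust = adjust, n_pairs = n_pairs,
               n_informative = n_inf)
  if (n_inf == 0 || all(D_all[informative, site] == 0)) {
    return(structure(c(base, list(
      coef = NA_real_, se = NA_real_, vcov = NULL, odds_ratio = NA_real_,
      ci = c(NA_real_, NA_real_), p = NA_real_, loglik = NA_real_,
      iterations = 0L, converged = FALSE, flag = "non_informative")),
      class = "cond_logit_fit"))
  }
  D <- D_all[informative, , drop = FALSE]
  # adjustment columns that difference out entirely cannot be estimated
  keep_col <- colSums(abs(D) > 0) > 0
  D <- D[, keep_col, drop = FALSE]
  k <- ncol(D)

  loglik <- function(b) sum(plogis(drop(D %*% b), log.p = TRUE))
  b <- rep(0, k)
  ll <- loglik(b)
  converged <- FALSE
  iter <- 0L
  H <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    p_i <- plogis(drop(D %*% b))
    g <- drop(crossprod(D, 1 - p_i))
    H <- crossprod(D, D * (p_i * (1 - p_i)))
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving: never accept a decrease in the log-likelihood
    lambda <- 1
    repeat {
      b_new <- b + lambda * step
      ll_new <- loglik(b_new)
      if (ll_new >= ll || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    done <- abs(ll_new - ll) < tol
    b <- b_new; ll <- ll_new
    if (done) { converged <- TRUE; break }
  }
  sds <- apply(D, 2, sd)
  sds[sds == 0] <- 1
  separated <- any(abs(b) * sds > sep_bound)
  if (separated) {
    return(structure(c(base, list(
      coef = NA_real_, se = NA_real_, vcov = NULL, odds_ratio = NA_real_,
      ci = c(NA_real_, NA_real_), p = NA_real_, loglik = ll,
      iterations = iter, converged = FALSE, flag = "separation")),
      class = "cond_logit_fit"))
  }
  p_i <- plogis(drop(D %*% b))
  H <- crossprod(D, D * (p_i * (1 - p_i)))
  V <- solve(H)
  j <- match(site, colnames(D))
  se <- unname(sqrt(V[j, j]))
  bj <- unname(b[j])
  z <- bj / se
  structure(c(base, list(
    coef = bj, se = se, vcov = V,
    coef_all = setNames(b, colnames(D)),
    odds_ratio = exp(bj),
    ci = exp(bj + c(-1, 1) * qnorm(0.975) * se),
    p = 2 * pnorm(-abs(z)),
    loglik = ll, iterations = iter, converged = converged,
    flag = if (converged) "ok" else "max_iter")),
    class = "cond_logit_fit")
}

#' @export
print.cond_logit_fit <- function(x, ...) {
  cat(sprintf("Conditional logistic fit for '%s' (1:1 matched pairs)\n", x$site))
  cat(sprintf("  pairs: %d (informative: %d)   flag: %s\n",
              x$n_pairs, x$n_informative, x$flag))
  if (x$flag %in% c("ok", "max_iter")) {
    cat(sprintf("  OR per pp: %.4f  (95%% CI %.4f-%.4f)  p = %.3g\n",
                x$odds_ratio, x$ci[1], x$ci[2], x$p))
  }
  invisible(x)
}

#' @method tidy cond_logit_fit
#' @export
tidy.cond_logit_fit <- function(x, ...) {
  tibble(term = x$site, estimate = x$coef, std.error = x$se,
         statistic = if (is.na(x$se)) NA_real_ else x$coef / x$se,
         p.value = x$p, odds.ratio = x$odds_ratio,
         conf.low = x$ci[1], conf.high = x$ci[2])
}

#' @method glance cond_logit_fit
#' @export
glance.cond_logit_fit <- function(x, ...) {
  tibble(site = x$site, odds_ratio = x$odds_ratio,
         or_ci_low = x$ci[1], or_ci_high = x$ci[2], p = x$p,
         n_pairs = x$n_pairs, n_informative = x$n_informative,
         iterations = x$iterations, converged = x$converged, flag = x$flag)
}
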