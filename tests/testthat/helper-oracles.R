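# Independent oracles and small fixture builders used across the suite.
# Every oracle is a deliberately naive implementation (normal equations,
# double loops, hand IRLS) kept separate from the code paths it checks.

# OLS via raw normal equations: coefficients, se, t for one response.
ols_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  bhat <- solve(XtX, t(X) %*% y)
  res <- y - X %*% bhat
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  covb <- sigma2 * solve(XtX)
  se <- sqrt(diag(covb))
  list(coef = drop(bhat), se = se, t = drop(bhat) / se, df = df)
}

# Benjamini-Hochberg step-up, written out directly from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# All-pairs point-in-interval scan (0-based half-open).
brute_overlap <- function(sites, features) {
  vapply(seq_len(nrow(sites)), function(i) {
    any(features$chrom == sites$chrom[i] &
          features$start <= sites$pos0[i] &
          sites$pos0[i] < features$end)
  }, logical(1))
}

# Logistic regression by hand-rolled IRLS (with intercept).
irls_oracle <- function(X, y, tol = 1e-12, max_iter = 100) {
  b <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    b_new <- solve(t(X) %*% (X * w), t(X) %*% (w * z))
    if (max(abs(b_new - b)) < tol) { b <- drop(b_new); break }
    b <- drop(b_new)
  }
  drop(b)
}

# A tiny deterministic methylation fixture: n samples x p sites with known
# structure and a matching sample table.
toy_cohort <- function(n = 24, p = 30, seed = 42) {
  withr::with_seed(seed, {
    group <- rep(c("control", "case"), length.out = n)
    samples <- tibble::tibble(
      sample_id = sprintf("s%02d", seq_len(n)),
      group = group,
      hba1c = round(ifelse(group == "case", rnorm(n, 50, 6), rnorm(n, 37, 3)), 1),
      age = round(rnorm(n, 60, 8), 1),
      bmi = round(rnorm(n, 26, 3), 1),
      sex = sample(c("M", "F"), n, replace = TRUE),
      purity = round(runif(n, 70, 100), 1),
      days_culture = 1 + rpois(n, 2)
    )
    beta <- matrix(runif(p * n, 0.05, 0.95), nrow = p,
                   dimnames = list(sprintf("cg%05d", seq_len(p)), samples$sample_id))
    mat <- dplyr::bind_cols(tibble::tibble(probe_id = rownames(beta)),
                            tibble::as_tibble(beta))
    list(mat = mat, samples = samples)
  })
}

# Random site/feature instances for overlap property tests.
random_sites <- function(n, seed, chroms = c("chr1", "chr2", "chr3")) {
  withr::with_seed(seed, tibble::tibble(
    probe_id = sprintf("cg%06d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    pos0 = sample.int(5e4, n, replace = TRUE) - 1
  ))
}

random_features <- function(n, seed, chroms = c("chr1", "chr2", "chr3")) {
  withr::with_seed(seed, {
    start <- sample.int(5e4, n, replace = TRUE) - 1
    tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                   start = start,
                   end = start + sample.int(2000, n, replace = TRUE))
  })
}

# Matched pairs with a binary exposure: n10 pairs case-exposed, n01 pairs
# control-exposed, n_conc concordant pairs.
binary_pairs <- function(n10, n01, n_conc = 0) {
  rows <- list()
  id <- 0
  add <- function(x_case, x_ctrl) {
    id <<- id + 1
    rows[[id]] <<- tibble::tibble(pair_id = sprintf("p%03d", id),
                                  is_case = c(TRUE, FALSE),
                                  x = c(x_case, x_ctrl))
  }
  for (i in seq_len(n10)) add(1, 0)
  for (i in seq_len(n01)) add(0, 1)
  for (i in seq_len(n_conc)) add(1, 1)
  dplyr::bind_rows(rows)
}
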