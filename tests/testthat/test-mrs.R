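test_that("gene selection requires a differential gene with at least six significant sites", {
  # hand-enumerated toy: g1 has 6 significant sites + DEG -> selected;
  # g2 has 5 -> rejected; g3 has 7 but not a DEG -> rejected; g4 has 2 -> rejected
  map <- tibble::tibble(
    probe_id = c(sprintf("a%d", 1:6), sprintf("b%d", 1:5),
                 sprintf("c%d", 1:7), sprintf("d%d", 1:2)),
    gene_id = rep(c("g1", "g2", "g3", "g4"), c(6, 5, 7, 2)))
  ewas <- tibble::tibble(probe_id = map$probe_id, q_value = 0.01,
                         coefficient_m = 1)
  degs <- tibble::tibble(gene_id = c("g1", "g2", "g4"), q_expression = 0.001)
  sel <- select_mrs_genes(ewas, degs, map)
  expect_equal(sel$gene_id, "g1")
  expect_equal(sel$n_sig_sites, 6)
  # push one g2 site over the line -> g2 selected too
  map2 <- dplyr::bind_rows(map, tibble::tibble(probe_id = "b6", gene_id = "g2"))
  ewas2 <- tibble::tibble(probe_id = map2$probe_id, q_value = 0.01, coefficient_m = 1)
  expect_setequal(select_mrs_genes(ewas2, degs, map2)$gene_id, c("g1", "g2"))
  expect_equal(nrow(select_mrs_genes(ewas[0, ], degs, map)), 0)
})

test_that("risk scores are exact weighted sums of methylation percent", {
  mat <- tibble::tibble(probe_id = c("cg1", "cg2"), s1 = c(0.80, 0.40))
  sc <- compute_mrs(mat, c("cg1", "cg2"), c(0.5, -0.2))
  expect_equal(sc$score, 0.5 * 80 - 0.2 * 40)  # 32.0 by hand
  expect_equal(compute_mrs(mat, "cg1", 1)$score, 80)
  expect_equal(compute_mrs(mat, c("cg1", "cg2"), c(0, 0))$score, 0)
  expect_error(compute_mrs(mat, "cgX", 1), "unknown site")
  expect_error(compute_mrs(mat, c("cg1", "cg2"), 1), "same length")
})

test_that("risk scores are linear in the weights and impute site means", {
  tc <- toy_cohort(n = 12, p = 8, seed = 23)
  sites <- tc$mat$probe_id[1:4]
  w <- c(0.4, -0.1, 0.2, 0.05)
  s1 <- compute_mrs(tc$mat, sites, w)
  s3 <- compute_mrs(tc$mat, sites, 3 * w)
  expect_equal(s3$score, 3 * s1$score, tolerance = 1e-12)
  mat_na <- tc$mat
  mat_na[1, "s05"] <- NA
  s_imp <- compute_mrs(mat_na, sites, w)
  expect_equal(attr(s_imp, "n_imputed"), 1)
  manual <- mean(as.numeric(mat_na[1, -1]), na.rm = TRUE)
  delta <- w[1] * 100 * (manual - tc$mat$s05[1])
  expect_equal(s_imp$score[s_imp$sample_id == "s05"],
               s1$score[s1$sample_id == "s05"] + delta, tolerance = 1e-9)
})

test_that("covariate-free logistic association equals the 2x2 cross-product odds ratio", {
  # exposed-case 20, exposed-control 10, unexposed-case 10, unexposed-control 20
  n <- c(ec = 20, ec0 = 10, uc = 10, uc0 = 20)
  samples <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:60),
    group = rep(c("case", "control", "case", "control"), n))
  scores <- tibble::tibble(sample_id = samples$sample_id,
                           score = rep(c(1, 1, 0, 0), n))
  fit <- mrs_association(scores, samples, covariates = character())
  gl <- glance(fit)
  expect_equal(gl$odds_ratio, (20 * 20) / (10 * 10), tolerance = 1e-6)
  expect_false(gl$separation)
})

test_that("logistic estimates match a hand-rolled IRLS oracle", {
  tc <- toy_cohort(n = 40, p = 2, seed = 29)
  scores <- withr::with_seed(30, tibble::tibble(
    sample_id = tc$samples$sample_id,
    score = rnorm(40, ifelse(tc$samples$group == "case", 55, 50), 6)))
  fit <- mrs_association(scores, tc$samples, covariates = c("age", "bmi"))
  X <- cbind(1, scores$score, tc$samples$age, tc$samples$bmi)
  y <- as.numeric(tc$samples$group == "case")
  b_oracle <- irls_oracle(X, y)
  expect_equal(unname(coef(fit$logistic)), unname(b_oracle), tolerance = 1e-6)
  # linear side against the normal-equations oracle
  lo <- ols_oracle(cbind(1, y, tc$samples$age, tc$samples$bmi), scores$score)
  expect_equal(glance(fit)$linear_beta, unname(lo$coef[2]), tolerance = 1e-8)
  expect_equal(glance(fit)$linear_se, unname(lo$se[2]), tolerance = 1e-8)
  # tidy() exposes both models
  td <- tidy(fit)
  expect_setequal(unique(td$model), c("linear", "logistic"))
})

test_that("complete separation is flagged, with no silent odds ratio", {
  samples <- tibble::tibble(sample_id = sprintf("s%02d", 1:30),
                            group = rep(c("case", "control"), each = 15))
  scores <- tibble::tibble(sample_id = samples$sample_id,
                           score = c(rnorm(15, 100, 1), rnorm(15, 0, 1)))
  fit <- mrs_association(scores, samples, covariates = character())
  expect_true(fit$separation)
  expect_true(is.na(glance(fit)$odds_ratio))
})

test_that("null scores give odds ratios centred on 1 over replicates", {
  ors <- vapply(1:30, function(i) {
    withr::with_seed(400 + i, {
      samples <- tibble::tibble(sample_id = sprintf("s%03d", 1:100),
                                group = rep(c("case", "control"), each = 50))
      scores <- tibble::tibble(sample_id = samples$sample_id,
                               score = rnorm(100, 50, 5))
      glance(mrs_association(scores, samples, covariates = character()))$odds_ratio
    })
  }, numeric(1))
  expect_lt(abs(mean(log(ors))), 0.03)
})

test_that("weights on the percent scale reproduce per-site group differences", {
  coh <- simulate_cohort(cohort_config(n_sites = 300, n_genes = 30,
                                       frac_differential = 0.05, seed = 44))
  tr <- coh$truth$sites
  planted <- tr$probe_id[tr$is_differential][1:5]
  w <- mrs_weights(coh$beta, coh$samples, planted)
  expect_equal(w$probe_id, planted)
  # weight sign tracks the planted direction
  dirs <- tr$direction[match(planted, tr$probe_id)]
  expect_true(all(sign(w$weight) == dirs))
  # m-scale weights agree in sign
  wm <- mrs_weights(coh$beta, coh$samples, planted, scale = "m")
  expect_true(all(sign(wm$weight) == dirs))
})
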