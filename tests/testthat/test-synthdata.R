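test_that("cohort configuration validates its fields by name", {
  expect_error(cohort_config(n_cases = 0), "n_cases")
  expect_error(cohort_config(frac_differential = 1.2), "frac_differential")
  expect_error(cohort_config(noise_sd_m = 0), "noise_sd_m")
  expect_error(cohort_config(covariate_params = list(
    age = c(mean = 61, sd = 9), bmi = c(mean = 26, sd = 3), sex_male_frac = 0.6,
    purity = c(mean = 65, sd = 7), days_culture_lambda = 2)), "purity")
  expect_error(simulate_cohort(list()), "cohort_config")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- cohort_config(n_sites = 300, n_genes = 30, seed = 17)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # and byte-identical in serialised form
  fa <- tempfile(); fb <- tempfile()
  write_methylation_matrix(a$beta, fa)
  write_methylation_matrix(b$beta, fb)
  expect_identical(readLines(fa), readLines(fb))
  # a different seed changes the draw
  expect_false(identical(a$beta,
                         simulate_cohort(cohort_config(n_sites = 300, n_genes = 30,
                                                       seed = 18))$beta))
})

test_that("a null configuration plants nothing", {
  cfg <- cohort_config(n_sites = 200, n_genes = 20, frac_differential = 0,
                       planted_delta_pp = 0, seed = 2)
  coh <- simulate_cohort(cfg)
  expect_equal(sum(coh$truth$sites$is_differential), 0)
  expect_true(all(coh$truth$sites$direction == 0))
})

test_that("planted beta differences are calibrated to the requested size", {
  # study-scale cohort: n = 100, 5000 sites, 2% differential at 10 pp
  coh <- simulate_cohort(cohort_config(seed = 1))
  tr <- coh$truth$sites
  M <- as.matrix(coh$beta[, -1])
  case <- coh$samples$group == "case"
  d <- 100 * (rowMeans(M[tr$is_differential, case]) -
                rowMeans(M[tr$is_differential, !case]))
  signed <- d * tr$direction[tr$is_differential]
  expect_equal(mean(signed), 10, tolerance = 0.1)  # within +/- 1 pp of 10
  expect_true(abs(mean(signed) - 10) < 1)
  # convergence at n = 500 within +/- 0.5 pp
  coh5 <- simulate_cohort(cohort_config(n_controls = 375, n_cases = 125,
                                        n_sites = 1000, n_genes = 60,
                                        frac_differential = 0.1, seed = 4))
  tr5 <- coh5$truth$sites
  M5 <- as.matrix(coh5$beta[, -1])
  case5 <- coh5$samples$group == "case"
  d5 <- 100 * (rowMeans(M5[tr5$is_differential, case5]) -
                 rowMeans(M5[tr5$is_differential, !case5]))
  expect_true(abs(mean(d5 * tr5$direction[tr5$is_differential]) - 10) < 0.5)
})

test_that("covariates and phenotypes respect the configured distributions", {
  coh <- simulate_cohort(cohort_config(seed = 9))
  s <- coh$samples
  expect_true(all(s$purity >= 70 & s$purity <= 100))
  expect_true(all(s$hba1c >= 23 & s$hba1c <= 86))
  expect_gt(mean(s$hba1c[s$group == "case"]), mean(s$hba1c[s$group == "control"]))
  expect_true(all(s$sex %in% c("M", "F")))
  expect_true(all(s$days_culture >= 1))
  b <- as.matrix(coh$beta[, -1])
  expect_true(all(b > 0 & b < 1))
  # every differential site is assigned an existing differential gene
  tr <- coh$truth$sites[coh$truth$sites$is_differential, ]
  expect_true(all(tr$gene_id %in% coh$truth$genes$gene_id[coh$truth$genes$is_deg]))
  expect_true(all(tr$direction != 0))
})

test_that("annotation tracks cover planted sites as configured", {
  coh <- simulate_cohort(cohort_config(n_sites = 400, n_genes = 40, seed = 21))
  sites <- tibble::tibble(probe_id = coh$manifest$probe_id,
                          chrom = coh$manifest$chromosome,
                          pos0 = coh$manifest$pos0)
  diff_sites <- sites[coh$truth$sites$is_differential, ]

  # overlap fraction 0: no differential site falls in any track
  tr0 <- simulate_annotation_tracks(coh$manifest, coh$truth$sites,
                                    overlap_frac = 0, seed = 5)
  for (t in tr0) expect_equal(sum(brute_overlap(diff_sites, t)), 0)

  # overlap fraction 1: every differential site inside each track (brute scan)
  tr1 <- simulate_annotation_tracks(coh$manifest, coh$truth$sites,
                                    overlap_frac = 1, seed = 5)
  expect_true(all(brute_overlap(diff_sites, tr1$FOXA2)))
  expect_true(all(brute_overlap(diff_sites, tr1$OCR)))
  expect_named(tr1, c("OCR", "FOXA2", "MAFB", "NKX2.2", "NKX6.1", "PDX1", "regulome"))
  expect_true(all(tr1$regulome$label %in% c("active_promoter", "enhancer_I",
                                            "enhancer_II", "enhancer_III",
                                            "strong_CTCF")))
  # deterministic under seed
  tr1b <- simulate_annotation_tracks(coh$manifest, coh$truth$sites,
                                     overlap_frac = 1, seed = 5)
  expect_identical(lapply(tr1, as.data.frame), lapply(tr1b, as.data.frame))
  expect_error(simulate_annotation_tracks(coh$manifest[0, ], coh$truth$sites),
               "empty")
})

test_that("matched pairs share matching covariates exactly", {
  cfg <- matched_cohort_config(n_pairs = 50, candidate_site_ids = c("cgA", "cgB"),
                               log_or_per_pp = c(0.2, 0), seed = 6)
  pp <- simulate_matched_blood_cohort(cfg)
  expect_equal(nrow(pp), 100)
  by_pair <- split(pp, pp$pair_id)
  for (p in by_pair) {
    expect_equal(nrow(p), 2)
    expect_equal(sum(p$is_case), 1)
    expect_equal(p$age[1], p$age[2])
    expect_equal(p$sex[1], p$sex[2])
  }
  expect_true(all(pp$cgA >= 0 & pp$cgA <= 100))
  expect_identical(pp, simulate_matched_blood_cohort(cfg))
  expect_error(matched_cohort_config(n_pairs = 1), "n_pairs")
  expect_error(matched_cohort_config(candidate_site_ids = character()),
               "candidate_site_ids")
})

test_that("a null matched cohort yields odds ratios centred on 1", {
  lors <- vapply(1:40, function(i) {
    cfg <- matched_cohort_config(n_pairs = 200, candidate_site_ids = "cg1",
                                 log_or_per_pp = 0, seed = 100 + i)
    conditional_logistic(simulate_matched_blood_cohort(cfg), "cg1")$coef
  }, numeric(1))
  expect_lt(abs(mean(lors)), 0.02)
})
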