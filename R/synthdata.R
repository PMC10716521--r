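# Synthetic islet cohorts with planted ground truth. The generator emulates
# the structure of a ~100-donor case/control islet cohort (with a continuous
# HbA1c phenotype on the same donors), a probe manifest, a gene/DEG table,
# regulatory interval tracks, and a 1:1-matched incident-disease blood
# cohort. Differential effects are planted additively on the M scale and
# numerically calibrated so the expected case-control beta difference equals
# the requested percentage points.

tf_track_names <- c("FOXA2", "MAFB", "NKX2.2", "NKX6.1", "PDX1")
regulome_states <- c("active_promoter", "enhancer_I", "enhancer_II",
                     "enhancer_III", "strong_CTCF")

#' Configuration for a synthetic islet cohort
#'
#' Defaults mirror the emulated study conditions: 75 controls and 25 cases;
#' donor covariates drawn from the clinical characteristics of the islet
#' cohorts (age ~ N(61.4, 9) years, BMI ~ N(26.3, 3.5) kg/m2, 63% male,
#' islet purity ~ N(83, 7) confined to \[70, 100\]%, days in culture
#' 1 + Poisson(2)); HbA1c ~ N(37, 3) mmol/mol for controls and N(50, 6) for
#' cases, clipped to \[23, 86\]; 77% of planted differential sites
#' hypomethylated in cases.
#'
#' @param n_controls,n_cases,n_sites,n_genes Cohort and universe sizes.
#' @param frac_differential Fraction of sites with a planted effect.
#' @param planted_delta_pp Mean case-control beta difference at true sites,
#'   percentage points.
#' @param hba1c_slope_pp_per_unit Planted methylation change per mmol/mol of
#'   HbA1c at true sites (percentage points), entering through the
#'   within-group HbA1c residual so the case-control difference stays at
#'   `planted_delta_pp`.
#' @param frac_hypo Fraction of planted sites hypomethylated in cases.
#' @param covariate_params Named list of covariate distribution parameters;
#'   see defaults.
#' @param noise_sd_m Within-group residual standard deviation on the M
#'   scale (> 0).
#' @param seed Master integer seed. Sub-streams use fixed documented offsets
#'   (covariates +11, HbA1c +13, truth/placement +17, baselines +19,
#'   noise +23) so adding a generator never perturbs the others.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_controls = 75, n_cases = 25,
                          n_sites = 5000, n_genes = 300,
                          frac_differential = 0.02,
                          planted_delta_pp = 10,
                          hba1c_slope_pp_per_unit = 0.5,
                          frac_hypo = 0.77,
                          covariate_params = list(
                            age = c(mean = 61.4, sd = 9),
                            bmi = c(mean = 26.3, sd = 3.5),
                            sex_male_frac = 0.63,
                            purity = c(mean = 83.2, sd = 7),
                            days_culture_lambda = 2
                          ),
                          noise_sd_m = 0.5,
                          seed = 1L) {
  cfg <- list(n_controls = n_controls, n_cases = n_cases, n_sites = n_sites,
              n_genes = n_genes, frac_differential = frac_differential,
              planted_delta_pp = planted_delta_pp,
              hba1c_slope_pp_per_unit = hba1c_slope_pp_per_unit,
              frac_hypo = frac_hypo, covariate_params = covariate_params,
              noise_sd_m = noise_sd_m, seed = seed)
  for (f in c("n_controls", "n_cases", "n_sites", "n_genes")) {
    assert_scalar_count(cfg[[f]], f)
  }
  assert_fraction(frac_differential, "frac_differential")
  assert_fraction(frac_hypo, "frac_hypo")
  if (!is.numeric(planted_delta_pp) || planted_delta_pp < 0 || planted_delta_pp > 90) {
    abort_config("planted_delta_pp", "must be in [0, 90] percentage points")
  }
  if (!is.numeric(noise_sd_m) || length(noise_sd_m) != 1 || noise_sd_m <= 0) {
    abort_config("noise_sd_m", "must be a single positive number")
  }
  pur <- covariate_params$purity
  if (is.null(pur) || pur[["mean"]] < 70 || pur[["mean"]] > 100) {
    abort_config("covariate_params$purity", "mean must lie in [70, 100]")
  }
  assert_scalar_count(seed, "seed", min = 0)
  structure(cfg, class = "cohort_config")
}

# Expected beta-value of m0 + sd * Z, Z ~ N(0,1), by Gauss-Hermite
# quadrature (31 nodes). Vectorised over m0.
gh_nodes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pracma::gaussHermite(31)
    cache
  }
})

expected_beta <- function(m0, sd) {
  gh <- gh_nodes()
  z <- sqrt(2) * gh$x
  w <- gh$w / sqrt(pi)
  vapply(m0, function(m) sum(w * m_to_beta(m + sd * z)), numeric(1))
}

# Signed M-scale shift dm such that E[beta(m0 + dm + sd Z)] - E[beta(m0 + sd Z)]
# equals delta_beta (a signed fraction).
calibrate_m_shift <- function(m0, delta_beta, sd) {
  vapply(seq_along(m0), function(i) {
    if (delta_beta[i] == 0) return(0)
    base <- expected_beta(m0[i], sd[i])
    f <- function(dm) expected_beta(m0[i] + dm, sd[i]) - base - delta_beta[i]
    uniroot(f, interval = c(-25, 25), tol = 1e-10)$root
  }, numeric(1))
}

#' Simulate a synthetic islet cohort with planted truth
#'
#' Draws per-site baseline beta-values (a bimodal mixture for null sites),
#' plants case-control effects on the M scale calibrated so the expected
#' beta difference at true sites equals `planted_delta_pp`, plants an HbA1c
#' association at the same sites with concordant sign, and records all
#' planted structure in a truth table. Differential sites are placed inside
#' the windows of designated differentially expressed genes (up to 8 sites
#' per gene) so the downstream gene-window and risk-score stages have
#' recoverable signal. Output is identical for identical seeds.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `beta` (methylation tibble: `probe_id` +
#'   sample columns), `samples` (sample table), `manifest` (probe manifest
#'   with `pos0`), `degs` (gene/DEG table), and `truth` (list of `sites`
#'   and `genes` tibbles).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort_config("config", "must be created with cohort_config()")
  }
  n <- config$n_controls + config$n_cases
  sample_id <- c(sprintf("ctrl%03d", seq_len(config$n_controls)),
                 sprintf("case%03d", seq_len(config$n_cases)))
  group <- rep(c("control", "case"), c(config$n_controls, config$n_cases))
  case_ind <- as.numeric(group == "case")
  cp <- config$covariate_params

  samples <- withr::with_seed(sub_seed(config$seed, 11), {
    tibble(
      sample_id = sample_id,
      group = group,
      age = round(clip(rnorm(n, cp$age[["mean"]], cp$age[["sd"]]), 30, 85), 1),
      bmi = round(clip(rnorm(n, cp$bmi[["mean"]], cp$bmi[["sd"]]), 18, 40.1), 1),
      sex = ifelse(runif(n) < cp$sex_male_frac, "M", "F"),
      purity = round(clip(rnorm(n, cp$purity[["mean"]], cp$purity[["sd"]]), 70, 100), 1),
      days_culture = 1 + rpois(n, cp$days_culture_lambda)
    )
  })
  samples$hba1c <- withr::with_seed(sub_seed(config$seed, 13), {
    round(clip(ifelse(case_ind == 1, rnorm(n, 50, 6), rnorm(n, 37, 3)), 23, 86), 1)
  })

  truth <- withr::with_seed(sub_seed(config$seed, 17), {
    plant_truth(config)
  })
  manifest <- truth$manifest
  site_truth <- truth$sites
  gene_truth <- truth$genes
  degs <- truth$degs

  beta0 <- withr::with_seed(sub_seed(config$seed, 19), {
    draw_baselines(site_truth, config$planted_delta_pp / 100)
  })
  m0 <- beta_to_m(beta0)

  # Calibrate planted shifts (deterministic given baselines and HbA1c draws).
  is_diff <- site_truth$is_differential
  dm <- rep(0, config$n_sites)
  sm <- rep(0, config$n_sites)
  hb_resid <- samples$hba1c -
    ifelse(case_ind == 1, mean(samples$hba1c[case_ind == 1]),
           mean(samples$hba1c[case_ind == 0]))
  if (any(is_diff)) {
    delta_signed <- site_truth$direction[is_diff] * config$planted_delta_pp / 100
    # local d(beta)/d(M) = ln2 * beta (1 - beta); slope per mmol/mol on M scale
    sm[is_diff] <- (config$hba1c_slope_pp_per_unit / 100) /
      (log(2) * beta0[is_diff] * (1 - beta0[is_diff]))
    sd_eff <- sqrt(config$noise_sd_m^2 + (sm[is_diff] * sd(hb_resid))^2)
    dm[is_diff] <- calibrate_m_shift(m0[is_diff], delta_signed, sd_eff)
  }

  M <- withr::with_seed(sub_seed(config$seed, 23), {
    matrix(rnorm(config$n_sites * n, sd = config$noise_sd_m),
           nrow = config$n_sites, ncol = n)
  })
  M <- M + m0 + outer(dm, case_ind) +
    (site_truth$direction * sm) %o% hb_resid
  beta <- matrix(m_to_beta(M), nrow = config$n_sites,
                 dimnames = list(site_truth$probe_id, sample_id))

  list(beta = meth_as_tibble(round(beta, 6)),
       samples = samples,
       manifest = manifest,
       degs = degs,
       truth = list(sites = site_truth, genes = gene_truth))
}

# Lay out genes and sites on the genome, pick differential sites and DEGs,
# and build manifest / DEG / truth tables. Runs inside a seeded block.
plant_truth <- function(config) {
  n_sites <- config$n_sites
  n_genes <- config$n_genes
  n_diff <- round(config$frac_differential * n_sites)

  gene_id <- sprintf("gene%04d", seq_len(n_genes))
  gene_chrom <- paste0("chr", sample(1:22, n_genes, replace = TRUE))
  gene_start <- round(runif(n_genes, 1e5, 2e8))
  gene_end <- gene_start + round(runif(n_genes, 5e3, 5e4))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)

  sites_per_deg <- 8
  n_deg <- if (n_diff > 0) {
    min(n_genes, max(1, ceiling(n_diff / sites_per_deg)))
  } else {
    max(1, round(0.05 * n_genes))
  }
  deg_genes <- sample(gene_id, n_deg)
  # methylation direction per planted gene: hypo in cases with prob frac_hypo
  gene_meth_dir <- ifelse(runif(n_deg) < config$frac_hypo, -1L, 1L)

  # every site starts near a random gene (within +/- 8 kb of the body)
  site_gene <- sample(gene_id, n_sites, replace = TRUE)
  gi <- match(site_gene, gene_id)
  pos0 <- round(runif(n_sites, gene_start[gi] - 8e3, gene_end[gi] + 8e3 - 1))

  is_differential <- rep(FALSE, n_sites)
  direction <- rep(0L, n_sites)
  if (n_diff > 0) {
    diff_idx <- seq_len(n_diff)  # deterministic block; ids are arbitrary labels
    assigned_gene <- rep(deg_genes, each = sites_per_deg)[seq_len(n_diff)]
    gi_d <- match(assigned_gene, gene_id)
    site_gene[diff_idx] <- assigned_gene
    pos0[diff_idx] <- round(runif(n_diff, gene_start[gi_d] - 8e3,
                                  gene_end[gi_d] + 8e3 - 1))
    is_differential[diff_idx] <- TRUE
    direction[diff_idx] <- gene_meth_dir[match(assigned_gene, deg_genes)]
  }
  ord <- sample(n_sites)  # shuffle so truth is not positional
  site_gene <- site_gene[ord]; pos0 <- pos0[ord]
  is_differential <- is_differential[ord]; direction <- direction[ord]

  probe_id <- sprintf("cg%08d", seq_len(n_sites))
  manifest <- tibble(
    probe_id = probe_id,
    chromosome = gene_chrom[match(site_gene, gene_id)],
    position = pos0 + 1,
    mean_detection_p = runif(n_sites, 0, 0.005),
    class_flags = "",
    gene_annotation = site_gene,
    pos0 = pos0
  )

  is_deg <- gene_id %in% deg_genes
  expr_dir <- rep(0L, n_genes)
  # expression direction opposite to planted methylation direction (promoter
  # convention); null genes get small noise around zero
  expr_dir[is_deg] <- -gene_meth_dir[match(gene_id[is_deg], deg_genes)]
  log2fc <- rnorm(n_genes, 0, 0.1)
  log2fc[is_deg] <- expr_dir[is_deg] * runif(sum(is_deg), 0.5, 2)
  q_expr <- runif(n_genes, 0.1, 1)
  q_expr[is_deg] <- runif(sum(is_deg), 1e-6, 0.04)

  degs <- tibble(gene_id = gene_id, chromosome = gene_chrom,
                 start = gene_start, end = gene_end, strand = strand,
                 log2_fold_change = round(log2fc, 4),
                 q_expression = signif(q_expr, 4))

  list(
    manifest = manifest,
    sites = tibble(probe_id = probe_id,
                   is_differential = is_differential,
                   direction = direction,
                   planted_delta_pp = ifelse(is_differential, config$planted_delta_pp, 0),
                   gene_id = site_gene),
    genes = tibble(gene_id = gene_id, is_deg = is_deg,
                   expression_direction = expr_dir),
    degs = degs
  )
}

# Baseline beta-values: bimodal mixture for null sites (arrays are dominated
# by near-0 and near-1 sites); planted sites drawn mid-range so the target
# shift keeps beta inside (0.02, 0.98).
draw_baselines <- function(site_truth, delta) {
  n <- nrow(site_truth)
  u <- runif(n)
  beta0 <- ifelse(u < 0.40, rbeta(n, 2, 10),
                  ifelse(u < 0.80, rbeta(n, 10, 2), rbeta(n, 5, 5)))
  beta0 <- clip(beta0, 0.02, 0.98)
  idx <- which(site_truth$is_differential)
  if (length(idx) > 0) {
    dirs <- site_truth$direction[idx]
    lo <- ifelse(dirs < 0, 0.07 + delta, 0.10)
    hi <- ifelse(dirs > 0, 0.93 - delta, 0.90)
    beta0[idx] <- runif(length(idx), lo, hi)
  }
  beta0
}

#' Simulate regulatory annotation tracks over a probe manifest
#'
#' Builds an open-chromatin (OCR) track, five named islet transcription
#' factor tracks (FOXA2, MAFB, NKX2.2, NKX6.1, PDX1), and a regulome track
#' with chromatin-state labels. For each track, a configurable fraction of
#' true differential sites is covered by an interval centred on the site, so
#' downstream overlap stages have planted signal; background intervals are
#' placed around randomly chosen null sites and never cover a differential
#' site. Deterministic under `seed`.
#'
#' @param manifest Probe manifest (needs `probe_id`, `chromosome`, `pos0`).
#' @param truth Site truth table from [simulate_cohort()]
#'   (`truth$sites`); pass a table with `is_differential = FALSE` everywhere
#'   to plant no signal.
#' @param overlap_frac Fraction of differential sites covered by each track,
#'   in `[0, 1]`.
#' @param halfwidth Interval half-width in bp (features are
#'   `[pos - halfwidth, pos + halfwidth + 1)`).
#' @param n_background Number of background intervals per track; default 5%
#'   of sites.
#' @param seed Integer seed (sub-streams offset per track).
#' @return A named list of `interval_track` objects: `OCR`, the five TF
#'   tracks, and `regulome`.
#' @export
simulate_annotation_tracks <- function(manifest, truth, overlap_frac = 0.6,
                                       halfwidth = 250, n_background = NULL,
                                       seed = 1L) {
  if (nrow(manifest) == 0) abort("probe manifest is empty")
  assert_fraction(overlap_frac, "overlap_frac")
  assert_columns(manifest, c("probe_id", "chromosome", "pos0"), "probe manifest")
  st <- truth[match(manifest$probe_id, truth$probe_id), , drop = FALSE]
  diff_idx <- which(st$is_differential %in% TRUE)
  null_idx <- setdiff(seq_len(nrow(manifest)), diff_idx)
  n_background <- n_background %||% max(1L, round(0.05 * nrow(manifest)))

  make_track <- function(name, offset, labels = NULL) {
    withr::with_seed(sub_seed(seed, offset), {
      sel <- if (length(diff_idx) > 0 && overlap_frac > 0) {
        sample(diff_idx, round(overlap_frac * length(diff_idx)))
      } else integer(0)
      bg <- sample(null_idx, min(n_background, length(null_idx)))
      idx <- c(sel, bg)
      feats <- tibble(
        chrom = manifest$chromosome[idx],
        start = pmax(0, manifest$pos0[idx] - halfwidth),
        end = manifest$pos0[idx] + halfwidth + 1,
        label = if (is.null(labels)) name else sample(labels, length(idx), replace = TRUE),
        planted = c(rep(TRUE, length(sel)), rep(FALSE, length(bg)))
      )
      # background intervals must not swallow a differential site by chance
      if (length(diff_idx) > 0 && any(!feats$planted)) {
        covers_diff <- vapply(seq_len(nrow(feats)), function(i) {
          any(manifest$chromosome[diff_idx] == feats$chrom[i] &
                manifest$pos0[diff_idx] >= feats$start[i] &
                manifest$pos0[diff_idx] < feats$end[i])
        }, logical(1))
        feats <- feats[feats$planted | !covers_diff, , drop = FALSE]
      }
      feats <- dplyr::arrange(feats[, c("chrom", "start", "end", "label")],
                              factor(.data$chrom, levels = chrom_levels(.data$chrom)),
                              .data$start)
      interval_track(feats, name = name)
    })
  }

  tracks <- c(
    list(OCR = make_track("OCR", 101)),
    setNames(lapply(seq_along(tf_track_names), function(i) {
      make_track(tf_track_names[i], 101 + 10 * i)
    }), tf_track_names),
    list(regulome = make_track("regulome", 997, labels = regulome_states))
  )
  tracks
}

#' Configuration for a 1:1-matched prospective blood cohort
#'
#' @param n_pairs Number of case-control pairs (>= 2).
#' @param candidate_site_ids Non-empty character vector of candidate CpG ids
#'   measured in blood.
#' @param log_or_per_pp Planted log odds ratio of incident disease per
#'   percentage point of methylation; a scalar applied to every candidate
#'   site or a vector aligned with `candidate_site_ids` (0 = null site).
#' @param site_mean_pct,site_sd_pct Blood methylation mean and
#'   between-individual standard deviation, percent.
#' @param matching_covariates Covariates shared exactly within a pair
#'   (subset of `age`, `sex`).
#' @param seed Integer seed.
#' @return A validated list of class `matched_cohort_config`.
#' @export
matched_cohort_config <- function(n_pairs = 500,
                                  candidate_site_ids = "cg00000001",
                                  log_or_per_pp = 0,
                                  site_mean_pct = 50, site_sd_pct = 3,
                                  matching_covariates = c("age", "sex"),
                                  seed = 1L) {
  assert_scalar_count(n_pairs, "n_pairs", min = 2)
  if (length(candidate_site_ids) == 0) {
    abort_config("candidate_site_ids", "must be non-empty")
  }
  if (!length(log_or_per_pp) %in% c(1L, length(candidate_site_ids))) {
    abort_config("log_or_per_pp", "must be scalar or one value per candidate site")
  }
  if (!all(matching_covariates %in% c("age", "sex"))) {
    abort_config("matching_covariates", "must be a subset of c('age', 'sex')")
  }
  assert_scalar_count(seed, "seed", min = 0)
  structure(list(n_pairs = n_pairs,
                 candidate_site_ids = as.character(candidate_site_ids),
                 log_or_per_pp = rep_len(log_or_per_pp, length(candidate_site_ids)),
                 site_mean_pct = site_mean_pct, site_sd_pct = site_sd_pct,
                 matching_covariates = matching_covariates, seed = seed),
            class = "matched_cohort_config")
}

#' Simulate a 1:1-matched incident-disease blood cohort
#'
#' Each pair shares its matching covariates exactly. Both members draw blood
#' methylation percentages at the candidate sites; the case label within a
#' pair is then drawn from the exact 1:1 conditional likelihood
#' `P(member 1 is the case) = logistic(theta' (x1 - x2))` with `theta` the
#' planted per-percentage-point log odds ratios — so conditional logistic
#' regression recovers the planted effects without bias. A per-member waist
#' circumference column is included as an unmatched adjustment covariate.
#'
#' @param config A [matched_cohort_config()].
#' @return A tibble, two rows per pair, with `pair_id`, `is_case`, the
#'   matching covariates, `waist`, and one `%`-scale column per candidate
#'   site.
#' @export
simulate_matched_blood_cohort <- function(config) {
  if (!inherits(config, "matched_cohort_config")) {
    abort_config("config", "must be created with matched_cohort_config()")
  }
  np <- config$n_pairs
  k <- length(config$candidate_site_ids)
  withr::with_seed(sub_seed(config$seed, 31), {
    age <- round(clip(rnorm(np, 52, 8), 35, 65))
    sex <- ifelse(runif(np) < 0.5, "M", "F")
    waist <- round(rnorm(2 * np, 95, 11), 1)
    x <- matrix(clip(rnorm(2 * np * k, config$site_mean_pct, config$site_sd_pct),
                     0, 100), nrow = 2 * np, ncol = k)
    colnames(x) <- config$candidate_site_ids
    m1 <- seq(1, 2 * np, by = 2)
    m2 <- m1 + 1
    eta_diff <- (x[m1, , drop = FALSE] - x[m2, , drop = FALSE]) %*% config$log_or_per_pp
    first_is_case <- runif(np) < plogis(drop(eta_diff))
    is_case <- logical(2 * np)
    is_case[m1] <- first_is_case
    is_case[m2] <- !first_is_case
    out <- tibble(
      pair_id = rep(sprintf("pair%04d", seq_len(np)), each = 2),
      is_case = is_case,
      age = rep(age, each = 2),
      sex = rep(sex, each = 2),
      waist = waist
    )
    out <- out[, c("pair_id", "is_case",
                   intersect(c("age", "sex"), config$matching_covariates), "waist")]
    dplyr::bind_cols(out, as_tibble(round(x, 4)))
  })
}
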