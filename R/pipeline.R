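# End-to-end orchestration: simulate (optional) -> probe filter -> EWAS
# (binary) -> EWAS (continuous) -> concordance -> regulatory overlaps ->
# gene windows -> methylation risk scores -> prospective matched-pair
# analysis, with a machine-readable run manifest. Rerunning with the same
# configuration and seed reproduces identical outputs.

#' Configuration for a full pipeline run
#'
#' Either supply input paths (`methylation`, `samples`, `manifest`, `degs`,
#' `pairs`, plus BED `tracks`) or leave them `NULL` to simulate everything
#' from `cohort` / `matched` configurations.
#'
#' @param cohort A [cohort_config()] used when simulating.
#' @param matched A [matched_cohort_config()] or `NULL` to derive one from
#'   the screened candidates (planted null effects).
#' @param paths Optional named list of input paths (run mode); all referenced
#'   paths must exist.
#' @param covariates Covariate column names for the islet models.
#' @param q_threshold Significance threshold in `(0, 1)`; strict `<`.
#' @param flank Gene-window flank in bp (>= 0).
#' @param mrs_scale Weight scale for risk scores: `"beta_pct"` or `"m"`.
#' @param window_anchor `"body"` or `"tss"`.
#' @param overlap_frac Planted track-overlap fraction (simulate mode).
#' @param out_dir Output directory (created; name carries no timestamp so
#'   reruns are comparable).
#' @param seed Master seed for all simulated stages.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            matched = NULL,
                            paths = NULL,
                            covariates = c("age", "bmi", "sex", "purity", "days_culture"),
                            q_threshold = 0.05,
                            flank = 10000,
                            mrs_scale = c("beta_pct", "m"),
                            window_anchor = c("body", "tss"),
                            overlap_frac = 0.6,
                            out_dir = "isletewas-run",
                            seed = 1L) {
  mrs_scale <- match.arg(mrs_scale)
  window_anchor <- match.arg(window_anchor)
  if (!is.numeric(q_threshold) || q_threshold <= 0 || q_threshold >= 1) {
    abort_config("q_threshold", "must lie in (0, 1)")
  }
  if (!is.numeric(flank) || flank < 0) abort_config("flank", "must be >= 0")
  if (!is.null(paths)) {
    need <- c("methylation", "samples", "manifest", "degs")
    missing_keys <- setdiff(need, names(paths))
    if (length(missing_keys) > 0) {
      abort_config("paths", sprintf("missing entries: %s", paste(missing_keys, collapse = ", ")))
    }
    gone <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(gone) > 0) {
      abort_config("paths", sprintf("file(s) not found: %s", paste(gone, collapse = ", ")))
    }
  }
  structure(list(cohort = cohort, matched = matched, paths = paths,
                 covariates = covariates, q_threshold = q_threshold,
                 flank = flank, mrs_scale = mrs_scale,
                 window_anchor = window_anchor, overlap_frac = overlap_frac,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage: %s\nerror: %s", name, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order, writes each stage's table under
#' `config$out_dir`, and finishes with `run_manifest.json` recording the
#' package and R versions, seed, configuration echo and per-stage row
#' counts. A stage error halts the run, names the stage, and leaves partial
#' outputs alongside a `FAILED` marker.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort_config("config", "must be created with pipeline_config()")
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out_dir, "FAILED"))
  counts <- list()

  inputs <- run_stage("input", out_dir, {
    if (is.null(config$paths)) {
      cohort <- simulate_cohort(config$cohort)
      tracks <- simulate_annotation_tracks(cohort$manifest, cohort$truth$sites,
                                           overlap_frac = config$overlap_frac,
                                           seed = config$seed)
      write_methylation_matrix(cohort$beta, file.path(out_dir, "methylation.tsv"))
      write_sample_table(cohort$samples, file.path(out_dir, "samples.tsv"))
      write_probe_manifest(cohort$manifest, file.path(out_dir, "manifest.tsv"))
      write_deg_table(cohort$degs, file.path(out_dir, "degs.tsv"))
      readr::write_tsv(cohort$truth$sites, file.path(out_dir, "truth_sites.tsv"))
      readr::write_tsv(cohort$truth$genes, file.path(out_dir, "truth_genes.tsv"))
      dir.create(file.path(out_dir, "tracks"), showWarnings = FALSE)
      for (nm in names(tracks)) {
        write_interval_track(tracks[[nm]], file.path(out_dir, "tracks", paste0(nm, ".bed")))
      }
      c(cohort, list(tracks = tracks))
    } else {
      p <- config$paths
      list(beta = read_methylation_matrix(p$methylation),
           samples = read_sample_table(p$samples),
           manifest = read_probe_manifest(p$manifest),
           degs = read_deg_table(p$degs),
           truth = NULL,
           tracks = if (!is.null(p$tracks)) {
             setNames(lapply(p$tracks, read_interval_track), names(p$tracks))
           } else list())
    }
  })
  counts$sites_input <- nrow(inputs$beta)
  counts$samples <- nrow(inputs$samples)

  filtered <- run_stage("filter", out_dir, {
    fp <- filter_probes(inputs$manifest)
    readr::write_tsv(fp$report, file.path(out_dir, "filter_report.tsv"))
    beta <- inputs$beta[inputs$beta$probe_id %in% fp$retained_ids, , drop = FALSE]
    beta <- drop_high_missing_probes(beta)
    list(beta = beta, manifest = fp$manifest)
  })
  counts$sites_retained <- nrow(filtered$beta)

  ewas_binary <- run_stage("ewas_binary", out_dir, {
    e <- run_ewas(filtered$beta, inputs$samples, "binary", config$covariates)
    write_ewas_table(e, file.path(out_dir, "ewas_binary.tsv"))
    e
  })
  counts$ewas_binary_sig <- sum(ewas_binary$q_value < config$q_threshold, na.rm = TRUE)

  ewas_hba1c <- run_stage("ewas_continuous", out_dir, {
    e <- run_ewas(filtered$beta, inputs$samples, "continuous", config$covariates)
    write_ewas_table(e, file.path(out_dir, "ewas_hba1c.tsv"))
    e
  })
  counts$ewas_hba1c_sig <- sum(ewas_hba1c$q_value < config$q_threshold, na.rm = TRUE)

  conc <- run_stage("concordance", out_dir, {
    cc <- concordant_sites(ewas_binary, ewas_hba1c, config$q_threshold)
    readr::write_tsv(cc$both, file.path(out_dir, "concordant_sites.tsv"))
    readr::write_tsv(cc$quadrant_counts, file.path(out_dir, "concordance_counts.tsv"))
    cc
  })
  counts$concordant <- nrow(conc$both)

  sig_sites <- dplyr::transmute(
    dplyr::filter(filtered$manifest,
                  .data$probe_id %in% ewas_binary$probe_id[
                    !is.na(ewas_binary$q_value) & ewas_binary$q_value < config$q_threshold]),
    probe_id = .data$probe_id, chrom = .data$chromosome, pos0 = .data$pos0)

  overlaps <- run_stage("overlaps", out_dir, {
    if (length(inputs$tracks) > 0) {
      ann <- annotate_sites(sig_sites, inputs$tracks, inputs$degs, config$flank)
      readr::write_tsv(ann, file.path(out_dir, "annotated_sites.tsv"))
      tf <- inputs$tracks[intersect(names(inputs$tracks), tf_track_names)]
      tally <- if (length(tf) > 0) multi_track_membership(sig_sites, tf)$tally else NULL
      if (!is.null(tally)) readr::write_tsv(tally, file.path(out_dir, "tf_membership_tally.tsv"))
      list(annotated = ann, tf_tally = tally)
    } else {
      list(annotated = NULL, tf_tally = NULL)
    }
  })
  counts$sites_in_ocr <- if (!is.null(overlaps$annotated)) sum(overlaps$annotated$in_ocr) else 0L

  windows <- run_stage("gene_windows", out_dir, {
    all_sites <- dplyr::transmute(filtered$manifest, probe_id = .data$probe_id,
                                  chrom = .data$chromosome, pos0 = .data$pos0)
    gw <- sites_in_gene_windows(all_sites, inputs$degs, config$flank,
                                anchor = config$window_anchor)
    readr::write_tsv(gw$map, file.path(out_dir, "site_gene_map.tsv"))
    gw
  })
  counts$site_gene_links <- nrow(windows$map)

  mrs <- run_stage("mrs", out_dir, {
    genes <- select_mrs_genes(ewas_binary, inputs$degs, windows$map,
                              config$q_threshold)
    rows <- purrr::map(genes$gene_id, function(g) {
      site_ids <- intersect(
        windows$map$probe_id[windows$map$gene_id == g],
        ewas_binary$probe_id[!is.na(ewas_binary$q_value) &
                               ewas_binary$q_value < config$q_threshold])
      w <- mrs_weights(filtered$beta, inputs$samples, site_ids,
                       config$covariates, scale = config$mrs_scale)
      sc <- compute_mrs(filtered$beta, w$probe_id, w$weight)
      gl <- glance(mrs_association(sc, inputs$samples, config$covariates))
      dplyr::bind_cols(tibble(gene_id = g, n_sites = length(site_ids)), gl)
    })
    tab <- dplyr::bind_rows(rows)
    readr::write_tsv(tab, file.path(out_dir, "mrs.tsv"))
    tab
  })
  counts$mrs_genes <- nrow(mrs)

  prospective <- run_stage("prospective", out_dir, {
    cand <- screen_candidate_sites(conc, windows$map, inputs$degs,
                                   filtered$manifest, config$q_threshold)
    readr::write_tsv(cand, file.path(out_dir, "candidate_sites.tsv"))
    matched_cfg <- config$matched
    if (is.null(matched_cfg) && nrow(cand) > 0) {
      matched_cfg <- matched_cohort_config(
        n_pairs = 200,
        candidate_site_ids = cand$probe_id,
        log_or_per_pp = 0,
        seed = config$seed)
    }
    if (is.null(matched_cfg)) {
      list(candidates = cand, results = tibble())
    } else {
      pairs <- simulate_matched_blood_cohort(matched_cfg)
      readr::write_tsv(pairs, file.path(out_dir, "matched_pairs.tsv"))
      res <- dplyr::bind_rows(purrr::map(
        intersect(matched_cfg$candidate_site_ids, names(pairs)),
        function(s) glance(conditional_logistic(pairs, s, adjust = "waist"))))
      readr::write_tsv(res, file.path(out_dir, "prospective.tsv"))
      list(candidates = cand, results = res)
    }
  })
  counts$candidates <- nrow(prospective$candidates)
  counts$prospective_fits <- nrow(prospective$results)

  manifest <- list(
    software = list(package = "isletewas",
                    version = as.character(packageVersion("isletewas")),
                    r_version = paste(R.version$major, R.version$minor, sep = ".")),
    seed = config$seed,
    config = config_echo(config),
    stage_rows = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(inputs = inputs, filtered = filtered,
                 ewas_binary = ewas_binary, ewas_hba1c = ewas_hba1c,
                 concordance = conc, overlaps = overlaps, windows = windows,
                 mrs = mrs, prospective = prospective, manifest = manifest))
}

# Flatten the configuration for the JSON manifest (drop non-scalar guts of
# sub-configs down to their own fields).
config_echo <- function(config) {
  list(
    cohort = unclass(config$cohort),
    matched = if (!is.null(config$matched)) unclass(config$matched) else NULL,
    paths = config$paths,
    covariates = config$covariates,
    q_threshold = config$q_threshold,
    flank = config$flank,
    mrs_scale = config$mrs_scale,
    window_anchor = config$window_anchor,
    overlap_frac = config$overlap_frac,
    out_dir = config$out_dir,
    seed = config$seed
  )
}
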