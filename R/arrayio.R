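# Readers, writers and probe filtering for the tabular/genomic formats the
# pipeline touches. All tables are UTF-8 TSV with a header; interval tracks
# are BED3/BED4. Internal genomic coordinates are 0-based half-open: manifest
# positions are read 1-based and converted on load (`pos0 = position - 1`).

# Every writer emits a small sidecar text file (<path>.sidecar.txt) logging
# row counts and filter decisions, so written artifacts are self-describing.
write_sidecar <- function(path, n_rows, what, extra = character()) {
  lines <- c(sprintf("file: %s", basename(path)),
             sprintf("content: %s", what),
             sprintf("rows: %d", n_rows),
             extra)
  writeLines(lines, paste0(path, ".sidecar.txt"))
  invisible(path)
}

#' Read a methylation beta-value matrix from TSV
#'
#' Expects a header row of sample ids, a first column of probe ids, and
#' beta-values in `[0, 1]`. Empty fields and `NA` are treated as missing.
#' Out-of-range values and duplicated probe or sample ids raise validation
#' errors that name the offending location.
#'
#' @param path Path to a tab-delimited text file.
#' @return A tibble with `probe_id` plus one numeric column per sample.
#' @export
read_methylation_matrix <- function(path) {
  mat <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    probe_id = readr::col_character()
  ), na = c("", "NA"), progress = FALSE)
  assert_columns(mat, "probe_id", "methylation matrix")
  if (anyDuplicated(mat$probe_id)) {
    abort(sprintf("duplicated probe id: %s", mat$probe_id[anyDuplicated(mat$probe_id)]))
  }
  samp <- setdiff(names(mat), "probe_id")
  if (anyDuplicated(samp)) abort("duplicated sample ids in header")
  for (s in samp) {
    x <- mat[[s]]
    bad <- which(!is.na(x) & (x < 0 | x > 1))
    if (length(bad) > 0) {
      abort(sprintf("beta-value out of [0, 1] at probe '%s', sample '%s': %g",
                    mat$probe_id[bad[1]], s, x[bad[1]]))
    }
  }
  mat
}

#' Write a methylation beta-value matrix as TSV
#'
#' @param mat Tibble with `probe_id` plus numeric sample columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylation_matrix <- function(mat, path) {
  assert_columns(mat, "probe_id", "methylation matrix")
  readr::write_tsv(mat, path, progress = FALSE)
  write_sidecar(path, nrow(mat),
                sprintf("methylation beta matrix, %d samples", ncol(mat) - 1))
  invisible(path)
}

#' Read a sample table from TSV
#'
#' Requires `sample_id` and at least one of `group` (case/control) or
#' `hba1c`; covariate columns are passed through as typed by the file.
#'
#' @param path Path to a tab-delimited text file.
#' @return A tibble, one row per sample.
#' @export
read_sample_table <- function(path) {
  st <- readr::read_tsv(path, col_types = readr::cols(), na = c("", "NA"),
                        progress = FALSE)
  assert_columns(st, "sample_id", "sample table")
  if (!any(c("group", "hba1c") %in% names(st))) {
    abort("sample table must contain at least one of 'group' or 'hba1c'")
  }
  if (anyDuplicated(st$sample_id)) abort("duplicated sample ids in sample table")
  st
}

#' @rdname read_sample_table
#' @param samples Sample tibble to write.
#' @export
write_sample_table <- function(samples, path) {
  readr::write_tsv(samples, path, progress = FALSE)
  write_sidecar(path, nrow(samples), "sample table")
  invisible(path)
}

#' Read a probe manifest from TSV
#'
#' Columns: `probe_id`, `chromosome`, `position` (1-based bp),
#' `mean_detection_p`, `class_flags` (comma-separated subset of
#' `Y_chromosome`, `rs_probe`, `ch_probe`, `cross_reactive`, `polymorphic`;
#' empty for a clean probe) and optional `gene_annotation`. A 0-based
#' `pos0` column is derived on load.
#'
#' @param path Path to a tab-delimited text file.
#' @return A tibble, one row per probe.
#' @export
read_probe_manifest <- function(path) {
  mf <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    chromosome = readr::col_character(),
    position = readr::col_double(),
    mean_detection_p = readr::col_double(),
    class_flags = readr::col_character(),
    .default = readr::col_guess()
  ), na = "NA", progress = FALSE)
  mf$class_flags[is.na(mf$class_flags)] <- ""
  validate_manifest(mf)
  mf$pos0 <- mf$position - 1
  mf
}

probe_flag_levels <- c("Y_chromosome", "rs_probe", "ch_probe",
                       "cross_reactive", "polymorphic")

validate_manifest <- function(mf) {
  assert_columns(mf, c("probe_id", "chromosome", "position",
                       "mean_detection_p", "class_flags"), "probe manifest")
  if (any(mf$position < 1, na.rm = TRUE)) abort("manifest positions must be >= 1 (1-based)")
  flags <- unlist(strsplit(mf$class_flags[mf$class_flags != ""], ","))
  unknown <- setdiff(trimws(flags), probe_flag_levels)
  if (length(unknown) > 0) {
    abort(sprintf("unknown probe class flag(s): %s", paste(unique(unknown), collapse = ", ")))
  }
  invisible(mf)
}

#' @rdname read_probe_manifest
#' @param manifest Manifest tibble to write (the derived `pos0` column is
#'   dropped; positions are stored 1-based).
#' @export
write_probe_manifest <- function(manifest, path) {
  readr::write_tsv(dplyr::select(manifest, -dplyr::any_of("pos0")), path,
                   progress = FALSE)
  write_sidecar(path, nrow(manifest), "probe manifest (positions 1-based)")
  invisible(path)
}

#' Read an interval track from BED text
#'
#' BED3/BED4: tab-separated `chrom start end [label]`, 0-based half-open,
#' stored exactly as read. Lines with `start >= end` or non-numeric
#' coordinates raise an error.
#'
#' @param path Path to a BED file.
#' @param name Track name (defaults to the file stem).
#' @return A tibble of class `interval_track` with columns `chrom`, `start`,
#'   `end`, `label`, and a `track_name` attribute.
#' @export
read_interval_track <- function(path, name = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) abort(sprintf("BED line %d has fewer than 3 fields", which(nf < 3)[1]))
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("non-numeric coordinate on BED line %d",
                  which(is.na(start) | is.na(end))[1]))
  }
  if (any(start < 0)) abort("BED start coordinates must be non-negative")
  if (any(start >= end)) {
    abort(sprintf("BED line %d has start >= end", which(start >= end)[1]))
  }
  label <- ifelse(nf >= 4, vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, ""),
                  NA_character_)
  interval_track(tibble(chrom = chrom, start = start, end = end, label = label),
                 name = name %||% sub("\\.bed$", "", basename(path)))
}

#' Construct an interval track
#'
#' @param features Tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and optional `label`.
#' @param name Track name.
#' @return The features tibble classed `interval_track` with a `track_name`
#'   attribute.
#' @export
interval_track <- function(features, name) {
  assert_columns(features, c("chrom", "start", "end"), "interval track")
  if (!"label" %in% names(features)) features$label <- NA_character_
  if (any(features$start < 0)) abort("interval starts must be non-negative")
  if (any(features$start >= features$end)) abort("every interval must satisfy start < end")
  structure(as_tibble(features[, c("chrom", "start", "end", "label")]),
            class = c("interval_track", class(as_tibble(features))),
            track_name = name)
}

#' @rdname read_interval_track
#' @param track An `interval_track` to write (BED4 when labels are present,
#'   BED3 otherwise).
#' @export
write_interval_track <- function(track, path) {
  df <- as_tibble(track)
  has_label <- any(!is.na(df$label))
  cols <- if (has_label) {
    df$label[is.na(df$label)] <- "."
    df[, c("chrom", "start", "end", "label")]
  } else {
    df[, c("chrom", "start", "end")]
  }
  readr::write_tsv(cols, path, col_names = FALSE, progress = FALSE)
  write_sidecar(path, nrow(df),
                sprintf("interval track '%s' (BED, 0-based half-open)",
                        attr(track, "track_name") %||% "unnamed"))
  invisible(path)
}

#' Read a table of differentially expressed genes from TSV
#'
#' Columns: `gene_id`, `chromosome`, `start`, `end` (0-based half-open),
#' `strand`, `log2_fold_change`, `q_expression`. Differential expression is
#' consumed, never computed, by this package.
#'
#' @param path Path to a tab-delimited text file.
#' @return A tibble, one row per gene.
#' @export
read_deg_table <- function(path) {
  dg <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    chromosome = readr::col_character(),
    strand = readr::col_character(),
    .default = readr::col_double()
  ), na = c("", "NA"), progress = FALSE)
  assert_columns(dg, c("gene_id", "chromosome", "start", "end",
                       "log2_fold_change", "q_expression"), "DEG table")
  if (any(dg$start >= dg$end)) abort("DEG table: every gene must satisfy start < end")
  if (any(dg$q_expression < 0 | dg$q_expression > 1, na.rm = TRUE)) {
    abort("DEG table: q_expression must lie in [0, 1]")
  }
  dg
}

#' @rdname read_deg_table
#' @param degs DEG tibble to write.
#' @export
write_deg_table <- function(degs, path) {
  readr::write_tsv(degs, path, progress = FALSE)
  write_sidecar(path, nrow(degs), "gene/DEG table (coordinates 0-based half-open)")
  invisible(path)
}

#' Apply array probe-exclusion rules
#'
#' Removes probes with mean detection p-value at or above the threshold and
#' probes bearing any exclusion-class flag. The removal report counts each
#' probe once, under the first matching class in the fixed priority order:
#' detection, Y chromosome, rs probe, ch probe, cross-reactive, polymorphic.
#' The retained set preserves input order; removing every probe yields an
#' empty result with a warning, not an error.
#'
#' @param manifest Probe manifest tibble (see [read_probe_manifest()]).
#' @param detection_threshold Probes with `mean_detection_p >=` this value
#'   are removed; default 0.01.
#' @return A list with `manifest` (retained rows), `retained_ids`, and
#'   `report` (tibble of class/n_removed, plus a retained row).
#' @export
filter_probes <- function(manifest, detection_threshold = 0.01) {
  if (nrow(manifest) == 0) abort("probe manifest is empty")
  validate_manifest(manifest)
  flags <- strsplit(manifest$class_flags, ",")
  has_flag <- function(f) vapply(flags, function(x) f %in% trimws(x), logical(1))
  classes <- c("detection", probe_flag_levels)
  fail <- cbind(
    detection = !is.na(manifest$mean_detection_p) &
      manifest$mean_detection_p >= detection_threshold,
    vapply(probe_flag_levels, has_flag, logical(nrow(manifest)))
  )
  first_class <- apply(fail, 1, function(r) if (any(r)) classes[which(r)[1]] else NA_character_)
  removed <- !is.na(first_class)
  report <- tibble(
    class = c(classes, "retained"),
    n = c(vapply(classes, function(cl) sum(first_class == cl, na.rm = TRUE), 0L),
          sum(!removed))
  )
  if (all(removed)) warn("all probes removed by filtering")
  list(manifest = manifest[!removed, , drop = FALSE],
       retained_ids = manifest$probe_id[!removed],
       report = report)
}

#' Drop probes with excessive missingness
#'
#' Probes missing in more than `max_missing` of samples are removed before
#' modelling; the remaining sites use complete cases per site.
#'
#' @param mat Methylation tibble (`probe_id` + sample columns).
#' @param max_missing Maximum tolerated fraction of missing samples per
#'   probe; default 0.10.
#' @return The filtered methylation tibble, with a `n_dropped` attribute.
#' @export
drop_high_missing_probes <- function(mat, max_missing = 0.1) {
  m <- meth_as_matrix(mat)
  frac <- rowMeans(is.na(m))
  keep <- frac <= max_missing
  out <- mat[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
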