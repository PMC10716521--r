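# Concordance between the two association analyses and genomic integration
# of CpG sites with interval tracks and gene windows. CpG sites are treated
# as 1-bp points (the interrogated cytosine); all coordinates are 0-based
# half-open and overlap is strand-blind. Overlap queries delegate to
# IRanges/GenomicRanges.

sites_granges <- function(sites) {
  assert_columns(sites, c("chrom", "pos0"), "site table")
  GenomicRanges::GRanges(sites$chrom,
                         IRanges::IRanges(start = sites$pos0 + 1, width = 1))
}

features_granges <- function(features) {
  GenomicRanges::GRanges(features$chrom,
                         IRanges::IRanges(start = features$start + 1,
                                          end = features$end))
}

#' Intersect two EWAS tables with directional concordance
#'
#' Sites significant (`q_value < q_threshold`) in both analyses are split by
#' coefficient sign: concordant sites (identical sign in A and B) form the
#' "both" set with an up/up or down/down quadrant label; doubly significant
#' sites with discordant signs are excluded from "both" and listed
#' separately. Both tables must cover the same probe universe.
#'
#' @param ewas_a,ewas_b `ewas_table`s over the same probe ids (e.g. the
#'   case/control and HbA1c analyses).
#' @param q_threshold Significance threshold, strict inequality; default
#'   0.05.
#' @return A list of class `concordance` with tibbles `both` (probe_id,
#'   sign_a, sign_b, quadrant), `a_only`, `b_only`, `discordant`, and a
#'   `quadrant_counts` tibble (up_up / down_down / discordant plus the
#'   exclusive counts).
#' @export
concordant_sites <- function(ewas_a, ewas_b, q_threshold = 0.05) {
  assert_columns(ewas_a, c("probe_id", "coefficient_m", "q_value"), "ewas_a")
  assert_columns(ewas_b, c("probe_id", "coefficient_m", "q_value"), "ewas_b")
  if (!setequal(ewas_a$probe_id, ewas_b$probe_id)) {
    abort("the two EWAS tables must cover the same probe universe")
  }
  b <- ewas_b[match(ewas_a$probe_id, ewas_b$probe_id), , drop = FALSE]
  sig_a <- !is.na(ewas_a$q_value) & ewas_a$q_value < q_threshold
  sig_b <- !is.na(b$q_value) & b$q_value < q_threshold
  sign_a <- sign(ewas_a$coefficient_m)
  sign_b <- sign(b$coefficient_m)
  both_sig <- sig_a & sig_b
  concord <- both_sig & sign_a == sign_b & sign_a != 0

  sa_c <- sign_a[concord]
  both <- tibble(probe_id = ewas_a$probe_id[concord],
                 sign_a = sa_c, sign_b = sign_b[concord],
                 quadrant = ifelse(sa_c > 0, "up_up", "down_down"))
  disc <- both_sig & !concord
  discordant <- tibble(probe_id = ewas_a$probe_id[disc],
                       sign_a = sign_a[disc], sign_b = sign_b[disc])
  res <- list(
    both = both,
    a_only = tibble(probe_id = ewas_a$probe_id[sig_a & !sig_b]),
    b_only = tibble(probe_id = ewas_a$probe_id[sig_b & !sig_a]),
    discordant = discordant,
    quadrant_counts = tibble(
      group = c("up_up", "down_down", "discordant", "a_only", "b_only"),
      n = c(sum(both$quadrant == "up_up"), sum(both$quadrant == "down_down"),
            nrow(discordant), sum(sig_a & !sig_b), sum(sig_b & !sig_a))
    ),
    q_threshold = q_threshold
  )
  structure(res, class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("Directional concordance at q < %g\n", x$q_threshold))
  cat(sprintf("  both (concordant): %d  [up/up %d, down/down %d]\n",
              nrow(x$both),
              sum(x$both$quadrant == "up_up"),
              sum(x$both$quadrant == "down_down")))
  cat(sprintf("  A only: %d   B only: %d   discordant: %d\n",
              nrow(x$a_only), nrow(x$b_only), nrow(x$discordant)))
  invisible(x)
}

#' Overlap CpG sites with one interval track
#'
#' A site at 0-based position `p` is inside a feature `[s, e)` iff
#' `s <= p < e`.
#'
#' @param sites Tibble with `probe_id`, `chrom`, `pos0`.
#' @param track An `interval_track` (or tibble with `chrom`, `start`, `end`).
#' @return The sites tibble with an added logical `in_track` column; the
#'   attribute `n_overlap` holds the member count.
#' @export
overlap_sites_track <- function(sites, track) {
  if (nrow(sites) == 0) {
    out <- dplyr::mutate(sites, in_track = logical(0))
    attr(out, "n_overlap") <- 0L
    return(out)
  }
  flags <- if (nrow(track) == 0) {
    rep(FALSE, nrow(sites))
  } else {
    q <- sites_granges(sites)
    s <- features_granges(track)
    hits <- GenomicRanges::findOverlaps(q, s)
    out <- rep(FALSE, nrow(sites))
    out[unique(S4Vectors::queryHits(hits))] <- TRUE
    out
  }
  out <- dplyr::mutate(sites, in_track = flags)
  attr(out, "n_overlap") <- sum(flags)
  out
}

#' Map CpG sites to flanked gene windows
#'
#' A site maps to a gene iff its 0-based position lies in
#' `[max(0, start - flank), end + flank)` of the gene body (default), or in
#' the `[tss - flank, tss + flank + 1)` window around the strand-aware
#' transcription start site when `anchor = "tss"`. Many-to-many mappings are
#' allowed.
#'
#' @param sites Tibble with `probe_id`, `chrom`, `pos0`.
#' @param genes Gene/DEG tibble with `gene_id`, `chromosome`, `start`,
#'   `end`, `strand`.
#' @param flank Window flank in bp; default 10000 (must be >= 0).
#' @param anchor `"body"` (default) or `"tss"`.
#' @return A list with `map` (tibble `probe_id`, `gene_id`) and
#'   `gene_counts` (tibble `gene_id`, `n_sites` of distinct mapped sites).
#' @export
sites_in_gene_windows <- function(sites, genes, flank = 10000,
                                  anchor = c("body", "tss")) {
  anchor <- match.arg(anchor)
  if (!is.numeric(flank) || length(flank) != 1 || flank < 0) {
    abort("`flank` must be a single non-negative number")
  }
  assert_columns(genes, c("gene_id", "chromosome", "start", "end"), "gene table")
  if (anchor == "tss") {
    strand <- if ("strand" %in% names(genes)) genes$strand else "+"
    tss <- ifelse(strand == "-", genes$end - 1, genes$start)
    win <- tibble(chrom = genes$chromosome,
                  start = pmax(0, tss - flank), end = tss + flank + 1)
  } else {
    win <- tibble(chrom = genes$chromosome,
                  start = pmax(0, genes$start - flank), end = genes$end + flank)
  }
  if (nrow(sites) == 0 || nrow(genes) == 0) {
    return(list(map = tibble(probe_id = character(), gene_id = character()),
                gene_counts = tibble(gene_id = character(), n_sites = integer())))
  }
  hits <- GenomicRanges::findOverlaps(sites_granges(sites), features_granges(win))
  map <- tibble(probe_id = sites$probe_id[S4Vectors::queryHits(hits)],
                gene_id = genes$gene_id[S4Vectors::subjectHits(hits)])
  map <- dplyr::distinct(map)
  gene_counts <- dplyr::summarise(dplyr::group_by(map, .data$gene_id),
                                  n_sites = dplyr::n_distinct(.data$probe_id),
                                  .groups = "drop")
  list(map = map, gene_counts = gene_counts)
}

#' Multi-track membership and k-of-n tally for CpG sites
#'
#' Computes, per site, the subset of tracks containing it and tallies sites
#' by membership cardinality `0..n`; Venn cell counts are derivable from the
#' per-site subsets.
#'
#' @param sites Tibble with `probe_id`, `chrom`, `pos0`.
#' @param tracks Named list of `interval_track`s (names must be unique).
#' @return A list with `membership` (sites tibble + one logical column per
#'   track + `n_tracks`) and `tally` (tibble `cardinality`, `n_sites` for
#'   0..n).
#' @export
multi_track_membership <- function(sites, tracks) {
  if (length(tracks) == 0) abort("at least one track is required")
  nms <- names(tracks) %||% vapply(tracks, function(t) attr(t, "track_name") %||% "", "")
  if (any(!nzchar(nms)) || anyDuplicated(nms)) {
    abort("tracks must carry unique, non-empty names")
  }
  memb <- sites
  for (i in seq_along(tracks)) {
    memb[[nms[i]]] <- overlap_sites_track(sites, tracks[[i]])$in_track
  }
  card <- rowSums(as.matrix(memb[, nms, drop = FALSE]))
  memb$n_tracks <- as.integer(card)
  tally <- tibble(cardinality = 0:length(tracks),
                  n_sites = vapply(0:length(tracks),
                                   function(k) sum(card == k), integer(1)))
  list(membership = memb, tally = tally)
}

#' Annotate significant sites with all regulatory context at once
#'
#' Convenience wrapper combining OCR membership, per-TF membership, regulome
#' state labels, and gene-window mapping into one site-level table.
#'
#' @param sites Tibble with `probe_id`, `chrom`, `pos0`.
#' @param tracks Named list from [simulate_annotation_tracks()] or built by
#'   hand: must contain `OCR`, the TF tracks, and `regulome`.
#' @param genes Gene/DEG tibble.
#' @param flank Gene-window flank in bp.
#' @return A tibble with `probe_id`, `chrom`, `pos0`, `in_ocr`, one logical
#'   column per TF, `n_tf`, `regulome_states` (comma-separated labels), and
#'   `genes_within_window` (comma-separated gene ids).
#' @export
annotate_sites <- function(sites, tracks, genes, flank = 10000) {
  tf <- tracks[intersect(names(tracks), tf_track_names)]
  out <- sites
  out$in_ocr <- if ("OCR" %in% names(tracks)) {
    overlap_sites_track(sites, tracks$OCR)$in_track
  } else FALSE
  if (length(tf) > 0) {
    mm <- multi_track_membership(sites, tf)
    for (nm in names(tf)) out[[nm]] <- mm$membership[[nm]]
    out$n_tf <- mm$membership$n_tracks
  }
  out$regulome_states <- if ("regulome" %in% names(tracks)) {
    reg <- tracks$regulome
    vapply(seq_len(nrow(sites)), function(i) {
      hit <- reg$chrom == sites$chrom[i] &
        reg$start <= sites$pos0[i] & sites$pos0[i] < reg$end
      paste(sort(unique(reg$label[hit])), collapse = ",")
    }, character(1))
  } else ""
  gw <- sites_in_gene_windows(sites, genes, flank = flank)
  agg <- dplyr::summarise(dplyr::group_by(gw$map, .data$probe_id),
                          genes_within_window = paste(sort(.data$gene_id), collapse = ","),
                          .groups = "drop")
  out <- dplyr::left_join(out, agg, by = "probe_id")
  out$genes_within_window[is.na(out$genes_within_window)] <- ""
  out
}
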