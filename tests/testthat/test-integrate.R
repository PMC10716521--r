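make_ewas_stub <- function(ids, q, coef) {
  tibble::tibble(probe_id = ids, coefficient_m = coef, q_value = q)
}

test_that("concordance partitions sites and excludes discordant signs", {
  ids <- sprintf("cg%d", 1:8)
  # hand-enumerated toy: 1,2 concordant up/up; 3 concordant down/down;
  # 4 discordant; 5 A-only; 6 B-only; 7,8 null
  a <- make_ewas_stub(ids, q = c(.01, .02, .01, .001, .01, .50, .90, .40),
                      coef = c(.2, .3, -.1, .2, .4, .1, .2, -.3))
  b <- make_ewas_stub(ids, q = c(.04, .01, .02, .020, .70, .01, .60, .90),
                      coef = c(.5, .1, -.4, -.5, .3, -.2, .1, .2))
  cc <- concordant_sites(a, b, 0.05)
  expect_setequal(cc$both$probe_id, c("cg1", "cg2", "cg3"))
  expect_equal(cc$both$quadrant[cc$both$probe_id == "cg3"], "down_down")
  expect_equal(cc$discordant$probe_id, "cg4")
  expect_equal(cc$a_only$probe_id, "cg5")
  expect_equal(cc$b_only$probe_id, "cg6")
  counts <- setNames(cc$quadrant_counts$n, cc$quadrant_counts$group)
  expect_equal(counts[["up_up"]], 2)
  expect_equal(counts[["down_down"]], 1)
  expect_equal(counts[["discordant"]], 1)
  # the groups partition the union of significant sites
  expect_equal(sort(c(cc$both$probe_id, cc$a_only$probe_id,
                      cc$b_only$probe_id, cc$discordant$probe_id)),
               sort(sprintf("cg%d", 1:6)))
  expect_error(concordant_sites(a, b[1:4, ]), "same probe universe")
})

test_that("the concordant set shrinks as the threshold tightens", {
  withr::with_seed(31, {
    ids <- sprintf("cg%03d", 1:300)
    a <- make_ewas_stub(ids, runif(300), rnorm(300))
    b <- make_ewas_stub(ids, runif(300), rnorm(300))
  })
  sizes <- vapply(c(0.2, 0.1, 0.05, 0.01),
                  function(th) nrow(concordant_sites(a, b, th)$both), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("interval overlap respects half-open boundaries", {
  track <- interval_track(tibble::tibble(chrom = "chr1", start = 100, end = 200), "t")
  sites <- tibble::tibble(probe_id = c("a", "b", "c"), chrom = "chr1",
                          pos0 = c(100, 199, 200))
  ov <- overlap_sites_track(sites, track)
  expect_equal(ov$in_track, c(TRUE, TRUE, FALSE))
  expect_equal(attr(ov, "n_overlap"), 2)
  # empty inputs yield zero, not an error
  expect_equal(attr(overlap_sites_track(sites[0, ], track), "n_overlap"), 0)
})

test_that("overlap equals the all-pairs brute-force scan on random instances", {
  sites <- random_sites(1000, seed = 41)
  feats <- random_features(50, seed = 42)
  track <- interval_track(feats, "rand")
  ov <- overlap_sites_track(sites, track)
  expect_equal(ov$in_track, brute_overlap(sites, feats))
  # invariant to feature order
  shuffled <- interval_track(feats[sample(nrow(feats)), ], "rand")
  expect_equal(overlap_sites_track(sites, shuffled)$in_track, ov$in_track)
  # invariant to splitting a feature [s,e) into [s,m) + [m,e)
  f1 <- feats[1, ]
  mid <- floor((f1$start + f1$end) / 2)
  split_feats <- dplyr::bind_rows(
    feats[-1, ],
    tibble::tibble(chrom = f1$chrom, start = c(f1$start, mid), end = c(mid, f1$end)))
  expect_equal(overlap_sites_track(sites, interval_track(split_feats, "s"))$in_track,
               ov$in_track)
})

test_that("gene windows are body-anchored, flanked, half-open", {
  genes <- tibble::tibble(gene_id = "g1", chromosome = "chr1",
                          start = 50000, end = 60000, strand = "+",
                          log2_fold_change = 1, q_expression = 0.01)
  sites <- tibble::tibble(probe_id = c("in_left", "out_right", "inside"),
                          chrom = "chr1", pos0 = c(40000, 70000, 55000))
  gw <- sites_in_gene_windows(sites, genes, flank = 10000)
  expect_setequal(gw$map$probe_id, c("in_left", "inside"))
  expect_equal(gw$gene_counts$n_sites, 2)
  expect_error(sites_in_gene_windows(sites, genes, flank = -1), "non-negative")
  # TSS anchoring on the minus strand uses the gene end
  genes_m <- dplyr::mutate(genes, strand = "-")
  # tss = 59999 (0-based), window [49999, 70000): 55000 inside, 70000 excluded
  gw_tss <- sites_in_gene_windows(sites, genes_m, flank = 10000, anchor = "tss")
  expect_equal(gw_tss$map$probe_id, "inside")
})

test_that("gene-window mapping equals a brute-force double loop", {
  sites <- random_sites(400, seed = 51)
  withr::with_seed(52, {
    start <- sample.int(4e4, 20)
    genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                            chromosome = sample(c("chr1", "chr2", "chr3"), 20, TRUE),
                            start = start, end = start + sample.int(5000, 20),
                            strand = "+", log2_fold_change = 0, q_expression = 0.5)
  })
  flank <- 3000
  gw <- sites_in_gene_windows(sites, genes, flank = flank)
  brute <- list()
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(genes))) {
      lo <- max(0, genes$start[j] - flank)
      hi <- genes$end[j] + flank
      if (sites$chrom[i] == genes$chromosome[j] &&
          sites$pos0[i] >= lo && sites$pos0[i] < hi) {
        brute[[length(brute) + 1]] <- c(sites$probe_id[i], genes$gene_id[j])
      }
    }
  }
  brute <- do.call(rbind, brute)
  got <- dplyr::arrange(gw$map, probe_id, gene_id)
  want <- dplyr::arrange(tibble::tibble(probe_id = brute[, 1], gene_id = brute[, 2]),
                         probe_id, gene_id)
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("multi-track membership reproduces brute-force Venn cells", {
  sites <- random_sites(200, seed = 61)
  tracks <- setNames(lapply(1:5, function(i) {
    interval_track(random_features(12, seed = 70 + i), sprintf("TF%d", i))
  }), sprintf("TF%d", 1:5))
  mm <- multi_track_membership(sites, tracks)
  brute <- sapply(tracks, function(t) brute_overlap(sites, t))
  expect_equal(as.matrix(mm$membership[, names(tracks)]), brute,
               ignore_attr = TRUE)
  expect_equal(mm$membership$n_tracks, unname(rowSums(brute)))
  expect_equal(mm$tally$n_sites,
               vapply(0:5, function(k) sum(rowSums(brute) == k), integer(1)))
  # venn cell counts derivable from subsets match brute enumeration
  key <- apply(brute, 1, paste, collapse = "")
  key2 <- apply(as.matrix(mm$membership[, names(tracks)]), 1, paste, collapse = "")
  expect_equal(as.vector(table(key2)), as.vector(table(key)))
  expect_equal(names(table(key2)), names(table(key)))
  expect_error(multi_track_membership(sites, tracks[c(1, 1)]), "unique")
})

test_that("saturating and empty tracks give extreme cardinalities", {
  sites <- random_sites(50, seed = 71)
  genome <- interval_track(tibble::tibble(
    chrom = c("chr1", "chr2", "chr3"), start = 0, end = 1e8), "all")
  five <- setNames(lapply(1:5, function(i) genome), sprintf("TF%d", 1:5))
  mm <- multi_track_membership(sites, five)
  expect_true(all(mm$membership$n_tracks == 5))
  empty <- setNames(lapply(1:3, function(i) {
    interval_track(tibble::tibble(chrom = character(), start = numeric(),
                                  end = numeric()), sprintf("E%d", i))
  }), sprintf("E%d", 1:3))
  mm0 <- multi_track_membership(sites, empty)
  expect_true(all(mm0$membership$n_tracks == 0))
})

test_that("planted tracks are enriched among significant sites", {
  coh <- simulate_cohort(cohort_config(n_sites = 1200, n_genes = 60,
                                       frac_differential = 0.05, seed = 33))
  tracks <- simulate_annotation_tracks(coh$manifest, coh$truth$sites,
                                       overlap_frac = 0.8, seed = 33)
  e <- run_ewas(coh$beta, coh$samples, "binary")
  sites <- tibble::tibble(probe_id = coh$manifest$probe_id,
                          chrom = coh$manifest$chromosome,
                          pos0 = coh$manifest$pos0)
  ov <- overlap_sites_track(sites, tracks$OCR)
  sig <- e$q_value[match(sites$probe_id, e$probe_id)] < 0.05
  expect_gt(mean(ov$in_track[sig]), mean(ov$in_track[!sig]))
})
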