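test_that("the paralog filter matches pairs without regard to order", {
  cand <- tibble::tibble(
    gene_a = c("gA", "gB"), gene_b = c("gB", "gC"),
    type = "inter", n_support = 1L,
    supporters = list(tibble::tibble(pair_id = "p", end_in_a = 1L))
  )
  dec <- paralog_filter(cand, tibble::tibble(gene_a = "gB", gene_b = "gA"))
  expect_equal(dec$kept, c(FALSE, TRUE))
  expect_true(all(paralog_filter(cand, NULL)$kept))
  expect_true(all(paralog_filter(cand, tibble::tibble(
    gene_a = character(0), gene_b = character(0)
  ))$kept))
})

test_that("the repeat filter prunes overlapping supporters and matches a nucleotide oracle", {
  models <- tiny_models()
  set.seed(13)
  pairs <- pairs_rbind(lapply(1:12, function(i) {
    s1 <- sample(100:360, 1)
    s2 <- sample(1000:1560, 1)
    make_pair(sprintf("r%02d", i),
      blocks1 = list(c(s1, s1 + 36L)),
      blocks2 = list(c(s2, s2 + 36L))
    )
  }))
  det <- detect_candidates(pairs, models)
  repeats <- tibble::tibble(
    chrom = c("chr1", "chr1"), start = c(150L, 1450L), end = c(190L, 1500L)
  )
  rf <- repeat_filter(det$candidates, det, repeats)
  # per-nucleotide oracle: a pair is pruned iff any of its aligned
  # nucleotides falls inside a repeat interval
  in_rep <- function(s, e, chrom) {
    any(repeats$chrom == chrom & pmax(repeats$start, s) < pmin(repeats$end, e))
  }
  pruned_oracle <- vapply(seq_len(nrow(pairs)), function(i) {
    b1 <- pairs$blocks1[[i]]
    b2 <- pairs$blocks2[[i]]
    in_rep(b1[1, 1], b1[1, 2], "chr1") || in_rep(b2[1, 1], b2[1, 2], "chr1")
  }, logical(1))
  surviving <- unlist(lapply(rf$candidates$supporters, function(s) s$pair_id))
  expect_setequal(surviving, pairs$pair_id[!pruned_oracle])

  # no repeat track: nothing pruned
  rf0 <- repeat_filter(det$candidates, det, NULL)
  expect_equal(rf0$candidates$n_support, det$candidates$n_support)

  # everything in repeats: the candidate is discarded
  rf_all <- repeat_filter(det$candidates, det,
    tibble::tibble(chrom = "chr1", start = 0L, end = 2000L)
  )
  expect_equal(nrow(rf_all$candidates), 0L)
  expect_false(any(rf_all$decisions$kept))
})

test_that("the small-scale similarity filter discards homology-supported candidates", {
  set.seed(14)
  chr1 <- random_dna(600)
  chr2 <- random_dna(600)
  models <- gene_models(tibble::tibble(
    gene_id = c("gP", "gQ"), tx_id = c("gP.1", "gQ.1"),
    chrom = c("chr1", "chr2"), strand = "+", start = 0L, end = 600L
  ))
  genome <- Biostrings::DNAStringSet(c(chr1 = chr1, chr2 = chr2))
  # reads copied verbatim from the partner's sequence: fast step fires
  hom_pair <- make_pair("h1",
    blocks1 = list(c(100L, 136L)), seq1 = substr(chr2, 301, 336),
    chrom2 = "chr2", blocks2 = list(c(300L, 336L)), seq2 = substr(chr2, 101, 136)
  )
  det_hom <- detect_candidates(hom_pair, models)
  dec_hom <- small_scale_similarity_filter(det_hom$candidates, det_hom, models, genome)
  expect_false(dec_hom$kept)
  expect_match(dec_hom$note, "k-mismatch")

  # genuinely distinct reads: kept
  real_pair <- make_pair("h2",
    blocks1 = list(c(100L, 136L)), seq1 = substr(chr1, 101, 136),
    chrom2 = "chr2", blocks2 = list(c(300L, 336L)), seq2 = substr(chr2, 301, 336)
  )
  det_real <- detect_candidates(real_pair, models)
  dec_real <- small_scale_similarity_filter(det_real$candidates, det_real, models, genome)
  expect_true(dec_real$kept)

  # diverged homologous segment (not within 3 mismatches, above 75% local
  # identity): refined step fires
  div_read <- mutate_at_positions(substr(chr2, 301, 336), c(5, 15, 25, 30, 35))
  div_pair <- make_pair("h3",
    blocks1 = list(c(100L, 136L)), seq1 = div_read,
    chrom2 = "chr2", blocks2 = list(c(300L, 336L)), seq2 = substr(chr2, 101, 136)
  )
  det_div <- detect_candidates(div_pair, models)
  dec_div <- small_scale_similarity_filter(det_div$candidates, det_div, models, genome)
  expect_false(dec_div$kept)

  expect_error(
    small_scale_similarity_filter(det_hom$candidates, det_hom, models, NULL),
    "genome"
  )
})

test_that("the ribosomal filter uses the 75%/10% rule", {
  set.seed(15)
  rrna <- Biostrings::DNAStringSet(c(rrna1 = random_dna(400)))
  models <- gene_models(tibble::tibble(
    gene_id = c("gP", "gQ"), tx_id = c("gP.1", "gQ.1"),
    chrom = c("chr1", "chr2"), strand = "+", start = 0L, end = 600L
  ))
  rr <- as.character(rrna[[1]])
  mk <- function(i, seq1) {
    make_pair(sprintf("rr%02d", i),
      blocks1 = list(c(100L + 2L * i, 136L + 2L * i)), seq1 = seq1,
      chrom2 = "chr2", blocks2 = list(c(300L + 2L * i, 336L + 2L * i)),
      seq2 = random_dna(36)
    )
  }
  # 2 of 10 pairs (i.e. 2/20 reads = 10%) carry an rRNA end: not above 10%
  pairs10 <- pairs_rbind(lapply(1:10, function(i) {
    mk(i, if (i <= 2) substr(rr, 50, 85) else random_dna(36))
  }))
  det10 <- detect_candidates(pairs10, models)
  expect_true(ribosomal_filter(det10$candidates, det10, rrna)$kept)

  # 3 of 10 pairs -> 15% of reads: discarded
  pairs15 <- pairs_rbind(lapply(1:10, function(i) {
    mk(i, if (i <= 3) substr(rr, 50, 85) else random_dna(36))
  }))
  det15 <- detect_candidates(pairs15, models)
  dec <- ribosomal_filter(det15$candidates, det15, rrna)
  expect_false(dec$kept)
  expect_equal(dec$statistic, 0.15)

  # no library: keep
  expect_true(ribosomal_filter(det15$candidates, det15, NULL)$kept)
})

test_that("the expression-consistency filter compares per-nucleotide signals", {
  # candidate with 20 supporters over ~500 nt of fragment, genes well
  # expressed -> keep; same chimeric signal against weak genes -> discard
  models <- gene_models(tibble::tibble(
    gene_id = c("gX", "gY", "gZ"), tx_id = c("gX.1", "gY.1", "gZ.1"),
    chrom = c("chr1", "chr2", "chr3"), strand = "+", start = 0L, end = 2000L
  ))
  chim <- pairs_rbind(lapply(1:20, function(i) {
    make_pair(sprintf("c%02d", i),
      blocks1 = list(c(800L + 8L * i, 836L + 8L * i)),
      chrom2 = "chr2", blocks2 = list(c(400L + 8L * i, 436L + 8L * i))
    )
  }))
  intra <- pairs_rbind(lapply(1:220, function(i) {
    g <- if (i %% 2 == 0) "chr1" else "chr2"
    s <- (i * 7L) %% 1900L
    make_pair(sprintf("n%03d", i),
      chrom1 = g, blocks1 = list(c(s, s + 36L)),
      chrom2 = g, blocks2 = list(c(s + 100L, s + 136L))
    )
  }))
  det_strong <- detect_candidates(pairs_rbind(chim, intra), models)
  dec_strong <- expression_consistency_filter(det_strong$candidates, det_strong, models)
  expect_true(dec_strong$kept)

  det_weak <- detect_candidates(chim, models) # no background expression
  dec_weak <- expression_consistency_filter(det_weak$candidates, det_weak, models)
  expect_false(dec_weak$kept)
})

test_that("the PCR filter requires independent coverage beyond the read size", {
  models <- gene_models(tibble::tibble(
    gene_id = c("gX", "gY"), tx_id = c("gX.1", "gY.1"),
    chrom = c("chr1", "chr2"), strand = "+", start = 0L, end = 2000L
  ))
  # identical duplicated fragment: span 36 < 41 on both sides
  dup <- pairs_rbind(lapply(1:50, function(i) {
    make_pair(sprintf("d%02d", i),
      blocks1 = list(c(500L, 536L)),
      chrom2 = "chr2", blocks2 = list(c(700L, 736L))
    )
  }))
  det_dup <- detect_candidates(dup, models)
  dec_dup <- pcr_filter(det_dup$candidates, det_dup, models, pcr_p = 5L)
  expect_false(dec_dup$kept)
  expect_equal(dec_dup$statistic, 36)

  # starts {100,105,110} on both sides: union span 46 >= 41
  spread <- pairs_rbind(lapply(0:2, function(i) {
    make_pair(sprintf("s%d", i),
      blocks1 = list(c(100L + 5L * i, 136L + 5L * i)),
      chrom2 = "chr2", blocks2 = list(c(100L + 5L * i, 136L + 5L * i))
    )
  }))
  det_spread <- detect_candidates(spread, models)
  dec_spread <- pcr_filter(det_spread$candidates, det_spread, models, pcr_p = 5L)
  expect_true(dec_spread$kept)
  expect_equal(dec_spread$statistic, 46)

  # raising p never grows the kept set
  kept_at <- function(p) {
    sum(pcr_filter(det_spread$candidates, det_spread, models, pcr_p = p)$kept)
  }
  expect_true(all(diff(vapply(c(0L, 5L, 10L, 11L, 50L), kept_at, numeric(1))) <= 0))
})

test_that("the cascade audits every candidate, and disabling filters keeps everything", {
  sim <- small_sim()
  det <- small_sim_detection()
  casc <- small_sim_cascade()
  # one decision per surviving candidate per candidate-level filter
  per_filter <- table(casc$audit$filter)
  expect_true(all(per_filter[names(per_filter) != "repeats"] ==
    per_filter[["paralogs"]]))
  # every kept candidate has supporters and a complete audit trail
  expect_true(all(casc$kept$n_support >= 1))
  kept_keys <- paste(casc$kept$gene_a, casc$kept$gene_b)
  audit_keys <- paste(casc$audit$gene_a, casc$audit$gene_b)
  expect_true(all(kept_keys %in% audit_keys))

  none <- run_cascade(det, sim$models, cascade_config(enable = character(0)))
  expect_equal(nrow(none$kept), nrow(det$candidates))

  # a missing mandatory resource names the filter
  expect_error(
    run_cascade(det, sim$models, cascade_config(enable = "small_scale", genome = NULL)),
    "small_scale"
  )
})

test_that("each planted artifact class is removed by its targeted filter", {
  sim <- small_sim()
  casc <- small_sim_cascade()
  roles <- sim$roles
  a <- casc$audit
  verdict <- function(g1, g2, filter) {
    row <- a[a$filter == filter &
      a$gene_a == min(g1, g2) & a$gene_b == max(g1, g2), ]
    nrow(row) == 1 && !row$kept
  }
  expect_true(verdict(roles$decoy_src, roles$decoy, "paralogs"))
  expect_true(verdict(roles$hot1, roles$hot2, "insert_size"))
  expect_true(verdict(roles$rrna1, roles$rrna2, "ribosomal"))
  expect_true(verdict(roles$pcr1, roles$pcr2, "pcr"))
  # every planted repeat-pair read is pruned before the candidate-level
  # filters run (the candidate itself may survive on unrelated supporters)
  rep_ids <- sim$truth$pair_id[sim$truth$label == "repeat-pair"]
  surviving <- unlist(lapply(casc$kept$supporters, function(s) s$pair_id))
  expect_false(any(rep_ids %in% surviving))
  rep_key <- paste(min(roles$rep1, roles$rep2), max(roles$rep1, roles$rep2))
  rep_row <- a[a$filter == "repeats" & paste(a$gene_a, a$gene_b) == rep_key, ]
  expect_gt(rep_row$statistic, 0) # some supporters were pruned there
  # and the implanted fusion survives everything
  fus_key <- paste(
    min(roles$fusion_a, roles$fusion_b), max(roles$fusion_a, roles$fusion_b)
  )
  expect_true(fus_key %in% paste(casc$kept$gene_a, casc$kept$gene_b))
})
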