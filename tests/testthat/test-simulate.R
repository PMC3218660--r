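fast_cfg <- function(...) {
  sim_config(
    seed = 3L, n_pairs = 3000L, n_genes = 20L, n_chroms = 2L,
    ...
  )
}

test_that("simulation is byte-identical under a fixed seed", {
  s1 <- simulate_dataset(fast_cfg())
  s2 <- simulate_dataset(fast_cfg())
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulated_dataset(s1, d1)
  write_simulated_dataset(s2, d2)
  for (f in c(
    "genome.fa", "rrna.fa", "annotation.gtf", "annotation.knowngene.tsv",
    "pairs.tsv", "pairs.sam", "paralogs.tsv", "repeats.bed", "truth.tsv"
  )) {
    expect_equal(
      unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f))),
      info = f
    )
  }
})

test_that("gene spans are pairwise disjoint within each chromosome", {
  sim <- small_sim()
  g <- composite_models(sim$models)
  for (ch in unique(g$chrom)) {
    gc <- g[g$chrom == ch, ]
    gc <- gc[order(gc$span_start), ]
    expect_true(all(gc$span_start[-1] >= gc$span_end[-nrow(gc)]))
  }
})

test_that("a zero-divergence decoy is an exact copy of its source", {
  sim <- simulate_dataset(fast_cfg(
    decoy = list(divergence = 0, chimera_fraction = 0.05, expr = 6)
  ))
  src <- pefusion:::composite_sequence(sim$models, sim$genome, sim$roles$decoy_src)
  dec <- pefusion:::composite_sequence(sim$models, sim$genome, sim$roles$decoy)
  expect_equal(as.character(src), as.character(dec))
})

test_that("F = 0 yields no fusion-labelled reads", {
  sim <- simulate_dataset(fast_cfg(
    fusion = list(enabled = TRUE, ratio = 0, expr_a = 8, expr_b = 4,
      breakpoint = "exon_boundary")
  ))
  expect_equal(sum(sim$truth$label == "fusion"), 0L)
  expect_null(sim$fusion_truth)
})

test_that("empirical fragment sizes match the configured distribution", {
  # two-exon genes have a single isoform, so composite-coordinate inserts
  # equal fragment lengths exactly (multi-isoform composites shift upward)
  sim <- simulate_dataset(sim_config(
    seed = 8L, n_pairs = 10000L, n_genes = 20L,
    exons_per_gene = c(2L, 2L), exon_length = c(300L, 420L),
    fragment_mean = 300, fragment_sd = 20,
    random_pair_rate = 0, pcr_duplicates = 0L, rrna_fraction = 0,
    decoy = list(divergence = 0.02, chimera_fraction = 0, expr = 6),
    n_repeat_pairs = 0L,
    fusion = list(enabled = FALSE, ratio = 0, expr_a = 8, expr_b = 4,
      breakpoint = "exon_boundary")
  ))
  det <- detect_candidates(sim$pairs, sim$models)
  inserts <- insert_size_distribution(det, sim$models)$values
  n <- length(inserts)
  expect_gt(n, 5000)
  se <- 20 / sqrt(n)
  # truncation to >= 2 read lengths biases upward very slightly; allow 3 SE
  # plus the sub-nucleotide truncation effect
  expect_lt(abs(mean(inserts) - 300), 3 * se + 0.5)
})

test_that("random pairing follows the product-of-expression null", {
  sim <- simulate_dataset(sim_config(
    seed = 12L, n_pairs = 4000L, n_genes = 20L,
    random_pair_rate = 0.5, # many random pairs for the goodness-of-fit
    pcr_duplicates = 0L, rrna_fraction = 0, n_repeat_pairs = 0L,
    decoy = list(divergence = 0.02, chimera_fraction = 0, expr = 6),
    fusion = list(enabled = FALSE, ratio = 0, expr_a = 8, expr_b = 4,
      breakpoint = "exon_boundary")
  ))
  rnd <- sim$truth$pair_id[sim$truth$label == "random-pair"]
  rows <- match(rnd, sim$pairs$pair_id)
  w <- sim$weights
  # each random end is drawn independently with probability proportional to
  # expression; bucket genes into the 5 hottest + rest and test the joint
  # (end1 gene, end2 gene) counts against the product law
  hot <- names(sort(w, decreasing = TRUE))[1:5]
  bucket <- function(g) ifelse(g %in% hot, g, "other")
  p_gene <- w / sum(w)
  p_bucket <- c(p_gene[hot], other = sum(p_gene[!names(p_gene) %in% hot]))
  # per-end gene of each random pair, recovered from the truth coordinates
  gene_of_end <- function(chrom, blocks) {
    g <- composite_models(sim$models)
    hit <- g$chrom == chrom & g$span_start <= blocks[1, "start"] &
      g$span_end >= blocks[1, "end"]
    g$gene_id[which(hit)[1]]
  }
  g1 <- mapply(gene_of_end, sim$pairs$chrom1[rows], sim$pairs$blocks1[rows])
  g2 <- mapply(gene_of_end, sim$pairs$chrom2[rows], sim$pairs$blocks2[rows])
  obs <- table(
    factor(bucket(g1), levels = names(p_bucket)),
    factor(bucket(g2), levels = names(p_bucket))
  )
  expected_p <- outer(p_bucket, p_bucket)
  gof <- suppressWarnings(
    stats::chisq.test(as.vector(obs), p = as.vector(expected_p))
  )
  expect_gt(gof$p.value, 0.01)
})

test_that("fusion reads land on both genes and junction ends join the pool", {
  sim <- small_sim()
  truth <- sim$truth
  fus <- truth$pair_id[truth$label == "fusion"]
  rows <- match(fus, sim$pairs$pair_id)
  # at least one end unmapped only for junction-spanning ends, whose raw
  # sequence must be retained
  unm <- !sim$pairs$mapped1[rows] | !sim$pairs$mapped2[rows]
  expect_gt(sum(unm), 0)
  expect_true(all(nchar(sim$pairs$seq1[rows]) == sim$config$read_length))
})

test_that("subsampling reads does not erode the fusion's standing", {
  sim <- small_sim()
  roles <- sim$roles
  fus_a <- min(roles$fusion_a, roles$fusion_b)
  fus_b <- max(roles$fusion_a, roles$fusion_b)
  resper_at <- function(frac) {
    set.seed(500 + round(100 * frac))
    sub <- sim$pairs[sort(sample.int(nrow(sim$pairs), round(frac * nrow(sim$pairs)))), ]
    det <- detect_candidates(sub, sim$models)
    sc <- score_candidates(det, sim$models) # pre-filter scores suffice here
    r <- sc$resper[sc$gene_a == fus_a & sc$gene_b == fus_b]
    if (length(r) == 0) 0 else r
  }
  shallow <- resper_at(0.2)
  deep <- resper_at(0.9)
  expect_gte(deep, shallow)
})
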