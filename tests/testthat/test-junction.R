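test_that("tile length is read length minus the required overlap", {
  expect_equal(tile_length(36L, 10L), 26L)
  expect_equal(2L * tile_length(36L, 10L), 52L)
  expect_equal(tile_length(51L, 10L), 41L)
  expect_equal(tile_length(36L, 35L), 1L)
  expect_error(tile_length(36L, 36L), "strictly between")
  expect_error(tile_length(36L, 0L), "strictly between")
})

fake_region <- function(seq, gene_id = "gX", chrom = "chr1", start = 0L,
                        strand = "+") {
  structure(
    list(
      gene_id = gene_id, chrom = chrom, strand = strand,
      intervals = cbind(start = start, end = start + nchar(seq)),
      seq = Biostrings::DNAString(seq), length = nchar(seq)
    ),
    class = "breakpoint_region"
  )
}

test_that("library cardinality follows the closed form without materialising", {
  set.seed(41)
  for (rep in 1:10) {
    la <- sample(30:200, 1)
    lb <- sample(30:200, 1)
    L <- sample(10:26, 1)
    lib <- build_junction_library(
      fake_region(random_dna(la)), fake_region(random_dna(lb), "gY", "chr2"), L
    )
    expect_equal(lib$n_elements, 2 * (la - L + 1) * (lb - L + 1))
  }
  expect_error(
    build_junction_library(
      fake_region(random_dna(10)), fake_region(random_dna(100), "gY"), 26L
    ),
    "shorter than the tile"
  )
})

test_that("junction elements concatenate the two tiles in either orientation", {
  a <- random_dna(60)
  b <- random_dna(60)
  lib <- build_junction_library(fake_region(a), fake_region(b, "gY", "chr2"), 26L)
  expect_equal(
    junction_element(lib, 3L, 7L, "AB"),
    paste0(substr(a, 3, 28), substr(b, 7, 32))
  )
  expect_equal(
    junction_element(lib, 3L, 7L, "BA"),
    paste0(substr(b, 7, 32), substr(a, 3, 28))
  )
})

test_that("the split matcher equals the brute-force element scan", {
  set.seed(43)
  a <- random_dna(45)
  b <- random_dna(45)
  L <- 26L
  lib <- build_junction_library(fake_region(a), fake_region(b, "gY", "chr2"), L)
  # reads: junction-crossing with 0-3 mismatches, one within-region read,
  # pure noise, and a reverse-complement crossing read
  el <- junction_element(lib, 5L, 9L, "AB")
  reads <- c(
    hit0 = substr(el, 4, 39),
    hit2 = mutate_at_positions(substr(el, 8, 43), c(3, 30)),
    hit3 = mutate_at_positions(substr(el, 8, 43), c(3, 17, 30)),
    rcht = paste(rev(strsplit(chartr("ACGT", "TGCA", substr(el, 6, 41)), "")[[1]]), collapse = ""),
    nois = random_dna(36)
  )
  got <- align_to_library(reads, lib, max_mismatches = 2L) |>
    dplyr::arrange(read_id, orientation, tile_a, tile_b, offset, strand)
  want <- brute_force_hits(reads, lib, 2L) |>
    dplyr::arrange(read_id, orientation, tile_a, tile_b, offset, strand)
  expect_equal(tibble::as_tibble(got), want)
  # the 3-mismatch read is found at its planted site only at max_mismatches 3
  expect_false("hit3" %in% got$read_id[got$tile_a == 5 & got$tile_b == 9])
  got3 <- align_to_library(reads, lib, max_mismatches = 3L)
  expect_true("hit3" %in% got3$read_id)
})

test_that("junction calls demand support and uniform coverage", {
  a <- random_dna(80)
  b <- random_dna(80)
  L <- 26L
  lib <- build_junction_library(fake_region(a), fake_region(b, "gY", "chr2"), L)
  el <- junction_element(lib, 20L, 11L, "AB")
  rl <- 36L

  # 20 reads piled at a single offset: PCR-like, no call
  pile <- setNames(rep(substr(el, 5, 40), 20), paste0("p", 1:20))
  hits_pile <- align_to_library(pile, lib, max_mismatches = 0L)
  expect_equal(nrow(call_junction(hits_pile, lib, read_length = rl)), 0L)

  # 30 reads spread over every valid offset: called, KS pass
  offs <- rep(0:(2 * L - rl), length.out = 30)
  uni <- setNames(
    vapply(offs, function(o) substr(el, o + 1, o + rl), character(1)),
    paste0("u", seq_along(offs))
  )
  hits_uni <- align_to_library(uni, lib, max_mismatches = 0L)
  calls <- call_junction(hits_uni, lib, read_length = rl)
  expect_gte(nrow(calls), 1L)
  expect_equal(calls$tile_a[1], 20L)
  expect_equal(calls$tile_b[1], 11L)
  expect_equal(calls$orientation[1], "AB")
  expect_equal(calls$uniformity[1], "ks")
  expect_equal(calls$support[1], 30L)
  # breakpoint coordinates: last base of tile A (1-based), first of tile B
  expect_equal(calls$break_a[1], 20L + L - 1L)
  expect_equal(calls$break_b[1], 11L)
  # element sequence reconstructs from the regions at the reported tiles
  expect_equal(
    calls$sequence[1],
    junction_element(lib, calls$tile_a[1], calls$tile_b[1], calls$orientation[1])
  )

  # a secondary junction with few but spread reads is reported alongside
  el2 <- junction_element(lib, 40L, 30L, "BA")
  sec <- setNames(
    vapply(c(0, 4, 8, 12, 16), function(o) substr(el2, o + 1, o + rl), character(1)),
    paste0("s", 1:5)
  )
  both <- call_junction(
    align_to_library(c(uni, sec), lib, max_mismatches = 0L),
    lib,
    read_length = rl
  )
  expect_equal(both$support[1], 30L)
  expect_true(any(both$orientation == "BA" & both$tile_a == 40L & both$support == 5L))

  # exact ties are all reported and flagged ambiguous
  el3 <- junction_element(lib, 2L, 2L, "AB")
  t1 <- setNames(
    vapply(c(0, 5, 10, 15), function(o) substr(el, o + 1, o + rl), character(1)),
    paste0("t", 1:4)
  )
  t2 <- setNames(
    vapply(c(0, 5, 10, 15), function(o) substr(el3, o + 1, o + rl), character(1)),
    paste0("t", 5:8)
  )
  tied <- call_junction(
    align_to_library(c(t1, t2), lib, max_mismatches = 0L),
    lib,
    read_length = rl
  )
  expect_gte(nrow(tied), 2L)
  expect_true(all(tied$ambiguous[tied$support == max(tied$support)]))

  expect_equal(nrow(call_junction(pefusion:::empty_hits(), lib, read_length = rl)), 0L)
})

test_that("genome uniqueness checks ignore the source loci but catch planted copies", {
  set.seed(44)
  chr <- random_dna(3000)
  el <- substr(chr, 500, 551) # 52-mer taken from the source region
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  src <- tibble::tibble(chrom = "chr1", start = 400L, end = 700L)
  expect_true(genome_uniqueness_check(el, genome, src))
  # plant a copy elsewhere
  chr_copy <- paste0(substr(chr, 1, 2000), el, substr(chr, 2053, 3000))
  genome2 <- Biostrings::DNAStringSet(c(chr1 = chr_copy))
  expect_false(genome_uniqueness_check(el, genome2, src))
  # a random 52-mer matches nowhere in a random genome
  expect_true(genome_uniqueness_check(
    random_dna(52), genome,
    tibble::tibble(chrom = character(0), start = integer(0), end = integer(0))
  ))
})

test_that("breakpoint regions cover footprint exons plus flanks and supported introns", {
  sim <- small_sim()
  det <- small_sim_detection()
  casc <- small_sim_cascade()
  roles <- sim$roles
  key <- paste(casc$kept$gene_a, casc$kept$gene_b)
  fus <- casc$kept[key == paste(
    min(roles$fusion_a, roles$fusion_b), max(roles$fusion_a, roles$fusion_b)
  ), ]
  regions <- select_breakpoint_regions(fus[1, ], det, sim$models, sim$genome)
  # the implanted breakpoint lies inside the regions
  bp <- sim$fusion_truth
  up_region <- if (regions$a$gene_id == bp$upstream_gene) regions$a else regions$b
  covered <- any(
    up_region$intervals[, "start"] < bp$upstream_break &
      up_region$intervals[, "end"] >= bp$upstream_break
  )
  expect_true(covered)
  # sequence length equals the interval total
  expect_equal(
    length(up_region$seq),
    sum(up_region$intervals[, "end"] - up_region$intervals[, "start"])
  )
})

test_that("the whole junction module recovers the implanted breakpoint", {
  sim <- small_sim()
  det <- small_sim_detection()
  casc <- small_sim_cascade()
  roles <- sim$roles
  key <- paste(casc$kept$gene_a, casc$kept$gene_b)
  fus <- casc$kept[key == paste(
    min(roles$fusion_a, roles$fusion_b), max(roles$fusion_a, roles$fusion_b)
  ), ]
  jr <- find_junction(fus[1, ], det, sim$models, sim$genome)
  expect_gt(nrow(jr$calls), 0)
  top <- jr$calls[1, ]
  truth <- sim$fusion_truth
  called <- if (top$gene_a == truth$upstream_gene) {
    c(up = top$break_a, down = top$break_b)
  } else {
    c(up = top$break_b, down = top$break_a)
  }
  expect_equal(unname(called["up"]), truth$upstream_break)
  expect_equal(unname(called["down"]), truth$downstream_break)
  expect_true(top$at_exon_edge)
})
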