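# Shared fixtures, built in code. Coordinates are 0-based half-open unless
# a function's contract says otherwise.

# two plus-strand genes and one minus-strand gene on two chromosomes
tiny_models <- function() {
  gene_models(tibble::tibble(
    gene_id = c("gA", "gA", "gA", "gB", "gB", "gC"),
    tx_id = c("gA.1", "gA.1", "gA.2", "gB.1", "gB.1", "gC.1"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    strand = c("+", "+", "+", "-", "-", "+"),
    start = c(100L, 300L, 100L, 1000L, 1400L, 50L),
    end = c(200L, 400L, 350L, 1200L, 1600L, 250L)
  ))
}

# one-row pair tibble; blocks given as list(c(start, end), ...)
make_pair <- function(pair_id = "p1",
                      chrom1 = "chr1", strand1 = "+", blocks1 = list(c(110L, 146L)),
                      seq1 = strrep("A", 36L),
                      chrom2 = "chr1", strand2 = "-", blocks2 = list(c(150L, 186L)),
                      seq2 = strrep("C", 36L),
                      mapped1 = TRUE, mapped2 = TRUE,
                      qc_pass = TRUE, unique_pair = TRUE) {
  as_block <- function(b) {
    m <- do.call(rbind, b)
    colnames(m) <- c("start", "end")
    m
  }
  tibble::tibble(
    pair_id = pair_id,
    chrom1 = if (mapped1) chrom1 else NA_character_,
    strand1 = if (mapped1) strand1 else NA_character_,
    blocks1 = list(if (mapped1) as_block(blocks1) else cbind(start = integer(0), end = integer(0))),
    seq1 = seq1, mapped1 = mapped1,
    chrom2 = if (mapped2) chrom2 else NA_character_,
    strand2 = if (mapped2) strand2 else NA_character_,
    blocks2 = list(if (mapped2) as_block(blocks2) else cbind(start = integer(0), end = integer(0))),
    seq2 = seq2, mapped2 = mapped2,
    qc_pass = qc_pass, unique_pair = unique_pair
  )
}

pairs_rbind <- function(...) dplyr::bind_rows(...)

# memoised small simulated sample shared across test files
.sim_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- simulate_dataset(sim_config(
      seed = 42L, n_pairs = 6000L, n_genes = 60L
    ))
  }
  .sim_cache$sim
}

small_sim_detection <- function() {
  if (is.null(.sim_cache$det)) {
    .sim_cache$det <- detect_candidates(small_sim()$pairs, small_sim()$models)
  }
  .sim_cache$det
}

small_sim_config <- function() {
  sim <- small_sim()
  cascade_config(
    paralogs = sim$paralogs, repeats = sim$repeats,
    rrna = sim$rrna, genome = sim$genome, seed = 5L
  )
}

small_sim_cascade <- function() {
  if (is.null(.sim_cache$cascade)) {
    .sim_cache$cascade <- run_cascade(
      small_sim_detection(), small_sim()$models, small_sim_config()
    )
  }
  .sim_cache$cascade
}

# brute-force junction-matcher oracle: materialise every library element and
# slide every read window over it
brute_force_hits <- function(reads, lib, mm) {
  rc <- function(x) paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  out <- list()
  L <- lib$tile_length
  for (orient in c("AB", "BA")) {
    for (a in seq_len(lib$n_tiles_a)) {
      for (b in seq_len(lib$n_tiles_b)) {
        el <- junction_element(lib, a, b, orient)
        for (r in seq_along(reads)) {
          for (strand in c("+", "-")) {
            rd <- if (strand == "+") reads[r] else rc(reads[r])
            rl <- nchar(rd)
            for (o in 0:(2 * L - rl)) {
              w <- substr(el, o + 1, o + rl)
              d <- sum(strsplit(w, "")[[1]] != strsplit(rd, "")[[1]])
              if (d <= mm) {
                out[[length(out) + 1]] <- tibble::tibble(
                  read_id = names(reads)[r], orientation = orient,
                  tile_a = a, tile_b = b, offset = o,
                  mismatches = d, strand = strand
                )
              }
            }
          }
        }
      }
    }
  }
  dplyr::bind_rows(out)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_at_positions <- function(seq, pos) {
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  paste(chars, collapse = "")
}

# detection fixture for the insert-size filter: genes with one 5-kb exon
# each; intra pairs in gene gZ set the transcriptome norm, chimeric pairs
# bridge gX and gY with configurable footprints
insert_fixture <- function(chim_a_starts, chim_b_starts, read_len = 36L,
                           intra_inserts = NULL, seed = 1L) {
  models <- gene_models(tibble::tibble(
    gene_id = c("gX", "gY", "gZ"), tx_id = c("gX.1", "gY.1", "gZ.1"),
    chrom = c("chr1", "chr2", "chr3"), strand = "+",
    start = 0L, end = 5000L
  ))
  withr_seed <- function(code) code
  if (is.null(intra_inserts)) {
    set.seed(seed)
    intra_inserts <- pmax(2L * read_len, round(rnorm(300, 300, 20)))
  }
  intra <- dplyr::bind_rows(lapply(seq_along(intra_inserts), function(i) {
    ins <- intra_inserts[i]
    s <- sample.int(5000L - ins, 1) - 1L
    make_pair(
      pair_id = sprintf("intra%04d", i),
      chrom1 = "chr3", blocks1 = list(c(s, s + read_len)),
      chrom2 = "chr3", blocks2 = list(c(s + ins - read_len, s + ins))
    )
  }))
  chim <- dplyr::bind_rows(lapply(seq_along(chim_a_starts), function(i) {
    make_pair(
      pair_id = sprintf("chim%04d", i),
      chrom1 = "chr1", blocks1 = list(c(chim_a_starts[i], chim_a_starts[i] + read_len)),
      chrom2 = "chr2", blocks2 = list(c(chim_b_starts[i], chim_b_starts[i] + read_len))
    )
  }))
  detection <- detect_candidates(dplyr::bind_rows(intra, chim), models)
  list(models = models, detection = detection)
}
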