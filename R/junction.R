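#' Tile length of the fusion-junction library
#'
#' Tiles are `read_length - min_overlap` nucleotides long, so that any read
#' aligned to a two-tile junction element overlaps each gene's tile by at
#' least `min_overlap` nucleotides. For 36-nt reads and a 10-nt minimum
#' overlap this gives 26-nt tiles and 52-nt junction elements.
#'
#' @param read_length Read length in nucleotides.
#' @param min_overlap Minimum required overlap across the junction.
#' @return The tile length; junction elements are twice this.
#' @export
tile_length <- function(read_length, min_overlap) {
  if (min_overlap >= read_length || min_overlap <= 0) {
    abort("min_overlap must lie strictly between 0 and read_length")
  }
  as.integer(read_length - min_overlap)
}

#' Select breakpoint regions for a candidate
#'
#' For each gene of a surviving candidate the region that can contain the
#' breakpoint is assembled from all composite exon blocks intersected by
#' chimeric-read footprints plus any intronic intervals directly supported by
#' chimeric reads, each extended by `flank` nucleotides on both sides;
#' overlapping extensions are merged and the genomic sequence concatenated.
#'
#' @param candidate One row of a candidate tibble.
#' @param detection The [detect_candidates()] result.
#' @param models A [gene_models()] object.
#' @param genome Genome `DNAStringSet`.
#' @param flank Flank size in nucleotides (default 150).
#' @return A list of two `breakpoint_region` objects (`$a`, `$b`), each with
#'   `gene_id`, `chrom`, `intervals` (0-based half-open matrix), `seq`
#'   (`DNAString`) and `length`.
#' @export
select_breakpoint_regions <- function(candidate, detection, models, genome,
                                      flank = 150L) {
  if (is.null(genome)) abort("breakpoint regions require genome sequences")
  fp <- chimeric_footprints(candidate, detection, models)
  build_side <- function(side, gene_id) {
    f <- fp[fp$side == side, , drop = FALSE]
    gb <- resolve_blocks(models, gene_id = gene_id)
    gi <- match(gene_id, models$genes$gene_id)
    chrom <- models$genes$chrom[gi]
    strand <- models$genes$strand[gi]
    foot_ir <- IRanges::IRanges(start = f$gstart + 1L, end = f$gend)
    block_ir <- IRanges::IRanges(start = gb[, "start"] + 1L, end = gb[, "end"])
    hit_blocks <- block_ir[IRanges::overlapsAny(block_ir, foot_ir)]
    intronic <- foot_ir[!f$exonic]
    parts <- c(hit_blocks, intronic)
    if (length(parts) == 0) parts <- foot_ir
    ext <- IRanges::reduce(IRanges::IRanges(
      start = pmax(1L, IRanges::start(parts) - flank),
      end = pmin(length(genome[[chrom]]), IRanges::end(parts) + flank)
    ))
    seqs <- as.character(Biostrings::extractAt(genome[[chrom]], ext))
    # region sequence follows the gene's transcriptional sense, so junction
    # elements read upstream-into-downstream like the fusion transcript does
    seq <- if (strand == "+") {
      Biostrings::DNAString(paste(seqs, collapse = ""))
    } else {
      Biostrings::reverseComplement(
        Biostrings::DNAString(paste(seqs, collapse = ""))
      )
    }
    structure(
      list(
        gene_id = gene_id, chrom = chrom, strand = strand,
        intervals = cbind(start = IRanges::start(ext) - 1L, end = IRanges::end(ext)),
        seq = seq,
        length = sum(IRanges::width(ext))
      ),
      class = "breakpoint_region"
    )
  }
  list(
    a = build_side("a", candidate$gene_a),
    b = build_side("b", candidate$gene_b)
  )
}

# genomic coordinate (0-based) of a 0-based offset within a breakpoint
# region; region offsets run along the gene's sense, so on minus-strand
# genes they count backwards from the genomic end of the region
region_offset_to_genomic <- function(region, offset) {
  iv <- region$intervals
  widths <- iv[, "end"] - iv[, "start"]
  total <- sum(widths)
  if (!is.null(region$strand) && region$strand == "-") {
    offset <- total - 1L - offset
  }
  cum <- cumsum(c(0L, widths))
  idx <- findInterval(offset, cum, rightmost.closed = FALSE)
  as.integer(iv[idx, "start"] + (offset - cum[idx]))
}

#' Build a (lazy) fusion-junction library
#'
#' Tiles spaced one nucleotide apart cover both breakpoint regions; the
#' library consists of every cross pairing of one tile per gene in both
#' orientations (gene A upstream of B, and vice versa). The element count is
#' `n_tiles_a * n_tiles_b * 2` with `n_tiles_x = region_length - tile_length
#' + 1`; elements are materialised on demand with [junction_element()], never
#' all at once.
#'
#' @param region_a,region_b `breakpoint_region` objects (or anything with a
#'   `$seq` and `$length`).
#' @param tile_len Tile length from [tile_length()].
#' @return A `junction_library` object with tile counts and `n_elements`.
#' @export
build_junction_library <- function(region_a, region_b, tile_len) {
  if (region_a$length < tile_len || region_b$length < tile_len) {
    abort("breakpoint region shorter than the tile length")
  }
  n_a <- region_a$length - tile_len + 1L
  n_b <- region_b$length - tile_len + 1L
  structure(
    list(
      region_a = region_a, region_b = region_b, tile_length = as.integer(tile_len),
      n_tiles_a = as.integer(n_a), n_tiles_b = as.integer(n_b),
      n_elements = 2 * as.numeric(n_a) * as.numeric(n_b)
    ),
    class = "junction_library"
  )
}

#' @export
print.junction_library <- function(x, ...) {
  cat("<junction_library> ", x$n_tiles_a, " x ", x$n_tiles_b,
    " tiles x 2 orientations = ", format(x$n_elements, big.mark = ","),
    " elements of ", 2L * x$tile_length, " nt\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname build_junction_library
#' @param library A `junction_library`.
#' @param tile_a,tile_b 1-based tile offsets within the two regions.
#' @param orientation `"AB"` (gene A upstream) or `"BA"`.
#' @return `junction_element()` returns the element sequence as a character
#'   string of length `2 * tile_length`.
#' @export
junction_element <- function(library, tile_a, tile_b, orientation = c("AB", "BA")) {
  orientation <- match.arg(orientation)
  L <- library$tile_length
  stopifnot(tile_a >= 1, tile_a <= library$n_tiles_a,
            tile_b >= 1, tile_b <= library$n_tiles_b)
  ta <- as.character(Biostrings::subseq(library$region_a$seq, tile_a, tile_a + L - 1L))
  tb <- as.character(Biostrings::subseq(library$region_b$seq, tile_b, tile_b + L - 1L))
  if (orientation == "AB") paste0(ta, tb) else paste0(tb, ta)
}

# worst-case guaranteed exact-run length of a read matching an element with
# <= mm mismatches; used as the seed length of the alignment screen
guaranteed_seed_length <- function(read_length, tile_len, max_mismatches) {
  run <- function(n, m) ceiling((n - m) / (m + 1))
  smin <- max(1L, read_length - tile_len)
  smax <- min(tile_len, read_length - 1L)
  best <- Inf
  for (s in smin:smax) {
    for (m1 in 0:max_mismatches) {
      for (m2 in 0:(max_mismatches - m1)) {
        best <- min(best, max(run(s, m1), run(read_length - s, m2)))
      }
    }
  }
  as.integer(best)
}

#' Align single-end reads to a junction library
#'
#' Every read (and its reverse complement) is matched against every library
#' element allowing up to `max_mismatches` substitutions. The matcher
#' enumerates the read's junction-crossing splits and matches prefix and
#' suffix against the two regions, which is exactly equivalent to the
#' brute-force scan over all materialised elements; a provably safe exact
#' k-mer screen discards reads that cannot hit anything.
#'
#' @param reads Named character vector of read sequences (names are read
#'   ids). Reads whose length differs from the modal read length are skipped
#'   with a warning.
#' @param library A [build_junction_library()] result.
#' @param max_mismatches Mismatch allowance (default 2).
#' @return A tibble with one row per (element, read, offset) hit: `read_id`,
#'   `orientation`, `tile_a`, `tile_b`, `offset` (0-based on the element),
#'   `mismatches`, `strand` (`+` read as given, `-` reverse complement).
#' @export
align_to_library <- function(reads, library, max_mismatches = 2L) {
  if (length(reads) == 0) return(empty_hits())
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  lens <- nchar(reads)
  rl <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  skipped <- sum(lens != rl)
  if (skipped > 0) {
    warn(paste0(skipped, " read(s) skipped: length differs from ", rl, " nt"))
    reads <- reads[lens == rl]
  }
  if (rl <= library$tile_length) {
    abort("read length must exceed the tile length")
  }
  fwd <- dna_matrix(reads, rl)
  rc <- dna_matrix(revcomp_chr_vec(reads), rl)
  seed_len <- guaranteed_seed_length(rl, library$tile_length, max_mismatches)
  res <- cpp_junction_align(
    dna_to_int(as.character(library$region_a$seq)),
    dna_to_int(as.character(library$region_b$seq)),
    fwd, rc, library$tile_length, as.integer(max_mismatches), seed_len
  )
  tibble(
    read_id = names(reads)[res$read],
    orientation = ifelse(res$orient == 0L, "AB", "BA"),
    tile_a = res$tile_a, tile_b = res$tile_b,
    offset = res$offset, mismatches = res$mismatches,
    strand = ifelse(res$strand == 0L, "+", "-")
  )
}

empty_hits <- function() {
  tibble(
    read_id = character(0), orientation = character(0),
    tile_a = integer(0), tile_b = integer(0), offset = integer(0),
    mismatches = integer(0), strand = character(0)
  )
}

#' Call the fusion junction from library hits
#'
#' Elements are ranked by read support (each read counts once per element).
#' An element is emitted as a junction call when its reads are uniformly
#' distributed across the valid offsets: with support of at least
#' `ks_min_support` a Kolmogorov-Smirnov test against the discrete uniform
#' over valid element offsets is used (pass when `p >= uniformity_alpha`),
#' otherwise a heuristic requiring at least `min_reads` reads with at least
#' `min_distinct_starts` distinct starting offsets. Elements tied for
#' maximal support are all reported and flagged ambiguous; among calls of
#' equal support, those whose breakpoint coincides with an annotated exon
#' edge are listed first.
#'
#' @param hits Hit tibble from [align_to_library()].
#' @param library The library the hits refer to.
#' @param read_length Read length used in the alignment.
#' @param min_reads,min_distinct_starts Heuristic thresholds (defaults 4, 2).
#' @param ks_min_support Minimum support for the KS route (default 10).
#' @param uniformity_alpha KS significance level below which uniformity is
#'   rejected (default 0.05).
#' @param models Optional [gene_models()] for exon-edge annotation.
#' @param genome Optional genome for the uniqueness check.
#' @param check_uniqueness Run [genome_uniqueness_check()] on emitted calls.
#' @return A tibble of class `junction_calls`, one row per emitted call,
#'   ordered by support (and exon-edge preference on ties): breakpoint
#'   coordinates for both genes (1-based genomic, the last included base of
#'   the upstream side and the first of the downstream side), `orientation`,
#'   `support`, `distinct_starts`, uniformity method/statistic/p,
#'   `ambiguous`, `at_exon_edge`, `unique_in_genome`, `sequence`. Zero rows
#'   mean no junction call (insufficient or non-uniform support).
#' @export
call_junction <- function(hits, library, read_length,
                          min_reads = 4L, min_distinct_starts = 2L,
                          ks_min_support = 10L, uniformity_alpha = 0.05,
                          models = NULL, genome = NULL,
                          check_uniqueness = FALSE) {
  empty <- junction_calls_tbl()
  if (nrow(hits) == 0) return(empty)
  # a read supports only its best-scoring element(s): a read crossing the
  # true junction also matches one-off elements with one extra mismatch, and
  # counting those would let shifted junctions tie the real one
  best_hits <- hits |>
    group_by(.data$read_id) |>
    filter(.data$mismatches == min(.data$mismatches)) |>
    ungroup()
  per_read <- distinct(best_hits, .data$read_id, .data$orientation,
    .data$tile_a, .data$tile_b,
    .keep_all = TRUE
  )
  elements <- per_read |>
    group_by(.data$orientation, .data$tile_a, .data$tile_b) |>
    summarise(
      support = dplyr::n_distinct(.data$read_id),
      distinct_starts = dplyr::n_distinct(.data$offset),
      offsets = list(.data$offset),
      .groups = "drop"
    ) |>
    arrange(desc(.data$support), .data$orientation, .data$tile_a, .data$tile_b)

  n_offsets <- 2L * library$tile_length - read_length + 1L
  assess <- function(support, offsets) {
    if (support >= ks_min_support) {
      stat <- suppressWarnings(ks.test((offsets + 0.5) / n_offsets, "punif"))
      list(
        method = "ks", statistic = unname(stat$statistic),
        p = stat$p.value, pass = stat$p.value >= uniformity_alpha
      )
    } else {
      list(
        method = "heuristic", statistic = NA_real_, p = NA_real_,
        pass = support >= min_reads && length(unique(offsets)) >= min_distinct_starts
      )
    }
  }
  res <- map(seq_len(nrow(elements)), function(i) {
    u <- assess(elements$support[i], elements$offsets[[i]])
    tibble(
      orientation = elements$orientation[i],
      tile_a = elements$tile_a[i], tile_b = elements$tile_b[i],
      support = elements$support[i],
      distinct_starts = elements$distinct_starts[i],
      uniformity = u$method, statistic = u$statistic, p_value = u$p,
      pass = u$pass
    )
  }) |> bind_rows()
  calls <- res[res$pass, , drop = FALSE]
  if (nrow(calls) == 0) return(empty)
  calls$ambiguous <- calls$support == max(calls$support) &
    sum(calls$support == max(calls$support)) > 1

  L <- library$tile_length
  ra <- library$region_a
  rb <- library$region_b
  # upstream side breaks after its tile's last base; downstream before its
  # tile's first base. Coordinates reported 1-based.
  calls$break_a <- ifelse(
    calls$orientation == "AB",
    region_offset_to_genomic(ra, calls$tile_a - 1L + L - 1L) + 1L,
    region_offset_to_genomic(ra, calls$tile_a - 1L) + 1L
  )
  calls$break_b <- ifelse(
    calls$orientation == "AB",
    region_offset_to_genomic(rb, calls$tile_b - 1L) + 1L,
    region_offset_to_genomic(rb, calls$tile_b - 1L + L - 1L) + 1L
  )
  calls$gene_a <- ra$gene_id
  calls$gene_b <- rb$gene_id
  calls$sequence <- map_chr(
    seq_len(nrow(calls)),
    function(i) junction_element(library, calls$tile_a[i], calls$tile_b[i], calls$orientation[i])
  )
  calls$at_exon_edge <- FALSE
  if (!is.null(models)) {
    edge_set <- function(gene_id) {
      b <- resolve_blocks(models, gene_id = gene_id)
      c(b[, "start"] + 1L, b[, "end"]) # 1-based first/last block bases
    }
    calls$at_exon_edge <- calls$break_a %in% edge_set(ra$gene_id) |
      calls$break_b %in% edge_set(rb$gene_id)
  }
  calls$unique_in_genome <- NA
  if (check_uniqueness && !is.null(genome)) {
    source_iv <- bind_rows(
      tibble(chrom = ra$chrom, start = ra$intervals[, "start"], end = ra$intervals[, "end"]),
      tibble(chrom = rb$chrom, start = rb$intervals[, "start"], end = rb$intervals[, "end"])
    )
    calls$unique_in_genome <- map_lgl(
      calls$sequence,
      function(s) genome_uniqueness_check(s, genome, source_iv)
    )
  }
  calls <- calls[order(-calls$support, -calls$at_exon_edge, calls$orientation,
    calls$tile_a, calls$tile_b,
    method = "radix"
  ), , drop = FALSE]
  out <- select(
    calls, "gene_a", "gene_b", "break_a", "break_b", "orientation",
    "support", "distinct_starts", "uniformity", "statistic", "p_value",
    "ambiguous", "at_exon_edge", "unique_in_genome", "tile_a", "tile_b",
    "sequence"
  )
  class(out) <- c("junction_calls", class(out))
  out
}

junction_calls_tbl <- function() {
  out <- tibble(
    gene_a = character(0), gene_b = character(0),
    break_a = integer(0), break_b = integer(0), orientation = character(0),
    support = integer(0), distinct_starts = integer(0),
    uniformity = character(0), statistic = numeric(0), p_value = numeric(0),
    ambiguous = logical(0), at_exon_edge = logical(0),
    unique_in_genome = logical(0), tile_a = integer(0), tile_b = integer(0),
    sequence = character(0)
  )
  class(out) <- c("junction_calls", class(out))
  out
}

#' Check that a junction element is unique in the genome
#'
#' Scans the genome (both strands) for loci matching at least `identity` of
#' the element length with substitutions only, ignoring hits overlapping the
#' element's two source regions. Junctions with an extra-locus match are
#' potential misalignment artifacts.
#'
#' @param element_seq Element sequence (character).
#' @param genome Genome `DNAStringSet`.
#' @param source_intervals Tibble `chrom`, `start`, `end` (0-based half-open)
#'   of the regions the element was built from.
#' @param identity Minimum matched fraction (default 0.75).
#' @return `TRUE` when no locus outside the source regions matches.
#' @export
genome_uniqueness_check <- function(element_seq, genome, source_intervals,
                                    identity = 0.75) {
  len <- nchar(element_seq)
  max_mm <- floor((1 - identity) * len)
  pat <- Biostrings::DNAString(element_seq)
  pats <- list(`+` = pat, `-` = Biostrings::reverseComplement(pat))
  for (chrom in names(genome)) {
    src <- source_intervals[source_intervals$chrom == chrom, , drop = FALSE]
    src_ir <- IRanges::IRanges(start = src$start + 1L, end = src$end)
    for (p in pats) {
      m <- Biostrings::matchPattern(p, genome[[chrom]], max.mismatch = max_mm)
      if (length(m) == 0) next
      hit_ir <- IRanges::IRanges(start = Biostrings::start(m), end = Biostrings::end(m))
      outside <- !IRanges::overlapsAny(hit_ir, src_ir)
      if (any(outside)) return(FALSE)
    }
  }
  TRUE
}

#' Resolve the junction sequence for one candidate
#'
#' Convenience wrapper chaining [select_breakpoint_regions()],
#' [build_junction_library()], [align_to_library()] over every single end of
#' the sample (mapped and unmapped alike) and [call_junction()].
#'
#' @inheritParams select_breakpoint_regions
#' @param min_overlap Minimum read overlap across the junction (default 10).
#' @param max_mismatches Mismatch allowance for the aligner (default 2).
#' @param ... Passed on to [call_junction()].
#' @return A list of class `junction_result`: `regions`, `library`, `hits`,
#'   `calls`.
#' @export
find_junction <- function(candidate, detection, models, genome,
                          flank = 150L, min_overlap = 10L,
                          max_mismatches = 2L, ...) {
  regions <- select_breakpoint_regions(candidate, detection, models, genome, flank)
  reads <- all_single_ends(detection)
  rl <- as.integer(names(sort(table(nchar(reads)), decreasing = TRUE))[1])
  lib <- build_junction_library(regions$a, regions$b, tile_length(rl, min_overlap))
  hits <- align_to_library(reads, lib, max_mismatches = max_mismatches)
  calls <- call_junction(hits, lib, read_length = rl, models = models,
    genome = genome, ...)
  structure(
    list(regions = regions, library = lib, hits = hits, calls = calls),
    class = "junction_result"
  )
}

#' @export
print.junction_result <- function(x, ...) {
  cat("<junction_result> ", nrow(x$calls), " call(s); library ",
    format(x$library$n_elements, big.mark = ","), " elements; ",
    dplyr::n_distinct(x$hits$read_id), " reads hit\n",
    sep = ""
  )
  invisible(x)
}

# every single-end sequence of the sample, including the unmapped pool
all_single_ends <- function(detection) {
  p <- detection$pairs
  c(
    setNames(p$seq1, paste0(p$pair_id, "/1")),
    setNames(p$seq2, paste0(p$pair_id, "/2"))
  )
}

#' Export called junction sequences as FASTA
#'
#' @param calls A `junction_calls` tibble.
#' @param path Output FASTA path.
#' @export
write_junction_fasta <- function(calls, path) {
  if (nrow(calls) == 0) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(), path)
    return(invisible(path))
  }
  seqs <- Biostrings::DNAStringSet(calls$sequence)
  names(seqs) <- paste0(
    calls$gene_a, ":", calls$break_a, "|", calls$gene_b, ":", calls$break_b,
    "|", calls$orientation, "|support=", calls$support
  )
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
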