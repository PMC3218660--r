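#' Read and write aligned read pairs
#'
#' The pipeline consumes paired-end alignments either from SAM/BAM or from a
#' plain tab-delimited pair table. The tab format has one row per pair and
#' eleven columns: `pair_id`, then `chrom`, `strand`, `blocks`, `seq` for each
#' end, then `qc_pass` and `unique` (`0`/`1`). `blocks` encodes the aligned
#' reference blocks as `start-end` pairs (0-based half-open) joined by `;`,
#' e.g. `100-136` or `100-120;340-356`; an unmapped end has `chrom = "*"` and
#' `blocks = "*"`. Round-trips through [write_pairs_tab()] are byte-exact.
#'
#' @param path File path.
#' @return A tibble with columns `pair_id`, `chrom1`, `strand1`, `blocks1`
#'   (list of 2-column integer matrices), `seq1`, `mapped1`, the same for end
#'   2, `qc_pass` and `unique_pair`.
#' @export
read_pairs_tab <- function(path) {
  cols <- c(
    "pair_id", "chrom1", "strand1", "blocks1", "seq1",
    "chrom2", "strand2", "blocks2", "seq2", "qc_pass", "unique"
  )
  raw <- readr::read_tsv(path,
    col_names = cols,
    col_types = readr::cols(.default = readr::col_character())
  )
  parse_end <- function(chrom, blocks) {
    mapped <- chrom != "*"
    bl <- vector("list", length(chrom))
    bl[!mapped] <- list(cbind(start = integer(0), end = integer(0)))
    if (any(mapped)) {
      bl[mapped] <- map(strsplit(blocks[mapped], ";", fixed = TRUE), function(b) {
        m <- do.call(rbind, strsplit(b, "-", fixed = TRUE))
        cbind(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
      })
    }
    list(mapped = mapped, blocks = bl)
  }
  e1 <- parse_end(raw$chrom1, raw$blocks1)
  e2 <- parse_end(raw$chrom2, raw$blocks2)
  tibble(
    pair_id = raw$pair_id,
    chrom1 = ifelse(e1$mapped, raw$chrom1, NA_character_),
    strand1 = ifelse(e1$mapped, raw$strand1, NA_character_),
    blocks1 = e1$blocks, seq1 = raw$seq1, mapped1 = e1$mapped,
    chrom2 = ifelse(e2$mapped, raw$chrom2, NA_character_),
    strand2 = ifelse(e2$mapped, raw$strand2, NA_character_),
    blocks2 = e2$blocks, seq2 = raw$seq2, mapped2 = e2$mapped,
    qc_pass = raw$qc_pass == "1",
    unique_pair = raw$unique == "1"
  )
}

#' @rdname read_pairs_tab
#' @param pairs A pair tibble as returned by [read_pairs_tab()] or
#'   [simulate_reads()].
#' @export
write_pairs_tab <- function(pairs, path) {
  fmt_blocks <- function(blocks, mapped) {
    out <- map_chr(blocks, function(b) {
      paste(paste0(b[, "start"], "-", b[, "end"]), collapse = ";")
    })
    ifelse(mapped, out, "*")
  }
  out <- tibble(
    pair_id = pairs$pair_id,
    chrom1 = ifelse(pairs$mapped1, pairs$chrom1, "*"),
    strand1 = ifelse(pairs$mapped1, pairs$strand1, "*"),
    blocks1 = fmt_blocks(pairs$blocks1, pairs$mapped1),
    seq1 = pairs$seq1,
    chrom2 = ifelse(pairs$mapped2, pairs$chrom2, "*"),
    strand2 = ifelse(pairs$mapped2, pairs$strand2, "*"),
    blocks2 = fmt_blocks(pairs$blocks2, pairs$mapped2),
    seq2 = pairs$seq2,
    qc_pass = as.integer(pairs$qc_pass),
    unique = as.integer(pairs$unique_pair)
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read paired alignments from SAM/BAM
#'
#' SAM files are converted with `Rsamtools::asBam()` and read back through
#' `Rsamtools::scanBam()`; aligned blocks are derived from the CIGAR
#' reference space (M/=/X/D advance the block, N splits it). Pairs whose
#' records are flagged as secondary or supplementary are dropped; pairs
#' failing the platform quality flag get `qc_pass = FALSE`.
#'
#' @param path Path to a SAM or BAM file.
#' @return A pair tibble as in [read_pairs_tab()].
#' @export
read_pairs_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("reading SAM/BAM requires the Rsamtools package")
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE, indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "strand", "pos", "cigar", "seq")
  res <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(what = what))[[1]]
  flag <- res$flag
  keep <- bitwAnd(flag, 0x900) == 0L # primary records only
  d <- tibble(
    qname = res$qname[keep], flag = flag[keep],
    rname = as.character(res$rname)[keep], strand = as.character(res$strand)[keep],
    pos = res$pos[keep], cigar = res$cigar[keep],
    seq = as.character(res$seq)[keep]
  )
  d$mapped <- bitwAnd(d$flag, 0x4) == 0L
  d$first <- bitwAnd(d$flag, 0x40) != 0L
  d$fail <- bitwAnd(d$flag, 0x200) != 0L
  d$blocks <- cigar_blocks(d$cigar, d$pos, d$mapped)

  e1 <- d[d$first, ]
  e2 <- d[!d$first, ]
  i <- match(e1$qname, e2$qname)
  if (anyNA(i)) abort(paste0("unpaired record(s), e.g. '", e1$qname[which(is.na(i))[1]], "'"))
  e2 <- e2[i, ]
  tibble(
    pair_id = e1$qname,
    chrom1 = ifelse(e1$mapped, e1$rname, NA_character_),
    strand1 = ifelse(e1$mapped, e1$strand, NA_character_),
    blocks1 = e1$blocks, seq1 = e1$seq, mapped1 = e1$mapped,
    chrom2 = ifelse(e2$mapped, e2$rname, NA_character_),
    strand2 = ifelse(e2$mapped, e2$strand, NA_character_),
    blocks2 = e2$blocks, seq2 = e2$seq, mapped2 = e2$mapped,
    qc_pass = !(e1$fail | e2$fail),
    unique_pair = TRUE
  )
}

cigar_blocks <- function(cigar, pos, mapped) {
  out <- vector("list", length(cigar))
  empty <- cbind(start = integer(0), end = integer(0))
  for (k in seq_along(cigar)) {
    if (!mapped[k] || is.na(cigar[k])) {
      out[[k]] <- empty
      next
    }
    ops <- stringr::str_match_all(cigar[k], "(\\d+)([MIDNSHP=X])")[[1]]
    len <- as.integer(ops[, 2])
    op <- ops[, 3]
    ref_pos <- pos[k] - 1L # to 0-based
    starts <- integer(0)
    ends <- integer(0)
    open <- NA_integer_
    for (j in seq_along(op)) {
      if (op[j] %in% c("M", "=", "X", "D")) {
        if (is.na(open)) open <- ref_pos
        ref_pos <- ref_pos + len[j]
      } else if (op[j] == "N") {
        if (!is.na(open)) {
          starts <- c(starts, open)
          ends <- c(ends, ref_pos)
          open <- NA_integer_
        }
        ref_pos <- ref_pos + len[j]
      }
      # I/S/H/P do not advance the reference
    }
    if (!is.na(open)) {
      starts <- c(starts, open)
      ends <- c(ends, ref_pos)
    }
    out[[k]] <- cbind(start = starts, end = ends)
  }
  out
}

#' Write read pairs as SAM
#'
#' Emits a minimal headered SAM file (CIGAR uses `M` for aligned blocks and
#' `N` for skips) mirroring what [read_pairs_sam()] consumes.
#'
#' @param pairs Pair tibble.
#' @param path Output path.
#' @param seq_lengths Named integer vector of reference sequence lengths.
#' @export
write_pairs_sam <- function(pairs, path, seq_lengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(paste0("@SQ\tSN:", names(seq_lengths), "\tLN:", as.integer(seq_lengths)), con)
  fmt_cigar <- function(b) {
    if (nrow(b) == 0) return("*")
    widths <- b[, "end"] - b[, "start"]
    if (nrow(b) == 1) return(paste0(widths, "M"))
    gaps <- b[-1, "start"] - b[-nrow(b), "end"]
    paste0(paste0(widths, "M", c(paste0(gaps, "N"), "")), collapse = "")
  }
  lines <- character(2L * nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    for (e in 1:2) {
      mapped <- pairs[[paste0("mapped", e)]][k]
      omapped <- pairs[[paste0("mapped", 3 - e)]][k]
      b <- pairs[[paste0("blocks", e)]][[k]]
      strand <- pairs[[paste0("strand", e)]][k]
      ostrand <- pairs[[paste0("strand", 3 - e)]][k]
      flag <- 0x1 + (if (e == 1) 0x40 else 0x80) +
        (if (!mapped) 0x4 else 0L) + (if (!omapped) 0x8 else 0L) +
        (if (mapped && identical(strand, "-")) 0x10 else 0L) +
        (if (omapped && identical(ostrand, "-")) 0x20 else 0L) +
        (if (!pairs$qc_pass[k]) 0x200 else 0L)
      lines[2L * (k - 1L) + e] <- paste(
        pairs$pair_id[k], flag,
        if (mapped) pairs[[paste0("chrom", e)]][k] else "*",
        if (mapped) b[1, "start"] + 1L else 0L,
        if (mapped) 60L else 0L,
        if (mapped) fmt_cigar(b) else "*",
        "*", 0L, 0L,
        pairs[[paste0("seq", e)]][k], "*",
        sep = "\t"
      )
    }
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read gene models from annotation files
#'
#' Supports GTF (via `rtracklayer`, using `gene_id`/`transcript_id`
#' attributes of `exon` records) and a UCSC knownGene-style tab table with
#' columns `name`, `chrom`, `strand`, `exonStarts`, `exonEnds` (0-based
#' comma-separated lists) and an optional trailing `gene_id` column
#' (defaulting to `name`).
#'
#' @param path Annotation file.
#' @param format `"auto"` (by extension), `"gtf"` or `"knowngene"`.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "knowngene")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "knowngene"
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
    exons <- tibble(
      gene_id = S4Vectors::mcols(gr)$gene_id,
      tx_id = S4Vectors::mcols(gr)$transcript_id,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr)
    )
    return(gene_models(exons))
  }
  tab <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"))
  if (ncol(tab) < 5) abort("knownGene-style table needs at least 5 columns")
  names(tab)[1:5] <- c("name", "chrom", "strand", "exonStarts", "exonEnds")
  gene_id <- if (ncol(tab) >= 6) tab[[6]] else tab$name
  split_pos <- function(x) map(strsplit(x, ",", fixed = TRUE), as.integer)
  starts <- split_pos(tab$exonStarts)
  ends <- split_pos(tab$exonEnds)
  n_ex <- lengths(starts)
  exons <- tibble(
    gene_id = rep(gene_id, n_ex), tx_id = rep(tab$name, n_ex),
    chrom = rep(tab$chrom, n_ex), strand = rep(tab$strand, n_ex),
    start = unlist(starts), end = unlist(ends)
  )
  gene_models(exons)
}

#' Write gene models
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @export
write_gene_models_gtf <- function(models, path) {
  ex <- models$exons
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand
  )
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$source <- "pefusion"
  S4Vectors::mcols(gr)$gene_id <- ex$gene_id
  S4Vectors::mcols(gr)$transcript_id <- ex$tx_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_gene_models_gtf
#' @export
write_gene_models_knowngene <- function(models, path) {
  ex <- models$exons
  tab <- ex |>
    group_by(.data$tx_id) |>
    summarise(
      chrom = .data$chrom[1], strand = .data$strand[1],
      exonStarts = paste0(paste(.data$start[order(.data$start)], collapse = ","), ","),
      exonEnds = paste0(paste(.data$end[order(.data$start)], collapse = ","), ","),
      gene_id = .data$gene_id[1], .groups = "drop"
    ) |>
    select("tx_id", "chrom", "strand", "exonStarts", "exonEnds", "gene_id")
  readr::write_tsv(tab, path, col_names = FALSE)
  invisible(path)
}

#' Read an unordered paralog pair table
#'
#' @param path Two-column TSV of gene identifiers, one putatively paralogous
#'   pair per row (order within a row is irrelevant).
#' @return A tibble with columns `gene_a`, `gene_b`.
#' @export
read_paralogs <- function(path) {
  tab <- readr::read_tsv(path,
    col_names = c("gene_a", "gene_b"),
    col_types = readr::cols(.default = "c")
  )
  as_tibble(tab)
}

#' Read repeat intervals from BED
#'
#' @param path BED file of repeat intervals.
#' @return A tibble `chrom`, `start`, `end` (0-based half-open).
#' @export
read_repeats_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Read sequences from FASTA
#'
#' Thin wrapper over `Biostrings::readDNAStringSet()` used for genome,
#' transcript and ribosomal sequence inputs.
#'
#' @param path FASTA file.
#' @return A `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
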