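#' Gene models with composite exon unions
#'
#' Builds the annotation object used throughout the pipeline from a table of
#' exons. Each gene's isoform exons are collapsed into its *composite model*:
#' the union of all exonic intervals across isoforms, which serves as the
#' gene's transcript-level coordinate system for insert-size computations.
#'
#' All coordinates are handled internally as 0-based, half-open intervals;
#' GTF input/output converts from/to the 1-based closed convention.
#'
#' @param exons A data frame with columns `gene_id`, `tx_id`, `chrom`,
#'   `strand` (`"+"` or `"-"`), `start`, `end` (0-based half-open), one row
#'   per exon.
#' @return An object of class `gene_models`: a list with `$exons` (the input,
#'   validated and sorted) and `$genes`, a tibble of composite models with
#'   columns `gene_id`, `chrom`, `strand`, `blocks` (list of two-column
#'   matrices of disjoint sorted intervals), `total_length`, `span_start`,
#'   `span_end`.
#' @examples
#' ex <- tibble::tibble(
#'   gene_id = "g1", tx_id = c("t1", "t1", "t2"), chrom = "chr1",
#'   strand = "+", start = c(10L, 30L, 15L), end = c(20L, 40L, 35L)
#' )
#' gm <- gene_models(ex)
#' composite_models(gm)$total_length
#' @export
gene_models <- function(exons) {
  exons <- as_tibble(exons)
  required <- c("gene_id", "tx_id", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0) {
    abort(paste0("exon table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(exons) == 0) abort("empty exon table")
  if (!all(exons$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (any(exons$end <= exons$start)) abort("exon end must exceed exon start (0-based half-open)")
  exons <- arrange(exons, .data$gene_id, .data$tx_id, .data$start)

  genes <- exons |>
    group_by(.data$gene_id) |>
    group_modify_composite() |>
    ungroup()

  structure(list(exons = exons, genes = genes), class = "gene_models")
}

# per-gene composite: dplyr::group_modify wrapper kept separate for reuse
group_modify_composite <- function(grouped) {
  dplyr::group_modify(grouped, function(df, key) {
    cm <- composite_from_exons(df, key$gene_id)
    cm[, setdiff(names(cm), "gene_id")]
  })
}

composite_from_exons <- function(df, gene_id) {
  if (length(unique(df$chrom)) != 1 || length(unique(df$strand)) != 1) {
    abort(paste0("gene '", gene_id, "': isoforms on mixed chromosomes or strands"))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = df$start + 1L, end = df$end))
  blocks <- cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  total_length <- sum(blocks[, "end"] - blocks[, "start"])
  span_start <- blocks[1, "start"]
  span_end <- blocks[nrow(blocks), "end"]
  tibble(
    gene_id = gene_id, chrom = df$chrom[1], strand = df$strand[1],
    blocks = list(blocks),
    total_length = total_length,
    span_start = span_start, span_end = span_end
  )
}

#' Build the composite model for one gene
#'
#' Collapses the exons of all isoforms of a single gene into the union of
#' exonic intervals. This is the per-gene primitive behind [gene_models()].
#'
#' @param isoforms Exon table as in [gene_models()], restricted to one gene.
#' @return A one-row tibble as in the `genes` component of [gene_models()].
#' @export
build_composite_model <- function(isoforms) {
  isoforms <- as_tibble(isoforms)
  if (nrow(isoforms) == 0) abort("no isoforms supplied")
  if (length(unique(isoforms$gene_id)) != 1) abort("isoforms belong to more than one gene")
  for (tx in split(isoforms, isoforms$tx_id)) {
    tx <- arrange(tx, .data$start)
    if (nrow(tx) > 1 && any(tx$start[-1] < tx$end[-nrow(tx)])) {
      abort(paste0("isoform '", tx$tx_id[1], "': overlapping exons within one isoform"))
    }
  }
  composite_from_exons(arrange(isoforms, .data$start), isoforms$gene_id[1])
}

#' Extract composite models
#'
#' @param models A `gene_models` object.
#' @return The tibble of per-gene composite models.
#' @export
composite_models <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  models$genes
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models> ", nrow(x$genes), " genes, ",
    length(unique(x$exons$tx_id)), " isoforms on ",
    length(unique(x$genes$chrom)), " chromosome(s)\n",
    sep = ""
  )
  invisible(x)
}

# GRanges of composite blocks (1-based closed) with gene_id metadata
blocks_granges <- function(models) {
  g <- models$genes
  nb <- map_int(g$blocks, nrow)
  all_blocks <- do.call(rbind, g$blocks)
  GenomicRanges::GRanges(
    seqnames = rep(g$chrom, nb),
    ranges = IRanges::IRanges(start = all_blocks[, "start"] + 1L, end = all_blocks[, "end"]),
    gene_id = rep(g$gene_id, nb)
  )
}

spans_granges <- function(models) {
  g <- models$genes
  GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$span_start + 1L, end = g$span_end),
    gene_id = g$gene_id
  )
}

#' Map a genomic position to a composite transcript offset
#'
#' The offset of a genomic position is the number of composite (exonic)
#' nucleotides strictly before it; [transcript_to_genomic()] inverts the map.
#'
#' @param model One row of [composite_models()] output (or a `gene_models`
#'   object together with `gene_id`).
#' @param pos Integer vector of genomic positions (0-based) inside composite
#'   blocks.
#' @param gene_id Gene to use when `model` is a `gene_models` object.
#' @return Integer vector of 0-based transcript offsets.
#' @export
genomic_to_transcript <- function(model, pos, gene_id = NULL) {
  blocks <- resolve_blocks(model, gene_id)
  starts <- blocks[, "start"]
  ends <- blocks[, "end"]
  cum_before <- cumsum(c(0L, (ends - starts)))[seq_along(starts)]
  idx <- findInterval(pos, starts)
  bad <- idx == 0L | pos >= ends[pmax(idx, 1L)]
  if (any(bad)) {
    abort(paste0(
      "position(s) ", paste(pos[bad], collapse = ", "),
      " not inside the composite model (intronic or outside the gene)"
    ))
  }
  as.integer(cum_before[idx] + (pos - starts[idx]))
}

#' @rdname genomic_to_transcript
#' @param offset Integer vector of 0-based composite offsets.
#' @export
transcript_to_genomic <- function(model, offset, gene_id = NULL) {
  blocks <- resolve_blocks(model, gene_id)
  widths <- blocks[, "end"] - blocks[, "start"]
  cum <- cumsum(c(0L, widths))
  total <- cum[length(cum)]
  if (any(offset < 0L | offset >= total)) abort("offset outside the composite model")
  idx <- findInterval(offset, cum, rightmost.closed = FALSE)
  as.integer(blocks[idx, "start"] + (offset - cum[idx]))
}

resolve_blocks <- function(model, gene_id) {
  if (inherits(model, "gene_models")) {
    stopifnot(!is.null(gene_id))
    i <- match(gene_id, model$genes$gene_id)
    if (is.na(i)) abort(paste0("unknown gene '", gene_id, "'"))
    return(model$genes$blocks[[i]])
  }
  if (is.matrix(model)) return(model)
  stopifnot(is.data.frame(model), nrow(model) == 1)
  model$blocks[[1]]
}

#' Classify a single mapped end against the annotation
#'
#' A single-end alignment is labelled `exon` when its one block lies fully
#' inside a composite exon block, `boundary` when a block straddles an
#' exon/intron edge, `junction` when it has two or more blocks each fully
#' exonic within one gene, and `intron` when it falls inside a gene span
#' without touching exons. An end overlapping exons of several genes is
#' assigned to the gene with the larger exonic overlap (ties broken towards
#' the lexicographically smaller `gene_id`, and flagged).
#'
#' @param blocks A data frame with `chrom`, `start`, `end` (0-based half-open)
#'   rows describing the aligned blocks of one end, sorted by `start`.
#' @param models A `gene_models` object.
#' @return A one-row tibble: `label` (`exon`, `intron`, `junction`,
#'   `boundary`, or `NA` label with `gene_id = NA` if no gene overlaps),
#'   `gene_id`, `ambiguous`.
#' @export
classify_single_end <- function(blocks, models) {
  blocks <- as_tibble(blocks)
  ends <- tibble(
    end_id = 1L, chrom = blocks$chrom[1],
    blocks = list(cbind(start = as.integer(blocks$start), end = as.integer(blocks$end)))
  )
  res <- classify_ends(ends, models)
  select(res, "label", "gene_id", "ambiguous")
}

# Vectorised classification of many ends. `ends` has columns end_id, chrom,
# blocks (list of 2-col matrices). Returns one row per end.
classify_ends <- function(ends, models) {
  nb <- map_int(ends$blocks, nrow)
  flat <- do.call(rbind, ends$blocks)
  block_gr <- GenomicRanges::GRanges(
    seqnames = rep(ends$chrom, nb),
    ranges = IRanges::IRanges(start = flat[, "start"] + 1L, end = flat[, "end"])
  )
  owner <- rep(seq_len(nrow(ends)), nb)

  exon_gr <- blocks_granges(models)
  hits <- GenomicRanges::findOverlaps(block_gr, exon_gr)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(block_gr)[S4Vectors::queryHits(hits)],
    IRanges::ranges(exon_gr)[S4Vectors::subjectHits(hits)]
  ))
  qw <- IRanges::width(IRanges::ranges(block_gr))[S4Vectors::queryHits(hits)]
  h_end <- owner[S4Vectors::queryHits(hits)]
  h_block <- S4Vectors::queryHits(hits)
  h_gene <- S4Vectors::mcols(exon_gr)$gene_id[S4Vectors::subjectHits(hits)]
  h_full <- ov == qw

  # exonic overlap per (end, gene); pick max overlap, tie -> smaller gene_id.
  # Aggregated in base R: the grouping can reach 1e5+ keys.
  gene_ids <- sort(unique(models$genes$gene_id))
  gi <- match(h_gene, gene_ids)
  key <- (h_end - 1) * length(gene_ids) + gi
  ukey <- sort(unique(key))
  kidx <- match(key, ukey)
  n_keys <- length(ukey)
  agg_overlap <- as.vector(rowsum(ov, kidx, reorder = TRUE))
  first_block <- !duplicated(paste(key, h_block))
  agg_nblocks <- as.vector(rowsum(as.integer(first_block), kidx, reorder = TRUE))
  agg_allfull <- as.vector(rowsum(as.integer(!h_full), kidx, reorder = TRUE)) == 0
  per_gene <- tibble(
    end = ((ukey - 1) %/% length(gene_ids)) + 1,
    gene_id = gene_ids[((ukey - 1) %% length(gene_ids)) + 1],
    overlap = agg_overlap, n_blocks_hit = agg_nblocks, all_full = agg_allfull
  )
  ord <- order(per_gene$end, -per_gene$overlap, per_gene$gene_id, method = "radix")
  pg <- per_gene[ord, , drop = FALSE]
  keep1 <- !duplicated(pg$end)
  second <- which(keep1) + 1L
  amb <- rep(FALSE, sum(keep1))
  # ambiguity: a second gene for the same end with equal overlap
  valid2 <- second <= nrow(pg)
  same_end <- valid2 & pg$end[pmin(second, nrow(pg))] == pg$end[keep1]
  amb[same_end] <- pg$overlap[pmin(second, nrow(pg))][same_end] ==
    pg$overlap[keep1][same_end]
  best <- tibble(
    end = pg$end[keep1], gene_id = pg$gene_id[keep1],
    ambiguous = amb,
    n_blocks_hit = pg$n_blocks_hit[keep1], all_full = pg$all_full[keep1]
  )

  out <- tibble(
    end_id = ends$end_id, n_blocks = nb,
    gene_id = NA_character_, label = NA_character_, ambiguous = FALSE
  )
  i <- match(best$end, seq_len(nrow(ends)))
  out$gene_id[i] <- best$gene_id
  out$ambiguous[i] <- best$ambiguous
  exonic <- !is.na(out$gene_id)
  multi <- out$n_blocks >= 2L
  out$label[exonic] <- ifelse(
    multi[exonic] & best$n_blocks_hit[match(which(exonic), best$end)] >= 2L &
      best$all_full[match(which(exonic), best$end)],
    "junction",
    ifelse(best$all_full[match(which(exonic), best$end)] & !multi[exonic],
      "exon", "boundary"
    )
  )

  # ends without exonic overlap: intronic if inside some gene span
  no_exon <- which(!exonic)
  if (length(no_exon) > 0) {
    span_gr <- spans_granges(models)
    sub_owner <- owner %in% no_exon
    shits <- GenomicRanges::findOverlaps(block_gr[sub_owner], span_gr)
    if (length(shits) > 0) {
      sov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(block_gr[sub_owner])[S4Vectors::queryHits(shits)],
        IRanges::ranges(span_gr)[S4Vectors::subjectHits(shits)]
      ))
      stbl <- tibble(
        end = owner[sub_owner][S4Vectors::queryHits(shits)],
        gene_id = S4Vectors::mcols(span_gr)$gene_id[S4Vectors::subjectHits(shits)],
        overlap = sov
      ) |>
        group_by(.data$end, .data$gene_id) |>
        summarise(overlap = sum(.data$overlap), .groups = "drop") |>
        arrange(.data$end, desc(.data$overlap), .data$gene_id) |>
        group_by(.data$end) |>
        summarise(
          gene_id = .data$gene_id[1],
          ambiguous = n() > 1 && .data$overlap[2] == .data$overlap[1],
          .groups = "drop"
        )
      j <- stbl$end
      out$gene_id[j] <- stbl$gene_id
      out$label[j] <- "intron"
      out$ambiguous[j] <- stbl$ambiguous
    }
  }
  select(out, "end_id", "label", "gene_id", "ambiguous")
}

#' Classify a candidate gene pair
#'
#' Candidates are `inter` when the two genes lie on different chromosomes and
#' `intra` otherwise. Intra-chromosomal pairs with no third gene between
#' their spans are refined to `read-through` (same strand) or `cis`
#' (opposite strands). A third gene counts as lying between the pair when its
#' composite span intersects the open interval separating the two spans,
#' regardless of its strand.
#'
#' @param gene_a,gene_b Gene identifiers (must differ).
#' @param models A `gene_models` object.
#' @return One of `"inter"`, `"intra"`, `"read-through"`, `"cis"`.
#' @export
classify_candidate_type <- function(gene_a, gene_b, models) {
  if (identical(gene_a, gene_b)) abort("a fusion candidate needs two distinct genes")
  g <- models$genes
  ia <- match(gene_a, g$gene_id)
  ib <- match(gene_b, g$gene_id)
  if (is.na(ia) || is.na(ib)) abort("both genes must be present in the annotation")
  if (g$chrom[ia] != g$chrom[ib]) return("inter")
  gap_start <- min(g$span_end[ia], g$span_end[ib])
  gap_end <- max(g$span_start[ia], g$span_start[ib])
  if (gap_start < gap_end) {
    others <- g[-c(ia, ib), , drop = FALSE]
    others <- others[others$chrom == g$chrom[ia], , drop = FALSE]
    between <- others$span_start < gap_end & others$span_end > gap_start
    if (any(between)) return("intra")
  }
  # adjacent (or overlapping) with nothing between
  if (g$strand[ia] == g$strand[ib]) "read-through" else "cis"
}
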