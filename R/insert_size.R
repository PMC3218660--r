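#' Intra-transcript insert-size distribution
#'
#' The insert size of an intra-gene pair is the outer span of the two ends
#' (rightmost end minus leftmost start) measured in the gene's composite
#' transcript coordinates, so that spliced-out introns do not inflate it.
#' Only pairs whose every aligned block is fully contained within composite
#' exon blocks contribute, matching how the normal-transcriptome norm is
#' defined.
#'
#' @param detection A [detect_candidates()] result.
#' @param models A [gene_models()] object.
#' @return An object of class `insert_size_distribution` with `values`
#'   (integer insert sizes) and `median`.
#' @export
insert_size_distribution <- function(detection, models) {
  a <- detection$assignments
  ok <- a$class == "intra" &
    a$label1 %in% c("exon", "junction") & a$label2 %in% c("exon", "junction")
  idx <- which(ok)
  values <- integer(0)
  if (length(idx) > 0) {
    pairs <- detection$pairs
    genes <- a$gene1[idx]
    for (g in unique(genes)) {
      gi <- idx[genes == g]
      gb <- resolve_blocks(models, gene_id = g)
      bl <- c(pairs$blocks1[gi], pairs$blocks2[gi])
      owner <- rep(rep(seq_along(gi), 2L), map_int(bl, nrow))
      flat <- do.call(rbind, bl)
      off_s <- genomic_to_transcript(gb, flat[, "start"])
      off_e <- genomic_to_transcript(gb, flat[, "end"] - 1L)
      lo <- tapply(off_s, owner, min)
      hi <- tapply(off_e, owner, max) + 1L
      values <- c(values, as.integer(hi - lo))
    }
  }
  new_insert_size_distribution(values)
}

new_insert_size_distribution <- function(values) {
  structure(
    list(values = as.integer(values), median = if (length(values)) median(values) else NA_real_),
    class = "insert_size_distribution"
  )
}

#' @export
print.insert_size_distribution <- function(x, ...) {
  cat("<insert_size_distribution> n = ", length(x$values),
    ", median = ", x$median, "\n",
    sep = ""
  )
  invisible(x)
}

# Composite-coordinate footprints of candidates' chimeric ends, computed for
# every candidate at once. One row per (candidate, supporter pair, gene
# side); `exonic` is TRUE when the end's blocks intersect composite exon
# blocks (the footprint covers the exonic portion only), otherwise only the
# genomic hull is recorded.
all_chimeric_footprints <- function(candidates, detection, models) {
  if (nrow(candidates) == 0) {
    return(tibble(
      cand = integer(0), pair_id = character(0), side = character(0),
      exonic = logical(0), cstart = integer(0), cend = integer(0),
      gstart = integer(0), gend = integer(0)
    ))
  }
  pairs <- detection$pairs
  n_sup <- map_int(candidates$supporters, nrow)
  sup <- bind_rows(candidates$supporters)
  cand <- rep(seq_len(nrow(candidates)), n_sup)
  base <- bind_rows(
    tibble(
      cand = cand, pair_id = sup$pair_id, side = "a",
      end = sup$end_in_a, gene = candidates$gene_a[cand]
    ),
    tibble(
      cand = cand, pair_id = sup$pair_id, side = "b",
      end = 3L - sup$end_in_a, gene = candidates$gene_b[cand]
    )
  )
  rows <- match(base$pair_id, pairs$pair_id)
  blocks <- vector("list", nrow(base))
  e1 <- base$end == 1L
  blocks[e1] <- pairs$blocks1[rows[e1]]
  blocks[!e1] <- pairs$blocks2[rows[!e1]]
  nb <- map_int(blocks, nrow)
  flat <- do.call(rbind, blocks)
  owner <- rep(seq_len(nrow(base)), nb)

  base$gstart <- map_int(blocks, function(b) min(b[, "start"]))
  base$gend <- map_int(blocks, function(b) max(b[, "end"]))

  # overlap end blocks with the composite blocks of their own gene by using
  # the gene id as the sequence name
  end_gr <- GenomicRanges::GRanges(
    seqnames = rep(base$gene, nb),
    ranges = IRanges::IRanges(start = flat[, "start"] + 1L, end = flat[, "end"])
  )
  g <- models$genes
  nbl <- map_int(g$blocks, nrow)
  all_bl <- do.call(rbind, g$blocks)
  comp_gr <- GenomicRanges::GRanges(
    seqnames = rep(g$gene_id, nbl),
    ranges = IRanges::IRanges(start = all_bl[, "start"] + 1L, end = all_bl[, "end"])
  )
  suppressWarnings(
    hits <- GenomicRanges::findOverlaps(end_gr, comp_gr)
  )
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  inter <- IRanges::pintersect(
    IRanges::ranges(end_gr)[q], IRanges::ranges(comp_gr)[s]
  )
  hit_owner <- owner[q]
  hit_tbl <- tibble(
    owner = hit_owner,
    gene = base$gene[hit_owner],
    istart = IRanges::start(inter) - 1L,
    iend = IRanges::end(inter) - 1L # last included base, 0-based
  )
  base$cstart <- NA_integer_
  base$cend <- NA_integer_
  base$exonic <- FALSE
  if (nrow(hit_tbl) > 0) {
    for (gid in unique(hit_tbl$gene)) {
      gb <- resolve_blocks(models, gene_id = gid)
      sel <- hit_tbl$gene == gid
      off_s <- genomic_to_transcript(gb, hit_tbl$istart[sel])
      off_e <- genomic_to_transcript(gb, hit_tbl$iend[sel])
      own <- hit_tbl$owner[sel]
      mins <- tapply(off_s, own, min)
      maxs <- tapply(off_e, own, max)
      idx <- as.integer(names(mins))
      base$cstart[idx] <- as.integer(mins)
      base$cend[idx] <- as.integer(maxs) + 1L
      base$exonic[idx] <- TRUE
    }
  }
  select(base, "cand", "pair_id", "side", "exonic", "cstart", "cend", "gstart", "gend")
}

# single-candidate wrapper over the batch computation
chimeric_footprints <- function(candidate, detection, models) {
  fp <- all_chimeric_footprints(candidate[1, , drop = FALSE], detection, models)
  select(fp, -"cand")
}

#' Minimal fusion transcript fragment
#'
#' The minimal fusion transcript fragment is the only part of a putative
#' fusion transcript that paired-end data can delimit: per gene, the smallest
#' composite-coordinate interval containing every chimeric-read footprint.
#' Its length is the sum of the two per-gene region lengths. Candidates whose
#' supporters are all intronic have no defined fragment (`applicable =
#' FALSE`), and the insert-size filter is then not applied.
#'
#' @param candidate One row of the `candidates` tibble of a detection result.
#' @param detection The [detect_candidates()] result it came from.
#' @param models A [gene_models()] object.
#' @return A list of class `minimal_fusion_fragment`: `region_a`, `region_b`
#'   (composite-coordinate `c(start, end)`), `length`, `applicable`, and the
#'   footprint table.
#' @export
minimal_fusion_fragment <- function(candidate, detection, models) {
  fragment_from_footprints(chimeric_footprints(candidate, detection, models))
}

# fragments for every candidate at once (shared by the filters)
candidate_fragments <- function(candidates, detection, models) {
  fp_all <- all_chimeric_footprints(candidates, detection, models)
  map(seq_len(nrow(candidates)), function(i) {
    fragment_from_footprints(
      select(fp_all[fp_all$cand == i, , drop = FALSE], -"cand")
    )
  })
}

fragment_from_footprints <- function(fp) {
  ex <- fp[fp$exonic, , drop = FALSE]
  # pairs with both sides exonic define the fragment (one row per side, so
  # a duplicated pair_id means both sides are exonic)
  dup <- ex$pair_id %in% ex$pair_id[duplicated(ex$pair_id)]
  both <- ex[dup, , drop = FALSE]
  if (nrow(both) == 0) {
    return(structure(
      list(
        region_a = NULL, region_b = NULL, length = NA_integer_,
        applicable = FALSE, footprints = fp
      ),
      class = "minimal_fusion_fragment"
    ))
  }
  fa <- both[both$side == "a", ]
  fb <- both[both$side == "b", ]
  region_a <- c(start = min(fa$cstart), end = max(fa$cend))
  region_b <- c(start = min(fb$cstart), end = max(fb$cend))
  structure(
    list(
      region_a = region_a, region_b = region_b,
      length = unname((region_a["end"] - region_a["start"]) +
        (region_b["end"] - region_b["start"])),
      applicable = TRUE, footprints = fp
    ),
    class = "minimal_fusion_fragment"
  )
}

# Insert sizes of exonic chimeric pairs on the concatenated minimal fragment.
# Two aspects of the geometry are unobservable from PE data and are resolved
# conservatively in favour of the candidate:
#   * which edge of each gene's region faces the junction — the span is
#     evaluated under the four edge-orientation combinations and the one
#     with the smallest median span is used;
#   * the junction-facing anchor itself — the raw hull edge is set by the
#     single most extreme footprint, so one stray background supporter
#     shifts every pair's span by a constant; with many supporters the
#     anchor is therefore the 98th-percentile footprint edge (type-1
#     quantile: no trimming below ~50 supporters).
chimeric_insert_sizes <- function(fragment) {
  stopifnot(inherits(fragment, "minimal_fusion_fragment"))
  if (!fragment$applicable) return(integer(0))
  fp <- fragment$footprints
  exall <- fp[fp$exonic, , drop = FALSE]
  ex <- exall[exall$pair_id %in% exall$pair_id[duplicated(exall$pair_id)], , drop = FALSE]
  fa <- ex[ex$side == "a", ]
  fb <- ex[ex$side == "b", ]
  fb <- fb[match(fa$pair_id, fb$pair_id), ]
  anchor_hi <- function(x) unname(quantile(x, 0.98, type = 1))
  anchor_lo <- function(x) unname(quantile(x, 0.02, type = 1))
  d_a <- cbind(
    right = anchor_hi(fa$cend) - fa$cstart,
    left = fa$cend - anchor_lo(fa$cstart)
  )
  d_b <- cbind(
    left = fb$cend - anchor_lo(fb$cstart),
    right = anchor_hi(fb$cend) - fb$cstart
  )
  combos <- expand.grid(a = 1:2, b = 1:2)
  spans <- lapply(seq_len(nrow(combos)), function(i) {
    unname(d_a[, combos$a[i]] + d_b[, combos$b[i]])
  })
  meds <- vapply(spans, median, numeric(1))
  as.integer(spans[[which.min(meds)]])
}

# Add-one resampling p-value: probability that the median of k draws from the
# intra-transcript distribution is at least the observed chimeric median.
insert_size_pvalue <- function(intra, observed_median, k,
                               n_resamples = 10000L, seed = 1L) {
  stopifnot(inherits(intra, "insert_size_distribution"))
  if (length(intra$values) == 0) abort("empty intra-transcript insert-size distribution")
  meds <- with_seed(seed, {
    draws <- matrix(
      sample(intra$values, k * n_resamples, replace = TRUE),
      nrow = k
    )
    if (k == 1L) draws[1L, ] else matrixStats::colMedians(draws)
  })
  (1 + sum(meds >= observed_median)) / (1 + n_resamples)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
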