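#' Candidate scores: SPER and its expectations
#'
#' The supportive-pairs score of candidate *i* is
#' `SPER_i = m_i / N_mapped * 1e6`: inter-transcript pairs per million mapped
#' pairs. Its analytic expectation under random joining of single ends is
#' `<SPER_i> = m_A * m_B / N_mapped^2 * 1e6` (the probability of a random
#' pair landing on genes A and B is the product of the single-end mapping
#' probabilities), `DASPER_i = SPER_i - <SPER_i>` measures excess over that
#' null, and `RESPER_i = SPER_i / mean_j(SPER_j)` compares a candidate with
#' the other candidates of the same sample. `LSPER` (supporting pairs per
#' mean partner RPKM) is reported as a diagnostic only: with monoallelic
#' fusions the parent-gene expression need not track the fusion, so it is
#' never used for ranking.
#'
#' @param m_i Number of supporting inter-transcript pairs.
#' @param n_mapped Total number of mapped pairs (> 0).
#' @return A numeric score.
#' @examples
#' sper(100, 1e6) # 100
#' expected_sper(1000, 2000, 1e6) # 2
#' dasper(36.54, 0.01) # 36.53
#' @export
sper <- function(m_i, n_mapped) {
  if (any(n_mapped <= 0)) abort("SPER undefined: n_mapped must be positive")
  m_i / n_mapped * 1e6
}

#' @rdname sper
#' @param m_a,m_b Single-end read counts of the two genes.
#' @export
expected_sper <- function(m_a, m_b, n_mapped) {
  if (any(n_mapped <= 0)) abort("expected SPER undefined: n_mapped must be positive")
  # counts can exceed the integer range once multiplied
  as.numeric(m_a) * as.numeric(m_b) / as.numeric(n_mapped)^2 * 1e6
}

#' @rdname sper
#' @param sper_i,expected_sper_i Observed and expected SPER computed from the
#'   same `n_mapped`.
#' @export
dasper <- function(sper_i, expected_sper_i) {
  sper_i - expected_sper_i
}

#' @rdname sper
#' @param spers Vector of SPER values over all `M` candidates of a sample.
#' @return `resper()` returns the vector of ratios to the sample mean SPER.
#' @export
resper <- function(spers) {
  if (length(spers) == 0) abort("RESPER undefined: no candidates")
  m <- mean(spers)
  if (m <= 0) abort("RESPER undefined: all SPER values are zero")
  spers / m
}

#' @rdname sper
#' @param rpkm_a,rpkm_b RPKM values of the two genes.
#' @export
lsper <- function(m_i, rpkm_a, rpkm_b) {
  denom <- (rpkm_a + rpkm_b) / 2
  if (any(denom <= 0)) abort("LSPER undefined: zero mean RPKM")
  m_i / denom
}

#' @rdname sper
#' @param read_count Reads mapped to the region.
#' @param region_length_nt Region length in nucleotides (> 0).
#' @export
rpkm <- function(read_count, region_length_nt, n_mapped) {
  if (any(region_length_nt <= 0)) abort("RPKM undefined: zero region length")
  if (any(n_mapped <= 0)) abort("RPKM undefined: n_mapped must be positive")
  read_count / (region_length_nt / 1e3) / (n_mapped / 1e6)
}

#' Score surviving fusion candidates
#'
#' Computes SPER, expected SPER, DASPER, RESPER and LSPER for every candidate
#' of a filtered cascade (or, if given a raw detection result, for every
#' detected candidate). RESPER's denominator is the mean SPER over the scored
#' set. Single-end counts `m_A`/`m_B` include the chimeric ends themselves, a
#' deliberately conservative expectation.
#'
#' @param x A `fusion_cascade` (scores the kept set) or `fusion_detection`
#'   (scores everything).
#' @param models A [gene_models()] object.
#' @return A tibble of class `fusion_scores` sorted by descending DASPER,
#'   with columns `gene_a`, `gene_b`, `type`, `m_i`, `m_a`, `m_b`, `sper`,
#'   `expected_sper`, `dasper`, `resper`, `lsper`, `rpkm_a`, `rpkm_b`.
#' @export
score_candidates <- function(x, models) {
  if (inherits(x, "fusion_cascade")) {
    candidates <- x$kept
    detection <- x$detection
  } else if (inherits(x, "fusion_detection")) {
    candidates <- x$candidates
    detection <- x
  } else {
    abort("x must be a fusion_cascade or fusion_detection")
  }
  n_mapped <- detection$n_mapped
  if (nrow(candidates) == 0) {
    out <- tibble(
      gene_a = character(0), gene_b = character(0), type = character(0),
      m_i = integer(0), m_a = integer(0), m_b = integer(0),
      sper = numeric(0), expected_sper = numeric(0), dasper = numeric(0),
      resper = numeric(0), lsper = numeric(0),
      rpkm_a = numeric(0), rpkm_b = numeric(0)
    )
    return(structure(out, class = c("fusion_scores", class(out)), n_mapped = n_mapped))
  }
  g <- models$genes
  m_a <- gene_count(detection, candidates$gene_a)
  m_b <- gene_count(detection, candidates$gene_b)
  len_a <- g$total_length[match(candidates$gene_a, g$gene_id)]
  len_b <- g$total_length[match(candidates$gene_b, g$gene_id)]
  sp <- sper(candidates$n_support, n_mapped)
  esp <- expected_sper(m_a, m_b, n_mapped)
  rpk_a <- rpkm(m_a, len_a, n_mapped)
  rpk_b <- rpkm(m_b, len_b, n_mapped)
  out <- tibble(
    gene_a = candidates$gene_a, gene_b = candidates$gene_b,
    type = candidates$type, m_i = candidates$n_support,
    m_a = m_a, m_b = m_b,
    sper = sp, expected_sper = esp, dasper = dasper(sp, esp),
    resper = resper(sp),
    lsper = ifelse(rpk_a + rpk_b > 0, lsper(candidates$n_support, rpk_a, rpk_b), NA_real_),
    rpkm_a = rpk_a, rpkm_b = rpk_b
  )
  out <- rank_candidates(out, key = "dasper")
  structure(out, class = c("fusion_scores", class(tibble())), n_mapped = n_mapped)
}

#' Rank scored candidates
#'
#' Stable descending sort by the chosen key; ties are broken by DASPER and
#' then by the gene-pair identifier, so the order is deterministic.
#'
#' @param scores A `fusion_scores` tibble.
#' @param key `"dasper"` (default report order), `"resper"` or `"sper"`.
#' @return The reordered tibble.
#' @export
rank_candidates <- function(scores, key = c("dasper", "resper", "sper")) {
  key <- match.arg(key)
  ord <- order(
    -scores[[key]], -scores$dasper,
    paste(scores$gene_a, scores$gene_b),
    method = "radix"
  )
  scores[ord, , drop = FALSE]
}

#' Write the candidate score table
#'
#' Fixed column order: gene pair, type, supporter count, SPER, expected SPER,
#' DASPER, RESPER, LSPER, single-end counts, RPKMs.
#'
#' @param scores A `fusion_scores` tibble.
#' @param path Output TSV path.
#' @export
write_score_table <- function(scores, path) {
  cols <- c(
    "gene_a", "gene_b", "type", "m_i", "sper", "expected_sper",
    "dasper", "resper", "lsper", "m_a", "m_b", "rpkm_a", "rpkm_b"
  )
  readr::write_tsv(as_tibble(scores)[, cols], path)
  invisible(path)
}
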