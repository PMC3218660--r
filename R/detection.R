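#' Assign read pairs to the transcriptome or to candidate gene pairs
#'
#' Every quality-passing, uniquely-mapping pair is assigned to exactly one of
#' three classes: `intra` when both ends classify to the same gene (part of
#' the normal transcriptome), `inter` when the two ends classify to two
#' distinct genes (a potential fusion supporter), and `unassigned` when an
#' end is unmapped or overlaps no gene. Sequences of unmapped ends are
#' retained for junction-sequence identification.
#'
#' @param pairs A pair tibble (see [read_pairs_tab()]).
#' @param models A [gene_models()] object.
#' @return An object of class `fusion_detection`: a list with
#'   * `candidates`: tibble keyed by unordered gene pair (`gene_a` <
#'     `gene_b`), with `type`, `n_support` and a nested `supporters` tibble
#'     (`pair_id`, `end_in_a`);
#'   * `assignments`: per-pair class and per-end gene/category labels;
#'   * `gene_counts`: single-end counts `m` per gene;
#'   * `n_mapped`: number of quality pairs with both ends mapped;
#'   * `unmapped`: tibble of retained unmapped-end sequences;
#'   * `pairs`: the quality-passing pairs the result was computed from.
#' @export
detect_candidates <- function(pairs, models) {
  stopifnot(inherits(models, "gene_models"))
  pairs <- as_tibble(pairs)
  keep <- pairs$qc_pass & pairs$unique_pair
  pairs <- pairs[keep, , drop = FALSE]

  n <- nrow(pairs)
  if (n == 0) {
    return(new_fusion_detection(
      candidates = empty_candidates(), assignments = tibble(),
      gene_counts = tibble(gene_id = character(0), m = integer(0)),
      n_mapped = 0L, unmapped = tibble(read_id = character(0), seq = character(0)),
      pairs = pairs
    ))
  }

  end_rows <- bind_rows(
    tibble(
      pair = seq_len(n), end = 1L, chrom = pairs$chrom1,
      blocks = pairs$blocks1, mapped = pairs$mapped1
    ),
    tibble(
      pair = seq_len(n), end = 2L, chrom = pairs$chrom2,
      blocks = pairs$blocks2, mapped = pairs$mapped2
    )
  )
  mapped_rows <- end_rows[end_rows$mapped, , drop = FALSE]
  cls <- classify_ends(
    tibble(
      end_id = seq_len(nrow(mapped_rows)), chrom = mapped_rows$chrom,
      blocks = mapped_rows$blocks
    ),
    models
  )
  end_rows$gene_id <- NA_character_
  end_rows$label <- NA_character_
  end_rows$gene_id[end_rows$mapped] <- cls$gene_id
  end_rows$label[end_rows$mapped] <- cls$label

  g1 <- end_rows$gene_id[end_rows$end == 1L][order(end_rows$pair[end_rows$end == 1L])]
  g2 <- end_rows$gene_id[end_rows$end == 2L][order(end_rows$pair[end_rows$end == 2L])]
  l1 <- end_rows$label[end_rows$end == 1L][order(end_rows$pair[end_rows$end == 1L])]
  l2 <- end_rows$label[end_rows$end == 2L][order(end_rows$pair[end_rows$end == 2L])]

  class <- ifelse(
    is.na(g1) | is.na(g2), "unassigned",
    ifelse(g1 == g2, "intra", "inter")
  )
  assignments <- tibble(
    pair_id = pairs$pair_id, class = class,
    gene1 = g1, gene2 = g2, label1 = l1, label2 = l2
  )

  gene_counts <- tibble(gene_id = c(g1, g2)) |>
    filter(!is.na(.data$gene_id)) |>
    dplyr::count(.data$gene_id, name = "m") |>
    arrange(.data$gene_id)

  inter <- which(class == "inter")
  if (length(inter) > 0) {
    a_first <- g1[inter] < g2[inter]
    cand_tbl <- tibble(
      gene_a = ifelse(a_first, g1[inter], g2[inter]),
      gene_b = ifelse(a_first, g2[inter], g1[inter]),
      pair_id = pairs$pair_id[inter],
      end_in_a = ifelse(a_first, 1L, 2L)
    ) |>
      arrange(.data$gene_a, .data$gene_b, .data$pair_id)
    candidates <- cand_tbl |>
      group_by(.data$gene_a, .data$gene_b) |>
      summarise(
        n_support = n(),
        supporters = list(tibble(pair_id = pair_id, end_in_a = end_in_a)),
        .groups = "drop"
      )
    candidates$type <- map2_chr_safe(candidates$gene_a, candidates$gene_b, models)
    candidates <- select(
      candidates, "gene_a", "gene_b", "type", "n_support", "supporters"
    )
  } else {
    candidates <- empty_candidates()
  }

  unmapped_ends <- end_rows[!end_rows$mapped, , drop = FALSE]
  unmapped <- tibble(
    read_id = paste0(pairs$pair_id[unmapped_ends$pair], "/", unmapped_ends$end),
    seq = ifelse(unmapped_ends$end == 1L,
      pairs$seq1[unmapped_ends$pair], pairs$seq2[unmapped_ends$pair]
    )
  )

  new_fusion_detection(
    candidates = candidates, assignments = assignments,
    gene_counts = gene_counts,
    n_mapped = sum(pairs$mapped1 & pairs$mapped2),
    unmapped = unmapped, pairs = pairs
  )
}

map2_chr_safe <- function(gene_a, gene_b, models) {
  map2(gene_a, gene_b, function(a, b) classify_candidate_type(a, b, models)) |>
    unlist()
}

empty_candidates <- function() {
  tibble(
    gene_a = character(0), gene_b = character(0), type = character(0),
    n_support = integer(0), supporters = list()
  )
}

new_fusion_detection <- function(candidates, assignments, gene_counts, n_mapped,
                                 unmapped, pairs) {
  structure(
    list(
      candidates = candidates, assignments = assignments,
      gene_counts = gene_counts, n_mapped = n_mapped,
      unmapped = unmapped, pairs = pairs
    ),
    class = "fusion_detection"
  )
}

#' @export
print.fusion_detection <- function(x, ...) {
  cat("<fusion_detection> ", x$n_mapped, " mapped pairs, ",
    nrow(x$candidates), " candidate gene pair(s), ",
    nrow(x$unmapped), " unmapped end(s) pooled\n",
    sep = ""
  )
  invisible(x)
}

#' Assign a single pair
#'
#' Single-pair convenience wrapper over the vectorised assignment performed
#' by [detect_candidates()].
#'
#' @param pair One-row pair tibble.
#' @param models A [gene_models()] object.
#' @return A list with `class` (`"intra"`, `"inter"` or `"unassigned"`) and
#'   the genes involved (`gene1`, `gene2`).
#' @export
assign_pair <- function(pair, models) {
  det <- detect_candidates(pair, models)
  a <- det$assignments
  if (nrow(a) == 0) abort("pair did not pass the quality filter")
  list(class = a$class[1], gene1 = a$gene1[1], gene2 = a$gene2[1])
}

# m_g lookup with zero default
gene_count <- function(detection, gene_id) {
  m <- detection$gene_counts$m[match(gene_id, detection$gene_counts$gene_id)]
  ifelse(is.na(m), 0L, m)
}
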