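#' Run the full fusion-discovery pipeline
#'
#' Chains detection, the filtration cascade, scoring and (optionally)
#' junction-sequence resolution for the top-ranked survivors.
#'
#' @param pairs Pair tibble (see [read_pairs_tab()]).
#' @param models A [gene_models()] object.
#' @param config A [cascade_config()]; its `genome` is also used by the
#'   junction stage.
#' @param junction Resolve junction sequences for the top candidates.
#' @param junction_top How many top candidates (by DASPER) to resolve.
#' @param ... Passed to [find_junction()].
#' @return An object of class `fusion_analysis` with components `detection`,
#'   `cascade`, `scores` and `junctions` (named list of [find_junction()]
#'   results).
#' @export
run_fusion_pipeline <- function(pairs, models, config = cascade_config(),
                                junction = TRUE, junction_top = 3L, ...) {
  detection <- detect_candidates(pairs, models)
  cascade <- run_cascade(detection, models, config)
  scores <- score_candidates(cascade, models)
  junctions <- list()
  if (junction && !is.null(config$genome) && nrow(scores) > 0) {
    top <- head(scores, junction_top)
    for (i in seq_len(nrow(top))) {
      key <- paste0(top$gene_a[i], "|", top$gene_b[i])
      cand <- cascade$kept[
        cascade$kept$gene_a == top$gene_a[i] & cascade$kept$gene_b == top$gene_b[i], ,
        drop = FALSE
      ]
      junctions[[key]] <- find_junction(
        cand[1, ], detection, models, config$genome, ...
      )
    }
  }
  structure(
    list(
      detection = detection, cascade = cascade, scores = scores,
      junctions = junctions
    ),
    class = "fusion_analysis"
  )
}

#' @export
print.fusion_analysis <- function(x, ...) {
  cat("<fusion_analysis>\n")
  print(x$detection)
  print(x$cascade)
  if (nrow(x$scores) > 0) {
    cat("top candidate: ", x$scores$gene_a[1], "-", x$scores$gene_b[1],
      " (DASPER ", sprintf("%.2f", x$scores$dasper[1]), ")\n",
      sep = ""
    )
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fusion_analysis <- function(x, ...) {
  as_tibble(x$scores)
}

#' @exportS3Method generics::glance
glance.fusion_analysis <- function(x, ...) {
  tibble(
    n_mapped = x$detection$n_mapped,
    n_candidates = x$cascade$n_in,
    n_kept = nrow(x$cascade$kept),
    overall_reduction_pct = overall_reduction(x$cascade),
    n_junction_calls = sum(map_int(x$junctions, function(j) nrow(j$calls))),
    top_dasper = if (nrow(x$scores) > 0) x$scores$dasper[1] else NA_real_
  )
}

#' @exportS3Method generics::tidy
tidy.fusion_detection <- function(x, ...) {
  select(x$candidates, "gene_a", "gene_b", "type", "n_support")
}

#' @exportS3Method generics::glance
glance.fusion_detection <- function(x, ...) {
  tibble(
    n_mapped = x$n_mapped, n_candidates = nrow(x$candidates),
    n_unmapped_pooled = nrow(x$unmapped)
  )
}
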