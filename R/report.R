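#' Per-filter removal percentages
#'
#' Summarises a cascade audit table: for each filter, the number of
#' candidates it evaluated, the number it would remove, and the removal
#' percentage (removed / entering x 100). The attached
#' `overall_reduction_pct` attribute gives the end-to-end reduction.
#'
#' @param audit Audit tibble (`tidy()` of a `fusion_cascade`, or the
#'   `audit.tsv` it exports).
#' @param n_in Number of candidates entering the cascade; defaults to the
#'   number evaluated by the first filter.
#' @return A tibble `filter`, `n_evaluated`, `n_removed`, `removed_pct`.
#' @export
summarize_filters <- function(audit, n_in = NULL) {
  if (nrow(audit) == 0) {
    out <- tibble(
      filter = character(0), n_evaluated = integer(0),
      n_removed = integer(0), removed_pct = numeric(0)
    )
    attr(out, "overall_reduction_pct") <- 0
    return(out)
  }
  out <- audit |>
    group_by(.data$filter) |>
    summarise(
      n_evaluated = n(), n_removed = sum(!.data$kept),
      removed_pct = 100 * sum(!.data$kept) / n(),
      .groups = "drop"
    )
  n_in <- n_in %||% out$n_evaluated[1]
  kept_final <- audit |>
    group_by(.data$gene_a, .data$gene_b) |>
    summarise(kept = all(.data$kept), .groups = "drop")
  n_kept <- sum(kept_final$kept)
  attr(out, "overall_reduction_pct") <-
    if (n_in > 0) 100 * (n_in - n_kept) / n_in else 0
  out
}

#' Export genome-browser tracks
#'
#' Writes static files in place of an interactive browser: a BED of the
#' supporting read footprints of each kept candidate, a GFF3 of the
#' composite gene models, and a WIG of per-base chimeric read coverage.
#' Coordinates follow each format's native convention (BED 0-based
#' half-open, GFF 1-based closed).
#'
#' @param cascade A `fusion_cascade` (kept candidates are exported).
#' @param models A [gene_models()] object.
#' @param dir Output directory.
#' @return Named list of written file paths, invisibly.
#' @export
export_tracks <- function(cascade, models, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  detection <- cascade$detection
  paths <- list(
    bed = file.path(dir, "supporting_reads.bed"),
    gff = file.path(dir, "composite_models.gff3"),
    wig = file.path(dir, "chimeric_coverage.wig")
  )

  rows <- list()
  cand <- cascade$kept
  for (i in seq_len(nrow(cand))) {
    sup <- cand$supporters[[i]]
    idx <- match(sup$pair_id, detection$pairs$pair_id)
    for (k in seq_along(idx)) {
      for (e in 1:2) {
        b <- detection$pairs[[paste0("blocks", e)]][[idx[k]]]
        if (nrow(b) == 0) next
        rows[[length(rows) + 1]] <- tibble(
          chrom = detection$pairs[[paste0("chrom", e)]][idx[k]],
          start = b[, "start"], end = b[, "end"],
          name = paste0(cand$gene_a[i], "-", cand$gene_b[i], "|", sup$pair_id[k], "/", e)
        )
      }
    }
  }
  read_tbl <- bind_rows(rows)
  read_gr <- if (nrow(read_tbl) > 0) {
    GenomicRanges::GRanges(
      seqnames = read_tbl$chrom,
      ranges = IRanges::IRanges(start = read_tbl$start + 1L, end = read_tbl$end),
      name = read_tbl$name
    )
  } else {
    GenomicRanges::GRanges()
  }
  rtracklayer::export(read_gr, paths$bed, format = "bed")

  comp_gr <- blocks_granges(models)
  S4Vectors::mcols(comp_gr)$type <- "exonic_block"
  S4Vectors::mcols(comp_gr)$source <- "pefusion"
  S4Vectors::mcols(comp_gr)$ID <- paste0(
    S4Vectors::mcols(comp_gr)$gene_id, ".", seq_along(comp_gr)
  )
  rtracklayer::export(comp_gr, paths$gff, format = "gff3")

  if (length(read_gr) > 0) {
    cov <- GenomicRanges::coverage(read_gr)
    cov_gr <- methods::as(cov, "GRanges")
    cov_gr <- cov_gr[S4Vectors::mcols(cov_gr)$score > 0]
    # WIG needs a uniform span: emit per-base positions
    per_base <- GenomicRanges::GPos(cov_gr)
    S4Vectors::mcols(per_base)$score <- rep(
      S4Vectors::mcols(cov_gr)$score, GenomicRanges::width(cov_gr)
    )
    rtracklayer::export(per_base, paths$wig, format = "wig")
  } else {
    writeLines(character(0), paths$wig)
  }
  invisible(paths)
}

#' Write a run manifest
#'
#' Records tool version, the configuration snapshot, the seed, optional
#' per-stage timings, and a checksum for every file in the output directory.
#'
#' @param dir Run output directory.
#' @param config A [cascade_config()] (resources are recorded by class, not
#'   content).
#' @param seed Seed used for the run.
#' @param timings Optional named numeric vector of stage timings (seconds).
#' @return Path of the written `manifest.json`, invisibly.
#' @export
write_run_manifest <- function(dir, config = NULL, seed = NA_integer_,
                               timings = NULL) {
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  sums <- tools::md5sum(file.path(dir, files))
  cfg <- NULL
  if (!is.null(config)) {
    scalar <- config[vapply(config, function(x) is.atomic(x) && length(x) <= 8, logical(1))]
    cfg <- scalar
  }
  manifest <- list(
    tool = "pefusion",
    version = as.character(utils::packageVersion("pefusion")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = cfg,
    timings = as.list(timings),
    outputs = map(seq_along(files), function(i) {
      list(file = files[i], md5 = unname(sums[i]))
    })
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write the cascade audit table
#'
#' One row per (candidate, filter) with the decision and its statistic.
#'
#' @param cascade A `fusion_cascade`.
#' @param path Output TSV path.
#' @export
write_audit_table <- function(cascade, path) {
  readr::write_tsv(cascade$audit, path)
  invisible(path)
}

#' Write the junction report
#'
#' @param calls A `junction_calls` tibble.
#' @param path Output TSV path.
#' @export
write_junction_table <- function(calls, path) {
  readr::write_tsv(as_tibble(calls), path)
  invisible(path)
}
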