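#' Configuration for the filtration cascade
#'
#' Bundles the thresholds and resources the seven artifact filters need.
#' Resources may be given as in-memory objects (tibbles, `DNAStringSet`s) or
#' as file paths, which are loaded lazily. Filters whose optional resource is
#' absent (paralog table, repeat track, ribosomal library) simply keep
#' everything; filters that cannot run without a mandatory resource (the
#' sequence-based ones need the genome) raise a configuration error naming
#' the filter when enabled.
#'
#' @param enable Character vector of filters to run; defaults to all seven.
#' @param fast_fraction,refined_fraction Per-gene-side read fractions above
#'   which the two steps of the small-scale similarity filter discard a
#'   candidate (defaults 0.01).
#' @param identity Matched fraction of read length that counts as a
#'   similarity hit (default 0.75), used by the refined small-scale step and
#'   the ribosomal filter.
#' @param max_mismatches Mismatch allowance of the fast small-scale step
#'   (default 3).
#' @param ribo_fraction Hit fraction above which the ribosomal filter
#'   discards (default 0.10).
#' @param alpha Insert-size filter p-value cutoff (default 0.01; samples with
#'   very tight insert distributions may warrant e.g. 1e-4).
#' @param n_resamples,seed Resampling settings for the insert-size p-value.
#' @param pcr_p Extra nucleotides beyond the read size that supporter
#'   footprints must independently cover on both gene sides (default 5).
#' @param read_length Read length used by the PCR filter; inferred from the
#'   supporter sequences when `NULL`.
#' @param paralogs,repeats,rrna,genome Resources: unordered paralog pair
#'   table (tibble or TSV path), repeat intervals (tibble or BED path),
#'   ribosomal sequences (`DNAStringSet` or FASTA path), genome sequences
#'   (`DNAStringSet` or FASTA path).
#' @return A `cascade_config` list.
#' @export
cascade_config <- function(enable = c(
                             "repeats", "paralogs", "small_scale",
                             "insert_size", "ribosomal",
                             "expression_consistency", "pcr"
                           ),
                           fast_fraction = 0.01, refined_fraction = 0.01,
                           identity = 0.75, max_mismatches = 3L,
                           ribo_fraction = 0.10,
                           alpha = 0.01, n_resamples = 10000L, seed = 1L,
                           pcr_p = 5L, read_length = NULL,
                           paralogs = NULL, repeats = NULL, rrna = NULL,
                           genome = NULL) {
  known <- c(
    "repeats", "paralogs", "small_scale", "insert_size", "ribosomal",
    "expression_consistency", "pcr"
  )
  bad <- setdiff(enable, known)
  if (length(bad) > 0) abort(paste0("unknown filter(s): ", paste(bad, collapse = ", ")))
  if (is.character(paralogs)) paralogs <- read_paralogs(paralogs)
  if (is.character(repeats)) repeats <- read_repeats_bed(repeats)
  if (is.character(rrna)) rrna <- read_fasta(rrna)
  if (is.character(genome)) genome <- read_fasta(genome)
  structure(
    list(
      enable = enable, fast_fraction = fast_fraction,
      refined_fraction = refined_fraction, identity = identity,
      max_mismatches = as.integer(max_mismatches),
      ribo_fraction = ribo_fraction, alpha = alpha,
      n_resamples = as.integer(n_resamples), seed = as.integer(seed),
      pcr_p = as.integer(pcr_p), read_length = read_length,
      paralogs = paralogs, repeats = repeats, rrna = rrna, genome = genome
    ),
    class = "cascade_config"
  )
}

#' Read a key-value cascade configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Keys match the arguments of [cascade_config()]; `enable` takes a
#' comma-separated filter list, resource keys take file paths.
#'
#' @param path Configuration file path.
#' @return A [cascade_config()] object.
#' @export
read_cascade_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- stringr::str_match(lines, "^([A-Za-z_]+)\\s*[:=]\\s*(.*)$")
  if (anyNA(kv[, 1])) abort(paste0("unparseable config line: '", lines[is.na(kv[, 1])][1], "'"))
  args <- as.list(trimws(kv[, 3]))
  names(args) <- kv[, 2]
  numeric_keys <- c(
    "fast_fraction", "refined_fraction", "identity", "ribo_fraction", "alpha"
  )
  integer_keys <- c("max_mismatches", "n_resamples", "seed", "pcr_p", "read_length")
  for (k in intersect(names(args), numeric_keys)) args[[k]] <- as.numeric(args[[k]])
  for (k in intersect(names(args), integer_keys)) args[[k]] <- as.integer(args[[k]])
  if ("enable" %in% names(args)) {
    args$enable <- trimws(strsplit(args$enable, ",", fixed = TRUE)[[1]])
  }
  do.call(cascade_config, args)
}

decision_row <- function(candidate, filter, kept, statistic = NA_real_, note = "") {
  tibble(
    gene_a = candidate$gene_a, gene_b = candidate$gene_b,
    filter = filter, kept = kept, statistic = statistic, note = note
  )
}

#' Large-scale similarity (paralog) filter
#'
#' Discards candidates whose gene pair appears in a user-supplied table of
#' paralogous pairs (the match is unordered). An empty or absent table keeps
#' everything.
#'
#' @param candidates Candidate tibble (rows of a detection result).
#' @param paralogs Tibble with columns `gene_a`, `gene_b`, or `NULL`.
#' @return A decision tibble: one row per candidate with `filter`, `kept`,
#'   `statistic`, `note`.
#' @export
paralog_filter <- function(candidates, paralogs = NULL) {
  if (is.null(paralogs) || nrow(paralogs) == 0) {
    return(decision_row(candidates, "paralogs", rep(TRUE, nrow(candidates)),
      note = "no paralog table"
    ))
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  table_keys <- key(paralogs$gene_a, paralogs$gene_b)
  hit <- key(candidates$gene_a, candidates$gene_b) %in% table_keys
  decision_row(candidates, "paralogs", !hit,
    note = ifelse(hit, "gene pair listed as paralogous", "")
  )
}

#' Small-scale sequence similarity filter
#'
#' Two-step screen for local homology between the two partner genes that
#' could misalign reads. Step 1: each supporting read from one gene is
#' matched end-to-end against the partner gene's composite sequence allowing
#' up to `max_mismatches` substitutions; if the hit fraction on either gene
#' side exceeds `fast_fraction` the candidate is discarded. Step 2 (only
#' when step 1 keeps): a local-similarity search; a hit needs at least
#' `identity` of the read length matched, and a side fraction above
#' `refined_fraction` discards.
#'
#' @inheritParams paralog_filter
#' @param detection The detection result the candidates came from.
#' @param models A [gene_models()] object.
#' @param genome Genome `DNAStringSet`.
#' @param fast_fraction,refined_fraction,identity,max_mismatches See
#'   [cascade_config()].
#' @return A decision tibble.
#' @export
small_scale_similarity_filter <- function(candidates, detection, models, genome,
                                          fast_fraction = 0.01,
                                          refined_fraction = 0.01,
                                          identity = 0.75, max_mismatches = 3L) {
  if (is.null(genome)) {
    abort("small_scale filter: genome sequences are required but not configured")
  }
  n <- nrow(candidates)
  kept <- rep(TRUE, n)
  stat <- rep(NA_real_, n)
  note <- rep("", n)
  seq_cache <- new.env(parent = emptyenv())
  comp_seq <- function(gid) {
    if (is.null(seq_cache[[gid]])) {
      seq_cache[[gid]] <- composite_sequence(models, genome, gid)
    }
    seq_cache[[gid]]
  }
  read_sets <- map(seq_len(n), function(i) supporter_reads(candidates[i, ], detection))
  make_jobs <- function(idx) {
    bind_rows(map(idx, function(i) {
      reads <- read_sets[[i]]
      tibble(
        cand = i, side = reads$side, seq = reads$seq,
        subject = ifelse(reads$side == "a", candidates$gene_b[i], candidates$gene_a[i])
      )
    }))
  }
  # the per-side hit fraction, maximised over sides, per candidate
  side_fractions <- function(jobs) {
    key <- paste(jobs$cand, jobs$side)
    frac <- tapply(jobs$hit, key, mean)
    cand <- as.integer(vapply(strsplit(names(frac), " "), `[`, "", 1L))
    tapply(as.vector(frac), cand, max)
  }
  run_engine <- function(jobs, engine) {
    jobs$hit <- FALSE
    for (gid in unique(jobs$subject)) {
      sel <- jobs$subject == gid
      uniq <- unique(jobs$seq[sel])
      h <- setNames(engine(uniq, comp_seq(gid)), uniq)
      jobs$hit[sel] <- unname(h[jobs$seq[sel]])
    }
    jobs
  }

  # step 1: exhaustive k-mismatch matching of each side's reads against the
  # partner gene's composite sequence, pooled by subject gene
  jobs <- run_engine(make_jobs(seq_len(n)), function(reads, subj) {
    kmismatch_hits(reads, subj, max_mismatches)
  })
  fast <- side_fractions(jobs)
  fast_cand <- as.integer(names(fast))
  fail1 <- fast_cand[fast > fast_fraction]
  kept[fail1] <- FALSE
  stat[fail1] <- fast[as.character(fail1)]
  note[fail1] <- "fast k-mismatch step"

  # step 2 (only for step-1 survivors): ungapped local similarity
  if (any(kept)) {
    jobs2 <- run_engine(make_jobs(which(kept)), function(reads, subj) {
      local_similarity_hits(reads, subj, identity)
    })
    refined <- side_fractions(jobs2)
    ref_cand <- as.integer(names(refined))
    stat[ref_cand] <- as.vector(refined)
    fail2 <- ref_cand[refined > refined_fraction]
    kept[fail2] <- FALSE
    note[fail2] <- "refined local-similarity step"
  }
  decision_row(candidates, "small_scale", kept, stat, note)
}

# supporter read sequences with their gene side
supporter_reads <- function(candidate, detection) {
  sup <- candidate$supporters[[1]]
  rows <- match(sup$pair_id, detection$pairs$pair_id)
  seq_a <- ifelse(sup$end_in_a == 1L,
    detection$pairs$seq1[rows], detection$pairs$seq2[rows]
  )
  seq_b <- ifelse(sup$end_in_a == 1L,
    detection$pairs$seq2[rows], detection$pairs$seq1[rows]
  )
  bind_rows(
    tibble(pair_id = sup$pair_id, side = "a", seq = seq_a),
    tibble(pair_id = sup$pair_id, side = "b", seq = seq_b)
  )
}

#' Repetitive-regions filter
#'
#' Removes supporting pairs with either end overlapping (by at least one
#' nucleotide) a repeat interval, then discards candidates left without
#' supporters. This is the one read-level filter: it prunes the supporter
#' sets that all candidate-level filters subsequently see.
#'
#' @inheritParams small_scale_similarity_filter
#' @param repeats Tibble `chrom`, `start`, `end` (0-based half-open) or `NULL`.
#' @return A list with `candidates` (pruned tibble, discarded rows removed)
#'   and `decisions`.
#' @export
repeat_filter <- function(candidates, detection, repeats = NULL) {
  if (is.null(repeats) || nrow(repeats) == 0 || nrow(candidates) == 0) {
    return(list(
      candidates = candidates,
      decisions = decision_row(candidates, "repeats", rep(TRUE, nrow(candidates)),
        statistic = rep(0, nrow(candidates)), note = "no repeat track"
      )
    ))
  }
  rep_gr <- GenomicRanges::GRanges(
    seqnames = repeats$chrom,
    ranges = IRanges::IRanges(start = repeats$start + 1L, end = repeats$end)
  )
  pairs <- detection$pairs
  # one overlap query for every supporter end of every candidate
  sup_rows <- unique(unlist(map(candidates$supporters, function(s) {
    match(s$pair_id, pairs$pair_id)
  })))
  flat <- list()
  for (e in 1:2) {
    bl <- pairs[[paste0("blocks", e)]][sup_rows]
    nb <- map_int(bl, nrow)
    m <- do.call(rbind, bl)
    flat[[e]] <- tibble(
      row = rep(sup_rows, nb),
      chrom = rep(pairs[[paste0("chrom", e)]][sup_rows], nb),
      start = m[, "start"], end = m[, "end"]
    )
  }
  flat <- bind_rows(flat)
  flat <- flat[!is.na(flat$chrom), , drop = FALSE]
  suppressWarnings(
    in_rep <- IRanges::overlapsAny(
      GenomicRanges::GRanges(
        seqnames = flat$chrom,
        ranges = IRanges::IRanges(start = flat$start + 1L, end = flat$end)
      ),
      rep_gr
    )
  )
  bad_rows <- unique(flat$row[in_rep])
  bad_ids <- pairs$pair_id[bad_rows]

  n <- nrow(candidates)
  kept <- rep(TRUE, n)
  stat <- numeric(n)
  out <- candidates
  for (i in seq_len(n)) {
    sup <- candidates$supporters[[i]]
    drop <- sup$pair_id %in% bad_ids
    stat[i] <- mean(drop)
    if (any(drop)) {
      sup <- sup[!drop, , drop = FALSE]
      out$supporters[[i]] <- sup
      out$n_support[i] <- nrow(sup)
      kept[i] <- nrow(sup) > 0
    }
  }
  list(
    candidates = out[kept, , drop = FALSE],
    decisions = decision_row(candidates, "repeats", kept, stat,
      note = ifelse(kept, "", "all supporters in repeats")
    )
  )
}

#' Abnormal insert-size filter
#'
#' Compares the median insert size of a candidate's chimeric pairs, measured
#' on the concatenated minimal fusion transcript fragment, with the
#' intra-transcript norm. The p-value is the add-one resampling estimate of
#' the probability that the median of `k` draws from the intra distribution
#' reaches the observed chimeric median; candidates with `p < alpha` are
#' discarded as random-pairing artifacts. Candidates with intronic-only
#' supporters pass with no statistic (the fragment is undefined there).
#'
#' @inheritParams small_scale_similarity_filter
#' @param intra An [insert_size_distribution()].
#' @param alpha,n_resamples,seed See [cascade_config()].
#' @return A decision tibble (`statistic` holds the p-value).
#' @export
abnormal_insert_size_filter <- function(candidates, detection, models, intra,
                                        alpha = 0.01, n_resamples = 10000L,
                                        seed = 1L, fragments = NULL) {
  if (length(intra$values) == 0) {
    abort("insert_size filter: empty intra-transcript insert-size distribution")
  }
  fragments <- fragments %||% candidate_fragments(candidates, detection, models)
  n <- nrow(candidates)
  kept <- rep(TRUE, n)
  stat <- rep(NA_real_, n)
  note <- rep("", n)
  for (i in seq_len(n)) {
    frag <- fragments[[i]]
    if (!frag$applicable) {
      note[i] <- "intronic supporters only; filter not applied"
      next
    }
    inserts <- chimeric_insert_sizes(frag)
    p <- insert_size_pvalue(intra, median(inserts), length(inserts),
      n_resamples = n_resamples, seed = seed
    )
    stat[i] <- p
    kept[i] <- p >= alpha
    if (!kept[i]) note[i] <- "abnormal chimeric insert size"
  }
  decision_row(candidates, "insert_size", kept, stat, note)
}

#' Ribosomal filter
#'
#' Flags supporting reads with at least `identity` of their length locally
#' matching a ribosomal sequence; when the hit fraction exceeds
#' `ribo_fraction`, the candidate is discarded as a likely
#' ribosomal-contamination chimera compounded by misalignment. An absent
#' ribosomal library keeps everything.
#'
#' @inheritParams small_scale_similarity_filter
#' @param rrna `DNAStringSet` of ribosomal sequences, or `NULL`.
#' @param identity,ribo_fraction See [cascade_config()].
#' @return A decision tibble (`statistic` holds the hit fraction).
#' @export
ribosomal_filter <- function(candidates, detection, rrna = NULL,
                             identity = 0.75, ribo_fraction = 0.10) {
  if (is.null(rrna) || length(rrna) == 0) {
    return(decision_row(candidates, "ribosomal", rep(TRUE, nrow(candidates)),
      note = "no ribosomal library"
    ))
  }
  n <- nrow(candidates)
  # pool the reads of all candidates and run the similarity engine once per
  # unique sequence
  read_sets <- map(seq_len(n), function(i) supporter_reads(candidates[i, ], detection)$seq)
  uniq <- unique(unlist(read_sets))
  hit <- setNames(local_similarity_hits(uniq, rrna, identity), uniq)
  stat <- map_dbl(read_sets, function(s) mean(hit[s]))
  kept <- stat <= ribo_fraction
  decision_row(candidates, "ribosomal", kept, stat,
    note = ifelse(kept, "", "supporters similar to ribosomal sequences")
  )
}

#' Expression-consistency filter
#'
#' A real fusion cannot be expressed above its parent genes. The chimeric
#' signal (supporting single ends per nucleotide of the minimal-fragment
#' region they cover) is compared with each gene's signal (single-end count
#' per composite nucleotide); the candidate is discarded when the chimeric
#' signal exceeds the smaller of the two gene signals.
#'
#' @inheritParams small_scale_similarity_filter
#' @return A decision tibble (`statistic` is chimeric signal minus the
#'   smaller gene signal).
#' @export
expression_consistency_filter <- function(candidates, detection, models,
                                          fragments = NULL) {
  fragments <- fragments %||% candidate_fragments(candidates, detection, models)
  n <- nrow(candidates)
  kept <- rep(TRUE, n)
  stat <- rep(NA_real_, n)
  g <- models$genes
  for (i in seq_len(n)) {
    frag <- fragments[[i]]
    covered <- if (frag$applicable) {
      frag$length
    } else {
      fp <- frag$footprints
      sum((fp |> group_by(.data$side) |>
        summarise(w = max(.data$gend) - min(.data$gstart), .groups = "drop"))$w)
    }
    chim <- (2L * candidates$n_support[i]) / covered
    sig_a <- gene_count(detection, candidates$gene_a[i]) /
      g$total_length[match(candidates$gene_a[i], g$gene_id)]
    sig_b <- gene_count(detection, candidates$gene_b[i]) /
      g$total_length[match(candidates$gene_b[i], g$gene_id)]
    stat[i] <- chim - min(sig_a, sig_b)
    kept[i] <- chim <= min(sig_a, sig_b)
  }
  decision_row(candidates, "expression_consistency", kept, stat,
    note = ifelse(kept, "", "chimeric signal exceeds both gene signals")
  )
}

#' PCR filter
#'
#' Requires the supporting reads to independently cover at least `pcr_p`
#' nucleotides beyond the read size on both gene sides; a single amplified
#' fragment piles identical footprints and fails. Coverage is the length of
#' the union of supporter footprints per side (composite coordinates where
#' exonic, genomic otherwise), so one distant read cannot fake breadth.
#'
#' @inheritParams small_scale_similarity_filter
#' @param pcr_p Required extra coverage in nucleotides (default 5).
#' @param read_length Read length; inferred from supporter sequences when `NULL`.
#' @return A decision tibble (`statistic` is the smaller side span).
#' @export
pcr_filter <- function(candidates, detection, models, pcr_p = 5L,
                       read_length = NULL, fragments = NULL) {
  fragments <- fragments %||% candidate_fragments(candidates, detection, models)
  n <- nrow(candidates)
  kept <- rep(TRUE, n)
  stat <- rep(NA_real_, n)
  rl_default <- read_length %||%
    max(nchar(head(c(detection$pairs$seq1, detection$pairs$seq2), 1000L)))
  for (i in seq_len(n)) {
    fp <- fragments[[i]]$footprints
    rl <- rl_default
    side_span <- function(side) {
      f <- fp[fp$side == side, , drop = FALSE]
      use_c <- all(f$exonic)
      s <- if (use_c) f$cstart else f$gstart
      e <- if (use_c) f$cend else f$gend
      sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start = s + 1L, end = e))))
    }
    span <- min(side_span("a"), side_span("b"))
    stat[i] <- span
    kept[i] <- span >= rl + pcr_p
  }
  decision_row(candidates, "pcr", kept, stat,
    note = ifelse(kept, "", "supporter footprints pile up (PCR-like)")
  )
}

#' Run the filtration cascade
#'
#' Applies the read-level repeat pruning first, then evaluates every enabled
#' candidate-level filter on that common pruned state; a candidate is kept
#' iff every applicable filter keeps it. Because the candidate-level filters
#' are independent predicates over the same state, their order does not
#' affect the kept set.
#'
#' @param detection A [detect_candidates()] result.
#' @param models A [gene_models()] object.
#' @param config A [cascade_config()].
#' @return An object of class `fusion_cascade`: `kept` (surviving candidate
#'   tibble, supporters pruned), `audit` (one row per candidate and executed
#'   filter), `summary` (per-filter removal percentages, see
#'   [summarize_filters()]), `n_in`, `detection`, `intra` (the insert-size
#'   distribution, when computed).
#' @export
run_cascade <- function(detection, models, config = cascade_config()) {
  candidates <- detection$candidates
  n_in <- nrow(candidates)
  audit <- list()
  intra <- NULL

  if ("repeats" %in% config$enable) {
    rf <- repeat_filter(candidates, detection, config$repeats)
    audit$repeats <- rf$decisions
    candidates <- rf$candidates
  }

  run <- function(name, fn) {
    if (!(name %in% config$enable) || nrow(candidates) == 0) return(NULL)
    fn(candidates)
  }
  # footprints/fragments are shared by the insert-size, expression and PCR
  # filters; compute them once on the pruned state
  fragments <- NULL
  need_frag <- any(c("insert_size", "expression_consistency", "pcr") %in% config$enable)
  if (need_frag && nrow(candidates) > 0) {
    fragments <- candidate_fragments(candidates, detection, models)
  }
  audit$paralogs <- run("paralogs", function(cand) {
    paralog_filter(cand, config$paralogs)
  })
  audit$small_scale <- run("small_scale", function(cand) {
    small_scale_similarity_filter(
      cand, detection, models, config$genome,
      fast_fraction = config$fast_fraction,
      refined_fraction = config$refined_fraction,
      identity = config$identity, max_mismatches = config$max_mismatches
    )
  })
  audit$insert_size <- run("insert_size", function(cand) {
    intra <<- insert_size_distribution(detection, models)
    abnormal_insert_size_filter(
      cand, detection, models, intra,
      alpha = config$alpha, n_resamples = config$n_resamples,
      seed = config$seed, fragments = fragments
    )
  })
  audit$ribosomal <- run("ribosomal", function(cand) {
    ribosomal_filter(cand, detection, config$rrna,
      identity = config$identity, ribo_fraction = config$ribo_fraction
    )
  })
  audit$expression_consistency <- run("expression_consistency", function(cand) {
    expression_consistency_filter(cand, detection, models, fragments = fragments)
  })
  audit$pcr <- run("pcr", function(cand) {
    pcr_filter(cand, detection, models,
      pcr_p = config$pcr_p, read_length = config$read_length,
      fragments = fragments
    )
  })

  audit_tbl <- bind_rows(audit)
  if (nrow(candidates) > 0 && nrow(audit_tbl) > 0) {
    verdict <- audit_tbl |>
      filter(.data$filter != "repeats") |>
      group_by(.data$gene_a, .data$gene_b) |>
      summarise(kept = all(.data$kept), .groups = "drop")
    keep_key <- paste(verdict$gene_a[verdict$kept], verdict$gene_b[verdict$kept])
    kept <- candidates[paste(candidates$gene_a, candidates$gene_b) %in% keep_key |
      nrow(verdict) == 0, , drop = FALSE]
  } else {
    kept <- candidates
  }

  structure(
    list(
      kept = kept, audit = audit_tbl,
      summary = summarize_filters(audit_tbl, n_in = n_in),
      n_in = n_in, detection = detection, intra = intra
    ),
    class = "fusion_cascade"
  )
}

#' @export
print.fusion_cascade <- function(x, ...) {
  cat("<fusion_cascade> ", x$n_in, " candidates in, ", nrow(x$kept),
    " kept (", sprintf("%.1f", overall_reduction(x)), "% removed)\n",
    sep = ""
  )
  invisible(x)
}

overall_reduction <- function(cascade) {
  if (cascade$n_in == 0) return(0)
  100 * (cascade$n_in - nrow(cascade$kept)) / cascade$n_in
}

#' @exportS3Method generics::tidy
tidy.fusion_cascade <- function(x, ...) {
  x$audit
}

#' @exportS3Method generics::glance
glance.fusion_cascade <- function(x, ...) {
  tibble(
    n_in = x$n_in, n_kept = nrow(x$kept),
    overall_reduction_pct = overall_reduction(x)
  )
}
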