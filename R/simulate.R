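#' Simulation configuration
#'
#' Describes a fully synthetic study: a multi-gene background transcriptome
#' with log-normal expression, size-selected fragments, one implanted fusion
#' expressed at a ratio `F` of its wild-type allele, and the artifact classes
#' the filtration cascade targets (random inter-transcript pairing
#' proportional to the product of expressions, PCR over-amplification of a
#' single chimeric fragment, ribosomal reads misassigned to genes, and reads
#' from a homologous decoy gene misassigned to its paralog). Every emitted
#' pair carries a truth label.
#'
#' @param seed Master seed; all randomness derives from it through fixed
#'   per-stage offsets, so artifact classes can be toggled without
#'   perturbing each other.
#' @param n_genes Number of background genes (default 200): enough genes
#'   that no single gene dominates the single-end mapping probabilities, as
#'   in a real transcriptome.
#' @param n_chroms Number of chromosomes the genes are spread over.
#' @param exons_per_gene,exon_length,intron_length,intergenic Integer ranges
#'   `c(min, max)` sampled uniformly.
#' @param expression Log-normal expression parameters
#'   (`list(meanlog, sdlog)`).
#' @param n_pairs Normal-transcriptome pair budget (default 50,000).
#' @param fragment_mean,fragment_sd Size-selected fragment length (nt).
#' @param read_length Read length (nt).
#' @param error_rate Uniform per-base substitution rate.
#' @param fusion `list(enabled, ratio, expr_a, expr_b, breakpoint)`:
#'   `ratio` is the fusion/wild-type expression ratio `F`; `expr_a`/`expr_b`
#'   are the partner genes' expression weights (well-expressed partners,
#'   as in driver fusions); `breakpoint` is `"exon_boundary"` (default) or
#'   `"uniform"` (uniform within the chosen exons).
#' @param random_pair_rate Random chimeric pairs as a fraction of `n_pairs`.
#' @param hot_expr Expression weight of the two "hot" genes that concentrate
#'   random pairing (product null).
#' @param pcr_duplicates Amplification factor of the single PCR-artifact
#'   chimeric fragment (0 disables).
#' @param rrna_fraction Ribosomal-misassignment pairs as a fraction of
#'   `n_pairs` (0 disables).
#' @param n_rrna,rrna_length Ribosomal decoy library.
#' @param decoy `list(divergence, chimera_fraction, expr)`: the decoy gene is
#'   a structural copy of its source diverged by the given substitution rate;
#'   a fraction of the source gene's fragments have one end misassigned to
#'   the decoy's coordinates (`chimera_fraction = 0` disables).
#' @param repeat_fraction Fraction of intergenic sequence covered by the
#'   repeat track.
#' @param n_repeat_pairs Chimeric pairs planted inside a repeat interval
#'   overlapping two genes (exercises the repeat filter; 0 disables).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 200L, n_chroms = 2L,
                       exons_per_gene = c(4L, 7L),
                       exon_length = c(120L, 260L),
                       intron_length = c(200L, 800L),
                       intergenic = c(300L, 1200L),
                       expression = list(meanlog = 0, sdlog = 1),
                       n_pairs = 50000L,
                       fragment_mean = 300, fragment_sd = 20,
                       read_length = 36L, error_rate = 0.001,
                       fusion = list(
                         enabled = TRUE, ratio = 0.5,
                         expr_a = 8, expr_b = 4, breakpoint = "exon_boundary"
                       ),
                       random_pair_rate = 0.01, hot_expr = 30,
                       pcr_duplicates = 50L,
                       rrna_fraction = 0.005, n_rrna = 2L, rrna_length = 1500L,
                       decoy = list(divergence = 0.02, chimera_fraction = 0.05, expr = 6),
                       repeat_fraction = 0.02, n_repeat_pairs = 6L) {
  if (n_genes < 16L) abort("need at least 16 genes to place the role genes")
  stopifnot(
    fusion$ratio >= 0, random_pair_rate >= 0, random_pair_rate <= 1,
    rrna_fraction >= 0, rrna_fraction <= 1, repeat_fraction >= 0,
    repeat_fraction <= 1
  )
  structure(
    as.list(environment()),
    class = "sim_config"
  )
}

sub_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + stage * 9973) %% .Machine$integer.max)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit) > 0) {
    for (i in hit) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    }
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic genome, annotation and filter resources
#'
#' Lays the configured genes out over random-sequence chromosomes,
#' designates the role genes (fusion partners, hot random-pairing pair, PCR
#' pair, ribosomal-misassignment pair, repeat pair, homolog source/decoy),
#' rewrites the decoy gene as a diverged structural copy of its source,
#' builds the ribosomal decoy library, the repeat track and the paralog
#' table. Deterministic under the configuration seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_scaffold`: `genome` (`DNAStringSet`),
#'   `models` ([gene_models()]), `tx_maps` (per-isoform transcript maps),
#'   `rrna`, `paralogs`, `repeats`, `roles`, `weights`, `fusion_truth`
#'   (populated by the read simulator) and the `config`.
#' @export
make_genome_and_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config$seed, 1L), {
    n <- config$n_genes
    gene_ids <- sprintf("g%03d", seq_len(n))
    roles <- list(
      fusion_a = gene_ids[11], fusion_b = gene_ids[12],
      hot1 = gene_ids[13], hot2 = gene_ids[14],
      pcr1 = gene_ids[7], pcr2 = gene_ids[8],
      rrna1 = gene_ids[9], rrna2 = gene_ids[10],
      rep1 = gene_ids[5], rep2 = gene_ids[6],
      decoy_src = gene_ids[15], decoy = gene_ids[16]
    )
    runifi <- function(k, range) {
      if (range[1] == range[2]) rep(range[1], k) else sample(range[1]:range[2], k, replace = TRUE)
    }

    # per-gene structure; the decoy copies its source's layout
    layout <- vector("list", n)
    for (i in seq_len(n)) {
      if (gene_ids[i] == roles$decoy) {
        layout[[i]] <- layout[[match(roles$decoy_src, gene_ids)]]
        next
      }
      n_ex <- runifi(1, config$exons_per_gene)
      layout[[i]] <- list(
        exon_w = runifi(n_ex, config$exon_length),
        intron_w = if (n_ex > 1) runifi(n_ex - 1, config$intron_length) else integer(0),
        strand = sample(c("+", "-"), 1)
      )
    }
    # same strand for source and decoy keeps the coordinate translation trivial
    layout[[match(roles$decoy, gene_ids)]]$strand <-
      layout[[match(roles$decoy_src, gene_ids)]]$strand

    chrom_of <- rep(sprintf("chr%d", seq_len(config$n_chroms)), length.out = n)
    chrom_of <- sort(chrom_of) # contiguous blocks of genes per chromosome
    exon_rows <- list()
    cursor <- setNames(rep(0L, config$n_chroms), sprintf("chr%d", seq_len(config$n_chroms)))
    gene_span <- matrix(0L, nrow = n, ncol = 2, dimnames = list(gene_ids, c("start", "end")))
    for (i in seq_len(n)) {
      ch <- chrom_of[i]
      gap <- runifi(1, config$intergenic)
      start <- cursor[ch] + gap
      lw <- layout[[i]]
      widths <- integer(0)
      for (k in seq_along(lw$exon_w)) {
        widths <- c(widths, lw$exon_w[k])
        if (k < length(lw$exon_w)) widths <- c(widths, lw$intron_w[k])
      }
      bounds <- start + cumsum(c(0L, widths))
      ex_idx <- seq(1, length(bounds) - 1, by = 2)
      ex_start <- bounds[ex_idx]
      ex_end <- bounds[ex_idx + 1]
      gene_span[i, ] <- c(start, bounds[length(bounds)])
      cursor[ch] <- bounds[length(bounds)]
      # isoform 1: all exons; isoform 2: skip one internal exon when possible
      rows <- tibble(
        gene_id = gene_ids[i], tx_id = paste0(gene_ids[i], ".1"),
        chrom = ch, strand = lw$strand, start = ex_start, end = ex_end
      )
      if (length(ex_start) >= 3) {
        skip <- sample(2:(length(ex_start) - 1), 1)
        rows <- bind_rows(rows, tibble(
          gene_id = gene_ids[i], tx_id = paste0(gene_ids[i], ".2"),
          chrom = ch, strand = lw$strand,
          start = ex_start[-skip], end = ex_end[-skip]
        ))
      }
      exon_rows[[i]] <- rows
    }
    exons <- bind_rows(exon_rows)
    models <- gene_models(exons)

    chrom_len <- cursor + 500L
    genome <- Biostrings::DNAStringSet(vapply(
      names(chrom_len),
      function(ch) rand_dna(chrom_len[ch]), character(1)
    ))
    names(genome) <- names(chrom_len)

    # the decoy gene is a diverged copy of its source's whole span
    src_i <- match(roles$decoy_src, gene_ids)
    dec_i <- match(roles$decoy, gene_ids)
    src_seq <- as.character(Biostrings::subseq(
      genome[[chrom_of[src_i]]], gene_span[src_i, 1] + 1L, gene_span[src_i, 2]
    ))
    dec_seq <- mutate_seq(src_seq, config$decoy$divergence)
    genome[[chrom_of[dec_i]]] <- Biostrings::replaceAt(
      genome[[chrom_of[dec_i]]],
      IRanges::IRanges(gene_span[dec_i, 1] + 1L, gene_span[dec_i, 2]),
      dec_seq
    )

    rrna <- Biostrings::DNAStringSet(vapply(
      seq_len(config$n_rrna),
      function(i) rand_dna(config$rrna_length), character(1)
    ))
    names(rrna) <- paste0("rrna", seq_len(config$n_rrna))

    # repeat track: intergenic intervals plus one interval over an exon of
    # each repeat-role gene (so planted repeat-pair supporters get pruned)
    repeats <- list()
    for (ch in names(chrom_len)) {
      genic <- IRanges::reduce(IRanges::IRanges(
        start = gene_span[chrom_of == ch, 1] + 1L,
        end = gene_span[chrom_of == ch, 2]
      ))
      inter <- IRanges::gaps(genic, start = 1L, end = chrom_len[ch])
      inter <- inter[IRanges::width(inter) >= 100]
      take <- ceiling(config$repeat_fraction * length(inter))
      if (take > 0 && length(inter) > 0) {
        pick <- inter[sample(length(inter), min(take, length(inter)))]
        repeats[[ch]] <- tibble(
          chrom = ch, start = IRanges::start(pick) - 1L, end = IRanges::end(pick)
        )
      }
    }
    for (rg in c(roles$rep1, roles$rep2)) {
      gi <- match(rg, gene_ids)
      first_ex <- exons |>
        filter(.data$gene_id == rg, .data$tx_id == paste0(rg, ".1")) |>
        arrange(.data$start)
      mid <- first_ex[ceiling(nrow(first_ex) / 2), ]
      repeats[[paste0("role_", rg)]] <- tibble(
        chrom = mid$chrom, start = mid$start, end = mid$end
      )
    }
    repeats <- bind_rows(repeats) |> arrange(.data$chrom, .data$start)

    weights <- stats::rlnorm(n, config$expression$meanlog, config$expression$sdlog)
    names(weights) <- gene_ids
    weights[roles$fusion_a] <- config$fusion$expr_a
    weights[roles$fusion_b] <- config$fusion$expr_b
    weights[c(roles$hot1, roles$hot2)] <- config$hot_expr
    weights[c(roles$decoy_src, roles$decoy)] <- config$decoy$expr
    weights[c(roles$pcr1, roles$pcr2)] <- pmax(weights[c(roles$pcr1, roles$pcr2)], 2)

    structure(
      list(
        genome = genome, models = models,
        tx_maps = build_tx_maps(models),
        rrna = rrna,
        paralogs = tibble(gene_a = roles$decoy_src, gene_b = roles$decoy),
        repeats = repeats, roles = roles, weights = weights,
        gene_span = gene_span, chrom_of = setNames(chrom_of, gene_ids),
        config = config
      ),
      class = "sim_scaffold"
    )
  })
}

# transcript maps: per isoform, exons in transcript order with cumulative
# widths, supporting transcript-interval -> genomic-blocks conversion
build_tx_maps <- function(models) {
  ex <- models$exons
  maps <- list()
  for (tx in unique(ex$tx_id)) {
    e <- ex[ex$tx_id == tx, , drop = FALSE]
    e <- arrange(e, .data$start)
    if (e$strand[1] == "-") e <- e[rev(seq_len(nrow(e))), , drop = FALSE]
    w <- e$end - e$start
    maps[[tx]] <- list(
      tx_id = tx, gene_id = e$gene_id[1], chrom = e$chrom[1], strand = e$strand[1],
      gstart = e$start, gend = e$end, cum = cumsum(c(0L, w)), tlen = sum(w)
    )
  }
  maps
}

# genomic blocks (sorted, 0-based half-open) of transcript interval [ts, te)
tx_to_blocks <- function(map, ts, te) {
  i1 <- findInterval(ts, map$cum, rightmost.closed = FALSE)
  i2 <- findInterval(te - 1L, map$cum, rightmost.closed = FALSE)
  rows <- i1:i2
  out <- matrix(0L, nrow = length(rows), ncol = 2, dimnames = list(NULL, c("start", "end")))
  for (k in seq_along(rows)) {
    i <- rows[k]
    a <- max(ts, map$cum[i])
    b <- min(te, map$cum[i + 1])
    if (map$strand == "+") {
      out[k, ] <- c(map$gstart[i] + (a - map$cum[i]), map$gstart[i] + (b - map$cum[i]))
    } else {
      out[k, ] <- c(map$gend[i] - (b - map$cum[i]), map$gend[i] - (a - map$cum[i]))
    }
  }
  out[order(out[, "start"]), , drop = FALSE]
}

block_dimnames <- list(NULL, c("start", "end"))

# vectorised tx_to_blocks over many intervals of one transcript; intervals
# within a single exon (the common case) avoid the general path
tx_blocks_batch <- function(m, ts, te) {
  i1 <- findInterval(ts, m$cum, rightmost.closed = FALSE)
  i2 <- findInterval(te - 1L, m$cum, rightmost.closed = FALSE)
  out <- vector("list", length(ts))
  simple <- i1 == i2
  if (any(simple)) {
    i <- i1[simple]
    a <- ts[simple]
    b <- te[simple]
    if (m$strand == "+") {
      st <- m$gstart[i] + (a - m$cum[i])
      en <- m$gstart[i] + (b - m$cum[i])
    } else {
      st <- m$gend[i] - (b - m$cum[i])
      en <- m$gend[i] - (a - m$cum[i])
    }
    idx <- which(simple)
    for (k in seq_along(idx)) {
      out[[idx[k]]] <- matrix(
        c(as.integer(st[k]), as.integer(en[k])), 1L, 2L,
        dimnames = block_dimnames
      )
    }
  }
  for (k in which(!simple)) out[[k]] <- tx_to_blocks(m, ts[k], te[k])
  out
}

tx_sequence <- function(map, genome) {
  pieces <- as.character(Biostrings::extractAt(
    genome[[map$chrom]],
    IRanges::IRanges(start = map$gstart + 1L, end = map$gend)
  ))
  s <- paste(pieces, collapse = "")
  if (map$strand == "-") {
    # exons are stored in transcript order but extracted on the plus strand
    s <- paste(rev(pieces), collapse = "")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    # reverse-complement of genomic-order concatenation equals transcript
    # sense; pieces were reordered to genomic order first
  }
  s
}

#' Simulate paired-end reads with truth labels
#'
#' Draws size-selected fragments from the spliced transcriptome at the
#' configured expression, adds the implanted fusion at ratio `F` of its
#' wild-type allele, and layers the enabled artifact classes on top. Reads
#' are emitted at their true source coordinates, except decoy reads (emitted
#' at the homolog's coordinates), ribosomal-misassignment reads (emitted at
#' the role genes' coordinates) and fusion ends spanning the breakpoint
#' (emitted unmapped with their sequence retained).
#'
#' @param scaffold A [make_genome_and_annotation()] result.
#' @return The scaffold, extended with `pairs` (pair tibble as in
#'   [read_pairs_tab()]), `truth` (one label per pair) and `fusion_truth`
#'   (upstream/downstream genes and 1-based breakpoint coordinates).
#' @export
simulate_reads <- function(scaffold) {
  stopifnot(inherits(scaffold, "sim_scaffold"))
  config <- scaffold$config
  rl <- config$read_length
  maps <- scaffold$tx_maps
  genome <- scaffold$genome
  roles <- scaffold$roles
  models <- scaffold$models

  tx_by_gene <- split(names(maps), vapply(maps, function(m) m$gene_id, character(1)))
  tx_seq_cache <- new.env(parent = emptyenv())
  get_tx_seq <- function(tx) {
    if (is.null(tx_seq_cache[[tx]])) tx_seq_cache[[tx]] <- tx_sequence(maps[[tx]], genome)
    tx_seq_cache[[tx]]
  }

  frag_lengths <- function(k, tmax) {
    fl <- round(rnorm(k, config$fragment_mean, config$fragment_sd))
    pmin(pmax(fl, 2L * rl), tmax)
  }

  # one normal fragment batch for gene `g`: returns list of per-pair records
  gene_fragments <- function(g, k) {
    if (k == 0) return(NULL)
    txs <- tx_by_gene[[g]]
    tx <- sample(txs, k, replace = TRUE)
    recs <- vector("list", k)
    for (tname in unique(tx)) {
      idx <- which(tx == tname)
      m <- maps[[tname]]
      tseq <- get_tx_seq(tname)
      fl <- frag_lengths(length(idx), m$tlen)
      s <- floor(runif(length(idx)) * (m$tlen - fl + 1L))
      seq1 <- substring(tseq, s + 1L, s + rl)
      seq2 <- revcomp_chr_vec(substring(tseq, s + fl - rl + 1L, s + fl))
      strand2 <- flip_strand(m$strand)
      b1 <- tx_blocks_batch(m, s, s + rl)
      b2 <- tx_blocks_batch(m, s + fl - rl, s + fl)
      for (jj in seq_along(idx)) {
        recs[[idx[jj]]] <- list(
          chrom1 = m$chrom, strand1 = m$strand,
          blocks1 = b1[[jj]],
          seq1 = seq1[jj],
          chrom2 = m$chrom, strand2 = strand2,
          blocks2 = b2[[jj]],
          seq2 = seq2[jj],
          mapped1 = TRUE, mapped2 = TRUE
        )
      }
    }
    recs
  }

  single_end_at <- function(tx, s, sense) {
    m <- maps[[tx]]
    tseq <- get_tx_seq(tx)
    raw <- substr(tseq, s + 1L, s + rl)
    list(
      chrom = m$chrom,
      strand = if (sense) m$strand else flip_strand(m$strand),
      blocks = tx_to_blocks(m, s, s + rl),
      seq = if (sense) raw else revcomp_chr(raw)
    )
  }

  all_recs <- list()
  all_labels <- list()
  add_batch <- function(recs, label) {
    if (length(recs) == 0) return(invisible(NULL))
    all_recs[[length(all_recs) + 1]] <<- recs
    all_labels[[length(all_labels) + 1]] <<- rep(label, length(recs))
    invisible(NULL)
  }

  # --- normal transcriptome -------------------------------------------------
  with_seed(sub_seed(config$seed, 2L), {
    w <- scaffold$weights
    counts <- as.vector(stats::rmultinom(1, config$n_pairs, w / sum(w)))
    names(counts) <- names(w)
    for (g in names(counts)) add_batch(gene_fragments(g, counts[g]), "normal")
  })

  # --- implanted fusion -----------------------------------------------------
  fusion_truth <- NULL
  if (isTRUE(config$fusion$enabled) && config$fusion$ratio > 0) {
    fusion_truth <- with_seed(sub_seed(config$seed, 3L), {
      ma <- maps[[paste0(roles$fusion_a, ".1")]]
      mb <- maps[[paste0(roles$fusion_b, ".1")]]
      ja <- ceiling(length(ma$gstart) / 2) # keep exons 1..ja of A
      kb <- ceiling(length(mb$gstart) / 2 + 0.5) # keep exons kb.. of B
      len_a <- ma$cum[ja + 1L]
      off_b <- mb$cum[kb]
      if (identical(config$fusion$breakpoint, "uniform")) {
        len_a <- sample.int(ma$tlen - rl, 1) + 0L
        off_b <- sample.int(mb$tlen - rl, 1) + 0L
      }
      seq_a <- substr(get_tx_seq(ma$tx_id), 1L, len_a)
      seq_b <- substr(get_tx_seq(mb$tx_id), off_b + 1L, mb$tlen)
      fseq <- paste0(seq_a, seq_b)
      flen_total <- nchar(fseq)

      # 1-based genomic coordinates flanking the junction
      bp_a_block <- tx_to_blocks(ma, len_a - 1L, len_a)
      bp_b_block <- tx_to_blocks(mb, off_b, off_b + 1L)

      if (identical(config$fusion$breakpoint, "exon_boundary")) {
        # remove any single-base microhomology at the junction edges: with
        # homology the breakpoint is only defined up to the homology length,
        # so exact recovery would be ill-posed. The adjusted bases are
        # intronic (the breakpoint sits on exon boundaries), leaving every
        # transcript sequence untouched.
        genome <- drop_edge_homology(
          genome, ma, mb, bp_a_block, bp_b_block
        )
        scaffold$genome <- genome
        # invalidate cached transcript sequences built from the old genome
        rm(list = ls(tx_seq_cache), envir = tx_seq_cache)
      }
      ft <- tibble(
        upstream_gene = roles$fusion_a, downstream_gene = roles$fusion_b,
        upstream_break = as.integer(
          if (ma$strand == "+") bp_a_block[1, "end"] else bp_a_block[1, "start"] + 1L
        ),
        downstream_break = as.integer(
          if (mb$strand == "+") bp_b_block[1, "start"] + 1L else bp_b_block[1, "end"]
        ),
        tx_break_a = as.integer(len_a), tx_break_b = as.integer(off_b)
      )

      # fusion expressed at F times the wild-type allele of gene A
      w <- scaffold$weights
      n_wt_a <- round(config$n_pairs * w[roles$fusion_a] / sum(w))
      n_fusion <- round(config$fusion$ratio * n_wt_a)
      recs <- vector("list", n_fusion)
      for (j in seq_len(n_fusion)) {
        fl <- frag_lengths(1, flen_total)
        s <- sample.int(flen_total - fl + 1L, 1) - 1L
        mk_end <- function(ts, sense) {
          te <- ts + rl
          raw <- substr(fseq, ts + 1L, ts + rl)
          if (ts < len_a && te > len_a) {
            return(list(chrom = NA_character_, strand = NA_character_,
              blocks = cbind(start = integer(0), end = integer(0)),
              seq = if (sense) raw else revcomp_chr(raw), mapped = FALSE))
          }
          if (te <= len_a) {
            b <- tx_to_blocks(ma, ts, te)
            ch <- ma$chrom; st <- ma$strand
          } else {
            b <- tx_to_blocks(mb, ts - len_a + off_b, te - len_a + off_b)
            ch <- mb$chrom; st <- mb$strand
          }
          list(chrom = ch, strand = if (sense) st else flip_strand(st),
            blocks = b, seq = if (sense) raw else revcomp_chr(raw), mapped = TRUE)
        }
        e1 <- mk_end(s, TRUE)
        e2 <- mk_end(s + fl - rl, FALSE)
        recs[[j]] <- list(
          chrom1 = e1$chrom, strand1 = e1$strand, blocks1 = e1$blocks,
          seq1 = e1$seq, mapped1 = e1$mapped,
          chrom2 = e2$chrom, strand2 = e2$strand, blocks2 = e2$blocks,
          seq2 = e2$seq, mapped2 = e2$mapped
        )
      }
      add_batch(recs, "fusion")
      ft
    })
  }

  # --- random inter-transcript pairing (product-of-expression null) ---------
  n_rand <- round(config$random_pair_rate * config$n_pairs)
  if (n_rand > 0) {
    with_seed(sub_seed(config$seed, 4L), {
      w <- scaffold$weights
      pick_end <- function(sense) {
        g <- sample(names(w), 1, prob = w)
        tx <- sample(tx_by_gene[[g]], 1)
        m <- maps[[tx]]
        s <- sample.int(m$tlen - rl + 1L, 1) - 1L
        single_end_at(tx, s, sense)
      }
      recs <- vector("list", n_rand)
      for (j in seq_len(n_rand)) {
        e1 <- pick_end(TRUE)
        e2 <- pick_end(FALSE)
        recs[[j]] <- list(
          chrom1 = e1$chrom, strand1 = e1$strand, blocks1 = e1$blocks,
          seq1 = e1$seq, mapped1 = TRUE,
          chrom2 = e2$chrom, strand2 = e2$strand, blocks2 = e2$blocks,
          seq2 = e2$seq, mapped2 = TRUE
        )
      }
      add_batch(recs, "random-pair")
    })
  }

  # --- PCR over-amplification of one chimeric fragment ----------------------
  if (config$pcr_duplicates > 0) {
    with_seed(sub_seed(config$seed, 5L), {
      t1 <- paste0(roles$pcr1, ".1")
      t2 <- paste0(roles$pcr2, ".1")
      s1 <- sample.int(maps[[t1]]$tlen - rl + 1L, 1) - 1L
      s2 <- sample.int(maps[[t2]]$tlen - rl + 1L, 1) - 1L
      e1 <- single_end_at(t1, s1, TRUE)
      e2 <- single_end_at(t2, s2, FALSE)
      rec <- list(
        chrom1 = e1$chrom, strand1 = e1$strand, blocks1 = e1$blocks,
        seq1 = e1$seq, mapped1 = TRUE,
        chrom2 = e2$chrom, strand2 = e2$strand, blocks2 = e2$blocks,
        seq2 = e2$seq, mapped2 = TRUE
      )
      add_batch(rep(list(rec), config$pcr_duplicates), "pcr-dup")
    })
  }

  # --- ribosomal misassignment ----------------------------------------------
  n_rrna_pairs <- round(config$rrna_fraction * config$n_pairs)
  if (n_rrna_pairs > 0 && length(scaffold$rrna) > 0) {
    with_seed(sub_seed(config$seed, 6L), {
      t1 <- paste0(roles$rrna1, ".1")
      t2 <- paste0(roles$rrna2, ".1")
      # misaligned placements concentrate in a narrow window of each gene
      base1 <- sample.int(maps[[t1]]$tlen - rl - 20L, 1) - 1L
      base2 <- sample.int(maps[[t2]]$tlen - rl - 20L, 1) - 1L
      recs <- vector("list", n_rrna_pairs)
      for (j in seq_len(n_rrna_pairs)) {
        rr <- scaffold$rrna[[sample.int(length(scaffold$rrna), 1)]]
        p1 <- sample.int(length(rr) - rl + 1L, 1)
        p2 <- sample.int(length(rr) - rl + 1L, 1)
        e1 <- single_end_at(t1, base1 + sample.int(20L, 1) - 1L, TRUE)
        e2 <- single_end_at(t2, base2 + sample.int(20L, 1) - 1L, FALSE)
        e1$seq <- as.character(Biostrings::subseq(rr, p1, p1 + rl - 1L))
        e2$seq <- revcomp_chr(as.character(Biostrings::subseq(rr, p2, p2 + rl - 1L)))
        recs[[j]] <- list(
          chrom1 = e1$chrom, strand1 = e1$strand, blocks1 = e1$blocks,
          seq1 = e1$seq, mapped1 = TRUE,
          chrom2 = e2$chrom, strand2 = e2$strand, blocks2 = e2$blocks,
          seq2 = e2$seq, mapped2 = TRUE
        )
      }
      add_batch(recs, "rrna")
    })
  }

  # --- homolog decoy misassignment ------------------------------------------
  if (config$decoy$chimera_fraction > 0) {
    with_seed(sub_seed(config$seed, 7L), {
      w <- scaffold$weights
      n_src <- round(config$n_pairs * w[roles$decoy_src] / sum(w))
      n_chim <- round(config$decoy$chimera_fraction * n_src)
      shift <- scaffold$gene_span[roles$decoy, "start"] -
        scaffold$gene_span[roles$decoy_src, "start"]
      dec_chrom <- scaffold$chrom_of[roles$decoy]
      recs <- gene_fragments(roles$decoy_src, n_chim)
      recs <- map(recs, function(r) {
        r$chrom2 <- unname(dec_chrom)
        r$blocks2 <- r$blocks2 + as.integer(shift)
        r
      })
      add_batch(recs, "decoy")
    })
  }

  # --- planted repeat-region chimeras ---------------------------------------
  if (config$n_repeat_pairs > 0) {
    with_seed(sub_seed(config$seed, 8L), {
      in_repeat_pos <- function(g) {
        # the role repeat interval is the genomically middle exon of isoform 1
        m <- maps[[paste0(g, ".1")]]
        n_ex <- length(m$gstart)
        mid_genomic <- ceiling(n_ex / 2)
        ti <- if (m$strand == "+") mid_genomic else n_ex - mid_genomic + 1L
        lo <- m$cum[ti]
        hi <- m$cum[ti + 1L] - rl
        lo + sample.int(max(1L, hi - lo), 1) - 1L
      }
      recs <- vector("list", config$n_repeat_pairs)
      for (j in seq_len(config$n_repeat_pairs)) {
        e1 <- single_end_at(paste0(roles$rep1, ".1"), in_repeat_pos(roles$rep1), TRUE)
        e2 <- single_end_at(paste0(roles$rep2, ".1"), in_repeat_pos(roles$rep2), FALSE)
        recs[[j]] <- list(
          chrom1 = e1$chrom, strand1 = e1$strand, blocks1 = e1$blocks,
          seq1 = e1$seq, mapped1 = TRUE,
          chrom2 = e2$chrom, strand2 = e2$strand, blocks2 = e2$blocks,
          seq2 = e2$seq, mapped2 = TRUE
        )
      }
      add_batch(recs, "repeat-pair")
    })
  }

  flat <- unlist(all_recs, recursive = FALSE)
  n_total <- length(flat)
  pairs <- tibble(
    pair_id = sprintf("p%07d", seq_len(n_total)),
    chrom1 = map_chr(flat, "chrom1"), strand1 = map_chr(flat, "strand1"),
    blocks1 = map(flat, "blocks1"), seq1 = map_chr(flat, "seq1"),
    mapped1 = map_lgl(flat, "mapped1"),
    chrom2 = map_chr(flat, "chrom2"), strand2 = map_chr(flat, "strand2"),
    blocks2 = map(flat, "blocks2"), seq2 = map_chr(flat, "seq2"),
    mapped2 = map_lgl(flat, "mapped2"),
    qc_pass = TRUE, unique_pair = TRUE
  )

  if (config$error_rate > 0) {
    with_seed(sub_seed(config$seed, 9L), {
      pairs$seq1 <- add_errors(pairs$seq1, config$error_rate)
      pairs$seq2 <- add_errors(pairs$seq2, config$error_rate)
    })
  }

  scaffold$pairs <- pairs
  scaffold$truth <- tibble(pair_id = pairs$pair_id, label = unlist(all_labels))
  scaffold$fusion_truth <- fusion_truth
  scaffold
}

add_errors <- function(seqs, rate) {
  rl <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), rl, rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    chars <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(rl[i], n_err[i])
    for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

# Ensure the fused edges share no single-base homology: the sense base
# following the upstream part must differ from the first downstream base,
# and the sense base preceding the downstream part must differ from the last
# upstream base. Both adjusted bases are intronic.
drop_edge_homology <- function(genome, ma, mb, bp_a_block, bp_b_block) {
  base_at <- function(chrom, pos1, strand) {
    b <- as.character(Biostrings::subseq(genome[[chrom]], pos1, pos1))
    if (strand == "-") chartr("ACGT", "TGCA", b) else b
  }
  set_sense_base <- function(chrom, pos1, strand, sense_base) {
    plus <- if (strand == "-") chartr("ACGT", "TGCA", sense_base) else sense_base
    genome[[chrom]] <<- Biostrings::replaceAt(
      genome[[chrom]], IRanges::IRanges(pos1, pos1), plus
    )
  }
  # 1-based genomic coordinates of the junction-adjacent bases
  a_last <- if (ma$strand == "+") bp_a_block[1, "end"] else bp_a_block[1, "start"] + 1L
  a_next <- if (ma$strand == "+") a_last + 1L else a_last - 1L
  b_first <- if (mb$strand == "+") bp_b_block[1, "start"] + 1L else bp_b_block[1, "end"]
  b_prev <- if (mb$strand == "+") b_first - 1L else b_first + 1L

  sense_a_last <- base_at(ma$chrom, a_last, ma$strand)
  sense_b_first <- base_at(mb$chrom, b_first, mb$strand)
  if (base_at(ma$chrom, a_next, ma$strand) == sense_b_first) {
    set_sense_base(
      ma$chrom, a_next, ma$strand,
      setdiff(c("A", "C", "G", "T"), sense_b_first)[1]
    )
  }
  if (base_at(mb$chrom, b_prev, mb$strand) == sense_a_last) {
    set_sense_base(
      mb$chrom, b_prev, mb$strand,
      setdiff(c("A", "C", "G", "T"), sense_a_last)[1]
    )
  }
  genome
}

revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1]]), collapse = "")
}

revcomp_chr_vec <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

flip_strand <- function(s) if (s == "+") "-" else "+"

#' Simulate a complete synthetic sample
#'
#' @param config A [sim_config()].
#' @return A `sim_scaffold` with reads and truth attached (see
#'   [simulate_reads()]).
#' @export
simulate_dataset <- function(config = sim_config()) {
  simulate_reads(make_genome_and_annotation(config))
}

#' Write all simulated inputs to a directory
#'
#' Emits the formats the pipeline consumes: genome FASTA, annotation (GTF and
#' knownGene-style), read pairs (tab format and SAM), ribosomal FASTA,
#' repeats BED, paralog TSV and the truth table TSV.
#'
#' @param sim A simulated dataset from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  Biostrings::writeXStringSet(sim$rrna, p("rrna.fa"))
  write_gene_models_gtf(sim$models, p("annotation.gtf"))
  write_gene_models_knowngene(sim$models, p("annotation.knowngene.tsv"))
  write_pairs_tab(sim$pairs, p("pairs.tsv"))
  write_pairs_sam(sim$pairs, p("pairs.sam"),
    seq_lengths = setNames(Biostrings::width(sim$genome), names(sim$genome))
  )
  readr::write_tsv(sim$paralogs, p("paralogs.tsv"), col_names = FALSE)
  rep_gr <- GenomicRanges::GRanges(
    seqnames = sim$repeats$chrom,
    ranges = IRanges::IRanges(start = sim$repeats$start + 1L, end = sim$repeats$end)
  )
  rtracklayer::export(rep_gr, p("repeats.bed"), format = "bed")
  readr::write_tsv(sim$truth, p("truth.tsv"))
  invisible(dir)
}
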