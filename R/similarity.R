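#' Sequence-similarity primitives used by the filters
#'
#' Two engines back the misalignment filters; both are exhaustive scans, so
#' their results equal a brute-force window comparison. The *k-mismatch*
#' engine asks whether a read matches a subject sequence end-to-end anywhere,
#' on either strand, with at most `max_mismatches` substitutions. The *local*
#' engine evaluates every ungapped alignment of the read against the subject
#' (all diagonals, partial overlaps included) and counts matched nucleotides;
#' a read is a hit when at least `identity` of its length matches. The local
#' engine fills the role an external local aligner plays in read-vs-gene and
#' read-vs-ribosome comparisons.
#'
#' @param reads Character vector of read sequences.
#' @param subject A `DNAString`/character subject sequence (for the local
#'   engine, a `DNAStringSet` of subjects is allowed).
#' @param max_mismatches Maximum substitutions for the k-mismatch engine.
#' @param identity Minimum matched fraction of the read length for the local
#'   engine.
#' @return `kmismatch_hits()` and `local_similarity_hits()` return a logical
#'   vector, one element per read.
#' @name similarity
NULL

#' @rdname similarity
#' @export
kmismatch_hits <- function(reads, subject, max_mismatches = 3L) {
  if (length(reads) == 0) return(logical(0))
  subject_int <- dna_to_int(as.character(subject))
  lens <- nchar(reads)
  out <- rep(FALSE, length(reads))
  for (rl in unique(lens)) {
    sel <- lens == rl
    if (rl > length(subject_int)) next
    fwd <- dna_matrix(reads[sel], rl)
    rc <- dna_matrix(revcomp_chr_vec(reads[sel]), rl)
    out[sel] <- cpp_kmismatch_any(subject_int, fwd, rc, as.integer(max_mismatches))
  }
  out
}

dna_to_int <- function(x) {
  v <- match(strsplit(x, "")[[1]], c("A", "C", "G", "T")) - 1L
  v[is.na(v)] <- -1L
  v
}

dna_matrix <- function(x, rl) {
  m <- matrix(
    match(strsplit(paste(x, collapse = ""), "")[[1]], c("A", "C", "G", "T")) - 1L,
    nrow = length(x), ncol = rl, byrow = TRUE
  )
  m[is.na(m)] <- -1L
  m
}

#' @rdname similarity
#' @export
local_similarity_hits <- function(reads, subject, identity = 0.75) {
  if (length(reads) == 0) return(logical(0))
  if (methods::is(subject, "DNAString")) subject <- Biostrings::DNAStringSet(subject)
  if (methods::is(subject, "DNAStringSet")) subject <- as.character(subject)
  need <- ceiling(identity * nchar(reads))
  hits <- rep(FALSE, length(reads))
  lens <- nchar(reads)
  for (rl in unique(lens)) {
    sel <- which(lens == rl)
    fwd <- dna_matrix(reads[sel], rl)
    rc <- dna_matrix(revcomp_chr_vec(reads[sel]), rl)
    best <- rep(0L, length(sel))
    for (s in subject) {
      todo <- best < need[sel]
      if (!any(todo)) break
      cnt <- cpp_local_match_count(
        dna_to_int(s),
        fwd[todo, , drop = FALSE], rc[todo, , drop = FALSE]
      )
      best[todo] <- pmax(best[todo], cnt)
    }
    hits[sel] <- best >= need[sel]
  }
  hits
}

# composite-model sequence of a gene: concatenated block sequences in genomic
# order (plus strand); similarity searches run both strands so orientation is
# immaterial
composite_sequence <- function(models, genome, gene_id) {
  i <- match(gene_id, models$genes$gene_id)
  if (is.na(i)) abort(paste0("unknown gene '", gene_id, "'"))
  chrom <- models$genes$chrom[i]
  if (!chrom %in% names(genome)) {
    abort(paste0("chromosome '", chrom, "' absent from the genome sequences"))
  }
  b <- models$genes$blocks[[i]]
  pieces <- Biostrings::extractAt(
    genome[[chrom]],
    IRanges::IRanges(start = b[, "start"] + 1L, end = b[, "end"])
  )
  Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
}
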