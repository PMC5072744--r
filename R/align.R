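# Mapping of host flanks and WGS reads: a k-mer seed-and-extend ungapped
# aligner over host + provirus indexed together, with mapping quality from
# the best-vs-second-best score gap and explicit co-optimal placement
# counts. An external gapped aligner can be substituted through SAM.

#' Build a k-mer index over host chromosomes and the provirus
#'
#' Host and provirus are indexed together so every read competes across
#' both references; the reference of the best-scoring placement decides a
#' read's assignment.
#'
#' @param genome a [genome_ref()].
#' @param provirus optional [provirus_ref()]; indexed as reference
#'   `"provirus"`.
#' @param k k-mer size (>= 8).
#' @param max_hits per-k-mer position cap; more frequent k-mers are
#'   repeat-masked at seeding.
#' @return an object of class `seq_index`.
#' @export
build_index <- function(genome, provirus = NULL, k = 15L, max_hits = 64L) {
  stopifnot(inherits(genome, "genome_ref"), k >= 8L)
  refs <- genome$sequences
  if (!is.null(provirus)) {
    if ("provirus" %in% names(refs))
      stop("genome already contains a sequence named 'provirus'")
    refs <- c(refs, provirus = provirus$sequence)
  }
  ptr <- .mapper_build(names(refs), unname(refs), as.integer(k),
                       as.integer(max_hits))
  lens <- nchar(refs)
  structure(list(ptr = ptr, refs = names(refs), lengths = lens,
                 offsets = c(0, cumsum(lens + k))[seq_along(refs)],
                 k = as.integer(k)),
            class = "seq_index")
}

#' @export
print.seq_index <- function(x, ...) {
  cat("seq_index: k =", x$k, "over", length(x$refs), "reference(s),",
      format(sum(x$lengths), big.mark = ","), "bp\n")
  invisible(x)
}

#' Exact k-mer lookup in an index
#'
#' Reports every position of the k-mer on both strands (a hit of the
#' reverse complement is a minus-strand hit at the same coordinates).
#'
#' @param index a [build_index()] result.
#' @param kmer string of length `k`.
#' @return data.frame `reference`, `start` (0-based), `strand`.
#' @export
kmer_hits <- function(index, kmer) {
  stopifnot(nchar(kmer) == index$k)
  cvt <- function(gpos, strand) {
    if (!length(gpos))
      return(data.frame(reference = character(), start = numeric(),
                        strand = character()))
    ri <- findInterval(gpos, index$offsets)
    data.frame(reference = index$refs[ri],
               start = gpos - index$offsets[ri], strand = strand)
  }
  fwd <- cvt(.mapper_kmer_hits(index$ptr, kmer), "+")
  rkm <- revcomp(kmer)
  rev <- cvt(.mapper_kmer_hits(index$ptr, rkm), "-")
  out <- rbind(fwd, rev)
  out[order(out$reference, out$start, out$strand), , drop = FALSE]
}

#' Map reads with seed-and-extend
#'
#' Ungapped extension around seeded diagonals; for each read the
#' maximal-scoring contiguous segment (match +1, mismatch -3) is reported,
#' which soft-clips chimeric junction reads into their host and provirus
#' parts. `mapq` is `min(60, 2 * (best - second best score))`, forced to 0
#' when co-optimal placements exist. Up to one (best) alignment per
#' reference is returned per read, best first.
#'
#' @param index a [build_index()] result.
#' @param reads character vector of read sequences.
#' @param max_candidates diagonals extended per strand.
#' @param seed_stride spacing of seed k-mers along the read (the read tail
#'   is always seeded); any exact segment of at least
#'   `k + seed_stride - 1` bp is guaranteed a seed.
#' @return data.frame: `read` (index into `reads`), `reference`, `start`,
#'   `end` (0-based half-open), `strand`, `qstart`, `qend` (0-based in the
#'   original read), `matched`, `mismatches`, `score`, `mapq`,
#'   `n_cooptimal`, `best`.
#' @export
map_reads <- function(index, reads, max_candidates = 16L,
                      seed_stride = 5L) {
  res <- .mapper_map(index$ptr, as.character(reads),
                     as.integer(max_candidates), as.integer(seed_stride))
  data.frame(read = res$read,
             reference = index$refs[res$ref],
             start = res$start, end = res$end,
             strand = ifelse(res$strand > 0, "+", "-"),
             qstart = res$qstart, qend = res$qend,
             matched = res$matched, mismatches = res$mismatches,
             score = res$score, mapq = res$mapq,
             n_cooptimal = res$n_cooptimal,
             best = res$best == 1L)
}

#' Classify a mate pair's joint placement
#'
#' @param aln1,aln2 single-row data.frames (or `NA`-rows) holding each
#'   mate's best alignment; vectorized over rows.
#' @param max_insert maximum implied insert for a proper pair, bp.
#' @return character vector: `properly_paired`, `discordant` or `single`.
#' @export
pair_status <- function(aln1, aln2, max_insert = 600L) {
  n <- max(nrow(aln1), nrow(aln2))
  out <- character(n)
  for (i in seq_len(n)) {
    a <- aln1[i, ]; b <- aln2[i, ]
    a_ok <- !is.na(a$reference); b_ok <- !is.na(b$reference)
    if (!a_ok && !b_ok) { out[i] <- "single"; next }
    if (xor(a_ok, b_ok)) { out[i] <- "single"; next }
    insert <- max(a$end, b$end) - min(a$start, b$start)
    out[i] <- if (a$reference == b$reference && a$strand != b$strand &&
                  insert <= max_insert) "properly_paired" else "discordant"
  }
  out
}

# vectorized proper-pair test against the host for the WGS denominator;
# aln data.frames must be keyed by pair index in column `read`
.properly_paired_count <- function(aln1, aln2, max_insert = 600L) {
  h1 <- aln1[aln1$best & aln1$reference != "provirus", , drop = FALSE]
  h2 <- aln2[aln2$best & aln2$reference != "provirus", , drop = FALSE]
  m <- merge(h1[, c("read", "reference", "start", "end", "strand")],
             h2[, c("read", "reference", "start", "end", "strand")],
             by = "read")
  ok <- m$reference.x == m$reference.y & m$strand.x != m$strand.y &
    (pmax(m$end.x, m$end.y) - pmin(m$start.x, m$start.y)) <= max_insert
  sum(ok)
}
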