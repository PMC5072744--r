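# Pre-alignment stages of the LTR-anchored analysis: read-pair merging,
# splinkerette trimming, and LTR-anchor detection/stripping.

# mismatches between equal-length raw views
.raw_mm <- function(ra, rb) sum(ra != rb)

#' Merge an overlapping read pair
#'
#' Searches every overlap of at least `min_overlap` bp between read 1 and
#' the reverse complement of read 2; an overlap is acceptable when its
#' mismatch fraction is at most `max_mismatch_fraction`. Among acceptable
#' overlaps the one with the most matching columns wins (ties break toward
#' the longer overlap). Disagreeing columns take the higher-quality base;
#' quality ties take the read-1 base. Returns the pair unchanged when no
#' acceptable overlap exists — a valid outcome, not an error.
#'
#' @param seq1,qual1 read 1 and its quality string.
#' @param seq2,qual2 read 2 (as sequenced) and its quality string.
#' @param min_overlap minimum overlap, bp.
#' @param max_mismatch_fraction maximum mismatch fraction in the overlap.
#' @return list with `merged` (flag), and either `seq`/`qual` of the merged
#'   read or the original pair.
#' @export
merge_pairs <- function(seq1, qual1, seq2, qual2, min_overlap = 10L,
                        max_mismatch_fraction = 0.1) {
  if (!nzchar(seq1) || !nzchar(seq2)) stop("mates must be non-empty")
  s2 <- revcomp(seq2)
  q2 <- paste(rev(strsplit(qual2, "")[[1]]), collapse = "")
  n1 <- nchar(seq1); n2 <- nchar(s2)
  r1 <- charToRaw(seq1); r2 <- charToRaw(s2)
  best_o <- 0L; best_matches <- -1L
  for (o in seq(min(n1, n2), min_overlap)) {
    a <- r1[(n1 - o + 1L):n1]
    b <- r2[1:o]
    mm <- .raw_mm(a, b)
    if (mm / o <= max_mismatch_fraction && (o - mm) > best_matches) {
      best_matches <- o - mm
      best_o <- o
    }
  }
  if (best_o == 0L)
    return(list(merged = FALSE, seq1 = seq1, qual1 = qual1,
                seq2 = seq2, qual2 = qual2))
  o <- best_o
  ov1 <- substr(seq1, n1 - o + 1L, n1); ovq1 <- substr(qual1, n1 - o + 1L, n1)
  ov2 <- substr(s2, 1L, o); ovq2 <- substr(q2, 1L, o)
  a <- strsplit(ov1, "")[[1]]; b <- strsplit(ov2, "")[[1]]
  qa <- strsplit(ovq1, "")[[1]]; qb <- strsplit(ovq2, "")[[1]]
  take2 <- a != b & utf8ToInt(paste(qb, collapse = "")) >
    utf8ToInt(paste(qa, collapse = ""))
  cons <- a; cons[take2] <- b[take2]
  consq <- qa; consq[take2] <- qb[take2]
  list(merged = TRUE,
       seq = paste0(substr(seq1, 1L, n1 - o),
                    paste(cons, collapse = ""),
                    substr(s2, o + 1L, n2)),
       qual = paste0(substr(qual1, 1L, n1 - o),
                     paste(consq, collapse = ""),
                     substr(q2, o + 1L, n2)))
}

#' Detect and strip the library's LTR anchor from a read
#'
#' A read carries the anchor when it begins with the end-specific anchor
#' sequence within `mismatch_tolerance` mismatches. Up to `max_erosion`
#' terminal bases of the anchor may be absent (recombination-style
#' junctions erode the LTR terminus); such reads are anchor-found but not
#' anchor-complete. The splinkerette flag is raised when the adapter starts
#' within the first 5 bases after the matched anchor — the signature of an
#' empty insert.
#'
#' @param seq the read sequence (merged read or read 1).
#' @param provirus a [provirus_ref()].
#' @param which_end 5 or 3.
#' @param mismatch_tolerance allowed mismatches in the anchor match.
#' @param max_erosion maximum missing terminal anchor bases still accepted.
#' @param adapter splinkerette adapter sequence.
#' @return list: `anchor_found`, `anchor_complete`, `ltr_end`,
#'   `host_sequence`, `splinkerette_immediately_after_anchor`.
#' @export
strip_anchor <- function(seq, provirus, which_end = 3L,
                         mismatch_tolerance = 0L, max_erosion = 5L,
                         adapter = SPLINKERETTE) {
  stopifnot(nzchar(seq), which_end %in% c(3L, 5L))
  anchor <- if (which_end == 3L) provirus$anchor_3 else provirus$anchor_5
  alen <- nchar(anchor)
  n <- nchar(seq)
  matched_len <- NA_integer_
  complete <- FALSE
  for (e in 0:max_erosion) {
    L <- alen - e
    if (L > n || L < 10L) break
    if (.mismatches(substr(seq, 1L, L), substr(anchor, 1L, L)) <=
        mismatch_tolerance) {
      matched_len <- L
      complete <- (e == 0L)
      break
    }
  }
  if (is.na(matched_len))
    return(list(anchor_found = FALSE, anchor_complete = FALSE,
                ltr_end = NA_integer_, host_sequence = seq,
                splinkerette_immediately_after_anchor = FALSE))
  rest <- substr(seq, matched_len + 1L, n)
  probe_len <- min(12L, nchar(adapter))
  splk <- FALSE
  for (off in 0:4) {
    frag <- substr(rest, off + 1L, off + probe_len)
    if (nchar(frag) < probe_len) break
    if (.mismatches(frag, substr(adapter, 1L, probe_len)) <= 1L) {
      splk <- TRUE
      break
    }
  }
  list(anchor_found = TRUE, anchor_complete = complete,
       ltr_end = as.integer(which_end), host_sequence = rest,
       splinkerette_immediately_after_anchor = splk)
}

#' Trim a trailing splinkerette adapter
#'
#' Removes the longest read suffix that matches a prefix of the adapter
#' with at least 10 matched bp and at most one mismatch per 10 bp.
#'
#' @param seq read sequence.
#' @param adapter adapter sequence (>= 10 bp).
#' @return trimmed sequence.
#' @export
trim_splinkerette <- function(seq, adapter = SPLINKERETTE) {
  stopifnot(nchar(adapter) >= 10L)
  n <- nchar(seq)
  if (n < 10L) return(seq)
  for (i in 1:(n - 9L)) {
    L <- min(n - i + 1L, nchar(adapter))
    if (L < 10L) break
    if (.mismatches(substr(seq, i, i + L - 1L),
                    substr(adapter, 1L, L)) <= L %/% 10L)
      return(substr(seq, 1L, i - 1L))
  }
  seq
}

#' Prepare a TraDIS library for alignment
#'
#' Runs pair merging, anchor detection and splinkerette trimming over a
#' simulated or parsed read-pair table, yielding one prepped record per
#' fragment with the bare host flank ready for mapping.
#'
#' @param pairs data.frame with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @param provirus a [provirus_ref()].
#' @param which_end 5 or 3.
#' @param params a [filter_params()]; supplies `min_overlap_merge` and
#'   `anchor_mismatch_tolerance`.
#' @param max_erosion maximum missing terminal anchor bases still accepted.
#' @return data.frame of prepped reads: `id`, `evidence`
#'   (merged/paired), `ltr_end`, `anchor_found`, `anchor_complete`,
#'   `splinkerette_immediately_after_anchor`, `host_sequence`. A `counts`
#'   attribute tallies the prep report (merged, paired, anchor_found,
#'   splinkerette_flagged).
#' @export
prep_tradis_reads <- function(pairs, provirus, which_end = 3L,
                              params = filter_params(), max_erosion = 5L) {
  n <- nrow(pairs)
  out <- vector("list", n)
  n_merged <- 0L
  for (i in seq_len(n)) {
    m <- merge_pairs(pairs$seq1[i], pairs$qual1[i],
                     pairs$seq2[i], pairs$qual2[i],
                     min_overlap = params$min_overlap_merge)
    if (m$merged) {
      evidence <- "merged"
      seq <- m$seq
      n_merged <- n_merged + 1L
    } else {
      evidence <- "paired"
      seq <- pairs$seq1[i]
    }
    an <- strip_anchor(seq, provirus, which_end,
                       mismatch_tolerance = params$anchor_mismatch_tolerance,
                       max_erosion = max_erosion)
    host <- if (an$anchor_found) trim_splinkerette(an$host_sequence) else ""
    out[[i]] <- data.frame(
      id = pairs$id[i], evidence = evidence,
      ltr_end = as.integer(which_end),
      anchor_found = an$anchor_found,
      anchor_complete = an$anchor_complete,
      splinkerette_immediately_after_anchor =
        an$splinkerette_immediately_after_anchor,
      host_sequence = host)
  }
  res <- if (n) do.call(rbind, out) else
    data.frame(id = character(), evidence = character(),
               ltr_end = integer(), anchor_found = logical(),
               anchor_complete = logical(),
               splinkerette_immediately_after_anchor = logical(),
               host_sequence = character())
  attr(res, "counts") <- c(
    merged = n_merged, paired = n - n_merged,
    anchor_found = sum(res$anchor_found),
    splinkerette_flagged = sum(res$splinkerette_immediately_after_anchor))
  res
}
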