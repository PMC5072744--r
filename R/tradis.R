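# The junction caller for LTR-anchored libraries: the four authenticity
# criteria, PCR deduplication, unique positions, 250-bp single-linkage
# clustering, and integrase-catalyzed vs. unresolved classification.

#' Authenticity filter thresholds
#'
#' The four criteria applied to every anchored read: (i) it begins with the
#' library's LTR anchor; (ii) the anchor is not immediately followed by
#' splinkerette adapter; (iii) the remaining host flank maps uniquely over
#' at least `min_host_match` bp; (iv) with mapping quality at least
#' `min_mapq`.
#'
#' @param min_overlap_merge minimum pair-merge overlap, bp.
#' @param min_host_match minimum uniquely mapped host bp.
#' @param min_mapq minimum mapping quality.
#' @param cluster_radius neighbouring unique positions within this radius
#'   collapse into one cluster, bp.
#' @param anchor_mismatch_tolerance mismatches allowed in the anchor match.
#' @param max_insert maximum proper-pair insert, bp.
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(min_overlap_merge = 10L, min_host_match = 30L,
                          min_mapq = 30L, cluster_radius = 250L,
                          anchor_mismatch_tolerance = 0L,
                          max_insert = 600L) {
  p <- list(min_overlap_merge = as.integer(min_overlap_merge),
            min_host_match = as.integer(min_host_match),
            min_mapq = as.integer(min_mapq),
            cluster_radius = as.integer(cluster_radius),
            anchor_mismatch_tolerance = as.integer(anchor_mismatch_tolerance),
            max_insert = as.integer(max_insert))
  if (any(unlist(p[c(1, 2, 3, 4, 6)]) <= 0) || p$anchor_mismatch_tolerance < 0)
    stop("filter thresholds must be positive")
  structure(p, class = "filter_params")
}

#' Call integration junctions from prepped reads
#'
#' Emits one call per read that passes all four authenticity criteria; the
#' junction is placed at the anchor-proximal boundary of the host
#' alignment, i.e. the first host base adjacent to the LTR terminus
#' (alignment start on `+`, end - 1 on `-`). The alignment must start at
#' the first base of the host flank (`qstart == 0`) so that the junction
#' coordinate is well defined. Rejected reads are tallied by their first
#' failing criterion in the `rejections` attribute.
#'
#' @param prepped data.frame from [prep_tradis_reads()].
#' @param alignments data.frame from [map_reads()] run on
#'   `prepped$host_sequence` (read indices refer to rows of `prepped`).
#' @param params a [filter_params()].
#' @param provirus a [provirus_ref()]; used for junction classification.
#' @return calls data.frame: `chromosome`, `position` (0-based), `strand`,
#'   `ltr_end`, `junction_class`, `evidence`, `read_id`, plus the
#'   classification evidence columns `anchor_complete` and `flank_start`.
#' @export
call_sites <- function(prepped, alignments, params = filter_params(),
                       provirus = NULL) {
  n <- nrow(prepped)
  known <- alignments$read >= 1 & alignments$read <= n
  if (!all(known)) stop("alignment for unknown read index")
  best <- alignments[alignments$best, , drop = FALSE]
  best_by_read <- split(best, best$read)
  rej <- c(i_no_anchor = 0L, ii_splinkerette = 0L,
           iii_short_or_multi = 0L, iv_mapq = 0L)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- prepped[i, ]
    if (!p$anchor_found) { rej[1] <- rej[1] + 1L; next }
    if (p$splinkerette_immediately_after_anchor) {
      rej[2] <- rej[2] + 1L; next
    }
    a <- best_by_read[[as.character(i)]]
    if (is.null(a) || nrow(a) == 0 || a$reference[1] == "provirus" ||
        a$matched[1] < params$min_host_match || a$n_cooptimal[1] != 1L ||
        a$qstart[1] != 0L) {
      rej[3] <- rej[3] + 1L; next
    }
    if (a$mapq[1] < params$min_mapq) { rej[4] <- rej[4] + 1L; next }
    pos <- if (a$strand[1] == "+") a$start[1] else a$end[1] - 1
    rows[[i]] <- data.frame(
      chromosome = a$reference[1], position = pos, strand = a$strand[1],
      ltr_end = p$ltr_end, evidence = p$evidence, read_id = p$id,
      anchor_complete = p$anchor_complete,
      flank_start = substr(p$host_sequence, 1L, 2L))
  }
  calls <- if (any(!vapply(rows, is.null, TRUE)))
    do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  else
    data.frame(chromosome = character(), position = numeric(),
               strand = character(), ltr_end = integer(),
               evidence = character(), read_id = character(),
               anchor_complete = logical(), flank_start = character())
  calls$junction_class <- classify_junction(calls, provirus)
  rownames(calls) <- NULL
  attr(calls, "rejections") <- rej
  calls
}

#' Classify junctions as integrase-catalyzed or unresolved
#'
#' A junction is integrase-catalyzed only when the read carries the
#' complete anchor — so the LTR terminal dinucleotide is intact — and the
#' host alignment begins at the very next base. A junction whose host
#' flank itself begins with the terminal dinucleotide is microhomologous:
#' the boundary cannot be assigned and the call is unresolved, as are
#' eroded-anchor junctions (recombination or end-joining products).
#'
#' @param calls calls data.frame carrying `anchor_complete` and
#'   `flank_start` (as produced by [call_sites()]).
#' @param provirus optional [provirus_ref()]; supplies the terminal
#'   dinucleotide (in read orientation both library anchors end with CA).
#' @return character vector, `integrase_catalyzed` or `unresolved`.
#' @export
classify_junction <- function(calls, provirus = NULL) {
  if (nrow(calls) == 0) return(character(0))
  terminal <- if (!is.null(provirus))
    substr(provirus$anchor_3, nchar(provirus$anchor_3) - 1L,
           nchar(provirus$anchor_3))
  else "CA"
  ifelse(calls$anchor_complete & calls$flank_start != terminal,
         "integrase_catalyzed", "unresolved")
}

#' Collapse PCR duplicates to unique positions
#'
#' Calls identical in (chromosome, position, strand, LTR end) collapse to
#' one unique-position record; supporting reads are pooled and a unique
#' position is integrase-catalyzed when any supporting read shows the
#' intact-terminus structure.
#'
#' @param calls calls data.frame from [call_sites()].
#' @return data.frame sorted by (chromosome, position): `chromosome`,
#'   `position`, `strand`, `ltr_end`, `junction_class`, `support`,
#'   `evidence` (merged if any supporting read was merged), `read_ids`.
#' @export
dedup_and_unique <- function(calls) {
  if (nrow(calls) == 0)
    return(data.frame(chromosome = character(), position = numeric(),
                      strand = character(), ltr_end = integer(),
                      junction_class = character(), support = integer(),
                      evidence = character(), read_ids = character()))
  key <- paste(calls$chromosome, calls$position, calls$strand,
               calls$ltr_end, sep = "\r")
  idx <- split(seq_len(nrow(calls)), key)
  out <- lapply(idx, function(j) {
    data.frame(
      chromosome = calls$chromosome[j[1]],
      position = calls$position[j[1]],
      strand = calls$strand[j[1]],
      ltr_end = calls$ltr_end[j[1]],
      junction_class = if (any(calls$junction_class[j] ==
                               "integrase_catalyzed"))
        "integrase_catalyzed" else "unresolved",
      support = length(j),
      evidence = if (any(calls$evidence[j] == "merged")) "merged"
      else "paired",
      read_ids = paste(calls$read_id[j], collapse = ","))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chromosome, out$position, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Cluster unique positions by single linkage
#'
#' Transitive chaining: walking each chromosome's sorted positions, a new
#' cluster starts whenever the gap to the previous position exceeds
#' `radius`, so a chain 0, 200, 400 at radius 250 is one cluster.
#'
#' @param unique_calls data.frame from [dedup_and_unique()] (any data.frame
#'   with `chromosome` and `position` works).
#' @param radius bp.
#' @return an object of class `cluster_set`: data.frame `chromosome`,
#'   `start`, `end` (span of member positions), `n_members`,
#'   `representative` (minimum member position), `integrase_any`; the
#'   radius is attached as an attribute.
#' @export
cluster_positions <- function(unique_calls, radius = 250L) {
  if (nrow(unique_calls) == 0) {
    out <- data.frame(chromosome = character(), start = numeric(),
                      end = numeric(), n_members = integer(),
                      representative = numeric(), integrase_any = logical())
    attr(out, "radius") <- radius
    class(out) <- c("cluster_set", "data.frame")
    return(out)
  }
  has_class <- "junction_class" %in% names(unique_calls)
  res <- list()
  for (chrom in sort(unique(unique_calls$chromosome))) {
    d <- unique_calls[unique_calls$chromosome == chrom, , drop = FALSE]
    d <- d[order(d$position), , drop = FALSE]
    gap_new <- c(TRUE, diff(d$position) > radius)
    cid <- cumsum(gap_new)
    for (g in split(seq_len(nrow(d)), cid)) {
      res[[length(res) + 1L]] <- data.frame(
        chromosome = chrom,
        start = min(d$position[g]), end = max(d$position[g]),
        n_members = length(g),
        representative = min(d$position[g]),
        integrase_any = if (has_class)
          any(d$junction_class[g] == "integrase_catalyzed") else NA)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "radius") <- radius
  class(out) <- c("cluster_set", "data.frame")
  out
}

#' Per-library-end summary table
#'
#' The call-level, unique-position and cluster counts for one library end,
#' split by evidence type with integrase-catalyzed percentages.
#'
#' @param calls calls data.frame from [call_sites()].
#' @param unique_calls optional precomputed [dedup_and_unique()] result.
#' @param clusters optional precomputed [cluster_positions()] result.
#' @param radius cluster radius used when `clusters` is missing.
#' @return data.frame rows `merged reads`, `read pairs`, `unique
#'   positions`, `unique clusters` with columns `integrase_catalyzed`,
#'   `unresolved`, `total`, `pct_integrase`.
#' @export
library_summary <- function(calls, unique_calls = NULL, clusters = NULL,
                            radius = 250L) {
  if (is.null(unique_calls)) unique_calls <- dedup_and_unique(calls)
  if (is.null(clusters)) clusters <- cluster_positions(unique_calls, radius)
  row_for <- function(ev) {
    d <- calls[calls$evidence == ev, , drop = FALSE]
    ic <- sum(d$junction_class == "integrase_catalyzed")
    data.frame(category = if (ev == "merged") "merged reads" else
      "read pairs",
      integrase_catalyzed = ic, unresolved = nrow(d) - ic,
      total = nrow(d),
      pct_integrase = if (nrow(d)) round(100 * ic / nrow(d), 1) else NA)
  }
  rbind(
    row_for("merged"), row_for("paired"),
    data.frame(category = "unique positions", integrase_catalyzed = NA,
               unresolved = NA, total = nrow(unique_calls),
               pct_integrase = NA),
    data.frame(category = "unique clusters", integrase_catalyzed = NA,
               unresolved = NA, total = nrow(clusters), pct_integrase = NA))
}
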