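# Region annotation: exon/intron/intergenic genome composition, site
# classification with exon > intron precedence, the one-tailed binomial
# bias test for non-coding integration, and per-chromosome rate tables.

# reduced exon and gene-span IRanges per chromosome (1-based closed for
# IRanges; converted from internal 0-based half-open)
.region_index <- function(genome) {
  ex <- list(); gn <- list()
  g <- genome$genes
  for (chrom in names(genome$sequences)) {
    d <- g[g$chromosome == chrom, , drop = FALSE]
    if (nrow(d) == 0) {
      ex[[chrom]] <- IRanges::IRanges()
      gn[[chrom]] <- IRanges::IRanges()
      next
    }
    ex[[chrom]] <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    spans <- do.call(rbind, lapply(split(d, d$gene_id), function(x)
      c(min(x$start) + 1L, max(x$end))))
    gn[[chrom]] <- IRanges::reduce(IRanges::IRanges(spans[, 1], spans[, 2]))
  }
  list(exon = ex, gene = gn)
}

#' Genome region composition
#'
#' Fractions of the genome covered by exons, introns (gene span minus
#' exon) and intergenic sequence, with exon taking precedence over intron
#' where transcripts overlap.
#'
#' @param genome a [genome_ref()] with gene annotation.
#' @return named numeric: `exon`, `intron`, `intergenic` (summing to 1).
#' @export
genome_composition <- function(genome) {
  ri <- .region_index(genome)
  exon_bp <- sum(vapply(ri$exon, function(x) sum(IRanges::width(x)), 0))
  gene_bp <- sum(vapply(ri$gene, function(x) sum(IRanges::width(x)), 0))
  total <- sum(as.numeric(genome$lengths))
  c(exon = exon_bp / total,
    intron = (gene_bp - exon_bp) / total,
    intergenic = (total - gene_bp) / total)
}

#' Classify integration sites by genomic region
#'
#' Each site (a cluster representative or a unique position) receives
#' exactly one label with precedence exon > intron > intergenic.
#'
#' @param sites data.frame with `chromosome` and `position` (0-based), or
#'   a [cluster_positions()] result (its `representative` is used).
#' @param genome a [genome_ref()].
#' @return list of class `region_stats`: `labels` (per site), `counts`
#'   (named exon/intron/intergenic) and `n_sites`.
#' @export
classify_sites <- function(sites, genome) {
  if (inherits(sites, "cluster_set"))
    sites <- data.frame(chromosome = sites$chromosome,
                        position = sites$representative)
  if (any(!sites$chromosome %in% names(genome$sequences)))
    stop("site on unknown chromosome")
  if (nrow(sites) &&
      any(sites$position < 0 |
          sites$position >= genome$lengths[sites$chromosome]))
    stop("site position out of chromosome bounds")
  ri <- .region_index(genome)
  labels <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chromosome[i]
    pt <- IRanges::IRanges(sites$position[i] + 1L, sites$position[i] + 1L)
    labels[i] <-
      if (IRanges::countOverlaps(pt, ri$exon[[chrom]]) > 0) "exon"
      else if (IRanges::countOverlaps(pt, ri$gene[[chrom]]) > 0) "intron"
      else "intergenic"
  }
  counts <- c(exon = sum(labels == "exon"),
              intron = sum(labels == "intron"),
              intergenic = sum(labels == "intergenic"))
  structure(list(labels = labels, counts = counts,
                 n_sites = length(labels)),
            class = "region_stats")
}

#' @export
print.region_stats <- function(x, ...) {
  cat("region_stats:", x$n_sites, "sites —",
      paste(sprintf("%s %d (%.1f%%)", names(x$counts), x$counts,
                    100 * x$counts / max(1, x$n_sites)), collapse = ", "),
      "\n")
  invisible(x)
}

#' One-tailed exact binomial test for non-coding bias
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n,
#' expected_fraction)`: the chance of seeing at least the observed number
#' of non-coding integrations if sites fell in proportion to genome
#' composition.
#'
#' @param k_noncoding observed non-coding sites.
#' @param n total sites.
#' @param expected_fraction genome fraction that is non-coding.
#' @return one-tailed p-value.
#' @export
noncoding_bias_test <- function(k_noncoding, n, expected_fraction) {
  if (expected_fraction <= 0 || expected_fraction >= 1)
    stop("expected_fraction must be in (0,1)")
  if (k_noncoding < 0 || k_noncoding > n) stop("need 0 <= k <= n")
  pbinom(k_noncoding - 1, n, expected_fraction, lower.tail = FALSE)
}

#' Per-chromosome integration rate table
#'
#' Counts and per-Mb rates for each library end; rates are kept at full
#' precision here and rounded to one decimal by [write_rates_tsv()].
#'
#' @param counts_5,counts_3 named integer vectors of event counts per
#'   chromosome (missing chromosomes count 0).
#' @param genome a [genome_ref()], or a named vector of assembly lengths.
#' @param unplaced optional character vector of scaffold names to
#'   aggregate into a single `Unplaced` row.
#' @return data.frame: `chromosome`, `assembly_length`, `count_5`,
#'   `count_3`, `rate_5`, `rate_3`.
#' @export
rate_table <- function(counts_5, counts_3, genome, unplaced = NULL) {
  lengths <- if (inherits(genome, "genome_ref")) genome$lengths else genome
  known <- names(lengths)
  bad <- setdiff(unique(c(names(counts_5), names(counts_3))), known)
  if (length(bad))
    stop("counts for unknown chromosome: ", paste(bad, collapse = ", "))
  cnt <- function(counts, chrom)
    if (chrom %in% names(counts)) as.numeric(counts[[chrom]]) else 0
  main <- setdiff(known, unplaced)
  rows <- lapply(main, function(chrom) data.frame(
    chromosome = chrom, assembly_length = as.numeric(lengths[[chrom]]),
    count_5 = cnt(counts_5, chrom), count_3 = cnt(counts_3, chrom)))
  if (length(unplaced)) {
    rows[[length(rows) + 1L]] <- data.frame(
      chromosome = "Unplaced",
      assembly_length = sum(as.numeric(lengths[unplaced])),
      count_5 = sum(vapply(unplaced, function(s) cnt(counts_5, s), 0)),
      count_3 = sum(vapply(unplaced, function(s) cnt(counts_3, s), 0)))
  }
  out <- do.call(rbind, rows)
  out$rate_5 <- out$count_5 / (out$assembly_length / 1e6)
  out$rate_3 <- out$count_3 / (out$assembly_length / 1e6)
  out
}

#' Write a rate table with report rounding
#'
#' @param rates [rate_table()] result.
#' @param path output TSV.
#' @export
write_rates_tsv <- function(rates, path) {
  rates$rate_5 <- round(rates$rate_5, 1)
  rates$rate_3 <- round(rates$rate_3, 1)
  write_tsv_file(rates, path)
}
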