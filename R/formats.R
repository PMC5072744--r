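# Readers/writers for the external formats the pipeline touches, plus the
# two reference containers (host genome + gene models, provirus).
#
# Internal coordinate convention: 0-based half-open everywhere. 1-based
# fully-closed appears only at the GFF3 boundary and in printed reports.

#' Host genome reference
#'
#' Bundles chromosome sequences with a flat exon table describing gene
#' models. Exon coordinates are 0-based half-open.
#'
#' @param sequences named character vector of chromosome sequences
#'   (A/C/G/T/N; case-normalized to upper).
#' @param genes `NULL` or a data.frame with columns `gene_id`, `chromosome`,
#'   `strand` (`+`/`-`), `start`, `end` — one row per exon, 0-based
#'   half-open intervals.
#' @return an object of class `genome_ref` with elements `sequences`,
#'   `lengths` and `genes`.
#' @export
genome_ref <- function(sequences, genes = NULL) {
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == ""))
    stop("all sequences must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicate chromosome names: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "))
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("non-ACGTN characters in sequence(s): ",
         paste(names(sequences)[bad], collapse = ", "))
  lengths <- setNames(nchar(sequences), names(sequences))
  if (!is.null(genes) && nrow(genes) > 0) {
    need <- c("gene_id", "chromosome", "strand", "start", "end")
    if (!all(need %in% names(genes)))
      stop("genes must have columns ", paste(need, collapse = ", "))
    genes <- genes[order(genes$gene_id, genes$start), need, drop = FALSE]
    rownames(genes) <- NULL
    if (any(!genes$chromosome %in% names(sequences)))
      stop("gene feature on unknown chromosome: ",
           paste(unique(setdiff(genes$chromosome, names(sequences))),
                 collapse = ", "))
    if (any(genes$end <= genes$start)) stop("empty exon interval")
    if (any(genes$start < 0 | genes$end > lengths[genes$chromosome]))
      stop("exon outside chromosome bounds")
    if (any(!genes$strand %in% c("+", "-"))) stop("exon strand must be +/-")
    for (g in split(genes, genes$gene_id)) {
      if (length(unique(g$chromosome)) != 1L ||
          length(unique(g$strand)) != 1L)
        stop("gene ", g$gene_id[1], " spans chromosomes or strands")
      if (nrow(g) > 1L && any(g$start[-1] < g$end[-nrow(g)]))
        stop("overlapping exons within gene ", g$gene_id[1])
    }
  } else {
    genes <- data.frame(gene_id = character(), chromosome = character(),
                        strand = character(), start = numeric(),
                        end = numeric())
  }
  structure(list(sequences = sequences, lengths = lengths, genes = genes),
            class = "genome_ref")
}

#' @export
print.genome_ref <- function(x, ...) {
  cat("genome_ref:", length(x$sequences), "sequence(s),",
      format(sum(x$lengths), big.mark = ","), "bp,",
      length(unique(x$genes$gene_id)), "gene(s)\n")
  invisible(x)
}

#' Provirus reference
#'
#' The proviral sequence with its LTR geometry and the two library anchor
#' sequences: `anchor_3` is the terminal 37 bp of the 3'-LTR (the expected
#' read prefix of a 3'-end library) and `anchor_5` is the reverse
#' complement of the first 32 bp of the 5'-LTR (the expected read prefix of
#' a 5'-end library). A provirus deposited by integrase starts with TG and
#' ends with CA.
#'
#' @param sequence proviral DNA string (5'-LTR ... 3'-LTR).
#' @param ltr_length length of each LTR in bp.
#' @param anchor3_length,anchor5_length anchor lengths in bp.
#' @return an object of class `provirus_ref`.
#' @export
provirus_ref <- function(sequence, ltr_length,
                         anchor3_length = 37L, anchor5_length = 32L) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (ltr_length < max(anchor3_length, anchor5_length) ||
      2 * ltr_length > n)
    stop("inconsistent LTR length")
  if (substr(sequence, 1, 2) != "TG")
    stop("provirus must begin with the terminal dinucleotide TG")
  if (substr(sequence, n - 1, n) != "CA")
    stop("provirus must end with the terminal dinucleotide CA")
  anchor_3 <- substr(sequence, n - anchor3_length + 1, n)
  anchor_5 <- revcomp(substr(sequence, 1, anchor5_length))
  if (grepl("N", anchor_3, fixed = TRUE) || grepl("N", anchor_5, fixed = TRUE))
    stop("N bases are not allowed inside LTR anchors")
  structure(list(sequence = sequence, ltr_length = ltr_length,
                 anchor_3 = anchor_3, anchor_5 = anchor_5,
                 terminal_5_dinucleotide = "TG",
                 terminal_3_dinucleotide = "CA"),
            class = "provirus_ref")
}

#' @export
print.provirus_ref <- function(x, ...) {
  cat("provirus_ref:", nchar(x$sequence), "bp, LTR", x$ltr_length, "bp\n",
      "3'-anchor:", x$anchor_3, "\n", "5'-anchor:", x$anchor_5, "\n")
  invisible(x)
}

# -- FASTA -------------------------------------------------------------------

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  first <- readLines(path, n = 1L)
  if (!startsWith(first, ">"))
    stop("malformed FASTA (line 1 does not start with '>'): ", path)
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm))
    stop("duplicate FASTA record names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  setNames(toupper(as.character(x)), nm)
}

#' Write sequences to FASTA
#'
#' @param x named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path, width = 70L)
  invisible(path)
}

# -- FASTQ -------------------------------------------------------------------

#' Read a FASTQ file
#'
#' @param path FASTQ file.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL)
}

#' Write reads to FASTQ
#'
#' @param ids,seqs,quals parallel character vectors.
#' @param path output file.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

# -- GFF3 --------------------------------------------------------------------

#' Read gene models from GFF3
#'
#' Understands gene/mRNA/exon features; exon coordinates are converted from
#' GFF's 1-based closed convention to the internal 0-based half-open one,
#' and exon-to-gene linkage is resolved through the Parent attribute
#' (exon -> mRNA -> gene, or exon -> gene directly).
#'
#' @param path GFF3 file.
#' @param genome optional `genome_ref`; when given, features are validated
#'   against its chromosome names and bounds.
#' @return exon-level data.frame (`gene_id`, `chromosome`, `strand`,
#'   `start`, `end`) suitable for [genome_ref()].
#' @export
read_gff <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path)
  typ <- as.character(gr$type)
  id_of <- function(g) if (!is.null(g$ID)) as.character(g$ID) else NA_character_
  feats <- data.frame(
    type = typ,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id = id_of(gr),
    parent = vapply(gr$Parent, function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1)),
    stringsAsFactors = FALSE)
  mrna2gene <- setNames(feats$parent[feats$type == "mRNA"],
                        feats$id[feats$type == "mRNA"])
  ex <- feats[feats$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0)
    return(data.frame(gene_id = character(), chromosome = character(),
                      strand = character(), start = numeric(),
                      end = numeric()))
  gene_id <- ifelse(ex$parent %in% names(mrna2gene),
                    mrna2gene[ex$parent], ex$parent)
  if (anyNA(gene_id)) stop("exon without resolvable Parent in ", path)
  out <- data.frame(gene_id = unname(gene_id), chromosome = ex$chromosome,
                    strand = ex$strand, start = ex$start, end = ex$end)
  if (!is.null(genome)) {
    if (any(!out$chromosome %in% names(genome$sequences)))
      stop("GFF feature on unknown chromosome: ",
           paste(unique(setdiff(out$chromosome, names(genome$sequences))),
                 collapse = ", "))
    if (any(out$start < 0 | out$end > genome$lengths[out$chromosome]))
      stop("exon outside chromosome bounds in ", path)
  }
  out <- out[order(out$gene_id, out$start), ]
  rownames(out) <- NULL
  out
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/exon rows (one mRNA per gene), converting internal
#' 0-based half-open intervals back to GFF's 1-based closed convention.
#'
#' @param genes exon-level data.frame as stored in a `genome_ref`.
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in split(genes, genes$gene_id)) {
    gid <- g$gene_id[1]
    gs <- min(g$start) + 1L
    ge <- max(g$end)
    writeLines(sprintf(
      "%s\tltrsites\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      g$chromosome[1], gs, ge, g$strand[1], gid), con)
    writeLines(sprintf(
      "%s\tltrsites\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
      g$chromosome[1], gs, ge, g$strand[1], gid, gid), con)
    writeLines(sprintf(
      "%s\tltrsites\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
      g$chromosome[1], g$start + 1L, g$end, g$strand[1], gid,
      seq_len(nrow(g)), gid), con)
  }
  invisible(path)
}

# -- BED / TSV ---------------------------------------------------------------

#' Write junction calls to BED6
#'
#' 0-based half-open; one base per call. `name` carries the junction class,
#' `score` the supporting-read count.
#'
#' @param calls data.frame with `chromosome`, `position`, `strand` and
#'   optionally `junction_class`, `support`.
#' @param path output file.
#' @export
write_calls_bed <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con)
  if (nrow(calls)) {
    nm <- if ("junction_class" %in% names(calls)) calls$junction_class else "."
    sc <- if ("support" %in% names(calls)) calls$support else 0L
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                       calls$chromosome, as.integer(calls$position),
                       as.integer(calls$position) + 1L, nm, as.integer(sc),
                       calls$strand), con)
  }
  invisible(path)
}

#' Read a BED file of positions
#'
#' @param path BED file (first three columns used; strand from column 6).
#' @return data.frame `chromosome`, `position` (= BED start), `strand`.
#' @export
read_bed <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (!length(ln))
    return(data.frame(chromosome = character(), position = numeric(),
                      strand = character()))
  f <- strsplit(ln, "\t", fixed = TRUE)
  data.frame(
    chromosome = vapply(f, `[`, "", 1L),
    position = as.numeric(vapply(f, `[`, "", 2L)),
    strand = vapply(f, function(x) if (length(x) >= 6) x[6] else "+", ""))
}

#' Write a fixed-column TSV
#'
#' @param x data.frame.
#' @param path output file.
#' @export
write_tsv_file <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_file()]
#' @param path file.
#' @return data.frame.
#' @export
read_tsv_file <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

# -- SAM ---------------------------------------------------------------------

#' Read a text SAM file
#'
#' Minimal reader for the 11 mandatory fields; used for alignment interop
#' with external aligners. Optional tags are ignored.
#'
#' @param path SAM file.
#' @return data.frame with columns qname, flag, rname, pos, mapq, cigar,
#'   rnext, pnext, tlen, seq, qual.
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@") & nzchar(ln)]
  if (!length(ln))
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(), mapq = integer(),
                      cigar = character(), rnext = character(),
                      pnext = integer(), tlen = integer(), seq = character(),
                      qual = character()))
  f <- strsplit(ln, "\t", fixed = TRUE)
  bad <- vapply(f, length, 0L) < 11L
  if (any(bad)) stop("malformed SAM record at data line ", which(bad)[1])
  g <- function(i) vapply(f, `[`, "", i)
  data.frame(qname = g(1), flag = as.integer(g(2)), rname = g(3),
             pos = as.integer(g(4)), mapq = as.integer(g(5)), cigar = g(6),
             rnext = g(7), pnext = as.integer(g(8)), tlen = as.integer(g(9)),
             seq = g(10), qual = g(11))
}

#' Write alignments as text SAM
#'
#' @param aln data.frame as returned by [read_sam()].
#' @param refs named integer/numeric vector of reference lengths for the
#'   `@SQ` header lines.
#' @param path output file.
#' @export
write_sam <- function(aln, refs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(refs), as.integer(refs)), con)
  if (nrow(aln))
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                       aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq,
                       aln$cigar, aln$rnext, aln$pnext, aln$tlen, aln$seq,
                       aln$qual), con)
  invisible(path)
}
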