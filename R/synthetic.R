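# Synthetic-data generators: host genomes with gene models of controlled
# exon/intron/intergenic composition, planted proviruses with realistic
# junction structure (intact integrase-style termini with target-site
# duplication, or recombination-style junctions with eroded termini), and
# TraDIS / WGS read sets with ground truth.

#' Built-in library anchor and adapter sequences
#'
#' `ANCHOR_3` is the terminal 37 bp of the 3'-LTR used as the expected read
#' prefix of 3'-end libraries; `ANCHOR_5` the reverse complement of the
#' first 32 bp of the 5'-LTR, the expected prefix of 5'-end libraries;
#' `SPLINKERETTE` is the splinkerette top-strand oligo ligated to fragment
#' far ends.
#'
#' @name anchors
#' @export
ANCHOR_3 <- "CTCAGACCCTTTTAGTCAGTGTGGAAAATCTCTAGCA"

#' @rdname anchors
#' @export
ANCHOR_5 <- "TTGTCTTTTTTGGGACCAAATTAGCCCTTCCA"

#' @rdname anchors
#' @export
SPLINKERETTE <- "GTTCCCATGGTACTACTCATATAATACGACTCACTATAGGTGACAGCGAGCGCT"

#' Synthetic provirus with realistic LTR geometry
#'
#' Builds a provirus whose two identical LTRs carry the canonical anchor
#' subsequences at their boundaries: the 5'-LTR begins with the reverse
#' complement of [ANCHOR_5] (hence with TG) and the 3'-LTR ends with
#' [ANCHOR_3] (hence with CA). LTR interiors and the internal region are
#' random sequence.
#'
#' @param internal_length bp between the two LTRs.
#' @param ltr_length bp per LTR.
#' @param seed RNG seed.
#' @return a [provirus_ref()].
#' @export
synthetic_provirus <- function(internal_length = 8400L, ltr_length = 634L,
                               seed = 1L) {
  set.seed(seed)
  ltr <- paste0(revcomp(ANCHOR_5),
                random_dna(ltr_length - nchar(ANCHOR_5) - nchar(ANCHOR_3)),
                ANCHOR_3)
  provirus_ref(paste0(ltr, random_dna(internal_length), ltr), ltr_length)
}

#' Simulation configuration
#'
#' Holds every knob of the synthetic-data module. Defaults emulate the
#' study conditions: genome composition 4% exon / 39% intron / 57%
#' intergenic, 200-400 bp amplicon fragments, 100-bp paired reads, 48-fold
#' WGS coverage, and a 5-bp target-site duplication for integrase events.
#'
#' @param seed RNG seed; all generators are reproducible from it.
#' @param chromosome_lengths bp per chromosome.
#' @param target_region_fractions exon/intron/intergenic bp fractions,
#'   summing to 1.
#' @param n_integrations proviruses to plant (per genome).
#' @param integrase_fraction proportion of events with intact termini and a
#'   target-site duplication; the rest get both termini eroded
#'   (recombination-style) and no duplication.
#' @param truncation_spectrum integer vector of candidate missing-bp counts
#'   for eroded termini (sampled uniformly).
#' @param tsd_length target-site duplication for integrase events, bp.
#' @param fragment_size min/max sequenced fragment length, bp.
#' @param read_length bp per read.
#' @param wgs_coverage fold coverage for WGS simulation.
#' @param sequencing_error_rate per-base substitution probability.
#' @param reads_per_event amplicon fragments per planted event (TraDIS).
#' @param decoy_rate host-only decoy fragments as a fraction of signal
#'   fragments (TraDIS).
#' @param empty_insert_rate fraction of amplicons with no host insert
#'   (anchor followed directly by splinkerette).
#' @param avoid_microhomology redraw planting sites whose junction flank
#'   would begin with the LTR terminal dinucleotide, keeping ground-truth
#'   junction classes unambiguous.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chromosome_lengths = c(chr1 = 1e6, chr2 = 7e5,
                                              chr3 = 3e5),
                       target_region_fractions = c(exon = 0.04,
                                                   intron = 0.39,
                                                   intergenic = 0.57),
                       n_integrations = 20L,
                       integrase_fraction = 1,
                       truncation_spectrum = 1:200,
                       tsd_length = 5L,
                       fragment_size = c(200L, 400L),
                       read_length = 100L,
                       wgs_coverage = 48,
                       sequencing_error_rate = 0.001,
                       reads_per_event = 20L,
                       decoy_rate = 0.1,
                       empty_insert_rate = 0.02,
                       avoid_microhomology = TRUE) {
  f <- target_region_fractions
  if (length(f) != 3 || any(f < 0) || any(f > 1) ||
      abs(sum(f) - 1) > 1e-9)
    stop("target_region_fractions must be three values in [0,1] summing to 1")
  if (is.null(names(f)) || !identical(names(f),
                                      c("exon", "intron", "intergenic")))
    names(f) <- c("exon", "intron", "intergenic")
  if (is.null(names(chromosome_lengths)))
    names(chromosome_lengths) <-
      paste0("chr", seq_along(chromosome_lengths))
  if (any(chromosome_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (read_length > fragment_size[1])
    stop("read_length must not exceed the minimum fragment size")
  if (n_integrations < 0 || reads_per_event < 0)
    stop("counts must be >= 0")
  if (integrase_fraction < 0 || integrase_fraction > 1)
    stop("integrase_fraction must be in [0,1]")
  if (tsd_length < 0 || tsd_length > 10)
    stop("tsd_length must be in 0..10")
  if (any(truncation_spectrum < 1)) stop("truncation_spectrum must be >= 1")
  structure(list(
    seed = as.integer(seed),
    chromosome_lengths = chromosome_lengths,
    target_region_fractions = f,
    n_integrations = as.integer(n_integrations),
    integrase_fraction = integrase_fraction,
    truncation_spectrum = as.integer(truncation_spectrum),
    tsd_length = as.integer(tsd_length),
    fragment_size = as.integer(fragment_size),
    read_length = as.integer(read_length),
    wgs_coverage = wgs_coverage,
    sequencing_error_rate = sequencing_error_rate,
    reads_per_event = as.integer(reads_per_event),
    decoy_rate = decoy_rate,
    empty_insert_rate = empty_insert_rate,
    avoid_microhomology = isTRUE(avoid_microhomology)),
    class = "sim_config")
}

# sample() that treats a length-1 x as a fixed value, not as 1:x
.sample_from <- function(x, n = 1L) {
  if (length(x) == 1L) rep(x, n) else sample(x, n, replace = TRUE)
}

# Draw one gene structure (relative exon offsets) targeting an in-gene exon
# fraction `f_ex_gene`; returns list(exon_starts, exon_ends, length).
.draw_gene <- function(f_ex_gene) {
  if (f_ex_gene >= 1 - 1e-9) {
    len <- sample(800:2500, 1)
    return(list(starts = 0L, ends = len, length = len))
  }
  m <- sample(6:12, 1)
  exlen <- sample(100:300, m, replace = TRUE)
  intron_total <- round(sum(exlen) * (1 - f_ex_gene) / f_ex_gene)
  w <- runif(m - 1)
  inlen <- floor(w / sum(w) * intron_total)
  inlen[1] <- inlen[1] + (intron_total - sum(inlen))
  starts <- integer(m); ends <- integer(m)
  pos <- 0L
  for (i in seq_len(m)) {
    starts[i] <- pos
    ends[i] <- pos + exlen[i]
    pos <- ends[i] + if (i < m) inlen[i] else 0L
  }
  list(starts = starts, ends = ends, length = ends[m])
}

#' Simulate a host genome with controlled region composition
#'
#' Generates random chromosome sequences and lays out multi-exon gene
#' models so that the realized exon/intron/intergenic bp fractions land
#' within about two percentage points of `target_region_fractions`.
#'
#' @param config a [sim_config()].
#' @return a [genome_ref()].
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  f <- config$target_region_fractions
  f_gene <- f[["exon"]] + f[["intron"]]
  f_ex_gene <- if (f_gene > 0) f[["exon"]] / f_gene else 0
  seqs <- character(0)
  genes <- list()
  gi <- 0L
  for (ci in seq_along(config$chromosome_lengths)) {
    L <- as.integer(config$chromosome_lengths[ci])
    cname <- names(config$chromosome_lengths)[ci]
    seqs[cname] <- random_dna(L)
    gene_target <- round(f_gene * L)
    if (gene_target > 0 && gene_target < 800)
      stop("chromosome ", cname,
           " too short for the requested gene fraction")
    drawn <- list()
    cum <- 0L
    while (cum < gene_target) {
      g <- .draw_gene(f_ex_gene)
      if (cum + g$length > gene_target) {
        # shrink the final gene's span to fit the budget; drop exons that
        # no longer fit
        keep <- g$ends <= (gene_target - cum)
        if (!any(keep)) break
        g$starts <- g$starts[keep]; g$ends <- g$ends[keep]
        g$length <- max(g$ends)
      }
      drawn[[length(drawn) + 1L]] <- g
      cum <- cum + g$length
    }
    ng <- length(drawn)
    if (ng > 0) {
      inter_total <- L - cum
      w <- runif(ng + 1)
      gaps <- floor(w / sum(w) * inter_total)
      gaps[ng + 1L] <- gaps[ng + 1L] + (inter_total - sum(gaps))
      pos <- 0L
      for (i in seq_len(ng)) {
        pos <- pos + gaps[i]
        g <- drawn[[i]]
        gi <- gi + 1L
        genes[[gi]] <- data.frame(
          gene_id = sprintf("gene%05d", gi),
          chromosome = cname,
          strand = sample(c("+", "-"), 1),
          start = pos + g$starts,
          end = pos + g$ends)
        pos <- pos + g$length
      }
    }
  }
  genome_ref(seqs, if (length(genes)) do.call(rbind, genes) else NULL)
}

# Host flanks in read orientation at a junction: f3 is the sequence a
# 3'-end amplicon reads into, f5 the one a 5'-end amplicon reads into.
# `p` is the 0-based insertion offset, `t` the duplicated bp (0 for
# recombination-style events).
.junction_flanks <- function(chrom_seq, p, t, orientation, width = 10L) {
  left <- substr(chrom_seq, max(1L, p - width + 1L), p)           # ...| p
  right <- substr(chrom_seq, p - t + 1L, p - t + width)           # p-t |...
  if (orientation == "+")
    list(f3 = right, f5 = revcomp(left))
  else
    list(f3 = revcomp(left), f5 = right)
}

#' Plant proviruses into a host genome
#'
#' Integrase-style events insert the full provirus flanked by a
#' `tsd_length` target-site duplication and keep the terminal TG...CA
#' dinucleotides intact; recombination-style events erode both termini by
#' draws from `truncation_spectrum` and create no duplication. Events are
#' spaced at least one fragment length apart (bounded redraws). Insertion
#' proceeds right-to-left so truth positions stay in reference coordinates.
#'
#' @param genome a [genome_ref()] (the reference the calls will be made
#'   against).
#' @param provirus a [provirus_ref()].
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed + 1`.
#' @return list with `genome` (modified sequences; gene annotation is
#'   dropped because insertions shift coordinates) and `truth`, a
#'   data.frame with one row per event: `chromosome`, `position` (0-based
#'   insertion offset in reference coordinates), `orientation`,
#'   `completeness`, `missing_5`, `missing_3`, `tsd`.
#' @export
plant_integrations <- function(genome, provirus, config,
                               seed = config$seed + 1L) {
  stopifnot(inherits(genome, "genome_ref"),
            inherits(provirus, "provirus_ref"),
            inherits(config, "sim_config"))
  n <- config$n_integrations
  empty_truth <- data.frame(
    chromosome = character(), position = numeric(),
    orientation = character(), completeness = character(),
    missing_5 = integer(), missing_3 = integer(), tsd = integer())
  if (n == 0)
    return(list(genome = genome, truth = empty_truth))
  set.seed(seed)
  min_sep <- 2L * config$fragment_size[2]
  margin <- config$fragment_size[2] + 100L
  lens <- genome$lengths
  if (any(2 * margin + min_sep > lens) && n > 0)
    lens <- lens[2 * margin + min_sep <= lens]
  if (!length(lens)) stop("no chromosome long enough for planting")
  picked <- data.frame(chromosome = character(n), position = numeric(n))
  truth <- vector("list", n)
  tries <- 0L
  i <- 1L
  while (i <= n) {
    tries <- tries + 1L
    if (tries > 200L * n)
      stop("could not place ", n, " events with the required spacing")
    chrom <- sample(names(lens), 1, prob = lens)
    p <- sample.int(lens[[chrom]] - 2L * margin, 1) + margin
    same <- picked$chromosome[seq_len(i - 1L)] == chrom
    if (any(same) &&
        min(abs(picked$position[seq_len(i - 1L)][same] - p)) < min_sep)
      next
    integrase <- runif(1) < config$integrase_fraction
    if (integrase) {
      m5 <- 0L; m3 <- 0L; t <- config$tsd_length
      completeness <- "full"
    } else {
      m5 <- .sample_from(config$truncation_spectrum)
      m3 <- .sample_from(config$truncation_spectrum)
      t <- 0L
      completeness <- if (m5 >= m3) "truncated_5" else "truncated_3"
    }
    orientation <- sample(c("+", "-"), 1)
    if (config$avoid_microhomology) {
      fl <- .junction_flanks(genome$sequences[[chrom]], p, t, orientation,
                             width = 4L)
      if (startsWith(fl$f3, "CA") || startsWith(fl$f5, "CA")) next
    }
    picked$chromosome[i] <- chrom
    picked$position[i] <- p
    truth[[i]] <- data.frame(
      chromosome = chrom, position = p, orientation = orientation,
      completeness = completeness, missing_5 = m5, missing_3 = m3, tsd = t)
    i <- i + 1L
  }
  truth <- do.call(rbind, truth)
  pseq <- provirus$sequence
  plen <- nchar(pseq)
  seqs <- genome$sequences
  for (chrom in unique(truth$chromosome)) {
    tt <- truth[truth$chromosome == chrom, , drop = FALSE]
    tt <- tt[order(-tt$position), , drop = FALSE]
    s <- seqs[[chrom]]
    for (j in seq_len(nrow(tt))) {
      p <- tt$position[j]
      ins <- substr(pseq, tt$missing_5[j] + 1L, plen - tt$missing_3[j])
      if (tt$orientation[j] == "-") ins <- revcomp(ins)
      t <- tt$tsd[j]
      s <- paste0(substr(s, 1L, p), ins, substr(s, p - t + 1L, nchar(s)))
    }
    seqs[[chrom]] <- s
  }
  truth <- truth[order(truth$chromosome, truth$position), ]
  rownames(truth) <- NULL
  list(genome = genome_ref(seqs), truth = truth)
}

# inject substitution errors at `rate` per base; error positions get
# quality '+' (Q10), everything else 'F' (Q37)
.with_errors <- function(seqs, rate) {
  n <- length(seqs)
  lens <- nchar(seqs)
  quals <- strrep("F", lens)
  if (rate <= 0 || n == 0)
    return(list(seq = seqs, qual = quals))
  nerr <- rbinom(n, lens, rate)
  hit <- which(nerr > 0)
  if (!length(hit)) return(list(seq = seqs, qual = quals))
  idx <- rep(hit, nerr[hit])
  pos <- ceiling(runif(length(idx)) * lens[idx])
  bases <- c("A", "C", "G", "T")
  old <- substr(seqs[idx], pos, pos)
  shift <- sample.int(3L, length(idx), replace = TRUE)
  nb <- bases[((match(old, bases) - 1L + shift) %% 4L) + 1L]
  nb[is.na(nb)] <- "N"   # leave non-ACGT (N) bases alone conceptually
  # multiple errors in one read are applied in rounds so none is lost to
  # duplicated-index assignment
  rnd <- stats::ave(seq_along(idx), idx, FUN = seq_along)
  for (r in seq_len(max(rnd))) {
    s <- rnd == r
    x <- seqs[idx[s]]
    substr(x, pos[s], pos[s]) <- nb[s]
    seqs[idx[s]] <- x
    q <- quals[idx[s]]
    substr(q, pos[s], pos[s]) <- "+"
    quals[idx[s]] <- q
  }
  list(seq = seqs, qual = quals)
}

#' Simulate an LTR-anchored (TraDIS-style) amplicon library
#'
#' Signal amplicons begin exactly at the library's LTR anchor (eroded
#' termini shorten the anchor portion accordingly; events whose erosion
#' removes the whole anchor region are invisible to the library) and extend
#' into flanking host sequence; the far end carries the splinkerette
#' adapter. Paired `read_length` reads are drawn from both fragment ends,
#' so fragments shorter than twice the read length yield overlapping
#' mates. Host-only decoy fragments and empty-insert (anchor +
#' splinkerette) artifacts are mixed in at configured rates.
#'
#' @param genome the reference [genome_ref()] (pre-insertion coordinates).
#' @param truth truth table from [plant_integrations()].
#' @param provirus a [provirus_ref()].
#' @param config a [sim_config()].
#' @param which_end 5 or 3: which LTR-end library to simulate.
#' @param seed RNG seed; defaults to `config$seed + 2 + which_end`.
#' @return data.frame of read pairs: `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`, `origin` (event row index, 0 for decoys, -1 for empty
#'   inserts).
#' @export
simulate_tradis_reads <- function(genome, truth, provirus, config,
                                  which_end = 3L,
                                  seed = config$seed + 2L + as.integer(which_end)) {
  stopifnot(which_end %in% c(3L, 5L))
  set.seed(seed)
  rl <- config$read_length
  anchor <- if (which_end == 3L) provirus$anchor_3 else provirus$anchor_5
  alen <- nchar(anchor)
  amps <- character(0)
  origin <- integer(0)
  if (nrow(truth) > 0) {
    for (e in seq_len(nrow(truth))) {
      tr <- truth[e, ]
      missing <- if (which_end == 3L) tr$missing_3 else tr$missing_5
      if (missing >= alen) next        # primer/anchor region destroyed
      anchor_part <- substr(anchor, 1L, alen - missing)
      chrom_seq <- genome$sequences[[tr$chromosome]]
      p <- tr$position
      t <- tr$tsd
      for (k in seq_len(config$reads_per_event)) {
        F <- .sample_from(config$fragment_size[1]:config$fragment_size[2])
        hostlen <- max(F - nchar(anchor_part), 20L)
        fwd_from_right <- (which_end == 3L) == (tr$orientation == "+")
        flank <- if (fwd_from_right)
          substr(chrom_seq, p - t + 1L, p - t + hostlen)
        else
          revcomp(substr(chrom_seq, p - hostlen + 1L, p))
        amps <- c(amps, paste0(anchor_part, flank))
        origin <- c(origin, e)
      }
    }
  }
  n_signal <- length(amps)
  n_decoy <- round(config$decoy_rate * n_signal)
  if (n_decoy > 0) {
    chroms <- sample(names(genome$lengths), n_decoy, replace = TRUE,
                     prob = genome$lengths)
    for (d in seq_len(n_decoy)) {
      F <- .sample_from(config$fragment_size[1]:config$fragment_size[2])
      s <- sample.int(genome$lengths[[chroms[d]]] - F, 1)
      amps <- c(amps, substr(genome$sequences[[chroms[d]]], s, s + F - 1L))
      origin <- c(origin, 0L)
    }
  }
  n_empty <- round(config$empty_insert_rate * n_signal)
  if (n_empty > 0) {
    amps <- c(amps, rep(anchor, n_empty))
    origin <- c(origin, rep(-1L, n_empty))
  }
  if (!length(amps))
    return(data.frame(id = character(), seq1 = character(),
                      qual1 = character(), seq2 = character(),
                      qual2 = character(), origin = integer()))
  template <- paste0(amps, SPLINKERETTE)
  r1 <- substr(template, 1L, rl)
  r2 <- substr(revcomp(amps), 1L, rl)
  e1 <- .with_errors(r1, config$sequencing_error_rate)
  e2 <- .with_errors(r2, config$sequencing_error_rate)
  data.frame(
    id = sprintf("tradis%d_%06d_e%d", which_end, seq_along(amps), origin),
    seq1 = e1$seq, qual1 = e1$qual, seq2 = e2$seq, qual2 = e2$qual,
    origin = origin)
}

#' Simulate whole-genome shotgun read pairs
#'
#' Uniform paired sampling from the (modified) genome at
#' `config$wgs_coverage` fold; fragment lengths are uniform over
#' `config$fragment_size`. Junction-spanning (partial), junction-straddling
#' (independent) and provirus-internal (virus-only) pairs arise from the
#' geometry of the planted insertions.
#'
#' @param genome the modified [genome_ref()] to sequence.
#' @param config a [sim_config()].
#' @param coverage fold coverage; defaults to `config$wgs_coverage`.
#' @param seed RNG seed; defaults to `config$seed + 10`.
#' @return data.frame of read pairs `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
simulate_wgs_reads <- function(genome, config,
                               coverage = config$wgs_coverage,
                               seed = config$seed + 10L) {
  stopifnot(coverage > 0)
  set.seed(seed)
  rl <- config$read_length
  G <- sum(genome$lengths)
  npairs <- round(coverage * G / (2 * rl))
  chrom <- sample(names(genome$lengths), npairs, replace = TRUE,
                  prob = genome$lengths)
  F <- .sample_from(config$fragment_size[1]:config$fragment_size[2], npairs)
  seq1 <- character(npairs)
  seq2 <- character(npairs)
  for (cn in unique(chrom)) {
    j <- which(chrom == cn)
    L <- genome$lengths[[cn]]
    s <- floor(runif(length(j), 1, L - F[j] + 1))
    seq1[j] <- substring(genome$sequences[[cn]], s, s + rl - 1L)
    seq2[j] <- revcomp(substring(genome$sequences[[cn]], s + F[j] - rl,
                                 s + F[j] - 1L))
  }
  e1 <- .with_errors(seq1, config$sequencing_error_rate)
  e2 <- .with_errors(seq2, config$sequencing_error_rate)
  data.frame(id = sprintf("wgs_%07d", seq_len(npairs)),
             seq1 = e1$seq, qual1 = e1$qual,
             seq2 = e2$seq, qual2 = e2$qual)
}

#' Simulate a WGS pool of distinct nuclei
#'
#' Emulates the mosaic structure of integration in a multicellular sample:
#' `n_nuclei` genomes are planted independently (each with
#' `config$n_integrations` events, the per-nucleus burden) and sequenced so
#' the pooled coverage reaches `config$wgs_coverage`. The default pool size
#' equals the number of diploid-genome-equivalents the run samples
#' (coverage / 4 for 100-bp pairs), the regime in which every planted
#' provirus is recoverable; see the methods vignette for why.
#'
#' @param genome the reference [genome_ref()].
#' @param provirus a [provirus_ref()].
#' @param config a [sim_config()]; `n_integrations` is per nucleus.
#' @param n_nuclei distinct genomes in the pool.
#' @param seed base RNG seed; defaults to `config$seed`.
#' @return list with `reads` (pooled pairs) and `truth` (all events, with
#'   a `nucleus` column).
#' @export
simulate_wgs_pool <- function(genome, provirus, config,
                              n_nuclei = max(1L, round(config$wgs_coverage / 4)),
                              seed = config$seed) {
  reads <- vector("list", n_nuclei)
  truth <- vector("list", n_nuclei)
  per_cov <- config$wgs_coverage / n_nuclei
  for (i in seq_len(n_nuclei)) {
    pl <- plant_integrations(genome, provirus, config,
                             seed = seed + 101L * i)
    rd <- simulate_wgs_reads(pl$genome, config, coverage = per_cov,
                             seed = seed + 101L * i + 50L)
    rd$id <- paste0("n", i, "_", rd$id)
    reads[[i]] <- rd
    if (nrow(pl$truth)) pl$truth$nucleus <- i
    truth[[i]] <- pl$truth
  }
  list(reads = do.call(rbind, reads), truth = do.call(rbind, truth))
}
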