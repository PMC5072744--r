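# Chimeric-read detection in whole-genome sequencing and the per-nucleus
# integration-burden estimator with exact (Clopper-Pearson) confidence
# intervals.

#' Categorize WGS read pairs by joint host/provirus placement
#'
#' Three evidence categories: `partial` — one read splits into a host part
#' and a provirus part in complementary query spans (the junction lies
#' inside the read); `independent` — one mate maps only to host, the other
#' only to provirus; `virus_only` — both mates map to provirus. Host-only
#' pairs are dropped. A provirus-side match counts only when it beats any
#' host placement of the same read by score, which suppresses false
#' positives from host elements resembling the provirus.
#'
#' @param aln1,aln2 [map_reads()] results for mate 1 and mate 2 of each
#'   pair (`read` column = pair index).
#' @param min_split minimum bp on each side of a split, and minimum
#'   provirus match, bp.
#' @param max_gap maximum gap/overlap between the two parts of a split
#'   read, bp.
#' @param min_mapq minimum mapping quality for the host side of evidence.
#' @return data.frame: `pair`, `category`, and for partial pairs the
#'   junction `chromosome`/`position` (0-based first host base adjacent to
#'   the virus side), for independent pairs the host-side
#'   `chromosome`/`h_start`/`h_end`.
#' @export
categorize_read_pairs <- function(aln1, aln2, min_split = 20L,
                                  max_gap = 8L, min_mapq = 30L) {
  pick <- function(aln) {
    host <- aln[aln$reference != "provirus", , drop = FALSE]
    host <- host[order(-host$score), , drop = FALSE]
    host <- host[!duplicated(host$read), , drop = FALSE]
    prov <- aln[aln$reference == "provirus", , drop = FALSE]
    prov <- prov[order(-prov$score), , drop = FALSE]
    prov <- prov[!duplicated(prov$read), , drop = FALSE]
    list(host = host, prov = prov)
  }
  m1 <- pick(aln1); m2 <- pick(aln2)
  # only pairs with provirus-side evidence can fall in a category;
  # everything else is host-only and dropped
  pairs <- sort(unique(c(m1$prov$read, m2$prov$read)))
  if (!length(pairs))
    return(data.frame(pair = integer(), category = character(),
                      chromosome = character(), position = numeric(),
                      h_start = numeric(), h_end = numeric()))
  col <- function(df, what, idx) df[[what]][idx]
  mate <- function(m) {
    hi <- match(pairs, m$host$read)
    pi <- match(pairs, m$prov$read)
    hok <- !is.na(hi); pok <- !is.na(pi)
    g <- function(df, what, idx) {
      v <- df[[what]][idx]
      v
    }
    list(hok = hok, pok = pok,
         h_matched = g(m$host, "matched", hi),
         h_qstart = g(m$host, "qstart", hi),
         h_qend = g(m$host, "qend", hi),
         h_start = g(m$host, "start", hi),
         h_end = g(m$host, "end", hi),
         h_strand = g(m$host, "strand", hi),
         h_ref = g(m$host, "reference", hi),
         h_score = g(m$host, "score", hi),
         h_best = g(m$host, "best", hi),
         h_mapq = g(m$host, "mapq", hi),
         p_matched = g(m$prov, "matched", pi),
         p_qstart = g(m$prov, "qstart", pi),
         p_qend = g(m$prov, "qend", pi),
         p_score = g(m$prov, "score", pi))
  }
  a <- mate(m1); b <- mate(m2)
  split_of <- function(x) {
    ok <- x$hok & x$pok &
      !is.na(x$h_matched) & x$h_matched >= min_split &
      !is.na(x$p_matched) & x$p_matched >= min_split
    host_first <- ok & abs(x$p_qstart - x$h_qend) <= max_gap
    host_last <- ok & abs(x$h_qstart - x$p_qend) <= max_gap
    is_split <- host_first | host_last
    is_split[is.na(is_split)] <- FALSE
    bnd <- ifelse(host_first,
                  ifelse(x$h_strand == "+", x$h_end - 1, x$h_start),
                  ifelse(x$h_strand == "+", x$h_start, x$h_end - 1))
    list(is_split = is_split, bnd = bnd)
  }
  sa <- split_of(a); sb <- split_of(b)
  prov_only <- function(x) {
    v <- x$pok & !is.na(x$p_matched) & x$p_matched >= min_split &
      (!x$hok | x$p_score > ifelse(is.na(x$h_score), -Inf, x$h_score))
    v[is.na(v)] <- FALSE
    v
  }
  host_only <- function(x) {
    v <- x$hok & !is.na(x$h_best) & x$h_best & x$h_mapq >= min_mapq &
      (!x$pok | ifelse(is.na(x$h_score), -Inf, x$h_score) >=
         ifelse(is.na(x$p_score), Inf, x$p_score) + min_split)
    v[is.na(v)] <- FALSE
    v
  }
  poa <- prov_only(a); pob <- prov_only(b)
  hoa <- host_only(a); hob <- host_only(b)
  partial <- sa$is_split | sb$is_split
  virus_only <- !partial & poa & pob
  indep <- !partial & !virus_only & ((hoa & pob) | (hob & poa))
  cat_chr <- ifelse(partial, ifelse(sa$is_split, a$h_ref, b$h_ref),
                    ifelse(indep, ifelse(hoa, a$h_ref, b$h_ref),
                           NA_character_))
  out <- data.frame(
    pair = pairs,
    category = ifelse(partial, "partial",
                      ifelse(virus_only, "virus_only",
                             ifelse(indep, "independent", NA_character_))),
    chromosome = cat_chr,
    position = ifelse(partial, ifelse(sa$is_split, sa$bnd, sb$bnd),
                      NA_real_),
    h_start = ifelse(indep, ifelse(hoa, a$h_start, b$h_start), NA_real_),
    h_end = ifelse(indep, ifelse(hoa, a$h_end, b$h_end), NA_real_))
  out <- out[!is.na(out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# single-linkage 1-d clustering; returns representative (minimum) position
# per cluster
.chain_positions <- function(chromosome, position, radius) {
  d <- data.frame(chromosome, position)
  d <- d[order(d$chromosome, d$position), , drop = FALSE]
  reps <- list()
  for (chrom in unique(d$chromosome)) {
    p <- d$position[d$chromosome == chrom]
    cid <- cumsum(c(TRUE, diff(p) > radius))
    reps[[chrom]] <- data.frame(
      chromosome = chrom,
      position = as.numeric(tapply(p, cid, min)))
  }
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  out
}

#' Count integration events from pair categories
#'
#' Partial junctions are deduplicated by single-linkage chaining at
#' `merge_radius`; independent pairs are chained the same way and, by
#' default, an independent event within one insert length of a counted
#' partial junction is suppressed as re-evidence of the same provirus.
#' Virus-only pairs contribute no events. The count is invariant to read
#' order and to duplicated category entries.
#'
#' @param categories data.frame from [categorize_read_pairs()].
#' @param merge_radius bp for junction deduplication.
#' @param suppress_independent drop independent events near partial
#'   junctions (set `FALSE` for purely additive counting).
#' @param suppression_radius bp; defaults to `merge_radius`.
#' @return list of class `wgs_counts`: `x` (total events), `n_partial`,
#'   `n_independent`, `n_virus_only_pairs`, and the partial-event
#'   positions.
#' @export
count_integrations <- function(categories, merge_radius = 400L,
                               suppress_independent = TRUE,
                               suppression_radius = merge_radius) {
  part <- categories[categories$category == "partial", , drop = FALSE]
  indep <- categories[categories$category == "independent", , drop = FALSE]
  nvir <- sum(categories$category == "virus_only")
  part_ev <- if (nrow(part))
    .chain_positions(part$chromosome, part$position, merge_radius)
  else data.frame(chromosome = character(), position = numeric())
  n_indep <- 0L
  if (nrow(indep)) {
    mid <- (indep$h_start + indep$h_end) / 2
    ind_ev <- .chain_positions(indep$chromosome, mid, merge_radius)
    if (suppress_independent && nrow(part_ev)) {
      keep <- vapply(seq_len(nrow(ind_ev)), function(i) {
        same <- part_ev$chromosome == ind_ev$chromosome[i]
        !any(same) ||
          min(abs(part_ev$position[same] - ind_ev$position[i])) >
          suppression_radius
      }, TRUE)
      ind_ev <- ind_ev[keep, , drop = FALSE]
    }
    n_indep <- nrow(ind_ev)
  }
  structure(list(x = nrow(part_ev) + n_indep,
                 n_partial = nrow(part_ev),
                 n_independent = n_indep,
                 n_virus_only_pairs = nvir,
                 partial_positions = part_ev),
            class = "wgs_counts")
}

#' @export
print.wgs_counts <- function(x, ...) {
  cat("wgs_counts: x =", x$x, "(", x$n_partial, "partial +",
      x$n_independent, "independent;", x$n_virus_only_pairs,
      "virus-only pairs )\n")
  invisible(x)
}

#' Sequenced segments per diploid genome
#'
#' The number of read-length segments a diploid genome contributes:
#' `S = 2 * sum(lengths) / read_length`.
#'
#' @param lengths chromosome assembly lengths, bp.
#' @param read_length bp.
#' @return S (real-valued).
#' @export
segments_per_diploid_genome <- function(lengths, read_length = 100) {
  if (read_length <= 0) stop("read_length must be > 0")
  if (any(lengths <= 0)) stop("lengths must be > 0")
  2 * sum(as.numeric(lengths)) / read_length
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Computed through the incomplete-beta inverse, equivalent to inverting
#' the binomial tail probabilities.
#'
#' @param x successes.
#' @param n trials.
#' @param conf confidence level.
#' @return c(lower, upper) for the success probability.
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  if (n <= 0 || x < 0 || x > n) stop("need 0 <= x <= n, n > 0")
  a <- 1 - conf
  lo <- if (x == 0) 0 else qbeta(a / 2, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a / 2, x + 1, n - x)
  c(lo, hi)
}

#' Per-nucleus integration-burden estimate
#'
#' Scales the per-segment integration proportion `x / R` by the number of
#' segments per diploid genome: `per_nucleus = x * S / R`, with an exact
#' Clopper-Pearson interval on `x / R` scaled the same way, and a
#' per-organism extrapolation.
#'
#' @param x detected integrations.
#' @param R properly paired read-pair total (sequenced segments).
#' @param S segments per diploid genome, from
#'   [segments_per_diploid_genome()].
#' @param confidence CI level.
#' @param nuclei_per_organism nuclei per organism for the extrapolation.
#' @return object of class `wgs_estimate`: `x`, `R`, `S`, `per_nucleus`,
#'   `ci`, `confidence`, `per_organism`, `ci_organism`,
#'   `nuclei_per_organism`.
#' @export
per_nucleus_estimate <- function(x, R, S, confidence = 0.95,
                                 nuclei_per_organism = 1000) {
  if (R <= 0) stop("R must be > 0")
  if (S <= 0) stop("S must be > 0")
  if (x < 0 || x > R) stop("need 0 <= x <= R")
  ci <- clopper_pearson(x, R, confidence) * S
  est <- structure(list(
    x = x, R = R, S = S,
    per_nucleus = x * S / R,
    ci = ci, confidence = confidence,
    nuclei_per_organism = nuclei_per_organism,
    per_organism = x * S / R * nuclei_per_organism,
    ci_organism = ci * nuclei_per_organism),
    class = "wgs_estimate")
  est
}

#' @export
print.wgs_estimate <- function(x, ...) {
  cat(sprintf(
    "wgs_estimate: %.1f integrations per nucleus (%.0f%% CI %.1f-%.1f)\n",
    x$per_nucleus, 100 * x$confidence, x$ci[1], x$ci[2]))
  cat(sprintf("  x = %d events in R = %s pairs; S = %s segments/diploid\n",
              x$x, format(x$R, big.mark = ","),
              format(round(x$S), big.mark = ",")))
  cat(sprintf("  ~%s per organism (%s nuclei)\n",
              format(round(x$per_organism), big.mark = ","),
              format(x$nuclei_per_organism, big.mark = ",")))
  invisible(x)
}

#' Nuclei represented in a DNA mass
#'
#' @param dna_mass_ng input DNA mass, ng.
#' @param diploid_genome_mass_pg mass of one diploid genome, pg.
#' @return nucleus count.
#' @export
nuclei_from_mass <- function(dna_mass_ng, diploid_genome_mass_pg = 0.79) {
  if (dna_mass_ng <= 0) stop("mass must be > 0")
  if (diploid_genome_mass_pg <= 0) stop("genome mass must be > 0")
  dna_mass_ng * 1000 / diploid_genome_mass_pg
}

#' Per-organism integration count
#'
#' @param estimate a [per_nucleus_estimate()] result.
#' @param nuclei_per_organism nuclei per organism.
#' @return list `value` and `ci` (both scaled from the per-nucleus
#'   estimate).
#' @export
per_organism <- function(estimate, nuclei_per_organism = 1000) {
  stopifnot(inherits(estimate, "wgs_estimate"))
  list(value = estimate$per_nucleus * nuclei_per_organism,
       ci = estimate$ci * nuclei_per_organism)
}
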