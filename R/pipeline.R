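# End-to-end orchestration: simulate -> prep -> align -> call -> annotate
# -> report, with a checksummed manifest for reproducibility.

#' Run one LTR-anchored library end to end
#'
#' Simulates (or accepts) a read set, preps it, maps the host flanks
#' against host + provirus, applies the authenticity criteria,
#' deduplicates, and clusters.
#'
#' @param genome reference [genome_ref()].
#' @param provirus a [provirus_ref()].
#' @param truth truth table from [plant_integrations()].
#' @param config a [sim_config()].
#' @param which_end 5 or 3.
#' @param params a [filter_params()].
#' @param index optional prebuilt [build_index()] (host + provirus).
#' @param pairs optional read-pair table; simulated from `truth` when
#'   missing.
#' @return list: `pairs`, `prepped`, `alignments`, `calls`, `unique`,
#'   `clusters`, `summary`.
#' @export
run_tradis_library <- function(genome, provirus, truth, config,
                               which_end = 3L, params = filter_params(),
                               index = NULL, pairs = NULL) {
  if (is.null(pairs))
    pairs <- simulate_tradis_reads(genome, truth, provirus, config,
                                   which_end)
  prepped <- prep_tradis_reads(pairs, provirus, which_end, params)
  if (is.null(index)) index <- build_index(genome, provirus)
  aln <- map_reads(index, prepped$host_sequence)
  calls <- call_sites(prepped, aln, params, provirus)
  uniq <- dedup_and_unique(calls)
  clusters <- cluster_positions(uniq, params$cluster_radius)
  list(pairs = pairs, prepped = prepped, alignments = aln, calls = calls,
       unique = uniq, clusters = clusters,
       summary = library_summary(calls, uniq, clusters))
}

#' Run a WGS burden experiment end to end
#'
#' Simulates a pool of nuclei carrying the configured per-nucleus burden,
#' maps all reads against host + provirus, categorizes pairs, counts
#' events, and returns the per-nucleus estimate with its exact CI.
#'
#' @param genome reference [genome_ref()].
#' @param provirus a [provirus_ref()].
#' @param config a [sim_config()]; `n_integrations` is the per-nucleus
#'   burden.
#' @param n_nuclei distinct nuclei in the pool; the default (coverage / 4)
#'   matches the number of diploid-genome-equivalents sequenced.
#' @param params a [filter_params()]; supplies `max_insert`.
#' @param index optional prebuilt [build_index()].
#' @param seed base RNG seed; defaults to `config$seed`.
#' @return list: `truth`, `categories`, `counts`, `R`, `S`, `estimate`.
#' @export
run_wgs_experiment <- function(genome, provirus, config,
                               n_nuclei = max(1L, round(config$wgs_coverage / 4)),
                               params = filter_params(), index = NULL,
                               seed = config$seed) {
  pool <- simulate_wgs_pool(genome, provirus, config, n_nuclei, seed)
  if (is.null(index)) index <- build_index(genome, provirus)
  aln1 <- map_reads(index, pool$reads$seq1, max_candidates = 8L)
  aln2 <- map_reads(index, pool$reads$seq2, max_candidates = 8L)
  categories <- categorize_read_pairs(aln1, aln2)
  counts <- count_integrations(categories,
                               merge_radius = config$fragment_size[2],
                               suppression_radius = params$max_insert)
  R <- .properly_paired_count(aln1, aln2, params$max_insert)
  S <- segments_per_diploid_genome(genome$lengths, config$read_length)
  est <- per_nucleus_estimate(counts$x, R, S)
  list(truth = pool$truth, categories = categories, counts = counts,
       R = R, S = S, estimate = est)
}

#' Full pipeline configuration
#'
#' @param outdir output directory.
#' @param sim a [sim_config()].
#' @param params a [filter_params()].
#' @param ends which library ends to run.
#' @param run_wgs also run the WGS burden experiment.
#' @param genome_fasta optional path to an existing host genome FASTA (with
#'   `annotation_gff`); when `NULL` a genome is simulated.
#' @param annotation_gff optional gene annotation for `genome_fasta`.
#' @param provirus_fasta optional provirus FASTA (single record); when
#'   `NULL` a synthetic provirus is used.
#' @param ltr_length LTR length for a provirus read from FASTA.
#' @return list of class `run_config`.
#' @export
run_config <- function(outdir, sim = sim_config(), params = filter_params(),
                       ends = c(5L, 3L), run_wgs = FALSE,
                       genome_fasta = NULL, annotation_gff = NULL,
                       provirus_fasta = NULL, ltr_length = 634L) {
  structure(list(outdir = outdir, sim = sim, params = params,
                 ends = as.integer(ends), run_wgs = isTRUE(run_wgs),
                 genome_fasta = genome_fasta,
                 annotation_gff = annotation_gff,
                 provirus_fasta = provirus_fasta,
                 ltr_length = as.integer(ltr_length)),
            class = "run_config")
}

#' Execute the full pipeline
#'
#' simulate -> prep -> align -> call -> annotate -> report. Every output
#' file is listed in `manifest.json` with an md5 checksum; with a fixed
#' seed the outputs (and hence the manifest's checksums) are reproducible
#' bit for bit.
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  if (!is.null(config$genome_fasta)) {
    if (!file.exists(config$genome_fasta))
      stop("genome FASTA not found: ", config$genome_fasta)
    seqs <- read_fasta(config$genome_fasta)
    genes <- if (!is.null(config$annotation_gff))
      read_gff(config$annotation_gff) else NULL
    genome <- genome_ref(seqs, genes)
  } else {
    genome <- simulate_genome(config$sim)
  }
  provirus <- if (!is.null(config$provirus_fasta)) {
    s <- read_fasta(config$provirus_fasta)
    if (length(s) != 1) stop("provirus FASTA must hold a single record")
    provirus_ref(unname(s), config$ltr_length)
  } else {
    synthetic_provirus(seed = config$sim$seed)
  }
  write_fasta(genome$sequences, out("genome.fa"))
  if (nrow(genome$genes)) write_gff3(genome$genes, out("genes.gff3"))
  write_fasta(c(provirus = provirus$sequence), out("provirus.fa"))

  planted <- plant_integrations(genome, provirus, config$sim)
  truth_bed <- data.frame(chromosome = planted$truth$chromosome,
                          position = planted$truth$position,
                          junction_class = planted$truth$completeness,
                          support = 0L,
                          strand = planted$truth$orientation)
  write_calls_bed(truth_bed, out("truth.bed"))

  index <- build_index(genome, provirus)
  rate_counts <- list(`5` = integer(0), `3` = integer(0))
  all_clusters <- list()
  for (end in config$ends) {
    res <- run_tradis_library(genome, provirus, planted$truth, config$sim,
                              which_end = end, params = config$params,
                              index = index)
    write_calls_bed(res$unique, out(sprintf("unique_positions_%d.bed", end)))
    write_tsv_file(as.data.frame(res$clusters),
                   out(sprintf("clusters_%d.tsv", end)))
    write_tsv_file(res$summary, out(sprintf("library_summary_%d.tsv", end)))
    tab <- table(res$clusters$chromosome)
    rate_counts[[as.character(end)]] <-
      setNames(as.integer(tab), names(tab))
    all_clusters[[as.character(end)]] <- res$clusters
  }
  rates <- rate_table(rate_counts[["5"]], rate_counts[["3"]], genome)
  write_rates_tsv(rates, out("rates.tsv"))

  comp <- genome_composition(genome)
  cl <- do.call(rbind, lapply(all_clusters, function(x)
    data.frame(chromosome = x$chromosome, position = x$representative)))
  region <- if (!is.null(cl) && nrow(cl)) classify_sites(cl, genome)
  else list(counts = c(exon = 0L, intron = 0L, intergenic = 0L),
            n_sites = 0L)
  bias_p <- if (region$n_sites > 0)
    noncoding_bias_test(region$counts[["intergenic"]], region$n_sites,
                        comp[["intergenic"]])
  else NA_real_
  region_out <- list(genome_fractions = as.list(comp),
                     site_counts = as.list(region$counts),
                     n_sites = region$n_sites,
                     p_noncoding_bias = bias_p)
  jsonlite::write_json(region_out, out("region_stats.json"),
                       auto_unbox = TRUE, digits = NA)

  if (config$run_wgs) {
    wgs <- run_wgs_experiment(genome, provirus, config$sim,
                              params = config$params, index = index)
    est <- wgs$estimate
    jsonlite::write_json(
      list(x = est$x, R = est$R, S = est$S,
           per_nucleus = est$per_nucleus,
           ci = as.numeric(est$ci),
           per_organism = est$per_organism),
      out("wgs_estimate.json"), auto_unbox = TRUE, digits = NA)
  }

  files <- setdiff(list.files(config$outdir), "manifest.json")
  manifest <- list(
    package = "ltrsites",
    version = as.character(utils::packageVersion("ltrsites")),
    seed = config$sim$seed,
    parameters = list(
      sim = config$sim[setdiff(names(config$sim), NULL)],
      filter = unclass(config$params),
      ends = config$ends, run_wgs = config$run_wgs),
    outputs = lapply(setNames(files, files), function(f)
      list(md5 = unname(tools::md5sum(out(f))))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
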