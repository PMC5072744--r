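test_that("simulated genome composition lands on the target fractions", {
  g <- small_genome()  # targets 4% exon / 39% intron / 57% intergenic
  comp <- genome_composition(g)
  expect_true(all(abs(comp - c(0.04, 0.39, 0.57)) <= 0.02))
  expect_equal(sum(comp), 1, tolerance = 1e-9)
})

test_that("all-intergenic config yields no gene models; same seed, same genome", {
  cfg <- sim_config(seed = 3, chromosome_lengths = c(c1 = 5e4),
                    target_region_fractions = c(0, 0, 1))
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$genes), 0L)
  g2 <- simulate_genome(cfg)
  expect_identical(g$sequences, g2$sequences)
  g3 <- simulate_genome(sim_config(seed = 4,
                                   chromosome_lengths = c(c1 = 5e4),
                                   target_region_fractions = c(0, 0, 1)))
  expect_false(identical(g$sequences, g3$sequences))
})

test_that("integrase events insert the full TG...CA provirus with a TSD", {
  cfg <- sim_config(seed = 11, chromosome_lengths = c(c1 = 2e5),
                    target_region_fractions = c(0, 0, 1),
                    n_integrations = 6, integrase_fraction = 1)
  g <- simulate_genome(cfg)
  pv <- small_provirus()
  pl <- plant_integrations(g, pv, cfg)
  tr <- pl$truth
  expect_equal(nrow(tr), 6L)
  expect_true(all(tr$completeness == "full"))
  expect_true(all(tr$missing_5 == 0 & tr$missing_3 == 0))
  # truth/modified-genome consistency: walking events left to right, each
  # junction in the modified sequence must reproduce the expected strings
  plen <- nchar(pv$sequence)
  shift <- 0
  mod <- pl$genome$sequences[["c1"]]
  orig <- g$sequences[["c1"]]
  for (i in seq_len(nrow(tr))) {
    p <- tr$position[i] + shift
    ins <- if (tr$orientation[i] == "+") pv$sequence else revcomp(pv$sequence)
    expect_identical(substr(mod, p + 1, p + plen), ins)
    # target-site duplication: tsd bases before the insert reappear after
    tsd <- tr$tsd[i]
    expect_identical(substr(mod, p - tsd + 1, p),
                     substr(mod, p + plen + 1, p + plen + tsd))
    shift <- shift + plen + tsd
  }
  # positions on the reference stay untouched before each event
  expect_identical(substr(mod, 1, tr$position[1]),
                   substr(orig, 1, tr$position[1]))
})

test_that("recombination-style events erode both termini and leave no TSD", {
  cfg <- sim_config(seed = 12, chromosome_lengths = c(c1 = 2e5),
                    target_region_fractions = c(0, 0, 1),
                    n_integrations = 5, integrase_fraction = 0,
                    truncation_spectrum = 5L)
  g <- simulate_genome(cfg)
  pv <- small_provirus()
  pl <- plant_integrations(g, pv, cfg)
  tr <- pl$truth
  expect_true(all(tr$missing_5 == 5L & tr$missing_3 == 5L))
  expect_true(all(tr$tsd == 0L))
  plen <- nchar(pv$sequence)
  shift <- 0
  mod <- pl$genome$sequences[["c1"]]
  for (i in seq_len(nrow(tr))) {
    p <- tr$position[i] + shift
    expected <- substr(pv$sequence, 6, plen - 5)   # both termini gone
    if (tr$orientation[i] == "-") expected <- revcomp(expected)
    expect_identical(substr(mod, p + 1, p + plen - 10), expected)
    shift <- shift + plen - 10
  }

  expect_identical(
    plant_integrations(g, pv,
                       sim_config(seed = 1,
                                  chromosome_lengths = c(c1 = 2e5),
                                  n_integrations = 0))$genome$sequences,
    g$sequences)
})

test_that("realized integrase fraction converges to the configured value", {
  pv <- small_provirus()
  cfg0 <- sim_config(seed = 1, chromosome_lengths = c(c1 = 3e5),
                     target_region_fractions = c(0, 0, 1),
                     n_integrations = 30, integrase_fraction = 0.5)
  g <- simulate_genome(cfg0)
  full <- 0L; total <- 0L
  for (s in 1:6) {
    cfg0$seed <- s
    tr <- plant_integrations(g, pv, cfg0, seed = 1000L + s)$truth
    full <- full + sum(tr$completeness == "full")
    total <- total + nrow(tr)
  }
  ci <- clopper_pearson(full, total)
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
})

test_that("TraDIS amplicons start at the anchor and mates overlap as geometry dictates", {
  pv <- small_provirus()
  cfg <- sim_config(seed = 21, chromosome_lengths = c(c1 = 2e5),
                    target_region_fractions = c(0, 0, 1),
                    n_integrations = 3, integrase_fraction = 1,
                    sequencing_error_rate = 0, reads_per_event = 5,
                    decoy_rate = 0, empty_insert_rate = 0)
  g <- simulate_genome(cfg)
  pl <- plant_integrations(g, pv, cfg)
  rd <- simulate_tradis_reads(g, pl$truth, pv, cfg, which_end = 3)
  expect_true(all(startsWith(rd$seq1, pv$anchor_3)))
  rd5 <- simulate_tradis_reads(g, pl$truth, pv, cfg, which_end = 5)
  expect_true(all(startsWith(rd5$seq1, pv$anchor_5)))
  expect_error(simulate_tradis_reads(g, pl$truth, pv, cfg, which_end = 4))

  # 150-bp fragments with 100-bp reads: mates overlap by 50 and merge back
  # to the full fragment
  cfg2 <- cfg
  cfg2$fragment_size <- c(150L, 150L)
  rd2 <- simulate_tradis_reads(g, pl$truth, pv, cfg2, which_end = 3)
  m <- merge_pairs(rd2$seq1[1], rd2$qual1[1], rd2$seq2[1], rd2$qual2[1])
  expect_true(m$merged)
  expect_equal(nchar(m$seq), 150L)

  # eroded 3' terminus: the amplicon junction lacks the CA adjacency
  cfg3 <- cfg
  cfg3$integrase_fraction <- 0
  cfg3$truncation_spectrum <- 2L
  pl3 <- plant_integrations(g, pv, cfg3)
  rd3 <- simulate_tradis_reads(g, pl3$truth, pv, cfg3, which_end = 3)
  expect_true(all(!startsWith(rd3$seq1, pv$anchor_3)))
  expect_true(all(startsWith(rd3$seq1,
                             substr(pv$anchor_3, 1, 35))))
})

test_that("WGS read count follows coverage arithmetic and a clean genome has no provirus reads", {
  cfg <- sim_config(seed = 31, chromosome_lengths = c(c1 = 2e5),
                    target_region_fractions = c(0, 0, 1),
                    wgs_coverage = 40, sequencing_error_rate = 0)
  g <- simulate_genome(cfg)
  rd <- simulate_wgs_reads(g, cfg)
  expect_equal(nrow(rd), round(40 * 2e5 / 200))

  cfg2 <- cfg
  cfg2$chromosome_lengths <- c(c1 = 5e4)
  cfg2$wgs_coverage <- 5
  g2 <- simulate_genome(cfg2)
  rd2 <- simulate_wgs_reads(g2, cfg2)
  idx <- build_index(g2, small_provirus())
  aln <- map_reads(idx, rd2$seq1)
  expect_equal(sum(aln$reference == "provirus"), 0L)
})
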