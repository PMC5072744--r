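# helper: one alignment row in map_reads() layout
aln_row <- function(pair, ref, start, end, strand = "+", qstart = 0,
                    qend = end - start, matched = end - start,
                    mism = 0, score = matched - mism, mapq = 60,
                    ncoopt = 1, best = TRUE) {
  data.frame(read = pair, reference = ref, start = start, end = end,
             strand = strand, qstart = qstart, qend = qend,
             matched = matched, mismatches = mism, score = score,
             mapq = mapq, n_cooptimal = ncoopt, best = best)
}

test_that("pair categories: partial, independent, virus-only", {
  # pair 1: read 1 splits 40 bp provirus + 60 bp host -> partial, junction
  # at the host boundary adjacent to the virus side
  a1 <- rbind(
    aln_row(1, "provirus", 9000, 9040, qstart = 0, qend = 40, matched = 40,
            best = FALSE),
    aln_row(1, "c1", 5000, 5060, qstart = 40, qend = 100, matched = 60),
    # pair 2: mate 1 host only
    aln_row(2, "c1", 800, 900),
    # pair 3: mate 1 provirus only
    aln_row(3, "provirus", 100, 200),
    # pair 4: host-only pair (dropped)
    aln_row(4, "c1", 10000, 10100))
  a2 <- rbind(
    aln_row(1, "c1", 5100, 5200, strand = "-"),
    aln_row(2, "provirus", 300, 400),      # mate 2 provirus only
    aln_row(3, "provirus", 500, 600),      # both mates provirus
    aln_row(4, "c1", 10200, 10300, strand = "-"))
  cats <- categorize_read_pairs(a1, a2)
  expect_equal(cats$category[cats$pair == 1], "partial")
  # host part is the read suffix: junction at host alignment start
  expect_equal(cats$position[cats$pair == 1], 5000)
  expect_equal(cats$category[cats$pair == 2], "independent")
  expect_equal(cats$h_start[cats$pair == 2], 800)
  expect_equal(cats$category[cats$pair == 3], "virus_only")
  expect_false(4 %in% cats$pair)

  # provirus-side score competition: a read matching host better than
  # provirus is not virus evidence
  b1 <- rbind(aln_row(5, "c1", 100, 200, matched = 100),
              aln_row(5, "provirus", 10, 100, matched = 90, best = FALSE))
  b2 <- aln_row(5, "c1", 350, 450, strand = "-")
  expect_equal(nrow(categorize_read_pairs(b1, b2)), 0L)
})

test_that("event counting dedups partial junctions and suppresses nearby independents", {
  cats <- data.frame(
    pair = 1:5,
    category = c("partial", "partial", "partial", "independent",
                 "independent"),
    chromosome = c("c1", "c1", "c1", "c1", "c2"),
    position = c(1000, 1002, 998, NA, NA),
    h_start = c(NA, NA, NA, 1100, 50000),
    h_end = c(NA, NA, NA, 1200, 50100))
  cnt <- count_integrations(cats, merge_radius = 400)
  # three partials at one junction collapse; the c1 independent sits within
  # an insert of it and is suppressed; the c2 independent stands alone
  expect_equal(cnt$n_partial, 1L)
  expect_equal(cnt$n_independent, 1L)
  expect_equal(cnt$x, 2L)

  cnt2 <- count_integrations(cats, merge_radius = 400,
                             suppress_independent = FALSE)
  expect_equal(cnt2$x, 3L)

  empty <- cats[0, ]
  expect_equal(count_integrations(empty)$x, 0L)

  # invariant under row order and duplication
  dup <- rbind(cats, cats)[sample.int(10), ]
  expect_equal(count_integrations(dup, merge_radius = 400)$x, cnt$x)
})

test_that("segments per diploid genome follow the published assembly arithmetic", {
  assembly <- c(79986414, 38216055, 38028725, 34586772, 10324086,
                20039393, 11043263, 61504481, 19871, 70778700)
  S <- segments_per_diploid_genome(assembly, 100)
  expect_equal(signif(S, 3), 7.29e6)
  expect_equal(segments_per_diploid_genome(100, 100), 2)
  expect_equal(segments_per_diploid_genome(assembly, 50), 2 * S)
  expect_error(segments_per_diploid_genome(assembly, 0), "read_length")
})

test_that("the per-nucleus estimator reproduces the published worked example", {
  est <- per_nucleus_estimate(60, 207576406, 7.29e6)
  expect_equal(round(est$per_nucleus, 1), 2.1)
  expect_equal(round(est$ci, 1), c(1.6, 2.7))
  org <- per_organism(est, 1000)
  expect_equal(round(org$value, -2), 2100)
  expect_equal(round(org$ci, -2), c(1600, 2700))

  z <- per_nucleus_estimate(0, 1000, 100)
  expect_equal(z$per_nucleus, 0)
  expect_equal(z$ci[1], 0)
  expect_error(per_nucleus_estimate(5, 0, 10), "R")

  e2 <- per_nucleus_estimate(10, 1e6, 1e5)
  expect_equal(e2$per_nucleus, 1)
  expect_true(e2$ci[1] <= e2$per_nucleus && e2$per_nucleus <= e2$ci[2])
})

test_that("Clopper-Pearson bounds equal CDF-inversion and keep nominal coverage", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:5000, 1)
    x <- sample(0:n, 1)
    expect_equal(clopper_pearson(x, n), cp_bisect(x, n), tolerance = 1e-9)
  }
  # empirical coverage at small n stays at or above the nominal level
  set.seed(18)
  p <- 0.03; n <- 500; hits <- 0; reps <- 400
  for (i in 1:reps) {
    x <- rbinom(1, n, p)
    ci <- clopper_pearson(x, n)
    hits <- hits + (ci[1] <= p && p <= ci[2])
  }
  expect_gte(hits / reps, 0.95)
})

test_that("nuclei-from-mass and per-organism scaling arithmetic", {
  expect_equal(signif(nuclei_from_mass(1700, 0.79), 2), 2.2e6)
  expect_equal(nuclei_from_mass(0.00079), 1)
  expect_equal(nuclei_from_mass(7.9), 10000)
  expect_error(nuclei_from_mass(0), "mass")
})
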