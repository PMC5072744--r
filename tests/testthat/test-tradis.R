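# helper: build a one-row prepped table
prep_row <- function(host, id = "r1", evidence = "merged", found = TRUE,
                     complete = TRUE, splk = FALSE, end = 3L) {
  data.frame(id = id, evidence = evidence, ltr_end = end,
             anchor_found = found, anchor_complete = complete,
             splinkerette_immediately_after_anchor = splk,
             host_sequence = host)
}

test_that("the four authenticity criteria admit and reject as specified", {
  set.seed(13)
  g <- small_genome()
  pv <- small_provirus()
  idx <- build_index(g, pv)

  flank60 <- substr(g$sequences[["chr1"]], 10001, 10060)
  flank25 <- substr(g$sequences[["chr1"]], 20001, 20025)

  prepped <- rbind(
    prep_row(flank60, "ok"),
    prep_row(flank60, "no_anchor", found = FALSE, complete = FALSE),
    prep_row(flank60, "splk", splk = TRUE),
    prep_row(flank25, "short"))
  aln <- map_reads(idx, prepped$host_sequence)
  calls <- call_sites(prepped, aln, filter_params(), pv)

  expect_equal(nrow(calls), 1L)
  expect_equal(calls$read_id, "ok")
  expect_equal(calls$chromosome, "chr1")
  expect_equal(calls$position, 10000)      # 0-based anchor-proximal base
  expect_equal(calls$junction_class, "integrase_catalyzed")
  rej <- attr(calls, "rejections")
  expect_equal(unname(rej), c(1L, 1L, 1L, 0L))

  # criterion iv: unique but unconfident mapping (near-duplicate locus)
  block <- random_dna(200)
  near <- block
  for (p in c(40, 120)) substr(near, p, p) <-
      ifelse(substr(near, p, p) == "A", "C", "A")
  g2 <- genome_ref(c(c1 = paste0(random_dna(300), block, random_dna(300),
                                 near, random_dna(300))))
  idx2 <- build_index(g2, pv)
  p2 <- prep_row(substr(block, 60, 159), "lowq")
  a2 <- map_reads(idx2, p2$host_sequence)
  c2 <- call_sites(p2, a2, filter_params(), pv)
  expect_equal(nrow(c2), 0L)
  expect_equal(unname(attr(c2, "rejections")["iv_mapq"]), 1L)

  # criterion iii: a verbatim repeat is co-optimal, rejected before iv
  g3 <- genome_ref(c(c1 = paste0(random_dna(300), block, random_dna(300),
                                 block, random_dna(300))))
  idx3 <- build_index(g3, pv)
  a3 <- map_reads(idx3, p2$host_sequence)
  c3 <- call_sites(p2, a3, filter_params(), pv)
  expect_equal(unname(attr(c3, "rejections")["iii_short_or_multi"]), 1L)
})

test_that("junction classification follows terminus integrity and microhomology", {
  pv <- small_provirus()
  calls <- data.frame(
    anchor_complete = c(TRUE, FALSE, TRUE),
    flank_start = c("GT", "GT", "CA"))
  expect_equal(classify_junction(calls, pv),
               c("integrase_catalyzed", "unresolved", "unresolved"))
})

test_that("deduplication equals the set-distinct oracle", {
  set.seed(14)
  n <- 1000
  calls <- data.frame(
    chromosome = sample(c("c1", "c2"), n, TRUE),
    position = sample(1:150, n, TRUE),
    strand = sample(c("+", "-"), n, TRUE),
    ltr_end = 3L,
    evidence = sample(c("merged", "paired"), n, TRUE),
    read_id = sprintf("r%04d", 1:n),
    anchor_complete = TRUE, flank_start = "GG",
    junction_class = "integrase_catalyzed")
  uniq <- dedup_and_unique(calls)
  oracle <- unique(calls[, c("chromosome", "position", "strand", "ltr_end")])
  expect_equal(nrow(uniq), nrow(oracle))
  expect_equal(sum(uniq$support), n)
  # sorted by chromosome, position
  expect_true(!is.unsorted(uniq$position[uniq$chromosome == "c1"]))

  simple <- calls[1:5, ]; simple$position <- 100; simple$chromosome <- "c1"
  u2 <- dedup_and_unique(simple)
  expect_lte(nrow(u2), 2L)   # at most one per strand
  expect_equal(sum(u2$support), 5L)
  two <- calls[1:2, ]
  two$position <- c(100, 101); two$strand <- "+"; two$chromosome <- "c1"
  expect_equal(nrow(dedup_and_unique(two)), 2L)
})

test_that("single-linkage clustering chains within the radius", {
  d <- data.frame(chromosome = "c1", position = c(100, 300, 700))
  cl <- cluster_positions(d, radius = 250)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$n_members, c(2L, 1L))
  expect_equal(cl$representative, c(100, 700))

  chain <- data.frame(chromosome = "c1", position = c(0, 200, 400, 600))
  cl2 <- cluster_positions(chain, radius = 250)
  expect_equal(nrow(cl2), 1L)
  expect_equal(cl2$n_members, 4L)

  single <- data.frame(chromosome = "c1", position = 5)
  expect_equal(nrow(cluster_positions(single)), 1L)
})

test_that("cluster count matches a union-find oracle and ignores input order", {
  set.seed(15)
  d <- data.frame(chromosome = sample(c("c1", "c2", "c3"), 1000, TRUE),
                  position = sample.int(2e5, 1000))
  cl <- cluster_positions(d, radius = 250)
  expect_equal(nrow(cl), uf_cluster_count(d$chromosome, d$position, 250))
  shuffled <- d[sample.int(nrow(d)), ]
  expect_equal(nrow(cluster_positions(shuffled, radius = 250)), nrow(cl))
  # within-cluster gaps <= radius; between-cluster gaps > radius
  for (chrom in unique(cl$chromosome)) {
    cc <- cl[cl$chromosome == chrom, ]
    cc <- cc[order(cc$start), ]
    if (nrow(cc) > 1)
      expect_true(all(cc$start[-1] - cc$end[-nrow(cc)] > 250))
  }
})

test_that("library summary arithmetic and the count ordering invariant hold", {
  set.seed(16)
  calls <- data.frame(
    chromosome = "c1",
    position = rep(c(10, 400, 900), c(5, 3, 2)),
    strand = "+", ltr_end = 3L,
    evidence = c(rep("merged", 7), rep("paired", 3)),
    read_id = sprintf("r%02d", 1:10),
    anchor_complete = rep(c(TRUE, FALSE), c(3, 7)),
    flank_start = "GG")
  calls$junction_class <- classify_junction(calls)
  s <- library_summary(calls)
  m <- s[s$category == "merged reads", ]
  expect_equal(m$total, 7)
  expect_equal(m$integrase_catalyzed, 3)
  expect_equal(m$pct_integrase, round(300 / 7, 1))
  up <- s$total[s$category == "unique positions"]
  uc <- s$total[s$category == "unique clusters"]
  expect_lte(uc, up)
  expect_lte(up, nrow(calls))

  empty <- calls[0, ]
  empty$junction_class <- character(0)
  s0 <- library_summary(empty)
  expect_true(all(s0$total == 0))
})
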