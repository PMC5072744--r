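test_that("pair merging reconstructs fragments and respects the overlap floor", {
  set.seed(2)
  q <- function(n) strrep("F", n)

  # identical mates: full overlap, merged read equals read 1
  s <- random_dna(100)
  m <- merge_pairs(s, q(100), revcomp(s), q(100))
  expect_true(m$merged)
  expect_identical(m$seq, s)

  # 150-bp fragment, 100-bp reads: merged length is the fragment length
  frag <- random_dna(150)
  m <- merge_pairs(substr(frag, 1, 100), q(100),
                   revcomp(substr(frag, 51, 150)), q(100))
  expect_true(m$merged)
  expect_identical(m$seq, frag)

  # 9-bp true overlap stays below the threshold
  frag <- random_dna(191)
  m <- merge_pairs(substr(frag, 1, 100), q(100),
                   revcomp(substr(frag, 92, 191)), q(100))
  expect_false(m$merged)

  # disagreement resolution: the higher-quality base wins, ties go to read 1
  a <- paste0(random_dna(40), "A", random_dna(9))
  b <- a; substr(b, 41, 41) <- "G"
  qa <- q(50); qb <- q(50)
  substr(qa, 41, 41) <- "+"              # read-1 base low quality
  m <- merge_pairs(a, qa, revcomp(b), qb)
  expect_identical(substr(m$seq, 41, 41), "G")
  m <- merge_pairs(a, q(50), revcomp(b), q(50))
  expect_identical(substr(m$seq, 41, 41), "A")
})

test_that("merging is symmetric under mate swap", {
  set.seed(3)
  q <- strrep("F", 100)
  for (i in 1:10) {
    frag <- random_dna(sample(120:190, 1))
    r1 <- substr(frag, 1, 100)
    r2 <- revcomp(substr(frag, nchar(frag) - 99, nchar(frag)))
    m12 <- merge_pairs(r1, q, r2, q)
    m21 <- merge_pairs(r2, q, r1, q)
    expect_true(m12$merged && m21$merged)
    expect_identical(m21$seq, revcomp(m12$seq))
  }
})

test_that("anchor stripping inverts anchor prepending and flags empty inserts", {
  pv <- small_provirus()
  set.seed(4)
  for (i in 1:20) {
    s <- random_dna(60)
    if (startsWith(s, substr(pv$anchor_3, 1, 4))) next
    out <- strip_anchor(paste0(pv$anchor_3, s), pv, 3)
    expect_true(out$anchor_found && out$anchor_complete)
    expect_identical(out$host_sequence, s)
    expect_equal(out$ltr_end, 3L)
    out5 <- strip_anchor(paste0(pv$anchor_5, s), pv, 5)
    expect_true(out5$anchor_found)
    expect_identical(out5$host_sequence, s)
  }

  # one substitution at zero tolerance: not an anchor
  x <- paste0(pv$anchor_3, random_dna(40))
  substr(x, 3, 3) <- ifelse(substr(x, 3, 3) == "A", "C", "A")
  expect_false(strip_anchor(x, pv, 3)$anchor_found)

  # anchor followed directly by splinkerette: flagged for rejection
  out <- strip_anchor(paste0(pv$anchor_3, SPLINKERETTE), pv, 3)
  expect_true(out$anchor_found)
  expect_true(out$splinkerette_immediately_after_anchor)

  # a genuine host flank is not flagged
  out <- strip_anchor(paste0(pv$anchor_3, random_dna(60)), pv, 3)
  expect_false(out$splinkerette_immediately_after_anchor)

  # eroded terminus within the erosion window: found but incomplete
  eroded <- paste0(substr(pv$anchor_3, 1, 34), random_dna(50))
  out <- strip_anchor(eroded, pv, 3)
  expect_true(out$anchor_found)
  expect_false(out$anchor_complete)
  # erosion beyond the window: lost
  gone <- paste0(substr(pv$anchor_3, 1, 25), random_dna(50))
  expect_false(strip_anchor(gone, pv, 3)$anchor_found)
})

test_that("splinkerette trimming removes adapter suffixes, sliding-window checked", {
  set.seed(5)
  host <- random_dna(70)

  expect_identical(trim_splinkerette(paste0(host, SPLINKERETTE)), host)
  expect_identical(trim_splinkerette(host), host)

  # 12-bp adapter prefix with one mismatch at the read end
  ad12 <- substr(SPLINKERETTE, 1, 12)
  substr(ad12, 6, 6) <- ifelse(substr(ad12, 6, 6) == "A", "C", "A")
  trimmed <- trim_splinkerette(paste0(host, ad12))
  expect_identical(trimmed, host)

  # oracle: an independent sliding-window scan agrees on random cases
  for (i in 1:10) {
    alen <- sample(10:30, 1)
    read <- paste0(random_dna(50), substr(SPLINKERETTE, 1, alen))
    oracle_cut <- NA
    for (pos in 1:(nchar(read) - 9)) {
      L <- min(nchar(read) - pos + 1, nchar(SPLINKERETTE))
      if (L >= 10 &&
          sum(charToRaw(substr(read, pos, pos + L - 1)) !=
              charToRaw(substr(SPLINKERETTE, 1, L))) <= L %/% 10) {
        oracle_cut <- pos; break
      }
    }
    expect_identical(trim_splinkerette(read),
                     substr(read, 1, oracle_cut - 1))
  }
})

test_that("library prep assigns evidence classes and tallies the report", {
  pv <- small_provirus()
  set.seed(6)
  q <- function(n) strrep("F", n)
  frag_short <- paste0(pv$anchor_3, random_dna(100))     # 137 bp: merges
  frag_long <- paste0(pv$anchor_3, random_dna(250))      # 287 bp: pairs
  pairs <- data.frame(
    id = c("a", "b", "c", "d"),
    seq1 = c(substr(frag_short, 1, 100), substr(frag_long, 1, 100),
             random_dna(100), paste0(pv$anchor_3, SPLINKERETTE)),
    qual1 = q(100),
    seq2 = c(revcomp(substr(frag_short, 38, 137)),
             revcomp(substr(frag_long, 188, 287)),
             random_dna(100),
             revcomp(substr(paste0(pv$anchor_3, SPLINKERETTE), 1, 91))),
    qual2 = c(q(100), q(100), q(100), q(91)))
  prepped <- prep_tradis_reads(pairs, pv, 3)
  expect_equal(prepped$evidence, c("merged", "paired", "paired", "merged"))
  expect_equal(prepped$anchor_found, c(TRUE, TRUE, FALSE, TRUE))
  expect_true(prepped$splinkerette_immediately_after_anchor[4])
  # merged read a: host flank is the fragment minus the anchor, adapter-free
  expect_identical(prepped$host_sequence[1], substr(frag_short, 38, 137))
  counts <- attr(prepped, "counts")
  expect_equal(unname(counts["merged"]), 2L)
  expect_equal(unname(counts["anchor_found"]), 3L)
})
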