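# Independent oracles used to cross-check the implementation.

# union-find clustering over the <= radius adjacency graph; returns the
# number of connected components per chromosome summed
uf_cluster_count <- function(chromosome, position, radius) {
  total <- 0L
  for (chrom in unique(chromosome)) {
    p <- position[chromosome == chrom]
    n <- length(p)
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && abs(p[i] - p[j]) <= radius) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
    roots <- vapply(seq_len(n), find, 1L)
    total <- total + length(unique(roots))
  }
  total
}

# Clopper-Pearson bounds by direct bisection of the binomial CDF
cp_bisect <- function(x, n, conf = 0.95, tol = 1e-12) {
  a <- (1 - conf) / 2
  upper_root <- function(f) {   # find p with f(p) = 0, f increasing
    lo <- 0; hi <- 1
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lo <- if (x == 0) 0 else
    upper_root(function(p) (1 - pbinom(x - 1, n, p)) - a)
  hi <- if (x == n) 1 else
    upper_root(function(p) a - pbinom(x, n, p))
  c(lo, hi)
}

# brute-force best ungapped placement of an error-free read: scan both
# strands of every reference with Biostrings exact matching
brute_best_map <- function(read, refs) {
  hits <- list()
  for (nm in names(refs)) {
    subj <- Biostrings::DNAString(refs[[nm]])
    f <- Biostrings::matchPattern(read, subj)
    if (length(f))
      hits[[length(hits) + 1L]] <- data.frame(
        reference = nm, start = Biostrings::start(f) - 1L, strand = "+")
    r <- Biostrings::matchPattern(revcomp(read), subj)
    if (length(r))
      hits[[length(hits) + 1L]] <- data.frame(
        reference = nm, start = Biostrings::start(r) - 1L, strand = "-")
  }
  if (!length(hits))
    return(data.frame(reference = character(), start = numeric(),
                      strand = character()))
  do.call(rbind, hits)
}

# exact upper-tail binomial probability by full outcome enumeration
# (feasible for n <= 20)
enum_upper_tail <- function(k, n, p) {
  grid <- expand.grid(rep(list(c(0L, 1L)), n))
  succ <- rowSums(grid)
  prob <- p^succ * (1 - p)^(n - succ)
  sum(prob[succ >= k])
}

# memoized shared fixtures (built once per test run)
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

small_provirus <- function() fixture("provirus", function()
  synthetic_provirus(internal_length = 2000L, ltr_length = 200L, seed = 42L))

small_genome <- function() fixture("genome", function() {
  cfg <- sim_config(seed = 7, chromosome_lengths = c(chr1 = 3e5, chr2 = 2e5))
  simulate_genome(cfg)
})
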