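# Shared fixtures and small helpers for the test suite.

fx <- worked_examples()

expect_genome_equal <- function(a, b) {
  expect_true(genome_equal(a, b),
              label = paste0("genomes differ: [", write_genome(a), "] vs [",
                             write_genome(b), "]"))
}

# random single-linear totally duplicated genome that is oriented
random_oriented_genome <- function(n, seed, tries = 200L) {
  for (k in seq_len(tries)) {
    g <- random_duplicated_genome(n, seed = seed * 1000L + k)
    og <- build_overlap_graph(g)
    if (orientation_status(og)$oriented) return(g)
  }
  stop("no oriented genome found")
}

# exhaustive minimum set cover of `missing` couples by the cycles' couple sets
brute_min_cover <- function(cycle_couples, missing) {
  if (!length(missing)) return(0L)
  k <- length(cycle_couples)
  for (size in seq_len(k)) {
    for (idx in utils::combn(k, size, simplify = FALSE)) {
      if (all(missing %in% unlist(cycle_couples[idx]))) return(size)
    }
  }
  Inf
}

# exhaustive maximum independent set size by subset enumeration
brute_mis <- function(adj) {
  N <- length(adj)
  if (N == 0L) return(0L)
  best <- 0L
  for (mask in 0:(2^N - 1L)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(N - 1L))) != 0L)
    ok <- TRUE
    for (v in sel) if (length(intersect(adj[[v]], sel))) { ok <- FALSE; break }
    if (ok) best <- max(best, length(sel))
  }
  best
}
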