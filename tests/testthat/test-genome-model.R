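test_that("parsing applies the grammar and canonicalizes copy labels", {
  g <- parse_genome("L 1 2 2' 1'")
  expect_length(g$chromosomes, 1L)
  expect_false(g$chromosomes[[1]]$circular)
  expect_equal(write_genome(g), "L 1 2 2' 1'")

  gc <- parse_genome("C 1 2 1' 2'")
  expect_true(gc$chromosomes[[1]]$circular)

  # comments, blank lines, multi-chromosome
  g2 <- parse_genome("# a comment\n\nL 1 -2\nC 3 4\n")
  expect_length(g2$chromosomes, 2L)

  # first occurrence becomes the plain copy even if written as bar
  g3 <- parse_genome("L 1' 2 1 2'")
  expect_equal(write_genome(g3), "L 1 2 1' 2'")

  expect_error(parse_genome("L 1 1 1"), "more than twice")
  expect_error(parse_genome("L 1 1"), "plain and one bar")
  expect_error(parse_genome("L 1 x"), "bad marker")
  expect_error(parse_genome("X 1 2"), "must start with L or C")
})

test_that("write/parse round-trips on seeded random genomes", {
  for (s in 1:200) {
    n <- 1L + s %% 7L
    g <- random_duplicated_genome(n, chromosomes = 1L + s %% min(3L, n),
                                  circular_fraction = 0.3, seed = s)
    expect_genome_equal(g, parse_genome(write_genome(g)))
  }
})

test_that("adjacency sets follow consecutive pairs plus telomeres", {
  expect_setequal(adjacencies(parse_genome("L 1 2")),
                  c("(-1,$)", "(1,2)", "(2,$)"))
  expect_length(adjacencies(parse_genome("C 1 2 1' 2'")), 4L)
  a4 <- adjacencies(fx$E4)
  expect_length(a4, 5L)
  expect_true("(2,2')" %in% a4)
  # reading-direction invariance: reflecting a chromosome preserves the set
  g <- random_duplicated_genome(5, seed = 11)
  r <- g
  r$chromosomes[[1]]$body <- -rev(r$chromosomes[[1]]$body)
  expect_setequal(adjacencies(g), adjacencies(r))
})

test_that("duplication status and the dedoubled predicate", {
  expect_equal(classify_genome(fx$E1)$status, "totally_duplicated")
  expect_true(classify_genome(fx$E1)$dedoubled)
  # inverted-adjacent form (x -x') is NOT dedoubled
  expect_false(classify_genome(parse_genome("L 1 -1' 2 2'"))$dedoubled)
  expect_false(classify_genome(fx$E4)$dedoubled)
  expect_equal(classify_genome(parse_genome("L 1 2 3"))$status, "non_duplicated")
  expect_equal(classify_genome(parse_genome("L 1 1' 5"))$status, "duplicated")
  # (-x' -x) is the (x x') form read backwards: dedoubled
  expect_true(is_dedoubled(parse_genome("L -2' -2 3")))
})

test_that("reduction collapses couples and keeps orientation", {
  expect_equal(write_genome(reduce_dedoubled(fx$E1)), "L 1 2")
  expect_equal(write_genome(reduce_dedoubled(parse_genome("L 1 1' -2' -2"))),
               "L 1 -2")
  expect_error(reduce_dedoubled(parse_genome("L 1 -1'")), "not_dedoubled")
  # after any emitted scenario the end genome always reduces cleanly
  res <- dcj_sort(fx$E6)
  expect_equal(n_couples(reduce_dedoubled(res$genome)), 0L)
})

test_that("totalization replaces maximal runs by dedoubled pairs", {
  tt <- totalize(parse_genome("L 1 1' 5 6 7 2 2'"))
  expect_equal(write_genome(tt$genome), "L 1 1' 5 5' 2 2'")
  expect_equal(names(tt$runmap), "5")
  expect_equal(tt$runmap[["5"]], parse_marker(c("5", "6", "7")))

  t2 <- totalize(parse_genome("L 1 2 3"))
  expect_equal(write_genome(t2$genome), "L 1 1'")

  # a run beginning with a negative marker gets a negative pair
  t3 <- totalize(parse_genome("L 1 1' -4 -3"))
  expect_equal(write_genome(t3$genome), "L 1 1' -4 -4'")
  expect_true(is_dedoubled(t3$genome))

  t4 <- totalize(fx$E4)
  expect_genome_equal(t4$genome, fx$E4)
  expect_length(t4$runmap, 0L)

  # circular chromosome with a wrapping run
  t5 <- totalize(parse_genome("C 6 1 1' 5"))
  expect_equal(classify_genome(t5$genome)$status, "totally_duplicated")
  expect_true(classify_genome(t5$genome)$dedoubled)
})

test_that("ancestor expansion inverts totalization", {
  rm5 <- list("5" = parse_marker(c("5", "6", "7")))
  expect_equal(write_genome(expand_ancestor(parse_genome("L 5 2"), rm5)),
               "L 5 6 7 2")
  expect_equal(write_genome(expand_ancestor(parse_genome("L -5 2"), rm5)),
               "L -7 -6 -5 2")
  expect_error(expand_ancestor(parse_genome("L 1 2"), rm5), "missing_key")
  for (s in 1:25) {
    anc <- random_ancestor(6, chromosomes = 1L + s %% 2L, seed = s)
    tt <- totalize(anc)
    back <- expand_ancestor(reduce_dedoubled(tt$genome), tt$runmap)
    expect_genome_equal(back, anc)
  }
})

test_that("totalization preserves the dedoubling distance (tiny oracle)", {
  # partially duplicated genomes with short runs: the brute-force distance to
  # the nearest dedoubled genome is unchanged by totalization
  cases <- list("L 1 5 1' 2 2'", "L 1 -1' 5 6", "L 2' 5 -2 1 1'",
                "L 1 2 5 1' 2'", "C 1 5 1'", "L -1 5 1' 6")
  for (txt in cases) {
    g <- parse_genome(txt)
    tg <- totalize(g)$genome
    expect_equal(bfs_oracle(g, "dcj"), bfs_oracle(tg, "dcj"), label = txt)
  }
})

test_that("copy-label swaps never change observable results", {
  for (s in 1:20) {
    g <- random_duplicated_genome(4, seed = 300 + s)
    fams <- duplicated_families(g)
    sw <- gdd:::swap_copy_labels(g, fams[c(1L, 1L + s %% length(fams))])
    expect_equal(dcj_distance(g)$distance, dcj_distance(sw)$distance)
    expect_equal(dcj_distance_linear(g)$m, dcj_distance_linear(sw)$m)
    expect_true(genome_equal(g, sw, copy_swap = TRUE))
  }
})
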