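element_summary <- function(g) {
  gr <- build_adjacency_graph(g)
  vapply(gr$elements, function(el) {
    paste0(el$kind, ":", paste(el$couples, collapse = ","))
  }, character(1))
}

test_that("the dedoubled adjacency graph decomposes into the expected elements", {
  # dedoubled genome: one independent self-loop per couple, plus the path
  expect_setequal(element_summary(fx$E1), c("path:1,2", "cycle:1", "cycle:2"))
  # (1 2 2' 1'): path {1} + two-edge cycle {1,2} + self-loop {2}
  expect_setequal(element_summary(fx$E4), c("path:1", "cycle:1,2", "cycle:2"))
  # (1 -1' 2 2'): one duplicated path + self-loop {2}
  expect_setequal(element_summary(fx$E2), c("path:1,1,2", "cycle:2"))
  # circular (1 2 1' 2'): a single duplicated cycle
  expect_setequal(element_summary(fx$circ2), c("cycle:1,1,2,2"))

  gr <- build_adjacency_graph(fx$E4)
  expect_equal(nrow(gr$edges), 2L * gr$n)
  degs <- table(c(gr$edges$v1, gr$edges$v2))
  expect_true(all(degs %in% 1:2))
  expect_error(build_adjacency_graph(parse_genome("L 1 1' 5")),
               "not_totally_duplicated")
})

test_that("element relations distinguish intersecting, independent and duplicated", {
  gr <- build_adjacency_graph(fx$E4)
  rel <- element_relations(gr)
  kinds <- vapply(gr$elements, `[[`, character(1), "kind")
  two_cycle <- which(vapply(gr$elements, function(e) e$size == 2L, logical(1)))
  path <- which(kinds == "path")
  loop <- setdiff(which(kinds == "cycle"), two_cycle)
  expect_true(rel$intersects[two_cycle, path])
  expect_true(rel$intersects[two_cycle, loop])
  expect_false(rel$intersects[path, loop])
  expect_false(any(rel$duplicated))
  expect_true(element_relations(build_adjacency_graph(fx$circ2))$duplicated)
  # two self-loops of different couples are independent
  rel1 <- element_relations(build_adjacency_graph(fx$E1))
  expect_false(any(rel1$intersects[2, 3], rel1$intersects[3, 2]))
})

test_that("path validity identifies the missing couples", {
  expect_true(path_validity(build_adjacency_graph(fx$E3))$valid)
  pv <- path_validity(build_adjacency_graph(fx$E4))
  expect_false(pv$valid)
  expect_equal(pv$missing_couples, 2L)
  # any dedoubled linear genome has a valid path
  for (s in 1:10) {
    anc <- random_ancestor(4, seed = s)
    dd <- totalize(anc)$genome
    expect_true(path_validity(build_adjacency_graph(dd))$valid)
  }
  expect_error(path_validity(build_adjacency_graph(fx$circ2)),
               "not_unichromosomal")
})

test_that("edge orientation follows the written signs of the copies", {
  gr <- build_adjacency_graph(fx$E2)
  expect_true(edge_orientation(gr, 1))
  expect_false(edge_orientation(gr, 2))
  # in the big worked genome, couple 8 is written -H ... H: oriented
  grf <- build_adjacency_graph(fx$worked26)
  expect_true(edge_orientation(grf, 8))
  expect_false(edge_orientation(grf, 2))
})

test_that("a genome is dedoubled iff every couple self-loops iff C_i = n", {
  for (s in 1:40) {
    g <- random_duplicated_genome(1L + s %% 5L, chromosomes = 1L + s %% 2L,
                                  circular_fraction = 0.2, seed = 40 + s)
    gr <- build_adjacency_graph(g)
    loops <- vapply(gr$elements, function(el) {
      el$kind == "cycle" && el$size == 1L
    }, logical(1))
    families_looped <- sort(unique(unlist(
      lapply(gr$elements[loops], `[[`, "couples"))))
    sel <- max_independent_cycles(build_conflict_graph(gr))
    expect_equal(is_dedoubled(g),
                 identical(families_looped, sort(duplicated_families(g))))
    expect_equal(is_dedoubled(g), sel$C_i == gr$n)
    expect_lte(sel$C_i, gr$n)
  }
})

test_that("a single DCJ changes C_i by at most one", {
  for (s in 1:60) {
    n <- 2L + s %% 4L
    g <- random_duplicated_genome(n, seed = 6000 + s)
    ci <- function(x) {
      max_independent_cycles(build_conflict_graph(build_adjacency_graph(x)))$C_i
    }
    amat <- gdd:::adjacency_matrix(g)
    set.seed(s)
    ij <- sample(ncol(amat), 2L)
    h <- apply_dcj(g, amat[, ij[1]], amat[, ij[2]], 1L + s %% 2L)
    expect_lte(abs(ci(h) - ci(g)), 1L)
  }
})

test_that("the graph is invariant under copy swap and reflection", {
  for (s in 1:15) {
    g <- random_duplicated_genome(4, seed = 900 + s)
    sw <- gdd:::swap_copy_labels(g, duplicated_families(g)[1:2])
    rf <- g
    rf$chromosomes[[1]]$body <- -rev(rf$chromosomes[[1]]$body)
    base <- sort(element_summary(g))
    expect_equal(sort(element_summary(sw)), base)
    expect_equal(sort(element_summary(rf)), base)
  }
})
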