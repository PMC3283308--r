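test_that("overlap graph intervals, orientation and proper crossing", {
  og <- build_overlap_graph(fx$E2)
  v1 <- og$vertices[og$vertices$family == 1, ]
  expect_true(v1$oriented && !v1$sorted)
  v2 <- og$vertices[og$vertices$family == 2, ]
  expect_true(v2$sorted)
  expect_equal(nrow(og$edges), 0L)
  expect_true(orientation_status(og)$oriented)

  og5 <- build_overlap_graph(fx$E5)  # (1 -2 -1' -2'): intervals [1,3] x [2,4]
  expect_equal(nrow(og5$edges), 1L)
  expect_true(og5$vertices$oriented[og5$vertices$family == 1])
  expect_false(og5$vertices$oriented[og5$vertices$family == 2])
  expect_true(orientation_status(og5)$oriented)

  # all-positive signs: unoriented
  st3 <- orientation_status(build_overlap_graph(fx$E3))
  expect_false(st3$oriented)
  expect_length(st3$offending, 1L)
  # dedoubled genome: vacuously oriented
  expect_true(orientation_status(build_overlap_graph(fx$E1))$oriented)
  expect_error(build_overlap_graph(fx$circ2), "not_unichromosomal")
})

test_that("the big worked genome has four oriented overlap components", {
  og <- build_overlap_graph(fx$worked26)
  expect_equal(length(og$components), 4L)
  expect_true(all(og$component_oriented, na.rm = TRUE))
  expect_true(orientation_status(og)$oriented)
  comp_sets <- lapply(og$components, sort)
  expect_true(any(vapply(comp_sets, identical, logical(1), c(1L, 2L))))
  expect_true(any(vapply(comp_sets, identical, logical(1), c(7L, 8L))))
  expect_true(any(vapply(comp_sets, identical, logical(1), c(11L, 12L, 13L))))
  expect_true(any(vapply(comp_sets, identical, logical(1),
                         c(3L, 4L, 5L, 6L, 9L, 10L))))
})

test_that("rho and rho_bar sort the couple and agree on the score", {
  expect_equal(write_genome(apply_rho(fx$E2, 1, "rho")), "L 1 1' 2 2'")
  expect_equal(write_genome(apply_rho(fx$E2, 1, "rho_bar")), "L -1 -1' 2 2'")
  expect_equal(vertex_score(fx$E2, 1), 0L)
  expect_equal(vertex_score(fx$E5, 1), 1L)
  expect_error(apply_rho(fx$E3, 1), "unoriented_vertex")
  expect_error(vertex_score(fx$E1, 1), "unoriented_vertex")

  score_via <- function(g, f, variant) {
    h <- apply_rho(g, f, variant)
    oh <- build_overlap_graph(h)
    sum(oh$vertices$oriented & !oh$vertices$sorted)
  }
  checked <- 0L
  for (s in 1:150) {
    g <- random_duplicated_genome(2L + s %% 5L, seed = 40000 + s)
    og <- build_overlap_graph(g)
    ok <- og$vertices$family[og$vertices$oriented & !og$vertices$sorted]
    for (f in ok) {
      expect_equal(score_via(g, f, "rho"), score_via(g, f, "rho_bar"))
      h <- apply_rho(g, f)
      oh <- build_overlap_graph(h)
      expect_true(oh$vertices$sorted[oh$vertices$family == f])
      checked <- checked + 1L
    }
    if (checked >= 300L) break
  }
  expect_gte(checked, 300L)
})

test_that("a sorting reversal acts as local complementation on the overlap graph", {
  edge_key <- function(ed) {
    if (!nrow(ed)) return(character(0))
    sort(paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2])))
  }
  checked <- 0L
  for (s in 1:120) {
    g <- random_duplicated_genome(2L + s %% 5L, seed = 70000 + s)
    og <- build_overlap_graph(g)
    ok <- og$vertices$family[og$vertices$oriented & !og$vertices$sorted]
    for (f in ok) {
      predicted <- gdd:::local_complement(og, f)
      rebuilt <- build_overlap_graph(apply_rho(g, f, "rho"))
      expect_setequal(edge_key(predicted$edges), edge_key(rebuilt$edges))
      po <- predicted$vertices[order(predicted$vertices$family), ]
      ro <- rebuilt$vertices[order(rebuilt$vertices$family), ]
      keep <- !po$sorted & !ro$sorted
      expect_equal(po$oriented[keep], ro$oriented[keep])
      checked <- checked + 1L
    }
    if (checked >= 200L) break
  }
  expect_gte(checked, 200L)
})

test_that("reversal distance equals the linear DCJ distance on oriented genomes", {
  expect_equal(reversal_distance(fx$E2)$distance, 1L)
  expect_equal(reversal_distance(fx$E5)$distance, 2L)
  expect_equal(reversal_distance(totalize(random_ancestor(4, seed = 5))$genome)$distance,
               0L)
  expect_error(reversal_distance(fx$E3), "unoriented_genome")
  for (s in 1:30) {
    g <- random_oriented_genome(2L + s %% 5L, seed = s)
    rv <- reversal_distance(g)
    expect_equal(rv$distance, dcj_distance_linear(g)$distance)
    expect_gte(rv$distance, dcj_distance(g)$distance)
  }
  # brute-force agreement at tiny sizes
  for (s in 1:10) {
    g <- random_oriented_genome(3, seed = 100 + s)
    expect_equal(reversal_distance(g)$distance, bfs_oracle(g, "reversal"))
  }
})

test_that("reversal sorting is optimal and keeps every intermediate oriented", {
  expect_length(reversal_sort(totalize(random_ancestor(4, seed = 6))$genome)$scenario,
                0L)
  res5 <- reversal_sort(fx$E5)
  expect_length(res5$scenario, 2L)
  expect_true(is_dedoubled(res5$genome))

  for (s in 1:40) {
    g <- random_oriented_genome(2L + s %% 5L, seed = 200 + s)
    res <- reversal_sort(g)
    expect_equal(length(res$scenario), res$report$distance)
    expect_true(all(vapply(res$scenario$ops, function(op) op$kind == "REVERSAL",
                           logical(1))))
    cur <- g
    for (op in res$scenario$ops) {
      cur <- gdd:::apply_op(cur, op)
      expect_true(gdd:::is_single_linear(cur))
      expect_true(orientation_status(build_overlap_graph(cur))$oriented)
    }
    expect_genome_equal(cur, res$genome)
    expect_true(is_dedoubled(cur))
  }
})
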