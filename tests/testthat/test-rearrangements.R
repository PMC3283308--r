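test_that("DCJ cuts and rejoins exactly two adjacencies", {
  g <- fx$E4
  r1 <- apply_dcj(g, "(1,2)", "(2',1')", 2)
  expect_true(is_dedoubled(r1))
  expect_length(r1$chromosomes, 2L)   # (1 1') linear plus circular (2 2')
  r2 <- apply_dcj(g, "(1,2)", "(2',1')", 1)
  expect_equal(write_genome(r2), "L 1 -2' -2 1'")
  expect_error(apply_dcj(g, "(1,1')", "(2,2')", 1), "adjacency_not_found")
  expect_error(apply_dcj(g, "(1,2)", "(1,2)", 1), "identical_cuts")
  # all adjacencies other than the cut pair survive
  before <- adjacencies(g)
  after <- adjacencies(r2)
  expect_length(setdiff(before, after), 2L)
  expect_length(setdiff(after, before), 2L)
})

test_that("a reversal inverts the segment between its cuts", {
  expect_equal(write_genome(apply_reversal(fx$E2, "(1,-1')", "(-1',2)")),
               "L 1 1' 2 2'")
  expect_equal(write_genome(apply_reversal(fx$E4, "(1,2)", "(1',$)")),
               "L 1 -1' -2' -2")
  # involution
  g <- fx$E6
  h <- apply_reversal(apply_reversal(g, "(2',1')", "(5,6)"),
                      "(2',-5)", "(-1',6)")
  expect_genome_equal(g, h)
  expect_error(apply_reversal(parse_genome("L 1 2\nL 3"), "(1,2)", "(3,$)"),
               "different_chromosomes")
})

test_that("a reversal is a DCJ with the orientation-reversing rejoin", {
  for (s in 1:30) {
    g <- random_duplicated_genome(4, seed = 500 + s)
    amat <- gdd:::adjacency_matrix(g)
    set.seed(s)
    ij <- sample(ncol(amat), 2L)
    rv <- apply_reversal(g, amat[, ij[1]], amat[, ij[2]])
    hit <- vapply(1:2, function(p) {
      genome_equal(rv, apply_dcj(g, amat[, ij[1]], amat[, ij[2]], p))
    }, logical(1))
    expect_true(any(hit))
  }
})

test_that("BD operations duplicate at the breakpoint and nothing else", {
  b <- parse_genome("L -2 -1 4 -3")
  op <- gdd_op("BD2_DCJ", "(-2,-1)", "(4,-3)", pattern = 2,
               dups = list(list(family = 2L, cut = 1L),
                           list(family = 4L, cut = 2L)))
  bb <- apply_bd(b, op)
  tab <- table(gdd:::marker_family(gdd:::genome_markers(bb)))
  expect_equal(tab[["2"]], 2L)
  expect_equal(tab[["4"]], 2L)
  expect_equal(tab[["1"]], 1L)
  expect_equal(tab[["3"]], 1L)
  # adjacencies away from the cuts are untouched
  expect_true(all(c("(2,$)", "(-1,4)", "(-3,$)") %in% adjacencies(bb)))

  b2 <- parse_genome("L 2 -1 -3 4")
  op2 <- gdd_op("BD1_REVERSAL", "(2,-1)", "(-3,4)",
                dups = list(list(family = 2L, cut = 1L)))
  r <- apply_bd(b2, op2)
  expect_equal(write_genome(r), "L 2 3 1 -2' 4")  # copies flank the breakpoint
  expect_length(r$chromosomes, 1L)

  dupg <- parse_genome("L 2 2' -1 -3 4")
  expect_error(apply_bd(dupg, op2), "already_duplicated")
})

test_that("scenarios fold left to right and report the failing step", {
  g <- fx$E4
  expect_genome_equal(apply_scenario(g, new_scenario()), g)
  s <- new_scenario(list(
    gdd_op("DCJ", "(1,2)", "(2',1')", 2),
    gdd_op("DCJ", "(1,2)", "(2,2')", 1)))  # stale cut: (1,2) is gone
  expect_error(apply_scenario(g, s), "step_2")
  snap <- apply_scenario(g, new_scenario(list(gdd_op("DCJ", "(1,2)", "(2',1')", 2))),
                         snapshots = TRUE)
  expect_length(snap$steps, 1L)
  expect_true(is_dedoubled(snap$genome))
})

test_that("a BD-reversal scenario from a small ancestor adds one copy per duplication", {
  anc <- parse_genome("L 1 2 3 4 5")
  sim <- random_bd_evolution(anc, 4L, model = "reversal", seed = 42)
  nd <- sum(vapply(sim$scenario$ops, function(op) length(op$dups), integer(1)))
  expect_equal(length(gdd:::genome_markers(sim$derived)), 5L + nd)
  expect_true(is_single_linear(sim$derived))
})

test_that("lifting a BD scenario yields an equal-length plain scenario from a dedoubled genome", {
  # trivial: no BD ops
  anc <- random_ancestor(5, seed = 3)
  sim0 <- random_bd_evolution(anc, 2L, model = "dcj", seed = 9,
                              probs = c(bd1 = 0, bd2 = 0, plain = 1))
  lf0 <- lift_bd_scenario(anc, sim0$scenario)
  expect_genome_equal(lf0$dedoubled, anc)
  expect_length(lf0$plain, 2L)

  for (s in 1:50) {
    model <- if (s %% 2 == 0) "dcj" else "reversal"
    anc <- random_ancestor(5 + s %% 3, seed = s)
    sim <- random_bd_evolution(anc, 1L + s %% 4L, model = model, seed = 700 + s)
    lf <- lift_bd_scenario(anc, sim$scenario)
    expect_length(lf$plain, length(sim$scenario))
    expect_genome_equal(reduce_dedoubled(lf$dedoubled), anc)
    expect_true(is_dedoubled(lf$dedoubled))
    expect_genome_equal(apply_scenario(lf$dedoubled, lf$plain), sim$derived)
    if (model == "reversal") {
      kinds <- vapply(lf$plain$ops, `[[`, character(1), "kind")
      expect_true(all(kinds == "REVERSAL"))
    }
  }
})

test_that("scenario text round-trips through the file format", {
  g <- fx$E4
  res <- dcj_sort_linear(g)
  txt <- write_scenario(res$scenario, g)
  s2 <- read_scenario(txt)
  expect_genome_equal(apply_scenario(g, s2), res$genome)
  # BD ops keep their duplication annotations
  op <- gdd_op("BD1_DCJ", "(2,-1)", "(-3,4)", pattern = 1,
               dups = list(list(family = 2L, cut = 1L)))
  txt2 <- gdd:::format_op(op)
  op2 <- read_scenario(txt2)$ops[[1]]
  expect_equal(op2$kind, "BD1_DCJ")
  expect_equal(op2$dups[[1]]$family, 2L)
})
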