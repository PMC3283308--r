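# DCJ dedoubling distances and scenarios.
#
# Multichromosomal case: d = n - C_i, where C_i is the maximum number of
# pairwise independent non-duplicated cycles of A(G).  Linear unichromosomal
# case (the final genome must again be one linear chromosome): d = n - C + 2m
# with C the number of cycles of A(G) and m = C - C_i the minimum number of
# cycle merges needed to make the path valid.

new_distance_report <- function(n, C, C_i, m, distance, model, method) {
  structure(list(n = n, C = C, C_i = C_i, m = m, distance = distance,
                 model = model, method = method), class = "gdd_distance")
}

#' @export
print.gdd_distance <- function(x, ...) {
  cat(sprintf("%s dedoubling distance: %d  (n=%d, C=%d, C_i=%d%s; %s)\n",
              x$model, x$distance, x$n, x$C, x$C_i,
              if (!is.na(x$m)) sprintf(", m=%d", x$m) else "",
              x$method))
  invisible(x)
}

solve_selection <- function(g, method, mis_limit) {
  gr <- build_adjacency_graph(g)
  cg <- build_conflict_graph(gr)
  sel <- max_independent_cycles(cg, method = method, limit = mis_limit)
  C <- sum(vapply(gr$elements, function(el) el$kind == "cycle", logical(1)))
  list(gr = gr, cg = cg, sel = sel, C = C)
}

#' DCJ dedoubling distance
#'
#' Minimum number of DCJ operations transforming a totally duplicated genome
#' into a dedoubled genome: `n - C_i`.  Callers holding a genome that is only
#' partially duplicated should pass it through [totalize()] first.
#'
#' @param g A totally duplicated `gdd_genome`.
#' @param method Independent-cycle selection method, `"exact"` or `"greedy"`.
#' @param mis_limit Node gate for the exact selector.
#' @return A `gdd_distance` report (fields `n`, `C`, `C_i`, `m`, `distance`).
#' @examples
#' dcj_distance(parse_genome("L 1 2 2' 1'"))
#' @export
dcj_distance <- function(g, method = c("exact", "greedy"), mis_limit = 25L) {
  method <- match.arg(method)
  st <- solve_selection(g, method, mis_limit)
  new_distance_report(st$gr$n, st$C, st$sel$C_i, NA_integer_,
                      st$gr$n - st$sel$C_i, "dcj", method)
}

#' DCJ dedoubling distance with a linear unichromosomal end state
#'
#' Minimum length of a DCJ scenario from a totally duplicated single linear
#' chromosome to a dedoubled genome that is again a single linear chromosome:
#' `n - C + 2m`.  Intermediate genomes may contain circular chromosomes.
#'
#' @inheritParams dcj_distance
#' @return A `gdd_distance` report.
#' @examples
#' dcj_distance_linear(parse_genome("L 1 2 2' 1'"))
#' @export
dcj_distance_linear <- function(g, method = c("exact", "greedy"), mis_limit = 25L) {
  method <- match.arg(method)
  if (!is_single_linear(g)) {
    stop("gdd_not_unichromosomal: the linear model needs one linear chromosome",
         call. = FALSE)
  }
  st <- solve_selection(g, method, mis_limit)
  mc <- merge_count(st$gr, st$sel)
  new_distance_report(st$gr$n, mc$C, st$sel$C_i, mc$m,
                      st$gr$n - mc$C + 2L * mc$m, "dcj_linear", method)
}

# The sorting DCJ of one couple edge: cut the edge's two endpoint adjacencies
# and rejoin the paralogous extremities into the dedoubled pair adjacency.
# Returns a gdd_op (pattern 1 pairs the couple extremities by construction).
one_shot_op <- function(gr, eid) {
  f <- gr$edges$family[eid]
  p <- 2L * f; b <- p + 1L
  if (gr$edges$which[eid] == "head") {
    x1 <- ext_head(p); x2 <- ext_tail(b)
  } else {
    x1 <- ext_tail(p); x2 <- ext_head(b)
  }
  other_slot <- function(x) {
    col <- which(gr$amat[1, ] == x | gr$amat[2, ] == x)[1]
    pair <- gr$amat[, col]
    if (pair[1] == x) pair[2] else pair[1]
  }
  gdd_op("DCJ", c(x1, other_slot(x1)), c(x2, other_slot(x2)), pattern = 1L)
}

# element index whose couples match `set` exactly (as a multiset), or NA
find_element_by_couples <- function(gr, set, kind = "cycle") {
  for (i in seq_along(gr$elements)) {
    el <- gr$elements[[i]]
    if (el$kind == kind && identical(sort(el$couples), sort(set))) return(i)
  }
  NA_integer_
}

sorted_couples <- function(g) {
  dup <- duplicated_families(g)
  if (!length(dup)) return(integer(0))
  amat <- adjacency_matrix(g)
  keys <- adj_key(amat[1, ], amat[2, ])
  dup[vapply(dup, function(f) {
    dd <- dedoubled_adj_keys(f)
    any(adj_key(dd[1, ], dd[2, ]) %in% keys)
  }, logical(1))]
}

#' DCJ dedoubling scenario
#'
#' Builds an optimal scenario of length `n - C_i`: every selected independent
#' cycle with k couples is resolved by k-1 self-loop extractions (its last
#' couple comes out sorted for free), and every couple not covered by the
#' selection is sorted by a single DCJ on one of its edges.  Operations touch
#' only adjacencies of the element being resolved, so sorted couples are
#' never disturbed.
#'
#' @param g A totally duplicated `gdd_genome`.
#' @param mis_limit Node gate for the exact cycle selection.
#' @return `list(scenario, genome, report)`: the scenario, the dedoubled end
#'   genome, and the distance report it realizes.
#' @export
dcj_sort <- function(g, mis_limit = 25L) {
  st <- solve_selection(g, "exact", mis_limit)
  covered <- lapply(st$sel$S_i, function(i) st$gr$elements[[i]]$couples)
  ops <- list()
  cur <- g
  # phase A: resolve each selected cycle internally
  for (set in covered[order(vapply(covered, min, numeric(1)))]) {
    remaining <- set
    while (length(remaining) > 1L) {
      gr <- build_adjacency_graph(cur)
      ei <- find_element_by_couples(gr, remaining)
      if (is.na(ei)) stop("gdd_internal: selected cycle lost during sorting")
      x <- min(remaining)
      eid <- gr$elements[[ei]]$edges[gr$edges$family[gr$elements[[ei]]$edges] == x][1]
      op <- one_shot_op(gr, eid)
      cur <- apply_op(cur, op)
      ops[[length(ops) + 1L]] <- op
      remaining <- setdiff(remaining, x)
    }
  }
  # phase B: one DCJ per uncovered couple
  uncovered <- setdiff(duplicated_families(g), unlist(covered))
  for (x in sort(uncovered)) {
    if (x %in% sorted_couples(cur)) next
    gr <- build_adjacency_graph(cur)
    eid <- which(gr$edges$family == x & gr$edges$which == "head")
    op <- one_shot_op(gr, eid)
    cur <- apply_op(cur, op)
    ops[[length(ops) + 1L]] <- op
  }
  if (!is_dedoubled(cur)) stop("gdd_internal: sorting did not reach a dedoubled genome")
  rep <- new_distance_report(st$gr$n, st$C, st$sel$C_i, NA_integer_,
                             st$gr$n - st$sel$C_i, "dcj", "exact")
  if (length(ops) != rep$distance) {
    stop("gdd_internal: scenario length ", length(ops),
         " != distance ", rep$distance)
  }
  list(scenario = new_scenario(ops), genome = cur, report = rep)
}

# exact remaining linear-model distance of an intermediate state holding
# exactly one linear chromosome (plus possibly circular ones)
linear_measure <- function(g, mis_limit = 25L) {
  st <- solve_selection(g, "exact", mis_limit)
  st$gr$n + st$C - 2L * st$sel$C_i
}

count_linear <- function(g) sum(!chromosome_shapes(g))

#' DCJ dedoubling scenario with a linear unichromosomal end state
#'
#' First merges every cycle outside the selected independent set into the
#' path (m merging DCJs, realized as reversals), then sorts couples one DCJ
#' at a time, choosing at each step an operation that provably decreases the
#' remaining distance `n - C + 2m` by one and ends with a dedoubled single
#' linear chromosome.  Intermediates may carry circular chromosomes, which
#' are reabsorbed by the end.
#'
#' @inheritParams dcj_sort
#' @return `list(scenario, genome, report)`.
#' @export
dcj_sort_linear <- function(g, mis_limit = 25L) {
  if (!is_single_linear(g)) {
    stop("gdd_not_unichromosomal: the linear model needs one linear chromosome",
         call. = FALSE)
  }
  st <- solve_selection(g, "exact", mis_limit)
  mc <- merge_count(st$gr, st$sel)
  target <- st$gr$n - mc$C + 2L * mc$m
  ops <- list()
  cur <- g
  # phase 1: merge every non-selected cycle into the path (a reversal on one
  # cycle adjacency and one path adjacency; C drops by one, m by one)
  merge_sets <- lapply(mc$to_merge, function(i) st$gr$elements[[i]]$couples)
  for (set in merge_sets[order(vapply(merge_sets, min, numeric(1)))]) {
    gr <- build_adjacency_graph(cur)
    ei <- find_element_by_couples(gr, set)
    if (is.na(ei)) stop("gdd_internal: cycle to merge lost")
    path_i <- which(vapply(gr$elements, function(el) el$kind == "path", logical(1)))[1]
    cvs <- gr$elements[[ei]]$vertices
    pvs <- gr$elements[[path_i]]$vertices
    cut1 <- gr$amat[, min(cvs)]
    g1 <- locate_adjacency(cur, cut1)$gap
    spans <- vapply(pvs, function(v) {
      abs(locate_adjacency(cur, gr$amat[, v])$gap - g1)
    }, numeric(1))
    cut2 <- gr$amat[, pvs[order(spans, pvs)][1]]
    op <- gdd_op("REVERSAL", cut1, cut2)
    cur <- apply_op(cur, op)
    ops[[length(ops) + 1L]] <- op
  }
  # phase 2: sort couples, one measure-decreasing DCJ per step
  repeat {
    unsorted <- setdiff(duplicated_families(cur), sorted_couples(cur))
    if (!length(unsorted) && is_single_linear(cur)) break
    cur_measure <- linear_measure(cur, mis_limit)
    gr <- build_adjacency_graph(cur)
    best <- NULL
    for (x in sort(unsorted)) {
      for (w in c("head", "tail")) {
        eid <- which(gr$edges$family == x & gr$edges$which == w)
        if (gr$edges$v1[eid] == gr$edges$v2[eid]) next  # already a self-loop
        op <- one_shot_op(gr, eid)
        res <- tryCatch(apply_op(cur, op), error = function(e) NULL)
        if (is.null(res) || count_linear(res) != 1L) next
        if (linear_measure(res, mis_limit) == cur_measure - 1L) {
          cand <- list(op = op, res = res,
                       circ = sum(chromosome_shapes(res)))
          if (is.null(best) || cand$circ < best$circ) best <- cand
        }
      }
    }
    if (is.null(best)) {
      # fall back to a search over all DCJs keeping one linear chromosome
      amat <- adjacency_matrix(cur)
      A <- ncol(amat)
      for (i in seq_len(A - 1L)) {
        for (j in (i + 1L):A) {
          for (p in 1:2) {
            op <- gdd_op("DCJ", amat[, i], amat[, j], pattern = p)
            res <- tryCatch(apply_op(cur, op), error = function(e) NULL)
            if (is.null(res) || count_linear(res) != 1L) next
            if (linear_measure(res, mis_limit) == cur_measure - 1L) {
              best <- list(op = op, res = res); break
            }
          }
          if (!is.null(best)) break
        }
        if (!is.null(best)) break
      }
    }
    if (is.null(best)) {
      stop("gdd_internal: no distance-decreasing DCJ found in the linear model")
    }
    cur <- best$res
    ops[[length(ops) + 1L]] <- best$op
  }
  if (!is_dedoubled(cur) || !is_single_linear(cur)) {
    stop("gdd_internal: linear sorting did not reach a dedoubled linear genome")
  }
  rep <- new_distance_report(st$gr$n, mc$C, st$sel$C_i, mc$m, target,
                             "dcj_linear", "exact")
  if (length(ops) != target) {
    stop("gdd_internal: scenario length ", length(ops), " != distance ", target)
  }
  list(scenario = new_scenario(ops), genome = cur, report = rep)
}
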