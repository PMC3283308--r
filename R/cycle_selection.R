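# Selecting a maximum-size set of pairwise independent non-duplicated cycles
# of the dedoubled adjacency graph.  This is the APX-complete core of both
# dedoubling distances: the exact branch-and-bound solver is the default at
# desk scale, the deterministic greedy provides the scalable alternative
# (empirically within the factor-2 contract of the exact optimum).

#' Build the conflict graph of non-duplicated cycles
#'
#' Nodes are the non-duplicated cycles of A(G); two nodes are linked when the
#' cycles intersect, i.e. share at least one couple.
#'
#' @param gr A `gdd_agraph`.
#' @return A `gdd_conflict`: list with `nodes` (element indices into
#'   `gr$elements`), `couples` (couple set per node), `adj` (neighbour list,
#'   indices into `nodes`), `shared` (couples shared per link).
#' @export
build_conflict_graph <- function(gr) {
  idx <- which(vapply(gr$elements, function(el) {
    el$kind == "cycle" && !el$duplicated
  }, logical(1)))
  couples <- lapply(gr$elements[idx], `[[`, "couples")
  N <- length(idx)
  adj <- vector("list", N)
  shared <- list()
  if (N > 1L) {
    for (i in seq_len(N - 1L)) {
      for (j in (i + 1L):N) {
        sh <- intersect(couples[[i]], couples[[j]])
        if (length(sh)) {
          adj[[i]] <- c(adj[[i]], j)
          adj[[j]] <- c(adj[[j]], i)
          shared[[paste(i, j)]] <- sh
        }
      }
    }
  }
  structure(list(nodes = idx, couples = couples, adj = adj, shared = shared),
            class = "gdd_conflict")
}

#' @export
print.gdd_conflict <- function(x, ...) {
  cat("Conflict graph:", length(x$nodes), "non-duplicated cycle(s),",
      length(x$shared), "link(s)\n")
  invisible(x)
}

# exact maximum independent set by branch and bound on the max-degree node
mis_exact <- function(adj) {
  N <- length(adj)
  if (N == 0L) return(integer(0))
  best <- integer(0)
  rec <- function(cand, cur) {
    if (length(cur) + length(cand) <= length(best)) return()
    if (!length(cand)) {
      if (length(cur) > length(best)) best <<- cur
      return()
    }
    deg <- vapply(cand, function(v) length(intersect(adj[[v]], cand)), integer(1))
    if (all(deg == 0L)) {
      tot <- c(cur, cand)
      if (length(tot) > length(best)) best <<- tot
      return()
    }
    v <- cand[which.max(deg)]
    rec(setdiff(cand, c(v, adj[[v]])), c(cur, v))  # include v
    rec(setdiff(cand, v), cur)                     # exclude v
  }
  rec(seq_len(N), integer(0))
  sort(best)
}

# deterministic greedy: repeatedly take the node of minimum current degree,
# deleting its neighbours; ties by smaller couple set, then lexicographic
# couples, then node index
mis_greedy <- function(adj, couples) {
  N <- length(adj)
  alive <- rep(TRUE, N)
  chosen <- integer(0)
  couple_key <- vapply(couples, function(cs) {
    sprintf("%03d|%s", length(cs), paste(sprintf("%06d", sort(cs)), collapse = ","))
  }, character(1))
  while (any(alive)) {
    cand <- which(alive)
    deg <- vapply(cand, function(v) sum(alive[adj[[v]]]), integer(1))
    sel <- cand[deg == min(deg)]
    v <- sel[order(couple_key[sel], sel)][1]
    chosen <- c(chosen, v)
    alive[c(v, adj[[v]])] <- FALSE
  }
  sort(chosen)
}

#' Maximum set of pairwise independent non-duplicated cycles
#'
#' The exact method is a branch-and-bound over the conflict graph (guaranteed
#' optimal, gated by `limit` nodes); the greedy method is a deterministic
#' minimum-degree heuristic.
#'
#' @param cg A `gdd_conflict` from [build_conflict_graph()].
#' @param method `"exact"` or `"greedy"`.
#' @param limit Node-count gate for the exact solver.
#' @return A list with `S_i` (selected element indices into the adjacency
#'   graph's elements), `C_i` (their number), `method`, and `certificate`.
#' @export
max_independent_cycles <- function(cg, method = c("exact", "greedy"), limit = 25L) {
  method <- match.arg(method)
  N <- length(cg$nodes)
  if (method == "exact") {
    if (N > limit) {
      stop("gdd_size_limit: exact solver gated at ", limit,
           " nodes (", N, " present); raise `limit` or use method = \"greedy\"",
           call. = FALSE)
    }
    picked <- mis_exact(cg$adj)
    cert <- "branch-and-bound over all independent subsets"
  } else {
    picked <- mis_greedy(cg$adj, cg$couples)
    cert <- "greedy minimum-degree heuristic"
  }
  list(S_i = cg$nodes[picked], C_i = length(picked), method = method,
       certificate = cert)
}

#' Number of cycle merges needed to make the path valid
#'
#' For a totally duplicated genome on one linear chromosome, the minimum
#' number m of cycles that must be merged into the path so that the path
#' contains every couple satisfies m = C - C_i, where C counts all cycles of
#' A(G).  The cycles to merge are exactly those outside the selected set.
#'
#' @param gr A `gdd_agraph` of a linear unichromosomal genome.
#' @param sel Result of [max_independent_cycles()].
#' @return List with `m`, `C`, `C_i`, and `to_merge` (element indices of the
#'   cycles outside the selection).
#' @export
merge_count <- function(gr, sel) {
  if (!is_single_linear(gr$genome)) {
    stop("gdd_not_unichromosomal: merge count needs one linear chromosome",
         call. = FALSE)
  }
  cycles <- which(vapply(gr$elements, function(el) el$kind == "cycle", logical(1)))
  C <- length(cycles)
  m <- C - sel$C_i
  list(m = m, C = C, C_i = sel$C_i, to_merge = setdiff(cycles, sel$S_i))
}
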