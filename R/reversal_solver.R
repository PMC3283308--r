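# Reversal dedoubling of oriented linear unichromosomal genomes, via a
# dedoubled overlap graph in the style of Hannenhalli-Pevzner arc overlap
# graphs: one vertex per couple carrying the smallest interval containing its
# two copies; an edge when two intervals properly cross (they intersect and
# neither contains the other); a vertex is oriented when its copies are
# written with opposite signs, and sorted when the couple already forms a
# dedoubled adjacency.  Sorted vertices are isolated and excluded from the
# oriented/unoriented component classification.

#' Build the dedoubled overlap graph
#'
#' @param g A totally duplicated `gdd_genome` on one linear chromosome.
#' @return A `gdd_overlap`: list with `vertices` (data frame: `family`, `lo`,
#'   `hi` 1-based closed interval, `oriented`, `sorted`), `edges` (two-column
#'   matrix of family pairs), `components` (list of family vectors),
#'   `component_oriented` (flag per component, ignoring sorted vertices).
#' @examples
#' og <- build_overlap_graph(parse_genome("L 1 -2 -1' -2'"))
#' og$vertices
#' @export
build_overlap_graph <- function(g) {
  if (!is_single_linear(g)) {
    stop("gdd_not_unichromosomal: the overlap graph needs one linear chromosome",
         call. = FALSE)
  }
  if (!is_totally_duplicated(g)) {
    stop("gdd_not_totally_duplicated", call. = FALSE)
  }
  b <- g$chromosomes[[1]]$body
  fams <- sort(duplicated_families(g))
  n <- length(fams)
  v <- data.frame(family = fams, lo = integer(n), hi = integer(n),
                  oriented = logical(n), sorted = logical(n))
  for (i in seq_len(n)) {
    pos <- which(marker_family(b) == fams[i])
    v$lo[i] <- pos[1]; v$hi[i] <- pos[2]
    s <- marker_sign(b[pos])
    v$oriented[i] <- s[1] != s[2]
    v$sorted[i] <- pos[2] == pos[1] + 1L && s[1] == s[2]
  }
  crosses <- function(i, j) {
    inside <- function(x, lo, hi) x > lo & x < hi
    sum(inside(c(v$lo[j], v$hi[j]), v$lo[i], v$hi[i])) == 1L
  }
  ed <- matrix(integer(0), ncol = 2)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (crosses(i, j)) ed <- rbind(ed, c(fams[i], fams[j]))
      }
    }
  }
  ig <- igraph::graph_from_data_frame(
    d = if (nrow(ed)) data.frame(from = as.character(ed[, 1]),
                                 to = as.character(ed[, 2]))
        else data.frame(from = character(0), to = character(0)),
    directed = FALSE,
    vertices = data.frame(name = as.character(fams)))
  comp <- igraph::components(ig)
  comps <- split(fams, comp$membership)
  comp_oriented <- vapply(comps, function(cf) {
    idx <- match(cf, fams)
    unsor <- idx[!v$sorted[idx]]
    if (!length(unsor)) return(NA)     # all-sorted component: ignored
    any(v$oriented[unsor])
  }, logical(1))
  structure(list(vertices = v, edges = ed, components = unname(comps),
                 component_oriented = unname(comp_oriented), genome = g),
            class = "gdd_overlap")
}

#' @export
print.gdd_overlap <- function(x, ...) {
  st <- orientation_status(x)
  cat("Dedoubled overlap graph:", nrow(x$vertices), "vertices,",
      nrow(x$edges), "edges,", length(x$components), "component(s);",
      "genome", if (st$oriented) "oriented" else "unoriented", "\n")
  invisible(x)
}

#' Orientation status of an overlap graph
#'
#' A component is oriented when it contains at least one oriented vertex; the
#' genome is oriented when every component holding an unsorted vertex is
#' oriented (components made only of sorted vertices are vacuously fine).
#'
#' @param og A `gdd_overlap`.
#' @return List with `oriented` (flag) and `offending` (list of unoriented
#'   components, as family vectors).
#' @export
orientation_status <- function(og) {
  bad <- which(!is.na(og$component_oriented) & !og$component_oriented)
  list(oriented = length(bad) == 0L, offending = og$components[bad])
}

is_oriented_genome <- function(g) {
  orientation_status(build_overlap_graph(g))$oriented
}

#' Apply the sorting reversal of an oriented vertex
#'
#' For a couple with copies at positions `i < j` carrying opposite signs, the
#' `rho` variant reverses positions `i+1..j` and the `rho_bar` variant
#' reverses `i..j-1`; either way the couple forms a dedoubled adjacency
#' afterwards.  On the overlap graph the effect is a local complementation:
#' the subgraph induced by the vertex and its neighbours is complemented and
#' their orientations flip.
#'
#' @param g A totally duplicated linear unichromosomal `gdd_genome`.
#' @param family The couple to sort; must be oriented and unsorted.
#' @param variant `"rho"` or `"rho_bar"`.
#' @return The reversed `gdd_genome`.
#' @examples
#' write_genome(apply_rho(parse_genome("L 1 -1' 2 2'"), 1))
#' @export
apply_rho <- function(g, family, variant = c("rho", "rho_bar")) {
  variant <- match.arg(variant)
  og <- build_overlap_graph(g)
  v <- og$vertices[og$vertices$family == family, ]
  if (!nrow(v)) stop("gdd_invalid_genome: no couple ", family, call. = FALSE)
  if (!v$oriented || v$sorted) {
    stop("gdd_unoriented_vertex: couple ", family,
         " is not an oriented unsorted vertex", call. = FALSE)
  }
  if (variant == "rho") {
    reverse_segment(g, 1L, v$lo, v$hi)          # gaps lo..hi: positions lo+1..hi
  } else {
    reverse_segment(g, 1L, v$lo - 1L, v$hi - 1L) # positions lo..hi-1
  }
}

#' Score of an oriented vertex
#'
#' The number of oriented (unsorted) vertices in the overlap graph of the
#' genome obtained by applying the vertex's sorting reversal; `rho` and
#' `rho_bar` give the same count.
#'
#' @inheritParams apply_rho
#' @return Integer score.
#' @export
vertex_score <- function(g, family) {
  h <- apply_rho(g, family, "rho")
  oh <- build_overlap_graph(h)
  sum(oh$vertices$oriented & !oh$vertices$sorted)
}

# Overlap-graph effect of rho(family) computed purely combinatorially:
# complement the subgraph induced by the vertex and its neighbours and flip
# their orientations; the vertex itself comes out sorted and isolated.  Used
# as the dual route to validate the rebuild-from-genome implementation.
local_complement <- function(og, family) {
  v <- og$vertices
  fams <- v$family
  nb <- unique(c(og$edges[og$edges[, 1] == family, 2],
                 og$edges[og$edges[, 2] == family, 1]))
  club <- c(family, nb)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  have <- new.env()
  if (nrow(og$edges)) {
    for (r in seq_len(nrow(og$edges))) {
      assign(key(og$edges[r, 1], og$edges[r, 2]), TRUE, envir = have)
    }
  }
  ed <- matrix(integer(0), ncol = 2)
  all_pairs <- if (length(fams) > 1L) utils::combn(sort(fams), 2L) else
    matrix(integer(0), nrow = 2)
  for (cidx in seq_len(ncol(all_pairs))) {
    a <- all_pairs[1, cidx]; b <- all_pairs[2, cidx]
    present <- exists(key(a, b), envir = have)
    if (a %in% club && b %in% club) present <- !present
    if (a == family || b == family) present <- FALSE  # sorted vertex isolates
    if (present) ed <- rbind(ed, c(a, b))
  }
  flip <- fams %in% club
  v$oriented[flip] <- !v$oriented[flip]
  v$sorted[v$family == family] <- TRUE
  list(vertices = v, edges = ed)
}

#' Reversal dedoubling distance of an oriented genome
#'
#' For an oriented, totally duplicated, linear unichromosomal genome the
#' reversal dedoubling distance equals `n - C` when the path of A(G) is valid
#' and `n - C + 2m` otherwise; it always coincides with the linear DCJ
#' distance.  Unoriented genomes are rejected.
#'
#' @inheritParams dcj_distance
#' @return A `gdd_distance` report.
#' @examples
#' reversal_distance(parse_genome("L 1 -2 -1' -2'"))
#' @export
reversal_distance <- function(g, method = c("exact", "greedy"), mis_limit = 25L) {
  method <- match.arg(method)
  og <- build_overlap_graph(g)
  if (!orientation_status(og)$oriented) {
    stop("gdd_unoriented_genome: reversal dedoubling handles oriented genomes only",
         call. = FALSE)
  }
  st <- solve_selection(g, method, mis_limit)
  mc <- merge_count(st$gr, st$sel)
  new_distance_report(st$gr$n, mc$C, st$sel$C_i, mc$m,
                      st$gr$n - mc$C + 2L * mc$m, "reversal", method)
}

#' Reversal dedoubling scenario
#'
#' Phase 1 merges every cycle outside the selected independent set into the
#' path with a merging reversal (which never creates unoriented components);
#' phase 2 repeatedly applies the sorting reversal of a maximum-score
#' oriented vertex, choosing the variant that extracts a cycle, so that every
#' step sorts one couple and decreases the distance by one.  Should the
#' maximum-score vertex offer no safe variant, all oriented vertices and
#' variants are searched before giving up.
#'
#' @inheritParams dcj_sort
#' @return `list(scenario, genome, report)`; the scenario contains only
#'   reversals and every intermediate genome stays oriented.
#' @export
reversal_sort <- function(g, mis_limit = 25L) {
  og0 <- build_overlap_graph(g)
  if (!orientation_status(og0)$oriented) {
    stop("gdd_unoriented_genome: reversal dedoubling handles oriented genomes only",
         call. = FALSE)
  }
  st <- solve_selection(g, "exact", mis_limit)
  mc <- merge_count(st$gr, st$sel)
  target <- st$gr$n - mc$C + 2L * mc$m
  ops <- list()
  cur <- g
  measure <- function(x) {
    stx <- solve_selection(x, "exact", mis_limit)
    mcx <- merge_count(stx$gr, stx$sel)
    stx$gr$n - mcx$C + 2L * mcx$m
  }
  push <- function(op, res) {
    ops[[length(ops) + 1L]] <<- op
    cur <<- res
  }
  # phase 1: merging reversals
  merge_sets <- lapply(mc$to_merge, function(i) st$gr$elements[[i]]$couples)
  for (set in merge_sets[order(vapply(merge_sets, min, numeric(1)))]) {
    gr <- build_adjacency_graph(cur)
    ei <- find_element_by_couples(gr, set)
    if (is.na(ei)) stop("gdd_internal: cycle to merge lost")
    path_i <- which(vapply(gr$elements, function(el) el$kind == "path", logical(1)))[1]
    cvs <- gr$elements[[ei]]$vertices
    pvs <- gr$elements[[path_i]]$vertices
    found <- FALSE
    cand_cvs <- cvs[order(cvs)]
    for (cv in cand_cvs) {
      cut1 <- gr$amat[, cv]
      g1 <- locate_adjacency(cur, cut1)$gap
      spans <- vapply(pvs, function(v) {
        abs(locate_adjacency(cur, gr$amat[, v])$gap - g1)
      }, numeric(1))
      for (pv in pvs[order(spans, pvs)]) {
        op <- gdd_op("REVERSAL", cut1, gr$amat[, pv])
        res <- apply_op(cur, op)
        if (is_oriented_genome(res) && measure(res) == measure(cur) - 1L) {
          push(op, res); found <- TRUE; break
        }
      }
      if (found) break
    }
    if (!found) stop("gdd_internal: no safe merging reversal found")
  }
  # phase 2: maximum-score sorting reversals
  repeat {
    ogc <- build_overlap_graph(cur)
    vtab <- ogc$vertices
    unsorted <- vtab$family[!vtab$sorted]
    if (!length(unsorted)) break
    orient <- vtab$family[vtab$oriented & !vtab$sorted]
    if (!length(orient)) stop("gdd_internal: stranded unoriented state")
    scores <- vapply(orient, function(f) vertex_score(cur, f), integer(1))
    order_f <- orient[order(-scores, orient)]
    done <- FALSE
    for (f in order_f) {
      for (variant in c("rho", "rho_bar")) {
        res <- apply_rho(cur, f, variant)
        if (!is_oriented_genome(res)) next
        if (measure(res) != measure(cur) - 1L) next
        v <- vtab[vtab$family == f, ]
        cut1 <- if (variant == "rho") gap_adjacency(cur, v$lo) else
          gap_adjacency(cur, v$lo - 1L)
        cut2 <- if (variant == "rho") gap_adjacency(cur, v$hi) else
          gap_adjacency(cur, v$hi - 1L)
        push(gdd_op("REVERSAL", cut1, cut2), res)
        done <- TRUE; break
      }
      if (done) break
    }
    if (!done) stop("gdd_internal: no safe sorting reversal found")
  }
  if (!is_dedoubled(cur) || !is_single_linear(cur)) {
    stop("gdd_internal: reversal sorting failed to dedouble")
  }
  rep <- new_distance_report(st$gr$n, mc$C, st$sel$C_i, mc$m, target,
                             "reversal", "exact")
  if (length(ops) != target) {
    stop("gdd_internal: scenario length ", length(ops), " != distance ", target)
  }
  list(scenario = new_scenario(ops), genome = cur, report = rep)
}

# adjacency (as an extremity pair) at gap `k` of the single linear chromosome
gap_adjacency <- function(g, k) {
  b <- g$chromosomes[[1]]$body
  L <- length(b)
  e1 <- if (k == 0L) 0L else right_ext(b[k])
  e2 <- if (k == L) 0L else left_ext(b[k + 1L])
  c(e1, e2)
}

#' DOT export of the dedoubled overlap graph
#'
#' Oriented vertices are drawn grey, per the usual convention.
#'
#' @param og A `gdd_overlap`.
#' @param file Optional output path.
#' @return DOT source as a single string.
#' @export
overlap_dot <- function(og, file = NULL) {
  lines <- c("graph O {", "  node [shape=circle];")
  for (i in seq_len(nrow(og$vertices))) {
    v <- og$vertices[i, ]
    style <- if (v$oriented) " style=filled fillcolor=grey" else ""
    lines <- c(lines, sprintf("  f%d [label=\"%d [%d,%d]%s\"%s];",
                              v$family, v$family, v$lo, v$hi,
                              if (v$sorted) " sorted" else "", style))
  }
  for (r in seq_len(nrow(og$edges))) {
    lines <- c(lines, sprintf("  f%d -- f%d;", og$edges[r, 1], og$edges[r, 2]))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) { writeLines(lines, file); return(invisible(txt)) }
  txt
}
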