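# The dedoubled adjacency graph A(G) of a totally duplicated genome G:
# vertices are the adjacencies of G; for every couple x there are exactly two
# edges pairing paralogous extremities crosswise,
#   E_head(x): adjacency containing head(x)  --  adjacency containing tail(x')
#   E_tail(x): adjacency containing tail(x)  --  adjacency containing head(x')
# Under this pairing a couple forms a self-loop exactly when it sits in one of
# the two dedoubled adjacency forms (x x') / (x' x).  All vertices have degree
# one (telomeric) or two, so connected components ("elements") are paths and
# cycles; a single linear chromosome yields exactly one path.

#' Build the dedoubled adjacency graph
#'
#' @param g A totally duplicated `gdd_genome`.
#' @return A `gdd_agraph`: list with `amat` (vertex adjacencies, one column
#'   each), `vertex_labels`, `edges` (data frame: `family`, `which`
#'   (head/tail), `v1`, `v2`), `elements` (ordered path/cycle components),
#'   `n` (number of couples), and the genome itself.
#' @examples
#' gr <- build_adjacency_graph(parse_genome("L 1 2 2' 1'"))
#' length(gr$elements)
#' @export
build_adjacency_graph <- function(g) {
  if (!is_totally_duplicated(g)) {
    stop("gdd_not_totally_duplicated: build the graph on a totalized genome",
         call. = FALSE)
  }
  amat <- adjacency_matrix(g)
  A <- ncol(amat)
  all_ext <- c(amat[1, ], amat[2, ])
  colof <- rep(seq_len(A), 2L)
  nz <- all_ext != 0L
  vert_of <- function(ext) colof[nz][match(ext, all_ext[nz])]
  fams <- duplicated_families(g)
  n <- length(fams)
  edges <- data.frame(
    family = rep(fams, each = 2L),
    which = rep(c("head", "tail"), times = n),
    v1 = integer(2L * n), v2 = integer(2L * n))
  for (i in seq_along(fams)) {
    f <- fams[i]; p <- 2L * f; b <- p + 1L
    edges$v1[2L * i - 1L] <- vert_of(ext_head(p))
    edges$v2[2L * i - 1L] <- vert_of(ext_tail(b))
    edges$v1[2L * i] <- vert_of(ext_tail(p))
    edges$v2[2L * i] <- vert_of(ext_head(b))
  }
  gr <- structure(list(
    genome = g, amat = amat,
    vertex_labels = vapply(seq_len(A), function(i) format_adjacency(amat[, i]),
                           character(1)),
    edges = edges, n = n), class = "gdd_agraph")
  gr$elements <- graph_elements(gr)
  gr
}

# Ordered path/cycle decomposition.  Paths start at their smallest degree-one
# vertex; cycles start at their smallest vertex and follow the smallest
# incident edge first, making the representation deterministic.
graph_elements <- function(gr) {
  A <- ncol(gr$amat)
  ne <- nrow(gr$edges)
  inc <- vector("list", A)
  for (e in seq_len(ne)) {
    v1 <- gr$edges$v1[e]; v2 <- gr$edges$v2[e]
    inc[[v1]] <- c(inc[[v1]], e)
    if (v2 != v1) inc[[v2]] <- c(inc[[v2]], e)
  }
  degree <- vapply(seq_len(A), function(v) {
    sum(gr$edges$v1 == v) + sum(gr$edges$v2 == v)
  }, integer(1))
  used_edge <- rep(FALSE, ne)
  seen_vertex <- rep(FALSE, A)
  elements <- list()
  walk <- function(start) {
    # degrees are at most two, so a self-loop is always an isolated
    # single-vertex cycle and the walk below needs no backtracking
    verts <- start
    eids <- integer(0)
    v <- start
    seen_vertex[start] <<- TRUE
    repeat {
      cand <- inc[[v]][!used_edge[inc[[v]]]]
      if (!length(cand)) break
      e <- min(cand)
      used_edge[e] <<- TRUE
      eids <- c(eids, e)
      nxt <- if (gr$edges$v1[e] == v) gr$edges$v2[e] else gr$edges$v1[e]
      if (nxt == start) break  # cycle closed (or self-loop)
      v <- nxt
      verts <- c(verts, v)
      seen_vertex[v] <<- TRUE
    }
    list(verts = verts, eids = eids)
  }
  add_element <- function(w, kind) {
    couples <- sort(gr$edges$family[w$eids])
    elements[[length(elements) + 1L]] <<- list(
      kind = kind, vertices = w$verts, edges = w$eids,
      couples = couples, duplicated = anyDuplicated(couples) > 0L,
      size = length(w$eids))
  }
  for (v in which(degree == 1L)) {
    if (seen_vertex[v]) next
    add_element(walk(v), "path")
  }
  for (v in seq_len(A)) {
    if (seen_vertex[v]) next
    add_element(walk(v), "cycle")
  }
  elements
}

#' @export
print.gdd_agraph <- function(x, ...) {
  kinds <- vapply(x$elements, `[[`, character(1), "kind")
  cat("Dedoubled adjacency graph:", length(x$vertex_labels), "vertices,",
      nrow(x$edges), "edges,", sum(kinds == "path"), "path(s),",
      sum(kinds == "cycle"), "cycle(s)\n")
  for (el in x$elements) {
    cat(sprintf("  %-5s size %d couples {%s}%s\n", el$kind, el$size,
                paste(unique(el$couples), collapse = ","),
                if (el$duplicated) " [duplicated]" else ""))
  }
  invisible(x)
}

#' Pairwise element relations
#'
#' Two elements intersect when they share at least one couple (each couple has
#' two edges, which can fall in two different elements); an element is
#' duplicated when it contains some couple twice.
#'
#' @param gr A `gdd_agraph`.
#' @return List with `intersects` (logical element-by-element matrix) and
#'   `duplicated` (logical vector over elements).
#' @export
element_relations <- function(gr) {
  k <- length(gr$elements)
  M <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      M[i, j] <- length(intersect(gr$elements[[i]]$couples,
                                  gr$elements[[j]]$couples)) > 0L
    }
  }
  list(intersects = M,
       duplicated = vapply(gr$elements, `[[`, logical(1), "duplicated"))
}

#' Validity of the path of a linear unichromosomal genome
#'
#' The unique path of A(G) is valid when it contains every couple of G.
#'
#' @param gr A `gdd_agraph` built on a single linear chromosome.
#' @return List with `valid` (flag) and `missing_couples` (integer vector).
#' @export
path_validity <- function(gr) {
  if (!is_single_linear(gr$genome)) {
    stop("gdd_not_unichromosomal: path validity needs one linear chromosome",
         call. = FALSE)
  }
  paths <- Filter(function(el) el$kind == "path", gr$elements)
  if (length(paths) != 1L) {
    stop("gdd_internal: expected exactly one path element", call. = FALSE)
  }
  missing <- setdiff(duplicated_families(gr$genome), paths[[1]]$couples)
  list(valid = length(missing) == 0L, missing_couples = missing)
}

#' Orientation of a couple's edges
#'
#' On a linear unichromosomal genome, a couple's two edges are oriented when
#' its copies are written with opposite signs.
#'
#' @param gr A `gdd_agraph` of a linear unichromosomal genome.
#' @param couple Family identifier.
#' @return Logical flag.
#' @export
edge_orientation <- function(gr, couple) {
  couple_oriented(gr$genome, couple)
}

couple_oriented <- function(g, family) {
  codes <- genome_markers(g)
  signs <- marker_sign(codes[marker_family(codes) == family])
  if (length(signs) != 2L) {
    stop("gdd_invalid_genome: family ", family, " is not a couple", call. = FALSE)
  }
  signs[1] != signs[2]
}

#' DOT export of the dedoubled adjacency graph
#'
#' @param gr A `gdd_agraph`.
#' @param file Optional output path.
#' @return DOT source as a single string.
#' @export
agraph_dot <- function(gr, file = NULL) {
  pal <- grDevices::rainbow(max(1L, length(gr$elements)))
  col_of <- integer(length(gr$vertex_labels))
  for (i in seq_along(gr$elements)) col_of[gr$elements[[i]]$vertices] <- i
  lines <- c("graph A {", "  node [shape=box];")
  for (v in seq_along(gr$vertex_labels)) {
    lines <- c(lines, sprintf("  v%d [label=\"%s\", color=\"%s\"];",
                              v, gr$vertex_labels[v], pal[max(1L, col_of[v])]))
  }
  for (e in seq_len(nrow(gr$edges))) {
    lines <- c(lines, sprintf("  v%d -- v%d [label=\"%d:E_%s\"];",
                              gr$edges$v1[e], gr$edges$v2[e],
                              gr$edges$family[e], gr$edges$which[e]))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) { writeLines(lines, file); return(invisible(txt)) }
  txt
}
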