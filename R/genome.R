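# A genome is a list of chromosomes; each chromosome is
# list(circular = flag, body = integer vector of marker codes).  Linear
# chromosomes carry implicit telomere caps at both ends.

new_genome <- function(chromosomes, validate = TRUE) {
  g <- structure(list(chromosomes = chromosomes), class = "gdd_genome")
  if (validate) validate_genome(g)
  g
}

validate_genome <- function(g) {
  codes <- genome_markers(g)
  if (length(codes)) {
    fam <- marker_family(codes)
    if (any(fam < 1L)) stop("gdd_invalid_genome: family < 1", call. = FALSE)
    tab <- table(fam)
    if (any(tab > 2L)) {
      stop("gdd_parse_error: family occurs more than twice: ",
           paste(names(tab)[tab > 2L], collapse = " "), call. = FALSE)
    }
    for (f in as.integer(names(tab)[tab == 2L])) {
      pair <- marker_bar(codes[marker_family(codes) == f])
      if (sum(pair) != 1L) {
        stop("gdd_parse_error: family ", f,
             " needs exactly one plain and one bar copy", call. = FALSE)
      }
    }
    if (any(tab == 1L)) {
      solo <- as.integer(names(tab)[tab == 1L])
      if (any(marker_bar(codes[marker_family(codes) %in% solo]))) {
        stop("gdd_invalid_genome: single occurrence must be the plain copy",
             call. = FALSE)
      }
    }
  }
  invisible(g)
}

genome_markers <- function(g) {
  if (!length(g$chromosomes)) return(integer(0))
  unlist(lapply(g$chromosomes, `[[`, "body"), use.names = FALSE)
}

# Relabel copies so that the first occurrence of each family, in chromosome
# order and left-to-right, is the plain copy.  Labels are interchangeable
# bookkeeping, so this changes nothing observable.
canonicalize_copies <- function(g) {
  codes <- genome_markers(g)
  fam <- marker_family(codes)
  dup <- as.integer(names(table(fam))[table(fam) == 2L])
  flip <- integer(0)
  for (f in dup) {
    first <- which(fam == f)[1]
    if (marker_bar(codes[first])) flip <- c(flip, f)
  }
  if (!length(flip)) return(g)
  g$chromosomes <- lapply(g$chromosomes, function(ch) {
    sel <- marker_family(ch$body) %in% flip
    ch$body[sel] <- marker_sign(ch$body[sel]) *
      marker_partner_cid(marker_cid(ch$body[sel]))
    ch
  })
  g
}

#' Parse a genome from its text representation
#'
#' One chromosome per line: `("L"|"C") marker marker ...`, where a marker is
#' an optionally negated positive integer with an optional trailing apostrophe
#' marking the bar (second) copy of a duplicated family.  `#` starts a
#' comment; blank lines are ignored.  Copy labels are canonicalized so that
#' the first occurrence of each family in reading order is the plain copy.
#'
#' @param text A single string (possibly multi-line) or character vector of lines.
#' @return A `gdd_genome`.
#' @examples
#' parse_genome("L 1 2 2' 1'")
#' parse_genome("C 1 2 1' 2'")
#' @export
parse_genome <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  chroms <- lapply(lines, function(ln) {
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    shape <- toks[1]
    if (!shape %in% c("L", "C")) {
      stop("gdd_parse_error: chromosome line must start with L or C: ", ln,
           call. = FALSE)
    }
    if (length(toks) < 2L) stop("gdd_parse_error: empty chromosome: ", ln, call. = FALSE)
    list(circular = shape == "C", body = parse_marker(toks[-1]))
  })
  g <- new_genome(chroms, validate = FALSE)
  g <- canonicalize_copies(g)
  validate_genome(g)
  g
}

#' Read a genome from a file
#'
#' @param path Path to a genome file (see [parse_genome()] for the grammar).
#' @return A `gdd_genome`.
#' @export
read_genome <- function(path) parse_genome(readLines(path, warn = FALSE))

#' Write a genome as text
#'
#' @param g A `gdd_genome`.
#' @param file Optional path; when `NULL` the text is returned invisibly-free.
#' @return The text representation, one chromosome per line.
#' @export
write_genome <- function(g, file = NULL) {
  lines <- vapply(g$chromosomes, function(ch) {
    paste(c(if (ch$circular) "C" else "L", format_marker(ch$body)), collapse = " ")
  }, character(1))
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) writeLines(lines, file)
  txt
}

#' @export
print.gdd_genome <- function(x, ...) {
  cls <- classify_genome(x)
  cat("Genome:", length(x$chromosomes), "chromosome(s),",
      length(genome_markers(x)), "markers,", cls$status,
      if (cls$dedoubled) "(dedoubled)" else "", "\n")
  cat(write_genome(x), "\n")
  invisible(x)
}

#' @export
format.gdd_genome <- function(x, ...) write_genome(x)

# ---- adjacency set ---------------------------------------------------------

# 2 x A integer matrix of sorted extremity pairs (0 = telomere), columns
# ordered lexicographically.  This is the whole genome up to chromosome order,
# rotation, and reflection.
adjacency_matrix <- function(g) {
  cols <- list()
  for (ch in g$chromosomes) {
    b <- ch$body
    L <- length(b)
    if (ch$circular) {
      lefts  <- left_ext(b)
      rights <- right_ext(b)
      prev <- rights[c(L, seq_len(L - 1L))]
      cols[[length(cols) + 1L]] <- rbind(pmin(prev, lefts), pmax(prev, lefts))
    } else {
      r <- c(0L, right_ext(b))
      l <- c(left_ext(b), 0L)
      cols[[length(cols) + 1L]] <- rbind(pmin(r, l), pmax(r, l))
    }
  }
  m <- if (length(cols)) do.call(cbind, cols) else matrix(integer(0), nrow = 2)
  m[, order(m[1, ], m[2, ]), drop = FALSE]
}

#' Adjacencies of a genome
#'
#' One adjacency per pair of consecutive markers, plus two telomeric
#' adjacencies per linear chromosome; a circular chromosome of length l
#' yields l adjacencies.  Adjacencies are returned in a canonical written
#' form in which `(x y)` and `(-y -x)` coincide; `$` denotes a telomere.
#'
#' @param g A `gdd_genome`.
#' @return Character vector of rendered adjacencies (sorted, no duplicates
#'   removed: in a copy-canonical genome they are pairwise distinct).
#' @examples
#' adjacencies(parse_genome("L 1 2 2' 1'"))
#' @export
adjacencies <- function(g) {
  m <- adjacency_matrix(g)
  if (!ncol(m)) return(character(0))
  sort(vapply(seq_len(ncol(m)), function(i) format_adjacency(m[, i]), character(1)))
}

# Rebuild a genome from an adjacency matrix (inverse of adjacency_matrix up to
# chromosome order / rotation / reflection).
genome_from_adjacencies <- function(amat) {
  if (!ncol(amat)) return(new_genome(list(), validate = FALSE))
  keep <- !(amat[1, ] == 0L & amat[2, ] == 0L)
  amat <- amat[, keep, drop = FALSE]
  A <- ncol(amat)
  # locate the unique column holding each extremity
  all_ext <- c(amat[1, ], amat[2, ])
  colof <- c(seq_len(A), seq_len(A))
  nz <- all_ext != 0L
  lookup_col <- function(ext) colof[nz][match(ext, all_ext[nz])]
  visited <- rep(FALSE, A)
  chroms <- list()
  walk <- function(start_col, enter_ext) {
    # enter_ext: extremity through which the first marker is entered
    body <- integer(0)
    ext <- enter_ext
    visited[start_col] <<- TRUE
    repeat {
      body <- c(body, code_entering(ext))
      exit <- bitwXor(ext, 1L)
      col2 <- lookup_col(exit)
      visited[col2] <<- TRUE
      pair <- amat[, col2]
      nxt <- if (pair[1] == exit) pair[2] else pair[1]
      if (nxt == 0L) return(list(circular = FALSE, body = body))
      if (nxt == enter_ext) return(list(circular = TRUE, body = body))
      ext <- nxt
    }
  }
  # linear chromosomes: start from telomeric adjacencies
  telo <- which(amat[1, ] == 0L)
  for (tc in telo) {
    if (visited[tc]) next
    chroms[[length(chroms) + 1L]] <- walk(tc, amat[2, tc])
  }
  # circular chromosomes: whatever is left
  repeat {
    left <- which(!visited)
    if (!length(left)) break
    c0 <- left[1]
    chroms[[length(chroms) + 1L]] <- walk(c0, amat[2, c0])
  }
  new_genome(chroms, validate = FALSE)
}

# ---- classification --------------------------------------------------------

duplicated_families <- function(g) {
  fam <- marker_family(genome_markers(g))
  as.integer(names(table(fam))[table(fam) == 2L])
}

#' Number of couples of paralogous markers
#'
#' @param g A `gdd_genome`.
#' @return Integer count of duplicated families (n in the distance formulas).
#' @export
n_couples <- function(g) length(duplicated_families(g))

# Sorted keys of the two admissible dedoubled adjacencies of family f:
# (x x') = {head(plain), tail(bar)} and (x' x) = {head(bar), tail(plain)}.
dedoubled_adj_keys <- function(f) {
  p <- 2L * f; b <- p + 1L
  k1 <- sort(c(ext_head(p), ext_tail(b)))
  k2 <- sort(c(ext_head(b), ext_tail(p)))
  cbind(k1, k2)
}

#' Is a genome dedoubled?
#'
#' A duplicated genome is dedoubled when every duplicated family `x` carries
#' the adjacency `(x x')` or `(x' x)` (equivalently `(-x' -x)` or `(-x -x')`):
#' the two copies are adjacent with the same orientation.  The
#' inverted-adjacent form `(x -x')` does not qualify.
#'
#' @param g A `gdd_genome`.
#' @return Logical flag.
#' @examples
#' is_dedoubled(parse_genome("L 1 1' 2 2'"))  # TRUE
#' is_dedoubled(parse_genome("L 1 -1'"))      # FALSE
#' @export
is_dedoubled <- function(g) {
  dup <- duplicated_families(g)
  if (!length(dup)) return(TRUE)
  amat <- adjacency_matrix(g)
  keys <- adj_key(amat[1, ], amat[2, ])
  all(vapply(dup, function(f) {
    dd <- dedoubled_adj_keys(f)
    any(adj_key(dd[1, ], dd[2, ]) %in% keys)
  }, logical(1)))
}

#' Classify a genome's duplication status
#'
#' @param g A `gdd_genome`.
#' @return A list with `status` (one of `"non_duplicated"`, `"duplicated"`,
#'   `"totally_duplicated"`) and `dedoubled` (logical).
#' @export
classify_genome <- function(g) {
  fam <- marker_family(genome_markers(g))
  tab <- table(fam)
  status <- if (!any(tab == 2L)) "non_duplicated"
            else if (all(tab == 2L)) "totally_duplicated"
            else "duplicated"
  list(status = status, dedoubled = is_dedoubled(g))
}

is_totally_duplicated <- function(g) classify_genome(g)$status == "totally_duplicated"

chromosome_shapes <- function(g) vapply(g$chromosomes, `[[`, logical(1), "circular")

is_single_linear <- function(g) {
  length(g$chromosomes) == 1L && !g$chromosomes[[1]]$circular
}

# ---- reduction and totalization -------------------------------------------

#' Reduce a dedoubled genome
#'
#' Collapses every dedoubled couple to a single marker carrying the
#' orientation of the pair: `(x x')` and `(x' x)` both reduce to `x`,
#' `(-x' -x)` and `(-x -x')` to `-x`.  Non-duplicated markers are untouched.
#'
#' @param g A dedoubled `gdd_genome`.
#' @return A `gdd_genome` with no duplicated family.
#' @examples
#' write_genome(reduce_dedoubled(parse_genome("L 1 1' 2 2'")))
#' @export
reduce_dedoubled <- function(g) {
  if (!is_dedoubled(g)) {
    stop("gdd_not_dedoubled: genome is not dedoubled", call. = FALSE)
  }
  g$chromosomes <- lapply(g$chromosomes, function(ch) {
    ch$body <- ch$body[!marker_bar(ch$body)]
    ch
  })
  g$chromosomes <- Filter(function(ch) length(ch$body) > 0L, g$chromosomes)
  validate_genome(g)
  g
}

#' Totalize a duplicated genome
#'
#' Replaces every maximal run of non-duplicated markers, read left to right
#' and beginning with signed marker `s*x`, by the already-dedoubled pair
#' `s*x, s*x'`.  The run map records the replaced runs so the ancestor can be
#' expanded back after sorting.  A totally duplicated genome is returned
#' unchanged with an empty run map.  The transformation adds one independent
#' self-loop per introduced couple to the dedoubled adjacency graph, so both
#' dedoubling distance formulas are preserved.
#'
#' @param g A `gdd_genome` (any duplication status).
#' @return `list(genome = <totally duplicated gdd_genome>, runmap = <named list>)`;
#'   run map names are family identifiers, values the original signed runs.
#' @examples
#' totalize(parse_genome("L 1 1' 5 6 7 2 2'"))
#' @export
totalize <- function(g) {
  dup <- duplicated_families(g)
  runmap <- list()
  chroms <- lapply(g$chromosomes, function(ch) {
    b <- ch$body
    isdup <- marker_family(b) %in% dup
    if (all(isdup)) return(ch)
    if (ch$circular && any(isdup)) {
      # rotate so the chromosome starts on a duplicated marker: runs then
      # never wrap around the origin
      k <- which(isdup)[1]
      b <- c(b[k:length(b)], b[seq_len(k - 1L)])
      isdup <- c(isdup[k:length(isdup)], isdup[seq_len(k - 1L)])
    }
    out <- integer(0)
    i <- 1L
    while (i <= length(b)) {
      if (isdup[i]) {
        out <- c(out, b[i]); i <- i + 1L
      } else {
        j <- i
        while (j < length(b) && !isdup[j + 1L]) j <- j + 1L
        run <- b[i:j]
        head_code <- run[1]
        f <- marker_family(head_code)
        runmap[[as.character(f)]] <<- run
        s <- marker_sign(head_code)
        out <- c(out, head_code, s * (marker_cid(head_code) + 1L))
        i <- j + 1L
      }
    }
    ch$body <- out
    ch
  })
  list(genome = new_genome(chroms), runmap = runmap)
}

#' Expand a reconstructed ancestor
#'
#' Inverse of [totalize()] on the reduced (non-duplicated) side: every marker
#' whose family is a key of the run map is replaced by the stored run,
#' reversed and negated when the marker appears with flipped sign.
#'
#' @param g A `gdd_genome` containing each run-map key exactly once.
#' @param runmap Run map produced by [totalize()].
#' @return The expanded `gdd_genome`.
#' @export
expand_ancestor <- function(g, runmap) {
  if (!length(runmap)) return(g)
  keys <- as.integer(names(runmap))
  fams <- marker_family(genome_markers(g))
  missing <- setdiff(keys, fams)
  if (length(missing)) {
    stop("gdd_missing_key: run-map families absent from genome: ",
         paste(missing, collapse = " "), call. = FALSE)
  }
  g$chromosomes <- lapply(g$chromosomes, function(ch) {
    out <- integer(0)
    for (m in ch$body) {
      f <- marker_family(m)
      k <- as.character(f)
      if (f %in% keys) {
        run <- runmap[[k]]
        if (marker_sign(m) != marker_sign(run[1])) run <- -rev(run)
        out <- c(out, run)
      } else {
        out <- c(out, m)
      }
    }
    ch$body <- out
    ch
  })
  validate_genome(g)
  g
}

# ---- equality and canonical keys ------------------------------------------

vec_min <- function(a, b) {
  # lexicographically smaller of two equal-length integer vectors
  d <- which(a != b)
  if (!length(d)) a else if (a[d[1]] < b[d[1]]) a else b
}

canonical_chromosome <- function(ch) {
  b <- ch$body
  rn <- -rev(b)
  if (!ch$circular) return(list(circular = FALSE, body = vec_min(b, rn)))
  L <- length(b)
  best <- NULL
  for (v in list(b, rn)) {
    for (k in seq_len(L)) {
      rot <- c(v[k:L], v[seq_len(k - 1L)])[seq_len(L)]
      if (is.null(best)) best <- rot else best <- vec_min(best, rot)
    }
  }
  list(circular = TRUE, body = best)
}

#' Canonical string key of a genome
#'
#' Equal keys characterize equality up to chromosome order, circular rotation,
#' and whole-chromosome reflection.  Copy labels are taken as-is; use
#' [genome_equal()] to additionally quotient by plain/bar label swaps.
#'
#' @param g A `gdd_genome`.
#' @return A single string.
#' @export
canonical_key <- function(g) {
  keys <- vapply(g$chromosomes, function(ch) {
    cc <- canonical_chromosome(ch)
    paste0(if (cc$circular) "C" else "L", paste(cc$body, collapse = ","))
  }, character(1))
  paste(sort(keys), collapse = ";")
}

swap_copy_labels <- function(g, families) {
  if (!length(families)) return(g)
  g$chromosomes <- lapply(g$chromosomes, function(ch) {
    sel <- marker_family(ch$body) %in% families
    ch$body[sel] <- marker_sign(ch$body[sel]) *
      marker_partner_cid(marker_cid(ch$body[sel]))
    ch
  })
  g
}

#' Genome equality up to symmetry
#'
#' Tests equality up to chromosome order, rotation of circular chromosomes,
#' reflection, and (optionally) swapping the interchangeable plain/bar labels
#' of any couple.
#'
#' @param a,b `gdd_genome` objects.
#' @param copy_swap Also quotient by per-family copy-label swaps (default TRUE).
#' @return Logical flag.
#' @export
genome_equal <- function(a, b, copy_swap = TRUE) {
  ka <- canonical_key(a)
  if (identical(ka, canonical_key(b))) return(TRUE)
  if (!copy_swap) return(FALSE)
  dup <- duplicated_families(b)
  if (length(dup) > 16L) stop("gdd_size_limit: too many couples for copy-swap equality")
  if (!length(dup)) return(FALSE)
  for (mask in seq_len(2^length(dup) - 1L)) {
    fams <- dup[bitwAnd(mask, bitwShiftL(1L, seq_along(dup) - 1L)) != 0L]
    if (identical(ka, canonical_key(swap_copy_labels(b, fams)))) return(TRUE)
  }
  FALSE
}
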