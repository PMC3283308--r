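# Rearrangement operations: DCJ, reversal, and their breakpoint-duplication
# (BD) generalizations, plus scenarios and the lifting of BD scenarios to
# plain scenarios from a dedoubled start genome.
#
# An operation is a list with class "gdd_op":
#   kind    one of DCJ, REVERSAL, BD1_DCJ, BD2_DCJ, BD1_REVERSAL, BD2_REVERSAL
#   cuts    list of two sorted extremity pairs (pre-duplication adjacencies)
#   pattern rejoin choice for DCJ kinds: cutting {a,b} and {c,d} (sorted pairs,
#           cut1 before cut2), pattern 1 joins {a,c}+{b,d}, pattern 2 joins
#           {a,d}+{b,c}; ignored for REVERSAL kinds (the rejoin is the unique
#           orientation-reversing one)
#   dups    for BD kinds: list of list(family, cut) saying which marker is
#           duplicated and at which cut its copy is inserted

OP_KINDS <- c("DCJ", "REVERSAL", "BD1_DCJ", "BD2_DCJ", "BD1_REVERSAL", "BD2_REVERSAL")

# Cuts keep their element order: the rejoin pattern pairs elements by
# position, so reordering a cut would silently flip the rejoin.
as_cut <- function(x) {
  if (is.character(x)) return(parse_adjacency(x))
  as.integer(x)
}

#' Construct a rearrangement operation
#'
#' @param kind One of `DCJ`, `REVERSAL`, `BD1_DCJ`, `BD2_DCJ`,
#'   `BD1_REVERSAL`, `BD2_REVERSAL`.
#' @param cut1,cut2 The two adjacencies to cut, as `"(x,y)"` strings or
#'   extremity pairs; element order is preserved (the rejoin pattern pairs
#'   elements by position).
#' @param pattern Rejoin choice for DCJ kinds (1 or 2); ignored for reversals.
#' @param dups For BD kinds: list of `list(family =, cut =)` entries naming
#'   the duplicated family and the cut (1 or 2) where its copy is inserted.
#' @return A `gdd_op`.
#' @export
gdd_op <- function(kind, cut1, cut2, pattern = NA_integer_, dups = list()) {
  kind <- match.arg(kind, OP_KINDS)
  structure(list(kind = kind, cuts = list(as_cut(cut1), as_cut(cut2)),
                 pattern = as.integer(pattern), dups = dups),
            class = "gdd_op")
}

#' @export
print.gdd_op <- function(x, ...) {
  cat(format_op(x), "\n")
  invisible(x)
}

format_op <- function(op, news = NULL) {
  dup <- if (length(op$dups)) {
    paste0(" ; dup=", paste(vapply(op$dups, function(d)
      paste0(d$family, "@", d$cut), character(1)), collapse = ","))
  } else ""
  newtxt <- if (!is.null(news)) {
    paste0(" ; ", format_adjacency(news[[1]]), " ; ", format_adjacency(news[[2]]))
  } else ""
  # BD news reference post-insertion extremities, so the rejoin is written
  # explicitly for them (and whenever no created adjacencies are available)
  if (!is.na(op$pattern) && (is.null(news) || length(op$dups))) {
    newtxt <- paste0(newtxt, " ; pattern=", op$pattern)
  }
  paste0(op$kind, " ; ", format_cut(op$cuts[[1]]), " ; ",
         format_cut(op$cuts[[2]]), newtxt, dup)
}

#' Construct a scenario from a list of operations
#'
#' @param ops List of `gdd_op` objects.
#' @return A `gdd_scenario`.
#' @export
new_scenario <- function(ops = list()) structure(list(ops = ops), class = "gdd_scenario")

#' @export
print.gdd_scenario <- function(x, ...) {
  cat("Scenario with", length(x$ops), "operation(s)\n")
  for (op in x$ops) cat(" ", format_op(op), "\n")
  invisible(x)
}

#' @export
length.gdd_scenario <- function(x) length(x$ops)

# ---- DCJ on the adjacency-set representation -------------------------------

find_cut_col <- function(amat, cut) {
  s <- sort(cut)
  hit <- which(amat[1, ] == s[1] & amat[2, ] == s[2])
  if (!length(hit)) {
    stop("gdd_adjacency_not_found: ", format_adjacency(cut), call. = FALSE)
  }
  hit[1]
}

dcj_on_amat <- function(amat, cut1, cut2, pattern) {
  i <- find_cut_col(amat, cut1)
  j <- find_cut_col(amat, cut2)
  if (i == j) stop("gdd_identical_cuts: a DCJ must cut two different adjacencies",
                   call. = FALSE)
  a <- cut1[1]; b <- cut1[2]; c <- cut2[1]; d <- cut2[2]
  if (pattern == 1L) {
    n1 <- sort(c(a, c)); n2 <- sort(c(b, d))
  } else {
    n1 <- sort(c(a, d)); n2 <- sort(c(b, c))
  }
  amat <- amat[, -c(i, j), drop = FALSE]
  add <- cbind(n1, n2)
  add <- add[, !(add[1, ] == 0L & add[2, ] == 0L), drop = FALSE]
  amat <- cbind(amat, add)
  amat[, order(amat[1, ], amat[2, ]), drop = FALSE]
}

#' Apply a DCJ operation
#'
#' Cuts two different adjacencies and rejoins the four exposed extremities
#' crosswise.  With cut adjacencies `{a,b}` and `{c,d}` (each a sorted
#' extremity pair), `pattern = 1` forms `{a,c}` and `{b,d}`, `pattern = 2`
#' forms `{a,d}` and `{b,c}`.  Telomeric cuts follow capped semantics: an
#' extremity joined to a telomere becomes a chromosome end, and a join of two
#' telomere caps vanishes.
#'
#' @param g A `gdd_genome`.
#' @param cut1,cut2 Adjacencies, as `"(x,y)"` strings (telomere `$`) or
#'   internal extremity pairs.
#' @param pattern Rejoin choice, 1 or 2.
#' @return The rearranged `gdd_genome`.
#' @examples
#' g <- parse_genome("L 1 2 2' 1'")
#' write_genome(apply_dcj(g, "(1,2)", "(2',1')", 2))
#' @export
apply_dcj <- function(g, cut1, cut2, pattern = 1L) {
  amat <- dcj_on_amat(adjacency_matrix(g), as_cut(cut1), as_cut(cut2), pattern)
  genome_from_adjacencies(amat)
}

# ---- reversal --------------------------------------------------------------

# Locate an adjacency as (chromosome index, gap index).  Gap k sits between
# positions k and k+1; gap 0 and gap L are the telomeric gaps of a linear
# chromosome; on a circular chromosome gap L wraps to position 1 and gap 0
# does not exist.
locate_adjacency <- function(g, cut) {
  key <- adj_key(cut[1], cut[2])
  for (ci in seq_along(g$chromosomes)) {
    ch <- g$chromosomes[[ci]]
    b <- ch$body
    L <- length(b)
    if (ch$circular) {
      prev <- right_ext(b[c(L, seq_len(L - 1L))])
      lefts <- left_ext(b)
      keys <- adj_key(pmin(prev, lefts), pmax(prev, lefts))
      hit <- which(keys == key)
      if (length(hit)) return(list(chrom = ci, gap = ifelse(hit[1] == 1L, L, hit[1] - 1L)))
    } else {
      r <- c(0L, right_ext(b))
      l <- c(left_ext(b), 0L)
      keys <- adj_key(pmin(r, l), pmax(r, l))
      hit <- which(keys == key)
      if (length(hit)) return(list(chrom = ci, gap = hit[1] - 1L))
    }
  }
  stop("gdd_adjacency_not_found: ", format_adjacency(cut), call. = FALSE)
}

reverse_segment <- function(g, chrom, gap1, gap2) {
  ch <- g$chromosomes[[chrom]]
  b <- ch$body
  lo <- min(gap1, gap2); hi <- max(gap1, gap2)
  if (lo == hi) stop("gdd_identical_cuts: a reversal must cut two different adjacencies",
                     call. = FALSE)
  seg <- (lo + 1L):hi
  b[seg] <- -rev(b[seg])
  g$chromosomes[[chrom]]$body <- b
  g
}

#' Apply a reversal
#'
#' A reversal is the DCJ on two adjacencies of one chromosome whose rejoin
#' inverts the intervening segment (reversing its order and all signs).
#' Telomeric cuts give prefix/suffix reversals.
#'
#' @inheritParams apply_dcj
#' @return The rearranged `gdd_genome`.
#' @examples
#' g <- parse_genome("L 1 -1' 2 2'")
#' write_genome(apply_reversal(g, "(1,-1')", "(-1',2)"))
#' @export
apply_reversal <- function(g, cut1, cut2) {
  p1 <- locate_adjacency(g, as_cut(cut1))
  p2 <- locate_adjacency(g, as_cut(cut2))
  if (p1$chrom != p2$chrom) {
    stop("gdd_cuts_on_different_chromosomes", call. = FALSE)
  }
  reverse_segment(g, p1$chrom, p1$gap, p2$gap)
}

# ---- breakpoint-duplication operations -------------------------------------

# Insert the bar copy of `family` next to its (unique, plain) marker inside
# the cut adjacency.  The copy is glued to the marker with the same
# orientation and the cut moves between the two copies, so that the second
# step separates them and the duplicate ends up on the far side of the
# breakpoint.  Returns the updated amat and the modified (pair) cut.
bd_insert <- function(amat, cut, family) {
  cid <- 2L * family
  pc <- cid + 1L
  in_cut <- ext_cid(cut) == cid
  if (!any(in_cut)) {
    stop("gdd_bad_duplication: family ", family, " does not flank cut ",
         format_adjacency(cut), call. = FALSE)
  }
  E <- cut[in_cut][1]
  w <- if (all(in_cut)) NA else cut[!in_cut]  # (x x) impossible; guard anyway
  endbit <- E %% 2L
  pair <- c(E, 2L * pc + (1L - endbit))   # adjacency between the copies
  far  <- c(2L * pc + endbit, w)          # copy keeps the old neighbour
  col <- find_cut_col(amat, cut)
  amat <- cbind(amat[, -col, drop = FALSE], sort(pair), sort(far))
  list(amat = amat[, order(amat[1, ], amat[2, ]), drop = FALSE], cut = pair)
}

#' Apply a breakpoint-duplication (BD) operation
#'
#' First step: the bar copy of each duplicated family is inserted adjacent to
#' its marker at the designated cut adjacency (one family for 1-BD, one per
#' cut for 2-BD), producing an adjacent same-orientation pair.  Second step:
#' a DCJ (or reversal, for the BD-reversal kinds) cuts the modified
#' adjacencies, separating each pair so that the two copies end up flanking
#' the breakpoint.
#'
#' @param g A `gdd_genome`, non-duplicated in the families being duplicated.
#' @param op A `gdd_op` of a BD kind (see [gdd_op()]).
#' @return The rearranged `gdd_genome`.
#' @export
apply_bd <- function(g, op) {
  stopifnot(inherits(op, "gdd_op"), startsWith(op$kind, "BD"))
  fams <- vapply(op$dups, `[[`, numeric(1), "family")
  if (any(fams %in% duplicated_families(g))) {
    stop("gdd_already_duplicated: ", paste(fams, collapse = " "), call. = FALSE)
  }
  nd <- if (startsWith(op$kind, "BD1")) 1L else 2L
  if (length(op$dups) != nd) {
    stop("gdd_bad_duplication: ", op$kind, " needs ", nd, " duplication(s)",
         call. = FALSE)
  }
  amat <- adjacency_matrix(g)
  cuts <- op$cuts
  # validate both cuts exist before modifying anything
  for (cut in cuts) find_cut_col(amat, cut)
  for (d in op$dups) {
    res <- bd_insert(amat, cuts[[d$cut]], d$family)
    amat <- res$amat
    cuts[[d$cut]] <- res$cut
  }
  g2 <- genome_from_adjacencies(amat)
  if (endsWith(op$kind, "REVERSAL")) {
    apply_reversal(g2, cuts[[1]], cuts[[2]])
  } else {
    genome_from_adjacencies(dcj_on_amat(adjacency_matrix(g2), cuts[[1]],
                                        cuts[[2]], op$pattern))
  }
}

# ---- scenarios -------------------------------------------------------------

apply_op <- function(g, op) {
  switch(op$kind,
    DCJ = apply_dcj(g, op$cuts[[1]], op$cuts[[2]], op$pattern),
    REVERSAL = apply_reversal(g, op$cuts[[1]], op$cuts[[2]]),
    apply_bd(g, op))
}

#' Apply a scenario
#'
#' Folds the operations left to right; a failing step is reported with its
#' 1-based index.
#'
#' @param g A `gdd_genome`.
#' @param s A `gdd_scenario`.
#' @param snapshots Keep per-step genomes for audit (default FALSE).
#' @return The final `gdd_genome`; with `snapshots = TRUE`, a list with
#'   `genome` and `steps`.
#' @export
apply_scenario <- function(g, s, snapshots = FALSE) {
  steps <- if (snapshots) vector("list", length(s$ops))
  for (k in seq_along(s$ops)) {
    g <- tryCatch(apply_op(g, s$ops[[k]]),
                  error = function(e) {
                    stop("gdd_scenario_invalid_at_step_", k, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
    if (snapshots) steps[[k]] <- g
  }
  if (snapshots) list(genome = g, steps = steps) else g
}

#' Lift a BD scenario to a plain scenario from a dedoubled genome
#'
#' Given a non-duplicated genome `a` and a BD-DCJ/BD-reversal scenario `s`
#' from `a`, constructs the dedoubled genome `D` obtained from `a` by
#' pre-inserting, for every family duplicated in `s`, its bar copy adjacent to
#' the marker (on the side where the BD operation inserts it), and the plain
#' DCJ/reversal scenario of the same length consisting of the second steps of
#' `s` in order.  The reduction of `D` is `a`, and replaying the plain
#' scenario from `D` ends in the same genome as replaying `s` from `a`.
#'
#' @param a A non-duplicated `gdd_genome`.
#' @param s A `gdd_scenario` valid from `a`.
#' @return `list(dedoubled = D, plain = <gdd_scenario>)`.
#' @export
lift_bd_scenario <- function(a, s) {
  if (length(duplicated_families(a))) {
    stop("gdd_invalid_genome: start genome must be non-duplicated", call. = FALSE)
  }
  # glue side per duplicated family: end bit of the marker extremity at the cut
  glue <- list()  # family -> end bit (1 = bar copy glued on the head side)
  for (op in s$ops) {
    for (d in op$dups) {
      cut <- op$cuts[[d$cut]]
      E <- cut[ext_cid(cut) == 2L * d$family][1]
      if (is.na(E)) stop("gdd_bad_duplication: family ", d$family,
                         " does not flank its cut", call. = FALSE)
      glue[[as.character(d$family)]] <- E %% 2L
    }
  }
  # D: insert every pending bar copy next to its marker in `a`
  D <- a
  D$chromosomes <- lapply(D$chromosomes, function(ch) {
    out <- integer(0)
    for (m in ch$body) {
      f <- as.character(marker_family(m))
      gl <- glue[[f]]
      if (is.null(gl)) { out <- c(out, m); next }
      partner <- marker_sign(m) * (marker_cid(m) + 1L)
      headside <- gl == 1L
      after <- xor(headside, m < 0L)  # head side is right of a forward marker
      out <- if (after) c(out, m, partner) else c(out, partner, m)
    }
    ch$body <- out
    ch
  })
  validate_genome(D)

  active <- names(glue)  # families whose glue is not yet separated
  adapt <- function(cut) {
    out <- vapply(cut, function(e) {
      if (e == 0L) return(e)
      cid <- ext_cid(e)
      f <- as.character(cid %/% 2L)
      if (cid %% 2L == 0L && f %in% active && glue[[f]] == e %% 2L) e + 2L else e
    }, integer(1))
    out
  }
  pair_cut <- function(op, i) {
    # adjacency between the two copies for a cut carrying a duplication
    for (d in op$dups) {
      if (d$cut == i) {
        cut <- op$cuts[[i]]
        E <- cut[ext_cid(cut) == 2L * d$family][1]
        return(c(E, 2L * (2L * d$family + 1L) + (1L - E %% 2L)))
      }
    }
    NULL
  }
  plain <- list()
  W <- D
  for (k in seq_along(s$ops)) {
    op <- s$ops[[k]]
    c1 <- pair_cut(op, 1L); if (is.null(c1)) c1 <- adapt(op$cuts[[1]])
    c2 <- pair_cut(op, 2L); if (is.null(c2)) c2 <- adapt(op$cuts[[2]])
    pk <- if (endsWith(op$kind, "REVERSAL")) "REVERSAL" else "DCJ"
    pop <- gdd_op(pk, c1, c2, pattern = op$pattern)
    W <- apply_op(W, pop)
    plain[[k]] <- pop
    for (d in op$dups) active <- setdiff(active, as.character(d$family))
  }
  list(dedoubled = D, plain = new_scenario(plain), end = W)
}

# ---- scenario text format --------------------------------------------------

#' Write a scenario as text
#'
#' One operation per line: `KIND ; cut1 ; cut2 ; new1 ; new2 [; dup=f@c,...]`,
#' adjacencies rendered `(x,y)` with `$` for telomeres.  When `g` is given the
#' scenario is replayed from it so that the created adjacencies can be
#' printed; otherwise the rejoin is written as `pattern=k`.
#'
#' @param s A `gdd_scenario`.
#' @param g Optional starting `gdd_genome` for rendering created adjacencies.
#' @param file Optional output path.
#' @return The text, invisibly when written to a file.
#' @export
write_scenario <- function(s, g = NULL, file = NULL) {
  lines <- character(length(s$ops))
  for (k in seq_along(s$ops)) {
    op <- s$ops[[k]]
    news <- NULL
    if (!is.null(g)) {
      before <- adjacency_matrix(g)
      g <- apply_op(g, op)
      after <- adjacency_matrix(g)
      bk <- adj_key(before[1, ], before[2, ])
      ak <- adj_key(after[1, ], after[2, ])
      created <- which(!(ak %in% bk))
      news <- lapply(created, function(i) after[, i])
      if (length(news) != 2L) news <- NULL  # e.g. join of two caps
    }
    lines[k] <- format_op(op, news)
  }
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) { writeLines(lines, file); return(invisible(txt)) }
  txt
}

#' Read a scenario from text
#'
#' @param text Scenario text or character vector of lines (see
#'   [write_scenario()] for the format).
#' @return A `gdd_scenario`.
#' @export
read_scenario <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  ops <- lapply(lines, function(ln) {
    parts <- trimws(strsplit(ln, ";", fixed = TRUE)[[1]])
    kind <- parts[1]
    if (!kind %in% OP_KINDS) stop("gdd_parse_error: unknown op kind: ", kind,
                                  call. = FALSE)
    cut1 <- parse_adjacency(parts[2])
    cut2 <- parse_adjacency(parts[3])
    rest <- parts[-(1:3)]
    dups <- list()
    pattern <- NA_integer_
    news <- list()
    for (p in rest) {
      if (startsWith(p, "dup=")) {
        items <- strsplit(sub("^dup=", "", p), ",", fixed = TRUE)[[1]]
        dups <- lapply(items, function(it) {
          fc <- strsplit(it, "@", fixed = TRUE)[[1]]
          list(family = as.integer(fc[1]), cut = as.integer(fc[2]))
        })
      } else if (startsWith(p, "pattern=")) {
        pattern <- as.integer(sub("^pattern=", "", p))
      } else {
        news[[length(news) + 1L]] <- parse_adjacency(p)
      }
    }
    if (is.na(pattern) && length(news) == 2L && !kind %in% c("REVERSAL") ) {
      # recover the rejoin pattern from the recorded new adjacencies; for BD
      # kinds the news refer to post-insertion cuts, so this is best-effort
      # and only exact for plain DCJ
      a <- cut1[1]; b <- cut1[2]; c2 <- cut2[1]; d <- cut2[2]
      k1 <- list(sort(c(a, c2)), sort(c(b, d)))
      keyset <- function(l) {
        paste(sort(vapply(l, function(p) paste(sort(p), collapse = ":"),
                          character(1))), collapse = "|")
      }
      pattern <- if (keyset(k1) == keyset(news)) 1L else 2L
    }
    gdd_op(kind, cut1, cut2, pattern = pattern, dups = dups)
  })
  new_scenario(ops)
}
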