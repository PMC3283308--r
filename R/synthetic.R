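# Seeded simulators of breakpoint-duplication evolution, brute-force
# breadth-first-search distance oracles, and the worked example genomes.

#' Random non-duplicated ancestor genome
#'
#' @param n Number of marker families (markers 1..n, each once).
#' @param chromosomes Number of chromosomes.
#' @param circular_fraction Expected fraction of circular chromosomes.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A non-duplicated `gdd_genome`.
#' @export
random_ancestor <- function(n, chromosomes = 1L, circular_fraction = 0,
                            seed = 1L) {
  stopifnot(n >= 1L, chromosomes >= 1L, chromosomes <= n)
  set.seed(seed)
  fams <- sample.int(n)
  signs <- sample(c(-1L, 1L), n, replace = TRUE)
  codes <- signs * (2L * fams)
  brk <- sort(sample.int(n - 1L, chromosomes - 1L))
  parts <- split(codes, findInterval(seq_len(n), c(0, brk) + 1L))
  chroms <- lapply(parts, function(b) {
    list(circular = stats::runif(1) < circular_fraction, body = unname(b))
  })
  new_genome(unname(chroms))
}

# candidate (slot extremity, family) duplications at a cut column
bd_candidates <- function(g, cut) {
  dup <- duplicated_families(g)
  out <- list()
  for (e in cut) {
    if (e == 0L) next
    f <- ext_cid(e) %/% 2L
    if (marker_cid(ext_cid(e)) %% 2L == 1L) next  # bar copies never re-duplicate
    if (f %in% dup) next
    out[[length(out) + 1L]] <- f
  }
  unique(unlist(out))
}

#' Simulate breakpoint-duplication evolution
#'
#' Evolves a non-duplicated ancestor by `k` operations drawn from the
#' configured mix of 1-BD, 2-BD and plain operations; in the `reversal` model
#' all operations are (BD-)reversals on the single chromosome.  With
#' `oriented_only = TRUE` the simulation is resampled until the totalized
#' derived genome is oriented.
#'
#' @param ancestor A non-duplicated `gdd_genome`.
#' @param k Number of operations.
#' @param model `"dcj"` or `"reversal"`.
#' @param seed Integer seed.
#' @param oriented_only Resample until the totalized derived genome is
#'   oriented (reversal model input contract).
#' @param probs Probabilities of (1-BD, 2-BD, plain) operations.
#' @param max_tries Resampling budget before giving up.
#' @return A simulation record: list with `ancestor`, `scenario`, `derived`,
#'   `seed`, `params`.
#' @export
random_bd_evolution <- function(ancestor, k, model = c("dcj", "reversal"),
                                seed = 1L, oriented_only = FALSE,
                                probs = c(bd1 = 0.4, bd2 = 0.3, plain = 0.3),
                                max_tries = 200L) {
  model <- match.arg(model)
  if (model == "reversal" && !is_single_linear(ancestor)) {
    stop("gdd_not_unichromosomal: reversal evolution needs one linear chromosome",
         call. = FALSE)
  }
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    sim <- tryCatch(draw_bd_scenario(ancestor, k, model, probs),
                    error = function(e) NULL)
    if (is.null(sim)) next
    ok <- TRUE
    if (oriented_only) {
      tg <- totalize(sim$derived)$genome
      ok <- is_single_linear(tg) && n_couples(tg) > 0L &&
        orientation_status(build_overlap_graph(tg))$oriented
      if (k == 0L) ok <- TRUE
    }
    if (ok) {
      sim$seed <- seed
      sim$params <- list(k = k, model = model, probs = probs,
                         oriented_only = oriented_only)
      return(sim)
    }
  }
  stop("gdd_exhausted_resampling: no admissible simulation in ", max_tries,
       " tries", call. = FALSE)
}

draw_bd_scenario <- function(ancestor, k, model, probs) {
  cur <- ancestor
  ops <- list()
  attempts <- 0L
  while (length(ops) < k) {
    attempts <- attempts + 1L
    if (attempts > 50L * k + 50L) {
      stop("gdd_internal: could not draw ", k, " operations")
    }
    amat <- adjacency_matrix(cur)
    A <- ncol(amat)
    if (A < 2L) stop("gdd_internal: genome too small for a rearrangement")
    kind_base <- sample(c("bd1", "bd2", "plain"), 1L, prob = probs)
    ij <- sample.int(A, 2L)
    cut1 <- amat[, ij[1]]; cut2 <- amat[, ij[2]]
    if (model == "reversal") {
      # both cuts must lie on the single chromosome: always true here
      l1 <- locate_adjacency(cur, cut1); l2 <- locate_adjacency(cur, cut2)
      if (l1$chrom != l2$chrom) next
    }
    c1f <- bd_candidates(cur, cut1)
    c2f <- bd_candidates(cur, cut2)
    dups <- list()
    if (kind_base == "bd2" && length(c1f) && length(setdiff(c2f, c1f[1]))) {
      f1 <- sample(rep(c1f, 2L), 1L)
      f2 <- sample(rep(setdiff(c2f, f1), 2L), 1L)
      dups <- list(list(family = f1, cut = 1L), list(family = f2, cut = 2L))
    } else if (kind_base %in% c("bd1", "bd2") && length(c(c1f, c2f))) {
      pool <- rbind(if (length(c1f)) cbind(c1f, 1L),
                    if (length(c2f)) cbind(c2f, 2L))
      pick <- pool[sample.int(nrow(pool), 1L), ]
      dups <- list(list(family = pick[1], cut = pick[2]))
    }
    kind <- if (!length(dups)) {
      if (model == "reversal") "REVERSAL" else "DCJ"
    } else {
      paste0("BD", length(dups), "_", if (model == "reversal") "REVERSAL" else "DCJ")
    }
    op <- gdd_op(kind, cut1, cut2,
                 pattern = if (model == "reversal") NA_integer_ else sample(2L, 1L),
                 dups = dups)
    nxt <- tryCatch(apply_op(cur, op), error = function(e) NULL)
    if (is.null(nxt)) next
    if (model == "reversal" && !is_single_linear(nxt)) next
    cur <- nxt
    ops[[length(ops) + 1L]] <- op
  }
  list(ancestor = ancestor, scenario = new_scenario(ops), derived = cur)
}

# ---- breadth-first-search distance oracles ---------------------------------

amat_key <- function(amat) paste(amat, collapse = ",")

amat_dedoubled <- function(amat, fams) {
  keys <- adj_key(amat[1, ], amat[2, ])
  for (f in fams) {
    dd <- dedoubled_adj_keys(f)
    if (!any(adj_key(dd[1, ], dd[2, ]) %in% keys)) return(FALSE)
  }
  TRUE
}

amat_successors <- function(amat) {
  A <- ncol(amat)
  out <- vector("list", A * (A - 1L))
  cnt <- 0L
  for (i in seq_len(A - 1L)) {
    for (j in (i + 1L):A) {
      a <- amat[1, i]; b <- amat[2, i]; c <- amat[1, j]; d <- amat[2, j]
      for (p in 1:2) {
        n1 <- if (p == 1L) sort(c(a, c)) else sort(c(a, d))
        n2 <- if (p == 1L) sort(c(b, d)) else sort(c(b, c))
        keep <- cbind(amat[, -c(i, j), drop = FALSE],
                      if (any(n1 != 0L)) n1, if (any(n2 != 0L)) n2)
        cnt <- cnt + 1L
        out[[cnt]] <- keep[, order(keep[1, ], keep[2, ]), drop = FALSE]
      }
    }
  }
  out[seq_len(cnt)]
}

body_key <- function(b) {
  r <- -rev(b)
  a <- paste(b, collapse = ",")
  z <- paste(r, collapse = ",")
  if (a < z) a else z
}

body_dedoubled <- function(b) {
  fams <- sort(unique(marker_family(b)))
  for (f in fams) {
    pos <- which(marker_family(b) == f)
    if (length(pos) != 2L) return(FALSE)
    if (pos[2] != pos[1] + 1L || marker_sign(b[pos[1]]) != marker_sign(b[pos[2]])) {
      return(FALSE)
    }
  }
  TRUE
}

#' Brute-force dedoubling distance by breadth-first search
#'
#' Explores genome states exhaustively and returns the exact minimum number
#' of operations to reach a dedoubled genome (`dcj`), a dedoubled single
#' linear chromosome (`dcj_linear`), or a dedoubled genome using reversals
#' only (`reversal`).  Intended as an independent validation oracle at tiny
#' problem sizes.
#'
#' @param g A totally duplicated `gdd_genome`.
#' @param model `"dcj"`, `"dcj_linear"`, or `"reversal"`.
#' @param max_n Refuse instances with more couples than this.
#' @param max_depth Safety cap on the search depth.
#' @return Integer distance.
#' @export
bfs_oracle <- function(g, model = c("dcj", "dcj_linear", "reversal"),
                       max_n = 4L, max_depth = 12L) {
  model <- match.arg(model)
  fams <- duplicated_families(g)
  if (length(fams) > max_n) {
    stop("gdd_size_limit: BFS oracle gated at ", max_n, " couples", call. = FALSE)
  }
  if (model == "reversal") {
    if (!is_single_linear(g)) stop("gdd_not_unichromosomal", call. = FALSE)
    b0 <- g$chromosomes[[1]]$body
    if (body_dedoubled(b0)) return(0L)
    frontier <- list(b0)
    visited <- new.env(hash = TRUE)
    assign(body_key(b0), TRUE, envir = visited)
    for (depth in seq_len(max_depth)) {
      nxt <- list()
      for (b in frontier) {
        L <- length(b)
        for (lo in 0:(L - 1L)) {
          for (hi in (lo + 1L):L) {
            nb <- b
            nb[(lo + 1L):hi] <- -rev(nb[(lo + 1L):hi])
            if (body_dedoubled(nb)) return(depth)
            k <- body_key(nb)
            if (!exists(k, envir = visited)) {
              assign(k, TRUE, envir = visited)
              nxt[[length(nxt) + 1L]] <- nb
            }
          }
        }
      }
      frontier <- nxt
      if (!length(frontier)) break
    }
    stop("gdd_internal: reversal BFS exhausted without reaching a dedoubled genome")
  }
  # DCJ models on the adjacency-set representation
  linear_goal <- model == "dcj_linear"
  goal <- function(amat) {
    if (!amat_dedoubled(amat, fams)) return(FALSE)
    if (!linear_goal) return(TRUE)
    if (sum(amat == 0L) != 2L) return(FALSE)
    length(genome_from_adjacencies(amat)$chromosomes) == 1L
  }
  a0 <- adjacency_matrix(g)
  if (goal(a0)) return(0L)
  frontier <- list(a0)
  visited <- new.env(hash = TRUE)
  assign(amat_key(a0), TRUE, envir = visited)
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (amat in frontier) {
      for (s in amat_successors(amat)) {
        if (goal(s)) return(depth)
        k <- amat_key(s)
        if (!exists(k, envir = visited)) {
          assign(k, TRUE, envir = visited)
          nxt[[length(nxt) + 1L]] <- s
        }
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  stop("gdd_internal: DCJ BFS exhausted without reaching the goal")
}

# ---- enumeration and fixtures ----------------------------------------------

#' Enumerate totally duplicated genomes, up to symmetry
#'
#' All genomes over `n` couples (markers 1..n twice), deduplicated by the
#' canonical key (chromosome order, rotation, reflection) and optionally
#' restricted to single linear chromosomes.  Exhaustive only for tiny `n`.
#'
#' @param n Number of couples (1 or 2 are practical).
#' @param single_linear Keep only single-linear-chromosome genomes.
#' @return List of `gdd_genome` objects.
#' @export
enumerate_duplicated_genomes <- function(n, single_linear = FALSE) {
  stopifnot(n <= 2L)
  codes <- unlist(lapply(seq_len(n), function(f) c(2L * f, 2L * f + 1L)))
  L <- length(codes)
  perms <- all_permutations(L)
  seen <- new.env(hash = TRUE)
  out <- list()
  signsets <- as.matrix(expand.grid(rep(list(c(1L, -1L)), L)))
  splits <- if (single_linear) list(integer(0)) else all_subsets(L - 1L)
  for (pi in seq_len(nrow(perms))) {
    base <- codes[perms[pi, ]]
    for (si in seq_len(nrow(signsets))) {
      v <- base * signsets[si, ]
      for (brk in splits) {
        bounds <- c(0L, brk, L)
        parts <- lapply(seq_len(length(bounds) - 1L), function(q) {
          v[(bounds[q] + 1L):bounds[q + 1L]]
        })
        shapes_list <- if (single_linear) list(FALSE) else
          shape_combinations(length(parts))
        for (shp in shapes_list) {
          gg <- try(new_genome(Map(function(b, circ) list(circular = circ, body = b),
                                   parts, as.list(shp)), validate = FALSE), silent = TRUE)
          if (inherits(gg, "try-error")) next
          gg <- canonicalize_copies(gg)
          key <- canonical_key(gg)
          if (!exists(key, envir = seen)) {
            assign(key, TRUE, envir = seen)
            out[[length(out) + 1L]] <- gg
          }
        }
      }
    }
  }
  out
}

all_permutations <- function(L) {
  if (L == 1L) return(matrix(1L))
  sub <- all_permutations(L - 1L)
  do.call(rbind, lapply(seq_len(L), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

all_subsets <- function(L) {
  pool <- seq_len(L)
  out <- list(integer(0))
  if (L >= 1L) {
    for (size in seq_len(L)) {
      cmb <- utils::combn(pool, size)
      for (q in seq_len(ncol(cmb))) out[[length(out) + 1L]] <- cmb[, q]
    }
  }
  out
}

shape_combinations <- function(k) {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  lapply(seq_len(nrow(grid)), function(r) as.logical(grid[r, ]))
}

#' Random totally duplicated genome
#'
#' Arranges the 2n copies of families 1..n uniformly with random signs over
#' the requested chromosomes; copy labels are canonicalized.
#'
#' @inheritParams random_ancestor
#' @return A totally duplicated `gdd_genome`.
#' @export
random_duplicated_genome <- function(n, chromosomes = 1L, circular_fraction = 0,
                                     seed = 1L) {
  stopifnot(n >= 1L, chromosomes >= 1L, chromosomes <= 2L * n)
  set.seed(seed)
  codes <- unlist(lapply(seq_len(n), function(f) c(2L * f, 2L * f + 1L)))
  L <- 2L * n
  v <- sample(codes) * sample(c(-1L, 1L), L, replace = TRUE)
  brk <- if (chromosomes > 1L) sort(sample.int(L - 1L, chromosomes - 1L)) else integer(0)
  bounds <- c(0L, brk, L)
  chroms <- lapply(seq_len(length(bounds) - 1L), function(q) {
    list(circular = stats::runif(1) < circular_fraction,
         body = v[(bounds[q] + 1L):bounds[q + 1L]])
  })
  canonicalize_copies(new_genome(chroms))
}

#' Worked example genomes
#'
#' Named fixtures used across the package: `worked26` is the 13-couple linear
#' genome of the worked overlap-graph example (letters A..M mapped to
#' families 1..13, second occurrences as bar copies, signs as printed), and
#' `E1`..`E6` are the small hand-worked genomes.
#'
#' @return Named list of `gdd_genome` objects.
#' @export
worked_examples <- function() {
  list(
    worked26 = parse_genome(paste("L 1 -2 -1' -2' 3 4 -3' -5 -6 -4'",
                               "7 -8 -7' 8' 9 -10 -6' -5' -9' 10'",
                               "11 -12 -13 -11' -12' -13'")),
    E1 = parse_genome("L 1 1' 2 2'"),
    E2 = parse_genome("L 1 -1' 2 2'"),
    E3 = parse_genome("L 1 2 1' 2'"),
    E4 = parse_genome("L 1 2 2' 1'"),
    E5 = parse_genome("L 1 -2 -1' -2'"),
    E6 = parse_genome("L 1 2 2' 1' 3 4 4' 3' 5 6 5' 6' 7 8 7' 8'"),
    circ2 = parse_genome("C 1 2 1' 2'"))
}
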