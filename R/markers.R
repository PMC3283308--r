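# Low-level encodings shared by the whole package.
#
# A marker copy is encoded as a signed integer code: sign * (2*family + copy),
# where copy is 0 for the plain copy and 1 for the bar (paralog) copy, written
# in text as a trailing apostrophe (e.g. "2'" is the bar copy of family 2,
# "-2'" the same copy read in reverse orientation).  family >= 1, so |code| >= 2
# and 0 never encodes a marker.
#
# Each unsigned copy id c = 2*family + copy owns two extremities: its tail
# (2*c) and its head (2*c + 1).  Reading a positively-signed marker left to
# right passes tail then head; a negative sign swaps them.  The integer 0
# denotes a telomere cap.

mk_marker <- function(family, bar = FALSE, sign = 1L) {
  stopifnot(all(family >= 1L), all(sign %in% c(-1L, 1L)))
  as.integer(sign * (2L * family + as.integer(bar)))
}

marker_family <- function(code) abs(code) %/% 2L
marker_bar    <- function(code) abs(code) %% 2L == 1L
marker_sign   <- function(code) ifelse(code >= 0L, 1L, -1L)
marker_cid    <- function(code) abs(code)           # unsigned copy id
marker_partner_cid <- function(cid) bitwXor(cid, 1L) # other copy of the family

ext_tail <- function(cid) 2L * cid
ext_head <- function(cid) 2L * cid + 1L
ext_cid  <- function(ext) ext %/% 2L
ext_is_head <- function(ext) ext %% 2L == 1L

# Extremity exposed on the written left/right side of a signed marker code.
left_ext  <- function(code) ifelse(code > 0L, ext_tail(abs(code)), ext_head(abs(code)))
right_ext <- function(code) ifelse(code > 0L, ext_head(abs(code)), ext_tail(abs(code)))

# Signed marker code entered through extremity `ext` while reading forwards.
code_entering <- function(ext) {
  cid <- ext_cid(ext)
  ifelse(ext_is_head(ext), -cid, cid)
}

#' Parse a marker token
#'
#' Tokens follow the genome file grammar: an optional minus sign, a positive
#' integer family identifier, and an optional trailing apostrophe marking the
#' bar (second, paralogous) copy of the family.
#'
#' @param token Character vector of marker tokens, e.g. `c("1", "-2'", "13")`.
#' @return Integer vector of internal marker codes.
#' @examples
#' parse_marker(c("1", "-2'"))
#' @export
parse_marker <- function(token) {
  token <- trimws(token)
  ok <- grepl("^-?[0-9]+'?$", token)
  if (!all(ok)) {
    stop("gdd_parse_error: bad marker token(s): ",
         paste(token[!ok], collapse = " "), call. = FALSE)
  }
  sgn <- ifelse(startsWith(token, "-"), -1L, 1L)
  bar <- endsWith(token, "'")
  fam <- as.integer(sub("'$", "", sub("^-", "", token)))
  if (any(fam < 1L)) stop("gdd_parse_error: family identifiers must be >= 1", call. = FALSE)
  mk_marker(fam, bar, sgn)
}

#' Format marker codes as text
#'
#' Inverse of [parse_marker()].
#'
#' @param code Integer vector of marker codes.
#' @return Character vector of tokens.
#' @export
format_marker <- function(code) {
  paste0(ifelse(code < 0L, "-", ""), marker_family(code),
         ifelse(marker_bar(code), "'", ""))
}

# ---- adjacencies -----------------------------------------------------------
#
# An adjacency is an unordered pair of extremities, stored as a sorted integer
# pair (telomere 0 sorts first).  The pair {right_ext(x), left_ext(y)} is the
# adjacency written "(x y)"; sorting makes (x y) and (-y -x) identical, which
# is the required reading-direction equivalence.

adj_key <- function(e1, e2) {
  a <- pmin(e1, e2); b <- pmax(e1, e2)
  a * 1000000L + b  # single-integer key; extremities stay far below 1e6
}

# Build adjacency from written marker pair; 0 (telomere) allowed on either side.
adj_from_markers <- function(x, y) {
  e1 <- if (identical(x, 0L) || x == 0) 0L else right_ext(x)
  e2 <- if (identical(y, 0L) || y == 0) 0L else left_ext(y)
  sort(c(e1, e2))
}

# Written rendering of an extremity pair, choosing the canonical direction:
# of the two equivalent writings (x y) / (-y -x), pick the one whose left
# marker has the smaller (family, copy, sign) triple; telomeres sort last.
format_adjacency <- function(pair) {
  e <- sort(pair)
  mk <- function(left, right) {
    l <- if (left == 0L) "$" else format_marker(code_leaving(left))
    r <- if (right == 0L) "$" else format_marker(code_entering(right))
    paste0("(", l, ",", r, ")")
  }
  # code read when leaving through extremity `ext` (ext is the right end)
  # ordering choice below
  cands <- list(c(e[1], e[2]), c(e[2], e[1]))
  keys <- vapply(cands, function(p) {
    lcode <- if (p[1] == 0L) NA_integer_ else code_leaving(p[1])
    if (is.na(lcode)) Inf else marker_rank(lcode)
  }, numeric(1))
  p <- cands[[which.min(keys)]]
  mk(p[1], p[2])
}

# Signed code of a marker whose RIGHT written end is extremity ext.
code_leaving <- function(ext) {
  cid <- ext_cid(ext)
  ifelse(ext_is_head(ext), cid, -cid)
}

# Total order on signed marker codes by (family, copy, sign) for canonical
# adjacency rendering.
marker_rank <- function(code) {
  marker_family(code) * 4 + marker_bar(code) * 2 + (code < 0)
}

# Order-preserving rendering of a cut: element 1 is the right end of the left
# marker, element 2 the left end of the right marker, so
# parse_adjacency(format_cut(p)) == p exactly.  Canonical display rendering is
# format_adjacency().
format_cut <- function(pair) {
  l <- if (pair[1] == 0L) "$" else format_marker(code_leaving(pair[1]))
  r <- if (pair[2] == 0L) "$" else format_marker(code_entering(pair[2]))
  paste0("(", l, ",", r, ")")
}

#' Parse an adjacency written as "(x,y)"
#'
#' Telomeres are written `$`.  Whitespace is ignored.
#'
#' @param text A single string such as `"(1,2')"` or `"(2,$)"`.
#' @return Integer extremity pair (sorted) with 0 for a telomere.
#' @export
parse_adjacency <- function(text) {
  s <- gsub("[()[:space:]]", "", text)
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("gdd_parse_error: bad adjacency: ", text, call. = FALSE)
  x <- if (parts[1] == "$") 0L else parse_marker(parts[1])
  y <- if (parts[2] == "$") 0L else parse_marker(parts[2])
  e1 <- if (x == 0L) 0L else right_ext(x)
  e2 <- if (y == 0L) 0L else left_ext(y)
  c(e1, e2)
}
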