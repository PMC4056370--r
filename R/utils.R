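## Small sequence / RNG helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#'
#' All randomized operations in the package route their seeds through this
#' helper, so fixed seeds give byte-identical outputs without disturbing the
#' caller's random-number stream.
#'
#' @param seed integer seed (NULL evaluates without touching the RNG)
#' @param expr expression to evaluate
#' @return value of `expr`
#' @export
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Random DNA string at a given GC content
#' @param n length in bp
#' @param gc GC fraction in (0, 1)
#' @return character scalar over A/C/G/T
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc > 0, gc < 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of a DNA string
#' @param x character scalar (A/C/G/T/N)
#' @return character scalar
#' @export
revcomp <- function(x) {
  if (nchar(x) == 0) return("")
  comp <- chartr("ACGTN", "TGCAN", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Reverse (no complement) of a string
#' @noRd
str_rev <- function(x) {
  if (nchar(x) == 0) return("")
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

## substring that clips to sequence bounds instead of erroring
substr_clip <- function(x, start, end) {
  n <- nchar(x)
  substr(x, max(1L, start), min(n, end))
}

## single-base replacement at position i
set_base <- function(x, i, base) {
  substr(x, i, i) <- base
  x
}

## a base different from every base listed in `avoid`
other_base <- function(avoid) {
  cand <- setdiff(BASES, avoid)
  if (length(cand) == 0) stop("no base available outside the avoid set")
  cand[[1L]]
}

## overlap length of [s1,e1] and [s2,e2] (1-based closed); 0 if disjoint
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

## total coverage of [lo,hi] positions by a set of (start,end) intervals
union_coverage <- function(starts, ends) {
  if (length(starts) == 0) return(0L)
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L; cs <- starts[1L]; ce <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= ce + 0L) ce <- max(ce, ends[i])
    else { tot <- tot + (ce - cs + 1L); cs <- starts[i]; ce <- ends[i] }
  }
  tot + (ce - cs + 1L)
}

## left-align a deletion [s, e] against reference `ref`: shift left while the
## base before the deletion equals its last base (junction ambiguity)
left_align_deletion <- function(ref, s, e) {
  while (s > 1L && substr(ref, s - 1L, s - 1L) == substr(ref, e, e)) {
    s <- s - 1L; e <- e - 1L
  }
  c(start = s, end = e)
}

## left-align an insertion (after position pos, sequence ins) against `ref`;
## rotates `ins` as the anchor moves left. Returns list(pos, ins).
left_align_insertion <- function(ref, pos, ins) {
  n <- nchar(ins)
  while (pos >= 1L && substr(ref, pos, pos) == substr(ins, n, n)) {
    ins <- paste0(substr(ref, pos, pos), substr(ins, 1L, n - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, ins = ins)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
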