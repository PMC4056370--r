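## SSA/NAHR-capable homology between a CNV and its flanks. Two published
## filters are applied to local ungapped alignments: type I (>= 30 bp at
## >= 98% identity, the hallmark of single-strand annealing) and type II
## (>= 200 bp at >= 95%, the hallmark of NAHR and SSA). Works from precise
## split-read coordinates (200 bp flanks) or imprecise array-style intervals
## (500 bp flanks extended 25% of the CNV length inward).

#' Extract the CNV sequence and its two flanks
#'
#' Precise mode takes exactly 200 bp on each side of the breakpoints.
#' Imprecise mode compensates for coordinate uncertainty: each flank reaches
#' 500 bp outward and 25% of the CNV length inward past the nominal
#' breakpoint (so flanks overlap the CNV ends).
#'
#' @param call one-row call (chrom, start, end) or a list with those fields
#' @param genome reference `sim_genome`
#' @param mode "precise" or "imprecise"
#' @param flank precise-mode flank width (default 200)
#' @param out_reach,in_frac imprecise-mode parameters (defaults 500 bp and
#'   0.25)
#' @return list of class `flank_triplet`: cnv_seq, five_flank, three_flank,
#'   coordinates of each piece, mode, truncated flag
#' @export
extract_flanks <- function(call, genome, mode = c("precise", "imprecise"),
                           flank = 200L, out_reach = 500L, in_frac = 0.25) {
  mode <- match.arg(mode)
  chrom <- genome$chromosomes[[call$chrom]]
  n <- nchar(chrom)
  s <- call$start; e <- call$end
  if (mode == "precise") {
    f5 <- c(s - flank, s - 1L)
    f3 <- c(e + 1L, e + flank)
  } else {
    reach_in <- as.integer(floor(in_frac * (e - s + 1L)))
    f5 <- c(s - out_reach, s - 1L + reach_in)
    f3 <- c(e + 1L - reach_in, e + out_reach)
  }
  truncated <- f5[1] < 1L || f3[2] > n
  f5 <- as.integer(pmax(1L, pmin(f5, n)))
  f3 <- as.integer(pmax(1L, pmin(f3, n)))
  structure(list(
    cnv_seq = substr(chrom, s, e),
    five_flank = substr(chrom, f5[1], f5[2]),
    three_flank = substr(chrom, f3[1], f3[2]),
    cnv_coords = c(s, e), five_coords = f5, three_coords = f3,
    chrom = call$chrom, mode = mode, truncated = truncated),
    class = "flank_triplet")
}

#' Local ungapped homology between two sequences
#'
#' On every diagonal of the comparison matrix, the longest window with
#' identity at or above `min_identity` is found exactly (integer prefix-sum
#' search); windows of at least `min_len` become hits. Identity is matches
#' divided by alignment columns. Hits contained in a longer hit (on both
#' sequences) are dropped as redundant.
#'
#' @param a,b DNA strings
#' @param min_len minimum hit length in bp
#' @param min_identity minimum identity as a fraction (e.g. 0.98)
#' @return data.frame of hits: a_start, a_end, b_start, b_end, length,
#'   matches, identity
#' @export
find_homology <- function(a, b, min_len = 30L, min_identity = 0.98) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  h <- cpp_diag_hits(a, b, as.integer(min_len), min_identity)
  if (nrow(h) == 0)
    return(data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      length = integer(0), matches = integer(0),
                      identity = numeric(0)))
  h$a_end <- h$a_start + h$length - 1L
  h$b_end <- h$b_start + h$length - 1L
  h$identity <- h$matches / h$length
  h <- h[order(-h$length), , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))[-1L]) {
    contained <- h$a_start[i] >= h$a_start[seq_len(i - 1L)] &
      h$a_end[i] <= h$a_end[seq_len(i - 1L)] &
      h$b_start[i] >= h$b_start[seq_len(i - 1L)] &
      h$b_end[i] <= h$b_end[seq_len(i - 1L)]
    if (any(contained & keep[seq_len(i - 1L)])) keep[i] <- FALSE
  }
  h <- h[keep, c("a_start", "a_end", "b_start", "b_end", "length", "matches",
                 "identity")]
  rownames(h) <- NULL
  h
}

## fraction of a sequence covered by its own most frequent k-mers; a cheap
## low-complexity/repetitiveness annotation standing in for a repeat screen
low_complexity_score <- function(seq, k = 4L) {
  n <- nchar(seq)
  if (n < 2L * k) return(0)
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  max(table(kmers)) * k / n
}

#' Flank-homology support for SSA/NAHR at one call
#'
#' Runs [find_homology()] over the three geometries (5' flank vs CNV, 3'
#' flank vs CNV, 5' flank vs 3' flank) under both published filters. In
#' imprecise mode, hits explained by the two pieces covering the same genomic
#' positions (self-hits from flanks overlapping the CNV) are removed. Hits in
#' repetitive/low-complexity sequence are annotated (never filtered).
#'
#' @param call one-row call data.frame
#' @param genome reference `sim_genome`
#' @param mode "precise" or "imprecise" (see [extract_flanks()])
#' @param type1 list(min_len, min_identity) for the SSA-scale filter
#' @param type2 list(min_len, min_identity) for the NAHR-scale filter
#' @return list of class `mechanism_support`: type_I and type_II flags,
#'   hits (with geometry, filter, low-complexity annotation), mode
#' @export
classify_mechanism_support <- function(call, genome,
                                       mode = c("precise", "imprecise"),
                                       type1 = list(min_len = 30L,
                                                    min_identity = 0.98),
                                       type2 = list(min_len = 200L,
                                                    min_identity = 0.95)) {
  mode <- match.arg(mode)
  tri <- extract_flanks(call, genome, mode)
  pieces <- list(five = tri$five_flank, three = tri$three_flank,
                 cnv = tri$cnv_seq)
  coords <- list(five = tri$five_coords, three = tri$three_coords,
                 cnv = tri$cnv_coords)
  geoms <- list(five_vs_cnv = c("five", "cnv"),
                three_vs_cnv = c("three", "cnv"),
                five_vs_three = c("five", "three"))
  all_hits <- list()
  for (ft in c("type_I", "type_II")) {
    fl <- if (ft == "type_I") type1 else type2
    for (gn in names(geoms)) {
      pa <- geoms[[gn]][1]; pb <- geoms[[gn]][2]
      if (nchar(pieces[[pa]]) < fl$min_len ||
          nchar(pieces[[pb]]) < fl$min_len) next
      h <- find_homology(pieces[[pa]], pieces[[pb]], fl$min_len,
                         fl$min_identity)
      if (nrow(h) == 0) next
      ## genomic projection for self-hit removal
      ga <- coords[[pa]][1] + cbind(h$a_start, h$a_end) - 1L
      gb <- coords[[pb]][1] + cbind(h$b_start, h$b_end) - 1L
      self <- interval_overlap(ga[, 1], ga[, 2], gb[, 1], gb[, 2]) > 0L
      h <- h[!self, , drop = FALSE]
      if (nrow(h) == 0) next
      h$geometry <- gn
      h$homology_type <- ft
      h$low_complexity <- vapply(seq_len(nrow(h)), function(i)
        low_complexity_score(substr(pieces[[pa]], h$a_start[i], h$a_end[i])) >
          0.5, logical(1))
      all_hits[[length(all_hits) + 1L]] <- h
    }
  }
  hits <- if (length(all_hits)) do.call(rbind, all_hits) else
    data.frame(homology_type = character(0))
  structure(list(type_I = any(hits$homology_type == "type_I"),
                 type_II = any(hits$homology_type == "type_II"),
                 hits = hits, mode = mode),
            class = "mechanism_support")
}

#' Mechanism-support flags for a whole call table
#' @inheritParams classify_mechanism_support
#' @param calls call data.frame
#' @return data.frame: call_id, type_I, type_II, n_hits
#' @export
mechanism_support_all <- function(calls, genome,
                                  mode = c("precise", "imprecise")) {
  mode <- match.arg(mode)
  out <- lapply(seq_len(nrow(calls)), function(i) {
    ms <- classify_mechanism_support(calls[i, ], genome, mode)
    data.frame(call_id = calls$call_id[i] %||% paste0("call", i),
               type_I = ms$type_I, type_II = ms$type_II,
               n_hits = nrow(ms$hits))
  })
  do.call(rbind, out)
}
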