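## Breakpoint-junction anatomy: junction realignment, the three microhomology
## geometries, the four breakpoint classes, outgroup polarization, and
## recurrent/complex region detection.
##
## Microhomology geometries (per-junction lengths, all capped at `max_k`):
##  type I   - identity between the event-internal sequence and the
##             breakpoint-adjacent EXTERNAL sequence, in the orientation that
##             can mediate the event (one of the two copies becomes part of
##             the deletion/insertion): max of the common prefix of
##             (segment, sequence following the 3' breakpoint) and the common
##             suffix of (segment, sequence preceding the 5' breakpoint).
##  type II  - chance control: identity straddling the junction between the
##             two EXTERNAL flanks (largest k with the k bases entering the
##             junction equal to the k bases leaving it).
##  type III - chance control: identity between the segment's 5' end and the
##             bases immediately preceding the event, a geometry that cannot
##             mediate the event.

#' Measure type I/II/III microhomology at a call's junction
#'
#' @param call one-row call data.frame (chrom, start, end, kind,
#'   inserted_seq) from [cluster_and_filter()], or a list with those fields
#' @param genome the reference `sim_genome`
#' @param max_k cap on reported microhomology length (default 50)
#' @return list of class `mh_profile`: type_I, type_II, type_III,
#'   junction_extra_bases, flank_truncated
#' @export
measure_microhomology <- function(call, genome, max_k = 50L) {
  chrom <- genome$chromosomes[[call$chrom]]
  n <- nchar(chrom)
  if (call$kind == "insertion") {
    segment <- call$inserted_seq
    pre_end <- call$start          # last base before the junction
    post_start <- call$start + 1L  # first base after
    extra <- ""
  } else {
    segment <- substr(chrom, call$start, call$end)
    pre_end <- call$start - 1L
    post_start <- call$end + 1L
    extra <- call$inserted_seq %||% ""
    if (is.na(extra)) extra <- ""
  }
  kcap <- min(max_k, nchar(segment))
  preceding <- substr_clip(chrom, pre_end - max_k + 1L, pre_end)
  following <- substr_clip(chrom, post_start, post_start + max_k - 1L)
  truncated <- nchar(preceding) < max_k || nchar(following) < max_k
  type_I <- min(kcap, max(cpp_lcp(segment, following),
                          cpp_lcs(segment, preceding)))
  type_II <- 0L
  for (kk in seq_len(min(max_k, nchar(preceding), nchar(following)))) {
    if (substring(preceding, nchar(preceding) - kk + 1L) ==
        substr(following, 1L, kk)) type_II <- kk
  }
  type_III <- 0L
  for (kk in seq_len(min(kcap, nchar(preceding)))) {
    if (substr(segment, 1L, kk) ==
        substring(preceding, nchar(preceding) - kk + 1L)) type_III <- kk
  }
  structure(list(type_I = type_I, type_II = type_II, type_III = type_III,
                 junction_extra_bases = extra, flank_truncated = truncated),
            class = "mh_profile")
}

#' Microhomology profiles for a whole call table
#' @param calls call data.frame
#' @param genome reference `sim_genome`
#' @param max_k cap on reported lengths
#' @return data.frame with call_id, type_I, type_II, type_III,
#'   junction_extra_bases, flank_truncated
#' @export
measure_microhomology_all <- function(calls, genome, max_k = 50L) {
  out <- lapply(seq_len(nrow(calls)), function(i) {
    p <- measure_microhomology(calls[i, ], genome, max_k)
    data.frame(call_id = calls$call_id[i] %||% paste0("call", i),
               type_I = p$type_I, type_II = p$type_II, type_III = p$type_III,
               junction_extra_bases = p$junction_extra_bases,
               flank_truncated = p$flank_truncated)
  })
  do.call(rbind, out)
}

#' Assign the four-way breakpoint class
#'
#' BLUNT: no microhomology (type I < 2) and no junction-inserted bases.
#' MICROHOMOLOGY: type I >= 2, no extra bases. COMPLEX: extra bases, type I
#' < 2. COMPLEX_MH: both. A minimum of 2 bp of identical sequence is required
#' to call microhomology, the smallest length showing a significant excess of
#' the mechanistically relevant geometry over the chance controls (see
#' [microhomology_excess_test()]); `long_identity` flags type I > 20 bp, the
#' scale at which single-strand annealing becomes a plausible mechanism.
#'
#' @param profile an `mh_profile` (or data.frame row with the same fields)
#' @param min_mh minimum type-I length to call microhomology (default 2)
#' @param long_mh threshold above which `long_identity` is set (default 20)
#' @return list of class `bp_class`: label, long_identity
#' @export
classify_breakpoint <- function(profile, min_mh = 2L, long_mh = 20L) {
  has_mh <- profile$type_I >= min_mh
  has_extra <- nchar(profile$junction_extra_bases %||% "") > 0
  label <- if (has_mh && has_extra) "COMPLEX_MH" else if (has_mh)
    "MICROHOMOLOGY" else if (has_extra) "COMPLEX" else "BLUNT"
  structure(list(label = label, long_identity = profile$type_I > long_mh),
            class = "bp_class")
}

#' Classify every profile in a table
#' @param profiles data.frame from [measure_microhomology_all()]
#' @inheritParams classify_breakpoint
#' @return the input with `label` and `long_identity` columns added
#' @export
classify_breakpoints_all <- function(profiles, min_mh = 2L, long_mh = 20L) {
  cl <- lapply(seq_len(nrow(profiles)),
               function(i) classify_breakpoint(profiles[i, ], min_mh, long_mh))
  profiles$label <- vapply(cl, `[[`, character(1), "label")
  profiles$long_identity <- vapply(cl, `[[`, logical(1), "long_identity")
  profiles
}

#' Excess of mechanistically oriented microhomology over chance controls
#'
#' For each k >= 1, counts breakpoints with type I >= k versus the pooled
#' type II/III controls >= k, and applies a two-proportion test (type I on n
#' junctions vs pooled controls on 2n). The smallest k with a significant
#' excess is the recommended minimum microhomology length for class
#' assignment.
#'
#' @param profiles data.frame with type_I/type_II/type_III columns (>= 30
#'   rows required)
#' @param alpha significance level (default 0.05, no multiplicity correction
#'   across k; a single pooled decision is the intended use)
#' @param max_k largest k examined
#' @return list: per-k table (counts and p-values), `smallest_significant_k`
#'   (NA if none)
#' @export
microhomology_excess_test <- function(profiles, alpha = 0.05, max_k = 15L) {
  n <- nrow(profiles)
  if (n < 30L) stop("need at least 30 junction profiles, got ", n)
  tab <- do.call(rbind, lapply(seq_len(max_k), function(k) {
    k1 <- sum(profiles$type_I >= k)
    k2 <- sum(profiles$type_II >= k) + sum(profiles$type_III >= k)
    pv <- if (k1 + k2 == 0L) 1 else
      two_proportion_test(k1, n, k2, 2L * n)$p_value
    data.frame(k = k, type_I = k1, controls = k2, p_value = pv,
               excess = k1 / n > k2 / (2 * n))
  }))
  sig <- tab$k[tab$p_value < alpha & tab$excess]
  list(table = tab,
       smallest_significant_k = if (length(sig)) min(sig) else NA_integer_,
       alpha = alpha)
}

## ---- junction realignment --------------------------------------------------

#' Re-derive junction content by realigning supporting reads
#'
#' Supporting reads are realigned against a window around the call with the
#' native split mapper; the junction each read implies (flank extents plus
#' unexplained inserted bases) is compared across reads. Reads must agree on
#' the junction content; disagreement flags the call `inconsistent`, which
#' excludes it downstream.
#'
#' @param call one-row call data.frame
#' @param reads `read_set` containing (at least) the supporting reads
#' @param genome reference `sim_genome`
#' @param window bp of reference context on each side of the call
#' @return list of class `bp_alignment`: call_id, per-read junction table
#'   (read_id, flank5_end, flank3_start, junction_extra_bases), `consistent`,
#'   and the consensus junction (NA if inconsistent)
#' @export
realign_junction <- function(call, reads, genome, window = 1500L) {
  ids <- strsplit(call$read_ids, ",")[[1]]
  sup <- reads[reads$id %in% ids, , drop = FALSE]
  if (nrow(sup) < 2L) stop("call has fewer than 2 supporting reads")
  chrom <- genome$chromosomes[[call$chrom]]
  lo <- max(1L, call$start - window)
  hi <- min(nchar(chrom), call$end + window)
  mini <- structure(list(
    chromosomes = setNames(substr(chrom, lo, hi), call$chrom),
    mask = data.frame(chrom = call$chrom, start = 1L, end = hi - lo + 1L),
    te = data.frame(chrom = character(0), start = integer(0), end = integer(0)),
    seed = NA_integer_), class = "sim_genome")
  al <- map_reads(sup, mini)
  sig <- detect_split_signatures(al, min_size = 1L, reads = sup)
  per <- data.frame(read_id = sig$read_id,
                    flank5_end = sig$start + lo - 1L - 1L,
                    flank3_start = if (nrow(sig)) ifelse(
                      sig$kind == "insertion", sig$start + lo - 1L + 1L,
                      sig$end + lo - 1L + 1L) else integer(0),
                    junction_extra_bases = if (nrow(sig)) ifelse(
                      sig$kind == "insertion", sig$inserted_seq,
                      sig$inserted_seq) else character(0))
  keyfun <- function(d) paste(d$flank5_end, d$flank3_start,
                              d$junction_extra_bases)
  consistent <- nrow(per) >= 2L && length(unique(keyfun(per))) == 1L
  consensus <- if (consistent) per[1L, -1L] else NULL
  structure(list(call_id = call$call_id, per_read = per,
                 consistent = consistent, consensus = consensus),
            class = "bp_alignment")
}

## ---- polarization ----------------------------------------------------------

#' Polarize a call against an outgroup genome under parsimony
#'
#' The region is located in the outgroup by an exact junction-adjacent
#' anchor; both allele probes (the reference allele carrying the segment, and
#' the derived allele without it, including any junction-inserted bases) are
#' aligned to the outgroup window and the closer allele decides: if the
#' outgroup carries the reference allele the variant is a derived deletion in
#' the strains (DELETION_IN_STRAIN); if it carries the derived allele with
#' similar breakpoints, parsimony implies the variant is an insertion in the
#' reference lineage (INSERTION_IN_REFERENCE). Insertion calls mirror this as
#' INSERTION_IN_STRAIN / DELETION_IN_REFERENCE. UNPOLARIZED when the flank
#' cannot be located, best identity falls below `min_identity` percent, or
#' the two alleles align equally well.
#'
#' @param call one-row call data.frame
#' @param outgroup outgroup `sim_genome` (NULL returns UNPOLARIZED with a
#'   warning)
#' @param genome reference `sim_genome`
#' @param window flank window in bp (default 500)
#' @param min_identity percent identity quality gate (default 70)
#' @param tie_margin minimum percent-identity difference between alleles
#' @return character scalar polarity state
#' @export
polarize <- function(call, outgroup, genome, window = 500L,
                     min_identity = 70, tie_margin = 0.5) {
  if (is.null(outgroup)) {
    warning("no outgroup genome available; call left unpolarized")
    return("UNPOLARIZED")
  }
  chrom <- genome$chromosomes[[call$chrom]]
  og <- outgroup$chromosomes[[call$chrom]]
  if (is.null(og)) return("UNPOLARIZED")
  ins <- call$kind == "insertion"
  s <- call$start; e <- call$end
  size <- if (ins) nchar(call$inserted_seq) else e - s + 1L
  J <- if (ins) call$inserted_seq else (call$inserted_seq %||% "")
  if (is.na(J)) J <- ""
  w <- window
  pre <- substr_clip(chrom, (if (ins) s - w + 1L else s - w), (if (ins) s else s - 1L))
  post <- substr_clip(chrom, (if (ins) s + 1L else e + 1L),
                      (if (ins) s + w else e + w))
  probeA <- if (ins) paste0(pre, post) else paste0(pre, substr(chrom, s, e), post)
  probeD <- if (ins) paste0(pre, J, post) else paste0(pre, J, post)
  ## anchor: junction-adjacent 5' 20-mer (falls back to the 3' side)
  anchor <- substring(pre, max(1L, nchar(pre) - 19L))
  hitpos <- NA_integer_
  for (mm in c(0L, 2L)) {
    m <- Biostrings::matchPattern(anchor, Biostrings::DNAString(og),
                                  max.mismatch = mm)
    if (length(m) > 0) { hitpos <- BiocGenerics::start(m)[1]; break }
  }
  if (is.na(hitpos)) {
    anchor2 <- substr(post, 1L, 20L)
    m <- Biostrings::matchPattern(anchor2, Biostrings::DNAString(og))
    if (length(m) > 0) hitpos <- BiocGenerics::start(m)[1] - nchar(pre) - size
    else return("UNPOLARIZED")
  }
  owin <- substr_clip(og, hitpos - nchar(pre) - size - 50L,
                      hitpos + nchar(pre) + size + nchar(post) + 50L)
  pid_of <- function(p) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(p), Biostrings::DNAString(owin),
      type = "global-local")
    Biostrings::pid(aln)
  }
  pidA <- pid_of(probeA)
  pidD <- pid_of(probeD)
  if (max(pidA, pidD) < min_identity) return("UNPOLARIZED")
  if (abs(pidA - pidD) < tie_margin) return("UNPOLARIZED")
  if (pidA > pidD) { if (ins) "INSERTION_IN_STRAIN" else "DELETION_IN_STRAIN" }
  else { if (ins) "DELETION_IN_REFERENCE" else "INSERTION_IN_REFERENCE" }
}

#' Polarize every call in a table
#' @inheritParams polarize
#' @param calls call data.frame
#' @return the input with a `polarity` column added
#' @export
polarize_all <- function(calls, outgroup, genome, window = 500L,
                         min_identity = 70, tie_margin = 0.5) {
  calls$polarity <- vapply(seq_len(nrow(calls)), function(i)
    polarize(calls[i, ], outgroup, genome, window, min_identity, tie_margin),
    character(1))
  calls
}

## ---- recurrence / complexity -----------------------------------------------

#' Detect recurrent and complex CNV regions
#'
#' Calls are grouped into regions by reference overlap. A region is RECURRENT
#' when it contains at least two distinct breakpoint junctions across at
#' least two strains (independent overlapping events in different
#' individuals); a region (or a lone pair) is COMPLEX when one strain carries
#' two or more distinct junctions within `proximity` bp, the footprint of a
#' single multi-breakpoint mutational event.
#'
#' @param calls call data.frame
#' @param proximity bp between junctions for the complex criterion
#' @return data.frame of regions: region_id, chrom, start, end, n_calls,
#'   n_junctions, strains, recurrent, complex, complex_strains,
#'   min_junction_gap
#' @export
find_recurrent_and_complex <- function(calls, proximity = 500L) {
  if (nrow(calls) == 0)
    return(data.frame(region_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_calls = integer(0), n_junctions = integer(0),
                      strains = character(0), recurrent = logical(0),
                      complex = logical(0), complex_strains = character(0),
                      min_junction_gap = integer(0)))
  gr <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$start,
                                                pmax(calls$start, calls$end)))
  ## region = overlap component, with `proximity` slack so nearby junctions
  ## in the same strain group together even when the calls do not touch
  red <- GenomicRanges::reduce(gr + proximity)
  memb <- GenomicRanges::findOverlaps(gr, red, select = "first")
  out <- list()
  for (r in unique(memb)) {
    cc <- calls[memb == r, , drop = FALSE]
    jkey <- paste(cc$kind, cc$start, cc$end, cc$inserted_seq)
    strains_all <- unique(unlist(strsplit(cc$strains, ",")))
    recurrent <- length(unique(jkey)) >= 2L && length(strains_all) >= 2L
    cx <- FALSE; cx_strains <- character(0); min_gap <- NA_integer_
    for (st in strains_all) {
      mine <- cc[vapply(strsplit(cc$strains, ","), function(x) st %in% x,
                        logical(1)), , drop = FALSE]
      if (length(unique(paste(mine$kind, mine$start, mine$end,
                              mine$inserted_seq))) < 2L) next
      mine <- mine[order(mine$start), ]
      gaps <- pmax(0L, mine$start[-1L] - mine$end[-nrow(mine)] - 1L)
      if (any(gaps <= proximity)) {
        cx <- TRUE
        cx_strains <- c(cx_strains, st)
        min_gap <- min(min_gap, min(gaps), na.rm = TRUE)
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      region_id = paste0("region", r), chrom = cc$chrom[1],
      start = min(cc$start), end = max(cc$end), n_calls = nrow(cc),
      n_junctions = length(unique(jkey)),
      strains = paste(sort(strains_all), collapse = ","),
      recurrent = recurrent, complex = cx,
      complex_strains = paste(sort(unique(cx_strains)), collapse = ","),
      min_junction_gap = min_gap)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
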