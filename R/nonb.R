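## Non-B DNA motif prediction and breakpoint enrichment. Five motif classes
## are detected natively: Z-DNA tracts, G-quadruplex-forming sequence,
## inverted repeats (cruciform), mirror repeats (triplex) and direct repeats
## (slipped-strand). Thresholds follow common non-B database conventions and
## are all configurable; arms/units are perfect (no mismatches), which keeps
## the detectors exactly decidable against brute-force enumeration.

#' Non-B scan configuration
#' @param min_z minimum Z-DNA tract length (alternating purine/pyrimidine
#'   dinucleotides from {GC, CG, GT, TG, AC, CA}), default 10 bp
#' @param min_grun minimum G-run length for quadruplexes, default 3
#' @param max_loop maximum quadruplex loop length, default 7
#' @param min_arm minimum inverted/mirror-repeat arm, default 10 bp
#' @param max_spacer maximum spacer between arms/units, default 8 bp
#' @param min_unit minimum direct-repeat unit, default 10 bp
#' @param classes which classes to scan
#' @return a list of class `nonb_config`
#' @export
nonb_config <- function(min_z = 10L, min_grun = 3L, max_loop = 7L,
                        min_arm = 10L, max_spacer = 8L, min_unit = 10L,
                        classes = c("ZDNA", "G4", "INVERTED_REPEAT",
                                    "MIRROR_REPEAT", "DIRECT_REPEAT")) {
  structure(list(min_z = min_z, min_grun = min_grun, max_loop = max_loop,
                 min_arm = min_arm, max_spacer = max_spacer,
                 min_unit = min_unit, classes = match.arg(
                   classes, c("ZDNA", "G4", "INVERTED_REPEAT",
                              "MIRROR_REPEAT", "DIRECT_REPEAT"),
                   several.ok = TRUE)),
            class = "nonb_config")
}

#' Scan sequences for non-B DNA motifs
#'
#' Overlapping candidate instances of a class (per strand for quadruplexes)
#' are merged into maximal intervals. Ambiguous (non-ACGT) positions are
#' masked so they can never participate in a motif; a message reports how
#' many were skipped.
#'
#' @param seqs character vector of DNA sequences (optionally named)
#' @param config a [nonb_config()]
#' @return data.frame: seq (name or index), motif_class, start, end, strand
#'   (1-based closed intervals)
#' @export
scan_nonb <- function(seqs, config = nonb_config()) {
  stopifnot(inherits(config, "nonb_config"))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    n_amb <- sum(vapply(gregexpr("[^ACGT]", seqs[bad]),
                        function(x) sum(x > 0), integer(1)))
    message("masked ", n_amb, " ambiguous base(s) in ", sum(bad),
            " sequence(s)")
    ## masked positions get pseudo-random sentinel letters (deterministic,
    ## non-periodic) so runs of ambiguity can never line up into a motif
    sent <- c("B", "D", "E", "F", "H", "I", "J", "K", "L", "M", "O")
    for (i in which(bad)) {
      v <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      at <- which(!v %in% BASES)
      v[at] <- with_seed(12345L + length(v),
                         sample(sent, length(at), replace = TRUE))
      seqs[i] <- paste(v, collapse = "")
    }
  }
  cl <- config$classes
  res <- cpp_scan_nonb(seqs, config$min_z, config$min_grun, config$max_loop,
                       config$min_arm, config$max_spacer, config$min_unit,
                       "ZDNA" %in% cl, "G4" %in% cl,
                       "INVERTED_REPEAT" %in% cl, "MIRROR_REPEAT" %in% cl,
                       "DIRECT_REPEAT" %in% cl)
  if (!is.null(names(seqs))) res$seq <- names(seqs)[res$seq]
  res
}

#' Scan a genome and write motifs as BED
#' @param genome `sim_genome`
#' @param path BED output (name = class, score = length)
#' @param config a [nonb_config()]
#' @return the motif data.frame, invisibly
#' @export
write_nonb_bed <- function(genome, path, config = nonb_config()) {
  mot <- scan_nonb(genome$chromosomes, config)
  bed <- data.frame(mot$seq, mot$start - 1L, mot$end, mot$motif_class,
                    mot$end - mot$start + 1L, mot$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(mot)
}

#' Breakpoint regions for non-B enrichment analysis
#'
#' Two regions per deletion-type call (one per breakpoint), each spanning
#' `inner` bp inside the CNV plus `flank` bp outside (225 bp by default).
#' The enrichment test window is the 2 x `inner` bp centred on the
#' breakpoint (25 bp in + 25 bp out); the full span is used for positional
#' histograms. CNVs shorter than 2 x `inner` have the inner part truncated
#' at the CNV midpoint and are flagged.
#'
#' @param calls call data.frame (deletion-type calls are used; their sequence
#'   is reference-resident)
#' @param genome reference `sim_genome`
#' @param inner bp inside the CNV (default 25)
#' @param flank bp outside the CNV (default 200)
#' @return data.frame of regions: region_id, call_id, side ("5p"/"3p"),
#'   chrom, start, end, inside_at ("left"/"right": which end of the window is
#'   the CNV interior), inner_len, flank_len, truncated
#' @export
breakpoint_regions <- function(calls, genome, inner = 25L, flank = 200L) {
  dels <- calls[calls$kind %in% c("deletion", "tandem_dup"), , drop = FALSE]
  chrom_len <- vapply(genome$chromosomes, nchar, integer(1))
  out <- list()
  for (i in seq_len(nrow(dels))) {
    cc <- dels[i, ]
    n <- chrom_len[[cc$chrom]]
    size <- as.integer(cc$end - cc$start + 1L)
    inn <- as.integer(min(inner, size %/% 2L))
    trunc_inner <- inn < inner
    ## 5' breakpoint: outside [start-flank, start-1], inside [start, start+inn-1]
    s5 <- as.integer(max(1L, cc$start - flank)); e5 <- as.integer(cc$start + inn - 1L)
    ## 3' breakpoint: inside [end-inn+1, end], outside [end+1, end+flank]
    s3 <- as.integer(cc$end - inn + 1L); e3 <- as.integer(min(n, cc$end + flank))
    out[[length(out) + 1L]] <- data.frame(
      region_id = paste0(cc$call_id, c("_5p", "_3p")),
      call_id = cc$call_id, side = c("5p", "3p"), chrom = cc$chrom,
      start = c(s5, s3), end = c(e5, e3),
      inside_at = c("right", "left"),
      inner_len = inn,
      flank_len = as.integer(c(cc$start - s5, e3 - cc$end)),
      truncated = trunc_inner | c(cc$start - s5 < flank, e3 - cc$end < flank))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(
    region_id = character(0), call_id = character(0), side = character(0),
    chrom = character(0), start = integer(0), end = integer(0),
    inside_at = character(0), inner_len = integer(0), flank_len = integer(0),
    truncated = logical(0))
  rownames(res) <- NULL
  res
}

## positive/histogram machinery shared by real and control regions.
## For each region sequence: positive iff any motif overlaps the test window
## (inner_len bases each side of the breakpoint boundary); histogram
## positions are folded so position 1..inner is the CNV interior and
## inner+1..inner+flank walks outward (breakpoint at inner/inner+1).
region_motif_stats <- function(seqs, inside_at, inner_len, flank_len,
                               config, span = 225L) {
  mot <- scan_nonb(seqs, config)
  n <- length(seqs)
  positive <- rep(FALSE, n)
  hist_pos <- integer(0)
  if (nrow(mot) > 0) {
    idx <- as.integer(mot$seq)
    L <- nchar(seqs)[idx]
    inn <- inner_len[idx]
    ## breakpoint boundary sits after `bnd` window positions
    bnd <- ifelse(inside_at[idx] == "right", L - inn, inn)
    hit <- mot$start <= bnd + inn & mot$end >= bnd - inn + 1L
    positive[unique(idx[hit])] <- TRUE
    ## folded midpoint coordinate: 1 = deepest inside the CNV, then outward
    mid <- floor((mot$start + mot$end) / 2)
    fold <- ifelse(inside_at[idx] == "right", L - mid + 1L, mid)
    fold <- fold[fold >= 1L & fold <= span]
    hist_pos <- fold
  }
  list(positive = positive, hist = tabulate(hist_pos, nbins = span))
}

#' Non-B enrichment at breakpoints versus shuffled controls
#'
#' Controls are size-preserving coordinate shuffles of the breakpoint
#' regions within their chromosome (`control_factor` per region). A region is
#' motif-positive when any motif overlaps its test window (the `inner` bp
#' each side of the breakpoint). Positives are compared by an exact 2x2
#' test; positional histograms of motif midpoints over the folded span
#' (position 1 = deepest inside the CNV, breakpoint boundary at
#' `inner`/`inner`+1) are returned for both sets.
#'
#' @param regions data.frame from [breakpoint_regions()]
#' @param genome reference `sim_genome`
#' @param control_factor controls per region (default 10)
#' @param seed integer seed for control placement
#' @param config a [nonb_config()]
#' @return list of class `enrichment_result`: counts (2x2 matrix), odds_ratio
#'   (Inf allowed), p_value, fisher (full TestResult), histograms (real and
#'   control motif-midpoint counts over the span), n_regions, n_controls
#' @export
enrichment_test <- function(regions, genome, control_factor = 10L, seed = 1L,
                            config = nonb_config()) {
  stopifnot(nrow(regions) > 0, control_factor >= 1L)
  span <- max(regions$end - regions$start + 1L)
  seqs <- vapply(seq_len(nrow(regions)), function(i)
    substr(genome$chromosomes[[regions$chrom[i]]], regions$start[i],
           regions$end[i]), character(1))
  real <- region_motif_stats(seqs, regions$inside_at, regions$inner_len,
                             regions$flank_len, config, span)
  ## shuffled controls: same chromosome, same width, inside the mask
  ctl <- with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(regions))) {
      w <- regions$end[i] - regions$start[i] + 1L
      m <- genome$mask[genome$mask$chrom == regions$chrom[i], , drop = FALSE]
      lo <- if (nrow(m)) m$start[1] else 1L
      hi <- (if (nrow(m)) m$end[nrow(m)] else
        nchar(genome$chromosomes[[regions$chrom[i]]])) - w + 1L
      if (hi < lo) stop("chromosome ", regions$chrom[i],
                        " too short for control placement")
      pos <- lo + floor(runif(control_factor) * (hi - lo + 1L))
      out[[i]] <- data.frame(chrom = regions$chrom[i], start = as.integer(pos),
                             end = as.integer(pos) + w - 1L,
                             inside_at = regions$inside_at[i],
                             inner_len = regions$inner_len[i],
                             flank_len = regions$flank_len[i])
    }
    do.call(rbind, out)
  })
  cseqs <- vapply(seq_len(nrow(ctl)), function(i)
    substr(genome$chromosomes[[ctl$chrom[i]]], ctl$start[i], ctl$end[i]),
    character(1))
  ctrl <- region_motif_stats(cseqs, ctl$inside_at, ctl$inner_len,
                             ctl$flank_len, config, span)
  counts <- matrix(c(sum(real$positive), sum(!real$positive),
                     sum(ctrl$positive), sum(!ctrl$positive)),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("breakpoint", "control"),
                                   c("with_motif", "without_motif")))
  ft <- fisher_exact(counts)
  a <- counts[1, 1]; b <- counts[1, 2]; cc <- counts[2, 1]; d <- counts[2, 2]
  or <- (a * d) / (b * cc)   # sample odds ratio; Inf when controls are clean
  structure(list(counts = counts, odds_ratio = or, p_value = ft$p_value,
                 fisher = ft,
                 histograms = list(real = real$hist, control = ctrl$hist),
                 n_regions = nrow(regions), n_controls = nrow(ctl)),
            class = "enrichment_result")
}
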