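## Where does inserted DNA come from? Each insertion is attributed to a
## tandem duplication (a full-length nearby copy), a repeat expansion (an
## integer-phase extension of a flanking short-repeat tract), or filler DNA
## (no full-length source). For filler, the fraction of inserted bases
## explicable by short direct/inverted repeats in the neighborhood is
## quantified against coordinate-shuffled controls.

#' Classify the origin of an inserted sequence
#'
#' Checks in order: (1) the insertion is a phase-consistent expansion of a
#' 1-6 bp unit repeated in the immediately adjacent flank
#' (REPEAT_EXPANSION); (2) a full-length copy at >= `min_identity` identity
#' within `search_radius` bp of the insertion point (TANDEM_DUP); otherwise
#' (3) FILLER. Expansion is tested first because an expansion of an adjacent
#' tract is always also a full-length local copy; the short-unit account is
#' the more specific one.
#'
#' @param ins one-row insertion call (kind "insertion", non-empty
#'   inserted_seq)
#' @param genome reference `sim_genome`
#' @param search_radius bp searched on each side of the insertion point for a
#'   full-length copy (default 1000; the tandem duplications of interest are
#'   copies of nearby sequence)
#' @param min_identity identity required of a full-length copy (fraction,
#'   default 0.9)
#' @return list of class `insertion_origin`: label, evidence (data.frame of
#'   the matching interval or repeat unit, possibly empty)
#' @export
classify_insertion_origin <- function(ins, genome, search_radius = 1000L,
                                      min_identity = 0.9) {
  if (ins$kind != "insertion") stop("call is not an insertion")
  I <- ins$inserted_seq
  if (is.null(I) || is.na(I) || nchar(I) == 0) stop("empty inserted sequence")
  chrom <- genome$chromosomes[[ins$chrom]]
  ## repeat expansion: smallest unit of 1-6 bp such that the insertion is
  ## copies of the unit (ragged final copy allowed) and the adjacent flank
  ## continues the same tract in phase
  for (ul in 1:6) {
    unit <- substr(I, 1L, ul)
    if (nchar(unit) < ul) break
    full <- strrep(unit, ceiling(nchar(I) / ul))
    if (substr(full, 1L, nchar(I)) != I) next
    if (nchar(I) < 2L * ul) next                 # need at least two copies
    ## phase: the insertion extends the tract ending at the insertion point,
    ## so the `ul` bases 5' of the point must be the unit rotated to end
    ## where the insertion begins
    pre_unit <- substr_clip(chrom, ins$start - ul + 1L, ins$start)
    post_unit <- substr_clip(chrom, ins$start + 1L, ins$start + ul)
    tract_5p <- nchar(pre_unit) == ul && pre_unit == unit
    tract_3p <- nchar(post_unit) == ul && post_unit == unit
    if (tract_5p || tract_3p) {
      ev <- data.frame(kind = "repeat_unit", unit = unit,
                       copies = nchar(I) / ul,
                       flank_side = if (tract_5p) "5p" else "3p")
      return(structure(list(label = "REPEAT_EXPANSION", evidence = ev),
                       class = "insertion_origin"))
    }
  }
  lo <- max(1L, ins$start - search_radius + 1L)
  hi <- min(nchar(chrom), ins$start + search_radius)
  local <- substr(chrom, lo, hi)
  hits <- cpp_diag_hits(I, local, nchar(I), min_identity)
  if (nrow(hits) > 0) {
    ev <- data.frame(kind = "full_length_copy",
                     chrom = ins$chrom,
                     start = lo + hits$b_start[1] - 1L,
                     end = lo + hits$b_start[1] + hits$length[1] - 2L,
                     identity = hits$matches[1] / hits$length[1])
    return(structure(list(label = "TANDEM_DUP", evidence = ev),
                     class = "insertion_origin"))
  }
  structure(list(label = "FILLER", evidence = data.frame()),
            class = "insertion_origin")
}

#' Match an insertion against its neighborhood
#'
#' Finds all maximal exact matches of at least `min_match` bp between the
#' inserted sequence and the trimmed flanks, on the forward strand and (when
#' `both_strands`) against the reverse complement of the flanks (inverted
#' repeats). `matched_nt` is the number of insertion bases covered by at
#' least one match (union, no double counting); a greedy longest-first
#' non-overlapping tiling of the insertion is reported in `segments`.
#'
#' @param ins_seq inserted sequence
#' @param five_flank,three_flank flank sequences already trimmed to the
#'   active window
#' @param min_match minimum exact-match length (default 7 bp, the lower end
#'   of the short matching repeats this analysis targets)
#' @param both_strands also match the reverse complement (default TRUE)
#' @return list of class `neighborhood_match`: window (flank length),
#'   matched_nt, matched_fraction, segments (ins_start, ins_end, flank,
#'   flank_start, flank_end, orientation, length)
#' @export
match_neighborhood <- function(ins_seq, five_flank, three_flank,
                               min_match = 7L, both_strands = TRUE) {
  n <- nchar(ins_seq)
  is_v <- integer(0); ie_v <- integer(0); fl_v <- character(0)
  fs_v <- integer(0); fe_v <- integer(0); or_v <- character(0)
  gather <- function(flank, label, orient) {
    if (nchar(flank) < min_match) return(invisible())
    h <- cpp_mem_hits(ins_seq, flank, min_match)
    if (nrow(h) == 0) return(invisible())
    is_v <<- c(is_v, h$a_start)
    ie_v <<- c(ie_v, h$a_start + h$length - 1L)
    fs_v <<- c(fs_v, h$b_start)
    fe_v <<- c(fe_v, h$b_start + h$length - 1L)
    fl_v <<- c(fl_v, rep(label, nrow(h)))
    or_v <<- c(or_v, rep(orient, nrow(h)))
    invisible()
  }
  gather(five_flank, "5p", "direct")
  gather(three_flank, "3p", "direct")
  if (both_strands) {
    gather(revcomp(five_flank), "5p", "inverted")
    gather(revcomp(three_flank), "3p", "inverted")
  }
  if (length(is_v) == 0)
    return(structure(list(window = nchar(five_flank), matched_nt = 0L,
                          matched_fraction = 0, segments = data.frame()),
                     class = "neighborhood_match"))
  matched_nt <- union_coverage(is_v, ie_v)
  ## greedy longest-first non-overlapping tiling on the insertion
  o <- order(-(ie_v - is_v), is_v)
  taken <- rep(FALSE, n)
  keep <- logical(length(o))
  for (j in seq_along(o)) {
    i <- o[j]
    span <- is_v[i]:ie_v[i]
    if (any(taken[span])) next
    taken[span] <- TRUE
    keep[j] <- TRUE
  }
  sel <- o[keep]
  segments <- data.frame(ins_start = is_v[sel], ins_end = ie_v[sel],
                         flank = fl_v[sel], flank_start = fs_v[sel],
                         flank_end = fe_v[sel], orientation = or_v[sel],
                         length = ie_v[sel] - is_v[sel] + 1L)
  structure(list(window = nchar(five_flank), matched_nt = matched_nt,
                 matched_fraction = matched_nt / n, segments = segments),
            class = "neighborhood_match")
}

#' Neighborhood matching for a set of insertions at one window size
#' @param calls insertion call data.frame (or shuffled controls; a
#'   `footprint_end` column marks reference-resident pseudo-insertions whose
#'   3' neighborhood starts beyond their own footprint)
#' @param genome reference `sim_genome`
#' @param window flank window in bp (e.g. 30, 60, 90, 120)
#' @inheritParams match_neighborhood
#' @return data.frame: call_id, window, ins_len, matched_nt, matched_fraction,
#'   any_match
#' @export
neighborhood_match_table <- function(calls, genome, window = 30L,
                                     min_match = 7L, both_strands = TRUE) {
  n <- nrow(calls)
  ids <- calls$call_id %||% paste0("ins", seq_len(n))
  chroms <- calls$chrom; starts <- calls$start
  fes <- calls$footprint_end %||% calls$start
  ins <- calls$inserted_seq
  matched <- integer(n)
  for (i in seq_len(n)) {
    chrom <- genome$chromosomes[[chroms[i]]]
    five <- substr_clip(chrom, starts[i] - window + 1L, starts[i])
    three <- substr_clip(chrom, fes[i] + 1L, fes[i] + window)
    matched[i] <- match_neighborhood(ins[i], five, three, min_match,
                                     both_strands)$matched_nt
  }
  data.frame(call_id = ids, window = window, ins_len = nchar(ins),
             matched_nt = matched, matched_fraction = matched / nchar(ins),
             any_match = matched > 0L)
}

#' Coordinate-shuffled control pseudo-insertions
#'
#' For each real insertion, `factor` pseudo-insertions of identical size are
#' placed uniformly at random on the same chromosome (inside the euchromatin
#' mask when available); the pseudo-inserted sequence is the reference
#' sequence at the shuffled location, so control neighborhoods carry the
#' genome's true repeat background. Size multisets are preserved exactly per
#' chromosome.
#'
#' @param insertions insertion call data.frame
#' @param genome reference `sim_genome`
#' @param factor controls per real insertion (default 10)
#' @param seed integer seed
#' @param margin bp kept clear of chromosome/mask edges (window headroom)
#' @return control data.frame in call-table form (kind "insertion",
#'   inserted_seq from the reference), with `source_id` and `replicate`
#' @export
shuffle_controls <- function(insertions, genome, factor = 10L, seed = 1L,
                             margin = 200L) {
  stopifnot(factor >= 1L)
  with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(insertions))) {
      cc <- insertions[i, ]
      chrom <- genome$chromosomes[[cc$chrom]]
      L <- nchar(cc$inserted_seq)
      if (L == 0L) L <- cc$end - cc$start + 1L
      m <- genome$mask[genome$mask$chrom == cc$chrom, , drop = FALSE]
      lo <- if (nrow(m)) m$start[1] + margin else 1L + margin
      hi <- (if (nrow(m)) m$end[nrow(m)] else nchar(chrom)) - margin - L
      if (hi <= lo) {
        warning("chromosome ", cc$chrom, " too short for insertion of ", L,
                " bp plus window; skipped")
        next
      }
      pos <- lo + floor(runif(factor) * (hi - lo + 1L))
      out[[length(out) + 1L]] <- data.frame(
        call_id = paste0(cc$call_id, "_ctl", seq_len(factor)),
        source_id = cc$call_id, replicate = seq_len(factor),
        chrom = cc$chrom, start = as.integer(pos), end = as.integer(pos),
        kind = "insertion",
        inserted_seq = substring(chrom, pos + 1L, pos + L),
        ## the pseudo-inserted sequence is resident in the reference, so its
        ## 3' neighborhood starts beyond this footprint (a real insertion is
        ## zero-width and has no footprint)
        footprint_end = as.integer(pos + L),
        size = L)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Enrichment of neighborhood matching in real versus control insertions
#'
#' Per window: (a) a rank-sum test comparing the distributions of matched
#' fractions, and (b) an exact 2x2 test on the counts of insertions with at
#' least one neighborhood match.
#'
#' @param real match table from [neighborhood_match_table()] on real calls
#' @param controls match table on shuffled controls (same window)
#' @return list: window, wilcoxon (TestResult), fisher (TestResult),
#'   match table (2x2 counts), summary fractions; degenerate all-zero input
#'   returns p = 1 with `degenerate = TRUE`
#' @export
filler_enrichment_tests <- function(real, controls) {
  stopifnot(nrow(real) > 0, nrow(controls) > 0)
  w <- unique(c(real$window, controls$window))
  if (length(w) != 1L) stop("real and control tables use different windows")
  degenerate <- all(real$matched_nt == 0) && all(controls$matched_nt == 0)
  if (degenerate) {
    wt <- list(method = "wilcoxon_rank_sum", statistic = NA_real_, p_value = 1,
               alternative = "two_sided")
    ft <- list(method = "fisher_exact", statistic = NA_real_, p_value = 1,
               alternative = "two_sided")
  } else {
    wt <- wilcoxon_rank_sum(real$matched_fraction, controls$matched_fraction)
    tab <- matrix(c(sum(real$any_match), sum(!real$any_match),
                    sum(controls$any_match), sum(!controls$any_match)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("real", "control"),
                                  c("with_match", "without_match")))
    ft <- fisher_exact(tab)
  }
  tab <- matrix(c(sum(real$any_match), sum(!real$any_match),
                  sum(controls$any_match), sum(!controls$any_match)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("real", "control"),
                                c("with_match", "without_match")))
  list(window = w, wilcoxon = wt, fisher = ft, table = tab,
       real_match_rate = mean(real$any_match),
       control_match_rate = mean(controls$any_match),
       degenerate = degenerate)
}
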