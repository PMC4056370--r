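## Native split-read mapper: exact k-mer anchors at both read ends, greedy
## gapless extension toward the middle, and at most one large gap per read.
## This replaces the two-pass map-then-realign strategy (strict mapper to
## remove concordant reads, gap-tolerant aligner for the remainder) with a
## single pass that labels reads concordant, split, ambiguous or unmapped.

#' Map reads to a reference with split-read awareness
#'
#' Each read is anchored by exact k-mers at its first and last `k` bases (in
#' both orientations), extended greedily inwards, and decomposed into one
#' block (concordant) or two blocks separated by a single reference gap
#' (deletion), read gap (insertion), or a flipped block order (the tandem
#' duplication signature). Junction ambiguity from microhomology is resolved
#' to the leftmost representation. Only unique best alignments are kept;
#' ties are reported as `ambiguous` and excluded downstream.
#'
#' @param reads a `read_set` data.frame (id, strain, seq, ...)
#' @param genome a `sim_genome` (or any object with `$chromosomes` as a named
#'   character vector)
#' @param k anchor seed length (>= 11)
#' @param max_mm_rate mismatch rate tolerated during extension
#' @param min_rematch matches required after a mismatch for extension to
#'   continue through it; the default (8) makes bridging a true junction on
#'   chance matches negligible while still crossing isolated sequencing
#'   errors
#' @param split_penalty score penalty for a two-block decomposition, so
#'   contiguous alignments win ties
#' @param max_anchor_hits per-anchor cap on candidate positions
#' @return data.frame of alignment blocks: read_id, strain, chrom, strand,
#'   read_start/read_end (in mapped orientation), ref_start/ref_end,
#'   mismatches, block, n_blocks, status, align_start, read_len. Unmapped and
#'   ambiguous reads appear with `chrom = NA` and their status.
#' @export
map_reads <- function(reads, genome, k = 20L, max_mm_rate = 0.05,
                      min_rematch = 8L, split_penalty = 4L,
                      max_anchor_hits = 25L) {
  stopifnot(k >= 11L)
  k <- as.integer(k)
  chroms <- genome$chromosomes
  n_reads <- nrow(reads)
  seq_f <- reads$seq
  seq_r <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seq_f)))
  rlen <- nchar(seq_f)
  usable <- rlen >= 2L * k - 5L  # anchors may overlap slightly on short reads

  anchor <- function(s, left) if (left) substr(s, 1L, k) else
    substring(s, nchar(s) - k + 1L, nchar(s))
  ## anchor tables: 4 per read (fwd-left, fwd-right, rc-left, rc-right)
  anchors <- c(anchor(seq_f, TRUE), anchor(seq_f, FALSE),
               anchor(seq_r, TRUE), anchor(seq_r, FALSE))
  keepA <- rep(usable, 4L) & !grepl("[^ACGT]", anchors)
  hit_chrom <- vector("list", length(anchors))
  hit_pos <- vector("list", length(anchors))
  if (any(keepA)) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(anchors[keepA]))
    idx_map <- which(keepA)
    for (ch in names(chroms)) {
      mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(chroms[[ch]]))
      st <- Biostrings::startIndex(mi)   # plain list: no per-pattern S4 cost
      nz <- which(lengths(st) > 0L)
      for (j in nz) {
        p <- st[[j]]
        if (length(p) > max_anchor_hits) p <- p[seq_len(max_anchor_hits)]
        gi <- idx_map[j]
        hit_chrom[[gi]] <- c(hit_chrom[[gi]], rep(ch, length(p)))
        hit_pos[[gi]] <- c(hit_pos[[gi]], p)
      }
    }
  }

  ## per-read best-candidate scan; all candidate state kept in flat vectors
  o_chrom <- character(n_reads); o_strand <- character(n_reads)
  o_status <- character(n_reads)
  o_b <- matrix(NA_integer_, n_reads, 10L)  # rs1 re1 fs1 fe1 mm1 rs2 re2 fs2 fe2 mm2
  for (i in seq_len(n_reads)) {
    n <- rlen[i]
    best_score <- -Inf; tie <- FALSE
    b_status <- "unmapped"; b_chrom <- NA_character_; b_strand <- NA_character_
    b_key <- ""
    bv <- rep(NA_integer_, 10L)
    done <- FALSE
    for (ori in c("+", "-")) {
      if (done) break
      s <- if (ori == "+") seq_f[i] else seq_r[i]
      il <- i + (if (ori == "+") 0L else 2L * n_reads)
      ir <- i + (if (ori == "+") n_reads else 3L * n_reads)
      lch <- hit_chrom[[il]]; lpo <- hit_pos[[il]]
      rch <- hit_chrom[[ir]]; rpo <- hit_pos[[ir]]
      nl <- length(lpo); nr <- length(rpo)
      if (nl == 0L && nr == 0L) next
      lL <- integer(nl); lmm <- integer(nl)
      for (j in seq_len(nl)) {
        e <- cpp_extend_greedy(s, substr_clip(chroms[[lch[j]]], lpo[j],
                                              lpo[j] + n - 1L),
                               max_mm_rate, min_rematch)
        lL[j] <- e[1]; lmm[j] <- e[2]
      }
      ## fast path: a unique perfect full-length match cannot be beaten
      pf <- which(lL == n & lmm == 0L)
      if (length(pf) == 1L && nl == length(pf) &&
          best_score < n - 1e-9) {
        j <- pf[1L]
        best_score <- n; tie <- FALSE; b_status <- "concordant"
        b_chrom <- lch[j]; b_strand <- ori
        b_key <- paste0(ori, lch[j], ":", lpo[j])
        bv <- c(1L, n, lpo[j], lpo[j] + n - 1L, 0L, rep(NA_integer_, 5L))
        done <- TRUE
        next
      }
      rL <- integer(nr); rmm <- integer(nr); rqe <- rpo + k - 1L
      for (j in seq_len(nr)) {
        e <- cpp_extend_greedy_rev(s, substr_clip(chroms[[rch[j]]],
                                                  rqe[j] - n + 1L, rqe[j]),
                                   max_mm_rate, min_rematch)
        rL[j] <- e[1]; rmm[j] <- e[2]
      }
      consider <- function(status, chrom, key, score, vec) {
        if (score > best_score + 1e-9) {
          best_score <<- score; tie <<- FALSE; b_status <<- status
          b_chrom <<- chrom; b_strand <<- ori; b_key <<- key; bv <<- vec
        } else if (score > best_score - 1e-9 && key != b_key) tie <<- TRUE
      }
      for (j in seq_len(nl)) {
        if (lL[j] < k) next
        if (lL[j] == n)
          consider("concordant", lch[j], paste0(ori, lch[j], ":", lpo[j]),
                   n - 3L * lmm[j],
                   c(1L, n, lpo[j], lpo[j] + n - 1L, lmm[j], rep(NA_integer_, 5L)))
      }
      if (nl > 0L && nr > 0L) {
        for (a in which(lL >= k & lL < n)) for (b in which(rL >= k & rL < n)) {
          if (lch[a] != rch[b]) next
          L1 <- lL[a]; L2 <- rL[b]
          p <- lpo[a]; qe <- rqe[b]
          o <- L1 + L2 - n
          if (o > 0L) L1 <- L1 - o            # trim read overlap, keep right
          if (L1 < 1L) next
          A <- p + L1 - 1L
          B <- qe - L2 + 1L
          readgap <- n - L1 - L2
          if (qe < p) {                       # flipped order: tandem dup
            if (readgap != 0L) next
          } else {
            g <- B - A - 1L
            if (g < 0L) {                     # ref overlap: trim left again
              L1 <- L1 + g
              if (L1 < 1L) next
              A <- A + g; readgap <- readgap - g; g <- 0L
            }
            if (g == 0L && readgap == 0L) next
          }
          sc <- (L1 + L2) - 3L * (lmm[a] + rmm[b]) - split_penalty
          consider("split", lch[a],
                   paste0(ori, lch[a], ":", p, ":", qe, ":", L1, ":", L2),
                   sc, c(1L, L1, p, A, lmm[a], n - L2 + 1L, n, B, qe, rmm[b]))
        }
      }
    }
    if (tie) b_status <- "ambiguous"
    o_status[i] <- b_status
    o_chrom[i] <- if (b_status %in% c("unmapped", "ambiguous")) NA_character_
      else b_chrom
    o_strand[i] <- if (is.na(o_chrom[i])) NA_character_ else b_strand
    o_b[i, ] <- if (is.na(o_chrom[i])) rep(NA_integer_, 10L) else bv
  }
  two <- !is.na(o_b[, 6L])
  one_rows <- data.frame(
    read_id = reads$id, strain = reads$strain, chrom = o_chrom,
    strand = o_strand, read_start = o_b[, 1L], read_end = o_b[, 2L],
    ref_start = o_b[, 3L], ref_end = o_b[, 4L], mismatches = o_b[, 5L],
    block = 1L, n_blocks = ifelse(is.na(o_chrom), 0L, ifelse(two, 2L, 1L)),
    status = o_status,
    align_start = pmin(o_b[, 3L], ifelse(two, o_b[, 8L], o_b[, 3L])),
    read_len = rlen)
  out <- one_rows
  if (any(two)) {
    two_rows <- data.frame(
      read_id = reads$id[two], strain = reads$strain[two], chrom = o_chrom[two],
      strand = o_strand[two], read_start = o_b[two, 6L],
      read_end = o_b[two, 7L], ref_start = o_b[two, 8L],
      ref_end = o_b[two, 9L], mismatches = o_b[two, 10L], block = 2L,
      n_blocks = 2L, status = o_status[two],
      align_start = pmin(o_b[two, 3L], o_b[two, 8L]), read_len = rlen[two])
    out <- rbind(one_rows, two_rows)
    out <- out[order(match(out$read_id, reads$id), out$block), ]
  }
  rownames(out) <- NULL
  out
}

#' Extract split-read signatures from alignments
#'
#' One signature per qualifying two-block alignment: a reference gap of at
#' least `min_size` (deletion; any unaligned read bases between the blocks
#' are kept as junction-inserted sequence), a read gap of at least `min_size`
#' with contiguous reference (insertion), or flipped block order on the same
#' strand (tandem duplication). Gaps below `min_size` produce nothing.
#'
#' @param alignments data.frame from [map_reads()] (or [import_psl()])
#' @param min_size minimum CNV size in bp; 25 is the lower bound separating
#'   CNVs from ordinary indels
#' @param reads optional `read_set` to recover inserted sequence for
#'   insertions and complex deletions
#' @return data.frame of signatures: read_id, strain, chrom, strand, kind,
#'   start, end, size, inserted_seq, min_end_distance, align_start
#' @export
detect_split_signatures <- function(alignments, min_size = 25L, reads = NULL) {
  al <- alignments[alignments$status == "split" & alignments$n_blocks == 2L, ,
                   drop = FALSE]
  if (nrow(al) == 0)
    return(data.frame(read_id = character(0), strain = character(0),
                      chrom = character(0), strand = character(0),
                      kind = character(0), start = integer(0), end = integer(0),
                      size = integer(0), inserted_seq = character(0),
                      min_end_distance = integer(0), align_start = integer(0)))
  if (any(al$read_end < al$read_start)) stop("malformed block list")
  seq_by_id <- NULL
  if (!is.null(reads)) seq_by_id <- setNames(reads$seq, reads$id)
  out <- vector("list", 0L)
  for (id in unique(al$read_id)) {
    bl <- al[al$read_id == id, ]
    bl <- bl[order(bl$block), ]
    if (nrow(bl) != 2L) stop("malformed block list for read ", id)
    L1e <- bl$read_end[1]; r2 <- bl$read_start[2]
    A <- bl$ref_end[1]; B <- bl$ref_start[2]
    n <- bl$read_len[1]
    readgap <- r2 - L1e - 1L
    mid <- ""
    if (readgap > 0L && !is.null(seq_by_id) && id %in% names(seq_by_id)) {
      s <- seq_by_id[[id]]
      if (bl$strand[1] == "-") s <- revcomp(s)
      mid <- substr(s, L1e + 1L, r2 - 1L)
    }
    if (B < bl$ref_start[1] && bl$ref_end[2] < bl$ref_start[1]) {
      kind <- "tandem_dup"; st <- B; en <- A; size <- en - st + 1L
    } else {
      g <- B - A - 1L
      if (g >= 1L) {
        kind <- "deletion"; st <- A + 1L; en <- B - 1L; size <- g
      } else if (g == 0L && readgap > 0L) {
        kind <- "insertion"; st <- A; en <- A; size <- readgap
      } else next
    }
    if (size < min_size) next
    ends <- c(L1e, n - r2 + 1L)  # junction distance from the two read ends
    out[[length(out) + 1L]] <- data.frame(
      read_id = id, strain = bl$strain[1], chrom = bl$chrom[1],
      strand = bl$strand[1], kind = kind, start = st, end = en,
      size = size, inserted_seq = mid, min_end_distance = min(ends),
      align_start = bl$align_start[1])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(
    read_id = character(0), strain = character(0), chrom = character(0),
    strand = character(0), kind = character(0), start = integer(0),
    end = integer(0), size = integer(0), inserted_seq = character(0),
    min_end_distance = integer(0), align_start = integer(0))
  rownames(res) <- NULL
  res
}
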