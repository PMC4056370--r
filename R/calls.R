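## From split-read signatures to filtered CNV calls. The filter chain mirrors
## a conservative breakpoint-curation strategy for sparse long-read data:
## independent-read support, PCR-duplicate exclusion, read-end margins, a
## euchromatin mask, and removal of TE-driven events.

#' Cluster split-read signatures into filtered CNV calls
#'
#' Signatures are grouped by identical breakpoint coordinates (and junction
#' sequence). A group becomes a call iff it (a) has at least `min_support`
#' distinct reads, (b) is not explicable as PCR duplicates — all supporting
#' reads sharing one exact alignment start position (on the same strand) are
#' counted once, (c) has its breakpoint at least `read_end_margin` bp from
#' both ends of every counted read (margin-failing reads are dropped before
#' support counting), (d) lies inside the euchromatin mask, and (e) has less
#' than `te_frac` of the deleted/duplicated sequence covered by TE
#' annotation. Every discarded group is logged with the failing filter in the
#' `discards` attribute.
#'
#' @param signatures data.frame from [detect_split_signatures()]
#' @param genome optional `sim_genome` supplying `mask`/`te` defaults
#' @param te TE intervals (data.frame chrom/start/end) or NULL
#' @param mask euchromatin intervals or NULL (NULL = no mask filter)
#' @param min_support minimum independent supporting reads (default 2)
#' @param read_end_margin minimum junction distance from read ends (default 10)
#' @param te_frac TE-overlap fraction at or above which a call is removed
#'   (default 0.8)
#' @param exclude_tandem_dups drop tandem duplications from the output (they
#'   are always flagged; the conservative published configuration excluded
#'   them entirely)
#' @return data.frame of CNV calls sorted by (chrom, start, kind): call_id,
#'   chrom, start, end, kind, size, inserted_seq, n_reads, n_strains,
#'   strains, read_ids, n_align_starts, tandem_flagged; attribute `discards`
#'   is a data.frame of discarded groups with the failing filter
#' @export
cluster_and_filter <- function(signatures, genome = NULL, te = NULL,
                               mask = NULL, min_support = 2L,
                               read_end_margin = 10L, te_frac = 0.8,
                               exclude_tandem_dups = FALSE) {
  if (is.null(te) && !is.null(genome)) te <- genome$te
  if (is.null(mask) && !is.null(genome)) mask <- genome$mask
  sig <- signatures
  discards <- list()
  empty <- data.frame(
    call_id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), kind = character(0), size = integer(0),
    inserted_seq = character(0), n_reads = integer(0), n_strains = integer(0),
    strains = character(0), read_ids = character(0),
    n_align_starts = integer(0), tandem_flagged = logical(0))
  if (nrow(sig) == 0) {
    attr(empty, "discards") <- data.frame(key = character(0), filter = character(0))
    return(empty)
  }
  ## (c) per-read margin pre-filter: a read whose junction sits within the
  ## margin of either end cannot support a call
  bad_margin <- sig$min_end_distance < read_end_margin
  if (any(bad_margin)) {
    discards[[length(discards) + 1L]] <- data.frame(
      key = paste0(sig$chrom[bad_margin], ":", sig$start[bad_margin], "-",
                   sig$end[bad_margin], ":", sig$kind[bad_margin]),
      filter = "read_end_margin")
    sig <- sig[!bad_margin, , drop = FALSE]
  }
  if (nrow(sig) == 0) {
    attr(empty, "discards") <- do.call(rbind, discards)
    return(empty)
  }
  key <- paste(sig$chrom, sig$kind, sig$start, sig$end, sig$inserted_seq,
               sep = "|")
  in_intervals <- function(chrom, pos, iv) {
    if (is.null(iv) || nrow(iv) == 0) return(rep(TRUE, length(pos)))
    ok <- logical(length(pos))
    for (i in seq_along(pos)) {
      m <- iv[iv$chrom == chrom[i], , drop = FALSE]
      ok[i] <- any(pos[i] >= m$start & pos[i] <= m$end)
    }
    ok
  }
  calls <- list()
  for (kk in unique(key)) {
    g <- sig[key == kk, , drop = FALSE]
    drop_reason <- NULL
    g <- g[!duplicated(g$read_id), , drop = FALSE]
    n_starts <- length(unique(paste(g$strand, g$align_start)))
    if (nrow(g) < min_support) drop_reason <- "min_support"
    else if (n_starts < 2L) drop_reason <- "pcr_duplicates"
    else {
      pos <- if (g$kind[1] == "insertion") c(g$start[1], g$start[1]) else
        c(g$start[1], g$end[1])
      if (!all(in_intervals(rep(g$chrom[1], 2L), pos, mask)))
        drop_reason <- "euchromatin_mask"
      else if (g$kind[1] %in% c("deletion", "tandem_dup") &&
               !is.null(te) && nrow(te) > 0) {
        tei <- te[te$chrom == g$chrom[1], , drop = FALSE]
        ovl <- if (nrow(tei)) interval_overlap(tei$start, tei$end,
                                               g$start[1], g$end[1]) else integer(0)
        cov <- if (any(ovl > 0)) union_coverage(
          pmax(tei$start[ovl > 0], g$start[1]),
          pmin(tei$end[ovl > 0], g$end[1])) else 0L
        if (cov >= te_frac * g$size[1]) drop_reason <- "te_overlap"
      }
    }
    if (!is.null(drop_reason)) {
      discards[[length(discards) + 1L]] <-
        data.frame(key = kk, filter = drop_reason)
      next
    }
    calls[[length(calls) + 1L]] <- data.frame(
      chrom = g$chrom[1], start = g$start[1], end = g$end[1],
      kind = g$kind[1], size = g$size[1], inserted_seq = g$inserted_seq[1],
      n_reads = nrow(g), n_strains = length(unique(g$strain)),
      strains = paste(sort(unique(g$strain)), collapse = ","),
      read_ids = paste(sort(g$read_id), collapse = ","),
      n_align_starts = n_starts,
      tandem_flagged = g$kind[1] == "tandem_dup")
  }
  out <- do.call(rbind, calls)
  if (is.null(out)) out <- empty[, -1L]
  if (exclude_tandem_dups && nrow(out) > 0) {
    td <- out$kind == "tandem_dup"
    if (any(td)) {
      discards[[length(discards) + 1L]] <- data.frame(
        key = paste0(out$chrom[td], ":", out$start[td], "-", out$end[td],
                     ":tandem_dup"),
        filter = "tandem_dup_excluded")
      out <- out[!td, , drop = FALSE]
    }
  }
  if (nrow(out) > 0) {
    out <- out[order(out$chrom, out$start, out$kind), , drop = FALSE]
    out <- cbind(call_id = paste0("call", seq_len(nrow(out))), out)
  } else out <- empty
  rownames(out) <- NULL
  attr(out, "discards") <- if (length(discards)) do.call(rbind, discards) else
    data.frame(key = character(0), filter = character(0))
  out
}

## ---- call table I/O --------------------------------------------------------

#' Write calls as a VCF-like tab table plus a JSON sidecar
#' @param calls call table from [cluster_and_filter()]
#' @param path output TSV path; the sidecar is written at `<path>.json`
#' @return `path`, invisibly
#' @export
write_calls <- function(calls, path) {
  v <- data.frame(CHROM = calls$chrom, POS = calls$start,
                  ID = calls$call_id,
                  SVTYPE = toupper(substr(calls$kind, 1, 3)),
                  END = calls$end, SIZE = calls$size,
                  SEQ = ifelse(calls$inserted_seq == "", ".", calls$inserted_seq),
                  SUPPORT = calls$n_reads, STRAINS = calls$strains)
  write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(calls, paste0(path, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a call table written by [write_calls()] (from the JSON sidecar)
#' @param path TSV path used at write time
#' @return call data.frame
#' @export
read_calls <- function(path) {
  as.data.frame(jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE))
}

## ---- PSL interchange -------------------------------------------------------

#' Import gapped alignments from a PSL file
#'
#' Accepts the 21-column PSL dialect (optional 5-line header). Blocks are
#' converted to the native alignment representation; query block starts on
#' the minus strand are kept in reverse-complemented query coordinates, which
#' is also the native convention, so import/export round-trips losslessly.
#'
#' @param path PSL file
#' @return alignment data.frame as produced by [map_reads()]
#' @export
import_psl <- function(path) {
  lines <- readLines(path)
  start_at <- 1L
  if (length(lines) >= 1 && grepl("^psLayout", lines[1])) start_at <- 6L
  rows <- list()
  for (ln in seq(start_at, length(lines))) {
    if (ln > length(lines)) break
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 21L)
      stop("malformed PSL line ", ln, ": expected 21 fields, got ", length(f))
    nb <- as.integer(f[18])
    bs <- as.integer(strsplit(f[19], ",")[[1]])[seq_len(nb)]
    qs <- as.integer(strsplit(f[20], ",")[[1]])[seq_len(nb)]
    ts <- as.integer(strsplit(f[21], ",")[[1]])[seq_len(nb)]
    qsize <- as.integer(f[11])
    status <- if (nb == 1L && bs[1] == qsize) "concordant" else "split"
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = f[10], strain = NA_character_, chrom = f[14], strand = f[9],
      read_start = qs + 1L, read_end = qs + bs,
      ref_start = ts + 1L, ref_end = ts + bs,
      mismatches = c(as.integer(f[2]), rep(0L, nb - 1L)),
      block = seq_len(nb), n_blocks = nb, status = status,
      align_start = min(ts) + 1L, read_len = qsize)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no alignments in PSL file: ", path)
  rownames(out) <- NULL
  out
}

#' Export alignments to PSL
#' @param alignments alignment data.frame (mapped reads only)
#' @param genome `sim_genome` supplying target sizes
#' @param path output file
#' @return `path`, invisibly
#' @export
export_psl <- function(alignments, genome, path) {
  al <- alignments[!is.na(alignments$chrom), , drop = FALSE]
  tlen <- nchar(genome$chromosomes)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in unique(al$read_id)) {
    bl <- al[al$read_id == id, , drop = FALSE]
    bl <- bl[order(bl$block), ]
    sizes <- bl$read_end - bl$read_start + 1L
    matches <- sum(sizes) - sum(bl$mismatches)
    line <- paste(
      matches, sum(bl$mismatches), 0L, 0L, 0L, 0L, 0L, 0L, bl$strand[1],
      id, bl$read_len[1], bl$read_start[1] - 1L, bl$read_end[nrow(bl)],
      bl$chrom[1], tlen[[bl$chrom[1]]], min(bl$ref_start) - 1L,
      max(bl$ref_end), nrow(bl),
      paste0(paste(sizes, collapse = ","), ","),
      paste0(paste(bl$read_start - 1L, collapse = ","), ","),
      paste0(paste(bl$ref_start - 1L, collapse = ","), ","),
      sep = "\t")
    writeLines(line, con)
  }
  invisible(path)
}
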