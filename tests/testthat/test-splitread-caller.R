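## Mapper, split-signature extraction, filter chain, and PSL interchange.

mini_genome <- function(len = 20000L, seed = 201L) {
  generate_genome(1, len, gc = 0.5, seed = seed)
}

read_df <- function(seqs, strain = "s1", ids = NULL) {
  data.frame(id = ids %||% paste0("r", seq_along(seqs)), strain = strain,
             chrom = NA, start = NA, strand = NA, seq = seqs)
}

test_that("exact substrings map as single concordant blocks", {
  g <- mini_genome()
  ch <- g$chromosomes[[1]]
  reads <- read_df(c(substr(ch, 5001, 5105), revcomp(substr(ch, 8001, 8105))))
  al <- map_reads(reads, g)
  expect_identical(al$status, c("concordant", "concordant"))
  expect_identical(al$ref_start, c(5001L, 8001L))
  expect_identical(al$strand, c("+", "-"))
})

test_that("a read spanning a reference gap yields two blocks with that gap", {
  g <- mini_genome()
  ch <- g$chromosomes[[1]]
  read <- paste0(substr(ch, 1001, 1030), substr(ch, 1061, 1090))
  al <- map_reads(read_df(read), g, k = 15)
  expect_identical(unique(al$status), "split")
  expect_identical(nrow(al), 2L)
  expect_identical(al$ref_end[1] + 1L, 1031L)
  expect_identical(al$ref_start[2], 1061L)
  sig <- detect_split_signatures(al, min_size = 25)
  expect_identical(sig$kind, "deletion")
  expect_identical(c(sig$start, sig$end), c(1031L, 1060L))
})

test_that("random non-reference reads are reported unmapped", {
  g <- mini_genome()
  set.seed(1)
  read <- random_dna(105, 0.5)
  expect_false(grepl(substr(read, 1, 20), g$chromosomes[[1]], fixed = TRUE))
  al <- map_reads(read_df(read), g)
  expect_identical(al$status, "unmapped")
  expect_true(is.na(al$chrom))
})

test_that("flipped block order is detected as the tandem-duplication signature", {
  g <- mini_genome()
  ch <- g$chromosomes[[1]]
  ## strain carries [4001,4200] twice; read spans the copy junction
  dup <- substr(ch, 4001, 4200)
  read <- paste0(substr(dup, 161, 200), substr(dup, 1, 40))
  al <- map_reads(read_df(read), g, k = 15)
  expect_identical(unique(al$status), "split")
  sig <- detect_split_signatures(al, min_size = 25)
  expect_identical(sig$kind, "tandem_dup")
  expect_identical(c(sig$start, sig$end), c(4001L, 4200L))
  ## the 3' read block maps 5' of the 5' read block
  expect_lt(al$ref_start[2], al$ref_start[1])
})

test_that("gaps below min_size produce no signature", {
  g <- mini_genome()
  ch <- g$chromosomes[[1]]
  r24 <- paste0(substr(ch, 2001, 2050), substr(ch, 2075, 2124))  # 24 bp gap
  r25 <- paste0(substr(ch, 6001, 6050), substr(ch, 6076, 6125))  # 25 bp gap
  al <- map_reads(read_df(c(r24, r25)), g, k = 15)
  sig <- detect_split_signatures(al, min_size = 25)
  expect_identical(nrow(sig), 1L)
  expect_identical(sig$size, 25L)
})

test_that("filter chain: support, PCR duplicates, margins, mask, TE", {
  g <- mini_genome()
  ch <- g$chromosomes[[1]]
  mk_sig <- function(id, start_pos, align_start, med = 40L, strain = "s1")
    data.frame(read_id = id, strain = strain, chrom = "chr1", strand = "+",
               kind = "deletion", start = start_pos, end = start_pos + 29L,
               size = 30L, inserted_seq = "", min_end_distance = med,
               align_start = align_start)
  ## one supporting read: dropped for support
  one <- mk_sig("a", 5000, 4950)
  expect_identical(nrow(cluster_and_filter(one, g)), 0L)
  expect_identical(attr(cluster_and_filter(one, g), "discards")$filter,
                   "min_support")
  ## two reads with the same exact start position: PCR duplicates
  pcr <- rbind(mk_sig("a", 5000, 4950), mk_sig("b", 5000, 4950))
  expect_identical(attr(cluster_and_filter(pcr, g), "discards")$filter,
                   "pcr_duplicates")
  ## distinct starts pass
  ok <- rbind(mk_sig("a", 5000, 4950), mk_sig("b", 5000, 4960))
  expect_identical(nrow(cluster_and_filter(ok, g)), 1L)
  ## margin failure on one read leaves a single read: filtered
  marg <- rbind(mk_sig("a", 5000, 4950, med = 5L), mk_sig("b", 5000, 4960))
  expect_identical(nrow(cluster_and_filter(marg, g)), 0L)
  ## outside the euchromatin mask (chromosome end)
  edge <- rbind(mk_sig("a", 50, 20), mk_sig("b", 50, 25))
  expect_identical(attr(cluster_and_filter(edge, g), "discards")$filter,
                   "euchromatin_mask")
  ## deletion wholly inside TE annotation
  g_te <- g
  g_te$te <- data.frame(chrom = "chr1", start = 4900L, end = 5100L)
  expect_identical(attr(cluster_and_filter(ok, g_te), "discards")$filter,
                   "te_overlap")
  ## 50% TE overlap is below the 80% bar: kept
  g_te2 <- g
  g_te2$te <- data.frame(chrom = "chr1", start = 5000L, end = 5014L)
  expect_identical(nrow(cluster_and_filter(ok, g_te2)), 1L)
})

test_that("min_size and min_support act monotonically and output is ordered", {
  fx <- fixture_cohort()
  sig20 <- detect_split_signatures(fx$alignments, min_size = 20,
                                   reads = fx$reads)
  sig25 <- detect_split_signatures(fx$alignments, min_size = 25,
                                   reads = fx$reads)
  calls20 <- cluster_and_filter(sig20, fx$genome)
  calls25 <- cluster_and_filter(sig25, fx$genome)
  key <- function(x) paste(x$chrom, x$start, x$end, x$kind)
  expect_true(all(key(calls25) %in% key(calls20)))
  calls_hi <- cluster_and_filter(sig25, fx$genome, min_support = 5)
  expect_true(all(key(calls_hi) %in% key(calls25)))
  ## deterministic ordering and byte-identical re-run
  expect_identical(calls25, cluster_and_filter(sig25, fx$genome))
  ord <- order(calls25$chrom, calls25$start, calls25$kind)
  expect_identical(ord, seq_len(nrow(calls25)))
})

test_that("PSL import: blocks, header, malformed lines, round-trip", {
  g <- mini_genome()
  psl_line <- paste(c(50, 0, 0, 0, 0, 0, 0, 0, "+", "readA", 50, 0, 50,
                      "chr1", 20000, 99, 149, 1, "50,", "0,", "99,"),
                    collapse = "\t")
  f <- tempfile(fileext = ".psl")
  writeLines(psl_line, f)
  al <- import_psl(f)
  expect_identical(nrow(al), 1L)
  expect_identical(al$ref_start, 100L)
  expect_identical(al$ref_end, 149L)
  expect_identical(al$read_start, 1L)
  ## 5-line header is skipped
  writeLines(c("psLayout version 3", "", "match mis-", "----", "-----",
               psl_line), f)
  expect_identical(nrow(import_psl(f)), 1L)
  ## wrong column count errors with the line number
  writeLines(paste(rep("x", 20), collapse = "\t"), f)
  expect_error(import_psl(f), "line 1")
  ## round-trip through the native representation
  fx <- fixture_cohort()
  al0 <- fx$alignments
  al0 <- al0[al0$status %in% c("concordant", "split"), ]
  al0 <- al0[al0$read_id %in% head(unique(al0$read_id), 20), ]
  export_psl(al0, fx$genome, f)
  back <- import_psl(f)
  for (col in c("read_id", "chrom", "strand", "read_start", "read_end",
                "ref_start", "ref_end", "block", "n_blocks"))
    expect_identical(back[[col]], al0[[col]])
  sig_a <- detect_split_signatures(al0, 25)
  sig_b <- detect_split_signatures(back, 25)
  expect_identical(sig_b[c("chrom", "kind", "start", "end")],
                   sig_a[c("chrom", "kind", "start", "end")])
})

test_that("recovery on the mixed cohort is complete and precise", {
  fx <- fixture_cohort()
  tr <- fx$truth
  key_t <- paste(tr$chrom, tr$start, tr$end, tr$kind)
  key_c <- paste(fx$calls$chrom, fx$calls$start, fx$calls$end, fx$calls$kind)
  ## a short tandem duplication is equivalently called as an insertion of the
  ## duplicated segment when the full copy fits inside a read
  short_dup <- tr$kind == "tandem_dup" & (tr$end - tr$start + 1L) < 105L
  expect_true(all(key_t[!short_dup] %in% key_c))
  ## precision: every call corresponds to a truth event
  alt_key <- paste(tr$chrom, tr$start - 1L, tr$start - 1L, "insertion")
  expect_true(all(key_c %in% c(key_t, alt_key)))
})
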