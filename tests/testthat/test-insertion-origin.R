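## Insertion-origin attribution and neighborhood matching against shuffled
## controls.

test_that("origin classification: tandem duplication, expansion, filler", {
  g <- generate_genome(1, 20000, gc = 0.5, seed = 401)
  ch <- g$chromosomes[[1]]
  ## a copy of the 40 bp immediately 5' of the site
  td <- list(chrom = "chr1", start = 5000L, end = 5000L, kind = "insertion",
             inserted_seq = substr(ch, 4961, 5000))
  expect_identical(classify_insertion_origin(td, g)$label, "TANDEM_DUP")
  ## expansion adjacent to a (CA)n tract written into the flank
  g2 <- g
  substr(g2$chromosomes[[1]], 6989, 7000) <- strrep("CA", 6)
  re <- list(chrom = "chr1", start = 7000L, end = 7000L, kind = "insertion",
             inserted_seq = "CACACACA")
  r <- classify_insertion_origin(re, g2)
  expect_identical(r$label, "REPEAT_EXPANSION")
  expect_identical(r$evidence$unit, "CA")
  ## implanted filler is attributed to filler DNA
  imp <- implant_cnvs(g, list(cnv_spec("insertion", 30, sig_filler())),
                      strains = "s1", seed = 402)
  tr <- imp$truth[1, ]
  expect_identical(classify_insertion_origin(tr, imp$reference)$label,
                   "FILLER")
  expect_error(classify_insertion_origin(
    list(chrom = "chr1", start = 100L, end = 100L, kind = "insertion",
         inserted_seq = ""), g), "empty")
})

test_that("neighborhood matching equals the brute-force union oracle", {
  set.seed(411)
  for (i in 1:150) {
    ins <- random_dna(sample(25:60, 1), 0.5)
    f5 <- random_dna(30, 0.5); f3 <- random_dna(30, 0.5)
    ## plant a flank copy in half the cases so matches actually occur
    if (i %% 2 == 0) {
      piece <- substr(ins, 5, 5 + sample(7:12, 1))
      substr(f5, 3, 2 + nchar(piece)) <- piece
    }
    m <- match_neighborhood(ins, f5, f3, min_match = 7)
    oracle <- oracle_neighborhood_cover(
      ins, c(f5, f3, oracle_rc(f5), oracle_rc(f3)), 7L)
    expect_identical(m$matched_nt, as.integer(oracle))
    ## greedy tiling never exceeds the union coverage
    tiled <- if (is.null(m$segments) || nrow(m$segments) == 0) 0L else
      sum(m$segments$length)
    expect_lte(tiled, m$matched_nt)
  }
})

test_that("planted matches and strandedness behave as designed", {
  set.seed(421)
  f5 <- random_dna(30, 0.5); f3 <- random_dna(30, 0.5)
  ins <- paste0(random_dna(10, 0.5), substr(f5, 11, 20), random_dna(10, 0.5))
  m <- match_neighborhood(ins, f5, f3, min_match = 7)
  expect_gte(m$matched_nt, 10L)
  ## inverted-repeat matching requires both_strands
  ins_rc <- paste0(random_dna(9, 0.5), oracle_rc(substr(f3, 10, 21)),
                   random_dna(9, 0.5))
  on_ <- match_neighborhood(ins_rc, f5, f3, min_match = 7, both_strands = TRUE)
  off <- match_neighborhood(ins_rc, f5, f3, min_match = 7, both_strands = FALSE)
  expect_gte(on_$matched_nt, 12L)
  expect_identical(off$matched_nt - oracle_neighborhood_cover(
    ins_rc, c(f5, f3), 7L), 0L)
})

test_that("window growth never loses matched nucleotides", {
  g <- generate_genome(1, 60000, gc = 0.5, seed = 431)
  imp <- implant_cnvs(g, lapply(1:6, function(i)
    cnv_spec("insertion", 30, sig_filler())), strains = "s1", seed = 432)
  tr <- imp$truth; tr$call_id <- tr$event_id
  prev <- rep(0L, nrow(tr))
  for (w in c(30, 60, 90, 120)) {
    tab <- neighborhood_match_table(tr, imp$reference, w)
    expect_true(all(tab$matched_nt >= prev))
    prev <- tab$matched_nt
  }
})

test_that("shuffled controls preserve counts, sizes and determinism", {
  g <- generate_genome(2, c(40000, 30000), gc = 0.5, seed = 441)
  ins <- data.frame(call_id = paste0("i", 1:10),
                    chrom = rep(c("chr1", "chr2"), each = 5),
                    start = rep(seq(5000, 25000, length.out = 5), 2),
                    kind = "insertion")
  ins$start <- as.integer(ins$start); ins$end <- ins$start
  set.seed(442)
  ins$inserted_seq <- vapply(sample(25:60, 10, replace = TRUE), random_dna,
                             character(1), gc = 0.5)
  ctl <- shuffle_controls(ins, g, factor = 10, seed = 443)
  expect_identical(nrow(ctl), 100L)
  for (ch in c("chr1", "chr2"))
    expect_identical(
      sort(rep(nchar(ins$inserted_seq[ins$chrom == ch]), 10)),
      sort(nchar(ctl$inserted_seq[ctl$chrom == ch])))
  expect_identical(ctl, shuffle_controls(ins, g, factor = 10, seed = 443))
  ## control sequence is the reference at the shuffled spot
  j <- 7
  expect_identical(ctl$inserted_seq[j],
                   substr(g$chromosomes[[ctl$chrom[j]]], ctl$start[j] + 1L,
                          ctl$start[j] + nchar(ctl$inserted_seq[j])))
})

test_that("planted flank copies are detected over shuffled controls with
           high power", {
  g <- generate_genome(1, 100000, gc = 0.5, seed = 461)
  ch <- g$chromosomes[[1]]
  rejections <- 0L
  for (r in 1:100) {
    set.seed(470 + r)
    pos <- sort(sample(seq(3000L, 96000L), 50))
    ## each real insertion carries a 10 bp copy of its own 5' flank
    ins_seq <- vapply(pos, function(p) {
      s <- random_dna(30, 0.5)
      substr(s, 11, 20) <- substr(ch, p - 19L, p - 10L)
      s
    }, character(1))
    real <- data.frame(call_id = paste0("i", seq_along(pos)), chrom = "chr1",
                       start = pos, end = pos, kind = "insertion",
                       inserted_seq = ins_seq)
    ctl <- shuffle_controls(real, g, factor = 10, seed = 480 + r)
    rt <- neighborhood_match_table(real, g, 30)
    ct <- neighborhood_match_table(ctl, g, 30)
    if (filler_enrichment_tests(rt, ct)$fisher$p_value < 0.05)
      rejections <- rejections + 1L
  }
  expect_gte(rejections, 90L)
})

test_that("enrichment tests: null case and enumeration cross-check", {
  set.seed(451)
  mk_tab <- function(fr, n, w = 30L)
    data.frame(call_id = paste0("x", seq_len(n)), window = w, ins_len = 30L,
               matched_nt = round(30 * fr), matched_fraction = fr,
               any_match = fr > 0)
  fr <- c(rep(0, 30), runif(20, 0.2, 0.6))
  real <- mk_tab(fr, 50)
  ctl <- mk_tab(rep(fr, 10), 500)
  r <- filler_enrichment_tests(real, ctl)
  expect_gt(r$wilcoxon$p_value, 0.9)
  expect_gt(r$fisher$p_value, 0.9)
  ## degenerate all-zero data
  r0 <- filler_enrichment_tests(mk_tab(rep(0, 10), 10),
                                mk_tab(rep(0, 100), 100))
  expect_true(r0$degenerate)
  expect_identical(r0$fisher$p_value, 1)
  ## 23/50 vs 135/500 with-match counts: exact test equals the
  ## hypergeometric enumeration
  real2 <- mk_tab(c(rep(0.3, 23), rep(0, 27)), 50)
  ctl2 <- mk_tab(c(rep(0.3, 135), rep(0, 365)), 500)
  r2 <- filler_enrichment_tests(real2, ctl2)
  expect_equal(r2$fisher$p_value, oracle_fisher2(23, 27, 135, 365),
               tolerance = 1e-10)
})
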