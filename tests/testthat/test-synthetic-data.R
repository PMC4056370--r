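test_that("genome generation is seed-deterministic and hits the requested GC", {
  g1 <- generate_genome(1, 50000, gc = 0.5, seed = 7)
  g2 <- generate_genome(1, 50000, gc = 0.5, seed = 7)
  expect_identical(g1$chromosomes, g2$chromosomes)

  g <- generate_genome(1, 50000, gc = 0.42, seed = 1)
  s <- g$chromosomes[[1]]
  gc_obs <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
  sd3 <- 3 * sqrt(0.42 * 0.58 / 50000)
  expect_lt(abs(gc_obs - 0.42), sd3)

  expect_error(generate_genome(1, 0, seed = 1), "positive")
  expect_error(generate_genome(1, 1000, gc = 1.2, seed = 1), "gc")
})

test_that("implanted signatures are verifiable from sequence alone", {
  fx <- fixture_cohort()
  tr <- fx$truth
  ref_len <- vapply(fx$genome$chromosomes, nchar, integer(1))
  ## length conservation per strain
  for (st in names(fx$strains)) {
    carried <- tr[vapply(strsplit(tr$strains, ","), function(x) st %in% x,
                         logical(1)), ]
    for (ch in names(ref_len)) {
      ev <- carried[carried$chrom == ch, ]
      dels <- ev$kind == "deletion"
      dups <- ev$kind == "tandem_dup"
      expected <- ref_len[[ch]] -
        sum(ev$end[dels] - ev$start[dels] + 1L) +
        sum(nchar(ev$inserted_seq)) +
        sum(ev$end[dups] - ev$start[dups] + 1L)
      expect_identical(nchar(fx$strains[[st]][[ch]]), as.integer(expected))
    }
  }
  ## every implanted signature recoverable by the classifier oracle
  for (i in seq_len(nrow(tr))) {
    p <- measure_microhomology(tr[i, ], fx$genome)
    if (tr$signature[i] == "microhomology")
      expect_identical(p$type_I, tr$mh_k[i])
    if (tr$signature[i] == "blunt" && tr$kind[i] == "deletion")
      expect_identical(p$type_I, 0L)
    expect_identical(nchar(p$junction_extra_bases),
                     if (tr$kind[i] == "deletion") tr$extra_len[i] else 0L)
  }
})

test_that("microhomology implanting matches the prefix/suffix oracle", {
  g0 <- generate_genome(1, 30000, gc = 0.5, seed = 21)
  imp <- implant_cnvs(g0, list(cnv_spec("deletion", 40, sig_microhomology(5)),
                               cnv_spec("deletion", 35, sig_microhomology(7))),
                      strains = "s1", seed = 22)
  for (i in seq_len(nrow(imp$truth))) {
    tr <- imp$truth[i, ]
    chrom <- imp$reference$chromosomes[[tr$chrom]]
    seg <- substr(chrom, tr$start, tr$end)
    prec <- substr(chrom, tr$start - 60, tr$start - 1)
    foll <- substr(chrom, tr$end + 1, tr$end + 60)
    expect_identical(oracle_type1(seg, prec, foll), tr$mh_k)
  }
})

test_that("filler insertions are novel at full length (exhaustive search)", {
  g0 <- generate_genome(1, 30000, gc = 0.5, seed = 31)
  imp <- implant_cnvs(g0, list(cnv_spec("insertion", 25, sig_filler())),
                      strains = "s1", seed = 32)
  ins <- imp$truth$inserted_seq[1]
  expect_identical(nchar(ins), 25L)
  chrom <- imp$reference$chromosomes[[1]]
  expect_false(grepl(ins, chrom, fixed = TRUE))
  expect_false(grepl(oracle_rc(ins), chrom, fixed = TRUE))
})

test_that("implant preconditions are enforced", {
  g0 <- generate_genome(1, 15000, gc = 0.5, seed = 41)
  expect_error(cnv_spec("deletion", 24), ">= 25")
  ## more events than the euchromatin can hold
  big <- lapply(1:40, function(i) cnv_spec("deletion", 200))
  expect_error(implant_cnvs(g0, big, strains = "s1", seed = 1), "fit within")
})

test_that("outgroup generation: identity case, divergence level, polarity", {
  g0 <- generate_genome(1, 50000, gc = 0.5, seed = 51)
  imp <- implant_cnvs(g0, list(cnv_spec("deletion", 30, sig_blunt()),
                               cnv_spec("deletion", 40, sig_microhomology(4))),
                      strains = "s1", seed = 52)
  og0 <- generate_outgroup(imp$reference, imp$truth, divergence = 0,
                           share = 0, seed = 53)
  expect_identical(og0$outgroup$chromosomes, imp$reference$chromosomes)
  expect_true(all(og0$truth$intended_polarity == "DELETION_IN_STRAIN"))

  og <- generate_outgroup(imp$reference, imp$truth, divergence = 0.05,
                          share = 0, seed = 54)
  n <- nchar(imp$reference$chromosomes[[1]])
  a <- strsplit(imp$reference$chromosomes[[1]], "")[[1]]
  b <- strsplit(og$outgroup$chromosomes[[1]], "")[[1]]
  nsub <- sum(a != b)
  expect_lt(abs(nsub - 0.05 * n), 3 * sqrt(0.05 * 0.95 * n) + 100)

  ## share = 1: the outgroup carries every derived allele, so a deletion call
  ## polarizes as an insertion in the reference
  og1 <- generate_outgroup(imp$reference, imp$truth, divergence = 0,
                           share = 1, seed = 55)
  tr <- og1$truth
  expect_true(all(tr$intended_polarity == "INSERTION_IN_REFERENCE"))
  tr$call_id <- tr$event_id
  pol <- polarize(tr[1, ], og1$outgroup, imp$reference)
  expect_identical(pol, "INSERTION_IN_REFERENCE")
})

test_that("read simulation: coverage accounting, purity, determinism", {
  g0 <- generate_genome(1, 20000, gc = 0.5, seed = 61)
  strains <- lapply(setNames(paste0("s", 1:9), paste0("s", 1:9)),
                    function(i) g0$chromosomes)
  rs <- simulate_reads(strains, coverage = 0.2, mean_len = 105, seed = 62)
  total <- sum(nchar(rs$seq))
  expect_lt(abs(total - 0.2 * 9 * 20000), 0.05 * 0.2 * 9 * 20000)

  rs10 <- simulate_reads(strains[1], coverage = 10, mean_len = 105,
                         error = 0, seed = 63)
  chrom <- g0$chromosomes[[1]]
  idx <- sample(nrow(rs10), 50)
  for (i in idx) {
    s <- rs10$seq[i]
    if (rs10$strand[i] == "-") s <- revcomp(s)
    expect_identical(substr(chrom, rs10$start[i],
                            rs10$start[i] + nchar(s) - 1L), s)
  }
  rs2 <- simulate_reads(strains, coverage = 0.2, mean_len = 105, seed = 62)
  expect_identical(rs, rs2)
  tmp <- tempfile(fileext = ".fastq")
  write_reads_fastq(rs10, tmp)
  back <- read_reads_fastq(tmp, strain = "s1")
  expect_identical(back$seq, rs10$seq)
  expect_identical(back$id, rs10$id)
})

test_that("genome FASTA round-trips", {
  g0 <- generate_genome(2, c(12000, 15000), gc = 0.5, seed = 71)
  tmp <- tempfile(fileext = ".fasta")
  write_genome_fasta(g0, tmp)
  back <- read_genome_fasta(tmp)
  expect_identical(back$chromosomes, g0$chromosomes)
})
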