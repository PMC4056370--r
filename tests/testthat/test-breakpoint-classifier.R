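## Junction anatomy: microhomology measurement and classing, the excess test,
## junction realignment, polarization, recurrence/complexity.

test_that("type-I microhomology on a worked example", {
  ## reference TTTTACGGGGACTTTT, deletion of ACGGGG: "AC" is shared between
  ## the segment start and the sequence following the 3' breakpoint
  g <- structure(list(chromosomes = c(chr1 = "TTTTACGGGGACTTTT"),
                      mask = data.frame(chrom = "chr1", start = 1L, end = 16L),
                      te = data.frame(), seed = 1L), class = "sim_genome")
  call <- list(chrom = "chr1", start = 5L, end = 10L, kind = "deletion",
               inserted_seq = "")
  p <- measure_microhomology(call, g)
  expect_identical(p$type_I, 2L)
})

test_that("microhomology scanner agrees with the brute-force oracle", {
  set.seed(301)
  n_cases <- 300
  g <- generate_genome(1, 20000, gc = 0.5, seed = 302)
  ch <- g$chromosomes[[1]]
  for (i in seq_len(n_cases)) {
    s <- sample(200:19000, 1)
    size <- sample(25:120, 1)
    call <- list(chrom = "chr1", start = s, end = s + size - 1L,
                 kind = "deletion", inserted_seq = "")
    p <- measure_microhomology(call, g)
    seg <- substr(ch, s, s + size - 1L)
    prec <- substr(ch, s - 50, s - 1)
    foll <- substr(ch, s + size, s + size + 49)
    expect_identical(p$type_I, oracle_type1(seg, prec, foll))
  }
})

test_that("breakpoint classes follow the 2 bp microhomology rule", {
  mk <- function(t1, extra) list(type_I = t1, type_II = 0L, type_III = 0L,
                                 junction_extra_bases = extra)
  expect_identical(classify_breakpoint(mk(0L, ""))$label, "BLUNT")
  expect_identical(classify_breakpoint(mk(1L, ""))$label, "BLUNT")
  expect_identical(classify_breakpoint(mk(2L, ""))$label, "MICROHOMOLOGY")
  expect_identical(classify_breakpoint(mk(0L, "GAT"))$label, "COMPLEX")
  expect_identical(classify_breakpoint(mk(3L, "GATTC"))$label, "COMPLEX_MH")
  expect_false(classify_breakpoint(mk(20L, ""))$long_identity)
  expect_true(classify_breakpoint(mk(21L, ""))$long_identity)
})

test_that("classification is invariant to junction normalization shift", {
  ## deletion with 3 bp of junction ambiguity: both representations give the
  ## same microhomology length and class
  pre <- "TTAACCGGTTAACC"; mh <- "GAT"; mid <- "CTTGGCAACTTGGCAACTTGGCAAAA"
  post <- "ACCAATTGGCCAATT"
  chrom <- paste0(pre, mh, mid, mh, post)
  g <- structure(list(chromosomes = c(chr1 = chrom),
                      mask = data.frame(chrom = "chr1", start = 1L,
                                        end = nchar(chrom)),
                      te = data.frame(), seed = 1L), class = "sim_genome")
  sL <- nchar(pre) + 1L
  szie <- nchar(mh) + nchar(mid)
  left <- list(chrom = "chr1", start = sL, end = sL + szie - 1L,
               kind = "deletion", inserted_seq = "")
  right <- list(chrom = "chr1", start = sL + 3L, end = sL + szie + 2L,
                kind = "deletion", inserted_seq = "")
  pl <- measure_microhomology(left, g)
  pr <- measure_microhomology(right, g)
  expect_identical(pl$type_I, 3L)
  expect_identical(pr$type_I, 3L)
  expect_identical(classify_breakpoint(pl)$label,
                   classify_breakpoint(pr)$label)
})

test_that("type I excess over controls is detected at the planted length", {
  ## all-zero profiles: nothing significant
  zero <- data.frame(type_I = rep(0L, 60), type_II = 0L, type_III = 0L)
  r0 <- microhomology_excess_test(zero)
  expect_true(is.na(r0$smallest_significant_k))
  ## identical counts for type I and the controls: p near 1 at every k
  same <- data.frame(type_I = rep(c(0L, 3L), 50),
                     type_II = rep(c(0L, 3L), 50),
                     type_III = rep(c(0L, 3L), 50))
  rs <- microhomology_excess_test(same)
  expect_true(all(rs$table$p_value[rs$table$k <= 3] > 0.5))
  ## planted type_I = 3 on random background: smallest significant k <= 3
  hits <- 0L
  for (rep_i in 1:20) {
    set.seed(400 + rep_i)
    n <- 200
    t2 <- rgeom(n, 0.75); t3 <- rgeom(n, 0.75)
    prof <- data.frame(type_I = 3L, type_II = t2, type_III = t3)
    rr <- microhomology_excess_test(prof)
    if (!is.na(rr$smallest_significant_k) && rr$smallest_significant_k <= 3)
      hits <- hits + 1L
  }
  expect_gte(hits, 19L)
  expect_error(microhomology_excess_test(zero[1:10, ]), "at least 30")
})

test_that("junction realignment recovers junction content and consistency", {
  fx <- fixture_cohort()
  tr <- fx$truth
  calls <- fx$calls
  ## clean deletion: empty junction extra; complex deletion: planted length
  for (i in seq_len(nrow(calls))) {
    cc <- calls[i, ]
    if (cc$kind != "deletion") next
    ra <- realign_junction(cc, fx$reads, fx$genome)
    expect_true(ra$consistent)
    ti <- which(tr$chrom == cc$chrom & tr$start == cc$start &
                  tr$kind == "deletion")
    if (length(ti) == 1)
      expect_identical(nchar(ra$consensus$junction_extra_bases),
                       tr$extra_len[ti])
  }
  ## reads implying different junction content flag the call inconsistent
  cc <- calls[calls$kind == "deletion", ][1, ]
  ids <- strsplit(cc$read_ids, ",")[[1]][1:2]
  reads2 <- fx$reads[fx$reads$id %in% ids, ]
  ## corrupt one read: inject 4 extra bases at the junction midpoint
  j <- 1L
  s <- reads2$seq[j]
  mid <- nchar(s) %/% 2
  reads2$seq[j] <- paste0(substr(s, 1, mid), "GGGG",
                          substr(s, mid + 1, nchar(s)))
  cc$read_ids <- paste(ids, collapse = ",")
  ra2 <- realign_junction(cc, reads2, fx$genome)
  expect_false(ra2$consistent)
})

test_that("polarization: reference-matching, derived-matching, degraded outgroup", {
  g0 <- generate_genome(1, 60000, gc = 0.5, seed = 311)
  imp <- implant_cnvs(g0, list(cnv_spec("deletion", 40, sig_blunt()),
                               cnv_spec("insertion", 30, sig_filler())),
                      strains = "s1", seed = 312)
  tr <- imp$truth; tr$call_id <- tr$event_id
  del <- tr[tr$kind == "deletion", ]
  ## outgroup identical to the reference: ancestral allele present
  og0 <- generate_outgroup(imp$reference, imp$truth, 0, 0, seed = 313)
  expect_identical(polarize(del, og0$outgroup, imp$reference),
                   "DELETION_IN_STRAIN")
  ## outgroup carrying the deletion junction: derived allele shared
  og1 <- generate_outgroup(imp$reference, imp$truth, 0, 1, seed = 314)
  expect_identical(polarize(del, og1$outgroup, imp$reference),
                   "INSERTION_IN_REFERENCE")
  ins <- tr[tr$kind == "insertion", ]
  expect_identical(polarize(ins, og0$outgroup, imp$reference),
                   "INSERTION_IN_STRAIN")
  expect_identical(polarize(ins, og1$outgroup, imp$reference),
                   "DELETION_IN_REFERENCE")
  ## missing outgroup
  expect_warning(p <- polarize(del, NULL, imp$reference), "outgroup")
  expect_identical(p, "UNPOLARIZED")
  ## heavily diverged flank fails the quality gate
  og_bad <- og0$outgroup
  set.seed(315)
  v <- strsplit(og_bad$chromosomes[[1]], "")[[1]]
  at <- sample(length(v), round(0.4 * length(v)))
  v[at] <- vapply(v[at], function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                            1), character(1))
  og_bad$chromosomes[[1]] <- paste(v, collapse = "")
  expect_identical(polarize(del, og_bad, imp$reference), "UNPOLARIZED")
})

test_that("recurrent and complex regions follow their definitions", {
  mk <- function(id, start, end, strains, ins = "")
    data.frame(call_id = id, chrom = "chr1", start = start, end = end,
               kind = "deletion", size = end - start + 1L, inserted_seq = ins,
               n_reads = 2L, n_strains = length(strsplit(strains, ",")[[1]]),
               strains = strains, read_ids = "x,y", n_align_starts = 2L,
               tandem_flagged = FALSE)
  ## identical junction in two strains: one shared CNV, not recurrent
  shared <- mk("c1", 1000, 1100, "s1,s2")
  r <- find_recurrent_and_complex(shared)
  expect_false(any(r$recurrent))
  ## overlapping intervals with different junctions in different strains
  rec <- rbind(mk("c1", 1000, 1100, "s1"), mk("c2", 1050, 1200, "s2"))
  r <- find_recurrent_and_complex(rec)
  expect_true(r$recurrent[1])
  expect_false(r$complex[1])
  ## two junctions 100 bp apart in one strain: complex, not recurrent
  cx <- rbind(mk("c1", 1000, 1100, "s1"), mk("c2", 1201, 1300, "s1"))
  r <- find_recurrent_and_complex(cx)
  expect_false(r$recurrent[1])
  expect_true(r$complex[1])
  expect_identical(r$min_junction_gap[1], 100)
  ## far-apart events in one strain are neither
  far <- rbind(mk("c1", 1000, 1100, "s1"), mk("c2", 9000, 9100, "s1"))
  r <- find_recurrent_and_complex(far)
  expect_false(any(r$recurrent))
  expect_false(any(r$complex))
})
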