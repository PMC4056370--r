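## Exact-test kernels against enumeration oracles; summary tables; context
## annotation; pipeline smoke and determinism.

test_that("fisher_exact matches hypergeometric enumeration", {
  set.seed(701)
  ## targeted examples
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))$p_value,
               oracle_fisher2(3, 1, 1, 3), tolerance = 1e-12)
  expect_identical(fisher_exact(matrix(c(0, 5, 0, 9), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2))$p_value,
               2 / choose(20, 10), tolerance = 1e-12)
  ## random small tables
  for (i in 1:200) {
    t <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (sum(t) == 0) next
    expect_equal(fisher_exact(t)$p_value,
                 oracle_fisher2(t[1, 1], t[1, 2], t[2, 1], t[2, 2]),
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("wilcoxon_rank_sum matches full enumeration on small samples", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1,
               tolerance = 1e-12)
  set.seed(711)
  for (i in 1:40) {
    x <- sample(1:1000, sample(3:5, 1))
    y <- sample(1001:2000, sample(3:5, 1)) - sample(500:1500, 1)
    if (any(duplicated(c(x, y)))) next
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, oracle_wilcox2(x, y),
                 tolerance = 1e-9)
  }
  r <- wilcoxon_rank_sum(rep(2, 5), rep(2, 7))
  expect_identical(r$p_value, 1)
  expect_true(r$degenerate)
})

test_that("two-proportion and chi-square kernels", {
  expect_gt(two_proportion_test(20, 100, 20, 100)$p_value, 0.99)
  expect_lt(two_proportion_test(90, 100, 10, 100)$p_value, 1e-10)
  expect_identical(two_proportion_test(1, 2, 1, 2)$p_value, 1)
  expect_error(two_proportion_test(1, 0, 1, 2), "positive")
  ## chi-square by hand for [[20,10],[10,20]]
  t <- matrix(c(20, 10, 10, 20), 2, byrow = TRUE)
  r <- chisq_independence(t)
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(r$p_value, stats::pchisq(20 / 3, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  ## identical row distributions: statistic 0, p 1
  t0 <- matrix(c(10, 20, 20, 40), 2, byrow = TRUE)
  r0 <- chisq_independence(t0)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)
  expect_error(chisq_independence(matrix(1:3, 1)), "2x2")
})

test_that("breakpoint-class percentages reproduce printed-table rounding", {
  tab <- breakpoint_class_table(c(223, 262, 2, 143, 14), 644)
  expect_identical(tab$percent, c(35, 41, 0.3, 22, 2))
  expect_error(breakpoint_class_table(c(1, 2, 3, 4, 5), 20), "sum")
  ## degenerate single-class input
  cls <- data.frame(label = rep("BLUNT", 10), long_identity = FALSE)
  st <- summarize_breakpoint_classes(cls)
  expect_identical(st$percent[st$class == "blunt"], 100)
  expect_error(summarize_breakpoint_classes(cls[0, ]), "no classified")
})

test_that("genomic-context annotation and frame flags", {
  gm <- data.frame(chrom = "chr1",
                   start = c(1000L, 1200L, 1600L),
                   end = c(2000L, 1400L, 1900L),
                   type = c("gene", "exon", "exon"))
  calls <- data.frame(call_id = c("a", "b", "c", "d"), chrom = "chr1",
                      start = c(1250L, 1380L, 1450L, 5000L),
                      end = c(1282L, 1450L, 1500L, 5100L),
                      kind = "deletion",
                      size = c(33L, 71L, 51L, 101L))
  ann <- annotate_context(calls, gm)
  expect_identical(ann$context, c("exonic", "exon_intron", "intronic",
                                  "intergenic"))
  expect_true(ann$frame_preserving[1])   # 33 is a multiple of three
  expect_warning(annotate_context(calls, NULL), "intergenic")
})

test_that("GFF3 intervals round-trip", {
  df <- data.frame(chrom = "chr1", start = c(100L, 400L), end = c(300L, 450L),
                   type = c("gene", "exon"))
  f <- tempfile(fileext = ".gff3")
  write_gff3(df, f)
  back <- read_gff3_intervals(f)
  expect_identical(back[c("chrom", "start", "end", "type")],
                   df[c("chrom", "start", "end", "type")])
})

test_that("the demo pipeline completes, replays identically, validates config", {
  outdir <- file.path(tempdir(), "cnvbreak_demo")
  cfg <- pipeline_config(mode = "simulate", outdir = outdir, seed = 11,
                         genome_length = 120000L, n_events = 25L,
                         n_strains = 4L, coverage = 12,
                         size_range = c(25L, 300L))
  res <- suppressWarnings(run_pipeline(cfg))
  expect_true(all(file.exists(file.path(outdir,
    c("truth.tsv", "calls.tsv", "classification.tsv", "regions.tsv",
      "class_summary.tsv", "confusion.tsv", "config.json")))))
  expect_gt(res$confusion$exact_recovered / res$confusion$n_truth, 0.9)
  ## replay: byte-identical call table
  outdir2 <- file.path(tempdir(), "cnvbreak_demo2")
  cfg2 <- cfg; cfg2$outdir <- outdir2
  res2 <- suppressWarnings(run_pipeline(cfg2))
  expect_identical(readLines(file.path(outdir, "calls.tsv")),
                   readLines(file.path(outdir2, "calls.tsv")))
  ## user mode without a reference errors immediately
  expect_error(run_pipeline(pipeline_config(mode = "user",
                                            outdir = tempdir())),
               "reference_fasta")
})
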