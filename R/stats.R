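## Statistical kernels and summary tables. The kernels are typed wrappers
## over the corresponding base R tests, returning a uniform `test_result`
## structure; the test suite verifies each against independent enumeration
## oracles on small problems.

test_result <- function(method, statistic, p_value, alternative, extra = list()) {
  structure(c(list(method = method, statistic = unname(statistic),
                   p_value = unname(p_value), alternative = alternative),
              extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, ": statistic =", signif(x$statistic, 4),
      ", p =", signif(x$p_value, 4), "(", x$alternative, ")\n")
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric p-value; the two-sided value sums all tables with the
#' fixed margins whose probability does not exceed the observed table's (the
#' "minimum-likelihood" convention).
#'
#' @param table 2x2 matrix of non-negative integer counts
#' @param alternative "two_sided", "greater" or "less"
#' @return a `test_result` (statistic = conditional odds-ratio estimate;
#'   `table` carried along)
#' @export
fisher_exact <- function(table, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("table must hold non-negative integer counts")
  ft <- stats::fisher.test(table, alternative = sub("_sided", ".sided",
                                                    sub("two_sided", "two.sided",
                                                        alternative)))
  test_result("fisher_exact", unname(ft$estimate), ft$p.value, alternative,
              list(table = table))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact permutation p-value when both samples are at or below `exact_below`
#' and untied; otherwise the normal approximation with tie correction.
#'
#' @param x,y numeric samples
#' @param exact_below sample-size bound for the exact computation
#' @param alternative "two_sided", "greater" or "less"
#' @return a `test_result` (statistic = W); all-tied degenerate data returns
#'   p = 1 with `degenerate = TRUE`
#' @export
wilcoxon_rank_sum <- function(x, y, exact_below = 20L,
                              alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1L)
    return(test_result("wilcoxon_rank_sum", NA_real_, 1, alternative,
                       list(degenerate = TRUE)))
  ties <- any(duplicated(c(x, y)))
  exact <- length(x) <= exact_below && length(y) <= exact_below && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, exact = exact, correct = !exact,
    alternative = sub("_sided", ".sided", sub("two_sided", "two.sided",
                                              alternative))))
  test_result("wilcoxon_rank_sum", wt$statistic, wt$p.value, alternative,
              list(exact = exact, n1 = length(x), n2 = length(y)))
}

#' Two-proportion test (chi-square with continuity correction)
#' @param k1,n1 successes and trials in group 1
#' @param k2,n2 successes and trials in group 2
#' @param alternative "two_sided", "greater" or "less"
#' @return a `test_result`
#' @export
two_proportion_test <- function(k1, n1, k2, n2,
                                alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive")
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  pt <- suppressWarnings(stats::prop.test(
    c(k1, k2), c(n1, n2),
    alternative = sub("_sided", ".sided", sub("two_sided", "two.sided",
                                              alternative))))
  test_result("two_proportion_test", pt$statistic, pt$p.value, alternative,
              list(estimates = unname(pt$estimate)))
}

#' Pearson chi-square test of independence (no continuity correction)
#' @param table r x c matrix of counts
#' @return a `test_result` (statistic, df carried along)
#' @export
chisq_independence <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("need at least a 2x2 table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in table")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  test_result("chisq_independence", ct$statistic, ct$p.value, "two_sided",
              list(df = unname(ct$parameter)))
}

## ---- summary tables --------------------------------------------------------

#' Round percentages the way the breakpoint-class table reports them:
#' integers, except values below 1% shown to one decimal
#' @param count numerator counts
#' @param total denominator
#' @return numeric vector of display percentages
#' @export
report_percent <- function(count, total) {
  p <- 100 * count / total
  ifelse(p < 1, round(p, 1), round(p))
}

#' Five-row breakpoint-class summary table
#'
#' Rows: blunt; microhomology; blunt/MH with long identity (> `long_mh` bp,
#' the SSA-scale row); inserted/deleted bases (complex); inserted/deleted
#' bases with microhomology. Percentages use [report_percent()].
#'
#' @param classes data.frame from [classify_breakpoints_all()] (columns
#'   `label`, `long_identity`)
#' @return data.frame with class, n, percent; attribute `total`
#' @export
summarize_breakpoint_classes <- function(classes) {
  if (nrow(classes) == 0) stop("no classified breakpoints")
  counts <- c(
    blunt = sum(classes$label == "BLUNT"),
    microhomology = sum(classes$label == "MICROHOMOLOGY" & !classes$long_identity),
    long_identity = sum(classes$label == "MICROHOMOLOGY" & classes$long_identity),
    inserted_deleted = sum(classes$label == "COMPLEX"),
    inserted_deleted_mh = sum(classes$label == "COMPLEX_MH"))
  total <- nrow(classes)
  if (sum(counts) != total) stop("class counts do not sum to the total")
  out <- data.frame(class = names(counts), n = unname(counts),
                    percent = report_percent(unname(counts), total))
  attr(out, "total") <- total
  out
}

#' Summary table directly from printed per-class counts
#' @param counts named or unnamed vector of five class counts
#' @param total denominator (default `sum(counts)`)
#' @return data.frame as in [summarize_breakpoint_classes()]
#' @export
breakpoint_class_table <- function(counts, total = sum(counts)) {
  if (sum(counts) != total) stop("class counts do not sum to the total")
  nm <- names(counts) %||% c("blunt", "microhomology", "long_identity",
                             "inserted_deleted", "inserted_deleted_mh")
  out <- data.frame(class = nm, n = unname(counts),
                    percent = report_percent(unname(counts), total))
  attr(out, "total") <- total
  out
}

#' Annotate genomic context of calls against gene models
#'
#' Labels each call exonic (wholly inside an exon), exon_intron (overlaps an
#' exon boundary), intronic (inside a gene, no exon overlap) or intergenic.
#' Exonic calls are flagged frame-preserving when their size is a multiple
#' of three.
#'
#' @param calls call data.frame
#' @param gene_models data.frame with chrom/start/end/type (type "exon" and
#'   "gene"), e.g. from [read_gff3_intervals()]; NULL labels everything
#'   intergenic with a warning
#' @return the calls with `context` and `frame_preserving` columns, plus a
#'   `context_summary` attribute (counts per context)
#' @export
annotate_context <- function(calls, gene_models = NULL) {
  if (is.null(gene_models) || nrow(gene_models) == 0) {
    warning("no gene models supplied; all calls labelled intergenic")
    calls$context <- "intergenic"
    calls$frame_preserving <- NA
  } else {
    ex <- gene_models[gene_models$type == "exon", , drop = FALSE]
    gn <- gene_models[gene_models$type == "gene", , drop = FALSE]
    ctx <- character(nrow(calls)); fp <- rep(NA, nrow(calls))
    for (i in seq_len(nrow(calls))) {
      s <- calls$start[i]; e <- max(calls$start[i], calls$end[i])
      exi <- ex[ex$chrom == calls$chrom[i], , drop = FALSE]
      gni <- gn[gn$chrom == calls$chrom[i], , drop = FALSE]
      within_exon <- nrow(exi) > 0 && any(exi$start <= s & exi$end >= e)
      touches_exon <- nrow(exi) > 0 &&
        any(interval_overlap(exi$start, exi$end, s, e) > 0)
      in_gene <- nrow(gni) > 0 &&
        any(interval_overlap(gni$start, gni$end, s, e) > 0)
      ctx[i] <- if (within_exon) "exonic" else if (touches_exon) "exon_intron"
        else if (in_gene) "intronic" else "intergenic"
      if (ctx[i] == "exonic")
        fp[i] <- (calls$size[i] %% 3L) == 0L
    }
    calls$context <- ctx
    calls$frame_preserving <- fp
  }
  attr(calls, "context_summary") <-
    as.data.frame(table(context = calls$context), responseName = "n")
  calls
}

#' Read exon/gene intervals from a GFF3 file
#' @param path GFF3 file
#' @param types feature types to keep (default exon and gene)
#' @return data.frame chrom/start/end/type/strand
#' @export
read_gff3_intervals <- function(path, types = c("exon", "gene")) {
  x <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                  quote = "", stringsAsFactors = FALSE)
  if (!is.null(types)) x <- x[x[[3]] %in% types, , drop = FALSE]
  data.frame(chrom = x[[1]], start = x[[4]], end = x[[5]], type = x[[3]],
             strand = x[[7]], stringsAsFactors = FALSE)
}

#' Write gene models / TE annotation as GFF3
#' @param df data.frame chrom/start/end/type (1-based closed)
#' @param path output file
#' @param source source column value
#' @return `path`, invisibly
#' @export
write_gff3 <- function(df, path, source = "cnvbreak") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  type <- df$type %||% rep("region", nrow(df))
  for (i in seq_len(nrow(df)))
    writeLines(paste(df$chrom[i], source, type[i], df$start[i], df$end[i],
                     ".", ".", ".", paste0("ID=", type[i], i), sep = "\t"), con)
  invisible(path)
}
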