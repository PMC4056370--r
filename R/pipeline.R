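## End-to-end orchestration: simulate -> call -> classify -> polarize ->
## insertion-origin -> homology -> non-B -> summarize, with every table
## written to a report directory alongside the exact configuration and seeds
## for replay.

#' Default pipeline configuration
#'
#' Simulate-mode defaults reflect the study design the simulator emulates:
#' nine strains, 105 bp reads, CNVs >= 25 bp. Coverage defaults to a value
#' high enough for the two-read support filter to engage on most events.
#'
#' @param mode "simulate" or "user"
#' @param outdir report directory
#' @param seed master seed
#' @param ... overrides for any default entry
#' @return configuration list
#' @export
pipeline_config <- function(mode = c("simulate", "user"), outdir = "cnvbreak_report",
                            seed = 1L, ...) {
  mode <- match.arg(mode)
  cfg <- list(
    mode = mode, outdir = outdir, seed = as.integer(seed),
    ## simulate mode
    genome_length = 200000L, gc = 0.42, n_chrom = 1L,
    n_strains = 9L, n_events = 40L,
    class_mix = c(blunt = 0.35, microhomology = 0.41, complex = 0.22,
                  complex_mh = 0.02),
    size_range = c(25L, 500L), coverage = 10, mean_len = 105L, len_sd = 15L,
    error = 0, outgroup_divergence = 0.05, outgroup_share = 0.15,
    ## user mode inputs
    reference_fasta = NULL, reads_fastq = NULL, te_gff = NULL, mask_bed = NULL,
    outgroup_fasta = NULL, gene_models_gff = NULL,
    ## caller
    min_size = 25L, min_support = 2L, read_end_margin = 10L, te_frac = 0.8,
    exclude_tandem_dups = FALSE,
    ## downstream
    windows = c(30L, 60L, 90L, 120L), min_match = 7L, control_factor = 10L,
    nonb = nonb_config())
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' Draw a cohort of CNV specs matching a class mix
#'
#' Deletion specs with signatures drawn from the four breakpoint classes
#' (blunt / microhomology / complex / complex+microhomology). Microhomology
#' lengths are 2-10 bp, junction insertions 1-20 bp; sizes log-uniform over
#' `size_range`.
#'
#' @param n number of events
#' @param class_mix named probabilities (blunt, microhomology, complex,
#'   complex_mh)
#' @param size_range min/max CNV size
#' @param seed integer seed
#' @param kind event kind for all specs (default deletion)
#' @return list of `cnv_spec`
#' @export
cohort_specs <- function(n, class_mix = c(blunt = 0.35, microhomology = 0.41,
                                          complex = 0.22, complex_mh = 0.02),
                         size_range = c(25L, 500L), seed = 1L,
                         kind = "deletion") {
  with_seed(seed, {
    cls <- sample(names(class_mix), n, replace = TRUE, prob = class_mix)
    sizes <- round(exp(runif(n, log(size_range[1]), log(size_range[2]))))
    lapply(seq_len(n), function(i) {
      sig <- switch(cls[i],
        blunt = sig_blunt(),
        microhomology = sig_microhomology(sample(2:10, 1)),
        complex = sig_filler(sample(1:20, 1)),
        complex_mh = sig_microhomology(sample(2:10, 1),
                                       extra_len = sample(1:20, 1)))
      cnv_spec(kind, max(sizes[i], 25L), sig)
    })
  })
}

stage <- function(name, outdir, expr) {
  message("[cnvbreak] stage: ", name)
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' @param config list from [pipeline_config()], or a path to a JSON file with
#'   the same fields
#' @return invisible list with the main objects (genome, truth, calls,
#'   classified table, region report, enrichment result, summary table);
#'   all tables are also written under `config$outdir`
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    config$nonb <- do.call(nonb_config, config$nonb %||% list())
  }
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(cfg[setdiff(names(cfg), "nonb")],
                       file.path(cfg$outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  truth <- NULL; outgroup <- NULL
  if (cfg$mode == "simulate") {
    sim <- stage("simulate", cfg$outdir, {
      g0 <- generate_genome(cfg$n_chrom, cfg$genome_length, cfg$gc,
                            seed = cfg$seed)
      specs <- cohort_specs(cfg$n_events, cfg$class_mix, cfg$size_range,
                            seed = cfg$seed + 1L)
      imp <- implant_cnvs(g0, specs, paste0("strain", seq_len(cfg$n_strains)),
                          seed = cfg$seed + 2L)
      og <- generate_outgroup(imp$reference, imp$truth,
                              cfg$outgroup_divergence, cfg$outgroup_share,
                              seed = cfg$seed + 3L)
      reads <- simulate_reads(imp$strains, cfg$coverage / cfg$n_strains,
                              cfg$mean_len, cfg$len_sd, cfg$error,
                              seed = cfg$seed + 4L)
      list(genome = imp$reference, strains = imp$strains, truth = og$truth,
           outgroup = og$outgroup, reads = reads)
    })
    genome <- sim$genome; truth <- sim$truth; outgroup <- sim$outgroup
    reads <- sim$reads
    write.table(truth, file.path(cfg$outdir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(cfg$outdir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    write_genome_fasta(genome, file.path(cfg$outdir, "reference.fasta"))
  } else {
    if (is.null(cfg$reference_fasta))
      stop("user mode requires a reference_fasta path")
    if (is.null(cfg$reads_fastq))
      stop("user mode requires reads_fastq path(s)")
    genome <- read_genome_fasta(cfg$reference_fasta)
    if (!is.null(cfg$mask_bed)) genome$mask <- read_bed(cfg$mask_bed)
    if (!is.null(cfg$te_gff))
      genome$te <- read_gff3_intervals(cfg$te_gff, types = NULL) %||% genome$te
    reads <- do.call(rbind, lapply(seq_along(cfg$reads_fastq), function(i)
      read_reads_fastq(cfg$reads_fastq[i],
                       strain = paste0("sample", i))))
    if (!is.null(cfg$outgroup_fasta))
      outgroup <- read_genome_fasta(cfg$outgroup_fasta)
  }

  calls <- stage("call", cfg$outdir, {
    al <- map_reads(reads, genome)
    sig <- detect_split_signatures(al, cfg$min_size, reads = reads)
    cluster_and_filter(sig, genome, min_support = cfg$min_support,
                       read_end_margin = cfg$read_end_margin,
                       te_frac = cfg$te_frac,
                       exclude_tandem_dups = cfg$exclude_tandem_dups)
  })
  write_calls(calls, file.path(cfg$outdir, "calls.tsv"))

  classified <- stage("classify", cfg$outdir, {
    if (nrow(calls) == 0) stop("no calls to classify")
    prof <- measure_microhomology_all(calls, genome)
    classify_breakpoints_all(prof)
  })
  classified <- stage("polarize", cfg$outdir, {
    pol <- if (!is.null(outgroup))
      polarize_all(calls, outgroup, genome)$polarity
    else { warning("no outgroup; calls unpolarized"); "UNPOLARIZED" }
    classified$polarity <- pol
    classified
  })
  regions <- stage("recurrence", cfg$outdir,
                   find_recurrent_and_complex(calls))
  write.table(classified, file.path(cfg$outdir, "classification.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(regions, file.path(cfg$outdir, "regions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  origins <- stage("insertion_origin", cfg$outdir, {
    ins <- calls[calls$kind == "insertion" & nchar(calls$inserted_seq) > 0, ,
                 drop = FALSE]
    if (nrow(ins) == 0) NULL else {
      lab <- vapply(seq_len(nrow(ins)), function(i)
        classify_insertion_origin(ins[i, ], genome)$label, character(1))
      org <- data.frame(call_id = ins$call_id, origin = lab)
      fill <- ins[lab == "FILLER", , drop = FALSE]
      tests <- NULL
      if (nrow(fill) >= 5) {
        ctl <- shuffle_controls(fill, genome, cfg$control_factor,
                                seed = cfg$seed + 5L)
        tests <- lapply(cfg$windows, function(w) {
          rt <- neighborhood_match_table(fill, genome, w, cfg$min_match)
          ct <- neighborhood_match_table(ctl, genome, w, cfg$min_match)
          filler_enrichment_tests(rt, ct)
        })
      }
      list(table = org, tests = tests)
    }
  })
  if (!is.null(origins))
    write.table(origins$table, file.path(cfg$outdir, "insertion_origins.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  homology <- stage("homology", cfg$outdir, {
    dels <- calls[calls$kind != "insertion", , drop = FALSE]
    if (nrow(dels) == 0) NULL else mechanism_support_all(dels, genome)
  })
  if (!is.null(homology))
    write.table(homology, file.path(cfg$outdir, "homology.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  enrich <- stage("nonb", cfg$outdir, {
    br <- breakpoint_regions(calls, genome)
    if (nrow(br) < 4L) NULL else
      enrichment_test(br, genome, cfg$control_factor, seed = cfg$seed + 6L,
                      config = cfg$nonb)
  })
  if (!is.null(enrich)) {
    jsonlite::write_json(
      list(counts = enrich$counts, odds_ratio = enrich$odds_ratio,
           p_value = enrich$p_value),
      file.path(cfg$outdir, "nonb_enrichment.json"), auto_unbox = TRUE,
      digits = NA, force = TRUE)
    write.table(
      data.frame(position = seq_along(enrich$histograms$real),
                 real = enrich$histograms$real,
                 control = enrich$histograms$control),
      file.path(cfg$outdir, "nonb_histogram.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  summary_tab <- stage("summarize", cfg$outdir, {
    st <- summarize_breakpoint_classes(classified)
    write.table(st, file.path(cfg$outdir, "class_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    st
  })

  confusion <- NULL
  if (!is.null(truth)) {
    confusion <- stage("confusion", cfg$outdir, {
      key_t <- paste(truth$chrom, truth$start, truth$end, truth$kind)
      key_c <- paste(calls$chrom, calls$start, calls$end, calls$kind)
      cm <- data.frame(
        n_truth = nrow(truth), n_called = nrow(calls),
        exact_recovered = sum(key_t %in% key_c),
        false_calls = sum(!key_c %in% key_t))
      write.table(cm, file.path(cfg$outdir, "confusion.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      cm
    })
  }
  invisible(list(genome = genome, truth = truth, reads = reads, calls = calls,
                 classified = classified, regions = regions,
                 origins = origins, homology = homology, enrichment = enrich,
                 summary = summary_tab, confusion = confusion, config = cfg))
}
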