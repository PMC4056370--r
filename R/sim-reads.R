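## Shotgun-read simulation from strain genomes. Reads emulate long 454-style
## single-end reads: mean length 105 bp by default (length drawn from a
## normal truncated to [50, 2 * mean]), uniform start positions, optional
## per-base substitution errors.

#' Simulate shotgun reads from strain genomes
#'
#' Total bases per strain approximate `coverage` times the strain genome
#' size. Each read records its origin (strain, chromosome, start, strand) so
#' calls can be audited against the truth ledger.
#'
#' @param strain_genomes named list of chromosome-sequence lists, as returned
#'   in `implant_cnvs()$strains`
#' @param coverage fold coverage per strain (> 0)
#' @param mean_len mean read length in bp (>= 50); default 105
#' @param len_sd read-length standard deviation in bp
#' @param error per-base substitution error rate
#' @param seed integer seed
#' @param both_strands draw reads from both strands (default TRUE)
#' @return data.frame of class `read_set`: id, strain, chrom, start, strand,
#'   seq; attributes `mean_length` and `error`
#' @export
simulate_reads <- function(strain_genomes, coverage, mean_len = 105L,
                           len_sd = 15L, error = 0, seed = 1L,
                           both_strands = TRUE) {
  stopifnot(coverage > 0, mean_len >= 50L, error >= 0, error < 0.5)
  with_seed(seed, {
    out <- vector("list", length(strain_genomes))
    names(out) <- names(strain_genomes)
    ctr <- 0L
    for (st in names(strain_genomes)) {
      g <- strain_genomes[[st]]
      glen <- vapply(g, nchar, integer(1))
      n_reads <- max(1L, round(coverage * sum(glen) / mean_len))
      chrom <- sample(names(g), n_reads, replace = TRUE,
                      prob = glen / sum(glen))
      len <- round(rnorm(n_reads, mean_len, len_sd))
      len <- pmin(pmax(len, 50L), 2L * mean_len)
      start <- integer(n_reads)
      seqs <- character(n_reads)
      for (ch in unique(chrom)) {
        ii <- which(chrom == ch)
        start[ii] <- 1L + floor(runif(length(ii)) * pmax(1L, glen[[ch]] - len[ii] + 1L))
        seqs[ii] <- substring(g[[ch]], start[ii], start[ii] + len[ii] - 1L)
      }
      strand <- if (both_strands)
        sample(c("+", "-"), n_reads, replace = TRUE) else rep("+", n_reads)
      flip <- strand == "-"
      if (any(flip)) seqs[flip] <- vapply(seqs[flip], revcomp, character(1),
                                          USE.NAMES = FALSE)
      if (error > 0) {
        nerr <- rbinom(n_reads, nchar(seqs), error)
        for (i in which(nerr > 0)) {
          v <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
          at <- sample.int(length(v), nerr[i])
          v[at] <- vapply(v[at], function(b) sample(setdiff(BASES, b), 1L),
                          character(1), USE.NAMES = FALSE)
          seqs[i] <- paste(v, collapse = "")
        }
      }
      out[[st]] <- data.frame(
        id = paste0(st, "_r", ctr + seq_len(n_reads)),
        strain = st, chrom = chrom, start = start, strand = strand,
        seq = seqs, stringsAsFactors = FALSE, row.names = NULL)
      ctr <- ctr + n_reads
    }
    reads <- do.call(rbind, out)
    rownames(reads) <- NULL
    structure(reads, mean_length = mean_len, error = error,
              class = c("read_set", "data.frame"))
  })
}

## ---- FASTA / FASTQ I/O -----------------------------------------------------

#' Write a genome to FASTA
#' @param genome `sim_genome` or named list/vector of sequences
#' @param path output file
#' @return `path`, invisibly
#' @export
write_genome_fasta <- function(genome, path) {
  chroms <- if (inherits(genome, "sim_genome")) genome$chromosomes else genome
  x <- Biostrings::DNAStringSet(unlist(chroms))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a genome from FASTA into a `sim_genome` (mask covering everything)
#' @param path FASTA file
#' @return a `sim_genome`
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  chroms <- setNames(as.character(x), sub("\\s.*", "", names(x)))
  structure(list(chromosomes = chroms,
                 mask = data.frame(chrom = names(chroms), start = 1L,
                                   end = nchar(chroms), row.names = NULL),
                 te = data.frame(chrom = character(0), start = integer(0),
                                 end = integer(0)),
                 seed = NA_integer_),
            class = "sim_genome")
}

#' Write reads to FASTQ (one file, or one per strain)
#' @param reads a `read_set`
#' @param path output FASTQ path; with `per_strain = TRUE` a directory
#' @param per_strain write one FASTQ per strain
#' @return written path(s), invisibly
#' @export
write_reads_fastq <- function(reads, path, per_strain = FALSE) {
  wr <- function(df, p) {
    qual <- vapply(nchar(df$seq), function(n) strrep("I", n), character(1))
    writeLines(paste0("@", df$id, "\n", df$seq, "\n+\n", qual), p)
    p
  }
  if (per_strain) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    ps <- vapply(split(reads, reads$strain), function(df)
      wr(df, file.path(path, paste0(df$strain[1], ".fastq"))), character(1))
    invisible(ps)
  } else invisible(wr(reads, path))
}

#' Read a FASTQ into a minimal `read_set` (origin fields unknown)
#' @param path FASTQ file
#' @param strain strain label to assign
#' @return a `read_set` data.frame
#' @export
read_reads_fastq <- function(path, strain = "sample") {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  structure(data.frame(id = sub("\\s.*", "", names(x)), strain = strain,
                       chrom = NA_character_, start = NA_integer_,
                       strand = NA_character_, seq = as.character(x),
                       stringsAsFactors = FALSE, row.names = NULL),
            mean_length = mean(nchar(as.character(x))), error = NA_real_,
            class = c("read_set", "data.frame"))
}

#' Write interval annotation as BED (0-based half-open on disk)
#' @param df data.frame with chrom/start/end (1-based closed in memory)
#' @param path output file
#' @param names optional name column values
#' @return `path`, invisibly
#' @export
write_bed <- function(df, path, names = NULL) {
  bed <- data.frame(df$chrom, df$start - 1L, df$end)
  if (!is.null(names)) bed$name <- names
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED intervals into 1-based closed coordinates
#' @param path BED file
#' @return data.frame chrom/start/end (plus name if present)
#' @export
read_bed <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(chrom = x[[1]], start = x[[2]] + 1L, end = x[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(x) >= 4) out$name <- x[[4]]
  out
}
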