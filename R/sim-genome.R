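## Synthetic genomes with implanted CNVs carrying controlled breakpoint
## signatures. The generator is the ground-truth side of the package: every
## implanted event is recorded in a truth ledger and every signature is
## verifiable by direct inspection of the mutated sequence.

#' Generate a random multi-chromosome genome
#'
#' Chromosome sequences are i.i.d. bases at the requested GC content. A
#' euchromatin mask covers each chromosome except `end_mask` bases at either
#' end (emulating pericentromeric/telomeric exclusion), and optional TE
#' "islands" are annotated (interval annotation only; the TE filter of the
#' caller needs intervals, not TE sequence families).
#'
#' @param n_chrom number of chromosomes
#' @param lengths integer vector of chromosome lengths in bp (recycled to
#'   `n_chrom`); 10 kb or more is recommended so that flank windows fit
#' @param gc GC fraction in (0, 1)
#' @param seed integer seed; regeneration from the same seed is byte-identical
#' @param end_mask bp excluded from the euchromatin mask at each chromosome end
#' @param te_islands number of TE intervals annotated per chromosome
#' @param te_len length of each TE interval
#' @param nonb_per_kb density of non-B DNA exemplar motifs written into the
#'   sequence (motifs per kb, cycling through the five classes). Default 0
#'   (pure i.i.d. sequence). Real euchromatin carries an appreciable non-B
#'   background (a few percent of short windows contain a motif), which pure
#'   i.i.d. sequence lacks almost entirely; set around 0.8/kb to emulate it.
#' @return an object of class `sim_genome`: list with `chromosomes` (named
#'   character vector), `mask` and `te` (data.frames chrom/start/end, 1-based
#'   closed), and `seed`
#' @export
#' @examples
#' g <- generate_genome(1, 12000, gc = 0.45, seed = 1)
#' nchar(g$chromosomes[["chr1"]])
generate_genome <- function(n_chrom = 1L, lengths = 50000L, gc = 0.5,
                            seed = 1L, end_mask = 1000L,
                            te_islands = 0L, te_len = 500L,
                            nonb_per_kb = 0) {
  lengths <- rep_len(as.integer(lengths), n_chrom)
  if (any(lengths <= 0L)) stop("chromosome lengths must be positive")
  if (gc <= 0 || gc >= 1) stop("gc must lie strictly between 0 and 1")
  with_seed(seed, {
    chroms <- setNames(
      vapply(lengths, function(L) random_dna(L, gc), character(1)),
      paste0("chr", seq_len(n_chrom)))
    if (nonb_per_kb > 0) {
      cls <- c("ZDNA", "G4", "INVERTED_REPEAT", "MIRROR_REPEAT",
               "DIRECT_REPEAT")
      mot_chars <- lapply(cls, function(cl)
        strsplit(nonb_exemplar(cl), "", fixed = TRUE)[[1]])
      for (ch in names(chroms)) {
        L <- nchar(chroms[[ch]])
        n_mot <- round(nonb_per_kb * L / 1000)
        if (n_mot < 1L) next
        at <- sort(sample.int(L - 40L, n_mot))
        at <- at[c(TRUE, diff(at) > 40L)]   # no overlapping exemplars
        v <- strsplit(chroms[[ch]], "", fixed = TRUE)[[1]]
        for (j in seq_along(at)) {
          mc <- mot_chars[[(j - 1L) %% 5L + 1L]]
          v[at[j]:(at[j] + length(mc) - 1L)] <- mc
        }
        chroms[[ch]] <- paste(v, collapse = "")
      }
    }
    mask <- data.frame(
      chrom = names(chroms),
      start = pmin(end_mask + 1L, lengths),
      end = pmax(lengths - end_mask, 1L))
    te <- data.frame(chrom = character(0), start = integer(0), end = integer(0))
    if (te_islands > 0L) {
      for (ch in names(chroms)) {
        m <- mask[mask$chrom == ch, ]
        span <- m$end - m$start + 1L - te_len
        if (span <= te_islands) next
        s <- sort(sample.int(span, te_islands)) + m$start - 1L
        te <- rbind(te, data.frame(chrom = ch, start = s, end = s + te_len - 1L))
      }
    }
    structure(list(chromosomes = chroms, mask = mask, te = te,
                   seed = as.integer(seed)),
              class = "sim_genome")
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("sim_genome:", length(x$chromosomes), "chromosome(s),",
      sum(nchar(x$chromosomes)), "bp total,", nrow(x$te), "TE interval(s)\n")
  invisible(x)
}

## ---- CNV specification -----------------------------------------------------

#' Specify a CNV to implant
#'
#' The signature controls the breakpoint-mechanism evidence written into the
#' sequence; see the `sig_*` constructors. Size must be >= 25 bp, the lower
#' bound used throughout for calling a variant a CNV rather than an indel.
#'
#' @param kind "deletion", "insertion" or "tandem_dup"
#' @param size event size in bp (>= 25)
#' @param signature a `sig_*()` object; defaults to `sig_blunt()`
#' @param strains character vector of strain names carrying the event, or NULL
#'   for all strains
#' @param chrom chromosome name, or NULL to place anywhere
#' @param planted_nonb optional non-B motif class name to embed next to the 5'
#'   breakpoint ("G4", "ZDNA", "INVERTED_REPEAT", "MIRROR_REPEAT",
#'   "DIRECT_REPEAT")
#' @return a `cnv_spec` object
#' @export
cnv_spec <- function(kind, size, signature = sig_blunt(), strains = NULL,
                     chrom = NULL, planted_nonb = NULL) {
  kind <- match.arg(kind, c("deletion", "insertion", "tandem_dup"))
  size <- as.integer(size)
  if (size < 25L) stop("CNV size must be >= 25 bp")
  if (!inherits(signature, "cnv_signature")) stop("signature must be a sig_*() object")
  if (signature$type == "microhomology" && signature$k >= size)
    stop("microhomology length must be smaller than the event size")
  structure(list(kind = kind, size = size, signature = signature,
                 strains = strains, chrom = chrom, planted_nonb = planted_nonb),
            class = "cnv_spec")
}

sig_new <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "cnv_signature")
}

#' Breakpoint signature constructors
#'
#' @description
#' * `sig_blunt()`: no microhomology, no junction-inserted bases.
#' * `sig_microhomology(k, extra_len = 0)`: exactly `k` bp of type-I
#'   microhomology are forced at the junction (the first `k` bases of the
#'   affected segment equal the `k` bases immediately following the event);
#'   a positive `extra_len` additionally inserts that many junction bases,
#'   producing a complex end with microhomology.
#' * `sig_filler(length = NULL, composition = "random")`: for insertions, the
#'   inserted sequence is novel DNA verified absent from the reference; for
#'   deletions, `length` untemplated bases are left at the junction (a complex
#'   end).
#' * `sig_repeat_expansion(unit, copies)`: insertion consisting of `copies`
#'   copies of `unit`, placed adjacent to a matching repeat tract written into
#'   the flank.
#' * `sig_nahr_flanks(repeat_len, identity)`: two repeats of the stated length
#'   and percent identity are written immediately flanking a deletion, the
#'   configuration detectable by the SSA/NAHR homology scan.
#'
#' @param k microhomology length in bp (>= 0)
#' @param extra_len junction-inserted bases (>= 0)
#' @param length filler length in bp
#' @param composition "random" (only supported composition)
#' @param unit repeat unit string (1-6 bp)
#' @param copies number of unit copies inserted (>= 2)
#' @param repeat_len flanking-repeat length in bp (>= 30)
#' @param identity percent identity of the two repeats (e.g. 98)
#' @name signatures
NULL

#' @rdname signatures
#' @export
sig_blunt <- function() sig_new("blunt")

#' @rdname signatures
#' @export
sig_microhomology <- function(k, extra_len = 0L) {
  stopifnot(k >= 0L, extra_len >= 0L)
  sig_new("microhomology", k = as.integer(k), extra_len = as.integer(extra_len))
}

#' @rdname signatures
#' @export
sig_filler <- function(length = NULL, composition = "random") {
  stopifnot(composition == "random")
  sig_new("filler", length = if (is.null(length)) NULL else as.integer(length),
          composition = composition)
}

#' @rdname signatures
#' @export
sig_repeat_expansion <- function(unit, copies) {
  stopifnot(nchar(unit) >= 1L, nchar(unit) <= 6L, copies >= 2L)
  sig_new("repeat_expansion", unit = toupper(unit), copies = as.integer(copies))
}

#' @rdname signatures
#' @export
sig_nahr_flanks <- function(repeat_len, identity = 98) {
  stopifnot(repeat_len >= 30L, identity > 50, identity <= 100)
  sig_new("nahr_flanks", repeat_len = as.integer(repeat_len),
          identity = as.numeric(identity))
}

#' Canonical exemplar sequence for a non-B DNA motif class
#'
#' Short sequences that satisfy the corresponding detector definition
#' exactly; used for planting motifs in simulations.
#'
#' @param class one of "G4", "ZDNA", "INVERTED_REPEAT", "MIRROR_REPEAT",
#'   "DIRECT_REPEAT"
#' @return character scalar motif sequence
#' @export
nonb_exemplar <- function(class) {
  switch(class,
    G4 = "GGGTTAGGGTTAGGGTTAGGG",
    ZDNA = "GCGCGCGCGCGCGC",
    INVERTED_REPEAT = paste0("ACGTTACGGCAT", "AGT", revcomp("ACGTTACGGCAT")),
    MIRROR_REPEAT = paste0("ACCGTTAGGCAT", "AGT", str_rev("ACCGTTAGGCAT")),
    DIRECT_REPEAT = paste0("ACGGATCCGTTA", "AG", "ACGGATCCGTTA"),
    stop("unknown non-B class: ", class))
}

## ---- implanting ------------------------------------------------------------

## choose non-overlapping implant sites with >= min_sep bp between events and
## `buffer` bp clear of the mask edges, via the order-statistics trick
place_sites <- function(genome, specs, min_sep = 1000L, buffer = 700L) {
  sizes <- vapply(specs, function(s) s$size, integer(1))
  want_chrom <- vapply(specs, function(s) s$chrom %||% NA_character_, character(1))
  chroms <- names(genome$chromosomes)
  mask_by <- split(genome$mask, genome$mask$chrom)
  ## assign unassigned specs to chromosomes proportional to usable span
  spans <- vapply(chroms, function(ch) {
    m <- mask_by[[ch]]
    max(0L, sum(m$end - m$start + 1L) - 2L * buffer)
  }, numeric(1))
  if (all(spans <= 0)) stop("no euchromatin available for implanting")
  idx_free <- which(is.na(want_chrom))
  if (length(idx_free))
    want_chrom[idx_free] <- sample(chroms, length(idx_free), replace = TRUE,
                                   prob = spans / sum(spans))
  out <- data.frame(spec = seq_along(specs), chrom = want_chrom, start = NA_integer_)
  for (ch in unique(want_chrom)) {
    ii <- which(want_chrom == ch)
    m <- mask_by[[ch]]
    if (is.null(m) || nrow(m) == 0) stop("chromosome has no mask: ", ch)
    lo <- m$start[1] + buffer
    hi <- m$end[nrow(m)] - buffer
    need <- sum(sizes[ii]) + (length(ii)) * min_sep
    avail <- hi - lo + 1L
    if (avail < need)
      stop("specs do not fit within the euchromatin of ", ch,
           " (need ", need, " bp, have ", avail, ")")
    slack <- avail - need
    offs <- sort(floor(runif(length(ii)) * slack))
    ord <- sample(ii)  # random order along the chromosome
    for (j in seq_along(ord)) {
      ## start = lo + sorted offset + room taken by the preceding events
      st <- lo + offs[j] + if (j == 1) 0L else
        sum(sizes[ord[seq_len(j - 1L)]]) + (j - 1L) * min_sep
      out$start[out$spec == ord[j]] <- as.integer(st)
    }
  }
  out
}

## write the signature-specific sequence edits for one event into the
## reference chromosome string; returns list(chrom_seq, event) where event is
## a one-row truth record
write_signature <- function(chrom_seq, spec, s) {
  kind <- spec$kind; size <- spec$size; sig <- spec$signature
  e <- s + size - 1L
  ins_seq <- ""; extra <- ""; mh_k <- 0L
  nahr_len <- NA_integer_; nahr_id <- NA_real_
  force_mismatch <- function(seq, i, must_differ_from) {
    if (substr(seq, i, i) %in% must_differ_from)
      seq <- set_base(seq, i, other_base(must_differ_from))
    seq
  }
  if (kind == "deletion" || kind == "tandem_dup") {
    if (kind == "deletion" && sig$type == "nahr_flanks") {
      rl <- sig$repeat_len
      rep1 <- random_dna(rl, 0.5)
      nmm <- max(0L, round((1 - sig$identity / 100) * rl))
      rep2 <- rep1
      if (nmm > 0) {
        at <- sample(rl, nmm)
        for (i in at) rep2 <- set_base(rep2, i, other_base(substr(rep2, i, i)))
      }
      substr(chrom_seq, s - rl, s - 1L) <- rep1
      substr(chrom_seq, e + 1L, e + rl) <- rep2
      nahr_len <- rl; nahr_id <- sig$identity
    }
    if (sig$type == "microhomology" && sig$k > 0L) {
      k <- sig$k
      substr(chrom_seq, s, s + k - 1L) <- substr(chrom_seq, e + 1L, e + k)
      ## cap type-I at exactly k: break the k+1 extension and the suffix route
      if (k < size)
        chrom_seq <- force_mismatch(chrom_seq, s + k,
                                    substr(chrom_seq, e + k + 1L, e + k + 1L))
      chrom_seq <- force_mismatch(chrom_seq, e, substr(chrom_seq, s - 1L, s - 1L))
      mh_k <- k
    } else {
      ## blunt-style junction: no type-I microhomology at all
      chrom_seq <- force_mismatch(chrom_seq, s, substr(chrom_seq, e + 1L, e + 1L))
      chrom_seq <- force_mismatch(chrom_seq, e, substr(chrom_seq, s - 1L, s - 1L))
    }
    el <- if (sig$type == "filler") (sig$length %||% 10L) else
          if (sig$type == "microhomology") sig$extra_len else 0L
    if (kind == "deletion" && el > 0L) {
      extra <- random_dna(el, 0.5)
      ## keep the junction unambiguous: the extra bases must not be
      ## absorbable into either flank, i.e. the first extra base must differ
      ## from the deleted segment's first base and the last from its last
      avoid_first <- substr(chrom_seq, s, s)
      avoid_last <- substr(chrom_seq, e, e)
      if (el == 1L) {
        if (substr(extra, 1L, 1L) %in% c(avoid_first, avoid_last))
          extra <- other_base(c(avoid_first, avoid_last))
      } else {
        if (substr(extra, 1L, 1L) == avoid_first)
          extra <- set_base(extra, 1L, other_base(avoid_first))
        if (substr(extra, el, el) == avoid_last)
          extra <- set_base(extra, el, other_base(avoid_last))
      }
    }
  } else { # insertion
    if (sig$type == "repeat_expansion") {
      u <- sig$unit; ul <- nchar(u)
      tract <- strrep(u, 2L)
      substr(chrom_seq, s - nchar(tract) + 1L, s) <- tract
      ins_seq <- strrep(u, sig$copies)
      if (nchar(ins_seq) < 25L)
        ins_seq <- strrep(u, ceiling(25 / ul))
    } else if (sig$type == "microhomology" && sig$k > 0L) {
      k <- sig$k
      ins_seq <- random_dna(size, 0.5)
      substr(ins_seq, 1L, k) <- substr(chrom_seq, s + 1L, s + k)
      if (k < size && substr(ins_seq, k + 1L, k + 1L) ==
            substr(chrom_seq, s + k + 1L, s + k + 1L))
        ins_seq <- set_base(ins_seq, k + 1L,
                            other_base(substr(chrom_seq, s + k + 1L, s + k + 1L)))
      if (substr(ins_seq, size, size) == substr(chrom_seq, s, s))
        ins_seq <- set_base(ins_seq, size, other_base(substr(chrom_seq, s, s)))
      mh_k <- k
    } else {
      ## filler (the default for insertions): novel DNA, verified absent
      ins_seq <- novel_sequence(size, chrom_seq)
      ## blunt junction on both sides
      if (substr(ins_seq, 1L, 1L) == substr(chrom_seq, s + 1L, s + 1L))
        ins_seq <- set_base(ins_seq, 1L, other_base(
          c(substr(chrom_seq, s + 1L, s + 1L), substr(chrom_seq, s, s))))
      if (substr(ins_seq, size, size) == substr(chrom_seq, s, s))
        ins_seq <- set_base(ins_seq, size, other_base(
          c(substr(chrom_seq, s, s), substr(chrom_seq, s + 1L, s + 1L))))
    }
  }
  if (!is.null(spec$planted_nonb)) {
    mot <- nonb_exemplar(spec$planted_nonb)
    substr(chrom_seq, s - nchar(mot) - 2L, s - 3L) <- mot
  }
  list(chrom_seq = chrom_seq,
       event = data.frame(
         chrom = NA_character_, start = s,
         end = if (kind == "insertion") s else e,
         kind = kind, signature = sig$type, mh_k = mh_k,
         extra_len = nchar(extra), inserted_seq =
           if (kind == "insertion") ins_seq else extra,
         nahr_len = nahr_len, nahr_identity = nahr_id,
         nonb_class = spec$planted_nonb %||% NA_character_,
         stringsAsFactors = FALSE))
}

#' A sequence of length n with no exact full-length match in `ref`
#' (either strand), found by rejection sampling with explicit verification
#' @noRd
novel_sequence <- function(n, ref, max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    cand <- random_dna(n, 0.5)
    hit <- Biostrings::countPattern(cand, Biostrings::DNAString(ref)) +
      Biostrings::countPattern(revcomp(cand), Biostrings::DNAString(ref))
    if (hit == 0L) return(cand)
  }
  stop("could not generate a novel sequence of length ", n)
}

#' Implant CNVs into a reference genome and derive strain genomes
#'
#' Sites are chosen within the euchromatin mask, non-overlapping, at least
#' 1 kb apart and clear of mask edges. Signatures that require reference
#' context (forced microhomology, NAHR-style flanking repeats, repeat tracts,
#' planted non-B motifs) are first written into the reference; strain genomes
#' are then derived from that edited reference, so the returned `$reference`
#' must be used for all downstream mapping and classification.
#'
#' Event coordinates in the truth ledger are left-aligned (the leftmost
#' equivalent representation under junction ambiguity), matching the
#' normalization applied by the caller.
#'
#' @param genome a `sim_genome`
#' @param specs list of `cnv_spec` objects
#' @param strains character vector of strain names (default 9 strains,
#'   matching the nine-line study design this simulates)
#' @param seed integer seed
#' @return list with `reference` (edited `sim_genome`), `strains` (named list
#'   of character vectors of chromosome sequences), and `truth` (data.frame
#'   ledger with one row per event: coordinates, kind, signature, forced
#'   microhomology length, junction-extra length, inserted sequence, NAHR
#'   repeat parameters, carrier strains)
#' @export
implant_cnvs <- function(genome, specs, strains = paste0("strain", 1:9),
                         seed = 1L) {
  stopifnot(inherits(genome, "sim_genome"), length(specs) > 0)
  with_seed(seed, {
    sites <- place_sites(genome, specs)
    chroms <- genome$chromosomes
    truth <- NULL
    for (i in order(sites$start)) {         # edits never move coordinates
      ch <- sites$chrom[i]
      res <- write_signature(chroms[[ch]], specs[[sites$spec[i]]], sites$start[i])
      chroms[[ch]] <- res$chrom_seq
      ev <- res$event
      ev$chrom <- ch
      ev$event_id <- paste0("cnv", sites$spec[i])
      sp <- specs[[sites$spec[i]]]
      carriers <- sp$strains %||% strains
      if (!all(carriers %in% strains)) stop("unknown strain in spec")
      ev$strains <- paste(carriers, collapse = ",")
      truth <- rbind(truth, ev)
    }
    truth <- truth[order(truth$chrom, truth$start), ]
    rownames(truth) <- NULL
    ## left-align coordinates against the edited reference
    for (i in seq_len(nrow(truth))) {
      ref <- chroms[[truth$chrom[i]]]
      if (truth$kind[i] == "deletion" && truth$extra_len[i] == 0L) {
        la <- left_align_deletion(ref, truth$start[i], truth$end[i])
        truth$start[i] <- la[["start"]]; truth$end[i] <- la[["end"]]
      } else if (truth$kind[i] == "insertion") {
        la <- left_align_insertion(ref, truth$start[i], truth$inserted_seq[i])
        truth$start[i] <- la$pos; truth$end[i] <- la$pos
        truth$inserted_seq[i] <- la$ins
      }
    }
    ref_genome <- genome
    ref_genome$chromosomes <- chroms
    strain_genomes <- lapply(setNames(strains, strains), function(st) {
      g <- chroms
      carried <- truth[vapply(strsplit(truth$strains, ","), function(x) st %in% x,
                              logical(1)), ]
      ## apply from the right so earlier coordinates stay valid
      carried <- carried[order(-carried$start), ]
      for (j in seq_len(nrow(carried))) {
        ev <- carried[j, ]
        seqc <- g[[ev$chrom]]
        if (ev$kind == "deletion") {
          g[[ev$chrom]] <- paste0(substr(seqc, 1L, ev$start - 1L),
                                  ev$inserted_seq,  # junction extra, often ""
                                  substr(seqc, ev$end + 1L, nchar(seqc)))
        } else if (ev$kind == "insertion") {
          g[[ev$chrom]] <- paste0(substr(seqc, 1L, ev$start),
                                  ev$inserted_seq,
                                  substr(seqc, ev$start + 1L, nchar(seqc)))
        } else { # tandem_dup: a second copy of [start, end] after end
          g[[ev$chrom]] <- paste0(substr(seqc, 1L, ev$end),
                                  substr(seqc, ev$start, ev$end),
                                  substr(seqc, ev$end + 1L, nchar(seqc)))
        }
      }
      g
    })
    attr(truth, "coordinate_convention") <- "1-based closed"
    list(reference = ref_genome, strains = strain_genomes, truth = truth)
  })
}

#' Derive an outgroup genome and record intended polarities
#'
#' The outgroup starts from the reference; a `share` fraction of implanted
#' events have their derived allele applied to the outgroup as well (under
#' parsimony those calls polarize as variants of the reference), and
#' substitutions at the requested divergence are applied uniformly outside
#' 20 bp junction-adjacent guard zones, so that polarization failures reflect
#' logic rather than simulated noise.
#'
#' @param genome the (edited) reference `sim_genome` from [implant_cnvs()]
#' @param truth truth ledger from [implant_cnvs()]
#' @param divergence substitutions per site (< 0.2)
#' @param share fraction of events whose derived allele the outgroup carries
#' @param seed integer seed
#' @return list with `outgroup` (`sim_genome`) and `truth` (ledger with
#'   `outgroup_state` and `intended_polarity` columns added)
#' @export
generate_outgroup <- function(genome, truth, divergence = 0.05, share = 0,
                              seed = 1L) {
  stopifnot(share >= 0, share <= 1, divergence >= 0, divergence < 0.2)
  with_seed(seed, {
    n_ev <- nrow(truth)
    derived <- rep(FALSE, n_ev)
    if (n_ev > 0 && share > 0)
      derived[sample(n_ev, round(share * n_ev))] <- TRUE
    truth$outgroup_state <- ifelse(derived, "derived", "ancestral")
    truth$intended_polarity <- ifelse(
      truth$kind == "deletion",
      ifelse(derived, "INSERTION_IN_REFERENCE", "DELETION_IN_STRAIN"),
      ifelse(derived, "DELETION_IN_REFERENCE", "INSERTION_IN_STRAIN"))
    guard <- 20L
    chroms <- genome$chromosomes
    out <- chroms
    ## guard zones in reference coordinates, then track the shift per event
    for (ch in names(out)) {
      ev <- truth[truth$chrom == ch, , drop = FALSE]
      ev <- ev[order(-ev$start), , drop = FALSE]
      seqc <- out[[ch]]
      for (j in seq_len(nrow(ev))) {
        if (ev$outgroup_state[j] != "derived") next
        if (ev$kind[j] == "deletion") {
          seqc <- paste0(substr(seqc, 1L, ev$start[j] - 1L), ev$inserted_seq[j],
                         substr(seqc, ev$end[j] + 1L, nchar(seqc)))
        } else if (ev$kind[j] == "insertion") {
          seqc <- paste0(substr(seqc, 1L, ev$start[j]), ev$inserted_seq[j],
                         substr(seqc, ev$start[j] + 1L, nchar(seqc)))
        } else {
          seqc <- paste0(substr(seqc, 1L, ev$end[j]),
                         substr(seqc, ev$start[j], ev$end[j]),
                         substr(seqc, ev$end[j] + 1L, nchar(seqc)))
        }
      }
      out[[ch]] <- seqc
    }
    if (divergence > 0) {
      for (ch in names(out)) {
        seqc <- out[[ch]]
        n <- nchar(seqc)
        ## guard zones: around every event junction, in outgroup coordinates
        ev <- truth[truth$chrom == ch, , drop = FALSE]
        shift <- 0L
        guard_iv <- NULL
        if (nrow(ev) > 0) {
          ev <- ev[order(ev$start), , drop = FALSE]
          for (j in seq_len(nrow(ev))) {
            s <- ev$start[j] + shift
            e2 <- ev$end[j] + shift
            guard_iv <- rbind(guard_iv,
                              c(s - guard, e2 + guard + nchar(ev$inserted_seq[j])))
            if (ev$outgroup_state[j] == "derived") {
              if (ev$kind[j] == "deletion")
                shift <- shift - (ev$end[j] - ev$start[j] + 1L) +
                  nchar(ev$inserted_seq[j])
              else if (ev$kind[j] == "insertion")
                shift <- shift + nchar(ev$inserted_seq[j])
              else shift <- shift + (ev$end[j] - ev$start[j] + 1L)
            }
          }
        }
        nsub <- rbinom(1L, n, divergence)
        if (nsub > 0) {
          at <- sample.int(n, nsub)
          if (!is.null(guard_iv)) {
            inside <- rep(FALSE, length(at))
            for (r in seq_len(nrow(guard_iv)))
              inside <- inside | (at >= guard_iv[r, 1] & at <= guard_iv[r, 2])
            at <- at[!inside]
          }
          if (length(at)) {
            v <- strsplit(seqc, "", fixed = TRUE)[[1]]
            ## substitute with a uniform draw from the three other bases
            v[at] <- vapply(v[at], function(b) sample(setdiff(BASES, b), 1L),
                            character(1), USE.NAMES = FALSE)
            seqc <- paste(v, collapse = "")
          }
        }
        out[[ch]] <- seqc
      }
    }
    og <- genome
    og$chromosomes <- out
    list(outgroup = og, truth = truth)
  })
}
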