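## Shared fixtures and independent oracles. Fixtures are built once per test
## run and cached in this environment; oracles are deliberately naive R
## implementations that share no code with the package internals.

.fx <- new.env(parent = emptyenv())

## small mixed-signature cohort used by several files
fixture_cohort <- function() {
  if (!is.null(.fx$cohort)) return(.fx$cohort)
  g0 <- generate_genome(2, c(60000, 40000), gc = 0.45, seed = 101)
  specs <- list(
    cnv_spec("deletion", 30, sig_blunt()),
    cnv_spec("deletion", 40, sig_microhomology(5)),
    cnv_spec("deletion", 60, sig_filler(8)),
    cnv_spec("deletion", 50, sig_microhomology(3, extra_len = 6)),
    cnv_spec("deletion", 45, sig_microhomology(7)),
    cnv_spec("insertion", 30, sig_filler()),
    cnv_spec("insertion", 25, sig_filler()),
    cnv_spec("insertion", 28, sig_repeat_expansion("CA", 14)),
    cnv_spec("deletion", 120, sig_nahr_flanks(60, 100)),
    cnv_spec("tandem_dup", 200, sig_blunt()))
  imp <- implant_cnvs(g0, specs, strains = paste0("s", 1:4), seed = 102)
  reads <- simulate_reads(imp$strains, coverage = 12, mean_len = 105,
                          seed = 103)
  al <- map_reads(reads, imp$reference)
  sig <- detect_split_signatures(al, 25, reads = reads)
  calls <- cluster_and_filter(sig, imp$reference)
  .fx$cohort <- list(genome = imp$reference, strains = imp$strains,
                     truth = imp$truth, reads = reads, alignments = al,
                     signatures = sig, calls = calls)
  .fx$cohort
}

## ---- oracles ---------------------------------------------------------------

oracle_lcp <- function(a, b) {
  n <- min(nchar(a), nchar(b)); i <- 0L
  while (i < n && substr(a, i + 1L, i + 1L) == substr(b, i + 1L, i + 1L))
    i <- i + 1L
  i
}

oracle_rev <- function(x)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")

oracle_rc <- function(x) oracle_rev(chartr("ACGT", "TGCA", x))

## type-I microhomology by naive per-character scan
oracle_type1 <- function(segment, preceding, following, max_k = 50L) {
  min(max_k, nchar(segment),
      max(oracle_lcp(segment, following),
          oracle_lcp(oracle_rev(segment), oracle_rev(preceding))))
}

## union coverage of an insertion by exact matches >= min_match against a set
## of target strings, via a full character match matrix (naive but exact)
oracle_neighborhood_cover <- function(ins, targets, min_match) {
  iv <- strsplit(ins, "", fixed = TRUE)[[1]]
  covered <- rep(FALSE, length(iv))
  for (tg in targets) {
    tv <- strsplit(tg, "", fixed = TRUE)[[1]]
    if (length(tv) < min_match) next
    M <- outer(iv, tv, "==")
    for (d in -(length(iv) - 1L):(length(tv) - 1L)) {
      ii <- if (d < 0) (-d + 1L):length(iv) else 1L:length(iv)
      jj <- ii + d
      ok <- jj >= 1L & jj <= length(tv)
      ii <- ii[ok]; jj <- jj[ok]
      if (length(ii) < min_match) next
      m <- M[cbind(ii, jj)]
      r <- rle(m)
      ends <- cumsum(r$lengths)
      for (q in which(r$values & r$lengths >= min_match)) {
        hi <- ends[q]; lo <- hi - r$lengths[q] + 1L
        covered[ii[lo:hi]] <- TRUE
      }
    }
  }
  sum(covered)
}

## merge 1-based closed intervals (used when assembling oracle motif sets)
oracle_reduce <- function(df) {
  if (is.null(df) || nrow(df) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  df <- df[order(df$start, df$end), , drop = FALSE]
  out <- list(); cs <- df$start[1]; ce <- df$end[1]
  for (i in seq_len(nrow(df))[-1]) {
    if (df$start[i] <= ce) ce <- max(ce, df$end[i])
    else { out[[length(out) + 1L]] <- c(cs, ce); cs <- df$start[i]; ce <- df$end[i] }
  }
  out[[length(out) + 1L]] <- c(cs, ce)
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

## Z-DNA oracle: vectorized step test + rle
oracle_zdna <- function(seq, min_z = 10L) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  if (n < min_z) return(data.frame(start = integer(0), end = integer(0)))
  a <- v[-n]; b <- v[-1]
  pur <- function(x) x %in% c("A", "G")
  step <- (pur(a) != pur(b)) & !((a == "A" & b == "T") | (a == "T" & b == "A"))
  r <- rle(step)
  ends <- cumsum(r$lengths)
  out <- list()
  for (q in which(r$values & (r$lengths + 1L) >= min_z)) {
    e <- ends[q]; s <- e - r$lengths[q] + 1L
    out[[length(out) + 1L]] <- data.frame(start = s, end = e + 1L)
  }
  oracle_reduce(if (length(out)) do.call(rbind, out) else NULL)
}

## G4 oracle: qualifying G-runs by regex, all quadruples with loop gaps 1..7
oracle_g4_strand <- function(seq, ch, min_run = 3L, max_loop = 7L) {
  m <- gregexpr(paste0(ch, "{", min_run, ",}"), seq)[[1]]
  if (m[1] == -1) return(NULL)
  rs <- as.integer(m); re <- rs + attr(m, "match.length") - 1L
  R <- length(rs); out <- list()
  if (R >= 4L) for (i in 1:(R - 3)) for (j in (i + 1):(R - 2))
    for (k in (j + 1):(R - 1)) for (l in (k + 1):R) {
      picks <- c(i, j, k, l)
      gaps <- rs[picks[-1]] - re[picks[-4]] - 1L
      if (all(gaps >= 1L & gaps <= max_loop))
        out[[length(out) + 1L]] <- data.frame(start = rs[i], end = re[l])
    }
  if (length(out)) do.call(rbind, out) else NULL
}
oracle_g4 <- function(seq, min_run = 3L, max_loop = 7L) {
  list(plus = oracle_reduce(oracle_g4_strand(seq, "G", min_run, max_loop)),
       minus = oracle_reduce(oracle_g4_strand(seq, "C", min_run, max_loop)))
}

## IR/MR oracle: per (junction, spacer), arm length by vectorized stepping
oracle_ir_mr <- function(seq, mirror = FALSE, min_arm = 10L, max_spacer = 8L) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- list()
  for (s in 0:max_spacer) {
    e_idx <- seq_len(n)          # 0-based left-arm end would be e_idx
    arm <- integer(n)
    alive <- rep(TRUE, n)
    t <- 0L
    while (any(alive)) {
      ii <- which(alive)
      li <- ii - t; ri <- ii + s + 1L + t
      ok <- li >= 1L & ri <= n
      ok[ok] <- if (mirror) v[li[ok]] == v[ri[ok]] else
        v[li[ok]] == unname(comp[v[ri[ok]]])
      alive[ii[!ok]] <- FALSE
      arm[ii[ok]] <- t + 1L
      t <- t + 1L
      if (t > n) break
    }
    for (e in which(arm >= min_arm))
      out[[length(out) + 1L]] <- data.frame(start = e - arm[e] + 1L,
                                            end = e + s + arm[e])
  }
  oracle_reduce(if (length(out)) do.call(rbind, out) else NULL)
}

## DR oracle: exhaustive (unit length, spacer) with vectorized substring
## comparison over all starts
oracle_dr <- function(seq, min_unit = 10L, max_spacer = 8L) {
  n <- nchar(seq)
  out <- list()
  for (m in min_unit:floor(n / 2)) for (s in 0:max_spacer) {
    span <- 2L * m + s
    if (span > n) next
    i <- 1L:(n - span + 1L)
    eq <- substring(seq, i, i + m - 1L) ==
      substring(seq, i + m + s, i + span - 1L)
    for (w in i[eq])
      out[[length(out) + 1L]] <- data.frame(start = w, end = w + span - 1L)
  }
  oracle_reduce(if (length(out)) do.call(rbind, out) else NULL)
}

## two-sided Fisher oracle by direct hypergeometric enumeration (choose())
oracle_fisher2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  xs <- lo:hi
  pr <- choose(r1, xs) * choose(n - r1, c1 - xs) / choose(n, c1)
  sum(pr[pr <= pr[xs == a] * (1 + 1e-7)])
}

## exact two-sided rank-sum oracle by full enumeration of group assignments
oracle_wilcox2 <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  ws <- apply(combs, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
  p_le <- mean(ws <= w_obs); p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}
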