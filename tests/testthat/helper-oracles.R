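# Independent oracles and small fixture builders used across tests.
# These are deliberately naive implementations kept separate from the
# package's own code paths.

rndDna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

rcOracle <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# full Smith-Waterman local alignment score, affine gaps costing
# open + g * ext for a gap of length g (score-only, O(nm) double loop)
swLocalScore <- function(a, b, match = 1, mismatch = -2, open = 5, ext = 2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  Hprev <- numeric(m + 1); Eprev <- NULL
  Fcol <- rep(-Inf, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    Hcur <- numeric(m + 1)
    Ecur <- -Inf
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      Ecur <- max(Ecur - ext, Hcur[j] - open - ext)
      Fcol[j + 1] <- max(Fcol[j + 1] - ext, Hprev[j + 1] - open - ext)
      h <- max(0, Hprev[j] + s, Ecur, Fcol[j + 1])
      Hcur[j + 1] <- h
      if (h > best) best <- h
    }
    Hprev <- Hcur
  }
  best
}

# brute-force end-to-end ungapped read-pair placement: enumerate every
# (offset1, offset2, which-mate-forward) triple
hammingStr <- function(p, s, at) {
  pv <- strsplit(p, "")[[1]]
  sv <- strsplit(substr(s, at, at + nchar(p) - 1L), "")[[1]]
  sum(pv != sv)
}

placeOracle <- function(rp, ref, max_mm = 2L) {
  lr <- nchar(ref)
  cands <- list()
  for (fwd in 1:2) {
    pf <- if (fwd == 1L) rp$mate1 else rp$mate2
    pr <- rcOracle(if (fwd == 1L) rp$mate2 else rp$mate1)
    if (nchar(pf) > lr || nchar(pr) > lr) next
    for (o1 in seq_len(lr - nchar(pf) + 1L)) {
      d1 <- hammingStr(pf, ref, o1)
      if (d1 > max_mm) next
      for (o2 in seq_len(lr - nchar(pr) + 1L)) {
        if (o1 > o2) next
        d2 <- hammingStr(pr, ref, o2)
        if (d2 > max_mm) next
        cands[[length(cands) + 1L]] <- list(
          start1 = o1, start2 = o2, which_forward = fwd, mm = d1 + d2)
      }
    }
  }
  if (!length(cands)) return(NULL)
  mms <- vapply(cands, function(x) x$mm, numeric(1))
  best <- which(mms == min(mms))
  if (length(best) != 1L) return(NULL)
  cands[[best]]
}

# plant a copy (optionally reverse-complemented and/or mutated at exact
# positions) of `seg` into a background; returns genome string and the
# 1-based interval of each copy
plantTwoCopies <- function(bg, seg, pos1, pos2, invert2 = FALSE,
                           nmut2 = 0L) {
  seg2 <- seg
  if (nmut2 > 0L) {
    v <- strsplit(seg2, "")[[1]]
    pos <- sample(length(v), nmut2)
    v[pos] <- vapply(v[pos],
                     function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                     character(1))
    seg2 <- paste(v, collapse = "")
  }
  if (invert2) seg2 <- rcOracle(seg2)
  stopifnot(pos2 > pos1 + nchar(seg))
  g <- paste0(substr(bg, 1, pos1 - 1), seg,
              substr(bg, pos1, pos2 - nchar(seg) - 1), seg2,
              substr(bg, pos2 - nchar(seg), nchar(bg)))
  list(genome = g,
       iv1 = c(pos1, pos1 + nchar(seg) - 1L),
       iv2 = c(pos2, pos2 + nchar(seg) - 1L))
}

# overlap length of two 1-based inclusive intervals
ivOverlapLen <- function(a1, a2, b1, b2) max(0L, min(a2, b2) - max(a1, b1) + 1L)

# small simulation config used by several tests: 4 genes covering the
# intron classes (cis, ancestral-override, split direct, split inverted)
smallSimConfig <- function(seed, genome_len = 28000L, n_pairs = 0L) {
  simConfig(
    seed = seed, genome_len = genome_len,
    genes = list(
      geneSpec("nad1", 978, list(
        list(pos = 394, mode = "cis", len = 1300),
        list(pos = 669, mode = "split", ref_len = 1700, loss = 700,
             invert = TRUE),
        list(pos = 728, mode = "split", ref_len = 2000, loss = 866,
             invert = FALSE))),
      geneSpec("cox1", 1584, list(
        list(pos = 729, mode = "cis", len = 1100))),
      geneSpec("nad4", 1488, list(
        list(pos = 976, mode = "split", ref_len = 1700, loss = 640,
             invert = FALSE))),
      geneSpec("rps3", 1677, list(
        list(pos = 74, mode = "split", ref_len = 1600, loss = 580,
             invert = TRUE)))),
    repeats = data.frame(len = c(100L, 150L), identity = c(100, 95),
                         orientation = c("direct", "inverted"),
                         active = c(TRUE, FALSE), stringsAsFactors = FALSE),
    mtpt = list(count = 2L, len_range = c(150L, 600L),
                divergence = c(0, 0.03)),
    plastome_len = 8000L,
    reads = list(n_pairs = n_pairs, read_len = 150L, insert_mean = 300,
                 insert_sd = 30, error_rate = 0.001))
}

# truncated-normal mean helper: E[max(0, L - c)] for L ~ N(mu, sd)
# truncated below at lo (matches the read simulator's rejection step)
truncExpExcess <- function(c, mu, sd, lo) {
  zlo <- (lo - mu) / sd
  Z <- 1 - pnorm(zlo)
  if (c < lo) {
    # L >= lo > c always, so E[max(0, L - c)] = E[L | L >= lo] - c
    mu + sd * dnorm(zlo) / Z - c
  } else {
    z <- (c - mu) / sd
    (sd * dnorm(z) + (mu - c) * (1 - pnorm(z))) / Z
  }
}
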