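## Seed-and-extend local homology search.
##
## The engine finds exact k-mer seeds on both subject strands, clusters
## them by diagonal, performs ungapped X-drop extension (match +1,
## mismatch -2), and refines imperfect candidates with an exact local
## alignment (affine gaps: open 5, extend 2) over the bounded candidate
## region. Circular sequences are linearised with an origin extension and
## hits are re-wrapped afterwards, so features spanning the origin are
## found once. Output is deterministic given the inputs.

ALN_MATCH <- 1L
ALN_MISMATCH <- -2L
ALN_GAP_OPEN <- 5    # affine: a gap of length g costs open + g * extend
ALN_GAP_EXT <- 2

## exact k-mer seed positions shared between two strings
findSeeds <- function(q, s, k) {
  nq <- nchar(q) - k + 1L
  ns <- nchar(s) - k + 1L
  if (nq < 1L || ns < 1L)
    return(data.frame(q = integer(), s = integer()))
  qk <- substring(q, seq_len(nq), seq_len(nq) + k - 1L)
  sk <- substring(s, seq_len(ns), seq_len(ns) + k - 1L)
  idx <- split(seq_len(ns), sk)
  m <- idx[qk]
  lens <- lengths(m)
  data.frame(q = rep.int(seq_len(nq), lens), s = unlist(m, use.names = FALSE))
}

## ungapped X-drop extension to the right of position (q1, s1) exclusive.
## Returns c(extension_length, score_gained); trims to the best-scoring
## prefix so the extension always ends on a match.
extendRight <- function(qi, si, q1, s1, xdrop = 20L, max_ext = 20000L) {
  avail <- min(length(qi) - q1, length(si) - s1, max_ext)
  if (avail <= 0L) return(c(0L, 0L))
  win <- min(512L, avail)
  repeat {
    a <- qi[(q1 + 1L):(q1 + win)]
    b <- si[(s1 + 1L):(s1 + win)]
    v <- ifelse(!is.na(a) & !is.na(b) & a == b, ALN_MATCH, ALN_MISMATCH)
    pref <- cumsum(v)
    peak <- cummax(pmax(pref, 0L))
    stop_at <- which(peak - pref > xdrop)
    if (length(stop_at) || win == avail) {
      lim <- if (length(stop_at)) stop_at[1] else win
      best <- which.max(pref[seq_len(lim)])
      if (pref[best] <= 0L) return(c(0L, 0L))
      return(c(best, pref[best]))
    }
    win <- min(avail, win * 4L)
  }
}

## mirror image of extendRight, extending left of (q0, s0) exclusive
extendLeft <- function(qi, si, q0, s0, xdrop = 20L, max_ext = 20000L) {
  ext <- extendRight(rev(qi), rev(si), length(qi) - q0 + 1L,
                     length(si) - s0 + 1L, xdrop, max_ext)
  ext
}

## do two (possibly origin-wrapped) intervals on a length-L sequence share
## any position?
wrapOverlap <- function(a1, a2, b1, b2, L) {
  pieces <- function(x1, x2) {
    if (x1 <= x2) list(c(x1, x2)) else list(c(x1, L), c(1L, x2))
  }
  for (p in pieces(a1, a2)) for (q in pieces(b1, b2)) {
    if (p[1] <= q[2] && q[1] <= p[2]) return(TRUE)
  }
  FALSE
}

## normalise a hit interval found on the origin-extended sequence back to
## 1..L coordinates; start > end encodes an origin wrap
normWrap <- function(start, end, L) {
  while (start > L) { start <- start - L; end <- end - L }
  if (end > L) end <- end - L
  c(start, end)
}

#' All local alignments between two sequences
#'
#' Seed-and-extend local search on both subject strands. Hits shorter than
#' \code{min_len} alignment columns, below \code{min_ident} percent
#' identity, or scoring below a minimum score derived from
#' \code{min_len} and \code{min_ident} are dropped. Overlapping candidate
#' alignments (same strand, overlapping on both query and subject) are
#' resolved greedily by score, so each local similarity is reported once.
#' On circular sequences the search window is extended past the origin and
#' hit coordinates are re-wrapped (\code{start > end} encodes the wrap).
#'
#' @param query,subject \linkS4class{CircularSeq} objects.
#' @param min_len Minimum alignment span (columns), default 50.
#' @param min_ident Minimum percent identity, default 80.
#' @param k Seed word size, default 11.
#' @param xdrop X-drop threshold for ungapped extension, default 20.
#' @param circ_ext Origin extension length for circular inputs; default
#'   \code{min(L - 1, 5000)}.
#' @param drop_self Drop hits whose query and subject intervals coincide
#'   on the plus strand (the trivial identity diagonal of a self-vs-self
#'   search). Set by \code{\link{selfRepeats}}.
#' @return A data.frame mirroring BLAST outfmt 6 columns: q_id, s_id,
#'   pident, length, mismatch, gapopen, q_start, q_end, s_start, s_end,
#'   score, plus strand and matches. Subject coordinates are on the
#'   forward strand with \code{strand} giving the subject orientation.
#' @export
localAlignAll <- function(query, subject, min_len = 50L, min_ident = 80,
                          k = 11L, xdrop = 20L, circ_ext = NULL,
                          drop_self = FALSE) {
  stopifnot(min_len >= 1L, min_ident > 0, min_ident <= 100)
  qchr <- seqChars(query); Lq <- nchar(qchr)
  schr <- seqChars(subject); Ls <- nchar(schr)
  if (Lq == 0L || Ls == 0L) stop("empty sequence")
  extq <- if (isCircular(query))
    min(Lq - 1L, if (is.null(circ_ext)) 5000L else circ_ext) else 0L
  exts <- if (isCircular(subject))
    min(Ls - 1L, if (is.null(circ_ext)) 5000L else circ_ext) else 0L
  qext <- if (extq > 0L) paste0(qchr, substr(qchr, 1L, extq)) else qchr
  sext <- if (exts > 0L) paste0(schr, substr(schr, 1L, exts)) else schr
  qi <- dnaToInt(qext)
  Lse <- nchar(sext)
  score_min <- floor(min_len *
    (ALN_MATCH * min_ident + ALN_MISMATCH * (100 - min_ident)) / 100)

  rows <- list()
  for (strand in c("+", "-")) {
    scur <- if (strand == "-") revComp(sext) else sext
    si <- dnaToInt(scur)
    seeds <- findSeeds(qext, scur, k)
    if (!nrow(seeds)) next
    seeds$diag <- seeds$q - seeds$s
    seeds <- seeds[order(seeds$diag, seeds$q), , drop = FALSE]
    new_cluster <- c(TRUE, diff(seeds$diag) != 0L | diff(seeds$q) > 40L)
    reps <- seeds[new_cluster, , drop = FALSE]

    ## phase 1: ungapped X-drop candidates, one per seed cluster
    cand <- list()
    done_diag <- list()  # per diagonal: covered q ranges, to skip seeds
    for (i in seq_len(nrow(reps))) {
      qpos <- reps$q[i]; spos <- reps$s[i]; dg <- as.character(reps$diag[i])
      cov <- done_diag[[dg]]
      if (!is.null(cov) && any(qpos >= cov[, 1] & qpos <= cov[, 2])) next
      er <- extendRight(qi, si, qpos + k - 1L, spos + k - 1L, xdrop)
      el <- extendLeft(qi, si, qpos, spos, xdrop)
      q0 <- qpos - el[1]; q1 <- qpos + k - 1L + er[1]
      s0 <- spos - el[1]; s1 <- spos + k - 1L + er[1]
      done_diag[[dg]] <- rbind(cov, c(q0, q1))
      cand[[length(cand) + 1L]] <- c(q0 = q0, q1 = q1, s0 = s0, s1 = s1)
    }
    if (!length(cand)) next
    cm <- unique(do.call(rbind, cand))
    ## phase 2: chain collinear candidates separated by a small gap on
    ## both axes (a small indel between two ungapped blocks); the chained
    ## region is refined by the exact gapped alignment below
    cm <- cm[order(cm[, "q0"]), , drop = FALSE]
    a <- 1L
    while (a < nrow(cm)) {
      b <- a + 1L
      while (b <= nrow(cm)) {
        if (cm[b, "q0"] > cm[a, "q1"] + 50L) break
        gq <- cm[b, "q0"] - cm[a, "q1"]
        gs <- cm[b, "s0"] - cm[a, "s1"]
        if (gq > -20L && gq <= 50L && gs > -20L && gs <= 50L &&
            abs(gq - gs) <= 30L) {
          cm[a, ] <- c(min(cm[a, "q0"], cm[b, "q0"]),
                       max(cm[a, "q1"], cm[b, "q1"]),
                       min(cm[a, "s0"], cm[b, "s0"]),
                       max(cm[a, "s1"], cm[b, "s1"]))
          cm <- cm[-b, , drop = FALSE]
        } else {
          b <- b + 1L
        }
      }
      a <- a + 1L
    }
    ## phase 3: statistics (exact gapped refinement for imperfect hits)
    seen <- character(0)
    for (i in seq_len(nrow(cm))) {
      q0 <- cm[i, "q0"]; q1 <- cm[i, "q1"]
      s0 <- cm[i, "s0"]; s1 <- cm[i, "s1"]
      len0 <- q1 - q0 + 1L
      if (len0 < min_len) next
      eq <- if (q1 - q0 == s1 - s0) {
        a <- qi[q0:q1]; b <- si[s0:s1]
        !is.na(a) & !is.na(b) & a == b
      } else FALSE
      if (all(eq)) {
        stat <- list(q0 = q0, q1 = q1, s0 = s0, s1 = s1, score = len0,
                     aln_len = len0, matches = len0, mismatch = 0L,
                     gapopen = 0L)
      } else {
        stat <- refineLocal(qext, scur, q0, q1, s0, s1)
        if (is.null(stat)) next
      }
      key <- paste(stat$q0, stat$q1, stat$s0, stat$s1, sep = ":")
      if (key %in% seen) next
      seen <- c(seen, key)
      if (stat$aln_len < min_len) next
      pident <- 100 * stat$matches / stat$aln_len
      if (pident < min_ident || stat$score < score_min) next
      ## subject coordinates back to forward strand
      if (strand == "-") {
        sf0 <- Lse - stat$s1 + 1L; sf1 <- Lse - stat$s0 + 1L
      } else {
        sf0 <- stat$s0; sf1 <- stat$s1
      }
      qn <- normWrap(stat$q0, stat$q1, Lq)
      sn <- normWrap(sf0, sf1, Ls)
      rows[[length(rows) + 1L]] <- data.frame(
        q_id = seqId(query), s_id = seqId(subject), pident = pident,
        length = stat$aln_len, mismatch = stat$mismatch,
        gapopen = stat$gapopen, q_start = qn[1], q_end = qn[2],
        s_start = sn[1], s_end = sn[2], score = stat$score,
        strand = strand, matches = stat$matches, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(emptyHits())
  hits <- do.call(rbind, rows)
  ## drop duplicates created by the origin extension
  key <- with(hits, paste(q_start, q_end, s_start, s_end, strand))
  hits <- hits[!duplicated(key), , drop = FALSE]
  if (drop_self) {
    triv <- hits$strand == "+" & hits$q_start == hits$s_start &
      hits$q_end == hits$s_end
    hits <- hits[!triv, , drop = FALSE]
    if (!nrow(hits)) return(emptyHits())
  }
  ## greedy score-ordered selection: keep a hit unless it overlaps an
  ## accepted hit on BOTH axes with the same strand (same local similarity
  ## reached from a different seed)
  hits <- hits[order(-hits$score, hits$q_start, hits$s_start), , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (hits$strand[i] == hits$strand[j] &&
          wrapOverlap(hits$q_start[i], hits$q_end[i],
                      hits$q_start[j], hits$q_end[j], Lq) &&
          wrapOverlap(hits$s_start[i], hits$s_end[i],
                      hits$s_start[j], hits$s_end[j], Ls)) {
        ok <- FALSE; break
      }
    }
    keep[i] <- ok
  }
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

emptyHits <- function() {
  data.frame(q_id = character(), s_id = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             q_start = integer(), q_end = integer(), s_start = integer(),
             s_end = integer(), score = numeric(), strand = character(),
             matches = integer(), stringsAsFactors = FALSE)
}

## exact local alignment over the candidate region (ungapped bounds plus a
## margin), used to refine imperfect candidates. Returns coordinates on
## the extended working strings.
refineLocal <- function(qext, scur, q0, q1, s0, s1, margin = 30L) {
  ra <- max(1L, q0 - margin); rb <- min(nchar(qext), q1 + margin)
  rc <- max(1L, s0 - margin); rd <- min(nchar(scur), s1 + margin)
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = ALN_MATCH, mismatch = ALN_MISMATCH, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(substr(qext, ra, rb)),
    Biostrings::DNAString(substr(scur, rc, rd)),
    type = "local", substitutionMatrix = sm,
    gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT)
  sc <- Biostrings::score(pa)
  if (sc <= 0) return(NULL)
  pr <- pa@pattern@range
  sr <- pa@subject@range
  aln_len <- nchar(as.character(Biostrings::alignedPattern(pa)))
  gp <- Biostrings::nindel(pa)
  gapopen <- sum(gp@insertion[, "Length"] > 0) +
    sum(gp@deletion[, "Length"] > 0)
  matches <- Biostrings::nmatch(pa)
  list(q0 = ra + IRanges::start(pr) - 1L, q1 = ra + IRanges::end(pr) - 1L,
       s0 = rc + IRanges::start(sr) - 1L, s1 = rc + IRanges::end(sr) - 1L,
       score = sc, aln_len = aln_len, matches = matches,
       mismatch = aln_len - matches -
         sum(gp@insertion[, "Length"]) - sum(gp@deletion[, "Length"]),
       gapopen = gapopen)
}

#' Dispersed repeat pairs within a genome
#'
#' Self-vs-self local search with the trivial full-length diagonal
#' removed, symmetric duplicates (A,B)/(B,A) collapsed, and
#' self-overlapping hits (the two copies sharing genomic positions)
#' discarded. Each pair is labelled \code{direct} (same strand) or
#' \code{inverted} (opposite strands).
#'
#' @param genome A circular or linear \linkS4class{CircularSeq}.
#' @param min_len Minimum repeat length, default 50 (pairs > 50 bp pass
#'   the default alignment-span filter).
#' @param min_ident Minimum percent identity between copies, default 80.
#' @param ... Passed to \code{\link{localAlignAll}}.
#' @return data.frame with one repeat pair per row: repeat_id, a_start,
#'   a_end, b_start, b_end, orientation, rep_len, identity, score.
#' @export
selfRepeats <- function(genome, min_len = 50L, min_ident = 80, ...) {
  L <- seqLength(genome)
  if (L <= 2L * min_len)
    stop("genome must be longer than twice the minimum repeat length")
  hits <- localAlignAll(genome, genome, min_len = min_len,
                        min_ident = min_ident, drop_self = TRUE, ...)
  if (!nrow(hits)) return(emptyRepeatPairs())
  ## copies must be disjoint
  ov <- mapply(wrapOverlap, hits$q_start, hits$q_end, hits$s_start,
               hits$s_end, MoreArgs = list(L = L))
  hits <- hits[!ov, , drop = FALSE]
  if (!nrow(hits)) return(emptyRepeatPairs())
  ## canonical copy order, then collapse symmetric duplicates
  swap <- hits$q_start > hits$s_start
  tmp_s <- hits$q_start[swap]; tmp_e <- hits$q_end[swap]
  hits$q_start[swap] <- hits$s_start[swap]
  hits$q_end[swap] <- hits$s_end[swap]
  hits$s_start[swap] <- tmp_s; hits$s_end[swap] <- tmp_e
  key <- with(hits, paste(q_start, q_end, s_start, s_end, strand))
  hits <- hits[!duplicated(key), , drop = FALSE]
  hits <- hits[order(hits$q_start, hits$s_start), , drop = FALSE]
  data.frame(
    repeat_id = sprintf("R%03d", seq_len(nrow(hits))),
    a_start = hits$q_start, a_end = hits$q_end,
    b_start = hits$s_start, b_end = hits$s_end,
    orientation = ifelse(hits$strand == "+", "direct", "inverted"),
    rep_len = ifelse(hits$q_end >= hits$q_start,
                     hits$q_end - hits$q_start + 1L,
                     L - hits$q_start + 1L + hits$q_end),
    identity = hits$pident, score = hits$score,
    stringsAsFactors = FALSE)
}

emptyRepeatPairs <- function() {
  data.frame(repeat_id = character(), a_start = integer(),
             a_end = integer(), b_start = integer(), b_end = integer(),
             orientation = character(), rep_len = integer(),
             identity = numeric(), score = numeric(),
             stringsAsFactors = FALSE)
}

#' Union base count of repeat copies
#'
#' Total bases covered by any repeat copy (union of intervals, so
#' overlapping copies are not double-counted) and the percent of the
#' genome they occupy.
#'
#' @param pairs Repeat pair table from \code{\link{selfRepeats}}.
#' @param genome_len Genome length (nt).
#' @return list(bp, pct).
#' @export
repeatUnionBp <- function(pairs, genome_len) {
  if (!nrow(pairs)) return(list(bp = 0L, pct = 0))
  iv <- list()
  addIv <- function(s, e) {
    if (s <= e) list(c(s, e)) else list(c(s, genome_len), c(1L, e))
  }
  for (i in seq_len(nrow(pairs))) {
    iv <- c(iv, addIv(pairs$a_start[i], pairs$a_end[i]),
            addIv(pairs$b_start[i], pairs$b_end[i]))
  }
  ir <- IRanges::IRanges(vapply(iv, `[`, numeric(1), 1),
                         vapply(iv, `[`, numeric(1), 2))
  bp <- sum(IRanges::width(IRanges::reduce(ir)))
  list(bp = bp, pct = percentOfGenome(bp, genome_len))
}
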