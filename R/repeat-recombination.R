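## Read-pair support for repeat-mediated recombination.
##
## For every dispersed repeat pair shorter than the library insert size,
## four small references are built: the two principal (assembled)
## arrangements and the two alternative (recombined) arrangements, each
## the repeat plus flanking context. A read pair supports recombination
## when it places end-to-end on an alternative reference, fails on both
## principals, and spans the novel junction with a minimum anchor in each
## flank. Read placement is exhaustive, ungapped and end-to-end with a
## mismatch cap, mirroring an end-to-end/no-mixed/no-discordant mapping
## contract.

#' Build principal and alternative conformation references
#'
#' With copy A context \code{A_L | R_A | A_R} and copy B context
#' \code{B_L | R_B | B_R} (forward-strand), the principals are those two
#' arrangements and the alternatives are, for direct repeats,
#' \code{A_L R B_R} / \code{B_L R A_R}, and for inverted repeats,
#' \code{A_L R revcomp(B_L)} / \code{revcomp(B_R) R A_R}, with R the copy
#' A repeat sequence (copy divergence is absorbed by the mismatch cap at
#' placement time).
#'
#' @param genome A \linkS4class{CircularSeq}.
#' @param pair Repeat pair row (a_start, a_end, b_start, b_end,
#'   orientation, repeat_id); copies must not wrap the origin.
#' @param flank Flank length (default 300 nt). On a circular genome
#'   flanks wrap the origin; on a linear one they are truncated at the
#'   ends and the set is flagged.
#' @return A \linkS4class{ConformationSet}.
#' @export
buildConformations <- function(genome, pair, flank = 300L) {
  pair <- as.list(pair)
  stopifnot(flank >= 1L)
  L <- seqLength(genome)
  a1 <- pair$a_start; a2 <- pair$a_end; b1 <- pair$b_start; b2 <- pair$b_end
  if (!(1 <= a1 && a1 <= a2 && a2 <= L && 1 <= b1 && b1 <= b2 && b2 <= L))
    stop("repeat copies must lie on the genome without wrapping the origin")
  if (a1 <= b2 && b1 <= a2)
    stop("repeat copies must be disjoint")
  s <- seqChars(genome)
  truncated <- FALSE
  grab <- function(from, to) {
    if (isCircular(genome)) return(circSubstr(s, from, to))
    f2 <- max(1L, from); t2 <- min(L, to)
    if (f2 > from || t2 < to) truncated <<- TRUE
    if (f2 > t2) return("")
    substr(s, f2, t2)
  }
  A_L <- grab(a1 - flank, a1 - 1L); A_R <- grab(a2 + 1L, a2 + flank)
  B_L <- grab(b1 - flank, b1 - 1L); B_R <- grab(b2 + 1L, b2 + flank)
  RA <- substr(s, a1, a2); RB <- substr(s, b1, b2)
  direct <- !identical(pair$orientation, "inverted")
  refs <- if (direct) {
    c(principalA = paste0(A_L, RA, A_R), principalB = paste0(B_L, RB, B_R),
      alt1 = paste0(A_L, RA, B_R), alt2 = paste0(B_L, RA, A_R))
  } else {
    c(principalA = paste0(A_L, RA, A_R), principalB = paste0(B_L, RB, B_R),
      alt1 = paste0(A_L, RA, revComp(B_L)),
      alt2 = paste0(revComp(B_R), RA, A_R))
  }
  rep_len <- a2 - a1 + 1L
  junctions <- list(
    principalA = c(nchar(A_L), nchar(A_L) + rep_len),
    principalB = c(nchar(B_L), nchar(B_L) + (b2 - b1 + 1L)),
    alt1 = c(nchar(A_L), nchar(A_L) + rep_len),
    alt2 = c(nchar(if (direct) B_L else B_R),
             nchar(if (direct) B_L else B_R) + rep_len))
  new("ConformationSet",
      repeat_id = as.character(if (is.null(pair$repeat_id)) "repeat"
                               else pair$repeat_id),
      orientation = if (direct) "direct" else "inverted",
      flank = as.integer(flank), rep_len = as.integer(rep_len),
      refs = refs, junctions = junctions, truncated = truncated)
}

## Hamming distances of a pattern at every offset of a subject
hammingOffsets <- function(pattern, subject, max_mm) {
  np <- Biostrings::nchar(pattern); ns <- Biostrings::nchar(subject)
  if (np > ns) return(integer(0))
  d <- Biostrings::neditStartingAt(pattern, subject,
                                   starting.at = seq_len(ns - np + 1L),
                                   with.indels = FALSE)
  which(d <= max_mm)
}

## quick k-mer prefilter: can this mate possibly place end-to-end with
## <= 2 mismatches somewhere in `text`? Non-overlapping exact probes: two
## mismatches can break at most two of them.
readMayHit <- function(mate, text, probe = 20L) {
  n <- nchar(mate)
  if (n < 3L * probe) return(TRUE)
  starts <- seq(1L, n - probe + 1L, by = probe)
  for (st in starts) {
    if (grepl(substr(mate, st, st + probe - 1L), text, fixed = TRUE))
      return(TRUE)
  }
  FALSE
}

#' Place a read pair on a reference, end-to-end and ungapped
#'
#' Tries every offset for both mate assignments (mate1 forward +
#' reverse-complemented mate2, and the swap). A placement is accepted
#' only if both mates align full-length with at most \code{max_mismatch}
#' mismatches each, in forward-reverse orientation with ordered mate
#' intervals. The unique best-scoring placement (fewest total
#' mismatches) is returned; ties or no valid placement give NULL.
#'
#' @param rp list or row with mate1 and mate2 (DNA strings).
#' @param ref Reference DNA string.
#' @param max_mismatch Per-mate mismatch cap, default 2.
#' @return NULL, or list(start1, start2, which_forward, mm, frag_start,
#'   frag_end).
#' @export
placePair <- function(rp, ref, max_mismatch = 2L) {
  rp <- as.list(rp)
  refd <- Biostrings::DNAString(ref)
  m1 <- Biostrings::DNAString(rp$mate1)
  m2 <- Biostrings::DNAString(rp$mate2)
  cands <- list()
  for (fwd_mate in 1:2) {
    pf <- if (fwd_mate == 1L) m1 else m2
    pr <- Biostrings::reverseComplement(if (fwd_mate == 1L) m2 else m1)
    of <- hammingOffsets(pf, refd, max_mismatch)
    if (!length(of)) next
    or <- hammingOffsets(pr, refd, max_mismatch)
    if (!length(or)) next
    df <- Biostrings::neditStartingAt(pf, refd, starting.at = of,
                                      with.indels = FALSE)
    dr <- Biostrings::neditStartingAt(pr, refd, starting.at = or,
                                      with.indels = FALSE)
    for (i in seq_along(of)) for (j in seq_along(or)) {
      if (of[i] > or[j]) next  # forward mate must be leftmost
      cands[[length(cands) + 1L]] <- list(
        start1 = of[i], start2 = or[j], which_forward = fwd_mate,
        mm = df[i] + dr[j], frag_start = of[i],
        frag_end = or[j] + Biostrings::nchar(pr) - 1L)
    }
  }
  if (!length(cands)) return(NULL)
  mms <- vapply(cands, function(x) x$mm, numeric(1))
  best <- which(mms == min(mms))
  if (length(best) != 1L) return(NULL)  # ambiguous placement
  cands[[best]]
}

#' Count read pairs supporting the alternative conformations
#'
#' A pair supports alternative k when it places on alt_k, fails to place
#' on BOTH principal references, and its outer fragment span covers at
#' least \code{min_anchor} nt in each of alt_k's two flanks (so the pair
#' genuinely spans the novel junction). Pairs are deduplicated by id and
#' counted at most once per repeat.
#'
#' @param reads data.frame(id, mate1, mate2).
#' @param conf A \linkS4class{ConformationSet}.
#' @param max_mismatch Per-mate mismatch cap, default 2.
#' @param min_anchor Minimum flank anchor (nt), default 5.
#' @return list: repeat_id, n_alt1, n_alt2, n_total, supporting (ids).
#' @export
countSupport <- function(reads, conf, max_mismatch = 2L, min_anchor = 5L) {
  if (anyDuplicated(reads$id)) stop("duplicate read ids in input")
  refs <- conf@refs
  jn <- conf@junctions
  text <- paste(refs, collapse = "NNNN")
  n1 <- 0L; n2 <- 0L; sup <- character(0)
  for (i in seq_len(nrow(reads))) {
    rp <- list(id = reads$id[i], mate1 = reads$mate1[i],
               mate2 = reads$mate2[i])
    if (!readMayHit(rp$mate1, text) && !readMayHit(revComp(rp$mate1), text))
      next
    if (!is.null(placePair(rp, refs[["principalA"]], max_mismatch))) next
    if (!is.null(placePair(rp, refs[["principalB"]], max_mismatch))) next
    for (k in c("alt1", "alt2")) {
      p <- placePair(rp, refs[[k]], max_mismatch)
      if (is.null(p)) next
      j <- jn[[k]]
      ref_len <- nchar(refs[[k]])
      left_ok <- p$frag_start <= j[1] - min_anchor + 1L && j[1] >= min_anchor
      right_ok <- p$frag_end >= j[2] + min_anchor &&
        ref_len - j[2] >= min_anchor
      if (left_ok && right_ok) {
        if (k == "alt1") n1 <- n1 + 1L else n2 <- n2 + 1L
        sup <- c(sup, rp$id)
        break  # a pair counts at most once per repeat
      }
    }
  }
  list(repeat_id = conf@repeat_id, n_alt1 = n1, n_alt2 = n2,
       n_total = n1 + n2, supporting = sup)
}

#' Screen all eligible repeat pairs for recombination support
#'
#' Repeats with \code{rep_len < insert_cap} (the library insert size; a
#' pair cannot span the junction of a longer repeat) are assessed with
#' \code{\link{buildConformations}} and \code{\link{countSupport}}.
#'
#' @param genome A \linkS4class{CircularSeq}.
#' @param repeats Repeat table from \code{\link{selfRepeats}} (or a truth
#'   table with the same columns).
#' @param reads data.frame(id, mate1, mate2).
#' @param insert_cap Insert-size eligibility cut-off, default 350 nt.
#' @param flank Flank length, default 300 nt.
#' @param max_mismatch,min_anchor See \code{\link{countSupport}}.
#' @return data.frame: repeat_id, copy coordinates, orientation, rep_len,
#'   identity, n_alt1, n_alt2, n_total, supporting (comma-separated ids);
#'   attribute "n_active" counts repeats with n_total >= 1.
#' @export
screenRepeats <- function(genome, repeats, reads, insert_cap = 350L,
                          flank = 300L, max_mismatch = 2L, min_anchor = 5L) {
  el <- repeats[repeats$rep_len < insert_cap, , drop = FALSE]
  rows <- lapply(seq_len(nrow(el)), function(i) {
    pair <- as.list(el[i, ])
    conf <- buildConformations(genome, pair, flank = flank)
    cs <- countSupport(reads, conf, max_mismatch = max_mismatch,
                       min_anchor = min_anchor)
    data.frame(repeat_id = pair$repeat_id, a_start = pair$a_start,
               a_end = pair$a_end, b_start = pair$b_start,
               b_end = pair$b_end, orientation = pair$orientation,
               rep_len = pair$rep_len, identity = pair$identity,
               n_alt1 = cs$n_alt1, n_alt2 = cs$n_alt2,
               n_total = cs$n_total,
               supporting = paste(cs$supporting, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(repeat_id = character(), a_start = integer(),
               a_end = integer(), b_start = integer(), b_end = integer(),
               orientation = character(), rep_len = integer(),
               identity = numeric(), n_alt1 = integer(), n_alt2 = integer(),
               n_total = integer(), supporting = character(),
               stringsAsFactors = FALSE)
  attr(out, "n_active") <- sum(out$n_total >= 1L)
  out
}
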