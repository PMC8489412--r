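## Mitochondrial plastid insertions (MTPTs).
##
## Plastid-derived segments in the mitogenome are found by local homology
## search against the plastome (> 100 bp at >= 80 percent identity by
## default), hits overlapping on mitogenome coordinates are merged into
## regions, and the plastid genes each region carries are classified as
## intact or pseudogenised (truncation, frameshift, internal stop).

#' Find plastid-derived insertions in a mitogenome
#'
#' Local alignments of the mitogenome against the plastome are filtered
#' by length and identity; hits overlapping on mitogenome coordinates are
#' merged into regions (union interval, length-weighted mean identity).
#' Adjacent but non-overlapping hits remain distinct regions.
#'
#' @param mito,plastome \linkS4class{CircularSeq} objects.
#' @param min_len Minimum insertion length, default 101 (i.e. > 100 bp).
#' @param min_ident Minimum percent identity, default 80.
#' @return list: regions (data.frame region_id, mito_start, mito_end,
#'   length, identity, n_hits, p_start, p_end, strand), hits (the
#'   underlying alignment table with a region_id column), and summary
#'   (n_regions, len_range, ident_range, coverage_bp, coverage_pct).
#' @export
findMtpt <- function(mito, plastome, min_len = 101L, min_ident = 80) {
  L <- seqLength(mito)
  hits <- localAlignAll(mito, plastome, min_len = min_len,
                        min_ident = min_ident)
  if (!nrow(hits)) {
    return(list(regions = data.frame(), hits = hits,
                summary = list(n_regions = 0L, len_range = c(NA, NA),
                               ident_range = c(NA, NA), coverage_bp = 0L,
                               coverage_pct = 0)))
  }
  ## origin-wrapping hits are kept as their own regions; merging operates
  ## on the non-wrapping ones
  wraps <- hits$q_start > hits$q_end
  ir <- IRanges::IRanges(hits$q_start[!wraps], hits$q_end[!wraps])
  red <- IRanges::reduce(ir, min.gapwidth = 0L, with.revmap = TRUE)
  idx_nw <- which(!wraps)
  region_rows <- lapply(seq_along(red), function(r) {
    members <- idx_nw[S4Vectors::mcols(red)$revmap[[r]]]
    h <- hits[members, , drop = FALSE]
    best <- members[which.max(h$score)]
    data.frame(mito_start = IRanges::start(red)[r],
               mito_end = IRanges::end(red)[r],
               length = IRanges::width(red)[r],
               identity = sum(h$pident * h$length) / sum(h$length),
               n_hits = length(members),
               p_start = hits$s_start[best], p_end = hits$s_end[best],
               strand = hits$strand[best],
               members = I(list(members)), stringsAsFactors = FALSE)
  })
  for (wi in which(wraps)) {
    h <- hits[wi, , drop = FALSE]
    region_rows[[length(region_rows) + 1L]] <- data.frame(
      mito_start = h$q_start, mito_end = h$q_end,
      length = L - h$q_start + 1L + h$q_end,
      identity = h$pident, n_hits = 1L, p_start = h$s_start,
      p_end = h$s_end, strand = h$strand, members = I(list(wi)),
      stringsAsFactors = FALSE)
  }
  regions <- do.call(rbind, region_rows)
  regions <- regions[order(regions$mito_start), , drop = FALSE]
  regions$region_id <- sprintf("MTPT%02d", seq_len(nrow(regions)))
  hits$region_id <- NA_character_
  for (r in seq_len(nrow(regions))) {
    hits$region_id[regions$members[[r]]] <- regions$region_id[r]
  }
  cov <- sum(regions$length)  # merged => disjoint by construction
  regions <- regions[, c("region_id", "mito_start", "mito_end", "length",
                         "identity", "n_hits", "p_start", "p_end",
                         "strand", "members")]
  rownames(regions) <- NULL
  list(regions = regions, hits = hits,
       summary = list(n_regions = nrow(regions),
                      len_range = range(regions$length),
                      ident_range = range(regions$identity),
                      coverage_bp = cov,
                      coverage_pct = percentOfGenome(cov, L)))
}

## translate a transferred gene copy and classify its functional status
classifyTransfer <- function(gene_cds, mito_seq, intact_cover = 0.95) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = ALN_MATCH, mismatch = ALN_MISMATCH, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(gene_cds), Biostrings::DNAString(mito_seq),
    type = "global-local", substitutionMatrix = sm,
    gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  both <- ap != "-" & as_ != "-"
  coverage <- sum(both) / nchar(gene_cds)
  if (coverage < intact_cover)
    return(list(status = "pseudo_truncated", coverage = coverage))
  core <- range(which(both))
  gapcol <- (ap == "-" | as_ == "-")
  gapcol <- gapcol[core[1]:core[2]]
  if (any(gapcol)) {
    runs <- rle(gapcol)
    if (any(runs$lengths[runs$values] %% 3L != 0L))
      return(list(status = "pseudo_frameshift", coverage = coverage))
  }
  ## translate the mito copy in the gene's reading frame
  p0 <- sum(ap[seq_len(core[1])] != "-")  # first aligned CDS position
  copy <- paste(as_[core[1]:core[2]][as_[core[1]:core[2]] != "-"],
                collapse = "")
  lead <- (3L - ((p0 - 1L) %% 3L)) %% 3L
  copy <- substr(copy, lead + 1L, nchar(copy))
  ncod <- nchar(copy) %/% 3L
  if (ncod >= 2L) {
    copy <- substr(copy, 1L, ncod * 3L)
    aa <- suppressWarnings(as.character(
      Biostrings::translate(Biostrings::DNAString(copy))))
    stops <- gregexpr("\\*", aa)[[1]]
    internal <- stops[stops > 0 & stops < nchar(aa)]
    ## a stop in the final codon position is the gene's own terminator
    if (length(internal))
      return(list(status = "pseudo_internal_stop", coverage = coverage))
  }
  list(status = "intact", coverage = coverage)
}

#' Functional status of plastid genes inside MTPT regions
#'
#' For each plastid gene overlapping a region's plastid coordinates, the
#' transferred copy is intact iff it covers at least \code{intact_cover}
#' of the gene, its alignment contains no indel run of length not
#' divisible by 3 within the covered core, and the in-frame translation
#' has no internal stop; otherwise the first failing rule names the
#' pseudogene class (pseudo_truncated, pseudo_frameshift,
#' pseudo_internal_stop).
#'
#' @param mtpt Result of \code{\link{findMtpt}}.
#' @param plastid_models List of \linkS4class{GeneModel} on the plastome.
#' @param mito,plastome The sequences used for \code{\link{findMtpt}}.
#' @param intact_cover Coverage threshold for "intact", default 0.95.
#' @return data.frame: region_id, gene, status, coverage.
#' @export
callMtptGenes <- function(mtpt, plastid_models, mito, plastome,
                          intact_cover = 0.95) {
  pid <- seqId(plastome)
  for (m in plastid_models) {
    if (any(vapply(m@exons, function(e) e@seq_id, character(1)) != pid))
      stop(sprintf("gene %s is not annotated on plastome %s", m@gene, pid))
  }
  regions <- mtpt$regions
  out <- list()
  for (r in seq_len(nrow(regions))) {
    rg <- regions[r, ]
    member_hits <- mtpt$hits[mtpt$hits$region_id == rg$region_id, ,
                             drop = FALSE]
    mseq <- extractInterval(mito, featureInterval(
      seqId(mito), rg$mito_start, rg$mito_end, strand = "+"))
    for (m in plastid_models) {
      gstart <- min(vapply(m@exons, function(e) e@start, integer(1)))
      gend <- max(vapply(m@exons, function(e) e@end, integer(1)))
      touches <- any(member_hits$s_start <= gend &
                       member_hits$s_end >= gstart)
      if (!touches) next
      cds <- splicedSeq(plastome, m)
      ori <- if (rg$strand == "-") revComp(mseq) else mseq
      cl <- classifyTransfer(cds, ori, intact_cover)
      out[[length(out) + 1L]] <- data.frame(
        region_id = rg$region_id, gene = m@gene, status = cl$status,
        coverage = cl$coverage, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(region_id = character(), gene = character(),
                      status = character(), coverage = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
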