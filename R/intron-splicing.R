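## Cis/trans classification of mitochondrial introns.
##
## An intron is named gene + "i" + the reference-CDS nucleotide position
## after which it is inserted (e.g. nad1i728). Classification works from
## exon placements on the genome: flanking exons that are adjacent, on one
## strand, in transcription order and separated by at most a plausible
## intron length are cis-spliced; anything else (strand flip, order
## violation, excessive separation) is trans-spliced. Introns that are
## trans-spliced in the common ancestor of seed plants are forced to trans
## even when their exons happen to be contiguous, because a shift back
## from trans- to cis-splicing is considered implausible.

#' Built-in intron registry
#'
#' Ships the mitochondrial introns this package refers to by name: the
#' five introns trans-spliced in the common ancestor of seed plants
#' (nad1i394, nad1i669, nad2i542, nad5i1455, nad5i1477, flagged
#' \code{ancestral_trans}), the sole group I intron cox1i729, and the
#' further named group II introns cox2i373, nad1i728, nad2i156, nad2i709,
#' nad4i976 and rps3i74. The remaining canonical angiosperm introns are
#' user-supplied via \code{\link{readIntronRegistry}} to avoid inventing
#' names. Insertion positions refer to the user's reference CDS.
#'
#' @return data.frame: name, gene, insertion_pos, group, ancestral_trans.
#' @export
intronRegistry <- function() {
  data.frame(
    name = c("nad1i394", "nad1i669", "nad2i542", "nad5i1455", "nad5i1477",
             "cox1i729", "cox2i373", "nad1i728", "nad2i156", "nad2i709",
             "nad4i976", "rps3i74"),
    gene = c("nad1", "nad1", "nad2", "nad5", "nad5",
             "cox1", "cox2", "nad1", "nad2", "nad2", "nad4", "rps3"),
    insertion_pos = c(394L, 669L, 542L, 1455L, 1477L,
                      729L, 373L, 728L, 156L, 709L, 976L, 74L),
    group = c("II", "II", "II", "II", "II",
              "I", "II", "II", "II", "II", "II", "II"),
    ancestral_trans = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                        FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Read an intron registry from TSV
#'
#' Columns: name, gene, insertion_pos, group, ancestral_trans.
#' @param path TSV file.
#' @return data.frame in registry layout.
#' @export
readIntronRegistry <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "gene", "insertion_pos", "group", "ancestral_trans")
  if (!all(need %in% colnames(df)))
    stop("registry must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$name)) stop("duplicate intron names in registry")
  df$insertion_pos <- as.integer(df$insertion_pos)
  df$ancestral_trans <- as.logical(df$ancestral_trans)
  stopifnot(all(df$insertion_pos >= 1L))
  df
}

#' Name an intron from its upstream exon
#'
#' The intron inserted after reference-CDS nucleotide \code{cds_end} of
#' \code{gene} is called \code{gene + "i" + cds_end}.
#'
#' @param gene Gene name.
#' @param cds_end Last reference-CDS position of the upstream exon.
#' @return The intron name, e.g. "nad1i728".
#' @examples
#' nameIntron("cox1", 729)
#' @export
nameIntron <- function(gene, cds_end) {
  stopifnot(cds_end >= 1)
  paste0(gene, "i", as.integer(cds_end))
}

#' Locate the exons of a gene on a genome
#'
#' Aligns the reference CDS against both genome strands and chains hits
#' into placements that are colinear in the CDS (each CDS position covered
#' at most once, greedy by score). Placements are returned sorted by CDS
#' start and indexed in transcript order.
#'
#' @param gene Gene name.
#' @param cds Reference CDS (DNA string, >= 60 nt).
#' @param genome A \linkS4class{CircularSeq}.
#' @param min_len Minimum exon hit span, default 15 nt.
#' @param min_ident Minimum percent identity, default 80.
#' @param min_cover Minimum fraction of the CDS that must be covered,
#'   default 0.5; below this the gene is reported as not found.
#' @return data.frame of exon placements: gene, exon_index, cds_start,
#'   cds_end, g_start, g_end, strand, identity.
#' @export
locateExons <- function(gene, cds, genome, min_len = 15L, min_ident = 80,
                        min_cover = 0.5) {
  cds <- normalizeDna(cds, what = gene)
  if (nchar(cds) < 60L) stop("reference CDS must be >= 60 nt")
  q <- circularSeq(paste0(gene, "_cds"), cds, circular = FALSE)
  hits <- localAlignAll(q, genome, min_len = min_len, min_ident = min_ident)
  if (!nrow(hits)) stop(sprintf("gene %s not found in %s", gene,
                                seqId(genome)))
  hits <- hits[order(-hits$score), , drop = FALSE]
  taken <- integer(0)  # CDS positions already covered
  sel <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    span <- hits$q_start[i]:hits$q_end[i]
    if (!any(span %in% taken)) {
      sel[i] <- TRUE
      taken <- c(taken, span)
    }
  }
  hits <- hits[sel, , drop = FALSE]
  if (length(taken) < min_cover * nchar(cds))
    stop(sprintf("gene %s not found: only %d of %d CDS nt covered",
                 gene, length(taken), nchar(cds)))
  hits <- hits[order(hits$q_start), , drop = FALSE]
  data.frame(gene = gene, exon_index = seq_len(nrow(hits)),
             cds_start = hits$q_start, cds_end = hits$q_end,
             g_start = hits$s_start, g_end = hits$s_end,
             strand = hits$strand, identity = hits$pident,
             stringsAsFactors = FALSE)
}

## circular gap between two exons in transcription direction of the
## upstream exon; NA when the strands differ. Returns the number of
## intervening bases (>= 0 after circular wrap).
exonGap <- function(up, down, L, circular) {
  if (up$strand != down$strand) return(NA_integer_)
  gap <- if (up$strand == "+") down$g_start - up$g_end - 1L
         else up$g_start - down$g_end - 1L
  if (gap < 0L) {
    if (!circular) return(NA_integer_)
    gap <- gap + L
  }
  gap
}

#' Classify introns as cis- or trans-spliced
#'
#' For each consecutive exon pair (in CDS order) of each gene, the raw
#' adjacency is \code{contiguous} when the exons lie on the same strand,
#' follow each other in transcription direction (circular wrap allowed)
#' and are separated by at most \code{max_intron_len} nt; otherwise it is
#' \code{split}. The mode is \code{trans} when the adjacency is split OR
#' the registry marks the intron as ancestrally trans-spliced
#' (\code{override_applied} is set in the latter, contiguous case), else
#' \code{cis}.
#'
#' @param placements Exon placements from \code{\link{locateExons}}
#'   (several genes may be rbind-ed).
#' @param genome The \linkS4class{CircularSeq} the placements refer to
#'   (supplies length and circularity).
#' @param registry Intron registry, default \code{\link{intronRegistry}()}.
#' @param max_intron_len Maximum plausible cis intron length, default
#'   10000 nt (plant mitochondrial cis introns are at most a few kb).
#' @return data.frame of intron calls: intron, gene, insertion_pos, mode,
#'   raw_adjacency, override_applied, genome_gap (NA when split), group,
#'   plus flanking-exon coordinates.
#' @export
classifyIntrons <- function(placements, genome, registry = intronRegistry(),
                            max_intron_len = 10000L) {
  L <- seqLength(genome)
  circular <- isCircular(genome)
  out <- list()
  for (g in unique(placements$gene)) {
    px <- placements[placements$gene == g, , drop = FALSE]
    px <- px[order(px$cds_start), , drop = FALSE]
    if (nrow(px) < 2L) next
    for (i in seq_len(nrow(px) - 1L)) {
      up <- as.list(px[i, ]); down <- as.list(px[i + 1L, ])
      if (wrapOverlap(up$g_start, up$g_end, down$g_start, down$g_end, L))
        stop(sprintf(
          "malformed annotation: consecutive exons of %s overlap on the genome",
          g))
      gap <- exonGap(up, down, L, circular)
      contiguous <- !is.na(gap) && gap >= 0L && gap <= max_intron_len
      name <- nameIntron(g, up$cds_end)
      reg <- registry[match(name, registry$name), , drop = FALSE]
      ancestral <- isTRUE(reg$ancestral_trans[1])
      override <- contiguous && ancestral
      mode <- if (!contiguous || ancestral) "trans" else "cis"
      out[[length(out) + 1L]] <- data.frame(
        intron = name, gene = g, insertion_pos = up$cds_end,
        mode = mode,
        raw_adjacency = if (contiguous) "contiguous" else "split",
        override_applied = override,
        genome_gap = if (contiguous) gap else NA_integer_,
        group = if (nrow(reg) && !is.na(reg$group[1])) reg$group[1]
                else NA_character_,
        up_start = up$g_start, up_end = up$g_end, up_strand = up$strand,
        down_start = down$g_start, down_end = down$g_end,
        down_strand = down$strand, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map the breakpoints of a trans-spliced intron against a cis reference
#'
#' Aligns the reference (cis-spliced) intron sequence against the genomic
#' windows flanking the two split exons: downstream of the upstream exon
#' (in its transcription direction) for the retained 5' intron end, and
#' upstream of the downstream exon for the retained 3' end. A retained end
#' must contain the reference intron's first (respectively last) base
#' within the extension tolerance and abut the exon. The lost middle is
#' the reference length minus the two retained ends.
#'
#' @param call One row of \code{\link{classifyIntrons}} output (as a list
#'   or one-row data.frame) with mode "trans".
#' @param ref_intron Reference intron DNA string from the cis-spliced
#'   relative.
#' @param genome The \linkS4class{CircularSeq} carrying the split exons.
#' @param min_ident Minimum percent identity for a retained end, default 80.
#' @param tol Extension tolerance (nt) when testing whether a hit reaches
#'   the intron end / the exon boundary, default 15.
#' @return list: retained5_len, retained3_len, lost_mid_len, found (TRUE
#'   unless neither end was recovered), plus the windows' hit tables.
#' @export
mapBreakpoints <- function(call, ref_intron, genome, min_ident = 80,
                           tol = 15L) {
  call <- as.list(call)
  if (!identical(call$mode, "trans"))
    stop("mapBreakpoints requires a trans-spliced intron call")
  ref_intron <- normalizeDna(ref_intron, what = "reference intron")
  rl <- nchar(ref_intron)
  W <- rl + 500L
  L <- seqLength(genome)
  s <- seqChars(genome)
  grab <- function(from, to, rc) {
    from2 <- from; to2 <- to
    if (!isCircular(genome)) {
      from2 <- max(1L, from); to2 <- min(L, to)
      if (from2 > to2) return("")
    }
    x <- circSubstr(s, from2, to2)
    if (rc) revComp(x) else x
  }
  w5 <- if (call$up_strand == "+")
    grab(call$up_end + 1L, call$up_end + W, FALSE)
  else grab(call$up_start - W, call$up_start - 1L, TRUE)
  w3 <- if (call$down_strand == "+")
    grab(call$down_start - W, call$down_start - 1L, FALSE)
  else grab(call$down_end + 1L, call$down_end + W, TRUE)

  qry <- circularSeq("ref_intron", ref_intron, circular = FALSE)
  alnWin <- function(w) {
    if (nchar(w) < 20L) return(emptyHits())
    localAlignAll(qry, circularSeq("win", w, circular = FALSE),
                  min_len = 30L, min_ident = min_ident)
  }
  h5 <- alnWin(w5)
  h3 <- alnWin(w3)
  ## 5' end: hit starts at the intron's first base and right after the exon
  ok5 <- h5[h5$q_start <= 1L + tol & h5$s_start <= 1L + tol &
              h5$strand == "+", , drop = FALSE]
  retained5 <- if (nrow(ok5)) max(ok5$q_end) else 0L
  ## 3' end: hit reaches the intron's last base and abuts the exon (window
  ## end)
  W3 <- nchar(w3)
  ok3 <- h3[h3$q_end >= rl - tol & h3$s_end >= W3 - tol &
              h3$strand == "+", , drop = FALSE]
  retained3 <- if (nrow(ok3)) rl - min(ok3$q_start) + 1L else 0L
  list(intron = call$intron,
       retained5_len = as.integer(retained5),
       retained3_len = as.integer(retained3),
       lost_mid_len = max(0L, rl - as.integer(retained5) -
                            as.integer(retained3)),
       ref_len = rl,
       found = retained5 > 0L || retained3 > 0L,
       hits5 = h5, hits3 = h3)
}
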