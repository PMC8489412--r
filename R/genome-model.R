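## Sequence/annotation accessors and FASTA/GFF3 I/O.
## Coordinates are 1-based inclusive everywhere; conversion to other
## conventions happens only inside the I/O wrappers.

#' @rdname circularSeq
#' @param x A CircularSeq.
#' @export
seqId <- function(x) x@id

#' @rdname circularSeq
#' @export
seqLength <- function(x) nchar(x@seq)

#' @rdname circularSeq
#' @export
isCircular <- function(x) x@circular

#' @rdname circularSeq
#' @export
seqChars <- function(x) x@seq

#' Length spanned by a FeatureInterval
#'
#' For a non-wrapping interval this is end - start + 1; for an
#' origin-wrapping interval (start > end on a circular sequence of length
#' L) it is L - start + 1 + end.
#'
#' @param iv A \linkS4class{FeatureInterval}.
#' @param L Length of the sequence the interval lives on.
#' @return Integer length, always >= 1.
#' @export
intervalLength <- function(iv, L) {
  if (iv@start <= iv@end) iv@end - iv@start + 1L else L - iv@start + 1L + iv@end
}

#' Extract the sequence of an interval, strand- and origin-aware
#'
#' Returns residues \code{start..end} inclusive; on strand "-" the reverse
#' complement is returned. \code{start > end} wraps the origin
#' (suffix + prefix) and is an error on linear sequences.
#'
#' @param seq A \linkS4class{CircularSeq}.
#' @param iv A \linkS4class{FeatureInterval} on that sequence.
#' @return A DNA string.
#' @examples
#' s <- circularSeq("s", "ACGTT", circular = TRUE)
#' extractInterval(s, featureInterval("s", 2, 4))        # "CGT"
#' extractInterval(s, featureInterval("s", 5, 1))        # "TA"
#' extractInterval(s, featureInterval("s", 2, 4, "-"))   # "ACG"
#' @export
extractInterval <- function(seq, iv) {
  if (iv@seq_id != seq@id)
    stop(sprintf("interval seq_id '%s' does not match sequence '%s'",
                 iv@seq_id, seq@id))
  L <- seqLength(seq)
  if (iv@start > L || iv@end > L)
    stop(sprintf("interval %d-%d outside sequence of length %d",
                 iv@start, iv@end, L))
  s <- if (iv@start <= iv@end) {
    substr(seq@seq, iv@start, iv@end)
  } else {
    if (!seq@circular)
      stop("origin wrap (start > end) requested on a non-circular sequence")
    paste0(substr(seq@seq, iv@start, L), substr(seq@seq, 1L, iv@end))
  }
  if (iv@strand == "-") revComp(s) else s
}

## circular substring by raw coordinates (1-based, may exceed L or be < 1)
circSubstr <- function(seq, from, to) {
  L <- nchar(seq)
  idx <- ((seq.int(from, to) - 1L) %% L) + 1L
  paste(strsplit(seq, "")[[1]][idx], collapse = "")
}

#' Read a (multi-)FASTA file into CircularSeq objects
#'
#' Residues are upper-cased and U is mapped to T so RNA-style FASTA is
#' accepted; any character outside {A,C,G,T,N} is rejected with its
#' position. Circularity is not encoded in FASTA, so it is supplied by the
#' caller.
#'
#' @param path FASTA file.
#' @param circular Logical, recycled over records.
#' @return A named list of \linkS4class{CircularSeq}.
#' @export
readFasta <- function(path, circular = FALSE) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  circular <- rep_len(circular, length(set))
  out <- lapply(seq_along(set), function(i) {
    circularSeq(ids[i], normalizeDna(as.character(set[[i]]), what = ids[i]),
                circular = circular[i])
  })
  names(out) <- ids
  out
}

#' Write CircularSeq objects to FASTA (60-column wrap)
#'
#' @param seqs A CircularSeq or list of them.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
writeFasta <- function(seqs, path) {
  if (is(seqs, "CircularSeq")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, seqChars, character(1)))
  names(set) <- vapply(seqs, seqId, character(1))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects exon features carrying attributes \code{gene} (gene name),
#' \code{part} (integer transcript order of the exon, 1-based) and
#' \code{product_kind}. Transcript order is taken from \code{part}, never
#' from genome order, because trans-spliced genes violate genome order.
#'
#' @param path GFF3 file.
#' @param seqs List of \linkS4class{CircularSeq} the annotation refers to.
#' @return Named list of \linkS4class{GeneModel}.
#' @export
readAnnotation <- function(path, seqs) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon features in ", path)
  known <- vapply(seqs, seqId, character(1))
  sid <- as.character(GenomicRanges::seqnames(gr))
  if (any(!sid %in% known))
    stop("exon references unknown sequence: ",
         paste(unique(setdiff(sid, known)), collapse = ", "))
  need <- c("gene", "part")
  mc <- S4Vectors::mcols(gr)
  if (!all(need %in% colnames(mc)))
    stop("exon features must carry 'gene' and 'part' attributes")
  genes <- split(seq_along(gr), as.character(mc$gene))
  out <- lapply(names(genes), function(g) {
    i <- genes[[g]]
    part <- as.integer(as.character(mc$part[i]))
    if (anyDuplicated(part))
      stop(sprintf("gene %s: duplicate exon order index %d", g,
                   part[duplicated(part)][1]))
    if (!setequal(part, seq_along(part))) {
      miss <- setdiff(seq_along(part), part)[1]
      stop(sprintf("gene %s: exon order index %d missing", g, miss))
    }
    i <- i[order(part)]
    pk <- if ("product_kind" %in% colnames(mc))
      as.character(mc$product_kind[i[1]]) else "protein"
    pseudo <- if ("pseudo" %in% colnames(mc))
      isTRUE(as.logical(mc$pseudo[i[1]])) else FALSE
    exons <- lapply(i, function(j) {
      featureInterval(sid[j], GenomicRanges::start(gr)[j],
                      GenomicRanges::end(gr)[j],
                      strand = as.character(GenomicRanges::strand(gr)[j]),
                      kind = "exon", attributes = list(gene = g))
    })
    geneModel(g, exons, product_kind = pk, pseudo = pseudo)
  })
  names(out) <- names(genes)
  out
}

#' Write gene models to GFF3
#'
#' Emits one exon feature per exon with attributes \code{gene},
#' \code{part} (transcript order) and \code{product_kind}; the
#' \code{readAnnotation}/\code{writeAnnotation} pair round-trips.
#'
#' @param models List of \linkS4class{GeneModel}.
#' @param path Output GFF3 file.
#' @return Invisibly, the path.
#' @export
writeAnnotation <- function(models, path) {
  rows <- do.call(rbind, lapply(models, function(m) {
    do.call(rbind, lapply(seq_along(m@exons), function(k) {
      e <- m@exons[[k]]
      data.frame(seqid = e@seq_id, start = e@start, end = e@end,
                 strand = e@strand, gene = m@gene, part = k,
                 product_kind = m@product_kind, pseudo = m@pseudo,
                 stringsAsFactors = FALSE)
    }))
  }))
  gr <- GenomicRanges::GRanges(rows$seqid,
                               IRanges::IRanges(rows$start, rows$end),
                               strand = rows$strand)
  gr$type <- "exon"
  gr$source <- "mitoshift"
  gr$gene <- rows$gene
  gr$part <- rows$part
  gr$product_kind <- rows$product_kind
  gr$pseudo <- rows$pseudo
  gr$ID <- sprintf("%s.exon%d", rows$gene, rows$part)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Spliced CDS of a gene model on a genome
#'
#' Concatenates the exon sequences in transcript order (strand-aware).
#' @param seq A \linkS4class{CircularSeq}.
#' @param model A \linkS4class{GeneModel}.
#' @return DNA string of the spliced transcript.
#' @export
splicedSeq <- function(seq, model) {
  paste(vapply(model@exons, function(e) extractInterval(seq, e),
               character(1)), collapse = "")
}
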