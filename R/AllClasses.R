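## S4 classes for the annotated circular genome data model.

#' CircularSeq: a (possibly circular) DNA sequence
#'
#' Holds one chromosome-scale DNA sequence over the alphabet {A,C,G,T,N}.
#' Plant mitochondrial and plastid genomes typically assemble as circular
#' molecules; the \code{circular} flag switches on origin-wrapping
#' coordinate arithmetic in \code{\link{extractInterval}}.
#'
#' @slot id Sequence identifier.
#' @slot seq The residues as a single character string.
#' @slot circular Whether coordinates may wrap the origin.
#' @export
setClass("CircularSeq",
  representation(id = "character", seq = "character", circular = "logical"),
  validity = function(object) {
    if (length(object@id) != 1L || !nzchar(object@id))
      return("id must be a single non-empty string")
    if (length(object@seq) != 1L || nchar(object@seq) < 1L)
      return("sequence must be non-empty")
    if (grepl("[^ACGTN]", object@seq))
      return("sequence contains characters outside {A,C,G,T,N}")
    if (length(object@circular) != 1L || is.na(object@circular))
      return("circular must be TRUE or FALSE")
    TRUE
  })

#' Construct a CircularSeq
#'
#' @param id Sequence identifier.
#' @param seq DNA string; upper-cased, U is accepted and mapped to T.
#' @param circular Logical; TRUE for circular molecules.
#' @return A \linkS4class{CircularSeq} object.
#' @examples
#' circularSeq("chrM", "ACGTACGT", circular = TRUE)
#' @export
circularSeq <- function(id, seq, circular = FALSE) {
  new("CircularSeq", id = as.character(id),
      seq = normalizeDna(seq, what = id), circular = isTRUE(circular))
}

#' FeatureInterval: a 1-based inclusive genomic interval
#'
#' Coordinates are 1-based inclusive throughout (GFF3 convention).
#' \code{start > end} is permitted only on circular sequences and denotes a
#' feature spanning the origin; the extracted length is then
#' \code{L - start + 1 + end}.
#'
#' @slot seq_id Identifier of the sequence the interval lives on.
#' @slot start,end 1-based inclusive coordinates.
#' @slot strand "+" or "-".
#' @slot kind Feature class: exon, gene, CDS, repeat, MTPT or other.
#' @slot attributes Free-form key/value list.
#' @export
setClass("FeatureInterval",
  representation(seq_id = "character", start = "integer", end = "integer",
                 strand = "character", kind = "character",
                 attributes = "list"),
  validity = function(object) {
    if (object@start < 1L || object@end < 1L)
      return("start and end must be >= 1")
    if (!object@strand %in% c("+", "-"))
      return("strand must be '+' or '-'")
    if (!object@kind %in% c("exon", "gene", "CDS", "repeat", "MTPT", "other"))
      return("kind must be one of exon/gene/CDS/repeat/MTPT/other")
    TRUE
  })

#' Construct a FeatureInterval
#'
#' @param seq_id Sequence identifier.
#' @param start,end 1-based inclusive coordinates; \code{start > end} marks
#'   an origin-spanning feature on a circular sequence.
#' @param strand "+" (default) or "-".
#' @param kind Feature class (default "other").
#' @param attributes Named list of extra attributes.
#' @return A \linkS4class{FeatureInterval}.
#' @examples
#' featureInterval("chrM", 120, 480, strand = "-", kind = "exon")
#' @export
featureInterval <- function(seq_id, start, end, strand = "+",
                            kind = "other", attributes = list()) {
  new("FeatureInterval", seq_id = as.character(seq_id),
      start = as.integer(start), end = as.integer(end),
      strand = strand, kind = kind, attributes = attributes)
}

#' GeneModel: exon structure of one gene in transcript order
#'
#' Exons are stored in transcript (5' to 3' coding) order, which is the
#' authoritative order: for trans-spliced genes the genomic order of exons
#' can differ from the transcript order, so genome coordinates alone cannot
#' reconstruct the CDS.
#'
#' @slot gene Gene name (e.g. "nad1").
#' @slot product_kind "protein", "rRNA" or "tRNA".
#' @slot exons List of \linkS4class{FeatureInterval}, transcript order.
#' @slot pseudo TRUE for pseudogenes.
#' @export
setClass("GeneModel",
  representation(gene = "character", product_kind = "character",
                 exons = "list", pseudo = "logical"),
  validity = function(object) {
    if (!length(object@exons)) return("at least one exon is required")
    if (!all(vapply(object@exons, is, logical(1), "FeatureInterval")))
      return("exons must be FeatureInterval objects")
    if (!object@product_kind %in% c("protein", "rRNA", "tRNA"))
      return("product_kind must be protein/rRNA/tRNA")
    TRUE
  })

#' Construct a GeneModel
#'
#' @param gene Gene name.
#' @param exons List of \linkS4class{FeatureInterval} in transcript order.
#' @param product_kind "protein" (default), "rRNA" or "tRNA".
#' @param pseudo Logical, TRUE for pseudogenes.
#' @return A \linkS4class{GeneModel}.
#' @export
geneModel <- function(gene, exons, product_kind = "protein", pseudo = FALSE) {
  new("GeneModel", gene = as.character(gene), product_kind = product_kind,
      exons = exons, pseudo = isTRUE(pseudo))
}

#' ConformationSet: recombination test references for one repeat pair
#'
#' For a dispersed repeat pair, the four small reference sequences used to
#' score read-pair support for repeat-mediated recombination: the two
#' principal (assembled) arrangements and the two alternative (recombined)
#' arrangements, each the repeat plus up to \code{flank} nt of context on
#' either side.
#'
#' @slot repeat_id Repeat pair identifier.
#' @slot orientation "direct" or "inverted".
#' @slot flank Flank length used (nt).
#' @slot rep_len Repeat length (nt).
#' @slot refs Named character vector: principalA, principalB, alt1, alt2.
#' @slot junctions Named list of integer pairs giving, for each reference,
#'   the flank/repeat boundary offsets within that reference.
#' @slot truncated TRUE if a flank was truncated at a linear sequence end.
#' @export
setClass("ConformationSet",
  representation(repeat_id = "character", orientation = "character",
                 flank = "integer", rep_len = "integer",
                 refs = "character", junctions = "list",
                 truncated = "logical"),
  validity = function(object) {
    need <- c("principalA", "principalB", "alt1", "alt2")
    if (!all(need %in% names(object@refs)))
      return("refs must contain principalA, principalB, alt1, alt2")
    if (!object@orientation %in% c("direct", "inverted"))
      return("orientation must be direct or inverted")
    TRUE
  })

#' MaskedAlignment: a gene alignment with masked-column bookkeeping
#'
#' Wraps a multiple sequence alignment as a character matrix (rows = taxa,
#' columns = alignment columns, gaps "-"). Masking removes columns (for
#' example alignment columns touched by predicted C-to-U RNA editing
#' sites) while retaining the map back to original column numbers, so
#' downstream coordinates (conversion fragments, region splits) can always
#' be reported on the original alignment.
#'
#' @slot mat Character matrix, rownames are taxa.
#' @slot colmap Integer vector: original column index of each current column.
#' @slot masked Integer vector of removed original columns.
#' @export
setClass("MaskedAlignment",
  representation(mat = "matrix", colmap = "integer", masked = "integer"),
  validity = function(object) {
    if (is.null(rownames(object@mat))) return("taxa (rownames) required")
    if (anyDuplicated(rownames(object@mat))) return("taxa must be unique")
    if (length(object@colmap) != ncol(object@mat))
      return("colmap length must equal column count")
    TRUE
  })

#' @export
setMethod("show", "CircularSeq", function(object) {
  cat(sprintf("CircularSeq '%s': %d nt, %s\n", object@id,
              nchar(object@seq),
              if (object@circular) "circular" else "linear"))
})

#' @export
setMethod("show", "FeatureInterval", function(object) {
  cat(sprintf("FeatureInterval %s:%d-%d(%s) [%s]%s\n", object@seq_id,
              object@start, object@end, object@strand, object@kind,
              if (object@start > object@end) " wraps origin" else ""))
})

#' @export
setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s (%s%s): %d exon(s)\n", object@gene,
              object@product_kind, if (object@pseudo) ", pseudo" else "",
              length(object@exons)))
})

#' @export
setMethod("show", "ConformationSet", function(object) {
  cat(sprintf("ConformationSet %s (%s, repeat %d nt, flank %d nt)\n",
              object@repeat_id, object@orientation, object@rep_len,
              object@flank))
})

#' @export
setMethod("show", "MaskedAlignment", function(object) {
  cat(sprintf("MaskedAlignment: %d taxa x %d columns (%d masked)\n",
              nrow(object@mat), ncol(object@mat), length(object@masked)))
})
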