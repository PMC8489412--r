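## Chimeric-gene screen: gene-conversion fragment detection, region
## splitting, identity profiles and per-region phylogenetic origin.
##
## The fragment detector condenses the alignment to polymorphic columns
## and, for each taxon pair, scores +1 where the pair agrees and -P where
## it disagrees, with P = scale * ceiling((1 - p)/p) and p the pair's
## overall disagreement fraction; maximal positive-scoring segments are
## candidate converted tracts. Any scale above 1 makes the expected
## per-column score negative for every pair (drift <= (1 - p)(1 - scale)),
## so segment maxima have exponential rather than random-walk tails; the
## default 1.5 balances sensitivity to long weak tracts against short
## strong ones. Significance is a column-order permutation
## test whose null statistic is the maximum segment score across ALL
## pairs (family-wise control), with each pair's segment score
## standardised by its own permutation moments so that no single
## low-divergence pair dominates the null. This is a declared
## approximation in the GENECONV family, not a re-derivation of
## GENECONV's inner-fragment statistics.

#' Construct a MaskedAlignment
#'
#' @param x A character matrix (rows = taxa, gaps "-"), a named character
#'   vector of equal-length aligned strings, or a Biostrings
#'   DNAStringSet.
#' @return A \linkS4class{MaskedAlignment}.
#' @export
maskedAlignment <- function(x) {
  if (is(x, "DNAStringSet") || is(x, "BStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  }
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("aligned strings must be named by taxon")
    if (length(unique(nchar(x))) != 1L)
      stop("aligned sequences must have equal length")
    x <- do.call(rbind, strsplit(toupper(x), ""))
  }
  if (!is.matrix(x)) stop("cannot interpret alignment input")
  new("MaskedAlignment", mat = x, colmap = seq_len(ncol(x)),
      masked = integer(0))
}

#' Read an aligned FASTA file
#' @param path FASTA of equal-length aligned sequences.
#' @return A \linkS4class{MaskedAlignment}.
#' @export
readAlignmentFasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  maskedAlignment(stats::setNames(toupper(as.character(set)),
                                  sub("\\s.*$", "", names(set))))
}

#' @rdname maskedAlignment
#' @param msa A MaskedAlignment.
#' @export
alnTaxa <- function(msa) rownames(msa@mat)

#' @rdname maskedAlignment
#' @export
alnWidth <- function(msa) ncol(msa@mat)

## current columns corresponding to an ungapped-coordinate span of a taxon
focalCols <- function(msa, focal, span = NULL) {
  if (!focal %in% rownames(msa@mat)) stop("taxon not in alignment: ", focal)
  keep <- which(msa@mat[focal, ] != "-")
  if (is.null(span)) return(keep)
  if (span[2] > length(keep))
    stop("span extends past the ungapped length of ", focal)
  keep[span[1]:span[2]]
}

#' Map original alignment columns to ungapped positions of a taxon
#'
#' @param msa A \linkS4class{MaskedAlignment}.
#' @param taxon Taxon name.
#' @param cols Original-alignment column indices.
#' @return Integer ungapped positions (NA where the taxon has a gap or
#'   the column is masked).
#' @export
colsToUngapped <- function(msa, taxon, cols) {
  cur <- match(cols, msa@colmap)
  ung <- cumsum(msa@mat[taxon, ] != "-")
  ung[msa@mat[taxon, ] == "-"] <- NA
  out <- rep(NA_integer_, length(cols))
  ok <- !is.na(cur)
  out[ok] <- ung[cur[ok]]
  out
}

#' Remove alignment columns containing listed sites
#'
#' Any alignment column containing a listed site in any taxon (positions
#' given on the taxon's ungapped sequence, e.g. predicted C-to-U RNA
#' editing sites) is removed; removed original columns are recorded and
#' coordinate bookkeeping is retained so downstream results can be
#' reported on original columns.
#'
#' @param msa A \linkS4class{MaskedAlignment}.
#' @param sites data.frame(taxon, pos) or NULL/empty for identity.
#' @return A \linkS4class{MaskedAlignment} with columns removed.
#' @export
maskSites <- function(msa, sites) {
  if (is.null(sites) || !nrow(sites)) return(msa)
  drop <- integer(0)
  for (i in seq_len(nrow(sites))) {
    tx <- sites$taxon[i]; pos <- sites$pos[i]
    keep <- which(msa@mat[tx, ] != "-")
    if (pos > length(keep))
      stop(sprintf("site %d beyond end of %s (%d nt)", pos, tx,
                   length(keep)))
    drop <- c(drop, keep[pos])
  }
  drop <- sort(unique(drop))
  new("MaskedAlignment", mat = msa@mat[, -drop, drop = FALSE],
      colmap = msa@colmap[-drop],
      masked = sort(c(msa@masked, msa@colmap[drop])))
}

#' Read edit-site lists from TSV
#' @param path TSV with columns taxon, pos.
#' @return data.frame(taxon, pos).
#' @export
readEditSites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("taxon", "pos") %in% colnames(df)))
  df$pos <- as.integer(df$pos)
  df
}

#' Exclude genes too short after masking
#'
#' @param msas Named list of \linkS4class{MaskedAlignment} (one per gene).
#' @param min_len Minimum post-masking alignment length, default 300 nt.
#' @return list: kept (named list), excluded (data.frame gene, length).
#' @export
filterShort <- function(msas, min_len = 300L) {
  lens <- vapply(msas, alnWidth, integer(1))
  ex <- lens < min_len
  list(kept = msas[!ex],
       excluded = data.frame(gene = names(msas)[ex], length = lens[ex],
                             row.names = NULL, stringsAsFactors = FALSE))
}

## best-scoring contiguous segment of a numeric vector
bestSegment <- function(x) {
  n <- length(x)
  s <- cumsum(x)
  pre <- c(0, s[-n])
  prem <- cummin(pre)
  gains <- s - prem
  j <- which.max(gains)
  i <- which(pre[seq_len(j)] == prem[j])[1]
  list(score = gains[j], i = i, j = j)
}

maxSegmentScore <- function(x) {
  s <- cumsum(x)
  max(0, s - cummin(c(0, s[-length(s)])))
}

#' Detect gene-conversion fragments in an alignment
#'
#' See the module header for the statistic. Fragments with permutation
#' p-value below \code{p_cutoff} are returned, sorted by score,
#' with coordinates mapped back to original alignment columns.
#'
#' @param msa A \linkS4class{MaskedAlignment} with >= 3 taxa and >= 2
#'   polymorphic columns.
#' @param penalty_scale Mismatch penalty scale (default 1.5; values above
#'   1 give every pair a negative expected per-column score, which the
#'   null distribution of segment maxima relies on).
#' @param n_perm Number of column-order permutations (default 10000).
#' @param seed Seed for the permutation null.
#' @param p_cutoff Report fragments with p below this (default 0.05; use
#'   1 to obtain every candidate with its p-value).
#' @param max_per_pair Maximum non-overlapping segments enumerated per
#'   taxon pair (default 5).
#' @return data.frame: taxon1, taxon2, start_col, end_col (original
#'   alignment columns), n_poly_sites, score, p_value.
#' @export
detectFragments <- function(msa, penalty_scale = 1.5, n_perm = 10000L,
                            seed = NULL, p_cutoff = 0.05,
                            max_per_pair = 5L) {
  mat <- msa@mat
  if (nrow(mat) < 3L) stop("at least 3 taxa are required")
  ok <- matrix(mat %in% c("A", "C", "G", "T"), nrow = nrow(mat))
  poly <- vapply(seq_len(ncol(mat)), function(j) {
    v <- mat[ok[, j], j]
    length(unique(v)) >= 2L
  }, logical(1))
  pc <- which(poly)
  m <- length(pc)
  if (m < 2L) stop("fewer than 2 polymorphic columns")
  taxa <- rownames(mat)
  prs <- utils::combn(taxa, 2)
  svecs <- list(); labs <- list()
  for (q in seq_len(ncol(prs))) {
    a <- mat[prs[1, q], pc]; b <- mat[prs[2, q], pc]
    av <- ok[match(prs[1, q], taxa), pc]; bv <- ok[match(prs[2, q], taxa), pc]
    both <- av & bv
    agree <- both & a == b
    dis <- both & a != b
    nboth <- sum(both)
    if (!nboth) next
    phat <- sum(dis) / nboth
    if (phat == 0) next  # identical sequences: skip pair
    P <- penalty_scale * ceiling((1 - phat) / phat)
    v <- numeric(m)
    v[agree] <- 1
    v[dis] <- -P
    svecs[[length(svecs) + 1L]] <- v
    labs[[length(labs) + 1L]] <- prs[, q]
  }
  if (!length(svecs)) {
    return(data.frame(taxon1 = character(), taxon2 = character(),
                      start_col = integer(), end_col = integer(),
                      n_poly_sites = integer(), score = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  ## observed candidates: greedy enumeration of non-overlapping positive
  ## segments per pair
  cand <- list()
  for (q in seq_along(svecs)) {
    x <- svecs[[q]]
    for (rep_i in seq_len(max_per_pair)) {
      bs <- bestSegment(x)
      if (bs$score <= 0) break
      cand[[length(cand) + 1L]] <- list(pair = labs[[q]], i = bs$i,
                                        j = bs$j, score = bs$score)
      x[bs$i:bs$j] <- -1e9
    }
  }
  ## permutation null: per permutation, the best segment score of every
  ## pair (common column permutation); pair scores are then standardised
  ## by the pair's own null moments and the family-wise statistic is the
  ## maximum standardised score across pairs
  M <- withSeed(seed, {
    res <- vapply(seq_len(n_perm), function(t) {
      idx <- sample.int(m)
      vapply(svecs, function(v) maxSegmentScore(v[idx]), numeric(1))
    }, numeric(length(svecs)))
    if (is.matrix(res)) t(res) else matrix(res, ncol = 1L)
  })
  mu <- colMeans(M)
  sg <- apply(M, 2, stats::sd)
  sg[sg == 0] <- Inf  # degenerate pair: never significant
  null_max_z <- apply((M - rep(mu, each = n_perm)) /
                        rep(sg, each = n_perm), 1, max)
  pair_key <- vapply(labs, paste, character(1), collapse = "\r")
  rows <- lapply(cand, function(cd) {
    q <- match(paste(cd$pair, collapse = "\r"), pair_key)
    z <- (cd$score - mu[q]) / sg[q]
    p <- (1 + sum(null_max_z >= z)) / (n_perm + 1)
    data.frame(taxon1 = cd$pair[1], taxon2 = cd$pair[2],
               start_col = msa@colmap[pc[cd$i]],
               end_col = msa@colmap[pc[cd$j]],
               n_poly_sites = cd$j - cd$i + 1L, score = cd$score,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$p_value < p_cutoff, , drop = FALSE]
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split a gene into contiguous regions at breakpoints
#'
#' k breakpoints produce k+1 contiguous 1-based inclusive regions whose
#' lengths sum to the gene length.
#'
#' @param gene_len Ungapped gene length (nt).
#' @param breakpoints Strictly increasing positions < gene_len; each
#'   breakpoint is the last position of its region.
#' @return data.frame: label (I, II, ...), start, end, length.
#' @examples
#' splitRegions(1506, c(1137, 1493))  # 1137, 356 and 13 nt regions
#' @export
splitRegions <- function(gene_len, breakpoints = integer(0)) {
  gene_len <- as.integer(gene_len)
  breakpoints <- as.integer(breakpoints)
  if (length(breakpoints)) {
    if (is.unsorted(breakpoints, strictly = TRUE))
      stop("breakpoints must be strictly increasing with no duplicates")
    if (any(breakpoints < 1L | breakpoints >= gene_len))
      stop("breakpoints must lie in [1, gene_len - 1]")
  }
  bounds <- c(0L, breakpoints, gene_len)
  k <- length(bounds) - 1L
  data.frame(label = as.character(utils::as.roman(seq_len(k))),
             start = bounds[-length(bounds)] + 1L, end = bounds[-1],
             length = diff(bounds), stringsAsFactors = FALSE)
}

#' Divide a region into near-equal subregions
#'
#' The first k-1 spans take the comparison length (the length of the
#' shortest comparand, when provided) or floor(len/k); the last span
#' takes the remainder. Used to compare a long region against a short
#' one on equal footing.
#'
#' @param region c(start, end), 1-based inclusive.
#' @param k Number of subregions, default 3.
#' @param comparand_len Optional target length for the first k-1 spans.
#' @return data.frame: start, end, length (spans tile the region).
#' @examples
#' splitEven(c(1, 1137), 3, comparand_len = 356)  # 1-356, 357-712, 713-1137
#' @export
splitEven <- function(region, k = 3L, comparand_len = NULL) {
  st <- as.integer(region[1]); en <- as.integer(region[2])
  k <- as.integer(k)
  len <- en - st + 1L
  if (k < 1L || len < k) stop("region too short for ", k, " subregions")
  base <- if (is.null(comparand_len)) len %/% k else as.integer(comparand_len)
  if (base < 1L || (k - 1L) * base >= len)
    stop("comparand length leaves no room for the final span")
  starts <- st + (seq_len(k) - 1L) * base
  ends <- c(starts[-1] - 1L, en)
  data.frame(start = starts, end = ends, length = ends - starts + 1L)
}

#' Pairwise identity of a focal taxon against a group over a span
#'
#' Identity is computed over the span's aligned columns, excluding
#' (pairwise) columns where either sequence has a gap or ambiguity.
#'
#' @param msa A \linkS4class{MaskedAlignment}.
#' @param span c(start, end) on the ungapped focal sequence.
#' @param focal Focal taxon.
#' @param group Character vector of comparison taxa (non-empty).
#' @return list: range = c(min, max) percent, per_taxon = named vector.
#' @export
pairwiseIdentityRange <- function(msa, span, focal, group) {
  if (!length(group)) stop("empty comparison group")
  cols <- focalCols(msa, focal, span)
  a <- msa@mat[focal, cols]
  per <- vapply(group, function(g) {
    b <- msa@mat[g, cols]
    both <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    if (!sum(both)) return(NA_real_)
    100 * sum(a[both] == b[both]) / sum(both)
  }, numeric(1))
  list(range = range(per, na.rm = TRUE), per_taxon = per)
}

## JC69 distances with per-pair fallback to p-distance where the JC log
## is undefined (saturation)
jcDist <- function(dnab) {
  d <- ape::dist.dna(dnab, model = "JC69", pairwise.deletion = TRUE)
  bad <- !is.finite(d)
  if (any(bad)) {
    raw <- ape::dist.dna(dnab, model = "raw", pairwise.deletion = TRUE)
    d[bad] <- raw[bad]
    attr(d, "jc_fallback") <- sum(bad)
  }
  d
}

#' Neighbor-joining tree (thin wrapper over a distance matrix)
#'
#' Recovers the generating topology exactly on tree-additive distances.
#' @param d A dist object or symmetric matrix.
#' @return An ape phylo.
#' @export
njTree <- function(d) ape::nj(stats::as.dist(d))

#' Bootstrap neighbor-joining tree over an alignment span
#'
#' Neighbor-joining on Jukes-Cantor distances (with p-distance fallback
#' for saturated pairs); bipartition supports are the percentage of
#' column-resampled bootstrap trees containing each bipartition, written
#' to \code{node.label}. Deterministic given the seed. This is the
#' package's stand-in for maximum-likelihood tree estimation; the origin
#' decision rule downstream (BS >= 70) is unchanged.
#'
#' @param msa A \linkS4class{MaskedAlignment} with >= 4 taxa.
#' @param span Optional c(start, end) on the ungapped focal sequence.
#' @param focal Focal taxon defining span coordinates (required with
#'   span).
#' @param n_boot Bootstrap replicates, default 1000.
#' @param seed Seed.
#' @param outgroup Optional taxon to root at (supports are carried as
#'   edge labels through rooting).
#' @return A rooted (if outgroup given) ape phylo with percent supports
#'   in node.label.
#' @export
njBootstrap <- function(msa, span = NULL, focal = NULL, n_boot = 1000L,
                        seed = NULL, outgroup = NULL) {
  if (nrow(msa@mat) < 4L) stop("at least 4 taxa are required")
  cols <- if (is.null(span)) seq_len(ncol(msa@mat))
          else focalCols(msa, focal, span)
  sub <- msa@mat[, cols, drop = FALSE]
  if (!any(vapply(seq_len(ncol(sub)), function(j) {
    v <- sub[, j]; v <- v[v %in% c("A", "C", "G", "T")]
    length(unique(v)) >= 2L
  }, logical(1)))) stop("span has no variable column")
  dnab <- ape::as.DNAbin(tolower(sub))
  tree <- njTree(jcDist(dnab))
  boots <- withSeed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(ncol(sub), replace = TRUE)
      njTree(jcDist(dnab[, idx]))
    })
  })
  cnt <- ape::prop.clades(tree, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  tree$node.label <- round(100 * cnt / n_boot, 1)
  if (!is.null(outgroup) && outgroup %in% tree$tip.label) {
    tree <- ape::root(tree, outgroup, resolve.root = TRUE, edgelabel = TRUE)
  }
  tree
}

#' Assign the phylogenetic origin of a focal taxon from a supported clade
#'
#' Walks rootward from the focal tip to the smallest ancestral clade that
#' contains at least one other taxon and has bootstrap support at or
#' above the threshold. If that clade's non-focal members all belong to
#' the native set the verdict is native; if they all belong to one
#' foreign set the verdict is foreign with that label; a mixed supported
#' clade, or no supported clade at all, is unresolved.
#'
#' @param tree A rooted ape phylo with percent supports in node.label.
#' @param focal Focal taxon.
#' @param native Character vector: taxa of the native lineage.
#' @param foreign_sets Named list of character vectors (candidate donor
#'   lineages), disjoint from native.
#' @param bs_threshold Bootstrap percent threshold, default 70.
#' @return list: verdict ("native", "foreign", "unresolved"), label
#'   (foreign set name or NA), sister_group (taxa of the deciding
#'   clade), support.
#' @export
assignOrigin <- function(tree, focal, native, foreign_sets,
                         bs_threshold = 70) {
  if (!focal %in% tree$tip.label) stop("focal taxon absent from tree")
  if (length(intersect(native, unlist(foreign_sets))))
    stop("native and foreign sets must be disjoint")
  nt <- length(tree$tip.label)
  tip <- match(focal, tree$tip.label)
  anc <- phangorn::Ancestors(tree, tip, "all")
  root_node <- nt + 1L
  sup <- suppressWarnings(as.numeric(tree$node.label))
  for (nd in anc) {
    if (nd == root_node) break  # the root bipartition has no support
    tips <- tree$tip.label[phangorn::Descendants(tree, nd, "tips")[[1]]]
    others <- setdiff(tips, focal)
    if (!length(others)) next
    s <- sup[nd - nt]
    if (is.na(s) || s < bs_threshold) next  # unsupported: widen the clade
    if (all(others %in% native)) {
      return(list(verdict = "native", label = NA_character_,
                  sister_group = others, support = s))
    }
    for (lb in names(foreign_sets)) {
      if (all(others %in% foreign_sets[[lb]])) {
        return(list(verdict = "foreign", label = lb,
                    sister_group = others, support = s))
      }
    }
    return(list(verdict = "unresolved", label = NA_character_,
                sister_group = others, support = s))
  }
  list(verdict = "unresolved", label = NA_character_,
       sister_group = character(0), support = NA_real_)
}
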