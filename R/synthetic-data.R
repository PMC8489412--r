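## Synthetic mitogenomes, reads and clade alignments with planted truth.
##
## The generator emulates the feature classes of a rearranged plant
## mitogenome: protein/rRNA genes whose introns are planted either
## cis-spliced (intron inline between adjacent exons) or split
## (cis-intron broken in the middle, the downstream half relocated and
## optionally inverted, with a configurable middle-loss deletion),
## dispersed repeat pairs at controlled identity, plastid-derived
## insertions copied from a generated toy plastome, and paired-end reads
## with a stated insert-size distribution and error rate. All randomness
## flows from a single seed.

rotateBase <- function(b) c(A = "C", C = "G", G = "T", T = "A", N = "A")[b]

## random protein CDS: ATG + non-stop codons + TAA
randomCds <- function(len, gc = 0.44) {
  stopifnot(len %% 3 == 0, len >= 9)
  b <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(b, b, b), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG",
         paste(sample(codons, len / 3 - 2, replace = TRUE), collapse = ""),
         "TAA")
}

## force the first/last 3 intron bases to differ position-wise from the
## CDS continuation, so exon alignment endpoints are exactly the planted
## exon boundaries (mirrors real splice boundaries, where intron termini
## are not CDS-like)
guardIntron <- function(iseq, next3, prev3) {
  v <- strsplit(iseq, "")[[1]]
  nx <- strsplit(next3, "")[[1]]
  for (i in seq_along(nx)) {
    if (i <= length(v) && v[i] == nx[i]) v[i] <- rotateBase(nx[i])
  }
  pv <- strsplit(prev3, "")[[1]]
  rl <- length(v)
  for (i in seq_along(pv)) {
    pos <- rl - length(pv) + i
    if (pos >= 1L && v[pos] == pv[i]) v[pos] <- rotateBase(pv[i])
  }
  paste(v, collapse = "")
}

mutateVec <- function(v, rate) {
  if (rate <= 0 || !length(v)) return(v)
  hit <- which(stats::runif(length(v)) < rate)
  if (length(hit)) {
    v[hit] <- vapply(v[hit],
                     function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                     character(1))
  }
  v
}

## flip exactly n distinct positions (used to hit a target repeat-copy
## identity precisely)
flipExactly <- function(s, n) {
  if (n <= 0L) return(s)
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), n)
  v[pos] <- vapply(v[pos],
                   function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                   character(1))
  paste(v, collapse = "")
}

#' Gene specification for the synthetic genome
#'
#' @param name Gene name (e.g. "nad1").
#' @param cds_len CDS length in nt (multiple of 3 for proteins).
#' @param introns List of intron specs: each
#'   \code{list(pos =, mode = "cis", len =)} for an inline intron or
#'   \code{list(pos =, mode = "split", ref_len =, loss =, invert =)} for a
#'   broken one (pos = reference-CDS position after which the intron
#'   sits; loss = nt of the reference intron deleted at the break).
#' @param product "protein" or "rRNA".
#' @return A gene spec list.
#' @export
geneSpec <- function(name, cds_len, introns = list(), product = "protein") {
  pos <- vapply(introns, function(x) x$pos, numeric(1))
  stopifnot(!is.unsorted(pos, strictly = TRUE) || length(pos) <= 1L,
            all(pos >= 1 & pos < cds_len))
  list(name = name, cds_len = as.integer(cds_len), introns = introns,
       product = product)
}

#' Default gene set of the synthetic mitogenome
#'
#' Mirrors the named introns of the registry: nad1 (i394 planted
#' contiguous to exercise the ancestral-trans override, i669 and i728
#' split, the latter with an 866 nt middle loss), nad2 (i156 cis, i542
#' and i709 split), nad5 (i1455 and i1477 split, flanking a 22 nt exon),
#' cox1 (i729 cis), cox2 (i373 split), nad4 (i976 split), rps3 (i74
#' split), plus intron-less atp1 and an rRNA gene.
#' @return List of gene specs.
#' @export
defaultGeneSpecs <- function() {
  list(
    geneSpec("nad1", 978, list(
      list(pos = 394, mode = "cis", len = 1300),
      list(pos = 669, mode = "split", ref_len = 1700, loss = 700,
           invert = TRUE),
      list(pos = 728, mode = "split", ref_len = 2000, loss = 866,
           invert = FALSE))),
    geneSpec("nad2", 1467, list(
      list(pos = 156, mode = "cis", len = 1200),
      list(pos = 542, mode = "split", ref_len = 1600, loss = 500,
           invert = TRUE),
      list(pos = 709, mode = "split", ref_len = 1500, loss = 450,
           invert = FALSE))),
    geneSpec("nad5", 2010, list(
      list(pos = 1455, mode = "split", ref_len = 1400, loss = 400,
           invert = FALSE),
      list(pos = 1477, mode = "split", ref_len = 1300, loss = 350,
           invert = TRUE))),
    geneSpec("cox1", 1584, list(
      list(pos = 729, mode = "cis", len = 1100))),
    geneSpec("cox2", 783, list(
      list(pos = 373, mode = "split", ref_len = 1500, loss = 520,
           invert = TRUE))),
    geneSpec("nad4", 1488, list(
      list(pos = 976, mode = "split", ref_len = 1700, loss = 640,
           invert = FALSE))),
    geneSpec("rps3", 1677, list(
      list(pos = 74, mode = "split", ref_len = 1600, loss = 580,
           invert = TRUE))),
    geneSpec("atp1", 1506),
    geneSpec("rrn18", 1900, product = "rRNA"))
}

#' Default repeat pair specifications
#'
#' Five dispersed pairs spanning the study's size range; the 400 bp pair
#' exceeds the default insert cap and is therefore excluded from
#' recombination screening; one shorter pair is flagged active for
#' recombined-read simulation.
#' @return data.frame: len, identity, orientation, active.
#' @export
defaultRepeatSpecs <- function() {
  data.frame(
    len = c(60L, 100L, 150L, 211L, 400L),
    identity = c(100, 100, 95, 90, 95),
    orientation = c("direct", "direct", "inverted", "direct", "direct"),
    active = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Default clade-simulation specification
#'
#' Twelve taxa: a native clade containing the focal taxon (within-clade
#' divergence about 3-5 percent), a foreign donor clade about 8-9 percent
#' diverged from it (the background divergence), a distant lineage and an
#' outgroup; branch lengths are per-site substitution probabilities. The conversion spec copies a 350 nt donor
#' segment (positions 1138-1487 of a 1506 nt gene, echoing the size and
#' 3'-position of the chimeric region the screen is designed to find)
#' into the focal taxon, then applies 2 percent post-transfer divergence.
#' @return Clade spec list.
#' @export
defaultCladeSpec <- function() {
  list(
    topology = paste0(
      "((((((focal:0.015,native1:0.015):0.008,(native2:0.015,native3:",
      "0.015):0.008):0.008,native4:0.03):0.012,(((foreign1:0.015,",
      "foreign2:0.015):0.008,(foreign3:0.015,foreign4:0.015):0.008):",
      "0.008,foreign5:0.03):0.012):0.015,other1:0.08):0.015,",
      "outgroup:0.1);"),
    gene_len = 1506L, gc = 0.44,
    focal = "focal",
    native = c("native1", "native2", "native3", "native4"),
    foreign = list(donor_clade = c("foreign1", "foreign2", "foreign3",
                                   "foreign4", "foreign5")),
    outgroup = "outgroup",
    conversion = list(donor = "foreign1", recipient = "focal",
                      start = 1138L, end = 1487L, post_div = 0.02))
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data module. Defaults emulate
#' the study conditions: 44 percent GC background, repeat pairs of
#' 60-400 bp, plastid insertions of 150-2500 bp at 0-5 percent
#' divergence, 150 nt paired reads with a Normal(300, 30) insert
#' truncated at twice the read length and a 0.001 per-base error rate.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param genome_len Mitogenome length (default 60000 nt).
#' @param gc Background GC content (default 0.44).
#' @param genes List of \code{\link{geneSpec}}.
#' @param repeats Repeat spec data.frame (len, identity, orientation,
#'   active).
#' @param mtpt list(count, len_range, divergence range).
#' @param plastome_len Toy plastome length.
#' @param reads list(n_pairs, read_len, insert_mean, insert_sd,
#'   error_rate).
#' @param recombined_fraction Fraction of read fragments drawn from the
#'   recombined conformation(s) in recombination simulations.
#' @param clade Clade spec, see \code{\link{defaultCladeSpec}}.
#' @param max_intron_len Classifier threshold the layout respects: split
#'   intron halves are guaranteed to be separated by more than this when
#'   colinear.
#' @param min_spacer Minimum spacer between planted blocks (nt).
#' @return A SimConfig list.
#' @export
simConfig <- function(seed = 1L, genome_len = 60000L, gc = 0.44,
                      genes = defaultGeneSpecs(),
                      repeats = defaultRepeatSpecs(),
                      mtpt = list(count = 10L, len_range = c(150L, 2500L),
                                  divergence = c(0, 0.05)),
                      plastome_len = 14000L,
                      reads = list(n_pairs = 2000L, read_len = 150L,
                                   insert_mean = 300, insert_sd = 30,
                                   error_rate = 0.001),
                      recombined_fraction = 0.1,
                      clade = defaultCladeSpec(),
                      max_intron_len = 10000L, min_spacer = 20L) {
  stopifnot(genome_len > 0, gc > 0, gc < 1,
            recombined_fraction >= 0, recombined_fraction <= 1,
            reads$error_rate >= 0, reads$error_rate <= 1)
  structure(list(seed = as.integer(seed), genome_len = as.integer(genome_len),
                 gc = gc, genes = genes, repeats = repeats, mtpt = mtpt,
                 plastome_len = as.integer(plastome_len), reads = reads,
                 recombined_fraction = recombined_fraction, clade = clade,
                 max_intron_len = as.integer(max_intron_len),
                 min_spacer = as.integer(min_spacer)),
            class = c("SimConfig", "list"))
}

## ---- gene block construction -------------------------------------------

emptyFeats <- function() {
  data.frame(kind = character(), name = character(), idx = integer(),
             wb_start = integer(), wb_end = integer(), strand = character(),
             cds_start = integer(), cds_end = integer(),
             p_start = integer(), p_end = integer(), divergence = numeric(),
             stringsAsFactors = FALSE)
}

featRow <- function(kind, name, idx, wb_start, wb_end, strand = "+",
                    cds_start = NA, cds_end = NA, p_start = NA, p_end = NA,
                    divergence = NA) {
  data.frame(kind = kind, name = name, idx = as.integer(idx),
             wb_start = as.integer(wb_start), wb_end = as.integer(wb_end),
             strand = strand, cds_start = as.integer(cds_start),
             cds_end = as.integer(cds_end), p_start = as.integer(p_start),
             p_end = as.integer(p_end), divergence = as.numeric(divergence),
             stringsAsFactors = FALSE)
}

## build the placed blocks of one gene; returns blocks, cds, intron truth
buildGeneBlocks <- function(spec, gc) {
  g <- spec$name
  cds <- if (spec$product == "protein") randomCds(spec$cds_len, gc)
         else randomDna(spec$cds_len, gc)
  pos <- vapply(spec$introns, function(x) x$pos, numeric(1))
  ex_start <- c(1L, as.integer(pos) + 1L)
  ex_end <- c(as.integer(pos), spec$cds_len)
  segs <- list()
  cur <- list(seq = "", feats = emptyFeats(), invert = FALSE)
  pushExon <- function(cur, k) {
    e <- substr(cds, ex_start[k], ex_end[k])
    at <- nchar(cur$seq)
    cur$seq <- paste0(cur$seq, e)
    cur$feats <- rbind(cur$feats,
                       featRow("exon", g, k, at + 1L, at + nchar(e),
                               cds_start = ex_start[k], cds_end = ex_end[k]))
    cur
  }
  cur <- pushExon(cur, 1L)
  introns <- list()
  for (j in seq_along(spec$introns)) {
    isp <- spec$introns[[j]]
    rl <- if (identical(isp$mode, "cis")) isp$len else isp$ref_len
    iseq <- randomDna(rl, gc)
    next3 <- substr(cds, pos[j] + 1L, min(pos[j] + 3L, spec$cds_len))
    prev3 <- substr(cds, max(1L, pos[j] - 2L), pos[j])
    iseq <- guardIntron(iseq, next3, prev3)
    if (identical(isp$mode, "cis")) {
      cur$seq <- paste0(cur$seq, iseq)
      cur <- pushExon(cur, j + 1L)
      introns[[j]] <- list(name = paste0(g, "i", pos[j]), gene = g,
                           pos = as.integer(pos[j]), planted = "cis",
                           ref_len = rl, loss = 0L, keep5 = rl, keep3 = 0L,
                           invert = FALSE, ref_seq = iseq)
    } else {
      loss <- as.integer(isp$loss)
      stopifnot(loss >= 0L, loss <= rl)
      keep5 <- as.integer(floor((rl - loss) / 2))
      keep3 <- rl - loss - keep5
      cur$seq <- paste0(cur$seq, substr(iseq, 1L, keep5))
      segs[[length(segs) + 1L]] <- cur
      cur <- list(seq = substr(iseq, rl - keep3 + 1L, rl),
                  feats = emptyFeats(), invert = isTRUE(isp$invert))
      cur <- pushExon(cur, j + 1L)
      introns[[j]] <- list(name = paste0(g, "i", pos[j]), gene = g,
                           pos = as.integer(pos[j]), planted = "split",
                           ref_len = rl, loss = loss, keep5 = keep5,
                           keep3 = keep3, invert = isTRUE(isp$invert),
                           ref_seq = iseq)
    }
  }
  segs[[length(segs) + 1L]] <- cur
  ## apply inversion to downstream segments flagged invert
  blocks <- lapply(segs, function(sg) {
    if (sg$invert) {
      blen <- nchar(sg$seq)
      f <- sg$feats
      new_start <- blen - f$wb_end + 1L
      new_end <- blen - f$wb_start + 1L
      f$wb_start <- new_start; f$wb_end <- new_end
      f$strand <- ifelse(f$strand == "+", "-", "+")
      list(seq = revComp(sg$seq), feats = f, tag = paste0("gene:", g))
    } else {
      list(seq = sg$seq, feats = sg$feats, tag = paste0("gene:", g))
    }
  })
  list(blocks = blocks, cds = cds, introns = introns,
       product = spec$product)
}

## ---- toy plastome -------------------------------------------------------

buildPlastome <- function(plastome_len, gc = 0.37) {
  gspec <- list(psbA = 1062L, rbcL = 1428L, petA = 963L)
  rrna <- list(rrn16 = 1491L)
  parts <- character(0); feats <- list(); cursor <- 0L
  addPart <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    cursor <<- cursor + nchar(s)
  }
  cds_list <- list()
  for (nm in names(gspec)) {
    addPart(randomDna(300L, gc))
    s <- randomCds(gspec[[nm]], gc)
    cds_list[[nm]] <- s
    feats[[length(feats) + 1L]] <- list(name = nm, kind = "protein",
                                        start = cursor + 1L,
                                        end = cursor + nchar(s))
    addPart(s)
  }
  for (nm in names(rrna)) {
    addPart(randomDna(300L, gc))
    s <- randomDna(rrna[[nm]], gc)
    cds_list[[nm]] <- s
    feats[[length(feats) + 1L]] <- list(name = nm, kind = "rRNA",
                                        start = cursor + 1L,
                                        end = cursor + nchar(s))
    addPart(s)
  }
  used <- cursor
  if (used > plastome_len - 100L)
    stop("plastome_len too small for the planted plastid genes")
  addPart(randomDna(plastome_len - used, gc))
  seqchr <- paste(unlist(parts), collapse = "")
  plastome <- circularSeq("plastome_sim", seqchr, circular = TRUE)
  models <- lapply(feats, function(f) {
    geneModel(f$name,
              list(featureInterval("plastome_sim", f$start, f$end,
                                   strand = "+", kind = "exon",
                                   attributes = list(gene = f$name))),
              product_kind = if (f$kind == "rRNA") "rRNA" else "protein")
  })
  names(models) <- vapply(feats, function(f) f$name, character(1))
  list(plastome = plastome, models = models, cds = cds_list)
}

## ---- layout -------------------------------------------------------------

## genome-coordinate exon table + trans-separation constraint; dispersed
## repeat copies must also be well separated (the recombination screen's
## flank geometry assumes the copies' contexts are distinct)
layoutOk <- function(feats, intron_truth, L, max_intron_len, margin = 500L,
                     min_rep_sep = 1000L) {
  rp <- feats[feats$kind == "repeat", , drop = FALSE]
  for (rid in unique(rp$name)) {
    r2 <- rp[rp$name == rid, , drop = FALSE]
    r2 <- r2[order(r2$g_start), , drop = FALSE]
    gap_lin <- r2$g_start[2] - r2$g_end[1] - 1L
    gap_circ <- L - (r2$g_end[2] - r2$g_start[1] + 1L)
    if (min(gap_lin, gap_circ) < min_rep_sep) return(FALSE)
  }
  ex <- feats[feats$kind == "exon", , drop = FALSE]
  for (it in intron_truth) {
    if (!identical(it$planted, "split")) next
    gx <- ex[ex$name == it$gene, , drop = FALSE]
    gx <- gx[order(gx$idx), , drop = FALSE]
    k <- which(vapply(seq_len(nrow(gx) - 1L), function(i) {
      gx$cds_end[i] == it$pos
    }, logical(1)))
    if (!length(k)) return(FALSE)
    up <- gx[k, ]; down <- gx[k + 1L, ]
    if (up$strand != down$strand) next  # strand flip: always split
    gap <- if (up$strand == "+") down$g_start - up$g_end - 1L
           else up$g_start - down$g_end - 1L
    if (gap < 0L) gap <- gap + L
    if (gap <= max_intron_len + margin) return(FALSE)
  }
  TRUE
}

layoutBlocks <- function(blocks, genome_len, gc, min_spacer, intron_truth,
                         max_intron_len, max_try = 1000L) {
  lens <- vapply(blocks, function(b) nchar(b$seq), integer(1))
  nb <- length(blocks)
  rem <- genome_len - sum(lens) - nb * min_spacer
  if (rem < 0L)
    stop("planted features do not fit in genome_len")
  for (try in seq_len(max_try)) {
    ord <- sample.int(nb)
    extra <- stats::rmultinom(1, rem, rep(1, nb))[, 1]
    sp <- min_spacer + extra
    cursor <- 0L
    feats <- list()
    offs <- integer(nb)
    for (j in seq_len(nb)) {
      b <- blocks[[ord[j]]]
      offs[j] <- cursor + 1L
      f <- b$feats
      if (nrow(f)) {
        f$g_start <- f$wb_start + cursor
        f$g_end <- f$wb_end + cursor
        feats[[length(feats) + 1L]] <- f
      }
      cursor <- cursor + lens[ord[j]] + sp[j]
    }
    feats <- do.call(rbind, feats)
    if (layoutOk(feats, intron_truth, genome_len, max_intron_len)) {
      parts <- character(0)
      for (j in seq_len(nb)) {
        parts <- c(parts, blocks[[ord[j]]]$seq, randomDna(sp[j], gc))
      }
      return(list(seq = paste(parts, collapse = ""), feats = feats))
    }
  }
  stop("could not satisfy layout constraints after ", max_try, " attempts")
}

## ---- main generator -----------------------------------------------------

#' Generate a synthetic annotated mitogenome with planted truth
#'
#' Builds a random circular genome containing the configured genes (with
#' cis and split introns), dispersed repeat pairs, and plastid-derived
#' insertions copied from a generated toy plastome, then lays the blocks
#' out with random spacers. The layout guarantees the structural truth of
#' every planted intron: split-intron halves on one strand are separated
#' by more than \code{max_intron_len}. Deterministic per seed.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @return list: genome (\linkS4class{CircularSeq}), models (GeneModel
#'   list), cds (named list of reference CDS), plastome,
#'   plastome_models, plastome_cds, and truth (exons, introns, repeats,
#'   mtpt tables).
#' @export
makeMitogenome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  withSeed(cfg$seed, {
    pl <- buildPlastome(cfg$plastome_len)
    blocks <- list(); cds <- list(); intron_truth <- list()
    products <- character(0)
    for (spec in cfg$genes) {
      gb <- buildGeneBlocks(spec, cfg$gc)
      blocks <- c(blocks, gb$blocks)
      cds[[spec$name]] <- gb$cds
      products[spec$name] <- gb$product
      intron_truth <- c(intron_truth, gb$introns)
    }
    ## repeats
    rs <- cfg$repeats
    for (i in seq_len(nrow(rs))) {
      copyA <- randomDna(rs$len[i], cfg$gc)
      nmut <- round(rs$len[i] * (100 - rs$identity[i]) / 100)
      copyB <- flipExactly(copyA, nmut)
      rid <- sprintf("rep%02d", i)
      inv <- rs$orientation[i] == "inverted"
      blocks <- c(blocks,
        list(list(seq = copyA,
                  feats = featRow("repeat", rid, 1L, 1L, rs$len[i], "+"),
                  tag = rid),
             list(seq = if (inv) revComp(copyB) else copyB,
                  feats = featRow("repeat", rid, 2L, 1L, rs$len[i],
                                  if (inv) "-" else "+"),
                  tag = rid)))
    }
    ## MTPT source intervals: non-overlapping on the plastome
    mt <- cfg$mtpt
    msrc <- list(); guard_iv <- IRanges::IRanges()
    tries <- 0L
    while (length(msrc) < mt$count && tries < 2000L) {
      tries <- tries + 1L
      len <- sample(mt$len_range[1]:mt$len_range[2], 1L)
      if (len >= cfg$plastome_len) next
      st <- sample.int(cfg$plastome_len - len, 1L)
      iv <- IRanges::IRanges(st, st + len - 1L)
      if (length(guard_iv) &&
          any(IRanges::overlapsAny(iv, guard_iv))) next
      guard_iv <- c(guard_iv, iv)
      msrc[[length(msrc) + 1L]] <- list(start = st, end = st + len - 1L,
                                        len = len)
    }
    if (length(msrc) < mt$count)
      stop("could not place non-overlapping MTPT source intervals")
    for (i in seq_along(msrc)) {
      m <- msrc[[i]]
      div <- stats::runif(1, mt$divergence[1], mt$divergence[2])
      strand <- sample(c("+", "-"), 1L)
      src <- substr(seqChars(pl$plastome), m$start, m$end)
      cp <- mutateDna(src, div)
      if (strand == "-") cp <- revComp(cp)
      blocks <- c(blocks,
        list(list(seq = cp,
                  feats = featRow("MTPT", sprintf("mtpt%02d", i), 1L, 1L,
                                  m$len, strand, p_start = m$start,
                                  p_end = m$end, divergence = div),
                  tag = "mtpt")))
    }
    lay <- layoutBlocks(blocks, cfg$genome_len, cfg$gc, cfg$min_spacer,
                        intron_truth, cfg$max_intron_len)
    genome <- circularSeq("mito_sim", lay$seq, circular = TRUE)
    feats <- lay$feats

    ## truth tables -------------------------------------------------------
    ex <- feats[feats$kind == "exon", , drop = FALSE]
    ex <- ex[order(ex$name, ex$idx), , drop = FALSE]
    exon_truth <- data.frame(gene = ex$name, exon_index = ex$idx,
                             cds_start = ex$cds_start, cds_end = ex$cds_end,
                             g_start = ex$g_start, g_end = ex$g_end,
                             strand = ex$strand, stringsAsFactors = FALSE)
    reg <- intronRegistry()
    intron_df <- do.call(rbind, lapply(intron_truth, function(it) {
      anc <- it$name %in% reg$name[reg$ancestral_trans]
      data.frame(name = it$name, gene = it$gene, pos = it$pos,
                 planted = it$planted,
                 expected_mode = if (identical(it$planted, "split") || anc)
                   "trans" else "cis",
                 ref_len = it$ref_len, loss = it$loss, keep5 = it$keep5,
                 keep3 = it$keep3, invert = it$invert,
                 stringsAsFactors = FALSE)
    }))
    ref_introns <- stats::setNames(
      lapply(intron_truth, function(it) it$ref_seq),
      vapply(intron_truth, function(it) it$name, character(1)))
    rp <- feats[feats$kind == "repeat", , drop = FALSE]
    repeat_truth <- do.call(rbind, lapply(unique(rp$name), function(rid) {
      r2 <- rp[rp$name == rid, , drop = FALSE]
      r2 <- r2[order(r2$g_start), , drop = FALSE]
      i <- match(rid, sprintf("rep%02d", seq_len(nrow(rs))))
      data.frame(repeat_id = rid, a_start = r2$g_start[1],
                 a_end = r2$g_end[1], b_start = r2$g_start[2],
                 b_end = r2$g_end[2], orientation = rs$orientation[i],
                 rep_len = rs$len[i], identity = rs$identity[i],
                 active = rs$active[i], stringsAsFactors = FALSE)
    }))
    mp <- feats[feats$kind == "MTPT", , drop = FALSE]
    mtpt_truth <- if (nrow(mp)) {
      data.frame(mtpt_id = mp$name, mito_start = mp$g_start,
                 mito_end = mp$g_end, p_start = mp$p_start,
                 p_end = mp$p_end, strand = mp$strand,
                 divergence = mp$divergence,
                 len = mp$g_end - mp$g_start + 1L, stringsAsFactors = FALSE)
    } else data.frame()

    models <- lapply(split(exon_truth, exon_truth$gene), function(df) {
      df <- df[order(df$exon_index), , drop = FALSE]
      exs <- lapply(seq_len(nrow(df)), function(i) {
        featureInterval("mito_sim", df$g_start[i], df$g_end[i],
                        strand = df$strand[i], kind = "exon",
                        attributes = list(gene = df$gene[i]))
      })
      geneModel(df$gene[1], exs,
                product_kind = unname(products[df$gene[1]]))
    })
    list(genome = genome, models = models, cds = cds,
         plastome = pl$plastome, plastome_models = pl$models,
         plastome_cds = pl$cds,
         truth = list(exons = exon_truth, introns = intron_df,
                      ref_introns = ref_introns, repeats = repeat_truth,
                      mtpt = mtpt_truth),
         cfg = cfg)
  })
}

#' Apply repeat-mediated recombination to a circular genome
#'
#' For an inverted repeat pair the segment between the copies is
#' reverse-complemented, giving one circle (an involution: applying it
#' twice restores the genome). For a direct pair, recombination on a
#' single circle excises the sequence between the copies: the products
#' are two circles, one carrying each alternative junction, whose total
#' length equals the input length.
#'
#' @param genome A circular \linkS4class{CircularSeq}.
#' @param pair One repeat pair (row of a repeat table or truth table)
#'   with a_start, a_end, b_start, b_end, orientation; copies must not
#'   wrap the origin and copy A must precede copy B.
#' @return list of \linkS4class{CircularSeq}: length 1 (inverted) or 2
#'   (direct).
#' @export
makeRecombinedGenome <- function(genome, pair) {
  pair <- as.list(pair)
  L <- seqLength(genome)
  a1 <- pair$a_start; a2 <- pair$a_end; b1 <- pair$b_start; b2 <- pair$b_end
  if (!(1 <= a1 && a1 <= a2 && a2 < b1 && b1 <= b2 && b2 <= L))
    stop("repeat pair coordinates not on the genome (or wrap the origin)")
  s <- seqChars(genome)
  S1 <- substr(s, 1L, a1 - 1L); RA <- substr(s, a1, a2)
  S2 <- substr(s, a2 + 1L, b1 - 1L); RB <- substr(s, b1, b2)
  S3 <- substr(s, b2 + 1L, L)
  if (identical(pair$orientation, "inverted")) {
    list(circularSeq(paste0(seqId(genome), "_rec"),
                     paste0(S1, RA, revComp(S2), RB, S3), circular = TRUE))
  } else {
    list(circularSeq(paste0(seqId(genome), "_recA"),
                     paste0(S1, RA, S3), circular = TRUE),
         circularSeq(paste0(seqId(genome), "_recB"),
                     paste0(RB, S2), circular = TRUE))
  }
}

## ---- paired-end read simulation ----------------------------------------

#' Simulate paired-end reads from weighted circular genomes
#'
#' Fragments are drawn per genome in proportion to the weights, start
#' positions uniform on each circle, fragment lengths
#' Normal(insert_mean, insert_sd) truncated (by rejection) to at least
#' twice the read length. Mates are the fragment ends; mate 2 is
#' reverse-complemented (forward-reverse orientation). A per-base
#' substitution error is applied. Deterministic per seed.
#'
#' @param genomes A \linkS4class{CircularSeq}, or list of
#'   \code{list(seq =, weight =)} with weights summing to 1.
#' @param n_pairs Number of read pairs.
#' @param read_len Read length (default 150 nt).
#' @param insert_mean,insert_sd Insert size distribution (default 300,
#'   30).
#' @param error_rate Per-base substitution error rate (default 0.001).
#' @param seed Seed; NULL uses the current RNG stream.
#' @param id_prefix Read id prefix.
#' @return list: reads (data.frame id, mate1, mate2) and truth
#'   (data.frame id, genome, start, insert).
#' @export
simulateReads <- function(genomes, n_pairs, read_len = 150L,
                          insert_mean = 300, insert_sd = 30,
                          error_rate = 0.001, seed = NULL,
                          id_prefix = "rp") {
  if (is(genomes, "CircularSeq"))
    genomes <- list(list(seq = genomes, weight = 1))
  w <- vapply(genomes, function(g) g$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-6) stop("genome weights must sum to 1")
  n_pairs <- as.integer(n_pairs)
  withSeed(seed, {
    if (n_pairs == 0L) {
      return(list(reads = data.frame(id = character(), mate1 = character(),
                                     mate2 = character(),
                                     stringsAsFactors = FALSE),
                  truth = data.frame()))
    }
    gl <- vapply(genomes, function(g) seqLength(g$seq), integer(1))
    gv <- lapply(genomes, function(g) strsplit(seqChars(g$seq), "")[[1]])
    gi <- sample.int(length(genomes), n_pairs, replace = TRUE, prob = w)
    lf <- round(stats::rnorm(n_pairs, insert_mean, insert_sd))
    bad <- which(lf < 2L * read_len)
    while (length(bad)) {
      lf[bad] <- round(stats::rnorm(length(bad), insert_mean, insert_sd))
      bad <- bad[lf[bad] < 2L * read_len]
    }
    if (any(lf > gl[gi]))
      stop("fragment longer than its source genome")
    st <- floor(stats::runif(n_pairs) * gl[gi]) + 1L
    m1 <- character(n_pairs); m2 <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
      v <- gv[[gi[i]]]; L <- gl[gi[i]]
      idx <- ((st[i] - 1L + 0:(lf[i] - 1L)) %% L) + 1L
      frag <- v[idx]
      r1 <- frag[seq_len(read_len)]
      r2 <- rev(chartr("ACGT", "TGCA", frag[(lf[i] - read_len + 1L):lf[i]]))
      if (error_rate > 0) {
        r1 <- mutateVec(r1, error_rate)
        r2 <- mutateVec(r2, error_rate)
      }
      m1[i] <- paste(r1, collapse = "")
      m2[i] <- paste(r2, collapse = "")
    }
    ids <- sprintf("%s%06d", id_prefix, seq_len(n_pairs))
    list(reads = data.frame(id = ids, mate1 = m1, mate2 = m2,
                            stringsAsFactors = FALSE),
         truth = data.frame(id = ids, genome = gi, start = st, insert = lf,
                            stringsAsFactors = FALSE))
  })
}

#' Write read pairs as two FASTQ files
#'
#' Fixed quality 'I'; mate ids get /1 and /2 suffixes.
#' @param reads data.frame(id, mate1, mate2).
#' @param path1,path2 Output FASTQ paths.
#' @return Invisibly, c(path1, path2).
#' @export
writePairedFastq <- function(reads, path1, path2) {
  wr <- function(seqs, ids, path, mate) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- paste0(ids, "/", mate)
    q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  if (nrow(reads)) {
    wr(reads$mate1, reads$id, path1, 1L)
    wr(reads$mate2, reads$id, path2, 2L)
  } else {
    file.create(path1); file.create(path2)
  }
  invisible(c(path1, path2))
}

#' Read paired FASTQ files
#'
#' Qualities are read but unused. Mate files must be in matching order.
#' @param path1,path2 FASTQ paths.
#' @return data.frame(id, mate1, mate2).
#' @export
readPairedFastq <- function(path1, path2) {
  if (file.size(path1) == 0L)
    return(data.frame(id = character(), mate1 = character(),
                      mate2 = character(), stringsAsFactors = FALSE))
  m1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  m2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  if (length(m1) != length(m2)) stop("mate files differ in length")
  ids <- sub("/[12]$", "", sub("\\s.*$", "", names(m1)))
  data.frame(id = ids, mate1 = unname(as.character(m1)),
             mate2 = unname(as.character(m2)), stringsAsFactors = FALSE)
}

## ---- clade simulation ---------------------------------------------------

#' Simulate a gap-free clade alignment with an optional planted conversion
#'
#' A root sequence is evolved down the configured topology, each branch
#' applying its per-site substitution probability (Jukes-Cantor style, no
#' indels). If a conversion is configured, the donor's segment is copied
#' into the recipient and then mutated at the post-transfer divergence,
#' creating a chimeric focal gene.
#'
#' @param clade Clade spec, see \code{\link{defaultCladeSpec}};
#'   \code{conversion = NULL} disables the transfer (null simulation).
#' @param seed Seed.
#' @return list: msa (\linkS4class{MaskedAlignment}), truth (donor,
#'   recipient, start, end or NULL), tree (the generating ape phylo).
#' @export
evolveClades <- function(clade = defaultCladeSpec(), seed = NULL) {
  tr <- ape::read.tree(text = clade$topology)
  if (is.null(tr)) stop("invalid topology")
  withSeed(seed, {
    tr2 <- stats::reorder(tr, "cladewise")
    nt <- length(tr2$tip.label)
    nn <- tr2$Nnode
    seqs <- vector("list", nt + nn)
    seqs[[nt + 1L]] <- strsplit(randomDna(clade$gene_len, clade$gc), "")[[1]]
    for (e in seq_len(nrow(tr2$edge))) {
      par <- tr2$edge[e, 1]; chl <- tr2$edge[e, 2]
      seqs[[chl]] <- mutateVec(seqs[[par]], tr2$edge.length[e])
    }
    mat <- do.call(rbind, seqs[seq_len(nt)])
    rownames(mat) <- tr2$tip.label
    truth <- NULL
    cv <- clade$conversion
    if (!is.null(cv)) {
      span <- cv$start:cv$end
      mat[cv$recipient, span] <- mat[cv$donor, span]
      mat[cv$recipient, span] <- mutateVec(mat[cv$recipient, span],
                                           cv$post_div)
      truth <- list(donor = cv$donor, recipient = cv$recipient,
                    start = cv$start, end = cv$end)
    }
    list(msa = maskedAlignment(mat), truth = truth, tree = tr)
  })
}
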