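## Run configuration, intron-mode matrix and pipeline orchestration.

#' Pipeline run configuration
#'
#' Bundles every analysis threshold; the configuration is echoed into the
#' header of every report written, so each output records the parameters
#' that produced it.
#'
#' @param min_repeat_len Minimum repeat length (nt), default 50.
#' @param min_ident Percent identity threshold for homology search,
#'   default 80.
#' @param mtpt_min_len Minimum MTPT length, default 101 (> 100 bp).
#' @param insert_cap Repeat-screen insert-size cap (nt), default 350.
#' @param flank Conformation flank (nt), default 300.
#' @param max_intron_len Maximum cis intron length (nt), default 10000.
#' @param bs_threshold Bootstrap percent for origin calls, default 70.
#' @param n_boot Bootstrap replicates, default 1000.
#' @param n_perm Permutations for the conversion screen, default 10000.
#' @param min_gene_len Minimum post-masking gene length (nt), default 300.
#' @param max_mismatch Per-mate mismatch cap, default 2.
#' @param min_anchor Junction anchor (nt), default 5.
#' @param seed Seed for all stochastic stages.
#' @return A RunConfig list.
#' @export
runConfig <- function(min_repeat_len = 50L, min_ident = 80,
                      mtpt_min_len = 101L, insert_cap = 350L, flank = 300L,
                      max_intron_len = 10000L, bs_threshold = 70,
                      n_boot = 1000L, n_perm = 10000L, min_gene_len = 300L,
                      max_mismatch = 2L, min_anchor = 5L, seed = 1L) {
  cfg <- list(min_repeat_len = min_repeat_len, min_ident = min_ident,
              mtpt_min_len = mtpt_min_len, insert_cap = insert_cap,
              flank = flank, max_intron_len = max_intron_len,
              bs_threshold = bs_threshold, n_boot = n_boot,
              n_perm = n_perm, min_gene_len = min_gene_len,
              max_mismatch = max_mismatch, min_anchor = min_anchor,
              seed = seed)
  stopifnot(all(vapply(cfg, function(x) is.numeric(x) && x > 0, logical(1))))
  structure(cfg, class = c("RunConfig", "list"))
}

#' Write a table as TSV with the run configuration in comment headers
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param config Optional RunConfig echoed as \code{# key=value} lines.
#' @return Invisibly, the path.
#' @export
writeTsvReport <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mitoshift %s", basename(path)), con)
  if (!is.null(config)) {
    writeLines(sprintf("# %s=%s", names(config),
                       vapply(config, format, character(1))), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Intron-mode matrix across genomes
#'
#' Builds the taxa-by-intron table with values cis/trans/absent, plus the
#' shift events of each genome relative to a declared ancestral-state row
#' (by default: trans for ancestrally trans-spliced registry introns, cis
#' otherwise).
#'
#' @param calls_by_genome Named list: genome/taxon name ->
#'   \code{\link{classifyIntrons}} output.
#' @param registry Intron registry, default \code{\link{intronRegistry}()}.
#' @param ancestral Optional named character vector of ancestral states
#'   per intron (cis/trans), overriding the registry-derived default.
#' @return list: matrix (character, taxa x introns), ancestral (named
#'   vector), shifts (data.frame genome, intron, from, to).
#' @export
intronMatrix <- function(calls_by_genome, registry = intronRegistry(),
                         ancestral = NULL) {
  if (!length(calls_by_genome)) stop("at least one genome is required")
  introns <- sort(unique(unlist(lapply(calls_by_genome,
                                       function(df) df$intron))))
  mat <- matrix("absent", nrow = length(calls_by_genome),
                ncol = length(introns),
                dimnames = list(names(calls_by_genome), introns))
  for (g in names(calls_by_genome)) {
    df <- calls_by_genome[[g]]
    for (i in seq_len(nrow(df))) {
      cur <- mat[g, df$intron[i]]
      if (cur != "absent" && cur != df$mode[i])
        stop(sprintf("conflicting duplicate calls for %s in %s",
                     df$intron[i], g))
      mat[g, df$intron[i]] <- df$mode[i]
    }
  }
  anc <- stats::setNames(rep("cis", length(introns)), introns)
  reg_anc <- registry$name[registry$ancestral_trans]
  anc[introns %in% reg_anc] <- "trans"
  if (!is.null(ancestral)) anc[names(ancestral)] <- ancestral
  shifts <- list()
  for (g in rownames(mat)) {
    for (i in introns) {
      if (mat[g, i] != "absent" && mat[g, i] != anc[i]) {
        shifts[[length(shifts) + 1L]] <- data.frame(
          genome = g, intron = i, from = unname(anc[i]), to = mat[g, i],
          stringsAsFactors = FALSE)
      }
    }
  }
  list(matrix = mat, ancestral = anc,
       shifts = if (length(shifts)) do.call(rbind, shifts)
                else data.frame(genome = character(), intron = character(),
                                from = character(), to = character(),
                                stringsAsFactors = FALSE))
}

#' Run the full pipeline on a synthetic dataset
#'
#' Generates a genome from \code{sim_cfg}, then runs every analysis
#' stage: intron classification (with breakpoint mapping for split
#' introns), repeat detection, recombination screening against simulated
#' reads (a fraction drawn from the recombined conformation of the first
#' active planted repeat), MTPT scanning with gene-status calls, and the
#' chimera screen on a simulated clade alignment. Reports are written to
#' \code{out_dir} as TSV (plus FASTA/GFF3 of the dataset) and a summary
#' list is returned.
#'
#' @param sim_cfg A \code{\link{simConfig}}.
#' @param config A \code{\link{runConfig}}.
#' @param out_dir Output directory (created if needed); NULL skips all
#'   file output.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of per-stage results and summary counts.
#' @export
runPipeline <- function(sim_cfg = simConfig(), config = runConfig(),
                        out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(out_dir))
      writeTsvReport(df, file.path(out_dir, name), config)
  }
  say("simulating genome (seed %d, %d nt)", sim_cfg$seed,
      sim_cfg$genome_len)
  sim <- makeMitogenome(sim_cfg)
  if (!is.null(out_dir)) {
    writeFasta(sim$genome, file.path(out_dir, "mitogenome.fasta"))
    writeAnnotation(sim$models, file.path(out_dir, "mitogenome.gff3"))
    writeFasta(sim$plastome, file.path(out_dir, "plastome.fasta"))
  }

  ## introns ---------------------------------------------------------------
  placements <- do.call(rbind, lapply(names(sim$cds), function(g) {
    locateExons(g, sim$cds[[g]], sim$genome, min_ident = config$min_ident)
  }))
  calls <- classifyIntrons(placements, sim$genome,
                           max_intron_len = config$max_intron_len)
  emit(calls, "intron_calls.tsv")
  say("introns: %d calls (%d cis, %d trans)", nrow(calls),
      sum(calls$mode == "cis"), sum(calls$mode == "trans"))
  bp <- lapply(which(calls$mode == "trans" & calls$raw_adjacency == "split"),
               function(i) {
    nm <- calls$intron[i]
    ref <- sim$truth$ref_introns[[nm]]
    if (is.null(ref)) return(NULL)
    r <- mapBreakpoints(calls[i, ], ref, sim$genome,
                        min_ident = config$min_ident)
    data.frame(intron = nm, retained5 = r$retained5_len,
               retained3 = r$retained3_len, lost_mid = r$lost_mid_len,
               ref_len = r$ref_len, stringsAsFactors = FALSE)
  })
  bp <- do.call(rbind, bp[!vapply(bp, is.null, logical(1))])
  if (!is.null(bp)) emit(bp, "intron_breakpoints.tsv")
  mx <- intronMatrix(list(mito_sim = calls))
  if (!is.null(out_dir))
    writeTsvReport(as.data.frame(mx$matrix), file.path(out_dir,
                   "intron_matrix.tsv"), config)

  ## repeats ---------------------------------------------------------------
  reps <- selfRepeats(sim$genome, min_len = config$min_repeat_len,
                      min_ident = config$min_ident)
  ru <- repeatUnionBp(reps, seqLength(sim$genome))
  emit(reps, "repeat_pairs.tsv")
  say("repeats: %d pairs, %d bp (%.2f%%)", nrow(reps), ru$bp, ru$pct)

  ## recombination ---------------------------------------------------------
  active <- sim$truth$repeats[sim$truth$repeats$active, , drop = FALSE]
  pools <- list(list(seq = sim$genome,
                     weight = 1 - sim_cfg$recombined_fraction))
  if (nrow(active) && sim_cfg$recombined_fraction > 0) {
    recs <- makeRecombinedGenome(sim$genome, active[1, ])
    lens <- vapply(recs, seqLength, integer(1))
    for (i in seq_along(recs)) {
      pools[[length(pools) + 1L]] <- list(
        seq = recs[[i]],
        weight = sim_cfg$recombined_fraction * lens[i] / sum(lens))
    }
  } else {
    pools[[1]]$weight <- 1
  }
  rd <- sim_cfg$reads
  reads <- simulateReads(pools, rd$n_pairs, rd$read_len, rd$insert_mean,
                         rd$insert_sd, rd$error_rate,
                         seed = sim_cfg$seed + 1L)
  support <- screenRepeats(sim$genome, reps, reads$reads,
                           insert_cap = config$insert_cap,
                           flank = config$flank,
                           max_mismatch = config$max_mismatch,
                           min_anchor = config$min_anchor)
  emit(support, "recombination_support.tsv")
  say("recombination: %d of %d eligible repeats active",
      attr(support, "n_active"), nrow(support))

  ## MTPT ------------------------------------------------------------------
  mtpt <- findMtpt(sim$genome, sim$plastome, min_len = config$mtpt_min_len,
                   min_ident = config$min_ident)
  genes <- callMtptGenes(mtpt, sim$plastome_models, sim$genome,
                         sim$plastome)
  emit(mtpt$regions[, setdiff(colnames(mtpt$regions), "members")],
       "mtpt_regions.tsv")
  if (nrow(genes)) emit(genes, "mtpt_genes.tsv")
  say("MTPT: %d regions covering %.2f%%", mtpt$summary$n_regions,
      mtpt$summary$coverage_pct)

  ## chimera ---------------------------------------------------------------
  cl <- sim_cfg$clade
  ev <- evolveClades(cl, seed = sim_cfg$seed + 2L)
  frags <- detectFragments(ev$msa, n_perm = config$n_perm,
                           seed = sim_cfg$seed + 3L)
  chim <- NULL
  if (nrow(frags)) {
    ff <- frags[frags$taxon1 == cl$focal | frags$taxon2 == cl$focal, ,
                drop = FALSE]
    if (nrow(ff)) {
      ff <- ff[seq_len(min(nrow(ff), 4L)), , drop = FALSE]
      bps <- sort(unique(unlist(lapply(seq_len(nrow(ff)), function(i) {
        u <- colsToUngapped(ev$msa, cl$focal,
                            c(ff$start_col[i], ff$end_col[i]))
        c(u[1] - 1L, u[2])
      }))))
      bps <- bps[bps >= 1L & bps < cl$gene_len]
      regions <- splitRegions(cl$gene_len, bps)
      orig <- lapply(seq_len(nrow(regions)), function(r) {
        oc <- tryCatch({
          tr <- njBootstrap(ev$msa, span = c(regions$start[r],
                                             regions$end[r]),
                            focal = cl$focal, n_boot = config$n_boot,
                            seed = sim_cfg$seed + 10L + r,
                            outgroup = cl$outgroup)
          assignOrigin(tr, cl$focal, cl$native, cl$foreign,
                       bs_threshold = config$bs_threshold)
        }, error = function(e) list(verdict = "unresolved",
                                    label = NA_character_,
                                    support = NA_real_))
        data.frame(region = regions$label[r], start = regions$start[r],
                   end = regions$end[r], verdict = oc$verdict,
                   label = oc$label, support = oc$support,
                   stringsAsFactors = FALSE)
      })
      chim <- do.call(rbind, orig)
      emit(chim, "chimera_origin.tsv")
    }
    emit(frags, "conversion_fragments.tsv")
  }
  say("chimera: %d significant fragment(s)", nrow(frags))

  invisible(list(sim = sim, placements = placements, intron_calls = calls,
                 breakpoints = bp, intron_matrix = mx, repeats = reps,
                 repeat_union = ru, support = support, mtpt = mtpt,
                 mtpt_genes = genes, fragments = frags, origin = chim,
                 config = config))
}
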