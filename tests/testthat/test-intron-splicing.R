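test_that("intron names follow the gene + i + CDS-position convention", {
  expect_identical(nameIntron("nad1", 728), "nad1i728")
  expect_identical(nameIntron("cox1", 729), "cox1i729")
  expect_identical(nameIntron("x", 1), "xi1")
  expect_error(nameIntron("x", 0))
})

test_that("registry TSV round-trips and is validated", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(intronRegistry(), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- readIntronRegistry(f)
  expect_identical(back, intronRegistry())
  write.table(data.frame(name = "a", gene = "g"), f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(readIntronRegistry(f), "columns")
})

test_that("locateExons finds intact, scattered and minus-strand genes", {
  set.seed(21)
  cds <- rndDna(900)
  # intact single-exon gene
  g1 <- circularSeq("g", paste0(rndDna(500), cds, rndDna(500)),
                    circular = TRUE)
  p1 <- locateExons("gx", cds, g1)
  expect_identical(nrow(p1), 1L)
  expect_identical(c(p1$cds_start, p1$cds_end), c(1L, 900L))
  # minus-strand placement keeps the CDS span
  g2 <- circularSeq("g", paste0(rndDna(500), rcOracle(cds), rndDna(500)),
                    circular = TRUE)
  p2 <- locateExons("gx", cds, g2)
  expect_identical(p2$strand, "-")
  expect_identical(c(p2$cds_start, p2$cds_end), c(1L, 900L))
  # gene absent
  expect_error(locateExons("gx", cds, circularSeq("g", rndDna(3000),
                                                  circular = TRUE)),
               "not found")
})

test_that("placements and intron calls match planted truth on a synthetic genome", {
  sim <- makeMitogenome(smallSimConfig(22))
  pl <- do.call(rbind, lapply(names(sim$cds), function(g)
    locateExons(g, sim$cds[[g]], sim$genome)))
  tr <- sim$truth$exons
  m <- merge(pl, tr, by = c("gene", "exon_index"), suffixes = c("", ".t"))
  expect_identical(nrow(m), nrow(tr))
  expect_identical(m$cds_start, m$cds_start.t)
  expect_identical(m$cds_end, m$cds_end.t)
  expect_identical(m$g_start, m$g_start.t)
  expect_identical(m$g_end, m$g_end.t)
  expect_identical(m$strand, m$strand.t)

  calls <- classifyIntrons(pl, sim$genome)
  # one call per consecutive exon pair
  for (g in unique(pl$gene)) {
    expect_identical(sum(calls$gene == g),
                     max(0L, sum(pl$gene == g) - 1L))
  }
  cmp <- merge(calls, sim$truth$introns, by.x = "intron", by.y = "name")
  expect_identical(nrow(cmp), nrow(sim$truth$introns))
  expect_identical(cmp$mode, cmp$expected_mode)
  # the ancestrally trans-spliced intron planted contiguous carries the
  # override flag; a cis call reports the genomic gap (the intron length)
  ov <- cmp[cmp$intron == "nad1i394", ]
  expect_identical(ov$mode, "trans")
  expect_identical(ov$raw_adjacency, "contiguous")
  expect_true(ov$override_applied)
  expect_identical(ov$genome_gap, 1300L)
  cis <- cmp[cmp$intron == "cox1i729", ]
  expect_identical(cis$mode, "cis")
  expect_identical(cis$genome_gap, 1100L)
})

test_that("overlapping consecutive exons are rejected as malformed", {
  sim <- makeMitogenome(smallSimConfig(23))
  pl <- locateExons("cox1", sim$cds$cox1, sim$genome)
  bad <- pl
  bad$g_start[2] <- bad$g_start[1]
  bad$g_end[2] <- bad$g_end[1] + 10L
  expect_error(classifyIntrons(bad, sim$genome), "malformed")
})

test_that("the override only widens the trans set; strand splits ignore max_intron_len", {
  sim <- makeMitogenome(smallSimConfig(24))
  pl <- do.call(rbind, lapply(names(sim$cds), function(g)
    locateExons(g, sim$cds[[g]], sim$genome)))
  empty_reg <- intronRegistry()[0, ]
  no_reg <- classifyIntrons(pl, sim$genome, registry = empty_reg)
  with_reg <- classifyIntrons(pl, sim$genome)
  expect_true(all(no_reg$intron[no_reg$mode == "trans"] %in%
                    with_reg$intron[with_reg$mode == "trans"]))
  # raising max_intron_len cannot rescue splits caused by strand flips
  wide <- classifyIntrons(pl, sim$genome, registry = empty_reg,
                          max_intron_len = 10000000L)
  inverted <- sim$truth$introns$name[sim$truth$introns$invert]
  expect_true(all(wide$mode[wide$intron %in% inverted] == "trans"))
})

test_that("breakpoint synteny recovers retained ends and middle loss", {
  sim <- makeMitogenome(smallSimConfig(25))
  pl <- do.call(rbind, lapply(names(sim$cds), function(g)
    locateExons(g, sim$cds[[g]], sim$genome)))
  calls <- classifyIntrons(pl, sim$genome)
  tr <- sim$truth$introns
  for (nm in tr$name[tr$planted == "split"]) {
    i <- which(calls$intron == nm)
    r <- mapBreakpoints(calls[i, ], sim$truth$ref_introns[[nm]], sim$genome)
    t1 <- tr[tr$name == nm, ]
    expect_lte(abs(r$retained5_len - t1$keep5), 15L)
    expect_lte(abs(r$retained3_len - t1$keep3), 15L)
    expect_lte(abs(r$lost_mid_len - t1$loss), 15L)
    expect_true(r$found)
  }
  # a cis call is a precondition violation
  cis_i <- which(calls$mode == "cis")[1]
  expect_error(mapBreakpoints(calls[cis_i, ], "ACGTACGT", sim$genome),
               "trans")
})

test_that("a zero-loss split retains the whole reference intron", {
  cfg <- simConfig(seed = 26, genome_len = 26000L,
    genes = list(geneSpec("nad4", 1488, list(
      list(pos = 976, mode = "split", ref_len = 1500, loss = 0,
           invert = FALSE)))),
    repeats = data.frame(len = integer(), identity = numeric(),
                         orientation = character(), active = logical()),
    mtpt = list(count = 0L, len_range = c(150L, 300L),
                divergence = c(0, 0)),
    plastome_len = 8000L)
  sim <- makeMitogenome(cfg)
  pl <- locateExons("nad4", sim$cds$nad4, sim$genome)
  calls <- classifyIntrons(pl, sim$genome)
  r <- mapBreakpoints(calls[1, ], sim$truth$ref_introns[["nad4i976"]],
                      sim$genome)
  expect_lte(r$lost_mid_len, 15L)
})
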