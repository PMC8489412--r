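test_that("the generator is byte-deterministic per seed", {
  a <- makeMitogenome(smallSimConfig(81))
  b <- makeMitogenome(smallSimConfig(81))
  expect_identical(seqChars(a$genome), seqChars(b$genome))
  expect_identical(a$truth$exons, b$truth$exons)
  expect_identical(a$truth$repeats, b$truth$repeats)
  c1 <- makeMitogenome(smallSimConfig(82))
  expect_false(identical(seqChars(a$genome), seqChars(c1$genome)))
  e1 <- evolveClades(seed = 83); e2 <- evolveClades(seed = 83)
  expect_identical(e1$msa@mat, e2$msa@mat)
  r1 <- simulateReads(a$genome, 20, seed = 84)
  r2 <- simulateReads(a$genome, 20, seed = 84)
  expect_identical(r1$reads, r2$reads)
})

test_that("emitted datasets round-trip through the package readers", {
  sim <- makeMitogenome(smallSimConfig(85))
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(list(sim$genome, sim$plastome), fa)
  back <- readFasta(fa, circular = TRUE)
  expect_identical(seqChars(back$mito_sim), seqChars(sim$genome))
  expect_identical(seqChars(back$plastome_sim), seqChars(sim$plastome))
  rd <- simulateReads(sim$genome, 15, seed = 86)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  writePairedFastq(rd$reads, f1, f2)
  rback <- readPairedFastq(f1, f2)
  expect_identical(rback, rd$reads)
  # empty read sets still produce valid (empty) files
  writePairedFastq(simulateReads(sim$genome, 0, seed = 1)$reads, f1, f2)
  expect_identical(nrow(readPairedFastq(f1, f2)), 0L)
})

test_that("a genome planted with only cis introns classifies all-cis", {
  cfg <- simConfig(seed = 87, genome_len = 20000L,
    genes = list(
      geneSpec("cox1", 1584, list(list(pos = 729, mode = "cis", len = 1100))),
      geneSpec("nad2", 1467, list(list(pos = 156, mode = "cis", len = 900)))),
    repeats = data.frame(len = integer(), identity = numeric(),
                         orientation = character(), active = logical()),
    mtpt = list(count = 0L, len_range = c(150L, 300L), divergence = c(0, 0)),
    plastome_len = 8000L)
  sim <- makeMitogenome(cfg)
  pl <- do.call(rbind, lapply(names(sim$cds), function(g)
    locateExons(g, sim$cds[[g]], sim$genome)))
  calls <- classifyIntrons(pl, sim$genome)
  expect_identical(sort(calls$mode), c("cis", "cis"))
})

test_that("configs that do not fit the genome are rejected", {
  expect_error(makeMitogenome(smallSimConfig(88, genome_len = 9000L)),
               "fit|constraints")
})

test_that("simulated inserts follow the truncated normal and errors are rare", {
  sim <- makeMitogenome(smallSimConfig(89, genome_len = 20000L))
  rd <- simulateReads(sim$genome, 1500, seed = 90)
  lf <- rd$truth$insert
  expect_true(all(lf >= 300L))
  # analytic mean of N(300, 30) truncated at 300
  mu <- 300 + 30 * dnorm(0) / 0.5
  se <- 30 / sqrt(1500)  # conservative: truncation shrinks the sd
  expect_lt(abs(mean(lf) - mu), 3 * se + 0.5)  # 0.5 allows for rounding
  # error rate: recompute mate1 mismatches against the source fragment
  v <- strsplit(seqChars(sim$genome), "")[[1]]
  L <- length(v)
  mm <- vapply(seq_len(200), function(i) {
    idx <- ((rd$truth$start[i] - 1L + 0:149) %% L) + 1L
    sum(strsplit(rd$reads$mate1[i], "")[[1]] != v[idx])
  }, numeric(1))
  expect_lt(mean(mm) / 150, 0.004)
  expect_gte(mean(mm) / 150, 0)
})

test_that("fragments longer than the genome are rejected", {
  tiny <- circularSeq("t", paste(rep("ACGT", 60), collapse = ""),
                      circular = TRUE)  # 240 nt < 2 * read_len
  expect_error(simulateReads(tiny, 5, read_len = 150, seed = 91), "longer")
})

test_that("zero branch lengths give identical tip sequences", {
  clade <- list(topology = "((A:0,B:0):0,(C:0,D:0):0);", gene_len = 200L,
                gc = 0.44, conversion = NULL)
  ev <- evolveClades(clade, seed = 92)
  expect_identical(unname(apply(ev$msa@mat, 1, paste, collapse = "")),
                   rep(paste(ev$msa@mat[1, ], collapse = ""), 4))
})

test_that("the planted conversion copies the donor segment into the recipient", {
  cl <- defaultCladeSpec()
  cl$conversion$post_div <- 0
  ev <- evolveClades(cl, seed = 93)
  span <- 1138:1487
  expect_identical(ev$msa@mat["focal", span], ev$msa@mat["foreign1", span])
  expect_gt(sum(ev$msa@mat["focal", 1:1137] !=
                  ev$msa@mat["foreign1", 1:1137]), 30)
  expect_identical(ev$truth$donor, "foreign1")
})
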