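test_that("FASTA reading normalises case and RNA, splits records", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s", "acgt"), f)
  recs <- readFasta(f)
  expect_length(recs, 1L)
  expect_identical(seqChars(recs[[1]]), "ACGT")
  expect_identical(seqLength(recs[[1]]), 4L)

  writeLines(c(">a", "AC", ">b desc", "GGU"), f)
  recs <- readFasta(f)
  expect_identical(vapply(recs, seqLength, integer(1)), c(a = 2L, b = 3L))
  expect_identical(seqChars(recs$b), "GGT")  # U -> T
})

test_that("non-IUPAC residues are rejected with their position", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s", "ACXGT"), f)
  expect_error(readFasta(f), "position 3")
  expect_error(readFasta(withr::local_tempfile(fileext = ".fa")))
})

test_that("FASTA write/read round-trips random genomes", {
  set.seed(41)
  f <- withr::local_tempfile(fileext = ".fasta")
  for (i in 1:20) {
    s <- circularSeq(sprintf("g%d", i), rndDna(sample(50:400, 1)),
                     circular = TRUE)
    writeFasta(s, f)
    back <- readFasta(f, circular = TRUE)[[1]]
    expect_identical(seqChars(back), seqChars(s))
    expect_identical(seqId(back), seqId(s))
  }
})

test_that("interval extraction handles strand, wrap and errors", {
  s <- circularSeq("s", "ACGTT", circular = TRUE)
  expect_identical(extractInterval(s, featureInterval("s", 2, 4)), "CGT")
  expect_identical(extractInterval(s, featureInterval("s", 5, 1)), "TA")
  expect_identical(extractInterval(s, featureInterval("s", 2, 4, "-")), "ACG")
  lin <- circularSeq("s", "ACGTT", circular = FALSE)
  expect_error(extractInterval(lin, featureInterval("s", 5, 1)),
               "non-circular")
  expect_error(extractInterval(s, featureInterval("x", 1, 2)), "seq_id")
  expect_error(extractInterval(s, featureInterval("s", 2, 9)), "outside")
})

test_that("coordinate arithmetic and strand consistency hold on random intervals", {
  set.seed(42)
  g <- circularSeq("g", rndDna(300), circular = TRUE)
  L <- seqLength(g)
  for (i in 1:50) {
    a <- sample(L, 1); b <- sample(L, 1)
    iv <- featureInterval("g", a, b)
    got <- extractInterval(g, iv)
    want_len <- if (a <= b) b - a + 1L else L - a + 1L + b
    expect_identical(nchar(got), want_len)
    expect_identical(intervalLength(iv, L), want_len)
    ivm <- featureInterval("g", a, b, "-")
    expect_identical(extractInterval(g, ivm), rcOracle(got))
  }
})

test_that("revComp validates, complements and is an involution", {
  expect_identical(revComp("AAC"), "GTT")
  expect_identical(revComp("ACGT"), "ACGT")
  expect_error(revComp("ACQT"), "position 3")
  set.seed(43)
  for (i in 1:100) {
    x <- rndDna(sample(1:80, 1), bases = c("A", "C", "G", "T", "N"))
    expect_identical(revComp(revComp(x)), x)
    expect_identical(revComp(x), rcOracle(x))
  }
})

test_that("annotation round-trips through GFF3 with transcript order intact", {
  sim <- makeMitogenome(smallSimConfig(7))
  f <- withr::local_tempfile(fileext = ".gff3")
  writeAnnotation(sim$models, f)
  back <- readAnnotation(f, list(sim$genome))
  expect_setequal(names(back), names(sim$models))
  for (g in names(sim$models)) {
    a <- sim$models[[g]]@exons
    b <- back[[g]]@exons
    expect_length(b, length(a))
    for (k in seq_along(a)) {
      expect_identical(b[[k]]@start, a[[k]]@start)
      expect_identical(b[[k]]@end, a[[k]]@end)
      expect_identical(b[[k]]@strand, a[[k]]@strand)
    }
    expect_identical(back[[g]]@product_kind, sim$models[[g]]@product_kind)
  }
})

test_that("annotation errors name the offending gene and index", {
  sim <- makeMitogenome(smallSimConfig(8))
  f <- withr::local_tempfile(fileext = ".gff3")
  gff <- c("##gff-version 3",
           "mito_sim\tx\texon\t10\t60\t.\t+\t.\tID=e1;gene=nad9;part=1;product_kind=protein",
           "mito_sim\tx\texon\t100\t160\t.\t+\t.\tID=e3;gene=nad9;part=3;product_kind=protein")
  writeLines(gff, f)
  expect_error(readAnnotation(f, list(sim$genome)), "nad9.*2")
  gff[3] <- "other\tx\texon\t100\t160\t.\t+\t.\tID=e2;gene=nad9;part=2;product_kind=protein"
  writeLines(gff, f)
  expect_error(readAnnotation(f, list(sim$genome)), "unknown sequence")
})
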