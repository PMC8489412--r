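test_that("conformation references are built from the stated flank algebra", {
  set.seed(31)
  bg <- rndDna(8000)
  seg <- rndDna(100)
  pl <- plantTwoCopies(bg, seg, 1001, 4001)
  g <- circularSeq("g", pl$genome, circular = TRUE)
  pair <- list(repeat_id = "r1", a_start = 1001L, a_end = 1100L,
               b_start = 4001L, b_end = 4100L, orientation = "direct")
  conf <- buildConformations(g, pair)
  expect_identical(unname(nchar(conf@refs)), rep(700L, 4))
  A_L <- substr(pl$genome, 701, 1000)
  B_R <- substr(pl$genome, 4101, 4400)
  expect_identical(substr(conf@refs[["alt1"]], 1, 300), A_L)
  expect_identical(substr(conf@refs[["alt1"]], 401, 700), B_R)
  expect_identical(substr(conf@refs[["alt1"]], 301, 400), seg)

  pair$orientation <- "inverted"
  confI <- buildConformations(g, pair)
  B_L <- substr(pl$genome, 3701, 4000)
  expect_identical(substr(confI@refs[["alt1"]], 401, 700), rcOracle(B_L))
})

test_that("rebuilding on an inverted-recombined genome swaps principals and alternatives", {
  set.seed(32)
  bg <- rndDna(9000)
  seg <- rndDna(120)
  pl <- plantTwoCopies(bg, seg, 1501, 5501, invert2 = TRUE)
  g <- circularSeq("g", pl$genome, circular = TRUE)
  pair <- list(repeat_id = "r1", a_start = 1501L, a_end = 1620L,
               b_start = 5501L, b_end = 5620L, orientation = "inverted")
  rec <- makeRecombinedGenome(g, pair)
  expect_length(rec, 1L)
  conf0 <- buildConformations(g, pair)
  conf1 <- buildConformations(rec[[1]], pair)
  expect_identical(conf1@refs[["principalA"]], conf0@refs[["alt1"]])
  expect_identical(conf1@refs[["principalB"]], revComp(conf0@refs[["alt2"]]))
  # involution: recombining again restores the genome
  back <- makeRecombinedGenome(rec[[1]], pair)
  expect_identical(seqChars(back[[1]]), seqChars(g))
})

test_that("direct-repeat recombination excises two circles carrying the alt junctions", {
  set.seed(33)
  bg <- rndDna(9000)
  seg <- rndDna(100)
  pl <- plantTwoCopies(bg, seg, 1501, 5501)
  g <- circularSeq("g", pl$genome, circular = TRUE)
  pair <- list(repeat_id = "r1", a_start = 1501L, a_end = 1600L,
               b_start = 5501L, b_end = 5600L, orientation = "direct")
  rec <- makeRecombinedGenome(g, pair)
  expect_length(rec, 2L)
  expect_identical(seqLength(rec[[1]]) + seqLength(rec[[2]]), seqLength(g))
  conf <- buildConformations(g, pair)
  dbl <- function(x) paste0(seqChars(x), seqChars(x))  # circular search
  expect_true(grepl(conf@refs[["alt1"]], dbl(rec[[1]]), fixed = TRUE))
  expect_true(grepl(conf@refs[["alt2"]], dbl(rec[[2]]), fixed = TRUE))
  expect_error(makeRecombinedGenome(g, list(a_start = 10, a_end = 5,
                                            b_start = 100, b_end = 200,
                                            orientation = "direct")))
})

test_that("placePair recovers true offsets and rejects excess mismatches", {
  set.seed(34)
  ref <- rndDna(700)
  frag <- substr(ref, 101, 420)
  rp <- list(id = "p1", mate1 = substr(frag, 1, 150),
             mate2 = rcOracle(substr(frag, 171, 320)))
  p <- placePair(rp, ref)
  expect_identical(p$start1, 101L)
  expect_identical(p$start2, 271L)
  expect_identical(p$which_forward, 1L)
  expect_identical(p$mm, 0L)
  # mate with 3 errors fails at max_mismatch = 2
  v <- strsplit(rp$mate1, "")[[1]]
  v[c(10, 50, 90)] <- vapply(v[c(10, 50, 90)], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  expect_null(placePair(list(mate1 = paste(v, collapse = ""),
                             mate2 = rp$mate2), ref))
})

test_that("placePair agrees with the brute-force oracle on 200 random pairs", {
  set.seed(35)
  for (i in 1:200) {
    ref <- rndDna(sample(150:400, 1))
    from_ref <- i %% 2 == 0
    if (from_ref && nchar(ref) >= 120) {
      st <- sample(nchar(ref) - 110, 1)
      frag <- substr(ref, st, st + sample(80:min(110, nchar(ref) - st), 1))
      l1 <- sample(30:45, 1); l2 <- sample(30:45, 1)
      rp <- list(mate1 = substr(frag, 1, l1),
                 mate2 = rcOracle(substr(frag, nchar(frag) - l2 + 1,
                                         nchar(frag))))
      # sprinkle up to 3 errors on mate1
      ne <- sample(0:3, 1)
      if (ne > 0) {
        v <- strsplit(rp$mate1, "")[[1]]
        at <- sample(length(v), ne)
        v[at] <- vapply(v[at], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        rp$mate1 <- paste(v, collapse = "")
      }
    } else {
      rp <- list(mate1 = rndDna(sample(20:40, 1)),
                 mate2 = rndDna(sample(20:40, 1)))
    }
    got <- placePair(rp, ref)
    want <- placeOracle(rp, ref)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_identical(got[c("start1", "start2", "which_forward")],
                       want[c("start1", "start2", "which_forward")])
      expect_equal(got$mm, want$mm)
    }
  }
})

test_that("reads from the principal genome alone never support recombination", {
  sim <- makeMitogenome(smallSimConfig(36, genome_len = 20000L))
  rd <- simulateReads(sim$genome, 500, seed = 37)
  sup <- screenRepeats(sim$genome, sim$truth$repeats, rd$reads)
  expect_true(all(sup$n_total == 0L))
  expect_identical(attr(sup, "n_active"), 0L)
})

test_that("duplicate read ids are rejected", {
  sim <- makeMitogenome(smallSimConfig(38, genome_len = 20000L))
  rd <- simulateReads(sim$genome, 10, seed = 39)$reads
  rd$id[2] <- rd$id[1]
  conf <- buildConformations(sim$genome, sim$truth$repeats[1, ])
  expect_error(countSupport(rd, conf), "duplicate")
})

test_that("relabelling the copies permutes alt counts but preserves the total", {
  sim <- makeMitogenome(smallSimConfig(40, genome_len = 20000L))
  pair <- sim$truth$repeats[sim$truth$repeats$active, ][1, ]
  recs <- makeRecombinedGenome(sim$genome, pair)
  lens <- vapply(recs, seqLength, integer(1))
  pools <- c(list(list(seq = sim$genome, weight = 0.6)),
             lapply(seq_along(recs), function(i)
               list(seq = recs[[i]], weight = 0.4 * lens[i] / sum(lens))))
  rd <- simulateReads(pools, 1500, seed = 41)$reads
  conf <- buildConformations(sim$genome, pair)
  cs <- countSupport(rd, conf)
  swapped <- pair
  swapped$a_start <- pair$b_start; swapped$a_end <- pair$b_end
  swapped$b_start <- pair$a_start; swapped$b_end <- pair$a_end
  cs2 <- countSupport(rd, buildConformations(sim$genome, swapped))
  expect_gte(cs$n_total, 1L)
  expect_identical(cs2$n_total, cs$n_total)
  expect_identical(c(cs2$n_alt1, cs2$n_alt2), c(cs$n_alt2, cs$n_alt1))
})

test_that("repeats at or above the insert cap are excluded from screening", {
  sim <- makeMitogenome(simConfig(seed = 42, genome_len = 25000L,
    genes = list(geneSpec("atp1", 1506)),
    repeats = data.frame(len = c(100L, 400L), identity = c(100, 100),
                         orientation = "direct", active = FALSE,
                         stringsAsFactors = FALSE),
    mtpt = list(count = 0L, len_range = c(150L, 300L), divergence = c(0, 0)),
    plastome_len = 8000L))
  rd <- simulateReads(sim$genome, 50, seed = 43)
  sup <- screenRepeats(sim$genome, sim$truth$repeats, rd$reads)
  expect_identical(nrow(sup), 1L)
  expect_identical(sup$rep_len, 100L)
})
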