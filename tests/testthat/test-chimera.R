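test_that("masking removes exactly the listed columns and keeps the map back", {
  m <- maskedAlignment(c(A = "ACGTACGTAC", B = "AC-TACGTAC", C = "ACGTACGTAC"))
  expect_identical(maskSites(m, NULL)@mat, m@mat)
  # position 5 on B's ungapped sequence is alignment column 6
  m2 <- maskSites(m, data.frame(taxon = "B", pos = 5))
  expect_identical(ncol(m2@mat), 9L)
  expect_identical(m2@masked, 6L)
  expect_identical(m2@colmap, c(1:5, 7:10))
  # round trip: current columns map back to original indices
  expect_identical(m2@colmap[match(7L, m2@colmap)], 7L)
  expect_error(maskSites(m, data.frame(taxon = "B", pos = 99)), "beyond")
})

test_that("short genes are excluded after masking, monotonically in the cut-off", {
  set.seed(61)
  mk <- function(n) maskedAlignment(
    rbind(A = sample(c("A", "C", "G", "T"), n, TRUE),
          B = sample(c("A", "C", "G", "T"), n, TRUE)))
  msas <- list(atp9 = mk(212), nad4L = mk(284), rps14 = mk(296),
               atp1 = mk(1480))
  fs <- filterShort(msas, 300)
  expect_setequal(fs$excluded$gene, c("atp9", "nad4L", "rps14"))
  expect_identical(names(fs$kept), "atp1")
  expect_identical(nrow(filterShort(msas, 0)$excluded), 0L)
  n_ex <- vapply(c(0, 213, 285, 297, 1481), function(ml)
    nrow(filterShort(msas, ml)$excluded), numeric(1))
  expect_true(all(diff(n_ex) >= 0))
})

test_that("identical sequences yield no conversion fragments", {
  s <- paste(rep("ACGT", 30), collapse = "")
  m <- maskedAlignment(c(A = s, B = s, C = s))
  expect_error(detectFragments(m), "polymorphic")
  # pairs with zero disagreement are skipped even when others vary
  set.seed(62)
  x <- rndDna(400)
  m2 <- maskedAlignment(c(A = x, B = x,
                          C = rndDna(400), D = rndDna(400)))
  fr <- detectFragments(m2, n_perm = 200, seed = 63, p_cutoff = 1.01)
  expect_false(any(fr$taxon1 == "A" & fr$taxon2 == "B"))
})

test_that("a planted donor tract is detected at the planted coordinates", {
  ev <- evolveClades(seed = 64)
  fr <- detectFragments(ev$msa, n_perm = 1000, seed = 65)
  expect_gt(nrow(fr), 0L)
  hit <- FALSE
  for (i in seq_len(nrow(fr))) {
    u <- colsToUngapped(ev$msa, "focal", c(fr$start_col[i], fr$end_col[i]))
    if (ivOverlapLen(u[1], u[2], 1138, 1487) >= 0.8 * 350) hit <- TRUE
  }
  expect_true(hit)
})

test_that("region splitting tiles the gene exactly", {
  r <- splitRegions(1506, c(1137, 1493))
  expect_identical(r$length, c(1137L, 356L, 13L))
  expect_identical(r$start, c(1L, 1138L, 1494L))
  expect_identical(r$end, c(1137L, 1493L, 1506L))
  expect_identical(splitRegions(500)$length, 500L)
  expect_error(splitRegions(100, c(50, 50)), "strictly increasing")
  expect_error(splitRegions(100, c(120)), "lie in")
  set.seed(66)
  for (i in 1:25) {
    n <- sample(50:5000, 1)
    bp <- sort(sample(n - 1, sample(0:5, 1)))
    rr <- splitRegions(n, bp)
    expect_identical(sum(rr$length), n)
    expect_identical(rr$start[-1], rr$end[-nrow(rr)] + 1L)
  }
})

test_that("even subdivision matches the comparand-length convention", {
  sp <- splitEven(c(1, 1137), 3, comparand_len = 356)
  expect_identical(sp$start, c(1L, 357L, 713L))
  expect_identical(sp$end, c(356L, 712L, 1137L))
  expect_identical(splitEven(c(1, 9), 3)$start, c(1L, 4L, 7L))
  set.seed(67)
  for (i in 1:25) {
    st <- sample(1000, 1); len <- sample(9:900, 1); k <- sample(1:4, 1)
    sp <- splitEven(c(st, st + len - 1), k)
    expect_identical(sp$start[1], st)
    expect_identical(sp$end[k], st + len - 1L)
    expect_identical(sum(sp$length), len)
    if (k > 1) expect_identical(sp$start[-1], sp$end[-k] + 1L)
  }
  expect_error(splitEven(c(1, 2), 3), "too short")
})

test_that("pairwise identity matches a column-count oracle", {
  set.seed(68)
  m <- maskedAlignment(rbind(
    F = sample(c("A", "C", "G", "T", "-"), 300, TRUE, prob = c(rep(0.24, 4), 0.04)),
    G = sample(c("A", "C", "G", "T", "-"), 300, TRUE, prob = c(rep(0.24, 4), 0.04)),
    H = sample(c("A", "C", "G", "T"), 300, TRUE)))
  ung <- sum(m@mat["F", ] != "-")
  for (i in 1:50) {
    a <- sample(ung - 5, 1); b <- a + sample(3:5, 1)
    got <- pairwiseIdentityRange(m, c(a, b), "F", c("G", "H"))
    keep <- which(m@mat["F", ] != "-")[a:b]
    for (g in c("G", "H")) {
      x <- m@mat["F", keep]; y <- m@mat[g, keep]
      ok <- x != "-" & y != "-"
      want <- if (sum(ok)) 100 * sum(x[ok] == y[ok]) / sum(ok) else NA_real_
      expect_equal(unname(got$per_taxon[g]), want)
    }
  }
  m2 <- maskedAlignment(c(F = "ACGT", G = "ACGT"))
  expect_equal(pairwiseIdentityRange(m2, c(1, 4), "F", "G")$range[2], 100)
  expect_error(pairwiseIdentityRange(m2, c(1, 4), "F", character(0)),
               "empty")
})

test_that("neighbor joining recovers topologies from additive distances", {
  set.seed(69)
  for (i in 1:15) {
    tips <- c("A", "B", "C", "D")
    top <- sample(c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));"), 1)
    tr <- ape::read.tree(text = top)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    d <- cophenetic(tr)[tips, tips]
    nj <- njTree(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(nj))), 0)
  }
})

test_that("bootstrap NJ recovers a simulated 4-taxon topology with high support", {
  clade <- list(topology = "((A:0.02,B:0.02):0.05,(C:0.02,D:0.02):0.05);",
                gene_len = 1200L, gc = 0.5, conversion = NULL)
  ev <- evolveClades(clade, seed = 70)
  tr <- njBootstrap(ev$msa, n_boot = 300, seed = 71)
  want <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(want))), 0)
  expect_gte(max(suppressWarnings(as.numeric(tr$node.label)), na.rm = TRUE),
             95)
})

test_that("identical sequences still produce a tree (zero-length tips)", {
  set.seed(72)
  x <- rndDna(300)
  mut <- function(s, n) {
    v <- strsplit(s, "")[[1]]
    at <- sample(length(v), n)
    v[at] <- vapply(v[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(v, collapse = "")
  }
  m <- maskedAlignment(c(A = x, B = x, C = mut(x, 30), D = mut(x, 60)))
  tr <- njBootstrap(m, n_boot = 50, seed = 73)
  expect_s3_class(tr, "phylo")
  ab <- match(c("A", "B"), tr$tip.label)
  lens <- tr$edge.length[match(ab, tr$edge[, 2])]
  expect_lte(max(abs(lens)), 1e-8)
})

test_that("origin verdicts follow the supported-clade membership rule", {
  native <- c("n1", "n2"); foreign <- list(don = c("f1", "f2"))
  mk <- function(txt) ape::read.tree(text = txt)
  t1 <- mk("((focal,n1)98,(f1,f2)90,n2);")
  oc <- assignOrigin(t1, "focal", native, foreign)
  expect_identical(oc$verdict, "native")
  expect_identical(oc$sister_group, "n1")
  expect_gte(oc$support, 70)
  t2 <- mk("((focal,f1)85,(n1,n2)92,f2);")
  oc2 <- assignOrigin(t2, "focal", native, foreign)
  expect_identical(oc2$verdict, "foreign")
  expect_identical(oc2$label, "don")
  # low support on the smallest clade walks outward; a mixed supported
  # clade (or the root) is unresolved
  t3 <- mk("((focal,f1)55,(n1,n2)92,f2);")
  expect_identical(assignOrigin(t3, "focal", native, foreign)$verdict,
                   "unresolved")
  t4 <- mk("(((focal,f1)55,n1)96,(n2,f2)50);")
  expect_identical(assignOrigin(t4, "focal", native, foreign)$verdict,
                   "unresolved")
  expect_error(assignOrigin(t1, "zz", native, foreign), "absent")
  expect_error(assignOrigin(t1, "focal", c(native, "f1"), foreign),
               "disjoint")
})
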