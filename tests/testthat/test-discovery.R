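# Discovery chain: self-alignment, piles, family calling. Toy genomes are
# built in code: unique background with exact planted copies forces the
# hit structure, so expected counts are known by construction.

toyGenome <- function(pieces) {
  Biostrings::DNAStringSet(c(chr1 = paste(pieces, collapse = "")))
}

test_that("random genome yields no self-alignment hits", {
  set.seed(101)
  g <- Biostrings::DNAStringSet(c(chr1 = randDna(50000)))
  expect_identical(nrow(selfAlignGenome(g)), 0L)
})

test_that("two exact copies give exactly one canonical hit pair", {
  set.seed(102)
  E <- randDna(600)
  g <- toyGenome(c(randDna(10000), E, randDna(5000), E, randDna(10000)))
  hits <- selfAlignGenome(g)
  expect_identical(nrow(hits), 1L)
  expect_equal(hits$startA, 10001, tolerance = 0.001)
  expect_equal(hits$endA, 10600, tolerance = 0.001)
  expect_equal(hits$startB, 15601, tolerance = 0.001)
  expect_gte(hits$identity, 0.99)
})

test_that("three exact copies give all three unordered copy pairs", {
  set.seed(103)
  E <- randDna(600)
  g <- toyGenome(c(randDna(8000), E, randDna(5000), E, randDna(5000), E,
                   randDna(8000)))
  hits <- selfAlignGenome(g)
  expect_identical(nrow(hits), 3L)
  # canonical ordering: footprint A precedes footprint B
  expect_true(all(hits$startA < hits$startB |
                    hits$seqA != hits$seqB))
})

test_that("genome shorter than the hit floor warns and returns empty", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAC"))
  expect_warning(h <- selfAlignGenome(g), "shorter")
  expect_identical(nrow(h), 0L)
})

test_that("piles merge overlapping footprints transitively", {
  mkHits <- function(ints) {
    # pair each interval with a partner far away so each contributes
    n <- length(ints)
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(seqA = "chr1", startA = ints[[i]][1], endA = ints[[i]][2],
                 seqB = "chr1", startB = 90000 + i * 3000,
                 endB = 90000 + i * 3000 + 500,
                 identity = 0.99, length = 500, score = 900,
                 strandRelation = "same")
    }))
  }
  # disjoint intervals -> separate piles (plus the partner piles)
  h <- mkHits(list(c(100, 700), c(2000, 2600)))
  p <- buildPiles(h)
  starts <- GenomicRanges::start(p)
  expect_true(all(c(100, 2000) %in% starts))
  expect_identical(length(p), 4L)
  # overlapping intervals merge
  h2 <- mkHits(list(c(100, 700), c(650, 1300)))
  p2 <- buildPiles(h2)
  merged <- p2[GenomicRanges::start(p2) == 100]
  expect_identical(GenomicRanges::end(merged), 1300L)
  # chain of 5 overlapping intervals -> single pile; matches union-find
  ints <- lapply(0:4, function(k) c(100 + k * 400, 700 + k * 400))
  h3 <- mkHits(ints)
  p3 <- buildPiles(h3)
  chain <- p3[GenomicRanges::start(p3) == 100]
  expect_identical(GenomicRanges::end(chain), 2300L)
  ids <- vapply(ints, function(iv) paste(iv, collapse = "-"), character(1))
  ovl <- which(outer(seq_along(ints), seq_along(ints), Vectorize(
    function(i, j) i < j && ints[[i]][2] >= ints[[j]][1] &&
      ints[[j]][2] >= ints[[i]][1])), arr.ind = TRUE)
  uf <- unionFind(ids, cbind(ids[ovl[, 1]], ids[ovl[, 2]]))
  expect_identical(length(uf), 1L)
})

test_that("family calling enforces the three-copy rule", {
  set.seed(104)
  E <- randDna(600)
  # two copies only: hits exist but no family
  g2 <- toyGenome(c(randDna(6000), E, randDna(5000), E, randDna(6000)))
  h2 <- selfAlignGenome(g2)
  f2 <- callFamilies(buildPiles(h2), h2, g2)
  expect_identical(length(f2$families), 0L)
  # three copies at ~98% mutual identity: one family of three
  g3 <- toyGenome(c(randDna(6000), mutateSeq(E, 0.01), randDna(5000),
                    mutateSeq(E, 0.01), randDna(5000), mutateSeq(E, 0.01),
                    randDna(6000)))
  h3 <- selfAlignGenome(g3)
  f3 <- callFamilies(buildPiles(h3), h3, g3)
  expect_identical(length(unique(S4Vectors::mcols(f3$families)$family)), 1L)
  expect_identical(length(f3$families), 3L)
  expect_identical(length(f3$sequences[["fam1"]]), 3L)
})

test_that("unrelated families never share members", {
  set.seed(105)
  A <- randDna(700); B <- randDna(550)
  g <- toyGenome(c(randDna(4000), A, randDna(3000), B, randDna(3000), A,
                   randDna(3000), B, randDna(3000), A, randDna(3000), B,
                   randDna(4000)))
  h <- selfAlignGenome(g)
  f <- callFamilies(buildPiles(h), h, g)
  fam <- S4Vectors::mcols(f$families)$family
  expect_identical(length(unique(fam)), 2L)
  expect_identical(as.integer(sort(table(fam))), c(3L, 3L))
  # members of different families do not overlap
  byFam <- split(f$families, fam)
  ov <- GenomicRanges::findOverlaps(byFam[[1]], byFam[[2]])
  expect_length(ov, 0)
})

test_that("discovery is invariant under scaffold order permutation", {
  set.seed(106)
  E <- randDna(600)
  s1 <- paste0(randDna(3000), E, randDna(3000), E, randDna(3000))
  s2 <- paste0(randDna(4000), E, randDna(4000))
  gA <- Biostrings::DNAStringSet(c(alpha = s1, beta = s2))
  gB <- Biostrings::DNAStringSet(c(beta = s2, alpha = s1))
  fA <- callFamilies(buildPiles(selfAlignGenome(gA)),
                     selfAlignGenome(gA), gA)
  fB <- callFamilies(buildPiles(selfAlignGenome(gB)),
                     selfAlignGenome(gB), gB)
  keyA <- sort(S4Vectors::mcols(fA$families)$member)
  keyB <- sort(S4Vectors::mcols(fB$families)$member)
  expect_identical(keyA, keyB)
})

test_that("hit tables dump in 12-column tabular form", {
  set.seed(107)
  E <- randDna(600)
  g <- toyGenome(c(randDna(5000), E, randDna(5000), E, randDna(5000)))
  h <- selfAlignGenome(g)
  f <- tempfile(fileext = ".tsv")
  writeSelfHits(h, f)
  back <- loadHitTable(f)
  expect_identical(nrow(back), nrow(h))
  expect_identical(ncol(back), 13L)  # 12 columns + positivity flag
})
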