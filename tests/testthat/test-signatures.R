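# Structural signatures: inverted repeats, direct repeats / LTR pairs,
# ORFs, PPT, PBS.

test_that("a planted perfect TIR is found with exact arms", {
  set.seed(401)
  tag <- randDna(25)
  seq <- paste0(tag, randDna(800), revcomp(tag))
  irs <- detectInvertedRepeats(seq)
  expect_gte(nrow(irs), 1)
  top <- irs[which.max(irs$armLen), ]
  # endpoints within the 2-nt recovery tolerance (the aligner may extend
  # an arm by chance complementarity in the flanks)
  expect_lte(abs(top$start1 - 1), 2)
  expect_lte(abs(top$end1 - 25), 2)
  expect_lte(abs(top$start2 - 826), 2)
  expect_lte(abs(top$end2 - 850), 2)
  expect_equal(top$identity, 1.0)
  expect_identical(top$geometry, "terminal")
})

test_that("random sequences yield no strong inverted repeats", {
  set.seed(402)
  for (rep in 1:10) {
    irs <- detectInvertedRepeats(randDna(800))
    strong <- irs[irs$armLen >= 15 & irs$identity >= 0.9, , drop = FALSE]
    expect_identical(nrow(strong), 0L)
  }
})

test_that("a perfect palindrome is one palindromic IR covering the seq", {
  set.seed(403)
  half <- randDna(30)
  pal <- paste0(half, revcomp(half))
  irs <- detectInvertedRepeats(pal)
  expect_gte(nrow(irs), 1)
  top <- irs[which.max(irs$armLen), ]
  expect_identical(top$geometry, "palindromic")
  expect_identical(top$start1, 1L)
  expect_identical(top$end2, 60L)
})

test_that("IR detection is strand-symmetric", {
  set.seed(404)
  tag <- randDna(20)
  seq <- paste0(randDna(100), tag, randDna(500), revcomp(tag),
                randDna(60))
  irs <- detectInvertedRepeats(seq)
  irsRc <- detectInvertedRepeats(revcomp(seq))
  L <- nchar(seq)
  expect_identical(nrow(irs), nrow(irsRc))
  # mirrored coordinates: arm at [s,e] maps to [L-e+1, L-s+1]
  mir <- data.frame(start1 = L - irsRc$end2 + 1, end1 = L - irsRc$start2 + 1,
                    start2 = L - irsRc$end1 + 1, end2 = L - irsRc$start1 + 1)
  o1 <- order(irs$start1); o2 <- order(mir$start1)
  expect_equal(irs$start1[o1], mir$start1[o2])
  expect_equal(irs$end2[o1], mir$end2[o2])
})

test_that("IR geometry labels follow the window rules", {
  ir <- list(start1 = 1, end1 = 25, start2 = 776, end2 = 800)
  expect_identical(classifyGeometry(ir, 800), "terminal")
  ir2 <- list(start1 = 200, end1 = 225, start2 = 500, end2 = 525)
  expect_identical(classifyGeometry(ir2, 800), "subterminal")
  # contiguous arms covering 58/60: palindromic by the coverage rule
  ir3 <- list(start1 = 2, end1 = 29, start2 = 30, end2 = 59)
  expect_identical(classifyGeometry(ir3, 60), "palindromic")
})

test_that("planted LTR pairs are detected with the expected identity", {
  set.seed(405)
  L <- randDna(150)
  seq <- paste0(L, randDna(3000), L)
  dr <- detectDirectRepeats(seq)
  expect_gte(nrow(dr), 1)
  top <- dr[1, ]
  expect_true(top$ltrCandidate)
  expect_equal(top$pairIdentity, 100)
  expect_identical(top$start5, 1L)
  expect_identical(top$start3, 3151L)
  # two substitutions in the 3' copy: ~98.7% pair identity
  L2 <- strsplit(L, "")[[1]]
  L2[30] <- setdiff(c("A", "C", "G", "T"), L2[30])[1]
  L2[90] <- setdiff(c("A", "C", "G", "T"), L2[90])[1]
  seq2 <- paste0(L, randDna(3000), paste(L2, collapse = ""))
  dr2 <- detectDirectRepeats(seq2)
  expect_gte(nrow(dr2), 1)
  expect_equal(dr2$pairIdentity[1], 100 * 148 / 150, tolerance = 0.01)
  # repeat-free sequence: empty
  expect_identical(nrow(detectDirectRepeats(randDna(3000))), 0L)
})

test_that("LTR arm identity is computed over alignment columns", {
  set.seed(406)
  arm <- randDna(149)
  seq <- paste0(arm, randDna(2000), arm)
  pair <- list(start5 = 1L, end5 = 149L, start3 = 2150L, end3 = 2298L)
  expect_equal(ltrPairIdentity(seq, pair), 100)
  # one mismatch in a 149-nt arm: 148/149
  armM <- strsplit(arm, "")[[1]]
  armM[75] <- setdiff(c("A", "C", "G", "T"), armM[75])[1]
  seqM <- paste0(arm, randDna(2000), paste(armM, collapse = ""))
  expect_equal(ltrPairIdentity(seqM, pair), 100 * 148 / 149,
               tolerance = 1e-6)
  # a 1-nt deletion: identity counted over columns including the gap
  armD <- paste(strsplit(arm, "")[[1]][-75], collapse = "")
  seqD <- paste0(arm, randDna(2000), armD, "A")
  pairD <- list(start5 = 1L, end5 = 149L, start3 = 2150L, end3 = 2297L)
  got <- ltrPairIdentity(seqD, pairD)
  oracle <- {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(arm), Biostrings::DNAString(armD),
      type = "global", gapOpening = 10, gapExtension = 4)
    as.numeric(Biostrings::pid(aln, type = "PID1"))
  }
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("ORF scan matches the code table on fixed cases", {
  o <- findOrfs("ATGAAATAA", minLenNt = 3)
  plus1 <- o[o$frame == 1, ]
  expect_identical(plus1$aa, "MK")
  expect_equal(plus1$start, 1)
  expect_equal(plus1$end, 6)
  # reverse complement: same ORF on frame -1
  o2 <- findOrfs(revcomp("ATGAAATAA"), minLenNt = 3)
  minus1 <- o2[o2$frame == -1 & o2$aa == "MK", ]
  expect_identical(nrow(minus1), 1L)
  expect_equal(minus1$lengthNt, 6)
})

test_that("ORF scan equals the brute-force six-frame oracle", {
  set.seed(407)
  for (rep in 1:25) {
    s <- randDna(sample(300:900, 1))
    minLen <- sample(c(30, 60, 90), 1)
    got <- findOrfs(s, minLen)
    want <- oracleOrfs(s, minLen)
    expect_identical(nrow(got), length(want))
    if (length(want)) {
      wantKey <- sort(vapply(want, function(x)
        paste(x["frame"], x["len"]), character(1)))
      gotKey <- sort(paste(got$frame, got$lengthNt))
      expect_identical(gotKey, wantKey)
    }
    # every reported ORF translates without stops and at 3x aa length
    if (nrow(got)) {
      expect_false(any(grepl("\\*", got$aa)))
      expect_identical(got$lengthNt, 3L * got$lengthAa)
    }
  }
})

test_that("PPT detection respects run and window rules", {
  set.seed(408)
  ltr <- randDna(100)
  # purine block directly upstream of the 3' LTR
  seq <- paste0(ltr, randDna(500), "TTCTTAGGGAGGAA", ltr)
  pair <- list(start5 = 1L, end5 = 100L,
               start3 = 615L, end3 = 714L)
  ppt <- detectPpt(seq, pair)
  expect_equal(ppt$length, 9)  # AGGGAGGAA
  expect_equal(ppt$end, 614)
  # pyrimidine-rich window: nothing
  seq2 <- paste0(ltr, randDna(500), "TTCTTCTTCTTCTT", ltr)
  expect_null(detectPpt(seq2, pair))
  # run straddling the window edge: only the in-window part counts
  seq3 <- paste0(ltr, randDna(480), strrep("A", 30),
                 substr(ltr, 1, 100))
  pair3 <- list(start5 = 1L, end5 = 100L, start3 = 611L, end3 = 710L)
  ppt3 <- detectPpt(seq3, pair3, minRun = 8, window = 20)
  expect_equal(ppt3$length, 20)  # clipped to the window
})

test_that("PBS detection reports all qualifying tRNAs", {
  set.seed(409)
  trnas <- Biostrings::DNAStringSet(c(trnaA = randDna(72),
                                      trnaB = randDna(72)))
  tail18 <- function(i) substr(as.character(trnas[[i]]), 55, 72)
  ltr <- randDna(120)
  pbsSeq <- revcomp(tail18(1))
  seq <- paste0(ltr, pbsSeq, randDna(800), ltr)
  pair <- list(start5 = 1L, end5 = 120L, start3 = 939L, end3 = 1058L)
  pbs <- detectPbs(seq, pair, trnas)
  expect_identical(pbs$trna, "trnaA")
  expect_identical(pbs$matchLen, 18L)
  expect_identical(pbs$start, 121L)
  # no complementarity: empty
  seq2 <- paste0(ltr, randDna(900), ltr)
  expect_identical(nrow(detectPbs(seq2, pair, trnas)), 0L)
  # empty library: warning and skip
  expect_warning(res <- detectPbs(seq, pair, NULL), "skipped")
  expect_identical(nrow(res), 0L)
  # two tRNAs sharing the planted 3' end: both reported
  trnas2 <- Biostrings::DNAStringSet(c(
    trnaA = as.character(trnas[[1]]),
    trnaC = paste0(randDna(54), tail18(1))))
  pbs2 <- detectPbs(seq, pair, trnas2)
  expect_setequal(pbs2$trna, c("trnaA", "trnaC"))
})
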