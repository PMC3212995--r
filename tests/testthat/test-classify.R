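# The classification decision ladder and element-type labels.

mkHom <- function(role, best = "ref1", e = 1e-30, positive = TRUE) {
  list(role = role, library = role,
       summary = data.frame(e_value = e, best_match = best, score = 500,
                            positive = positive))
}

emptyIrs <- function() {
  data.frame(start1 = integer(0), end1 = integer(0), start2 = integer(0),
             end2 = integer(0), armLen = integer(0), identity = numeric(0),
             evalue = numeric(0), geometry = character(0))
}

terminalIrs <- function(L, arm = 25L) {
  data.frame(start1 = 1L, end1 = arm, start2 = L - arm + 1L, end2 = L,
             armLen = arm, identity = 1, evalue = 1e-9,
             geometry = "terminal")
}

ltrPairRow <- function(L, arm = 150L) {
  data.frame(start5 = 1L, end5 = arm, start3 = L - arm + 1L, end3 = L,
             length = arm, pairIdentity = 100, evalue = 1e-30,
             ltrCandidate = TRUE)
}

bigOrf <- function(nt = 3900L) {
  data.frame(frame = 1L, start = 200L, end = 200L + nt - 1L,
             lengthNt = nt, lengthAa = nt / 3,
             aa = strrep("K", nt / 3), stringsAsFactors = FALSE)
}

test_that("LTR pair plus RVT evidence classifies as class I / LTR", {
  feats <- list(irs = emptyIrs(), directRepeats = ltrPairRow(4500),
                orfs = bigOrf(), consensusLen = 4500,
                homology = list(rvt = mkHom("rvt")))
  cls <- classifyCluster(feats)
  expect_identical(cls$te_class, "I")
  expect_identical(cls$te_order, "LTR")
  rules <- vapply(cls$evidence, `[[`, character(1), "rule")
  expect_true("LTR" %in% rules)
  expect_gte(length(cls$evidence), 1)
})

test_that("RVT without direct repeats classifies as NLTR, not LTR", {
  feats <- list(irs = emptyIrs(), directRepeats = NULL, orfs = bigOrf(900),
                consensusLen = 3000,
                homology = list(rvt = mkHom("rvt"),
                                nltr = list(role = "nltr_known",
                                            library = "nltr",
                                            summary = data.frame(
                                              e_value = 1e-40,
                                              best_match = "NL1",
                                              score = 800,
                                              positive = TRUE))))
  cls <- classifyCluster(feats)
  expect_identical(cls$te_class, "I")
  expect_identical(cls$te_order, "NLTR")
  expect_identical(cls$family, "NL1")
})

test_that("TIRs plus transposase classify as class II", {
  feats <- list(irs = terminalIrs(1800), directRepeats = NULL,
                orfs = bigOrf(800), consensusLen = 1800,
                homology = list(tp = mkHom("transposase")))
  cls <- classifyCluster(feats)
  expect_identical(cls$te_class, "II")
  expect_identical(cls$te_order, "TIR")
})

test_that("sole rRNA hits are non-TE", {
  feats <- list(irs = emptyIrs(), directRepeats = NULL,
                orfs = bigOrf(300), consensusLen = 1500,
                homology = list(rrna = mkHom("rrna")))
  cls <- classifyCluster(feats)
  expect_identical(cls$te_class, "non-TE")
  expect_identical(cls$element_type, "rRNA")
})

test_that("short TIR element with no hits is MITE-like novel", {
  set.seed(601)
  tir <- randDna(20)
  cons <- paste0(tir, randDna(410), revcomp(tir))
  feats <- list(irs = terminalIrs(450, 20L), directRepeats = NULL,
                orfs = data.frame(frame = 1L, start = 1L, end = 120L,
                                  lengthNt = 120L, lengthAa = 40L,
                                  aa = strrep("A", 40)),
                consensusLen = 450, consensus = cons, homology = list())
  cls <- classifyCluster(feats)
  expect_identical(cls$element_type, "MITE-like-novel")
  expect_identical(cls$te_class, "II")
})

test_that("TIRs matching a known family yield a MITE call", {
  set.seed(602)
  tir <- randDna(22)
  cons <- paste0(tir, randDna(430), revcomp(tir))
  feats <- list(irs = terminalIrs(474, 22L), directRepeats = NULL,
                orfs = data.frame(frame = 1L, start = 1L, end = 90L,
                                  lengthNt = 90L, lengthAa = 30L,
                                  aa = strrep("A", 30)),
                consensusLen = 474, consensus = cons,
                homology = list(),
                knownTirs = Biostrings::DNAStringSet(c(TIRFAM = tir)))
  cls <- classifyCluster(feats)
  expect_identical(cls$element_type, "MITE")
  expect_identical(cls$family, "TIRFAM")
})

test_that("classification is invariant to homology list order", {
  feats <- list(irs = terminalIrs(1800), directRepeats = NULL,
                orfs = bigOrf(800), consensusLen = 1800,
                homology = list(tp = mkHom("transposase"),
                                x = mkHom("classii_known", "CII")))
  cls1 <- classifyCluster(feats)
  feats$homology <- rev(feats$homology)
  cls2 <- classifyCluster(feats)
  expect_identical(cls1$te_class, cls2$te_class)
  expect_identical(cls1$te_order, cls2$te_order)
  expect_identical(cls1$family, cls2$family)
})

test_that("element-type bands follow canonical coverage", {
  set.seed(603)
  canonical <- Biostrings::DNAStringSet(c(can = randDna(5000)))
  full <- assignElementType(as.character(canonical[[1]]), canonical)
  expect_identical(full$element_type, "full")
  expect_equal(full$coverage, 1.0, tolerance = 0.01)
  remn <- assignElementType(substr(as.character(canonical[[1]]), 1, 300),
                            canonical)
  expect_identical(remn$element_type, "remnant")
  expect_equal(remn$coverage, 0.06, tolerance = 0.01)
  frag <- assignElementType(substr(as.character(canonical[[1]]), 1, 2500),
                            canonical)
  expect_identical(frag$element_type, "fragment")
  expect_equal(frag$coverage, 0.5, tolerance = 0.01)
  # structural fallback without a canonical element
  featsFull <- list(directRepeats = ltrPairRow(4000), orfs = bigOrf())
  expect_identical(assignElementType(randDna(4000), NULL,
                                     featsFull)$element_type, "full")
})

test_that("Solo-LTR detection needs arm identity, coverage and short length", {
  set.seed(604)
  arm <- randDna(150)
  arms <- Biostrings::DNAStringSet(c(FAM1 = arm))
  expect_true(detectSoloLtr(arm, arms)$solo)
  # an LTR with a 50-nt flank still qualifies (<= 1.5 x arm)
  expect_true(detectSoloLtr(paste0(arm, randDna(50)), arms)$solo)
  # a full element fails the length test
  fullEl <- paste0(arm, randDna(2500), arm)
  expect_false(detectSoloLtr(fullEl, arms)$solo)
  expect_false(detectSoloLtr(randDna(150), arms)$solo)
})

test_that("TIR subfamily linking groups shared TIRs with alien interiors", {
  set.seed(605)
  tir <- randDna(25)
  mk <- function() paste0(tir, randDna(400), revcomp(tir))
  consA <- mk(); consB <- mk()
  tirX <- randDna(25)
  consC <- paste0(tirX, randDna(400), revcomp(tirX))
  tirs <- list(
    A = Biostrings::DNAStringSet(c(t1 = tir)),
    B = Biostrings::DNAStringSet(c(t1 = tir)),
    C = Biostrings::DNAStringSet(c(t1 = tirX)))
  consensi <- Biostrings::DNAStringSet(c(A = consA, B = consB, C = consC))
  groups <- linkTirSubfamilies(tirs, consensi)
  expect_identical(groups, list(c("A", "B")))
  # three clusters with chained TIR identity: one group of three
  consD <- mk()
  tirs$D <- Biostrings::DNAStringSet(c(t1 = tir))
  consensi <- c(consensi, Biostrings::DNAStringSet(c(D = consD)))
  groups2 <- linkTirSubfamilies(tirs, consensi)
  expect_identical(groups2, list(c("A", "B", "D")))
})
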