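# Progressive alignment, consensus, centroid, truncation profile.

test_that("aligner parameter contract is validated", {
  p <- alignerParams()
  expect_equal(p@gapOpen, -500)
  expect_equal(p@gapExtend, -50)
  expect_equal(p@center, -1)
  expect_error(alignerParams(gapOpen = -10, gapExtend = -50), "gapOpen")
  expect_error(alignerParams(gapExtend = 5), "gapOpen")
})

test_that("identical sequences align gap-free at input width", {
  set.seed(301)
  s <- randDna(120)
  m <- Biostrings::DNAStringSet(setNames(rep(s, 3), paste0("m", 1:3)))
  aln <- progressiveAlign(m)
  mat <- as.matrix(aln)
  expect_identical(ncol(mat), 120L)
  expect_false(any(mat == "-"))
  expect_identical(buildConsensus(aln), s)
})

test_that("exact 3'-fragments left-pad with terminal gaps, no mismatches", {
  set.seed(302)
  full <- randDna(1000)
  m <- Biostrings::DNAStringSet(c(F = full,
                                  f1 = substr(full, 401, 1000),
                                  f2 = substr(full, 501, 1000)))
  aln <- progressiveAlign(m)
  mat <- as.matrix(aln)
  expect_identical(ncol(mat), 1000L)
  expect_identical(paste(mat["f1", 401:1000], collapse = ""),
                   substr(full, 401, 1000))
  expect_true(all(mat["f1", 1:400] == "-"))
  expect_true(all(mat["f2", 1:500] == "-"))
  mmCols <- sum(apply(mat, 2, function(cc) {
    b <- cc[cc != "-"]; length(unique(b)) > 1
  }))
  expect_identical(mmCols, 0L)
})

test_that("alignment rows de-gap back to their inputs; width >= longest", {
  set.seed(303)
  for (rep in 1:5) {
    base <- randDna(sample(300:600, 1))
    n <- sample(3:6, 1)
    seqs <- vapply(seq_len(n), function(i) {
      s <- mutateSeq(base, 0.05)
      if (runif(1) < 0.5) s <- substr(s, sample(1:100, 1), nchar(s))
      s
    }, character(1))
    names(seqs) <- paste0("s", seq_len(n))
    m <- Biostrings::DNAStringSet(seqs)
    aln <- progressiveAlign(m)
    mat <- as.matrix(aln)
    expect_gte(ncol(mat), max(width(m)))
    for (i in seq_len(n)) {
      degap <- paste(mat[names(seqs)[i], mat[names(seqs)[i], ] != "-"],
                     collapse = "")
      expect_identical(degap, unname(seqs[i]))
    }
  }
})

test_that("progressiveAlign rejects singletons", {
  m <- Biostrings::DNAStringSet(c(a = "ACGTACGT"))
  expect_error(progressiveAlign(m), "at least 2")
})

test_that("consensus column rules match direct counting on contract cases", {
  # 4-row column: A,A,C + terminal gap; A wins 2/3 of spanning rows,
  # spanning 3/4 >= half -> uppercase A
  mat <- rbind(c("A", "C"), c("A", "C"), c("C", "C"), c("-", "C"))
  rownames(mat) <- paste0("r", 1:4)
  cons <- buildConsensus(mat)
  expect_identical(substr(cons, 1, 1), "A")
  # 4-row column A,A,C,C: no majority -> plurality tie, alphabetical,
  # lowercase
  mat2 <- rbind(c("A", "G"), c("A", "G"), c("C", "G"), c("C", "G"))
  rownames(mat2) <- paste0("r", 1:4)
  expect_identical(buildConsensus(mat2), "aG")
})

test_that("consensus equals the counting oracle on randomized alignments", {
  set.seed(304)
  for (rep in 1:30) {
    n <- sample(3:7, 1); W <- sample(10:40, 1)
    mat <- matrix(sample(c("A", "C", "G", "T", "-"), n * W, TRUE,
                         prob = c(0.22, 0.22, 0.22, 0.22, 0.12)),
                  n, W, dimnames = list(paste0("r", 1:n), NULL))
    # impose some terminal gap runs
    for (i in seq_len(n)) {
      if (runif(1) < 0.5) mat[i, seq_len(sample(0:5, 1))] <- "-"
      if (runif(1) < 0.5)
        mat[i, W - seq_len(sample(0:5, 1)) + 1] <- "-"
    }
    expect_identical(buildConsensus(mat), oracleConsensus(mat),
                     info = paste("replicate", rep))
  }
})

test_that("a consensus over identical rows is the sequence itself", {
  set.seed(305)
  s <- randDna(200)
  mat <- matrix(rep(strsplit(s, "")[[1]], 4), nrow = 4, byrow = TRUE,
                dimnames = list(paste0("r", 1:4), NULL))
  expect_identical(buildConsensus(mat), s)
})

test_that("centroid is the all-to-all score argmax; ties are canonical", {
  set.seed(306)
  # identical members: first id by the tie rule
  s <- randDna(500)
  m <- Biostrings::DNAStringSet(setNames(rep(s, 3), c("b", "a", "c")))
  expect_identical(selectCentroid(m), "a")
  # full-length member dominates its own fragments
  full <- randDna(1500)
  m2 <- Biostrings::DNAStringSet(c(f1 = substr(full, 501, 1500),
                                   F = full,
                                   f2 = substr(full, 1, 900)))
  # oracle score matrix from exhaustive pairwise local alignment
  ids <- names(m2)
  sm <- matrix(0, 3, 3, dimnames = list(ids, ids))
  for (i in 1:2) for (j in (i + 1):3) {
    sc <- Biostrings::pairwiseAlignment(m2[[ids[i]]], m2[[ids[j]]],
                                        type = "local")@score
    sm[i, j] <- sc; sm[j, i] <- sc
  }
  expect_identical(selectCentroid(m2, sm), "F")
  expect_identical(selectCentroid(m2), "F")
  # invariance under member order permutation
  expect_identical(selectCentroid(rev(m2)), "F")
})

test_that("consensus/centroid comparison reports identity and ratio", {
  set.seed(307)
  s <- randDna(600)
  res <- compareConsensusCentroid(s, s)
  expect_equal(res$identity, 1.0)
  expect_equal(res$lengthRatio, 1.0)
  # centroid a strict substring of consensus
  res2 <- compareConsensusCentroid(s, substr(s, 101, 500))
  expect_equal(res2$identity, 1.0)
  expect_gt(res2$lengthRatio, 1)
  # unrelated pair: any reported identity comes with low coverage
  res3 <- compareConsensusCentroid(randDna(600), randDna(600))
  if (!is.na(res3$identity)) expect_lt(res3$coverage, 0.5)
})

test_that("truncation profile equals the regex run oracle", {
  gapFree <- matrix(sample(c("A", "C"), 30, TRUE), nrow = 3,
                    dimnames = list(paste0("r", 1:3), NULL))
  tp <- truncationProfile(gapFree)
  expect_true(all(tp$table$leading == 0) && all(tp$table$trailing == 0))

  mat <- rbind(strsplit("----ACGT", "")[[1]])
  rownames(mat) <- "x"
  tp2 <- truncationProfile(mat)
  expect_identical(tp2$table$leading, 4L)
  expect_identical(tp2$table$trailing, 0L)

  set.seed(308)
  for (rep in 1:100) {
    row <- paste(sample(c("A", "C", "G", "T", "-"), 40, TRUE), collapse = "")
    m <- matrix(strsplit(row, "")[[1]], nrow = 1,
                dimnames = list("r", NULL))
    got <- truncationProfile(m)$table
    want <- oracleGapRuns(row)
    expect_identical(c(got$leading, got$trailing),
                     unname(as.integer(want)))
  }
})

test_that("length statistics follow the member set", {
  m <- Biostrings::DNAStringSet(c(a = strrep("A", 100),
                                  b = strrep("C", 80),
                                  c = strrep("G", 50)))
  ls <- lengthStats(m, strrep("A", 90))
  expect_identical(ls$longest, 100L)
  expect_identical(ls$shortest, 50L)
  expect_identical(ls$consensus_len, 90L)
  expect_equal(ls$ratio, 2)
})

test_that("end trimming drops only ragged end columns and logs", {
  mat <- do.call(rbind, c(replicate(5, strsplit("--ACGT--", "")[[1]],
                                    simplify = FALSE),
                          list(strsplit("AAACGTAA", "")[[1]])))
  rownames(mat) <- paste0("r", 1:6)
  expect_message(tr <- trimAlignmentEnds(mat), "trimmed")
  expect_identical(ncol(as.matrix(tr)), 4L)
})
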