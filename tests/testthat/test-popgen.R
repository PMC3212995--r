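# Evolutionary statistics: p-distance, Nei-Gojobori dN/dS, Tajima's D.

test_that("p-distance handles fixed cases and pairwise deletion", {
  mat <- matrix(strsplit(paste0(strrep("ACGT", 25), strrep("ACGT", 25)),
                         "")[[1]], nrow = 2, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
  res <- pDistance(mat)
  expect_equal(res$mean_p, 0)
  expect_equal(res$sd_p, 0)
  expect_identical(res$n_pairs, 1L)
  # one difference among 100 comparable sites
  mat2 <- mat
  mat2["b", 10] <- setdiff(c("A", "C", "G", "T"), mat2["b", 10])[1]
  expect_equal(pDistance(mat2)$mean_p, 0.01)
  # gap and N columns are deleted pairwise
  mat3 <- mat2
  mat3["a", 1:10] <- "-"
  mat3["b", 11:15] <- "N"
  expect_equal(pDistance(mat3)$mean_p, 0)  # the mismatch sat in col 10
})

test_that("p-distance equals the counting oracle on simulated rows", {
  set.seed(701)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    base <- strsplit(randDna(200), "")[[1]]
    mat <- do.call(rbind, lapply(seq_len(n), function(i) {
      r <- base
      mut <- runif(200) < 0.05
      r[mut] <- sample(c("A", "C", "G", "T", "-", "N"), sum(mut), TRUE)
      r
    }))
    rownames(mat) <- paste0("s", 1:n)
    got <- pDistance(mat)
    want <- oraclePDist(mat)
    expect_equal(got$mean_p, mean(want), tolerance = 1e-12)
    expect_equal(got$sd_p, sqrt(mean((want - mean(want))^2)),
                 tolerance = 1e-12)
    expect_identical(got$n_pairs, length(want))
  }
})

test_that("NG86 codon counting matches the code table on canonical pairs", {
  # identical ORFs: no substitutions at all
  m0 <- matrix(strsplit("TTTAAAGGG", "")[[1]], nrow = 2, ncol = 9,
               byrow = TRUE, dimnames = list(c("a", "b"), NULL))
  r0 <- neiGojobori(m0)
  expect_equal(r0$dN, 0); expect_equal(r0$dS, 0)
  expect_true(is.na(r0$ratio))
  # TTT -> TTC (Phe -> Phe): one synonymous difference
  m1 <- rbind(strsplit("TTT", "")[[1]], strsplit("TTC", "")[[1]])
  rownames(m1) <- c("a", "b")
  r1 <- neiGojobori(m1)
  expect_equal(r1$Sd, 1); expect_equal(r1$Nd, 0)
  # site counts: TTT has 1/3 synonymous site at position 3
  expect_equal(oracleSynSites("TTT"), 1 / 3)
  expect_equal(r1$S, (oracleSynSites("TTT") + oracleSynSites("TTC")) / 2)
  # TTT -> GTT (Phe -> Val): one nonsynonymous difference
  m2 <- rbind(strsplit("TTT", "")[[1]], strsplit("GTT", "")[[1]])
  rownames(m2) <- c("a", "b")
  r2 <- neiGojobori(m2)
  expect_equal(r2$Sd, 0); expect_equal(r2$Nd, 1)
})

test_that("NG86 pathway averaging equals the enumeration oracle", {
  set.seed(702)
  bases <- c("A", "C", "G", "T")
  code <- Biostrings::GENETIC_CODE
  for (rep in 1:50) {
    c1 <- paste(sample(bases, 3, TRUE), collapse = "")
    c2 <- paste(sample(bases, 3, TRUE), collapse = "")
    if (code[c1] == "*" || code[c2] == "*") next
    m <- rbind(strsplit(c1, "")[[1]], strsplit(c2, "")[[1]])
    rownames(m) <- c("a", "b")
    got <- neiGojobori(m)
    want <- oracleCodonPair(c1, c2)
    expect_equal(got$Sd, unname(want["Sd"]), tolerance = 1e-12,
                 info = paste(c1, c2))
    expect_equal(got$Nd, unname(want["Nd"]), tolerance = 1e-12,
                 info = paste(c1, c2))
  }
})

test_that("gapped and stop codons are excluded pairwise", {
  m <- rbind(strsplit("TTT---AAATAA", "")[[1]],
             strsplit("TTCAAAAAGTAA", "")[[1]])
  rownames(m) <- c("a", "b")
  r <- neiGojobori(m)
  # only codons 1 (TTT/TTC, synonymous) and 3 (AAA/AAG, synonymous)
  # compare; codon 2 has a gap, codon 4 is a stop in both
  expect_equal(r$Sd, 2)
  expect_equal(r$Nd, 0)
})

test_that("dS >= dN whenever the synonymous proportion dominates", {
  set.seed(703)
  for (rep in 1:20) {
    n <- sample(4:6, 1)
    anc <- vapply(seq_len(60), function(i) {
      repeat {
        cod <- paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = "")
        if (Biostrings::GENETIC_CODE[cod] != "*") return(cod)
      }
    }, character(1))
    mat <- do.call(rbind, lapply(seq_len(n), function(i) {
      s <- strsplit(paste(anc, collapse = ""), "")[[1]]
      mut <- sample(180, 5)
      for (p in mut) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
      s
    }))
    rownames(mat) <- paste0("s", 1:n)
    r <- neiGojobori(mat)
    if (!is.na(r$ratio) && r$Sd / r$S >= r$Nd / r$N)
      expect_gte(r$dS, r$dN)
  }
})

test_that("Tajima's D matches the direct formula and handles S = 0", {
  # hand-built alignment, n = 4: columns with known S and pi
  mat <- rbind(strsplit("AAAAAAAAAA", "")[[1]],
               strsplit("AAAAAAAAAG", "")[[1]],
               strsplit("AAAAAAAAGG", "")[[1]],
               strsplit("CAAAAAAAGG", "")[[1]])
  rownames(mat) <- paste0("s", 1:4)
  got <- tajimaD(mat)
  expect_identical(got$S, 3L)
  # pairwise differences: computed by direct counting
  pd <- 0; for (i in 1:3) for (j in (i + 1):4)
    pd <- pd + sum(mat[i, ] != mat[j, ])
  pi <- pd / 6
  expect_equal(got$pi, pi, tolerance = 1e-12)
  expect_equal(got$D, oracleTajimaD(4, 3, pi), tolerance = 1e-10)
  # S = 0: NaN flag, not significant
  m0 <- matrix("A", 4, 10, dimnames = list(paste0("s", 1:4), NULL))
  r0 <- tajimaD(m0)
  expect_true(is.nan(r0$D))
  expect_false(r0$significant)
  expect_error(tajimaD(mat[1:3, ]), "at least 4")
})

test_that("statistics are invariant under row permutation", {
  set.seed(704)
  base <- strsplit(randDna(120), "")[[1]]
  mat <- do.call(rbind, lapply(1:6, function(i) {
    r <- base; mut <- sample(120, 3)
    for (p in mut) r[p] <- sample(setdiff(c("A", "C", "G", "T"), r[p]), 1)
    r
  }))
  rownames(mat) <- paste0("s", 1:6)
  perm <- mat[sample(6), ]
  expect_equal(pDistance(mat)$mean_p, pDistance(perm)$mean_p)
  expect_equal(tajimaD(mat)$D, tajimaD(perm)$D)
  expect_equal(neiGojobori(mat)$dN, neiGojobori(perm)$dN)
})
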