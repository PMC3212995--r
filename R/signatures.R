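## Structural TE signatures: inverted repeats (terminal/subterminal/
## palindromic), direct terminal repeats (LTR candidates), six-frame ORFs,
## polypurine tract (PPT) and primer-binding site (PBS). The IR/LTR scans
## follow the classic recipe: blast the sequence against itself and read
## minus-strand hits as inverted repeats and off-diagonal plus-strand hits
## as direct repeats.

# Outward/inward endpoint refinement. Local alignment trims terminal
# mismatches, so a detected arm systematically stops a few nt short of the
# biological boundary whenever the boundary positions diverged. Starting
# from a detected endpoint pair, walk the two paired positions outward
# (or inward) scoring +1 for a (complementary) match and -1 otherwise, and
# move the endpoint to the farthest position attaining the running maximum.
# Balanced mismatch/match tails are thereby recovered; walks into random
# flank drift negative and are rejected.
.extendPaired <- function(ch, i, j, di, dj, comp, maxSteps = 40L,
                          ties = TRUE) {
  n <- length(ch)
  best <- 0L; bestK <- 0L; score <- 0L
  compOf <- c(A = "T", C = "G", G = "C", T = "A", N = "X")
  for (k in seq_len(maxSteps)) {
    ii <- i + di * k; jj <- j + dj * k
    if (ii < 1 || ii > n || jj < 1 || jj > n) break
    a <- ch[ii]
    b <- if (comp) compOf[[ch[jj]]] else ch[jj]
    score <- score + (if (!is.na(a) && a == b) 1L else -1L)
    if (if (ties) score >= best else score > best) {
      best <- score; bestK <- k
    }
    if (score < best - 6L) break
  }
  bestK
}

# Anchored terminal-repeat scan. Short, diverged TIR arms (say 15 nt with
# one or two substitutions) can never reach e-value significance in a free
# local self-scan -- score-equivalent chance patterns are common anywhere
# on a long sequence. Anchoring the comparison at the two sequence ends
# removes the positional search space: walk k = 1..maxArm pairing position
# k with L+1-k (complementary), track the cumulative +1/-1 score, and take
# the arm at the score maximum (strict improvement only, so the walk does
# not wander into the interior). The candidate is kept if the arm passes
# the length/identity floors and a binomial significance bound.
.anchoredTirScan <- function(ch, minArm, minArmIdentity, maxExpect,
                             maxArm = 250L) {
  L <- length(ch)
  compOf <- c(A = "T", C = "G", G = "C", T = "A", N = "X")
  lim <- min(maxArm, L %/% 2)
  if (lim < minArm) return(NULL)
  score <- 0L; best <- 0L; bestK <- 0L; matches <- 0L; bestM <- 0L
  for (k in seq_len(lim)) {
    hit <- !is.na(ch[k]) && ch[k] == compOf[[ch[L + 1L - k]]]
    matches <- matches + hit
    score <- score + (if (hit) 1L else -1L)
    if (score > best) { best <- score; bestK <- k; bestM <- matches }
    if (score < best - 8L) break
  }
  if (bestK < minArm) return(NULL)
  ident <- bestM / bestK
  if (ident < minArmIdentity) return(NULL)
  # single anchored comparison: chance probability of >= bestM matches
  pTail <- stats::pbinom(bestM - 1L, bestK, 0.25, lower.tail = FALSE)
  if (pTail > min(maxExpect, 1e-4)) return(NULL)
  data.frame(start1 = 1L, end1 = bestK, start2 = L - bestK + 1L,
             end2 = L, armLen = bestK, identity = ident, evalue = pTail)
}

.asDNAStringSet1 <- function(seq, name = "seq") {
  if (is(seq, "DNAStringSet")) {
    if (is.null(names(seq))) names(seq) <- name
    return(seq[1])
  }
  x <- Biostrings::DNAStringSet(toupper(as.character(seq)))
  names(x) <- name
  x
}

#' Detect inverted repeats by self-comparison on the minus strand
#'
#' Minus-strand local self-alignments map arm pairs where the right arm is
#' the reverse complement of the left. Mirrored duplicate reports are
#' collapsed to one IR. Significance is controlled by the aligner's
#' length-adaptive e-value (\code{maxExpect}) in addition to the arm
#' length/identity floor: a fixed floor alone cannot separate real short
#' arms on sub-kilobase elements from chance matches on long sequences.
#'
#' @param seq a DNA sequence (character, \code{DNAString} or 1-element
#'   \code{DNAStringSet}).
#' @param minArm minimum arm length in nt (default 10).
#' @param minArmIdentity minimum arm identity fraction (default 0.80).
#' @param maxExpect e-value ceiling for reported arms (default 1e-3).
#' @param refineEnds polish arm endpoints with the paired outward/inward
#'   walk (default TRUE); local alignment alone trims boundary mismatches.
#' @return data.frame(start1, end1, start2, end2, armLen, identity, evalue,
#'   geometry) with 1-based closed arm intervals, arm1 left of arm2;
#'   geometry from \code{\link{classifyGeometry}}.
#' @export
detectInvertedRepeats <- function(seq, minArm = 10, minArmIdentity = 0.80,
                                  maxExpect = 1e-3, refineEnds = TRUE) {
  x <- .asDNAStringSet1(seq)
  L <- width(x)
  if (L < 2 * minArm) stop("sequence shorter than two arms")
  hits <- blastPairs(x, x, program = "blastn", task = "blastn-short",
                     wordSize = 4, evalue = maxExpect)
  empty <- data.frame(start1 = integer(0), end1 = integer(0),
                      start2 = integer(0), end2 = integer(0),
                      armLen = integer(0), identity = numeric(0),
                      evalue = numeric(0), geometry = character(0))
  hits <- hits[hits$send < hits$sstart, , drop = FALSE]  # minus strand
  anchored <- .anchoredTirScan(strsplit(as.character(x[[1]]), "")[[1]],
                               minArm, minArmIdentity, maxExpect)
  if (nrow(hits) == 0 && is.null(anchored)) return(empty)
  armQ <- cbind(hits$qstart, hits$qend)
  armS <- cbind(hits$send, hits$sstart)
  # order arms left/right; a palindrome maps an interval onto itself
  left <- ifelse(armQ[, 1] <= armS[, 1], 1L, 2L)
  s1 <- ifelse(left == 1L, armQ[, 1], armS[, 1])
  e1 <- ifelse(left == 1L, armQ[, 2], armS[, 2])
  s2 <- ifelse(left == 1L, armS[, 1], armQ[, 1])
  e2 <- ifelse(left == 1L, armS[, 2], armQ[, 2])
  df <- data.frame(start1 = s1, end1 = e1, start2 = s2, end2 = e2,
                   armLen = pmin(e1 - s1 + 1L, e2 - s2 + 1L),
                   identity = hits$pident / 100, evalue = hits$evalue)
  # a full palindromic self-hit covers one interval; split arms at center
  selfpal <- df$start1 == df$start2 & df$end1 == df$end2
  if (any(selfpal)) {
    mid <- (df$start1[selfpal] + df$end1[selfpal]) %/% 2L
    df$end1[selfpal] <- mid
    df$start2[selfpal] <- mid + 1L
    df$armLen[selfpal] <- pmin(df$end1[selfpal] - df$start1[selfpal] + 1L,
                               df$end2[selfpal] - df$start2[selfpal] + 1L)
  }
  df <- df[!duplicated(paste(df$start1, df$end1, df$start2, df$end2)), ,
           drop = FALSE]
  df <- df[df$armLen >= minArm & df$identity >= minArmIdentity &
             df$evalue <= maxExpect, , drop = FALSE]
  if (nrow(df) == 0 && is.null(anchored)) return(empty)
  if (refineEnds && nrow(df) > 0) {
    ch <- strsplit(as.character(x[[1]]), "")[[1]]
    for (i in seq_len(nrow(df))) {
      kOut <- .extendPaired(ch, df$start1[i], df$end2[i], -1L, 1L,
                            comp = TRUE)
      df$start1[i] <- df$start1[i] - kOut
      df$end2[i] <- df$end2[i] + kOut
      room <- (df$start2[i] - df$end1[i] - 1L) %/% 2L
      if (room > 0) {
        kIn <- .extendPaired(ch, df$end1[i], df$start2[i], 1L, -1L,
                             comp = TRUE, maxSteps = min(40L, room),
                             ties = FALSE)
        df$end1[i] <- df$end1[i] + kIn
        df$start2[i] <- df$start2[i] - kIn
      }
    }
    df$armLen <- pmin(df$end1 - df$start1 + 1L, df$end2 - df$start2 + 1L)
    df <- df[!duplicated(paste(df$start1, df$end1, df$start2, df$end2)), ,
             drop = FALSE]
  }
  # re-derive identity and significance from the refined arms; for
  # adjacent-arm (palindromic) hits the aligner's e-value is over-
  # confident -- its 2n columns are only n independent base pairs -- so
  # significance is recomputed as a pair-based binomial expectation.
  if (nrow(df) > 0) {
    ch2 <- strsplit(as.character(x[[1]]), "")[[1]]
    compOf <- c(A = "T", C = "G", G = "C", T = "A", N = "X")
    for (i in seq_len(nrow(df))) {
      len1 <- df$end1[i] - df$start1[i] + 1L
      len2 <- df$end2[i] - df$start2[i] + 1L
      if (len1 != len2) next
      a1 <- ch2[df$start1[i]:df$end1[i]]
      a2 <- ch2[df$end2[i]:df$start2[i]]  # reversed
      matched <- sum(a1 == compOf[a2])
      df$identity[i] <- matched / len1
      if (df$start2[i] - df$end1[i] - 1L <= 2L) {
        df$evalue[i] <- L *
          stats::pbinom(matched - 1L, len1, 0.25, lower.tail = FALSE)
      }
    }
    df <- df[df$identity >= minArmIdentity & df$evalue <= maxExpect &
               df$armLen >= minArm, , drop = FALSE]
  }
  if (!is.null(anchored)) {
    # drop blast rows that re-describe the anchored terminal repeat
    if (nrow(df) > 0) {
      dup <- df$start1 <= anchored$end1 & df$end2 >= anchored$start2 &
        abs(df$start1 - 1L) <= 5 & abs(df$end2 - L) <= 5
      df <- df[!dup, , drop = FALSE]
    }
    df <- rbind(df, anchored)
  }
  df$geometry <- vapply(seq_len(nrow(df)), function(i)
    classifyGeometry(df[i, ], L), character(1))
  df <- df[order(df$start1, df$start2), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Classify inverted-repeat geometry
#'
#' Palindromic: the arms are (near-)contiguous (inter-arm gap at most 10%
#' of the sequence) and together cover at least 80% of it. Terminal (TIR):
#' arm1 starts within the first \code{termFrac} of the sequence and arm2
#' ends within the last \code{termFrac}. Anything else is subterminal.
#'
#' @param ir one IR row (list or 1-row data.frame with start1, end1,
#'   start2, end2).
#' @param seqLen sequence length.
#' @param termFrac terminal window fraction (default 0.10).
#' @return one of \code{"palindromic"}, \code{"terminal"},
#'   \code{"subterminal"}.
#' @export
classifyGeometry <- function(ir, seqLen, termFrac = 0.10) {
  gap <- ir$start2 - ir$end1 - 1
  cover <- (ir$end1 - ir$start1 + 1) + (ir$end2 - ir$start2 + 1)
  if (gap <= 0.10 * seqLen && cover >= 0.80 * seqLen) return("palindromic")
  if (ir$start1 <= termFrac * seqLen &&
      ir$end2 >= (1 - termFrac) * seqLen) return("terminal")
  "subterminal"
}

#' Detect direct terminal repeats (LTR candidates)
#'
#' Off-diagonal same-strand local self-alignments; a pair is an LTR
#' candidate when the 5' copy lies in the first \code{termWindow} of the
#' sequence and the 3' copy ends in the last \code{termWindow}, and the
#' two copies are within 20% of each other in length.
#'
#' @param seq the sequence.
#' @param minLen minimum repeat length (default 80).
#' @param minIdentity minimum identity fraction (default 0.85).
#' @param termWindow terminal window fraction for the LTR-candidate label
#'   (default 0.20).
#' @param refineEnds polish copy endpoints with the paired walk
#'   (default TRUE).
#' @return data.frame(start5, end5, start3, end3, length, pairIdentity
#'   (percent), evalue, ltrCandidate).
#' @export
detectDirectRepeats <- function(seq, minLen = 80, minIdentity = 0.85,
                                termWindow = 0.20, refineEnds = TRUE) {
  x <- .asDNAStringSet1(seq)
  L <- width(x)
  if (L <= 2 * minLen) stop("sequence too short for two direct repeats")
  hits <- blastPairs(x, x, program = "blastn", task = "blastn",
                     wordSize = 7, evalue = 1e-5)
  empty <- data.frame(start5 = integer(0), end5 = integer(0),
                      start3 = integer(0), end3 = integer(0),
                      length = integer(0), pairIdentity = numeric(0),
                      evalue = numeric(0), ltrCandidate = logical(0))
  hits <- hits[hits$sstart <= hits$send, , drop = FALSE]  # same strand
  # drop the trivial self-diagonal (and any overlapping self-extension)
  ovl <- pmax(0L, pmin(hits$qend, hits$send) -
                pmax(hits$qstart, hits$sstart) + 1L)
  spanQ <- hits$qend - hits$qstart + 1L
  spanS <- hits$send - hits$sstart + 1L
  hits <- hits[ovl < 0.5 * pmin(spanQ, spanS), , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  first5 <- hits$qstart <= hits$sstart
  s5 <- ifelse(first5, hits$qstart, hits$sstart)
  e5 <- ifelse(first5, hits$qend, hits$send)
  s3 <- ifelse(first5, hits$sstart, hits$qstart)
  e3 <- ifelse(first5, hits$send, hits$qend)
  df <- data.frame(start5 = s5, end5 = e5, start3 = s3, end3 = e3,
                   length = hits$length, pairIdentity = hits$pident,
                   evalue = hits$evalue)
  df <- df[!duplicated(paste(df$start5, df$end5, df$start3, df$end3)), ,
           drop = FALSE]
  len5 <- df$end5 - df$start5 + 1L
  len3 <- df$end3 - df$start3 + 1L
  # rough pre-filter; the definitive length floor is applied after
  # endpoint refinement (local alignment trims diverged copy ends)
  df <- df[df$length >= 0.9 * minLen & df$pairIdentity >= minIdentity * 100 &
             pmin(len5, len3) >= 0.8 * pmax(len5, len3), , drop = FALSE]
  if (nrow(df) == 0) return(empty)
  if (refineEnds) {
    ch <- strsplit(as.character(x[[1]]), "")[[1]]
    for (i in seq_len(nrow(df))) {
      room <- df$start3[i] - df$end5[i] - 1L
      if (room <= 0) next
      kL <- .extendPaired(ch, df$start5[i], df$start3[i], -1L, -1L,
                          comp = FALSE,
                          maxSteps = min(40L, df$start5[i] - 1L, room))
      df$start5[i] <- df$start5[i] - kL
      df$start3[i] <- df$start3[i] - kL
      room <- df$start3[i] - df$end5[i] - 1L
      kR <- .extendPaired(ch, df$end5[i], df$end3[i], 1L, 1L,
                          comp = FALSE, maxSteps = min(40L, room))
      df$end5[i] <- df$end5[i] + kR
      df$end3[i] <- df$end3[i] + kR
    }
    df <- df[!duplicated(paste(df$start5, df$end5, df$start3, df$end3)), ,
             drop = FALSE]
  }
  df <- df[pmin(df$end5 - df$start5, df$end3 - df$start3) + 1L >= minLen, ,
           drop = FALSE]
  if (nrow(df) == 0) return(empty)
  df$ltrCandidate <- df$start5 <= termWindow * L &
    df$end3 >= (1 - termWindow) * L
  df <- df[order(-df$length, df$start5), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Percent identity between the two arms of a direct-repeat pair
#'
#' Global (Needleman-Wunsch) alignment of the two arms; percent identity is
#' computed over all alignment columns, gap columns included.
#'
#' @param seq the element sequence.
#' @param pair one row of \code{\link{detectDirectRepeats}} output.
#' @return percent identity (0-100).
#' @export
ltrPairIdentity <- function(seq, pair) {
  x <- .asDNAStringSet1(seq)[[1]]
  arm5 <- Biostrings::subseq(x, pair$start5, pair$end5)
  arm3 <- Biostrings::subseq(x, pair$start3, pair$end3)
  aln <- Biostrings::pairwiseAlignment(arm5, arm3, type = "global",
                                       gapOpening = 10, gapExtension = 4)
  as.numeric(Biostrings::pid(aln, type = "PID1"))
}

#' Six-frame open reading frame scan
#'
#' Stop-to-stop segments in all six frames (no start-codon requirement:
#' degenerate TE copies routinely lose starts). Intervals are on the
#' forward strand, 1-based closed, and cover the codons only.
#'
#' @param seq the sequence.
#' @param minLenNt minimum ORF length in nt (default 300).
#' @return data.frame(frame, start, end, lengthNt, lengthAa, aa), frames in
#'   {+1,+2,+3,-1,-2,-3}, sorted by decreasing length; attribute
#'   \code{"longest"} holds the first row (or NULL).
#' @export
findOrfs <- function(seq, minLenNt = 300) {
  x <- .asDNAStringSet1(seq)[[1]]
  L <- length(x)
  out <- list()
  for (strand in c(1, -1)) {
    s <- if (strand == 1) x else Biostrings::reverseComplement(x)
    for (off in 0:2) {
      nCodon <- (length(s) - off) %/% 3
      if (nCodon < 1) next
      cod <- Biostrings::subseq(s, off + 1, off + 3 * nCodon)
      aa <- as.character(Biostrings::translate(
        cod, if.fuzzy.codon = "X", no.init.codon = TRUE))
      stops <- c(0L, which(strsplit(aa, "")[[1]] == "*"), nCodon + 1L)
      for (k in seq_len(length(stops) - 1)) {
        a <- stops[k] + 1L; b <- stops[k + 1] - 1L
        if (b < a) next
        lenAa <- b - a + 1L
        if (3L * lenAa < minLenNt) next
        # codon positions on the strand-local sequence
        ntA <- off + 3L * (a - 1L) + 1L
        ntB <- off + 3L * b
        if (strand == 1) {
          st <- ntA; en <- ntB; fr <- off + 1L
        } else {
          st <- L - ntB + 1L; en <- L - ntA + 1L; fr <- -(off + 1L)
        }
        out[[length(out) + 1]] <- data.frame(
          frame = fr, start = st, end = en,
          lengthNt = 3L * lenAa, lengthAa = lenAa,
          aa = substr(aa, a, b), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    res <- data.frame(frame = integer(0), start = integer(0),
                      end = integer(0), lengthNt = integer(0),
                      lengthAa = integer(0), aa = character(0))
    attr(res, "longest") <- NULL
    return(res)
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$lengthNt, res$start, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "longest") <- res[1, ]
  res
}

#' Detect the polypurine tract upstream of the 3' LTR
#'
#' Longest A/G run within \code{window} nt immediately upstream of the 3'
#' LTR start; runs straddling the window edge are counted only for their
#' in-window part.
#'
#' @param seq the element sequence.
#' @param ltrPair a direct-repeat pair row (needs \code{start3}).
#' @param minRun minimum purine run length (default 8).
#' @param window search window in nt (default 20).
#' @return list(start, end, length) in element coordinates, or NULL.
#' @export
detectPpt <- function(seq, ltrPair, minRun = 8, window = 20) {
  x <- .asDNAStringSet1(seq)[[1]]
  lo <- max(1L, ltrPair$start3 - window)
  hi <- ltrPair$start3 - 1L
  if (hi < lo) return(NULL)
  region <- strsplit(as.character(Biostrings::subseq(x, lo, hi)), "")[[1]]
  isPur <- region %in% c("A", "G")
  r <- rle(isPur)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pur <- which(r$values & r$lengths >= minRun)
  if (length(pur) == 0) return(NULL)
  best <- pur[which.max(r$lengths[pur])]
  list(start = lo + starts[best] - 1L, end = lo + ends[best] - 1L,
       length = r$lengths[best])
}

#' Detect primer-binding sites downstream of the 5' LTR
#'
#' Scans \code{window} nt downstream of the 5' LTR end for an exact
#' reverse-complement match of at least \code{minMatch} nt to the
#' 3'-terminal 18 nt of any tRNA in the library. All qualifying tRNAs are
#' reported.
#'
#' @param seq the element sequence.
#' @param ltrPair a direct-repeat pair row (needs \code{end5}).
#' @param trnaLib named \code{DNAStringSet} of tRNA sequences; empty or
#'   NULL skips the scan with a warning.
#' @param minMatch minimum complementary match length (default 8).
#' @param window search window in nt (default 20).
#' @return data.frame(trna, matchLen, start, end); zero rows if none.
#' @export
detectPbs <- function(seq, ltrPair, trnaLib, minMatch = 8, window = 20) {
  empty <- data.frame(trna = character(0), matchLen = integer(0),
                      start = integer(0), end = integer(0))
  if (is.null(trnaLib) || length(trnaLib) == 0) {
    warning("no tRNA library supplied; PBS detection skipped")
    return(empty)
  }
  x <- .asDNAStringSet1(seq)[[1]]
  lo <- ltrPair$end5 + 1L
  hi <- min(length(x), ltrPair$end5 + window)
  if (hi - lo + 1 < minMatch) return(empty)
  region <- as.character(Biostrings::subseq(x, lo, hi))
  res <- empty
  for (i in seq_along(trnaLib)) {
    t3 <- Biostrings::subseq(trnaLib[[i]],
                             max(1L, length(trnaLib[[i]]) - 17L),
                             length(trnaLib[[i]]))
    target <- as.character(Biostrings::reverseComplement(t3))
    m <- .longestCommonSubstring(region, target)
    if (m$len >= minMatch) {
      res <- rbind(res, data.frame(
        trna = names(trnaLib)[i], matchLen = m$len,
        start = lo + m$at - 1L, end = lo + m$at + m$len - 2L))
    }
  }
  if (nrow(res)) res <- res[order(-res$matchLen, res$trna), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# longest exact common substring of two short strings; returns its length
# and start offset in `a`
.longestCommonSubstring <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- 0L; at <- 0L
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    for (j in seq_len(nb)) {
      if (av[i] == bv[j]) {
        cur[j] <- if (j > 1) prev[j - 1] + 1L else 1L
        if (cur[j] > best) { best <- cur[j]; at <- i - cur[j] + 1L }
      }
    }
    prev <- cur
  }
  list(len = best, at = at)
}
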