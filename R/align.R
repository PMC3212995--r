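## Longest-first progressive multiple alignment, majority-rule consensus
## with case flags, centroid selection and truncation profiling.

.STATES <- c("A", "C", "G", "T", "N", "-")

.alnMatrix <- function(aln) {
  if (methods::is(aln, "DNAMultipleAlignment"))
    return(as.matrix(aln))
  if (is.matrix(aln)) return(aln)
  if (is.character(aln))
    return(do.call(rbind, strsplit(aln, "", fixed = TRUE)))
  stop("unsupported alignment representation")
}

.profileCounts <- function(mat) {
  apply(mat, 2, function(col) {
    tab <- tabulate(match(col, .STATES), nbins = 6)
    tab
  })
}

#' Longest-first progressive multiple alignment
#'
#' Members are sorted by decreasing length (ties keep input order), the two
#' longest are aligned first, and every further sequence is aligned onto
#' the running profile. The profile aligner is an affine-gap Gotoh variant
#' with free terminal gaps honoring the \code{\link{AlignerParams-class}}
#' gap model, so 5'/3'-truncated copies pad with terminal gaps rather than
#' paying the -500 opening cost at their ends.
#'
#' @param members named \code{DNAStringSet} with at least 2 sequences.
#' @param params an \code{AlignerParams} object.
#' @return a \code{DNAMultipleAlignment}; rows are in the input order of
#'   \code{members} and de-gapping any row reproduces its input sequence.
#' @export
progressiveAlign <- function(members, params = alignerParams()) {
  stopifnot(is(members, "DNAStringSet"))
  if (length(members) < 2)
    stop("progressiveAlign needs at least 2 members (singleton clusters ",
         "are handled by the caller)")
  if (is.null(names(members)))
    names(members) <- paste0("seq", seq_along(members))
  validObject(params)
  ord <- order(-width(members))  # stable: ties keep input order
  chars <- strsplit(as.character(members), "", fixed = TRUE)
  mat <- matrix(chars[[ord[1]]], nrow = 1)
  rownames(mat) <- names(members)[ord[1]]
  for (k in seq(2, length(members))) {
    i <- ord[k]
    newRow <- matrix(chars[[i]], nrow = 1)
    res <- c_profile_align(.profileCounts(mat), .profileCounts(newRow),
                           params@match, params@mismatch,
                           params@gapOpen, params@gapExtend)
    ops <- res$ops
    W <- length(ops)
    out <- matrix("-", nrow = nrow(mat) + 1, ncol = W)
    ai <- 0L; bi <- 0L
    colA <- integer(W); colB <- integer(W)
    for (w in seq_len(W)) {
      if (ops[w] != 3L) ai <- ai + 1L
      if (ops[w] != 2L) bi <- bi + 1L
      colA[w] <- if (ops[w] != 3L) ai else NA_integer_
      colB[w] <- if (ops[w] != 2L) bi else NA_integer_
    }
    keepA <- !is.na(colA)
    out[seq_len(nrow(mat)), keepA] <- mat[, colA[keepA], drop = FALSE]
    keepB <- !is.na(colB)
    out[nrow(mat) + 1, keepB] <- newRow[, colB[keepB], drop = FALSE]
    rownames(out) <- c(rownames(mat), names(members)[i])
    mat <- out
  }
  mat <- mat[names(members), , drop = FALSE]
  Biostrings::DNAMultipleAlignment(
    setNames(apply(mat, 1, paste, collapse = ""), rownames(mat)))
}

# leading/trailing terminal-gap run lengths per alignment row
.terminalGapRuns <- function(mat) {
  lead <- apply(mat, 1, function(r) {
    nz <- which(r != "-")
    if (length(nz) == 0) length(r) else nz[1] - 1L
  })
  trail <- apply(mat, 1, function(r) {
    nz <- which(r != "-")
    if (length(nz) == 0) 0L else length(r) - nz[length(nz)]
  })
  list(leading = lead, trailing = trail)
}

#' Majority-rule consensus with case flags
#'
#' Per column, the spanning rows are those whose sequence has started and
#' not yet ended there (terminal gap runs do not span; internal gaps do,
#' as deletion states). The consensus keeps, at each position, the residue
#' held by more than \code{majority} of the spanning rows, independently of
#' how many rows span the position -- this yields the longest possible
#' consensus. A column is dropped when the deletion state wins. Positions
#' spanned by fewer than half of all rows are written in lowercase, as is
#' any position where no residue exceeds the majority (plurality base,
#' alphabetical tie-break).
#'
#' @param aln a \code{DNAMultipleAlignment} (or character matrix).
#' @param majority majority fraction, exclusive (default 0.5).
#' @return consensus as a single character string over
#'   \code{[ACGTNacgtn]}.
#' @export
buildConsensus <- function(aln, majority = 0.5) {
  mat <- .alnMatrix(aln)
  n <- nrow(mat); W <- ncol(mat)
  runs <- .terminalGapRuns(mat)
  out <- character(0)
  for (j in seq_len(W)) {
    spanning <- which(runs$leading < j & j <= W - runs$trailing)
    if (length(spanning) == 0) next
    col <- mat[spanning, j]
    nGap <- sum(col == "-")
    if (nGap > majority * length(spanning)) next  # deletion wins: drop
    bases <- col[col != "-"]
    counts <- table(factor(bases, levels = c("A", "C", "G", "N", "T")))
    top <- which.max(counts)  # which.max takes the first (alphabetical) tie
    base <- names(counts)[top]
    confident <- counts[top] > majority * length(spanning)
    lowercase <- (length(spanning) < 0.5 * n) || !confident
    out <- c(out, if (lowercase) tolower(base) else base)
  }
  paste(out, collapse = "")
}

#' Select the centroid member of a cluster
#'
#' The centroid is the member with the highest sum of all-to-all local
#' alignment scores against the other members (ties: longest member, then
#' smallest id). When \code{scoreMatrix} is NULL the matrix is computed
#' with blastn (sum of the best bitscore per ordered pair, symmetrized).
#'
#' @param members named \code{DNAStringSet}.
#' @param scoreMatrix optional complete symmetric score matrix with
#'   dimnames matching the member names.
#' @return the centroid member id (character scalar).
#' @export
selectCentroid <- function(members, scoreMatrix = NULL) {
  stopifnot(is(members, "DNAStringSet"), !is.null(names(members)))
  ids <- names(members)
  if (length(ids) == 1) return(ids)
  if (is.null(scoreMatrix)) {
    hits <- blastPairs(members, members, program = "blastn",
                       task = "blastn", evalue = 1e-3)
    scoreMatrix <- matrix(0, length(ids), length(ids),
                          dimnames = list(ids, ids))
    if (nrow(hits)) {
      hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
      if (nrow(hits)) {
        best <- vapply(split(hits$bitscore,
                             paste(hits$qseqid, hits$sseqid, sep = "\r")),
                       max, numeric(1))
        for (k in seq_along(best)) {
          pq <- strsplit(names(best)[k], "\r", fixed = TRUE)[[1]]
          scoreMatrix[pq[1], pq[2]] <- best[k]
        }
        scoreMatrix <- (scoreMatrix + t(scoreMatrix)) / 2
      }
    }
  } else {
    stopifnot(identical(sort(rownames(scoreMatrix)), sort(ids)),
              isTRUE(all.equal(scoreMatrix, t(scoreMatrix),
                               check.attributes = FALSE)))
    scoreMatrix <- scoreMatrix[ids, ids]
  }
  diag(scoreMatrix) <- 0
  sums <- rowSums(scoreMatrix)
  ord <- order(-sums, -width(members), ids)
  ids[ord[1]]
}

#' Compare consensus and centroid sequences
#'
#' @param consensus consensus sequence (character or \code{DNAString});
#'   case flags are ignored for the alignment.
#' @param centroid centroid sequence.
#' @return list(identity, lengthRatio, coverage): best local alignment
#'   identity (fraction; NA when no alignment is found), consensus/centroid
#'   length ratio, and aligned-span coverage of the shorter sequence.
#' @export
compareConsensusCentroid <- function(consensus, centroid) {
  cons <- Biostrings::DNAStringSet(toupper(as.character(consensus)))
  cent <- Biostrings::DNAStringSet(toupper(as.character(centroid)))
  names(cons) <- "consensus"; names(cent) <- "centroid"
  hits <- blastPairs(cons, cent, program = "blastn", task = "blastn",
                     evalue = 1e-3)
  lr <- width(cons) / width(cent)
  if (nrow(hits) == 0)
    return(list(identity = NA_real_, lengthRatio = lr, coverage = 0))
  best <- hits[order(-hits$bitscore)[1], ]
  list(identity = best$pident / 100, lengthRatio = lr,
       coverage = best$length / min(width(cons), width(cent)))
}

#' Terminal truncation profile of an alignment
#'
#' Counts the maximal runs of "-" at the 5' and 3' end of every alignment
#' row (the within-alignment rendering of 5'/3' deletions) and renders a
#' fixed-width text block, one line per member.
#'
#' @param aln a \code{DNAMultipleAlignment} (or character matrix).
#' @param barWidth width of the rendered occupancy bar (default 60).
#' @return list(table = data.frame(member, leading, trailing, length),
#'   rendering = character vector of text lines).
#' @export
truncationProfile <- function(aln, barWidth = 60) {
  mat <- .alnMatrix(aln)
  runs <- .terminalGapRuns(mat)
  W <- ncol(mat)
  tab <- data.frame(member = rownames(mat),
                    leading = as.integer(runs$leading),
                    trailing = as.integer(runs$trailing),
                    length = as.integer(W - runs$leading - runs$trailing),
                    stringsAsFactors = FALSE)
  render <- vapply(seq_len(nrow(tab)), function(i) {
    l <- round(tab$leading[i] / W * barWidth)
    t <- round(tab$trailing[i] / W * barWidth)
    m <- max(0, barWidth - l - t)
    sprintf("%-30s %s%s%s  5'gaps=%d 3'gaps=%d",
            substr(tab$member[i], 1, 30),
            strrep(".", l), strrep("=", m), strrep(".", t),
            tab$leading[i], tab$trailing[i])
  }, character(1))
  list(table = tab, rendering = render)
}

#' Length statistics of a cluster
#' @param members \code{DNAStringSet} of member sequences.
#' @param consensus consensus string.
#' @return data.frame(longest, shortest, consensus_len, ratio).
#' @export
lengthStats <- function(members, consensus) {
  w <- width(members)
  data.frame(longest = max(w), shortest = min(w),
             consensus_len = nchar(consensus),
             ratio = max(w) / min(w))
}

#' Trim ragged alignment ends
#'
#' Removes leading/trailing alignment columns whose gap fraction exceeds
#' \code{maxGapFrac}. Off by default in the pipeline because trimming
#' removes residues from the longest members and breaks the row/member
#' round-trip; provided for display and manual-curation style cleanup.
#'
#' @param aln a \code{DNAMultipleAlignment} or character matrix.
#' @param maxGapFrac gap fraction above which an end column is dropped
#'   (default 0.8).
#' @return a \code{DNAMultipleAlignment}.
#' @export
trimAlignmentEnds <- function(aln, maxGapFrac = 0.8) {
  mat <- .alnMatrix(aln)
  gapFrac <- colMeans(mat == "-")
  keep <- gapFrac <= maxGapFrac
  if (!any(keep)) stop("trimming would remove the whole alignment")
  lo <- which(keep)[1]; hi <- tail(which(keep), 1)
  if (lo > 1 || hi < ncol(mat))
    message("trimAlignmentEnds: trimmed ", lo - 1, " leading and ",
            ncol(mat) - hi, " trailing column(s)")
  mat <- mat[, lo:hi, drop = FALSE]
  Biostrings::DNAMultipleAlignment(
    setNames(apply(mat, 1, paste, collapse = ""), rownames(mat)))
}
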