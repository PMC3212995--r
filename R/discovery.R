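## Dispersed-repeat discovery: genome self-alignment, pile condensation and
## family calling. Hits are canonical unordered pairs of genomic footprints;
## piles are the transitive merge of overlapping footprints; families are
## connected components of piles linked by near-full-length hits.

#' Align a genome against itself and collect repeat-generating local hits
#'
#' Runs a megablast self-comparison of the scaffolds, removes the trivial
#' self-diagonal, and returns each off-diagonal local alignment once as a
#' canonical unordered pair of footprints. Emitted hits satisfy
#' \code{\link{selfHitAccept}}: identity above \code{minIdentity} with both
#' footprints at least \code{minHitLen} long.
#'
#' @param genome named \code{DNAStringSet} of scaffolds.
#' @param minIdentity minimum identity fraction (default 0.94).
#' @param minHitLen minimum footprint length in nt (default 400).
#' @return data.frame with columns seqA, startA, endA, seqB, startB, endB
#'   (1-based closed), identity (fraction), length (alignment columns),
#'   score (bitscore), strandRelation ("same"/"inverted").
#' @export
selfAlignGenome <- function(genome, minIdentity = 0.94, minHitLen = 400) {
  stopifnot(is(genome, "DNAStringSet"), length(genome) > 0)
  if (all(width(genome) < minHitLen)) {
    warning("genome shorter than minHitLen; no self-alignment possible")
    return(.emptySelfHits())
  }
  hits <- blastPairs(genome, genome, program = "blastn", task = "megablast",
                     evalue = 1e-30, percIdentity = minIdentity * 100)
  if (nrow(hits) == 0) return(.emptySelfHits())
  sMin <- pmin(hits$sstart, hits$send)
  sMax <- pmax(hits$sstart, hits$send)
  inverted <- hits$send < hits$sstart
  spanA <- hits$qend - hits$qstart + 1L
  spanB <- sMax - sMin + 1L
  # self-diagonal: same scaffold, footprints overlapping > 50% of the shorter
  ovl <- pmax(0L, pmin(hits$qend, sMax) - pmax(hits$qstart, sMin) + 1L)
  diagSelf <- hits$qseqid == hits$sseqid & ovl > 0.5 * pmin(spanA, spanB)
  keep <- !diagSelf &
    selfHitAccept(hits$pident / 100, spanA, spanB, minIdentity, minHitLen)
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0) return(.emptySelfHits())
  df <- data.frame(seqA = hits$qseqid, startA = hits$qstart,
                   endA = hits$qend, seqB = hits$sseqid,
                   startB = sMin[keep], endB = sMax[keep],
                   identity = hits$pident / 100, length = hits$length,
                   score = hits$bitscore,
                   strandRelation = ifelse(inverted[keep],
                                           "inverted", "same"),
                   stringsAsFactors = FALSE)
  .canonicalizeHits(df)
}

.emptySelfHits <- function() {
  data.frame(seqA = character(0), startA = integer(0), endA = integer(0),
             seqB = character(0), startB = integer(0), endB = integer(0),
             identity = numeric(0), length = integer(0), score = numeric(0),
             strandRelation = character(0), stringsAsFactors = FALSE)
}

# order each hit's two footprints lexicographically and drop the mirrored
# duplicate blast reports for the symmetric comparison
.canonicalizeHits <- function(df) {
  swap <- df$seqB < df$seqA |
    (df$seqB == df$seqA &
       (df$startB < df$startA |
          (df$startB == df$startA & df$endB < df$endA)))
  if (any(swap)) {
    tmp <- df[swap, c("seqA", "startA", "endA")]
    df[swap, c("seqA", "startA", "endA")] <-
      df[swap, c("seqB", "startB", "endB")]
    df[swap, c("seqB", "startB", "endB")] <- tmp
  }
  key <- paste(df$seqA, df$startA, df$endA, df$seqB, df$startB, df$endB)
  df <- df[order(key), , drop = FALSE]
  df <- df[!duplicated(paste(df$seqA, df$startA, df$endA,
                             df$seqB, df$startB, df$endB)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.hitFootprints <- function(hits) {
  GenomicRanges::GRanges(
    c(hits$seqA, hits$seqB),
    IRanges::IRanges(c(hits$startA, hits$startB),
                     c(hits$endA, hits$endB)),
    hit = rep(seq_len(nrow(hits)), 2),
    side = rep(c("A", "B"), each = nrow(hits)))
}

#' Condense overlapping hit footprints into piles
#'
#' Each footprint of each hit is an interval; overlapping intervals are
#' merged transitively (interval union over the overlap graph). Piles whose
#' footprint is mostly covered by intra-pile hits (both endpoints of a hit
#' inside the same pile) are flagged \code{tandem}: they are tandem arrays
#' or satellites rather than dispersed copies, and are excluded from
#' dispersed-family calling.
#'
#' @param hits hit table from \code{\link{selfAlignGenome}}.
#' @param tandemFrac fraction of a pile's footprint that must be covered by
#'   intra-pile hit footprints before the pile is flagged tandem
#'   (default 0.8).
#' @return \code{GRanges} of piles with metadata columns \code{pile}
#'   (integer id) and \code{tandem} (logical).
#' @export
buildPiles <- function(hits, tandemFrac = 0.8) {
  if (nrow(hits) == 0)
    return(GenomicRanges::GRanges(pile = integer(0), tandem = logical(0)))
  fp <- .hitFootprints(hits)
  piles <- GenomicRanges::reduce(fp, ignore.strand = TRUE)
  S4Vectors::mcols(piles)$pile <- seq_along(piles)
  # assign each footprint to its pile
  ov <- GenomicRanges::findOverlaps(fp, piles, select = "first")
  pA <- ov[seq_len(nrow(hits))]
  pB <- ov[nrow(hits) + seq_len(nrow(hits))]
  tandem <- logical(length(piles))
  intra <- which(pA == pB)
  if (length(intra)) {
    for (p in unique(pA[intra])) {
      idx <- intra[pA[intra] == p]
      cov <- GenomicRanges::reduce(fp[c(idx, nrow(hits) + idx)])
      covered <- sum(GenomicRanges::width(
        GenomicRanges::intersect(cov, piles[p])))
      if (covered > tandemFrac * GenomicRanges::width(piles[p]))
        tandem[p] <- TRUE
    }
  }
  S4Vectors::mcols(piles)$tandem <- tandem
  piles
}

#' Call dispersed repeat families from piles and hits
#'
#' Two piles are linked when some hit's footprints cover at least
#' \code{covFrac} of both piles ("globally alignable" copies); families are
#' the connected components with at least \code{minMembers} piles, every
#' pile footprint longer than \code{minLen}. Tandem-flagged piles never
#' join families. Member sequences are extracted on the + strand.
#'
#' @param piles \code{GRanges} from \code{\link{buildPiles}}.
#' @param hits hit table from \code{\link{selfAlignGenome}}.
#' @param genome the scaffolds the hits were computed on.
#' @param minMembers minimum copy number (default 3).
#' @param minLen minimum copy length, exclusive (default 400).
#' @param covFrac linkage coverage fraction (default 0.90).
#' @return list with \code{families}: \code{GRanges} of member piles with
#'   metadata \code{family} (e.g. "fam1") and \code{member} (sequence id);
#'   \code{sequences}: named list of \code{DNAStringSet} per family;
#'   \code{piles}: the input piles.
#' @export
callFamilies <- function(piles, hits, genome, minMembers = 3,
                         minLen = 400, covFrac = 0.90) {
  empty <- list(families = GenomicRanges::GRanges(family = character(0),
                                                  member = character(0)),
                sequences = list(), piles = piles)
  if (length(piles) == 0 || nrow(hits) == 0) return(empty)
  fp <- .hitFootprints(hits)
  ov <- GenomicRanges::findOverlaps(fp, piles, select = "first")
  n <- nrow(hits)
  pA <- ov[seq_len(n)]; pB <- ov[n + seq_len(n)]
  spanA <- hits$endA - hits$startA + 1
  spanB <- hits$endB - hits$startB + 1
  wid <- GenomicRanges::width(piles)
  tandem <- S4Vectors::mcols(piles)$tandem
  eligible <- !tandem & wid > minLen
  edge <- pA != pB & eligible[pA] & eligible[pB] &
    spanA >= covFrac * wid[pA] & spanB >= covFrac * wid[pB]
  if (!any(edge)) return(empty)
  g <- igraph::graph_from_edgelist(
    cbind(as.character(pA[edge]), as.character(pB[edge])), directed = FALSE)
  comp <- igraph::components(g)
  memb <- split(as.integer(names(comp$membership)), comp$membership)
  memb <- Filter(function(m)
    familyAccept(length(m), wid[m], minMembers, minLen), memb)
  if (length(memb) == 0) return(empty)
  # canonical family order: by leftmost member coordinate
  firstPos <- vapply(memb, function(m) {
    o <- order(as.character(GenomicRanges::seqnames(piles))[m],
               GenomicRanges::start(piles)[m])
    GenomicRanges::start(piles)[m[o[1]]]
  }, numeric(1))
  firstSeq <- vapply(memb, function(m) {
    min(as.character(GenomicRanges::seqnames(piles))[m])
  }, character(1))
  memb <- memb[order(firstSeq, firstPos)]
  famGr <- GenomicRanges::GRanges()
  seqsByFam <- list()
  for (i in seq_along(memb)) {
    m <- sort(memb[[i]])
    gr <- piles[m]
    GenomicRanges::strand(gr) <- "+"
    ids <- sprintf("%s:%d-%d",
                   as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr), GenomicRanges::end(gr))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      family = sprintf("fam%d", i), member = ids)
    famGr <- c(famGr, gr)
    sq <- extractInterval(genome, gr)
    names(sq) <- ids
    seqsByFam[[sprintf("fam%d", i)]] <- sq
  }
  list(families = famGr, sequences = seqsByFam, piles = piles)
}

#' Write a hit table in 12-column tabular (outfmt-6 style) format
#' @param hits canonical hit table (from \code{\link{selfAlignGenome}}).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSelfHits <- function(hits, path) {
  qid <- sprintf("%s:%d-%d", hits$seqA, hits$startA, hits$endA)
  sid <- sprintf("%s:%d-%d", hits$seqB, hits$startB, hits$endB)
  df <- data.frame(qid, sid, pident = round(hits$identity * 100, 3),
                   length = hits$length, mismatch = 0L, gapopen = 0L,
                   qstart = hits$startA, qend = hits$endA,
                   sstart = ifelse(hits$strandRelation == "inverted",
                                   hits$endB, hits$startB),
                   send = ifelse(hits$strandRelation == "inverted",
                                 hits$startB, hits$endB),
                   evalue = 0, bitscore = hits$score)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
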