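## 90/90 single-linkage clustering of discovered repeat sequences, plus the
## relaxed translated-space passes that link clusters sharing descent.

#' Cluster repeat sequences at 90% identity over 90% of length
#'
#' Builds a graph with an edge between two sequences when their best local
#' alignment passes \code{\link{clusterEdgeAccept}} (identity above
#' \code{idMin} over at least \code{covMin} of the shorter sequence; the
#' shorter-sequence denominator is what lets fragments join their family).
#' Clusters are the connected components with at least three members;
#' smaller components are reported as unclustered. Output is deterministic:
#' members are sorted within clusters and clusters by their first member.
#'
#' @param seqs named \code{DNAStringSet}.
#' @param idMin identity threshold, exclusive (default 0.90).
#' @param covMin coverage threshold on the shorter sequence (default 0.90).
#' @param minMembers minimum cluster size (default 3).
#' @return list with \code{clusters} (named list of member-id vectors,
#'   names "C001", ...) and \code{unclustered} (character vector of ids).
#' @export
clusterSequences <- function(seqs, idMin = 0.90, covMin = 0.90,
                             minMembers = 3) {
  stopifnot(is(seqs, "DNAStringSet"), !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  lens <- setNames(width(seqs), names(seqs))
  hits <- blastPairs(seqs, seqs, program = "blastn", task = "blastn",
                     evalue = 1e-10, percIdentity = idMin * 100)
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  edges <- NULL
  if (nrow(hits)) {
    ok <- clusterEdgeAccept(hits$pident / 100, hits$length,
                            lens[hits$qseqid], lens[hits$sseqid],
                            idMin, covMin)
    hits <- hits[ok, , drop = FALSE]
    if (nrow(hits))
      edges <- unique(t(apply(cbind(hits$qseqid, hits$sseqid), 1, sort)))
  }
  .componentsToClusters(names(seqs), edges, minMembers)
}

.componentsToClusters <- function(ids, edges, minMembers) {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(sort(ids))
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, sort)
  big <- vapply(groups, length, integer(1)) >= minMembers
  clusters <- groups[big]
  clusters <- clusters[order(vapply(clusters, `[`, character(1), 1))]
  names(clusters) <- sprintf("C%03d", seq_along(clusters))
  list(clusters = clusters,
       unclustered = sort(as.character(unlist(groups[!big],
                                              use.names = FALSE))))
}

#' Relaxed translated-space linkage between cluster consensus sequences
#'
#' Compares all cluster consensus sequences in six-frame translated space
#' (tblastx) and links two clusters at each identity threshold whose best
#' translated alignment reaches that identity over at least \code{covMin}
#' of the shorter consensus. Because a single hit set is thresholded, link
#' sets are nested: every link at a higher threshold is present at every
#' lower one.
#'
#' @param consensi named \code{DNAStringSet} of cluster consensus sequences
#'   (names are cluster ids). Clusters without a consensus should simply be
#'   absent; a warning is emitted for zero-width entries, which are skipped.
#' @param thresholds identity thresholds, fractions (default
#'   \code{c(0.35, 0.50, 0.75, 0.90)}).
#' @param covMin coverage fraction of the shorter consensus (default 0.50).
#' @return data.frame(threshold, cluster_a, cluster_b, identity, coverage);
#'   one row per link per threshold, \code{cluster_a < cluster_b}.
#' @export
relaxedLinkPass <- function(consensi,
                            thresholds = c(0.35, 0.50, 0.75, 0.90),
                            covMin = 0.50) {
  stopifnot(is(consensi, "DNAStringSet"), !is.null(names(consensi)))
  empty <- data.frame(threshold = numeric(0), cluster_a = character(0),
                      cluster_b = character(0), identity = numeric(0),
                      coverage = numeric(0))
  drop <- width(consensi) == 0
  if (any(drop)) {
    warning("skipping cluster(s) without consensus: ",
            paste(names(consensi)[drop], collapse = ", "))
    consensi <- consensi[!drop]
  }
  if (length(consensi) < 2) return(empty)
  lens <- setNames(width(consensi), names(consensi))
  hits <- blastPairs(consensi, consensi, program = "tblastx", evalue = 1e-3)
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  # per unordered pair, best hit by bitscore; coverage measured as the
  # nucleotide span of the hit on the shorter consensus
  a <- pmin(hits$qseqid, hits$sseqid)
  b <- pmax(hits$qseqid, hits$sseqid)
  shorter <- pmin(lens[hits$qseqid], lens[hits$sseqid])
  spanQ <- abs(hits$qend - hits$qstart) + 1
  spanS <- abs(hits$send - hits$sstart) + 1
  span <- ifelse(lens[hits$qseqid] <= lens[hits$sseqid], spanQ, spanS)
  cand <- data.frame(a, b, identity = hits$pident / 100,
                     coverage = span / shorter, score = hits$bitscore,
                     stringsAsFactors = FALSE)
  cand <- cand[cand$coverage >= covMin, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  key <- paste(cand$a, cand$b)
  best <- do.call(rbind, lapply(split(cand, key), function(d) {
    d[order(-d$identity, -d$score)[1], , drop = FALSE]
  }))
  out <- do.call(rbind, lapply(sort(thresholds), function(th) {
    sel <- best[best$identity >= th, , drop = FALSE]
    if (nrow(sel) == 0) return(NULL)
    data.frame(threshold = th, cluster_a = sel$a, cluster_b = sel$b,
               identity = sel$identity, coverage = sel$coverage)
  }))
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out[order(out$threshold, out$cluster_a, out$cluster_b), , drop = FALSE]
}
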