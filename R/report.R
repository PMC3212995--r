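## Pipeline orchestration and database emission: runs discovery ->
## clustering -> alignment/consensus -> signatures -> homology ->
## classification -> statistics -> relaxed pass, then writes the master
## table plus one artifact directory per cluster.

#' Characterize one cluster of member sequences
#'
#' Runs the per-cluster stages (progressive alignment, consensus, centroid,
#' signatures, homology, classification, statistics) and returns a
#' \code{\linkS4class{TECluster}}.
#'
#' @param id cluster id.
#' @param members named \code{DNAStringSet} (>= 2 for alignment-dependent
#'   stages; singletons yield a degenerate cluster).
#' @param libraries list of \code{ReferenceLibrary} objects (possibly
#'   empty: structural-only mode).
#' @param trnaLib optional \code{DNAStringSet} of tRNAs for PBS detection.
#' @param knownTirs optional \code{DNAStringSet} of known TIR arms.
#' @param knownLtrArms optional \code{DNAStringSet} of known LTR arms
#'   (Solo-LTR detection).
#' @param canonical optional \code{DNAStringSet}: canonical elements named
#'   by family, matched via the classification's family assignment.
#' @param params \code{AlignerParams}.
#' @return a \code{TECluster}.
#' @export
characterizeCluster <- function(id, members, libraries = list(),
                                trnaLib = NULL, knownTirs = NULL,
                                knownLtrArms = NULL, canonical = NULL,
                                params = alignerParams()) {
  stopifnot(length(members) >= 1)
  aln <- NULL
  consensus <- as.character(members[[1]])
  if (length(members) >= 2) {
    aln <- progressiveAlign(members, params)
    consensus <- buildConsensus(aln)
  }
  centroid <- selectCentroid(members)
  consUp <- toupper(consensus)

  irs <- tryCatch(detectInvertedRepeats(consUp),
                  error = function(e) NULL)
  dr <- tryCatch(detectDirectRepeats(consUp),
                 error = function(e) NULL)
  orfs <- findOrfs(consUp)
  ltrPair <- NULL
  ppt <- NULL; pbs <- NULL; pairIdent <- NULL
  if (!is.null(dr) && nrow(dr) > 0 && any(dr$ltrCandidate)) {
    ltrPair <- dr[dr$ltrCandidate, , drop = FALSE][1, ]
    pairIdent <- ltrPairIdentity(consUp, ltrPair)
    ppt <- detectPpt(consUp, ltrPair)
    if (!is.null(trnaLib) && length(trnaLib) > 0)
      pbs <- detectPbs(consUp, ltrPair, trnaLib)
  }

  query <- Biostrings::DNAStringSet(consUp)
  names(query) <- id
  homology <- list()
  for (lib in libraries) {
    mode <- if (lib@molecule == "protein") "blastx" else "nucleotide"
    hits <- searchLibrary(query, lib, mode = mode)
    homology[[lib@name]] <- list(role = lib@role, library = lib@name,
                                 hits = hits,
                                 summary = bestHitSummary(hits,
                                                          nchar(consUp)))
  }

  features <- list(irs = irs, directRepeats = dr, orfs = orfs,
                   consensusLen = nchar(consUp), consensus = consUp,
                   homology = homology, knownTirs = knownTirs,
                   ltrPairIdentity = pairIdent)
  cls <- classifyCluster(features)

  # element type refinement: canonical coverage, then Solo-LTR override
  canon <- NULL
  if (!is.null(canonical) && !is.na(cls$family) &&
      cls$family %in% names(canonical))
    canon <- canonical[cls$family]
  if (cls$te_class %in% c("I", "II") &&
      !cls$element_type %in% c("MITE", "MITE-like-novel", "Class II-NA")) {
    et <- assignElementType(consUp, canon, features)
    cls$element_type <- et$element_type
    cls$coverage <- et$coverage
  }
  if (cls$te_class %in% c("I", "unknown") && !is.null(knownLtrArms)) {
    solo <- detectSoloLtr(consUp, knownLtrArms)
    if (solo$solo && is.null(ltrPair)) {
      cls$te_class <- "I"; cls$te_order <- "LTR"
      cls$element_type <- "Solo-LTR"
      if (identical(cls$family, "novel")) cls$family <- solo$family
      cls$evidence[[length(cls$evidence) + 1]] <-
        list(rule = "Solo-LTR",
             datum = paste("matches LTR arm of", solo$family))
    }
  }

  stats <- list()
  if (length(members) >= 2) {
    stats <- c(stats, pDistance(aln))
    if (length(members) >= 4) {
      td <- tajimaD(aln)
      stats$tajima_S <- td$S; stats$tajima_pi <- td$pi
      stats$tajima_D <- td$D; stats$tajima_p <- td$p_value
      stats$tajima_significant <- td$significant
    }
    ng <- .clusterDnDs(aln, orfs)
    if (!is.null(ng)) {
      stats$dN <- ng$dN; stats$dS <- ng$dS; stats$dnds <- ng$ratio
    }
  }
  sig <- list(irs = irs, directRepeats = dr, orfs = orfs,
              ltrPair = ltrPair, ltrPairIdentity = pairIdent,
              ppt = ppt, pbs = pbs)
  new("TECluster", id = id, members = members, alignment = aln,
      consensus = consensus, centroidId = centroid,
      signatures = sig, homology = homology, classification = cls,
      stats = stats)
}

# project the consensus's longest ORF onto the alignment and run
# Nei-Gojobori on the in-frame member codons; NULL when no ORF or the
# projection fails
.clusterDnDs <- function(aln, orfs) {
  if (is.null(orfs) || nrow(orfs) == 0) return(NULL)
  longest <- orfs[1, ]
  if (longest$frame < 0) return(NULL)  # keep it simple: forward frames
  mat <- .alnMatrix(aln)
  # map consensus coordinates onto alignment columns: the consensus keeps
  # the columns where a base won; approximate the ORF span by ungapped
  # majority columns. Use the first row's coordinate system instead: take
  # alignment columns whose first-row position falls inside the ORF when
  # the ORF was found on the consensus scaled to the first row. To stay
  # exact we recompute ORFs per member on the alignment columns where all
  # rows are gap-free, which preserves frame.
  gapFree <- colSums(mat == "-") == 0
  if (sum(gapFree) < 60) return(NULL)
  sub <- mat[, gapFree, drop = FALSE]
  # find the longest common in-frame stop-free window across members
  w <- ncol(sub) - ncol(sub) %% 3
  if (w < 60) return(NULL)
  sub <- sub[, seq_len(w), drop = FALSE]
  best <- NULL
  for (off in 0:2) {
    wo <- w - off; wo <- wo - wo %% 3
    if (wo < 60) next
    block <- sub[, off + seq_len(wo), drop = FALSE]
    ok <- tryCatch({
      r <- neiGojobori(block)
      r
    }, error = function(e) NULL)
    if (!is.null(r <- ok)) {
      if (is.null(best) || (!is.na(r$ratio) && is.na(best$ratio)))
        best <- r
    }
  }
  best
}

#' Run the full pipeline on a genome
#'
#' Stages: self-alignment discovery, pile condensation, family calling,
#' 90/90 clustering of all family member sequences, per-cluster
#' characterization, and the relaxed translated-space linkage pass. Each
#' stage logs its input/output counts.
#'
#' @param genome named \code{DNAStringSet} (or FASTA path).
#' @param libraries list of \code{ReferenceLibrary}.
#' @param trnaLib optional tRNA \code{DNAStringSet}.
#' @param knownTirs,knownLtrArms,canonical optional known-element
#'   structures (see \code{\link{characterizeCluster}}).
#' @param config named list overriding thresholds: minIdentity (0.94),
#'   minHitLen (400), minMembers (3), minLen (400), covFrac (0.9),
#'   clusterId (0.90), clusterCov (0.90), relaxedThresholds
#'   (0.35, 0.5, 0.75, 0.9), relaxedCov (0.5).
#' @param verbose log stage counts via message (default TRUE).
#' @param cacheDir optional directory for stage caching; with
#'   \code{resume = TRUE} a cached discovery hit table is reused instead
#'   of re-running the genome self-alignment.
#' @param resume reuse cached intermediates when present (default FALSE).
#' @return a \code{\linkS4class{TEClusterSet}}.
#' @export
runPipeline <- function(genome, libraries = list(), trnaLib = NULL,
                        knownTirs = NULL, knownLtrArms = NULL,
                        canonical = NULL, config = list(),
                        verbose = TRUE, cacheDir = NULL, resume = FALSE) {
  cfg <- utils::modifyList(list(
    minIdentity = 0.94, minHitLen = 400, minMembers = 3, minLen = 400,
    covFrac = 0.9, clusterId = 0.90, clusterCov = 0.90,
    relaxedThresholds = c(0.35, 0.5, 0.75, 0.9), relaxedCov = 0.5),
    config)
  if (is.character(genome)) genome <- readFastaDNA(genome)
  log <- function(...) if (verbose) message("[denovoTE] ", ...)

  hitCache <- if (!is.null(cacheDir))
    file.path(cacheDir, "discovery_hits.rds") else NULL
  if (resume && !is.null(hitCache) && file.exists(hitCache)) {
    hits <- readRDS(hitCache)
    log("discovery: reusing cached hit table (", nrow(hits), " hits)")
  } else {
    log("self-alignment of ", length(genome), " scaffold(s), ",
        sum(width(genome)), " bp")
    hits <- selfAlignGenome(genome, cfg$minIdentity, cfg$minHitLen)
    if (!is.null(hitCache)) {
      dir.create(cacheDir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(hits, hitCache)
    }
  }
  log("hits: ", nrow(hits))
  piles <- buildPiles(hits)
  log("piles: ", length(piles), " (",
      sum(S4Vectors::mcols(piles)$tandem), " tandem-flagged)")
  fams <- callFamilies(piles, hits, genome, cfg$minMembers, cfg$minLen,
                       cfg$covFrac)
  nFam <- length(unique(S4Vectors::mcols(fams$families)$family))
  log("families: ", nFam, " with ", length(fams$families), " members")

  allSeqs <- Biostrings::DNAStringSet()
  for (f in fams$sequences) allSeqs <- c(allSeqs, f)
  if (length(allSeqs) == 0) {
    log("no repeat families found; empty cluster set")
    return(new("TEClusterSet", clusters = list(),
               unclustered = character(0),
               linkage = data.frame(),
               genomeInfo = list(config = cfg, families = fams$families)))
  }
  cl <- clusterSequences(allSeqs, cfg$clusterId, cfg$clusterCov,
                         cfg$minMembers)
  log("clusters: ", length(cl$clusters), " (+",
      length(cl$unclustered), " unclustered)")

  clusters <- list()
  for (cid in names(cl$clusters)) {
    log("characterizing ", cid, " (", length(cl$clusters[[cid]]),
        " members)")
    clusters[[cid]] <- characterizeCluster(
      cid, allSeqs[cl$clusters[[cid]]], libraries = libraries,
      trnaLib = trnaLib, knownTirs = knownTirs,
      knownLtrArms = knownLtrArms, canonical = canonical)
  }

  consensi <- Biostrings::DNAStringSet(
    vapply(clusters, function(x) toupper(consensusSeq(x)), character(1)))
  linkage <- if (length(consensi) >= 2)
    relaxedLinkPass(consensi, cfg$relaxedThresholds, cfg$relaxedCov)
  else data.frame()
  log("relaxed links: ", nrow(linkage))

  new("TEClusterSet", clusters = clusters, unclustered = cl$unclustered,
      linkage = linkage,
      genomeInfo = list(config = cfg, families = fams$families,
                        piles = piles))
}

#' Emit the master database and per-cluster artifact directories
#'
#' Writes \code{master.tsv} (column groups ordered classification ->
#' structural -> homology -> linkage) and a directory per cluster holding
#' consensus.fasta, centroid.fasta, alignment.afa, irs.aln,
#' truncation.txt, hits/<library>.tsv and stats.tsv. Emission is
#' deterministic: rerunning on the same input produces byte-identical
#' files.
#'
#' @param cset a \code{TEClusterSet}.
#' @param outdir output directory (created if needed).
#' @return invisibly, the master table data.frame.
#' @export
emitDatabase <- function(cset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (cl in cset@clusters) {
    cid <- clusterId(cl)
    cdir <- file.path(outdir, cid)
    dir.create(cdir, showWarnings = FALSE)
    consSet <- Biostrings::BStringSet(consensusSeq(cl))
    names(consSet) <- paste0(cid, "_consensus")
    Biostrings::writeXStringSet(consSet,
                                file.path(cdir, "consensus.fasta"))
    cent <- memberSeqs(cl)[centroidId(cl)]
    Biostrings::writeXStringSet(cent, file.path(cdir, "centroid.fasta"))
    if (!is.null(cl@alignment)) {
      rows_aln <- as.character(cl@alignment)
      alnSet <- Biostrings::BStringSet(rows_aln)
      Biostrings::writeXStringSet(alnSet,
                                  file.path(cdir, "alignment.afa"))
      tp <- truncationProfile(cl@alignment)
      writeLines(tp$rendering, file.path(cdir, "truncation.txt"))
    }
    sig <- signatures(cl)
    irLines <- if (!is.null(sig$irs) && nrow(sig$irs)) {
      c(sprintf("# inverted repeats of %s consensus", cid),
        sprintf("%d-%d / %d-%d id=%.3f geometry=%s",
                sig$irs$start1, sig$irs$end1, sig$irs$start2,
                sig$irs$end2, sig$irs$identity, sig$irs$geometry))
    } else "# no inverted repeats detected"
    writeLines(irLines, file.path(cdir, "irs.aln"))
    hdir <- file.path(cdir, "hits")
    dir.create(hdir, showWarnings = FALSE)
    for (h in cl@homology)
      writeHitTable(h$hits, file.path(hdir, paste0(h$library, ".tsv")))
    st <- clusterStats(cl)
    stDf <- data.frame(stat = names(st),
                       value = vapply(st, function(v)
                         format(v, digits = 10), character(1)))
    write.table(stDf, file.path(cdir, "stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    rows[[cid]] <- .masterRow(cl, cset@linkage)
  }
  master <- if (length(rows)) do.call(rbind, rows) else
    .masterRow(NULL, NULL)[0, ]
  write.table(master, file.path(outdir, "master.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(master)
}

.masterRow <- function(cl, linkage) {
  if (is.null(cl)) {
    return(data.frame(cluster = character(0), te_class = character(0),
                      subclass = character(0), te_order = character(0),
                      superfamily = character(0), family = character(0),
                      element_type = character(0)))
  }
  cls <- classification(cl)
  sig <- signatures(cl)
  st <- clusterStats(cl)
  ls <- lengthStats(memberSeqs(cl), consensusSeq(cl))
  longestOrf <- if (!is.null(sig$orfs) && nrow(sig$orfs))
    sig$orfs$lengthNt[1] else 0L
  orfFrame <- if (!is.null(sig$orfs) && nrow(sig$orfs))
    sig$orfs$frame[1] else NA_integer_
  nTir <- if (!is.null(sig$irs)) sum(sig$irs$geometry == "terminal") else 0L
  nPal <- if (!is.null(sig$irs)) sum(sig$irs$geometry == "palindromic")
          else 0L
  homCols <- list()
  for (h in cl@homology) {
    s <- h$summary
    homCols[[paste0(h$library, "_evalue")]] <- s$e_value
    homCols[[paste0(h$library, "_best")]] <- s$best_match
    homCols[[paste0(h$library, "_positive")]] <- s$positive
  }
  links <- ""
  if (!is.null(linkage) && nrow(linkage)) {
    mine <- linkage[linkage$cluster_a == clusterId(cl) |
                      linkage$cluster_b == clusterId(cl), , drop = FALSE]
    if (nrow(mine)) {
      other <- ifelse(mine$cluster_a == clusterId(cl),
                      mine$cluster_b, mine$cluster_a)
      links <- paste(sprintf("%s@%.2f", other, mine$threshold),
                     collapse = ",")
    }
  }
  flags <- cls$activity_flags %||% list()
  base <- data.frame(
    cluster = clusterId(cl),
    te_class = cls$te_class, subclass = cls$subclass,
    te_order = cls$te_order, superfamily = cls$superfamily,
    family = cls$family, element_type = cls$element_type,
    n_members = length(memberSeqs(cl)),
    longest = ls$longest, shortest = ls$shortest,
    consensus_len = ls$consensus_len, length_ratio = round(ls$ratio, 3),
    centroid = centroidId(cl),
    longest_orf_nt = longestOrf, orf_frame = orfFrame,
    n_tir = nTir, n_palindromic = nPal,
    ltr_pair = !is.null(sig$ltrPair),
    ltr_pair_identity = if (!is.null(sig$ltrPairIdentity))
      round(sig$ltrPairIdentity, 2) else NA_real_,
    ppt = !is.null(sig$ppt),
    pbs = !is.null(sig$pbs) && nrow(sig$pbs) > 0,
    mean_p = st$mean_p %||% NA_real_,
    sd_p = st$sd_p %||% NA_real_,
    dN = st$dN %||% NA_real_, dS = st$dS %||% NA_real_,
    dnds = st$dnds %||% NA_real_,
    tajima_D = st$tajima_D %||% NA_real_,
    tajima_significant = st$tajima_significant %||% NA,
    identical_ltrs = isTRUE(flags$identical_ltrs),
    full_orf_with_domains = isTRUE(flags$full_orf_with_domains),
    expression_hit = isTRUE(flags$expression_hit),
    stringsAsFactors = FALSE)
  for (nm in names(homCols)) base[[nm]] <- homCols[[nm]]
  base$relaxed_links <- links
  base
}
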