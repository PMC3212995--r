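## Wicker-style classification: class / subclass / order / superfamily /
## family plus element-type labels, driven by a deterministic first-match
## decision ladder over structural signatures and library homology.

.TE_ROLES <- c("ltr_known", "nltr_known", "classii_known", "rvt", "rve",
               "peptidase_a17", "transposase", "polyprotein", "gag")

.positiveRoles <- function(homology) {
  if (length(homology) == 0) return(character(0))
  pos <- vapply(homology, function(h) isTRUE(h$summary$positive), logical(1))
  roles <- vapply(homology, function(h) h$role, character(1))
  unique(roles[pos])
}

.bestByRole <- function(homology, role) {
  cand <- Filter(function(h)
    h$role == role && isTRUE(h$summary$positive), homology)
  if (length(cand) == 0) return(NULL)
  ev <- vapply(cand, function(h) h$summary$e_value, numeric(1))
  cand[[which.min(ev)]]
}

#' Classify a cluster from its structural and homology features
#'
#' Applies a deterministic first-match decision ladder:
#' \enumerate{
#'   \item non-TE when the only positive hits are to rRNA/host libraries;
#'   \item class I / order LTR when a terminal direct-repeat pair is
#'     present, or an LTR-diagnostic protein set (Peptidase_A17, RVE) is
#'     positive, or a known-LTR library is positive;
#'   \item class I / order NLTR when RVT, polyprotein or a known-NLTR
#'     library is positive without terminal direct repeats (RVT alone is
#'     shared retroelement machinery and is not taken as LTR evidence);
#'   \item class II / order TIR when terminal inverted repeats co-occur
#'     with a transposase or known-class-II positive;
#'   \item MITE when the TIRs match a known family's TIR arms at >= 0.80
#'     identity, the consensus is shorter than 800 nt and the longest ORF
#'     is under 300 nt;
#'   \item MITE-like novel when TIRs or palindromic termini are present
#'     with no positive TE-library hit and only small ORFs;
#'   \item otherwise, repeat with no signature.
#' }
#' Every assignment carries an evidence trail; activity indicators
#' (identical within-element LTRs, large domain-bearing ORF, expression
#' hit) are reported as flags, never as a hard verdict.
#'
#' @param features list with elements: \code{irs} (from
#'   \code{\link{detectInvertedRepeats}}), \code{directRepeats} (from
#'   \code{\link{detectDirectRepeats}}), \code{orfs} (from
#'   \code{\link{findOrfs}}), \code{consensusLen}, \code{homology} (list of
#'   \code{list(role, library, summary)} per library), optional
#'   \code{knownTirs} (\code{DNAStringSet}), optional \code{ltrPairIdentity}
#'   (percent), optional \code{subjectMeta} (data.frame id/superfamily/
#'   nonautonomous).
#' @return list(te_class, subclass, te_order, superfamily, family,
#'   element_type, evidence, activity_flags).
#' @export
classifyCluster <- function(features) {
  irs <- features$irs
  dr <- features$directRepeats
  orfs <- features$orfs
  hom <- features$homology %||% list()
  L <- features$consensusLen
  evidence <- list()
  addEv <- function(rule, datum)
    evidence[[length(evidence) + 1]] <<- list(rule = rule, datum = datum)

  posRoles <- .positiveRoles(hom)
  tePos <- intersect(posRoles, .TE_ROLES)
  hasTerminalIR <- !is.null(irs) && nrow(irs) > 0 &&
    any(irs$geometry == "terminal")
  hasPalindrome <- !is.null(irs) && nrow(irs) > 0 &&
    any(irs$geometry == "palindromic")
  ltrPairs <- if (!is.null(dr) && nrow(dr) > 0)
    dr[dr$ltrCandidate, , drop = FALSE] else dr
  hasLtrPair <- !is.null(ltrPairs) && nrow(ltrPairs) > 0
  longestOrf <- if (!is.null(orfs) && nrow(orfs) > 0)
    max(orfs$lengthNt) else 0L

  res <- list(te_class = "unknown", subclass = NA_character_,
              te_order = NA_character_, superfamily = "unknown",
              family = "novel", element_type = "repeat-no-signature")

  superFrom <- function(h) {
    id <- h$summary$best_match
    meta <- features$subjectMeta
    if (!is.null(meta) && id %in% meta$id) {
      sf <- meta$superfamily[match(id, meta$id)]
      if (!is.na(sf) && nzchar(sf)) return(sf)
    }
    id
  }

  if (length(posRoles) > 0 && length(tePos) == 0 &&
      all(posRoles %in% c("rrna", "host"))) {
    # (1) non-TE
    res$te_class <- "non-TE"
    res$element_type <- if ("rrna" %in% posRoles) "rRNA" else "host-gene"
    addEv("non-TE", paste("sole positive roles:",
                          paste(posRoles, collapse = ",")))
  } else if (hasLtrPair || any(c("peptidase_a17", "rve") %in% posRoles) ||
             "ltr_known" %in% posRoles) {
    # (2) class I / LTR
    res$te_class <- "I"; res$te_order <- "LTR"
    res$element_type <- "fragment"
    if (hasLtrPair)
      addEv("LTR", sprintf("terminal direct-repeat pair %d-%d / %d-%d",
                           ltrPairs$start5[1], ltrPairs$end5[1],
                           ltrPairs$start3[1], ltrPairs$end3[1]))
    for (r in intersect(c("peptidase_a17", "rve"), posRoles))
      addEv("LTR", paste("positive protein-set hit:", r))
    h <- .bestByRole(hom, "ltr_known")
    if (!is.null(h)) {
      res$superfamily <- superFrom(h)
      res$family <- h$summary$best_match
      addEv("LTR", paste("known LTR element:", h$summary$best_match))
    }
  } else if (length(intersect(c("rvt", "polyprotein", "nltr_known"),
                              posRoles)) > 0 && !hasLtrPair) {
    # (3) class I / NLTR
    res$te_class <- "I"; res$te_order <- "NLTR"
    res$element_type <- "fragment"
    for (r in intersect(c("rvt", "polyprotein"), posRoles))
      addEv("NLTR", paste("positive protein-set hit:", r))
    h <- .bestByRole(hom, "nltr_known")
    if (!is.null(h)) {
      res$superfamily <- superFrom(h)
      res$family <- h$summary$best_match
      addEv("NLTR", paste("known NLTR element:", h$summary$best_match))
    }
  } else if (hasTerminalIR &&
             any(c("transposase", "classii_known") %in% posRoles)) {
    # (4) class II / TIR
    res$te_class <- "II"; res$subclass <- "1"; res$te_order <- "TIR"
    res$element_type <- "fragment"
    addEv("ClassII", "terminal inverted repeats")
    if ("transposase" %in% posRoles)
      addEv("ClassII", "positive transposase hit")
    h <- .bestByRole(hom, "classii_known")
    if (!is.null(h)) {
      res$superfamily <- superFrom(h)
      res$family <- h$summary$best_match
      addEv("ClassII", paste("known class II element:",
                             h$summary$best_match))
      meta <- features$subjectMeta
      if (!is.null(meta) &&
          isTRUE(meta$nonautonomous[match(h$summary$best_match,
                                          meta$id)])) {
        res$element_type <- "Class II-NA"
        addEv("ClassII", "best match annotated non-autonomous")
      }
    }
  } else if (hasTerminalIR && !is.null(features$knownTirs) &&
             length(features$knownTirs) > 0 &&
             L < 800 && longestOrf < 300 &&
             .tirMatchesKnown(features, minIdentity = 0.80)$match) {
    # (5) MITE of a known family
    m <- .tirMatchesKnown(features, minIdentity = 0.80)
    res$te_class <- "II"; res$subclass <- "1"; res$te_order <- "TIR"
    res$element_type <- "MITE"
    res$family <- m$family
    addEv("MITE", sprintf(
      "TIR matches known family '%s' at %.2f identity; length %d < 800; longest ORF %d < 300",
      m$family, m$identity, L, longestOrf))
  } else if ((hasTerminalIR || hasPalindrome) && length(tePos) == 0 &&
             longestOrf < 300) {
    # (6) novel MITE-like
    res$te_class <- "II"; res$subclass <- "1"; res$te_order <- "TIR"
    res$element_type <- "MITE-like-novel"
    addEv("MITE-like-novel",
          paste0(if (hasTerminalIR) "TIRs" else "palindromic termini",
                 ", no positive TE-library hit, longest ORF ",
                 longestOrf, " nt"))
  } else {
    addEv("no-signature",
          "no structural signature or positive TE-library hit")
  }

  if (res$te_class == "I") res$subclass <- NA_character_
  res$activity_flags <- list(
    identical_ltrs = isTRUE(!is.null(features$ltrPairIdentity) &&
                              features$ltrPairIdentity >= 100),
    full_orf_with_domains = longestOrf >= 900 &&
      length(intersect(c("rvt", "rve", "peptidase_a17", "transposase"),
                       posRoles)) > 0,
    expression_hit = "expression" %in% posRoles)
  res$evidence <- evidence
  res
}

.tirMatchesKnown <- function(features, minIdentity = 0.80, minSpan = 15) {
  irs <- features$irs
  term <- irs[irs$geometry == "terminal", , drop = FALSE]
  no <- list(match = FALSE, family = NA_character_, identity = NA_real_)
  if (nrow(term) == 0) return(no)
  cons <- features$consensus
  if (is.null(cons)) return(no)
  x <- .asDNAStringSet1(cons)[[1]]
  arms <- Biostrings::DNAStringSet(lapply(seq_len(nrow(term)), function(i)
    Biostrings::subseq(x, term$start1[i], term$end1[i])))
  best <- no
  for (i in seq_along(arms)) {
    for (k in seq_along(features$knownTirs)) {
      m <- .armIdentity(arms[[i]], features$knownTirs[[k]])
      if (m$span >= minSpan && m$identity >= minIdentity &&
          (!best$match || m$identity > best$identity)) {
        best <- list(match = TRUE,
                     family = names(features$knownTirs)[k],
                     identity = m$identity)
      }
    }
  }
  best
}

# best local-alignment identity and span between two short arms,
# trying both orientations
.armIdentity <- function(a, b) {
  score <- function(p, q) {
    aln <- Biostrings::pairwiseAlignment(p, q, type = "local",
                                         gapOpening = 10, gapExtension = 4)
    list(identity = Biostrings::pid(aln, type = "PID1") / 100,
         span = Biostrings::nchar(aln))
  }
  f <- score(a, b)
  r <- score(a, Biostrings::reverseComplement(b))
  if (r$span * r$identity > f$span * f$identity) r else f
}

#' Assign the element-type completeness label
#'
#' Coverage is the fraction of the canonical element covered by local
#' alignments of the consensus: full at >= 0.90, remnant below 0.10,
#' fragment in between. Without a canonical element the label falls back
#' to structural completeness (an LTR pair plus an intact long ORF reads
#' as full).
#'
#' @param consensus consensus sequence (character).
#' @param canonical canonical family element (\code{DNAStringSet} of 1) or
#'   NULL.
#' @param features optional feature list (used in the no-canonical branch).
#' @return list(element_type, coverage).
#' @export
assignElementType <- function(consensus, canonical = NULL,
                              features = NULL) {
  if (is.null(canonical)) {
    hasLtr <- !is.null(features$directRepeats) &&
      nrow(features$directRepeats) > 0 &&
      any(features$directRepeats$ltrCandidate)
    bigOrf <- !is.null(features$orfs) && nrow(features$orfs) > 0 &&
      max(features$orfs$lengthNt) >= 900
    return(list(element_type = if (hasLtr && bigOrf) "full" else "fragment",
                coverage = NA_real_))
  }
  cons <- .asDNAStringSet1(consensus, "consensus")
  canon <- .asDNAStringSet1(canonical, "canonical")
  hits <- blastPairs(cons, canon, program = "blastn", task = "blastn",
                     evalue = 1e-3)
  if (nrow(hits) == 0)
    return(list(element_type = "remnant", coverage = 0))
  spans <- IRanges::reduce(IRanges::IRanges(pmin(hits$sstart, hits$send),
                                            pmax(hits$sstart, hits$send)))
  coverage <- sum(IRanges::width(spans)) / width(canon)
  type <- if (coverage >= 0.90) "full"
          else if (coverage < 0.10) "remnant" else "fragment"
  list(element_type = type, coverage = unname(coverage))
}

#' Is a consensus a Solo-LTR of a known LTR family?
#'
#' TRUE when the consensus aligns at >= 0.80 identity to some family's LTR
#' arm over >= 0.80 of the arm, and is no longer than 1.5 x the arm (a
#' full element fails the length test).
#'
#' @param consensus consensus sequence.
#' @param ltrArms named \code{DNAStringSet} of known LTR arms.
#' @return list(solo, family): logical and the matching family (or NA).
#' @export
detectSoloLtr <- function(consensus, ltrArms) {
  no <- list(solo = FALSE, family = NA_character_)
  if (is.null(ltrArms) || length(ltrArms) == 0) return(no)
  cons <- .asDNAStringSet1(consensus, "consensus")
  hits <- blastPairs(cons, ltrArms, program = "blastn", task = "blastn",
                     evalue = 1e-3)
  if (nrow(hits) == 0) return(no)
  armLen <- setNames(width(ltrArms), names(ltrArms))
  ok <- hits$pident >= 80 &
    hits$length >= 0.80 * armLen[hits$sseqid] &
    width(cons) <= 1.5 * armLen[hits$sseqid]
  hits <- hits[ok, , drop = FALSE]
  if (nrow(hits) == 0) return(no)
  best <- hits[order(-hits$bitscore)[1], ]
  list(solo = TRUE, family = best$sseqid)
}

#' Group MITE-like clusters that share TIRs but not interiors
#'
#' Two clusters are linked when some TIR arm of one aligns to a TIR arm of
#' the other at >= 0.80 identity over >= 15 nt while their whole consensus
#' sequences share under 0.50 identity; groups are the transitive closure.
#'
#' @param clusterTirs named list: per cluster id, a \code{DNAStringSet} of
#'   its TIR arms.
#' @param consensi named \code{DNAStringSet} of the cluster consensus
#'   sequences.
#' @return list of character vectors, each a group of >= 2 cluster ids.
#' @export
linkTirSubfamilies <- function(clusterTirs, consensi) {
  ids <- names(clusterTirs)
  if (length(ids) < 2) return(list())
  edges <- NULL
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq(i + 1, length(ids))) {
      a <- ids[i]; b <- ids[j]
      tirOk <- FALSE
      for (p in seq_along(clusterTirs[[a]])) {
        for (q in seq_along(clusterTirs[[b]])) {
          m <- .armIdentity(clusterTirs[[a]][[p]], clusterTirs[[b]][[q]])
          if (m$span >= 15 && m$identity >= 0.80) { tirOk <- TRUE; break }
        }
        if (tirOk) break
      }
      if (!tirOk) next
      if (.wholeConsensusIdentity(consensi[[a]], consensi[[b]]) < 0.50)
        edges <- rbind(edges, c(a, b))
    }
  }
  if (is.null(edges)) return(list())
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)
  unname(lapply(split(names(comp$membership), comp$membership), sort))
}

# identity over the whole (shorter) consensus: best local hit identity if
# it covers at least half of the shorter sequence, else 0
.wholeConsensusIdentity <- function(a, b) {
  A <- .asDNAStringSet1(a, "a"); B <- .asDNAStringSet1(b, "b")
  hits <- blastPairs(A, B, program = "blastn", task = "blastn",
                     evalue = 1e-3)
  if (nrow(hits) == 0) return(0)
  shorter <- min(width(A), width(B))
  hits <- hits[hits$length >= 0.5 * shorter, , drop = FALSE]
  if (nrow(hits) == 0) return(0)
  max(hits$pident) / 100
}
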