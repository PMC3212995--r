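## Planted-truth benchmark: simulate the default 12-family genome, run the
## full pipeline against libraries derived from the simulation's ancestral
## elements, and score recovery and classification against the truth.

# expected (class, order) per planted TE kind
.expectedLabel <- function(teKind) {
  switch(teKind,
         LTR = c("I", "LTR"), NLTR = c("I", "NLTR"),
         TIR = c("II", "TIR"), MITE = c("II", "TIR"),
         c("unknown", NA))
}

# parse member ids of the form "chr:start-end" back into GRanges
.memberRanges <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):(\\d+)-(\\d+)$", ids))
  GenomicRanges::GRanges(
    vapply(m, `[`, character(1), 2),
    IRanges::IRanges(as.integer(vapply(m, `[`, character(1), 3)),
                     as.integer(vapply(m, `[`, character(1), 4))))
}

#' Build reference libraries from a simulated genome's ancestors
#'
#' The ancestral elements stand in for a curated TE library: nucleotide
#' sub-libraries per planted kind (roles ltr_known / nltr_known /
#' classii_known) plus the bundled synthetic protein-tag libraries.
#'
#' @param sg a \code{SyntheticGenome}.
#' @return list of \code{ReferenceLibrary}.
#' @export
benchmarkLibraries <- function(sg) {
  kinds <- vapply(sg@specs, `[[`, character(1), "teKind")
  labels <- vapply(sg@specs, `[[`, character(1), "label")
  libs <- list()
  mk <- function(kind, role, name) {
    keep <- labels[kinds %in% kind]
    keep <- keep[keep %in% names(sg@ancestors)]
    if (length(keep))
      libs[[length(libs) + 1]] <<-
        referenceLibrary(name, sg@ancestors[keep], "nucleotide", role)
  }
  mk("LTR", "ltr_known", "known_ltr")
  mk("NLTR", "nltr_known", "known_nltr")
  mk("TIR", "classii_known", "known_classii")
  c(libs, unname(proteinTagLibraries()))
}

#' Run the planted-family benchmark end to end
#'
#' Simulates the default benchmark genome (12 families, 1\% per-copy
#' substitution), runs the full pipeline with libraries derived from the
#' ancestral elements, and scores family recovery and classification
#' accuracy against the planted truth. Classification is correct when a
#' cluster's (class, order) equals the label implied by the majority
#' planted family among its members.
#'
#' @param seed simulation seed.
#' @param genomeLength genome size in bp (default 2e6).
#' @param substRate per-copy substitution rate (default 0.01).
#' @param verbose pipeline logging (default FALSE).
#' @return list(recall, precision, copyF1, accuracy, nClusters, perCluster,
#'   discovery, clusterSet, genome).
#' @export
runBenchmark <- function(seed = 1, genomeLength = 2e6, substRate = 0.01,
                         verbose = FALSE) {
  sg <- simulateGenome(defaultBenchmarkSpecs(substRate),
                       genomeLength = genomeLength, seed = seed)
  kinds <- setNames(vapply(sg@specs, `[[`, character(1), "teKind"),
                    vapply(sg@specs, `[[`, character(1), "label"))
  tirKinds <- names(kinds)[kinds == "TIR"]
  knownTirs <- sg@tirArms[intersect(tirKinds, names(sg@tirArms))]
  cs <- runPipeline(sg@genome, libraries = benchmarkLibraries(sg),
                    trnaLib = trnaLibrary(), knownTirs = knownTirs,
                    knownLtrArms = sg@ltrArms, canonical = sg@ancestors,
                    verbose = verbose)
  fams <- cs@genomeInfo$families
  disc <- evaluateDiscovery(truthRanges(sg), fams)

  perCluster <- NULL
  nCorrect <- 0; nScored <- 0
  for (cl in cs@clusters) {
    mr <- .memberRanges(names(memberSeqs(cl)))
    ov <- GenomicRanges::findOverlaps(mr, truthRanges(sg))
    truthFam <- if (length(ov)) {
      fam <- S4Vectors::mcols(truthRanges(sg))$family[
        S4Vectors::subjectHits(ov)]
      names(sort(table(fam), decreasing = TRUE))[1]
    } else NA_character_
    cls <- classification(cl)
    expected <- if (!is.na(truthFam))
      .expectedLabel(kinds[[truthFam]]) else c(NA, NA)
    ok <- !is.na(truthFam) &&
      identical(c(cls$te_class, cls$te_order), expected)
    if (!is.na(truthFam)) { nScored <- nScored + 1; nCorrect <- nCorrect + ok }
    perCluster <- rbind(perCluster, data.frame(
      cluster = clusterId(cl), truthFamily = truthFam,
      te_class = cls$te_class, te_order = cls$te_order,
      element_type = cls$element_type,
      expected_class = expected[1], expected_order = expected[2],
      correct = ok, stringsAsFactors = FALSE))
  }
  list(recall = disc$familyRecall, precision = disc$familyPrecision,
       copyF1 = disc$copyF1,
       accuracy = if (nScored) nCorrect / nScored else NA_real_,
       nClusters = length(cs), perCluster = perCluster,
       discovery = disc, clusterSet = cs, genome = sg)
}
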