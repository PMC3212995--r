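#' Aligner parameters for the progressive profile aligner
#'
#' Container for the gap model of the longest-first progressive aligner.
#' The defaults are the MUSCLE-style settings used throughout the pipeline:
#' \code{center = -1}, \code{gapOpen = -500}, \code{gapExtend = -50}.
#' \code{center} is retained for interface parity with MUSCLE's gap-placement
#' parameter; the internal aligner places gaps by the affine model alone.
#' Terminal gaps are free, which is what lets truncated copies sit flush
#' inside a longer profile.
#'
#' @slot center numeric, MUSCLE center parameter (kept for parity).
#' @slot gapOpen numeric, gap opening penalty (<= gapExtend <= 0).
#' @slot gapExtend numeric, gap extension penalty.
#' @slot match numeric, match score.
#' @slot mismatch numeric, mismatch score.
#' @export
setClass("AlignerParams",
  representation(center = "numeric", gapOpen = "numeric",
                 gapExtend = "numeric", match = "numeric",
                 mismatch = "numeric"))

setValidity("AlignerParams", function(object) {
  if (length(object@gapOpen) != 1 || length(object@gapExtend) != 1)
    return("gapOpen and gapExtend must be scalars")
  if (!(object@gapOpen <= object@gapExtend && object@gapExtend <= 0))
    return("must have gapOpen <= gapExtend <= 0")
  if (object@match <= object@mismatch)
    return("match score must exceed mismatch score")
  TRUE
})

#' @param center,gapOpen,gapExtend,match,mismatch see slot documentation.
#' @return an \code{AlignerParams} object.
#' @rdname AlignerParams-class
#' @export
alignerParams <- function(center = -1, gapOpen = -500, gapExtend = -50,
                          match = 100, mismatch = -100) {
  new("AlignerParams", center = center, gapOpen = gapOpen,
      gapExtend = gapExtend, match = match, mismatch = mismatch)
}

#' Reference sequence library for homology annotation
#'
#' A named nucleotide or protein library searched against cluster consensus
#' sequences. The \code{role} tag drives the classification ladder:
#' typical roles are \code{"ltr_known"}, \code{"nltr_known"},
#' \code{"classii_known"}, \code{"rvt"}, \code{"rve"}, \code{"peptidase_a17"},
#' \code{"transposase"}, \code{"polyprotein"}, \code{"gag"}, \code{"rrna"},
#' \code{"host"}, \code{"expression"}, or \code{"generic"}.
#'
#' @slot name library name (used in reports).
#' @slot molecule \code{"nucleotide"} or \code{"protein"}.
#' @slot entries an \code{XStringSet} of library sequences.
#' @slot role character role tag (see description).
#' @export
setClass("ReferenceLibrary",
  representation(name = "character", molecule = "character",
                 entries = "XStringSet", role = "character"))

setValidity("ReferenceLibrary", function(object) {
  if (length(object@entries) == 0) return("library has no entries")
  if (!object@molecule %in% c("nucleotide", "protein"))
    return("molecule must be 'nucleotide' or 'protein'")
  if (is.null(names(object@entries)) || anyDuplicated(names(object@entries)))
    return("library entries must carry unique names")
  TRUE
})

#' @param name,entries,molecule,role see slot documentation.
#' @return a \code{ReferenceLibrary}.
#' @rdname ReferenceLibrary-class
#' @export
referenceLibrary <- function(name, entries,
                             molecule = c("nucleotide", "protein"),
                             role = "generic") {
  molecule <- match.arg(molecule)
  new("ReferenceLibrary", name = name, molecule = molecule,
      entries = entries, role = role)
}

#' Total residue count of a reference library
#' @param x a \code{ReferenceLibrary}.
#' @return integer total residues.
#' @export
totalResidues <- function(x) sum(width(x@entries))

#' A characterized repeat cluster
#'
#' One row of the master database: the member sequences of a repeat family
#' cluster together with everything the pipeline derives from them.
#'
#' @slot id cluster identifier.
#' @slot members member sequences (\code{DNAStringSet}).
#' @slot alignment \code{DNAMultipleAlignment} (or NULL before alignment).
#' @slot consensus majority-rule consensus (character; lowercase marks
#'   positions spanned by under half of the members).
#' @slot centroidId id of the centroid member.
#' @slot signatures list of structural features (irs, directRepeats, orfs,
#'   ppt, pbs, ...).
#' @slot homology list of per-library hit tables and best-hit summaries.
#' @slot classification list (te_class, subclass, te_order, superfamily,
#'   family, element_type, evidence, activity_flags).
#' @slot stats list of evolutionary statistics.
#' @export
setClass("TECluster",
  representation(id = "character", members = "DNAStringSet",
                 alignment = "ANY", consensus = "character",
                 centroidId = "character", signatures = "list",
                 homology = "list", classification = "list",
                 stats = "list"))

setValidity("TECluster", function(object) {
  if (length(object@id) != 1 || !nzchar(object@id))
    return("cluster id must be a non-empty scalar")
  if (length(object@members) < 1) return("cluster has no members")
  if (is.null(names(object@members)) ||
      anyDuplicated(names(object@members)))
    return("member sequences must carry unique names")
  TRUE
})

#' A set of characterized repeat clusters
#'
#' @slot clusters list of \code{TECluster}.
#' @slot unclustered ids of sequences in components of size < 3.
#' @slot linkage relaxed-pass linkage table (data.frame).
#' @slot genomeInfo bookkeeping list (scaffold names/lengths, parameters).
#' @export
setClass("TEClusterSet",
  representation(clusters = "list", unclustered = "character",
                 linkage = "data.frame", genomeInfo = "list"))

setValidity("TEClusterSet", function(object) {
  ok <- vapply(object@clusters, function(x) is(x, "TECluster"), logical(1))
  if (length(ok) && !all(ok)) return("clusters must all be TECluster")
  ids <- vapply(object@clusters, function(x) x@id, character(1))
  if (anyDuplicated(ids)) return("duplicate cluster ids")
  TRUE
})

#' A simulated genome with planted TE families
#'
#' @slot genome simulated scaffolds (\code{DNAStringSet}).
#' @slot truth planted-copy intervals with family labels and copy types
#'   (\code{GRanges}, metadata columns \code{family}, \code{copy_type}).
#' @slot specs the \code{FamilySpec} list the genome was built from.
#' @slot ancestors unmutated ancestral element per family.
#' @slot ltrArms ancestral LTR arm per LTR family.
#' @slot tirArms ancestral TIR arm per TIR/MITE family.
#' @slot seed integer seed the simulation used.
#' @export
setClass("SyntheticGenome",
  representation(genome = "DNAStringSet", truth = "GRanges",
                 specs = "list", ancestors = "DNAStringSet",
                 ltrArms = "DNAStringSet", tirArms = "DNAStringSet",
                 seed = "integer"))

## ---- accessors -----------------------------------------------------------

#' @export
setGeneric("clusterId", function(x) standardGeneric("clusterId"))
#' @export
setGeneric("memberSeqs", function(x) standardGeneric("memberSeqs"))
#' @export
setGeneric("consensusSeq", function(x) standardGeneric("consensusSeq"))
#' @export
setGeneric("centroidId", function(x) standardGeneric("centroidId"))
#' @export
setGeneric("classification", function(x) standardGeneric("classification"))
#' @export
setGeneric("signatures", function(x) standardGeneric("signatures"))
#' @export
setGeneric("clusterStats", function(x) standardGeneric("clusterStats"))
#' @export
setGeneric("truthRanges", function(x) standardGeneric("truthRanges"))

#' @rdname TECluster-class
setMethod("clusterId", "TECluster", function(x) x@id)
#' @rdname TECluster-class
setMethod("memberSeqs", "TECluster", function(x) x@members)
#' @rdname TECluster-class
setMethod("consensusSeq", "TECluster", function(x) x@consensus)
#' @rdname TECluster-class
setMethod("centroidId", "TECluster", function(x) x@centroidId)
#' @rdname TECluster-class
setMethod("classification", "TECluster", function(x) x@classification)
#' @rdname TECluster-class
setMethod("signatures", "TECluster", function(x) x@signatures)
#' @rdname TECluster-class
setMethod("clusterStats", "TECluster", function(x) x@stats)

#' @rdname TEClusterSet-class
setMethod("length", "TEClusterSet", function(x) length(x@clusters))
#' @rdname TEClusterSet-class
setMethod("[[", "TEClusterSet", function(x, i) x@clusters[[i]])
#' @rdname TEClusterSet-class
setMethod("names", "TEClusterSet",
          function(x) vapply(x@clusters, clusterId, character(1)))

#' @rdname SyntheticGenome-class
setMethod("truthRanges", "SyntheticGenome", function(x) x@truth)

## ---- show ----------------------------------------------------------------

setMethod("show", "AlignerParams", function(object) {
  cat("AlignerParams: center=", object@center,
      " gapOpen=", object@gapOpen, " gapExtend=", object@gapExtend,
      " match=", object@match, " mismatch=", object@mismatch, "\n", sep = "")
})

setMethod("show", "ReferenceLibrary", function(object) {
  cat("ReferenceLibrary '", object@name, "' (", object@molecule,
      ", role=", object@role, "): ", length(object@entries),
      " entries, ", totalResidues(object), " residues\n", sep = "")
})

setMethod("show", "TECluster", function(object) {
  cls <- object@classification
  lab <- if (length(cls)) {
    paste0(cls$te_class %||% "?", "/", cls$te_order %||% "?",
           " [", cls$element_type %||% "?", "]")
  } else "(unclassified)"
  cat("TECluster ", object@id, ": ", length(object@members),
      " members, consensus ", nchar(object@consensus), " nt, ",
      lab, "\n", sep = "")
})

setMethod("show", "TEClusterSet", function(object) {
  cat("TEClusterSet with ", length(object@clusters), " clusters (",
      length(object@unclustered), " unclustered sequences)\n", sep = "")
})

setMethod("show", "SyntheticGenome", function(object) {
  cat("SyntheticGenome: ", length(object@genome), " scaffold(s), ",
      sum(width(object@genome)), " bp, ", length(object@truth),
      " planted copies from ", length(object@specs),
      " families (seed ", object@seed, ")\n", sep = "")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
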