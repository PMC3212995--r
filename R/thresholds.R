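## The pipeline's filter chain as named predicates. Every stage calls these
## rather than inlining comparisons, so the accept/reject semantics
## (strict vs non-strict) live in exactly one place:
##   self-alignment hits:   identity > 0.94, both footprints >= 400 nt
##   family calling:        >= 3 copies, each copy footprint > 400 nt
##   90/90 clustering edge: identity > 0.90 over >= 0.90 x shorter length
##   homology positivity:   e-value < 1e-15

#' Self-alignment hit acceptance
#' @param identity fraction identity of the local alignment.
#' @param spanA,spanB footprint lengths (nt) on the two copies.
#' @param minIdentity identity threshold (exclusive); default 0.94.
#' @param minHitLen minimum footprint length (inclusive); default 400.
#' @return logical.
#' @export
selfHitAccept <- function(identity, spanA, spanB,
                          minIdentity = 0.94, minHitLen = 400) {
  identity > minIdentity & spanA >= minHitLen & spanB >= minHitLen
}

#' Family acceptance: copy number and copy length
#' @param nCopies number of member piles.
#' @param copyLengths footprint lengths of the member piles.
#' @param minMembers minimum copy number (inclusive); default 3.
#' @param minLen copy length threshold (exclusive); default 400.
#' @return logical scalar.
#' @export
familyAccept <- function(nCopies, copyLengths, minMembers = 3, minLen = 400) {
  nCopies >= minMembers && all(copyLengths > minLen)
}

#' 90/90 clustering edge acceptance
#' @param identity fraction identity of the best local alignment.
#' @param alnLen aligned span (columns).
#' @param lenA,lenB the two sequence lengths.
#' @param idMin identity threshold (exclusive); default 0.90.
#' @param covMin coverage threshold on the shorter sequence (inclusive);
#'   default 0.90.
#' @return logical.
#' @export
clusterEdgeAccept <- function(identity, alnLen, lenA, lenB,
                              idMin = 0.90, covMin = 0.90) {
  identity > idMin & alnLen >= covMin * pmin(lenA, lenB)
}

#' Homology positivity rule
#' @param evalue BLAST e-value(s).
#' @param eMax positivity threshold (exclusive); default 1e-15.
#' @return logical.
#' @export
hitPositive <- function(evalue, eMax = 1e-15) {
  evalue < eMax
}
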