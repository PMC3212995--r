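## Parameter-recovery simulators for the evolutionary statistics: a codon
## evolver with thinned nonsynonymous acceptance (purifying selection) and
## a neutral coalescent alignment generator for Tajima's D calibration.

#' Simulate codon sequences under purifying selection
#'
#' A random stop-free ancestral ORF evolves along a star phylogeny: each
#' tip proposes substitutions at \code{proposalRate} per site and accepts
#' synonymous changes always, nonsynonymous changes with probability
#' \code{omega} (the classic acceptance-thinning construction, so the
#' realized nonsynonymous/synonymous rate ratio is \code{omega}).
#' Proposals creating stop codons are rejected.
#'
#' @param nSeq number of tip sequences (default 10).
#' @param nCodons ORF length in codons (default 300).
#' @param proposalRate expected substitution proposals per site per branch
#'   (default 0.05).
#' @param omega acceptance probability for nonsynonymous proposals
#'   (default 0.2).
#' @return character matrix alignment (rows = tips), in frame.
#' @export
simulateCodonEvolution <- function(nSeq = 10, nCodons = 300,
                                   proposalRate = 0.05, omega = 0.2) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  anc <- character(nCodons)
  for (k in seq_len(nCodons)) {
    repeat {
      cod <- paste(sample(bases, 3, TRUE), collapse = "")
      if (code[cod] != "*") break
    }
    anc[k] <- cod
  }
  ancCh <- strsplit(paste(anc, collapse = ""), "")[[1]]
  n <- length(ancCh)
  tips <- matrix(NA_character_, nSeq, n)
  for (t in seq_len(nSeq)) {
    ch <- ancCh
    nProp <- rpois(1, proposalRate * n)
    sites <- sample.int(n, min(nProp, n), replace = TRUE)
    for (p in sites) {
      newBase <- sample(setdiff(bases, ch[p]), 1)
      codIdx <- (p - 1) %/% 3
      cod <- ch[(3 * codIdx + 1):(3 * codIdx + 3)]
      newCod <- cod
      newCod[p - 3 * codIdx] <- newBase
      aaOld <- code[paste(cod, collapse = "")]
      aaNew <- code[paste(newCod, collapse = "")]
      if (aaNew == "*") next
      if (aaOld == aaNew || runif(1) < omega) ch[p] <- newBase
    }
    tips[t, ] <- ch
  }
  rownames(tips) <- paste0("tip", seq_len(nSeq))
  tips
}

#' Simulate a neutral coalescent alignment (infinite sites)
#'
#' Standard n-coalescent with exponential waiting times; mutations fall on
#' branches as a Poisson process with rate \code{theta}/2 per unit
#' coalescent time, each creating a new segregating column. Under
#' neutrality and a stationary population, Tajima's D over replicates is
#' centered near zero.
#'
#' @param n sample size (default 10).
#' @param theta population-scaled mutation rate (default 10).
#' @return character matrix alignment; monomorphic single-column matrix
#'   when no mutation occurred.
#' @export
simulateNeutralAlignment <- function(n = 10, theta = 10) {
  parent <- rep(NA_integer_, 2 * n - 1)
  nodeTime <- numeric(2 * n - 1)
  active <- seq_len(n)
  nxt <- n + 1L
  t <- 0
  while (length(active) > 1) {
    k <- length(active)
    t <- t + rexp(1, rate = k * (k - 1) / 2)
    pair <- sample(active, 2)
    nodeTime[nxt] <- t
    parent[pair] <- nxt
    active <- c(setdiff(active, pair), nxt)
    nxt <- nxt + 1L
  }
  descend <- function(node) {
    if (node <= n) return(node)
    unlist(lapply(which(parent == node), descend))
  }
  cols <- list()
  for (node in seq_len(2 * n - 2)) {
    len <- nodeTime[parent[node]] - nodeTime[node]
    m <- rpois(1, theta / 2 * len)
    if (m > 0) {
      carriers <- descend(node)
      for (k in seq_len(m)) {
        col <- rep("A", n)
        col[carriers] <- "G"
        cols[[length(cols) + 1]] <- col
      }
    }
  }
  mat <- if (length(cols)) do.call(cbind, cols)
         else matrix("A", n, 1)
  rownames(mat) <- paste0("s", seq_len(n))
  mat
}
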