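## Per-cluster evolutionary diagnostics: pairwise p-distance, Nei-Gojobori
## (1986) dN/dS with Jukes-Cantor correction, and Tajima's D with the
## beta-approximation significance test.

#' Mean pairwise p-distance of an alignment
#'
#' Per pair of rows, the proportion of differing sites among columns where
#' both rows hold an unambiguous base (pairwise deletion of gap/N columns).
#' Pairs with zero comparable sites are skipped with a message.
#'
#' @param aln a \code{DNAMultipleAlignment} or character matrix (>= 2 rows).
#' @return list(mean_p, sd_p, n_pairs): mean and population standard
#'   deviation over all compared pairs.
#' @export
pDistance <- function(aln) {
  mat <- .alnMatrix(aln)
  n <- nrow(mat)
  if (n < 2) stop("p-distance needs at least 2 rows")
  valid <- mat %in% c("A", "C", "G", "T")
  dim(valid) <- dim(mat)
  ps <- numeric(0)
  skipped <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      comp <- valid[i, ] & valid[j, ]
      nc <- sum(comp)
      if (nc == 0) { skipped <- skipped + 1L; next }
      ps <- c(ps, sum(mat[i, comp] != mat[j, comp]) / nc)
    }
  }
  if (skipped > 0)
    message("pDistance: skipped ", skipped, " pair(s) with no comparable sites")
  m <- mean(ps)
  list(mean_p = m, sd_p = sqrt(mean((ps - m)^2)), n_pairs = length(ps))
}

## ---- Nei-Gojobori --------------------------------------------------------

# Memoized codon machinery: codon index 1..64, per-codon synonymous site
# fractions, and 64x64 pairwise (Sd, Nd) matrices with equal-pathway
# averaging. Mutations to stop codons count as nonsynonymous in site
# counting; substitution pathways passing through a stop codon are
# excluded from the averaging (all pathways used if every one is blocked).
.codonSetup <- function() {
  if (!is.null(.denovoTE_env$codon)) return(.denovoTE_env$codon)
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- sort(codons)
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  isStop <- aa == "*"
  # synonymous site count per codon: sum over positions of the fraction of
  # the 3 possible changes that preserve the amino acid
  synSites <- vapply(seq_along(codons), function(ci) {
    if (isStop[ci]) return(NA_real_)
    cod <- strsplit(codons[ci], "")[[1]]
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, cod[p])) {
        mut <- cod; mut[p] <- b
        if (gc[paste(mut, collapse = "")] == aa[ci]) s <- s + 1 / 3
      }
    }
    s
  }, numeric(1))
  # pairwise Sd/Nd with pathway averaging
  n <- length(codons)
  Sd <- matrix(0, n, n); Nd <- matrix(0, n, n)
  countPath <- function(from, to) {
    diffPos <- which(from != to)
    k <- length(diffPos)
    if (k == 0) return(c(0, 0))
    perms <- if (k == 1) list(diffPos) else {
      if (k == 2) list(diffPos, rev(diffPos)) else {
        idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                    c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
        lapply(idx, function(o) diffPos[o])
      }
    }
    paths <- list(); pathsAll <- list()
    for (perm in perms) {
      cur <- from; s <- 0; ns <- 0; blocked <- FALSE
      for (p in perm) {
        nxt <- cur; nxt[p] <- to[p]
        aaCur <- gc[paste(cur, collapse = "")]
        aaNxt <- gc[paste(nxt, collapse = "")]
        if (aaNxt == "*") blocked <- TRUE
        if (aaCur == aaNxt) s <- s + 1 else ns <- ns + 1
        cur <- nxt
      }
      pathsAll[[length(pathsAll) + 1]] <- c(s, ns)
      if (!blocked) paths[[length(paths) + 1]] <- c(s, ns)
    }
    use <- if (length(paths)) paths else pathsAll
    Reduce(`+`, use) / length(use)
  }
  for (i in seq_len(n)) {
    if (isStop[i]) next
    ci <- strsplit(codons[i], "")[[1]]
    for (j in seq_len(n)) {
      if (isStop[j] || j == i) next
      sn <- countPath(ci, strsplit(codons[j], "")[[1]])
      Sd[i, j] <- sn[1]; Nd[i, j] <- sn[2]
    }
  }
  .denovoTE_env$codon <- list(codons = codons, isStop = isStop,
                              synSites = synSites, Sd = Sd, Nd = Nd)
  .denovoTE_env$codon
}

#' Nei-Gojobori dN/dS over a codon alignment
#'
#' Classic NG86 counting: per codon, synonymous site fractions; per codon
#' pair, synonymous/nonsynonymous differences averaged over all
#' substitution pathways (pathways through stop codons excluded). The
#' proportions pS = Sd/S and pN = Nd/N are Jukes-Cantor corrected,
#' d = -3/4 ln(1 - 4/3 p), and averaged over all sequence pairs. Codons
#' containing a gap, N, or a stop in either sequence of a pair are
#' excluded pairwise.
#'
#' @param codonAln a character matrix / \code{DNAMultipleAlignment}, in
#'   frame, alignment length divisible by 3.
#' @return list(dN, dS, ratio, S, N, Sd, Nd, undefined): means over pairs;
#'   ratio is NA with \code{undefined = "dS=0"} when dS is 0, and the
#'   correction is flagged when some p >= 3/4.
#' @export
neiGojobori <- function(codonAln) {
  mat <- .alnMatrix(codonAln)
  if (ncol(mat) %% 3 != 0) stop("alignment length not divisible by 3")
  tab <- .codonSetup()
  n <- nrow(mat); nCod <- ncol(mat) / 3
  codIdx <- matrix(NA_integer_, n, nCod)
  for (i in seq_len(n)) {
    cods <- vapply(seq_len(nCod), function(k)
      paste(mat[i, (3 * k - 2):(3 * k)], collapse = ""), character(1))
    idx <- match(cods, tab$codons)
    idx[!is.na(idx) & tab$isStop[idx]] <- NA_integer_
    codIdx[i, ] <- idx
  }
  dNs <- c(); dSs <- c(); Ss <- c(); Ns <- c(); Sds <- c(); Nds <- c()
  flagged <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- !is.na(codIdx[i, ]) & !is.na(codIdx[j, ])
      if (!any(ok)) next
      ci <- codIdx[i, ok]; cj <- codIdx[j, ok]
      S <- sum((tab$synSites[ci] + tab$synSites[cj]) / 2)
      N <- 3 * length(ci) - S
      Sd <- sum(tab$Sd[cbind(ci, cj)])
      Nd <- sum(tab$Nd[cbind(ci, cj)])
      pS <- if (S > 0) Sd / S else 0
      pN <- if (N > 0) Nd / N else 0
      jc <- function(p) {
        if (p >= 3 / 4) { flagged <<- TRUE; return(NA_real_) }
        -3 / 4 * log(1 - 4 / 3 * p)
      }
      dSs <- c(dSs, jc(pS)); dNs <- c(dNs, jc(pN))
      Ss <- c(Ss, S); Ns <- c(Ns, N); Sds <- c(Sds, Sd); Nds <- c(Nds, Nd)
    }
  }
  if (length(Ss) == 0) stop("no comparable codons in any pair")
  dN <- mean(dNs, na.rm = TRUE); dS <- mean(dSs, na.rm = TRUE)
  undefined <- if (flagged) "p>=3/4 in some pair"
               else if (dS == 0) "dS=0" else NA_character_
  list(dN = dN, dS = dS,
       ratio = if (isTRUE(dS > 0)) dN / dS else NA_real_,
       S = mean(Ss), N = mean(Ns), Sd = mean(Sds), Nd = mean(Nds),
       undefined = undefined)
}

#' Tajima's D with beta-approximation significance
#'
#' D contrasts mean pairwise differences (pi) with the scaled number of
#' segregating sites (S/a1); the constants a1..e2 are the standard
#' functions of the sample size (Tajima 1989). Significance uses the
#' beta-distribution approximation on the (Dmin, Dmax) support, two-sided
#' at 0.05. Columns are compared over rows holding an unambiguous base;
#' sites segregate when at least two states are present.
#'
#' @param aln a \code{DNAMultipleAlignment} or character matrix (>= 4 rows).
#' @return list(n, S, pi, D, p_value, significant). With S = 0, D is NaN
#'   and significant is FALSE.
#' @export
tajimaD <- function(aln) {
  mat <- .alnMatrix(aln)
  n <- nrow(mat)
  if (n < 4) stop("Tajima's D needs at least 4 sequences")
  valid <- mat %in% c("A", "C", "G", "T")
  dim(valid) <- dim(mat)
  S <- 0L
  for (j in seq_len(ncol(mat))) {
    states <- unique(mat[valid[, j], j])
    if (length(states) >= 2) S <- S + 1L
  }
  # mean pairwise difference count
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      comp <- valid[i, ] & valid[j, ]
      tot <- tot + sum(mat[i, comp] != mat[j, comp])
      np <- np + 1
    }
  }
  pi <- tot / np
  if (S == 0)
    return(list(n = n, S = 0L, pi = pi, D = NaN, p_value = NA_real_,
                significant = FALSE))
  tmp <- seq_len(n - 1)
  a1 <- sum(1 / tmp); a2 <- sum(1 / tmp^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  Dmin <- (2 / n - 1 / a1) / sqrt(e2)
  Dmax <- ((n + 1) / (2 * n) - 1 / a1) / sqrt(e2)
  tmp1 <- 1 + Dmin * Dmax
  tmp2 <- Dmax - Dmin
  a <- -tmp1 * Dmax / tmp2
  b <- tmp1 * Dmin / tmp2
  p <- pbeta((D - Dmin) / tmp2, b, a)
  p <- 2 * min(p, 1 - p)
  list(n = n, S = S, pi = pi, D = D, p_value = p,
       significant = isTRUE(p < 0.05))
}
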