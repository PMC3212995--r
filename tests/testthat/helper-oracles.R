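# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

randDna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

mutateSeq <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# --- consensus oracle: literal restatement of the column rules ------------
oracleConsensus <- function(mat, majority = 0.5) {
  n <- nrow(mat)
  lead <- apply(mat, 1, function(r) {
    nz <- which(r != "-"); if (!length(nz)) ncol(mat) else nz[1] - 1
  })
  trail <- apply(mat, 1, function(r) {
    nz <- which(r != "-"); if (!length(nz)) 0 else ncol(mat) - max(nz)
  })
  res <- character(0)
  for (j in seq_len(ncol(mat))) {
    span <- which(lead < j & j <= ncol(mat) - trail)
    if (!length(span)) next
    col <- mat[span, j]
    if (sum(col == "-") > majority * length(span)) next
    votes <- col[col != "-"]
    cnt <- sapply(c("A", "C", "G", "T", "N"), function(b) sum(votes == b))
    cnt <- cnt[cnt > 0]
    if (!length(cnt)) next
    win <- names(cnt)[order(-cnt, names(cnt))][1]
    strong <- cnt[win] > majority * length(span)
    lower <- length(span) < 0.5 * n || !strong
    res <- c(res, if (lower) tolower(win) else win)
  }
  paste(res, collapse = "")
}

# --- terminal gap-run oracle via regex ------------------------------------
oracleGapRuns <- function(rowString) {
  lead <- nchar(sub("^(-*).*$", "\\1", rowString))
  trail <- nchar(sub("^.*?(-*)$", "\\1", rowString))
  if (lead == nchar(rowString)) trail <- 0
  c(leading = lead, trailing = trail)
}

# --- six-frame ORF scan oracle --------------------------------------------
oracleOrfs <- function(seq, minLenNt) {
  code <- Biostrings::GENETIC_CODE
  segs <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    ch <- strsplit(s, "")[[1]]
    for (off in 0:2) {
      ncod <- (length(ch) - off) %/% 3
      if (ncod < 1) next
      aas <- vapply(seq_len(ncod), function(k) {
        cod <- paste(ch[(off + 3 * k - 2):(off + 3 * k)], collapse = "")
        if (grepl("[^ACGT]", cod)) "X" else unname(code[cod])
      }, character(1))
      run <- 0
      for (k in seq_len(ncod + 1)) {
        if (k <= ncod && aas[k] != "*") run <- run + 1
        else {
          if (3 * run >= minLenNt)
            segs[[length(segs) + 1]] <- c(
              len = 3 * run,
              frame = if (strand == "+") off + 1 else -(off + 1))
          run <- 0
        }
      }
    }
  }
  segs
}

# --- pairwise p-distance counting oracle ----------------------------------
oraclePDist <- function(mat) {
  n <- nrow(mat); ps <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- mat[i, ] %in% c("A", "C", "G", "T") &
      mat[j, ] %in% c("A", "C", "G", "T")
    if (!any(ok)) next
    ps <- c(ps, mean(mat[i, ok] != mat[j, ok]))
  }
  ps
}

# --- Tajima's D direct formula evaluation ---------------------------------
oracleTajimaD <- function(n, S, pi) {
  h <- 1:(n - 1)
  a1 <- sum(1 / h); a2 <- sum(1 / h^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# --- Nei-Gojobori oracle for a single codon pair --------------------------
# enumerates substitution pathways directly from the code table
oracleCodonPair <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  syn <- 0; nonsyn <- 0
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(d) == 0) return(c(Sd = 0, Nd = 0))
  perms <- if (length(d) == 1) list(d) else
    lapply(combinat_perms(length(d)), function(o) d[o])
  paths <- list()
  for (perm in perms) {
    cur <- strsplit(c1, "")[[1]]; tgt <- strsplit(c2, "")[[1]]
    s <- 0; ns <- 0; blocked <- FALSE
    for (p in perm) {
      nxt <- cur; nxt[p] <- tgt[p]
      if (code[paste(nxt, collapse = "")] == "*") blocked <- TRUE
      if (code[paste(cur, collapse = "")] ==
          code[paste(nxt, collapse = "")]) s <- s + 1 else ns <- ns + 1
      cur <- nxt
    }
    paths[[length(paths) + 1]] <- list(s = s, ns = ns, blocked = blocked)
  }
  open <- Filter(function(p) !p$blocked, paths)
  use <- if (length(open)) open else paths
  c(Sd = mean(vapply(use, `[[`, numeric(1), "s")),
    Nd = mean(vapply(use, `[[`, numeric(1), "ns")))
}

combinat_perms <- function(k) {
  if (k == 1) return(list(1))
  if (k == 2) return(list(c(1, 2), c(2, 1)))
  list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
       c(3, 1, 2), c(3, 2, 1))
}

oracleSynSites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
    mut <- ch; mut[p] <- b
    if (code[paste(mut, collapse = "")] == code[codon]) s <- s + 1 / 3
  }
  s
}

# --- union-find ------------------------------------------------------------
unionFind <- function(ids, edges) {
  parent <- setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  if (!is.null(edges) && nrow(edges))
    for (k in seq_len(nrow(edges)))
      parent[[find(edges[k, 1])]] <- find(edges[k, 2])
  roots <- vapply(ids, find, character(1))
  unname(lapply(split(ids, roots), sort))
}

# --- neutral coalescent simulator (infinite sites) ------------------------
# returns a character matrix alignment of n sequences with theta = 4Nu
simCoalescentAlignment <- function(n, theta, siteLen = 2000) {
  # build coalescent tree: times and merges
  nodes <- as.list(seq_len(n))
  times <- rep(0, n)
  branch <- list()  # per node: (parent assigned later)
  active <- seq_len(n)
  nodeTime <- rep(0, 2 * n - 1)
  parent <- rep(NA_integer_, 2 * n - 1)
  nxt <- n + 1
  t <- 0
  while (length(active) > 1) {
    k <- length(active)
    t <- t + rexp(1, rate = k * (k - 1) / 2)
    pair <- sample(active, 2)
    nodeTime[nxt] <- t
    parent[pair] <- nxt
    active <- c(setdiff(active, pair), nxt)
    nxt <- nxt + 1
  }
  root <- active
  # mutations: Poisson(theta/2 * branch length) per branch, infinite sites
  seqs <- matrix(0L, n, 0)
  mutsOnBranch <- function(node) {
    if (is.na(parent[node])) return(integer(0))
    len <- nodeTime[parent[node]] - nodeTime[node]
    rpois(1, theta / 2 * len)
  }
  descend <- function(node) {
    if (node <= n) return(node)
    kids <- which(parent == node)
    unlist(lapply(kids, descend))
  }
  for (node in seq_len(2 * n - 2)) {
    m <- mutsOnBranch(node)
    if (m > 0) {
      carriers <- descend(node)
      block <- matrix(0L, n, m)
      block[carriers, ] <- 1L
      seqs <- cbind(seqs, block)
    }
  }
  # encode as bases
  S <- ncol(seqs)
  mat <- matrix("A", n, max(S, 1))
  if (S > 0) mat[, seq_len(S)][seqs == 1L] <- "G"
  rownames(mat) <- paste0("s", seq_len(n))
  mat
}
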