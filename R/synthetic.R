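## Seeded genome simulator: plants TE families of known structure into an
## i.i.d. background so that discovery, clustering, signature detection,
## classification and the evolutionary statistics are all testable at desk
## scale with exact truth.

#' Specification of one planted TE family
#'
#' @param label family label (unique within a simulation).
#' @param teKind \code{"LTR"}, \code{"NLTR"}, \code{"TIR"} or \code{"MITE"}.
#' @param elementLength full element length in nt.
#' @param copyNumber number of planted copies (>= 1).
#' @param ltrLen LTR arm length (LTR kind; >= 50).
#' @param tirLen TIR arm length (TIR/MITE kinds; >= 10).
#' @param substRate per-site substitution rate applied independently to
#'   each copy (in [0, 0.2]).
#' @param indelRate per-site indel rate (events of 1-3 nt; in [0, 0.2]).
#' @param truncation \code{"none"} or \code{"five_prime_geometric"}
#'   (5'-truncation with geometric length, NLTR biology).
#' @param truncMean mean truncation length in nt.
#' @param truncProb probability that a given copy is truncated at all
#'   (clusters of real NLTRs mix full-length and truncated copies).
#' @param soloLtrProb probability that an LTR-family copy is planted as a
#'   solitary LTR (recombination product) instead of a full element.
#' @param orfCassette \code{"none"}, \code{"rvt_like"} (NLTR-style pol),
#'   \code{"rvt_rve_like"} (LTR-style pol with integrase) or
#'   \code{"transposase_like"}.
#' @param tirSource label of another (TIR) family whose TIR arms this MITE
#'   inherits, or NULL for novel TIRs.
#' @return a \code{FamilySpec} (classed list).
#' @export
familySpec <- function(label, teKind = c("LTR", "NLTR", "TIR", "MITE"),
                       elementLength, copyNumber,
                       ltrLen = NULL, tirLen = NULL,
                       substRate = 0.01, indelRate = 0.001,
                       truncation = c("none", "five_prime_geometric"),
                       truncMean = 0, truncProb = 0.5,
                       soloLtrProb = 0,
                       orfCassette = c("none", "rvt_like", "rvt_rve_like",
                                       "transposase_like"),
                       tirSource = NULL) {
  teKind <- match.arg(teKind)
  truncation <- match.arg(truncation)
  orfCassette <- match.arg(orfCassette)
  if (substRate < 0 || substRate > 0.2 || indelRate < 0 || indelRate > 0.2)
    stop("mutation rates must lie in [0, 0.2]")
  if (teKind == "LTR" && (is.null(ltrLen) || ltrLen < 50))
    stop("LTR kind requires ltrLen >= 50")
  if (teKind %in% c("TIR", "MITE") && is.null(tirSource) &&
      (is.null(tirLen) || tirLen < 10))
    stop(teKind, " kind requires tirLen >= 10 (or a tirSource)")
  structure(list(label = label, teKind = teKind,
                 elementLength = as.integer(elementLength),
                 copyNumber = as.integer(copyNumber),
                 ltrLen = ltrLen, tirLen = tirLen,
                 substRate = substRate, indelRate = indelRate,
                 truncation = truncation, truncMean = truncMean,
                 truncProb = truncProb, soloLtrProb = soloLtrProb,
                 orfCassette = orfCassette, tirSource = tirSource),
            class = "FamilySpec")
}

.randDna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

.revcompChr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# reverse-translate an amino-acid string with random synonymous codons;
# never emits a stop codon because the input has no '*'
.reverseTranslate <- function(aa) {
  tab <- .codonSetup()
  gcAA <- Biostrings::GENETIC_CODE
  byAA <- split(names(gcAA), unname(gcAA))
  paste(vapply(strsplit(aa, "")[[1]], function(a) {
    cods <- byAA[[a]]
    cods[sample.int(length(cods), 1)]
  }, character(1)), collapse = "")
}

# bundled synthetic protein tags (60-aa stand-ins for the conserved-domain
# subsets a real run would take from curated TE protein libraries)
#' Load the bundled synthetic protein-tag libraries
#' @return named list of \code{ReferenceLibrary} objects with roles rvt,
#'   rve, peptidase_a17 and transposase.
#' @export
proteinTagLibraries <- function() {
  dir <- system.file("extdata", "protein_tags", package = "denovoTE")
  files <- list.files(dir, pattern = "\\.faa$", full.names = TRUE)
  libs <- lapply(files, function(f) {
    entries <- Biostrings::readAAStringSet(f)
    names(entries) <- sub("\\s.*", "", names(entries))
    role <- sub("_synthetic\\.faa$", "", basename(f))
    referenceLibrary(name = sub("\\.faa$", "", basename(f)),
                     entries = entries, molecule = "protein", role = role)
  })
  setNames(libs, vapply(libs, function(l) l@role, character(1)))
}

#' Load the bundled synthetic tRNA library
#' @return a \code{DNAStringSet} of synthetic tRNA stand-ins.
#' @export
trnaLibrary <- function() {
  f <- system.file("extdata", "trna_synthetic.fasta", package = "denovoTE")
  x <- Biostrings::readDNAStringSet(f)
  names(x) <- sub("\\s.*", "", names(x))
  x
}

.tagAA <- function(role, entry = 1) {
  libs <- proteinTagLibraries()
  ents <- libs[[role]]@entries
  if (is.character(entry)) entry <- match(entry, names(ents))
  as.character(ents[[entry]])
}

# build a stop-free in-frame ORF cassette of `lenAA` amino acids carrying
# the given tags at deterministic offsets
.orfCassette <- function(lenAA, tags) {
  aaAlph <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  aa <- paste(sample(aaAlph, lenAA, replace = TRUE), collapse = "")
  off <- 10
  for (tg in tags) {
    substr(aa, off + 1, off + nchar(tg)) <- tg
    off <- off + nchar(tg) + 15
  }
  .reverseTranslate(aa)
}

# ancestral element per family; returns list(element, ltrArm, tirArm)
.buildAncestor <- function(spec, gc, tirFromSource = NULL) {
  L <- spec$elementLength
  kind <- spec$teKind
  if (kind == "LTR") {
    ltr <- .randDna(spec$ltrLen, gc)
    trna <- trnaLibrary()[[1]]
    pbs <- .revcompChr(as.character(
      Biostrings::subseq(trna, length(trna) - 17, length(trna))))
    ppt <- "AAGGAGGGGAAG"
    cass <- switch(spec$orfCassette,
                   none = "",
                   rvt_like = .orfCassette(260, .tagAA("rvt", "rvt_1_synthetic")),
                   rvt_rve_like = .orfCassette(
                     340, c(.tagAA("rvt", "rvt_2_synthetic"),
                            .tagAA("rve"))),
                   transposase_like = .orfCassette(260,
                                                   .tagAA("transposase")))
    inner <- L - 2 * spec$ltrLen - nchar(pbs) - nchar(ppt) - nchar(cass)
    if (inner < 40) stop("elementLength too short for LTR structure")
    pad1 <- .randDna(inner %/% 2, gc)
    pad2 <- .randDna(inner - nchar(pad1), gc)
    el <- paste0(ltr, pbs, pad1, cass, pad2, ppt, ltr)
    return(list(element = el, ltrArm = ltr, tirArm = NULL))
  }
  if (kind == "NLTR") {
    cass <- switch(spec$orfCassette,
                   none = "",
                   rvt_like = .orfCassette(260, .tagAA("rvt", "rvt_1_synthetic")),
                   rvt_rve_like = .orfCassette(
                     340, c(.tagAA("rvt", "rvt_2_synthetic"),
                            .tagAA("rve"))),
                   transposase_like = .orfCassette(260,
                                                   .tagAA("transposase")))
    polyA <- strrep("A", 12)
    inner <- L - nchar(cass) - nchar(polyA)
    if (inner < 40) stop("elementLength too short for NLTR structure")
    pad1 <- .randDna(inner %/% 2, gc)
    pad2 <- .randDna(inner - nchar(pad1), gc)
    el <- paste0(pad1, cass, pad2, polyA)
    return(list(element = el, ltrArm = NULL, tirArm = NULL))
  }
  # TIR / MITE
  tir <- if (!is.null(tirFromSource)) tirFromSource
         else .randDna(spec$tirLen, gc)
  cass <- switch(spec$orfCassette,
                 none = "",
                 rvt_like = .orfCassette(260, .tagAA("rvt", "rvt_1_synthetic")),
                 rvt_rve_like = .orfCassette(
                   340, c(.tagAA("rvt", "rvt_2_synthetic"),
                          .tagAA("rve"))),
                 transposase_like = .orfCassette(260, .tagAA("transposase")))
  inner <- L - 2 * nchar(tir) - nchar(cass)
  if (inner < 20) stop("elementLength too short for TIR structure")
  pad1 <- .randDna(inner %/% 2, gc)
  pad2 <- .randDna(inner - nchar(pad1), gc)
  el <- paste0(tir, pad1, cass, pad2, .revcompChr(tir))
  list(element = el, ltrArm = NULL, tirArm = tir)
}

# mutate one copy: substitutions then short indels
.mutateCopy <- function(seq, substRate, indelRate) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  nSub <- rbinom(1, n, substRate)
  if (nSub > 0) {
    pos <- sample.int(n, nSub)
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
  }
  nInd <- rbinom(1, n, indelRate)
  if (nInd > 0) {
    for (k in seq_len(nInd)) {
      p <- sample.int(length(chars), 1)
      w <- sample.int(3, 1)
      if (runif(1) < 0.5) {
        ins <- sample(c("A", "C", "G", "T"), w, replace = TRUE)
        chars <- append(chars, ins, after = p)
      } else {
        hi <- min(length(chars), p + w - 1)
        if (hi - p + 1 < length(chars)) chars <- chars[-(p:hi)]
      }
    }
  }
  paste(chars, collapse = "")
}

#' Simulate a genome with planted TE families
#'
#' Background sequence is i.i.d. with the requested GC content (chance
#' 400-bp matches at 94% identity are then effectively impossible, keeping
#' discovery tests sharp). Each planted copy is independently mutated at
#' its family's substitution/indel rates; NLTR copies may be 5'-truncated;
#' LTR copies may be planted as solo LTRs. Copies are placed uniformly
#' with at least \code{minSpacing} nt between planted intervals. The
#' result is byte-deterministic for a given seed.
#'
#' @param specs list of \code{\link{familySpec}} objects.
#' @param genomeLength total genome length (single scaffold "chr1").
#' @param gc background GC fraction (default 0.5).
#' @param seed integer seed.
#' @param minSpacing minimum distance between planted copies (default 300).
#' @return a \code{\linkS4class{SyntheticGenome}}.
#' @export
simulateGenome <- function(specs, genomeLength = 2e6, gc = 0.5, seed = 1,
                           minSpacing = 300) {
  stopifnot(all(vapply(specs, inherits, logical(1), "FamilySpec")))
  labels <- vapply(specs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate family labels")
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  genomeLength <- as.integer(genomeLength)

  # ancestors (TIR families first so MITEs can inherit arms)
  ord <- order(vapply(specs, function(s)
    is.null(s$tirSource), logical(1)), decreasing = TRUE)
  anc <- list(); ltrArms <- list(); tirArms <- list()
  for (i in ord) {
    s <- specs[[i]]
    src <- NULL
    if (!is.null(s$tirSource)) {
      if (is.null(tirArms[[s$tirSource]]))
        stop("tirSource '", s$tirSource, "' not built before '",
             s$label, "'")
      src <- tirArms[[s$tirSource]]
      # MITEs keep the outer part of the donor TIR (shorter arm)
      keep <- if (!is.null(s$tirLen)) min(s$tirLen, nchar(src))
              else nchar(src)
      src <- substr(src, 1, keep)
    }
    a <- .buildAncestor(s, gc, src)
    anc[[s$label]] <- a$element
    if (!is.null(a$ltrArm)) ltrArms[[s$label]] <- a$ltrArm
    if (!is.null(a$tirArm)) tirArms[[s$label]] <- a$tirArm
  }

  # realize copies
  copies <- list()
  for (s in specs) {
    full <- anc[[s$label]]
    for (k in seq_len(s$copyNumber)) {
      copyType <- "full"
      base <- full
      if (s$teKind == "LTR" && runif(1) < s$soloLtrProb) {
        base <- ltrArms[[s$label]]
        copyType <- "solo_ltr"
      } else if (s$truncation == "five_prime_geometric" &&
                 runif(1) < s$truncProb) {
        tl <- rgeom(1, 1 / max(1, s$truncMean)) + 1L
        tl <- min(tl, nchar(base) - 450L)
        if (tl > 0) {
          base <- substr(base, tl + 1L, nchar(base))
          copyType <- "truncated"
        }
      }
      if (s$teKind == "MITE") copyType <- "mite"
      mut <- .mutateCopy(base, s$substRate, s$indelRate)
      copies[[length(copies) + 1]] <- list(family = s$label,
                                           copy_type = copyType,
                                           seq = mut)
    }
  }
  totalPlanted <- sum(vapply(copies, function(cp) nchar(cp$seq), numeric(1)))
  if (totalPlanted >= 0.5 * genomeLength)
    stop("total planted length exceeds half the genome; enlarge the genome")

  background <- .randDna(genomeLength, gc)
  # placement: sample non-overlapping insertion points with spacing
  placed <- IRanges::IRanges()
  positions <- integer(length(copies))
  for (i in seq_along(copies)) {
    w <- nchar(copies[[i]]$seq)
    ok <- FALSE
    for (attempt in seq_len(2000)) {
      st <- sample.int(genomeLength - w, 1)
      cand <- IRanges::IRanges(st, st + w - 1)
      if (length(placed) == 0 ||
          !any(IRanges::overlapsAny(
            cand, placed + minSpacing))) {
        placed <- c(placed, cand)
        positions[i] <- st
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place all copies; use a longer genome")
  }
  # overwrite background with copies (placement is on a fixed-length
  # canvas, so truth coordinates are exact)
  chars <- strsplit(background, "")[[1]]
  for (i in seq_along(copies)) {
    w <- nchar(copies[[i]]$seq)
    chars[positions[i]:(positions[i] + w - 1)] <-
      strsplit(copies[[i]]$seq, "")[[1]]
  }
  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- "chr1"

  truth <- GenomicRanges::GRanges(
    rep("chr1", length(copies)),
    IRanges::IRanges(positions,
                     width = vapply(copies, function(cp) nchar(cp$seq),
                                    numeric(1))),
    strand = rep("+", length(copies)),
    family = vapply(copies, `[[`, character(1), "family"),
    copy_type = vapply(copies, `[[`, character(1), "copy_type"))
  truth <- sort(truth)

  ancSet <- if (length(anc))
    Biostrings::DNAStringSet(unlist(anc[labels]))
  else Biostrings::DNAStringSet()
  ltrSet <- if (length(ltrArms))
    Biostrings::DNAStringSet(unlist(ltrArms)) else Biostrings::DNAStringSet()
  tirSet <- if (length(tirArms))
    Biostrings::DNAStringSet(unlist(tirArms)) else Biostrings::DNAStringSet()
  new("SyntheticGenome", genome = genome, truth = truth, specs = specs,
      ancestors = ancSet, ltrArms = ltrSet, tirArms = tirSet,
      seed = as.integer(seed))
}

#' The default planted-family benchmark configuration
#'
#' Twelve families in a 2-Mb genome at 1% per-copy substitution: three LTR
#' families (one planting half of its copies as solo LTRs, with a 500-nt
#' arm so solos pass the 400-nt discovery floor), three 5'-truncating NLTR
#' families, three transposase-bearing TIR families and three MITE
#' families inheriting their TIRs from the TIR families.
#'
#' @param substRate per-copy substitution rate (default 0.01).
#' @return list of \code{FamilySpec}.
#' @export
defaultBenchmarkSpecs <- function(substRate = 0.01) {
  list(
    familySpec("LTR1", "LTR", 4500, 5, ltrLen = 200,
               substRate = substRate, orfCassette = "rvt_rve_like"),
    familySpec("LTR2", "LTR", 3600, 5, ltrLen = 150,
               substRate = substRate, orfCassette = "rvt_rve_like"),
    familySpec("LTR3", "LTR", 4000, 6, ltrLen = 500,
               substRate = substRate, soloLtrProb = 0.5,
               orfCassette = "rvt_rve_like"),
    familySpec("NLTR1", "NLTR", 3000, 6, substRate = substRate,
               truncation = "five_prime_geometric", truncMean = 400,
               truncProb = 0.5, orfCassette = "rvt_like"),
    familySpec("NLTR2", "NLTR", 2600, 6, substRate = substRate,
               truncation = "five_prime_geometric", truncMean = 400,
               truncProb = 0.5, orfCassette = "rvt_like"),
    familySpec("NLTR3", "NLTR", 2200, 6, substRate = substRate,
               truncation = "five_prime_geometric", truncMean = 300,
               truncProb = 0.5, orfCassette = "rvt_like"),
    familySpec("TIR1", "TIR", 2000, 5, tirLen = 30, substRate = substRate,
               orfCassette = "transposase_like"),
    familySpec("TIR2", "TIR", 1700, 5, tirLen = 25, substRate = substRate,
               orfCassette = "transposase_like"),
    familySpec("TIR3", "TIR", 1400, 5, tirLen = 20, substRate = substRate,
               orfCassette = "transposase_like"),
    familySpec("MITE1", "MITE", 520, 5, tirLen = 22,
               substRate = substRate, tirSource = "TIR1"),
    familySpec("MITE2", "MITE", 480, 5, tirLen = 20,
               substRate = substRate, tirSource = "TIR2"),
    familySpec("MITE3", "MITE", 450, 5, tirLen = 18,
               substRate = substRate, tirSource = "TIR3"))
}

#' Score discovered families against the planted truth
#'
#' A discovered member matches a truth copy when their reciprocal overlap
#' is at least \code{minOverlap} of each. A discovered family maps to the
#' truth family holding the majority of its matched members. Family-level
#' recall is the fraction of planted families hit by at least one
#' discovered family; precision the fraction of discovered families that
#' map to some planted family; copy-level F1 combines matched copies on
#' both sides. A planted family hit by more than one discovered family is
#' reported as split.
#'
#' @param truth \code{GRanges} with \code{family} metadata (from
#'   \code{\link{simulateGenome}}).
#' @param families \code{GRanges} of discovered members with \code{family}
#'   metadata (from \code{\link{callFamilies}}).
#' @param minOverlap reciprocal-overlap fraction (default 0.5).
#' @return list(familyRecall, familyPrecision, copyF1, mapping, splits,
#'   perFamily).
#' @export
evaluateDiscovery <- function(truth, families, minOverlap = 0.5) {
  if (length(families) == 0) {
    return(list(familyRecall = 0, familyPrecision = NA_real_, copyF1 = 0,
                mapping = data.frame(), splits = character(0),
                perFamily = data.frame()))
  }
  ov <- GenomicRanges::findOverlaps(families, truth)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  inter <- GenomicRanges::width(GenomicRanges::pintersect(
    families[qh], truth[sh]))
  recip <- inter >= minOverlap * GenomicRanges::width(families[qh]) &
    inter >= minOverlap * GenomicRanges::width(truth[sh])
  qh <- qh[recip]; sh <- sh[recip]
  dfam <- S4Vectors::mcols(families)$family
  tfam <- S4Vectors::mcols(truth)$family
  mapping <- data.frame(discovered = dfam[qh], truthFamily = tfam[sh],
                        stringsAsFactors = FALSE)
  # majority truth family per discovered family
  majority <- vapply(split(mapping$truthFamily, mapping$discovered),
                     function(v) names(sort(table(v),
                                            decreasing = TRUE))[1],
                     character(1))
  truthFams <- unique(tfam)
  hitFams <- unique(unname(majority))
  familyRecall <- mean(truthFams %in% hitFams)
  familyPrecision <- mean(unique(dfam) %in% names(majority))
  matchedCopies <- length(unique(sh))
  matchedMembers <- length(unique(qh))
  prec <- matchedMembers / length(families)
  rec <- matchedCopies / length(truth)
  copyF1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  splits <- names(which(table(unname(majority)) > 1))
  perFamily <- do.call(rbind, lapply(truthFams, function(f) {
    idx <- which(tfam == f)
    data.frame(family = f, nPlanted = length(idx),
               nRecovered = length(unique(sh[sh %in% idx])),
               recall = length(unique(sh[sh %in% idx])) / length(idx))
  }))
  list(familyRecall = familyRecall, familyPrecision = familyPrecision,
       copyF1 = copyF1, mapping = mapping, splits = splits,
       perFamily = perFamily)
}
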