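## Sequence and interval I/O. Sequences live in Biostrings DNAStringSet
## objects (ids in names(), free-text descriptions in mcols()$description);
## intervals live in GRanges, 1-based closed per the Bioconductor convention.
## BED output converts to the format's 0-based half-open coordinates.

#' Read a DNA FASTA file into a normalized DNAStringSet
#'
#' Residues are uppercased and any IUPAC ambiguity code other than A/C/G/T/N
#' is normalized to N (a message reports how many). Gap characters are
#' rejected: this reader is for unaligned sequence. Ids (the first
#' whitespace-delimited token of each header) must be unique; the remainder
#' of the header is kept as the description.
#'
#' @param path path to a FASTA file.
#' @return a \code{DNAStringSet} named by id, with a \code{description}
#'   metadata column.
#' @export
readFastaDNA <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop("empty FASTA file: ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(raw))
  if (any(grepl("[-.]", seqs, perl = TRUE)))
    stop("gap character in unaligned FASTA: ", path)
  nonstd <- vapply(seqs,
                   function(s) nchar(gsub("[ACGTN]", "", s)), integer(1),
                   USE.NAMES = FALSE)
  if (sum(nonstd) > 0) {
    message("readFastaDNA: normalized ", sum(nonstd),
            " non-ACGTN residue(s) to N in ", basename(path))
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1),
                   USE.NAMES = FALSE)
  }
  if (any(nchar(seqs) < 1)) stop("zero-length sequence in ", path)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

#' Write a DNAStringSet (or AAStringSet) to FASTA
#' @param x an \code{XStringSet}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFastaDNA <- function(x, path) {
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Extract genomic intervals, honoring strand
#'
#' Minus-strand intervals are returned reverse-complemented.
#'
#' @param genome a named \code{DNAStringSet} of scaffolds.
#' @param gr a \code{GRanges} (1-based closed); \code{*} strand is treated
#'   as \code{+}.
#' @return a \code{DNAStringSet}, one sequence per range, named
#'   \code{seqid:start-end(strand)} unless \code{gr} carries names.
#' @export
extractInterval <- function(genome, gr) {
  sid <- as.character(GenomicRanges::seqnames(gr))
  bad <- setdiff(unique(sid), names(genome))
  if (length(bad)) stop("unknown scaffold id(s): ", paste(bad, collapse = ", "))
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  lens <- setNames(width(genome), names(genome))
  if (any(st < 1) || any(en > lens[sid]))
    stop("interval out of scaffold bounds")
  res <- Biostrings::DNAStringSet(lapply(seq_along(gr), function(i) {
    s <- Biostrings::subseq(genome[[sid[i]]], st[i], en[i])
    if (as.character(GenomicRanges::strand(gr)[i]) == "-")
      s <- Biostrings::reverseComplement(s)
    s
  }))
  nm <- names(gr)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- sprintf("%s:%d-%d(%s)", sid, st, en,
                  as.character(GenomicRanges::strand(gr)))
  names(res) <- nm
  res
}

#' Write intervals as BED6
#'
#' Converts from the internal 1-based closed \code{GRanges} representation
#' to BED's 0-based half-open coordinates; the name column is taken from
#' \code{mcols(gr)$name}, then \code{names(gr)}, then \code{"."}.
#'
#' @param gr a \code{GRanges}.
#' @param path output path.
#' @param score numeric score column (recycled; default 0).
#' @return invisibly, \code{path}.
#' @export
writeBed6 <- function(gr, path, score = 0) {
  if (length(gr) == 0) {
    file.create(path)
    return(invisible(path))
  }
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- names(gr)
  if (is.null(nm)) nm <- rep(".", length(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = nm, score = rep_len(score, length(gr)),
                   strand = strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file into GRanges
#' @param path path to a BED file (at least 6 columns).
#' @return a \code{GRanges} with a \code{name} metadata column.
#' @export
readBed6 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0)
    return(GenomicRanges::GRanges(name = character(0)))
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("BED file has fewer than 6 columns: ", path)
  gr <- GenomicRanges::GRanges(df[[1]],
        IRanges::IRanges(df[[2]] + 1L, df[[3]]), strand = df[[6]])
  S4Vectors::mcols(gr)$name <- as.character(df[[4]])
  S4Vectors::mcols(gr)$score <- df[[5]]
  gr
}
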