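## Thin wrapper around the NCBI BLAST+ command-line programs, the local
## alignment engine behind self-alignment, clustering, signature scans and
## library searches. Everything travels through the standard 12-column
## tabular format (outfmt 6).

.hitCols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
              "gapopen", "qstart", "qend", "sstart", "send",
              "evalue", "bitscore")

.emptyHits <- function() {
  df <- as.data.frame(setNames(rep(list(character(0)), 12), .hitCols))
  num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore")
  for (k in num) df[[k]] <- numeric(0)
  df
}

.blastBin <- function(program) {
  bin <- Sys.which(program)
  if (!nzchar(bin))
    stop("BLAST+ program '", program, "' not found on the PATH; ",
         "install NCBI BLAST+ to use the alignment-dependent stages")
  bin
}

#' Run a BLAST+ pairwise search and return the tabular hits
#'
#' Runs \code{program -query ... -subject ...} (bl2seq mode, no database
#' build) and parses the standard 12-column tabular output. All sequences in
#' \code{query} are compared against all sequences in \code{subject}.
#'
#' @param query,subject \code{XStringSet} objects (written to temporary
#'   FASTA files) or paths to existing FASTA files.
#' @param program one of \code{"blastn"}, \code{"tblastx"}, \code{"blastx"}.
#' @param task blastn task (\code{"megablast"}, \code{"blastn"},
#'   \code{"blastn-short"}); ignored for translated programs.
#' @param evalue e-value cutoff passed to BLAST.
#' @param percIdentity minimum percent identity (blastn only), or NULL.
#' @param wordSize word size override, or NULL for the task default.
#' @param dust disable low-complexity filtering when FALSE (the default:
#'   repeat pipelines must not mask the very repeats they look for).
#' @param extraArgs extra command-line arguments (character vector).
#' @return data.frame with columns qseqid, sseqid, pident, length, mismatch,
#'   gapopen, qstart, qend, sstart, send, evalue, bitscore.
#' @export
blastPairs <- function(query, subject,
                       program = c("blastn", "tblastx", "blastx"),
                       task = NULL, evalue = 10, percIdentity = NULL,
                       wordSize = NULL, dust = FALSE,
                       extraArgs = character()) {
  program <- match.arg(program)
  bin <- .blastBin(program)
  qf <- .asFastaPath(query, "query")
  sf <- .asFastaPath(subject, "subject")
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out), add = TRUE)
  args <- c("-query", qf, "-subject", sf, "-outfmt", shQuote("6 std"),
            "-evalue", format(evalue, scientific = TRUE), "-out", out)
  if (program == "blastn") {
    if (!is.null(task)) args <- c(args, "-task", task)
    if (!is.null(percIdentity))
      args <- c(args, "-perc_identity", format(percIdentity))
    if (!dust) args <- c(args, "-dust", "no", "-soft_masking", "false")
  } else {
    if (!dust) args <- c(args, "-seg", "no")
  }
  if (!is.null(wordSize)) args <- c(args, "-word_size", wordSize)
  args <- c(args, extraArgs)
  status <- system2(bin, args, stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0)
    stop(program, " failed (exit ", code, "): ",
         paste(status, collapse = "\n"))
  if (!file.exists(out) || file.size(out) == 0) return(.emptyHits())
  hits <- read.table(out, sep = "\t", stringsAsFactors = FALSE,
                     col.names = .hitCols)
  hits$qseqid <- as.character(hits$qseqid)
  hits$sseqid <- as.character(hits$sseqid)
  hits
}

.asFastaPath <- function(x, what) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("no such ", what, " FASTA: ", x)
    return(x)
  }
  if (!methods::is(x, "XStringSet"))
    stop(what, " must be an XStringSet or a FASTA path")
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  path <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(x, path)
  path
}
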