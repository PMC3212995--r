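## Similarity annotation of consensus sequences against reference
## libraries, with the e < 1e-15 positivity rule and the 11-field
## best-match summary.

#' Search a reference library with a nucleotide query
#'
#' Mode picks the program: \code{"nucleotide"} runs blastn (nucleotide
#' library), \code{"tblastx"} compares six-frame translations of query and
#' nucleotide library (for highly divergent or deteriorated elements), and
#' \code{"blastx"} compares the translated query against a protein library.
#' All hits are returned; those with e-value below \code{eMax} carry the
#' positivity flag used for annotation.
#'
#' @param query named \code{DNAStringSet}.
#' @param library a \code{ReferenceLibrary}.
#' @param mode \code{"nucleotide"}, \code{"tblastx"} or \code{"blastx"}.
#' @param eMax positivity threshold (default 1e-15).
#' @return data.frame: the 12 tabular columns plus \code{positive},
#'   \code{library} and \code{role}.
#' @export
searchLibrary <- function(query, library,
                          mode = c("nucleotide", "tblastx", "blastx"),
                          eMax = 1e-15) {
  mode <- match.arg(mode)
  stopifnot(is(library, "ReferenceLibrary"))
  if (length(query) == 0) stop("empty query")
  needed <- if (mode == "blastx") "protein" else "nucleotide"
  if (library@molecule != needed)
    stop("mode '", mode, "' requires a ", needed, " library; '",
         library@name, "' is ", library@molecule)
  program <- switch(mode, nucleotide = "blastn", tblastx = "tblastx",
                    blastx = "blastx")
  hits <- blastPairs(query, library@entries, program = program,
                     task = if (program == "blastn") "blastn" else NULL,
                     evalue = 1e-3)
  hits$positive <- hitPositive(hits$evalue, eMax)
  hits$library <- rep_len(library@name, nrow(hits))
  hits$role <- rep_len(library@role, nrow(hits))
  hits
}

#' Load a 12-column tabular hit table
#'
#' Reads an outfmt-6-style file (query id, subject id, \%identity, length,
#' mismatches, gap opens, q.start, q.end, s.start, s.end, e-value, score),
#' applying the positivity flag at \code{eMax}. Malformed lines raise an
#' error naming the line number.
#'
#' @param path path to the tabular file.
#' @param eMax positivity threshold (default 1e-15).
#' @return data.frame as from \code{\link{searchLibrary}} (without
#'   library/role columns).
#' @export
loadHitTable <- function(path, eMax = 1e-15) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    out <- .emptyHits(); out$positive <- logical(0); return(out)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  bad <- which(nf != 12)
  if (length(bad))
    stop("malformed hit table ", path, ": line ", bad[1], " has ",
         nf[bad[1]], " fields (12 expected)")
  mat <- do.call(rbind, fields)
  df <- data.frame(qseqid = mat[, 1], sseqid = mat[, 2],
                   stringsAsFactors = FALSE)
  numCols <- .hitCols[3:12]
  for (k in seq_along(numCols)) {
    v <- suppressWarnings(as.numeric(mat[, k + 2]))
    if (anyNA(v))
      stop("malformed hit table ", path, ": non-numeric '", numCols[k],
           "' on line ", which(is.na(v))[1])
    df[[numCols[k]]] <- v
  }
  df$positive <- hitPositive(df$evalue, eMax)
  df
}

#' Write hits in 12-column tabular format
#' @param hits a hit data.frame carrying the 12 standard columns.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeHitTable <- function(hits, path) {
  write.table(hits[, .hitCols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Eleven-field best-match summary for one query against one library
#'
#' Best hit = lowest e-value, ties broken by higher score then subject id.
#' The summary fields follow the classic spreadsheet layout: e-value, best
#' match, score, extent of the match (query span), length of best match
#' (alignment columns), \% identity, \% match length (query span over query
#' length), first residue of match (query start), first residue of sequence
#' (subject start), number of segments (hits to the best subject), and
#' orientation.
#'
#' @param hits hit table for a single query/library combination.
#' @param queryLen query length in nt.
#' @return one-row data.frame with the 11 fields plus \code{positive};
#'   all-NA (positive = FALSE) when \code{hits} is empty.
#' @export
bestHitSummary <- function(hits, queryLen) {
  if (nrow(hits) == 0) {
    return(data.frame(e_value = NA_real_, best_match = NA_character_,
                      score = NA_real_, extent_of_match = NA_integer_,
                      length_of_best_match = NA_integer_,
                      pct_identity = NA_real_, pct_match_length = NA_real_,
                      first_residue_of_match = NA_integer_,
                      first_residue_of_sequence = NA_integer_,
                      number_of_segments = NA_integer_,
                      orientation = NA_character_, positive = FALSE,
                      stringsAsFactors = FALSE))
  }
  ord <- order(hits$evalue, -hits$bitscore, hits$sseqid)
  best <- hits[ord[1], ]
  segments <- sum(hits$sseqid == best$sseqid)
  orientation <- if (best$send >= best$sstart) "+" else "-"
  extent <- abs(best$qend - best$qstart) + 1L
  data.frame(e_value = best$evalue, best_match = best$sseqid,
             score = best$bitscore, extent_of_match = extent,
             length_of_best_match = best$length,
             pct_identity = best$pident,
             pct_match_length = 100 * extent / queryLen,
             first_residue_of_match = min(best$qstart, best$qend),
             first_residue_of_sequence = min(best$sstart, best$send),
             number_of_segments = segments,
             orientation = orientation,
             positive = isTRUE(best$positive),
             stringsAsFactors = FALSE)
}
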