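#' @include curate.R
NULL

#' Parse NCBI BLAST tabular output (outfmt 6)
#'
#' Cross-validation backend: reads the default 12-column tabular format
#' of a blastn self-comparison so its alignments can be compared with
#' [selfCompare()] output (after [dropSelfIdentity()] and
#' [deduplicateHsps()]).  Minus-strand alignments are recognized by
#' descending subject coordinates and normalized to ascending intervals
#' with strand `"-"`.  Raw scores are recomputed from length and
#' mismatch count under the supplied scoring so they are comparable with
#' engine scores; gapped rows are refused (the method is ungapped).
#'
#' @param path tabular output file (`-outfmt 6`).
#' @param scoring [ScoringScheme-class] used to recompute raw scores.
#' @return HSP `data.frame` (see [extendUngapped()]).
#' @export
readBlastTable <- function(path, scoring = scoringScheme()) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  t <- utils::read.delim(path, header = FALSE, col.names = cols,
                         stringsAsFactors = FALSE)
  if (!nrow(t)) return(.emptyHsp())
  if (any(t$gapopen > 0))
    stop("gapped alignments in ", path,
         "; expected ungapped blastn output")
  minus <- t$sstart > t$send
  h <- data.frame(
    qStart = pmin(t$qstart, t$qend), qEnd = pmax(t$qstart, t$qend),
    sStart = pmin(t$sstart, t$send), sEnd = pmax(t$sstart, t$send),
    strand = ifelse(minus, "-", "+"),
    length = t$length,
    score = scoring@matchReward * (t$length - t$mismatch) +
      scoring@mismatchPenalty * t$mismatch,
    mismatches = as.integer(t$mismatch),
    stringsAsFactors = FALSE)
  .sortHsp(h)
}

#' Remove the full-length self-identity alignment
#'
#' A BLAST self-comparison reports the trivial alignment of the genome
#' with itself; [selfCompare()] never emits it, so imported tables must
#' drop it (and any other exact plus-strand self-listing) before
#' comparison or curation.
#'
#' @param hsps HSP `data.frame`.
#' @return the table without plus-strand rows whose query and subject
#'   intervals are identical.
#' @export
dropSelfIdentity <- function(hsps) {
  if (!nrow(hsps)) return(hsps)
  self <- hsps$strand == "+" & hsps$qStart == hsps$sStart &
    hsps$qEnd == hsps$sEnd
  out <- hsps[!self, , drop = FALSE]
  rownames(out) <- NULL
  out
}
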