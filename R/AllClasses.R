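#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet readBStringSet
#'   writeXStringSet reverseComplement
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
#' @importClassesFrom Biostrings DNAString
NULL

setOldClass(c("data.table", "data.frame"))

#' A validated single-sequence genome
#'
#' Holds one nucleotide sequence (typically an organelle genome of
#' 15 kb to 1 Mb), its identifier, and whether the molecule is circular.
#' After validation the sequence contains only A/C/G/T, plus N for
#' positions masked at read time; a masked position can never take part
#' in a seed word or an alignment column, including against itself.
#'
#' @slot id accession-like identifier.
#' @slot seq the sequence as a [Biostrings::DNAString].
#' @slot circular logical; `TRUE` for circular molecules.
#' @export
setClass("GenomeSeq",
  representation(id = "character", seq = "DNAString", circular = "logical"))

setValidity("GenomeSeq", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@seq) < 1L)
    msg <- c(msg, "sequence must have length >= 1")
  if (length(object@circular) != 1L || is.na(object@circular))
    msg <- c(msg, "'circular' must be TRUE or FALSE")
  s <- as.character(object@seq)
  if (grepl("[^ACGTN]", s))
    msg <- c(msg, "sequence may contain only A/C/G/T (or N for masked)")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeSeq
#'
#' @param id single identifier string.
#' @param seq character string or `DNAString`; uppercased on input.
#' @param circular logical flag, default `FALSE` (linear).
#' @return a [GenomeSeq-class] object.
#' @examples
#' g <- GenomeSeq("toy", "ACGTACGT")
#' genomeLength(g)
#' @export
GenomeSeq <- function(id, seq, circular = FALSE) {
  if (is.character(seq)) seq <- DNAString(toupper(seq))
  new("GenomeSeq", id = as.character(id), seq = seq,
      circular = isTRUE(circular))
}

setMethod("show", "GenomeSeq", function(object) {
  cat("GenomeSeq", object@id, "-", length(object@seq), "bp,",
      if (object@circular) "circular" else "linear", "\n")
})

#' Alignment scoring scheme
#'
#' Parameters of the ungapped self-comparison: the exact seed word size,
#' the match reward and mismatch penalty (blastn-style, in raw score
#' units), the minimum score for a reported alignment, and the X-drop
#' used during extension (extension stops once the running score falls
#' more than `xDrop` below the best score seen; the alignment ends at
#' the farthest position attaining the best score, so equal-scoring
#' extensions resolve to the longest).
#'
#' The default minimum score equals `wordSize * matchReward`: with the
#' stringent default scoring (+1/-20) any alignment that clears it
#' necessarily contains a word-size exact core, which stands in for the
#' permissive E-value reporting threshold of a BLAST-based search.  The
#' default `xDrop` of `2 * abs(mismatchPenalty)` lets extension cross
#' isolated mismatches but terminates at a cluster of three or more
#' consecutive ones, so a long duplication interrupted by a central
#' mismatch cluster is reported as two distinct repeats.
#'
#' @slot wordSize exact seed length in bp (>= 8).
#' @slot matchReward positive per-column score for a match.
#' @slot mismatchPenalty negative per-column score for a mismatch.
#' @slot minScore minimum reported alignment score (positive).
#' @slot xDrop positive extension drop-off in raw score units.
#' @export
setClass("ScoringScheme",
  representation(wordSize = "integer", matchReward = "numeric",
                 mismatchPenalty = "numeric", minScore = "numeric",
                 xDrop = "numeric"))

setValidity("ScoringScheme", function(object) {
  msg <- character()
  if (object@wordSize < 8L) msg <- c(msg, "wordSize must be >= 8")
  if (object@matchReward <= 0) msg <- c(msg, "matchReward must be > 0")
  if (object@mismatchPenalty >= 0) msg <- c(msg, "mismatchPenalty must be < 0")
  if (object@minScore <= 0) msg <- c(msg, "minScore must be > 0")
  if (object@xDrop <= 0) msg <- c(msg, "xDrop must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a ScoringScheme
#'
#' @param wordSize exact seed length in bp; default 50.
#' @param matchReward match score; default +1.
#' @param mismatchPenalty mismatch score; default -20.
#' @param minScore minimum reported score; default
#'   `wordSize * matchReward`.
#' @param xDrop extension drop-off; default `2 * abs(mismatchPenalty)`.
#' @return a [ScoringScheme-class] object.
#' @examples
#' scoringScheme()
#' scoringScheme(wordSize = 24, mismatchPenalty = -5)
#' @export
scoringScheme <- function(wordSize = 50L, matchReward = 1,
                          mismatchPenalty = -20,
                          minScore = wordSize * matchReward,
                          xDrop = 2 * abs(mismatchPenalty)) {
  new("ScoringScheme", wordSize = as.integer(wordSize),
      matchReward = as.numeric(matchReward),
      mismatchPenalty = as.numeric(mismatchPenalty),
      minScore = as.numeric(minScore), xDrop = as.numeric(xDrop))
}

setMethod("show", "ScoringScheme", function(object) {
  cat(sprintf(
    "ScoringScheme: word %d, match %+g, mismatch %+g, minScore %g, xDrop %g\n",
    object@wordSize, object@matchReward, object@mismatchPenalty,
    object@minScore, object@xDrop))
})

#' Exact-word seed index of a genome
#'
#' Maps every word of length `wordSize` in the genome (and, queryably,
#' its reverse complement) to the sorted positions of its occurrences.
#' Words overlapping a masked residue are absent.  Positions are 1-based.
#'
#' @slot wordSize word length in bp.
#' @slot genomeId identifier of the indexed genome.
#' @slot forward keyed table (word, pos) over the forward strand.
#' @slot revcomp keyed table (word, pos) over the reverse complement,
#'   positions in reverse-complement coordinates.
#' @export
setClass("SeedIndex",
  representation(wordSize = "integer", genomeId = "character",
                 forward = "data.table", revcomp = "data.table"))

setMethod("show", "SeedIndex", function(object) {
  cat("SeedIndex for", object@genomeId, "- word size", object@wordSize,
      "-", nrow(object@forward), "indexed words\n")
})

#' A distinct repeat family
#'
#' One distinct repeated sequence together with every genomic copy.
#' All copies share a single length (the curation premise under
#' stringent mismatch penalties); the representative is the genome
#' subsequence of the first plus-strand copy.  A palindromic locus
#' appears as a pair of copies with identical coordinates on opposite
#' strands.
#'
#' @slot familyId label such as "R1", assigned by descending length.
#' @slot representative representative sequence ([Biostrings::DNAString]).
#' @slot copies [GenomicRanges::GRanges] of all copies; strand is the
#'   copy orientation and the metadata column `mismatches` counts
#'   substitutions relative to the representative.
#' @slot tandem logical; `TRUE` when any two copies overlap or abut.
#' @export
setClass("RepeatFamily",
  representation(familyId = "character", representative = "DNAString",
                 copies = "GRanges", tandem = "logical"))

setValidity("RepeatFamily", function(object) {
  msg <- character()
  n <- length(object@copies)
  if (n < 1L) msg <- c(msg, "a family needs at least one located copy")
  w <- IRanges::width(object@copies)
  if (n && any(w != length(object@representative)))
    msg <- c(msg, "all copies must have the representative's length")
  if (n && is.null(mcols(object@copies)$mismatches))
    msg <- c(msg, "copies must carry a 'mismatches' metadata column")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RepeatFamily", function(object) {
  cat(sprintf("RepeatFamily %s: %d bp, %d copies%s\n",
              object@familyId, length(object@representative),
              length(object@copies),
              if (object@tandem) " (tandem)" else ""))
})
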