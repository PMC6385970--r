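#' @include seqio.R
#' @import data.table
NULL

## ---- diagonal match vectors -------------------------------------------
## "+" strand: position t pairs with t + d (d >= 1); match vector over
## t = 1 .. L - d.  NA marks a masked column (hard barrier).
.diagMatch <- function(code, d) {
  n <- length(code) - d
  a <- code[seq_len(n)]
  b <- code[seq.int(d + 1L, d + n)]
  m <- a == b
  m[a == 9L | b == 9L] <- NA
  m
}

## "-" strand: antidiagonal c; position t pairs with c - t (reverse
## complement), a match when the two codes sum to 5.  Returns the match
## vector over t = tlo .. thi together with tlo.
.antiMatch <- function(code, cc) {
  L <- length(code)
  tlo <- max(1L, cc - L)
  thi <- min(L, cc - 1L)
  if (thi < tlo) return(list(tlo = tlo, m = logical(0L)))
  a <- code[seq.int(tlo, thi)]
  b <- code[seq.int(cc - tlo, by = -1L, length.out = thi - tlo + 1L)]
  m <- (a + b) == 5L
  m[a == 9L | b == 9L] <- NA
  list(tlo = tlo, m = m)
}

## ---- X-drop extension --------------------------------------------------
## One-sided extension over the outward-ordered match vector v.  Scoring
## accumulates reward/penalty per column; scanning stops at a masked
## column, the sequence end, or when the running score falls more than
## xDrop below the running best.  The extension length returned is the
## farthest offset attaining the best cumulative score (ties resolve to
## the longest extension); 0 when no extension improves or equals it.
.xdropSide <- function(v, reward, penalty, xDrop) {
  if (!length(v)) return(0L)
  na <- which(is.na(v))
  if (length(na)) v <- v[seq_len(na[1L] - 1L)]
  if (!length(v)) return(0L)
  C <- cumsum(ifelse(v, reward, penalty))
  B <- pmax(cummax(C), 0)
  trig <- which(C < B - xDrop)
  if (length(trig)) C <- C[seq_len(trig[1L] - 1L)]
  if (!length(C)) return(0L)
  best <- max(0, max(C))
  w <- which(C == best)
  if (length(w)) max(w) else 0L
}

## extend a seed run [a, b] (local indices into match vector m, all TRUE)
## in both directions; returns c(lo, hi)
.xdropExtend <- function(m, a, b, scoring) {
  r <- scoring@matchReward; p <- scoring@mismatchPenalty; X <- scoring@xDrop
  leftv <- if (a > 1L) rev(m[seq_len(a - 1L)]) else logical(0L)
  rightv <- if (b < length(m)) m[seq.int(b + 1L, length(m))] else logical(0L)
  c(a - .xdropSide(leftv, r, p, X), b + .xdropSide(rightv, r, p, X))
}

## ---- seed index --------------------------------------------------------

#' Build the exact-word seed index of a genome
#'
#' Indexes every word of length `wordSize` on the forward strand and on
#' the reverse complement; words containing a masked residue are absent.
#' This replaces the word lookup of a BLAST-style search with an exact,
#' exhaustive index.
#'
#' @param genome a [GenomeSeq-class].
#' @param wordSize word length in bp; must not exceed the genome length.
#' @return a [SeedIndex-class].
#' @examples
#' idx <- buildSeedIndex(GenomeSeq("toy", "ACGTACGT"), 4)
#' seedPositions(idx, "ACGT")
#' @export
buildSeedIndex <- function(genome, wordSize) {
  wordSize <- as.integer(wordSize)
  s <- genomeString(genome)
  code <- .encodeSeq(s)
  if (wordSize > length(code))
    stop("word size (", wordSize, ") exceeds genome length (",
         length(code), ")")
  rcs <- .revcompStr(s)
  new("SeedIndex", wordSize = wordSize, genomeId = genomeId(genome),
      forward = .kmerTable(s, code, wordSize),
      revcomp = .kmerTable(rcs, .encodeSeq(rcs), wordSize))
}

#' Look up the forward-strand positions of a word
#'
#' @param index a [SeedIndex-class].
#' @param word character word of the index's word size.
#' @param revcomp if `TRUE`, look the word up on the reverse complement
#'   strand instead (positions returned in reverse-complement
#'   coordinates).
#' @return sorted integer positions (1-based); empty when absent.
#' @export
seedPositions <- function(index, word, revcomp = FALSE) {
  if (nchar(word) != index@wordSize)
    stop("word must have length ", index@wordSize)
  tab <- if (revcomp) index@revcomp else index@forward
  sort(tab[list(word), on = "w", nomatch = NULL]$pos)
}

## ---- seed enumeration --------------------------------------------------

.emptySeeds <- function() {
  data.frame(qStart = integer(), qEnd = integer(), sStart = integer(),
             sEnd = integer(), strand = character(), span = integer(),
             stringsAsFactors = FALSE)
}

#' Enumerate coalesced seed matches of a genome against itself
#'
#' Yields every pair of positions sharing an exact word on the same
#' strand and every pair where one word is the reverse complement of the
#' other, excluding the trivial self-match of each position with itself.
#' Seeds lying on the same (anti)diagonal in one maximal exact run are
#' coalesced into a single seed whose `span` is the run length, so a
#' long exact duplication contributes one seed rather than thousands.
#' Each unordered pair is reported once (canonical orientation: query
#' interval not after subject interval).
#'
#' @param index [SeedIndex-class] built from `genome`.
#' @param genome the indexed [GenomeSeq-class].
#' @return `data.frame` with columns `qStart`, `qEnd`, `sStart`, `sEnd`,
#'   `strand`, `span`.  On the minus strand the alignment pairs `qStart`
#'   with `sEnd`.
#' @export
enumerateSeedMatches <- function(index, genome) {
  k <- index@wordSize
  L <- genomeLength(genome)
  w <- pos <- i <- j <- d <- rid <- NULL  # data.table NSE

  fwd <- index@forward
  plus <- fwd[, {
    if (.N > 1L) {
      p <- sort(pos)
      cmb <- utils::combn(p, 2L)
      list(i = cmb[1L, ], j = cmb[2L, ])
    } else NULL
  }, by = w]

  seedsP <- .emptySeeds()
  if (nrow(plus)) {
    pd <- data.table(d = plus$j - plus$i, i = plus$i)
    setorder(pd, d, i)
    pd[, rid := cumsum(c(TRUE, diff(i) != 1L | diff(d) != 0L))]
    runs <- pd[, list(qStart = i[1L], span = i[.N] - i[1L] + k,
                      d = d[1L]), by = rid]
    seedsP <- data.frame(qStart = runs$qStart,
                         qEnd = runs$qStart + runs$span - 1L,
                         sStart = runs$qStart + runs$d,
                         sEnd = runs$qStart + runs$span - 1L + runs$d,
                         strand = "+", span = runs$span,
                         stringsAsFactors = FALSE)
  }

  mrg <- merge(fwd, index@revcomp, by = "w", allow.cartesian = TRUE,
               suffixes = c(".q", ".r"))
  seedsM <- .emptySeeds()
  if (nrow(mrg)) {
    qi <- mrg$pos.q
    rj <- mrg$pos.r
    keep <- (qi + rj) <= (L - k + 2L)  # one listing per mirror pair
    qi <- qi[keep]; rj <- rj[keep]
    if (length(qi)) {
      md <- data.table(cc = qi + L - rj + 1L, i = qi)
      setorder(md, cc, i)
      md[, rid := cumsum(c(TRUE, diff(i) != 1L | diff(cc) != 0L))]
      cc <- NULL
      runs <- md[, list(qStart = i[1L], span = i[.N] - i[1L] + k,
                        cc = cc[1L]), by = rid]
      seedsM <- data.frame(qStart = runs$qStart,
                           qEnd = runs$qStart + runs$span - 1L,
                           sStart = runs$cc - (runs$qStart + runs$span - 1L),
                           sEnd = runs$cc - runs$qStart,
                           strand = "-", span = runs$span,
                           stringsAsFactors = FALSE)
    }
  }
  out <- rbind(seedsP, seedsM)
  rownames(out) <- NULL
  out
}

## ---- extension of one seed --------------------------------------------

## seed: list/1-row data.frame with qStart, qEnd, sStart, sEnd, strand
.extendSeedRow <- function(code, seed, scoring) {
  r <- scoring@matchReward; p <- scoring@mismatchPenalty
  if (seed$strand == "+") {
    d <- seed$sStart - seed$qStart
    m <- .diagMatch(code, d)
    ext <- .xdropExtend(m, seed$qStart, seed$qEnd, scoring)
    lo <- ext[1L]; hi <- ext[2L]
    mm <- sum(!m[seq.int(lo, hi)])
    q1 <- lo; q2 <- hi; s1 <- lo + d; s2 <- hi + d
    strand <- "+"
  } else {
    cc <- seed$qStart + seed$sEnd
    am <- .antiMatch(code, cc)
    a <- seed$qStart - am$tlo + 1L
    b <- seed$qEnd - am$tlo + 1L
    ext <- .xdropExtend(am$m, a, b, scoring)
    mm <- sum(!am$m[seq.int(ext[1L], ext[2L])])
    t1 <- am$tlo + ext[1L] - 1L
    t2 <- am$tlo + ext[2L] - 1L
    q1 <- t1; q2 <- t2; s1 <- cc - t2; s2 <- cc - t1
    if (q1 > s1 || (q1 == s1 && q2 > s2)) {  # canonical orientation
      tmp1 <- q1; tmp2 <- q2; q1 <- s1; q2 <- s2; s1 <- tmp1; s2 <- tmp2
    }
    strand <- "-"
  }
  len <- q2 - q1 + 1L
  score <- r * (len - mm) + p * mm
  if (score < scoring@minScore) return(NULL)
  data.frame(qStart = q1, qEnd = q2, sStart = s1, sEnd = s2,
             strand = strand, length = len, score = score,
             mismatches = as.integer(mm), stringsAsFactors = FALSE)
}

#' Extend one seed match into an ungapped alignment
#'
#' Extends the seed in both directions along its (anti)diagonal under
#' X-drop semantics (see [scoringScheme()]): scanning stops at the
#' sequence ends, at a masked residue, or when the running score drops
#' more than `xDrop` below the best seen; the reported segment ends at
#' the farthest position attaining the best score, so equal-scoring
#' extensions resolve to the longest segment.
#'
#' @param genome the [GenomeSeq-class] the seed refers to.
#' @param seed one row of [enumerateSeedMatches()] output (or a list
#'   with fields `qStart`, `qEnd`, `sStart`, `sEnd`, `strand`).
#' @param scoring a [ScoringScheme-class].
#' @return a one-row HSP `data.frame` (columns `qStart`, `qEnd`,
#'   `sStart`, `sEnd`, `strand`, `length`, `score`, `mismatches`), or
#'   `NULL` when the extended segment scores below `minScore`.
#' @export
extendUngapped <- function(genome, seed, scoring = scoringScheme()) {
  .extendSeedRow(.encodeSeq(genomeString(genome)), as.list(seed), scoring)
}

## ---- whole-genome self comparison -------------------------------------

.selfCompareLinear <- function(genome, scoring) {
  idx <- buildSeedIndex(genome, scoring@wordSize)
  seeds <- enumerateSeedMatches(idx, genome)
  if (!nrow(seeds)) return(.emptyHsp())
  code <- .encodeSeq(genomeString(genome))
  out <- vector("list", nrow(seeds))
  for (r in seq_len(nrow(seeds)))
    out[[r]] <- .extendSeedRow(code, lapply(seeds, `[`, r), scoring)
  h <- do.call(rbind, c(list(.emptyHsp()), out))
  .sortHsp(.dedupHspRows(h))
}

## circular topology: the sequence is conceptually doubled; alignments
## whose query starts beyond the original length are duplicates, no
## alignment may exceed the original length, and the self-identity of
## the genome with its own junction image (diagonal offset exactly L)
## is discarded.  Subject coordinates are reduced modulo L; an end
## beyond L denotes an interval wrapping across the junction.
.selfCompareCircular <- function(genome, scoring) {
  L <- genomeLength(genome)
  s <- genomeString(genome)
  dbl <- GenomeSeq(genomeId(genome), paste0(s, s), circular = FALSE)
  h <- .selfCompareLinear(dbl, scoring)
  if (!nrow(h)) return(h)
  h <- h[h$length <= L & h$qStart <= L, , drop = FALSE]
  selfdiag <- h$strand == "+" & (h$sStart - h$qStart) == L
  h <- h[!selfdiag, , drop = FALSE]
  shift <- h$sStart > L
  h$sStart[shift] <- h$sStart[shift] - L
  h$sEnd[shift] <- h$sEnd[shift] - L
  swap <- h$qStart > h$sStart |
    (h$qStart == h$sStart & h$qEnd > h$sEnd)
  if (any(swap)) {
    tmp <- h[swap, c("qStart", "qEnd")]
    h[swap, c("qStart", "qEnd")] <- h[swap, c("sStart", "sEnd")]
    h[swap, c("sStart", "sEnd")] <- tmp
  }
  .sortHsp(.dedupHspRows(h))
}

#' Find all ungapped self-alignments of a genome
#'
#' Orchestrates seed indexing, seed enumeration and X-drop extension on
#' both strands, removes the full-length self-identity and duplicate
#' listings, and returns the distinct high-scoring segment pairs sorted
#' by descending score.  On a random sequence of organelle scale the
#' result is empty at the default 50-bp word: a chance 50-mer collision
#' has probability around 1e-20 at 100 kb.  A perfect palindrome is a
#' genuine reverse-complement self-match and is reported with
#' overlapping query and subject intervals.
#'
#' @param genome a [GenomeSeq-class]; circular genomes are handled by
#'   conceptual doubling (subject intervals wrapping the junction have
#'   `sEnd > genomeLength`).
#' @param scoring a [ScoringScheme-class].
#' @return HSP `data.frame` (see [extendUngapped()] for columns); the
#'   query interval never sorts after the subject interval, so each
#'   unordered pair appears exactly once.
#' @examples
#' g <- generateBackground(3000, seed = 1)
#' nrow(selfCompare(g))  # 0: random sequence has no 50-bp repeats
#' @export
selfCompare <- function(genome, scoring = scoringScheme()) {
  stopifnot(is(genome, "GenomeSeq"), is(scoring, "ScoringScheme"))
  if (isCircularGenome(genome)) .selfCompareCircular(genome, scoring)
  else .selfCompareLinear(genome, scoring)
}
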