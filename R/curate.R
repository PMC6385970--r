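#' @include engine.R
NULL

#' Remove duplicate and reciprocal alignment listings
#'
#' A both-strand self-comparison (or an imported BLAST table) lists the
#' same repeat twice, once as (A, B) and once as (B, A).  Alignments are
#' sorted by size and, within each size class, query coordinates are
#' compared against subject coordinates of the other listings; the
#' canonical listing (query interval not after the subject interval) is
#' kept once.  Distinct interval pairs among three or more copies of one
#' repeat are all retained; resolving them into a single family is the
#' job of [buildFamilies()].
#'
#' @param hsps HSP `data.frame` as returned by [selfCompare()] or
#'   [readBlastTable()].
#' @return deduplicated HSP `data.frame`, sorted by descending length.
#' @export
deduplicateHsps <- function(hsps) {
  if (!nrow(hsps)) return(.emptyHsp())
  h <- hsps
  swap <- h$qStart > h$sStart | (h$qStart == h$sStart & h$qEnd > h$sEnd)
  if (any(swap)) {
    tmp <- h[swap, c("qStart", "qEnd")]
    h[swap, c("qStart", "qEnd")] <- h[swap, c("sStart", "sEnd")]
    h[swap, c("sStart", "sEnd")] <- tmp
  }
  h <- .dedupHspRows(h)
  h <- h[order(-h$length, h$qStart, h$sStart, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Extract one representative sequence per distinct repeat
#'
#' For each deduplicated alignment the query-interval subsequence is
#' taken; sequences identical in content, or identical to the reverse
#' complement of another, collapse to one.
#'
#' @param hsps deduplicated HSP `data.frame`.
#' @param genome the [GenomeSeq-class] the alignments refer to.
#' @return a [Biostrings::DNAStringSet] of representatives, named by
#'   their source interval, ordered by descending length then position.
#' @export
selectRepresentatives <- function(hsps, genome) {
  if (!nrow(hsps)) return(DNAStringSet())
  h <- hsps[order(-hsps$length, hsps$qStart), , drop = FALSE]
  s <- genomeString(genome)
  seqs <- substring(s, h$qStart, h$qEnd)
  key <- vapply(seqs, function(x) min(x, .revcompStr(x)), character(1L),
                USE.NAMES = FALSE)
  keep <- !duplicated(key)
  out <- DNAStringSet(seqs[keep])
  names(out) <- sprintf("%s:%d-%d", genomeId(genome),
                        h$qStart[keep], h$qEnd[keep])
  out
}

## all full-length placements of query (code vector) in subject (code
## vector), allowing at most maxMM mismatching columns; seeds shared
## words between query and subject.  Returns data.frame(start, end,
## strand, mismatches) in subject coordinates.
.fullLengthPlacements <- function(qStr, qCode, sStr, sCode, k, maxMM) {
  n <- length(qCode)
  Ls <- length(sCode)
  qt <- .kmerTable(qStr, qCode, k)
  st <- .kmerTable(sStr, sCode, k)
  hits <- merge(qt, st, by = "w", allow.cartesian = TRUE,
                suffixes = c(".q", ".s"))
  res <- list()
  if (nrow(hits)) {
    for (d in unique(hits$pos.s - hits$pos.q)) {
      a <- d + 1L  # subject start of a full-length placement
      if (a < 1L || a + n - 1L > Ls) next
      sc <- sCode[seq.int(a, a + n - 1L)]
      if (any(sc == 9L) || any(qCode == 9L)) next
      mm <- sum(sc != qCode)
      if (mm <= maxMM)
        res[[length(res) + 1L]] <- data.frame(
          start = a, end = a + n - 1L, strand = "+",
          mismatches = as.integer(mm), stringsAsFactors = FALSE)
    }
  }
  rcS <- .revcompStr(sStr)
  rt <- .kmerTable(rcS, .encodeSeq(rcS), k)
  hitsM <- merge(qt, rt, by = "w", allow.cartesian = TRUE,
                 suffixes = c(".q", ".r"))
  if (nrow(hitsM)) {
    ## query position i pairs with subject position cc - i
    ccAll <- hitsM$pos.q + Ls - hitsM$pos.r + 1L
    for (cc in unique(ccAll)) {
      a <- cc - n  # subject start; query t pairs subject cc - t
      if (a < 1L || cc - 1L > Ls) next
      sc <- sCode[seq.int(cc - 1L, by = -1L, length.out = n)]
      if (any(sc == 9L) || any(qCode == 9L)) next
      mm <- sum((sc + qCode) != 5L)
      if (mm <= maxMM)
        res[[length(res) + 1L]] <- data.frame(
          start = a, end = cc - 1L, strand = "-",
          mismatches = as.integer(mm), stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[!duplicated(paste(out$start, out$end, out$strand)), ,
             drop = FALSE]
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate every genomic copy of a repeat
#'
#' The second pass of the curation: a self-comparison does not enumerate
#' every copy of a repeat with more than two copies, so each
#' representative is re-queried against the entire genome on both
#' strands.  A location counts as a copy when the alignment covers the
#' representative full-length with at most `tolerancePer100` mismatches
#' per 100 bp (the scoring's break-even: one mismatch costs as much as
#' `abs(mismatchPenalty)` matches), which preserves the equal-copy-length
#' premise of the curation.
#'
#' @param representative character string or `DNAString`, length at
#'   least `wordSize`.
#' @param genome the [GenomeSeq-class] to search.
#' @param scoring a [ScoringScheme-class].
#' @param tolerancePer100 allowed mismatches per 100 bp of
#'   representative length (default 1; the copy threshold is
#'   `floor(length * tolerancePer100 / 100)`).
#' @return a [RepeatFamily-class] with all copies sorted by start.  A
#'   family with fewer than two copies is returned with a warning (it is
#'   excluded from [buildFamilies()] output).
#' @export
locateAllCopies <- function(representative, genome,
                            scoring = scoringScheme(),
                            tolerancePer100 = 1) {
  qStr <- toupper(as.character(representative))
  n <- nchar(qStr)
  if (n < scoring@wordSize)
    stop("representative (", n, " bp) is shorter than the word size (",
         scoring@wordSize, ")")
  sStr <- genomeString(genome)
  if (isCircularGenome(genome)) {
    L <- genomeLength(genome)
    pl <- .fullLengthPlacements(qStr, .encodeSeq(qStr),
                                paste0(sStr, sStr),
                                .encodeSeq(paste0(sStr, sStr)),
                                scoring@wordSize,
                                floor(n * tolerancePer100 / 100))
    pl <- pl[pl$start <= L, , drop = FALSE]
  } else {
    pl <- .fullLengthPlacements(qStr, .encodeSeq(qStr), sStr,
                                .encodeSeq(sStr), scoring@wordSize,
                                floor(n * tolerancePer100 / 100))
  }
  .familyFromPlacements(qStr, pl, genome)
}

## assemble a RepeatFamily from placements, re-anchoring the
## representative on the first plus-strand copy
.familyFromPlacements <- function(qStr, pl, genome, familyId = "R?") {
  s <- genomeString(genome)
  n <- nchar(qStr)
  if (!nrow(pl))
    stop("representative has no full-length copy in ", genomeId(genome))
  if (nrow(pl)) {
    plus <- which(pl$strand == "+")
    rep <- if (length(plus))
      substring(s, pl$start[plus[1L]], pl$end[plus[1L]])
    else
      .revcompStr(substring(s, pl$start[1L], pl$end[1L]))
    repCode <- .encodeSeq(rep)
    mm <- vapply(seq_len(nrow(pl)), function(i) {
      cs <- substring(s, pl$start[i], pl$end[i])
      if (pl$strand[i] == "-") cs <- .revcompStr(cs)
      sum(.encodeSeq(cs) != repCode)
    }, integer(1L))
    pl$mismatches <- mm
  } else rep <- qStr
  gr <- GRanges(seqnames = genomeId(genome),
                ranges = IRanges(start = pl$start, end = pl$end),
                strand = pl$strand)
  mcols(gr)$mismatches <- pl$mismatches
  tandem <- FALSE
  if (length(gr) > 1L) {
    o <- order(pl$start, pl$end)
    tandem <- any(pl$start[o][-1L] <= pl$end[o][-nrow(pl)] + 1L)
  }
  if (length(gr) < 2L)
    warning("representative has fewer than two genomic copies; ",
            "a repeat needs at least two")
  new("RepeatFamily", familyId = familyId, representative = DNAString(rep),
      copies = gr, tandem = tandem)
}

## copy identity for curation merging is the genomic interval; the
## strand is relative to the representative's orientation and two
## representatives of one family may be reverse complements of each
## other, so it must not enter the key
.copyKeys <- function(fam) {
  gr <- repeatCopies(fam)
  paste(GenomicRanges::start(gr), GenomicRanges::end(gr))
}

## set each placement's strand (and mismatch count) relative to a given
## representative: the orientation with fewer substitutions wins
.orientPlacements <- function(pl, repStr, genome) {
  s <- genomeString(genome)
  repCode <- .encodeSeq(repStr)
  for (i in seq_len(nrow(pl))) {
    cs <- .encodeSeq(substring(s, pl$start[i], pl$end[i]))
    mmF <- sum(cs != repCode)
    mmR <- sum(.revcompCodes(cs) != repCode)
    pl$strand[i] <- if (mmF <= mmR) "+" else "-"
    pl$mismatches[i] <- min(mmF, mmR)
  }
  pl
}

#' Assemble distinct repeat families from raw self-alignments
#'
#' The full curation pipeline: duplicate listings are removed
#' ([deduplicateHsps()]), one representative is extracted per distinct
#' repeat ([selectRepresentatives()]), every genomic copy of each
#' representative is located ([locateAllCopies()]), families with
#' identical copy sets are merged, families of the same length sharing a
#' copy are merged, and family ids `R1, R2, ...` are assigned by
#' descending length.  Representatives with fewer than two located
#' copies are dropped with a warning.  The tandem flag marks families in
#' which any two copies overlap or abut; tandem arrays are detected and
#' flagged, not removed.
#'
#' @param hsps raw HSP `data.frame` from [selfCompare()].
#' @param genome the [GenomeSeq-class] searched.
#' @param scoring a [ScoringScheme-class].
#' @param tolerancePer100 see [locateAllCopies()].
#' @return list of [RepeatFamily-class] objects in output order
#'   (descending length, then first-copy start, then sequence).
#' @examples
#' pf <- plantFamily(generateBackground(5000, seed = 2),
#'                   plantSpec(length = 300, nCopies = 2), seed = 3)
#' fams <- buildFamilies(selfCompare(pf$genome), pf$genome)
#' vapply(fams, copyCount, integer(1))
#' @export
buildFamilies <- function(hsps, genome, scoring = scoringScheme(),
                          tolerancePer100 = 1) {
  hsps <- deduplicateHsps(hsps)
  reps <- selectRepresentatives(hsps, genome)
  fams <- list()
  for (i in seq_along(reps)) {
    fam <- withCallingHandlers(
      locateAllCopies(reps[[i]], genome, scoring, tolerancePer100),
      warning = function(w) invokeRestart("muffleWarning"))
    if (copyCount(fam) >= 2L) fams[[length(fams) + 1L]] <- fam
    else warning("dropping single-copy representative ", names(reps)[i])
  }
  if (!length(fams)) return(list())

  ## merge families with identical copy sets
  sig <- vapply(fams, function(f) paste(sort(.copyKeys(f)), collapse = ";"),
                character(1L))
  fams <- fams[!duplicated(sig)]

  ## merge same-length families sharing at least one copy (union of
  ## copy sets, connected components within each length class)
  len <- vapply(fams, familyLength, integer(1L))
  merged <- list()
  for (l in unique(len)) {
    grp <- fams[len == l]
    keys <- lapply(grp, .copyKeys)
    comp <- seq_along(grp)
    repeat {
      changed <- FALSE
      for (i in seq_along(grp)) for (j in seq_along(grp)) {
        if (comp[i] != comp[j] && length(intersect(keys[[i]], keys[[j]]))) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cid in unique(comp)) {
      members <- grp[comp == cid]
      if (length(members) == 1L) {
        merged[[length(merged) + 1L]] <- members[[1L]]
      } else {
        pl <- do.call(rbind, lapply(members, function(f) {
          gr <- repeatCopies(f)
          data.frame(start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     mismatches = 0L, stringsAsFactors = FALSE)
        }))
        pl <- pl[!duplicated(paste(pl$start, pl$end)), , drop = FALSE]
        pl <- pl[order(pl$start, pl$end, pl$strand), , drop = FALSE]
        pl <- .orientPlacements(
          pl, as.character(representative(members[[1L]])), genome)
        merged[[length(merged) + 1L]] <- .familyFromPlacements(
          as.character(representative(members[[1L]])), pl, genome)
      }
    }
  }

  merged <- .orderFamilies(merged)
  for (i in seq_along(merged)) merged[[i]]@familyId <- paste0("R", i)
  merged
}
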