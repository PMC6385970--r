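#' @include summarize.R
NULL

#' Generate a random background genome
#'
#' I.i.d. nucleotide sequence with the requested GC content,
#' deterministic given the seed.  This realizes the null model against
#' which detected repeats are judged: at the default 50-bp word a chance
#' repeat in random sequence is effectively impossible (collision
#' probability about 1e-20 at 100 kb), and the generator additionally
#' verifies that no word of `wordSize` occurs twice (nor matches a
#' reverse complement elsewhere), regenerating in the astronomically
#' unlikely event one does, so planted truth sets are exact.
#'
#' @param length genome length in bp (>= 1).
#' @param gc GC fraction in (0, 1); default 0.45, typical of plant
#'   mitochondrial DNA.
#' @param seed integer seed; the caller's RNG state is untouched.
#' @param wordSize word length used for the self-repeat guard.
#' @param id identifier of the returned genome.
#' @return a [GenomeSeq-class].
#' @examples
#' g <- generateBackground(10000, gc = 0.45, seed = 7)
#' @export
generateBackground <- function(length, gc = 0.45, seed,
                               wordSize = 50L, id = "synthetic") {
  if (!(gc > 0 && gc < 1)) stop("gc must be strictly between 0 and 1")
  if (length < 1L) stop("length must be >= 1")
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  .withSeed(seed, {
    for (attempt in 1:20) {
      s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                        prob = prob), collapse = "")
      if (length < wordSize) break
      w <- substring(s, seq_len(length - wordSize + 1L),
                     seq.int(wordSize, length))
      rc <- .revcompStr(s)
      wr <- substring(rc, seq_len(length - wordSize + 1L),
                      seq.int(wordSize, length))
      if (!anyDuplicated(w) && !any(w %chin% wr)) break
    }
    GenomeSeq(id, s)
  })
}

#' Specify a repeat family to plant
#'
#' @param length copy length in bp.
#' @param nCopies number of copies (>= 2).
#' @param strands orientation per copy (`"+"`/`"-"`), recycled; default
#'   all plus.
#' @param mismatches per-copy substitutions relative to the family unit:
#'   either an integer vector of counts (positions drawn at plant time,
#'   uniformly over the copy interior, at least 25 bp from either end so
#'   alignment boundaries stay sharp) or a list of explicit 1-based
#'   position vectors.  Default: no mismatches.
#' @param starts explicit 1-based copy start positions, or `NULL` for
#'   random non-overlapping placement.
#' @return a `PlantSpec` (plain list with class attribute).
#' @examples
#' plantSpec(600, nCopies = 3, strands = c("+", "+", "-"))
#' @export
plantSpec <- function(length, nCopies = 2L, strands = "+",
                      mismatches = NULL, starts = NULL) {
  nCopies <- as.integer(nCopies)
  if (nCopies < 2L) stop("a repeat family needs at least 2 copies")
  strands <- rep_len(strands, nCopies)
  if (!all(strands %in% c("+", "-"))) stop("strands must be '+' or '-'")
  if (is.null(mismatches)) {
    mismatches <- rep_len(list(integer(0L)), nCopies)
  } else if (is.numeric(mismatches) && !is.list(mismatches)) {
    ## counts: positions drawn at plant time
    mismatches <- lapply(rep_len(as.integer(mismatches), nCopies),
                         function(x) structure(x, mmcount = TRUE))
  } else if (is.list(mismatches)) {
    mismatches <- rep_len(lapply(mismatches, as.integer), nCopies)
    for (m in mismatches)
      if (length(m) && any(m < 1L | m > length))
        stop("mismatch positions must lie within the copy")
  } else stop("mismatches must be counts or a list of positions")
  if (length(mismatches) != nCopies)
    stop("mismatches must have one entry per copy")
  if (!is.null(starts) && length(starts) != nCopies)
    stop("starts must have one entry per copy")
  structure(list(length = as.integer(length), nCopies = nCopies,
                 strands = strands, mismatches = mismatches,
                 starts = if (!is.null(starts)) as.integer(starts)),
            class = "PlantSpec")
}

## mismatch spec entry -> explicit positions (scalar count => random
## interior positions, margin 25 bp from each end)
.mmPositions <- function(entry, len) {
  if (is.list(entry)) entry <- entry[[1L]]
  if (!is.null(attr(entry, "mmcount"))) {
    cnt <- as.integer(entry)
    if (cnt == 0L) return(integer(0L))
    lo <- min(25L, max(1L, len %/% 4L))
    sort(sample(seq.int(lo + 1L, len - lo), cnt))
  } else sort(as.integer(entry))
}

#' Plant repeat families into a background genome
#'
#' Writes each family's copies into the background (reverse complement
#' for minus-strand copies), introduces the specified substitutions, and
#' records exact coordinates in a truth table.  Copies are placed
#' non-overlapping (margin 30 bp) unless explicit starts are given.  The
#' bases immediately flanking the planted copies are resampled so that
#' every pairwise copy alignment terminates exactly at the copy
#' boundaries, making the planted lengths sharp ground truth for any
#' local aligner.
#'
#' @param genome background [GenomeSeq-class] (see
#'   [generateBackground()]).
#' @param specs list of [plantSpec()] objects (or a single one).
#' @param seed integer seed controlling unit sequences, placement and
#'   mismatch draws.
#' @param margin minimum background gap around randomly placed copies.
#' @return list with `genome` (the planted [GenomeSeq-class]) and
#'   `truth` (`data.frame`: `family`, `copy`, `start`, `end`, `strand`,
#'   `mismatches`, `length`).
#' @export
plantFamilies <- function(genome, specs, seed, margin = 30L) {
  if (inherits(specs, "PlantSpec")) specs <- list(specs)
  L <- genomeLength(genome)
  chars <- strsplit(genomeString(genome), "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  .withSeed(seed, {
    occupied <- matrix(numeric(0L), ncol = 2L)
    truth <- list()
    placements <- list()
    for (fi in seq_along(specs)) {
      sp <- specs[[fi]]
      len <- sp$length
      unit <- paste(sample(bases, len, TRUE), collapse = "")
      starts <- sp$starts
      if (is.null(starts)) {
        starts <- integer(sp$nCopies)
        for (ci in seq_len(sp$nCopies)) {
          for (try in 1:1000) {
            st <- sample.int(L - len - 2L * margin, 1L) + margin
            if (!nrow(occupied) ||
                all(st > occupied[, 2L] + margin |
                    st + len - 1L < occupied[, 1L] - margin)) break
            if (try == 1000L) stop("could not place copy; genome too full")
          }
          starts[ci] <- st
          occupied <- rbind(occupied, c(st, st + len - 1L))
        }
      } else {
        for (ci in seq_len(sp$nCopies)) {
          st <- starts[ci]
          if (st < 1L || st + len - 1L > L)
            stop("explicit start out of range: ", st)
          if (nrow(occupied) &&
              any(st <= occupied[, 2L] & st + len - 1L >= occupied[, 1L]))
            stop("explicit placement overlaps an earlier copy")
          occupied <- rbind(occupied, c(st, st + len - 1L))
        }
      }
      for (ci in seq_len(sp$nCopies)) {
        pos <- .mmPositions(sp$mismatches[ci], len)
        copySeq <- strsplit(unit, "", fixed = TRUE)[[1L]]
        for (p in pos)
          copySeq[p] <- sample(setdiff(bases, copySeq[p]), 1L)
        if (sp$strands[ci] == "-")
          copySeq <- rev(chartr("ACGT", "TGCA", copySeq))
        st <- starts[ci]
        chars[seq.int(st, st + len - 1L)] <- copySeq
        truth[[length(truth) + 1L]] <- data.frame(
          family = paste0("F", fi), copy = ci, start = st,
          end = st + len - 1L, strand = sp$strands[ci],
          mismatches = length(pos), length = len,
          stringsAsFactors = FALSE)
        placements[[length(placements) + 1L]] <- list(
          family = fi, start = st, end = st + len - 1L,
          strand = sp$strands[ci])
      }
    }

    ## sharpen boundaries: for every same-family copy pair, the aligned
    ## flanking columns must mismatch so extension stops at the copy ends
    inCopy <- logical(L)
    for (p in placements) inCopy[seq.int(p$start, p$end)] <- TRUE
    comp <- function(x) chartr("ACGT", "TGCA", x)
    for (it in 1:200) {
      fixed <- TRUE
      for (ai in seq_along(placements)) for (bi in seq_along(placements)) {
        if (bi <= ai) next
        a <- placements[[ai]]; b <- placements[[bi]]
        if (a$family != b$family) next
        if (a$strand == b$strand) {
          prs <- list(c(a$start - 1L, b$start - 1L, FALSE),
                      c(a$end + 1L, b$end + 1L, FALSE))
        } else {
          prs <- list(c(a$start - 1L, b$end + 1L, TRUE),
                      c(a$end + 1L, b$start - 1L, TRUE))
        }
        for (pr in prs) {
          p1 <- pr[1L]; p2 <- pr[2L]
          if (p1 < 1L || p1 > L || p2 < 1L || p2 > L) next
          c2 <- if (pr[3L]) comp(chars[p2]) else chars[p2]
          if (chars[p1] == c2) {
            tgt <- if (!inCopy[p1]) p1 else if (!inCopy[p2]) p2 else NA
            if (is.na(tgt)) next
            chars[tgt] <- sample(setdiff(bases, chars[tgt]), 1L)
            fixed <- FALSE
          }
        }
      }
      if (fixed) break
    }
    list(genome = GenomeSeq(genomeId(genome), paste(chars, collapse = ""),
                            circular = isCircularGenome(genome)),
         truth = do.call(rbind, truth))
  })
}

#' @rdname plantFamilies
#' @param spec a single [plantSpec()].
#' @export
plantFamily <- function(genome, spec, seed, margin = 30L)
  plantFamilies(genome, list(spec), seed, margin)

#' Write a truth table as TSV
#'
#' @param truth truth `data.frame` from [plantFamilies()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTruthSet <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a genome as a single-record FASTA file
#'
#' @param genome a [GenomeSeq-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  set <- DNAStringSet(genomeString(genome))
  names(set) <- genomeId(genome)
  writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

## ---- brute-force oracle -------------------------------------------------

## scalar-walk segment finder used only by the oracle: every maximal
## exact run >= k on the match vector, extended by explicit stepping
## with the same published semantics as the engine (stop at NA/end or
## when the running score falls more than X below the best; end at the
## farthest position attaining the best)
.oraSegments <- function(m, k, reward, penalty, X) {
  isT <- !is.na(m) & m
  rl <- rle(isT)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  idx <- which(rl$values & rl$lengths >= k)
  segs <- vector("list", length(idx))
  n <- length(m)
  for (si in seq_along(idx)) {
    a <- starts[idx[si]]; b <- ends[idx[si]]
    cur <- 0; best <- 0; hi <- b
    jj <- b + 1L
    while (jj <= n && !is.na(m[jj])) {
      cur <- cur + if (m[jj]) reward else penalty
      if (cur >= best) { best <- cur; hi <- jj }
      if (cur < best - X) break
      jj <- jj + 1L
    }
    cur <- 0; best <- 0; lo <- a
    jj <- a - 1L
    while (jj >= 1L && !is.na(m[jj])) {
      cur <- cur + if (m[jj]) reward else penalty
      if (cur >= best) { best <- cur; lo <- jj }
      if (cur < best - X) break
      jj <- jj - 1L
    }
    segs[[si]] <- c(lo, hi)
  }
  segs
}

#' Brute-force self-comparison oracle
#'
#' Reference implementation for validating [selfCompare()]: scans every
#' diagonal of the genome against itself and every antidiagonal against
#' its reverse complement, finds all maximal exact runs of at least the
#' word size, extends each by explicit scalar stepping, and
#' canonicalizes identically to the engine.  Quadratic in genome length
#' and guarded to 20 kb.
#'
#' @inheritParams selfCompare
#' @return HSP `data.frame`, same contract as [selfCompare()].
#' @export
oracleSelfCompare <- function(genome, scoring = scoringScheme()) {
  L <- genomeLength(genome)
  if (L > 20000L)
    stop("oracle is quadratic; refusing genomes longer than 20 kb")
  code <- .encodeSeq(genomeString(genome))
  k <- scoring@wordSize
  r <- scoring@matchReward; p <- scoring@mismatchPenalty
  X <- scoring@xDrop
  rows <- list()
  addRow <- function(q1, q2, s1, s2, strand, mm) {
    len <- q2 - q1 + 1L
    sc <- r * (len - mm) + p * mm
    if (sc < scoring@minScore) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      qStart = q1, qEnd = q2, sStart = s1, sEnd = s2, strand = strand,
      length = len, score = sc, mismatches = as.integer(mm),
      stringsAsFactors = FALSE)
  }
  if (L > k) for (d in seq_len(L - k)) {
    n <- L - d
    a <- code[seq_len(n)]; b <- code[seq.int(d + 1L, L)]
    m <- a == b
    m[a == 9L | b == 9L] <- NA
    for (seg in .oraSegments(m, k, r, p, X))
      addRow(seg[1L], seg[2L], seg[1L] + d, seg[2L] + d, "+",
             sum(!m[seq.int(seg[1L], seg[2L])]))
  }
  for (cc in seq.int(2L, 2L * L)) {
    tlo <- max(1L, cc - L); thi <- min(L, cc - 1L)
    if (thi - tlo + 1L < k) next
    a <- code[seq.int(tlo, thi)]
    b <- code[seq.int(cc - tlo, by = -1L, length.out = thi - tlo + 1L)]
    m <- (a + b) == 5L
    m[a == 9L | b == 9L] <- NA
    for (seg in .oraSegments(m, k, r, p, X)) {
      t1 <- tlo + seg[1L] - 1L; t2 <- tlo + seg[2L] - 1L
      q1 <- t1; q2 <- t2; s1 <- cc - t2; s2 <- cc - t1
      if (q1 > s1) { tmp1 <- q1; tmp2 <- q2; q1 <- s1; q2 <- s2
                     s1 <- tmp1; s2 <- tmp2 }
      addRow(q1, q2, s1, s2, "-", sum(!m[seq.int(seg[1L], seg[2L])]))
    }
  }
  h <- do.call(rbind, c(list(.emptyHsp()), rows))
  .sortHsp(.dedupHspRows(h))
}
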