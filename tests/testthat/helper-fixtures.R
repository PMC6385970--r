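## Fixture builders shared across test files.  Everything is generated
## in code under fixed seeds; nothing is read from disk.

## background + planted families in one call
plantedGenome <- function(specs, seed, L = 8000L, gc = 0.45) {
  bg <- generateBackground(L, gc = gc, seed = seed)
  plantFamilies(bg, specs, seed = seed + 1000L)
}

## comparable canonical form of an HSP table
hspCanon <- function(h) {
  h <- h[order(h$qStart, h$qEnd, h$sStart, h$sEnd, h$strand),
         c("qStart", "qEnd", "sStart", "sEnd", "strand", "length",
           "score", "mismatches")]
  rownames(h) <- NULL
  h
}

## draw a random plant specification for property-style tests
randomPlantSpec <- function(maxLen = 400L) {
  len <- sample(60:maxLen, 1L)
  n <- sample(2:3, 1L)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  mm <- sample(0:2, n, replace = TRUE)
  mm[1L] <- 0L  # keep the first copy exact so truth lengths are sharp
  plantSpec(len, n, strands, mismatches = mm)
}

## summary of a family list comparable against a truth table
familySummary <- function(fams) {
  do.call(rbind, lapply(fams, function(f) {
    data.frame(length = familyLength(f), copies = copyCount(f),
               strands = paste(sort(as.character(
                 GenomicRanges::strand(repeatCopies(f)))), collapse = ""),
               stringsAsFactors = FALSE)
  }))
}

truthSummary <- function(truth) {
  sp <- split(truth, truth$family)
  out <- do.call(rbind, lapply(sp, function(t)
    data.frame(length = t$length[1L], copies = nrow(t),
               strands = paste(sort(t$strand), collapse = ""),
               stringsAsFactors = FALSE)))
  out <- out[order(-out$length, out$strands), , drop = FALSE]
  rownames(out) <- NULL
  out
}

sortedFamilySummary <- function(fams) {
  out <- familySummary(fams)
  if (is.null(out)) return(out)
  out <- out[order(-out$length, out$strands), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## write a GenomeSeq to a temp FASTA, return the path
tmpFasta <- function(genome, dir = tempdir()) {
  p <- tempfile(tmpdir = dir, fileext = ".fasta")
  writeGenomeFasta(genome, p)
  p
}
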