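## Internal low-level helpers shared across modules.
## Sequences are handled as integer code vectors for speed:
## A=1, C=2, G=3, T=4, masked/other=9.  A base and its complement sum to 5;
## the masked code can never take part in a match, including with itself.

.CODE_MAP <- local({
  m <- integer(128L)
  m[utf8ToInt("A")] <- 1L
  m[utf8ToInt("C")] <- 2L
  m[utf8ToInt("G")] <- 3L
  m[utf8ToInt("T")] <- 4L
  m
})

.encodeSeq <- function(s) {
  v <- .CODE_MAP[utf8ToInt(s)]
  v[v == 0L] <- 9L
  v
}

.decodeSeq <- function(code) {
  chars <- c("A", "C", "G", "T", rep("N", 5L))
  paste(chars[code], collapse = "")
}

.complementCodes <- function(code) {
  out <- 5L - code
  out[code == 9L] <- 9L
  out
}

.revcompCodes <- function(code) rev(.complementCodes(code))

## reverse complement of a plain character string (ACGTN only)
.revcompStr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

## all words of length k starting at 1..L-k+1; validity excludes words
## touching a masked residue
.kmerTable <- function(s, code, k) {
  L <- length(code)
  if (k > L) stop("word size (", k, ") exceeds sequence length (", L, ")")
  starts <- seq_len(L - k + 1L)
  w <- substring(s, starts, starts + k - 1L)
  maskcum <- cumsum(code == 9L)
  bad <- (maskcum[starts + k - 1L] - c(0L, maskcum)[starts]) > 0L
  data.table::data.table(w = w[!bad], pos = starts[!bad], key = "w")
}

## run a block of code under a fixed RNG seed, restoring the caller's
## RNG state afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## empty HSP table with canonical column set
.emptyHsp <- function() {
  data.frame(qStart = integer(), qEnd = integer(),
             sStart = integer(), sEnd = integer(),
             strand = character(), length = integer(),
             score = numeric(), mismatches = integer(),
             stringsAsFactors = FALSE)
}

.sortHsp <- function(h) {
  if (!nrow(h)) return(h)
  h <- h[order(-h$score, h$qStart, h$qEnd, h$sStart, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  h
}

.dedupHspRows <- function(h) {
  if (!nrow(h)) return(h)
  key <- paste(h$qStart, h$qEnd, h$sStart, h$sEnd, h$strand)
  h <- h[!duplicated(key), , drop = FALSE]
  rownames(h) <- NULL
  h
}
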