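#' @include AllGenerics.R
NULL

#' Read and validate a single-genome FASTA file
#'
#' Reads exactly one FASTA record and validates its alphabet.  Organelle
#' assemblies sometimes carry IUPAC ambiguity codes or gap characters;
#' ungapped exact-seed alignment is undefined on them, so the default
#' policy rejects such sequences outright (naming the first offending
#' position), while `ambiguity = "mask"` replaces every non-ACGT residue
#' with a masked sentinel that can never seed or extend an alignment.
#'
#' @param path path to a FASTA file containing exactly one record.
#' @param ambiguity `"reject"` (default) to error on any non-ACGT
#'   residue, or `"mask"` to replace them.
#' @param circular logical; mark the molecule as circular.
#' @return a validated [GenomeSeq-class] (sequence uppercased).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">toy", "acgtACGT"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path, ambiguity = c("reject", "mask"),
                       circular = FALSE) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  if (length(set) > 1L)
    stop("expected exactly one FASTA record in ", path, ", found ",
         length(set), " (multi-sequence assemblies are not supported)")
  s <- toupper(as.character(set[[1L]]))
  if (!nzchar(s)) stop("zero-length sequence in ", path)
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0L) {
    if (ambiguity == "reject")
      stop(sprintf(
        "non-ACGT residue '%s' at position %d in %s; use ambiguity = \"mask\" to mask such residues",
        substr(s, bad, bad), bad, path))
    s <- gsub("[^ACGT]", "N", s)
  }
  id <- strsplit(names(set)[1L], "[ \t]")[[1L]][1L]
  GenomeSeq(id, s, circular = circular)
}

## deterministic family order used by every writer:
## descending length, then first-copy start, then representative sequence
.orderFamilies <- function(families) {
  if (!length(families)) return(families)
  len <- vapply(families, familyLength, integer(1L))
  fst <- vapply(families, function(f)
    min(GenomicRanges::start(repeatCopies(f))), integer(1L))
  rep <- vapply(families, function(f)
    as.character(representative(f)), character(1L))
  families[order(-len, fst, rep)]
}

#' Write repeat families as FASTA
#'
#' One record per family; the header carries the family id, length and
#' copy number (`"R1 len=600 copies=2"`) and the sequence is the
#' representative copy.  Families are written in descending length
#' order, ties broken by first-copy start then by sequence, so output is
#' byte-stable.
#'
#' @param families list of [RepeatFamily-class] objects (may be empty).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRepeatFasta <- function(families, path) {
  families <- .orderFamilies(families)
  seqs <- DNAStringSet(vapply(families, function(f)
    as.character(representative(f)), character(1L)))
  names(seqs) <- vapply(families, function(f)
    sprintf("%s len=%d copies=%d", familyId(f), familyLength(f),
            copyCount(f)), character(1L))
  writeXStringSet(seqs, filepath = path, width = 70L)
  invisible(path)
}

#' @importFrom Biostrings DNAStringSet
NULL

## internal: feature-table lines from a copy table
## (data.frame with family_id, start, end, strand)
.featureLines <- function(copies, genomeId, genomeLength = NA) {
  header <- paste0(">Feature ", genomeId)
  if (!nrow(copies)) return(header)
  if (!is.na(genomeLength)) {
    bad <- copies$start < 1L | copies$end > genomeLength
    if (any(bad))
      stop("copy coordinates outside [1, ", genomeLength, "]: ",
           paste(sprintf("%d-%d", copies$start[bad], copies$end[bad]),
                 collapse = ", "))
  }
  lines <- character(0L)
  for (i in seq_len(nrow(copies))) {
    a <- copies$start[i]; b <- copies$end[i]
    if (identical(copies$strand[i], "-")) { tmp <- a; a <- b; b <- tmp }
    lines <- c(lines,
               sprintf("%d\t%d\trepeat_region", a, b),
               "\t\t\trpt_type\tdispersed",
               paste0("\t\t\tnote\t", copies$family_id[i]))
  }
  c(header, lines)
}

#' Write an NCBI 5-column feature table of repeat annotations
#'
#' Emits the tab-delimited feature-table (.tbl) format used for GenBank
#' submissions: a `">Feature <id>"` header, then per repeat copy one
#' `start<TAB>end<TAB>repeat_region` line with qualifiers
#' `rpt_type dispersed` and `note <family_id>`.  Minus-strand copies are
#' encoded by start > end, as the format prescribes.
#'
#' @param families list of [RepeatFamily-class] objects.
#' @param genomeId identifier written in the header line.
#' @param path output file path.
#' @param genomeLength optional; when given, coordinates outside
#'   `[1, genomeLength]` are an error.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(families, genomeId, path, genomeLength = NA) {
  families <- .orderFamilies(families)
  copies <- do.call(rbind, c(list(
    data.frame(family_id = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)),
    lapply(families, function(f) {
      gr <- repeatCopies(f)
      data.frame(family_id = familyId(f),
                 start = GenomicRanges::start(gr),
                 end = GenomicRanges::end(gr),
                 strand = as.character(GenomicRanges::strand(gr)),
                 stringsAsFactors = FALSE)
    })))
  writeLines(.featureLines(copies, genomeId, genomeLength), path)
  invisible(path)
}

#' Parse a 5-column feature table of repeat_region features
#'
#' Inverse of [writeFeatureTable()]: returns the copy intervals and
#' strands (start > end on the feature line encodes the minus strand).
#'
#' @param path path to a .tbl file.
#' @return `data.frame` with columns `family_id`, `start`, `end`,
#'   `strand`, plus the genome id as attribute `"genomeId"`.
#' @export
readFeatureTable <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], ">Feature "))
    stop("not a feature table: ", path)
  gid <- sub("^>Feature ", "", lines[1L])
  out <- data.frame(family_id = character(), start = integer(),
                    end = integer(), strand = character(),
                    stringsAsFactors = FALSE)
  i <- 2L
  while (i <= length(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) >= 3L && f[3L] == "repeat_region") {
      a <- as.integer(f[1L]); b <- as.integer(f[2L])
      fam <- NA_character_
      j <- i + 1L
      while (j <= length(lines) &&
             startsWith(lines[j], "\t\t\t")) {
        q <- strsplit(lines[j], "\t", fixed = TRUE)[[1L]]
        if (length(q) >= 5L && q[4L] == "note") fam <- q[5L]
        j <- j + 1L
      }
      out <- rbind(out, data.frame(
        family_id = fam,
        start = min(a, b), end = max(a, b),
        strand = if (a > b) "-" else "+",
        stringsAsFactors = FALSE))
      i <- j
    } else i <- i + 1L
  }
  attr(out, "genomeId") <- gid
  out
}

#' Read a species-to-group mapping table
#'
#' Two-column tab-separated file with a header row: genome id (or input
#' file stem) and taxonomic group label.
#'
#' @param path path to the TSV file.
#' @return `data.frame` with columns `id` and `group`.
#' @export
readGroupMap <- function(path) {
  m <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(m) < 2L) stop("group map needs two columns (id, group): ", path)
  data.frame(id = as.character(m[[1L]]), group = as.character(m[[2L]]),
             stringsAsFactors = FALSE)
}
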