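#' @include curate.R
NULL

#' Default repeat-size bin edges
#'
#' 50, 100, 200, ..., 900, 1000, 2000, ..., 9000, 10000 bp; the last bin
#' is unbounded ("10000+").  Bins are right-open, so a repeat of exactly
#' 200 bp counts in the bin starting at 200.  The range spans the repeat
#' sizes observed across green-plant mitochondrial genomes, from the
#' 50 bp detection floor to the multi-kilobase recombinogenic repeats of
#' vascular plants.
#'
#' @return increasing integer vector of bin lower edges.
#' @export
defaultBinEdges <- function() {
  as.integer(c(50, seq(100, 900, by = 100), seq(1000, 10000, by = 1000)))
}

.binLabels <- function(edges) {
  n <- length(edges)
  c(sprintf("%d-%d", edges[-n], edges[-1L] - 1L),
    sprintf("%d+", edges[n]))
}

#' Bin repeat families by size
#'
#' Counts each family once in the unique right-open bin `[a, b)`
#' containing its length (the last bin is unbounded).  Families shorter
#' than the first edge are not counted.
#'
#' @param families list of [RepeatFamily-class] objects.
#' @param binEdges strictly increasing lower bin edges; default
#'   [defaultBinEdges()].
#' @param genomeId optional label stored as attribute.
#' @return `data.frame` with columns `bin_start`, `bin_end` (`Inf` for
#'   the last), `label`, `count`.
#' @export
binRepeats <- function(families, binEdges = defaultBinEdges(),
                       genomeId = NA_character_) {
  if (is.unsorted(binEdges, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  lens <- vapply(families, familyLength, integer(1L))
  upper <- c(binEdges[-1L], Inf)
  counts <- vapply(seq_along(binEdges), function(i)
    sum(lens >= binEdges[i] & lens < upper[i]), integer(1L))
  out <- data.frame(bin_start = binEdges, bin_end = upper,
                    label = .binLabels(binEdges), count = counts,
                    stringsAsFactors = FALSE)
  attr(out, "genomeId") <- genomeId
  out
}

#' Tabulate repeat copies and per-genome summary statistics
#'
#' @param families list of [RepeatFamily-class] objects.
#' @param genome the [GenomeSeq-class] they were found in.
#' @return list with elements `copies` (one row per copy: `family_id`,
#'   `length`, `copy_count`, `copy_index` in start order, `start`,
#'   `end`, `strand`, `mismatches`, `tandem`) and `summary` (one row:
#'   `genome_id`, `genome_bp`, `n_families`, `largest_bp`,
#'   `repeated_bp` = sum over families of length times copy number, and
#'   `fraction_repeated` = `repeated_bp / genome_bp`).
#' @export
genomeRepeatTable <- function(families, genome) {
  families <- .orderFamilies(families)
  rows <- lapply(families, function(f) {
    gr <- repeatCopies(f)
    o <- order(GenomicRanges::start(gr), GenomicRanges::end(gr))
    gr <- gr[o]
    data.frame(family_id = familyId(f), length = familyLength(f),
               copy_count = length(gr), copy_index = seq_along(gr),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               mismatches = mcols(gr)$mismatches,
               tandem = isTandem(f), stringsAsFactors = FALSE)
  })
  copies <- do.call(rbind, c(list(data.frame(
    family_id = character(), length = integer(), copy_count = integer(),
    copy_index = integer(), start = integer(), end = integer(),
    strand = character(), mismatches = integer(), tandem = logical(),
    stringsAsFactors = FALSE)), rows))
  lens <- vapply(families, familyLength, integer(1L))
  ncop <- vapply(families, copyCount, integer(1L))
  summary <- data.frame(
    genome_id = genomeId(genome), genome_bp = genomeLength(genome),
    n_families = length(families),
    largest_bp = if (length(lens)) max(lens) else 0L,
    repeated_bp = sum(lens * ncop),
    fraction_repeated = sum(lens * ncop) / genomeLength(genome),
    stringsAsFactors = FALSE)
  list(copies = copies, summary = summary)
}

#' Run the full repeat-finding pipeline on one genome
#'
#' Convenience wrapper: self-comparison then family curation.
#'
#' @inheritParams selfCompare
#' @inheritParams locateAllCopies
#' @return list of [RepeatFamily-class] objects.
#' @export
findRepeats <- function(genome, scoring = scoringScheme(),
                        tolerancePer100 = 1) {
  buildFamilies(selfCompare(genome, scoring), genome, scoring,
                tolerancePer100)
}

## write the standard per-genome output files under prefix
.writeGenomeOutputs <- function(families, genome, prefix,
                                binEdges = defaultBinEdges(),
                                scoring = scoringScheme()) {
  tab <- genomeRepeatTable(families, genome)
  writeRepeatFasta(families, paste0(prefix, "_repeats.fasta"))
  utils::write.table(tab$copies, paste0(prefix, "_copies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bins <- binRepeats(families, binEdges, genomeId(genome))
  utils::write.table(bins[, c("label", "count")],
                     paste0(prefix, "_bins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeFeatureTable(families, genomeId(genome), paste0(prefix, ".tbl"),
                    genomeLength = genomeLength(genome))
  utils::write.table(tab$summary, paste0(prefix, "_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Find repeats in every genome of a directory
#'
#' Runs the full pipeline on each FASTA file (sorted filename order, for
#' reproducible output) and assembles a combined genomes-by-bins count
#' matrix.  A failure on one genome is recorded and does not abort the
#' batch.
#'
#' @param directory directory containing single-genome FASTA files
#'   (`.fa`, `.fasta`, `.fna`).
#' @param scoring a [ScoringScheme-class].
#' @param outDir optional output directory; when given, the per-genome
#'   output files and the combined matrix are written there, keyed by
#'   input file stem.
#' @param binEdges bin lower edges for the combined matrix.
#' @param ambiguity passed to [readGenome()].
#' @param tolerancePer100 passed to [buildFamilies()].
#' @return list with `families` (named list of family lists), `matrix`
#'   (`data.frame`: one row per genome, one column per size bin),
#'   `summaries` (row-bound per-genome summaries) and `failures` (named
#'   character vector of error messages).
#' @export
batchRun <- function(directory, scoring = scoringScheme(), outDir = NULL,
                     binEdges = defaultBinEdges(),
                     ambiguity = "reject", tolerancePer100 = 1) {
  if (!dir.exists(directory)) stop("not a directory: ", directory)
  files <- sort(list.files(directory, pattern = "\\.(fa|fasta|fna)$",
                           full.names = TRUE))
  if (!length(files)) stop("no FASTA files in ", directory)
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  fams <- list(); failures <- character(); summaries <- list()
  binrows <- list()
  for (f in files) {
    stem <- tools::file_path_sans_ext(basename(f))
    res <- tryCatch({
      g <- readGenome(f, ambiguity = ambiguity)
      fam <- findRepeats(g, scoring, tolerancePer100)
      list(genome = g, fam = fam)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[stem] <- conditionMessage(res)
      next
    }
    fams[[stem]] <- res$fam
    bins <- binRepeats(res$fam, binEdges, genomeId(res$genome))
    binrows[[stem]] <- stats::setNames(bins$count, bins$label)
    summaries[[stem]] <- genomeRepeatTable(res$fam, res$genome)$summary
    if (!is.null(outDir))
      .writeGenomeOutputs(res$fam, res$genome, file.path(outDir, stem),
                          binEdges, scoring)
  }
  if (!length(fams)) stop("all genomes failed: ",
                          paste(failures, collapse = "; "))
  mat <- as.data.frame(do.call(rbind, binrows))
  mat <- cbind(genome = names(binrows), mat)
  rownames(mat) <- NULL
  if (!is.null(outDir))
    utils::write.table(mat, file.path(outDir, "combined_bins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  list(families = fams, matrix = mat,
       summaries = do.call(rbind, c(list(NULL), summaries)),
       failures = failures)
}

#' Fraction of species per group with a repeat in each size bin
#'
#' For every taxonomic group and size bin, the fraction of the group's
#' species having at least one repeat family whose length falls in that
#' bin.  Fractions are k/n with k an integer count of species and n the
#' group size, so a one-species group yields only 0 or 1.
#'
#' @param batch result of [batchRun()], or its `matrix` element.
#' @param groupMap `data.frame` with columns `id`, `group` (see
#'   [readGroupMap()]); every genome in the batch must appear.
#' @param binEdges must match the edges the batch was binned with (used
#'   for labelling only).
#' @return `data.frame`: one row per group with `group`, `n_species`,
#'   and one fraction column per size bin.
#' @export
groupFractionMatrix <- function(batch, groupMap,
                                binEdges = defaultBinEdges()) {
  mat <- if (is.data.frame(batch)) batch else batch$matrix
  missing <- setdiff(mat$genome, groupMap$id)
  if (length(missing))
    stop("genomes missing from the group map: ",
         paste(missing, collapse = ", "))
  grp <- groupMap$group[match(mat$genome, groupMap$id)]
  bins <- setdiff(colnames(mat), "genome")
  pres <- as.matrix(mat[, bins, drop = FALSE]) > 0
  groups <- unique(grp)
  fr <- t(vapply(groups, function(g)
    colMeans(pres[grp == g, , drop = FALSE]), numeric(length(bins))))
  out <- data.frame(group = groups,
                    n_species = as.integer(table(grp)[groups]),
                    stringsAsFactors = FALSE, check.names = FALSE)
  cbind(out, as.data.frame(fr, check.names = FALSE))
}

#' Heat-map of a group fraction matrix
#'
#' Simple presentation extra: blue encodes fraction 1, yellow fraction
#' 0, interpolating in between.
#'
#' @param gm output of [groupFractionMatrix()].
#' @param main plot title.
#' @return invisibly, the plotted fraction matrix.
#' @export
plotGroupMatrix <- function(gm, main = "Repeat size spectrum by group") {
  bins <- setdiff(colnames(gm), c("group", "n_species"))
  m <- as.matrix(gm[, bins, drop = FALSE])
  rownames(m) <- gm$group
  pal <- grDevices::colorRampPalette(c("yellow", "blue"))(100L)
  graphics::image(seq_along(bins), seq_len(nrow(m)),
                  t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = pal, zlim = c(0, 1), axes = FALSE,
                  xlab = "repeat size bin (bp)", ylab = "", main = main)
  graphics::axis(1L, at = seq_along(bins), labels = bins, las = 2L,
                 cex.axis = 0.7)
  graphics::axis(2L, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 1L, cex.axis = 0.8)
  invisible(m)
}
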