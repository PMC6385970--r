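test_that("reciprocal listings of one repeat collapse to a single alignment", {
  ## both orderings of a 600 bp repeat pair, as a blastn-style table
  h <- data.frame(qStart = c(1001L, 3301L), qEnd = c(1600L, 3900L),
                  sStart = c(3301L, 1001L), sEnd = c(3900L, 1600L),
                  strand = "+", length = 600L, score = 600,
                  mismatches = 0L, stringsAsFactors = FALSE)
  d <- deduplicateHsps(h)
  expect_identical(nrow(d), 1L)
  expect_identical(d$qStart, 1001L)  # canonical orientation kept
  ## distinct pairs among three copies are all retained
  h3 <- data.frame(qStart = c(1L, 1L), qEnd = c(200L, 200L),
                   sStart = c(1001L, 2001L), sEnd = c(1200L, 2200L),
                   strand = "+", length = 200L, score = 200,
                   mismatches = 0L, stringsAsFactors = FALSE)
  expect_identical(nrow(deduplicateHsps(h3)), 2L)
  expect_identical(nrow(deduplicateHsps(h3[0, ])), 0L)
})

test_that("representatives collapse content-identical and reverse-complement copies", {
  pf <- plantedGenome(list(plantSpec(300, 3, c("+", "+", "-"))),
                      seed = 301)
  h <- selfCompare(pf$genome)
  expect_identical(nrow(h), 3L)  # all three pairwise alignments
  reps <- selectRepresentatives(deduplicateHsps(h), pf$genome)
  expect_length(reps, 1L)
  expect_identical(Biostrings::width(reps), 300L)
})

test_that("locateAllCopies finds every copy, including inverted and mismatched", {
  pf <- plantedGenome(list(plantSpec(600, 3, c("+", "+", "-"))),
                      seed = 311)
  rep <- substr(genomeString(pf$genome), pf$truth$start[1],
                pf$truth$end[1])
  fam <- locateAllCopies(rep, pf$genome)
  expect_identical(copyCount(fam), 3L)
  expect_setequal(as.character(GenomicRanges::strand(repeatCopies(fam))),
                  c("+", "+", "-"))
  expect_identical(sort(GenomicRanges::start(repeatCopies(fam))),
                   sort(pf$truth$start))
  ## a copy carrying one substitution is still recovered, with its
  ## divergence recorded
  pf2 <- plantedGenome(list(plantSpec(600, 2,
                       mismatches = list(integer(0), 300L))), seed = 312)
  first <- pf2$truth[pf2$truth$mismatches == 0, ]
  rep2 <- substr(genomeString(pf2$genome), first$start, first$end)
  fam2 <- locateAllCopies(rep2, pf2$genome)
  expect_identical(copyCount(fam2), 2L)
  expect_identical(sort(S4Vectors::mcols(repeatCopies(fam2))$mismatches),
                   c(0L, 1L))
  ## representatives shorter than the word size are refused
  expect_error(locateAllCopies(substr(rep, 1, 30), pf$genome),
               "shorter than the word size")
  ## a sequence with a single genomic occurrence is not a repeat
  single <- substr(genomeString(pf$genome), 10, 200)
  expect_warning(fam1 <- locateAllCopies(single, pf$genome),
                 "fewer than two")
  expect_identical(copyCount(fam1), 1L)
})

test_that("buildFamilies reproduces the planted family structure", {
  pf <- plantedGenome(list(plantSpec(600, 3), plantSpec(300, 2, c("+", "-"))),
                      seed = 321)
  fams <- buildFamilies(selfCompare(pf$genome), pf$genome)
  expect_length(fams, 2L)
  expect_identical(vapply(fams, familyId, character(1)), c("R1", "R2"))
  expect_identical(vapply(fams, familyLength, integer(1)), c(600L, 300L))
  expect_identical(vapply(fams, copyCount, integer(1)), c(3L, 2L))
  expect_false(any(vapply(fams, isTandem, logical(1))))
  ## representative anchored on the first plus-strand copy
  f1 <- fams[[1]]
  firstPlus <- min(GenomicRanges::start(
    repeatCopies(f1)[GenomicRanges::strand(repeatCopies(f1)) == "+"]))
  expect_identical(as.character(representative(f1)),
                   substr(genomeString(pf$genome), firstPlus,
                          firstPlus + 599L))
  ## random genome without plants yields no family
  expect_length(findRepeats(generateBackground(20000, seed = 322)), 0L)
})

test_that("copy-length homogeneity holds across random planted genomes", {
  for (seed in c(331, 332, 333)) {
    withr::with_seed(seed, {
      specs <- lapply(seq_len(sample(1:2, 1)), function(i)
        randomPlantSpec())
      pf <- plantedGenome(specs, seed = seed)
      ## heavily mismatched short plants may leave trimmed single-copy
      ## representatives behind; those are dropped with a warning
      fams <- suppressWarnings(
        buildFamilies(selfCompare(pf$genome), pf$genome))
      for (f in fams)
        expect_true(all(IRanges::width(repeatCopies(f)) ==
                        familyLength(f)))
    })
  }
})

test_that("adjacent identical copies form one family flagged tandem", {
  bg <- generateBackground(4000, seed = 341)
  unit <- genomeString(generateBackground(200, seed = 342, id = "u"))
  s <- genomeString(bg)
  ## two abutting copies; flanks chosen to differ from the unit's ends
  ## so the planted boundaries are sharp
  lf <- setdiff(c("A", "C", "G", "T"), substr(unit, 200, 200))[1]
  rf <- setdiff(c("A", "C", "G", "T"), substr(unit, 1, 1))[1]
  s2 <- paste0(substr(s, 1, 999), lf, unit, unit, rf,
               substr(s, 1402, 4000))
  g <- GenomeSeq("tandem", s2)
  fams <- buildFamilies(selfCompare(g), g)
  expect_length(fams, 1L)
  expect_identical(familyLength(fams[[1]]), 200L)
  expect_identical(copyCount(fams[[1]]), 2L)
  expect_true(isTandem(fams[[1]]))
})

test_that("curation is idempotent: re-expressing family copies returns the same families", {
  pf <- plantedGenome(list(plantSpec(500, 3), plantSpec(250, 2, c("+", "-"))),
                      seed = 351)
  fams <- buildFamilies(selfCompare(pf$genome), pf$genome)
  ## express every copy pair of each family as an HSP and re-curate
  rows <- list()
  for (f in fams) {
    gr <- repeatCopies(f)
    n <- length(gr)
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      si <- as.character(GenomicRanges::strand(gr[i]))
      sj <- as.character(GenomicRanges::strand(gr[j]))
      rows[[length(rows) + 1]] <- data.frame(
        qStart = GenomicRanges::start(gr[i]),
        qEnd = GenomicRanges::end(gr[i]),
        sStart = GenomicRanges::start(gr[j]),
        sEnd = GenomicRanges::end(gr[j]),
        strand = if (si == sj) "+" else "-",
        length = familyLength(f),
        score = familyLength(f),
        mismatches = 0L, stringsAsFactors = FALSE)
    }
  }
  fams2 <- buildFamilies(do.call(rbind, rows), pf$genome)
  expect_identical(familySummary(fams2), familySummary(fams))
  expect_identical(lapply(fams2, function(f)
    as.character(repeatCopies(f))), lapply(fams, function(f)
    as.character(repeatCopies(f))))
})

test_that("a central mismatch cluster splits a duplication into two repeats", {
  pf <- plantedGenome(list(plantSpec(300, 2,
          mismatches = list(integer(0), c(149L, 150L, 151L)))),
        seed = 361)
  fams <- buildFamilies(selfCompare(pf$genome), pf$genome)
  expect_length(fams, 2L)
  lens <- sort(vapply(fams, familyLength, integer(1)))
  expect_identical(lens, c(148L, 149L))
  expect_identical(vapply(fams, copyCount, integer(1)), c(2L, 2L))
})
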