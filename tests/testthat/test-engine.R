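test_that("seed index maps words to sorted positions on both strands", {
  g <- GenomeSeq("toy", "ACGTACGT")
  idx <- buildSeedIndex(g, 4)
  expect_identical(seedPositions(idx, "ACGT"), c(1L, 5L))
  expect_identical(seedPositions(idx, "CGTA"), 2L)
  expect_identical(seedPositions(idx, "AAAA"), integer(0))
  ## homopolymer: one word, one position; its reverse complement is
  ## absent from the forward table but queryable on the other strand
  g2 <- GenomeSeq("homo", "AAAA")
  idx2 <- buildSeedIndex(g2, 4)
  expect_identical(seedPositions(idx2, "AAAA"), 1L)
  expect_identical(seedPositions(idx2, "TTTT"), integer(0))
  expect_identical(seedPositions(idx2, "TTTT", revcomp = TRUE), 1L)
  expect_error(buildSeedIndex(g2, 10), "exceeds")
  ## words overlapping a masked residue are not indexed
  gm <- GenomeSeq("masked", "CAGTNACGTACGTT")
  idxm <- buildSeedIndex(gm, 4)
  expect_identical(seedPositions(idxm, "ACGT"), c(6L, 10L))
  expect_identical(seedPositions(idxm, "GTNA"), integer(0))
})

test_that("no 50-mer repeats by chance in random backgrounds", {
  for (seed in 1:5) {
    g <- generateBackground(20000, seed = seed)
    idx <- buildSeedIndex(g, 50)
    expect_identical(nrow(enumerateSeedMatches(idx, g)), 0L)
  }
})

test_that("seeds on one diagonal coalesce to a single seed per exact run", {
  g <- GenomeSeq("toy", "ACGTACGT")
  seeds <- enumerateSeedMatches(buildSeedIndex(g, 4), g)
  plus <- seeds[seeds$strand == "+", ]
  expect_identical(nrow(plus), 1L)
  expect_identical(plus$qStart, 1L)
  expect_identical(plus$sStart, 5L)
  ## a planted exact duplicate yields exactly one coalesced plus seed
  pf <- plantedGenome(list(plantSpec(600, 2)), seed = 201, L = 6000L)
  seeds <- enumerateSeedMatches(buildSeedIndex(pf$genome, 50), pf$genome)
  expect_identical(nrow(seeds), 1L)
  expect_identical(seeds$span, 600L)
  expect_identical(seeds$strand, "+")
  t <- pf$truth
  expect_identical(seeds$qStart, min(t$start))
  expect_identical(seeds$sStart, max(t$start))
})

test_that("X-drop extension crosses isolated mismatches and ties break long", {
  ## copy pair differing at position 51 of a 71 bp unit:
  ## 50 matches + 1 mismatch + 20 matches scores 50 both truncated and
  ## crossed; the longest segment wins
  pf <- plantedGenome(list(plantSpec(71, 2,
                      mismatches = list(integer(0), 51L))), seed = 211)
  h <- selfCompare(pf$genome)
  expect_identical(nrow(h), 1L)
  expect_identical(h$length, 71L)
  expect_identical(h$score, 50)
  expect_identical(h$mismatches, 1L)
  ## with only 19 matches after the mismatch, extension does not pay
  pf <- plantedGenome(list(plantSpec(70, 2,
                      mismatches = list(integer(0), 51L))), seed = 212)
  h <- selfCompare(pf$genome)
  expect_identical(nrow(h), 1L)
  expect_identical(h$length, 50L)
  expect_identical(h$score, 50)
  expect_identical(h$mismatches, 0L)
})

test_that("extendUngapped recovers a planted duplication from its seed", {
  pf <- plantedGenome(list(plantSpec(600, 2)), seed = 221, L = 6000L)
  seeds <- enumerateSeedMatches(buildSeedIndex(pf$genome, 50), pf$genome)
  hsp <- extendUngapped(pf$genome, seeds[1, ])
  expect_identical(hsp$length, 600L)
  expect_identical(hsp$score, 600)
  expect_identical(hsp$mismatches, 0L)
  ## extension below the minimum score reports nothing
  expect_null(extendUngapped(pf$genome, seeds[1, ],
                             scoringScheme(minScore = 1000)))
})

test_that("selfCompare finds planted direct and inverted repeats, never itself", {
  pf <- plantedGenome(list(plantSpec(600, 2), plantSpec(300, 2, c("+", "-"))),
                      seed = 231)
  h <- selfCompare(pf$genome)
  expect_identical(nrow(h), 2L)
  expect_setequal(h$length, c(600L, 300L))
  expect_setequal(h$strand, c("+", "-"))
  ## the full-length self-identity never appears
  expect_false(any(h$qStart == h$sStart & h$qEnd == h$sEnd &
                   h$strand == "+"))
  ## determinism: identical input gives identical output
  expect_identical(h, selfCompare(pf$genome))
})

test_that("random 100 kb genomes contain no reportable repeat", {
  g <- generateBackground(100000, seed = 77)
  expect_identical(nrow(selfCompare(g)), 0L)
})

test_that("strand symmetry: reverse-complementing the genome preserves the repeat set", {
  pf <- plantedGenome(list(plantSpec(500, 2, c("+", "-")),
                           plantSpec(200, 3)), seed = 241)
  h <- selfCompare(pf$genome)
  rc <- GenomeSeq("rc", as.character(
    Biostrings::reverseComplement(DNAString(genomeString(pf$genome)))))
  h2 <- selfCompare(rc)
  expect_identical(sort(h$length), sort(h2$length))
  expect_identical(sort(h$score), sort(h2$score))
  expect_identical(table(h$strand), table(h2$strand))
})

test_that("HSP scores and exact cores recompute from the sequence", {
  pf <- plantedGenome(list(plantSpec(400, 2, c("+", "-"),
                                     mismatches = c(0, 3)),
                           plantSpec(150, 2, mismatches = c(0, 1))),
                      seed = 251)
  sc <- scoringScheme()
  h <- selfCompare(pf$genome, sc)
  s <- genomeString(pf$genome)
  for (i in seq_len(nrow(h))) {
    q <- substr(s, h$qStart[i], h$qEnd[i])
    sub <- substr(s, h$sStart[i], h$sEnd[i])
    if (h$strand[i] == "-")
      sub <- as.character(Biostrings::reverseComplement(DNAString(sub)))
    qc <- strsplit(q, "")[[1]]; sc2 <- strsplit(sub, "")[[1]]
    mm <- sum(qc != sc2)
    expect_identical(mm, h$mismatches[i])
    expect_identical(sc@matchReward * (h$length[i] - mm) +
                     sc@mismatchPenalty * mm, h$score[i])
    ## at least one exact run of word size
    runs <- rle(qc == sc2)
    expect_gte(max(runs$lengths[runs$values]), sc@wordSize)
  }
})

test_that("a perfect palindrome is reported as an overlapping minus-strand self-match", {
  bg <- generateBackground(3000, seed = 261)
  arm <- genomeString(generateBackground(60, seed = 262, id = "arm"))
  pal <- paste0(arm, as.character(
    Biostrings::reverseComplement(DNAString(arm))))
  s <- genomeString(bg)
  g <- GenomeSeq("pal", paste0(substr(s, 1, 1000), pal,
                               substr(s, 1121, 3000)))
  h <- selfCompare(g)
  expect_identical(nrow(h), 1L)
  expect_identical(h$strand, "-")
  expect_identical(h$qStart, h$sStart)  # locus matches itself
  expect_gte(h$length, 120L)
})

test_that("circular mode recovers a repeat copy spanning the origin", {
  bg <- generateBackground(5000, seed = 271)
  unit <- genomeString(generateBackground(300, seed = 272, id = "u"))
  s <- genomeString(bg)
  ## copy 1 internal; copy 2 wraps: 100 bp before the end + 200 bp after
  s2 <- paste0(substr(unit, 101, 300), substr(s, 201, 999), unit,
               substr(s, 1300, 4900), substr(unit, 1, 100))
  lin <- selfCompare(GenomeSeq("c", s2, circular = FALSE))
  circ <- selfCompare(GenomeSeq("c", s2, circular = TRUE))
  expect_lt(max(lin$length), 300L)
  expect_gte(max(circ$length), 300L)
  ## wrapped subject interval is flagged by an end beyond the length
  expect_true(any(circ$sEnd > nchar(s2)))
})
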