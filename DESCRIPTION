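Package: OrganelleRepeats
Title: Dispersed Repeat Discovery and Size-Spectrum Analysis for
    Organelle Genomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Finds non-tandem (dispersed) repeats of about 50 bp and larger
    in organelle-scale genome sequences by exact k-mer seeding and ungapped
    X-drop extension of both-strand self-alignments under a stringent
    match/mismatch scoring scheme, curates the raw alignments into distinct
    repeat families with every genomic copy located by a second
    query-versus-genome pass, and summarizes repeat size spectra per genome,
    across genome collections, and across taxonomic groups. Includes a
    synthetic-genome generator with planted repeat families and a
    brute-force alignment oracle for validation, writers for repeat FASTA,
    tabular and NCBI feature-table (GenBank annotation) output, a parser
    for BLAST tabular output for cross-validation, and a command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'seqio.R'
    'engine.R'
    'curate.R'
    'blast.R'
    'summarize.R'
    'synthfix.R'
    'cli.R'
    'utils-internal.R'
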