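Place user-supplied single-genome FASTA files here, named
<accession>.fasta (for example EU306617.1.fasta), before installing the
package.  The accession-based tests in tests/testthat/test-acceptance.R
read them from this directory (or from options(orgrep.genomeDir=)).
This package never downloads sequences itself.
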