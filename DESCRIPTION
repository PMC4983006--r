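Package: isomajor
Title: Isoform-Level Expression Summaries, Major-Isoform Calling, and
    Expression-Prioritized Variant Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Summarizes transcript-isoform expression from RSEM-style
    fraction-of-transcripts matrices across tumor/normal cohorts, calls the
    major (most expressed) isoform per gene and group with a Q3 tie-break,
    infers candidate tumor-specific isoforms (Type I tumor-only expression,
    Type II major-isoform switching), takes a census of agreement between
    major and canonical/principal isoforms, and annotates VCF variants with
    expression-sorted isoform lists and transcript-structure element labels
    (exon/intron/UTR) so that protein-level consequences can be interpreted
    on the most plausible transcript backbone.  Includes deterministic
    synthetic-fixture generators (genome, gene models, expression, VCF) and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
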