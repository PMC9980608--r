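Package: mviomics
Title: Multiomic Integration Analysis of the Gut Virome
Version: 0.1.0
Authors@R:
    person("Virome", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to integrate metagenome (MG), metavirome (MV) and
    metatranscriptome (MT) sequencing of the same gut-microbiome samples
    into a single viral-contig analysis. Implements containment
    clustering of contigs across datasets (95% identity over 90% of the
    smaller contig), source-of-origin and integration-capable (IC) versus
    non-integrated (NI) classification of viral contigs, prophage masking
    of host contigs, breadth-of-coverage filtering, length-normalized
    relative abundance (NRA), transcriptional-activity calling, integrase
    detection and integration likelihood ratios, alpha/beta-diversity
    ecology with rarefaction, and detection-based sequencing-depth
    saturation curves. A ground-truthed synthetic-community generator
    emulating a 3-participant, 3-site (proximal colon, distal colon,
    stool) study design drives recovery testing of every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
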