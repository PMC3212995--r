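Package: denovoTE
Title: De Novo Discovery, Clustering and Characterization of
    Transposable Elements in Assembled Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A combined homology/structure pipeline for transposable
    element (TE) annotation. Dispersed repeat families are discovered by
    aligning an assembled genome against itself, condensing overlapping
    local alignments into piles and calling families of three or more
    copies longer than 400 bp. Family members are clustered at 90%
    identity over 90% of length, aligned with a longest-first progressive
    profile aligner, and summarized by majority-rule consensus and
    centroid sequences. Each cluster is then characterized structurally
    (terminal inverted repeats, LTR direct-repeat pairs, palindromes,
    six-frame ORFs, polypurine tract, primer-binding site) and by
    similarity to user-supplied reference libraries, classified into the
    Wicker TE hierarchy with element-type labels (full-length, fragment,
    remnant, Solo-LTR, MITE), and profiled with per-cluster evolutionary
    statistics (p-distance, Nei-Gojobori dN/dS, Tajima's D). A seeded
    genome simulator plants TE families with known truth so every stage
    is benchmarkable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
SystemRequirements: NCBI BLAST+ (blastn, tblastx, blastx on the PATH)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
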