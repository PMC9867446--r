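Package: clcscan
Title: Annotation and Phylogenetics of CLC Anion Channel Family Proteins
Version: 0.1.0
Authors@R:
    person("clcscan", "developers", email = "clcscan@example.org", role = c("aut", "cre"))
Description: Sequence-based characterization of CLC chloride-channel-family
    proteins. Scans the conserved CLC motifs (GxGxPE selectivity filter,
    GKxGPxxH, PxxGxLF) and cytosolic sorting signals (YXXphi, dileucine),
    classifies anion specificity (proline = nitrate, serine = chloride) and
    transport mechanism (anion/H+ antiporter versus channel) from the gating
    and proton glutamates, locates CBS regulatory domains, computes
    physicochemical summaries (mass, isoelectric point, GRAVY,
    hydropathy-based transmembrane sketch), performs affine-gap global
    alignment and percent identity, builds JTT maximum-likelihood
    phylogenies with neighbor-joining starts, NNI search and bootstrap
    support, assigns eukaryotic/prokaryotic subgroups, applies in-silico
    point mutagenesis to coding sequences, and generates fully specified
    synthetic CLC-like test data with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
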