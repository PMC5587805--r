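Package: thermusRM
Title: In-Silico Analysis of Thermus-Family Type IIC/IIL Restriction-Modification Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational characterization of Thermus-family
    Type IIC/IIL restriction-modification enzymes such as TaqII and TaqIII.
    Simulates cleavage at fixed 11/9 offsets downstream of asymmetric
    recognition sites, inverts run-off Sanger sequencing observations to infer
    cleavage geometry, predicts recognition motifs from target-recognition-domain
    anchor residues via a declarative amino-acid-to-base rule table, computes
    ProtParam-style protein physicochemical profiles (theoretical pI,
    instability index, aliphatic index), compares paralogous enzymes by global
    alignment with domain-level difference mapping and theoretical tryptic
    peptide classification, and generates seed-deterministic synthetic
    substrates and protein variants with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
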