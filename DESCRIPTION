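Package: cirDNAstructure
Title: Structural Profiling of Circulating Nuclear and Mitochondrial DNA
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to characterise the circulating structural forms of
    cell-free nuclear and mitochondrial DNA from plasma. Builds 1-bp
    fragment-size frequency profiles (30-1000 bp/nt) from aligned paired-end
    reads or fragment tables, contrasting double-strand (DSP) and
    single-strand (SSP) sequencing library preparations; quantifies targets
    from qPCR standard curves including the DNA Integrity Index; and infers
    the repartition of DNA across structural classes (large structures,
    extracellular vesicles, nucleoprotein complexes) from differential
    centrifugation and filtration series. A calibrated synthetic-data
    generator (banded fragment-length mixtures and a mechanistic
    jagged-end/nick duplex simulator) makes every stage testable without
    sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Rsamtools, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
biocViews: Sequencing, Preprocessing, QualityControl, Epigenetics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
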