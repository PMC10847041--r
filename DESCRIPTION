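Package: TaxoSpectra
Title: Taxonomically Resolved Search of Tandem Mass Spectrometry Repositories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained search engine for repositories of microbial
    monoculture MS/MS spectra. Reference spectra in Mascot Generic Format are
    indexed by precursor m/z, queried with the modified cosine score in exact
    or analogue (mass-shift-tolerant) mode, and matches are aggregated onto an
    NCBI-style taxonomic tree with upstream propagation, per-taxon match
    proportions, and blank/QC accounting. Includes batch search from MGF files
    or Universal Spectrum Identifier lists, exportable result tables and trees
    (JSON, Newick, HTML), a germ-free versus colonized cohort
    spectral-subtraction workflow with producer-domain partitioning, and a
    deterministic synthetic-repository generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cohort.R'
    'fixtures.R'
    'index.R'
    'repository.R'
    'search.R'
    'similarity.R'
    'spectra-io.R'
    'taxonomy.R'
    'utils.R'
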