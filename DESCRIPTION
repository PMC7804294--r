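Package: RiboArch
Title: Evolutionary Archaeology of Ribosomal Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct and analyse the evolution of ribosomal
    protein (r-protein) interaction networks across the three kingdoms of
    life. Detects inter-chain interfaces in ribosome structures by solvent
    accessible surface area (SASA) difference with a rolling probe, builds
    centre-of-mass network graphs whose nodes are r-proteins and functional
    sites (PTC, exit tunnel, mRNA and tRNA sites), annotates edges by
    evolutionary status and contact type, intersects kingdom networks into a
    universal core, computes per-transition statistics of newly acquired
    contacts, tests network non-randomness against Erdos-Renyi null graphs
    with centrality-based Monte Carlo statistics, and maps multiple sequence
    alignment conservation and aromatic-residue acquisitions onto
    interfaces. Seeded synthetic-data generators produce toy complexes,
    annotated edge tables and alignments with planted ground truth for every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RiboArch-package.R'
    'archaeology.R'
    'components.R'
    'conservation.R'
    'graphstats.R'
    'interfaces.R'
    'network.R'
    'pipeline.R'
    'radii.R'
    'sasa.R'
    'structure-io.R'
    'synthetic-msa.R'
    'synthetic-network.R'
    'synthetic-structure.R'
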