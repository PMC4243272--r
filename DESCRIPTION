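Package: LigandCuration
Title: Small-Molecule Annotation Toolkit for Macromolecular Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Curation-grade annotation of small molecules bound to
    macromolecular structures: a reader, writer and validator for chemical
    component dictionary (CCD) definitions in the CIF dialect; identification
    of observed components against a dictionary by element-labelled graph
    matching tolerant of absent hydrogens and leaving atoms; symmetry-aware
    delineation of ligand-binding sites at a fixed contact cutoff with
    _struct_site/_struct_site_gen output; detection of inter-component
    covalent linkages and metal-coordination centres with all pairwise
    angles (REMARK 620 and _pdbx_struct_conn_angle); classification of
    peptide-like inhibitors and antibiotics by consecutive-peptide-bond
    counting (polymer, non-polymer with subcomponents, or group) with
    PRD/FAM reference-dictionary handling; and ligand validation by
    dictionary-geometry deviation and the local ligand density fit (LLDF)
    Z-score on real-space R-values. A deterministic fixture generator
    produces every input format synthetically, so the full pipeline runs
    without external archives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
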