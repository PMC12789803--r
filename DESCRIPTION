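Package: urimod
Title: Structural Survey of Uridine Modifications in RNA 3D Structures
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to survey six naturally occurring uridine modifications
    (pseudouridine, 5-methyluridine, 3-methyluridine, 2'-O-methyluridine,
    4-thiouridine and 5,6-dihydrouridine) in experimentally solved RNA
    three-dimensional structures.  Provides mmCIF/PDB structure input with a
    residue-quality screen, a geometry kernel (torsions, Kabsch superposition,
    iterative mean structures, representative-model selection), sugar-pucker
    pseudorotation and glycosidic-angle classification, geometric annotation of
    hydrogen bonds, base stacking, base pairs and hairpin secondary-structure
    elements, dataset curation with resolution filtering and NMR-ensemble
    representative selection, hairpin motif clipping and canonical-counterpart
    matching against a local library, sequence-representative-structure (SRS)
    selection and modified-versus-unmodified all-atom RMSD comparison with
    interaction differencing, survey reporting, and a synthetic A-form hairpin
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
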