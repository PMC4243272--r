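# LigandCuration

Curation-grade annotation of small molecules bound to macromolecular
structures, in R.

Every deposited crystal structure carries small molecules — cofactors,
carbohydrates, inhibitors, metals, waters — and archival quality depends on
identifying each one against a chemical reference dictionary, recording how
it is bound, and validating how well it fits the data. `LigandCuration`
implements that workflow as a reusable toolkit:

* **Chemical component dictionary (CCD) handling** — an S4 data model
  (`ChemCompDef`) with a reader, writer and validator for the CCD CIF
  dialect (`_chem_comp`, `_chem_comp_atom`, `_chem_comp_bond`,
  `_pdbx_chem_comp_descriptor`), including leaving-atom flags: the anomeric
  hydroxyl of α-D-glucose is marked as eliminated when the sugar
  polymerises, so one definition serves both the free and the bound form.
* **Component identification** — bonds are perceived from coordinates by a
  covalent-radius criterion (`r_i + r_j + 0.45 Å`), and the observed
  heavy-atom graph is embedded into dictionary graphs with element labels
  required to agree. Dictionary hydrogens and leaving atoms may be absent
  without penalty; a bounded fraction of other atoms may be missing
  (disorder). Matched components are renamed to dictionary nomenclature;
  novel molecules get draft definitions (`buildNewDefinition`).
* **Binding sites** — `delineateSites()` lists every residue with any atom
  within 3.7 Å of any ligand atom, crystallographic symmetry included
  (space-group operators × ±1 lattice translations), with multi-component
  molecules (oligosaccharides, peptide-like antibiotics) treated as one
  site. Sites get AC1…ZZ9 identifiers and are written as
  `_struct_site`/`_struct_site_gen`.
* **Linkages and metals** — inter-component covalent bonds (`_struct_conn`:
  covale/disulf/metalc, with polymer backbone bonds excluded) and metal
  coordination centres with all k(k−1)/2 pairwise angles, written as
  REMARK 620 and `_pdbx_struct_conn_angle`.
* **Peptide-like molecules (BIRD)** — peptide bonds are inter-subcomponent
  carbonyl-C→N bonds; two or more consecutive peptide bonds make a
  molecule a standard POLYMER, fewer make it a non-polymer with an N→C
  subcomponent sequence, and sugar or acyl attachments to a peptide core
  force GROUP representation. PRD/FAM reference files round-trip.
* **Validation** — geometry deviations against dictionary ideal
  coordinates, chirality by signed volume, and the **LLDF** (local ligand
  density fit): the Z-score of a ligand's real-space R-value against the
  mean and sample standard deviation of the RSR of polymeric standard
  residues within 5 Å,

  LLDF = (RSR_ligand − mean(RSR_neighbours)) / sd(RSR_neighbours),

  flagged when LLDF > 2.
* **Synthetic fixtures** — `makeCcdFixture()`, `makeStructureFixture()` and
  `makeRsrFixture()` generate every input format deterministically with
  brute-force ground truth, so the whole surface runs with no archive
  access.

## Worked example

```r
library(LigandCuration)

dict <- makeCcdDictionary()                       # GLC, ALA, BNZ, HOH, LIP
fx <- makeStructureFixture(list(spaceGroup = "P 1 21 1",
                                cell = c(30, 32, 34),
                                symContactDistance = 3.2), seed = 7)
sites <- delineateSites(fx$model, siteParams())   # 3.7 A, symmetry on
sites[[1]]
#> BindingSite AC1 for PRB S 1 - 2 contact residue(s)
siteContacts(sites[[1]])
#>   compId authChain authSeq insCode symLabel minDistance
#> 1    ALA         A       1            2_555    3.200000
#> 2    ALA         A       3            2_555    3.435056
```

The probe ligand touches nothing in its own asymmetric unit; both contacts
come through the second space-group operator (`2_555`), the nearest at
exactly the 3.2 Å the fixture placed it.

```r
glc <- dict$GLC
a <- atoms(glc)
obs <- data.frame(atomName = a$atomId, element = a$element, altLoc = "",
                  x = a$idealX, y = a$idealY, z = a$idealZ)
obs <- obs[obs$element != "H" & obs$atomId != "O1", ]   # bound form
m <- matchComponent(obs, glc)
m
#> ComponentMatch -> GLC [partial]
#>   mapped: 11  missing: 13  extra: 0  rmsd: 0.000 A
missingAtoms(m)[missingAtoms(m)$kind != "hydrogen", ]
#>    atomId    kind
#> 1      O1 leaving
```

A glucose observed without its anomeric oxygen is still identified as GLC —
the missing atom is the annotated leaving atom, exactly what a glycosidic
bond eliminates.

A command-line wrapper lives at `exec/ligand-curation`
(`match`, `sites`, `links`, `bird`, `validate`, `fixture`, `annotate`).

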