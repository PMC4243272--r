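---
title: "Methods: small-molecule curation, binding sites and ligand validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-molecule curation, binding sites and ligand validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LigandCuration)
```

This vignette is the package's account of its science: the models and
procedures it implements, the parameters that matter, what the synthetic
fixtures emulate, and the numerical choices made where the design was
genuinely open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The dictionary model and leaving atoms

A chemical component definition (`ChemCompDef`) describes the *neutral,
unbound* form of a molecule: atoms with element, charge, aromaticity,
tetrahedral stereo configuration and both an idealized and an example
experimental conformer; bonds with orders (`SING`/`DOUB`/`TRIP`/`AROM`);
and opaque descriptor strings (SMILES, InChI) that the package stores but
never interprets or regenerates — descriptor chemistry is out of scope, so
comparison is exact text.

Atoms eliminated on covalent attachment are flagged as **leaving atoms**
(a carboxylic OXT, an anomeric O1). This single flag lets one definition
serve both the free ligand and the covalently bound residue: the matcher
treats a missing leaving atom as expected rather than as disorder.

Validation (`validateDef`) reports violations as coded issues rather than
repairing them: a curator needs to hold an invalid definition in hand.
Checked invariants: component-id shape (1–3 alphanumeric, upper case —
the archive uses up to three characters), atom-id uniqueness, known
elements, bonds referencing two distinct existing atoms with each
unordered pair unique, formula reconciliation against per-element atom
counts with hydrogens included, and formal charge equal to the sum of
atomic charges. Missing coordinates are `NA`, never `0,0,0`: absent
geometry must not masquerade as an origin atom. Unknown CIF categories are
preserved verbatim so documents round-trip; the controlled vocabularies of
`type`/`pdbx_type` are accepted as free text because no complete
enumeration is published.

## Bond perception and component matching

Connectivity is deduced from coordinates: atoms *i, j* are bonded iff

d(i, j) ≤ r_cov(i) + r_cov(j) + tol,  tol = 0.45 Å,

with single-bond covalent radii (Cordero-style consensus values) and a
0.4 Å floor below which atoms are considered coincident. The tolerance is
a design choice: it accepts stretched covalent bonds (C–C up to 1.97 Å)
while rejecting hydrogen-bond contacts, which run ≥ 2.4 Å heavy-to-heavy.
Altlocs must be equal, or either blank, for a pair to bond.

Identification embeds the observed heavy-atom graph into the dictionary
heavy-atom graph (igraph's LAD solver with element-restricted candidate
domains). Three asymmetries are deliberate:

* dictionary **hydrogens** may always be absent — X-ray depositions
  routinely omit them;
* dictionary **leaving atoms** may be absent — the bound form;
* up to 20% of the remaining heavy atoms may be missing (default
  `maxMissingFrac = 0.2`), a budget for disordered ligands. No published
  tolerance exists for this; the figure is a documented toolkit decision.

Bond *orders* are never compared: they are unobservable in X-ray
coordinates. Ties among embeddings are broken by (fewest missing
non-leaving atoms, lowest RMSD after Kabsch superposition onto the
dictionary conformer, lexicographic atom map) — the last key makes results
reproducible for symmetric molecules such as benzene, whose twelve
automorphisms are otherwise indistinguishable. A match is *exact* only
when every non-hydrogen atom was observed; a bound sugar missing its
leaving oxygen is identified but not exact.

Draft definitions for novel molecules are explicitly draft quality: bond
orders come from greedy valence satisfaction, with an upgrade to a double
bond requiring both under-valence *and* a distance at least 0.11 Å below
the single-bond sum (valence deficit alone is not evidence when hydrogens
are unobserved); aromatic perception covers planar six-membered C/N rings
(plane RMS < 0.1 Å); tetrahedral handedness is called from the signed
volume of the three highest-priority substituents with |V| > 0.1 Å³
(below that, `N` — no call). These are initial deductions for curator
review, recorded as such in an audit category, not CIP assignments.

## Binding-site delineation under crystallographic symmetry

A residue belongs to a ligand's site iff any of its atoms — or any
crystallographic image of them — lies within **3.7 Å** of any ligand
atom. Images are generated by every space-group operator combined with
lattice translations in ±1 cell along each axis, sufficient for contact
radii far below the cell edges; each image carries an `op_555`-style
label. Operators come from an embedded table (P 1, P 1 2 1, P 1 21 1,
C 1 2 1, P 2 2 2, P 21 21 2, P 21 21 21, with spacing-insensitive
aliases); an unknown symbol is an error, never a silent non-symmetric
fallback, and only crystallographic (not non-crystallographic) symmetry is
considered. Coordinates are orthogonal Å throughout; fractional
coordinates exist only inside the symmetry arithmetic.

Contacts are computed atom-to-atom over all altlocs and then deduplicated
at residue level, keeping the minimum distance and the symmetry label at
which it occurs — a residue-level record matches how site tables are
consumed. Waters count as neighbours by default (toggleable) but are never
ligands of interest. Residues of the ligand's own group are excluded at
identity; a symmetry mate of the ligand itself is a genuine packing
neighbour and is kept. Multi-component molecules declared as groups
(oligosaccharides, peptide-like antibiotics) get one site for the whole
molecule, so the same sugar is not repeated across sites.

Site identifiers follow a fixed enumeration — two upper-case letters and
a digit 1–9, digit fastest, then second letter, then first, starting at
AC1 — which the tests pin. The enumeration order beyond the AC1…ZZ9
endpoints is not published anywhere; this one is declared and documented.

## Linkages and metal coordination

Inter-component atom pairs passing the bond-perception criterion
(symmetry-aware) become `_struct_conn` rows: S–S between two cysteines is
`disulf`, metal–donor pairs are `metalc`, the rest `covale`. Standard
backbone bonds — peptide C–N and nucleic O3′–P between sequence-adjacent
residues of one chain — are excluded by sequence adjacency, so genuine
nonstandard cross-links (chromophores, isopeptide bonds) are retained.

Metal centres collect donor atoms (N, O, S, Se, halides) within
element-pair cutoffs: Zn–N/O 2.6 Å, Na/K–O 3.2 Å, 3.0 Å default — common
coordination-chemistry practice, configurable, since no cutoff table is
published for the curation pipeline. Alternate conformers are separate
ligators, and angles are reported for *all* pairs including
cross-conformer pairs, matching how a disordered carboxylate is listed
with both conformers. All k(k−1)/2 angles about the metal go to REMARK 620
(fixed columns, 0.1° precision) and `_pdbx_struct_conn_angle`; both
round-trip-parse to the same numbers.

## Peptide-like molecules

A **peptide bond** here is an inter-subcomponent C–N bond whose carbon
carries a double-bonded oxygen within its own subcomponent and whose
nitrogen is bonded to a carbon of the downstream subcomponent; ester
junctions fail the nitrogen criterion. Bonds are directed C→N, the
amino-to-carboxy direction, and "consecutive" is the longest directed
path through consecutive subcomponents (branches contribute their longest
branch; cycles are walked as simple paths, starting at the lowest comp id
for determinism).

Classification applies, in order: saccharide/lipid subcomponents
covalently attached to the peptide core force **GROUP**; else ≥ 2
consecutive peptide bonds make a **POLYMER**; else the molecule is a
non-polymer with a subcomponent sequence. The group-over-polymer
precedence is deliberate — a glycopeptide's core alone would qualify as a
polymer, yet the attachments require group representation. D-amino acids
and N-methylated residues are treated identically by the topological
criterion; nothing finer is published. Attachment recognition keys on the
dictionary `type` strings (saccharide, lipid); UniProt/Norine accessions
are stored opaque, never resolved.

## Ligand validation and the LLDF

Geometry checks compare every dictionary bond and bond angle with all
atoms observed against values computed on the dictionary's idealized
conformer, with fixed reference sigmas (0.02 Å, 2°) for rms-Z summaries;
chirality is compared by signed volume with a shared substituent order on
both sides. Without ideal coordinates the report is limited to chirality
and says so. (CSD-based geometry statistics are a different instrument
and out of scope; the ideal-geometry comparison is the declared
substitute.)

The **LLDF** is the Z-score of the ligand's per-residue real-space
R-value against its neighbourhood:

LLDF = (RSR_ligand − mean RSR_nb) / sd RSR_nb,

where the neighbours are the polymeric *standard* residues (20 amino
acids, standard nucleotides; modified residues excluded) with any atom —
symmetry included — within **5 Å** of any ligand atom, each contributing
its whole-residue RSR. Two choices are documented toolkit decisions where
the literature is silent: the sample (n−1) standard deviation, and the
exclusion of waters from the neighbour set. Fewer than two RSR-carrying
neighbours, or zero spread, leaves the score *undefined* — an error, not
a zero. Scores above 2 are flagged. RSR itself is an input (a TSV of
per-residue values); computing it from electron density belongs to map
software, not to this package.

## The synthetic fixture universe

The generator produces every input the toolkit consumes, deterministically
from one integer seed with counter-based streams (adding a fixture never
shifts existing draws):

* **Dictionary fixtures** — a glucose analogue (puckered pyranose-like
  ring, O1 leaving, C6H12O6 reconciling), an alanine analogue (OXT
  leaving), benzene, water, and a short acyl chain. Topology and ideal
  coordinates are canonical; the model conformer is seed-perturbed by
  0.01 Å, far below the perception tolerance.
* **Crystal fixtures** — alanine residues scattered in P1, P2₁, C2 or
  P2₁2₁2₁ cells; probe ligands placed at exact separations; a ligand set
  at a chosen distance from a *symmetry image* of a protein atom; a
  cyclodextrin-like ring of seven sugars whose glycosidic geometry is
  solved numerically (ring radius from a root-find on the C1⋯O4 gap, a
  60° tilt about the tangent clearing the inner rim) so that exactly
  seven inter-sugar links exist; and a tetrahedral zinc with four donors
  at 2.0 Å. Ground truth — contact lists, link lists, metal angles — is
  computed by separate brute-force code (explicit operator × shift × atom
  loops with its own orthogonalization matrix), independent of the
  engines under test.
* **RSR fixtures** — neighbour residues draw RSR ~ Normal(base, σ), the
  ligand gets base + offset, so E[LLDF] ≈ offset/σ. That approximation
  carries the small-sample bias of the sample standard deviation
  (E[σ/S] > 1): with six neighbours the expected score runs ~20% above
  offset/σ, with a dozen it is within a few percent, so the Monte-Carlo
  calibration uses a dozen neighbours — a realistic count for a buried
  ligand.

What passing these fixtures does *not* show: real depositions have
disordered density, alternate conformations beyond the constructed ones,
non-ideal chemistry (charged states, tautomers), NCS, and map-derived RSR
with residue-to-residue correlation. The fixtures establish algorithmic
correctness against enumerable ground truth, not archive-scale behaviour.

## Numerical choices and degenerate inputs

* Orthogonalization uses the standard crystallographic convention (a
  along x, b in the xy plane); `fractionalize ∘ orthogonalize` is the
  identity to 1e-8 Å and is tested as such.
* Contact comparisons at an *exact* cutoff distance are a knife edge:
  two correct implementations can disagree through ~1e-12 rounding. The
  oracle fixtures therefore sample distances on both sides of the cutoff
  but never exactly on it.
* Zero-heavy-atom components never match; single atoms match trivially by
  element. Components with unknown elements are an error naming the
  element.
* The AC1…ZZ9 scheme holds 6066 identifiers; overflow is an error.
* Multi-model input: annotation operates on one model (the first by
  default).

## Problem sizes

The default suite runs ~450 assertions in well under a minute on one CPU:
51 oracle crystals of ~30 atoms, matcher oracles on components of ≤ 12
heavy atoms (the exhaustive-permutation oracle is factorial and is kept
to sizes where it is still exact), a 30-case classification table, and
200 Monte-Carlo LLDF draws. These sizes were chosen so every check is
exact or statistically stable, and they are regenerated — never stored —
at test time.
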