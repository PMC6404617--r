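---
title: "Consequence scanning: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consequence scanning: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steriscan)
```

## The model

`steriscan` answers a deliberately narrow question: on a *fixed* template
backbone, can a substituted side chain be placed in any plausible rotamer
without disrupting the local packing? The model is purely geometric —
hard-sphere sterics, a distance shell for favorable van der Waals
contact, and distance/angle criteria for hydrogen bonds. There is no
energy function, no ΔΔG, and no backbone relaxation. These are
assumptions, not omissions: the approach mirrors how a structural
biologist reads a mutagenesis-wizard session, where the verdict is
"clashes in every rotamer" or "loses the packing contacts", not a
free-energy number. It is most trustworthy at tightly packed sites where
sterics dominate, and least trustworthy where the backbone would visibly
relax to accommodate the new residue.

A scan proceeds per variant:

1. enumerate candidate rotamers of the substituted amino acid;
2. build each side chain from ideal internal coordinates on the template
   backbone;
3. score each placement against the unchanged environment;
4. condense the per-rotamer reports into one call from the vocabulary
   *Steric clash*, *Loss of van der Waals*, *Loss of H-bonds*, *None*.

In-frame deletions never enter the geometric path. Removing one residue
shifts every residue C-terminal to the site by one position relative to
its interaction partners, so the hydrogen-bonding register of the whole
element is lost regardless of any rotamer choice. `classify_variant()`
encodes this as a fixed rule (`rule_based = TRUE`, label *Loss of
H-bonds*), because the argument is made from sequence register, not
coordinates.

## Parameters

All thresholds live in `scan_params()` and are echoed into every report.

| parameter | default | units | rationale |
|---|---|---|---|
| `overlap_threshold` | 0.4 | Å | severe-clash convention: a pair clashes when r₁ + r₂ − d exceeds this |
| `contact_shell` | 0.5 | Å | a pair is a favorable contact when d ≤ r₁ + r₂ + shell (and is not a clash) |
| `env_radius` | 8 | Å | residues with any atom within this distance of the wild-type CB (CA for Gly) form the environment; covers the directly packed shell |
| `hbond$max_distance` | 3.5 | Å | heavy-atom donor–acceptor cutoff |
| `hbond$min_angle` | 90 | ° | antecedent–donor–acceptor angle; rejects impossible approach geometries without requiring hydrogens |
| `f_contact` | 0.6 | — | the best rotamer must keep at least this fraction of the wild-type side chain's contacts to avoid *Loss of van der Waals* |
| `clash_free_fraction_min` | 0.5 | — | below this clash-free fraction, a variant that *also* loses interactions picks up *Steric clash* as a secondary label |

Radii are Bondi values (C 1.70, N 1.55, O 1.52, S 1.80 Å …), shipped as
an editable config (`inst/extdata/vdw_radii.txt`); elements outside the
table (e.g. Se) are refused by name rather than guessed. Hydrogens are
flagged and excluded from scoring by default, since crystallographic
templates mostly lack them.

## Classification rules, and one deliberate refinement

The primary clash rule is strict: *Steric clash* is assigned when **no**
enumerated rotamer is clash-free. A pure fraction-based rule ("clash
label whenever fewer than half the rotamers are clash-free") was
considered and rejected, because at any tightly packed site even the
wild-type amino acid threads through a single χ₁ channel — its clash-free
fraction over a full library is well below one half — and such a rule
would label the identity substitution a clash. Instead the fraction
enters only as a *secondary* label: when a minority of rotamers are
clash-free (< `clash_free_fraction_min`) **and** even the best of those
loses contacts or hydrogen bonds, the call carries both the loss label
and *Steric clash* — the "depends on the rotamer examined" situation that
conservative-but-shorter substitutions (Glu→Asp at a packed site)
produce. This keeps two invariants that any user would expect:
identity substitutions always classify *None*, and an isosteric
substitution is never called worse than a branched one at the same site.

*Loss of van der Waals* requires the wild type to make side-chain
contacts at all (`wt contacts > 0`). A glycine substitution at a
solvent-facing position whose wild-type side chain touches nothing
therefore classifies *None* — backbone flexibility introduced by glycine
is outside the model.

The best rotamer is chosen deterministically: among clash-free rotamers,
most contacts, then most H-bonds, then enumeration order; with no
clash-free rotamer, fewest clashes. The H-bond census likewise breaks
ties by minimal donor–acceptor distance, then partner label order, so
identical inputs always give identical outputs.

## Rotamer library and side-chain geometry

The shipped library (`inst/extdata/rotamer_library.csv`, 329 entries) is
generated from well structure rather than survey statistics: staggered
wells {−60°, 60°, 180°} for every sp³ torsion; {0°, 90°} for the
near-symmetric terminal carboxylates (Asp χ₂, Glu χ₃) and aromatic ring
torsions; {−90°, 0°, 90°, 180°} for terminal amides and imidazole; and
{−90°, 90°, 180°} for the guanidinium torsion. Grid mode
(`enumerate_rotamers(..., mode = "grid")`) approximates "all possible"
rotamers with 30° steps for χ₁/χ₂ and 60° beyond, and is the
cross-check when a library verdict looks marginal. The backbone-dependent
filter is deliberately coarse: on 20° φ/ψ bins, the g⁺ χ₁ well is
excluded inside the broad α and β regions. That is the minimal faithful
reading of backbone dependence; a full rotamer-probability library is out
of scope.

Side chains are built by natural-extension placement from an internal-
coordinate table (`sidechain_geometry()`): standard ideal bond lengths
and angles, CB placed at C–N–CA–CB = −122.6° (L-configuration, verified
against deposited structures), branch offsets measured from real
coordinates (Val CG2 at χ₁ + 121.6°, Ile CG2 at χ₁ − 128.7°, …), planar
rings closed with fixed torsions. Proline is excluded from construction:
its ring closure couples χ to the backbone φ and cannot be realised by a
fixed internal-coordinate chain; requesting it raises the geometry-table
error. Pro χ angles can still be *measured*.

## Numerical choices

- Dihedrals follow the IUPAC sign convention (cis = 0°, range
  (−180°, 180°]); four collinear atoms raise an explicit error rather
  than returning an arbitrary value.
- Kabsch superposition uses SVD with the determinant correction, refuses
  < 3 points or collinear sets, and reports unweighted RMSD over the
  selection only (default selection: backbone N, CA, C, O of the shared
  residue range).
- Build/measure χ round trips hold to < 10⁻⁶° (property-tested over
  random rotamers of all buildable amino acids); rigid-motion recovery
  holds to < 10⁻⁹ Å.
- Percentages round half-up (`floor(x + 0.5)`) because the published
  table this format mirrors rounds 23.53 % to 24 %; base R `round()`
  half-even would print 23 %. Raw fractions in (0, 1) % display as
  "≤ 1%" — a bound, since such values reflect assay background rather
  than a measured rate.
- The Fisher p-value comes from `stats::fisher.test` (two-sided); the
  odds ratio reported alongside is the simple cross-product ratio with
  Haldane's +0.5 correction when a cell is empty, flagged in the output.
  The association statistic is this package's formalisation — the
  assay-table format it ingests reports no statistic — and is labeled as
  such in reports.

## The synthetic fixtures

`make_mini_hairpin()` builds two antiparallel ideal β-strands
(φ = −139°, ψ = 135°, 3.8 Å Cα steps) with a central Glu on one strand
packed against the other at contact distance. The opposing strand is
placed in a frame derived from the strand axis and the Glu face
direction; the default geometry was fixed once, by construction, so that
the site discriminates substitutions the way a packed loop interface
does: the same-reach isostere (Gln) is tolerated, the branched short
chain (Val) clashes in every rotamer, side-chain removal (Gly) loses the
packing contacts, and pulling the strands 2 Å apart de-clashes Val. The
engineered residue sits at position 5; the opposing segment is numbered
from 101 so the fixture is a single scannable protomer.

`make_ensemble()` replicates a five-residue template (an Asp–Lys–Glu
core) under random rigid motions, choosing the lysine's χ per copy so
that its hydrogen-bond partner follows a prescribed partition exactly
(default (5, 23, 8) over partners A, none, B across 36 copies — the
shape of a published protomer census this format mirrors); small χ noise
is added and each assignment re-verified, so census recovery is
guaranteed by construction, not by luck. `make_counts_table()` draws
binomial counts per variant and timepoint.

What the fixtures do *not* emulate: crystallographic disorder, altloc
mixtures, missing atoms, solvent, metals, or backbone heterogeneity
between protomers. A test passing on fixtures therefore validates the
*machinery* (geometry, counting, classification logic), not the
biological calibration of the thresholds on real structures — for that,
scan a real template and inspect the per-rotamer evidence.

## Problem sizes

The test suite and acceptance script run at deliberately small scale,
chosen as the smallest sizes that exercise every code path: 100
randomized atom clouds (8 probe × 30–50 environment atoms) for the
brute-force oracle comparisons, 36-protomer ensembles for the census, a
16-residue hairpin for classification, and the 24-row packaged count
table. The production code paths are vectorised and handle full-size
protomers (~150 residues, ~1200 atoms) without modification.

## Known limitations

- Fixed backbone: substitutions rescued by small main-chain shifts will
  be over-called as clashes; glycine-introduced flexibility is not
  modeled.
- No electrostatics or solvation: charge reversals that preserve shape
  classify *None*.
- Heavy-atom H-bond criteria only; hydrogen-aware scoring is accepted as
  a flag but templates rarely provide hydrogens.
- The rotamer library is compact by design; rare non-rotameric
  conformations are reachable only through grid mode.
- Proline cannot be built (see above); metal ions are parsed and take
  part in sterics but carry no coordination chemistry.
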