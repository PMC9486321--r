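---
title: "Dissecting protein-DNA interfaces: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting protein-DNA interfaces: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnaface)
```

## The problem and the model

A protein-DNA complex buries part of each partner's solvent accessible
surface. The buried patch - the interface - differs from the rest of the
protein surface in composition, hydrogen-bonding capacity and evolutionary
conservation, and those differences are strong enough to pick the true
binding mode out of a set of incorrect docked arrangements. `dnaface`
computes the full set of interface descriptors from a complex structure and
exposes the three discriminative features used for that ranking:

* the **residue propensity score** `Rp = sum_i n_i * p_i`, where `n_i` is
  the number of interface residues of amino-acid type `i` and `p_i` its
  log-scale propensity to occur at protein-DNA interfaces rather than on
  the general protein surface;
* the **potential donor count** `Dp`: the number of designated side-chain
  donor atoms (Arg NE/NH1/NH2, His ND1/NE2, Lys NZ, Asn ND2, Gln NE2,
  Trp NE1, Ser OG, Thr OG1, Tyr OH) with accessible surface area of at
  least 10 A^2 among the scored residues;
* the **conserved residue count** `Ncons`: the number of interface residues
  whose alignment-column Shannon entropy `s(i)` lies strictly below the
  interface mean `<s>_int = sum(s(i))/n`.

## Definitions and their numerical conventions

**Accessible surface area.** ASA is computed by the Shrake-Rupley
construction: each heavy atom's van der Waals sphere is expanded by the
probe radius (default 1.4 A, a water molecule) and sampled with a
deterministic golden-spiral point set (default 960 points per atom); the
accessible area is the expanded-sphere area times the fraction of points
outside every neighbour's expanded sphere. The point set involves no RNG,
so areas are bit-reproducible for a fixed point count. Radii follow the
Chothia-style convention of classic accessibility programs (O 1.40, N 1.65,
S 1.85, P 1.90, sp2 C 1.76, sp3 C 1.87 A); unknown elements fall back to a
generic element radius with a warning. Hydrogens and waters are excluded
from component ASA, matching heavy-atom-era conventions. Because the
engine is numerical rather than analytic, areas agree with analytic
closed forms to a few tenths of a percent at the default point count; the
test suite pins the lone-sphere and two-sphere closed forms at 0.5% and a
20-atom cluster against an independent 100,000-point quadrature at 1% of
the expanded-sphere area.

**Interface, core and rim.** An atom is interfacial when it loses more
than 0.1 A^2 of ASA between the isolated component and the complex; a
residue or nucleotide is interfacial when it owns at least one such atom.
An interface atom is *fully buried* when its in-complex ASA is at most the
same 0.1 A^2 threshold - "exactly zero" is numerically fragile under
quadrature, so the interface threshold doubles as the numerical-zero
convention. Residues with at least one fully buried atom form the core;
the remainder form the rim.

**Whole-interface statistics.** The 18-parameter table reports, per
component and in total: interface area (the sum of per-atom buried area -
both sides are summed, not halved), interface/surface ratio (denominator:
the isolated component's total ASA), atom and residue counts, the fraction
and buried area of non-polar atoms (C and S), the fraction of fully buried
atoms, local density, and polypeptide segments. Two of these have no
universally fixed definition and are treated as conventions here,
documented and soft-checked only: *local density* is the mean number of
same-component interface atoms within 12 A of each interface atom, and a
*segment* is a maximal run of interface residues in which consecutive
interface residues are separated by at most four non-interface residues.

**Hydrogen bonds.** Rather than placing hydrogens, bonds are detected on
heavy atoms: a dictionary donor and acceptor (side-chain and backbone
groups of the 20 amino acids, all base/sugar/phosphate N/O of the four
deoxynucleotides, water oxygen as both) bond when their distance is at
most 3.35 A and, where the donor has a covalently bonded heavy-atom
antecedent, the antecedent-donor-acceptor angle is at least 90 degrees.
Each unordered atom pair is reported once. The 3.35 A cutoff is the
midpoint of common heavy-atom D-A criteria; it is configurable, and counts
that depend on it should be read with that sensitivity in mind.

**Interface water.** A crystallographic water is an interface water when
its oxygen lies within 4.5 A of at least one protein and one DNA heavy
atom. Each interface water receives exactly one category from its
hydrogen bonds: bridging (bonded to both components), protein-only,
dna-only, water-only (bonded only to other interface waters) or none (no
bonds at all; such waters exist in real structures and would otherwise be
unaccounted for). The bridging *interaction* count is the number of
distinct protein-DNA atom pairs connected through one water, i.e. the
per-water product of protein-side and DNA-side bond counts, summed over
bridging waters; it therefore equals or exceeds the bridging water count.

**Conservation.** Entropies use the natural logarithm over the 20
amino-acid classes, with gaps excluded from the frequencies and each
homolog counted once (no sequence weighting). Absolute entropies are
therefore comparable only within one alignment; any published value from a
different alignment snapshot is a soft reference, not a target. The
alignment is user-supplied aligned FASTA whose first record is the query
(a stated convention); homologs below 30% identity to the query (computed
over mutually non-gap columns) are dropped by default. Chain residues map
onto the query row's ungapped columns in order; interface residues that
cannot be mapped are excluded from `n` with a warning.

**Secondary structure.** Per-residue assignment uses backbone dihedral
windows (helix: phi in [-100, -30], psi in [-80, -5]; strand: phi in
[-180, -40], psi in [90, 180] or [-180, -170]) rather than a
hydrogen-bond-pattern method. The interface class follows the
interface-residue fractions: alpha if `f_H >= 0.35` and `f_E < 0.10`, beta
symmetrically, alphabeta if both reach 0.10, otherwise NR (non-regular).

**Patches and projection.** Interface residues are clustered by single
linkage at 20 A between residue representatives (C-alpha for protein, C1'
for nucleotides, centroid fallback); the projection view transforms the
interface atom coordinates to their principal axes and drops the
smallest-variance axis, preserving the in-plane geometry of the binding
patch for plotting.

**Decoy ranking.** Candidates are ranked per feature in descending order
with competition ranking (ties share the better rank); the native is
"ranked #1" when it falls within the top decile of candidates, the usual
convention in decoy benchmarks. Overlap between a decoy interface and the
native one is measured residue-wise on the protein side: the fraction of
native protein-interface residues also present in the decoy's interface.
Stratified summaries remove decoys above an overlap cutoff and re-rank.

## The propensity table

The propensity values `p_i` are a trained quantity - the log ratio of
interface to surface frequencies over a curated set of complexes - and no
such training set ships with this package. Two things are provided
instead: `compute_propensity_table()`, which derives a table from any
user-supplied list of complexes by the same log-ratio procedure (with one
pseudo-count per type), and `propensity_table_synthetic()`, a bundled
synthetic table that encodes the well-known enrichment trends
(arginine/lysine and hydroxyl/amide residues positive, acidic and large
hydrophobic residues negative) for testing and demonstration. The
synthetic table is labelled as such everywhere; analyses intended for
publication should train their own.

## What the synthetic generators emulate

The test suite and benchmark run entirely on generated fixtures, built by
three deterministic generators (same seed, byte-identical output; the
caller's RNG stream is left untouched).

`make_toy_complex()` builds an idealised alpha-helical peptide by internal
coordinates (standard bond lengths and angles, phi/psi defaulting to
-57/-47) facing an idealised B-DNA-like duplex (rise 3.38 A, twist 36
degrees per base pair, planar bases with standard ring geometry, full
phosphate/sugar/base moieties) at a controlled axis separation, and plants
waters at constructed positions: bridging waters equidistant (2.8 A)
between a protein oxygen and a DNA oxygen, far waters on the opposite
face. The generator emits ground-truth labels so tests compare pipeline
output against construction. Two deliberate departures from real B-DNA:
the two strands are not base-paired (each base is rotated tangentially so
the duplex is clash-free without modelling pairing), and side chains are
truncated at C-beta except serine/threonine hydroxyls, which are built so
donor and hydrogen-bond fixtures involve real atoms. The geometry is
therefore sufficient for area, contact, hydration and counting logic, but
nothing here validates behaviour on real crystallographic detail
(alternate conformations beyond occupancy selection, modified bases,
ions, chain breaks), and passing tests should be read accordingly.

`make_synthetic_msa()` derives homologs from a query by independent
per-column substitution at specified rates, so a column's expected entropy
is a monotone function of its rate: rate 0 is perfectly conserved, rate 1
approaches alphabet-uniform. This plants conservation gradients exactly
where a test wants them, but real alignments have phylogenetic
correlation, gaps and indels that this generator does not attempt.

`make_decoy_set()` re-places the DNA rigidly against other parts of the
peptide. For a zero-overlap schedule the placement window starts beyond
the native residues' coordinate range by a safety margin (maximum atom
offset from C-alpha plus the occlusion reach of two expanded spheres, ~10.5
A) and the first placement is verified by measurement; fractional overlap
targets are solved by bisection on the measured overlap (tolerance 0.1).

## The benchmark conditions

The decoy benchmark (`decoy_benchmark()`) uses 15 independent entries of
one 64-residue helical peptide each, whose first 26 residues are the
binding site: serine/threonine-rich (planting the `Rp` and `Dp` gaps) and
strongly conserved (substitution rate 0.02, with every fifth column at 0.9
so the interface mean stays above the conserved columns and `Ncons` sits
near 0.8 of the interface size); the remaining residues are
leucine/alanine with alternating rates 0.02/0.9, which pins any decoy
interface's `Ncons` near half its size with little variance - an iid-rate
decoy region would occasionally hand many correlated decoys a high
`Ncons` through one lucky column.
The DNA binds natively over the conserved span and each entry draws 100
zero-overlap decoys. 15 x 100 keeps the full benchmark inside a few
minutes of one CPU while leaving the rank-1 criterion far from its
decision boundary. The conservation study (`conservation_recovery()`)
uses the measured core/rim split of one toy complex at a closer axis
separation (12.5 A, so that fully buried atoms - a core - actually exist)
and 100 replicate alignments at rates 0.05 (core), 0.6 (rim), 0.3
(elsewhere).

## Degenerate inputs and edge behaviour

Empty interfaces are valid results (warning, zeroed statistics); an
interface with fewer than three atoms, or collinear geometry, cannot be
projected and errors; all-gap alignment columns are undefined entropy
(`NA` with a warning) and are excluded from profile means; interface
residues that do not map to the alignment are excluded from `n` with a
warning; a water with no hydrogen bonds at all keeps category `none`
rather than being silently dropped. Alternate locations keep the
highest-occupancy conformer (ties by altloc letter); only the first MODEL
of a multi-model entry is read; modified residues (MSE and similar) map to
their parent type and stay protein atoms.

## Known limitations

* PDB input only; mmCIF is not parsed in this version.
* No explicit hydrogen placement: hydrogen-bond counts depend on the
  heavy-atom criterion and shift by a few bonds under criterion variation.
* No analytic ASA: all areas carry quadrature noise at the sub-percent
  level; thresholded counts can flip for atoms sitting exactly at a
  threshold.
* The bundled propensity table is synthetic; `Rp` values are only
  comparable across interfaces scored with the same table.
* Secondary structure from dihedral windows disagrees with
  hydrogen-bond-pattern methods at helix/strand termini.
* Local density and segment counts follow the conventions stated above;
  other programs define them differently.
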