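---
title: "Methods: scoring the disruptive potential of complex I flavoprotein variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring the disruptive potential of complex I flavoprotein variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavotriage)
```

## The model

The NDUFV1 (51-kDa) subunit of mitochondrial complex I binds the FMN at
which NADH is oxidized and ligates the 4Fe-4S cluster N3. The package's
central quantity is a **disruptive potential score** for a missense variant
in this subunit, built from three ingredients that are each cheap to obtain:

1. the minimum distance from the residue's Cα to any atom of the FMN;
2. the same distance to the nearest atom of cluster N3 (hetero residue
   `SF4`);
3. the most general nested taxonomic clade — chordata ⊂ metazoa ⊂
   eukaryota ⊂ all species — in which the residue is conserved in more than
   95% of sequences of a clade-annotated multiple sequence alignment.

Each distance is binned to even points (8 within 5 Å falling to 0 beyond
20 Å), conservation to 0–8 points by clade breadth, and the three components
are summed (0–24) and classified: ≤ 5 *none*, 6–10 *mild*, 11–15 *impaired*,
≥ 16 *strongly impaired*. The underlying assumption is that damage tracks
proximity to the two redox cofactors and evolutionary constraint, and that a
coarse, even-valued binning is as much resolution as the inputs support —
this is a triage instrument, not a calibrated pathogenicity probability.

### Boundary closures

The published description of the bins leaves the edge values ambiguous
(5/10/15/20 Å each appear in two ranges; totals 5 and 16 fall between
classes). The package fixes the unique closure consistent with the bundled
reference table: distance bins are right-open except that exactly 20 Å still
scores 2 points (`<5`, `[5,10)`, `[10,15)`, `[15,20]`, `>20`), and classes
close as ≤ 5 / 6–10 / 11–15 / ≥ 16. Two table rows pin the distance closure
(10.0 Å scores 4 points for T423M; 19.8 Å scores 2 for A117T) and the nine
rows with total 16 pin the class closure. Because all components are even,
the ambiguous odd totals are unreachable with default points anyway. Whether
a distance of exactly 20 Å "should" score 0 or 2 cannot be decided from the
printed data; the choice is configurable through `score_config()`.

The bundled table carries one internally inconsistent published label:
R147W is printed *mild* at 4 points, where the stated boundaries give
*none* (compare A341V, also 4 points, printed *none*).
`validate_reference_scores()` treats the text rule as authoritative and
reports the R147W row as a warning rather than a failure.

## Numbering schemes

Clinical variants are reported on the human precursor (target peptide
included); structure files number from the mature N-terminus; the yeast
homolog has its own numbering. All numbering is 1-based and every
`residue_map` carries explicit scheme labels, because silent off-by-20
errors are the dominant failure mode in this kind of bookkeeping. When full
sequences are available, maps are built from a global BLOSUM62 alignment
(affine gaps, opening 10, extension 1, a gap of length L costing
`10 + L`); identity uses gap-free columns as denominator and similarity
additionally counts substitution pairs with positive BLOSUM62 score. When
they are not, `human_bovine_map()` applies the constant offset of 20 —
the human target-peptide length — which the reference table exhibits at
every one of its 19 positions, and `table_yeast_map()` derives the
human-to-yeast correspondence from the table's paired variant labels.
Alignment parameters barely matter for near-full-length homolog pairs, which
is why a single default parameter set is adequate.

## Distances

`load_structure()` reads PDB or mmCIF through `bio3d`, keeps the selected
protein chain plus all hetero atoms, collapses alternate locations to the
highest-occupancy conformer, and rejects insertion codes. Cofactor atoms
are selected by hetero residue name (`FMN`, `SF4`), not element, matching
the "nearest atom of the cofactor" convention; hydrogens participate if
deposited. The intact complex contains several FeS clusters, so when a
selector matches more than one cofactor copy the default policy keeps the
copy nearest the selected chain (overridable with `copy_policy = "all"` or
a chain-restricted selector) — otherwise a cluster belonging to another
subunit could shadow N3 for surface residues. Distances are held at full
precision internally and printed to 0.1 Å, the precision of the reference
table.

## Conservation

Clade membership is cumulative: the metazoa fraction includes the
chordates, and so on, mirroring nested taxonomic ranks. "Conserved" means
identical to the reference residue; gaps and `X` count as mismatches, and
the `> 0.95` comparison is strict. Conservative-substitution conservation
was considered and rejected as the default because the score tracks
specific residues whose mutation is under study; the threshold is
configurable via `conservation_config()`. A clade with no sequences is
reported `NA` (not evaluable) and never qualifies. The 200-sequence
alignment behind the packaged conservation calls is not redistributable, so
the packaged calls are the authoritative input for score validation and the
MSA code path is exercised on synthetic alignments.

## Melt-curve analytics

The ThermoFMN assay tracks flavin release by fluorescence as temperature
ramps 1.5 °C per 30 s from 20 °C. The fit is a four-parameter logistic
(baseline, amplitude, midpoint, width); for a logistic the steepest-slope
point *is* the midpoint, so the fitted midpoint is reported as the
dissociation temperature, and the amplitude — the total intensity change —
is proportional to bound flavin, making the variant/wild-type amplitude
ratio an estimate of relative flavin content. Fitting uses `stats::nls`
(port algorithm) with deterministic starts: baseline and amplitude from the
curve extremes, midpoint from the peak of a 3-point-smoothed finite
difference derivative; bounds keep the midpoint inside the observed range
and the amplitude non-negative. Non-convergence, including curves whose
fitted amplitude is within four residual standard deviations of zero (no
transition observed), is flagged on the result rather than raised, so batch
processing can continue past failed wells. The simulator uses additive
i.i.d. Gaussian noise — standard for plate fluorimetry — and defaults to
the wild-type dissociation temperature of 51.9 °C with a 2 °C width on a
20–95 °C grid. Absorbance-slope conversion is plain Beer–Lambert:
`rate = slope / (ε · path · protein)` in µmol min⁻¹ mg⁻¹, with a sign
switch for assays monitored as falling absorbance.

## Synthetic fixtures and what passing tests show

All test inputs are generated in code. Synthetic structures are minimal
single-model PDB files with one Cα per residue and ligand atoms at
constructed coordinates (0.001 Å format precision); they validate geometry
and parsing, not protein realism. Synthetic alignments realize a requested
per-column conservation call by **exact counting** — every member of the
target clade carries the reference residue, every row outside it carries a
different one — so the realized fractions sit deterministically on the
intended side of the threshold and classifier tests cannot flake; the
generator refuses clade sizes for which a broader level could not be held
at or below the threshold. The default clade split (40 chordates, 60
further metazoans, 50 further eukaryotes, 50 others) mirrors a 200-sequence
alignment spread across the phylogenetic tree. Melt-curve tests use 50
simulated wild-type curves at 2%-of-amplitude noise and recover the mean
midpoint well within the ±0.2 °C experimental uncertainty; 100 random
synthetic structures check distances against a brute-force oracle at
1e-9 Å. These sizes keep the whole suite under a minute while leaving the
statistical checks comfortably powered. What passing does *not* show:
agreement of recomputed distances with a real crystal structure, or of
alignment identities with published figures — those need downloads and live
in `inst/integration/`.

## Known limitations

* The score is an initial-evaluation heuristic; it ignores secondary
  structure context (it underestimates variants on the structurally
  critical final Rossmann-fold helix, e.g. P252R and R257Q) and is not
  calibrated against variant databases.
* Stop gains parse but are never scored; nucleotide-level (HGVS c.)
  notation and VCF input are out of scope.
* Only NDUFV1 assets ship, though every resource (structure, chain, maps,
  MSA, bins) is injectable, so the machinery generalizes.
* Absolute flavin quantitation is out of scope; melt-curve amplitudes are
  only meaningful relative to a wild-type control measured under the same
  protocol.
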