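---
title: "glycoquant: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{glycoquant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoquant)
```

This vignette documents the scientific model behind `glycoquant`, the
parameters that matter, and the design decisions taken where more than one
reasonable choice existed.

## Mass model

A glycan composition is a multiset of residue counts over a fixed 15-slot
registry plus a flag for the M3 core (Man)₃(GlcNAc)₂. The theoretical
singly charged sodiated m/z of a reducing-end-labeled glycan is the sum of
monoisotopic residue masses, the core contribution (3 Hex + 2 HexNAc
residues), and a single constant

\[ K = m(\mathrm{H_2O}) + \Delta m(\text{label}) + m(\mathrm{Na}) . \]

For the default *O*-benzylhydroxylamine (BOA) oxime label, the net
increment is C₇H₉NO − H₂O = 105.057849 Da, giving K = 146.058184 Da. The
registry ships the residues of SALSA-derivatized serum N-glycomics: Hex
162.0528, HexNAc 203.0793, Fuc 146.0579, 3-8NeuAc 304.1270, 6NeuAc
332.1583, 3-8NeuGc 320.1219, 6NeuGc 348.1532, GlcA 217.0950 Da. SALSA
(sialic acid linkage-specific alkylamidation) amidates α2,6-linked sialic
acids with isopropylamine and α2,3/α2,8-linked ones with methylamine, so
the two linkage families differ by exactly 28.0313 Da and can be treated
as distinct residues. Only monoisotopic, singly charged [M+Na]⁺ species
are modeled; isotope patterns, multiple charging and other adducts are out
of scope. Registry, label and adduct are all loadable from plain files, so
other labels (e.g. aoWR) or glycan classes need no code change.

One terminological note: in the originating toolchain the label-mass
parameter is described as belonging to the *non*-reducing terminal,
although oxime labels derivatize the reducing terminus. The arithmetic is
unaffected (the label enters only through K); `glycoquant` calls it a
reducing-end label.

## List enumeration rules

Published rule sets for composition enumeration are only partially
specified, so the package declares its own and states it explicitly
(`default_class_rules()`):

* **Oligomannose (HM)**: 2–6 non-core Hex, nothing else.
* **Hybrid / mannose-rich hybrid**: 2–6 non-core Hex; 1–3 non-core HexNAc
  (the antennal GlcNAc, optionally a bisecting GlcNAc and/or one LacDiNAc
  GalNAc); 0–3 Fuc; acid count at most the HexNAc count. "Mannose-rich"
  labels the entries with more than 3 non-core Hex, structures that forced
  raising the non-core Hex ceiling from 4 to 6.
* **Complex (1_ant…4_ant)**: antennae *a* ∈ 1–4; non-core HexNAc is *a* or
  *a*+1 (the +1 admits one LacDiNAc branch, which is what lets HexNAc
  exceed Hex); non-core Hex (galactoses) ≤ *a*; 0–3 Fuc; acids ≤ HexNAc.

Acidic residues compete for antenna caps: NeuAc + NeuGc + GlcA ≤ 4 and
GlcA ≤ 1. Generic sialic acid counts are expanded at generation time into
all (a+1)(g+1) SALSA linkage splits. Compositions reachable from several
classes are kept once (first class in rule order), and the list is sorted
by theoretical mass; generation is fully deterministic.

Two deliberate consequences. First, the hybrid HexNAc ceiling of 3 is the
package's own reading: a strict "mono-antennary" hybrid rule cannot
generate observed serum compositions such as (Hex)5 (HexNAc)3 (Fuc)3 +
core, while an unconstrained cross-product generates biosynthetic
nonsense; antenna + bisect + LacDiNAc is the narrowest rule covering the
observed material. Second, the historical figure of 1686 entries for the
NeuGc-free human list depends on an unpublished 43-class rule set; the
default rules here give 1817 NeuGc-free entries (6333 with NeuGc), and no
attempt is made to reverse-engineer an exact historical count. Users can
always hand-edit the list CSV — it is designed to be edited.

## Annotation, clustering, quantification

**Matching.** A peak acquires every list entry within the tolerance
(default 0.2 Da, a reflectron-MALDI-scale figure; always overridable from
the plate file or the call). All isobaric candidates are kept: without
MS/MS there is no principled way to pick one, and the summary makes the
ambiguity visible instead of hiding it.

**Clustering.** Replicate spots yield near-identical peaks. Matched peaks
from all experiments are single-linkage grouped on m/z with the tolerance
as link threshold, processing peaks in ascending m/z for determinism.
Within a group each experiment may contribute at most one peak — the one
nearest the group mean; displaced peaks re-enter the linkage among
themselves and seed new clusters. Clusters are numbered densely from 1 by
ascending mean m/z (the "spectral ID"). Where no experiment contributes
two peaks to a component, this reduces exactly to connected components of
the |Δm/z| ≤ tolerance graph, which is how the tests oracle it. The
nearest-wins rule for two same-experiment peaks inside one tolerance
window is a declared choice; summing them instead would conflate resolved
signals.

**Quantification.** One-point internal-standard quantitation:
pmol = area / area(IS) × pmol(IS), with no per-glycan response factors
(none are available at this level of the analysis). The IS peak is the
peak nearest the configured IS m/z within tolerance, and it is excluded
from annotation — this matters because the default IS mass sits within
0.04 Da of a real list composition. The default IS m/z (2229.8767 Da) is
the BOA/Na mass of the disialyloctasaccharide A2GN1, computed from its
total composition (Hex)₅(HexNAc)₃(6NeuAc)₂; because A2GN1 lacks one core
GlcNAc it is itself not a valid N-glycan composition and never appears in
the list. The IS m/z is a plain config value for users with a different
standard. A missing IS peak invalidates that experiment (amounts NA),
whereas a cluster merely absent from an experiment contributes 0 pmol:
"not measurable" and "not detected" are kept distinct.

**Statistics.** Per series: arithmetic mean, sample (n−1) standard
deviation, CV = 100·sd/mean (NA for singleton series or non-positive
means). Between series: two-sided Welch t-tests on per-experiment amounts;
raw p-values by default with an optional Benjamini–Hochberg flag, since
the appropriate correction depends on how the table will be used. When
both series are constant the Welch statistic is undefined; equal means
report p = 1, unequal p = 0.

## Calibration curves and the R² filter

For calibration plates, each spectral ID gets an ordinary least-squares
line of pmol on spotted volume (µL), fitted to the individual replicate
points — not per-volume means — because the replicate scatter is exactly
what the fit quality should reflect; plots show per-volume mean ± sd error
bars on top of the points. R² = 1 − SS_res/SS_tot. The filter keeps
R² ≥ 0.8, read inclusively (the source material prints both a strict and
an inclusive form; the threshold is configurable, so the choice is purely
a default). Degenerate case: if SS_tot = 0 the response is constant; with
zero residuals the line is a perfect fit and R² reports 1, otherwise 0.
A flat response also has slope ≈ 0, so constant backgrounds do not
masquerade as quantifiable glycans by this convention.

The summary also lists **linked glycans**: detected compositions at L1
distance exactly 1 in residue-count space (one residue more or less, same
core state), with their spectral IDs in brackets. These are biosynthetic
neighbors (precursor/product candidates) and serve as a plausibility check
on attributions. **Glyconnect URLs** are built from total counts (core
folded in: Hex+3, HexNAc+2; Fuc as dHex; the two SALSA variants summed
back to generic NeuAc/NeuGc since the database indexes generic
compositions; GlcA as HexA) in the fixed segment order Hex, HexNAc, dHex,
NeuAc, NeuGc, HexA, zero counts omitted. NeuGc's position is declared for
determinism even though serum tables never exercise it. URLs are
constructed strings only; the service is never queried.

## Plate files and batch input generation

The plate workbook imitates a 384-spot MALDI target: row 1 holds common
parameters as alternating key/value cells (`is_pmol`, `tolerance_da`,
optional `protein_level`; unknown keys are carried through), rows 2–17 map
to plate rows A–P and columns 1–24 to plate columns. Spot codes:
`volume_replicate` (underscore convention) for calibration spots — the
replicate number is optional and defaults to occurrence order, since the
printed convention specifies only the underscore — and `series#label` (or
a bare series integer) for category spots. Masslist tabs correspond to
occupied spots positionally (tab *i* ↔ *i*-th occupied spot, row-major
A1→P24); an explicit `tab_map` overrides this when tab names encode
addresses differently. Generated inputs are plain CSVs (a key/value
metadata block, then `mz,area` rows), routed to `calibration_line/` or
`analysis/` under a folder named after the masslist; generation is
idempotent and byte-stable.

## Synthetic data: what it does and does not emulate

The generator (`synth_design()`, `generate_masslist()`,
`generate_plate()`) emulates the standard calibration layout — four
replicate spots at each of 2, 4, 6, 8, 10 µL — with a 12-glycan panel
spanning abundant biantennary glycans, oligomannose, mannose-rich hybrid,
GlcA-bearing and LacDiNAc compositions at 0.3–30 pmol/µL, an internal
standard at 20 pmol, and a three-part noise model: Gaussian m/z jitter
(default sd 0.02 Da), multiplicative Gaussian area noise (default CV 5 %,
a realistic MALDI replicate spread), and uniform contaminant peaks kept at
least `noise_clearance` (default 0.5 Da) away from true masses. Seeded
runs are byte-identical.

What it does **not** model: ionization suppression, detector saturation,
baseline and peak-shape effects, isotope envelopes, mass-dependent
calibration drift, or correlated noise between glycans sharing a spot.
Passing the pipeline's tests on this generator therefore demonstrates
correctness of the *computational* chain (annotation, clustering,
quantification, fitting, filtering), not robustness to every
instrumental artifact of real spectra.

## Numerical and scale choices

Test and acceptance runs use desk-scale problems chosen to exercise every
code path quickly: the full default list (6333 entries) for matching and
end-to-end runs, 20-spot calibration designs, a 384-tab workbook for the
plate-capacity check, and 8–20-point random instances for the brute-force
matching and clustering oracles. Mass comparisons use the published
precision (1 or 4 decimals) where a printed value exists and 1e-9
tolerances for internal closed-form oracles. CSV outputs round to 6
decimals; list masses are written at full precision. XLSX files are
written with fixed timestamps so identical content yields identical bytes.

## Known limitations

* Composition-level only: no topology or linkage inference beyond the
  SALSA linkage classes, and no MS/MS disambiguation of isobaric
  candidates.
* One internal standard, no response-factor correction: amounts are
  relative quantities expressed in pmol-of-IS-equivalents unless response
  factors happen to be 1.
* The enumeration rules are deliberately permissive around hybrids; rare
  compositions outside them (e.g. penta-fucosylated species) must be added
  to the list CSV by hand, which the format is designed to make trivial.
* Vendor raw spectra are not read; the instrument's XLSX peak export is
  the input contract.
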