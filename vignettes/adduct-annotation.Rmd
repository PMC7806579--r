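---
title: "Graph-based adduct annotation of ESI-MS1 spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based adduct annotation of ESI-MS1 spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adductgraph)
```

## The problem

Electrospray ionization of a small molecule rarely produces only the
protonated molecule. A single analyte can appear as `[M+H]+`, ammonium,
sodium and potassium adducts, water and ammonia losses, dimers and trimers,
and replacement series in which labile protons are exchanged for metal
cations (`[M+nNa-(n-1)H]+`, each member 21.9819 Da apart). In mixed or
flow-injection spectra these species multiply the apparent number of
analytes and hide the true `[M+H]+`. The package annotates centroided
positive-mode high-resolution MS1 spectra by linking peaks whose m/z
differences match known (and combined) ion-species relations, clustering
the linked peaks, and ranking each cluster's most plausible protonated
molecule.

## The model

Every singly charged species is represented on a protonated frame:

$$ m/z = n\,M + \delta_{\text{species}}, \qquad
   \delta_{[\mathrm{M+H}]^+} = m_H - m_e = 1.007276\ \text{Da}, $$

where $n$ is the multimer order and $\delta$ accumulates composable base
deltas computed from monoisotopic element masses: Na−H (21.9819), K−H
(37.9559), Ca−2H (37.9469), +NH$_3$ (17.0265), −H$_2$O (18.0106), −NH$_3$.
Charged adducts carry the element mass minus one electron, which
reproduces standard adduct m/z values to four decimals (e.g. trigonelline
`[M+K]+` 176.0108, proline `[M+Na+K-H]+` 176.0084). Two numerical notes:

* Ca−2H computes to 37.9469 Da from standard element masses. A value of
  37.9464 is sometimes quoted from low-precision subtraction; this package
  always derives deltas from the element table and reports the computed
  value. Either way the Ca and K readings differ by only ~9 mmu, which is
  why a 10 mmu window cannot separate them on a monomer and why flexible
  annotation sets matter.
* A +17.027 Da shift is intrinsically ambiguous: `[M+H]+ -> [M+NH4]+`
  (adduct) or, read backwards, an in-source NH$_3$ loss. The theoretical
  value 17.0265 is used for matching and such edges are bidirectional.

### Species closure

The annotation set holds a *small* list of base deltas; combinations are
expanded into a species closure up to `max_depth` (default 3) applications
per species, for each multimer order (default monomer, dimer, trimer).
Repeated application is allowed — the sodium replacement series requires
it. One restriction applies by default: at most one neutral-loss step per
combined species (`max_losses = 1`). Deeper loss chains open many windows
at low m/z and, worse, create exact compositional coincidences between
unrelated metabolites — homocitrulline minus two NH$_3$ minus H$_2$O *is*
trigonelline's elemental composition, so an unrestricted depth-3 closure
would merge their clusters on any instrument, at any mass accuracy. Users
exploring heavy in-source fragmentation can raise the budget.

### Graph construction

Each retained peak P is treated as a putative `[M+H]+` of neutral mass
`mz(P) - 1.007276`. Every other retained peak within the absolute tolerance
(default 10 mmu; ppm matching deliberately not default, matching the
constant-mmu behavior of TOF instruments in this mass range) of a closure
species' m/z receives a directed edge P → peak, labeled with the species
and the signed mass error. Adduct edges point protonated → adducted,
losses precursor → product, multimer edges monomer → multimer; pure
±NH$_3$ monomer relations become one bidirectional edge. When several
species match a pair, the smallest-|error| relation labels the edge and
alternates are retained — that is what supports the K-versus-Ca
re-interpretation workflow on replacement series.

### Clustering, ranking, indexes

Clusters are weakly connected components. Within a cluster, each peak's
*explained TIC* is the intensity sum of all peaks reachable along edge
direction (bidirectional edges traversable both ways, self included);
its *connectivity* is the number of peaks it explains by a direct
annotation, excluding itself. The candidate is the member with the largest
explained TIC, ties broken by connectivity, then lowest m/z, then smallest
summed |mass error|. Two ranking choices deserve justification:

* Connectivity counts direct annotations, not the reachable set. A
  bidirectional ±NH$_3$ pair shares its entire reachable set, so
  reachable-set size can never break the tie it creates; direct
  connectivity can, and it is what separates a protonated frame with many
  first-hop relations from an NH$_3$-loss frame that reaches the same
  peaks only through composites.
* The post-connectivity tie-break is lowest m/z, not mass error. When the
  relative-intensity filter strips a compound to
  `{[M+H]+, [M+NH4]+, [M+Na]+}`, the ammonium frame ties the protonated
  frame on TIC *and* connectivity (through the `[M+Na-NH3]+` composite)
  and the summed error then depends on instrument jitter — a coin flip.
  The lower-m/z frame reads the +17.027 partner as an ammonium adduct,
  which is far more common in positive ESI than an in-source ammonia
  loss, so that prior decides deterministically.

Singletons are never ranked (a lone peak carries no corroborating
relation) but are reported as unexplained `[M+H]+` putatives and count in
the index denominators. Each cluster gets three confidence indexes: CGC
(member count), CIC (percent of the filtered spectrum's TIC in the
cluster) and CCC (percent of the retained peak count). Across the clusters
of a spectrum CIC and CCC each sum to 100%. A "reduced from N peaks to k
candidates" summary counts ranked candidates plus singletons.

All orderings are deterministic (sorted by m/z), so identical inputs and
configuration give byte-identical outputs.

## Filters

Defaults: absolute intensity ≥ 500 cps, relative intensity ≥ 1% of the
base peak (taken after the optional m/z window — common practice; the
choice only matters when the window removes the base peak), deisotoping
for z = 1 with the 1.003355 Da ¹³C spacing and an isotope/monoisotopic
intensity ratio window of 1–100%, and monoisotopic validation, which
vetoes any candidate that could itself be a ¹³C peak of a 1.0034-Da-lower
neighbor. The ratio is always taken against the envelope's monoisotopic
peak, and a peak claimed as an isotope cannot start a new envelope; the
walk is greedy from the lightest peak, which makes it deterministic.
Multiply charged envelopes are out of scope. Removed peaks are flagged,
not deleted, so reports can show what each rule did.

## Heterodimer diagnostics

Proton-bound heterodimers (A·H⁺·B) match no single-analyte species; the
graph typically force-fits them with a conspicuous error (a
creatinine–proline dimer lands ~2.6 mmu high as `[M+Na+NH3]+` of a
co-eluting analyte). After ranking, every pair of candidates (including
singleton putatives) defines an expected peak at
$m/z_A + m/z_B - 1.007276$; retained peaks within tolerance are flagged,
with a note whether the graph had already annotated them. This is a
diagnostic only — flagged peaks are never merged into clusters, since
confirming a heterodimer needs orthogonal evidence (chromatographic
profiles).

## The synthetic generator and the reference fixtures

`simulate_spectrum()` emulates what the annotator consumes: one peak per
(compound, species) with Gaussian m/z jitter (default sd 1 mmu, matching
the ~1 mmu error spread of TOF-class LC data), multiplicative intensity
noise (CV 0.2), optional ¹³C envelopes with +1 abundance 0.011 × carbon
count (adequate for exercising the deisotoper, not for quantitation), and
uniform background peaks. Every non-noise peak carries its
(compound, species) truth. `random_compound_set()` draws compounds whose
species cannot cross-match each other's closure windows or ¹³C windows,
which is what "non-interfering" means in the recovery tests. What the
generator does *not* emulate: chromatographic peak shape, detector
saturation, correlated calibration drift, charge states above one, and
real electrospray response factors — so green recovery tests certify the
algorithm under its stated assumptions, not performance on arbitrary real
data.

Two deterministic fixtures reconstruct archetypal annotation situations
from known metabolite formulas: a 19-peak LC mixed spectrum (co-eluting
proline, trigonelline, creatinine/creatine, homocitrulline and a
heterodimer peak, clustering 7+6+5+1 with a connectivity-resolved tie at
the homocitrulline `[M+H]+`) and a 33-peak FIA proline spectrum
(replacement series to tetramers with a Ca/K near-degeneracy, clustering
13+4+2+2+2+10). Printed m/z values exist for several of these ions and
the fixtures place peaks at the corresponding observed positions (small
documented offsets ≤ 4 mmu); intensities are *solved from constraints*
(base-peak identity, the explained-TIC tie, the cluster intensity
coverages of 61/42/37/20%), so tests asserting CIC values verify fixture
construction, not independent physics — the peak-count coverages (CCC)
and the partitions are the substantive checks.

## Worked example

```{r}
ann <- annotate_spectrum(fixture_lc_mix())
ann
candidate_table(ann)[, c("candidate_mz", "cgc", "cic", "ccc")]
```

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tolerance` | 0.010 | Da | constant-mmu accuracy of high-resolution TOF spectra in the 100–600 m/z range |
| `max_depth` | 3 | steps | reproduces all replacement-series and combination species seen in practice without exploding the closure |
| `max_losses` | 1 | steps | false-positive control; see closure section |
| `multimers` | 1–3 | — | dimers and trimers are routinely observed; tetramers arise at high analyte concentration and can be added |
| `abs_intensity_min` | 500 | cps | noise floor of centroided TOF exports |
| `rel_intensity_min` | 1 | % base peak | drops background while keeping the low-intensity peaks that carry connectivity |
| `isotope_ratio_range` | 1–100 | % | a ¹³C peak cannot exceed its monoisotopic for small molecules |

## Known limitations

* Positive mode, single charge only; negative-mode sets have config slots
  but nothing is shipped.
* Compounds 18.0106 Da apart co-occurring in one spectrum are merged and
  the lighter one is annotated as a water loss — reproduced deliberately in
  the regression tests; only chromatographic profiles can resolve it.
* Shared-adduct coincidences can merge clusters of co-eluting analytes
  (an `[M+Na]+` of one compound within tolerance of a loss combination of
  another), yielding a single candidate for two real analytes.
* No likelihood scoring of annotations: the design reports all candidates
  with CGC/CIC/CCC and leaves thresholds to the analyst.

## Problem sizes used in the shipped tests

Property tests run the builder against a brute-force O(n²) oracle on 200
random spectra of up to 50 peaks, and recovery tests annotate 200 seeded
synthetic spectra of 1–5 non-interfering compounds; both finish in a few
minutes on one core, which keeps the suite practical while the oracle
remains exhaustive per spectrum.
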