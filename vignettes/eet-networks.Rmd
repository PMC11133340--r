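---
title: "Structure-based excitation energy-transfer networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based excitation energy-transfer networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eetnet)
```

## The model

Photosynthetic membrane supercomplexes hold tens to hundreds of
chlorophylls whose excited-state energy migrates to the reaction centre by
Förster resonance energy transfer. In the weak-coupling (Förster) limit
the pairwise rate is

$$k_{\mathrm{FRET}} = \frac{C\,\kappa^2}{n^4\,r^6}$$

with $r$ the donor–acceptor distance, $n$ the refractive index of the
medium, $C$ a constant absorbing the donor-emission/acceptor-absorption
spectral overlap, and $\kappa$ the mutual orientation factor of the two
transition dipoles,

$$\kappa = \hat u_D \cdot \hat u_A
  - 3\,(\hat u_D \cdot \hat R)(\hat u_A \cdot \hat R), \qquad
  \kappa^2 \in [0, 4].$$

This package evaluates that expression over every chlorophyll pair of an
atomic model, using three standard structural surrogates:

* the **pair distance** $r$ is the distance between the central Mg atoms;
* the **Qy transition dipole** $\hat u$ of each chlorin is the unit vector
  along its NB→ND ring-nitrogen axis (the sign of that axis is immaterial:
  $\kappa^2$ is quadratic in each dipole, and a property test asserts the
  flip invariance);
* the **coupling constant** $C$ is supplied, not computed. The default,
  32.26 with $n = 1.55$, parameterises chlorophyll a → chlorophyll a
  transfer; rates then come out in ps$^{-1}$ when $r$ is expressed in nm.

### Why the distance unit is nanometres

The rate formula is often quoted without units; the package makes the
choice explicit (`fret_params(distance_unit = )`) and defaults to nm
($r = R[\text{Å}]/10$). The decision is pinned empirically: published
rate/distance pairs for this class of complex (e.g. $k = 0.163$ ps$^{-1}$
at $R = 13.70$ Å) imply $\kappa^2 = k\,n^4 r^6 / C \approx 0.19$ under the
nm convention — physically admissible — whereas the Å convention would
imply $\kappa^2 \approx 1.9\times10^5$, far outside the mathematical
maximum of 4. The acceptance suite carries this argument as a test.

### Orientation-factor form

Some published methods sections print the bracket as
$[\hat u_D \cdot \hat u_A - 3(\hat u_D \cdot \hat R)]^2$, which is not
rotation-consistent (it omits the $\hat u_A \cdot \hat R$ factor and mixes
a scalar with a projection). The package implements the standard Förster
form above; its output reproduces published rate/distance pairs when the
deposited coordinates are supplied.

## Parameters that matter

| parameter | default | unit | meaning |
|---|---|---|---|
| `C` | 32.26 | — | spectral-overlap factor, Chl a → Chl a |
| `n` | 1.55 | — | refractive index of the protein medium |
| `cutoff` | 30 | Å | Mg–Mg pair cutoff, strict `<` |
| `taus` | 10, 100 | ps | lifetime thresholds of the filtered networks |
| `contact_threshold` | 5 | Å | carotenoid–chlorophyll cluster distance |
| `ligand_cutoff` | 3.5 | Å | Mg axial-ligand search radius |

The 30 Å cutoff and the 10/100 ps filters mirror the conventions used when
such networks are reported alongside structures; 5 Å is the customary
"short contact" threshold for carotenoid–chlorophyll clusters. No
published convention exists for the axial-ligand radius; 3.5 Å is the
upper end of Mg–N/O coordination distances and is configurable. Networks
default to chlorophyll a only (`pair_selector = "chl_a_only"`), because
the default `C` is specific to that pairing; `all_chl` is available but
applies the single supplied `C` to every pair.

## Extraction rules

* Alternate locations are resolved per residue: the conformer with the
  highest mean occupancy wins, ties go to the lexicographically smallest
  altloc id. This makes re-reading a file byte-deterministic.
* A chlorophyll residue must carry Mg, NB and ND atoms; residues missing
  any of them are skipped with a warning and tabulated in
  `inventory$skipped` rather than aborting a 200-pigment extraction.
* Chemical-component codes are data, not code: only `CLA` (chlorophyll a),
  `KC1`/`KC2` (chlorophylls c) and the thylakoid lipid codes are assumed
  globally; carotenoid codes vary by deposition and come from a per-accession
  JSON profile, as does the chain → subunit naming map.
* Waters and ions stay in the `structure_model` (they are axial-ligand
  candidates) but are never census-counted.
* Shortest-contact calculations drop the chlorophyll phytol tail
  (atom names `C1`–`C20`) by default, matching how pigment contacts are
  conventionally reported; `include_phytol = TRUE` restores them.
* Polar contacts are a heavy-atom N/O distance proxy (default 3.5 Å) with
  no angle term: cryo-EM models at typical resolution carry no hydrogens,
  and reported hydrogen-bond distances are heavy-atom–heavy-atom.

## Stromal/lumenal layer classification

Chlorophylls of membrane antennas arrange into two sheets parallel to the
membrane. `classify_layers()` must therefore estimate the membrane normal
and split the Mg projections in two.

The obvious estimator — the smallest-eigenvalue eigenvector of the Mg
covariance matrix — is biased at realistic sample sizes: the two-sheet
separation inflates the variance along the normal, and finite-sample
cross-covariance between the (wide) in-plane spread and the (narrow)
normal spread tilts the eigenvector. A tilt of even 0.1 rad leaks tens of
Å of in-plane scatter into the projections and can swamp a 15–20 Å sheet
gap; on seeded two-sheet fixtures the naive estimator recovered the
planted partition in only about half the runs. The package instead scans a
deterministic 300-point Fibonacci hemisphere for the axis minimising the
*two-parallel-planes objective* — the within-cluster sum of squares of the
one-dimensional 2-means split of the projections — and then polishes the
winner to a fixed point against the pooled within-layer covariance (which,
unlike the global covariance, contains no between-sheet term). Both stages
are deterministic: 2-means is a Lloyd iteration with centres initialised
at the extreme projections and ties assigned to the lower cluster. A
degenerate spread along the normal (all Mg effectively coplanar) raises a
classification error. Passing an explicit `axis` bypasses the estimate.

Which layer is *stromal* is annotation, not geometry: sidedness comes from
knowledge such as where the extrinsic lumenal subunits sit. Without a
`stromal_direction` hint the layers are labelled `layer1`/`layer2` with a
warning.

## The synthetic-data generator

`fixture_spec()` + `make_fixture()` write minimal legal mmCIF/PDB files
realising a declarative placement list, together with analytic ground
truth (census, closed-form FRET edges via `analytic_rate()`, planted layer
membership). Design choices:

* Each chlorophyll becomes Mg plus NB/ND nitrogens at ±1 Å along the
  requested dipole, so the reconstructed NB→ND axis realises the planted
  direction exactly; 2 Å is within a real chlorin's N–N scale.
* Chlorophylls reuse the real component codes so the default code map
  applies; the fixture carotenoid codes (`ALX`, `ACA`, `CRX`, `MND`) are
  synthetic stand-ins and are labelled as such.
* mmCIF coordinates are written at 13 decimals — effectively lossless — so
  the full file → inventory → network route matches the closed-form oracle
  to 1e-9 relative. PDB output is bound to 3 decimals by its fixed
  columns (0.0005 Å worst case per coordinate).
* Seeded Gaussian noise is applied to written coordinates only *after* the
  ground truth is computed, and only layer fixtures use it (their planted
  partition is noise-robust); census/edge fixtures stay exact. Identical
  spec + seed gives a byte-identical file.
* `two_layer_spec()` scatters its sheets over a 60 Å in-plane extent by
  default — roughly the membrane patch that 17 chlorophylls occupy at
  realistic in-plane Mg spacings — wide enough that the in-plane variance
  dominates the normal variance, as in a real membrane complex.

What the generator does **not** emulate: complete chlorin rings or phytol
tails, protein fold context, B-factors/occupancy disorder, or a real
spectral overlap. A green fixture test therefore establishes the geometry
and bookkeeping of the pipeline — dipole reconstruction, the rate law,
cutoffs, layer logic, serialisation — but says nothing about the physical
accuracy of the point-dipole approximation or of `C` for a particular
pigment pair.

## Numerical conventions

* Cutoffs are strict: an edge needs `R < cutoff`, a filtered edge needs
  `lifetime < tau` (rate `> 1/tau`).
* Edges are undirected with a single rate; with one `C`, forward and
  backward rates are equal, and the symmetry is asserted exactly.
* A rate of zero (orthogonal geometry) yields an `NA` lifetime, not `Inf`.
* Coincident dipole origins, zero-length direction vectors and degenerate
  layer projections raise typed errors naming the offending site.
* JSON network exports carry 17 significant digits, so
  `import_network_json()` restores every numeric field bit for bit;
  GraphML export goes through igraph.
* The whole pipeline is deterministic — the only randomness anywhere is
  the seeded fixture noise.

## Comparing against published values

`run_pipeline()` accepts an *expectation set*: a JSON file of
`{id, quantity, selector, expected, tolerance}` records (census counts,
FRET rates, Mg–Mg distances, contact distances, layer counts, polar
distances). Published numbers live in such files — versioned, citeable
data, not code — and the comparison report states each deviation. When a
selector matches several structural copies (the two halves of a C2 dimer),
the copy closest to the expected value is scored, because refined models
are never exactly symmetric. The shipped
`extdata/expectations/8wb4_reported.json` encodes the printed reference
values for PDB entry 8WB4 at their printed precisions (rates ±0.01
ps$^{-1}$, Mg–Mg ±0.02 Å, contacts ±0.1 Å); running it requires a local
copy of those coordinates plus a completed accession profile, neither of
which the test suite needs or fetches.

## Known limitations

* The point-dipole approximation degrades below ~10 Å separation, exactly
  where rates are largest; computed rates there are indicative, not
  quantitative.
* `C` is a constant per network; heterogeneous pairings (chlorophyll c,
  carotenoids) need externally supplied couplings, and no spectral overlap
  is computed from spectra.
* No excitonic delocalisation, coherence, or kinetic propagation: the
  output is a rate graph, not a dynamics simulation.
* Layer sidedness requires an orientation hint (see above).
* The polar-contact screen is distance-only and will happily report
  non-bonding N/O pairs at 3.4 Å; it is a shortlist generator, not a
  hydrogen-bond validator.
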