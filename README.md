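# eetnet

Excitation energy-transfer (EET) networks from the atomic structures of
photosynthetic pigment–protein supercomplexes.

Light harvested by the chlorophylls of a membrane antenna migrates to the
reaction centre by Förster resonance energy transfer (FRET). Given an
atomic model (mmCIF or PDB) of a supercomplex — for example a photosystem II
dimer with its membrane-intrinsic antenna subunits — `eetnet` extracts the
pigment cofactors and answers the structural questions that define the
energy landscape:

* which chlorophyll pairs exchange energy fast, and along which pathways
  (the FRET rate network, with 10 ps / 100 ps lifetime filters);
* how many pigments and lipids of each kind the model contains (census);
* how the chlorophylls split into the stromal- and lumenal-side membrane
  layers;
* which carotenoids sit close enough to chlorophylls (< 5 Å) for energy
  transfer or triplet quenching;
* what ligates each chlorophyll's central Mg, and which polar contacts
  stitch the subunit interfaces together.

## The rate model

For a donor/acceptor chlorophyll pair the transfer rate is the point-dipole
Förster expression

```
k_FRET = C κ² / (n⁴ r⁶)
```

* `r` — distance between the two central Mg atoms, in **nanometres**
  (`r = R[Å]/10`);
* `κ = û_D·û_A − 3(û_D·R̂)(û_A·R̂)` — the standard orientation factor,
  `κ² ∈ [0, 4]`, with the Qy transition dipole `û` of each chlorin taken
  along its NB→ND ring-nitrogen axis and `R̂` the unit Mg→Mg vector;
* `C = 32.26` — an overlap-integral factor for chlorophyll a → chlorophyll a
  transfer (treated as an opaque constant; supply your own for other
  pairings);
* `n = 1.55` — refractive index of the protein medium.

With these defaults the rate is in ps⁻¹ and edges are built for every
chlorophyll-a pair with Mg–Mg distance strictly below 30 Å. The nm
convention is pinned by a unit-consistency test: published rate/distance
pairs only admit a physical κ² (≤ 4) under it.

## Worked example

Everything is testable without any deposited structure: the synthetic
fixture generator writes a minimal legal mmCIF file and the matching
analytic ground truth.

```r
library(eetnet)

spec <- fixture_spec(list(
  chl_placement("A", 601, c(0, 0, 0),   c(0, 0, 1)),
  chl_placement("A", 602, c(10, 0, 0),  c(0, 0, 1)),
  chl_placement("A", 603, c(10, 14, 0), c(1, 0, 0)),
  carotenoid_placement("A", 615, c(3.5, 0, 0), c(0, 1, 0))))
path  <- tempfile(fileext = ".cif")
truth <- make_fixture(spec, path)$truth

inv <- extract_pigments(read_structure(path), fixture_code_map())
pigment_census(inv)
#> <census_table>
#>   CHL_A  3
#>   ALX    1
#>   pigments 4, lipids 0

net <- build_network(inv)
net$edges[, c("donor_label", "acceptor_label", "R", "kappa_sq", "rate", "lifetime")]
#>   donor_label acceptor_label        R kappa_sq     rate  lifetime
#> 1      a601_A         a602_A 10.00000        1 5.589045 0.1789215
#> 2      a602_A         a603_A 14.00000        0 0.000000        NA
#> 3      a601_A         a603_A 17.20465        0 0.000000        NA

nrow(lifetime_filter(net, 10)$edges)   # edges faster than 10 ps
#> [1] 1

contact_map(inv, threshold = 5)[, c("label_a", "label_b", "min_distance")]
#>    label_a label_b min_distance
#> 1 Alx615_A  a601_A          3.5

analytic_rate(spec$placements[[1]], spec$placements[[2]])$rate
#> [1] 5.589045
```

The first pair sits 10 Å apart with parallel dipoles perpendicular to the
separation (κ² = 1), so `k = 32.26 / 1.55⁴ ≈ 5.589 ps⁻¹` — and the
file-independent closed-form oracle agrees. The other two pairs have
orthogonal dipole geometry (κ² = 0): geometry, not just distance, decides
the network.

For a full run (census + networks + contacts + ligands + layers + report):

```r
cfg <- run_config(structure = "model.cif",
                  profile = system.file("extdata", "profiles", "fixture.json",
                                        package = "eetnet"),
                  taus = c(10, 100), out_dir = "out")
report <- run_pipeline(cfg)
```

or from the shell via the installed CLI script:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "eet.R", package = "eetnet"))') \
    run --structure model.cif --out out
```

Analysing a deposited entry (e.g. PDB 8WB4) needs an accession profile
mapping its chemical-component codes and chain ids to pigment kinds and
subunit labels — see `inst/extdata/profiles/8wb4_template.json` — plus the
published reference values shipped in
`inst/extdata/expectations/8wb4_reported.json`, which `run_pipeline()`
compares against automatically when passed as `expectations`.

## Scope

No excitonic/quantum-coherent treatment, no spectral-overlap computation
(C is a constant), no kinetic master equations, no structure refinement or
map handling, and no remote fetching inside library code. See
`vignettes/eet-networks.Rmd` for the model assumptions, parameter choices
and known limitations.
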