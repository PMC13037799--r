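---
title: "Methods: mesh phantom engineering and kerma-mode photon dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mesh phantom engineering and kerma-mode photon dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Organ doses from external irradiation are evaluated with computational
human phantoms coupled to radiation transport codes. Voxel phantoms built
from ~1 mm tomographic data cannot represent micrometre-scale
radiosensitive targets (the 50–100 µm basal cell layer of the skin, the
anterior sensitive region of the eye lens), and their rasterized membranes
leave holes through which the tissue beneath is exposed directly to the
surface field. Polygon-mesh phantoms solve both problems but bring their
own engineering burden: meshes must be watertight, free of
self-intersections, mass-matched to population reference values, layered
into sensitive sub-regions, and converted to the tetrahedral or voxel
representations transport codes consume. `phantomdose` implements that
tool chain plus a desk-scale photon transport and the dose bookkeeping
that turns tallies into protection quantities.

# The dose model

## Transport

`run_transport()` performs analog Monte Carlo photon transport on a voxel
raster under an AP (anterior-to-posterior, +y) uniform parallel beam whose
rectangular field covers the phantom bounding box, so all results are
normalized per unit incident fluence (pGy·cm² for absorbed dose).

* **Tracking** is Woodcock delta-tracking: free paths are drawn against a
  global majorant `µ_maj(E) = max over materials µ_tot(E)`; collisions in
  a voxel with `µ_tot < µ_maj` are accepted with probability
  `µ_tot/µ_maj`, otherwise virtual. This removes all ray/boundary
  geometry from the kernel and is unbiased for any raster.
* **Channels**: photoelectric (full local absorption), incoherent
  scattering sampled from the exact free-electron Klein–Nishina
  distribution (rejection sampling in `x = E'/E` with envelope `x + 1/x`),
  and pair production (local deposit of `E − 1.022 MeV`, two 0.511 MeV
  annihilation photons emitted isotropically back-to-back). Coherent
  (Rayleigh) scattering is omitted: it transfers no energy and its angular
  redistribution is irrelevant at the accuracy this desk-scale model
  targets; this is a documented difference from full production codes.
* **Kerma approximation**: all charged-particle energy deposits at the
  interaction site; no electron transport. Photons below the 1 keV cutoff
  deposit their residual energy locally, so each batch conserves energy
  exactly (`injected = deposited + escaped` to accumulation precision, a
  tested invariant).
* **Fluence** is tallied with the delta-tracking collision estimator
  (score `1/µ_maj` at every real or virtual collision), binned in
  logarithmic energy bins (20 per decade, top edge at the source energy).
* **Reproducibility**: each batch runs on R's RNG seeded with
  `seed + batch − 1`; identical inputs give bit-identical tallies.

## Interaction data

No evaluated photon data library is bundled. The packaged elemental
tables (`elemental_photon_tables()`, shipped as
`mu_elemental_synthetic.tsv` and labelled synthetic) are an analytic
stand-in: exact Klein–Nishina incoherent coefficients; a
`Z^4.5/(A E^3)` photoelectric parameterization calibrated to water at
0.01 MeV; and a `Z²/A` pair term calibrated to water at 10 MeV. The mass
energy-absorption coefficient is constructed to be *exactly consistent
with the kernel's deposition rules*:

```
µ_en/ρ = µ_pe/ρ · 1  +  µ_inc/ρ · f_tr(E)  +  µ_pair/ρ · (E − 1.022)/E
```

with `f_tr(E)` the Klein–Nishina mean transferred fraction by quadrature.
Consequently the thin-target kerma identity
`D = Φ E (µ_en/ρ) c` holds in expectation inside the model, and the test
suite verifies transport against these same packaged tables (slab
transmission `e^{−µt}`, thin-slab kerma, estimator consistency). Absolute
agreement with evaluated data is *not* claimed: photoelectric values for
high-Z constituents (Ca, I) can deviate by tens of percent. Every
energy-dependent conclusion in this package is therefore internal-
consistency or trend-level, which is exactly how the tests use it.

## Bone component doses

Homogenized bone regions mix hard bone, active and inactive marrow and
endosteum (`homogenize_region()`: mass-weighted elemental fractions,
harmonic-mean density). Because the components are not geometrically
resolved, the dose to the active marrow or endosteum of anatomical region
`a` is estimated from the in-region fluence spectrum:

```
ED_a = M_a · Σ_bins Φ_a(E) (µ_en/ρ)_component(E) E        [MeV]
D_a  = ED_a · c / M_a                                      [Gy]
```

with `c = 1.602176634e-13 J/MeV`. The component mass cancels, as the
closed form implies — the dose depends only on the spectrum and the
component's own µ_en/ρ (the pure-component coefficient by default,
configurable). At and above 1 MeV this kerma weighting overestimates, so
the dose switches to mass-proportional partition of the region's total
deposited energy, which makes the mass-specific dose identical across
components: `D = ED_region·c/M_region`. The two routes are tested for
consistency on a homogeneous bone-mixture block at exactly 1 MeV.
Whole-body marrow/endosteum doses are mass-weighted means over the
packaged 20-region inventories.

Below ~0.2 MeV, secondary-electron equilibrium does not hold in real
trabecular bone and photoelectrons emitted from bone trabeculae enhance
marrow dose; this enhancement is intentionally outside the model, so
low-energy marrow/endosteum doses carry the corresponding bias.

## Effective dose

Equivalent dose uses `w_R = 1` for photons and electrons. Effective dose
is the ICRP-103 sex average `E = Σ_T w_T (H_T^male + H_T^female)/2`, with
the remainder tissue evaluated as the arithmetic mean over the packaged
13-member remainder list per sex before averaging; gonads map to testes /
ovaries and the prostate/uterus pair enters the remainder. The weight
table is editable config (`tissue_weighting()`), since available regions
differ between phantoms.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| skin full thickness | 1.28 (male) / 1.13 (female) | mm | reference whole-skin depth matching adult-Japanese average skin mass |
| basal sensitive layer | 50–100 | µm | depth window of the radiosensitive basal cell layer |
| eyeball / lens mass targets | 15 g, 0.4 g (male); 12 g, 0.3 g (female) | kg | adult-Japanese average masses; generator scales meshes to hit them |
| voxel pitch | 0.98 × 0.98 × 1.0 | mm | canonical tomographic raster; fully configurable, anisotropic allowed |
| transport cutoff | 0.001 | MeV | below it residual energy deposits locally |
| fluence bins | 20 per decade | – | Eq.-type spectrum integration accuracy vs memory |
| high-energy threshold | 1.0 | MeV | switch from spectrum estimator to mass partition |
| c | 1.602176634e-13 | J/MeV | MeV→J; CODATA value |
| beam energy range | 0.01–20 | MeV | validated source-energy range |

# The synthetic phantoms: what a green test establishes

`make_layered_body()` emulates the *structure* of a layered mesh phantom,
not its anatomy: an ellipsoid with a watertight skin shell, the 50–100 µm
basal sublayer, a sub-skin "breast-analog" layer and a homogenized bone
slab. `make_stylized_eye()` provides a spherical eyeball with an
anterior-placed lens split at its equator into sensitive (anterior) and
insensitive (posterior) halves, both scaled to the printed mass targets.
Everything is deterministic (pure functions of the spec; the only seeds
are in transport and skin perforation).

The breast-analog deserves a note. Its purpose is the enclosure
experiment: voxel skins cannot enclose the body, so the tissue just below
the skin sits at the surface in raster holes and sees the unshielded
field. A tangent sphere under the skin has near-zero contact area and
raster holes almost never expose it, which would make the effect
unmeasurable for geometric rather than dosimetric reasons; the
breast-analog is therefore a 5 mm sub-skin shell immediately beneath the
skin, and `make_perforated_voxel_skin()` reassigns a seeded fraction of
skin voxels to the tissue directly beneath (stepping inward along the
dominant axis toward the centroid).

What the stylized phantoms do **not** emulate: real organ shapes and
locations, heterogeneous bone microstructure, posture, or body-size
variation. A green trend test therefore establishes that the *mechanism*
(shielding by an intact shell; short mean free paths elevating shallow-
layer dose; depth ordering of anterior/posterior lens dose) operates in
the code with the right sign and a defensible magnitude — not that any
published dose coefficient is reproduced. Published magnitudes depend on
the full anatomical phantoms and a production transport stack and are out
of scope by design.

# Numerical choices

* **Offsets**: shell layers move vertices inward along angle-weighted
  vertex normals, preserving connectivity so nested layers share surfaces
  exactly (layer additivity `(d0,d1)+(d1,d2)=(d0,d2)` is exact). A layer
  whose inner offset collapses the surface errors out. Concave creases
  are handled by the angle weighting alone; there is no post-offset
  remeshing.
* **Tetrahedralization**: no constrained Delaunay mesher is bundled.
  Star-shaped leaf regions are centroid-fanned (exact volume); a parent
  enclosing exactly one child with identical mesh connectivity (offset or
  concentric copies — all generated phantoms) is decomposed into prisms
  coned from their centroids, with boundary quads split by a
  min-vertex-id diagonal rule so neighbouring prisms tile without gaps.
  Other nesting configurations raise an error instead of guessing.
* **Voxelization** classifies voxel centers by z-column crossing parity
  with a tiny deterministic center offset (~1e-7·pitch) so rays through
  mesh edges cannot double-count; regions are painted in decreasing
  volume order so the innermost nested region wins ties (thin shells
  survive coarse pitch).
* **Degenerate tets** (< 1e-9 cm³) are kept and flagged, excluded only
  from volume sums.
* **Spectrum integration** defaults to the log-midpoint rule on the tally
  grid. A monoenergetic source line sits at its bin's *top edge*, so the
  midpoint rule biases single-line spectra by ~4 %; the tally therefore
  also records track-length-weighted mean energies per bin
  (`tally$bin_energies`), which remove that bias and are used in the
  consistency tests.
* **Ratio reporting** uses half-up rounding at two decimals, matching the
  printed mass-ratio convention (`mass_ratio()`).
* **Orientation**: inward-wound surfaces are auto-corrected and flagged,
  never rejected.

# Known limitations

* **No electron transport.** The kerma approximation cannot reproduce
  effects driven by secondary-electron buildup. Concretely: the published
  inversion of skin sensitive-layer vs whole-skin dose above ~0.4 MeV
  does not occur in this model (collision kerma varies by only a few
  tenths of a percent across a 1.3 mm skin at 2 MeV); the corresponding
  acceptance sub-test is deliberately left failing rather than weakened,
  and the low-energy half of the same criterion (short mean free paths
  elevating the basal-layer dose at 0.01 MeV) passes strongly.
* **Synthetic interaction data** (see above): trends and internal
  consistency, not evaluated-library accuracy.
* **No Rayleigh scattering**, no bound-electron (Doppler/ incoherent
  function) corrections, no fluorescence: photoelectric absorption is
  total and local.
* **Bone microstructure** is homogenized; low-energy photoelectron dose
  enhancement to marrow/endosteum is excluded by construction.
* `tetrahedralize()` intentionally refuses geometry it cannot decompose
  exactly; arbitrary nested soups need an external constrained mesher.
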