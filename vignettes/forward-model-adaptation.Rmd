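---
title: "Mesh optimization and analytic Jacobian rescaling for Monte Carlo optical tomography"
author: "mmcadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesh optimization and analytic Jacobian rescaling for Monte Carlo optical tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem this package addresses

Fluorescence molecular tomography (FMT) reconstructs the 3-D distribution
of a fluorophore's effective quantum yield $\eta(r)$ inside tissue from
boundary measurements.  The forward model links $\eta$ to the detected
time-resolved fluorescence through a sensitivity (Jacobian) matrix:

$$U_F(r_s, r_d, t) \;=\; \int_\Omega W(r_s, r_d, r, t)\, \eta(r)\, dr,$$

where $W$ is built from time-dependent Green's functions of the excitation
($G^x$, launched at the source) and emission ($G^m$, launched adjointly at
the detector) light, convolved with the fluorophore's exponential lifetime
decay:

$$W(r_s, r_d, r, t) = \int_0^t e^{-(t-t')/\tau}\, dt' \int_0^{t'}
G^x(r_s, r, t'-t'')\, G^m(r, r_d, t'')\, dt''.$$

When the Green's functions come from mesh-based Monte Carlo (mMC)
transport — the gold standard where the diffusion approximation fails
(thin or low-scattering tissue, early time gates) — the cost of building
$W$ scales with the number of photons, and the *statistical* quality of
$W$ at a node scales with how many photons visit that node's volume.
Uniform fine meshes therefore waste photons: elements midway between the
optodes are visited rarely and carry the worst statistics.

The remedy implemented here is to adapt the mesh to the forward model —
coarsen where sensitivity or photon visitation is low — and, crucially,
to *rescale the already-computed Jacobian analytically* onto each adapted
mesh instead of re-running the Monte Carlo at every iteration.

## The Monte Carlo transport kernel

`propagate()` traces weighted photon packets through a conforming
tetrahedral mesh by straight-segment ray/face traversal (compiled code,
single-threaded, bit-reproducible for a fixed seed).

* Step lengths are sampled as $-\ln \xi / \mu_t$ with
  $\mu_t = \mu_a + \mu_s$ and $\mu_s = \mu_s' / (1 - g)$.
* At each interaction a fraction $\mu_a/\mu_t$ of the packet weight is
  absorbed.  The absorbed weight is converted to fluence by dividing by
  $\mu_a$ and the nodal volume share (one quarter of the incident element
  volumes), i.e. an absorption estimator rather than a track-length
  estimator; the two are interchangeable in expectation, and the
  absorption estimator keeps the traversal loop simple.  The deposit is
  spread over the containing element's four nodes by the barycentric
  coordinates of the interaction point, because the Jacobian is nodal.
* Scattering angles follow the Henyey–Greenstein phase function
  (`sample_hg_cosine()` exposes exactly the kernel's inversion formula);
  azimuth is uniform.
* The external boundary applies unpolarized Fresnel reflection against
  air ($n = 1$); total internal reflection is handled.  The launch is a
  collimated pencil beam with no specular loss at entry.
* Russian roulette below weight $10^{-4}$ with survival probability 0.1
  (standard MCML values).  Roulette boosts survivors by $1/0.1$; the
  kernel therefore reports separate weight buckets (`deposited`,
  `exited`, `killed`, `expired`, `lost`, `boosted`) whose signed sum
  equals the launched weight exactly up to round-off —
  `conservation_residual()` checks this identity.
* Time of flight advances by path $\times\, n/c$ with
  $c = 0.299792458$ mm/ps; packets outliving the gated window are
  terminated (`expired`).

Units are mm, mm$^{-1}$ and ps throughout; literature values in cm$^{-1}$
are converted at construction (`optical_properties(..., unit = "cm")`).

Default gating is 50 ps $\times$ 40 gates (0–2 ns).  The gate width is a
free parameter of `time_gating()`; 50 ps resolves the rise of a
transmission TPSF through a few millimetres of tissue while keeping the
per-gate photon statistics workable at desk-scale photon budgets.

## Jacobian assembly

`assemble_jacobian()` discretizes both temporal integrals with
left-endpoint Riemann sums at $\Delta t$ equal to the gate width.  This
choice is deliberate and documented so that the brute-force triple-loop
oracle in the test suite matches the implementation to $10^{-12}$ rather
than "approximately".  No $1/\tau$ normalization is applied to the decay
kernel: the kernel is the pure exponential $e^{-t/\tau}$, so the
time-integrated Jacobian grows with $\tau$ (a property the tests assert).
`forward_tpsf()` closes the loop with
$U_F[k] = \sum_r W[k, r]\, \eta(r)\, V(r)$, using the same nodal volume
shares as the fluence estimator.

## Solution fields and the size field

Seven per-node fields can drive adaptation
(`compute_solution_field()`): the Jacobian row sum, its log, the
per-row-normalized sum, a curvature metric
$u_i = S_i - \frac{1}{n-1}\sum_{j \ne i} S_j$ (the dense operator with 1
on the diagonal and $-1/(n-1)$ off it, which annihilates constants), the
log of the curvature's positive part, the minimum distance to any
optode, and the Beer–Lambert attenuation $e^{-\mu\,d}$ of that distance.
The distance field coarsens *high* values; all others coarsen *low*
values.  The attenuation coefficient $\mu$ defaults to
$\mu_a + \mu_s'$ — the transport attenuation scale — and is exposed as a
free parameter since either the scattering or the reduced-scattering
coefficient is a defensible choice.

`to_size_field()` converts a field to per-node size factors using two
thresholds: $T_{lo} = 0.2 \times \mathrm{median}$ and
$T_{hi} = 8\,T_{lo}$ by default.  Values below $T_{lo}$ receive the
maximum size factor, above $T_{hi}$ the minimum, and in between the
exponential map

$$y(x) = \mathit{sf}_{max}\,
 \left(\tfrac{\mathit{sf}_{min}}{\mathit{sf}_{max}}\right)^{\frac{x - T_{lo}}{T_{hi} - T_{lo}}}$$

is used.  The constants of the exponential are pinned by requiring
continuity with the clamped plateaus at both thresholds: any other
exponential would jump at $T_{lo}$ or $T_{hi}$ and produce discontinuous
size fields.  Log-family fields can have a nonpositive median, which
makes the thresholds cross; this is precisely the instability that makes
those fields fragile in practice, and the package raises a diagnostic
error by default (`fallback = "shift"` opts into a shift-to-positive
rescue).

## Mesh adaptation

Only edge collapses (coarsening) and edge splits (refinement) are
implemented.  These two local operations span the coarsen/refine space
for isotropic size fields; face and region operations would add
implementation surface without changing what the size field can express.

The semantics of the size factor deserve explanation, because it is the
one place where the package had to make a genuine design choice.  A size
factor is *relative*: 1.25 at a node means "edges here should become
about 25% longer".  If the target of an edge is defined against the
*current* mesh at every iteration, the factor compounds without bound —
in experiments this produced runaway coarsening into degenerate
50 mm$^3$ elements and no convergence.  The package therefore measures
size factors against a per-node **reference length scale** `h_ref`: the
mean incident edge length of the *initial* mesh, carried through the
loop (a collapse keeps the kept node's value, a split midpoint averages
its parents).  An edge's target length is
$\mathrm{mean}(\mathit{sf}) \times \mathrm{mean}(h_{ref})$ of its
endpoints.  One adaptation loop then applies the size field once, in the
sense that a converged mesh has edge lengths close to
$\mathit{sf} \times h_{ref}$ — the standard absolute-metric reading of
"adapting the mesh to fit a size field" — and larger maximum size
factors yield strictly coarser converged meshes, which is the trend that
matters for choosing the factor.

Within a pass (`adapt_once()`):

* collapse candidates are edges with mean factor $> 1$ whose
  current/target ratio is below `collapse_ratio` (default 1: any edge
  shorter than its target), processed most-undersized first with ties
  broken on node indices;
* split candidates are edges with mean factor $< 1$ and ratio above
  `split_ratio` (default $\sqrt 2$), longest first;
* each accepted operation freezes its cavity's nodes for the rest of
  the pass, which keeps passes local, bounded and deterministic.

A collapse must pass a battery of guards: no surviving element may
invert or fall below the mean-ratio quality floor (default 0.02); the
merged cavity may not create duplicate elements or faces shared by more
than two elements; new edges at the kept node may not overshoot
$\sqrt 2 \times$ their target; and the cavity volume must be conserved —
exactly (to $10^{-7}$ relative) for interior collapses, and to
$10^{-9}$ of the total mesh volume for boundary collapses, which
restricts boundary merging to coplanar surface patches and thereby
preserves the domain shape.  A boundary node may only merge into another
boundary node along an edge of the boundary surface; merging the
boundary into the interior is always rejected.  Total volume drift over
a whole adaptation loop is bounded by these guards at well under the 2%
the test suite asserts (in practice it is zero on the phantoms shipped
here).

`adapt_loop()` iterates passes, recomputing the solution field on each
new mesh — from the analytically rescaled Jacobian for sensitivity
recipes, from geometry for the distance/attenuation recipes — and stops
at convergence (a pass changes neither node nor element count), at a
maximum-element-volume cutoff, or at `max_iterations` (default 30).

## The transformation matrix

`build_transformation()` produces the sparse input-nodes $\times$
output-nodes operator $T$.  Each output node is classified:

1. **carried** — an input node within $10^{-9} \times$ the bounding-box
   diagonal: a unit column.  (Collapses never move surviving nodes, so
   after pure coarsening almost every column is carried and the rescaled
   Jacobian is exact at surviving nodes.)
2. **interior** — inside an input element: the four vertices are
   weighted by inverse distance $w_i = 1/d(x, x_i)$, normalized.
3. **exterior** — outside the input mesh: the four nearest input nodes
   (exact scan, ties to the lowest index), same weights, with no
   distance cap.

Every column sums to one, so constants are preserved exactly, rescaled
values stay within the convex hull of the inputs for interior columns,
and compositions of transformations equal sequential application to
$10^{-12}$ — all properties the test suite asserts literally.
Inverse-distance weighting is the primary method; linear shape-function
(barycentric) interpolation is available as an explicitly flagged
comparison mode (`method = "barycentric"`), not the default.
`rescale_jacobian()` right-multiplies every (pair, gate) slice by $T$.

## Accuracy metrics

`tpsf_error()` gives per-gate percent errors (zero-reference gates
masked), `nodal_error()` the per-node percent deviation
$e(r) = |v - v_{ref}|/|v_{ref}| \times 100$ with zero-reference nodes
excluded and counted, and `central_node_set()` selects the nodes around
the source–detector midpoint — the region of worst statistics — with a
default radius of 15% of the pair separation — a choice that captures
the mid-plane neighborhood of worst statistics without touching the
optodes.  Reference Jacobians at desk
scale use $10^6$–$10^7$ photons; the photon budget is recorded in the
report metadata because $e(r)$ is only meaningful relative to its
reference's own noise floor.

## Synthetic phantoms

`make_slab_mesh()` builds a conforming structured slab (each grid cell
split into six tetrahedra); its volume is exact, which anchors the
volume-conservation tests.  `make_slice_phantom()` emulates a thin
cross-sectional slice of a small-animal torso: an extruded ellipse
(defaults: semi-axes 12 and 8 mm, 4 mm thick, 1 mm edges, about 2 300
nodes and 10 000 elements) with 7 sources and 7 detectors on opposing
perimeter arcs in transmission geometry, and homogeneous optical
properties typical of mouse tissue in the near infrared
($\mu_a = 0.3\ \mathrm{cm}^{-1}$, $\mu_s' = 15\ \mathrm{cm}^{-1}$,
$g = 0.9$, $n = 1.37$).  Fixture generation is fully deterministic.

What the phantoms deliberately do *not* capture: anatomically realistic
geometry, heterogeneous per-organ optical properties (the methodology is
validated under the homogeneous assumption standard in normalized-Born
FMT), smooth curved surfaces (the ellipse is faceted at the mesh
resolution), and wide-field illumination patterns.  Passing tests on
these phantoms therefore demonstrate the correctness of the operators
and the stability of the pipeline, not organ-level anatomical fidelity.

## Validation problem sizes

The shipped validation uses problem sizes chosen to exercise every code
path at desk scale: transport runs of $10^3$–$10^7$ photons on meshes of
$10^2$–$10^4$ elements, 40–100 time gates, and adaptation loops of up to
30 iterations.  The headline check — rescaling fidelity on the slice
phantom — runs $10^7$ photons for the central pair, adapts with the
attenuation recipe at maximum size factor 1.25 to convergence, rescales,
and requires the TPSF from the rescaled Jacobian to stay within 1.5% of
the original at and after the TPSF peak.  Statistical-error scaling is
checked against the $N^{-1/2}$ law, and the continuous-wave fluence at a
node 5 mm deep in a thick slab is checked against the diffusion closed
form $\mu_{eff} = \sqrt{3 \mu_a (\mu_a + \mu_s')}$ with image sources,
under index-matched isotropic conditions where the diffusion
approximation is cleanest.  That probe sits 5 mm off the beam axis: on
the axis the collapsed point-source diffusion model misses the
low-order-scattering contribution of the extended first-scatter line and
underestimates the fluence by some 20% — a known limitation of the
diffusion model, not of the transport kernel.

## Known limitations

* Transport is single-threaded; large photon budgets scale linearly in
  wall time.
* Heterogeneous optical properties per region are not supported (the
  homogeneous assumption is baked into the phantoms and the kernel).
* The adaptation is isotropic; anisotropic (tensor) size fields and
  guaranteed-quality Delaunay refinement are out of scope.
* Inverse reconstruction of $\eta$ from measurements is out of scope;
  the package builds and validates the forward model only.
* Boundary coarsening is restricted to coplanar patches, so curved
  (faceted) surfaces retain their initial boundary resolution.
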