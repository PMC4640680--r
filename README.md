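# mmcadapt

Mesh optimization and analytic Jacobian rescaling for mesh-based Monte
Carlo optical tomography, in R.

## What problem this solves

Time-resolved fluorescence molecular tomography (FMT) needs a forward
model linking the unknown fluorophore yield `η(r)` to the detected
time-gated signal:

    U_F(r_s, r_d, t) = ∫_Ω W(r_s, r_d, r, t) η(r) dr

with the sensitivity (Jacobian) `W` assembled from forward and adjoint
Monte Carlo Green's functions convolved with the fluorophore lifetime
decay:

    W(r_s, r_d, r, t) = ∫₀ᵗ e^{-(t-t')/τ} dt' ∫₀^{t'} Gˣ(r_s, r, t'-t'') Gᵐ(r, r_d, t'') dt''

Monte Carlo transport on tetrahedral meshes is the accurate choice where
the diffusion approximation fails (thin tissue, early gates), but its
statistical quality per node depends on how many photons visit that
node.  Adapting the mesh — coarsening the poorly-visited mid-plane
between optodes — improves statistics and shrinks the inverse problem,
yet naively it forces a full Monte Carlo recomputation of `W` on every
adapted mesh.  This package implements the alternative: size-field
driven edge-collapse/edge-split adaptation plus a sparse
transformation matrix (unit column sums, inverse-distance weights) that
rescales the existing Jacobian onto each adapted mesh **analytically**,
with no new stochastic simulation, while preserving time-gated forward
accuracy.

It provides, as testable modules:

* `tet_mesh()` + TetGen/legacy-VTK readers and writers, geometry
  queries, conformity validation (`R/mesh-core.R`, `R/mesh-io.R`);
* a compiled mesh-based Monte Carlo kernel producing time-gated nodal
  Green's functions — Henyey–Greenstein scattering, Fresnel boundaries,
  Russian roulette, exact weight bookkeeping (`propagate()`,
  `adjoint_green()`);
* forward-adjoint Jacobian assembly with lifetime convolution
  (`assemble_jacobian()`, `forward_tpsf()`, `rising_gate()`);
* seven solution fields and the threshold/exponential size-field map
  (`compute_solution_field()`, `to_size_field()`);
* iterative adaptation with convergence and volume-cutoff stopping
  (`split_edge()`, `collapse_edge()`, `adapt_once()`, `adapt_loop()`);
* transformation matrices and Jacobian rescaling
  (`build_transformation()`, `rescale_jacobian()`);
* TPSF and nodal error metrics (`tpsf_error()`, `nodal_error()`,
  `central_node_set()`);
* deterministic synthetic phantoms: a structured slab and an extruded
  elliptical slice with 7+7 transmission optodes and mouse-tissue
  optical properties (`make_slab_mesh()`, `make_slice_phantom()`,
  `place_transmission_optodes()`, `default_properties()`);
* a command-line tool (`inst/cli/mmcadapt.R`, or `run_cli()` from R)
  with subcommands `fixtures`, `forward`, `jacobian`, `fields`,
  `adapt`, `rescale`, `validate`, `demo`.

See `vignettes/forward-model-adaptation.Rmd` for the model, the
numerical choices and their rationale.

## Worked example

```r
library(mmcadapt)

mesh    <- make_slice_phantom(a = 12, b = 8, thickness = 4, h = 1)
optodes <- place_transmission_optodes(mesh, 7, 7)
props   <- default_properties()          # mu_a 0.3 /cm, mu_s' 15 /cm, g 0.9, n 1.37
gating  <- time_gating(50, 40)           # 50 ps gates, 0-2 ns

src <- optodes[[4]]; det <- optodes[[11]]            # central pair
gx <- propagate(mesh, props, src, 1e6, gating, seed = 11)
gm <- adjoint_green(mesh, props, det, 1e6, gating, seed = 12)
W  <- assemble_jacobian(gx, gm, tau = 1000)          # tau = 1 ns
jac <- jacobian(list(W), list(list(source = src, detector = det)),
                gating, mesh)

res <- adapt_loop(mesh, "attenuation", size_field_params(1.25),
                  jacobian = jac, optodes = optodes, props = props)
tail(res$report, 3)

tpsf0 <- forward_tpsf(W, 1, mesh)
tpsf1 <- forward_tpsf(matrix(res$jacobian$W[1, , ], nrow = 40), 1, res$mesh)
err   <- tpsf_error(tpsf1, tpsf0)
cat(sprintf("peak gate %d; max error at/after peak %.4f%%\n",
            which.max(tpsf0), max(err[which.max(tpsf0):40], na.rm = TRUE)))
```

which prints (elided to the last report rows):

```
   iteration nodes elements max_elem_vol_mm3 splits collapses
9          9  1911     8377        0.4811252      0         3
10        10  1910     8374        0.4811252      0         1
11        11  1910     8374        0.4811252      0         0
peak gate 8; max error at/after peak 0.0938%
```

Reading: starting from 2 345 nodes / 10 368 elements, the
attenuation-field recipe converged in 11 iterations to 1 910 nodes,
coarsening the poorly-visited central region (maximum element volume
grew from 0.14 to 0.48 mm³); the TPSF computed from the analytically
rescaled Jacobian on that mesh deviates from the original forward model
by at most 0.09% across all gates at and after the TPSF peak — the
rescaling preserves the time-resolved forward model.

The same pipeline from a shell:

```sh
Rscript inst/cli/mmcadapt.R demo --out demo_out --photons 20000 --seed 3
```

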