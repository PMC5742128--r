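---
title: "Methods: model-based vestibular afferent stimulation in vestim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model-based vestibular afferent stimulation in vestim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vestim implements a modular workflow for simulating electrical stimulation of
vestibular nerve branches in labeled tetrahedral models of inner-ear anatomy:
labeled volume → conforming tet mesh → per-branch nerve-fiber orientation
fields → synthetic nerve fibers with nodes of Ranvier → virtual electrodes →
quasistatic unit-current potential distributions → per-fiber activation
thresholds → recruitment and ROC/AUC selectivity analysis. This vignette
explains the models behind each stage, the tunable parameters and their
defaults, the numerical choices, and what the synthetic phantom does and does
not establish about real anatomy.

## Geometry: labeled voxels to conforming tetrahedra

All geometry is carried by a `tet_mesh`: vertices in meters, 4-index
tetrahedra, and a tissue-region label per tet. Labeled voxel volumes are
converted by `voxel_to_tetmesh()` using the translation-invariant Kuhn
(Freudenthal) 6-tet subdivision of each voxel. Because the subdivision is the
same in every voxel, face diagonals agree across voxel boundaries and the
mesh is conforming by construction; per-label volume is conserved exactly
(each tet has volume $h_x h_y h_z/6$). We deliberately do not attempt
boundary-conforming or graded meshing — resolution is uniform, set by the
voxel pitch, with finer studies achieved by regenerating at a smaller pitch.
Validation checks positive tet volumes (after consistent re-orientation), a
face census (every interior face shared by exactly two tets), and duplicated
vertex coordinates, which are how "tets that touch but share no face"
non-conformities manifest in assembled label meshes.

Units are SI throughout the package (m, s, S/m, A, V); helpers `um()`,
`mm()`, `us()`, `mA()` convert customary units at the configuration surface.

## Fiber orientation from Laplace solves

Nerve tissue conducts markedly better along the fiber axis than across it,
so each nerve branch needs a per-tet unit vector field estimating the local
fiber direction. vestim computes it from two P1 finite-element solves on the
branch volume (which must be single-connected):

1. **Distance surrogate** (`solve_distance_surrogate`): Laplace's equation
   with $\phi = 0$ on the start surface $\Gamma_s$ and a uniform unit
   outflow $-\nabla\phi\cdot n = 1$ on the rest of the boundary. The field
   is non-positive and its surface minimum approximates the point most
   distant from $\Gamma_s$; a Dijkstra geodesic patch (vertex-graph
   distances with Euclidean edge weights) of radius `patch_radius` around
   that point becomes the target surface $\Gamma_t$
   (`find_target_surface`). For tube-like volumes without a labeled sensory
   contact the same trick, started from a random surface element, finds a
   definitive start surface first (`auto_start_surface_tube`).

2. **Orientation potential** (`solve_orientation_potential`): Laplace's
   equation with the Cauchy (Robin) condition
   $-\nabla\phi\cdot n = \alpha(x)\,[\phi - \phi_e(x)]$ on the whole
   surface, where $(\alpha, \phi_e)$ is $(\alpha_s, 0)$ on $\Gamma_s$,
   $(\alpha_t, 1)$ on $\Gamma_t$ and insulating elsewhere. The potential
   rises continuously from start to target; the fiber orientation is its
   normed per-tet gradient $F = \nabla\phi/|\nabla\phi|$
   (`orientation_from_potential`; degenerate-gradient tets inherit the mean
   of their face neighbours).

$\alpha_s = \alpha_t = 100$ (in the solve's SI length units) is the default;
larger values force a steeper fiber entry/exit angle at the coupled
surfaces, and the package's tests assert this monotonicity over
$\alpha \in \{1, 10, 100, 1000\}$. The geodesic `patch_radius` is not a
physical constant: the default is twice a crude tube-radius estimate of the
branch, and both the radius and fully manual start/target patches (explicit
triangle lists) are supported, mirroring practice on imperfect segmentations.

Discretization choices: linear (P1) tetrahedral elements assembled from
closed-form per-tet gradients; consistent (not lumped) surface mass matrices
for the Robin terms; sparse symmetric direct solves (CHOLMOD through the
Matrix package). P1 is the minimum order that carries the workflow, and on
the problem sizes this package targets (up to a few hundred thousand tets) a
direct solve is both fastest and free of iterative-tolerance
non-determinism. Dirichlet constraints are imposed by row/column
elimination, which keeps the reduced system symmetric positive definite.

## Synthetic fibers and nodes of Ranvier

Fiber trajectories are streamlines of $F$ (`trace_streamline`): fixed-step
RK4 on $dx/ds = F(x)$ with $F$ piecewise constant per tet, point location by
tet walking with a bucketed global fallback, and exact clipping of the last
segment to the boundary face through which the trace leaves the region. The
default step is 1/4 of the branch's mean tet edge — small enough that a
step never skips a tet of the walk, large enough to keep traces cheap; the
tests verify that halving the step moves the exit point by less than one
step.

Fiber synthesis (`generate_fibers`) seeds start points uniformly over
$\Gamma_s$ (triangle selection weighted by area, then uniform barycentric
sampling) and accepts a trace only if it terminates by crossing $\Gamma_t$;
rejected traces are replaced by drawing a new start point. Generation is
bit-reproducible given the seed. Fiber counts are per-branch configuration;
400 per branch is the customary full-study value, and the phantom scenarios
default to 50 to keep runtimes in minutes.

Afferent types (regular, irregular, dimorphic) are assigned by epithelial
zone: a fiber is *central* when its seed's geodesic distance to the
patch-centroid vertex is below the `central_fraction` quantile (default 0.5)
of all patch-vertex distances, and the type is drawn from a per-zone
categorical distribution (defaults: central → irregular/dimorphic 50/50,
peripheral → regular/dimorphic 50/50). The zone rule and the probabilities
are configuration, not literature values — the quantitative human zone
composition is not established in sources available to this package, so the
scheme is fully exposed and easily overridden. The same holds for the
internodal distances (defaults 350/250/300 µm for regular/irregular/
dimorphic, a plausible myelinated-afferent range at the customary
length-to-diameter ratio of ~100): they are placeholders to be replaced by
study-specific morphometry. Nodes of Ranvier are placed arithmetically along
the fiber at the type's internodal spacing (`place_nodes_of_ranvier`).

## Electrodes and stimuli

Electrodes are spheres placed by relabeling: all tets whose centroid lies
inside the sphere become region `electrode_<id>` (`place_electrode`), with
the original labels retained so `deactivate_electrode()` restores them
exactly — the multi-electrode activate/deactivate bookkeeping used to
compare configurations without remeshing. We intentionally do not perform
cavity-cut-and-remesh electrode insertion: with a high electrode
conductivity (10⁶ S/m) the relabeled region reproduces the electrical
effect of a metal body, and boundary-conforming tet surgery would add a
meshing subsystem without changing the quantities this package reports. The
mesh must resolve the electrode (effective voxel pitch ≤ 1/3 diameter),
otherwise placement errors with advice to regenerate the mesh at finer
resolution — local red-subdivision refinement is deliberately avoided
because it would break mesh conformity (hanging nodes).

`standard_configurations()` builds the four canonical configurations at an
ampullary nerve: monopolar (one sphere at a standoff from the sensory
epithelium along its transverse axis, distant return at the grounded outer
saline surface) and three bipolar pairs centered at the monopolar position
with dipole moments along the canal tangent (axial), the transverse axis
(transverse-parallel, active electrode nearer the epithelium) and the
mutually perpendicular direction. Defaults are the customary 200 µm spheres,
750 µm standoff and 1 mm pair separation. **On the phantom** these are
geometrically unresolvable at the default voxel pitch, so the phantom
scenario scales the electrode geometry to the mesh (8 mm spheres, 8.75 mm
standoff, 10 mm separation); the mono-vs-bipolar contrasts of interest are
scale-free in character, but absolute amplitudes from the phantom are not
comparable to microelectrode studies.

The stimulus is a piecewise-constant waveform; `biphasic_waveform()` builds
the standard charge-balanced cathodic-first pulse (200 µs phases, 30 µs
interphase gap, total support 430 µs).

## Quasistatic potentials

Tissues are treated as purely resistive: dielectric relaxation in biological
tissue is much faster than the stimulus time scale, so the potential at any
instant is the unit-current solution scaled by the instantaneous stimulus
amplitude (`scale_potential`; no re-solve per time step). The unit solution
solves $-\nabla\cdot(\sigma\nabla\phi) = I_s$ with the unit current
distributed uniformly over the active electrode tets ($I_s = I/V_a$),
zero-flux outer boundary, and the reference at 0 V — all vertices of the
reference electrode region (bipolar) or of the outer saline surface
(monopolar).

Conductivity is a per-tet 3×3 tensor: isotropic $\sigma I$ for fluids, bone
and metal; for nerve regions
$\sigma_t I + (\sigma_l - \sigma_t) F F^{\mathsf T}$ bound to the branch
orientation field, so the principal axis follows the fibers. Defaults
(S/m): bone 0.0139, nerve 0.3333 longitudinal / 0.0143 transversal,
cochlear nerve 0.1738 (the average, used where no fiber field exists —
also the package's default for the merged canal region and the thin
epithelium discs), perilymph/endolymph and scalae 2.0, saline 2.0,
electrode 10⁶; all overridable per region. Solver diagnostics report the
residual and the current balance at the reference (algebraically the
absorbed current equals the injected current; the tests assert it to 1e-6).

## Per-fiber activation and thresholds

The extracellular potential is interpolated at each fiber's nodes of Ranvier
(barycentric P1 interpolation, `interpolate_at_points`) and drives a
discrete myelinated-axon cable model at the nodes:

$$C\,\frac{dV_n}{dt} = G_a\,(V_{n-1} - 2V_n + V_{n+1}
 + V_{e,n-1} - 2V_{e,n} + V_{e,n+1}) - I_{ion}(V_n,\,m,\,h),$$

with sealed ends, $V_{e,n}(t) = A\,w(t)\,u_n$ coupling the unit-current node
potentials $u_n$ through waveform $w$ and amplitude $A$, nodal capacitance
and axial internodal conductance derived from fiber diameter and internodal
distance. The default nodal kinetics are the CRRSS mammalian node (fast
sodium + leak at 37 °C) — a standard published formulation chosen because
the morphometry-adapted human vestibular kinetics used in specialised
studies are not publicly specified; every parameter is exposed in
`neuron_params()` and the model variant is pluggable. A `linear_sdc`
variant (spike iff the peak positive activating second-difference drive
crosses a constant) provides a closed-form threshold oracle for testing the
search machinery.

Integration is fixed-step implicit Euler for the membrane equation (the
constant tridiagonal system is Thomas-factorized once per fiber) with
exponential-Euler gate updates, default $dt = 2$ µs over the stimulus
support plus a 1 ms tail, implemented in compiled code with a pure-R
reference stepper cross-checked in the tests. A spike is any node crossing
0 mV absolute (full overshoot) — a deliberately conservative criterion that
is insensitive to subthreshold depolarization. Thresholds are found by
doubling from a floor (default 10 µA) until a spike, then bisecting to 1%
relative tolerance; fibers silent at the ceiling (default 10⁶ × floor) are
flagged non-excitable and never activate in recruitment curves. Tests pin
the bisection against exhaustive fine-grid amplitude scans, the $1/k$
scaling of thresholds under $k$-scaled node potentials, strength–duration
monotonicity over 50–400 µs phases, and stability under $dt$ halving (<2%).

Spontaneous discharge variability is not modeled: thresholds are
deterministic, which sharpens recruitment curves relative to physiology.
After-hyperpolarization adaptation and pulse-train effects are likewise out
of scope for single-pulse thresholds.

## Selectivity evaluation

Per branch, the recruitment curve is the right-continuous step function
(#thresholds ≤ amplitude)/N, with non-excitable fibers in the denominator
and never counted active. The selectivity of a configuration is the area
under the ROC traced by (maximal non-target recruitment, target recruitment)
over increasing amplitude, completed with (0,0) and (1,1) and integrated by
trapezoids over the monotone staircase — a rule chosen because it reproduces
the definitional limits exactly: 1 when every target fiber activates before
any non-target fiber, 0 in the anti-selective case, 0.5 for identical
threshold multisets. The amplitude reported for a recruitment level (default
80%) is the ⌈level·N⌉-th order statistic of the thresholds — an exact
consequence of the step-function recruitment definition, not an
interpolation. Charge per pulse is amplitude × phase duration per polarity;
the energy figure is $A^2 \int w^2 dt \cdot R_{access}$ with the lumped
access resistance read from the FEM solution (mean unit potential over the
active-electrode vertices minus the reference mean) — a reporting
convention, stated as such, with alternatives pluggable.

## The phantom: what it emulates and what it does not

`make_phantom()` rasterizes a synthetic inner-ear-like anatomy: a 5 cm bone
sphere in a 1 cm saline shell; an endolymph labyrinth with two ampulla-like
cavities joined by a horizontal tube; a thin sensory-epithelium disc at the
base of each cavity; one nerve tube per ampulla running from its epithelium
down to a merged canal (IAC) region that both branches join. It reproduces
the *topology* the workflow assumes — single-connected nerve volumes
contacting an epithelium/endolymph interface, a fluid labyrinth, embedding
bone, outer saline — at a deliberately coarse, millimetre scale (default
2.5 mm voxels, nerve radius 4 mm) so the full pipeline runs in minutes on
one CPU. It does **not** emulate real dimensions of nerve branches,
multi-canal geometry, utricle/saccule/facial-nerve compartments, or
anatomical variability; passing tests on the phantom demonstrate the
correctness and qualitative behavior of the machinery (e.g. monopolar
configurations couple more strongly but select less well than the
transverse-parallel dipole), not quantitative predictions for human
stimulation. Those require segmented specimen anatomy run through exactly
the same pipeline.

Problem sizes used by the shipped studies: the phantom meshes to ~69k tets;
the orientation solves act on a few hundred tets per branch; acceptance
studies use 50 fibers per branch and two to four electrode configurations.
The analytic verification fixture (grounded homogeneous sphere, central
source) uses ~62k tets, where the FEM potential at r = R/2 sits within 5%
of $\phi(r) = \frac{I}{4\pi\sigma}(1/r - 1/R)$.

## Degenerate inputs and tie-breaks

Empty start surfaces, non-single-connected nerve regions, overlapping
start/target patches, electrodes that capture no tets or overlap other
electrodes, probability vectors that do not sum to one, and fibers too short
for two nodes all raise immediate errors. Extremal-point ties break to the
lowest vertex index; geodesic patches always include the seed's incident
triangles so a zero radius is valid; the streamline tracer flags (rather
than silently truncates) traces that exhaust the step budget, and the fiber
generator reports its acceptance rate when the attempt budget is exhausted.

## Reproducibility

Every random stage (seed sampling, type assignment, the temporary surface
element of the automatic tube start) draws from a named sub-stream derived
from the scenario seed; reruns with the same seed give bit-identical fibers
and, up to direct-solver roundoff, identical thresholds and reports.
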