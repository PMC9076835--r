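---
title: "Modelling the dandelion apical plate as a hygroscopic actuator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the dandelion apical plate as a hygroscopic actuator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The system and the model

The dandelion diaspore carries its parachute-like pappus on a small disk
of tissue, the apical plate. The plate is a humidity-driven actuator:
when it dries, the roughly one hundred hairs attached at its flanks
splay open; when it is wetted they close. The quantity summarizing the
actuator's state is the holding angle $\theta$ - the angle between the
vertical and the line from the upper corner of the plate to the lowest
point of the side region's lateral edge, measured in the dry state.

`pappus` models the longitudinal section of the plate as a
two-dimensional, isotropic, linearly elastic body under plane strain.
Four tissue regions surround a central cavity:

* **floral podium** - the dense, phenolic-rich cap at the top;
* **vasculature** - two stiff, lignified, low-swelling bands flanking
  the cavity;
* **side regions** - the lipid-rich domains at the upper outer flanks
  where the hairs attach;
* **cortex** - the large-celled tissue forming the lower bulges.

The hydrated configuration is taken stress-free. Each region $r$
carries an intrinsic swelling factor $s_r \in (0,1)$: the fraction of
area it would lose on drying if detached from its neighbours. Drying is
imposed as a region-wise isotropic eigenstrain

$$\varepsilon^*_r = \left(\sqrt{1-s_r\,}-1\right) I_2,$$

which reproduces the free area ratio $1-s_r$ exactly for an isolated
region (this identity is verified in the test suite to machine
precision). Region stiffness follows the measured density of cell-wall
material, $E_r = E_\mathrm{vasc}\,\rho_r/\rho_\mathrm{vasc}$, with one
Poisson ratio $\nu = 0.29$ for all regions; because the problem is
driven purely by eigenstrain and prescribed displacement, the scale
$E_\mathrm{vasc}$ cancels (also a tested invariant). Mismatch between
the regions' eigenstrains produces residual stress and the global shape
change that rotates the hair attachment sites.

The solver minimizes the discrete plane-strain energy on linear
(constant-strain) triangles, assembled sparsely and factorized once per
stiffness distribution; repeated solves with different swelling factors
(as in the calibration) reuse the factorization and cost one
substitution each.

## Geometry construction

Nine measured lengths define the hydrated section (micrometres): plate
diameter $D = 491$, height $H = 240$, podium radius of curvature
$R = 363$, podium height $H_{pod} = 38.8$, side-region height
$H_{side} = 91.4$ and width $W_{side} = 47.6$, vascular-band width
$W_{vasc} = 34.3$, basal cavity diameter $D_{cavity} = 74.8$, and the
prescribed wet-to-dry displacement of the vascular base
$d_{vasc} = 15.3$.

The exact region shapes beyond these lengths are only drawn, not
dimensioned, so the construction here is one consistent reading, chosen
after a systematic comparison of alternatives (below):

* the plate's shoulder is flat at $y = H - H_{pod}$ and capped by the
  podium, the circular segment of radius $R$ and sagitta $H_{pod}$;
* the cavity is a trapezoid widening upward from basal width
  $D_{cavity}$ to the underside of the podium (its roof);
* the vascular bands run parallel to the cavity flanks, from a base of
  width $W_{vasc}$ up and outward to the inner corners of the side
  regions - consistent with the bundles supplying the hairs. At the
  measured values the band top, the podium chord end
  ($\sqrt{H_{pod}(2R - H_{pod})} = 163.3$) and the side-region corner
  ($D/2 - W_{side} - W_{vasc} = 163.6$) coincide to a third of a
  micrometre, which strongly suggests this is the intended topology;
* the podium rests on the band tops over a seat of width $W_{vasc}/2$
  at each chord end. The seat width is not dimensioned anywhere; the
  computed mechanics are insensitive to it (varying it from
  $W_{vasc}/8$ to $W_{vasc}$ moves $\theta$ by under $0.2^\circ$);
* side regions are $W_{side} \times H_{side}$ rectangles flush with the
  rim; the cortex fills the remainder.

Alternative readings were implemented and rejected because they fail to
reproduce the reported qualitative behaviour: a narrow triangular
cavity with near-vertical bands leaves the vasculature mechanically
inert (substituting its material changes $\theta$ by under a degree,
where a strong effect is reported); a dome-shaped podium layer of
thickness $H_{pod}$ bonded over the whole band top reverses the sign of
the reference response; a podium connected only at a point decouples it
entirely (podium substitutions then have no effect, where a moderate
effect is reported). The construction above is the only variant found
whose responses carry the reported sign for every parameter and the
reported ordering across all material-substitution scenarios.

### Boundary conditions

The vascular-base nodes are displaced horizontally toward the axis by
$d_{vasc}$ with vertical displacement fixed; on the half model the
symmetry axis carries a roller condition. The direction of the
prescribed displacement is stated only as "a fixed amount" in the
source analysis; the horizontal-inward reading follows the dominant
radial motion of the measured displacement fields. Prescribing the
vertical component instead (or leaving it free) changes $\theta$ by
less than a degree, so the choice is not critical.

### Perturbations

Four geometric perturbations reproduce the published experiments:
filling the cavity horizontally (shrinking it toward the axis) or
vertically (lowering its roof), with the vacated space becoming cortex;
trimming the cortex from below the bulges (the cut following the band's
outer edge); and moving the lower outer corners radially. Magnitude 0
is the identity for every kind, and area bookkeeping under each
perturbation is verified by the shoelace formula.

## Calibration, sensitivity and propagation

`fit_swelling_factors()` recovers the four swelling factors by
minimizing the (optionally inverse-variance weighted) squared mismatch
between modelled and target regional expansions (wet/dry convention),
with Nelder-Mead on a logistic-transformed scale, box bounds
$[0.01, 0.95]$, and seeded jittered restarts. Self-consistency is exact
to better than 0.02 per factor, and with 5% target noise the median
absolute error stays below 0.05 over 20 seeded replicates.

`oat_sensitivity()` computes the dimensionless one-at-a-time
sensitivity $S_p = (\Delta\theta/\theta_{ref})/(\Delta p/p_{ref})$ from
central differences at $p_{ref}(1 \pm 0.05)$; a parameter whose
perturbed geometry is invalid is recorded as failed without stopping
the sweep. Note that varying $H_{side}$ legitimately moves the
measurement line itself: $\theta$ is always measured with the current
geometry's landmarks.

`predict_correlations()` propagates parameter covariation to first
order: with $g_j = S_j\theta_{ref}/p_j$ and $\sigma_j = CV_j p_j$,
$\mathrm{corr}(\theta, p_i) = \sum_j g_j\sigma_j\sigma_i\rho_{ij}\,/\,
(\sigma_i\sqrt{\sum_{jk} g_j g_k \sigma_j\sigma_k\rho_{jk}})$. The
measured covariation of the nine geometric parameters is not published,
so it is a user input; `example_geometry_covariation()` ships a
plausible positive-definite one-factor structure for testing. The
analytic propagation is validated against a $10^5$-draw Monte-Carlo
oracle on the linearized response to within 0.01.

## Landmark strain mapping

The image-analysis stage mirrors the published procedure: Delaunay
triangulation on the dry landmarks (a Bowyer-Watson kernel built into
the package); exclusion of triangles not fully enclosed by the dry
outline; per-triangle area ratio (wet/dry); invalidation of triangles
whose wet image inverts or overlaps another wet triangle's interior by
more than $10^{-6}$ of its area; one smoothing pass averaging each
valid triangle with its edge-adjacent valid neighbours; principal
stretches and directions from the SVD of the per-triangle deformation
gradient; region assignment by the 40% polygon-overlap rule (largest
overlap on ties, then the fixed priority podium > vasculature > side);
and circularity $4\pi A/P^2$. Adjacency by shared edge and a single
smoothing pass are choices the published text leaves open. The product
of principal stretches equals the raw area ratio to $10^{-9}$ for every
valid triangle, and all outputs are invariant under a common rigid
motion.

## AFM force-curve processing

Curves follow the seven-segment protocol (two extend-retract cycles, a
third extension, a 10 s constant-force pause, a final retraction) with
a 3 uN trigger. Processing: per-segment baseline flattening on the 30%
of samples farthest from the surface; first contact-point estimate at
the first zero crossing scanning from the trigger end; conversion to
tip-sample separation (height minus deflection); and a Sneddon
conical-indenter fit $F = \frac{E}{1-\nu^2}\frac{2\tan\alpha}{\pi}
\delta^2$ with $\alpha = 18^\circ$, $\nu = 0.5$, on the last
retraction. The effective modulus, the contact point and a force offset
are free; the first contact estimate fixes the fitting range, which
removes the degeneracy in which an ever-deeper contact point fits an
ever-shorter arc ever better. The least squares is weighted for a
predominantly multiplicative force-error model (relative weights with a
2%-of-peak floor). Curves whose last-retraction adhesion (magnitude of
the minimum force) is 160 nN or more are rejected - strictly below the
threshold is kept. Noiseless closure is better than 0.1% across
0.1-50 GPa; at 2% multiplicative noise the median error at 5 GPa is
about 1%. At 50 GPa with a 3 uN trigger the indentation is only about
15 nm, so with the standard 1 nm sampling the 2%-noise scatter rises to
several percent - a sampling limit of the measurement configuration,
not of the estimator.

## Synthetic data

The generators provide every input the pipeline consumes without any
imaging data, and each is a pure function of its spec including the
seed. Landmark sets use a strip layout whose deformation field has an
exactly controlled local area factor ($x' = \int_0^x\sqrt{f},\;
y' = y\sqrt{f(x)}$, Jacobian $f(x)$ everywhere, with $f$ blended over
10 um at strip boundaries), so ground truth is exact away from
boundaries and the field never folds. This emulates the region-wise
expansion structure of real tissue but not its curved outlines, its
landmark sparsity gradients, or correlated annotation error, so passing
closure tests demonstrates correctness of the mapping pipeline, not
fidelity to any particular specimen. Force curves superpose the Sneddon
contact branch (solved consistently with cantilever compliance), a
linear baseline, a Gaussian pull-off dip on the final retraction and
multiplicative noise. Geometry samples draw from a multivariate normal
around the reference means with requested CVs and correlations,
resampling invalid geometries (which preserves correlations among
accepted draws at the cost of a small bias at large CVs).

## Problem sizes and numerical choices

The default mesh edge is 4 um (about $W_{vasc}/8$), at which
$|\theta(4\,\mu m) - \theta(2\,\mu m)| < 0.1^\circ$; convergence-grade
results use 2 um (about 20,000 triangles on the half section, solving
in seconds). Calibration studies run at 8 um, where one fit takes well
under a second after the one-off factorization. Boundary chains are
sampled at the arc resolution (2 um), interior points on a jittered
hexagonal lattice; region tags come from triangle centroids, and the
recovered region areas match the polygon areas to machine precision at
these resolutions. Ties and degeneracies are handled deterministically
(fixed jitter pattern, fixed region priority, strict inequality at the
adhesion threshold).

## Known limitations

* The model is two-dimensional and end-state only: no water transport
  dynamics, no out-of-plane (circumferential) mechanics beyond the
  plane-strain idealization and the prescribed vascular-base
  displacement that stands in for it, and no anisotropic cell-wall
  swelling (isotropy suffices to produce the actuation).
* Linear kinematics are retained at 25-35% shrinkage strains, matching
  the stated model class; an incremental geometrically updated variant
  changed the reference angle by about one degree.
* With the construction above, the reference model produces
  $\theta \approx 8.9^\circ$ - the right sign and a complete match to
  the reported qualitative structure (every one-at-a-time sensitivity
  sign; the full ordering of the material-substitution scenarios,
  including inversion to $\approx -10^\circ$ when vasculature and
  podium both take side-region properties), but roughly half the
  reported reference magnitude of about $20^\circ$. The discrepancy is
  systematic: substitution effects that do not involve the vasculature
  match the reported differences almost exactly, while
  vasculature-linked effects run at about two thirds of the reported
  size. Extensive exploration (cavity taper, podium-junction topology
  and bond width, boundary-condition direction and magnitude,
  out-of-plane eigenstrain, plane stress, mesh refinement, geometric
  nonlinearity, alternative measurement lines) did not close the gap,
  which we attribute to section-geometry details that are only drawn,
  not dimensioned, in the source figures. Quantities tied to the
  absolute angle scale inherit this bias; sign structure, orderings,
  calibration closure and the mapping/AFM pipelines do not.
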