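---
title: "Virtual FFR from angiograms: models, numerics and design choices"
author: "vffr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual FFR from angiograms: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`vffr` estimates fractional flow reserve (FFR) — the ratio of
distal-to-stenosis pressure `Pd` to proximal pressure `Pa` under
hyperaemia — and wall-shear indices (TAWSS, OSI, RRT) for a single stenosed
coronary segment, starting from two-dimensional contrast angiogram frames.
The stages are: cine normalisation and end-diastolic frame selection, lumen
segmentation, centerline extraction and sub-pixel diameter measurement,
stenosis quantification (the degree of stenosis
$\beta = 100\,(1 - d/D)$), reconstruction of the lumen as a surface of
revolution, a transient finite-volume solution of the incompressible
Navier–Stokes equations with shear-thinning blood rheology under one of four
boundary-condition (BC) methodologies, and post-processing to FFR and
wall-shear indices.

Because clinical angiograms and pressure-wire recordings cannot be shipped,
the package carries a first-class synthetic-data module whose outputs have
known ground truth; all quantitative claims in the test suite are made
against that ground truth, never against patient data.

# The synthetic data model and its limits

`make_radius_profile()` generates an analytic lumen,
$r(s) = r_0\,(1 - \tfrac{\beta_t}{100} e^{-(s-c)^2/(2w^2)})$.
The defaults describe a proximal-LAD-like segment: length 30 mm, healthy
radius 1.5 mm, throat mid-segment, Gaussian half-width \(w = 0.9\) mm (a
focal lesion roughly 3.5 mm long).  The half-width matters: the upstream
reference diameter \(D\) is measured over a window proximal to the throat
(below), so a lesion much wider than ~1 mm would leak into its own reference
window and bias \(\beta\) low, while the measurement smoothing flattens a
lesion much narrower than the sampling.  \(w = 0.9\) mm keeps both effects
below 0.3 percentage points of \(\beta\) — this error budget is what makes
the half-point recovery contract in the tests achievable.

`render_cine()` renders frames under a mono-energetic contrast model: pixel
intensity is background minus an attenuation proportional to the contrast
path length, the lumen chord \(2\sqrt{r^2-d_\perp^2}\), scaled by a
cardiac-phase contrast factor that peaks at the end-diastolic frame, plus
optional additive Gaussian noise clipped to the bit depth.  Defaults:
0.08 mm/pixel, 16-bit frames, background 58000, attenuation 12000 grey/mm.
The model deliberately omits scatter, beam hardening, projection
foreshortening and cardiac/table motion; consequently the segmentation tests
demonstrate correctness of the measurement chain, not robustness to X-ray
physics.

Pressure and flow waves are truncated Fourier series (a systolic plus a
dicrotic von-Mises bump).  The inlet wave defaults to a mean of 75 mmHg —
the proximal pressure level the framework is designed around — with a
40 mmHg pulse over a 0.8 s cycle.  The bundled `cohort_reference()` carries
five published patient-specific Windkessel parameter sets with their
invasive and computed FFR values; the synthetic cohort generator
(`make_cohort()`) jitters wave means a few percent around these anchors and
produces, per patient, the distal pressure trace implied by its Windkessel
set — the ground truth that parameter fitting must recover.

# Segmentation

Frames are normalised by one affine map from the global cine min/max, which
preserves pixel ordering exactly (clipped percentile normalisation would
not, and rank preservation is part of the module's contract).  The
end-diastolic frame minimises mean intensity over a vessel-candidate region
(dark pixels of the temporal-minimum image); ties break to the lowest index.

**Threshold rule.**  The default lumen threshold is *fractional-depth*:
background (frame median) minus 0.15 of the global dynamic depth.  A
mid-histogram (Otsu) threshold — offered as an override — is the wrong
default for contrast-chord images: the intensity profile across a projected
cylinder falls off as \(\sqrt{r^2-x^2}\), so a threshold at half depth
crosses at \(x = 0.87\,r\) and systematically pulls the detected edge
~13% of the radius inward.  At 0.15 of the depth the crossing sits within
half a pixel of the true edge for every radius in the fixture range, which
is what the 1-pixel mask contract requires.

**Centerline.**  The mask is thinned (Zhang–Suen) to a skeleton, the
longest endpoint-to-endpoint geodesic through the skeleton graph is taken,
path samples within one local half-width of the blunt vessel ends are
trimmed (skeletons grow unreliable tails into corners), and each remaining
sample is re-centred to the midpoint of the mask extent along the local
perpendicular.  This medial refinement matters: the raw skeleton of a
slanted band can sit a full pixel off-centre, while the refined polyline
stays within ~0.4 px of the true centerline for bends up to 2 mm amplitude.
A five-sample moving average suppresses pixelation without erasing a focal
stenosis.

**Diameters.**  The mask-based measurement (edge-to-edge ray marching)
carries ±1 px quantisation and is kept as the plain contract.  The pipeline
itself uses the sub-pixel path: along each perpendicular, the interpolated
contrast depth is traced to the point where it falls to a fraction
\(q = 0.5\) of its local centerline value; for a circular cross-section that
crossing sits at \(r\sqrt{1-q^2}\), so dividing the measured half-width by
\(\sqrt{1-q^2}\) recovers the radius.  Because the threshold is *relative*
to the local depth, the geometric correction is exact for any radius, and
\(\beta\) — a ratio of diameters — is unbiased by construction.  At zero
noise the measured profile lands within ~0.05 mm of truth (a factor ~3
below the 2-px contract) and \(\beta\) within ~0.3 points.

**Branch pruning** scores every endpoint-to-endpoint skeleton path by its
cumulative distance-transform value (lumen half-width) and keeps the best;
the mask is rebuilt as the union of inscribed disks along that path.  Ties
in width go to the longer path, with a warning.

# Stenosis quantification and geometry

\(\beta(s) = 100\,(1-d(s)/D)\) with \(D\) the mean diameter over a 5 mm
window ending 2 mm proximal to the throat (the guard band keeps the lesion
shoulder out of its own reference).  The throat is the global minimum of
the smoothed profile, ties breaking proximally, but \(\beta\) itself is
evaluated on unsmoothed diameters so the minimum is not flattened twice.
An exactly uniform tube has no throat and reports \(\beta \equiv 0\).

The lumen is revolved about the straightened centerline into a triangulated
surface (for export/visualisation) and into a structured axisymmetric
\((s, r)\) grid: a uniform radial core plus seven wall layers whose
thicknesses form a geometric sequence with ratio 1.1 (finest at the wall,
occupying 35% of the local radius), and axial stations optionally clustered
around the throat.  The axisymmetric reduction is the central geometric
design decision: the reconstructed lumen *is* a surface of revolution, so a
revolved 2-D solution preserves every modelled physical effect at a small
fraction of a 3-D tetrahedral solve, at the price of discarding
out-of-plane curvature (the solver straightens the centerline).

# Blood rheology

Carreau–Yasuda shear-thinning viscosity,
\(\mu = (\mu_0-\mu_\infty)(1+(\lambda\dot\gamma)^a)^{(m-1)/a} + \mu_\infty\),
with \(\mu_0 = 0.056\) Pa s, \(\mu_\infty = 0.0035\) Pa s,
\(\lambda = 1.902\) s, \(a = 1.25\), \(m = 0.22\), density 1056 kg/m³.
The shear rate is the full axisymmetric invariant
\(\sqrt{2\,D\!:\!D}\) including the hoop component \(u_r/r\).  Setting
\(\mu_0 = \mu_\infty\) gives the Newtonian degenerate mode used by every
analytic solver oracle.  Internally everything is SI; mmHg and ml appear
only at I/O boundaries (1 mmHg = 133.322 Pa).

# The 0D outlet: three-element Windkessel

The outlet law
\(P = (R_1+R_2)Q - R_2C\,\dot P + R_1R_2C\,\dot Q\)
is integrated in time by rewriting it in the capacitor pressure
\(P_c = P - R_1 Q\), which removes the stiff \(\dot Q\) term exactly
(\(\dot P_c = (Q - P_c/R_2)/C\)), and advancing with classical RK4;
integration proceeds to a periodic state and the final period is returned.

`wk3_fit()` is bounded Levenberg–Marquardt on log-parameters; its model is
the *exact periodic response* evaluated through the impedance transfer
function \(Z(\omega) = R_1 + R_2/(1+i\omega R_2 C)\), which keeps every
objective evaluation cheap and free of initial-transient bias while the
time-domain integrator remains an independent implementation that the tests
cross-check against the same transfer function.  The default initial guess
is \(R_1+R_2 = \bar P/\bar Q\) split 20/80 with a compliance giving an
\(R_2C\) decay time of half a period.

**Identifiability.**  \(R_2\) and \(C\) are always well determined by the
mean pressure and the decay of the pulse.  \(R_1\) is the high-frequency
impedance; its pressure signature scales with the sharp content of the flow
wave.  In the bundled cohort \(R_1\) is only 0.2–0.5% of the total
resistance, so at 2% multiplicative measurement noise its signature
(~0.1 mmHg) sits below the noise floor and *no* fitting algorithm can
resolve it to a few percent — the recovery simulation therefore uses a
ground-truth set with the textbook characteristic-impedance fraction
(2% of total) and emulates a four-beat recording whose beats are
ensemble-averaged (through the package's FFT wave averaging) before
fitting.  Constant flow against constant pressure leaves \(C\)
structurally unidentifiable; the fit flags this and returns only
\(R_1+R_2\).

Cohort averaging is the component-wise arithmetic mean, and wave averaging
is performed in the frequency domain (FFT, element-wise spectral mean,
inverse FFT), which for equal-length inputs is algebraically the pointwise
time mean.  The published comparison tables print error percentages
*truncated toward zero* (26.9% as 26, 3.45% as 3.4); `wk3_error_report()`
and `ffr_error()` reproduce exactly that convention.  The option of
rescaling the averaged inlet wave to one patient's mean pressure exists but
is off by default, since which patient should anchor the scale is an open
choice.

# The flow solver

Axisymmetric incompressible Navier–Stokes on the body-fitted structured
grid: collocated finite volumes, SIMPLE pressure–velocity coupling with
Rhie–Chow momentum interpolation, implicit first-order upwind convection
with a deferred central correction (blend 0.5), over-relaxed treatment of
mesh non-orthogonality, and a Jacobi-preconditioned conjugate-gradient
pressure solve.  The viscous term uses the Laplacian form
\(\nabla\cdot(\mu\nabla u)\) with the axisymmetric sink \(-\mu u_r/r^2\),
i.e. the form the governing equations are stated in, rather than the full
variable-viscosity stress divergence; for the mild viscosity gradients of
blood at coronary shear rates the difference is far below the spatial
discretisation error.  All face areas and volumes carry the \(2\pi r\)
measure, which makes the axis a zero-area face needing no boundary
condition.  Walls are rigid no-slip; inlet and outlet impose static
pressure with zero normal velocity gradient.

Time stepping is second-order backward differencing (BDF2) with a
first-order bootstrap step, at `dt = 0.005` s; three cardiac cycles are run
and the final cycle is extracted, with a cycle-to-cycle periodicity metric
recorded (typical final value ~1e-6 relative).  Each step iterates SIMPLE
until the normalised RMS residual falls below 1e-5; residuals are
normalised by a common velocity scale so the near-zero radial component in
a straight tube is measured against the flow rather than against itself,
and an exactly quiescent solution (whose relative residual is
roundoff-dominated) is accepted through a machine-precision stagnation
criterion.  The Rhie–Chow coefficient uses the steady part of the momentum
diagonal only, making the converged state independent of the time step.

**0D coupling.**  The outlet law is linearised per time step as
\(P_{target} = A + KQ\) (resistance: \(A = P_{ref}, K = R\); Windkessel:
\(A, K\) absorb the BDF history).  A naive relaxed fixed point on the
outlet pressure diverges whenever \(K\) exceeds the vessel's own
resistance — which is essentially always, since a coronary outlet carries
two orders of magnitude more resistance than 30 mm of epicardial vessel.
Transient steps therefore use a quasi-Newton update with a secant estimate
of \(dQ/dP\); steady solves, where the per-iteration secant underestimates
the slowly developing fluid response, use a relaxed update whose gain is
bounded through an a-priori vessel-conductance estimate
(\(\pi r_{max}^4 / 8\mu L\)), keeping the loop gain at 0.8 for any outlet
stiffness.  Sub-iterations are converged when the outlet pressure moves by
less than 1e-3 mmHg; replaying the recorded outlet flow through the
standalone RK4 integrator reproduces the coupled outlet pressure to ~0.3%.

**Problem sizes.**  The validation suite runs the Poiseuille oracle on a
200×30-cell grid (flow and velocity-profile errors ~1.2% and ~1.6%), the
pulsatile fixtures on 60×12 cells with 160 steps per cycle, and the grid
sensitivity study on 20×11 / 40×15 / 80×23 cells — sizes chosen so the
whole suite is a desk-scale computation while every claimed property is
still resolved.

# FFR and wall metrics

`Pa` is the area-averaged inlet cross-section pressure and `Pd` the
area-average at the virtual wire station.  Clinically the wire sits 2–3 cm
beyond the lesion; `compute_ffr()` defaults to a 20 mm offset and clips to
90% of the remaining vessel with a warning, while the pipeline default is
10 mm because the 30 mm synthetic vessel with a mid-segment throat cannot
accommodate the clinical offset.  The canonical FFR is the ratio of
cycle-averaged pressures over the final cycle ("FFR time point" is not a
uniquely defined instant; the instantaneous trace `FFR(t)` is also
returned, and a single-instant evaluation is available).

Wall shear stress is evaluated from the wall-adjacent cell: shear rate as
tangential velocity over wall distance, viscosity at that shear rate, sign
following the axial flow direction (axisymmetric flow has no
circumferential component).  With the default wall layering the first cell
centre sits ~2% of the radius off the wall, giving ~1% systematic error
against the Poiseuille closed form.  TAWSS is the trapezoidal cycle mean of
|WSS|; OSI is \(\tfrac12(1-|\overline{WSS}|/\overline{|WSS|})\in[0,0.5]\);
RRT is \(1/((1-2\,OSI)\,TAWSS)\) with `Inf` at OSI = 0.5 and a flag where
TAWSS vanishes.  HOLMES is exported optionally as
\(TAWSS\,(0.5-OSI)\) and carries a provenance flag: that definition is
adopted from the general WSS-metrics literature, not from a formula printed
in the framework's own description.

# Known limitations

* The solver straightens the centerline; curvature- and torsion-induced
  secondary flows are absent.
* Convection is upwind-biased (deferred central correction at blend 0.5);
  post-stenotic recirculation lengths on coarse grids are diffused.
* Rigid walls and a single outlet; no side-branch flow split (branches are
  pruned during segmentation, consistent with lumped outlet parameters).
* The imaging model is sufficient for the segmentation contract, not
  radiographically realistic; robustness to motion or foreshortening is out
  of scope.
* Synthetic FFR values on the bundled fixtures sit near the top of the
  clinical range (~0.95–0.99) because the 30 mm fixture vessel is shorter
  and its lesion more focal than a diseased LAD; the suite therefore tests
  orderings, identities and tolerances, not agreement with any patient
  value.
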