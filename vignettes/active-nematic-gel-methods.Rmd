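---
title: "Methods: quantifying flow-driven actin alignment with an active nematic gel model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying flow-driven actin alignment with an active nematic gel model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexflow)
```

## The scientific problem

During both pseudocleavage and cytokinesis in the *C. elegans* zygote, the
actomyosin cortex flows from posterior to anterior. Where this flow
decelerates, the cortical gel is compressed along the anterior–posterior
(AP) axis, and actin filaments reorient circumferentially — the geometry
needed for a contractile ring. `cortexflow` implements the quantitative
chain of analysis that connects these observations: measuring filament
orientation and flow from cortical images, fitting a one-dimensional
active nematic gel model to the resulting profiles, and predicting furrow
ingression from the anisotropic tension of the aligned gel. Because no
public imaging data accompany this pipeline, every step is exercised
end-to-end on synthetic data with known ground truth; the synthetic
generators are first-class, tested package code.

## The gel model

The scalar nematic order parameter is `Q = -Qxx` of the 2D nematic tensor,
positive when filaments align orthogonally to the AP axis. Its dynamics
along the AP coordinate `x` are

```
dQ/dt = -v dQ/dx - (beta/2) dv/dx - Q/tau + (ell^2/tau) d2Q/dx2
```

with `v(x)` the AP flow (um/min). The four processes are advection of
order by the flow, generation of order by compression (`-dv/dx > 0`
compresses the gel), relaxation toward isotropy with time constant `tau`
(min, e.g. by filament turnover), and spatial coupling of orientation over
the alignment length `ell` (um). During the stationary flow phase the
time derivative is dropped and, multiplying by `tau`, the steady profile
obeys the linear two-point boundary value problem

```
Q = -tau v dQ/dx - (beta*tau/2) dv/dx + ell^2 d2Q/dx2 [+ lambda'tau c(x)/c0 Q]
```

The optional last term is myosin-coupled *active* alignment: existing
order is amplified in proportion to the local myosin concentration
`c(x)` (normalised by its spatial mean `c0` over the fit region, a choice
this package makes explicit because the normalisation is otherwise
underdetermined). Only the products `beta*tau` (min) and `lambda'tau`
(dimensionless) are identifiable from steady profiles, which is why they
are the fitted quantities. The model is solved with Dirichlet boundary
values `C1`, `C2` at the edges of the fit region — the boundary placement
is itself a modelling choice; we put them at the fit-domain edges, the
most conservative option. Stability requires
`1 - lambda'tau c(x)/c0 > 0` everywhere; the solver raises an explicit
error otherwise, since beyond that threshold active alignment would
amplify order without bound and the linear steady state is meaningless.

### Numerics

The BVP is discretised with centred second-order finite differences on a
grid refined to at most 0.25 um (the fitted alignment lengths reach
~1.7 um and must be resolved by several points) and solved directly as a
sparse tridiagonal system. A fine-grid shooting integrator (independent
initial-value integrations combined by linearity) reproduces the solver
to better than 1e-4, and the uniform-compression closed form
`Q = beta*tau k/2` is exact to machine precision.

The dynamic equation is integrated with implicit (backward Euler)
relaxation and diffusion. Two advection schemes are provided: explicit
first-order upwinding (with a CFL guard `max|v| dt <= dx`), and a fully
implicit centred stencil. The centred scheme's fixed point coincides
exactly with the steady solver's discretisation, so dynamic-to-steady
consistency holds to the 1e-4 level at any grid; upwinding converges to
the same solution only at first order in `dx`, which we verify as a
convergence property rather than an identity.

## Fitting and identifiability

For fixed `(tau, ell, lambda'tau)` the steady solution is affine in
`(beta_tau, C1, C2)`. The fit exploits this: those three parameters are
profiled out *exactly* by linear least squares at every objective
evaluation, and a quasi-Newton search with a 4x4 log-spaced multi-start
grid runs over `(log tau, log ell)` (plus `lambda'tau` starts at 0 and
0.3 when the active term is enabled). This is deliberately different
from multi-starting over `(tau, beta_tau, ell)`: profiling the linear
directions removes three dimensions from the nonconvex search and makes
the noiseless recovery experiments exact to optimizer tolerance. Ties are
broken toward smaller `tau`.

When advection is weak (`|v| <= 1` um/min, the pseudocleavage regime),
`tau` only enters through the small term `tau v dQ/dx` and becomes
unidentifiable from below. Following the reporting convention of the
fitted tables, the fitter pins `tau` at a grid of values in `(0, 0.5]`
min, re-optimises the remaining parameters, and declares `tau` "< 0.5
(n.d.)" when the residual stays flat. Residual flatness is measured on
variance-normalised residuals `nrss = rss / sum((Q - mean Q)^2)` with an
absolute threshold (0.01 for the fitter's rule; 0.05 for the
identifiability scan): a rule *relative* to the optimum rss would be
ill-posed on noiseless synthetic data, where the optimum rss is zero to
machine precision. The identifiability scan itself refits only `C1, C2`
(a 2-column linear solve) at each scanned parameter value, and reports
the contiguous flat region around the minimum.

Uncertainty is quantified two ways, mirroring the two reporting styles of
the study: a nonparametric bootstrap over embryos (resample embryos with
replacement, average profiles, refit; median and 16th–84th percentile
interval) and a linearised 95% interval from the Jacobian of the
residuals at the optimum. Bootstrap refits are warm-started from the
full-data optimum plus a coarse grid; resampling is fully determined by
an explicit integer seed.

## Orientation quantification

Filament orientation is estimated per 32-px window (~3.2 um at the 0.1
um/px default — small enough to resolve alignment lengths of 1–6 um,
large enough to hold several filament widths), sliding with 50% overlap.
Each window is optionally rank-transformed through its empirical CDF
(histogram equalisation), which makes the estimator invariant to
monotone intensity rescaling; the window is then tapered (Hann),
Fourier-transformed, and the spectral power inside the annulus of spatial
periods 4–16 px is binned by wavevector angle (180 bins of 1 degree),
rotated by 90 degrees so angles refer to real-space filament orientation.
The azimuthal mean power at each radius — the isotropic noise floor — is
subtracted (clipped at zero) before binning, which counteracts the
downward bias of the order magnitude at low signal-to-noise. The nematic
tensor follows as the second circular moments
`Qxx = int p cos 2theta`, `Qxy = int p sin 2theta`; sub-bin accuracy
comes from these integrals, not from peak picking.

The synthetic meshwork generator grows filaments as persistent random
walks: starting positions uniform, starting angle drawn from a nematic
von Mises density `~ exp(B cos 2(theta - pi/2))` (uniform at `B = 0`,
concentrated toward vertical as `B` grows), per-step heading increments
Gaussian. Only the initial direction is biased, so the measurable order
saturates with `B` — the growth wander sets the ceiling. Filaments are
rendered by sub-pixel bilinear splatting, blurred with a Gaussian PSF,
and overlaid with Gaussian noise scaled so that peak signal over
background sd equals the requested SNR (the study names an SNR without a
formula; this is our definition, stated once and used consistently).
Growth-step and wander magnitudes (2 px and 0.15 rad by default) are this
package's choices — the source imaging study does not state the values it
used — picked so that a 40-px filament wanders visibly but stays
recognisably fibrous. The generator emulates orientation statistics,
density and noise of a cortical image; it does not emulate myosin foci,
bundling, or out-of-plane structure, so passing these tests validates the
orientation estimator, not biological realism.

## Flow measurement

PIV uses normalised cross-correlation of 32-px interrogation windows
(50% overlap), FFT-accelerated with the correlation renormalised by the
per-shift overlap area — without that renormalisation the finite window
biases peaks toward zero displacement. Subpixel refinement is the
standard 3-point Gaussian fit per axis; vectors with a weak correlation
peak are flagged invalid, and vectors deviating more than 2 neighbourhood
standard deviations from their 3x3 median are replaced by it. On
advected synthetic meshworks the pipeline recovers uniform shifts to
better than 0.1 px and a Gaussian-bump flow to under 0.2 px RMS.

Compression rates are centred differences of the Gaussian-smoothed
(sigma = 2 um by default; the study smooths its velocity profiles without
stating a kernel) velocity profile. Flow onset is timed by fitting
`v(t) = a + b erf((t - t0)/s)`; the stationary phase is the longest
window (>= 1 min) in which each monitored series stays within 10%
(relative to its window median) of that median — the study marks such
windows by eye, so the tolerance is a documented, testable stand-in.

## Correlations and delays

Profile cross-correlations are Pearson correlations of the overlapping
segments at each lag, restricted to the central 30 um and averaged over
the stationary time points; this normalisation keeps `C` in [-1, 1] by
construction. Peaks are localised by a Gaussian-plus-offset least-squares
fit within 5 um of the discrete maximum. In a stationary flow, a spatial
offset between co-moving fields corresponds to the temporal delay
`dt = dx / |v_mean|`, with `v_mean` the mean flow in the central
`[-10, 0]` um; the velocity's absolute value is used (the study does not
state signed versus absolute; signs are carried by the offset's
downstream projection instead). Myosin foci are sized by the radius at
which the azimuthally averaged image autocorrelation falls to 1/e, which
equals twice the Gaussian radius for an isolated Gaussian focus.

## Ingression

The outer ingression distance is `u(x) = R0(x) - r(x)` relative to the
rigid eggshell. Its prediction uses a small-deformation treatment: the
cortical tension has an isotropic active part proportional to `c/c0`
shared by the AP (`t_ss`) and circumferential (`t_phiphi`) components, a
viscous part proportional to `dv/dx` on the AP component, and an
anisotropic active part `p3 Q` added circumferentially and subtracted
axially — aligned filaments pull harder along their axis. The inward
normal traction is `t_phiphi / R0` plus the AP tension times the
meridional curvature of the reference shape; where it exceeds its
confinement-balancing baseline (the fit-region mean, so a uniform cortex
ingresses nowhere) the cortex moves inward proportionally, with one
global scale parameter shared between pseudocleavage and cytokinesis and
fitted in closed form. The full nonlinear axisymmetric shape problem is
out of scope: outer ingressions are at most a few um against a ~15 um
radius, so the linear response captures the comparison that matters —
the isotropic control (`p3 = 0`) strictly underperforms the anisotropic
model on data generated with tension anisotropy. Under noise, `p3`
trades off against the shared scale wherever the myosin band and the
alignment band overlap spatially; the noiseless round trip is exact.

## Study conditions used by the synthetic experiments

The synthetic experiments fix the flow conditions once, at the scales the
imaging study reports: a cytokinesis-like Gaussian-bump flow (peak speed
5.77 um/min placed so the compression peak of ~0.7/min sits at the embryo
centre) and a pseudocleavage-like weak front (`|v| <= 1` um/min, central
compression peak ~0.4/min), both on `x in [-15, 15]` um sampled at 0.5 um
with boundary order 0.05; measurement noise on Q of sd 0.02 per embryo
and 10–12 embryos per condition where replication matters. Meshwork
images are 256x256 px at 0.1 um/px with 60–120 filaments. These sizes
keep every experiment comfortably within interactive runtimes while
leaving all recovery margins wide.

## Known limitations

* The flow field is always an input; the package does not model how
  myosin contractility generates it.
* The fit is one-dimensional along the AP axis; no 2D tensor-field
  fitting.
* The ingression model is linear-response with a single shared scale; it
  is a comparison tool for isotropic versus anisotropic tension, not a
  shape simulator.
* Synthetic data shares the generating model of the fit, so recovery
  tests demonstrate correctness of the estimation machinery, not model
  adequacy for real cortices.
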