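---
title: "Symmetric group-wise modeling of serial MRI: methods and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetric group-wise modeling of serial MRI: methods and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`longreg` fits a single generative model to $N \ge 2$ scans $f_n$ of one
subject.  Each scan is assumed to be a deformed copy of an evolving
within-subject template $\mu$, scaled by a smooth multiplicative
inhomogeneity field, with known additive Gaussian noise of precision
$\lambda_n$:

$$f_n(\varphi_n(x)) \approx \mu(x)\, e^{b_n(\varphi_n(x))},
  \qquad \varphi_n = \xi_{q_n} \circ \phi_{v_n}.$$

The deformation composes a rigid-body transform $\xi_{q_n}$, parameterized
by a vector $q_n$ in the Lie algebra of SE(3) (SE(2) for 2D problems), with
a diffeomorphism $\phi_{v_n}$ generated by geodesic shooting of an initial
velocity field $v_n$.  The objective is the sum of the precision- and
Jacobian-weighted squared residuals plus quadratic penalties
$\tfrac12\|L_v v_n\|^2$ and $\tfrac12\|L_b b_n\|^2$ on the velocities and
log-fields.

Three zero-mean constraints keep the template an *average* of the group
rather than an arbitrary gauge choice: $\sum_n q_n = 0$ (the template stays
in the average position), the mean momentum $\tfrac1N\sum_n L_v^\dagger L_v
v_n$ is the zero field (average shape), and in the stand-alone
inhomogeneity mode $\sum_n b_n = 0$ voxel-wise, so the geometric mean of
the multiplicative fields is one (average intensity).  Because every scan
relates to one template, pairwise registration is inverse consistent by
construction and multi-time-point registration is transitive: the map from
scan $m$ to scan $n$ is exactly $\varphi_n \circ \varphi_m^{-1}$
(`map_between()`).

The template grid itself is placed at the group average position: the
exponential barycenter of the scans' voxel-to-world affines (the
bi-invariant group mean, found by a matrix-log fixed point iterated to
1e-10 in the Frobenius norm, at most 100 iterations), projected onto the
closest translation-rotation-axis-aligned-scaling transform by
Levenberg-Marquardt on the Frobenius distance (parameterized by
translations, the rotation Lie algebra, and log-scales — log-scales keep
the scales positive without constraints).  Template voxel sizes default to
per-axis geometric means of the input voxel sizes, and the bounding box of
all projected image corners gets a 2-voxel margin.

## Geodesic shooting

A diffeomorphism is generated from its initial velocity by Euler
integration of the EPDiff system over unit time: the initial momentum $u =
L_v^\dagger L_v v$ is transported by the evolving inverse map (resampled,
multiplied by the transposed Jacobian and its determinant), smoothed by the
Green's function $K$ of $L_v^\dagger L_v$ to give the current velocity, and
both the forward and inverse maps are updated by composition.  The step
count is $\lceil 3\,T \rceil + 2$ for a time interval of $T$ years (so 5
steps in pure group-wise mode).  Momentum conservation — $\|L v_t\|^2$
constant along the trajectory — is the accuracy diagnostic: its drift
decreases as steps are added, and the integrator uses cubic interpolation
internally because with linear interpolation the interpolation diffusion,
not the Euler error, dominates the drift and step refinement stops helping.

The operator combines linear elasticity and bending energy with weights
$(\omega_1, \omega_2, \omega_3)$ for stretch/shear, divergence, and bending,
plus an optional absolute-displacement weight $\omega_0$ (zero by default:
translations belong to the rigid part, so the DC coefficient of $K$ is set
to zero and velocities are kept DC-free).  $\omega_3 > 0$ is enforced
whenever $\omega_0 = 0$, because pure length-change or divergence penalties
have Green's functions with point singularities.  Everything is applied
spectrally under circulant boundaries; velocities are stored in voxel units
and anisotropic voxel sizes enter the operator symbol through the per-axis
spacings.  The defaults $(0.001, 0.001, 2.0)$ are the bending-dominant
regime, which behaved best in the package's own regularization study
(below).

## Inhomogeneity fields

Log-fields $b_n$ live on each scan's own grid (the artifact belongs to the
acquisition, not the anatomy), are carried by linear interpolation, and are
penalized by the bending energy $\omega_{b0}\sum (\nabla^2 b)^2$ with
Neumann boundaries.  Their spatial gradients are represented by a separately
interpolated centered-difference field with mirror (zero normal derivative)
edges — consistent with both the Neumann condition and symmetric variations
of the kinked linear interpolant, which is what the finite-difference
derivative checks probe.  During the combined fit the data-term derivatives
are computed on the template grid and pushed through the inverse
deformation to the scan grids; the fields are deliberately *not*
mean-corrected there (only $N-1$ relative fields are identifiable; the
residual gauge freedom trades a common log-field against the template
intensities and is harmless).  `bias_omega0` defaults to `1e6`
(mm$^4$-scaled), which leaves decimeter-wavelength modulations nearly free
while crushing voxel-scale variation; the synthetic studies use smaller
values matched to their grid sizes.

## Optimization

All three parameter groups are updated by safeguarded Gauss-Newton against
the single evolving template, interleaved in the order rigid →
inhomogeneity → velocity within each outer iteration, with the template
(and its gradients) re-estimated between groups and the constraints
re-imposed after each group.  The linear systems — diagonal-plus-bending
for the fields, rank-one-plus-operator for the velocities — are solved by
preconditioned conjugate gradients with spectral (circulant) inverses as
preconditioners; on grids up to $16^2$ the solutions match dense direct
solves to 1e-6, which is the package's substitute for the full multigrid
solver a production implementation would use.

Several numerical choices here were forced by experiments on the
piecewise-constant simulated pair, and are worth recording:

* **Per-scan data gradients.**  The group-blended gradient field (the
  weighted blend of pulled-back scan gradients) is the classical choice for
  driving the template-based updates, and it is exposed and tested
  (`template_gradients()`, `combined_gradients()`).  The fit drivers,
  however, use the per-scan form $g_n = e^{-b'_n}\nabla f'_n - \mu \nabla
  b'_n$: by the envelope theorem it is the exact gradient of the
  template-profiled objective, it shares the blended form's fixed point,
  and — unlike the blend — it is measurably a descent direction for the
  per-scan safeguarded objective on large-residual images.
* **Exact discrete Jacobian-variation term.**  The derivative of the
  warped-image data term under composition with a small displacement
  includes the variation of the Jacobian determinants.  Discrete
  integration by parts (the central-difference gradient is the exact
  negative adjoint of the central-difference divergence under wrap) folds
  that term in exactly (`exact_data_gradient()`); in the continuum this is
  precisely what turns warped-scan gradients into template-gradient form.
* **Levenberg-Marquardt safeguarding.**  Rank-one Gauss-Newton Hessians
  badly underestimate curvature where residuals saturate (piecewise
  constant images), and plain step-halving of a poor direction stalls.  On
  rejection the system is re-solved with the regularizer inflated, which
  degrades gracefully into a short Green's-function-smoothed gradient step;
  a bounded line search along that smoothed direction is the final
  fallback.  Zero gradient maps to zero step at any damping, so fixed
  points are unchanged.
* **A global safeguard around the momentum correction.**  The zero-mean
  momentum projection is not a descent step, and when the per-scan updates
  are accepted at different sizes it can undo their progress.  Each
  iteration's velocity steps are therefore scaled *together* until the
  corrected group state does not increase the total objective; at scale
  zero the correction is a no-op because the constraint already held at
  the iteration start, so the search always terminates.
* **Stable integration domains.**  Field-of-view masks are frozen during
  each scan's update: voxels entering and leaving the mask under
  infinitesimal trial steps otherwise produce spurious objective jumps
  that the safeguard misreads.  In the aligned-grid diffeomorphic driver
  the whole grid is the domain.
* **Coarse-to-fine by image smoothing, not resampling.**  A conventional
  pyramid changes the operator metric between levels, and a velocity
  prolonged from a coarse level shoots to a measurably different
  deformation under the finer metric (template correlation dropped from
  0.985 to 0.75 at a transition in development), stranding the optimizer.
  The fit drivers instead smooth the images on a fixed grid (stage $\ell$
  uses $2\cdot4^{\ell-2}$ passes of a 1-2-1 kernel), so all stages share
  one metric and parameters carry over unchanged.  The resampling pyramid
  utilities (`build_pyramid()`, `restrict_image()`, `prolong_velocity()`)
  remain available.

The combined objective uses the $\tfrac12$ factors on both penalty terms,
matching the component objectives and the printed derivatives (the
unhalved penalties that appear in one statement of the combined objective
are treated as a typographical slip; with them the gradients would not be
the derivatives of the objective and the safeguard would reject valid
steps).

## Acquisition timing

With acquisition times given, the template sits at the median time and each
scan's operator is scaled by $1/|t_n|$ (energy per unit time), clamped at
one day; scans at the reference time are pinned at zero velocity, and their
Green's functions are so stiff that the momentum mean-correction leaves
them there.  Because $K_n L_n^\dagger L_n$ is the same off-DC projection for
every scan regardless of its time scaling, the mean-momentum constraint is
satisfied exactly even with per-scan kernels.

## Noise estimation

Scanner noise is estimated by fitting a two-component Rician mixture to a
256-bin histogram of the intensities up to the 99.9th percentile, by EM on
the binned counts with moment-matching M-steps through the SNR fixed-point
inversion; the smaller fitted variance is the noise estimate.  Two
refinements guard the degenerate cases: a single-component and a
Rayleigh-constrained ($\nu = 0$) model are compared by BIC, and a
low-SNR noise component ($\nu/\sigma < 1$) is re-read through its
responsibility-weighted Rayleigh maximum likelihood, because near the
Rayleigh floor the $\nu$–$\sigma$ split is ill-determined and the moment
inversion alone carries a few-percent bias.  Averaged inputs with
non-Rician noise are handled identically, as intended default behavior.

## What the synthetic studies do and do not show

The generators (`make_figure3_pair()`, `make_biased_pair()`,
`make_warped_pair()`) define the package's study conditions:

* the simulated shape pair is 256×128 (scaled down to 128×64 in the
  regularization study and 64×32 in the inverse-consistency checks) with
  intensities in [0, 1], circles and ellipses of exactly matched areas and
  anti-aliased edges;
* bias pairs use a smooth Gaussian random log-field (standard deviation
  0.15, 8–10-voxel correlation length) at SNR 50;
* warped pairs are generated by shooting $\pm v_0/2$ from a midpoint image
  with the package's *own* integrator (amplitude 2 voxels, 8-voxel
  correlation length), an inverse crime by design: recovery closes a loop
  and validates the estimator, not registration accuracy on real data.
  Recovery studies use textured images because velocities are only
  observable where images have contrast.

Passing these studies shows internal consistency — exact swap symmetry,
constraint conservation, positive Jacobians, calibrated operators and
derivatives, parameter recovery under the model's own assumptions, and the
qualitative regularization-regime pattern (similar warped images, sharply
different volume-change maps, with the divergence-dominant regime's
$|\log\det J|$ far below the bending regime's).  They do not demonstrate
accuracy on real brains: no tissue classes, no skull, no partial fields of
view, no real scanner artifacts.

Problem sizes were chosen so the whole default test suite and the
acceptance script each run comfortably on a single CPU: derivative checks
on $16^2$–$32^2$ grids, recoveries at $32^2$–$64^2$, and the regime study
at 128×64 with three smoothing stages and 10 outer iterations per stage.

## Known limitations

* Appearance change that is genuinely anatomical (myelination, lesions) is
  mis-attributed to the inhomogeneity fields or the warps; the model treats
  all intensity modulation as acquisition artifact.
* The velocity updates optimize initial velocities only (geodesic
  shooting); no full time-dependent path optimization is attempted.
* The periodic boundary convention of the velocity operator means content
  near opposite image edges interacts weakly; real-data use should pad the
  field of view.
* 2D problems are first-class (and used throughout the tests); 3D code
  paths are exercised by smaller smoke tests only.

## A worked example

```{r example}
library(longreg)

dims <- c(64L, 32L)
pair <- make_figure3_pair(dims)
scans <- list(scan_image(pair$A, diag(3), lam = 400),
              scan_image(pair$B, diag(3), lam = 400))
fit <- fit_longitudinal(scans, config = longit_config(levels = 2L,
                                                      max_iter = 5L))
fit
# divergence of the first scan's initial velocity: the expansion map
div1 <- divergence_field(fit$velocities[[1]], fit$space$dims)
```
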