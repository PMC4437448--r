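---
title: "Quantitative stroke MRI with strokevol: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative stroke MRI with strokevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokevol)
```

## The measurement problem

Temporary middle cerebral artery occlusion (MCAO) in the rat produces a
cortical and striatal infarct accompanied by vasogenic edema: blood–brain
barrier leakage raises extracellular water, which both prolongs the T2
relaxation time of the tissue and swells the ipsilateral hemisphere,
displacing midline structures. A single multi-echo T2-weighted (CPMG)
acquisition supports three complementary readouts: voxel-wise T2 maps (and
from them an ipsilateral–contralateral T2 difference as an edema measure),
hemispheric/lesion volumetry (with the lesion burden corrected for the
space-occupying effect of the swelling), and the midline shift. strokevol
implements all three, plus the two-group statistics used to compare
treatment arms, and a synthetic phantom generator that provides ground
truth for every stage.

Segmentation itself is out of scope: hemisphere and lesion outlines enter
as integer label masks, exactly as manual planimetric tracing would produce
them. The pipeline begins where tracing ends. A single consensus mask per
animal is assumed; inter-rater combination is not modelled.

## T2 relaxometry

Each voxel's echo train is modelled as a mono-exponential magnitude decay
without constant offset,

$$S(TE) = S_0 \, e^{-TE/T_2},$$

the minimal standard model for a CPMG train when no multi-component or
stimulated-echo correction is attempted. Two estimators are provided:

* **`log_linear`** — weighted linear regression of $\ln S$ on $TE$ with
  weights $S^2$. These are the classical variance-stabilizing weights: if
  the noise on $S$ is homoscedastic, the noise on $\ln S$ scales as $1/S$,
  so weighting by $S^2$ restores efficiency. The solution is closed-form and
  fully vectorized, which is why it is the default for whole-volume maps.
* **`nonlinear`** — least squares on the native signal scale, initialized
  from the log-linear solution and optimized over $(\log S_0, \log T_2)$,
  an unconstrained parametrization that keeps both parameters positive. It
  was verified to agree with `stats::nls` to machine precision on the same
  objective.

Echoes at or below a configurable **noise floor** are dropped per voxel
(default floor 0; when a background noise SD is supplied the floor is
$k\sigma$ with $k = 3$). A fit is marked invalid — never clipped — when
fewer than 3 echoes survive, the fitted slope is non-decaying, $T_2$ falls
outside the plausibility bounds $[1, 1000]$ ms (generous for 7 T tissue),
or the native-scale $R^2$ is negative. $R^2$ is computed on the native
signal scale for both methods so their quality measures are comparable.

The edema readout mirrors the ischemic-core ROI across the sagittal
midline plane to define the contralateral reference ("corresponding
position on the contralateral hemisphere"), pools ROI voxels across all
lesion-bearing slices (voxel-weighted, not slice-averaged — unbiased when
ROI size varies across slices), averages valid voxels only, and reports
$\Delta T_2 = \bar T_2^{\mathrm{ipsi}} - \bar T_2^{\mathrm{contra}}$.

A note on attainable precision: at a first-echo SNR of 50 the Cramér–Rao
bound for $T_2$ from a 12-echo train at TE 18–216 ms is roughly 2.6–3.2%
relative SD over $T_2 \in [40, 90]$ ms, i.e. a median absolute relative
error just under 2%. The estimator operates essentially at this bound;
claims of much higher single-voxel precision at this SNR would be
information-theoretically impossible, which is why ROI averaging matters.

## Volumetry and edema correction

Volumes follow the planimetric rule — region area per slice summed over
slices, times the slice thickness — generalized to gapped protocols as
$V = N_{\mathrm{vox}} \cdot d_{xy}^2 (d_z + g)$ with in-plane spacing
$d_{xy}$, thickness $d_z$ and gap $g$ (default 0). Percentages are computed
from mm³, never voxel counts, so results are invariant to
volume-preserving resampling.

With $HV_c$, $HV_i$ the contralateral/ipsilateral hemisphere volumes and
$LV$ the lesion volume:

$$\%HLV_{uc} = \frac{LV}{(HV_c + HV_i)/2} \cdot 100, \qquad
\%HLV_{ec} = \frac{HV_c^2 + LV(HV_c + HV_i) - HV_i^2}{HV_c (HV_c + HV_i)}
\cdot 100.$$

The corrected expression is algebraically
$100\,(LV - (HV_i - HV_c))/HV_c$: the swelling $HV_i - HV_c$ is removed
from the lesion and the remainder expressed against the unaffected
hemisphere. Both forms are evaluated at run time and required to agree to
$10^{-9}$ relative — a permanent internal consistency check. When swelling
exceeds the lesion the corrected value is negative; it is **reported as-is
with a warning**, because silent clipping would hide generator or mask
errors. The per-animal denominators are used throughout (the alternative —
group-level denominators — is not supported; per-animal is the natural
reading when each animal contributes one row).

Midline shift is $MLS = (A - B)/2$ from the bilateral
cortex-to-third-ventricle distances, evaluated on every supplied slice and
reported at the slice of maximum displacement; ties break toward the lowest
slice index for determinism. Landmarks are first-class inputs (they are
measured manually on T2-weighted images in practice);
`landmarks_from_ventricle()` derives them from a ventricle mask for
phantoms, but supplied landmarks always take precedence.

## Two-group statistics

Endpoints are compared with the classical pooled-variance Student t-test
(default, and reported alongside its Welch counterpart), or the
Mann–Whitney U test. The summary-statistics entry point
`t_test_from_summary()` exists because published comparisons must be
reproducible from printed mean ± SD values. Exact Mann–Whitney p-values are
computed from the exact U distribution (count recurrence) whenever
$n_1 + n_2 \le 12$ and there are no ties — the two-sided p is the
probability of a U at least as far from $n_1 n_2 / 2$ as observed — and
otherwise from the normal approximation with tie correction and a 0.5
continuity correction. The threshold 12 covers the n = 8 + 8 design while
keeping enumeration instant. α is 0.05 by default and configurable. **No
multiple-testing correction is applied**, matching common practice in this
literature; with five endpoints per study this is a real limitation and the
per-endpoint p-values should be read accordingly.

Both rounded summaries and small n mean published p-values are generally
not recoverable exactly; only significance bounds (p < 0.05 vs p > 0.05)
are stable under rounding, and that is what the package's acceptance tests
assert.

## The synthetic phantom: what it emulates, and what it does not

Each phantom slice contains two half-ellipse hemispheres anchored at a
midline displaced by $d$ toward the contralateral side. The contralateral
in-plane semi-axis is $a_c$; the ipsilateral one is $a_i = a_c (1 + s)$, so
the hemisphere volume ratio is $1 + s$ by construction (the swelling
factor $s$, drawn per animal). The third ventricle sits on the displaced
midline, so the construction's true midline shift is
$(a_i - a_c)/2$ — with $s = 0$ the phantom is symmetric and the shift is 0.
The default $d = a\,s/2$ ties displacement to swelling, which is the
qualitative behaviour seen in space-occupying edema. The lesion is the set
of $k$ ipsilateral voxels nearest (in mm) to a lateral cortical/striatal
focus, with $k$ chosen to hit the requested lesion fraction exactly to one
voxel — contiguous, cortico-striatal in position, and quantitatively
controlled. The ischemic-core ROI is the inner 30% of that ordering, i.e.
an eroded lesion core safely away from the midline.

Default acquisition and tissue values state the world the package targets:
8 contiguous 2 mm slices, 37 × 37 mm FOV, 12 echoes at TE 18–216 ms;
tissue T2 50 ms and lesion T2 70 ms (a 20 ms vasogenic elevation; CSF
150 ms), S0 ≈ 1000; Rician noise with $\sigma = S_{0,\mathrm{tissue}}/SNR$,
SNR 50. The in-plane matrix defaults to 128 × 128 rather than a scanner's
512 × 256 — the geometry is resolution-independent and this keeps desk-scale
runtimes; the drawn ventricle is floored at about half a voxel so the
midline structure survives coarse test matrices. The default contralateral
hemisphere volume (550 mm³) is a typical adult rat value.

Ground-truth volumes are defined as the **voxel counts of the generated
masks** (times the voxel volume): the masks are exactly what downstream
volumetry consumes, so volumetric recovery from truth masks is exact and
deterministic, and noise affects only the relaxometry endpoints. This is a
deliberate choice: it isolates the formula pipeline from segmentation
error. Consequently a green end-to-end volumetry test establishes the
correctness of the computation, **not** robustness to tracing variability —
for that, `perturb_mask()` dilates/erodes the lesion boundary by k voxels
as an explicit, separate experiment. The phantoms likewise do not model
real anatomy, partial-volume effects, B0/B1 inhomogeneity or motion.

Cohorts draw per-animal lesion fraction, swelling factor and lesion T2
elevation from truncated-normal group distributions (truncation to
physically valid ranges: fraction in [0.02, 0.6], swelling in [0, 0.35],
elevation in [1, 80] ms). The paper-like preset (two arms, n = 8) gives the
treatment arm larger lesions, more swelling and higher T2 elevation at
plausible scales; it is a qualitative stand-in, and no test asserts
quantitative equality between simulated and any published group means.
Per-animal seeds are derived from the master seed by a fixed integer hash,
so identical master seeds give bit-identical cohorts.

## Numerical and interface choices

* **1-based voxel indices** (R-native) with the slice axis third;
  "ipsilateral" is the larger-x half (right-hemisphere occlusion
  convention), overridable via each mask's `midline_x`.
* **NIfTI-1 I/O is implemented natively** (uncompressed `.nii`, both
  endiannesses, float64 by default so round trips are bit-exact) because
  the target installation carries no R NIfTI package; echo times live in a
  JSON sidecar rather than header extensions — bit-exact, human-readable,
  dialect-free.
* Label masks are single integer volumes with hierarchical region
  semantics: the ipsilateral hemisphere includes the lesion and its core
  ROI, the lesion includes its core. The lesion-inside-ipsilateral
  invariant is validated geometrically against the declared midline at read
  time.
* Degenerate statistics are conventions, not errors: two zero-variance
  groups give p = 1 when means agree and p = 0 (with a warning) when they
  differ; all-noise voxels yield `valid = FALSE` fits rather than
  exceptions.
* Where a maximum is selected (midline-shift slice), ties break toward the
  lowest index; every stochastic routine takes an explicit seed.

## A short demonstration

```{r demo, eval = FALSE}
ph  <- generate_phantom(phantom_spec(lesion_fraction = 0.2,
                                     swelling_factor = 0.1, seed = 7))
res <- analyze_animal(ph$image, ph$truth$mask, ph$truth$landmarks,
                      noise_floor = 60)
res[, c("pct_hlv_uc", "pct_hlv_ec", "mls_mm", "delta_t2")]

gen <- generate_cohort(paperlike_cohort_defaults(master_seed = 1))
results <- analyze_cohort(gen, noise_floor = 60)
compare_cohort(results, c("pct_hlv_uc", "pct_hlv_ec", "mls_mm", "delta_t2"))
```

## Known limitations

Mono-exponential T2 only (no multi-component water pools, no EPG/stimulated
echo correction, no B1 mapping); landmark-based midline shift (no
deformation field); no automated segmentation; no multiple-testing
correction; phantom anatomy is elliptical, not atlas-based. These bounds
are deliberate: the package models the computation chain downstream of
acquisition and tracing, and models it completely.
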