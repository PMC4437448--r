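# strokevol

Quantitative T2 relaxometry and edema-corrected lesion volumetry for
multi-echo MRI of experimental stroke in the rat.

## What it does

After middle cerebral artery occlusion (MCAO), the standard quantitative
readouts from a multi-echo T2-weighted (CPMG) acquisition are:

- **T2 relaxation time (T2-RT).** Each voxel's echo train is fitted with the
  mono-exponential decay `S(TE) = S0 · exp(−TE / T2)`. The vasogenic-edema
  readout is `ΔT2 = T2(ischemic-core ROI) − T2(mirrored contralateral ROI)`,
  pooled over all lesion-bearing slices.
- **Hemispheric lesion volumetry.** Region areas are summed over slices and
  multiplied by the slice thickness. With `HVc`/`HVi` the contralateral /
  ipsilateral hemisphere volumes and `LV` the lesion volume:

  ```
  %HLVuc = LV / ((HVc + HVi) / 2) · 100
  %HLVec = (HVc² + LV·(HVc + HVi) − HVi²) / (HVc·(HVc + HVi)) · 100
  ```

  The edema-corrected form is algebraically `100·(LV − (HVi − HVc)) / HVc`:
  the space-occupying swelling `HVi − HVc` is subtracted from the lesion and
  the result is expressed against the unaffected hemisphere.
- **Midline shift.** `MLS = (A − B) / 2` from the bilateral
  cortex-to-third-ventricle distances at the slice of maximum lateral
  ventricle displacement.
- **Two-group statistics.** Mean ± SD summaries, Student (pooled) and Welch
  t-tests — including directly from published summary statistics — and a
  Mann–Whitney U test with exact small-sample p-values.

Because such studies rarely deposit images, the package ships a synthetic
phantom generator: multi-slice two-hemisphere brains with a cortical+striatal
lesion of elevated T2, ipsilateral swelling that displaces the midline, a
CPMG echo train (12 echoes, TE 18–216 ms, 2 mm slices) and Rician noise, all
with exact ground truth. Every pipeline stage is testable end to end.

It is aimed at preclinical stroke researchers who have segmented multi-echo
data (NIfTI images and label masks) and want reproducible volumetry,
relaxometry and statistics, and at methodologists who want a controlled test
bed for those computations.

## Worked example

```r
library(strokevol)

# a synthetic animal: 20% lesion, 10% swelling, Rician noise at SNR 50
ph  <- generate_phantom(phantom_spec(lesion_fraction = 0.2,
                                     swelling_factor = 0.1, seed = 7))
res <- analyze_animal(ph$image, ph$truth$mask, ph$truth$landmarks,
                      noise_floor = 60)
res[, c("pct_hlv_uc", "pct_hlv_ec", "mls_mm", "delta_t2")]
#> # A tibble: 1 × 4
#>   pct_hlv_uc pct_hlv_ec mls_mm delta_t2
#>        <dbl>      <dbl>  <dbl>    <dbl>
#> 1       21.1       10.8  0.289     20.1
```

The uncorrected lesion occupies 21.1% of the mean hemisphere volume; after
subtracting the swelling term the edema-corrected burden is 10.8%; the
midline is displaced 0.29 mm toward the contralateral side; and lesion T2
is elevated by 20.1 ms over the mirrored contralateral tissue (the generator
truth is exactly 20 ms).

A whole cohort, compared between groups:

```r
gen <- generate_cohort(paperlike_cohort_defaults(master_seed = 1))
results <- analyze_cohort(gen, noise_floor = 60)
compare_cohort(results, c("pct_hlv_uc", "pct_hlv_ec", "mls_mm", "delta_t2"))
```

And a comparison straight from published summary statistics (mean ± SD,
n = 8 per group):

```r
t_test_from_summary(27.1, 11.1, 8, 14.3, 7.2, 8, variant = "pooled")
#>   test     statistic    df p_two_sided significant
#>   t_pooled      2.74    14      0.0161 TRUE
```

`tidy()`/`glance()` methods summarize fitted T2 maps and masks;
`autoplot()`, `plot_decay()` and `plot_endpoint()` produce the standard
figures.

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch: it simulates
a two-arm cohort (n = 8 per group) under the default acquisition, analyzes
every animal (T2 mapping, ROI ΔT2, volumetry with and without edema
correction, midline shift), runs the group comparisons, recomputes the
published-summary t-tests, and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
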