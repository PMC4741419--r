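# t1pve — partial-volume estimation for deep gray matter on quantitative T1 maps

Voxels in the deep gray matter nuclei (thalamus, caudate, putamen,
pallidum) mix gray-matter (GM) and white-matter (WM) tissue, so a change
in the region-average T1 of a patient group cannot be attributed to a
specific tissue pool. `t1pve` disentangles the two components on
quantitative T1 relaxometry maps and carries the separation through to
group statistics. It is aimed at neuroimaging researchers comparing
patient cohorts (e.g. early multiple sclerosis vs healthy controls) on
co-registered T1 maps with region labels and optional lesion masks.

## The model

Each voxel of a region follows the two-tissue mixture

```
y_i = mu_GM * c_i + mu_WM * (1 - c_i) + eps_i,   eps_i ~ N(0, sigma^2)
```

with `c_i` in `[0, 1]` the local GM concentration and `(mu_GM, mu_WM)`
the region-global *characteristic intensities* — the T1 of 100% GM and
100% WM tissue. `fit_pve()` alternates, from the standard 3T start
(1350/850 ms) for 10 iterations:

1. the closed-form clamped concentration update
   `c = clamp((y - mu_WM) / (mu_GM - mu_WM), 0, 1)`, and
2. re-estimation of `(mu_GM, mu_WM, sigma)` by maximum likelihood under
   a uniform concentration prior — a box ⊗ Gaussian marginal whose
   `1/(mu_GM - mu_WM)` factor makes the problem identifiable — with the
   intensities constrained to the observed intensity range.

Per subject and region the pipeline extracts the feature triple
`(mu_GM, mu_WM, C_GM/C_WM)` plus the lesion-excluded mean T1, and
compares groups with (i) a MANOVA (Pillai's trace) on the triple with
age and sex as covariates, (ii) two-tailed permutation t-tests per
component (Freedman–Lane residual permutation), and (iii) a classical
global-averaging t-test on mean T1, with Bonferroni or max-statistic
FWE multiplicity correction. A synthetic phantom/cohort generator
(`generate_phantom()`, `generate_cohort()`) provides ground-truthed data
for all of it. See `vignette("t1pve-methods")` for the full account.

## Worked example

Fit one simulated thalamus (about 3000 voxels, noise SD 50 ms, true
intensities 1389/912 ms):

```r
library(t1pve)
ph  <- generate_phantom(phantom_truth(noise_sd = 50, seed = 42), subject_id = "demo")
fit <- fit_region(ph$t1, ph$labels, "thalamus")
fit
#> <pve_fit> 2979 voxels, 10 iteration(s)
#>   mu_gm = 1395.42 ms, mu_wm = 916.34 ms, sigma = 50.71 ms
#>   final RSS = 4.466e+05 ms^2, mean c_gm = 0.502
```

The characteristic intensities land within a few ms of the truth and the
noise SD is recovered. A small cohort (10 controls vs 20 patients drawn
from the default group parameters, where only the thalamic GM pool
differs between groups) run through both analysis arms:

```r
spec <- cohort_spec(n_control = 10, n_patient = 20, seed = 7)
gen  <- generate_cohort(spec)
cfg  <- default_run_config()
cfg$regions <- c("thalamus", "putamen"); cfg$stats$n_perm <- 999
feats <- extract_cohort_features(gen$cohort, cfg, volumes = gen$volumes)
run_comparison(feats, gen$cohort, cfg)[, c("region","arm","feature","statistic","p_raw","p_corrected")]
#>    region          arm feature statistic   p_raw p_corrected
#>  thalamus    pv_manova    <NA>   0.43672 0.00285     0.00569
#>  thalamus pv_component   mu_gm   3.95895 0.00100     0.00300
#>  thalamus pv_component   mu_wm   1.30433 0.21900     0.65700
#>  thalamus pv_component   ratio   0.00702 0.99000     1.00000
#>  thalamus  global_mean mean_t1   3.27872 0.00296     0.00592
#>   putamen    pv_manova    <NA>   0.17534 0.19350     0.38699
#>   putamen pv_component   mu_gm   0.28613 0.77100     1.00000
#>   putamen pv_component   mu_wm   0.00212 0.99800     1.00000
#>   putamen pv_component   ratio   2.11839 0.04600     0.13800
#>   putamen  global_mean mean_t1  -0.64778 0.52281     1.00000
```

The MANOVA flags the thalamus and the component tests attribute the
difference to the GM characteristic T1 (`mu_gm`, permutation p = 0.001),
while WM and the concentration ratio are unremarkable — the injected
effect, correctly localized and attributed.

## Command line

```sh
Rscript inst/cli/t1pve.R simulate --spec spec.yaml --out data/ --seed 1
Rscript inst/cli/t1pve.R fit      --cohort data/cohort.csv --out fits/ --write-maps
Rscript inst/cli/t1pve.R compare  --features fits/features.csv --cohort data/cohort.csv \
                                  --out results/ --correction bonferroni --n-perm 10000 --seed 1
```

`simulate` writes NIfTI volumes, a cohort CSV and a truth manifest;
`fit` writes the per-subject feature table (and GM concentration maps
with `--write-maps`); `compare` writes a results CSV and a text report.

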