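# muscledti

Test-retest repeatability analysis for skeletal-muscle diffusion tensor
imaging (DTI), with intravoxel incoherent motion (IVIM) perfusion
correction — an end-to-end, fully simulated pipeline for bilateral
upper-leg studies.

## Who this is for

Quantitative-MRI researchers who need to (a) process multi-b-value muscle
DWI into per-muscle DTI indices with and without perfusion correction, and
(b) quantify how repeatable those indices are across scan sessions — the
precondition for using them to track injury and recovery. Since raw
patient data cannot ship with a package, a synthetic two-session leg
phantom with known ground truth exercises every stage and doubles as the
test bed.

## The models at the core

**Signal model.** Per voxel, with b-value $b$ (s/mm²) and unit gradient
direction $g$:

```
S(b, g) = S0 [ f exp(-b Dp) + (1 - f) exp(-b gᵀ D g) ]
```

`f` is the microvascular (pseudo-diffusion) fraction, `Dp` its
pseudo-diffusivity, and `D` the 3×3 tissue tensor with eigenvalues
λ₁ ≥ λ₂ ≥ λ₃, MD = (λ₁+λ₂+λ₃)/3 and the standard FA expression.

**Pipeline.** (1) Marchenko–Pastur PCA denoising with a per-voxel noise σ
map; (2) per-voxel IVIM fit on the shell-averaged decay
(Levenberg–Marquardt, init S0 = 1, f = 0.05, D = 0.003, Dp = 0.1) and
subtraction of the isotropic perfusion signal, with an anisotropy
refinement loop that makes the separation exact on noiseless data;
(3) iteratively weighted linear least-squares (iWLLS) tensor fit on the
log-signal, weights = squared predicted signal; (4) per-muscle ROI means
after 1-voxel erosion and restriction to the 20 middle slices, with
muscles excluded when SNR = mean(b0)/σ < 20 (pair-wise: losing one session
drops the muscle pair); (5) paired statistics per muscle and DTI
parameter: Bland–Altman bias and 95% limits of agreement, within-subject
coefficient of variation wsCV = 100·SD(paired differences)/mean, and
minimal detectable difference MDD = 1.96·SD(differences), plus paired t
tests comparing the corrected and standard modes.

See `vignettes/muscle-dti-repeatability.Rmd` for assumptions, parameter
rationale, and limitations.

## Worked example

```r
library(muscledti)

# published worked values: MD and FA from an eigenvalue triplet
round(md(2.23, 1.70, 1.47), 2)   # 1.80  (10^-3 mm^2/s)
round(fa(2.23, 1.70, 1.47), 2)   # 0.21

# aggregate the published per-muscle wsCV values for corrected MD
w <- thigh_wscv_reference()
summarize_wscv(w$md[w$mode == "ivim"])[c("mean_1dp", "sd_1dp")]
# $mean_1dp 4.5   $sd_1dp 1.4      (percent)

# a small simulated two-session cohort, end to end
cfg <- run_config(seed = 7, n_subjects = 4, n_slices = 8,
                  in_plane_shape = c(48, 32), snr_target = 40,
                  between_session_cv = 0.03, n_middle = 6,
                  phantom = phantom_config(roi_radius = 2.2, ring_radius = 6.5))
res <- run_all(cfg)
print(res)
```

which prints (abridged):

```
Cohort run: 4 subjects, SNR target 40
Records: 112 (0 excluded, 0.0%); 56 complete pairs
Mean wsCV (%) per parameter and mode:
  parameter     mode n_muscles wscv_mean wscv_sd p_vs_other
         l1 standard        14      3.77    1.42    0.02243
         l1     ivim        14      3.94    1.52    0.02243
         md standard        14      3.65    1.38    0.00551
         md     ivim        14      3.88    1.48    0.00551
  ...
```

Records: 4 subjects × 14 muscles × 2 sessions = 112; none fall below the
SNR 20 threshold at this noise level. The per-muscle MD wsCV concentrates
near `100·cv·√2 ≈ 4.2%` for `between_session_cv = 0.03`, the order of
published in-vivo values. `run_all()` also writes CSV tables, a JSON
summary, Bland–Altman plots and a log when `out_dir` is set, and
`inst/cli/muscledti` exposes `simulate / denoise / fit / run-all`
subcommands over the same functions.

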