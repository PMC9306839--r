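# blindAU

Blind deconvolution by autocorrelation inversion for multiview
light-sheet fluorescence microscopy.

## The problem

Multiview light-sheet imaging records the same specimen from several
angles, each view blurred by a point spread function (PSF) elongated
along that view's detection axis, `o_mu = o * h`, and displaced by an
unknown rigid shift.  The standard pipeline must register the views,
fuse them, and deconvolve with a *measured* PSF — but registration is
error-prone and the PSF is often not measurable at all.

`blindAU` sidesteps both steps.  Autocorrelation is invariant to
translation, so the per-view autocorrelations can be averaged with no
alignment into one fusion target

```
chi_mu = (1/m) sum_i  o_mu,i  (star)  o_mu,i   =   (o (star) o) * H,      H = h (star) h
```

where `(star)` is correlation, `*` is convolution, `o` is the fused
aligned object and `h` the average PSF.  The package inverts `chi_mu`
for **both** `o` and `h` with a Richardson–Lucy-shaped multiplicative
fixed-point scheme (the *anchor update*, AU):

```
object block:   K = o (star) H        o <- o . [ chi_mu / (o * K) * K~ ]
PSF block:      K' = h (star) O       h <- h . [ chi_mu / (h * K') * K~' ]
```

alternated for a fixed schedule of inner iterations and outer cycles
(Blind-AU).  Plain Richardson–Lucy deconvolution, the synthetic
vessel-phantom study used to validate the method, multiview
preprocessing (background subtraction, quarter-turn rotation,
cross-correlation registration, fusion) and quality metrics
(`20*log10(peak/background)` SNR; energy-normalized MSE) are all
included.  The iteration cores run in C++ on FFTW transforms
(~10 ms per 191×191 AU iteration); the identical pure-R single-step
functions serve as their cross-check.

## Worked example

A reduced-scale run of the full synthetic study (95×95 phantom, 50/50
iteration blocks, 50 cycles, 500 RL iterations):

```r
library(blindAU)
cfg <- experimentConfig(
  phantom  = PhantomSpec(shape = c(95L, 95L), structureCount = 8L, seed = 2L),
  schedule = BlindSchedule(50, 50, 50, 25),
  rlIterations = 500L)
rep <- runSyntheticExperiment(cfg)
rep$metrics
#>        image    snrDb         mse
#>  measurement 59.05352          NA
#>      blindAU 81.18446 0.042478297
#>          RLD 64.50858 0.002955973
```

The table reads: the blurred, noisy fused measurement has a
peak-over-background SNR of 59.1 dB; Blind-AU — knowing *nothing* about
the PSF — raises it to 81.2 dB, here even ahead of Richardson–Lucy
deconvolution given the exact PSF (64.5 dB at only 500 iterations).  The
`mse` column is the energy-normalized residual between each
reconstruction re-blurred with its PSF and the measurement.
`psfEstimate(rep$blind)` contains the recovered star-shaped kernel;
`convergenceHistory(rep$blind)` the per-checkpoint trace.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/blindau-cli.R`
(`blindau-cli.R {simulate|fuse|rl|au|blind|metrics|experiment}`).

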