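# pcctmd

Noise and noise correlation in multi-material decomposition
photon-counting spectral CT: a desk-scale simulator and analysis toolkit
in R.

## What it is for

Photon-counting CT records photons in K spectral channels; solving the
polychromatic system

    Ībar_k(L) = ∫ D_k(E) N0(E) exp( − Σ_p A_p(L) μ_p(E) ) dE,   k = 1..K

ray by ray yields the basis line integrals A_p, whose filtered
backprojections are the material-specific (basis) images a_p(x). The
package is built for medical-physics questions about this chain: how
Poisson count noise propagates into A-space,

    V[A] = F⁻¹ V[I] F⁻ᵀ,   F_kp = −Ībar_k μ_kp,
    μ_kp = −(1/Ībar_k) ∂Ībar_k/∂A_p,

why the noise of two basis images is almost perfectly anticorrelated in
two-material decomposition, why the pairwise correlations alternate
between ±1 when three or four materials are decomposed, and why virtual
monochromatic images (VMI, Σ_p a_p(x) μ_p(E0)) stay quantitatively stable
across basis-material sets whose basis images differ drastically in noise.

It provides, as S4 classes and plain functions:

* packaged 1-keV attenuation tables (water, soft tissue, cortical bone,
  adipose, PMMA, Teflon, iodine and gadolinium solutions with K-edges at
  33.2 / 50.2 keV), mixtures and dilute solutions;
* a filtered 140 kVp source spectrum, the equal-count spectral channel
  presets, and ideal / distorted (charge-sharing, K-escape, tail) detector
  response models;
* exact Siddon fan-beam forward projection, polychromatic expected counts
  and an exact charge-sharing Poisson sampler;
* projection-domain Newton–Raphson decomposition with polynomial
  calibration, and equiangular fan-beam FBP (Hann-windowed ramp);
* analytic noise propagation (`effectiveMu`, `propagateCovariance`,
  `closedForm2MD`) with a single-ray Monte Carlo oracle;
* digital phantoms (three-rod noise-correlation cylinder, modified
  Shepp–Logan head) with ground-truth coefficient maps, ROI statistics,
  Pearson noise-correlation reports, CNR and VMI synthesis;
* end-to-end experiment drivers (`runNoiseCorrelation`, `runHeadVMI`,
  `sweepHeadVMI`) with YAML configs, seeded determinism and CSV/JSON/TIFF
  artifacts, plus a thin CLI at `inst/scripts/pcctmd`.

## Worked example

```r
library(pcctmd)
cfg <- runConfig("noise_correlation", mode = "2md", response = "ideal",
                 seed = 1)
rep <- runNoiseCorrelation(cfg)
rep$pearson
#>   roi   material1     material2          R    N
#>  rod1 soft_tissue cortical_bone -0.9945903 2828
#>  rod2 soft_tissue cortical_bone -0.9937253 2822
#>  rod3 soft_tissue cortical_bone -0.9928575 2822
```

Each row is the Pearson correlation between the soft-tissue and
cortical-bone noise images (noisy minus matched noiseless reconstruction)
inside the 6 cm ROI of one rod of the three-rod water phantom: the
two-material basis-image noise is almost perfectly anticorrelated, and
the analytic single-ray propagation at the rod-3 operating point gives the
same coefficient (−0.995):

```r
rep$analytic$rod3
#> CovarianceEstimate (analytic) for soft_tissue, cortical_bone
#>   sigma_A: 3.196 1.493
#>   rho(soft_tissue, cortical_bone) = -0.995
```

The head study sweeps four basis-material sets at matched dose and
compares basis-image noise against 45 keV VMI noise and CNR:

```r
sw <- sweepHeadVMI(runConfig("head_vmi", seed = 1))
sw$summary
```

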