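# fgskinetics

Compartmental pharmacokinetic modeling of targeted and control
(untargeted) fluorescent imaging agents, for choosing the optimal time of
fluorescence-guided surgery (FGS).

Tumor-to-normal contrast after injecting a molecular-targeted fluorescent
agent is strongly time dependent: it depends on delivery (K1), washout
(k2), and binding (kon, koff, available receptor concentration Bavail) in
both tissues. This package is for imaging scientists and modelers who
want to (i) simulate agent uptake and the resulting tumor-discrimination
metrics for single-agent (SA) and paired-agent (PA) protocols, (ii)
predict the time of maximum contrast analytically from a handful of
patient-measurable rate constants, and (iii) exercise a full dual-channel
image-analysis chain on synthetic data with realistic shot noise.

## The model in brief

Plasma input: `Cp(t) = s [A e^(-αt) + B e^(-βt)]` (nM, min). Control
agent (one-compartment Kety model):

    dCf,C/dt = K1 Cp(t) − k2 Cf,C

Targeted agent (free + specifically bound pools, trace-level binding):

    dCf,T/dt = K1 Cp(t) − (k2 + k3) Cf,T + k4 Cb,T
    dCb,T/dt = k3 Cf,T − k4 Cb,T ,     k3 = kon·Bavail, k4 = koff

Contrast metrics per image frame: the contrast-to-variability ratio
`CVR = |μT − μB| / √(σT² + σB²)` and the ideal-observer AUROC
(Mann–Whitney). The PA protocol scores the ratiometric binding potential
`BPratio = (ROI_T − ROI_C)/ROI_C`, which at equilibrium approaches
`BP = Bavail/KD`. Closed-form predictions of the time of maximum CVR:

    Tmax,SA ≅ ln(K1′/K1) / (k2′ − k2a),   k2a = k2/(1 + BP)
    Tmax,PA ≅ 10/(k2 − k2a) · [ln(1/k2² − 1/k2a²) − ln(2/k2² − 2/(k2·k2a))]

(primes: normal tissue). A Monte-Carlo study (`runStudy()`) compares
these predictions against peak times measured on simulated CVR curves
over human-cancer parameter ranges for four agent classes (peptides,
low-/high-molecular-weight antibody fragments, antibodies).

## Worked example

```r
library(fgskinetics)

## analytical timing predictions for a peptide-like agent
tmaxPA(k2_tumor = 0.66, BP = 40)
#> [1] 47.28236
tmaxSA(K1_tumor = 0.2, K1_normal = 0.4, k2_tumor = 0.66,
       k2_normal = 0.5, BP = 40)
#> [1] 1.432411
#> attr(,"contrastImmediate")
#> [1] FALSE

## synthetic dual-channel scene: affibody kinetics, tumor BP = 2
spec  <- sceneFromPreset("affibody", BPtumor = 2, dim = c(32L, 32L),
                         seed = 7L, frameTimes = seq(0, 60, 2))
scene <- renderImageStack(spec)
scene
#> RenderedScene: 32x32 px, 31 frames, 88 tumor / 508 background pixels
#>   peak expected count 13107; joint scale 1.136e+04 counts/nM; noise: poisson

## full analysis chain: subtraction, normalization, metrics, BPratio map
res <- analyzeExperiment(scene = scene)
round(c(tumor = res$bpTumor, background = res$bpBackground), 3)
#>      tumor background
#>      1.983      0.012
findTmax(res$pa)
#> ContrastWindow: Tmax = 58 min (CVRmax = 3.85)
#>   98% window: [57.3208, 58.1129] min (length 0.792043)
```

The scene programs a tumor binding potential of 2 on a receptor-free
background; the pipeline's ROI-averaged BPratio recovers 1.98 in the
tumor and ~0 in the background, and the PA contrast is still rising
toward its equilibrium plateau at the end of this 60-min acquisition.

A command-line veneer covers the same ground
(`inst/scripts/fgs-cli.R simulate|render-scene|analyze|predict-tmax|run-study|make-grid`).

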