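# eitrpca

Spike-noise removal for thoracic electrical impedance tomography (EIT)
recordings by robust principal component analysis, with a complete synthetic
validation pipeline: a 16-electrode finite-element forward simulator,
GREIT-style difference-image reconstruction, functional EIT imaging, image
quality metrics and clinical ventilation indices, and the baseline filters
the method is compared against.

## The problem

Bedside EIT monitors regional lung ventilation by injecting small currents
through 16 chest electrodes and reconstructing conductivity changes from
boundary voltages. The inverse problem is severely ill-posed, so brief
disturbances — electrode contact problems, patient movement, nursing
procedures — produce spike-like excursions in a few channels or frames that
can wreck the reconstructed images and the clinical indices derived from
them (center of ventilation, global inhomogeneity, ventral/dorsal and
right/left ratios).

A recording is a matrix $D \in \mathbb{R}^{192\times T}$ (192 measurement
channels by time frames). Because every channel watches the same respiratory
conductivity modulation, $D$ is approximately low rank — the first singular
value carries ~98% of the singular-value sum — while the spike contamination
is sparse and large. `eitrpca` separates the two by solving

$$\min_{L,S} \|L\|_* + \lambda\|S\|_1 \quad\text{s.t.}\quad D = L + S$$

with an augmented-Lagrangian ADMM (singular value thresholding for the
low-rank update, entrywise soft thresholding for the sparse update;
$\lambda = 0.01$, penalty $\lambda_0 = 10$, relative stopping tolerance
$10^{-8}$ by default, plus an inexact-ALM continuation mode that reaches the
same optimum in a few dozen iterations). $L$ is the cleaned recording, $S$
the isolated artifact.

## Worked example

Simulate a breathing thorax phantom, contaminate one channel of one frame
with a 50x spike, denoise, reconstruct, and score against the clean image:

```r
library(eitrpca)

phantom   <- make_phantom("thorax")
breathing <- synth_breathing(n_frames = 600, frame_rate = 20,
                             rate_bpm = 15, depth = 0.5)
clean     <- forward_voltages(phantom, breathing)   # 192 x 600, millivolts

corrupted <- inject_spikes(clean,
  spike_spec(channels = 35, frame_window = c(299, 299), magnitude = 50))

den <- rpca_denoise(corrupted, method = "continuation")
summary(den$fit)
#> RPCA summary: 89 iterations (converged)
#>   ||D-L-S||_F = 7.6e-07; rank(L) = 6; ||L||_* = 80.94
#>   ...

model <- build_reconstructor(phantom)
ref   <- pick_reference_frame(clean, near_frame = 299)  # inspiration start: 321
gt    <- reconstruct_frame(model, clean$data[, 299]      - clean$data[, ref])
raw   <- reconstruct_frame(model, corrupted$data[, 299]  - corrupted$data[, ref])
fixed <- reconstruct_frame(model, den$clean$data[, 299]  - den$clean$data[, ref])

image_correlation(raw, gt);  image_error(raw, gt)
#> [1] 0.09653063
#> [1] 2.57863
index_report(fixed, gt)
#> Image vs reference: corr = 1.0000, error = 0.0004156
#>   CoV = 52.12% (err 0.00278), GI = 1.115 (err 0.00516)
#>   VtoD = 0.781 (err 0.00055), RtoL = 0.641 (err 0.00417)
```

The single spike drops the raw image's correlation with the truth to 0.097
and inflates its image error to 2.58; after decomposition the reconstruction
is essentially exact (correlation 0.99995, error 0.0004) and all four
clinical indices are recovered to three decimals.

The full simulation studies — 19 spike magnitudes, 11 temporal widths,
14 channel extents, and the heterogeneous-lung comparison against low-pass
and median filtering — are one call each:

```r
setup <- sweep_setup(seed = 1)
run_magnitude_sweep(setup = setup)
run_width_sweep(setup = setup)
run_channel_sweep(setup = setup)
run_filter_comparison(seed = 1)
```

Each returns a per-case table of image correlation/error (raw vs denoised)
and index errors, and can write a CSV plus a JSON manifest of the injected
contamination (`outdir =`). See the methods vignette
(`vignettes/eitrpca-methods.Rmd`) for the model, conventions (image
orientation, reference-frame choice, metric normalizations) and design
decisions.

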