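# camdce

Unsupervised deconvolution of dynamic contrast-enhanced (DCE) imaging
series from heterogeneous tumors, for imaging scientists who need to
resolve spatially intermingled vascular compartments that single-pixel
compartment modeling conflates.

## What it does

A DCE series is a time-by-pixel tracer-concentration matrix. Each tissue
compartment *j* follows two-compartment kinetics driven by the plasma input
C<sub>p</sub>(t),

&nbsp;&nbsp;&nbsp;&nbsp;C<sub>e,j</sub>(t) = K<sup>trans</sup><sub>j</sub> (C<sub>p</sub> ∗ e<sup>−k<sub>ep,j</sub> t</sup>)(t),

and each pixel is a non-negative mixture
x<sub>i</sub> = Σ<sub>j</sub> K<sub>i,j</sub> C<sub>e,j</sub> + v<sub>p,i</sub> C<sub>p</sub>
with local volume transfer constants K<sub>i,j</sub> and local plasma
volume v<sub>p,i</sub>. After sum normalization every pixel lies in the
convex hull of the normalized compartment curves, so the compartment
kinetics sit at the **vertices of the scatter simplex**. The package:

1. preprocesses the series (mask, pre-uptake frame removal, 5%
   uninformative-pixel filter, sum normalization);
2. clusters normalized time-courses by affinity propagation with EM
   refinement (cluster count M is data-driven);
3. identifies the J vertex centers by exhaustive convex-hull-to-data
   fitting: the subset of cluster centers minimizing the summed
   margin-of-error of the remaining centers to its hull;
4. detects the number of compartments J by minimum description length;
5. estimates per-compartment flux rate constants k<sub>ep</sub> (/min) and
   relative transfer constants K<sup>trans</sup> by Toeplitz-based
   deconvolution of the vertex curves, plus per-pixel transfer-constant
   maps by non-negative least squares.

A synthetic-study generator (`generate_synthetic_study()`) emulates the
rim/core tumour validation design -- known compartment curves times
customized transfer-constant maps with designated pure-pixel regions and
additive Gaussian noise -- and is the basis of the test suite.

## Worked example

```r
library(camdce)
study <- generate_synthetic_study(synthetic_config(snr_db = 30, seed = 2))
fit <- deconvolve_series(study$series)
fit
#> <dce_fit> J = 3 compartments from M = 15 clusters (total margin 0.1109)
#>  compartment basis_column    ktrans       kep fit_residual reliable
#>            1            1 1.0980150 1.5251268  0.003975064     TRUE
#>            2            2 0.2786505 0.1545687  0.002445606     TRUE
#>   partial-volume fraction: 0.901
```

MDL selected J = 3 (two tissue pools + plasma input, matching the
generator); the flux rate constants 1.53 and 0.155 /min recover the
generative 1.5 and 0.15 /min; `ktrans` is on the relative
(sum-normalized) scale. The per-pixel maps in `fit$maps` correlate > 0.99
per compartment with the generator's ground-truth maps, and 90% of pixels
are flagged partial-volume (the designed fraction is 89%).
`plot_scatter_simplex(fit)` draws the pixel cloud inside the selected
simplex; `run_pipeline()` writes the full result bundle (MDL curve, basis
curves, PK table, maps, plots, manifest) to a directory, and
`inst/cli/camdce` exposes `simulate`/`fit` subcommands for shell use.

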