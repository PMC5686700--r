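# gnrhsense

How much does a single cell learn about the gonadotropin-releasing hormone
(GnRH) concentration in its environment from its own NFAT translocation
response? This package implements the information-theoretic analysis of
GnRH receptor signalling for systems biologists working with single-cell
imaging data: Bayesian mutual-information estimation on binned single-cell
measurements, a hybrid deterministic/stochastic simulator of the
GnRHR → Ca²⁺ → calmodulin/calcineurin → NFAT cascade, synthetic
single-cell cohort generators, and an MCMC nucleus-matching cell tracker.

## The statistics and the model

Signalling is treated as a noisy channel from the stimulus *S* (GnRH level,
a categorical input) to a response *Z* (e.g. the NFAT nuclear fraction,
NFAT-NF). Information transfer is

    I(Z;S) = H(Z) − H(Z|S)   [bits],

with entropies estimated on a 30-bin discretisation by the
Nemenman–Shafee–Bialek (NSB) estimator — a Dirichlet-mixture posterior that
is nearly unbiased in the undersampled regime and yields error bars. Joint
(two-readout), trajectory (three time points) and conditional quantities
use product alphabets, and the information a second pulse adds beyond a
first follows the chain rule

    I(Z₂;S|Z₁) = I(Z₂;S) − I(Z₁;Z₂) + I(Z₁;Z₂|S).

The simulator couples a six-state deterministic cascade (receptor
occupancy, Ca²⁺, calcineurin, three NFAT pools) to exponentiated
Ornstein–Uhlenbeck fluctuations of the two effector totals (GnRHR and
calmodulin) with a controllable fluctuation lifetime FL: 10 min = unstable
effectors, 10,000 min = stable, with the same lognormal marginal at every
FL. See `vignettes/gnrh-nfat-information.Rmd` for the model, the
calibration anchors and the numerical choices.

## Worked example

```r
library(gnrhsense)

# two-pulse protocol (15 min / 135 min gap / 60 min) across effector
# stabilities, 1000 cells per GnRH level
tp <- two_pulse_analysis(n_cells = 1000, seed = 1)
tp$table[, c("fl", "I_z1_s", "I_z2_s", "additional", "I_z1_z2")]
#>      fl    I_z1_s    I_z2_s additional   I_z1_z2
#> 1    10 0.7006568 0.4903056 0.18788122 0.2736167
#> 2   100 0.7692891 0.5699342 0.16041789 0.2247659
#> 3  1000 0.8576914 0.7506138 0.08143400 1.0984459
#> 4 10000 0.7996722 0.8439838 0.07068155 2.0482096
```

Reading the table: each pulse individually carries well under 1 bit about
the 2-bit input (four GnRH levels) — most information is lost to cell-to-cell
variability. As the effector fluctuation lifetime grows from 10 to 10,000
minutes, the mutual information between a cell's pulse-1 and pulse-2
responses (`I_z1_z2`) climbs from ~0.3 to ~2 bits — with stable effectors a
cell's first response predicts its second — and the additional information
gained by sensing the second pulse (`additional`) decays toward zero.
Unstable effectors give the opposite: little memory, more to learn from the
next pulse.

The numbered scripts under `analysis/` run the full set of analyses
(snapshot cohorts and joint sensing, trajectory information on tracked
cohorts, during/after-pulse sensing, the two-pulse sweep above, and tracker
validation), printing what they find and writing tables under `results/`:

```sh
Rscript analysis/01_snapshot_mi.R
Rscript analysis/04_two_pulse.R   # etc.
```

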