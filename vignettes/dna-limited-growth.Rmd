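---
title: "Quantifying DNA-limited growth: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA-limited growth: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnalim)
```

## The scientific question

When a bacterium such as *E. coli* keeps growing while DNA replication is
blocked, its single chromosome is progressively diluted by the expanding
cytoplasm. If the genome itself is a limiting substrate for transcription,
this dilution should propagate downstream: fewer promoter encounters per
RNA polymerase (RNAP), a falling active-RNAP fraction, a shrinking mRNA
pool, a falling active-ribosome fraction, and finally a relative growth
rate that decays with cell size — sub-exponential growth. Cells whose
chromosome number keeps pace with volume (division-blocked filaments)
serve as the control: their genome concentration is constant and growth
stays exponential.

`dnalim` implements the full measurement chain behind this comparison:
single-cell growth kinetics from segmentation masks, single-molecule
diffusivity classification of active RNAPs and ribosomes, spot/nucleoid
image analysis for ploidy assignment, proteome/transcriptome size-scaling
slopes, matched-population concentration ratios, and two ordinary
differential equation (ODE) models of DNA-limited gene expression. A
synthetic-data module generates inputs with the statistical structure each
stage assumes, so every stage is testable without external data.

## Growth kinetics

A cell's area series $A(t)$ (µm², sampled uniformly, typically every
minute) is smoothed by a centered moving average of 5 points; the
**absolute growth rate** is the forward difference of the smoothed series
per minute, and the **relative growth rate** is the absolute rate divided
by the smoothed area. On a noiseless exponential $A = A_0 e^{kt}$ sampled
every $\Delta t$, the discrete relative rate is the constant
$(e^{k\Delta t}-1)/\Delta t$, which is what the estimators return to
machine precision:

```{r growth}
g <- sim_growth(1, "exponential", k = 0.01, a0 = 2, t_end = 100,
                sample_interval = 5, noise_sd = 0)
gs <- growth_rates(g$t_min, g$area_um2)
range(gs$rel_rate_per_min)   # constant, equals (e^{0.05} - 1)/5
```

Design choices the data do not dictate:

* **Edge handling of the smoother.** The window and interval are standard;
  edge handling is not. We truncate (no padding), so the output loses
  `window` rows in total (smoothing plus differencing). Padding would
  bias rates at the trajectory ends, exactly where filaments matter.
* **Derivative.** Forward difference on the smoothed series, matching the
  "difference between consecutive frames" definition; a centered
  difference is available via `method = "central"`.
* **Filament truncation.** Very large filaments stop supporting growth;
  series are cut at the maximum absolute growth rate (inclusive).
  Truncation is idempotent. An alternative rule (cut where the rate falls
  below a fraction of its maximum) is selectable, since "based on the
  maximum" admits both readings.
* **Area-to-volume conversion** models the rod as a cylinder with
  hemispherical caps whose 2D projection matches the measured area at the
  measured width: $L = (A - \pi w^2/4)/w$,
  $V = \pi w^2 L/4 + \pi w^3/6$. Exact mesh integration of the cell
  contour is out of scope; for filaments of constant width the two agree
  in trend (identical ranks).

**The segmentation-bias artifact.** A constant additive offset
$\varepsilon$ in measured area turns a truly exponential
$\dot A = kA$ into an apparent relative rate
$kA/(A+\varepsilon)$ — increasing with $A$ for $\varepsilon > 0$. A
+0.2 µm² offset makes a $k = 0.01$/min cell appear to accelerate from
0.00909 to 0.00976/min between 2 and 8 µm². `segmentation_bias()`
reproduces this closed form, and the growth generator plants the offset
(`area_bias`) *after* multiplicative noise so the artifact survives
averaging. This is why a slightly rising relative rate in control
filaments is not, by itself, evidence of super-exponential growth.

## Single-molecule diffusivity

Localizations are linked into tracks within each cell: a position
continues a track if it appears in the next frame within 0.8 µm; a single
missed frame (blinking) is bridged; any ambiguity — two candidate
positions for one track head, or one position reachable from two heads —
removes those localizations from analysis rather than guessing. Each track
of at least 9 consecutive-frame displacements yields an apparent diffusion
coefficient

$$D_a = \frac{1}{4 n \Delta t} \sum_{i=1}^{n}
  \left[(x_{i+1}-x_i)^2 + (y_{i+1}-y_i)^2\right],$$

with $\Delta t = 10.7$ ms by default. Displacements spanning a bridged
frame are excluded from the sum (the formula is defined on
consecutive-frame steps); `gap_policy = "half"` instead includes them with
the doubled interval.

The population of $\log_{10} D_a$ values is fitted with a three-component
Gaussian mixture — engaged ("active", slowest), freely diffusing within
complexes, and free protein — by maximum-likelihood EM with seeded
multistart (a k-means start plus random restarts, best likelihood kept;
the default model-based hierarchical initialization of 1D mixtures is
prone to poor local optima on well-separated states). Zero $D_a$ values,
possible for immobile molecules, are floored at $10^{-5}$ µm²/s, below
any physical state, before the log transform. Per cell, the **active
fraction** is the fraction of that cell's tracks assigned (maximum
posterior) to the slowest state; cells with fewer than 50 tracks are
dropped. Soft (posterior-mean) fractions are available behind a flag. The
**total active amount** per cell is total fluorescence × active fraction,
binned by area with a percentile-bootstrap confidence interval.

Localization error $\sigma$ adds $\sigma^2/\Delta t$ to $D_a$; the track
generator applies it per localization so that recovery tests can account
for this inflation explicitly. Tracks are confined by specular reflection
at the cell boundary, which preserves step-length statistics better than
truncation; with the default rod geometry the fastest state is visibly
confinement-biased, so convergence tests use a large cell.

## Spots, nucleoids, ploidy

Spot detection band-pass filters the image (difference of Gaussians,
σ = 1 and 5 px by default; the original kernel sizes are not published),
finds local maxima, and fits each candidate with an isotropic 2D Gaussian.
The spot score is $\text{intensity} \cdot q / \sigma_\text{fit}$ with
$q = 1 - \text{RSS}/\text{TSS}$ of the fit clipped to (0, 1] — the
published score names but does not define its quality term, so the
normalized goodness-of-fit is our choice. Raising the score threshold can
only remove spots.

Nucleoid counting thresholds the DNA signal within each cell mask by
two-threshold Otsu (foreground = highest class), labels connected
components, filters them by area, and classifies ploidy purely by count:
one nucleoid = "1N", two or more = "multiN", none = "ambiguous". A
snapshot-style variant (Laplacian-of-Gaussian + local-mean adaptive filter
+ hard threshold) is selectable. Total cell fluorescence subtracts the
median extracellular intensity from each pixel before summing, and may
legitimately be negative for empty cells.

## Omics size-scaling slopes

For tandem-mass-tag (TMT) proteomics, each peptide's reporter intensity is
divided by that peptide's mean across channels (the *relative signal*
$y_i$); each channel's mean cell area is divided by the experiment mean
(the *normalized size* $x_i$). Peptide measurements (same sequence,
different charge state or fraction count separately) are consolidated per
protein and channel by the median, and the **protein slope** is the
coefficient of $\log_2 y$ on $\log_2 x$: slope 0 means concentration
proportional to the proteome, −1 means a fixed amount diluted by growth.
Proteins need ≥ 3 peptide measurements (a stricter ≥ 4 is a per-analysis
option); replicate slopes are computed separately and averaged. The
regression keeps a free intercept — per-peptide mean normalization does
not exactly center the logs — with a no-intercept mode behind a flag.

Two subtleties worth stating plainly:

* Per-peptide normalization removes peptide-level scale (ionization
  efficiency) but **not** channel-level scale: multiplying one channel by
  a constant shifts *every* slope by the regression of that log-constant
  on $\log_2 x$. Equal-loading channel normalization
  (`normalize_channels = TRUE`, dividing each channel by its summed
  intensity) restores that invariance at the cost of measuring
  concentration *relative to the proteome-wide trend*; it is off by
  default to match the printed procedure.
* With 10 peptides, 5 channels and 10% intensity noise the per-protein
  slope standard error is ≈ 0.025, so individual slopes scatter
  accordingly; recovery is tested on the mean and RMSE.

RNA slopes work the same way on TPM tables: optional re-normalization
after restricting to the focal organism's genes, a floor of TPM ≥ 1,
per-gene normalization to the gene mean, and a log2–log2 regression
against normalized areas. `oric_distance()` gives the circular distance of
a gene midpoint from the replication origin
(default *E. coli* K-12: oriC at bp 3,925,859 of 4,641,652) as the minimum
of the three wrap-around differences. `pca_summary()`,
`gene_set_compare()` (Mann–Whitney), `correlate_covariate()` (Spearman
with equal-count bins) and `ms1_abundance()` (summed ion intensity over
protein length) complete the module.

## Matched-population ratios

Comparing a per-cell concentration signal between 1N and multi-N
populations requires matched cell-area distributions.
`match_distributions()` subsamples, per area bin, the larger population
without replacement down to the smaller one (bins under a minimum pooled
count are dropped). `ratio_vs_area()` instead uses all cells via repeated
equal-n resampling *with* replacement per biological replicate and bin:
the sample size is the smaller per-bin count and the iteration count is
$10\,|n_A - n_B|$, floored at one iteration when the counts are equal
(the estimate must exist; one resample already uses all cells). The
per-iteration statistic is the ratio of sample means, averaged over
iterations (a ratio-of-averaged-means mode is selectable; the two agree
closely on these data and the published procedure does not specify
which). A single exponential decay $a e^{-bA}$ is fitted to the binned
average ratios by least squares. Defaults: 1-µm² bins over 2–10 µm²,
≥ 10 cells per replicate-bin, 1000 bootstrap replicates for binned means.

## The ODE models of DNA-limited expression

mRNA number $X$ and protein number $Y$ evolve as

$$\frac{dX}{dt} = r_1\, \alpha_\text{RNAP}\, Y - \delta X, \qquad
  \frac{dY}{dt} = r_2\, \alpha_\text{ribo}\, Y,$$

with bulk transcription and translation rates $r_1, r_2$ normalized by
total protein number, mRNA degradation rate $\delta$, negligible protein
degradation, and cell volume and area proportional to protein:
$V = cY$, $A = c'Y$. The active-ribosome fraction is
$\alpha_\text{ribo} = \frac{X/V}{K_2 + X/V}$. For RNAPs:

* **Model A** (DNA limiting, RNAPs not):
  $\alpha_\text{RNAP} = \frac{Z}{K_1 + Z}$ with genome concentration $Z$
  in chromosome copies/µm³.
* **Model B** (DNA and RNAPs limiting): RNAPs partition into free,
  promoter-bound, and transcribing states by mass action with rates
  `k_on`, `k_off`, `k_init`, `k_term` and promoter concentration
  `n_promoter` × $Z$, evaluated at quasi-steady state with promoter
  occupancy accounted for (a quadratic balance). "Active" counts bound
  plus transcribing RNAPs — promoter-bound RNAPs remain slow-diffusing —
  with a transcribing-only mode selectable. Because occupancy depletion
  makes the fraction depend on total RNAP concentration, the empirically
  increasing RNAP concentration of genome-diluted cells enters through a
  user-suppliable concentration-vs-area profile (default: linear rise to
  2× between 2 and 15 µm²). When RNAPs are scarce the quasi-steady state
  reduces to a Michaelis–Menten form with
  $K = (n_\text{promoter}\,\gamma\,(1+\tau))^{-1}$,
  $\gamma = k_\text{on}/(k_\text{off}+k_\text{init})$,
  $\tau = k_\text{init}/k_\text{term}$, which is how models A and B are
  cross-checked numerically.

Two genome laws close the system: **multiN** holds $Z$ constant
(balanced growth — chromosome number scales with volume) and **oneN**
keeps one chromosome copy, $Z = 1/(cY)$, so the genome dilutes as the
cell grows. Integration uses a Bogacki–Shampine (ode23-type) adaptive
solver at relative/absolute tolerances $10^{-4}$/$10^{-5}$.
`balanced_growth_init()` integrates the multiN system until $X/Y$ is
stationary (relative change below $10^{-8}$ per 500-min chunk, with the
state rescaled each chunk so numbers stay bounded) and rescales to a
target protein number; at the fixed point
$X/Y = r_1 \alpha_\text{RNAP}/(\lambda + \delta)$ with
$\lambda = r_2 \alpha_\text{ribo}$, which the tests verify
independently.

```{r model}
p <- model_params()
init <- balanced_growth_init(p, Y_target = 2.5 / p$c_prime)
one <- simulate_model(p, "oneN", init["X"], init["Y"], t_end = 600, dt_out = 50)
round(one[, c("t_min", "A_um2", "alpha_rnap", "alpha_ribo",
              "rel_rate_per_min")], 4)
```

Default parameters are literature-scale for *E. coli* in minimal medium —
$Y \approx 3\times10^6$ proteins per µm³ of volume
($c = 3.3\times10^{-7}$ µm³), 2.5 µm² of area at that size
($c' = 8.3\times10^{-7}$ µm²), mRNA lifetime 5 min
($\delta = 0.2$/min), a doubling time near an hour
($r_2 = 0.016$/min with $\alpha_\text{ribo} \approx 0.77$), $K_1$ set so
that balanced-growth DNA concentration half-saturates RNAP activity, and
$K_2$ set so the balanced mRNA concentration gives the observed active
ribosome fraction. They are starting points for fitting, not results.

**Fitting and identifiability.** `fit_model_params()` minimizes weighted
least squares over six curves — growth rate, active-RNAP fraction, and
active-ribosome fraction versus area, for both genome laws — with
Nelder–Mead multistart on log parameters ($r_2$ fixed by the growth-rate
scale). One caveat is structural: the observables are exactly invariant
under $(r_1, K_2) \to (s r_1, s K_2)$, because scaling the (unobserved)
mRNA number leaves $\alpha_\text{ribo}$ and hence $Y$ unchanged. The
identifiable set is $(\delta, K_1, r_1/K_2)$, and recovery tests assert
≤ 5% error on exactly those; pinning $r_1$ and $K_2$ individually
requires external information such as absolute mRNA counts. Fitting only
one genome law is flagged `underdetermined` ($K_1$ cannot be constrained
while $Z$ never varies).

**Limiting concentration.** The cell area at which the total-active-RNAP
curve of single-chromosome cells falls below the wild-type linear scaling
(by 10%, sustained for all larger bins; `detect_deviation_area()`)
converts directly into a minimal limiting genome concentration,
copies/area. Deviation at 2 µm² with one chromosome gives 0.5 copies/µm²
(fast growth); at 1 µm², 1 copy/µm² (slow growth).

## What the synthetic data does and does not emulate

The generators reproduce the *statistical structure* each estimator
assumes: state-mixture Brownian tracks with per-localization error and
reflective confinement; exponential/linear/model-driven area trajectories
with lognormal measurement noise and additive segmentation bias;
peptide tables with planted log–log slopes, lognormal intensity noise
(CV-parameterized, mean-one) and lognormal peptide base abundances;
images as background + Gaussian spots + smooth nucleoid blobs + Poisson
noise in rectangular rod masks; two populations with planted per-bin
concentration ratios. All randomness in a generator call flows from one
explicit seed, and fixed seeds give bit-identical outputs.

They deliberately do not emulate: fluorophore photophysics (blinking
beyond single-frame dropouts, bleaching), motion blur, non-Gaussian
localization errors, cell-to-cell parameter heterogeneity beyond
per-cell growth rates, peptide-level missingness patterns of real MS
runs, compositional closure of TPM re-normalization, or realistic cell
shapes and segmentation errors. Passing recovery tests therefore
demonstrates correctness of the estimators under their stated
assumptions, not robustness to every pathology of real data.

## Numerical choices and problem sizes

Tolerances: ODE integration $10^{-4}$/$10^{-5}$ (relative/absolute); EM
log-likelihood $10^{-6}$; balanced-growth stationarity $10^{-8}$ per
chunk; decay and spot fits run Levenberg–Marquardt to its defaults.
Ties and degenerate inputs: mixture states are identified by sorted
means; hard classification breaks posterior ties by the slower state;
empty cells classify "ambiguous"; all-zero peptide rows are dropped and
logged; a zero denominator mean excludes a ratio bin.

The shipped tests and the acceptance script use moderate problem sizes —
20 000 mixture draws (5 seeds), 500 proteins × 10 peptides, ~3 000 cells
per population for ratios, 2 multistarts for the six-curve fit — chosen
so the whole suite completes in a few minutes on one CPU while every
recovery margin retains a comfortable factor over its threshold.

## Known limitations

Mask linking assumes maximum pixel overlap identifies parentage (fast
drift breaks it); the rod volume model ignores curvature and septation;
the mixture model has a fixed number of states and no within-track state
switching (no hidden-Markov analysis); TPM re-normalization assumes the
retained gene set dominates the library; model B's promoter pool is a
single aggregated species; and the deposited-data checks (proteome slope
census, RNA–protein slope concordance, PC1 variance) require the study's
supplementary tables, which this package does not bundle — the
corresponding acceptance tests state exactly where to place them.
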