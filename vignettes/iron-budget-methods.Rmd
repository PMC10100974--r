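---
title: "Methods: from anaerobic growth curves to a microbiome iron budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from anaerobic growth curves to a microbiome iron budget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironbudget)
```

`ironbudget` chains five quantitative steps: fit a growth model to optical
density, convert OD to cell-count surrogates, quantify iron and porphyrins
against standard curves, normalize the loads to genomic DNA, and extrapolate
to the gut microbiome's cell census. A sixth, independent module surveys the
*hmu* heme-uptake operon across genomes. This vignette records the model
assumptions, the tunable parameters and their defaults, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## The growth model

Batch growth is described by the modified Gompertz equation

$$\mathrm{OD}(t) = A \exp\{-\exp[k(\lambda - t) + 1]\}, \qquad
k = \mu_m e / A,$$

a three-parameter sigmoid in which $A$ (au) is the saturation plateau,
$\mu_m$ (au h$^{-1}$) the maximum specific growth rate, and $\lambda$ (h)
the lag time. The parameterization has a clean geometric reading: the curve
inflects at $t = \lambda + 1/k$ where its value is $A/e$ and its slope is
exactly $\mu_m$, and the tangent drawn there crosses the time axis at
$\lambda$. `lag_time_geometry()` exposes these identities and the test suite
verifies them to $10^{-9}$ against numeric differentiation.

```{r geometry}
p <- gompertz_params(A = 1.46, mu_m = 0.260, lam = 4.94)
lag_time_geometry(p)
```

$A$ is treated as an OD asymptote in absorbance units throughout. An
alternative reading of the asymptote as a log cell-count ratio
($\ln N_\infty/N_0$) exists in the growth-curve literature; we do not apply
a log transform, because the saturation values being modelled (for example
$A \approx 1.46$ au) are plain OD readings and all downstream conversion
factors are linear in OD.

### Fitting

`fit_gompertz()` minimizes squared residuals with Levenberg–Marquardt
(`minpack.lm::nlsLM`). Positivity of $A$ and $\mu_m$ and non-negativity of
$\lambda$ are enforced with box constraints rather than a log-transform of
the parameters: the constraint set is identical, convergence on sigmoid data
is equally robust, and the untransformed parameters keep the fit summary
directly interpretable. Starting values are taken from the data — $A_0$ the
maximum OD, $\mu_0$ the steepest finite-difference slope, $\lambda_0$ the
first time OD clears 5 % of $A_0$ — which lands inside the basin of
attraction for any reasonably sampled sigmoid. On noiseless synthetic curves
the generating parameters are recovered to better than $10^{-6}$ relative
error; the fit is invariant to time-axis translation (shifting $t$ by
$\Delta$ shifts $\lambda$ by $\Delta$ and nothing else). Flat curves and
fewer than five points are rejected rather than fitted. Replicates are
fitted independently; summaries across replicates are means ± SD.

## Cell metrics

A cell carrying one genome copy of $G$ bp holds $G \times 650 / N_A$ grams
of DNA. The average base-pair mass of 650 g mol$^{-1}$ is the
double-stranded, sodium-free convention; it is the value under which a
6.26-Mbp genome gives 6.76 fg per cell and hence $1.48 \times 10^8$ cells
per µg DNA. (A cruder rule of thumb of $1.3 \times 10^8$ cells per µg
circulates in the literature; the genome-derived value is used everywhere
here.) Chromosome copy number above one during fast exponential growth is a
known bias and is not modelled.

OD converts to proxies through measured linear factors, by default
6.0 µg DNA mL$^{-1}$ au$^{-1}$ and 3.4 mg wet pellet mL$^{-1}$ au$^{-1}$;
`fit_conversion_factor()` estimates such factors from paired OD/proxy data
by ordinary least squares with a free intercept and flags intercepts larger
than 10 % of the data range, since every proxy must vanish at zero biomass.
The cells-per-OD factor is the chain
$6.0 \times 1.48\times10^8 = 8.88 \times 10^8$ cells mL$^{-1}$ au$^{-1}$
(commonly quoted rounded as $9 \times 10^8$).

## Quantification

Calibration lines are fit by least squares with a free intercept
(`fit_calibration()`), and flagged when $R^2 < 0.99$ or the intercept
exceeds 5 % of the top standard signal. Conversion of a sample signal to
concentration is slope-only by default:

$$[\mathrm{A}]~(\mu M) = \mathrm{signal} / m, \qquad
\mathrm{conc} = [\mathrm{A}] \times \mathrm{dilution} / V_{\mathrm{culture}}.$$

The fitted intercept is deliberately *not* subtracted in the default path.
With standards whose true intercept is zero, the fitted intercept is pure
noise with standard error of order 0.01–0.02 µM-equivalents (at 1 %
multiplicative standard noise), which is negligible for analytes injected at
micromolar levels but corrupts trace analytes near the detection limit by
up to ~10 %. Instruments with a genuine blank offset are handled by
`subtract_intercept = TRUE`. The per-injection detection limit defaults to
0.25 µM (250 nM); sub-LOD values are reported with a `below_lod` flag rather
than zeroed, so downstream tables can display them as censored.

Porphyrin signals are peak areas. `extract_eic()` sums intensities within
±0.02 Da of the target mass (Q-TOF-class accuracy; the width is a parameter
because no universal value exists), and `integrate_peak()` integrates the
trace by the trapezoidal rule over a retention-time window (default ±4 peak
sigmas) after subtracting a constant baseline estimated as the median
intensity outside the window. On a clean Gaussian peak this reproduces the
closed-form area $h\sigma\sqrt{2\pi}$ to better than 1 % whenever the scan
interval is at most $\sigma/5$, and halving the interval moves the area by
under 0.5 % (quadrature convergence). The ±4σ window clips 0.006 % of a
Gaussian — far below instrument noise. The 282.13 m/z PPIX fragment is
carried as annotation only; fragment-based confirmation is out of scope.

Normalization to DNA is the exact rescaling
$\mathrm{pmol}\,\mu g^{-1} = \mathrm{nmol\,mL^{-1}} \times 1000 /
[\mathrm{DNA}]_{\mu g\,mL^{-1}}$. Technical replicates are averaged after
quantification.

## Reservoir extrapolation

The microbiome model defaults to $3.8\times10^{13}$ cells at 5 pg wet mass
each (≈190 g, "about 200 g" of biomass) treated as if composed entirely of
the measured organism, whose genome then fixes the total DNA at
$3.8\times10^{13} \times 6.76\,\mathrm{fg} \approx 2.57\times10^5$ µg. A
load of $x$ pmol iron per µg DNA extrapolates to
$x \times 2.57\times10^5 \times 55.845 \times 10^{-9}$ mg of iron.

The heme column is reported as **iron-equivalent mass** — each heme carries
one iron atom, so the heme pool is multiplied by the molar mass of iron
(55.845 g mol$^{-1}$), not of hemin chloride (651.94 g mol$^{-1}$). Only
this convention is dimensionally consistent with reporting the heme pool as
part of an elemental iron budget, and only it reproduces the 2.0 / 1.7 mg
scale of the supplemented-media heme reservoirs from 140 / 120 pmol µg$^{-1}$
loads. Uncertainty propagates by the same linear scaling, so SD columns
scale exactly like the means. `buffer_days()` divides the reservoir by a
host absorption rate of 1–3 mg/day to express it as a starvation buffer.

## Operon survey

Homology is called on global percent identity: `global_align()` implements
Needleman–Wunsch with match/mismatch/linear-gap scoring (+2/−1/−2 default).
A substitution matrix is unnecessary for threshold calls at 30 % on
synthetic families and is left as an extension. Identity uses the full
alignment length as denominator — gap columns count against identity — the
conservative choice when the cutoff definition does not specify one.
Whether such cutoffs should use local or global identity is genuinely
ambiguous in cluster-survey tools; global identity is used and stated.

The dynamic programme is row-vectorized: with a linear gap penalty $g$ the
in-row recurrence collapses to a running maximum,
$M_{i,j} = g j + \max_{k \le j}(P_k - g k)$ with $P$ the best
diagonal/vertical entry per column, so alignment of two 300-residue proteins
costs 300 vectorized row updates. Scores are verified in the tests against
an exponential enumerate-all-alignments oracle on short sequences (the
exhaustive cross of all 4-letter-alphabet sequences to length 2, plus
hundreds of random pairs to length 6, under two scoring schemes).

Conservation patterns score each of the six baits 0/1/2 (absent / one copy /
two or more copies) into a string ordered *hmuYRSTUV*; `tally_patterns()`
counts exact multisets. `check_synteny()` calls loci colocalized when they
share a contig with adjacent gaps ≤ 20 kb (the convention of gene-cluster
detection tools; configurable) and order-preserved when the genomic order of
present genes matches the canonical order or its exact reverse — an operon
read off the minus strand is still syntenic. Duplicated copies break strict
order comparison and report `order_preserved = FALSE`.

Database-scale claims — profile-HMM searches, survey counts over thousands
of genomes, E-value statistics — are out of scope; those depend on database
versions and are not reproducible at desk scale. The operon logic is instead
validated on constructed genomes with known patterns.

## The synthetic-data generator

The generator emulates exactly the statistical structure the analysis
assumes:

* **OD curves** — Gompertz mean plus additive i.i.d. Gaussian noise
  (default SD 0.01 au, a typical plate-reader floor), floored at zero.
* **Calibration ladders** — $s_i = m\,L_i (1+\varepsilon_i)$ with
  multiplicative Gaussian noise (default 1 %), matching the
  constant-relative-error behaviour of absorbance and ion-count readouts;
  blanks stay exactly zero. Default ladders: 0.1–4 ppm (8 points, AA iron)
  and 0.25–6 µM (6 points, porphyrins).
* **Chromatograms** — a dense fixed-interval scan grid (default 0.02 min)
  with Gaussian elution peaks (default $\sigma$ = 0.1 min; heme at 4 min,
  PPIX at 5 min over an 8-min run); co-eluting peaks sum within an m/z
  channel and never across channels. Centroiding, isotope envelopes, ion
  suppression and retention drift are *not* modelled.
* **Protein families** — uniform random substitutions (no indels) at per-site
  rate $1 - \mathrm{identity}/100$, so realized identity concentrates within
  ±3 points of target for length ≥ 200 by binomial concentration. Indels in
  real proteins are handled by the aligner but deliberately absent from the
  generator, keeping identity exactly controllable.
* **Genome layouts** — loci placed from a pattern string with configurable
  intergenic gaps; duplicated copies land 1 Mbp away; `shuffle` breaks
  synteny without changing content.
* **Culture bundles** — a growth curve, a DNA yield, AA and porphyrin
  calibrations, one sample absorbance and one sample chromatogram, all
  generated so that the forward instrument model is the exact inverse of
  the quantification chain. Defaults: 20 mL culture volume, 4× AA dilution,
  6× MS dilution, AA response 0.05 abs/ppm, MS response
  $5\times10^4$ counts·min/µM.

Every generator is deterministic under a fixed seed (and restores the
caller's RNG state). Passing tests on these data shows the *pipeline
arithmetic and fitting* are correct under the stated noise model; it does
not validate matrix effects, extraction recovery, or peak-shape anomalies in
real instrument data.

## Numerical choices and degenerate inputs

* Zero-level standards carry zero multiplicative noise by construction; the
  calibration fit therefore stays full-rank with as few as three distinct
  levels, and fewer are rejected.
* `heme_fraction()` permits heme up to 5 % above total iron (measurement
  noise on two independent assays) and errors beyond that.
* Sub-LOD concentrations are reported with flags; negative back-calculated
  levels are clamped to zero before unit conversion.
* `integrate_peak()` floors the baseline-subtracted trace and the final area
  at zero, so noise dips cannot produce negative areas.
* Alignment traceback prefers diagonal moves, then vertical; tied optima
  return one canonical alignment (scores, and hence identity thresholds on
  ungapped families, are unaffected).

## Problem sizes

The shipped tests run on: growth grids of 60–61 points; 20 noisy replicates
for fit-recovery statistics (σ = 0.02 au); chromatograms of ≈400 scans ×
2 channels; protein families of 150–300 residues with proteomes of up to 7
members; and a few hundred alignment-oracle pairs of length ≤ 6. The whole
suite completes in well under a minute, and the acceptance script in
seconds.

## Known limitations

* Single-organism surrogate: the reservoir model scales one organism's
  per-DNA load to the entire microbiome; community composition weighting is
  out of scope.
* One genome copy per cell; fast growers with multiple replication forks
  will be undercounted by up to ~2×.
* The quantification chain assumes linear response through the working
  range; saturation or matrix suppression must be handled upstream.
* No blank-well OD correction beyond what the user subtracts before fitting;
  alternative growth models (logistic, Baranyi) are not provided.
* Operon calls use simple-scoring global alignment; divergent homologs below
  ~30 % identity (a known issue for the fast-evolving hemophore) are
  reported as absent, exactly as a fixed-threshold survey would.
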