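---
title: "Reconstructing cancer evolution from two longitudinal measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing cancer evolution from two longitudinal measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonechron)
```

## The model

clonechron treats a growing cancer as a multi-type branching process. The
initiated (parental) population — clone 0 — starts from a single cell at
time 0; each of its cells divides at rate $b$ and dies at rate $d$, giving
a net growth rate $r = b - d > 0$. At time $t_1$ a driver mutation arises
in one randomly chosen cell and founds clone 1, an independent branching
process with its own rates $b_1, d_1$ and $r_1 = b_1 - d_1$; further
drivers may arise inside any existing clone, giving an arbitrary forest of
subclones rooted at clone 0. Selectively neutral passenger mutations accrue
in every cell as a Poisson process with rate $u$, shared by all clones, at
any point of the cell cycle (not only at division); each new passenger is
unique (infinite-sites) and never reverts. Only tumors that survive
stochastic drift are considered — all estimators condition on survival.

The data are two bulk measurements taken late in growth, a known $\Delta$
apart: total cancer cell counts $M_1, M_2$ (for leukemias, from white
blood cell counts), the fraction of cells carrying each driver
($\alpha_i$ at the first timepoint, $\beta_i$ at the second), the number
$\gamma$ of subclonal passengers with frequency in a window $[f_1, f_2]$,
and per-clone clonal passenger counts $m_{obs}$ (mutations present in
every cell of a clone's clade).

## The estimators

Writing $\alpha_i^c$ for *exclusive* fractions (cells whose most recent
driver is $i$; `clone_exclusive_fractions()`), the chain of closed forms
is:

* **Growth rates.** The conditional mean of a surviving birth–death
  process is $(b/r)e^{rt}$, so equating measured clone sizes at the two
  timepoints gives $\hat r_i = \log[\beta_i^c M_2 / (\alpha_i^c M_1)] /
  \Delta$ (`estimate_growth_rates()`). The same formula applies to every
  clone of any phylogeny; the single/nested/sibling special cases are kept
  as independent cross-checks. A driver's selective advantage is
  $g = (r_{child}/r_{parent} - 1)\cdot 100\%$.
* **Mutation rate.** An exponentially growing clone carries an expected
  $(u/r)(1/f_1 - 1/f_2)$ subclonal passengers with frequency in
  $[f_1, f_2]$; summing clones weighted by exclusive fractions and
  inverting gives $\hat u = f_1 f_2 \gamma / [(f_2 - f_1)\sum_i
  \beta_i^c/\hat r_i]$ (`estimate_mutation_rate()`, with
  `expected_gamma()` its exact inverse). With several timepoints the
  per-timepoint estimates are averaged.
* **Driver timing.** Passengers in a driver's founder cell are a Poisson
  clock: $\hat t_i = m_i/\hat u$ maximizes the Poisson likelihood. The
  observed clonal count is corrected for passengers that fixed in the
  subclone after the driver (expected $u/r_i$) and, for drivers nested
  inside another driver subclone, for founder passengers that fixed in the
  parent clone and were assigned to the parent's branch (add back
  $u/r_{parent}$): `correct_clonal_count()`. For drivers arising directly
  from clone 0 the parent term is omitted — this follows the layout-specific
  forms of the theory, which treat passengers fixing in the parental
  population as truncal rather than mis-assigned.
* **Time since the last driver.** The expected first-passage time of a
  surviving clone to size $n$ is $(\log(n r/b) + \gamma_E)/r$ (the mean of
  the limiting Gumbel law); `time_since_driver()` drops the
  $\log(r/b) + \gamma_E$ terms, which are of order 1 against
  $\log n \approx 19$–25 for observable cancers. `et_approximation()`
  reports the dropped term and the resulting percent error; at clone size
  $10^9$ it is below 4% for every growth regime shipped with the package,
  and it shrinks further with size.
* **MRCA age.** The theory gives no explicit clone-0 timing formula; the
  package times initiation by the same molecular clock applied to the
  truncal count, $\hat t_{MRCA} = (m_{obs,0} - u/r_0)/u$ (`mrca_age()`).
  This is an interpretation, isolated in one function, and is exercised by
  the zero-noise fixture recovery test.

## Uncertainty

`ci_pipeline()` propagates the modeled noise sources by sampling: subclone
CCFs are drawn from their posterior samples (as produced by subclonal
reconstruction tools; draws violating the tree's nesting constraints are
rejected and redrawn, capped at 100 attempts per draw), growth parameters
are refit per draw — directly for two timepoints, or sampled from the
bivariate normal distribution of the fitted (intercept, rate) when more
are available (`fit_growth()`, `sample_growth_params()`) — and driver
times are drawn from the posterior $P(t_i \mid m_i)$. Under a flat prior
on $t_i > 0$ that posterior is Gamma$(m_i + 1, u)$, whose mode is the MLE
$m_i/u$; the flat prior is our choice, made so that the reported point
estimate and the posterior mode agree. Intervals are percentile intervals
across draws, and all uncertainty sources are combined within each draw.

When a fitted growth rate (possibly negative, as in declining subclones)
is below the minimal rate needed to reach the observed clone size,
$\log(\text{size})/\text{available time}$, the minimal rate is substituted
for all downstream quantities while the raw fitted rate is still reported.
"Available time" is not defined by the theory; we take the patient's age
at observation minus the estimated origin of the clone's parent lineage
(birth, when there is none). Both the substitution and this definition are
confined to `minimal_growth_rate()` and its call sites.

Clinical detectability (`detectability_time()`) is the root of
$\sum_i e^{\theta_{0i} + \theta_{1i} t} = T$, found by bracketed bisection
(tolerance $10^{-6}$ years, bracket birth to last observation + 50 years,
expanded upward as needed). The default threshold is leukocytosis —
11,500 WBC/µL in 5 L of blood, i.e. $5.75\times 10^{10}$ cells
(`wbc_to_cell_count()`); both constants are configurable.

## The simulator

`simulate_tumor()` is an exact per-cell Gillespie simulation: cells are
stored per clone as a vector of labels (a cell's label is its most recent
passenger mutation), so one event — a uniformly chosen cell dividing,
dying, or mutating, with waiting times exponential at total rate
$N_j(b_j + d_j + u)$ — costs O(1). Carrier sets are subtree sums over the
global mutation ancestor vector. Driver subclones are founded by removing
one uniformly chosen parent-clone cell at the scheduled origin time and
are simulated sequentially, justified by the branching property.

Conventions worth knowing:

* Frequency windows are closed intervals $[f_1, f_2]$ everywhere
  (simulator, read simulator, estimators).
* Checkpoints record the state immediately before the first event whose
  time crosses the checkpoint; this choice affects nothing in expectation.
* Conditioning on survival: clone-0 extinction before its drivers are
  founded (or, with no drivers, before the schedule ends) restarts the
  whole run; extinction of a driver subclone restarts that subclone from
  its founder cell at its origin time (the same founder, so the founder's
  passenger set is drawn once). Clone 0 may die after all drivers exist —
  the run is kept if the tumor survives to the end of the schedule.
  Restart counts are returned, and all restarts consume one RNG stream, so
  a seed fully determines the run.
* An event budget (`max_events`) guards near-critical configurations.

Time is measured in days inside the simulator and in years in the
patient-facing interface (365.25 days/year).

`simulate_reads()` adds the sequencing layer: per-site coverage
$R_i \sim \mathrm{Binomial}(M, R/M)$ and variant reads
$Z_i \sim \mathrm{Binomial}(R_i, \chi_i/2)$ for heterozygous diploid
sites; post-processing discards mutations with $Z_i \le L$ (default
$L = 2$), and the observed subclonal count uses the frequency $2Z_i/R$
with the *average* coverage in the denominator, exactly as filtered
pipelines do. Because filtered counts miss mutations below
$2L/(pR)$, `gamma_corrected()` rescales by
$(1/f_1 - 1/f_2) / (pR/(2L) - 1/f_2)$; when the cutoff does not exceed
$f_1$ nothing is expected lost and the observed count is returned
unchanged (our clamping choice — the derivation presumes the cutoff lies
above $f_1$).

## Simulated study conditions

Three growth regimes are shipped (`tumor_regime()`), with rates in
events/day: fast ($b = 0.14$, $d = 0.07$, $r = 0.07$), slow (death rate
kept, birth reduced: $b = 0.095$, $r = 0.025$), and no death
($b = r = 0.07$). Driver subclones double the parent's net rate — a 100%
selective advantage — by raising the birth rate, the natural reading of a
proliferative driver; the sibling layout's second driver confers 150% so
the two subclones remain distinguishable. Observation schedules were
chosen once so that simulated tumors reach roughly $10^5$–$4\times10^5$
cells and every clone stays macroscopic (exclusive fraction above
$f_2 = 0.2$) at the measurement timepoint; the windowed-SFS formula is
asymptotic, and below roughly $10^3$ carriers at the window bottom the
window count runs a few percent short of it, which would leak into the
mutation-rate estimate as spurious bias. Mutation rates follow the
validation studies: $u = 1$/day (and 3, 5, or 10 for the high-rate
variants), within observed genome-wide point mutation rates.

The validation suite (`validation_study()`, `gamma_study()`,
`mpe_table()`) reruns the recovery experiments at configurable replicate
counts: the default test suite uses 30–60 tumors per batch and the
acceptance script 50 (15 in the slow regime, whose event counts are an
order of magnitude higher); percent-error comparisons carry ±3 Monte Carlo
standard errors. The read-simulation study skips mutations with CCF below
one hundredth of the filter cutoff — their probability of passing the
filter is ~$10^{-6}$, bounding the error at under 0.1 mutations while
removing the singleton tail that dominates the mutation list.

## What the fixture generator does and does not emulate

`generate_patient_fixture()` produces a patient bundle whose statistics
follow the model exactly: deterministic clone sizes $(b_i/r_i)e^{r_i
\cdot \text{age}}$ with optional lognormal noise, Beta-distributed CCF
posterior samples centered on the truth (concentration $\kappa = 500$ by
default, an exome-scale posterior width), Poisson clonal counts with the
fixation excess included, Poisson subclonal counts thinned to the
post-filter window, and a WBC series consistent with the total size. It
does **not** emulate subclonal-reconstruction failure modes: mis-clustered
mutations, wrong tree topologies, copy-number distortions of CCFs, or
miscalibrated posteriors. Passing coverage and recovery tests therefore
show the pipeline is correct *given* a faithful reconstruction, not that
reconstruction errors are harmless. Coverage is validated under the noise
sources the interval pipeline models (CCF posterior width and Poisson
counts); biological size fluctuations around the growth curve are a real
additional noise source in patients that the intervals do not claim to
cover.

## Numerical choices and degenerate inputs

* Exclusive fractions in $(-10^{-9}, 0)$ are clamped to 0; larger
  violations raise an inconsistent-CCF error. A clone unobserved at a
  timepoint makes its growth rate undefined (error), and such runs are
  excluded from simulation studies as non-surviving.
* Corrected mutation counts and corrected $\gamma$ are floored at 0.
* The Euler–Mascheroni constant enters the exact first-passage mean as
  `-digamma(1)`.
* Two-point growth fits have exactly zero covariance (the fit is exact);
  degenerate covariances make `sample_growth_params()` return the mean.
* All stochastic entry points accept one integer seed and are
  bit-reproducible under it.

## Known limitations

Exponential growth is assumed throughout; logistic or Gompertz-like
deceleration, spatial structure, treatment effects, and per-clone mutation
rate differences are out of scope. The driver-timing clock inherits the
full dispersion of a single Poisson observation — intervals on $t_i$ are
honest but wide for cancers with few mutations. The MRCA timing rule and
the "available time" definition in the minimal-rate rule are documented
interpretations. Simulated validation uses tumors of ~$10^5$ cells; the
time-since-driver estimator is noticeably noisier there than at clinical
sizes ($10^{11}$ cells), where its first-passage dispersion is a small
fraction of the estimate.
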