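---
title: "Models and methods behind rbalance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rbalance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbalance)
library(dplyr)
```

`rbalance` implements the computational core of a proteome-allocation study
of a facultative chemolithoautotroph: a resource balance analysis (RBA)
growth model, apparent catalytic rate (k~app~) calibration from flux
sampling and proteomics, enzyme-utilization scoring, a transposon
insertion-index essentiality classifier, and a barcoded-mutant (BarSeq)
fitness scorer. Every stage can be exercised on synthetic data with known
ground truth, and this vignette explains the models, the tunable parameters
and the design decisions.

## The resource balance analysis model

Flux balance analysis asks which steady-state flux distributions a
stoichiometric network admits. RBA additionally charges each flux its
protein cost: a reaction running at rate $v$ (mmol gDCW^-1^ hr^-1^)
requires enzyme at concentration $[E] \ge v / k_{app}$, where $k_{app}$
(hr^-1^) is the enzyme's apparent catalytic rate in vivo — an effective
rate under full substrate saturation, not an in-vitro $k_{cat}$. Protein is
finite: the total pool (default 6.18 mmol amino acids gDCW^-1^, i.e.
0.68 g protein gDCW^-1^ at a mean residue mass of 110 g mol^-1^) is split
between compartments (cytoplasm, membrane) by linear functions of the
growth rate $\mu$, and within each compartment a linear non-enzymatic
fraction is reserved for proteins outside the model's scope.
Macromolecular machines are treated the same way: the ribosome must keep up
with protein synthesis ($\mu \cdot c_{aa}^{tot} \le rate_{rib} \cdot
[rib]$, its own protein included), chaperones with a configurable folded
fraction (default 10%), and the RNA/DNA polymerases with a fixed
transcription/replication demand per doubling.

At fixed $\mu$ all of these constraints are linear, so the model is a
feasibility LP: mass balance with the biomass reaction pinned to $\mu$,
maintenance ATP bounded below by $NGAM + GAM \cdot \mu$, a
growth-rate-proportional storage-polymer (PHB) demand, enzyme capacity per
reaction direction, machinery capacity, and compartment budgets. Growth
maximization is a bisection over $\mu$ (default tolerance $10^{-4}$
hr^-1^): feasibility is monotone in $\mu$ for ordinary conditions because
every growth-coupled demand scales with $\mu$ while the protein supply does
not expand. When fluxes are pinned by equality — for instance a forced
CO~2~ fixation rate at a fixed substrate uptake — very low growth rates can
be infeasible too (the excess substrate cannot be dissipated within the
enzyme budget at rest), so `maximize_growth()` falls back to a coarse grid
to bracket the upper edge of the feasible interval before bisecting.

Reversible reactions are split into two non-negative directed fluxes, each
with its own capacity constraint; isoenzymes (GPR alternatives) are
separate variables feeding the same capacity constraint. Among the many
optimal allocations at $\mu^*$ the package always reports the one
minimizing total protein investment $\sum_i L_i [E_i]$ (amino-acid-weighted
over enzymes *and* machines, since machinery is protein too). This
minimal-enzyme solution is the reference for utilization; remaining
degeneracy between equally cheap isoenzymes is resolved arbitrarily by the
solver and documented as non-unique. The PHB demand is implemented as
$v_{PHB} = 3\mu$ mmol gDCW^-1^ hr^-1^ per unit growth rate (configurable):
the demand is growth-rate-dependent and this scaling is the only
dimensionally consistent reading of a per-gDCW coefficient.

### The LP engine

No linear-programming backend is available in the package's dependency
envelope, and the two textbook simplex implementations shipped with base-R
adjacent packages fail on RBA problems: the many zero right-hand-side
equality rows keep artificial variables basic at level zero, a degenerate
configuration that both mishandle. The package therefore carries a dense
two-phase primal simplex (`R/simplex.R`) using Bland's rule throughout
(immune to cycling), explicit post-phase-1 removal of zero-level artificial
variables, and deletion of redundant rows. It is validated against a
brute-force basic-solution enumerator on randomized LPs in the test suite.
Numerical tolerances: pivoting $10^{-9}$, flux-zero reporting $10^{-6}$
mmol gDCW^-1^ hr^-1^, bisection $10^{-4}$ hr^-1^ — chosen to separate
numerical noise from "utilized".

## The toy model

The synthetic network (`gen_toy_network()`) is a deliberately small,
fully electron-balanced lump of knallgas-bacterium central metabolism:
three substrates (fructose-like sugar, formate, succinate), an
Entner-Doudoroff glycolytic route, a CBB (Calvin) cycle consuming
3 CO~2~ + 5 NADH + 6.5 ATP per pyruvate, formate dehydrogenase, a TCA
lump, oxidative phosphorylation with two isoenzymes (proton-pumping
complex I analogue and a cheap alternative NADH dehydrogenase), a
growth-coupled PHB sink and explicit biomass/maintenance pseudo-reactions.
Each metabolite carries carbon and available-electron annotations so that
`reduction_audit()` can verify conservation per reaction. The degrees of
reduction of sugar (4.0 per C-mol) and biomass (4.12 per C-mol) are nearly
equal by construction, which is why forcing CO~2~ fixation on sugar cannot
improve the biomass yield: there is no spare redox power to pay for it, and
the extra ATP/NADH demand must be met by burning more carbon, so the cells
*emit* more CO~2~. The qualitative forced-CBB experiment (growth and yield
non-increasing, net CO~2~ emission non-decreasing as the forced flux rises
at a fixed sugar uptake of 4 mmol gDCW^-1^ hr^-1^) is reproduced
structurally by the toy model over its feasible forcing range
(0–1.3 mmol gDCW^-1^ hr^-1^; the range is narrower than in a genome-scale
model because the toy budget is small).

Toy parameters were set once to give realistic physiology and are not
tuned afterwards: transporter and catabolic k~app~ values between 4 × 10^3^
and 4 × 10^4^ hr^-1^, the CBB complex deliberately the most protein-
expensive route per unit flux (5960 amino acids per complex), maintenance
NGAM = 3 mmol gDCW^-1^ hr^-1^ and GAM = 40 mmol gDCW^-1^, and compartment
budget models with a non-enzymatic reserve of roughly 30–38% falling
mildly with $\mu$ (matching the observed non-modeled proteome mass share).
The resulting optima — $\mu^*$ ≈ 0.38 hr^-1^ on sugar (yield
0.53 gDCW g^-1^), 0.15 hr^-1^ on formate with obligatory CBB flux, 0.32
hr^-1^ on succinate — are in the physiological range for the organism
class. The budget fraction models are valid for $\mu \in [0, 1]$; the
growth bisection defaults to that bracket.

## k_app calibration

Calibration inverts the capacity relation on measured data: for each
reaction direction, $k_{app} = \max_{conditions} v^{max} / [E]^{meas}$,
the maximum flux per unit allocated enzyme. Fluxes come from uniform
sampling of the metabolic flux polytope at the chemostat steady state
(growth pinned to the dilution rate, maintenance bounded, uptake bounded
or — when the steady-state uptake rate was measured, as in a chemostat —
pinned). The sampler is hit-and-run in the null space of the equality
system, started from the average of the flux-variability-analysis (FVA)
vertex solutions; reactions that FVA shows to be pinned are frozen as
equalities so the walk only explores genuinely free directions. FVA itself
is retained as an independent cross-check: sampled envelopes must lie
inside FVA bounds. Measured protein abundance is allocated to reactions by
the sharing rule: a protein used by several reactions is split equally
among them, an isoenzyme complex is limited by its scarcest subunit
(minimum of allocated abundance per required copy), and a reaction sums
its alternatives. Reactions with no flux or no measured enzyme receive the
median of the fitted k~app~ distribution, flagged `median_filled` — never
silently. On noiseless synthetic proteomes generated from a known solution
with pinned uptake the polytope collapses to the steady-state point and
calibration recovers the generating k~app~ exactly.

The randomized ensemble (`sample_kapp_ensemble()`) resamples every
reaction's k~app~ independently, with replacement, from the pooled fitted
distribution; whether the original analysis permuted whole tables or
resampled per reaction is not documented anywhere, and per-reaction
resampling is the more conservative choice for counting *potentially*
utilizable reactions. `count_utilized_reactions()` then reports, per
condition, reactions carrying flux in at least one ensemble member, their
union, the core used in every simulation of every condition, and
condition-unique sets.

## Enzyme utilization

Utilization is the ratio of predicted minimal to measured abundance,
$U_E = [E]^{min}/[E]^{meas} \times 100\%$. Enzymes measured but absent
from the prediction get $U_E = 0$; predicted-but-unmeasured enzymes are
reported separately, and a measured zero with a positive prediction is
flagged undefined rather than infinite. Mean utilization across the
designated conditions sorts enzymes into low ($\le 33\%$), moderate
($33\%$–$66\%$] and high ($> 66\%$) — both boundaries inclusive on the
lower category, a convention that matters only for enzymes landing exactly
on a boundary and is configurable. Over-unity utilization (measured below
predicted) is retained and flagged because it diagnoses calibration error.
Cross-condition variability uses the sample (n−1) standard deviation over
the per-condition mean abundance. With noiseless synthetic proteomes and
known per-enzyme excess factors $x \ge 1$, utilization recovers
$100/x$ exactly and categories follow deterministically.

## Essentiality from transposon insertion data

Insertions within the central 80% of an ORF count as true knockouts
(positions outside [0.1, 0.9] of the ORF are discarded). The insertion
index of gene $i$ is its per-bp insertion density normalized by the local
density, $II_i = (n_i/k_i)/(n_r/k_r)$, with the window $r$ spanning 100
genes centered on the target (the target included — the distinction is
negligible at this window size), truncated at replicon ends by default and
optionally wrapped for circular replicons. The II distribution of a dense
library is bimodal; a two-component gamma mixture is fitted by EM with
moment-based initialization from the density antimode, which for a
locally-normalized index always lies between the essential mode near 0 and
the non-essential mode near 1 (the search is restricted to (0.05, 0.9)).
The M-step solves the weighted gamma likelihood by Newton iteration on the
shape; convergence is declared on a relative log-likelihood change below
$10^{-8}$, and fits whose component means fail to separate at least
twofold are flagged degenerate rather than used for thresholds.

Zero-insertion genes have $II = 0$ exactly, where a gamma mixture has no
usable density. Instead of substituting a single constant (which collapses
the low component onto a point mass), the fit uses a smoothed index in
which a zero count is replaced by half an insertion: the resulting pseudo-
index varies with gene length and local density, giving the essential
component a proper spread. Classification itself uses the raw index:
the lower threshold is the largest II where the essential component's
density is at least fivefold the non-essential one, the upper threshold
the smallest II above it where the reverse holds; genes below, between and
above are called essential, probably essential (ambiguous) and
non-essential. An index of zero is always essential. Reaction-level calls
take the worst gene: any essential gene makes the reaction essential, else
any probably-essential gene makes it probably essential.

The synthetic library generator draws gene lengths lognormal (median
0.9 kb), per-gene insertion propensities gamma-distributed (mean 1, shape
3) for overdispersion, Poisson counts at 15 insertions/kb — the density
scale of a saturated library — and a rate ratio of 0.02 for essential
genes. Recovery is scored with abstentions (ambiguous calls) counted by
their own criterion: label accuracy is measured over decided calls, the
ambiguous fraction separately. Residual errors are genuine overlap:
non-essential genes whose propensity draw is very low are statistically
indistinguishable from essential genes, which mirrors real libraries.

## BarSeq gene fitness

Per-barcode fitness is the library-size-normalized log2 fold change
$f = \log_2\frac{c_t + \psi}{N_t} - \log_2\frac{c_0 + \psi}{N_0}$ with
pseudocount $\psi = 0.5$ shrinking low-count estimates toward zero. Gene
fitness is the inverse-variance weighted mean over the gene's central-ORF
barcodes ($w = 1/(1/(c_0+\psi) + 1/(c_t+\psi))$, the Poisson delta-method
variance of a log fold change; equal weights available), recentered per
sample so the median of designated neutral genes — all genes by default —
is zero. Median-centering assumes a mostly-neutral library; with a large
depleted fraction an explicit neutral list should be supplied. A score is
significant when $|F| \ge 3$ after at least 8 generations, a threshold
sitting well outside the neutral bulk (−2..2). The generator drifts
barcode abundances as $2^{F g/g_{ref}}$ over $g$ generations
($g_{ref} = 8$, the span defining one fitness unit) and draws multinomial
counts at the requested depth, so recovery at the 8-generation sample is
directly comparable to the generating fitness.

## Chemostat physiology

`substrate_uptake_rate()` implements $q_S = D (S_i - S_r)/c_{bm}$ in the
per-volume convention: with the biomass term a concentration, the culture
volume cancels and has no place in the formula. The yield/maintenance fit
is ordinary least squares of $q_S$ on $\mu$ (yield = 1/slope, intercept =
maintenance). `protein_pool_mmol()` and `retention_time()` are the unit
conversions used to parameterize budgets and sampling times
(0.68 g gDCW^-1^ → 6.18 mmol aa gDCW^-1^; $t_R = 1/D$, sampling after
$5t_R$). `compartment_fraction_fit()` produces the linear fraction models
consumed by `budget_spec()`, clipping predictions to [0, 1] with a
warning.

## What the synthetic data do and do not show

The generators emulate the statistical structure the analyses assume:
lognormal multiplicative proteome noise (strictly positive,
CV-parameterizable), Poisson/gamma insertion counts with uniform positions,
multinomial sequencing counts under exponential selection. Passing the
recovery suites shows the estimators are correct and well-calibrated under
those assumptions at desk scale (a 15-reaction network, 500-gene
libraries, 10^6^ reads); it does not show robustness to structured
artifacts real data carry — batch effects, ionization biases, positional
insertion hotspots, PCR jackpots — nor does the toy model's size reproduce
genome-scale headline counts. Problem sizes in the tests (hundreds of LP
solves, 10-seed recovery runs) were chosen so the whole suite runs on a
single CPU in a few minutes.

## Example

```{r example, eval = FALSE}
net <- gen_toy_network()
kapp <- as_kapp_table(attr(net, "kapp_true"))
opt <- maximize_growth(net, toy_machineries(), toy_budgets(), kapp,
                       toy_conditions(net)$fructose)
glance(opt)
tidy(opt) |> filter(flux != 0)
autoplot(opt)

# full synthetic pipeline
res <- run_pipeline(pipeline_config(seed = 1))
res$utilization_categories
```
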