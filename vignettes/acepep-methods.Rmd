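---
title: "Methods: in silico ACE-inhibitory peptide discovery with acepep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico ACE-inhibitory peptide discovery with acepep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acepep)
```

`acepep` models the computational arc of a bioactive-peptide screening
campaign: rank parent proteins and proteases in silico, optimise hydrolysis
conditions by response-surface methodology, score the peptides identified by
mass spectrometry, and characterise inhibition kinetics. This vignette
records the models, the tunable parameters, and the design decisions taken
where the methodology literature leaves the choice open.

## Occurrence and release statistics

For a protein of length $N$ and a reference table of (activity, fragment)
pairs, the frequency of occurrence of an activity is

$$A = a / N,$$

where $a$ counts matches of that activity's fragments in the sequence.
Published descriptions of this statistic do not state how overlapping
matches are handled. `acepep` counts **every (fragment, start-position)
pair**, overlaps included, because occurrence-counting tools in this field
report fragment occurrences rather than covered positions; a
`count = "distinct"` switch counts each fragment at most once per protein
for users who prefer the coarser convention. Both modes are checked against
a brute-force substring enumeration in the test suite.

Consequences worth knowing: $A$ is not bounded by 1 in general (overlapping
dipeptide matches can exceed one per residue), it is invariant to protein
metadata, and it scales as $1/N$ when a fixed match set is embedded in a
longer inert sequence.

After digestion, the frequency of release is $A_E = d / N$ with $d$ the
number of released fragments **exactly equal** to a reference fragment,
counted with multiplicity. Exact identity — not substring containment — is
the release criterion, matching the convention that a bioactive fragment
still buried inside a longer peptide has not been released.

The bundled `ace_reference()` is a small curated stand-in (a few dozen
di/tripeptides with reported ACE-inhibitory activity, plus small DPP-IV and
antioxidant sets). It is explicitly *not* a snapshot of any database, so
absolute $A$ and $A_E$ values computed against it are not comparable with
values computed against curated databases; only the machinery is the same.
This is also why tests assert structural identities and oracle agreement,
never absolute occurrence values.

## Proteolysis rules

Cleavage specificity is data-driven: a rule is a P1 residue set plus an
optional P1′ exclusion set, and the bond after residue $i$ is cut iff
residue $i$ is in P1 and residue $i+1$ is not excluded. The shipped
seven-enzyme table uses the classical approximations (trypsin K/R not
before P; chymotrypsin A F/Y/W not before P; pepsin pH 1.3 F/L; broad
hydrophobic/aromatic P1 sets for papain, stem bromelain, subtilisin and
proteinase K). Exact cleavage tables vary between databases; users can
substitute their own via `read_protease_rules()`. The theoretical degree of
hydrolysis is $DH_t = 100 \cdot |\text{sites}| / (N-1)$ per chain; a
single-residue chain has no bonds and is rejected rather than given a
conventional value. Multi-protein summaries average $DH_t$ per protein
rather than pooling bonds, because screening reports quote per-protein
ranges; since the per-enzyme release-frequency headline could be either a
per-protein mean or a residue-pooled value, `enzyme_panel()` emits both.

## Response-surface model

The hydrolysis optimisation uses the three-factor Box–Behnken design
(12 edge midpoints + 5 centre replicates) with factors coded to
$\{-1,0,1\}$ (defaults: temperature 50/55/60 °C, pH 8/8.5/9, time 2/3/4 h)
and the full second-order model — 10 coefficients, 7 residual df — fit by
ordinary least squares. The bundled `hydrolysis_design()` table holds the
published triplicate-mean responses; the per-replicate raw data are not
public, so the fit uses the 17 printed means, and small discrepancies with
the published ANOVA (e.g. a pure error recomputed as 1.38 from printed
means against a published 1.52) are inherited from upstream rounding, not
chased.

ANOVA uses partial (type III) sums of squares per term, which coincide with
sequential sums of squares here because the design is orthogonal — an
identity asserted in the tests ($SS_{\text{main}} = 8\hat\beta^2$ on this
design). The residual is split into lack of fit and pure error using the
centre replicates (df 3 + 4 = 7); term F tests use the residual mean
square, the lack-of-fit test the pure-error mean square. Diagnostics follow
the response-surface software conventions: PRESS via the leave-one-out
identity $\sum (e_i/(1-h_{ii}))^2$, predicted $R^2 = 1 - PRESS/SS_{tot}$,
and adequate precision
$(\max\hat y - \min\hat y)/\sqrt{p\,MS_{res}/n}$.

`find_optimum()` maximises the fitted quadratic over the coded cube
$[-1,1]^3$: if the Hessian is negative definite and the stationary point is
interior, it is returned analytically; otherwise a 27-start L-BFGS-B search
with box bounds finds the boundary optimum (with a warning when the surface
is a saddle). The test oracle is a dense grid — a 0.02-step coarse pass
refined locally to step 0.001, which bounds the oracle's own location error
well below the 0.01 coded-unit comparison tolerance. A full 0.001-step grid
over the cube ($10^9$ points) would add nothing at that tolerance.

## Candidate scoring

Each candidate carries three positive channels: MS abundance, de novo
confidence, and the magnitude of the docking binding energy (a non-negative
energy is rejected — a docked pose must be favourable to be meaningful
here). Although screening papers describe the normalisation loosely as
"min-max scaling", the published worked example is only reproduced by
**ratio to the channel maximum** ×100 (so the best candidate scores exactly
100 and the worst scores above 0); `acepep` therefore defaults to
ratio-to-max and offers `method = "min_max"` for the literal convention.
The total is the weighted sum with default weights 0.40/0.30/0.30 (A/B/C),
validated to sum to 1 within $10^{-9}$. Ranking ties are broken by
descending abundance, then sequence, so ranks are reproducible. Subscores
and totals are invariant to rescaling any channel by a positive constant.

The bundled `rj_candidates()` table carries the seven published candidates
with both raw channels and published subscores. The published score A was
normalised over all 57 identified peptides, of which only these seven
abundances are public; recomputed score A values therefore differ slightly
from the published column, while scores B and C are fully recomputable.
Tests compare totals recombined from the published subscores and recompute
B and C from the raw columns.

## Inhibition kinetics

The endpoint assay formula is
$\text{inhibition} = 100\,[(a_1-a_2)-(b_1-b_2)]/(a_1-a_2)$; a blank that
does not react ($a_1 \le a_2$) is an error, and negative inhibition
(apparent activation) is returned as-is with a warning.

`fit_mm()` provides the double-reciprocal Lineweaver–Burk route
(unweighted OLS of $1/v$ on $1/S$; $V_{max}$ and $K_m$ from the
intercepts) and a direct nonlinear Michaelis–Menten fit as the standard
cross-check; on noiseless data they coincide, and under multiplicative
noise the direct fit has lower error — both properties are asserted
statistically in the tests.

`classify_inhibition()` fits one curve per inhibitor concentration and
reads the inhibition mode from the apparent $K_m$ and $V_{max}$
trajectories relative to the uninhibited series, with a relative tolerance
(default 0.10) separating "constant" from "varying": $K_m$ up /
$V_{max}$ flat is competitive, $V_{max}$ down / $K_m$ flat is
non-competitive, both moving is mixed, and a falling $K_m$ is flagged as
inconsistent. The shifts are taken from a linear regression of the
per-series estimates on inhibitor concentration, evaluated at the highest
level — pooling the whole trajectory rather than trusting the single
noisiest series, whose apparent parameters are the worst-extrapolated.
$K_i$ comes from the secondary plot: reciprocal-line slopes regressed on
inhibitor concentration, $K_i$ = −(X-intercept); for competitive,
non-competitive and the $\alpha$-parameterised mixed model alike, that
X-intercept is exactly $-K_i$. The "lines crossing left of the 1/v axis"
reading of mixed inhibition is a plot diagnostic, not the classifier.

IC50 is estimated with the four-parameter logistic
$y = b + (t-b)/(1+(IC_{50}/x)^h)$ by Levenberg–Marquardt least squares on
$\log IC_{50}$. Start values pad the asymptotes 5% beyond the observed
range — starting them exactly at the extremes makes the initial Jacobian
rank-deficient on noise-free data — and an IC50 outside the measured
concentration span is flagged. Published peptide assays report
concentrations in mg/mL but IC50s in µM; `mgml_to_uM()` converts using
average residue masses.

## Synthetic data

Every generator is a pure function of (parameters, seed); each draws from
its own stream derived from the master seed by a stable labelled sub-seed,
so adding a generator never perturbs the others' output. Defaults mirror
the royal-jelly study's scales: nine proteins of 300–600 residues;
responses generated from the fitted coefficients of the bundled experiment
with σ = 0.9 (its residual standard deviation); abundances log-normal
around 1.5×10¹⁰ with 57 candidates; binding energies uniform on
[−9.5, −6.8] kcal/mol; kinetics with $V_{max}=1$, $K_m = 0.5$ mM FAPGG,
$K_i = 10$ µM at inhibitor levels 0/5/10 µM over a 6-point substrate grid
spanning 0.2–5 × $K_m$, in triplicate with 1–5% multiplicative rate noise
(the assay protocols the generator stands in for run all measurements at
least in triplicate); dose-response around IC50 16.9 µM, Hill 1, additive
noise 2 percentage points.

What the generators do **not** emulate: real MS spectra and their
intensity biases, missed cleavages and partial digestion, pH/temperature
dependence of protease activity, peptide solubility or matrix effects, and
correlated assay drift. Passing simulation tests therefore demonstrates
the estimators' correctness and calibration under the stated noise models,
not robustness to every artefact of real data.

Problem sizes in the test suite were chosen to make the Monte-Carlo checks
statistically meaningful while keeping a full run around a minute on one
core: 1000 random digests, 100 random proteomes against the substring
oracle, 200 response-surface replicates for coefficient-recovery bias, a
3 × 3 × 100 classification grid, 100 $K_i$ replicates and 500 IC50
replicates.

## Pipeline

`run_pipeline()` drives any subset of stages (index, digest, rsm, score,
kinetics, ic50) from a validated configuration (unknown keys rejected,
referenced files must exist), writes per-stage tables, and produces a JSON
report carrying input MD5 hashes, the seed and the package version. Reruns
with identical inputs are identical apart from the timestamp. The
command-line wrapper in `inst/cli/` is a thin veneer over these functions.

## Known limitations

* Occurrence/release values depend entirely on the supplied reference
  table and cleavage rules; the bundled ones are demonstrative stand-ins.
* The response-surface fit assumes homoscedastic Gaussian residuals across
  the design and is fit to per-run means when replicate-level data are
  unavailable.
* The kinetics classifier assumes clean initial-rate data and the three
  canonical reversible-inhibition archetypes; substrate inhibition,
  tight-binding behaviour and progress-curve effects are out of scope.
* IC50 comparability across studies is limited by assay conditions (enzyme
  source, substrate concentration, buffer); the 4PL fit quantifies the
  bundled assay format only.
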