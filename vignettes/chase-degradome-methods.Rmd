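---
title: "Methods: half-life estimation and degradome discovery from CHX chase proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: half-life estimation and degradome discovery from CHX chase proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protchase)
```

## The turnover model

Cellular protein abundance reflects a balance of zero-order synthesis and
first-order degradation,

$$\frac{dI}{dt} = k_{syn} - k_{deg}\, I,$$

where $I$ is the protein's LFQ intensity, $k_{syn}$ (intensity/h) the
synthesis rate and $k_{deg}$ (1/h) the degradation rate constant. In a
nonproliferative steady state, $I = k_{syn}/k_{deg}$ and intensities are
constant. Treating cells with cycloheximide (CHX) blocks translation and
removes the $k_{syn}$ term, so over a chase each protein decays as

$$I(t) = I_0\, e^{-k_{deg} t}, \qquad t_{1/2} = \frac{\ln 2}{k_{deg}}.$$

$\ln I$ is therefore linear in time and $k_{deg}$ is the negative slope of
an ordinary least-squares fit. A proteolysis-targeting chimera (PROTAC)
recruits its target to an E3 ligase and accelerates that target's
$k_{deg}$; co-treating CHX with the degrader makes the acceleration visible
as a steeper decay, and the half-life reduction
$\Delta t_{1/2} = t_{1/2}^{CHX} - t_{1/2}^{CHX+PROTAC}$ quantifies potency.

The model assumes (i) an actual steady state before the chase (verified in
the data by the flatness of the vehicle-control profiles), (ii) decay that
is first-order over the chase window, and (iii) negligible dilution by cell
division. It ignores compound uptake kinetics, which introduce a lag and
bias short chases; this is a known limitation of the assay, not of the
implementation.

## Pipeline stages and the two branches

Starting from a MaxQuant-style protein-groups table and a sample design
(condition, timepoint, replicate per sample), the pipeline:

1. drops reversed-sequence decoys, common contaminants and
   site-only identifications (`filter_decoys()`);
2. on a **differential branch**, log2-transforms, imputes left-censored
   missing values, and runs the moderated permutation-FDR contrast of
   CHX+PROTAC vs CHX at the chase endpoint (`volcano()`);
3. on a **kinetics branch** that never sees imputed values, converts linear
   intensities to protein fraction remaining (`compute_pfr()`), classifies
   chase profiles (`classify_profiles()`) and fits first-order decay
   (`fit_first_order()`);
4. intersects volcano candidates with decaying kinetics
   (`discover_targets()`), optionally checks proteasome-inhibition rescue
   (`rescue_check()`), and summarizes decaying-set overlaps, per-condition
   median half-lives and the $\Delta t_{1/2}$ ranking.

Keeping imputed values out of the kinetics branch is enforced at run time:
`compute_pfr()` and `fit_first_order()` refuse a matrix whose `imputed`
flag is set. Imputation fabricates plausible low values for the
differential test; feeding those into a decay fit would fabricate decay.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| imputation downshift | 1.8 | column SDs | centres imputed draws at the detection limit, below the observed distribution |
| imputation width | 0.3 | column SDs | narrow left-censored dropout model |
| volcano `s0` | 0.1 | log2 intensity | damps tiny-variance proteins in the moderated t |
| volcano FDR | 0.05 | — | permutation-estimated global threshold on \|t\| |
| permutations | 250 | — | enumerated exhaustively when fewer distinct splits exist |
| volcano `top_k` | 10 | proteins | strongest decreases kept as candidates regardless of significance |
| stability band | 80–120 | % PFR | per-replicate band defining "stable" |
| decrease tolerance | 0 | relative | strict monotone decrease defines "decaying" |
| half-life cap | 60 | h | longer half-lives are not estimable from an 8 h chase |
| rescue depletion / restoration | 0.7 / 0.8 | fraction of control | operational cut-offs for "depleted" and "restored" |

The stability band is applied to every replicate value (the stricter
reading); a per-timepoint-mean mode exists (`band_mode = "mean"`).
Imputation statistics are computed per sample column (the convention of the
mainstream proteomics tools); a whole-matrix mode is available
(`per_column = FALSE`). The rescue thresholds are this package's own
operational quantification of an assay that is usually read qualitatively
from bar plots, and should be tuned to the experiment's noise.

## The moderated permutation test

For groups $a, b$ with pooled standard error $se$, the statistic is
$t_{mod} = (\bar a - \bar b)/(se + s_0)$: the SAM-style fudge factor $s_0$
prevents proteins with accidentally tiny within-group variance from
dominating the volcano. Significance is called by a single global threshold
$c$ on $|t_{mod}|$: for each candidate $c$ the FDR is estimated as the mean
number of permuted $|t_{mod}| \ge c$ (over label permutations, all proteins)
divided by the observed count, and the smallest $c$ with estimated
FDR $\le$ 0.05 is the threshold (ties at $c$ are significant). This is
simpler than the significance-curve geometry some desktop tools draw in
(difference, p) space, and is directly verifiable against a brute-force
enumeration; for symmetric designs the calls are equivalent.

One design decision deserves emphasis. A triplicate-vs-triplicate contrast
has $\binom{6}{3} = 20$ distinct label splits, but two of them — the
observed labels and their group swap — reproduce the observed statistics
verbatim. If they are left in the null, the estimated FDR can never fall
below $2/20 = 0.10$ and *no protein can ever be significant at FDR 0.05*,
which contradicts how such volcanos behave in practice. The permutation
null here therefore excludes the observed-equivalent assignments (18 splits
remain for 3 vs 3, enumerated exhaustively; larger designs sample distinct
assignments without replacement under the run seed). Under a global null
this estimator remains conservative: the suite verifies that the fraction
of significant calls on pure-noise data stays within Monte-Carlo error of
the nominal rate.

## Profile classification and fitting rules

Per condition, only chase timepoints ($t > 0$) are used; the $t = 0$
baseline is harvested for the vehicle control only and serves exclusively
as the PFR denominator. Per protein and condition, in order of precedence:

- **incomplete** — any replicate missing at any chase timepoint
  (the 3-of-3 detection rule);
- **stable** — every replicate PFR within the stability band at every
  chase timepoint;
- **decaying** — strictly decreasing per-timepoint mean PFR;
- **other** — the rest.

Fits regress $\ln I$ on time over all individual replicate points (no
pre-averaging; for balanced complete data this equals the mean-based fit),
require at least 3 present points spanning at least 2 distinct timepoints,
and report $k_{deg} = -\text{slope}$, $t_{1/2} = \ln 2 / k_{deg}$ (undefined
for $k_{deg} \le 0$), and $r^2$. Natural log is used so the slope is
$k_{deg}$ directly; log2 is reserved for the differential branch. Numerical
edge cases: an exactly constant series is assigned slope 0 (not
floating-point dust), and its $r^2$ is undefined; half-lives above the cap
are retained but flagged `excluded_long`, and the flag is honoured only at
summary stages. Ranking ties in $\Delta t_{1/2}$ break lexicographically by
accession. In the full pipeline the $\Delta t_{1/2}$ table is restricted to
proteins classified decaying in both arms — the only proteins whose
half-life is meaningful in each condition.

## What the simulator emulates

`simulate_chase()` draws per-protein steady intensities (log-normal,
default median 1e7, sdlog 2 — spanning the orders of magnitude of real LFQ
tables) and basal rates $k_{deg}$ (log-normal, default median
$\ln 2 / 15$ 1/h, i.e. a 15 h median half-life on the scale reported for
nonproliferative steady-state cells, with sdlog 1 to match the one-to-two
orders of magnitude spread of measured proteome half-lives). A configurable
fraction of proteins are degrader targets whose treated rate is multiplied
by a uniform 3–10 factor. Arms follow the model exactly: CON constant,
CHX and CHX+PROTAC exponential with the basal/treated rate. The optional
rescue arms keep synthesis running (no CHX): the degrader-only arm follows
the full ODE solution relaxing toward the new steady state
$k_{syn}/k^{treat}_{deg}$, and the proteasome-inhibited arm stays at the
basal steady state because the degrader-induced acceleration is blocked.

Measurement noise is multiplicative log-normal with
$\sigma = \sqrt{\ln(1 + CV^2)}$ and unit mean. Missingness is applied MNAR
first — noisy values below a configurable quantile of the full value
distribution drop out, emulating the detection limit — then MAR as
independent Bernoulli dropout. The generator does **not** simulate
replicate batch effects, peptide-level identification, ratio compression,
or uptake-kinetics lag; passing tests on simulated data therefore validate
the estimators and wiring under the model's own assumptions, not robustness
to every artefact of real LFQ data.

## Problem sizes and what the checks show

The package's property checks use 100 noiseless proteins for exact
closed-form recovery (relative $k_{deg}$ error below 1e-9), 1,000 proteins
at 10% CV for noisy recovery (median relative half-life error well under
15% for true half-lives of 2–20 h), 1,000 proteins with 5% planted 5×
targets for discovery, a 2,000-protein pure-noise matrix for FDR
calibration, and 12,000 imputed cells for the imputation distribution —
sizes chosen so each property is measured with comfortable Monte-Carlo
margins at desk scale. The acceptance script (`scripts/acceptance.R`)
recomputes all of these from scratch at run time.

One property deserves a caveat rather than a number: the strict
no-tolerance decrease filter is intentionally conservative. At 10% CV,
even a target degraded with a 3 h half-life fails the strict
mean-decrease test in roughly one run in twelve (the 0.5 h grid steps are
small relative to replicate noise), and slower targets fail more often.
Verified-target sensitivity on a realistic half-life spread is therefore
meaningfully below 1 by design of the filter — the trade-off that buys its
near-zero false-verification rate. Raising `decrease_tolerance` trades
specificity back for sensitivity.

## Known limitations

- Half-lives beyond ~60 h are not estimable from an 8 h chase; they are
  flagged rather than reported as estimates.
- The assay itself cannot separate degradation from other loss processes
  once translation is blocked; apoptosis or stress responses during the
  chase would masquerade as decay.
- The permutation test needs at least two replicates per group and gains
  resolution slowly with replicates; with triplicates the achievable
  threshold granularity is limited by 18 usable splits.
- The rescue check compares single-endpoint means; it has no replicate
  significance model and should be read as a screen, not a test.
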