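---
title: "Deconvolving RNA structure ensembles from chemical probing reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving RNA structure ensembles from chemical probing reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spdeconv)
library(dplyr)
```

## The problem

An RNA in solution is rarely one structure. Riboswitches toggle between
ligand-bound and unbound folds, riboSNitches rearrange locally around a SNP,
and cotranscriptional intermediates coexist at every transcript length.
Chemical structure profiling (SP) — SHAPE or DMS probing read out by
sequencing — measures, at each nucleotide, how often the *ensemble* was
modified there. Averaged per-site reactivities therefore blur the
constituent structures together: a site paired in half the molecules looks
"half reactive", and no single structure fits the profile.

`spdeconv` resolves this by working at the level of whole reads rather than
per-site averages. Each sequenced cDNA carries a *modification pattern*:
in truncation chemistries, the single position where reverse transcriptase
stopped; in mutational profiling, the set of positions mutated within the
read. Given a set of candidate structures, the package computes the
probability that each structure generates each pattern, and finds the
sparse, non-negative mixture of candidates whose predicted pattern
frequencies best match the observed ones.

## The model

Number the sites $1..L$ from the 3' end (site 1 is adjacent to the priming
site); every user-facing table and file uses conventional 5'→3'
coordinates, and the conversion happens exactly once at the I/O boundary.
Each candidate structure is reduced to a per-site binary state:
*constrained* (base-paired, or marked constrained because of a ligand
contact or tertiary interaction) or *unconstrained*. Two parameters govern
detection:

* $\eta$ — the probability that an unconstrained site is modified, assumed
  common to all unconstrained sites of all structures of one sequence;
  constrained sites are assumed unmodifiable.
* $\gamma_l$ — the per-site noise probability (natural polymerase drop-off,
  or background mutation), estimated from a mock-treated control.

The per-site probability of a detectable event under structure $s$ is
$e_l = 1-(1-\eta)(1-\gamma_l)$ at unconstrained sites and $e_l = \gamma_l$
at constrained sites (0 at sites the chemistry cannot assay). In truncation
mode a read stops at the first event counted from the primer, so

$$\Pr(\text{stop at } p \mid s) = e_p \prod_{l<p}(1-e_l), \qquad
  \Pr(\text{complete read} \mid s) = \prod_{l=1}^{L}(1-e_l),$$

and each design-matrix column is an exact probability distribution over the
$L+1$ patterns (the test suite verifies this against a brute-force
enumeration of all per-site event outcomes, to $10^{-12}$). In mutation
mode events at different sites are independent within a read, so a pattern
(a mutated-site set $M$) has probability
$\prod_{l \in M} e_l \prod_{l \notin M}(1-e_l)$ over the informative sites.
Recording only each read's first modification projects mutation data onto
the truncation pattern space; the projection is exact at the distribution
level (the min-site marginal of the mutation model *is* the truncation
model), which the suite checks by enumeration to $10^{-10}$.

Observed pattern frequencies $\mathbf{y}$ are then modeled as
$\mathbf{y} = X\boldsymbol{\rho} + \boldsymbol{\varepsilon}$ with
$x_{ps} = \Pr(p \mid s)$, and the abundances are estimated by non-negative
least squares (Lawson–Hanson, via `pracma::lsqnonneg`). Structures whose
normalized abundance exceeds a threshold (default 1 %) are selected and
their abundances renormalized to sum to 1.

### Parameter estimation

With $X_l$, $C_{l+}$ the event count and local coverage at site $l$ in the
treated sample and $Y_l$, $C_{l-}$ their control counterparts:

$$\hat\gamma_l = Y_l / C_{l-}, \qquad
  \hat\beta_l = \frac{X_l/C_{l+} - \hat\gamma_l}{1-\hat\gamma_l}.$$

In truncation mode local coverage counts reads that stop at or read through
the site; in (full-overlap) mutation mode every read covers every site.
Without a control, $\gamma$ is set to 0 with a message. Negative
$\hat\beta_l$ (noise exceeding signal) are clamped to 0 and counted —
downstream probabilities require $[0,1]$, and the clamp count is a useful
data-quality signal. $\hat\eta$ is the median of the reactivities strictly
exceeding their mean: sites that are unpaired in essentially all structures
carry $\beta_l \approx \eta$, and the median protects against the outliers
common in SP data. When no value strictly exceeds the mean (a constant
profile) the maximum is used, with a warning. For base-selective
chemistries (DMS) all estimation is restricted to the informative A/C
sites.

### Pre-filtering

Before fitting, candidates that contradict the data are removed: with
$H = \{l : \hat\beta_l > \hat\eta\}$ the highly reactive sites, a structure
is dropped when it constrains more than $\max(1, |H|/2)$ of them — more
than a single nucleotide, and more than half the highly reactive set. A
single highly reactive site therefore never removes anything; highly
reactive sites are the noisiest measurements and a one-site conflict is
weak evidence.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.01 | minimum normalized abundance for selection; selected abundances are renormalized |
| `eta` | estimated | unconstrained-site modification probability (unitless probability); pass a value to override the estimator |
| `gamma` | control-estimated, else 0 | per-site noise probability |
| `prefilter` | `TRUE` | reactivity-consistency screen described above |
| `min_fraction` (motifs) | 1 | fraction of a motif's pairs required for cluster membership |
| `window` (smoothing) | 3 | mean-filter width for trajectories, shrinking at the edges |

Candidate identity is judged over the analysis region intersected with the
informative sites: structures identical there are indistinguishable to the
assay, so `dedup()` keeps the first occurrence (samplers emit in draw
order, making the choice deterministic), and the fit additionally merges
exactly duplicate design columns and reports the merged group rather than
splitting abundance arbitrarily — SP data cannot reveal pairing partners,
so this is an information-theoretic limit, not a defect.

## What the simulator emulates — and what it does not

`ground_truth()` + `pattern_distribution()` + `draw_reads()` generate reads
from the same generative model the fit assumes: multinomial sampling over
exact pattern probabilities, with two noise mechanisms layered on top —
relative Gaussian perturbation of pattern counts
(`add_count_noise()`, sd $= \sigma \cdot$ count, so one $\sigma$ is
meaningful across patterns of very different frequency) and dilution of the
ensemble by decoy structures (`add_decoys()`, which scales the true
abundances by $1-f$ and splits $f$ equally among the decoys). Mutation-mode
simulation beyond 20 informative sites switches to per-read Bernoulli
sampling (`draw_reads_bernoulli()`), distributionally identical by the
independence of the per-site events.

Passing simulation tests therefore shows that the estimation chain inverts
the model correctly at realistic depths; it does *not* show robustness to
everything real libraries contain — PCR and priming biases, partial-overlap
reads, alignment artifacts, or modification-rate heterogeneity among
unconstrained sites (the single-$\eta$ assumption). The mock control in the
simulations reuses the treated ensemble with $\eta = 0$, exactly matching
the assumption that controls share the noise process.

The bundled test RNA is a 36-nt engineered bistable hairpin toy. Its
candidate pool (`inst/extdata/bistable36_sample.db`) is a deduplicated
1000-draw Boltzmann sample produced externally with `RNAsubopt`, mirroring
how candidate sets are produced in practice; statistical sampling itself is
deliberately outside this package — any sampler that writes dot-bracket
files can feed it. Ground truths for the recovery studies are the pool's
four dominant, mutually distinguishable folds; decoys are drawn from the
same pool, because decoys in practice *are* plausible folds of the same
sequence. Early experiments with uniformly random decoy structures showed
why this matters: unconstrained random decoys occasionally differ from a
true structure at only one or two sites, which makes the split formally
unidentifiable and says nothing about the method.

## Study sizes and numerical choices

The recovery suites use $N = 10^5$ reads per sample (treated and control),
20 seeded ground truths with 2–4 structures, flat-Dirichlet abundances,
$\eta \sim U[0.05, 0.3]$, constant $\gamma = 0.01$, and 10 decoys
populating 10 % of the ensemble. These sizes keep the whole suite under a
minute while leaving multinomial error well below the effects being
measured. Tolerances: design columns and enumeration oracles agree to
$10^{-12}$; the projection identity to $10^{-10}$; noiseless NNLS recovery
to $10^{-8}$ (solver tolerance); stochastic recovery checks use 3 binomial
standard errors, or the absolute bounds stated with each test. Ties in the
$\hat\eta$ rule (values exactly at the mean) are excluded, matching the
strict inequality used for the highly-reactive set. The 2–8 %
display normalization rounds its outlier and normalizer counts up
(`ceiling`), requires 13 finite values, and is never used inside the model.
All randomness flows through explicit seeds; two runs with the same
configuration are bit-identical, and `run_deconvolution()` writes a
provenance block (config hash, seed, package version) beside its results.

One observed limitation is worth stating plainly: when decoys genuinely
populate 1 % of the generating ensemble each, the fit cannot be expected to
report *every* decoy below a 1 % threshold. NNLS zeroes most decoys and
folds their mass into the true structures, but the residual decoy mass
tends to concentrate in one or two decoys at a few percent — and this
persists even when the fit is given the exact generating parameters, so it
is a property of the estimation problem, not of the implementation. The
package's tests assert the stronger property anyway and document the
failure rather than weakening it.

## A worked run

```{r example}
pool <- read_vienna(
  system.file("extdata", "bistable36_sample.db", package = "spdeconv")
)
cands <- dedup(pool)
rna <- attr(pool, "sequence")

truth <- ground_truth(
  candidate_set(list(
    rna_structure("((((((......))))))..................", rna, id = "left"),
    rna_structure("............((((((......))))))......", rna, id = "right")
  )),
  abundances = c(0.7, 0.3), eta = 0.2, gamma = 0.01, mode = "truncation"
)
treated <- draw_reads(pattern_distribution(truth), 1e5, seed = 11)
ctrl_truth <- truth; ctrl_truth$eta <- 0
control <- draw_reads(pattern_distribution(ctrl_truth), 1e5, seed = 12)

fit <- deconvolve(treated, cands, control = control)
selected_structures(fit)
glance(fit)
```

```{r postprocess}
es <- ensemble_summary(fit)
glance(es)
head(tidy(es))
```

`autoplot(fit)` shows the abundance spectrum against the selection
threshold, `autoplot(es)` the pairing-probability matrix, and
`plot_reactivity(fit$reactivity)` the per-site profile with the $\hat\eta$
line. For cotranscriptional series, `cluster_abundances()` +
`plot_cluster_trajectories()` and `entropy_trajectory()` reproduce the
motif-cluster and diversity views; cluster priority is declared by the
order of the motif list, so a structure containing several key motifs is
assigned deterministically rather than by manual judgment.

## Design choices that were genuinely open

* **Threshold placement** — the 1 % selection threshold is applied to
  abundances normalized by the total fitted mass, before the survivors are
  renormalized; applying it to raw NNLS coefficients would make the cut
  depend on the captured pattern mass.
* **Mutation-mode pattern space** — rows are the observed patterns plus the
  empty pattern; enumerating all $2^K$ rows is infeasible and adds only
  zeros to $\mathbf{y}$. Column sums over included rows ("captured mass")
  are reported so poorly covered structures are visible.
* **Degenerate inputs** — a single observed pattern fits with a warning
  (severely under-determined); all-zero design columns are dropped with a
  warning; an empty candidate set after pre-filtering is an error rather
  than a silent fallback.
* **Mean-filter edges** — the smoothing window shrinks at trajectory ends;
  a `"valid"` mode that returns `NA` there is available when comparability
  across the whole series matters more than completeness.
* **Entropy across lengths** — mean per-site base-pairing entropy is
  compared across transcript lengths, never joint structural entropy:
  ensembles over different lengths have incomparable joint distributions,
  and shared motifs are captured site-wise. Entropy is computed over the
  selected structures only, so it underestimates the diversity of the true
  ensemble by construction.
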