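---
title: "Screening kinase inhibition against adverse events: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening kinase inhibition against adverse events: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Small-molecule kinase inhibitors (SMKIs) are oral anticancer drugs that
inhibit many kinases besides their nominal targets, and both on- and
off-target inhibition can drive adverse events (AEs). Attributing an AE to
a specific kinase from clinical data is hard because every patient receives
a *drug* (a whole inhibition profile), not a single kinase perturbation, and
because exposure to the same dose varies widely between patients.

`kinomescreen` implements a pipeline that makes the drug identity drop out
of the analysis. For patient $i$ on drug $j$, the inhibition of kinase $k$
is summarised by the dimensionless ratio

$$x_{ik} = \frac{C^{ss}_{ave,i}}{K_{d,jk}},$$

where $C^{ss}_{ave,i}$ is the patient's steady-state average plasma
concentration and $K_{d,jk}$ the drug's dissociation constant against
kinase $k$, both in nM. Missing $K_d$ entries (no quantifiable binding) are
imputed with the fixed weak-binding constant $10^4$ nM, so an unprofiled
kinase contributes a near-zero feature rather than a hole. Two patients on
different drugs with the same ratio vector are identical to the model,
which is what lets data from many drugs be pooled into one kinome-wide
analysis.

The response per AE term is the time from treatment start to first
occurrence, in whole days; patients without the event are censored at their
end of follow-up. AE vocabularies are consolidated before analysis through
a user-supplied many-to-one term map (for example "mouth ulceration" into
"stomatitis"); unmapped terms pass through as their own analysis term, and
severity grades are carried for event filtering (a grade $\ge 4$ analysis
is an outcome filter, not a different model).

# The model

Each AE term gets its own random survival forest. Trees are grown on
bootstrap samples (with replacement); at each node `mtry` candidate
predictors are drawn and the candidate (predictor, threshold) pair
maximizing the standardized log-rank statistic

$$\frac{|\sum_k (d_{1k} - n_{1k} d_k / n_k)|}
       {\sqrt{\sum_k \frac{d_k (n_k - d_k)}{n_k - 1}
        \frac{n_{1k}(n_k - n_{1k})}{n_k^2}}}$$

splits it, thresholds being midpoints between consecutive distinct observed
values inside the node. Tied event times are aggregated at their common
time (Breslow convention) both here and in the hazard estimates. Terminal
nodes store the Nelson–Aalen cumulative hazard
$\hat H(t) = \sum_{t_k \le t} d_k / n_k$ of their members on the shared
grid of distinct training event times; the ensemble prediction is the
arithmetic mean of the member-tree hazards and
$\hat S(t) = \exp(-\hat H(t))$. The scalar risk score used everywhere
("ensemble mortality") is the ensemble cumulative hazard summed over the
grid.

Variable importance is the Breiman–Cutler permutation scheme: for each
tree, the out-of-bag (OOB) prediction error — one minus Harrell's C of the
tree's mortality on its OOB patients — is recomputed after permuting the
predictor's OOB values, and the error differences are averaged over trees.
A predictor never used by any split scores exactly zero. Minimal depth (the
average depth of a predictor's first split, with non-splitting trees
contributing their maximal depth plus one) is reported alongside as a
second, error-free importance measure. Harrell's C counts a pair
permissible when the shorter observed time belongs to a subject with an
event and the times differ; risk ties count one half.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_trees` | 500 | ensemble size; importance stabilises with more trees |
| `mtry` | `ceiling(sqrt(p))` | candidate predictors per node |
| `min_node_size` | 15 | smallest (weighted) node the splitter will touch |
| `min_node_events` | 3 | smallest (weighted) event count to attempt a split |
| `top_k` | 25 | length of the reported importance extract |
| `vimp_repeats` | 1 | extra permutation rounds per predictor |

Units: all times are days (integer, day 1 = first treatment day);
concentrations and dissociation constants are nM; sex is coded 0 = female,
1 = male, recorded in the dataset metadata.

Determinism is a contract: identical data, configuration and seed give a
bit-identical forest, importance table, and prediction. Tie-breaks are
fixed (first candidate in the seeded random draw order wins among equal
log-rank statistics; within a predictor, the smallest qualifying
threshold), and every random draw in a pipeline run descends from one
master seed through labelled child seeds, so stage order cannot change
results.

# Evaluation protocols

*Bootstrap cross-validation*: in each of `B` iterations (500 by default),
80% of patients are drawn **without replacement** as training data — note
the contrast with the forest's internal bootstrap, which is with
replacement — a forest is fitted, and Harrell's C of ensemble mortality on
the held-out 20% is recorded. The summary is the mean C with the empirical
5th–95th percentile interval. Splits that leave either side without events
are redrawn.

*Leave-one-out cross-validation*: one forest per patient, each trained
without that patient; the held-out mortalities are pooled into a single C.
Pooling is the default report; when several AE terms are evaluated, the
mean of the pooled per-term values is the natural patient-level summary.

*External validation*: per-AE forests trained on one population are applied
to an external cohort sharing the kinase feature space. The predicted
probability of an AE is the cohort mean of $1 - \hat S(h)$ at horizon $h$
(default: the external cohort's maximum follow-up, clipped to the model
grid); it is compared with the observed incidence at a frequent-AE
threshold (10% by default, 15% and 20% as sensitivity analyses), giving
sensitivity and specificity over AE terms, plus the Pearson correlation
between predicted probability and observed incidence among the frequently
reported terms.

*Reporting odds ratio*: for drug-level disproportionality summaries,
$\mathrm{ROR} = ad/bc$ from the 2×2 table of AE × drug-of-interest report
counts, with the Haldane–Anscombe 0.5 correction (flagged) when any cell is
zero and a log-scale 95% interval. The comparator set is a parameter;
by default all other drugs in the dataset.

*Stratified curves*: for a (kinase, AE) pair, patients are split at the
median of the kinase feature — strictly above the median is "higher
inhibition", ties go to the lower stratum, and a constant feature is an
error rather than an arbitrary split. The forest-predicted survival curves
are averaged pointwise within each stratum with a normal-approximation 95%
band ($\bar S \pm 1.96\,\mathrm{se}$, clamped to $[0,1]$) across patients;
no bootstrap band is attempted. Diverging strata indicate
exposure-dependent onset.

No multiple-testing correction is applied to importance rankings: the
screen reports rankings, not p-values, and downstream use should treat top
pairs as hypotheses for experimental confirmation.

# The synthetic-data generator

Real registrational-trial data of this kind cannot be redistributed, so the
package ships a generator that emulates the statistical structure the
analysis assumes, with known ground truth:

- **Kinome panel**: each drug receives 3–8 targets drawn with
  gamma-distributed kinase "druggability" weights (so target sets overlap
  partially), tight $K_d$ values log-uniform on 1–100 nM; off-target
  entries are missing with probability `kd_sparsity` (default 0.9) and
  otherwise weak (log-uniform 100–$10^4$ nM). As a boundary convention,
  `kd_sparsity = 1` requests a fully missing panel.
- **Exposures**: per-drug median steady-state concentrations log-uniform on
  100–3000 nM; individual exposures log-normal around the drug median with
  coefficient of variation `exposure_cv` (default 0.5, reflecting the
  considerable inter-individual variability of oral SMKI exposure). Ages
  are normal (60 ± 10, clamped 18–90), sex Bernoulli(0.5).
- **Outcomes**: per AE term, proportional hazards on the log-inhibition
  scale, $h_i(t) = h_0(t) \exp\{\sum_k \beta_k \log(1 + x_{ik})\}$ over the
  designated causal kinases. `log1p` keeps the zero-inhibition case
  well-defined while making effects multiplicative on hazard; the
  non-parametric forest is agnostic to this particular monotone link.
  Coefficients are specified as hazard ratios per standard deviation of the
  realised log feature ($\beta_k = \log(\mathrm{HR}) / \mathrm{sd}_k$), and
  the baseline (exponential by default, Weibull optional) is calibrated so
  a patient at the average linear predictor reaches the configured event
  fraction (default 0.5) by the administrative censoring day (default
  365). Event times are rounded up to whole days, matching the integer
  onset days of clinical AE records; events with onset on or after the
  administrative day are censored at that day.
- **Causal kinases**: unless named explicitly, each term's causal set is
  drawn uniformly among kinases with at least one tight $K_d$ — a kinase no
  drug inhibits potently cannot produce a population-level signal, and
  uniform sampling avoids degenerate choices such as stacking all effects
  on near-collinear promiscuity hubs, whose features are statistically
  indistinguishable from their neighbours'.

What the generator does *not* emulate: real MedDRA coding noise, competing
risks and informative censoring (dropout for progression or toxicity),
dose modifications over time, correlated AE terms within patients, and
population-PK estimation error in $C^{ss}_{ave}$. Passing recovery tests on
this generator therefore shows the pipeline can find designed signal in
data of the assumed structure — not that it will perform equally on real
trial populations.

## The versioned recovery benchmark

`run_recovery_benchmark()` fixes the benchmark study conditions: 600
patients (8 drugs × 75), a 200-kinase panel, one AE term with 5 causal
kinases at hazard ratio 2.5 per SD of the log feature, ~50% events by day
365, and 20 replicate seeds. Reported per replicate: recall of the causal
kinases in the top-25 importance list, the forest's OOB C-index, and the
mean held-out C from bootstrap cross-validation at `B = 50`. The
cross-validation forests use 25 trees — held-out concordance is flat in
ensemble size well below the screening default, so the benchmark spends its
budget on the screening forests where importance stability needs it.

A fundamental property of this design is worth stating plainly: within one
drug, every kinase feature is the same monotone transform of exposure, so
kinases can only be told apart through their *between-drug* $K_d$
contrasts. With 8 drugs the attribution problem is appreciably harder than
with the 16 drugs of a full pooled submission database, and kinases whose
panel columns are nearly collinear with a causal kinase's column share its
importance. Recall of the exact causal identities on this benchmark is
therefore a demanding test, and the honest yardstick for what a screen of
this kind can and cannot resolve.

# Numerical and degenerate-input choices

- Log-rank variance terms with $n_k \le 1$ at-risk are skipped; a zero
  variance yields statistic 0 (no admissible split).
- A node with fewer (weighted) patients than `min_node_size`, fewer events
  than `min_node_events`, or no admissible split becomes terminal.
- Forests refuse to fit an outcome with zero events; screening flags such
  terms "not fitted" instead of failing the run.
- `harrell_c()` raises an explicit error when no permissible pair exists.
- Horizons beyond a model's event-time grid are clipped to the grid maximum
  with a warning.
- CSV round-trips hold to double precision at 15 significant digits (the
  text-serialisation limit), which is why round-trip tests compare at
  `1e-9` rather than bit-identity; *within* a run, outputs are
  byte-reproducible under a fixed master seed because the RNG stream, not
  the serialisation, is the only source of variation. Stage wall-clock
  timings are logged to `run.log`, outside the deterministic manifest.

# Problem sizes used by the shipped checks

The test suite exercises the full benchmark (20 replicates at the versioned
conditions above, 500-tree screening forests, `B = 50` cross-validation
with 25-tree fits), oracle comparisons on exhaustive small instances (up to
10 subjects), a 100-replicate null-concordance simulation at n = 500, and
byte-identity of a small pipeline run executed twice. Unit tests use
reduced configurations (tens to a few hundred patients, 10–100 trees)
chosen so each property is still sharply testable.

# Known limitations

- Importance is diluted among strongly correlated kinase columns; rankings
  identify equivalence classes of kinases more reliably than single
  identities, exactly as in the real kinome where family members share
  inhibition profiles.
- No competing-risks machinery; death from other causes is ordinary
  censoring.
- The consolidation map is data: no MedDRA versioning logic is provided.
- $C^{ss}_{ave}$ is an input; population-PK estimation is out of scope.
- Forests are fitted per AE term independently; no information is shared
  across related terms.
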