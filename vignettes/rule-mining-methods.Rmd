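---
title: "Mining prognostic rules from clinical and plasma-protein data in neuroendocrine tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining prognostic rules from clinical and plasma-protein data in neuroendocrine tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netarm)
```

## The problem

Grade 1–2 neuroendocrine tumors of the small intestine (siNET) and
pancreas (pNET) are mostly slow-growing, but a subset progresses within a
few years of diagnosis, and no single baseline marker — including plasma
chromogranin A (CgA), the most used one — identifies that subset
reliably. `netarm` implements an interpretable alternative to black-box
classifiers: association rule mining (ARM) over baseline clinical
characteristics and a 92-protein plasma panel, with a binary 3-year
outcome label — stable disease (SD) or progressive disease (PD, deaths
included) — as the rule consequent. The output is not a prediction score
but a ranked list of readable conjunctions such as
*CgA > 4 ULN ∩ Ki-67 > 5% → PD*, each with exact occurrence statistics.

## The model

A patient is encoded as a *transaction*: the set of categorical items
they carry. An association rule is an implication $X \Rightarrow Y$ with
$X, Y \subseteq I$ and $X \cap Y = \emptyset$, scored by

* **support** — the absolute number of transactions containing
  $X \cup Y$ (kept as an integer count, because the selection thresholds
  are phrased on counts);
* **confidence** — $\mathrm{supp}(X \cup Y)/\mathrm{supp}(X)$, the
  conditional frequency of the consequent among antecedent carriers;
* **lift** — confidence divided by the baseline consequent rate
  $\mathrm{supp}(Y)/N$; lift > 1 indicates positive association.

Only rules whose consequent is an outcome label (or, in the second
characterization pass, a fixed composite target) are generated, with at
most three antecedent items.

### Discretization

ARM needs categories. Three mechanisms are used, mirroring how the items
in the study's printed rules are labelled:

* **Control reference band.** For each panel protein, the 95% z-interval
  of the control-cohort mean, $\bar{x} \pm 1.96\, s/\sqrt{n}$
  ($n = 143$). A patient emits `"VAR < low"` below the band,
  `"VAR > high"` above it, and *no item* inside it. The band is an
  interval for the *mean*, so it is deliberately narrow: it asks whether
  a patient is distinguishable from the control average, not whether
  they are within the population range. Comparisons use unrounded
  bounds; item labels round to 2 decimals (a label like `CPE < 3.03`
  comes from the unrounded 3.034). A z rather than t quantile is used;
  at $n = 143$ the difference is under 0.002 on the CPE scale and the z
  bound reproduces the printed labels.
* **Fixed clinical thresholds**, configurable via `item_thresholds()`:
  CgA > 4 ULN (CgA is carried as a multiple of the upper limit of
  normal, simulated on the log scale), 5-HIAA > 455 %ULN, the Ki-67 5%
  split (both directions are items, since grade-related proliferation is
  informative either way), and > 10 metastases.
* **Categorical passthrough**: gender, NET grade (a missing grade emits
  nothing), N/M stage, liver metastasis (emitted only when present),
  per-symptom carcinoid-syndrome items plus `"no CS symptoms"` when the
  triad is absent, and treatment class.

All inequalities are strict, matching the `<`/`>` item vocabulary.
Normal-range values emit no item rather than a "normal" item: every
biomarker item in the study's tables is directional, and absence coding
keeps the catalog at the visible vocabulary. Age is not discretized by
default (no age item appears in any printed rule); a fixed-threshold
spec can be added through the cut-off table if wanted.

### Mining and selection

`mine_frequent_itemsets()` is an exact level-wise Apriori: level-$k$
candidates join frequent $(k{-}1)$-sets sharing a $(k{-}2)$-prefix, and
each prefix group's tail-pair counts are obtained in one cross-product
of the prefix-projected incidence matrix. This keeps counting exact
while the expansion is vectorized; at the default study scale
(115 patients, ~208 items, support floor 14) roughly 6×10⁵ frequent
itemsets are enumerated in a few seconds. Output order is canonical
lexicographic, so results are deterministic.

Selection profiles ship as presets (`filter_profile()`): siNET-PD
(support > 20, confidence ≥ 0.70, lift ≥ 1.2), siNET-SD (support > 14),
pNET-PD (support > 14, lift ≥ 1.25), and the characterization pass
(support ≥ 8, confidence ≥ 0.80). The operators follow the printed
thresholds exactly — strict for support, inclusive for lift and
confidence — and are configurable per profile. Two printed statements
about the support floor conflict (a rule "in at least 30% of patients"
versus selection at support > 20 of 115, about 17%); both are exposed as
configuration and the analysis scripts use the printed counts.
Permutation-redundant rules (same attribute sets, different order) are
collapsed to one canonical representative; ranking is by lift, then
support, then label — a total order, so ties cannot reorder output
between runs.

### Subgroup characterization and diagnostics

The second pass fixes a composite consequent — by default
{female, CgA > 4 ULN} — and mines what else characterizes that subgroup.
Because $\mathrm{supp}(X \cup T)$ for a fixed target $T$ is just the
support of $X$ among target carriers, antecedents are mined in the
target-projected database and their confidence/lift denominators come
from full-cohort counts; this is identical to filtering the generic
miner's output for that consequent (property-tested), but never
enumerates itemsets that cannot reach it. Outcome labels are excluded
from characterization antecedents — the pass describes baseline
variables, and in the regime of interest the target carriers are all PD,
which would make the outcome a degenerate antecedent. With a rare target
the lift scale changes meaning: at a 23/115 baseline, confidence 0.94
already implies lift ≈ 4.7, which is why the characterization profile
reports very high lifts without a lift threshold doing any work.

`evaluate_rule_as_classifier()` treats an antecedent as a binary test
within a stratum (e.g. gender): the 2×2 table against the outcome label
gives PPV, NPV, sensitivity and specificity, with zero-denominator
metrics flagged undefined rather than zeroed, and percentages rounded
half away from zero (62.5% prints as 63%).

### Supporting statistics

* `summarize_group()`: mean, sample SD, z-based CI — the same mechanism
  as the cut-offs, so the printed control bounds double as a check of
  both.
* `ls_means_anova()`: additive fixed-effects fit
  `response ~ group + treatment`; a group's LS mean averages the model
  prediction over treatment levels with equal weights (the classical
  definition; the weighting is otherwise unstated), and the group effect
  is the extra-sum-of-squares F against the model without group. With a
  single treatment level this reduces to one-way ANOVA.
* `logistic_group_test()`: binomial GLM (IRLS/Newton ML, tolerance
  1e-10) with a likelihood-ratio test against the intercept-only model;
  complete separation and degenerate outcomes warn but still report the
  LRT p-value. On a 2×2 table the statistic equals the G-test.
* `roc_auc()`: the rank (Mann–Whitney) statistic with half credit for
  ties. Direction is fixed — higher score means PD — so markers elevated
  in stable disease (e.g. CD160) report AUC < 0.5 rather than being
  flipped; flipping would silently overstate discrimination.

## The synthetic cohort generator

No patient-level data are deposited, so the generator *is* the study
population for every test. Its defaults are the published siNET
conditions: 115 patients with exactly 65 PD / 50 SD, 143 controls,
log-CgA per group (control 1.29 (0.48), SD 2.35 (1.01), PD 3.57 (1.37)),
CPE per group (control 3.09 (0.34), SD 2.96 (0.33), PD 3.32 (0.74)), and
clinical category frequencies from the baseline characteristics table.
Where the study states no value, one realistic choice was made and
fixed: proteins are normal on the NPX-like log scale (the study states
no distributional form — this is an assumption); rule-bearing markers
get moderate group shifts in the reported direction (WISP-1, VIM, DLL1
up in PD; CD160, PVRL4 up in SD; TRAIL, ITGAV down in PD); markers
printed without a direction sit at their printed threshold with no group
effect; the remaining panel is null N(3, 1). Ki-67 is drawn inside the
WHO band of the simulated grade; 5-HIAA is log-normal with a higher PD
location; metastasis count is negative-binomial. Markers are independent
by default — the analysis consumes only marginal cut-offs — with an
optional single-factor equicorrelation for stress tests. Missing
clinical values are not generated (the analysis set was complete-case);
a missing NET grade exists only as the explicit category the baseline
table reports.

Ground-truth rules can be *planted*: a chosen fraction of patients
(carriers) has every antecedent variable pushed past its cut-off, and
their outcome is resampled to the consequent with a set penetrance.
Patients outside the carrier set who satisfy the antecedent naturally
have one antecedent variable pushed back across its cut-off, so
antecedent-positivity coincides with carrier status. Without that
closure the mined confidence would estimate a mixture of penetrance and
the background outcome rate — under the default CgA parameters roughly a
third of non-carriers satisfy {female, CgA > 4 ULN} naturally — and
penetrance would not be identifiable from the mined rule; the cost is a
distortion of the marginals of antecedent variables, which the
exchangeability tests therefore run on unplanted configurations.

What passing tests do and do not show: the generator emulates marginal
group distributions and plantable conjunctions, not the correlation
structure of a real proteomic panel, assay batch effects, informative
missingness, or the adjudication noise of a clinical progression call.
Recovery of a planted rule demonstrates that the pipeline's arithmetic
and selection logic are correct, not that the study's specific rules
would replicate in new patients.

## Numerical and reproducibility choices

Every stochastic step runs from an explicit integer seed; the same
config is bit-identical, and `run_study()` writes an md5 manifest so
whole-run identity is checkable file-for-file. Itemsets and rule strings
are kept in C-locale lexicographic order everywhere, which makes set
identity equal string identity and removes platform collation from the
output. Support is thresholded as an integer count, so no floating-point
boundary can flip a selection decision; confidence and lift are exact
ratios of integer counts. Degenerate inputs are contracts, not crashes:
zero-variance controls collapse their band to the mean with a warning,
empty strata and unknown items are errors, zero-denominator diagnostics
are `NA` with the metric named.

Problem sizes in the test-suite simulations (e.g. 200 seeds × n = 2000
for penetrance recovery, 400 seeds for exchangeability, 1000 null
simulations for logistic calibration, 600 for the LS-mean recovery) were
chosen so that Monte-Carlo error is several times smaller than the
asserted tolerance in each case.

## Known limitations and documented discrepancies

* The published lift values are not reproducible from the published
  marginals: confidence-1.00 PD rules are printed with lift 2.08, which
  implies a baseline PD rate of ≈ 48%, while the reported cohort gives
  65/115 ≈ 57% (lift 1.77); similarly the top SD rule's 2.53 at
  confidence 0.94 implies ≈ 37% vs 50/115 ≈ 43%. The package implements
  the standard definition and makes no attempt to match 2.08; the
  transaction base behind the published figure cannot be reconstructed.
* The published CPE group comparison appears once as p = 0.003 and once
  as p = 0.03; with no raw data neither can be arbitrated, and neither
  is asserted anywhere in this package.
* Data-dependent rule counts (2231 PD rules, 216 SD rules, 54
  characterization rules, 29 pNET rules) require the original cohort;
  the workflow reproduces their *mechanisms* and orders of magnitude on
  synthetic data, not the counts.
* The male-stratum 2×2 is reconstructed (34 CgA-positive: 21 PD/13 SD)
  as the integer table consistent with the published margins and
  percentages; it is a derived fixture, not printed data.
* pNET mining is a configuration of the same pipeline (the `pnet_pd`
  profile with `cohort_config(n_patients = 30, pd_fraction = 22/30,
  cohort = "pNET")`); pNET SD rules are out of scope, as in the study
  (the group has 8 patients).
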