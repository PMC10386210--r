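---
title: "Disproportionality signal detection in spontaneous reporting data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection in spontaneous reporting data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(srssignal)
```

## The problem

Spontaneous reporting systems (SRS) such as JADER or FAERS collect voluntary
reports of suspected adverse drug reactions. They have no denominator — the
number of people *taking* a drug is unknown — so incidence cannot be
estimated. What can be estimated is *disproportionality*: whether an event
is reported more often together with a drug than the rest of the database
would predict. The reporting odds ratio (ROR) is the odds-ratio form of this
comparison, taken over the 2×2 table of drug exposure against event presence
among all reports. An ROR is a screening statistic, not a risk estimate:
reporting bias, confounding by indication, and duplicate reporting all act
on it, which is why results are used to rank and triage rather than to
quantify risk.

The package implements the complete desk workflow for such a screen on
databases shipped in the JADER dialect — three case-linked tables (DEMO,
DRUG, REAC) keyed by a case identification number — together with a
synthetic generator that makes the whole chain testable without access to
the real database.

## Table construction

Real SRS extracts are messy in specific, well-known ways, and the ETL
mirrors the standard cleaning sequence:

1. **Stacking.** Multi-valued fields hold several values joined by `";"`
   (DRUG route, date, dose, dose unit, divided doses; the DEMO reporter
   field), and combination drug names join components with an interpunct
   `"·"`. Each such row is expanded into one row per value, order preserved.
   A trailing separator denotes an empty final value and is padded
   explicitly, so the total count of atomic values is conserved.
2. **Deduplication.** A duplicate is a byte-identical row within one table
   *after* stacking. Nothing subtler (similarity matching, case linkage
   heuristics) is attempted.
3. **Join.** The three tables are combined on the case id. The case — not
   the record row — is the counting unit for every downstream statistic: a
   case contributes its *set* of drugs and *set* of event PTs, so a drug
   recorded twice for one case counts once.
4. **Exclusion.** Cases exposed to any *indicator medication* (drugs that
   treat the event under study — for a glaucoma screen, IOP-lowering drugs)
   are removed entirely: their presence marks prevalent patients whose
   event predates the exposure of interest. The list is configuration, not
   code; the shipped `glaucoma_medications.txt` is an illustrative default.

A flow log records the record count after every step. Note that stacking a
`";"`-merged row expands each multi-valued field independently, which can
cross-combine a case's drug names with its routes; this is harmless here
because only the per-case drug *set* feeds the statistics, and the
mess-neutrality test verifies the cleaned case table is bit-identical with
and without injected mess.

Missing sex/age arrive as empty strings and become `NA`. Age is
canonicalized onto decade tokens (`"0s"`–`"90s"`) plus the categorical
`"elderly"`, `"adult"`, `"unknown"`; any unmapped non-empty spelling maps to
`"unknown"` rather than erroring, since SRS age fields are free-entry in
practice.

## The estimator

For drug $D$ and event set $E$, with cells $a, b, c, d$ as usual
($a$ = reports with both, $d$ = with neither):

$$\mathrm{ROR} = \frac{(a+0.5)(d+0.5)}{(b+0.5)(c+0.5)}$$

The 0.5 is the Haldane continuity correction: it keeps the ratio defined
when a cell is zero and stabilizes small-count estimates. The 95% interval
is the Wald (Woolf) interval on the log scale with
$z = 1.959964$, using the corrected cells in the variance term. The
two-sided Fisher exact test runs on the **raw** counts — the correction is
an estimation device, not a testing one — with the minimum-likelihood
two-sided convention (sum the hypergeometric probabilities of all tables
with the observed margins that are no more likely than the observed table).
Other two-sided conventions (doubling the one-sided tail) can differ in the
third decimal; the package's validation tolerances allow for this.

A drug is a **signal** when $\mathrm{ROR} \ge 1$ and $p < 0.05$. This is
deliberately the unadjusted criterion common in SRS screening; no
multiplicity correction is applied by default. A Benjamini–Hochberg column
is available (`fdr = TRUE`) for users who want it, but it is off by default
so that the default behaviour matches standard pharmacovigilance practice.
The volcano representation plots $\ln \mathrm{ROR}$ against
$-\log_{10} p$ (signals sit in the upper-right quadrant, above
$-\log_{10} 0.05 \approx 1.3$) with point colour encoding
$\log_{10}(a+b)$, since a large ROR on three reports means something very
different from the same ROR on three thousand.

## Demographics

Cases are split by event status and compared on sex and on two age
dichotomies — 70-and-older and 40-and-older — by Fisher exact test. The
unspecified `"elderly"` category counts as 70-and-older (and therefore also
40-and-older); `"adult"` and `"unknown"` are excluded from the age analyses
because they cannot be placed against either cut point; the under-10 decade
falls below both. Missing values are excluded per factor, and the output
reconciles used + excluded counts with the total so the bookkeeping is
auditable.

## Structure analysis

Screening many drugs against one aggregate event set hides *which* PTs
drive each association, so the structure stage works at (drug, PT)
resolution. To keep the profiles estimable, report-count filters are
applied first — defaults: drugs with at least 100 total reports and at
least 10 event reports, PTs with at least 50 reports. These are screening
heuristics (roughly: enough events that a per-PT lnROR is not dominated by
the continuity correction), kept as explicit tunable parameters.

Each retained (drug, PT) cell is the natural-log Haldane ROR from that
pair's own 2×2 table over the full analysis table — the same crosstab
scheme as the screen with the event set restricted to the single PT. The
dialect never states this denominator choice; using the full table is the
construction consistent with computing every cell "from the
crosstabulation table", and it keeps cells comparable across PTs.

Rows (drugs) are clustered with Ward's minimum-variance criterion on
Euclidean distances (`hclust` method `ward.D2`, whose merge height is
$\sqrt{2\,\Delta\mathrm{ESS}}$); ties are resolved by `hclust`'s
deterministic row-order convention, so results are reproducible. The tree
cut defaults to $k = 3$ — in the motivating corticosteroid analysis the
three-group reading (strong / intermediate / weak association profiles) is
the informative one, while the two-group cut merely splits off the
high-volume drugs — and both the $k=2$ and $k=3$ cuts are recorded in the
pipeline manifest.

PCA is computed on the **covariance** matrix (columns centered, not
scaled): the columns are all on the same lnROR scale, so scaling to unit
variance would discard exactly the between-PT differences in effect spread
that the analysis is after. Scores are the centered rows projected on the
eigenvectors; contributions are eigenvalue shares of total variance. Since
eigenvector signs are arbitrary, each component is oriented so its
largest-magnitude loading is positive — printed loading signs from other
software may differ by a global flip per component, which changes nothing
substantive.

## The synthetic generator

The generator emulates the features of the real database that the ETL and
estimator must survive: case-linked triple tables, `";"`-merged multi-value
DRUG fields, duplicated rows, decade-coded age strings with
`adult`/`unknown` categories, and missing sex/age. Its event model is
logistic: case $i$ reports PT $j$ with probability

$$p_{ij} = \mathrm{logit}^{-1}\Big(\mathrm{logit}(\pi_j) + \sum_{d \in \text{exposed}(i)} \log m_{dj}\Big)$$

where $\pi_j$ is the PT's baseline reporting probability and $m_{dj}$ the
injected odds multiplier. Exposure to each drug is independent Bernoulli.
When each injected association targets its own PT (as in the default
configuration), exposure to the drug multiplies that PT's odds by exactly
$m$ in both exposed and unexposed strata, so the *population* reporting
odds ratio equals the multiplier — no non-collapsibility gap — and
parameter recovery is a clean test of the whole chain. A multiplier of zero
is a hard veto (probability exactly zero), and a baseline of zero makes the
PT impossible outright.

Defaults define the package's recovery study conditions: 50,000 cases, six
drugs at 10% exposure, eight PTs at 1% baseline, multipliers 2/5/10 on
three disjoint pairs, 1% duplicate rate, 10% merge rate. At these sizes the
expected exposed-event count is ≥ 20 even for the weakest pair, which is
the regime where the Wald interval's nominal coverage is trustworthy. Mess
is drawn *after* all scientific randomness, so for one seed the messy and
mess-free databases contain identical underlying cases — that is what makes
the mess-neutrality property exactly testable.

What the generator does **not** emulate: reporting-bias mechanisms,
dose/route effects, time trends, correlated co-prescription, or free-text
name variants. Passing the recovery study therefore shows the pipeline is
statistically and mechanically correct under independent exposures and a
clean vocabulary; it says nothing about confounding in real SRS data.

## Numerical and design choices

- **Confidence interval formula:** log-scale Wald on Haldane-corrected
  cells. Published SRS screens print 95% CIs without stating a formula;
  this is the standard pharmacovigilance construction.
- **Name matching** is exact string equality after trimming, whitespace
  collapsing, case folding, and an optional synonym map — both for drugs
  and PTs (a controlled vocabulary). Two typographically corrupted PT
  spellings seen in circulation ship as synonyms of the cleaned terms.
- **Censored printed p-values** (`"<0.001"`) in reference tables are kept
  as bounds; a censored bound ≤ α counts as significant at α.
- **Degenerate inputs:** an all-zero 2×2 table yields ROR 1 (all cells
  0.5); a zero margin yields Fisher p = 1; an empty join warns and returns
  an empty table rather than failing; a p-value underflowing to 0 is capped
  in the volcano at a configurable maximum with a warning.
- **Determinism:** one integer seed drives the generator; `hclust` and
  `prcomp` are deterministic; the pipeline manifest records MD5 checksums,
  and rerunning a config reproduces them bit-for-bit.

## Validation strategy and problem sizes

The test suite checks each stage against an independent oracle: the exact
test against exhaustive hypergeometric enumeration over all 2×2 tables with
row margins up to 12; the Haldane ROR against direct arithmetic and its
inversion/monotonicity properties; Ward linkage against a hand-computed
merge sequence on four collinear points; PCA against a direct
eigendecomposition of the explicitly formed covariance matrix, plus exact
reconstruction; and the ETL against hand-tallied fixtures. The recovery
study uses 50 seeds at 50,000 cases — enough that per-multiplier 95%-CI
coverage has a binomial standard error of about 3 points, which motivates
the 88–100% acceptance band around the nominal 95%.

## Limitations

The package screens; it does not infer. No adjustment for co-medication,
indication, or reporting dynamics is attempted, matching how RORs are used
in practice. Japanese-language normalization of real JADER exports (and
Shift-JIS quirks beyond an encoding switch), MedDRA hierarchy services, and
record-level duplicate *case* detection are out of scope: PTs are expected
pre-coded and the vocabulary clean.
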