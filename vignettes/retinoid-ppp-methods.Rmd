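---
title: "Methods: measuring the impact of the 2018 retinoid pregnancy-prevention revision"
author: "rmmits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring the impact of the 2018 retinoid pregnancy-prevention revision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmmits)
```

## The problem

Oral retinoids (isotretinoin, acitretin, alitretinoin) are highly teratogenic,
and their European pregnancy prevention programme (PPP) was revised in 2018:
contraception requirements, pregnancy testing, prescriber and pharmacist
checklists, maximum 30-day supplies. Whether such risk-minimisation measures
(RMMs) change prescribing in practice is an empirical question, usually asked
of routinely collected electronic health databases (EHDs): prescription and
dispensing records, diagnosis events, and fragmentary pregnancy registries.

`rmmits` implements the full computational chain of such an impact
evaluation, for females of childbearing potential (12–55 years) observed
monthly from January 2010 to December 2020:

1. **treatment episodes** from drug records (permissible-gap merging,
   discontinuation, reason classification);
2. **pregnancy identification** from four source streams with colour-coded
   date certainty and gestational imputation;
3. **monthly utilisation series** (incidence, prevalence, discontinuation,
   contraception, pregnancy testing) and exposed-pregnancy rates;
4. **segmented generalised-least-squares interrupted time-series (ITS)**
   with seasonal adjustment and autoregressive errors.

Because the source databases cannot be redistributed, the package ships a
seeded **synthetic-data generator** that emulates their table structure and
the statistical features the analysis relies on, together with a
ground-truth ledger. Every stage is therefore testable end to end, and the
estimators' sampling properties can be measured by parameter recovery.

## Episode construction

A drug record covers `[record_date, record_date + days_supply − 1]`. All
intervals in the package are closed intervals on whole calendar days — the
gap rules are day-count rules, and one convention avoids off-by-one drift.
When `days_supply` is missing we assume 30 days, the maximum supply the
revised programme mandates; user-independent contraceptive devices
(intra-uterine devices, implants) default instead to a 3-year coverage
(1,095 days), a conventional device lifetime that is configuration-exposed
because databases rarely record it. When a prescription and a dispensing
share a person, drug and date, the dispensing wins (it reflects actual
supply).

Coverage intervals separated by a gap of **fewer than 30 days** merge into
one episode, during which the person is assumed exposed; a gap of 30 days
or more starts a new episode (merge iff gap < 30, strictly). Stockpiling is
ignored: overlapping supplies do not carry forward, a deliberate
simplification documented here because dose and strength are out of scope.

An episode is **discontinued** when no same-class record follows within 90
days of its last record (30 days in the sensitivity analysis). Episodes
whose 90-day window runs past the person's observation end, the study end,
or the COVID censor date are *not assessable* and never enter
discontinuation numerators — otherwise end-of-follow-up truncation would
masquerade as discontinuation.

**Discontinuation reasons** screen the 90 days after the episode end, with
precedence *pregnancy* > *pregnancy wish* (folic acid, ATC B03BB01, for
isotretinoin/alitretinoin only — acitretin's three-year teratogenic window
makes planned conception implausible) > *adverse drug reaction* (a
configured diagnosis code, or an antidepressant record as depression
proxy) > *unknown*, the default. The source rules carry no explicit
precedence; pregnancy dominates clinically and frequently co-occurs with
folic acid, which fixes the order used here.

## Pregnancy identification

Four streams report pregnancies — birth registry, administrative diagnoses,
the congenital-anomaly registry, and a tailored stream — each with possibly
missing start and end dates. Source rows are clustered into one pregnancy
when their anchor dates (recorded start; else recorded end minus one
gestation; else the record date) fall within 273 days and are not separated
by a recorded pregnancy end. Within a cluster, stream priority birth
registry > administrative > anomaly registry > tailored chooses the dates.

The certainty **colour** encodes what was recorded for the chosen dates:

| colour | start | end | imputation |
|--------|-------|-----|------------|
| green  | recorded | recorded | none |
| yellow | imputed | recorded | start = end − gestational age (273 d default) |
| blue   | recorded | imputed | end = start + 273 d |
| red    | imputed | imputed | anchored on the record date |

The imputed gestation length is a single documented constant, 273 days;
a recorded gestational age overrides it. Red events assume the record falls
mid-pregnancy (start = record date − 136 days). If a cross-stream
inconsistency makes the chosen start precede the chosen end impossible, the
end record is trusted and the event demotes to yellow. The main analysis
admits green and yellow only — a recorded end date anchors the event in
time — and the sensitivity analysis adds red.

**Exposed pregnancies** are counted two ways, each pregnancy at most once
per kind: a pregnancy starting inside a retinoid episode extended by 30
days (the teratogenic extension, applied uniformly to all three retinoids
because post-2018 follow-up is too short for acitretin's three-year
window), and a retinoid record dated inside a pregnancy window. Rates are
per 1,000 prevalent users per period, split at the RMM implementation date,
with a 99% Wald (Poisson-count) interval on the rate difference. The
published source does not state its interval method; the normal
approximation is implemented and documented, and agreement with published
intervals is deliberately not asserted.

## Monthly series

All series share one long layout (`series_name`, `stratum`, `month`,
`numerator`, `denominator`, `value`). A person-month counts a person
observed at least one day of the month — fractional person-time is not
used, and the convention is applied identically to numerators and
denominators. Age is evaluated at the month start by whole-year (birthday)
arithmetic; whether source studies evaluate age at entry or continuously is
not stated, and monthly evaluation makes the denominators reproducible.

- **Incidence** (per 1,000 person-months): new users with no same-class
  record in the 365 days before the month start; a person must be observed
  for the full lookback to be evaluable, so the first observation year
  contributes no denominators (a literal reading of the one-year lookback).
- **Prevalence** (per 1,000 persons): any episode day overlapping the month.
- **Discontinuation**: discontinuations in the month over distinct users of
  the preceding *calendar* quarter (rolling three months would be the
  alternative; calendar quarters are chosen and documented). The measure
  can exceed 1 when a month's discontinuers were not prior-quarter users;
  it is reported as computed.
- **Contraception**: fraction of retinoid starts inside a coverage interval,
  and fraction with a contraceptive start in the preceding 90 days.
  Coverage is the union of user-independent episodes; hormonal methods
  qualify only in permissive mode, since the barrier method they must be
  paired with is over-the-counter and invisible to EHDs.
- **Pregnancy testing**: fraction of initiations with a test within ±90
  days, and witnessed tests per 1,000 person-months.

Counts below 5 are masked (`<5`) in human-readable reports only; machine
outputs keep exact values so tests remain exact.

## The interrupted time-series model

For a monthly outcome $y_t$ with intervention at month $T$:

$$y_t = \beta_0 + \beta_1 t + \beta_2 \, \mathbf{1}[t \ge T]
      + \beta_3 (t-T)^+ + s_t + \varepsilon_t,
\qquad \varepsilon_t \sim \mathrm{AR}(p),$$

where $s_t$ is the seasonal term — eleven calendar-month indicators by
default (January reference), or $k$ sine/cosine harmonic pairs — and
$\beta_2$, $\beta_3$ are the level and trend changes of interest. The
months between the RMM's promulgation and its national implementation are
excluded (the policy was neither absent nor in force), and the intervention
anchors at the implementation end; the four national windows are built in,
with Spain as the default. A fit is refused when fewer than two
pre- or post-intervention points survive the exclusions — mirroring the
data source that could not be modelled for lack of post-2018 points.

Estimation is iterative feasible GLS: OLS, then Yule–Walker AR($p$) on the
residuals, then exact whitening with the implied AR correlation — evaluated
at the true calendar lags, so the excluded gap months are handled exactly
rather than by pretending the series is contiguous — and re-estimation
until the coefficients move by less than $10^{-8}$ (at most 100 iterations;
non-convergence is reported, not hidden). With $p = 0$ the fit *is* OLS, to
machine precision. For AR(1) errors the Yule–Walker coefficient receives a
small-sample bias correction $\hat\rho + (1+3\hat\rho+k)/n$ — the Kendall
term plus the serial correlation absorbed by the $k$ fitted regressors.
Residual-based autocorrelation estimates are biased toward zero, which
would otherwise leave the level- and trend-change tests measurably liberal:
on 132-month series with $\rho = 0.4$, about 7% empirical size at nominal
5% uncorrected versus about 5.7% corrected. Standard errors come from the whitened cross-product
with $n-k$ degrees of freedom and t-based p-values. The AR order is chosen
in $0..p_{\max}$ (default 2) by BIC on the whitened Gaussian likelihood;
the $\log n$ penalty keeps spurious orders off white-noise residuals, and
ties resolve to the smaller order. Autocorrelation is reported through the
Durbin–Watson statistic of both the raw and the whitened residuals.

## What the generator emulates — and what it does not

The generator draws monthly initiation hazards
$\lambda_t = b\,(1 - a\cos 2\pi (m_t-7)/12) + \delta\,\mathbf{1}[t\ge T] +
\gamma (t-T)^+$ per 1,000 person-months: baseline $b = 0.2$ (the order
observed pre-intervention in the Danish register), trough amplitude
$a = 0.3$ in mid-July (the summer dip is reported without a functional
form; a cosine is the simplest shape with one trough), and null
intervention effects by default, matching the finding of no significant
change. Episodes carry exact 30-day supplies with refill gaps drawn below
the merge threshold, and successive episodes are separated by more than the
discontinuation window — so episode truth is unambiguous and the
reconstruction oracle can demand exact agreement. Pregnancies arrive at 60
per 1,000 person-years in ages 16–44 (a realistic European rate), last 273
days for births and 273 minus a truncated-normal shortening (mean 180, sd
30, bounded 60–240 days) otherwise, and are reported through streams with
configurable start/end-date completeness; the ledger records both the true
dates and the dates a correct reconciliation should produce, plus the
implied colour.

The generator deliberately omits: demographic turnover (immigration,
death), dose and strength, switching between products, stockpiling,
multi-country heterogeneity within one run, and informative missingness
correlated with outcomes. Passing the oracle tests therefore shows the
algorithms are correct under the stated recording model — not that real
databases satisfy that model. In particular, real days-supply fields are
noisy and real pregnancy streams disagree on dates; only the colour coding,
not the tests, addresses that uncertainty.

## Problem sizes and numerical choices

The packaged analysis scripts use 20,000 persons over 132 months; the test
suite uses cohorts of 250–3,000 persons, a 1,000-person fixture for the
brute-force overlap cross-check, and 500 replicates of 132-month series for
parameter recovery of $(\beta_0,\beta_1,\beta_2,\beta_3) =
(10, 0.05, -2, -0.1)$ under AR(1) $\rho = 0.4$, $\sigma = 0.5$ — sizes at
which Monte-Carlo standard errors are small enough to detect bias while the
whole suite runs in minutes on one CPU. Degenerate inputs are handled
explicitly: empty record sets produce empty outputs, unsorted episode input
is an error, an all-zero residual vector has no defined Durbin–Watson
statistic, rank-deficient designs are refused, and zero-user periods make
rates undefined (`NA`) rather than zero.

## Known limitations

Real-data coefficients from the published evaluation (database-specific
incidence levels, the Spanish contraception trend change, the Italian
acitretin trend) are not reproducible without the source databases and are
not asserted anywhere; the generator's scenarios cover them qualitatively.
The 99% interval on rate differences is a normal approximation whose match
to published intervals is unknown. The contraceptive ATC mapping and the
ADR code list are configuration, not vocabulary — real studies map local
codes. And the pregnancy reconciliation is a compact reimplementation of
the hierarchical idea, not of the full external algorithm it abbreviates.
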