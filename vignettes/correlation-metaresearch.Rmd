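---
title: "Methods: mining and modelling published correlational effect sizes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and modelling published correlational effect sizes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrlit)
```

## The problem

Effect-size benchmarks ("small/medium/large") are only meaningful relative
to what a field actually publishes. For Pearson correlations this package
supports the full chain of a distributional meta-research study: mine
`r(df) = x, p = y` reports from article text, audit the reported
significance labels against what `r` and the sample size actually imply,
summarise the distribution of `|r|` (overall, stratified, and as a function
of sample size), and translate the resulting typical effect sizes into
power and required sample sizes. A synthetic-literature generator with
known ground truth closes the loop: every pipeline stage can be calibrated
against data whose true effects, labels and placements are known.

All descriptive analyses run on absolute values `|r|`. Mined signs are
unreliable (character-encoding quirks can silently swallow a minus), and
quartiles of `|r|` are the quantities of interest.

## The statistical kernel

For a correlation computed on $N$ pairs, $df = N - 2$ and
$t = r\sqrt{df}/\sqrt{1-r^2}$ follows a central $t_{df}$ distribution under
the null. This gives:

* `exact_p(r, df)` — the p-value recomputed from the printed `r` and df
  alone. One-sided p-values take the observed direction as the hypothesised
  one (the most favourable reading, an upper bound on claimed
  significance).
* `critical_r(df, alpha)` — the boundary $r_c = t_c/\sqrt{t_c^2 + df}$.
  Significance is $p \le \alpha$, so a value exactly on the boundary counts
  as significant.
* `null_density(r, df)` — $f_0(r) = (1-r^2)^{(df-2)/2}/B(\tfrac12,
  \tfrac{df}{2})$, equivalently $r^2 \sim \mathrm{Beta}(\tfrac12,
  \tfrac{df}{2})$. The test suite uses the Beta form as an independent
  route to the same p-values.
* `expected_abs_r_nonsig(df, alpha)` — the mean $|r|$ among non-significant
  results if the null were true. Defined as the integral of $u \cdot
  2f_0(u)$ from 0 to $r_c$; we normalise by the probability of
  non-significance by default, because the quantity is compared against
  *observed means of non-significant values*, which are conditional by
  construction. The unnormalised integral (which differs by the factor
  $1-\alpha$) is available with `conditional = FALSE`. Both pieces have
  closed forms, so no quadrature is involved.

### Exact power

Power uses the exact sampling distribution of $r$ under a bivariate-normal
population with correlation $\rho$ (Hotelling's density, evaluated with a
${}_2F_1(\tfrac12,\tfrac12;n-\tfrac12;\cdot)$ series), integrated over the
rejection region. `required_n()` performs integer bisection for the minimal
$N$ reaching the target power — no rounding of a fractional solution.

Two reference points, both recomputed by `scripts/acceptance.R`:

```{r}
required_n(0.30, alpha = 0.05, power = 0.8)
required_n(0.17, alpha = 0.05, power = 0.8)
power_at_n(0.17, 268)
```

The second case sits on a knife edge: exact power at $N = 268$ is 0.79952,
so the minimal integer under the exact model is 269. Approximate Fisher-z
formulations with a small-sample bias term yield fractional solutions near
268.5 and round to 268; we keep the exact model as the default and expose
the Fisher-z approximation only as a labelled cross-check
(`method = "fisher_z"`), documenting rather than splitting the one-unit
difference. Either way the headline comparison stands: detecting a typical
published correlation of 0.17 needs roughly a 219% larger sample than the
conventional "medium" 0.3.

## Text extraction

`find_candidates()` matches a standalone lowercase `r` — not adjacent to a
letter, digit or underscore — optionally followed by a parenthesised token,
then `=`, ignoring ASCII spaces between the tokens. Each hit carries a
56-character window starting at the `r`. Windows end at a newline by
default: line breaks inside a report are a documented failure mode of
text-only mining, and we reproduce it deliberately (`join_lines = TRUE`
lifts it). Parsing accepts leading-dot decimals (`.38`), signs including
the Unicode minus (text is NFKC-normalised and minus lookalikes are mapped
before matching), rejects values outside $[-1, 1]$, takes a parenthesised
integer as df (a non-integer keeps `r` but stores no df), and attaches a
standalone `p =`, `p <` or `p >` report with a value in $[0, 1]$. Plural
`ps < .05` statements are not per-record reports and are ignored; `p ≤` is
coded as `<`. Only lowercase `r` is matched, which keeps regression `R`
and `R²` out of scope; `r2`/`r²` fail the standalone test.

`validate_extraction()` scores extraction against a rendered corpus: a
truth record counts as detected when a parsed hit lies within ±2
characters of its offset and matches `|r|` to two decimals.

## The synthetic-literature generator

`generator_config()` fixes the study conditions; its defaults emulate a
manually coded social/developmental psychology corpus and are chosen once:

* **Scale.** 243 studies; records per study log-normal with median 26
  (`sdlog = 1.2`, giving a mean near 53 and hence roughly 12 000 records —
  matching the ratio of records to studies in such corpora).
* **Sample sizes.** Log-normal, rounded, minimum 5. The published anchors
  are quartiles 140/230/564, which no two-parameter log-normal reproduces
  exactly; we anchor the median at 230 and take `sdlog = 1.03`, the least
  squares fit to the three log-quartiles. Quartiles of generated N come
  out near 116/230/466 — the right order of magnitude and skew.
* **Effects.** A fraction `null_fraction = 0.25` of population
  correlations are exactly zero; non-null magnitudes follow Beta(1.2, 5)
  (median ≈ 0.17) with random signs. These two choices jointly give
  roughly 55–60% significant records at the generated sample sizes, in
  the ballpark of reported corpora. No published true-effect distribution
  exists; these are calibration defaults, fully user-configurable.
* **Reporting.** Observed `r` is drawn by simulating bivariate-normal
  pairs (`r_method = "pairs"`); an exact order-equivalent sampler via
  $r/\sqrt{1-r^2} = (Z + \lambda\sqrt{\chi^2_{n-1}})/\sqrt{\chi^2_{n-2}}$
  is available for bulk work and is checked against the data-level route
  by a two-sample test. Labels come from the exact two-sided p at
  `alpha = 0.05`; 3% of records are reported without significance status
  and 0.5% of labels are flipped (misreporting). Placement: a
  non-significant record lands in text with probability 0.03; significant
  records have 4× the odds — back-solved so that with ~58% significant
  records the significant share among text records is ≈ 83%, the kind of
  text-emphasis gap reported for real corpora.

What the generator does *not* emulate: journal layout and tables, PDF
artefacts, correlated records within a study (each record draws fresh
data at the study's N), hypothesis-direction coding, and any dependence of
true effect size on sample size. Passing pipeline tests on generated data
therefore demonstrates correctness of the computations and the
directional reproduction of reporting-bias patterns, not realism of any
particular parameter value.

`render_corpus()` serialises text-located records into sentences using
nine format variants (canonical `r(34) = .52, p = .003`, variants without
df or p, inequality p, leading-dot, forced negative, and the adversarial
line-break, subscript and verbal forms). Table records are never rendered
— the text-miner's blind spot. The default mix gives the covered variants
93% of records, so default recall is 0.93 with zero false positives.

## Distribution summaries

* Quartiles everywhere use linear interpolation of order statistics at
  position $1 + (n-1)p$ (`stats::quantile` type 7, the R default), so
  results are reproducible against analyses run with default R settings.
  The quantile rule matters at these sample sizes only in the third
  decimal, but fixing it removes an ambiguity.
* `cumulative_percentiles_by_max_df()` evaluates at every distinct df (not
  binned) — the finest faithful resolution; records lacking df are
  excluded from the curve but retained in overall summaries.
* `bootstrap_median_ci()` implements the "standard normal interval"
  $(2\hat\theta - \bar{\theta^*}) \pm z_{(1+level)/2}\,sd(\theta^*)$ with
  10 000 resamples by default. Besides plain resampling it offers an
  `orderstat` engine that draws the resample's middle order statistics
  directly from their exact joint law (Beta-distributed uniform order
  statistics mapped through the sorted sample) — distributionally
  identical, O(reps) instead of O(n·reps), and cross-checked against both
  the resampling engine and `boot::boot.ci(type = "norm")` in the tests.
* `spearman_r_vs_df_by_year()` uses average-rank ties
  (`stats::cor(method = "spearman")`) and a Fisher-z interval with
  SE $1/\sqrt{n-3}$. The interval construction for rank correlations is a
  known approximation; it is adequate for the descriptive per-year tables
  it serves. Years with fewer than 10 usable records report no
  coefficient.

## Consistency auditing

`classify_records()` compares each reported label with the two-sided
boundary at the configured $\alpha$ (the one-sided boundary is recorded
alongside): reportedly significant records below it are
`too_small_for_sig`, reportedly non-significant records at or above it are
`too_large_for_nonsig`. Flags mark *suspects*, not errors — a legitimate
multiplicity adjustment produces exactly the `too_large_for_nonsig`
pattern. A record with no label but a `p < x` report with $x \le \alpha$
is audited as a significance claim. Records with neither N nor df are
`unresolvable`. `resolve_unspecified()` recomputes exact p-values for
unlabelled records under both sidednesses.

On misreport-free generated data the audit flags nothing; with label flips
enabled it flags exactly the flipped records (a flip always crosses the
boundary because labels derive from the same exact p the audit uses) —
both properties are tests.

## Numerical choices and degenerate inputs

* The ${}_2F_1$ series terminates when terms fall below $10^{-16}$ of the
  running sum; its argument $(1+\rho r)/2 < 1$ guarantees convergence.
  Power integrals use `stats::integrate` at `rel.tol = 1e-10`.
* `exact_p` pins $|r| = 1$ to $p = 0$; `r_to_t` returns signed infinity.
* Empty strata return an explicit `n = 0` marker, never NaN quartiles.
* CSV reading rejects (with logged row-level reasons) rather than repairs:
  `r` outside $[-1,1]$, N < 3, unparseable numerics, missing `r`. A
  record whose N and df disagree with $df = N-2$ is flagged
  (`df_inconsistent`), never corrected. Records reported as exactly
  `r = 0` are retained.
* All stochastic functions take a `seed` and restore the RNG state
  (`withr`), so any generated literature, corpus or interval is a pure
  function of (configuration, seed).

## Problem sizes in the test suite

The suite calibrates against: $10^5$ null simulations for the type-I
check, $2\times10^4$ data-level replicates per power grid point, $10^6$
null draws for the non-significant-mean check, a ~50 000-record generated
literature for end-to-end parameter recovery, and 500 replications of a
10 000-resample bootstrap for coverage. These sizes keep Monte-Carlo error
well below the asserted tolerances while running in minutes.

## Known limitations

* The extractor consumes plain text; PDF decoding, encoding repair and
  table extraction are out of scope, and the line-break miss behaviour is
  intentionally preserved by default.
* Power analysis covers a single Pearson correlation only — no
  multiplicity-adjusted or multi-test designs.
* The deposited real-literature record tables are not shipped; the loader
  (`read_records_csv()` with `col_map`) accepts them as drop-in CSVs under
  `inst/extdata/dryad/` for the reproduction checks in the test suite.
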