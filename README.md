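# corrlit

Tools for meta-research on Pearson correlations published in the
scientific literature — mining them from article text, auditing what was
reported, describing their distribution, and drawing the power-analysis
consequences.

## What it does

Large-scale surveys of published correlational effect sizes need four
computational pieces, and `corrlit` provides all of them behind one record
model:

1. **Extraction** — `find_candidates()` / `extract_document()` mine
   `r(df) = x, p = y` style reports from plain-text article bodies
   (standalone lowercase `r`, optional parenthesised df, `=`, a value in
   [-1, 1], an optional `p =`/`p <`/`p >` report; 56-character windows on
   one logical line). `validate_extraction()` measures recall and false
   positives against corpora with embedded ground truth.
2. **Audit** — for a correlation on `N` pairs, `t = r√df/√(1-r²)` with
   `df = N - 2` is exact under the null, so every reported label can be
   checked: `exact_p()`, `critical_r()`, `classify_records()` (flags
   `too_small_for_sig` / `too_large_for_nonsig` suspects),
   `resolve_unspecified()` for records reported without a significance
   status.
3. **Description** — quartiles of `|r|` (`percentile_summary()`,
   `stratified_summary()`), cumulative quartiles by maximum df
   (`cumulative_percentiles_by_max_df()`), block medians
   (`rolling_group_medians()`), bootstrap normal-interval CIs for medians
   (`bootstrap_median_ci()`), yearly Spearman associations of `|r|` with
   df (`spearman_r_vs_df_by_year()`).
4. **Inference** — exact power of the correlation test under the
   bivariate-normal model (Hotelling's density of the sample correlation)
   via `power_at_n()`, minimal sample sizes via `required_n()`, and the
   null expectation of non-significant `|r|` via
   `expected_abs_r_nonsig()`.

A synthetic-literature generator (`generator_config()`,
`generate_records()`, `render_corpus()`) produces record sets and
annotated pseudo-article text with known truth — null/non-null effect
mixtures, heavy-tailed sample sizes, significance-dependent text
placement, misreporting — so every stage of the pipeline is testable
end to end.

## Worked example

```r
library(corrlit)

cfg <- generator_config(n_studies = 120, seed = 2026)
g   <- generate_records(cfg)          # 5544 records across 120 studies

percentile_summary(g$records$abs_r)
#>   stratum     n    q25   q50   q75
#> 1 all      5544 0.0472 0.121 0.244

audit_summary(g$records)
#> Consistency audit of 5544 records
#>   consistent_sig           2495 (45.0%)
#>   consistent_nonsig        2852 (51.4%)
#>   too_small_for_sig          14 (0.3%)
#>   too_large_for_nonsig        9 (0.2%)
#>   unresolvable                0 (0.0%)
#>   unspecified               174 (3.1%)
#>   unspecified: 174 (83 significant two-sided, 92 one-sided of 174 resolvable)

validate_extraction(render_corpus(g$records, seed = 2027))
#> Extraction recall report
#>   truth records : 379
#>   detected      : 357 (recall 0.942)
#>   false positives: 0
```

The audit's 23 flagged records are exactly the labels the generator
flipped (misreporting rate 0.5%); recall falls short of 1 only on the
adversarial line-break/subscript formats the renderer embeds by design.

On the inference side:

```r
required_n(0.30, alpha = 0.05, power = 0.8)   # 84
required_n(0.17, alpha = 0.05, power = 0.8)   # 269 (exact model)
exact_p(0.17, 228)                            # 0.0098
critical_r(228)                               # 0.1294
```

Halving the target effect from the conventional "medium" 0.3 to 0.17 — a
typical published median — more than triples the required sample. Power
at N = 268 is 0.79952 under the exact model, a knife-edge case discussed
in the methods vignette (`vignettes/correlation-metaresearch.Rmd`);
rounded Fisher-z solutions give 268.

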