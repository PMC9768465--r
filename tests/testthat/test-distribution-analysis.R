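test_that("quartiles interpolate order statistics at 1 + (n-1)p", {
  s <- percentile_summary(c(0.1, 0.2, 0.3))
  expect_equal(c(s$q25, s$q50, s$q75), c(0.15, 0.20, 0.25), tolerance = 1e-12)
  s2 <- percentile_summary(rep(0.4, 10))
  expect_equal(c(s2$q25, s2$q50, s2$q75), c(0.4, 0.4, 0.4))
  # order invariance
  x <- runif(101)
  expect_equal(percentile_summary(x)[, -1], percentile_summary(sample(x))[, -1])
  # explicit empty-stratum marker rather than NaN quartiles
  e <- percentile_summary(numeric(0), "void")
  expect_true(e$empty)
  expect_identical(e$n, 0L)
})

test_that("cumulative percentile curve equals a brute-force filter-and-sort oracle", {
  withr::local_seed(88)
  rs <- make_rs(r = runif(400, 0, 0.9),
                df = sample(c(10L, 25L, 25L, 60L, 120L, 480L), 400, TRUE))
  curve <- cumulative_percentiles_by_max_df(rs)
  expect_identical(curve$df_max, sort(unique(rs$df)))
  expect_true(all(diff(curve$n_included) >= 0))
  for (i in seq_len(nrow(curve))) {
    sub <- rs$abs_r[rs$df <= curve$df_max[i]]
    expect_identical(curve$n_included[i], length(sub))
    expect_equal(unlist(curve[i, c("q25", "q50", "q75")], use.names = FALSE),
                 unname(quantile(sub, c(.25, .5, .75), type = 7)),
                 tolerance = 1e-12)
  }
  # last row equals the overall df-bearing summary
  ov <- percentile_summary(rs$abs_r)
  expect_equal(unlist(curve[nrow(curve), c("q25", "q50", "q75")],
                      use.names = FALSE),
               c(ov$q25, ov$q50, ov$q75), tolerance = 1e-12)
  # records without df are excluded; none at all yields an empty curve
  rs_na <- make_rs(r = c(0.1, 0.2))
  expect_identical(nrow(cumulative_percentiles_by_max_df(rs_na)), 0L)
})

test_that("block medians partition the df-sorted records", {
  rs <- make_rs(r = runif(25, 0, 0.9), df = sample(1000L, 25))
  one <- rolling_group_medians(make_rs(r = runif(10, 0, .9), df = 1:10 * 10L), 10)
  expect_identical(nrow(one), 1L)
  blocks <- rolling_group_medians(rs, 10)
  expect_identical(blocks$n, c(10L, 10L, 5L))
  # each block median recomputable from the df-sorted records
  o <- order(rs$df)
  expect_equal(blocks$median_abs_r[1], median(rs$abs_r[o][1:10]), tolerance = 1e-12)
  expect_equal(blocks$median_abs_r[3], median(rs$abs_r[o][21:25]), tolerance = 1e-12)
})

test_that("bootstrap median CI is deterministic, degenerate on constants, and matches boot", {
  x <- rnorm(80)
  a <- bootstrap_median_ci(x, reps = 2000, seed = 10)
  b <- bootstrap_median_ci(x, reps = 2000, seed = 10)
  expect_identical(a, b)
  cst <- bootstrap_median_ci(rep(0.4, 30), reps = 500, seed = 1)
  expect_equal(cst$lower, 0.4, tolerance = 1e-12)
  expect_equal(cst$upper, 0.4, tolerance = 1e-12)
  expect_error(bootstrap_median_ci(1), "at least 2")

  # independent oracle: boot's "normal" interval on the same data
  withr::local_seed(77)
  bo <- boot::boot(x, function(d, i) median(d[i]), R = 5000)
  ci_boot <- boot::boot.ci(bo, type = "norm")$normal[2:3]
  mine <- bootstrap_median_ci(x, reps = 5000, seed = 78)
  expect_lt(max(abs(c(mine$lower, mine$upper) - ci_boot)), 0.02)

  # the order-statistic engine reproduces the resampling engine
  fast <- bootstrap_median_ci(x, reps = 5000, seed = 79, engine = "orderstat")
  expect_lt(max(abs(c(fast$lower - mine$lower, fast$upper - mine$upper))), 0.02)
})

test_that("bootstrap interval width shrinks like 1/sqrt(n)", {
  withr::local_seed(55)
  widths <- vapply(c(100, 400, 1600), function(n) {
    ci <- bootstrap_median_ci(rnorm(n), reps = 4000, seed = n,
                              engine = "orderstat")
    ci$upper - ci$lower
  }, numeric(1))
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.3)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.3)
})

test_that("yearly Spearman association behaves at the extremes and under rank transforms", {
  rs <- make_rs(r = seq(0.9, 0.1, length.out = 20),
                df = as.integer(seq(10, 200, length.out = 20)),
                year = 2015L)
  out <- spearman_r_vs_df_by_year(rs)
  expect_equal(out$rho, -1, tolerance = 1e-12)
  expect_true(out$ci_lower <= out$rho & out$rho <= out$ci_upper)
  # monotone transform of df leaves rho unchanged
  rs2 <- rs
  rs2$df <- as.integer(rs$df^2 %/% 7L)
  expect_equal(spearman_r_vs_df_by_year(rs2)$rho, out$rho, tolerance = 1e-12)
  # sparse years are emitted with rho absent
  rs3 <- make_rs(r = c(0.1, 0.2), df = c(10L, 20L), year = 2019L)
  expect_true(is.na(spearman_r_vs_df_by_year(rs3)$rho))
  # independent abs_r and df give a small rho at n = 300 (fixed seed)
  withr::local_seed(66)
  rs4 <- make_rs(r = runif(300, 0, 0.9), df = sample(1000L, 300, TRUE),
                 year = 2018L)
  expect_lt(abs(spearman_r_vs_df_by_year(rs4)$rho), 0.12)
})

test_that("stratified summaries partition the record set", {
  cfg <- generator_config(n_studies = 50, r_method = "exact", seed = 44)
  g <- generate_records(cfg)
  s <- stratified_summary(g$records, c("location", "sig_label"))
  expect_identical(sum(s$n), nrow(g$records))
  # single whole-set stratum equals the plain summary
  rs_all <- g$records
  rs_all$subfield <- NA_character_
  s1 <- stratified_summary(rs_all, "subfield")
  ov <- percentile_summary(g$records$abs_r)
  expect_identical(s1$subfield, "unknown")
  expect_equal(c(s1$r_q25, s1$r_q50, s1$r_q75), c(ov$q25, ov$q50, ov$q75),
               tolerance = 1e-12)
  # proportions of labels sum to one within each stratum
  expect_equal(s$prop_significant + s$prop_non_significant + s$prop_unspecified,
               rep(1, nrow(s)), tolerance = 1e-12)
})
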