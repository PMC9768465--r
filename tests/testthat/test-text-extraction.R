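test_that("candidate matching requires a standalone r followed by =", {
  expect_identical(nrow(find_candidates("we found r = .38 overall")), 1L)
  expect_identical(find_candidates("we found r = .38 overall")$match_offset, 9L)
  expect_identical(nrow(find_candidates("r_extraversion = .40")), 0L)
  expect_identical(nrow(find_candidates("year = 2010")), 0L)
  expect_identical(nrow(find_candidates("R = .40 and r2 = .16")), 0L)
  expect_identical(nrow(find_candidates("r ( 34 ) = .52")), 1L)
  expect_identical(nrow(find_candidates("")), 0L)
})

test_that("windows hold at most 56 characters on one logical line", {
  long <- paste0("r = .52, ", strrep("x", 100))
  h <- find_candidates(long)
  expect_lte(nchar(h$window), 56L)
  h2 <- find_candidates("r(34) =\n.52, p = .003")
  expect_identical(h2$window, "r(34) =")
})

test_that("hits parse r, df and p reports by the stated rules", {
  p1 <- parse_hits(find_candidates("r(34) = .52, p < .01"))
  expect_equal(p1$r, 0.52)
  expect_identical(p1$df, 34L)
  expect_identical(p1$p_comparator, "<")
  expect_equal(p1$p_value, 0.01)
  expect_true(is.na(p1$reject_reason))

  # out-of-range value is rejected, not truncated
  p2 <- parse_hits(find_candidates("r = 1.5, p = .02"))
  expect_identical(p2$reject_reason, "out_of_range")
  expect_true(is.na(p2$r))

  # Unicode minus normalises to a signed value
  p3 <- parse_hits(find_candidates("r = −.21"))
  expect_equal(p3$r, -0.21)

  # absent df/p leave fields absent; non-integer parentheses keep r only
  p4 <- parse_hits(find_candidates("r = 0.38"))
  expect_true(is.na(p4$df) && is.na(p4$p_comparator))
  p5 <- parse_hits(find_candidates("r(34.5) = .52"))
  expect_equal(p5$r, 0.52)
  expect_true(is.na(p5$df))

  # plural "ps < .05" is not a per-record p report
  p6 <- parse_hits(find_candidates("r(20) = .30, ps < .05"))
  expect_true(is.na(p6$p_comparator))

  # "p <= x" is coded as a "<" report; p outside [0,1] is ignored
  p7 <- parse_hits(find_candidates("r(20) = .30, p ≤ .05"))
  expect_identical(p7$p_comparator, "<")
  p8 <- parse_hits(find_candidates("r(20) = .30, p = 3.5"))
  expect_true(is.na(p8$p_comparator))
})

test_that("document extraction is pure and ordered, with absolute values by default", {
  txt <- "We saw r(34) = .52, p < .01. Also r = -0.21 here. Then r(98) = .10, p > .05."
  rs <- extract_document(txt, doc_id = "d1")
  expect_identical(nrow(rs), 3L)
  expect_equal(rs$r, c(0.52, 0.21, 0.10))
  expect_identical(rs$df, c(34L, NA_integer_, 98L))
  expect_identical(rs$location, rep("text", 3))
  rs_signed <- extract_document(txt, strict_absolute = FALSE)
  expect_equal(rs_signed$r[2], -0.21)
  # purity: identical output on identical input
  expect_identical(as.data.frame(rs), as.data.frame(extract_document(txt, doc_id = "d1")))
  expect_identical(nrow(extract_document("")), 0L)
})

test_that("line-break reports are missed by default and recovered with join-lines", {
  txt <- "We saw r(34) =\n.52, p = .003 in the data."
  expect_identical(nrow(extract_document(txt)), 0L)
  joined <- extract_document(txt, join_lines = TRUE)
  expect_equal(joined$r, 0.52)
})

test_that("extraction recovers rendered records exactly for covered formats, with zero false positives", {
  cfg <- generator_config(n_studies = 60, base_text_prob = 1,
                          text_emphasis_odds = 1, r_method = "exact",
                          seed = 301)
  g <- generate_records(cfg)
  covered <- c(canonical = 1, no_df = 1, no_p = 1, p_inequality = 1,
               leading_dot = 1, negative = 1)
  corp <- render_corpus(g$records, variant_mix = covered, seed = 302)
  rep1 <- validate_extraction(corp)
  expect_identical(rep1$recall, 1)
  expect_identical(rep1$n_false_positive, 0L)
  expect_identical(rep1$n_truth, nrow(g$records))
  # extraction agrees with the generator record by record
  for (doc in corp[1:5]) {
    rs <- extract_document(doc$text, doc$doc_id)
    truth <- doc$truth[order(doc$truth$offset), ]
    expect_equal(rs$abs_r, round(abs(truth$r), 2), tolerance = 1e-12)
    expect_identical(rs$df, truth$df)
    expect_identical(rs$p_comparator, truth$p_comparator)
  }
})

test_that("adversarial formats are missed and accounted per variant", {
  cfg <- generator_config(n_studies = 40, base_text_prob = 1,
                          text_emphasis_odds = 1, r_method = "exact",
                          seed = 303)
  g <- generate_records(cfg)
  adv <- c(canonical = 0.5, linebreak = 0.2, subscript = 0.2, verbal = 0.1)
  corp <- render_corpus(g$records, variant_mix = adv, seed = 304,
                        exact_mix = TRUE)
  rep1 <- validate_extraction(corp)
  expect_identical(rep1$n_false_positive, 0L)
  expect_equal(rep1$recall, 0.5, tolerance = 0.003)
  mb <- rep1$miss_breakdown
  expect_identical(sum(mb), rep1$n_truth - rep1$n_detected)
  expect_true(all(mb[c("linebreak", "subscript", "verbal")] > 0))
  expect_identical(mb[["canonical"]], 0L)
  # a verbal-only corpus is undetectable by design
  corp_v <- render_corpus(g$records, variant_mix = c(verbal = 1), seed = 305)
  rep_v <- validate_extraction(corp_v)
  expect_identical(rep_v$recall, 0)
  expect_identical(rep_v$n_false_positive, 0L)
})
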