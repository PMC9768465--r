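# auditing reported significance against exact critical boundaries

consistency_levels <- c("consistent_sig", "consistent_nonsig",
                        "too_small_for_sig", "too_large_for_nonsig",
                        "unresolvable", "unspecified")

#' Classify reported significance against the exact boundary
#'
#' For each record with a resolvable df (reported df, else `n - 2`), the
#' reported label is compared with the two-sided critical boundary at
#' `cfg$alpha`: a reportedly significant `|r|` below the boundary is
#' `too_small_for_sig`; a reportedly non-significant `|r|` at or above it is
#' `too_large_for_nonsig` (significance means `p <= alpha`, so the boundary
#' itself is significant). Records lacking both `n` and `df` are
#' `unresolvable`; unspecified labels stay `unspecified`. A record with no
#' label but a reported `p <` bound at or below `alpha` is audited as
#' significant (the inequality is itself a significance claim). Flags mark
#' suspects, not proven errors: legitimate multiplicity adjustments can
#' produce `too_large_for_nonsig` records.
#'
#' @param rs A record set.
#' @param cfg An [analysis_config()].
#' @return The record set with columns `consistency`, `df_used`,
#'   `r_crit_two`, `r_crit_one` appended.
#' @export
classify_records <- function(rs, cfg = analysis_config()) {
  rs <- as_record_set(rs)
  dfu <- record_df(rs)
  has_df <- !is.na(dfu) & dfu >= 1
  rc2 <- rep(NA_real_, nrow(rs))
  rc1 <- rep(NA_real_, nrow(rs))
  rc2[has_df] <- critical_r(dfu[has_df], cfg$alpha, "two.sided")
  rc1[has_df] <- critical_r(dfu[has_df], cfg$alpha, "one.sided")

  label <- rs$sig_label
  claim_sig <- is.na(label) & !is.na(rs$p_comparator) & rs$p_comparator == "<" &
    !is.na(rs$p_value) & rs$p_value <= cfg$alpha
  label[claim_sig] <- "significant"
  label[is.na(label)] <- "unspecified"

  out <- rep("unspecified", nrow(rs))
  out[!has_df & label != "unspecified"] <- "unresolvable"
  sig <- has_df & label == "significant"
  non <- has_df & label == "non_significant"
  out[sig & rs$abs_r >= rc2] <- "consistent_sig"
  out[sig & rs$abs_r < rc2] <- "too_small_for_sig"
  out[non & rs$abs_r < rc2] <- "consistent_nonsig"
  out[non & rs$abs_r >= rc2] <- "too_large_for_nonsig"

  rs$consistency <- out
  rs$df_used <- dfu
  rs$r_crit_two <- rc2
  rs$r_crit_one <- rc1
  rs
}

#' Resolve records reported without a significance status
#'
#' Recomputes exact p-values for records labelled `unspecified` (with a
#' resolvable df) and counts how many reach `alpha` under a two-sided and a
#' one-sided test. The one-sided count is always at least the two-sided one
#' since the one-sided p is half the two-sided p.
#'
#' @inheritParams classify_records
#' @return List with `n_unspecified` (all unspecified records),
#'   `n_resolvable`, `count_sig_two_sided`, `count_sig_one_sided`.
#' @export
resolve_unspecified <- function(rs, cfg = analysis_config()) {
  rs <- as_record_set(rs)
  unspec <- is.na(rs$sig_label) | rs$sig_label == "unspecified"
  dfu <- record_df(rs)
  res <- unspec & !is.na(dfu) & dfu >= 1 & !is.na(rs$abs_r)
  p2 <- exact_p(rs$abs_r[res], dfu[res], "two.sided")
  p1 <- exact_p(rs$abs_r[res], dfu[res], "one.sided")
  list(
    n_unspecified = sum(unspec),
    n_resolvable = sum(res),
    count_sig_two_sided = sum(p2 <= cfg$alpha),
    count_sig_one_sided = sum(p1 <= cfg$alpha)
  )
}

#' Corpus-level consistency audit
#'
#' Full tally of [classify_records()] labels, significance proportions
#' overall and by text/table location, the count of records reported as
#' exactly `r = 0`, and the [resolve_unspecified()] block.
#'
#' @inheritParams classify_records
#' @return A list of class `audit_report` with `n_records`, `label_counts`,
#'   `label_proportions`, `sig_by_location` (tibble), `n_zero_r`,
#'   `unspecified_resolution`. Label counts partition the record set.
#' @export
audit_summary <- function(rs, cfg = analysis_config()) {
  cls <- classify_records(rs, cfg)
  counts <- table(factor(cls$consistency, levels = consistency_levels))
  loc <- cls
  loc$location[is.na(loc$location)] <- "unknown"
  by_loc <- loc |>
    dplyr::group_by(.data$location) |>
    dplyr::summarise(
      n = dplyr::n(),
      prop_significant = mean(.data$sig_label == "significant", na.rm = TRUE),
      prop_non_significant = mean(.data$sig_label == "non_significant", na.rm = TRUE),
      prop_unspecified = mean(is.na(.data$sig_label) |
                                .data$sig_label == "unspecified"),
      .groups = "drop"
    )
  structure(list(
    n_records = nrow(cls),
    label_counts = as.list(counts),
    label_proportions = as.list(counts / max(1, nrow(cls))),
    sig_overall = list(
      prop_significant = mean(cls$sig_label == "significant", na.rm = TRUE),
      prop_non_significant = mean(cls$sig_label == "non_significant", na.rm = TRUE),
      prop_unspecified = mean(is.na(cls$sig_label) |
                                cls$sig_label == "unspecified")
    ),
    sig_by_location = by_loc,
    n_zero_r = sum(!is.na(cls$r) & cls$r == 0),
    unspecified_resolution = resolve_unspecified(rs, cfg)
  ), class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat("Consistency audit of", x$n_records, "records\n")
  for (lab in names(x$label_counts)) {
    cat(sprintf("  %-22s %6d (%.1f%%)\n", lab, x$label_counts[[lab]],
                100 * x$label_proportions[[lab]]))
  }
  cat(sprintf("  r = 0 reports: %d\n", x$n_zero_r))
  u <- x$unspecified_resolution
  cat(sprintf("  unspecified: %d (%d significant two-sided, %d one-sided of %d resolvable)\n",
              u$n_unspecified, u$count_sig_two_sided, u$count_sig_one_sided,
              u$n_resolvable))
  invisible(x)
}
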