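# statistical-report mining from plain article text
#
# The matcher looks for a standalone lowercase "r" — optionally followed by
# a parenthesised degrees-of-freedom token — followed by "=", ignoring ASCII
# spaces between "r", "(", ")" and "=". A window of at most 56 characters
# starting at the "r" is taken on the same logical line (a newline ends the
# window), which reproduces the documented line-break failure mode of
# text-only mining; `join_lines = TRUE` lifts that restriction.

window_chars <- 56L

# NFKC normalisation plus mapping of minus-sign lookalikes to ASCII hyphen;
# all 1:1 on the characters involved, so offsets refer to normalised text.
normalize_text <- function(text, join_lines = FALSE) {
  text <- stringi::stri_trans_nfkc(text)
  text <- stringi::stri_replace_all_regex(text,
    "[−‒–‐‑]", "-")
  if (join_lines) text <- gsub("\n", " ", text, fixed = TRUE)
  text
}

candidate_pattern <- "(?<![\\p{L}\\p{N}_])r[ ]*(?:\\([^)\\n]*\\))?[ ]*="

#' Locate candidate correlation reports in text
#'
#' Finds every standalone lowercase `r` (not preceded or followed by a
#' letter, digit or underscore) that is followed — ignoring ASCII spaces and
#' an optional parenthesised token — by `=`. Each hit carries the raw
#' extraction window of at most 56 characters starting at the `r`,
#' truncated at the first newline unless `join_lines`.
#'
#' @param text A character scalar (Unicode text; NFKC-normalised
#'   internally, offsets refer to the normalised text).
#' @param doc_id Identifier attached to the hits.
#' @param join_lines Treat newlines as spaces inside windows.
#' @return A tibble of hits: `doc_id`, `match_offset` (0-based index of the
#'   matched `r`), `window`, and empty parse columns (`r`, `df`,
#'   `p_comparator`, `p_value`, `reject_reason`) to be filled by
#'   [parse_hits()].
#' @examples
#' find_candidates("we found r = .38 overall")
#' @export
find_candidates <- function(text, doc_id = "doc", join_lines = FALSE) {
  stopifnot(length(text) == 1)
  text <- normalize_text(text, join_lines)
  empty <- tibble::tibble(doc_id = character(), match_offset = integer(),
                          window = character(), r = double(), df = integer(),
                          p_comparator = character(), p_value = double(),
                          reject_reason = character())
  if (!nzchar(text)) return(empty)
  m <- gregexpr(candidate_pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(empty)
  starts <- as.integer(m)
  windows <- vapply(starts, function(s) {
    w <- substr(text, s, min(s + window_chars - 1L, nchar(text)))
    nl <- regexpr("\n", w, fixed = TRUE)
    if (nl > 0) w <- substr(w, 1L, nl - 1L)
    w
  }, character(1))
  tibble::tibble(doc_id = doc_id, match_offset = starts - 1L,
                 window = windows, r = NA_real_, df = NA_integer_,
                 p_comparator = NA_character_, p_value = NA_real_,
                 reject_reason = NA_character_)
}

number_re <- "[+-]?(?:[0-9]+\\.?[0-9]*|\\.[0-9]+)"

parse_window <- function(w) {
  out <- list(r = NA_real_, df = NA_integer_, p_comparator = NA_character_,
              p_value = NA_real_, reject_reason = NA_character_)
  m <- regexec("^r[ ]*(?:\\(([^)]*)\\))?[ ]*=[ ]*(.*)$", w)
  g <- regmatches(w, m)[[1]]
  if (length(g) == 0) {
    out$reject_reason <- "no_value"
    return(out)
  }
  paren <- g[2]
  rest <- g[3]
  vm <- regexpr(paste0("^", number_re), rest)
  if (vm == -1) {
    out$reject_reason <- "no_value"
    return(out)
  }
  val <- as.numeric(regmatches(rest, vm))
  if (abs(val) > 1) {
    out$reject_reason <- "out_of_range"
    return(out)
  }
  out$r <- val
  # parenthesised integer -> df; a non-integer token keeps r but stores no df
  if (nzchar(paren)) {
    paren <- trimws(paren)
    if (grepl("^[0-9]+$", paren)) out$df <- as.integer(paren)
  }
  after <- substr(rest, attr(vm, "match.length") + 1L, nchar(rest))
  pm <- regexec(paste0("(?<![\\p{L}\\p{N}_])p[ ]*(=|<|>|≤)[ ]*(",
                       number_re, ")"), after, perl = TRUE)
  pg <- regmatches(after, pm)[[1]]
  if (length(pg) > 0) {
    pv <- as.numeric(pg[3])
    if (pv >= 0 && pv <= 1) {
      cmp <- pg[2]
      if (cmp == "≤") cmp <- "<"  # "p <= x" coded as a "<" report
      out$p_comparator <- cmp
      out$p_value <- pv
    }
  }
  out
}

#' Parse candidate hits into statistical records
#'
#' For each window: the first numeric token after `=` (optional sign,
#' leading-dot decimals allowed) becomes `r` — values outside `[-1, 1]` are
#' rejected with reason `out_of_range`, a missing token with `no_value`; a
#' parenthesised integer becomes `df`; a following standalone `p` with
#' comparator `=`, `<` or `>` and a value in `[0, 1]` becomes the p-value
#' report. Absent df/p leave the fields absent. A hit is either parsed or
#' rejected, never both.
#'
#' @param hits A tibble from [find_candidates()].
#' @return The hits with parse columns filled.
#' @export
parse_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  parsed <- lapply(hits$window, parse_window)
  hits$r <- vapply(parsed, `[[`, numeric(1), "r")
  hits$df <- vapply(parsed, `[[`, integer(1), "df")
  hits$p_comparator <- vapply(parsed, `[[`, character(1), "p_comparator")
  hits$p_value <- vapply(parsed, `[[`, numeric(1), "p_value")
  hits$reject_reason <- vapply(parsed, `[[`, character(1), "reject_reason")
  hits
}

#' Extract all correlation reports from one document
#'
#' Composition of [find_candidates()] and [parse_hits()]: returns a record
#' set of the successfully parsed reports in document order, located in
#' `text`. By default signs are discarded (`abs_r` drives all downstream
#' analysis; mined signs are unreliable because character-encoding quirks
#' can silently drop a minus).
#'
#' @inheritParams find_candidates
#' @param strict_absolute Discard the sign of extracted `r` (default TRUE).
#' @return A record set tibble (possibly empty).
#' @export
extract_document <- function(text, doc_id = "doc", strict_absolute = TRUE,
                             join_lines = FALSE) {
  hits <- parse_hits(find_candidates(text, doc_id, join_lines))
  ok <- hits[is.na(hits$reject_reason), , drop = FALSE]
  rs <- as_record_set(tibble::tibble(
    record_id = if (nrow(ok)) paste0(doc_id, "_", seq_len(nrow(ok))) else character(),
    r = if (strict_absolute) abs(ok$r) else ok$r,
    df = ok$df,
    p_comparator = ok$p_comparator, p_value = ok$p_value,
    location = rep("text", nrow(ok)),
    study_id = rep(doc_id, nrow(ok))
  ), provenance = paste0("extract_document(", doc_id, ")"))
  attr(rs, "hits") <- hits
  rs
}

#' Measure extraction recall on an annotated corpus
#'
#' Runs [extract_document()] on every document of a corpus produced by
#' [render_corpus()] and scores parsed hits against the embedded ground
#' truth: a truth record counts as detected when some parsed hit sits
#' within +/-2 characters of its offset and agrees on `|r|` to 2 decimals.
#' Parsed hits matching no truth record are false positives.
#'
#' @param corpus List of annotated documents.
#' @param join_lines Passed through to extraction.
#' @return A list of class `recall_report`: `n_truth`, `n_detected`,
#'   `n_false_positive`, `recall` and `miss_breakdown` (misses per format
#'   variant).
#' @export
validate_extraction <- function(corpus, join_lines = FALSE) {
  n_truth <- 0L
  n_detected <- 0L
  n_fp <- 0L
  misses <- character()
  for (doc in corpus) {
    hits <- parse_hits(find_candidates(doc$text, doc$doc_id, join_lines))
    ok <- hits[is.na(hits$reject_reason), , drop = FALSE]
    truth <- doc$truth
    n_truth <- n_truth + nrow(truth)
    used <- rep(FALSE, nrow(ok))
    for (i in seq_len(nrow(truth))) {
      cand <- which(!used &
                      abs(ok$match_offset - truth$offset[i]) <= 2 &
                      round(abs(ok$r), 2) == round(abs(truth$r[i]), 2))
      if (length(cand) > 0) {
        used[cand[1]] <- TRUE
        n_detected <- n_detected + 1L
      } else {
        misses <- c(misses, truth$variant[i])
      }
    }
    n_fp <- n_fp + sum(!used)
  }
  structure(list(
    n_truth = n_truth, n_detected = n_detected, n_false_positive = n_fp,
    recall = if (n_truth > 0) n_detected / n_truth else NA_real_,
    miss_breakdown = table(factor(misses, levels = format_variants))
  ), class = "recall_report")
}

#' @export
print.recall_report <- function(x, ...) {
  cat("Extraction recall report\n")
  cat(sprintf("  truth records : %d\n", x$n_truth))
  cat(sprintf("  detected      : %d (recall %.3f)\n", x$n_detected, x$recall))
  cat(sprintf("  false positives: %d\n", x$n_false_positive))
  mb <- x$miss_breakdown[x$miss_breakdown > 0]
  if (length(mb)) {
    cat("  misses by variant:\n")
    for (v in names(mb)) cat(sprintf("    %-12s %d\n", v, mb[[v]]))
  }
  invisible(x)
}
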