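# serialisation of a single correlation report in a given format variant
format_variants <- c("canonical", "no_df", "no_p", "p_inequality",
                     "leading_dot", "negative", "linebreak", "subscript",
                     "verbal")

fmt_num <- function(x, digits = 2, leading_dot = FALSE) {
  s <- sprintf(paste0("%.", digits, "f"), x)
  if (leading_dot) s <- sub("^(-?)0\\.", "\\1.", s)
  s
}

fmt_p <- function(p, leading_dot = FALSE) {
  if (is.na(p)) return("")
  if (p < 0.001) return(paste0("p < ", fmt_num(0.001, 3, leading_dot)))
  paste0("p = ", fmt_num(p, 3, leading_dot))
}

render_stat <- function(r, df, p, variant) {
  r2 <- fmt_num(r)
  dfpart <- if (!is.na(df)) paste0("(", df, ")") else ""
  switch(variant,
    canonical = paste0("r", dfpart, " = ", r2,
                       if (!is.na(p)) paste0(", ", fmt_p(p)) else ""),
    no_df = paste0("r = ", r2,
                   if (!is.na(p)) paste0(", ", fmt_p(p)) else ""),
    no_p = paste0("r", dfpart, " = ", r2),
    p_inequality = paste0("r", dfpart, " = ", r2, ", ",
                          if (!is.na(p) && p <= 0.05) "p < 0.05" else "p > 0.05"),
    leading_dot = paste0("r", dfpart, " = ", fmt_num(r, 2, TRUE),
                         if (!is.na(p)) paste0(", ", fmt_p(p, TRUE)) else ""),
    negative = paste0("r", dfpart, " = −", fmt_num(abs(r))),
    linebreak = paste0("r", dfpart, " =\n", r2,
                       if (!is.na(p)) paste0(", ", fmt_p(p)) else ""),
    subscript = paste0("r_scale = ", r2),
    verbal = paste0("the correlation was ", sprintf("%.2f", abs(r))),
    stop("unknown variant: ", variant)
  )
}

filler_sentences <- c(
  "Participants completed all questionnaires online.",
  "Descriptive statistics are shown for each scale.",
  "The measures showed adequate internal consistency.",
  "Data were collected across two academic terms.",
  "All analyses were conducted on the full sample."
)

#' Render a record set into annotated pseudo-article text
#'
#' Serialises each text-located record into a sentence using a sampled
#' format variant, grouped into one document per study. Table-located
#' records are deliberately not rendered — emulating the blind spot of
#' text-only mining. The ground truth (0-based character offset of each
#' embedded report, its record and variant) is returned with each document,
#' so extraction recall can be measured exactly. Variants `linebreak`,
#' `subscript` and `verbal` are adversarial: they defeat the extraction
#' rules by construction.
#'
#' @param rs A record set.
#' @param variant_mix Named probability vector over
#'   `r format_variants`; the default allocates 7% to the
#'   adversarial line-break/subscript formats and none to verbal reports.
#' @param seed Optional seed.
#' @param exact_mix Allocate variant counts exactly proportional to
#'   `variant_mix` (largest-remainder rounding) instead of sampling them.
#' @return A list of annotated documents, each a list with `doc_id`, `text`
#'   and a `truth` tibble (`offset`, `variant`, `record_id`, `r`, `df`,
#'   `p_comparator`, `p_value`).
#' @export
render_corpus <- function(rs,
                          variant_mix = c(canonical = 0.30, no_df = 0.16,
                                          no_p = 0.16, p_inequality = 0.12,
                                          leading_dot = 0.12, negative = 0.07,
                                          linebreak = 0.04, subscript = 0.03,
                                          verbal = 0),
                          seed = NULL, exact_mix = FALSE) {
  rs <- as_record_set(rs)
  if (!all(names(variant_mix) %in% format_variants)) {
    stop("unknown variant in variant_mix")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  rs <- rs[!is.na(rs$location) & rs$location == "text" & !is.na(rs$r), ,
           drop = FALSE]
  if (nrow(rs) == 0) return(list())
  mix <- variant_mix / sum(variant_mix)
  nr <- nrow(rs)
  if (exact_mix) {
    counts <- floor(mix * nr)
    rem <- nr - sum(counts)
    if (rem > 0) {
      extra <- order(mix * nr - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    variant <- sample(rep(names(mix), counts))
  } else {
    variant <- sample(names(mix), nr, replace = TRUE, prob = mix)
  }

  doc_ids <- rs$study_id
  doc_ids[is.na(doc_ids)] <- "doc"
  out <- lapply(split(seq_len(nr), doc_ids), function(ix) {
    parts <- filler_sentences[1 + (seq_along(ix) %% length(filler_sentences))]
    text <- ""
    truth <- vector("list", length(ix))
    for (j in seq_along(ix)) {
      i <- ix[j]
      lead <- paste0(parts[j], " We observed ")
      stat <- render_stat(rs$r[i], rs$df[i], rs$p_value[i], variant[i])
      # negative variant renders a forced minus; truth carries the signed value
      r_truth <- if (variant[i] == "negative") -abs(rs$r[i]) else rs$r[i]
      # truth p fields reflect what was rendered, not the unrounded record
      p <- rs$p_value[i]
      pc <- pv <- NA
      if (variant[i] %in% c("canonical", "no_df", "leading_dot") && !is.na(p)) {
        pc <- if (p < 0.001) "<" else "="
        pv <- if (p < 0.001) 0.001 else round(p, 3)
      } else if (variant[i] == "p_inequality") {
        pc <- if (!is.na(p) && p <= 0.05) "<" else ">"
        pv <- 0.05
      }
      # df as rendered: variants without a parenthesised df carry none
      df_truth <- if (variant[i] %in% c("no_df", "subscript", "verbal")) {
        NA_integer_
      } else rs$df[i]
      offset <- nchar(text, type = "chars") + nchar(lead, type = "chars")
      text <- paste0(text, lead, stat, " in this sample.\n")
      truth[[j]] <- tibble::tibble(
        offset = offset, variant = variant[i], record_id = rs$record_id[i],
        r = r_truth, df = df_truth,
        p_comparator = as.character(pc), p_value = as.numeric(pv)
      )
    }
    list(doc_id = unique(doc_ids[ix]), text = text,
         truth = dplyr::bind_rows(truth))
  })
  unname(out)
}
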