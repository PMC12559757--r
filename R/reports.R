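#' BI-RADS-style density category labels, in ascending density order
#' @keywords internal
density_labels <- c("Almost entirely fatty",
                    "Scattered areas of fibroglandular density",
                    "Heterogeneously dense",
                    "Extremely dense")

#' Build an ordered density-category factor
#'
#' @param level integer vector in 1..4 (1 = almost entirely fatty,
#'   4 = extremely dense); `NA` marks unclassifiable.
#' @return ordered factor over the four density labels.
#' @export
density_category <- function(level) {
  factor(density_labels[as.integer(level)], levels = density_labels,
         ordered = TRUE)
}

#' Keyword rule table for report-text density extraction
#'
#' Each row maps a case-insensitive key phrase to an ordinal density level.
#' The same table seeds the synthetic report generator, so mapper and
#' generator share one vocabulary. The table is the editable extension point
#' for site-specific phrasing.
#'
#' @return tibble with columns `level`, `label`, `phrase`.
#' @export
density_keyword_table <- function() {
  tibble::tribble(
    ~level, ~phrase,
    4L, "extremely dense",
    4L, "extremely fibroglandular",
    3L, "heterogeneously dense",
    3L, "heterogeneously fibroglandular",
    2L, "scattered fibroglandular",
    1L, "entirely fatty",
    1L, "predominantly fatty"
  ) %>% mutate(label = density_labels[.data$level]) %>%
    select("level", "label", "phrase")
}

#' Classify mammography report text into a density category
#'
#' Case-insensitive substring matching against the keyword table, evaluated
#' in descending level order (4 down to 1); the first matching level wins.
#' Internal runs of whitespace are collapsed before matching so line wraps in
#' reports do not break key phrases. A text matching no phrase is explicitly
#' unclassifiable (`NA` in the result, with a warning naming the count); a
#' text matching several levels (e.g. a report quoting a prior exam) warns
#' and keeps the highest level. Negation is not parsed: "not extremely
#' dense" still matches "extremely dense" — a documented limitation.
#'
#' @param text character vector of report texts.
#' @param rules rule table, by default [density_keyword_table()].
#' @return ordered factor over the four density labels, `NA` where
#'   unclassifiable.
#' @export
classify_report_text <- function(text, rules = density_keyword_table()) {
  if (length(text) == 0 || any(!nzchar(text) | is.na(text))) {
    abort("`text` must be non-empty character strings.")
  }
  norm <- stringr::str_squish(tolower(text))
  hit <- matrix(FALSE, nrow = length(text), ncol = 4)
  for (lv in 1:4) {
    for (ph in rules$phrase[rules$level == lv]) {
      hit[, lv] <- hit[, lv] | stringr::str_detect(norm, stringr::fixed(ph))
    }
  }
  n_levels <- rowSums(hit)
  out <- rep(NA_integer_, length(text))
  any_hit <- n_levels > 0
  if (any(any_hit)) {
    out[any_hit] <- apply(hit[any_hit, , drop = FALSE], 1,
                          function(h) max(which(h)))
  }
  if (any(n_levels > 1)) {
    warn(sprintf(
      "%d report(s) matched phrases from multiple density levels; keeping the highest level for each.",
      sum(n_levels > 1)))
  }
  if (any(!any_hit)) {
    warn(sprintf("%d report(s) unclassifiable (no density key phrase found); returned NA.",
                 sum(!any_hit)))
  }
  density_category(out)
}

# Sentence templates per level; every template embeds a rule phrase so the
# generator and the mapper stay in lock-step.
report_templates <- list(
  c("The breasts are almost entirely fatty.",
    "The breast tissue is predominantly fatty."),
  c("There are scattered fibroglandular densities.",
    "Scattered fibroglandular tissue is noted throughout both breasts."),
  c("The breast tissue is heterogeneously dense, which may obscure small masses.",
    "Heterogeneously fibroglandular tissue is present."),
  c("The breast tissue is extremely dense, which lowers the sensitivity of mammography.",
    "The parenchyma is extremely fibroglandular.")
)

# Draw one report sentence for a category level (uses the current RNG stream).
render_report_text <- function(level) {
  vapply(as.integer(level), function(lv) {
    tpl <- report_templates[[lv]]
    tpl[sample.int(length(tpl), 1)]
  }, character(1))
}
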