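# Exact 2x2 proportion comparison: sample odds ratio plus Fisher's exact
# two-sided p-value (point-probability convention).

#' Exact test for a 2x2 proportion table
#'
#' Compares a binary trait between two groups. Reports the sample odds
#' ratio `ad/bc` (with explicit handling of zero cells: `Inf` when only the
#' denominator is zero, `0` when only the numerator is, `NaN` when both)
#' and the exact two-sided Fisher p-value, computed by summing the
#' probabilities of all tables with the fixed margins whose point
#' probability does not exceed that of the observed table.
#'
#' @param table A 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = trait present/absent), or the four counts `a, b, c, d` given
#'   via the `...` shortcut below.
#' @param ... Alternatively pass `a, b, c, d` as four scalars.
#' @return A tibble with `odds_ratio`, `p`, and the four counts.
#' @examples
#' # mutation carriers vs wild-type in two cohorts of 77 and 172 tumors
#' proportion_test(matrix(c(2, 75, 12, 160), 2, 2, byrow = TRUE))
#' @export
proportion_test <- function(table = NULL, ...) {
  extra <- list(...)
  if (is.null(table)) {
    if (length(extra) != 4) abort("supply a 2x2 matrix or four counts a, b, c, d")
    table <- matrix(as.numeric(unlist(extra)), 2, 2, byrow = TRUE)
  }
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("`table` must be 2x2")
  if (any(table < 0) || any(table != floor(table))) abort("counts must be non-negative integers")
  if (sum(table) == 0) abort("empty table: at least one positive margin required")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  num <- a * d; den <- b * c
  orr <- if (den == 0 && num == 0) NaN else if (den == 0) Inf else num / den
  p <- fisher.test(table, alternative = "two.sided")$p.value
  tibble(odds_ratio = orr, p = p, a = a, b = b, c = c, d = d)
}
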