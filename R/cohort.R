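#' Drop unconfirmed-EIM enrollees
#'
#' Participants with clinical symptoms of EIMs but no specialist-confirmed
#' diagnosis (`eim_status == "unconfirmed"`) are excluded from analysis;
#' all other records pass through unchanged.
#'
#' @param records Cohort tibble (see [make_cohort_fixture()]).
#' @return The filtered tibble.
#' @export
apply_enrollment_filter <- function(records) {
  dplyr::filter(records, .data$eim_status != "unconfirmed")
}

#' Group-by-subtype cell counts and margins
#'
#' Tabulates the analysis cohort into EIM/control by CD/UC cells, with
#' `(all)` margin rows for each dimension. `group` is `"EIM"` for confirmed
#' EIM cases and `"C"` otherwise.
#'
#' @param records Filtered cohort tibble; every record needs a subtype.
#' @return A tibble: `group`, `subtype`, `n`, including margin rows.
#' @export
group_sizes <- function(records) {
  if (nrow(records) && any(is.na(records$subtype))) {
    stop("record(s) missing subtype", call. = FALSE)
  }
  if (!nrow(records)) {
    grid <- tidyr::expand_grid(group = c("EIM", "C", "(all)"),
                               subtype = c("CD", "UC", "(all)"))
    return(dplyr::mutate(grid, n = 0L))
  }
  rec <- dplyr::mutate(records,
                       group = ifelse(.data$eim_status == "confirmed", "EIM", "C"))
  cells <- rec %>%
    dplyr::count(.data$group, .data$subtype) %>%
    tidyr::complete(group = c("EIM", "C"), subtype = c("CD", "UC"),
                    fill = list(n = 0L))
  gm <- cells %>% dplyr::count(.data$group, wt = .data$n) %>%
    dplyr::mutate(subtype = "(all)")
  sm <- cells %>% dplyr::count(.data$subtype, wt = .data$n) %>%
    dplyr::mutate(group = "(all)")
  tot <- tibble::tibble(group = "(all)", subtype = "(all)", n = sum(cells$n))
  dplyr::bind_rows(cells, gm, sm, tot) %>%
    dplyr::arrange(.data$group, .data$subtype)
}

as_2x2 <- function(table) {
  if (is.data.frame(table)) table <- as.matrix(table)
  if (is.numeric(table) && length(table) == 4 && is.null(dim(table))) {
    table <- matrix(table, 2, 2, byrow = TRUE)
  }
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)),
            all(table >= 0), all(table == round(table)))
  if (sum(table) == 0) stop("empty contingency table", call. = FALSE)
  table
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by hypergeometric enumeration: the sum of the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed the observed table's. The odds ratio is the sample
#' estimate `ad / (bc)` (infinite when `bc = 0`).
#'
#' @param table 2x2 matrix (rows = group, columns = trait), or the four
#'   cells `a, b, c, d` in row order.
#' @return A tibble: `odds_ratio`, `p`.
#' @export
fisher_exact <- function(table) {
  tb <- as_2x2(table)
  a <- tb[1, 1]; b <- tb[1, 2]; c <- tb[2, 1]; d <- tb[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    stop("degenerate margin: use a table with positive margins", call. = FALSE)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, c1, c2, r1)
  p_obs <- stats::dhyper(a, c1, c2, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  tibble::tibble(odds_ratio = or, p = min(p, 1))
}

#' Pearson chi-square test for a 2x2 table
#'
#' `sum((O - E)^2 / E)` against chi-square with 1 degree of freedom;
#' the Yates continuity correction is off by default.
#'
#' @inheritParams fisher_exact
#' @param correct Apply the Yates continuity correction.
#' @return A tibble: `statistic`, `p`.
#' @export
chi_square <- function(table, correct = FALSE) {
  tb <- as_2x2(table)
  E <- outer(rowSums(tb), colSums(tb)) / sum(tb)
  if (any(E == 0)) {
    stop("zero expected cell count: use fisher_exact() instead", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tb, correct = correct))
  tibble::tibble(statistic = unname(ct$statistic), p = ct$p.value)
}
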