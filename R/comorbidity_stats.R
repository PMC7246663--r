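# Prevalence, comorbidity-count, pairwise co-occurrence and relative-risk
# statistics, plus the 2x2 group-comparison tests used by the report tables.

# Sparse patient x disease incidence matrix over non-index diagnoses.
.incidenceMatrix <- function(cohort) {
  dxl <- cohort@diagnoses
  codes <- unlist(dxl, use.names = FALSE)
  pat <- rep.int(seq_len(length(cohort)), elementNROWS(dxl))
  keep <- !(codes %in% cohort@indexCodes)
  codes <- codes[keep]
  pat <- pat[keep]
  lev <- sort(unique(codes))
  sparseMatrix(i = pat, j = match(codes, lev), x = 1,
               dims = c(length(cohort), length(lev)),
               dimnames = list(NULL, as.character(lev)))
}

#' Per-disease carrier counts and prevalences
#'
#' One row per non-index disease observed in at least one patient, with the
#' carrier count and the prevalence `count / N` (denominator: the full
#' cohort size). Rows are ordered by count descending, ties broken by code
#' ascending, and carry a dense `rank`.
#'
#' @param cohort an index-filtered, normalized [Cohort-class].
#' @return data.frame with columns `code`, `count`, `prevalence`, `rank`,
#'   plus attributes `N` (cohort size) and `indexCodes`. Empty cohort gives
#'   an empty table with `N = 0`.
#' @seealso [pairCounts()], [relativeRisk()]
#' @export
prevalenceTable <- function(cohort) {
  stopifnot(is(cohort, "Cohort"))
  X <- .incidenceMatrix(cohort)
  cnt <- colSums(X)
  N <- length(cohort)
  tab <- data.frame(
    code = as.character(colnames(X)),
    count = as.integer(cnt),
    prevalence = if (N > 0) as.numeric(cnt) / N else numeric(length(cnt)),
    stringsAsFactors = FALSE
  )
  tab <- tab[tab$count > 0, , drop = FALSE]
  tab <- tab[order(-tab$count, tab$code), , drop = FALSE]
  rownames(tab) <- NULL
  tab$rank <- seq_len(nrow(tab))
  attr(tab, "N") <- N
  attr(tab, "indexCodes") <- cohort@indexCodes
  tab
}

#' Distribution of the number of comorbidities per patient
#'
#' For each patient, k is the number of distinct non-index diagnoses; the
#' distribution reports, for every k from 0 to the maximum observed, the
#' patient count `n` and fraction `f = n / N`.
#'
#' @param cohort an index-filtered, normalized [Cohort-class].
#' @param label optional stratum label stored as an attribute.
#' @return data.frame with columns `k`, `n`, `f`; attributes `N`,
#'   `meanCount` (mean comorbidity count) and `label`.
#' @export
comorbidityCountDistribution <- function(cohort, label = "all") {
  stopifnot(is(cohort, "Cohort"))
  k <- elementNROWS(cohort@diagnoses) -
    countCodeHits(cohort, cohort@indexCodes)
  N <- length(cohort)
  kk <- if (N > 0) 0:max(k) else integer()
  n <- vapply(kk, function(v) sum(k == v), 1L)
  out <- data.frame(k = kk, n = n,
                    f = if (N > 0) n / N else numeric(0))
  attr(out, "N") <- N
  attr(out, "meanCount") <- if (N > 0) mean(k) else NA_real_
  attr(out, "label") <- label
  out
}

#' Pairwise co-occurrence counts
#'
#' Counts, for every unordered pair of non-index diseases, the number of
#' patients carrying both. Only pairs with a positive count are returned;
#' pairs are stored with `codeA < codeB`.
#'
#' @param cohort an index-filtered, normalized [Cohort-class].
#' @return data.frame with columns `codeA`, `codeB`, `count`, ordered by
#'   count descending then codes; attribute `N` carries the cohort size.
#' @export
pairCounts <- function(cohort) {
  stopifnot(is(cohort, "Cohort"))
  X <- .incidenceMatrix(cohort)
  CP <- as(crossprod(X), "TsparseMatrix")
  keep <- CP@i < CP@j & CP@x > 0        # strict upper triangle, 0-based idx
  lev <- as.character(colnames(X))
  out <- data.frame(
    codeA = lev[CP@i[keep] + 1L],
    codeB = lev[CP@j[keep] + 1L],
    count = as.integer(CP@x[keep]),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$count, out$codeA, out$codeB), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "N") <- length(cohort)
  out
}

#' Relative risk of a disease pair from raw counts
#'
#' The co-occurrence relative risk is the observed pair prevalence divided
#' by the expected pair prevalence under independence,
#' `RR = (C_AB / N) / ((C_A / N) * (C_B / N)) = C_AB * N / (C_A * C_B)`.
#'
#' @param cAB patients carrying both diseases.
#' @param cA,cB marginal carrier counts (must be positive).
#' @param N cohort size.
#' @return The relative risk as a single number.
#' @examples
#' rrFromCounts(3258, 8449, 4348, 14891)  # 1.3206
#' @export
rrFromCounts <- function(cAB, cA, cB, N) {
  for (v in list(cAB = cAB, cA = cA, cB = cB, N = N)) .assertCount(v, "count")
  if (cA <= 0 || cB <= 0)
    stop("relative risk is undefined when a marginal count is zero",
         call. = FALSE)
  if (cAB > min(cA, cB))
    stop("integrity error: pair count exceeds a marginal count", call. = FALSE)
  (cAB * N) / (cA * cB)
}

#' Pairwise relative-risk statistics
#'
#' Joins pair co-occurrence counts with the marginal prevalence table and
#' computes, per pair: observed pair prevalence `C_AB / N`, expected pair
#' prevalence `p_A * p_B`, relative risk `RR = (C_AB * N) / (C_A * C_B)`,
#' the significance flag `RR > 1` (strict, the network edge criterion), and
#' a Katz log-normal 95% confidence interval for RR (stored for reference;
#' not used for filtering).
#'
#' @param pairs output of [pairCounts()].
#' @param prevalence output of [prevalenceTable()] from the same cohort.
#' @return data.frame with columns `codeA`, `codeB`, `count`, `observed`,
#'   `expected`, `rr`, `rrLow`, `rrHigh`, `significant`; attribute `N`.
#'   Pairs whose marginal count is zero cannot occur in `pairs` from the
#'   same cohort, but are dropped with a message if present.
#' @export
relativeRisk <- function(pairs, prevalence) {
  N <- attr(pairs, "N")
  if (is.null(N)) N <- attr(prevalence, "N")
  if (is.null(N)) stop("inputs carry no cohort size attribute", call. = FALSE)
  cnt <- setNames(prevalence$count, prevalence$code)
  cA <- as.numeric(cnt[pairs$codeA])
  cB <- as.numeric(cnt[pairs$codeB])
  bad <- is.na(cA) | is.na(cB) | cA == 0 | cB == 0
  if (any(bad)) {
    message("dropping ", sum(bad),
            " pair(s) with zero/unknown marginal counts (RR undefined)")
    pairs <- pairs[!bad, , drop = FALSE]
    cA <- cA[!bad]; cB <- cB[!bad]
  }
  if (any(pairs$count > pmin(cA, cB)))
    stop("integrity error: pair count exceeds a marginal count", call. = FALSE)
  rr <- (pairs$count * N) / (cA * cB)
  # Katz: RR equals risk of B given A vs. risk of B in the cohort
  se <- sqrt(pmax(0, 1 / pairs$count - 1 / cA + 1 / cB - 1 / N))
  z <- qnorm(0.975)
  out <- data.frame(
    codeA = pairs$codeA, codeB = pairs$codeB, count = pairs$count,
    observed = pairs$count / N,
    expected = (cA / N) * (cB / N),
    rr = rr,
    rrLow = rr * exp(-z * se),
    rrHigh = rr * exp(z * se),
    significant = rr > 1,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "N") <- N
  out
}

#' Compare carrier proportions between groups
#'
#' For a 2 x k contingency table (rows: carriers / non-carriers; columns:
#' groups), runs the two-sided test chosen by the Cochran rule on expected
#' counts: Pearson chi-squared when all expected counts are >= 5; Yates
#' continuity-corrected chi-squared when the minimum expected count is in
#' \[1, 5); Fisher's exact test when any expected count is < 1. Tables wider
#' than 2 x 2 always use the plain chi-squared test.
#'
#' @param tab 2 x k matrix of non-negative integer counts.
#' @return one-row data.frame with columns `test` (`"chi2"`,
#'   `"chi2_continuity"` or `"fisher"`), `statistic` (NA for Fisher) and
#'   `p_value`.
#' @examples
#' groupComparison(matrix(c(6495, 4824, 1954, 1618), nrow = 2))
#' @export
groupComparison <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2L || ncol(tab) < 2L)
    stop("expected a 2 x k table with k >= 2", call. = FALSE)
  if (any(is.na(tab)) || any(tab < 0) || any(tab != trunc(tab)))
    stop("table entries must be non-negative integers", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: a row or column margin is zero", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (ncol(tab) > 2L || min(expected) >= 5) {
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    test <- "chi2"
  } else if (min(expected) >= 1) {
    ht <- suppressWarnings(chisq.test(tab, correct = TRUE))
    test <- "chi2_continuity"
  } else {
    ht <- fisher.test(tab)
    test <- "fisher"
  }
  data.frame(test = test,
             statistic = if (test == "fisher") NA_real_
                         else unname(ht$statistic),
             p_value = unname(ht$p.value),
             stringsAsFactors = FALSE)
}
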