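# Prevalence, comorbidity counts, pair co-occurrence, relative risk and the
# 2x2 group-comparison tests.

test_that("prevalence matches a brute-force per-patient recount", {
  gen <- generateCohort(defaultSyntheticConfig(200L), seed = 4)
  pt <- prevalenceTable(gen$cohort)
  oracle <- bruteForcePrevalence(gen$cohort)
  expect_setequal(pt$code, names(oracle))
  expect_equal(setNames(pt$count, pt$code)[names(oracle)], oracle)
  expect_equal(pt$prevalence, pt$count / 200)
  # p_d * N = C_d exactly
  expect_true(all(abs(pt$prevalence * 200 - pt$count) < 1e-12))
  # index disease absent, ranks dense and count-sorted
  expect_false("C220" %in% pt$code)
  expect_equal(pt$rank, seq_len(nrow(pt)))
  expect_false(is.unsorted(-pt$count))
})

test_that("prevalence handles saturation and empty cohorts", {
  co <- makeCohort(rep(list(c("C220", "K74")), 4))
  pt <- prevalenceTable(co)
  expect_equal(pt$prevalence[pt$code == "K74"], 1.0)
  empty <- suppressWarnings(filterIndexCohort(co, "Z000"))
  ptE <- prevalenceTable(empty)
  expect_equal(nrow(ptE), 0L)
  expect_equal(attr(ptE, "N"), 0L)
})

test_that("comorbidity count distribution counts non-index diagnoses", {
  co <- makeCohort(list("C220", c("C220", "K74", "B18", "I10")))
  d <- comorbidityCountDistribution(co)
  expect_equal(d$n[d$k == 0], 1L)   # index-only patient
  expect_equal(d$n[d$k == 3], 1L)
  expect_equal(sum(d$n), 2L)
  expect_equal(sum(d$f), 1, tolerance = 1e-12)
  # linearity of expectation: mean k equals the sum of prevalences
  gen <- generateCohort(defaultSyntheticConfig(300L), seed = 8)
  dist <- comorbidityCountDistribution(gen$cohort)
  pt <- prevalenceTable(gen$cohort)
  expect_equal(attr(dist, "meanCount"), sum(pt$prevalence),
               tolerance = 1e-12)
})

test_that("pair counts match a quadratic-scan recount", {
  co <- makeCohort(list(c("C220", "A", "B"), c("C220", "A", "B"),
                        c("C220", "A"), c("C220", "D")))
  pc <- pairCounts(co)
  expect_equal(pc$count[pc$codeA == "A" & pc$codeB == "B"], 2L)
  # disjoint carriers: pair absent (sparsity contract)
  expect_false(any(pc$codeA == "A" & pc$codeB == "D"))
  gen <- generateCohort(defaultSyntheticConfig(100L), seed = 6)
  pc <- pairCounts(gen$cohort)
  oracle <- bruteForcePairCounts(gen$cohort)
  got <- pc[order(pc$codeA, pc$codeB), ]
  want <- oracle[order(oracle$codeA, oracle$codeB), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got[, c("codeA", "codeB", "count")], want)
})

test_that("relative risk follows the observed/expected prevalence ratio", {
  # printed marginal and pair counts of the cirrhosis-hepatitis B pair
  expect_equal(rrFromCounts(3258, 8449, 4348, 14891), 1.320627,
               tolerance = 1e-6)
  # perfectly nested pair: RR = N / C
  expect_equal(rrFromCounts(10, 10, 10, 200), 20)
  # exact independence sits on the strict boundary: not significant
  co <- local({
    dx <- rep(list("C220"), 200)
    for (i in 1:50) dx[[i]] <- c(dx[[i]], "A")
    for (i in c(1:10, 51:80)) dx[[i]] <- c(dx[[i]], "B")
    makeCohort(dx)
  })
  rr <- relativeRisk(pairCounts(co), prevalenceTable(co))
  row <- rr[rr$codeA == "A" & rr$codeB == "B", ]
  expect_equal(row$count, 10L)
  expect_equal(row$rr, 1.0)
  expect_false(row$significant)
  expect_equal(row$observed, 10 / 200)
  expect_equal(row$expected, (50 / 200) * (40 / 200))
  # Katz CI brackets the point estimate
  expect_true(row$rrLow < 1 && row$rrHigh > 1)
  expect_error(rrFromCounts(30, 20, 25, 100), "integrity")
})

test_that("relative risk is symmetric and additive over disjoint cohorts", {
  gen <- generateCohort(recoveryConfig(N = 150L), seed = 3)
  co <- gen$cohort
  perm <- sample(length(co))
  rr1 <- relativeRisk(pairCounts(co), prevalenceTable(co))
  co2 <- co[perm]
  rr2 <- relativeRisk(pairCounts(co2), prevalenceTable(co2))
  expect_equal(rr1, rr2)
  # split into two disjoint halves: counts are additive
  a <- co[1:75]; b <- co[76:150]
  pcA <- pairCounts(a); pcB <- pairCounts(b); pcAll <- pairCounts(co)
  key <- function(d) setNames(d$count, paste(d$codeA, d$codeB))
  kA <- key(pcA); kB <- key(pcB); kAll <- key(pcAll)
  allKeys <- names(kAll)
  expect_equal(kAll,
               setNames(ifelse(is.na(kA[allKeys]), 0L, kA[allKeys]) +
                        ifelse(is.na(kB[allKeys]), 0L, kB[allKeys]),
                        allKeys))
  cntOf <- function(x) setNames(x$count, x$code)
  ptA <- cntOf(prevalenceTable(a)); ptB <- cntOf(prevalenceTable(b))
  ptAll <- cntOf(prevalenceTable(co))
  expect_equal(ptAll,
               setNames(ifelse(is.na(ptA[names(ptAll)]), 0L,
                               ptA[names(ptAll)]) +
                        ifelse(is.na(ptB[names(ptAll)]), 0L,
                               ptB[names(ptAll)]), names(ptAll)))
})

test_that("under independence, half the pairs exceed RR 1 and mean RR is 1", {
  cfg <- syntheticConfig(50000L, background = setNames(
    rep(0.2, 20), sprintf("X%02d", 1:20)))
  gen <- generateCohort(cfg, seed = 31)
  rr <- relativeRisk(pairCounts(gen$cohort), prevalenceTable(gen$cohort))
  expect_equal(mean(rr$rr), 1, tolerance = 0.05)
  # 190 pairs, binomial sd ~ 0.036: two sd band around 1/2
  expect_lt(abs(mean(rr$rr > 1) - 0.5), 0.075)
})

test_that("group comparison picks the Cochran-rule test and gets the
           published cirrhosis p-value", {
  # male 6495/11319 vs female 1954/3572 cirrhosis carriers -> plain chi2
  res <- groupComparison(matrix(c(6495, 11319 - 6495, 1954, 3572 - 1954),
                                nrow = 2))
  expect_equal(res$test, "chi2")
  expect_equal(round(res$p_value, 4), 0.0049)
  # symmetric table: no association
  expect_equal(groupComparison(matrix(c(5, 5, 5, 5), 2))$p_value, 1.0)
  # continuity correction when min expected in [1, 5)
  expect_equal(groupComparison(matrix(c(2, 8, 8, 40), 2))$test,
               "chi2_continuity")
  # Fisher when an expected count < 1
  fisherTab <- matrix(c(1, 1, 1, 50), 2)
  expect_equal(groupComparison(fisherTab)$test, "fisher")
  # zero column margin
  expect_error(groupComparison(matrix(c(0, 0, 10, 40), 2)), "degenerate")
  expect_error(groupComparison(matrix(c(-1, 2, 3, 4), 2)), "integer")
})

test_that("Fisher two-sided p matches hypergeometric tail enumeration", {
  # oracle: enumerate all tables with the observed margins and sum the
  # probabilities of those at most as probable as the observed one
  fisherOracle <- function(tab) {
    rs <- rowSums(tab); cs <- colSums(tab)
    pTab <- function(a) dhyper(a, rs[1], rs[2], cs[1])
    pObs <- pTab(tab[1, 1])
    as_ <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
    sum(pTab(as_)[pTab(as_) <= pObs * (1 + 1e-7)])
  }
  # classic hand-checkable case
  expect_equal(fisherOracle(matrix(c(3, 1, 1, 3), 2)), 0.4857143,
               tolerance = 1e-6)
  # tables that the selection rule actually routes to Fisher
  for (tab in list(matrix(c(1, 1, 1, 50), 2), matrix(c(2, 1, 0, 60), 2),
                   matrix(c(1, 3, 2, 90), 2))) {
    res <- groupComparison(tab)
    expect_equal(res$test, "fisher")
    expect_equal(res$p_value, fisherOracle(tab), tolerance = 1e-12)
  }
})

test_that("plain chi-squared equals the squared two-proportion z statistic", {
  set.seed(12)
  for (i in 1:10) {
    a <- sample(20:80, 2); n <- a + sample(50:150, 2)
    res <- groupComparison(rbind(a, n - a))
    p <- a / n; pp <- sum(a) / sum(n)
    z <- (p[1] - p[2]) / sqrt(pp * (1 - pp) * (1 / n[1] + 1 / n[2]))
    expect_equal(res$statistic, z^2, tolerance = 1e-10)
  }
})
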