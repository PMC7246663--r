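# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# Quick cohort from a list of diagnosis-code vectors.
makeCohort <- function(dx, index = "C220", age = NULL, sex = NULL) {
  n <- length(dx)
  Cohort(sprintf("p%03d", seq_len(n)),
         if (is.null(age)) rep(50L, n) else age,
         if (is.null(sex)) rep("male", n) else sex,
         dx, indexCodes = index)
}

# Toy network from an edge data.frame (unit prevalence attributes).
toyNetwork <- function(edgeDf, codes = NULL, prevalence = 0.5) {
  if (is.null(codes)) codes <- sort(unique(c(edgeDf$from, edgeDf$to)))
  nd <- data.frame(code = codes, label = codes,
                   prevalence = rep_len(prevalence, length(codes)),
                   degree = 0L, stringsAsFactors = FALSE)
  if (!"weight" %in% names(edgeDf)) edgeDf$weight <- 1
  if (!"rr" %in% names(edgeDf)) edgeDf$rr <- 2
  ComorbidNet:::.makeNetwork(nd, edgeDf)
}

# Two 3-cliques joined by one bridge edge (unit weights): the canonical
# hand-evaluable modularity example (m = 7, clique partition Q = 5/14).
twoCliquesBridge <- function() {
  toyNetwork(data.frame(
    from = c("a", "a", "b", "d", "d", "e", "c"),
    to   = c("b", "c", "c", "e", "f", "f", "d")))
}

triangleNetwork <- function() {
  toyNetwork(data.frame(from = c("a", "a", "b"), to = c("b", "c", "c")))
}

# Disjoint union of unit-weight cliques of the given sizes.
disjointCliques <- function(sizes) {
  edgeList <- list()
  off <- 0L
  for (s in sizes) {
    ids <- sprintf("n%02d", off + seq_len(s))
    pr <- t(combn(ids, 2))
    edgeList[[length(edgeList) + 1L]] <-
      data.frame(from = pr[, 1], to = pr[, 2], stringsAsFactors = FALSE)
    off <- off + s
  }
  toyNetwork(do.call(rbind, edgeList))
}

# Erdos-Renyi G(n, p) with unit weights; guarantees at least one edge.
erdosRenyi <- function(n, p, seed) {
  set.seed(seed)
  pr <- t(combn(n, 2))
  sel <- runif(nrow(pr)) < p
  if (!any(sel)) sel[sample.int(length(sel), 1)] <- TRUE
  codes <- sprintf("n%02d", seq_len(n))
  toyNetwork(data.frame(from = codes[pr[sel, 1]], to = codes[pr[sel, 2]],
                        stringsAsFactors = FALSE), codes = codes)
}

# Brute-force per-patient recount oracles (quadratic scan, independent of
# the sparse-matrix implementation path).
bruteForcePrevalence <- function(cohort) {
  dx <- as.list(diagnoses(cohort))
  idx <- indexCodes(cohort)
  codes <- sort(setdiff(unique(unlist(dx)), idx))
  vapply(codes, function(cd)
    sum(vapply(dx, function(v) cd %in% v, NA)), 1L)
}

bruteForcePairCounts <- function(cohort) {
  dx <- as.list(diagnoses(cohort))
  idx <- indexCodes(cohort)
  codes <- sort(setdiff(unique(unlist(dx)), idx))
  out <- list()
  for (i in seq_along(codes)) for (j in seq_len(i - 1L)) {
    a <- codes[j]; b <- codes[i]
    cnt <- sum(vapply(dx, function(v) a %in% v && b %in% v, NA))
    if (cnt > 0) out[[length(out) + 1L]] <-
        data.frame(codeA = a, codeB = b, count = cnt,
                   stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(codeA = character(), codeB = character(),
                  count = integer())
}

# The three-planted-module configuration used for recovery experiments.
recoveryConfig <- function(N = 5000L, pi = 0.3, q1 = 0.8, q0 = 0.05) {
  syntheticConfig(N, modules = list(
    list(codes = sprintf("A%02d", 1:5), pi = pi, q1 = q1, q0 = q0),
    list(codes = sprintf("B%02d", 1:5), pi = pi, q1 = q1, q0 = q0),
    list(codes = sprintf("C%02d", 1:5), pi = pi, q1 = q1, q0 = q0)))
}

# Cohort with hand-set marginal counts (worked-example reproduction of
# printed tables): males first, then females; each disease assigned to the
# first maleCounts[d] males and first femaleCounts[d] females; ages filled
# bin-by-bin independently of sex and disease.
marginCohort <- function(nMale, nFemale, maleCounts, femaleCounts,
                         ageCounts = NULL) {
  N <- nMale + nFemale
  sex <- c(rep("male", nMale), rep("female", nFemale))
  age <- if (is.null(ageCounts)) rep(55L, N)
         else rep(c(30L, 45L, 55L, 65L, 75L), times = ageCounts)
  stopifnot(length(age) == N)
  dx <- rep(list("C220"), N)
  for (d in names(maleCounts)) {
    idx <- c(seq_len(maleCounts[[d]]),
             if (femaleCounts[[d]] > 0) nMale + seq_len(femaleCounts[[d]]))
    for (i in idx) dx[[i]] <- c(dx[[i]], d)
  }
  Cohort(sprintf("p%05d", seq_len(N)), age, sex, dx, indexCodes = "C220")
}

# Cohort with per-age-bin carrier counts for a single disease.
ageMarginCohort <- function(binSizes, carrierCounts, code = "K746") {
  N <- sum(binSizes)
  age <- rep(c(30L, 45L, 55L, 65L, 75L), times = binSizes)
  dx <- rep(list("C220"), N)
  off <- 0L
  for (b in seq_along(binSizes)) {
    for (i in off + seq_len(carrierCounts[b])) dx[[i]] <- c(dx[[i]], code)
    off <- off + binSizes[b]
  }
  Cohort(sprintf("q%05d", seq_len(N)), age, rep("male", N), dx,
         indexCodes = "C220")
}
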