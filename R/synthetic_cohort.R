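# Planted-module synthetic cohort generation with closed-form expected
# statistics, and the adjusted Rand index for partition recovery.

# Age-bin fractions and male fraction of the reference cohort demographics.
.AGE_PROBS_DEFAULT <- c(0.0289, 0.1459, 0.2947, 0.3526, 0.1779)
.MALE_FRACTION_DEFAULT <- 0.7601
# sampling ranges (years) within each age bin
.AGE_RANGES <- list(c(18L, 39L), c(40L, 49L), c(50L, 59L), c(60L, 69L),
                    c(70L, 90L))

#' Build a synthetic cohort configuration
#'
#' See [SyntheticConfig-class] for the generative model. `q1`/`q0` may be
#' scalars (recycled over the module's diseases) or per-disease vectors.
#'
#' @param N cohort size.
#' @param modules list of modules, each a list with `codes`, `pi`, `q1`,
#'   `q0`.
#' @param background named numeric vector of independent carriage rates.
#' @param ageProbs probabilities of the five age bins; defaults to the
#'   reference cohort's fractions (2.89/14.59/29.47/35.26/17.79%).
#' @param maleFraction male fraction; default 0.7601.
#' @param indexCode index-disease code planted in every patient.
#' @return A validated [SyntheticConfig-class].
#' @export
syntheticConfig <- function(N, modules = list(), background = numeric(),
                            ageProbs = .AGE_PROBS_DEFAULT,
                            maleFraction = .MALE_FRACTION_DEFAULT,
                            indexCode = "C220") {
  modules <- lapply(modules, function(m) {
    k <- length(m$codes)
    list(codes = normalizeCodeVector(m$codes),
         pi = as.numeric(m$pi),
         q1 = rep_len(as.numeric(m$q1), k),
         q0 = rep_len(as.numeric(m$q0), k))
  })
  if (length(background)) names(background) <- normalizeCodeVector(names(background))
  new("SyntheticConfig", N = as.integer(N), modules = modules,
      background = background, ageProbs = as.numeric(ageProbs),
      maleFraction = as.numeric(maleFraction),
      indexCode = normalizeCodeVector(indexCode))
}

#' Default study-scale synthetic configuration
#'
#' Emulates the structure of a hepatocellular-carcinoma inpatient cohort:
#' every patient carries the index code C220; five comorbidity modules of
#' 12/10/10/9/6 diseases (liver-cirrhosis complex, cysts/stones/lung,
#' metabolic and gastrointestinal-hemorrhage, chronic cardiovascular,
#' secondary cancers) plus 8 independent background diseases, giving 55
#' comorbid codes with marginal prevalences spanning ~0.2% to ~56%;
#' demographics follow the reference cohort's age-bin fractions and a
#' 76.01% male fraction.
#'
#' @param N cohort size (default 14891).
#' @return A [SyntheticConfig-class].
#' @export
defaultSyntheticConfig <- function(N = 14891L) {
  modules <- list(
    list( # cirrhosis complex
      codes = c("K746", "B181", "K766", "D733", "R18", "K650", "K720",
                "I859", "K762", "B942", "K759", "K768"),
      pi = 0.62,
      q1 = c(0.88, 0.44, 0.17, 0.16, 0.13, 0.10, 0.08, 0.07, 0.06, 0.05,
             0.04, 0.03),
      q0 = c(0.05, 0.02, rep(0.01, 10))),
    list( # cysts, stones, gallbladder, lung
      codes = c("Q446", "N280", "N200", "K802", "K811", "J189", "J449",
                "K819", "N138", "J984"),
      pi = 0.35,
      q1 = c(0.30, 0.26, 0.22, 0.18, 0.15, 0.12, 0.10, 0.08, 0.06, 0.04),
      q0 = rep(0.01, 10)),
    list( # metabolic + gastrointestinal hemorrhage
      codes = c("E778", "E878", "E876", "E871", "K922", "D62", "D649",
                "E872", "K921", "R58"),
      pi = 0.30,
      q1 = c(0.28, 0.24, 0.20, 0.17, 0.14, 0.11, 0.09, 0.07, 0.05, 0.04),
      q0 = rep(0.01, 10)),
    list( # chronic cardiovascular / endocrine
      codes = c("I10", "E119", "I259", "I639", "I509", "E785", "I48",
                "I209", "N189"),
      pi = 0.25,
      q1 = c(0.55, 0.50, 0.18, 0.15, 0.12, 0.10, 0.06, 0.05, 0.04),
      q0 = rep(0.02, 9)),
    list( # cancers
      codes = c("C349", "C859", "C795", "C787", "C169", "D377"),
      pi = 0.12,
      q1 = c(0.50, 0.35, 0.30, 0.20, 0.15, 0.10),
      q0 = rep(0.005, 6))
  )
  background <- c(B182 = 0.105, K297 = 0.040, E039 = 0.015, N390 = 0.012,
                  M545 = 0.009, L299 = 0.006, H269 = 0.004, A049 = 0.002)
  syntheticConfig(N, modules, background)
}

# marginal prevalence of every comorbid disease under the model
#' Expected marginal prevalences under a synthetic configuration
#'
#' For a module disease j in module m, `p_j = pi_m q1_j + (1 - pi_m) q0_j`;
#' for a background disease its rate.
#'
#' @param config a [SyntheticConfig-class].
#' @return Named numeric vector of expected prevalences.
#' @export
expectedPrevalence <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  p <- numeric()
  for (m in config@modules)
    p <- c(p, setNames(m$pi * m$q1 + (1 - m$pi) * m$q0, m$codes))
  c(p, config@background)
}

#' Analytic pairwise relative risk under a synthetic configuration
#'
#' For two diseases in the same module m,
#' `RR = (pi_m q1_j q1_k + (1 - pi_m) q0_j q0_k) / (p_j p_k)`; diseases in
#' different modules (or involving background diseases) have independent
#' activations, so `RR = 1` exactly.
#'
#' @param config a [SyntheticConfig-class].
#' @param codeJ,codeK two distinct disease codes from the configuration.
#' @return The expected relative risk.
#' @export
expectedPairRR <- function(config, codeJ, codeK) {
  stopifnot(is(config, "SyntheticConfig"))
  codeJ <- normalizeCodeVector(codeJ)
  codeK <- normalizeCodeVector(codeK)
  if (codeJ == codeK) stop("codes must differ", call. = FALSE)
  find <- function(code) {
    for (mi in seq_along(config@modules))
      if (code %in% config@modules[[mi]]$codes) return(mi)
    if (code %in% names(config@background)) return(0L)
    stop("unknown disease code: ", code, call. = FALSE)
  }
  mj <- find(codeJ); mk <- find(codeK)
  if (mj == 0L || mk == 0L || mj != mk) return(1)
  mod <- config@modules[[mj]]
  j <- match(codeJ, mod$codes); k <- match(codeK, mod$codes)
  pj <- mod$pi * mod$q1[j] + (1 - mod$pi) * mod$q0[j]
  pk <- mod$pi * mod$q1[k] + (1 - mod$pi) * mod$q0[k]
  (mod$pi * mod$q1[j] * mod$q1[k] + (1 - mod$pi) * mod$q0[j] * mod$q0[k]) /
    (pj * pk)
}

#' Generate a synthetic cohort with planted comorbidity modules
#'
#' Samples, per patient: an age bin and sex from the configured
#' demographics (independent of disease status); a module activation
#' `z_m ~ Bernoulli(pi_m)` per module; each module disease with probability
#' `q1` if its module is active, else `q0`; each background disease
#' independently. Every patient carries the index code. Patients exceeding
#' the 15 secondary-diagnosis slots have their lowest-marginal-rate codes
#' truncated (count reported via a message and the `truncated` attribute).
#' The same config and seed reproduce the cohort exactly.
#'
#' @param config a [SyntheticConfig-class].
#' @param seed integer RNG seed.
#' @return list with elements `cohort` (a [Cohort-class], index codes set),
#'   `moduleOf` (named integer: disease code -> module index, 0 for
#'   background) and `activations` (N x nModules logical matrix).
#' @export
generateCohort <- function(config, seed = 1L) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  N <- config@N
  p <- expectedPrevalence(config)
  moduleOf <- integer(length(p))
  names(moduleOf) <- names(p)
  i0 <- 0L
  for (mi in seq_along(config@modules)) {
    k <- length(config@modules[[mi]]$codes)
    moduleOf[i0 + seq_len(k)] <- mi
    i0 <- i0 + k
  }
  withSeed(seed, {
    bin <- sample.int(5L, N, replace = TRUE, prob = config@ageProbs)
    age <- vapply(bin, function(b) {
      r <- .AGE_RANGES[[b]]
      sample(r[1]:r[2], 1L)
    }, 1L)
    sex <- ifelse(runif(N) < config@maleFraction, "male", "female")
    M <- length(config@modules)
    Z <- matrix(FALSE, N, M)
    X <- matrix(FALSE, N, length(p),
                dimnames = list(NULL, names(p)))
    col <- 0L
    for (mi in seq_len(M)) {
      mod <- config@modules[[mi]]
      Z[, mi] <- runif(N) < mod$pi
      for (j in seq_along(mod$codes)) {
        col <- col + 1L
        pr <- ifelse(Z[, mi], mod$q1[j], mod$q0[j])
        X[, col] <- runif(N) < pr
      }
    }
    for (j in seq_along(config@background)) {
      col <- col + 1L
      X[, col] <- runif(N) < config@background[j]
    }
  })
  # order columns by marginal rate (desc) so truncation drops the rarest
  ordCols <- order(-p, names(p))
  X <- X[, ordCols, drop = FALSE]
  codes <- colnames(X)
  hits <- which(X, arr.ind = TRUE)
  lst <- split(codes[hits[, 2]], hits[, 1])
  dx <- rep(list(character(0)), N)
  dx[as.integer(names(lst))] <- lst
  len <- lengths(dx)
  nTrunc <- sum(len > 15L)
  if (nTrunc > 0) {
    dx[len > 15L] <- lapply(dx[len > 15L], function(v) v[1:15])
    message("truncated ", nTrunc,
            " patient(s) to the 15 secondary-diagnosis slot limit")
  }
  dx <- lapply(dx, function(v) c(config@indexCode, v))
  ids <- sprintf(paste0("P%0", nchar(as.character(N)), "d"), seq_len(N))
  cohort <- Cohort(ids, age, sex, dx, indexCodes = config@indexCode)
  out <- list(cohort = cohort, moduleOf = moduleOf, activations = Z)
  attr(out, "truncated") <- nTrunc
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions (up
#' to relabelling), approximately 0 for independent ones. Partitions may be
#' named vectors over the same element set (aligned by name) or unnamed
#' vectors of equal length.
#'
#' @param a,b partition label vectors.
#' @return ARI in \[-1, 1\].
#' @export
adjustedRandIndex <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("partitions cover different element sets", call. = FALSE)
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("partitions cover different element sets", call. = FALSE)
  }
  ct <- table(a, b)
  nij <- sum(choose(ct, 2))
  ai <- sum(choose(rowSums(ct), 2))
  bj <- sum(choose(colSums(ct), 2))
  n2 <- choose(sum(ct), 2)
  expected <- ai * bj / n2
  maxidx <- (ai + bj) / 2
  if (abs(maxidx - expected) < .Machine$double.eps * 100) return(1)
  (nij - expected) / (maxidx - expected)
}
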