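#' @importClassesFrom IRanges CharacterList
NULL

#' Cohort of patient diagnosis records
#'
#' An S4 container for one cohort: per-patient demographics plus the
#' de-duplicated collection of normalized ICD-10 diagnosis codes, and the
#' code set defining the index disease (the condition every cohort member
#' carries once the cohort has been index-filtered). Codes are stored
#' uppercased, whitespace-stripped and dot-free ("C22.0" is held as "C220").
#'
#' @slot patientId character, unique opaque patient identifiers.
#' @slot age integer, age in completed years (>= 0).
#' @slot sex character, "male" or "female".
#' @slot diagnoses [IRanges::CharacterList] of unique normalized codes, one
#'   element per patient, each non-empty.
#' @slot indexCodes character, normalized codes defining the index disease
#'   (may be empty before [filterIndexCohort()] is applied).
#'
#' @seealso [Cohort()], [readRecords()], [filterIndexCohort()],
#'   [stratifyCohort()]
#' @aliases Cohort-class
#' @exportClass Cohort
setClass("Cohort",
  slots = c(
    patientId  = "character",
    age        = "integer",
    sex        = "character",
    diagnoses  = "CharacterList",
    indexCodes = "character"
  )
)

setValidity("Cohort", function(object) {
  n <- length(object@patientId)
  msg <- character()
  if (length(object@age) != n || length(object@sex) != n ||
      length(object@diagnoses) != n)
    msg <- c(msg, "patientId, age, sex and diagnoses must have equal length")
  if (anyDuplicated(object@patientId))
    msg <- c(msg, "patient_id values must be unique within a cohort")
  if (n > 0) {
    if (anyNA(object@age) || any(object@age < 0))
      msg <- c(msg, "age must be a non-negative integer for every patient")
    if (!all(object@sex %in% c("male", "female")))
      msg <- c(msg, "sex must be 'male' or 'female' for every patient")
    len <- elementNROWS(object@diagnoses)
    if (any(len == 0))
      msg <- c(msg, "every patient must carry at least one diagnosis code")
    codes <- unlist(object@diagnoses, use.names = FALSE)
    if (length(codes) &&
        anyDuplicated(paste(rep.int(seq_len(n), len), codes)))
      msg <- c(msg, "diagnosis codes must be unique within a patient")
  }
  if (length(msg)) msg else TRUE
})

#' Weighted undirected comorbidity network
#'
#' Diseases passing a prevalence threshold are nodes; disease pairs whose
#' relative risk exceeds a threshold are edges, weighted by the raw
#' co-occurrence count and annotated with the relative risk. Nodes that pass
#' the prevalence filter but gain no edge are retained as isolates.
#'
#' @slot nodes data.frame with columns `code`, `label`, `prevalence`,
#'   `degree` (one row per retained disease).
#' @slot edges data.frame with columns `from`, `to`, `weight`, `rr`;
#'   `from < to` lexicographically, no self loops, no parallel edges.
#'
#' @seealso [buildNetwork()], [exportNetwork()], [louvain()]
#' @aliases ComorbidityNetwork-class
#' @exportClass ComorbidityNetwork
setClass("ComorbidityNetwork",
  slots = c(nodes = "data.frame", edges = "data.frame")
)

setValidity("ComorbidityNetwork", function(object) {
  msg <- character()
  needN <- c("code", "label", "prevalence", "degree")
  needE <- c("from", "to", "weight", "rr")
  if (!all(needN %in% names(object@nodes)))
    msg <- c(msg, paste("nodes must have columns:", paste(needN, collapse = ", ")))
  if (!all(needE %in% names(object@edges)))
    msg <- c(msg, paste("edges must have columns:", paste(needE, collapse = ", ")))
  if (!length(msg)) {
    if (anyDuplicated(object@nodes$code))
      msg <- c(msg, "duplicate node codes")
    if (nrow(object@edges)) {
      if (!all(object@edges$from %in% object@nodes$code) ||
          !all(object@edges$to %in% object@nodes$code))
        msg <- c(msg, "every edge must join two retained nodes")
      if (any(object@edges$from == object@edges$to))
        msg <- c(msg, "self loops are not allowed")
      if (any(object@edges$from > object@edges$to))
        msg <- c(msg, "edges must be stored with from < to")
      if (anyDuplicated(paste(object@edges$from, object@edges$to)))
        msg <- c(msg, "parallel edges are not allowed")
      if (any(object@edges$weight <= 0))
        msg <- c(msg, "edge weights must be positive")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Community partition of a comorbidity network
#'
#' Assignment of every network node to exactly one community, together with
#' the weighted modularity of the assignment, the resolution parameter and
#' the RNG seed that produced it. Community ids are contiguous integers
#' starting at 0, relabelled in order of first appearance over the node
#' order.
#'
#' @slot membership named integer vector, node code -> community id.
#' @slot modularity numeric, modularity Q of the assignment.
#' @slot gamma numeric, resolution parameter used.
#' @slot seed integer, RNG seed used (NA for deterministic optimizers).
#' @slot converged logical, FALSE if the optimizer hit its pass limit.
#'
#' @seealso [louvain()], [bruteForceBestPartition()], [modularityScore()]
#' @aliases CommunityPartition-class
#' @exportClass CommunityPartition
setClass("CommunityPartition",
  slots = c(
    membership = "integer",
    modularity = "numeric",
    gamma      = "numeric",
    seed       = "integer",
    converged  = "logical"
  )
)

setValidity("CommunityPartition", function(object) {
  msg <- character()
  if (is.null(names(object@membership)))
    msg <- c(msg, "membership must be named by node code")
  ids <- sort(unique(object@membership))
  if (length(ids) && !identical(ids, seq_len(length(ids)) - 1L))
    msg <- c(msg, "community ids must be contiguous integers starting at 0")
  if (length(msg)) msg else TRUE
})

#' Configuration of the planted-module synthetic cohort generator
#'
#' Describes a generative model for index-disease cohorts: every patient
#' carries the index code; each comorbidity module m is switched on per
#' patient with probability pi_m, and a module disease j is then carried
#' with probability q1_j (module active) or q0_j (inactive, q1_j > q0_j);
#' background diseases are independent Bernoulli draws. Demographics are
#' sampled independently of disease status.
#'
#' @slot N integer, cohort size.
#' @slot modules list; each element a list with `codes` (character), `pi`
#'   (scalar activation probability) and per-disease vectors `q1`, `q0`.
#' @slot background named numeric, independent carriage rate per background
#'   disease code.
#' @slot ageProbs numeric(5), probabilities of the five age bins
#'   (<=39, 40-49, 50-59, 60-69, >=70).
#' @slot maleFraction numeric scalar in \[0, 1\].
#' @slot indexCode character(1), index-disease code planted in every patient.
#'
#' @seealso [syntheticConfig()], [defaultSyntheticConfig()],
#'   [generateCohort()], [expectedPairRR()]
#' @aliases SyntheticConfig-class
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  slots = c(
    N            = "integer",
    modules      = "list",
    background   = "numeric",
    ageProbs     = "numeric",
    maleFraction = "numeric",
    indexCode    = "character"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (length(object@N) != 1L || is.na(object@N) || object@N < 1L)
    msg <- c(msg, "N must be a positive integer")
  prOK <- function(p) all(!is.na(p) & p >= 0 & p <= 1)
  allCodes <- character()
  for (m in object@modules) {
    if (!all(c("codes", "pi", "q1", "q0") %in% names(m))) {
      msg <- c(msg, "each module needs fields codes, pi, q1, q0")
      next
    }
    k <- length(m$codes)
    if (length(m$q1) != k || length(m$q0) != k)
      msg <- c(msg, "q1 and q0 must have one entry per module disease")
    else if (!prOK(m$pi) || !prOK(m$q1) || !prOK(m$q0))
      msg <- c(msg, "module probabilities must lie in [0, 1]")
    else if (any(m$q1 <= m$q0))
      msg <- c(msg, "q1 must exceed q0 for every module disease")
    allCodes <- c(allCodes, m$codes)
  }
  if (!prOK(object@background))
    msg <- c(msg, "background rates must lie in [0, 1]")
  allCodes <- c(allCodes, names(object@background))
  if (anyDuplicated(allCodes))
    msg <- c(msg, "disease codes must be unique across modules and background")
  if (object@indexCode %in% allCodes)
    msg <- c(msg, "the index code cannot also be a comorbidity")
  if (length(object@ageProbs) != 5L || !prOK(object@ageProbs) ||
      abs(sum(object@ageProbs) - 1) > 1e-8)
    msg <- c(msg, "ageProbs must be 5 probabilities summing to 1")
  if (!prOK(object@maleFraction))
    msg <- c(msg, "maleFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
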