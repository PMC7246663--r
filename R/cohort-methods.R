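#' Construct a Cohort
#'
#' Builds a [Cohort-class] from parallel per-patient vectors. Diagnosis codes
#' are normalized (uppercase, whitespace stripped, dots removed) and
#' de-duplicated within each patient, preserving first-appearance order.
#'
#' @param patientId character vector of unique patient identifiers.
#' @param age integer vector of ages in years.
#' @param sex character vector, `"male"` or `"female"` (case-insensitive).
#' @param diagnoses list (or [IRanges::CharacterList]) of diagnosis code
#'   vectors, one element per patient.
#' @param indexCodes codes defining the index disease; may be empty.
#' @return A validated [Cohort-class] object.
#' @examples
#' co <- Cohort("p1", 57L, "male", list(c("C22.0", "K74.6")))
#' diagnoses(co)[[1]]  # "C220" "K746"
#' @export
Cohort <- function(patientId, age, sex, diagnoses, indexCodes = character()) {
  dx <- unname(lapply(diagnoses, function(v) unique(normalizeCodeVector(v))))
  obj <- new("Cohort",
    patientId  = as.character(patientId),
    age        = as.integer(age),
    sex        = tolower(as.character(sex)),
    diagnoses  = CharacterList(dx),
    indexCodes = unique(normalizeCodeVector(indexCodes))
  )
  obj
}

#' Accessors for Cohort objects
#'
#' @param x A [Cohort-class] object.
#' @param i index vector for subsetting.
#' @param j,...,drop ignored.
#' @return `patientIds()`, `sexes()` character; `ages()` integer;
#'   `diagnoses()` a [IRanges::CharacterList]; `indexCodes()` character;
#'   `length()` the number of patients; `[` a sub-`Cohort`.
#' @name Cohort-accessors
#' @aliases patientIds ages sexes diagnoses indexCodes
NULL

#' @rdname Cohort-accessors
#' @export
setMethod("patientIds", "Cohort", function(x) x@patientId)

#' @rdname Cohort-accessors
#' @export
setMethod("ages", "Cohort", function(x) x@age)

#' @rdname Cohort-accessors
#' @export
setMethod("sexes", "Cohort", function(x) x@sex)

#' @rdname Cohort-accessors
#' @export
setMethod("diagnoses", "Cohort", function(x) x@diagnoses)

#' @rdname Cohort-accessors
#' @export
setMethod("indexCodes", "Cohort", function(x) x@indexCodes)

#' @rdname Cohort-accessors
#' @export
setMethod("length", "Cohort", function(x) length(x@patientId))

#' @rdname Cohort-accessors
#' @export
setMethod("[", "Cohort", function(x, i, j, ..., drop = FALSE) {
  new("Cohort",
    patientId  = x@patientId[i],
    age        = x@age[i],
    sex        = x@sex[i],
    diagnoses  = x@diagnoses[i],
    indexCodes = x@indexCodes
  )
})

setMethod("show", "Cohort", function(object) {
  cat("Cohort with", length(object), "patients\n")
  if (length(object@indexCodes))
    cat("  index codes:", paste(object@indexCodes, collapse = ", "), "\n")
  if (length(object)) {
    k <- elementNROWS(object@diagnoses)
    cat(sprintf("  diagnoses per patient: median %g (range %d-%d)\n",
                stats::median(k), min(k), max(k)))
    cat(sprintf("  male fraction: %.3f; age range %d-%d\n",
                mean(object@sex == "male"), min(object@age), max(object@age)))
  }
  invisible(NULL)
})
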