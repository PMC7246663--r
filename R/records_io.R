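# Reading, writing, normalizing and stratifying patient diagnosis records.

AGE_BIN_LABELS <- c("<=39", "40-49", "50-59", "60-69", ">=70")

#' Assign ages to the five standard age bins
#'
#' Bins are `<=39`, `40-49`, `50-59`, `60-69`, `>=70`.
#'
#' @param age integer vector of ages in years.
#' @return factor with the five bin levels.
#' @examples
#' ageBin(c(39, 40, 69, 70))
#' @export
ageBin <- function(age) {
  cut(as.integer(age), breaks = c(-Inf, 39, 49, 59, 69, Inf),
      labels = AGE_BIN_LABELS)
}

.readDelim <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.table(path, header = TRUE, sep = sep, quote = "\"",
             colClasses = "character", check.names = FALSE,
             stringsAsFactors = FALSE, fileEncoding = "UTF-8",
             na.strings = NULL, comment.char = "")
}

.requireColumns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("format error in '", path, "': missing mandatory column(s) ",
         paste0("'", miss, "'", collapse = ", "), call. = FALSE)
}

.parseDemographics <- function(pid, ageRaw, sexRaw) {
  age <- suppressWarnings(as.integer(ageRaw))
  badAge <- unique(pid[is.na(age) | age < 0])
  sex <- tolower(trimws(sexRaw))
  badSex <- unique(pid[!sex %in% c("male", "female")])
  if (length(badAge) || length(badSex)) {
    parts <- character()
    if (length(badAge))
      parts <- c(parts, paste0("unparseable age for patient_id(s): ",
                               paste(badAge, collapse = ", ")))
    if (length(badSex))
      parts <- c(parts, paste0("invalid sex for patient_id(s): ",
                               paste(badSex, collapse = ", ")))
    stop(paste(parts, collapse = "; "), call. = FALSE)
  }
  list(age = age, sex = sex)
}

#' Read patient diagnosis records from delimited text
#'
#' Two layouts are supported. `long`: one row per diagnosis with columns
#' `patient_id, age, sex, dx_rank, icd10`; all rows of a patient are merged
#' into one record (conflicting age or sex across rows is an error).
#' `wide`: one row per patient with columns `patient_id, age, sex,
#' dx_primary, dx_sec_1 .. dx_sec_15` (secondary columns optional, empty
#' cells allowed) — one primary plus up to 15 secondary diagnosis slots.
#' Codes are uppercased, whitespace-stripped and dot-stripped, then
#' de-duplicated per patient.
#'
#' @param path path to a UTF-8 delimited text file with a header row.
#' @param layout `"long"` or `"wide"`.
#' @param sep field delimiter; comma by default, tab accepted.
#' @return A [Cohort-class] (with no index codes set yet).
#' @seealso [writeRecords()], [filterIndexCohort()]
#' @export
readRecords <- function(path, layout = c("long", "wide"), sep = ",") {
  layout <- match.arg(layout)
  df <- .readDelim(path, sep)
  if (layout == "long") {
    .requireColumns(df, c("patient_id", "age", "sex", "dx_rank", "icd10"), path)
    if (nrow(df) == 0)
      return(Cohort(character(), integer(), character(), list()))
    key <- paste(df$patient_id, df$dx_rank, sep = "\r")
    if (anyDuplicated(key)) {
      bad <- unique(df$patient_id[duplicated(key)])
      stop("format error in '", path, "': duplicate (patient_id, dx_rank) for ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    ord <- order(match(df$patient_id, unique(df$patient_id)),
                 suppressWarnings(as.integer(df$dx_rank)))
    df <- df[ord, , drop = FALSE]
    first <- !duplicated(df$patient_id)
    dem <- .parseDemographics(df$patient_id, df$age, df$sex)
    # one demographic tuple per patient: conflicting rows are an error
    conflict <- unique(df$patient_id[stats::ave(
      paste(dem$age, dem$sex), df$patient_id,
      FUN = function(v) length(unique(v))) > 1])
    if (length(conflict))
      stop("conflicting age/sex across rows for patient_id(s): ",
           paste(conflict, collapse = ", "), call. = FALSE)
    pid <- df$patient_id[first]
    dx <- split(df$icd10, factor(df$patient_id, levels = pid))
    Cohort(pid, dem$age[first], dem$sex[first], dx)
  } else {
    .requireColumns(df, c("patient_id", "age", "sex", "dx_primary"), path)
    if (anyDuplicated(df$patient_id))
      stop("format error in '", path, "': duplicate patient_id in wide layout",
           call. = FALSE)
    if (nrow(df) == 0)
      return(Cohort(character(), integer(), character(), list()))
    dem <- .parseDemographics(df$patient_id, df$age, df$sex)
    secCols <- paste0("dx_sec_", 1:15)
    secCols <- secCols[secCols %in% names(df)]
    dxm <- as.matrix(df[, c("dx_primary", secCols), drop = FALSE])
    dx <- lapply(seq_len(nrow(dxm)), function(i) {
      v <- trimws(dxm[i, ])
      v[!is.na(v) & nzchar(v)]
    })
    if (any(vapply(dx, length, 1L) == 0))
      stop("record-level error: empty dx_primary for patient_id(s): ",
           paste(df$patient_id[vapply(dx, length, 1L) == 0], collapse = ", "),
           call. = FALSE)
    Cohort(df$patient_id, dem$age, dem$sex, dx)
  }
}

#' Write a cohort back to delimited text
#'
#' Inverse of [readRecords()]: `long` emits one row per diagnosis with
#' `dx_rank` numbering codes in stored order; `wide` emits one row per
#' patient (error if any patient exceeds the 16 diagnosis slots). Writing is
#' deterministic, so write-read-write round trips are byte-identical.
#'
#' @param cohort a [Cohort-class].
#' @param path output file path.
#' @inheritParams readRecords
#' @return `path`, invisibly.
#' @export
writeRecords <- function(cohort, path, layout = c("long", "wide"), sep = ",") {
  layout <- match.arg(layout)
  stopifnot(is(cohort, "Cohort"))
  len <- elementNROWS(cohort@diagnoses)
  if (layout == "long") {
    df <- data.frame(
      patient_id = rep.int(cohort@patientId, len),
      age = rep.int(cohort@age, len),
      sex = rep.int(cohort@sex, len),
      dx_rank = unlist(lapply(len, seq_len), use.names = FALSE),
      icd10 = unlist(cohort@diagnoses, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  } else {
    if (any(len > 16))
      stop("wide layout supports at most 16 diagnosis slots; patient(s) ",
           paste(cohort@patientId[len > 16], collapse = ", "), " exceed it",
           call. = FALSE)
    m <- matrix("", nrow = length(cohort), ncol = 16)
    dx <- as.list(cohort@diagnoses)
    for (i in seq_along(dx)) m[i, seq_along(dx[[i]])] <- dx[[i]]
    df <- data.frame(
      patient_id = cohort@patientId, age = cohort@age, sex = cohort@sex,
      dx_primary = m[, 1], stringsAsFactors = FALSE
    )
    for (j in 1:15) df[[paste0("dx_sec_", j)]] <- m[, j + 1]
  }
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Restrict a cohort to carriers of the index disease
#'
#' Retains exactly the patients whose diagnosis collection intersects
#' `codes`; the retained cohort records those codes as its index-disease
#' definition. Matching is exact on normalized codes ("C220" does not match
#' "C221"; use [normalizeCodes()] first for a 3-character rollup).
#'
#' @param cohort a [Cohort-class].
#' @param codes non-empty character vector of index codes (default: the
#'   hepatocellular-carcinoma code "C220").
#' @return The filtered [Cohort-class]; empty result yields a warning, not
#'   an error.
#' @export
filterIndexCohort <- function(cohort, codes = "C220") {
  stopifnot(is(cohort, "Cohort"))
  codes <- unique(normalizeCodeVector(codes))
  if (!length(codes)) stop("index code set must be non-empty", call. = FALSE)
  hit <- countCodeHits(cohort, codes) > 0
  out <- cohort[hit]
  out@indexCodes <- codes
  if (length(out) == 0)
    warning("index cohort is empty for codes: ",
            paste(codes, collapse = ", "), call. = FALSE)
  out
}

#' Roll diagnosis codes up to a coding level
#'
#' `level = "category3"` truncates every code (including the index codes) to
#' its first three characters and re-de-duplicates per patient; `"full"` is
#' the identity. Truncation never increases a patient's diagnosis count and
#' is idempotent.
#'
#' @param cohort a [Cohort-class].
#' @param level `"full"` or `"category3"`.
#' @return The re-coded [Cohort-class].
#' @export
normalizeCodes <- function(cohort, level = c("full", "category3")) {
  level <- match.arg(level)
  stopifnot(is(cohort, "Cohort"))
  if (level == "full") return(cohort)
  dx <- lapply(as.list(cohort@diagnoses),
               function(v) unique(substr(v, 1L, 3L)))
  cohort@diagnoses <- CharacterList(dx)
  cohort@indexCodes <- unique(substr(cohort@indexCodes, 1L, 3L))
  validObject(cohort)
  cohort
}

#' Split a cohort into demographic strata
#'
#' Partitions the cohort by sex, age bin (five fixed bins, see [ageBin()]),
#' or their cross. Strata are disjoint, order-preserving, and their sizes
#' sum to the parent cohort size; empty strata are dropped.
#'
#' @param cohort a [Cohort-class].
#' @param by `"sex"`, `"age_bin"` or `"sex_x_age_bin"`.
#' @return Named list of [Cohort-class] objects; names carry the stratum
#'   definition (e.g. `"male"`, `"60-69"`, `"male:60-69"`).
#' @export
stratifyCohort <- function(cohort, by = c("sex", "age_bin", "sex_x_age_bin")) {
  by <- match.arg(by)
  stopifnot(is(cohort, "Cohort"))
  sexF <- factor(cohort@sex, levels = c("male", "female"))
  binF <- ageBin(cohort@age)
  lab <- switch(by,
    sex = sexF,
    age_bin = binF,
    sex_x_age_bin = factor(paste(sexF, binF, sep = ":"),
                           levels = as.vector(t(outer(levels(sexF),
                                                      levels(binF),
                                                      paste, sep = ":"))))
  )
  idx <- split(seq_len(length(cohort)), lab, drop = FALSE)
  idx <- idx[vapply(idx, length, 1L) > 0]
  lapply(idx, function(i) cohort[i])
}
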