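# Reading, writing, normalizing and stratifying diagnosis records.

writeTempCsv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

test_that("long layout merges a patient's rows and normalizes codes", {
  f <- writeTempCsv(c(
    "patient_id,age,sex,dx_rank,icd10",
    "p1,57,male,1,C220",
    "p1,57,male,2, k74.6",
    "p1,57,male,3,B18.1"))
  co <- readRecords(f, "long")
  expect_s4_class(co, "Cohort")
  expect_equal(length(co), 1L)
  expect_equal(as.character(diagnoses(co)[[1]]), c("C220", "K746", "B181"))
  expect_equal(ages(co), 57L)
})

test_that("wide layout accepts all 16 diagnosis slots and empty cells", {
  row16 <- paste(c("p1,45,female,C220", paste0("D", 1:15)), collapse = ",")
  row2 <- paste(c("p2,61,male,C220,K74", rep("", 14)), collapse = ",")
  f <- writeTempCsv(c(
    paste(c("patient_id,age,sex,dx_primary",
            paste0("dx_sec_", 1:15)), collapse = ","),
    row16, row2))
  co <- readRecords(f, "wide")
  expect_equal(length(co), 2L)
  expect_equal(lengths(as.list(diagnoses(co))), c(16L, 2L))
})

test_that("write-read round trip preserves a synthetic cohort and is idempotent", {
  gen <- generateCohort(recoveryConfig(N = 20L), seed = 11)
  co <- gen$cohort
  for (layout in c("long", "wide")) {
    f1 <- tempfile(fileext = ".csv")
    writeRecords(co, f1, layout)
    co2 <- readRecords(f1, layout)
    expect_equal(patientIds(co2), patientIds(co))
    expect_equal(ages(co2), ages(co))
    expect_equal(sexes(co2), sexes(co))
    expect_identical(as.list(diagnoses(co2)), as.list(diagnoses(co)))
    f2 <- tempfile(fileext = ".csv")
    writeRecords(co2, f2, layout)
    expect_identical(readLines(f1), readLines(f2))
  }
})

test_that("malformed inputs fail with informative format errors", {
  # missing mandatory column, named
  f <- writeTempCsv(c("patient_id,age,sex,icd10", "p1,50,male,C220"))
  expect_error(readRecords(f, "long"), "dx_rank")
  # unparseable age / sex name the offending patients
  f <- writeTempCsv(c("patient_id,age,sex,dx_rank,icd10",
                      "p9,fifty,male,1,C220"))
  expect_error(readRecords(f, "long"), "p9")
  f <- writeTempCsv(c("patient_id,age,sex,dx_rank,icd10",
                      "p7,50,unknown,1,C220"))
  expect_error(readRecords(f, "long"), "p7")
  # duplicate (patient_id, dx_rank)
  f <- writeTempCsv(c("patient_id,age,sex,dx_rank,icd10",
                      "p1,50,male,1,C220", "p1,50,male,1,K74"))
  expect_error(readRecords(f, "long"), "dx_rank")
  # conflicting demographics across a patient's rows
  f <- writeTempCsv(c("patient_id,age,sex,dx_rank,icd10",
                      "p1,50,male,1,C220", "p1,51,male,2,K74"))
  expect_error(readRecords(f, "long"), "conflicting")
})

test_that("index filtering keeps exactly the carriers, by exact code", {
  co <- makeCohort(list(c("C220", "K74"), c("C220"), c("K74"),
                        c("C221"), c("C220", "B18")), index = character())
  out <- filterIndexCohort(co, "C220")
  expect_equal(length(out), 3L)                  # C221 is not C220
  expect_equal(indexCodes(out), "C220")
  expect_warning(filterIndexCohort(co, "Z999"), "empty")
  # the generator plants the index code in every patient
  gen <- generateCohort(recoveryConfig(N = 200L), seed = 2)
  expect_equal(length(filterIndexCohort(gen$cohort, "C220")), 200L)
})

test_that("category3 rollup truncates, dedupes, and is idempotent", {
  co <- makeCohort(list(c("C220", "K746", "K740"), c("B181", "B182")),
                   index = "C220")
  c3 <- normalizeCodes(co, "category3")
  expect_equal(as.character(diagnoses(c3)[[1]]), c("C22", "K74"))
  expect_equal(as.character(diagnoses(c3)[[2]]), c("B18"))
  expect_equal(indexCodes(c3), "C22")
  expect_identical(as.list(diagnoses(normalizeCodes(c3, "category3"))),
                   as.list(diagnoses(c3)))
  expect_identical(as.list(diagnoses(normalizeCodes(co, "full"))),
                   as.list(diagnoses(co)))
  # truncation never increases a patient's diagnosis count
  set.seed(5)
  for (i in 1:20) {
    dx <- replicate(5, unique(paste0(
      sample(LETTERS[1:4], 8, TRUE),
      sample(10:99, 8, TRUE), sample(0:9, 8, TRUE))), simplify = FALSE)
    co <- makeCohort(dx, index = character())
    expect_true(all(lengths(as.list(diagnoses(normalizeCodes(co, "category3"))))
                    <= lengths(as.list(diagnoses(co)))))
  }
})

test_that("age bins follow the five fixed boundaries", {
  expect_equal(as.character(ageBin(c(39, 40, 69, 70, 35, 62))),
               c("<=39", "40-49", "60-69", ">=70", "<=39", "60-69"))
})

test_that("stratification partitions the cohort", {
  co <- makeCohort(list("C220", "C220", "C220"),
                   age = c(35L, 45L, 62L),
                   sex = c("male", "female", "male"))
  byAge <- stratifyCohort(co, "age_bin")
  expect_equal(names(byAge), c("<=39", "40-49", "60-69"))
  expect_equal(unname(vapply(byAge, length, 1L)), c(1L, 1L, 1L))
  gen <- generateCohort(defaultSyntheticConfig(500L), seed = 9)
  for (by in c("sex", "age_bin", "sex_x_age_bin")) {
    strata <- stratifyCohort(gen$cohort, by)
    ids <- unlist(lapply(strata, patientIds))
    expect_equal(sum(vapply(strata, length, 1L)), length(gen$cohort))
    expect_false(anyDuplicated(ids) > 0)        # disjoint
    expect_setequal(ids, patientIds(gen$cohort))  # exhaustive
  }
  expect_lte(length(stratifyCohort(gen$cohort, "sex_x_age_bin")), 10L)
  # order-preserving within strata
  males <- stratifyCohort(gen$cohort, "sex")$male
  expect_false(is.unsorted(match(patientIds(males),
                                 patientIds(gen$cohort))))
})
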