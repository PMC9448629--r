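test_that("items validate, normalize and round-trip their role", {
  expect_equal(tcm_item(c("Easy  Fatigue", " pale face "), "symptom"),
               c("symptom:easy fatigue", "symptom:pale face"))
  expect_equal(tcm_item("pdc", "constitution"), "constitution:PDC")
  expect_equal(item_role("constitution:PDC"), "constitution")
  expect_equal(item_token("symptom:easy fatigue"), "easy fatigue")
  expect_error(tcm_item("  ", "symptom"), "empty token")
  expect_error(tcm_item("a|b", "symptom"), "must not contain")
  expect_error(tcm_item("XXX", "constitution"), "unknown constitution")
})

test_that("medical_record enforces its invariants", {
  r <- medical_record("r1", c("fatigue", "fatigue", "Pale  Face"), "qdc",
                      secondary_constitutions = "BC")
  expect_s3_class(r, "tcm_record")
  expect_equal(r$symptoms, c("fatigue", "pale face"))  # deduplicated
  expect_equal(r$primary_constitution, "QDC")
  expect_error(
    medical_record("r2", "fatigue", "QDC", secondary_constitutions = "QDC"),
    "must not appear in secondary")
  expect_error(medical_record("", "fatigue", "QDC"), "record_id")
  expect_error(medical_record("r3", "fatigue", "NOPE"),
               "unknown constitution")
})

test_that("empty and single-line corpora read correctly", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), path)
  expect_length(read_records(path), 0)
  writeLines(
    '{"record_id":"r1","symptoms":["fatigue"],"primary_constitution":"QDC"}',
    path)
  recs <- read_records(path)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$symptoms, "fatigue")
  expect_equal(recs[[1]]$primary_constitution, "QDC")
})

test_that("write -> read round-trip is the identity in both formats", {
  recs <- list(
    medical_record("r1", c("fatigue", "pale face"), "QDC",
                   secondary_constitutions = "BC",
                   regimen = c("warm diet", "qihai massage"),
                   diseases = "hypertension", drugs = "licorice root"),
    medical_record("r2", character(0), "PDC"),
    medical_record("r3", "red tongue", "YIDC", regimen = "cooling food")
  )
  for (fmt in c("jsonl", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_records(recs, path, fmt)
    back <- read_records(path, fmt)
    expect_equal(back, recs, info = fmt)
  }
})

test_that("reader errors name the offending line and label", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"record_id":"r1","symptoms":["a"],"primary_constitution":"QDC"}',
    '{"record_id":"r2","symptoms":["b"],"primary_constitution":"BAD"}'),
    path)
  expect_error(read_records(path), "line 2.*unknown constitution")
  writeLines(c(
    '{"record_id":"r1","symptoms":["a"],"primary_constitution":"QDC"}',
    '{not json'), path)
  expect_error(read_records(path), "line 2")
  writeLines(rep(
    '{"record_id":"dup","symptoms":["a"],"primary_constitution":"QDC"}', 2),
    path)
  expect_error(read_records(path), "duplicate record_id")
})

test_that("to_transactions applies the stated projections", {
  rec <- medical_record("r1", c("s1", "s2"), "PDC", regimen = "r1tok",
                        diseases = "d1", drugs = "g1")
  expect_setequal(to_transactions(list(rec), "symptom_constitution")[[1]],
                  c("symptom:s1", "symptom:s2", "constitution:PDC"))
  expect_setequal(to_transactions(list(rec), "constitution_regimen")[[1]],
                  c("constitution:PDC", "regimen:r1tok"))
  expect_setequal(to_transactions(list(rec), "full")[[1]],
                  c("symptom:s1", "symptom:s2", "constitution:PDC",
                    "regimen:r1tok", "disease:d1", "drug:g1"))
  expect_error(to_transactions(list(rec), "nope"))
})

test_that("transactions preserve record multiplicity (multiset semantics)", {
  rec1 <- medical_record("a", c("s1", "s2"), "PDC")
  rec2 <- medical_record("b", c("s1", "s2"), "PDC")  # identical content
  trans <- to_transactions(list(rec1, rec2), "symptom_constitution")
  expect_length(trans, 2)
  expect_identical(trans[[1]], trans[[2]])
  # both contribute to support
  fl <- build_flist(trans, 2)
  expect_equal(fl$count, rep(2L, 3))
  # secondary constitutions excluded by default, included on request
  rec3 <- medical_record("c", "s1", "PDC", secondary_constitutions = "DHC")
  expect_false("constitution:DHC" %in%
                 to_transactions(list(rec3), "symptom_constitution")[[1]])
  expect_true("constitution:DHC" %in%
                to_transactions(list(rec3), "symptom_constitution",
                                include_secondary = TRUE)[[1]])
})
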