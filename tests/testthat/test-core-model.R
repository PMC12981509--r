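test_that("TSV registry ingestion parses ids, labels, and synonyms", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "MONDO:0007803\tmultiple system atrophy",
    "MONDO:0005180\tParkinson disease\tparalysis agitans|PD"
  ), f)
  reg <- read_disease_registry(f)
  expect_s3_class(reg, "disease_registry")
  expect_equal(reg$id, c("MONDO:0007803", "MONDO:0005180"))
  expect_equal(reg$label[1], "multiple system atrophy")
  expect_equal(reg$synonyms[[2]], c("paralysis agitans", "PD"))
  expect_equal(reg$synonyms[[1]], character(0))
})

test_that("empty registry file yields an empty registry", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f)
  expect_equal(nrow(read_disease_registry(f)), 0L)
})

test_that("duplicate and malformed ids are rejected with context", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("MONDO:0005180\ta", "MONDO:0005180\tb"), f)
  expect_error(read_disease_registry(f), "MONDO:0005180")

  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("MONDO:0005180\ta", "not_a_curie\tb"), g)
  expect_error(read_disease_registry(g), "line 2")
})

test_that("non-MONDO prefixes warn but do not fail", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("OMIM:123456\tsome disease", f)
  expect_warning(reg <- read_disease_registry(f), "OMIM")
  expect_equal(nrow(reg), 1L)
})

test_that("registry round-trips through TSV, JSON, and the OBO subset", {
  reg <- gen_registry(5)
  t <- withr::local_tempfile(fileext = ".tsv")
  j <- withr::local_tempfile(fileext = ".json")
  write_registry_tsv(reg, t)
  write_registry_json(reg, j)
  rt <- read_disease_registry(t)
  rj <- read_disease_registry(j)
  expect_equal(rt$id, reg$id)
  expect_equal(rt$synonyms, reg$synonyms)
  expect_equal(rj$label, reg$label)
  expect_equal(rj$synonyms, reg$synonyms)

  o <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: MONDO:0007803", "name: multiple system atrophy",
    "synonym: \"MSA\" EXACT []", "",
    "[Term]", "id: MONDO:0005180", "name: Parkinson disease"
  ), o)
  ro <- read_disease_registry(o, format = "obo")
  expect_equal(ro$id, c("MONDO:0007803", "MONDO:0005180"))
  expect_equal(ro$synonyms[[1]], "MSA")
})

test_that("default criteria form the 4/4/3 eleven-criterion framework", {
  cr <- default_criteria()
  expect_silent(validate_criteria(cr))
  counts <- table(cr$category)
  expect_equal(as.integer(counts[c(
    "patient_suffering", "standard_of_care", "accessibility"
  )]), c(4L, 4L, 3L))
})

test_that("default weights match the published scheme and are immutable", {
  w <- default_weights()
  expect_equal(unname(w["Mortality"]), 1.0)
  expect_equal(unname(w["Disease modification"]), 1.0)
  expect_equal(unname(w["Regulatory barriers"]), 0.25)
  expect_equal(sum(w), 5.75)
  w["Mortality"] <- 99
  expect_equal(unname(default_weights()["Mortality"]), 1.0)
  expect_silent(validate_weights(default_weights()))
})

test_that("weight schemes round-trip through JSON and are validated", {
  f <- withr::local_tempfile(fileext = ".json")
  write_weights_json(default_weights(), f)
  expect_identical(read_weights_json(f), default_weights())
  expect_error(validate_weights(default_weights()[-1]), "Commonality")
  bad <- default_weights(); bad[1] <- -1
  expect_error(validate_weights(bad), "non-negative")
})

test_that("score audit enumerates exactly the violating cells", {
  m <- flat_scores(4)
  expect_equal(nrow(validate_scores(m)), 0L)
  m[1, 1] <- 3.5
  m[2, 3] <- 7
  m[3, 5] <- NA # missing is representable, not a violation
  rep <- validate_scores(m)
  expect_equal(nrow(rep), 2L)
  expect_setequal(rep$reason, c("noninteger", "out of range"))
  expect_equal(rep$value[rep$reason == "noninteger"], 3.5)
})

test_that("score matrices round-trip through the frozen CSV dialect", {
  pair <- gen_rater_pair(7, seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  write_score_csv(pair$expert, f)
  back <- read_score_csv(f, rater_id = "expert")
  expect_identical(unclass(back)[, ], unclass(pair$expert)[, ])
  expect_equal(rater_id(back), "expert")

  m <- flat_scores(3)
  m[2, 4] <- NA
  write_score_csv(m, f)
  expect_identical(is.na(read_score_csv(f))[2, 4], TRUE)
})
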