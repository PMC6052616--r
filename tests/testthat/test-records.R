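test_that("valid records survive a write/read round trip in both formats", {
  pub <- make_publication(list(make_model("development")), "P1", jif = 4.2)
  td <- withr::local_tempdir()

  stem <- file.path(td, "rec")
  write_records(list(pub), stem, "csv_long")
  back <- read_records(stem, "csv_long")
  expect_length(back, 1)
  expect_equal(back[[1]]$journal_impact_factor, 4.2)
  expect_equal(back[[1]]$models[[1]]$study_type, "development")
  expect_equal(sort(names(back[[1]]$models[[1]]$judgements)),
               sort(names(pub$models[[1]]$judgements)))

  jp <- file.path(td, "rec.json")
  write_records(list(pub), jp, "json")
  back_j <- read_records(jp, "json")
  expect_equal(back_j[[1]]$models[[1]]$judgements,
               back[[1]]$models[[1]]$judgements)
})

test_that("canonical serialisation is a fixed point of read/write", {
  cohort <- generate_cohort(generator_config(n_publications = 6, seed = 21))
  td <- withr::local_tempdir()
  s1 <- file.path(td, "a"); s2 <- file.path(td, "b")
  write_records(cohort, s1, "csv_long")
  write_records(read_records(s1, "csv_long"), s2, "csv_long")
  for (suffix in c(".judgements.csv", ".models.csv", ".publications.csv")) {
    expect_identical(readLines(paste0(s2, suffix)),
                     readLines(paste0(s1, suffix)))
  }
  j1 <- file.path(td, "a.json"); j2 <- file.path(td, "b.json")
  write_records(cohort, j1, "json")
  write_records(read_records(j1, "json"), j2, "json")
  expect_identical(readLines(j2), readLines(j1))
})

test_that("judgement rows cover exactly the applicable elements", {
  cohort <- generate_cohort(generator_config(n_publications = 10, seed = 8))
  td <- withr::local_tempdir()
  stem <- file.path(td, "c")
  write_records(cohort, stem, "csv_long")
  jud <- readr::read_csv(paste0(stem, ".judgements.csv"), show_col_types = FALSE)
  expected <- sum(vapply(cohort, function(pub) {
    sum(vapply(pub$models, function(m) {
      length(element_ids_of(CL, applicable_item_set(CL, m$study_type)))
    }, 1L))
  }, 1L))
  expect_equal(nrow(jud), expected)
})

test_that("an empty record list writes header-only files", {
  td <- withr::local_tempdir()
  stem <- file.path(td, "empty")
  write_records(list(), stem, "csv_long")
  expect_equal(length(readLines(paste0(stem, ".judgements.csv"))), 1)
  expect_length(read_records(stem, "csv_long"), 0)
})

test_that("validation pinpoints violations with record coordinates", {
  m <- make_model("development", model_id = "M7", publication_id = "P9")
  # reference judgement on an item that does not accept references
  m_badref <- m
  m_badref$judgements["15a.1"] <- "reported_by_reference"
  pub <- publication_extraction("P9", 5.1, TRUE, list(m_badref))
  v <- validate_records(list(pub))
  expect_true(any(grepl("15a.1", v$message)))
  expect_true(all(v$model_id == "M7", na.rm = TRUE))

  # missing judgement
  m_miss <- m
  m_miss$judgements <- m_miss$judgements[names(m_miss$judgements) != "4b.2"]
  v <- validate_records(list(publication_extraction("P9", 5.1, TRUE, list(m_miss))))
  expect_true(any(grepl("missing judgement.*4b\\.2", v$message)))

  # judgement outside the applicable item set (development has no 13c)
  m_extra <- m
  m_extra$judgements <- c(m_extra$judgements, c("13c.1" = "reported"))
  v <- validate_records(list(publication_extraction("P9", 5.1, TRUE, list(m_extra))))
  expect_true(any(grepl("outside the applicable item set.*13c\\.1", v$message)))

  # valid records yield zero violations
  expect_equal(nrow(validate_records(list(pub_valid <- publication_extraction(
    "P9", 5.1, TRUE, list(m)
  )))), 0)
})

test_that("constructors refuse structurally invalid records", {
  m <- make_model("development")
  expect_error(
    publication_extraction("P1", 5, TRUE, list(m, m)),
    "duplicated study_type", class = "tripod_validation_error"
  )
  expect_error(
    publication_extraction("P1", -2, TRUE, list(m)),
    "impact", class = "tripod_validation_error"
  )
  expect_error(
    publication_extraction("P1", 5, TRUE, list()),
    "at least one model", class = "tripod_validation_error"
  )
  expect_error(
    make_model("development", n_predictors = 0L),
    "n_predictors", class = "tripod_validation_error"
  )
  bad_flag <- make_model("development", flags = NULL)
  bad_flag$applicability <- c(bad_flag$applicability, "13c" = TRUE)
  expect_true(any(grepl("non-flaggable", validate_model_extraction(bad_flag, CL))))
})

test_that("write_records refuses invalid record sets", {
  m <- make_model("development")
  pub <- publication_extraction("P1", 5, TRUE, list(m))
  pub$models <- list(m, m) # bypass constructor validation
  expect_error(
    write_records(list(pub), tempfile(), "csv_long"),
    "duplicated study_type", class = "tripod_validation_error"
  )
})

test_that("unknown study types are a parse error on read", {
  pub <- make_publication(list(make_model("development")))
  td <- withr::local_tempdir()
  stem <- file.path(td, "r")
  write_records(list(pub), stem, "csv_long")
  mod <- readLines(paste0(stem, ".models.csv"))
  writeLines(gsub("development", "meta_analysis", mod), paste0(stem, ".models.csv"))
  expect_error(read_records(stem, "csv_long"), "meta_analysis",
               class = "tripod_parse_error")
})

test_that("favourable merge takes the best judgement per shared element", {
  dev <- make_model("development", fill = "reported", model_id = "M1")
  val <- make_model("external_validation", fill = "not_reported", model_id = "M1")
  merged <- merge_model_parts(dev, val)
  expect_equal(merged$study_type, "development_and_validation")
  expect_setequal(scored_item_set(merged),
                  setdiff(applicable_item_set(CL, "development_and_validation"), "21"))
  # shared element reported in the development part wins
  expect_equal(unname(merged$judgements["1.1"]), "reported")
  # development-only elements come from the dev part, validation-only from val
  expect_equal(unname(merged$judgements["10a.1"]), "reported")
  expect_equal(unname(merged$judgements["13c.1"]), "not_reported")

  # both parts unreported stays unreported
  dev0 <- make_model("development", fill = "not_reported", model_id = "M1")
  merged0 <- merge_model_parts(dev0, val)
  expect_true(all(merged0$judgements == "not_reported"))

  # strict mode takes the worst shared judgement
  strict <- merge_model_parts(dev, val, mode = "strict")
  expect_equal(unname(strict$judgements["1.1"]), "not_reported")
  expect_equal(unname(strict$judgements["10a.1"]), "reported")
})

test_that("merge is symmetric on shared elements and rejects mismatches", {
  set.seed(404)
  lv <- c("reported", "not_reported", "not_applicable")
  dev <- make_model("development", fill = "reported", model_id = "M1")
  val <- make_model("external_validation", fill = "reported", model_id = "M1")
  shared_el <- element_ids_of(CL, intersect(
    applicable_item_set(CL, "development"),
    applicable_item_set(CL, "external_validation")
  ))
  dev$judgements[shared_el] <- sample(lv, length(shared_el), replace = TRUE)
  val$judgements[shared_el] <- sample(lv, length(shared_el), replace = TRUE)
  m1 <- merge_model_parts(dev, val)
  # swap shared judgements between the parts: favourable merge unchanged
  dev2 <- dev; val2 <- val
  dev2$judgements[shared_el] <- val$judgements[shared_el]
  val2$judgements[shared_el] <- dev$judgements[shared_el]
  m2 <- merge_model_parts(dev2, val2)
  expect_equal(m1$judgements[shared_el], m2$judgements[shared_el])
  # merging a merged record's inputs again changes nothing (idempotence)
  val3 <- val
  val3$judgements[shared_el] <- m1$judgements[shared_el]
  dev3 <- dev
  dev3$judgements[shared_el] <- m1$judgements[shared_el]
  m3 <- merge_model_parts(dev3, val3)
  expect_equal(m3$judgements, m1$judgements)

  wrong <- make_model("external_validation", model_id = "OTHER")
  expect_error(merge_model_parts(dev, wrong), class = "tripod_merge_error")
  expect_error(merge_model_parts(val, dev), class = "tripod_merge_error")
})
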