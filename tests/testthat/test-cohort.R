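# Cohort ingestion, validation, exclusion filtering and descriptive
# summaries.

test_that("ingestion preserves records and keeps missing cells missing", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "specimen_id,collection,sex,age_years,lateral_angle_deg,aub_mm",
    "s1,Vienna,F,2.5,48.2,85.1",
    "s2,Graz,M,10,,112.0",
    "s3,Terzer,F,0.4,51.3,"), f)
  tab <- read_cohort_table(f)
  expect_s3_class(tab, "cohort_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(sum(is.na(tab$lateral_angle_deg)), 1L)
  expect_equal(sum(is.na(tab$aub_mm)), 1L)
  expect_identical(tab$lateral_angle_deg[2], NA_real_)
  expect_equal(tab$aub_mm[2], 112.0)
})

test_that("malformed rows are rejected with informative messages", {
  base <- data.frame(specimen_id = "s1", collection = "Vienna", sex = "X",
                     age_years = 2, stringsAsFactors = FALSE)
  expect_error(as_cohort_table(base), "unknown sex code 'X'.*row 1")
  base$sex <- "F"; base$age_years <- -1
  expect_error(as_cohort_table(base), "negative age")
  base$age_years <- 2; base$lateral_angle_deg <- -1
  expect_error(as_cohort_table(base), "sentinel")
  base$lateral_angle_deg <- 45; base$aub_mm <- 30
  expect_error(as_cohort_table(base), "aub_mm out of")
  base$aub_mm <- 90; base$collection <- "Howells"
  expect_warning(tab <- as_cohort_table(base), "mapped to 'other'")
  expect_identical(tab$collection, "other")
  expect_error(as_cohort_table(data.frame(specimen_id = "x")),
               "missing required column")
})

test_that("write/read round-trips a cohort table", {
  tab <- simulate_cohort(sim_config(n_per_sex = 25, seed = 7))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(tab, f)
  back <- read_cohort_table(f)
  expect_identical(back$specimen_id, tab$specimen_id)
  expect_identical(is.na(back$lateral_angle_deg),
                   is.na(tab$lateral_angle_deg))
  for (col in c("age_years", "lateral_angle_deg", "aub_mm"))
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-8)
  # tab-separated dialect
  write_cohort_table(tab, f, sep = "\t")
  expect_equal(read_cohort_table(f, sep = "\t")$aub_mm, tab$aub_mm,
               tolerance = 1e-8)
})

test_that("exclusion rules drop the right rows and log the first rule hit", {
  tab <- as_cohort_table(data.frame(
    specimen_id = paste0("s", 1:5),
    collection = c("Graz", "Graz", "Vienna", "NMDID", "NMDID"),
    sex = c("M", "F", "F", "M", "F"),
    age_years = c(25, 10, 3, 35, 20),
    excluded_flag = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE))
  res <- apply_exclusions(tab, exclusion_rules())
  expect_equal(nrow(res$table), 2L)
  expect_setequal(res$table$specimen_id, c("s2", "s3"))
  log <- res$log
  expect_equal(log$rule[log$specimen_id == "s1"], "collection_age_cap")
  expect_equal(log$rule[log$specimen_id == "s4"], "max_age")
  expect_equal(log$rule[log$specimen_id == "s5"], "flagged")

  # flags ignored when drop_flagged = FALSE
  res2 <- apply_exclusions(tab, exclusion_rules(drop_flagged = FALSE))
  expect_true("s5" %in% res2$table$specimen_id)

  # identity when no rule applies, and idempotence
  clean <- res$table
  res3 <- apply_exclusions(clean, exclusion_rules())
  expect_identical(res3$table, clean)
  expect_equal(nrow(res3$log), 0L)
})

test_that("apply_exclusions is idempotent on random cohorts", {
  tab <- simulate_cohort(sim_config(n_per_sex = 40, seed = 21))
  rules <- exclusion_rules(max_age_years = 18)
  once <- apply_exclusions(tab, rules)
  twice <- apply_exclusions(once$table, rules)
  expect_identical(twice$table, once$table)
})

test_that("summarize_cohort matches a brute-force two-pass computation", {
  for (seed in c(3, 14)) {
    tab <- simulate_cohort(sim_config(n_per_sex = 50, seed = seed))
    sm <- summarize_cohort(tab)
    for (i in sample(nrow(sm), 12)) {
      row <- sm[i, ]
      vals <- tab[[row$variable]][tab$collection == row$collection &
                                    tab$sex == row$sex]
      ref <- bf_summary(vals)
      expect_equal(row$n, ref$n)
      if (ref$n > 0) {
        expect_equal(row$mean, ref$mean, tolerance = 1e-10)
        expect_equal(row$median, ref$median, tolerance = 1e-10)
        expect_equal(row$min, ref$min)
        expect_equal(row$max, ref$max)
      }
      if (ref$n > 1) expect_equal(row$sd, ref$sd, tolerance = 1e-10)
    }
  }
})

test_that("summary strata follow the stated conventions", {
  tab <- toy_cohort()
  sm <- summarize_cohort(tab)
  # single observation: sd is missing, not 0
  one <- sm[sm$collection == "Terzer" & sm$sex == "F" &
              sm$variable == "lateral_angle_deg", ]
  expect_equal(one$n, 1L)
  expect_equal(one$mean, 50)
  expect_true(is.na(one$sd))
  # empty stratum present with n = 0 and missing statistics
  none <- sm[sm$collection == "NMDID" & sm$sex == "F" &
               sm$variable == "aub_mm", ]
  expect_equal(none$n, 0L)
  expect_true(is.na(none$mean))
  # deterministic ordering: collections in canonical order within variable
  age_rows <- sm[sm$variable == "age_years", ]
  expect_identical(unique(age_rows$collection),
                   c("Vienna", "Graz", "Terzer", "NMDID"))
  expect_identical(summarize_cohort(tab), summary(tab))
})

test_that("reference fixtures load with the documented layout", {
  ref <- reference_collection_summary()
  expect_setequal(names(ref),
                  c("collection", "sex", "variable", "n", "mean", "sd",
                    "median", "min", "max"))
  adult <- ref[ref$collection == "NMDID" & ref$variable == "aub_mm", ]
  expect_equal(adult$mean[adult$sex == "M"] - adult$mean[adult$sex == "F"],
               5.6, tolerance = 1e-9)
  lit <- lateral_angle_literature()
  expect_true(all(lit$female_mean_deg > 0 & lit$female_mean_deg < 90))
})
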