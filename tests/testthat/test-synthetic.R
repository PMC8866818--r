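test_that("generated cohorts match configured group sizes and are seed-reproducible", {
  coh <- generate_cohorts(table1_config(seed = 5))
  t1 <- coh$tables$dataset1; t2 <- coh$tables$dataset2
  expect_equal(sum(t1$GROUP == "PD"), 29L)
  expect_equal(sum(t1$GROUP == "HC"), 21L)
  expect_equal(sum(t2$CONDX == "PD"), 69L)
  expect_equal(sum(t2$CONDX == "HC"), 31L)
  coh2 <- generate_cohorts(table1_config(seed = 5))
  expect_identical(coh$tables, coh2$tables)
  expect_identical(coh$truth, coh2$truth)
  coh3 <- generate_cohorts(table1_config(seed = 6))
  expect_false(identical(coh$tables, coh3$tables))
  # generation does not disturb the caller's RNG stream
  set.seed(99); a <- runif(1)
  set.seed(99); invisible(generate_cohorts(table1_config(seed = 5))); b <- runif(1)
  expect_identical(a, b)
})

test_that("zero-sd MoCA collapses to the rounded group mean", {
  s <- cohort_config(seed = 1)$sources
  for (sn in names(s)) for (gn in c("pd", "hc")) s[[sn]][[gn]]$moca_sd <- 0
  coh <- generate_cohorts(cohort_config(sources = s, seed = 1))
  expect_true(all(coh$tables$dataset1$MOCA_total[coh$tables$dataset1$GROUP == "PD"] == 25L))
  expect_true(all(coh$tables$dataset2$MCATOT[coh$tables$dataset2$CONDX == "HC"] == 28L))
})

test_that("written CSVs round-trip through load_source_table cell for cell", {
  cfg <- small_config(seed = 41, n = c(6, 5, 7, 4))
  coh <- generate_cohorts(cfg)
  dir <- withr::local_tempdir()
  paths <- write_source_files(coh, dir)
  t1 <- load_source_table(paths[["dataset1"]], "dataset1", "SUBJECT_ID")
  reread <- t1$rows
  orig <- coh$tables$dataset1
  expect_identical(names(reread), names(orig))
  for (col in names(orig)) {
    if (is.numeric(orig[[col]])) {
      expect_identical(as.numeric(reread[[col]]), as.numeric(orig[[col]]),
                       info = col)
    } else {
      expect_identical(reread[[col]], as.character(orig[[col]]), info = col)
    }
  }
  # truth covers every row
  truth <- utils::read.csv(paths[["truth"]])
  expect_equal(nrow(truth), nrow(coh$tables$dataset1) + nrow(coh$tables$dataset2))
})

test_that("the two dialects share no assessment or volume columns", {
  coh <- generate_cohorts(small_config(seed = 42, n = c(3, 3, 3, 3)))
  shared <- intersect(names(coh$tables$dataset1), names(coh$tables$dataset2))
  assessment_like <- grepl("MOCA|MCA|HIPP|ICV|VOL", shared, ignore.case = TRUE)
  expect_false(any(assessment_like))
})

test_that("planted sub-threshold subjects score below 26 and carry the volume deficit", {
  cfg <- conservation_config(seed = 43)
  coh <- generate_cohorts(cfg)
  expect_equal(sum(coh$truth$true_below[coh$truth$source == "dataset1"]), 78L)
  expect_equal(sum(coh$truth$true_below[coh$truth$source == "dataset2"]), 32L)
  expect_true(all(coh$truth$moca_total[coh$truth$true_below] < 26))
  expect_true(all(coh$truth$moca_total[!coh$truth$true_below] >= 26))
  # planted = PD and below
  expect_equal(coh$truth$planted_effect,
               coh$truth$group == "PD" & coh$truth$true_below)
  # the shifted volume distribution is visible in the planted group
  t1 <- coh$tables$dataset1
  key <- match(t1$SUBJECT_ID, coh$truth$subject_id)
  planted <- coh$truth$planted_effect[key]
  pd <- t1$GROUP == "PD"
  expect_lt(mean(t1$LHIPPO_VOL_MM3[pd & planted]),
            mean(t1$LHIPPO_VOL_MM3[pd & !planted]))
})

test_that("sample means track configured means within 3 standard errors at large n", {
  s <- cohort_config(seed = 44)$sources
  s$dataset1$pd$n <- 2000L
  cfg <- cohort_config(sources = s, seed = 44)
  coh <- generate_cohorts(cfg)
  t1 <- coh$tables$dataset1
  pd <- t1$GROUP == "PD"
  g <- cfg$sources$dataset1$pd
  checks <- list(
    c(mean(t1$AGE[pd]), g$age_mean, g$age_sd),
    c(mean(t1$EDUCATION_YRS[pd]), g$education_mean, g$education_sd),
    c(mean(t1$MOCA_total[pd]), g$moca_mean, g$moca_sd))
  for (ck in checks) {
    se <- ck[[3]] / sqrt(sum(pd))
    expect_lt(abs(ck[[1]] - ck[[2]]), 3 * se + 0.06)  # + rounding slack
  }
})

test_that("invalid configs fail validation with the offending fields listed", {
  s <- cohort_config(seed = 1)$sources
  s$dataset1$pd$n <- 0
  expect_error(cohort_config(sources = s), "n must be > 0")
  s <- cohort_config(seed = 1)$sources
  s$dataset2$hc$moca_sd <- -1
  expect_error(cohort_config(sources = s), "moca_sd")
  s <- cohort_config(seed = 1)$sources
  s$dataset1$pd$n_below <- 999
  expect_error(cohort_config(sources = s), "n_below")
})

test_that("cohort configs round-trip through YAML and the shipped preset loads", {
  cfg <- small_config(seed = 45, n = c(4, 4, 4, 4))
  p <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_config(cfg, p)
  cfg2 <- read_cohort_config(p)
  expect_identical(generate_cohorts(cfg)$tables, generate_cohorts(cfg2)$tables)
  preset <- system.file("extdata", "table1.yaml", package = "cohortkg")
  cfg3 <- read_cohort_config(preset)
  expect_identical(generate_cohorts(cfg3)$tables,
                   generate_cohorts(table1_config(seed = cfg3$seed))$tables)
})
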