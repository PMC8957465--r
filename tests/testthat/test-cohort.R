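test_that("the default cohort reproduces the published joint counts", {
  spec <- default_cohort_spec()
  expect_equal(sum(spec$joints_per_type), 146)
  expect_equal(spec$joints_per_type,
               c(knee = 84L, ankle = 38L, elbow = 10L, hip = 14L))
  expect_equal(unname(spec$grade_distributions$effusion), c(14L, 59L, 37L))
  expect_equal(unname(spec$grade_distributions$synovial_hyperplasia),
               c(15L, 50L, 27L, 54L))
  expect_equal(unname(spec$grade_distributions$hemosiderin),
               c(36L, 46L, 22L, 44L))

  co <- suppressWarnings(make_cohort(spec))
  expect_equal(nrow(co), 146)
  expect_equal(as.integer(table(co$joint_type)[c("knee", "ankle", "elbow", "hip")]),
               c(84, 38, 10, 14))
  # hyperplasia counts sum to 146 and are reproduced verbatim per joint
  expect_equal(unname(grade_counts(co, "synovial_hyperplasia")),
               c(15L, 50L, 27L, 54L))
  # effusion: the printed counts sum to 110; the 2-3 bin is split but its
  # union is exact, and 36 joints stay ungraded
  gc <- grade_counts(co, "effusion")
  expect_equal(unname(gc[c("0", "1")]), c(14L, 59L))
  expect_equal(unname(gc[["2"]] + gc[["3"]]), 37L)
  expect_equal(sum(is.na(co$effusion_pathology)), 36)
  expect_equal(sum(co$rs_treated), 42)
  expect_equal(length(unique(co$patient_id)), 60)
})

test_that("grade-count/joint-total mismatches are rejected unless exempted", {
  bad <- cohort_spec(grade_distributions = list(
    synovial_hyperplasia = c(`0` = 10L, `1` = 10L)))
  expect_error(make_cohort(bad), "sum to 20 but the cohort has 146")
  ok <- cohort_spec(grade_distributions = list(
    synovial_hyperplasia = c(`0` = 10L, `1` = 10L)),
    skip_sum_check = "synovial_hyperplasia")
  co <- make_cohort(ok)
  expect_equal(sum(is.na(co$synovial_hyperplasia_pathology)), 126)
  # over-long distributions drop from the last bin, with a warning
  over <- cohort_spec(grade_distributions = list(
    hemosiderin = c(`0` = 36L, `1` = 46L, `2` = 22L, `3` = 44L)),
    skip_sum_check = "hemosiderin")
  expect_warning(co2 <- make_cohort(over), "dropping 2")
  expect_equal(unname(grade_counts(co2, "hemosiderin")),
               c(36L, 46L, 22L, 42L))
})

test_that("volumes follow the multiplicative reduction model", {
  # reduction 1 and zero noise: post equals pre exactly
  spec <- cohort_spec(grade_distributions = list(),
                      volume_model = list(pre_mean = 20000, pre_cv = 0.2,
                                          reduction = 1, post_cv = 0))
  co <- make_cohort(spec)
  expect_equal(co$volume_post, co$volume_pre)
  expect_true(all(co$volume_pre > 0))

  # reduction 0.7: the post/pre ratio centers on 0.7
  spec2 <- cohort_spec(grade_distributions = list(),
                       volume_model = list(pre_mean = 30000, pre_cv = 0.2,
                                           reduction = 0.7, post_cv = 0.2))
  co2 <- make_cohort(spec2)
  expect_equal(mean(co2$volume_post / co2$volume_pre), 0.7, tolerance = 0.06)
  expect_error(cohort_spec(volume_model = list(pre_mean = 1, pre_cv = 0.1,
                                               reduction = 1.4, post_cv = 0.1)),
               "reduction")
})

test_that("cohort generation is deterministic in the spec seed", {
  a <- suppressWarnings(make_cohort(default_cohort_spec()))
  b <- suppressWarnings(make_cohort(default_cohort_spec()))
  expect_identical(as.data.frame(a), as.data.frame(b))
  spec_c <- default_cohort_spec(); spec_c$seed <- 999L
  c <- suppressWarnings(make_cohort(spec_c))
  expect_false(identical(a$volume_pre, c$volume_pre))
})

test_that("the MRI arms degrade pathology grades at their error rates", {
  co <- suppressWarnings(make_cohort(default_cohort_spec()))
  ok <- !is.na(co$synovial_hyperplasia_pathology)
  mismatch_conv <- mean(co$synovial_hyperplasia_conventional[ok] !=
                          co$synovial_hyperplasia_pathology[ok])
  mismatch_canny <- mean(co$synovial_hyperplasia_canny[ok] !=
                           co$synovial_hyperplasia_pathology[ok])
  expect_gt(mismatch_conv, mismatch_canny)
  expect_lt(abs(mismatch_conv - 0.25), 0.10)
  # arm grades never leave the 0-3 range
  for (col in grep("_conventional$|_canny$", names(co), value = TRUE)) {
    expect_true(all(stats::na.omit(co[[col]]) %in% 0:3), info = col)
  }
})

test_that("cohorts round-trip through the long TSV exchange format", {
  dir <- withr::local_tempdir()
  co <- suppressWarnings(make_cohort(default_cohort_spec()))
  path <- file.path(dir, "cohort.tsv")
  write_cohort(co, path)
  long <- utils::read.delim(path)
  expect_equal(nrow(long), 3 * 146)
  expect_setequal(unique(long$arm), c("pathology", "conventional", "canny"))
  back <- read_cohort(path)
  expect_equal(nrow(back), 146)
  for (col in c("patient_id", "joint_type", "volume_pre", "bleeds_post",
                "effusion_pathology", "hemosiderin_canny")) {
    expect_equal(back[[col]], co[[col]], info = col, tolerance = 1e-9)
  }
  expect_error(read_cohort({
    p <- file.path(dir, "bad.tsv")
    utils::write.table(data.frame(a = 1), p, sep = "\t", row.names = FALSE)
    p
  }), "lacks columns")
})
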