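test_that("wound coverage follows its defining ratio", {
  s <- wound_coverage(tibble::tibble(time_h = c(0, 24), area = c(100, 25)))
  expect_equal(s$coverage, c(0, 0.75))
  s2 <- wound_coverage(tibble::tibble(time_h = c(0, 24), area = c(80, 80)))
  expect_equal(s2$coverage[2], 0)
  s3 <- wound_coverage(tibble::tibble(time_h = c(0, 48), area = c(60, 0)))
  expect_equal(s3$coverage[2], 1)
  # regrowth beyond the original area clips at zero coverage
  s4 <- wound_coverage(tibble::tibble(time_h = c(0, 24), area = c(50, 70)))
  expect_equal(s4$coverage[2], 0)
})

test_that("wound coverage requires a t = 0 reference", {
  expect_error(
    wound_coverage(tibble::tibble(time_h = c(24, 48), area = c(10, 5))),
    class = "tensiomag_input_error"
  )
  expect_error(
    wound_coverage(tibble::tibble(time_h = c(0, 24), area = c(0, 0))),
    class = "tensiomag_input_error"
  )
})

test_that("coverage is monotone for shrinking wounds and scale invariant", {
  withr::local_seed(5)
  for (i in 1:10) {
    areas <- sort(runif(5, 0, 100), decreasing = TRUE)
    d <- tibble::tibble(time_h = c(0, 6, 12, 24, 48), area = areas)
    cov <- wound_coverage(d)$coverage
    expect_true(all(diff(cov) >= 0))
    cov_scaled <- wound_coverage(dplyr::mutate(d, area = area * 3.7))$coverage
    expect_equal(cov_scaled, cov, tolerance = 1e-12)
  }
})

test_that("grouped wound series are normalized per group", {
  d <- dplyr::bind_rows(
    tibble::tibble(field = "a", time_h = c(0, 24), area = c(100, 50)),
    tibble::tibble(field = "b", time_h = c(0, 24), area = c(200, 50))
  )
  res <- d %>% dplyr::group_by(field) %>% wound_coverage() %>% dplyr::ungroup()
  expect_equal(res$coverage[res$field == "a" & res$time_h == 24], 0.5)
  expect_equal(res$coverage[res$field == "b" & res$time_h == 24], 0.75)
})

test_that("wound area respects the pixel scale", {
  mask <- matrix(0L, 10, 10); mask[3:6, 2:9] <- 1L
  expect_equal(wound_area(mask), 32)
  expect_equal(wound_area(mask, scale_um_per_px = 2), 32 * 4)
})

test_that("invasion index matches its defining ratio", {
  expect_identical(invasion_index(c(10, 10, 10), c(10, 10, 10)), 1)
  expect_equal(invasion_index(c(65, 65, 65), c(10, 10, 10)), 6.5)
  expect_equal(invasion_index(c(0, 0, 0), c(4, 6)), 0)
})

test_that("invasion index validates its inputs", {
  expect_error(invasion_index(c(1, 2), c(0, 0)),
               class = "tensiomag_input_error")
  expect_error(invasion_index(numeric(0), c(1, 2)),
               class = "tensiomag_input_error")
  expect_error(invasion_index(c(1.5, 2), c(1, 2)),
               class = "tensiomag_input_error")
  expect_error(invasion_index(c(-1, 2), c(1, 2)),
               class = "tensiomag_input_error")
})

test_that("invasion index is scale and permutation invariant", {
  withr::local_seed(6)
  test <- rpois(15, 30); ctrl <- rpois(15, 10)
  i0 <- invasion_index(test, ctrl)
  expect_equal(invasion_index(test * 4L, ctrl * 4L), i0, tolerance = 1e-12)
  expect_equal(invasion_index(sample(test), sample(ctrl)), i0,
               tolerance = 1e-12)
})

test_that("study-level invasion summary anchors the control at 1", {
  counts <- dplyr::bind_rows(
    synth_invasion_counts(10, condition = "NT", seed = 11),
    synth_invasion_counts(65, condition = "KO", seed = 12)
  )
  res <- summarize_invasion(counts, control = "NT")
  expect_identical(res$index[res$condition == "NT"], 1)
  expect_identical(res$index_sem[res$condition == "NT"], 0)
  expect_gt(res$index[res$condition == "KO"], 3)
  expect_error(summarize_invasion(counts, control = "missing"),
               class = "tensiomag_input_error")
})
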