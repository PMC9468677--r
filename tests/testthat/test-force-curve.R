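test_that("segment structure is validated", {
  good <- synth_force_curve(seed = 1)
  expect_s3_class(as_force_curve(good), "force_curve")
  bad <- good
  bad$segment <- rev(bad$segment)
  expect_error(as_force_curve(bad), class = "tensiomag_input_error")
  no_retract <- good[good$segment != "retract", ]
  expect_error(as_force_curve(no_retract), class = "tensiomag_input_error")
  expect_error(
    baseline_correct(good[good$segment != "retract" | good$time_s > 4.99, ]),
    class = "tensiomag_input_error"
  )
})

test_that("baseline correction removes a constant offset", {
  cv <- synth_force_curve(dip_nn = 1, noise_sd_nn = 0, offset_nn = 0.5,
                          seed = 1)
  corr <- baseline_correct(cv)
  f <- corr$force_nn[corr$segment == "retract"]
  tail_mean <- mean(tail(f, floor(length(f) * 0.2)))
  expect_lt(abs(tail_mean), 1e-8)
})

test_that("baseline correction detrends a linear drift", {
  cv <- synth_force_curve(dip_nn = 1, noise_sd_nn = 0,
                          drift_nn_per_s = 0.01, seed = 1)
  corr <- baseline_correct(cv)
  ret <- corr[corr$segment == "retract", ]
  tail_rows <- tail(seq_len(nrow(ret)), floor(nrow(ret) * 0.2))
  slope <- coef(lm(force_nn ~ time_s, data = ret[tail_rows, ]))[[2]]
  expect_lt(abs(slope), 1e-4)
})

test_that("an already-zero baseline passes through unchanged", {
  cv <- synth_force_curve(dip_nn = 1.5, noise_sd_nn = 0, seed = 1)
  corr <- baseline_correct(cv)
  expect_lt(max(abs(corr$force_nn - cv$force_nn)), 1e-10)
})

test_that("detachment is the dip magnitude after baseline removal", {
  # trace dipping to an absolute -1.2 nN on a +0.2 nN baseline: the
  # corrected dip is 1.4 nN
  cv <- synth_force_curve(dip_nn = 1.4, noise_sd_nn = 0, offset_nn = 0.2,
                          seed = 1)
  expect_equal(detachment_force(cv), 1.4, tolerance = 0.01)
  ret <- cv[cv$segment == "retract", ]
  expect_equal(min(ret$force_nn), -1.2, tolerance = 0.01)
})

test_that("a monotone retract with no dip reports zero", {
  cv <- synth_force_curve(dip_nn = 0, noise_sd_nn = 0.05, seed = 2)
  expect_identical(detachment_force(cv), 0)
})

test_that("detachment force is invariant to any affine baseline", {
  base <- synth_force_curve(dip_nn = 1.8, noise_sd_nn = 0, seed = 3)
  d0 <- detachment_force(base)
  for (ab in list(c(0.5, 0), c(-0.3, 0.02), c(1, -0.05))) {
    shifted <- base
    shifted$force_nn <- shifted$force_nn + ab[1] + ab[2] * shifted$time_s
    expect_equal(detachment_force(shifted), d0, tolerance = 1e-3)
  }
})

test_that("noisy dips are recovered without systematic bias", {
  dips <- vapply(1:15, function(i) {
    detachment_force(synth_force_curve(dip_nn = 1.8, noise_sd_nn = 0.1,
                                       seed = i))
  }, numeric(1))
  expect_lt(abs(mean(dips) - 1.8), 0.08)
})

test_that("batch summaries reproduce per-condition means", {
  curves <- purrr::map_dfr(1:6, function(i) {
    dplyr::bind_cols(
      tibble::tibble(condition = if (i <= 3) "A" else "B", curve = i),
      synth_force_curve(dip_nn = if (i <= 3) 1.0 else 2.0,
                        noise_sd_nn = 0.05, seed = 100 + i)
    )
  })
  each <- detachment_force_each(curves)
  expect_identical(nrow(each), 6L)
  summ <- summarize_detachment(each)
  expect_identical(summ$n, c(3L, 3L))
  expect_lt(abs(summ$mean_nn[summ$condition == "A"] - 1.0), 0.15)
  expect_lt(abs(summ$mean_nn[summ$condition == "B"] - 2.0), 0.15)
})
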