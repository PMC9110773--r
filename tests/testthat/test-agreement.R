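test_that("bias and limits of agreement match hand computation", {
  ref <- c(120, 130, 140, 125, 135)
  s_id <- paired_series(ref, ref)
  bl <- bias_loa(s_id)
  expect_equal(bl$bias, 0)
  expect_equal(bl$loa_half_width, 0)
  bl5 <- bias_loa(paired_series(ref + 5, ref))
  expect_equal(bl5$bias, 5, tolerance = 1e-12)
  expect_equal(bl5$sd_diff, 0)
  # fixture diffs {-3, 1, 2, 4, -4}: sd = sqrt(46/4), LOA = 1.96 sd
  d <- c(-3, 1, 2, 4, -4)
  bl3 <- bias_loa(paired_series(ref + d, ref))
  expect_equal(bl3$bias, 0, tolerance = 1e-12)
  expect_equal(bl3$sd_diff, sqrt(46 / 4), tolerance = 1e-12)
  expect_equal(bl3$loa_half_width, 1.96 * sqrt(46 / 4), tolerance = 1e-12)
  expect_equal(bl3$loa_half_width, 6.65, tolerance = 1e-3)
})

test_that("CV is the difference SD relative to the reference mean", {
  ref <- c(120, 132, 144)
  expect_equal(cv_percent(paired_series(ref, ref)), 0)
  # construct diffs with sample SD 13.2 about a reference with mean 132
  ref2 <- c(132, 132, 132, 132)
  d <- c(-1, 1, -1, 1) * 13.2 * sqrt(3) / 2
  expect_equal(cv_percent(paired_series(ref2 + d, ref2)), 10,
               tolerance = 1e-12)
  # invariant to common rescaling
  s <- paired_series(c(150, 160, 140, 170), c(140, 150, 160, 150))
  s_k <- paired_series(c(150, 160, 140, 170) * 3, c(140, 150, 160, 150) * 3)
  expect_equal(cv_percent(s), cv_percent(s_k), tolerance = 1e-12)
})

test_that("SEE is zero for exact linear relations and matches OLS", {
  ref <- c(100, 120, 140, 160, 180)
  expect_equal(see(paired_series(2 * ref + 3, ref)), 0, tolerance = 1e-9)
  set.seed(5)
  for (i in 1:10) {
    p <- random_pairs(sample(5:30, 1))
    expect_equal(see(paired_series(p$pred, p$ref)),
                 brute_stats(p$pred, p$ref)$see, tolerance = 1e-12)
  }
  expect_error(see(paired_series(c(1, 2, 3), c(5, 5, 5))), "degenerate")
})

test_that("SEE estimates the residual SD consistently", {
  set.seed(9)
  ref <- stats::runif(2000, 100, 180)
  pred <- 1.1 * ref + 4 + stats::rnorm(2000, 0, 7)
  expect_equal(see(paired_series(pred, ref)), 7, tolerance = 0.05)
})

test_that("Pearson correlation covers the exact limits and the oracle", {
  ref <- c(100, 120, 140, 160)
  expect_equal(pearson(paired_series(ref, ref))$r, 1, tolerance = 1e-12)
  expect_equal(pearson(paired_series(300 - ref, ref))$r, -1,
               tolerance = 1e-12)
  set.seed(13)
  p <- random_pairs(6)
  got <- pearson(paired_series(p$pred, p$ref))
  want <- brute_stats(p$pred, p$ref)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p, want$r_p, tolerance = 1e-12)
  expect_error(pearson(paired_series(c(5, 5, 5), ref[1:3])), "constant")
})

test_that("paired t-test follows the textbook statistic and conventions", {
  ref <- c(120, 130, 140, 150)
  expect_equal(paired_t(paired_series(ref, ref)), 1)
  set.seed(17)
  noisy <- ref + 40 + stats::rnorm(4, 0, 0.01)
  expect_lt(paired_t(paired_series(noisy, ref)), 1e-6)
  p <- random_pairs(12)
  expect_equal(paired_t(paired_series(p$pred, p$ref)),
               brute_stats(p$pred, p$ref)$t_p, tolerance = 1e-12)
})

test_that("proportional bias regression detects slope in the differences", {
  ref <- c(100, 110, 120, 130, 140, 150, 160, 170)
  pb0 <- proportional_bias(paired_series(ref + 7, ref))
  expect_equal(pb0$slope, 0, tolerance = 1e-10)
  expect_equal(pb0$p, 1)
  expect_false(pb0$significant)
  set.seed(19)
  ref2 <- stats::runif(200, 100, 180)
  pb1 <- proportional_bias(paired_series(ref2 * 1.1 + stats::rnorm(200, 0, 1),
                                         ref2))
  expect_equal(pb1$slope, 0.1, tolerance = 0.05)
  expect_lt(pb1$p, 1e-6)
  p <- random_pairs(8)
  got <- proportional_bias(paired_series(p$pred, p$ref))
  want <- brute_stats(p$pred, p$ref)
  expect_equal(got$slope, want$slope, tolerance = 1e-12)
  expect_equal(got$p, want$slope_p, tolerance = 1e-12)
})

test_that("percentage differences are elementwise and signed", {
  ref <- c(100, 150, 120)
  expect_equal(unname(percent_differences(paired_series(1.1 * ref, ref))),
               rep(10, 3), tolerance = 1e-12)
  expect_equal(unname(percent_differences(paired_series(ref, ref))),
               rep(0, 3))
  pred <- c(90, 180, 126)
  expect_equal(unname(percent_differences(paired_series(pred, ref))),
               100 * (pred - ref) / ref, tolerance = 1e-12)
})

test_that("accuracy ranking credits the best method and splits ties", {
  ref <- c(100, 120, 140)
  methods <- list(exact = paired_series(ref, ref),
                  high = paired_series(ref * 1.2, ref),
                  low = paired_series(ref * 0.9, ref))
  rk <- rank_accuracy(methods)
  expect_equal(rk$most_n[rk$method == "exact"], 3)
  expect_equal(rk$most_pct[rk$method == "exact"], 100)
  expect_equal(rk$least_n[rk$method == "high"], 3)
  # symmetric +-5%: tie splits 0.5/0.5
  tie <- list(up = paired_series(ref * 1.05, ref),
              down = paired_series(ref * 0.95, ref),
              far = paired_series(ref * 1.5, ref))
  rk2 <- rank_accuracy(tie)
  expect_equal(rk2$most_n[rk2$method == "up"], 1.5)
  expect_equal(rk2$most_n[rk2$method == "down"], 1.5)
  expect_equal(sum(rk2$most_n), 3)
  expect_equal(sum(rk2$least_n), 3)
})

test_that("accuracy ranking matches exhaustive enumeration on a small
           fixture", {
  ref <- c(100, 120, 140)
  pred <- list(m1 = c(102, 125, 160), m2 = c(95, 121, 139),
               m3 = c(110, 132, 150))
  methods <- lapply(pred, paired_series, reference = ref)
  rk <- rank_accuracy(methods)
  # brute-force enumeration
  most <- least <- c(m1 = 0, m2 = 0, m3 = 0)
  for (i in 1:3) {
    e <- sapply(pred, function(p) abs(100 * (p[i] - ref[i]) / ref[i]))
    most[names(which.min(e))] <- most[names(which.min(e))] + 1
    least[names(which.max(e))] <- least[names(which.max(e))] + 1
  }
  expect_equal(stats::setNames(rk$most_n, rk$method), most)
  expect_equal(stats::setNames(rk$least_n, rk$method), least)
})

test_that("reader variability composes bias, LOA, CV and SEE correctly", {
  base <- c(120, 135, 150, 128, 160)
  expect_equal(reader_variability(base, base)$cv_pct, 0)
  rv <- reader_variability(base, base * 1.05)
  expect_equal(rv$bias, 0.05 * mean(base), tolerance = 1e-12)
  set.seed(23)
  rep2 <- base + stats::rnorm(5, 2, 4)
  rv2 <- reader_variability(base, rep2)
  s <- paired_series(rep2, base)
  expect_equal(rv2$bias, bias_loa(s)$bias, tolerance = 1e-12)
  expect_equal(rv2$loa_half_width, bias_loa(s)$loa_half_width,
               tolerance = 1e-12)
  expect_equal(rv2$cv_pct, 100 * stats::sd(rep2 - base) / mean(base),
               tolerance = 1e-12)
  expect_equal(rv2$see, see(s), tolerance = 1e-12)
  expect_error(reader_variability(base, rep2[1:4]), "alignment")
})

test_that("agreement summary object is consistent with the individual
           operations", {
  set.seed(29)
  p <- random_pairs(20)
  s <- paired_series(p$pred, p$ref)
  ag <- lvm_agreement(s)
  expect_s3_class(ag, "lvm_agreement")
  expect_equal(ag$bias, bias_loa(s)$bias, tolerance = 1e-12)
  expect_equal(ag$cv_pct, cv_percent(s), tolerance = 1e-12)
  expect_equal(ag$see, see(s), tolerance = 1e-12)
  expect_equal(ag$pearson_r, pearson(s)$r, tolerance = 1e-12)
  expect_equal(ag$paired_t_p, paired_t(s), tolerance = 1e-12)
  expect_equal(ag$prop_bias_slope, proportional_bias(s)$slope,
               tolerance = 1e-12)
  expect_output(print(ag), "bias")
  expect_output(summary(ag), "Proportional bias")
  pdf_file <- tempfile(fileext = ".pdf")
  grDevices::pdf(pdf_file)
  expect_silent(plot(ag))
  expect_silent(plot_percent_differences(list(a = s, b = s)))
  grDevices::dev.off()
  expect_true(file.exists(pdf_file))
})

test_that("paired series enforce its invariants", {
  expect_error(paired_series(c(1, 2), c(1, 2)), "at least 3")
  expect_error(paired_series(c(1, 2, NA), c(1, 2, 3)), "missing")
  expect_error(paired_series(c(1, 2, -3), c(1, 2, 3)), "positive")
  expect_error(paired_series(c(1, 2, 3), c(1, 2)), "equal length")
})
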