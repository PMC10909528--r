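conf_from_counts <- function(tp, fp, tn, fn) {
  # reference: tp+fn sleep then tn+fp wake; device agrees/disagrees per count
  ref <- c(rep("sleep", tp + fn), rep("wake", tn + fp))
  dev <- c(rep("sleep", tp), rep("wake", fn), rep("wake", tn),
           rep("sleep", fp))
  epoch_confusion(state_series(dev, 30), state_series(ref, 30))
}

test_that("confusion statistics follow the printed formulas", {
  cs <- conf_from_counts(tp = 80, fp = 70, tn = 30, fn = 20)
  expect_equal(c(cs$tp, cs$fp, cs$tn, cs$fn), c(80, 70, 30, 20))
  expect_equal(cs$sensitivity, 0.80)
  expect_equal(cs$specificity, 0.30)
  expect_equal(cs$accuracy, 0.55)
})

test_that("identical series score perfectly; mismatched lengths error", {
  s <- runs_ss(w = 10, s = 20, w = 5, step_s = 30)
  cs <- epoch_confusion(s, s)
  expect_equal(cs$sensitivity, 1)
  expect_equal(cs$specificity, 1)
  expect_equal(cs$accuracy, 1)
  expect_error(epoch_confusion(s, runs_ss(w = 10, step_s = 30)),
               "35.*10|10.*35")
})

test_that("an all-sleep reference leaves specificity undefined, flagged", {
  cs <- epoch_confusion(runs_ss(s = 5, w = 5, step_s = 30),
                        runs_ss(s = 10, step_s = 30))
  expect_true(is.na(cs$specificity))
  expect_equal(cs$undefined, "specificity")
  expect_false(is.na(cs$sensitivity))
})

test_that("accuracy decomposes into prevalence-weighted sens/spec", {
  set.seed(707)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    dev <- sample(c("sleep", "wake"), n, TRUE)
    ref <- sample(c("sleep", "wake"), n, TRUE)
    cs <- epoch_confusion(state_series(dev, 30), state_series(ref, 30))
    if (length(cs$undefined)) next
    P <- cs$tp + cs$fn
    N <- cs$tn + cs$fp
    expect_equal(cs$accuracy,
                 cs$sensitivity * P / (P + N) + cs$specificity * N / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("cohort averaging is per participant with exclusions logged", {
  five <- replicate(5, conf_from_counts(80, 70, 30, 20), simplify = FALSE)
  tab <- cohort_confusion(five)
  expect_equal(tab$sd, rep(0, 3))

  two <- list(conf_from_counts(80, 10, 10, 20),    # sens 0.8
              conf_from_counts(100, 10, 10, 0))    # sens 1.0
  tab2 <- cohort_confusion(two)
  sens_row <- tab2[tab2$statistic == "sensitivity", ]
  expect_equal(sens_row$mean, 0.9)
  expect_equal(sens_row$sd, sqrt(0.02), tolerance = 1e-6)

  mixed <- list(conf_from_counts(5, 0, 0, 5),      # all-sleep ref
                conf_from_counts(8, 2, 3, 2),
                conf_from_counts(7, 1, 4, 3))
  tab3 <- cohort_confusion(mixed)
  spec_row <- tab3[tab3$statistic == "specificity", ]
  expect_equal(spec_row$n, 2)
  expect_equal(spec_row$n_excluded, 1)
  expect_error(cohort_confusion(list()), "no confusion")
})

test_that("Bland-Altman on the unit-variance symmetric case", {
  ba <- bland_altman(c(-1, 0, 1), c(0, 0, 0))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(c(ba$loa_lower, ba$loa_upper), c(-1.96, 1.96))
  expect_equal(ba$loar, 3.92)
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("Bland-Altman matches an independently coded textbook oracle", {
  set.seed(808)
  for (i in 1:50) {
    n <- sample(5:80, 1)
    ref <- rnorm(n, 400, 60)
    dev <- ref + rnorm(n, -20, 40)
    ba <- bland_altman(dev, ref)
    oracle <- ba_oracle(dev, ref)
    expect_equal(ba$bias, oracle$bias, tolerance = 1e-9)
    expect_equal(ba$sd_diff, oracle$sd, tolerance = 1e-9)
    expect_equal(c(ba$loa_lower, ba$loa_upper), oracle$loa,
                 tolerance = 1e-9)
    expect_equal(ba$ci_bias, oracle$ci_bias, tolerance = 1e-9)
    expect_equal(ba$ci_loa_lower, oracle$ci_loa_lower, tolerance = 1e-9)
    expect_equal(ba$ci_loa_upper, oracle$ci_loa_upper, tolerance = 1e-9)
    expect_equal(ba$pearson_r, cor(dev, ref), tolerance = 1e-12)
  }
})

test_that("agreement degenerates and symmetrises correctly", {
  x <- c(300, 350, 400, 450)
  same <- bland_altman(x, x)
  expect_equal(same$bias, 0)
  expect_equal(same$loar, 0)
  expect_true(is.na(same$pearson_r) || same$pearson_r == 1)

  set.seed(909)
  ref <- rnorm(30, 400, 50)
  dev <- ref + rnorm(30, -15, 30)
  ab <- bland_altman(dev, ref)
  ba <- bland_altman(ref, dev)
  expect_equal(ab$bias, -ba$bias)
  expect_equal(ab$loa_lower, -ba$loa_upper)
  expect_equal(ab$loar, ba$loar)
  expect_equal(abs(ab$pearson_r), abs(ba$pearson_r))
})

test_that("LoAR recovers the published precision from printed limits", {
  expect_equal(loa_range(-86, 44), 130)
  expect_equal(loa_range(-148, 85), 233)
})

test_that("extreme reference sleepers are excluded at 2 SD and the
           analysis recomputes on the remainder", {
  mk_vars <- function(tst) {
    data.frame(id = paste0("n", seq_along(tst)),
               sleep_interval_min = tst + 30,
               total_sleep_time_min = tst,
               sleep_latency_min = rep(10, length(tst)),
               waso_min = rep(30, length(tst)),
               sleep_efficiency_pct = rep(85, length(tst)),
               awakening_index_per_h = rep(1, length(tst)),
               no_sleep = FALSE)
  }
  ref_tst <- c(400, 395, 405, 398, 402, 290)
  set.seed(10)
  dev_tst <- ref_tst + rnorm(6, -10, 15)
  device <- mk_vars(dev_tst)
  reference <- mk_vars(ref_tst)
  # oracle: threshold arithmetic on the reference TST
  out_expect <- reference$id[abs(ref_tst - mean(ref_tst)) >
                               2 * sd(ref_tst)]
  res <- outlier_sensitivity(device, reference)
  expect_equal(res$excluded_ids, out_expect)
  expect_equal(length(out_expect), 1)
  tst_row <- res$retained[res$retained$variable == "total_sleep_time_min", ]
  expect_equal(tst_row$n, 5)

  # no value beyond 2 SD -> identical to the full analysis
  ref2 <- mk_vars(c(400, 395, 405, 398, 402))
  dev2 <- mk_vars(c(390, 380, 420, 399, 410))
  res2 <- outlier_sensitivity(dev2, ref2)
  expect_equal(res2$excluded_ids, character(0))
  expect_equal(res2$retained, res2$full)
})

test_that("agreement tables pair nights by id and name unmatched ones", {
  a <- data.frame(id = c("x", "y", "z"), total_sleep_time_min = 1:3)
  b <- data.frame(id = c("x", "q", "z"), total_sleep_time_min = 1:3)
  expect_error(agreement_table(a, b), "y")
})
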