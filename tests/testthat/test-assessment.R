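test_that("truth tables count the four cells correctly", {
  t0 <- truth_table(rep(TRUE, 10), rep(TRUE, 10))
  expect_identical(c(t0$TP, t0$FN, t0$FP, t0$TN), c(10L, 0L, 0L, 0L))

  # 106-fraction fixture encoding the all-major row counts (18, 51, 8, 29)
  flags <- c(rep(TRUE, 18), rep(FALSE, 51), rep(TRUE, 8), rep(FALSE, 29))
  viols <- c(rep(TRUE, 69), rep(FALSE, 37))
  t1 <- truth_table(flags, viols)
  expect_identical(c(t1$TP, t1$FN, t1$FP, t1$TN), c(18L, 51L, 8L, 29L))
  expect_identical(t1$total, 106L)

  set.seed(9)
  for (rep in 1:5) {
    f <- runif(50) < 0.3; v <- runif(50) < 0.4
    t <- truth_table(f, v)
    # brute-force four-way tally
    tab <- c(sum(f & v), sum(!f & v), sum(f & !v), sum(!f & !v))
    expect_identical(c(t$TP, t$FN, t$FP, t$TN), as.integer(tab))
    expect_identical(t$TP + t$FN + t$FP + t$TN, 50L)
  }

  expect_error(truth_table(c(TRUE, FALSE), TRUE), "equal length")
})

test_that("diagnostic metrics implement the five defining ratios", {
  mk <- function(tp, fn, fp, tn)
    truth_table(c(rep(TRUE, tp), rep(FALSE, fn), rep(TRUE, fp), rep(FALSE, tn)),
                c(rep(TRUE, tp + fn), rep(FALSE, fp + tn)))
  m <- diagnostic_metrics(mk(18, 51, 8, 29))
  expect_equal(m$sensitivity, 18 / 69)
  expect_equal(round(100 * m$sensitivity, 1), 26.1)
  expect_equal(m$specificity, 29 / 37)
  expect_equal(m$ppv, 18 / 26)
  expect_equal(m$npv, 29 / 80)
  expect_equal(m$accuracy, 47 / 106)

  # the target-coverage-with-PTV row gives the printed sensitivity maximum
  m2 <- diagnostic_metrics(mk(18, 46, 8, 34))
  expect_equal(round(100 * m2$sensitivity), 28)

  # degenerate denominator is absent, not zero
  m3 <- diagnostic_metrics(mk(0, 0, 5, 5))
  expect_true(is.na(m3$sensitivity))
  expect_equal(m3$specificity, 0.5)
})

test_that("category assessment composes the per-category machinery", {
  cord <- criterion_spec("cord_dmax", "spinal_cord", 48, "limit",
                         v_major = 3, class = "major")
  vals <- c(49.5, 47, 50, 48, 49.45, 46)
  params <- lapply(vals, function(v) c(cord_dmax = v))
  crs <- make_course(c(2, 0.3, 1.8, 0.2, 0.1, 1.9), assessed = 1:6,
                     params = params, planned = c(cord_dmax = 46),
                     n_fractions = 6)
  ev <- art_evaluate(crs, list(cord))
  expect_s3_class(ev, "art_assessment")
  expect_equal(ev$n, 6)

  flags <- c(2, 0.3, 1.8, 0.2, 0.1, 1.9) > 1.5  # recompute manually
  viol <- vals > 49.44
  manual <- truth_table(flags, viol)
  t <- ev$tables$all_major
  expect_identical(c(t$TP, t$FN, t$FP, t$TN),
                   c(manual$TP, manual$FN, manual$FP, manual$TN))
  expect_equal(ev$metrics$all_major$sensitivity,
               diagnostic_metrics(manual)$sensitivity)
  # no target parameters: with/without PTV rows identical, all negative
  expect_identical(unclass(ev$tables$target_with_ptv)[c("TP", "FN", "FP", "TN")],
                   unclass(ev$tables$target_without_ptv)[c("TP", "FN", "FP", "TN")])
  expect_equal(ev$tables$target_with_ptv$TP + ev$tables$target_with_ptv$FN, 0)

  expect_error(assess_categories(crs, list()), "reports")
})

test_that("random-flag baseline: closed forms and Monte-Carlo agreement", {
  # certain flagging
  r1 <- random_flag_sensitivity(p_flag = 1, k = 6, n_patients = 2000, seed = 1)
  expect_equal(r1$closed_form, 1)
  expect_equal(r1$mc_estimate, 1)

  # unconditioned sensitivity is p_flag
  r2 <- random_flag_sensitivity(0.2, 0.15, k = 6, n_patients = 30000,
                                condition_on_flagged = FALSE, seed = 2)
  expect_equal(r2$closed_form, 0.2)
  expect_lt(abs(r2$mc_estimate - 0.2), 3 * r2$mc_se)

  # conditioned closed form p/(1-(1-p)^k) = 0.271 at the defaults
  r3 <- random_flag_sensitivity(0.2, 0.15, k = 6, n_patients = 50000, seed = 3)
  expect_equal(r3$closed_form, 0.2 / (1 - 0.8^6))
  expect_equal(round(100 * r3$closed_form), 27)
  expect_lt(abs(r3$mc_estimate - r3$closed_form), 3 * r3$mc_se)

  expect_error(random_flag_sensitivity(p_flag = 0), "retains no|conditioning")
})

test_that("conditioned sensitivity exceeds p_flag and decays toward it in k", {
  p <- 0.2
  ks <- c(1, 2, 4, 6, 10, 20, 50)
  cf <- p / (1 - (1 - p)^ks)
  expect_true(all(cf >= p))
  expect_true(all(diff(cf) < 0))
  expect_lt(cf[length(ks)] - p, 0.001)
})

test_that("conditioned sensitivity is independent of the violation rate", {
  base <- random_flag_sensitivity(0.2, 0.15, k = 6, n_patients = 40000,
                                  seed = 4)
  for (pv in c(0.05, 0.3, 0.6)) {
    r <- random_flag_sensitivity(0.2, pv, k = 6, n_patients = 40000,
                                 seed = 4 + round(100 * pv))
    expect_equal(r$closed_form, base$closed_form)
    expect_lt(abs(r$mc_estimate - base$closed_form),
              3 * sqrt(r$mc_se^2 + base$mc_se^2) + 3 * base$mc_se)
  }
})
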