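test_that("DVH statistics on hand-computable fixtures", {
  dim3 <- c(10, 1, 1)
  dose <- array(70, dim = dim3)
  mask <- array(TRUE, dim = dim3)
  expect_equal(dvh_parameter(dose, mask, dose_parameter_spec("x", "s", "max")), 70)
  expect_equal(dvh_parameter(dose, mask, dose_parameter_spec("x", "s", "mean")), 70)
  expect_equal(dvh_parameter(dose, mask,
                             dose_parameter_spec("x", "s", "dose_at_volume", 95)), 70)
  expect_equal(dvh_parameter(dose, mask,
                             dose_parameter_spec("x", "s", "volume_at_dose", 49.4)), 100)

  # 10 voxels with doses 1..10: D50% is the 5th-highest (= 6), V6 = 50%
  dose10 <- array(1:10, dim = dim3)
  expect_equal(dvh_parameter(dose10, mask,
                             dose_parameter_spec("x", "s", "dose_at_volume", 50)), 6)
  expect_equal(dvh_parameter(dose10, mask,
                             dose_parameter_spec("x", "s", "volume_at_dose", 6)), 50)

  # cord-PRV style fixture: 13 of 1000 voxels at/above the violation dose
  d3 <- c(10, 10, 10)
  prv_dose <- array(40, dim = d3); prv_dose[1:13] <- 49.5
  prv_mask <- array(TRUE, dim = d3)
  expect_equal(dvh_parameter(prv_dose, prv_mask,
                             dose_parameter_spec("v", "prv", "volume_at_dose", 49.44)),
               1.3)

  expect_error(dvh_parameter(dose, array(FALSE, dim = dim3),
                             dose_parameter_spec("x", "cord", "max")), "cord")
})

test_that("DVH statistics agree exactly with a sort-based oracle", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(50:1000, 1)
    dims <- c(n, 1, 1)
    dose <- array(round(runif(n, 0, 80), 3), dim = dims)
    mask <- array(TRUE, dim = dims)
    x <- runif(1, 1, 100)
    lvl <- runif(1, 1, 80)
    sorted <- sort(as.vector(dose), decreasing = TRUE)
    expect_identical(
      dvh_parameter(dose, mask, dose_parameter_spec("d", "s", "dose_at_volume", x)),
      sorted[ceiling(x / 100 * n)])
    expect_identical(
      dvh_parameter(dose, mask, dose_parameter_spec("v", "s", "volume_at_dose", lvl)),
      100 * sum(as.vector(dose) >= lvl) / n)
  }
})

test_that("DVH statistics are monotone in their levels", {
  set.seed(13)
  dims <- c(200, 1, 1)
  dose <- array(runif(200, 0, 75), dim = dims)
  mask <- array(TRUE, dim = dims)
  dmax <- dvh_parameter(dose, mask, dose_parameter_spec("m", "s", "max"))
  xs <- c(2, 20, 50, 95, 100)
  dx <- vapply(xs, function(x)
    dvh_parameter(dose, mask, dose_parameter_spec("d", "s", "dose_at_volume", x)),
    numeric(1))
  expect_true(all(dmax >= dx))
  expect_true(all(diff(dx) <= 0))
  vs <- vapply(c(10, 30, 50, 70), function(lvl)
    dvh_parameter(dose, mask, dose_parameter_spec("v", "s", "volume_at_dose", lvl)),
    numeric(1))
  expect_true(all(diff(vs) <= 0))
})

test_that("fraction parameter extraction composes dvh_parameter", {
  ph <- test_phantom()
  specs <- list(dose_parameter_spec("cord_dmax", "spinal_cord", "max"),
                dose_parameter_spec("ptv_low_d95", "ptv_low",
                                    "dose_at_volume", 95,
                                    exclude = "ptv_high"))
  vals <- extract_fraction_parameters(ph$dose, ph$structures, specs)
  expect_named(vals, c("cord_dmax", "ptv_low_d95"))
  expect_identical(vals[["cord_dmax"]],
                   max(ph$dose[ph$structures$masks$spinal_cord]))
  lowmask <- ph$structures$masks$ptv_low & !ph$structures$masks$ptv_high
  expect_identical(vals[["ptv_low_d95"]],
                   dvh_parameter(ph$dose, lowmask,
                                 dose_parameter_spec("x", "s", "dose_at_volume", 95)))
  expect_length(extract_fraction_parameters(ph$dose, ph$structures, list()), 0)
  expect_error(extract_fraction_parameters(
    ph$dose, ph$structures,
    list(dose_parameter_spec("oops", "no_such_structure", "max"))), "oops")
})

test_that("course interpolation: linear inside, hold outside, mean overall", {
  s <- interpolate_series(c(1, 6), c(100, 110), n_fractions = 10)
  expect_equal(s$values[3], 104)
  expect_equal(s$values[1:6], c(100, 102, 104, 106, 108, 110))
  expect_equal(s$values[7:10], rep(110, 4))  # hold after last assessed

  s1 <- interpolate_series(10, 50, n_fractions = 33)
  expect_equal(s1$values, rep(50, 33))
  expect_equal(s1$accumulated, 50)

  s2 <- interpolate_series(c(1, 33), c(0, 33), n_fractions = 33)
  expect_equal(s2$accumulated, mean(seq(0, 33, length.out = 33)))  # 16.5
  expect_equal(s2$accumulated, 16.5)

  # assessed values reproduced exactly
  set.seed(3)
  fx <- sort(sample(1:33, 6)); v <- runif(6, 40, 70)
  s3 <- interpolate_series(fx, v, 33)
  expect_equal(s3$values[fx], v)

  expect_error(interpolate_series(integer(0), numeric(0), 33),
               "at least one")
  expect_error(interpolate_series(40, 5, 33), "1..n_fractions")
})

test_that("accumulate_course interpolates every recorded parameter", {
  params <- list(c(a = 10, b = 1), c(a = 20, b = 1), c(a = 30, b = 1))
  crs <- make_course(c(0.2, 0.3, 0.4), assessed = c(1, 5, 9),
                     params = params, n_fractions = 10)
  acc <- accumulate_course(crs)
  expect_named(acc, c("a", "b"))
  expect_equal(acc$b$accumulated, 1)
  expect_equal(acc$a$values[3], 15)  # midway between fx1=10 and fx5=20
  expect_equal(acc$a$values[10], 30)
})
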