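test_that("survey aggregation takes medians with the even-count convention", {
  expect_equal(unname(aggregate_survey(list(p = c(3, 3, 5, 5, 10)))), 5)
  expect_equal(unname(aggregate_survey(list(p = c(2, 4)))), 3)
  expect_equal(unname(aggregate_survey(list(p = 7))), 7)
  expect_error(aggregate_survey(list(p = numeric(0))), "no survey")
  expect_error(aggregate_survey(list(p = c(3, -1))), "must be finite")
})

test_that("violation thresholds: the cord anchor and both directions", {
  cord <- criterion_spec("cord_dmax", "spinal_cord", 48, "limit",
                         v_major = 3, class = "major")
  expect_equal(violation_threshold(cord, "major"), 49.44)
  expect_equal(round(violation_threshold(cord, "major"), 1), 49.4)

  cov <- criterion_spec("d95", "ptv_high", 66.5, "coverage", v_major = 5)
  expect_equal(violation_threshold(cov, "major"), 63.175)

  zero <- criterion_spec("x", "s", 50, "limit", v_major = 0)
  expect_equal(violation_threshold(zero, "major"), 50)

  expect_error(violation_threshold(cord, "minor"), "no minor margin")
  expect_error(criterion_spec("x", "s", 50, v_major = 2, v_minor = 5),
               "v_major")
})

test_that("fraction grading: strict breach, severity and categories", {
  cord <- criterion_spec("cord_dmax", "spinal_cord", 48, "limit",
                         v_major = 3, class = "major")
  # 49.3 Gy does not breach the 49.44 Gy threshold
  r1 <- grade_fraction(c(cord_dmax = 49.3), NULL, list(cord))
  expect_identical(unname(r1$status), "none")
  expect_false(any(r1$categories))
  # a value exactly at threshold is not a violation
  r0 <- grade_fraction(c(cord_dmax = 49.44), NULL, list(cord))
  expect_identical(unname(r0$status), "none")
  # 49.5 Gy is a major OAR violation
  r2 <- grade_fraction(c(cord_dmax = 49.5), NULL, list(cord))
  expect_identical(unname(r2$status), "major")
  expect_true(r2$categories[["all_major"]])
  expect_true(r2$categories[["all_major_excl_ptv"]])
  expect_true(r2$categories[["oar"]])
  expect_false(r2$categories[["target_with_ptv"]])
  expect_false(r2$categories[["target_without_ptv"]])

  expect_error(grade_fraction(c(other = 1), NULL, list(cord)), "cord_dmax")
})

test_that("planned parameter values never violate their own criteria", {
  ph <- test_phantom()
  rep <- grade_fraction(ph$planned_parameters, ph$planned_parameters,
                        default_criteria())
  expect_true(all(rep$status == "none"))
  expect_false(any(rep$categories))
})

test_that("grading is order-independent and categories nest correctly", {
  criteria <- default_criteria()
  set.seed(17)
  ph <- test_phantom()
  planned <- ph$planned_parameters
  for (rep in 1:10) {
    vals <- planned * runif(length(planned), 0.85, 1.15)
    names(vals) <- names(planned)
    a <- grade_fraction(vals, planned, criteria)
    b <- grade_fraction(vals, planned, sample(criteria))
    expect_identical(a$status[order(names(a$status))],
                     b$status[order(names(b$status))])
    expect_identical(a$categories, b$categories)
    # GTV/CTV violations imply the with-PTV category
    if (a$categories[["target_without_ptv"]])
      expect_true(a$categories[["target_with_ptv"]])
    # dropping PTV parameters cannot create an excluding-PTV violation
    if (a$categories[["all_major_excl_ptv"]])
      expect_true(a$categories[["all_major"]])
  }
})

test_that("criteria YAML round-trips and the shipped default file loads", {
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_criteria(default_criteria(), tf)
  back <- read_criteria(tf)
  expect_length(back, length(default_criteria()))
  expect_identical(vapply(back, function(x) x$parameter, character(1)),
                   vapply(default_criteria(), function(x) x$parameter,
                          character(1)))

  shipped <- read_criteria(system.file("extdata", "default_criteria.yaml",
                                       package = "artflag"))
  cord <- shipped[[which(vapply(shipped, function(x) x$parameter,
                                character(1)) == "cord_dmax")]]
  expect_equal(violation_threshold(cord, "major"), 49.44)

  # a "planned" reference needs planned values
  ptv <- shipped[[which(vapply(shipped, function(x) x$parameter,
                               character(1)) == "ptv_high_d95")]]
  expect_error(violation_threshold(ptv, "major"), "planned")
  expect_equal(violation_threshold(ptv, "major",
                                   planned = c(ptv_high_d95 = 70)), 66.5)
})
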