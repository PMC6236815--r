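test_that("central-axis dose change follows the exponential depth model", {
  expect_equal(central_axis_dose_change(0), 0)
  # 15-cm cylinder losing 1.5 cm of radius: ~5% at 6 MV
  expect_equal(round(100 * central_axis_dose_change(1.5, 0.035)), 5)
  expect_equal(central_axis_dose_change(1.5, 0.035), exp(0.035 * 1.5) - 1)
  # first-order limit
  for (d in c(1e-3, 1e-5)) {
    expect_equal(central_axis_dose_change(d, 0.035) / (0.035 * d), 1,
                 tolerance = 1e-3)
  }
  expect_error(central_axis_dose_change(1, mu = 0), "positive")
})

test_that("the default phantom plan meets its planning objectives", {
  ph <- test_phantom()
  m <- ph$structures$masks
  # high-dose PTV: >= 95% of voxels at >= 95% of prescription
  expect_gte(mean(ph$dose[m$ptv_high] >= 0.95 * 70), 0.95)
  expect_gte(ph$planned_parameters[["ptv_high_d95"]], 0.95 * 70)
  # spinal cord entirely outside the 49.44 Gy violation isodose
  expect_lt(max(ph$dose[m$spinal_cord]), 49.44)
  # zero margins collapse the target recipe (ptv_low minus ptv_high would
  # be empty, so evaluate no parameters)
  ph0 <- build_phantom(margins = margin_spec(0, 0, 0, 0, 0), specs = list())
  expect_identical(ph0$structures$masks$gtv_high, ph0$structures$masks$ptv_high)
})

test_that("an identity course changes nothing", {
  ph <- test_phantom()
  crs <- simulate_course(ph, scenario_config("none", noise_sd = 0))
  idx <- assessed_indices(crs)
  expect_identical(idx, c(5L, 10L, 15L, 20L, 25L, 30L))
  for (f in crs$fractions[idx]) {
    expect_equal(f$contour_change, 0)
    expect_false(f$flagged)
    expect_equal(f$parameters, ph$planned_parameters)
  }
})

test_that("weight loss erodes the contour at the configured rate and flags late", {
  ph <- test_phantom()
  sc <- scenario_config("weight_loss", shrink_rate = 0.05, noise_sd = 0)
  crs <- simulate_course(ph, sc)
  idx <- assessed_indices(crs)
  tol <- sqrt(2) * ph$grid$spacing[1]
  for (f in crs$fractions[idx])
    expect_equal(f$contour_change, 0.05 * f$fraction_index, tolerance = tol)
  # first flag at the first assessed fraction whose change exceeds 1.5 cm
  sc2 <- scenario_config("weight_loss", shrink_rate = 0.1, noise_sd = 0)
  crs2 <- simulate_course(ph, sc2)
  flags <- vapply(crs2$fractions[assessed_indices(crs2)],
                  function(f) f$flagged, logical(1))
  changes <- vapply(crs2$fractions[assessed_indices(crs2)],
                    function(f) f$contour_change, numeric(1))
  expect_identical(flags, changes > 1.5)
  expect_true(any(flags))
})

test_that("pure shrinkage (no advection) monotonically raises hot-spot doses", {
  ph <- test_phantom()
  sc <- scenario_config("weight_loss", shrink_rate = 0.06, noise_sd = 0,
                        advect_soft_tissue = FALSE)
  crs <- simulate_course(ph, sc)
  idx <- assessed_indices(crs)
  cord <- vapply(crs$fractions[idx],
                 function(f) f$parameters[["cord_dmax"]], numeric(1))
  hot <- vapply(crs$fractions[idx],
                function(f) f$parameters[["ptv_high_dmax"]], numeric(1))
  expect_true(all(diff(cord) > 0))
  expect_true(all(diff(hot) > 0))
  expect_true(all(cord > ph$planned_parameters[["cord_dmax"]]))
})

test_that("edema reproduces the tumor volume-ratio trajectory", {
  # finer grid so voxelization error stays inside the 2% tolerance
  grid <- voxel_grid(c(120, 74, 45), spacing = c(0.15, 0.15, 0.15),
                     origin = c(-9, -5.5, 2.2))
  an <- default_anatomy()
  an$z_range <- c(2.3, 8.9)
  an$brainstem$z_range <- c(8.0, 8.9)
  ph <- build_phantom(grid = grid, anatomy = an)
  sc <- scenario_config("localized_edema", noise_sd = 0)
  v0 <- sum(ph$structures$masks$ctv_high)
  v8 <- sum(fraction_anatomy(ph, sc, 8)$masks$ctv_high)
  v33 <- sum(fraction_anatomy(ph, sc, 33)$masks$ctv_high)
  expect_equal(v8 / v0, 1.256, tolerance = 0.02)
  expect_equal(v33 / v0, 0.598, tolerance = 0.02)
})

test_that("edema contour change peaks at the configured peak fraction", {
  ph <- test_phantom()
  sc <- scenario_config("localized_edema", noise_sd = 0,
                        schedule = c(2, 5, 8, 14, 20, 26, 33))
  crs <- simulate_course(ph, sc)
  idx <- assessed_indices(crs)
  cc <- vapply(crs$fractions[idx], function(f) f$contour_change, numeric(1))
  expect_equal(idx[which.max(cc)], 8L)
})

test_that("a systematic lateral target shift degrades high-dose coverage", {
  ph <- test_phantom()
  for (shift in c(0.5, 1.0)) {
    sc <- scenario_config("none", target_shift = c(shift, 0, 0),
                          noise_sd = 0)
    crs <- simulate_course(ph, sc)
    d95 <- crs$fractions[[5]]$parameters[["ptv_high_d95"]]
    expect_lt(d95, ph$planned_parameters[["ptv_high_d95"]])
  }
})

test_that("every simulated fraction satisfies the structure-set invariants", {
  ph <- test_phantom()
  for (kind in c("weight_loss", "localized_edema", "shoulder_shift")) {
    sc <- scenario_config(kind, shrink_rate = 0.07, noise_sd = 0)
    for (f in c(8L, 33L)) {
      ss <- fraction_anatomy(ph, sc, f)  # constructor validates containment
      expect_s3_class(ss, "structure_set")
      expect_true(any(ss$masks$gtv_high))
      expect_true(all(ss$masks$external[ss$masks$ptv_low]))
    }
  }
})

test_that("cohort simulation is reproducible and a null cohort is silent", {
  ph <- test_phantom()
  c1 <- simulate_cohort(3, seed = 11, phantom = ph)
  c2 <- simulate_cohort(3, seed = 11, phantom = ph)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_course_csv(c1, f1); write_course_csv(c2, f2)
  expect_identical(readLines(f1), readLines(f2))

  null_cohort <- simulate_cohort(2, mix = c(none = 1), seed = 5, phantom = ph)
  ev <- art_evaluate(null_cohort)
  flags <- unlist(lapply(attr(ev, "courses"), function(cr)
    vapply(cr$fractions, function(f) f$flagged, logical(1))))
  expect_false(any(flags))
  for (t in ev$tables) expect_equal(t$TP + t$FN + t$FP, 0)
})
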