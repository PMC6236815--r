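#' Scenario configuration for the synthetic cohort generator
#'
#' Emulates the interfractional anatomy changes the flag is meant to catch:
#' `weight_loss` erodes the external contour radially at a constant rate
#' with soft-tissue structures advected proportionally toward the eroded
#' surface (bony frame fixed); `localized_edema` scales the tumor volumes
#' along a piecewise-linear volume-ratio trajectory (1 at plan, 1.256 at the
#' peak fraction 8, 0.598 at fraction 33) with a matching local external
#' bulge; `shoulder_shift` displaces the external contour of the inferior
#' (shoulder) slices by a constant setup-error vector; `composite` combines
#' weight loss with a systematic target shift. CBCT assessment defaults to
#' approximately every five fractions, optionally also the first three.
#'
#' @param kind scenario kind.
#' @param shrink_rate radial erosion rate, cm per fraction (weight loss).
#' @param edema_peak_fraction changepoint fraction, default 8.
#' @param edema_peak_ratio tumor volume ratio at the peak, default 1.256.
#' @param edema_end_ratio volume ratio at end of course, default 0.598.
#' @param edema_bulge_gain ratio of the local external bulge amplitude to
#'   the CTV radius change (peritumoral soft-tissue swelling; the CTV
#'   radius change alone is sub-voxel), default 8.
#' @param edema_shift_gain ratio of the target-center displacement (toward
#'   the nearest surface) to the CTV radius change, default 3; asymmetric
#'   growth is what degrades target coverage.
#' @param shoulder_shift length-2 shift (x, y) in cm of the shoulder slices.
#' @param target_shift length-3 constant displacement (cm) of the target
#'   volumes in the bony frame.
#' @param advect_soft_tissue advect targets/parotids under weight loss.
#' @param noise_sd sd (cm) of the zero-mean Gaussian added to the measured
#'   contour change (therapist measurement uncertainty), default 0.1.
#' @param schedule assessed (CBCT) fraction indices; `NULL` = every 5.
#' @param include_first_three also assess fractions 1-3.
#' @param seed optional RNG seed used by [simulate_course()].
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(kind = c("none", "weight_loss", "localized_edema",
                                     "shoulder_shift", "composite"),
                            shrink_rate = 0.05,
                            edema_peak_fraction = 8L,
                            edema_peak_ratio = 1.256,
                            edema_end_ratio = 0.598,
                            edema_bulge_gain = 8,
                            edema_shift_gain = 3,
                            shoulder_shift = c(0.8, 0),
                            target_shift = c(0, 0, 0),
                            advect_soft_tissue = TRUE,
                            noise_sd = 0.1,
                            schedule = NULL,
                            include_first_three = FALSE,
                            seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(shrink_rate >= 0, edema_peak_ratio > 0, edema_end_ratio > 0,
            noise_sd >= 0, edema_peak_fraction >= 1)
  structure(list(kind = kind, shrink_rate = shrink_rate,
                 edema_peak_fraction = as.integer(edema_peak_fraction),
                 edema_peak_ratio = edema_peak_ratio,
                 edema_end_ratio = edema_end_ratio,
                 edema_bulge_gain = edema_bulge_gain,
                 edema_shift_gain = edema_shift_gain,
                 shoulder_shift = rep_len(shoulder_shift, 2L),
                 target_shift = rep_len(target_shift, 3L),
                 advect_soft_tissue = isTRUE(advect_soft_tissue),
                 noise_sd = noise_sd, schedule = schedule,
                 include_first_three = isTRUE(include_first_three),
                 seed = seed),
            class = "scenario_config")
}

cbct_schedule <- function(scenario, n_fractions) {
  s <- scenario$schedule
  if (is.null(s)) s <- seq(5L, n_fractions, by = 5L)
  if (scenario$include_first_three) s <- c(1L, 2L, 3L, s)
  s <- sort(unique(as.integer(s)))
  if (any(s < 1L | s > n_fractions))
    stop("CBCT schedule must lie within 1..n_fractions", call. = FALSE)
  s
}

#' Simple megavoltage beam model
#'
#' Two opposed lateral 6 MV beams in the bony frame. Beyond build-up the
#' central-axis dose falls off approximately exponentially with tissue
#' depth; `mu` is the fractional falloff per cm (default 0.035/cm, which
#' lands the classic worked example: a 1.5 cm reduction in the radius of a
#' 15 cm cylinder gives a ~5% increase in central-axis dose). `penumbra_sd`
#' is the Gaussian lateral penumbra width of the planned conformal dose.
#'
#' @param mu fractional dose falloff per cm of tissue path, > 0.
#' @param penumbra_sd lateral penumbra sigma in cm, > 0.
#' @param directions beam entry directions (fixed lateral pair).
#' @return Object of class `beam_model`.
#' @export
beam_model <- function(mu = 0.035, penumbra_sd = 0.3,
                       directions = c("left", "right")) {
  stopifnot(mu > 0, penumbra_sd > 0)
  structure(list(mu = mu, penumbra_sd = penumbra_sd, directions = directions),
            class = "beam_model")
}

#' Fractional central-axis dose change for a tissue-path reduction
#'
#' Exponential percent-depth-dose model beyond build-up: a reduction of
#' `depth_reduction` cm in the tissue path to a point multiplies its dose by
#' `exp(mu * depth_reduction)`; the fractional change is that factor minus
#' one. With `mu = 0.035`/cm, a 1.5 cm depth reduction (a 15-cm-diameter
#' cylinder losing 1.5 cm of radius) gives ~5%.
#'
#' @param depth_reduction reduction in tissue path, cm (negative = added
#'   tissue).
#' @param mu fractional falloff per cm, > 0.
#' @return Fractional dose change (e.g. 0.054 for +5.4%).
#' @examples
#' round(100 * central_axis_dose_change(1.5))  # 5
#' @export
central_axis_dose_change <- function(depth_reduction, mu = 0.035) {
  if (mu <= 0) stop("`mu` must be positive", call. = FALSE)
  exp(mu * depth_reduction) - 1
}

#' Default phantom anatomy (cm, bony/room frame)
#'
#' An elliptic-cylinder neck with wider shoulder slices inferiorly, a
#' spherical GTV, a posterior spinal-cord cylinder (bony frame, never
#' moves), a superior brainstem cylinder and lateral parotid spheres. The
#' positions place the planned spinal-cord Dmax in the mid-40s Gy — below,
#' but within reach of, the 49.4 Gy violation dose under late-course
#' shrinkage.
#'
#' @return List of analytic shape parameters consumed by [build_phantom()].
#' @export
default_anatomy <- function() {
  list(
    neck = list(a = 5.5, b = 4.5),
    shoulder = list(a = 8.2, b = 4.0, z_top = 2.5),
    z_range = c(0, 10),
    gtv = list(center = c(1.2, 0.62, 6.0), radius = 1.0),
    cord = list(center = c(0.5, -2.76), radius = 0.4),
    brainstem = list(center = c(0.5, -2.2), radius = 0.5,
                     z_range = c(8.5, 10)),
    parotid_left = list(center = c(-4.3, 0.9, 6.0), radius = 1.0),
    parotid_right = list(center = c(4.3, 0.9, 6.0), radius = 1.0)
  )
}

#' Default grid for the phantom (0.25 cm isotropic)
#' @return A [voxel_grid()] covering the default anatomy.
#' @export
default_grid <- function() {
  voxel_grid(c(72L, 44L, 40L), spacing = c(0.25, 0.25, 0.25),
             origin = c(-9, -5.5, 0))
}

#' Default DVH parameter set tracked per fraction
#'
#' Spinal-cord and brainstem Dmax, cord-PRV volume receiving the cord
#' violation dose (V49.4 Gy, evaluated at the exact 48 Gy + 3% threshold),
#' target D95%/D99% coverage (the low-dose PTV evaluated excluding the
#' high-dose PTV volume), the high-dose PTV hot spot, and parotid mean
#' doses.
#'
#' @param include_parotids include the parotid Dmean parameters.
#' @return List of [dose_parameter_spec()]s.
#' @export
default_parameter_specs <- function(include_parotids = TRUE) {
  sp <- list(
    dose_parameter_spec("cord_dmax", "spinal_cord", "max"),
    dose_parameter_spec("cord_prv_v49.4", "spinal_cord_prv", "volume_at_dose",
                        level = 48 * 1.03),
    dose_parameter_spec("brainstem_dmax", "brainstem", "max"),
    dose_parameter_spec("gtv_high_d99", "gtv_high", "dose_at_volume", 99),
    dose_parameter_spec("ctv_high_d99", "ctv_high", "dose_at_volume", 99),
    dose_parameter_spec("ctv_low_d99", "ctv_low", "dose_at_volume", 99),
    dose_parameter_spec("ptv_high_d95", "ptv_high", "dose_at_volume", 95),
    dose_parameter_spec("ptv_high_d99", "ptv_high", "dose_at_volume", 99),
    dose_parameter_spec("ptv_high_dmax", "ptv_high", "max"),
    dose_parameter_spec("ptv_low_d95", "ptv_low", "dose_at_volume", 95,
                        exclude = "ptv_high")
  )
  if (include_parotids) sp <- c(sp, list(
    dose_parameter_spec("parotid_left_dmean", "parotid_left", "mean"),
    dose_parameter_spec("parotid_right_dmean", "parotid_right", "mean")
  ))
  sp
}

# ---- analytic rasterization -------------------------------------------------

ellipse_radius <- function(theta, a, b) {
  a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
}

# Angular weighting of weight-loss erosion: soft tissue is lost laterally
# (cheeks/neck fat, full rate) and barely at all posteriorly over the
# spine, keeping the bony frame inside the body at realistic total losses.
erosion_weight <- function(theta) 0.15 + 0.85 * cos(theta)^2

# Per-fraction analytic state of the anatomy.
anatomy_state <- function(anatomy, scenario, f, n_fractions, margins) {
  d <- 0; scale <- 1; bulge_amp <- 0
  tcen <- anatomy$gtv$center
  pl <- anatomy$parotid_left$center
  pr <- anatomy$parotid_right$center
  sh <- c(0, 0)
  kind <- scenario$kind
  r_ctv <- anatomy$gtv$radius + margins$ctv_from_gtv
  if (kind %in% c("weight_loss", "composite")) {
    d <- scenario$shrink_rate * f
    if (scenario$advect_soft_tissue && d > 0) {
      advect <- function(p) {
        th <- atan2(p[2], p[1])
        re <- ellipse_radius(th, anatomy$neck$a, anatomy$neck$b)
        c(p[1:2] * max(0, 1 - d * erosion_weight(th) / re), p[-(1:2)])
      }
      tcen <- advect(tcen); pl <- advect(pl); pr <- advect(pr)
    }
  }
  if (kind == "localized_edema") {
    fp <- scenario$edema_peak_fraction
    ratio <- if (f <= fp) 1 + (scenario$edema_peak_ratio - 1) * f / fp
    else scenario$edema_peak_ratio +
      (scenario$edema_end_ratio - scenario$edema_peak_ratio) *
      (f - fp) / (n_fractions - fp)
    scale <- ratio^(1 / 3)
    # peritumoral swelling bulges the adjacent surface by a multiple of the
    # CTV radius change; deflation leaves a shallower local indentation
    dr <- (scale - 1) * r_ctv
    bulge_amp <- scenario$edema_bulge_gain * dr * if (dr >= 0) 1 else 0.3
    th0 <- atan2(anatomy$gtv$center[2], anatomy$gtv$center[1])
    tcen <- tcen + scenario$edema_shift_gain * dr *
      c(cos(th0), sin(th0), 0)
  }
  if (kind == "shoulder_shift") sh <- scenario$shoulder_shift
  if (kind == "composite" || any(scenario$target_shift != 0))
    tcen <- tcen + scenario$target_shift
  list(shrink = d, target_center = tcen, target_scale = scale,
       bulge_amp = bulge_amp,
       bulge_theta = atan2(anatomy$gtv$center[2], anatomy$gtv$center[1]),
       bulge_z = anatomy$gtv$center[3],
       shoulder_shift = sh,
       parotid_left = pl, parotid_right = pr)
}

external_mask <- function(anatomy, state, mesh, grid) {
  x <- mesh$x; y <- mesh$y; z <- mesh$z
  d <- state$shrink
  zr <- anatomy$z_range
  theta <- atan2(y, x)
  r <- sqrt(x^2 + y^2)
  # radial erosion, angularly weighted: full rate laterally so the maximum
  # contour change of a shrink of d measures as ~d (at the lateral axis)
  re <- ellipse_radius(theta, anatomy$neck$a, anatomy$neck$b) -
    d * erosion_weight(theta)
  if (state$bulge_amp != 0) {
    dth <- atan2(sin(theta - state$bulge_theta), cos(theta - state$bulge_theta))
    re <- re + state$bulge_amp *
      exp(-dth^2 / (2 * 0.5^2) - (z - state$bulge_z)^2 / (2 * 1.5^2))
  }
  ztop <- if (is.null(anatomy$shoulder)) zr[1] else anatomy$shoulder$z_top
  neck <- r <= re & z >= ztop & z >= zr[1] & z <= zr[2]
  if (is.null(anatomy$shoulder)) return(neck)
  xs <- x - state$shoulder_shift[1]; ys <- y - state$shoulder_shift[2]
  ths <- atan2(ys, xs)
  shd <- sqrt(xs^2 + ys^2) <=
    ellipse_radius(ths, anatomy$shoulder$a, anatomy$shoulder$b) -
    d * erosion_weight(ths)
  neck | (shd & z < ztop & z >= zr[1])
}

sphere_mask <- function(center, radius, mesh) {
  (mesh$x - center[1])^2 + (mesh$y - center[2])^2 +
    (mesh$z - center[3])^2 <= radius^2
}

cylinder_mask <- function(center_xy, radius, mesh, z_range = NULL) {
  m <- (mesh$x - center_xy[1])^2 + (mesh$y - center_xy[2])^2 <= radius^2
  if (!is.null(z_range)) m <- m & mesh$z >= z_range[1] & mesh$z <= z_range[2]
  m
}

# Rasterize the full structure set for one analytic state. Target margins
# are applied analytically (exact Euclidean dilation of a sphere is a larger
# sphere), so plan-time and per-fraction masks share one voxelization
# convention and an identity scenario reproduces the plan exactly.
rasterize_state <- function(anatomy, state, margins, mesh, grid) {
  ext <- external_mask(anatomy, state, mesh, grid)
  s <- state$target_scale
  r_gtv <- anatomy$gtv$radius * s
  r_ctv <- (anatomy$gtv$radius + margins$ctv_from_gtv) * s
  r_low <- anatomy$gtv$radius + margins$ctv_from_gtv + margins$elective
  tc <- state$target_center
  masks <- list(
    external = ext,
    gtv_high = sphere_mask(tc, r_gtv, mesh) & ext,
    ctv_high = sphere_mask(tc, r_ctv, mesh) & ext,
    ctv_low = sphere_mask(tc, r_low, mesh) & ext,
    ptv_high = sphere_mask(tc, r_ctv + margins$ptv_from_ctv, mesh) & ext,
    ptv_low = sphere_mask(tc, r_low + margins$ptv_from_ctv, mesh) & ext,
    spinal_cord = cylinder_mask(anatomy$cord$center, anatomy$cord$radius,
                                mesh) & ext,
    spinal_cord_prv = cylinder_mask(anatomy$cord$center,
                                    anatomy$cord$radius + margins$prv_cord,
                                    mesh) & ext,
    brainstem = cylinder_mask(anatomy$brainstem$center,
                              anatomy$brainstem$radius, mesh,
                              anatomy$brainstem$z_range) & ext,
    brainstem_prv = cylinder_mask(anatomy$brainstem$center,
                                  anatomy$brainstem$radius +
                                    margins$prv_brainstem, mesh,
                                  anatomy$brainstem$z_range) & ext,
    parotid_left = sphere_mask(state$parotid_left,
                               anatomy$parotid_left$radius, mesh) & ext,
    parotid_right = sphere_mask(state$parotid_right,
                                anatomy$parotid_right$radius, mesh) & ext
  )
  structure_set(masks, grid)
}

# Planned conformal dose: for each voxel, the maximum over prescription
# levels of Rx * conformity, conformity = 1 inside the level's PTV sphere
# and a Gaussian penumbra falloff with distance outside it.
planned_dose_field <- function(anatomy, margins, plan, beam, mesh) {
  tc <- anatomy$gtv$center
  r_hi <- anatomy$gtv$radius + margins$ctv_from_gtv + margins$ptv_from_ctv
  r_lo <- anatomy$gtv$radius + margins$ctv_from_gtv + margins$elective +
    margins$ptv_from_ctv
  dist <- sqrt((mesh$x - tc[1])^2 + (mesh$y - tc[2])^2 + (mesh$z - tc[3])^2)
  s2 <- 2 * beam$penumbra_sd^2
  conf <- function(r) exp(-pmax(dist - r, 0)^2 / s2)
  pmax(plan$prescription_high * conf(r_hi), plan$prescription_low * conf(r_lo))
}

# Tissue path along a lateral beam for every (y, z) row of an external mask:
# index of the first/last in-body voxel along x.
row_entry_exit <- function(ext) {
  n <- dim(ext)
  mat <- matrix(ext, nrow = n[1])
  first <- apply(mat, 2, function(col) match(TRUE, col))
  last <- n[1] + 1L - apply(mat[n[1]:1, , drop = FALSE], 2,
                            function(col) match(TRUE, col))
  list(first = first, last = last)
}

# Multiplicative dose-scaling field: delivered = planned * exp(mu * mean
# reduction in tissue path over the lateral beams), held fixed per (y,z) row.
path_scale_field <- function(ext_plan, ext_cur, beam, grid) {
  n <- dim(ext_plan)
  p <- row_entry_exit(ext_plan); q <- row_entry_exit(ext_cur)
  dl <- (q$first - p$first) * grid$spacing[1]  # left surface moved inward
  dr <- (p$last - q$last) * grid$spacing[1]    # right surface moved inward
  red <- (ifelse(is.na(dl), 0, dl) + ifelse(is.na(dr), 0, dr)) / 2
  red[is.na(p$first) | is.na(q$first)] <- 0
  array(rep(exp(beam$mu * red), each = n[1]), dim = n)
}

#' Build the planning phantom
#'
#' Rasterizes the analytic anatomy on the grid, derives the planning
#' structures by (exact, analytic) margin expansion, and computes the
#' planned conformal dose and the planned DVH parameter values.
#'
#' @param plan a [course_plan()].
#' @param margins a [margin_spec()].
#' @param grid a [voxel_grid()]; default [default_grid()].
#' @param anatomy analytic anatomy; default [default_anatomy()].
#' @param beam a [beam_model()].
#' @param specs DVH parameters to evaluate; default
#'   [default_parameter_specs()].
#' @return Object of class `art_phantom` with elements `structures`
#'   (planning [structure_set()]), `dose` (planned Gy array),
#'   `planned_parameters`, plus the configuration.
#' @export
build_phantom <- function(plan = course_plan(), margins = margin_spec(),
                          grid = default_grid(), anatomy = default_anatomy(),
                          beam = beam_model(),
                          specs = default_parameter_specs()) {
  mesh <- grid_mesh(grid)
  ident <- anatomy_state(anatomy, scenario_config("none"), 0L,
                         plan$n_fractions, margins)
  structures <- rasterize_state(anatomy, ident, margins, mesh, grid)
  if (!any(structures$masks$gtv_high))
    stop("anatomy does not fit on the grid: GTV rasterized empty",
         call. = FALSE)
  dose <- planned_dose_field(anatomy, margins, plan, beam, mesh)
  planned <- extract_fraction_parameters(dose, structures, specs)
  structure(list(plan = plan, margins = margins, grid = grid,
                 anatomy = anatomy, beam = beam, specs = specs, mesh = mesh,
                 structures = structures, dose = dose,
                 planned_parameters = planned),
            class = "art_phantom")
}

#' @export
print.art_phantom <- function(x, ...) {
  cat("<art_phantom>\n")
  print(x$grid)
  print(round(x$planned_parameters, 2))
  invisible(x)
}

#' Anatomy of one simulated fraction
#'
#' Rasterizes the structure set a scenario produces at fraction `f`
#' (exported for inspection and testing of scenario trajectories).
#'
#' @param phantom an [build_phantom()] result.
#' @param scenario a [scenario_config()].
#' @param f fraction index (0 gives the planning anatomy).
#' @return A [structure_set()].
#' @export
fraction_anatomy <- function(phantom, scenario, f) {
  st <- anatomy_state(phantom$anatomy, scenario, f,
                      phantom$plan$n_fractions, phantom$margins)
  rasterize_state(phantom$anatomy, st, phantom$margins, phantom$mesh,
                  phantom$grid)
}

#' Simulate one treatment course
#'
#' For every fraction on the CBCT schedule, transforms the anatomy per the
#' scenario, measures the body-contour change against the planning external
#' (with optional Gaussian measurement noise), rescales the planned dose by
#' the exponential path-length model (dose fixed in the bony frame), and
#' extracts the DVH parameters. The flagging protocol is then applied.
#'
#' @param phantom a [build_phantom()] result.
#' @param scenario a [scenario_config()].
#' @param protocol a [flag_protocol()].
#' @param patient_id identifier for the course.
#' @param keep_geometry store per-assessed-fraction structure sets and dose
#'   arrays in the result's `geometry` attribute (memory-heavy).
#' @param seed RNG seed for the measurement noise; defaults to the
#'   scenario's seed.
#' @return A [course_record()] with flags applied.
#' @export
simulate_course <- function(phantom, scenario = scenario_config(),
                            protocol = flag_protocol(), patient_id = "P1",
                            keep_geometry = FALSE, seed = scenario$seed) {
  stopifnot(inherits(phantom, "art_phantom"),
            inherits(scenario, "scenario_config"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  n <- phantom$plan$n_fractions
  sched <- cbct_schedule(scenario, n)
  ext_plan <- phantom$structures$masks$external
  attr(ext_plan, "grid") <- phantom$grid
  geometry <- list()
  fractions <- lapply(seq_len(n), function(f) {
    if (!f %in% sched) return(fraction_record(f, assessed = FALSE))
    st <- anatomy_state(phantom$anatomy, scenario, f, n, phantom$margins)
    ss <- rasterize_state(phantom$anatomy, st, phantom$margins, phantom$mesh,
                          phantom$grid)
    cur <- ss$masks$external
    attr(cur, "grid") <- phantom$grid
    cc <- body_contour_change(ext_plan, cur)
    measured <- max(0, cc$max_distance +
                      if (scenario$noise_sd > 0)
                        stats::rnorm(1, 0, scenario$noise_sd) else 0)
    dose <- phantom$dose *
      path_scale_field(phantom$structures$masks$external, ss$masks$external,
                       phantom$beam, phantom$grid)
    params <- extract_fraction_parameters(dose, ss, phantom$specs)
    if (keep_geometry)
      geometry[[as.character(f)]] <<- list(structures = ss, dose = dose)
    fraction_record(f, assessed = TRUE, contour_change = measured,
                    parameters = params)
  })
  course <- course_record(patient_id, phantom$plan,
                          phantom$planned_parameters, fractions)
  course <- apply_flag(course, protocol)
  if (keep_geometry) attr(course, "geometry") <- geometry
  course
}

#' Simulate a cohort of patients
#'
#' Draws a scenario kind per patient from `mix`, randomizes the scenario
#' magnitudes within clinically plausible ranges (weight-loss rate 0.03-0.09
#' cm/fraction; shoulder shifts 0.5-1.2 cm; composite adds a 0.3-0.8 cm
#' systematic target shift to weight loss), gives roughly a third of
#' patients the first-three-fractions imaging add-on, and simulates each
#' course on a shared phantom. Fully reproducible from `seed`.
#'
#' @param n_patients number of patients, >= 1.
#' @param mix named probabilities over scenario kinds (normalized).
#' @param seed master RNG seed.
#' @param phantom optional prebuilt [build_phantom()] (built once otherwise).
#' @param protocol a [flag_protocol()].
#' @param noise_sd contour measurement noise sd (cm).
#' @return List of [course_record()]s; the drawn scenario of each course is
#'   attached as attribute `"scenario"`.
#' @export
simulate_cohort <- function(n_patients = 12L,
                            mix = c(weight_loss = 0.35, localized_edema = 0.25,
                                    shoulder_shift = 0.2, composite = 0.1,
                                    none = 0.1),
                            seed = 1L, phantom = NULL,
                            protocol = flag_protocol(), noise_sd = 0.1) {
  stopifnot(n_patients >= 1L, !is.null(names(mix)), all(mix >= 0), sum(mix) > 0)
  if (is.null(phantom)) phantom <- build_phantom()
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  kinds <- sample(names(mix), n_patients, replace = TRUE,
                  prob = mix / sum(mix))
  lapply(seq_len(n_patients), function(i) {
    kind <- kinds[i]
    sc <- scenario_config(
      kind,
      shrink_rate = stats::runif(1, 0.03, 0.09),
      shoulder_shift = c(sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.2), 0),
      target_shift = if (kind == "composite")
        c(sample(c(-1, 1), 1) * stats::runif(1, 0.3, 0.8), 0, 0) else c(0, 0, 0),
      noise_sd = noise_sd,
      include_first_three = stats::runif(1) < 1 / 3,
      seed = sample.int(.Machine$integer.max, 1)
    )
    crs <- simulate_course(phantom, sc, protocol,
                           patient_id = sprintf("P%02d", i))
    attr(crs, "scenario") <- sc
    crs
  })
}
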