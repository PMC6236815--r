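# Shared fixtures, all built in code.

# One default phantom per test run (deterministic, ~0.15 s to build).
test_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_phantom()
    cache
  }
})

# Dense point sampling of a circle of given radius (cm).
circle_points <- function(radius, n = 2000, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

# Stacked circular-cylinder external mask with per-slice radii.
cylinder_external <- function(radii, grid, center = c(0, 0)) {
  mesh <- grid_mesh(grid)
  m <- empty_mask(grid)
  for (k in seq_along(radii)) {
    m[, , k] <- (mesh$x[, , k] - center[1])^2 +
      (mesh$y[, , k] - center[2])^2 <= radii[k]^2
  }
  attr(m, "grid") <- grid
  m
}

# Brute-force symmetric Hausdorff distance by explicit double loops.
brute_hausdorff <- function(a, b) {
  dmin_over <- function(p, q) {
    vapply(seq_len(nrow(p)), function(i)
      min(sqrt((q[, 1] - p[i, 1])^2 + (q[, 2] - p[i, 2])^2)), numeric(1))
  }
  max(max(dmin_over(a, b)), max(dmin_over(b, a)))
}

# Minimal course: given per-fraction contour changes at assessed fractions
# and a named list of per-fraction parameter vectors (optional).
make_course <- function(changes, assessed = seq_along(changes),
                        params = NULL, planned = NULL,
                        n_fractions = max(assessed, 10L), id = "T") {
  plan <- course_plan(n_fractions = n_fractions)
  fx <- lapply(seq_len(n_fractions), function(f) {
    i <- match(f, assessed)
    if (is.na(i)) return(fraction_record(f, assessed = FALSE))
    fraction_record(f, assessed = TRUE, contour_change = changes[i],
                    parameters = if (!is.null(params)) params[[i]])
  })
  course_record(id, plan, planned, fx)
}
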