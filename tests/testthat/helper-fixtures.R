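# Shared fixtures and independent oracles, built in code at test time.

# Unit-peak alpha transient (independent re-statement for fixtures).
alpha_shape <- function(t, onset, tau) {
  s <- (t - onset) / tau
  ifelse(s > 0, s * exp(1 - s), 0)
}

# Conductance pair with the synthetic module's kinetics (150 ms alpha
# kernel), on a grid of step dt_ms.
fixture_conductances <- function(dt_ms, duration_ms = 1000,
                                 g_exc_peak = 5, g_inh_peak = 10) {
  t <- seq(0, duration_ms, by = dt_ms)
  conductance_trace(t,
                    g_exc_peak * alpha_shape(t, 100, 150),
                    g_inh_peak * alpha_shape(t, 120, 150))
}

# Brute-force vector-sum oracle via complex arithmetic.
complex_vector_sum <- function(angles_deg, r) {
  z <- sum(r * exp(1i * angles_deg * pi / 180))
  list(mag = Mod(z), angle = (Arg(z) * 180 / pi) %% 360)
}

# Geometric (nonlinear least-squares) circle fit oracle: minimises
# sum((dist to center - radius)^2) over center, with radius profiled out.
geometric_circle_fit <- function(x, y) {
  obj <- function(c0) {
    d <- sqrt((x - c0[1])^2 + (y - c0[2])^2)
    sum((d - mean(d))^2)
  }
  ctr <- stats::optim(c(mean(x), mean(y)), obj,
                      control = list(reltol = 1e-15))$par
  list(center = ctr,
       radius = mean(sqrt((x - ctr[1])^2 + (y - ctr[2])^2)))
}

# Monte-Carlo polygon-area oracle by rejection sampling in the bounding box.
mc_polygon_area <- function(vertices, n = 1e5, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  xr <- range(vertices[, 1])
  yr <- range(vertices[, 2])
  px <- stats::runif(n, xr[1], xr[2])
  py <- stats::runif(n, yr[1], yr[2])
  inside <- point_in_convex(px, py, vertices)
  p <- mean(inside)
  box <- diff(xr) * diff(yr)
  list(area = p * box, se = sqrt(p * (1 - p) / n) * box)
}

# Vectorised point-in-convex-polygon test (CCW vertices): non-negative
# cross product against every edge.
point_in_convex <- function(px, py, vertices) {
  n <- nrow(vertices)
  inside <- rep(TRUE, length(px))
  for (k in seq_len(n)) {
    a <- vertices[k, ]
    b <- vertices[if (k == n) 1 else k + 1, ]
    cr <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    inside <- inside & cr >= -1e-12
  }
  inside
}

# Constant-velocity synthetic eye trace: linear position at `v` deg/s along
# x, rendered straight into an eye_trace (scale 1 deg/px).
constant_velocity_trace <- function(v, n = 200, fps = 100, sigma = 2) {
  tt <- (seq_len(n) - 1) / fps
  build_eye_trace(cbind(v * tt, 0), rep(FALSE, n), scale = 1,
                  fps = fps, gaussian_sigma = sigma)
}

# Random convex hulls from points in a disk.
random_hull <- function(n_pts, radius, center = c(0, 0), seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  r <- radius * sqrt(stats::runif(n_pts))
  th <- stats::runif(n_pts, 0, 2 * pi)
  convex_hull(cbind(center[1] + r * cos(th), center[2] + r * sin(th)))
}

# IV dataset with an exactly prescribed R-squared: residuals orthogonal to
# the design (1, V) leave the OLS line untouched while setting
# R^2 = SS_signal / (SS_signal + |r|^2).
iv_with_r2 <- function(r2_target, g = 2, e_rev = -60,
                       holds = seq(-80, -40, by = 10)) {
  clean <- g * (holds - e_rev)
  resid0 <- stats::residuals(stats::lm(holds^2 ~ holds))
  ss_signal <- sum((clean - mean(clean))^2)
  ss_res <- ss_signal * (1 - r2_target) / r2_target
  peaks <- clean + resid0 / sqrt(sum(resid0^2)) * sqrt(ss_res)
  list(holds = holds, peaks = peaks, n_trials = 1)
}
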