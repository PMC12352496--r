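# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generators do not perturb the session stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

deg2rad <- function(deg) deg * pi / 180

rad2deg <- function(rad) rad * 180 / pi

# Wrap an angle in degrees onto [0, 360).
wrap360 <- function(deg) deg %% 360

# Minimal signed circular difference a - b, in (-180, 180].
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Alpha-function transient, unit peak at t = onset + tau; zero before onset.
alpha_kernel <- function(t, onset, tau) {
  s <- (t - onset) / tau
  ifelse(s > 0, s * exp(1 - s), 0)
}

# Von-Mises-shaped direction-tuning kernel rescaled so f(0) = 1, f(180) = 0.
# `delta_deg` is the angular distance to the preferred direction.
vm_kernel <- function(delta_deg, kappa) {
  (exp(kappa * cos(deg2rad(delta_deg))) - exp(-kappa)) /
    (exp(kappa) - exp(-kappa))
}

# Concentration giving a stated half-width: vm_kernel(half_width) = 0.5.
kappa_from_half_width <- function(half_width_deg) {
  stopifnot(half_width_deg > 0, half_width_deg < 180)
  f <- function(k) vm_kernel(half_width_deg, k) - 0.5
  # kappa -> 0 gives a broad (cosine-like) kernel; large kappa a narrow one.
  stats::uniroot(f, interval = c(1e-6, 500), tol = 1e-10)$root
}

# Gaussian smoothing of a regularly sampled series (sigma in samples),
# reflected at the edges; sigma = 0 returns the input.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  pad <- c(x[pmin(half:1, n)], x, x[pmax(n - (1:half) + 1, 1L)])
  as.numeric(stats::filter(pad, k, sides = 2))[(half + 1L):(half + n)]
}

# Central-difference gradient (one-sided at the edges), per sample.
gradient1 <- function(x) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  g <- numeric(n)
  g[1] <- x[2] - x[1]
  g[n] <- x[n] - x[n - 1]
  if (n > 2L) g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  g
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
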