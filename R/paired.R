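#' Assemble an IV curve from per-hold recordings
#'
#' For each holding potential, trials are averaged and the peak evoked
#' current is taken as the largest absolute deflection from the
#' pre-stimulation baseline within the depolarization epoch (sign
#' preserved). Commanded holds are corrected for the liquid junction
#' potential.
#'
#' @param per_hold Either a list (one element per hold) of
#'   `samples x trials` matrices of current traces, or a numeric matrix /
#'   list of per-trial peak currents (pA) when peaks were measured upstream.
#' @param holds_mv Commanded holding potentials, mV (one per element).
#' @param junction_mv Liquid junction correction added to the commanded
#'   holds, mV (default -10).
#' @param t Time axis for trace input, s.
#' @param epoch `c(start, end)` of the depolarization epoch, s (trace input
#'   only).
#' @param baseline `c(start, end)` of the pre-stimulation baseline, s.
#' @return An `iv_curve`: sorted corrected `holds` (mV), trial-averaged
#'   `peaks` (pA), `n_trials`.
#' @export
build_iv <- function(per_hold, holds_mv, junction_mv = -10,
                     t = NULL, epoch = NULL, baseline = NULL) {
  n_elem <- if (is.matrix(per_hold)) nrow(per_hold) else length(per_hold)
  if (n_elem != length(holds_mv)) {
    stop_invalid("per_hold and holds_mv lengths differ")
  }
  if (length(unique(holds_mv)) < 2) stop_invalid("need >= 2 distinct holds")
  peak_of <- function(x) {
    if (is.matrix(x)) {
      if (is.null(t) || is.null(epoch)) {
        stop_invalid("trace input needs t and epoch")
      }
      avg <- rowMeans(x)
      base_sel <- if (is.null(baseline)) t < epoch[1] else {
        t >= baseline[1] & t <= baseline[2]
      }
      avg <- avg - mean(avg[base_sel])
      seg <- avg[t >= epoch[1] & t <= epoch[2]]
      seg[which.max(abs(seg))]
    } else {
      mean(x)
    }
  }
  if (is.matrix(per_hold)) {
    peaks <- rowMeans(per_hold)
    n_trials <- ncol(per_hold)
  } else {
    peaks <- vapply(per_hold, peak_of, 1)
    n_trials <- if (is.matrix(per_hold[[1]])) {
      ncol(per_hold[[1]])
    } else {
      length(per_hold[[1]])
    }
  }
  holds <- holds_mv + junction_mv
  o <- order(holds)
  structure(list(holds = holds[o], peaks = peaks[o], n_trials = n_trials),
            class = "iv_curve")
}

#' Linear fit of an IV curve: conductance, reversal, quality gate
#'
#' Ordinary least squares of peak current (pA) against holding potential
#' (mV). The slope is the synaptic conductance in nS (pA/mV); the reversal
#' potential is the x-intercept `-b/a`. Recordings are accepted only when
#' the fit's R-squared strictly exceeds 0.80.
#'
#' @param iv An `iv_curve` from [build_iv()] or a list with `holds`, `peaks`.
#' @return A `linear_fit`: `slope_ns`, `intercept_pa`, `e_rev_mv`
#'   (`NA` and flagged when the slope is numerically zero), `r_squared`,
#'   `passes_qc`.
#' @export
fit_iv <- function(iv) {
  v <- iv$holds
  i <- iv$peaks
  if (length(unique(v)) < 2) stop_invalid("zero variance in holds")
  fit <- stats::lm(i ~ v)
  a <- stats::coef(fit)[[2]]
  b <- stats::coef(fit)[[1]]
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((i - mean(i))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  slope_ok <- is.finite(a) && abs(a) > 1e-12
  structure(list(
    slope_ns = a, intercept_pa = b,
    e_rev_mv = if (slope_ok) -b / a else NA_real_,
    reversal_defined = slope_ok,
    r_squared = r2,
    passes_qc = isTRUE(r2 > 0.80)
  ), class = "linear_fit")
}

#' Convex hull of a planar point set
#'
#' @param points An `n x 2` matrix of coordinates, micrometres.
#' @return A `hull_poly`: counterclockwise `vertices` matrix and `area`
#'   (square micrometres, shoelace formula). Fewer than 3 distinct points or
#'   collinear input raise a degenerate-geometry error.
#' @export
convex_hull <- function(points) {
  points <- unique(as.matrix(points))
  if (nrow(points) < 3) stop_invalid("degenerate geometry: need >= 3 points")
  idx <- grDevices::chull(points[, 1], points[, 2])  # clockwise indices
  verts <- points[rev(idx), , drop = FALSE]          # -> counterclockwise
  a <- shoelace_area(verts)
  if (a <= 0) stop_invalid("degenerate geometry: collinear points")
  structure(list(vertices = verts, area = a), class = "hull_poly")
}

shoelace_area <- function(v) {
  x <- v[, 1]
  y <- v[, 2]
  j <- c(2:nrow(v), 1)
  sum(x * y[j] - x[j] * y) / 2
}

# Clip convex polygon `subj` (CCW matrix) by the half-plane left of edge
# a -> b of a CCW clip polygon (Sutherland-Hodgman step).
clip_halfplane <- function(subj, a, b) {
  if (nrow(subj) == 0) return(subj)
  side <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  out <- matrix(numeric(0), 0, 2)
  n <- nrow(subj)
  for (k in seq_len(n)) {
    p <- subj[k, ]
    q <- subj[if (k == n) 1 else k + 1, ]
    sp <- side(p)
    sq <- side(q)
    if (sp >= 0) out <- rbind(out, p)
    if ((sp > 0 && sq < 0) || (sp < 0 && sq > 0)) {
      tt <- sp / (sp - sq)
      out <- rbind(out, p + tt * (q - p))
    }
  }
  out
}

#' Intersection area of two convex hulls
#'
#' Convex-convex polygon clipping (Sutherland-Hodgman); symmetric in its
#' arguments, zero for disjoint hulls, and never exceeding the smaller hull
#' area.
#'
#' @param poly_a,poly_b `hull_poly` objects from [convex_hull()].
#' @return A `hull_overlap` list: `area_a`, `area_b`, `area_intersection`
#'   (square micrometres) and the clipped `polygon` vertices.
#' @export
hull_overlap <- function(poly_a, poly_b) {
  subj <- poly_a$vertices
  clip <- poly_b$vertices
  n <- nrow(clip)
  for (k in seq_len(n)) {
    subj <- clip_halfplane(subj, clip[k, ], clip[if (k == n) 1 else k + 1, ])
    if (nrow(subj) == 0) break
  }
  area <- if (nrow(subj) >= 3) shoelace_area(subj) else 0
  structure(list(area_a = poly_a$area, area_b = poly_b$area,
                 area_intersection = max(area, 0), polygon = subj),
            class = "hull_overlap")
}

#' Squared correlation of conductance against dendritic overlap
#'
#' Squared Pearson correlation of paired-recording conductance versus
#' convex-hull intersection area across pairs.
#'
#' @param g_gaba Conductances, nS (one per pair).
#' @param overlap_area Hull intersection areas, square micrometres.
#' @return R-squared in `[0, 1]`, or `NA` (with a warning) under zero
#'   variance.
#' @export
overlap_conductance_relation <- function(g_gaba, overlap_area) {
  if (length(g_gaba) != length(overlap_area) || length(g_gaba) < 3) {
    stop_invalid("need >= 3 paired observations")
  }
  if (stats::sd(g_gaba) == 0 || stats::sd(overlap_area) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(g_gaba, overlap_area)^2
}
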