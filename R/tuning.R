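#' Construct a direction tuning curve
#'
#' @param angles Stimulus directions, degrees (canonically 8 at 45 degree
#'   spacing).
#' @param magnitudes Non-negative response magnitudes (|peak|), one per
#'   angle: pA, Hz or mV depending on `metric`.
#' @param pathway `"on"` or `"off"`.
#' @param metric One of `"IPSC"`, `"EPSC"`, `"spike_rate"`, `"delta_vm"`.
#' @return A `tuning_curve` list.
#' @export
tuning_curve <- function(angles, magnitudes, pathway = "on",
                         metric = c("IPSC", "EPSC", "spike_rate",
                                    "delta_vm")) {
  metric <- match.arg(metric)
  if (length(angles) != length(magnitudes)) {
    stop_invalid("angles and magnitudes must have equal length")
  }
  if (any(magnitudes < 0)) stop_invalid("magnitudes must be >= 0")
  structure(list(angles = wrap360(angles), magnitudes = magnitudes,
                 pathway = pathway, metric = metric),
            class = "tuning_curve")
}

#' Vector sum of a direction tuning curve
#'
#' Sums the response-weighted unit vectors over directions. The resulting
#' angle points toward the directions with the largest responses; the
#' magnitude is normalized by the peak response `rmax` (not by the sum), so
#' a perfectly selective cell has normalized length 1 and an untuned cell 0.
#'
#' @param curve A [tuning_curve()].
#' @return A `vector_sum_result`: `angle` (degrees in `[0, 360)`, `NA` when
#'   the sum is degenerate), `magnitude` (response units), `normalized`
#'   (`|sum| / rmax`), and `defined` (FALSE for symmetric curves whose sum
#'   vanishes).
#' @export
vector_sum <- function(curve) {
  r <- curve$magnitudes
  if (length(unique(curve$angles)) < 2) stop_invalid("need >= 2 angles")
  rmax <- max(r)
  if (rmax <= 0) stop_invalid("all-zero magnitudes: vector-sum angle undefined")
  th <- deg2rad(curve$angles)
  sx <- sum(r * cos(th))
  sy <- sum(r * sin(th))
  mag <- sqrt(sx^2 + sy^2)
  defined <- mag > 1e-9 * sum(r)
  structure(list(
    angle = if (defined) wrap360(rad2deg(atan2(sy, sx))) else NA_real_,
    magnitude = mag, normalized = mag / rmax, defined = defined
  ), class = "vector_sum_result")
}

#' Null and preferred direction from an inhibitory tuning curve
#'
#' In these circuits the null direction (ND) is defined by inhibition: under
#' the `"argmax"` convention it is the direction of the maximal IPSC, under
#' the `"vector"` convention the vector-sum angle of the IPSC curve. The
#' preferred direction (PD) is 180 degrees opposite, snapped to the nearest
#' sampled angle for response lookup. Argmax ties go to the angle closest to
#' the vector-sum angle, then to the smallest angle.
#'
#' @param curve An IPSC [tuning_curve()].
#' @param convention `"argmax"` or `"vector"`.
#' @return A `dsi_result`: `pd_angle`, `nd_angle` (degrees), `pd_resp`,
#'   `nd_resp` (response units, looked up at the snapped angles), `dsi`,
#'   `convention`, and `defined` (FALSE when a symmetric curve leaves the
#'   vector-based ND undefined).
#' @export
null_and_preferred_from_inhibition <- function(curve,
                                               convention = c("argmax",
                                                              "vector")) {
  convention <- match.arg(convention)
  if (curve$metric != "IPSC") stop_invalid("expected an IPSC curve")
  vs <- vector_sum(curve)
  if (convention == "vector") {
    if (!vs$defined) {
      return(structure(list(pd_angle = NA_real_, nd_angle = NA_real_,
                            pd_resp = NA_real_, nd_resp = NA_real_,
                            dsi = NA_real_, convention = convention,
                            defined = FALSE), class = "dsi_result"))
    }
    nd <- vs$angle
  } else {
    mx <- max(curve$magnitudes)
    cand <- curve$angles[curve$magnitudes == mx]
    if (length(cand) > 1 && vs$defined) {
      cand <- cand[order(abs(circ_diff_deg(cand, vs$angle)), cand)]
    } else {
      cand <- sort(cand)
    }
    nd <- cand[1]
  }
  pd <- wrap360(nd + 180)
  snap <- function(a) {
    curve$angles[which.min(abs(circ_diff_deg(curve$angles, a)))]
  }
  nd_s <- snap(nd)
  pd_s <- snap(pd)
  nd_resp <- curve$magnitudes[match(nd_s, curve$angles)]
  pd_resp <- curve$magnitudes[match(pd_s, curve$angles)]
  structure(list(pd_angle = pd, nd_angle = nd,
                 pd_resp = pd_resp, nd_resp = nd_resp,
                 dsi = if (pd_resp + nd_resp > 0) {
                   dsi(pd_resp, nd_resp)
                 } else {
                   NA_real_
                 },
                 convention = convention, defined = TRUE),
            class = "dsi_result")
}

#' Preferred direction from an output tuning curve
#'
#' For spiking or subthreshold-potential curves the preferred direction is
#' the vector-sum angle itself (no 180 degree flip).
#'
#' @param curve A `spike_rate` or `delta_vm` [tuning_curve()].
#' @return PD in degrees, or `NA` (with a warning) for symmetric curves.
#' @export
preferred_from_output <- function(curve) {
  if (!curve$metric %in% c("spike_rate", "delta_vm")) {
    stop_invalid("expected a spike_rate or delta_vm curve")
  }
  vs <- vector_sum(curve)
  if (!vs$defined) {
    warning("symmetric curve: preferred direction undefined")
    return(NA_real_)
  }
  vs$angle
}

#' Direction selectivity index
#'
#' `DSI = (PD - ND) / (PD + ND)` of the preferred- and null-direction
#' response magnitudes; 1 for a perfectly selective cell, 0 for an untuned
#' one. Bounded in `[-1, 1]` for non-negative responses.
#'
#' @param pd_resp,nd_resp Non-negative response magnitudes.
#' @return Dimensionless DSI.
#' @export
dsi <- function(pd_resp, nd_resp) {
  if (pd_resp + nd_resp <= 0) {
    stop_invalid("DSI undefined: PD + ND responses must be positive")
  }
  (pd_resp - nd_resp) / (pd_resp + nd_resp)
}

#' Asymmetric inhibition component
#'
#' The tuned component of inhibition attributed to starburst amacrine cells:
#' the null-direction IPSC peak minus the preferred-direction IPSC peak, in
#' pA. The sign is preserved (negative when inhibition is stronger in the
#' preferred direction).
#'
#' @param nd_ipsc,pd_ipsc IPSC peak magnitudes, pA.
#' @return Signed difference, pA.
#' @export
asymmetric_inhibition <- function(nd_ipsc, pd_ipsc) nd_ipsc - pd_ipsc

#' Signed circular offset of a preferred direction from a nominal axis
#'
#' @param pd_angle Preferred direction, degrees.
#' @param nominal_axis Nominal axis, degrees (e.g. 180 for nasal).
#' @return Minimal signed difference `pd_angle - nominal_axis` in
#'   `(-180, 180]`, degrees.
#' @export
alignment_offset <- function(pd_angle, nominal_axis) {
  circ_diff_deg(pd_angle, nominal_axis)
}
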