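#' Parameters of the single-compartment parallel-conductance model
#'
#' Defaults are the empirically determined population constants: capacitance
#' 80 pF, resting conductance 3.3 nS, resting potential -55 mV, with
#' excitatory and inhibitory (chloride) reversals at 0 and -60 mV. With
#' conductances in nS, voltages in mV and capacitance in pF, dV/dt comes out
#' in mV/ms, so `dt` is in ms.
#'
#' @param cm Membrane capacitance, pF.
#' @param g_leak Resting (leak) conductance, nS.
#' @param e_leak Resting potential, mV.
#' @param e_exc,e_inh Excitatory and inhibitory reversal potentials, mV.
#' @param dt Integration step, ms.
#' @param v_init Initial voltage, mV (defaults to `e_leak`).
#' @return A `model_params` list.
#' @export
model_params <- function(cm = 80, g_leak = 3.3, e_leak = -55,
                         e_exc = 0, e_inh = -60, dt = 0.1,
                         v_init = e_leak) {
  if (cm <= 0) stop_invalid("cm must be > 0")
  if (g_leak < 0) stop_invalid("g_leak must be >= 0")
  if (dt <= 0) stop_invalid("dt must be > 0")
  structure(list(cm = cm, g_leak = g_leak, e_leak = e_leak,
                 e_exc = e_exc, e_inh = e_inh, dt = dt, v_init = v_init),
            class = "model_params")
}

#' Conductance time series for the membrane model
#'
#' @param t_ms Time grid, ms (uniform).
#' @param g_exc,g_inh Excitatory and inhibitory conductances, nS; negative
#'   values are rectified to zero.
#' @param direction Stimulus direction label, degrees.
#' @param pathway `"on"` or `"off"`.
#' @return A `conductance_trace` list.
#' @export
conductance_trace <- function(t_ms, g_exc, g_inh, direction = NA_real_,
                              pathway = "on") {
  if (length(g_exc) != length(t_ms) || length(g_inh) != length(t_ms)) {
    stop_invalid("g_exc, g_inh and t_ms must share one grid")
  }
  structure(list(t_ms = t_ms, g_exc = pmax(g_exc, 0),
                 g_inh = pmax(g_inh, 0),
                 direction = direction, pathway = pathway),
            class = "conductance_trace")
}

#' Extract synaptic conductances from voltage-clamp currents
#'
#' Converts baseline-subtracted, trial-averaged currents recorded at the
#' opposing reversal potentials into conductances by Ohm's law:
#' `g_inh(t) = I_ipsc(t) / (V_hold_inh - e_inh)` (hold at the cation
#' reversal, 0 mV) and `g_exc(t) = I_epsc(t) / (V_hold_exc - e_exc)` (hold
#' at the chloride reversal, -60 mV). Negative conductances are rectified to
#' zero after the division.
#'
#' @param mean_epsc,mean_ipsc Baseline-subtracted mean currents, pA, on a
#'   common grid.
#' @param t_ms Time grid, ms.
#' @param params A [model_params()].
#' @param hold_exc,hold_inh Holding potentials used for the EPSC and IPSC
#'   recordings, mV.
#' @param direction,pathway Labels carried through.
#' @return A `conductance_trace` (nS).
#' @export
extract_conductance <- function(mean_epsc, mean_ipsc, t_ms,
                                params = model_params(),
                                hold_exc = -60, hold_inh = 0,
                                direction = NA_real_, pathway = "on") {
  if (hold_inh == params$e_inh || hold_exc == params$e_exc) {
    stop_invalid("holding potential equals the reversal: zero driving force")
  }
  g_inh <- mean_ipsc / (hold_inh - params$e_inh)
  g_exc <- mean_epsc / (hold_exc - params$e_exc)
  conductance_trace(t_ms, g_exc, g_inh, direction, pathway)
}

euler_integrate <- function(g_exc, g_inh, params, i_inj = 0, v_init = NULL) {
  n <- length(g_exc)
  if (length(i_inj) == 1L) i_inj <- rep(i_inj, n)
  v <- numeric(n)
  v[1] <- if (is.null(v_init)) params$v_init else v_init
  dt <- params$dt
  cm <- params$cm
  gl <- params$g_leak
  el <- params$e_leak
  ee <- params$e_exc
  ei <- params$e_inh
  for (k in seq_len(n - 1L)) {
    dv <- (-(g_exc[k] * (v[k] - ee) + g_inh[k] * (v[k] - ei) +
               gl * (v[k] - el)) + i_inj[k]) / cm
    v[k + 1L] <- v[k] + dt * dv
  }
  v
}

#' Simulate subthreshold membrane potential by forward Euler
#'
#' Integrates the parallel-conductance RC model
#' `dV/dt = -(g_exc (V - e_exc) + g_inh (V - e_inh) + g_leak (V - e_leak)) / cm`
#' with the forward Euler update `V(t + dt) = V(t) + dV/dt * dt`. With zero
#' synaptic input the voltage relaxes to `e_leak`; in general it stays
#' between the smallest and largest reversal for any non-negative
#' conductances and a stable step.
#'
#' @param cond A [conductance_trace()]; its grid must match `params$dt`.
#' @param params A [model_params()].
#' @return A `sim_result`: `t_ms`, `v_mv`, `direction`, `pathway`, `params`.
#'   Divergence (`|V| > 200` mV) aborts with the required step bound
#'   `dt < cm / (g_leak + max(g_exc + g_inh))`.
#' @export
simulate_vm <- function(cond, params = model_params()) {
  if (!inherits(cond, "conductance_trace")) {
    stop_invalid("cond must be a conductance_trace")
  }
  if (length(cond$t_ms) > 1) {
    step <- diff(cond$t_ms[1:2])
    if (abs(step - params$dt) > 1e-9) {
      stop_invalid("conductance grid step (%g ms) != params$dt (%g ms)",
                   step, params$dt)
    }
  }
  v <- euler_integrate(cond$g_exc, cond$g_inh, params)
  if (any(!is.finite(v)) || any(abs(v) > 200)) {
    bound <- params$cm / (params$g_leak + max(cond$g_exc + cond$g_inh))
    stop_invalid(
      "forward Euler diverged: reduce dt below cm/(g_leak+max g) = %.4g ms",
      bound
    )
  }
  structure(list(t_ms = cond$t_ms, v_mv = v, direction = cond$direction,
                 pathway = cond$pathway, params = params),
            class = "sim_result")
}

#' Tuning curve of simulated depolarizations
#'
#' Extracts the peak depolarization (`V - v_init`) within the ON or OFF
#' window from one simulation per direction and assembles a `delta_vm`
#' tuning curve for [dsi()] / [vector_sum()].
#'
#' @param sims List of `sim_result`s, one per direction.
#' @param windows A [response_windows()] (seconds; converted to ms).
#' @param pathway `"on"` or `"off"`.
#' @return A [tuning_curve()] with `metric = "delta_vm"` (mV).
#' @export
simulated_tuning <- function(sims, windows = response_windows(),
                             pathway = c("on", "off")) {
  pathway <- match.arg(pathway)
  dirs <- vapply(sims, function(s) s$direction, 1)
  if (anyNA(dirs)) stop_invalid("every sim_result needs a direction label")
  b <- window_bounds(windows, pathway) * 1000  # s -> ms
  peaks <- vapply(sims, function(s) {
    sel <- s$t_ms >= b[1] & s$t_ms <= b[2]
    if (!any(sel)) stop_invalid("window lies outside the simulation")
    max(s$v_mv[sel] - s$params$v_init)
  }, 1)
  tuning_curve(dirs, pmax(peaks, 0), pathway = pathway, metric = "delta_vm")
}

#' Passive response of the model to a clamp or current step
#'
#' Test harness for recovering the printed passive constants. Under voltage
#' clamp the membrane charges instantaneously to the command, so the leak
#' current is `g_leak * (V_hold - e_leak)` throughout; under a current step
#' the voltage relaxes exponentially with `tau = cm / g_leak` toward
#' `e_leak + I / g_leak`.
#'
#' @param params A [model_params()].
#' @param mode `"voltage_clamp"` or `"current_step"`.
#' @param level Command potential (mV) or injected current (pA).
#' @param duration_ms Simulated duration, ms.
#' @return List with `t_ms` and either `i_pa` (clamp) or `v_mv` (step).
#' @export
passive_step_response <- function(params = model_params(),
                                  mode = c("voltage_clamp", "current_step"),
                                  level = 0, duration_ms = 200) {
  mode <- match.arg(mode)
  t_ms <- seq(0, duration_ms, by = params$dt)
  if (mode == "voltage_clamp") {
    i <- rep(params$g_leak * (level - params$e_leak), length(t_ms))
    list(t_ms = t_ms, i_pa = i, mode = mode, level = level)
  } else {
    v <- euler_integrate(numeric(length(t_ms)), numeric(length(t_ms)),
                         params, i_inj = level)
    list(t_ms = t_ms, v_mv = v, mode = mode, level = level)
  }
}

#' Fit a membrane time constant to a relaxation
#'
#' Fits the single exponential `V(t) = V_inf + (V_0 - V_inf) exp(-t / tau)`
#' through its exact autoregressive form: on a uniform grid,
#' `V(t + dt) = a + b V(t)` with `b = exp(-dt / tau)`, so an ordinary
#' least-squares fit of successive samples yields
#' `tau = -dt / log(b)`. This form is exact for noiseless exponentials
#' (where direct nonlinear least squares breaks down at zero residual) and
#' unbiased to first order for small additive noise.
#'
#' @param t_ms Time, ms (uniform grid).
#' @param v_mv Voltage, mV.
#' @return Fitted time constant, ms.
#' @export
fit_membrane_tau <- function(t_ms, v_mv) {
  n <- length(v_mv)
  if (n < 4) stop_invalid("relaxation too short to fit")
  dt <- t_ms[2] - t_ms[1]
  dev <- abs(v_mv - v_mv[n])
  sel <- which(dev > 0.02 * dev[1])   # fit the informative decay only
  if (length(sel) < 3) stop_invalid("relaxation too short to fit")
  k <- sel[-length(sel)]
  b <- stats::coef(stats::lm(v_mv[k + 1L] ~ v_mv[k]))[[2]]
  if (!is.finite(b) || b <= 0 || b >= 1) {
    stop_invalid("relaxation is not a decaying exponential")
  }
  -dt / log(b)
}
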