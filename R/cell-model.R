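#' Ionic currents of the minimal ventricular model
#'
#' Evaluates the three transmembrane currents of the four-variable minimal
#' model -- fast inward (`J_fi`), slow outward (`J_so`) and slow inward
#' (`J_si`) -- at a given state. Heaviside gate switches use the convention
#' H(0) = 1 and are evaluated at the thresholds `u_v`, `u_w`, `u_o`.
#'
#' @param state named numeric `(u, v, w, s)`.
#' @param params a [bocf_params()] vector.
#' @return A one-row tibble with columns `J_fi`, `J_so`, `J_si`, `J_total`.
#' @examples
#' ionic_current(cell_rest_state(), bocf_params())
#' @export
ionic_current <- function(state, params = bocf_params()) {
  state <- as_cell_state(state)
  res <- cpp_ionic_current(state, params_vec(params))
  tibble::as_tibble(res[c("J_fi", "J_so", "J_si", "J_total")])
}

as_cell_state <- function(state) {
  if (is.list(state)) state <- unlist(state)
  if (is.null(names(state)) && length(state) == 4L)
    names(state) <- c("u", "v", "w", "s")
  if (!all(c("u", "v", "w", "s") %in% names(state)))
    abort("`state` must have components u, v, w, s")
  s <- as.numeric(state[c("u", "v", "w", "s")])
  if (any(!is.finite(s))) abort("non-finite cell state: solver divergence")
  s
}

params_vec <- function(p) {
  out <- as.numeric(p)
  names(out) <- names(p)
  out
}

#' Advance a single cell state by one time step
#'
#' One step of the second-order (midpoint) generalisation of the Rush--Larsen
#' method: gating variables are advanced by the exponential update using
#' quasi-steady values and rate constants frozen at a half-step predictor,
#' giving overall second-order accuracy in `dt`; gates remain in \[0, 1\] by
#' construction of the exponential update.
#'
#' @inheritParams ionic_current
#' @param dt time step (ms), > 0.
#' @param I_stim additive stimulus current (model units).
#' @return Named numeric `(u, v, w, s)` after the step.
#' @export
step_cell <- function(state, params = bocf_params(), dt = 0.05, I_stim = 0) {
  if (!is.numeric(dt) || dt <= 0) abort("`dt` must be > 0")
  cpp_step_cell(as_cell_state(state), params_vec(params), dt, I_stim)
}

#' Simulate a single-cell action potential
#'
#' Integrates the cell model from rest with a square additive stimulus
#' current applied during `[0, stim_duration]`.
#'
#' @inheritParams step_cell
#' @param stim_amplitude stimulus current amplitude (model units).
#' @param stim_duration stimulus duration (ms).
#' @param total_time total simulated time (ms).
#' @return An `ap_trace` tibble with columns `time_ms`, `u`, `v`, `w`, `s`
#'   and attribute `stimulus`.
#' @examples
#' tr <- simulate_single_cell(total_time = 200)
#' measure_apd(tr, 0.9)
#' @export
simulate_single_cell <- function(params = bocf_params(), stim_amplitude = 1,
                                 stim_duration = 1, total_time = 500, dt = 0.05) {
  if (!(total_time > stim_duration) || stim_duration < 0)
    abort("need total_time > stim_duration >= 0")
  n_steps <- as.integer(ceiling(total_time / dt))
  m <- cpp_simulate_cell(params_vec(params), dt, n_steps,
                         stim_amplitude, stim_duration)
  out <- tibble::tibble(
    time_ms = seq(0, by = dt, length.out = n_steps + 1L),
    u = m[, 1], v = m[, 2], w = m[, 3], s = m[, 4]
  )
  attr(out, "stimulus") <- list(amplitude = stim_amplitude,
                                duration = stim_duration, dt = dt)
  class(out) <- c("ap_trace", class(out))
  out
}

#' Action potential duration at a repolarisation fraction
#'
#' Measures the duration from the upstroke crossing of the activation
#' threshold to the downstroke crossing of the potential level corresponding
#' to the stated repolarisation fraction of the AP amplitude (baseline is the
#' pre-upstroke potential, amplitude is peak minus baseline). Crossing times
#' are linearly interpolated between samples. APD90 corresponds to
#' `repolarisation_fraction = 0.9`.
#'
#' @param trace an `ap_trace`, or any data frame with `time_ms` and `u`.
#' @param repolarisation_fraction fraction of the amplitude that must have
#'   repolarised (in (0, 1)); 0.9 gives APD90.
#' @param activation_threshold upstroke detection level; defaults to the
#'   excitation threshold `u_v` = 0.3 of the cell model.
#' @return APD in ms.
#' @export
measure_apd <- function(trace, repolarisation_fraction = 0.9,
                        activation_threshold = 0.3) {
  stopifnot(repolarisation_fraction > 0, repolarisation_fraction < 1)
  t <- trace$time_ms; u <- trace$u
  up <- which(u[-1] >= activation_threshold & u[-length(u)] < activation_threshold)
  if (length(up) == 0L) abort("no AP detected: trace never crosses the activation threshold")
  i <- up[1]
  t_up <- t[i] + (activation_threshold - u[i]) / (u[i + 1] - u[i]) * (t[i + 1] - t[i])
  baseline <- min(u[1:i])                # resting potential before the upstroke
  peak <- max(u[(i + 1):length(u)])
  level <- peak - repolarisation_fraction * (peak - baseline)
  ipk <- i + which.max(u[(i + 1):length(u)])
  seg <- ipk:length(u)
  dn <- which(u[seg][-1] < level & u[seg][-length(seg)] >= level)
  if (length(dn) == 0L) abort("no AP detected: trace never repolarises to the requested level")
  j <- seg[dn[1]]
  t_dn <- t[j] + (level - u[j]) / (u[j + 1] - u[j]) * (t[j + 1] - t[j])
  t_dn - t_up
}
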