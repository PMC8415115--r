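#' Parameters of the fibrosis-remodelled minimal ventricular cell model
#'
#' Returns the full parameter set of the four-variable
#' Bueno-Orovio--Cherry--Fenton (BOCF) minimal ventricular model in the
#' remodelled variant used throughout this package, which shortens the action
#' potential to roughly 50 ms and (with the calibrated tissue conductivity)
#' slows conduction to 23 cm/s, representing myocardium with significant
#' fibrotic damage. Any individual constant can be overridden by name.
#'
#' The naming follows the parameter table of the remodelled set; the mapping
#' onto the minimal-model formulas is: `u_v`, `u_w`, `u_o` are the Heaviside
#' thresholds (theta_v, theta_w, theta_o), `uv_minus` is theta_v^-,
#' `uw_minus`/`kw_minus` the midpoint/steepness of the tau_w^- sigmoid,
#' `u_so`/`k_so` those of the tau_so sigmoid, `u_s`/`k_s` the s-gate steady
#' state, `u_u` the upper potential, and `w_inf_star` the plateau of w_inf.
#' Time constants are in milliseconds; potentials and gates are
#' dimensionless.
#'
#' @param ... named overrides of individual parameters, e.g. `tau_si = 1.8887`.
#'
#' @return A named numeric vector of class `bocf_params`.
#' @examples
#' p <- bocf_params()
#' p["tau_fi"] # 0.11 * C_m
#' @export
bocf_params <- function(...) {
  C_m <- 1
  p <- c(
    C_m   = C_m,
    u_v   = 0.3,     uv_minus = 0.006, u_w = 0.13,   uw_minus = 0.03,
    u_o   = 0.006,   u_s = 0.9087,     u_so = 0.4,   u_u = 1.2,
    w_inf_star = 0.94,
    tau_v_plus = 1.4506, tau_v1_minus = 60,  tau_v2_minus = 1150,
    tau_w_plus = 200,    tau_w1_minus = 60,  tau_w2_minus = 15,
    tau_w_inf  = 0.07,
    tau_o1 = 400,    tau_o2 = 6,
    tau_s1 = 2.7342, tau_s2 = 16,
    tau_fi = 0.11 * C_m, tau_si = 2.8,
    tau_so1 = 30.0181,   tau_so2 = 0.9957,
    k_s = 2.0994, kw_minus = 65, k_so = 2.0458
  )
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
    p[names(dots)] <- dots
    if ("C_m" %in% names(dots) && !("tau_fi" %in% names(dots)))
      p["tau_fi"] <- 0.11 * p["C_m"]
  }
  validate_bocf_params(p)
  structure(p, class = "bocf_params")
}

validate_bocf_params <- function(p) {
  taus <- p[grepl("^tau_", names(p))]
  if (any(taus <= 0)) abort("all time constants must be strictly positive")
  if (!(p["u_o"] <= p["uv_minus"] && p["uv_minus"] < p["u_w"] &&
        p["u_w"] < p["u_v"] && p["u_v"] < p["u_u"]))
    warn("threshold ordering u_o <= uv_minus < u_w < u_v < u_u violated")
  invisible(p)
}

#' @export
print.bocf_params <- function(x, ...) {
  cat("<bocf_params> fibrosis-remodelled minimal ventricular model\n")
  print(unclass(x))
  invisible(x)
}

#' Resting state of the cell model
#'
#' @return Named numeric `(u, v, w, s)` = (0, 1, 1, 0).
#' @export
cell_rest_state <- function() c(u = 0, v = 1, w = 1, s = 0)
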