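test_that("default parameters reproduce the remodelled parameter table", {
  p <- bocf_params()
  expect_equal(unname(p["C_m"]), 1)
  expect_equal(unname(p["u_v"]), 0.3)
  expect_equal(unname(p["uv_minus"]), 0.006)
  expect_equal(unname(p["u_w"]), 0.13)
  expect_equal(unname(p["uw_minus"]), 0.03)
  expect_equal(unname(p["u_o"]), 0.006)
  expect_equal(unname(p["u_s"]), 0.9087)
  expect_equal(unname(p["u_so"]), 0.4)
  expect_equal(unname(p["u_u"]), 1.2)
  expect_equal(unname(p["w_inf_star"]), 0.94)
  expect_equal(unname(p["tau_v_plus"]), 1.4506)
  expect_equal(unname(p["tau_v1_minus"]), 60)
  expect_equal(unname(p["tau_v2_minus"]), 1150)
  expect_equal(unname(p["tau_w_plus"]), 200)
  expect_equal(unname(p["tau_w1_minus"]), 60)
  expect_equal(unname(p["tau_w2_minus"]), 15)
  expect_equal(unname(p["tau_w_inf"]), 0.07)
  expect_equal(unname(p["tau_o1"]), 400)
  expect_equal(unname(p["tau_o2"]), 6)
  expect_equal(unname(p["tau_s1"]), 2.7342)
  expect_equal(unname(p["tau_s2"]), 16)
  expect_equal(unname(p["tau_fi"]), 0.11 * 1)
  expect_equal(unname(p["tau_si"]), 2.8)
  expect_equal(unname(p["tau_so1"]), 30.0181)
  expect_equal(unname(p["tau_so2"]), 0.9957)
  expect_equal(unname(p["k_s"]), 2.0994)
  expect_equal(unname(p["kw_minus"]), 65)
  expect_equal(unname(p["k_so"]), 2.0458)
  # threshold ordering of the default set
  expect_true(p["u_o"] <= p["uv_minus"] && p["uv_minus"] < p["u_w"] &&
              p["u_w"] < p["u_v"] && p["u_v"] < p["u_u"])
  # all time constants strictly positive
  expect_true(all(p[grepl("^tau_", names(p))] > 0))
})

test_that("ionic currents vanish where their gates or driving terms do", {
  p <- bocf_params()
  # at rest every threshold exceeds u: fast and slow inward currents closed
  j <- ionic_current(cell_rest_state(), p)
  expect_equal(j$J_fi, 0)
  expect_equal(j$J_si, 0)
  # at u = u_u the fast-inward driving term (u_u - u) vanishes
  j2 <- ionic_current(c(u = unname(p["u_u"]), v = 1, w = 1, s = 1), p)
  expect_equal(j2$J_fi, 0)
  # Heaviside convention H(0) = 1: at exactly u = u_v the fast current is
  # switched on (zero only through the (u - u_v) factor), and at u = u_w
  # the slow-inward current conducts
  j3 <- ionic_current(c(u = unname(p["u_w"]), v = 1, w = 1, s = 1), p)
  expect_lt(j3$J_si, 0)
  expect_error(ionic_current(c(u = NaN, v = 1, w = 1, s = 0)), "non-finite")
})

test_that("currents match an independent transcription at mid-upstroke states", {
  p <- bocf_params()
  states <- list(c(0.5, 0.8, 0.9, 0.2), c(0.2, 0.5, 0.5, 0.5),
                 c(1.0, 0.1, 0.7, 0.9), c(0.05, 1, 1, 0))
  for (st in states) {
    got <- ionic_current(stats::setNames(st, c("u", "v", "w", "s")), p)
    ref <- oracle_currents(st[1], st[2], st[3], st[4], as.list(p))
    expect_equal(got$J_fi, ref$J_fi, tolerance = 1e-12)
    expect_equal(got$J_so, ref$J_so, tolerance = 1e-12)
    expect_equal(got$J_si, ref$J_si, tolerance = 1e-12)
    expect_equal(got$J_total, ref$J_fi + ref$J_so + ref$J_si, tolerance = 1e-12)
  }
})

test_that("a tiny step is the identity to first order", {
  s0 <- c(u = 0.5, v = 0.8, w = 0.9, s = 0.2)
  s1 <- step_cell(s0, dt = 1e-9)
  expect_equal(unname(s1), unname(s0), tolerance = 1e-6)
  expect_error(step_cell(s0, dt = 0), "dt")
})

test_that("gate relaxation matches the closed-form exponential", {
  # frozen u below every threshold: v relaxes to v_inf = 1 with tau_v1_minus
  p <- bocf_params()
  dt <- 0.05
  v <- 0.4
  for (k in 1:400)
    v <- unname(step_cell(c(u = 0, v = unname(v), w = 1, s = 0), p, dt)["v"])
  t_tot <- 400 * dt
  v_exact <- 1 + (0.4 - 1) * exp(-t_tot / p[["tau_v1_minus"]])
  expect_equal(unname(v), v_exact, tolerance = 1e-6)
})

test_that("the integrator is second-order accurate in dt", {
  p <- bocf_params()
  advance <- function(dt, t_end = 2) {
    st <- c(u = 0.4, v = 0.9, w = 0.95, s = 0.1)
    for (k in seq_len(round(t_end / dt))) st <- step_cell(st, p, dt)
    st
  }
  ref <- advance(0.003125)
  e1 <- max(abs(advance(0.05) - ref))
  e2 <- max(abs(advance(0.025) - ref))
  order <- log2(e1 / e2)
  expect_gt(order, 1.8)
})

test_that("gates stay in [0,1] over long integrations and rest is stable", {
  p <- bocf_params()
  st <- c(u = 0, v = 1, w = 1, s = 0)
  lo <- c(Inf, Inf, Inf); hi <- c(-Inf, -Inf, -Inf)
  st <- cell_rest_state()
  # strong repeated stimulation exercises the full state space
  tr <- simulate_single_cell(p, stim_amplitude = 2, stim_duration = 1,
                             total_time = 500, dt = 0.05)
  expect_true(all(tr$v >= 0 & tr$v <= 1))
  expect_true(all(tr$w >= 0 & tr$w <= 1))
  expect_true(all(tr$s >= 0 & tr$s <= 1))
  # 10,000 steps from an excited state
  st <- c(u = 0.6, v = 0.5, w = 0.5, s = 0.5)
  for (k in 1:10000) {
    st <- step_cell(st, p, 0.05)
    if (k %% 500 == 0) {
      expect_true(all(st[c("v", "w", "s")] >= 0 & st[c("v", "w", "s")] <= 1))
    }
  }
  # quiescent rest: u moves by less than 0.01 over 1,000 ms
  tr0 <- simulate_single_cell(p, stim_amplitude = 0, total_time = 1000)
  expect_lt(max(abs(tr0$u)), 0.01)
})

test_that("zero-amplitude stimulus never excites; suprathreshold gives one AP", {
  p <- bocf_params()
  tr0 <- simulate_single_cell(p, stim_amplitude = 0, total_time = 300)
  expect_true(all(tr0$u < p[["u_v"]]))
  tr <- simulate_single_cell(p, stim_amplitude = 1, total_time = 300)
  expect_gt(max(tr$u), p[["u_w"]])
  expect_lt(abs(tr$u[nrow(tr)] - tr$u[1]), 0.01 + p[["u_o"]])
  # exactly one upstroke
  up <- sum(diff(tr$u >= p[["u_v"]]) == 1)
  expect_equal(up, 1)
})

test_that("trajectory agrees with a generic stiff ODE solve of the same RHS", {
  skip_if_not_installed("deSolve")
  p <- bocf_params()
  rhs <- function(t, y, parms) {
    u <- y[1]; v <- y[2]; w <- y[3]; s <- y[4]
    o <- oracle_currents(u, v, w, s, as.list(p))
    tau_vm <- if (u <= p[["uv_minus"]]) p[["tau_v1_minus"]] else p[["tau_v2_minus"]]
    tau_wm <- p[["tau_w1_minus"]] + (p[["tau_w2_minus"]] - p[["tau_w1_minus"]]) *
      (1 + tanh(p[["kw_minus"]] * (u - p[["uw_minus"]]))) / 2
    tau_s <- if (u < p[["u_w"]]) p[["tau_s1"]] else p[["tau_s2"]]
    vinf <- as.numeric(u <= p[["uv_minus"]])
    winf <- if (u < p[["u_o"]]) 1 - u / p[["tau_w_inf"]] else p[["w_inf_star"]]
    dv <- if (u < p[["u_v"]]) (vinf - v) / tau_vm else -v / p[["tau_v_plus"]]
    dw <- if (u < p[["u_w"]]) (winf - w) / tau_wm else -w / p[["tau_w_plus"]]
    ds <- ((1 + tanh(p[["k_s"]] * (u - p[["u_s"]]))) / 2 - s) / tau_s
    stim <- if (t < 1) 1 else 0
    list(c(-(o$J_fi + o$J_so + o$J_si) + stim, dv, dw, ds))
  }
  out <- deSolve::lsoda(c(u = 0, v = 1, w = 1, s = 0), seq(0, 200, by = 0.05),
                        rhs, NULL, rtol = 1e-8, atol = 1e-10)
  tr <- simulate_single_cell(p, stim_amplitude = 1, stim_duration = 1,
                             total_time = 200, dt = 0.05)
  amp <- max(tr$u)
  expect_lt(max(abs(tr$u - out[, "u"])), 0.01 * amp)
})

test_that("APD measurement recovers hand-computed values on synthetic pulses", {
  # triangular pulse: up from 0 to 1 over 1 ms, down to 0 over 99 ms.
  # upstroke crosses 0.3 at t = 0.3; APD90 level = 0.1, reached on the
  # downstroke at t = 1 + 0.9 * 99 = 90.1 -> APD90 = 89.8 exactly
  tr <- tibble::tibble(time_ms = c(0, 1, 100, 120),
                       u = c(0, 1, 0, 0))
  expect_equal(measure_apd(tr, 0.9), 90.1 - 0.3)
  expect_equal(measure_apd(tr, 0.5), (1 + 0.5 * 99) - 0.3)
  # flat sub-threshold trace
  flat <- tibble::tibble(time_ms = 0:10, u = rep(0.05, 11))
  expect_error(measure_apd(flat), "no AP detected")
  # monotone level sets: APD50 <= APD90 on a real AP
  ap <- simulate_single_cell(total_time = 300)
  expect_lte(measure_apd(ap, 0.5), measure_apd(ap, 0.9))
})
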