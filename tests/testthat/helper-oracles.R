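# Independent straight-line transcription of the minimal-model currents,
# written directly from the published formulas; used as an oracle against
# the package implementation.
oracle_currents <- function(u, v, w, s, p) {
  H <- function(x) as.numeric(x >= 0)
  tau_so <- p[["tau_so1"]] + (p[["tau_so2"]] - p[["tau_so1"]]) *
    (1 + tanh(p[["k_so"]] * (u - p[["u_so"]]))) / 2
  tau_o <- if (u < p[["u_o"]]) p[["tau_o1"]] else p[["tau_o2"]]
  J_fi <- -v * H(u - p[["u_v"]]) * (u - p[["u_v"]]) * (p[["u_u"]] - u) / p[["tau_fi"]]
  J_so <- (u - p[["u_o"]]) * (1 - H(u - p[["u_w"]])) / tau_o + H(u - p[["u_w"]]) / tau_so
  J_si <- -H(u - p[["u_w"]]) * w * s / p[["tau_si"]]
  list(J_fi = J_fi, J_so = J_so, J_si = J_si)
}

# brute-force RVI: explicit double loop over node pairs restricted to the
# Chebyshev neighbourhood
oracle_rvi <- function(first_at, first_rt, radius = 1L) {
  nr <- nrow(first_at); nc <- ncol(first_at)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(first_at[i, j])) next
    best <- Inf
    for (di in -radius:radius) for (dj in -radius:radius) {
      if (di == 0 && dj == 0) next
      i2 <- i + di; j2 <- j + dj
      if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
      if (is.na(first_rt[i2, j2])) next
      best <- min(best, first_rt[i2, j2] - first_at[i, j])
    }
    if (is.finite(best)) out[i, j] <- best
  }
  out
}

# build an activation_markers object directly from first-crossing matrices
# (synthetic marker fixtures without running a simulation)
markers_from_matrices <- function(first_at, first_rt, end_time = 1000) {
  nr <- nrow(first_at); nc <- ncol(first_at)
  ev_at <- which(!is.na(first_at), arr.ind = TRUE)
  ev_rt <- which(!is.na(first_rt), arr.ind = TRUE)
  events <- rbind(
    tibble::tibble(node_row = ev_at[, 1], node_col = ev_at[, 2],
                   time_ms = first_at[ev_at], event = "activation"),
    tibble::tibble(node_row = ev_rt[, 1], node_col = ev_rt[, 2],
                   time_ms = first_rt[ev_rt], event = "repolarisation"))
  events <- events[order(events$time_ms), ]
  rec <- list(events = events, node_rows = nr, node_cols = nc,
              end_time = end_time, active = matrix(TRUE, nr, nc),
              provenance = list())
  extract_markers(rec)
}
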