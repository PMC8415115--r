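#' Run one monodomain tissue simulation
#'
#' Integrates the monodomain reaction--diffusion equation on the assembled
#' operators with operator splitting: the reaction step advances every active
#' node by the second-order Rush--Larsen cell update, the diffusion step is a
#' Crank--Nicolson solve with the consistent (non-diagonal) mass matrix
#' through a pre-computed sparse Cholesky factor shared across scenarios.
#' Upward/downward crossings of the activation threshold are recorded per
#' node (with a refractory lockout); the run ends at quiescence or `t_max`.
#'
#' @param operators [assemble_operators()] result.
#' @param params [bocf_params()].
#' @param scenario one row of a stimulus-site tibble (or a list with
#'   `scenario_id` and `nodes`).
#' @param config [sim_config()].
#' @return A `sim_record`: tibble of crossing events (`node_row`, `node_col`,
#'   `time_ms`, `event`), plus `end_time`, `termination`
#'   (`"quiescence"`/`"time_limit"`/`"reentry_stop"`), `reentry` flag (second
#'   activation of a boundary node seen in-run), dimensions and provenance.
#' @export
run_simulation <- function(operators, params = bocf_params(), scenario,
                           config = sim_config()) {
  stopifnot(inherits(operators, "mesh_operators"))
  if (is.data.frame(scenario)) scenario <- as.list(scenario[1, ])
  nodes <- scenario$nodes
  if (is.list(nodes) && !is.matrix(nodes)) nodes <- nodes[[1]]
  sol <- solver_for(operators, config)
  nr <- operators$node_rows; nc <- operators$node_cols

  nid <- (nodes[, 2] - 1L) * nr + nodes[, 1]
  if (any(nodes[, 1] < 1L | nodes[, 1] > nr | nodes[, 2] < 1L | nodes[, 2] > nc))
    abort("stimulated nodes lie outside the node grid")
  stim_act <- match(nid, sol$active_ids)      # drop nodes with no conducting element
  stim_act <- stim_act[!is.na(stim_act)]
  if (length(stim_act) == 0L)
    abort("no stimulated node is active (all incident elements obstructed)")

  arow <- ((sol$active_ids - 1L) %% nr) + 1L
  acol <- ((sol$active_ids - 1L) %/% nr) + 1L
  boundary <- arow == 1L | arow == nr | acol == 1L | acol == nc

  res <- cpp_run_monodomain(
    params_vec(params),
    sol$Bp, sol$Bi, sol$Bx, sol$Lp, sol$Li, sol$Lx, sol$perm0,
    as.integer(stim_act - 1L),
    0, config$stim_duration, config$stim_amplitude,
    boundary, config$dt, config$t_max,
    config$activation_threshold, config$lockout_ms,
    config$quiescence_u, config$check_every,
    config$stop_on_reentry)

  events <- tibble::tibble(
    node_row = c(arow[res$act_node + 1L], arow[res$rep_node + 1L]),
    node_col = c(acol[res$act_node + 1L], acol[res$rep_node + 1L]),
    time_ms = c(res$act_time, res$rep_time),
    event = rep(c("activation", "repolarisation"),
                c(length(res$act_node), length(res$rep_node))))
  events <- dplyr::arrange(events, .data$time_ms, .data$node_row, .data$node_col)

  structure(list(events = events,
                 end_time = res$end_time,
                 termination = if (res$termination == "reentry_stop") "reentry_stop"
                               else res$termination,
                 reentry = res$reentry,
                 node_rows = nr, node_cols = nc,
                 n_rows = operators$n_rows, n_cols = operators$n_cols,
                 element_size = operators$element_size,
                 active = operators$active,
                 provenance = list(pattern_seed = operators$pattern_seed,
                                   rho = operators$rho,
                                   scenario_id = scenario$scenario_id)),
            class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  cat(sprintf("<sim_record> %d x %d nodes, %d activations / %d repolarisations, end %g ms (%s)%s\n",
              x$node_rows, x$node_cols,
              sum(x$events$event == "activation"),
              sum(x$events$event == "repolarisation"),
              x$end_time, x$termination,
              if (isTRUE(x$reentry)) ", RE-ENTRY" else ""))
  invisible(x)
}

#' Conduction velocity between two probes
#'
#' Euclidean probe distance divided by the difference of single activation
#' times, converted to cm/s (node spacing = `element_size` mm).
#'
#' @param record a `sim_record`.
#' @param probe_a,probe_b node coordinates `c(row, col)`.
#' @return Speed in cm/s (absolute value).
#' @export
measure_cv <- function(record, probe_a, probe_b) {
  at <- function(p) {
    t <- record$events$time_ms[record$events$event == "activation" &
                               record$events$node_row == p[1] &
                               record$events$node_col == p[2]]
    if (length(t) != 1L)
      abort(sprintf("probe (%d, %d) activated %d times; need exactly one activation",
                    p[1], p[2], length(t)))
    t
  }
  ta <- at(probe_a); tb <- at(probe_b)
  dist_mm <- sqrt(sum((probe_a - probe_b)^2)) * record$element_size
  abs(dist_mm / (tb - ta)) * 100     # mm/ms -> cm/s
}

#' Simulate a planar wave on an obstacle-free strip
#'
#' Convenience wrapper used for conductivity calibration and conduction
#' velocity checks: an obstacle-free `n_rows` x `n_cols` element strip with a
#' full west-edge stimulus.
#'
#' @param n_rows,n_cols strip size in elements.
#' @param config a [sim_config()]; `t_max` can be short since the wave
#'   crosses quickly.
#' @param params [bocf_params()].
#' @return A `sim_record`.
#' @export
planar_strip_run <- function(n_rows = 20, n_cols = 200,
                             config = sim_config(t_max = 300),
                             params = bocf_params()) {
  pat <- generate_pattern(n_rows, n_cols, rho = 0, seed = 0,
                          element_size = config$element_size)
  ops <- assemble_operators(pat, config)
  scen <- edge_stimulus_sites(n_rows, n_cols, edges = "west")
  run_simulation(ops, params, scen[1, ], config)
}
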