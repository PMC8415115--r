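#' Simulation configuration
#'
#' Collects the numerical settings of the tissue solver. The defaults are the
#' reference discretisation: dt = 0.05 ms on 0.1 mm square elements, implicit
#' (Crank--Nicolson) diffusion with the consistent bilinear mass matrix, and
#' the conductivity calibrated once so a planar wave travels at 23 cm/s (see
#' [tissue_conductivity()]).
#'
#' @param dt time step (ms).
#' @param t_max simulation horizon (ms); runs stop earlier on quiescence.
#' @param D isotropic conductivity / effective diffusivity (mm^2/ms).
#' @param element_size element side (mm).
#' @param activation_threshold potential level whose upward/downward crossings
#'   define node activation/repolarisation (the excitation threshold `u_v`).
#' @param lockout_ms refractory lockout between successive activations of one
#'   node. The default (50 ms) covers the AP duration: within it a node
#'   cannot fire a second regenerative AP, so any extra threshold crossing
#'   is passive electrotonic chatter at the wave back, not re-activation.
#' @param quiescence_u activity dies out when max u over active nodes falls
#'   below this level (checked every `check_every` steps) after the stimulus.
#' @param check_every quiescence check interval in steps.
#' @param stim_amplitude,stim_duration stimulus current (model units) and
#'   duration (ms) applied to scenario nodes at t = 0.
#' @param stop_on_reentry if TRUE the run stops as soon as re-entry (a second
#'   activation of any boundary node) is observed; first-crossing markers are
#'   unaffected.
#' @return A `sim_config` list.
#' @export
sim_config <- function(dt = 0.05, t_max = 2000, D = tissue_conductivity(),
                       element_size = 0.1, activation_threshold = 0.3,
                       lockout_ms = 50, quiescence_u = 0.05, check_every = 20,
                       stim_amplitude = 2, stim_duration = 1,
                       stop_on_reentry = FALSE) {
  stopifnot(dt > 0, t_max > 0, D > 0, element_size > 0)
  structure(list(dt = dt, t_max = t_max, D = D, element_size = element_size,
                 activation_threshold = activation_threshold,
                 lockout_ms = lockout_ms, quiescence_u = quiescence_u,
                 check_every = as.integer(check_every),
                 stim_amplitude = stim_amplitude, stim_duration = stim_duration,
                 stop_on_reentry = stop_on_reentry),
            class = "sim_config")
}

#' Calibrated tissue conductivity
#'
#' The effective isotropic diffusivity (mm^2/ms) of the monodomain equation.
#' The value was calibrated once, by bisection on planar-strip simulations at
#' the reference discretisation (0.1 mm elements, dt = 0.05 ms, consistent
#' mass CVFEM), so that the planar conduction velocity of the remodelled cell
#' model equals 23 cm/s; it is then held fixed for every other run.
#'
#' @return Diffusivity in mm^2/ms.
#' @export
tissue_conductivity <- function() 0.0219

# 4-node bilinear element matrices on a square, node order
# [ (r,c), (r+1,c), (r,c+1), (r+1,c+1) ]  (column-major corners):
# rows 1-2 and 3-4 vertically adjacent, 1-3 / 2-4 horizontally adjacent,
# 1-4 / 2-3 diagonal.
.K_unit <- (1 / 6) * matrix(c(4, -1, -1, -2,
                              -1, 4, -2, -1,
                              -1, -2, 4, -1,
                              -2, -1, -1, 4), 4, 4)
.M_unit <- (1 / 36) * matrix(c(4, 2, 2, 1,
                               2, 4, 1, 2,
                               2, 1, 4, 2,
                               1, 2, 2, 4), 4, 4)

#' Assemble the vertex-centred finite-element operators
#'
#' Builds the sparse stiffness (diffusion) and consistent (non-diagonal) mass
#' operators of the vertex-centred control-volume finite-element
#' discretisation with bilinear interpolants on square elements. Each
#' conducting element contributes the standard 4-node bilinear stiffness
#' block (diagonal 2/3 D, edge-adjacent -1/6 D, opposite-corner -1/3 D) and
#' the consistent mass block (entries summing to the element area);
#' obstructed elements contribute nothing. A node incident only to obstructed
#' elements is flagged inactive and has empty operator rows. Boundaries are
#' natural (no-flux) Neumann.
#'
#' @param pattern a [generate_pattern()] result.
#' @param config a [sim_config()].
#' @return A `mesh_operators` object: sparse `K` and `M` over the full node
#'   grid, logical `active` node matrix, node/element dimensions, and a cache
#'   environment for factorised solvers.
#' @export
assemble_operators <- function(pattern, config = sim_config()) {
  stopifnot(inherits(pattern, "fibrosis_pattern"))
  R <- pattern$n_rows; C <- pattern$n_cols
  nr <- R + 1L; nc <- C + 1L; n_nodes <- nr * nc
  cond <- which(pattern$occupancy == 0L)           # conducting element indices
  h2 <- config$element_size^2

  if (length(cond)) {
    er <- ((cond - 1L) %% R) + 1L                  # element row
    ec <- ((cond - 1L) %/% R) + 1L                 # element col
    nid <- function(i, j) (j - 1L) * nr + i        # node id, column-major
    Enodes <- cbind(nid(er, ec), nid(er + 1L, ec),
                    nid(er, ec + 1L), nid(er + 1L, ec + 1L))
    ii <- Enodes[, rep(1:4, each = 4L), drop = FALSE]
    jj <- Enodes[, rep(1:4, times = 4L), drop = FALSE]
    kx <- rep(as.vector(t(.K_unit)), each = length(cond)) * config$D
    mx <- rep(as.vector(t(.M_unit)), each = length(cond)) * h2
    # t(.K_unit) flattened matches ii/jj pairing: entry (a,b) at column (a-1)*4+b
    K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj), x = kx,
                              dims = c(n_nodes, n_nodes))
    M <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj), x = mx,
                              dims = c(n_nodes, n_nodes))
    active_ids <- unique(as.vector(Enodes))
  } else {
    K <- M <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                   dims = c(n_nodes, n_nodes))
    active_ids <- integer()
  }
  active <- matrix(FALSE, nr, nc)
  active[active_ids] <- TRUE

  structure(list(K = K, M = M, active = active,
                 node_rows = nr, node_cols = nc,
                 n_rows = R, n_cols = C,
                 element_size = config$element_size, D = config$D,
                 pattern_seed = pattern$seed, rho = pattern$rho,
                 cache = new.env(parent = emptyenv())),
            class = "mesh_operators")
}

#' @export
print.mesh_operators <- function(x, ...) {
  cat(sprintf("<mesh_operators> %d x %d nodes, %d active (%.1f%%), D = %g mm^2/ms\n",
              x$node_rows, x$node_cols, sum(x$active),
              100 * mean(x$active), x$D))
  invisible(x)
}

# Factorise (M + dt/2 K) restricted to active nodes; cached per (dt) on the
# operators object so the 13 stimulus scenarios of one pattern share it.
solver_for <- function(operators, config) {
  key <- sprintf("dt=%.10g", config$dt)
  cache <- operators$cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  act <- which(as.vector(operators$active))
  Ka <- operators$K[act, act, drop = FALSE]
  Ma <- operators$M[act, act, drop = FALSE]
  A <- methods::as(Ma + (config$dt / 2) * Ka, "symmetricMatrix")
  B <- Ma - (config$dt / 2) * Ka
  ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE, super = FALSE)
  ex <- Matrix::expand(ch)
  L <- methods::as(ex$L, "CsparseMatrix")
  perm <- ex$P@perm                     # (P b)[i] = b[perm[i]]
  # the C++ solves assume each column's first stored entry is its diagonal
  stopifnot(all(L@i[L@p[seq_len(ncol(L))] + 1L] == seq_len(ncol(L)) - 1L))
  Bc <- methods::as(B, "CsparseMatrix")
  sol <- list(active_ids = act,
              Bp = Bc@p, Bi = Bc@i, Bx = Bc@x,
              Lp = L@p, Li = L@i, Lx = L@x,
              perm0 = as.integer(perm - 1L))
  cache[[key]] <- sol
  sol
}
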