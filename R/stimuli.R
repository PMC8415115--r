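#' The 13-site stimulus protocol
#'
#' Returns the 13 stimulus scenarios applied separately to each fibrotic
#' realisation to probe many propagation directions: small square node
#' patches at the four corners, the four edge midpoints, the domain centre,
#' and the four midpoints between centre and corners.
#'
#' @param n_rows,n_cols element counts of the domain (>= 20 each).
#' @param patch side of the square stimulated node patch (nodes).
#' @return A tibble with columns `scenario_id`, `name`, and list-column
#'   `nodes` (two-column matrices of node row/col), one row per scenario.
#' @export
default_stimulus_sites <- function(n_rows, n_cols, patch = 5L) {
  if (n_rows < 20L || n_cols < 20L)
    abort("domain must be at least 20 elements on a side for the 13-site protocol")
  nr <- n_rows + 1L; nc <- n_cols + 1L
  # corner and edge patches are inset 5% from the domain border: the
  # stimulated region must not itself sit on the re-entry-detection
  # boundary, where stimulated but poorly connected pockets would later be
  # re-activated by the detouring wave and masquerade as re-entry
  rel <- rbind(
    c(0.05, 0.05), c(0.05, 0.95), c(0.95, 0.05), c(0.95, 0.95),  # corners
    c(0.05, 0.5), c(0.95, 0.5), c(0.5, 0.05), c(0.5, 0.95),      # edge mids
    c(0.5, 0.5),                                                 # centre
    c(0.25, 0.25), c(0.25, 0.75), c(0.75, 0.25), c(0.75, 0.75))
  names_ <- c("corner_nw", "corner_ne", "corner_sw", "corner_se",
              "edge_n", "edge_s", "edge_w", "edge_e", "centre",
              "mid_nw", "mid_ne", "mid_sw", "mid_se")
  half <- (patch - 1L) %/% 2L
  nodes <- lapply(seq_len(nrow(rel)), function(k) {
    cr <- 1L + round(rel[k, 1] * (nr - 1L))
    cc <- 1L + round(rel[k, 2] * (nc - 1L))
    r0 <- min(max(cr - half, 1L), nr - patch + 1L)
    c0 <- min(max(cc - half, 1L), nc - patch + 1L)
    as.matrix(expand.grid(row = r0:(r0 + patch - 1L),
                          col = c0:(c0 + patch - 1L)))
  })
  tibble::tibble(scenario_id = seq_along(names_), name = names_, nodes = nodes)
}

#' Full-edge stimulus scenarios
#'
#' One scenario per domain edge, stimulating the complete line of boundary
#' nodes on that edge (`depth` node rows deep). Used by the generalisation
#' experiment on small domains and for planar-wave runs.
#'
#' @inheritParams default_stimulus_sites
#' @param edges which edges to include.
#' @param depth how many node rows deep the stimulated band is.
#' @return A tibble like [default_stimulus_sites()].
#' @export
edge_stimulus_sites <- function(n_rows, n_cols,
                                edges = c("west", "east", "north", "south"),
                                depth = 2L) {
  nr <- n_rows + 1L; nc <- n_cols + 1L
  nodes <- lapply(edges, function(e) {
    switch(e,
      west  = as.matrix(expand.grid(row = 1:nr, col = 1:depth)),
      east  = as.matrix(expand.grid(row = 1:nr, col = (nc - depth + 1L):nc)),
      north = as.matrix(expand.grid(row = 1:depth, col = 1:nc)),
      south = as.matrix(expand.grid(row = (nr - depth + 1L):nr, col = 1:nc)))
  })
  tibble::tibble(scenario_id = seq_along(edges), name = paste0("edge_", edges),
                 nodes = nodes)
}
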