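#' Extract per-node activation/repolarisation markers
#'
#' Reorganises a simulation record into per-node ordered marker lists and
#' validates that, within every node, activation and repolarisation times
#' interleave with activation first.
#'
#' @param record a `sim_record` (or a compatible list with an `events` tibble
#'   and node-grid dimensions).
#' @return An `activation_markers` object: matrices `first_at` / `first_rt`
#'   (first activation / repolarisation time per node, NA where none),
#'   `n_act` counts, per-node lists `at` and `rt`, and grid dimensions.
#' @export
extract_markers <- function(record) {
  ev <- record$events
  nr <- record$node_rows; nc <- record$node_cols
  id <- (ev$node_col - 1L) * nr + ev$node_row
  is_act <- ev$event == "activation"

  first_of <- function(sel) {
    m <- matrix(NA_real_, nr, nc)
    sub <- ev[sel, ]
    sid <- id[sel]
    # events are time-ordered; keep the first occurrence per node
    keep <- !duplicated(sid)
    m[sid[keep]] <- sub$time_ms[keep]
    m
  }
  first_at <- first_of(is_act)
  first_rt <- first_of(!is_act)
  n_act <- matrix(0L, nr, nc)
  tab <- table(id[is_act])
  n_act[as.integer(names(tab))] <- as.integer(tab)

  at <- split(ev$time_ms[is_act], id[is_act])
  rt <- split(ev$time_ms[!is_act], id[!is_act])
  for (k in names(rt)) {
    a <- at[[k]]
    r <- rt[[k]]
    if (is.null(a) || r[1] < a[1])
      abort("malformed record: repolarisation precedes activation at a node")
  }

  structure(list(first_at = first_at, first_rt = first_rt, n_act = n_act,
                 at = at, rt = rt,
                 node_rows = nr, node_cols = nc,
                 end_time = record$end_time,
                 active = record$active,
                 provenance = record$provenance),
            class = "activation_markers")
}

#' Boundary nodes of a node grid
#'
#' @param node_rows,node_cols node-grid dimensions.
#' @return Two-column matrix of perimeter node coordinates.
#' @export
boundary_nodes <- function(node_rows, node_cols) {
  rows <- c(rep(1L, node_cols), rep(node_rows, node_cols),
            2:(node_rows - 1L), 2:(node_rows - 1L))
  cols <- c(1:node_cols, 1:node_cols,
            rep(1L, node_rows - 2L), rep(node_cols, node_rows - 2L))
  cbind(row = rows, col = cols)
}

#' Detect re-entry from repeated boundary activation
#'
#' TRUE iff any boundary node of the domain activated more than once --
#' capturing ectopic waves that successfully escape the fibrotic region.
#' Repeated activation of interior nodes alone does not count.
#'
#' @param markers an [extract_markers()] result.
#' @param boundary two-column matrix of boundary node coordinates; defaults
#'   to the domain perimeter.
#' @return Logical scalar.
#' @export
detect_reentry <- function(markers,
                           boundary = boundary_nodes(markers$node_rows,
                                                     markers$node_cols)) {
  idx <- cbind(boundary[, 1], boundary[, 2])
  any(markers$n_act[idx] >= 2L)
}

#' Compute the re-entry vulnerability index map
#'
#' For every node with at least one activation, RVI is the minimum over its
#' neighbouring nodes (all nodes within `radius` in the Chebyshev metric,
#' default the 8 surrounding nodes) of the neighbour's first repolarisation
#' time minus the node's own first activation time. Strongly negative values
#' mark locations where a neighbour had already activated and repolarised
#' when the node first activated -- re-excitable substrate capable of
#' seeding re-entry. Nodes with no activation, or with no neighbour that
#' repolarised, are undefined (NA).
#'
#' @param markers an [extract_markers()] result.
#' @param radius neighbourhood radius in nodes (Chebyshev); 1 = 8 neighbours.
#' @return An `rvi_map`: matrix of RVI values (ms) over the node grid with
#'   attributes `radius` and provenance.
#' @export
compute_rvi <- function(markers, radius = 1L) {
  nr <- markers$node_rows; nc <- markers$node_cols
  at <- markers$first_at; rt <- markers$first_rt
  min_rt <- matrix(Inf, nr, nc)
  for (dr in -radius:radius) for (dc in -radius:radius) {
    if (dr == 0L && dc == 0L) next
    sr <- max(1L, 1L - dr):min(nr, nr - dr)   # rows where neighbour exists
    sc <- max(1L, 1L - dc):min(nc, nc - dc)
    nb <- rt[sr + dr, sc + dc, drop = FALSE]
    cur <- min_rt[sr, sc, drop = FALSE]
    nb[is.na(nb)] <- Inf
    min_rt[sr, sc] <- pmin(cur, nb)
  }
  rvi <- min_rt - at                 # NA where node never activated
  rvi[is.infinite(min_rt)] <- NA_real_
  structure(rvi, radius = radius, class = "rvi_map",
            provenance = markers$provenance)
}

#' Merge below-threshold RVI nodes into block sites
#'
#' Nodes with RVI at or below the threshold (default -50 ms) are grouped into
#' 8-connected components; each contiguous group is simplified to a single
#' site at its centroid, rounded half-down toward the smaller index and
#' mapped to element coordinates.
#'
#' @param rvi an [compute_rvi()] map.
#' @param threshold block threshold in ms (sites have RVI <= threshold).
#' @return A tibble with one row per site: `site_id`, `row`, `col` (element
#'   coordinates), `min_rvi`, `n_nodes`, and a list-column `nodes` of member
#'   node coordinates.
#' @export
detect_block_sites <- function(rvi, threshold = -50) {
  nr <- nrow(rvi); nc <- ncol(rvi)
  hit <- which(!is.na(rvi) & rvi <= threshold)
  empty <- tibble::tibble(site_id = integer(), row = integer(), col = integer(),
                          min_rvi = numeric(), n_nodes = integer(),
                          nodes = list())
  if (length(hit) == 0L) return(empty)
  hr <- ((hit - 1L) %% nr) + 1L
  hc <- ((hit - 1L) %/% nr) + 1L
  # 8-connected components among below-threshold nodes
  comp <- label_components8(hr, hc, nr, nc)
  out <- lapply(seq_len(max(comp)), function(k) {
    sel <- comp == k
    rr <- hr[sel]; cc <- hc[sel]
    # centroid rounded half-down toward the smaller index, node -> element:
    # element (r, c) spans nodes rows r..r+1, so clamp into the element grid
    er <- min(max(floor(mean(rr) + 0.5 - 1e-9), 1L), nr - 1L)
    ec <- min(max(floor(mean(cc) + 0.5 - 1e-9), 1L), nc - 1L)
    tibble::tibble(row = as.integer(er), col = as.integer(ec),
                   min_rvi = min(rvi[cbind(rr, cc)]),
                   n_nodes = sum(sel), nodes = list(cbind(row = rr, col = cc)))
  })
  out <- dplyr::bind_rows(out)
  out$site_id <- seq_len(nrow(out))
  out[, c("site_id", "row", "col", "min_rvi", "n_nodes", "nodes")]
}

# label 8-connected components of a sparse set of grid nodes
label_components8 <- function(hr, hc, nr, nc) {
  id <- (hc - 1L) * nr + hr
  pos <- integer(nr * nc)
  pos[id] <- seq_along(id)
  from <- integer(0); to <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    r2 <- hr + dr; c2 <- hc + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    id2 <- (c2[ok] - 1L) * nr + r2[ok]
    p2 <- pos[id2]
    hit2 <- p2 > 0L
    from <- c(from, which(ok)[hit2])
    to <- c(to, p2[hit2])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(id) - igraph::vcount(g)))
  igraph::components(g)$membership[seq_along(id)]
}
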