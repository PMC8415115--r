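#' Generate a random diffuse-fibrosis obstacle field
#'
#' Each element of an `n_rows` x `n_cols` grid is independently replaced by a
#' non-conducting obstacle with probability `rho`, the standard percolation
#' style model of diffuse fibrosis. Elements are squares of side
#' `element_size` (mm); cardiac tissue nodes sit on the element vertices, so
#' excitation can still pass through the "crack" between two diagonally
#' opposed obstructions.
#'
#' @param n_rows,n_cols element counts (default 200 x 200, i.e. a 2 x 2 cm
#'   sheet at 0.1 mm resolution).
#' @param rho obstruction probability in \[0, 1\].
#' @param seed RNG seed; regenerating with identical arguments is
#'   bit-identical and independent of the caller's RNG state.
#' @param element_size element side length in mm.
#' @return A `fibrosis_pattern`: list with integer `occupancy` matrix
#'   (1 = obstacle), `n_rows`, `n_cols`, `rho`, `seed`, `element_size`.
#' @examples
#' p <- generate_pattern(50, 50, rho = 0.48, seed = 1)
#' mean(p$occupancy)
#' @export
generate_pattern <- function(n_rows = 200, n_cols = 200, rho, seed,
                             element_size = 0.1) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho < 0 || rho > 1)
    abort("`rho` must be a single probability in [0, 1]")
  occ <- with_local_seed(seed, {
    matrix(as.integer(runif(n_rows * n_cols) < rho), n_rows, n_cols)
  })
  new_fibrosis_pattern(occ, rho, seed, element_size)
}

new_fibrosis_pattern <- function(occupancy, rho, seed, element_size = 0.1) {
  structure(list(occupancy = occupancy,
                 n_rows = nrow(occupancy), n_cols = ncol(occupancy),
                 rho = rho, seed = seed, element_size = element_size),
            class = "fibrosis_pattern")
}

#' @export
print.fibrosis_pattern <- function(x, ...) {
  cat(sprintf("<fibrosis_pattern> %d x %d elements (%.1f x %.1f mm), rho = %s, realised density = %.4f\n",
              x$n_rows, x$n_cols, x$n_rows * x$element_size,
              x$n_cols * x$element_size, format(x$rho), mean(x$occupancy)))
  invisible(x)
}

#' Node-level conduction mask for display
#'
#' Marks a node of the vertex grid as conducting iff at least one of its (up
#' to four) incident elements is conducting, so that the diagonal "crack"
#' connectivity of the vertex-centred mesh is respected visually: the shared
#' corner node of two diagonally opposed obstacles remains conducting.
#'
#' @param pattern a [generate_pattern()] result.
#' @return Logical `(n_rows + 1) x (n_cols + 1)` matrix, TRUE = conducting.
#' @export
render_connectivity <- function(pattern) {
  stopifnot(inherits(pattern, "fibrosis_pattern"))
  cond <- pattern$occupancy == 0L
  R <- pattern$n_rows; C <- pattern$n_cols
  node <- matrix(FALSE, R + 1L, C + 1L)
  # a node is conducting if any incident element is conducting
  node[1:R,       1:C      ] <- node[1:R,       1:C      ] | cond
  node[2:(R + 1), 1:C      ] <- node[2:(R + 1), 1:C      ] | cond
  node[1:R,       2:(C + 1)] <- node[1:R,       2:(C + 1)] | cond
  node[2:(R + 1), 2:(C + 1)] <- node[2:(R + 1), 2:(C + 1)] | cond
  node
}

#' Specification of a planted channel-into-bay motif
#'
#' Describes the archetypal source--sink-mismatch geometry: a thin conducting
#' channel opening into a fully open square bay. Used to build deterministic,
#' separable fixture patterns for classifier tests.
#'
#' @param channel_width channel width in elements (>= 1).
#' @param channel_length channel length in elements.
#' @param bay_size side of the open square bay in elements.
#' @param surround_density obstacle probability outside the motif.
#' @param orientation propagation direction of the channel into the bay, one
#'   of "east", "north", "west", "south".
#' @return A `motif_spec` list.
#' @export
motif_spec <- function(channel_width = 1, channel_length = 5, bay_size = 7,
                       surround_density = 0,
                       orientation = c("east", "north", "west", "south")) {
  orientation <- match.arg(orientation)
  stopifnot(channel_width >= 1, channel_length >= 1, bay_size >= 1,
            surround_density >= 0, surround_density <= 1)
  structure(list(channel_width = channel_width, channel_length = channel_length,
                 bay_size = bay_size, surround_density = surround_density,
                 orientation = orientation),
            class = "motif_spec")
}

#' Plant a deterministic channel-into-bay motif in a fibrosis pattern
#'
#' Embeds the [motif_spec()] geometry at the centre of the grid: an open
#' channel of `channel_width` flanked by obstructed walls, opening into a
#' fully open `bay_size` x `bay_size` bay; the surrounding tissue is filled
#' with random obstacles at `surround_density`. Rotating the spec's
#' orientation rotates the planted pattern.
#'
#' @inheritParams generate_pattern
#' @param motif a [motif_spec()].
#' @param seed RNG seed for the random surround.
#' @return A `fibrosis_pattern`.
#' @export
plant_motif <- function(n_rows, n_cols, motif, seed, element_size = 0.1) {
  stopifnot(inherits(motif, "motif_spec"))
  # build in canonical (east) orientation on a square canvas, then rotate
  side <- max(n_rows, n_cols)
  mh <- motif$channel_width + 2L                    # channel plus two walls
  mw <- motif$channel_length + motif$bay_size
  if (max(mh, motif$bay_size) > side || mw > side)
    abort("motif too large for the requested grid")
  canvas <- with_local_seed(seed, {
    matrix(as.integer(runif(side * side) < motif$surround_density), side, side)
  })
  r0 <- (side - mh) %/% 2L                          # top of channel walls
  c0 <- (side - mw) %/% 2L                          # left end of channel
  ch_rows <- (r0 + 2L):(r0 + 1L + motif$channel_width)
  ch_cols <- (c0 + 1L):(c0 + motif$channel_length)
  canvas[c(r0 + 1L, r0 + 2L + motif$channel_width), ch_cols] <- 1L  # walls
  canvas[ch_rows, ch_cols] <- 0L                                    # channel
  b0 <- (side - motif$bay_size) %/% 2L
  bay_rows <- (b0 + 1L):(b0 + motif$bay_size)
  bay_cols <- (c0 + motif$channel_length + 1L):(c0 + mw)
  canvas[bay_rows, bay_cols] <- 0L                                  # open bay
  rot <- switch(motif$orientation, east = 0L, north = 1L, west = 2L, south = 3L)
  for (k in seq_len(rot)) canvas <- rotate90_ccw(canvas)
  occ <- canvas[seq_len(n_rows) + (side - n_rows) %/% 2L,
                seq_len(n_cols) + (side - n_cols) %/% 2L, drop = FALSE]
  out <- new_fibrosis_pattern(occ, motif$surround_density, seed, element_size)
  out$motif <- motif
  out
}

rotate90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

#' Write / read a fibrosis pattern as an ASCII 0/1 grid
#'
#' Plain-text serialisation: a header line `# rho=<r> seed=<s> element_size=<h>`
#' followed by one row of space-separated 0/1 per element row.
#'
#' @param pattern a `fibrosis_pattern`.
#' @param path file path.
#' @return `read_pattern_ascii` returns the reconstructed `fibrosis_pattern`.
#' @export
write_pattern_ascii <- function(pattern, path) {
  hdr <- sprintf("# rho=%s seed=%s element_size=%s",
                 format(pattern$rho, digits = 17), format(pattern$seed),
                 format(pattern$element_size, digits = 17))
  rows <- apply(pattern$occupancy, 1L, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_pattern_ascii
#' @export
read_pattern_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# ", "", lines[1]), " ")[[1]]
  kv <- strsplit(hdr, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  occ <- do.call(rbind, lapply(lines[-1], function(l)
    as.integer(strsplit(l, " ")[[1]])))
  new_fibrosis_pattern(occ, as.numeric(vals["rho"]), as.numeric(vals["seed"]),
                       as.numeric(vals["element_size"]))
}
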