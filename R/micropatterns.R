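#' Extract discriminative micropatterns around block sites
#'
#' Cuts one square binary occupancy window per detected block site, centred
#' on the site's element, labelled `"discriminative"` (the structure showed
#' RVI-detected selective conduction block). Sites whose window would
#' overhang the domain are skipped, so both classes see identical border
#' geometry statistics.
#'
#' @param pattern the source [generate_pattern()] pattern.
#' @param sites a [detect_block_sites()] tibble.
#' @param side odd window side in elements, 5..23.
#' @return A micropattern tibble: `centre_row`, `centre_col`, `side`,
#'   `label`, list-column `mask` (side x side integer matrices), and
#'   provenance columns `rho`, `pattern_seed`.
#' @export
extract_discriminative <- function(pattern, sites, side = 9L) {
  check_side(side)
  half <- (side - 1L) %/% 2L
  keep <- sites$row - half >= 1L & sites$row + half <= pattern$n_rows &
          sites$col - half >= 1L & sites$col + half <= pattern$n_cols
  sites <- sites[keep, , drop = FALSE]
  masks <- purrr::map2(sites$row, sites$col, function(r, c)
    pattern$occupancy[(r - half):(r + half), (c - half):(c + half), drop = FALSE])
  tibble::tibble(centre_row = sites$row, centre_col = sites$col,
                 side = as.integer(side), label = rep("discriminative", nrow(sites)),
                 mask = masks, rho = pattern$rho, pattern_seed = pattern$seed)
}

check_side <- function(side) {
  if (side %% 2L != 1L || side < 5L || side > 23L)
    abort("`side` must be an odd element count between 5 and 23")
}

#' Sample indiscriminate control micropatterns
#'
#' Uniformly samples window centres (seeded) and keeps windows that satisfy
#' both control rules: (1) at least 40% of the window's excitable
#' (conducting) elements were activated by the simulation, so the structure's
#' effect on propagation was actually tested (an element counts as activated
#' if any of its corner nodes activated); and (2) the window contains no node
#' whose RVI is at or below the block threshold. Windows overhanging the
#' domain are never drawn. Sampling stops when `count` windows are accepted
#' or candidate centres are exhausted (with a warning).
#'
#' @param pattern the source pattern.
#' @param markers [extract_markers()] of the same simulation.
#' @param rvi [compute_rvi()] of the same simulation.
#' @param side odd window side in elements.
#' @param count number of windows requested.
#' @param seed RNG seed.
#' @param threshold block threshold (ms) used for rule 2.
#' @param activation_fraction minimum activated fraction for rule 1
#'   (inclusive).
#' @return A micropattern tibble like [extract_discriminative()], with label
#'   `"indiscriminate"`.
#' @export
sample_indiscriminate <- function(pattern, markers, rvi, side = 9L, count,
                                  seed, threshold = -50,
                                  activation_fraction = 0.4) {
  check_side(side)
  stopifnot(count >= 0)
  half <- (side - 1L) %/% 2L
  R <- pattern$n_rows; C <- pattern$n_cols
  rows_ok <- (1L + half):(R - half)
  cols_ok <- (1L + half):(C - half)
  centres <- as.matrix(expand.grid(row = rows_ok, col = cols_ok))
  ord <- with_local_seed(seed, sample.int(nrow(centres)))
  centres <- centres[ord, , drop = FALSE]

  act_node <- !is.na(markers$first_at)            # node activated at least once
  # element activated if any corner node activated
  act_elem <- act_node[1:R, 1:C] | act_node[2:(R + 1), 1:C] |
              act_node[1:R, 2:(C + 1)] | act_node[2:(R + 1), 2:(C + 1)]
  blocked_node <- !is.na(rvi) & rvi <= threshold

  picked <- list(); n_ok <- 0L
  for (k in seq_len(nrow(centres))) {
    if (n_ok >= count) break
    r <- centres[k, 1]; c <- centres[k, 2]
    er <- (r - half):(r + half); ec <- (c - half):(c + half)
    win <- pattern$occupancy[er, ec, drop = FALSE]
    excitable <- sum(win == 0L)
    if (excitable == 0L) next
    frac <- sum(act_elem[er, ec] & win == 0L) / excitable
    if (frac < activation_fraction) next
    # nodes incident to the window's elements
    if (any(blocked_node[er[1]:(er[length(er)] + 1L),
                         ec[1]:(ec[length(ec)] + 1L)])) next
    n_ok <- n_ok + 1L
    picked[[n_ok]] <- tibble::tibble(centre_row = r, centre_col = c,
                                     side = as.integer(side),
                                     label = "indiscriminate",
                                     mask = list(win),
                                     rho = pattern$rho,
                                     pattern_seed = pattern$seed)
  }
  if (n_ok < count)
    warn(sprintf("indiscriminate sampling exhausted: %d of %d accepted", n_ok, count))
  if (n_ok == 0L)
    return(tibble::tibble(centre_row = integer(), centre_col = integer(),
                          side = integer(), label = character(), mask = list(),
                          rho = numeric(), pattern_seed = numeric()))
  dplyr::bind_rows(picked)
}

#' Assemble a balanced, split, labelled micropattern dataset
#'
#' Balances the two classes by truncating (or drawing from a supplier
#' function) the indiscriminate class to the discriminative count, then
#' splits stratified by class and grouped by source realisation
#' (`pattern_seed`): no realisation contributes to more than one split, which
#' prevents leakage of near-duplicate windows between training and test.
#'
#' @param discriminative micropattern tibble of the positive class.
#' @param indiscriminate micropattern tibble of the negative class, or a
#'   supplier `function(n)` returning up to `n` more rows.
#' @param split_fractions named numeric `(train, validation, test)` summing
#'   to 1.
#' @param seed RNG seed for balancing and splitting.
#' @return A `micro_dataset`: the combined tibble with a `split` column,
#'   plus `X` (flattened 0/1 matrix, one row per window), `y` (1 =
#'   discriminative), `side`, and class counts.
#' @export
build_balanced_dataset <- function(discriminative, indiscriminate,
                                   split_fractions = c(train = 0.7,
                                                       validation = 0.15,
                                                       test = 0.15),
                                   seed = 1L) {
  if (nrow(discriminative) == 0L) abort("need at least one discriminative pattern")
  stopifnot(abs(sum(split_fractions) - 1) < 1e-8)
  n_pos <- nrow(discriminative)
  if (is.function(indiscriminate)) indiscriminate <- indiscriminate(n_pos)
  if (nrow(indiscriminate) < n_pos)
    abort(sprintf("cannot balance dataset: %d discriminative vs %d indiscriminate",
                  n_pos, nrow(indiscriminate)))
  neg <- with_local_seed(seed,
    indiscriminate[sample.int(nrow(indiscriminate), n_pos), , drop = FALSE])
  data <- dplyr::bind_rows(discriminative, neg)
  side <- unique(data$side)
  if (length(side) != 1L) abort("all micropatterns must share one side")

  data$split <- with_local_seed(seed + 1L, assign_grouped_splits(data, split_fractions))
  X <- t(vapply(data$mask, as.vector, numeric(side^2)))
  y <- as.integer(data$label == "discriminative")
  structure(list(data = data, X = X, y = y, side = side,
                 counts = table(data$label), seed = seed),
            class = "micro_dataset")
}

# stratified-by-class, grouped-by-realisation split assignment
assign_grouped_splits <- function(data, fr) {
  groups <- unique(data$pattern_seed)
  groups <- sample(groups)
  split <- character(nrow(data))
  if (length(groups) >= 3L) {
    n_tr <- max(1L, round(fr[["train"]] * length(groups)))
    n_va <- max(1L, round(fr[["validation"]] * length(groups)))
    n_tr <- min(n_tr, length(groups) - 2L)
    g_tr <- groups[seq_len(n_tr)]
    g_va <- groups[n_tr + seq_len(min(n_va, length(groups) - n_tr - 1L))]
    split[data$pattern_seed %in% g_tr] <- "train"
    split[data$pattern_seed %in% g_va] <- "validation"
    split[split == ""] <- "test"
  } else {
    # too few realisations to group: fall back to per-row stratified split
    for (lab in unique(data$label)) {
      idx <- sample(which(data$label == lab))
      n <- length(idx)
      n_tr <- max(1L, round(fr[["train"]] * n))
      n_va <- max(1L, round(fr[["validation"]] * n))
      n_tr <- min(n_tr, n - 2L)
      split[idx[seq_len(n_tr)]] <- "train"
      split[idx[n_tr + seq_len(min(n_va, n - n_tr - 1L))]] <- "validation"
      split[idx[split[idx] == ""]] <- "test"
    }
  }
  split
}

#' @export
print.micro_dataset <- function(x, ...) {
  cat(sprintf("<micro_dataset> %d windows of %d x %d, classes: %s, splits: %s\n",
              nrow(x$data), x$side, x$side,
              paste(names(x$counts), as.integer(x$counts), collapse = " / "),
              paste(names(table(x$data$split)), table(x$data$split),
                    sep = "=", collapse = " ")))
  invisible(x)
}

#' Write / read a micropattern dataset as CSV
#'
#' Plain-text round trip: one row per window with the flattened
#' (column-major) mask as a 0/1 string plus label, centre, split and
#' provenance columns.
#'
#' @param dataset a `micro_dataset`.
#' @param path CSV path.
#' @return `read_dataset_csv` reconstructs the `micro_dataset` bit-exactly.
#' @export
write_dataset_csv <- function(dataset, path) {
  d <- dataset$data
  out <- data.frame(centre_row = d$centre_row, centre_col = d$centre_col,
                    side = d$side, label = d$label, split = d$split,
                    rho = d$rho, pattern_seed = d$pattern_seed,
                    mask = vapply(d$mask, function(m) paste(as.vector(m), collapse = ""), ""),
                    seed = dataset$seed)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @importFrom utils read.csv write.csv
#' @export
read_dataset_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(mask = "character"))
  side <- raw$side[1]
  masks <- lapply(raw$mask, function(s)
    matrix(as.integer(strsplit(s, "")[[1]]), side, side))
  data <- tibble::tibble(centre_row = raw$centre_row, centre_col = raw$centre_col,
                         side = as.integer(raw$side), label = raw$label,
                         mask = masks, rho = raw$rho,
                         pattern_seed = raw$pattern_seed, split = raw$split)
  X <- t(vapply(data$mask, as.vector, numeric(side^2)))
  structure(list(data = data, X = X,
                 y = as.integer(data$label == "discriminative"),
                 side = as.integer(side), counts = table(data$label),
                 seed = raw$seed[1]),
            class = "micro_dataset")
}

#' Separable planted-motif fixture dataset
#'
#' Builds a classifier fixture of two separable-by-construction classes:
#' positives are windows holding a planted channel-into-bay motif (the
#' archetypal source--sink-mismatch geometry, random orientation and random
#' surround), negatives are uniform random masks at the matched mean
#' obstacle density. Used by unit tests and as a capacity/sanity benchmark;
#' it is not a substitute for the simulation-derived pipeline dataset.
#'
#' @param n_per_class windows per class.
#' @param side odd window side in elements.
#' @param seed RNG seed.
#' @param surround_density obstacle density around the motif.
#' @return A `micro_dataset` with balanced classes and splits.
#' @export
motif_fixture_dataset <- function(n_per_class = 500L, side = 9L, seed = 1L,
                                  surround_density = 0.35) {
  check_side(side)
  orientations <- c("east", "north", "west", "south")
  pos <- lapply(seq_len(n_per_class), function(i) {
    or <- orientations[1L + (i %% 4L)]
    m <- motif_spec(channel_width = 1L + (i %% 2L),
                    channel_length = max(2L, side %/% 2L),
                    bay_size = max(3L, side %/% 2L),
                    surround_density = surround_density, orientation = or)
    pat <- plant_motif(side, side, m, seed = seed * 100000L + i)
    tibble::tibble(centre_row = (side + 1L) %/% 2L, centre_col = (side + 1L) %/% 2L,
                   side = as.integer(side), label = "discriminative",
                   mask = list(pat$occupancy), rho = surround_density,
                   pattern_seed = seed * 100000L + i)
  })
  pos <- dplyr::bind_rows(pos)
  dens <- mean(vapply(pos$mask, mean, 0))
  neg <- lapply(seq_len(n_per_class), function(i) {
    pat <- generate_pattern(side, side, rho = dens, seed = seed * 100000L + 50000L + i)
    tibble::tibble(centre_row = (side + 1L) %/% 2L, centre_col = (side + 1L) %/% 2L,
                   side = as.integer(side), label = "indiscriminate",
                   mask = list(pat$occupancy), rho = dens,
                   pattern_seed = seed * 100000L + 50000L + i)
  })
  neg <- dplyr::bind_rows(neg)
  build_balanced_dataset(pos, neg, seed = seed)
}
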