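test_that("marker extraction preserves interleaving and flags malformed records", {
  # single-AP node plus a re-entrant two-AP node plus a silent node
  events <- tibble::tibble(
    node_row = c(1, 1, 2, 2, 2, 2),
    node_col = c(1, 1, 1, 1, 1, 1),
    time_ms  = c(10, 40, 12, 45, 300, 330),
    event    = c("activation", "repolarisation",
                 "activation", "repolarisation", "activation", "repolarisation"))
  rec <- list(events = events[order(events$time_ms), ], node_rows = 3,
              node_cols = 3, end_time = 400, active = matrix(TRUE, 3, 3),
              provenance = list())
  mk <- extract_markers(rec)
  expect_equal(mk$first_at[1, 1], 10)
  expect_equal(mk$first_rt[1, 1], 40)
  expect_equal(mk$n_act[2, 1], 2L)
  expect_equal(mk$at[["2"]], c(12, 300))
  expect_equal(mk$rt[["2"]], c(45, 330))
  expect_true(is.na(mk$first_at[3, 3]))        # never-activated node: empty
  # repolarisation before any activation is malformed
  bad <- rec
  bad$events <- tibble::tibble(node_row = 1, node_col = 1, time_ms = 5,
                               event = "repolarisation")
  expect_error(extract_markers(bad), "malformed")
})

test_that("re-entry detection is boundary-only and monotone", {
  nr <- nc <- 5
  at <- matrix(NA_real_, nr, nc)
  rt <- matrix(NA_real_, nr, nc)
  # interior node with two activations only -> no re-entry
  at[3, 3] <- 10; rt[3, 3] <- 40
  mk <- markers_from_matrices(at, rt)
  mk$n_act[3, 3] <- 2L
  expect_false(detect_reentry(mk))
  # boundary node activating twice -> re-entry
  mk$n_act[1, 3] <- 2L
  expect_true(detect_reentry(mk))
  # adding activations can never flip true -> false
  mk$n_act[5, 5] <- 3L
  expect_true(detect_reentry(mk))
  # no activations anywhere
  empty <- markers_from_matrices(matrix(NA_real_, nr, nc),
                                 matrix(NA_real_, nr, nc))
  expect_false(detect_reentry(empty))
})

test_that("RVI reproduces hand arithmetic on a two-node toy", {
  at <- matrix(NA_real_, 2, 2)
  rt <- matrix(NA_real_, 2, 2)
  at[1, 1] <- 100                      # node of interest activates late
  at[1, 2] <- 5; rt[1, 2] <- 40        # neighbour already repolarised
  mk <- markers_from_matrices(at, rt)
  rvi <- compute_rvi(mk)
  expect_equal(rvi[1, 1], 40 - 100)    # -60 ms
  # the neighbour itself has no repolarised neighbour -> undefined
  expect_true(is.na(rvi[1, 2]))
  expect_true(is.na(rvi[2, 2]))
})

test_that("RVI agrees with the brute-force pair loop on random grids", {
  for (seed in 1:4) {
    set.seed(seed)
    nr <- sample(8:20, 1); nc <- sample(8:20, 1)
    at <- matrix(ifelse(runif(nr * nc) < 0.7, runif(nr * nc, 0, 300), NA), nr, nc)
    rt <- at + runif(nr * nc, 5, 80)
    rt[runif(nr * nc) < 0.3] <- NA
    mk <- markers_from_matrices(at, rt)
    for (radius in 1:2) {
      expect_equal(unclass(compute_rvi(mk, radius = radius))[, ],
                   oracle_rvi(at, rt, radius = radius),
                   ignore_attr = TRUE)
    }
  }
})

test_that("a uniform planar wave yields only positive RVI and no block sites", {
  cfg <- sim_config(t_max = 200)
  rec <- planar_strip_run(10, 60, cfg)
  mk <- extract_markers(rec)
  rvi <- compute_rvi(mk)
  expect_true(all(rvi[!is.na(rvi)] > 0))
  expect_equal(nrow(detect_block_sites(rvi)), 0)
  expect_false(detect_reentry(mk))
})

test_that("block sites merge 8-connected clusters to single locations", {
  rvi <- matrix(NA_real_, 10, 10)
  class(rvi) <- "rvi_map"
  expect_equal(nrow(detect_block_sites(rvi)), 0)
  # one isolated node at -60
  rvi[4, 7] <- -60
  sites <- detect_block_sites(rvi)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$row, 4)
  expect_equal(sites$col, 7)
  expect_equal(sites$min_rvi, -60)
  # an L-shaped 8-connected cluster merges into exactly one site
  rvi2 <- matrix(NA_real_, 10, 10)
  rvi2[cbind(c(2, 3, 4, 4, 4), c(2, 2, 2, 3, 4))] <- c(-55, -60, -70, -80, -90)
  class(rvi2) <- "rvi_map"
  sites2 <- detect_block_sites(rvi2)
  expect_equal(nrow(sites2), 1)
  expect_equal(sites2$min_rvi, -90)
  expect_equal(sites2$n_nodes, 5L)
  # centroid (3.4, 2.6) rounds to element (3, 3)... half-down convention:
  # mean row 3.4 -> 3, mean col 2.6 -> 3
  expect_equal(sites2$row, 3)
  expect_equal(sites2$col, 3)
  # two separated negatives give two sites; values above threshold never count
  rvi3 <- matrix(NA_real_, 10, 10)
  rvi3[2, 2] <- -51; rvi3[8, 8] <- -51; rvi3[5, 5] <- -49.9
  class(rvi3) <- "rvi_map"
  expect_equal(nrow(detect_block_sites(rvi3)), 2)
  # exact threshold equality is included (RVI <= -50)
  rvi4 <- matrix(NA_real_, 5, 5); rvi4[3, 3] <- -50
  class(rvi4) <- "rvi_map"
  expect_equal(nrow(detect_block_sites(rvi4)), 1)
  # centroid tie rounds half-down toward the smaller index
  rvi5 <- matrix(NA_real_, 5, 5)
  rvi5[2, 2] <- -60; rvi5[3, 2] <- -60       # mean row 2.5 -> 2
  class(rvi5) <- "rvi_map"
  s5 <- detect_block_sites(rvi5)
  expect_equal(s5$row, 2)
})
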