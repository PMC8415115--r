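#' Protocol configuration for density sweeps
#'
#' Describes a full simulation protocol: for every (rho, realisation) pair a
#' fibrosis pattern is generated and simulated under every stimulus scenario.
#' Two bundled configurations matter: [paper_protocol()] records the
#' full-scale protocol (2 x 2 cm domains, a coarse sweep of 50 realisations
#' for each of 21 densities in 0.40..0.60 plus 800 further realisations for
#' each of the five densities 0.46..0.50, 13 stimulus sites -- 5,050 unique
#' patterns, 65,650 simulations), and [desk_protocol()] is a scaled-down
#' version sized to run on one CPU in minutes.
#'
#' @param n_rows,n_cols domain size in elements.
#' @param rho vector of obstruction densities.
#' @param realisations realisation count per density (recycled to
#'   `length(rho)`).
#' @param stimuli `"sites13"` for the 13-site protocol or `"edges4"` for
#'   four full-edge stimuli.
#' @param config a [sim_config()].
#' @param rvi_threshold block threshold (ms).
#' @param base_seed base RNG seed; the pattern for realisation k of density
#'   i has its own derived seed, independent of execution order.
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(n_rows = 200, n_cols = 200,
                            rho = seq(0.40, 0.60, by = 0.01),
                            realisations = 50L,
                            stimuli = c("sites13", "edges4"),
                            config = sim_config(),
                            rvi_threshold = -50,
                            base_seed = 20210813) {
  stimuli <- match.arg(stimuli)
  stopifnot(all(rho >= 0 & rho <= 1), all(realisations >= 1L))
  realisations <- rep_len(as.integer(realisations), length(rho))
  structure(list(n_rows = n_rows, n_cols = n_cols, rho = rho,
                 realisations = realisations, stimuli = stimuli,
                 config = config, rvi_threshold = rvi_threshold,
                 base_seed = base_seed),
            class = "protocol_config")
}

#' @rdname protocol_config
#' @export
paper_protocol <- function() {
  protocol_config(n_rows = 200, n_cols = 200,
                  rho = c(seq(0.40, 0.60, by = 0.01), seq(0.46, 0.50, by = 0.01)),
                  realisations = c(rep(50L, 21L), rep(800L, 5L)),
                  stimuli = "sites13")
}

#' @rdname protocol_config
#' @param ... overrides passed to [protocol_config()].
#' @export
desk_protocol <- function(...) {
  defaults <- list(n_rows = 50, n_cols = 50,
                   rho = c(0.40, 0.44, 0.48, 0.52, 0.56, 0.60),
                   realisations = 6L,
                   config = sim_config(t_max = 600, stop_on_reentry = TRUE))
  args <- utils::modifyList(defaults, list(...))
  do.call(protocol_config, args)
}

#' Protocol arithmetic: pattern and simulation totals
#'
#' Computes, without executing any run, the bookkeeping totals a protocol
#' declares: unique patterns per density, stimulus count, and total
#' simulations (= patterns x stimuli).
#'
#' @param protocol a [protocol_config()].
#' @return One-row tibble: `n_rho`, `unique_patterns`, `n_stimuli`,
#'   `simulations`.
#' @export
protocol_counts <- function(protocol) {
  n_stim <- if (protocol$stimuli == "sites13") 13L else 4L
  up <- sum(protocol$realisations)
  tibble::tibble(n_rho = length(protocol$rho), unique_patterns = up,
                 n_stimuli = n_stim, simulations = up * n_stim)
}

# deterministic per-(rho index, realisation) pattern seed, independent of
# execution order; kept well below 2^31
pattern_seed_for <- function(base_seed, rho_index, realisation) {
  (as.integer(base_seed) %% 1000000L) * 2000L + rho_index * 1009L + realisation
}

#' Run a full simulation protocol
#'
#' For every (rho, realisation) pattern, all stimulus scenarios are
#' simulated; re-entry is flagged per simulation (second activation of any
#' boundary node) and per realisation (re-entry under at least one
#' scenario), RVI maps are computed and merged into block sites. Scaled-down
#' configurations complete on one CPU; the full-scale configuration is
#' recorded by [protocol_counts()] arithmetic rather than desk execution.
#'
#' @param protocol a [protocol_config()].
#' @param params [bocf_params()].
#' @param side micropattern window side kept with extracted sites.
#' @param keep_sim_data if TRUE, per-simulation markers and RVI maps are
#'   retained (needed to build datasets); otherwise only summaries.
#' @param progress print one line per realisation.
#' @return A `protocol_results` list: `runs` (one tibble row per simulation:
#'   rho, realisation, scenario_id, reentry, n_block_sites, end_time,
#'   termination), `realisations` (per-pattern label and site totals), and
#'   optionally `sim_data` for dataset extraction.
#' @export
run_protocol <- function(protocol, params = bocf_params(), side = 9L,
                         keep_sim_data = TRUE, progress = FALSE) {
  scen_fun <- if (protocol$stimuli == "sites13") default_stimulus_sites else
    function(nr, nc) edge_stimulus_sites(nr, nc)
  scenarios <- scen_fun(protocol$n_rows, protocol$n_cols)
  run_rows <- list(); sim_data <- list(); real_rows <- list()
  for (i in seq_along(protocol$rho)) {
    rho <- protocol$rho[i]
    for (k in seq_len(protocol$realisations[i])) {
      seed <- pattern_seed_for(protocol$base_seed, i, k)
      pat <- generate_pattern(protocol$n_rows, protocol$n_cols, rho, seed,
                              protocol$config$element_size)
      ops <- assemble_operators(pat, protocol$config)
      pat_runs <- list()
      for (s in seq_len(nrow(scenarios))) {
        rec <- run_simulation(ops, params, scenarios[s, ], protocol$config)
        mk <- extract_markers(rec)
        rvi <- compute_rvi(mk)
        sites <- detect_block_sites(rvi, protocol$rvi_threshold)
        reentry <- detect_reentry(mk)
        pat_runs[[s]] <- tibble::tibble(
          rho = rho, realisation = k, pattern_seed = seed,
          scenario_id = scenarios$scenario_id[s],
          reentry = reentry, n_block_sites = nrow(sites),
          end_time = rec$end_time, termination = rec$termination)
        if (keep_sim_data)
          sim_data[[length(sim_data) + 1L]] <-
            list(pattern = pat, markers = mk, rvi = rvi, sites = sites,
                 rho = rho, realisation = k, pattern_seed = seed,
                 scenario_id = scenarios$scenario_id[s], reentry = reentry)
      }
      pr <- dplyr::bind_rows(pat_runs)
      run_rows[[length(run_rows) + 1L]] <- pr
      real_rows[[length(real_rows) + 1L]] <- tibble::tibble(
        rho = rho, realisation = k, pattern_seed = seed,
        reentry = any(pr$reentry), n_block_sites = sum(pr$n_block_sites))
      if (progress)
        message(sprintf("rho %.2f realisation %d: %d/%d re-entrant runs, %d sites",
                        rho, k, sum(pr$reentry), nrow(pr), sum(pr$n_block_sites)))
    }
  }
  structure(list(runs = dplyr::bind_rows(run_rows),
                 realisations = dplyr::bind_rows(real_rows),
                 sim_data = if (keep_sim_data) sim_data,
                 protocol = protocol, side = side),
            class = "protocol_results")
}

#' Summarise a protocol run
#'
#' Per-density re-entry probabilities at both granularities (per realisation:
#' re-entry under at least one stimulus; per simulation: an individual run),
#' block-site count distributions grouped by re-entry outcome, and the
#' run-total bookkeeping.
#'
#' @param results a [run_protocol()] result.
#' @return A `protocol_summary` list of tibbles: `per_rho`, `site_counts`,
#'   `totals`.
#' @export
summarize_protocol <- function(results) {
  runs <- results$runs; reals <- results$realisations
  per_rho <- dplyr::left_join(
    dplyr::summarise(dplyr::group_by(reals, .data$rho),
                     n_realisations = dplyr::n(),
                     p_reentry_realisation = mean(.data$reentry),
                     .groups = "drop"),
    dplyr::summarise(dplyr::group_by(runs, .data$rho),
                     n_simulations = dplyr::n(),
                     p_reentry_simulation = mean(.data$reentry),
                     .groups = "drop"),
    by = "rho")
  site_counts <- dplyr::summarise(
    dplyr::group_by(reals, .data$reentry),
    n = dplyr::n(),
    mean_block_sites = mean(.data$n_block_sites),
    median_block_sites = stats::median(.data$n_block_sites),
    .groups = "drop")
  totals <- tibble::tibble(
    simulations = nrow(runs),
    reentrant_simulations = sum(runs$reentry),
    unique_patterns = nrow(reals),
    reentrant_patterns = sum(reals$reentry))
  structure(list(per_rho = per_rho, site_counts = site_counts, totals = totals),
            class = "protocol_summary")
}

#' @export
print.protocol_summary <- function(x, ...) {
  cat("<protocol_summary>\n")
  print(x$totals); print(x$per_rho); print(x$site_counts)
  invisible(x)
}

#' Build the labelled micropattern dataset from a protocol run
#'
#' Extracts discriminative windows around every retained block site and
#' samples matched indiscriminate windows from the same simulations, then
#' balances and splits with [build_balanced_dataset()].
#'
#' @param results a [run_protocol()] result with `keep_sim_data = TRUE`.
#' @param side odd window side in elements.
#' @param seed RNG seed for sampling, balancing and splitting.
#' @param per_sim_indiscriminate how many indiscriminate candidates to draw
#'   per simulation before balancing.
#' @return A `micro_dataset`.
#' @export
build_pipeline_dataset <- function(results, side = 9L, seed = 1L,
                                   per_sim_indiscriminate = 8L) {
  if (is.null(results$sim_data))
    abort("run_protocol() must be called with keep_sim_data = TRUE")
  pos <- list(); negs <- list()
  for (j in seq_along(results$sim_data)) {
    sd <- results$sim_data[[j]]
    if (nrow(sd$sites) > 0L) {
      d <- extract_discriminative(sd$pattern, sd$sites, side)
      if (nrow(d)) { d$scenario_id <- sd$scenario_id; pos[[length(pos) + 1L]] <- d }
    }
    n <- sample_indiscriminate(sd$pattern, sd$markers, sd$rvi, side,
                               count = per_sim_indiscriminate,
                               seed = seed + j,
                               threshold = results$protocol$rvi_threshold)
    if (nrow(n)) { n$scenario_id <- sd$scenario_id; negs[[length(negs) + 1L]] <- n }
  }
  pos <- dplyr::bind_rows(pos); negs <- dplyr::bind_rows(negs)
  if (nrow(pos) == 0L) abort("no block sites found: cannot build a dataset")
  build_balanced_dataset(pos, negs, seed = seed)
}

#' Generalisation experiment on small unseen domains
#'
#' Runs fresh simulations on small square domains (46 x 46 elements by
#' default) with single stimuli triggered separately on all four edges,
#' extracts micropatterns by the same RVI pipeline, and evaluates a trained
#' classifier on them.
#'
#' @param model a trained `fibro_mlp` for the chosen window side.
#' @param rho obstruction density of the fresh patterns.
#' @param n_patterns number of fresh realisations.
#' @param n_rows,n_cols domain size (46 x 46 elements).
#' @param config a [sim_config()].
#' @param params [bocf_params()].
#' @param seed base seed for the fresh patterns.
#' @param rvi_threshold block threshold (ms).
#' @return List with `metrics` (an `eval_metrics`), `cases` (per-window
#'   tibble with predicted probability and correctness) and the run tibble.
#' @export
generalisation_experiment <- function(model, rho = 0.48, n_patterns = 10L,
                                      n_rows = 46L, n_cols = 46L,
                                      config = sim_config(t_max = 600),
                                      params = bocf_params(),
                                      seed = 99000L, rvi_threshold = -50) {
  side <- model$side
  proto <- protocol_config(n_rows = n_rows, n_cols = n_cols, rho = rho,
                           realisations = n_patterns, stimuli = "edges4",
                           config = config, rvi_threshold = rvi_threshold,
                           base_seed = seed)
  res <- run_protocol(proto, params, side = side, keep_sim_data = TRUE)
  ds <- build_pipeline_dataset(res, side = side, seed = seed %% 1000L + 1L)
  p <- predict(model, ds$X)
  cases <- dplyr::mutate(ds$data,
                         probability = p,
                         predicted = ifelse(p >= 0.5, "discriminative", "indiscriminate"),
                         correct = .data$predicted == .data$label)
  metrics <- evaluate_classifier(model, ds$X, ds$y)
  list(metrics = metrics, cases = cases, runs = res$runs)
}
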