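#' Run one active-learning campaign
#'
#' Executes a full fixed-budget active-learning campaign on a compound pool:
#' each cycle acquires a batch by the current phase's strategy (using the
#' surrogate trained after the previous cycle), reveals the acquired
#' compounds' (possibly noisy) labels, retrains the surrogate from scratch on
#' everything acquired so far, predicts the remaining pool, and records
#' metrics. Enrichment metrics (top-2%/5% recall and F1) are scored
#' cumulatively over the acquired set against the true, noiseless top-k
#' sets; regression metrics (R2, Spearman rho, RMSE) are computed on the
#' remaining (unacquired) pool against true potency. If the budget exceeds
#' the pool, the final batch shrinks and the campaign is flagged truncated.
#'
#' One master `seed` deterministically derives independent streams for the
#' random batches, the label noise (unless the [noise_spec()] carries its own
#' seed) and any stochastic surrogate step, so a campaign is a pure function
#' of its arguments.
#'
#' @param pool A [compound_pool()] with fingerprints (unless the surrogate
#'   does not need them).
#' @param protocol An [build_protocol()] protocol.
#' @param surrogate An `al_surrogate` such as [gp_surrogate()].
#' @param noise A [noise_spec()]; noisy labels are used for training only,
#'   never for scoring.
#' @param seed Master integer seed of the campaign.
#' @return An object of class `al_campaign` with elements `log` (one row per
#'   cycle: cycle, strategy, acquired ids, noisy labels used), `trajectory`
#'   (one row per cycle of metrics in a tidy schema), `truncated`, and a
#'   `config` echo. [tidy()] returns the trajectory, [glance()] the final
#'   cycle.
#' @examples
#' \donttest{
#' pool <- generate_library(scenario_preset("small-diverse"))
#' camp <- run_campaign(pool, build_protocol("random-exploit"),
#'                      gp_surrogate(), noise_spec(0), seed = 1)
#' glance(camp)
#' }
#' @export
run_campaign <- function(pool, protocol, surrogate = gp_surrogate(),
                         noise = noise_spec(0), seed = 1L) {
  if (!inherits(protocol, "al_protocol")) abort("`protocol` must come from build_protocol().")
  if (!inherits(surrogate, "al_surrogate")) abort("`surrogate` must be an al_surrogate.")
  if (!inherits(noise, "noise_spec")) abort("`noise` must come from noise_spec().")
  seed <- check_count(seed, "seed", min = 0)
  n_pool <- nrow(pool)

  streams <- derive_seeds(seed, 3)
  if (is.null(noise$seed)) noise$seed <- streams[2]
  noisy_labels <- add_label_noise(pool$potency, potency_sd(pool), noise)

  cycles <- tidyr::uncount(protocol$phases, .data$n_cycles)
  rand_seeds <- local_seed_eval(streams[1], sample.int(.Machine$integer.max - 1L, nrow(cycles)))

  S_pool <- if (isTRUE(surrogate$needs_fingerprints)) tanimoto_matrix(pool_fingerprints(pool))
  spec2 <- top_k_spec(pool, 0.02)
  spec5 <- top_k_spec(pool, 0.05)

  acquired <- integer(0)
  model <- NULL
  posterior <- NULL # over `remaining`, from the previous cycle's retrain
  log_rows <- list()
  traj_rows <- list()
  truncated <- FALSE

  for (j in seq_len(nrow(cycles))) {
    strategy <- cycles$strategy[j]
    remaining <- setdiff(seq_len(n_pool), acquired)
    if (length(remaining) == 0) {
      truncated <- TRUE
      break
    }
    bs <- min(cycles$batch_size[j], length(remaining))
    if (bs < cycles$batch_size[j]) truncated <- TRUE

    if (strategy == "random") {
      batch_ids <- select_batch(tibble::tibble(id = pool$id[remaining]),
                                "random", bs, seed = rand_seeds[j])
    } else {
      if (is.null(posterior)) {
        abort(sprintf("Cycle %d uses strategy '%s' but no model has been trained yet.",
                      j, strategy))
      }
      batch_ids <- select_batch(
        tibble::tibble(id = pool$id[remaining],
                       mean = posterior$mean, variance = posterior$variance),
        strategy, bs)
    }
    batch_idx <- match(batch_ids, pool$id)
    acquired <- c(acquired, batch_idx)
    remaining <- setdiff(seq_len(n_pool), acquired)

    # retrain from scratch on everything acquired so far, with noisy labels
    model <- tryCatch(
      surrogate$fit(pool, acquired, noisy_labels[acquired],
                    similarity = if (!is.null(S_pool)) S_pool[acquired, acquired, drop = FALSE],
                    seed = streams[3]),
      error = function(e) abort(sprintf("Surrogate fit failed at cycle %d (%s, %d acquired): %s",
                                        j, strategy, length(acquired), conditionMessage(e))))
    posterior <- if (length(remaining) > 0) {
      surrogate$predict(model, pool, remaining,
                        cross_similarity = if (!is.null(S_pool)) S_pool[acquired, remaining, drop = FALSE])
    }

    acq_ids <- pool$id[acquired]
    reg <- if (length(remaining) >= 2) {
      regression_metrics(posterior$mean, pool$potency[remaining])
    } else {
      tibble::tibble(r2 = NA_real_, spearman_rho = NA_real_, rmse = NA_real_)
    }
    n_acq <- length(acquired)
    log_rows[[j]] <- tibble::tibble(
      cycle = j, strategy = strategy, n_acquired = n_acq,
      ids = list(batch_ids), noisy_labels = list(noisy_labels[batch_idx]))
    traj_rows[[j]] <- tibble::tibble(
      seed = seed, cycle = j, n_acquired = n_acq, strategy = strategy,
      recall_top2 = recall_topk(acq_ids, spec2),
      recall_top5 = recall_topk(acq_ids, spec5),
      f1_top2 = f1_topk(acq_ids, spec2),
      f1_top5 = f1_topk(acq_ids, spec5),
      r2 = reg$r2, spearman = reg$spearman_rho, rmse = reg$rmse,
      baseline_recall_top2 = random_baseline_tp(spec2$r, n_acq) / spec2$k,
      baseline_recall_top5 = random_baseline_tp(spec5$r, n_acq) / spec5$k)
  }

  structure(list(
    log = dplyr::bind_rows(log_rows),
    trajectory = dplyr::bind_rows(traj_rows),
    truncated = truncated,
    config = list(protocol = protocol$name, total_budget = protocol$total_budget,
                  surrogate = surrogate$label, noise_multiplier = noise$multiplier,
                  redraw_noise = FALSE, seed = seed, n_pool = n_pool)),
    class = "al_campaign")
}

#' @export
print.al_campaign <- function(x, ...) {
  final <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf("AL campaign '%s' on %d compounds (seed %d%s): %d cycles, %d acquired\n",
              x$config$protocol, x$config$n_pool, x$config$seed,
              if (x$truncated) ", truncated" else "", nrow(x$trajectory),
              final$n_acquired))
  cat(sprintf("  final top-2%% recall %.3f (baseline %.3f), top-5%% recall %.3f, Spearman %.3f\n",
              final$recall_top2, final$baseline_recall_top2, final$recall_top5,
              final$spearman))
  invisible(x)
}

#' Tidy an active-learning campaign
#'
#' @param x An `al_campaign` from [run_campaign()].
#' @param ... Unused.
#' @return `tidy()`: the per-cycle metrics trajectory (seed, cycle,
#'   n_acquired, strategy, recall_top2/5, f1_top2/5, r2, spearman, rmse and
#'   the random-baseline recalls). `glance()`: the final cycle as a one-row
#'   tibble with the truncation flag.
#' @method tidy al_campaign
#' @export
tidy.al_campaign <- function(x, ...) x$trajectory

#' @rdname tidy.al_campaign
#' @method glance al_campaign
#' @export
glance.al_campaign <- function(x, ...) {
  out <- x$trajectory[nrow(x$trajectory), ]
  out$truncated <- x$truncated
  out$protocol <- x$config$protocol
  out$noise_multiplier <- x$config$noise_multiplier
  out
}

#' Repeat a campaign over several seeds
#'
#' Runs [run_campaign()] once per seed and aggregates the per-cycle metric
#' trajectories into a mean and a min-max band across repeats, mirroring the
#' usual presentation of active-learning benchmarks (a line with a shaded
#' variability ribbon).
#'
#' @inheritParams run_campaign
#' @param seeds Integer vector of master seeds, one campaign per seed.
#' @return An object of class `al_repeats` with elements `campaigns` (list of
#'   `al_campaign`), `trajectories` (their tidies, bound) and `summary`
#'   (per cycle and metric: mean, min, max across seeds).
#' @export
repeat_campaigns <- function(pool, protocol, surrogate = gp_surrogate(),
                             noise = noise_spec(0), seeds = c(1L, 2L, 3L)) {
  if (length(seeds) < 1) abort("At least one seed is required.")
  campaigns <- purrr::map(seeds, function(s) {
    run_campaign(pool, protocol, surrogate = surrogate, noise = noise, seed = s)
  })
  trajectories <- purrr::map_dfr(campaigns, tidy)
  metric_cols <- c("recall_top2", "recall_top5", "f1_top2", "f1_top5",
                   "r2", "spearman", "rmse",
                   "baseline_recall_top2", "baseline_recall_top5")
  summary <- trajectories |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$cycle, .data$n_acquired, .data$strategy, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), min = min(.data$value),
                     max = max(.data$value), .groups = "drop")
  structure(list(campaigns = campaigns, trajectories = trajectories,
                 summary = summary, seeds = seeds),
            class = "al_repeats")
}

#' @export
print.al_repeats <- function(x, ...) {
  cat(sprintf("AL campaign repeats over %d seed(s): %s\n", length(x$seeds),
              paste(x$seeds, collapse = ", ")))
  fin <- x$summary[x$summary$cycle == max(x$summary$cycle) &
                     x$summary$metric == "recall_top2", ]
  cat(sprintf("  final top-2%% recall %.3f (range %.3f-%.3f)\n",
              fin$mean, fin$min, fin$max))
  invisible(x)
}

#' Tidy repeated campaigns
#'
#' @param x An `al_repeats` from [repeat_campaigns()].
#' @param ... Unused.
#' @return `tidy()`: the bound per-seed trajectories. `glance()`: final-cycle
#'   mean and min-max band per metric (long format).
#' @method tidy al_repeats
#' @export
tidy.al_repeats <- function(x, ...) x$trajectories

#' @rdname tidy.al_repeats
#' @method glance al_repeats
#' @export
glance.al_repeats <- function(x, ...) {
  x$summary[x$summary$cycle == max(x$summary$cycle), ]
}

#' Per-compound acquisition counts across repeats
#'
#' How many of the repeated campaigns acquired each compound — the tabular
#' form of the acquisition-frequency maps used to show that model-guided
#' acquisition consistently homes in on the same regions of chemical space.
#'
#' @param x An `al_repeats` from [repeat_campaigns()].
#' @return A tibble with columns `id` and `n_campaigns_acquired`, one row per
#'   compound acquired at least once.
#' @export
acquisition_counts <- function(x) {
  if (!inherits(x, "al_repeats")) abort("`x` must come from repeat_campaigns().")
  purrr::map_dfr(x$campaigns, function(cmp) {
    tibble::tibble(id = unlist(cmp$log$ids))
  }) |>
    dplyr::count(.data$id, name = "n_campaigns_acquired")
}
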