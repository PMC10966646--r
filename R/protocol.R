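#' Build an acquisition protocol
#'
#' A protocol is an ordered list of acquisition phases (strategy, batch size,
#' number of cycles) under a fixed total labeling budget, so that protocols
#' differing in batch size or strategy mix are compared at equal cost. Every
#' protocol starts with a randomly selected initial batch, since no model
#' exists before the first labels arrive.
#'
#' The named catalogue (all with the default 360-compound budget and a
#' 60-compound random initial batch):
#'
#' * `"random-exploit"`: 10 exploitation cycles of 30.
#' * `"random-explore-exploit"`: 2 exploration cycles of 30, then 8
#'   exploitation cycles of 30 (effective initial batch of 120).
#' * `"random-random-exploit"`: a second random batch of 60, then 8
#'   exploitation cycles of 30.
#' * `"batch-size-20"`: 3 exploration cycles of 20, then 12 exploitation
#'   cycles of 20.
#' * `"batch-size-30"`: alias of `"random-explore-exploit"`.
#' * `"batch-size-60"`: 1 exploration cycle of 60, then 4 exploitation
#'   cycles of 60.
#' * `"batch-size-120"`: 1 exploration cycle of 60, then 2 exploitation
#'   cycles of 120.
#'
#' @param name A protocol name from the catalogue above, or `NULL` when
#'   supplying custom `phases`.
#' @param total_budget Total number of compounds acquired over the campaign.
#'   The named protocols are defined at 360.
#' @param phases Optional custom phase table: a data frame with columns
#'   `strategy` (`"random"`, `"explore"`, `"exploit"`), `batch_size` and
#'   `n_cycles`. Must start with a random phase and sum to `total_budget`.
#' @return An object of class `al_protocol` with fields `name`, `phases`
#'   (a tibble) and `total_budget`.
#' @examples
#' build_protocol("batch-size-20")
#' @export
build_protocol <- function(name = NULL, total_budget = 360L, phases = NULL) {
  total_budget <- check_count(total_budget, "total_budget")
  catalogue <- list(
    "random-exploit"         = list(c("random", 60, 1), c("exploit", 30, 10)),
    "random-explore-exploit" = list(c("random", 60, 1), c("explore", 30, 2), c("exploit", 30, 8)),
    "random-random-exploit"  = list(c("random", 60, 2), c("exploit", 30, 8)),
    "batch-size-20"          = list(c("random", 60, 1), c("explore", 20, 3), c("exploit", 20, 12)),
    "batch-size-30"          = list(c("random", 60, 1), c("explore", 30, 2), c("exploit", 30, 8)),
    "batch-size-60"          = list(c("random", 60, 1), c("explore", 60, 1), c("exploit", 60, 4)),
    "batch-size-120"         = list(c("random", 60, 1), c("explore", 60, 1), c("exploit", 120, 2)))
  if (is.null(phases)) {
    if (is.null(name) || !name %in% names(catalogue)) {
      abort(sprintf("Unknown protocol '%s'; valid names are: %s.",
                    paste(name, collapse = ", "),
                    paste(names(catalogue), collapse = ", ")))
    }
    ph <- catalogue[[name]]
    phases <- tibble::tibble(
      strategy = vapply(ph, `[`, "", 1),
      batch_size = as.integer(vapply(ph, `[`, "", 2)),
      n_cycles = as.integer(vapply(ph, `[`, "", 3)))
  } else {
    phases <- tibble::as_tibble(phases)
    if (!all(c("strategy", "batch_size", "n_cycles") %in% names(phases))) {
      abort("Custom `phases` need columns strategy, batch_size, n_cycles.")
    }
    if (!all(phases$strategy %in% c("random", "explore", "exploit"))) {
      abort("Phase strategies must be random, explore or exploit.")
    }
    phases$batch_size <- as.integer(phases$batch_size)
    phases$n_cycles <- as.integer(phases$n_cycles)
    name <- name %||% "custom"
  }
  if (phases$strategy[1] != "random") {
    abort("The first phase must use the random strategy (no model exists yet).")
  }
  total <- sum(phases$batch_size * phases$n_cycles)
  if (total != total_budget) {
    abort(sprintf("Phases acquire %d compounds but the budget is %d (deficit %d).",
                  total, total_budget, total_budget - total))
  }
  structure(list(name = name, phases = phases, total_budget = total_budget),
            class = "al_protocol")
}

#' @export
print.al_protocol <- function(x, ...) {
  cat(sprintf("AL protocol '%s' (budget %d):\n", x$name, x$total_budget))
  for (i in seq_len(nrow(x$phases))) {
    cat(sprintf("  %d. %s: %d cycle(s) of %d\n", i, x$phases$strategy[i],
                x$phases$n_cycles[i], x$phases$batch_size[i]))
  }
  invisible(x)
}

#' Gaussian label-noise specification
#'
#' Describes the noise added to training labels in the robustness experiment:
#' zero-mean Gaussian noise whose standard deviation is `multiplier` times
#' the population SD of the pool's potencies, so that the relative noise
#' level is comparable across pools with different potency spreads. The
#' benchmark grid uses multipliers 0, 0.5, 1, 1.5 and 2.
#'
#' @param multiplier Non-negative noise multiplier; 0 means noiseless labels.
#' @param seed Optional integer seed; when `NULL`, [run_campaign()] derives
#'   one from its master seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(multiplier = 0, seed = NULL) {
  multiplier <- check_number(multiplier, "multiplier", min = 0)
  structure(list(multiplier = multiplier,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "noise_spec")
}

#' Add Gaussian noise to potency labels
#'
#' Draws one noise term per compound, `noisy[i] = potency[i] + e_i` with
#' `e_i ~ N(0, (multiplier * pool_sd)^2)`. A multiplier of 0 returns the
#' input unchanged. The draw is a pure function of the spec's seed: a label,
#' once "measured", stays fixed for the whole campaign.
#'
#' @param potency Numeric vector of true potencies, pK units.
#' @param pool_sd Population SD of the pool's potencies (see [potency_sd()]).
#' @param spec A [noise_spec()] with a non-`NULL` seed.
#' @return Numeric vector of noisy potencies.
#' @export
add_label_noise <- function(potency, pool_sd, spec) {
  if (!inherits(spec, "noise_spec")) abort("`spec` must be created with noise_spec().")
  pool_sd <- check_number(pool_sd, "pool_sd", min = 0)
  if (any(!is.finite(potency))) abort("All potencies must be finite.")
  if (spec$multiplier == 0) return(potency)
  if (is.null(spec$seed)) abort("`spec$seed` must be set to draw noise.")
  noise_sd <- spec$multiplier * pool_sd
  potency + local_seed_eval(spec$seed, rnorm(length(potency), 0, noise_sd))
}

#' Cost of labeling compounds by alchemical free-energy calculation
#'
#' Linear cost model for relative binding free energy (RBFE) labeling on GPU
#' hardware: `n_compounds * gpu_hours_each * rate`. At the defaults (8 GPU
#' hours per compound, 2.50 USD per GPU hour) labeling a 5000-compound
#' library costs 100,000 USD while an active-learning campaign labeling 300
#' compounds costs 6,000 USD.
#'
#' @param n_compounds Number of compounds labeled.
#' @param gpu_hours_each GPU hours per RBFE calculation.
#' @param rate USD per GPU hour.
#' @return Cost in USD.
#' @examples
#' rbfe_cost(5000)
#' rbfe_cost(300)
#' @export
rbfe_cost <- function(n_compounds, gpu_hours_each = 8, rate = 2.50) {
  n_compounds <- check_number(n_compounds, "n_compounds", min = 0)
  gpu_hours_each <- check_number(gpu_hours_each, "gpu_hours_each", min = 0)
  rate <- check_number(rate, "rate", min = 0)
  n_compounds * gpu_hours_each * rate
}
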