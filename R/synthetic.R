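#' Define a synthetic structure-activity library scenario
#'
#' A scenario describes a synthetic compound library with explicit cluster
#' (congeneric-series) structure: each cluster has a set of dedicated "core"
#' fingerprint bits shared by every member (its scaffold) and a set of
#' "substituent" bits of which each member carries a random subset (its
#' R-group decoration). Potency follows an additive structure-activity model,
#'
#'   potency = cluster effect + sum of substituent-bit effects + residual,
#'
#' with the cluster effect drawn from N(0, `cluster_effect_sd`), each
#' substituent bit contributing a fixed per-cluster coefficient drawn from
#' N(0, `substituent_effect_sd`), and an i.i.d. N(0, `residual_sd`) residual.
#' This gives a Gaussian-process surrogate a learnable smooth signal within
#' series, plus between-series jumps, which is the qualitative structure of
#' real lead-optimization libraries.
#'
#' `active_cluster_fraction` controls how concentrated the top binders are:
#' the largest drawn cluster effects are assigned to the first
#' `ceiling(fraction * n_clusters)` clusters, so a small fraction concentrates
#' the actives in a few series (as in a combinatorial congeneric library)
#' while 1 leaves them dispersed.
#'
#' @param n_compounds Number of compounds to generate.
#' @param n_clusters Number of clusters (congeneric series).
#' @param cluster_size_dispersion Non-negative dispersion of cluster sizes:
#'   0 gives deterministic near-equal sizes; larger values draw multinomial
#'   cluster probabilities from an increasingly skewed Dirichlet.
#' @param core_bits_per_cluster Number of scaffold bits per cluster.
#' @param substituent_bits Number of substituent bits per cluster.
#' @param fingerprint_length Total fingerprint length (default 4096).
#' @param cluster_effect_sd SD of the between-cluster potency effect, pK units.
#' @param substituent_effect_sd SD of per-bit substituent coefficients, pK units.
#' @param residual_sd SD of the residual, pK units.
#' @param active_cluster_fraction Fraction in (0, 1] of clusters that receive
#'   the largest cluster effects.
#' @param seed Integer seed; the generated library is a pure function of the
#'   scenario, including this seed.
#'
#' @return An object of class `synthetic_scenario`.
#' @seealso [scenario_preset()], [generate_library()]
#' @export
synthetic_scenario <- function(n_compounds, n_clusters,
                               cluster_size_dispersion = 0,
                               core_bits_per_cluster = 24,
                               substituent_bits = 32,
                               fingerprint_length = 4096,
                               cluster_effect_sd = 1,
                               substituent_effect_sd = 0.25,
                               residual_sd = 0.3,
                               active_cluster_fraction = 1,
                               seed = 1L) {
  n_compounds <- check_count(n_compounds, "n_compounds")
  n_clusters <- check_count(n_clusters, "n_clusters")
  if (n_compounds < n_clusters) {
    abort("`n_compounds` must be at least `n_clusters`.")
  }
  cluster_size_dispersion <- check_number(cluster_size_dispersion, "cluster_size_dispersion", min = 0)
  core_bits_per_cluster <- check_count(core_bits_per_cluster, "core_bits_per_cluster")
  substituent_bits <- check_count(substituent_bits, "substituent_bits", min = 0)
  fingerprint_length <- check_count(fingerprint_length, "fingerprint_length")
  if (fingerprint_length < core_bits_per_cluster + substituent_bits) {
    abort(sprintf(
      "Infeasible bit budget: core (%d) + substituent (%d) bits exceed fingerprint_length (%d).",
      core_bits_per_cluster, substituent_bits, fingerprint_length))
  }
  cluster_effect_sd <- check_number(cluster_effect_sd, "cluster_effect_sd", min = 0)
  substituent_effect_sd <- check_number(substituent_effect_sd, "substituent_effect_sd", min = 0)
  residual_sd <- check_number(residual_sd, "residual_sd", min = 0)
  active_cluster_fraction <- check_number(active_cluster_fraction, "active_cluster_fraction", min = 0, strict = TRUE)
  if (active_cluster_fraction > 1) abort("`active_cluster_fraction` must be in (0, 1].")
  structure(
    list(n_compounds = n_compounds, n_clusters = n_clusters,
         cluster_size_dispersion = cluster_size_dispersion,
         core_bits_per_cluster = core_bits_per_cluster,
         substituent_bits = substituent_bits,
         fingerprint_length = fingerprint_length,
         cluster_effect_sd = cluster_effect_sd,
         substituent_effect_sd = substituent_effect_sd,
         residual_sd = residual_sd,
         active_cluster_fraction = active_cluster_fraction,
         seed = as.integer(seed)),
    class = "synthetic_scenario")
}

#' Preset scenarios emulating the benchmark's dataset regimes
#'
#' Three presets emulate the qualitative regimes of public binding-affinity
#' pools used in active-learning benchmarking:
#'
#' * `"congeneric"`: a combinatorial lead-optimization library — few (8)
#'   large clusters with strong scaffold signal, top binders concentrated in
#'   2 of them, n = 2000, pooled potency SD about 1.4 pK units.
#' * `"heterogeneous"`: many small congeneric series — 150 series of 15
#'   compounds each, actives dispersed across series, pooled SD about 1.4.
#' * `"small-diverse"`: a small screening pool (n = 600) with weak cluster
#'   signal and pooled SD about 0.9, where a 360-compound budget acquires
#'   more than half the pool.
#'
#' @param name One of `"congeneric"`, `"heterogeneous"`, `"small-diverse"`.
#' @param n_compounds Optional override of the preset's pool size.
#' @param seed Integer seed passed into the scenario.
#' @return A [synthetic_scenario()].
#' @examples
#' scenario_preset("congeneric")
#' @export
scenario_preset <- function(name, n_compounds = NULL, seed = 1L) {
  presets <- c("congeneric", "heterogeneous", "small-diverse")
  if (length(name) != 1 || !name %in% presets) {
    abort(sprintf("Unknown scenario '%s'; valid presets are: %s.",
                  paste(name, collapse = ", "), paste(presets, collapse = ", ")))
  }
  sc <- switch(name,
    "congeneric" = synthetic_scenario(
      n_compounds = n_compounds %||% 2000L, n_clusters = 8L,
      cluster_size_dispersion = 0.25,
      core_bits_per_cluster = 32L, substituent_bits = 48L,
      cluster_effect_sd = 1.45, substituent_effect_sd = 0.16, residual_sd = 0.30,
      active_cluster_fraction = 0.25, seed = seed),
    "heterogeneous" = synthetic_scenario(
      n_compounds = n_compounds %||% 2250L, n_clusters = 150L,
      cluster_size_dispersion = 0,
      core_bits_per_cluster = 24L, substituent_bits = 24L,
      cluster_effect_sd = 1.2, substituent_effect_sd = 0.20, residual_sd = 0.39,
      active_cluster_fraction = 1, seed = seed),
    "small-diverse" = synthetic_scenario(
      n_compounds = n_compounds %||% 600L, n_clusters = 60L,
      cluster_size_dispersion = 0,
      core_bits_per_cluster = 16L, substituent_bits = 16L,
      cluster_effect_sd = 0.55, substituent_effect_sd = 0.18, residual_sd = 0.50,
      active_cluster_fraction = 1, seed = seed))
  sc
}

#' Generate a synthetic compound library
#'
#' Deterministically expands a [synthetic_scenario()] into a
#' [compound_pool()]: identical scenarios (including the seed) give
#' bit-identical pools. See [synthetic_scenario()] for the generative model.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A [compound_pool()] of exactly `n_compounds` compounds with
#'   `cluster_id` provenance.
#' @examples
#' pool <- generate_library(scenario_preset("small-diverse"))
#' nrow(pool)
#' potency_sd(pool)
#' @export
generate_library <- function(scenario) {
  if (!inherits(scenario, "synthetic_scenario")) {
    abort("`scenario` must be created with synthetic_scenario() or scenario_preset().")
  }
  s <- scenario
  local_seed_eval(s$seed, {
    k <- s$n_clusters
    n <- s$n_compounds

    # cluster sizes: deterministic near-equal split at dispersion 0, otherwise
    # multinomial with Dirichlet-like weights (every cluster keeps >= 1 member)
    if (s$cluster_size_dispersion == 0) {
      sizes <- rep(n %/% k, k) + as.integer(seq_len(k) <= n %% k)
    } else {
      shape <- 1 / s$cluster_size_dispersion
      w <- rgamma(k, shape = shape, rate = shape)
      sizes <- as.integer(rmultinom(1, n - k, w / sum(w))) + 1L
    }
    cluster_id <- rep.int(seq_len(k), sizes)

    # per-cluster bit vocabulary: disjoint core vs substituent bits within a
    # cluster; clusters sample their bits independently over the full length
    nb <- s$core_bits_per_cluster + s$substituent_bits
    bit_sets <- lapply(seq_len(k), function(c) sample.int(s$fingerprint_length, nb))
    core_bits <- lapply(bit_sets, function(b) b[seq_len(s$core_bits_per_cluster)])
    sub_bits <- lapply(bit_sets, function(b) b[-seq_len(s$core_bits_per_cluster)])

    # cluster effects; the largest effects go to the designated active clusters
    mu <- rnorm(k, 0, s$cluster_effect_sd)
    if (s$active_cluster_fraction < 1) {
      n_active <- ceiling(s$active_cluster_fraction * k)
      ord <- order(mu, decreasing = TRUE)
      mu <- c(mu[ord][seq_len(n_active)], mu[ord][-seq_len(n_active)])
    }
    beta <- lapply(seq_len(k), function(c) rnorm(s$substituent_bits, 0, s$substituent_effect_sd))

    fp <- matrix(0, nrow = n, ncol = s$fingerprint_length)
    potency <- numeric(n)
    for (c in seq_len(k)) {
      idx <- which(cluster_id == c)
      fp[idx, core_bits[[c]]] <- 1
      if (s$substituent_bits > 0) {
        on <- matrix(stats::runif(length(idx) * s$substituent_bits) < 0.5,
                     nrow = length(idx))
        fp[idx, sub_bits[[c]]] <- on + 0
        potency[idx] <- mu[c] + drop(on %*% beta[[c]])
      } else {
        potency[idx] <- mu[c]
      }
    }
    potency <- potency + rnorm(n, 0, s$residual_sd)

    compound_pool(sprintf("cpd%05d", seq_len(n)), potency,
                  fingerprints = fp, cluster_id = cluster_id)
  })
}
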