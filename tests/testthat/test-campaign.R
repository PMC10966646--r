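# A small clustered pool keeps GP campaigns fast while preserving signal.
small_clustered_pool <- function(n = 150, seed = 17) {
  generate_library(synthetic_scenario(
    n, 6, seed = seed, fingerprint_length = 256, core_bits_per_cluster = 12,
    substituent_bits = 12, cluster_effect_sd = 1.2, substituent_effect_sd = 0.2,
    residual_sd = 0.3, active_cluster_fraction = 0.5))
}

mini_protocol <- function() {
  build_protocol(phases = data.frame(
    strategy = c("random", "explore", "exploit"),
    batch_size = c(20L, 10L, 10L), n_cycles = c(1L, 1L, 3L)),
    total_budget = 60)
}

test_that("a random-only protocol yields one cycle of the stated size", {
  pool <- small_clustered_pool(80)
  proto <- build_protocol(phases = data.frame(strategy = "random", batch_size = 60L,
                                              n_cycles = 1L), total_budget = 60)
  camp <- run_campaign(pool, proto, oracle_surrogate(), noise_spec(0), seed = 1)
  expect_equal(nrow(camp$trajectory), 1)
  expect_equal(camp$trajectory$n_acquired, 60)
  expect_false(camp$truncated)
})

test_that("budget conservation, distinct ids and monotone recall hold", {
  pool <- small_clustered_pool()
  camp <- run_campaign(pool, mini_protocol(), gp_surrogate(init = gp_hyperparams(fit_iterations = 40)),
                       noise_spec(0), seed = 2)
  ids <- unlist(camp$log$ids)
  expect_equal(length(ids), 60)            # budget conservation
  expect_false(anyDuplicated(ids) > 0)     # no re-acquisition
  expect_true(all(diff(camp$trajectory$recall_top2) >= 0))
  expect_true(all(diff(camp$trajectory$recall_top5) >= 0))
  expect_true(all(ids %in% pool$id))
  expect_equal(camp$trajectory$n_acquired, cumsum(lengths(camp$log$ids)))
})

test_that("campaigns are pure functions of the master seed", {
  pool <- small_clustered_pool(100)
  surr <- gp_surrogate(init = gp_hyperparams(fit_iterations = 30))
  c1 <- run_campaign(pool, mini_protocol(), surr, noise_spec(0.5), seed = 5)
  c2 <- run_campaign(pool, mini_protocol(), surr, noise_spec(0.5), seed = 5)
  expect_identical(c1$trajectory, c2$trajectory)
  expect_identical(c1$log$ids, c2$log$ids)
  c3 <- run_campaign(pool, mini_protocol(), surr, noise_spec(0.5), seed = 6)
  expect_false(identical(c1$log$ids[[1]], c3$log$ids[[1]]))
})

test_that("a budget above the pool size exhausts the pool and flags truncation", {
  pool <- small_clustered_pool(100)
  proto <- build_protocol(phases = data.frame(
    strategy = c("random", "exploit"), batch_size = c(60L, 30L), n_cycles = c(1L, 10L)),
    total_budget = 360)
  camp <- run_campaign(pool, proto, oracle_surrogate(), noise_spec(0), seed = 3)
  expect_true(camp$truncated)
  expect_equal(max(camp$trajectory$n_acquired), 100) # min(budget, pool)
  expect_setequal(unlist(camp$log$ids), pool$id)
  # once everything is acquired recall is exactly 1
  expect_equal(dplyr::last(camp$trajectory$recall_top2), 1)
})

test_that("a perfect oracle with pure exploitation hits the recall ceiling", {
  pool <- small_clustered_pool(200)
  spec <- top_k_spec(pool, 0.02)
  proto <- build_protocol(phases = data.frame(
    strategy = c("random", "exploit"), batch_size = c(10L, 10L), n_cycles = c(1L, 2L)),
    total_budget = 30)
  camp <- run_campaign(pool, proto, oracle_surrogate(), noise_spec(0), seed = 4)
  # after the exploit cycles N_acq >= k, so every active compound is in hand
  expect_gte(max(camp$trajectory$n_acquired), spec$k)
  expect_equal(dplyr::last(camp$trajectory$recall_top2), 1)
})

test_that("repeat_campaigns aggregates mean and min-max bands across seeds", {
  pool <- small_clustered_pool(100)
  surr <- oracle_surrogate()
  one <- repeat_campaigns(pool, mini_protocol(), surr, noise_spec(0), seeds = 1)
  expect_true(all(one$summary$min == one$summary$max)) # single seed: no band

  reps <- repeat_campaigns(pool, mini_protocol(), surr, noise_spec(0), seeds = 1:3)
  expect_equal(nrow(reps$trajectories), 3 * 5)
  expect_true(all(reps$summary$min <= reps$summary$mean + 1e-12))
  expect_true(all(reps$summary$max >= reps$summary$mean - 1e-12))
  # initial random batches differ between seeds, protocol structure does not
  first_batches <- purrr::map(reps$campaigns, ~ .x$log$ids[[1]])
  expect_false(identical(first_batches[[1]], first_batches[[2]]))
  expect_identical(reps$campaigns[[1]]$trajectory$strategy,
                   reps$campaigns[[2]]$trajectory$strategy)

  rerun <- repeat_campaigns(pool, mini_protocol(), surr, noise_spec(0), seeds = 1:3)
  expect_identical(rerun$summary, reps$summary)

  counts <- acquisition_counts(reps)
  expect_true(all(counts$n_campaigns_acquired %in% 1:3))
  expect_true(all(counts$id %in% pool$id))
})

test_that("tidy, glance and autoplot expose campaign results", {
  pool <- small_clustered_pool(100)
  camp <- run_campaign(pool, mini_protocol(), oracle_surrogate(), noise_spec(0), seed = 1)
  expect_identical(tidy(camp), camp$trajectory)
  gl <- glance(camp)
  expect_equal(gl$cycle, 5)
  expect_s3_class(autoplot(camp), "ggplot")
  reps <- repeat_campaigns(pool, mini_protocol(), oracle_surrogate(), noise_spec(0), seeds = 1:2)
  expect_s3_class(autoplot(reps), "ggplot")
  expect_s3_class(autoplot(reps, metric = "spearman"), "ggplot")
})
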